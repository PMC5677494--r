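## Internal MCMC engine: Hamiltonian Monte Carlo within Gibbs.
##
## Parameterization is non-centred: the HMC block holds the fixed
## effects and zero-part coefficients (normal priors, SD `beta_sd`)
## together with standardized smooth coefficients and random effects
## (iid standard-normal priors). The group scales — one smoothing SD per
## phase smooth, the survey SD and the transect-within-survey SD —
## multiply the standardized coefficients inside the linear predictor
## and are updated by univariate slice sampling of the data likelihood
## on the log scale, as is the NB dispersion. Non-centring removes the
## funnel geometry between coefficients and their scales when the data
## permit small scales, which is exactly the regime of weak spatial or
## survey-level structure.
##
## The zero-inflation indicators of the ZIP model are marginalized out
## of the likelihood, so the posterior is smooth and gradient-based
## updates are valid.

## Unnormalized log-likelihood (additive terms depending on y alone are
## dropped: they cancel in MH ratios and slice-level comparisons) and
## d(loglik)/d(linear predictors).
.ll_grad <- function(family, y, eta, theta = NULL, g = NULL) {
  mu <- exp(eta)
  if (family == "NB") {
    ll <- sum(y * eta - (y + theta) * log(mu + theta))
    list(ll = ll, weta = y - (y + theta) * mu / (mu + theta), wg = NULL)
  } else {
    pi0 <- stats::plogis(g)
    pos <- y > 0
    weta <- numeric(length(y)); wg <- numeric(length(y))
    ll <- 0
    if (any(pos)) {
      ll <- sum(log1p(-pi0[pos]) + y[pos] * eta[pos] - mu[pos])
      weta[pos] <- y[pos] - mu[pos]
      wg[pos] <- -pi0[pos]
    }
    z <- !pos
    if (any(z)) {
      em <- exp(-mu[z])
      p0 <- pi0[z] + (1 - pi0[z]) * em
      ll <- ll + sum(log(p0))
      weta[z] <- -(1 - pi0[z]) * em * mu[z] / p0
      wg[z] <- pi0[z] * (1 - pi0[z]) * (1 - em) / p0
    }
    list(ll = ll, weta = weta, wg = wg)
  }
}

.ll_only <- function(family, y, eta, theta = NULL, g = NULL) {
  mu <- exp(eta)
  if (family == "NB")
    return(sum(y * eta - (y + theta) * log(mu + theta)))
  pi0 <- stats::plogis(g)
  pos <- y > 0
  ll <- 0
  if (any(pos))
    ll <- sum(log1p(-pi0[pos]) + y[pos] * eta[pos] - mu[pos])
  if (any(!pos)) {
    z <- !pos
    ll <- ll + sum(log(pi0[z] + (1 - pi0[z]) * exp(-mu[z])))
  }
  ll
}

## per-coordinate scale vector (non-centred parameterization) and prior
## precision for the HMC block
.coord_scales <- function(dat, sig) {
  sc <- rep(1, dat$P)
  for (lv in names(dat$grp$smooth))
    sc[dat$grp$smooth[[lv]]] <- sig[paste0("sigma_smooth_", lv)]
  sc[dat$grp$survey] <- sig["sigma_survey"]
  sc[dat$grp$transect] <- sig["sigma_transect"]
  sc
}

.prior_prec <- function(dat, beta_sd) {
  pr <- rep(1, dat$P)
  pr[dat$grp$fixed] <- 1 / beta_sd^2
  if (length(dat$idx_zero)) pr[dat$idx_zero] <- 1 / beta_sd^2
  pr
}

## negative log posterior (potential) and gradient at standardized v
.make_potential <- function(dat, prior_prec) {
  force(dat); force(prior_prec)
  function(v, sc, theta) {
    cv <- v * sc
    eta <- drop(dat$X %*% cv[dat$idx_count]) + dat$offset
    g <- if (dat$family == "ZIP") drop(dat$Xz %*% cv[dat$idx_zero])
    lg <- .ll_grad(dat$family, dat$y, eta, theta, g)
    val <- -(lg$ll - 0.5 * sum(prior_prec * v^2))
    gr <- numeric(length(v))
    gr[dat$idx_count] <- drop(crossprod(dat$X, lg$weta))
    if (dat$family == "ZIP")
      gr[dat$idx_zero] <- drop(crossprod(dat$Xz, lg$wg))
    list(val = val, grad = -(gr * sc - prior_prec * v))
  }
}

## univariate slice sampler (Neal 2003, stepping out + shrinkage)
.slice1 <- function(x0, logf, w = 1, m = 30) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero density")
  logy <- f0 - stats::rexp(1)
  L <- x0 - stats::runif(1) * w
  R <- L + w
  j <- floor(stats::runif(1) * m)
  k <- m - 1 - j
  while (j > 0 && logf(L) > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) > logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

## one leapfrog HMC transition; returns new state and acceptance prob
.hmc_step <- function(v, potential, sc, theta, eps, L, mass) {
  p <- stats::rnorm(length(v), 0, sqrt(mass))
  cur <- potential(v, sc, theta)
  H0 <- cur$val + sum(p^2 / (2 * mass))
  vn <- v
  p1 <- p - eps / 2 * cur$grad
  prop <- cur
  for (l in seq_len(L)) {
    vn <- vn + eps * p1 / mass
    prop <- potential(vn, sc, theta)
    if (!is.finite(prop$val)) break
    p1 <- p1 - eps * (if (l < L) 1 else 0.5) * prop$grad
  }
  if (!is.finite(prop$val)) return(list(v = v, aprob = 0))
  H1 <- prop$val + sum(p1^2 / (2 * mass))
  aprob <- min(1, exp(H0 - H1))
  if (!is.finite(aprob)) aprob <- 0
  if (stats::runif(1) < aprob) list(v = vn, aprob = aprob)
  else list(v = v, aprob = aprob)
}

## run one chain; returns post-warmup draws for coefficients and hypers
## on the natural (centred) scale
.run_chain <- function(dat, spec, chain_seed, init) {
  set.seed(chain_seed)
  P <- dat$P
  v <- init$v + stats::rnorm(P, 0, 0.05)
  sig <- init$sig
  theta <- init$theta
  nw <- spec$warmup
  nd <- spec$draws
  Lbase <- spec$hmc$L
  target <- spec$hmc$target_accept
  prior_prec <- .prior_prec(dat, spec$priors$beta_sd)
  potential <- .make_potential(dat, prior_prec)
  half_sd <- spec$priors$sd_scale

  eps <- 0.05
  da_init <- function(eps) list(mu = log(10 * eps), lbar = log(eps),
                                hbar = 0, g = 0.05, t0 = 10,
                                kappa = 0.75, i = 0, eps = eps)
  da <- da_init(eps)
  da_update <- function(da, aprob) {
    da$i <- da$i + 1
    da$hbar <- (1 - 1 / (da$i + da$t0)) * da$hbar +
      (target - aprob) / (da$i + da$t0)
    leps <- da$mu - sqrt(da$i) / da$g * da$hbar
    w <- da$i^(-da$kappa)
    da$lbar <- w * leps + (1 - w) * da$lbar
    da$eps <- exp(leps)
    da
  }

  mass <- rep(1, P)
  win <- floor(c(0.35, 0.75) * nw)
  keep <- matrix(NA_real_, nd, P + length(sig) + !is.na(theta))
  win_draws <- matrix(NA_real_, win[2] - win[1] + 1, P)

  for (it in seq_len(nw + nd)) {
    adapting <- it <= nw
    L <- sample(max(2, Lbase - 3):(Lbase + 3), 1)
    sc <- .coord_scales(dat, sig)
    st <- .hmc_step(v, potential, sc, theta, eps, L, mass)
    v <- st$v
    if (adapting) {
      da <- da_update(da, st$aprob)
      eps <- min(da$eps, 1)
      if (it >= win[1] && it <= win[2])
        win_draws[it - win[1] + 1, ] <- v
      if (it == win[2]) {
        vv <- apply(win_draws, 2, stats::var)
        mass <- 1 / pmax(vv, 1e-4)
        da <- da_init(eps)
      }
      if (it == nw) eps <- exp(da$lbar)
    }

    ## Ancillarity moves: exact Gaussian Gibbs updates along directions
    ## that leave the likelihood invariant (a shear reparameterization
    ## with unit Jacobian). A phase-level coefficient plus a common
    ## shift of its surveys' standardized effects, and a survey effect
    ## plus a common shift of its transects' effects, are such
    ## directions because surveys nest in phases and transects in
    ## surveys. These decouple the intercept/phase contrasts from the
    ## random effects, whose joint posterior is otherwise a slow ridge.
    bsd2 <- spec$priors$beta_sd^2
    ss <- sig["sigma_survey"]; st <- sig["sigma_transect"]
    for (an in dat$ancil_phase) {
      ns <- length(an$surveys)
      if (!ns) next
      tau <- 1 / bsd2 + ns / ss^2
      m <- (-v[an$fixed] / bsd2 + sum(v[an$surveys]) / ss) / tau
      delta <- stats::rnorm(1, m, sqrt(1 / tau))
      v[an$fixed] <- v[an$fixed] + delta
      v[an$surveys] <- v[an$surveys] - delta / ss
    }
    for (an in dat$ancil_survey) {
      nt <- length(an$transects)
      if (!nt) next
      tau <- 1 / ss^2 + nt / st^2
      m <- (-v[an$survey] / ss + sum(v[an$transects]) / st) / tau
      delta <- stats::rnorm(1, m, sqrt(1 / tau))
      v[an$survey] <- v[an$survey] + delta / ss
      v[an$transects] <- v[an$transects] - delta / st
    }

    ## Gibbs: group scales by slice sampling of the data likelihood on
    ## log sigma (non-centred, so sigma enters the likelihood linearly
    ## through its group's contribution gvec)
    cv <- v * .coord_scales(dat, sig)
    eta <- drop(dat$X %*% cv[dat$idx_count]) + dat$offset
    gz <- if (dat$family == "ZIP") drop(dat$Xz %*% cv[dat$idx_zero])
    for (nm in names(sig)) {
      idx <- switch(nm,
        sigma_survey = dat$grp$survey,
        sigma_transect = dat$grp$transect,
        dat$grp$smooth[[sub("sigma_smooth_", "", nm)]])
      gvec <- drop(dat$X[, idx, drop = FALSE] %*% v[idx])
      base <- eta - sig[nm] * gvec
      lf <- function(z) {
        s <- exp(z)
        .ll_only(dat$family, dat$y, base + s * gvec, theta, gz) -
          s^2 / (2 * half_sd^2) + z
      }
      sig[nm] <- exp(.slice1(log(sig[nm]), lf, w = 0.7))
      eta <- base + sig[nm] * gvec
      ## interweaving (ASIS): re-update the scale in the centred
      ## parameterization, holding the natural-scale coefficients
      ## b = sigma * v fixed (likelihood-invariant), then map back.
      ## The centred conditional depends only on b and the prior.
      b_nat <- sig[nm] * v[idx]
      ssq <- sum(b_nat^2)
      q <- length(idx)
      lf2 <- function(z)
        -q * z - ssq / 2 * exp(-2 * z) - exp(2 * z) / (2 * half_sd^2) + z
      sig[nm] <- exp(.slice1(log(sig[nm]), lf2, w = 0.7))
      v[idx] <- b_nat / sig[nm]
    }

    ## NB dispersion: slice on log theta against the full likelihood;
    ## lgamma(y + theta) is accumulated over the tabulated distinct
    ## counts, the rest is vectorized without special functions
    if (dat$family == "NB") {
      mu <- exp(eta)
      a <- spec$priors$theta_shape; b <- spec$priors$theta_rate
      n <- length(dat$y)
      lf <- function(z) {
        th <- exp(z)
        sum(dat$ytab$n * lgamma(dat$ytab$u + th)) - n * lgamma(th) +
          n * th * log(th) - sum((dat$y + th) * log(mu + th)) +
          a * z - b * th
      }
      theta <- exp(.slice1(log(theta), lf, w = 0.7))
    }

    if (!adapting)
      keep[it - nw, ] <- c(v * .coord_scales(dat, sig), sig,
                           if (!is.na(theta)) theta)
  }
  colnames(keep) <- c(dat$par_names, names(sig),
                      if (!is.na(theta)) "theta")
  keep
}
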