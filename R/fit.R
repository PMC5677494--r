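## Model specification and fitting front-end for the two hierarchical
## count models:
##
##   NB GAMM  (seabird):  y_i ~ NB(mu_i, theta)
##   ZIP GAMM (cetacean): y_i ~ ZIP(mu_i, pi0_i)
##
##   log mu_i  = beta_phase + f_phase(x_i, y_i) + b_survey + b_transect
##               + log(effort_i / nominal)
##   logit pi0_i = gamma0 + gamma_cond * [condition_i == "poor"]   (ZIP)
##
## with phase-varying two-dimensional smooths f_phase, nested random
## effects (transect within survey) and the preconstruction phase as
## baseline.

#' Specify a count GAMM
#'
#' @param family `"NB"` (negative binomial, log link) or `"ZIP"`
#'   (zero-inflated Poisson; log link for the count part, logit link for
#'   the extra-zero part).
#' @param knots number of spatial knots per smooth (default 25).
#' @param chains,warmup,draws MCMC settings (chains >= 2 for R-hat).
#' @param seed integer seed; the fit is reproducible given the seed.
#' @param priors list: `beta_sd` (SD of the normal prior on fixed and
#'   zero-part coefficients, default 10), `sd_scale` (scale of the
#'   half-normal priors on random-effect and smoothing SDs, default 2),
#'   `theta_shape`, `theta_rate` (gamma prior on the NB dispersion,
#'   default 0.01, 0.01).
#' @param hmc list: `L` (baseline number of leapfrog steps, default 12),
#'   `target_accept` (dual-averaging target, default 0.8).
#' @return an object of class `disp_spec`.
#' @export
model_spec <- function(family = c("NB", "ZIP"), knots = 25,
                       chains = 3, warmup = 1000, draws = 1000, seed = 1,
                       priors = list(), hmc = list()) {
  family <- match.arg(family)
  if (chains < 2) warning("fewer than 2 chains: R-hat unavailable")
  pr <- utils::modifyList(
    list(beta_sd = 10, sd_scale = 2, theta_shape = 0.01, theta_rate = 0.01),
    priors)
  h <- utils::modifyList(list(L = 12, target_accept = 0.8), hmc)
  structure(list(family = family, knots = knots, chains = chains,
                 warmup = warmup, draws = draws, seed = seed,
                 priors = pr, hmc = h),
            class = "disp_spec")
}

## assemble design matrices and bookkeeping for the sampler
.build_fit_data <- function(seg, spec) {
  y <- seg$count
  ph <- droplevels(factor(seg$phase, levels = PHASE_LEVELS))
  lev <- levels(ph)
  nominal <- attr(seg, "nominal_length") %||% max(seg$effort_m)
  offset <- log(seg$effort_m / nominal)
  coords <- cbind(seg$x, seg$y)
  kn <- place_knots(coords, spec$knots, seed = spec$seed)
  basis <- build_basis(coords, kn)
  pb <- expand_by_phase(basis, ph)
  ctr <- c(x = mean(seg$x), y = mean(seg$y))
  xs <- (seg$x - ctr["x"]) / 1000
  ys <- (seg$y - ctr["y"]) / 1000
  Xf <- cbind(`(Intercept)` = rep(1, length(y)))
  for (lv in lev[-1]) {
    col <- as.numeric(ph == lv)
    Xf <- cbind(Xf, col)
    colnames(Xf)[ncol(Xf)] <- paste0("phase_", lv)
  }
  for (lv in lev) {
    ind <- as.numeric(ph == lv)
    Xf <- cbind(Xf, xs * ind, ys * ind)
    colnames(Xf)[ncol(Xf) - 1:0] <- paste0(c("lin_x_", "lin_y_"), lv)
  }
  sv <- factor(seg$survey_id)
  tr <- factor(paste(seg$survey_id, seg$transect_id, sep = ":"))
  Zs <- stats::model.matrix(~ sv - 1)
  Zt <- stats::model.matrix(~ tr - 1)
  X <- cbind(Xf, pb$design, Zs, Zt)
  q <- pb$rank
  nf <- ncol(Xf)
  par_names <- c(
    colnames(Xf),
    unlist(lapply(lev, function(lv) paste0("s_", lv, "[", 1:q, "]"))),
    paste0("b_survey[", levels(sv), "]"),
    paste0("b_transect[", levels(tr), "]"))
  grp <- list(
    fixed = seq_len(nf),
    smooth = stats::setNames(lapply(seq_along(lev), function(p)
      nf + ((p - 1) * q + 1):(p * q)), lev),
    survey = nf + length(lev) * q + seq_len(nlevels(sv)),
    transect = nf + length(lev) * q + nlevels(sv) + seq_len(nlevels(tr)))
  idx_count <- seq_len(ncol(X))
  ## likelihood-invariant directions for the ancillarity Gibbs moves:
  ## each phase's level coefficient trades off against its surveys'
  ## random effects (surveys nest in phases), and each survey's effect
  ## against its transects' effects
  sv_phase <- tapply(as.character(ph), sv, function(x) x[1])
  ancil_phase <- lapply(seq_along(lev), function(p) {
    if (p == 1)  # the intercept shifts every segment: pair all surveys
      list(fixed = 1L, surveys = grp$survey)
    else
      list(fixed = which(colnames(Xf) == paste0("phase_", lev[p])),
           surveys = grp$survey[which(sv_phase == lev[p])])
  })
  tr_survey <- tapply(as.character(sv), tr, function(x) x[1])
  ancil_survey <- lapply(seq_len(nlevels(sv)), function(s) {
    list(survey = grp$survey[s],
         transects = grp$transect[which(tr_survey == levels(sv)[s])])
  })
  if (spec$family == "ZIP") {
    poor <- as.numeric(seg$condition == "poor")
    Xz <- cbind(gamma0 = rep(1, length(y)), gamma_cond = poor)
    par_names <- c(par_names, "gamma0", "gamma_cond")
    idx_zero <- ncol(X) + 1:2
  } else {
    Xz <- NULL
    idx_zero <- integer(0)
  }
  ytab <- as.data.frame(table(y))
  ytab <- data.frame(u = as.numeric(as.character(ytab$y)), n = ytab$Freq)
  list(family = spec$family, y = y, ytab = ytab, X = X, Xz = Xz,
       offset = offset,
       P = ncol(X) + length(idx_zero),
       idx_count = idx_count, idx_zero = idx_zero,
       grp = grp, par_names = par_names,
       ancil_phase = ancil_phase, ancil_survey = ancil_survey,
       levels = lev, basis = basis, nominal = nominal, ctr = ctr,
       hull = .convex_hull(seg$x, seg$y),
       survey_levels = levels(sv), transect_levels = levels(tr))
}

#' Fit a spatial count GAMM by MCMC
#'
#' Fits the NB or ZIP GAMM to a segment table by HMC-within-Gibbs (see
#' the package vignette for the sampler design). Convergence is assessed
#' with split-free between-chain R-hat and effective sample sizes via
#' \pkg{coda}; a fit whose worst monitored R-hat exceeds 1.1 is returned
#' with `converged = FALSE` (degraded status), not discarded.
#'
#' @param seg a `segment_table` from [build_segments()] (needs >= 2
#'   surveys per phase; for ZIP both condition levels must be present).
#' @param spec a `disp_spec` from [model_spec()].
#' @return an object of class `disp_fit`: posterior `draws` (matrix,
#'   iterations x parameters, with a `chain` vector), `diagnostics`
#'   (per-parameter R-hat and ESS for the monitored scalar parameters),
#'   `converged`, the smooth `basis` and the data bookkeeping needed for
#'   prediction.
#' @export
fit_gamm <- function(seg, spec) {
  stopifnot(inherits(spec, "disp_spec"))
  tab <- table(seg$phase, seg$survey_id)
  if (any(rowSums(tab > 0) < 2 & rowSums(tab) > 0))
    stop("need at least 2 surveys per phase")
  if (spec$family == "ZIP" && length(unique(seg$condition)) < 2)
    stop("ZIP fit needs both good and poor condition segments")
  dat <- .build_fit_data(seg, spec)
  init <- list(
    v = c(log(max(mean(dat$y), 0.05)),
          rep(0, dat$P - 1)),
    sig = stats::setNames(
      rep(0.5, length(dat$levels) + 2),
      c(paste0("sigma_smooth_", dat$levels), "sigma_survey",
        "sigma_transect")),
    theta = if (spec$family == "NB") 1 else NA_real_)
  rng <- .save_rng()
  on.exit(.restore_rng(rng))
  set.seed(spec$seed)
  seeds <- sample.int(2^30, spec$chains)
  chains <- lapply(seq_len(spec$chains), function(ch)
    .run_chain(dat, spec, seeds[ch], init))
  draws <- do.call(rbind, chains)
  chain <- rep(seq_len(spec$chains), each = spec$draws)

  ## diagnostics on the scalar (reportable) parameters
  mon <- c(dat$par_names[dat$grp$fixed], names(init$sig),
           if (spec$family == "NB") "theta",
           if (spec$family == "ZIP") c("gamma0", "gamma_cond"))
  mcl <- coda::mcmc.list(lapply(chains, function(m)
    coda::mcmc(m[, mon, drop = FALSE])))
  rhat <- if (spec$chains >= 2)
    coda::gelman.diag(mcl, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1]
  else rep(NA_real_, length(mon))
  ess <- coda::effectiveSize(mcl)
  diagnostics <- data.frame(parameter = mon, rhat = rhat,
                            ess = as.numeric(ess[mon]),
                            row.names = NULL)
  converged <- !any(is.finite(diagnostics$rhat) & diagnostics$rhat > 1.1)
  if (!converged)
    warning("max R-hat > 1.1: fit flagged as not converged (degraded)")
  structure(list(draws = draws, chain = chain, spec = spec,
                 diagnostics = diagnostics, converged = converged,
                 basis = dat$basis, levels = dat$levels,
                 nominal = dat$nominal, ctr = dat$ctr, hull = dat$hull,
                 grp = dat$grp, par_names = dat$par_names,
                 species = attr(seg, "species")),
            class = "disp_fit")
}

#' @export
print.disp_fit <- function(x, ...) {
  cat(sprintf("%s GAMM fit: %d draws x %d parameters (%d chains)\n",
              x$spec$family, nrow(x$draws), ncol(x$draws),
              x$spec$chains))
  cat(sprintf("converged: %s (max monitored R-hat %.3f)\n",
              x$converged, suppressWarnings(max(x$diagnostics$rhat))))
  invisible(x)
}

#' Posterior draws of the phase contrasts
#'
#' Returns draws of the three pairwise phase contrasts on the log (raw)
#' scale, named as reported: preconstruction vs construction (the
#' construction effect), construction vs operation, and preconstruction
#' vs operation, the second computed as a derived quantity from the
#' draws. Positive values mean the second-named phase has the higher
#' expected count.
#'
#' @param fit a `disp_fit`.
#' @return matrix of draws with one column per contrast.
#' @export
phase_contrasts <- function(fit) {
  d <- fit$draws
  con <- if ("phase_construction" %in% colnames(d))
    d[, "phase_construction"] else 0
  op <- if ("phase_operation" %in% colnames(d))
    d[, "phase_operation"] else 0
  cbind(
    pre_vs_con = con,
    con_vs_op = op - con,
    pre_vs_op = op
  )
}

#' Transform raw (link-scale) estimates to the response level
#'
#' Elementwise inverse-link transform of an estimate and its credible
#' interval: `exp` for the log link (count part), inverse-logit for the
#' logit link (extra-zero part). Ordering lower <= estimate <= upper is
#' preserved because both transforms are strictly increasing.
#'
#' @param est,lower,upper raw-scale estimate and 95% CrI bounds.
#' @param link `"log"` or `"logit"`.
#' @return data.frame with transformed `est`, `lower`, `upper`.
#' @export
response_level <- function(est, lower = NULL, upper = NULL,
                           link = c("log", "logit")) {
  link <- match.arg(link)
  if (!is.null(lower) && any(lower > est | est > (upper %||% Inf)))
    stop("require lower <= estimate <= upper")
  tf <- if (link == "log") exp else stats::plogis
  out <- data.frame(est = tf(est))
  if (!is.null(lower)) { out$lower <- tf(lower); out$upper <- tf(upper) }
  out
}

#' Credible-interval significance rule
#'
#' A predictor is significant when its 95% credible interval on the raw
#' (link) scale does not bound zero, i.e. the 2.5th and 97.5th posterior
#' percentiles have the same sign.
#'
#' @param draws numeric vector of posterior draws (>= 400 recommended),
#'   or a length-2 numeric of precomputed interval bounds.
#' @return `"Yes"` or `"No"`.
#' @export
significance <- function(draws) {
  ci <- if (length(draws) == 2) sort(draws)
  else stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  if (sign(ci[1]) == sign(ci[2]) && ci[1] != 0) "Yes" else "No"
}

#' Write posterior draws as a columnar text table
#'
#' Long format: `parameter, chain, iteration, value`.
#'
#' @param fit a `disp_fit`.
#' @param path output path (CSV).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  d <- fit$draws
  long <- data.frame(
    parameter = rep(colnames(d), each = nrow(d)),
    chain = rep(fit$chain, ncol(d)),
    iteration = rep(stats::ave(fit$chain, fit$chain, FUN = seq_along),
                    ncol(d)),
    value = as.vector(d))
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
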