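## Count-model kernels shared by the sampler, the simulator and tests.
##
## The negative binomial uses the mean-dispersion parameterization
## (Var = mu + mu^2 / theta, log link). The zero-inflated Poisson mixes a
## point mass at zero (probability pi0, logit link) with a Poisson count
## process: P(0) = pi0 + (1 - pi0) exp(-mu), P(y > 0) = (1 - pi0) *
## Poisson(y; mu).

#' Negative binomial log-pmf (mean-dispersion parameterization)
#'
#' @param y non-negative integer counts.
#' @param mu mean (> 0).
#' @param theta dispersion (size) parameter (> 0); the variance is
#'   `mu + mu^2 / theta`, so the Poisson is recovered as `theta -> Inf`.
#' @return log-probabilities, same length as `y`.
#' @export
nb_logpmf <- function(y, mu, theta) {
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(mu <= 0) || any(theta <= 0)) stop("mu and theta must be positive")
  stats::dnbinom(y, size = theta, mu = mu, log = TRUE)
}

#' Zero-inflated Poisson log-pmf
#'
#' @param y non-negative integer counts.
#' @param mu Poisson mean of the count part (> 0).
#' @param pi0 extra-zero probability in `[0, 1]`.
#' @return log-probabilities, same length as `y`.
#' @export
zip_logpmf <- function(y, mu, pi0) {
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(pi0 < 0) || any(pi0 > 1)) stop("pi0 must lie in [0, 1]")
  if (any(mu <= 0)) stop("mu must be positive")
  n <- max(length(y), length(mu), length(pi0))
  y <- rep_len(y, n); mu <- rep_len(mu, n); pi0 <- rep_len(pi0, n)
  out <- log1p(-pi0) + stats::dpois(y, mu, log = TRUE)
  z <- y == 0
  if (any(z))
    out[z] <- log(pi0[z] + exp(log1p(-pi0[z]) - mu[z]))
  out
}

#' Evaluate the model's linear predictors for segments
#'
#' The count part is
#' `log mu = beta_phase + f_phase(x, y) + b_survey + b_transect +
#' log(effort / nominal)`; the binary (extra-zero) part of the ZIP model
#' is `logit pi0 = gamma0 + gamma_cond * [condition == "poor"]`.
#'
#' @param segment data.frame of segments with `phase`, `x`, `y`,
#'   `survey_id`, `transect_id`, `effort_m`, `condition`.
#' @param params list with any of: `beta` (named per-phase intercepts on
#'   the log scale), `f` (function `(x, y, phase) -> smooth value`),
#'   `b_survey`, `b_transect` (named vectors), `gamma0`, `gamma_cond`,
#'   `nominal_length` (metres; defaults to `max(effort_m)`). Missing
#'   components default to zero.
#' @return list with `log_mu`, `mu`, `logit_pi0`, `pi0`.
#' @export
linear_predictor <- function(segment, params = list()) {
  ph <- as.character(segment$phase)
  if (!all(ph %in% PHASE_LEVELS)) stop("unknown phase")
  if (!is.null(segment$condition) &&
      !all(segment$condition %in% c("good", "poor")))
    stop("unknown condition")
  nominal <- params$nominal_length %||% max(segment$effort_m)
  pick <- function(v, keys) if (is.null(v)) 0 else {
    out <- v[keys]; out[is.na(out)] <- 0; unname(out)
  }
  beta <- pick(params$beta, ph)
  f <- if (is.null(params$f)) 0 else params$f(segment$x, segment$y, ph)
  bs <- pick(params$b_survey, as.character(segment$survey_id))
  bt <- pick(params$b_transect,
             paste(segment$survey_id, segment$transect_id, sep = ":"))
  log_mu <- beta + f + bs + bt + log(segment$effort_m / nominal)
  g0 <- params$gamma0 %||% 0
  gc <- params$gamma_cond %||% 0
  lpi <- g0 + gc * as.numeric(segment$condition == "poor")
  if (is.null(segment$condition)) lpi <- rep(g0, nrow(segment))
  list(log_mu = log_mu, mu = exp(log_mu),
       logit_pi0 = lpi, pi0 = stats::plogis(lpi))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
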