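# Shared fitted-model fixtures, built once per test run and cached.
# Fit-time settings are scaled for test turnaround; the acceptance tests
# run their own replicate studies.

.fixture_env <- new.env(parent = emptyenv())

# NB scenario matching the documented recovery example: 900 segments,
# construction contrast -0.5, theta = 2, small survey/transect noise so
# the single-instance accuracy check is informative.
nb_fixture <- function() {
  if (is.null(.fixture_env$nb)) {
    cfg <- scenario_config(transect_length = 9000, surveys_per_phase = 2,
                           sigma_survey = 0.05, sigma_transect = 0.05,
                           seed = 42)
    sim <- simulate_surveys(cfg)
    seg <- build_segments(sim, "guillemot")
    spec <- model_spec("NB", knots = 12, chains = 2, warmup = 600,
                       draws = 400, seed = 7, hmc = list(L = 12))
    fit <- suppressWarnings(fit_gamm(seg, spec))
    .fixture_env$nb <- list(sim = sim, seg = seg, fit = fit)
  }
  .fixture_env$nb
}

zip_fixture <- function() {
  if (is.null(.fixture_env$zip)) {
    cfg <- scenario_config(transect_length = 6000, surveys_per_phase = 2,
                           sigma_survey = 0.05, sigma_transect = 0.05,
                           seed = 43)
    sim <- simulate_surveys(cfg)
    seg <- build_segments(sim, "harbor_porpoise")
    spec <- model_spec("ZIP", knots = 12, chains = 2, warmup = 600,
                       draws = 400, seed = 8, hmc = list(L = 12))
    fit <- suppressWarnings(fit_gamm(seg, spec))
    .fixture_env$zip <- list(sim = sim, seg = seg, fit = fit)
  }
  .fixture_env$zip
}

# Hand-built fit object with known draws, for closed-form prediction
# checks: one phase block basis on a small grid of coordinates.
fake_fit <- function(draws_overrides = list(), family = "NB",
                     n_draws = 50) {
  set.seed(99)
  coords <- as.matrix(expand.grid(x = seq(0, 5000, by = 500),
                                  y = seq(0, 5000, by = 500)))
  basis <- build_basis(coords, place_knots(coords, 8, seed = 1))
  q <- basis$rank
  levels <- c("preconstruction", "construction", "operation")
  nms <- c("(Intercept)", "phase_construction", "phase_operation",
           unlist(lapply(levels, function(l) paste0("lin_x_", l))),
           unlist(lapply(levels, function(l) paste0("lin_y_", l))),
           unlist(lapply(levels, function(l) paste0("s_", l, "[", 1:q, "]"))),
           if (family == "ZIP") c("gamma0", "gamma_cond"))
  d <- matrix(0, n_draws, length(nms), dimnames = list(NULL, nms))
  for (nm in names(draws_overrides)) d[, nm] <- draws_overrides[[nm]]
  structure(list(
    draws = d, chain = rep(1L, n_draws),
    spec = list(family = family),
    levels = levels, basis = basis,
    nominal = 600, ctr = c(x = mean(coords[, 1]), y = mean(coords[, 2])),
    hull = cbind(c(0, 5000, 5000, 0), c(0, 0, 5000, 5000)),
    species = if (family == "NB") "guillemot" else "harbor_porpoise"),
    class = "disp_fit")
}
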