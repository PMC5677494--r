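# summarize a draws matrix (draws x cells) into a prediction_grid-like
# object, for rule-invariance checks on manufactured posteriors
grid_from_draws <- function(x, y, mu) {
  out <- data.frame(
    x = x, y = y, mean = colMeans(mu), sd = apply(mu, 2, sd),
    lower = apply(mu, 2, quantile, 0.025, names = FALSE),
    upper = apply(mu, 2, quantile, 0.975, names = FALSE))
  attr(out, "draws") <- mu
  class(out) <- c("prediction_grid", "data.frame")
  out
}

test_that("zero coefficients predict unit abundance everywhere", {
  fit <- fake_fit()
  grid <- make_grid(fit, 1000)
  for (ph in fit$levels) {
    s <- predict_surface(fit, grid, ph)
    expect_equal(s$mean, rep(1, nrow(grid)))
    expect_equal(s$sd, rep(0, nrow(grid)))
    expect_true(all(s$lower <= s$mean & s$mean <= s$upper))
  }
  expect_error(predict_surface(fit, grid, "decommissioning"), "absent")
})

test_that("adding log(2) to the phase effect doubles every cell mean", {
  f1 <- fake_fit(list(phase_construction = 0.4,
                      `s_construction[1]` = 0.3))
  f2 <- fake_fit(list(phase_construction = 0.4 + log(2),
                      `s_construction[1]` = 0.3))
  grid <- make_grid(f1, 1000)
  s1 <- predict_surface(f1, grid, "construction")
  s2 <- predict_surface(f2, grid, "construction")
  expect_equal(s2$mean, 2 * s1$mean, tolerance = 1e-12)
})

test_that("ZIP predictions shrink with the extra-zero probability", {
  fg <- fake_fit(list(gamma0 = -1, gamma_cond = 1.2), family = "ZIP")
  grid <- make_grid(fg, 1000)
  good <- predict_surface(fg, grid, "operation", condition = "good")
  poor <- predict_surface(fg, grid, "operation", condition = "poor")
  # pi0(poor) > pi0(good), so expected counts are lower under poor
  expect_true(all(poor$mean < good$mean))
  expect_equal(good$mean, rep(1 - plogis(-1), nrow(grid)))
})

test_that("uncertainty maps are SD-to-mean ratios with flagged zeros", {
  g <- data.frame(x = 1:3, y = 0, mean = c(2, 5, 0), sd = c(1, 0, 0.2))
  u <- uncertainty_map(g)
  expect_equal(u$ratio[1], 0.5)
  expect_equal(u$ratio[2], 0)
  expect_true(is.na(u$ratio[3]) && u$flagged[3])
})

test_that("uncertainty grows toward the sparse edge of the surveyed area", {
  fx <- nb_fixture()
  grid <- make_grid(fx$fit, 600)
  s <- predict_surface(fx$fit, grid, "preconstruction")
  u <- uncertainty_map(s)
  ctr <- c(mean(grid$x), mean(grid$y))
  d <- sqrt((grid$x - ctr[1])^2 + (grid$y - ctr[2])^2)
  expect_gt(cor(d, u$ratio, method = "spearman"), 0)
})

test_that("change maps apply the interval non-overlap rule", {
  mk <- function(lo, hi) data.frame(x = 1, y = 1, mean = (lo + hi) / 2,
                                    sd = 1, lower = lo, upper = hi)
  expect_true(change_map(mk(1, 2), mk(3, 4))$significant)
  expect_false(change_map(mk(1, 2), mk(1.5, 2.5))$significant)
  g <- mk(1, 2)
  self <- change_map(g, g)
  expect_equal(self$diff, 0)
  expect_false(self$significant)
  expect_error(change_map(mk(1, 2), data.frame(x = 2, y = 1, mean = 1,
                                               sd = 1, lower = 0,
                                               upper = 2)), "geometry")
})

test_that("change maps are antisymmetric under phase swap", {
  fx <- nb_fixture()
  grid <- make_grid(fx$fit, 1200)
  a <- predict_surface(fx$fit, grid, "preconstruction")
  b <- predict_surface(fx$fit, grid, "construction")
  ab <- change_map(a, b)
  ba <- change_map(b, a)
  expect_equal(ab$diff, -ba$diff)
  expect_identical(ab$significant, ba$significant)
  # difference-CrI variant is exposed and antisymmetric too
  ab2 <- change_map(a, b, method = "difference")
  ba2 <- change_map(b, a, method = "difference")
  expect_identical(ab2$significant, ba2$significant)
})

test_that("significance flags are invariant to common monotone rescaling", {
  set.seed(44)
  x <- rep(1:6, 2); y <- rep(1:2, each = 6)
  muA <- matrix(rlnorm(200 * 12, 0, 0.3), 200)
  muB <- matrix(rlnorm(200 * 12, 1.6, 0.3), 200)
  g1 <- change_map(grid_from_draws(x, y, muA), grid_from_draws(x, y, muB))
  rescale <- function(m) 3 * m^1.7   # strictly monotone
  g2 <- change_map(grid_from_draws(x, y, rescale(muA)),
                   grid_from_draws(x, y, rescale(muB)))
  expect_identical(g1$significant, g2$significant)
  expect_true(any(g1$significant))
})

test_that("footprint summaries average member cells per draw", {
  set.seed(45)
  x <- rep(seq(500, 2500, by = 1000), 3)
  y <- rep(seq(500, 2500, by = 1000), each = 3)
  mu <- matrix(rlnorm(100 * 9, 0, 0.2), 100)
  g <- grid_from_draws(x, y, mu)
  one <- footprint_summary(g, cbind(c(0, 1000, 1000, 0), c(0, 0, 1000, 1000)))
  expect_equal(one$n_cells, 1)
  expect_equal(one$mean, mean(mu[, 1]))
  expect_equal(unname(c(one$lower, one$upper)),
               unname(quantile(mu[, 1], c(0.025, 0.975))))
  # a uniform surface summarizes to the uniform value
  gu <- grid_from_draws(x, y, matrix(2, 100, 9))
  all_cells <- footprint_summary(gu, cbind(c(0, 3000, 3000, 0),
                                           c(0, 0, 3000, 3000)))
  expect_equal(all_cells$mean, 2)
  expect_equal(all_cells$n_cells, 9)
  expect_error(footprint_summary(g, cbind(c(9e5, 9e5 + 1, 9e5 + 1, 9e5),
                                          c(0, 0, 1, 1))),
               "no grid cells")
})

test_that("the fitted surface tracks the true intensity surface", {
  # pronounced spatial structure (log-scale surface SD 1) so the rank
  # correlation is signal- rather than noise-limited
  cfg <- scenario_config(transect_length = 9000, surveys_per_phase = 4,
                         surface_sd = 1, sigma_survey = 0.05,
                         sigma_transect = 0.05, seed = 23)
  sim <- simulate_surveys(cfg)
  seg <- build_segments(sim, "guillemot")
  spec <- model_spec("NB", knots = 15, chains = 2, warmup = 500,
                     draws = 350, seed = 9, hmc = list(L = 12))
  fit <- suppressWarnings(fit_gamm(seg, spec))
  grid <- make_grid(fit, 600)
  for (ph in fit$levels) {
    s <- predict_surface(fit, grid, ph)
    truth <- sim$truth$surfaces$guillemot[[ph]]$eval(grid$x, grid$y)
    expect_gte(cor(truth, s$mean, method = "spearman"), 0.9)
  }
})

test_that("grids and change maps serialize to CSV and GeoJSON", {
  fx <- nb_fixture()
  grid <- make_grid(fx$fit, 1800)
  s <- predict_surface(fx$fit, grid, "operation")
  csv <- tempfile(fileext = ".csv")
  gj <- tempfile(fileext = ".geojson")
  write_grid(s, csv, gj)
  back <- read.csv(csv)
  expect_equal(back$mean, s$mean, tolerance = 1e-12)
  feats <- jsonlite::read_json(gj)
  expect_equal(length(feats$features), nrow(s))
  expect_equal(feats$features[[1]]$properties$mean, s$mean[1],
               tolerance = 1e-9)
})
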