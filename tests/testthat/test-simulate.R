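test_that("the same seed reproduces a byte-identical file set", {
  cfg <- scenario_config(transect_length = 4800, surveys_per_phase = 1,
                         seed = 31)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario(simulate_surveys(cfg), d1)
  write_scenario(simulate_surveys(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 32
  d3 <- tempfile()
  write_scenario(simulate_surveys(cfg2), d3)
  expect_false(identical(readLines(file.path(d1, "sightings.csv")),
                         readLines(file.path(d3, "sightings.csv"))))
})

test_that("vanishing intensity produces no sightings", {
  b <- c(preconstruction = -20, construction = -20, operation = -20)
  cfg <- scenario_config(transect_length = 4800, surveys_per_phase = 1,
                         guillemot = list(beta = b),
                         porpoise = list(beta = b), seed = 33)
  sim <- simulate_surveys(cfg)
  expect_equal(nrow(sim$sightings), 0)
})

test_that("simulated counts obey the generating law and dispersion", {
  # flat surface, no random effects, log-intensity chosen for mean 2:
  # ~10,000 seabird segments (10 x 60 km transects, 10 surveys)
  cfg <- scenario_config(
    transect_length = 60000, surveys_per_phase = c(4, 3, 3),
    surface_sd = 0, sigma_survey = 0, sigma_transect = 0,
    guillemot = list(beta = c(preconstruction = log(2),
                              construction = log(2),
                              operation = log(2))),
    in_flight_frac = 0.25, seed = 34)
  sim <- simulate_surveys(cfg)
  seg <- build_segments(sim, "guillemot")
  n <- nrow(seg)
  expect_equal(n, 10000)
  # LLN: mean within 3 MC SEs of 2 (NB variance = mu + mu^2/theta = 4)
  se <- sqrt(4 / n)
  expect_lt(abs(mean(seg$count) - 2), 3 * se)
  # overdispersion relative to Poisson
  expect_gt(var(seg$count) / mean(seg$count), 1)
  # count conservation: the on-sea filter dropped the in-flight records
  s <- sim$sightings[sim$sightings$species == "guillemot", ]
  expect_equal(sum(seg$count), sum(s$count[s$behavior == "on_sea"]))
  expect_gt(sum(s$behavior == "in_flight"), 0)

  # cetacean zero inflation: more zeros than a Poisson of matched mean
  segz <- build_segments(sim, "harbor_porpoise")
  expect_gt(mean(segz$count == 0), exp(-mean(segz$count)) + 0.02)
})

test_that("the sea-state chain visits good and poor at stationary rates", {
  cfg <- scenario_config(transect_length = 18000,
                         surveys_per_phase = c(8, 6, 6), seed = 35)
  sim <- simulate_surveys(cfg)
  good_stat <- sum(sim$truth$sea_stationary[1:3])
  g <- as.numeric(sim$seastate$beaufort <= 2)
  expect_gt(sum(g), 0)
  expect_gt(sum(1 - g), 0)
  # Markov-chain records are autocorrelated: inflate the binomial SE by
  # the AR(1) effective-sample-size factor
  rho <- suppressWarnings(cor(g[-1], g[-length(g)]))
  se <- sqrt(good_stat * (1 - good_stat) / length(g)) *
    sqrt((1 + rho) / (1 - rho))
  expect_lt(abs(mean(g) - good_stat), 3 * se)
})

test_that("displacement scenarios set the construction footprint factor", {
  base <- scenario_config(seed = 1)
  cfg <- displacement_scenario(base, 0.7)
  expect_equal(cfg$displacement$construction, 0.3)
  expect_equal(cfg$displacement$preconstruction, 1)
  expect_equal(cfg$displacement$operation, 1)
  expect_identical(displacement_scenario(base, 0)$displacement,
                   base$displacement)
  expect_error(displacement_scenario(base, 1), "factor")
  expect_error(scenario_config(displacement = list(
    preconstruction = 1, construction = 0, operation = 1)), "> 0")
})

test_that("the displacement factor enters the latent truth exactly", {
  base <- scenario_config(transect_length = 9000, surveys_per_phase = 1,
                          share_surfaces = TRUE, seed = 36)
  cfg <- displacement_scenario(base, 0.7)
  sim <- simulate_surveys(cfg)
  tr <- sim$truth
  # equal betas by default? no: contrast the latent law directly
  fp <- tr$footprint_utm
  x0 <- mean(fp[, 1]); y0 <- mean(fp[, 2])
  lam <- function(ph) exp(tr$beta$guillemot[[ph]] +
    tr$surfaces$guillemot[[ph]]$eval(x0, y0) +
    log(tr$displacement[[ph]]))
  ratio <- lam("construction") / lam("preconstruction") /
    exp(tr$beta$guillemot[["construction"]] -
          tr$beta$guillemot[["preconstruction"]])
  expect_equal(ratio, 0.3, tolerance = 1e-12)
})

test_that("a footprint outside the study area is rejected", {
  cfg <- scenario_config(transect_length = 4800, surveys_per_phase = 1,
                         seed = 37)
  cfg$footprint_utm[, 2] <- cfg$footprint_utm[, 2] + 1e6
  expect_error(simulate_surveys(cfg), "outside the study area")
})

test_that("truth reports align with the fit's reportable parameters", {
  fx <- nb_fixture()
  tr_nb <- truth_report(fx$sim$truth, "guillemot")
  expect_setequal(tr_nb$parameter, reportable_parameters(fx$fit))
  expect_true("theta" %in% tr_nb$parameter)
  expect_false("gamma0" %in% tr_nb$parameter)
  fz <- zip_fixture()
  tr_zip <- truth_report(fz$sim$truth, "harbor_porpoise")
  expect_setequal(tr_zip$parameter, reportable_parameters(fz$fit))
  expect_true(all(c("gamma0", "gamma_cond") %in% tr_zip$parameter))
  # contrast rows are differences of the generating phase levels
  b <- fx$sim$truth$beta$guillemot
  expect_equal(tr_nb$value[tr_nb$parameter == "con_vs_op"],
               b[["operation"]] - b[["construction"]])
  # every reportable name indexes the fit draws or derived contrasts
  derived <- colnames(phase_contrasts(fx$fit))
  avail <- c(colnames(fx$fit$draws), derived)
  expect_true(all(tr_nb$parameter %in% avail))
})

test_that("scenario files ingest cleanly through the survey reader", {
  cfg <- scenario_config(transect_length = 4800, surveys_per_phase = 1,
                         seed = 38)
  sim <- simulate_surveys(cfg)
  d <- tempfile()
  write_scenario(sim, d)
  dat <- read_survey(d)
  expect_setequal(names(dat$track),
                  c("survey_id", "transect_id", "timestamp", "lon", "lat"))
  expect_equal(nrow(dat$phases), 3)
  expect_false(is.null(dat$footprint))
  # timestamps are written at second precision; assignment still
  # conserves almost all individuals
  seg_file <- build_segments(dat, "guillemot")
  seg_mem <- build_segments(sim, "guillemot")
  expect_equal(sum(seg_file$count), sum(seg_mem$count))
  tj <- jsonlite::read_json(file.path(d, "truth.json"),
                            simplifyVector = TRUE)
  expect_equal(tj$beta$guillemot[["construction"]],
               cfg$guillemot$beta[["construction"]])
})
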