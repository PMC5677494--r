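## Synthetic boat-based line-transect survey generator with known ground
## truth, emulating the study design: ten parallel transects ~18 km long
## spaced 2 km apart over a 360 km^2 area, three development phases,
## NB-distributed seabird counts and zero-inflated Poisson cetacean
## counts with sea-state-dependent excess zeros, phase-specific latent
## spatial intensity surfaces, and an optional multiplicative intensity
## reduction inside the wind-farm footprint (displacement).

#' Scenario configuration for the synthetic survey generator
#'
#' Defaults reproduce the study design: 10 parallel north-south
#' transects, 18 km long, 2 km apart (360 km^2), surveyed 24/16/21 times
#' in the preconstruction/construction/operation phases (the per-phase
#' effort implied by a ~180 km survey), a 3.6 x 3.6 km (~13 km^2)
#' footprint in the centre of the area, vessel speed 5 m/s with a GPS fix
#' every 30 s, and Beaufort sea state evolving as a persistent Markov
#' chain on 0..5 recorded at the start of each transect and every 15 min.
#' Species effect sizes are test settings chosen for desk-scale power,
#' not estimates of any real system.
#'
#' @param transects number of transects.
#' @param transect_length,spacing metres.
#' @param surveys_per_phase integer, length 1 or 3.
#' @param guillemot,porpoise species parameter lists; see Details.
#' @param sigma_survey,sigma_transect random-effect SDs (log scale).
#' @param surface_sd,length_scale SD and range (m) of the Gaussian-process
#'   latent log-intensity surfaces (drawn once per species and phase).
#' @param share_surfaces draw a single surface per species and share it
#'   across phases (a spatially stable population; useful as the null
#'   scenario for displacement tests).
#' @param sea_persistence probability that the Beaufort state repeats
#'   between consecutive 15-min records (remainder split between
#'   neighbouring states).
#' @param in_flight_frac rate of extra in-flight seabird sightings
#'   relative to the on-sea intensity (in-flight birds are excluded by
#'   the analysis; they exercise the behaviour filter).
#' @param displacement named list of per-phase multiplicative intensity
#'   factors (> 0) applied inside the footprint.
#' @param origin UTM zone 30N coordinates (m) of the south-west corner.
#' @param vessel_speed m/s; `fix_interval` s between GPS fixes.
#' @param seed integer; the whole file set is reproducible given the seed.
#'
#' @details `guillemot` fields: `beta` (named per-phase log intensity per
#' full segment), `theta` (NB dispersion). `porpoise` fields: `beta`,
#' `gamma0`, `gamma_cond` (logit-scale extra-zero intercept and poor-
#' condition effect).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(
    transects = 10, transect_length = 18000, spacing = 2000,
    surveys_per_phase = c(24, 16, 21),
    guillemot = list(),
    porpoise = list(),
    sigma_survey = 0.15, sigma_transect = 0.1,
    surface_sd = 0.5, length_scale = 5000, share_surfaces = FALSE,
    sea_persistence = 0.7, in_flight_frac = 0.4,
    displacement = list(preconstruction = 1, construction = 1,
                        operation = 1),
    origin = c(x = 450000, y = 6055000),
    vessel_speed = 5, fix_interval = 30, seed = 1) {
  gl <- utils::modifyList(list(
    beta = c(preconstruction = 0, construction = -0.5, operation = 0.2),
    theta = 2), guillemot)
  hp <- utils::modifyList(list(
    beta = c(preconstruction = 0, construction = -0.9, operation = 0),
    gamma0 = -1, gamma_cond = 1.2), porpoise)
  if (any(unlist(displacement) <= 0))
    stop("displacement factors must be > 0")
  stopifnot(spacing > 0, sigma_survey >= 0, sigma_transect >= 0)
  if (length(surveys_per_phase) == 1)
    surveys_per_phase <- rep(surveys_per_phase, 3)
  width <- transects * spacing
  fp_half <- 1800
  cx <- origin["x"] + width / 2
  cy <- origin["y"] + transect_length / 2
  footprint_utm <- cbind(
    x = cx + c(-1, 1, 1, -1) * fp_half,
    y = cy + c(-1, -1, 1, 1) * fp_half)
  structure(list(
    transects = transects, transect_length = transect_length,
    spacing = spacing, surveys_per_phase = surveys_per_phase,
    guillemot = gl, porpoise = hp,
    sigma_survey = sigma_survey, sigma_transect = sigma_transect,
    surface_sd = surface_sd, length_scale = length_scale,
    share_surfaces = share_surfaces,
    sea_persistence = sea_persistence, in_flight_frac = in_flight_frac,
    displacement = displacement, origin = origin,
    vessel_speed = vessel_speed, fix_interval = fix_interval,
    footprint_utm = footprint_utm, seed = seed
  ), class = "scenario_config")
}

#' Derive a displacement scenario
#'
#' Sets the construction-phase intensity factor inside the footprint to
#' `1 - reduction`, leaving other phases at 1.
#'
#' @param base a `scenario_config`.
#' @param reduction fraction of intensity removed during construction
#'   (`0 <= reduction < 1`; a full reduction is rejected because the
#'   factor must stay positive).
#' @return the modified `scenario_config`.
#' @export
displacement_scenario <- function(base, reduction) {
  if (reduction < 0 || reduction >= 1)
    stop("reduction must be in [0, 1): the intensity factor must be > 0")
  base$displacement <- list(preconstruction = 1,
                            construction = 1 - reduction,
                            operation = 1)
  base
}

## Beaufort transition matrix: persistence p, remainder to neighbours
.sea_transition <- function(p) {
  M <- matrix(0, 6, 6)
  for (s in 1:6) {
    nb <- intersect(c(s - 1, s + 1), 1:6)
    M[s, s] <- p
    M[s, nb] <- (1 - p) / length(nb)
  }
  M
}

.sea_stationary <- function(M) {
  e <- eigen(t(M))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

## bilinear interpolation of a grid surface
.bilinear <- function(xg, yg, Z, x, y) {
  ix <- pmin(pmax(findInterval(x, xg), 1), length(xg) - 1)
  iy <- pmin(pmax(findInterval(y, yg), 1), length(yg) - 1)
  tx <- (x - xg[ix]) / (xg[ix + 1] - xg[ix])
  ty <- (y - yg[iy]) / (yg[iy + 1] - yg[iy])
  tx <- pmin(pmax(tx, 0), 1); ty <- pmin(pmax(ty, 0), 1)
  Z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
    Z[cbind(ix + 1, iy)] * tx * (1 - ty) +
    Z[cbind(ix, iy + 1)] * (1 - tx) * ty +
    Z[cbind(ix + 1, iy + 1)] * tx * ty
}

## draw one squared-exponential GP surface on a coarse grid; returns a
## vectorized evaluator f(x, y)
.draw_surface <- function(cfg) {
  nx <- 26; ny <- 26
  xg <- seq(cfg$origin["x"] - 1000,
            cfg$origin["x"] + cfg$transects * cfg$spacing + 1000,
            length.out = nx)
  yg <- seq(cfg$origin["y"] - 1000,
            cfg$origin["y"] + cfg$transect_length + 1000,
            length.out = ny)
  gg <- expand.grid(x = xg, y = yg)
  d2 <- as.matrix(stats::dist(gg))^2
  K <- cfg$surface_sd^2 * exp(-d2 / (2 * cfg$length_scale^2)) +
    diag(1e-8, nrow(gg))
  z <- drop(crossprod(chol(K), stats::rnorm(nrow(gg))))
  Z <- matrix(z, nx, ny)
  list(xg = xg, yg = yg, Z = Z,
       eval = function(x, y) .bilinear(xg, yg, Z, x, y))
}

## canonical segment layout along the straight transect lines
.canonical_segments <- function(cfg, L) {
  xs <- cfg$origin["x"] + (seq_len(cfg$transects) - 0.5) * cfg$spacing
  segs <- do.call(rbind, lapply(seq_len(cfg$transects), function(j) {
    starts <- seq(0, cfg$transect_length - 1e-9, by = L)
    ends <- pmin(starts + L, cfg$transect_length)
    data.frame(transect = j, start = starts, end = ends,
               x = xs[j], y = cfg$origin["y"] + (starts + ends) / 2,
               effort = ends - starts)
  }))
  rownames(segs) <- NULL
  segs
}

#' Simulate a complete synthetic survey file set
#'
#' Generates GPS track points (every `fix_interval` s at fixed vessel
#' speed along each transect, alternating direction), Beaufort sea-state
#' records (start of transect plus every 15 min, Markov chain), sighting
#' records with timestamps drawn uniformly within the time window of the
#' segment that generated them (so positions are implied by time, as in
#' the field protocol), a survey-to-phase lookup and the footprint
#' polygon, together with the generating truth.
#'
#' Counts per canonical segment are drawn from the latent model
#' `log mu = beta_phase + f_phase(x, y) + log(displacement factor inside
#' the footprint) + b_survey + b_transect`: negative binomial for the
#' seabird, zero-inflated Poisson (extra-zero probability
#' `plogis(gamma0 + gamma_cond * poor)`) for the cetacean. Each phase
#' surface is centred to mean zero over that species' segment midpoints
#' so that the phase intercepts remain identified.
#'
#' @param cfg a `scenario_config`.
#' @return list with `track`, `sightings`, `seastate`, `phases`
#'   (data.frames, timestamps in seconds), `footprint` (lon/lat matrix)
#'   and `truth` (a `sim_truth`). The first five elements mirror the
#'   on-disk formats read by [read_survey()]; [write_scenario()] writes
#'   them out.
#' @export
simulate_surveys <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  fx <- range(cfg$footprint_utm[, 1])
  fy <- range(cfg$footprint_utm[, 2])
  if (fx[1] < cfg$origin["x"] ||
      fx[2] > cfg$origin["x"] + cfg$transects * cfg$spacing ||
      fy[1] < cfg$origin["y"] || fy[2] > cfg$origin["y"] +
        cfg$transect_length)
    stop("footprint outside the study area")
  rng <- .save_rng()
  on.exit(.restore_rng(rng))
  set.seed(cfg$seed)

  nsv <- sum(cfg$surveys_per_phase)
  survey_ids <- sprintf("S%02d", seq_len(nsv))
  phase_of <- rep(PHASE_LEVELS, cfg$surveys_per_phase)
  phases <- data.frame(survey_id = survey_ids, phase = phase_of)

  ## latent surfaces per species x phase, centred over segment midpoints
  species <- c(guillemot = 600, harbor_porpoise = 1000)
  surfaces <- list()
  for (sp in names(species)) {
    mids <- .canonical_segments(cfg, species[[sp]])
    centred_surface <- function() {
      s <- .draw_surface(cfg)
      ctr <- mean(s$eval(mids$x, mids$y))
      s$Z <- s$Z - ctr
      s$eval <- local({
        xg <- s$xg; yg <- s$yg; Z <- s$Z
        function(x, y) .bilinear(xg, yg, Z, x, y)
      })
      s
    }
    shared <- if (isTRUE(cfg$share_surfaces)) centred_surface()
    surfaces[[sp]] <- lapply(stats::setNames(PHASE_LEVELS, PHASE_LEVELS),
                             function(ph)
                               if (isTRUE(cfg$share_surfaces)) shared
                               else centred_surface())
  }

  b_survey <- stats::setNames(stats::rnorm(nsv, 0, cfg$sigma_survey),
                              survey_ids)
  trans_ids <- sprintf("T%02d", seq_len(cfg$transects))
  b_transect <- stats::setNames(
    stats::rnorm(nsv * cfg$transects, 0, cfg$sigma_transect),
    as.vector(outer(trans_ids, survey_ids,
                    function(t, s) paste(s, t, sep = ":"))))

  M <- .sea_transition(cfg$sea_persistence)
  v <- cfg$vessel_speed
  dur <- cfg$transect_length / v
  gap <- 600
  xs_line <- cfg$origin["x"] + (seq_len(cfg$transects) - 0.5) * cfg$spacing

  track <- list(); seastate <- list(); sightings <- list()
  day0 <- as.numeric(as.POSIXct("2002-06-01 06:00:00", tz = "UTC"))
  stationary <- .sea_stationary(M)

  for (s in seq_len(nsv)) {
    sv <- survey_ids[s]
    ph <- phase_of[s]
    t0 <- day0 + (s - 1) * 14 * 86400
    state <- sample.int(6, 1, prob = stationary)  # Beaufort + 1
    for (j in seq_len(cfg$transects)) {
      tstart <- t0 + (j - 1) * (dur + gap)
      tt <- seq(0, dur, by = cfg$fix_interval)
      if (tt[length(tt)] < dur) tt <- c(tt, dur)
      chain_at <- tt * v
      northbound <- j %% 2 == 1
      ys <- if (northbound) cfg$origin["y"] + chain_at
            else cfg$origin["y"] + cfg$transect_length - chain_at
      ll <- utm_to_lonlat(rep(xs_line[j], length(tt)), ys)
      track[[length(track) + 1]] <- data.frame(
        survey_id = sv, transect_id = trans_ids[j],
        timestamp = tstart + tt, lon = ll$lon, lat = ll$lat)
      ## sea state: record at transect start then every 15 min
      rec_t <- seq(tstart, tstart + dur, by = 900)
      bf <- integer(length(rec_t))
      for (r in seq_along(rec_t)) {
        if (r > 1) state <- sample.int(6, 1, prob = M[state, ])
        bf[r] <- state - 1L
      }
      seastate[[length(seastate) + 1]] <- data.frame(
        survey_id = sv, transect_id = trans_ids[j],
        timestamp = rec_t, beaufort = bf)

      ## counts per canonical segment on this transect
      for (sp in names(species)) {
        L <- species[[sp]]
        pars <- if (sp == "guillemot") cfg$guillemot else cfg$porpoise
        starts <- seq(0, cfg$transect_length - 1e-9, by = L)
        ends <- pmin(starts + L, cfg$transect_length)
        midc <- (starts + ends) / 2
        ymid <- cfg$origin["y"] + midc
        xmid <- rep(xs_line[j], length(midc))
        inside <- points_in_polygon(xmid, ymid, cfg$footprint_utm)
        f <- surfaces[[sp]][[ph]]$eval(xmid, ymid)
        eta <- pars$beta[[ph]] + f +
          log(cfg$displacement[[ph]]) * inside +
          b_survey[sv] + b_transect[paste(sv, trans_ids[j], sep = ":")] +
          log((ends - starts) / L)
        mu <- exp(eta)
        ## segment time window (chainage -> time along this transect)
        seg_t0 <- tstart + (if (northbound) starts
                            else cfg$transect_length - ends) / v
        seg_t1 <- seg_t0 + (ends - starts) / v
        ## midpoint-time condition from the records just generated
        mid_t <- (seg_t0 + seg_t1) / 2
        idxr <- pmax(findInterval(mid_t, rec_t), 1)
        poor <- bf[idxr] >= 3
        if (sp == "guillemot") {
          y <- stats::rnbinom(length(mu), size = pars$theta, mu = mu)
          nfly <- stats::rpois(length(mu), cfg$in_flight_frac * mu)
        } else {
          pi0 <- stats::plogis(pars$gamma0 + pars$gamma_cond * poor)
          z <- stats::rbinom(length(mu), 1, pi0)
          y <- (1 - z) * stats::rpois(length(mu), mu)
          nfly <- 0 * y
        }
        ## split each segment's individuals into sighting records of
        ## random group size with timestamps uniform in the segment's
        ## time window
        rts <- numeric(0); rct <- integer(0); rbe <- character(0)
        beh <- if (sp == "guillemot") "on_sea" else "not_applicable"
        for (k in seq_along(y)) {
          for (spec_beh in list(c(y[k], beh), c(nfly[k], "in_flight"))) {
            total <- as.integer(spec_beh[1])
            while (total > 0) {
              grp <- min(total, 1 + stats::rpois(1, 0.7))
              rts <- c(rts, stats::runif(1, seg_t0[k], seg_t1[k]))
              rct <- c(rct, grp)
              rbe <- c(rbe, spec_beh[2])
              total <- total - grp
            }
          }
        }
        if (length(rts))
          sightings[[length(sightings) + 1]] <- data.frame(
            survey_id = sv, timestamp = rts, species = sp,
            count = rct, behavior = rbe)
      }
    }
  }
  track <- do.call(rbind, track)
  seastate <- do.call(rbind, seastate)
  sightings <- if (length(sightings)) do.call(rbind, sightings)
    else data.frame(survey_id = character(), timestamp = numeric(),
                    species = character(), count = integer(),
                    behavior = character())
  sightings <- sightings[order(sightings$survey_id, sightings$timestamp), ]
  rownames(sightings) <- NULL
  fp_ll <- utm_to_lonlat(cfg$footprint_utm[, 1], cfg$footprint_utm[, 2])
  footprint <- cbind(lon = fp_ll$lon, lat = fp_ll$lat)

  truth <- structure(list(
    config = cfg,
    beta = list(guillemot = cfg$guillemot$beta,
                porpoise = cfg$porpoise$beta),
    theta = cfg$guillemot$theta,
    gamma0 = cfg$porpoise$gamma0, gamma_cond = cfg$porpoise$gamma_cond,
    sigma_survey = cfg$sigma_survey, sigma_transect = cfg$sigma_transect,
    b_survey = b_survey, b_transect = b_transect,
    surfaces = surfaces, displacement = cfg$displacement,
    footprint_utm = cfg$footprint_utm,
    sea_stationary = stationary
  ), class = "sim_truth")

  list(track = track, sightings = sightings, seastate = seastate,
       phases = phases, footprint = footprint, truth = truth)
}

#' True generating parameters aligned with fit parameter names
#'
#' One row per estimable scalar parameter, with names matching the
#' reportable parameters of a fitted model (see
#' [reportable_parameters()]) so recovery tests can join mechanically.
#' Contrast rows are differences of the per-phase generating
#' log-intensities.
#'
#' @param truth a `sim_truth` from [simulate_surveys()].
#' @param species `"guillemot"` (NB) or `"harbor_porpoise"` (ZIP).
#' @return data.frame with columns `parameter`, `value`.
#' @export
truth_report <- function(truth, species = "guillemot") {
  b <- if (species == "guillemot") truth$beta$guillemot
       else truth$beta$porpoise
  rows <- data.frame(parameter = c("pre_vs_con", "con_vs_op", "pre_vs_op"),
                     value = c(b[["construction"]] - b[["preconstruction"]],
                               b[["operation"]] - b[["construction"]],
                               b[["operation"]] - b[["preconstruction"]]))
  rows <- rbind(rows, data.frame(
    parameter = c("sigma_survey", "sigma_transect"),
    value = c(truth$sigma_survey, truth$sigma_transect)))
  if (species == "guillemot")
    rows <- rbind(rows, data.frame(parameter = "theta",
                                   value = truth$theta))
  else
    rows <- rbind(rows, data.frame(
      parameter = c("gamma0", "gamma_cond"),
      value = c(truth$gamma0, truth$gamma_cond)))
  rows
}

#' Reportable scalar parameters of a fit
#'
#' The phase contrasts, random-effect SDs and family-specific parameters
#' (`theta` for NB; `gamma0`, `gamma_cond` for ZIP) — the parameter set
#' that [truth_report()] mirrors.
#'
#' @param fit a `disp_fit`.
#' @return character vector of parameter names.
#' @export
reportable_parameters <- function(fit) {
  c("pre_vs_con", "con_vs_op", "pre_vs_op",
    "sigma_survey", "sigma_transect",
    if (fit$spec$family == "NB") "theta" else c("gamma0", "gamma_cond"))
}

#' Write a simulated scenario to disk
#'
#' Emits exactly the file formats read by [read_survey()]
#' (`track.csv`, `sightings.csv`, `seastate.csv`, `phases.csv`,
#' `footprint.geojson`) plus `truth.json` with the generating parameters
#' and grid evaluations of the latent surfaces.
#'
#' @param sim output of [simulate_surveys()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(d, f) {
    d$timestamp <- .fmt_time(d$timestamp)
    utils::write.csv(d, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  w(sim$track, "track.csv")
  w(sim$sightings, "sightings.csv")
  w(sim$seastate, "seastate.csv")
  utils::write.csv(sim$phases, file.path(dir, "phases.csv"),
                   row.names = FALSE, quote = FALSE)
  write_footprint(sim$footprint, file.path(dir, "footprint.geojson"))
  tr <- sim$truth
  jsonlite::write_json(list(
    beta = lapply(tr$beta, as.list), theta = tr$theta, gamma0 = tr$gamma0,
    gamma_cond = tr$gamma_cond, sigma_survey = tr$sigma_survey,
    sigma_transect = tr$sigma_transect, displacement = tr$displacement,
    b_survey = as.list(tr$b_survey), b_transect = as.list(tr$b_transect),
    surfaces = lapply(tr$surfaces, function(sp) lapply(sp, function(s)
      list(xg = s$xg, yg = s$yg, z = s$Z)))
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
  matrix = "rowmajor")
  invisible(dir)
}
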