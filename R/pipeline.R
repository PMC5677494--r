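## Pipeline orchestration: one call runs segmentation, model fitting,
## prediction, change mapping and table rendering for one species, and
## writes every artifact (plus a reproducibility manifest) under a single
## run directory. A verification helper re-derives the rendered tables
## from the stored draws and segments and diffs them, so every number in
## the tables is recomputable from artifacts.

#' Pipeline run configuration
#'
#' @param input directory with the survey file set (see [read_survey()]).
#' @param species `"guillemot"` or `"harbor_porpoise"`.
#' @param out output (artifact) directory.
#' @param segment_length segment length in metres; defaults to 600
#'   (guillemot) or 1000 (harbour porpoise).
#' @param grid_cell prediction cell side in metres; defaults to the
#'   segment length.
#' @param knots,chains,warmup,draws model settings (see [model_spec()]).
#' @param seed integer seed for every source of randomness in the run.
#' @param verbose emit progress messages to stderr.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, species = "guillemot", out = tempfile("run"),
                       segment_length = NULL, grid_cell = NULL,
                       knots = 25, chains = 3, warmup = 1000, draws = 1000,
                       seed = 1, verbose = TRUE) {
  structure(list(
    input = input, species = species, out = out,
    segment_length = segment_length %||%
      (if (species == "guillemot") 600 else 1000),
    grid_cell = grid_cell %||% segment_length %||%
      (if (species == "guillemot") 600 else 1000),
    knots = knots, chains = chains, warmup = warmup, draws = draws,
    seed = seed, verbose = verbose), class = "run_config")
}

.log <- function(cfg, ...) if (isTRUE(cfg$verbose))
  message("[marinedisp] ", sprintf(...))

## tiny polynomial rolling hash for the manifest config fingerprint
.fnv1a <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full displacement-analysis pipeline
#'
#' Reads the survey inputs, builds the segment table, fits the count
#' GAMM, predicts per-phase surfaces, derives uncertainty and change
#' maps, renders the effort and parameter tables and writes everything
#' (with a manifest carrying the seed, a config hash and versions) under
#' `config$out`. Missing inputs give status `"failed"`; a fit whose
#' R-hat exceeds 1.1 gives status `"degraded"` with artifacts retained;
#' otherwise `"ok"`.
#'
#' @param config a `run_config`.
#' @return list with `status`, `dir`, `message` and (on success) the
#'   `fit`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dat <- tryCatch(read_survey(config$input), error = function(e) e)
  if (inherits(dat, "error"))
    return(list(status = "failed", dir = config$out,
                message = conditionMessage(dat)))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  .log(config, "segmenting transects (%d m segments)",
       config$segment_length)
  seg <- build_segments(dat, config$species, config$segment_length)
  write_segment_table(seg, file.path(config$out, "segments.csv"))
  if (!is.null(dat$footprint))
    write_footprint(dat$footprint, file.path(config$out,
                                             "footprint.geojson"))
  ledger <- effort_ledger(seg, dat$footprint)
  utils::write.csv(ledger, file.path(config$out, "effort_table.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(render_effort_table(ledger),
             file.path(config$out, "effort_table.txt"))

  family <- if (config$species == "guillemot") "NB" else "ZIP"
  spec <- model_spec(family, knots = config$knots, chains = config$chains,
                     warmup = config$warmup, draws = config$draws,
                     seed = config$seed)
  .log(config, "fitting %s GAMM (%d chains x %d draws)", family,
       spec$chains, spec$draws)
  fit <- withCallingHandlers(
    fit_gamm(seg, spec),
    warning = function(w) {
      .log(config, "warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write_draws(fit, file.path(config$out, "draws.csv"))
  utils::write.csv(fit$diagnostics,
                   file.path(config$out, "diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  write_basis(fit$basis, file.path(config$out, "basis.json"))

  .log(config, "predicting phase surfaces (%d m cells)", config$grid_cell)
  grid <- make_grid(fit, config$grid_cell)
  surfaces <- lapply(stats::setNames(fit$levels, fit$levels),
                     function(ph) predict_surface(fit, grid, ph))
  for (ph in fit$levels) {
    write_grid(surfaces[[ph]],
               file.path(config$out, paste0("surface_", ph, ".csv")),
               file.path(config$out, paste0("surface_", ph, ".geojson")))
    utils::write.csv(uncertainty_map(surfaces[[ph]]),
                     file.path(config$out,
                               paste0("uncertainty_", ph, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  pairs <- list(c("preconstruction", "construction"),
                c("construction", "operation"),
                c("preconstruction", "operation"))
  for (p in pairs) {
    if (!all(p %in% fit$levels)) next
    cm <- change_map(surfaces[[p[1]]], surfaces[[p[2]]])
    write_grid(cm, file.path(config$out,
                             paste0("change_", p[1], "_vs_", p[2], ".csv")),
               file.path(config$out,
                         paste0("change_", p[1], "_vs_", p[2], ".geojson")))
  }
  ptab <- render_parameter_table(fit)
  utils::write.csv(ptab, file.path(config$out, "parameter_table.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(format_parameter_table(ptab),
             file.path(config$out, "parameter_table.txt"))

  manifest <- list(
    seed = config$seed, species = config$species,
    segment_length = config$segment_length,
    grid_cell = config$grid_cell, family = family,
    mcmc = list(chains = spec$chains, warmup = spec$warmup,
                draws = spec$draws, knots = spec$knots),
    converged = fit$converged,
    config_hash = .fnv1a(paste(deparse(config), collapse = "")),
    versions = list(R = paste(R.version$major, R.version$minor, sep = "."),
                    marinedisp = as.character(
                      utils::packageVersion("marinedisp"))))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  status <- if (fit$converged) "ok" else "degraded"
  .log(config, "done: status %s", status)
  invisible(list(status = status, dir = config$out,
                 message = "pipeline complete", fit = fit))
}

#' Render the phase-contrast parameter table
#'
#' One row per phase contrast (plus the sea-state row for ZIP fits):
#' raw (link-scale) posterior mean and 95% CrI, response-level estimate
#' and CrI (elementwise inverse link of the raw columns), and the
#' credible-interval significance call.
#'
#' @param fit a `disp_fit`, or a data.frame of precomputed raw rows with
#'   columns `parameter`, `raw_est`, `raw_lower`, `raw_upper`, `link`
#'   (for rendering externally reported estimates).
#' @return data.frame with raw and response-level columns and
#'   `significant`.
#' @export
render_parameter_table <- function(fit) {
  if (inherits(fit, "disp_fit")) {
    cc <- phase_contrasts(fit)
    labs <- c(pre_vs_con = "Preconstruction versus construction",
              con_vs_op = "Construction versus operation",
              pre_vs_op = "Preconstruction versus operation")
    rows <- lapply(colnames(cc), function(p) {
      ci <- stats::quantile(cc[, p], c(0.025, 0.975), names = FALSE)
      data.frame(parameter = labs[[p]], raw_est = mean(cc[, p]),
                 raw_lower = ci[1], raw_upper = ci[2], link = "log")
    })
    raw <- do.call(rbind, rows)
    if (fit$spec$family == "ZIP") {
      g <- fit$draws[, "gamma_cond"]
      ci <- stats::quantile(g, c(0.025, 0.975), names = FALSE)
      raw <- rbind(raw, data.frame(
        parameter = "Good sea state versus poor sea state",
        raw_est = mean(g), raw_lower = ci[1], raw_upper = ci[2],
        link = "logit"))
    }
  } else raw <- fit
  resp <- do.call(rbind, lapply(seq_len(nrow(raw)), function(i)
    response_level(raw$raw_est[i], raw$raw_lower[i], raw$raw_upper[i],
                   link = raw$link[i])))
  data.frame(parameter = raw$parameter,
             raw_est = raw$raw_est, raw_lower = raw$raw_lower,
             raw_upper = raw$raw_upper,
             resp_est = resp$est, resp_lower = resp$lower,
             resp_upper = resp$upper,
             significant = vapply(seq_len(nrow(raw)), function(i)
               significance(c(raw$raw_lower[i], raw$raw_upper[i])),
               character(1)))
}

#' Format the parameter table as aligned text
#'
#' Parameters are printed with 3 decimals.
#'
#' @param tab output of [render_parameter_table()].
#' @return character vector of lines.
#' @export
format_parameter_table <- function(tab) {
  f <- function(x) sprintf("%.3f", x)
  hdr <- sprintf("%-42s %8s %18s %8s %18s  %s",
                 "Model parameter", "Raw", "95% CrI", "Response",
                 "95% CrI", "Significant")
  rows <- vapply(seq_len(nrow(tab)), function(i) sprintf(
    "%-42s %8s (%7s, %7s) %8s (%7s, %7s)  %s",
    tab$parameter[i], f(tab$raw_est[i]), f(tab$raw_lower[i]),
    f(tab$raw_upper[i]), f(tab$resp_est[i]), f(tab$resp_lower[i]),
    f(tab$resp_upper[i]), tab$significant[i]), character(1))
  c(hdr, rows)
}

#' Format the effort ledger as aligned text
#'
#' Effort in km with the footprint effort bracketed, counts with
#' thousands separators, rate with its standard error.
#'
#' @param ledger output of [effort_ledger()].
#' @return character vector of lines.
#' @export
render_effort_table <- function(ledger) {
  big <- function(x) format(round(x), big.mark = ",", trim = TRUE)
  hdr <- sprintf("%-16s %18s %14s %22s", "Phase", "Effort km (fp)",
                 "Individuals", "Rate per km (+-SE)")
  rows <- vapply(seq_len(nrow(ledger)), function(i) sprintf(
    "%-16s %12s (%s) %14s %14.3f (%s)",
    ledger$phase[i], big(ledger$effort_km[i]),
    big(ledger$footprint_km[i]), big(ledger$individuals[i]),
    ledger$rate[i],
    if (is.na(ledger$se[i])) "n/a" else sprintf("+-%.3f", ledger$se[i])),
    character(1))
  c(hdr, rows)
}

#' Verify that rendered tables are recomputable from stored artifacts
#'
#' Re-derives the parameter table from `draws.csv` and the effort table
#' from `segments.csv` (+ `footprint.geojson` if present) in a run
#' directory and diffs them against the stored CSVs.
#'
#' @param dir a run directory written by [run_pipeline()].
#' @param tol numeric tolerance for the comparison.
#' @return `TRUE` if both tables match; otherwise a character vector of
#'   mismatches.
#' @export
verify_run <- function(dir, tol = 1e-8) {
  problems <- character(0)
  draws_long <- utils::read.csv(file.path(dir, "draws.csv"))
  d <- do.call(cbind, split(draws_long$value, draws_long$parameter))
  stored <- utils::read.csv(file.path(dir, "parameter_table.csv"))
  fam <- if ("gamma_cond" %in% colnames(d)) "ZIP" else "NB"
  con <- if ("phase_construction" %in% colnames(d))
    d[, "phase_construction"] else 0
  op <- if ("phase_operation" %in% colnames(d)) d[, "phase_operation"]
    else 0
  cc <- cbind(con, op - con, op)
  raw <- data.frame(
    parameter = stored$parameter[1:3],
    raw_est = colMeans(cc),
    raw_lower = apply(cc, 2, stats::quantile, 0.025),
    raw_upper = apply(cc, 2, stats::quantile, 0.975),
    link = "log")
  if (fam == "ZIP") {
    g <- d[, "gamma_cond"]
    raw <- rbind(raw, data.frame(
      parameter = stored$parameter[4], raw_est = mean(g),
      raw_lower = stats::quantile(g, 0.025),
      raw_upper = stats::quantile(g, 0.975), link = "logit"))
  }
  redone <- render_parameter_table(raw)
  num <- sapply(redone, is.numeric)
  if (nrow(redone) != nrow(stored) ||
      max(abs(as.matrix(redone[, num]) - as.matrix(stored[, num]))) > tol)
    problems <- c(problems, "parameter_table.csv not reproducible")
  seg <- utils::read.csv(file.path(dir, "segments.csv"))
  fp <- if (file.exists(file.path(dir, "footprint.geojson")))
    read_footprint(file.path(dir, "footprint.geojson")) else NULL
  redone_led <- effort_ledger(seg, fp)
  stored_led <- utils::read.csv(file.path(dir, "effort_table.csv"))
  numl <- sapply(redone_led, is.numeric)
  a <- as.matrix(redone_led[, numl]); b <- as.matrix(stored_led[, numl])
  a[is.na(a)] <- -1; b[is.na(b)] <- -1
  if (max(abs(a - b)) > tol)
    problems <- c(problems, "effort_table.csv not reproducible")
  if (length(problems)) problems else TRUE
}
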