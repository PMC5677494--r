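## Posterior prediction surfaces per development phase and pairwise
## change maps with the credible-interval non-overlap displacement rule.
##
## Predictions are population-level relative abundance: random effects
## at zero, full nominal segment effort, good sea state (ZIP), so a cell
## value is the expected count per segment for an average survey.

#' Build a prediction grid over the surveyed area
#'
#' Regular grid of square cells (side = `cell_size` metres) covering the
#' convex hull of the surveyed segment midpoints; cells whose centres
#' fall outside the hull are dropped to avoid extrapolating the smooths
#' off-support.
#'
#' @param fit a `disp_fit` (the hull of its training midpoints is used),
#'   or a `segment_table`.
#' @param cell_size cell side in metres; defaults to the fit's nominal
#'   segment length (600 m -> 0.36 km^2 cells, 1000 m -> 1 km^2 cells).
#' @return data.frame with cell centre columns `x`, `y`; attribute
#'   `cell_area_km2`.
#' @export
make_grid <- function(fit, cell_size = NULL) {
  if (inherits(fit, "disp_fit")) {
    hull <- fit$hull
    cell_size <- cell_size %||% fit$nominal
  } else {
    hull <- .convex_hull(fit$x, fit$y)
    cell_size <- cell_size %||% attr(fit, "nominal_length") %||% 600
  }
  rx <- range(hull[, 1]); ry <- range(hull[, 2])
  cx <- seq(rx[1] + cell_size / 2, rx[2], by = cell_size)
  cy <- seq(ry[1] + cell_size / 2, ry[2], by = cell_size)
  g <- expand.grid(x = cx, y = cy)
  keep <- points_in_polygon(g$x, g$y, hull)
  g <- g[keep, , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "cell_area_km2") <- (cell_size / 1000)^2
  g
}

#' Posterior prediction surface for one development phase
#'
#' For every posterior draw and grid cell the expected count per segment
#' is `mu = exp(beta_phase + f_phase(x, y))` with random effects at zero
#' and full nominal effort; for the ZIP model it is `(1 - pi0) * mu` at
#' the stated sea-state condition. Cells are summarized by the posterior
#' mean, SD and 2.5%/97.5% quantiles.
#'
#' @param fit a `disp_fit`.
#' @param grid prediction grid from [make_grid()].
#' @param phase one of the phases present in the fit.
#' @param condition sea-state condition for the ZIP zero part
#'   (default `"good"`).
#' @return a `prediction_grid` data.frame (`x`, `y`, `mean`, `sd`,
#'   `lower`, `upper`) with the per-cell draw matrix in the `draws`
#'   attribute.
#' @export
predict_surface <- function(fit, grid, phase, condition = "good") {
  if (!phase %in% fit$levels)
    stop("phase '", phase, "' absent from the fitted model")
  d <- fit$draws
  q <- fit$basis$rank
  U <- basis_design(fit$basis, cbind(grid$x, grid$y))
  xs <- (grid$x - fit$ctr["x"]) / 1000
  ys <- (grid$y - fit$ctr["y"]) / 1000
  cols <- c("(Intercept)",
            if (paste0("phase_", phase) %in% colnames(d))
              paste0("phase_", phase),
            paste0("lin_x_", phase), paste0("lin_y_", phase),
            paste0("s_", phase, "[", 1:q, "]"))
  Xg <- cbind(1,
              if (paste0("phase_", phase) %in% colnames(d))
                rep(1, nrow(grid)),
              xs, ys, U)
  eta <- d[, cols, drop = FALSE] %*% t(Xg)   # draws x cells
  mu <- exp(eta)
  if (fit$spec$family == "ZIP") {
    g <- d[, "gamma0"] + d[, "gamma_cond"] * (condition == "poor")
    mu <- (1 - stats::plogis(g)) * mu
  }
  out <- data.frame(
    x = grid$x, y = grid$y,
    mean = colMeans(mu),
    sd = apply(mu, 2, stats::sd),
    lower = apply(mu, 2, stats::quantile, 0.025, names = FALSE),
    upper = apply(mu, 2, stats::quantile, 0.975, names = FALSE))
  attr(out, "draws") <- mu
  attr(out, "phase") <- phase
  attr(out, "species") <- fit$species
  attr(out, "cell_area_km2") <- attr(grid, "cell_area_km2")
  class(out) <- c("prediction_grid", "data.frame")
  out
}

#' Per-cell uncertainty map
#'
#' Posterior SD expressed as a proportion of the posterior mean. A
#' degenerate cell (SD = 0) maps to 0; a zero-mean cell is flagged and
#' its ratio is `NA`.
#'
#' @param grid a `prediction_grid`.
#' @return data.frame `x`, `y`, `ratio`, `flagged`.
#' @export
uncertainty_map <- function(grid) {
  stopifnot(all(grid$mean >= 0))
  zero <- grid$mean == 0 & grid$sd > 0
  ratio <- ifelse(grid$sd == 0, 0, grid$sd / grid$mean)
  ratio[zero] <- NA_real_
  data.frame(x = grid$x, y = grid$y, ratio = ratio, flagged = zero)
}

#' Pairwise phase change map
#'
#' Difference of posterior means (`B - A`) per cell, with a per-cell
#' significance flag. The default `"overlap"` rule flags a cell when the
#' two phases' marginal 95% credible intervals are disjoint (a
#' conservative test); `"difference"` instead flags cells whose 95% CrI
#' of the per-draw difference excludes zero.
#'
#' @param gridA,gridB `prediction_grid`s on identical cell geometry
#'   (e.g. preconstruction and construction surfaces).
#' @param method `"overlap"` (default) or `"difference"`.
#' @return a `change_map` data.frame: `x`, `y`, `diff`, `significant`.
#' @export
change_map <- function(gridA, gridB, method = c("overlap", "difference")) {
  method <- match.arg(method)
  if (nrow(gridA) != nrow(gridB) ||
      any(gridA$x != gridB$x) || any(gridA$y != gridB$y))
    stop("prediction grids have mismatched cell geometry")
  sig <- if (method == "overlap") {
    gridB$lower > gridA$upper | gridA$lower > gridB$upper
  } else {
    da <- attr(gridA, "draws"); db <- attr(gridB, "draws")
    if (is.null(da) || is.null(db))
      stop("difference method needs per-cell draws")
    dd <- db - da
    lo <- apply(dd, 2, stats::quantile, 0.025, names = FALSE)
    hi <- apply(dd, 2, stats::quantile, 0.975, names = FALSE)
    lo > 0 | hi < 0
  }
  out <- data.frame(x = gridA$x, y = gridA$y,
                    diff = gridB$mean - gridA$mean,
                    significant = sig)
  attr(out, "phases") <- c(attr(gridA, "phase"), attr(gridB, "phase"))
  class(out) <- c("change_map", "data.frame")
  out
}

#' Summarize predicted abundance inside the wind-farm footprint
#'
#' Per posterior draw, the mean predicted count per segment over the
#' cells whose centres fall inside the footprint polygon; summarized by
#' posterior mean and 95% CrI.
#'
#' @param grid a `prediction_grid` (with draws).
#' @param polygon footprint polygon: lon/lat matrix (projected
#'   automatically) or UTM `x`,`y` matrix.
#' @return list with `mean`, `lower`, `upper`, `n_cells` and the
#'   per-draw means (`draws`).
#' @export
footprint_summary <- function(grid, polygon) {
  fp <- as.matrix(polygon)
  if (max(abs(fp[, 1])) <= 180 && max(abs(fp[, 2])) <= 90)
    fp <- as.matrix(project_to_utm(fp[, 1], fp[, 2]))
  inside <- points_in_polygon(grid$x, grid$y, fp)
  if (!any(inside)) stop("footprint contains no grid cells")
  mu <- attr(grid, "draws")
  if (is.null(mu)) stop("prediction grid carries no draws")
  per_draw <- rowMeans(mu[, inside, drop = FALSE])
  list(mean = mean(per_draw),
       lower = stats::quantile(per_draw, 0.025, names = FALSE),
       upper = stats::quantile(per_draw, 0.975, names = FALSE),
       n_cells = sum(inside), draws = per_draw)
}

#' Write a prediction grid or change map as delimited text and GeoJSON
#'
#' @param grid a `prediction_grid` or `change_map`.
#' @param path output CSV path.
#' @param geojson optional path for a GeoJSON FeatureCollection of cell
#'   centres (WGS84) carrying the same columns as properties.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path, geojson = NULL) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE,
                   quote = FALSE)
  if (!is.null(geojson)) {
    ll <- utm_to_lonlat(grid$x, grid$y)
    feats <- lapply(seq_len(nrow(grid)), function(i) {
      props <- as.list(as.data.frame(grid)[i, setdiff(names(grid),
                                                      c("x", "y"))])
      list(type = "Feature",
           properties = props,
           geometry = list(type = "Point",
                           coordinates = c(ll$lon[i], ll$lat[i])))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         geojson, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
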