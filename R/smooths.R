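## Low-rank penalized two-dimensional spline bases over UTM coordinates.
##
## The spatial smooth f(x, y) is represented with a thin-plate radial
## basis: design column j is eta(||s - kappa_j||) with eta(r) = r^2 log r
## (eta(0) = 0) on a space-filling set of knots kappa, plus an
## unpenalized linear span (1, x, y) handled at the model-matrix level.
## The wiggliness penalty is the kernel Gram matrix on the knots. The
## thin-plate kernel is conditionally positive definite of order 2, so
## penalized coefficients are constrained to the orthogonal complement of
## the degree-1 polynomials on the knots (null-space projection N), which
## makes the projected penalty positive semi-definite. A sum-to-zero
## centering over the observed rows keeps the smooth identifiable
## alongside the intercept.

.tps_eta <- function(r) ifelse(r > 0, r^2 * log(r), 0)

.cross_dist <- function(a, b) {
  ## euclidean distances between rows of a (n x 2) and b (k x 2)
  sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0))
}

#' Choose space-filling knot locations
#'
#' Farthest-point (greedy cover) design over the distinct observed
#' coordinates: starting from a seed-chosen point, repeatedly adds the
#' point farthest from the current knot set. Deterministic given `seed`.
#'
#' @param coords two-column matrix of coordinates (metres).
#' @param k number of knots (>= 4).
#' @param seed integer seed selecting the starting point.
#' @return a `k` x 2 matrix of knot coordinates.
#' @export
place_knots <- function(coords, k, seed = 1) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  u <- unique(coords)
  if (k < 4) stop("need at least 4 knots")
  if (k > nrow(u)) stop("k exceeds the number of distinct coordinates")
  if (k == nrow(u)) return(unname(u))
  rng <- .save_rng()
  on.exit(.restore_rng(rng))
  set.seed(seed)
  sel <- sample.int(nrow(u), 1)
  mind <- .cross_dist(u, u[sel, , drop = FALSE])[, 1]
  while (length(sel) < k) {
    nxt <- which.max(mind)  # ties: lowest index, deterministic
    sel <- c(sel, nxt)
    mind <- pmin(mind, .cross_dist(u, u[nxt, , drop = FALSE])[, 1])
  }
  unname(u[sel, , drop = FALSE])
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Build a constrained low-rank thin-plate radial basis
#'
#' @param coords two-column matrix of observed coordinates (metres).
#' @param knots knot matrix from [place_knots()] (metres); coincident
#'   knots are rejected.
#' @return an object of class `tprs_basis` with elements:
#'   `design` (constrained, centred design, `n x rank`), `penalty`
#'   (positive semi-definite penalty for `design` coefficients),
#'   `udesign` (whitened design whose coefficients carry an iid normal
#'   prior in the sampler), `knots`, `rank`, and the stored centering
#'   constants needed to reproduce predictions.
#' @export
build_basis <- function(coords, knots) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  knots <- as.matrix(knots)[, 1:2, drop = FALSE]
  if (nrow(knots) < 4) stop("need at least 4 knots")
  if (anyDuplicated(knots)) stop("coincident knots")
  scale <- 1000  # work in km for numerical conditioning
  kk <- knots / scale
  cc <- coords / scale
  E <- .tps_eta(.cross_dist(kk, kk))
  Tk <- cbind(1, kk)
  N <- qr.Q(qr(Tk), complete = TRUE)[, -(1:3), drop = FALSE]
  P <- crossprod(N, E %*% N)
  P <- (P + t(P)) / 2
  eg <- eigen(P, symmetric = TRUE)
  if (any(eg$values < -1e-8 * max(abs(eg$values))))
    stop("projected penalty not positive semi-definite")
  lam <- pmax(eg$values, 1e-10 * max(eg$values))
  Z <- .tps_eta(.cross_dist(cc, kk)) %*% N
  cm <- colMeans(Z)
  Zc <- sweep(Z, 2, cm)
  W <- eg$vectors %*% diag(1 / sqrt(lam), length(lam))
  structure(list(
    knots = knots, scale = scale, N = N, penalty = P,
    whiten = W, colmeans = cm,
    design = Zc, udesign = Zc %*% W,
    rank = ncol(Zc)
  ), class = "tprs_basis")
}

#' Evaluate a basis at new coordinates
#'
#' Returns the constrained (centred) design matrix for new points, or the
#' whitened version matching the sampler's coefficient scale.
#'
#' @param basis a `tprs_basis`.
#' @param coords two-column matrix of coordinates (metres).
#' @param whitened return the whitened design (default) or the raw
#'   constrained design.
#' @return matrix with `basis$rank` columns.
#' @export
basis_design <- function(basis, coords, whitened = TRUE) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  Z <- .tps_eta(.cross_dist(coords / basis$scale,
                            basis$knots / basis$scale)) %*% basis$N
  Zc <- sweep(Z, 2, basis$colmeans)
  if (whitened) Zc %*% basis$whiten else Zc
}

#' Expand a basis into phase-specific blocks
#'
#' Factor-by expansion: the design is block-diagonal over development
#' phases so a distinct smooth is estimated for each phase. A row has
#' nonzero entries only in its own phase's block. With a single phase the
#' expansion is degenerate and returns the input design.
#'
#' @param basis a `tprs_basis`.
#' @param phases factor (or character) of phase labels, one per row of
#'   the coordinates the basis was built on; unknown labels are rejected.
#' @return an object of class `phase_basis` with the expanded `design`
#'   (`n x (nlevels * rank)`), the per-column `block` index, the shared
#'   `basis` and the phase `levels`.
#' @export
expand_by_phase <- function(basis, phases) {
  if (is.character(phases)) {
    if (!all(phases %in% PHASE_LEVELS)) stop("unknown phase label")
    phases <- factor(phases, levels = PHASE_LEVELS)
  }
  phases <- droplevels(as.factor(phases))
  if (anyNA(phases)) stop("unknown phase label")
  lev <- levels(phases)
  q <- basis$rank
  U <- basis$udesign
  if (nrow(U) != length(phases))
    stop("phase vector length does not match the basis rows")
  D <- matrix(0, nrow(U), q * length(lev))
  for (p in seq_along(lev)) {
    rows <- phases == lev[p]
    D[rows, ((p - 1) * q + 1):(p * q)] <- U[rows, , drop = FALSE]
  }
  structure(list(design = D, block = rep(seq_along(lev), each = q),
                 basis = basis, levels = lev, rank = q),
            class = "phase_basis")
}

#' Serialize a basis to a plain-text sidecar
#'
#' Stores knots, centering constants and transforms as JSON so that
#' prediction surfaces are exactly reproducible across runs.
#'
#' @param basis a `tprs_basis`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_basis <- function(basis, path) {
  jsonlite::write_json(
    list(knots = basis$knots, scale = basis$scale, N = basis$N,
         whiten = basis$whiten, colmeans = basis$colmeans,
         penalty = basis$penalty, rank = basis$rank),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a basis sidecar written by [write_basis()]
#' @param path path to the JSON sidecar.
#' @return a `tprs_basis` (without the observed-row designs).
#' @export
read_basis <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(knots = b$knots, scale = b$scale, N = b$N,
                 whiten = b$whiten, colmeans = b$colmeans,
                 penalty = b$penalty, rank = b$rank),
            class = "tprs_basis")
}
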