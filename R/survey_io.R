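## Ingestion of boat-based line-transect survey logs, segmentation of
## transects into fixed-length along-track segments, and assembly of the
## per-segment modelling table.
##
## The modelling unit is the segment: a half-open chainage interval
## [k*L, (k+1)*L) along a transect's GPS polyline (L = 600 m for the
## seabird analysis, 1000 m for the cetacean analysis). Counts of
## individuals, a good/poor sea-state condition and a development phase
## are attached to each segment.

PHASE_LEVELS <- c("preconstruction", "construction", "operation")
SPECIES_LEVELS <- c("guillemot", "harbor_porpoise")

.parse_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(t)) stop("unparseable ISO-8601 timestamps")
  as.numeric(t)
}

.fmt_time <- function(t) format(.POSIXct(t, tz = "UTC"), "%Y-%m-%dT%H:%M:%S")

#' Read a survey file set
#'
#' Reads the four delimited survey files (`track.csv`, `sightings.csv`,
#' `seastate.csv`, `phases.csv`) and, when present, the wind-farm
#' footprint polygon `footprint.geojson` from a directory. Timestamps
#' are parsed to seconds since epoch; basic invariants (timestamp order
#' within transects, Beaufort range 0-5, positive counts) are checked.
#'
#' @param dir directory containing the input files.
#' @return a list with elements `track`, `sightings`, `seastate`,
#'   `phases` (data.frames) and `footprint` (lon/lat matrix or `NULL`).
#' @export
read_survey <- function(dir) {
  need <- c("track.csv", "sightings.csv", "seastate.csv", "phases.csv")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing input file: ", f)
  track <- utils::read.csv(file.path(dir, "track.csv"))
  sightings <- utils::read.csv(file.path(dir, "sightings.csv"))
  seastate <- utils::read.csv(file.path(dir, "seastate.csv"))
  phases <- utils::read.csv(file.path(dir, "phases.csv"))
  track$timestamp <- .parse_time(track$timestamp)
  sightings$timestamp <- .parse_time(sightings$timestamp)
  seastate$timestamp <- .parse_time(seastate$timestamp)
  if (any(track$lat <= -90 | track$lat >= 90) ||
      any(track$lon <= -180 | track$lon >= 180))
    stop("track coordinates out of range")
  ord <- order(track$survey_id, track$transect_id, track$timestamp)
  track <- track[ord, , drop = FALSE]
  key <- interaction(track$survey_id, track$transect_id, drop = TRUE)
  if (any(unlist(tapply(track$timestamp, key, function(t) diff(t) <= 0))))
    stop("track timestamps not strictly increasing within a transect")
  if (any(sightings$count < 1 | sightings$count != round(sightings$count)))
    stop("sighting counts must be positive integers")
  if (!all(sightings$species %in% SPECIES_LEVELS))
    stop("unknown species in sightings")
  bad <- sightings$behavior == "not_applicable" &
    sightings$species != "harbor_porpoise"
  if (any(bad)) stop("behavior 'not_applicable' is porpoise-only")
  if (any(!(seastate$beaufort %in% 0:5)))
    stop("Beaufort sea state must be an integer in 0..5")
  if (!all(phases$phase %in% PHASE_LEVELS))
    stop("unknown development phase in phases.csv")
  fp <- file.path(dir, "footprint.geojson")
  footprint <- if (file.exists(fp)) read_footprint(fp) else NULL
  list(track = track, sightings = sightings, seastate = seastate,
       phases = phases, footprint = footprint)
}

## per-transect chainage geometry: projected coords, cumulative distance
.transect_geom <- function(tr) {
  p <- project_to_utm(tr$lon, tr$lat)
  dd <- sqrt(diff(p$x)^2 + diff(p$y)^2)
  list(x = p$x, y = p$y, t = tr$timestamp, chain = c(0, cumsum(dd)))
}

.interp_at_chain <- function(g, s) {
  list(x = stats::approx(g$chain, g$x, s, ties = "ordered", rule = 2)$y,
       y = stats::approx(g$chain, g$y, s, ties = "ordered", rule = 2)$y,
       t = stats::approx(g$chain, g$t, s, ties = "ordered", rule = 2)$y)
}

#' Divide transect tracks into fixed-length segments
#'
#' Computes along-track chainage from consecutive projected GPS fixes and
#' partitions each transect into half-open chainage intervals
#' `[k*L, (k+1)*L)`. The final partial segment is retained with its true
#' effort length. Segment midpoints (position and time) are interpolated
#' along the polyline at chainage `(start + end) / 2`.
#'
#' @param track data.frame with columns `survey_id`, `transect_id`,
#'   `timestamp` (seconds), `lon`, `lat`; at least two fixes per transect.
#' @param nominal_length nominal segment length L in metres (600 or 1000).
#' @return data.frame of segments with identifiers, chainage bounds,
#'   midpoint easting/northing `x`,`y`, midpoint time `t_mid`, time window
#'   `t_start`,`t_end` and `effort_m`. Counts are unset at this stage.
#' @export
segment_transects <- function(track, nominal_length) {
  stopifnot(nominal_length > 0)
  key <- interaction(track$survey_id, track$transect_id, drop = TRUE)
  out <- lapply(split(track, key), function(tr) {
    if (nrow(tr) < 2)
      stop("transect with fewer than 2 track points: ",
           tr$survey_id[1], "/", tr$transect_id[1])
    g <- .transect_geom(tr)
    total <- g$chain[length(g$chain)]
    if (total <= 0)
      stop("zero-length transect: ", tr$survey_id[1], "/", tr$transect_id[1])
    starts <- seq(0, total, by = nominal_length)
    if (starts[length(starts)] >= total)
      starts <- starts[-length(starts)]
    ends <- pmin(starts + nominal_length, total)
    ## fold a sub-millimetre terminal sliver (floating-point chainage)
    ## into the previous segment so the partition is preserved exactly
    k <- length(starts)
    if (k > 1 && ends[k] - starts[k] < 1e-3) {
      starts <- starts[-k]; ends <- ends[-k]
      ends[k - 1] <- total
    }
    mid <- .interp_at_chain(g, (starts + ends) / 2)
    t0 <- .interp_at_chain(g, starts)$t
    t1 <- .interp_at_chain(g, ends)$t
    data.frame(
      survey_id = tr$survey_id[1], transect_id = tr$transect_id[1],
      seg_index = seq_along(starts),
      chain_start = starts, chain_end = ends,
      x = mid$x, y = mid$y,
      t_start = t0, t_mid = mid$t, t_end = t1,
      effort_m = ends - starts
    )
  })
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$segment_id <- paste(seg$survey_id, seg$transect_id, seg$seg_index,
                          sep = ":")
  seg[, c("segment_id", "survey_id", "transect_id", "seg_index",
          "chain_start", "chain_end", "x", "y",
          "t_start", "t_mid", "t_end", "effort_m")]
}

#' Assign sightings to segments
#'
#' Each sighting's along-track position is obtained by linear
#' interpolation of chainage against time between the bracketing GPS
#' fixes of the transect whose time span contains the sighting. The
#' sighting is assigned to the segment whose half-open chainage interval
#' contains that position (a sighting exactly on a boundary `(k+1)*L`
#' belongs to segment `k+1`), and counts are summed per segment.
#' Sightings whose timestamps fall outside every transect's time span
#' are excluded and counted in the `excluded` attribute.
#'
#' @param sightings data.frame with `survey_id`, `timestamp`, `species`,
#'   `count`, `behavior`.
#' @param track track data.frame (as for [segment_transects()]).
#' @param segments segment data.frame from [segment_transects()].
#' @param species `"guillemot"` or `"harbor_porpoise"`; only sightings of
#'   this species are used.
#' @param on_sea_only drop `in_flight` records (the seabird analysis uses
#'   only birds on the sea surface).
#' @return `segments` with a `count` column; attributes `species`,
#'   `nominal_length` and `excluded` (number of unassignable sightings).
#' @export
assign_sightings <- function(sightings, track, segments, species,
                             on_sea_only = species == "guillemot") {
  s <- sightings[sightings$species == species, , drop = FALSE]
  if (on_sea_only) s <- s[s$behavior != "in_flight", , drop = FALSE]
  counts <- integer(nrow(segments))
  assigned <- rep(FALSE, nrow(s))
  key <- interaction(track$survey_id, track$transect_id, drop = TRUE)
  for (tr in split(track, key)) {
    sv <- tr$survey_id[1]; tid <- tr$transect_id[1]
    span <- range(tr$timestamp)
    si <- which(s$survey_id == sv & s$timestamp >= span[1] &
                  s$timestamp <= span[2] & !assigned)
    if (!length(si)) next
    assigned[si] <- TRUE
    g <- .transect_geom(tr)
    chain <- stats::approx(g$t, g$chain, s$timestamp[si],
                           ties = "ordered")$y
    segs_tr <- which(segments$survey_id == sv & segments$transect_id == tid)
    st <- segments[segs_tr, ]
    ## half-open intervals [start, end): a sighting exactly on a boundary
    ## belongs to the next segment; the transect's final chainage (== last
    ## segment's end) is absorbed by the last segment
    idx <- findInterval(chain, c(st$chain_start, st$chain_end[nrow(st)]),
                        rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= nrow(st)
    add <- tapply(s$count[si][ok], idx[ok], sum)
    at <- segs_tr[as.integer(names(add))]
    counts[at] <- counts[at] + as.integer(add)
  }
  excluded <- sum(!assigned)
  if (excluded > 0)
    message(excluded, " sighting(s) outside track time spans were excluded")
  segments$count <- counts
  attr(segments, "species") <- species
  attr(segments, "nominal_length") <- max(segments$chain_end -
                                            segments$chain_start)
  attr(segments, "excluded") <- excluded
  segments
}

#' Classify segment survey conditions from Beaufort sea state
#'
#' Each segment takes the Beaufort value of the most recent sea-state
#' record (same survey and transect) at or before its midpoint time; if
#' none precedes the midpoint the transect's first record is used (sea
#' state is recorded at the start of each transect). Beaufort 0-2 is
#' classed `good`, 3-5 `poor`.
#'
#' @param seastate data.frame with `survey_id`, `transect_id`,
#'   `timestamp`, `beaufort`.
#' @param segments segment data.frame with `t_mid`.
#' @return `segments` with `beaufort` and `condition` columns.
#' @export
classify_conditions <- function(seastate, segments) {
  bfts <- integer(nrow(segments))
  for (grp in split(seq_len(nrow(segments)),
                    paste(segments$survey_id, segments$transect_id))) {
    sv <- segments$survey_id[grp[1]]
    tr <- segments$transect_id[grp[1]]
    rec <- seastate[seastate$survey_id == sv & seastate$transect_id == tr, ]
    if (nrow(rec) == 0)
      stop("no sea-state record for transect ", sv, "/", tr)
    rec <- rec[order(rec$timestamp), ]
    idx <- findInterval(segments$t_mid[grp], rec$timestamp)
    idx[idx == 0] <- 1L  # fall back to the start-of-transect record
    bfts[grp] <- rec$beaufort[idx]
  }
  segments$beaufort <- bfts
  segments$condition <- ifelse(bfts <= 2, "good", "poor")
  segments
}

#' Build the per-segment modelling table
#'
#' One-stop assembly: segments transects, assigns sightings of one
#' species, classifies sea-state conditions and attaches development
#' phases from the survey lookup.
#'
#' @param data survey file set from [read_survey()] (or the equivalent
#'   in-memory list from [simulate_surveys()]).
#' @param species `"guillemot"` or `"harbor_porpoise"`.
#' @param nominal_length segment length in metres; defaults to 600 for
#'   guillemot and 1000 for harbour porpoise.
#' @param on_sea_only see [assign_sightings()].
#' @return a `segment_table` data.frame, one row per surveyed segment.
#' @export
build_segments <- function(data, species,
                           nominal_length = if (species == "guillemot")
                             600 else 1000,
                           on_sea_only = species == "guillemot") {
  seg <- segment_transects(data$track, nominal_length)
  seg <- assign_sightings(data$sightings, data$track, seg, species,
                          on_sea_only)
  seg <- classify_conditions(data$seastate, seg)
  ph <- data$phases$phase[match(seg$survey_id, data$phases$survey_id)]
  if (anyNA(ph)) stop("survey missing from phase lookup")
  seg$phase <- factor(ph, levels = PHASE_LEVELS)
  attr(seg, "species") <- species
  attr(seg, "nominal_length") <- nominal_length
  class(seg) <- c("segment_table", "data.frame")
  seg
}

#' Write a segment table as delimited text
#'
#' Fixed column order:
#' `segment_id,survey_id,transect_id,phase,x,y,effort_m,condition,count`.
#'
#' @param seg a `segment_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segment_table <- function(seg, path) {
  out <- seg[, c("segment_id", "survey_id", "transect_id", "phase",
                 "x", "y", "effort_m", "condition", "count")]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-phase effort ledger
#'
#' Summarizes survey effort and observations per development phase:
#' total effort (km), effort of segments whose midpoints fall inside the
#' wind-farm footprint, total individuals, and the encounter rate
#' computed as the mean over surveys of per-survey individuals per km
#' with its standard error across surveys. A `total` row pools all
#' surveys.
#'
#' @param seg a `segment_table` with counts and phases.
#' @param footprint optional footprint polygon, lon/lat matrix (as from
#'   [read_footprint()]) or UTM matrix with columns `x`,`y`.
#' @return data.frame with one row per phase plus a total row.
#' @export
effort_ledger <- function(seg, footprint = NULL) {
  inside <- rep(FALSE, nrow(seg))
  if (!is.null(footprint)) {
    fp <- as.matrix(footprint)
    if (all(c("lon", "lat") %in% colnames(fp)) ||
        max(abs(fp[, 1])) <= 180 && max(abs(fp[, 2])) <= 90) {
      fp <- as.matrix(project_to_utm(fp[, 1], fp[, 2]))
    }
    inside <- points_in_polygon(seg$x, seg$y, fp)
  }
  one <- function(rows, label) {
    d <- seg[rows, , drop = FALSE]
    by_survey <- split(d, factor(d$survey_id))
    rates <- vapply(by_survey, function(s)
      sum(s$count) / (sum(s$effort_m) / 1000), numeric(1))
    n <- length(rates)
    data.frame(
      phase = label,
      effort_km = sum(d$effort_m) / 1000,
      footprint_km = sum(d$effort_m[inside[rows]]) / 1000,
      individuals = sum(d$count),
      rate = mean(rates),
      se = if (n > 1) stats::sd(rates) / sqrt(n) else NA_real_,
      n_surveys = n
    )
  }
  phases <- PHASE_LEVELS[PHASE_LEVELS %in% as.character(seg$phase)]
  if (length(phases) < length(unique(seg$phase)))
    warning("phases with zero effort omitted")
  rows <- lapply(phases, function(p) one(which(seg$phase == p), p))
  out <- do.call(rbind, c(rows, list(one(seq_len(nrow(seg)), "total"))))
  rownames(out) <- NULL
  out
}
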