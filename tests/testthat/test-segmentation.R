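test_that("a straight transect is partitioned into nominal segments", {
  tr <- straight_track(1800)
  seg <- segment_transects(tr, 600)
  expect_equal(nrow(seg), 3)
  expect_equal((seg$chain_start + seg$chain_end) / 2, c(300, 900, 1500),
               tolerance = 1e-6)
  expect_equal(seg$effort_m, rep(600, 3), tolerance = 1e-6)
  # midpoints lie on the transect line at the right northing
  expect_equal(seg$y - min(seg$y), c(0, 600, 1200), tolerance = 0.01)
})

test_that("the final partial segment keeps its true effort length", {
  seg <- segment_transects(straight_track(2000), 600)
  expect_equal(nrow(seg), 4)
  expect_equal(seg$effort_m, c(600, 600, 600, 200), tolerance = 1e-6)
})

test_that("dog-leg transects match a dense polyline walk to < 2 m", {
  # L-shaped transect built from UTM vertices
  xs <- c(455000, 455000, 455600, 456400)
  ys <- c(6060000, 6061000, 6061800, 6061800)
  # densify to GPS-like fixes along each leg
  px <- c(); py <- c()
  for (i in 1:(length(xs) - 1)) {
    t <- seq(0, 1, length.out = 8)[-8]
    px <- c(px, xs[i] + t * (xs[i + 1] - xs[i]))
    py <- c(py, ys[i] + t * (ys[i + 1] - ys[i]))
  }
  px <- c(px, xs[length(xs)]); py <- c(py, ys[length(ys)])
  ll <- utm_to_lonlat(px, py)
  tr <- data.frame(survey_id = "S1", transect_id = "T1",
                   timestamp = seq_along(px) * 30, lon = ll$lon,
                   lat = ll$lat)
  seg <- segment_transects(tr, 600)
  ref <- walk_midpoints(px, py, 600)
  expect_equal(nrow(seg), nrow(ref))
  expect_lt(max(sqrt((seg$x - ref$x)^2 + (seg$y - ref$y)^2)), 2)
  expect_equal(seg$effort_m, ref$effort, tolerance = 1e-6)
})

test_that("segment efforts partition the polyline length", {
  set.seed(4)
  # wiggly transect
  px <- 455000 + cumsum(runif(40, 50, 200))
  py <- 6060000 + cumsum(rnorm(40, 100, 60))
  ll <- utm_to_lonlat(px, py)
  tr <- data.frame(survey_id = "S1", transect_id = "T1",
                   timestamp = seq_along(px) * 30, lon = ll$lon,
                   lat = ll$lat)
  seg <- segment_transects(tr, 600)
  p <- project_to_utm(tr$lon, tr$lat)
  total <- sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
  expect_lt(abs(sum(seg$effort_m) - total), 1)
  # nominal length equal to the transect length gives a single segment
  seg1 <- segment_transects(tr, ceiling(total) + 10)
  expect_equal(nrow(seg1), 1)
  expect_equal(seg1$effort_m, total, tolerance = 1e-6)
})

test_that("degenerate transects are rejected", {
  tr <- straight_track(600)[1, ]
  expect_error(segment_transects(tr, 600), "fewer than 2")
})

test_that("sightings are summed per segment with the on-sea filter", {
  tr <- straight_track(1800, n_fix = 25)  # 360 s total, 5 m/s
  seg <- segment_transects(tr, 600)
  s <- data.frame(
    survey_id = "S1",
    timestamp = c(30, 50, 70, 200, 500),   # 500 s is outside the span
    species = "guillemot",
    count = c(3, 2, 4, 1, 7),
    behavior = c("on_sea", "on_sea", "in_flight", "on_sea", "on_sea"))
  expect_message(
    out <- assign_sightings(s, tr, seg, "guillemot", on_sea_only = TRUE),
    "1 sighting")
  # 30 s and 50 s -> 150 m and 250 m -> segment 1; in-flight dropped;
  # 200 s -> 1000 m -> segment 2
  expect_equal(out$count, c(5, 1, 0))
  expect_equal(attr(out, "excluded"), 1)
  # total conservation of assignable on-sea individuals
  expect_equal(sum(out$count), 6)
})

test_that("assignment interpolates linearly in time between fixes", {
  # two fixes 60 m apart, 12 s apart; sighting exactly midway in time
  ll <- utm_to_lonlat(c(455000, 455000), c(6060000, 6060060))
  tr <- data.frame(survey_id = "S1", transect_id = "T1",
                   timestamp = c(0, 12), lon = ll$lon, lat = ll$lat)
  seg <- segment_transects(tr, 20)
  s <- data.frame(survey_id = "S1", timestamp = 6, species = "guillemot",
                  count = 2, behavior = "on_sea")
  out <- assign_sightings(s, tr, seg, "guillemot")
  # midway in time -> 30 m along -> interior of [20, 40)
  expect_equal(out$count, c(0, 2, 0))
  # a sighting exactly on a boundary chainage belongs to the next
  # segment (half-open intervals): t = 4 s -> 20 m -> [20, 40)
  s2 <- data.frame(survey_id = "S1", timestamp = 4, species = "guillemot",
                   count = 1, behavior = "on_sea")
  expect_equal(assign_sightings(s2, tr, seg, "guillemot")$count,
               c(0, 1, 0))
})

test_that("assignment is independent of sighting input order", {
  tr <- straight_track(3000, n_fix = 40)
  seg <- segment_transects(tr, 600)
  set.seed(8)
  s <- data.frame(survey_id = "S1",
                  timestamp = runif(30, 0, 600),
                  species = "guillemot",
                  count = rpois(30, 2) + 1,
                  behavior = "on_sea")
  a <- assign_sightings(s, tr, seg, "guillemot")
  b <- assign_sightings(s[sample(nrow(s)), ], tr, seg, "guillemot")
  expect_equal(a$count, b$count)
  expect_equal(sum(a$count), sum(s$count))
})

test_that("empty sightings give all-zero counts", {
  tr <- straight_track(1800)
  seg <- segment_transects(tr, 600)
  s <- data.frame(survey_id = character(), timestamp = numeric(),
                  species = character(), count = integer(),
                  behavior = character())
  out <- assign_sightings(s, tr, seg, "guillemot")
  expect_true(all(out$count == 0))
})

test_that("sea states classify as good (0-2) / poor (3-5) with carry-forward", {
  tr <- straight_track(1800, n_fix = 25)
  seg <- segment_transects(tr, 600)  # midpoints at t = 60, 180, 300
  ss <- data.frame(survey_id = "S1", transect_id = "T1",
                   timestamp = c(0, 170), beaufort = c(2, 3))
  out <- classify_conditions(ss, seg)
  expect_equal(out$condition, c("good", "poor", "poor"))
  # boundary values of the rule
  for (b in 0:5) {
    ss2 <- data.frame(survey_id = "S1", transect_id = "T1",
                      timestamp = 0, beaufort = b)
    expect_equal(unique(classify_conditions(ss2, seg)$condition),
                 if (b <= 2) "good" else "poor")
  }
  # a record after every midpoint: fall back to the transect's first
  ss3 <- data.frame(survey_id = "S1", transect_id = "T1",
                    timestamp = c(900, 950), beaufort = c(4, 1))
  expect_equal(classify_conditions(ss3, seg)$beaufort, c(4, 4, 4))
  # most-recent rule at a stated time
  ss4 <- data.frame(survey_id = "S1", transect_id = "T1",
                    timestamp = c(0, 900), beaufort = c(1, 4))
  seg950 <- seg; seg950$t_mid <- c(60, 180, 950)
  expect_equal(classify_conditions(ss4, seg950)$condition[3], "poor")
})

test_that("effort ledger computes per-survey rates with SE across surveys", {
  seg <- data.frame(
    survey_id = rep(c("A", "B"), each = 2),
    transect_id = "T1",
    phase = factor("construction", levels = PHASE_LEVELS),
    x = c(0, 1000, 0, 1000), y = 500,
    effort_m = 500,
    count = c(1, 0, 1, 1))
  # survey A: 1 per km, survey B: 2 per km
  led <- effort_ledger(seg)
  con <- led[led$phase == "construction", ]
  expect_equal(con$rate, 1.5)
  expect_equal(con$se, 0.5)
  expect_equal(con$effort_km, 2)
  expect_equal(con$individuals, 3)
})

test_that("ledger phase rows add up to the total row", {
  fx <- nb_fixture()
  led <- effort_ledger(fx$seg, fx$sim$footprint)
  ph <- led[led$phase != "total", ]
  tot <- led[led$phase == "total", ]
  expect_equal(sum(ph$effort_km), tot$effort_km)
  expect_equal(sum(ph$footprint_km), tot$footprint_km)
  expect_equal(sum(ph$individuals), tot$individuals)
  expect_gt(tot$footprint_km, 0)
  # count conservation against the generator's on-sea sightings
  s <- fx$sim$sightings
  keep <- s$species == "guillemot" & s$behavior == "on_sea"
  expect_equal(tot$individuals, sum(s$count[keep]))
})

test_that("footprint membership uses midpoint point-in-polygon", {
  poly <- cbind(x = c(0, 1000, 1000, 0), y = c(0, 0, 1000, 1000))
  expect_equal(points_in_polygon(c(500, 1500), c(500, 500), poly),
               c(TRUE, FALSE))
  seg <- data.frame(survey_id = "A", transect_id = "T1",
                    phase = factor("operation", levels = PHASE_LEVELS),
                    x = c(500, 2000), y = c(500, 500),
                    effort_m = c(600, 600), count = c(1, 1))
  led <- effort_ledger(seg, poly)
  expect_equal(led$footprint_km[led$phase == "operation"], 0.6)
})
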