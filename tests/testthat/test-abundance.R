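# straight 10 km eastward track sampled every 100 m
straight_track <- function(length_m = 10000, step_m = 100, lat0 = -33.9,
                           lon0 = 25.7) {
  n <- length_m / step_m + 1
  dlon <- step_m / (6371008.8 * cos(lat0 * pi / 180)) * 180 / pi
  data.frame(time_s = seq_len(n), lat_dd = lat0, lon_dd = lon0 + (seq_len(n) - 1) * dlon)
}

school_at <- function(track, along_m, height = 10, width = 50) {
  i <- along_m / 100 + 1
  lo <- floor(i); frac <- i - lo
  lon <- track$lon_dd[lo] * (1 - frac) + track$lon_dd[min(lo + 1, nrow(track))] * frac
  data.frame(Lat_dd = track$lat_dd[1], Long_dd = lon,
             SchoolHeight = height, SchoolWidth = width)
}

test_that("EDSU partitioning follows the half-open and partial-unit rules", {
  tr <- straight_track(1240)
  a <- assign_edsus(data.frame(), tr)
  # 240 m remainder < 250 m merges into the previous unit
  expect_equal(nrow(a$edsus), 2)
  expect_equal(a$edsus$end_m[2], max(along_track_distance(tr)), tolerance = 1e-6)

  tr2 <- straight_track(1260, step_m = 20)
  a2 <- assign_edsus(data.frame(), tr2)
  expect_equal(nrow(a2$edsus), 3)
  expect_equal(a2$edsus$start_m[3], 1000)

  # the boundary is half-open: just past it joins the later unit
  tr3 <- straight_track(2000)
  a3 <- assign_edsus(school_at(tr3, 1000.5), tr3)
  expect_equal(a3$school_edsu, 3L)
  a3b <- assign_edsus(school_at(tr3, 999.5), tr3)
  expect_equal(a3b$school_edsu, 2L)
  # empty school list still tiles the track
  expect_equal(assign_edsus(data.frame(), tr3)$edsus$index, 1:4)
})

test_that("off-track schools warn and snap", {
  tr <- straight_track(2000)
  s <- school_at(tr, 700)
  s$Lat_dd <- s$Lat_dd + 0.02 # ~2.2 km off-track
  expect_warning(a <- assign_edsus(s, tr), "off-track")
  expect_equal(a$school_edsu, 2L)
})

test_that("edsu_sa implements the nautical-mile scaling", {
  tr <- straight_track(2000)
  s <- school_at(tr, 750, height = 10, width = 50)
  a <- assign_edsus(s, tr)
  e <- edsu_sa(a, s, sv_linear = 1e-5)
  # sv*H*W/500 = 1e-5 -> s_A = 4 pi 1852^2 1e-5
  expect_equal(e$sa[2], 4 * pi * 1852^2 * 1e-5, tolerance = 1e-6)
  expect_equal(e$sa[-2], rep(0, nrow(e) - 1))
  expect_true(e$presence[2] && !any(e$presence[-2]))
  # doubling the width doubles s_A
  s2 <- s; s2$SchoolWidth <- 100
  e2 <- edsu_sa(assign_edsus(s2, tr), s2, 1e-5)
  expect_equal(e2$sa[2], 2 * e$sa[2])
})

test_that("binned s_a conserves the school total and ignores school order", {
  tr <- straight_track(5000)
  set.seed(13)
  n <- 12
  s <- do.call(rbind, lapply(stats::runif(n, 50, 4950), school_at, track = tr,
                             height = 8, width = 30))
  s$SchoolHeight <- stats::runif(n, 2, 15)
  s$SchoolWidth <- stats::runif(n, 10, 80)
  sv <- stats::runif(n, 1e-6, 1e-4)
  a <- assign_edsus(s, tr)
  e <- edsu_sa(a, s, sv)
  lhs <- sum(e$sa / (4 * pi * 1852^2) * (e$end_m - e$start_m))
  rhs <- sum(sv * s$SchoolHeight * s$SchoolWidth)
  expect_equal(lhs, rhs, tolerance = 1e-9)

  perm <- sample(n)
  e2 <- edsu_sa(assign_edsus(s[perm, ], tr), s[perm, ], sv[perm])
  expect_equal(e2$sa, e$sa, tolerance = 1e-9)
})

test_that("detection_table reproduces hand-computed odds ratios", {
  pres <- function(counts) {
    rff <- rep(c(TRUE, TRUE, FALSE, FALSE), counts)
    ses <- rep(c(TRUE, FALSE, TRUE, FALSE), counts)
    list(rff = rff, ses = ses)
  }
  p <- pres(c(28, 10, 15, 23))
  dt <- detection_table(p$rff, p$ses)
  expect_equal(unname(dt$table[1, ]), c(28, 10))
  expect_equal(dt$odds_ratio, (28 * 23) / (10 * 15))
  expect_lt(dt$p.value, 0.01)
  expect_false(dt$haldane)

  # perfect concordance: Haldane correction keeps the estimate finite
  p2 <- pres(c(30, 0, 0, 30))
  dt2 <- detection_table(p2$rff, p2$ses)
  expect_true(dt2$haldane)
  expect_true(is.finite(dt2$odds_ratio))

  # independent systems: association not significant at n = 76
  set.seed(19)
  dt3 <- detection_table(stats::runif(76) < 0.5, stats::runif(76) < 0.5)
  expect_gt(dt3$p.value, 0.05)
})

test_that("matched descriptor regressions behave on identical and noisy pairs", {
  m <- pixel_mapping(-65, 1.3)
  pairs <- generate_matched_pairs(36, mapping = m, seed = 3)
  ident <- pairs
  ident$MeanDepthRFF <- ident$MeanDepthSES
  fit <- matched_descriptor_fit(ident, "depth")
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  depth <- matched_descriptor_fit(pairs, "depth")
  area <- matched_descriptor_fit(pairs, "area")
  expect_gt(depth$r2, 0.9)  # depths agree closely between systems
  expect_gt(area$r2, 0.3)   # areas agree moderately on the log scale
  expect_lt(area$r2, depth$r2)
})

test_that("rolling-scale concordance degenerates correctly at 0.5 km", {
  set.seed(23)
  sa_r <- stats::rexp(60, 1 / 100) * stats::rbinom(60, 1, 0.6)
  sa_s <- sa_r * exp(stats::rnorm(60, 0, 0.3)) * stats::rbinom(60, 1, 0.9)
  rc <- rolling_scale_concordance(sa_r, sa_s, scales_km = 0.5)
  direct <- summary(stats::lm(log(sa_s / 0.5 + 0.1) ~ log(sa_r / 0.5 + 0.1)))$r.squared
  expect_equal(rc$r2, direct, tolerance = 1e-12)
  expect_equal(rc$window, 1L)

  rc2 <- rolling_scale_concordance(sa_r, sa_r)
  expect_true(all(abs(rc2$r2 - 1) < 1e-9))

  expect_warning(rolling_scale_concordance(sa_r[1:10], sa_s[1:10],
                                           scales_km = 17.5),
                 "skipped")
})

test_that("agreement improves with scale for a structured field plus local noise", {
  # the gain with scale requires a spatially autocorrelated prey field:
  # with i.i.d. density, window sums correlate no better than single units
  set.seed(29)
  gains <- replicate(100, {
    lam <- stats::filter(stats::rnorm(80), 0.9, method = "recursive")
    base <- 20 * exp(as.numeric(lam)) # smooth density field
    sa_r <- base * stats::rbinom(80, 1, 0.8) * exp(stats::rnorm(80, 0, 0.8))
    sa_s <- base * stats::rbinom(80, 1, 0.8) * exp(stats::rnorm(80, 0, 0.8))
    rc <- rolling_scale_concordance(sa_r, sa_s, scales_km = c(0.5, 10.5))
    diff(rc$r2)
  })
  expect_gt(mean(gains), 0)
  expect_gt(mean(gains > 0), 0.8)
})
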