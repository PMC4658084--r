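test_that("make_mask marks exactly the echo pixels", {
  px <- matrix(0L, 6, 6)
  px[2:3, 2:4] <- 5L
  fr <- toy_frame(px)
  expect_equal(sum(make_mask(fr)), 6)
  expect_true(all(make_mask(toy_frame(matrix(0L, 4, 4))) == FALSE))
})

test_that("candidate labelling matches the flood-fill oracle", {
  set.seed(5)
  for (conn in c(4L, 8L)) for (i in 1:20) {
    mask <- matrix(stats::runif(64) < 0.4, 8, 8)
    got <- label_components(mask, conn)
    want <- flood_fill_labels(mask, conn)
    expect_equal(max(got), max(want))
    if (max(got) > 0) {
      key <- paste(got[mask], want[mask]) # same partition <=> label bijection
      expect_equal(length(unique(key)), max(got))
    }
  }
})

test_that("find_candidates separates blobs and computes metric extents", {
  mask <- matrix(FALSE, 6, 7)
  mask[2:3, 2:3] <- TRUE
  mask[2:3, 5:6] <- TRUE # one empty column between
  fr <- toy_frame(matrix(0L, 6, 7))
  expect_length(find_candidates(mask, fr, connectivity = 4L), 2)

  one <- matrix(FALSE, 4, 4)
  one[2, 2] <- TRUE
  fr05 <- echogram_frame(matrix(0L, 4, 4), 0, 2, scale8, metres_per_col = 0.5)
  cand <- find_candidates(one, fr05)[[1]]
  expect_equal(cand$L_m, 0.5)
  expect_equal(cand$H_m, 0.5)
})

test_that("exclusion rules fire on the stated boundaries", {
  rules <- aggregation_rules()
  mapping <- pixel_mapping(-64.9, 1) # colour 1 -> exactly -64.9 dB
  # 0-8 m deep, 0.2 m rows, 1 m columns; seabed edge on row 30 (5.9 m).
  # the anomaly sits one empty row above the seabed so the tracer does not
  # absorb it into the bottom line
  px <- matrix(0L, 40, 12)
  px[30, ] <- 7L
  px[6:10, 2:5] <- 1L    # top at 1.1 m -> nearfield
  px[28, 7:11] <- 1L     # altitude 0.4 m -> bathymetric anomaly
  px[17:24, 7:10] <- 1L  # valid: 4 x 1.6 m, Sv -64.9
  fr <- echogram_frame(px, 0, 8, scale8, metres_per_col = 1)
  sb <- trace_seabed(detect_upper_edges(fr))
  expect_equal(sb$row_per_col, rep(30L, 12))
  fr <- mask_below_seabed(fr, sb)
  cands <- find_candidates(make_mask(fr), fr, seabed = sb)
  out <- filter_candidates(cands, rules, fr, mapping)
  expect_length(out$retained, 1)
  expect_setequal(out$rejected$rule, c("nearfield", "altitude"))
  expect_equal(out$retained[[1]]$top_depth_m, 3.3)

  # 0.9 x 3 m -> min size; same shape at 1 x 3 m passes
  fr2 <- echogram_frame(matrix(0L, 40, 12), 0, 20, scale8, metres_per_col = 0.9)
  c2 <- toy_candidate(15:20, rep(5L, 6), fr2)
  c2$altitude_m <- 5
  out2 <- filter_candidates(list(c2), rules, fr2, mapping)
  expect_equal(out2$rejected$rule, "min_size")

  # mean Sv below -65 is dropped, -64.9 is kept
  weak <- pixel_mapping(-66, 0.5)
  fr3 <- toy_frame(matrix(1L, 40, 12))
  c3 <- toy_candidate(rep(15:18, 4), rep(2:5, each = 4), fr3)
  c3$altitude_m <- 5
  expect_equal(filter_candidates(list(c3), rules, fr3, weak)$rejected$rule,
               "sv_threshold")
})

test_that("linking-ellipse merging follows the gap geometry transitively", {
  rules <- aggregation_rules()
  fr <- echogram_frame(matrix(0L, 50, 60), 0, 50, scale8, metres_per_col = 1)
  big <- function(c0) toy_candidate(rep(10:21, 11), rep(c0:(c0 + 10), each = 12), fr)
  # 12 x 11 px = 11 x 12 m blocks (exceed the 10 x 5 minimum school size)
  a <- big(2)
  b <- big(17) # gap = 17 - 12 - 1 = 4 m <= 5 m semi-axis -> merge
  merged <- link_schools(list(a, b), rules, fr)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$n, a$n + b$n)

  c2 <- big(19) # gap = 6 m -> separate
  expect_length(link_schools(list(a, c2), rules, fr), 2)

  # chain a-b-c each pairwise linkable collapses to one school
  c3 <- big(32) # 4 m from b
  expect_length(link_schools(list(a, b, c3), rules, fr), 1)

  # merging is independent of candidate order
  m1 <- link_schools(list(a, b, c3), rules, fr)[[1]]
  m2 <- link_schools(list(c3, a, b), rules, fr)[[1]]
  expect_setequal(paste(m1$rows, m1$cols), paste(m2$rows, m2$cols))

  # aggregates below the minimum school size are discarded
  tiny <- toy_candidate(rep(10:12, 3), rep(2:4, each = 3), fr) # 3 x 3 m
  expect_length(link_schools(list(tiny), rules, fr), 0)
})

test_that("vertical gaps use the short ellipse axis", {
  rules <- aggregation_rules()
  fr <- echogram_frame(matrix(0L, 60, 40), 0, 30, scale8, metres_per_col = 1)
  # 0.5 m rows: blocks 12 m wide, 6 m high
  blk <- function(r0) toy_candidate(rep(r0:(r0 + 11), 12),
                                    rep(5:16, each = 12), fr)
  a <- blk(10)
  b <- blk(23) # vertical gap = (23 - 21 - 1) * 0.5 = 0.5 m <= 1 m semi-axis
  expect_length(link_schools(list(a, b), rules, fr), 1)
  c2 <- blk(27) # gap 2.5 m -> separate
  expect_length(link_schools(list(a, c2), rules, fr), 2)
})

test_that("extract_parameters reproduces hand-computed geometry", {
  px <- matrix(0L, 30, 30)
  px[11:15, 6:15] <- 6L # 10 x 5 m solid rectangle at 1 m/px
  px[30, ] <- 7L        # seabed bottom row
  fr <- echogram_frame(px, 0, 30, scale8, metres_per_col = 1)
  sb <- trace_seabed(detect_upper_edges(fr))
  fr <- mask_below_seabed(fr, sb)
  sch <- find_candidates(make_mask(fr), fr)[[1]]
  row <- extract_parameters(sch, fr, sb)
  expect_equal(row$Area, 50)
  expect_equal(row$AreaLV, 50)
  expect_equal(row$SchoolWidth, 10)
  expect_equal(row$SchoolHeight, 5)
  expect_equal(row$MaxCalDiam, sqrt(125))
  expect_equal(row$MeanDepth, 12.5)
  expect_equal(row$TopDepth, 10.5)
  expect_equal(row$BotDepth, 29.5)
  expect_equal(row$MeanAltitude, row$BotDepth - row$MeanDepth)
  expect_equal(row$Px6, 50)
  expect_false(row$Truncated)

  # a vacuole is excluded from AreaLV but filled into Area
  px2 <- px
  px2[13, 10] <- 0L
  fr2 <- echogram_frame(px2, 0, 30, scale8, metres_per_col = 1)
  sch2 <- find_candidates(make_mask(mask_below_seabed(fr2, sb)), fr2)[[1]]
  row2 <- extract_parameters(sch2, fr2, sb)
  expect_equal(row2$Area, 50)
  expect_equal(row2$AreaLV, 49)
})

test_that("recovered schools satisfy the rules and match planted geometry", {
  res <- small_survey(seed = 12)
  out <- process_survey(res$sv$frames, res$spec$mapping)
  tr <- res$sv$truth[order(res$sv$truth$centroid_col), ]
  sc <- out$schools[order(out$schools$Long_dd), ]
  expect_equal(nrow(sc), nrow(tr))
  rules <- aggregation_rules()
  expect_true(all(sc$TopDepth >= rules$min_depth_m))
  expect_true(all(sc$BotAltitude >= rules$min_altitude_m))
  expect_true(all(sc$SchoolWidth >= rules$min_school_l_m))
  expect_true(all(sc$SchoolHeight >= rules$min_school_h_m))
  expect_true(all(abs(sc$MeanDepth - tr$mean_depth_m) <=
                    res$spec$metres_per_row))
  validate_school_table(sc)
})
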