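test_that("detect_upper_edges marks top rows of objects only", {
  blank <- toy_frame(matrix(0L, 8, 8))
  expect_true(all(detect_upper_edges(blank) == 0L))

  px <- matrix(0L, 10, 10)
  px[4:7, 3:8] <- 5L # filled rectangle
  fr <- toy_frame(px)
  e <- detect_upper_edges(fr)
  expect_true(all(e[4, 3:8] == 1L))
  expect_equal(sum(e), 6)
})

test_that("edge detection recovers the seabed top row on synthetic profiles", {
  spec <- survey_spec(seed = 31, n_frames = 4L, n_schools = 0L,
                      speckle_density = 0, noise_col_rate = 0)
  sv <- generate_survey(spec)
  e <- detect_upper_edges(sv$global)
  hit <- e[cbind(sv$seabed_row, seq_along(sv$seabed_row))] == 1L
  expect_gte(mean(hit), 0.99)
})

test_that("trace_seabed locks onto a perfect edge row", {
  edges <- matrix(0L, 10, 12)
  edges[7, ] <- 1L
  p <- trace_seabed(edges, lambda = 0.5, P = 2)
  expect_equal(p$row_per_col, rep(7L, 12))
  expect_equal(p$score, 12)
  expect_false(p$no_evidence)
})

test_that("trace_seabed matches the exhaustive oracle across random frames", {
  set.seed(42)
  for (i in 1:40) {
    N <- sample(3:8, 1)
    R <- sample(3:10, 1)
    P <- if (N <= 5) 2L else 1L
    lambda <- sample(c(0, 0.5, 1), 1)
    edges <- random_edge_map(R, N)
    got <- trace_seabed(edges, lambda, P)
    want <- brute_seabed(edges, lambda, P)
    expect_equal(got$row_per_col, want$path,
                 info = sprintf("case %d (R=%d N=%d P=%d l=%.1f)", i, R, N, P, lambda))
    expect_equal(got$score, want$score)
  }
})

test_that("a gap in the seabed edge is bridged optimally", {
  edges <- matrix(0L, 8, 6)
  edges[5, c(1, 2, 5, 6)] <- 1L # 2-column gap
  got <- trace_seabed(edges, lambda = 0.5, P = 2)
  want <- brute_seabed(edges, 0.5, 2)
  expect_equal(got$row_per_col, want$path)
})

test_that("full-occupancy rows beat partial ones for any lambda", {
  set.seed(7)
  edges <- matrix(0L, 9, 10)
  edges[3, sample(10, 8)] <- 1L # 80% occupancy
  edges[6, ] <- 1L              # 100% occupancy
  for (lambda in c(0, 0.3, 1, 5)) {
    expect_equal(trace_seabed(edges, lambda, 2)$row_per_col, rep(6L, 10))
  }
})

test_that("empty edge maps give the deepest path with a no-evidence flag", {
  p <- trace_seabed(matrix(0L, 6, 5), lambda = 0.5, P = 2)
  expect_equal(p$row_per_col, rep(6L, 5))
  expect_true(p$no_evidence)
})

test_that("score is non-increasing in lambda; lambda 0 maximises occupancy", {
  set.seed(99)
  for (i in 1:10) {
    edges <- random_edge_map(sample(3:8, 1), sample(3:6, 1))
    lams <- c(0, 0.25, 0.5, 1, 2)
    scores <- vapply(lams, function(l) trace_seabed(edges, l, 2)$score, numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
    occ0 <- sum(edges[cbind(trace_seabed(edges, 0, 2)$row_per_col,
                            seq_len(ncol(edges)))])
    expect_equal(occ0, brute_seabed(edges, 0, 2)$score)
  }
})

test_that("mask_below_seabed clears at and below the path", {
  px <- matrix(3L, 6, 4)
  fr <- toy_frame(px)
  path <- trace_seabed(rbind(matrix(0L, 5, 4), 1L), 0.5, 2)
  expect_equal(path$row_per_col, rep(6L, 4))
  m <- mask_below_seabed(fr, path)
  expect_true(all(m$pixels[1:5, ] == 3L))
  expect_true(all(m$pixels[6, ] == 0L))
  # margin equal to the full depth clears everything
  m2 <- mask_below_seabed(fr, path, margin_m = 6)
  expect_true(all(m2$pixels == 0L))
})

test_that("schools above the seabed survive masking exactly", {
  spec <- survey_spec(seed = 32, n_frames = 4L, n_schools = 3L,
                      speckle_density = 0, noise_col_rate = 0)
  sv <- generate_survey(spec)
  sb <- trace_seabed(detect_upper_edges(sv$global))
  m <- mask_below_seabed(sv$global, sb)
  for (k in seq_len(nrow(sv$truth))) {
    tr <- sv$truth[k, ]
    block <- m$pixels[tr$row0:tr$row1, tr$col0:tr$col1]
    expect_identical(block, sv$global$pixels[tr$row0:tr$row1, tr$col0:tr$col1])
  }
})

test_that("despeckle removes isolated speckles and keeps block interiors", {
  px <- matrix(0L, 9, 9)
  px[5, 5] <- 7L
  fr <- toy_frame(px)
  expect_true(all(despeckle(fr, 3)$pixels == 0L))

  blk <- matrix(0L, 9, 9)
  blk[3:7, 3:7] <- 4L
  out <- despeckle(toy_frame(blk), 3)
  expect_true(all(out$pixels[4:6, 4:6] == 4L))
  expect_error(despeckle(fr, 4), "odd")
})

test_that("despeckle clears salt noise but preserves school pixels", {
  spec <- survey_spec(seed = 33, speckle_density = 0.01, noise_col_rate = 0)
  sv <- generate_survey(spec)
  sb <- trace_seabed(detect_upper_edges(sv$global))
  m <- mask_below_seabed(sv$global, sb)
  d <- despeckle(m, 3)
  stencil <- matrix(FALSE, nrow(m$pixels), ncol(m$pixels))
  for (k in seq_len(nrow(sv$truth)))
    stencil[cbind(
      rep(sv$truth$row0[k]:sv$truth$row1[k],
          times = sv$truth$col1[k] - sv$truth$col0[k] + 1),
      rep(sv$truth$col0[k]:sv$truth$col1[k],
          each = sv$truth$row1[k] - sv$truth$row0[k] + 1))] <- TRUE
  salt <- sv$speckle[!stencil[sv$speckle], , drop = FALSE]
  cleared <- d$pixels[salt] == 0L
  expect_gte(mean(cleared), 0.99)
  # school pixels keep their mask membership (the filter may smooth the
  # within-school colour texture, but must not erode the school itself)
  clean_stencil <- sv$global_clean$pixels > 0 & stencil
  eroded <- d$pixels[clean_stencil] == 0L
  expect_lte(mean(eroded), 0.02)
})

test_that("remove_noise_columns flags saturated pings and nothing else", {
  same <- toy_frame(matrix(2L, 6, 10))
  r <- remove_noise_columns(same)
  expect_length(r$removed, 0)

  # a lone saturated ping: its z grows like sqrt(n_cols), so use a frame
  # wide enough for the spike to clear the default threshold
  px <- matrix(0L, 10, 40)
  px[, 5] <- 7L
  r2 <- remove_noise_columns(toy_frame(px))
  expect_equal(r2$removed, 5L)
  expect_true(all(r2$frame$pixels[, 5] == 0L))
})

test_that("noise-column recall and false-positive rate meet spec on synthetic pings", {
  hits <- 0; injected <- 0; fp <- 0; clean_cols <- 0
  for (seed in 41:44) {
    spec <- survey_spec(seed = seed, noise_col_rate = 0.01, speckle_density = 0.01)
    sv <- generate_survey(spec)
    sb <- trace_seabed(detect_upper_edges(sv$global))
    m <- mask_below_seabed(sv$global, sb) # columns tested pre-despeckle
    r <- remove_noise_columns(m)
    injected <- injected + length(sv$noise_cols)
    hits <- hits + sum(sv$noise_cols %in% r$removed)
    fp <- fp + sum(!(r$removed %in% sv$noise_cols))
    clean_cols <- clean_cols + ncol(m$pixels) - length(sv$noise_cols)
  }
  expect_gte(hits / injected, 0.95)
  expect_lte(fp / clean_cols, 0.02)
})

test_that("despeckle and seabed masking commute when the margin covers the kernel", {
  spec <- survey_spec(seed = 34, n_frames = 4L, n_schools = 3L,
                      speckle_density = 0, noise_col_rate = 0)
  sv <- generate_survey(spec)
  sb <- trace_seabed(detect_upper_edges(sv$global))
  margin <- 2 * sv$global$metres_per_row # >= kernel radius (1 row)
  a <- despeckle(mask_below_seabed(sv$global, sb, margin), 3)
  b <- mask_below_seabed(despeckle(sv$global, 3), sb, margin)
  expect_identical(a$pixels, b$pixels)
})
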