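#' Matched-pair tables
#'
#' Cross-calibration operations consume a *matched-pairs* data.frame, one
#' row per school insonified by both instruments, with columns: `MatchID`,
#' `Time` (sortable; used only for tie-breaking), `MeanDepthSES`,
#' `MeanDepthRFF` (m), `AreaSES`, `AreaRFF` (m^2), `sv_ses` (linear mean
#' volume backscattering coefficient of the scientific echo-sounder, m^-1),
#' and the fish-finder pixel histogram columns `Px1 ... PxK` (counts per
#' colour index). [generate_matched_pairs()] produces this layout.
#'
#' @name matched_pairs
NULL

pair_px_matrix <- function(pairs) {
  pxc <- grep("^Px[0-9]+$", names(pairs), value = TRUE)
  if (!length(pxc)) stop("matched pairs carry no Px* histogram columns", call. = FALSE)
  pxc <- pxc[order(as.integer(sub("^Px", "", pxc)))]
  as.matrix(pairs[pxc])
}

#' Mean backscatter of a school from its pixel histogram
#'
#' Averages in the linear domain: `sv = sum(n_c * 10^(Sv(c)/10)) / sum(n_c)`
#' over the retained colours (index 0/background is excluded by
#' construction), then `Sv = 10 log10(sv)`.
#'
#' @param pixel_value_counts Numeric vector of counts for colours `1..K`.
#' @param mapping A [pixel_mapping()].
#' @return List `sv_linear` (m^-1) and `Sv_db` (dB re 1 m^-1).
#' @export
school_mean_sv <- function(pixel_value_counts, mapping) {
  n <- as.numeric(pixel_value_counts)
  if (!length(n) || sum(n) <= 0)
    stop("empty pixel histogram: mean Sv undefined", call. = FALSE)
  sv_c <- db_to_linear(sv_of_colour(seq_along(n), mapping))
  sv <- sum(n * sv_c) / sum(n)
  list(sv_linear = sv, Sv_db = linear_to_db(sv))
}

#' Skewness of a school's pixel-value distribution
#'
#' Sample skewness `g1 = m3 / m2^(3/2)` of the colour indices, computed from
#' the histogram.
#'
#' @param pixel_value_counts Counts per colour index `1..K`.
#' @return `g1`, or `NA` (with a warning) when the variance is zero.
#' @export
pixel_skewness <- function(pixel_value_counts) {
  n <- as.numeric(pixel_value_counts)
  N <- sum(n)
  if (N < 3) stop("need at least 3 pixels for skewness", call. = FALSE)
  v <- seq_along(n)
  mu <- sum(n * v) / N
  m2 <- sum(n * (v - mu)^2) / N
  if (m2 == 0) {
    warning("zero pixel variance: skewness undefined")
    return(NA_real_)
  }
  m3 <- sum(n * (v - mu)^3) / N
  m3 / m2^1.5
}

#' Select the three calibration scenario schools
#'
#' Computes pixel skewness for every matched school and returns the schools
#' with the minimum, closest-to-zero and maximum skewness (scenarios 1-3).
#' Ties are resolved by earlier survey time; the three selected schools must
#' be distinct.
#'
#' Fully saturated schools (every pixel the same colour) have undefined
#' skewness; they are excluded from the ranking with a warning.
#'
#' @param pairs A [matched_pairs] data.frame (>= 3 rows).
#' @return List with `index` (integer vector of 3 row indices) and
#'   `skewness` (their g1 values).
#' @export
select_scenarios <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  px <- pair_px_matrix(pairs)
  g <- suppressWarnings(apply(px, 1, pixel_skewness))
  if (anyNA(g)) {
    warning(sum(is.na(g)),
            " school(s) with undefined (zero-variance) skewness excluded",
            call. = FALSE)
    if (sum(!is.na(g)) < 3L)
      stop("fewer than 3 schools with defined skewness", call. = FALSE)
  }
  ok <- which(!is.na(g))
  ord_time <- if ("Time" %in% names(pairs)) order(pairs$Time) else seq_len(nrow(pairs))
  pick <- function(key) {
    cand <- ok[key[ok] == min(key[ok])]
    cand[order(match(cand, ord_time))][1]
  }
  idx <- c(min = pick(g), zero = pick(abs(g)), max = pick(-g))
  if (length(unique(idx)) < 3L)
    stop("scenario schools are not distinct", call. = FALSE)
  list(index = idx, skewness = g[idx])
}

#' Grid search of the colour-index mapping against a matched SES value
#'
#' For every (starting value, colour step) combination, the fish-finder
#' school's mean Sv is computed from its pixel histogram and compared with
#' the echo-sounder's Sv for the same school. Low `|dSv|` marks mapping
#' combinations that reconcile the two instruments. The default grid follows
#' the calibration protocol: starting values -70 to -60 dB in 0.5 dB
#' increments, colour steps 0.1 to 2 dB in 0.1 dB increments.
#'
#' @param pixel_value_counts RFF pixel histogram of the scenario school.
#' @param sv_ses_db The SES mean Sv of the same school (dB).
#' @param starts,steps Grid values (dB).
#' @param baseline_start_db Starting value at which the headline optimal
#'   step is reported (default -65 dB, the SES's own minimum).
#' @return List: `surface` (data.frame `start_db, step_db, Sv_rff_db,
#'   dSv_db`), `best` (grid row minimising `|dSv|` globally) and
#'   `best_at_baseline` (minimiser restricted to the baseline start).
#' @export
grid_search_mapping <- function(pixel_value_counts, sv_ses_db,
                                starts = seq(-70, -60, by = 0.5),
                                steps = seq(0.1, 2, by = 0.1),
                                baseline_start_db = -65) {
  grid <- expand.grid(start_db = starts, step_db = steps)
  n <- as.numeric(pixel_value_counts)
  if (sum(n) <= 0) stop("empty pixel histogram", call. = FALSE)
  v <- seq_along(n)
  # Sv_rff(start, step) = start + 10 log10( sum w_c 10^(step (c-1)/10) )
  w <- n / sum(n)
  sv_rff <- vapply(seq_len(nrow(grid)), function(i) {
    grid$start_db[i] +
      10 * log10(sum(w * 10^(grid$step_db[i] * (v - 1) / 10)))
  }, numeric(1))
  surface <- data.frame(grid, Sv_rff_db = sv_rff, dSv_db = sv_ses_db - sv_rff)
  best <- surface[which.min(abs(surface$dSv_db)), , drop = FALSE]
  at_base <- surface[surface$start_db == baseline_start_db, , drop = FALSE]
  best_base <- at_base[which.min(abs(at_base$dSv_db)), , drop = FALSE]
  list(surface = surface, best = best, best_at_baseline = best_base)
}

#' Saturation-correction regression
#'
#' The fish-finder's narrow dynamic range saturates dense schools, so its
#' linear-domain sv values compress near the top. The correction model is an
#' ordinary least-squares fit of `log10(sv_SES)` on the *linear* `sv_RFF`
#' over the matched schools; its coefficients de-saturate fish-finder
#' backscatter via `sv_corr = 10^(beta0 + beta1 * sv_RFF)`.
#'
#' @param pairs A [matched_pairs] data.frame.
#' @param mapping The [pixel_mapping()] used to evaluate `sv_RFF` from the
#'   pixel histograms.
#' @return A `correction_model`: `beta0`, `beta1`, `r2`, `n`, `mapping`.
#' @export
fit_correction <- function(pairs, mapping) {
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  px <- pair_px_matrix(pairs)
  sv_rff <- apply(px, 1, function(cnt) school_mean_sv(cnt, mapping)$sv_linear)
  if (stats::var(sv_rff) == 0) stop("singular design: sv_RFF constant", call. = FALSE)
  fit <- stats::lm(log10(pairs$sv_ses) ~ sv_rff)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 r2 = summary(fit)$r.squared,
                 n = nrow(pairs), mapping = mapping),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf(
    "<correction_model> log10(sv_SES) = %.4g + %.4g * sv_RFF  (R2 = %.3f, n = %d)\n",
    x$beta0, x$beta1, x$r2, x$n))
  invisible(x)
}

#' Apply the saturation correction
#'
#' @param model A [fit_correction()] result.
#' @param sv_rff Linear sv values (m^-1) to correct; vectorised.
#' @return List `sv_linear` (corrected sv, always > 0) and `Sv_db`.
#' @export
apply_correction <- function(model, sv_rff) {
  stopifnot(inherits(model, "correction_model"))
  sv <- 10^(model$beta0 + model$beta1 * sv_rff)
  list(sv_linear = sv, Sv_db = linear_to_db(sv))
}

#' Bin Sv values into 4 dB classes
#'
#' Half-open bins `[edge, edge + width)` anchored at -68 dB.
#'
#' @param values Sv values (dB).
#' @param width Bin width (dB), default 4.
#' @param anchor A bin edge (default -68 dB).
#' @return data.frame `bin_lo, bin_hi, count` covering the data range.
#' @export
bin_sv <- function(values, width = 4, anchor = -68) {
  stopifnot(all(is.finite(values)))
  k <- floor((values - anchor) / width)
  ks <- seq(min(k), max(k))
  data.frame(bin_lo = anchor + ks * width,
             bin_hi = anchor + (ks + 1) * width,
             count = as.integer(table(factor(k, levels = ks))))
}

#' Wilcoxon signed-rank test for paired Sv samples
#'
#' Zero differences are excluded, ties take mid-ranks. The exact signed-rank
#' distribution is used when there are no ties and n <= 50; otherwise the
#' normal approximation with tie and continuity correction is applied. When
#' every difference is zero, p = 1 is returned with a warning.
#'
#' @param x,y Equal-length paired samples.
#' @return List `statistic` (V, sum of positive ranks), `p.value`, `n_used`,
#'   `method`.
#' @export
paired_rank_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero")
    return(list(statistic = 0, p.value = 1, n_used = 0L, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= 50L) {
    p <- if (V > n * (n + 1) / 4) {
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(V, n)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie/continuity corrected)"
  }
  list(statistic = V, p.value = p, n_used = n, method = method)
}

#' Depth dependence of school backscatter (TVG check)
#'
#' Regresses `log10(sv)` of the matched schools on mean school depth for one
#' system. A strong negative slope in the fish-finder but not the
#' echo-sounder would indicate uncompensated time-varied gain.
#'
#' @param pairs A [matched_pairs] data.frame.
#' @param system `"ses"` or `"rff"`.
#' @param mapping A [pixel_mapping()], required for the RFF system.
#' @param correction Optional [fit_correction()] model applied to RFF sv.
#' @return List `slope`, `intercept`, `r2`, `slope_se`.
#' @export
depth_dependence <- function(pairs, system = c("ses", "rff"), mapping = NULL,
                             correction = NULL) {
  system <- match.arg(system)
  if (nrow(pairs) < 3L) stop("need at least 3 matched pairs", call. = FALSE)
  if (system == "ses") {
    sv <- pairs$sv_ses
    depth <- pairs$MeanDepthSES
  } else {
    if (is.null(mapping)) stop("`mapping` required for the RFF system", call. = FALSE)
    px <- pair_px_matrix(pairs)
    sv <- apply(px, 1, function(cnt) school_mean_sv(cnt, mapping)$sv_linear)
    if (!is.null(correction)) sv <- apply_correction(correction, sv)$sv_linear
    depth <- pairs$MeanDepthRFF
  }
  fit <- stats::lm(log10(sv) ~ depth)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = s$r.squared,
       slope_se = s$coefficients[2, 2])
}
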