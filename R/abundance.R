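#' Cumulative along-track distance of a survey track
#'
#' @param track data.frame with `lat_dd`, `lon_dd` (and optionally `time_s`)
#'   in survey order.
#' @return Numeric vector of cumulative great-circle distance (m), starting
#'   at 0.
#' @export
along_track_distance <- function(track) {
  n <- nrow(track)
  if (n < 2L) return(numeric(n))
  seg <- haversine_m(track$lat_dd[-n], track$lon_dd[-n],
                     track$lat_dd[-1], track$lon_dd[-1])
  c(0, cumsum(seg))
}

# project positions onto the track polyline (local equirectangular plane);
# returns along-track distance (m) and off-track distance (m)
project_on_track <- function(lat, lon, track) {
  cum <- along_track_distance(track)
  R <- 6371008.8
  lat0 <- mean(track$lat_dd)
  to_xy <- function(la, lo) {
    cbind(x = (lo - track$lon_dd[1]) * cos(lat0 * pi / 180) * pi / 180 * R,
          y = (la - track$lat_dd[1]) * pi / 180 * R)
  }
  P <- to_xy(lat, lon)
  Tk <- to_xy(track$lat_dd, track$lon_dd)
  n <- nrow(Tk)
  along <- off <- numeric(length(lat))
  for (i in seq_along(lat)) {
    best <- Inf
    besta <- 0
    for (s in seq_len(max(1L, n - 1L))) {
      a <- Tk[s, ]
      b <- Tk[min(s + 1L, n), ]
      ab <- b - a
      len2 <- sum(ab^2)
      t <- if (len2 == 0) 0 else max(0, min(1, sum((P[i, ] - a) * ab) / len2))
      q <- a + t * ab
      d <- sqrt(sum((P[i, ] - q)^2))
      if (d < best) {
        best <- d
        besta <- cum[s] + t * (cum[min(s + 1L, n)] - cum[s])
      }
    }
    along[i] <- besta
    off[i] <- best
  }
  list(along_m = along, off_m = off)
}

#' Partition a survey track into elementary distance sampling units
#'
#' EDSU `k` covers along-track metres `[L*(k-1), L*k)` (half-open: a school
#' exactly on a boundary joins the later unit). The final partial unit is
#' kept if at least `min_partial_m` long, otherwise merged into the previous
#' unit. Schools are assigned by the along-track distance of their centroid
#' position; schools more than `max_offtrack_m` off the track raise a
#' warning and snap to the nearest along-track point.
#'
#' @param schools School data.frame with `Lat_dd`/`Long_dd` (may be empty).
#' @param track Track data.frame (`lat_dd`, `lon_dd`, survey order).
#' @param edsu_m Unit length (m), default 500.
#' @param min_partial_m Minimum length of the final partial unit.
#' @param max_offtrack_m Off-track warning distance (default 1000 m).
#' @return List: `edsus` (data.frame `index, start_m, end_m`),
#'   `school_edsu` (EDSU index per school row), `along_m`, `off_m`.
#' @export
assign_edsus <- function(schools, track, edsu_m = 500, min_partial_m = 250,
                         max_offtrack_m = 1000) {
  total <- max(along_track_distance(track))
  if (total <= 0) stop("degenerate track", call. = FALSE)
  n_full <- floor(total / edsu_m)
  rem <- total - n_full * edsu_m
  starts <- edsu_m * seq(0, max(0, n_full - 1))
  ends <- starts + edsu_m
  if (rem >= min_partial_m || n_full == 0) {
    starts <- c(starts, edsu_m * n_full)
    ends <- c(ends, total)
  } else if (rem > 0) {
    ends[length(ends)] <- total
  }
  edsus <- data.frame(index = seq_along(starts), start_m = starts, end_m = ends)

  if (nrow(schools)) {
    proj <- project_on_track(schools$Lat_dd, schools$Long_dd, track)
    if (any(proj$off_m > max_offtrack_m))
      warning(sum(proj$off_m > max_offtrack_m),
              " school(s) > ", max_offtrack_m,
              " m off-track; snapped to nearest along-track point")
    k <- findInterval(proj$along_m, starts)
    k[k < 1L] <- 1L
    k[k > nrow(edsus)] <- nrow(edsus)
    list(edsus = edsus, school_edsu = k,
         along_m = proj$along_m, off_m = proj$off_m)
  } else {
    list(edsus = edsus, school_edsu = integer(0),
         along_m = numeric(0), off_m = numeric(0))
  }
}

#' Echo-integrate schools to nautical area scattering coefficients per EDSU
#'
#' Per unit, `s_a = sum_i(sv_i * H_i * W_i) / unit_length` — the range
#' interval is the height of all schools weighted by their lengths — and
#' `s_A = 4 pi 1852^2 * s_a` (m^2 nmi^-2). Units without schools score 0.
#'
#' @param assignment Result of [assign_edsus()].
#' @param schools The same school data.frame (needs `SchoolHeight`,
#'   `SchoolWidth`).
#' @param sv_linear Linear mean sv (m^-1) per school (e.g. corrected
#'   fish-finder values from [apply_correction()]).
#' @return data.frame `index, start_m, end_m, n_schools, presence, sa`
#'   (`sa` is s_A in m^2 nmi^-2).
#' @export
edsu_sa <- function(assignment, schools, sv_linear) {
  ed <- assignment$edsus
  stopifnot(nrow(schools) == length(assignment$school_edsu),
            nrow(schools) == length(sv_linear))
  contrib <- sv_linear * schools$SchoolHeight * schools$SchoolWidth
  tot <- rep(0, nrow(ed))
  cnt <- rep(0L, nrow(ed))
  if (nrow(schools)) {
    agg <- tapply(contrib, assignment$school_edsu, sum)
    tot[as.integer(names(agg))] <- agg
    tcnt <- table(assignment$school_edsu)
    cnt[as.integer(names(tcnt))] <- as.integer(tcnt)
  }
  sa_coef <- tot / (ed$end_m - ed$start_m)
  data.frame(ed, n_schools = cnt, presence = cnt > 0L,
             sa = 4 * pi * 1852^2 * sa_coef)
}

#' Detection concordance between the two systems
#'
#' Builds the 2x2 presence/absence contingency table over EDSUs and tests
#' the association with a binary-predictor logistic fit, equivalent to a
#' Wald test on the log odds ratio. Zero cells get the Haldane 0.5
#' correction.
#'
#' @param presence_rff,presence_ses Logical vectors, one entry per EDSU.
#' @return List: `table` (2x2 matrix, rows = RFF fish/no fish, cols = SES),
#'   `odds_ratio`, `log_or`, `se`, `z`, `p.value`, `haldane` (whether the
#'   correction was applied).
#' @export
detection_table <- function(presence_rff, presence_ses) {
  stopifnot(length(presence_rff) == length(presence_ses),
            length(presence_rff) >= 1L)
  tab <- matrix(c(sum(presence_rff & presence_ses),
                  sum(presence_rff & !presence_ses),
                  sum(!presence_rff & presence_ses),
                  sum(!presence_rff & !presence_ses)),
                2, 2, byrow = TRUE,
                dimnames = list(RFF = c("fish", "no fish"),
                                SES = c("fish", "no fish")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  haldane <- any(tab == 0)
  w <- tab + if (haldane) 0.5 else 0
  log_or <- log(w[1, 1] * w[2, 2] / (w[1, 2] * w[2, 1]))
  se <- sqrt(sum(1 / w))
  z <- log_or / se
  list(table = tab, odds_ratio = exp(log_or), log_or = log_or, se = se,
       z = z, p.value = if (degenerate) NA_real_ else 2 * stats::pnorm(-abs(z)),
       haldane = haldane, degenerate = degenerate)
}

#' Regression between matched school descriptors
#'
#' OLS of the echo-sounder descriptor on the fish-finder descriptor across
#' the matched schools: mean school depth, or school area after log10
#' transform.
#'
#' @param pairs A [matched_pairs] data.frame.
#' @param descriptor `"depth"` or `"area"`.
#' @return List `slope`, `intercept`, `r2`, `n`.
#' @export
matched_descriptor_fit <- function(pairs, descriptor = c("depth", "area")) {
  descriptor <- match.arg(descriptor)
  if (descriptor == "depth") {
    x <- pairs$MeanDepthRFF
    y <- pairs$MeanDepthSES
  } else {
    x <- log10(pairs$AreaRFF)
    y <- log10(pairs$AreaSES)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = nrow(pairs))
}

#' Between-system agreement across rolling spatial scales
#'
#' For each scale, per-system s_A series are summed over a rolling window
#' (stride one EDSU), divided by the scale length, transformed
#' `log(x + 0.1)` (the offset accommodates empty units), and the R^2 of the
#' between-system OLS regression is recorded.
#'
#' @param sa_rff,sa_ses s_A per EDSU (aligned vectors).
#' @param edsu_m EDSU length (m).
#' @param scales_km Scales to evaluate; default 18 values 0.5, 1.5, ...,
#'   17.5 km.
#' @return data.frame `scale_km, window, n_windows, r2`; scales longer than
#'   the track are skipped with a warning.
#' @export
rolling_scale_concordance <- function(sa_rff, sa_ses, edsu_m = 500,
                                      scales_km = seq(0.5, 17.5, by = 1)) {
  stopifnot(length(sa_rff) == length(sa_ses))
  n <- length(sa_rff)
  roll <- function(x, w) {
    cs <- cumsum(c(0, x))
    cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  }
  out <- lapply(scales_km, function(s) {
    w <- max(1L, as.integer(round(s * 1000 / edsu_m)))
    if (w > n || (n - w + 1L) < 3L) {
      warning(sprintf("scale %.1f km exceeds the usable track; skipped", s))
      return(NULL)
    }
    x <- log(roll(sa_rff, w) / s + 0.1)
    y <- log(roll(sa_ses, w) / s + 0.1)
    r2 <- if (stats::var(x) == 0 || stats::var(y) == 0) NA_real_ else
      stats::cor(x, y)^2
    data.frame(scale_km = s, window = w, n_windows = n - w + 1L, r2 = r2)
  })
  do.call(rbind, out)
}
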