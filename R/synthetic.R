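#' Specification of a synthetic paired survey
#'
#' Describes a reproducible synthetic fish-finder survey: a vessel track, a
#' smooth seabed profile, planted schools of known position/size/backscatter,
#' interference (speckle and saturated ping columns), and the fish-finder's
#' colour quantisation with its saturation ceiling. Defaults emulate the
#' inter-calibration survey conditions: 7 kn vessel speed, a 0-50 m display
#' window, 2 pings per second (1.8 m per ping column), a 16-colour display
#' (the top colour then sits near -45 dB under the default mapping, matching
#' the saturation behaviour of real units), and a -65 dB / 1.3 dB colour
#' mapping.
#'
#' School stencils are rectangles with their four corner pixels clipped —
#' the largest simple shape invariant under the 3 x 3 median despeckle — so
#' planted pixel counts remain comparable after processing. Interference
#' columns are only injected at pings that do not intersect a school, so
#' planted ground truth stays well-defined.
#'
#' @param seed RNG seed (integer).
#' @param n_schools Number of planted schools (placed with >= 60 m spacing).
#' @param n_frames,frame_rows,frame_cols,overlap_cols Frame geometry;
#'   consecutive frames repeat `overlap_cols` pings.
#' @param depth_min_m,depth_max_m Displayed depth range.
#' @param ping_interval_s Ping period (s).
#' @param speed_kn Vessel speed (knots).
#' @param start_lat,start_lon,heading_deg Track start and constant heading.
#' @param seabed_range_m Depth band of the seabed random walk.
#' @param school_depth_m,school_l_m,school_h_m,school_sv_db Ranges from
#'   which school mean depth, length, height and mean Sv are drawn.
#' @param school_spread_db Within-school pixel Sv standard deviation (dB);
#'   pixel Sv is normal in dB, i.e. lognormal in the linear domain.
#' @param speckle_density Fraction of water-column pixels hit by salt
#'   speckle.
#' @param noise_col_rate Fraction of ping columns replaced by saturated
#'   interference columns.
#' @param mapping The fish-finder's true [pixel_mapping()].
#' @param n_colours Display colours (see [colour_scale()]).
#' @param schools Optional explicit school table (`along_m, depth_m, l_m,
#'   h_m, sv_db`) overriding the random draw.
#' @return A `survey_spec` object.
#' @export
survey_spec <- function(seed = 1L,
                        n_schools = 10L,
                        n_frames = 8L, frame_rows = 100L, frame_cols = 160L,
                        overlap_cols = 10L,
                        depth_min_m = 0, depth_max_m = 50,
                        ping_interval_s = 0.5, speed_kn = 7,
                        start_lat = -33.85, start_lon = 25.7,
                        heading_deg = 90,
                        seabed_range_m = c(32, 46),
                        school_depth_m = c(10, 24),
                        school_l_m = c(15, 40),
                        school_h_m = c(6, 12),
                        school_sv_db = c(-52, -42),
                        school_spread_db = 3,
                        speckle_density = 0.01,
                        noise_col_rate = 0.005,
                        mapping = pixel_mapping(-65, 1.3),
                        n_colours = 16L,
                        schools = NULL) {
  seed <- as.integer(seed)
  total_cols <- frame_cols + (n_frames - 1L) * (frame_cols - overlap_cols)
  mpr <- (depth_max_m - depth_min_m) / frame_rows
  mpc <- speed_kn * 1852 / 3600 * ping_interval_s
  if (is.null(schools) && n_schools > 0L) {
    set.seed(seed)
    track_len <- total_cols * mpc
    usable <- track_len - 80
    if (n_schools * 60 > usable)
      stop("too many schools for the track length", call. = FALSE)
    base <- seq(40, track_len - 40, length.out = n_schools)
    schools <- data.frame(
      along_m = base + stats::runif(n_schools, -15, 15),
      depth_m = stats::runif(n_schools, school_depth_m[1], school_depth_m[2]),
      l_m = stats::runif(n_schools, school_l_m[1], school_l_m[2]),
      h_m = stats::runif(n_schools, school_h_m[1], school_h_m[2]),
      sv_db = stats::runif(n_schools, school_sv_db[1], school_sv_db[2])
    )
  } else if (is.null(schools)) {
    schools <- data.frame(along_m = numeric(0), depth_m = numeric(0),
                          l_m = numeric(0), h_m = numeric(0), sv_db = numeric(0))
  }
  if (any(schools$depth_m - schools$h_m / 2 < depth_min_m) ||
      any(schools$depth_m + schools$h_m / 2 > depth_max_m))
    stop("planted school outside the displayed depth range", call. = FALSE)
  # planted schools must respect the survey exclusion rules, or ground
  # truth and pipeline output would legitimately disagree
  if (any(schools$depth_m - schools$h_m / 2 < 3.5))
    stop("planted school top inside the 3 m nearfield exclusion", call. = FALSE)
  structure(list(
    seed = seed, n_frames = n_frames, frame_rows = frame_rows,
    frame_cols = frame_cols, overlap_cols = overlap_cols,
    total_cols = total_cols,
    depth_min_m = depth_min_m, depth_max_m = depth_max_m,
    metres_per_row = mpr, metres_per_col = mpc,
    ping_interval_s = ping_interval_s, speed_kn = speed_kn,
    start_lat = start_lat, start_lon = start_lon, heading_deg = heading_deg,
    seabed_range_m = seabed_range_m,
    school_spread_db = school_spread_db,
    speckle_density = speckle_density, noise_col_rate = noise_col_rate,
    mapping = mapping, scale = colour_scale(n_colours),
    schools = schools
  ), class = "survey_spec")
}

# dB -> display colour under the spec's mapping, hard-clipped at the top
# colour (the saturation ceiling) and floored at colour 1
quantise_sv <- function(sv_db, mapping, n_colours) {
  c0 <- round((sv_db - mapping$start_db) / mapping$step_db) + 1
  pmin(pmax(c0, 1), n_colours - 1L)
}

# rectangle stencil with the 4 corner pixels clipped (3x3-median invariant)
school_stencil <- function(r0, r1, c0, c1) {
  g <- expand.grid(row = r0:r1, col = c0:c1)
  corner <- (g$row == r0 | g$row == r1) & (g$col == c0 | g$col == c1)
  g[!corner, , drop = FALSE]
}

#' Generate a synthetic fish-finder survey
#'
#' Renders the global echogram described by a [survey_spec()], cuts it into
#' overlapping frames, and (optionally) writes PNG frames plus the sidecar
#' CSV to `dir`. Identical spec and seed give identical output.
#'
#' @param spec A [survey_spec()].
#' @param dir Optional output directory for `frame_###.png` + `sidecar.csv`.
#' @return List: `frames` (georeferenced, de-duplicated in-memory frames),
#'   `sidecar` (data.frame), `truth` (planted-school table: stencil pixel
#'   counts, centroids, metric sizes, mean Sv), `seabed_row` (true seabed
#'   row per global ping), `noise_cols` (injected interference pings),
#'   `speckle` (row/col of salt pixels), `global` (the noise-free stitched
#'   frame before interference, as an [echogram_frame()]), and `paths`
#'   (written PNG files, when `dir` is given).
#' @export
generate_survey <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "survey_spec"))
  R <- spec$frame_rows
  TC <- spec$total_cols
  mpr <- spec$metres_per_row
  mpc <- spec$metres_per_col
  n_col <- spec$scale$n_colours

  set.seed(spec$seed + 1L)
  # seabed: bounded random walk, |step| <= 1 row per column
  sb_lo <- ceiling((spec$seabed_range_m[1] - spec$depth_min_m) / mpr)
  sb_hi <- floor((spec$seabed_range_m[2] - spec$depth_min_m) / mpr)
  sb <- integer(TC)
  sb[1] <- sample(sb_lo:sb_hi, 1)
  steps <- sample(c(-1L, 0L, 0L, 1L), TC - 1L, replace = TRUE)
  for (i in 2:TC) sb[i] <- min(sb_hi, max(sb_lo, sb[i - 1] + steps[i - 1]))

  px <- matrix(0L, R, TC)
  for (i in seq_len(TC)) px[sb[i]:R, i] <- n_col - 1L # solid seabed echo

  # plant schools
  truth <- spec$schools
  nsch <- nrow(truth)
  for (nm in c("row0", "row1", "col0", "col1", "n_pixels"))
    truth[[nm]] <- rep(NA_integer_, nsch)
  for (nm in c("centroid_row", "centroid_col", "mean_depth_m", "area_m2"))
    truth[[nm]] <- rep(NA_real_, nsch)
  school_cols_mask <- logical(TC)
  if (nrow(truth)) {
    for (k in seq_len(nrow(truth))) {
      cc <- truth$along_m[k] / mpc
      rr <- (truth$depth_m[k] - spec$depth_min_m) / mpr
      hw <- max(2L, round(truth$l_m[k] / mpc / 2))
      hh <- max(2L, round(truth$h_m[k] / mpr / 2))
      c0 <- max(2L, round(cc) - hw)
      c1 <- min(TC - 1L, round(cc) + hw)
      r0 <- max(2L, round(rr) - hh)
      r1 <- round(rr) + hh
      sb_here <- min(sb[c0:c1])
      if (r1 >= sb_here - 2L)
        stop("planted school intersects the seabed margin", call. = FALSE)
      st <- school_stencil(r0, r1, c0, c1)
      sv_pix <- stats::rnorm(nrow(st), truth$sv_db[k], spec$school_spread_db)
      px[cbind(st$row, st$col)] <- quantise_sv(sv_pix, spec$mapping, n_col)
      # buffer of 2 pings: an interference column within the despeckle
      # kernel radius of a school is inseparable from it, so ground truth
      # would be ill-defined there
      school_cols_mask[max(1L, c0 - 2L):min(TC, c1 + 2L)] <- TRUE
      truth$row0[k] <- r0; truth$row1[k] <- r1
      truth$col0[k] <- c0; truth$col1[k] <- c1
      truth$n_pixels[k] <- nrow(st)
      truth$centroid_row[k] <- mean(st$row)
      truth$centroid_col[k] <- mean(st$col)
      truth$mean_depth_m[k] <- spec$depth_min_m + (mean(st$row) - 0.5) * mpr
      truth$area_m2[k] <- nrow(st) * mpr * mpc
    }
  }
  global_clean <- px

  # interference columns: saturated pings, planted away from schools
  n_noise <- stats::rbinom(1, TC, spec$noise_col_rate)
  free <- which(!school_cols_mask)
  noise_cols <- sort(sample(free, min(n_noise, length(free))))
  for (i in noise_cols) px[1:R, i] <- n_col - 1L

  # salt speckle in the water column (above the seabed)
  water <- which(row(px) < matrix(sb, R, TC, byrow = TRUE)[, , drop = FALSE])
  n_salt <- stats::rbinom(1, length(water), spec$speckle_density)
  salt <- sample(water, n_salt)
  px[salt] <- n_col - 1L
  speckle <- cbind(row = ((salt - 1L) %% R) + 1L,
                   col = ((salt - 1L) %/% R) + 1L)

  # track georeference (constant heading/speed, equirectangular step)
  t0 <- as.numeric(as.POSIXct("2014-05-10 08:00:00", tz = "UTC"))
  times <- t0 + (seq_len(TC) - 1L) * spec$ping_interval_s
  speed_ms <- spec$speed_kn * 1852 / 3600
  Rearth <- 6371008.8
  dist <- (seq_len(TC) - 1L) * speed_ms * spec$ping_interval_s
  th <- spec$heading_deg * pi / 180
  lat <- spec$start_lat + (dist * cos(th)) / Rearth * 180 / pi
  lon <- spec$start_lon + (dist * sin(th)) /
    (Rearth * cos(spec$start_lat * pi / 180)) * 180 / pi

  truth$lat_dd <- if (nrow(truth)) lat[round(truth$centroid_col)] else numeric(0)
  truth$lon_dd <- if (nrow(truth)) lon[round(truth$centroid_col)] else numeric(0)

  # cut into overlapping frames
  stride <- spec$frame_cols - spec$overlap_cols
  frame_start <- 1L + (seq_len(spec$n_frames) - 1L) * stride
  sidecar <- data.frame(
    frame_file = sprintf("frame_%03d.png", seq_len(spec$n_frames)),
    time_iso8601 = format(as.POSIXct(times[frame_start], origin = "1970-01-01",
                                     tz = "UTC"), "%Y-%m-%dT%H:%M:%S"),
    lat_dd = lat[frame_start], lon_dd = lon[frame_start],
    depth_min_m = spec$depth_min_m, depth_max_m = spec$depth_max_m
  )
  frames <- lapply(seq_len(spec$n_frames), function(i) {
    cols <- frame_start[i]:(frame_start[i] + spec$frame_cols - 1L)
    keep <- if (i == 1L) seq_along(cols) else (spec$overlap_cols + 1L):length(cols)
    cols <- cols[keep]
    echogram_frame(px[, cols, drop = FALSE], spec$depth_min_m,
                   spec$depth_max_m, spec$scale,
                   col_times = times[cols], col_lat = lat[cols],
                   col_lon = lon[cols], metres_per_col = mpc,
                   file = sidecar$frame_file[i])
  })

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, sidecar$frame_file)
    for (i in seq_len(spec$n_frames)) {
      cols <- frame_start[i]:(frame_start[i] + spec$frame_cols - 1L)
      png::writePNG(px[, cols, drop = FALSE] / (spec$scale$n_colours - 1L),
                    paths[i])
    }
    utils::write.csv(sidecar, file.path(dir, "sidecar.csv"), row.names = FALSE)
  }

  global <- echogram_frame(px, spec$depth_min_m, spec$depth_max_m, spec$scale,
                           col_times = times, col_lat = lat, col_lon = lon,
                           metres_per_col = mpc, file = "global")
  list(frames = frames, sidecar = sidecar, truth = truth,
       seabed_row = sb, noise_cols = noise_cols, speckle = speckle,
       global = global,
       global_clean = echogram_frame(global_clean, spec$depth_min_m,
                                     spec$depth_max_m, spec$scale,
                                     col_times = times, col_lat = lat,
                                     col_lon = lon, metres_per_col = mpc,
                                     file = "global_clean"),
       track = data.frame(time_s = times, lat_dd = lat, lon_dd = lon),
       paths = paths)
}

#' Generate paired echo-sounder / fish-finder matched schools
#'
#' Produces a synthetic [matched_pairs] table. Two modes:
#'
#' * **physical** (default, `truth = NULL`): each school's pixels carry an
#'   Sv drawn normally (in dB) around a school mean sampled over
#'   `sv_range_db`; the echo-sounder records the exact linear mean, while
#'   the fish-finder quantises pixels through `mapping` with a hard ceiling
#'   at `ceiling_db` (or the top colour), reproducing saturation.
#' * **calibration truth** (`truth = list(beta0, beta1, sigma)`): fish-finder
#'   sv values are drawn first and the echo-sounder response generated from
#'   the prescribed log-linear relation `log10(sv_ses) = beta0 + beta1 *
#'   sv_rff + N(0, sigma)`; pixel histograms mix two adjacent colours so the
#'   histogram's mean sv equals `sv_rff` exactly, enabling regression
#'   parameter-recovery tests.
#'
#' Matched depths are highly concordant between systems and areas agree on
#' the log scale with moderate noise, mirroring real matched-school
#' behaviour.
#'
#' @param n_pairs Number of matched schools (>= 3).
#' @param mapping Fish-finder [pixel_mapping()].
#' @param n_colours Display colours (16 by default, matching [survey_spec()]).
#' @param seed RNG seed.
#' @param sv_range_db Range of school mean Sv (dB), default -54 to -31.
#' @param spread_db Within-school pixel spread (dB).
#' @param ceiling_db Saturation ceiling (dB); pixels above it clip to the
#'   top colour. `NULL` means the only ceiling is the top display colour.
#' @param truth Optional calibration-truth parameters (see above).
#' @param n_pix_range Range of pixel counts per school.
#' @return A [matched_pairs] data.frame with attribute `"sv_rff_true"` (the
#'   generating sv_rff, truth mode only).
#' @export
generate_matched_pairs <- function(n_pairs = 36L,
                                   mapping = pixel_mapping(-65, 1.3),
                                   n_colours = 16L, seed = 1L,
                                   sv_range_db = c(-54, -31),
                                   spread_db = 2,
                                   ceiling_db = NULL,
                                   truth = NULL,
                                   n_pix_range = c(200L, 1500L)) {
  if (n_pairs < 3L) stop("need n_pairs >= 3", call. = FALSE)
  set.seed(seed)
  K <- n_colours - 1L
  depth <- pmin(55, pmax(5, stats::rnorm(n_pairs, 26.5, 12.6)))
  depth_rff <- depth + stats::rnorm(n_pairs, 0, 0.7)
  area_ses <- exp(stats::rnorm(n_pairs, log(150), 0.9))
  area_rff <- area_ses * exp(stats::rnorm(n_pairs, 0, 0.45))
  n_pix <- sample(n_pix_range[1]:n_pix_range[2], n_pairs, replace = TRUE)

  px <- matrix(0, n_pairs, K)
  sv_ses <- numeric(n_pairs)
  sv_rff_true <- rep(NA_real_, n_pairs)

  if (is.null(truth)) {
    cap <- if (is.null(ceiling_db)) K else
      max(1L, min(K, floor((ceiling_db - mapping$start_db) / mapping$step_db) + 1L))
    mean_sv <- stats::runif(n_pairs, sv_range_db[1], sv_range_db[2])
    for (i in seq_len(n_pairs)) {
      sv_pix <- stats::rnorm(n_pix[i], mean_sv[i], spread_db)
      sv_ses[i] <- mean(db_to_linear(sv_pix))
      colours <- pmin(quantise_sv(sv_pix, mapping, n_colours), cap)
      px[i, ] <- tabulate(colours, nbins = K)
    }
  } else {
    stopifnot(is.numeric(truth$beta0), is.numeric(truth$beta1),
              truth$beta1 > 0)
    sigma <- if (is.null(truth$sigma)) 0 else truth$sigma
    sv_lo <- db_to_linear(sv_of_colour(1L, mapping))
    sv_hi <- db_to_linear(sv_of_colour(K, mapping))
    sv_rff_true <- stats::runif(n_pairs, sv_lo, sv_hi)
    sv_col <- db_to_linear(sv_of_colour(seq_len(K), mapping))
    for (i in seq_len(n_pairs)) {
      cc <- findInterval(sv_rff_true[i], sv_col)
      cc <- min(max(cc, 1L), K - 1L)
      # mix colours cc and cc+1 so the histogram mean is sv_rff exactly
      frac <- (sv_rff_true[i] - sv_col[cc]) / (sv_col[cc + 1] - sv_col[cc])
      n_hi <- round(frac * n_pix[i])
      px[i, cc] <- n_pix[i] - n_hi
      px[i, cc + 1] <- n_hi
      # rounding shifts the mean slightly; correct sv_rff_true to the
      # realised histogram mean so recovery is exact up to the model noise
      sv_rff_true[i] <- (px[i, cc] * sv_col[cc] + px[i, cc + 1] * sv_col[cc + 1]) /
        n_pix[i]
    }
    sv_ses <- 10^(truth$beta0 + truth$beta1 * sv_rff_true +
                    stats::rnorm(n_pairs, 0, sigma))
  }
  out <- data.frame(
    MatchID = seq_len(n_pairs),
    Time = format(as.POSIXct("2014-05-10 08:00:00", tz = "UTC") +
                    300 * seq_len(n_pairs), "%H:%M:%S"),
    MeanDepthSES = depth, MeanDepthRFF = depth_rff,
    AreaSES = area_ses, AreaRFF = area_rff,
    sv_ses = sv_ses
  )
  pxd <- as.data.frame(px)
  names(pxd) <- paste0("Px", seq_len(K))
  out <- cbind(out, pxd)
  attr(out, "sv_rff_true") <- sv_rff_true
  out
}
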