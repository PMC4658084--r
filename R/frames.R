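#' Echogram frame
#'
#' One fish-finder screen frame: a grid of colour indices (row 1 is the
#' shallowest depth sample, column 1 the oldest ping) together with its
#' displayed depth range, per-column times and interpolated position fixes,
#' and the reconciled vertical/horizontal pixel scales in metres.
#'
#' @param pixels Integer matrix of colour indices in `[0, n_colours - 1]`.
#' @param depth_min_m,depth_max_m Displayed depth range (m), `max > min >= 0`.
#' @param scale A [colour_scale()].
#' @param col_times Numeric vector (seconds since epoch) per column,
#'   non-decreasing; may be `NULL` before georeferencing.
#' @param col_lat,col_lon Decimal-degree position per column; may be `NULL`.
#' @param metres_per_col Horizontal scale (m/pixel); may be `NA` before
#'   reconciliation.
#' @param file Source file name (informative).
#' @return An object of class `echogram_frame`. `metres_per_row` is always
#'   `(depth_max_m - depth_min_m) / nrow(pixels)`.
#' @export
echogram_frame <- function(pixels, depth_min_m, depth_max_m, scale,
                           col_times = NULL, col_lat = NULL, col_lon = NULL,
                           metres_per_col = NA_real_, file = NA_character_) {
  stopifnot(inherits(scale, "colour_scale"))
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (depth_max_m <= depth_min_m || depth_min_m < 0)
    stop("need depth_max_m > depth_min_m >= 0", call. = FALSE)
  if (any(pixels < 0L | pixels >= scale$n_colours))
    stop("pixel colour indices outside [0, n_colours - 1]", call. = FALSE)
  nc <- ncol(pixels)
  if (!is.null(col_times)) {
    stopifnot(length(col_times) == nc)
    if (is.unsorted(col_times)) stop("col_times must be non-decreasing", call. = FALSE)
  }
  if (!is.null(col_lat)) stopifnot(length(col_lat) == nc, all(abs(col_lat) <= 90))
  if (!is.null(col_lon)) stopifnot(length(col_lon) == nc, all(abs(col_lon) <= 180))
  structure(list(
    pixels = pixels,
    depth_min_m = as.numeric(depth_min_m),
    depth_max_m = as.numeric(depth_max_m),
    metres_per_row = (depth_max_m - depth_min_m) / nrow(pixels),
    metres_per_col = as.numeric(metres_per_col),
    col_times = col_times, col_lat = col_lat, col_lon = col_lon,
    scale = scale, file = file
  ), class = "echogram_frame")
}

#' @export
print.echogram_frame <- function(x, ...) {
  cat(sprintf(
    "<echogram_frame> %d rows x %d pings, %.1f-%.1f m (%.3f m/row, %s m/col)\n",
    nrow(x$pixels), ncol(x$pixels), x$depth_min_m, x$depth_max_m,
    x$metres_per_row,
    if (is.na(x$metres_per_col)) "?" else sprintf("%.3f", x$metres_per_col)))
  invisible(x)
}

#' Depth (m) at the centre of each pixel row
#'
#' Row `r` (1-based) spans depths `depth_min + (r-1)*mpr` to
#' `depth_min + r*mpr`; its centre is `depth_min + (r - 0.5) * mpr`.
#'
#' @param frame An [echogram_frame()].
#' @return Numeric vector of length `nrow(frame$pixels)`.
#' @export
row_depths <- function(frame) {
  frame$depth_min_m + (seq_len(nrow(frame$pixels)) - 0.5) * frame$metres_per_row
}

#' Great-circle (haversine) distance in metres
#'
#' @param lat1,lon1,lat2,lon2 Decimal degrees; vectorised.
#' @param radius_m Earth radius (m).
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2, radius_m = 6371008.8) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_m * asin(pmin(1, sqrt(a)))
}

read_png_indices <- function(path, scale, quantise_tol = 0.02) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE]
  if (length(dim(img)) == 2L) {
    chans <- list(img, img, img)
  } else if (dim(img)[3] == 1L) {
    chans <- list(img[, , 1], img[, , 1], img[, , 1])
  } else {
    chans <- list(img[, , 1], img[, , 2], img[, , 3])
  }
  pal <- scale$palette
  best <- matrix(Inf, nrow(chans[[1]]), ncol(chans[[1]]))
  idx <- matrix(0L, nrow(chans[[1]]), ncol(chans[[1]]))
  for (k in seq_len(nrow(pal))) {
    d <- pmax(abs(chans[[1]] - pal[k, 1]), abs(chans[[2]] - pal[k, 2]),
              abs(chans[[3]] - pal[k, 3]))
    hit <- d < best
    idx[hit] <- k - 1L
    best[hit] <- d[hit]
  }
  if (any(best > quantise_tol)) {
    w <- which(best > quantise_tol, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "pixel at row %d, col %d of '%s' (value %.4f/%.4f/%.4f) matches no palette colour",
      w[1], w[2], basename(path),
      chans[[1]][w[1], w[2]], chans[[2]][w[1], w[2]], chans[[3]][w[1], w[2]]),
      call. = FALSE)
  }
  idx
}

#' Read a frame sidecar log
#'
#' One CSV row per frame: `frame_file, time_iso8601, lat_dd, lon_dd,
#' depth_min_m, depth_max_m`.
#'
#' @param path CSV file path, or a data.frame already in the schema.
#' @return data.frame with a numeric `time_s` column added (seconds since
#'   epoch, UTC).
#' @export
read_sidecar <- function(path) {
  sc <- if (is.data.frame(path)) path else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame_file", "time_iso8601", "lat_dd", "lon_dd",
            "depth_min_m", "depth_max_m")
  miss <- setdiff(need, names(sc))
  if (length(miss))
    stop("sidecar missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  sc$time_s <- as.numeric(as.POSIXct(sc$time_iso8601, tz = "UTC",
                                     tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                    "%Y-%m-%d %H:%M:%OS")))
  if (anyNA(sc$time_s)) stop("unparseable sidecar timestamps", call. = FALSE)
  if (any(abs(sc$lat_dd) > 90) || any(abs(sc$lon_dd) > 180))
    stop("sidecar fixes outside valid lat/lon range", call. = FALSE)
  sc
}

#' Read fish-finder frames from raster captures
#'
#' Loads PNG screen captures, quantises them to colour indices against the
#' declared palette, removes duplicated columns shared by overlapping
#' contiguous frames, and georeferences every column by linear interpolation
#' between the per-frame sidecar fixes. The sidecar timestamp/fix refers to a
#' frame's first (oldest, left-most) column; the ping interval of frame *i*
#' is inferred as `(t[i+1] - t[i]) / (ncol[i] - overlap[i+1])`, i.e. from the
#' unique-ping count revealed by de-duplication. The horizontal scale is the
#' vessel speed over each inter-fix segment (great-circle) times the ping
#' interval.
#'
#' @param image_paths Character vector of PNG paths, in survey order.
#' @param sidecar Sidecar CSV path or data.frame (see [read_sidecar()]).
#' @param scale A [colour_scale()].
#' @param dedup Remove duplicated overlap columns (default `TRUE`).
#' @param quantise_tol Maximum per-channel deviation tolerated when matching
#'   pixels to palette colours.
#' @return List of [echogram_frame()] objects. Frames without a sidecar row
#'   are rejected with a warning naming the file.
#' @export
read_frames <- function(image_paths, sidecar, scale, dedup = TRUE,
                        quantise_tol = 0.02) {
  sc <- read_sidecar(sidecar)
  keep <- basename(image_paths) %in% basename(sc$frame_file)
  if (any(!keep)) {
    warning("rejecting frame(s) with no sidecar row: ",
            paste(basename(image_paths)[!keep], collapse = ", "), call. = FALSE)
    image_paths <- image_paths[keep]
  }
  if (!length(image_paths)) return(list())
  sc <- sc[match(basename(image_paths), basename(sc$frame_file)), , drop = FALSE]
  if (any(diff(sc$time_s) <= 0))
    stop("sidecar frame times must be strictly increasing", call. = FALSE)

  raw <- lapply(seq_along(image_paths), function(i) {
    echogram_frame(read_png_indices(image_paths[i], scale, quantise_tol),
                   sc$depth_min_m[i], sc$depth_max_m[i], scale,
                   file = basename(image_paths[i]))
  })

  n <- length(raw)
  overlap <- integer(n) # overlap[i] = columns trimmed from frame i
  if (dedup && n > 1L) {
    for (i in 2:n) {
      ded <- dedup_overlap(raw[[i - 1]], raw[[i]])
      overlap[i] <- attr(ded, "overlap_removed")
      raw[[i]] <- ded
    }
  }

  # per-frame ping interval and vessel speed from inter-fix segments
  widths <- vapply(raw, function(f) ncol(f$pixels), integer(1))
  dt <- speed <- rep(NA_real_, n)
  if (n > 1L) {
    for (i in 1:(n - 1)) {
      # original frame i+1 starts k=overlap[i+1] pings before frame i ends, so
      # t[i+1] - t[i] spans (original width of i) - overlap[i+1] pings
      span_cols <- widths[i] + overlap[i] - overlap[i + 1]
      dt[i] <- (sc$time_s[i + 1] - sc$time_s[i]) / span_cols
      speed[i] <- haversine_m(sc$lat_dd[i], sc$lon_dd[i],
                              sc$lat_dd[i + 1], sc$lon_dd[i + 1]) /
        (sc$time_s[i + 1] - sc$time_s[i])
    }
    dt[n] <- dt[n - 1]
    speed[n] <- speed[n - 1]
  } else {
    dt[1] <- 1
    speed[1] <- 0
  }

  out <- vector("list", n)
  for (i in seq_len(n)) {
    w <- widths[i]
    # original first column of frame i sits at sc$time_s[i]; `overlap[i]`
    # leading columns were trimmed, so retained column j is ping overlap[i]+j-1
    t_cols <- sc$time_s[i] + (overlap[i] + seq_len(w) - 1) * dt[i]
    fix <- interp_track(t_cols, sc$time_s, sc$lat_dd, sc$lon_dd)
    out[[i]] <- echogram_frame(raw[[i]]$pixels,
                               sc$depth_min_m[i], sc$depth_max_m[i], scale,
                               col_times = t_cols,
                               col_lat = fix$lat, col_lon = fix$lon,
                               metres_per_col = speed[i] * dt[i],
                               file = raw[[i]]$file)
  }
  out
}

# linear interpolation of lat/lon in time; linear extrapolation at the ends
interp_track <- function(t, fix_t, fix_lat, fix_lon) {
  if (length(fix_t) == 1L)
    return(list(lat = rep(fix_lat, length(t)), lon = rep(fix_lon, length(t))))
  lat <- stats::approx(fix_t, fix_lat, xout = t, rule = 2)$y
  lon <- stats::approx(fix_t, fix_lon, xout = t, rule = 2)$y
  hi <- t > fix_t[length(fix_t)]
  if (any(hi)) { # extrapolate with the last segment's velocity
    m <- length(fix_t)
    sl_lat <- (fix_lat[m] - fix_lat[m - 1]) / (fix_t[m] - fix_t[m - 1])
    sl_lon <- (fix_lon[m] - fix_lon[m - 1]) / (fix_t[m] - fix_t[m - 1])
    lat[hi] <- fix_lat[m] + sl_lat * (t[hi] - fix_t[m])
    lon[hi] <- fix_lon[m] + sl_lon * (t[hi] - fix_t[m])
  }
  list(lat = lat, lon = lon)
}

#' Remove duplicated columns shared by overlapping contiguous frames
#'
#' A scrolling fish-finder display repeats the newest pings of one screen
#' capture at the start of the next. The longest run of left-most columns of
#' `next_frame` that is pixel-identical to the right-most columns of `prev`
#' is removed from `next_frame`.
#'
#' @param prev,next_frame Two contiguous [echogram_frame()] objects sharing
#'   depth range and palette.
#' @return `next_frame` with its duplicated leading columns dropped; the
#'   number removed is recorded in `attr(, "overlap_removed")`.
#' @export
dedup_overlap <- function(prev, next_frame) {
  stopifnot(inherits(prev, "echogram_frame"), inherits(next_frame, "echogram_frame"))
  if (prev$depth_min_m != next_frame$depth_min_m ||
      prev$depth_max_m != next_frame$depth_max_m)
    stop("frames have differing depth ranges; rescale before de-duplication",
         call. = FALSE)
  if (nrow(prev$pixels) != nrow(next_frame$pixels))
    stop("frames have differing row counts", call. = FALSE)
  a <- prev$pixels
  b <- next_frame$pixels
  kmax <- min(ncol(a), ncol(b))
  k <- 0L
  for (cand in kmax:1) { # longest exact suffix(prev)/prefix(next) match
    if (identical(a[, (ncol(a) - cand + 1):ncol(a), drop = FALSE],
                  b[, 1:cand, drop = FALSE])) {
      k <- cand
      break
    }
  }
  if (k == ncol(b)) k <- k - 1L # never emit an empty frame
  keep <- if (k > 0L) (k + 1L):ncol(b) else seq_len(ncol(b))
  out <- echogram_frame(b[, keep, drop = FALSE],
                        next_frame$depth_min_m, next_frame$depth_max_m,
                        next_frame$scale,
                        col_times = next_frame$col_times[keep],
                        col_lat = next_frame$col_lat[keep],
                        col_lon = next_frame$col_lon[keep],
                        metres_per_col = next_frame$metres_per_col,
                        file = next_frame$file)
  attr(out, "overlap_removed") <- k
  out
}

#' Concatenate de-duplicated frames into one continuous echogram
#'
#' @param frames List of [echogram_frame()] objects with identical depth
#'   range, row count and palette, already de-duplicated.
#' @return A single [echogram_frame()]; `metres_per_col` is the
#'   width-weighted mean of the inputs'.
#' @export
stitch_frames <- function(frames) {
  stopifnot(length(frames) >= 1L)
  f1 <- frames[[1]]
  for (f in frames[-1]) {
    if (f$depth_min_m != f1$depth_min_m || f$depth_max_m != f1$depth_max_m ||
        nrow(f$pixels) != nrow(f1$pixels))
      stop("frames must share depth range and row count to be stitched",
           call. = FALSE)
  }
  px <- do.call(cbind, lapply(frames, `[[`, "pixels"))
  cat_or_null <- function(field) {
    vals <- lapply(frames, `[[`, field)
    if (any(vapply(vals, is.null, logical(1)))) NULL else do.call(c, vals)
  }
  w <- vapply(frames, function(f) ncol(f$pixels), integer(1))
  mpc <- stats::weighted.mean(vapply(frames, `[[`, numeric(1), "metres_per_col"), w)
  echogram_frame(px, f1$depth_min_m, f1$depth_max_m, f1$scale,
                 col_times = cat_or_null("col_times"),
                 col_lat = cat_or_null("col_lat"),
                 col_lon = cat_or_null("col_lon"),
                 metres_per_col = mpc, file = f1$file)
}
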