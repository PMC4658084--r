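#' Echo-return mask
#'
#' @param frame A seabed-masked, denoised [echogram_frame()].
#' @return Logical matrix, `TRUE` where the colour index is > 0.
#' @export
make_mask <- function(frame) frame$pixels > 0L

#' Connected-component labelling
#'
#' Iterative flood fill over a logical mask.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8 (default 8: echo traces step diagonally at ping
#'   boundaries).
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  R <- nrow(mask)
  C <- ncol(mask)
  lbl <- matrix(0L, R, C)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- rep(c(-1L, 0L, 1L), 3L)[-5L]
    dc <- rep(c(-1L, 0L, 1L), each = 3L)[-5L]
  }
  n <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lbl[start] != 0L) next
    n <- n + 1L
    stack <- start
    lbl[start] <- n
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pr <- ((p - 1L) %% R) + 1L
      pc <- ((p - 1L) %/% R) + 1L
      nr <- pr + dr
      nc <- pc + dc
      ok <- nr >= 1L & nr <= R & nc >= 1L & nc <= C
      q <- (nc[ok] - 1L) * R + nr[ok]
      q <- q[mask[q] & lbl[q] == 0L]
      if (length(q)) {
        lbl[q] <- n
        stack <- c(stack, q)
      }
    }
  }
  lbl
}

#' Fill interior holes (vacuoles) of a mask
#'
#' Background connected (4-connectivity) to the matrix border stays
#' background; enclosed background becomes foreground.
#'
#' @param mask Logical matrix.
#' @return Logical matrix with vacuoles filled.
#' @export
fill_holes <- function(mask) {
  R <- nrow(mask)
  C <- ncol(mask)
  open_bg <- matrix(FALSE, R, C)
  border <- unique(c(which(col(mask) %in% c(1L, C)), which(row(mask) %in% c(1L, R))))
  seeds <- border[!mask[border]]
  open_bg[seeds] <- TRUE
  stack <- seeds
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, -1L, 1L)
  while (length(stack)) {
    p <- stack[length(stack)]
    stack <- stack[-length(stack)]
    pr <- ((p - 1L) %% R) + 1L
    pc <- ((p - 1L) %/% R) + 1L
    nr <- pr + dr
    nc <- pc + dc
    ok <- nr >= 1L & nr <= R & nc >= 1L & nc <= C
    q <- (nc[ok] - 1L) * R + nr[ok]
    q <- q[!mask[q] & !open_bg[q]]
    if (length(q)) {
      open_bg[q] <- TRUE
      stack <- c(stack, q)
    }
  }
  mask | !open_bg
}

candidate_geometry <- function(rows, cols, frame, seabed_depth_per_col = NULL) {
  mpr <- frame$metres_per_row
  mpc <- frame$metres_per_col
  bbox <- c(minr = min(rows), maxr = max(rows), minc = min(cols), maxc = max(cols))
  top_depth <- frame$depth_min_m + (bbox["minr"] - 0.5) * mpr
  bot_pixel_depth <- frame$depth_min_m + (bbox["maxr"] - 0.5) * mpr
  alt <- NA_real_
  if (!is.null(seabed_depth_per_col)) {
    sb <- max(seabed_depth_per_col[bbox["minc"]:bbox["maxc"]])
    alt <- sb - bot_pixel_depth
  }
  list(rows = rows, cols = cols, n = length(rows), bbox = bbox,
       L_m = unname(bbox["maxc"] - bbox["minc"] + 1) * mpc,
       H_m = unname(bbox["maxr"] - bbox["minr"] + 1) * mpr,
       top_depth_m = unname(top_depth),
       bot_pixel_depth_m = unname(bot_pixel_depth),
       altitude_m = unname(alt))
}

#' Detect candidate echo regions
#'
#' Labels contiguous echo returns in the mask and computes their metric
#' extents from the frame geometry.
#'
#' @param mask Logical mask (from [make_mask()]).
#' @param frame The [echogram_frame()] supplying the pixel scales.
#' @param seabed Optional [trace_seabed()] result used to compute altitudes.
#' @param connectivity Passed to [label_components()].
#' @return List of candidate regions (`rows`, `cols`, `n`, `bbox`, `L_m`,
#'   `H_m`, `top_depth_m`, `altitude_m`).
#' @export
find_candidates <- function(mask, frame, seabed = NULL, connectivity = 8L) {
  lbl <- label_components(mask, connectivity)
  k <- max(lbl)
  if (k == 0L) return(list())
  sbd <- if (!is.null(seabed)) seabed_depths(frame, seabed)
  idx <- which(lbl > 0L)
  ord <- order(lbl[idx])
  idx <- idx[ord]
  grp <- split(idx, lbl[idx])
  lapply(grp, function(p) {
    candidate_geometry(((p - 1L) %% nrow(mask)) + 1L,
                       ((p - 1L) %/% nrow(mask)) + 1L,
                       frame, sbd)
  })
}

#' Exclusion rules and aggregation parameters
#'
#' Defaults follow the survey protocol: echo returns shallower than 3 m
#' (acoustic nearfield) or within 0.5 m of the seabed (bathymetric
#' anomalies) are excluded, candidates smaller than 1 x 1 m (L x H) are
#' treated as non-schooling fish, schools weaker than Sv = -65 dB are
#' dropped, candidates are aggregated through a 10 x 2 m (L x H) linking
#' ellipse, and aggregated schools smaller than 10 x 5 m (L x H) are
#' discarded.
#'
#' @param link_ellipse_l_m,link_ellipse_h_m Full axis lengths (m) of the
#'   gap-acceptance ellipse.
#' @param min_school_l_m,min_school_h_m Minimum aggregated school size (m).
#' @param min_candidate_l_m,min_candidate_h_m Minimum candidate size (m).
#' @param min_depth_m Nearfield exclusion depth (m).
#' @param min_altitude_m Minimum altitude above the seabed (m).
#' @param sv_threshold_db Minimum mean Sv (dB re 1 m^-1).
#' @return An `aggregation_rules` object.
#' @export
aggregation_rules <- function(link_ellipse_l_m = 10, link_ellipse_h_m = 2,
                              min_school_l_m = 10, min_school_h_m = 5,
                              min_candidate_l_m = 1, min_candidate_h_m = 1,
                              min_depth_m = 3, min_altitude_m = 0.5,
                              sv_threshold_db = -65) {
  r <- list(link_ellipse_l_m = link_ellipse_l_m,
            link_ellipse_h_m = link_ellipse_h_m,
            min_school_l_m = min_school_l_m, min_school_h_m = min_school_h_m,
            min_candidate_l_m = min_candidate_l_m,
            min_candidate_h_m = min_candidate_h_m,
            min_depth_m = min_depth_m, min_altitude_m = min_altitude_m,
            sv_threshold_db = sv_threshold_db)
  if (any(unlist(r[1:8]) <= 0))
    stop("all rule lengths must be > 0", call. = FALSE)
  structure(r, class = "aggregation_rules")
}

#' Apply the candidate exclusion rules
#'
#' Rejects candidates whose top depth is above `min_depth_m` (nearfield),
#' whose altitude above the seabed is below `min_altitude_m`, whose length
#' or height is below 1 m, or whose mean Sv is below the threshold; each
#' rejection is logged with the triggering rule.
#'
#' @param cands Candidates from [find_candidates()].
#' @param rules An [aggregation_rules()] object.
#' @param frame The source [echogram_frame()] (for pixel colours).
#' @param mapping A [pixel_mapping()] used to evaluate the Sv threshold.
#' @return List with `retained` (candidate list) and `rejected`
#'   (data.frame: candidate index, rule).
#' @export
filter_candidates <- function(cands, rules, frame, mapping) {
  keep <- logical(length(cands))
  why <- character(length(cands))
  for (i in seq_along(cands)) {
    cd <- cands[[i]]
    colours <- frame$pixels[cbind(cd$rows, cd$cols)]
    counts <- tabulate(colours, nbins = frame$scale$n_colours - 1L)
    sv_db <- if (sum(counts) > 0) school_mean_sv(counts, mapping)$Sv_db else -Inf
    rule <- if (cd$top_depth_m < rules$min_depth_m) "nearfield"
    else if (!is.na(cd$altitude_m) && cd$altitude_m < rules$min_altitude_m) "altitude"
    else if (cd$L_m < rules$min_candidate_l_m ||
             cd$H_m < rules$min_candidate_h_m) "min_size"
    else if (sv_db < rules$sv_threshold_db) "sv_threshold"
    else ""
    keep[i] <- rule == ""
    why[i] <- rule
  }
  list(retained = cands[keep],
       rejected = data.frame(candidate = which(!keep), rule = why[!keep]))
}

# squared linking-ellipse value of the nearest gap between two pixel sets;
# semi-axes are half the stated full axis lengths
min_ellipse_gap <- function(c1, c2, mpc, mpr, semi_x, semi_z) {
  # bounding-box prefilter: component-wise gaps lower-bound every pixel pair
  gx_bb <- max(0L, max(c1$bbox["minc"] - c2$bbox["maxc"],
                       c2$bbox["minc"] - c1$bbox["maxc"]) - 1L) * mpc
  gz_bb <- max(0L, max(c1$bbox["minr"] - c2$bbox["maxr"],
                       c2$bbox["minr"] - c1$bbox["maxr"]) - 1L) * mpr
  lb <- (gx_bb / semi_x)^2 + (gz_bb / semi_z)^2
  if (lb > 1) return(lb)
  dx <- abs(outer(c1$cols, c2$cols, "-")) - 1L
  dz <- abs(outer(c1$rows, c2$rows, "-")) - 1L
  gx <- pmax(dx, 0L) * mpc
  gz <- pmax(dz, 0L) * mpr
  min((gx / semi_x)^2 + (gz / semi_z)^2)
}

#' Aggregate candidates into schools through the linking ellipse
#'
#' Two candidates merge when the nearest gap between their pixel sets
#' (horizontal gap dx, vertical gap dz, in metres, measured between pixel
#' edges) falls inside the linking ellipse:
#' `(dx / (L/2))^2 + (dz / (H/2))^2 <= 1` with the stated `L x H = 10 x 2 m`
#' as full axis lengths. Merging is closed transitively (union-find), and
#' aggregated schools smaller than the minimum school size are discarded.
#'
#' @param cands Filtered candidates.
#' @param rules An [aggregation_rules()] object.
#' @param frame The [echogram_frame()] supplying pixel scales.
#' @return List of aggregated schools (same geometry structure as
#'   candidates, pixel sets unioned).
#' @export
link_schools <- function(cands, rules, frame) {
  n <- length(cands)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  semi_x <- rules$link_ellipse_l_m / 2
  semi_z <- rules$link_ellipse_h_m / 2
  if (n > 1L) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (min_ellipse_gap(cands[[i]], cands[[j]], frame$metres_per_col,
                          frame$metres_per_row, semi_x, semi_z) <= 1) {
        ri <- find(i)
        rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  out <- lapply(split(seq_len(n), root), function(members) {
    rows <- unlist(lapply(cands[members], `[[`, "rows"), use.names = FALSE)
    cols <- unlist(lapply(cands[members], `[[`, "cols"), use.names = FALSE)
    g <- candidate_geometry(rows, cols, frame)
    g$altitude_m <- min(vapply(cands[members], `[[`, numeric(1), "altitude_m"))
    g
  })
  keep <- vapply(out, function(s) {
    s$L_m >= rules$min_school_l_m && s$H_m >= rules$min_school_h_m
  }, logical(1))
  unname(out[keep])
}

# Moore-neighbour boundary trace of a filled mask restricted to one region;
# returns ordered boundary pixel indices (rows, cols)
trace_boundary <- function(rows, cols) {
  minr <- min(rows); minc <- min(cols)
  R <- max(rows) - minr + 3L
  C <- max(cols) - minc + 3L
  m <- matrix(FALSE, R, C)
  m[cbind(rows - minr + 2L, cols - minc + 2L)] <- TRUE
  # start: topmost pixel of the leftmost occupied column
  sc <- min(which(colSums(m) > 0))
  sr <- min(which(m[, sc]))
  # clockwise Moore neighbourhood starting north
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  cur <- c(sr, sc)
  dir <- 7L # came from the west; start searching at W neighbour's successor
  path_r <- integer(0)
  path_c <- integer(0)
  repeat {
    path_r <- c(path_r, cur[1])
    path_c <- c(path_c, cur[2])
    found <- FALSE
    for (k in 0:7) {
      d <- (dir + k) %% 8L
      nr <- cur[1] + dr[d + 1L]
      nc <- cur[2] + dc[d + 1L]
      if (m[nr, nc]) {
        cur <- c(nr, nc)
        dir <- (d + 6L) %% 8L # backtrack: start next search just past where we came from
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (cur[1] == sr && cur[2] == sc) break
    if (length(path_r) > 4L * length(rows) + 8L) break # safety cap
  }
  cbind(row = path_r + minr - 2L, col = path_c + minc - 2L)
}

#' Perimeter of a pixel region (m)
#'
#' Outer-boundary length of the filled region: boundary pixels are traced in
#' order (Moore neighbourhood) and consecutive centre-to-centre segment
#' lengths are summed, so diagonal steps contribute their true hypotenuse
#' (the corner correction). A single-pixel region reports the pixel's own
#' circumference.
#'
#' @param rows,cols Pixel coordinates of the (filled) region.
#' @param mpr,mpc Vertical/horizontal pixel scale (m).
#' @return Perimeter in metres.
#' @export
region_perimeter <- function(rows, cols, mpr, mpc) {
  if (length(rows) == 1L) return(2 * (mpr + mpc))
  b <- trace_boundary(rows, cols)
  if (nrow(b) < 2L) return(2 * (mpr + mpc))
  drs <- diff(c(b[, 1], b[1, 1])) * mpr
  dcs <- diff(c(b[, 2], b[1, 2])) * mpc
  sum(sqrt(drs^2 + dcs^2))
}

#' Feret (caliper) geometry of a pixel region
#'
#' Computes the maximum caliper diameter over all orientations from the
#' convex hull of the pixel *corner* points in metric coordinates, the
#' extent perpendicular to that diameter, and the diameter's orientation in
#' degrees from the horizontal (ping) axis, reported in `[0, 180)`.
#'
#' @param rows,cols Pixel coordinates of the region.
#' @param mpr,mpc Pixel scales (m).
#' @return List `max_diam_m`, `min_diam_m`, `angle_deg`.
#' @export
region_feret <- function(rows, cols, mpr, mpc) {
  x <- c((cols - 1) * mpc, cols * mpc, (cols - 1) * mpc, cols * mpc)
  z <- c((rows - 1) * mpr, (rows - 1) * mpr, rows * mpr, rows * mpr)
  h <- grDevices::chull(x, z)
  hx <- x[h]
  hz <- z[h]
  n <- length(h)
  best <- 0
  bi <- bj <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d2 <- (hx[i] - hx[j])^2 + (hz[i] - hz[j])^2
    if (d2 > best) {
      best <- d2
      bi <- i
      bj <- j
    }
  }
  maxd <- sqrt(best)
  if (maxd == 0) return(list(max_diam_m = 0, min_diam_m = 0, angle_deg = 0))
  ux <- (hx[bj] - hx[bi]) / maxd
  uz <- (hz[bj] - hz[bi]) / maxd
  proj <- hx * (-uz) + hz * ux # perpendicular direction
  ang <- atan2(uz, ux) * 180 / pi
  ang <- ang %% 180
  list(max_diam_m = maxd, min_diam_m = max(proj) - min(proj), angle_deg = ang)
}

#' Extract the full descriptor record of one school
#'
#' Fills every field of the school schema (see [school_table]) from the
#' school's pixel set, the frame geometry, the traced seabed and the column
#' georeferences. The seabed depth (`BotDepth`) is the deepest traced seabed
#' under the school's column span, which guarantees the depth-ordering
#' invariants on seabed-masked frames. Schools touching the frame edge are
#' flagged in the extra `Truncated` column (not part of the CSV schema; it
#' is dropped on write).
#'
#' @param school A pixel region (from [link_schools()]).
#' @param frame The processed [echogram_frame()].
#' @param seabed A [trace_seabed()] result.
#' @param colour_frame Frame supplying the pixel-value histogram (defaults
#'   to `frame`; pass the pre-masking frame to histogram raw colours).
#' @return One-row data.frame in the school schema.
#' @export
extract_parameters <- function(school, frame, seabed, colour_frame = frame) {
  rows <- school$rows
  cols <- school$cols
  mpr <- frame$metres_per_row
  mpc <- frame$metres_per_col
  bbox <- school$bbox
  sbd <- seabed_depths(frame, seabed)
  bot_depth <- max(sbd[bbox["minc"]:bbox["maxc"]])

  depths <- frame$depth_min_m + (rows - 0.5) * mpr
  mean_depth <- mean(depths)
  top_depth <- frame$depth_min_m + (bbox["minr"] - 0.5) * mpr
  height <- unname(bbox["maxr"] - bbox["minr"] + 1) * mpr
  width <- unname(bbox["maxc"] - bbox["minc"] + 1) * mpc
  bot_pixel_depth <- frame$depth_min_m + (bbox["maxr"] - 0.5) * mpr
  bot_depth <- max(bot_depth, top_depth + height) # sloped-seabed guard

  filled <- fill_region(rows, cols)
  area <- nrow(filled) * mpr * mpc
  area_lv <- length(rows) * mpr * mpc
  perim <- region_perimeter(filled[, 1], filled[, 2], mpr, mpc)
  fer <- region_feret(filled[, 1], filled[, 2], mpr, mpc)

  ccol <- round(mean(cols))
  at <- function(v, i) if (is.null(v)) NA_real_ else v[i]
  t_c <- at(frame$col_times, ccol)
  counts <- tabulate(colour_frame$pixels[cbind(rows, cols)],
                     nbins = frame$scale$n_colours - 1L)
  out <- data.frame(
    File = frame$file,
    Time = if (is.na(t_c)) NA_character_ else
      format(as.POSIXct(t_c, origin = "1970-01-01", tz = "UTC"), "%H:%M:%S"),
    Date = if (is.na(t_c)) NA_character_ else
      format(as.POSIXct(t_c, origin = "1970-01-01", tz = "UTC"), "%y/%m/%d"),
    PicRef = frame$file,
    Lat_dd = at(frame$col_lat, ccol), Long_dd = at(frame$col_lon, ccol),
    LeftLat = at(frame$col_lat, bbox["minc"]),
    LeftLon = at(frame$col_lon, bbox["minc"]),
    RightLat = at(frame$col_lat, bbox["maxc"]),
    RightLon = at(frame$col_lon, bbox["maxc"]),
    BotAltitude = bot_depth - bot_pixel_depth,
    TopDepth = top_depth,
    MeanAltitude = bot_depth - mean_depth,
    MeanDepth = mean_depth,
    BotDepth = bot_depth,
    SchoolHeight = height,
    SchoolWidth = width,
    Area = area,
    AreaLV = area_lv,
    Perimeter = perim,
    MaxCalDiam = fer$max_diam_m,
    MinCalDiam = fer$min_diam_m,
    MaxCalAngle = fer$angle_deg,
    Truncated = bbox["minc"] == 1L || bbox["maxc"] == ncol(frame$pixels) ||
      bbox["minr"] == 1L || bbox["maxr"] == nrow(frame$pixels),
    row.names = NULL
  )
  px <- as.data.frame(as.list(counts))
  names(px) <- px_cols(frame$scale$n_colours)
  cbind(out, px)
}

# pixel set of the region with its vacuoles filled
fill_region <- function(rows, cols) {
  minr <- min(rows); minc <- min(cols)
  m <- matrix(FALSE, max(rows) - minr + 1L, max(cols) - minc + 1L)
  m[cbind(rows - minr + 1L, cols - minc + 1L)] <- TRUE
  f <- fill_holes(m)
  w <- which(f, arr.ind = TRUE)
  cbind(row = w[, 1] + minr - 1L, col = w[, 2] + minc - 1L)
}
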