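#' Median-filter despeckling
#'
#' Replaces every pixel by the median colour index of its `kernel x kernel`
#' neighbourhood (borders reflected), removing isolated speckles of
#' interference. Implemented by counting-threshold search over the small
#' colour alphabet, so cost is `O(n_colours * kernel^2)` vector operations
#' rather than one sort per pixel.
#'
#' @param frame An [echogram_frame()].
#' @param kernel Odd window size >= 3.
#' @return The despeckled frame.
#' @export
despeckle <- function(frame, kernel = 3L) {
  kernel <- as.integer(kernel)
  if (kernel %% 2L != 1L || kernel < 3L)
    stop("`kernel` must be an odd integer >= 3", call. = FALSE)
  px <- frame$pixels
  R <- nrow(px)
  C <- ncol(px)
  h <- kernel %/% 2L
  if (R < 1L || C < 1L) return(frame)
  ridx <- reflect_index(R, h)
  cidx <- reflect_index(C, h)
  pad <- px[ridx, cidx, drop = FALSE]
  need <- (kernel * kernel + 1L) %/% 2L  # rank of the median
  med <- matrix(NA_integer_, R, C)
  left <- matrix(TRUE, R, C)             # pixels whose median is still unknown
  count <- matrix(0L, R, C)
  for (v in 0:(frame$scale$n_colours - 1L)) {
    cnt <- matrix(0L, R, C)
    for (dr in 0:(kernel - 1L)) for (dc in 0:(kernel - 1L)) {
      cnt <- cnt + (pad[dr + seq_len(R), dc + seq_len(C), drop = FALSE] <= v)
    }
    hit <- left & (cnt >= need)
    med[hit] <- v
    left[hit] <- FALSE
    if (!any(left)) break
  }
  frame$pixels <- med
  frame
}

# symmetric reflection indices for padding: (c b a | a b c ... | c b a)
reflect_index <- function(n, h) {
  idx <- (1L - h):(n + h)
  m <- 2L * n
  j <- ((idx - 1L) %% m + m) %% m
  j <- ifelse(j >= n, m - 1L - j, j)
  j + 1L
}

#' Vertical noise-column suppression
#'
#' A vertical interference column shows up as a peak in the per-ping echo
#' sum. Columns whose summed colour index exceeds the robust centre
#' (median) by `z_threshold` robust standard deviations (MAD-based) are
#' cleared; their georeference is retained.
#'
#' The scale is the *wider* of the MAD and the ordinary standard deviation:
#' echogram ping sums are zero-inflated (most pings are empty water), so the
#' MAD alone tracks the speckle floor and would flag legitimate dense school
#' pings, while on speckle-free frames it collapses to zero. Requiring a
#' column to be extreme under both scales keeps full-height interference
#' columns far above threshold and school pings well below it in either
#' regime. A frame of identical columns removes nothing.
#'
#' @param frame An [echogram_frame()] (apply after seabed masking).
#' @param z_threshold Robust z-score threshold (default 5).
#' @return List with the cleaned `frame` and the integer vector `removed`
#'   of cleared column indices.
#' @export
remove_noise_columns <- function(frame, z_threshold = 5) {
  px <- frame$pixels
  if (ncol(px) < 3L) stop("need at least 3 columns", call. = FALSE)
  s <- colSums(px)
  med <- stats::median(s)
  scale <- max(stats::mad(s), stats::sd(s), na.rm = TRUE)
  z <- if (!is.finite(scale) || scale == 0) rep(0, length(s)) else (s - med) / scale
  removed <- which(z > z_threshold)
  if (length(removed)) px[, removed] <- 0L
  frame$pixels <- px
  list(frame = frame, removed = removed)
}
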