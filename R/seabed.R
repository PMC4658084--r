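#' Upper-edge detection
#'
#' Marks pixel (r, c) when its colour index reaches the edge threshold while
#' the pixel directly above it does not — the upper edge of every echo
#' object, including the seabed. Row 1 can only be marked if it itself
#' reaches the threshold (there is no pixel above it).
#'
#' @param frame An [echogram_frame()].
#' @param threshold Minimum colour index counting as "object" (default 1,
#'   i.e. any echo).
#' @return Integer 0/1 matrix of the frame's dimensions.
#' @export
detect_upper_edges <- function(frame, threshold = 1L) {
  px <- frame$pixels
  obj <- px >= threshold
  above <- rbind(FALSE, obj[-nrow(obj), , drop = FALSE])
  out <- matrix(0L, nrow(px), ncol(px))
  out[obj & !above] <- 1L
  out
}

#' Seabed tracing by dynamic programming
#'
#' Finds the left-to-right path `d(1..N)` (one row per column) that maximises
#' edge occupancy minus an anti-vertical penalty,
#' `sum_i edge(d(i), i) - lambda * sum_i |d(i+1) - d(i)|`, subject to the
#' per-column transition bound `|d(i+1) - d(i)| <= P`. The recursion is the
#' Viterbi forward pass over all (row, column) states. Ties in score are
#' broken by preferring deeper paths (larger total row index), then
#' straighter ones (smaller total vertical transition) — so a flat seabed
#' under a fish school is not traced through the school.
#'
#' @param edges 0/1 edge matrix (from [detect_upper_edges()]).
#' @param lambda Anti-vertical penalty per pixel of transition (>= 0).
#' @param P Maximum vertical transition per column step (>= 0 pixels).
#' @return An object of class `seabed_path`: `row_per_col` (integer vector),
#'   `score`, `lambda`, `P`, and `no_evidence` (`TRUE` when the optimal path
#'   crosses no edge pixel at all, e.g. on an empty edge map — the path then
#'   sits on the deepest row).
#' @export
trace_seabed <- function(edges, lambda = 0.5, P = 2L) {
  stopifnot(lambda >= 0, P >= 0)
  edges <- as.matrix(edges)
  R <- nrow(edges)
  N <- ncol(edges)
  if (R < 1L || N < 1L) stop("empty edge map", call. = FALSE)
  P <- as.integer(P)

  # state value is the lexicographic tuple (score, sum of rows, -sum |jumps|)
  S <- as.numeric(edges[, 1])
  D <- as.numeric(seq_len(R))
  J <- numeric(R)
  ptr <- matrix(0L, R, N)
  if (N > 1L) {
    for (i in 2:N) {
      bS <- rep(-Inf, R); bD <- rep(-Inf, R); bJ <- rep(-Inf, R)
      bp <- integer(R)
      for (delta in -P:P) {
        if (abs(delta) >= R) next
        # previous row r' = r - delta
        if (delta >= 0) {
          idx <- c(rep(NA_integer_, delta), seq_len(R - delta))
        } else {
          idx <- c(seq_len(R)[-seq_len(-delta)], rep(NA_integer_, -delta))
        }
        ok <- !is.na(idx)
        cS <- rep(-Inf, R); cD <- rep(-Inf, R); cJ <- rep(-Inf, R)
        cS[ok] <- S[idx[ok]] - lambda * abs(delta)
        cD[ok] <- D[idx[ok]]
        cJ[ok] <- J[idx[ok]] - abs(delta)
        better <- (cS > bS) | (cS == bS & cD > bD) | (cS == bS & cD == bD & cJ > bJ)
        better[!ok] <- FALSE
        bS[better] <- cS[better]
        bD[better] <- cD[better]
        bJ[better] <- cJ[better]
        bp[better] <- seq_len(R)[better] - delta
      }
      S <- bS + edges[, i]
      D <- bD + seq_len(R)
      J <- bJ
      ptr[, i] <- bp
    }
  }
  best <- which(S == max(S))
  best <- best[order(D[best], J[best], decreasing = TRUE)][1]
  path <- integer(N)
  path[N] <- best
  if (N > 1L) for (i in N:2) path[i - 1L] <- ptr[path[i], i]
  occupancy <- sum(edges[cbind(path, seq_len(N))])
  structure(list(row_per_col = path, score = S[best],
                 lambda = lambda, P = P,
                 no_evidence = occupancy == 0),
            class = "seabed_path")
}

#' @export
print.seabed_path <- function(x, ...) {
  cat(sprintf("<seabed_path> %d columns, score %.3f (lambda %.2f, P %d)%s\n",
              length(x$row_per_col), x$score, x$lambda, x$P,
              if (x$no_evidence) " [no seabed evidence]" else ""))
  invisible(x)
}

#' Clear all echo at or below the traced seabed
#'
#' @param frame An [echogram_frame()].
#' @param path A [trace_seabed()] result conforming to the frame.
#' @param margin_m Optional safety margin (m) subtracted from the seabed
#'   depth before clearing (converted to whole rows, rounded).
#' @return The frame with every pixel at row `>= d(i) - margin_rows` set to
#'   colour 0.
#' @export
mask_below_seabed <- function(frame, path, margin_m = 0) {
  stopifnot(inherits(path, "seabed_path"),
            length(path$row_per_col) == ncol(frame$pixels))
  margin_rows <- round(margin_m / frame$metres_per_row)
  px <- frame$pixels
  cut <- pmax(1L, path$row_per_col - as.integer(margin_rows))
  rows <- row(px)
  px[rows >= matrix(cut, nrow(px), ncol(px), byrow = TRUE)] <- 0L
  frame$pixels <- px
  frame
}

#' Seabed depth (m) under each column
#'
#' Depth of the traced seabed row centre per column.
#'
#' @param frame An [echogram_frame()].
#' @param path A [trace_seabed()] result.
#' @return Numeric vector, one depth per column.
#' @export
seabed_depths <- function(frame, path) {
  frame$depth_min_m + (path$row_per_col - 0.5) * frame$metres_per_row
}
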