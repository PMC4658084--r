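# Independent oracles: deliberately naive implementations used to freeze or
# cross-check expected values. They must not share code with the package.

# exhaustive seabed-path search with the same lexicographic tie-break
# (max score, then max total depth, then min total vertical transition)
brute_seabed <- function(edges, lambda, P) {
  R <- nrow(edges)
  N <- ncol(edges)
  if (N == 1L) {
    s <- edges[, 1]
    best <- which(s == max(s))
    return(max(best))
  }
  trans <- as.matrix(expand.grid(rep(list(-P:P), N - 1L)))
  cs <- if (N == 2L) matrix(trans, ncol = 1L) else t(apply(trans, 1, cumsum))
  best <- NULL
  key <- c(-Inf, -Inf, Inf)
  for (r0 in seq_len(R)) {
    paths <- cbind(r0, r0 + cs)
    ok <- rowSums(paths < 1L | paths > R) == 0L
    if (!any(ok)) next
    paths <- paths[ok, , drop = FALSE]
    sc <- numeric(nrow(paths))
    for (i in seq_len(N)) sc <- sc + edges[cbind(paths[, i], i)]
    jumps <- rowSums(abs(paths[, -1, drop = FALSE] -
                           paths[, -N, drop = FALSE]))
    score <- sc - lambda * jumps
    depth <- rowSums(paths)
    ord <- order(-score, -depth, jumps)[1]
    cand_key <- c(score[ord], depth[ord], jumps[ord])
    if (cand_key[1] > key[1] ||
        (cand_key[1] == key[1] && cand_key[2] > key[2]) ||
        (cand_key[1] == key[1] && cand_key[2] == key[2] && cand_key[3] < key[3])) {
      key <- cand_key
      best <- paths[ord, ]
    }
  }
  list(path = as.integer(best), score = key[1])
}

# recursive flood fill labelling
flood_fill_labels <- function(mask, connectivity = 8L) {
  R <- nrow(mask)
  C <- ncol(mask)
  lbl <- matrix(0L, R, C)
  if (connectivity == 4L) {
    nb <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    nb <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
    nb <- nb[!(nb[, 1] == 0 & nb[, 2] == 0), ]
  }
  fill <- function(r, c, id) {
    if (r < 1 || r > R || c < 1 || c > C) return()
    if (!mask[r, c] || lbl[r, c] != 0L) return()
    lbl[r, c] <<- id
    for (k in seq_len(nrow(nb))) fill(r + nb[k, 1], c + nb[k, 2], id)
  }
  id <- 0L
  for (c in seq_len(C)) for (r in seq_len(R)) {
    if (mask[r, c] && lbl[r, c] == 0L) {
      id <- id + 1L
      fill(r, c, id)
    }
  }
  lbl
}

# exact two-sided signed-rank p by enumerating all 2^n sign assignments
enum_signrank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  mu <- n * (n + 1) / 4
  p <- if (V > mu) 2 * mean(Vs >= V) else 2 * mean(Vs <= V)
  min(1, p)
}

# random sparse edge map for property tests
random_edge_map <- function(R, C, density = 0.3) {
  matrix(as.integer(stats::runif(R * C) < density), R, C)
}
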