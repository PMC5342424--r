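# Independent brute-force oracles used across the suite.

# rasterize a closed disk on an nr x nc grid (pixel centers at integers)
rast_disk <- function(nr, nc, cr, cc, r) {
  rows <- matrix(rep(seq_len(nr), nc), nr)
  cols <- matrix(rep(seq_len(nc), each = nr), nr)
  (rows - cr)^2 + (cols - cc)^2 <= r^2
}

# brute-force Euclidean distance of each TRUE pixel to the nearest FALSE
# pixel (O(n^2) pairwise search)
bf_distance_to_complement <- function(bw) {
  idx <- which(bw, arr.ind = TRUE)
  comp <- which(!bw, arr.ind = TRUE)
  vapply(seq_len(nrow(idx)), function(i) {
    sqrt(min((comp[, 1] - idx[i, 1])^2 + (comp[, 2] - idx[i, 2])^2))
  }, numeric(1))
}

# full-enumeration two-sided Wilcoxon rank-sum p-value (no ties assumed)
enumeration_wilcoxon_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  m <- n1 * n2 / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - m) >= abs(u_obs - m))
}

# explicit pairwise-mean UPGMA recursion on a dissimilarity matrix;
# returns the sorted merge heights and the final flat memberships traced
# through the merges
bf_upgma_heights <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  act <- seq_len(n)
  d <- D
  heights <- numeric(0)
  while (length(act) > 1L) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(act)) for (j in seq_len(i - 1L)) {
      a <- act[i]; b <- act[j]
      # mean of all cross-pair dissimilarities
      h <- mean(D[clusters[[a]], clusters[[b]]])
      if (h < bh - 1e-12) { bh <- h; best <- c(a, b) }
    }
    heights <- c(heights, bh)
    a <- best[1]; b <- best[2]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    act <- setdiff(act, b)
  }
  sort(heights)
}

# 8-connected labeling oracle via igraph components
igraph_label_count <- function(bw) {
  idx <- which(bw, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  key <- paste(idx[, 1], idx[, 2])
  edges <- c()
  for (i in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- match(paste(idx[i, 1] + dr, idx[i, 2] + dc), key)
      if (!is.na(j) && j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$no
}

# tiny deterministic random instance for solver tests
random_instance <- function(seed, n = 20, d = 8, c_ = 5, T_ = 3) {
  set.seed(seed)
  X <- array(rnorm(n * d * T_), c(n, d, T_))
  Y <- matrix(rnorm(n * c_), n, c_)
  list(X = X, Y = Y)
}

temporal_deviation <- function(W) {
  Wbar <- apply(W, c(1, 2), mean)
  max(vapply(seq_len(dim(W)[3]),
             function(t) max(abs(W[, , t] - Wbar)), numeric(1)))
}

numerical_rank <- function(W, tol = 1e-6) {
  sv <- svd(matrix(W, dim(W)[1]))$d
  sum(sv > tol * max(sv))
}
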