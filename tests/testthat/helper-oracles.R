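# Independent oracles: brute-force / enumeration implementations kept
# deliberately separate from the package's algorithms.

make_epoch <- function(X, fs = 500, index = 1L) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  structure(list(data = as.matrix(X), fs = fs, index = index,
                 band = NA_character_, subject_id = "S", group = "Control",
                 state = "EO"),
            class = "eeg_epoch")
}

random_digraph <- function(n, p = 0.4) {
  A <- matrix(as.integer(stats::runif(n * n) < p), n)
  diag(A) <- 0L
  A
}

# Floyd-Warshall shortest paths (vs the package's BFS)
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A != 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracle_ge <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) s <- s + 1 / D[i, j]
  s / (n * (n - 1))
}

oracle_le <- function(A) {
  n <- nrow(A)
  vals <- numeric(n)
  for (i in seq_len(n)) {
    nb <- setdiff(which(A[i, ] != 0 | A[, i] != 0), i)
    vals[i] <- if (length(nb) >= 2) oracle_ge(A[nb, nb, drop = FALSE]) else 0
  }
  mean(vals)
}

# explicit triple-loop directed triangle census
oracle_triangles <- function(A) {
  n <- nrow(A)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      s <- s + (A[i, j] + A[j, i]) * (A[i, h] + A[h, i]) * (A[j, h] + A[h, j])
    }
    t_i[i] <- s / 2
  }
  t_i
}

oracle_cc <- function(A) {
  t_i <- oracle_triangles(A)
  kout <- rowSums(A); kin <- colSums(A)
  ktot <- kout + kin
  krec <- sapply(seq_len(nrow(A)), function(i) sum(A[i, ] * A[, i]))
  den <- ktot * (ktot - 1) - 2 * krec
  mean(ifelse(den > 0, t_i / pmax(den, 1), 0))
}

oracle_transitivity <- function(A) {
  t_i <- oracle_triangles(A)
  kout <- rowSums(A); kin <- colSums(A)
  ktot <- kout + kin
  krec <- sapply(seq_len(nrow(A)), function(i) sum(A[i, ] * A[, i]))
  den <- sum(ktot * (ktot - 1) - 2 * krec)
  if (den <= 0) 0 else sum(t_i) / den
}

# assortativity by the explicit Pearson formula over the edge list
oracle_assort <- function(A) {
  e <- which(A != 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(NA_real_)
  x <- rowSums(A)[e[, 1]]
  y <- colSums(A)[e[, 2]]
  sx <- sqrt(mean(x^2) - mean(x)^2)
  sy <- sqrt(mean(y^2) - mean(y)^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  (mean(x * y) - mean(x) * mean(y)) / (sx * sy)
}

oracle_modularity_value <- function(A, memb) {
  m <- sum(A)
  kout <- rowSums(A); kin <- colSums(A)
  s <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) s <- s + A[i, j] - kout[i] * kin[j] / m
  s / m
}

# exhaustive max-modularity by recursive label assignment (first label fixed)
oracle_modularity_max <- function(A) {
  n <- nrow(A)
  best <- -Inf
  memb <- integer(n)
  rec <- function(i, used) {
    if (i > n) {
      q <- oracle_modularity_value(A, memb)
      if (q > best) best <<- q
      return(invisible())
    }
    for (l in seq_len(used + 1L)) {
      memb[i] <<- l
      rec(i + 1L, max(used, l))
    }
  }
  rec(1L, 0L)
  best
}

# hand step-up BH rule
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# stationary autocovariance of a bivariate MVAR(1) by fixed-point iteration
# on Gamma(0) = A Gamma(0) A' + Sigma, Gamma(1) = A Gamma(0)
oracle_mvar1_autocov <- function(A1, Sigma, iters = 500) {
  G0 <- Sigma
  for (i in seq_len(iters)) G0 <- A1 %*% G0 %*% t(A1) + Sigma
  list(G0 = G0, G1 = A1 %*% G0)
}
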