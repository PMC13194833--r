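# Two-tier binarization: a maximum-weight spanning tree guarantees (weak)
# connectivity, then the strongest remaining edges are added up to a fixed
# density identical across subjects. Ties are broken lexicographically on
# (source, sink) so results are deterministic.

round_half_up <- function(x) floor(x + 0.5)

binary_network <- function(A, directed, density) {
  diag(A) <- 0
  kout <- rowSums(A); kin <- colSums(A)
  structure(
    list(A = A, directed = directed, density = density,
         m = if (directed) sum(A) else sum(A) / 2,
         k_out = kout, k_in = kin, k_tot = kout + kin,
         k_recip = rowSums(A * t(A))),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d %s edges (density %.3f)\n",
              nrow(x$A), x$m, if (x$directed) "directed" else "undirected",
              x$density))
  invisible(x)
}

# Kruskal maximum spanning tree on a symmetric weight matrix; returns the
# (i, j) pairs (i < j) of tree edges. Deterministic: edges sorted by
# (-weight, i, j).
max_spanning_tree <- function(Wu) {
  n <- nrow(Wu)
  ii <- row(Wu)[upper.tri(Wu)]; jj <- col(Wu)[upper.tri(Wu)]
  ww <- Wu[upper.tri(Wu)]
  ord <- order(-ww, ii, jj)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  tree <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (e in ord) {
    ri <- find(ii[e]); rj <- find(jj[e])
    if (ri != rj) {
      parent[ri] <- rj
      k <- k + 1L
      tree[k, ] <- c(ii[e], jj[e])
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) stop("weight matrix does not admit a spanning tree")
  tree
}

edge_weight_matrix <- function(W) {
  if (inherits(W, "conn_matrix")) {
    # DTF stores W[i, j] = flow j -> i; networks use A[i, j] = edge i -> j
    if (identical(W$measure, "DTF")) t(W$W) else W$W
  } else as.matrix(W)
}

#' MST-seeded fixed-density binarization of a directed weight matrix
#'
#' The weighted matrix is symmetrized by `max(w_ij, w_ji)` and inverted so a
#' minimum spanning tree identifies the tree of strongest connections. For
#' each tree link the directed edge attaining the maximum is seeded
#' (lexicographic tie-break); the strongest remaining directed edges are
#' then added until exactly `round(density * n * (n-1))` edges (round half
#' up) are present, and the result is binarized. The output is weakly
#' connected by construction.
#'
#' @param W a directed `conn_matrix` (DTF) or a non-negative weight matrix
#'   with `A[i, j]` = strength of edge i -> j.
#' @param density target edge density as a fraction of the `n(n-1)` possible
#'   directed edges (default 0.15).
#' @return A `binary_network` (directed) with degree bookkeeping.
#' @export
mst_density_threshold_directed <- function(W, density = 0.15) {
  Wd <- edge_weight_matrix(W)
  n <- nrow(Wd)
  if (any(Wd < 0)) stop("weights must be non-negative")
  diag(Wd) <- 0
  m_target <- round_half_up(density * n * (n - 1L))
  if (m_target < n - 1L)
    stop(sprintf("density %.3f gives %d edges, below the %d needed for a spanning tree",
                 density, m_target, n - 1L))
  Wu <- pmax(Wd, t(Wd))
  tree <- max_spanning_tree(Wu)
  A <- matrix(0L, n, n)
  for (t in seq_len(nrow(tree))) {
    i <- tree[t, 1L]; j <- tree[t, 2L]
    if (Wd[i, j] >= Wd[j, i]) A[i, j] <- 1L else A[j, i] <- 1L
  }
  # remaining directed edges in descending weight, lexicographic tie-break
  cand <- which(diag(n) == 0 & A == 0L)
  ord <- cand[order(-Wd[cand], row(Wd)[cand], col(Wd)[cand])]
  need <- m_target - sum(A)
  if (need > 0) A[ord[seq_len(need)]] <- 1L
  rownames(A) <- colnames(A) <- rownames(Wd)
  binary_network(A, directed = TRUE, density = density)
}

#' MST-seeded fixed-density binarization of a symmetric weight matrix
#'
#' For undirected estimators (iCOH, wPLI): a maximum-weight spanning tree on
#' the symmetrized weights seeds the edge set, then the strongest remaining
#' undirected edges are added until `round(density * n * (n-1) / 2)` edges
#' (round half up) are present. The output is connected.
#'
#' @param W a symmetric `conn_matrix` or weight matrix.
#' @param density target density as a fraction of the `n(n-1)/2` possible
#'   undirected edges (default 0.15).
#' @return A `binary_network` (undirected; adjacency stored symmetric).
#' @export
proportional_threshold_symmetric <- function(W, density = 0.15) {
  Wm <- edge_weight_matrix(W)
  n <- nrow(Wm)
  if (any(Wm < 0)) stop("weights must be non-negative")
  Wu <- pmax(Wm, t(Wm))
  diag(Wu) <- 0
  m_target <- round_half_up(density * n * (n - 1L) / 2)
  if (m_target < n - 1L)
    stop(sprintf("density %.3f gives %d edges, below the %d needed for a spanning tree",
                 density, m_target, n - 1L))
  tree <- max_spanning_tree(Wu)
  A <- matrix(0L, n, n)
  A[tree] <- 1L
  A <- A | t(A)
  ut <- which(upper.tri(Wu) & !A)
  ord <- ut[order(-Wu[ut], row(Wu)[ut], col(Wu)[ut])]
  need <- m_target - (n - 1L)
  if (need > 0) {
    add <- ord[seq_len(need)]
    A[add] <- TRUE
    A <- A | t(A)
  }
  A <- A * 1L
  rownames(A) <- colnames(A) <- rownames(Wm)
  binary_network(A, directed = FALSE, density = density)
}

#' Simple proportional threshold at a fraction of the maximum weight
#'
#' Alternative binarization retaining all edges whose weight is at least
#' `fraction` of the maximum off-diagonal weight. Provided as an optional
#' legacy rule; it controls neither density nor connectivity, so the
#' MST-seeded functions are the package default.
#'
#' @param W weight matrix or `conn_matrix`.
#' @param fraction fraction of the maximum weight (default 0.6).
#' @param directed treat the matrix as directed (default follows the input).
#' @return A `binary_network` (connectivity not guaranteed).
#' @export
threshold_fraction_of_max <- function(W, fraction = 0.6, directed = NULL) {
  if (is.null(directed))
    directed <- if (inherits(W, "conn_matrix")) W$directed else TRUE
  Wm <- edge_weight_matrix(W)
  diag(Wm) <- 0
  A <- (Wm >= fraction * max(Wm)) * 1L
  diag(A) <- 0L
  if (!directed) A <- ((A | t(A))) * 1L
  n <- nrow(A)
  dens <- if (directed) sum(A) / (n * (n - 1L)) else sum(A) / (n * (n - 1L))
  binary_network(A, directed = directed, density = dens)
}
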