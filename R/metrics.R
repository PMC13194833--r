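# Directed graph indices on binary networks, following the directed
# conventions of the binary brain-network literature (Fagiolo directed
# clustering/transitivity; efficiency from directed BFS distances; directed
# degree-correlation assortativity; directed Newman modularity).

adj_of <- function(A) {
  if (inherits(A, "binary_network")) A <- A$A
  A <- as.matrix(A) * 1
  diag(A) <- 0
  A
}

# BFS all-pairs shortest directed path lengths; Inf where unreachable
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  nbr <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(nbr[frontier]))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  diag(D) <- 0
  D
}

#' Global efficiency of a directed binary network
#'
#' Mean inverse shortest directed path length over ordered node pairs;
#' unreachable pairs contribute 0.
#'
#' @param A a `binary_network` or binary adjacency matrix (`A[i, j] = 1` for
#'   edge i -> j).
#' @return Global efficiency in `[0, 1]`.
#' @export
global_efficiency <- function(A) {
  A <- adj_of(A)
  n <- nrow(A)
  if (n < 2L) stop("need at least 2 nodes")
  D <- bfs_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1L))
}

#' Local efficiency of a directed binary network
#'
#' Mean over nodes of the global efficiency of the subgraph induced on the
#' node's neighbors (union of in- and out-neighbors, excluding the node,
#' directionality preserved). Nodes with fewer than 2 neighbors contribute 0.
#'
#' @inheritParams global_efficiency
#' @return Local efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(A) {
  A <- adj_of(A)
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] != 0 | A[, i] != 0)
    nb <- setdiff(nb, i)
    if (length(nb) < 2L) return(0)
    global_efficiency(A[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

directed_triangle_counts <- function(A) {
  As <- A + t(A)
  diag(As %*% As %*% As) / 2
}

clustering_denominator <- function(A) {
  kout <- rowSums(A); kin <- colSums(A)
  ktot <- kout + kin
  krecip <- rowSums(A * t(A))
  ktot * (ktot - 1) - 2 * krecip
}

#' Directed clustering coefficient
#'
#' Per node, the directed triangle count around the node divided by
#' `k_tot (k_tot - 1) - 2 k_recip`, the number of possible directed
#' triangles given the node's total degree and reciprocal connections;
#' nodes with zero denominator contribute 0. Returns the mean over nodes.
#'
#' @inheritParams global_efficiency
#' @return Clustering coefficient in `[0, 1]`.
#' @export
clustering_coef <- function(A) {
  A <- adj_of(A)
  t_i <- directed_triangle_counts(A)
  den <- clustering_denominator(A)
  mean(ifelse(den > 0, t_i / pmax(den, 1), 0))
}

#' Directed transitivity
#'
#' Ratio of the total directed triangle count to the total number of
#' connected directed triplets, `sum t_i / sum [k_tot (k_tot - 1) -
#' 2 k_recip]`; 0 when the denominator vanishes.
#'
#' @inheritParams global_efficiency
#' @return Transitivity in `[0, 1]`.
#' @export
transitivity_dir <- function(A) {
  A <- adj_of(A)
  den <- sum(clustering_denominator(A))
  if (den <= 0) return(0)
  sum(directed_triangle_counts(A)) / den
}

#' Directed (out-in) degree assortativity
#'
#' Pearson correlation, over directed edges i -> j, between the out-degree
#' of the source i and the in-degree of the target j.
#'
#' @inheritParams global_efficiency
#' @return Correlation in `[-1, 1]`, or `NA` (flagged via the
#'   `"undefined"` attribute) when either degree sequence is constant over
#'   the edge list.
#' @export
assortativity_outin <- function(A) {
  A <- adj_of(A)
  e <- which(A != 0, arr.ind = TRUE)
  if (nrow(e) < 2L) stop("need at least 2 edges")
  x <- rowSums(A)[e[, 1L]]
  y <- colSums(A)[e[, 2L]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    r <- NA_real_
    attr(r, "undefined") <- "zero degree variance over edges"
    return(r)
  }
  stats::cor(x, y)
}

# ---- modularity ------------------------------------------------------------

modularity_value <- function(A, membership) {
  m <- sum(A)
  if (m == 0) stop("modularity undefined on an empty graph")
  B <- A - outer(rowSums(A), colSums(A)) / m
  same <- outer(membership, membership, `==`)
  sum(B[same]) / m
}

# enumerate all set partitions of n items as restricted growth strings
partitions_rgs <- function(n) {
  out <- vector("list", 0L)
  a <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a[seq_len(n)]
      return(invisible())
    }
    for (l in seq_len(maxl + 1L)) {
      a[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  out
}

modularity_exact <- function(A) {
  n <- nrow(A)
  best_q <- -Inf; best_p <- NULL
  for (p in partitions_rgs(n)) {
    q <- modularity_value(A, p)
    if (q > best_q + 1e-15) { best_q <- q; best_p <- p }
  }
  list(Q = best_q, membership = best_p)
}

modularity_greedy <- function(A, seed = 1L, restarts = 20L) {
  n <- nrow(A)
  m <- sum(A)
  B <- A - outer(rowSums(A), colSums(A)) / m
  Bs <- B + t(B)                        # symmetric gain matrix
  best_q <- -Inf; best_p <- NULL
  set.seed(seed)
  for (r in seq_len(restarts)) {
    # agglomeration on the community-aggregated gain matrix; merging c and d
    # raises Q by M[c, d] / m
    M <- Bs
    groups <- as.list(seq_len(n))
    alive <- rep(TRUE, n)
    repeat {
      idx <- which(alive)
      if (length(idx) == 1L) break
      Msub <- M[idx, idx, drop = FALSE]
      diag(Msub) <- -Inf
      g <- max(Msub)
      if (g <= 1e-12) break
      hits <- which(Msub == g, arr.ind = TRUE)
      pick <- hits[sample(nrow(hits), 1L), ]
      a <- idx[min(pick)]; b <- idx[max(pick)]
      groups[[a]] <- c(groups[[a]], groups[[b]])
      M[a, ] <- M[a, ] + M[b, ]
      M[, a] <- M[, a] + M[, b]
      alive[b] <- FALSE
    }
    memb <- integer(n)
    for (ci in seq_along(which(alive)))
      memb[groups[[which(alive)[ci]]]] <- ci
    # local node moves: Delta(Q) * m for moving i to community d is
    # sum_{j in d} Bs[i, j] - sum_{j in own, j != i} Bs[i, j]
    repeat {
      k <- max(memb)
      S <- Bs %*% outer(memb, seq_len(k + 1L), `==`)  # node x community sums
      own <- S[cbind(seq_len(n), memb)] - diag(Bs)
      gain <- sweep(S, 1L, own)
      gain[cbind(seq_len(n), memb)] <- 0
      if (max(gain) <= 1e-12) break
      mv <- which(gain == max(gain), arr.ind = TRUE)[1L, ]
      memb[mv[1L]] <- mv[2L]
      memb <- match(memb, sort(unique(memb)))
    }
    q <- modularity_value(A, memb)
    if (q > best_q) { best_q <- q; best_p <- memb }
  }
  list(Q = best_q, membership = match(best_p, unique(best_p)))
}

#' Directed modularity and its optimal community partition
#'
#' Maximizes `Q = (1/m) sum_ij (A_ij - k_i^out k_j^in / m)
#' delta(c_i, c_j)` over community partitions. For networks with up to
#' `exact_n` nodes the search is exact (enumeration over all set
#' partitions); above that, seeded greedy agglomeration with random
#' restarts and local node moves is used.
#'
#' @inheritParams global_efficiency
#' @param seed seed for the greedy search's random tie-breaks and restarts.
#' @param restarts number of greedy restarts (default 20).
#' @param exact_n exact-enumeration size limit (default 8).
#' @return List with `Q` and the integer community `membership`.
#' @export
modularity_dir <- function(A, seed = 1L, restarts = 20L, exact_n = 8L) {
  A <- adj_of(A)
  if (sum(A) == 0) stop("modularity undefined on an empty graph")
  if (nrow(A) <= exact_n) modularity_exact(A) else
    modularity_greedy(A, seed = seed, restarts = restarts)
}

#' All six graph indices of a binary network
#'
#' Convenience wrapper computing modularity (Q), global efficiency (GE),
#' local efficiency (LE), clustering coefficient (CC), transitivity (T) and
#' out-in assortativity (R).
#'
#' @inheritParams modularity_dir
#' @return Named numeric vector `c(Q, GE, LE, CC, T, R)`; `R` is `NA` when
#'   undefined.
#' @export
graph_indices <- function(A, seed = 1L) {
  A <- adj_of(A)
  c(Q = modularity_dir(A, seed = seed)$Q,
    GE = global_efficiency(A),
    LE = local_efficiency(A),
    CC = clustering_coef(A),
    T = transitivity_dir(A),
    R = suppressWarnings(as.numeric(assortativity_outin(A))))
}
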