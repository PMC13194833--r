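# The six directed graph indices against hand values and enumeration oracles.

assortativity_outin_or_na <- function(A) {
  if (sum(A != 0) < 2) NA_real_ else assortativity_outin(A)
}

test_that("hand-checkable graphs give the known index values", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4), 1)
  expect_equal(clustering_coef(K4), 1)
  expect_equal(transitivity_dir(K4), 1)
  expect_true(is.na(assortativity_outin(K4)))   # zero degree variance
  expect_equal(modularity_dir(K4)$Q, 0, tolerance = 1e-12)

  path <- matrix(0, 3, 3); path[1, 2] <- 1; path[2, 3] <- 1
  expect_equal(global_efficiency(path), (1 + 1 + 0.5) / 6)

  empty <- matrix(0, 4, 4)
  expect_equal(global_efficiency(empty), 0)
  expect_error(modularity_dir(empty), "empty graph")

  # bidirectional star: hub subgraph empty, leaves have one neighbor
  star <- matrix(0, 5, 5); star[1, 2:5] <- 1; star[2:5, 1] <- 1
  expect_equal(local_efficiency(star), 0)
  expect_equal(transitivity_dir(star), 0)
  expect_equal(assortativity_outin(star), -1)

  cyc <- matrix(0, 3, 3); cyc[1, 2] <- 1; cyc[2, 3] <- 1; cyc[3, 1] <- 1
  expect_equal(clustering_coef(cyc), oracle_cc(cyc), tolerance = 1e-14)

  bip <- matrix(0, 4, 4); bip[1, 3] <- 1; bip[1, 4] <- 1; bip[2, 3] <- 1
  expect_equal(clustering_coef(bip), 0)   # triangle-free
})

test_that("two disjoint 3-cliques have modularity 0.5 at the 2-community split", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  res <- modularity_dir(A)
  expect_equal(res$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$membership)), 2)
  expect_true(all(res$membership[1:3] == res$membership[1]))
  # direct evaluation of the quality at the known optimal partition
  expect_equal(oracle_modularity_value(A, c(1, 1, 1, 2, 2, 2)), 0.5)
})

test_that("all indices agree with enumeration oracles on random small digraphs", {
  set.seed(1)
  for (rep in 1:60) {
    n <- sample(3:5, 1)
    A <- random_digraph(n, runif(1, 0.25, 0.7))
    expect_equal(global_efficiency(A), oracle_ge(A), tolerance = 1e-12)
    expect_equal(local_efficiency(A), oracle_le(A), tolerance = 1e-12)
    expect_equal(clustering_coef(A), oracle_cc(A), tolerance = 1e-12)
    expect_equal(transitivity_dir(A), oracle_transitivity(A), tolerance = 1e-12)
    r <- assortativity_outin_or_na(A)
    ro <- oracle_assort(A)
    if (is.na(ro)) expect_true(is.na(r)) else
      expect_equal(as.numeric(r), ro, tolerance = 1e-12)
    if (sum(A) > 0)
      expect_equal(modularity_dir(A)$Q, oracle_modularity_max(A),
                   tolerance = 1e-12)
  }
})

test_that("greedy modularity search matches the exact answer above the exact-n cutoff", {
  set.seed(2)
  for (rep in 1:20) {
    A <- random_digraph(6, 0.35)
    if (sum(A) == 0) next
    g <- modularity_dir(A, exact_n = 0)     # force the greedy path
    e <- modularity_dir(A, exact_n = 8)     # exact enumeration
    expect_equal(g$Q, e$Q, tolerance = 1e-10)
  }
})

test_that("directed CC and T reduce to the undirected values on symmetric graphs", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    A <- random_digraph(n, 0.5)
    A <- ((A | t(A))) * 1
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    t_ig <- igraph::transitivity(g, type = "global")
    if (!is.nan(t_ig))
      expect_equal(transitivity_dir(A), t_ig, tolerance = 1e-12)
    cc_ig <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
    expect_equal(clustering_coef(A), mean(cc_ig), tolerance = 1e-12)
  }
})

test_that("indices are invariant under node relabeling", {
  set.seed(4)
  A <- random_digraph(7, 0.4)
  perm <- sample(7)
  Ap <- A[perm, perm]
  expect_equal(global_efficiency(A), global_efficiency(Ap), tolerance = 1e-12)
  expect_equal(local_efficiency(A), local_efficiency(Ap), tolerance = 1e-12)
  expect_equal(clustering_coef(A), clustering_coef(Ap), tolerance = 1e-12)
  expect_equal(transitivity_dir(A), transitivity_dir(Ap), tolerance = 1e-12)
  expect_equal(modularity_dir(A, exact_n = 7)$Q,
               modularity_dir(Ap, exact_n = 7)$Q, tolerance = 1e-12)
})

test_that("deleting edges from a complete digraph never increases global efficiency", {
  set.seed(5)
  for (rep in 1:20) {
    A <- matrix(1, 6, 6); diag(A) <- 0
    ge <- global_efficiency(A)
    edges <- sample(which(A == 1))
    for (e in edges[1:15]) {
      A[e] <- 0
      ge_new <- global_efficiency(A)
      expect_lte(ge_new, ge + 1e-12)
      ge <- ge_new
    }
  }
})
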