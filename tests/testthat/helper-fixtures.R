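# Shared fixtures and independent oracles.

# Small, fast simulation config for unit tests.
small_sim_config <- function(seed = 1L, n_acute = 150L, n_followup = 80L,
                             n_proteins = 40L, ...) {
  simulation_config(
    n_acute = n_acute, n_followup = n_followup, n_overlap = n_followup,
    n_proteins = n_proteins,
    active_acute = c("P001", "P002"),
    active_followup = c("P001", "P003"),
    active_shared = "P001",
    effect_shapes = c(P001 = "linear", P002 = "log", P003 = "reciprocal"),
    seed = seed, ...)
}

# Centered orthonormal design: columns orthogonal to each other and to the
# intercept, scaled so that x_j' x_j = n (unit sample variance up to n/(n-1)).
orthonormal_design <- function(n, p, seed = 1) {
  set.seed(seed)
  Z <- scale(matrix(rnorm(n * (p + 5)), n, p + 5), center = TRUE,
             scale = FALSE)
  X <- qr.Q(qr(cbind(1, Z)))[, 2:(p + 1), drop = FALSE] * sqrt(n)
  colnames(X) <- sprintf("F%02d", seq_len(p))
  X
}

# Wrap a plain feature matrix as a single-power basis (one protein per
# column) for direct lasso_path testing.
as_basis <- function(X) {
  list(X = X, map = data.frame(feature_id = colnames(X),
                               protein_id = colnames(X), power = 1,
                               stringsAsFactors = FALSE))
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail: draw all
# C(background, query) query subsets and count those with >= overlap hits.
# Only feasible for small instances.
hyper_oracle_enum <- function(overlap, query_n, set_n, background_n) {
  universe <- seq_len(background_n)
  inset <- seq_len(set_n)
  draws <- utils::combn(universe, query_n)
  hits <- colSums(matrix(draws %in% inset, nrow = query_n))
  mean(hits >= overlap)
}

# Closed-sum oracle (exact rational-style accumulation) for larger counts.
hyper_oracle_sum <- function(overlap, query_n, set_n, background_n) {
  j <- overlap:min(query_n, set_n)
  sum(exp(lchoose(set_n, j) + lchoose(background_n - set_n, query_n - j) -
            lchoose(background_n, query_n)))
}

# Independent straightforward MCL reimplementation (dense, no pruning),
# used as the oracle for mcl_cluster.
mcl_oracle <- function(adj, inflation = 2, iters = 200) {
  diag(adj) <- 1
  M <- sweep(adj, 2, colSums(adj), "/")
  for (i in seq_len(iters)) {
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
  }
  supp <- (M > 1e-6) | t(M > 1e-6)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected")
  igraph::components(g)$membership
}

# Toy graphs.
graph_two_triangles <- function() {
  build_graph(data.frame(a = c("A", "B", "C", "X", "Y", "Z"),
                         b = c("B", "C", "A", "Y", "Z", "X")))
}

graph_barbell <- function() {
  cl1 <- t(utils::combn(paste0("A", 1:5), 2))
  cl2 <- t(utils::combn(paste0("B", 1:5), 2))
  edges <- rbind(cl1, cl2, c("A1", "B1"))
  build_graph(data.frame(a = edges[, 1], b = edges[, 2]))
}

# 6-clique with a 3-node pendant path hanging off one clique vertex.
graph_clique_pendant <- function() {
  cl <- t(utils::combn(paste0("C", 1:6), 2))
  path <- cbind(c("C1", "p1", "p2"), c("p1", "p2", "p3"))
  build_graph(data.frame(a = c(cl[, 1], path[, 1]),
                         b = c(cl[, 2], path[, 2])))
}

# Planted 5-clique + 4-clique in sparse background noise, fixed seed.
graph_planted_cliques <- function(seed = 42, n_noise = 41, p_edge = 0.05) {
  set.seed(seed)
  five <- paste0("F", 1:5)
  four <- paste0("G", 1:4)
  noise <- sprintf("N%02d", seq_len(n_noise))
  nodes <- c(five, four, noise)
  pairs <- t(utils::combn(nodes, 2))
  in5 <- pairs[, 1] %in% five & pairs[, 2] %in% five
  in4 <- pairs[, 1] %in% four & pairs[, 2] %in% four
  noise_keep <- runif(nrow(pairs)) < p_edge & !in5 & !in4
  keep <- in5 | in4 | noise_keep
  build_graph(data.frame(a = pairs[keep, 1], b = pairs[keep, 2]))
}

expect_selection_sane <- function(sel) {
  expect_s3_class(sel, "protein_selection")
  expect_true(all(sel$lambda_ratio[sel$selected] >= 1))
  expect_true(all(is.na(sel$lambda_ratio[!sel$selected])))
}
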