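# Protein-protein interaction graphs: Markov clustering (MCL) and dense
# complex detection (MCODE), plus enrichment-based complex labelling.

#' Build an interaction graph from an edge table
#'
#' Deduplicates edges (keeping the maximum weight), drops self-loops and
#' malformed rows, and optionally restricts to physical interactions.
#'
#' @param edges Data frame whose first two columns are endpoints; optional
#'   `weight` (in (0, 1], default 1) and `physical` (logical, default TRUE)
#'   columns.
#' @param restrict_physical Drop edges not flagged physical.
#' @return An undirected [igraph::graph] with `weight` and `physical` edge
#'   attributes and an attribute `n_skipped` (malformed rows).
#' @export
build_graph <- function(edges, restrict_physical = FALSE) {
  stopifnot(ncol(edges) >= 2)
  a <- as.character(edges[[1]]); b <- as.character(edges[[2]])
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, nrow(edges))
  phys <- if ("physical" %in% names(edges)) as.logical(edges$physical) else
    rep(TRUE, nrow(edges))
  bad <- is.na(a) | is.na(b) | !nzchar(a) | !nzchar(b) | a == b |
    !is.finite(w) | w <= 0 | w > 1 | is.na(phys)
  n_skipped <- sum(bad)
  if (n_skipped) warning(sprintf("skipping %d malformed edge row(s)",
                                 n_skipped))
  df <- data.frame(from = a[!bad], to = b[!bad], weight = w[!bad],
                   physical = phys[!bad], stringsAsFactors = FALSE)
  if (restrict_physical) df <- df[df$physical, , drop = FALSE]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.loops = TRUE, remove.multiple = TRUE,
                        edge.attr.comb = list(weight = "max",
                                              physical = "first"))
  attr(g, "n_skipped") <- n_skipped
  g
}

#' Markov clustering of an interaction graph
#'
#' Classical MCL on the column-stochastic transition matrix of the weighted
#' adjacency with unit self-loops: alternate expansion (matrix squaring)
#' and inflation (elementwise power `inflation`, then column
#' renormalization) until the matrix changes by less than `tol` or
#' `max_iter` iterations.  Clusters are read off as connected components of
#' the converged matrix's support.  Deterministic; node order has no effect
#' beyond label numbering, which follows the smallest node identifier in
#' each cluster.
#'
#' @param graph An [igraph::graph] (edge `weight` used if present).
#' @param inflation Inflation exponent (default 2, the canonical MCL
#'   default).
#' @param max_iter,tol Convergence controls.
#' @return Named integer vector of cluster labels, with attributes
#'   `iterations`, `converged`, and `stochastic_deviation` (per-iteration
#'   max deviation of column sums from 1).
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100, tol = 1e-8) {
  n <- igraph::vcount(graph)
  if (n == 0) stop_config("empty graph")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(
    graph, attr = if ("weight" %in% igraph::edge_attr_names(graph))
      "weight" else NULL, sparse = FALSE)
  diag(A) <- 1
  normalize <- function(M) sweep(M, 2, colSums(M), "/")
  M <- normalize(A)
  dev <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M2 <- M %*% M                 # expansion
    M2 <- M2^inflation            # inflation
    M2[M2 < 1e-14] <- 0           # prune numerical dust
    M2 <- normalize(M2)
    dev <- c(dev, max(abs(colSums(M2) - 1)))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("MCL did not converge in %d iterations", max_iter))
  }
  support <- (M > 1e-6) | t(M > 1e-6)
  comp <- integer(n); comp[] <- 0L
  label <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      label <- label + 1L
      queue <- i
      comp[i] <- label
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(support[v, ] & comp == 0L)
        comp[nb] <- label
        queue <- c(queue, nb)
      }
    }
  }
  # renumber so cluster 1 contains the lexicographically smallest node
  first_node <- vapply(seq_len(label), function(l) min(nodes[comp == l]),
                       character(1))
  relab <- match(comp, order(first_node))
  out <- setNames(as.integer(relab), nodes)
  attr(out, "iterations") <- iter
  attr(out, "converged") <- converged
  attr(out, "stochastic_deviation") <- dev
  out
}

graph_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# Stage-1 MCODE vertex weight: highest k-core of the closed neighborhood,
# weighted by that core's density.
mcode_weights <- function(graph, degree_cutoff) {
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  w <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, names(igraph::neighbors(graph, v)))
    H <- igraph::induced_subgraph(graph, nb)
    cores <- igraph::coreness(H)
    kmax <- max(cores)
    K <- igraph::induced_subgraph(H, names(cores)[cores >= kmax])
    w[v] <- kmax * graph_density(K)
  }
  w
}

#' Molecular complex detection (MCODE)
#'
#' Three stages: (1) weight each vertex by the density of the highest
#' k-core of its closed neighborhood times that core number; (2) grow
#' complexes outward breadth-first from unused seeds in descending weight
#' order, admitting neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight (each node used once);
#' (3) "haircut" each candidate to its 2-core and keep complexes with at
#' least 3 nodes.  Edge weights are ignored (topological algorithm).
#'
#' @param graph An [igraph::graph].
#' @param degree_cutoff Minimum degree for a vertex to receive a weight
#'   (default 2).
#' @param node_score_cutoff Admission tolerance relative to the seed weight
#'   (default 0.2).
#' @param k_core Core threshold for the final filter (default 2).
#' @param max_depth Breadth-first growth radius (default 100).
#' @return List of complexes, each a list with `nodes`, `seed`, `density`,
#'   `score` (= density x size), sorted by descending score (ties by seed
#'   identifier); complexes are pairwise node-disjoint.
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100) {
  if (igraph::vcount(graph) == 0) stop_config("empty graph")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) {
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))
    nodes <- igraph::V(graph)$name
  }
  w <- mcode_weights(graph, degree_cutoff)
  order_seeds <- nodes[order(-w[nodes], nodes)]
  used <- setNames(logical(length(nodes)), nodes)
  complexes <- list()
  for (seed in order_seeds) {
    if (used[seed] || w[seed] <= 0) next
    thr <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      depth <- depth + 1L
      nxt <- character(0)
      for (v in frontier) {
        for (u in names(igraph::neighbors(graph, v))) {
          if (!used[u] && w[u] >= thr) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
    }
    if (length(members) < 3) next
    sub <- igraph::induced_subgraph(graph, members)
    cores <- igraph::coreness(sub)
    keep <- names(cores)[cores >= k_core]      # haircut to the 2-core
    if (length(keep) < 3) next
    sub <- igraph::induced_subgraph(graph, keep)
    complexes[[length(complexes) + 1L]] <-
      list(nodes = sort(keep), seed = seed, density = graph_density(sub),
           score = graph_density(sub) * length(keep))
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               vapply(complexes, `[[`, character(1), "seed"))
  complexes[ord]
}

#' Label complexes by gene-set enrichment
#'
#' Each complex is labelled with the lowest-p gene set from an
#' over-representation analysis of its members against the measured
#' background; complexes with no set at p < `alpha` stay unlabelled (`NA`).
#'
#' @param complexes List from [mcode()].
#' @param db Gene-set database (named list).
#' @param background Measured-protein background.
#' @param alpha Significance cutoff (default 0.05).
#' @return The complexes, each gaining `label` and `label_p` fields.
#' @export
label_complexes <- function(complexes, db, background, alpha = 0.05) {
  lapply(complexes, function(cx) {
    q <- intersect(cx$nodes, background)
    if (!length(q)) {
      cx$label <- NA_character_; cx$label_p <- NA_real_
      return(cx)
    }
    res <- suppressWarnings(enrich(q, db, background, alpha = alpha))
    if (nrow(res) && res$p[1] < alpha) {
      cx$label <- res$set[1]; cx$label_p <- res$p[1]
    } else {
      cx$label <- NA_character_; cx$label_p <- NA_real_
    }
    cx
  })
}
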