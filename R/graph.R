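#' Binarize a weighted connectivity matrix at a sparsity level
#'
#' Keeps the strongest `s` fraction of off-diagonal weights as edges:
#' `round(s * n(n-1)/2)` edges in total. Ties are broken by a fixed total
#' order (weight descending, then lexicographic pair index), so the edge set
#' is deterministic.
#'
#' @param weights symmetric finite weight matrix.
#' @param s sparsity (retained-edge fraction) in `(0, 1]`.
#' @return list of class `binary_graph`: `adjacency` (symmetric logical,
#'   zero diagonal), `sparsity`, `n_edges`.
#' @export
threshold_by_sparsity <- function(weights, s) {
  if (!is.numeric(s) || s <= 0 || s > 1) stop("sparsity must be in (0, 1]")
  weights <- as.matrix(weights)
  if (!isSymmetric(unname(weights), tol = 1e-10))
    stop("weights must be symmetric")
  n <- nrow(weights)
  ij <- which(upper.tri(weights), arr.ind = TRUE)
  w <- weights[ij]
  if (any(!is.finite(w))) stop("weights must be finite")
  m <- round(s * n * (n - 1) / 2)
  ord <- order(-w, ij[, 1], ij[, 2])
  keep <- ord[seq_len(m)]
  A <- matrix(FALSE, n, n)
  A[ij[keep, , drop = FALSE]] <- TRUE
  A <- A | t(A)
  structure(list(adjacency = A, sparsity = s, n_edges = m),
            class = "binary_graph")
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Mean clustering coefficient
#'
#' Mean over nodes of `E_i / (k_i (k_i - 1) / 2)` where `E_i` counts edges
#' among the neighbors of node i; nodes with degree < 2 contribute 0.
#'
#' @param g a `binary_graph` from [threshold_by_sparsity()].
#' @return CC in `[0, 1]`.
#' @export
clustering_coefficient <- function(g) {
  igraph::transitivity(as_igraph(g), type = "localaverage",
                       isolates = "zero")
}

#' Global efficiency
#'
#' Mean over ordered node pairs of the inverse shortest-path length;
#' disconnected pairs contribute 0.
#'
#' @param g a `binary_graph`.
#' @return GE in `[0, 1]`.
#' @export
global_efficiency <- function(g) {
  igraph::global_efficiency(as_igraph(g))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced on each
#' node's neighbors; nodes with fewer than 2 neighbors contribute 0.
#'
#' @param g a `binary_graph`.
#' @return LE in `[0, 1]`.
#' @export
local_efficiency <- function(g) {
  A <- g$adjacency
  n <- nrow(A)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ])
    if (length(nb) < 2) return(0)
    sub <- structure(list(adjacency = A[nb, nb, drop = FALSE]),
                     class = "binary_graph")
    global_efficiency(sub)
  }, numeric(1))
  mean(vals)
}

#' Modularity of a partition / greedy partition search
#'
#' `modularity_q` evaluates `Q = sum_m [l_m / L - (d_m / 2L)^2]` for a given
#' node partition (`l_m` = within-module edges, `d_m` = module degree sum,
#' `L` = total edges). `find_partition` maximizes Q by greedy agglomeration
#' (fast-greedy community detection) and returns the membership vector; the
#' reported network modularity is `modularity_q(g, find_partition(g))`.
#'
#' @param g a `binary_graph`.
#' @param partition integer module membership per node.
#' @return scalar Q (`modularity_q`); integer membership (`find_partition`).
#' @export
modularity_q <- function(g, partition) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0) stop("graph has no edges")
  if (length(partition) != nrow(g$adjacency))
    stop("partition must cover all nodes")
  igraph::modularity(ig, membership = as.integer(factor(partition)))
}

#' @rdname modularity_q
#' @export
find_partition <- function(g) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0) return(seq_len(nrow(g$adjacency)))
  as.integer(igraph::membership(igraph::cluster_fast_greedy(ig)))
}

#' Graph-metric curves over a sparsity grid with AUC summaries
#'
#' Computes CC, GE, LE and modularity (of the greedy-optimal partition) of
#' the binarized network at each sparsity level, and the trapezoid area under
#' each curve as the sparsity-independent summary.
#'
#' @param weights symmetric connectivity weight matrix (`NA` rows/columns,
#'   e.g. invalid channels, are dropped first).
#' @param grid sparsity grid (default 0.10 to 0.50 in steps of 0.05).
#' @return object of class `graph_metric_curves`: data frame `curves`
#'   (sparsity, cc, ge, le, q) and named `auc` vector.
#' @export
metric_curves <- function(weights, grid = seq(0.10, 0.50, by = 0.05)) {
  weights <- as.matrix(weights)
  keep <- !apply(is.na(weights), 1, all)
  W <- weights[keep, keep, drop = FALSE]
  if (anyNA(W)) stop("connectivity matrix contains NA beyond whole channels")
  res <- t(vapply(grid, function(s) {
    g <- threshold_by_sparsity(W, s)
    q <- if (g$n_edges == 0) NA_real_ else modularity_q(g, find_partition(g))
    c(cc = clustering_coefficient(g), ge = global_efficiency(g),
      le = local_efficiency(g), q = q)
  }, numeric(4)))
  curves <- data.frame(sparsity = grid, res)
  auc <- vapply(c("cc", "ge", "le", "q"),
                function(mm) pracma::trapz(grid, curves[[mm]]), numeric(1))
  names(auc) <- paste0("auc_", names(auc))
  structure(list(curves = curves, auc = auc), class = "graph_metric_curves")
}
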