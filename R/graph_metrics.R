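## Weighted shortest-path distance matrix with edge length = 1/weight
## (strong edges are short). Unreachable pairs are Inf.
weight_distances <- function(W) {
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  unname(D)
}

check_weights <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) stop("negative edge weights are not allowed")
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  W
}

as_weight_matrix <- function(W) {
  if (inherits(W, "connectome")) W <- W$weights
  check_weights(W)
}

#' Global efficiency of a weighted network
#'
#' Mean over ordered node pairs of the inverse shortest-path length, with
#' edge length `1/weight`; unreachable pairs contribute 0. A
#' capacity-for-integration measure: 1 for a complete unit-weight graph,
#' 0 for an empty one.
#'
#' @param W Symmetric non-negative weight matrix or `connectome`.
#' @return Scalar efficiency.
#' @export
global_efficiency <- function(W) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  if (n < 2L) stop("global efficiency requires at least 2 nodes")
  D <- weight_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Delta efficiency by synthetic node lesioning
#'
#' Removes a node and all of its connections and reports the percentage
#' change in global efficiency,
#' `100 * (E_lesioned - E_intact) / E_intact`. By default the lesioned
#' efficiency is computed on the reduced (n-1)-node graph; the alternative
#' convention keeps the lesioned node as an isolate in an n-node graph.
#'
#' @param W Symmetric non-negative weight matrix or `connectome`.
#' @param node Node index to lesion.
#' @param convention `"reduced"` (default) or `"isolated"`.
#' @return Percentage change in global efficiency (NA with a warning when
#'   the intact efficiency is 0).
#' @export
delta_efficiency <- function(W, node, convention = c("reduced", "isolated")) {
  W <- as_weight_matrix(W)
  convention <- match.arg(convention)
  n <- nrow(W)
  if (n < 3L) stop("delta efficiency requires at least 3 nodes")
  e0 <- global_efficiency(W)
  if (e0 == 0) {
    warning("intact global efficiency is 0; delta efficiency undefined")
    return(NA_real_)
  }
  Wl <- W
  Wl[node, ] <- 0
  Wl[, node] <- 0
  e1 <- if (convention == "reduced")
    global_efficiency(W[-node, -node, drop = FALSE])
  else global_efficiency(Wl)
  100 * (e1 - e0) / e0
}

## Participation coefficient and within-module strength z-score, standard
## modular-role formulas on weighted graphs.
participation_coefficient <- function(W, modules) {
  k <- rowSums(W)
  p <- rep(0, nrow(W))
  pos <- k > 0
  for (m in unique(modules)) {
    km <- rowSums(W[, modules == m, drop = FALSE])
    p[pos] <- p[pos] + (km[pos] / k[pos])^2
  }
  ifelse(pos, 1 - p, 0)
}

within_module_z <- function(W, modules) {
  z <- rep(0, nrow(W))
  for (m in unique(modules)) {
    sel <- modules == m
    kin <- rowSums(W[sel, sel, drop = FALSE])
    s <- stats::sd(kin)
    z[sel] <- if (is.na(s) || s == 0) 0 else (kin - mean(kin)) / s
  }
  z
}

## Principal (Perron) eigenvector of W, non-negative, unit Euclidean norm.
eigenvector_centrality <- function(W) {
  e <- eigen(W, symmetric = TRUE)
  v <- e$vectors[, which.max(e$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  v / sqrt(sum(v^2))
}

z_score <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) rep(0, length(x)) else
    (x - mean(x, na.rm = TRUE)) / s
}

#' Node centrality and robustness metrics
#'
#' Computes the pre-hoc centrality set on a weighted undirected network:
#' node strength (row sum), nodal efficiency (each node's mean inverse
#' shortest-path length to the others, its contribution to global
#' efficiency), betweenness centrality (shortest paths with edge length
#' `1/weight`), within-module degree z-score and participation coefficient
#' (modular role measures), eigenvector centrality (principal eigenvector
#' of the weight matrix), and delta efficiency from synthetic lesioning.
#' Z-scored variants of every measure (across nodes) are appended as
#' `z_*` columns.
#'
#' @param W Symmetric non-negative weight matrix or `connectome`.
#' @param partition Optional integer module labels; when absent, a
#'   modularity-maximising (Louvain) partition is computed under `seed` and
#'   recorded in the `partition` attribute.
#' @param seed RNG seed for the partition heuristic.
#' @param lesion_convention Passed to [delta_efficiency()].
#' @return An object of class `node_metrics` (data frame keyed by `node`,
#'   plus the partition as an attribute).
#' @export
node_centralities <- function(W, partition = NULL, seed = 1L,
                              lesion_convention = "reduced") {
  conn <- if (inherits(W, "connectome")) W else NULL
  W <- as_weight_matrix(W)
  n <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (is.null(partition)) {
    partition <- with_preserved_rng({
      set.seed(seed)
      as.integer(igraph::membership(igraph::cluster_louvain(g)))
    })
  }
  stopifnot(length(partition) == n)
  D <- weight_distances(W)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  ew <- igraph::E(g)$weight
  btw <- if (length(ew)) igraph::betweenness(g, weights = 1 / ew)
         else rep(0, n)
  out <- data.frame(
    node = if (!is.null(conn)) conn$ids else seq_len(n),
    strength = rowSums(W),
    nodal_efficiency = rowSums(inv) / max(1L, n - 1L),
    betweenness = as.numeric(btw),
    within_module_z = within_module_z(W, partition),
    participation = participation_coefficient(W, partition),
    eigenvector = eigenvector_centrality(W),
    delta_efficiency = vapply(seq_len(n), function(i)
      delta_efficiency(W, i, lesion_convention), numeric(1))
  )
  base <- setdiff(names(out), "node")
  for (nm in base) out[[paste0("z_", nm)]] <- z_score(out[[nm]])
  attr(out, "partition") <- partition
  class(out) <- c("node_metrics", "data.frame")
  out
}

#' Contralateral homologue ratios of node metrics
#'
#' Expresses each node's metrics as a ratio over the value in the
#' homologous node of the contralateral hemisphere. Nodes that are
#' unpaired, whose homologue was removed (e.g. for tumor overlap), or whose
#' homologue value is 0 get NA.
#'
#' @param metrics A [node_centralities()] table whose `node` column matches
#'   parcel ids.
#' @param parc A paired `parcellation` (see [pair_homologues()]).
#' @param columns Metric columns to ratio (default the unscaled measures).
#' @return The metrics table with appended `ratio_*` columns.
#' @export
homologue_ratio <- function(metrics, parc,
                            columns = c("strength", "nodal_efficiency",
                                        "betweenness", "within_module_z",
                                        "participation", "eigenvector",
                                        "delta_efficiency")) {
  stopifnot(inherits(metrics, "node_metrics"), inherits(parc, "parcellation"))
  p <- parc$parcels
  hom <- p$homologue_id[match(metrics$node, p$id)]
  hrow <- match(hom, metrics$node)   # NA when homologue absent/removed
  for (nm in intersect(columns, names(metrics))) {
    denom <- metrics[[nm]][hrow]
    r <- metrics[[nm]] / denom
    r[is.na(hrow) | !is.finite(r)] <- NA_real_
    metrics[[paste0("ratio_", nm)]] <- r
  }
  metrics
}
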