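## Shared fixtures, all built in code.

## Small phantom spec for pipeline-level tests: 32x24x24 grid at 2 mm,
## 4-mm tumor at (20, 0, 0) mm, 64 timepoints.
small_phantom_spec <- function(n_subjects = 1L, seed = 11L,
                               n_timepoints = 64L) {
  phantom_spec(grid_shape = c(32L, 24L, 24L), voxel_size_mm = 2,
               n_timepoints = n_timepoints, tr_s = 2.42,
               tumor_center_mm = c(20, 0, 0), tumor_radius_mm = 4,
               n_subjects = n_subjects, seed = seed)
}

## Random connected weighted graph on n nodes (continuous weights, so
## shortest paths are a.s. unique).
random_weighted_graph <- function(n, p_edge = 0.7) {
  repeat {
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    on <- stats::runif(length(up)) < p_edge
    W[up[on]] <- stats::runif(sum(on), 0.2, 1.5)
    W <- W + t(W)
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    if (igraph::is_connected(g) && sum(W) > 0) return(W)
  }
}

## Brute-force weighted shortest-path lengths (edge length 1/w) by
## enumerating every simple path; independent of igraph.
brute_shortest_paths <- function(W) {
  n <- nrow(W)
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  paths_between <- function(s, t) {
    found <- list()
    recurse <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        found[[length(found) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (u in seq_len(n)) {
        if (W[v, u] > 0 && !(u %in% path))
          recurse(c(path, u), len + 1 / W[v, u])
      }
    }
    recurse(s, 0)
    found
  }
  all_paths <- vector("list", n * n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    ps <- paths_between(s, t)
    if (length(ps)) {
      lens <- vapply(ps, `[[`, numeric(1), "len")
      best[s, t] <- min(lens)
      all_paths[[(s - 1) * n + t]] <- ps[abs(lens - min(lens)) < 1e-12]
    }
  }
  list(dist = best, shortest = all_paths)
}

## Brute-force betweenness from the enumerated shortest paths.
brute_betweenness <- function(W) {
  n <- nrow(W)
  bp <- brute_shortest_paths(W)
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    ps <- bp$shortest[[(s - 1) * n + t]]
    if (is.null(ps) || !length(ps)) next
    sigma <- length(ps)
    for (p in ps) {
      inner <- setdiff(p$path, c(s, t))
      btw[inner] <- btw[inner] + 1 / sigma
    }
  }
  btw
}

brute_global_efficiency <- function(W) {
  n <- nrow(W)
  D <- brute_shortest_paths(W)$dist
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

## Power-iteration eigenvector centrality oracle. The diagonal shift keeps
## the iteration from oscillating when |lambda_min| ~ lambda_max without
## changing the principal eigenvector of a non-negative matrix.
power_eigenvector <- function(W, iters = 50000, tol = 1e-15) {
  Ws <- W + diag(max(rowSums(W)) + 1, nrow(W))
  v <- rep(1 / sqrt(nrow(W)), nrow(W))
  for (i in seq_len(iters)) {
    nv <- Ws %*% v
    nv <- nv / sqrt(sum(nv^2))
    if (max(abs(nv - v)) < tol) break
    v <- drop(nv)
  }
  drop(v)
}
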