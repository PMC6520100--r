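#' Modular weighted network specification
#'
#' Fixture generator spec for graph-metric tests: a symmetric non-negative
#' weighted network with a known module partition, where within-module
#' weights are on average stronger than between-module weights.
#'
#' @param n_nodes Number of nodes.
#' @param n_modules Number of modules (nodes assigned in contiguous blocks).
#' @param p_within_weight Mean weight of within-module edges.
#' @param p_between_weight Mean weight of between-module edges (0 gives
#'   exactly disconnected modules).
#' @param seed Integer RNG seed.
#' @return An object of class `modular_net_spec`.
#' @export
modular_net_spec <- function(n_nodes, n_modules, p_within_weight = 1,
                             p_between_weight = 0.2, seed = 1L) {
  stopifnot(n_nodes >= 2, n_modules >= 1, n_modules <= n_nodes,
            p_within_weight >= 0, p_between_weight >= 0,
            p_within_weight > p_between_weight)
  structure(list(n_nodes = as.integer(n_nodes),
                 n_modules = as.integer(n_modules),
                 p_within_weight = p_within_weight,
                 p_between_weight = p_between_weight,
                 seed = as.integer(seed)),
            class = "modular_net_spec")
}

#' Simulate a modular weighted network
#'
#' Edge weights are gamma-distributed (shape 4) with mean
#' `p_within_weight` inside modules and `p_between_weight` between modules
#' (a zero mean gives weight exactly 0). The matrix is symmetric with a
#' zero diagonal; the generating partition is returned.
#'
#' @param spec A [modular_net_spec()].
#' @return List with `weights` (n x n symmetric matrix) and `modules`
#'   (integer vector of module labels).
#' @export
simulate_modular_network <- function(spec) {
  stopifnot(inherits(spec, "modular_net_spec"))
  n <- spec$n_nodes
  modules <- sort(rep_len(seq_len(spec$n_modules), n))
  with_preserved_rng({
    set.seed(spec$seed)
    W <- matrix(0, n, n)
    up <- which(upper.tri(W))
    same <- outer(modules, modules, "==")[up]
    mw <- ifelse(same, spec$p_within_weight, spec$p_between_weight)
    w <- numeric(length(up))
    pos <- mw > 0
    w[pos] <- stats::rgamma(sum(pos), shape = 4, rate = 4 / mw[pos])
    W[up] <- w
    W <- W + t(W)
    list(weights = W, modules = modules)
  })
}
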