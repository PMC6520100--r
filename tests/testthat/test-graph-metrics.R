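test_that("global efficiency matches hand-enumerated values", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), (1 + 1 + 0.5) / 3)
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  expect_equal(global_efficiency(K5), 1)
  expect_equal(global_efficiency(matrix(0, 4, 4)), 0)
  expect_error(global_efficiency(matrix(0, 1, 1)), "2 nodes")
})

test_that("delta efficiency follows the lesioning contract", {
  K5 <- matrix(1, 5, 5); diag(K5) <- 0
  for (i in 1:5) expect_equal(delta_efficiency(K5, i), 0)
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(delta_efficiency(path3, 2), -100)
  ## complete graph + isolate: removing the isolate raises efficiency
  W <- matrix(0, 5, 5); W[1:4, 1:4] <- 1; diag(W) <- 0
  expect_gt(delta_efficiency(W, 5), 0)
  ## oracle by definition
  e0 <- global_efficiency(W)
  expect_equal(delta_efficiency(W, 5),
               100 * (global_efficiency(W[-5, -5]) - e0) / e0)
  ## isolated-node convention keeps n nodes
  expect_equal(delta_efficiency(K5, 1, convention = "isolated"),
               100 * (global_efficiency({
                 Wl <- K5; Wl[1, ] <- 0; Wl[, 1] <- 0; Wl
               }) - 1) / 1)
  expect_warning(out <- delta_efficiency(matrix(0, 4, 4), 1), "undefined")
  expect_true(is.na(out))
})

test_that("star graph: the hub dominates every centrality", {
  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S[2:5, 1] <- 1
  m <- node_centralities(S, partition = rep(1L, 5))
  expect_identical(which.max(m$strength), 1L)
  expect_identical(which.max(m$betweenness), 1L)
  expect_identical(which.max(m$eigenvector), 1L)
  expect_true(all(m$participation == 0))   # single module
  expect_error(node_centralities(-S), "negative")
})

test_that("centralities match brute-force oracles on random small graphs", {
  set.seed(61)
  for (rep in 1:30) {
    n <- sample(3:5, 1)
    W <- random_weighted_graph(n)
    modules <- sample(1:2, n, replace = TRUE)
    m <- node_centralities(W, partition = modules)
    ## strength
    expect_equal(m$strength, rowSums(W), tolerance = 1e-9)
    ## efficiency from exhaustive path enumeration
    expect_equal(global_efficiency(W), brute_global_efficiency(W),
                 tolerance = 1e-9)
    D <- brute_shortest_paths(W)$dist
    inv <- 1 / D; diag(inv) <- 0; inv[!is.finite(inv)] <- 0
    expect_equal(m$nodal_efficiency, rowSums(inv) / (n - 1),
                 tolerance = 1e-9)
    ## betweenness
    expect_equal(m$betweenness, brute_betweenness(W), tolerance = 1e-9)
    ## eigenvector centrality vs power iteration
    expect_equal(m$eigenvector, power_eigenvector(W), tolerance = 1e-8)
    ## modular formulas recomputed directly
    k <- rowSums(W)
    part <- 1 - sapply(seq_len(n), function(i)
      sum(sapply(unique(modules), function(md)
        sum(W[i, modules == md])^2)) / k[i]^2)
    part[k == 0] <- 0
    expect_equal(m$participation, part, tolerance = 1e-9)
    wz <- numeric(n)
    for (md in unique(modules)) {
      sel <- modules == md
      kin <- rowSums(W[sel, sel, drop = FALSE])
      s <- stats::sd(kin)
      wz[sel] <- if (is.na(s) || s == 0) 0 else (kin - mean(kin)) / s
    }
    expect_equal(m$within_module_z, wz, tolerance = 1e-9)
    ## delta efficiency by definition (reduced-graph convention)
    e0 <- brute_global_efficiency(W)
    for (i in seq_len(n)) {
      e1 <- brute_global_efficiency(W[-i, -i, drop = FALSE])
      expect_equal(m$delta_efficiency[i], 100 * (e1 - e0) / e0,
                   tolerance = 1e-9)
    }
  }
})

test_that("centralities are permutation equivariant", {
  set.seed(62)
  W <- random_weighted_graph(5)
  modules <- c(1L, 1L, 2L, 2L, 2L)
  m <- node_centralities(W, partition = modules)
  perm <- c(4, 2, 5, 1, 3)
  mp <- node_centralities(W[perm, perm], partition = modules[perm])
  for (nm in c("strength", "nodal_efficiency", "betweenness",
               "within_module_z", "participation", "delta_efficiency"))
    expect_equal(mp[[nm]], m[[nm]][perm], tolerance = 1e-9)
})

test_that("efficiency is monotone under weight increases", {
  set.seed(63)
  W <- random_weighted_graph(5)
  e0 <- global_efficiency(W)
  W2 <- W
  W2[1, 2] <- W2[2, 1] <- W[1, 2] + 1
  expect_gte(global_efficiency(W2), e0)
  W3 <- W
  zero <- which(W3 == 0 & upper.tri(W3))
  if (length(zero)) {
    W3[zero[1]] <- 0.7
    W3 <- pmax(W3, t(W3))
    expect_gte(global_efficiency(W3), e0)
  }
})

test_that("z-scored columns standardise across nodes", {
  set.seed(64)
  W <- random_weighted_graph(8)
  m <- node_centralities(W, partition = rep(1:2, each = 4))
  for (nm in c("z_strength", "z_betweenness", "z_eigenvector")) {
    expect_lt(abs(mean(m[[nm]])), 1e-10)
    expect_lt(abs(stats::sd(m[[nm]]) - 1), 1e-10)
  }
})

test_that("homologue ratios follow pairing and removal", {
  dim3 <- c(8L, 4L, 4L)
  affine <- centered_affine(dim3, 2)
  labels <- array(0L, dim3)
  labels[5:6, 1:2, 1:2] <- 1L
  labels[7:8, 3:4, 3:4] <- 2L
  labels[3:4, 1:2, 1:2] <- 3L
  labels[1:2, 3:4, 3:4] <- 4L
  parc <- pair_homologues(parcellation_from_labels(labels, affine))
  metrics <- structure(
    data.frame(node = 1:4, strength = c(2, 4, 1, 4),
               delta_efficiency = c(-10, -20, -10, -20)),
    class = c("node_metrics", "data.frame"))
  out <- homologue_ratio(metrics, parc,
                         columns = c("strength", "delta_efficiency"))
  expect_equal(out$ratio_strength, c(2, 1, 0.5, 1))
  expect_equal(out$ratio_delta_efficiency, c(1, 1, 1, 1))
  ## hemispherically symmetric metrics -> all ratios 1
  sym <- structure(data.frame(node = 1:4, strength = c(3, 5, 3, 5)),
                   class = c("node_metrics", "data.frame"))
  expect_true(all(homologue_ratio(sym, parc,
                                  "strength")$ratio_strength == 1))
  ## removed homologue -> undefined ratio for its partner
  parc2 <- remove_tumor_parcels(parc, labels == 3L)
  met2 <- structure(data.frame(node = c(1L, 2L, 4L),
                               strength = c(2, 4, 4)),
                    class = c("node_metrics", "data.frame"))
  out2 <- homologue_ratio(met2, parc2, "strength")
  expect_true(is.na(out2$ratio_strength[out2$node == 1L]))
  expect_false(is.na(out2$ratio_strength[out2$node == 2L]))
})
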