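## Shared small bilateral mask: two 8x10x10-voxel slabs at +/- x.
bilateral_fixture <- function() {
  dim3 <- c(20L, 12L, 12L)
  affine <- centered_affine(dim3, 2)
  xyz <- penumbra:::voxel_world(seq_len(prod(dim3)), dim3, affine)
  gm <- array(abs(xyz[, 1]) >= 3 & abs(xyz[, 1]) <= 17 &
              abs(xyz[, 2]) <= 9 & abs(xyz[, 3]) <= 9, dim3)
  list(gm = gm, affine = affine, dim3 = dim3, xyz = xyz)
}

test_that("random parcellation partitions the mask into connected parcels", {
  fx <- bilateral_fixture()
  parc <- random_parcellation(fx$gm, fx$affine, n_parcels = 24L, seed = 5L)
  expect_s3_class(parc, "parcellation")
  expect_identical(sort(unique(as.integer(parc$labels[parc$labels > 0]))),
                   1:24)
  ## partition: labels cover exactly the mask
  expect_identical(parc$labels > 0, fx$gm)
  sizes <- parc$parcels$size
  expect_lte(max(sizes) / min(sizes), 2)
  ## connectivity of each parcel (6-neighbour graph)
  for (id in c(1L, 12L, 24L)) {
    m <- parc$labels == id
    idx <- which(m)
    ijk <- arrayInd(idx, fx$dim3)
    d <- as.matrix(stats::dist(ijk, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(d == 1, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
  ## determinism
  parc2 <- random_parcellation(fx$gm, fx$affine, n_parcels = 24L, seed = 5L)
  expect_identical(parc$labels, parc2$labels)
})

test_that("one parcel per voxel is the degenerate limit", {
  dim3 <- c(6L, 4L, 4L)
  affine <- centered_affine(dim3, 2)
  gm <- array(FALSE, dim3); gm[2:5, 2:3, 2:3] <- TRUE
  parc <- random_parcellation(gm, affine, n_parcels = sum(gm), seed = 1L)
  expect_true(all(parc$parcels$size == 1L))
  expect_error(random_parcellation(gm, affine, n_parcels = sum(gm) + 1L),
               "exceeds")
})

test_that("parcel means average valid voxels only", {
  dim3 <- c(4L, 2L, 2L)
  affine <- centered_affine(dim3, 2)
  labels <- array(0L, dim3)
  labels[1:2, 1, 1] <- 1L
  labels[3:4, 1, 1] <- 2L
  parc <- parcellation_from_labels(labels, affine)
  vals <- array(NA_real_, dim3)
  vals[1:2, 1, 1] <- 0.6
  vals[3:4, 1, 1] <- 0.8
  hm <- structure(list(values = vals, validity = !is.na(vals),
                       threshold = 0.5), class = "hurst_map")
  pm <- parcel_means(hm, parc)
  expect_equal(pm$value, c(0.6, 0.8))
  ## constant map -> every parcel mean equals the constant
  vals2 <- array(0.7, dim3)
  hm2 <- structure(list(values = vals2, validity = array(TRUE, dim3),
                        threshold = 0.5), class = "hurst_map")
  expect_true(all(parcel_means(hm2, parc)$value == 0.7))
  ## thresholded voxels excluded: recompute with an explicit mask oracle
  keep <- array(TRUE, dim3); keep[1, 1, 1] <- FALSE
  hm3 <- structure(list(values = vals2, validity = keep, threshold = 0.5),
                   class = "hurst_map")
  pm3 <- parcel_means(hm3, parc)
  expect_equal(pm3$n_valid_voxels, c(1L, 2L))
  expect_equal(pm3$value[1], mean(vals2[labels == 1L & keep]))
})

test_that("tumor-overlapping parcels are removed without renumbering", {
  fx <- bilateral_fixture()
  parc <- random_parcellation(fx$gm, fx$affine, n_parcels = 10L, seed = 2L)
  expect_identical(remove_tumor_parcels(parc, array(FALSE, fx$dim3))$parcels,
                   parc$parcels)
  ## tumor exactly covering one parcel
  tum1 <- parc$labels == 3L
  r1 <- remove_tumor_parcels(parc, tum1)
  expect_identical(sum(r1$parcels$kept), nrow(r1$parcels) - 1L)
  expect_false(r1$parcels$kept[r1$parcels$id == 3L])
  expect_identical(r1$parcels$id, parc$parcels$id)
  ## tumor straddling two parcels removes both (>= 1 voxel criterion)
  v3 <- which(parc$labels == 3L)[1]
  v4 <- which(parc$labels == 4L)[1]
  tum2 <- array(FALSE, fx$dim3); tum2[c(v3, v4)] <- TRUE
  r2 <- remove_tumor_parcels(parc, tum2)
  expect_false(any(r2$parcels$kept[r2$parcels$id %in% c(3L, 4L)]))
  expect_identical(sum(!r2$parcels$kept), 2L)
})

test_that("homologue pairing is a symmetric involution on mirrored templates", {
  fx <- bilateral_fixture()
  parc <- random_parcellation(fx$gm, fx$affine, n_parcels = 16L, seed = 7L)
  parc <- pair_homologues(parc)
  p <- parc$parcels
  paired <- !is.na(p$homologue_id)
  expect_gte(mean(paired), 0.95)
  for (i in which(paired)) {
    j <- match(p$homologue_id[i], p$id)
    expect_identical(p$homologue_id[j], p$id[i])
    expect_false(p$hemisphere[i] == p$hemisphere[j])
  }
  ## single-hemisphere template: all unpaired, no error
  right <- fx$gm
  right[1:10, , ] <- FALSE
  pr <- pair_homologues(random_parcellation(right, fx$affine, 8L, seed = 1L))
  expect_true(all(is.na(pr$parcels$homologue_id)))
})

test_that("exactly mirrored labels pair with their mirror partners", {
  dim3 <- c(8L, 4L, 4L)
  affine <- centered_affine(dim3, 2)
  labels <- array(0L, dim3)
  labels[5:6, 1:2, 1:2] <- 1L   # right, front
  labels[7:8, 3:4, 3:4] <- 2L   # right, back
  labels[3:4, 1:2, 1:2] <- 3L   # mirror of 1
  labels[1:2, 3:4, 3:4] <- 4L   # mirror of 2
  parc <- pair_homologues(parcellation_from_labels(labels, affine))
  hom <- stats::setNames(parc$parcels$homologue_id, parc$parcels$id)
  expect_identical(unname(hom[c("1", "2", "3", "4")]), c(3L, 4L, 1L, 2L))
})

test_that("node-tumor distances match the centroid oracle", {
  fx <- bilateral_fixture()
  parc <- random_parcellation(fx$gm, fx$affine, n_parcels = 12L, seed = 3L)
  tumor <- array(FALSE, fx$dim3)
  tumor[15:16, 6:7, 6:7] <- TRUE
  parc <- node_tumor_distance(parc, tumor)
  tc <- penumbra:::mask_centroid(tumor, fx$affine)
  for (i in seq_len(nrow(parc$parcels))) {
    id <- parc$parcels$id[i]
    idx <- which(parc$labels == id)
    cen <- colMeans(penumbra:::voxel_world(idx, fx$dim3, fx$affine))
    expect_equal(parc$parcels$tumor_distance_mm[i],
                 sqrt(sum((cen - tc)^2)), tolerance = 1e-10)
  }
  ## Pythagorean sanity via a hand-placed pair
  expect_equal(sqrt(sum((c(3, 4, 0) - c(0, 0, 0))^2)), 5)
})

test_that("parcel means commute with tumor-parcel removal on kept parcels", {
  fx <- bilateral_fixture()
  parc <- random_parcellation(fx$gm, fx$affine, n_parcels = 10L, seed = 4L)
  set.seed(44)
  vals <- array(stats::runif(prod(fx$dim3), 0.5, 1), fx$dim3)
  hm <- structure(list(values = vals, validity = array(TRUE, fx$dim3),
                       threshold = 0.5), class = "hurst_map")
  tumor <- parc$labels == 5L
  a <- parcel_means(hm, remove_tumor_parcels(parc, tumor))
  b <- parcel_means(hm, parc)
  b <- b[b$id %in% a$id, ]
  expect_equal(a$value, b$value)
})
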