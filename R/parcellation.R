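#' Parcellation container
#'
#' A parcellation couples an integer label volume (0 = background) with a
#' per-parcel table: world-mm centroid, size, hemisphere, homologue pairing,
#' kept/removed flag, and tumor distance. Parcels are never renumbered:
#' removal (e.g. for tumor overlap) flips the `kept` flag so ids stay
#' stable across pipeline stages.
#'
#' @param labels 3D integer array of parcel labels (0 = background).
#' @param affine 4x4 voxel-to-world affine.
#' @return An object of class `parcellation`.
#' @export
parcellation_from_labels <- function(labels, affine) {
  stopifnot(length(dim(labels)) == 3L)
  ids <- sort(unique(as.integer(labels[labels > 0])))
  if (!length(ids)) stop("label volume contains no parcels")
  idx <- which(labels > 0)
  lab <- as.integer(labels[idx])
  xyz <- voxel_world(idx, dim(labels), affine)
  cen <- rowsum(xyz, lab) / as.vector(table(lab))
  sizes <- as.integer(table(lab))
  parcels <- data.frame(
    id = ids,
    x_mm = cen[, 1], y_mm = cen[, 2], z_mm = cen[, 3],
    size = sizes,
    hemisphere = ifelse(cen[, 1] > 0, "R", ifelse(cen[, 1] < 0, "L", "M")),
    homologue_id = NA_integer_,
    kept = TRUE,
    tumor_distance_mm = NA_real_
  )
  rownames(parcels) <- NULL
  structure(list(labels = labels, parcels = parcels, affine = affine),
            class = "parcellation")
}

## Balanced seeded region growing of one connected set of voxel indices.
## Returns an integer vector of parcel assignments (1..n_parcels) aligned
## with gm_idx, or stops if voxels are unreachable from the seeds.
grow_balanced <- function(gm_idx, dim3, xyz, n_parcels) {
  ngm <- length(gm_idx)
  comp <- integer(prod(dim3))
  comp[gm_idx] <- seq_len(ngm)
  ## 6-connectivity neighbour table (compact ids; 0 = none/not gm)
  ijk <- arrayInd(gm_idx, dim3)
  nbr <- matrix(0L, ngm, 6L)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (o in seq_len(6)) {
    nij <- sweep(ijk, 2, offs[o, ], "+")
    ok <- nij[, 1] >= 1 & nij[, 1] <= dim3[1] &
          nij[, 2] >= 1 & nij[, 2] <= dim3[2] &
          nij[, 3] >= 1 & nij[, 3] <= dim3[3]
    lin <- rep(0L, ngm)
    lin[ok] <- (nij[ok, 3] - 1L) * dim3[1] * dim3[2] +
               (nij[ok, 2] - 1L) * dim3[1] + nij[ok, 1]
    nbr[, o] <- ifelse(ok, comp[pmax(lin, 1L)], 0L)
  }
  if (n_parcels >= ngm) return(seq_len(ngm))
  ## seeds: k-means centres on world coordinates, snapped to nearest voxel
  centers <- tryCatch(
    stats::kmeans(xyz, centers = n_parcels, iter.max = 30L,
                  nstart = 1L)$centers,
    error = function(e) xyz[sample(ngm, n_parcels), , drop = FALSE])
  seeds <- integer(n_parcels)
  taken <- rep(FALSE, ngm)
  for (p in seq_len(n_parcels)) {
    d2 <- colSums((t(xyz) - centers[p, ])^2)
    d2[taken] <- Inf
    seeds[p] <- which.min(d2)
    taken[seeds[p]] <- TRUE
  }
  assign <- integer(ngm)
  queue <- vector("list", n_parcels)
  head <- rep(1L, n_parcels)
  sizes <- integer(n_parcels)
  active <- rep(TRUE, n_parcels)
  for (p in seq_len(n_parcels)) queue[[p]] <- seeds[p]
  n_assigned <- 0L
  while (n_assigned < ngm && any(active)) {
    s <- sizes
    s[!active] <- NA
    p <- which.min(s)
    v <- 0L
    while (head[p] <= length(queue[[p]])) {
      cand <- queue[[p]][head[p]]
      head[p] <- head[p] + 1L
      if (assign[cand] == 0L) { v <- cand; break }
    }
    if (v == 0L) { active[p] <- FALSE; next }
    assign[v] <- p
    sizes[p] <- sizes[p] + 1L
    n_assigned <- n_assigned + 1L
    nb <- nbr[v, ]
    nb <- nb[nb > 0L]
    nb <- nb[assign[nb] == 0L]
    if (length(nb)) queue[[p]] <- c(queue[[p]], nb)
  }
  if (n_assigned < ngm)
    stop("region growing could not reach ", ngm - n_assigned,
         " voxel(s): the mask is disconnected; at most ",
         length(unique(assign[assign > 0])),
         " connected parcels are achievable with these seeds")
  assign
}

#' Random equal-size parcellation
#'
#' Space-filling partition of a grey-matter mask into `n_parcels` connected,
#' near-equal-size parcels by balanced seeded region growing: seed voxels
#' are placed by k-means on world coordinates (fixed seed), then parcels
#' grow one voxel at a time with priority to the currently smallest parcel.
#' Bilateral masks are partitioned per hemisphere (parcel counts allocated
#' proportionally to hemisphere volume) so every parcel is unilateral and
#' homologue pairing is meaningful.
#'
#' @param gm 3D logical grey-matter mask.
#' @param affine 4x4 voxel-to-world affine.
#' @param n_parcels Total number of parcels (default 256, the randomized
#'   template size; at most the number of mask voxels).
#' @param seed Integer RNG seed (deterministic output).
#' @return A [parcellation_from_labels()] object.
#' @export
random_parcellation <- function(gm, affine, n_parcels = 256L, seed = 1L) {
  stopifnot(is.logical(gm), length(dim(gm)) == 3L)
  ngm <- sum(gm)
  if (!ngm) stop("grey-matter mask is empty")
  n_parcels <- as.integer(n_parcels)
  if (n_parcels > ngm)
    stop("n_parcels (", n_parcels, ") exceeds mask voxel count (", ngm, ")")
  dim3 <- dim(gm)
  idx <- which(gm)
  xyz <- voxel_world(idx, dim3, affine)
  right <- xyz[, 1] > 0
  labels <- array(0L, dim3)
  with_preserved_rng({
    set.seed(seed)
    if (all(right) || all(!right)) {
      labels[idx] <- grow_balanced(idx, dim3, xyz, n_parcels)
    } else {
      nR <- max(1L, min(n_parcels - 1L,
                        as.integer(round(n_parcels * mean(right)))))
      nL <- n_parcels - nR
      aR <- grow_balanced(idx[right], dim3, xyz[right, , drop = FALSE], nR)
      aL <- grow_balanced(idx[!right], dim3, xyz[!right, , drop = FALSE], nL)
      labels[idx[right]] <- aR
      labels[idx[!right]] <- aL + nR
    }
  })
  parcellation_from_labels(labels, affine)
}

#' Per-parcel mean Hurst values
#'
#' Mean of the valid (unthresholded) Hurst-map voxels within each kept
#' parcel; parcels with no valid voxel get an NA value and are flagged by
#' `n_valid_voxels = 0`.
#'
#' @param map A [hurst_map()].
#' @param parc A [parcellation_from_labels()] object.
#' @return Data frame (`parcel_values`) with columns `id`, `value`,
#'   `n_valid_voxels`.
#' @export
parcel_means <- function(map, parc) {
  stopifnot(inherits(map, "hurst_map"), inherits(parc, "parcellation"))
  if (!identical(dim(map$values), dim(parc$labels)))
    stop("Hurst map grid does not match parcellation grid")
  vals <- map$values
  vals[!map$validity] <- NA_real_
  kept <- parc$parcels$id[parc$parcels$kept]
  lab <- as.integer(parc$labels)
  inp <- lab %in% kept & !is.na(vals)
  sums <- rowsum(as.vector(vals)[inp], lab[inp])
  cnts <- rowsum(rep(1L, sum(inp)), lab[inp])
  got <- as.integer(rownames(sums))
  value <- rep(NA_real_, length(kept))
  nval <- rep(0L, length(kept))
  m <- match(got, kept)
  value[m] <- sums[, 1] / cnts[, 1]
  nval[m] <- cnts[, 1]
  out <- data.frame(id = kept, value = value, n_valid_voxels = nval)
  class(out) <- c("parcel_values", "data.frame")
  out
}

#' Remove parcels overlapping the tumor
#'
#' Marks every parcel containing at least one tumor voxel as removed
#' (`kept = FALSE`). Ids are not renumbered, and homologues of removed
#' parcels remain kept.
#'
#' @param parc A `parcellation`.
#' @param tumor 3D logical tumor mask on the same grid.
#' @return The updated `parcellation`.
#' @export
remove_tumor_parcels <- function(parc, tumor) {
  stopifnot(inherits(parc, "parcellation"), is.logical(tumor))
  if (!identical(dim(tumor), dim(parc$labels)))
    stop("tumor mask grid does not match parcellation grid")
  hit <- unique(as.integer(parc$labels[tumor & parc$labels > 0]))
  parc$parcels$kept[parc$parcels$id %in% hit] <- FALSE
  parc
}

#' Pair homologous parcels across hemispheres
#'
#' Each parcel is paired with the contralateral parcel whose centroid is
#' nearest its mirror image (world `x` negated); only mutual-nearest pairs
#' are accepted, so the pairing is symmetric. Unpaired parcels (including
#' all parcels of a single-hemisphere template) keep `homologue_id = NA`.
#'
#' @param parc A `parcellation`.
#' @param affine Affine (defaults to the parcellation's own).
#' @return The updated `parcellation`.
#' @export
pair_homologues <- function(parc, affine = parc$affine) {
  stopifnot(inherits(parc, "parcellation"))
  p <- parc$parcels
  p$homologue_id <- NA_integer_
  iR <- which(p$hemisphere == "R")
  iL <- which(p$hemisphere == "L")
  if (length(iR) && length(iL)) {
    cR <- as.matrix(p[iR, c("x_mm", "y_mm", "z_mm")])
    cL <- as.matrix(p[iL, c("x_mm", "y_mm", "z_mm")])
    cRm <- cR; cRm[, 1] <- -cRm[, 1]
    d <- outer(rowSums(cRm^2), rowSums(cL^2), "+") - 2 * cRm %*% t(cL)
    bestL <- apply(d, 1, which.min)   # for each R, nearest L
    bestR <- apply(d, 2, which.min)   # for each L, nearest R
    mutual <- which(bestR[bestL] == seq_along(iR))
    p$homologue_id[iR[mutual]] <- p$id[iL[bestL[mutual]]]
    p$homologue_id[iL[bestL[mutual]]] <- p$id[iR[mutual]]
  }
  parc$parcels <- p
  parc
}

#' Parcel-centroid to tumor-centroid distances
#'
#' Euclidean distance (mm) from the centre of each node to the centre of
#' the tumor, stored in the parcel table.
#'
#' @param parc A `parcellation`.
#' @param tumor 3D logical tumor mask (non-empty) on the same grid.
#' @param affine Affine (defaults to the parcellation's own).
#' @return The updated `parcellation`.
#' @export
node_tumor_distance <- function(parc, tumor, affine = parc$affine) {
  stopifnot(inherits(parc, "parcellation"), is.logical(tumor))
  if (!any(tumor)) stop("tumor mask is empty")
  cen <- mask_centroid(tumor, affine)
  p <- parc$parcels
  parc$parcels$tumor_distance_mm <-
    sqrt((p$x_mm - cen[1])^2 + (p$y_mm - cen[2])^2 + (p$z_mm - cen[3])^2)
  parc
}

#' Write the parcel table
#'
#' @param parc A `parcellation`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_parcel_table <- function(parc, path) {
  utils::write.table(parc$parcels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
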