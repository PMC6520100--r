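#' Pipeline run configuration
#'
#' Settings shared by the per-subject and cohort pipelines. The pipeline
#' consumes already co-registered volumes on one grid (upstream denoising,
#' segmentation and registration are out of scope) and echoes the full
#' configuration, plus an FNV-1a fingerprint of it, into every output.
#'
#' @param wavelet,n_levels,threshold Hurst estimator settings (see
#'   [hurst_config()]).
#' @param annulus_step_mm,annulus_max_mm Peritumoral annulus geometry.
#' @param n_parcels Parcel count for the randomized template.
#' @param connectivity_methods Character vector of connectome methods to
#'   run (subset of pearson/partial/wavelet).
#' @param wavelet_scale Scale for the wavelet connectome.
#' @param lesion_convention Delta-efficiency convention (see
#'   [delta_efficiency()]).
#' @param seed Seed for parcellation and partition heuristics.
#' @return A list of class `run_config`.
#' @export
run_config <- function(wavelet = "db8", n_levels = 5L, threshold = 0.5,
                       annulus_step_mm = 2, annulus_max_mm = 30,
                       n_parcels = 256L,
                       connectivity_methods = "pearson",
                       wavelet_scale = 2L,
                       lesion_convention = "reduced",
                       seed = 1L) {
  structure(list(wavelet = wavelet, n_levels = as.integer(n_levels),
                 threshold = threshold,
                 annulus_step_mm = annulus_step_mm,
                 annulus_max_mm = annulus_max_mm,
                 n_parcels = as.integer(n_parcels),
                 connectivity_methods = connectivity_methods,
                 wavelet_scale = as.integer(wavelet_scale),
                 lesion_convention = lesion_convention,
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(verbose, ...) if (verbose) message("[penumbra] ", ...)

#' Run the full per-subject analysis
#'
#' Stages: voxelwise Hurst map (grey + white matter, thresholded at
#' `H < threshold`); peritumoral annuli restricted to grey matter with the
#' homologous-region gradient profile; parcellation (supplied or randomized)
#' with tumor-parcel removal, homologue pairing and tumor distances; parcel
#' mean H; connectome(s); node centralities with delta efficiency, z-scores
#' and homologue ratios. A missing tumor mask skips the annulus and
#' distance stages with a warning; the remaining stages still run.
#'
#' @param bold 4D BOLD array.
#' @param affine 4x4 voxel-to-world affine.
#' @param segmentation 3D integer tissue labels (1 CSF, 2 GM, 3 WM,
#'   4 tumor).
#' @param tumor 3D logical tumor mask, or NULL.
#' @param parc Optional shared `parcellation`; generated from the GM mask
#'   when NULL.
#' @param config A [run_config()].
#' @param stages Character subset of
#'   `c("fractal", "annuli", "parcels", "connectome")` to run; later stages
#'   depend on earlier ones.
#' @param verbose Log stage progress and voxel/parcel counts.
#' @return A list (class `subject_result`) with elements `hmap`, `profile`,
#'   `parcellation`, `parcel_h`, `connectomes`, `metrics`, plus the echoed
#'   `config` and its `config_hash`.
#' @export
run_subject <- function(bold, affine, segmentation, tumor = NULL,
                        parc = NULL, config = run_config(),
                        stages = c("fractal", "annuli", "parcels",
                                   "connectome"),
                        verbose = FALSE) {
  stopifnot(length(dim(bold)) == 4L)
  if (!identical(dim(bold)[1:3], dim(segmentation)))
    stop("grid mismatch: segmentation does not match the BOLD grid")
  if (!is.null(tumor) && !identical(dim(tumor), dim(segmentation)))
    stop("grid mismatch: tumor mask does not match the BOLD grid")
  hcfg <- hurst_config(config$wavelet, config$n_levels, config$threshold)
  res <- list(config = config, config_hash = fnv1a_hash(config))
  gm <- segmentation == SEG_GM
  brain <- segmentation == SEG_GM | segmentation == SEG_WM
  pipeline_log(verbose, "fractal stage: ", sum(brain), " brain voxels")
  res$hmap <- hurst_map(bold, brain, hcfg)
  pipeline_log(verbose, "  valid (H >= ", config$threshold, "): ",
               sum(res$hmap$validity))
  if ("annuli" %in% stages) {
    if (is.null(tumor) || !any(tumor)) {
      warning("no tumor mask: annulus and distance stages skipped")
    } else {
      ann <- dilate_annuli(tumor, affine, config$annulus_step_mm,
                           config$annulus_max_mm)
      ann <- restrict_to_gm(ann, gm & !tumor)
      res$profile <- gradient_profile(res$hmap, ann, affine)
      pipeline_log(verbose, "annuli: ", length(ann$annuli), " bands, ",
                   sum(res$profile$n_voxels), " GM voxels")
    }
  }
  if ("parcels" %in% stages) {
    if (is.null(parc))
      parc <- random_parcellation(gm, affine, config$n_parcels, config$seed)
    if (!is.null(tumor) && any(tumor)) {
      parc <- remove_tumor_parcels(parc, tumor)
      parc <- node_tumor_distance(parc, tumor, affine)
    }
    parc <- pair_homologues(parc, affine)
    res$parcellation <- parc
    res$parcel_h <- parcel_means(res$hmap, parc)
    pipeline_log(verbose, "parcels: ", sum(parc$parcels$kept), " kept of ",
                 nrow(parc$parcels))
  }
  if ("connectome" %in% stages && !is.null(res$parcellation)) {
    ts <- extract_timeseries(bold, res$parcellation)
    res$connectomes <- list()
    res$metrics <- list()
    for (m in config$connectivity_methods) {
      conn <- connectivity(ts, m, scale = config$wavelet_scale,
                           wavelet = config$wavelet)
      met <- node_centralities(conn, seed = config$seed,
                               lesion_convention = config$lesion_convention)
      met <- homologue_ratio(met, res$parcellation)
      p <- res$parcellation$parcels
      met$tumor_distance_mm <- p$tumor_distance_mm[match(met$node, p$id)]
      res$connectomes[[m]] <- conn
      res$metrics[[m]] <- met
      pipeline_log(verbose, "connectome [", m, "]: ",
                   nrow(conn$weights), " nodes")
    }
  }
  class(res) <- "subject_result"
  res
}

## Pool annulus-profile rows from subject results.
pool_profiles <- function(results, subjects_idx) {
  rows <- lapply(results[subjects_idx], function(r) {
    if (is.null(r$profile)) return(NULL)
    r$profile
  })
  do.call(rbind, rows)
}

#' Run a cohort analysis
#'
#' Runs [run_subject()] for every subject (sharing one parcellation when
#' the subjects share a grid), then pools results per cohort split
#' (discovery / validation / complete): distance-gradient model fits with
#' AIC selection on the annulus homologous-region ratios and on parcel
#' homologue ratios, an ANCOVA for cohort differences in the log-H versus
#' distance slope, a tissue ANOVA of per-subject mean H by tissue class,
#' and metric-Hurst correlations.
#'
#' @param subjects List of subject inputs; each element is a list with
#'   `bold`, `affine`, `segmentation`, `tumor` (a `phantom_subject` works
#'   as-is).
#' @param split Character/factor cohort label per subject (e.g.
#'   `"discovery"` / `"validation"`).
#' @param config A [run_config()].
#' @param stages Passed to [run_subject()].
#' @param shared_parcellation Reuse one parcellation across subjects
#'   (default TRUE; valid because subjects are registered to one grid).
#' @param verbose Log progress.
#' @return A list (class `cohort_report`): `subject_results`,
#'   `annulus_fits` (per cohort: `gradient_fits`, with `$best`),
#'   `parcel_fits`, `ancova`, `tissue_anova`, `correlations`, `config`,
#'   `config_hash`.
#' @export
run_cohort <- function(subjects, split, config = run_config(),
                       stages = c("fractal", "annuli", "parcels",
                                  "connectome"),
                       shared_parcellation = TRUE, verbose = FALSE) {
  stopifnot(length(subjects) >= 1L, length(split) == length(subjects))
  split <- as.character(split)
  parc <- NULL
  if (shared_parcellation && "parcels" %in% stages) {
    gm <- subjects[[1]]$segmentation == SEG_GM
    parc <- random_parcellation(gm, subjects[[1]]$affine, config$n_parcels,
                                config$seed)
  }
  results <- lapply(seq_along(subjects), function(i) {
    pipeline_log(verbose, "subject ", i, " [", split[i], "]")
    s <- subjects[[i]]
    run_subject(s$bold, s$affine, s$segmentation, s$tumor, parc = parc,
                config = config, stages = stages, verbose = verbose)
  })
  cohorts <- c(stats::setNames(lapply(unique(split), function(l)
    which(split == l)), unique(split)),
    list(complete = seq_along(subjects)))
  report <- list(subject_results = results, split = split, config = config,
                 config_hash = fnv1a_hash(config))
  ## Annulus-ratio gradient fits per cohort
  if (any(!vapply(results, function(r) is.null(r$profile), logical(1)))) {
    report$annulus_profiles <- lapply(cohorts, function(ii)
      pool_profiles(results, ii))
    report$annulus_fits <- lapply(report$annulus_profiles, function(pr) {
      fits <- fit_gradient_models(pr$distance_mm, pr$ratio)
      fits$best <- select_best(fits)$family
      fits
    })
  }
  ## Parcel homologue-ratio fits per cohort (H ratio vs tumor distance)
  if ("parcels" %in% stages) {
    parcel_rows <- do.call(rbind, lapply(seq_along(results), function(i) {
      r <- results[[i]]
      if (is.null(r$parcel_h)) return(NULL)
      p <- r$parcellation$parcels
      ph <- r$parcel_h
      hom <- p$homologue_id[match(ph$id, p$id)]
      hval <- ph$value[match(hom, ph$id)]
      data.frame(subject = i, cohort = split[i], id = ph$id,
                 h = ph$value, h_ratio = ph$value / hval,
                 distance_mm = p$tumor_distance_mm[match(ph$id, p$id)])
    }))
    report$parcel_values <- parcel_rows
    ipsi_rows <- parcel_rows[is.finite(parcel_rows$h_ratio) &
                             is.finite(parcel_rows$distance_mm), ]
    if (nrow(ipsi_rows) >= 6L) {
      report$parcel_fits <- lapply(cohorts, function(ii) {
        rows <- ipsi_rows[ipsi_rows$subject %in% ii, ]
        if (nrow(rows) < 6L) return(NULL)
        fits <- fit_gradient_models(rows$distance_mm, rows$h_ratio)
        fits$best <- select_best(fits)$family
        fits
      })
    }
    ## ANCOVA on log H vs distance across declared cohorts
    anc <- ipsi_rows[is.finite(ipsi_rows$h) & ipsi_rows$h > 0, ]
    if (length(unique(split)) >= 2L &&
        all(table(anc$cohort) >= 3L) && length(unique(anc$cohort)) >= 2L) {
      report$ancova <- cohort_ancova(log(anc$h), anc$distance_mm,
                                     anc$cohort)
    } else {
      warning("ANCOVA skipped: need at least 2 cohorts with 3+ parcels")
    }
  }
  ## Tissue ANOVA: per-subject mean estimated H by tissue class
  tissue_rows <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    seg <- subjects[[i]]$segmentation
    vals <- r$hmap$values
    vals[!r$hmap$validity] <- NA
    tissues <- c(GM = SEG_GM, WM = SEG_WM)
    do.call(rbind, lapply(names(tissues), function(tn)
      data.frame(subject = i, tissue = tn,
                 mean_h = mean(vals[seg == tissues[[tn]]], na.rm = TRUE))))
  }))
  report$tissue_means <- tissue_rows
  if (length(unique(tissue_rows$subject)) >= 2L)
    report$tissue_anova <- tissue_anova(tissue_rows$mean_h,
                                        tissue_rows$tissue)
  ## Metric-H correlations pooled across subjects
  if ("connectome" %in% stages) {
    for (m in config$connectivity_methods) {
      pooled <- do.call(rbind, lapply(results, function(r) {
        if (is.null(r$metrics[[m]])) return(NULL)
        met <- r$metrics[[m]]
        met$h <- r$parcel_h$value[match(met$node, r$parcel_h$id)]
        met
      }))
      if (!is.null(pooled) && nrow(pooled) >= 4L) {
        report$correlations[[m]] <- metric_hurst_correlations(
          pooled$h, pooled,
          columns = c("strength", "nodal_efficiency", "betweenness",
                      "within_module_z", "participation", "eigenvector",
                      "delta_efficiency"))
      }
    }
  }
  class(report) <- "cohort_report"
  report
}
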