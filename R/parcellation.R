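#' Average absolute growth-rate map
#'
#' Voxelwise mean of the absolute Gompertz rate `|gamma|` over a set of
#' channels. Fast-maturing transient white-matter compartments appear as
#' high values; the map is non-negative by construction.
#'
#' @param gamma_maps named list of [scalar_image] rate maps (e.g. from the
#'   `gamma` maps of per-channel fits).
#' @return a [scalar_image].
#' @export
average_growth_rate_map <- function(gamma_maps) {
  if (length(gamma_maps) < 1) stop("need at least one gamma map")
  d <- gamma_maps[[1]]$grid_shape
  acc <- array(0, d)
  for (g in gamma_maps) {
    if (!all(g$grid_shape == d)) stop("gamma maps do not share a grid")
    acc <- acc + abs(g$values)
  }
  scalar_image(acc / length(gamma_maps), gamma_maps[[1]]$voxel_to_world)
}

#' Threshold parcellation of a rate map
#'
#' Binarises the average growth-rate map at `threshold`, decomposes the
#' supra-threshold voxels into 26-connected components, drops components
#' smaller than `min_region_voxels`, and labels the survivors in order of
#' decreasing size (label 1 = largest).
#'
#' @param gamma_av [scalar_image], e.g. from [average_growth_rate_map].
#' @param threshold rate threshold (per week).
#' @param min_region_voxels smallest component kept.
#' @param connectivity 26 (default) or 6.
#' @return a `parcellation_map`: list with `labels` (integer array, 0 =
#'   background) and `table` (data frame id/name/n_voxels).
#' @export
threshold_parcellation <- function(gamma_av, threshold = 0.25,
                                   min_region_voxels = 27,
                                   connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  bin <- gamma_av$values >= threshold
  if (!any(bin)) {
    warning("no voxels at or above threshold ", threshold,
            "; returning an empty parcellation")
    return(structure(list(labels = array(0L, gamma_av$grid_shape),
                          table = data.frame(id = integer(), name = character(),
                                             n_voxels = integer()),
                          voxel_to_world = gamma_av$voxel_to_world),
                     class = "parcellation_map"))
  }
  raw <- cpp_label_components(array(as.integer(bin), dim(bin)),
                              as.integer(dim(bin)), as.integer(connectivity))
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_region_voxels)
  keep <- keep[order(-sizes[keep])]
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labels <- array(0L, dim(bin))
  nz <- raw > 0
  labels[nz] <- relab[raw[nz]]
  structure(list(labels = labels,
                 table = data.frame(id = seq_along(keep),
                                    name = sprintf("region_%02d",
                                                   seq_along(keep)),
                                    n_voxels = sizes[keep]),
                 voxel_to_world = gamma_av$voxel_to_world),
            class = "parcellation_map")
}

#' @export
print.parcellation_map <- function(x, ...) {
  cat(sprintf("<parcellation_map> %d regions, %d labelled voxels\n",
              nrow(x$table), sum(x$labels > 0)))
  invisible(x)
}

#' Robust per-region statistics
#'
#' For each region of a parcellation, computes the robust mean of a
#' subject's map: voxels deviating from the in-region mean by more than
#' `sd_threshold` population standard deviations are excluded and the mean
#' of the retained voxels reported (at least one voxel is always
#' retained).
#'
#' @param subject_map [scalar_image] in atlas space.
#' @param parcellation a `parcellation_map` on the same grid.
#' @param sd_threshold exclusion threshold in population SDs.
#' @param subject_id,age,ga_birth,group optional metadata copied into the
#'   output rows.
#' @param channel channel name recorded in the rows.
#' @return data frame: subject id, age, GA at birth, group, ROI id,
#'   channel, robust mean, voxels retained / total.
#' @export
roi_robust_stats <- function(subject_map, parcellation, sd_threshold = 1.5,
                             subject_id = NA_character_, age = NA_real_,
                             ga_birth = NA_real_, group = NA_character_,
                             channel = NA_character_) {
  if (!all(dim(subject_map$values) == dim(parcellation$labels)))
    stop("subject map and parcellation do not share a grid")
  ids <- parcellation$table$id
  rows <- lapply(ids, function(id) {
    v <- subject_map$values[parcellation$labels == id]
    if (length(v) == 0) {
      message("ROI ", id, " absent from the map; row skipped")
      return(NULL)
    }
    mu <- mean(v)
    sd_pop <- sqrt(mean((v - mu)^2))
    keep <- abs(v - mu) <= sd_threshold * sd_pop + 1e-9 * max(abs(mu), 1)
    data.frame(subject_id = subject_id, age = age, ga_birth = ga_birth,
               group = group, roi = id, channel = channel,
               robust_mean = mean(v[keep]), n_retained = sum(keep),
               n_voxels = length(v))
  })
  do.call(rbind, rows)
}

#' Linear-model association analysis over regions
#'
#' Per (ROI, channel) cell of the statistics table, fits the ordinary
#' linear model `robust_mean ~ ga_birth + age` and reports the coefficient
#' and p-value for gestational age at birth, Bonferroni-corrected over the
#' number of tests (`p_corrected = min(1, p * n_tests)`).
#'
#' @param table data frame as produced by [roi_robust_stats] rows bound
#'   over subjects (columns `robust_mean`, `ga_birth`, `age`, `roi`,
#'   `channel`).
#' @param min_subjects minimum rows per cell.
#' @return data frame: roi, channel, n, estimate, se, p_raw, p_bonferroni,
#'   estimable flag.
#' @export
association_analysis <- function(table, min_subjects = 10) {
  cells <- unique(table[, c("roi", "channel")])
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$roi == cells$roi[i] &
                   table$channel == cells$channel[i], ]
    out <- data.frame(roi = cells$roi[i], channel = cells$channel[i],
                      n = nrow(sub), estimate = NA_real_, se = NA_real_,
                      p_raw = NA_real_, estimable = FALSE)
    if (nrow(sub) < min_subjects) return(out)
    fit <- lm(robust_mean ~ ga_birth + age, data = sub)
    cf <- summary(fit)$coefficients
    if ("ga_birth" %in% rownames(cf) && is.finite(cf["ga_birth", 4])) {
      out$estimate <- cf["ga_birth", 1]
      out$se <- cf["ga_birth", 2]
      out$p_raw <- cf["ga_birth", 4]
      out$estimable <- TRUE
    }
    out
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- NA_real_
  res$p_bonferroni[res$estimable] <-
    p.adjust(res$p_raw[res$estimable], method = "bonferroni")
  res
}
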