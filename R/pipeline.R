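#' Cohort manifests
#'
#' A cohort manifest is a UTF-8 tab-separated table with columns
#' `subject_id`, `age` (weeks PMA), optional `ga_birth` (weeks GA at
#' birth), optional `group`, and one column per channel holding NIfTI file
#' paths (column name = channel name).
#'
#' @param path manifest file.
#' @return `read_manifest()`: the manifest data frame (validated).
#' @export
read_manifest <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  req <- c("subject_id", "age")
  if (!all(req %in% names(df)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  if (any(!is.finite(df$age)) || any(df$age <= 0))
    stop("ages must be positive numbers")
  ch_cols <- setdiff(names(df), c("subject_id", "age", "ga_birth", "group"))
  if (length(ch_cols) == 0) stop("manifest holds no channel columns")
  for (cc in ch_cols) {
    missing <- !file.exists(df[[cc]])
    if (any(missing))
      stop("manifest row(s) ", paste(which(missing), collapse = ", "),
           ": file not found for channel '", cc, "': ",
           df[[cc]][which(missing)[1]])
  }
  attr(df, "channel_columns") <- ch_cols
  df
}

#' @rdname read_manifest
#' @param df manifest data frame.
#' @export
write_manifest <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_manifest
#' @return `load_cohort()`: list of [channel_set], one per manifest row,
#'   with `ga_birth`/`group` attached as attributes.
#' @export
load_cohort <- function(path) {
  df <- if (is.data.frame(path)) path else read_manifest(path)
  ch_cols <- attr(df, "channel_columns")
  if (is.null(ch_cols))
    ch_cols <- setdiff(names(df), c("subject_id", "age", "ga_birth", "group"))
  lapply(seq_len(nrow(df)), function(i) {
    chans <- lapply(setNames(ch_cols, ch_cols), function(cc)
      read_channel(df[[cc]][i]))
    cs <- channel_set(df$subject_id[i], df$age[i], chans)
    attr(cs, "ga_birth") <- if ("ga_birth" %in% names(df)) df$ga_birth[i] else NA
    attr(cs, "group") <- if ("group" %in% names(df)) df$group[i] else NA
    cs
  })
}

#' Pipeline configuration
#'
#' Bundles the stage configurations; round-trips losslessly through YAML.
#'
#' @param atlas an [atlas_config].
#' @param parcellation_threshold rate threshold for the transient-region
#'   parcellation.
#' @param parcellation_min_voxels smallest component kept.
#' @param fit_channels channels to fit in time (`NULL` = all scalar
#'   channels).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(atlas = atlas_config(),
                            parcellation_threshold = 0.25,
                            parcellation_min_voxels = 27,
                            fit_channels = NULL, seed = 1L) {
  structure(list(atlas = atlas,
                 parcellation_threshold = parcellation_threshold,
                 parcellation_min_voxels = parcellation_min_voxels,
                 fit_channels = fit_channels, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg$atlas <- do.call(atlas_config, modifyList(
    raw$atlas,
    list(registration = do.call(registration_config, raw$atlas$registration))))
  cfg
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Run the full atlas pipeline
#'
#' Orchestrates the end-to-end construction: stage-1 registration of all
#' subjects to the reference and global template averaging; stage-2
#' multi-channel re-registration against the stage-1 templates with
#' age-windowed robust template averaging and unbiasing transforms;
#' Gompertz fitting of the scalar-channel templates and of the unbiasing
#' transforms (skipped with a message when fewer than 5 windows are
#' populated); optional transient-region parcellation. All outputs are
#' written as NIfTI / TSV under `out_dir` together with a YAML log echoing
#' the configuration and MD5 checksums of every written file. Re-running
#' with identical inputs reproduces identical checksums.
#'
#' @param cohort list of [channel_set] or a manifest path/data frame.
#' @param reference a [channel_set] (the stage-1 reference template).
#' @param config a [pipeline_config].
#' @param out_dir output directory (created).
#' @return invisible list with the stage results, fits, parcellation and
#'   the checksum table.
#' @export
run_pipeline <- function(cohort, reference, config = pipeline_config(),
                         out_dir) {
  if (!is.list(cohort) || is.data.frame(cohort))
    cohort <- load_cohort(cohort)
  stopifnot(inherits(reference, "channel_set"), length(cohort) >= 2)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  put <- function(img, ...) {
    p <- file.path(out_dir, sprintf(...))
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    write_channel(img, p)
    written <<- c(written, p)
    p
  }
  stage1 <- build_atlas_stage(cohort, reference, stage = 1,
                              config = config$atlas)
  ref2 <- templates_as_channelset(stage1$templates, age = reference$age)
  stage2 <- build_atlas_stage(cohort, ref2, stage = 2,
                              config = config$atlas)
  for (r in stage2$records) {
    put(r$warp_to_reference, "warps/%s_to_ref.nii.gz", r$subject_id)
    put(r$warp_from_reference, "warps/%s_from_ref.nii.gz", r$subject_id)
    put(jacobian_map(r$warp_to_reference), "warps/%s_jacobian.nii.gz",
        r$subject_id)
  }
  for (key in names(stage2$templates))
    for (nm in names(stage2$templates[[key]]))
      put(stage2$templates[[key]][[nm]], "templates/%s/%s.nii.gz", nm, key)
  for (key in names(stage2$unbias$warp)) {
    put(stage2$unbias$warp[[key]], "unbias/warp_%s.nii.gz", key)
    p <- file.path(out_dir, sprintf("unbias/affine_%s.txt", key))
    write.table(stage2$unbias$affine[[key]]$matrix, p, row.names = FALSE,
                col.names = FALSE)
    written <- c(written, p)
  }
  keys <- names(stage2$templates)
  centers <- as.numeric(keys)
  fits <- NULL; tf_fits <- NULL; parc <- NULL
  if (length(keys) >= 5) {
    ch1 <- stage2$records[[1]]$channelset$channels
    fit_ch <- config$fit_channels
    if (is.null(fit_ch))
      fit_ch <- names(ch1)[vapply(names(ch1), function(nm)
        identical(attr(ch1[[nm]], "role"), "intensity"), logical(1))]
    fits <- lapply(setNames(fit_ch, fit_ch), function(nm)
      fit_gompertz_maps(centers,
                        lapply(keys, function(k) stage2$templates[[k]][[nm]])))
    for (nm in names(fits))
      for (par in c("alpha", "delta", "gamma", "tau", "r_squared"))
        put(scalar_image(fits[[nm]][[par]], fits[[nm]]$voxel_to_world),
            "gompertz/%s_%s.nii.gz", nm, par)
    sub_unbias <- list(warp = stage2$unbias$warp[keys],
                       affine = stage2$unbias$affine[keys])
    tf_fits <- fit_gompertz_warps(centers, sub_unbias)
    gmaps <- lapply(fits, function(f)
      scalar_image(f$gamma, f$voxel_to_world))
    gav <- average_growth_rate_map(gmaps)
    put(gav, "parcellation/gamma_av.nii.gz")
    parc <- threshold_parcellation(gav, config$parcellation_threshold,
                                   config$parcellation_min_voxels)
    put(scalar_image(array(as.double(parc$labels), dim(parc$labels)),
                     parc$voxel_to_world), "parcellation/labels.nii.gz")
    p <- file.path(out_dir, "parcellation/labels.tsv")
    write.table(parc$table, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, p)
  } else {
    message("only ", length(keys),
            " populated windows; temporal fitting skipped (needs >= 5)")
  }
  checks <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", written),
                       md5 = unname(tools::md5sum(written)))
  write.table(checks, file.path(out_dir, "checksums.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  log <- list(config = unclass_deep(config),
              n_subjects = length(cohort),
              skipped = c(stage1$skipped, stage2$skipped),
              windows = lapply(stage2$windows, function(w)
                list(center = w$center, n = length(w$members))))
  yaml::write_yaml(log, file.path(out_dir, "log.yaml"))
  invisible(list(stage1 = stage1, stage2 = stage2, fits = fits,
                 transform_fits = tf_fits, parcellation = parc,
                 checksums = checks))
}
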