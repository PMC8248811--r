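#' Atlas construction configuration
#'
#' @param window_centers age-window centers in weeks PMA; the standard
#'   atlas uses the arithmetic sequence 37.0, 37.5, ..., 44.0 (15 windows
#'   of 0.5 weeks).
#' @param sd_threshold robust-averaging exclusion threshold, in population
#'   standard deviations.
#' @param registration a [registration_config] used for the per-subject
#'   registrations.
#' @param do_affine run global-NCC affine pre-alignment before the
#'   non-linear registration (off by default: phantom cohorts are generated
#'   affinely aligned; enable for data with bulk pose/size differences).
#' @param resolution_mm optional isotropic output resolution; `NULL` keeps
#'   the reference grid.
#' @param min_window_subjects windows retaining fewer subjects than this
#'   are reported as deficient.
#' @return an `atlas_config` list.
#' @export
atlas_config <- function(window_centers = seq(37, 44, by = 0.5),
                         sd_threshold = 1.5,
                         registration = registration_config(),
                         do_affine = FALSE,
                         resolution_mm = NULL,
                         min_window_subjects = 2) {
  structure(list(window_centers = window_centers,
                 sd_threshold = sd_threshold, registration = registration,
                 do_affine = do_affine, resolution_mm = resolution_mm,
                 min_window_subjects = min_window_subjects),
            class = "atlas_config")
}

#' Assign subjects to age windows
#'
#' Each subject goes to the window whose center is nearest its age; exact
#' midpoints go to the younger window. Windows are disjoint.
#'
#' @param ages numeric vector of ages (weeks PMA).
#' @param centers window centers, ascending.
#' @return list of `age_window` entries: `center` and integer `members`
#'   (indices into `ages`; possibly empty).
#' @export
assign_age_windows <- function(ages, centers = seq(37, 44, by = 0.5)) {
  if (any(ages < min(centers) - 0.25 | ages > max(centers) + 0.25))
    warning("some ages fall outside the window range [",
            min(centers), ", ", max(centers), "]")
  pick <- vapply(ages, function(a) {
    d <- abs(centers - a)
    which(d <= min(d) + 1e-12)[1]   # ties resolve to the younger center
  }, integer(1))
  lapply(seq_along(centers), function(i)
    structure(list(center = centers[i], members = which(pick == i)),
              class = "age_window"))
}

#' Robust weighted averaging across subjects
#'
#' Voxelwise (per coefficient for SH images) across the input images:
#' values deviating from the across-subject mean by more than
#' `sd_threshold` population standard deviations get weight 0, all others
#' weight 1, and the template is the weighted mean. At least one subject is
#' always retained at every voxel (not all deviations can exceed 1.5 SD),
#' and a zero-variance voxel retains everyone.
#'
#' @param images list (>= 2) of [scalar_image] or [sh_image] on a shared
#'   grid.
#' @param sd_threshold exclusion threshold in population SDs.
#' @return list with `template` (same class as the inputs) and `retention`
#'   (list of binary weight arrays, one per input).
#' @export
robust_weighted_average <- function(images, sd_threshold = 1.5) {
  n <- length(images)
  if (n < 2) stop("robust averaging needs at least 2 images")
  is_sh <- inherits(images[[1]], "sh_image")
  get_arr <- function(img) if (is_sh) img$coeffs else img$values
  d <- dim(get_arr(images[[1]]))
  X <- vapply(images, function(im) as.double(get_arr(im)),
              numeric(prod(d)))
  mu <- rowMeans(X)
  dev <- abs(X - mu)
  sd_pop <- sqrt(rowMeans(dev^2))     # population SD, centred (no cancellation)
  w <- (dev <= sd_threshold * sd_pop + 1e-9 * pmax(abs(mu), 1)) * 1.0
  wsum <- rowSums(w)
  tmpl <- rowSums(X * w) / wsum
  retention <- lapply(seq_len(n), function(i) array(w[, i], d))
  template <- if (is_sh) {
    sh_image(array(tmpl, d), images[[1]]$lmax, images[[1]]$voxel_to_world)
  } else scalar_image(array(tmpl, d), images[[1]]$voxel_to_world)
  list(template = template, retention = retention)
}

#' Average inverse warp of a window
#'
#' Voxelwise arithmetic mean of the inverted warps, the non-linear part of
#' the unbiasing transform from the age-specific average space back to the
#' global reference space.
#'
#' @param warps list of [displacement_field] on the reference grid.
#' @return the average inverse [displacement_field].
#' @export
average_inverse_warp <- function(warps) {
  if (length(warps) == 0) stop("no warps to average")
  inv <- lapply(warps, invert_warp)
  acc <- inv[[1]]$vectors
  for (i in seq_along(inv)[-1]) acc <- acc + inv[[i]]$vectors
  displacement_field(acc / length(inv), warps[[1]]$voxel_to_world)
}

# matrix log / exp / sqrt of a symmetric positive-definite 3x3
sym_fun <- function(S, f) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(f(e$values)) %*% t(e$vectors)
}

#' Average inverse affine (scale/shear only)
#'
#' Decomposes each linear part by polar decomposition `A = R S`, averages
#' the symmetric stretch factors `S` in matrix-logarithm space, and inverts
#' the average. Rotation and translation are discarded.
#'
#' @param affines list of [affine_transform].
#' @return an [affine_transform] with flags `c("scale", "shear")`.
#' @export
average_inverse_affine <- function(affines) {
  if (length(affines) == 0) stop("no affines to average")
  acc <- matrix(0, 3, 3)
  for (a in affines) {
    L <- a$matrix[1:3, 1:3]
    S <- sym_fun(crossprod(L), sqrt)       # (L'L)^(1/2), the stretch factor
    acc <- acc + sym_fun(S, log)
  }
  Sinv <- sym_fun(acc / length(affines), function(v) exp(-v))
  M <- diag(4)
  M[1:3, 1:3] <- Sinv
  affine_transform(M, flags = c("scale", "shear"))
}

# rescale a subject's ODF channel so its mean l=0 coefficient inside the
# mask equals `target`
normalize_odf_channel <- function(cs, target, mask_channel = "cortex_mask") {
  odf_names <- names(cs$channels)[vapply(cs$channels, inherits,
                                         logical(1), "sh_image")]
  for (nm in odf_names) {
    ch <- cs$channels[[nm]]
    m <- odf_l0_mean(ch)
    if (m > 0) ch$coeffs <- ch$coeffs * (target / m)
    attr(ch, "role") <- "odf"
    cs$channels[[nm]] <- ch
  }
  cs
}

odf_l0_mean <- function(sh) {
  l0 <- sh$coeffs[, , , 1]
  mean(l0[l0 > 0.01 * max(l0)])
}

#' Build one atlas stage
#'
#' Stage 1 registers every subject to a single reference using the scalar
#' and mask channels only and builds one global robust-average template per
#' channel. Stage 2 first globally rescales each subject's ODF channel to
#' the cohort median `l = 0` level, re-registers with scalar, mask and ODF
#' channels against the supplied (stage-1) template set, and then produces
#' age-windowed robust templates plus the per-window unbiasing transforms
#' (average inverse warp, and scale/shear-only average inverse affine).
#'
#' @param cohort list of [channel_set].
#' @param reference a [channel_set] providing the stage's driver channels
#'   (for stage 2, pass the stage-1 template set).
#' @param stage 1 or 2.
#' @param config an [atlas_config].
#' @return list with `records` (per subject: warps, affine, age), and
#'   `templates`; stage 2 adds `windows` and `unbias`.
#' @export
build_atlas_stage <- function(cohort, reference, stage = 1,
                              config = atlas_config()) {
  stopifnot(length(cohort) >= 1, stage %in% c(1, 2))
  if (stage == 2) {
    l0s <- vapply(cohort, function(cs) {
      sh <- Filter(function(ch) inherits(ch, "sh_image"), cs$channels)
      if (length(sh) == 0) NA_real_ else odf_l0_mean(sh[[1]])
    }, numeric(1))
    target <- median(l0s, na.rm = TRUE)
    if (is.finite(target))
      cohort <- lapply(cohort, normalize_odf_channel, target = target)
  }
  driver_roles <- if (stage == 1) c("intensity", "mask")
                  else c("intensity", "mask", "odf")
  ref_use <- driver_subset(reference, driver_roles)
  records <- list(); skipped <- list()
  for (i in seq_along(cohort)) {
    cs <- cohort[[i]]
    rec <- tryCatch({
      aff <- if (config$do_affine) {
        drv <- names(ref_use$channels)[vapply(ref_use$channels, function(ch)
          !inherits(ch, "sh_image") && !inherits(ch, "mask_image"),
          logical(1))][1]
        affine_register(ref_use, cs, drv)
      } else affine_transform(diag(4))
      cs_aligned <- if (config$do_affine)
        apply_affine_channelset(cs, aff,
                                grid = list(grid_shape = ref_use$channels[[1]]$grid_shape,
                                            voxel_to_world = ref_use$channels[[1]]$voxel_to_world))
      else cs
      mv <- driver_subset(cs_aligned, driver_roles)
      reg <- register_multichannel(ref_use, mv, config$registration)
      list(channelset = cs_aligned, age = cs$age,
           subject_id = cs$subject_id,
           affine_to_reference = aff,
           warp_to_reference = reg$warp_moving_to_fixed,
           warp_from_reference = reg$warp_fixed_to_moving,
           log = reg$log)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      skipped[[cs$subject_id]] <- conditionMessage(rec)
      message("skipping subject ", cs$subject_id, ": ",
              conditionMessage(rec))
    } else records[[length(records) + 1]] <- rec
  }
  if (length(records) < 2)
    stop("fewer than 2 subjects registered successfully")
  # warp every channel of every subject into reference space
  warped <- lapply(records, function(r)
    warp_channelset(r$channelset, r$warp_to_reference))
  ch_names <- names(warped[[1]]$channels)
  if (stage == 1) {
    templates <- lapply(setNames(ch_names, ch_names), function(nm) {
      ra <- robust_weighted_average(lapply(warped, function(w)
        as_plain_image(w$channels[[nm]])), config$sd_threshold)
      out <- ra$template
      attr(out, "role") <- attr(records[[1]]$channelset$channels[[nm]], "role")
      out
    })
    return(list(stage = 1, records = records, templates = templates,
                skipped = skipped))
  }
  ages <- vapply(records, `[[`, numeric(1), "age")
  windows <- assign_age_windows(ages, config$window_centers)
  deficient <- vapply(windows, function(w)
    length(w$members) > 0 && length(w$members) < config$min_window_subjects,
    logical(1))
  if (any(deficient))
    message(sum(deficient), " window(s) hold fewer than ",
            config$min_window_subjects, " subjects")
  templates <- list(); unbias_warp <- list(); unbias_affine <- list()
  weights <- list()
  for (wi in seq_along(windows)) {
    mem <- windows[[wi]]$members
    key <- sprintf("%.1f", windows[[wi]]$center)
    if (length(mem) < 1) next
    templates[[key]] <- lapply(setNames(ch_names, ch_names), function(nm) {
      if (length(mem) == 1) {
        # a single-subject window cannot reject outliers; the template is
        # that subject's warped map with full retention
        tpl <- as_plain_image(warped[[mem]]$channels[[nm]])
        arr <- if (inherits(tpl, "sh_image")) tpl$coeffs else tpl$values
        attr(tpl, "retention") <- list(array(1, dim(arr)))
      } else {
        ra <- robust_weighted_average(lapply(warped[mem], function(w)
          as_plain_image(w$channels[[nm]])), config$sd_threshold)
        tpl <- ra$template
        attr(tpl, "retention") <- ra$retention
      }
      attr(tpl, "role") <-
        attr(records[[1]]$channelset$channels[[nm]], "role")
      tpl
    })
    unbias_warp[[key]] <- average_inverse_warp(
      lapply(records[mem], `[[`, "warp_to_reference"))
    unbias_affine[[key]] <- average_inverse_affine(
      lapply(records[mem], `[[`, "affine_to_reference"))
  }
  list(stage = 2, records = records, templates = templates,
       windows = windows,
       unbias = list(warp = unbias_warp, affine = unbias_affine),
       skipped = skipped)
}

#' Assemble a template channel set
#'
#' Wraps a stage-1 template list (or one window of a stage-2 result) as a
#' [channel_set], e.g. to serve as the reference of the next stage.
#'
#' @param templates named list of template images carrying `role`
#'   attributes.
#' @param age nominal age tag for the set.
#' @param id id string.
#' @return a [channel_set].
#' @export
templates_as_channelset <- function(templates, age = 40, id = "template") {
  channel_set(id, age, templates)
}

# strip the mask class so robust averaging yields a soft template map
as_plain_image <- function(img) {
  if (inherits(img, "mask_image")) {
    out <- scalar_image(img$values, img$voxel_to_world)
    attr(out, "role") <- "mask"
    out
  } else img
}

driver_subset <- function(cs, roles) {
  keep <- vapply(names(cs$channels), function(nm)
    attr(cs$channels[[nm]], "role") %in% roles, logical(1))
  channel_set(cs$subject_id, cs$age, cs$channels[keep])
}
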