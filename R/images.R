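#' Image containers
#'
#' Light-weight S3 containers for the volumes the pipeline moves around:
#' `scalar_image` (3D real channel), `mask_image` (binary channel),
#' `sh_image` (4D grid of real even-order SH coefficient vectors, see
#' [real_sh_basis] for the convention) and `displacement_field` (per-voxel
#' world-mm 3-vectors on a reference grid). All carry a `voxel_to_world`
#' 4 x 4 affine (mm, RAS axes, 0-based voxel indices).
#'
#' @param values 3D numeric array.
#' @param voxel_to_world 4 x 4 affine mapping 0-based voxel indices to world
#'   mm; defaults to identity spacing 1 mm.
#' @return an object of the corresponding class.
#' @export
scalar_image <- function(values, voxel_to_world = diag(4)) {
  values <- as.array(values)
  stopifnot(length(dim(values)) == 3)
  check_affine(voxel_to_world)
  structure(list(values = values, grid_shape = dim(values),
                 voxel_to_world = voxel_to_world),
            class = "scalar_image")
}

#' @rdname scalar_image
#' @export
mask_image <- function(values, voxel_to_world = diag(4)) {
  values <- as.array(values)
  if (!all(values %in% c(0, 1)))
    stop("mask values must be binary 0/1")
  img <- scalar_image(values, voxel_to_world)
  class(img) <- c("mask_image", "scalar_image")
  img
}

#' @rdname scalar_image
#' @param coeffs 4D numeric array, 4th dimension indexing SH coefficients in
#'   the package order.
#' @param lmax even SH order; inferred from the coefficient count if missing.
#' @export
sh_image <- function(coeffs, lmax = NULL, voxel_to_world = diag(4)) {
  coeffs <- as.array(coeffs)
  stopifnot(length(dim(coeffs)) == 4)
  if (is.null(lmax)) lmax <- sh_lmax_from_n(dim(coeffs)[4])
  if (is.na(lmax)) stop("4th dimension (", dim(coeffs)[4],
                        ") matches no even-degree SH coefficient count")
  check_lmax(lmax)
  if (dim(coeffs)[4] != sh_n_coef(lmax))
    stop("coefficient count ", dim(coeffs)[4], " does not match lmax ", lmax)
  if (!all(is.finite(coeffs))) stop("SH coefficients must be finite")
  check_affine(voxel_to_world)
  structure(list(coeffs = coeffs, lmax = as.integer(lmax),
                 grid_shape = dim(coeffs)[1:3],
                 voxel_to_world = voxel_to_world),
            class = "sh_image")
}

#' @rdname scalar_image
#' @param vectors 4D numeric array `(nx, ny, nz, 3)` of world-mm
#'   displacements.
#' @export
displacement_field <- function(vectors, voxel_to_world = diag(4)) {
  vectors <- as.array(vectors)
  stopifnot(length(dim(vectors)) == 4, dim(vectors)[4] == 3)
  if (!all(is.finite(vectors))) stop("displacement field must be finite")
  check_affine(voxel_to_world)
  structure(list(vectors = vectors, grid_shape = dim(vectors)[1:3],
                 voxel_to_world = voxel_to_world),
            class = "displacement_field")
}

check_affine <- function(M) {
  if (!is.matrix(M) || !all(dim(M) == c(4, 4)) || !all(is.finite(M)) ||
      abs(det(M)) < 1e-12)
    stop("voxel_to_world must be an invertible finite 4x4 affine")
  invisible(M)
}

#' @rdname scalar_image
#' @param matrix 4 x 4 affine matrix (mm), last row (0, 0, 0, 1).
#' @param flags character subset of `c("rotation", "scale", "shear",
#'   "translation")` recording which components the transform carries.
#' @export
affine_transform <- function(matrix = diag(4),
                             flags = c("rotation", "scale", "shear",
                                       "translation")) {
  check_affine(matrix)
  if (max(abs(matrix[4, ] - c(0, 0, 0, 1))) > 1e-10)
    stop("last affine row must be (0,0,0,1)")
  structure(list(matrix = matrix, flags = flags), class = "affine_transform")
}

#' @rdname scalar_image
#' @param subject_id character id.
#' @param age postmenstrual age at scan in weeks, sanity range 20-50.
#' @param channels named list of images; each entry must carry a `role`
#'   attribute in `c("intensity", "odf", "mask")` (set automatically for
#'   `mask_image`/`sh_image` inputs).
#' @export
channel_set <- function(subject_id, age, channels) {
  if (length(channels) == 0 || is.null(names(channels)) ||
      any(names(channels) == ""))
    stop("channels must be a non-empty named list")
  if (age < 20 || age > 50)
    stop("age ", age, " weeks outside the sanity range [20, 50]")
  g <- NULL; M <- NULL
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(attr(ch, "role")))
      attr(channels[[nm]], "role") <- default_role(ch)
    if (is.null(g)) { g <- ch$grid_shape; M <- ch$voxel_to_world }
    if (!all(ch$grid_shape == g) ||
        max(abs(ch$voxel_to_world - M)) > 1e-6)
      stop("channel '", nm, "' does not share the common grid")
  }
  structure(list(subject_id = subject_id, age = age, channels = channels),
            class = "channel_set")
}

default_role <- function(img) {
  if (inherits(img, "sh_image")) "odf"
  else if (inherits(img, "mask_image")) "mask"
  else "intensity"
}

channel_role <- function(cs, name) attr(cs$channels[[name]], "role")

#' @export
print.scalar_image <- function(x, ...) {
  cat(sprintf("<%s> %s, spacing %s mm\n", class(x)[1],
              paste(x$grid_shape, collapse = "x"),
              paste(signif(voxel_spacing(x), 4), collapse = "x")))
  invisible(x)
}

#' @export
print.sh_image <- function(x, ...) {
  cat(sprintf("<sh_image> %s, lmax %d (%d coefficients)\n",
              paste(x$grid_shape, collapse = "x"), x$lmax,
              sh_n_coef(x$lmax)))
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(rowSums(matrix(x$vectors, ncol = 3)^2))
  cat(sprintf("<displacement_field> %s, |u| mean %.3g max %.3g mm\n",
              paste(x$grid_shape, collapse = "x"), mean(mag), max(mag)))
  invisible(x)
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set> subject %s, age %.2f weeks\n", x$subject_id,
              x$age))
  for (nm in names(x$channels))
    cat(sprintf("  %-12s [%s]\n", nm, channel_role(x, nm)))
  invisible(x)
}

#' Voxel spacing of an image
#' @param img any package image object.
#' @return numeric length-3, mm per voxel step along each grid axis.
#' @export
voxel_spacing <- function(img) {
  M <- img$voxel_to_world[1:3, 1:3]
  sqrt(colSums(M^2))
}

# world coordinates (n x 3) of all voxels of a grid, 0-based indices
grid_world_coords <- function(grid_shape, voxel_to_world) {
  idx <- as.matrix(expand.grid(x = seq_len(grid_shape[1]) - 1,
                               y = seq_len(grid_shape[2]) - 1,
                               z = seq_len(grid_shape[3]) - 1))
  sweep(idx %*% t(voxel_to_world[1:3, 1:3]), 2,
        voxel_to_world[1:3, 4], "+")
}

world_to_voxel <- function(world, voxel_to_world) {
  Minv <- solve(voxel_to_world)
  sweep(world %*% t(Minv[1:3, 1:3]), 2, Minv[1:3, 4], "+")
}

#' Read and write channel volumes as NIfTI
#'
#' Scalar and mask channels are stored as 3D NIfTI; SH channels as 4D NIfTI
#' with the 4th dimension indexing coefficients in the package SH order;
#' displacement fields as 4D NIfTI with 3 world-mm components. The header
#' description field tags the role (`mcatlas:odf lmax=L`, `mcatlas:mask`,
#' `mcatlas:warp`, `mcatlas:scalar`) so round trips recover the type; on
#' untagged files the role is inferred from dimensionality (a 4D volume
#' count that matches no even lmax and is not 3 is a format error).
#'
#' @param img image object to write.
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @export
write_channel <- function(img, path) {
  if (inherits(img, "sh_image")) {
    arr <- img$coeffs; tag <- sprintf("mcatlas:odf lmax=%d", img$lmax)
  } else if (inherits(img, "displacement_field")) {
    arr <- img$vectors; tag <- "mcatlas:warp"
  } else if (inherits(img, "mask_image")) {
    arr <- img$values; tag <- "mcatlas:mask"
  } else if (inherits(img, "scalar_image")) {
    arr <- img$values; tag <- "mcatlas:scalar"
  } else stop("unsupported image class: ", class(img)[1])
  nif <- RNifti::asNifti(arr, reference = list(descrip = tag))
  nif <- RNifti::`sform<-`(nif, structure(img$voxel_to_world, code = 2L))
  RNifti::writeNifti(nif, path)
  invisible(path)
}

#' @rdname write_channel
#' @param path file to read.
#' @param expected_role one of `"auto"`, `"intensity"`, `"mask"`, `"odf"`,
#'   `"warp"`; non-`auto` values assert the stored role.
#' @export
read_channel <- function(path, expected_role = "auto") {
  nif <- RNifti::readNifti(path)
  M <- unclass(RNifti::xform(nif))
  attributes(M) <- list(dim = dim(M))
  if (abs(det(M)) < 1e-12) stop("non-invertible affine in NIfTI header")
  hdr <- RNifti::niftiHeader(nif)
  tag <- sub("^mcatlas:", "", hdr$descrip[1])
  arr <- as.array(nif)
  attributes(arr) <- list(dim = dim(arr))   # drop RNifti header attributes
  nd <- length(dim(arr))
  role <- if (grepl("^odf", tag)) "odf"
          else if (tag == "mask") "mask"
          else if (tag == "warp") "warp"
          else if (tag == "scalar") "intensity"
          else if (nd == 3) "intensity"
          else if (nd == 4 && dim(arr)[4] == 3) "warp"
          else "odf"
  if (expected_role != "auto" && expected_role != role)
    stop("file ", path, " holds role '", role, "', expected '",
         expected_role, "'")
  if (role == "odf") {
    if (nd != 4) stop("ODF channel must be 4D NIfTI")
    lmax <- sh_lmax_from_n(dim(arr)[4])
    if (is.na(lmax))
      stop("4D volume count ", dim(arr)[4],
           " matches no even-lmax SH coefficient count")
    sh_image(arr, lmax, M)
  } else if (role == "warp") {
    displacement_field(arr, M)
  } else if (role == "mask") {
    mask_image(round(arr), M)
  } else {
    if (nd != 3) stop("scalar channel must be 3D NIfTI")
    scalar_image(arr, M)
  }
}
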