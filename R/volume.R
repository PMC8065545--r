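#' 3D image volume with physical voxel spacing
#'
#' Lightweight container for a scalar 3D grid on an anisotropic voxel lattice,
#' the common currency of the pipeline (T2w signal, DWI signal at one b-value,
#' or an ADC map in mm^2/s).
#'
#' @param intensities numeric 3D array of voxel values.
#' @param spacing_mm numeric length-3, voxel size along each axis in mm.
#' @param origin numeric length-3, physical position (mm) of the first voxel
#'   centre. Only carried through I/O; no computation depends on it.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm, origin = c(0, 0, 0)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite numbers", call. = FALSE)
  if (any(!is.finite(intensities)))
    stop("`intensities` contains non-finite values", call. = FALSE)
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         origin = as.numeric(origin)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %d x %d x %d voxels, spacing (%.3g, %.3g, %.3g) mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$intensities)

is_image_volume <- function(x) inherits(x, "image_volume")

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$intensities), dim(b$intensities)))
    stop(sprintf("grid mismatch between %s: %s vs %s", what,
                 paste(dim(a$intensities), collapse = "x"),
                 paste(dim(b$intensities), collapse = "x")), call. = FALSE)
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stop(sprintf("spacing mismatch between %s", what), call. = FALSE)
  invisible(TRUE)
}

#' Read / write a volume as NIfTI
#'
#' Thin wrappers over RNifti that carry the voxel spacing through the pixdim
#' header field. Masks are written as 0/1 integer volumes.
#'
#' @param x an `image_volume` (or 3D 0/1 array for masks).
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns an `image_volume`; `write_volume` the path,
#'   invisibly.
#' @export
write_volume <- function(x, path) {
  if (is_image_volume(x)) {
    img <- RNifti::asNifti(x$intensities, reference = NULL)
    RNifti::pixdim(img) <- x$spacing_mm
  } else {
    img <- RNifti::asNifti(array(as.integer(x), dim = dim(x)))
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @param spacing_mm spacing override for mask files written without one.
#' @export
read_volume <- function(path, spacing_mm = NULL) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  if (!is.null(spacing_mm)) sp <- spacing_mm
  image_volume(array(as.numeric(img), dim = dim(img)[1:3]), sp)
}

read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img)[1:3])
}
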