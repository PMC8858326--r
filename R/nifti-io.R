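# CT volume container and NIfTI I/O --------------------------------------

#' Construct a CT volume object
#'
#' Minimal container for a 3-D intensity grid on a Hounsfield-unit-like
#' scale. Axis convention (used by every imaging function in this package):
#' axis 1 is left-right with the index increasing towards patient-left,
#' axis 2 is posterior-anterior, axis 3 runs through the axial slices.
#'
#' @param data numeric 3-D array of intensities.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(data, spacing = c(1.5, 1.5, 3.0)) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop_config("CT intensities must be finite")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_config("voxel spacing must be three positive numbers")
  structure(list(data = data, spacing = as.numeric(spacing),
                 orientation = "axis1=+left, axis2=+anterior, axis3=+superior"),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.1f, %.1f] HU\n",
              min(x$data), max(x$data)))
  invisible(x)
}

voxel_volume_ml <- function(spacing) prod(spacing) / 1000

#' Write / read a CT volume as NIfTI-1
#'
#' Intensities are stored as 32-bit floats; spacing is carried in the NIfTI
#' pixdim. Round-trips preserve intensities to stored precision.
#'
#' @param vol a [ct_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   `ct_volume`.
#' @export
write_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_config("no such file: %s", path)
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) {
      stop_config("failed to parse NIfTI file '%s' (size %d bytes): %s",
                  path, file.info(path)$size, conditionMessage(e))
    }
  )
  ct_volume(as.array(img), spacing = RNifti::pixdim(img)[1:3])
}
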