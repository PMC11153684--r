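#' 3D scalar volume with voxel spacing
#'
#' Lightweight container for a gray-scale CT-like volume: a 3D numeric array
#' plus the physical voxel spacing in mm per axis. World coordinates are
#' `(voxel index) * spacing` with 0-based indices and axis order (x, y, z).
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @return An object of class `volume_image` with elements `data` and `spacing`.
#' @examples
#' v <- volume_image(array(0, c(16, 16, 16)), spacing = c(1, 1, 2.5))
#' dim(v$data)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)")
  structure(list(data = data, spacing = spacing), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Read / write volumes as NIfTI
#'
#' `read_volume()` loads a `.nii`/`.nii.gz` file into a [volume_image()];
#' `write_volume()` writes one back. Data, shape and voxel spacing round-trip
#' exactly (volumes are stored as float64).
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume()` returns a `volume_image`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(dim(img)) != 3) stop("expected a 3D NIfTI volume, got ",
                                  length(dim(img)), " dimensions")
  arr <- array(as.numeric(img), dim = dim(img)) # plain array, no NIfTI attrs
  volume_image(arr, spacing = RNifti::pixdim(img)[1:3])
}

#' @param volume a [volume_image()] (or bare 3D array for `write_volume()`).
#' @param spacing voxel spacing used when `volume` is a bare array.
#' @rdname read_volume
#' @export
write_volume <- function(volume, path, spacing = NULL) {
  if (is.array(volume)) volume <- volume_image(volume, spacing %||% c(1, 1, 1))
  img <- RNifti::asNifti(volume$data + 0) # force double storage
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
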