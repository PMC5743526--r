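#' 3-D image volume
#'
#' Lightweight container for a 3-D scalar field together with its voxel
#' spacing and the main-field (B0) axis. Susceptibility and field maps are
#' carried in ppm, phase in radians; the container itself is unit-agnostic.
#'
#' @param data 3-D numeric array (all dimensions must be at least 4).
#' @param voxel_size voxel edge lengths in mm, length 1 or 3, strictly
#'   positive.
#' @param b0_axis direction of the main magnetic field; normalized
#'   internally. Default +z.
#' @return An object of class `vol3d`: a list with elements `data`,
#'   `voxel_size` and `b0_axis`.
#' @export
vol3d <- function(data, voxel_size = c(1, 1, 1), b0_axis = c(0, 0, 1)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) {
    stop("vol3d requires a 3-D array, got ", length(dim(data)), " dimensions")
  }
  if (any(dim(data) < 4L)) {
    stop("all volume dimensions must be >= 4")
  }
  if (!is.numeric(data) || anyNA(data)) {
    stop("volume data must be numeric and free of NA")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive lengths (mm)")
  }
  b0_axis <- as.numeric(b0_axis)
  nb <- sqrt(sum(b0_axis^2))
  if (length(b0_axis) != 3L || !is.finite(nb) || nb == 0) {
    stop("b0_axis must be a non-zero 3-vector")
  }
  structure(
    list(data = data, voxel_size = voxel_size, b0_axis = b0_axis / nb),
    class = "vol3d"
  )
}

#' Coerce to a volume
#'
#' Arrays are wrapped with the supplied metadata; existing volumes are
#' returned unchanged.
#'
#' @inheritParams vol3d
#' @param x array or `vol3d`.
#' @return A `vol3d`.
#' @export
as_vol3d <- function(x, voxel_size = c(1, 1, 1), b0_axis = c(0, 0, 1)) {
  if (inherits(x, "vol3d")) x else vol3d(x, voxel_size, b0_axis)
}

#' Extract the data array of a volume
#'
#' @param x a `vol3d` or a plain array (returned as-is).
#' @return The underlying 3-D array.
#' @export
vol_data <- function(x) {
  if (inherits(x, "vol3d")) x$data else x
}

# voxel size of a volume, or a fallback for bare arrays
vox_of <- function(x, default = c(1, 1, 1)) {
  if (inherits(x, "vol3d")) x$voxel_size else default
}

# rebuild a volume around new data, keeping metadata from a template
vol_like <- function(data, template, voxel_size = NULL) {
  if (inherits(template, "vol3d")) {
    vol3d(data, if (is.null(voxel_size)) template$voxel_size else voxel_size,
          template$b0_axis)
  } else {
    data
  }
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<vol3d> %d x %d x %d voxels, %.3g x %.3g x %.3g mm, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}
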