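# NIfTI I/O and structured-text configuration.
# Conventions: ppm for susceptibility, radians for phase, axis order
# (x, y, z) with B0 along +z unless stated; 1-based voxel indexing in R.

#' Read a 3-D NIfTI volume
#'
#' @param path NIfTI-1 file (`.nii` or `.nii.gz`).
#' @param b0_axis main-field axis to record on the volume.
#' @return A [vol3d()] with voxel size taken from the header.
#' @export
read_volume <- function(path, b0_axis = c(0, 0, 1)) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) {
    a <- array(a, dim(a)[1:3])
  }
  if (length(dim(a)) != 3L) {
    stop("expected a 3-D NIfTI volume, got ", length(dim(a)), " dimensions")
  }
  a <- array(as.numeric(a), dim(a)) # drop image-class attributes
  vsz <- RNifti::pixdim(img)[1:3]
  vol3d(a, vsz, b0_axis)
}

#' Write a volume as NIfTI-1
#'
#' Voxel size is stored in the header `pixdim`; the k-space grid
#' convention used throughout the package (DC at the corner) is recorded
#' in the header description.
#'
#' @param vol a [vol3d()] or 3-D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  vol <- as_vol3d(vol)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size
  img$descrip <- "mudick: DC-at-corner k-space convention"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Load phantom and reconstruction configuration
#'
#' Reads a YAML file with optional `phantom:` and `recon:` sections whose
#' keys mirror the arguments of [phantom_spec()] and [recon_config()]
#' bit-exactly. An empty (or missing-section) file yields the calibrated
#' defaults; unknown sections or keys are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return List with elements `phantom` (a `phantom_spec`) and `recon`
#'   (a `recon_config`).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping")
  bad <- setdiff(names(raw), c("phantom", "recon"))
  if (length(bad)) {
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "))
  }
  check_keys <- function(x, fun, what) {
    if (is.null(x)) return(list())
    if (!is.list(x)) stop(what, " section must be a mapping")
    # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back to the
    # grid-size argument of phantom_spec()
    names(x)[names(x) == "FALSE"] <- "n"
    allowed <- names(formals(fun))
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
    }
    x
  }
  ph <- check_keys(raw$phantom, phantom_spec, "phantom")
  rc <- check_keys(raw$recon, recon_config, "recon")
  list(
    phantom = do.call(phantom_spec, ph),
    recon = do.call(recon_config, rc)
  )
}
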