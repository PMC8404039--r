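#' SUVr map container
#'
#' A lightweight container for a standardised uptake value ratio (SUVr) map:
#' a 3D lattice of unitless, non-negative values together with its voxel size
#' and an alignment tag.  Reduced representations keep degenerate trailing
#' dimensions, so a 2D slice has shape `c(91, 109, 1)` and a 1D profile
#' `c(91, 1, 1)`.
#'
#' @param values numeric array with up to three dimensions; coerced to 3D by
#'   appending unit dimensions.
#' @param voxel_size_mm positive scalar, isotropic voxel edge length in mm.
#' @param space alignment tag, `"template-aligned"` or `"native/misaligned"`.
#' @return An object of class `suvr_map`.
#' @examples
#' m <- suvr_map(array(1, c(4, 4, 4)))
#' dim(m$values)
#' @export
suvr_map <- function(values, voxel_size_mm = MNI_VOXEL_MM,
                     space = c("template-aligned", "native/misaligned")) {
  space <- match.arg(space)
  values <- as_map_array(values)
  if (!all(is.finite(values)))
    stop("SUVr values must all be finite")
  if (any(values < 0))
    stop("SUVr values must be non-negative")
  if (!is.numeric(voxel_size_mm) || length(voxel_size_mm) != 1L ||
      voxel_size_mm <= 0)
    stop("voxel_size_mm must be a positive scalar")
  structure(list(values = values, voxel_size_mm = voxel_size_mm,
                 space = space),
            class = "suvr_map")
}

# Coerce a vector/matrix/array to a bare 3D double array (foreign
# attributes, e.g. from NIfTI handles, are dropped).
as_map_array <- function(values) {
  if (inherits(values, "suvr_map")) return(values$values)
  d <- dim(values)
  if (is.null(d)) d <- length(values)
  if (length(d) > 3L) stop("SUVr maps have at most 3 dimensions")
  values <- as.double(values)
  dim(values) <- c(d, rep(1L, 3L - length(d)))
  values
}

#' @export
print.suvr_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("SUVr map %d x %d x %d (%.3g mm voxels, %s)\n",
              d[1], d[2], d[3], x$voxel_size_mm, x$space))
  v <- x$values[x$values > 0]
  if (length(v))
    cat(sprintf("  nonzero voxels: %d, range %.3f - %.3f\n",
                length(v), min(v), max(v)))
  invisible(x)
}

#' Read and write SUVr maps as NIfTI-1
#'
#' Maps are stored as NIfTI-1 with a diagonal affine whose scale is the voxel
#' size; reduced maps keep their degenerate trailing dimensions.
#'
#' @param map a [suvr_map()].
#' @param path file path, conventionally ending in `.nii.gz`.
#' @param space alignment tag to attach on read (NIfTI does not carry it).
#' @return `write_suvr_map` returns `path` invisibly; `read_suvr_map` returns
#'   a [suvr_map()].
#' @export
write_suvr_map <- function(map, path) {
  stopifnot(inherits(map, "suvr_map"))
  img <- RNifti::asNifti(map$values)
  RNifti::pixdim(img) <- rep(map$voxel_size_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_suvr_map
#' @export
read_suvr_map <- function(path,
                          space = c("template-aligned", "native/misaligned")) {
  img <- RNifti::readNifti(path)
  vox <- RNifti::pixdim(img)[1]
  suvr_map(as.array(img), voxel_size_mm = vox, space = match.arg(space))
}

# Run code with a private RNG stream: seeds R's RNG, restoring the caller's
# state afterwards.  seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
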