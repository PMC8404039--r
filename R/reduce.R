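#' Reduce a 3D SUVr map to its striatal axial slice
#'
#' Returns the single axial plane through the axial coordinate of the
#' striatal-mask centroid (the "middle slice where the striatum is visible"),
#' with values copied bit-exactly from the 3D map.  Output shape is
#' `(nx, ny, 1)`.
#'
#' @param map a 3D [suvr_map()] or array.
#' @param striatal_mask logical array on the same grid.
#' @return A [suvr_map()] of shape `c(nx, ny, 1)`.
#' @export
to_2d <- function(map, striatal_mask) {
  v <- as_map_array(map)
  mask <- as_map_array(striatal_mask) > 0
  if (!any(mask)) stop("striatal mask is empty")
  if (!all(dim(mask) == dim(v))) stop("mask and map grids differ")
  k <- centroid_index(mask, axis = 3L)
  out <- v[, , k, drop = FALSE]
  reduced(map, out)
}

#' Reduce a 2D slice to its striatal 1D profile
#'
#' Returns the first-axis profile of a 2D slice passing through the in-plane
#' striatal centroid.  Output shape is `(nx, 1, 1)`.
#'
#' @param map2d a [suvr_map()] or array of shape `(nx, ny, 1)`.
#' @param striatal_mask logical array; a 3D mask is collapsed over its axial
#'   axis to the in-plane striatal extent.
#' @return A [suvr_map()] of shape `c(nx, 1, 1)`.
#' @export
to_1d <- function(map2d, striatal_mask) {
  v <- as_map_array(map2d)
  if (dim(v)[3] != 1L) stop("to_1d expects a 2D slice")
  mask <- as_map_array(striatal_mask) > 0
  if (!any(mask)) stop("striatal mask is empty")
  mask2 <- apply(mask, c(1, 2), any)
  if (!all(dim(mask2) == dim(v)[1:2])) stop("mask and slice grids differ")
  j <- centroid_index(array(mask2, c(dim(mask2), 1L)), axis = 2L)
  out <- v[, j, 1, drop = FALSE]
  reduced(map2d, out)
}

# Rounded centroid of a mask along one axis (1-based; .5 rounds up).
centroid_index <- function(mask, axis) {
  idx <- which(mask, arr.ind = TRUE)[, axis]
  floor(mean(idx) + 0.5)
}

reduced <- function(src, values) {
  vox <- if (inherits(src, "suvr_map")) src$voxel_size_mm else MNI_VOXEL_MM
  space <- if (inherits(src, "suvr_map")) src$space else "template-aligned"
  m <- suvr_map(values, voxel_size_mm = vox)
  m$space <- space
  m
}

#' Downsample a SUVr map by an integer factor
#'
#' Reduces the grid by keeping every `factor`-th voxel along each
#' non-degenerate axis (`"decimate"`, the default) or by averaging complete
#' `factor`-wide blocks (`"average"`).  Decimation samples the underlying
#' field without low-pass filtering, so voxel-level noise statistics -- the
#' signature the SNR classifier learns -- are preserved under reduction;
#' averaging suppresses them by roughly `factor^(d/2)`.
#'
#' @param map a [suvr_map()] or array.
#' @param factor integer >= 1.
#' @param method `"decimate"` or `"average"`.
#' @return The reduced [suvr_map()]; its voxel size grows by `factor`.
#' @export
downsample_map <- function(map, factor, method = c("decimate", "average")) {
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  v <- as_map_array(map)
  vox <- if (inherits(map, "suvr_map")) map$voxel_size_mm else MNI_VOXEL_MM
  if (factor == 1L) return(reduced(map, v))
  d <- dim(v)
  take <- lapply(d, function(n) if (n > 1L) seq(1L, n, by = factor)
                                else 1L)
  if (method == "decimate") {
    out <- v[take[[1]], take[[2]], take[[3]], drop = FALSE]
  } else {
    nd <- ifelse(d > 1L, d %/% factor, 1L)
    if (any(nd < 1L)) stop("factor larger than grid")
    out <- array(0, nd)
    f <- ifelse(d > 1L, factor, 1L)
    for (i in seq_len(f[1])) for (j in seq_len(f[2])) for (k in seq_len(f[3]))
      out <- out + v[seq(i, by = f[1], length.out = nd[1]),
                     seq(j, by = f[2], length.out = nd[2]),
                     seq(k, by = f[3], length.out = nd[3]), drop = FALSE]
    out <- out / prod(f)
  }
  m <- reduced(map, out)
  m$voxel_size_mm <- vox * factor
  m
}

#' Stack manifest maps into a training array
#'
#' Loads (or takes from memory) every map of a manifest, optionally reduces
#' it (downsampling for 3D, slice/profile extraction for 2D/1D against the
#' template striatal mask), and stacks the results into an array whose last
#' dimension indexes maps, ready for [densenet_train()].
#'
#' @param manifest a `dataset_manifest`.
#' @param dims target dimensionality: 3 (volumes), 2 (striatal slices) or 1
#'   (striatal profiles).  Slice/profile selection uses the fixed
#'   template-defined striatal mask, not the individual image.
#' @param downsample integer decimation factor applied to 3D volumes.
#' @param classes optional character vector restricting (and ordering) the
#'   classes kept; the returned labels are a factor with those levels.
#' @return A list with `x` (array, samples last) and `y` (factor).
#' @export
stack_dataset <- function(manifest, dims = 3, downsample = 1,
                          classes = NULL) {
  entries <- manifest$entries
  if (!is.null(classes)) {
    keep <- entries$class %in% classes
    entries <- entries[keep, , drop = FALSE]
  } else {
    classes <- unique(entries$class)
  }
  n <- nrow(entries)
  if (n == 0L) stop("no maps selected")
  masks <- NULL
  xs <- vector("list", n)
  sel <- which(manifest$entries$id %in% entries$id)
  for (i in seq_len(n)) {
    m <- manifest_map(manifest, sel[i])
    if (dims <= 2) {
      if (is.null(masks))
        masks <- template_masks_cached(dim(m$values), m$voxel_size_mm)
      m <- to_2d(m, masks$striatal)
      if (dims == 1) m <- to_1d(m, masks$striatal)
    } else if (downsample > 1) {
      m <- downsample_map(m, downsample)
    }
    xs[[i]] <- m$values
  }
  d <- dim(xs[[1]])
  keep_dims <- d[seq_len(dims)]
  x <- array(unlist(xs), c(keep_dims, n))
  list(x = x, y = factor(entries$class, levels = classes))
}
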