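#' Template region masks for the synthetic FDOPA phantom
#'
#' Builds binary masks for the striatum (two mirrored ellipsoids, caudate and
#' putamen merged), the cerebellum (one inferior-posterior ellipsoid) and the
#' whole brain (a single containing ellipsoid) on a regular grid in the
#' MNI-like frame used throughout the package.  These are the anatomical
#' proxies for the regions entering QC criterion 4 (striatal SUVr > 1.5,
#' cerebellar SUVr ~ 1) and the brain mask of the SNR statistic.
#'
#' @param shape integer triple, grid dimensions (default 91 x 109 x 91).
#' @param voxel_size_mm positive scalar, isotropic voxel size (default 2 mm).
#' @return A list with logical arrays `striatal`, `cerebellar`, `brain`, plus
#'   the `shape` and `voxel_size_mm` used.
#' @examples
#' m <- make_template_masks()
#' sum(m$striatal)
#' @export
make_template_masks <- function(shape = MNI_SHAPE,
                                voxel_size_mm = MNI_VOXEL_MM) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be a positive integer triple")
  # Keep the world origin at the same relative grid position as the default
  # template so masks scale with resolution.
  origin <- 1 + (MNI_ORIGIN_VOX - 1) * (shape - 1) / (MNI_SHAPE - 1)
  xs <- (seq_len(shape[1]) - origin[1]) * voxel_size_mm
  ys <- (seq_len(shape[2]) - origin[2]) * voxel_size_mm
  zs <- (seq_len(shape[3]) - origin[3]) * voxel_size_mm

  ellipsoid <- function(e) {
    dx2 <- ((xs - e$centre[1]) / e$semi_axes[1])^2
    dy2 <- ((ys - e$centre[2]) / e$semi_axes[2])^2
    dz2 <- ((zs - e$centre[3]) / e$semi_axes[3])^2
    q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    q <= 1
  }

  striatal <- ellipsoid(STRIATUM_ELLIPSOIDS$left) |
    ellipsoid(STRIATUM_ELLIPSOIDS$right)
  cerebellar <- ellipsoid(CEREBELLUM_ELLIPSOID)
  brain <- ellipsoid(BRAIN_ELLIPSOID) | cerebellar
  if (!any(striatal) || !any(cerebellar) || !any(brain))
    stop("shape too small to contain the template masks")
  list(striatal = striatal, cerebellar = cerebellar, brain = brain,
       shape = shape, voxel_size_mm = voxel_size_mm)
}

#' Phantom specification
#'
#' Parameters of the synthetic good-quality FDOPA SUVr map generator.  The
#' defaults encode the physiological regime a QC-passing scan shows: striatal
#' SUVr well above 1.5, cerebellar and parenchymal SUVr near 1, zero
#' background, about 4.5 mm effective resolution, and mild inter-subject
#' variability (5% global intensity jitter plus sub-threshold rigid jitter of
#' at most 2 mm / 1 degree, far below the 8 mm motion criterion).
#'
#' @param striatal_suvr_range length-2 numeric, uniform sampling interval for
#'   the striatal plateau SUVr; its lower bound must exceed 1.5.
#' @param cerebellar_suvr,parenchyma_suvr unitless baseline SUVr values.
#' @param smoothing_fwhm_mm effective resolution (Gaussian FWHM, mm).
#' @param intensity_jitter relative SD of the per-subject global scaling.
#' @param rigid_jitter_mm,rigid_jitter_deg maxima of the sub-threshold rigid
#'   jitter applied to good maps.
#' @param shape,voxel_size_mm grid geometry.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(striatal_suvr_range = c(2.0, 3.5),
                         cerebellar_suvr = 1.0,
                         parenchyma_suvr = 1.0,
                         smoothing_fwhm_mm = 4.5,
                         intensity_jitter = 0.05,
                         rigid_jitter_mm = 2,
                         rigid_jitter_deg = 1,
                         shape = MNI_SHAPE,
                         voxel_size_mm = MNI_VOXEL_MM) {
  if (length(striatal_suvr_range) != 2L ||
      diff(striatal_suvr_range) < 0)
    stop("striatal_suvr_range must be an interval")
  if (striatal_suvr_range[1] <= STRIATAL_SUVR_MIN)
    stop("striatal_suvr_range lower bound must exceed ", STRIATAL_SUVR_MIN,
         " so that clean phantoms satisfy QC criterion 4")
  if (smoothing_fwhm_mm <= 0) stop("smoothing_fwhm_mm must be positive")
  if (intensity_jitter < 0) stop("intensity_jitter must be >= 0")
  structure(list(striatal_suvr_range = striatal_suvr_range,
                 cerebellar_suvr = cerebellar_suvr,
                 parenchyma_suvr = parenchyma_suvr,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 intensity_jitter = intensity_jitter,
                 rigid_jitter_mm = rigid_jitter_mm,
                 rigid_jitter_deg = rigid_jitter_deg,
                 shape = as.integer(shape),
                 voxel_size_mm = voxel_size_mm),
            class = "phantom_spec")
}

#' Synthesise a good-quality FDOPA SUVr map
#'
#' Generates one template-aligned synthetic SUVr map: piecewise-constant
#' region values (striatum drawn uniformly from the spec range, cerebellum
#' and parenchyma near 1, background 0) smoothed to the scanner's effective
#' resolution, then multiplied by a per-subject global intensity factor and
#' perturbed by sub-threshold rigid jitter so that no two "good" maps are
#' identical while all satisfy the 8 mm motion criterion.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed; identical `(spec, seed)` give bit-identical maps.
#' @return A [suvr_map()].
#' @examples
#' m <- synth_suvr_map(seed = 1)
#' masks <- make_template_masks()
#' mean(m$values[masks$striatal])   # > 1.5
#' @export
synth_suvr_map <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- template_masks_cached(spec$shape, spec$voxel_size_mm)
  with_seed(seed, {
    u <- runif(1, spec$striatal_suvr_range[1], spec$striatal_suvr_range[2])
    vol <- array(0, spec$shape)
    vol[masks$brain] <- spec$parenchyma_suvr
    vol[masks$cerebellar] <- spec$cerebellar_suvr
    vol[masks$striatal] <- u
    sigma_vox <- spec$smoothing_fwhm_mm / (2 * sqrt(2 * log(2))) /
      spec$voxel_size_mm
    vol <- array(cpp_gauss_smooth(vol, spec$shape, sigma_vox), spec$shape)
    # global intensity jitter, clamped to keep SUVr physiology intact
    scale <- 1 + max(-2.5, min(2.5, rnorm(1))) * spec$intensity_jitter
    vol <- vol * scale
    # sub-threshold rigid jitter
    if (spec$rigid_jitter_mm > 0 || spec$rigid_jitter_deg > 0) {
      dir <- rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      t_mm <- dir * runif(1, 0, spec$rigid_jitter_mm)
      r_deg <- runif(3, -spec$rigid_jitter_deg, spec$rigid_jitter_deg)
      vol <- array(cpp_rigid_resample(vol, spec$shape,
                                      t_mm / spec$voxel_size_mm, r_deg),
                   spec$shape)
    }
    vol[vol < 0] <- 0
    suvr_map(vol, voxel_size_mm = spec$voxel_size_mm,
             space = "template-aligned")
  })
}

# Mask construction is deterministic; cache the default grid.
.mask_cache <- new.env(parent = emptyenv())
template_masks_cached <- function(shape, voxel_size_mm) {
  key <- paste(c(shape, voxel_size_mm), collapse = "x")
  if (is.null(.mask_cache[[key]]))
    .mask_cache[[key]] <- make_template_masks(shape, voxel_size_mm)
  .mask_cache[[key]]
}

#' Synthesise a labelled QC dataset
#'
#' Generates a dataset emulating the structure of a QC study sample: clean
#' template-aligned maps, maps misaligned beyond the 8 mm motion criterion,
#' and maps degraded with zero-mean Gaussian noise whose SD is a fixed
#' fraction (default 20%) of the noise-free voxel value.
#'
#' @param composition named integer vector with counts for `good`,
#'   `misaligned` and `noisy` maps (missing names count as 0).
#' @param spec a [phantom_spec()].
#' @param seed master seed; per-map seeds are derived from it, so identical
#'   `(composition, spec, seed)` reproduce the dataset exactly.
#' @param dir if non-`NULL`, maps are written there as NIfTI (`.nii.gz`) and
#'   the manifest records their paths; otherwise maps are kept in memory.
#' @param noise_fraction noise SD as a fraction of the voxel value.
#' @return An object of class `dataset_manifest`: a list with `entries` (a
#'   data frame with id, path, class, degradation parameters and seed) and
#'   `maps` (a named list of [suvr_map()]s when `dir` is `NULL`).
#' @examples
#' ds <- synth_dataset(c(good = 2, misaligned = 1, noisy = 1), seed = 7)
#' table(ds$entries$class)
#' @export
synth_dataset <- function(composition, spec = phantom_spec(), seed = NULL,
                          dir = NULL, noise_fraction = 0.20) {
  comp <- c(good = 0L, misaligned = 0L, noisy = 0L)
  if (is.null(names(composition)) && length(composition) == 3L)
    names(composition) <- names(comp)
  if (!all(names(composition) %in% names(comp)))
    stop("composition names must be good/misaligned/noisy")
  comp[names(composition)] <- as.integer(composition)
  if (any(comp < 0)) stop("composition counts must be >= 0")
  n <- sum(comp)

  classes <- rep(names(comp), comp)
  seeds <- if (n > 0) with_seed(seed, sample.int(2^31 - 10, n)) else integer()
  entries <- data.frame(
    id = sprintf("map_%04d", seq_len(n)),
    path = rep(NA_character_, n),
    class = classes,
    tx_mm = numeric(n), ty_mm = numeric(n), tz_mm = numeric(n),
    rx_deg = numeric(n), ry_deg = numeric(n), rz_deg = numeric(n),
    noise_fraction = numeric(n),
    seed = seeds,
    stringsAsFactors = FALSE
  )
  if (n == 0)
    return(structure(list(entries = entries, maps = list(), spec = spec),
                     class = "dataset_manifest"))

  maps <- vector("list", n)
  names(maps) <- entries$id
  for (i in seq_len(n)) {
    m <- synth_suvr_map(spec, seed = seeds[i])
    if (classes[i] == "misaligned") {
      dspec <- sample_misalignment(seed = seeds[i] + 1L)
      m <- apply_rigid(m, dspec$translation_mm, dspec$rotation_deg)
      entries[i, c("tx_mm", "ty_mm", "tz_mm")] <- dspec$translation_mm
      entries[i, c("rx_deg", "ry_deg", "rz_deg")] <- dspec$rotation_deg
    } else if (classes[i] == "noisy") {
      m <- add_noise(m, noise_fraction, seed = seeds[i] + 2L)
      entries$noise_fraction[i] <- noise_fraction
    }
    if (is.null(dir)) {
      maps[[i]] <- m
    } else {
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      p <- file.path(dir, paste0(entries$id[i], ".nii.gz"))
      write_suvr_map(m, p)
      entries$path[i] <- p
    }
  }
  structure(list(entries = entries,
                 maps = if (is.null(dir)) maps else list(),
                 spec = spec),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("QC dataset manifest:", nrow(x$entries), "maps\n")
  if (nrow(x$entries)) print(table(x$entries$class))
  invisible(x)
}

#' Write or read a dataset manifest as CSV
#'
#' @param manifest a `dataset_manifest` (or its `entries` data frame).
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   a `dataset_manifest` whose maps are loaded lazily from `path` entries.
#' @export
write_manifest <- function(manifest, path) {
  entries <- if (inherits(manifest, "dataset_manifest")) manifest$entries
             else manifest
  write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  entries <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(entries = entries, maps = list(), spec = NULL),
            class = "dataset_manifest")
}

# Fetch the i-th map of a manifest, from memory or disk.
manifest_map <- function(manifest, i) {
  e <- manifest$entries[i, ]
  if (length(manifest$maps) && !is.null(manifest$maps[[e$id]]))
    return(manifest$maps[[e$id]])
  if (is.na(e$path) || !file.exists(e$path))
    stop("map file missing: ", e$path)
  read_suvr_map(e$path,
                space = if (e$class == "misaligned") "native/misaligned"
                        else "template-aligned")
}
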