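#' Add multiplicative-scaled Gaussian noise to a SUVr map
#'
#' Each voxel value `v` becomes `v + e` with `e ~ Normal(0, (f * v)^2)` drawn
#' independently per voxel, emulating low-SNR reconstructions: the noise SD
#' is a fixed fraction `f` of the noise-free voxel value (default 20%).
#' Zero-valued voxels are unchanged and negative results are clipped to 0
#' (SUVr is non-negative by definition), so the spatial support of the signal
#' is preserved.
#'
#' @param map a [suvr_map()] or numeric array.
#' @param noise_fraction positive fraction of the voxel value used as SD.
#' @param seed integer seed for reproducible noise.
#' @return A degraded [suvr_map()].
#' @examples
#' m <- suvr_map(array(2, c(8, 8, 8)))
#' n <- add_noise(m, 0.2, seed = 1)
#' sd(n$values - m$values)  # ~ 0.4
#' @export
add_noise <- function(map, noise_fraction = 0.20, seed = NULL) {
  vox <- if (inherits(map, "suvr_map")) map$voxel_size_mm else MNI_VOXEL_MM
  space <- if (inherits(map, "suvr_map")) map$space else "template-aligned"
  v <- as_map_array(map)
  if (!all(is.finite(v))) stop("input voxels must be finite")
  if (!is.numeric(noise_fraction) || noise_fraction <= 0 ||
      noise_fraction > 1)
    stop("noise_fraction must be in (0, 1]")
  out <- with_seed(seed,
                   v + rnorm(length(v)) * (noise_fraction * as.vector(v)))
  out[out < 0] <- 0
  dim(out) <- dim(v)
  m <- suvr_map(out, voxel_size_mm = vox)
  m$space <- space
  m
}

#' Apply a rigid-body transform to a SUVr map
#'
#' Resamples the map under a rigid transform -- rotation about the grid
#' centre followed by translation -- with trilinear interpolation; voxels
#' pulled from outside the field of view are 0.  When the translation
#' magnitude reaches the 8 mm motion criterion the output is tagged
#' `"native/misaligned"`.
#'
#' @param map a [suvr_map()] or numeric array (3D).
#' @param translation_mm numeric length 3, translation in mm.
#' @param rotation_deg numeric length 3, rotations about x/y/z in degrees.
#' @return The resampled [suvr_map()].
#' @export
apply_rigid <- function(map, translation_mm = c(0, 0, 0),
                        rotation_deg = c(0, 0, 0)) {
  vox <- if (inherits(map, "suvr_map")) map$voxel_size_mm else MNI_VOXEL_MM
  v <- as_map_array(map)
  if (length(translation_mm) != 3L || length(rotation_deg) != 3L ||
      !all(is.finite(c(translation_mm, rotation_deg))))
    stop("translation_mm and rotation_deg must be finite length-3 vectors")
  out <- array(cpp_rigid_resample(v, dim(v), translation_mm / vox,
                                  rotation_deg),
               dim(v))
  out[out < 0] <- 0
  misaligned <- sqrt(sum(translation_mm^2)) >= MOTION_THRESHOLD_MM
  m <- suvr_map(out, voxel_size_mm = vox)
  m$space <- if (misaligned) "native/misaligned" else
    (if (inherits(map, "suvr_map")) map$space else "template-aligned")
  m
}

#' Sample an unambiguous misalignment
#'
#' Draws a rigid degradation whose translation magnitude is uniform in
#' [8, 25] mm with uniform random direction, and rotations uniform in
#' [-10, 10] degrees per axis -- every sample violates the 8 mm motion
#' acceptance criterion while keeping the brain inside the field of view.
#'
#' @param seed integer seed.
#' @param mag_range_mm translation magnitude interval (lower bound must be at
#'   least the 8 mm criterion).
#' @param rot_range_deg maximum absolute per-axis rotation.
#' @return A list of class `degradation_spec` with elements `kind`,
#'   `translation_mm`, `rotation_deg`, `seed`.
#' @examples
#' s <- sample_misalignment(seed = 3)
#' sqrt(sum(s$translation_mm^2))  # in [8, 25]
#' @export
sample_misalignment <- function(seed = NULL, mag_range_mm = c(8, 25),
                                rot_range_deg = 10) {
  if (mag_range_mm[1] < MOTION_THRESHOLD_MM)
    stop("misalignment magnitude must be >= the ", MOTION_THRESHOLD_MM,
         " mm criterion so the label is unambiguous")
  with_seed(seed, {
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    mag <- runif(1, mag_range_mm[1], mag_range_mm[2])
    rot <- runif(3, -rot_range_deg, rot_range_deg)
    structure(list(kind = "misalignment", translation_mm = dir * mag,
                   rotation_deg = rot, seed = seed),
              class = "degradation_spec")
  })
}
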