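# Fixed geometry and thresholds for the synthetic FDOPA template.
#
# All coordinates are in mm in an MNI-like frame: world = (voxel - origin) *
# voxel_size, with 1-based voxel indices and the axial (third) index
# increasing inferior -> superior.  The striatum is modelled as two mirrored
# ellipsoids (caudate and putamen merged), the cerebellum as a single
# inferior-posterior ellipsoid, and the brain as one large ellipsoid
# containing both.

MNI_SHAPE <- c(91L, 109L, 91L)
MNI_VOXEL_MM <- 2.0
MNI_ORIGIN_VOX <- c(46, 64, 37)  # 1-based voxel at world (0, 0, 0)

STRIATUM_ELLIPSOIDS <- list(
  left  = list(centre = c(-22, 4, 4), semi_axes = c(10, 17, 12)),
  right = list(centre = c(22, 4, 4), semi_axes = c(10, 17, 12))
)
CEREBELLUM_ELLIPSOID <- list(centre = c(0, -52, -28), semi_axes = c(34, 20, 16))
BRAIN_ELLIPSOID <- list(centre = c(0, -12, 6), semi_axes = c(66, 80, 70))

# QC thresholds (motion criterion and physiological SUVr ranges).
MOTION_THRESHOLD_MM <- 8
STRIATAL_SUVR_MIN <- 1.5
CEREBELLAR_SUVR_RANGE <- c(0.8, 1.2)

# Numerical constants.
BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1    # running-statistics update weight
CE_EPS <- 1e-7        # probability clamp in the cross-entropy
# Adam defaults as published with the method.
ADAM_BETA1 <- 0.9
ADAM_BETA2 <- 0.999
ADAM_EPS <- 1e-8
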