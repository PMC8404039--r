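#' Brain SNR statistic
#'
#' Signal-to-noise ratio of a SUVr map: the mean of the within-brain SUVr
#' values divided by their standard deviation (sample SD, n - 1 convention).
#' The statistic is invariant to global intensity scaling.
#'
#' @param map a [suvr_map()] or array.
#' @param brain_mask logical array on the same grid.
#' @return A positive scalar.
#' @examples
#' snr_statistic(array(c(1, 1, 3, 3), c(4, 1, 1)),
#'               array(TRUE, c(4, 1, 1)))  # 2 / 1.1547
#' @export
snr_statistic <- function(map, brain_mask) {
  v <- as_map_array(map)
  mask <- as_map_array(brain_mask) > 0
  if (!any(mask)) stop("brain mask is empty")
  vals <- v[mask]
  s <- sd(vals)
  if (!is.finite(s) || s == 0)
    stop("SNR undefined: constant image within the brain mask")
  mean(vals) / s
}

#' Physiological SUVr range checks (QC criterion 4)
#'
#' The striatal check passes when the striatal-mask mean SUVr strictly
#' exceeds 1.5; the cerebellar check passes when the cerebellar-mask mean
#' lies in [0.8, 1.2] (the operational reading of "SUVr ~ 1").
#'
#' @param map a [suvr_map()] or array.
#' @param striatal_mask,cerebellar_mask logical arrays on the same grid.
#' @return A list with `striatal_pass`, `cerebellar_pass` and the two means.
#' @export
check_suvr_ranges <- function(map, striatal_mask, cerebellar_mask) {
  v <- as_map_array(map)
  sm <- as_map_array(striatal_mask) > 0
  cm <- as_map_array(cerebellar_mask) > 0
  if (!any(sm) || !any(cm)) stop("region mask is empty")
  smean <- mean(v[sm])
  cmean <- mean(v[cm])
  list(striatal_pass = smean > STRIATAL_SUVR_MIN,
       cerebellar_pass = cmean >= CEREBELLAR_SUVR_RANGE[1] &&
         cmean <= CEREBELLAR_SUVR_RANGE[2],
       striatal_mean = smean, cerebellar_mean = cmean)
}

#' Motion check (QC criterion 2)
#'
#' Passes when the maximum between-frame displacement is strictly below the
#' threshold (default 8 mm).
#'
#' @param displacements_mm numeric vector of per-frame displacement
#'   magnitudes in mm.
#' @param threshold_mm acceptance threshold.
#' @return A list with `pass`, `max_motion_mm` and, on failure, the
#'   offending values.
#' @export
check_motion <- function(displacements_mm, threshold_mm = MOTION_THRESHOLD_MM) {
  if (length(displacements_mm) == 0)
    stop("no displacement values supplied")
  if (!all(is.finite(displacements_mm)))
    stop("displacements must be finite")
  mx <- max(displacements_mm)
  list(pass = mx < threshold_mm, max_motion_mm = mx,
       offending_mm = displacements_mm[displacements_mm >= threshold_mm])
}

#' Rule-based QC verdict
#'
#' Evaluates the automatable manual QC criteria on one map: criterion 2
#' (motion, when a displacement trace is supplied) and criterion 4
#' (physiological SUVr ranges), and computes the brain SNR statistic.  The
#' purely visual criteria (1: plausible signal distribution, 3: atlas
#' co-registration, 5: spatial normalisation) are reported as not evaluated
#' -- the CNN classifiers stand in for them.  The verdict is `"pass"` iff
#' every evaluated criterion passes.
#'
#' @param map a [suvr_map()] or array.
#' @param masks template masks as from [make_template_masks()].
#' @param motion_mm optional numeric vector of per-frame displacements (mm).
#' @return An object of class `qc_report`.
#' @export
qc_verdict <- function(map, masks, motion_mm = NULL) {
  v <- as_map_array(map)
  if (!all(dim(v) == dim(as_map_array(masks$brain))))
    stop("map and masks are on different grids")
  ranges <- check_suvr_ranges(v, masks$striatal, masks$cerebellar)
  snr <- snr_statistic(v, masks$brain)
  criteria <- list(
    signal_distribution = NA,           # criterion 1, visual only
    motion = if (is.null(motion_mm)) NA else check_motion(motion_mm)$pass,
    atlas_coregistration = NA,          # criterion 3, visual only
    suvr_ranges = ranges$striatal_pass && ranges$cerebellar_pass,
    spatial_normalisation = NA          # criterion 5, visual only
  )
  evaluated <- !vapply(criteria, is.na, logical(1))
  verdict <- if (all(unlist(criteria[evaluated]))) "pass" else "fail"
  structure(list(
    snr_value = snr,
    striatal_mean_suvr = ranges$striatal_mean,
    cerebellar_mean_suvr = ranges$cerebellar_mean,
    max_motion_mm = if (is.null(motion_mm)) NA_real_ else max(motion_mm),
    criteria = criteria,
    failed = names(criteria)[evaluated][!unlist(criteria[evaluated])],
    verdict = verdict
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Rule-based QC:", toupper(x$verdict), "\n")
  cat(sprintf("  SNR %.2f | striatal SUVr %.2f | cerebellar SUVr %.2f\n",
              x$snr_value, x$striatal_mean_suvr, x$cerebellar_mean_suvr))
  if (!is.na(x$max_motion_mm))
    cat(sprintf("  max motion %.1f mm\n", x$max_motion_mm))
  for (nm in names(x$criteria)) {
    v <- x$criteria[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                if (is.na(v)) "not evaluated" else if (v) "pass" else "FAIL"))
  }
  invisible(x)
}

#' Serialise a QC report to JSON
#'
#' @param report a `qc_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @export
qc_report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
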