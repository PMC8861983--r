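#' Migration axis labels
#'
#' The six degrees of freedom of stem migration, in the fixed package order:
#' translations (mm) along the transverse (x), longitudinal (y) and sagittal
#' (z) axes, then rotations (degrees) about the same axes. Subsidence is
#' distal translation, i.e. negative \code{ty}; \code{ry} is internal (+) /
#' external (-) rotation; \code{rz} is varus (+) / valgus (-) tilt.
#'
#' @format Character vector of length 6.
#' @export
RSA_AXES <- c("tx", "ty", "tz", "rx", "ry", "rz")

#' Default clinical precision limits per axis
#'
#' Precision of the RSA measurement per axis, expressed as the 95% limit of
#' repeated double examinations: 0.140, 0.110 and 0.350 mm for the x-, y- and
#' z-translations and 0.50, 1.04 and 0.18 degrees for the rotations.
#' The measurement-noise standard deviation used by the synthetic generator
#' is \code{limit / 1.96} (see [trial_config()]).
#'
#' @format Named numeric vector (mm for tx/ty/tz, degrees for rx/ry/rz).
#' @export
RSA_PRECISION_LIMITS <- c(
  tx = 0.140, ty = 0.110, tz = 0.350,
  rx = 0.50, ry = 1.04, rz = 0.18
)

#' Marker QC acceptability thresholds
#'
#' Default upper limits for the mean error of rigid-body fitting (ME, mm) and
#' the condition number (CN) above which an RSA examination is considered
#' unacceptable. Both are configuration defaults, overridable in
#' [flag_unacceptable()]: CN conventions differ across RSA platforms, so the
#' CN threshold is only meaningful together with the scale constant of
#' [condition_number()].
#'
#' @format Named numeric vector with elements `me` and `cn`.
#' @export
QC_THRESHOLDS <- c(me = 0.35, cn = 150)

#' Frozen outlier cutoffs for the trial cohort
#'
#' The per-axis migration cutoffs that defined the without-outliers cohort of
#' the source trial: subsidence (distal y-translation) beyond 5.44 mm, and
#' y-axis rotation beyond 5.52 degrees of internal (+) or 4.32 degrees of
#' external (-) rotation. They were derived from the trial data with a
#' 1.5 x IQR rule by the original software and are shipped as constants
#' because the patient-level data needed to re-derive them are not public.
#'
#' @return An object of class `outlier_rules` (see [outlier_rules()]) with
#'   rules for the `ty` and `ry` axes.
#' @export
trial_outlier_rules <- function() {
  outlier_rules(
    ty = c(lower = -5.44, upper = Inf),
    ry = c(lower = -4.32, upper = 5.52)
  )
}
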