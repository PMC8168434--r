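#' Acquisition parameters for a dynamic contrast-enhanced series
#'
#' Bundles the scanner and contrast-agent constants needed by the relaxometry,
#' kinetic-model and phantom stages. Defaults follow a 3 T abdominal protocol:
#' a spoiled-gradient-echo dynamic series of 40 frames at 6 s spacing
#' (240 s total), TR/TE = 3.9/1.4 ms, a 12 degree dynamic flip angle, two
#' pre-contrast frames, and gadolinium injected at 0.1 mmol/kg.
#'
#' @param repetition_time Repetition time TR in seconds.
#' @param echo_time Echo time TE in seconds (carried for provenance; the SPGR
#'   steady-state signal used here does not depend on TE).
#' @param flip_angle_dynamic Flip angle of the dynamic series, degrees.
#' @param flip_angles_t1 Flip angles of the multi-angle baseline T1
#'   acquisition, degrees. At least two distinct angles.
#' @param n_timepoints Number of dynamic frames.
#' @param dt Frame spacing in seconds.
#' @param n_baseline Number of pre-contrast frames (>= 1, < `n_timepoints`).
#' @param relaxivity_r1 Longitudinal relaxivity of the contrast agent,
#'   s^-1 (mmol/L)^-1. The conversion equations write this constant as gamma.
#' @param dose Contrast dose, mmol per kg body weight.
#' @param hematocrit Hematocrit fraction used to convert whole-blood to plasma
#'   concentration.
#'
#' @return An object of class `acq_params` (a validated list).
#' @export
#' @examples
#' p <- acq_params()
#' p$dt * p$n_timepoints  # total scan duration, seconds
acq_params <- function(repetition_time = 0.0039,
                       echo_time = 0.0014,
                       flip_angle_dynamic = 12,
                       flip_angles_t1 = c(3, 6, 9, 12, 15),
                       n_timepoints = 40,
                       dt = 6,
                       n_baseline = 2,
                       relaxivity_r1 = 4.3,
                       dose = 0.1,
                       hematocrit = 0.42) {
  p <- list(
    repetition_time = repetition_time, echo_time = echo_time,
    flip_angle_dynamic = flip_angle_dynamic, flip_angles_t1 = flip_angles_t1,
    n_timepoints = as.integer(n_timepoints), dt = dt,
    n_baseline = as.integer(n_baseline), relaxivity_r1 = relaxivity_r1,
    dose = dose, hematocrit = hematocrit
  )
  scalars <- c("repetition_time", "echo_time", "flip_angle_dynamic",
               "n_timepoints", "dt", "relaxivity_r1", "dose")
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("acq_params: '", nm, "' must be a positive finite scalar", call. = FALSE)
    }
  }
  if (p$hematocrit < 0 || p$hematocrit >= 1) {
    stop("acq_params: hematocrit must be in [0, 1)", call. = FALSE)
  }
  if (p$n_baseline < 1L || p$n_baseline >= p$n_timepoints) {
    stop("acq_params: need 1 <= n_baseline < n_timepoints", call. = FALSE)
  }
  angles <- c(p$flip_angle_dynamic, p$flip_angles_t1)
  if (any(!is.finite(angles)) || any(angles <= 0) || any(angles > 90)) {
    stop("acq_params: flip angles must lie in (0, 90] degrees", call. = FALSE)
  }
  structure(p, class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat("DCE-MRI acquisition parameters\n")
  cat(sprintf("  TR/TE: %.4g/%.4g ms, dynamic flip angle: %g deg\n",
              x$repetition_time * 1000, x$echo_time * 1000, x$flip_angle_dynamic))
  cat(sprintf("  %d frames at %g s (%g s total), %d baseline frame(s)\n",
              x$n_timepoints, x$dt, x$n_timepoints * x$dt, x$n_baseline))
  cat(sprintf("  VFA angles: %s deg\n", paste(x$flip_angles_t1, collapse = ", ")))
  cat(sprintf("  r1 = %g /s/mM, dose = %g mmol/kg, Hct = %g\n",
              x$relaxivity_r1, x$dose, x$hematocrit))
  invisible(x)
}

#' Sampling times of the dynamic series
#'
#' Frame k is acquired at (k-1) * dt seconds, so the first frame is t = 0.
#'
#' @param params An [acq_params()] object.
#' @return Numeric vector of length `n_timepoints`, seconds.
#' @export
acq_times <- function(params) {
  (seq_len(params$n_timepoints) - 1) * params$dt
}

## internal: consistent degrees -> radians
.deg2rad <- function(deg) deg * pi / 180
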