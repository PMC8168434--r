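#' Steady-state spoiled gradient echo signal
#'
#' Evaluates the SPGR steady-state signal
#' \deqn{S = M_0 \sin\alpha \, (1 - E) / (1 - E\cos\alpha), \quad E = e^{-TR/T_1}.}
#' Vectorized over `m0` and `t1`.
#'
#' @param m0 Equilibrium magnetization (arbitrary signal units).
#' @param t1 Longitudinal relaxation time, seconds; must be > 0.
#' @param params An [acq_params()] object supplying TR.
#' @param flip_angle Flip angle in degrees; defaults to the dynamic-series angle.
#' @return Signal in the units of `m0`.
#' @export
spgr_signal <- function(m0, t1, params, flip_angle = params$flip_angle_dynamic) {
  if (any(!is.finite(t1)) || any(t1 <= 0)) {
    stop("spgr_signal: t1 must be finite and > 0", call. = FALSE)
  }
  a <- .deg2rad(flip_angle)
  e1 <- exp(-params$repetition_time / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Construct a dynamic series container
#'
#' A 4D signal grid (x, y, z, t) with its sampling times and acquisition
#' parameters.
#'
#' @param signal 4D numeric array.
#' @param times Sampling times in seconds, strictly increasing, one per frame.
#' @param params An [acq_params()] object.
#' @return Object of class `dynamic_series`.
#' @export
dynamic_series <- function(signal, times, params) {
  if (length(dim(signal)) != 4L) {
    stop("dynamic_series: signal must be a 4D array (x, y, z, t)", call. = FALSE)
  }
  if (length(times) != dim(signal)[4]) {
    stop("dynamic_series: length(times) must equal the 4th dimension", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("dynamic_series: times must be strictly increasing", call. = FALSE)
  }
  structure(list(signal = signal, times = as.numeric(times), params = params),
            class = "dynamic_series")
}

#' Variable-flip-angle T1 fit
#'
#' Estimates a baseline T1 map (and M0) from spoiled-gradient-echo volumes
#' acquired at two or more flip angles, using the linearized SPGR relation
#' \eqn{S/\sin\alpha = E \cdot S/\tan\alpha + M_0(1-E)} whose slope is
#' \eqn{E = e^{-TR/T_1}}. Voxels with a non-physical slope (outside (0, 1)) or
#' degenerate signal are flagged invalid (`NA` in the maps).
#'
#' @param volumes List of 3D arrays, one per flip angle, congruent shapes.
#' @param flip_angles Flip angles in degrees, one per volume; at least two
#'   distinct values.
#' @param params An [acq_params()] object supplying TR.
#' @return Object of class `t1_map`: list with 3D arrays `t1` (seconds), `m0`,
#'   and logical `valid`.
#' @export
vfa_t1_fit <- function(volumes, flip_angles, params) {
  if (length(volumes) < 2L || length(unique(flip_angles)) < 2L) {
    stop("vfa_t1_fit: need volumes at >= 2 distinct flip angles", call. = FALSE)
  }
  if (length(volumes) != length(flip_angles)) {
    stop("vfa_t1_fit: one volume per flip angle required", call. = FALSE)
  }
  dims <- dim(volumes[[1]])
  if (length(dims) != 3L) stop("vfa_t1_fit: volumes must be 3D", call. = FALSE)
  for (v in volumes) {
    if (!identical(dim(v), dims)) {
      stop("vfa_t1_fit: volumes must share a common grid", call. = FALSE)
    }
  }
  a <- .deg2rad(flip_angles)
  n <- prod(dims)
  k <- length(a)
  # per-voxel simple linear regression of y = S/sin(a) on x = S/tan(a),
  # done with closed-form sums so the whole map is vectorized
  sig <- matrix(unlist(volumes, use.names = FALSE), nrow = n, ncol = k)
  y <- sweep(sig, 2, sin(a), "/")
  x <- sweep(sig, 2, tan(a), "/")
  sx <- rowMeans(x); sy <- rowMeans(y)
  sxx <- rowMeans(x * x); sxy <- rowMeans(x * y)
  varx <- sxx - sx^2
  slope <- (sxy - sx * sy) / varx
  intercept <- sy - slope * sx
  valid <- is.finite(slope) & slope > 0 & slope < 1 & varx > 0 & intercept > 0
  t1 <- rep(NA_real_, n)
  m0 <- rep(NA_real_, n)
  t1[valid] <- -params$repetition_time / log(slope[valid])
  m0[valid] <- intercept[valid] / (1 - slope[valid])
  structure(list(t1 = array(t1, dims), m0 = array(m0, dims),
                 valid = array(valid, dims)),
            class = "t1_map")
}

.check_congruent <- function(dyn, t10) {
  if (!identical(dim(dyn$signal)[1:3], dim(t10$t1))) {
    stop("signal and T1 map grids are not congruent", call. = FALSE)
  }
}

.baseline_signal <- function(dyn) {
  nb <- dyn$params$n_baseline
  d <- dim(dyn$signal)
  base <- dyn$signal[, , , seq_len(nb), drop = FALSE]
  array(rowMeans(matrix(base, nrow = prod(d[1:3]), ncol = nb)), d[1:3])
}

#' Signal-to-concentration conversion (linear reduction)
#'
#' Converts a dynamic SPGR series to contrast-agent concentration using the
#' linear small-enhancement reduction
#' \deqn{C(t) = \frac{S(t) - S_0}{S_0 \, r_1 \, T_{10}},}
#' where \eqn{S_0} is the mean over the pre-contrast frames. Negative computed
#' concentrations are retained by default so noise statistics stay unbiased.
#' Voxels with \eqn{S_0 = 0} or invalid T1 are flagged (`NA` over all frames).
#'
#' @param dyn A [dynamic_series()].
#' @param t10 A `t1_map` from [vfa_t1_fit()] (baseline T1, seconds).
#' @param params An [acq_params()] object supplying r1 and the baseline count.
#' @param clip_negative If `TRUE`, negative concentrations are set to 0.
#' @return Object of class `conc_series`: list with 4D `conc` (mmol/L) and
#'   `times`.
#' @export
signal_to_concentration_linear <- function(dyn, t10, params = dyn$params,
                                           clip_negative = FALSE) {
  .check_congruent(dyn, t10)
  d <- dim(dyn$signal)
  s0 <- .baseline_signal(dyn)
  bad <- !is.finite(s0) | s0 == 0 | !is.finite(t10$t1) | t10$t1 <= 0
  denom <- s0 * params$relaxivity_r1 * t10$t1
  conc <- sweep(dyn$signal, 1:3, s0, "-")
  conc <- sweep(conc, 1:3, denom, "/")
  if (any(bad)) conc[array(bad, d)] <- NA_real_
  if (clip_negative) conc[conc < 0] <- 0
  structure(list(conc = conc, times = dyn$times), class = "conc_series")
}

#' Signal-to-concentration conversion (exact SPGR inversion)
#'
#' Inverts the SPGR steady-state ratio \eqn{S(t)/S_0} in closed form for
#' \eqn{T_1(t)} and sets \eqn{C(t) = (1/T_1(t) - 1/T_{10}) / r_1}. Exact for
#' noiseless SPGR data at any enhancement level, unlike the linear reduction
#' which saturates at high concentration. Samples whose signal ratio falls
#' outside the invertible range are flagged `NA`.
#'
#' @inheritParams signal_to_concentration_linear
#' @return Object of class `conc_series`.
#' @export
signal_to_concentration_exact <- function(dyn, t10, params = dyn$params) {
  .check_congruent(dyn, t10)
  d <- dim(dyn$signal)
  s0 <- .baseline_signal(dyn)
  a <- .deg2rad(params$flip_angle_dynamic)
  tr <- params$repetition_time
  bad0 <- !is.finite(s0) | s0 == 0 | !is.finite(t10$t1) | t10$t1 <= 0
  e0 <- exp(-tr / t10$t1)
  # ratio * baseline saturation factor; then solve (1-Et)/(1-Et*cos a) = B
  scale0 <- (1 - e0) / (1 - e0 * cos(a))
  s0[bad0] <- NA_real_
  b <- sweep(dyn$signal, 1:3, s0, "/")
  b <- sweep(b, 1:3, scale0, "*")
  et <- (1 - b) / (1 - b * cos(a))
  invalid <- !is.finite(et) | et <= 0 | et >= 1
  et[invalid] <- NA_real_
  t1t <- -tr / log(et)
  conc <- sweep(1 / t1t, 1:3, 1 / t10$t1, "-") / params$relaxivity_r1
  structure(list(conc = conc, times = dyn$times), class = "conc_series")
}

#' Convert a dynamic series to concentration
#'
#' Front end selecting the linear reduction (default, mirroring common
#' perfusion software) or the exact SPGR inversion.
#'
#' @inheritParams signal_to_concentration_linear
#' @param method `"linear"` or `"exact"`.
#' @return Object of class `conc_series`.
#' @export
signal_to_concentration <- function(dyn, t10, params = dyn$params,
                                    method = c("linear", "exact")) {
  method <- match.arg(method)
  switch(method,
         linear = signal_to_concentration_linear(dyn, t10, params),
         exact = signal_to_concentration_exact(dyn, t10, params))
}
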