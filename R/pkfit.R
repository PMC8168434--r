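#' Extended Tofts forward model
#'
#' Tissue concentration predicted by the extended Tofts dual-compartment model
#' \deqn{C_t(t) = v_p C_p(t) + K^{trans} \int_0^t C_p(\tau)\,
#'   e^{-k_{ep}(t-\tau)} d\tau.}
#' Rate constants are given per minute (the convention of perfusion software);
#' integration is carried out in seconds internally. The convolution uses
#' causal trapezoidal quadrature on the sampling grid.
#'
#' @param ktrans Volume transfer constant, min^-1, >= 0.
#' @param kep Back-flux rate constant, min^-1; must be > 0 when `ktrans > 0`.
#' @param vp Plasma volume fraction in `[0, 1]`.
#' @param aif An [aif_curve()] sampled on `times`.
#' @param times Sampling times, seconds; defaults to the AIF grid.
#' @return Numeric vector of tissue concentration, mmol/L.
#' @export
tofts_forward <- function(ktrans, kep, vp, aif, times = aif$times) {
  if (ktrans < 0 || vp < 0) {
    stop("tofts_forward: parameters must be nonnegative", call. = FALSE)
  }
  if (ktrans > 0 && kep <= 0) {
    stop("tofts_forward: kep must be > 0 when ktrans > 0", call. = FALSE)
  }
  if (!isTRUE(all.equal(times, aif$times))) {
    stop("tofts_forward: times must match the AIF sampling grid", call. = FALSE)
  }
  vp * aif$cp + (ktrans / 60) * .exp_conv(aif$cp, kep / 60, times)
}

## causal trapezoidal convolution of cp with exp(-k t), in seconds.
## Recursive update: I(t_n) = I(t_{n-1}) e^{-k dt} + trapezoid of the
## integrand over [t_{n-1}, t_n]; identical to direct trapezoidal quadrature
## of int_0^t cp(u) exp(-k (t-u)) du on the sampling grid.
.exp_conv <- function(cp, k_per_s, times) {
  n <- length(times)
  out <- numeric(n)
  for (i in seq_len(n)[-1]) {
    dt <- times[i] - times[i - 1]
    e <- exp(-k_per_s * dt)
    out[i] <- out[i - 1] * e + dt / 2 * (cp[i] + cp[i - 1] * e)
  }
  out
}

## linear least-squares formulation of the extended Tofts equations
## (integral form): Ct = a1 * int Cp + a2 * int Ct + a3 * Cp with
## a1 = ktrans + kep * vp, a2 = -kep, a3 = vp (rates per second here).
.tofts_linear_init <- function(ct, cp, times) {
  icp <- .cumtrapz(times, cp)
  ict <- .cumtrapz(times, ct)
  x <- cbind(icp, ict, cp)
  fit <- tryCatch(stats::lm.fit(x, ct), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) return(NULL)
  a <- fit$coefficients
  kep <- -a[2]
  vp <- a[3]
  ktrans <- a[1] + a[2] * a[3]  # a1 - kep * vp
  c(ktrans = unname(ktrans) * 60, kep = unname(kep) * 60, vp = unname(vp))
}

.cumtrapz <- function(t, y) {
  n <- length(t)
  c(0, cumsum(diff(t) * (y[-1] + y[-n]) / 2))
}

#' Fit the extended Tofts model to one voxel curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the parameters
#' (Ktrans, kep, vp), initialized from the linear matrix formulation of the
#' extended Tofts equations. `ve` is reported as Ktrans/kep. Bounds:
#' Ktrans in \[0, 5\] min^-1, kep in (0, 10\] min^-1, vp in \[0, 0.5\].
#' A fit that fails or terminates on a bound is flagged `fit_ok = FALSE`.
#'
#' @param ct Tissue concentration curve, mmol/L.
#' @param aif An [aif_curve()].
#' @param times Sampling times, seconds; defaults to the AIF grid.
#' @param linear_only If `TRUE`, return the linear least-squares estimate
#'   without nonlinear refinement (fast mode).
#' @return Named list: `ktrans`, `kep`, `ve`, `vp` (min^-1 / fractions) and
#'   logical `fit_ok`.
#' @export
fit_voxel <- function(ct, aif, times = aif$times, linear_only = FALSE) {
  na_fit <- list(ktrans = NA_real_, kep = NA_real_, ve = NA_real_,
                 vp = NA_real_, fit_ok = FALSE)
  if (length(ct) < 10L) {
    stop("fit_voxel: need at least 10 timepoints", call. = FALSE)
  }
  if (any(!is.finite(ct))) return(na_fit)
  if (all(ct == 0)) {
    return(list(ktrans = 0, kep = NA_real_, ve = 0, vp = 0, fit_ok = TRUE))
  }
  lower <- c(0, 1e-6, 0)
  upper <- c(5, 10, 0.5)
  init <- .tofts_linear_init(ct, aif$cp, times)
  if (is.null(init)) init <- c(ktrans = 0.2, kep = 0.5, vp = 0.01)
  init <- pmin(pmax(init, lower + c(0, 1e-3, 0)), upper)
  if (linear_only) {
    ve <- if (init[["kep"]] > 0) init[["ktrans"]] / init[["kep"]] else NA_real_
    return(list(ktrans = init[["ktrans"]], kep = init[["kep"]], ve = ve,
                vp = init[["vp"]], fit_ok = TRUE))
  }
  resid_fun <- function(p) {
    tofts_forward(p[1], p[2], p[3], aif, times) - ct
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                       fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info < 1 || fit$info > 4) return(na_fit)
  p <- fit$par
  on_bound <- p[1] >= upper[1] - 1e-9 || p[2] >= upper[2] - 1e-9 ||
    p[2] <= lower[2] + 1e-9 || p[3] >= upper[3] - 1e-9
  ve <- p[1] / p[2]
  ok <- !on_bound && is.finite(ve) && ve >= 0 && ve <= 1
  list(ktrans = unname(p[1]), kep = unname(p[2]), ve = unname(ve),
       vp = unname(p[3]), fit_ok = ok)
}

#' Voxelwise extended Tofts fit over a lesion mask
#'
#' Applies [fit_voxel()] to every in-mask voxel and assembles Ktrans, Kep, ve
#' and vp maps. Voxels outside the mask are `NA`; solver failures are flagged
#' in `fit_ok` and counted in the attached fit log.
#'
#' @param conc A `conc_series`.
#' @param mask Logical 3D array, nonempty, congruent with the grid.
#' @param aif An [aif_curve()].
#' @param linear_only Passed to [fit_voxel()].
#' @return Object of class `pk_maps`: 3D arrays `ktrans`, `kep`, `ve`, `vp`,
#'   logical `fit_ok`, and a `fit_log` list (voxel counts).
#' @export
fit_map <- function(conc, mask, aif, linear_only = FALSE) {
  d <- dim(conc$conc)
  if (!identical(as.integer(dim(mask)), as.integer(d[1:3]))) {
    stop("fit_map: mask grid does not match the concentration grid", call. = FALSE)
  }
  idx <- which(mask)
  if (length(idx) == 0L) stop("fit_map: mask is empty", call. = FALSE)
  shape <- d[1:3]
  mk_map <- function() array(NA_real_, shape)
  maps <- list(ktrans = mk_map(), kep = mk_map(), ve = mk_map(), vp = mk_map())
  fit_ok <- array(FALSE, shape)
  cmat <- matrix(conc$conc, nrow = prod(shape), ncol = d[4])
  n_fail <- 0L
  for (v in idx) {
    f <- fit_voxel(cmat[v, ], aif, conc$times, linear_only = linear_only)
    maps$ktrans[v] <- f$ktrans
    maps$kep[v] <- f$kep
    maps$ve[v] <- f$ve
    maps$vp[v] <- f$vp
    fit_ok[v] <- f$fit_ok
    if (!f$fit_ok) n_fail <- n_fail + 1L
  }
  structure(c(maps, list(fit_ok = fit_ok,
                         fit_log = list(n_voxels = length(idx),
                                        n_failed = n_fail))),
            class = "pk_maps")
}

#' @export
print.pk_maps <- function(x, ...) {
  ok <- x$fit_ok
  cat(sprintf("Extended Tofts parameter maps: %d fitted voxels (%d failed)\n",
              x$fit_log$n_voxels, x$fit_log$n_failed))
  for (nm in c("ktrans", "kep", "ve", "vp")) {
    cat(sprintf("  %-6s mean %.4g over fit_ok voxels\n", nm,
                mean(x[[nm]][ok], na.rm = TRUE)))
  }
  invisible(x)
}
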