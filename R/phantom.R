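## Class-conditional generator moments for lesion-level pharmacokinetics.
## Means/SDs per response class (CR = complete response, PR = partial
## response) and visit (pre = before the first treatment round, post = after
## the second). These are the study conditions the phantom emulates.
.lesion_moments <- list(
  post = list(
    CR = list(ktrans = c(0.117, 0.065), ve = c(0.130, 0.094), vp = c(0.003, 0.003)),
    PR = list(ktrans = c(0.299, 0.231), ve = c(0.322, 0.204), vp = c(0.004, 0.008))
  ),
  pre = list(
    CR = list(ktrans = c(0.454, 0.213), ve = c(0.388, 0.107), vp = c(0.008, 0.006)),
    PR = list(ktrans = c(0.444, 0.162), ve = c(0.352, 0.057), vp = c(0.011, 0.020))
  )
)

## Entropy moments per class/visit (texture condition emulated by the fast
## table-level simulator).
.entropy_moments <- list(
  post = list(CR = c(6.084, 0.442), PR = c(6.777, 0.827)),
  pre = list(CR = c(5.775, 0.440), PR = c(5.779, 0.348))
)

## Heterogeneity of the voxelwise parameter fields, per visit and class. The
## fields are bounded mean-one multiplicative modulations built from a
## Gaussian random field pushed through a beta quantile (a Gaussian copula);
## flatter marginals and weaker neighbor correlation both raise co-occurrence
## entropy. Pre-treatment lesions of both classes share one texture regime
## (no pre-treatment class difference); after treatment CR lesions roughen
## slightly and PR lesions become markedly rougher, so map entropy rises in
## both classes and is higher in PR -- the direction of the texture
## conditions.
.hetero_settings <- list(
  pre = list(
    CR = list(smooth_sigma = 1.3, shape_a = 4, width = 1.1),
    PR = list(smooth_sigma = 1.3, shape_a = 4, width = 1.1)
  ),
  post = list(
    CR = list(smooth_sigma = 0.9, shape_a = 3, width = 1.1),
    PR = list(smooth_sigma = 0.5, shape_a = 1.7, width = 1.1)
  )
)

## mean of a two-sided truncated normal
.tnorm_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd; b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

## draw from a truncated normal whose *truncated* mean equals `target`:
## the location is adjusted so truncation does not bias the class mean.
.rtnorm_target <- function(n, target, sd, lo, hi) {
  mu <- tryCatch(
    stats::uniroot(function(m) .tnorm_mean(m, sd, lo, hi) - target,
                   lower = target - 4 * sd, upper = target + 4 * sd,
                   tol = 1e-10)$root,
    error = function(e) target
  )
  u <- stats::runif(n, stats::pnorm(lo, mu, sd), stats::pnorm(hi, mu, sd))
  stats::qnorm(u, mu, sd)
}

## separable 3D Gaussian smoothing with reflecting edges (small kernels only)
.smooth3d <- function(x, sigma) {
  if (sigma <= 0.05) return(x)
  half <- max(1L, ceiling(2.5 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(arr, axis) {
    d <- dim(arr)
    out <- array(0, d)
    for (s in seq_along(k)) {
      sh <- s - half - 1L
      idx <- seq_len(d[axis]) + sh
      idx <- pmin(pmax(idx, 1L), d[axis])  # replicate edges
      out <- out + k[s] * switch(axis,
                                 arr[idx, , , drop = FALSE],
                                 arr[, idx, , drop = FALSE],
                                 arr[, , idx, drop = FALSE])
    }
    out
  }
  smooth_axis(smooth_axis(smooth_axis(x, 1L), 2L), 3L)
}

## bounded mean-one multiplicative field: smoothed Gaussian field mapped
## through a symmetric beta quantile (Gaussian copula), then centred on 1.
## Values lie in [1 - width/2, 1 + width/2].
.hetero_field <- function(shape, smooth_sigma, shape_a, width) {
  z <- array(stats::rnorm(prod(shape)), shape)
  z <- .smooth3d(z, smooth_sigma)
  z <- z / stats::sd(z)  # restore unit variance after smoothing
  b <- stats::qbeta(stats::pnorm(z), shape_a, shape_a)
  1 + width * (b - 0.5)
}

## ellipsoidal mask inscribed in the grid
.ellipsoid_mask <- function(shape, shrink = 0.95) {
  c0 <- (shape + 1) / 2
  r <- pmax((shape - 1) / 2 * shrink, 0.6)
  ix <- slice.index(array(0, shape), 1)
  iy <- slice.index(array(0, shape), 2)
  iz <- slice.index(array(0, shape), 3)
  ((ix - c0[1]) / r[1])^2 + ((iy - c0[2]) / r[2])^2 + ((iz - c0[3]) / r[3])^2 <= 1
}

#' Population arterial input function (closed form)
#'
#' Plasma concentration of a standard-dose gadolinium bolus: zero before the
#' bolus onset, then a smooth rise multiplying a biexponential washout,
#' \deqn{C_p(t) = s_D (1 - e^{-r\tau}) (a_1 e^{-m_1\tau} + a_2 e^{-m_2\tau}),}
#' with \eqn{\tau} minutes since onset and \eqn{s_D} the dose in mmol/kg.
#' Washout amplitudes/rates follow the classical biexponential plasma decay
#' (a1 = 3.99, a2 = 4.78 kg/L; m1 = 0.144, m2 = 0.0111 min^-1); the rise rate
#' r = 6 min^-1 models a 2 mL/s power-injector bolus.
#'
#' @param t Times in seconds (vector).
#' @param onset Bolus arrival time, seconds.
#' @param dose Dose in mmol/kg.
#' @return Plasma concentration, mmol/L.
#' @export
population_aif_conc <- function(t, onset, dose = 0.1) {
  tau <- pmax(t - onset, 0) / 60
  amp <- dose * (3.99 * exp(-0.144 * tau) + 4.78 * exp(-0.0111 * tau))
  ifelse(t < onset, 0, (1 - exp(-6 * tau)) * amp)
}

#' Sample the population AIF on an acquisition grid
#'
#' @param params An [acq_params()] (supplies the dose).
#' @param times Sampling times, seconds, nondecreasing.
#' @param onset Bolus arrival, seconds; defaults to the end of the baseline
#'   frames (`n_baseline * dt`).
#' @return An [aif_curve()].
#' @export
make_population_aif <- function(params, times = acq_times(params),
                                onset = params$n_baseline * params$dt) {
  if (any(diff(times) < 0)) {
    stop("make_population_aif: times must be nondecreasing", call. = FALSE)
  }
  if (onset < 0 || onset > max(times)) {
    stop("make_population_aif: onset must lie within [0, max(times)]", call. = FALSE)
  }
  aif_curve(times, population_aif_conc(times, onset, params$dose))
}

#' Simulate a ground-truth lesion
#'
#' Draws voxelwise Ktrans, ve and vp maps for one lesion of the given response
#' class. A lesion-level mean is drawn from the class's truncated-normal
#' distribution (location-adjusted so truncation leaves the class mean
#' unchanged), then modulated by a spatially correlated mean-one multiplicative
#' field whose roughness is class-specific: PR lesions are more heterogeneous,
#' so their parameter maps carry higher co-occurrence entropy. Kep is derived
#' as Ktrans/ve voxelwise.
#'
#' @param class_label `"CR"` or `"PR"`.
#' @param shape Voxel dimensions of the lesion bounding grid, each >= 3.
#' @param seed Integer seed; the same seed reproduces the lesion exactly.
#' @param visit `"post"` (default) or `"pre"`: which visit's class moments to
#'   draw from.
#' @return Object of class `gt_lesion`: list with 3D arrays `ktrans`, `kep`,
#'   `ve`, `vp` (`NA` outside the mask), logical `mask`, `class_label`,
#'   `visit`, the drawn lesion-level means, and `seed`.
#' @export
make_lesion <- function(class_label, shape = c(9, 9, 5), seed = 1,
                        visit = c("post", "pre")) {
  visit <- match.arg(visit)
  if (!class_label %in% c("CR", "PR")) {
    stop("make_lesion: class_label must be 'CR' or 'PR'", call. = FALSE)
  }
  if (length(shape) != 3L || any(shape < 3)) {
    stop("make_lesion: shape must be 3 dimensions, each >= 3", call. = FALSE)
  }
  mom <- .lesion_moments[[visit]][[class_label]]
  het <- .hetero_settings[[visit]][[class_label]]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu_ktrans <- .rtnorm_target(1, mom$ktrans[1], mom$ktrans[2], 0.01, 2)
  mu_ve <- .rtnorm_target(1, mom$ve[1], mom$ve[2], 0.02, 0.9)
  mu_vp <- .rtnorm_target(1, mom$vp[1], mom$vp[2], 5e-4, 0.05)
  mask <- .ellipsoid_mask(shape)
  f_k <- .hetero_field(shape, het$smooth_sigma, het$shape_a, het$width)
  f_v <- .hetero_field(shape, het$smooth_sigma, het$shape_a, het$width)
  ktrans <- pmin(mu_ktrans * f_k, 4.5)
  ve <- pmin(mu_ve * f_v, 0.95)
  # keep voxel kinetics inside the physiological fitting range (kep <= 9.5)
  ve <- pmax(ve, ktrans / 9.5)
  vp <- array(pmin(pmax(mu_vp * (1 + 0.1 * stats::rnorm(prod(shape))), 1e-4), 0.1),
              shape)
  blank <- function(x) { x[!mask] <- NA_real_; x }
  ktrans <- blank(ktrans); ve <- blank(ve); vp <- blank(vp)
  structure(list(ktrans = ktrans, kep = ktrans / ve, ve = ve, vp = vp,
                 mask = mask, class_label = class_label, visit = visit,
                 mu = c(ktrans = mu_ktrans, ve = mu_ve, vp = mu_vp),
                 seed = as.integer(seed)),
            class = "gt_lesion")
}

## save/restore the global RNG state so generator calls do not disturb
## the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Ground-truth forward signal model
#'
#' Generates the noiseless dynamic SPGR series of a lesion: per in-mask voxel
#' the extended Tofts model convolves the AIF into a concentration curve,
#' concentration shortens T1 via \eqn{1/T_1(t) = 1/T_{10} + r_1 C(t)}, and the
#' SPGR steady-state equation turns T1 into signal. Out-of-mask voxels keep
#' their constant pre-contrast signal. Baseline frames (before bolus arrival)
#' equal the pre-contrast SPGR signal by construction.
#'
#' @param lesion A `gt_lesion` from [make_lesion()].
#' @param aif An [aif_curve()] sampled on the acquisition grid.
#' @param t10 A `t1_map` congruent with the lesion grid (true baseline T1/M0).
#' @param params An [acq_params()].
#' @return A [dynamic_series()].
#' @export
forward_signal <- function(lesion, aif, t10, params) {
  shape <- dim(lesion$mask)
  if (!identical(as.integer(dim(t10$t1)), as.integer(shape))) {
    stop("forward_signal: lesion and T1 map grids are not congruent", call. = FALSE)
  }
  times <- aif$times
  nt <- length(times)
  sig <- array(0, c(shape, nt))
  base <- spgr_signal(t10$m0, t10$t1, params)
  sig[] <- rep(base, nt)
  idx <- which(lesion$mask)
  n3 <- prod(shape)
  for (v in idx) {
    ct <- tofts_forward(lesion$ktrans[v], lesion$kep[v], lesion$vp[v], aif, times)
    t1t <- 1 / (1 / t10$t1[v] + params$relaxivity_r1 * ct)
    sig[v + n3 * (seq_len(nt) - 1L)] <- spgr_signal(t10$m0[v], t1t, params)
  }
  dynamic_series(sig, times, params)
}

## scene geometry used by make_cohort: a lesion block and an aorta block
## side by side in one volume
.scene_geometry <- function(lesion_shape = c(9, 9, 5)) {
  gap <- 2L
  aorta_w <- 5L
  shape <- c(lesion_shape[1] + gap + aorta_w, max(lesion_shape[2], 5L),
             lesion_shape[3])
  lesion_off <- c(0L, 0L, 0L)
  aorta <- array(FALSE, shape)
  ax <- lesion_shape[1] + gap + seq_len(aorta_w)
  cy <- (shape[2] + 1) / 2
  cx <- mean(ax)
  for (x in ax) for (y in seq_len(shape[2])) {
    if ((x - cx)^2 + (y - cy)^2 <= 1.6^2) aorta[x, y, ] <- TRUE
  }
  list(shape = shape, lesion_off = lesion_off, aorta = aorta)
}

## true baseline T1/M0 of the scene (tissue 1.0 s, blood 1.6 s)
.scene_t10 <- function(shape, aorta_mask, t1_tissue = 1.0, t1_blood = 1.6,
                       m0 = 1000) {
  t1 <- array(t1_tissue, shape)
  t1[aorta_mask] <- t1_blood
  structure(list(t1 = t1, m0 = array(m0, shape),
                 valid = array(TRUE, shape)),
            class = "t1_map")
}

#' Simulate a DCE-MRI phantom cohort on disk
#'
#' Writes, per synthetic patient and visit (pre- and post-treatment), a 4D
#' dynamic series, a multi-flip-angle baseline set (one 4D file, one volume
#' per angle), a lesion mask and an aorta mask as NIfTI-1 files, plus a CSV
#' manifest with the true lesion-level parameters and class labels. Pre-visit
#' kinetics are drawn from the pre-treatment class moments, post-visit from
#' the post-treatment moments. Additive Gaussian noise is applied to all
#' signal volumes.
#'
#' @param n_cr,n_pr Number of complete-response / partial-response patients.
#' @param noise_sd Noise standard deviation in signal units; `NULL` (default)
#'   means 2 percent of the mean baseline signal; `0` disables noise.
#' @param seed Integer master seed; all draws derive from it.
#' @param out_dir Output directory (created if needed).
#' @param params An [acq_params()].
#' @param lesion_shape Voxel dimensions of the lesion bounding block.
#' @return Invisibly, the manifest `data.frame` (also written to
#'   `manifest.csv` in `out_dir`).
#' @export
make_cohort <- function(n_cr, n_pr, noise_sd = NULL, seed = 1,
                        out_dir = tempfile("cohort"),
                        params = acq_params(), lesion_shape = c(9, 9, 5)) {
  if (n_cr < 1 || n_pr < 1) stop("make_cohort: counts must be >= 1", call. = FALSE)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("make_cohort: cannot create output directory ", out_dir, call. = FALSE)
  }
  geom <- .scene_geometry(lesion_shape)
  t10 <- .scene_t10(geom$shape, geom$aorta)
  onset <- params$n_baseline * params$dt
  aif <- make_population_aif(params, onset = onset)
  classes <- c(rep("CR", n_cr), rep("PR", n_pr))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lesion_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                    2L * length(classes)),
                         ncol = 2)
  rows <- list()
  for (i in seq_along(classes)) {
    pid <- sprintf("P%03d", i)
    for (vi in c(1L, 2L)) {
      visit <- c("pre", "post")[vi]
      lesion <- make_lesion(classes[i], lesion_shape,
                            seed = lesion_seeds[i, vi], visit = visit)
      scene <- .embed_lesion_scene(lesion, geom, t10, aif, params)
      s_sd <- if (is.null(noise_sd)) 0.02 * mean(scene$base_signal) else noise_sd
      dyn_sig <- scene$dyn
      vfa <- scene$vfa
      if (s_sd > 0) {
        dyn_sig <- dyn_sig + array(stats::rnorm(length(dyn_sig), 0, s_sd),
                                   dim(dyn_sig))
        vfa <- vfa + array(stats::rnorm(length(vfa), 0, s_sd), dim(vfa))
      }
      paths <- c(dynamic = sprintf("dyn_%s_%s.nii", pid, visit),
                 vfa = sprintf("vfa_%s_%s.nii", pid, visit),
                 lesion_mask = sprintf("lesionmask_%s_%s.nii", pid, visit),
                 aorta_mask = sprintf("aortamask_%s_%s.nii", pid, visit))
      write_volume(dyn_sig, file.path(out_dir, paths["dynamic"]))
      write_volume(vfa, file.path(out_dir, paths["vfa"]))
      write_volume(scene$lesion_mask * 1, file.path(out_dir, paths["lesion_mask"]))
      write_volume(geom$aorta * 1, file.path(out_dir, paths["aorta_mask"]))
      tm <- lesion$mask
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = pid, class = classes[i], visit = visit,
        dynamic = paths[["dynamic"]], vfa = paths[["vfa"]],
        lesion_mask = paths[["lesion_mask"]], aorta_mask = paths[["aorta_mask"]],
        true_ktrans_mean = mean(lesion$ktrans[tm]),
        true_ve_mean = mean(lesion$ve[tm]),
        true_vp_mean = mean(lesion$vp[tm]),
        true_kep_mean = mean(lesion$kep[tm]),
        lesion_seed = lesion_seeds[i, vi],
        stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  attr(manifest, "out_dir") <- out_dir
  attr(manifest, "params") <- params
  invisible(manifest)
}

## place a lesion block into the scene, run the forward model, and build the
## multi-flip-angle baseline volumes
.embed_lesion_scene <- function(lesion, geom, t10, aif, params) {
  shape <- geom$shape
  ls <- dim(lesion$mask)
  full <- list(ktrans = array(NA_real_, shape), kep = array(NA_real_, shape),
               ve = array(NA_real_, shape), vp = array(NA_real_, shape),
               mask = array(FALSE, shape))
  ix <- seq_len(ls[1]); iy <- seq_len(ls[2]); iz <- seq_len(ls[3])
  for (nm in c("ktrans", "kep", "ve", "vp")) {
    full[[nm]][ix, iy, iz] <- lesion[[nm]]
  }
  full$mask[ix, iy, iz] <- lesion$mask
  full_lesion <- structure(c(full, list(class_label = lesion$class_label)),
                           class = "gt_lesion")
  dyn <- forward_signal(full_lesion, aif, t10, params)
  # blood voxels carry the whole-blood AIF concentration
  nt <- length(aif$times)
  n3 <- prod(shape)
  cb <- aif$cp * (1 - params$hematocrit)
  for (v in which(geom$aorta)) {
    t1t <- 1 / (1 / t10$t1[v] + params$relaxivity_r1 * cb)
    dyn$signal[v + n3 * (seq_len(nt) - 1L)] <-
      spgr_signal(t10$m0[v], t1t, params)
  }
  angles <- params$flip_angles_t1
  vfa <- array(0, c(shape, length(angles)))
  for (k in seq_along(angles)) {
    vfa[, , , k] <- spgr_signal(t10$m0, t10$t1, params, flip_angle = angles[k])
  }
  list(dyn = dyn$signal, vfa = vfa, lesion_mask = full$mask,
       base_signal = spgr_signal(t10$m0, t10$t1, params))
}
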