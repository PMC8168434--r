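#' Construct an arterial input function curve
#'
#' @param times Sampling times, seconds, nondecreasing.
#' @param cp Plasma contrast concentration, mmol/L, one value per time.
#' @return Object of class `aif_curve`.
#' @export
aif_curve <- function(times, cp) {
  if (length(times) != length(cp)) {
    stop("aif_curve: times and cp must have equal length", call. = FALSE)
  }
  if (any(diff(times) < 0)) {
    stop("aif_curve: times must be nondecreasing", call. = FALSE)
  }
  if (any(!is.finite(cp))) {
    stop("aif_curve: cp must be finite", call. = FALSE)
  }
  structure(list(times = as.numeric(times), cp = as.numeric(cp)),
            class = "aif_curve")
}

#' Extract the arterial input function from an aorta region
#'
#' Averages the blood concentration curve over the voxels of an aorta mask and
#' divides by (1 - hematocrit) to convert whole-blood to plasma concentration,
#' as required by the Tofts model (whose driving function is plasma
#' concentration). The correction can be disabled by passing `hematocrit = 0`.
#'
#' @param conc A `conc_series` (4D concentration, mmol/L).
#' @param aorta_mask Logical 3D array, congruent with the concentration grid.
#' @param hematocrit Hematocrit fraction in `[0, 1)`.
#' @return An [aif_curve()].
#' @export
extract_aif <- function(conc, aorta_mask, hematocrit = 0.42) {
  d <- dim(conc$conc)
  if (!identical(as.integer(dim(aorta_mask)), as.integer(d[1:3]))) {
    stop("extract_aif: mask grid does not match the concentration grid", call. = FALSE)
  }
  idx <- which(aorta_mask)
  if (length(idx) == 0L) {
    stop("extract_aif: aorta mask is empty", call. = FALSE)
  }
  if (hematocrit < 0 || hematocrit >= 1) {
    stop("extract_aif: hematocrit must be in [0, 1)", call. = FALSE)
  }
  cmat <- matrix(conc$conc, nrow = prod(d[1:3]), ncol = d[4])
  cb <- colMeans(cmat[idx, , drop = FALSE], na.rm = TRUE)
  aif_curve(conc$times, cb / (1 - hematocrit))
}

#' Write / read an AIF as a two-column CSV
#'
#' Columns `time_s`, `cp_mmol_per_L`.
#'
#' @param aif An [aif_curve()].
#' @param path File path.
#' @return `write_aif_csv` returns `path` invisibly; `read_aif_csv` returns an
#'   [aif_curve()].
#' @export
write_aif_csv <- function(aif, path) {
  utils::write.csv(data.frame(time_s = aif$times, cp_mmol_per_L = aif$cp),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_aif_csv
#' @export
read_aif_csv <- function(path) {
  df <- utils::read.csv(path)
  aif_curve(df$time_s, df$cp_mmol_per_L)
}
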