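#' Quantize a parameter map for co-occurrence analysis
#'
#' Min-max equal-width binning of the in-mask values into integer gray levels
#' `1..n_levels`. Bins are left-closed with a right-closed top bin, so the
#' maximum maps to `n_levels`. A constant map quantizes to a single level (1).
#' Quantization is invariant to affine rescaling of the input map.
#'
#' @param map Numeric 3D array.
#' @param mask Logical 3D array, congruent, nonempty.
#' @param n_levels Number of gray levels, >= 2.
#' @return Integer 3D array with levels inside the mask, `NA` outside.
#' @export
quantize <- function(map, mask, n_levels = 32) {
  if (!identical(dim(map), dim(mask))) {
    stop("quantize: map and mask grids differ", call. = FALSE)
  }
  idx <- which(mask & is.finite(map))
  if (length(idx) == 0L) stop("quantize: mask is empty", call. = FALSE)
  if (n_levels < 2) stop("quantize: n_levels must be >= 2", call. = FALSE)
  v <- map[idx]
  lo <- min(v); hi <- max(v)
  q <- array(NA_integer_, dim(map))
  if (hi == lo) {
    q[idx] <- 1L
  } else {
    lev <- floor((v - lo) / (hi - lo) * n_levels) + 1L
    lev[lev > n_levels] <- as.integer(n_levels)  # right-closed top bin
    q[idx] <- as.integer(lev)
  }
  q
}

## the 13 unique 3D direction offsets (half of the 26-neighborhood)
.glcm_offsets_3d <- function(distance = 1L) {
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # keep one of each +/- pair: lexicographically positive direction
  keep <- offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
    (offs$dz == 0 & offs$dy == 0 & offs$dx > 0)
  as.matrix(offs[keep, ]) * as.integer(distance)
}

#' 3D gray-level co-occurrence matrix
#'
#' Accumulates co-occurring level pairs over the 13 unique 3D direction
#' offsets at the given distance, restricted to voxel pairs that are both
#' inside the mask, pooled into a single matrix (not averaged per direction).
#' In symmetric mode each pair is also counted transposed. The matrix is
#' normalized to sum to 1.
#'
#' @param q Integer 3D array of gray levels (from [quantize()]), `NA` outside
#'   the region.
#' @param mask Logical 3D array; pairs are counted only when both voxels are
#'   in-mask. Must contain at least 2 voxels.
#' @param n_levels Number of gray levels of the quantization.
#' @param distance Offset length in voxels, >= 1.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @return Object of class `glcm`: list with probability matrix `p`
#'   (`n_levels` x `n_levels`), `n_levels`, `offsets`, `n_pairs`.
#' @export
glcm_3d <- function(q, mask, n_levels = max(q, na.rm = TRUE), distance = 1,
                    symmetric = TRUE) {
  if (sum(mask) < 2L) stop("glcm_3d: mask must contain >= 2 voxels", call. = FALSE)
  if (distance < 1) stop("glcm_3d: distance must be >= 1", call. = FALSE)
  d <- dim(q)
  offsets <- .glcm_offsets_3d(distance)
  counts <- matrix(0, n_levels, n_levels)
  inmask <- mask & !is.na(q)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    # overlapping index ranges of the shifted grids
    rng <- function(n, ofs) {
      lo <- max(1, 1 - ofs); hi <- min(n, n - ofs)
      if (hi < lo) integer(0) else lo:hi
    }
    xs <- rng(d[1], o[1]); ys <- rng(d[2], o[2]); zs <- rng(d[3], o[3])
    if (!length(xs) || !length(ys) || !length(zs)) next
    a <- q[xs, ys, zs, drop = FALSE]
    b <- q[xs + o[1], ys + o[2], zs + o[3], drop = FALSE]
    ok <- inmask[xs, ys, zs, drop = FALSE] &
      inmask[xs + o[1], ys + o[2], zs + o[3], drop = FALSE]
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(n_levels)),
                 factor(b[ok], levels = seq_len(n_levels)))
    counts <- counts + unclass(tab)
  }
  if (symmetric) counts <- counts + t(counts)
  total <- sum(counts)
  if (total == 0) stop("glcm_3d: no co-occurring in-mask pairs found", call. = FALSE)
  structure(list(p = counts / total, n_levels = as.integer(n_levels),
                 offsets = offsets, n_pairs = total),
            class = "glcm")
}

#' Haralick-type texture features of a co-occurrence matrix
#'
#' The seven classical features: energy \eqn{\sum p^2}, entropy
#' \eqn{-\sum p \log_2 p} (with \eqn{0 \log 0 = 0}), inertia (contrast)
#' \eqn{\sum (i-j)^2 p}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p / (\sigma_i \sigma_j)}, cluster shade
#' \eqn{\sum (i+j-\mu_i-\mu_j)^3 p}, cluster prominence
#' \eqn{\sum (i+j-\mu_i-\mu_j)^4 p}, and inverse difference moment
#' \eqn{\sum p / (1+(i-j)^2)}. Correlation is `NA` when either marginal is
#' degenerate.
#'
#' @param g A `glcm` from [glcm_3d()], or a normalized probability matrix.
#' @param log_base Base of the entropy logarithm (default 2, i.e. bits).
#' @return Object of class `texture_features`: named list with `energy`,
#'   `entropy`, `inertia`, `correlation`, `cluster_shade`,
#'   `cluster_prominence`, `idm`.
#' @export
texture_features <- function(g, log_base = 2) {
  p <- if (inherits(g, "glcm")) g$p else as.matrix(g)
  if (nrow(p) != ncol(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("texture_features: input must be a normalized square probability matrix",
         call. = FALSE)
  }
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  pos <- p > 0
  mu_i <- sum(i * p)
  mu_j <- sum(j * p)
  sd_i <- sqrt(sum((i - mu_i)^2 * p))
  sd_j <- sqrt(sum((j - mu_j)^2 * p))
  corr <- if (sd_i > 0 && sd_j > 0) {
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  } else NA_real_
  s <- i + j - mu_i - mu_j
  structure(list(
    energy = sum(p^2),
    entropy = -sum(p[pos] * log(p[pos], base = log_base)),
    inertia = sum((i - j)^2 * p),
    correlation = corr,
    cluster_shade = sum(s^3 * p),
    cluster_prominence = sum(s^4 * p),
    idm = sum(p / (1 + (i - j)^2))
  ), class = "texture_features")
}

#' @export
print.texture_features <- function(x, ...) {
  cat("GLCM texture features\n")
  for (nm in names(x)) cat(sprintf("  %-18s %.6g\n", nm, x[[nm]]))
  invisible(x)
}

#' Texture features of a lesion on a parameter map
#'
#' Convenience chain quantize -> glcm_3d -> texture_features. By default the
#' features are computed on the Ktrans map at 32 gray levels, distance 1,
#' symmetric, pooled over the 13 unique 3D directions.
#'
#' @param map Numeric 3D array (typically a parameter map such as Ktrans).
#' @param mask Logical 3D lesion mask.
#' @param n_levels,distance,symmetric,log_base Passed to the component steps.
#' @return A `texture_features` object.
#' @export
lesion_texture <- function(map, mask, n_levels = 32, distance = 1,
                           symmetric = TRUE, log_base = 2) {
  q <- quantize(map, mask, n_levels)
  g <- glcm_3d(q, mask, n_levels = n_levels, distance = distance,
               symmetric = symmetric)
  texture_features(g, log_base = log_base)
}
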