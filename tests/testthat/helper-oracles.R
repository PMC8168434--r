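# Independent oracles and small fixture builders used across the suite.

# constant-T1 map on a grid
uniform_t1_map <- function(shape, t1 = 1.0, m0 = 1000) {
  structure(list(t1 = array(t1, shape), m0 = array(m0, shape),
                 valid = array(TRUE, shape)),
            class = "t1_map")
}

# brute-force GLCM: O(N^2) double loop over all voxel pairs, counting pairs
# whose displacement matches any +/- offset at the given distance
brute_glcm <- function(q, mask, n_levels, distance = 1) {
  d <- dim(q)
  idx <- which(mask & !is.na(q))
  pos <- arrayInd(idx, d)
  offs <- rbind(
    expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  )
  offs <- as.matrix(offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ])
  offs <- offs * distance
  counts <- matrix(0, n_levels, n_levels)
  for (a in seq_along(idx)) for (b in seq_along(idx)) {
    if (a == b) next
    dv <- pos[b, ] - pos[a, ]
    if (any(apply(offs, 1, function(o) all(o == dv)))) {
      counts[q[idx[a]], q[idx[b]]] <- counts[q[idx[a]], q[idx[b]]] + 1
    }
  }
  # counting ordered pairs over all +/- directions equals the symmetric GLCM
  counts / sum(counts)
}

# term-by-term texture feature summation on a probability matrix
brute_features <- function(p) {
  n <- nrow(p)
  mu_i <- 0; mu_j <- 0
  for (i in 1:n) for (j in 1:n) { mu_i <- mu_i + i * p[i, j]; mu_j <- mu_j + j * p[i, j] }
  sd_i <- 0; sd_j <- 0
  for (i in 1:n) for (j in 1:n) {
    sd_i <- sd_i + (i - mu_i)^2 * p[i, j]; sd_j <- sd_j + (j - mu_j)^2 * p[i, j]
  }
  sd_i <- sqrt(sd_i); sd_j <- sqrt(sd_j)
  out <- list(energy = 0, entropy = 0, inertia = 0, correlation = 0,
              cluster_shade = 0, cluster_prominence = 0, idm = 0)
  for (i in 1:n) for (j in 1:n) {
    pij <- p[i, j]
    out$energy <- out$energy + pij^2
    if (pij > 0) out$entropy <- out$entropy - pij * log2(pij)
    out$inertia <- out$inertia + (i - j)^2 * pij
    out$correlation <- out$correlation + (i - mu_i) * (j - mu_j) * pij
    s <- i + j - mu_i - mu_j
    out$cluster_shade <- out$cluster_shade + s^3 * pij
    out$cluster_prominence <- out$cluster_prominence + s^4 * pij
    out$idm <- out$idm + pij / (1 + (i - j)^2)
  }
  out$correlation <- out$correlation / (sd_i * sd_j)
  out
}

# exact two-sided Mann-Whitney p by enumeration of all label assignments
enum_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, function(ix) u_of(pooled[ix], pooled[-ix]))
  mu <- n1 * (length(pooled) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# rank-sum AUC oracle: U / (n1 * n2) with half credit for ties,
# oriented so the positive class scores higher
rank_auc <- function(scores, labels, positive) {
  xs <- scores[labels == positive]
  ys <- scores[labels != positive]
  (sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))) /
    (length(xs) * length(ys))
}

# one-voxel noisy recovery experiment through the signal domain:
# true Tofts curve -> SPGR signal -> additive noise -> exact conversion -> fit
noisy_voxel_fit <- function(ktrans, kep, vp, aif, params, t10 = 1.0,
                            m0 = 1000, noise_frac = 0.02) {
  ct <- tofts_forward(ktrans, kep, vp, aif)
  t1t <- 1 / (1 / t10 + params$relaxivity_r1 * ct)
  sig <- spgr_signal(m0, t1t, params)
  s0 <- spgr_signal(m0, t10, params)
  sig <- sig + stats::rnorm(length(sig), 0, noise_frac * s0)
  shape <- c(1, 1, 1)
  dyn <- dynamic_series(array(rep(sig, each = 1), c(shape, length(sig))),
                        aif$times, params)
  tmap <- uniform_t1_map(shape, t10, m0)
  conc <- signal_to_concentration_exact(dyn, tmap, params)
  fit_voxel(conc$conc[1, 1, 1, ], aif)
}
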