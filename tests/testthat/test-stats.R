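test_that("Mann-Whitney: exact small-sample p, identical samples, constant input", {
  # U = 0 for x; exact two-sided p = 2/6 by enumeration of C(4,2) assignments
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, enum_mwu_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_equal(mw$p_value, 1 / 3, tolerance = 1e-12)
  # identical multisets -> p = 1 within tolerance
  expect_gt(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  expect_warning(mwc <- mann_whitney(rep(5, 4), rep(5, 4)), "constant")
  expect_equal(mwc$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1), "nonempty")
})

test_that("exact enumeration and normal approximation agree for n = 16 + 16", {
  set.seed(52)
  x <- rnorm(16); y <- rnorm(16, 0.5)
  approx_p <- mann_whitney(x, y)$p_value
  exact_p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_lt(abs(approx_p - exact_p), 0.02)
})

test_that("group screening has power at the post-treatment effect size", {
  # 16 vs 16 drawn at the post-treatment Ktrans class moments
  set.seed(61)
  nrep <- 1000
  hits <- vapply(seq_len(nrep), function(i) {
    cr <- rnorm(16, 0.117, 0.065)
    pr <- rnorm(16, 0.299, 0.231)
    mann_whitney(cr, pr)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.70)
})

test_that("Spearman filter keeps the smallest-p member of correlated groups", {
  set.seed(3)
  n <- 40
  a <- rnorm(n)
  tab <- data.frame(a = a, b = 2 * a + 1, c = rnorm(n))  # b is rank-identical to a
  pv <- c(a = 0.01, b = 0.03, c = 0.02)
  expect_identical(spearman_filter(tab, c("a", "b", "c"), pv), c("a", "c"))
  # mutually independent features are all retained
  tab2 <- data.frame(x = rnorm(n), y = rnorm(n), z = rnorm(n))
  pv2 <- c(x = 0.01, y = 0.02, z = 0.03)
  expect_identical(spearman_filter(tab2, c("x", "y", "z"), pv2), c("x", "y", "z"))
  expect_identical(spearman_filter(tab2, character(0), pv2), character(0))
})

test_that("Spearman filter reproduces the post-triple retention pattern", {
  # six candidates: three post markers plus strongly correlated change twins;
  # the post members get the smaller screening p-values
  set.seed(77)
  n <- 32
  kp <- rnorm(n); vp_ <- rnorm(n); ep <- rnorm(n)
  tab <- data.frame(
    ktrans_post = kp, ve_post = vp_, entropy_post = ep,
    ktrans_change = kp + 0.1 * rnorm(n),
    ve_change = vp_ + 0.1 * rnorm(n),
    entropy_change = ep + 0.1 * rnorm(n)
  )
  pv <- c(ktrans_post = 0.002, ve_post = 0.002, entropy_post = 0.032,
          ktrans_change = 0.008, ve_change = 0.005, entropy_change = 0.047)
  kept <- spearman_filter(tab, names(pv), pv)
  expect_setequal(kept, c("ktrans_post", "ve_post", "entropy_post"))
})

test_that("logistic reporting arithmetic reproduces Wald, OR and CI from (coef, SE)", {
  # entropy-term row: coefficient -3.235, SE 1.605
  w <- wald_table(-3.235, 1.605)
  expect_equal(w$wald, 4.063, tolerance = 0.005 / 4.063)
  expect_equal(w$odds_ratio, 0.039, tolerance = 0.0005 / 0.039)
  # zero coefficient: OR 1, CI spans 1
  w0 <- wald_table(0, 2)
  expect_equal(w0$odds_ratio, 1)
  expect_lt(w0$ci_lower, 1); expect_gt(w0$ci_upper, 1)
})

test_that("logistic fit recovers known coefficients on simulated data", {
  set.seed(40)
  n <- 2000
  x1 <- rnorm(n); x2 <- rnorm(n)
  eta <- 0.5 - 1.2 * x1 + 0.8 * x2
  y <- rbinom(n, 1, plogis(eta))
  tab <- data.frame(x1 = x1, x2 = x2,
                    group = ifelse(y == 1, "CR", "PR"))
  fit <- fit_logistic(tab, c("x1", "x2"))
  est <- fit$terms
  truth <- c(0.5, -1.2, 0.8)
  for (i in 1:3) {
    expect_lt(abs(est$coefficient[i] - truth[i]), 2 * est$std_error[i])
  }
  expect_true(fit$converged)
  expect_false(fit$separation)
  # invariants of the reporting columns
  expect_true(all(est$odds_ratio > 0))
  expect_true(all(est$ci_lower < est$odds_ratio & est$odds_ratio < est$ci_upper))
})

test_that("perfect separation is flagged, never silent", {
  tab <- data.frame(x = c(1:5, 11:15),
                    group = rep(c("PR", "CR"), each = 5))
  expect_warning(fit <- fit_logistic(tab, "x"), "separation")
  expect_true(fit$separation)
})

test_that("preset response model evaluates the published-style formula exactly", {
  preset <- response_model_preset()
  hand <- function(k, v, e) {
    1 / (1 + exp(-(26.772 - 17.010 * k - 15.854 * v - 3.235 * e)))
  }
  # arbitrary inputs agree with hand evaluation to 1e-12
  set.seed(5)
  for (i in 1:20) {
    k <- runif(1, 0, 1); v <- runif(1, 0, 1); e <- runif(1, 4, 8)
    got <- predict_prob(preset, data.frame(ktrans_post = k, ve_post = v,
                                           entropy_post = e))
    expect_equal(got, hand(k, v, e), tolerance = 1e-12)
  }
  # all-zero features: intercept-only evaluation, essentially 1
  expect_equal(predict_prob(preset, data.frame(ktrans_post = 0, ve_post = 0,
                                               entropy_post = 0)),
               1 / (1 + exp(-26.772)), tolerance = 1e-12)
  # CR post-treatment group means -> about 0.954; PR means strictly lower
  p_cr <- predict_prob(preset, data.frame(ktrans_post = 0.117, ve_post = 0.130,
                                          entropy_post = 6.084))
  p_pr <- predict_prob(preset, data.frame(ktrans_post = 0.299, ve_post = 0.322,
                                          entropy_post = 6.777))
  expect_equal(p_cr, hand(0.117, 0.130, 6.084), tolerance = 1e-12)
  expect_equal(round(p_cr, 3), 0.954)
  expect_lt(p_pr, p_cr)
  # monotone decreasing in each feature
  base <- data.frame(ktrans_post = 0.2, ve_post = 0.2, entropy_post = 6)
  for (f in c("ktrans_post", "ve_post", "entropy_post")) {
    up <- base; up[[f]] <- up[[f]] + 0.1
    expect_lt(predict_prob(preset, up), predict_prob(preset, base))
  }
  expect_error(predict_prob(preset, data.frame(ktrans_post = 1)), "missing")
})

test_that("ROC analysis: perfect separation, permutation null, rank identity", {
  r <- roc_analysis(c(1, 2, 3, 4), c("PR", "PR", "CR", "CR"))
  expect_equal(r$auc, 1)
  expect_gt(r$cutoff, 2); expect_lt(r$cutoff, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_error(roc_analysis(1:4, rep("CR", 4)), "both classes")
  # label-independent scores: mean AUC 0.5 (auto direction folds at 0.5,
  # so compare the oriented rank AUC to 0.5)
  set.seed(71)
  aucs <- replicate(400, {
    s <- rnorm(20)
    lab <- rep(c("CR", "PR"), 10)
    rank_auc(s, lab, "CR")
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  # AUC = U / (n1 n2) identity on random (tied and untied) inputs
  for (i in 1:20) {
    s <- sample(1:8, 24, replace = TRUE)
    lab <- sample(rep(c("CR", "PR"), 12))
    r <- roc_analysis(s, lab)
    oracle <- rank_auc(s, lab, "CR")
    expect_equal(r$auc, max(oracle, 1 - oracle), tolerance = 1e-12)
  }
})

test_that("DeLong comparison: identical models give p = 1; internal AUCs consistent", {
  set.seed(9)
  s <- rnorm(32)
  lab <- rep(c("CR", "PR"), 16)
  expect_warning(d <- delong_test(s, s, lab), "degenerate")
  expect_equal(d$p_value, 1)
  # AUCs inside the test equal the rank-sum AUCs of the two score vectors
  s2 <- rnorm(32)
  d2 <- suppressWarnings(delong_test(s, s2, lab))
  expect_equal(d2$auc_a, rank_auc(s, lab, "CR"), tolerance = 1e-12)
  expect_equal(d2$auc_b, rank_auc(s2, lab, "CR"), tolerance = 1e-12)
})

test_that("DeLong null calibration: type-I error near 0.05", {
  set.seed(83)
  nrep <- 1000
  rej <- vapply(seq_len(nrep), function(i) {
    lab <- rep(c("CR", "PR"), 16)
    suppressWarnings(
      delong_test(rnorm(32), rnorm(32), lab)$p_value < 0.05
    )
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("full analysis chain is deterministic and calibrated under the null", {
  tab <- simulate_feature_table(16, 16, seed = 12)
  r1 <- suppressWarnings(run_full_analysis(tab))
  r2 <- suppressWarnings(run_full_analysis(tab))
  expect_equal(r1$screen, r2$screen)
  expect_identical(r1$retained, r2$retained)
  if (!is.null(r1$roc_model)) expect_equal(r1$roc_model$auc, r2$roc_model$auc)
  # shuffled labels: per-feature null rejection rate near alpha, and the
  # median count of significant features is small
  set.seed(95)
  nrep <- 60
  counts <- integer(nrep)
  rates <- numeric(0)
  for (i in seq_len(nrep)) {
    tb <- simulate_feature_table(16, 16, seed = 3000 + i)
    tb$group <- sample(tb$group)
    rp <- suppressWarnings(run_full_analysis(tb))
    counts[i] <- length(rp$significant)
    rates <- c(rates, rp$screen$p_value < 0.05)
  }
  expect_lt(abs(mean(rates) - 0.05), 0.03)
  expect_lte(median(counts), 2)
})
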