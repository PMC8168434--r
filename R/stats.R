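#' Mann-Whitney U test between two groups
#'
#' Two-sided rank-sum comparison. The exact null distribution is used for
#' small samples without ties (pooled n <= 12); otherwise the normal
#' approximation with tie and continuity correction is applied.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param feature Optional feature name carried into the result.
#' @return List with `feature`, `u_statistic` (U of the first sample) and
#'   two-sided `p_value`.
#' @export
mann_whitney <- function(x, y, feature = NA_character_) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("mann_whitney: both samples must be nonempty", call. = FALSE)
  }
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("mann_whitney: pooled sample is constant; p = 1", call. = FALSE)
    return(list(feature = feature, u_statistic = length(x) * length(y) / 2,
                p_value = 1))
  }
  ties <- any(duplicated(pooled))
  use_exact <- !ties && (length(x) + length(y)) <= 12L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(feature = feature, u_statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Greedy Spearman redundancy filter
#'
#' Orders candidate features by ascending screening p-value and retains a
#' candidate only if its absolute Spearman rank correlation with every
#' already-retained feature is below the threshold. Reproduces the usual
#' "drop correlated features, keep the stronger one" reduction.
#'
#' @param table A `feature_table` (or data.frame) holding the feature columns.
#' @param candidates Character vector of feature column names.
#' @param pvals Named numeric vector of screening p-values, one per candidate.
#' @param threshold Exclusion threshold on |rho| (default 0.6).
#' @return Character vector of retained feature names (ascending p order).
#' @export
spearman_filter <- function(table, candidates, pvals, threshold = 0.6) {
  if (length(candidates) == 0L) return(character(0))
  pv <- pvals[candidates]
  ord <- candidates[order(pv)]
  retained <- character(0)
  for (f in ord) {
    ok <- TRUE
    for (r in retained) {
      rho <- suppressWarnings(
        stats::cor(table[[f]], table[[r]], method = "spearman",
                   use = "complete.obs"))
      if (is.finite(rho) && abs(rho) >= threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, f)
  }
  retained
}

#' Reporting arithmetic for logistic coefficients
#'
#' Pure function of (coefficient, standard error): Wald statistic
#' (coef/SE)^2, odds ratio exp(coef), and the 95 percent Wald confidence
#' interval exp(coef +/- z * SE).
#'
#' @param coef,se Numeric vectors of equal length.
#' @param conf_z Normal quantile for the interval (default 1.96).
#' @return data.frame with `coefficient`, `std_error`, `wald`, `p_value`
#'   (chi-square, 1 df), `odds_ratio`, `ci_lower`, `ci_upper`.
#' @export
wald_table <- function(coef, se, conf_z = 1.96) {
  wald <- (coef / se)^2
  data.frame(
    coefficient = coef, std_error = se, wald = wald,
    p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    odds_ratio = exp(coef),
    ci_lower = exp(coef - conf_z * se),
    ci_upper = exp(coef + conf_z * se)
  )
}

#' Fit a logistic response model
#'
#' Maximum-likelihood logistic regression (IRLS via `glm`) of the response
#' class on the given features, with CR coded as the positive class. Standard
#' errors come from the inverse observed information; Wald, odds-ratio and
#' 95 percent CI columns follow [wald_table()]. Non-convergence and
#' quasi-separation are reported via flags, never silently.
#'
#' @param table A `feature_table` with a `group` column (`"CR"`/`"PR"`).
#' @param features Character vector of predictor column names.
#' @param positive Level treated as the positive outcome (default `"CR"`).
#' @return Object of class `logistic_fit`: list with `terms` (a
#'   [wald_table()] data.frame with an `(Intercept)` row), `converged`,
#'   `separation`, `features`, `positive`, and the underlying `glm` object.
#' @export
fit_logistic <- function(table, features, positive = "CR") {
  y <- as.integer(table$group == positive)
  if (length(unique(y)) < 2L) {
    stop("fit_logistic: both outcome classes must be present", call. = FALSE)
  }
  df <- table[, features, drop = FALSE]
  df$.y <- y
  fml <- stats::as.formula(paste(".y ~", paste(features, collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  sm <- summary(fit)$coefficients
  # quasi-separation heuristic: fitted probabilities pinned at 0/1 or huge SEs
  p_hat <- stats::fitted(fit)
  separation <- any(p_hat > 1 - 1e-8) && any(p_hat < 1e-8) ||
    any(sm[, "Std. Error"] > 1e3)
  if (separation) {
    warning("fit_logistic: (quasi-)separation detected; coefficients unstable",
            call. = FALSE)
  }
  terms <- wald_table(sm[, "Estimate"], sm[, "Std. Error"])
  rownames(terms) <- rownames(sm)
  structure(list(terms = terms, converged = fit$converged,
                 separation = separation, features = features,
                 positive = positive, glm = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic response model (positive class: %s)%s\n", x$positive,
              if (x$separation) " [separation flagged]" else ""))
  print(round(x$terms, 4))
  invisible(x)
}

#' Reference coefficient preset for the post-treatment response model
#'
#' The shipped post-treatment combined model: logit(P(CR)) =
#' 26.772 - 17.010 Ktrans_post - 15.854 ve_post - 3.235 entropy_post, with
#' the reported standard errors. Lower post-treatment permeability, smaller
#' extravascular volume fraction and lower map entropy all push the predicted
#' probability of complete response up.
#'
#' @return A `logistic_fit`-like object (class `logistic_preset`) with a
#'   `terms` table usable by [predict_prob()].
#' @export
response_model_preset <- function() {
  coef <- c("(Intercept)" = 26.772, ktrans_post = -17.010,
            ve_post = -15.854, entropy_post = -3.235)
  se <- c("(Intercept)" = 11.699, ktrans_post = 8.737,
          ve_post = 7.869, entropy_post = 1.605)
  terms <- wald_table(coef, se)
  rownames(terms) <- names(coef)
  structure(list(terms = terms, converged = TRUE, separation = FALSE,
                 features = setdiff(names(coef), "(Intercept)"),
                 positive = "CR"),
            class = c("logistic_preset", "logistic_fit"))
}

#' Predicted probability of the positive class
#'
#' Evaluates the logistic transform of the linear predictor for a fitted
#' model or a coefficient preset. All model features must be present in
#' `newdata`.
#'
#' @param fit A `logistic_fit` or `logistic_preset`.
#' @param newdata data.frame (or named list) with one column per model
#'   feature.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(fit, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(fit$features, names(newdata))
  if (length(missing)) {
    stop("predict_prob: missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  coef <- fit$terms$coefficient
  names(coef) <- rownames(fit$terms)
  eta <- rep(coef[["(Intercept)"]], nrow(newdata))
  for (f in fit$features) eta <- eta + coef[[f]] * newdata[[f]]
  stats::plogis(eta)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' AUC by the rank (Mann-Whitney) formulation with half credit for ties,
#' 95 percent confidence interval by DeLong variance, and the cutoff
#' maximizing Youden's J = sensitivity + specificity - 1 (ties broken toward
#' higher sensitivity). The score direction is chosen so AUC >= 0.5
#' (`direction` records it), matching how single markers are reported.
#'
#' @param scores Numeric marker or model scores.
#' @param labels Class labels.
#' @param positive Positive class (default `"CR"`).
#' @return Object of class `roc_result`: `auc`, `ci95` (length 2), `cutoff`,
#'   `sensitivity`, `specificity`, `direction`, `n_pos`, `n_neg`, and the
#'   underlying `pROC::roc` object.
#' @export
roc_analysis <- function(scores, labels, positive = "CR") {
  y <- labels == positive
  if (!any(y) || all(y)) {
    stop("roc_analysis: both classes must be present", call. = FALSE)
  }
  r <- suppressMessages(pROC::roc(response = y, predictor = scores,
                                  levels = c(FALSE, TRUE), direction = "<",
                                  quiet = TRUE))
  if (as.numeric(pROC::auc(r)) < 0.5) {
    r <- suppressMessages(pROC::roc(response = y, predictor = scores,
                                    levels = c(FALSE, TRUE), direction = ">",
                                    quiet = TRUE))
  }
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(
    suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))[c(1, 3)]),
    error = function(e) c(NA_real_, NA_real_))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"),
                     transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[which.max(co$sensitivity[best])]
  structure(list(auc = auc, ci95 = ci, cutoff = co$threshold[best],
                 sensitivity = co$sensitivity[best],
                 specificity = co$specificity[best],
                 direction = r$direction, n_pos = sum(y), n_neg = sum(!y),
                 roc = r),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), cutoff %.4g: sens %.1f%%, spec %.1f%%\n",
              x$auc, x$ci95[1], x$ci95[2], x$cutoff,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' DeLong test for two paired AUCs
#'
#' Two-sided comparison of the AUCs of two score vectors measured on the same
#' subjects, via the DeLong structural-components z statistic. Degenerate
#' variance (e.g. identical scores) yields p = 1 with a warning.
#'
#' @param scores_a,scores_b Paired score vectors.
#' @param labels Class labels (same subjects for both scores).
#' @param positive Positive class (default `"CR"`).
#' @return List with `p_value`, `auc_a`, `auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "CR") {
  y <- labels == positive
  if (isTRUE(all.equal(scores_a, scores_b))) {
    warning("delong_test: identical score vectors; degenerate variance, p = 1",
            call. = FALSE)
    auc <- roc_analysis(scores_a, labels, positive)$auc
    return(list(p_value = 1, auc_a = auc, auc_b = auc))
  }
  # a fixed common direction keeps the paired comparison calibrated
  ra <- suppressMessages(pROC::roc(y, scores_a, levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE))
  rb <- suppressMessages(pROC::roc(y, scores_b, levels = c(FALSE, TRUE),
                                   direction = "<", quiet = TRUE))
  res <- tryCatch(
    suppressWarnings(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)),
    error = function(e) NULL
  )
  p <- if (is.null(res)) NaN else res$p.value
  if (!is.finite(p)) {
    warning("delong_test: degenerate AUC-difference variance; p = 1",
            call. = FALSE)
    p <- 1
  }
  list(p_value = p, auc_a = as.numeric(pROC::auc(ra)),
       auc_b = as.numeric(pROC::auc(rb)))
}

#' Full statistics stage: screen, filter, model, compare
#'
#' Runs the complete downstream chain on a pre/post/change feature table:
#' Mann-Whitney screening of every feature column between the CR and PR
#' groups, selection at p < alpha, greedy Spearman redundancy filtering,
#' logistic modelling of the retained features, per-feature and combined-model
#' ROC analysis, and DeLong comparisons of the post-only / change-only /
#' combined model variants.
#'
#' @param table A `feature_table` with a `group` column.
#' @param alpha Screening significance level (default 0.05).
#' @param rho_threshold Spearman exclusion threshold (default 0.6).
#' @param positive Positive class (default `"CR"`).
#' @return Object of class `analysis_report`: list with `screen`
#'   (data.frame feature/U/p), `significant`, `retained`, `model`
#'   (`logistic_fit` or NULL), `roc_single` (named list of `roc_result`),
#'   `roc_model` (`roc_result` or NULL), `model_variants` (AUC per variant)
#'   and `delong` (pairwise p-values).
#' @export
run_full_analysis <- function(table, alpha = 0.05, rho_threshold = 0.6,
                              positive = "CR") {
  feats <- setdiff(names(table), c("patient_id", "group"))
  feats <- feats[vapply(table[feats], is.numeric, logical(1))]
  grp <- table$group
  screen <- do.call(rbind, lapply(feats, function(f) {
    mw <- mann_whitney(table[[f]][grp == positive],
                       table[[f]][grp != positive], feature = f)
    data.frame(feature = f, u_statistic = mw$u_statistic,
               p_value = mw$p_value, stringsAsFactors = FALSE)
  }))
  pv <- stats::setNames(screen$p_value, screen$feature)
  significant <- screen$feature[screen$p_value < alpha]
  retained <- spearman_filter(table, significant, pv, rho_threshold)
  model <- NULL; roc_model <- NULL
  roc_single <- lapply(stats::setNames(retained, retained), function(f) {
    roc_analysis(table[[f]], grp, positive)
  })
  if (length(retained) >= 1L) {
    model <- fit_logistic(table, retained, positive)
    roc_model <- roc_analysis(predict_prob(model, table), grp, positive)
  }
  # model variants: post-only, change-only, and both, over the significant set
  variant_sets <- list(
    post = grep("_post$", significant, value = TRUE),
    change = grep("_change$", significant, value = TRUE),
    change_post = grep("_(post|change)$", significant, value = TRUE)
  )
  variant_scores <- lapply(variant_sets, function(fs) {
    if (length(fs) == 0L) return(NULL)
    predict_prob(fit_logistic(table, fs, positive), table)
  })
  model_variants <- vapply(variant_scores, function(s) {
    if (is.null(s)) NA_real_ else roc_analysis(s, grp, positive)$auc
  }, numeric(1))
  pairs <- utils::combn(names(variant_scores), 2, simplify = FALSE)
  delong <- lapply(pairs, function(pr) {
    a <- variant_scores[[pr[1]]]; b <- variant_scores[[pr[2]]]
    if (is.null(a) || is.null(b)) return(NULL)
    c(stats::setNames(delong_test(a, b, grp, positive)$p_value,
                      paste(pr, collapse = "_vs_")))
  })
  delong <- unlist(Filter(Negate(is.null), delong))
  structure(list(screen = screen, significant = significant,
                 retained = retained, model = model,
                 roc_single = roc_single, roc_model = roc_model,
                 model_variants = model_variants, delong = delong,
                 alpha = alpha, rho_threshold = rho_threshold,
                 positive = positive),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Response-biomarker analysis report\n")
  cat(sprintf("  %d features screened, %d significant at p < %g\n",
              nrow(x$screen), length(x$significant), x$alpha))
  cat("  retained after Spearman filter:",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "(none)",
      "\n")
  if (!is.null(x$roc_model)) {
    cat(sprintf("  combined model AUC %.3f\n", x$roc_model$auc))
    for (f in names(x$roc_single)) {
      cat(sprintf("    %-16s AUC %.3f\n", f, x$roc_single[[f]]$auc))
    }
  }
  if (length(x$delong)) {
    cat("  DeLong model comparisons:\n")
    for (nm in names(x$delong)) {
      cat(sprintf("    %-24s p = %.4f\n", nm, x$delong[[nm]]))
    }
  }
  invisible(x)
}
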