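# DeLong placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  v10 <- vapply(pos, function(p)
    mean((p > neg) + 0.5 * (p == neg)), numeric(1))
  v01 <- vapply(neg, function(q)
    mean((pos > q) + 0.5 * (pos == q)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' ROC curve and AUC with DeLong variance
#'
#' AUC is the Mann-Whitney concordance with half credit for ties; the
#' 95% CI is `AUC +/- 1.96 sqrt(var)` with the DeLong variance, clipped
#' to `[0, 1]`. The threshold sweep predicts positive at
#' `score >= threshold`.
#'
#' @param scores continuous scores (higher = more likely positive).
#' @param labels binary 0/1 outcomes; both classes must be present.
#' @return A `roc_result`: `auc`, `var`, `ci`, and `sweep` (data.frame
#'   of threshold, sensitivity, specificity).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
  pl <- delong_placements(scores, labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  v <- var(pl$v10) / n1 + var(pl$v01) / n0
  ci <- pmin(pmax(pl$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v), 0), 1)
  thr <- c(-Inf, sort(unique(scores)))
  sweep_df <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(scores[labels == 1] >= t),
                         numeric(1)),
    specificity = vapply(thr, function(t) mean(scores[labels == 0] < t),
                         numeric(1)))
  structure(list(auc = pl$auc, var = v, ci = ci, sweep = sweep_df,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci[1], x$ci[2]))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two models scored on the same cases via the
#' covariance-adjusted normal test on the AUC difference (placement
#' values).
#'
#' @param scores_a,scores_b scores of the two models on the same cases.
#' @param labels shared binary outcomes.
#' @return list with `statistic` (z), `p` (two-sided), `auc_a`, `auc_b`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("paired design required: equal lengths")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$v10)
  n0 <- length(pa$v01)
  s10 <- cov(cbind(pa$v10, pb$v10))
  s01 <- cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- pa$auc - pb$auc
  if (v <= 0) {
    if (abs(d) > 0)
      warning("degenerate DeLong variance with unequal AUCs")
    return(list(statistic = 0, p = 1, auc_a = pa$auc, auc_b = pb$auc))
  }
  z <- d / sqrt(v)
  list(statistic = z, p = 2 * pnorm(-abs(z)), auc_a = pa$auc,
       auc_b = pb$auc)
}

#' Youden-optimal decision threshold
#'
#' The cutoff maximizing sensitivity + specificity; ties resolve to the
#' lowest threshold. A flat sweep (chance-level score) warns and returns
#' the lowest threshold.
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return Numeric threshold.
#' @export
optimal_cutoff <- function(roc) {
  sw <- roc$sweep
  if (nrow(sw) == 0) stop("empty threshold sweep")
  j <- sw$sensitivity + sw$specificity
  if (max(j) - min(j) < 1e-12)
    warning("flat Youden index: score carries no information")
  finite <- is.finite(sw$threshold)
  cand <- which(j == max(j) & finite)
  if (!length(cand)) cand <- which.max(j)
  sw$threshold[min(cand)]
}

#' Disease control rate table and group comparison
#'
#' DCR per group as a percentage (1 decimal), with a Pearson chi-square
#' test (no continuity correction), falling back to Fisher's exact test
#' when any expected cell count is below 5.
#'
#' @param groups two-level factor (e.g. low/high infiltration).
#' @param control_flags logical/0-1 vector: disease controlled.
#' @return list with `table` (2x2), `dcr_pct` (per group), `test`
#'   (`"chisq"` or `"fisher"`) and `p`.
#' @export
dcr_table <- function(groups, control_flags) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) == 0)) stop("empty group")
  control <- as.integer(control_flags)
  tab <- table(groups, factor(control, levels = c(0, 1)))
  dcr <- round(100 * tab[, "1"] / rowSums(tab), 1)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    test <- "fisher"
    p <- fisher.test(tab)$p.value
  } else {
    test <- "chisq"
    p <- if (any(colSums(tab) == 0)) 1 else
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }
  list(table = tab, dcr_pct = dcr, test = test, p = p)
}
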