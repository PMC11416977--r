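#' Kaplan-Meier fit with restricted mean survival
#'
#' Product-limit estimator (via the survival package) with Greenwood
#' standard errors. The restricted mean is the area under the KM curve
#' up to the largest observed time, with the standard KM-mean variance
#' `sum_i A_i^2 d_i / (n_i (n_i - d_i))`, where `A_i` is the area under
#' the curve beyond event time `i`.
#'
#' @param times non-negative follow-up times.
#' @param events 1 = event observed, 0 = censored.
#' @return A `survival_fit`: step function (`time`, `surv`, `std_err`),
#'   `rmean`, `rmean_se`, `horizon`.
#' @export
km_fit <- function(times, events) {
  if (any(times < 0)) stop("negative follow-up time")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  tau <- max(times)
  tt <- c(0, sf$time)
  ss <- c(1, sf$surv)
  keep <- tt <= tau
  tt <- tt[keep]; ss <- ss[keep]
  widths <- diff(c(tt, tau))
  rmean <- sum(ss * widths)
  ev <- sf$n.event > 0 & sf$time <= tau
  a_i <- vapply(sf$time[ev], function(t0) {
    seg_t <- pmax(tt, t0)
    sum(ss * pmax(diff(c(seg_t, tau)), 0))
  }, numeric(1))
  d_i <- sf$n.event[ev]
  n_i <- sf$n.risk[ev]
  denom <- n_i * (n_i - d_i)
  var_terms <- ifelse(denom > 0, a_i^2 * d_i / denom, 0)
  structure(list(time = sf$time, surv = sf$surv, std_err = sf$std.err,
                 n_risk = sf$n.risk, n_event = sf$n.event,
                 rmean = rmean, rmean_se = sqrt(sum(var_terms)),
                 horizon = tau),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: restricted mean %.2f +/- %.2f (to %.2f)\n",
              x$rmean, x$rmean_se, x$horizon))
  invisible(x)
}

#' Log-rank and Breslow (generalized Wilcoxon) group comparison
#'
#' The log-rank test is the unweighted Mantel-Haenszel test (via
#' `survival::survdiff`). The Breslow test is the generalized Wilcoxon
#' test with weight equal to the number at risk, which up-weights early
#' differences; it is computed directly from the risk tables since the
#' rho-family in `survdiff` uses Peto-Peto weights instead.
#'
#' @param times follow-up times.
#' @param events event indicators.
#' @param group two-level grouping.
#' @return list with `logrank_p`, `breslow_p`, `logrank_chisq`,
#'   `breslow_chisq`.
#' @export
compare_survival <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  if (sum(events) == 0) stop("no events observed in either group")
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  logrank_chisq <- sd_fit$chisq
  logrank_p <- pchisq(logrank_chisq, df = 1, lower.tail = FALSE)
  # Gehan-Breslow: weight = number at risk at each distinct event time
  ev_times <- sort(unique(times[events == 1]))
  u <- 0; v <- 0
  g1 <- group == levels(group)[1]
  for (t0 in ev_times) {
    at_risk <- times >= t0
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g1)
    d_t <- sum(times == t0 & events == 1)
    d1_t <- sum(times == t0 & events == 1 & g1)
    if (n_t < 2) next
    w <- n_t
    u <- u + w * (d1_t - d_t * n1_t / n_t)
    v <- v + w^2 * d_t * (n_t - d_t) * n1_t * (n_t - n1_t) /
      (n_t^2 * (n_t - 1))
  }
  breslow_chisq <- if (v > 0) u^2 / v else 0
  breslow_p <- if (v > 0)
    pchisq(breslow_chisq, df = 1, lower.tail = FALSE) else 1
  list(logrank_p = logrank_p, breslow_p = breslow_p,
       logrank_chisq = logrank_chisq, breslow_chisq = breslow_chisq)
}

#' Multivariable Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling (via
#' `survival::coxph`). Hazard ratios are exponentiated coefficients with
#' Wald p-values; the per-case risk score is the linear predictor, whose
#' ordering is invariant to covariate centering.
#'
#' @param covariates numeric matrix or data.frame (cases x covariates);
#'   no constant or duplicated columns.
#' @param times follow-up times.
#' @param events event indicators.
#' @return A `cox_fit`: `coef`, `hr`, `se`, `p`, `risk_score`, `fit`.
#' @export
cox_fit <- function(covariates, times, events) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(x)[const], collapse = ", "))
  if (qr(cbind(x))$rank < ncol(x))
    stop("rank-deficient covariates (duplicated or collinear columns)")
  if (sum(events) < ncol(x) + 1)
    stop("too few events for ", ncol(x), " covariates")
  df <- data.frame(x)
  df$.time <- times
  df$.event <- events
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(colnames(x), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        warning("Cox fit may diverge (monotone likelihood); ",
                "coefficients capped at last iteration", call. = FALSE)
      suppressWarnings(
        survival::coxph(fml, data = df, ties = "breslow",
                        control = survival::coxph.control(eps = 1e-9,
                                                          iter.max = 50)))
    })
  sm <- summary(fit)
  structure(list(coef = coef(fit),
                 hr = exp(coef(fit)),
                 se = sm$coefficients[, "se(coef)"],
                 p = sm$coefficients[, "Pr(>|z|)"],
                 risk_score = drop(x %*% coef(fit)),
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  out <- data.frame(coef = x$coef, HR = x$hr, se = x$se, p = x$p)
  print(round(out, 4))
  invisible(x)
}

#' AUC of the Cox linear risk score against a binary outcome
#'
#' Scores each case by its Cox linear predictor and evaluates
#' discrimination of a binary label (e.g. 12-month progression) via
#' [roc_auc()]. The risk score increases with hazard, so it is compared
#' against the progression label directly.
#'
#' @param fit a [cox_fit()].
#' @param binary_outcome 0/1 outcome aligned with the fitted cases.
#' @return A `roc_result`.
#' @export
cox_risk_auc <- function(fit, binary_outcome) {
  keep <- !is.na(binary_outcome)
  roc_auc(fit$risk_score[keep], binary_outcome[keep])
}
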