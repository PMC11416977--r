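#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random effects, absolute agreement, single measurement:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E))` from the
#' two-way ANOVA decomposition of an n-subjects x k-raters table. This
#' is the standard reliability index for repeat-segmentation radiomics
#' studies. A table with zero total variance returns 1 (identical
#' constants agree perfectly).
#'
#' @param table numeric matrix, n subjects (rows) x k raters (columns),
#'   n >= 3, k >= 2, finite entries.
#' @return ICC value in (-1, 1].
#' @export
icc <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- ncol(table)
  if (n < 3) stop("ICC requires at least 3 subjects")
  if (k < 2) stop("ICC requires at least 2 raters")
  if (any(!is.finite(table))) stop("ICC table contains non-finite entries")
  grand <- mean(table)
  if (all(table == table[1])) return(1)
  row_m <- rowMeans(table)
  col_m <- colMeans(table)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((table - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  ms_r <- ss_r / (n - 1)
  ms_c <- ss_c / (k - 1)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e)
  if (denom <= 0) return(1)
  (ms_r - ms_e) / denom
}

#' Filter features by intra-observer reproducibility
#'
#' Computes ICC(2,1) per feature between two raters' extractions of the
#' same cases and retains features whose ICC strictly exceeds the
#' threshold (default 0.80, the conventional cut for commendable
#' reliability).
#'
#' @param features_r1,features_r2 numeric matrices (cases x features)
#'   sharing identical column names, e.g. the 851-id manifest.
#' @param threshold retention threshold; strict comparison (`>`).
#' @return list with `retained` (feature ids), `icc` (data.frame of
#'   per-feature ICCs) and `threshold`.
#' @export
filter_robust <- function(features_r1, features_r2, threshold = 0.80) {
  if (!identical(colnames(features_r1), colnames(features_r2))) {
    d1 <- setdiff(colnames(features_r1), colnames(features_r2))
    d2 <- setdiff(colnames(features_r2), colnames(features_r1))
    stop("feature id mismatch between raters; only in rater 1: ",
         paste(head(d1, 5), collapse = ", "), "; only in rater 2: ",
         paste(head(d2, 5), collapse = ", "))
  }
  if (nrow(features_r1) != nrow(features_r2))
    stop("rater extractions cover different numbers of cases")
  vals <- vapply(seq_len(ncol(features_r1)), function(j)
    icc(cbind(features_r1[, j], features_r2[, j])), numeric(1))
  report <- data.frame(feature_id = colnames(features_r1), icc = vals,
                       retained = vals > threshold,
                       stringsAsFactors = FALSE)
  list(retained = report$feature_id[report$retained], icc = report,
       threshold = threshold)
}
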