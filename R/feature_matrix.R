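#' Median dichotomization of a continuous marker
#'
#' Values strictly above the cohort median are encoded 1
#' (high-infiltrated); values at or below the median 0 (low-infiltrated,
#' ties go low).
#'
#' @param values numeric vector, length >= 2.
#' @return Integer vector of 0/1 labels.
#' @export
median_dichotomize <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  if (length(unique(values)) == 1L)
    stop("all values identical: no median split exists")
  as.integer(values > median(values))
}

#' Encode iRECIST response categories
#'
#' CR and PR are a favorable response (1); SD and PD a poor response
#' (0).
#'
#' @param category character vector with values in CR, PR, SD, PD.
#' @return Integer vector of 0/1 labels.
#' @export
encode_response <- function(category) {
  map <- c(CR = 1L, PR = 1L, SD = 0L, PD = 0L)
  bad <- !(category %in% names(map))
  if (any(bad))
    stop("unknown response category: ",
         paste(unique(category[bad]), collapse = ", "))
  unname(map[category])
}

#' Encode 12-month progression status
#'
#' Progression observed at or before the horizon is 1; follow-up beyond
#' the horizon (event or censored) is 0; censoring before the horizon is
#' indeterminate and excluded (`NA`).
#'
#' @param pfs_months non-negative follow-up times in months.
#' @param event_flag 1 = progression observed, 0 = censored.
#' @param horizon landmark in months (default 12).
#' @return Integer vector with `NA` for excluded cases.
#' @export
encode_pfs12 <- function(pfs_months, event_flag, horizon = 12) {
  if (any(pfs_months < 0)) stop("negative follow-up time")
  out <- ifelse(pfs_months > horizon, 0L,
                ifelse(event_flag == 1, 1L, NA_integer_))
  as.integer(out)
}

#' Fit and apply Z-score normalization
#'
#' Normalization parameters (per-feature mean and population 1/n
#' standard deviation) are fitted on the training rows only and applied
#' to every row, so test rows never leak into the scaling. Constant
#' training columns are dropped with a warning. The result carries a
#' `normalized` attribute; re-applying a fitted transform to an already
#' normalized matrix is an error (the transform is not idempotent).
#'
#' @param matrix numeric cases x features matrix.
#' @param train_rows integer indices of the training rows.
#' @return list with `matrix` (normalized, possibly fewer columns) and
#'   `params` (means, sds, kept column names).
#' @export
zscore_fit_apply <- function(matrix, train_rows) {
  params <- zscore_fit(matrix[train_rows, , drop = FALSE])
  list(matrix = zscore_apply(matrix, params), params = params)
}

#' @rdname zscore_fit_apply
#' @export
zscore_fit <- function(matrix) {
  mu <- colMeans(matrix)
  n <- nrow(matrix)
  sds <- sqrt(colMeans(sweep(matrix, 2, mu)^2))
  keep <- sds > 0
  if (!all(keep))
    warning(sum(!keep), " constant training feature(s) dropped")
  list(mean = mu[keep], sd = sds[keep], features = colnames(matrix)[keep])
}

#' @rdname zscore_fit_apply
#' @param params a fit from `zscore_fit`.
#' @export
zscore_apply <- function(matrix, params) {
  if (isTRUE(attr(matrix, "normalized")))
    stop("matrix is already normalized; refusing to re-apply the transform")
  out <- sweep(sweep(matrix[, params$features, drop = FALSE], 2,
                     params$mean), 2, params$sd, `/`)
  attr(out, "normalized") <- TRUE
  out
}

#' Deduplicate highly correlated features
#'
#' Greedy scan in canonical (column) order: a feature is dropped when
#' its absolute Pearson correlation with any already-retained feature
#' exceeds the threshold, so the earlier member of an offending pair is
#' kept. Deterministic given the column order and invariant to row
#' order. Correlations must be computed on training rows only.
#'
#' @param matrix numeric training matrix (cases x features).
#' @param threshold absolute-correlation cut (default 0.99).
#' @return Character vector of retained feature ids.
#' @export
pcc_dedup <- function(matrix, threshold = 0.99) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  cm <- suppressWarnings(abs(cor(matrix)))
  cm[!is.finite(cm)] <- 0
  p <- ncol(matrix)
  keep <- logical(p)
  for (j in seq_len(p)) {
    keep[j] <- !any(cm[j, keep] > threshold)
  }
  colnames(matrix)[keep]
}

#' Assemble a labelled analysis matrix
#'
#' Joins a feature matrix with a per-case binary label, dropping cases
#' with indeterminate labels (e.g. censored before the 12-month
#' landmark).
#'
#' @param features cases x features matrix with row names.
#' @param labels integer 0/1 vector aligned with the rows (`NA` =
#'   excluded).
#' @param label_kind one of `"cd3"`, `"cd8"`, `"trm"`, `"response"`,
#'   `"pfs12"`.
#' @return list with `x` (matrix), `y` (labels) and `label_kind`
#'   (class `labelled_matrix`).
#' @export
labelled_matrix <- function(features, labels,
                            label_kind = c("cd3", "cd8", "trm",
                                           "response", "pfs12")) {
  label_kind <- match.arg(label_kind)
  stopifnot(nrow(features) == length(labels))
  keep <- !is.na(labels)
  structure(list(x = features[keep, , drop = FALSE],
                 y = as.integer(labels[keep]),
                 label_kind = label_kind),
            class = "labelled_matrix")
}
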