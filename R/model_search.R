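SELECTOR_NAMES <- c("ANOVA", "KW", "RFE", "Relief")

#' Model-exploration grid
#'
#' The default grid crosses 4 selectors, 9 classifiers and 1-10
#' retained features (360 configurations per split seed).
#'
#' @param selectors subset of `r paste(SELECTOR_NAMES, collapse = ", ")`.
#' @param classifiers subset of
#'   `r paste(CLASSIFIER_NAMES, collapse = ", ")`.
#' @param n_features vector of feature-count values.
#' @return A `model_grid` list.
#' @export
model_grid <- function(selectors = SELECTOR_NAMES,
                       classifiers = CLASSIFIER_NAMES,
                       n_features = 1:10) {
  stopifnot(all(selectors %in% SELECTOR_NAMES),
            all(classifiers %in% CLASSIFIER_NAMES),
            all(n_features >= 1))
  structure(list(selectors = selectors, classifiers = classifiers,
                 n_features = as.integer(n_features)),
            class = "model_grid")
}

#' Stratified train/test split
#'
#' Deterministic in `seed`; allocates cases per class by largest
#' remainder so the overall partition is within one case of the target
#' fraction, with both classes present on both sides.
#'
#' @param labels binary 0/1 labels.
#' @param fraction training fraction (default 0.7).
#' @param seed integer.
#' @return list with integer row indices `train` and `test`.
#' @export
split_cohort <- function(labels, fraction = 0.7, seed = 1L) {
  labels <- as.integer(labels)
  if (min(table(labels)) < 2)
    stop("each class needs at least 2 cases to split")
  n <- length(labels)
  target <- round(fraction * n)
  quota <- fraction * as.numeric(table(labels))
  base <- floor(quota)
  rem <- target - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  train <- with_seed(seed, {
    unlist(lapply(seq_along(base), function(ci) {
      cls <- sort(unique(labels))[ci]
      idx <- which(labels == cls)
      sample(idx, base[ci])
    }))
  })
  train <- sort(train)
  test <- setdiff(seq_len(n), train)
  if (min(table(labels[train])) < 1 || min(table(labels[test])) < 1)
    stop("split left a class empty; increase n or adjust fraction")
  list(train = train, test = test)
}

#' Explore the selector x classifier grid
#'
#' FAE-style single-split exploration: the cohort is split 70/30 with
#' stratification, Z-score normalization and absolute-PCC
#' deduplication are fitted on the training rows, each selector
#' produces one ranking, and every (selector, classifier, k)
#' configuration is trained on the same training rows and ranked by
#' independent-test AUC. Ties resolve to fewer features, then canonical
#' selector/classifier order. The whole run is a pure function of
#' `(x, y, grid, seed)`.
#'
#' @param x cases x features matrix (named columns).
#' @param y binary 0/1 labels.
#' @param grid a [model_grid()].
#' @param seed integer split/classifier seed.
#' @param fraction training fraction.
#' @param pcc_threshold absolute-correlation deduplication cut.
#' @return list with `best` (a `model_result`), `leaderboard`
#'   (data.frame over the full grid), `split`, `norm_params`,
#'   `features_after_dedup`.
#' @export
grid_search <- function(x, y, grid = model_grid(), seed = 1L,
                        fraction = 0.7, pcc_threshold = 0.99) {
  y <- as.integer(y)
  split <- split_cohort(y, fraction = fraction, seed = seed)
  norm <- zscore_fit(x[split$train, , drop = FALSE])
  xn <- zscore_apply(x, norm)
  kept <- pcc_dedup(xn[split$train, , drop = FALSE],
                    threshold = pcc_threshold)
  xn <- xn[, kept, drop = FALSE]
  xtr <- xn[split$train, , drop = FALSE]
  ytr <- y[split$train]
  xte <- xn[split$test, , drop = FALSE]
  yte <- y[split$test]
  kmax <- min(max(grid$n_features), ncol(xtr))
  rankings <- lapply(setNames(grid$selectors, grid$selectors),
                     function(s) select_features(s, xtr, ytr, kmax))
  rows <- list()
  results <- list()
  ridx <- 0L
  for (sel in grid$selectors) {
    for (k in grid$n_features) {
      if (k > kmax) next
      feats <- rankings[[sel]][seq_len(k)]
      for (clf in grid$classifiers) {
        model <- train_classifier(clf, xtr[, feats, drop = FALSE], ytr,
                                  seed = child_seed(seed, ridx))
        tr_scores <- predict(model, xtr[, feats, drop = FALSE])
        te_scores <- predict(model, xte[, feats, drop = FALSE])
        tr_roc <- roc_auc(tr_scores, ytr)
        te_roc <- roc_auc(te_scores, yte)
        ridx <- ridx + 1L
        rows[[ridx]] <- data.frame(selector = sel, classifier = clf,
                                   n_features = k,
                                   train_auc = tr_roc$auc,
                                   test_auc = te_roc$auc,
                                   stringsAsFactors = FALSE)
        results[[ridx]] <- list(model = model, features = feats,
                                train_roc = tr_roc, test_roc = te_roc,
                                train_scores = tr_scores,
                                test_scores = te_scores)
      }
    }
  }
  leaderboard <- do.call(rbind, rows)
  ord <- order(-leaderboard$test_auc, leaderboard$n_features,
               match(leaderboard$selector, SELECTOR_NAMES),
               match(leaderboard$classifier, CLASSIFIER_NAMES))
  best_i <- ord[1]
  best_raw <- results[[best_i]]
  thr <- suppressWarnings(optimal_cutoff(best_raw$train_roc))
  best <- structure(list(
    config = leaderboard[best_i, c("selector", "classifier",
                                   "n_features")],
    features = best_raw$features,
    model = best_raw$model,
    train_auc = best_raw$train_roc$auc,
    train_ci = best_raw$train_roc$ci,
    test_auc = best_raw$test_roc$auc,
    test_ci = best_raw$test_roc$ci,
    test_scores = best_raw$test_scores,
    threshold = thr), class = "model_result")
  list(best = best, leaderboard = leaderboard[ord, ], split = split,
       norm_params = norm, features_after_dedup = kept)
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf(
    "<model_result> %s + %s, %d feature(s)\n  train AUC %.3f (%.2f-%.2f), test AUC %.3f (%.2f-%.2f)\n",
    x$config$selector, x$config$classifier, x$config$n_features,
    x$train_auc, x$train_ci[1], x$train_ci[2],
    x$test_auc, x$test_ci[1], x$test_ci[2]))
  invisible(x)
}

#' Integrated TIME-immunotherapy model
#'
#' Combines the features retained by a TIME infiltration model (fitted
#' on the surgical cohort) with those retained by the immunotherapy
#' response model, refits the TIME-winning classifier on the full
#' surgical cohort over the combined feature set, and scores every
#' immunotherapy-cohort case. Cases are dichotomized into low/high
#' predicted infiltration at the Youden-optimal threshold fitted on the
#' surgical cohort. Normalization parameters come from the surgical
#' cohort and are applied unchanged to the immunotherapy rows.
#'
#' @param time_x,time_y surgical-cohort feature matrix and binary
#'   infiltration labels.
#' @param time_result `model_result` of the winning TIME model.
#' @param response_result `model_result` of the response model (its
#'   retained features join the set); may be `NULL` with
#'   `combine = "time_only"`.
#' @param ici_x immunotherapy-cohort feature matrix (raw scale); must
#'   contain every needed feature column.
#' @param ici_response optional 0/1 response labels; when given, the
#'   score's AUC against them is reported.
#' @param combine feature combination rule: union (default),
#'   intersection, or the TIME features alone.
#' @param seed classifier seed for the refit.
#' @return list with `scores`, `groups` (`"low"`/`"high"`), `threshold`,
#'   `features`, and `response_roc` when labels were supplied.
#' @export
build_integrated_model <- function(time_x, time_y, time_result,
                                   response_result, ici_x,
                                   ici_response = NULL,
                                   combine = c("union", "intersection",
                                               "time_only"),
                                   seed = 1L) {
  combine <- match.arg(combine)
  feats <- switch(combine,
                  union = union(time_result$features,
                                response_result$features),
                  intersection = intersect(time_result$features,
                                           response_result$features),
                  time_only = time_result$features)
  if (!length(feats))
    stop("combined feature set is empty (intersection rule with ",
         "disjoint models?)")
  missing_cols <- setdiff(feats, colnames(ici_x))
  if (length(missing_cols))
    stop("ICI feature table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  norm <- zscore_fit(time_x[, feats, drop = FALSE])
  xtr <- zscore_apply(time_x[, feats, drop = FALSE], norm)
  xici <- zscore_apply(ici_x[, feats, drop = FALSE], norm)
  feats <- norm$features  # constants (if any) dropped
  clf <- time_result$config$classifier
  model <- train_classifier(clf, xtr, as.integer(time_y), seed = seed)
  train_scores <- predict(model, xtr)
  thr <- suppressWarnings(
    optimal_cutoff(roc_auc(train_scores, as.integer(time_y))))
  scores <- predict(model, xici)
  groups <- factor(ifelse(scores >= thr, "high", "low"),
                   levels = c("low", "high"))
  out <- list(scores = scores, groups = groups, threshold = thr,
              features = feats, classifier = clf, model = model,
              combine = combine)
  if (!is.null(ici_response))
    out$response_roc <- roc_auc(scores, as.integer(ici_response))
  out
}
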