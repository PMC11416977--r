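# Feature selectors. Each scorer returns one score per column (higher =
# better); constant features always score lowest and are never selected
# before a non-constant one.

anova_scores <- function(x, y) {
  # one-way ANOVA F statistic per feature; for two groups F = t^2
  n <- nrow(x)
  g1 <- y == 1
  n1 <- sum(g1); n0 <- n - n1
  m1 <- colMeans(x[g1, , drop = FALSE])
  m0 <- colMeans(x[!g1, , drop = FALSE])
  mg <- colMeans(x)
  ss_b <- n1 * (m1 - mg)^2 + n0 * (m0 - mg)^2
  ss_w <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) +
    colSums(sweep(x[!g1, , drop = FALSE], 2, m0)^2)
  f <- (ss_b / 1) / (ss_w / (n - 2))
  f[ss_w == 0 & ss_b == 0] <- 0
  f[ss_w == 0 & ss_b > 0] <- Inf
  f
}

kw_scores <- function(x, y) {
  # Kruskal-Wallis H with tie correction, per feature
  n <- nrow(x)
  vapply(seq_len(ncol(x)), function(j) {
    r <- rank(x[, j])
    rb1 <- mean(r[y == 1]); rb0 <- mean(r[y == 0])
    n1 <- sum(y == 1); n0 <- n - n1
    h <- 12 / (n * (n + 1)) * (n1 * rb1^2 + n0 * rb0^2) - 3 * (n + 1)
    ties <- table(x[, j])
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    if (corr <= 0) 0 else h / corr
  }, numeric(1))
}

relief_scores <- function(x, y, k = 3) {
  # binary ReliefF: k nearest hits/misses, every case an anchor
  n <- nrow(x)
  dm <- as.matrix(dist(x))
  diag(dm) <- Inf
  rng <- apply(x, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  w <- numeric(ncol(x))
  for (i in seq_len(n)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_g <- which(y != y[i])
    hits <- same[order(dm[i, same])][seq_len(min(k, length(same)))]
    misses <- diff_g[order(dm[i, diff_g])][seq_len(min(k, length(diff_g)))]
    if (!length(hits) || !length(misses)) next
    dh <- abs(sweep(x[hits, , drop = FALSE], 2, x[i, ])) / rep(rng, each = length(hits))
    dm_ <- abs(sweep(x[misses, , drop = FALSE], 2, x[i, ])) / rep(rng, each = length(misses))
    w <- w + colMeans(dm_) - colMeans(dh)
  }
  w / n
}

rfe_order <- function(x, y) {
  # recursive feature elimination with an L2-regularized logistic base
  # model; eliminates ~10% of remaining features per refit until few
  # remain, then one at a time. Returns ids, best first.
  remaining <- colnames(x)
  eliminated <- character(0)
  while (length(remaining) > 1) {
    xr <- x[, remaining, drop = FALSE]
    sds <- apply(xr, 2, sd)
    if (any(sds == 0)) {
      drop_now <- remaining[sds == 0]
    } else {
      fit <- glmnet::glmnet(xr, y, family = "binomial", alpha = 0,
                            lambda = 0.01, standardize = TRUE)
      beta <- abs(as.numeric(fit$beta))
      step <- if (length(remaining) > 20)
        ceiling(0.1 * length(remaining)) else 1L
      drop_now <- remaining[order(beta)][seq_len(step)]
    }
    eliminated <- c(drop_now, eliminated)
    remaining <- setdiff(remaining, drop_now)
  }
  c(remaining, eliminated)
}

#' Rank and select features
#'
#' Four selectors: `ANOVA` ranks by the one-way F statistic, `KW` by the
#' tie-corrected Kruskal-Wallis H, `RFE` by recursive elimination of the
#' smallest-weight feature of an L2 logistic refit, and `Relief` by the
#' k-nearest hit/miss margin (k = 3, all cases as anchors). Constant
#' features are never selected before non-constant ones.
#'
#' @param method one of `"ANOVA"`, `"KW"`, `"RFE"`, `"Relief"`.
#' @param x training feature matrix (cases x features, named columns).
#' @param y binary 0/1 labels.
#' @param k number of features to retain (k <= ncol(x)).
#' @return Character vector of `k` feature ids, best first.
#' @export
select_features <- function(method = c("ANOVA", "KW", "RFE", "Relief"),
                            x, y, k) {
  method <- match.arg(method)
  if (k > ncol(x)) stop("k exceeds the number of available features")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) length(unique(col)) == 1L)
  ord <- if (method == "RFE") {
    rfe_order(x, y)
  } else {
    scores <- switch(method,
                     ANOVA = anova_scores(x, y),
                     KW = kw_scores(x, y),
                     Relief = relief_scores(x, y))
    scores[const] <- -Inf
    colnames(x)[order(scores, decreasing = TRUE)]
  }
  # constant features sink to the end under every method
  ord <- c(setdiff(ord, colnames(x)[const]), colnames(x)[const])
  ord[seq_len(k)]
}
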