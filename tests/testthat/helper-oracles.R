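# Brute-force reference implementations used as independent oracles.
# These deliberately use naive enumeration (nested loops, hand BFS) and
# never call the package's fast paths.

make_droi <- function(levels) {
  lev <- array(as.integer(levels), dim = dim(levels))
  structure(list(levels = lev, ng = max(lev, na.rm = TRUE),
                 n_voxels = sum(!is.na(lev)), bin_width = 1),
            class = "discretized_roi")
}

dirs13 <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

lv_at <- function(lev, p) {
  d <- dim(lev)
  if (!in_grid(p, d)) return(NA_integer_)
  lev[p[1], p[2], p[3]]
}

# symmetric co-occurrence counts for one offset
bf_glcm <- function(lev, off, ng) {
  d <- dim(lev)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    b <- lv_at(lev, c(x, y, z) + off)
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

# run-length counts for one direction
bf_glrlm <- function(lev, off, ng) {
  d <- dim(lev)
  maxlen <- max(d)
  M <- matrix(0, ng, maxlen)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    prev <- lv_at(lev, c(x, y, z) - off)
    if (!is.na(prev) && prev == a) next
    len <- 1
    p <- c(x, y, z) + off
    while (!is.na(lv_at(lev, p)) && lv_at(lev, p) == a) {
      len <- len + 1
      p <- p + off
    }
    M[a, len] <- M[a, len] + 1
  }
  M
}

# 26-connected zones: returns sorted (level, size) pairs
bf_glszm <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  zones <- NULL
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    a <- lev[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(nbrs))) {
        q <- p + nbrs[r, ]
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue <- c(queue, list(q))
        }
      }
    }
    zones <- rbind(zones, c(a, size))
  }
  zones[order(zones[, 1], zones[, 2]), , drop = FALSE]
}

# NGTDM n_i and s_i by direct neighbour averaging
bf_ngtdm <- function(lev, ng) {
  d <- dim(lev)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    vals <- c()
    for (r in seq_len(nrow(nbrs))) {
      v <- lv_at(lev, c(x, y, z) + nbrs[r, ])
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (!length(vals)) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(vals))
  }
  cbind(n_i, s_i)
}

# GLDM dependence census
bf_gldm <- function(lev, ng, alpha = 0) {
  d <- dim(lev)
  nbrs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbrs <- nbrs[rowSums(abs(nbrs)) > 0, ]
  M <- matrix(0, ng, 27)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    dep <- 0
    for (r in seq_len(nrow(nbrs))) {
      v <- lv_at(lev, c(x, y, z) + nbrs[r, ])
      if (!is.na(v) && abs(v - a) <= alpha) dep <- dep + 1
    }
    M[a, dep + 1] <- M[a, dep + 1] + 1
  }
  M
}

# AUC by explicit positive-negative pair counting
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ICC(2,1) through R's own two-way ANOVA
bf_icc <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Cox partial log-likelihood for one covariate (Breslow ties)
bf_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- which(times >= times[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# random discretized ROI on a small grid, with some voxels masked out
random_droi <- function(dim3, ng, seed, roi_frac = 0.85) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dim3), replace = TRUE), dim = dim3)
  drop <- runif(prod(dim3)) > roi_frac
  lev[drop] <- NA_integer_
  if (all(is.na(lev))) lev[1] <- 1L
  make_droi(lev)
}

ball_mask <- function(r, n = 2 * r + 6, spacing = c(1, 1, 1)) {
  ctr <- (n - 1) / 2
  ax <- seq_len(n) - 1
  q <- outer(outer((ax - ctr)^2, (ax - ctr)^2, `+`), (ax - ctr)^2, `+`)
  roi_mask(array(as.integer(q <= r^2), dim = c(n, n, n)), spacing = spacing)
}

small_phantom <- function(seed = 1, contrast = 40, grid = c(20, 20, 20),
                          axes = c(6, 6, 6)) {
  generate_phantom(phantom_spec(grid_shape = grid, roi_axes = axes,
                                texture_contrast = contrast, seed = seed))
}
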