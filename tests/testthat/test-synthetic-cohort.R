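test_that("phantom generation is deterministic and validates its spec", {
  spec <- phantom_spec(grid_shape = c(20, 20, 20), roi_axes = c(6, 6, 6),
                       seed = 11)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_gt(sum(a$mask$voxels), 0)
  # different seed changes the field
  c2 <- generate_phantom(phantom_spec(grid_shape = c(20, 20, 20),
                                      roi_axes = c(6, 6, 6), seed = 12))
  expect_false(identical(a$volume$voxels, c2$volume$voxels))
  expect_error(phantom_spec(grid_shape = c(6, 20, 20)), "grid_shape")
  expect_error(phantom_spec(grid_shape = c(16, 16, 16),
                            roi_axes = c(40, 6, 6)), "fit")
})

test_that("zero texture contrast gives a spatially constant ROI interior", {
  p <- small_phantom(seed = 5, contrast = 0)
  inside <- p$volume$voxels[p$mask$voxels == 1]
  expect_equal(sd(inside), 0)
  expect_equal(unique(inside), 40)
})

test_that("ROI texture variance scales as the squared contrast", {
  v_at <- function(contrast) {
    mean(vapply(1:20, function(s) {
      p <- generate_phantom(phantom_spec(roi_axes = c(10, 10, 10),
                                         texture_contrast = contrast,
                                         seed = s))
      var(p$volume$voxels[p$mask$voxels == 1])
    }, numeric(1)))
  }
  ratio <- v_at(80) / v_at(20)
  expect_gt(ratio, 16 * 0.9)
  expect_lt(ratio, 16 * 1.1)
})

test_that("infiltration percentages keep the subset ordering TRM <= CD8 <= CD3", {
  for (seed in 1:5) {
    clin <- sample_infiltration(cohort_spec(n_cases = 50, seed = seed))
    expect_true(all(clin$trm_pct <= clin$cd8_pct))
    expect_true(all(clin$cd8_pct <= clin$cd3_pct))
    expect_true(all(clin$cd3_pct <= 100 & clin$trm_pct >= 0))
  }
})

test_that("adding cases never perturbs earlier cases (per-case substreams)", {
  a <- sample_infiltration(cohort_spec(n_cases = 10, seed = 3))
  b <- sample_infiltration(cohort_spec(n_cases = 20, seed = 3))
  expect_equal(a$cd8_pct, b$cd8_pct[1:10])
})

test_that("censoring_rate = 0 yields all observed events", {
  clin <- sample_ici_clinical(cohort_spec(n_cases = 60,
                                          censoring_rate = 0, seed = 2))
  expect_true(all(clin$event == 1))
  clin2 <- sample_ici_clinical(cohort_spec(n_cases = 400,
                                           censoring_rate = 0.3, seed = 2))
  expect_gt(mean(clin2$event == 0), 0.15)
})

test_that("response marginals match the link-implied probabilities", {
  # with a null link slope the category probabilities are exactly the
  # baseline probabilities; chi-square goodness of fit at n = 2000
  spec <- cohort_spec(n_cases = 2000, response_link = 0, seed = 9)
  clin <- sample_ici_clinical(spec)
  obs <- table(factor(clin$response, levels = c("PD", "SD", "PR", "CR")))
  p <- chisq.test(obs, p = spec$response_base_probs)$p.value
  expect_gt(p, 0.01)
})

test_that("a positive response link shifts responders toward high CD8", {
  clin <- sample_ici_clinical(cohort_spec(n_cases = 400,
                                          response_link = 1.5, seed = 4))
  resp <- encode_response(clin$response)
  expect_gt(mean(clin$latent_cd8[resp == 1]),
            mean(clin$latent_cd8[resp == 0]))
})

test_that("survival link of log(0.218) is recovered by a Cox fit at n = 400", {
  hits <- 0
  for (seed in 1:20) {
    clin <- sample_ici_clinical(cohort_spec(n_cases = 400,
                                            survival_link = log(0.218),
                                            censoring_rate = 0,
                                            seed = seed))
    z <- (clin$cd8_pct - mean(clin$cd8_pct)) / sd(clin$cd8_pct)
    fit <- cox_fit(cbind(cd8 = z), clin$pfs_months, clin$event)
    if (fit$hr >= 0.15 && fit$hr <= 0.32) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("null survival link gives uniform log-rank p-values over seeds", {
  ps <- vapply(1:40, function(seed) {
    clin <- sample_ici_clinical(cohort_spec(n_cases = 80,
                                            survival_link = 0,
                                            censoring_rate = 0,
                                            seed = seed))
    grp <- clin$latent_cd8 > median(clin$latent_cd8)
    compare_survival(clin$pfs_months, clin$event, grp)$logrank_p
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
  expect_lt(mean(ps < 0.05), 0.25)
})

test_that("cohort generators couple texture mean to latent infiltration", {
  ph <- phantom_spec(grid_shape = c(16, 16, 16), roi_axes = c(5, 5, 5))
  coh <- generate_time_cohort(cohort_spec(n_cases = 12, effect_size = 2,
                                          seed = 6), ph)
  roi_means <- vapply(seq_len(12), function(i)
    mean(coh$volumes[[i]]$voxels[coh$masks[[i]]$voxels == 1]), numeric(1))
  expect_gt(cor(roi_means, coh$clinical$latent_cd8), 0.9)
  # effect_size = 0 decouples images from labels
  coh0 <- generate_time_cohort(cohort_spec(n_cases = 12, effect_size = 0,
                                           seed = 6), ph)
  roi_means0 <- vapply(seq_len(12), function(i)
    mean(coh0$volumes[[i]]$voxels[coh0$masks[[i]]$voxels == 1]), numeric(1))
  expect_lt(abs(cor(roi_means0, coh0$clinical$latent_cd8)), 0.9)
})
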