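#' Specify a synthetic patient cohort
#'
#' Controls the clinical side of the simulator: infiltration marginals,
#' the coupling between latent infiltration and image texture
#' (`effect_size`), the ordinal response link, and the proportional-
#' hazards progression-free survival (PFS) model.
#'
#' Infiltration percentages are drawn hierarchically
#' (CD3, then CD8 | CD3, then TRM | CD8, each via a Beta fraction), which
#' enforces TRM <= CD8 <= CD3 per case by construction. The latent driver
#' of both imaging texture and outcome is the CD8 percentage,
#' standardized by its closed-form marginal moments so that the
#' standardization does not depend on the realized cohort.
#'
#' @param n_cases number of cases (>= 4).
#' @param effect_size coupling between standardized latent CD8
#'   infiltration and ROI texture, in units of the texture SD per latent
#'   SD; 0 decouples images from labels entirely.
#' @param infiltration_marginals list with Beta parameters `cd3`
#'   (CD3 fraction of leukocytes), `cd8` (CD8 fraction of CD3), `trm`
#'   (TRM fraction of CD8), each length-2 `c(shape1, shape2)`.
#' @param response_link slope of the proportional-odds (cumulative
#'   logistic) link from latent CD8 to the ordered response
#'   PD < SD < PR < CR.
#' @param response_base_probs baseline category probabilities at latent
#'   0, ordered `c(PD, SD, PR, CR)`; the default mirrors the shape of a
#'   typical checkpoint-inhibitor cohort (about 9/16/68/7 percent).
#' @param survival_link log hazard ratio of progression per unit latent
#'   CD8 (negative: more infiltration, slower progression).
#' @param median_pfs_months baseline median PFS in months.
#' @param censoring_rate expected fraction of randomly censored cases in
#'   `[0, 1)`; 0 disables censoring entirely.
#' @param censoring_horizon_months cap on censoring times (months);
#'   active only when `censoring_rate > 0`.
#' @param seed integer; fans out to per-case substreams so adding a case
#'   never perturbs earlier cases.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 135,
                        effect_size = 1,
                        infiltration_marginals = list(cd3 = c(5, 3),
                                                      cd8 = c(4, 4),
                                                      trm = c(3, 3)),
                        response_link = 1,
                        response_base_probs = c(PD = 0.089, SD = 0.161,
                                                PR = 0.679, CR = 0.071),
                        survival_link = log(0.218),
                        median_pfs_months = 10.3,
                        censoring_rate = 0.02,
                        censoring_horizon_months = 24,
                        seed = 1L) {
  if (n_cases < 4) stop("n_cases must be >= 4")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (!is.finite(survival_link)) stop("survival_link must be finite")
  p <- response_base_probs / sum(response_base_probs)
  structure(list(n_cases = as.integer(n_cases),
                 effect_size = effect_size,
                 infiltration_marginals = infiltration_marginals,
                 response_link = response_link,
                 response_base_probs = p,
                 survival_link = survival_link,
                 median_pfs_months = median_pfs_months,
                 censoring_rate = censoring_rate,
                 censoring_horizon_months = censoring_horizon_months,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Closed-form mean/sd of the CD8 percentage under the hierarchical Beta
# marginals (product of two independent Beta variables, times 100).
cd8_marginal_moments <- function(marginals) {
  m1 <- function(ab) ab[1] / (ab[1] + ab[2])
  m2 <- function(ab) {
    v <- ab[1] * ab[2] / ((ab[1] + ab[2])^2 * (ab[1] + ab[2] + 1))
    v + m1(ab)^2
  }
  mean_frac <- m1(marginals$cd3) * m1(marginals$cd8)
  second <- m2(marginals$cd3) * m2(marginals$cd8)
  v <- second - mean_frac^2
  list(mean = 100 * mean_frac, sd = 100 * sqrt(max(v, 0)))
}

#' Sample infiltration percentages for a cohort
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with `case_id`, `cd3_pct`, `cd8_pct`, `trm_pct` and
#'   the standardized latent driver `latent_cd8`. Per-case ordering
#'   `trm_pct <= cd8_pct <= cd3_pct` holds by construction.
#' @export
sample_infiltration <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mg <- spec$infiltration_marginals
  for (nm in c("cd3", "cd8", "trm")) {
    ab <- mg[[nm]]
    v <- ab[1] * ab[2] / ((ab[1] + ab[2])^2 * (ab[1] + ab[2] + 1))
    if (v <= 0)
      warning("degenerate (zero-variance) marginal for ", nm,
              "; labels still emitted")
  }
  n <- spec$n_cases
  draws <- t(vapply(seq_len(n), function(i) {
    with_seed(child_seed(spec$seed, i), {
      cd3 <- 100 * rbeta(1, mg$cd3[1], mg$cd3[2])
      cd8 <- cd3 * rbeta(1, mg$cd8[1], mg$cd8[2])
      trm <- cd8 * rbeta(1, mg$trm[1], mg$trm[2])
      c(cd3, cd8, trm)
    })
  }, numeric(3)))
  mom <- cd8_marginal_moments(mg)
  data.frame(case_id = sprintf("case_%03d", seq_len(n)),
             cd3_pct = draws[, 1], cd8_pct = draws[, 2],
             trm_pct = draws[, 3],
             latent_cd8 = (draws[, 2] - mom$mean) / mom$sd,
             stringsAsFactors = FALSE)
}

# Phantom for one case: texture mean shifted by effect_size * latent (in
# texture-SD units); ROI size jittered independently of the labels.
case_phantom <- function(pspec, latent, effect_size, case_seed) {
  jitter <- with_seed(child_seed(case_seed, 7L), runif(3, 0.8, 1.2))
  spec <- phantom_spec(
    grid_shape = pspec$grid_shape,
    voxel_spacing = pspec$voxel_spacing,
    roi_axes = pmin(pspec$roi_axes * jitter,
                    (pspec$grid_shape - 2) / 2 * pspec$voxel_spacing * 0.95),
    texture_correlation_length = pspec$texture_correlation_length,
    texture_contrast = pspec$texture_contrast,
    roi_mean = pspec$roi_mean +
      effect_size * latent * pspec$texture_contrast,
    background_mean = pspec$background_mean,
    background_std = pspec$background_std,
    seed = case_seed)
  generate_phantom(spec)
}

#' Generate the surgical (TIME) cohort
#'
#' Each case carries a phantom CT volume, its tumor mask, and flow-
#' cytometry-style infiltration percentages. The ROI texture mean is
#' shifted by `effect_size * latent_cd8` texture SDs, so
#' `effect_size = 0` makes images independent of the labels.
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [phantom_spec()] serving as the case template.
#' @return list with `volumes` (list of `image_volume`), `masks`
#'   (list of `roi_mask`) and `clinical` (data.frame from
#'   [sample_infiltration()]).
#' @export
generate_time_cohort <- function(spec, phantom) {
  clin <- sample_infiltration(spec)
  cases <- lapply(seq_len(spec$n_cases), function(i) {
    case_phantom(phantom, clin$latent_cd8[i], spec$effect_size,
                 child_seed(spec$seed, 100000 + i))
  })
  list(volumes = lapply(cases, `[[`, "volume"),
       masks = lapply(cases, `[[`, "mask"),
       clinical = clin)
}

#' Sample clinical outcomes for the immunotherapy cohort
#'
#' Response categories follow a proportional-odds model on the latent
#' CD8 driver; PFS is exponential with log hazard ratio
#' `survival_link` per latent unit, with independent censoring.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with infiltration columns plus `response`
#'   (CR/PR/SD/PD), `pfs_months` and `event` (1 = progression observed).
#' @export
sample_ici_clinical <- function(spec) {
  clin <- sample_infiltration(spec)
  cuts <- qlogis(cumsum(spec$response_base_probs)[1:3])  # PD, SD, PR
  lambda0 <- log(2) / spec$median_pfs_months
  out <- t(vapply(seq_len(spec$n_cases), function(i) {
    z <- clin$latent_cd8[i]
    with_seed(child_seed(spec$seed, 200000 + i), {
      u <- runif(1)
      cum <- plogis(cuts - spec$response_link * z)
      cat_i <- findInterval(u, cum) + 1L  # 1=PD, 2=SD, 3=PR, 4=CR
      lam <- lambda0 * exp(spec$survival_link * z)
      tt <- rexp(1, lam)
      if (spec$censoring_rate > 0) {
        cr <- spec$censoring_rate
        cc <- min(rexp(1, lam * cr / (1 - cr)), spec$censoring_horizon_months)
      } else cc <- Inf
      c(cat_i, min(tt, cc), as.numeric(tt <= cc))
    })
  }, numeric(3)))
  clin$response <- c("PD", "SD", "PR", "CR")[out[, 1]]
  clin$pfs_months <- out[, 2]
  clin$event <- as.integer(out[, 3])
  clin
}

#' Generate the immunotherapy (ICI) cohort
#'
#' @param spec a [cohort_spec()].
#' @param phantom a [phantom_spec()] case template.
#' @return list with `volumes`, `masks` and `clinical` (from
#'   [sample_ici_clinical()]).
#' @export
generate_ici_cohort <- function(spec, phantom) {
  clin <- sample_ici_clinical(spec)
  cases <- lapply(seq_len(spec$n_cases), function(i) {
    case_phantom(phantom, clin$latent_cd8[i], spec$effect_size,
                 child_seed(spec$seed, 300000 + i))
  })
  list(volumes = lapply(cases, `[[`, "volume"),
       masks = lapply(cases, `[[`, "mask"),
       clinical = clin)
}

#' Write a cohort to disk
#'
#' Volumes and masks are written as NIfTI pairs
#' (`case_xxx.nii.gz` / `case_xxx_mask.nii.gz`) plus a `clinical.csv`.
#'
#' @param cohort result of [generate_time_cohort()] or
#'   [generate_ici_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- cohort$clinical$case_id
  for (i in seq_along(ids)) {
    write_volume(cohort$volumes[[i]], file.path(dir, paste0(ids[i], ".nii.gz")))
    write_volume(cohort$masks[[i]],
                 file.path(dir, paste0(ids[i], "_mask.nii.gz")))
  }
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  invisible(dir)
}
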