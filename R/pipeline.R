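#' Study run configuration
#'
#' Bundles every knob of the two-cohort study: cohort sizes and
#' couplings, the phantom template, extraction settings, the
#' exploration grid, and the analysis thresholds (ICC 0.80, PCC 0.99,
#' 70% training fraction, 12-month PFS landmark).
#'
#' The demo-scale defaults (smaller cohorts, a reduced grid and a 24^3
#' phantom grid) keep a full run in the minutes range; the full study
#' shape is obtained with `n_time = 135`, `n_ici = 112`,
#' `grid = model_grid()`.
#'
#' @param seed master seed; every stage derives its own substream.
#' @param n_time,n_ici cohort sizes.
#' @param effect_size texture-infiltration coupling (see
#'   [cohort_spec()]).
#' @param survival_link log hazard ratio per latent CD8 unit.
#' @param phantom a [phantom_spec()] template.
#' @param extraction an [extract_config()].
#' @param grid a [model_grid()].
#' @param icc_threshold,pcc_threshold,train_fraction,pfs_horizon
#'   analysis thresholds.
#' @param n_rater_cases cases re-segmented for the robustness stage.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1L,
                       n_time = 60, n_ici = 50,
                       effect_size = 1.5,
                       survival_link = log(0.218),
                       phantom = phantom_spec(grid_shape = c(24, 24, 24),
                                              roi_axes = c(8, 8, 8)),
                       extraction = extract_config(),
                       grid = model_grid(selectors = c("ANOVA", "KW"),
                                         classifiers = c("LR", "LDA",
                                                         "NB"),
                                         n_features = c(2, 5, 8)),
                       icc_threshold = 0.80,
                       pcc_threshold = 0.99,
                       train_fraction = 0.7,
                       pfs_horizon = 12,
                       n_rater_cases = 20) {
  stopifnot(icc_threshold > 0, icc_threshold < 1,
            pcc_threshold > 0, pcc_threshold <= 1,
            train_fraction > 0, train_fraction < 1, pfs_horizon > 0)
  structure(list(seed = as.integer(seed), n_time = n_time, n_ici = n_ici,
                 effect_size = effect_size, survival_link = survival_link,
                 phantom = phantom, extraction = extraction, grid = grid,
                 icc_threshold = icc_threshold,
                 pcc_threshold = pcc_threshold,
                 train_fraction = train_fraction,
                 pfs_horizon = pfs_horizon,
                 n_rater_cases = n_rater_cases),
            class = "run_config")
}

# Second-rater mask: emulates an independent re-segmentation by dilating
# a random fraction of the outer boundary and eroding a smaller random
# fraction of the interior surface.
perturb_mask <- function(mask, seed, flip_prob = 0.2) {
  m <- mask$voxels
  d <- dim(m)
  dilated <- array(FALSE, dim = d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    src <- dst <- lapply(d, seq_len)
    if (s == 1L) { src[[ax]] <- 1:(d[ax] - 1); dst[[ax]] <- 2:d[ax] }
    else { src[[ax]] <- 2:d[ax]; dst[[ax]] <- 1:(d[ax] - 1) }
    sh <- array(FALSE, dim = d)
    sh[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]] == 1L
    dilated <- dilated | sh
  }
  outer_bnd <- which(dilated & m == 0L)
  m2 <- m
  m2[with_seed(seed, outer_bnd[runif(length(outer_bnd)) < flip_prob])] <- 1L
  fg <- which(m == 1L)
  m2[with_seed(child_seed(seed, 1L),
               fg[runif(length(fg)) < flip_prob / 2])] <- 0L
  if (sum(m2) < 8) m2 <- m  # keep the ROI usable
  roi_mask(array(m2, dim = d), spacing = mask$spacing)
}

#' Run the full two-cohort study
#'
#' Executes simulate, extract, robustness filter, matrix building, grid
#' search for the five labels (CD3/CD8/TRM infiltration, response,
#' 12-month progression), the three integrated TIME-immunotherapy
#' models, and the survival analyses (DCR tables, KM comparisons,
#' multivariable Cox with risk-score AUC). Fully deterministic in the
#' config seed.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return A nested `study_report` list.
#' @export
run_study <- function(config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  say("simulating cohorts")
  tspec <- cohort_spec(n_cases = config$n_time,
                       effect_size = config$effect_size,
                       survival_link = config$survival_link,
                       seed = child_seed(seed, 1L))
  ispec <- cohort_spec(n_cases = config$n_ici,
                       effect_size = config$effect_size,
                       survival_link = config$survival_link,
                       seed = child_seed(seed, 2L))
  time_cohort <- generate_time_cohort(tspec, config$phantom)
  ici_cohort <- generate_ici_cohort(ispec, config$phantom)
  say("extracting features")
  time_x <- extract_cohort(time_cohort$volumes, time_cohort$masks,
                           config$extraction,
                           case_ids = time_cohort$clinical$case_id)
  ici_x <- extract_cohort(ici_cohort$volumes, ici_cohort$masks,
                          config$extraction,
                          case_ids = ici_cohort$clinical$case_id)
  say("robustness filtering")
  n_rater <- min(config$n_rater_cases, config$n_time)
  rater_idx <- with_seed(child_seed(seed, 3L),
                         sort(sample(config$n_time, n_rater)))
  masks2 <- lapply(seq_along(rater_idx), function(i)
    perturb_mask(time_cohort$masks[[rater_idx[i]]],
                 child_seed(seed, 4000 + i)))
  x_r2 <- extract_cohort(lapply(rater_idx, function(i)
    time_cohort$volumes[[i]]), masks2, config$extraction)
  rob <- filter_robust(time_x[rater_idx, , drop = FALSE], x_r2,
                       threshold = config$icc_threshold)
  time_xr <- time_x[, rob$retained, drop = FALSE]
  ici_xr <- ici_x[, rob$retained, drop = FALSE]
  say("searching TIME models")
  time_models <- lapply(
    setNames(c("cd3_pct", "cd8_pct", "trm_pct"), c("cd3", "cd8", "trm")),
    function(col) {
      y <- median_dichotomize(time_cohort$clinical[[col]])
      grid_search(time_xr, y, grid = config$grid,
                  seed = child_seed(seed, 10L),
                  fraction = config$train_fraction,
                  pcc_threshold = config$pcc_threshold)
    })
  say("searching response / PFS models")
  # small demo cohorts can leave a response or landmark class too thin
  # to split and train on; such models are skipped with a note
  searchable <- function(y) length(y) >= 8 && min(table(y)) >= 4
  y_resp <- encode_response(ici_cohort$clinical$response)
  resp_search <- if (searchable(y_resp)) {
    grid_search(ici_xr, y_resp, grid = config$grid,
                seed = child_seed(seed, 11L),
                fraction = config$train_fraction,
                pcc_threshold = config$pcc_threshold)
  } else NULL
  y_pfs12 <- encode_pfs12(ici_cohort$clinical$pfs_months,
                          ici_cohort$clinical$event,
                          horizon = config$pfs_horizon)
  lm_pfs <- labelled_matrix(ici_xr, y_pfs12, "pfs12")
  pfs_search <- if (searchable(lm_pfs$y)) {
    grid_search(lm_pfs$x, lm_pfs$y, grid = config$grid,
                seed = child_seed(seed, 12L),
                fraction = config$train_fraction,
                pcc_threshold = config$pcc_threshold)
  } else NULL
  say("integrated models and survival")
  integrated <- lapply(setNames(names(time_models), names(time_models)),
                       function(marker) {
    y <- median_dichotomize(
      time_cohort$clinical[[paste0(marker, "_pct")]])
    build_integrated_model(time_xr, y, time_models[[marker]]$best,
                           if (is.null(resp_search)) NULL else
                             resp_search$best,
                           ici_xr,
                           ici_response = if (length(unique(y_resp)) == 2)
                             y_resp else NULL,
                           combine = if (is.null(resp_search)) "time_only"
                           else "union",
                           seed = child_seed(seed, 20L))
  })
  control <- ici_cohort$clinical$response %in% c("CR", "PR", "SD")
  survival_section <- lapply(integrated, function(im) {
    g <- im$groups
    if (nlevels(droplevels(g)) < 2) {
      return(list(note = "single predicted group; no comparison"))
    }
    dcr <- dcr_table(g, control)
    cmp <- compare_survival(ici_cohort$clinical$pfs_months,
                            ici_cohort$clinical$event, g)
    km <- lapply(split(seq_along(g), g), function(ix)
      km_fit(ici_cohort$clinical$pfs_months[ix],
             ici_cohort$clinical$event[ix]))
    list(dcr_pct = dcr$dcr_pct, dcr_test = dcr$test, dcr_p = dcr$p,
         logrank_p = cmp$logrank_p, breslow_p = cmp$breslow_p,
         rmean_low = km$low$rmean, rmean_low_se = km$low$rmean_se,
         rmean_high = km$high$rmean, rmean_high_se = km$high$rmean_se)
  })
  cov_mat <- do.call(cbind, lapply(integrated, function(im)
    as.integer(im$groups == "high")))
  colnames(cov_mat) <- paste0(names(integrated), "_high")
  cox_section <- NULL
  ok_cov <- apply(cov_mat, 2, function(col) length(unique(col)) > 1)
  cm <- cov_mat[, ok_cov, drop = FALSE]
  if (ncol(cm) >= 1 && qr(cm)$rank == ncol(cm) &&
      sum(ici_cohort$clinical$event) >= ncol(cm) + 1) {
    cox <- tryCatch(
      suppressWarnings(cox_fit(cm, ici_cohort$clinical$pfs_months,
                               ici_cohort$clinical$event)),
      error = function(e) NULL)
    if (!is.null(cox)) {
      risk_roc <- tryCatch(cox_risk_auc(cox, y_pfs12),
                           error = function(e) NULL)
      cox_section <- list(hr = cox$hr, p = cox$p,
                          risk_auc = if (!is.null(risk_roc))
                            risk_roc$auc else NA_real_)
    }
  }
  report <- list(
    config = list(seed = seed, n_time = config$n_time,
                  n_ici = config$n_ici,
                  effect_size = config$effect_size,
                  survival_link = config$survival_link),
    robustness = list(n_features = ncol(time_x),
                      n_retained = length(rob$retained)),
    time_models = lapply(time_models, function(m) list(
      selector = m$best$config$selector,
      classifier = m$best$config$classifier,
      n_features = m$best$config$n_features,
      train_auc = m$best$train_auc, test_auc = m$best$test_auc)),
    response_model = if (is.null(resp_search)) {
      list(note = "response classes too thin to model at this n")
    } else list(
      selector = resp_search$best$config$selector,
      classifier = resp_search$best$config$classifier,
      n_features = resp_search$best$config$n_features,
      train_auc = resp_search$best$train_auc,
      test_auc = resp_search$best$test_auc),
    pfs_model = if (is.null(pfs_search)) {
      list(note = "12-month progression classes too thin to model at this n")
    } else list(
      selector = pfs_search$best$config$selector,
      classifier = pfs_search$best$config$classifier,
      n_features = pfs_search$best$config$n_features,
      train_auc = pfs_search$best$train_auc,
      test_auc = pfs_search$best$test_auc),
    integrated = lapply(integrated, function(im) list(
      response_auc = if (!is.null(im$response_roc))
        im$response_roc$auc else NA_real_,
      n_high = sum(im$groups == "high"),
      n_low = sum(im$groups == "low"))),
    survival = survival_section,
    cox = cox_section)
  structure(report, class = "study_report")
}

#' Serialize a study report to JSON
#'
#' Byte-stable: the same report always yields the same text, so a rerun
#' under an identical config can be compared with `identical()`.
#'
#' @param report a `study_report`.
#' @param path optional output file.
#' @return JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  txt <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
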