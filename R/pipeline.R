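#' Full-pipeline configuration
#'
#' One object (or YAML file) fully determines a run; per-stage seeds are
#' derived deterministically from the global seed.
#'
#' @param cohort an [cohort_spec()].
#' @param roi an [roi_config()].
#' @param bank a [feature_bank_config()].
#' @param smote an [smote_config()].
#' @param screening an [screening_config()].
#' @param gbdt an [gbdt_config()].
#' @param scheme an [split_scheme()].
#' @param seed global seed, propagated to every stochastic stage.
#' @param out_dir optional directory for stage artifacts (CSV/JSON).
#' @param leakage_safe apply SMOTE inside each training split only, instead
#'   of once on the full data set before splitting (the default mirrors the
#'   published workflow; the leakage-safe mode is the honest alternative for
#'   unbiased validation).
#' @param full_scale use 10000 boosting iterations instead of the
#'   desk-scale 500.
#' @return An object of class `rd_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), roi = roi_config(),
                            bank = feature_bank_config(),
                            smote = smote_config(),
                            screening = screening_config(),
                            gbdt = gbdt_config(),
                            scheme = split_scheme(),
                            seed = 1, out_dir = NULL,
                            leakage_safe = FALSE, full_scale = FALSE) {
  seed <- as.integer(seed)
  cohort$seed <- derive_seed(seed, "cohort")
  smote$seed <- derive_seed(seed, "smote")
  screening$seed <- derive_seed(seed, "screen")
  gbdt$seed <- derive_seed(seed, "gbdt")
  scheme$seed <- derive_seed(seed, "splits")
  if (full_scale) gbdt$n_trees <- 10000L
  structure(list(cohort = cohort, roi = roi, bank = bank, smote = smote,
                 screening = screening, gbdt = gbdt, scheme = scheme,
                 seed = seed, out_dir = out_dir,
                 leakage_safe = isTRUE(leakage_safe),
                 full_scale = isTRUE(full_scale)),
            class = "rd_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; each stage key
#' holds the corresponding constructor's arguments.
#'
#' @param path YAML file.
#' @return An `rd_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  pipeline_config(
    cohort = build(cohort_spec, y$cohort),
    roi = build(roi_config, y$roi),
    bank = build(feature_bank_config, y$bank),
    smote = build(smote_config, y$smote),
    screening = build(screening_config, y$screening),
    gbdt = build(gbdt_config, y$gbdt),
    scheme = build(split_scheme, y$scheme),
    seed = if (is.null(y$seed)) 1 else y$seed,
    out_dir = y$out_dir,
    leakage_safe = isTRUE(y$leakage_safe),
    full_scale = isTRUE(y$full_scale))
}

#' Run the complete analysis pipeline
#'
#' Stages, in order: synthetic cohort generation; ROI construction and
#' radiomics extraction; null-feature removal; clinical univariate tests,
#' permissive pre-screen (p < 0.5) and multivariable logistic regression;
#' SMOTE balancing; the radiomics screening cascade; and the 5-model
#' train/validation evaluation of the clinical, radiomics and combined
#' predictor sets. Deterministic under the global seed.
#'
#' @param config an [pipeline_config()].
#' @param verbose print stage progress.
#' @param cohort optionally, a previously generated `rd_cohort` matching the
#'   config (skips the simulate stage).
#' @param features optionally, a previously extracted feature table from
#'   [extract_cohort_features()] (skips the extract stage); requires
#'   `cohort`.
#' @return An object of class `rd_pipeline`: list with `cohort` (spec only),
#'   `retention`, `univariate`, `clinical_selected`, `logistic`,
#'   `screening`, `evaluations` (per kind) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE,
                         cohort = NULL, features = NULL) {
  say <- function(...) if (verbose) message(sprintf(...))

  if (is.null(cohort)) {
    say("stage 1/5: simulating cohort (n = %d)", config$cohort$n_patients)
    cohort <- generate_cohort(config$cohort)
  } else {
    stopifnot(inherits(cohort, "rd_cohort"))
    say("stage 1/5: using supplied cohort")
  }
  labels <- cohort$labels

  if (is.null(features)) {
    say("stage 2/5: extracting radiomics features")
    feats <- extract_cohort_features(cohort, config$roi, config$bank,
                                     verbose = verbose)
  } else {
    say("stage 2/5: using supplied feature table")
    feats <- features
  }

  say("stage 3/5: preprocessing")
  dropped <- drop_null_features(feats)
  radiomics <- as.matrix(dropped$features[setdiff(names(dropped$features), "id")])
  clin_tab <- cohort$clinical
  if (anyNA(clin_tab))
    clin_tab <- impute_clinical(clin_tab, seed = derive_seed(config$seed, "impute"))
  clinical <- encode_clinical(clin_tab)

  uni <- univariate_table(clin_tab, labels)
  clin_sel <- clinical_prescreen(uni, alpha = 0.5)
  if (!length(clin_sel)) clin_sel <- colnames(clinical)
  logit <- if (length(clin_sel) >= 1)
    fit_logistic(clinical, labels, variables = clin_sel) else NULL

  cat_cols <- attr(clinical, "categorical")
  if (!config$leakage_safe) {
    bal <- smote(cbind(clinical[, clin_sel, drop = FALSE], radiomics),
                 labels, config$smote, round_cols = cat_cols)
    Xb <- bal$X; yb <- bal$y
  } else {
    Xb <- cbind(clinical[, clin_sel, drop = FALSE], radiomics)
    yb <- labels
  }

  say("stage 4/5: screening radiomics features")
  rad_cols <- colnames(radiomics)
  screening <- screen_features(Xb[, rad_cols, drop = FALSE], yb,
                               config$screening)

  say("stage 5/5: training and evaluating GBDT models")
  evals <- lapply(c("clinical", "radiomics", "combined"), function(kind) {
    if (!config$leakage_safe) {
      run_experiment(Xb[, screening$retained, drop = FALSE],
                     Xb[, clin_sel, drop = FALSE],
                     yb, kind, config$scheme, config$gbdt)
    } else {
      run_experiment_leakage_safe(
        Xb[, screening$retained, drop = FALSE],
        Xb[, clin_sel, drop = FALSE],
        yb, kind, config$scheme, config$gbdt, config$smote,
        round_cols = cat_cols)
    }
  })
  names(evals) <- c("clinical", "radiomics", "combined")

  out <- structure(list(cohort_spec = config$cohort,
                        labels = labels,
                        retention = dropped$report,
                        univariate = uni,
                        clinical_selected = clin_sel,
                        logistic = logit,
                        screening = screening,
                        evaluations = evals,
                        config = config),
                   class = "rd_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

# Leakage-safe variant: SMOTE is refit inside every training split; the
# validation rows are untouched originals.
run_experiment_leakage_safe <- function(radiomics, clinical, labels, kind,
                                        scheme, gbdt_cfg, smote_cfg,
                                        round_cols = NULL) {
  X <- switch(kind,
              clinical = as.matrix(clinical),
              radiomics = as.matrix(radiomics),
              combined = cbind(as.matrix(clinical), as.matrix(radiomics)))
  y <- as.integer(as.factor(labels)) - 1L
  splits <- make_splits(y, scheme)
  rows <- list(); imps <- list(); rocs <- list()
  for (m in seq_along(splits)) {
    sp <- splits[[m]]
    cfg_s <- smote_cfg
    cfg_s$seed <- derive_seed(smote_cfg$seed, paste0("ls", kind, m))
    bal <- smote(X[sp$train, , drop = FALSE], y[sp$train], cfg_s,
                 round_cols = round_cols)
    cfg_m <- gbdt_cfg
    cfg_m$seed <- derive_seed(gbdt_cfg$seed, paste0(kind, "model", m))
    fit <- gbdt(bal$X, bal$y, cfg_m)
    s_tr <- predict(fit, bal$X)
    s_va <- predict(fit, X[sp$validation, , drop = FALSE])
    ci_tr <- delong_ci(s_tr, bal$y)
    ci_va <- delong_ci(s_va, y[sp$validation])
    rows[[m]] <- data.frame(model = m,
                            train_auc = ci_tr["auc"], train_lower = ci_tr["lower"],
                            train_upper = ci_tr["upper"],
                            valid_auc = ci_va["auc"], valid_lower = ci_va["lower"],
                            valid_upper = ci_va["upper"], row.names = NULL)
    imps[[m]] <- gbdt_importance(fit)
    rocs[[m]] <- roc_points(s_va, y[sp$validation])
  }
  structure(list(kind = kind, models = do.call(rbind, rows),
                 importance = do.call(cbind, imps), splits = splits,
                 roc = rocs, features = colnames(X)),
            class = "rd_eval")
}

write_pipeline_artifacts <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(res$retention, file.path(dir, "retention.csv"), row.names = FALSE)
  write.csv(res$univariate, file.path(dir, "univariate.csv"), row.names = FALSE)
  if (!is.null(res$logistic))
    write.csv(res$logistic$coefficients, file.path(dir, "logistic.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(retained = res$screening$retained,
         stages = lapply(res$screening$stages, identity),
         vif = as.list(res$screening$vif)),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  for (kind in names(res$evaluations))
    write.csv(res$evaluations[[kind]]$models,
              file.path(dir, paste0("eval_", kind, ".csv")), row.names = FALSE)
  jsonlite::write_json(
    lapply(res$evaluations, function(e)
      list(kind = e$kind, models = e$models, features = e$features)),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}

#' Human-readable pipeline summary
#'
#' Prints the per-kind best train/validation AUCs with their DeLong
#' intervals and the top-12 combined-model importances (mean and SD across
#' the five models).
#'
#' @param result an `rd_pipeline`.
#' @return Invisibly, a list with the summary tables.
#' @export
report_summary <- function(result) {
  stopifnot(inherits(result, "rd_pipeline"))
  cat(sprintf("Cohort: %d patients (%d RD2+), screening retained %d radiomics features\n",
              length(result$labels), sum(result$labels),
              length(result$screening$retained)))
  best <- lapply(names(result$evaluations), function(kind) {
    df <- result$evaluations[[kind]]$models
    bt <- df[which.max(df$train_auc), ]
    bv <- df[which.max(df$valid_auc), ]
    cat(sprintf("%-10s best train AUC %.3f (%.3f-%.3f, model %d); best valid AUC %.3f (%.3f-%.3f, model %d)\n",
                kind, bt$train_auc, bt$train_lower, bt$train_upper, bt$model,
                bv$valid_auc, bv$valid_lower, bv$valid_upper, bv$model))
    data.frame(kind = kind, best_train = bt$train_auc, best_valid = bv$valid_auc)
  })
  imp <- result$evaluations$combined$importance
  mu <- rowMeans(imp)
  sdv <- apply(imp, 1, sd)
  ord <- order(mu, decreasing = TRUE)
  top <- head(ord, min(12, length(mu)))
  cat("\nTop variables by mean relative influence (combined model):\n")
  for (i in top)
    cat(sprintf("  %-50s %6.2f +/- %5.2f\n", rownames(imp)[i], mu[i], sdv[i]))
  invisible(list(best = do.call(rbind, best),
                 importance = data.frame(feature = rownames(imp)[ord],
                                         mean = mu[ord], sd = sdv[ord])))
}

#' @export
print.rd_pipeline <- function(x, ...) {
  cat("<rd_pipeline>\n")
  report_summary(x)
  invisible(x)
}
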