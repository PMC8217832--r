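# End-to-end glue: cohort -> segmentation -> kinetic maps -> per-map
# feature tables -> stratified split -> correlation filter + LASSO +
# stepwise logistic -> Youden-threshold ROC on train, frozen-threshold
# evaluation on test. Every stage is a package function; the analysis/
# scripts and the acceptance script are thin drivers over this file.

#' Kinetic maps and per-map features for one case
#'
#' @param case a `synthetic_case` (or list with `series`, `mask`, `label`).
#' @param config a `run_config`.
#' @param segment if TRUE (default), delineate the lesion on the
#'   `config$segmentation_phase` subtraction image; on segmentation failure
#'   fall back to the provided mask with a warning. If FALSE, use the
#'   provided mask.
#' @return list: `mask` used, `maps` (`kinetic_map_set`), `features` (7 x 55
#'   matrix, rows = kinetic maps).
#' @export
process_case <- function(case, config = run_config(), segment = TRUE) {
  mask <- case$mask
  if (segment) {
    sub <- subtraction_image(case$series, config$segmentation_phase)
    mask <- tryCatch(segment_lesion(sub),
                     error = function(e) {
                       warning(sprintf("%s: %s; using provided mask",
                                       case$series$case_id, conditionMessage(e)))
                       case$mask
                     })
  }
  maps <- compute_all_maps(case$series, mask)
  feats <- t(vapply(kinetic_map_names(), function(nm) {
    extract_all(maps$maps[[nm]], maps$validity[[nm]], maps$mask, config)
  }, numeric(55)))
  list(mask = mask, maps = maps, features = feats)
}

#' Build the seven per-map feature tables for a cohort
#'
#' @param cohort output of [generate_cohort()], or a list of cases.
#' @param config a `run_config`.
#' @param segment passed to [process_case()].
#' @return named list of 7 data.frames (one per kinetic map), each with
#'   columns case_id, label, and the 55 canonical features.
#' @export
build_feature_tables <- function(cohort, config = run_config(), segment = TRUE) {
  cases <- if (!is.null(cohort$cases)) cohort$cases else cohort
  per_case <- lapply(cases, process_case, config = config, segment = segment)
  nm <- kinetic_map_names()
  tables <- lapply(nm, function(m) {
    rows <- lapply(seq_along(cases), function(i) {
      data.frame(case_id = cases[[i]]$series$case_id,
                 label = cases[[i]]$label,
                 as.list(per_case[[i]]$features[m, ]),
                 check.names = FALSE)
    })
    do.call(rbind, rows)
  })
  names(tables) <- nm
  tables
}

#' Train one per-map model on a training feature table
#'
#' Correlation filter, LASSO selection, forward stepwise logistic fit, and
#' a Youden threshold frozen from the training ROC.
#'
#' @param table feature table (case_id, label, 55 features).
#' @param config a `run_config`.
#' @param map_name map identifier for the model spec.
#' @return list: `model` (`model_spec` with threshold set), `train_roc`
#'   (`roc_report`), `filter_log`, `lasso` (selection record).
#' @export
train_map_model <- function(table, config = run_config(), map_name = "map") {
  table <- validate_feature_table(table, require_label = TRUE)
  labels <- as.integer(table$label)
  x <- table[, feature_names()]
  filt <- correlation_filter(x, threshold = config$correlation_threshold)
  las <- lasso_select(filt$x, labels, folds = config$cv_folds,
                      seed = config$seed)
  candidates <- las$selected
  if (length(candidates) == 0L) {
    # LASSO found nothing: stepwise runs on the filtered set, typically
    # returning the flagged intercept-only model
    candidates <- filt$kept
  }
  model <- forward_stepwise_logistic(x[, candidates, drop = FALSE], labels,
                                     entry_p = config$entry_p,
                                     removal_p = config$removal_p,
                                     map_name = map_name)
  scores <- predict_model(model, x)$Y
  train_roc <- roc_analysis(scores, labels)
  model$threshold <- train_roc$threshold
  list(model = model, train_roc = train_roc,
       filter_log = filt$log, lasso = las)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates the cohort, builds the seven per-map feature tables, splits
#' stratified 70/30, trains one model per kinetic map on the training set,
#' and evaluates each on the test set at its frozen threshold.
#'
#' @param n_pos,n_neg cohort class sizes (defaults 48 / 54).
#' @param config a `run_config`; its seed drives the cohort, the split and
#'   the LASSO folds.
#' @param segment segment lesions (TRUE) or use generator masks.
#' @param ... passed to [generate_cohort()].
#' @return list: `tables`, `split`, per-map `models` (model, train_roc,
#'   test_roc), and `summary` (data.frame of AUC/CI/sens/spec/acc per map
#'   and split).
#' @export
run_pipeline <- function(n_pos = 48L, n_neg = 54L, config = run_config(),
                         segment = TRUE, ...) {
  cohort <- generate_cohort(n_pos, n_neg, seed = config$seed, ...)
  tables <- build_feature_tables(cohort, config, segment = segment)
  labels <- cohort$manifest$label
  split <- stratified_split(labels, 0.7, seed = config$seed)
  models <- list()
  rows <- list()
  for (m in kinetic_map_names()) {
    tr <- tables[[m]][split$train, ]
    te <- tables[[m]][split$test, ]
    fit <- train_map_model(tr, config, map_name = m)
    test_roc <- evaluate_on_test(fit$model, te[, feature_names()],
                                 te$label)
    models[[m]] <- c(fit, list(test_roc = test_roc))
    rows[[length(rows) + 1L]] <- data.frame(
      map = m, split = c("training", "test"),
      auc = c(fit$train_roc$auc, test_roc$auc),
      ci_low = c(fit$train_roc$ci[1], test_roc$ci[1]),
      ci_high = c(fit$train_roc$ci[2], test_roc$ci[2]),
      sensitivity = c(fit$train_roc$sensitivity, test_roc$sensitivity),
      specificity = c(fit$train_roc$specificity, test_roc$specificity),
      accuracy = c(fit$train_roc$accuracy, test_roc$accuracy))
  }
  list(manifest = cohort$manifest, tables = tables, split = split,
       models = models, summary = do.call(rbind, rows))
}

#' Lesion-mean kinetic comparison between classes
#'
#' Computes per-case lesion means of the seven maps and compares the
#' classes with the continuous-variable dispatch (clinical Table-3 layout).
#'
#' @param cohort output of [generate_cohort()].
#' @param segment use segmentation (default FALSE: generator masks).
#' @return data.frame: map, per-class summary, test, p.
#' @export
kinetic_mean_table <- function(cohort, segment = FALSE) {
  config <- run_config()
  means <- t(vapply(cohort$cases, function(cs) {
    lesion_means(compute_all_maps(cs$series, cs$mask))
  }, numeric(7)))
  labels <- cohort$manifest$label
  rows <- lapply(kinetic_map_names(), function(m) {
    cmp <- compare_continuous(means[, m], labels)
    data.frame(map = m,
               positive = cmp$summaries[["1"]], negative = cmp$summaries[["0"]],
               test = cmp$test, p = cmp$p)
  })
  do.call(rbind, rows)
}
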