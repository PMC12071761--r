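#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled by `seed` and dealt into
#' `n_folds` parts whose sizes differ by at most one, so every fold's test
#' set has (near-)equal class composition. Deterministic given `seed`.
#'
#' @param labels Per-sample class labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return A `cv_plan`: `n_folds`, `assignments` (fold index `1..n_folds`
#'   per sample), `stratified = TRUE`, `seed`.
#' @examples
#' plan <- stratified_kfold(rep(c("a", "b"), each = 10), 5, seed = 1)
#' table(plan$assignments)
#' @export
stratified_kfold <- function(labels, n_folds, seed = 1) {
  labels <- as.character(labels)
  n_folds <- as.integer(n_folds)
  tab <- table(labels)
  if (any(tab < n_folds)) {
    small <- names(tab)[tab < n_folds][1]
    stop("class '", small, "' has ", tab[small], " samples, fewer than ",
         n_folds, " folds", call. = FALSE)
  }
  assignments <- integer(length(labels))
  with_preserved_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      shuffled <- idx[sample.int(length(idx))]
      assignments[shuffled] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  structure(list(n_folds = n_folds, assignments = assignments,
                 stratified = TRUE, seed = as.integer(seed)),
            class = "cv_plan")
}

macro_metrics <- function(confusion) {
  K <- nrow(confusion)
  tp <- diag(confusion)
  prec <- ifelse(colSums(confusion) > 0, tp / colSums(confusion), 0)
  rec <- ifelse(rowSums(confusion) > 0, tp / rowSums(confusion), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

new_metrics_report <- function(combo_label, per_fold_accuracy, confusion,
                               error = NA_character_) {
  if (is.na(error)) {
    mm <- macro_metrics(confusion)
    rep <- list(combo_label = combo_label,
                per_fold_accuracy = per_fold_accuracy,
                mean_accuracy = mean(per_fold_accuracy),
                accuracy_sd = stats::sd(per_fold_accuracy),
                macro_precision = mm$macro_precision,
                macro_recall = mm$macro_recall,
                macro_f1 = mm$macro_f1,
                confusion = confusion, error = NA_character_)
  } else {
    rep <- list(combo_label = combo_label, per_fold_accuracy = NULL,
                mean_accuracy = NA_real_, accuracy_sd = NA_real_,
                macro_precision = NA_real_, macro_recall = NA_real_,
                macro_f1 = NA_real_, confusion = NULL, error = error)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> ", x$combo_label, "\n", sep = "")
  if (!is.na(x$error)) {
    cat("failed:", x$error, "\n")
    return(invisible(x))
  }
  cat(sprintf("mean accuracy %.4f (sd %.4f); macro P %.4f R %.4f F1 %.4f\n",
              x$mean_accuracy, x$accuracy_sd, x$macro_precision,
              x$macro_recall, x$macro_f1))
  invisible(x)
}

#' @rdname tidy_metrics
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  if (!is.na(x$error)) {
    return(tibble::tibble(fold = integer(0), accuracy = numeric(0)))
  }
  tibble::tibble(fold = seq_along(x$per_fold_accuracy),
                 accuracy = x$per_fold_accuracy)
}

#' Tidy and summarize a cross-validation metrics report
#'
#' `tidy()` gives per-fold accuracies; `glance()` a one-row summary with the
#' pooled macro metrics.
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy_metrics
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(combo_label = x$combo_label,
                 mean_accuracy = x$mean_accuracy,
                 accuracy_sd = x$accuracy_sd,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall,
                 macro_f1 = x$macro_f1,
                 error = x$error)
}

fit_predict_classifier <- function(classifier, tr_scores, tr_labels,
                                   te_scores, cart_cfg, boost_cfg) {
  if (toupper(classifier) == "CART") {
    tree <- select_subtree_cv(tr_scores, tr_labels, cart_cfg)
    predict(tree, te_scores)
  } else if (toupper(classifier) == "BOOST") {
    model <- fit_boosted(tr_scores, tr_labels, boost_cfg)
    predict_boosted(model, te_scores)$class
  } else {
    stop("unknown classifier: ", classifier, call. = FALSE)
  }
}

#' Run one preprocessing x extractor x classifier combination under a CV plan
#'
#' Per fold: the preprocessing chain (including any MSC reference) is fitted
#' on the training fold and applied to both folds; the discriminant
#' extractor is fitted on the preprocessed training fold; both folds are
#' projected; the classifier is fitted on the projected training fold and
#' predicts the test fold. No information from any test fold influences any
#' fit. Accuracies are recorded per fold; precision/recall/F1 are
#' macro-averaged over classes on the confusion matrix pooled across folds.
#'
#' An extractor that is structurally not applicable (e.g. common-vector LDA
#' when the within-class scatter is nonsingular) yields a report whose
#' `error` field records the failure instead of an exception.
#'
#' @param data A [spectra_set()].
#' @param preprocess A [preprocess_spec()].
#' @param extractor One of [extractor_methods()].
#' @param classifier `"CART"` or `"BOOST"`.
#' @param plan A [stratified_kfold()] plan over `data$labels`.
#' @param n_components Discriminant components to extract; default one fewer
#'   than the number of classes.
#' @param rank_tolerance Passed to the extractor.
#' @param cart_cfg,boost_cfg Classifier configurations.
#' @return A `metrics_report`.
#' @examples
#' \donttest{
#' s <- simulate_spectra(sim_config(samples_per_class = 10, grid_points = 120))
#' plan <- stratified_kfold(s$labels, 5, seed = 1)
#' run_combo_cv(s, preprocess_spec("SNV"), "NLDA", "BOOST", plan,
#'              boost_cfg = boost_config(iterations = 50))
#' }
#' @export
run_combo_cv <- function(data, preprocess, extractor, classifier, plan,
                         n_components = NULL, rank_tolerance = NULL,
                         cart_cfg = cart_config(), boost_cfg = boost_config()) {
  validate_spectra_set(data)
  stopifnot(inherits(plan, "cv_plan"),
            length(plan$assignments) == n_samples(data))
  combo_label <- paste(
    if (length(preprocess$steps)) paste(preprocess$steps, collapse = "+")
    else "none",
    toupper(extractor), toupper(classifier), sep = "-")

  classes <- sort(unique(data$labels))
  K <- length(classes)
  confusion <- matrix(0L, K, K, dimnames = list(true = classes,
                                                predicted = classes))
  per_fold <- numeric(plan$n_folds)

  for (f in seq_len(plan$n_folds)) {
    tr <- data[plan$assignments != f]
    te <- data[plan$assignments == f]
    pp <- fit_apply_chain(preprocess, tr, te)
    model <- tryCatch(
      fit_extractor(extractor, pp$train$absorbance, pp$train$labels,
                    d = n_components, rank_tolerance = rank_tolerance),
      error = function(e) e
    )
    if (inherits(model, "error")) {
      return(new_metrics_report(combo_label, error = conditionMessage(model)))
    }
    tr_scores <- project(model, pp$train$absorbance)
    te_scores <- project(model, pp$test$absorbance)
    pred <- fit_predict_classifier(classifier, tr_scores, pp$train$labels,
                                   te_scores, cart_cfg, boost_cfg)
    per_fold[f] <- mean(pred == te$labels)
    for (i in seq_along(pred)) {
      confusion[te$labels[i], pred[i]] <- confusion[te$labels[i], pred[i]] + 1L
    }
  }
  new_metrics_report(combo_label, per_fold, confusion)
}

#' Evaluate a grid of pipeline combinations
#'
#' One [run_combo_cv()] per (preprocessing, extractor, classifier) triple
#' under one shared CV plan; failures are recorded in-row rather than
#' aborting the grid.
#'
#' @param data A [spectra_set()].
#' @param preprocess_list Character vector of treatment names (see
#'   [preprocess_methods()]) or a list of [preprocess_spec()] objects.
#' @param extractor_list Character vector of extractor names.
#' @param classifier_list Character vector from `c("CART", "BOOST")`.
#' @param plan A [stratified_kfold()] plan.
#' @param ... Passed on to [run_combo_cv()].
#' @return A tibble with one row per combination (`preprocess`, `extractor`,
#'   `classifier`, the [glance()] metrics) and the full `metrics_report`
#'   objects in a list-column `report`.
#' @seealso [grid_average()] for the per-treatment average-accuracy rows.
#' @export
grid_report <- function(data, preprocess_list = preprocess_methods(),
                        extractor_list = extractor_methods(),
                        classifier_list = c("CART", "BOOST"),
                        plan, ...) {
  stopifnot(length(preprocess_list) > 0, length(extractor_list) > 0,
            length(classifier_list) > 0)
  if (!is.list(preprocess_list)) {
    names(preprocess_list) <- preprocess_list
    preprocess_list <- lapply(preprocess_list, preprocess_spec)
  }
  if (is.null(names(preprocess_list))) {
    names(preprocess_list) <- vapply(
      preprocess_list, function(s) paste(s$steps, collapse = "+"), character(1))
  }
  grid <- tidyr::expand_grid(
    preprocess = names(preprocess_list),
    extractor = extractor_list,
    classifier = classifier_list
  )
  reports <- purrr::pmap(grid, function(preprocess, extractor, classifier) {
    run_combo_cv(data, preprocess_list[[preprocess]], extractor, classifier,
                 plan, ...)
  })
  dplyr::bind_cols(
    grid,
    dplyr::bind_rows(lapply(reports, glance))["mean_accuracy"],
    dplyr::bind_rows(lapply(reports, glance))[
      c("accuracy_sd", "macro_precision", "macro_recall", "macro_f1", "error")]
  ) |>
    dplyr::mutate(report = reports)
}

#' Average accuracy per preprocessing treatment and classifier
#'
#' The analog of an "average accuracy rate" row: the arithmetic mean of
#' `mean_accuracy` over extractors, per (preprocess, classifier) column.
#'
#' @param grid A tibble from [grid_report()].
#' @return A tibble with `preprocess`, `classifier`, `average_accuracy`.
#' @export
grid_average <- function(grid) {
  grid |>
    dplyr::group_by(.data$preprocess, .data$classifier) |>
    dplyr::summarise(average_accuracy = mean(.data$mean_accuracy),
                     .groups = "drop")
}

#' Write the grid (combos plus average rows) to CSV
#'
#' @param grid A tibble from [grid_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  flat <- dplyr::select(grid, -dplyr::any_of("report"))
  avg <- grid_average(grid) |>
    dplyr::mutate(extractor = "AVERAGE") |>
    dplyr::rename(mean_accuracy = "average_accuracy")
  utils::write.csv(dplyr::bind_rows(flat, avg), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Tidy a pooled confusion matrix
#'
#' @param report A `metrics_report`.
#' @return A tibble with `true`, `predicted`, `n`.
#' @export
confusion_tbl <- function(report) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.na(report$error)) stop("combo failed: ", report$error, call. = FALSE)
  as.data.frame.table(report$confusion, responseName = "n") |>
    tibble::as_tibble() |>
    dplyr::rename(true = 1, predicted = 2)
}
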