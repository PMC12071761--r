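#' Read and validate a pipeline configuration
#'
#' The declarative YAML config binds all stages. Top-level keys:
#' \describe{
#'   \item{input}{either `input: csv: <path>` to load spectra, or
#'     `input: synthetic: <sim_config fields>` to generate them (exactly one).}
#'   \item{preprocess}{`method` (one of `none`, `SG`, `SNV`, `MSC`, `MSC+SG`,
#'     `SNV+SG`, `SNV+MSC`), `sg_window`, `sg_polyorder`.}
#'   \item{extract}{`method` (`ALDA`/`CLDA`/`MLDA`/`NLDA`), `components`,
#'     `rank_tolerance`.}
#'   \item{classifier}{`name` (`CART`/`BOOST`) plus nested config keys.}
#'   \item{cv}{`n_folds`, `seed`.}
#'   \item{output_dir}{where artifacts are written.}
#' }
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  cfg$input <- cfg$input %||% list(synthetic = list())
  has_csv <- !is.null(cfg$input$csv)
  has_syn <- !is.null(cfg$input$synthetic)
  if (has_csv == has_syn) {
    stop("config key 'input' must contain exactly one of 'csv' or 'synthetic'",
         call. = FALSE)
  }
  if (has_syn) {
    known <- names(formals(sim_config))
    bad <- setdiff(names(cfg$input$synthetic), known)
    if (length(bad)) {
      stop("unknown synthetic config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  cfg$preprocess <- cfg$preprocess %||% list(method = "none")
  cfg$extract <- cfg$extract %||% list(method = "NLDA")
  if (!toupper(cfg$extract$method) %in% extractor_methods()) {
    stop("config key 'extract.method' invalid: ", cfg$extract$method,
         call. = FALSE)
  }
  cfg$classifier <- cfg$classifier %||% list(name = "BOOST")
  if (!toupper(cfg$classifier$name) %in% c("CART", "BOOST")) {
    stop("config key 'classifier.name' invalid: ", cfg$classifier$name,
         call. = FALSE)
  }
  cfg$cv <- cfg$cv %||% list()
  cfg$cv$n_folds <- cfg$cv$n_folds %||% 5L
  cfg$cv$seed <- cfg$cv$seed %||% 1L
  cfg$output_dir <- cfg$output_dir %||% "nirdisc_output"
  structure(cfg, class = "pipeline_config")
}

load_input <- function(cfg) {
  if (!is.null(cfg$input$csv)) {
    if (!file.exists(cfg$input$csv)) {
      stop("input file not found: ", cfg$input$csv, call. = FALSE)
    }
    read_spectra_csv(cfg$input$csv)
  } else {
    simulate_spectra(do.call(sim_config, cfg$input$synthetic))
  }
}

config_preprocess_spec <- function(cfg) {
  pp <- cfg$preprocess
  preprocess_spec(pp$method %||% "none",
                  sg_window = pp$sg_window %||% 11,
                  sg_polyorder = pp$sg_polyorder %||% 2)
}

config_classifier_cfgs <- function(cfg) {
  cl <- cfg$classifier
  list(
    cart = cart_config(
      gini_split_threshold = cl$gini_split_threshold %||% 0.01,
      min_samples_split = cl$min_samples_split %||% 2,
      max_depth = cl$max_depth %||% 20,
      cv_folds_for_pruning = cl$cv_folds_for_pruning %||% 5,
      seed = cl$seed %||% 1),
    boost = boost_config(
      iterations = cl$iterations %||% 500,
      depth = cl$depth %||% 6,
      learning_rate = cl$learning_rate %||% 0.1,
      seed = cl$seed %||% 1)
  )
}

write_manifest <- function(cfg, out_dir) {
  manifest <- list(
    package_version = as.character(utils::packageVersion("nirdisc")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = unclass(cfg),
    seeds = list(cv = cfg$cv$seed,
                 synthetic = cfg$input$synthetic$seed %||%
                   formals(sim_config)$seed,
                 classifier = cfg$classifier$seed %||% 1L)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null", force = TRUE)
}

#' Generate spectra from a config and write them to CSV
#'
#' @param cfg A [pipeline_config()] (or path to one) whose `input` is
#'   `synthetic`.
#' @return Path of the written spectra CSV, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  if (is.null(cfg$input$synthetic)) {
    stop("simulate requires a synthetic input config", call. = FALSE)
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  data <- load_input(cfg)
  path <- file.path(cfg$output_dir, "spectra.csv")
  write_spectra_csv(data, path)
  write_manifest(cfg, cfg$output_dir)
  message("wrote ", n_samples(data), " spectra to ", path)
  invisible(path)
}

#' Run the configured pipeline end to end
#'
#' Loads or simulates the spectra, runs either the single configured
#' combination or (with `grid = TRUE`) the full treatment x extractor x
#' classifier grid under one stratified CV plan, and writes `metrics.json`,
#' `confusion.csv`, per-fold projected scores (`scores_fold<i>.csv`) or
#' `grid.csv`, plus a `run_manifest.json` sufficient to reproduce the run.
#'
#' @param cfg A [pipeline_config()] or path to one.
#' @param grid Run the full comparison grid instead of the single combo.
#' @return The `metrics_report` (or grid tibble), invisibly.
#' @export
cmd_run <- function(cfg, grid = FALSE) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  data <- load_input(cfg)
  message(sprintf("[%s] loaded %d spectra x %d wavenumbers",
                  format(Sys.time() - t0), n_samples(data),
                  length(data$wavenumbers)))
  plan <- stratified_kfold(data$labels, cfg$cv$n_folds, cfg$cv$seed)
  pp_spec <- config_preprocess_spec(cfg)
  cls <- config_classifier_cfgs(cfg)

  if (grid) {
    res <- grid_report(data, plan = plan,
                       n_components = cfg$extract$components,
                       rank_tolerance = cfg$extract$rank_tolerance,
                       cart_cfg = cls$cart, boost_cfg = cls$boost)
    write_grid_csv(res, file.path(cfg$output_dir, "grid.csv"))
    message(sprintf("[%s] grid of %d combos written", format(Sys.time() - t0),
                    nrow(res)))
  } else {
    res <- run_combo_cv(data, pp_spec, cfg$extract$method,
                        cfg$classifier$name, plan,
                        n_components = cfg$extract$components,
                        rank_tolerance = cfg$extract$rank_tolerance,
                        cart_cfg = cls$cart, boost_cfg = cls$boost)
    if (!is.na(res$error)) {
      stop("combo ", res$combo_label, " failed: ", res$error, call. = FALSE)
    }
    jsonlite::write_json(
      as.list(glance(res)), file.path(cfg$output_dir, "metrics.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
    utils::write.csv(res$confusion, file.path(cfg$output_dir, "confusion.csv"))
    # per-fold projected scores (refit per fold, as in evaluation)
    for (f in seq_len(plan$n_folds)) {
      tr <- data[plan$assignments != f]
      pp <- fit_apply_chain(pp_spec, tr, data[plan$assignments == f])
      model <- fit_extractor(cfg$extract$method, pp$train$absorbance,
                             pp$train$labels, d = cfg$extract$components,
                             rank_tolerance = cfg$extract$rank_tolerance)
      utils::write.csv(project_scores(model, pp$test),
                       file.path(cfg$output_dir,
                                 sprintf("scores_fold%d.csv", f)),
                       row.names = FALSE)
    }
    message(sprintf("[%s] %s: mean accuracy %.4f", format(Sys.time() - t0),
                    res$combo_label, res$mean_accuracy))
  }
  write_manifest(cfg, cfg$output_dir)
  invisible(res)
}
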