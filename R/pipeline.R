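# End-to-end orchestration: manifest in, run directory out.

#' Default pipeline configuration
#'
#' @param manifest path to a manifest (CSV or JSON) with columns
#'   `subject_id`, `volume`, `mask`, `label`, or `NULL` when subjects are
#'   passed in memory.
#' @param out_dir run directory for all artifacts.
#' @param n_slices,n_levels,offsets extraction parameters.
#' @param train_fraction,alpha,spearman_threshold,n_folds selection
#'   parameters.
#' @param threshold classification probability cut-off.
#' @param seed master seed; per-stage seeds are derived from it by a fixed
#'   offset per stage name so each stage is independently reproducible.
#' @return a `run_config` list.
#' @export
run_config <- function(manifest = NULL, out_dir = "run",
                       n_slices = 9L, n_levels = 16L, offsets = c(1L, 4L, 7L),
                       train_fraction = 0.7, alpha = 0.05,
                       spearman_threshold = 0.9, n_folds = 10L,
                       threshold = 0.5, seed = 1L) {
  stopifnot(n_slices %% 2 == 1, n_levels >= 2, train_fraction > 0,
            train_fraction < 1, alpha > 0, alpha < 1,
            spearman_threshold >= 0, spearman_threshold <= 1,
            n_folds >= 2, threshold > 0, threshold < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [run_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

# Fixed per-stage seed derivation from the master seed.
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, split = 211L, lasso = 307L)
  as.integer((as.numeric(seed) * 7919 + offs[[stage]]) %%
               .Machine$integer.max)
}

.read_manifest <- function(path) {
  man <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("subject_id", "volume", "mask", "label")
  if (!all(need %in% colnames(man)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  man
}

.load_subjects <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    if (!file.exists(r$volume))
      stop("subject ", r$subject_id, ": volume file missing: ", r$volume)
    if (!file.exists(r$mask))
      stop("subject ", r$subject_id, ": mask file missing: ", r$mask)
    vol <- load_volume(r$volume)
    list(subject_id = r$subject_id, volume = vol,
         mask = load_mask(r$mask, vol), label = as.integer(r$label))
  })
}

#' Run the whole pipeline
#'
#' Feature extraction over all manifest subjects, the three-stage selection
#' cascade, the logistic fit, and evaluation of both partitions; writes
#' `features.csv`, `selection_trace.json`, `model.json`,
#' `eval_report.json`, ROC and score CSVs, diagnostic plots and a
#' `run.log` into the run directory. Identical configurations reproduce
#' identical artifacts.
#'
#' @param config a `run_config`.
#' @param subjects optional in-memory subject list (as from
#'   [make_cohort()]); when `NULL` the manifest is loaded from disk.
#' @return list with `features`, `selection`, `model`, `reports`
#'   (train/test), invisibly; artifacts on disk in `config$out_dir`.
#' @export
run_all <- function(config, subjects = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf)
  stage <- "load"
  res <- tryCatch({
    if (is.null(subjects)) subjects <- .load_subjects(
      .read_manifest(config$manifest))
    log_line("subjects: ", length(subjects))

    stage <- "extract"
    features <- extract_cohort(subjects, n_slices = config$n_slices,
                               n_levels = config$n_levels,
                               offsets = config$offsets)
    write.csv(features, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    log_line("features per subject: ", length(.feature_cols(features)))

    stage <- "select"
    sel <- run_selection(features, config$train_fraction, config$alpha,
                         config$spearman_threshold, config$n_folds,
                         seed = .stage_seed(config$seed, "split"))
    jsonlite::write_json(
      list(counts = as.list(sel$trace$counts),
           survivors = sel$trace$survivors,
           lambda = sel$trace$lasso_lambda),
      file.path(config$out_dir, "selection_trace.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_line("selection counts: ",
             paste(sel$trace$counts, collapse = " -> "))

    stage <- "train"
    model <- fit_logistic(sel$train)
    jsonlite::write_json(
      list(intercept = model$intercept,
           coefficients = as.list(model$coefficients),
           separation = model$separation),
      file.path(config$out_dir, "model.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)

    stage <- "evaluate"
    reports <- list(train = evaluate(model, sel$train, config$threshold),
                    test = evaluate(model, sel$test, config$threshold))
    jsonlite::write_json(
      lapply(reports, function(r)
        list(counts = as.list(r$counts), metrics = as.list(r$metrics),
             reported = as.list(r$reported))),
      file.path(config$out_dir, "eval_report.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (p in names(reports)) {
      write.csv(reports[[p]]$roc,
                file.path(config$out_dir, paste0("roc_", p, ".csv")),
                row.names = FALSE)
      write.csv(reports[[p]]$scores,
                file.path(config$out_dir, paste0("scores_", p, ".csv")),
                row.names = FALSE)
    }
    log_line("test AUC: ", sprintf("%.3f", reports$test$metrics[["auc"]]))

    stage <- "plot"
    save_plot <- function(p, name, w = 7, h = 5) {
      pdf(file.path(config$out_dir, name), width = w, height = h)
      print(p)
      dev.off()
    }
    uni_surv <- sel$trace$survivors$univariate
    if (length(uni_surv) >= 2) {
      tr_std <- standardize(features[sel$split$train, , drop = FALSE],
                            features[sel$split$test, , drop = FALSE])$train
      save_plot(plot_correlation_heatmap(
        tr_std[, c("subject_id", "label", uni_surv)]), "correlation.pdf")
    }
    if (!is.null(sel$trace$lasso_cv)) {
      save_plot(plot_cv_error(sel$trace), "cv_error.pdf")
      save_plot(plot_coefficient_paths(sel$trace), "coef_paths.pdf")
    }
    save_plot(plot_roc(reports), "roc.pdf")
    save_plot(plot_score_waterfall(reports$test), "scores_test.pdf")

    jsonlite::write_json(unclass(config)[!vapply(config, is.null,
                                                 logical(1))],
                         file.path(config$out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    log_line("done")
    list(features = features, selection = sel, model = model,
         reports = reports)
  }, error = function(e) {
    log_line("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
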