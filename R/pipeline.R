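#' Run the screening pipeline end to end
#'
#' Orchestrates the full analysis on a raw peak table: feature presence
#' filter, internal-standard normalization, half-minimum imputation of
#' residual missing cells, a stratified 70:30 train/test split, log +
#' autoscale fitted on the training set, correlation/stability/missingness
#' screening on the training samples, optional genetic-algorithm feature
#' selection, grid-search training of the seven base models, admission
#' (CV accuracy > 0.65 and CV AUC > 0.85, no overfitting), ensemble voting on
#' the held-out set, Youden-index threshold, and the diagnostic panel.
#'
#' @param table a raw [peak_table()] with CTRL/EC labels.
#' @param kinds model kinds to train (default all seven).
#' @param ga `"shared"` (one GA run, its subset reused by every model),
#'   `"per_model"` (one GA per classifier kind, each with that kind as
#'   fitness), or `"none"`.
#' @param ga_cfg a [ga_config()]; default a desk-scale configuration
#'   (population 20, 10 generations, 3-fold fitness CV).
#' @param ga_fitness_kind fitness model of the shared GA run (default GLM).
#' @param folds CV folds for grid search (default 5).
#' @param train_frac training fraction of the stratified split (default 0.7).
#' @param presence_threshold feature presence filter (default 0.8).
#' @param seed integer seed governing the split, folds, GA and stochastic
#'   learners.
#' @return list with the fitted artifacts: `filtered` (presence-filter
#'   output), `train_ids`, `test_ids`, `pm_train`, `x_test`, `screen`,
#'   `ga` (per-kind feature subsets or `NULL`), `models` (all trained),
#'   `admitted`, `result` (test-set `eml_result` at the Youden threshold),
#'   `threshold` (a `threshold_result`), `panel` (test-set
#'   `diagnostic_panel`), `summary` (per-class score summary).
#' @export
run_eml_pipeline <- function(table, kinds = model_kinds(),
                             ga = c("shared", "per_model", "none"),
                             ga_cfg = NULL, ga_fitness_kind = "GLM",
                             folds = 5, train_frac = 0.7,
                             presence_threshold = 0.80, seed = 1L) {
  stopifnot(inherits(table, "peak_table"))
  ga <- match.arg(ga)
  kinds <- match.arg(kinds, model_kinds(), several.ok = TRUE)
  ga_cfg <- ga_cfg %||% ga_config(population = 20, generations = 10,
                                  folds = 3, init_density = 0.3,
                                  seed = seed)

  filtered <- filter_features(table, presence_threshold)
  norm <- normalize_to_is(filtered$table)
  complete <- impute_missing(norm, "half_min")$table
  y <- as_class_factor(complete$label)

  # stratified 70:30 split
  ids <- rownames(complete$areas)
  train_ids <- withr::with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      i <- ids[y == cl]
      sample(i, round(train_frac * length(i)))
    }), use.names = FALSE)
  })
  test_ids <- setdiff(ids, train_ids)

  pm <- log_and_autoscale(complete, fit_on = train_ids)
  x_train <- pm$x[train_ids, , drop = FALSE]
  y_train <- pm$label[train_ids]
  x_test <- pm$x[test_ids, , drop = FALSE]
  y_test <- pm$label[test_ids]

  screen <- screen_features(x_train, y_train)
  x_train <- x_train[, screen$retained, drop = FALSE]
  x_test <- x_test[, screen$retained, drop = FALSE]

  subsets <- NULL
  if (ga != "none") {
    if (ga == "shared") {
      sel <- ga_select(x_train, y_train, ga_fitness_kind, ga_cfg)
      subsets <- setNames(rep(list(sel$features), length(kinds)), kinds)
      ga_runs <- list(shared = sel)
    } else {
      ga_runs <- lapply(kinds, function(k) {
        cfg <- ga_cfg
        cfg$seed <- ga_cfg$seed + match(k, model_kinds())
        ga_select(x_train, y_train, k, cfg)
      })
      names(ga_runs) <- kinds
      subsets <- lapply(ga_runs, `[[`, "features")
    }
  } else {
    subsets <- setNames(rep(list(colnames(x_train)), length(kinds)), kinds)
    ga_runs <- NULL
  }

  models <- lapply(kinds, function(k) {
    train_model(k, x_train[, subsets[[k]], drop = FALSE], y_train,
                folds = folds, seed = seed + match(k, model_kinds()))
  })
  names(models) <- kinds
  admitted <- admit_models(models)
  if (length(admitted) == 0) {
    return(list(filtered = filtered, train_ids = train_ids,
                test_ids = test_ids, pm_train = pm, screen = screen,
                ga = ga_runs, models = models, admitted = admitted,
                result = NULL, threshold = NULL, panel = NULL,
                summary = NULL))
  }

  scores0 <- screen_cohort(admitted, x_test, threshold = 0)
  thr <- choose_threshold(scores0$samples$score, y_test)
  result <- screen_cohort(admitted, x_test, threshold = thr$threshold)
  panel <- diagnostic_panel(result$samples$class, y_test,
                            scores = result$samples$score)
  list(filtered = filtered, train_ids = train_ids, test_ids = test_ids,
       pm_train = pm, x_test = x_test, screen = screen, ga = ga_runs,
       models = models, admitted = admitted, result = result,
       threshold = thr, panel = panel,
       summary = summarize_scores(result, as.character(y_test)))
}
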