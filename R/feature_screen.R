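#' Pre-model feature screening
#'
#' Applies the three exclusion criteria, in order (the first failing criterion
#' tags the feature):
#' \enumerate{
#'   \item correlation: features whose point-biserial correlation with the
#'     class label is too close (`|r| >= r_high`, suspected leakage;
#'     tag `correlation_high`) or absent (`|r| <= r_low`, uninformative;
#'     tag `correlation_null`);
#'   \item stability: features where more than `identical_frac` of the values
#'     are identical (near-constant; tag `unstable`);
#'   \item missing data: features with any missing value (tag `missing`).
#' }
#'
#' @param x feature matrix or `processed_matrix`.
#' @param labels binary class vector (CTRL/EC); taken from a
#'   `processed_matrix` if omitted.
#' @param r_high,r_low correlation exclusion bounds.
#' @param identical_frac exclusive bound on the identical-value fraction.
#' @return object of class `screen_report`: `retained` (feature names) and
#'   `excluded` (data.frame feature/reason). Retained and excluded partition
#'   the input features.
#' @export
screen_features <- function(x, labels = NULL, r_high = 0.95, r_low = 0.05,
                            identical_frac = 0.80) {
  if (inherits(x, "processed_matrix")) {
    if (is.null(labels)) labels <- x$label
    x <- x$x
  }
  y <- as_class_factor(labels)
  y01 <- as.numeric(y == POSITIVE_CLASS)
  reasons <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    obs <- !is.na(v)
    r <- if (sum(obs) >= 3 && sd(v[obs]) > 0 && sd(y01[obs]) > 0) {
      cor(v[obs], y01[obs])
    } else NA_real_
    if (!is.na(r) && abs(r) >= r_high) return("correlation_high")
    if (!is.na(r) && abs(r) <= r_low) return("correlation_null")
    if (max(table(v[obs])) / sum(obs) > identical_frac) return("unstable")
    if (any(!obs)) return("missing")
    "retained"
  }, character(1))
  excluded <- data.frame(feature = colnames(x)[reasons != "retained"],
                         reason = reasons[reasons != "retained"],
                         stringsAsFactors = FALSE)
  structure(list(retained = colnames(x)[reasons == "retained"],
                 excluded = excluded,
                 params = list(r_high = r_high, r_low = r_low,
                               identical_frac = identical_frac)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report> retained ", length(x$retained), " / ",
      length(x$retained) + nrow(x$excluded), " features\n", sep = "")
  if (nrow(x$excluded)) print(table(x$excluded$reason))
  invisible(x)
}

#' Genetic-algorithm configuration
#'
#' Settings of the binary-mask GA used for wrapper feature selection. Fitness
#' of a mask is the mean stratified cross-validated accuracy of a given
#' classifier kind restricted to the masked features.
#'
#' @param population chromosomes per generation (>= 2).
#' @param generations number of generations.
#' @param crossover_rate probability of uniform crossover per mating pair.
#' @param mutation_rate per-bit flip probability.
#' @param elitism chromosomes copied unchanged into the next generation.
#' @param folds CV folds of the fitness evaluation (>= 2).
#' @param init_density expected fraction of selected features in the initial
#'   population.
#' @param seed integer seed.
#' @return object of class `ga_config`.
#' @export
ga_config <- function(population = 50, generations = 40,
                      crossover_rate = 0.8, mutation_rate = 0.02,
                      elitism = 2, folds = 5, init_density = 0.5, seed = 1L) {
  stopifnot(population >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, elitism < population, folds >= 2,
            init_density > 0, init_density <= 1)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 elitism = as.integer(elitism), folds = as.integer(folds),
                 init_density = init_density, seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm wrapper feature selection
#'
#' Evolves binary feature masks by tournament selection (size 2), uniform
#' crossover, per-bit mutation, and elitism. A mask's fitness is the mean
#' stratified k-fold CV accuracy of `model_kind` (at its default
#' hyperparameters) on the masked features. Deterministic for a fixed
#' `config$seed`; with `elitism >= 1` the best fitness is non-decreasing
#' across generations.
#'
#' @param x feature matrix or `processed_matrix` (screened, complete).
#' @param labels class vector (CTRL/EC).
#' @param model_kind fitness model, a code from [model_kinds()].
#' @param config a [ga_config()].
#' @return list with `features` (best mask's feature names), `mask` (logical),
#'   `fitness` (best CV accuracy), and `trace` (best fitness per generation).
#' @export
ga_select <- function(x, labels = NULL, model_kind = "GLM",
                      config = ga_config()) {
  if (inherits(x, "processed_matrix")) {
    if (is.null(labels)) labels <- x$label
    x <- x$x
  }
  model_kind <- match.arg(model_kind, model_kinds())
  y <- as_class_factor(labels)
  p <- ncol(x)
  if (p == 0) stop("empty feature set after screening")
  if (anyNA(x)) stop("GA requires a complete matrix")
  fold_id <- make_folds(y, config$folds, config$seed)
  hyper <- as.list(default_grid(model_kind, p)[1, , drop = FALSE])

  fitness_of <- function(mask) {
    cv_evaluate(model_kind, x[, mask, drop = FALSE], y, hyper, fold_id,
                seed = config$seed)$accuracy
  }

  withr::with_seed(config$seed, {
    ensure_one <- function(m) {
      if (!any(m)) m[sample(p, 1)] <- TRUE
      m
    }
    pop <- lapply(seq_len(config$population), function(i) {
      ensure_one(runif(p) < config$init_density)
    })
    fit <- vapply(pop, fitness_of, numeric(1))
    trace <- numeric(config$generations)
    for (g in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      nextpop <- pop[ord[seq_len(config$elitism)]]
      while (length(nextpop) < config$population) {
        tour <- function() {
          ij <- sample(config$population, 2)
          pop[[ij[which.max(fit[ij])]]]
        }
        a <- tour(); b <- tour()
        if (runif(1) < config$crossover_rate) {
          swap <- runif(p) < 0.5
          tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
        }
        a <- xor(a, runif(p) < config$mutation_rate)
        b <- xor(b, runif(p) < config$mutation_rate)
        nextpop <- c(nextpop, list(ensure_one(a)))
        if (length(nextpop) < config$population) {
          nextpop <- c(nextpop, list(ensure_one(b)))
        }
      }
      pop <- nextpop
      fit <- vapply(pop, fitness_of, numeric(1))
      trace[g] <- max(fit)
    }
    best <- which.max(fit)
    list(features = colnames(x)[pop[[best]]], mask = pop[[best]],
         fitness = fit[best], trace = trace, config = config,
         model_kind = model_kind)
  })
}

#' Serialize a screen report or GA result as JSON
#'
#' @param x a `screen_report` or the list returned by [ga_select()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_screen_json <- function(x, path) {
  out <- if (inherits(x, "screen_report")) {
    list(retained = x$retained, excluded = x$excluded, params = x$params)
  } else {
    list(features = x$features, fitness = x$fitness, trace = x$trace,
         model_kind = x$model_kind, config = unclass(x$config))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
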