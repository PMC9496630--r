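#' Default planted-effect metabolites
#'
#' The twelve serum metabolites that separate endometrial-cancer (EC) sera
#' from controls in the univariate (volcano) analysis: three raised in EC
#' (glycerol, 3-hydroxybutyric acid, stearic acid) and nine lowered (glycine,
#' phenyl pyruvic acid, serine, valine, urea, oxyproline, phenylalanine,
#' glyceraldehyde 3-phosphate, gluconic acid). Fold changes are on the raw
#' (multiplicative) scale: EC geometric mean / CTRL geometric mean.
#'
#' @param fc_up fold change for metabolites raised in EC (default 3).
#' @param fc_down fold change for metabolites lowered in EC (default 1/3).
#' @return data.frame with columns `feature`, `fold_change`, `direction`.
#' @export
default_effects <- function(fc_up = 3, fc_down = 1 / 3) {
  up <- c("glycerol", "3-hydroxybutyric acid", "stearic acid")
  down <- c("glycine", "phenyl pyruvic acid", "serine", "valine", "urea",
            "oxyproline", "phenylalanine", "glyceraldehyde 3-phosphate",
            "gluconic acid")
  data.frame(
    feature = c(up, down),
    fold_change = c(rep(fc_up, length(up)), rep(fc_down, length(down))),
    direction = c(rep("up", length(up)), rep("down", length(down))),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic case-control GC-MS cohort. Raw peak areas are
#' log-normal; planted effects act multiplicatively on the raw scale so that
#' the configured fold change is the EC/CTRL geometric-mean ratio in
#' expectation. Missing cells are inserted completely at random.
#'
#' @param n_ctrl,n_ec number of control / EC samples (positive).
#' @param n_features number of metabolite features (default 251, the number
#'   of consistently detected GC-MS signals the analysis assumes).
#' @param effect_features data.frame with columns `feature` and `fold_change`
#'   (raw-scale, > 0); default [default_effects()]. May have zero rows.
#' @param base_log_mean,base_log_sd location and scale (natural-log scale) of
#'   peak areas. Per-feature log-means are drawn around `base_log_mean`
#'   (spread 1.0) and per-feature log-sds around `base_log_sd`
#'   (multiplicative spread 0.7-1.3), giving features spanning roughly two
#'   decades of abundance with 30-60% biological CV.
#' @param missing_rate fraction of cells set missing, in \[0, 1\].
#' @param is_area nominal internal-standard peak area (> 0); per-sample IS
#'   areas get 5% log-normal injection variation.
#' @param seed integer seed; a fixed seed gives bit-identical tables.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_ctrl, n_ec, n_features = 251,
                          effect_features = default_effects(),
                          base_log_mean = log(2e5), base_log_sd = 0.45,
                          missing_rate = 0.02, is_area = 5e5, seed = 1L) {
  stopifnot(n_ctrl >= 1, n_ec >= 1, n_features >= 1,
            missing_rate >= 0, missing_rate <= 1, is_area > 0,
            base_log_sd > 0)
  effect_features <- as.data.frame(effect_features)
  if (nrow(effect_features) > 0) {
    stopifnot(all(c("feature", "fold_change") %in% names(effect_features)),
              all(effect_features$fold_change > 0),
              !anyDuplicated(effect_features$feature))
  }
  if (n_features < nrow(effect_features)) {
    stop("n_features (", n_features, ") is smaller than the number of effect features (",
         nrow(effect_features), ")")
  }
  structure(
    list(n_ctrl = as.integer(n_ctrl), n_ec = as.integer(n_ec),
         n_features = as.integer(n_features),
         effect_features = effect_features,
         base_log_mean = base_log_mean, base_log_sd = base_log_sd,
         missing_rate = missing_rate, is_area = is_area,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Construct a peak table
#'
#' The pipeline's entry format: one sample per row, one metabolite feature per
#' column, plus the internal-standard (IS) peak area and a class label per
#' sample. Missing measurements are `NA`.
#'
#' @param areas numeric matrix (samples x features), non-negative, `NA` for
#'   missing; must have row and column names.
#' @param is_area numeric vector of internal-standard areas, strictly
#'   positive, one per sample.
#' @param label character/factor vector of class labels (e.g. "CTRL", "EC").
#' @param batch optional batch id per sample.
#' @param normalized logical flag: areas already divided by the IS area.
#' @return object of class `peak_table`: a list with elements `areas`,
#'   `is_area`, `label`, `batch`, `normalized`.
#' @export
peak_table <- function(areas, is_area, label, batch = NULL,
                       normalized = FALSE) {
  areas <- as.matrix(areas)
  if (is.null(rownames(areas)) || is.null(colnames(areas))) {
    stop("areas must have sample (row) and feature (column) names")
  }
  if (anyDuplicated(colnames(areas))) stop("feature names must be unique")
  if (anyDuplicated(rownames(areas))) stop("sample ids must be unique")
  stopifnot(length(is_area) == nrow(areas), length(label) == nrow(areas))
  bad <- !is.finite(is_area) | is_area <= 0
  if (any(bad)) {
    stop("non-positive internal-standard area for sample(s): ",
         paste(rownames(areas)[bad], collapse = ", "))
  }
  if (any(areas < 0, na.rm = TRUE)) stop("peak areas must be non-negative")
  structure(
    list(areas = areas, is_area = setNames(as.numeric(is_area), rownames(areas)),
         label = setNames(as.character(label), rownames(areas)),
         batch = if (!is.null(batch)) setNames(as.character(batch), rownames(areas)),
         normalized = isTRUE(normalized)),
    class = "peak_table"
  )
}

#' @export
print.peak_table <- function(x, ...) {
  cat("<peak_table> ", nrow(x$areas), " samples x ", ncol(x$areas),
      " features", if (x$normalized) " (IS-normalized)", "\n", sep = "")
  cat("  labels:", paste(sprintf("%s=%d", names(table(x$label)),
                                 table(x$label)), collapse = ", "), "\n")
  cat("  missing cells:", sum(is.na(x$areas)), "\n")
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$areas)

#' Subset a peak table by samples and/or features
#'
#' @param x a `peak_table`.
#' @param samples,features row / column selectors (names, indices or logical).
#' @return a `peak_table`.
#' @export
subset_peak_table <- function(x, samples = NULL, features = NULL) {
  stopifnot(inherits(x, "peak_table"))
  s <- samples %||% rownames(x$areas)
  f <- features %||% colnames(x$areas)
  peak_table(x$areas[s, f, drop = FALSE], x$is_area[s], x$label[s],
             batch = if (!is.null(x$batch)) x$batch[s],
             normalized = x$normalized)
}

#' Simulate a case-control GC-MS cohort
#'
#' Draws a sample x feature table of raw peak areas. Each feature j has a
#' log-normal abundance with its own log-mean and log-sd; for every planted
#' effect feature the EC group's log-mean is shifted by log(fold change), so
#' the EC/CTRL geometric-mean ratio equals the configured fold change in
#' expectation. Cells are set missing completely at random at
#' `config$missing_rate`. Output is deterministic for a fixed
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a [peak_table()] with labels "CTRL" then "EC"; planted effect
#'   features carry their configured names, the remainder are `met_###`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    n <- config$n_ctrl + config$n_ec
    p <- config$n_features
    eff <- config$effect_features
    other <- sprintf("met_%03d", seq_len(p))
    features <- c(eff$feature, other[seq_len(p - nrow(eff))])
    label <- c(rep("CTRL", config$n_ctrl), rep("EC", config$n_ec))
    samples <- sprintf("S%04d", seq_len(n))

    mu <- rnorm(p, config$base_log_mean, 1.0)
    sigma <- config$base_log_sd * runif(p, 0.7, 1.3)
    logx <- matrix(rnorm(n * p), n, p) * rep(sigma, each = n) +
      rep(mu, each = n)
    if (nrow(eff) > 0) {
      shift <- log(eff$fold_change)
      ec <- label == "EC"
      logx[ec, seq_len(nrow(eff))] <-
        logx[ec, seq_len(nrow(eff)), drop = FALSE] +
        rep(shift, each = sum(ec))
    }
    areas <- exp(logx)
    dimnames(areas) <- list(samples, features)
    if (config$missing_rate > 0) {
      miss <- runif(n * p) < config$missing_rate
      areas[matrix(miss, n, p)] <- NA_real_
    }
    is_area <- config$is_area * exp(rnorm(n, 0, 0.05))
    peak_table(areas, is_area, label)
  })
}

# The 15-molecule QC standard mix (organic acids, sugars, amino acids,
# steroids, fatty acids) with fixed expected IS-normalized areas.
standard_mix_reference <- function() {
  mol <- c("alanine", "valine", "leucine", "proline", "glycine",
           "lactic acid", "succinic acid", "citric acid", "malic acid",
           "glucose", "fructose", "sucrose", "palmitic acid",
           "stearic acid", "cholesterol")
  expected <- c(0.82, 0.61, 0.55, 0.47, 0.91, 1.24, 0.38, 0.52, 0.44,
                1.65, 1.12, 0.73, 0.96, 0.88, 0.29)
  setNames(expected, mol)
}

#' Split a cohort into analytical batches with QC injections
#'
#' Consecutive batches of at most `batch_size` samples, each carrying the four
#' quality-control injections that batch validation monitors: a solvent blank
#' (no peaks), a standard mix of 15 reference molecules with known expected
#' IS-normalized areas, a pooled sample (one cohort-level pool built from the
#' mean raw profile of `pool_n` randomly selected samples, re-injected per
#' batch), and a duplicate injection of one randomly chosen in-batch sample.
#' Small multiplicative log-normal noise emulates injection variability.
#'
#' @param table a raw [peak_table()].
#' @param batch_size samples per batch (default 25).
#' @param seed integer seed.
#' @param pool_n samples entering the pool (default 50, or all if fewer).
#' @param standard_noise,pooled_noise,duplicate_noise log-scale injection
#'   noise sd for the respective QC injections.
#' @return list of `batch_record` objects; each holds member profiles, the
#'   four QC profiles, and the duplicate's source sample id.
#' @export
generate_batches <- function(table, batch_size = 25, seed = 1L,
                             pool_n = 50, standard_noise = 0.01,
                             pooled_noise = 0.005, duplicate_noise = 0.01) {
  stopifnot(inherits(table, "peak_table"), nrow(table$areas) > 0,
            batch_size >= 1)
  withr::with_seed(seed, {
    n <- nrow(table$areas)
    idx <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
    std <- standard_mix_reference()
    pool_ids <- sample(n, min(pool_n, n))
    pool_base <- colMeans(table$areas[pool_ids, , drop = FALSE], na.rm = TRUE)
    pool_base[!is.finite(pool_base)] <- 0
    pool_is <- mean(table$is_area[pool_ids])

    lapply(seq_along(idx), function(b) {
      ii <- idx[[b]]
      dup_i <- ii[sample(length(ii), 1)]
      dup_profile <- table$areas[dup_i, ] *
        exp(rnorm(ncol(table$areas), 0, duplicate_noise))
      is_qc <- mean(table$is_area[ii])
      structure(list(
        batch_id = sprintf("B%02d", b),
        sample_ids = rownames(table$areas)[ii],
        profiles = table$areas[ii, , drop = FALSE],
        is_area = table$is_area[ii],
        blank = list(areas = setNames(numeric(ncol(table$areas)),
                                      colnames(table$areas)),
                     is_area = is_qc),
        standard = list(
          expected = std,
          areas = std * is_qc * exp(rnorm(length(std), 0, standard_noise)),
          is_area = is_qc),
        pooled = list(
          areas = pool_base * exp(rnorm(length(pool_base), 0, pooled_noise)),
          is_area = pool_is),
        duplicate = list(sample_id = rownames(table$areas)[dup_i],
                         areas = dup_profile,
                         original = table$areas[dup_i, ],
                         is_area = table$is_area[dup_i])
      ), class = "batch_record")
    })
  })
}

#' @export
print.batch_record <- function(x, ...) {
  cat("<batch_record> ", x$batch_id, ": ", length(x$sample_ids),
      " samples + 4 QC injections (duplicate of ", x$duplicate$sample_id,
      ")\n", sep = "")
  invisible(x)
}

#' Inject a targeted QC failure into a batch
#'
#' Produces a batch guaranteed to fail exactly one of the four acceptance
#' conditions when `magnitude` exceeds that condition's tolerance:
#' `blank_peak` adds a contaminating peak to the solvent blank;
#' `standard_drift` scales every standard-mix analyte by `1 + magnitude`;
#' `duplicate_variance` scales the duplicate injection by `1 + magnitude`
#' (top-100 relative deviation becomes exactly `magnitude`); `pooled_outlier`
#' displaces the pooled profile by `magnitude` times the per-feature spread of
#' the batch members (deviation score becomes about `magnitude`).
#'
#' @param batch a `batch_record`.
#' @param failure_mode one of `"blank_peak"`, `"standard_drift"`,
#'   `"duplicate_variance"`, `"pooled_outlier"`.
#' @param magnitude positive real; relative size of the induced fault.
#' @param seed integer seed (used only by `blank_peak` to pick the feature).
#' @return a modified `batch_record`.
#' @export
corrupt_batch <- function(batch, failure_mode, magnitude, seed = 1L) {
  stopifnot(inherits(batch, "batch_record"), magnitude > 0)
  failure_mode <- match.arg(failure_mode,
                            c("blank_peak", "standard_drift",
                              "duplicate_variance", "pooled_outlier"))
  withr::with_seed(seed, {
    switch(failure_mode,
      blank_peak = {
        j <- sample(length(batch$blank$areas), 1)
        batch$blank$areas[j] <- magnitude *
          median(batch$profiles, na.rm = TRUE)
      },
      standard_drift = {
        # replace injection noise with an exact drift so the max relative
        # deviation from the expected values equals `magnitude`
        batch$standard$areas <- batch$standard$expected *
          batch$standard$is_area * (1 + magnitude)
      },
      duplicate_variance = {
        batch$duplicate$areas <- batch$duplicate$original * (1 + magnitude)
      },
      pooled_outlier = {
        spread <- apply(batch$profiles, 2, sd, na.rm = TRUE)
        spread[!is.finite(spread)] <- 0
        # displace along the per-feature sd direction, scaled so the
        # normalized euclidean deviation score equals `magnitude`
        batch$pooled$areas <- batch$pooled$areas +
          magnitude * spread / batch$is_area[1] * batch$pooled$is_area
      })
    batch
  })
}

#' Write / read a peak table as CSV
#'
#' Layout: first column `sample_id`, then `label`, `is_area`, optional
#' `batch`, then one column per feature. Missing cells are empty.
#'
#' @param table a [peak_table()].
#' @param path file path.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a [peak_table()].
#' @export
write_peak_table <- function(table, path) {
  stopifnot(inherits(table, "peak_table"))
  df <- data.frame(sample_id = rownames(table$areas),
                   label = unname(table$label),
                   is_area = unname(table$is_area),
                   check.names = FALSE)
  if (!is.null(table$batch)) df$batch <- unname(table$batch)
  df <- cbind(df, as.data.frame(table$areas, check.names = FALSE))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_peak_table
#' @param normalized logical; mark the table as already IS-normalized.
#' @export
read_peak_table <- function(path, normalized = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  meta <- intersect(c("sample_id", "label", "is_area", "batch"), names(df))
  feats <- setdiff(names(df), meta)
  areas <- as.matrix(df[, feats, drop = FALSE])
  rownames(areas) <- df$sample_id
  peak_table(areas, df$is_area, df$label,
             batch = if ("batch" %in% meta) df$batch,
             normalized = normalized)
}

#' Read a cohort configuration from YAML
#'
#' @param path YAML file with fields matching [cohort_config()] arguments;
#'   `effect_features` as a list of `{feature, fold_change}` records.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$effect_features)) {
    y$effect_features <- do.call(rbind, lapply(y$effect_features, function(e) {
      data.frame(feature = e$feature, fold_change = e$fold_change,
                 stringsAsFactors = FALSE)
    }))
  }
  do.call(cohort_config, y)
}
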