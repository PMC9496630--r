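#' Normalize peak areas to the internal standard
#'
#' Divides every feature area by its sample's internal-standard peak area
#' (2-isopropyl malic acid in the assay this emulates). Missing cells stay
#' missing; the IS column itself is kept (all ones after normalization would
#' be redundant, so `is_area` is reset to 1).
#'
#' @param table a raw [peak_table()].
#' @return the IS-normalized [peak_table()] (`normalized = TRUE`).
#' @export
normalize_to_is <- function(table) {
  stopifnot(inherits(table, "peak_table"))
  if (table$normalized) return(table)
  areas <- sweep(table$areas, 1, table$is_area, "/")
  peak_table(areas, rep(1, nrow(areas)), table$label, batch = table$batch,
             normalized = TRUE)
}

#' Impute sporadic missing cells
#'
#' For features that survive the presence filter but still carry occasional
#' missing cells (e.g. in newly acquired samples), replaces each missing cell
#' per feature: `half_min` uses half the feature's minimum observed value (the
#' usual below-detection-limit surrogate), `feature_median` its median.
#' Features that are entirely missing cannot be imputed and raise an error.
#'
#' @param table an IS-normalized [peak_table()].
#' @param strategy `"half_min"` or `"feature_median"`.
#' @return list with `table` (complete [peak_table()]) and `n_imputed`.
#' @export
impute_missing <- function(table, strategy = c("half_min", "feature_median")) {
  stopifnot(inherits(table, "peak_table"))
  strategy <- match.arg(strategy)
  areas <- table$areas
  n_missing <- sum(is.na(areas))
  if (n_missing > 0) {
    all_na <- colSums(!is.na(areas)) == 0
    if (any(all_na)) {
      stop("cannot impute entirely-missing feature(s): ",
           paste(colnames(areas)[all_na], collapse = ", "))
    }
    fill <- apply(areas, 2, function(v) {
      switch(strategy,
             half_min = min(v, na.rm = TRUE) / 2,
             feature_median = median(v, na.rm = TRUE))
    })
    idx <- which(is.na(areas), arr.ind = TRUE)
    areas[idx] <- fill[idx[, 2]]
  }
  list(table = peak_table(areas, table$is_area, table$label,
                          batch = table$batch, normalized = table$normalized),
       n_imputed = n_missing)
}

#' Log-transform and autoscale a peak table
#'
#' Applies the natural log to the (IS-normalized, strictly positive) areas,
#' then autoscales each feature: mean-centred and divided by its standard
#' deviation (n-1 denominator). The per-feature mean and sd are computed on
#' the `fit_on` samples only and frozen, so held-out samples are transformed
#' with the training parameters. Features constant on `fit_on` (sd = 0) are
#' dropped with a warning.
#'
#' @param table a complete, IS-normalized [peak_table()].
#' @param fit_on sample ids (or indices / logical) defining the training set
#'   the parameters are estimated on; default all samples.
#' @return object of class `processed_matrix`: `x` (samples x features matrix
#'   of autoscaled log values), `label`, `params` (feature names, `center`,
#'   `scale`), `fit_on`, and provenance `flags`.
#' @export
log_and_autoscale <- function(table, fit_on = NULL) {
  stopifnot(inherits(table, "peak_table"))
  areas <- table$areas
  if (any(is.na(areas))) {
    stop("table has missing cells; apply impute_missing() (or drop the features) first")
  }
  if (any(areas <= 0)) stop("all areas must be strictly positive to take logs")
  samples <- rownames(areas)
  fit_ids <- if (is.null(fit_on)) samples else samples[match_samples(fit_on, samples)]
  if (length(fit_ids) == 0) stop("fit_on selects no samples")
  lx <- log(areas)
  center <- colMeans(lx[fit_ids, , drop = FALSE])
  scale <- apply(lx[fit_ids, , drop = FALSE], 2, sd)
  const <- scale == 0 | !is.finite(scale)
  if (any(const)) {
    warning("dropping ", sum(const), " feature(s) constant on the fitting set: ",
            paste(head(colnames(lx)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
    lx <- lx[, !const, drop = FALSE]
    center <- center[!const]
    scale <- scale[!const]
  }
  x <- sweep(sweep(lx, 2, center), 2, scale, "/")
  structure(
    list(x = x, label = table$label,
         params = list(features = colnames(lx), center = center, scale = scale),
         fit_on = fit_ids,
         flags = c(normalized = table$normalized, logged = TRUE,
                   autoscaled = TRUE)),
    class = "processed_matrix"
  )
}

match_samples <- function(sel, samples) {
  if (is.character(sel)) {
    i <- match(sel, samples)
    if (anyNA(i)) stop("unknown sample id(s) in fit_on")
    i
  } else if (is.logical(sel)) {
    which(sel)
  } else {
    as.integer(sel)
  }
}

#' @export
print.processed_matrix <- function(x, ...) {
  cat("<processed_matrix> ", nrow(x$x), " samples x ", ncol(x$x),
      " features (", paste(names(x$flags)[x$flags], collapse = " + "),
      "); fitted on ", length(x$fit_on), " samples\n", sep = "")
  invisible(x)
}

#' Apply frozen preprocessing parameters to new samples
#'
#' @param params the `params` element of a `processed_matrix` (or the object
#'   itself).
#' @param table a complete, IS-normalized [peak_table()] containing at least
#'   the fitted features.
#' @return autoscaled log matrix for the new samples, columns in fitted order.
#' @export
apply_autoscale <- function(params, table) {
  if (inherits(params, "processed_matrix")) params <- params$params
  stopifnot(inherits(table, "peak_table"))
  missing_feats <- setdiff(params$features, colnames(table$areas))
  if (length(missing_feats)) {
    stop("table lacks fitted feature(s): ",
         paste(head(missing_feats, 5), collapse = ", "))
  }
  a <- table$areas[, params$features, drop = FALSE]
  if (any(is.na(a)) || any(a <= 0)) {
    stop("new samples must be complete and strictly positive; impute first")
  }
  sweep(sweep(log(a), 2, params$center), 2, params$scale, "/")
}

#' Invert the autoscale + log transform
#'
#' @param params fitted parameters (see [apply_autoscale()]).
#' @param x autoscaled matrix with the fitted features as columns.
#' @return matrix of IS-normalized areas on the original scale.
#' @export
invert_autoscale <- function(params, x) {
  if (inherits(params, "processed_matrix")) params <- params$params
  exp(sweep(sweep(x[, params$features, drop = FALSE], 2, params$scale, "*"),
            2, params$center, "+"))
}

#' Serialize a processed matrix (CSV + JSON sidecar)
#'
#' @param pm a `processed_matrix`.
#' @param path CSV path for the matrix; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_processed_matrix <- function(pm, path) {
  stopifnot(inherits(pm, "processed_matrix"))
  df <- data.frame(sample_id = rownames(pm$x), label = unname(pm$label),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(pm$x, check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(features = pm$params$features,
         center = unname(pm$params$center),
         scale = unname(pm$params$scale),
         fit_on = pm$fit_on, flags = as.list(pm$flags)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
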