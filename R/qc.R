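# Pooled-QC injections monitor the instrument, not the cohort: they are
# excluded from feature missing-rate and outlier statistics, but carried
# through filters and imputation so normalization can still use them.
study_mask <- function(ms, qc_col = "qc") {
  s <- ms$samples
  if (qc_col %in% names(s) && is.logical(s[[qc_col]])) !(s[[qc_col]] %in% TRUE)
  else rep(TRUE, nrow(s))
}

#' Missing rates per feature and per sample
#'
#' Feature rates are computed over study (non-QC) samples only; sample rates
#' over all features. A sample is a QC injection when the logical column named
#' by `qc_col` is `TRUE`.
#'
#' @param ms A `metabolite_set`.
#' @param qc_col Name of the logical QC-flag column in the sample table;
#'   ignored when absent.
#' @return A list of two tibbles: `features` (`feature_id`, `missing_rate`) and
#'   `samples` (`sample_id`, `missing_rate`); rates in \[0, 1\].
#' @export
missing_rates <- function(ms, qc_col = "qc") {
  stopifnot(is_metabolite_set(ms))
  a <- ms$assay
  st <- study_mask(ms, qc_col)
  fr <- if (any(st)) colMeans(is.na(a[st, , drop = FALSE])) else
    stats::setNames(rep(0, ncol(a)), colnames(a))
  sr <- rowMeans(is.na(a))
  list(features = tibble::tibble(feature_id = colnames(a), missing_rate = unname(fr)),
       samples = tibble::tibble(sample_id = rownames(a), missing_rate = unname(sr)))
}

#' Filter features (metabolites) by missing rate
#'
#' Removes features whose missing rate among study samples is **strictly
#' greater** than `threshold`: a feature missing in exactly half the samples
#' survives the default `threshold = 0.5`. Values of surviving features are
#' untouched.
#'
#' @inheritParams missing_rates
#' @param threshold Missing-rate cutoff in \[0, 1\]; default 0.5.
#' @return A new `metabolite_set`; removed IDs are recorded in the log.
#' @export
filter_features_by_missing <- function(ms, threshold = 0.5, qc_col = "qc") {
  stopifnot(is_metabolite_set(ms), threshold >= 0, threshold <= 1)
  rates <- missing_rates(ms, qc_col)$features
  drop <- rates$feature_id[rates$missing_rate > threshold]
  keep <- setdiff(rates$feature_id, drop)
  if (!length(keep)) warning("All features removed by the missing-rate filter.")
  out <- ms
  out$assay <- ms$assay[, match(keep, colnames(ms$assay)), drop = FALSE]
  out$features <- ms$features[match(keep, ms$features$feature_id), , drop = FALSE]
  append_log(out, "filter_features_by_missing",
             params = list(threshold = threshold),
             counts = list(removed = length(drop),
                           removed_ids = as.list(utils::head(drop, 50))))
}

#' Filter samples by missing rate
#'
#' Mirror of [filter_features_by_missing()] along the sample axis (strict
#' inequality; rate computed over all features). QC injections are subject to
#' their own rate like any other row.
#'
#' @inheritParams filter_features_by_missing
#' @return A new `metabolite_set`.
#' @export
filter_samples_by_missing <- function(ms, threshold = 0.5) {
  stopifnot(is_metabolite_set(ms), threshold >= 0, threshold <= 1)
  sr <- rowMeans(is.na(ms$assay))
  drop <- rownames(ms$assay)[sr > threshold]
  keep <- setdiff(rownames(ms$assay), drop)
  if (!length(keep)) warning("All samples removed by the missing-rate filter.")
  out <- ms
  out$assay <- ms$assay[match(keep, rownames(ms$assay)), , drop = FALSE]
  out$samples <- ms$samples[match(keep, ms$samples$sample_id), , drop = FALSE]
  append_log(out, "filter_samples_by_missing",
             params = list(threshold = threshold),
             counts = list(removed = length(drop),
                           removed_ids = as.list(utils::head(drop, 50))))
}

#' Detect extreme values per feature
#'
#' For each feature, the mean and sample (n-1) SD are computed over non-missing
#' study-sample values; an entry is flagged iff `|x - mean| > k_sd * sd`.
#' Features with fewer than 3 observed values or zero SD produce no flags, and
#' QC-injection entries are never flagged. Detection operates on values as
#' given — no implicit log; transform first for log-scale detection.
#'
#' @inheritParams missing_rates
#' @param k_sd Number of SDs defining an outlier (default 5).
#' @return A logical samples-x-features matrix of class `outlier_mask` carrying
#'   the per-feature detection statistics (`center`, `spread`, `k_sd`) as
#'   attributes, for consistent winsorization by [handle_outliers()].
#' @export
detect_outliers <- function(ms, k_sd = 5, qc_col = "qc") {
  stopifnot(is_metabolite_set(ms), k_sd > 0)
  a <- ms$assay
  st <- study_mask(ms, qc_col)
  sub <- a[st, , drop = FALSE]
  n_obs <- colSums(!is.na(sub))
  mu <- colMeans(sub, na.rm = TRUE)
  sigma <- apply(sub, 2, stats::sd, na.rm = TRUE)
  usable <- n_obs >= 3 & !is.na(sigma) & sigma > 0
  mask <- matrix(FALSE, nrow(a), ncol(a), dimnames = dimnames(a))
  if (any(usable)) {
    dev <- abs(sweep(a[, usable, drop = FALSE], 2, mu[usable], "-"))
    lim <- rep(k_sd * sigma[usable], each = nrow(a))
    flags <- dev > lim & !is.na(a[, usable, drop = FALSE])
    flags[!st, ] <- FALSE
    mask[, usable] <- flags
  }
  mu[!usable] <- NA_real_; sigma[!usable] <- NA_real_
  structure(mask, class = c("outlier_mask", class(mask)),
            center = mu, spread = sigma, k_sd = k_sd)
}

#' Replace or winsorize flagged outliers
#'
#' `action = "to_missing"` turns flagged entries into missing values.
#' `action = "winsorize"` clamps each flagged entry to the detection boundary
#' `center ± k_sd * spread` on the side of the excursion, using the statistics
#' of the detection pass (carried on the mask; recomputed from `ms` if a plain
#' logical matrix is supplied, which is only equivalent when `ms` is the set
#' the mask was computed from).
#'
#' @param ms A `metabolite_set`.
#' @param mask Logical samples-x-features matrix, ideally from
#'   [detect_outliers()].
#' @param action `"winsorize"` or `"to_missing"`.
#' @param k_sd Used only when `mask` lacks detection statistics.
#' @param qc_col See [missing_rates()].
#' @return A new `metabolite_set`; per-feature replacement counts in the log.
#' @export
handle_outliers <- function(ms, mask, action = c("winsorize", "to_missing"),
                            k_sd = 5, qc_col = "qc") {
  stopifnot(is_metabolite_set(ms))
  action <- match.arg(action)
  if (!is.logical(mask) || !identical(dim(mask), dim(ms$assay))) {
    stop("`mask` must be a logical matrix with the assay's dimensions.", call. = FALSE)
  }
  if (is.null(attr(mask, "center"))) {
    ref <- detect_outliers(ms, k_sd = k_sd, qc_col = qc_col)
    flags <- unclass(mask) # honour the caller's flags, borrow the statistics
    mask <- ref
    mask[] <- flags
  }
  mu <- attr(mask, "center"); sigma <- attr(mask, "spread")
  k <- attr(mask, "k_sd")
  a <- ms$assay
  idx <- which(unclass(mask), arr.ind = TRUE)
  n_per_feature <- colSums(unclass(mask))
  if (nrow(idx)) {
    if (action == "to_missing") {
      a[idx] <- NA_real_
    } else {
      j <- idx[, 2]
      x <- a[idx]
      hi <- mu[j] + k * sigma[j]
      lo <- mu[j] - k * sigma[j]
      a[idx] <- ifelse(x > hi, hi, ifelse(x < lo, lo, x))
    }
  }
  out <- ms
  out$assay <- a
  append_log(out, "handle_outliers",
             params = list(action = action, k_sd = k),
             counts = list(n_replaced = nrow(idx),
                           per_feature = as.list(n_per_feature[n_per_feature > 0])))
}

#' Impute missing values
#'
#' Per-feature imputation of missing entries; observed values are never
#' modified. Methods:
#' \describe{
#'   \item{half_min}{half the feature's minimum observed value — a proxy for
#'     below-detection-limit censoring.}
#'   \item{median}{the feature's observed median.}
#'   \item{zero}{0.}
#'   \item{knn}{feature-neighbour averaging: features are standardized
#'     (observed mean 0, SD 1); the distance between two features is the
#'     root-mean-square difference of their standardized values over samples
#'     where both are observed (no overlap = not a neighbour); a missing entry
#'     (i, j) takes the average of the standardized values at sample i of the
#'     `knn_k` nearest features having an observed value there, back-transformed
#'     to feature j's scale. Entries with no qualifying neighbour fall back to
#'     the feature median.}
#' }
#' Fully-missing features cannot be imputed; they remain missing and are
#' reported in the log.
#'
#' @param ms A `metabolite_set`.
#' @param method One of `"half_min"`, `"median"`, `"zero"`, `"knn"`.
#' @param knn_k Number of neighbouring features averaged (default 10).
#' @return A new `metabolite_set`.
#' @export
impute_missing <- function(ms, method = c("half_min", "median", "zero", "knn"),
                           knn_k = 10) {
  stopifnot(is_metabolite_set(ms))
  method <- match.arg(method)
  a <- ms$assay
  miss <- is.na(a)
  n_obs <- colSums(!miss)
  all_missing <- colnames(a)[n_obs == 0]
  if (method == "knn") {
    if (ncol(a) < 2) stop("KNN imputation needs at least 2 features.", call. = FALSE)
    stopifnot(knn_k >= 1)
    a <- knn_impute_matrix(a, knn_k)
  } else {
    fill <- switch(method,
      half_min = apply(a, 2, function(x) suppressWarnings(min(x, na.rm = TRUE)) / 2),
      median = apply(a, 2, stats::median, na.rm = TRUE),
      zero = rep(0, ncol(a))
    )
    for (j in which(n_obs > 0 | method == "zero")) {
      a[miss[, j], j] <- fill[j]
    }
  }
  out <- ms
  out$assay <- a
  append_log(out, "impute_missing",
             params = list(method = method,
                           knn_k = if (method == "knn") knn_k else NULL),
             counts = list(n_imputed = sum(miss) - sum(is.na(a)),
                           all_missing_features = as.list(all_missing)))
}

# KNN by feature-neighbour averaging on standardized values; vectorized over
# features, O(p^2) distances.
knn_impute_matrix <- function(a, k) {
  p <- ncol(a); n <- nrow(a)
  mu <- colMeans(a, na.rm = TRUE)
  sigma <- apply(a, 2, stats::sd, na.rm = TRUE)
  sigma_use <- ifelse(is.na(sigma) | sigma == 0, 1, sigma)
  z <- sweep(sweep(a, 2, mu, "-"), 2, sigma_use, "/")
  obs <- !is.na(z)
  z0 <- z; z0[!obs] <- 0
  # pairwise RMS distance over co-observed samples
  co <- crossprod(obs) # overlap counts
  ss <- crossprod(z0^2, obs) + crossprod(obs, z0^2) - 2 * crossprod(z0)
  d <- sqrt(pmax(ss, 0) / ifelse(co > 0, co, NA))
  diag(d) <- NA
  med <- apply(a, 2, stats::median, na.rm = TRUE)
  out <- a
  for (j in seq_len(p)) {
    mi <- which(is.na(a[, j]))
    if (!length(mi)) next
    if (all(is.na(a[, j]))) next # fully missing: stays missing
    ord <- order(d[, j], na.last = NA) # candidate neighbours, nearest first
    for (i in mi) {
      cand <- ord[obs[i, ord]]
      cand <- utils::head(cand, k)
      if (length(cand)) {
        out[i, j] <- mu[j] + mean(z[i, cand]) * sigma_use[j]
      } else {
        out[i, j] <- med[j]
      }
    }
  }
  out
}

#' QC parameter bundle
#'
#' Defaults follow standard practice for non-targeted MS peak-area data:
#' missing-rate cutoffs of 0.5 on both axes, +/-5 SD outlier detection with
#' winsorization, half-minimum imputation.
#'
#' @param feature_missing_threshold,sample_missing_threshold Missing-rate
#'   cutoffs in \[0, 1\] (strict-inequality removal).
#' @param outlier_sd SD multiple defining outliers.
#' @param outlier_action `"winsorize"`, `"to_missing"` or `"none"`.
#' @param impute_method `"half_min"`, `"median"`, `"zero"`, `"knn"` or `"none"`.
#' @param knn_k Neighbours for KNN imputation.
#' @return A `qc_params` list.
#' @export
qc_params <- function(feature_missing_threshold = 0.5,
                      sample_missing_threshold = 0.5,
                      outlier_sd = 5,
                      outlier_action = c("winsorize", "to_missing", "none"),
                      impute_method = c("half_min", "median", "zero", "knn", "none"),
                      knn_k = 10) {
  outlier_action <- match.arg(outlier_action)
  impute_method <- match.arg(impute_method)
  stopifnot(feature_missing_threshold >= 0, feature_missing_threshold <= 1,
            sample_missing_threshold >= 0, sample_missing_threshold <= 1,
            outlier_sd > 0, knn_k >= 1)
  structure(list(feature_missing_threshold = feature_missing_threshold,
                 sample_missing_threshold = sample_missing_threshold,
                 outlier_sd = outlier_sd, outlier_action = outlier_action,
                 impute_method = impute_method, knn_k = as.integer(knn_k)),
            class = "qc_params")
}

#' One-call quality-control pipeline
#'
#' Applies, in order: feature missing-rate filter, sample missing-rate filter,
#' outlier detection + handling, imputation — each step identical to (and
#' logged like) its standalone function, so the pipeline equals the manual
#' composition of the four operations.
#'
#' @param ms A `metabolite_set`.
#' @param params A [qc_params()] bundle.
#' @param qc_col Logical QC-flag column name (see [missing_rates()]).
#' @return A list of class `qc_result`: `set` (the processed `metabolite_set`)
#'   and `report` (a `qc_report`: per-axis missing rates, removed IDs, outlier
#'   counts, imputation summary).
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 60, n_features = 8,
#'                                             n_batches = 2, seed = 3))
#' res <- qc_pipeline(sim$set)
#' res$report
#' @export
qc_pipeline <- function(ms, params = qc_params(), qc_col = "qc") {
  stopifnot(is_metabolite_set(ms), inherits(params, "qc_params"))
  rates0 <- missing_rates(ms, qc_col)
  out <- filter_features_by_missing(ms, params$feature_missing_threshold, qc_col)
  removed_features <- setdiff(colnames(ms$assay), colnames(out$assay))
  out2 <- filter_samples_by_missing(out, params$sample_missing_threshold)
  removed_samples <- setdiff(rownames(out$assay), rownames(out2$assay))
  out <- out2

  outlier_counts <- tibble::tibble(feature_id = colnames(out$assay),
                                   n_outliers = 0L)
  if (params$outlier_action != "none") {
    mask <- detect_outliers(out, k_sd = params$outlier_sd, qc_col = qc_col)
    outlier_counts$n_outliers <- unname(colSums(unclass(mask)))
    out <- handle_outliers(out, mask, action = params$outlier_action,
                           qc_col = qc_col)
  }

  n_missing_before <- sum(is.na(out$assay))
  if (params$impute_method != "none") {
    out <- impute_missing(out, method = params$impute_method, knn_k = params$knn_k)
  }
  n_imputed <- n_missing_before - sum(is.na(out$assay))

  report <- structure(list(
    feature_missing = rates0$features,
    sample_missing = rates0$samples,
    removed_features = removed_features,
    removed_samples = removed_samples,
    outlier_action = params$outlier_action,
    outlier_counts = outlier_counts,
    impute_method = params$impute_method,
    n_imputed = n_imputed,
    params = params
  ), class = "qc_report")
  structure(list(set = out, report = report), class = "qc_result")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  features removed (missing rate): %d\n", length(x$removed_features)))
  cat(sprintf("  samples removed (missing rate): %d\n", length(x$removed_samples)))
  cat(sprintf("  outlier action: %s (%d entries flagged)\n", x$outlier_action,
              sum(x$outlier_counts$n_outliers)))
  cat(sprintf("  imputation: %s (%d entries imputed)\n", x$impute_method, x$n_imputed))
  invisible(x)
}

#' Tidy a QC report
#'
#' @param x A `qc_report` from [qc_pipeline()].
#' @param ... Unused.
#' @return A tibble with one row per feature: missing rate, whether removed,
#'   outlier count.
#' @method tidy qc_report
#' @export
tidy.qc_report <- function(x, ...) {
  dplyr::left_join(
    dplyr::mutate(x$feature_missing,
                  removed = .data$feature_id %in% x$removed_features),
    x$outlier_counts, by = "feature_id"
  ) |>
    dplyr::mutate(n_outliers = dplyr::coalesce(.data$n_outliers, 0L))
}

#' Plot per-feature and per-sample missing rates
#'
#' @param ms A `metabolite_set`.
#' @param qc_col Logical QC-flag column name.
#' @return A ggplot: histograms of missing rates on both axes.
#' @export
plot_missing_rates <- function(ms, qc_col = "qc") {
  r <- missing_rates(ms, qc_col)
  df <- dplyr::bind_rows(
    tibble::tibble(axis = "features", rate = r$features$missing_rate),
    tibble::tibble(axis = "samples", rate = r$samples$missing_rate)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "grey20") +
    ggplot2::facet_wrap(~axis, scales = "free_y") +
    ggplot2::labs(x = "missing rate", y = "count") +
    ggplot2::theme_minimal()
}
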