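# Shared block iterator: per-(feature, batch) cells of the assay.
batch_levels <- function(ms, batch_col) {
  if (!batch_col %in% names(ms$samples)) {
    stop(sprintf("Sample table has no '%s' column.", batch_col), call. = FALSE)
  }
  as.character(ms$samples[[batch_col]])
}

#' Batch-median normalization
#'
#' Divides each feature's values, batch by batch, by the median of that
#' feature's non-missing **study-sample** values in the batch, setting the
#' per-(feature, batch) study median to one. QC injections are divided by the
#' same divisor (they ride along) but do not contribute to it, so repeated
#' pooled-QC injections cannot bias the batch medians. Blocks whose median is
#' undefined (all missing) or non-positive are left unchanged with a warning
#' recorded in the log.
#'
#' @param ms A `metabolite_set` on the raw (positive) scale.
#' @param batch_col Sample-table column with batch labels.
#' @param qc_col Logical QC-flag column (ignored when absent).
#' @return A new `metabolite_set` with per-batch medians scaled to 1.
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 40, n_features = 4,
#'                                             n_batches = 2, seed = 2))
#' norm <- batch_norm(sim$set)
#' @export
batch_norm <- function(ms, batch_col = "batch", qc_col = "qc") {
  stopifnot(is_metabolite_set(ms))
  batches <- batch_levels(ms, batch_col)
  st <- study_mask(ms, qc_col)
  a <- ms$assay
  n_warn <- 0L
  for (b in unique(batches)) {
    rows <- batches == b
    sub <- a[rows & st, , drop = FALSE]
    m <- apply(sub, 2, stats::median, na.rm = TRUE)
    ok <- !is.na(m) & m > 0
    n_warn <- n_warn + sum(!ok)
    if (any(ok)) {
      a[rows, ok] <- sweep(a[rows, ok, drop = FALSE], 2, m[ok], "/")
    }
  }
  if (n_warn > 0) {
    warning(sprintf("%d (feature, batch) block(s) had no valid median and were left unchanged.",
                    n_warn))
  }
  out <- ms
  out$assay <- a
  append_log(out, "batch_norm", params = list(batch_col = batch_col),
             counts = list(n_unchanged_blocks = n_warn))
}

#' Pooled-QC-sample normalization
#'
#' Like [batch_norm()], but the per-(feature, batch) divisor is the median of
#' the **QC-sample** values (pooled study reference or commercial standard), so
#' the QC median becomes one in each batch. Blocks with no observed QC value
#' fall back to unchanged with a warning.
#'
#' @inheritParams batch_norm
#' @return A new `metabolite_set`.
#' @export
qcmatrix_norm <- function(ms, batch_col = "batch", qc_col = "qc") {
  stopifnot(is_metabolite_set(ms))
  batches <- batch_levels(ms, batch_col)
  st <- study_mask(ms, qc_col)
  if (all(st)) stop("No QC samples in the set (logical QC column required).",
                    call. = FALSE)
  a <- ms$assay
  n_warn <- 0L
  for (b in unique(batches)) {
    rows <- batches == b
    qcsub <- a[rows & !st, , drop = FALSE]
    m <- if (nrow(qcsub)) apply(qcsub, 2, stats::median, na.rm = TRUE)
         else rep(NA_real_, ncol(a))
    ok <- !is.na(m) & m > 0
    n_warn <- n_warn + sum(!ok)
    if (any(ok)) {
      a[rows, ok] <- sweep(a[rows, ok, drop = FALSE], 2, m[ok], "/")
    }
  }
  if (n_warn > 0) {
    warning(sprintf("%d (feature, batch) block(s) lacked observed QC values and were left unchanged.",
                    n_warn))
  }
  out <- ms
  out$assay <- a
  append_log(out, "qcmatrix_norm", params = list(batch_col = batch_col),
             counts = list(n_unchanged_blocks = n_warn))
}

#' Nearest-QC-sample normalization
#'
#' Each value is divided by the corresponding feature's value in the QC
#' injection **nearest in run order** within the same batch (ties broken
#' toward the earlier injection; QC injections with a missing value are
#' skipped in favour of the next nearest). The block is then rescaled so the
#' per-(feature, batch) study median is one, for comparability with
#' [batch_norm()] and [qcmatrix_norm()]. Samples with no usable QC value in
#' their batch are left unchanged with a warning.
#'
#' @inheritParams batch_norm
#' @param runorder_col Sample-table column with integer injection order.
#' @return A new `metabolite_set`.
#' @export
nearest_qc_norm <- function(ms, batch_col = "batch", qc_col = "qc",
                            runorder_col = "run_order") {
  stopifnot(is_metabolite_set(ms))
  batches <- batch_levels(ms, batch_col)
  if (!runorder_col %in% names(ms$samples)) {
    stop(sprintf("Sample table has no '%s' column.", runorder_col), call. = FALSE)
  }
  st <- study_mask(ms, qc_col)
  if (all(st)) stop("No QC samples in the set (logical QC column required).",
                    call. = FALSE)
  ro <- as.numeric(ms$samples[[runorder_col]])
  a <- ms$assay
  out_a <- a
  n_warn <- 0L
  for (b in unique(batches)) {
    rows <- which(batches == b)
    qrows <- rows[!st[rows]]
    for (j in seq_len(ncol(a))) {
      qobs <- qrows[!is.na(a[qrows, j])]
      if (!length(qobs)) { n_warn <- n_warn + 1L; next }
      ratio <- rep(NA_real_, length(rows))
      for (ii in seq_along(rows)) {
        i <- rows[ii]
        if (is.na(a[i, j])) next
        dist <- abs(ro[qobs] - ro[i])
        # nearest; ties -> earlier run order
        best <- qobs[order(dist, ro[qobs])][1]
        ratio[ii] <- a[i, j] / a[best, j]
      }
      srows <- st[rows]
      med <- stats::median(ratio[srows], na.rm = TRUE)
      if (is.na(med) || med <= 0) med <- 1
      out_a[rows, j] <- ifelse(is.na(ratio), a[rows, j], ratio / med)
    }
  }
  if (n_warn > 0) {
    warning(sprintf("%d (feature, batch) block(s) lacked usable QC values and were left unchanged.",
                    n_warn))
  }
  out <- ms
  out$assay <- out_a
  append_log(out, "nearest_qc_norm",
             params = list(batch_col = batch_col, runorder_col = runorder_col),
             counts = list(n_unchanged_blocks = n_warn))
}

#' LOESS run-order drift correction
#'
#' Per (feature, batch): a locally weighted regression (degree 1, tricube
#' weights, `span`) is fitted to the **log** QC values against run order; the
#' fitted drift curve is predicted at every sample's run order (linear
#' extrapolation beyond the QC range from the boundary local fits) and divided
#' out as `x / exp(d(t) - median(d at QC positions))`, flattening the QC trend
#' while preserving each batch's QC median. Operating on the log scale keeps
#' the correction multiplicative and the output positive. Blocks with fewer
#' than 4 observed QC values fall back to the [qcmatrix_norm()] divisor for
#' that block, recorded in the log.
#'
#' @inheritParams nearest_qc_norm
#' @param span LOESS span in (0, 1\]; default 0.75.
#' @return A new `metabolite_set`.
#' @export
loess_norm <- function(ms, batch_col = "batch", qc_col = "qc",
                       runorder_col = "run_order", span = 0.75) {
  stopifnot(is_metabolite_set(ms), span > 0, span <= 1)
  batches <- batch_levels(ms, batch_col)
  if (!runorder_col %in% names(ms$samples)) {
    stop(sprintf("Sample table has no '%s' column.", runorder_col), call. = FALSE)
  }
  st <- study_mask(ms, qc_col)
  if (all(st)) stop("No QC samples in the set (logical QC column required).",
                    call. = FALSE)
  a <- ms$assay
  if (any(a[!is.na(a)] <= 0)) {
    stop("Non-positive values present; LOESS drift correction works on the raw positive scale - normalize before log-transforming.",
         call. = FALSE)
  }
  ro <- as.numeric(ms$samples[[runorder_col]])
  n_fallback <- 0L
  for (b in unique(batches)) {
    rows <- which(batches == b)
    qrows <- rows[!st[rows]]
    for (j in seq_len(ncol(a))) {
      qobs <- qrows[!is.na(a[qrows, j])]
      if (length(qobs) < 4) {
        # too few QC points for a local fit: constant QC-median correction
        n_fallback <- n_fallback + 1L
        m <- stats::median(a[qobs, j])
        if (length(qobs) && !is.na(m) && m > 0) a[rows, j] <- a[rows, j] / m
        next
      }
      t_q <- ro[qobs]
      fit <- stats::loess(log(a[qobs, j]) ~ t_q, span = span, degree = 1,
                          family = "gaussian",
                          control = stats::loess.control(surface = "direct"))
      d <- predict_loess_extrap(fit, t_q, ro[rows])
      d_qc <- predict_loess_extrap(fit, t_q, t_q)
      a[rows, j] <- a[rows, j] / exp(d - stats::median(d_qc))
    }
  }
  if (n_fallback > 0) {
    warning(sprintf("%d (feature, batch) block(s) had < 4 observed QC values; fell back to QC-median scaling.",
                    n_fallback))
  }
  out <- ms
  out$assay <- a
  append_log(out, "loess_norm",
             params = list(batch_col = batch_col, runorder_col = runorder_col,
                           span = span),
             counts = list(n_fallback_blocks = n_fallback))
}

# predict with linear extrapolation beyond the fitted range, using the slope
# of the boundary local fits
predict_loess_extrap <- function(fit, t_fit, t_new) {
  lo <- min(t_fit); hi <- max(t_fit)
  inside <- pmin(pmax(t_new, lo), hi)
  d <- stats::predict(fit, newdata = data.frame(t_q = inside))
  h <- max((hi - lo) * 1e-3, 1e-8)
  slope_lo <- (stats::predict(fit, data.frame(t_q = lo + h)) -
               stats::predict(fit, data.frame(t_q = lo))) / h
  slope_hi <- (stats::predict(fit, data.frame(t_q = hi)) -
               stats::predict(fit, data.frame(t_q = hi - h))) / h
  below <- t_new < lo; above <- t_new > hi
  d[below] <- d[below] + slope_lo * (t_new[below] - lo)
  d[above] <- d[above] + slope_hi * (t_new[above] - hi)
  unname(d)
}
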