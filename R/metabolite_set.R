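#' The `metabolite_set` container
#'
#' A `metabolite_set` bundles everything one metabolomics experiment needs to
#' travel through a preprocessing and analysis pipeline:
#'
#' * **assay** — a numeric matrix of measurements (e.g. peak areas), samples in
#'   rows, metabolites in columns. Missing values are `NA`, never a sentinel
#'   number: zero imputation and missingness are distinct states.
#' * **features** — a tibble of metabolite annotations keyed by `feature_id`
#'   (one row per assay column, same order).
#' * **samples** — a tibble of sample annotations keyed by `sample_id`
#'   (one row per assay row, same order). Typical columns: batch label,
#'   integer run (injection) order, a logical pooled-QC flag, phenotypes.
#' * **log** — an append-only audit trail; every operation that returns a
#'   modified set appends exactly one entry (timestamp, operation, parameters,
#'   summary counts).
#' * **misc** — a free-form named list for ancillary data.
#'
#' Sets are immutable by convention: operations return new sets, so the log is
#' a faithful history of how the data in hand were produced.
#'
#' @param assay Numeric matrix, samples in rows and metabolites in columns.
#'   Row names are sample IDs and column names are feature IDs; both are
#'   required unless the corresponding annotation table supplies them (in which
#'   case dimnames are taken from the tables by position).
#' @param features Optional tibble/data frame with a `feature_id` column, one
#'   row per assay column. If `NULL`, a minimal table holding only the IDs is
#'   created.
#' @param samples Optional tibble/data frame with a `sample_id` column, one row
#'   per assay row. If `NULL`, a minimal table holding only the IDs is created.
#' @param misc Optional named list of ancillary data.
#'
#' @details Annotation tables are keyed, not positional: their rows are
#'   reordered to match the assay's dimnames at construction. Unknown, missing
#'   or duplicated IDs are a validation error naming the offending IDs (first
#'   10 shown).
#'
#' @return A validated `metabolite_set` with one initial log entry recording
#'   dimensions and missing-value count.
#' @examples
#' m <- matrix(rlnorm(12), 4, 3,
#'             dimnames = list(paste0("S", 1:4), paste0("M", 1:3)))
#' ms <- metabolite_set(m)
#' ms
#' @export
metabolite_set <- function(assay, features = NULL, samples = NULL, misc = list()) {
  if (!is.matrix(assay) || !is.numeric(assay)) {
    stop("`assay` must be a numeric matrix (samples x metabolites).", call. = FALSE)
  }
  if (is.null(rownames(assay))) {
    if (!is.null(samples)) rownames(assay) <- as.character(samples[["sample_id"]])
    else rownames(assay) <- paste0("sample_", seq_len(nrow(assay)))
  }
  if (is.null(colnames(assay))) {
    if (!is.null(features)) colnames(assay) <- as.character(features[["feature_id"]])
    else colnames(assay) <- paste0("feature_", seq_len(ncol(assay)))
  }
  if (is.null(features)) features <- tibble::tibble(feature_id = colnames(assay))
  if (is.null(samples)) samples <- tibble::tibble(sample_id = rownames(assay))
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)

  ms <- structure(
    list(assay = assay, features = features, samples = samples,
         log = list(), misc = misc),
    class = "metabolite_set"
  )
  ms <- validate_metabolite_set(ms)
  append_log(ms, "metabolite_set",
             params = list(),
             counts = list(n_samples = nrow(assay), n_features = ncol(assay),
                           n_missing = sum(is.na(assay))))
}

#' @rdname metabolite_set
#' @param x Object to test.
#' @export
is_metabolite_set <- function(x) inherits(x, "metabolite_set")

# ---- validation --------------------------------------------------------------

id_preview <- function(ids) {
  shown <- utils::head(ids, 10)
  out <- paste(shown, collapse = ", ")
  if (length(ids) > 10) out <- paste0(out, ", ... (", length(ids), " total)")
  out
}

check_key <- function(ids, what) {
  ids <- as.character(ids)
  bad <- is.na(ids) | !nzchar(ids)
  if (any(bad)) {
    stop(sprintf("%s IDs must be non-empty: %d empty/NA entries.", what, sum(bad)),
         call. = FALSE)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop(sprintf("Duplicate %s IDs: %s", what, id_preview(dup)), call. = FALSE)
  }
  ids
}

#' Validate a `metabolite_set`
#'
#' Checks the cross-key invariants (assay dimnames vs annotation keys, unique
#' non-empty IDs) and reorders annotation rows to assay order. Called by every
#' constructor-like operation; exported for defensive use after manual surgery
#' on a set's components.
#'
#' @param ms A `metabolite_set`.
#' @return The validated set (annotation rows aligned to assay order).
#' @export
validate_metabolite_set <- function(ms) {
  stopifnot(is_metabolite_set(ms))
  assay <- ms$assay
  if (!"feature_id" %in% names(ms$features)) {
    stop("`features` must have a `feature_id` column.", call. = FALSE)
  }
  if (!"sample_id" %in% names(ms$samples)) {
    stop("`samples` must have a `sample_id` column.", call. = FALSE)
  }
  fid <- check_key(ms$features$feature_id, "feature")
  sid <- check_key(ms$samples$sample_id, "sample")
  check_key(colnames(assay), "assay column")
  check_key(rownames(assay), "assay row")

  miss_f <- setdiff(colnames(assay), fid)
  if (length(miss_f)) {
    stop(sprintf("Assay columns missing from the feature table: %s",
                 id_preview(miss_f)), call. = FALSE)
  }
  extra_f <- setdiff(fid, colnames(assay))
  if (length(extra_f)) {
    stop(sprintf("Feature table rows absent from the assay: %s",
                 id_preview(extra_f)), call. = FALSE)
  }
  miss_s <- setdiff(rownames(assay), sid)
  if (length(miss_s)) {
    stop(sprintf("Assay rows missing from the sample table: %s",
                 id_preview(miss_s)), call. = FALSE)
  }
  extra_s <- setdiff(sid, rownames(assay))
  if (length(extra_s)) {
    stop(sprintf("Sample table rows absent from the assay: %s",
                 id_preview(extra_s)), call. = FALSE)
  }
  ms$features <- ms$features[match(colnames(assay), fid), , drop = FALSE]
  ms$samples <- ms$samples[match(rownames(assay), sid), , drop = FALSE]
  ms
}

# ---- log ---------------------------------------------------------------------

append_log <- function(ms, op, params = list(), counts = list()) {
  entry <- list(
    time = format(Sys.time(), "%Y-%m-%d %H:%M:%OS3", tz = "UTC"),
    op = op,
    params = params,
    counts = counts
  )
  ms$log <- c(ms$log, list(entry))
  ms
}

# ---- accessors ---------------------------------------------------------------

#' Accessors for `metabolite_set` components
#'
#' @param ms A `metabolite_set`.
#' @return `assay_values()` the numeric matrix; `feature_data()` and
#'   `sample_data()` annotation tibbles; `processing_log()` the list of log
#'   entries; `misc_data()` the ancillary list.
#' @name accessors
NULL

#' @rdname accessors
#' @export
assay_values <- function(ms) { stopifnot(is_metabolite_set(ms)); ms$assay }

#' @rdname accessors
#' @export
feature_data <- function(ms) { stopifnot(is_metabolite_set(ms)); ms$features }

#' @rdname accessors
#' @export
sample_data <- function(ms) { stopifnot(is_metabolite_set(ms)); ms$samples }

#' @rdname accessors
#' @export
processing_log <- function(ms) { stopifnot(is_metabolite_set(ms)); ms$log }

#' @rdname accessors
#' @export
misc_data <- function(ms) { stopifnot(is_metabolite_set(ms)); ms$misc }

#' @export
dim.metabolite_set <- function(x) dim(x$assay)

#' @export
print.metabolite_set <- function(x, ...) {
  a <- x$assay
  cat(sprintf("<metabolite_set> %d samples x %d features\n", nrow(a), ncol(a)))
  nm <- sum(is.na(a))
  cat(sprintf("  missing: %d (%.1f%%)\n", nm, 100 * nm / max(1, length(a))))
  if ("qc" %in% names(x$samples) && is.logical(x$samples$qc)) {
    cat(sprintf("  QC samples: %d\n", sum(x$samples$qc, na.rm = TRUE)))
  }
  ann <- setdiff(names(x$samples), "sample_id")
  if (length(ann)) cat("  sample annotations:", paste(ann, collapse = ", "), "\n")
  cat(sprintf("  log entries: %d (last: %s)\n", length(x$log),
              if (length(x$log)) x$log[[length(x$log)]]$op else "-"))
  invisible(x)
}

#' Tidy a `metabolite_set` into a long tibble
#'
#' One row per (sample, feature) cell, with the assay value; handy for ggplot2
#' and dplyr workflows.
#'
#' @param x A `metabolite_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `feature_id`, `value`.
#' @method tidy metabolite_set
#' @export
tidy.metabolite_set <- function(x, ...) {
  a <- x$assay
  tibble::tibble(
    sample_id = rep(rownames(a), times = ncol(a)),
    feature_id = rep(colnames(a), each = nrow(a)),
    value = as.vector(a)
  )
}

#' One-line summary of a `metabolite_set`
#'
#' @param x A `metabolite_set`.
#' @param ... Unused.
#' @return A one-row tibble: sample/feature counts, missing count and fraction,
#'   number of QC samples (if a logical `qc` column exists), log length.
#' @method glance metabolite_set
#' @export
glance.metabolite_set <- function(x, ...) {
  a <- x$assay
  tibble::tibble(
    n_samples = nrow(a),
    n_features = ncol(a),
    n_missing = sum(is.na(a)),
    missing_rate = sum(is.na(a)) / max(1L, length(a)),
    n_qc = if ("qc" %in% names(x$samples)) sum(x$samples$qc %in% TRUE) else NA_integer_,
    n_log = length(x$log)
  )
}

# ---- subset ------------------------------------------------------------------

resolve_ids <- function(sel, table, key, what) {
  ids <- table[[key]]
  if (is.null(sel)) return(ids)
  if (is.function(sel)) {
    keep <- sel(table)
    if (!is.logical(keep) || length(keep) != nrow(table)) {
      stop(sprintf("%s predicate must return one logical per row.", what),
           call. = FALSE)
    }
    return(ids[keep %in% TRUE])
  }
  sel <- as.character(sel)
  unknown <- setdiff(sel, ids)
  if (length(unknown)) {
    stop(sprintf("Unknown %s IDs: %s", what, id_preview(unknown)), call. = FALSE)
  }
  ids[ids %in% sel] # preserve original set order
}

#' Subset a `metabolite_set` by sample and/or feature
#'
#' Assay, feature table and sample table are restricted consistently. Selection
#' can be a character vector of IDs or a predicate function taking the
#' annotation tibble and returning a logical vector. The original ordering of
#' retained samples/features is preserved regardless of the order of the ID
#' vector. Appends one log entry.
#'
#' @param ms A `metabolite_set`.
#' @param samples,features `NULL` (keep all), character IDs, or a predicate
#'   over the corresponding annotation tibble.
#' @return A new `metabolite_set`.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("S", 1:3), c("M1", "M2")))
#' ms <- metabolite_set(m * 1.0)
#' dim(ms_subset(ms, features = "M1"))
#' @export
ms_subset <- function(ms, samples = NULL, features = NULL) {
  stopifnot(is_metabolite_set(ms))
  keep_s <- resolve_ids(samples, ms$samples, "sample_id", "sample")
  keep_f <- resolve_ids(features, ms$features, "feature_id", "feature")
  out <- ms
  out$assay <- ms$assay[match(keep_s, rownames(ms$assay)),
                        match(keep_f, colnames(ms$assay)), drop = FALSE]
  out$samples <- ms$samples[match(keep_s, ms$samples$sample_id), , drop = FALSE]
  out$features <- ms$features[match(keep_f, ms$features$feature_id), , drop = FALSE]
  append_log(out, "ms_subset",
             params = list(),
             counts = list(n_samples = length(keep_s), n_features = length(keep_f),
                           dropped_samples = nrow(ms$assay) - length(keep_s),
                           dropped_features = ncol(ms$assay) - length(keep_f)))
}

# ---- merge -------------------------------------------------------------------

#' Merge two `metabolite_set`s along samples or features
#'
#' Concatenates two sets that agree exactly on the fixed axis: with
#' `axis = "features"` both sets must measure the same samples (any order) and
#' the feature sets must be disjoint; with `axis = "samples"` vice versa.
#' Deliberately no outer join: induced missingness from partial overlap is a
#' silent data-quality hazard, so ID mismatches on the fixed axis are an error.
#' A `.source` provenance column is added to the annotation table of the grown
#' axis.
#'
#' @param a,b `metabolite_set`s.
#' @param axis `"features"` (default) to combine measurement panels on shared
#'   samples, or `"samples"` to stack cohorts measured on the same panel.
#' @return A new `metabolite_set`; its log is `a`'s log plus one merge entry
#'   (`b`'s log is preserved under `misc_data(.)$merged_log`).
#' @export
ms_merge <- function(a, b, axis = c("features", "samples")) {
  stopifnot(is_metabolite_set(a), is_metabolite_set(b))
  axis <- match.arg(axis)
  if (axis == "samples") {
    # reuse the feature-axis path on transposed roles
    at <- transpose_set(a); bt <- transpose_set(b)
    out <- ms_merge_features(at, bt)
    out <- transpose_set(out)
    out$log <- a$log
    out$misc$merged_log <- b$log
    return(append_log(out, "ms_merge", params = list(axis = "samples"),
                      counts = list(n_samples = nrow(out$assay),
                                    n_features = ncol(out$assay))))
  }
  out <- ms_merge_features(a, b)
  out$misc$merged_log <- b$log
  append_log(out, "ms_merge", params = list(axis = "features"),
             counts = list(n_samples = nrow(out$assay),
                           n_features = ncol(out$assay)))
}

ms_merge_features <- function(a, b) {
  sa <- rownames(a$assay); sb <- rownames(b$assay)
  only_a <- setdiff(sa, sb); only_b <- setdiff(sb, sa)
  if (length(only_a) || length(only_b)) {
    stop(sprintf("Sample IDs must match exactly to merge features; unmatched: %s",
                 id_preview(c(only_a, only_b))), call. = FALSE)
  }
  dupf <- intersect(colnames(a$assay), colnames(b$assay))
  if (length(dupf)) {
    stop(sprintf("Duplicate feature IDs across sets: %s", id_preview(dupf)),
         call. = FALSE)
  }
  b_assay <- b$assay[match(sa, sb), , drop = FALSE]
  fa <- a$features; fb <- b$features
  fa$.source <- rep("a", nrow(fa)); fb$.source <- rep("b", nrow(fb))
  feats <- dplyr::bind_rows(fa, fb)
  out <- a
  out$assay <- cbind(a$assay, b_assay)
  out$features <- feats
  out <- validate_metabolite_set(out)
  out
}

transpose_set <- function(ms) {
  out <- ms
  out$assay <- t(ms$assay)
  feats <- ms$samples; names(feats)[names(feats) == "sample_id"] <- "feature_id"
  samps <- ms$features; names(samps)[names(samps) == "feature_id"] <- "sample_id"
  out$features <- feats
  out$samples <- samps
  out
}
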