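# All transformations are per-feature value maps on observed entries: missing
# values never enter the statistics and are preserved in the output. Each
# application is logged, so "was this set already log-transformed?" is always
# answerable from the audit trail.

transform_apply <- function(ms, op, fn, params = list()) {
  a <- ms$assay
  for (j in seq_len(ncol(a))) {
    obs <- which(!is.na(a[, j]))
    if (length(obs)) a[obs, j] <- fn(a[obs, j], colnames(a)[j])
  }
  out <- ms
  out$assay <- a
  append_log(out, op, params = params,
             counts = list(n_features = ncol(a)))
}

#' Natural-log transformation
#'
#' @param ms A `metabolite_set` with strictly positive observed values.
#' @return A new set with each observed value replaced by its natural log.
#'   A non-positive value is an error naming the first offending cell.
#' @export
log_transform <- function(ms) {
  stopifnot(is_metabolite_set(ms))
  a <- ms$assay
  bad <- which(!is.na(a) & a <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("Non-positive value at sample '%s', feature '%s' (%g); log is undefined.",
                 rownames(a)[bad[1, 1]], colnames(a)[bad[1, 2]],
                 a[bad[1, 1], bad[1, 2]]), call. = FALSE)
  }
  transform_apply(ms, "log_transform", function(x, id) log(x))
}

#' Pareto scaling
#'
#' Per feature: `(x - mean) / sqrt(sd)` over observed values — a compromise
#' between no scaling and full unit-variance autoscaling that damps, without
#' erasing, fold-change information. Constant features map to 0 with a warning.
#'
#' @param ms A `metabolite_set`.
#' @return A new `metabolite_set`.
#' @export
pareto_scale <- function(ms) {
  scale_by(ms, "pareto_scale", function(s) sqrt(s))
}

#' Unit-variance autoscaling
#'
#' Per feature: `(x - mean) / sd` over observed values, giving observed mean 0
#' and sample SD 1. Constant features map to 0 with a warning.
#'
#' @param ms A `metabolite_set`.
#' @return A new `metabolite_set`.
#' @export
auto_scale <- function(ms) {
  scale_by(ms, "auto_scale", function(s) s)
}

scale_by <- function(ms, op, denom_fn) {
  stopifnot(is_metabolite_set(ms))
  constant <- character()
  out <- transform_apply(ms, op, function(x, id) {
    mu <- mean(x)
    s <- stats::sd(x)
    if (length(x) < 2 || is.na(s) || s == 0) {
      constant <<- c(constant, id)
      return(rep(0, length(x)))
    }
    (x - mu) / denom_fn(s)
  })
  if (length(constant)) {
    warning(sprintf("%d constant feature(s) mapped to 0: %s",
                    length(constant), id_preview(constant)))
  }
  out
}

#' Rank-based inverse normal transformation
#'
#' Per feature, over the `n` observed values: average ranks `r`, then
#' `qnorm((r - 0.375) / (n + 0.25))` — the Blom offset, the convention of
#' metabolomics and GWAS pipelines. Tie-free features of equal `n` therefore
#' share one fixed multiset of scores, symmetric about 0, and the output order
#' equals the input order.
#'
#' @param ms A `metabolite_set`.
#' @return A new `metabolite_set`.
#' @export
inverse_normal_transform <- function(ms) {
  stopifnot(is_metabolite_set(ms))
  transform_apply(ms, "inverse_normal_transform", function(x, id) {
    r <- rank(x, ties.method = "average")
    stats::qnorm((r - 0.375) / (length(x) + 0.25))
  })
}

#' Apply a named transformation
#'
#' Dispatcher used by the pipeline runner and CLI.
#'
#' @param ms A `metabolite_set`.
#' @param method `"log"`, `"pareto_scale"`, `"scale"` or `"int"`.
#' @return A new `metabolite_set`.
#' @export
transform_features <- function(ms, method = c("log", "pareto_scale", "scale", "int")) {
  method <- match.arg(method)
  switch(method,
         log = log_transform(ms),
         pareto_scale = pareto_scale(ms),
         scale = auto_scale(ms),
         int = inverse_normal_transform(ms))
}
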