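# Metabolite-wide association scans: one regression per metabolite, the
# metabolite as the exposure on the right-hand side, standardized per analysis
# so estimates are per-SD and comparable across metabolites.

#' Metabolite-wide association scan
#'
#' Fits one model per metabolite regressing the outcome on the metabolite plus
#' covariates, across five model families:
#' \describe{
#'   \item{linear}{`stats::lm`, continuous outcome}
#'   \item{logistic}{`stats::glm(family = binomial)`, 0/1 outcome}
#'   \item{cox}{`survival::coxph` on `Surv(time, event)`}
#'   \item{lmm}{`lmerTest::lmer` with a random intercept per `group`
#'     (Satterthwaite p-values)}
#'   \item{logistic_lmm}{`lme4::glmer(family = binomial)` with a random
#'     intercept per `group` (Wald p-values)}
#' }
#' Per feature: QC injections are excluded, complete cases are taken over the
#' outcome, covariates and that metabolite only (`n` is recorded per record),
#' and the metabolite is standardized to mean 0, SD 1 over the analysed
#' samples, so estimates are per-SD effects (log-odds for logistic,
#' log-hazards for cox). Failed or degenerate fits are recorded with a
#' non-`"ok"` status and `NA` estimates — never raised — so one bad metabolite
#' cannot kill a thousand-feature scan. Results are independent of `workers`.
#'
#' @param ms A `metabolite_set` (typically log-transformed).
#' @param phenotypes Data frame keyed by `sample_id` with the outcome,
#'   covariates and (for mixed models) the grouping column. Sample-table
#'   columns may be used too; phenotype columns win on name clashes.
#' @param model One of `"linear"`, `"logistic"`, `"cox"`, `"lmm"`,
#'   `"logistic_lmm"`.
#' @param outcome Outcome column name (ignored for `cox`).
#' @param covariates Character vector of covariate column names (optional).
#' @param time,event Survival time and 0/1 event columns (`cox` only).
#' @param group Random-intercept grouping column (`lmm`/`logistic_lmm` only).
#' @param features Optional feature-ID subset; default all.
#' @param workers Number of parallel workers (forked; an execution detail —
#'   results are identical for any value).
#' @param p_adjust_method `"BH"` (default) or `"bonferroni"`, applied across
#'   the successfully fitted features of this call.
#' @param qc_col Logical QC-flag column in the sample table.
#' @return A tibble of class `assoc_result`, one row per feature:
#'   `feature_id`, `outcome`, `model`, `n`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `p_adjust`, `status`.
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 100, n_features = 10,
#'                                             missing_rate = 0, n_true_effects = 2,
#'                                             effect_size = 1, seed = 11))
#' res <- regress_features(log_transform(sim$set), sim$phenotypes,
#'                         model = "linear", outcome = "y",
#'                         covariates = c("age", "sex"))
#' dplyr::arrange(res, p_value)
#' @export
regress_features <- function(ms, phenotypes,
                             model = c("linear", "logistic", "cox", "lmm", "logistic_lmm"),
                             outcome = NULL, covariates = NULL,
                             time = NULL, event = NULL, group = NULL,
                             features = NULL, workers = 1L,
                             p_adjust_method = c("BH", "bonferroni"),
                             qc_col = "qc") {
  stopifnot(is_metabolite_set(ms))
  model <- match.arg(model)
  p_adjust_method <- match.arg(p_adjust_method)
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!"sample_id" %in% names(phenotypes)) {
    stop("`phenotypes` must have a `sample_id` column.", call. = FALSE)
  }

  if (model == "cox") {
    if (is.null(time) || is.null(event)) {
      stop("Cox models need `time` and `event` column names.", call. = FALSE)
    }
    outcome_label <- paste0(time, "/", event)
    needed <- c(time, event, covariates)
  } else {
    if (is.null(outcome)) stop("`outcome` is required.", call. = FALSE)
    outcome_label <- outcome
    needed <- c(outcome, covariates)
  }
  if (model %in% c("lmm", "logistic_lmm")) {
    if (is.null(group)) stop(sprintf("`group` is required for %s.", model), call. = FALSE)
    needed <- c(needed, group)
  }

  # assemble the per-sample frame: study samples only, phenotype columns
  # overriding same-named sample annotations
  st <- study_mask(ms, qc_col)
  samp <- ms$samples[st, , drop = FALSE]
  keep_cols <- c("sample_id", setdiff(names(samp), names(phenotypes)))
  frame <- dplyr::inner_join(samp[keep_cols], phenotypes, by = "sample_id")
  missing_cols <- setdiff(needed, names(frame))
  if (length(missing_cols)) {
    stop(sprintf("Column(s) not found in phenotypes/sample table: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  feat_ids <- if (is.null(features)) colnames(ms$assay) else {
    unknown <- setdiff(features, colnames(ms$assay))
    if (length(unknown)) stop(sprintf("Unknown feature IDs: %s", id_preview(unknown)),
                              call. = FALSE)
    features
  }
  a <- ms$assay[match(frame$sample_id, rownames(ms$assay)), , drop = FALSE]

  fit_one <- function(fid) {
    fit_single_feature(a[, fid], frame, model, outcome, covariates, time, event, group)
  }
  workers <- max(1L, as.integer(workers))
  rows <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(feat_ids, fit_one, mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(feat_ids, fit_one)
  }
  res <- dplyr::bind_rows(rows)
  res$feature_id <- feat_ids
  res$outcome <- outcome_label
  res$model <- model
  res$p_adjust <- adjust_pvalues(res$p_value, method = p_adjust_method)
  res <- res[, c("feature_id", "outcome", "model", "n", "estimate", "std_error",
                 "statistic", "p_value", "p_adjust", "status")]
  if (all(res$status != "ok")) {
    stop("All model fits failed; check the outcome/covariate specification.",
         call. = FALSE)
  }
  structure(res, class = c("assoc_result", class(res)),
            params = list(model = model, outcome = outcome_label,
                          covariates = covariates, group = group,
                          p_adjust_method = p_adjust_method))
}

na_row <- function(n, status) {
  tibble::tibble(n = n, estimate = NA_real_, std_error = NA_real_,
                 statistic = NA_real_, p_value = NA_real_, status = status)
}

fit_single_feature <- function(x, frame, model, outcome, covariates, time, event, group) {
  df <- frame
  df$.metab <- as.numeric(x)
  needed <- switch(model,
    cox = c(".metab", time, event, covariates),
    lmm = c(".metab", outcome, covariates, group),
    logistic_lmm = c(".metab", outcome, covariates, group),
    c(".metab", outcome, covariates))
  cc <- stats::complete.cases(df[needed])
  df <- df[cc, , drop = FALSE]
  n <- nrow(df)
  if (n < length(covariates) + 3) return(na_row(n, "skipped: too few complete cases"))
  s <- stats::sd(df$.metab)
  if (is.na(s) || s == 0) return(na_row(n, "skipped: zero variance"))
  df$.metab <- (df$.metab - mean(df$.metab)) / s

  rhs <- paste(c(".metab", covariates), collapse = " + ")
  out <- tryCatch({
    if (model == "linear") {
      fit <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = df)
      co <- summary(fit)$coefficients[".metab", ]
      list(est = co[[1]], se = co[[2]], stat = co[[3]], p = co[[4]])
    } else if (model == "logistic") {
      fit <- stats::glm(stats::as.formula(paste(outcome, "~", rhs)), data = df,
                        family = stats::binomial())
      co <- summary(fit)$coefficients[".metab", ]
      list(est = co[[1]], se = co[[2]], stat = co[[3]], p = co[[4]])
    } else if (model == "cox") {
      f <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
      fit <- survival::coxph(f, data = df)
      co <- summary(fit)$coefficients[".metab", ]
      list(est = co[["coef"]], se = co[["se(coef)"]], stat = co[["z"]],
           p = co[["Pr(>|z|)"]])
    } else if (model == "lmm") {
      f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, rhs, group))
      fit <- lmerTest::lmer(f, data = df)
      co <- stats::coef(summary(fit))[".metab", ]
      list(est = co[["Estimate"]], se = co[["Std. Error"]], stat = co[["t value"]],
           p = co[["Pr(>|t|)"]])
    } else {
      f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, rhs, group))
      fit <- suppressMessages(lme4::glmer(f, data = df, family = stats::binomial()))
      co <- stats::coef(summary(fit))[".metab", ]
      list(est = co[["Estimate"]], se = co[["Std. Error"]], stat = co[["z value"]],
           p = co[["Pr(>|z|)"]])
    }
  }, error = function(e) e, warning = function(w) {
    # refit ignoring the warning but flag convergence chatter in the status
    res <- tryCatch(suppressWarnings(
      fit_single_feature_quiet(df, model, outcome, covariates, time, event, group, rhs)
    ), error = function(e) e)
    if (inherits(res, "error")) res else c(res, list(note = conditionMessage(w)))
  })
  if (inherits(out, "error")) {
    return(na_row(n, paste0("error: ", conditionMessage(out))))
  }
  status <- if (!is.null(out$note)) paste0("warning: ", out$note) else "ok"
  tibble::tibble(n = n, estimate = out$est, std_error = out$se,
                 statistic = out$stat, p_value = out$p,
                 status = if (is.null(out$note)) "ok" else status)
}

fit_single_feature_quiet <- function(df, model, outcome, covariates, time, event, group, rhs) {
  if (model == "linear") {
    fit <- stats::lm(stats::as.formula(paste(outcome, "~", rhs)), data = df)
    co <- summary(fit)$coefficients[".metab", ]
    list(est = co[[1]], se = co[[2]], stat = co[[3]], p = co[[4]])
  } else if (model == "logistic") {
    fit <- stats::glm(stats::as.formula(paste(outcome, "~", rhs)), data = df,
                      family = stats::binomial())
    co <- summary(fit)$coefficients[".metab", ]
    list(est = co[[1]], se = co[[2]], stat = co[[3]], p = co[[4]])
  } else if (model == "cox") {
    f <- stats::as.formula(sprintf("survival::Surv(%s, %s) ~ %s", time, event, rhs))
    fit <- survival::coxph(f, data = df)
    co <- summary(fit)$coefficients[".metab", ]
    list(est = co[["coef"]], se = co[["se(coef)"]], stat = co[["z"]],
         p = co[["Pr(>|z|)"]])
  } else if (model == "lmm") {
    f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, rhs, group))
    fit <- lmerTest::lmer(f, data = df)
    co <- stats::coef(summary(fit))[".metab", ]
    list(est = co[["Estimate"]], se = co[["Std. Error"]], stat = co[["t value"]],
         p = co[["Pr(>|t|)"]])
  } else {
    f <- stats::as.formula(sprintf("%s ~ %s + (1 | %s)", outcome, rhs, group))
    fit <- suppressMessages(lme4::glmer(f, data = df, family = stats::binomial()))
    co <- stats::coef(summary(fit))[".metab", ]
    list(est = co[["Estimate"]], se = co[["Std. Error"]], stat = co[["z value"]],
         p = co[["Pr(>|z|)"]])
  }
}

#' Multiple-testing adjustment with missing-value bookkeeping
#'
#' Benjamini–Hochberg step-up or Bonferroni. Missing p-values (failed fits)
#' are excluded from the number of tests `m` and returned as missing.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @param method `"BH"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03))
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must be in [0, 1].", call. = FALSE)
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = method)
  out
}

#' Sorted association table, optionally written to CSV
#'
#' @param results An `assoc_result` from [regress_features()].
#' @param path Optional CSV path to write the sorted table to.
#' @return The results sorted by p-value (successful fits first).
#' @export
volcano_table <- function(results, path = NULL) {
  stopifnot(inherits(results, "assoc_result"))
  if (!any(results$status == "ok")) {
    stop("No successful fits to tabulate.", call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(results), is.na(.data$p_value),
                        .data$p_value)
  if (!is.null(path)) readr::write_csv(out, path, na = "")
  out
}

#' Volcano plot of a metabolite-wide scan
#'
#' Per-SD estimate against -log10 p, features significant after adjustment
#' (at `alpha`) highlighted.
#'
#' @param object An `assoc_result`.
#' @param alpha Adjusted-p significance threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assoc_result
#' @export
autoplot.assoc_result <- function(object, alpha = 0.05, ...) {
  if (!any(object$status == "ok")) stop("No successful fits to plot.", call. = FALSE)
  df <- dplyr::filter(tibble::as_tibble(object), .data$status == "ok")
  df$significant <- !is.na(df$p_adjust) & df$p_adjust < alpha
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = -log10(.data$p_value),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50", `TRUE` = "firebrick"),
                                 name = sprintf("adj. p < %g", alpha)) +
    ggplot2::labs(x = "estimate (per SD)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.assoc_result
#' @param results An `assoc_result`.
#' @export
plot_volcano <- function(results, alpha = 0.05) {
  autoplot.assoc_result(results, alpha = alpha)
}

#' Summarise a metabolite-wide scan
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return One-row tibble: model, features tested, fits OK, significant at
#'   adjusted p < 0.05, smallest p.
#' @method glance assoc_result
#' @export
glance.assoc_result <- function(x, ...) {
  tibble::tibble(model = x$model[1], n_features = nrow(x),
                 n_ok = sum(x$status == "ok"),
                 n_significant = sum(x$p_adjust < 0.05, na.rm = TRUE),
                 min_p = suppressWarnings(min(x$p_value, na.rm = TRUE)))
}
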