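# Declarative pipeline runner: an ordered list of stages, validated in full
# before anything executes (fail-fast), then applied in sequence with a
# reproducibility manifest.

stage_registry <- function() {
  list(
    import_delimited = list(fn = read_metabolite_delimited, input = "none"),
    import_workbook = list(fn = read_metabolite_workbook, input = "none"),
    import_dir = list(fn = read_metabolite_dir, input = "none"),
    simulate = list(fn = NULL, input = "none"), # handled specially (config + seed)
    qc = list(fn = NULL, input = "set"),        # wraps qc_pipeline via qc_params
    filter_features_by_missing = list(fn = filter_features_by_missing, input = "set"),
    filter_samples_by_missing = list(fn = filter_samples_by_missing, input = "set"),
    impute = list(fn = impute_missing, input = "set"),
    batch_norm = list(fn = batch_norm, input = "set"),
    qcmatrix_norm = list(fn = qcmatrix_norm, input = "set"),
    nearest_qc_norm = list(fn = nearest_qc_norm, input = "set"),
    loess_norm = list(fn = loess_norm, input = "set"),
    log = list(fn = log_transform, input = "set"),
    pareto_scale = list(fn = pareto_scale, input = "set"),
    scale = list(fn = auto_scale, input = "set"),
    int = list(fn = inverse_normal_transform, input = "set"),
    drop_qc = list(fn = NULL, input = "set"),
    pca = list(fn = run_pca, input = "set"),
    umap = list(fn = run_umap, input = "set"),
    tsne = list(fn = run_tsne, input = "set"),
    assoc = list(fn = NULL, input = "set")      # needs the phenotype table
  )
}

stage_formals <- function(name) {
  reg <- stage_registry()[[name]]
  extra <- switch(name,
    simulate = names(formals(synth_config)),
    qc = c(names(formals(qc_params)), "qc_col"),
    assoc = setdiff(names(formals(regress_features)), c("ms", "phenotypes")),
    drop_qc = "qc_col",
    NULL)
  c(extra, if (!is.null(reg$fn)) setdiff(names(formals(reg$fn)), c("ms", "...")))
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) || is.null(config$stages) || !length(config$stages)) {
    stop("Pipeline config must be a list (or YAML file) with a non-empty `stages` list.",
         call. = FALSE)
  }
  reg <- stage_registry()
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    if (is.character(st)) st <- list(stage = st)
    if (is.null(st$stage)) {
      stop(sprintf("Stage %d has no `stage` name.", i), call. = FALSE)
    }
    if (!st$stage %in% names(reg)) {
      stop(sprintf("Unknown stage '%s' (stage %d). Known: %s", st$stage, i,
                   paste(names(reg), collapse = ", ")), call. = FALSE)
    }
    params <- setdiff(names(st), c("stage", "checkpoint"))
    bad <- setdiff(params, stage_formals(st$stage))
    if (length(bad)) {
      stop(sprintf("Stage '%s' (stage %d): unknown parameter(s) %s.", st$stage, i,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
    config$stages[[i]] <- st
  }
  config
}

#' Run a declarative pipeline
#'
#' Executes an ordered list of stages (import or simulate, QC, normalization,
#' transformation, embedding, association) described by a list or a YAML file.
#' The whole config is validated before any stage runs, so a typo in stage 5
#' never costs you stages 1–4. Every stage is logged in the set's audit trail;
#' the returned manifest records the package version, a config hash, per-stage
#' input/output dimensions, and a hash of all outputs (timestamps excluded),
#' so identical config + seed gives an identical manifest hash.
#'
#' Stage names: `import_delimited`, `import_workbook`, `import_dir`,
#' `simulate`, `qc`, `filter_features_by_missing`, `filter_samples_by_missing`,
#' `impute`, `batch_norm`, `qcmatrix_norm`, `nearest_qc_norm`, `loess_norm`,
#' `log`, `pareto_scale`, `scale`, `int`, `drop_qc`, `pca`, `umap`, `tsne`,
#' `assoc`. Each stage block names the stage plus that operation's parameters;
#' `seed` at the top level feeds `simulate` and the embedding stages unless a
#' stage overrides it.
#'
#' @param config A list with elements `stages` (list of stage blocks) and
#'   optionally `seed`, or a path to a YAML file with the same shape.
#' @param out_dir Optional directory: the final set is written there
#'   ([write_metabolite_set()]) together with `manifest.json`; stages with
#'   `checkpoint: true` write intermediate sets to `checkpoint_<i>_<stage>/`.
#' @return A list of class `pipeline_result`: `set` (final `metabolite_set`),
#'   `results` (named list of non-set stage outputs: embeddings, association
#'   tables, QC reports), `manifest`.
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 60, n_features = 8,
#'                                             n_batches = 2, seed = 4))
#' dir <- tempfile(); write_metabolite_set(sim$set, dir)
#' res <- run_pipeline(list(stages = list(
#'   list(stage = "import_dir", dir = dir),
#'   list(stage = "qc"),
#'   list(stage = "batch_norm"),
#'   list(stage = "log"),
#'   list(stage = "pca", n_components = 2)
#' )))
#' res$manifest$stages
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_pipeline_config(config)
  seed <- config$seed %||% 1L
  ms <- NULL
  pheno <- config$phenotypes %||% NULL
  if (is.character(pheno)) {
    pheno <- readr::read_csv(pheno, show_col_types = FALSE)
  }
  results <- list()
  stage_log <- list()

  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    name <- st$stage
    params <- st[setdiff(names(st), c("stage", "checkpoint"))]
    dim_in <- if (is.null(ms)) c(NA_integer_, NA_integer_) else dim(ms)
    out <- tryCatch(
      run_stage(name, params, ms, pheno, seed),
      error = function(e) {
        done <- vapply(stage_log, function(s) s$stage, "")
        stop(sprintf("Pipeline failed at stage %d ('%s'): %s\nCompleted stages: %s",
                     i, name, conditionMessage(e),
                     if (length(done)) paste(done, collapse = " -> ") else "none"),
             call. = FALSE)
      })
    if (is_metabolite_set(out)) {
      ms <- out
    } else if (inherits(out, "synth_data")) {
      ms <- out$set
      pheno <- pheno %||% out$phenotypes
      results$truth <- out$truth
    } else if (inherits(out, "qc_result")) {
      ms <- out$set
      results$qc_report <- out$report
    } else {
      results[[paste0(name, "_", i)]] <- out
    }
    stage_log[[i]] <- list(stage = name, order = i,
                           dim_in = as.integer(dim_in),
                           dim_out = as.integer(dim(ms)))
    if (isTRUE(st$checkpoint) && !is.null(out_dir)) {
      write_metabolite_set(ms, file.path(out_dir, sprintf("checkpoint_%02d_%s", i, name)))
    }
  }

  hashable <- list(assay = ms$assay, features = ms$features, samples = ms$samples,
                   ops = vapply(ms$log, function(e) e$op, ""))
  manifest <- list(
    tool = "metabopipe",
    version = as.character(utils::packageVersion("metabopipe")),
    seed = seed,
    config_hash = rlang::hash(config),
    output_hash = rlang::hash(hashable),
    stages = stage_log
  )
  if (!is.null(out_dir)) {
    write_metabolite_set(ms, out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(set = ms, results = results, manifest = manifest),
            class = "pipeline_result")
}

run_stage <- function(name, params, ms, pheno, seed) {
  reg <- stage_registry()[[name]]
  if (reg$input == "set" && is.null(ms)) {
    stop("No data set loaded yet; start with an import or simulate stage.",
         call. = FALSE)
  }
  if (name == "simulate") {
    params$seed <- params$seed %||% seed
    return(simulate_metabolite_set(do.call(synth_config, params)))
  }
  if (name == "qc") {
    qc_col <- params$qc_col %||% "qc"
    params$qc_col <- NULL
    return(qc_pipeline(ms, do.call(qc_params, params), qc_col = qc_col))
  }
  if (name == "drop_qc") {
    qc_col <- params$qc_col %||% "qc"
    keep <- ms$samples$sample_id[study_mask(ms, qc_col)]
    return(ms_subset(ms, samples = keep))
  }
  if (name == "assoc") {
    if (is.null(pheno)) stop("assoc stage needs a phenotype table (config$phenotypes or a simulate stage).",
                             call. = FALSE)
    return(do.call(regress_features, c(list(ms = ms, phenotypes = pheno), params)))
  }
  if (name %in% c("umap", "tsne")) params$seed <- params$seed %||% seed
  if (reg$input == "none") return(do.call(reg$fn, params))
  do.call(reg$fn, c(list(ms), params))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d stages, output hash %s\n",
              length(x$manifest$stages), substr(x$manifest$output_hash, 1, 12)))
  for (s in x$manifest$stages) {
    cat(sprintf("  %2d. %-28s %s -> %s\n", s$order, s$stage,
                paste(s$dim_in, collapse = "x"), paste(s$dim_out, collapse = "x")))
  }
  invisible(x)
}
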