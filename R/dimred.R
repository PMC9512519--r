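# Embeddings are tibbles joined to the sample table, so colouring by batch,
# QC flag or phenotype needs no further merging.

new_embedding <- function(coords, ms, method, params, var_explained = NULL) {
  k <- ncol(coords)
  df <- tibble::as_tibble(coords, .name_repair = "minimal")
  names(df) <- colnames(coords)
  emb <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(ms$assay)), df)
  emb <- dplyr::left_join(emb, ms$samples, by = "sample_id")
  structure(emb, class = c("metabo_embedding", class(emb)),
            method = method, params = params, var_explained = var_explained,
            dims = colnames(coords))
}

check_complete <- function(ms, fn) {
  if (anyNA(ms$assay)) {
    stop(sprintf("%s requires a complete assay matrix; impute missing values first (see impute_missing()).",
                 fn), call. = FALSE)
  }
}

# standardize features; constant features are an error (they carry no
# geometry and break unit-variance scaling)
standardized_assay <- function(ms, scale = TRUE) {
  a <- ms$assay
  s <- apply(a, 2, stats::sd)
  if (scale && any(s == 0)) {
    stop(sprintf("Constant feature(s) cannot be unit-variance scaled: %s. Drop them or use scale = FALSE.",
                 id_preview(colnames(a)[s == 0])), call. = FALSE)
  }
  scale(a, center = TRUE, scale = if (scale) s else FALSE)
}

#' Principal components analysis of a `metabolite_set`
#'
#' Features are centred and (by default) unit-variance scaled — metabolite
#' peak areas span orders of magnitude, so unscaled PCA is dominated by the
#' most abundant features — then decomposed by SVD. Component signs follow a
#' fixed convention (the largest-magnitude loading of each component is
#' positive), making the result fully deterministic.
#'
#' @param ms A `metabolite_set` with no missing values.
#' @param n_components Number of PCs to return (default 10, capped at the
#'   matrix rank bound `min(n_samples, n_features)` being an error if exceeded).
#' @param scale Unit-variance scale features first (default `TRUE`).
#' @return A `metabo_embedding` tibble: `sample_id`, `PC1..PCk`, sample
#'   annotations; attributes `var_explained` (fractions, non-increasing) and
#'   `params`.
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 30, n_features = 6,
#'                                             missing_rate = 0, seed = 5))
#' emb <- run_pca(sim$set, n_components = 3)
#' head(emb)
#' @export
run_pca <- function(ms, n_components = 10, scale = TRUE) {
  stopifnot(is_metabolite_set(ms))
  check_complete(ms, "run_pca")
  if (nrow(ms$assay) < 2) stop("PCA needs at least 2 samples.", call. = FALSE)
  if (n_components > min(dim(ms$assay))) {
    stop(sprintf("n_components (%d) exceeds min(n_samples, n_features) = %d.",
                 n_components, min(dim(ms$assay))), call. = FALSE)
  }
  x <- standardized_assay(ms, scale)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    jmax <- which.max(abs(rot[, c]))
    if (rot[jmax, c] < 0) { rot[, c] <- -rot[, c]; scores[, c] <- -scores[, c] }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  colnames(scores) <- paste0("PC", seq_len(k))
  new_embedding(scores, ms, "pca",
                params = list(n_components = k, scale = scale),
                var_explained = ve[seq_len(k)])
}

#' UMAP embedding of a `metabolite_set`
#'
#' Features are standardized as in [run_pca()], then embedded in 2-D with
#' uniform manifold approximation and projection. Runs single-threaded with a
#' fixed seed so identical calls give identical coordinates.
#'
#' @param ms A `metabolite_set` with no missing values.
#' @param n_neighbors UMAP neighbourhood size (default 15); clamped to
#'   `n_samples - 1` with a warning when too large.
#' @param seed Integer seed.
#' @return A `metabo_embedding` tibble with columns `UMAP1`, `UMAP2`.
#' @export
run_umap <- function(ms, n_neighbors = 15, seed = 42) {
  stopifnot(is_metabolite_set(ms))
  check_complete(ms, "run_umap")
  n <- nrow(ms$assay)
  if (n_neighbors >= n) {
    warning(sprintf("n_neighbors (%d) >= n_samples (%d); clamped to %d.",
                    n_neighbors, n, n - 1))
    n_neighbors <- n - 1
  }
  x <- standardized_assay(ms, scale = TRUE)
  coords <- uwot::umap(x, n_neighbors = n_neighbors, n_components = 2,
                       n_threads = 1, n_sgd_threads = 0, seed = seed)
  colnames(coords) <- c("UMAP1", "UMAP2")
  rownames(coords) <- rownames(ms$assay)
  new_embedding(coords, ms, "umap",
                params = list(n_neighbors = n_neighbors, seed = seed))
}

#' t-SNE embedding of a `metabolite_set`
#'
#' Features are standardized as in [run_pca()], then embedded in 2-D with
#' t-distributed stochastic neighbour embedding (single-threaded, seeded).
#' The perplexity must satisfy `3 * perplexity < n_samples - 1`; larger values
#' are clamped with a warning.
#'
#' @param ms A `metabolite_set` with no missing values.
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed Integer seed.
#' @return A `metabo_embedding` tibble with columns `TSNE1`, `TSNE2`.
#' @export
run_tsne <- function(ms, perplexity = 30, seed = 42) {
  stopifnot(is_metabolite_set(ms))
  check_complete(ms, "run_tsne")
  n <- nrow(ms$assay)
  p_max <- (n - 2) / 3
  if (perplexity > p_max) {
    warning(sprintf("perplexity (%g) too large for %d samples; clamped to %g.",
                    perplexity, n, floor(p_max)))
    perplexity <- floor(p_max)
  }
  if (perplexity < 1) stop("Too few samples for t-SNE.", call. = FALSE)
  x <- standardized_assay(ms, scale = TRUE)
  coords <- withr::with_seed(seed,
    Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, check_duplicates = FALSE,
                 pca = TRUE, num_threads = 1)$Y)
  colnames(coords) <- c("TSNE1", "TSNE2")
  rownames(coords) <- rownames(ms$assay)
  new_embedding(coords, ms, "tsne",
                params = list(perplexity = perplexity, seed = seed))
}

#' @export
print.metabo_embedding <- function(x, ...) {
  cat(sprintf("<metabo_embedding: %s> %d samples x %d dims\n",
              attr(x, "method"), nrow(x), length(attr(x, "dims"))))
  ve <- attr(x, "var_explained")
  if (!is.null(ve)) {
    cat("  variance explained:",
        paste(sprintf("%.1f%%", 100 * utils::head(ve, 5)), collapse = " "), "\n")
  }
  NextMethod()
}

#' Glance at an embedding
#'
#' @param x A `metabo_embedding`.
#' @param ... Unused.
#' @return One-row tibble: method, sample count, dimensions, variance explained
#'   by the first two components (PCA only).
#' @method glance metabo_embedding
#' @export
glance.metabo_embedding <- function(x, ...) {
  ve <- attr(x, "var_explained")
  tibble::tibble(method = attr(x, "method"), n_samples = nrow(x),
                 n_dims = length(attr(x, "dims")),
                 var_explained_2d = if (is.null(ve)) NA_real_ else sum(ve[1:2]))
}

#' Scatter plot of an embedding
#'
#' @param object A `metabo_embedding` from [run_pca()], [run_umap()] or
#'   [run_tsne()].
#' @param colour Optional sample-annotation column name to colour points by
#'   (e.g. `"batch"` to inspect batch effects, `"qc"` for QC injections).
#' @param ... Unused.
#' @return A ggplot of the first two embedding dimensions.
#' @method autoplot metabo_embedding
#' @export
autoplot.metabo_embedding <- function(object, colour = NULL, ...) {
  dims <- attr(object, "dims")
  ve <- attr(object, "var_explained")
  labs <- dims[1:2]
  if (!is.null(ve)) {
    labs <- sprintf("%s (%.1f%%)", dims[1:2], 100 * ve[1:2])
  }
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[dims[1]]],
                                            y = .data[[dims[2]]]))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.8)
  }
  p + ggplot2::labs(x = labs[1], y = labs[2]) + ggplot2::theme_minimal()
}

#' @rdname autoplot.metabo_embedding
#' @param embedding A `metabo_embedding`.
#' @export
plot_embedding <- function(embedding, colour = NULL) {
  autoplot.metabo_embedding(embedding, colour = colour)
}
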