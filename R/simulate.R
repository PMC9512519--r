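#' Configuration for the synthetic-data generator
#'
#' Captures the structure of multi-batch non-targeted MS peak-area data:
#' log-normal metabolite abundances, multiplicative per-batch factors,
#' within-batch run-order drift, pooled-QC injections interleaved every
#' `qc_every`-th position, non-random missingness, sparse extreme outliers and
#' case/control or survival phenotypes driven by a known subset of features.
#'
#' @param n_samples Number of study (non-QC) samples.
#' @param n_features Number of metabolites.
#' @param n_batches Number of instrument batches (contiguous run-order blocks).
#' @param qc_every A pooled-QC injection occupies every `qc_every`-th run-order
#'   position within each batch.
#' @param batch_scale_sd SD (natural-log scale) of the multiplicative
#'   per-(batch, feature) factors; 0 disables batch effects.
#' @param drift_amplitude Maximum relative intensity change over a batch's run
#'   order; the drift is a linear ramp from 1 to `1 + drift_amplitude`,
#'   multiplicative, shared by study and QC injections (pooled QCs exist
#'   precisely to measure this drift).
#' @param missing_rate Expected fraction of study-sample entries masked.
#' @param missing_mechanism `"MCAR"` or `"intensity"` (masking probability
#'   decreases with log-intensity through a logistic link centred at each
#'   feature's 20th percentile; probabilities rescaled so the expected overall
#'   rate equals `missing_rate`).
#' @param outlier_rate Fraction of study entries multiplied by
#'   `exp(outlier_magnitude * feature log-SD)`.
#' @param outlier_magnitude Outlier size in units of the feature's log-SD
#'   (>= 6 recommended so injected outliers are unambiguous).
#' @param n_true_effects Number of features with a real phenotype effect.
#' @param effect_size Effect per SD of the (log) metabolite on the outcome's
#'   linear predictor.
#' @param outcome_kind `"continuous"`, `"binary"` or `"survival"`.
#' @param seed Single integer seed governing all randomness.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_samples = 300, n_features = 50, n_batches = 3,
                         qc_every = 10, batch_scale_sd = 0.3,
                         drift_amplitude = 0.3, missing_rate = 0.1,
                         missing_mechanism = c("MCAR", "intensity"),
                         outlier_rate = 0.001, outlier_magnitude = 8,
                         n_true_effects = 5, effect_size = 0.5,
                         outcome_kind = c("continuous", "binary", "survival"),
                         seed = 1L) {
  missing_mechanism <- match.arg(missing_mechanism)
  outcome_kind <- match.arg(outcome_kind)
  cfg <- list(n_samples = as.integer(n_samples), n_features = as.integer(n_features),
              n_batches = as.integer(n_batches), qc_every = as.integer(qc_every),
              batch_scale_sd = batch_scale_sd, drift_amplitude = drift_amplitude,
              missing_rate = missing_rate, missing_mechanism = missing_mechanism,
              outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
              n_true_effects = as.integer(n_true_effects), effect_size = effect_size,
              outcome_kind = outcome_kind, seed = as.integer(seed))
  for (r in c("missing_rate", "outlier_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(sprintf("%s must be in [0, 1].", r), call. = FALSE)
  }
  if (cfg$n_true_effects > cfg$n_features) {
    stop("n_true_effects cannot exceed n_features.", call. = FALSE)
  }
  if (cfg$n_samples < 1 || cfg$n_features < 1 || cfg$n_batches < 1) {
    stop("n_samples, n_features and n_batches must be positive.", call. = FALSE)
  }
  if (cfg$qc_every < 2 || cfg$qc_every > cfg$n_samples) {
    stop("Impossible config: qc_every must be in [2, n_samples].", call. = FALSE)
  }
  if (cfg$n_samples < cfg$n_batches) {
    stop("Impossible config: fewer samples than batches.", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# number of run positions needed to host n study samples with a QC at every
# k-th position: positions p with p %% k == 0 are QC injections
positions_for <- function(n_study, k) {
  p <- n_study
  while (p - (p %/% k) < n_study) p <- p + 1
  p
}

#' Simulate a `metabolite_set` with known ground truth
#'
#' Generative model, in order: (1) per-feature log-normal abundances with
#' log-mean ~ U(10, 20) and log-SD ~ U(0.2, 0.8); (2) per-(batch, feature)
#' multiplicative factors `exp(N(0, batch_scale_sd))`; (3) a linear multiplicative
#' drift ramp from 1 to `1 + drift_amplitude` over each batch's run order;
#' (4) pooled-QC injections drawn from the pooled mean profile with log-SD 0.05
#' noise, carrying the same batch factor and drift; (5) sparse outliers;
#' (6) missingness (MCAR or intensity-dependent), applied to study entries;
#' (7) phenotypes from a linear predictor over the true-effect features'
#' standardized log abundances (binary via a logistic link; survival via an
#' exponential hazard with administrative censoring at the 70th percentile of
#' event times, ~30% censored). One seed drives a single RNG stream.
#'
#' @param config A [synth_config()].
#' @return A list with class `synth_data`:
#' \describe{
#'   \item{set}{the `metabolite_set` (columns `batch`, `run_order`, `qc` in the
#'     sample table; QC samples named `QC_<batch>_<position>`)}
#'   \item{phenotypes}{tibble keyed by `sample_id` with outcome (`y`, or
#'     `time`/`event`), covariates `age`, `sex` and a `group` column (= batch)}
#'   \item{truth}{ground truth: batch-factor matrix, drift amplitude matrix,
#'     true-effect features and coefficients, injected outlier and masked-entry
#'     bookkeeping}
#' }
#' @examples
#' sim <- simulate_metabolite_set(synth_config(n_samples = 40, n_features = 5,
#'                                             n_batches = 2, seed = 7))
#' sim$set
#' @export
simulate_metabolite_set <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::local_seed(config$seed)
  nf <- config$n_features
  feature_ids <- sprintf("M%03d", seq_len(nf))
  log_mean <- stats::runif(nf, 10, 20)
  log_sd <- stats::runif(nf, 0.2, 0.8)

  # allocate study samples to contiguous batches as evenly as possible
  batch_sizes <- diff(round(seq(0, config$n_samples, length.out = config$n_batches + 1)))
  batch_ids <- sprintf("B%d", seq_len(config$n_batches))

  sample_rows <- lapply(seq_len(config$n_batches), function(b) {
    P <- positions_for(batch_sizes[b], config$qc_every)
    pos <- seq_len(P)
    tibble::tibble(batch = batch_ids[b], pos_in_batch = pos,
                   qc = pos %% config$qc_every == 0, batch_len = P)
  })
  inj <- dplyr::bind_rows(sample_rows)
  inj$run_order <- seq_len(nrow(inj))
  n_study_total <- sum(!inj$qc)
  study_ids <- sprintf("S%04d", seq_len(n_study_total))
  ids <- character(nrow(inj))
  ids[!inj$qc] <- study_ids
  ids[inj$qc] <- sprintf("QC_%s_%d", inj$batch[inj$qc], inj$pos_in_batch[inj$qc])
  inj$sample_id <- ids

  # (1) base study log-abundances
  base_log <- matrix(stats::rnorm(n_study_total * nf,
                                  mean = rep(log_mean, each = n_study_total),
                                  sd = rep(log_sd, each = n_study_total)),
                     nrow = n_study_total, ncol = nf,
                     dimnames = list(study_ids, feature_ids))

  # (2) batch factors
  bf <- matrix(if (config$batch_scale_sd > 0)
                 exp(stats::rnorm(config$n_batches * nf, 0, config$batch_scale_sd))
               else 1,
               nrow = config$n_batches, ncol = nf,
               dimnames = list(batch_ids, feature_ids))

  # (3) drift multiplier per injection (linear ramp within batch)
  ramp <- ifelse(inj$batch_len > 1,
                 1 + config$drift_amplitude * (inj$pos_in_batch - 1) / (inj$batch_len - 1),
                 1)

  # pooled profile for QC injections (natural scale mean of clean study values)
  pooled <- colMeans(exp(base_log))

  assay <- matrix(NA_real_, nrow(inj), nf, dimnames = list(inj$sample_id, feature_ids))
  study_idx <- which(!inj$qc)
  assay[study_idx, ] <- exp(base_log)
  qc_idx <- which(inj$qc)
  if (length(qc_idx)) {
    qc_noise <- matrix(stats::rnorm(length(qc_idx) * nf, 0, 0.05),
                       nrow = length(qc_idx), ncol = nf)
    assay[qc_idx, ] <- rep(pooled, each = length(qc_idx)) * exp(qc_noise)
  }
  bmat <- bf[match(inj$batch, batch_ids), , drop = FALSE]
  assay <- assay * bmat * ramp

  clean_assay <- assay

  # (5) outliers among study entries
  outliers <- tibble::tibble(sample_id = character(), feature_id = character(),
                             clean_value = numeric(), value = numeric())
  if (config$outlier_rate > 0) {
    cand <- expand.grid(i = study_idx, j = seq_len(nf))
    pick <- stats::runif(nrow(cand)) < config$outlier_rate
    if (any(pick)) {
      ii <- cand$i[pick]; jj <- cand$j[pick]
      mult <- exp(config$outlier_magnitude * log_sd[jj])
      old <- assay[cbind(ii, jj)]
      assay[cbind(ii, jj)] <- old * mult
      outliers <- tibble::tibble(sample_id = inj$sample_id[ii],
                                 feature_id = feature_ids[jj],
                                 clean_value = old, value = old * mult)
    }
  }

  # (6) masking of study entries (injected outliers exempt so outlier
  # bookkeeping stays well-defined)
  masked <- tibble::tibble(sample_id = character(), feature_id = character(),
                           true_value = numeric())
  if (config$missing_rate > 0) {
    prot <- matrix(FALSE, nrow(inj), nf)
    if (nrow(outliers)) {
      prot[cbind(match(outliers$sample_id, inj$sample_id),
                 match(outliers$feature_id, feature_ids))] <- TRUE
    }
    p <- matrix(0, length(study_idx), nf)
    if (config$missing_mechanism == "MCAR") {
      p[] <- config$missing_rate
    } else {
      lx <- log(assay[study_idx, , drop = FALSE])
      q20 <- apply(lx, 2, stats::quantile, probs = 0.2, names = FALSE)
      sc <- pmax(log_sd * 0.5, 1e-8)
      # logistic in -(log intensity), midpoint at the feature's 20th percentile;
      # rescaled so the expected overall rate equals missing_rate
      z <- sweep(lx, 2, q20, "-") / rep(sc, each = length(study_idx))
      w <- stats::plogis(-z)
      p <- pmin(1, config$missing_rate * w / mean(w))
    }
    u <- matrix(stats::runif(length(study_idx) * nf), length(study_idx), nf)
    mask <- u < p & !prot[study_idx, , drop = FALSE]
    if (any(mask)) {
      mi <- which(mask, arr.ind = TRUE)
      masked <- tibble::tibble(sample_id = inj$sample_id[study_idx[mi[, 1]]],
                               feature_id = feature_ids[mi[, 2]],
                               true_value = assay[cbind(study_idx[mi[, 1]], mi[, 2])])
      assay[cbind(study_idx[mi[, 1]], mi[, 2])] <- NA_real_
    }
  }

  # (7) phenotypes from standardized clean log abundances
  true_feats <- if (config$n_true_effects > 0)
    sort(sample.int(nf, config$n_true_effects)) else integer()
  beta <- stats::setNames(rep(config$effect_size, length(true_feats)),
                          feature_ids[true_feats])
  lp <- rep(0, n_study_total)
  for (j in true_feats) lp <- lp + config$effect_size * as.vector(scale(base_log[, j]))
  age <- stats::rnorm(n_study_total, 50, 10)
  sex <- stats::rbinom(n_study_total, 1, 0.5)
  pheno <- tibble::tibble(sample_id = study_ids,
                          group = inj$batch[study_idx],
                          age = age, sex = sex)
  censor_time <- NA_real_
  if (config$outcome_kind == "continuous") {
    pheno$y <- lp + stats::rnorm(n_study_total)
  } else if (config$outcome_kind == "binary") {
    pheno$y <- stats::rbinom(n_study_total, 1, stats::plogis(lp))
  } else {
    tt <- stats::rexp(n_study_total, rate = 0.1 * exp(lp))
    censor_time <- stats::quantile(tt, 0.7, names = FALSE)
    pheno$time <- pmin(tt, censor_time)
    pheno$event <- as.integer(tt <= censor_time)
  }

  samples <- tibble::tibble(sample_id = inj$sample_id, batch = inj$batch,
                            run_order = inj$run_order, qc = inj$qc)
  features <- tibble::tibble(feature_id = feature_ids,
                             log_mean = log_mean, log_sd = log_sd)
  ms <- metabolite_set(assay, features = features, samples = samples)
  ms <- relog(ms, "simulate_metabolite_set",
              params = list(seed = config$seed, n_batches = config$n_batches,
                            missing_mechanism = config$missing_mechanism,
                            outcome_kind = config$outcome_kind))

  truth <- list(batch_factor = bf,
                drift_amplitude = matrix(config$drift_amplitude,
                                         config$n_batches, nf,
                                         dimnames = list(batch_ids, feature_ids)),
                drift_ramp = stats::setNames(ramp, inj$sample_id),
                true_features = feature_ids[true_feats],
                beta = beta,
                outliers = outliers,
                masked = masked,
                clean_assay = clean_assay,
                censor_time = censor_time,
                config = config)
  structure(list(set = ms, phenotypes = pheno, truth = truth),
            class = "synth_data")
}
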