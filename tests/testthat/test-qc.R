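test_that("missing rates are computed per axis, QC injections excluded from feature rates", {
  m <- matrix(c(1, NA, 3, NA,
                1, 2, 3, 4,
                NA, NA, NA, 4), 4, 3,
              dimnames = list(paste0("S", 1:4), paste0("M", 1:3)))
  ms <- metabolite_set(m)
  r <- missing_rates(ms)
  expect_equal(r$features$missing_rate, c(0.5, 0, 0.75))
  expect_equal(r$samples$missing_rate, c(1 / 3, 2 / 3, 1 / 3, 1 / 3))

  # with a QC flag, feature rates consider study samples only
  samp <- tibble::tibble(sample_id = paste0("S", 1:4), qc = c(FALSE, FALSE, FALSE, TRUE))
  ms_qc <- metabolite_set(m, samples = samp)
  r2 <- missing_rates(ms_qc)
  expect_equal(r2$features$missing_rate, c(1 / 3, 0, 1))

  # fully observed matrix: all rates 0
  ms0 <- toy_set(n = 3, p = 2)
  r0 <- missing_rates(ms0)
  expect_true(all(r0$features$missing_rate == 0) && all(r0$samples$missing_rate == 0))
})

test_that("missing-rate filters use strict inequality and never alter values", {
  m <- matrix(c(NA, NA, NA, 4,   # 0.75
                1, 2, NA, NA,    # 0.5
                1, 2, 3, NA), 4, 3,
              dimnames = list(paste0("S", 1:4), paste0("M", 1:3)))
  ms <- metabolite_set(m)
  f <- filter_features_by_missing(ms, threshold = 0.5)
  expect_equal(feature_data(f)$feature_id, c("M2", "M3"))
  expect_identical(assay_values(f), m[, c("M2", "M3")])

  expect_equal(ncol(filter_features_by_missing(ms, threshold = 1)), 3L)
  expect_equal(ncol(suppressWarnings(filter_features_by_missing(ms, threshold = 0))), 0L)

  # sample filter mirrors it: S3 and S4 are each missing 2 of 3 features
  s <- filter_samples_by_missing(ms, threshold = 0.5)
  expect_equal(sample_data(s)$sample_id, c("S1", "S2"))
  # boundary rate retained at its own threshold
  m2 <- matrix(c(NA, 1, NA, 2, 1, 3, 1, 4, 1, 5), 2, 5,
               dimnames = list(c("A", "B"), paste0("M", 1:5)))
  ms2 <- metabolite_set(m2) # sample A rate = 0.4
  expect_true("A" %in% sample_data(filter_samples_by_missing(ms2, 0.4))$sample_id)
})

test_that("outlier detection matches the mean +/- k sd rule with sample SD", {
  x <- c(1, 1, 1, 1, 100)
  m <- cbind(M1 = x, M2 = rep(7, 5), M3 = rep(NA_real_, 5))
  rownames(m) <- paste0("S", 1:5)
  ms <- metabolite_set(m)
  expect_equal(mean(x), 20.8)
  expect_equal(sd(x), 44.27415, tolerance = 1e-6)
  mask5 <- detect_outliers(ms, k_sd = 5)
  expect_false(any(mask5)) # |100 - 20.8| = 79.2 < 5 * 44.27
  mask1 <- detect_outliers(ms, k_sd = 1)
  expect_true(mask1["S5", "M1"])
  expect_equal(sum(mask1), 1L) # constant and all-missing columns produce no flags
})

test_that("QC injections are excluded from outlier statistics and never flagged", {
  vals <- c(10, 11, 9, 10, 1000) # last row is a wild QC injection
  m <- cbind(M1 = vals)
  rownames(m) <- paste0("S", 1:5)
  samp <- tibble::tibble(sample_id = paste0("S", 1:5),
                         qc = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  ms <- metabolite_set(m, samples = samp)
  mask <- detect_outliers(ms, k_sd = 3)
  expect_false(any(mask)) # QC row ignored; study values are tight
})

test_that("winsorize clamps to the detection boundary; to_missing adds exactly the flags", {
  set.seed(11)
  base <- rnorm(30, 100, 5)
  x <- c(base, 400, -200)
  m <- cbind(M1 = x, M2 = rnorm(32, 50, 2))
  rownames(m) <- sprintf("S%02d", seq_len(32))
  ms <- metabolite_set(m)
  mask <- detect_outliers(ms, k_sd = 3)
  expect_equal(sum(mask), 2L)
  mu <- attr(mask, "center")["M1"]; sg <- attr(mask, "spread")["M1"]

  w <- handle_outliers(ms, mask, action = "winsorize")
  expect_equal(unname(assay_values(w)["S31", "M1"]), unname(mu + 3 * sg))
  expect_equal(unname(assay_values(w)["S32", "M1"]), unname(mu - 3 * sg))
  # winsorize bound: whole processed feature within [mu - k sg, mu + k sg]
  expect_true(all(assay_values(w)[, "M1"] >= mu - 3 * sg - 1e-12 &
                  assay_values(w)[, "M1"] <= mu + 3 * sg + 1e-12))
  # untouched entries identical
  expect_identical(assay_values(w)[1:30, ], m[1:30, ])

  tm <- handle_outliers(ms, mask, action = "to_missing")
  expect_equal(sum(is.na(assay_values(tm))), sum(is.na(m)) + 2)

  # empty mask: identity plus a log entry
  none <- handle_outliers(ms, detect_outliers(ms, k_sd = 50), "winsorize")
  expect_identical(assay_values(none), m)
  expect_length(processing_log(none), length(processing_log(ms)) + 1)
})

test_that("half_min, median and zero imputation follow their rules exactly", {
  m <- cbind(M1 = c(4, 8, NA, NA), M2 = c(NA, 1, 2, 9), M3 = rep(NA_real_, 4))
  rownames(m) <- paste0("S", 1:4)
  ms <- metabolite_set(m)

  hm <- assay_values(impute_missing(ms, "half_min"))
  expect_equal(unname(hm[3:4, "M1"]), c(2, 2))
  expect_equal(unname(hm[1, "M2"]), 0.5)
  expect_true(all(is.na(hm[, "M3"]))) # fully missing stays missing

  md <- assay_values(impute_missing(ms, "median"))
  expect_equal(unname(md[3, "M1"]), 6)
  expect_equal(unname(md[1, "M2"]), 2)

  z <- assay_values(impute_missing(ms, "zero"))
  expect_equal(unname(z[3, "M1"]), 0)
  expect_equal(unname(z[, "M3"]), rep(0, 4))
  # observed values untouched by any method
  obs <- !is.na(m)
  expect_identical(hm[obs], m[obs])
  expect_identical(z[obs], m[obs])
})

test_that("KNN imputation equals the brute-force oracle on a fixed toy matrix", {
  set.seed(21)
  a <- matrix(rnorm(24, 10, 3), 6, 4,
              dimnames = list(paste0("S", 1:6), paste0("M", 1:4)))
  a[cbind(c(1, 3, 5), c(2, 4, 1))] <- NA
  ms <- metabolite_set(a)
  got <- assay_values(impute_missing(ms, "knn", knn_k = 2))
  want <- oracle_knn_impute(a, 2)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("KNN matches the oracle across many random matrices with missing blocks", {
  for (seed in 1:50) {
    set.seed(seed)
    a <- matrix(rnorm(48, 5, 2), 8, 6,
                dimnames = list(paste0("S", 1:8), paste0("M", 1:6)))
    a[sample(length(a), 10)] <- NA
    ms <- metabolite_set(a)
    got <- assay_values(impute_missing(ms, "knn", knn_k = 3))
    want <- oracle_knn_impute(a, 3)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("imputation completeness: observed-once features end with no missing entries", {
  for (method in c("half_min", "median", "zero", "knn")) {
    sim <- simulate_metabolite_set(synth_config(n_samples = 40, n_features = 8,
                                                missing_rate = 0.25, seed = 13))
    out <- assay_values(impute_missing(sim$set, method))
    had_obs <- colSums(!is.na(assay_values(sim$set))) > 0
    expect_false(anyNA(out[, had_obs]))
    if (method == "half_min") {
      mins <- apply(assay_values(sim$set), 2, min, na.rm = TRUE)
      was_na <- is.na(assay_values(sim$set))
      for (j in which(had_obs)) {
        expect_true(all(out[was_na[, j], j] <= mins[j]))
      }
    }
  }
})

test_that("outlier recovery on synthetic data: recall >= 0.9 at 5 SD for magnitude-8 spikes", {
  sim <- simulate_metabolite_set(synth_config(
    n_samples = 300, n_features = 50, n_batches = 1, batch_scale_sd = 0,
    drift_amplitude = 0, missing_rate = 0, outlier_rate = 0.005,
    outlier_magnitude = 8, seed = 17))
  truth <- sim$truth$outliers
  expect_gt(nrow(truth), 20)
  # detection on the log scale, where the generative model is additive
  mask <- detect_outliers(log_transform(sim$set), k_sd = 5)
  hits <- mask[cbind(truth$sample_id, truth$feature_id)]
  expect_gte(mean(hits), 0.9)
})

test_that("qc_pipeline equals the manual composition of its four steps", {
  sim <- simulate_metabolite_set(synth_config(n_samples = 120, n_features = 15,
                                              n_batches = 2, missing_rate = 0.2,
                                              outlier_rate = 0.01, seed = 19))
  res <- suppressWarnings(qc_pipeline(sim$set))
  manual <- sim$set |>
    filter_features_by_missing(0.5) |>
    filter_samples_by_missing(0.5)
  manual <- suppressWarnings(
    handle_outliers(manual, detect_outliers(manual, 5), "winsorize"))
  manual <- impute_missing(manual, "half_min")
  expect_sets_equal(res$set, manual)
  # same operations in the audit trail (timestamps aside)
  expect_equal(log_ops(res$set), log_ops(manual))
})

test_that("qc_pipeline on a clean set is the identity with four log entries", {
  ms <- toy_set(n = 10, p = 4, seed = 23)
  res <- qc_pipeline(ms)
  expect_identical(assay_values(res$set), assay_values(ms))
  expect_length(processing_log(res$set), length(processing_log(ms)) + 4)
  expect_equal(res$report$n_imputed, 0)
})

test_that("impute_method none leaves missing values and reports zero imputed", {
  ms <- toy_set(n = 8, p = 3, missing = 4, seed = 29)
  res <- qc_pipeline(ms, qc_params(impute_method = "none", outlier_action = "none"))
  expect_gt(sum(is.na(assay_values(res$set))), 0)
  expect_equal(res$report$n_imputed, 0)
  expect_equal(res$report$outlier_action, "none")
})
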