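make_linear_sim <- function(n = 200, p = 5, beta = 1.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rlnorm(n * p, 8, 0.5), n, p,
              dimnames = list(sprintf("S%03d", 1:n), paste0("M", 1:p)))
  ms <- metabolite_set(m)
  z1 <- as.vector(scale(log(m[, 1])))
  pheno <- tibble::tibble(sample_id = rownames(m),
                          age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                          y = beta * z1 + 0.02 * (50 - rnorm(n, 50, 10)) + rnorm(n))
  list(ms = ms, pheno = pheno)
}

test_that("linear estimates and SEs match closed-form normal equations", {
  for (seed in 1:10) {
    d <- make_linear_sim(n = 60, p = 3, beta = 0.8, seed = seed)
    ms_log <- log_transform(d$ms)
    res <- regress_features(ms_log, d$pheno, model = "linear", outcome = "y",
                            covariates = c("age", "sex"))
    for (j in 1:3) {
      o <- oracle_ols(d$pheno$y, log(assay_values(d$ms)[, j]),
                      covars = cbind(d$pheno$age, d$pheno$sex))
      expect_equal(res$estimate[j], o$estimate, tolerance = 1e-8)
      expect_equal(res$std_error[j], o$se, tolerance = 1e-8)
    }
  }
})

test_that("a strong causal feature is recovered with a tight estimate and top rank", {
  d <- make_linear_sim(n = 500, p = 30, beta = 2, seed = 3)
  res <- regress_features(log_transform(d$ms), d$pheno, model = "linear",
                          outcome = "y")
  top <- volcano_table(res)
  expect_equal(top$feature_id[1], "M1")
  est <- res$estimate[res$feature_id == "M1"]
  expect_gt(est, 1.8); expect_lt(est, 2.2)
  expect_lt(res$p_value[res$feature_id == "M1"], 1e-10)
})

test_that("results are identical for 1 and 8 workers", {
  d <- make_linear_sim(n = 120, p = 20, seed = 5)
  r1 <- regress_features(log_transform(d$ms), d$pheno, "linear", outcome = "y",
                         covariates = "age", workers = 1)
  r8 <- regress_features(log_transform(d$ms), d$pheno, "linear", outcome = "y",
                         covariates = "age", workers = 8)
  expect_identical(as.data.frame(r1), as.data.frame(r8))
})

test_that("complete cases are taken per feature and QC injections excluded", {
  sim <- simulate_metabolite_set(synth_config(n_samples = 80, n_features = 5,
                                              missing_rate = 0.2, seed = 7))
  res <- regress_features(log_transform(sim$set), sim$phenotypes,
                          model = "linear", outcome = "y")
  a <- assay_values(sim$set)
  st <- !sample_data(sim$set)$qc
  for (j in seq_len(5)) {
    expect_equal(res$n[j], sum(!is.na(a[st, j])))
  }
  expect_true(all(res$n <= sum(st)))
})

test_that("constant metabolites are skipped with a status, not dropped", {
  set.seed(9)
  m <- cbind(M1 = rep(5, 50), M2 = rlnorm(50, 8, 0.4))
  rownames(m) <- sprintf("S%02d", 1:50)
  pheno <- tibble::tibble(sample_id = rownames(m), y = rnorm(50))
  res <- regress_features(metabolite_set(m), pheno, "linear", outcome = "y")
  expect_equal(nrow(res), 2)
  expect_match(res$status[res$feature_id == "M1"], "zero variance")
  expect_true(is.na(res$estimate[res$feature_id == "M1"]))
  expect_equal(res$status[res$feature_id == "M2"], "ok")
  # failed fits excluded from the BH family
  expect_true(is.na(res$p_adjust[res$feature_id == "M1"]))
})

test_that("logistic and Cox families recover simulated effects", {
  set.seed(13)
  n <- 1000
  m <- cbind(M1 = rlnorm(n, 8, 0.5), M2 = rlnorm(n, 8, 0.5))
  rownames(m) <- sprintf("S%04d", 1:n)
  z <- as.vector(scale(log(m[, 1])))
  # logistic: true log-odds 1 per SD
  yb <- rbinom(n, 1, plogis(z))
  ph_b <- tibble::tibble(sample_id = rownames(m), y = yb)
  rb <- regress_features(log_transform(metabolite_set(m)), ph_b, "logistic",
                         outcome = "y")
  est_b <- rb$estimate[rb$feature_id == "M1"]
  expect_gt(est_b, 0.75); expect_lt(est_b, 1.25)
  expect_lt(rb$p_value[rb$feature_id == "M1"], 1e-8)

  # cox: true log-hazard 0.5 per SD, ~30% administrative censoring
  tt <- rexp(n, rate = 0.1 * exp(0.5 * z))
  cens <- quantile(tt, 0.7)
  ph_c <- tibble::tibble(sample_id = rownames(m),
                         time = pmin(tt, cens), event = as.integer(tt <= cens))
  rc <- regress_features(log_transform(metabolite_set(m)), ph_c, "cox",
                         time = "time", event = "event")
  est_c <- rc$estimate[rc$feature_id == "M1"]
  expect_gt(est_c, 0.4); expect_lt(est_c, 0.6)
  expect_equal(rc$outcome[1], "time/event")
})

test_that("mixed model keeps type-I error near nominal where pooled OLS fails", {
  set.seed(17)
  n_groups <- 25; per <- 8; n <- n_groups * per
  grp <- rep(sprintf("G%02d", 1:n_groups), each = per)
  u <- rnorm(n_groups) # group intercepts, ICC = 0.5
  y <- u[match(grp, sprintf("G%02d", 1:n_groups))] + rnorm(n)
  p_feat <- 150
  # null metabolites that cluster by group (the trap for pooled OLS)
  mg <- matrix(rnorm(n_groups * p_feat), n_groups, p_feat)
  m <- exp(8 + mg[match(grp, sprintf("G%02d", 1:n_groups)), ] +
             matrix(rnorm(n * p_feat, sd = 1), n, p_feat))
  dimnames(m) <- list(sprintf("S%03d", 1:n), sprintf("M%03d", 1:p_feat))
  ms <- log_transform(metabolite_set(m))
  pheno <- tibble::tibble(sample_id = rownames(m), y = y, site = grp)

  r_lmm <- suppressMessages(
    regress_features(ms, pheno, "lmm", outcome = "y", group = "site"))
  r_ols <- regress_features(ms, pheno, "linear", outcome = "y")
  t1_lmm <- mean(r_lmm$p_value[r_lmm$status == "ok"] < 0.05)
  t1_ols <- mean(r_ols$p_value < 0.05)
  expect_gte(t1_lmm, 0.0); expect_lte(t1_lmm, 0.09)
  expect_gt(t1_ols, t1_lmm)
  expect_gt(t1_ols, 0.09)
})

test_that("logistic mixed model runs and flags its metabolite term", {
  set.seed(19)
  n_groups <- 20; per <- 15; n <- n_groups * per
  grp <- rep(sprintf("G%02d", 1:n_groups), each = per)
  u <- rnorm(n_groups, sd = 1)
  m <- cbind(M1 = rlnorm(n, 8, 0.5))
  rownames(m) <- sprintf("S%03d", 1:n)
  z <- as.vector(scale(log(m[, 1])))
  y <- rbinom(n, 1, plogis(u[match(grp, unique(grp))] + 1.2 * z))
  pheno <- tibble::tibble(sample_id = rownames(m), y = y, site = grp)
  res <- regress_features(log_transform(metabolite_set(m)), pheno,
                          "logistic_lmm", outcome = "y", group = "site")
  expect_equal(res$status, "ok")
  expect_gt(res$estimate, 0.6)
  expect_lt(res$p_value, 1e-4)
})

test_that("Wald 95% CIs for the linear estimate cover the truth at the right rate", {
  beta <- 0.5
  covered <- logical(600)
  for (s in seq_along(covered)) {
    set.seed(2000 + s)
    n <- 80
    x <- rlnorm(n, 8, 0.5)
    y <- beta * as.vector(scale(log(x))) + rnorm(n)
    m <- cbind(M1 = x); rownames(m) <- sprintf("S%03d", 1:n)
    res <- regress_features(log_transform(metabolite_set(m)),
                            tibble::tibble(sample_id = rownames(m), y = y),
                            "linear", outcome = "y")
    lo <- res$estimate - 1.96 * res$std_error
    hi <- res$estimate + 1.96 * res$std_error
    covered[s] <- lo <= beta && beta <= hi
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("adjust_pvalues matches hand BH and handles NAs and bonferroni", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.002, 0.04, NA, 0.9, 0.013)
  adj <- adjust_pvalues(p)
  expect_true(is.na(adj[3]))
  expect_equal(adj[!is.na(p)], oracle_bh(p[!is.na(p)]))
  expect_equal(adjust_pvalues(0.2), 0.2) # single p unchanged
  expect_equal(adjust_pvalues(c(0.4, 0.7), "bonferroni"), c(0.8, 1.0))
  expect_error(adjust_pvalues(c(0.5, 1.7)), "0, 1")
  # BH never below the raw p
  set.seed(23)
  p2 <- runif(50)
  expect_true(all(adjust_pvalues(p2) >= p2))
})

test_that("volcano outputs highlight only real signal", {
  d <- make_linear_sim(n = 300, p = 40, beta = 2, seed = 29)
  res <- regress_features(log_transform(d$ms), d$pheno, "linear", outcome = "y")
  tab_path <- tempfile(fileext = ".csv")
  tab <- volcano_table(res, path = tab_path)
  expect_true(file.exists(tab_path))
  expect_equal(tab$feature_id[1], "M1")
  p <- plot_volcano(res)
  expect_s3_class(p, "ggplot")

  # all-null scan: no BH hits (seed fixed; FDR-controlled display)
  set.seed(31)
  n <- 200; pfeat <- 50
  m0 <- matrix(rlnorm(n * pfeat, 8, 0.5), n, pfeat,
               dimnames = list(sprintf("S%03d", 1:n), sprintf("M%02d", 1:pfeat)))
  res0 <- regress_features(metabolite_set(m0),
                           tibble::tibble(sample_id = rownames(m0), y = rnorm(n)),
                           "linear", outcome = "y")
  expect_equal(sum(res0$p_adjust < 0.05, na.rm = TRUE), 0)
})

test_that("input validation names the problem", {
  d <- make_linear_sim(n = 30, p = 2, seed = 37)
  expect_error(regress_features(d$ms, d$pheno, "linear"), "outcome")
  expect_error(regress_features(d$ms, d$pheno, "cox", outcome = "y"), "time")
  expect_error(regress_features(d$ms, d$pheno, "lmm", outcome = "y"), "group")
  expect_error(regress_features(d$ms, d$pheno, "linear", outcome = "nope"), "nope")
  expect_error(regress_features(d$ms, d$pheno, "linear", outcome = "y",
                                features = "MX"), "MX")
})
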