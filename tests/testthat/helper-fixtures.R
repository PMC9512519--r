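# Small in-code fixtures shared across tests.

toy_set <- function(n = 3, p = 2, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(rlnorm(n * p, meanlog = 5), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("M", seq_len(p))))
  if (missing > 0) {
    idx <- sample(length(m), missing)
    m[idx] <- NA_real_
  }
  metabolite_set(m)
}

# set with explicit batch / run-order / QC structure for normalization tests
bench_set <- function(values, batch, run_order, qc, feature_ids = NULL) {
  n <- length(batch)
  m <- as.matrix(values)
  if (is.null(feature_ids)) {
    feature_ids <- if (!is.null(colnames(m))) colnames(m)
                   else paste0("M", seq_len(ncol(m)))
  }
  dimnames(m) <- list(sprintf("S%02d", seq_len(n)), feature_ids)
  metabolite_set(m, samples = tibble::tibble(
    sample_id = rownames(m), batch = batch,
    run_order = as.integer(run_order), qc = qc))
}

# Write a three-sheet xlsx via the system python's openpyxl (no R xlsx writer
# is available); sheets is a named list of data frames.
write_fixture_xlsx <- function(path, sheets) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop("python not on PATH; cannot build xlsx fixture")
  csvs <- vapply(seq_along(sheets), function(i) {
    f <- tempfile(fileext = ".csv")
    utils::write.csv(sheets[[i]], f, row.names = FALSE, na = "")
    f
  }, "")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import csv, sys",
    "from openpyxl import Workbook",
    "wb = Workbook(); wb.remove(wb.active)",
    sprintf("names = %s", paste0("[", paste(sprintf("'%s'", names(sheets)), collapse = ","), "]")),
    sprintf("files = %s", paste0("[", paste(sprintf("'%s'", csvs), collapse = ","), "]")),
    "for name, f in zip(names, files):",
    "    ws = wb.create_sheet(title=name)",
    "    with open(f) as fh:",
    "        for row in csv.reader(fh):",
    "            ws.append([c if c != '' else None for c in row])",
    sprintf("wb.save('%s')", path)
  ), script)
  status <- system2(py, script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(path)) stop("xlsx fixture build failed: ", paste(status, collapse = "\n"))
  invisible(path)
}

fixture_tables <- function() {
  assay <- data.frame(
    sample_id = paste0("S", 1:4),
    M1 = c(10.5, 20.25, NA, 40),
    M2 = c(1e6, 2e6, 3e6, 4e6),
    M3 = c(5, NA, 15, 20),
    check.names = FALSE
  )
  features <- data.frame(feature_id = c("M1", "M2", "M3"),
                         pathway = c("lipid", "amino acid", "lipid"))
  samples <- data.frame(sample_id = paste0("S", 1:4),
                        batch = c("B1", "B1", "B2", "B2"),
                        qc = c(FALSE, FALSE, FALSE, TRUE))
  list(assay = assay, features = features, samples = samples)
}

write_fixture_csvs <- function(dir) {
  tabs <- fixture_tables()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(data = file.path(dir, "assay.csv"),
                features = file.path(dir, "features.csv"),
                samples = file.path(dir, "samples.csv"))
  utils::write.csv(tabs$assay, paths$data, row.names = FALSE, na = "")
  utils::write.csv(tabs$features, paths$features, row.names = FALSE, na = "")
  utils::write.csv(tabs$samples, paths$samples, row.names = FALSE, na = "")
  paths
}

# data-field comparison ignoring log timestamps
expect_sets_equal <- function(a, b, tolerance = 0) {
  expect_equal(assay_values(a), assay_values(b), tolerance = tolerance)
  expect_equal(as.data.frame(feature_data(a)), as.data.frame(feature_data(b)),
               tolerance = tolerance)
  expect_equal(as.data.frame(sample_data(a)), as.data.frame(sample_data(b)),
               tolerance = tolerance)
}

log_ops <- function(ms) vapply(processing_log(ms), function(e) e$op, "")
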