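#' @importFrom rlang %||% .data
NULL

# Shared numeric parser so every loader treats cells identically.
# Missing tokens: empty, NA, NaN, N/A (case-insensitive). Numbers are parsed
# in the C locale; anything else (including thousands separators) is an error
# rather than a guess.
MISSING_TOKENS <- c("", "na", "nan", "n/a")

parse_assay_numeric <- function(x, context = "assay") {
  x <- trimws(as.character(x))
  is_missing <- is.na(x) | tolower(x) %in% MISSING_TOKENS
  out <- rep(NA_real_, length(x))
  to_parse <- which(!is_missing)
  if (length(to_parse)) {
    vals <- suppressWarnings(as.numeric(x[to_parse]))
    bad <- is.na(vals)
    if (any(bad)) {
      stop(sprintf("Non-numeric %s cell(s): %s", context,
                   id_preview(unique(x[to_parse][bad]))), call. = FALSE)
    }
    out[to_parse] <- vals
  }
  out
}

# CSVs carry no type information; restore integer-valued columns as integer so
# round-trips are stable (documented normalisation).
normalize_annotation_types <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) {
      ok <- !is.na(col)
      if (any(ok) && all(col[ok] == trunc(col[ok])) &&
          all(abs(col[ok]) < .Machine$integer.max)) {
        return(as.integer(col))
      }
    }
    col
  })
  df
}

assay_from_wide <- function(df, origin) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (ncol(df) < 2) {
    stop(sprintf("%s: need a sample-ID column plus at least one metabolite column.",
                 origin), call. = FALSE)
  }
  feat_ids <- names(df)[-1]
  if (names(df)[1] %in% feat_ids) {
    stop(sprintf("%s: first column header '%s' (sample IDs) duplicates a metabolite ID.",
                 origin, names(df)[1]), call. = FALSE)
  }
  sample_ids <- check_key(as.character(df[[1]]), "sample")
  m <- vapply(seq_along(feat_ids), function(j) {
    parse_assay_numeric(df[[j + 1]], context = sprintf("assay column '%s'", feat_ids[j]))
  }, numeric(nrow(df)))
  m <- matrix(m, nrow = nrow(df), ncol = length(feat_ids),
              dimnames = list(sample_ids, feat_ids))
  m
}

key_table <- function(df, key_candidates, key_out, origin) {
  df <- tibble::as_tibble(df)
  hit <- intersect(key_candidates, names(df))
  if (length(hit)) {
    names(df)[names(df) == hit[1]] <- key_out
  } else {
    names(df)[1] <- key_out
  }
  df[[key_out]] <- as.character(df[[key_out]])
  df <- normalize_annotation_types(df)
  if (!nrow(df)) stop(sprintf("%s: empty table.", origin), call. = FALSE)
  df
}

#' Read a three-sheet workbook into a `metabolite_set`
#'
#' Expects the layout common to vendor exports: one sheet of wide assay data
#' whose first column holds the sample IDs and whose remaining column headers
#' are metabolite IDs; one metabolite-annotation sheet; one sample-annotation
#' sheet. Blank cells and the tokens `NA`, `NaN`, `N/A` (any case) become
#' missing values.
#'
#' @param path Path to an `.xlsx` workbook.
#' @param data_sheet,feature_sheet,sample_sheet Sheet index (1-based) or name
#'   for the assay, feature-annotation and sample-annotation sheets. Must be
#'   three distinct sheets.
#' @return A `metabolite_set`.
#' @seealso [read_metabolite_delimited()] for the equivalent CSV/TSV layout;
#'   both loaders share one cell parser and produce identical sets from
#'   equivalent content.
#' @export
read_metabolite_workbook <- function(path, data_sheet = 1, feature_sheet = 2,
                                     sample_sheet = 3) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  if (length(unique(list(data_sheet, feature_sheet, sample_sheet))) != 3) {
    stop("data_sheet, feature_sheet and sample_sheet must be three distinct sheets.",
         call. = FALSE)
  }
  read_sheet <- function(sheet) {
    df <- readxl::read_excel(path, sheet = sheet, col_types = "text",
                             .name_repair = "minimal")
    as.data.frame(df, stringsAsFactors = FALSE)
  }
  assay <- assay_from_wide(read_sheet(data_sheet), origin = basename(path))
  features <- key_table(retype_text_table(read_sheet(feature_sheet)),
                        c("feature_id", "featureID", "metabolite"), "feature_id",
                        "feature sheet")
  samples <- key_table(retype_text_table(read_sheet(sample_sheet)),
                       c("sample_id", "sampleID"), "sample_id", "sample sheet")
  ms <- metabolite_set(assay, features = features, samples = samples)
  relog(ms, "read_metabolite_workbook",
        params = list(path = basename(path), data_sheet = data_sheet,
                      feature_sheet = feature_sheet, sample_sheet = sample_sheet))
}

# Annotation sheets are read as text (shared parser); re-type columns the way
# a delimited reader would: numeric if all non-missing cells parse, logical if
# all are TRUE/FALSE, otherwise character.
retype_text_table <- function(df) {
  df[] <- lapply(df, function(col) {
    x <- trimws(as.character(col))
    miss <- is.na(x) | tolower(x) %in% MISSING_TOKENS
    x[miss] <- NA_character_
    obs <- x[!miss]
    if (!length(obs)) return(rep(NA_character_, length(x)))
    if (all(toupper(obs) %in% c("TRUE", "FALSE", "T", "F"))) {
      out <- rep(NA, length(x))
      out[!miss] <- toupper(obs) %in% c("TRUE", "T")
      return(out)
    }
    num <- suppressWarnings(as.numeric(obs))
    if (!anyNA(num)) {
      out <- rep(NA_real_, length(x))
      out[!miss] <- num
      return(out)
    }
    x
  })
  df
}

relog <- function(ms, op, params) {
  counts <- ms$log[[1]]$counts
  ms$log <- list()
  append_log(ms, op, params = params, counts = counts)
}

detect_delim <- function(path) {
  switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", txt = "\t", ",")
}

read_delim_text <- function(path, delimiter) {
  if (!file.exists(path)) stop(sprintf("File not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop(sprintf("%s: empty file.", basename(path)), call. = FALSE)
  parsed <- lapply(lines, function(l) scan(text = l, what = character(), sep = delimiter,
                                           quote = "\"", quiet = TRUE,
                                           blank.lines.skip = FALSE, strip.white = FALSE))
  widths <- lengths(parsed)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("%s: line %d has %d fields, expected %d.",
                 basename(path), bad, widths[bad], widths[1]), call. = FALSE)
  }
  header <- parsed[[1]]
  body <- parsed[-1]
  df <- as.data.frame(do.call(rbind, body), stringsAsFactors = FALSE)
  if (!length(body)) df <- as.data.frame(matrix(character(), 0, length(header)),
                                         stringsAsFactors = FALSE)
  names(df) <- header
  df
}

#' Read a `metabolite_set` from delimited text files
#'
#' Reads the wide assay table (first column sample IDs, remaining headers
#' metabolite IDs) plus optional feature- and sample-annotation tables. The
#' delimiter is inferred from the extension (`.csv` comma; `.tsv`/`.txt` tab)
#' unless given. Ragged rows are a parse error with the line number. When the
#' annotation paths are omitted, minimal ID-only tables are generated.
#'
#' @param data_path Path to the assay table.
#' @param feature_path,sample_path Optional annotation table paths.
#' @param delimiter Field separator; `NULL` to infer from `data_path`.
#' @return A `metabolite_set`.
#' @export
read_metabolite_delimited <- function(data_path, feature_path = NULL,
                                      sample_path = NULL, delimiter = NULL) {
  delim <- delimiter %||% detect_delim(data_path)
  assay <- assay_from_wide(read_delim_text(data_path, delim),
                           origin = basename(data_path))
  features <- NULL
  if (!is.null(feature_path)) {
    features <- key_table(retype_text_table(read_delim_text(feature_path, delim)),
                          c("feature_id", "featureID", "metabolite"), "feature_id",
                          basename(feature_path))
  }
  samples <- NULL
  if (!is.null(sample_path)) {
    samples <- key_table(retype_text_table(read_delim_text(sample_path, delim)),
                         c("sample_id", "sampleID"), "sample_id",
                         basename(sample_path))
  }
  ms <- metabolite_set(assay, features = features, samples = samples)
  relog(ms, "read_metabolite_delimited",
        params = list(data_path = basename(data_path)))
}

#' Write a `metabolite_set` to a directory of plain-text files
#'
#' Writes `assay.csv` (wide, first column `sample_id`), `features.csv`,
#' `samples.csv` and `log.json`. Numeric values are written with full
#' round-trip precision, and missing values as blank cells, so
#' [read_metabolite_delimited()] on the outputs reproduces the set exactly.
#'
#' @param ms A `metabolite_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_metabolite_set <- function(ms, dir) {
  stopifnot(is_metabolite_set(ms))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("Cannot create directory: %s", dir), call. = FALSE)
  paths <- c(assay = file.path(dir, "assay.csv"),
             features = file.path(dir, "features.csv"),
             samples = file.path(dir, "samples.csv"),
             log = file.path(dir, "log.json"))
  assay_df <- tibble::as_tibble(ms$assay)
  assay_df <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(ms$assay)),
                               assay_df)
  ok <- tryCatch({
    readr::write_csv(assay_df, paths[["assay"]], na = "")
    readr::write_csv(ms$features, paths[["features"]], na = "")
    readr::write_csv(ms$samples, paths[["samples"]], na = "")
    jsonlite::write_json(ms$log, paths[["log"]], auto_unbox = TRUE, null = "null",
                         digits = NA)
    TRUE
  }, error = function(e) {
    stop(sprintf("Failed writing to %s: %s", dir, conditionMessage(e)), call. = FALSE)
  })
  invisible(paths)
}

#' Read a directory written by [write_metabolite_set()]
#'
#' @param dir Directory containing `assay.csv`, `features.csv`, `samples.csv`
#'   (and optionally `log.json`, restored into `misc_data(.)$restored_log`).
#' @return A `metabolite_set`.
#' @export
read_metabolite_dir <- function(dir) {
  ms <- read_metabolite_delimited(
    file.path(dir, "assay.csv"),
    feature_path = file.path(dir, "features.csv"),
    sample_path = file.path(dir, "samples.csv")
  )
  logp <- file.path(dir, "log.json")
  if (file.exists(logp)) {
    ms$misc$restored_log <- jsonlite::read_json(logp, simplifyVector = FALSE)
  }
  ms
}
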