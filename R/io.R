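# File-format contracts. All tables are UTF-8 CSV/TSV with a header row,
# "." decimal separator, no locale dependence; unknown age is an empty
# field. Gene and sample identifiers are opaque strings.

.read_table_checked <- function(path, required, sep = ",", what = "table") {
  .check(file.exists(path), sprintf("file not found: %s", path), "mozage_input_error")
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                      check.names = FALSE, quote = "\"", comment.char = ""),
    error = function(e) {
      .err(sprintf("malformed %s in %s: %s", what, path, conditionMessage(e)),
           "mozage_input_error")
    })
  missing_cols <- setdiff(required, names(df))
  .check(length(missing_cols) == 0,
         sprintf("%s %s is missing column(s): %s", what, path,
                 paste(missing_cols, collapse = ", ")),
         "mozage_input_error")
  df
}

#' Read / write a long-format Ct table
#'
#' Columns: `sample_id`, `gene_id`, `replicate`, `ct`.
#'
#' @param path CSV file path.
#' @return data frame (validated).
#' @export
read_ct_table <- function(path) {
  df <- .read_table_checked(path, c("sample_id", "gene_id", "replicate", "ct"),
                            what = "Ct table")
  df$ct <- as.numeric(df$ct)
  .validate_ct_table(df)
  df
}

#' @rdname read_ct_table
#' @param ct the Ct table to write.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct[, c("sample_id", "gene_id", "replicate", "ct")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' Columns: `sample_id`, `sex` (F/M), `age_days` (non-negative integer;
#' empty = unknown, for samples to be predicted).
#'
#' @param path CSV file path.
#' @return data frame with `age_days` numeric (NA = unknown).
#' @export
read_sample_meta <- function(path) {
  df <- .read_table_checked(path, c("sample_id", "sex", "age_days"),
                            what = "sample metadata")
  df$age_days <- suppressWarnings(as.numeric(df$age_days))
  .check(!anyDuplicated(df$sample_id), "duplicated sample_id in metadata",
         "mozage_input_error")
  .check(all(df$sex %in% c("F", "M")), "sex must be F or M", "mozage_input_error")
  .check(all(is.na(df$age_days) | df$age_days >= 0),
         "age_days must be non-negative or empty", "mozage_input_error")
  df
}

#' @rdname read_sample_meta
#' @param meta the metadata table to write.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.csv(meta[, c("sample_id", "sex", "age_days")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' First column `gene_id`; remaining columns are array ids; values are raw
#' fluorescence.
#'
#' @param path TSV file path.
#' @return numeric matrix, gene ids in rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- .read_table_checked(path, "gene_id", sep = "\t", what = "expression matrix")
  .check(ncol(df) >= 2, "expression matrix needs at least one array column",
         "mozage_input_error")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  .validate_expr(m)
}

#' @rdname read_expression_tsv
#' @param expr matrix to write (genes x arrays).
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read array metadata (array_id, age_days, sex)
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_array_meta <- function(path) {
  df <- .read_table_checked(path, c("array_id", "age_days", "sex"),
                            what = "array metadata")
  df$age_days <- as.numeric(df$age_days)
  df
}

#' Serialize / restore a fitted age model
#'
#' Plain-text `key = value` format so a calibration fitted in one session
#' can reproduce predictions in another; the round trip is lossless (all
#' numbers are written with 17 significant digits).
#'
#' @param model an `age_model`.
#' @param path output file.
#' @export
write_age_model <- function(model, path) {
  .check(inherits(model, "age_model"), "model must be an age_model")
  red <- model$redundancy
  lines <- c(
    "format = mozage_age_model_v1",
    paste0("sex = ", ifelse(is.na(model$sex_label), "", model$sex_label)),
    paste0("n = ", model$n),
    paste0("alpha = ", .fmt_num(model$alpha)),
    paste0("beta = ", .fmt_num(model$beta)),
    paste0("r_squared = ", .fmt_num(model$r_squared)),
    paste0("canonical_correlation = ", .fmt_num(red$canonical_correlation)),
    paste0("genes = ", paste(red$gene_ids, collapse = ",")),
    paste0("mu = ", paste(.fmt_num(red$mu), collapse = ",")),
    paste0("s = ", paste(.fmt_num(red$s), collapse = ",")),
    paste0("w = ", paste(.fmt_num(red$w), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_age_model
#' @return `read_age_model()` returns the restored `age_model` (without the
#'   training variate scores, which are not needed for prediction).
#' @export
read_age_model <- function(path) {
  .check(file.exists(path), sprintf("file not found: %s", path), "mozage_input_error")
  lines <- readLines(path)
  kv <- regmatches(lines, regexpr(" = ", lines, fixed = TRUE), invert = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", "")
  get <- function(k) {
    .check(k %in% keys, sprintf("model file %s is missing key '%s'", path, k),
           "mozage_input_error")
    vals[match(k, keys)]
  }
  .check(identical(get("format"), "mozage_age_model_v1"),
         "unrecognized model file format", "mozage_input_error")
  nums <- function(k) as.numeric(strsplit(get(k), ",", fixed = TRUE)[[1]])
  red <- structure(
    list(gene_ids = strsplit(get("genes"), ",", fixed = TRUE)[[1]],
         mu = nums("mu"), s = nums("s"), w = nums("w"),
         canonical_correlation = as.numeric(get("canonical_correlation")),
         variate = NULL, n = as.integer(get("n"))),
    class = "redundancy_model")
  sex <- get("sex")
  structure(
    list(redundancy = red, alpha = as.numeric(get("alpha")),
         beta = as.numeric(get("beta")), r_squared = as.numeric(get("r_squared")),
         n = as.integer(get("n")),
         sex_label = if (nzchar(sex)) sex else NA_character_),
    class = "age_model")
}

#' Read a flat key = value configuration file
#'
#' One `key = value` pair per line; blank lines and `#` comments ignored.
#' Known numeric keys are converted; everything else stays character.
#' Defaults are the screening / assay settings: `alpha = 0.01`,
#' `r_up = 0.8`, `r_down = -0.4`, `fc_min = 4`, `signal_percentile = 20`,
#' `qc_ct_sd = 0.5`, `bootstrap_b = 1000`, `seed = 1`,
#' `reference_gene_id = "AGAP010592-RA"`.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(alpha = 0.01, r_up = 0.8, r_down = -0.4, fc_min = 4,
                   signal_percentile = 20, qc_ct_sd = 0.5, bootstrap_b = 1000,
                   seed = 1, reference_gene_id = "AGAP010592-RA")
  if (is.null(path)) return(defaults)
  .check(file.exists(path), sprintf("file not found: %s", path), "mozage_input_error")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  bad <- which(!grepl("=", lines, fixed = TRUE))
  .check(length(bad) == 0,
         sprintf("config line %d is not 'key = value'", bad[1]), "mozage_input_error")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  cfg <- defaults
  numeric_keys <- c("alpha", "r_up", "r_down", "fc_min", "signal_percentile",
                    "qc_ct_sd", "bootstrap_b", "seed")
  for (i in seq_along(keys)) {
    cfg[[keys[i]]] <- if (keys[i] %in% numeric_keys) as.numeric(vals[i]) else vals[i]
  }
  cfg
}

#' Write a run manifest
#'
#' Records, next to every pipeline output, what produced it: the
#' subcommand, configuration values, seed, package and R versions and a
#' timestamp, as flat `key = value` lines. The manifest plus the input
#' files are sufficient to re-run the step.
#'
#' @param path manifest file path.
#' @param command subcommand or function name.
#' @param params named list of parameter values (scalars).
#' @export
write_manifest <- function(path, command, params = list()) {
  lines <- c(paste0("command = ", command),
             paste0("mozage_version = ", as.character(utils::packageVersion("mozage"))),
             paste0("r_version = ", R.version.string),
             paste0("timestamp = ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
             vapply(names(params),
                    function(k) paste0(k, " = ", paste(params[[k]], collapse = ",")),
                    ""))
  writeLines(lines, path)
  invisible(path)
}
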