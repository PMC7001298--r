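## Flat-file schemas.  All tables are headed CSV; numeric columns are
## written with 17 significant digits so re-parsing reproduces the
## in-memory values exactly.

.schemas <- list(
  counts = c("sample_id", "line_id", "generation", "snp_id",
             "count_HI", "count_HII"),
  design = c("line_id", "start_freq", "environment", "replicate"),
  freqs = c("line_id", "generation", "f_HI"),
  truth = c("line_id", "generation", "true_p", "census")
)

.validationError <- function(...) {
  stop(structure(class = c("validationError", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.checkSchema <- function(df, what, path = NULL) {
  want <- .schemas[[what]]
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    .validationError(what, " table", if (!is.null(path)) paste0(" '", path,
                     "'"), " lacks column(s): ", paste(missing,
                     collapse = ", "))
  }
  df[, want, drop = FALSE]
}

.checkNonNegInt <- function(df, cols, what) {
  for (cl in cols) {
    x <- df[[cl]]
    bad <- which(!is.finite(x) | x < 0 | x != round(x))
    if (length(bad)) {
      .validationError(what, " column '", cl, "' must hold non-negative ",
                       "integers (first bad row: ", bad[1], ")")
    }
  }
  invisible(df)
}

.validateCountsDf <- function(df, path = NULL) {
  df <- .checkSchema(df, "counts", path)
  .checkNonNegInt(df, c("generation", "count_HI", "count_HII"), "counts")
  df
}

.validateDesignDf <- function(df, path = NULL) {
  df <- .checkSchema(df, "design", path)
  if (anyDuplicated(df$line_id)) {
    .validationError("design has duplicated line_id")
  }
  if (any(!is.finite(df$start_freq) | df$start_freq < 0 | df$start_freq > 1)) {
    .validationError("design column 'start_freq' must lie in [0, 1]")
  }
  df
}

.readTable <- function(path, what) {
  if (!file.exists(path)) {
    .validationError(what, " file not found: '", path, "'")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  .checkSchema(df, what, path)
}

#' Read and validate pipeline CSV tables
#'
#' `readCountsCsv()` reads the per-SNP read-count table
#' (`sample_id,line_id,generation,snp_id,count_HI,count_HII`);
#' `readDesignCsv()` the per-line design
#' (`line_id,start_freq,environment,replicate`); `readFreqsCsv()` per-sample
#' frequency estimates (`line_id,generation,f_HI`).  Schema violations raise
#' a `validationError` naming the offending column or row.
#'
#' @param path Path to the CSV file.
#' @return A validated `data.frame` in the schema's column order.
#' @export
readCountsCsv <- function(path) .validateCountsDf(.readTable(path, "counts"),
                                                  path)

#' @rdname readCountsCsv
#' @export
readDesignCsv <- function(path) .validateDesignDf(.readTable(path, "design"),
                                                  path)

#' @rdname readCountsCsv
#' @export
readFreqsCsv <- function(path) .readTable(path, "freqs")

#' Write a pipeline table as headed CSV
#'
#' Numeric columns are rendered with 17 significant digits so that reading
#' the file back reproduces the written values to full double precision.
#'
#' @param df The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeTableCsv <- function(df, path) {
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) out[[cl]] <- sprintf("%.17g", out[[cl]])
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
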