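# Delimited-text readers/writers for the pipeline's tabular interfaces.
# Separators (tab or comma) are auto-detected from the header line; numeric
# columns are validated with row numbers in the error message, and
# locale-style decimal commas are rejected explicitly.

.detect_sep <- function(path) {
  first <- readLines(path, n = 50L)
  first <- first[!grepl("^#", first)][1L]
  if (is.na(first)) stop("empty file: ", path, call. = FALSE)
  if (grepl("\t", first)) "\t" else ","
}

.validate_numeric <- function(df, cols, path) {
  for (col in cols) {
    raw <- trimws(as.character(df[[col]]))
    if (any(grepl("^-?[0-9]+,[0-9]+$", raw))) {
      line <- which(grepl("^-?[0-9]+,[0-9]+$", raw))[1L]
      stop("column '", col, "' of ", path, " uses decimal commas ",
           "(data row ", line, "); use '.' as the decimal separator",
           call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw) & raw != "NA")
    if (length(bad))
      stop("column '", col, "' of ", path, " is not numeric at data row ",
           bad[1L], " ('", raw[bad[1L]], "')", call. = FALSE)
    df[[col]] <- val
  }
  df
}

#' Read a delimited table against a schema
#'
#' @param path file path (tab- or comma-separated; `#` comments allowed).
#' @param required character vector of required column names.
#' @param numeric_cols columns validated and converted to numeric.
#' @return A data frame.
#' @export
read_table_schema <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, comment.char = "#",
                   stringsAsFactors = FALSE, colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  .validate_numeric(df, intersect(numeric_cols, names(df)), path)
}

#' Read / write a long-format peak-height table
#'
#' Columns: `residue_index`, `residue`, `time_min`, `height`, and optionally
#' `pD`, `temperature_K`.
#'
#' @param path file path.
#' @return A data frame (reader); `path` invisibly (writer).
#' @export
read_peak_table <- function(path) {
  df <- read_table_schema(path,
                          required = c("residue_index", "residue",
                                       "time_min", "height"),
                          numeric_cols = c("residue_index", "time_min",
                                           "height", "pD", "temperature_K"))
  df$residue_index <- as.integer(df$residue_index)
  df
}

#' @param peaks data frame as produced by [simulate_hdx()].
#' @param sep field separator (default tab).
#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path, sep = "\t") {
  write.table(peaks, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a denaturation curve (denaturant_M, theta_mre)
#'
#' @param path file path; two required columns `denaturant_M`, `theta_mre`.
#' @return A data frame.
#' @export
read_denaturation_curve <- function(path) {
  read_table_schema(path, required = c("denaturant_M", "theta_mre"))
}

#' Read a DSC thermogram (temp_C, signal)
#'
#' @param path file path; two required columns `temp_C`, `signal`.
#' @return A data frame.
#' @export
read_thermogram <- function(path) {
  read_table_schema(path, required = c("temp_C", "signal"))
}

#' Write a report object as JSON
#'
#' @param x a list (coerced via jsonlite).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
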