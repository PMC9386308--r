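#' Reference composition table
#'
#' Per-sample laboratory reference values, one row per sample. The standard
#' trait columns are `protein_pct`, `tdf_pct`, `starch_pct`, `amylose_pct`
#' and `oil_pct`, all percent on a dry basis; additional columns (for
#' example `moisture_pct` or `nitrogen_pct`) are carried through with
#' declared unit `"unknown"` unless specified.
#'
#' @param df data.frame with a `sample_id` column and at least one numeric
#'   trait column.
#' @param units named character vector of units per trait column; columns
#'   not named default to `"unknown"`.
#' @return a `reference_table` (a classed data.frame with a `units`
#'   attribute).
#' @export
reference_table <- function(df, units = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    names(df)[1] <- "sample_id"
  }
  df$sample_id <- as.character(df$sample_id)
  trait_cols <- setdiff(names(df), "sample_id")
  if (!length(trait_cols)) stop("reference table needs at least one trait column")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  for (col in trait_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("non-numeric values in trait column '", col, "'")
    }
    if (!all(is.finite(v))) {
      stop("non-finite value in trait column '", col, "' at row ",
           which(!is.finite(v))[1])
    }
    if (any(v < 0)) {
      stop("negative value in trait column '", col, "' at row ",
           which(v < 0)[1])
    }
  }
  u <- stats::setNames(rep("unknown", length(trait_cols)), trait_cols)
  default_units <- c(protein_pct = "% dry basis", tdf_pct = "% dry basis",
                     starch_pct = "% dry basis", amylose_pct = "% dry basis",
                     oil_pct = "% dry basis", moisture_pct = "% fresh weight",
                     nitrogen_pct = "% dry basis")
  known <- intersect(names(default_units), trait_cols)
  u[known] <- default_units[known]
  if (!is.null(units)) u[names(units)] <- units
  attr(df, "units") <- u
  class(df) <- c("reference_table", "data.frame")
  df
}

#' @export
print.reference_table <- function(x, ...) {
  cat("<reference_table> ", nrow(x), " samples, traits: ",
      paste(setdiff(names(x), "sample_id"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Trait column names of a reference table
#' @param x a `reference_table`.
#' @return character vector of trait column names.
#' @export
trait_names <- function(x) setdiff(names(x), "sample_id")

#' Read a reference composition table from CSV
#'
#' First column (or a column named `sample_id`) is the sample id; remaining
#' columns are numeric trait values.
#'
#' @param path CSV file.
#' @param units optional named character vector of units.
#' @return a [reference_table()].
#' @export
read_reference <- function(path, units = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty reference CSV: ", path)
  trait_cols <- setdiff(names(df), names(df)[1])
  for (col in trait_cols) {
    if (all(is.na(df[[col]]))) stop("empty trait column '", col, "' in ", path)
    if (!is.numeric(df[[col]])) {
      row <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop("non-numeric trait cell in ", path, ", column '", col,
           "', row ", row)
    }
  }
  reference_table(df, units = units)
}

#' Write a reference table to CSV
#' @param x a `reference_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference <- function(x, path) {
  stopifnot(inherits(x, "reference_table"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
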