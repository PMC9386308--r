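#' Spectra set container
#'
#' A `spectra_set` holds a block of diffuse-reflectance spectra expressed as
#' apparent absorbance Log(1/R) on a common wavelength grid, together with
#' sample identifiers and free-form provenance metadata. It is the object
#' every scatter correction, math treatment and clustering step transforms.
#'
#' @param absorbance numeric matrix, samples in rows, wavelengths in columns.
#' @param wavelengths_nm strictly increasing numeric wavelength grid (nm);
#'   length must equal `ncol(absorbance)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to the matrix rownames.
#' @param meta list of provenance entries. `meta$history` (a character
#'   vector of processing steps) is appended to, never overwritten, by
#'   downstream operations.
#'
#' @return an object of class `spectra_set` with fields `sample_ids`,
#'   `wavelengths_nm`, `absorbance` and `meta`.
#' @export
spectra_set <- function(absorbance, wavelengths_nm,
                        sample_ids = rownames(absorbance),
                        meta = list()) {
  absorbance <- as.matrix(absorbance)
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  sample_ids <- as.character(sample_ids)
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (is.null(meta$history)) meta$history <- character()
  obj <- structure(
    list(sample_ids = sample_ids,
         wavelengths_nm = wavelengths_nm,
         absorbance = absorbance,
         meta = meta),
    class = "spectra_set")
  validate_spectra_set(obj)
}

validate_spectra_set <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (nrow(x$absorbance) != length(x$sample_ids)) {
    stop("number of absorbance rows (", nrow(x$absorbance),
         ") does not match number of sample ids (", length(x$sample_ids), ")")
  }
  if (ncol(x$absorbance) != length(x$wavelengths_nm)) {
    stop("number of absorbance columns (", ncol(x$absorbance),
         ") does not match wavelength grid length (",
         length(x$wavelengths_nm), ")")
  }
  if (anyDuplicated(x$sample_ids)) {
    dup <- unique(x$sample_ids[duplicated(x$sample_ids)])
    stop("duplicate sample ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (length(x$wavelengths_nm) > 1 && any(diff(x$wavelengths_nm) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  if (!all(is.finite(x$absorbance))) {
    bad <- which(!is.finite(x$absorbance), arr.ind = TRUE)[1, ]
    stop("non-finite absorbance value at sample '", x$sample_ids[bad[1]],
         "', wavelength ", x$wavelengths_nm[bad[2]], " nm")
  }
  dimnames(x$absorbance) <- list(x$sample_ids, NULL)
  x
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("<spectra_set> ", length(x$sample_ids), " samples x ",
      length(x$wavelengths_nm), " wavelengths (",
      min(x$wavelengths_nm), "-", max(x$wavelengths_nm), " nm)\n", sep = "")
  if (length(x$meta$history)) {
    cat("  history: ", paste(x$meta$history, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$absorbance)

#' Subset a spectra set by sample
#'
#' @param x a `spectra_set`.
#' @param i sample indices or ids.
#' @return a `spectra_set` with the selected rows, metadata carried through.
#' @export
subset_samples <- function(x, i) {
  stopifnot(inherits(x, "spectra_set"))
  if (is.character(i)) {
    idx <- match(i, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample ids: ",
                         paste(i[is.na(idx)], collapse = ", "))
  } else {
    idx <- i
  }
  spectra_set(x$absorbance[idx, , drop = FALSE], x$wavelengths_nm,
              x$sample_ids[idx], x$meta)
}

append_history <- function(x, entry) {
  x$meta$history <- c(x$meta$history, entry)
  x
}

#' Read spectra from CSV or JCAMP-DX
#'
#' The CSV dialect is a wide matrix: first column sample id, remaining
#' columns one wavelength each, header row holding the wavelengths in nm.
#' JCAMP-DX support covers single-spectrum files with an
#' `##XYDATA=(X++(Y..Y))` table.
#'
#' @param path input file.
#' @param format `"csv"` (default) or `"jcamp"`.
#' @return a validated [spectra_set()]. A warning (not an error) is issued
#'   when the wavelength grid is non-uniformly spaced.
#' @export
read_spectra <- function(path, format = c("csv", "jcamp")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  out <- switch(format,
                csv = read_spectra_csv(path),
                jcamp = read_spectra_jcamp(path))
  w <- out$wavelengths_nm
  if (length(w) > 2 && diff(range(diff(w))) > 1e-8 * mean(diff(w))) {
    warning("wavelength grid is not uniformly spaced")
  }
  out
}

read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed spectra CSV: ", path)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  wl <- suppressWarnings(as.numeric(names(df)[-1]))
  if (anyNA(wl)) {
    stop("non-numeric wavelength header in ", path, ": column '",
         names(df)[-1][which(is.na(wl))[1]], "'")
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad + 1]]))))[1]
    stop("non-numeric absorbance cell in ", path, " at row ", row,
         " (sample '", ids[row], "'), column '", names(df)[bad + 1], "'")
  }
  spectra_set(mat, wl, ids,
              meta = list(source = path, history = character()))
}

# Minimal JCAMP-DX reader: single spectrum, ##XYDATA=(X++(Y..Y)) with
# AFFN-encoded values; FIRSTX/LASTX/NPOINTS/XFACTOR/YFACTOR honoured.
read_spectra_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty JCAMP-DX file: ", path)
  get_field <- function(key, default = NA) {
    hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^##", key, "="), "", hit[1])
  }
  title <- trimws(get_field("TITLE", "spectrum"))
  xfac <- as.numeric(get_field("XFACTOR", "1"))
  yfac <- as.numeric(get_field("YFACTOR", "1"))
  npoints <- as.numeric(get_field("NPOINTS", NA))
  start <- grep("^##XYDATA=", lines)
  if (!length(start)) stop("no ##XYDATA table in ", path)
  end <- grep("^##END", lines)
  end <- if (length(end)) min(end[end > start[1]]) else length(lines) + 1L
  body <- lines[(start[1] + 1L):(end - 1L)]
  body <- body[!grepl("^##", body) & nzchar(trimws(body))]
  xs <- numeric(0); ys <- numeric(0)
  for (ln in body) {
    vals <- as.numeric(strsplit(trimws(ln), "[[:space:],]+")[[1]])
    if (anyNA(vals) || length(vals) < 2) stop("unparseable XYDATA line: ", ln)
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (!is.na(npoints) && length(ys) != npoints) {
    stop("NPOINTS mismatch in ", path, ": declared ", npoints,
         ", found ", length(ys))
  }
  firstx <- as.numeric(get_field("FIRSTX", xs[1] * xfac))
  lastx <- as.numeric(get_field("LASTX", NA))
  n <- length(ys)
  wl <- if (!is.na(lastx) && n > 1) seq(firstx, lastx, length.out = n)
        else firstx + (seq_len(n) - 1) * xfac
  spectra_set(matrix(ys * yfac, nrow = 1), wl, title,
              meta = list(source = path, history = character()))
}

#' Write a spectra set to wide CSV
#'
#' @param x a `spectra_set`.
#' @param path output file; UTF-8, '.' decimal separator.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path) {
  stopifnot(inherits(x, "spectra_set"))
  df <- data.frame(sample_id = x$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.data.frame(x$absorbance)
  names(mat) <- format(x$wavelengths_nm, trim = TRUE, scientific = FALSE)
  df <- cbind(df, mat)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pair spectra with reference values by sample id
#'
#' Inner join on sample id, preserving the spectra order. Counts of
#' unmatched ids on either side are attached as attributes
#' `n_unmatched_spectra` and `n_unmatched_reference`.
#'
#' @param spectra a [spectra_set()].
#' @param reference a [reference_table()].
#' @return list with components `spectra` (subset, spectra order) and
#'   `reference` (rows reordered to match).
#' @export
join_spectra_reference <- function(spectra, reference) {
  stopifnot(inherits(spectra, "spectra_set"),
            inherits(reference, "reference_table"))
  common <- spectra$sample_ids[spectra$sample_ids %in% reference$sample_id]
  if (!length(common)) stop("no sample ids shared between spectra and reference table")
  sp <- subset_samples(spectra, common)
  ref <- reference[match(common, reference$sample_id), , drop = FALSE]
  rownames(ref) <- NULL
  out <- list(spectra = sp, reference = ref)
  attr(out, "n_unmatched_spectra") <- length(spectra$sample_ids) - length(common)
  attr(out, "n_unmatched_reference") <- nrow(reference) - length(common)
  out
}
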