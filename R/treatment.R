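#' Parse a WinISI-style math-treatment code
#'
#' Math treatments are written `"d,g,s1,s2"`: derivative order `d`, gap `g`
#' in grid points for the centered difference, and two moving-average
#' smoothing widths `s1` (applied before derivatization) and `s2` (applied
#' after). `"0,0,1,1"` is the identity treatment.
#'
#' @param code treatment string, e.g. `"4,8,8,1"`.
#' @return a `math_treatment` object with fields `d`, `g`, `s1`, `s2`.
#' @export
parse_treatment <- function(code) {
  if (inherits(code, "math_treatment")) return(code)
  parts <- strsplit(trimws(code), ",", fixed = TRUE)[[1]]
  if (length(parts) != 4) {
    stop("math treatment must have four comma-separated integers, got '",
         code, "'")
  }
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || any(vals != round(vals))) {
    stop("non-integer component in math treatment '", code, "'")
  }
  math_treatment(vals[1], vals[2], vals[3], vals[4])
}

#' @rdname parse_treatment
#' @param d derivative order (>= 0).
#' @param g gap in grid points; must be a positive even integer when
#'   `d >= 1` (the centered difference reaches `g/2` points either side).
#' @param s1,s2 moving-average widths in grid points (>= 1; 1 = identity).
#' @export
math_treatment <- function(d, g, s1, s2) {
  d <- as.integer(d); g <- as.integer(g)
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (d < 0) stop("derivative order must be >= 0")
  if (s1 < 1 || s2 < 1) stop("smoothing widths must be >= 1")
  if (g < 0) stop("gap must be >= 0")
  if (d >= 1) {
    if (g == 0) stop("gap must be positive when derivative order >= 1")
    if (g %% 2 != 0) {
      stop("odd gap (", g, ") with derivative order >= 1 is not supported; ",
           "the centered difference needs an even gap")
    }
  }
  structure(list(d = d, g = g, s1 = s1, s2 = s2), class = "math_treatment")
}

#' @export
format.math_treatment <- function(x, ...) {
  paste(x$d, x$g, x$s1, x$s2, sep = ",")
}

#' @export
print.math_treatment <- function(x, ...) {
  cat("<math_treatment> ", format(x),
      " (derivative ", x$d, ", gap ", x$g, ", smooth ", x$s1, "/", x$s2,
      ")\n", sep = "")
  invisible(x)
}

# Centered boxcar moving average along the wavelength axis.
# Even widths use the left-center convention: window i-w/2 .. i+w/2-1.
# Returns list(mat, keep) where keep are the retained column indices.
boxcar_smooth <- function(mat, width) {
  n <- ncol(mat)
  if (width <= 1) return(list(mat = mat, keep = seq_len(n)))
  if (width %% 2 == 0) {
    left <- width %/% 2; right <- width %/% 2 - 1L
  } else {
    left <- right <- (width - 1L) %/% 2
  }
  if (n - left - right < 1) {
    stop("spectrum too short for smoothing width ", width,
         " (need at least ", left + right + 1, " points)")
  }
  keep <- (1L + left):(n - right)
  out <- matrix(0, nrow(mat), length(keep))
  for (k in -left:right) {
    out <- out + mat[, keep + k, drop = FALSE]
  }
  list(mat = out / width, keep = keep)
}

# One centered gap derivative: y[i] = x[i + g/2] - x[i - g/2].
gap_derivative <- function(mat, gap) {
  h <- gap %/% 2
  n <- ncol(mat)
  if (n - 2L * h < 1) {
    stop("spectrum too short for gap ", gap,
         " (need at least ", 2L * h + 1L, " points)")
  }
  keep <- (1L + h):(n - h)
  list(mat = mat[, keep + h, drop = FALSE] - mat[, keep - h, drop = FALSE],
       keep = keep)
}

#' Apply a math treatment to a spectra set
#'
#' Operator order is: moving-average smooth of width `s1`, then `d`
#' successive centered gap derivatives (`y[i] = x[i + g/2] - x[i - g/2]`,
#' gap in grid points), then a smooth of width `s2`. Wavelengths whose value
#' would require points beyond the grid edge are trimmed — never padded —
#' and the output grid records the trim.
#'
#' @param spectra a [spectra_set()].
#' @param treatment a `math_treatment` or its string code.
#' @return a [spectra_set()] on the trimmed grid with the treatment appended
#'   to the processing history.
#' @export
apply_treatment <- function(spectra, treatment) {
  stopifnot(inherits(spectra, "spectra_set"))
  t <- parse_treatment(treatment)
  mat <- spectra$absorbance
  wl <- spectra$wavelengths_nm
  step <- function(res) {
    mat <<- res$mat
    wl <<- wl[res$keep]
  }
  step(boxcar_smooth(mat, t$s1))
  if (t$d >= 1) {
    for (i in seq_len(t$d)) step(gap_derivative(mat, t$g))
  }
  step(boxcar_smooth(mat, t$s2))
  out <- spectra_set(mat, wl, spectra$sample_ids, spectra$meta)
  append_history(out, paste0("treatment:", format(t)))
}
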