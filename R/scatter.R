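#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed against a reference spectrum `m`
#' (by default the mean spectrum of the set being fitted):
#' `x = a + b * m`, and the corrected spectrum is `(x - a) / b`. This
#' removes per-sample additive offsets and multiplicative scatter. The
#' fitted reference spectrum is returned so it can be applied unchanged to
#' out-of-set (validation) spectra — it is never recomputed on new data.
#'
#' @param spectra a [spectra_set()].
#' @param reference optional reference (mean) spectrum; required length
#'   equal to the wavelength grid. When `NULL` the column mean of
#'   `spectra` is used (requires >= 2 spectra).
#' @return list with `spectra` (corrected set) and `correction` (a
#'   `scatter_correction` carrying the reference spectrum).
#' @export
msc_fit_apply <- function(spectra, reference = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.null(reference)) {
    if (nrow(spectra$absorbance) < 2) {
      stop("MSC needs >= 2 spectra to fit a mean reference; ",
           "supply `reference` for single spectra")
    }
    reference <- colMeans(spectra$absorbance)
  }
  if (length(reference) != length(spectra$wavelengths_nm)) {
    stop("MSC reference length (", length(reference),
         ") does not match wavelength grid (",
         length(spectra$wavelengths_nm), ")")
  }
  corr <- structure(list(method = "msc", reference = as.numeric(reference)),
                    class = "scatter_correction")
  list(spectra = apply_scatter(corr, spectra), correction = corr)
}

#' Standard normal variate with detrend (SNV-DT)
#'
#' Per spectrum: subtract the spectrum mean and divide by its standard
#' deviation (SNV), then fit a second-degree polynomial of absorbance on
#' wavelength and subtract it (detrend). Any affine or quadratic baseline
#' is thereby removed exactly.
#'
#' @param spectra a [spectra_set()].
#' @return a corrected [spectra_set()].
#' @export
snv_detrend <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  corr <- structure(list(method = "snv_dt"), class = "scatter_correction")
  apply_scatter(corr, spectra)
}

#' Build a scatter-correction specification
#'
#' @param method one of `"none"`, `"msc"`, `"snv_dt"`.
#' @param reference for `"msc"`, the stored reference spectrum (may be
#'   `NULL` until fitted).
#' @return a `scatter_correction` object.
#' @export
scatter_correction <- function(method = c("none", "msc", "snv_dt"),
                               reference = NULL) {
  method <- match.arg(method)
  structure(list(method = method, reference = reference),
            class = "scatter_correction")
}

#' Apply a fitted scatter correction to spectra
#'
#' Row-local application: for MSC the stored calibration-set reference mean
#' is used, never the mean of `spectra` itself.
#'
#' @param correction a `scatter_correction`.
#' @param spectra a [spectra_set()].
#' @return corrected [spectra_set()].
#' @export
apply_scatter <- function(correction, spectra) {
  stopifnot(inherits(correction, "scatter_correction"),
            inherits(spectra, "spectra_set"))
  mat <- spectra$absorbance
  out <- switch(
    correction$method,
    none = return(spectra),
    msc = {
      m <- correction$reference
      if (is.null(m)) stop("MSC correction has no fitted reference spectrum")
      mc <- m - mean(m)
      denom <- sum(mc^2)
      xbar <- rowMeans(mat)
      b <- as.numeric((mat - xbar) %*% mc) / denom
      small <- abs(b) < 1e-12
      if (any(small)) {
        stop("MSC slope numerically zero for sample(s): ",
             paste(spectra$sample_ids[small], collapse = ", "))
      }
      a <- xbar - b * mean(m)
      (mat - a) / b
    },
    snv_dt = {
      sds <- apply(mat, 1, stats::sd)
      flat <- sds < 1e-12
      if (any(flat)) {
        stop("constant spectrum (SD < 1e-12) for sample(s): ",
             paste(spectra$sample_ids[flat], collapse = ", "))
      }
      z <- (mat - rowMeans(mat)) / sds
      wl <- spectra$wavelengths_nm
      wc <- (wl - mean(wl)) / stats::sd(wl)  # scaled for conditioning
      q <- qr.Q(qr(cbind(1, wc, wc^2)))
      z - (z %*% q) %*% t(q)
    })
  out_set <- spectra_set(out, spectra$wavelengths_nm, spectra$sample_ids,
                         spectra$meta)
  append_history(out_set, paste0("scatter:", correction$method))
}

#' Scatter correction followed by a math treatment
#'
#' The standard preprocessing chain: scatter correction first, then the
#' WinISI-style math treatment. Both steps are recorded in the processing
#' history. When `scatter` is the string `"msc"` the reference spectrum is
#' fitted on `spectra`; pass a fitted `scatter_correction` to reuse a
#' calibration-set reference on validation data.
#'
#' @param spectra a [spectra_set()].
#' @param scatter `"none"`, `"msc"`, `"snv_dt"`, or a fitted
#'   `scatter_correction`.
#' @param treatment a `math_treatment` or code string (default identity).
#' @return a [spectra_set()]; the fitted `scatter_correction` is attached
#'   as `meta$scatter_correction` for out-of-set reuse.
#' @export
preprocess <- function(spectra, scatter = "none", treatment = "0,0,1,1") {
  stopifnot(inherits(spectra, "spectra_set"))
  if (is.character(scatter)) {
    if (scatter == "msc") {
      fit <- msc_fit_apply(spectra)
      corrected <- fit$spectra
      corr <- fit$correction
    } else {
      corr <- scatter_correction(scatter)
      corrected <- apply_scatter(corr, spectra)
    }
  } else {
    corr <- scatter
    corrected <- apply_scatter(corr, spectra)
  }
  out <- apply_treatment(corrected, treatment)
  out$meta$scatter_correction <- corr
  out
}
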