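#' Fit a full calibration model from raw spectra
#'
#' The standard calibration chain for one trait: pair spectra with
#' reference values, fit the scatter correction on the calibration set,
#' apply the math treatment, choose the latent-variable count by
#' contiguous-block cross-validation under the component cap (default 5),
#' run iterative outlier elimination, and fit the final model. The
#' returned model carries everything needed to predict raw out-of-set
#' spectra: the fitted scatter correction, the treatment, the treated
#' wavelength grid, centering vectors and the coefficient vector.
#'
#' @param spectra raw calibration [spectra_set()].
#' @param reference a [reference_table()] covering the calibration ids.
#' @param trait trait column to calibrate.
#' @param method `"pls"`, `"mpls"` or `"pcr"`.
#' @param scatter `"none"`, `"msc"` or `"snv_dt"`.
#' @param treatment math-treatment code or object.
#' @param max_pcs component cap (default 5).
#' @param cv_groups cross-validation blocks (default 4).
#' @param outlier_removal run iterative outlier elimination (default TRUE).
#' @param t_limit,gh_limit,max_passes,max_remove_frac passed to
#'   [remove_outliers()].
#' @return a `calibration_model`.
#' @export
calibrate <- function(spectra, reference, trait,
                      method = c("mpls", "pls", "pcr"),
                      scatter = c("snv_dt", "msc", "none"),
                      treatment = "0,0,1,1",
                      max_pcs = 5, cv_groups = 4,
                      outlier_removal = TRUE,
                      t_limit = 2.5, gh_limit = 3.0, max_passes = 2,
                      max_remove_frac = 0.10) {
  method <- match.arg(method)
  scatter <- match.arg(scatter)
  treatment <- parse_treatment(treatment)
  paired <- join_spectra_reference(spectra, reference)
  if (!trait %in% names(paired$reference)) {
    stop("trait column '", trait, "' not present in reference table")
  }
  treated <- preprocess(paired$spectra, scatter, treatment)
  X <- treated$absorbance
  y <- paired$reference[[trait]]
  ids <- treated$sample_ids
  cv <- cross_validate(X, y, method = method, n_pcs_max = max_pcs,
                       n_groups = cv_groups)
  n_pcs <- cv$n_pcs
  if (outlier_removal) {
    elim <- remove_outliers(X, y, method = method, n_pcs = n_pcs,
                            t_limit = t_limit, gh_limit = gh_limit,
                            max_passes = max_passes,
                            max_remove_frac = max_remove_frac, ids = ids)
    keep <- elim$keep
    removed <- elim$removed
    fit <- elim$fit
  } else {
    keep <- seq_along(y)
    removed <- data.frame(id = character(), pass = integer(),
                          reason = character(), stringsAsFactors = FALSE)
    fit <- fit_latent(X, y, n_pcs = n_pcs, method = method)
  }
  y_kept <- y[keep]
  rss <- sum(fit$residuals^2)
  structure(list(
    method = method, trait = trait,
    scatter = scatter,
    scatter_correction = treated$meta$scatter_correction,
    treatment = treatment,
    wavelengths_nm = treated$wavelengths_nm,
    n_pcs = fit$n_pcs,
    x_mean = fit$x_mean, y_mean = fit$y_mean,
    coef = fit$coef,
    sample_ids = ids[keep],
    outliers = removed,
    stats = list(
      n = length(keep),
      rsq = rsq(fit$fitted, y_kept),
      slope = slope(fit$fitted, y_kept),
      sd = stats::sd(y_kept),
      sec = sqrt(rss / (length(keep) - 1)),
      secv = cv$secv[n_pcs],
      secv_path = cv$secv,
      cal_range = range(y_kept))),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  s <- x$stats
  cat("<calibration_model> ", x$trait, ": ", toupper(x$method),
      " / ", x$scatter, " / ", format(x$treatment),
      ", ", x$n_pcs, " PCs\n", sep = "")
  cat(sprintf("  n=%d  RSQ=%.3f  SEC=%.3f  SECV=%.3f  SD=%.3f  outliers=%d\n",
              s$n, s$rsq, s$sec, s$secv, s$sd, nrow(x$outliers)))
  invisible(x)
}

#' Predict trait values from raw spectra
#'
#' Applies the model's stored scatter correction (for MSC, the
#' calibration-set reference spectrum) and math treatment to raw spectra,
#' then the regression coefficients.
#'
#' @param object a `calibration_model`.
#' @param newdata a raw [spectra_set()], or a numeric matrix already on the
#'   model's treated grid.
#' @param ... unused.
#' @return named numeric vector of predictions.
#' @export
predict.calibration_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    treated <- preprocess(newdata, object$scatter_correction,
                          object$treatment)
    if (!isTRUE(all.equal(treated$wavelengths_nm, object$wavelengths_nm))) {
      stop("treated wavelength grid of new spectra does not match the model")
    }
    X <- treated$absorbance
    ids <- treated$sample_ids
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$coef)) {
      stop("matrix has ", ncol(X), " columns; model expects ",
           length(object$coef))
    }
    ids <- rownames(X)
  }
  pred <- as.numeric(sweep(X, 2, object$x_mean) %*% object$coef) +
    object$y_mean
  stats::setNames(pred, ids)
}

#' Save / load a calibration model as JSON
#'
#' Full-precision JSON serialization (coefficients, provenance, statistics)
#' that round-trips predictions exactly.
#'
#' @param model a `calibration_model`.
#' @param path JSON file path.
#' @return `path` invisibly (`save_model`); a `calibration_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- unclass(model)
  obj$treatment <- format(model$treatment)
  obj$scatter_correction <- list(
    method = model$scatter_correction$method,
    reference = model$scatter_correction$reference)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$treatment <- parse_treatment(obj$treatment)
  ref <- obj$scatter_correction$reference
  obj$scatter_correction <- scatter_correction(
    obj$scatter_correction$method,
    reference = if (!is.null(ref) && length(ref)) as.numeric(ref) else NULL)
  obj$outliers <- as.data.frame(obj$outliers, stringsAsFactors = FALSE)
  if (!nrow(obj$outliers)) {
    obj$outliers <- data.frame(id = character(), pass = integer(),
                               reason = character(), stringsAsFactors = FALSE)
  }
  obj$stats <- lapply(obj$stats, function(v) if (is.list(v)) unlist(v) else v)
  structure(obj, class = "calibration_model")
}
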