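#' External-validation statistics
#'
#' The statistics used to judge NIRS prediction models on an external
#' validation set: squared correlation (RSQ), regression slope, signed
#' bias, standard error of prediction (SEP, optionally bias-corrected),
#' and the ratio of performance to deviation (RPD) with its conventional
#' qualitative bands.
#'
#' @param predicted numeric vector of model predictions.
#' @param reference numeric vector of laboratory reference values.
#' @return `rsq()`: squared Pearson correlation in [0, 1].
#' @export
rsq <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference), length(predicted) >= 3)
  if (stats::sd(predicted) < 1e-12 || stats::sd(reference) < 1e-12) {
    stop("zero variance in predicted or reference values")
  }
  stats::cor(predicted, reference)^2
}

#' @rdname rsq
#' @return `slope()`: ordinary-least-squares slope of predicted on
#'   reference (the change in predicted value per unit change in the
#'   reference value; 1 is ideal).
#' @export
slope <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  v <- stats::var(reference)
  if (v < 1e-24) stop("zero variance in reference values")
  stats::cov(predicted, reference) / v
}

#' @rdname rsq
#' @return `bias()`: signed mean difference `mean(reference - predicted)`;
#'   negative means the model overestimates relative to the laboratory.
#' @export
bias <- function(predicted, reference) {
  stopifnot(length(predicted) == length(reference))
  mean(reference - predicted)
}

#' @rdname rsq
#' @param bias_corrected when `TRUE` (SEP(C)) the mean difference is
#'   subtracted before squaring; when `FALSE` the raw RMS difference is
#'   returned. Either way the denominator is n.
#' @param n_minus_1 use an n-1 denominator instead (for comparison with
#'   software reporting the sample-SD convention); default `FALSE`.
#' @return `sep()`: standard error of prediction,
#'   `sqrt(sum((predicted - reference - b)^2) / n)` with `b` the mean
#'   difference when `bias_corrected`, else 0. The algebraic identity
#'   `SEP^2 = SEP(C)^2 + bias^2` holds exactly under the n denominator.
#' @export
sep <- function(predicted, reference, bias_corrected = TRUE,
                n_minus_1 = FALSE) {
  stopifnot(length(predicted) == length(reference),
            length(predicted) >= 2)
  d <- predicted - reference
  b <- if (bias_corrected) mean(d) else 0
  denom <- length(d) - as.integer(n_minus_1)
  sqrt(sum((d - b)^2) / denom)
}

#' @rdname rsq
#' @param sd_reference standard deviation of the reference values in the
#'   validation set.
#' @param sep_value standard error of prediction.
#' @return `rpd()`: `sd_reference / sep_value`.
#' @export
rpd <- function(sd_reference, sep_value) {
  if (sep_value <= 0) {
    stop("SEP is zero (or negative): RPD is unbounded for a perfect fit")
  }
  sd_reference / sep_value
}

#' @rdname rsq
#' @param rpd_value an RPD value (>= 0).
#' @return `rpd_class()`: qualitative label — `"very poor"` (< 1.0),
#'   `"poor"` (1.0-1.4), `"fair"` (1.4-1.8), `"good"` (1.8-2.0),
#'   `"very good"` (2.0-2.5), `"excellent"` (>= 2.5).
#' @export
rpd_class <- function(rpd_value) {
  stopifnot(rpd_value >= 0)
  as.character(cut(rpd_value, breaks = c(-Inf, 1.0, 1.4, 1.8, 2.0, 2.5, Inf),
                   labels = c("very poor", "poor", "fair", "good",
                              "very good", "excellent"),
                   right = FALSE))
}

#' Paired-sample t-test between laboratory and predicted values
#'
#' Two-sided paired t-test on the differences `lab - predicted`: mean,
#' sample SD (n-1 denominator), SE = SD/sqrt(n), t = mean/SE, df = n-1,
#' 95 percent confidence interval and the two-sided p-value from
#' Student's t distribution.
#'
#' @param lab laboratory reference values.
#' @param predicted model predictions (same length).
#' @param conf_level confidence level (default 0.95).
#' @return a `paired_test_result` with fields `mean_diff`, `sd_diff`,
#'   `se_mean`, `ci_lower`, `ci_upper`, `t_value`, `df`, `p_value`, `n`.
#'   Zero-variance differences with nonzero mean give `t = +/-Inf`,
#'   `p = 0`; identical vectors give `t = 0`, `p = 1`.
#' @export
paired_t_test <- function(lab, predicted, conf_level = 0.95) {
  stopifnot(length(lab) == length(predicted), length(lab) >= 2)
  d <- lab - predicted
  n <- length(d)
  m <- mean(d)
  s <- sqrt(sum((d - m)^2) / (n - 1))
  se <- s / sqrt(n)
  df <- n - 1L
  if (se < 1e-14) {
    t_val <- if (abs(m) < 1e-14) 0 else sign(m) * Inf
    p <- if (abs(m) < 1e-14) 1 else 0
    ci <- c(m, m)
  } else {
    t_val <- m / se
    p <- 2 * stats::pt(-abs(t_val), df)
    crit <- stats::qt(1 - (1 - conf_level) / 2, df)
    ci <- c(m - crit * se, m + crit * se)
  }
  structure(list(mean_diff = m, sd_diff = s, se_mean = se,
                 ci_lower = ci[1], ci_upper = ci[2],
                 t_value = t_val, df = df, p_value = p, n = n),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(paste0("<paired_test_result> mean diff %.6f (SD %.6f, SE %.6f)\n",
                     "  95%% CI [%.6f, %.6f]  t = %.3f, df = %d, p = %.3f\n"),
              x$mean_diff, x$sd_diff, x$se_mean, x$ci_lower, x$ci_upper,
              x$t_value, x$df, x$p_value))
  invisible(x)
}

#' External validation of a calibration model
#'
#' Applies a fitted model (stored scatter correction and math treatment
#' included) to a disjoint validation set and assembles the full
#' validation-statistics row: n, calibration and validation reference
#' ranges, RSQ, slope, bias, SD of the validation reference values, SEP
#' (bias-corrected and uncorrected), RPD and its class, plus the paired
#' t-test. No outlier removal is performed in external validation.
#'
#' @param model a `calibration_model`.
#' @param spectra raw validation [spectra_set()].
#' @param reference a [reference_table()] covering the validation ids.
#' @param rpd_from `"sep_c"` (default) or `"sep"`: which SEP flavour the
#'   RPD is computed from.
#' @param allow_in_sample permit overlap with the training ids, flagging
#'   the report `in_sample = TRUE` instead of erroring (default FALSE).
#' @return a `validation_report`.
#' @export
validation_report <- function(model, spectra, reference,
                              rpd_from = c("sep_c", "sep"),
                              allow_in_sample = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  rpd_from <- match.arg(rpd_from)
  paired <- join_spectra_reference(spectra, reference)
  overlap <- intersect(paired$spectra$sample_ids, model$sample_ids)
  in_sample <- length(overlap) > 0
  if (in_sample && !allow_in_sample) {
    stop("validation set overlaps the model's training ids (",
         length(overlap), " shared); external validation requires ",
         "disjoint samples")
  }
  pred <- predict(model, paired$spectra)
  lab <- paired$reference[[model$trait]]
  sd_ref <- stats::sd(lab)
  sep_c <- sep(pred, lab, bias_corrected = TRUE)
  sep_u <- sep(pred, lab, bias_corrected = FALSE)
  sep_used <- if (rpd_from == "sep_c") sep_c else sep_u
  rpd_val <- rpd(sd_ref, sep_used)
  structure(list(
    trait = model$trait,
    n = length(lab),
    method = model$method,
    scatter = model$scatter,
    treatment = format(model$treatment),
    n_pcs = model$n_pcs,
    cal_range = model$stats$cal_range,
    val_range = range(lab),
    rsq = rsq(pred, lab),
    slope = slope(pred, lab),
    bias = bias(pred, lab),
    sd = sd_ref,
    sep_c = sep_c,
    sep = sep_u,
    rpd = rpd_val,
    rpd_class = rpd_class(rpd_val),
    t_test = paired_t_test(lab, pred),
    in_sample = in_sample,
    predicted = pred,
    reference_values = stats::setNames(lab, paired$spectra$sample_ids)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$trait, " (", toupper(x$method), " / ",
      x$scatter, " / ", x$treatment, ", ", x$n_pcs, " PCs)",
      if (x$in_sample) "  [IN-SAMPLE]", "\n", sep = "")
  cat(sprintf("  n=%d  RSQ=%.3f  slope=%.3f  bias=%+.3f  SD=%.3f  SEP(C)=%.3f  RPD=%.2f (%s)\n",
              x$n, x$rsq, x$slope, x$bias, x$sd, x$sep_c, x$rpd,
              x$rpd_class))
  cat(sprintf("  paired t = %.3f (df %d, p = %.3f)\n",
              x$t_test$t_value, x$t_test$df, x$t_test$p_value))
  invisible(x)
}

#' One-row data.frame view of a validation report
#' @param x a `validation_report`.
#' @param ... unused.
#' @return a one-row data.frame mirroring the standard validation-table
#'   column order.
#' @export
as.data.frame.validation_report <- function(x, ...) {
  data.frame(trait = x$trait, n = x$n,
             cal_min = x$cal_range[1], cal_max = x$cal_range[2],
             val_min = x$val_range[1], val_max = x$val_range[2],
             method = x$method, scatter = x$scatter,
             treatment = x$treatment, n_pcs = x$n_pcs,
             rsq = x$rsq, slope = x$slope, bias = x$bias, sd = x$sd,
             sep_c = x$sep_c, sep = x$sep, rpd = x$rpd,
             rpd_class = x$rpd_class,
             t_value = x$t_test$t_value, p_value = x$t_test$p_value,
             stringsAsFactors = FALSE)
}
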