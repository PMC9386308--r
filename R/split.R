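#' Rank-ordered 2:1 calibration/validation split
#'
#' Samples are sorted ascending by the named trait (ties broken by sample
#' id, so the split is deterministic) and every third sample, counting from
#' the second rank (ranks 2, 5, 8, ...), is taken out for the validation
#' set; the remainder forms the calibration set. The validation set has
#' exactly `floor(n/3)` members, and because rank 1 and rank n are never
#' drawn, the global trait minimum and maximum always stay in calibration:
#' the validation trait range is contained in the calibration range.
#'
#' @param reference a [reference_table()].
#' @param trait trait column name to rank by.
#' @return a `split_plan` with fields `trait`, `ranked_ids` (ascending in
#'   the trait), `calibration_ids`, `validation_ids`.
#' @export
split_by_trait <- function(reference, trait) {
  stopifnot(inherits(reference, "reference_table"))
  if (!trait %in% names(reference)) {
    stop("trait column '", trait, "' not present in reference table")
  }
  n <- nrow(reference)
  if (n < 3) stop("need at least 3 samples for a 2:1 split")
  ord <- order(reference[[trait]], reference$sample_id)
  ranked_ids <- reference$sample_id[ord]
  n_val <- n %/% 3L
  val_ranks <- 2L + 3L * (seq_len(n_val) - 1L)
  validation_ids <- ranked_ids[val_ranks]
  calibration_ids <- ranked_ids[-val_ranks]
  structure(list(trait = trait,
                 ranked_ids = ranked_ids,
                 calibration_ids = calibration_ids,
                 validation_ids = validation_ids),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("<split_plan> trait '", x$trait, "': ",
      length(x$calibration_ids), " calibration / ",
      length(x$validation_ids), " validation\n", sep = "")
  invisible(x)
}
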