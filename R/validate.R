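# Segmentation validation: does the automatic pipeline reproduce the
# ground-truth morphometrics? Reported as coefficients of determination for
# tip counts and total length (truth on the x axis) plus mean Dice.

# R^2 = 1 - SS_res / SS_tot with truth as the reference
r_squared <- function(pred, truth) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((pred - truth)^2) / ss_tot
}

#' Validate measured morphometrics against ground truth
#'
#' @param pred_records data.frame with columns `neuron_id`, `tip_count`,
#'   `total_length_um` and optionally `dice` (per-neuron mask Dice).
#' @param truth_records data.frame with columns `neuron_id`, `tip_count`,
#'   `total_length_um` (ground truth).
#' @return object of class `validation_report`: per-neuron table, `r2_tips`,
#'   `r2_length`, `mean_dice` (NA if no Dice column). Zero variance in the
#'   truth makes the corresponding R^2 `NA`.
#' @export
validate_against_truth <- function(pred_records, truth_records) {
  need <- c("neuron_id", "tip_count", "total_length_um")
  stopifnot(all(need %in% names(pred_records)),
            all(need %in% names(truth_records)))
  ids <- intersect(pred_records$neuron_id, truth_records$neuron_id)
  if (length(ids) < 3) stop("need at least 3 matched neurons")
  p <- pred_records[match(ids, pred_records$neuron_id), ]
  t <- truth_records[match(ids, truth_records$neuron_id), ]
  per <- data.frame(neuron_id = ids,
                    tips_pred = p$tip_count, tips_true = t$tip_count,
                    length_pred = p$total_length_um,
                    length_true = t$total_length_um)
  if ("dice" %in% names(p)) per$dice <- p$dice
  out <- list(per_neuron = per,
              r2_tips = r_squared(per$tips_pred, per$tips_true),
              r2_length = r_squared(per$length_pred, per$length_true),
              mean_dice = if ("dice" %in% names(per)) mean(per$dice) else NA_real_,
              n = length(ids))
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> n=%d  R2(tips)=%.4f  R2(length)=%.4f  mean Dice=%s\n",
    x$n, x$r2_tips, x$r2_length,
    if (is.na(x$mean_dice)) "NA" else sprintf("%.3f", x$mean_dice)))
  invisible(x)
}
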