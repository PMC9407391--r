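# Postprocessing of probability maps: threshold, fill gaps, remove small
# fragments. Plus the Dice overlap index and segmentation-fidelity report.

#' Binarize a probability map and clean the mask
#'
#' Threshold, then morphological closing with a square element of radius
#' `gap_close_px` (fills small gaps along broken branches), then removal of
#' connected components smaller than `min_fragment_px` (suppresses noise
#' specks and debris). The component containing the soma (deepest erosion
#' depth) is always retained regardless of size.
#'
#' @param prob probability-map matrix in `[0, 1]`.
#' @param threshold binarization threshold in `(0, 1)`.
#' @param min_fragment_px minimum component size kept, in pixels.
#' @param gap_close_px closing radius in pixels.
#' @return logical mask with attributes `params` and `dead` (TRUE when the
#'   cleaned mask is empty, e.g. a fully degenerated neuron).
#' @export
binarize_and_clean <- function(prob, threshold = 0.5, min_fragment_px = 30,
                               gap_close_px = 1) {
  stopifnot(threshold > 0, threshold < 1)
  bw <- prob >= threshold
  bw <- close_box(bw, gap_close_px)
  dead <- FALSE
  if (any(bw)) {
    lab <- label_components(bw)
    sizes <- tabulate(lab[lab > 0])
    soma_comp <- lab[which.max(erosion_depth(bw))]
    keep <- which(sizes >= min_fragment_px)
    keep <- union(keep, soma_comp)
    bw <- matrix(lab %in% keep, nrow(bw), ncol(bw))
  }
  if (!any(bw)) {
    dead <- TRUE
    warning("empty mask after cleaning (neuron may be dead)")
  }
  attr(bw, "params") <- list(threshold = threshold,
                             min_fragment_px = min_fragment_px,
                             gap_close_px = gap_close_px)
  attr(bw, "dead") <- dead
  bw
}

#' Dice spatial overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b logical matrices of identical shape.
#' @return value in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}
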