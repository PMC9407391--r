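# Training-free segmentation baseline: multiscale curvilinear enhancement
# combined with local background subtraction, normalized into a probability
# map. Invariant to a constant background offset by construction.

#' Classical dendrite segmentation into a probability map
#'
#' Bright curvilinear structures are enhanced with a multiscale Hessian ridge
#' filter; a high-pass intensity term (image minus large-scale background
#' estimate) confines the response to the true branch support. Both terms
#' are normalized by a high quantile of their positive values and combined
#' geometrically, then gamma-compressed so that faint terminal branches still
#' clear the default binarization threshold.
#'
#' @param image numeric matrix (grayscale, any offset/scale).
#' @param ridge_sigma_set ridge filter scales in pixels.
#' @param bg_sigma background estimation scale in pixels.
#' @param norm_quantile quantile of positive responses mapped to 1.
#' @param gamma compression exponent applied to the combined response.
#' @return probability-map matrix in `[0, 1]` (attribute `backend` =
#'   "classical"); a constant image yields an all-zero map with a warning.
#'   Note the classical filter responds to dendrite debris as well; debris
#'   suppression is the job of the fragment filter in
#'   [binarize_and_clean()] or of the trained backend.
#' @export
segment_classical <- function(image, ridge_sigma_set = c(1, 1.5, 2.5),
                              bg_sigma = 16, norm_quantile = 0.995,
                              gamma = 0.25) {
  stopifnot(is.matrix(image))
  if (max(image) - min(image) < 1e-12) {
    warning("constant image: returning an all-zero probability map")
    out <- matrix(0, nrow(image), ncol(image))
    attr(out, "backend") <- "classical"
    return(out)
  }
  fm <- stats::fft(image)
  hp <- pmax(image - gauss_blur(image, bg_sigma, fm = fm), 0)
  ridge <- ridge_response(image, ridge_sigma_set, fm = fm)
  norm01 <- function(m) {
    top <- max(m)
    if (!is.finite(top) || top <= 0) return(m * 0)
    # ignore FFT roundoff crumbs when picking the normalization quantile
    q <- stats::quantile(m[m > 1e-9 * top], norm_quantile, names = FALSE)
    if (!is.finite(q) || q <= 0) return(m * 0)
    pmin(m / q, 1)
  }
  p <- (norm01(ridge) * norm01(hp))^gamma
  attr(p, "backend") <- "classical"
  p
}
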