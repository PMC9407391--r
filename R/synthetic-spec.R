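# Generator parameters for synthetic class-IV-like dendritic arbors.

#' Parameters for the synthetic arbor generator
#'
#' Defaults emulate a larval class IV da ("c4da") sensory neuron: a central
#' soma with several primary dendrites radiating into a planar, roughly
#' space-filling arbor; branches are 1-3 px wide at 2 px/um, terminal
#' branches are rendered fainter than the backbone, and detached high-intensity
#' debris speckles (engulfed membrane fragments) appear in the image but never
#' in the ground-truth mask.
#'
#' @param n_primary number of primary branches leaving the soma (4-8 typical).
#' @param branch_prob per-segment probability that a growth cone bifurcates.
#' @param term_prob per-segment probability that a growth cone terminates
#'   (creating an interior tip) once past `min_depth_term` segments.
#' @param seg_len_mean_um,seg_len_sd_um segment length distribution in um.
#' @param max_depth cap on segment depth from the soma.
#' @param angle_jitter_deg s.d. of the per-segment heading noise in degrees.
#' @param target_tips optional terminal-tip target; branching stops once the
#'   projected tip count reaches it (generated count is within +/-10%).
#' @param field_size_px side of the square image field in pixels.
#' @param px_per_um spatial scale.
#' @param width_px_range rendered branch diameter range `c(min, max)` px;
#'   width decays from soma to terminals.
#' @param soma_radius_px rendered soma radius.
#' @param psf_sigma_px Gaussian blur emulating the microscope PSF.
#' @param noise_sd additive Gaussian noise s.d. (image is on a 0-1 scale).
#' @param background constant background level.
#' @param faint_tip_contrast intensity of terminal branches relative to the
#'   backbone (terminal branches are "relatively faint" in real images).
#' @param debris_rate expected debris fragments per 10^4 px^2.
#' @param margin_px free border kept between the arbor and the image edge.
#' @param seed integer seed; identical spec + seed gives identical output.
#' @return object of class `synthetic_spec` (a validated list).
#' @export
synthetic_spec <- function(n_primary = 5L,
                           branch_prob = 0.35,
                           term_prob = 0.05,
                           seg_len_mean_um = 6,
                           seg_len_sd_um = 2,
                           max_depth = 64L,
                           angle_jitter_deg = 18,
                           target_tips = NULL,
                           field_size_px = 1024L,
                           px_per_um = 2,
                           width_px_range = c(1, 2),
                           soma_radius_px = 6,
                           psf_sigma_px = 1,
                           noise_sd = 0.05,
                           background = 0.1,
                           faint_tip_contrast = 0.55,
                           debris_rate = 0.3,
                           margin_px = 16,
                           seed = 1L) {
  spec <- list(n_primary = as.integer(n_primary), branch_prob = branch_prob,
               term_prob = term_prob, seg_len_mean_um = seg_len_mean_um,
               seg_len_sd_um = seg_len_sd_um, max_depth = as.integer(max_depth),
               angle_jitter_deg = angle_jitter_deg,
               target_tips = if (is.null(target_tips)) NULL else as.integer(target_tips),
               field_size_px = as.integer(field_size_px), px_per_um = px_per_um,
               width_px_range = width_px_range, soma_radius_px = soma_radius_px,
               psf_sigma_px = psf_sigma_px, noise_sd = noise_sd,
               background = background, faint_tip_contrast = faint_tip_contrast,
               debris_rate = debris_rate, margin_px = margin_px,
               seed = as.integer(seed))
  validate_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}

validate_spec <- function(spec) {
  probs <- c(branch_prob = spec$branch_prob, term_prob = spec$term_prob,
             faint_tip_contrast = spec$faint_tip_contrast)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities/contrasts must lie in [0, 1]")
  }
  pos <- c(spec$n_primary, spec$seg_len_mean_um, spec$field_size_px,
           spec$px_per_um, spec$soma_radius_px, spec$max_depth)
  if (any(pos <= 0)) stop("counts, lengths, sizes and scales must be > 0")
  if (any(c(spec$seg_len_sd_um, spec$psf_sigma_px, spec$noise_sd,
            spec$debris_rate, spec$margin_px, spec$background) < 0)) {
    stop("noise, blur, debris and margin parameters must be >= 0")
  }
  if (length(spec$width_px_range) != 2 || any(spec$width_px_range <= 0) ||
      diff(spec$width_px_range) < 0) {
    stop("width_px_range must be an increasing positive pair")
  }
  if (!is.null(spec$target_tips) && spec$target_tips < spec$n_primary) {
    stop("target_tips must be >= n_primary")
  }
  invisible(spec)
}

#' Derive a modified copy of a spec
#' @param spec a `synthetic_spec`.
#' @param ... fields to override.
#' @export
update_spec <- function(spec, ...) {
  mods <- list(...)
  for (nm in names(mods)) spec[[nm]] <- mods[[nm]]
  validate_spec(spec)
  class(spec) <- "synthetic_spec"
  spec
}
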