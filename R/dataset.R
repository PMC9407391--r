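# Batch generation of labeled synthetic corpora: images, ground-truth masks,
# SWC skeletons, transition labels for paired time points, and a manifest
# CSV holding per-neuron ground-truth morphometrics.

#' Generate a labeled synthetic dataset on disk
#'
#' Writes, per neuron, an intensity image (16-bit PGM), a ground-truth mask
#' (8-bit PGM), and an SWC skeleton; with `paired = TRUE` each neuron gets
#' two time points related by branch elimination/addition (plus optional
#' growth and rigid offset) and a tip-label CSV. The manifest CSV is written
#' last via an atomic rename so a failed run never leaves a manifest that
#' references missing files.
#'
#' @param spec a [synthetic_spec()]; per-neuron seeds are derived from
#'   `spec$seed`.
#' @param n_neurons number of neurons.
#' @param paired generate two time points per neuron.
#' @param out_dir output directory (created if needed).
#' @param tip_range if non-NULL, per-neuron `target_tips` values are drawn
#'   log-uniformly from `c(lo, hi)`; otherwise `spec` is used as-is.
#' @param p_elim,p_add,growth,offset_px evolution parameters (paired mode).
#' @return path of the manifest CSV, invisibly; the manifest has one row per
#'   neuron with file paths, seeds, and ground-truth morphometrics.
#' @export
make_dataset <- function(spec, n_neurons, paired = FALSE, out_dir,
                         tip_range = NULL, p_elim = 0.15, p_add = 0.1,
                         growth = 1, offset_px = c(3, -2)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", n_neurons)
  tip_targets <- if (!is.null(tip_range)) {
    with_seed(spec$seed + 31L, {
      round(exp(stats::runif(n_neurons, log(tip_range[1]), log(tip_range[2]))))
    })
  } else NULL

  for (i in seq_len(n_neurons)) {
    nid <- sprintf("n%03d", i)
    seed_i <- spec$seed + 7919L * i
    spec_i <- update_spec(spec, seed = seed_i)
    if (!is.null(tip_targets)) spec_i <- update_spec(spec_i, target_tips = tip_targets[i])
    skel <- generate_arbor(spec_i)
    gt <- function(s, tp) {
      data.frame(gt_length_um = total_length(s),
                 gt_tips = length(tip_ids(s)),
                 gt_territory_pct = territory_coverage(s))
    }
    if (!paired) {
      ren <- render_arbor(skel, spec_i)
      img_f <- file.path(out_dir, paste0(nid, "_img.pgm"))
      msk_f <- file.path(out_dir, paste0(nid, "_mask.pgm"))
      swc_f <- file.path(out_dir, paste0(nid, ".swc"))
      write_pgm(ren$image, img_f, maxval = 65535L)
      write_pgm(ren$mask * 1, msk_f, maxval = 255L)
      write_swc(skel, swc_f)
      rows[[i]] <- cbind(
        data.frame(neuron_id = nid, seed = seed_i,
                   image = basename(img_f), mask = basename(msk_f),
                   swc = basename(swc_f)),
        gt(skel))
    } else {
      ev <- evolve_arbor(skel, p_elim = p_elim, p_add = p_add, growth = growth,
                         offset_px = offset_px, seed = seed_i + 1L)
      files <- list()
      for (tp in c("t1", "t2")) {
        s <- if (tp == "t1") skel else ev$t2
        ren <- render_arbor(s, update_spec(spec_i, seed = seed_i + ifelse(tp == "t1", 0L, 13L)))
        files[[paste0("image_", tp)]] <- file.path(out_dir, paste0(nid, "_", tp, "_img.pgm"))
        files[[paste0("mask_", tp)]] <- file.path(out_dir, paste0(nid, "_", tp, "_mask.pgm"))
        files[[paste0("swc_", tp)]] <- file.path(out_dir, paste0(nid, "_", tp, ".swc"))
        write_pgm(ren$image, files[[paste0("image_", tp)]], maxval = 65535L)
        write_pgm(ren$mask * 1, files[[paste0("mask_", tp)]], maxval = 255L)
        write_swc(s, files[[paste0("swc_", tp)]])
      }
      lab_f <- file.path(out_dir, paste0(nid, "_labels.csv"))
      lab_df <- rbind(
        data.frame(timepoint = "t1", ev$labels$t1_tip_labels),
        data.frame(timepoint = "t2", ev$labels$t2_tip_labels))
      utils::write.csv(lab_df, lab_f, row.names = FALSE)
      cnt <- ev$labels$counts
      g1 <- gt(skel); names(g1) <- paste0(names(g1), "_t1")
      g2 <- gt(ev$t2); names(g2) <- paste0(names(g2), "_t2")
      rows[[i]] <- cbind(
        data.frame(neuron_id = nid, seed = seed_i,
                   image_t1 = basename(files$image_t1), mask_t1 = basename(files$mask_t1),
                   swc_t1 = basename(files$swc_t1),
                   image_t2 = basename(files$image_t2), mask_t2 = basename(files$mask_t2),
                   swc_t2 = basename(files$swc_t2),
                   labels = basename(lab_f),
                   offset_dx = offset_px[1], offset_dy = offset_px[2],
                   growth = growth,
                   gt_stable = cnt[["stable"]], gt_eliminated = cnt[["eliminated"]],
                   gt_added = cnt[["added"]]),
        g1, g2)
    }
  }
  manifest <- do.call(rbind, rows)
  tmp <- tempfile(tmpdir = out_dir, fileext = ".csv")
  utils::write.csv(manifest, tmp, row.names = FALSE)
  man_f <- file.path(out_dir, "manifest.csv")
  file.rename(tmp, man_f)
  invisible(man_f)
}
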