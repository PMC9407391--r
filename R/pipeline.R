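# End-to-end pipeline: simulate -> (train) -> segment -> quantify ->
# dynamics -> report, with a serializable config and deterministic outputs.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed global seed; all stage seeds derive from it.
#' @param n_neurons number of simulated neurons.
#' @param paired simulate and analyze two time points per neuron.
#' @param backend segmentation backend, "classical" or "trained".
#' @param ... overrides for nested blocks (`spec`, `segment`, `clean`,
#'   `quantify`, `dynamics`, `report`, `train`).
#' @return nested configuration list of class `pipeline_config`.
#' @export
default_config <- function(out_dir, seed = 1L, n_neurons = 30L,
                           paired = TRUE, backend = "classical", ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    n_neurons = as.integer(n_neurons), paired = paired, backend = backend,
    model_path = NULL,
    spec = list(field_size_px = 512L, target_tips = 80L, n_primary = 5L,
                margin_px = 12),
    train = list(n_images = 0L, epochs = 8L),
    evolve = list(p_elim = 0.15, p_add = 0.1, growth = 1, offset_px = c(3, -2)),
    segment = list(ridge_sigma_set = c(1, 1.5, 2.5)),
    clean = list(threshold = 0.5, min_fragment_px = 30, gap_close_px = 2),
    quantify = list(px_per_um = 2, min_spur_px = 3, cell_px = 20,
                    sholl_step_um = 10),
    dynamics = list(match_tol_px = 3, cover_frac = 0.7, search_px = 10),
    report = list(method = "student_t", metric = "tip_count")
  )
  mods <- list(...)
  for (nm in names(mods)) {
    if (is.list(mods[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(mods[[nm]])) cfg[[nm]][[k]] <- mods[[nm]][[k]]
    } else cfg[[nm]] <- mods[[nm]]
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                        null = "null")
  # small deterministic FNV-1a style hash; avoids extra dependencies
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", h)
}

write_stamped_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# dendromorph ", as.character(utils::packageVersion("dendromorph"))),
    paste0("# config_hash ", config_hash(cfg))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by the pipeline (skipping stamp comments)
#' @param path CSV path.
#' @export
read_stamped_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate a labeled dataset; optionally train the segmenter on a
#' disjoint training set; segment and clean every image; quantify
#' morphometry; for paired data compute dynamics records and the survival
#' table; summarize and run the configured group comparison. Every stage
#' failure aborts with a stage-named error. Outputs are deterministic given
#' the same config (no timestamps).
#'
#' @param cfg a [default_config()] list.
#' @return invisible list with the output paths and in-memory tables.
#' @export
run_pipeline <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(cfg$out_dir, "data")
  mask_dir <- file.path(cfg$out_dir, "masks")
  dir.create(mask_dir, showWarnings = FALSE)

  spec <- stage("config", do.call(synthetic_spec,
                                  c(cfg$spec, list(seed = cfg$seed))))
  man_f <- stage("simulate", make_dataset(
    spec, cfg$n_neurons, paired = cfg$paired, out_dir = data_dir,
    p_elim = cfg$evolve$p_elim, p_add = cfg$evolve$p_add,
    growth = cfg$evolve$growth, offset_px = cfg$evolve$offset_px))
  manifest <- utils::read.csv(man_f)

  model <- NULL
  if (cfg$backend == "trained") {
    if (!is.null(cfg$model_path)) {
      if (!file.exists(cfg$model_path)) {
        stop("pipeline stage 'segment' failed: trained backend selected but ",
             "model file '", cfg$model_path, "' does not exist; train one ",
             "with train_segmenter() or set backend = 'classical'",
             call. = FALSE)
      }
      model <- load_model(cfg$model_path)
    } else if (cfg$train$n_images >= 8) {
      model <- stage("train", {
        tr_dir <- file.path(cfg$out_dir, "train_data")
        tr_spec <- update_spec(spec, seed = cfg$seed + 500000L)
        tr_man <- make_dataset(tr_spec, cfg$train$n_images, paired = FALSE,
                               out_dir = tr_dir)
        m <- train_segmenter(tr_man, segmenter_config(
          epochs = cfg$train$epochs, seed = cfg$seed))
        save_model(m, file.path(cfg$out_dir, "model.json"))
        m
      })
    } else {
      stop("pipeline stage 'segment' failed: trained backend selected but ",
           "no model_path given and train$n_images < 8", call. = FALSE)
    }
  }

  seg_one <- function(img_file, mask_file_out) {
    img <- read_pgm(file.path(data_dir, img_file))
    prob <- if (cfg$backend == "trained") segment_trained(img, model) else
      do.call(segment_classical, c(list(img), cfg$segment))
    msk <- suppressWarnings(do.call(binarize_and_clean,
                                    c(list(prob), cfg$clean)))
    write_pgm(msk * 1, file.path(mask_dir, mask_file_out), maxval = 255L)
    msk
  }

  morpho <- list(); dyn <- list(); alive <- c()
  stage("segment+quantify", {
    tps <- if (cfg$paired) c("t1", "t2") else ""
    for (i in seq_len(nrow(manifest))) {
      nid <- manifest$neuron_id[i]
      skels <- list()
      for (tp in tps) {
        img_col <- if (cfg$paired) paste0("image_", tp) else "image"
        msk <- seg_one(manifest[[img_col]][i],
                       paste0(nid, ifelse(tp == "", "", paste0("_", tp)), "_mask.pgm"))
        dead <- isTRUE(attr(msk, "dead"))
        rec <- do.call(quantify, c(list(
          msk, neuron_id = nid, timepoint = if (tp == "") "t1" else tp),
          cfg$quantify))
        morpho[[length(morpho) + 1]] <- as.data.frame(rec)
        if (cfg$paired) {
          skels[[tp]] <- if (dead) empty_skeleton(cfg$quantify$px_per_um) else
            skeletonize(msk, px_per_um = cfg$quantify$px_per_um,
                        min_spur_px = cfg$quantify$min_spur_px)
        }
        if (tp == tps[length(tps)]) alive <- c(alive, !dead)
      }
      if (cfg$paired) {
        rec <- do.call(dynamics_record, c(list(
          skels$t1, skels$t2, neuron_id = nid), cfg$dynamics))
        dyn[[length(dyn) + 1]] <- as.data.frame(rec)
      }
    }
  })
  morpho <- do.call(rbind, morpho)
  write_stamped_csv(morpho, file.path(cfg$out_dir, "morphometry.csv"), cfg)

  out <- list(morphometry = morpho, manifest = manifest,
              out_dir = cfg$out_dir)
  if (cfg$paired) {
    dyn <- do.call(rbind, dyn)
    write_stamped_csv(dyn, file.path(cfg$out_dir, "dynamics.csv"), cfg)
    surv <- survival_rate(alive)
    write_stamped_csv(as.data.frame(surv),
                      file.path(cfg$out_dir, "survival.csv"), cfg)
    out$dynamics <- dyn
    out$survival <- surv
  }
  stage("report", {
    summ <- summarize_records(morpho, keys = "timepoint",
                              metrics = c("total_length_um", "tip_count",
                                          "territory_pct"))
    write_stamped_csv(summ, file.path(cfg$out_dir, "summary.csv"), cfg)
    out$summary <- summ
    if (cfg$paired) {
      cmpr <- compare_groups(morpho[[cfg$report$metric]], morpho$timepoint,
                             method = cfg$report$method,
                             metric = cfg$report$metric)
      write_stamped_csv(cmpr$groups,
                        file.path(cfg$out_dir, "comparison_groups.csv"), cfg)
      if (!is.null(cmpr$pairs)) {
        write_stamped_csv(cmpr$pairs,
                          file.path(cfg$out_dir, "comparison_pairs.csv"), cfg)
      }
      out$comparison <- cmpr
    }
  })
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out)
}
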