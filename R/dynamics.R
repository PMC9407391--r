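# Two-time-point dendrite dynamics: rigid alignment, the transition-state
# arbor (dendrites present at both time points), and the stable / eliminated
# / added tip accounting with its conservation identities
#   stable + eliminated = tips(t1),  stable + added = tips(t2).

raster_dim_for <- function(...) {
  skels <- list(...)
  mx <- 0; my <- 0
  for (s in skels) {
    if (nrow(s$nodes) == 0) next
    mx <- max(mx, max(s$nodes$x)); my <- max(my, max(s$nodes$y))
  }
  c(ceiling(my) + 4L, ceiling(mx) + 4L)
}

#' Estimate the rigid offset between two skeletons
#'
#' Exhaustive search over integer translations in
#' `[-search_px, search_px]^2`, scoring the number of t1 skeleton pixels
#' falling inside the t2 skeleton dilated by `match_tol_px`. Ties are broken
#' toward the smallest offset. The convention is `t2 ~ t1 + offset`.
#'
#' @param skel_t1,skel_t2 non-empty [skeleton_graph()] objects.
#' @param search_px half-width of the search window.
#' @param match_tol_px dilation tolerance for the overlap score.
#' @return list `dx`, `dy`, `score`; when no translation yields any overlap
#'   the identity offset is returned with a warning.
#' @export
align_skeletons <- function(skel_t1, skel_t2, search_px = 10,
                            match_tol_px = 2) {
  if (nrow(skel_t1$nodes) == 0 || nrow(skel_t2$nodes) == 0) {
    stop("cannot align empty skeletons")
  }
  dimr <- raster_dim_for(skel_t1, skel_t2) + 2L * search_px
  r2 <- rasterize_skeleton(skel_t2, dimr)
  d2 <- dilate_disk(r2, match_tol_px)
  x1 <- round(skel_t1$nodes$x); y1 <- round(skel_t1$nodes$y)
  best <- c(0L, 0L); best_score <- -1
  offs <- expand.grid(dx = -search_px:search_px, dy = -search_px:search_px)
  offs <- offs[order(abs(offs$dx) + abs(offs$dy)), ]
  for (k in seq_len(nrow(offs))) {
    xs <- x1 + offs$dx[k]; ys <- y1 + offs$dy[k]
    ok <- xs >= 1 & xs <= dimr[2] & ys >= 1 & ys <= dimr[1]
    # exact raster hits dominate so the dilation plateau cannot pull the
    # optimum toward smaller offsets; dilated hits break remaining ties
    sc <- 2 * sum(r2[cbind(ys[ok], xs[ok])]) + sum(d2[cbind(ys[ok], xs[ok])])
    if (sc > best_score) { best_score <- sc; best <- c(offs$dx[k], offs$dy[k]) }
  }
  if (best_score <= 0) {
    warning("no skeleton overlap within the search window; using identity")
    best <- c(0L, 0L)
  }
  list(dx = best[1], dy = best[2], score = best_score)
}

#' Transition-state arbor: the sub-arbor present at both time points
#'
#' Keeps the t1 skeleton (the backbone) nodes that lie within
#' `match_tol_px` of the t2 skeleton after applying `offset` to t1, then
#' drops leftover fragments smaller than `min_fragment_nodes`.
#'
#' @param skel_t1,skel_t2 [skeleton_graph()] objects.
#' @param match_tol_px matching tolerance in pixels.
#' @param offset integer `c(dx, dy)` with `t2 ~ t1 + offset` (from
#'   [align_skeletons()]); default assumes pre-aligned input.
#' @param min_fragment_nodes smallest fragment kept after intersection.
#' @return a [skeleton_graph()] in t1 coordinates (possibly empty).
#' @export
transition_arbor <- function(skel_t1, skel_t2, match_tol_px = 3,
                             offset = c(0, 0), min_fragment_nodes = 3) {
  if (nrow(skel_t2$nodes) == 0 || nrow(skel_t1$nodes) == 0) {
    return(empty_skeleton(skel_t1$px_per_um))
  }
  dimr <- raster_dim_for(skel_t1, skel_t2) + 2L * ceiling(max(abs(offset)))
  d2 <- dilate_disk(rasterize_skeleton(skel_t2, dimr), match_tol_px)
  xs <- pmin(dimr[2], pmax(1, round(skel_t1$nodes$x + offset[1])))
  ys <- pmin(dimr[1], pmax(1, round(skel_t1$nodes$y + offset[2])))
  keep <- d2[cbind(ys, xs)]
  if (!any(keep)) return(empty_skeleton(skel_t1$px_per_um))
  tr <- subset_skeleton(skel_t1, skel_t1$nodes$id[keep])
  # drop small disconnected fragments
  g <- as_igraph(tr)
  comp <- igraph::components(g)
  big <- which(comp$csize >= min_fragment_nodes)
  root_comp <- comp$membership[match(tr$root, tr$nodes$id)]
  big <- union(big, root_comp)
  if (length(big) < comp$no) {
    tr <- subset_skeleton(tr, tr$nodes$id[comp$membership %in% big])
  }
  tr
}

# coverage fraction of each terminal branch of `skel` (shifted by offset)
# inside the dilated raster `dil`; sampled at ~1 px steps along the chain so
# long simplified edges are measured fairly
branch_coverage <- function(skel, dil, offset = c(0, 0)) {
  chains <- terminal_branch_nodes(skel)
  nd <- skel$nodes
  dimr <- dim(dil)
  vapply(chains, function(ids) {
    i <- match(ids, nd$id)
    xs0 <- nd$x[i]; ys0 <- nd$y[i]
    xs <- xs0[1]; ys <- ys0[1]
    if (length(i) > 1) {
      for (k in seq_len(length(i) - 1)) {
        L <- sqrt((xs0[k + 1] - xs0[k])^2 + (ys0[k + 1] - ys0[k])^2)
        t <- seq(0, 1, length.out = max(2L, ceiling(L) + 1L))[-1]
        xs <- c(xs, xs0[k] + t * (xs0[k + 1] - xs0[k]))
        ys <- c(ys, ys0[k] + t * (ys0[k + 1] - ys0[k]))
      }
    }
    xi <- pmin(dimr[2], pmax(1, round(xs + offset[1])))
    yi <- pmin(dimr[1], pmax(1, round(ys + offset[2])))
    mean(dil[cbind(yi, xi)])
  }, numeric(1))
}

#' Dendrite dynamics record for one neuron across two time points
#'
#' A t1 tip is stable when at least `cover_frac` of its terminal branch lies
#' within the t2 skeleton dilated by `match_tol_px` (after rigid alignment).
#' Eliminated and added counts follow by subtraction from the tip totals, so
#' the conservation identities hold by construction:
#' `S + E = T1`, `S + A = T2`.
#'
#' @param skel_t1,skel_t2 [skeleton_graph()] objects for the same neuron.
#' @param neuron_id,t1,t2 identifiers stored in the record.
#' @param match_tol_px matching tolerance.
#' @param cover_frac minimum covered fraction of a terminal branch for the
#'   tip to count as stable.
#' @param search_px alignment search half-width; `align = FALSE` skips
#'   alignment (inputs already registered).
#' @param align run rigid alignment first.
#' @return object of class `dynamics_record` with fields `T1`, `T2`, `S`,
#'   `E`, `A`, `pct_eliminated`, `pct_added`, `delta_length_um`,
#'   `delta_tips`, `ratio_length`, `ratio_tips`, `offset`, `dead`.
#' @export
dynamics_record <- function(skel_t1, skel_t2, neuron_id = "n1",
                            t1 = "t1", t2 = "t2", match_tol_px = 3,
                            cover_frac = 0.7, search_px = 10, align = TRUE) {
  T1 <- count_tips(skel_t1)
  L1 <- total_length(skel_t1)
  dead <- nrow(skel_t2$nodes) == 0
  if (dead) {
    S <- 0L; E <- T1; A <- 0L; T2 <- 0L; L2 <- 0
    off <- list(dx = 0, dy = 0)
    S2 <- 0L
  } else {
    T2 <- count_tips(skel_t2)
    L2 <- total_length(skel_t2)
    off <- if (align) {
      align_skeletons(skel_t1, skel_t2, search_px = search_px)
    } else list(dx = 0, dy = 0)
    dimr <- raster_dim_for(skel_t1, skel_t2) + 2L * search_px
    dil2 <- dilate_disk(rasterize_skeleton(skel_t2, dimr), match_tol_px)
    dil1 <- dilate_disk(rasterize_skeleton(
      transform_skeleton(skel_t1, dx = off$dx, dy = off$dy), dimr), match_tol_px)
    cov1 <- branch_coverage(skel_t1, dil2, offset = c(off$dx, off$dy))
    # restrict to counted tips (terminal_branch_nodes includes all leaves)
    tips1 <- as.character(tip_ids(skel_t1))
    cov1 <- cov1[names(cov1) %in% tips1]
    S <- sum(cov1 >= cover_frac)
    S <- min(S, T2)   # cannot have more stable tips than tips at t2
    cov2 <- branch_coverage(skel_t2, dil1)
    tips2 <- as.character(tip_ids(skel_t2))
    S2 <- sum(cov2[names(cov2) %in% tips2] >= cover_frac)
    E <- T1 - S
    A <- T2 - S
  }
  rec <- list(neuron_id = neuron_id, t1 = t1, t2 = t2,
              T1 = T1, T2 = T2, S = S, E = E, A = A,
              S_t2_view = S2,
              pct_eliminated = if (T1 > 0) 100 * E / T1 else 0,
              pct_added = if (T2 > 0) 100 * A / T2 else 0,
              delta_length_um = L2 - L1, delta_tips = T2 - T1,
              ratio_length = if (L1 > 0) L2 / L1 else NA_real_,
              ratio_tips = if (T1 > 0) T2 / T1 else NA_real_,
              L1 = L1, L2 = L2,
              offset = c(dx = off$dx, dy = off$dy), dead = dead,
              params = list(match_tol_px = match_tol_px,
                            cover_frac = cover_frac, search_px = search_px))
  class(rec) <- "dynamics_record"
  rec
}

#' @export
as.data.frame.dynamics_record <- function(x, ...) {
  data.frame(neuron_id = x$neuron_id, t1 = x$t1, t2 = x$t2,
             T1 = x$T1, T2 = x$T2, S = x$S, E = x$E, A = x$A,
             pct_eliminated = x$pct_eliminated, pct_added = x$pct_added,
             delta_length_um = x$delta_length_um, delta_tips = x$delta_tips,
             ratio_length = x$ratio_length, ratio_tips = x$ratio_tips,
             offset_dx = x$offset[["dx"]], offset_dy = x$offset[["dy"]],
             dead = x$dead, stringsAsFactors = FALSE)
}

#' @export
print.dynamics_record <- function(x, ...) {
  cat(sprintf(
    "<dynamics_record> %s %s->%s: T1=%d T2=%d S=%d E=%d A=%d (elim %.1f%%, added %.1f%%)%s\n",
    x$neuron_id, x$t1, x$t2, x$T1, x$T2, x$S, x$E, x$A,
    x$pct_eliminated, x$pct_added, if (x$dead) " [dead]" else ""))
  invisible(x)
}

#' Neuron survival table by condition
#'
#' A neuron counts as alive when its final-time-point mask survives cleaning
#' (the soma component is present); the caller supplies the per-neuron
#' alive/dead calls.
#'
#' @param alive logical vector (one element per neuron).
#' @param condition factor or character vector of the same length.
#' @return data.frame of class `survival_table` with `condition`, `n_alive`,
#'   `n_total`, `survival_pct`.
#' @export
survival_rate <- function(alive, condition = rep("all", length(alive))) {
  stopifnot(length(alive) == length(condition), length(alive) >= 1)
  tab <- stats::aggregate(alive, by = list(condition = condition),
                          FUN = function(v) c(sum(v), length(v)))
  out <- data.frame(condition = tab$condition,
                    n_alive = tab$x[, 1], n_total = tab$x[, 2])
  out$survival_pct <- 100 * out$n_alive / out$n_total
  class(out) <- c("survival_table", "data.frame")
  out
}
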