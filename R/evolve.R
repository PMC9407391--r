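# Evolve a ground-truth arbor between two imaging time points: whole terminal
# branches are eliminated, new terminal branches sprout, the surviving
# geometry optionally scales (larval growth) and shifts (re-mounting offset).
# Every terminal branch carries a ground-truth label so the downstream
# dynamics accounting can be validated exactly.

#' Evolve an arbor into a second time point with known transition labels
#'
#' A fraction `p_elim` of terminal branches (tip back to the nearest branch
#' point) is removed; new unbranched terminal branches are grown so that
#' added / tips(t2) is close to `p_add`; all surviving geometry is scaled by
#' `growth` about the soma and translated by `offset_px`.
#'
#' @param skel a tree-structured [skeleton_graph()] (with a `parent` column).
#' @param p_elim fraction of t1 terminal branches eliminated, in `[0, 1)`;
#'   `p_elim = 1` is allowed and flagged degenerate (soma-only survivor).
#' @param p_add target fraction added / tips(t2), in `[0, 1)`.
#' @param growth uniform scale factor `>= 1` applied about the soma.
#' @param offset_px rigid translation `c(dx, dy)` applied to the t2 arbor.
#' @param seed integer seed.
#' @param field_size_px bounds check for the scaled/translated arbor; taken
#'   from the generating spec when available.
#' @return list with elements `t2` (the evolved [skeleton_graph()]) and
#'   `labels` (a `transition_labels` object: per-tip labels for both time
#'   points, the t1 to t2 node id map, and the applied offset).
#' @export
evolve_arbor <- function(skel, p_elim = 0.15, p_add = 0.1, growth = 1,
                         offset_px = c(0, 0), seed = 1L,
                         field_size_px = NULL) {
  if (!"parent" %in% names(skel$nodes)) {
    stop("evolve_arbor needs a tree-structured skeleton (parent column)")
  }
  stopifnot(p_elim >= 0, p_elim <= 1, p_add >= 0, p_add < 1, growth >= 1)
  spec <- attr(skel, "spec")
  if (is.null(field_size_px)) {
    field_size_px <- if (!is.null(spec)) spec$field_size_px else Inf
  }

  with_seed(seed, {
    nodes <- skel$nodes
    n <- nrow(nodes)
    children <- vector("list", n)
    for (i in seq_len(n)) {
      p <- nodes$parent[i]
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
    n_children <- lengths(children)
    alive <- rep(TRUE, n)
    is_leaf <- n_children == 0L & seq_len(n) != skel$root
    t1_tips <- which(is_leaf)
    T1 <- length(t1_tips)
    E_target <- round(p_elim * T1)

    # walk from a tip toward the soma while nodes are pass-through
    terminal_chain <- function(tip) {
      chain <- integer(0)
      cur <- tip
      repeat {
        chain <- c(chain, cur)
        p <- nodes$parent[cur]
        if (is.na(p)) break
        live_kids <- sum(alive[children[[p]]])
        if (p == skel$root || live_kids > 1L) break
        cur <- p
      }
      chain
    }

    eliminated_tips <- integer(0)
    if (E_target > 0 && T1 > 0) {
      order_tips <- sample(t1_tips)
      for (tip in order_tips) {
        if (length(eliminated_tips) >= E_target) break
        chain <- terminal_chain(tip)
        stop_node <- nodes$parent[chain[length(chain)]]
        # removal must not turn the attachment node into a new (unlabeled) tip
        if (!is.na(stop_node) && stop_node != skel$root) {
          deg_after <- sum(alive[children[[stop_node]]]) - 1L +
            (!is.na(nodes$parent[stop_node]))
          if (deg_after < 2L) next
        }
        alive[chain] <- FALSE
        eliminated_tips <- c(eliminated_tips, tip)
      }
    }
    E <- length(eliminated_tips)
    S <- T1 - E
    degenerate <- S == 0L
    if (degenerate && p_add == 0) {
      warning("degenerate evolution: only the soma survives")
    }

    # additions: A / (S + A) ~= p_add
    A_target <- round(p_add * S / (1 - p_add))
    if (degenerate && p_add > 0) A_target <- max(A_target, 1L)

    seg_mu <- if (!is.null(spec)) spec$seg_len_mean_um * skel$px_per_um else 12
    seg_sd <- if (!is.null(spec)) spec$seg_len_sd_um * skel$px_per_um else 4
    add_x <- c(); add_y <- c(); add_parent <- c(); add_depth <- c()
    pad <- 1 + ceiling(max(abs(offset_px)))   # new growth must survive the shift
    add_leaf_local <- integer(0)
    live_internal <- which(alive & (n_children > 0L | seq_len(n) == skel$root))
    n_new <- 0L
    if (A_target > 0 && length(live_internal) > 0) {
      base_nodes <- sample(live_internal, A_target, replace = TRUE)
      for (b in base_nodes) {
        nseg <- sample(1:3, 1)
        h <- stats::runif(1, 0, 2 * pi)
        cx <- nodes$x[b]; cy <- nodes$y[b]
        par_local <- -b   # negative = index into original nodes
        start_n <- n_new
        for (s in seq_len(nseg)) {
          L <- max(8, stats::rnorm(1, seg_mu, seg_sd))
          h <- h + stats::rnorm(1, 0, 0.3)
          cx <- cx + L * cos(h); cy <- cy + L * sin(h)
          if (is.finite(field_size_px) &&
              (cx < 1 + pad || cx > field_size_px - pad ||
               cy < 1 + pad || cy > field_size_px - pad)) break
          n_new <- n_new + 1L
          add_x[n_new] <- cx; add_y[n_new] <- cy
          add_parent[n_new] <- par_local
          add_depth[n_new] <- nodes$depth[b] + s
          par_local <- n_new
        }
        if (n_new > start_n) add_leaf_local <- c(add_leaf_local, n_new)
      }
    }

    # assemble t2: surviving original nodes first, then added nodes
    keep <- which(alive)
    new_id <- integer(n); new_id[keep] <- seq_along(keep)
    t2_nodes <- data.frame(
      id = seq_along(keep),
      x = nodes$x[keep], y = nodes$y[keep],
      radius = nodes$radius[keep],
      parent = ifelse(is.na(nodes$parent[keep]), NA_integer_,
                      new_id[nodes$parent[keep]]),
      depth = nodes$depth[keep]
    )
    wmin <- if (!is.null(spec)) spec$width_px_range[1] else 1
    if (n_new > 0) {
      off <- nrow(t2_nodes)
      add_ids <- off + seq_len(n_new)
      par2 <- integer(n_new)
      pos <- add_parent[seq_len(n_new)] > 0
      par2[pos] <- off + add_parent[seq_len(n_new)][pos]
      par2[!pos] <- new_id[-add_parent[seq_len(n_new)][!pos]]
      t2_nodes <- rbind(t2_nodes, data.frame(
        id = add_ids, x = add_x[seq_len(n_new)], y = add_y[seq_len(n_new)],
        radius = wmin / 2, parent = par2, depth = add_depth[seq_len(n_new)]))
    }
    t2 <- skeleton_graph(t2_nodes, root = new_id[skel$root],
                         px_per_um = skel$px_per_um,
                         soma_radius_px = skel$soma_radius_px)
    t2 <- transform_skeleton(t2, dx = offset_px[1], dy = offset_px[2],
                             scale = growth)
    if (is.finite(field_size_px)) {
      if (any(t2$nodes$x < 1 | t2$nodes$x > field_size_px |
              t2$nodes$y < 1 | t2$nodes$y > field_size_px)) {
        stop("impossible geometry: scaled/shifted arbor leaves the field")
      }
    }
    attr(t2, "spec") <- spec

    stable_tips_t1 <- setdiff(t1_tips, eliminated_tips)
    added_tips_t2 <- if (n_new > 0) length(keep) + add_leaf_local else integer(0)
    labels <- structure(list(
      t1_tip_labels = data.frame(
        id = c(stable_tips_t1, eliminated_tips),
        label = rep(c("stable", "eliminated"),
                    c(length(stable_tips_t1), E))),
      t2_tip_labels = data.frame(
        id = c(new_id[stable_tips_t1], added_tips_t2),
        label = rep(c("stable", "added"),
                    c(length(stable_tips_t1), length(added_tips_t2)))),
      node_map = data.frame(t1_id = keep, t2_id = new_id[keep]),
      offset_px = offset_px, growth = growth,
      counts = c(T1 = T1, T2 = T1 - E + length(added_tips_t2),
                 stable = length(stable_tips_t1), eliminated = E,
                 added = length(added_tips_t2)),
      degenerate = degenerate
    ), class = "transition_labels")

    list(t2 = t2, labels = labels)
  })
}

#' @export
print.transition_labels <- function(x, ...) {
  cat(sprintf(
    "<transition_labels> T1=%d T2=%d stable=%d eliminated=%d added=%d offset=(%g, %g)\n",
    x$counts["T1"], x$counts["T2"], x$counts["stable"],
    x$counts["eliminated"], x$counts["added"],
    x$offset_px[1], x$offset_px[2]))
  invisible(x)
}
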