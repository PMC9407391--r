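# Stochastic growth of a rooted planar dendritic tree. Growth cones elongate
# in micrometer-scale segments with heading noise and a weak outward tropism
# (real c4da dendrites radiate from the soma and tile their territory), and
# are contact-inhibited: like real da dendrites, which are self-avoiding, a
# cone terminates instead of crossing an existing branch. Cones bifurcate
# with a per-segment probability and terminate stochastically (interior
# tips), on contact, or at the field border.

#' Generate a synthetic dendritic arbor
#'
#' Grows a rooted self-avoiding tree inside the image field described by
#' `spec`. When `spec$target_tips` is set, branching stops once the projected
#' terminal count reaches the target (and terminal elongation is curtailed),
#' so the generated tip count equals the target whenever the geometry allows;
#' a shortfall beyond 10% is an error.
#'
#' @param spec a [synthetic_spec()].
#' @return a [skeleton_graph()] whose `nodes` carry `parent`, `depth` and
#'   `radius` columns; node 1 is the soma.
#' @export
generate_arbor <- function(spec) {
  validate_spec(spec)
  with_seed(spec$seed, {
    fs <- spec$field_size_px
    margin <- spec$margin_px
    cx <- (fs + 1) / 2; cy <- (fs + 1) / 2
    seg_mu <- spec$seg_len_mean_um * spec$px_per_um
    seg_sd <- spec$seg_len_sd_um * spec$px_per_um
    jit <- spec$angle_jitter_deg * pi / 180
    wmin <- spec$width_px_range[1]; wmax <- spec$width_px_range[2]
    avoid_r <- 6L   # self-avoidance standoff between centerlines, px

    min_keep <- 9   # shortest segment worth keeping when a cone terminates
    cap <- 1024L
    x <- numeric(cap); y <- numeric(cap); parent <- integer(cap)
    depth <- integer(cap); radius <- numeric(cap)
    n_children <- integer(cap); counted_tip <- logical(cap)
    n <- 1L
    x[1] <- cx; y[1] <- cy; parent[1] <- NA_integer_; depth[1] <- 0L
    radius[1] <- spec$soma_radius_px

    grow_slot <- function() {
      if (n > cap) {
        cap <<- cap * 2L
        length(x) <<- cap; length(y) <<- cap; length(parent) <<- cap
        length(depth) <<- cap; length(radius) <<- cap
        length(n_children) <<- cap; length(counted_tip) <<- cap
        n_children[is.na(n_children)] <<- 0L
        counted_tip[is.na(counted_tip)] <<- FALSE
      }
    }
    node_radius <- function(d) 0.5 * (wmin + (wmax - wmin) * exp(-d / 10))

    # occupancy raster of already-stamped centerlines (self-avoidance)
    occ <- matrix(FALSE, fs, fs)
    nb <- expand.grid(dr = -avoid_r:avoid_r, dc = -avoid_r:avoid_r)
    nb <- nb[nb$dr^2 + nb$dc^2 <= avoid_r^2, ]   # Euclidean disk window
    stamp <- function(x1, y1, x2, y2) {
      len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.7) + 1L))
      rr <- pmin(fs, pmax(1, round(y1 + t * (y2 - y1))))
      cc <- pmin(fs, pmax(1, round(x1 + t * (x2 - x1))))
      occ[cbind(rr, cc)] <<- TRUE
    }
    # first contact point along the proposed segment, ignoring the first
    # `skip_px` (own origin and sibling stamps); returns truncation t or NA
    contact_t <- function(x1, y1, x2, y2, skip_px = avoid_r + 1) {
      len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
      if (len <= skip_px) return(NA_real_)
      ts <- seq(skip_px / len, 1, by = 1 / len)
      for (t in ts) {
        pr <- round(y1 + t * (y2 - y1)); pc <- round(x1 + t * (x2 - x1))
        rr <- nb$dr + pr; cc <- nb$dc + pc
        ok <- rr >= 1 & rr <= fs & cc >= 1 & cc <= fs
        if (any(occ[cbind(rr[ok], cc[ok])])) return(t)
      }
      NA_real_
    }

    # FIFO queue of growth cones: list(node, heading, depth)
    cones <- vector("list", 4096L)
    head_i <- 1L; tail_i <- 0L
    push <- function(cone) {
      tail_i <<- tail_i + 1L
      if (tail_i > length(cones)) length(cones) <<- 2L * length(cones)
      cones[[tail_i]] <<- cone
    }
    tips_done <- 0L
    h0 <- stats::runif(1, 0, 2 * pi / spec$n_primary)
    for (k in seq_len(spec$n_primary)) {
      h <- h0 + 2 * pi * (k - 1) / spec$n_primary + stats::rnorm(1, 0, jit)
      push(list(node = 1L, h = h, depth = 0L))
    }

    target <- spec$target_tips
    projected <- function() (tail_i - head_i + 1L) + tips_done
    # once the target is reached, remaining cones wrap up quickly instead of
    # wandering to the border (keeps terminal-branch lengths realistic)
    term_prob_idle <- max(spec$term_prob, 0.3)

    interstitial_budget <- if (is.null(target)) 0L else 40L * target
    while (TRUE) {
      if (head_i > tail_i) {
        # queue exhausted: if a tip target remains unmet, sprout interstitial
        # cones from existing internal nodes (real c4da neurons add branches
        # interstitially, not only at the arbor front)
        if (is.null(target) || tips_done >= target ||
            interstitial_budget <= 0L || n < 2L) break
        nb_try <- min(interstitial_budget, max(4L, (target - tips_done)))
        interstitial_budget <- interstitial_budget - nb_try
        bases <- if (n > 2L) sample(2:n, nb_try, replace = TRUE) else rep(2L, nb_try)
        for (b in bases) {
          push(list(node = b, h = stats::runif(1, 0, 2 * pi),
                    depth = depth[b]))
        }
      }
      cone <- cones[[head_i]]; head_i <- head_i + 1L
      L <- max(8, stats::rnorm(1, seg_mu, seg_sd))
      # primaries clear the soma region so no leaf can ever fall inside the
      # soma exclusion zone used by tip counting
      if (cone$depth == 0L) L <- max(L, spec$soma_radius_px + 16)
      h <- cone$h + stats::rnorm(1, 0, jit)
      # weak outward tropism keeps the arbor radial and reduces self-crossing
      px0 <- x[cone$node]; py0 <- y[cone$node]
      if (abs(px0 - cx) + abs(py0 - cy) > 1e-9) {
        out_h <- atan2(py0 - cy, px0 - cx)
        h <- atan2(0.8 * sin(h) + 0.2 * sin(out_h),
                   0.8 * cos(h) + 0.2 * cos(out_h))
      }
      nx <- px0 + L * cos(h); ny <- py0 + L * sin(h)
      hit_border <- nx < margin || nx > fs - margin ||
        ny < margin || ny > fs - margin
      terminate <- FALSE
      if (hit_border) {
        # clip the segment at the border and terminate there
        tmax <- 1
        if (cos(h) != 0) {
          tmax <- min(tmax, max((margin - px0) / (nx - px0),
                                (fs - margin - px0) / (nx - px0)))
        }
        if (sin(h) != 0) {
          tmax <- min(tmax, max((margin - py0) / (ny - py0),
                                (fs - margin - py0) / (ny - py0)))
        }
        tmax <- max(0, min(1, tmax))
        nx <- px0 + tmax * L * cos(h); ny <- py0 + tmax * L * sin(h)
        L <- tmax * L
        terminate <- TRUE
      }
      skip0 <- if (cone$node == 1L) spec$soma_radius_px + avoid_r + 2 else avoid_r + 1
      tc <- contact_t(px0, py0, nx, ny, skip_px = skip0)
      if (!is.na(tc)) {
        # stop short of the contact to keep the standoff
        tstop <- max(0, tc - (avoid_r - 1) / L)
        nx <- px0 + tstop * L * cos(h); ny <- py0 + tstop * L * sin(h)
        L <- tstop * L
        terminate <- TRUE
      }
      if (terminate && (L < min_keep || cone$depth == 0L)) {
        # stub not worth keeping (or a primary dying on its first segment,
        # which would leave a tip inside the soma exclusion zone): the cone
        # dies at its base node, which becomes a tip only if nothing else
        # grew from it
        b <- cone$node
        if (b != 1L && n_children[b] == 0L && !counted_tip[b]) {
          counted_tip[b] <- TRUE
          tips_done <- tips_done + 1L
        }
        next
      }
      stamp(px0, py0, nx, ny)
      n <- n + 1L; grow_slot()
      nd <- cone$depth + 1L
      x[n] <- nx; y[n] <- ny; parent[n] <- cone$node
      depth[n] <- nd; radius[n] <- node_radius(nd)
      b <- cone$node
      n_children[b] <- n_children[b] + 1L
      if (counted_tip[b]) {   # base was provisionally a tip; it no longer is
        counted_tip[b] <- FALSE
        tips_done <- tips_done - 1L
      }
      if (terminate) {
        counted_tip[n] <- TRUE
        tips_done <- tips_done + 1L
        next
      }
      # projected() excludes the cone being processed; +1 restores it so a
      # bifurcation never pushes the final tip count past the target
      at_target <- !is.null(target) && projected() + 1L >= target
      tp <- if (at_target) term_prob_idle else spec$term_prob
      if (nd >= 4L && stats::runif(1) < tp) {
        counted_tip[n] <- TRUE
        tips_done <- tips_done + 1L   # stochastic interior termination
        next
      }
      may_branch <- nd < spec$max_depth && !at_target
      # with a tip target, branching pressure adapts to the remaining
      # deficit so large arbors reach their target before cones die out
      bp <- spec$branch_prob
      if (!is.null(target)) {
        deficit <- target - (projected() + 1L)
        active <- tail_i - head_i + 2L
        bp <- max(bp, min(0.55, 0.55 * deficit / (deficit + active)))
      }
      if (may_branch && stats::runif(1) < bp) {
        dh <- stats::runif(1, 0.55, 0.85)
        push(list(node = n, h = h + dh, depth = nd))
        push(list(node = n, h = h - dh, depth = nd))
      } else {
        push(list(node = n, h = h, depth = nd))
      }
    }

    if (!is.null(target) && tips_done < ceiling(0.9 * target)) {
      stop(sprintf(paste0(
        "arbor cannot fit field: reached %d of %d target tips; ",
        "increase field_size_px or reduce target_tips"), tips_done, target))
    }

    nodes <- data.frame(id = seq_len(n), x = x[seq_len(n)], y = y[seq_len(n)],
                        radius = radius[seq_len(n)],
                        parent = parent[seq_len(n)], depth = depth[seq_len(n)])
    skel <- skeleton_graph(nodes, root = 1L, px_per_um = spec$px_per_um,
                           soma_radius_px = spec$soma_radius_px)
    attr(skel, "spec") <- spec
    skel
  })
}
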