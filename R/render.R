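# Rasterize a skeleton into a microscopy-like intensity image plus the
# noiseless ground-truth mask. Terminal branches are rendered fainter than
# the backbone; detached debris speckles appear only in the image.

# 8-connected 1-px digital line (one pixel per major-axis step); such lines
# are invariant under Zhang-Suen thinning, so thin terminal branches survive
# skeletonization end-to-end.
bresenham_pixels <- function(dim, x1, y1, x2, y2) {
  n <- max(abs(round(x2) - round(x1)), abs(round(y2) - round(y1))) + 1L
  t <- seq(0, 1, length.out = max(2L, n))
  rr <- round(y1 + t * (y2 - y1)); cc <- round(x1 + t * (x2 - x1))
  keep <- rr >= 1 & rr <= dim[1] & cc >= 1 & cc <= dim[2]
  unique((cc[keep] - 1L) * dim[1] + rr[keep])
}

# Stamp all pixels within `r` of the segment (x1,y1)-(x2,y2) using `fun`
# on the target matrix (environment-captured); returns linear indices.
segment_pixels <- function(dim, x1, y1, x2, y2, r) {
  rmin <- max(1L, floor(min(y1, y2) - r)); rmax <- min(dim[1], ceiling(max(y1, y2) + r))
  cmin <- max(1L, floor(min(x1, x2) - r)); cmax <- min(dim[2], ceiling(max(x1, x2) + r))
  if (rmin > rmax || cmin > cmax) return(integer(0))
  rs <- rmin:rmax; cs <- cmin:cmax
  py <- rep(rs, times = length(cs))
  px <- rep(cs, each = length(rs))
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < 1e-12) {
    d2 <- (px - x1)^2 + (py - y1)^2
  } else {
    t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
  }
  keep <- d2 <= r * r
  (px[keep] - 1L) * dim[1] + py[keep]
}

# ids of nodes lying on terminal branches (tip back to the nearest branch
# point, exclusive), used to render faint terminals and to test stability
terminal_branch_nodes <- function(skel) {
  deg <- node_degrees(skel)
  g <- as_igraph(skel)
  leaves <- skel$nodes$id[deg == 1L & skel$nodes$id != skel$root]
  out <- vector("list", length(leaves))
  adj <- igraph::as_adj_list(g)
  idx_of <- seq_len(nrow(skel$nodes)); names(idx_of) <- as.character(skel$nodes$id)
  for (i in seq_along(leaves)) {
    cur <- idx_of[[as.character(leaves[i])]]
    prev <- 0L
    chain <- integer(0)
    repeat {
      chain <- c(chain, cur)
      nb <- setdiff(as.integer(adj[[cur]]), prev)
      if (length(nb) != 1L) break
      nxt <- nb[1]
      if (deg[nxt] >= 3L || skel$nodes$id[nxt] == skel$root) break
      prev <- cur; cur <- nxt
    }
    out[[i]] <- skel$nodes$id[chain]
  }
  names(out) <- as.character(leaves)
  out
}

#' Render an arbor into an intensity image and ground-truth mask
#'
#' The mask is the noiseless branch support (debris excluded); the image adds
#' faint terminal branches, point-spread blur, background, additive noise,
#' and detached debris fragments displaced at least 3 px from true branches.
#'
#' @param skel a [skeleton_graph()].
#' @param spec a [synthetic_spec()]; rendering noise/debris randomness is
#'   seeded from `spec$seed` so identical inputs give identical images.
#' @return list with `image` (numeric matrix in `[0,1]`), `mask` (logical
#'   ground truth) and `debris_mask` (logical, debris support only).
#' @export
render_arbor <- function(skel, spec) {
  fs <- spec$field_size_px
  dimg <- c(fs, fs)
  if (any(skel$nodes$x < 1 | skel$nodes$x > fs |
          skel$nodes$y < 1 | skel$nodes$y > fs)) {
    stop("arbor does not fit the rendering field")
  }
  mask <- matrix(FALSE, fs, fs)
  inten <- matrix(0, fs, fs)

  faint_ids <- unique(unlist(terminal_branch_nodes(skel), use.names = FALSE))
  idx_of <- seq_len(nrow(skel$nodes)); names(idx_of) <- as.character(skel$nodes$id)
  xs <- skel$nodes$x; ys <- skel$nodes$y
  rad <- if ("radius" %in% names(skel$nodes)) skel$nodes$radius else
    rep(mean(spec$width_px_range) / 2, nrow(skel$nodes))
  faint <- skel$nodes$id %in% faint_ids

  if (nrow(skel$edges) > 0) {
    a <- idx_of[as.character(skel$edges[, 1])]
    b <- idx_of[as.character(skel$edges[, 2])]
    for (k in seq_along(a)) {
      r <- max(0.5, (rad[a[k]] + rad[b[k]]) / 2)
      # edges leaving the soma take the child's branch radius, not the soma's
      if (skel$edges[k, 1] == skel$root || skel$edges[k, 2] == skel$root) {
        r <- max(0.5, min(rad[a[k]], rad[b[k]]))
      }
      thin_edge <- r < 0.9 || (faint[a[k]] && faint[b[k]])
      px <- if (thin_edge) {
        bresenham_pixels(dimg, xs[a[k]], ys[a[k]], xs[b[k]], ys[b[k]])
      } else {
        segment_pixels(dimg, xs[a[k]], ys[a[k]], xs[b[k]], ys[b[k]], r)
      }
      if (length(px)) {
        mask[px] <- TRUE
        val <- if (faint[a[k]] && faint[b[k]]) spec$faint_tip_contrast else
          if (faint[b[k]] || faint[a[k]]) (1 + spec$faint_tip_contrast) / 2 else 1
        inten[px] <- pmax(inten[px], val)
      }
    }
  }
  # soma disk
  ri <- match(skel$root, skel$nodes$id)
  px <- segment_pixels(dimg, xs[ri], ys[ri], xs[ri], ys[ri], spec$soma_radius_px)
  mask[px] <- TRUE
  inten[px] <- 1

  # the ground truth is the *visible* dendrite support: what an annotator
  # traces on the blurred image, i.e. the PSF-convolved noiseless signal
  # above a fraction of the faintest branch peak (with psf 0 this is exactly
  # the rendered support)
  if (spec$psf_sigma_px > 0) {
    vis <- gauss_blur(inten, spec$psf_sigma_px)
    mask <- mask | vis >= 0.22 * spec$faint_tip_contrast
  }

  debris <- matrix(FALSE, fs, fs)
  img <- with_seed(spec$seed + 104729L, {
    dlayer <- matrix(0, fs, fs)
    n_debris <- round(spec$debris_rate * fs * fs / 1e4)
    if (n_debris > 0) {
      excl <- dilate_disk(mask, 3)
      free <- which(!excl)
      if (length(free) > 0) {
        centers <- sample(free, min(n_debris, length(free)))
        cy <- ((centers - 1L) %% fs) + 1L
        cx <- ((centers - 1L) %/% fs) + 1L
        for (j in seq_along(centers)) {
          len <- stats::runif(1, 0.5, 4)
          ang <- stats::runif(1, 0, pi)
          pxd <- segment_pixels(dimg, cx[j], cy[j],
                                cx[j] + len * cos(ang), cy[j] + len * sin(ang),
                                stats::runif(1, 0.5, 1))
          pxd <- pxd[!excl[pxd]]
          if (length(pxd)) {
            debris[pxd] <- TRUE
            dlayer[pxd] <- pmax(dlayer[pxd], stats::runif(1, 0.7, 1.1))
          }
        }
      }
    }
    im <- pmax(inten, dlayer)
    im <- gauss_blur(im, spec$psf_sigma_px)
    im <- im + spec$background
    if (spec$noise_sd > 0) {
      im <- im + matrix(stats::rnorm(fs * fs, 0, spec$noise_sd), fs, fs)
    }
    pmin(pmax(im, 0), 1)
  })
  list(image = img, mask = mask, debris_mask = debris)
}
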