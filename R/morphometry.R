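# The four morphology parameters measured per neuron and time point:
# total dendrite length, terminal tip count, percentage of territory covered,
# and the Sholl intersection profile.

#' Skeletonize a binary mask into a centerline graph
#'
#' Topology-preserving thinning to 1-px centerlines; nodes are skeleton
#' pixels, edges connect 8-neighbors (diagonal steps that duplicate an
#' orthogonal 2-step path are dropped so path lengths are not double
#' counted). Terminal spurs shorter than `min_spur_px` are pruned. The soma
#' is the pixel with the deepest erosion depth in the input mask.
#'
#' @param mask logical matrix (non-empty).
#' @param px_per_um spatial scale.
#' @param min_spur_px prune terminal branches shorter than this many pixels
#'   (suppresses thinning artifacts on wide branches).
#' @return a [skeleton_graph()]; may contain cycles if the mask does.
#' @export
skeletonize <- function(mask, px_per_um = 2, min_spur_px = 3) {
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  depth <- erosion_depth(mask)
  soma_radius <- max(depth)
  # among equally deep pixels take the one nearest the mask centroid, so a
  # flat (uniformly thin) mask still gets a central, reproducible soma
  cand <- which(depth == soma_radius)
  cr <- ((cand - 1L) %% nr) + 1L
  ccc <- ((cand - 1L) %/% nr) + 1L
  fg <- which(mask)
  cen_r <- mean(((fg - 1L) %% nr) + 1L)
  cen_c <- mean(((fg - 1L) %/% nr) + 1L)
  soma_lin <- cand[which.min((cr - cen_r)^2 + (ccc - cen_c)^2)]
  soma_r <- ((soma_lin - 1L) %% nr) + 1L
  soma_c <- ((soma_lin - 1L) %/% nr) + 1L

  sk <- thin_mask(mask)
  idx <- which(sk)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  pos <- integer(nr * nc); pos[idx] <- seq_along(idx)

  edge_list <- list()
  # orthogonal forward neighbors: S, E
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- idx[ok] + d[1] + d[2] * nr
    hit <- sk[j]
    edge_list[[length(edge_list) + 1]] <- cbind(pos[idx[ok][hit]], pos[j[hit]])
  }
  # diagonal neighbors SE, NE; skip when an orthogonal bridge pixel exists
  for (d in list(c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    i0 <- idx[ok]
    j <- i0 + d[1] + d[2] * nr
    hit <- sk[j]
    i0 <- i0[hit]; j <- j[hit]
    bridge1 <- sk[i0 + d[1]]        # vertical neighbor of i
    bridge2 <- sk[i0 + d[2] * nr]   # horizontal neighbor of i
    keep <- !(bridge1 | bridge2)
    edge_list[[length(edge_list) + 1]] <- cbind(pos[i0[keep]], pos[j[keep]])
  }
  edges <- do.call(rbind, edge_list)
  if (is.null(edges)) edges <- matrix(integer(0), ncol = 2)

  nodes <- data.frame(id = seq_along(idx), x = as.numeric(cc), y = as.numeric(r))
  root <- pos[soma_lin]
  if (root == 0L) {
    # soma pixel thinned away: root at the skeleton pixel nearest to it
    d2 <- (nodes$x - soma_c)^2 + (nodes$y - soma_r)^2
    root <- which.min(d2)
  }
  skel <- skeleton_graph(nodes, edges = edges, root = root,
                         px_per_um = px_per_um, soma_radius_px = soma_radius)
  skel <- prune_spurs(skel, min_spur_px)
  simplify_skeleton(skel, tol = 1)
}

# Douglas-Peucker polyline simplification; returns indices kept
dp_keep <- function(xs, ys, tol) {
  n <- length(xs)
  if (n <= 2) return(seq_len(n))
  keep <- logical(n); keep[c(1, n)] <- TRUE
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- seg[1]; b <- seg[2]
    if (b - a < 2) next
    dx <- xs[b] - xs[a]; dy <- ys[b] - ys[a]
    L <- sqrt(dx^2 + dy^2)
    ii <- (a + 1):(b - 1)
    d <- if (L < 1e-12) {
      sqrt((xs[ii] - xs[a])^2 + (ys[ii] - ys[a])^2)
    } else {
      abs(dx * (ys[ii] - ys[a]) - dy * (xs[ii] - xs[a])) / L
    }
    k <- which.max(d)
    if (d[k] > tol) {
      m <- ii[k]
      keep[m] <- TRUE
      stack[[length(stack) + 1]] <- c(a, m)
      stack[[length(stack) + 1]] <- c(m, b)
    }
  }
  which(keep)
}

#' Simplify degree-2 pixel chains into polylines
#'
#' Thinning produces staircase pixel chains whose step-count length
#' overestimates the true curve length (up to ~20% at unlucky angles).
#' Collapsing every degree-2 chain with Douglas-Peucker (tolerance `tol` px)
#' leaves junctions and tips in place and makes the Euclidean edge-length sum
#' an unbiased estimate of the traced curve length.
#'
#' @param skel a [skeleton_graph()].
#' @param tol maximum deviation of the simplified polyline from the pixel
#'   chain, in pixels.
#' @return a [skeleton_graph()] with collapsed chains.
#' @export
simplify_skeleton <- function(skel, tol = 1) {
  n <- nrow(skel$nodes)
  if (n <= 2 || nrow(skel$edges) == 0) return(skel)
  nd <- skel$nodes
  root_i <- match(skel$root, nd$id)
  em <- cbind(match(skel$edges[, 1], nd$id), match(skel$edges[, 2], nd$id))
  ne <- nrow(em)
  deg <- tabulate(c(em[, 1], em[, 2]), nbins = n)
  anchor <- deg != 2L
  anchor[root_i] <- TRUE
  # incident edge ids per vertex (integer bookkeeping, no hashing)
  inc <- vector("list", n)
  ord <- order(c(em[, 1], em[, 2]))
  vs <- c(em[, 1], em[, 2])[ord]
  es <- c(seq_len(ne), seq_len(ne))[ord]
  starts <- c(1L, which(diff(vs) > 0) + 1L, length(vs) + 1L)
  uv <- vs[starts[-length(starts)]]
  for (q in seq_along(uv)) inc[[uv[q]]] <- es[starts[q]:(starts[q + 1] - 1L)]
  other <- function(e, v) if (em[e, 1] == v) em[e, 2] else em[e, 1]

  visited <- logical(ne)
  keep <- anchor
  chains <- list()
  for (a in which(anchor)) {
    for (e0 in inc[[a]]) {
      if (visited[e0]) next
      visited[e0] <- TRUE
      cur <- other(e0, a)
      path <- c(a, cur)
      pe <- e0
      while (!anchor[cur]) {
        ee <- inc[[cur]]
        nxt_e <- ee[ee != pe][1]
        if (is.na(nxt_e) || visited[nxt_e]) break
        visited[nxt_e] <- TRUE
        cur <- other(nxt_e, cur)
        path <- c(path, cur)
        pe <- nxt_e
      }
      chains[[length(chains) + 1]] <- path
    }
  }
  new_edges <- vector("list", length(chains) + ne)
  nei <- 0L
  for (path in chains) {
    ki <- dp_keep(nd$x[path], nd$y[path], tol)
    keep[path[ki]] <- TRUE
    nei <- nei + 1L
    new_edges[[nei]] <- cbind(path[ki[-length(ki)]], path[ki[-1]])
  }
  # pure cycles with no anchor node: keep them as-is
  un <- which(!visited)
  if (length(un)) {
    keep[em[un, ]] <- TRUE
    nei <- nei + 1L
    new_edges[[nei]] <- em[un, , drop = FALSE]
  }
  keep_idx <- which(keep)
  remap <- integer(n); remap[keep_idx] <- seq_along(keep_idx)
  nodes <- nd[keep_idx, , drop = FALSE]
  nodes$id <- seq_along(keep_idx)
  edges <- do.call(rbind, new_edges[seq_len(nei)])
  edges <- cbind(remap[edges[, 1]], remap[edges[, 2]])
  skeleton_graph(nodes, edges = edges, root = remap[root_i],
                 px_per_um = skel$px_per_um,
                 soma_radius_px = skel$soma_radius_px)
}

# iteratively remove terminal branches shorter than min_spur_px (path length
# in px); the root's node is never pruned
prune_spurs <- function(skel, min_spur_px) {
  if (min_spur_px <= 0 || nrow(skel$nodes) == 0) return(skel)
  repeat {
    g <- as_igraph(skel)
    deg <- igraph::degree(g)
    nd <- skel$nodes
    tips <- which(deg == 1L & nd$id != skel$root)
    if (length(tips) == 0) break
    adj <- igraph::as_adj_list(g)
    drop <- logical(nrow(nd))
    for (tp in tips) {
      cur <- tp; prev <- 0L
      chain <- integer(0); plen <- 0
      repeat {
        chain <- c(chain, cur)
        nb <- setdiff(as.integer(adj[[cur]]), prev)
        if (length(nb) != 1L) { nxt <- NA_integer_; break }
        nxt <- nb[1]
        plen <- plen + sqrt((nd$x[cur] - nd$x[nxt])^2 + (nd$y[cur] - nd$y[nxt])^2)
        if (deg[nxt] >= 3L || nd$id[nxt] == skel$root || plen >= min_spur_px) break
        prev <- cur; cur <- nxt
      }
      if (plen < min_spur_px && !any(nd$id[chain] == skel$root)) {
        drop[chain] <- TRUE
      }
    }
    if (!any(drop)) break
    keep_ids <- nd$id[!drop]
    skel <- subset_skeleton(skel, keep_ids)
  }
  skel
}

# induced subgraph on a set of node ids; root remapped to nearest kept node
subset_skeleton <- function(skel, keep_ids) {
  nd <- skel$nodes
  keep <- nd$id %in% keep_ids
  new_nodes <- nd[keep, , drop = FALSE]
  old_root_i <- match(skel$root, nd$id)
  remap <- integer(max(nd$id)); remap[new_nodes$id] <- seq_len(nrow(new_nodes))
  e <- skel$edges
  ekeep <- keep[match(e[, 1], nd$id)] & keep[match(e[, 2], nd$id)]
  new_edges <- cbind(remap[e[ekeep, 1]], remap[e[ekeep, 2]])
  if ("parent" %in% names(new_nodes)) new_nodes$parent <- NULL
  if (nrow(new_nodes) == 0) {
    return(empty_skeleton(skel$px_per_um))
  }
  root <- if (skel$root %in% new_nodes$id) remap[skel$root] else {
    d2 <- (new_nodes$x - nd$x[old_root_i])^2 + (new_nodes$y - nd$y[old_root_i])^2
    which.min(d2)
  }
  new_nodes$id <- seq_len(nrow(new_nodes))
  skeleton_graph(new_nodes, edges = new_edges, root = root,
                 px_per_um = skel$px_per_um,
                 soma_radius_px = skel$soma_radius_px)
}

empty_skeleton <- function(px_per_um = 2) {
  obj <- list(nodes = data.frame(id = integer(0), x = numeric(0), y = numeric(0)),
              edges = matrix(integer(0), ncol = 2), root = NA_integer_,
              px_per_um = px_per_um, soma_radius_px = 0)
  class(obj) <- "skeleton_graph"
  obj
}

#' Total dendrite length in micrometers
#'
#' Sum of Euclidean distances between edge endpoints divided by the pixel
#' scale; on a pixel skeleton this is exactly 1 px per orthogonal step and
#' sqrt(2) px per diagonal step.
#'
#' @param skel a [skeleton_graph()].
#' @return length in um.
#' @export
total_length <- function(skel) {
  if (nrow(skel$edges) == 0) return(0)
  i <- match(skel$edges[, 1], skel$nodes$id)
  j <- match(skel$edges[, 2], skel$nodes$id)
  sum(sqrt((skel$nodes$x[i] - skel$nodes$x[j])^2 +
           (skel$nodes$y[i] - skel$nodes$y[j])^2)) / skel$px_per_um
}

#' Count terminal dendrite tips
#'
#' Degree-1 skeleton nodes excluding those within the soma exclusion radius;
#' nodes on cycles have degree 2 and therefore never count.
#'
#' @param skel a [skeleton_graph()].
#' @param soma_exclusion_radius_px default: stored soma radius + 2.
#' @return integer tip count.
#' @export
count_tips <- function(skel, soma_exclusion_radius_px = NULL) {
  if (nrow(skel$nodes) == 0) return(0L)
  length(tip_ids(skel, soma_exclusion_radius_px))
}

#' Percentage of dendritic territory covered
#'
#' A square grid of side `cell_px` is laid over the field; the territory is
#' the set of grid cells whose centers fall inside the convex hull of the
#' skeleton, and coverage is the percentage of those cells containing at
#' least one skeleton pixel. A degenerate (collinear) hull scores 100 by
#' convention.
#'
#' @param skel a [skeleton_graph()].
#' @param cell_px grid cell side in pixels.
#' @return percentage in `[0, 100]`.
#' @export
territory_coverage <- function(skel, cell_px = 20) {
  nd <- skel$nodes
  if (nrow(nd) < 3) return(100)
  dimr <- c(ceiling(max(nd$y) + 2), ceiling(max(nd$x) + 2))
  ras <- rasterize_skeleton(skel, dimr)
  idx <- which(ras)
  yr <- ((idx - 1L) %% dimr[1]) + 1L
  xr <- ((idx - 1L) %/% dimr[1]) + 1L
  hull <- grDevices::chull(nd$x, nd$y)
  hx <- nd$x[hull]; hy <- nd$y[hull]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  occupied <- unique(paste(ceiling(xr / cell_px), ceiling(yr / cell_px)))
  if (area < cell_px^2 / 4) return(100)  # degenerate hull: line-like arbor
  cxi <- seq_len(ceiling(dimr[2] / cell_px))
  cyi <- seq_len(ceiling(dimr[1] / cell_px))
  centers_x <- rep((cxi - 0.5) * cell_px, each = length(cyi))
  centers_y <- rep((cyi - 0.5) * cell_px, times = length(cxi))
  inside <- point_in_polygon(centers_x, centers_y, hx, hy)
  key <- paste(rep(cxi, each = length(cyi)), rep(cyi, times = length(cxi)))
  n_terr <- sum(inside)
  if (n_terr == 0) return(100)
  n_cov <- sum(inside & key %in% occupied)
  100 * n_cov / n_terr
}

# vectorized ray-casting point-in-polygon (boundary points count as inside)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Sholl intersection profile
#'
#' For concentric circles of radius `step_um, 2*step_um, ...` centered on the
#' soma, counts intersections between skeleton edges and each circle. Each
#' edge is treated as a straight segment and can contribute two crossings
#' when it dips through a circle tangentially; for unit-length pixel edges
#' this reduces to counting edges whose endpoint distances straddle the
#' radius.
#'
#' @param skel a [skeleton_graph()] with a defined root.
#' @param step_um radius increment in micrometers.
#' @param r_max_um largest radius; default covers the whole arbor.
#' @return data.frame with columns `radius_um`, `crossings`.
#' @export
sholl <- function(skel, step_um = 10, r_max_um = NULL) {
  nd <- skel$nodes
  ri <- match(skel$root, nd$id)
  d <- sqrt((nd$x - nd$x[ri])^2 + (nd$y - nd$y[ri])^2) / skel$px_per_um
  if (is.null(r_max_um)) r_max_um <- max(d) + step_um
  radii <- seq(step_um, r_max_um, by = step_um)
  if (nrow(skel$edges) == 0) {
    return(data.frame(radius_um = radii, crossings = 0L))
  }
  i <- match(skel$edges[, 1], nd$id); j <- match(skel$edges[, 2], nd$id)
  # segment p(t) = p1 + t (p2 - p1), t in (0, 1]; roots of |p(t)|^2 = r^2
  x1 <- (nd$x[i] - nd$x[ri]) / skel$px_per_um
  y1 <- (nd$y[i] - nd$y[ri]) / skel$px_per_um
  dx <- (nd$x[j] - nd$x[i]) / skel$px_per_um
  dy <- (nd$y[j] - nd$y[i]) / skel$px_per_um
  a <- dx^2 + dy^2
  b <- 2 * (x1 * dx + y1 * dy)
  crossings <- vapply(radii, function(r) {
    cc <- x1^2 + y1^2 - r^2
    disc <- b^2 - 4 * a * cc
    ok <- disc > 0 & a > 0
    n <- 0L
    if (any(ok)) {
      sq <- sqrt(disc[ok])
      t1 <- (-b[ok] - sq) / (2 * a[ok])
      t2 <- (-b[ok] + sq) / (2 * a[ok])
      n <- sum(t1 > 0 & t1 <= 1) + sum(t2 > 0 & t2 <= 1)
    }
    as.integer(n)
  }, integer(1))
  data.frame(radius_um = radii, crossings = crossings)
}

#' Quantify a neuron: all four morphology parameters in one record
#'
#' Accepts a binary mask (logical matrix), a probability-map/mask image file
#' (PGM), an SWC skeleton file, or a [skeleton_graph()].
#'
#' @param x input (matrix, file path, or skeleton graph).
#' @param neuron_id,timepoint identifiers stored in the record.
#' @param px_per_um spatial scale (ignored for skeleton input).
#' @param min_spur_px spur-pruning threshold for mask input.
#' @param cell_px territory grid size.
#' @param sholl_step_um Sholl radius step.
#' @param soma_exclusion_radius_px tip exclusion radius override.
#' @return a `morphometry_record` (list) with fields `neuron_id`, `timepoint`,
#'   `total_length_um`, `tip_count`, `territory_pct`, `sholl`, `soma_px`,
#'   `dead`, and the parameters used.
#' @export
quantify <- function(x, neuron_id = "n1", timepoint = "t1", px_per_um = 2,
                     min_spur_px = 3, cell_px = 20, sholl_step_um = 10,
                     soma_exclusion_radius_px = NULL) {
  params <- list(px_per_um = px_per_um, min_spur_px = min_spur_px,
                 cell_px = cell_px, sholl_step_um = sholl_step_um)
  if (is.character(x)) {
    x <- if (grepl("\\.swc$", x, ignore.case = TRUE)) {
      read_swc(x, px_per_um = px_per_um)
    } else {
      read_pgm(x) > 0.5
    }
  }
  if (is.matrix(x)) {
    if (!any(x)) {
      rec <- list(neuron_id = neuron_id, timepoint = timepoint,
                  total_length_um = 0, tip_count = 0L, territory_pct = 0,
                  sholl = data.frame(radius_um = numeric(0), crossings = integer(0)),
                  soma_px = c(NA_real_, NA_real_), dead = TRUE, params = params)
      class(rec) <- "morphometry_record"
      return(rec)
    }
    x <- skeletonize(x, px_per_um = px_per_um, min_spur_px = min_spur_px)
  }
  stopifnot(inherits(x, "skeleton_graph"))
  ri <- match(x$root, x$nodes$id)
  rec <- list(
    neuron_id = neuron_id, timepoint = timepoint,
    total_length_um = total_length(x),
    tip_count = count_tips(x, soma_exclusion_radius_px),
    territory_pct = territory_coverage(x, cell_px = cell_px),
    sholl = sholl(x, step_um = sholl_step_um),
    soma_px = c(x$nodes$x[ri], x$nodes$y[ri]),
    dead = FALSE, params = params
  )
  class(rec) <- "morphometry_record"
  rec
}

#' @export
as.data.frame.morphometry_record <- function(x, ...) {
  data.frame(neuron_id = x$neuron_id, timepoint = x$timepoint,
             total_length_um = x$total_length_um, tip_count = x$tip_count,
             territory_pct = x$territory_pct, dead = x$dead,
             stringsAsFactors = FALSE)
}

#' @export
print.morphometry_record <- function(x, ...) {
  cat(sprintf(
    "<morphometry_record> %s/%s: length=%.1f um, tips=%d, territory=%.1f%%%s\n",
    x$neuron_id, x$timepoint, x$total_length_um, x$tip_count,
    x$territory_pct, if (x$dead) " [dead]" else ""))
  invisible(x)
}
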