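# SkeletonGraph: the centerline representation shared by the simulator
# (where it is a rooted tree with parent pointers) and by mask skeletonization
# (where it is a pixel graph that may contain cycles). Coordinates are in
# pixels, x = column, y = row; physical lengths are derived via px_per_um.

#' Construct a skeleton graph
#'
#' @param nodes data.frame with columns `id` (1..n), `x`, `y` (pixel
#'   coordinates), and optionally `radius` (px) and `parent` (id of parent
#'   node, NA for the root; present only for tree-structured skeletons).
#' @param edges two-column integer matrix of node ids; ignored (derived from
#'   `parent`) when `nodes$parent` is present and `edges` is NULL.
#' @param root id of the soma node.
#' @param px_per_um pixels per micrometer.
#' @param soma_radius_px radius of the soma in pixels (used for tip exclusion).
#' @return object of class `skeleton_graph`.
#' @export
skeleton_graph <- function(nodes, edges = NULL, root = 1L, px_per_um = 2,
                           soma_radius_px = 0) {
  stopifnot(is.data.frame(nodes), all(c("id", "x", "y") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  if (is.null(edges)) {
    if (!"parent" %in% names(nodes)) stop("need edges or a parent column")
    has_par <- !is.na(nodes$parent) & nodes$parent > 0
    edges <- cbind(nodes$parent[has_par], nodes$id[has_par])
  }
  edges <- matrix(as.integer(edges), ncol = 2)
  if (!root %in% nodes$id) stop("root id not present in nodes")
  obj <- list(nodes = nodes, edges = edges, root = as.integer(root),
              px_per_um = px_per_um, soma_radius_px = soma_radius_px)
  class(obj) <- "skeleton_graph"
  obj
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf(
    "<skeleton_graph> %d nodes, %d edges, root=%d, %.3g px/um, %d tips\n",
    nrow(x$nodes), nrow(x$edges), x$root, x$px_per_um, length(tip_ids(x))))
  invisible(x)
}

# node degree vector indexed by position in nodes$id
node_degrees <- function(skel) {
  deg <- integer(nrow(skel$nodes))
  names(deg) <- as.character(skel$nodes$id)
  if (nrow(skel$edges) > 0) {
    t1 <- table(as.character(skel$edges))
    deg[names(t1)] <- as.integer(t1)
  }
  deg
}

#' Terminal (degree-1) node ids, excluding a disk around the soma
#'
#' @param skel a `skeleton_graph`.
#' @param soma_exclusion_radius_px exclusion radius around the root; default
#'   is the stored soma radius plus 2 px.
#' @return integer vector of node ids.
#' @export
tip_ids <- function(skel, soma_exclusion_radius_px = NULL) {
  if (is.null(soma_exclusion_radius_px)) {
    soma_exclusion_radius_px <- skel$soma_radius_px + 2
  }
  deg <- node_degrees(skel)
  cand <- skel$nodes$id[deg == 1L & skel$nodes$id != skel$root]
  if (length(cand) == 0) return(integer(0))
  ri <- match(skel$root, skel$nodes$id)
  ci <- match(cand, skel$nodes$id)
  d <- sqrt((skel$nodes$x[ci] - skel$nodes$x[ri])^2 +
            (skel$nodes$y[ci] - skel$nodes$y[ri])^2)
  cand[d > soma_exclusion_radius_px]
}

# igraph view (vertex name = node id as character)
as_igraph <- function(skel) {
  g <- igraph::make_empty_graph(n = nrow(skel$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(skel$nodes$id))
  if (nrow(skel$edges) > 0) {
    g <- igraph::add_edges(g, t(matrix(
      match(skel$edges, skel$nodes$id), ncol = 2)))
  }
  g
}

#' Rasterize skeleton nodes onto a logical matrix
#'
#' Nodes are rounded to pixel centers; edges shorter than ~1.5 px need no
#' interpolation, longer edges (SWC-style skeletons) are sampled at 0.7-px
#' steps so the raster is connected.
#'
#' @param skel a `skeleton_graph`.
#' @param dim image dimensions `c(nrow, ncol)`.
#' @return logical matrix.
#' @export
rasterize_skeleton <- function(skel, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  xs <- skel$nodes$x; ys <- skel$nodes$y
  id2i <- seq_len(nrow(skel$nodes)); names(id2i) <- as.character(skel$nodes$id)
  px <- c(); py <- c()
  if (nrow(skel$edges) > 0) {
    a <- id2i[as.character(skel$edges[, 1])]
    b <- id2i[as.character(skel$edges[, 2])]
    len <- sqrt((xs[a] - xs[b])^2 + (ys[a] - ys[b])^2)
    for (k in seq_along(a)) {
      n <- max(2L, ceiling(len[k] / 0.7) + 1L)
      t <- seq(0, 1, length.out = n)
      px <- c(px, xs[a[k]] + t * (xs[b[k]] - xs[a[k]]))
      py <- c(py, ys[a[k]] + t * (ys[b[k]] - ys[a[k]]))
    }
  }
  px <- c(px, xs); py <- c(py, ys)
  r <- pmin(dim[1], pmax(1, round(py)))
  cc <- pmin(dim[2], pmax(1, round(px)))
  out[cbind(r, cc)] <- TRUE
  out
}

#' Apply a rigid translation (and optional uniform scaling about the soma)
#' @param skel a `skeleton_graph`.
#' @param dx,dy translation in pixels.
#' @param scale uniform scale factor about the root node.
#' @return transformed `skeleton_graph`.
#' @export
transform_skeleton <- function(skel, dx = 0, dy = 0, scale = 1) {
  ri <- match(skel$root, skel$nodes$id)
  cx <- skel$nodes$x[ri]; cy <- skel$nodes$y[ri]
  skel$nodes$x <- cx + scale * (skel$nodes$x - cx) + dx
  skel$nodes$y <- cy + scale * (skel$nodes$y - cy) + dy
  skel
}
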