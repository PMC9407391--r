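# Standard 7-column SWC morphology files (id, type, x, y, z, radius, parent).
# Coordinates and radii are written in micrometers; these arbors are planar
# so z is always 0.

#' Write a tree-structured skeleton to an SWC file
#'
#' @param skel a [skeleton_graph()] with a `parent` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  if (!"parent" %in% names(skel$nodes)) {
    stop("write_swc needs a tree-structured skeleton (parent column)")
  }
  nd <- skel$nodes
  s <- skel$px_per_um
  type <- ifelse(nd$id == skel$root, 1L, 3L)
  radius_um <- if ("radius" %in% names(nd)) nd$radius / s else rep(0.5 / s, nrow(nd))
  lines <- sprintf("%d %d %.6f %.6f 0 %.6f %d",
                   nd$id, type, nd$x / s, nd$y / s, radius_um,
                   ifelse(is.na(nd$parent), -1L, nd$parent))
  writeLines(c("# SWC export (x y in um, z = 0)", lines), path)
  invisible(path)
}

#' Read an SWC file into a skeleton graph
#'
#' @param path SWC file.
#' @param px_per_um scale used to place the morphology on a pixel grid.
#' @return a [skeleton_graph()].
#' @export
read_swc <- function(path, px_per_um = 2) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  root <- tab$id[tab$parent == -1][1]
  if (is.na(root)) stop("SWC has no root (parent = -1) entry")
  nodes <- data.frame(id = tab$id,
                      x = tab$x * px_per_um, y = tab$y * px_per_um,
                      radius = tab$radius * px_per_um,
                      parent = ifelse(tab$parent == -1, NA_integer_, tab$parent))
  soma_r <- nodes$radius[nodes$id == root]
  skeleton_graph(nodes, root = root, px_per_um = px_per_um,
                 soma_radius_px = soma_r)
}
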