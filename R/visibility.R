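# Visibility graph analysis (VGA): the open space is discretised on a square
# lattice; two cells are connected when the open segment between their centers
# does not pass through an obstacle interior (grazing along a wall counts as
# visible). Per-cell visual connectivity, mean depth and integration follow
# the same definitions as the axial metrics.

#' Build the visibility graph of a layout
#'
#' The lattice has its origin at the lower-left corner; cell `(row, col)` is
#' 0-based with center `((col + 0.5) res, (row + 0.5) res)`, and a cell is
#' open iff its center lies in open (non-obstacle) space.
#'
#' @param layout a [env_layout()].
#' @param metrics `"global"` (default) errors if the visibility graph is
#'   disconnected, `"component"` scores cells within their connected
#'   component, `"none"` skips depth/integration (adjacency only).
#' @return an object of class `vis_graph`: lattice dimensions, the open-cell
#'   table `cells` (`row`, `col` 0-based, center `x`, `y`), the visibility
#'   `edges` (two-column matrix of 1-based cell indices), and `metrics`
#'   (per-cell `connectivity`, `mean_depth`, `integration`,
#'   `integration_defined`, `component`).
#' @export
build_visibility_graph <- function(layout,
                                   metrics = c("global", "component", "none")) {
  stopifnot(inherits(layout, "nav_layout"))
  metrics <- match.arg(metrics)
  res <- layout$grid_resolution
  ncol_g <- max(1L, floor(layout$width / res + 1e-9))
  nrow_g <- max(1L, floor(layout$height / res + 1e-9))
  cols <- rep(0:(ncol_g - 1), times = nrow_g)
  rows <- rep(0:(nrow_g - 1), each = ncol_g)
  cx <- (cols + 0.5) * res
  cy <- (rows + 0.5) * res
  open <- !points_in_obstacle(cx, cy, layout$obstacles)
  if (!any(open)) stop("configuration error: layout has no open cells")
  cells <- data.frame(row = rows[open], col = cols[open],
                      x = cx[open], y = cy[open])
  n <- nrow(cells)
  edges <- .cpp_visibility_edges(cells$x, cells$y, layout$obstacles)
  stats <- .cpp_bfs_depth_stats(n, edges)
  connectivity <- as.integer(stats[, 1])
  reached <- as.integer(stats[, 3])
  # connected components (needed for component sizes / disconnection check)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  comp <- igraph::components(g)
  md <- rep(NA_real_, n)
  integ <- rep(NA_real_, n)
  if (metrics != "none") {
    if (comp$no > 1 && metrics == "global")
      stop("connectivity error: visibility graph is disconnected (",
           comp$no, " components); use metrics = \"component\"")
    csize <- comp$csize[comp$membership]
    ok <- reached >= 1
    md[ok] <- stats[ok, 2] / reached[ok]
    big <- ok & csize >= 3
    integ[big] <- integration(md[big], csize[big])
  }
  structure(
    list(nrow = nrow_g, ncol = ncol_g, resolution = res,
         cells = cells, edges = edges,
         metrics = data.frame(connectivity = connectivity,
                              mean_depth = md,
                              integration = integ,
                              integration_defined = !is.na(integ),
                              component = as.integer(comp$membership))),
    class = "vis_graph")
}

#' @export
print.vis_graph <- function(x, ...) {
  cat(sprintf("<vis_graph> %d x %d lattice @ %g vm, %d open cell(s), %d visibility pair(s)\n",
              x$nrow, x$ncol, x$resolution, nrow(x$cells), nrow(x$edges)))
  invisible(x)
}

#' Line-of-sight test between point pairs
#'
#' TRUE when the open segment between the two points does not pass through
#' any obstacle interior.
#'
#' @param layout a `nav_layout`.
#' @param px,py,qx,qy endpoint coordinates (vectorised).
#' @return logical vector.
#' @export
line_of_sight <- function(layout, px, py, qx, qy) {
  stopifnot(inherits(layout, "nav_layout"))
  if (length(layout$obstacles) == 0) return(rep(TRUE, length(px)))
  !.cpp_segment_blocked(as.numeric(px), as.numeric(py),
                        as.numeric(qx), as.numeric(qy), layout$obstacles)
}
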