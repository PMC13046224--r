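# Axial-map analysis: street networks abstracted as the fewest longest
# sight lines, scored with the classic space-syntax triplet
# (connectivity, mean depth, integration).

#' Build the axial graph of a layout
#'
#' Nodes are axial lines; two lines are adjacent iff their segments intersect
#' or touch within `tol` (endpoints touching count, so chains of streets are
#' connected at junctions).
#'
#' @param layout a [env_layout()] with at least one axial line.
#' @param tol intersection tolerance in vm (default 1e-6).
#' @return an object of class `axial_graph` with elements `n_lines`, `ids`,
#'   and a symmetric logical `adjacency` matrix with no self-adjacency.
#' @export
build_axial_graph <- function(layout, tol = 1e-6) {
  stopifnot(inherits(layout, "nav_layout"))
  lines <- layout$axial_lines
  n <- nrow(lines)
  if (n == 0) stop("configuration error: layout has no axial lines")
  adj <- matrix(FALSE, n, n, dimnames = list(lines$id, lines$id))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        hit <- segments_intersect(
          c(lines$x1[i], lines$y1[i]), c(lines$x2[i], lines$y2[i]),
          c(lines$x1[j], lines$y1[j]), c(lines$x2[j], lines$y2[j]),
          tol = tol)
        adj[i, j] <- adj[j, i] <- hit
      }
    }
  }
  structure(list(n_lines = n, ids = lines$id, adjacency = adj),
            class = "axial_graph")
}

#' @export
print.axial_graph <- function(x, ...) {
  cat(sprintf("<axial_graph> %d line(s), %d adjacency pair(s)\n",
              x$n_lines, sum(x$adjacency) / 2))
  invisible(x)
}

as_igraph <- function(graph) {
  if (inherits(graph, "axial_graph")) {
    igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
  } else if (inherits(graph, "igraph")) {
    graph
  } else if (is.matrix(graph)) {
    igraph::graph_from_adjacency_matrix(graph != 0, mode = "undirected")
  } else {
    stop("cannot interpret object of class ", paste(class(graph), collapse = "/"),
         " as a graph")
  }
}

#' Topological depths from one node
#'
#' Shortest-path step counts from `origin` to every node of an unweighted
#' graph (BFS). Unreachable nodes are flagged with `NA`.
#'
#' @param graph an `axial_graph`, an adjacency matrix, or an igraph object.
#' @param origin node index (1-based).
#' @return integer vector of depths; `depth[origin] == 0`; `NA` marks
#'   unreachable nodes.
#' @export
graph_depths <- function(graph, origin) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  stopifnot(origin >= 1, origin <= n)
  d <- as.numeric(igraph::distances(g, v = origin, mode = "all"))
  d[is.infinite(d)] <- NA_real_
  as.integer(d)
}

#' Mean topological depth
#'
#' Arithmetic mean of the depths from one node to all others.
#'
#' @param depths depth vector as returned by [graph_depths()] (origin depth 0
#'   included).
#' @return numeric mean depth.
#' @export
mean_depth <- function(depths) {
  if (length(depths) < 2)
    stop("mean depth needs at least 2 nodes")
  if (anyNA(depths))
    stop("connectivity error: graph is disconnected from the origin")
  sum(depths) / (length(depths) - 1)
}

#' Relative asymmetry
#'
#' `RA = 2 (MD - 1) / (n - 2)`: mean depth rescaled to \[0, 1\] between the
#' theoretical minimum (a hub seeing everything at depth 1) and maximum
#' (the end of a chain).
#'
#' @param md mean depth.
#' @param n number of nodes (>= 3).
#' @return numeric RA.
#' @export
ra_value <- function(md, n) {
  if (any(n < 3)) stop("RA requires n >= 3 nodes")
  2 * (md - 1) / (n - 2)
}

#' Diamond-value normalisation constant
#'
#' `D_n = 2 { n [log2((n+2)/3) - 1] + 1 } / [(n-1)(n-2)]`, the mean RA of the
#' "diamond" graph of the same size, used to make RA comparable across
#' systems of different size.
#'
#' @param n number of nodes (>= 3).
#' @return numeric D-value.
#' @export
d_value <- function(n) {
  if (any(n < 3)) stop("D-value requires n >= 3 nodes")
  2 * (n * (log2((n + 2) / 3) - 1) + 1) / ((n - 1) * (n - 2))
}

#' Space-syntax integration
#'
#' Integration is the reciprocal of the real relative asymmetry,
#' `1 / (RA / D_n)`: the higher the value, the more accessible the node is
#' from the rest of the system. When `md == 1` (the node reaches every other
#' node in one step) RA is 0 and integration is undefined/infinite; this is
#' flagged by returning `NA` rather than a large number.
#'
#' @param md mean depth (>= 1).
#' @param n number of nodes (>= 3).
#' @return numeric integration value, `NA` when `md == 1`.
#' @export
integration <- function(md, n) {
  if (any(n < 3)) stop("integration requires n >= 3 nodes")
  ra <- ra_value(md, n)
  out <- d_value(n) / ra
  out[ra <= 0] <- NA_real_
  out
}

#' Axial metrics for every line
#'
#' Per-line connectivity (degree), mean depth and integration of the axial
#' graph. The graph must be connected; per-component analysis must be asked
#' for explicitly via `per_component = TRUE`, in which case mean depth and
#' integration are computed within each connected component.
#'
#' @param graph an [build_axial_graph()] result.
#' @param per_component compute metrics within connected components instead
#'   of erroring on a disconnected graph.
#' @return data.frame with columns `id`, `connectivity`, `mean_depth`,
#'   `integration`, `integration_defined`, and `component`.
#' @export
axial_metrics <- function(graph, per_component = FALSE) {
  stopifnot(inherits(graph, "axial_graph"))
  g <- as_igraph(graph)
  n <- graph$n_lines
  comp <- igraph::components(g)
  if (comp$no > 1 && !per_component)
    stop("connectivity error: axial graph is disconnected (",
         comp$no, " components); use per_component = TRUE for per-component metrics")
  connectivity <- as.integer(igraph::degree(g))
  md <- rep(NA_real_, n)
  integ <- rep(NA_real_, n)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    if (nc < 2) next
    sub <- igraph::induced_subgraph(g, idx)
    dmat <- igraph::distances(sub, mode = "all")
    md[idx] <- rowSums(dmat) / (nc - 1)
    if (nc >= 3) integ[idx] <- integration(md[idx], nc)
  }
  data.frame(id = graph$ids,
             connectivity = connectivity,
             mean_depth = md,
             integration = integ,
             integration_defined = !is.na(integ),
             component = as.integer(comp$membership))
}
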