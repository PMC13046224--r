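# Experienced space-syntax metrics: the average of an environmental metric
# over the elements (axial line / grid cell) a participant actually occupied,
# sample by sample. Because the average is over samples rather than
# arclength, dwelling in a region up-weights it — which is exactly what makes
# the metrics "experienced" rather than a property of the route geometry.

#' Assign points to their nearest axial line
#'
#' Each point maps to the axial line with minimum perpendicular (segment)
#' distance; ties break toward the lower line id. The rule is total, so
#' off-street points (parks, plazas) still receive the nearest street's line.
#'
#' @param x,y point coordinates (vectorised).
#' @param layout a [env_layout()] with at least one axial line.
#' @return integer vector of row indices into `layout$axial_lines`.
#' @export
assign_axial_line <- function(x, y, layout) {
  lines <- layout$axial_lines
  n <- nrow(lines)
  if (n == 0) stop("layout has no axial lines")
  ord <- order(lines$id)
  dmat <- vapply(ord, function(i) {
    point_segment_distance(x, y, lines$x1[i], lines$y1[i],
                           lines$x2[i], lines$y2[i])
  }, numeric(length(x)))
  dmat <- matrix(dmat, nrow = length(x))
  ord[max.col(-dmat, ties.method = "first")]
}

#' Assign points to visibility-grid cells
#'
#' Points map to the containing cell (points exactly on a cell edge belong to
#' the lower-index cell); a point whose containing cell is closed (inside an
#' obstacle, e.g. through clipping noise) falls back to the nearest open cell
#' by center distance.
#'
#' @param x,y point coordinates (vectorised), must lie within the layout
#'   bounds.
#' @param grid a [build_visibility_graph()] result.
#' @return integer vector of row indices into `grid$cells`.
#' @export
assign_cell <- function(x, y, grid) {
  stopifnot(inherits(grid, "vis_graph"))
  res <- grid$resolution
  if (any(x < 0 | y < 0 | x > grid$ncol * res + 1e-9 | y > grid$nrow * res + 1e-9))
    stop("data error: point outside the layout bounds")
  col <- pmax(0, ceiling(x / res - 1e-12) - 1)
  row <- pmax(0, ceiling(y / res - 1e-12) - 1)
  col <- pmin(col, grid$ncol - 1)
  row <- pmin(row, grid$nrow - 1)
  key <- row * grid$ncol + col
  open_key <- grid$cells$row * grid$ncol + grid$cells$col
  idx <- match(key, open_key)
  miss <- which(is.na(idx))
  for (m in miss) {
    d2 <- (grid$cells$x - x[m])^2 + (grid$cells$y - y[m])^2
    idx[m] <- which.min(d2)
  }
  idx
}

#' Experienced axial and visual metrics of a trajectory
#'
#' The six trajectory-averaged space-syntax values: experienced axial
#' integration/connectivity/mean-depth (EAI, EAC, EMAD) average the assigned
#' axial line's metric over all n samples, and the experienced visual metrics
#' (EVI, EVC, EVMD) do the same with the occupied grid cell's visual metric.
#' Every sample, endpoints included, enters the average; navigation states
#' play no role here.
#'
#' @param traj a [trajectory()] (or plain data.frame with `x`, `y`).
#' @param layout the [env_layout()].
#' @param axial an [axial_metrics()] table (rows aligned with
#'   `layout$axial_lines`).
#' @param grid a [build_visibility_graph()] result.
#' @return one-row data.frame with `EAI`, `EAC`, `EMAD`, `EVI`, `EVC`, `EVMD`.
#' @export
experienced_metrics <- function(traj, layout, axial, grid) {
  stopifnot(nrow(traj) >= 1)
  line_idx <- assign_axial_line(traj$x, traj$y, layout)
  cell_idx <- assign_cell(traj$x, traj$y, grid)
  ia <- axial$integration[line_idx]
  iv <- grid$metrics$integration[cell_idx]
  if (anyNA(ia) || anyNA(iv))
    stop("undefined-metric error: trajectory visits an element whose ",
         "integration is flagged undefined")
  data.frame(
    EAI  = mean(ia),
    EAC  = mean(axial$connectivity[line_idx]),
    EMAD = mean(axial$mean_depth[line_idx]),
    EVI  = mean(iv),
    EVC  = mean(grid$metrics$connectivity[cell_idx]),
    EVMD = mean(grid$metrics$mean_depth[cell_idx])
  )
}
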