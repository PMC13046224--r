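#' Describe a navigable 2-D environment
#'
#' An environment layout is the static geometry everything else is computed
#' against: a rectangular domain in virtual meters (vm) with the origin at the
#' lower-left corner, polygonal obstacles (buildings/blocks), target
#' locations, the axial-line map of the street network, and the grid
#' resolution used for visibility-graph analysis.
#'
#' @param width,height domain extent in vm; both must be positive.
#' @param obstacles list of simple polygons, each a two-column matrix of
#'   vertex coordinates (vm); rings are not closed (first vertex is not
#'   repeated).
#' @param targets data.frame with columns `id`, `label`, `x`, `y`; every
#'   target must lie in open (non-obstacle) space.
#' @param axial_lines data.frame with columns `id`, `x1`, `y1`, `x2`, `y2`;
#'   may be empty if no axial analysis is intended.
#' @param grid_resolution cell edge length in vm for visibility analysis
#'   (default 1).
#' @return an object of class `nav_layout`.
#' @export
env_layout <- function(width, height, obstacles = list(),
                       targets = NULL, axial_lines = NULL,
                       grid_resolution = 1.0) {
  stopifnot(is.numeric(width), is.numeric(height))
  if (width <= 0 || height <= 0)
    stop("layout bounds must be positive (width=", width, ", height=", height, ")")
  if (grid_resolution <= 0)
    stop("grid_resolution must be positive")
  obstacles <- lapply(obstacles, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 2 || nrow(p) < 3)
      stop("each obstacle must be a polygon with >= 3 vertices (two columns)")
    if (!ring_is_simple(p))
      stop("obstacle polygon is self-intersecting")
    if (any(p[, 1] < -1e-9 | p[, 1] > width + 1e-9 |
            p[, 2] < -1e-9 | p[, 2] > height + 1e-9))
      stop("obstacle polygon extends outside the domain bounds")
    p
  })
  if (is.null(targets)) {
    targets <- data.frame(id = integer(), label = character(),
                          x = numeric(), y = numeric())
  } else {
    targets <- as.data.frame(targets)
    stopifnot(all(c("id", "x", "y") %in% names(targets)))
    if (!"label" %in% names(targets)) targets$label <- as.character(targets$id)
    if (nrow(targets) > 0) {
      inside <- points_in_obstacle(targets$x, targets$y, obstacles)
      if (any(inside))
        stop("target(s) ", paste(targets$id[inside], collapse = ", "),
             " lie inside an obstacle")
      if (any(targets$x < 0 | targets$x > width |
              targets$y < 0 | targets$y > height))
        stop("target outside domain bounds")
    }
  }
  if (is.null(axial_lines)) {
    axial_lines <- data.frame(id = integer(), x1 = numeric(), y1 = numeric(),
                              x2 = numeric(), y2 = numeric())
  } else {
    axial_lines <- as.data.frame(axial_lines)
    stopifnot(all(c("id", "x1", "y1", "x2", "y2") %in% names(axial_lines)))
  }
  structure(
    list(width = as.numeric(width), height = as.numeric(height),
         obstacles = obstacles, targets = targets,
         axial_lines = axial_lines,
         grid_resolution = as.numeric(grid_resolution)),
    class = "nav_layout")
}

#' @export
print.nav_layout <- function(x, ...) {
  cat(sprintf("<nav_layout> %g x %g vm | %d obstacle(s), %d target(s), %d axial line(s), grid %g vm\n",
              x$width, x$height, length(x$obstacles), nrow(x$targets),
              nrow(x$axial_lines), x$grid_resolution))
  invisible(x)
}

#' Read an environment layout from JSON
#'
#' The schema is a single object with `width`, `height`,
#' `obstacles` (array of vertex-ring arrays), `targets`
#' (array of `{id,label,x,y}`), `axial_lines` (array of
#' `{id,x1,y1,x2,y2}`) and `grid_resolution`.
#'
#' @param path file path.
#' @return a [env_layout()] object.
#' @export
read_environment <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  obstacles <- list()
  if (!is.null(j$obstacles) && length(j$obstacles) > 0) {
    obstacles <- lapply(j$obstacles, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
  }
  env_layout(width = j$width, height = j$height, obstacles = obstacles,
             targets = if (length(j$targets)) as.data.frame(j$targets) else NULL,
             axial_lines = if (length(j$axial_lines)) as.data.frame(j$axial_lines) else NULL,
             grid_resolution = if (is.null(j$grid_resolution)) 1.0 else j$grid_resolution)
}

#' Write an environment layout to JSON
#'
#' Inverse of [read_environment()]; the round trip reproduces the layout
#' exactly.
#'
#' @param layout a `nav_layout`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_environment <- function(layout, path) {
  stopifnot(inherits(layout, "nav_layout"))
  obj <- list(
    width = layout$width, height = layout$height,
    obstacles = lapply(layout$obstacles, function(m) unname(m)),
    targets = layout$targets,
    axial_lines = layout$axial_lines,
    grid_resolution = layout$grid_resolution
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
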