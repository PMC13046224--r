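#' Wayfinding density map with top-percentile hotspots
#'
#' Bins WAYFINDING-labelled sample positions into a 2-D histogram over the
#' layout bounds, optionally smooths it with a separable Gaussian kernel, and
#' marks the top fraction (default 1%) of positive-density cells — the zones
#' of intensified wayfinding activity. The hotspot mask always contains
#' `ceiling(top_frac * #positive cells)` cells; ties at the threshold break
#' by cell index (row-major from the lower-left corner).
#'
#' @param x,y coordinates of wayfinding-labelled samples (at least one).
#' @param layout a [env_layout()] providing the bounds.
#' @param cell cell edge length in vm (default 1).
#' @param smooth_sigma Gaussian smoothing standard deviation in cells;
#'   0 disables smoothing (default 2).
#' @param top_frac fraction of positive-density cells in the hotspot mask
#'   (default 0.01).
#' @return object of class `density_map`: `density` matrix (rows = grid rows,
#'   from the bottom), logical `top_mask` of the same shape, `cell`,
#'   `threshold`.
#' @export
wayfinding_density <- function(x, y, layout, cell = 1, smooth_sigma = 2,
                               top_frac = 0.01) {
  if (length(x) == 0) stop("no wayfinding points supplied")
  stopifnot(inherits(layout, "nav_layout"), length(x) == length(y))
  nc <- max(1L, ceiling(layout$width / cell))
  nr <- max(1L, ceiling(layout$height / cell))
  ci <- pmin(nc - 1, pmax(0, floor(x / cell)))
  ri <- pmin(nr - 1, pmax(0, floor(y / cell)))
  dens <- matrix(0, nr, nc)
  tab <- table(factor(ri * nc + ci, levels = 0:(nr * nc - 1)))
  dens[] <- matrix(as.numeric(tab), nr, nc, byrow = TRUE)
  if (smooth_sigma > 0) {
    half <- max(1L, ceiling(3 * smooth_sigma))
    kern <- dnorm(-half:half, sd = smooth_sigma)
    kern <- kern / sum(kern)
    conv1 <- function(v) {
      # zero-padded 1-D convolution
      padded <- c(rep(0, half), v, rep(0, half))
      vapply(seq_along(v), function(i) sum(padded[i:(i + 2 * half)] * rev(kern)),
             numeric(1))
    }
    dens <- apply(dens, 2, conv1)
    dens <- t(apply(dens, 1, conv1))
  }
  pos <- which(dens > 0)
  m <- ceiling(top_frac * length(pos))
  # row-major (from lower-left) cell index for deterministic tie-breaking
  rows0 <- (pos - 1) %% nr
  cols0 <- (pos - 1) %/% nr
  cell_index <- rows0 * nc + cols0
  ord <- order(-dens[pos], cell_index)
  top <- pos[ord[seq_len(m)]]
  mask <- matrix(FALSE, nr, nc)
  mask[top] <- TRUE
  structure(list(density = dens, top_mask = mask, cell = cell,
                 threshold = min(dens[top])),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %d x %d cells @ %g vm; %d hotspot cell(s) (threshold %.4g)\n",
              nrow(x$density), ncol(x$density), x$cell,
              sum(x$top_mask), x$threshold))
  invisible(x)
}
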