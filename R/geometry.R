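# Low-level raster geometry shared by the generator and the detectors.
# Images are plain numeric matrices indexed [x, y] (first dim = x), matching
# EBImage's convention, with polygons stored as two-column (x, y) matrices in
# 1-based pixel-centre coordinates.

#' Rasterize a closed polygon onto a pixel grid
#'
#' Even-odd scanline fill at pixel centres. Vertices are given in 1-based
#' pixel coordinates; the polygon is closed implicitly.
#'
#' @param poly two-column numeric matrix of (x, y) vertices.
#' @param dim integer vector `c(nx, ny)`, the grid size.
#' @return logical matrix of dimension `dim`, `TRUE` inside the polygon.
#' @keywords internal
rasterize_polygon <- function(poly, dim) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  nx <- dim[1]; ny <- dim[2]
  out <- matrix(FALSE, nx, ny)
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- c(poly[-1, 1], poly[1, 1]); y2 <- c(poly[-1, 2], poly[1, 2])
  for (xi in seq_len(nx)) {
    # edges crossing the vertical line x = xi (half-open rule avoids
    # double-counting vertices)
    cross <- (x1 <= xi & xi < x2) | (x2 <= xi & xi < x1)
    if (!any(cross)) next
    t <- (xi - x1[cross]) / (x2[cross] - x1[cross])
    yc <- sort(y1[cross] + t * (y2[cross] - y1[cross]))
    # fill between successive pairs of crossings
    for (k in seq(1, length(yc) - 1, by = 2)) {
      lo <- ceiling(yc[k]); hi <- floor(yc[k + 1])
      if (hi >= lo) {
        lo <- max(1L, lo); hi <- min(ny, hi)
        if (hi >= lo) out[xi, lo:hi] <- TRUE
      }
    }
  }
  out
}

# Is every vertex of `poly` inside an nx-by-ny grid?
polygon_in_grid <- function(poly, dim) {
  all(poly[, 1] >= 1 & poly[, 1] <= dim[1] & poly[, 2] >= 1 & poly[, 2] <= dim[2])
}

# Rectangle polygon helper (x0, x1, y0, y1 inclusive pixel bounds).
rect_polygon <- function(x0, x1, y0, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# Pixel-offset footprint of a disc of radius r (px), centred at the origin.
# Cached because the generator asks for the same radii repeatedly.
.disc_cache <- new.env(parent = emptyenv())
disc_offsets <- function(r) {
  key <- sprintf("r%.3f", r)
  hit <- .disc_cache[[key]]
  if (!is.null(hit)) return(hit)
  ri <- ceiling(r)
  g <- expand.grid(dx = -ri:ri, dy = -ri:ri)
  g <- g[g$dx^2 + g$dy^2 <= r^2, , drop = FALSE]
  out <- as.matrix(g)
  .disc_cache[[key]] <- out
  out
}

# Linear indices of a set of (x, y) offsets placed at centre (cx, cy) on an
# nx-by-ny grid; points falling off the grid are dropped.
offsets_at <- function(offsets, cx, cy, dim) {
  x <- offsets[, 1] + round(cx)
  y <- offsets[, 2] + round(cy)
  ok <- x >= 1 & x <= dim[1] & y >= 1 & y <= dim[2]
  (y[ok] - 1L) * dim[1] + x[ok]
}
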