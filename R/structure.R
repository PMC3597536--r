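# Structural validation metrics: projected radius, circularity,
# connection statistics and virtual sectioning. The projected metrics
# mirror the image-based measurements used for real embryoid bodies, so
# they are computed on a rasterised 2D footprint of the aggregate.

project_axes <- function(axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  switch(axis, z = c("x", "y"), x = c("y", "z"), y = c("x", "z"))
}

# Rasterise the union of projected disks on a regular pixel grid.
# Returns a list with the logical mask and pixel size; resolution
# defaults to 0.25 um/pixel, comfortably below the cell radius.
footprint_mask <- function(agg, axis = "z", pixel = 0.25) {
  agg <- as_aggregate(agg)
  ax <- project_axes(axis)
  cx <- agg$cells[[ax[1]]]
  cy <- agg$cells[[ax[2]]]
  r <- agg$cells$radius
  x0 <- min(cx - r) - pixel
  y0 <- min(cy - r) - pixel
  nx <- ceiling((max(cx + r) - x0) / pixel) + 2
  ny <- ceiling((max(cy + r) - y0) / pixel) + 2
  mask <- matrix(FALSE, nx, ny)
  gx <- x0 + (seq_len(nx) - 0.5) * pixel
  gy <- y0 + (seq_len(ny) - 0.5) * pixel
  for (k in seq_along(cx)) {
    ix <- which(abs(gx - cx[k]) <= r[k])
    iy <- which(abs(gy - cy[k]) <= r[k])
    if (length(ix) == 0 || length(iy) == 0) next
    sub <- outer((gx[ix] - cx[k])^2, (gy[iy] - cy[k])^2, `+`) <= r[k]^2
    mask[ix, iy] <- mask[ix, iy] | sub
  }
  list(mask = mask, pixel = pixel, gx = gx, gy = gy)
}

#' Projected aggregate radius
#'
#' Projects the aggregate onto a plane, measures the area of the union
#' of the projected disks, and reports the radius of the circle of
#' equal area -- the same estimator applied to brightfield images of
#' real embryoid bodies.
#'
#' @param agg An [eb_aggregate()].
#' @param axis Projection axis (`"z"`, `"x"` or `"y"`).
#' @param pixel Raster resolution in um/pixel.
#' @return Radius in um.
#' @export
aggregate_radius <- function(agg, axis = "z", pixel = 0.25) {
  agg <- as_aggregate(agg)
  if (nrow(agg$cells) == 0) abort("empty aggregate")
  fp <- footprint_mask(agg, axis, pixel)
  area <- sum(fp$mask) * fp$pixel^2
  sqrt(area / pi)
}

#' Projected circularity
#'
#' Fits an ellipse to the projected footprint via its second central
#' moments and returns the minor-to-major axis ratio, 1 for a perfect
#' circle. This mirrors the ellipse-fitting circularity applied to
#' brightfield images of real embryoid bodies.
#'
#' @inheritParams aggregate_radius
#' @return Circularity in (0, 1].
#' @export
circularity <- function(agg, axis = "z", pixel = 0.25) {
  agg <- as_aggregate(agg)
  if (nrow(agg$cells) == 0) abort("empty aggregate")
  fp <- footprint_mask(agg, axis, pixel)
  idx <- which(fp$mask, arr.ind = TRUE)
  px <- fp$gx[idx[, 1]]
  py <- fp$gy[idx[, 2]]
  cxx <- stats::var(px) + fp$pixel^2 / 12 # pixel smoothing term
  cyy <- stats::var(py) + fp$pixel^2 / 12
  cxy <- stats::cov(px, py)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2), symmetric = TRUE)$values
  ev <- pmax(ev, .Machine$double.eps)
  sqrt(ev[2] / ev[1])
}

#' Connection statistics
#'
#' Summarises the contact graph: per-cell connection counts (degree)
#' and per-edge connection lengths (centre distances).
#'
#' @param agg An [eb_aggregate()].
#' @return A one-row tibble with `mean_count`, `sd_count`,
#'   `mean_length`, `sd_length`, `n_cells` and `n_edges`.
#' @export
connection_stats <- function(agg) {
  agg <- as_aggregate(agg)
  deg <- contact_degree(agg)
  if (nrow(agg$edges) == 0) {
    warn("aggregate has no contacts; length statistics are zero")
  }
  tibble(
    mean_count = if (length(deg)) mean(deg) else 0,
    sd_count = if (length(deg) > 1) stats::sd(deg) else 0,
    mean_length = if (nrow(agg$edges)) mean(agg$edges$length) else 0,
    sd_length = if (nrow(agg$edges) > 1) stats::sd(agg$edges$length) else 0,
    n_cells = nrow(agg$cells),
    n_edges = nrow(agg$edges)
  )
}

#' Virtual section through an aggregate
#'
#' Extracts the cells whose centres lie in a slab of given thickness
#' (default 10 um, emulating a confocal optical section) and projects
#' them to the x-y plane. The section keeps the 2D adjacency induced by
#' restricting the 3D contact graph to its members, so sections can be
#' classified like whole aggregates.
#'
#' @param agg An [eb_aggregate()].
#' @param z_center Slab centre (um). Defaults to 25 um below the top of
#'   the aggregate, matching common confocal imaging depth.
#' @param thickness Slab thickness (um).
#' @return An object of class `eb_section`: a tibble with columns
#'   `cell_id`, `x`, `y`, `radius`, `state`, carrying the induced edge
#'   table, `z_center` and `thickness` as attributes.
#' @export
virtual_section <- function(agg, z_center = NULL, thickness = 10) {
  agg <- as_aggregate(agg)
  if (thickness <= 0) abort("`thickness` must be positive")
  if (is.null(z_center)) {
    z_center <- max(agg$cells$z + agg$cells$radius) - 25
  }
  keep <- abs(agg$cells$z - z_center) <= thickness / 2
  if (!any(keep)) warn("section slab contains no cell centres")
  cells <- agg$cells[keep, c("cell_id", "x", "y", "radius", "state")]
  ids <- cells$cell_id
  edges <- agg$edges[agg$edges$from %in% ids & agg$edges$to %in% ids, ]
  structure(cells, class = c("eb_section", class(cells)),
            edges = edges, z_center = z_center, thickness = thickness)
}

#' Structure report
#'
#' The four structural validation metrics in one row: projected radius,
#' circularity, and connection count/length statistics.
#'
#' @inheritParams aggregate_radius
#' @return A one-row tibble.
#' @export
structure_report <- function(agg, axis = "z") {
  agg <- as_aggregate(agg)
  cs <- connection_stats(agg)
  dplyr::bind_cols(
    tibble(radius = aggregate_radius(agg, axis),
           circularity = circularity(agg, axis)),
    cs
  )
}
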