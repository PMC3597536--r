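# Tabular I/O. CSV is the canonical on-disk format for cell and edge
# tables; full-precision doubles ensure bit-exact round trips.

# 17 significant digits round-trip every IEEE double exactly
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  bad <- !is.finite(x)
  out[bad] <- as.character(x[bad])
  out
}

#' Read and write cell tables
#'
#' Cell tables are CSV files with columns `id`, `x_um`, `y_um`, `z_um`,
#' `radius_um`, `state` (`POS`/`NEG`) and optionally
#' `next_division_h`. Doubles are written at full precision, so a
#' write/read round trip reproduces the table bit-exactly.
#'
#' @param path File path.
#' @param contact_slack Contact tolerance used to rebuild the graph on
#'   read.
#' @return `read_cells()` returns an [eb_aggregate()]; `write_cells()`
#'   returns `path` invisibly.
#' @export
read_cells <- function(path, contact_slack = 0.05) {
  # read everything as text and convert with as.numeric (strtod), which
  # rounds correctly in the last ulp; the fast multi-threaded CSV double
  # parser does not, and would break bit-exact round trips
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  cells <- tibble(cell_id = as.integer(df$id), x = as.numeric(df$x_um),
                  y = as.numeric(df$y_um), z = as.numeric(df$z_um),
                  radius = as.numeric(df$radius_um),
                  state = as.character(df$state))
  if ("next_division_h" %in% names(df)) {
    cells$next_division <- as.numeric(df$next_division_h)
  }
  eb_aggregate(cells, contact_slack = contact_slack)
}

#' @rdname read_cells
#' @param agg An [eb_aggregate()] or cell table.
#' @export
write_cells <- function(agg, path) {
  cells <- if (inherits(agg, "eb_aggregate")) agg$cells else as_tibble(agg)
  out <- tibble(id = cells$cell_id, x_um = fmt_full(cells$x),
                y_um = fmt_full(cells$y), z_um = fmt_full(cells$z),
                radius_um = fmt_full(cells$radius), state = cells$state)
  if ("next_division" %in% names(cells)) {
    out$next_division_h <- fmt_full(cells$next_division)
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write contact edge tables
#'
#' Edge tables are CSV files with columns `id_a`, `id_b`, `length_um`.
#'
#' @param path File path.
#' @return `read_edges()` returns a tibble with columns `from`, `to`,
#'   `length`.
#' @export
read_edges <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  tibble(from = as.integer(df$id_a), to = as.integer(df$id_b),
         length = as.numeric(df$length_um))
}

#' @rdname read_edges
#' @param agg An [eb_aggregate()] or edge table.
#' @export
write_edges <- function(agg, path) {
  edges <- if (inherits(agg, "eb_aggregate")) agg$edges else as_tibble(agg)
  readr::write_csv(tibble(id_a = edges$from, id_b = edges$to,
                          length_um = fmt_full(edges$length)), path)
  invisible(path)
}

#' Render a virtual section to a PNG image
#'
#' Rasterises a section with the standard colour convention: Oct4+
#' cells cyan, Oct4- cells dark blue, on a black background, with a
#' white scale bar. Pixels are a deterministic function of the
#' section, so identical sections produce identical files.
#'
#' @param section An [virtual_section()] result.
#' @param path Output PNG path.
#' @param pixel Raster resolution, um per pixel.
#' @param scale_bar_um Scale-bar length (um); 0 suppresses it.
#' @return `path`, invisibly.
#' @export
render_section <- function(section, path, pixel = 0.25, scale_bar_um = 25) {
  if (nrow(section) == 0) abort("cannot render an empty section")
  col_pos <- c(0, 1, 1)       # cyan
  col_neg <- c(0.05, 0.05, 0.55) # dark blue
  r <- section$radius
  x0 <- min(section$x - r) - 2 * pixel
  y0 <- min(section$y - r) - 2 * pixel
  nx <- ceiling((max(section$x + r) - x0) / pixel) + 4
  ny <- ceiling((max(section$y + r) - y0) / pixel) + 4
  img <- array(0, dim = c(ny, nx, 3))
  gx <- x0 + (seq_len(nx) - 0.5) * pixel
  gy <- y0 + (seq_len(ny) - 0.5) * pixel
  # draw larger (rearmost) disks first so small cells stay visible
  for (k in order(-section$radius)) {
    ix <- which(abs(gx - section$x[k]) <= r[k])
    iy <- which(abs(gy - section$y[k]) <= r[k])
    if (!length(ix) || !length(iy)) next
    disk <- outer((gy[iy] - section$y[k])^2, (gx[ix] - section$x[k])^2,
                  `+`) <= r[k]^2
    col <- if (section$state[k] == "POS") col_pos else col_neg
    for (ch in 1:3) {
      plane <- img[iy, ix, ch, drop = FALSE]
      plane[cbind(which(disk, arr.ind = TRUE), 1L)] <- col[ch]
      img[iy, ix, ch] <- plane
    }
  }
  if (scale_bar_um > 0) {
    bar_px <- min(nx - 4, round(scale_bar_um / pixel))
    rows <- (ny - 6):(ny - 4)
    img[rows, 3:(2 + bar_px), ] <- 1
  }
  # image rows run top to bottom; flip so +y points up
  png::writePNG(img[rev(seq_len(ny)), , , drop = FALSE], path)
  invisible(path)
}
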