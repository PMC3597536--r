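#' Deterministic test aggregates with known patterns
#'
#' Generates labelled aggregates that operationalise the six verbal
#' pattern definitions, so every analysis operation can be tested
#' without external data. Except for the FCC lattice, fixtures are
#' built on relaxed random packings (via [aggregate_cells()]) so
#' classifier tests see realistic contact graphs.
#'
#' Kinds:
#' * `"fcc_lattice"`: equal spheres on face-centred cubic sites
#'   (`n` is ignored; use `shells`).
#' * `"shell_inside_out"`: Oct4- core -- cells with normalised radial
#'   position below `inner_cut` are differentiated.
#' * `"shell_outside_in"`: Oct4- rim -- cells beyond `outer_cut` are
#'   differentiated.
#' * `"two_blob_connected"`: two contiguous Oct4- regions grown from
#'   opposite sides of the aggregate, together holding
#'   `blob_fraction` of the cells.
#' * `"checkerboard_random"`: states assigned independently per cell
#'   with probability `fraction_pos` of being Oct4+.
#' * `"uniform_state"`: all cells in `uniform` state.
#'
#' @param kind Fixture kind (see above).
#' @param n Number of cells.
#' @param seed Integer seed; fixtures are reproducible given the seed.
#' @param shells Shell count for `"fcc_lattice"`.
#' @param inner_cut,outer_cut Normalised radial cut points of the
#'   shell fixtures.
#' @param blob_fraction Total Oct4- fraction of the two-blob fixture.
#' @param fraction_pos Per-cell Oct4+ probability of the checkerboard
#'   fixture.
#' @param uniform State of the `"uniform_state"` fixture.
#' @return An [eb_aggregate()].
#' @export
#' @examples
#' fx <- make_fixture("shell_inside_out", n = 200, seed = 1)
#' classify_pattern(fx)
make_fixture <- function(kind = c("fcc_lattice", "shell_inside_out",
                                  "shell_outside_in", "two_blob_connected",
                                  "checkerboard_random", "uniform_state"),
                         n = 500, seed = 1, shells = 3, inner_cut = 0.5,
                         outer_cut = 0.75, blob_fraction = 0.4,
                         fraction_pos = 0.5, uniform = "POS") {
  kind <- match.arg(kind)
  if (kind == "fcc_lattice") return(fcc_aggregate(shells))
  agg <- with_seed_maybe(seed, {
    seed_cells(n) |> aggregate_cells()
  })
  rn <- radial_positions(as.matrix(agg$cells[, c("x", "y", "z")]))
  states <- with_seed_maybe(seed + 1L, switch(kind,
    shell_inside_out = ifelse(rn < inner_cut, "NEG", "POS"),
    shell_outside_in = ifelse(rn > outer_cut, "NEG", "POS"),
    two_blob_connected = two_blob_states(agg, blob_fraction),
    checkerboard_random = ifelse(runif(n) < fraction_pos, "POS", "NEG"),
    uniform_state = rep(uniform, n)
  ))
  agg$cells$state <- states
  agg
}

# Grow two Oct4- blobs by breadth-first search from the two cells at
# the extremes of the x axis, alternating between blobs until the
# requested fraction of cells is differentiated.
two_blob_states <- function(agg, blob_fraction) {
  n <- nrow(agg$cells)
  target <- max(4L, round(blob_fraction * n))
  g <- as_igraph(agg)
  seeds <- c(which.min(agg$cells$x), which.max(agg$cells$x))
  ord1 <- as.integer(igraph::bfs(g, root = seeds[1])$order)
  ord2 <- as.integer(igraph::bfs(g, root = seeds[2])$order)
  neg <- logical(n)
  i1 <- i2 <- 1L
  while (sum(neg) < target) {
    while (i1 <= n && neg[ord1[i1]]) i1 <- i1 + 1L
    if (i1 <= n) neg[ord1[i1]] <- TRUE
    if (sum(neg) >= target) break
    while (i2 <= n && neg[ord2[i2]]) i2 <- i2 + 1L
    if (i2 <= n) neg[ord2[i2]] <- TRUE
  }
  ifelse(neg, "NEG", "POS")
}
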