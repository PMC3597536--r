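#' Embryoid-body aggregate
#'
#' The central container of the package: a table of cells (rigid
#' spheres with a binary Oct4 state) together with the undirected
#' contact graph linking physically adjacent cells. Most analysis and
#' simulation functions take and return this class.
#'
#' @param cells A data frame with columns `cell_id` (unique integers),
#'   `x`, `y`, `z` (centre coordinates, um), `radius` (um, > 0) and
#'   `state` (`"POS"` for Oct4+, `"NEG"` for Oct4-). An optional
#'   `next_division` column (hours) carries division clocks in the
#'   dynamic model.
#' @param contact_slack Fractional tolerance used to build the contact
#'   graph: cells `i` and `j` are connected when their centre distance
#'   is at most `(r_i + r_j) * (1 + contact_slack)`. The default 5%
#'   absorbs the small residual gaps left by mechanical relaxation.
#' @param time Simulation time stamp in hours.
#' @param edges Optional pre-computed edge table (`from`, `to`,
#'   `length`); when `NULL` the contact graph is built from positions.
#' @return An object of class `eb_aggregate`: a list with elements
#'   `cells` (tibble), `edges` (tibble with columns `from`, `to`,
#'   `length`), `time` and `contact_slack`.
#' @export
#' @examples
#' cells <- tibble::tibble(cell_id = 1:2, x = c(0, 6.6), y = 0, z = 0,
#'                         radius = 3.3, state = "POS")
#' eb_aggregate(cells)
eb_aggregate <- function(cells, contact_slack = 0.05, time = 0,
                         edges = NULL) {
  cells <- as_tibble(cells)
  needed <- c("cell_id", "x", "y", "z", "radius", "state")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols) > 0) {
    abort(paste0("`cells` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(cells$cell_id)) abort("`cell_id` must be unique")
  if (any(cells$radius <= 0)) abort("`radius` must be positive")
  check_states(cells$state)
  if (is.null(edges)) {
    edges <- contact_edges(cells, contact_slack)
  }
  structure(list(cells = cells, edges = as_tibble(edges), time = time,
                 contact_slack = contact_slack),
            class = "eb_aggregate")
}

# low-level contact edge construction on a plain cell table
contact_edges <- function(cells, contact_slack) {
  if (nrow(cells) < 2) {
    return(tibble(from = integer(), to = integer(), length = double()))
  }
  pos <- as.matrix(cells[, c("x", "y", "z")])
  p <- cpp_contact_pairs(pos, cells$radius, contact_slack)
  tibble(from = cells$cell_id[p$i], to = cells$cell_id[p$j],
         length = p$length)
}

#' Rebuild the contact graph of an aggregate
#'
#' @param agg An [eb_aggregate()] or a plain cell table.
#' @param contact_slack Fractional contact tolerance; defaults to the
#'   slack stored in `agg` (or 0.05 for a bare table).
#' @return An [eb_aggregate()] with a freshly computed edge table.
#' @export
build_contact_graph <- function(agg, contact_slack = NULL) {
  if (inherits(agg, "eb_aggregate")) {
    slack <- contact_slack %||% agg$contact_slack
    eb_aggregate(agg$cells, contact_slack = slack, time = agg$time)
  } else {
    eb_aggregate(agg, contact_slack = contact_slack %||% 0.05)
  }
}

as_aggregate <- function(x, contact_slack = 0.05) {
  if (inherits(x, "eb_aggregate")) x else eb_aggregate(x, contact_slack)
}

#' @export
print.eb_aggregate <- function(x, ...) {
  cat(sprintf(
    "<eb_aggregate: %d cells (%d Oct4+), %d contacts, t = %g h>\n",
    nrow(x$cells), sum(x$cells$state == "POS"), nrow(x$edges), x$time))
  invisible(x)
}

#' @export
as_tibble.eb_aggregate <- function(x, ...) x$cells

#' Per-cell contact degree
#'
#' @param agg An [eb_aggregate()].
#' @return Integer vector of contact counts, aligned with
#'   `agg$cells$cell_id`.
#' @export
contact_degree <- function(agg) {
  agg <- as_aggregate(agg)
  idx <- match(c(agg$edges$from, agg$edges$to), agg$cells$cell_id)
  tabulate(idx, nbins = nrow(agg$cells))
}

# maximum sphere-sphere overlap as a fraction of the smaller radius
max_overlap_fraction <- function(agg) {
  agg <- as_aggregate(agg)
  if (nrow(agg$edges) == 0) return(0)
  i <- match(agg$edges$from, agg$cells$cell_id)
  j <- match(agg$edges$to, agg$cells$cell_id)
  ov <- (agg$cells$radius[i] + agg$cells$radius[j] - agg$edges$length) /
    pmin(agg$cells$radius[i], agg$cells$radius[j])
  max(0, ov)
}

#' Aggregation parameters
#'
#' Controls for [aggregate_cells()], the gravitational-point-source
#' aggregation that packs randomly seeded spheres into a spheroid.
#'
#' @param step_size Distance (um) each cell advances toward the
#'   attractor per iteration before collisions are resolved.
#' @param max_iterations Iteration cap.
#' @param convergence_displacement Net per-iteration displacement (um)
#'   below which the packing is declared converged.
#' @param overlap_tolerance Maximum admissible sphere interpenetration
#'   as a fraction of the smaller radius.
#' @param attractor Optional 3-vector (um); defaults to the centroid of
#'   the seeded cells.
#' @return A list of class `aggregation_params`.
#' @export
aggregation_params <- function(step_size = 1, max_iterations = 10000,
                               convergence_displacement = 0.01,
                               overlap_tolerance = 0.01,
                               attractor = NULL) {
  if (step_size <= 0) abort("`step_size` must be positive")
  structure(list(step_size = step_size, max_iterations = max_iterations,
                 convergence_displacement = convergence_displacement,
                 overlap_tolerance = overlap_tolerance,
                 attractor = attractor),
            class = "aggregation_params")
}

#' Seed non-overlapping cells in a box
#'
#' Places `n` spheres uniformly at random in a cubic box by rejection
#' sampling, so that no two spheres overlap. The box is the initial
#' boundary of an aggregation run.
#'
#' @param n Number of cells.
#' @param radii Vector of radii (um), recycled to length `n`; defaults
#'   to draws from [radius_distribution()].
#' @param box_side Side length of the box (um). The box volume must be
#'   at least four times the total sphere volume.
#' @param seed Optional integer seed.
#' @param max_attempts Rejection attempts per cell before giving up.
#' @return A cell tibble (all cells Oct4+).
#' @export
seed_cells <- function(n, radii = NULL, box_side = NULL, seed = NULL,
                       max_attempts = 2000) {
  if (n < 1) abort("`n` must be >= 1")
  with_seed_maybe(seed, {
    if (is.null(radii)) radii <- sample_cell_radii(n)
    radii <- rep_len(radii, n)
    if (is.null(box_side)) {
      # 8x total sphere volume gives comfortable rejection headroom
      box_side <- max((8 * sum((4 / 3) * pi * radii^3))^(1 / 3),
                      4 * max(radii))
    }
    if (box_side^3 < 4 * sum((4 / 3) * pi * radii^3)) {
      abort("box volume must be at least 4x the total sphere volume")
    }
    pos <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        cand <- runif(3, radii[i], box_side - radii[i])
        if (i == 1) { ok <- TRUE } else {
          prev <- pos[seq_len(i - 1), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          ok <- all(d2 >= (radii[seq_len(i - 1)] + radii[i])^2)
        }
        if (ok) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) {
        abort("failed to place non-overlapping cells; enlarge `box_side`")
      }
    }
    tibble(cell_id = seq_len(n), x = pos[, 1], y = pos[, 2], z = pos[, 3],
           radius = radii, state = "POS")
  })
}

#' Aggregate cells into a spheroid
#'
#' Pulls every cell toward a gravitational point source while resolving
#' rigid-sphere collisions by symmetric pairwise projection, producing
#' the packed spheroidal structure on which the differentiation rules
#' run. The scheme is overdamped: each iteration every cell advances
#' `step_size` um toward the attractor and overlapping pairs are then
#' pushed apart along their centre line in randomised order. The step
#' is annealed when net motion stalls, so the packing settles to a
#' jammed state.
#'
#' @param cells A cell tibble (e.g. from [seed_cells()]) or an
#'   [eb_aggregate()].
#' @param params An [aggregation_params()].
#' @param contact_slack Contact tolerance for the resulting graph.
#' @param seed Optional integer seed controlling the randomised
#'   collision-resolution order.
#' @return An [eb_aggregate()] with attribute `converged` (logical) and
#'   `iterations` (integer count).
#' @export
#' @examples
#' agg <- seed_cells(50, seed = 1) |> aggregate_cells(seed = 1)
#' igraph::is_connected(as_igraph(agg))
aggregate_cells <- function(cells, params = aggregation_params(),
                            contact_slack = 0.05, seed = NULL) {
  if (inherits(cells, "eb_aggregate")) cells <- cells$cells
  cells <- as_tibble(cells)
  pos <- as.matrix(cells[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  attractor <- unname(params$attractor %||% colMeans(pos))
  # Work in attractor-local coordinates, snapped to a 2^-26 um
  # (~1.5e-8 um) grid: translating the input shifts local coordinates
  # only at floating-point rounding level, so after snapping the solver
  # sees bit-identical input and aggregation is exactly translation
  # equivariant. The snap is far below any physical length scale.
  local <- round(sweep(pos, 2, attractor) * 2^26) / 2^26
  res <- with_seed_maybe(seed, {
    cpp_aggregate(local, cells$radius, c(0, 0, 0), params$step_size,
                  params$convergence_displacement, params$max_iterations,
                  params$overlap_tolerance, settle_sweeps = 200L)
  })
  res$pos <- sweep(res$pos, 2, attractor, `+`)
  if (!res$converged) {
    warn(sprintf("aggregation did not converge in %d iterations (max displacement %.3g um)",
                 res$iterations, res$max_disp))
  }
  out <- cells
  out$x <- res$pos[, 1]; out$y <- res$pos[, 2]; out$z <- res$pos[, 3]
  agg <- eb_aggregate(out, contact_slack = contact_slack)
  attr(agg, "converged") <- res$converged
  attr(agg, "iterations") <- res$iterations
  agg
}

#' Convert an aggregate's contact graph to igraph
#'
#' @param agg An [eb_aggregate()].
#' @return An undirected [igraph::graph] whose vertex names are cell
#'   ids.
#' @export
as_igraph <- function(agg) {
  agg <- as_aggregate(agg)
  igraph::graph_from_data_frame(
    data.frame(from = as.character(agg$edges$from),
               to = as.character(agg$edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(agg$cells$cell_id))
  )
}
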