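# Pattern analytics: cluster counting on the contact graph, the
# six-class spatial pattern scheme, and trajectory summaries on the
# normalised time axis.

pattern_levels <- c("oct4_pos", "inside_out", "outside_in", "connected",
                    "random", "oct4_neg")

# Normalise an eb_aggregate or eb_section to a common internal form:
# list(coords matrix, states, edges(from,to), ids)
pattern_input <- function(x) {
  if (inherits(x, "eb_section")) {
    list(coords = cbind(x$x, x$y), states = x$state,
         edges = attr(x, "edges"), ids = x$cell_id)
  } else {
    x <- as_aggregate(x)
    list(coords = cbind(x$cells$x, x$cells$y, x$cells$z),
         states = x$cells$state, edges = x$edges, ids = x$cells$cell_id)
  }
}

cluster_count_impl <- function(edges, states, ids, state) {
  sel <- states[match(edges$from, ids)] == state &
    states[match(edges$to, ids)] == state
  if (!any(sel)) return(0L)
  el <- cbind(as.character(edges$from[sel]), as.character(edges$to[sel]))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  as.integer(igraph::count_components(g))
}

#' Count same-state cell clusters
#'
#' A cluster is a connected group of two or more cells of the same
#' Oct4 state in the contact graph; isolated cells do not count.
#' The number of Oct4+ clusters is the undifferentiated cluster number
#' (UCN); the number of Oct4- clusters is the differentiated cluster
#' number (DCN).
#'
#' @param x An [eb_aggregate()] or [virtual_section()].
#' @param state `"POS"` or `"NEG"`.
#' @return Integer cluster count.
#' @export
count_state_clusters <- function(x, state = c("POS", "NEG")) {
  state <- match.arg(state)
  pi <- pattern_input(x)
  cluster_count_impl(pi$edges, pi$states, pi$ids, state)
}

radial_positions <- function(coords) {
  ctr <- colMeans(coords)
  r <- sqrt(rowSums(sweep(coords, 2, ctr)^2))
  rmax <- max(r)
  if (rmax == 0) rep(0, length(r)) else r / rmax
}

#' Pattern metrics
#'
#' Quantitative descriptors of a state pattern: the undifferentiated
#' and differentiated cluster numbers (UCN, DCN), the Oct4+ fraction,
#' and the mean radial position (normalised to the outermost cell
#' centre) of each state.
#'
#' @param x An [eb_aggregate()] or [virtual_section()].
#' @return A one-row tibble with columns `ucn`, `dcn`, `fraction_pos`,
#'   `mean_radial_pos`, `mean_radial_neg` and `n_cells`.
#' @export
pattern_metrics <- function(x) {
  pi <- pattern_input(x)
  if (length(pi$states) == 0) abort("empty input")
  rn <- radial_positions(pi$coords)
  pos <- pi$states == "POS"
  tibble(
    ucn = cluster_count_impl(pi$edges, pi$states, pi$ids, "POS"),
    dcn = cluster_count_impl(pi$edges, pi$states, pi$ids, "NEG"),
    fraction_pos = mean(pos),
    mean_radial_pos = if (any(pos)) mean(rn[pos]) else NA_real_,
    mean_radial_neg = if (any(!pos)) mean(rn[!pos]) else NA_real_,
    n_cells = length(pi$states)
  )
}

#' Spatial aggregation z-score of the minority state
#'
#' Join-count statistic testing whether the minority state is more
#' spatially aggregated on the contact graph than a random relabelling
#' of the same cells. The observed number of minority-minority edges
#' is standardised by its exact mean and variance under random
#' labelling without replacement, which are closed-form functions of
#' the edge count, the degree sequence and the minority count.
#' Patterns consistent with random labelling score near 0; patched
#' (connected) patterns score strongly positive.
#'
#' @param x An [eb_aggregate()] or [virtual_section()].
#' @return A list with `z`, `observed`, `expected` and `variance`. For
#'   degenerate inputs (fewer than two minority cells or zero null
#'   variance) `z` is 0.
#' @export
minority_aggregation <- function(x) {
  pi <- pattern_input(x)
  n <- length(pi$states)
  n_pos <- sum(pi$states == "POS")
  minority <- if (n_pos <= n - n_pos) "POS" else "NEG"
  m <- min(n_pos, n - n_pos)
  e <- nrow(pi$edges)
  is_min <- pi$states == minority
  obs <- sum(is_min[match(pi$edges$from, pi$ids)] &
               is_min[match(pi$edges$to, pi$ids)])
  if (m < 2 || e == 0) {
    return(list(z = 0, observed = obs, expected = 0, variance = 0))
  }
  deg <- tabulate(match(c(pi$edges$from, pi$edges$to), pi$ids), nbins = n)
  p2 <- m * (m - 1) / (n * (n - 1))
  p3 <- if (n >= 3) p2 * (m - 2) / (n - 2) else 0
  p4 <- if (n >= 4) p3 * (m - 3) / (n - 3) else 0
  s_adj <- sum(deg * (deg - 1) / 2)    # unordered edge pairs sharing a vertex
  s_dis <- e * (e - 1) / 2 - s_adj     # disjoint edge pairs
  mu <- e * p2
  ej2 <- e * p2 + 2 * (s_adj * p3 + s_dis * p4)
  v <- max(ej2 - mu^2, 0)
  z <- if (v <= 0) 0 else (obs - mu) / sqrt(v)
  list(z = z, observed = obs, expected = mu, variance = v)
}

#' Classify a spatial differentiation pattern
#'
#' Assigns one of six classes to an aggregate or virtual section:
#' `oct4_pos` (>= 90% of cells Oct4+), `oct4_neg` (<= 10% Oct4+), and
#' for intermediate Oct4+ fractions the transition patterns
#' `inside_out` (differentiated core), `outside_in` (differentiated
#' rim), `connected` (distinct contiguous same-state regions) or
#' `random` (no identifiable pattern). Transition snapshots are
#' resolved in order: a radial-bias test (difference in mean normalised
#' radial position between states larger than `radial_delta`, with at
#' most `max_shell_clusters` clusters per state) yields
#' `inside_out`/`outside_in`; otherwise the pattern is `connected`
#' when the minority state is significantly more spatially aggregated
#' than random labelling of the same cells
#' ([minority_aggregation()] z-score above `z_crit`), and `random`
#' otherwise.
#'
#' @param x An [eb_aggregate()] or [virtual_section()].
#' @param hi,lo Oct4+ fraction thresholds for the uniform classes.
#' @param radial_delta Minimum difference in mean normalised radial
#'   position for a shell pattern.
#' @param max_shell_clusters Maximum cluster count per state compatible
#'   with a shell pattern.
#' @param z_crit Join-count z threshold separating `connected` from
#'   `random` (default: one-sided 5% normal critical value).
#' @return A factor of length 1 with the six pattern levels.
#' @export
#' @examples
#' classify_pattern(make_fixture("uniform_state", n = 100, seed = 1))
classify_pattern <- function(x, hi = 0.9, lo = 0.1, radial_delta = 0.15,
                             max_shell_clusters = 2,
                             z_crit = qnorm(0.95)) {
  pi <- pattern_input(x)
  if (length(pi$states) == 0) abort("empty input")
  pm <- pattern_metrics(x)
  cls <- if (pm$fraction_pos >= hi) {
    "oct4_pos"
  } else if (pm$fraction_pos <= lo) {
    "oct4_neg"
  } else if (!is.na(pm$mean_radial_pos) && !is.na(pm$mean_radial_neg) &&
             abs(pm$mean_radial_neg - pm$mean_radial_pos) > radial_delta &&
             pm$ucn <= max_shell_clusters &&
             pm$dcn <= max_shell_clusters) {
    if (pm$mean_radial_neg < pm$mean_radial_pos) "inside_out" else "outside_in"
  } else if (minority_aggregation(x)$z > z_crit) {
    "connected"
  } else {
    "random"
  }
  factor(cls, levels = pattern_levels)
}

#' Normalised time axis of a trajectory
#'
#' Each time step is divided by the total number of steps the
#' simulation needed to complete, so trajectories of different length
#' can be compared on a common \[0, 1\] axis. For a run that hit the
#' step cutoff without completing, steps are normalised by the cutoff
#' and a warning is raised.
#'
#' @param traj An `eb_trajectory` from [simulate_states()].
#' @return Numeric vector of tau values, one per recorded step.
#' @export
normalize_time <- function(traj) {
  if (!inherits(traj, "eb_trajectory")) abort("`traj` must be an eb_trajectory")
  if (!attr(traj, "completed")) {
    warn("trajectory did not complete; tau is normalised by the step cutoff")
  }
  traj$tau
}

# nearest-tau lookup of trajectory rows on a common grid
resample_trajectory <- function(traj, grid) {
  idx <- vapply(grid, function(g) which.min(abs(traj$tau - g)), integer(1))
  out <- traj[idx, , drop = FALSE]
  out$tau_grid <- grid
  as_tibble(out)
}

#' Summarise replicate trajectories on a common tau grid
#'
#' Resamples each replicate's UCN/DCN curves onto a shared normalised
#' time grid by nearest-step lookup, then reports across-replicate
#' means and variances plus the cumulative (grid-summed) variance of
#' each metric -- a scalar measure of how reproducible a rule's
#' patterning trajectory is.
#'
#' @param runs A list of `eb_trajectory` objects (>= 2 for variances).
#' @param grid Tau grid in \[0, 1\].
#' @return A tibble with columns `tau`, `ucn_mean`, `ucn_var`,
#'   `dcn_mean`, `dcn_var`, `frac_pos_mean`; the cumulative variances
#'   are in attribute `cumulative_variance` (named vector with
#'   elements `ucn` and `dcn`).
#' @export
summarize_trajectories <- function(runs, grid = seq(0, 1, by = 0.05)) {
  if (length(runs) < 2) abort("need at least 2 runs to estimate variance")
  res <- purrr::map(runs, resample_trajectory, grid = grid)
  ucn <- vapply(res, function(r) as.numeric(r$ucn), numeric(length(grid)))
  dcn <- vapply(res, function(r) as.numeric(r$dcn), numeric(length(grid)))
  fp <- vapply(res, function(r) r$frac_pos, numeric(length(grid)))
  out <- tibble(
    tau = grid,
    ucn_mean = rowMeans(ucn), ucn_var = apply(ucn, 1, var),
    dcn_mean = rowMeans(dcn), dcn_var = apply(dcn, 1, var),
    frac_pos_mean = rowMeans(fp)
  )
  attr(out, "cumulative_variance") <- c(ucn = sum(out$ucn_var),
                                        dcn = sum(out$dcn_var))
  out
}

#' Classify snapshots along a trajectory
#'
#' Re-applies [classify_pattern()] to the recorded per-step states of a
#' trajectory at the requested normalised times (nearest recorded
#' step). The trajectory must have been run with
#' `record_states = TRUE`.
#'
#' @param traj An `eb_trajectory` with recorded states.
#' @param agg The aggregate the trajectory was simulated on.
#' @param taus Normalised times to classify at.
#' @param ... Passed to [classify_pattern()].
#' @return A tibble with columns `tau`, `step`, `frac_pos`, `class`.
#' @export
classify_trajectory <- function(traj, agg,
                                taus = seq(0.1, 0.9, by = 0.1), ...) {
  states <- attr(traj, "states")
  if (is.null(states)) {
    abort("trajectory has no recorded states; rerun with `record_states = TRUE`")
  }
  agg <- as_aggregate(agg)
  idx <- vapply(taus, function(g) which.min(abs(traj$tau - g)), integer(1))
  cls <- purrr::map_chr(idx, function(i) {
    agg$cells$state <- states[i, match(agg$cells$cell_id,
                                       colnames(states))]
    as.character(classify_pattern(agg, ...))
  })
  tibble(tau = taus, step = traj$step[idx], frac_pos = traj$frac_pos[idx],
         class = factor(cls, levels = pattern_levels))
}

#' Pattern-class distribution over time
#'
#' Fractions of each pattern class at each time point, for stacked
#' distribution plots of how patterning evolves.
#'
#' @param classified A data frame with a time column and a `class`
#'   column (factor over the six pattern levels), e.g. row-bound
#'   results of [classify_trajectory()] over replicates.
#' @param time_col Name of the time column.
#' @return A tibble with columns `{time_col}`, `class`, `n` and
#'   `fraction`; fractions sum to 1 at every time point.
#' @export
pattern_distribution <- function(classified, time_col = "tau") {
  cl <- factor(classified$class, levels = pattern_levels)
  tt <- classified[[time_col]]
  tab <- as.data.frame(table(time = tt, class = cl))
  tab$time <- as.numeric(as.character(tab$time))
  out <- as_tibble(tab)
  names(out)[1] <- time_col
  out |>
    dplyr::group_by(.data[[time_col]]) |>
    dplyr::mutate(n = .data$Freq, fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(time_col), "class", "n", "fraction")
}
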