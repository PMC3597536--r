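#' Growth-model parameters
#'
#' Parameters of the dynamic (growing) embryoid-body model, in which
#' rigid spherical cells connected by springs divide asynchronously
#' with state-specific doubling times while the differentiation rule
#' runs on the evolving contact graph.
#'
#' @param doubling_time_pos Population doubling time of Oct4+ (stem)
#'   cells, hours. The default 18 h was estimated from embryoid-body
#'   growth curves.
#' @param doubling_time_neg Doubling time of Oct4- (differentiated)
#'   cells, hours (default 51 h).
#' @param spring_stiffness Spring constant of cell-cell connections, in
#'   um displacement per um stretch per hour (overdamped units).
#' @param rest_length_factor Spring rest length as a multiple of the
#'   sum of the two cell radii.
#' @param mechanics_dt Mechanical relaxation time step, hours.
#' @param rule_dt Interval between rule evaluations (and trajectory
#'   records), hours; the static model's per-step probabilities apply
#'   per evaluation.
#' @param duration Maximum simulated time, hours (default 144 h = 6
#'   days).
#' @param changed_fraction_stop Stop once this fraction of cells has
#'   differentiated (default 99%).
#' @param max_cells Stop once this many cells exist (default 40000).
#' @param contact_slack Contact tolerance for graph construction.
#' @param adhesion_slack Capture range of the cell-cell springs as a
#'   fraction of the rest length: pairs separated by up to this
#'   fraction beyond rest length are pulled back together, modelling
#'   short-range adhesion. Must be at least `contact_slack`, or cells
#'   nudged just past contact range would detach from the aggregate.
#' @param overlap_tolerance Maximum admissible interpenetration as a
#'   fraction of the smaller radius.
#' @return A list of class `growth_params`.
#' @export
growth_params <- function(doubling_time_pos = 18, doubling_time_neg = 51,
                          spring_stiffness = 1, rest_length_factor = 1,
                          mechanics_dt = 0.1, rule_dt = 1,
                          duration = 144, changed_fraction_stop = 0.99,
                          max_cells = 40000, contact_slack = 0.05,
                          adhesion_slack = 0.2,
                          overlap_tolerance = 0.01) {
  if (doubling_time_pos <= 0 || doubling_time_neg <= 0) {
    abort("doubling times must be positive")
  }
  if (duration <= 0) abort("`duration` must be positive")
  if (changed_fraction_stop <= 0 || changed_fraction_stop > 1) {
    abort("`changed_fraction_stop` must be in (0, 1]")
  }
  structure(list(doubling_time_pos = doubling_time_pos,
                 doubling_time_neg = doubling_time_neg,
                 spring_stiffness = spring_stiffness,
                 rest_length_factor = rest_length_factor,
                 mechanics_dt = mechanics_dt, rule_dt = rule_dt,
                 duration = duration,
                 changed_fraction_stop = changed_fraction_stop,
                 max_cells = max_cells, contact_slack = contact_slack,
                 adhesion_slack = max(adhesion_slack, contact_slack),
                 overlap_tolerance = overlap_tolerance),
            class = "growth_params")
}

#' Exponential growth rate between two counts
#'
#' `r = ln(n2 / n1) / (t2 - t1)`, the specific growth rate under
#' exponential growth, applied between discrete time points of a
#' growth curve.
#'
#' @param n1,n2 Cell counts (> 0) at times `t1` and `t2`.
#' @param t1,t2 Times in hours, `t2 > t1`.
#' @return Growth rate per hour.
#' @export
estimate_growth_rate <- function(n1, n2, t1, t2) {
  if (any(n1 <= 0) || any(n2 <= 0)) abort("counts must be positive")
  if (any(t2 <= t1)) abort("`t2` must exceed `t1`")
  log(n2 / n1) / (t2 - t1)
}

#' Doubling time from a growth rate
#'
#' `T = ln(2) / r`, the inverse of the doubling case of
#' [estimate_growth_rate()].
#'
#' @param r Growth rate per hour (> 0).
#' @return Doubling time in hours.
#' @export
doubling_time <- function(r) {
  if (any(r <= 0)) abort("`r` must be positive")
  log(2) / r
}

#' Cell count from an aggregate radius
#'
#' Estimates the number of cells in a spheroid of radius `eb_radius`
#' from the volume of an average cell and a maximal close-packing
#' fraction, the approximation used to convert measured embryoid-body
#' radii into cell counts for growth-rate estimation.
#'
#' @param eb_radius Aggregate radius, um.
#' @param cell_diameter Mean cell diameter, um (default 6.6).
#' @param packing Packing fraction in (0, 1\]. The default is the
#'   conventional rounded close-packing constant 0.7408; the analytic
#'   face-centred cubic value is `pi / sqrt(18)` = 0.74048.
#' @return Integer cell count (floored).
#' @export
cells_from_radius <- function(eb_radius, cell_diameter = 6.6,
                              packing = 0.7408) {
  if (any(eb_radius <= 0) || any(cell_diameter <= 0)) {
    abort("`eb_radius` and `cell_diameter` must be positive")
  }
  if (any(packing <= 0) || any(packing > 1)) {
    abort("`packing` must be in (0, 1]")
  }
  floor(packing * (eb_radius / (cell_diameter / 2))^3)
}

#' Draw the next division time for cells
#'
#' Division is unsynchronised: waiting times to the next division are
#' exponential with rate `ln(2) / T_state`, where `T_state` is the
#' state-specific doubling time. The memoryless draw makes the
#' population grow exactly exponentially at the configured rate.
#'
#' @param state Character vector of cell states (`"POS"`/`"NEG"`).
#' @param time Current simulation time, hours.
#' @param params A [growth_params()].
#' @return Numeric vector of absolute next-division times (hours).
#' @export
schedule_division <- function(state, time, params = growth_params()) {
  check_states(state)
  t_dbl <- ifelse(state == "POS", params$doubling_time_pos,
                  params$doubling_time_neg)
  time + rexp(length(state), rate = log(2) / t_dbl)
}

#' Divide one cell
#'
#' Symmetric division: the daughter inherits the parent's state and
#' radius (cell size does not change appreciably during early
#' differentiation) and is placed one parent radius away in a uniformly
#' random direction; the resulting overlap is resolved by the
#' mechanics. Both parent and daughter receive fresh division clocks.
#'
#' @param agg An [eb_aggregate()] whose cells carry a `next_division`
#'   column.
#' @param cell_id Id of the dividing cell.
#' @param params A [growth_params()].
#' @return The aggregate with one extra cell (contact graph not
#'   rebuilt; callers relax and rebuild).
#' @export
divide_cell <- function(agg, cell_id, params = growth_params()) {
  agg <- as_aggregate(agg)
  i <- match(cell_id, agg$cells$cell_id)
  if (is.na(i)) abort(sprintf("no cell with id %s", cell_id))
  parent <- agg$cells[i, ]
  u <- random_unit_vector()
  daughter <- parent
  daughter$cell_id <- max(agg$cells$cell_id) + 1L
  daughter$x <- parent$x + parent$radius * u[1]
  daughter$y <- parent$y + parent$radius * u[2]
  daughter$z <- parent$z + parent$radius * u[3]
  agg$cells$next_division[i] <- schedule_division(parent$state, agg$time,
                                                  params)
  daughter$next_division <- schedule_division(parent$state, agg$time,
                                              params)
  agg$cells <- dplyr::bind_rows(agg$cells, daughter)
  agg
}

random_unit_vector <- function() {
  z <- runif(1, -1, 1)
  th <- runif(1, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  c(s * cos(th), s * sin(th), z)
}

#' One overdamped mass-spring relaxation step
#'
#' Applies linear spring forces along all pairs within the adhesion
#' capture range (rest length `rest_length_factor` times the sum of
#' radii, captured up to `adhesion_slack` beyond it) as an overdamped
#' displacement, then projects out any remaining hard-sphere overlaps
#' with complete pairwise collision detection. Compressed springs push
#' apart; stretched ones pull back, which keeps marginally separated
#' cells adherent to the aggregate.
#'
#' @param agg An [eb_aggregate()].
#' @param params A [growth_params()].
#' @param steps Number of relaxation steps.
#' @return The aggregate with updated positions and contact graph.
#' @export
spring_relax <- function(agg, params = growth_params(), steps = 1) {
  agg <- as_aggregate(agg)
  pos <- as.matrix(agg$cells[, c("x", "y", "z")])
  for (s in seq_len(steps)) {
    res <- cpp_spring_step(pos, agg$cells$radius, params$adhesion_slack,
                           params$spring_stiffness,
                           params$rest_length_factor,
                           params$mechanics_dt,
                           params$overlap_tolerance, 40L)
    pos <- res$pos
  }
  agg$cells$x <- pos[, 1]; agg$cells$y <- pos[, 2]; agg$cells$z <- pos[, 3]
  eb_aggregate(agg$cells, contact_slack = agg$contact_slack,
               time = agg$time)
}

#' Run the growing-aggregate simulation
#'
#' Event loop of the dynamic model: mechanics are advanced every
#' `mechanics_dt` hours, cells divide at their scheduled times, and
#' (optionally) the differentiation rule is evaluated every `rule_dt`
#' hours with per-evaluation probabilities. The run stops at the first
#' satisfied criterion: the configured duration, the differentiated
#' fraction reaching `changed_fraction_stop`, or the cell count
#' reaching `max_cells`. With `rule = NULL` the simulation is a
#' division-only control.
#'
#' @param initial An [eb_aggregate()] or cell table; states should be
#'   all Oct4+ for the canonical study condition.
#' @param rule A [rule_params()] or `NULL` for growth only. For the
#'   competing-feedback rule in the dynamic model, pass
#'   `rule_params("competing_feedback", weight = 0.01)`.
#' @param growth A [growth_params()].
#' @param seed Optional integer seed.
#' @param record_structure Also record projected radius, density and
#'   circularity at each record point (slower for large aggregates).
#' @return An `eb_growth` object: a tibble with one row per `rule_dt`
#'   record -- columns `time`, `n_cells`, `frac_pos`, `ucn_norm`,
#'   `dcn_norm` (cluster numbers normalised by cell count),
#'   `mean_count`, `mean_length`, and (if `record_structure`)
#'   `radius`, `density`, `circularity` -- with attributes
#'   `final_aggregate`, `stop_reason`, `seed` and `params`.
#' @export
#' @examples
#' \donttest{
#' agg <- seed_cells(60, seed = 2) |> aggregate_cells(seed = 2)
#' gr <- simulate_growth(agg, growth = growth_params(duration = 24),
#'                       seed = 2)
#' glance(gr)
#' }
simulate_growth <- function(initial, rule = NULL,
                            growth = growth_params(), seed = NULL,
                            record_structure = TRUE) {
  agg <- as_aggregate(initial, contact_slack = growth$contact_slack)
  n0 <- nrow(agg$cells)
  with_seed_maybe(seed, {
    if (!"next_division" %in% names(agg$cells) ||
        all(is.na(agg$cells$next_division))) {
      agg$cells$next_division <- schedule_division(agg$cells$state, 0,
                                                   growth)
    }
    t <- 0
    next_record <- 0
    rec <- list()
    stop_reason <- "duration"
    record <- function(time) {
      cs <- connection_stats(agg)
      row <- tibble(
        time = time, n_cells = nrow(agg$cells),
        frac_pos = mean(agg$cells$state == "POS"),
        ucn_norm = count_state_clusters(agg, "POS") / nrow(agg$cells),
        dcn_norm = count_state_clusters(agg, "NEG") / nrow(agg$cells),
        mean_count = cs$mean_count, mean_length = cs$mean_length
      )
      if (record_structure) {
        r <- aggregate_radius(agg)
        row$radius <- r
        row$density <- sum((4 / 3) * pi * agg$cells$radius^3) /
          ((4 / 3) * pi * r^3)
        row$circularity <- circularity(agg)
      }
      row
    }
    rec[[1]] <- record(0)
    next_record <- growth$rule_dt
    repeat {
      if (t >= growth$duration - 1e-9) break
      t <- t + growth$mechanics_dt
      # divisions due by now, in clock order
      repeat {
        due <- which(agg$cells$next_division <= t)
        if (length(due) == 0) break
        first <- due[which.min(agg$cells$next_division[due])]
        agg$time <- t
        agg <- divide_cell(agg, agg$cells$cell_id[first], growth)
        if (nrow(agg$cells) >= growth$max_cells) break
      }
      agg <- spring_relax(agg, growth, steps = 1)
      agg$time <- t
      if (nrow(agg$cells) >= growth$max_cells) {
        stop_reason <- "max_cells"
        rec[[length(rec) + 1]] <- record(t)
        break
      }
      if (t >= next_record - 1e-9) {
        if (!is.null(rule)) {
          agg <- step_states(agg, rule)
        }
        rec[[length(rec) + 1]] <- record(t)
        next_record <- next_record + growth$rule_dt
        if (!is.null(rule) &&
            mean(agg$cells$state == "NEG") >= growth$changed_fraction_stop) {
          stop_reason <- "changed_fraction"
          break
        }
      }
    }
    out <- dplyr::bind_rows(rec)
    structure(out, class = c("eb_growth", class(out)),
              final_aggregate = agg, stop_reason = stop_reason,
              seed = seed, params = growth, rule = rule, n0 = n0)
  })
}

#' @export
print.eb_growth <- function(x, ...) {
  cat(sprintf("<eb_growth: %d -> %d cells over %g h (stopped: %s)>\n",
              attr(x, "n0"), x$n_cells[nrow(x)], x$time[nrow(x)],
              attr(x, "stop_reason")))
  NextMethod()
}

#' @rdname simulate_growth
#' @param x An `eb_growth`.
#' @param ... Unused.
#' @export
tidy.eb_growth <- function(x, ...) as_tibble(unclass(x)[names(x)])

#' @rdname simulate_growth
#' @export
glance.eb_growth <- function(x, ...) {
  fit <- fit_doubling_time(x)
  tibble(n0 = attr(x, "n0"), n_final = x$n_cells[nrow(x)],
         hours = x$time[nrow(x)], stop_reason = attr(x, "stop_reason"),
         final_frac_pos = x$frac_pos[nrow(x)],
         fitted_doubling_time = fit$doubling_time,
         fit_r_squared = fit$r_squared)
}

#' Fit a population doubling time to a growth trajectory
#'
#' Ordinary least squares of `ln(cell count)` against time; the
#' doubling time is `ln(2)` over the fitted slope.
#'
#' @param gr An `eb_growth` object or a data frame with `time` and
#'   `n_cells` columns.
#' @return A list with `rate` (per hour), `doubling_time` (hours) and
#'   `r_squared`.
#' @export
fit_doubling_time <- function(gr) {
  df <- as_tibble(unclass(gr)[c("time", "n_cells")])
  if (nrow(df) < 3 || stats::sd(df$n_cells) == 0) {
    return(list(rate = NA_real_, doubling_time = NA_real_,
                r_squared = NA_real_))
  }
  fit <- lm(log(n_cells) ~ time, data = df)
  slope <- coef(fit)[["time"]]
  list(rate = slope,
       doubling_time = if (slope > 0) log(2) / slope else NA_real_,
       r_squared = summary(fit)$r.squared)
}
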