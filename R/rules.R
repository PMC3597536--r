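#' Differentiation rule parameters
#'
#' Parameters of the three probabilistic rules governing the
#' irreversible Oct4+ to Oct4- transition. Every rule is a function of
#' a cell's nearest neighbours only:
#'
#' * `"random"`: a constant basal probability `alpha` per time step.
#' * `"positive_feedback"`: differentiated neighbours promote the
#'   transition; the neighbour term `beta / epsilon` (number of Oct4-
#'   neighbours over the maximum possible number of neighbours) is
#'   combined with the basal rate through an or-gate.
#' * `"competing_feedback"`: differentiated neighbours promote and
#'   undifferentiated neighbours inhibit the transition through the
#'   sigmoidal term `beta^k / (beta^k + gamma^k)`, scaled by `weight`
#'   and or-gated with the basal rate.
#'
#' @param kind `"random"`, `"positive_feedback"` or
#'   `"competing_feedback"`.
#' @param alpha Basal per-step transition probability (default 1%).
#' @param epsilon Maximum possible number of neighbours used to
#'   normalise `beta`; 12 is the kissing number of close-packed equal
#'   spheres.
#' @param weight Scaling of the competing-feedback neighbour term in
#'   \[0, 1\]. 1 for static-structure simulations; 0.01 is the value
#'   used with the growing (dynamic) model, where rules are evaluated
#'   once per hour.
#' @param exponent Exponent `k` of the competing-feedback term. The
#'   default 2 gives a sigmoidal response in `beta` without a separate
#'   half-saturation constant.
#' @return A list of class `rule_params`.
#' @export
rule_params <- function(kind = c("random", "positive_feedback",
                                 "competing_feedback"),
                        alpha = 0.01, epsilon = 12, weight = 1,
                        exponent = 2) {
  kind <- match.arg(kind)
  if (alpha < 0 || alpha > 1) abort("`alpha` must be in [0, 1]")
  if (epsilon < 1) abort("`epsilon` must be >= 1")
  if (weight < 0 || weight > 1) abort("`weight` must be in [0, 1]")
  if (exponent <= 0) abort("`exponent` must be positive")
  structure(list(kind = kind, alpha = alpha, epsilon = epsilon,
                 weight = weight, exponent = exponent),
            class = "rule_params")
}

#' @export
print.rule_params <- function(x, ...) {
  cat(sprintf("<rule_params: %s, alpha = %g, epsilon = %g, weight = %g, exponent = %g>\n",
              x$kind, x$alpha, x$epsilon, x$weight, x$exponent))
  invisible(x)
}

#' Or-gate combination of probabilities
#'
#' Probabilistic union of two independent transition mechanisms:
#' `1 - (1 - p1) * (1 - p2)`. Commutative, bounded by
#' `max(p1, p2) <= or_gate(p1, p2) <= min(1, p1 + p2)`.
#'
#' @param p1,p2 Probabilities in \[0, 1\]; vectorised.
#' @return Combined probability.
#' @export
or_gate <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1)) {
    abort("probabilities must be in [0, 1]")
  }
  1 - (1 - p1) * (1 - p2)
}

#' Per-cell transition probability
#'
#' Evaluates the configured rule for cells with `beta` differentiated
#' and `gamma` undifferentiated neighbours. `beta / epsilon` is clamped
#' to 1 when contact slack admits more than `epsilon` neighbours, and
#' the competing term is defined as 0 for an isolated cell
#' (`beta = gamma = 0`), which then feels only the basal rate.
#'
#' @param beta Number of Oct4- neighbours (vectorised).
#' @param gamma Number of Oct4+ neighbours (vectorised).
#' @param params A [rule_params()].
#' @return Vector of per-step transition probabilities.
#' @export
transition_probability <- function(beta, gamma, params) {
  if (any(beta < 0) || any(gamma < 0)) abort("neighbour counts must be >= 0")
  n <- max(length(beta), length(gamma))
  beta <- rep_len(beta, n); gamma <- rep_len(gamma, n)
  switch(params$kind,
    random = rep_len(params$alpha, n),
    positive_feedback = {
      or_gate(params$alpha, pmin(beta / params$epsilon, 1))
    },
    competing_feedback = {
      k <- params$exponent
      denom <- beta^k + gamma^k
      f <- ifelse(denom == 0, 0, beta^k / denom)
      or_gate(params$alpha, params$weight * f)
    }
  )
}

# beta (Oct4- neighbours) and gamma (Oct4+ neighbours) for every cell,
# aligned with agg$cells rows
neighbor_state_counts <- function(agg) {
  n <- nrow(agg$cells)
  i <- match(agg$edges$from, agg$cells$cell_id)
  j <- match(agg$edges$to, agg$cells$cell_id)
  neg <- agg$cells$state == "NEG"
  beta <- tabulate(c(i[neg[j]], j[neg[i]]), nbins = n)
  gamma <- tabulate(c(i[!neg[j]], j[!neg[i]]), nbins = n)
  list(beta = beta, gamma = gamma)
}

#' One synchronous rule-update step
#'
#' Computes each undifferentiated cell's transition probability from
#' the start-of-step states, then applies independent Bernoulli draws.
#' Only Oct4+ cells may transition and transitions are irreversible.
#' One uniform deviate is consumed per undifferentiated cell, in
#' increasing `cell_id` order, which makes the update reproducible
#' under a seeded RNG.
#'
#' @param agg An [eb_aggregate()].
#' @param params A [rule_params()].
#' @return The aggregate with updated states; the number of
#'   transitions is in attribute `transitions`.
#' @export
step_states <- function(agg, params) {
  agg <- as_aggregate(agg)
  ord <- order(agg$cells$cell_id)
  pos_rows <- ord[agg$cells$state[ord] == "POS"]
  if (length(pos_rows) == 0) {
    attr(agg, "transitions") <- 0L
    return(agg)
  }
  nb <- neighbor_state_counts(agg)
  p <- transition_probability(nb$beta[pos_rows], nb$gamma[pos_rows], params)
  u <- runif(length(pos_rows))
  flip <- pos_rows[u < p]
  agg$cells$state[flip] <- "NEG"
  attr(agg, "transitions") <- length(flip)
  agg
}

#' Run a static-structure differentiation simulation
#'
#' Applies the configured rule synchronously on a fixed aggregate
#' structure until every cell has differentiated or `max_steps` time
#' steps have elapsed (default 500, the average completion time of the
#' random rule). The canonical study condition starts from a
#' homogeneous Oct4+ population.
#'
#' @param agg An [eb_aggregate()]; by default its states are reset to
#'   all Oct4+ before the run (`reset_states = FALSE` keeps them).
#' @param params A [rule_params()].
#' @param max_steps Time-step cutoff.
#' @param seed Optional integer seed; trajectories are bitwise
#'   reproducible given the seed.
#' @param record_states Keep the full per-step state matrix (needed to
#'   re-classify intermediate snapshots).
#' @param reset_states Reset all states to Oct4+ first.
#' @return An `eb_trajectory`: a tibble with one row per recorded step
#'   (step 0 = initial state) and columns `step`, `tau`, `n_pos`,
#'   `frac_pos`, `ucn`, `dcn`, `transitions`, plus attributes
#'   `completed`, `seed`, `params`, `n_cells` and (optionally) `states`
#'   (a steps-by-cells character matrix).
#' @export
#' @examples
#' agg <- fcc_aggregate(2)
#' tr <- simulate_states(agg, rule_params("random", alpha = 0.2), seed = 1)
#' glance(tr)
simulate_states <- function(agg, params = rule_params(), max_steps = 500,
                            seed = NULL, record_states = FALSE,
                            reset_states = TRUE) {
  if (max_steps < 1) abort("`max_steps` must be >= 1")
  agg <- as_aggregate(agg)
  if (reset_states) agg$cells$state <- "POS"
  n <- nrow(agg$cells)
  rec <- vector("list", max_steps + 1)
  states <- if (record_states) {
    matrix(NA_character_, max_steps + 1, n,
           dimnames = list(NULL, agg$cells$cell_id))
  }
  snapshot <- function(step, transitions) {
    tibble(step = step, n_pos = sum(agg$cells$state == "POS"),
           ucn = count_state_clusters(agg, "POS"),
           dcn = count_state_clusters(agg, "NEG"),
           transitions = transitions)
  }
  k <- 0L
  with_seed_maybe(seed, {
    rec[[1]] <- snapshot(0L, 0L)
    if (record_states) states[1, ] <- agg$cells$state
    while (k < max_steps && any(agg$cells$state == "POS")) {
      agg <- step_states(agg, params)
      k <- k + 1L
      rec[[k + 1]] <- snapshot(k, attr(agg, "transitions"))
      if (record_states) states[k + 1, ] <- agg$cells$state
    }
  })
  out <- dplyr::bind_rows(rec[seq_len(k + 1)])
  completed <- out$n_pos[k + 1] == 0
  out$tau <- out$step / (if (completed) k else max_steps)
  out$frac_pos <- out$n_pos / n
  out <- out[, c("step", "tau", "n_pos", "frac_pos", "ucn", "dcn",
                 "transitions")]
  structure(out, class = c("eb_trajectory", class(out)),
            completed = completed, seed = seed, params = params,
            n_cells = n,
            states = if (record_states) states[seq_len(k + 1), , drop = FALSE],
            final_states = agg$cells$state)
}

#' @export
print.eb_trajectory <- function(x, ...) {
  cat(sprintf("<eb_trajectory: %d cells, %d steps, %s>\n",
              attr(x, "n_cells"), max(x$step),
              if (attr(x, "completed")) "completed" else "cutoff reached"))
  NextMethod()
}

#' @rdname simulate_states
#' @param x An `eb_trajectory`.
#' @param ... Unused.
#' @export
tidy.eb_trajectory <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' @rdname simulate_states
#' @export
glance.eb_trajectory <- function(x, ...) {
  tibble(n_cells = attr(x, "n_cells"), n_steps = max(x$step),
         completed = attr(x, "completed"),
         final_frac_pos = x$frac_pos[nrow(x)],
         max_ucn = max(x$ucn), max_dcn = max(x$dcn))
}
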