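test_that("or-gate has identity, absorption and union bounds", {
  expect_equal(or_gate(0, 0.3), 0.3)
  expect_equal(or_gate(1, 0.3), 1)
  expect_equal(or_gate(0.5, 0.5), 0.75)
  expect_equal(or_gate(0.2, 0.4), or_gate(0.4, 0.2))
  # bounds over a probability grid
  g <- expand.grid(p1 = seq(0, 1, 0.1), p2 = seq(0, 1, 0.1))
  og <- or_gate(g$p1, g$p2)
  expect_true(all(og >= pmax(g$p1, g$p2) - 1e-12))
  expect_true(all(og <= pmin(1, g$p1 + g$p2) + 1e-12))
  expect_error(or_gate(-0.1, 0.5), "0, 1")
})

test_that("rule probabilities follow their closed forms", {
  # random: the basal 1% regardless of neighbourhood
  expect_equal(transition_probability(5, 7, rule_params("random")), 0.01)
  expect_equal(transition_probability(0, 0,
                                      rule_params("random", alpha = 0)), 0)
  expect_equal(transition_probability(0, 0,
                                      rule_params("random", alpha = 1)), 1)

  pf <- rule_params("positive_feedback")
  expect_equal(transition_probability(0, 5, pf), 0.01)
  expect_equal(transition_probability(12, 0, pf), 1)
  expect_equal(transition_probability(6, 6, pf), 1 - 0.99 * 0.5)
  # beta/epsilon clamps at 1 when slack admits > epsilon contacts
  expect_equal(transition_probability(14, 0, pf), 1)

  cf <- rule_params("competing_feedback")
  expect_equal(transition_probability(0, 5, cf), 0.01)
  expect_equal(transition_probability(0, 0, cf), 0.01)
  expect_equal(transition_probability(4, 4,
                                      rule_params("competing_feedback",
                                                  alpha = 0)), 0.5)
  # dynamic-model weighting scales the neighbour term only
  cfw <- rule_params("competing_feedback", alpha = 0, weight = 0.01)
  expect_equal(transition_probability(4, 4, cfw), 0.005)
  expect_error(transition_probability(-1, 0, cf), ">= 0")
})

test_that("competing feedback is monotone over the full neighbour grid", {
  cf <- rule_params("competing_feedback")
  grid <- expand.grid(beta = 0:12, gamma = 0:12)
  p <- matrix(transition_probability(grid$beta, grid$gamma, cf), 13, 13)
  # non-decreasing in beta (rows), non-increasing in gamma (columns)
  expect_true(all(diff(p) >= -1e-12))
  expect_true(all(t(diff(t(p))) <= 1e-12))
})

test_that("positive feedback dominates the random rule cell-by-cell", {
  grid <- expand.grid(beta = 0:12, gamma = 0:12)
  p_pos <- transition_probability(grid$beta, grid$gamma,
                                  rule_params("positive_feedback"))
  p_rnd <- transition_probability(grid$beta, grid$gamma,
                                  rule_params("random"))
  expect_true(all(p_pos >= p_rnd - 1e-12))
})

test_that("synchronous updates transition only Oct4+ cells, irreversibly", {
  agg <- shared_packing(100)
  # all differentiated: nothing can change
  neg <- with_states(agg, rep("NEG", 100))
  expect_equal(attr(step_states(neg, rule_params("random")), "transitions"),
               0L)
  # certain transition: every Oct4+ cell flips in one step
  withr::with_seed(1, {
    out <- step_states(agg, rule_params("random", alpha = 1))
  })
  expect_true(all(out$cells$state == "NEG"))
})

test_that("a seeded step replays the exact Bernoulli draws", {
  # 5-cell path graph with a differentiated end; replay the update by
  # consuming the same uniforms in cell-id order
  path5 <- tibble::tibble(cell_id = 1:5, x = (0:4) * 6.6, y = 0, z = 0,
                          radius = 3.3,
                          state = c("NEG", "POS", "POS", "POS", "POS"))
  agg <- eb_aggregate(path5)
  cf <- rule_params("competing_feedback")
  # beta/gamma by hand: cell2 sees {NEG, POS}, cells 3,4 see {POS,POS},
  # cell5 sees {POS}
  p_manual <- transition_probability(c(1, 0, 0, 0), c(1, 2, 2, 1), cf)
  withr::with_seed(99, u <- runif(4))
  expected <- ifelse(u < p_manual, "NEG", "POS")
  withr::with_seed(99, out <- step_states(agg, cf))
  expect_identical(out$cells$state[2:5], expected)
  expect_identical(out$cells$state[1], "NEG")
})

test_that("static simulations respect stop criteria and determinism", {
  agg <- shared_packing(100)
  # alpha = 1 completes in one step with tau grid {0, 1}
  tr1 <- simulate_states(agg, rule_params("random", alpha = 1), seed = 1)
  expect_true(attr(tr1, "completed"))
  expect_equal(tr1$tau, c(0, 1))

  # alpha = 0 positive feedback with no differentiated seed: nothing
  # ever happens, run hits the cutoff
  tr0 <- simulate_states(agg, rule_params("positive_feedback", alpha = 0),
                         max_steps = 20, seed = 1)
  expect_false(attr(tr0, "completed"))
  expect_equal(max(tr0$step), 20)
  expect_true(all(tr0$frac_pos == 1))
  expect_warning(normalize_time(tr0), "cutoff")

  # bitwise reproducibility under the seed
  a <- simulate_states(agg, rule_params("competing_feedback"), seed = 5)
  b <- simulate_states(agg, rule_params("competing_feedback"), seed = 5)
  expect_identical(tidy(a), tidy(b))

  # irreversibility: Oct4+ fraction never increases
  expect_true(all(diff(a$frac_pos) <= 0))
  expect_error(simulate_states(agg, max_steps = 0), "max_steps")
})

test_that("the random rule survival curve is geometric", {
  agg <- shared_packing(250)
  tr <- simulate_states(agg, rule_params("random"), max_steps = 120,
                        seed = 21)
  t <- tr$step
  expected <- 0.99^t
  sd3 <- 3 * sqrt(expected * (1 - expected) / 250)
  ok <- abs(tr$frac_pos - expected) <= pmax(sd3, 1e-12)
  expect_gte(mean(ok), 0.98)
})
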