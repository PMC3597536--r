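test_that("growth rate and doubling time follow the exponential forms", {
  expect_equal(estimate_growth_rate(100, 200, 0, 18), log(2) / 18)
  expect_equal(estimate_growth_rate(500, 500, 10, 20), 0)
  expect_equal(estimate_growth_rate(100, 800, 0, 54), 3 * log(2) / 54)
  expect_equal(doubling_time(log(2) / 18), 18)
  expect_equal(doubling_time(log(2) / 51), 51)
  # round trip for arbitrary doubling scenarios
  for (T in c(5, 18, 51, 100)) {
    expect_equal(doubling_time(estimate_growth_rate(30, 60, 0, T)), T)
  }
  expect_error(estimate_growth_rate(-1, 10, 0, 1), "positive")
  expect_error(estimate_growth_rate(10, 10, 5, 5), "t2")
  expect_error(doubling_time(0), "positive")
})

test_that("radius-to-cell-count conversion uses close packing", {
  # radius 10x the cell radius: 0.7408 * 1000, floored
  expect_equal(cells_from_radius(33, 6.6), 740)
  expect_equal(cells_from_radius(3.3, 6.6, packing = 1), 1)
  # monotone non-decreasing in radius
  r <- seq(5, 100, by = 2.5)
  expect_true(all(diff(cells_from_radius(r)) >= 0))
  expect_error(cells_from_radius(-5), "positive")
  expect_error(cells_from_radius(10, packing = 1.2), "0, 1")
})

test_that("division clocks are exponential with state-specific rates", {
  gp <- growth_params()
  withr::with_seed(1, {
    waits <- schedule_division(rep("POS", 1e5), 0, gp)
  })
  # exponential mean T / ln 2 = 25.97 h for the 18 h doubling time
  se <- (18 / log(2)) / sqrt(1e5)
  expect_lt(abs(mean(waits) - 18 / log(2)), 3 * se)
  withr::with_seed(1, {
    waits_neg <- schedule_division(rep("NEG", 1e5), 0, gp)
  })
  expect_lt(abs(mean(waits_neg) - 51 / log(2)), 3 * (51 / log(2)) / sqrt(1e5))
  # same seed, same schedule
  a <- withr::with_seed(2, schedule_division(rep("POS", 10), 5, gp))
  b <- withr::with_seed(2, schedule_division(rep("POS", 10), 5, gp))
  expect_identical(a, b)
  expect_true(all(a > 5))
})

test_that("division is symmetric and size-preserving", {
  agg <- shared_packing(50)
  agg$cells$state <- c(rep("NEG", 10), rep("POS", 40))
  agg$cells$next_division <- Inf
  withr::with_seed(6, {
    for (k in 1:30) {
      parent_id <- sample(agg$cells$cell_id, 1)
      parent <- agg$cells[agg$cells$cell_id == parent_id, ]
      n_before <- nrow(agg$cells)
      agg <- divide_cell(agg, parent_id)
      daughter <- agg$cells[nrow(agg$cells), ]
      expect_equal(nrow(agg$cells), n_before + 1)
      expect_identical(daughter$state, parent$state)
      expect_identical(daughter$radius, parent$radius)
      # daughter is placed one parent radius away
      d <- sqrt((daughter$x - parent$x)^2 + (daughter$y - parent$y)^2 +
                  (daughter$z - parent$z)^2)
      expect_equal(d, parent$radius, tolerance = 1e-9)
    }
  })
  expect_error(divide_cell(agg, 99999), "no cell")
})

test_that("spring relaxation settles contacts and dissipates energy", {
  gp <- growth_params()
  # two cells at rest length: no motion
  pair <- eb_aggregate(tibble::tibble(cell_id = 1:2, x = c(0, 6.6), y = 0,
                                      z = 0, radius = 3.3, state = "POS"))
  out <- withr::with_seed(1, spring_relax(pair, gp))
  expect_equal(out$cells$x, pair$cells$x, tolerance = 1e-9)

  # two overlapping cells are separated to contact within tolerance
  ov <- eb_aggregate(tibble::tibble(cell_id = 1:2, x = c(0, 4), y = 0,
                                    z = 0, radius = 3.3, state = "POS"))
  out2 <- withr::with_seed(1, spring_relax(ov, gp))
  d <- abs(diff(out2$cells$x))
  expect_gte(d, 6.6 * (1 - 0.01) - 1e-9)

  # compressed three-cell chain: spring energy is non-increasing
  chain <- eb_aggregate(tibble::tibble(cell_id = 1:3, x = c(0, 5, 10),
                                       y = 0, z = 0, radius = 3.3,
                                       state = "POS"))
  energy <- function(agg) {
    e <- contact_edges(agg$cells, gp$contact_slack)
    if (nrow(e) == 0) return(0)
    i <- match(e$from, agg$cells$cell_id)
    j <- match(e$to, agg$cells$cell_id)
    L0 <- gp$rest_length_factor *
      (agg$cells$radius[i] + agg$cells$radius[j])
    sum(0.5 * gp$spring_stiffness * (e$length - L0)^2)
  }
  es <- numeric(6)
  es[1] <- energy(chain)
  cur <- chain
  withr::with_seed(4, {
    for (k in 2:6) {
      cur <- spring_relax(cur, gp)
      es[k] <- energy(cur)
    }
  })
  expect_true(all(diff(es) <= 1e-9))
})

test_that("growth-only simulations grow exponentially at the set rate", {
  init <- shared_packing(100)
  gr <- simulate_growth(init, growth = growth_params(duration = 60),
                        seed = 31, record_structure = FALSE)
  fit <- fit_doubling_time(gr)
  expect_gt(fit$r_squared, 0.99)
  expect_lt(abs(fit$doubling_time - 18) / 18, 0.10)
  # radii never change after creation; cell count never decreases
  expect_true(all(attr(gr, "final_aggregate")$cells$radius %in%
                    init$cells$radius))
  expect_true(all(diff(gr$n_cells) >= 0))
})

test_that("growth stop criteria fire at the first satisfied condition", {
  init <- shared_packing(50)
  # max_cells cap
  gr <- simulate_growth(init, growth = growth_params(max_cells = 100),
                        seed = 3, record_structure = FALSE)
  expect_equal(attr(gr, "stop_reason"), "max_cells")
  expect_lte(max(gr$n_cells), 100)

  # certain rule: stops at the first rule evaluation via the
  # changed-fraction criterion
  gr2 <- simulate_growth(init, rule = rule_params("random", alpha = 1),
                         growth = growth_params(duration = 144),
                         seed = 3, record_structure = FALSE)
  expect_equal(attr(gr2, "stop_reason"), "changed_fraction")
  expect_lte(max(gr2$time), 1 + 1e-9)
})

test_that("dynamic runs keep overlaps bounded and states irreversible", {
  init <- shared_packing(50)
  gr <- simulate_growth(init,
                        rule = rule_params("competing_feedback",
                                           weight = 0.01, alpha = 0.05),
                        growth = growth_params(duration = 24),
                        seed = 8, record_structure = FALSE)
  # irreversibility in a growing population: differentiated cells never
  # revert (and divide), so the Oct4- head count is non-decreasing even
  # though frac_pos itself can rise when Oct4+ cells divide faster
  n_neg <- round(gr$n_cells * (1 - gr$frac_pos))
  expect_true(all(diff(n_neg) >= 0))
  fin <- attr(gr, "final_aggregate")
  expect_lte(ebsim:::max_overlap_fraction(fin), 0.02)
  expect_true(igraph::is_connected(as_igraph(fin)))
})
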