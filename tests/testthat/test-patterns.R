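test_that("cluster counting requires two or more same-state cells", {
  # one isolated differentiated cell is not a cluster
  iso <- tibble::tibble(cell_id = 1:3, x = c(0, 20, 40), y = 0, z = 0,
                        radius = 3.3, state = c("NEG", "POS", "POS"))
  expect_equal(count_state_clusters(eb_aggregate(iso), "NEG"), 0)
  # two adjacent differentiated cells are exactly one cluster
  pair <- tibble::tibble(cell_id = 1:2, x = c(0, 6.6), y = 0, z = 0,
                         radius = 3.3, state = "NEG")
  expect_equal(count_state_clusters(eb_aggregate(pair), "NEG"), 1)
  expect_equal(count_state_clusters(eb_aggregate(pair), "POS"), 0)
})

test_that("cluster counts equal a brute-force DFS oracle on random graphs", {
  withr::with_seed(7, {
    for (k in 1:200) {
      n <- sample(5:50, 1)
      agg <- random_state_graph(n, p_edge = runif(1, 0.02, 0.3))
      for (st in c("POS", "NEG")) {
        expect_identical(
          count_state_clusters(agg, st),
          dfs_cluster_count(agg$cells$cell_id, agg$cells$state,
                            agg$edges$from, agg$edges$to, st))
      }
    }
  })
})

test_that("pattern metrics summarise clusters and radial bias", {
  agg <- shared_packing(250)
  pm_all <- pattern_metrics(with_states(agg, rep("POS", 250)))
  expect_equal(pm_all[, c("ucn", "dcn", "fraction_pos")],
               tibble::tibble(ucn = 1L, dcn = 0L, fraction_pos = 1))
  pm_none <- pattern_metrics(with_states(agg, rep("NEG", 250)))
  expect_equal(pm_none[, c("ucn", "dcn", "fraction_pos")],
               tibble::tibble(ucn = 0L, dcn = 1L, fraction_pos = 0))

  shell <- make_fixture("shell_inside_out", n = 250, seed = 31)
  pm <- pattern_metrics(shell)
  expect_lt(pm$mean_radial_neg, pm$mean_radial_pos)

  # each cluster has >= 2 cells, so UCN + DCN <= n / 2
  withr::with_seed(11, {
    for (k in 1:20) {
      a <- random_state_graph(40, p_edge = 0.1)
      pmk <- pattern_metrics(a)
      expect_lte(pmk$ucn + pmk$dcn, 20)
    }
  })
})

test_that("join-count moments match a permutation oracle", {
  withr::with_seed(3, {
    for (k in 1:5) {
      agg <- random_state_graph(60, p_edge = 0.08, p_pos = 0.7)
      ma <- minority_aggregation(agg)
      m <- min(sum(agg$cells$state == "POS"),
               sum(agg$cells$state == "NEG"))
      i <- match(agg$edges$from, agg$cells$cell_id)
      j <- match(agg$edges$to, agg$cells$cell_id)
      sim <- replicate(2000, {
        lab <- logical(60)
        lab[sample(60, m)] <- TRUE
        sum(lab[i] & lab[j])
      })
      expect_equal(ma$expected, mean(sim),
                   tolerance = 4 * sd(sim) / sqrt(2000) / max(mean(sim), 1))
      expect_equal(ma$variance, var(sim), tolerance = 0.15)
    }
  })
})

test_that("the 90%/10% classifier boundaries are inclusive", {
  agg <- shared_packing(100)
  frac_class <- function(k) {
    states <- rep("NEG", 100)
    withr::with_seed(17, states[sample(100, k)] <- "POS")
    as.character(classify_pattern(with_states(agg, states)))
  }
  expect_equal(frac_class(90), "oct4_pos")
  expect_equal(frac_class(100), "oct4_pos")
  expect_equal(frac_class(10), "oct4_neg")
  expect_equal(frac_class(0), "oct4_neg")
  expect_false(frac_class(89) %in% c("oct4_pos", "oct4_neg"))
  expect_false(frac_class(11) %in% c("oct4_pos", "oct4_neg"))
})

test_that("canonical fixtures classify to their designed patterns", {
  expect_equal(as.character(classify_pattern(
    make_fixture("shell_inside_out", n = 300, seed = 41))), "inside_out")
  expect_equal(as.character(classify_pattern(
    make_fixture("shell_outside_in", n = 300, seed = 41))), "outside_in")
  expect_equal(as.character(classify_pattern(
    make_fixture("two_blob_connected", n = 300, seed = 41))), "connected")
  expect_equal(as.character(classify_pattern(
    make_fixture("uniform_state", n = 100, seed = 41))), "oct4_pos")
  expect_equal(as.character(classify_pattern(
    make_fixture("uniform_state", n = 100, seed = 41,
                 uniform = "NEG"))), "oct4_neg")
})

test_that("iid checkerboard states classify as random with high probability", {
  agg <- shared_packing(250)
  cls <- withr::with_seed(23, {
    vapply(1:40, function(k) {
      states <- ifelse(runif(250) < 0.5, "POS", "NEG")
      as.character(classify_pattern(with_states(agg, states)))
    }, character(1))
  })
  expect_gte(mean(cls == "random"), 0.8)
})

test_that("classification is invariant to rigid motions", {
  fx <- make_fixture("shell_inside_out", n = 200, seed = 13)
  base <- classify_pattern(fx)
  th <- 1.1
  rot <- fx
  rot$cells$x <- cos(th) * fx$cells$x - sin(th) * fx$cells$y + 200
  rot$cells$y <- sin(th) * fx$cells$x + cos(th) * fx$cells$y - 50
  rot <- build_contact_graph(rot)
  expect_equal(classify_pattern(rot), base)
})

test_that("normalised time and trajectory resampling behave", {
  agg <- shared_packing(100)
  tr <- simulate_states(agg, rule_params("random", alpha = 0.05),
                        seed = 2)
  tau <- normalize_time(tr)
  k <- max(tr$step)
  expect_equal(tau, tr$step / k)
  expect_equal(tau[length(tau)], 1)
  # nearest-step resampling preserves the endpoints
  rs <- ebsim:::resample_trajectory(tr, c(0, 0.5, 1))
  expect_equal(rs$step[1], 0)
  expect_equal(rs$step[3], k)
})

test_that("trajectory summaries aggregate replicate variance", {
  agg <- shared_packing(100)
  tr <- simulate_states(agg, rule_params("competing_feedback"), seed = 4)
  # identical replicates: zero variance everywhere
  s0 <- summarize_trajectories(list(tr, tr))
  expect_true(all(s0$ucn_var == 0))
  expect_equal(unname(attr(s0, "cumulative_variance")), c(0, 0))

  # constant offset c between two runs: sample variance c^2 / 2 per point
  tr2 <- tr
  tr2$ucn <- tr$ucn + 3
  s1 <- summarize_trajectories(list(tr, tr2), grid = seq(0, 1, 0.1))
  expect_true(all(abs(s1$ucn_var - 9 / 2) < 1e-12))
  expect_equal(attr(s1, "cumulative_variance")[["ucn"]], 11 * 9 / 2)
  expect_error(summarize_trajectories(list(tr)), "at least 2")
})

test_that("pattern distributions are normalised stacked fractions", {
  df <- tibble::tibble(
    tau = rep(c(0.2, 0.5), each = 4),
    class = factor(c("oct4_pos", "oct4_pos", "random", "connected",
                     "connected", "connected", "random", "oct4_neg"),
                   levels = ebsim:::pattern_levels))
  pd <- pattern_distribution(df)
  sums <- tapply(pd$fraction, pd$tau, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(pd$fraction[pd$tau == 0.2 & pd$class == "oct4_pos"], 0.5)
  # degenerate single-class input
  one <- tibble::tibble(tau = 0.3, class = "random")
  pd1 <- pattern_distribution(one)
  expect_equal(pd1$fraction[pd1$class == "random"], 1)
})
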