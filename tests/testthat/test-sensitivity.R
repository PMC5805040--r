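test_that("one-way sweep of hospitalization reproduces published endpoints", {
  tor <- tornado(td_parameters())
  hosp <- dplyr::filter(tor, parameter == "p_hospitalization")
  expect_equal(round_half_up(hosp$low_output), 82)
  expect_equal(round_half_up(hosp$high_output), 190)
  expect_equal(tor$parameter[1], "p_hospitalization") # largest swing
  expect_true(all(diff(tor$swing) <= 0))
  expect_equal(round_half_up(attr(tor, "base_output")), 115)
  expect_equal(attr(tor, "base_output"), 114.7, tolerance = 5e-3)
})

test_that("a point-mass parameter set has zero tornado swing everywhere", {
  set.seed(3)
  tor <- tornado(random_parameter_set(), top_k = Inf)
  expect_equal(tor$swing, rep(0, nrow(tor)))
})

test_that("sampled parameter sets are valid and reproduce triangular moments", {
  ps <- td_parameters()
  set.seed(11)
  for (i in 1:25) {
    s <- sample_parameter_set(ps)
    expect_true(all(validate_parameters(s)$pass))
  }
  # unnormalized triangular draw: empirical mean within 3 SE of (a+m+b)/3
  set.seed(12)
  n <- 1e5
  draws <- tdcea:::sample_draws(ps, n)
  m_th <- (2325 + 2907 + 3488) / 3
  se <- triangular_sd(2325, 2907, 3488) / sqrt(n)
  expect_lt(abs(mean(draws$cost_hospital) - m_th), 3 * se)
  # normal draws honor truncation support
  expect_true(all(draws$monthly_incidence >= 0 &
                    draws$monthly_incidence <= 1))
  expect_true(all(draws$ddl_suboptimal >= 0))
  # sibling groups renormalized to exactly one
  expect_equal(draws$p_no_mh + draws$p_mh_treatment +
                 draws$p_hospitalization + draws$p_medevac,
               rep(1, n), tolerance = 1e-12)
  expect_equal(draws$p_suboptimal + draws$p_optimal + draws$p_bedrest,
               rep(1, n), tolerance = 1e-12)
})

test_that("a fully point-mass set samples to itself", {
  ps <- point_mass_params(td_parameters())
  set.seed(5)
  s <- sample_parameter_set(ps)
  expect_equal(s$value, ps$value, tolerance = 1e-12)
})

test_that("PSA runs are seed-deterministic and order-free", {
  ps <- td_parameters()
  grid <- td_scenario_grid()
  a <- run_psa(ps, grid, n_iterations = 300, seed = 42)
  b <- run_psa(ps, grid, n_iterations = 300, seed = 42)
  expect_identical(a, b)
  # common draws make each scenario row independent of grid composition
  solo <- run_psa(ps, grid[6, ], n_iterations = 300, seed = 42)
  expect_equal(tibble::as_tibble(solo), tibble::as_tibble(a[6, ]))
})

test_that("point-mass degeneration collapses the PSA onto Table-shaped values", {
  ps <- point_mass_params(td_parameters())
  psa <- run_psa(ps, n_iterations = 50, seed = 9)
  det <- run_scenarios(td_parameters())[-1, ]
  expect_equal(psa$ddl_averted_median, det$ddl_averted, tolerance = 1e-9)
  expect_equal(psa$cer_median, det$cer, tolerance = 1e-9)
  expect_equal(psa$ddl_averted_q3 - psa$ddl_averted_q1, rep(0, 9))
  expect_equal(psa$cer_q3 - psa$cer_q1, rep(0, 9))
})

test_that("the vectorized PSA evaluator agrees with the tree evaluator", {
  set.seed(21)
  for (i in 1:10) {
    ps <- random_parameter_set()
    v <- tdcea:::params_as_values(ps)
    v <- lapply(v, rep, 2)
    ev_vec <- tdcea:::eval_values(v)
    pe <- expected_per_episode(build_tree(ps))
    expect_equal(ev_vec$cost, rep(pe$cost_per_episode, 2))
    expect_equal(ev_vec$ddl, rep(pe$ddl_per_episode, 2))
  }
})

test_that("scenario application on sampled draws conserves branch mass", {
  set.seed(31)
  draws <- tdcea:::sample_draws(td_parameters(), 500)
  for (s in list(td_scenario("hcsb", hcsb_level = 0.7),
                 td_scenario("opb", opb_level = 0.85),
                 td_scenario("combination", hcsb_level = 0.4,
                             opb_level = 0.65))) {
    v <- tdcea:::apply_scenario_values(draws, s$strategy, s$hcsb_level,
                                       s$opb_level)
    expect_equal(v$p_no_mh + v$p_mh_treatment + v$p_hospitalization +
                   v$p_medevac, rep(1, 500), tolerance = 1e-12)
    expect_equal(v$p_suboptimal + v$p_optimal + v$p_bedrest,
                 rep(1, 500), tolerance = 1e-12)
    expect_true(all(v$p_no_mh >= 0 & v$p_suboptimal >= 0))
  }
})

test_that("PSA medians are stable as iterations grow", {
  ps <- td_parameters()
  scen <- td_scenario("opb", opb_level = 0.85)
  m3k <- vapply(1:5, function(s) {
    run_psa(ps, scen, n_iterations = 3000, seed = s)$ddl_averted_median
  }, numeric(1))
  m30k <- run_psa(ps, scen, n_iterations = 30000, seed = 99)$ddl_averted_median
  expect_lt(abs(m30k - mean(m3k)), max(m3k) - min(m3k))
})
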