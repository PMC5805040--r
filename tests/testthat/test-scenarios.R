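test_that("the outpatient pool splits to the published one-decimal mixes", {
  expect_equal(opb_split(0.65), tibble::tibble(p_suboptimal = 0.220,
                                               p_optimal = 0.409))
  expect_equal(opb_split(0.75), tibble::tibble(p_suboptimal = 0.157,
                                               p_optimal = 0.472))
  # the base-case optimal:suboptimal ratio is 55.8%
  expect_equal(opb_split(0.558), tibble::tibble(p_suboptimal = 0.278,
                                                p_optimal = 0.351))
})

test_that("scenario transforms override exactly the targeted parameters", {
  base <- td_parameters()

  hcsb <- apply_scenario(base, td_scenario("hcsb", hcsb_level = 0.70))
  expect_equal(param_value(hcsb, "p_mh_treatment"), 0.70)
  expect_equal(param_value(hcsb, "p_no_mh"), 0.2907)
  expect_equal(param_value(hcsb, c("ddl_optimal", "ddl_bedrest")),
               c(0.31, 1.41))
  expect_equal(param_value(hcsb, "cost_optimal"), 82)

  opb <- apply_scenario(base, td_scenario("opb", opb_level = 0.85))
  expect_equal(param_value(opb, c("p_suboptimal", "p_optimal")),
               c(0.094, 0.535))
  expect_equal(param_value(opb, c("cost_optimal", "ddl_optimal",
                                  "ddl_bedrest")), c(30, 0.33, 0.88))
  expect_equal(param_value(opb, "p_mh_treatment"), 0.30)

  comb <- apply_scenario(base,
                         td_scenario("combination", hcsb_level = 0.70,
                                     opb_level = 0.85))
  expect_equal(param_value(comb, c("ddl_optimal", "ddl_bedrest")),
               c(0.11, 0.69))

  # cohort, hospitalization/medevac and self-care parameters never move
  untouched <- c("deployment_size", "duration_months", "monthly_incidence",
                 "p_hospitalization", "p_medevac", "cost_hospital",
                 "cost_medevac", "p_run_course", "p_self_success",
                 "p_self_failure", "cost_self_failure")
  for (ps in list(hcsb, opb, comb)) {
    expect_equal(param_value(ps, untouched), param_value(base, untouched))
    expect_true(all(validate_parameters(ps)$pass))
  }
})

test_that("scenario specs reject missing or out-of-range levels", {
  expect_error(td_scenario("hcsb"), "hcsb_level required")
  expect_error(td_scenario("combination", hcsb_level = 0.4), "opb_level")
  expect_error(td_scenario("opb", opb_level = 1.2), "\\(0, 1\\)")
  expect_error(td_scenario("base", hcsb_level = 0.4), "no levels")
})

test_that("the nine scenarios reproduce the published annual DDL exactly", {
  comp <- run_scenarios(td_parameters())
  expect_equal(round_half_up(comp$total_ddl),
               c(25918, 27101, 30958, 34816, 21326, 20973, 20619,
                 19584, 19590, 19031))
  expect_equal(round_half_up(comp$ddl_averted[-1]),
               c(-1183, -5041, -8898, 4592, 4945, 5299, 6333, 6328, 6887))
})

test_that("scenario costs agree with the published totals within 0.2%", {
  comp <- run_scenarios(td_parameters())
  printed <- c(2974311, 3403120, 4046333, 4689547, 2660662, 2622427,
               2584192, 2988061, 3405534, 3784775)
  expect_true(all(abs(comp$total_cost - printed) / printed < 0.002))
})

test_that("DDL responds monotonically to the implementation level", {
  base <- td_parameters()
  opb_ddl <- vapply(
    c(0.60, 0.65, 0.70, 0.75, 0.80, 0.85),
    function(l) evaluate_model(apply_scenario(base, td_scenario("opb", opb_level = l)))$total_ddl,
    numeric(1)
  )
  expect_true(all(diff(opb_ddl) < 0))
  hcsb_ddl <- vapply(
    c(0.35, 0.40, 0.55, 0.70),
    function(l) evaluate_model(apply_scenario(base, td_scenario("hcsb", hcsb_level = l)))$total_ddl,
    numeric(1)
  )
  expect_true(all(diff(hcsb_ddl) > 0))
})

test_that("comparing a scenario with itself leaves the CER undefined", {
  ev <- evaluate_model(td_parameters())
  expect_warning(res <- compare_evaluations(ev, ev), "undefined")
  expect_equal(res$cost_difference, 0)
  expect_equal(res$ddl_averted, 0)
  expect_true(is.na(res$cer))
})

test_that("the CER carries the cost-difference sign over |DDL| change", {
  comp <- run_scenarios(td_parameters())
  hcsb <- dplyr::filter(comp, strategy == "hcsb")
  expect_true(all(hcsb$ddl_averted < 0 & hcsb$cer > 0)) # $/DDL-gained
  opb <- dplyr::filter(comp, strategy == "opb")
  expect_true(all(opb$ddl_averted > 0 & opb$cer < 0)) # cost-saving
  expect_equal(comp$cer[-1],
               comp$cost_difference[-1] / abs(comp$ddl_averted[-1]))
})

test_that("the report table is metric-by-scenario with rounded cells", {
  comp <- run_scenarios(td_parameters())
  tab <- scenario_table(comp)
  expect_equal(tab$metric[1], "Annual episodes")
  expect_equal(ncol(tab), 11) # metric column + base + nine scenarios
  expect_equal(unname(unlist(tab[tab$metric == "Duty days lost (DDL)/yr", -1])),
               c(25918, 27101, 30958, 34816, 21326, 20973, 20619,
                 19584, 19590, 19031))
  expect_true(all(is.na(unlist(tab[tab$metric == "DDL-averted", "Base case"]))))
})
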