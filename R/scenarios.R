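# Fixed scenario overrides. The HCSB strategy shortens the pre-treatment
# delay from 1.5 days to about 8 hours, which lowers the optimal-care and
# bed-rest DDL outcomes; OPB switches optimal care to single-dose antibiotic
# plus loperamide delivered largely by medics ($30 blended cost, 15 h
# post-treatment TLUS, 12 h bed rest); the combination compounds both
# duration reductions. Values chosen are the ones consistent with the
# scenario DDL totals (see the methods vignette for the reconciliation).
scenario_overrides <- list(
  hcsb = list(ddl_optimal = 0.31, ddl_bedrest = 1.41),
  opb = list(cost_optimal = 30, ddl_optimal = 0.33, ddl_bedrest = 0.88),
  combination = list(cost_optimal = 30, ddl_optimal = 0.11, ddl_bedrest = 0.69)
)

scenario_label <- function(strategy, hcsb_level, opb_level) {
  pct <- function(x) paste0(round_half_up(100 * x), "%")
  switch(strategy,
    base = "Base case",
    hcsb = paste("HCSB", pct(hcsb_level)),
    opb = paste("OPB", pct(opb_level)),
    combination = paste("Combination", pct(hcsb_level), "/", pct(opb_level))
  )
}

#' Define a management-strategy scenario
#'
#' A scenario is one of four strategies: `"base"` (no change), `"hcsb"`
#' (increased health-care-seeking behavior: a larger share of ill service
#' members seeks military-healthcare treatment, earlier), `"opb"` (optimized
#' provider behavior: providers shift outpatient care toward single-dose
#' antibiotic plus loperamide), or `"combination"` (both). `hcsb_level` is the
#' post-intervention probability of treatment by a military healthcare
#' provider; `opb_level` is the optimal:suboptimal prescribing ratio.
#'
#' @param strategy One of `"base"`, `"hcsb"`, `"opb"`, `"combination"`.
#' @param hcsb_level Probability in (0, 1); required for `hcsb` and
#'   `combination`.
#' @param opb_level Ratio in (0, 1); required for `opb` and `combination`.
#' @return A one-row tibble with columns `strategy`, `hcsb_level`,
#'   `opb_level`, `label`.
#' @examples
#' td_scenario("opb", opb_level = 0.85)
#' @export
td_scenario <- function(strategy = c("base", "hcsb", "opb", "combination"),
                        hcsb_level = NULL, opb_level = NULL) {
  strategy <- match.arg(strategy)
  needs_hcsb <- strategy %in% c("hcsb", "combination")
  needs_opb <- strategy %in% c("opb", "combination")
  if (needs_hcsb && is.null(hcsb_level)) {
    stop("hcsb_level required for strategy '", strategy, "'", call. = FALSE)
  }
  if (needs_opb && is.null(opb_level)) {
    stop("opb_level required for strategy '", strategy, "'", call. = FALSE)
  }
  if (strategy == "base" && (!is.null(hcsb_level) || !is.null(opb_level))) {
    stop("base scenario takes no levels", call. = FALSE)
  }
  chk <- function(x, nm) {
    if (!is.null(x) && (x <= 0 || x >= 1)) {
      stop(nm, " must lie in (0, 1)", call. = FALSE)
    }
  }
  chk(hcsb_level, "hcsb_level")
  chk(opb_level, "opb_level")
  tibble::tibble(
    strategy = strategy,
    hcsb_level = if (needs_hcsb) hcsb_level else NA_real_,
    opb_level = if (needs_opb) opb_level else NA_real_,
    label = scenario_label(strategy, hcsb_level, opb_level)
  )
}

#' Standard grid of the nine modeled scenario levels
#'
#' Three implementation levels per strategy: health-care seeking raised to
#' 40/55/70%, the optimal:suboptimal prescribing ratio raised to 65/75/85%,
#' and the combination pairing them level-for-level.
#'
#' @param hcsb_levels,opb_levels Numeric vectors of equal length.
#' @return A tibble of scenarios (one row each), suitable for
#'   [run_scenarios()] and [run_psa()].
#' @examples
#' td_scenario_grid()
#' @export
td_scenario_grid <- function(hcsb_levels = c(0.40, 0.55, 0.70),
                             opb_levels = c(0.65, 0.75, 0.85)) {
  stopifnot(length(hcsb_levels) == length(opb_levels))
  dplyr::bind_rows(
    purrr::map(hcsb_levels, ~ td_scenario("hcsb", hcsb_level = .x)),
    purrr::map(opb_levels, ~ td_scenario("opb", opb_level = .x)),
    purrr::map2(hcsb_levels, opb_levels,
                ~ td_scenario("combination", hcsb_level = .x, opb_level = .y))
  )
}

#' Split the outpatient therapeutic pool by an optimal:suboptimal ratio
#'
#' The OPB strategy fixes the share of outpatient encounters receiving
#' optimal (antibiotic + loperamide) versus suboptimal (symptomatic-only)
#' care. The therapeutic pool excludes bed rest: for the baseline outpatient
#' mix it is `1 - 0.371 = 0.629`. The optimal share is `level * pool`,
#' rounded half-up to three decimals so the resulting probabilities match
#' one-decimal percentage reporting; the suboptimal share takes the
#' remainder, which conserves the pool exactly.
#'
#' @param level Optimal:suboptimal ratio in (0, 1).
#' @param pool Therapeutic pool mass (default the baseline 0.629).
#' @return A one-row tibble with columns `p_suboptimal`, `p_optimal`.
#' @examples
#' opb_split(0.85)
#' opb_split(0.558) # reproduces the baseline 27.8% / 35.1% mix
#' @export
opb_split <- function(level, pool = 0.629) {
  stopifnot(level > 0, level < 1, all(pool > 0))
  p_opt <- round_half_up(level * pool, 3)
  tibble::tibble(p_suboptimal = pool - p_opt, p_optimal = p_opt)
}

# Scenario transformation on a named list of (possibly vector) parameter
# values; shared by apply_scenario() and the PSA. The HCSB shift moves
# probability mass from the no-treatment arm into the treated arm so the
# disposition group total is conserved for any starting values.
apply_scenario_values <- function(v, strategy, hcsb_level = NA, opb_level = NA) {
  if (strategy == "base") return(v)
  if (strategy %in% c("hcsb", "combination")) {
    delta <- hcsb_level - v$p_mh_treatment
    v$p_mh_treatment <- v$p_mh_treatment + delta
    v$p_no_mh <- v$p_no_mh - delta
    if (any(v$p_no_mh < 0 | v$p_no_mh > 1)) {
      stop("HCSB shift pushes p_no_mh outside [0, 1]", call. = FALSE)
    }
  }
  if (strategy %in% c("opb", "combination")) {
    pool <- v$p_suboptimal + v$p_optimal
    split <- opb_split(opb_level, pool = pool)
    v$p_suboptimal <- split$p_suboptimal
    v$p_optimal <- split$p_optimal
    if (any(v$p_suboptimal < 0 | v$p_suboptimal > 1)) {
      stop("OPB split pushes p_suboptimal outside [0, 1]", call. = FALSE)
    }
  }
  for (nm in names(scenario_overrides[[strategy]])) {
    v[[nm]] <- scenario_overrides[[strategy]][[nm]]
  }
  v
}

#' Apply a management scenario to a parameter set
#'
#' Returns a modified copy of `params` with the scenario's parameter
#' overrides: the HCSB strategy raises `p_mh_treatment` to its level with a
#' complementary reduction of `p_no_mh` (group mass conserved) and shortens
#' the optimal-care and bed-rest DDL outcomes; OPB re-splits the outpatient
#' therapeutic pool via [opb_split()], sets the blended optimal-care cost of
#' $30, and shortens optimal-care and bed-rest DDL; the combination applies
#' both probability shifts with its own, further reduced, DDL outcomes.
#' Hospitalization, medevac, self-care and cohort parameters are never
#' touched.
#'
#' @param params A `td_params` tibble (the base parameter set).
#' @param scenario A one-row scenario tibble from [td_scenario()] (or one row
#'   of [td_scenario_grid()]).
#' @return The transformed `td_params` tibble.
#' @examples
#' ps <- apply_scenario(td_parameters(), td_scenario("hcsb", hcsb_level = 0.7))
#' param_value(ps, "p_no_mh") # 0.2907
#' @export
apply_scenario <- function(params, scenario) {
  stopifnot(is.data.frame(scenario), nrow(scenario) == 1)
  v <- apply_scenario_values(params_as_values(params), scenario$strategy,
                             scenario$hcsb_level, scenario$opb_level)
  changed <- names(v)[!purrr::map2_lgl(v, params_as_values(params), identical)]
  if (length(changed)) {
    params <- set_param_values(params, !!!v[changed])
    # scenario overrides define a new point estimate; keep bounds consistent
    params$low <- pmin(params$low, params$value)
    params$high <- pmax(params$high, params$value)
  }
  params
}

#' Compare a scenario evaluation against the base case
#'
#' Computes the two primary outcome measures: `ddl_averted = base - scenario`
#' total DDL (negative values are DDL-gained), and the cost-effectiveness
#' ratio `cer = cost_difference / |ddl_averted|`. The sign convention keeps
#' the cost difference's sign: a scenario that gains DDL at extra cost has a
#' positive $/DDL-gained CER, while a cost-saving, DDL-averting scenario has
#' a negative CER.
#'
#' @param base,scenario One-row `td_eval` tibbles from [evaluate_model()],
#'   computed on the same cohort.
#' @return A one-row tibble with columns `cost_difference`, `ddl_averted`,
#'   `cer`. When `ddl_averted` is exactly zero the CER is undefined: `NA`
#'   with a warning.
#' @export
compare_evaluations <- function(base, scenario) {
  cost_difference <- scenario$total_cost - base$total_cost
  ddl_averted <- base$total_ddl - scenario$total_ddl
  if (ddl_averted == 0) {
    warning("ddl_averted is zero; CER undefined", call. = FALSE)
    cer <- NA_real_
  } else {
    cer <- cost_difference / abs(ddl_averted)
  }
  tibble::tibble(cost_difference = cost_difference,
                 ddl_averted = ddl_averted, cer = cer)
}

#' Evaluate a set of scenarios against the base case
#'
#' Runs the deterministic model for the base case and every scenario in the
#' grid, returning one row per scenario (base case first) with full-precision
#' outcome columns. Use [scenario_table()] for the rounded, report-shaped
#' view.
#'
#' @param params The base `td_params` tibble.
#' @param scenarios A scenario tibble, default [td_scenario_grid()].
#' @return A tibble of class `td_comparison` with columns `label`, `strategy`,
#'   `hcsb_level`, `opb_level`, `episodes`, `total_cost`, `total_ddl`,
#'   `cost_ratio`, `cost_difference`, `ddl_averted`, `cer` (the base row has
#'   `NA` comparison columns).
#' @examples
#' run_scenarios(td_parameters())
#' @export
run_scenarios <- function(params, scenarios = td_scenario_grid()) {
  assert_valid_params(params)
  base_eval <- evaluate_model(params)
  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, ]
    ev <- evaluate_model(apply_scenario(params, s))
    dplyr::bind_cols(s[, c("label", "strategy", "hcsb_level", "opb_level")],
                     ev, compare_evaluations(base_eval, ev))
  })
  base_row <- dplyr::bind_cols(
    tibble::tibble(label = "Base case", strategy = "base",
                   hcsb_level = NA_real_, opb_level = NA_real_),
    base_eval,
    tibble::tibble(cost_difference = NA_real_, ddl_averted = NA_real_,
                   cer = NA_real_)
  )
  out <- dplyr::bind_rows(base_row, rows)
  class(out) <- unique(c("td_comparison", class(out)))
  out
}

#' Report-shaped scenario outcome table
#'
#' Pivots a [run_scenarios()] result into the conventional display layout:
#' one row per outcome metric, one column per scenario, integers rounded half
#' away from zero. Keep the `td_comparison` tibble itself for full-precision
#' values.
#'
#' @param comparison A `td_comparison` tibble.
#' @return A tibble with a `metric` column followed by one column per
#'   scenario label.
#' @examples
#' scenario_table(run_scenarios(td_parameters()))
#' @export
scenario_table <- function(comparison) {
  long <- comparison |>
    dplyr::transmute(
      .data$label,
      `Annual episodes` = round_half_up(.data$episodes),
      `Scenario total cost` = round_half_up(.data$total_cost),
      `Cost difference with base case` = round_half_up(.data$cost_difference),
      `Duty days lost (DDL)/yr` = round_half_up(.data$total_ddl),
      `DDL-averted` = round_half_up(.data$ddl_averted),
      `Cost ratio ($/DDL)` = round_half_up(.data$cost_ratio),
      `CER ($/DDL-averted or gained)` = round_half_up(.data$cer)
    ) |>
    tidyr::pivot_longer(-"label", names_to = "metric", values_to = "value")
  tidyr::pivot_wider(long, names_from = "label", values_from = "value")
}
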