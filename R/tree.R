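# Leaf order is fixed; reports and simulations index pathways by this order.
td_leaf_labels <- c(
  "outpatient_suboptimal", "outpatient_optimal", "outpatient_bedrest",
  "no_tx_run_course", "no_tx_self_success", "no_tx_self_failure",
  "hospitalization", "medevac"
)

# Expected per-episode cost and DDL from parameter values given as a named
# list of equal-length numeric vectors. Single implementation shared by the
# scalar evaluator and the vectorized PSA; the tree route in
# expected_per_episode() is an independent computation used to cross-check it.
eval_values <- function(v) {
  outpatient_cost <- v$p_suboptimal * v$cost_suboptimal +
    v$p_optimal * v$cost_optimal + v$p_bedrest * v$cost_bedrest
  outpatient_ddl <- v$p_suboptimal * v$ddl_suboptimal +
    v$p_optimal * v$ddl_optimal + v$p_bedrest * v$ddl_bedrest
  selfcare_cost <- v$p_self_failure * v$cost_self_failure
  selfcare_ddl <- v$p_run_course * v$ddl_run_course +
    v$p_self_success * v$ddl_self_success +
    v$p_self_failure * v$ddl_self_failure
  list(
    cost = v$p_mh_treatment * outpatient_cost + v$p_no_mh * selfcare_cost +
      v$p_hospitalization * v$cost_hospital + v$p_medevac * v$cost_medevac,
    ddl = v$p_mh_treatment * outpatient_ddl + v$p_no_mh * selfcare_ddl +
      v$p_hospitalization * v$ddl_hospital + v$p_medevac * v$ddl_medevac
  )
}

params_as_values <- function(params) {
  stats::setNames(as.list(params$value), params$name)
}

#' Build the eight-leaf care-pathway decision tree
#'
#' Converts a parameter set into the terminal outcomes of the decision tree:
#' three outpatient leaves (suboptimal care, optimal care, bed rest) under
#' military-healthcare treatment, three self-care leaves (run its course,
#' self-treatment success, self-treatment failure) under no treatment, plus
#' hospitalization and medevac as top-level dispositions. Each leaf carries
#' its unconditional path probability, per-episode cost (USD), and per-episode
#' duty days lost. Run-its-course and self-treatment success incur no cost to
#' the military healthcare system; self-treatment failure is a terminal,
#' costed outcome.
#'
#' @param params A `td_params` tibble; must pass [validate_parameters()]
#'   unless `validate = FALSE` (used internally by the one-way sensitivity
#'   sweep, which deliberately breaks group sums).
#' @param validate Check the parameter set first (default `TRUE`).
#' @return A tibble of class `td_tree` with columns `leaf`, `branch`,
#'   `path_probability`, `unit_cost`, `unit_ddl`; path probabilities sum to
#'   one for any valid parameter set.
#' @examples
#' build_tree(td_parameters())
#' @export
build_tree <- function(params, validate = TRUE) {
  if (validate) assert_valid_params(params)
  v <- params_as_values(params)
  tree <- tibble::tibble(
    leaf = td_leaf_labels,
    branch = c(rep("outpatient", 3), rep("no_treatment", 3),
               "hospitalization", "medevac"),
    path_probability = c(
      v$p_mh_treatment * c(v$p_suboptimal, v$p_optimal, v$p_bedrest),
      v$p_no_mh * c(v$p_run_course, v$p_self_success, v$p_self_failure),
      v$p_hospitalization, v$p_medevac
    ),
    unit_cost = c(v$cost_suboptimal, v$cost_optimal, v$cost_bedrest,
                  0, 0, v$cost_self_failure, v$cost_hospital, v$cost_medevac),
    unit_ddl = c(v$ddl_suboptimal, v$ddl_optimal, v$ddl_bedrest,
                 v$ddl_run_course, v$ddl_self_success, v$ddl_self_failure,
                 v$ddl_hospital, v$ddl_medevac)
  )
  class(tree) <- unique(c("td_tree", class(tree)))
  tree
}

#' Annual episode count of travelers' diarrhea in the deployed cohort
#'
#' Episodes per deployment-year are the product of deployment size, deployment
#' duration in months, and the monthly attack rate. The unrounded value is
#' retained for all downstream arithmetic; reports round half-up at the final
#' step.
#'
#' @param params A `td_params` tibble (only the cohort rows are used).
#' @return Unrounded episode count (numeric scalar).
#' @examples
#' annual_episodes(td_parameters()) # 50575
#' @export
annual_episodes <- function(params) {
  v <- param_value(params, c("deployment_size", "duration_months",
                             "monthly_incidence"))
  prod(v)
}

#' Expected per-episode cost and duty days lost
#'
#' Expectation over the eight terminal outcomes: `sum(p_i * unit_cost_i)` and
#' `sum(p_i * unit_ddl_i)`.
#'
#' @param tree A `td_tree` tibble from [build_tree()].
#' @return A one-row tibble with columns `cost_per_episode` (USD) and
#'   `ddl_per_episode` (days).
#' @examples
#' expected_per_episode(build_tree(td_parameters()))
#' @export
expected_per_episode <- function(tree) {
  tibble::tibble(
    cost_per_episode = sum(tree$path_probability * tree$unit_cost),
    ddl_per_episode = sum(tree$path_probability * tree$unit_ddl)
  )
}

#' Evaluate the cost-of-illness model for one parameter set
#'
#' Deterministic base evaluation: annual episodes times the per-episode
#' expectations of the decision tree. The cost ratio is total management cost
#' divided by total duty days lost (USD/DDL), the base output metric of the
#' one-way sensitivity analysis.
#'
#' @inheritParams build_tree
#' @return A one-row tibble of class `td_eval` with columns `episodes`
#'   (unrounded), `total_cost` (USD/yr), `total_ddl` (days/yr), `cost_ratio`
#'   (USD per DDL).
#' @examples
#' evaluate_model(td_parameters())
#' @export
evaluate_model <- function(params, validate = TRUE) {
  tree <- build_tree(params, validate = validate)
  pe <- expected_per_episode(tree)
  n <- annual_episodes(params)
  total_ddl <- pe$ddl_per_episode * n
  if (total_ddl == 0) {
    stop("total DDL is zero; cost ratio undefined", call. = FALSE)
  }
  out <- tibble::tibble(
    episodes = n,
    total_cost = pe$cost_per_episode * n,
    total_ddl = total_ddl,
    cost_ratio = pe$cost_per_episode / pe$ddl_per_episode
  )
  class(out) <- unique(c("td_eval", class(out)))
  out
}
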