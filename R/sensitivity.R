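# Inverse-CDF draw from a triangular(a, m, b) distribution; degenerate
# (a == b) intervals return the point mass. Vectorized over u.
rtriangular <- function(n, a, m, b) {
  if (a == b) return(rep(a, n))
  u <- stats::runif(n)
  fc <- (m - a) / (b - a)
  ifelse(u < fc,
         a + sqrt(u * (b - a) * (m - a)),
         b - sqrt((1 - u) * (b - a) * (b - m)))
}

# Truncated-normal draw by rejection; out-of-support values are redrawn up to
# max_tries rounds before erroring. With sd = range/3.92 and supports that
# include the mean, rejection mass is small and one or two rounds suffice.
rnorm_trunc <- function(n, mean, sd, lower, upper, max_tries = 100) {
  x <- stats::rnorm(n, mean, sd)
  for (i in seq_len(max_tries)) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("truncated-normal sampling failed after ", max_tries, " rounds",
       call. = FALSE)
}

# n joint parameter draws as a named list of length-n vectors: every
# parameter sampled independently from param_distributions(), then each
# sibling probability group rescaled proportionally so it sums to one.
sample_draws <- function(params, n) {
  dists <- param_distributions(params)
  draws <- purrr::pmap(dists, function(name, kind, a, m, b, sd,
                                       trunc_lower, trunc_upper) {
    switch(kind,
      point = rep(m, n),
      triangular = rtriangular(n, a, m, b),
      normal = rnorm_trunc(n, m, sd, max(trunc_lower, -Inf), trunc_upper)
    )
  })
  names(draws) <- dists$name
  for (g in unique(stats::na.omit(params$group))) {
    members <- params$name[!is.na(params$group) & params$group == g]
    total <- Reduce(`+`, draws[members])
    for (nm in members) draws[[nm]] <- draws[[nm]] / total
  }
  draws
}

#' Draw one random parameter set for probabilistic sensitivity analysis
#'
#' Samples every parameter (cohort constants included) independently from its
#' distribution in [param_distributions()], then rescales each sibling
#' probability group proportionally so that it sums to one, mirroring the
#' percentage normalization of the Monte Carlo analysis. Uses the current RNG
#' state; seed outside with `set.seed()` for reproducibility.
#'
#' @param params A valid `td_params` tibble.
#' @return A `td_params` tibble whose `value` column holds the draw (bounds
#'   are widened where a normalized draw leaves the original `[low, high]`,
#'   so the returned set always validates).
#' @examples
#' set.seed(1)
#' sample_parameter_set(td_parameters())
#' @export
sample_parameter_set <- function(params) {
  assert_valid_params(params)
  v <- unlist(sample_draws(params, 1))
  out <- set_param_values(params, !!!as.list(v))
  # proportional renormalization can land just outside the elicited range
  out$low <- pmin(out$low, out$value)
  out$high <- pmax(out$high, out$value)
  out
}

#' One-way (tornado) sensitivity analysis of the base-case cost ratio
#'
#' For each parameter in turn, sets it alone to its low and then high
#' estimate — siblings are deliberately not renormalized, so branch mass may
#' transiently differ from one, the convention of spreadsheet one-way
#' sensitivity tools — and recomputes the cost ratio (USD per duty day lost).
#' Parameters are ranked by swing, the absolute difference between the two
#' outputs. Cohort parameters scale cost and DDL equally and therefore show
#' zero swing on this ratio.
#'
#' @param params A valid `td_params` tibble.
#' @param top_k Number of entries to return, by descending swing (default 10;
#'   `Inf` for all).
#' @return A tibble of class `td_tornado` with columns `parameter`, `label`,
#'   `low_output`, `high_output`, `swing`, ordered by decreasing swing, with
#'   the base-case cost ratio in attribute `base_output`.
#' @examples
#' tornado(td_parameters())
#' @export
tornado <- function(params, top_k = 10) {
  assert_valid_params(params)
  base_ratio <- evaluate_model(params)$cost_ratio
  ratio_at <- function(name, value) {
    ps <- set_param_values(params, !!!stats::setNames(list(value), name))
    evaluate_model(ps, validate = FALSE)$cost_ratio
  }
  out <- params |>
    dplyr::mutate(
      low_output = purrr::map2_dbl(.data$name, .data$low, ratio_at),
      high_output = purrr::map2_dbl(.data$name, .data$high, ratio_at),
      swing = abs(.data$high_output - .data$low_output)
    ) |>
    dplyr::transmute(parameter = .data$name, .data$label, .data$low_output,
                     .data$high_output, .data$swing) |>
    dplyr::arrange(dplyr::desc(.data$swing)) |>
    dplyr::slice_head(n = min(top_k, nrow(params)))
  attr(out, "base_output") <- base_ratio
  class(out) <- unique(c("td_tornado", class(out)))
  out
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Per iteration, one joint parameter draw (see [sample_parameter_set()]) is
#' evaluated under the base case and under each scenario — scenario overrides
#' are applied to the same draw after sampling, so base and scenario share
#' common random numbers — and the two primary outcomes, DDL-averted and the
#' cost-effectiveness ratio, are recorded. Scenario override values (e.g. the
#' $30 optimal-care cost) are fixed constants, not sampled. Each scenario's
#' outcomes are summarized by the median and interquartile range using the
#' linear-interpolation quantile convention (`stats::quantile()` type 7).
#' Iterations with exactly zero DDL-averted contribute to the DDL summaries
#' but are excluded from the CER summaries (`n_cer_excluded`).
#'
#' @param params The base `td_params` tibble.
#' @param scenarios A scenario tibble, default [td_scenario_grid()].
#' @param n_iterations Monte Carlo iterations per scenario (default 3000).
#' @param seed Integer seed; recorded in the output. `NULL` uses the current
#'   RNG state (not reproducible).
#' @param sample_cohort If `TRUE` (default) the cohort constants (deployment
#'   size, duration, monthly incidence) are sampled from their distributions
#'   like every other parameter; if `FALSE` they are held at their point
#'   estimates and only the tree parameters vary.
#' @param keep_draws If `TRUE`, attach the per-iteration outcome tibble as
#'   attribute `"draws"` for audit.
#' @return A tibble of class `td_psa`: one row per scenario with columns
#'   `label`, `strategy`, `hcsb_level`, `opb_level`, `n_iterations`, `seed`,
#'   `ddl_averted_median`, `ddl_averted_q1`, `ddl_averted_q3`, `cer_median`,
#'   `cer_q1`, `cer_q3`, `n_cer_excluded`.
#' @examples
#' run_psa(td_parameters(), td_scenario_grid()[6, ], n_iterations = 200, seed = 1)
#' @export
run_psa <- function(params, scenarios = td_scenario_grid(),
                    n_iterations = 3000, seed = NULL, sample_cohort = TRUE,
                    keep_draws = FALSE) {
  assert_valid_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (!sample_cohort) {
    i <- params$role == "cohort"
    params$low[i] <- params$value[i]
    params$high[i] <- params$value[i]
  }
  draws <- sample_draws(params, n_iterations)
  episodes <- draws$deployment_size * draws$duration_months *
    draws$monthly_incidence
  base <- eval_values(draws)
  q <- function(x, p) {
    if (!length(x)) return(NA_real_)
    unname(stats::quantile(x, p, type = 7, names = FALSE))
  }
  per_iter <- list()
  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    s <- scenarios[i, ]
    sv <- apply_scenario_values(draws, s$strategy, s$hcsb_level, s$opb_level)
    scen <- eval_values(sv)
    ddl_averted <- (base$ddl - scen$ddl) * episodes
    cost_difference <- (scen$cost - base$cost) * episodes
    nonzero <- ddl_averted != 0
    cer <- cost_difference[nonzero] / abs(ddl_averted[nonzero])
    if (keep_draws) {
      per_iter[[i]] <<- tibble::tibble(
        label = s$label, iteration = seq_len(n_iterations),
        ddl_averted = ddl_averted, cost_difference = cost_difference,
        cer = ifelse(nonzero, cost_difference / abs(ddl_averted), NA_real_)
      )
    }
    tibble::tibble(
      label = s$label, strategy = s$strategy,
      hcsb_level = s$hcsb_level, opb_level = s$opb_level,
      n_iterations = n_iterations,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      ddl_averted_median = q(ddl_averted, 0.5),
      ddl_averted_q1 = q(ddl_averted, 0.25),
      ddl_averted_q3 = q(ddl_averted, 0.75),
      cer_median = q(cer, 0.5),
      cer_q1 = q(cer, 0.25),
      cer_q3 = q(cer, 0.75),
      n_cer_excluded = sum(!nonzero)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (keep_draws) attr(out, "draws") <- dplyr::bind_rows(per_iter)
  class(out) <- unique(c("td_psa", class(out)))
  out
}
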