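#' Simulate individual travelers'-diarrhea episodes through the decision tree
#'
#' Brute-force counterpart of the deterministic expectation: each episode
#' draws one terminal pathway from the categorical distribution of leaf path
#' probabilities and accrues that leaf's unit cost and duty days lost. Costs
#' and DDL are deterministic given the pathway — the model carries no
#' within-pathway variance.
#'
#' @param params A valid `td_params` tibble.
#' @param n_episodes Number of episodes to simulate (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `td_cohort` with columns `episode_id`,
#'   `pathway`, `cost`, `ddl`, and attributes `seed` and `parameters`.
#' @seealso [summarize_cohort()], [expected_per_episode()]
#' @examples
#' simulate_cohort(td_parameters(), n_episodes = 5, seed = 42)
#' @export
simulate_cohort <- function(params, n_episodes, seed = NULL) {
  stopifnot(n_episodes >= 1)
  tree <- build_tree(params)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(tree), size = n_episodes, replace = TRUE,
                    prob = tree$path_probability)
  out <- tibble::tibble(
    episode_id = seq_len(n_episodes),
    pathway = tree$leaf[idx],
    cost = tree$unit_cost[idx],
    ddl = tree$unit_ddl[idx]
  )
  attr(out, "seed") <- seed
  attr(out, "parameters") <- params
  class(out) <- unique(c("td_cohort", class(out)))
  out
}

#' Summarize a simulated cohort into evaluation totals
#'
#' Aggregates episode records to the same shape as [evaluate_model()]:
#' episode count, total cost, total DDL, and their ratio. As the episode
#' count grows, these totals (scaled per episode) converge to the
#' deterministic tree expectations — the package's main internal consistency
#' check.
#'
#' @param cohort A `td_cohort` tibble from [simulate_cohort()].
#' @return A one-row tibble with columns `episodes`, `total_cost`,
#'   `total_ddl`, `cost_ratio`.
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  total_ddl <- sum(cohort$ddl)
  if (total_ddl == 0) {
    stop("total DDL is zero; cost ratio undefined", call. = FALSE)
  }
  tibble::tibble(
    episodes = nrow(cohort),
    total_cost = sum(cohort$cost),
    total_ddl = total_ddl,
    cost_ratio = sum(cohort$cost) / total_ddl
  )
}

#' Generate a random valid parameter set
#'
#' Property-test fixture generator: sibling probability groups are drawn from
#' a uniform simplex (symmetric Dirichlet with unit concentration), costs
#' log-uniformly in [1, 20000] USD, DDL uniformly in [0, 10] days, and cohort
#' constants uniformly within their default elicitation ranges. Bounds are
#' collapsed to the drawn value (`low == value == high`, point
#' distributions), so the returned set always passes
#' [validate_parameters()]. Uses the current RNG state; seed outside with
#' `set.seed()`.
#'
#' @return A `td_params` tibble.
#' @examples
#' set.seed(7)
#' all(validate_parameters(random_parameter_set())$pass)
#' @export
random_parameter_set <- function() {
  params <- td_parameters()
  v <- params_as_values(params)
  for (g in unique(stats::na.omit(params$group))) {
    members <- params$name[!is.na(params$group) & params$group == g]
    e <- -log(stats::runif(length(members)))
    v[members] <- as.list(e / sum(e))
  }
  for (nm in params$name[params$role == "cost_usd"]) {
    v[[nm]] <- exp(stats::runif(1, log(1), log(20000)))
  }
  for (nm in params$name[params$role == "ddl_days"]) {
    v[[nm]] <- stats::runif(1, 0, 10)
  }
  for (nm in params$name[params$role == "cohort"]) {
    i <- match(nm, params$name)
    v[[nm]] <- stats::runif(1, params$low[i], params$high[i])
  }
  params <- set_param_values(params, !!!v)
  params$low <- params$value
  params$high <- params$value
  params$dist <- "point"
  params
}
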