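#' Default parameter set for the deployment TD cost-of-illness model
#'
#' Returns the baseline parameter table of the decision-tree model: cohort
#' constants (deployment size, deployment duration, monthly incidence of
#' travelers' diarrhea), the branch probabilities of the eight-leaf care
#' pathway tree, per-episode treatment costs (USD), and per-episode duty days
#' lost (DDL). Each parameter carries a point estimate (`value`), low/high
#' bounds, and the distribution kind used by the probabilistic sensitivity
#' analysis (`"triangular"` or `"normal"`; parameters with `low == high` are
#' treated as point masses).
#'
#' Probabilities belong to sibling groups that must sum to one:
#' * `disposition` — medical disposition of an episode: no military-healthcare
#'   (MH) treatment, MH outpatient treatment, hospitalization, medevac.
#' * `outpatient` — suboptimal care, optimal (antibiotic) care, bed rest,
#'   conditional on MH outpatient treatment.
#' * `selfcare` — run its course, self-treatment success, self-treatment
#'   failure, conditional on no MH treatment.
#'
#' @param ... Named point-estimate overrides, e.g.
#'   `td_parameters(p_bedrest = 0.5)`. Only the `value` column is changed;
#'   bounds are untouched, so overrides outside `[low, high]` will be flagged
#'   by [validate_parameters()].
#'
#' @return A tibble of class `td_params` with columns `name`, `label`, `role`
#'   (`cohort`, `probability`, `cost_usd`, `ddl_days`), `group`, `value`,
#'   `low`, `high`, `dist`.
#' @seealso [validate_parameters()], [param_distributions()], [build_tree()]
#' @examples
#' ps <- td_parameters()
#' param_value(ps, "cost_hospital")
#' @export
td_parameters <- function(...) {
  p <- tibble::tribble(
    ~name, ~label, ~role, ~group, ~value, ~low, ~high, ~dist,
    "deployment_size", "Yearly deployment size", "cohort", NA_character_,
      50000, 35000, 80000, "triangular",
    "duration_months", "Deployment duration (months)", "cohort", NA_character_,
      3.5, 1, 12, "triangular",
    "monthly_incidence", "Monthly incidence of TD", "cohort", NA_character_,
      0.289, 0.162, 0.416, "normal",
    "p_no_mh", "[P] of no MH provider rx | illness", "probability", "disposition",
      0.6907, 0.68, 0.87, "triangular",
    "p_run_course", "[P] no self-treatment (run its course)", "probability", "selfcare",
      0.60, 0.30, 0.90, "triangular",
    "p_self_success", "[P] self-treatment success", "probability", "selfcare",
      0.32, 0.16, 0.48, "triangular",
    "p_self_failure", "[P] self-treatment failure", "probability", "selfcare",
      0.08, 0.04, 0.12, "triangular",
    "p_medevac", "[P] medical evacuation", "probability", "disposition",
      0.0003, 0.0002, 0.0004, "triangular",
    "p_mh_treatment", "[P] of treatment by MH provider | illness", "probability", "disposition",
      0.30, 0.13, 0.42, "triangular",
    "p_suboptimal", "[P] suboptimal outpatient care", "probability", "outpatient",
      0.278, 0.16, 0.51, "triangular",
    "p_optimal", "[P] optimal outpatient care", "probability", "outpatient",
      0.351, 0.27, 0.57, "triangular",
    "p_bedrest", "[P] confinement to bed rest (SIQ)", "probability", "outpatient",
      0.371, 0.13, 0.47, "triangular",
    "p_hospitalization", "[P] hospitalization", "probability", "disposition",
      0.009, 0.003, 0.024, "triangular",
    "cost_medevac", "Cost: medical evacuation", "cost_usd", NA_character_,
      16938, 13550, 20326, "triangular",
    "cost_hospital", "Cost: hospitalization (deployed)", "cost_usd", NA_character_,
      2907, 2325, 3488, "triangular",
    "cost_bedrest", "Cost: confinement to bed rest", "cost_usd", NA_character_,
      104, 84, 125, "triangular",
    "cost_suboptimal", "Cost: suboptimal care", "cost_usd", NA_character_,
      70, 56, 84, "triangular",
    "cost_optimal", "Cost: optimal care", "cost_usd", NA_character_,
      82, 65, 98, "triangular",
    "cost_self_failure", "Cost: self-treatment failure", "cost_usd", NA_character_,
      27, 22, 32, "triangular",
    "ddl_suboptimal", "DDL: outpatient (suboptimal)", "ddl_days", NA_character_,
      0.7, 0.4, 1.0, "normal",
    "ddl_optimal", "DDL: outpatient (optimal)", "ddl_days", NA_character_,
      0.37, 0.23, 0.52, "normal",
    "ddl_bedrest", "DDL: confinement to bed rest", "ddl_days", NA_character_,
      1.6, 1.0, 2.0, "triangular",
    "ddl_hospital", "DDL: hospitalization", "ddl_days", NA_character_,
      1.7, 1.0, 3.0, "triangular",
    "ddl_medevac", "DDL: medical evacuation", "ddl_days", NA_character_,
      7, 3, 10, "triangular",
    "ddl_run_course", "DDL: no self-treatment (run its course)", "ddl_days", NA_character_,
      0.37, 0.23, 0.52, "normal",
    "ddl_self_success", "DDL: self-treatment success", "ddl_days", NA_character_,
      0.18, 0.11, 0.25, "normal",
    "ddl_self_failure", "DDL: self-treatment failure", "ddl_days", NA_character_,
      0.48, 0.29, 0.67, "normal"
  )
  p <- new_td_params(p)
  overrides <- list(...)
  if (length(overrides)) {
    p <- set_param_values(p, !!!overrides)
  }
  p
}

new_td_params <- function(x) {
  stopifnot(is.data.frame(x))
  class(x) <- unique(c("td_params", class(tibble::as_tibble(x))))
  x
}

#' Read or modify point estimates of a parameter set
#'
#' `param_value()` extracts one point estimate by name; `set_param_values()`
#' replaces point estimates (the `value` column) for the named parameters and
#' returns the modified set.
#'
#' @param params A `td_params` tibble from [td_parameters()].
#' @param name A single parameter name.
#' @return `param_value()`: a numeric scalar. `set_param_values()`: the
#'   modified `td_params` tibble.
#' @examples
#' ps <- set_param_values(td_parameters(), p_mh_treatment = 0.4)
#' param_value(ps, "p_mh_treatment")
#' @export
param_value <- function(params, name) {
  i <- match(name, params$name)
  if (anyNA(i)) {
    stop("unknown parameter: ", paste(name[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  params$value[i]
}

#' @rdname param_value
#' @param ... Named numeric scalars, `<parameter name> = <new value>`.
#' @export
set_param_values <- function(params, ...) {
  vals <- rlang::list2(...)
  if (!length(vals)) return(params)
  nm <- names(vals)
  if (is.null(nm) || any(nm == "")) {
    stop("all overrides must be named", call. = FALSE)
  }
  i <- match(nm, params$name)
  if (anyNA(i)) {
    stop("unknown parameter: ", paste(nm[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  params$value[i] <- vapply(vals, as.numeric, numeric(1))
  params
}

#' Validate a parameter set
#'
#' Checks (a) that each sibling probability group (disposition, outpatient,
#' self-care) sums to one within `tol`, (b) per-parameter bound ordering
#' `low <= value <= high`, (c) range constraints by role: probabilities in
#' `[0, 1]`, costs and DDL non-negative, cohort constants strictly positive
#' with monthly incidence at most one. Returns a report rather than signalling
#' so callers can display every violation at once.
#'
#' @param params A `td_params` tibble.
#' @param tol Absolute tolerance for group sums (default `1e-6`).
#' @return A tibble with columns `check`, `target`, `detail`, `pass`; one row
#'   per group-sum check and one per violated parameter constraint.
#' @examples
#' all(validate_parameters(td_parameters())$pass)
#' @export
validate_parameters <- function(params, tol = 1e-6) {
  grp <- dplyr::filter(params, !is.na(.data$group))
  group_report <- grp |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(s = sum(.data$value), .groups = "drop") |>
    dplyr::transmute(
      check = "group_sum",
      target = .data$group,
      detail = sprintf("sum = %.6f", .data$s),
      pass = abs(.data$s - 1) <= tol
    )

  bound_rows <- purrr::pmap(params, function(name, role, value, low, high, ...) {
    bad <- character(0)
    if (!(low <= value && value <= high)) {
      bad <- c(bad, sprintf("value %.6g outside [low, high] = [%.6g, %.6g]",
                            value, low, high))
    }
    if (role == "probability" && (low < 0 || high > 1)) {
      bad <- c(bad, "bounds outside [0, 1]")
    }
    if (role %in% c("cost_usd", "ddl_days") && low < 0) {
      bad <- c(bad, "negative low bound")
    }
    if (role == "cohort" && (value <= 0 || low <= 0)) {
      bad <- c(bad, "cohort values must be strictly positive")
    }
    if (name == "monthly_incidence" && high > 1) {
      bad <- c(bad, "incidence bounds exceed 1")
    }
    if (!length(bad)) return(NULL)
    tibble::tibble(check = "bounds", target = name,
                   detail = paste(bad, collapse = "; "), pass = FALSE)
  })
  dplyr::bind_rows(group_report, purrr::compact(bound_rows))
}

# Stop with a readable message when a parameter set fails validation.
assert_valid_params <- function(params, tol = 1e-6) {
  rep <- validate_parameters(params, tol = tol)
  bad <- dplyr::filter(rep, !.data$pass)
  if (nrow(bad)) {
    stop("invalid parameter set:\n",
         paste(sprintf("  %s [%s]: %s", bad$check, bad$target, bad$detail),
               collapse = "\n"),
         call. = FALSE)
  }
  invisible(params)
}

#' Sampling distributions implied by a parameter set
#'
#' Expands each parameter's `(value, low, high, dist)` into the concrete
#' distribution the probabilistic sensitivity analysis draws from:
#' * `triangular` — mode `value` on `[low, high]`;
#' * `normal` — mean `value`, `sd = (high - low) / (2 * 1.96)` (the printed
#'   range is read as a 95% confidence interval), truncated to the parameter's
#'   natural support (`[0, 1]` for probabilities, `[0, Inf)` otherwise);
#' * `point` — any parameter with `low == high` degenerates to a point mass.
#'
#' @param params A `td_params` tibble.
#' @return A tibble with columns `name`, `kind`, `a`, `m`, `b`, `sd`,
#'   `trunc_lower`, `trunc_upper`.
#' @examples
#' param_distributions(td_parameters())
#' @export
param_distributions <- function(params) {
  bad <- params$low > params$value | params$value > params$high
  if (any(bad)) {
    stop("low <= value <= high violated for: ",
         paste(params$name[bad], collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(params$dist), c("triangular", "normal", "point"))
  if (length(unknown)) {
    stop("unknown distribution kind: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tibble::tibble(
    name = params$name,
    kind = ifelse(params$low == params$high, "point", params$dist),
    a = params$low,
    m = params$value,
    b = params$high,
    sd = ifelse(params$dist == "normal", (params$high - params$low) / (2 * 1.96), NA_real_),
    trunc_lower = 0,
    # monthly incidence is a per-person-month probability despite its cohort role
    trunc_upper = ifelse(params$role == "probability" |
                           params$name == "monthly_incidence", 1, Inf)
  )
}

#' Round half away from zero
#'
#' Reported integers (episodes, DDL totals, dollar amounts) use conventional
#' half-up rounding at the final step only; internal arithmetic is never
#' rounded. `round()` in R rounds half to even, so reports use this helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal digits (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.5, 1.5, -0.5))
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * trunc(abs(x) * f + 0.5) / f
}
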