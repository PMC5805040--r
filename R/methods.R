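#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidy a tornado analysis
#'
#' @param x A `td_tornado` tibble from [tornado()].
#' @param ... Unused.
#' @return A plain tibble with the tornado entries plus a `base_output`
#'   column (the base-case cost ratio).
#' @export
tidy.td_tornado <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$base_output <- attr(x, "base_output")
  out
}

#' Tidy a probabilistic sensitivity analysis
#'
#' @param x A `td_psa` tibble from [run_psa()].
#' @param ... Unused.
#' @return A long tibble: one row per scenario and metric (`ddl_averted`,
#'   `cer`) with `median`, `q1`, `q3`.
#' @export
tidy.td_psa <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^(ddl_averted|cer)_(median|q1|q3)$"),
      names_to = c("metric", ".value"),
      names_pattern = "^(ddl_averted|cer)_(median|q1|q3)$"
    )
}

#' Tidy a scenario comparison
#'
#' @param x A `td_comparison` tibble from [run_scenarios()].
#' @param ... Unused.
#' @return A plain tibble (class markers dropped).
#' @export
tidy.td_comparison <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a model evaluation
#'
#' @param x A `td_eval` tibble from [evaluate_model()].
#' @param ... Unused.
#' @return A one-row tibble with the unrounded totals plus rounded report
#'   values (`ddl_report`, `cost_ratio_report`).
#' @export
glance.td_eval <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      episodes_report = round_half_up(.data$episodes),
      ddl_report = round_half_up(.data$total_ddl),
      cost_ratio_report = round_half_up(.data$cost_ratio)
    )
}

#' One-row summary of a probabilistic sensitivity analysis
#'
#' @param x A `td_psa` tibble.
#' @param ... Unused.
#' @return A one-row tibble with `n_scenarios`, `n_iterations`, `seed`.
#' @export
glance.td_psa <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    n_iterations = x$n_iterations[1],
    seed = x$seed[1]
  )
}

#' Tornado plot of one-way sensitivity swings
#'
#' Horizontal bars from the base-case cost ratio out to the output at each
#' parameter's low and high estimate, ranked by swing.
#'
#' @param object A `td_tornado` tibble from [tornado()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.td_tornado <- function(object, ...) {
  base_output <- attr(object, "base_output")
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(label = factor(.data$label, levels = rev(.data$label))) |>
    tidyr::pivot_longer(c("low_output", "high_output"),
                        names_to = "end", values_to = "output")
  ggplot2::ggplot(dat, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = base_output, xend = .data$output,
                   yend = .data$label, colour = .data$end),
      linewidth = 4
    ) +
    ggplot2::geom_vline(xintercept = base_output, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(low_output = "#1f78b4", high_output = "#e31a1c"),
      labels = c(low_output = "Low estimate", high_output = "High estimate"),
      name = NULL
    ) +
    ggplot2::labs(x = "Cost ratio (USD per duty day lost)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Median and interquartile range of PSA outcomes
#'
#' @param object A `td_psa` tibble from [run_psa()].
#' @param metric `"ddl_averted"` (default) or `"cer"`.
#' @param ... Unused.
#' @return A ggplot object: one point (median) with an IQR error bar per
#'   scenario.
#' @export
autoplot.td_psa <- function(object, metric = c("ddl_averted", "cer"), ...) {
  metric <- match.arg(metric)
  dat <- tidy(object) |> dplyr::filter(.data$metric == !!metric)
  ylab <- if (metric == "ddl_averted") {
    "DDL-averted per year (median, IQR)"
  } else {
    "CER, USD per DDL-averted or gained (median, IQR)"
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$median,
                                    colour = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$q1, ymax = .data$q3),
                           width = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = NULL, y = ylab, colour = "Strategy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Deterministic scenario outcomes at a glance
#'
#' @param object A `td_comparison` tibble from [run_scenarios()].
#' @param ... Unused.
#' @return A ggplot object: DDL-averted per scenario (base case omitted).
#' @export
autoplot.td_comparison <- function(object, ...) {
  dat <- tibble::as_tibble(object) |>
    dplyr::filter(.data$strategy != "base")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label, y = .data$ddl_averted,
                                    fill = .data$strategy)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "DDL-averted per year", fill = "Strategy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
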