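required_entry_keys <- c("value", "low", "high", "dist")

params_to_config <- function(params) {
  entry <- function(rows) {
    stats::setNames(
      purrr::pmap(rows, function(value, low, high, dist, ...) {
        list(value = value, low = low, high = high, dist = dist)
      }),
      rows$name
    )
  }
  list(
    cohort = entry(dplyr::filter(params, .data$role == "cohort")),
    parameters = entry(dplyr::filter(params, .data$role != "cohort"))
  )
}

#' Write a parameter configuration file
#'
#' Serializes a parameter set to the JSON configuration format consumed by
#' [read_td_config()]: a `cohort` block and a `parameters` block, each entry
#' holding `value`, `low`, `high`, `dist`. The file shipped at
#' `system.file("extdata", "default_config.json", package = "tdcea")`
#' reproduces [td_parameters()].
#'
#' @param params A `td_params` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_td_config <- function(params, path) {
  # I(17) = 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(params_to_config(params), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Read and validate a parameter configuration file
#'
#' Parses the JSON configuration, checks it structurally (unknown top-level
#' keys, unknown or missing parameter names, and unknown keys inside an entry
#' are each rejected with a message naming the offender), and validates the
#' resulting parameter set with [validate_parameters()], signalling on any
#' failure. Parameter names are fixed identifiers; roles, sibling groups and
#' labels are restored from the canonical table by name.
#'
#' @param path Path to a JSON configuration file.
#' @return A `td_params` tibble.
#' @examples
#' cfg <- system.file("extdata", "default_config.json", package = "tdcea")
#' identical(read_td_config(cfg), td_parameters())
#' @export
read_td_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  extra <- setdiff(names(cfg), c("cohort", "parameters"))
  if (length(extra)) {
    stop("unknown top-level config key: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (!all(c("cohort", "parameters") %in% names(cfg))) {
    stop("config must contain 'cohort' and 'parameters' blocks", call. = FALSE)
  }
  template <- td_parameters()
  entries <- c(cfg$cohort, cfg$parameters)
  unknown <- setdiff(names(entries), template$name)
  if (length(unknown)) {
    stop("unknown parameter in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(template$name, names(entries))
  if (length(missing)) {
    stop("config missing required parameter: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort_names <- template$name[template$role == "cohort"]
  misplaced <- c(
    setdiff(names(cfg$cohort), cohort_names),
    intersect(names(cfg$parameters), cohort_names)
  )
  if (length(misplaced)) {
    stop("parameter in wrong config block: ",
         paste(misplaced, collapse = ", "), call. = FALSE)
  }
  for (nm in names(entries)) {
    e <- entries[[nm]]
    bad_keys <- setdiff(names(e), required_entry_keys)
    if (length(bad_keys)) {
      stop("unknown key in config entry '", nm, "': ",
           paste(bad_keys, collapse = ", "), call. = FALSE)
    }
    missing_keys <- setdiff(required_entry_keys, names(e))
    if (length(missing_keys)) {
      stop("config entry '", nm, "' missing key: ",
           paste(missing_keys, collapse = ", "), call. = FALSE)
    }
  }
  entries <- entries[match(template$name, names(entries))]
  template$value <- unname(purrr::map_dbl(entries, ~ as.numeric(.x$value)))
  template$low <- unname(purrr::map_dbl(entries, ~ as.numeric(.x$low)))
  template$high <- unname(purrr::map_dbl(entries, ~ as.numeric(.x$high)))
  template$dist <- unname(purrr::map_chr(entries, ~ as.character(.x$dist)))
  unknown_dist <- setdiff(unique(template$dist),
                          c("triangular", "normal", "point"))
  if (length(unknown_dist)) {
    stop("unknown distribution kind in config: ",
         paste(unknown_dist, collapse = ", "), call. = FALSE)
  }
  assert_valid_params(template)
  template
}

#' Write a scenario outcome report
#'
#' Writes the rounded, report-shaped CSV from [scenario_table()] together
#' with a full-precision JSON sidecar carrying the unrounded
#' [run_scenarios()] rows (CSV cells are integer dollars and days by
#' convention; the JSON is the machine-readable record).
#'
#' @param comparison A `td_comparison` tibble from [run_scenarios()].
#' @param path Output CSV path; the JSON sidecar is written next to it with
#'   extension `.json` unless `json_path` is given.
#' @param json_path Optional explicit path for the JSON sidecar.
#' @return A character vector of the two written paths, invisibly.
#' @export
write_scenario_table <- function(comparison, path, json_path = NULL) {
  if (!nrow(comparison)) stop("empty comparison", call. = FALSE)
  if (is.null(json_path)) {
    json_path <- paste0(sub("\\.csv$", "", path), ".json")
  }
  utils::write.csv(scenario_table(comparison), path, row.names = FALSE,
                   na = "")
  jsonlite::write_json(comparison, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(path, json_path))
}
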