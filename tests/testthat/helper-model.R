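# Shared fixtures for the model tests.

# Parameter set whose disposition branch sends every episode to medevac;
# conditional groups are untouched (they stay valid).
medevac_only_params <- function() {
  ps <- tdcea::set_param_values(
    tdcea::td_parameters(),
    p_no_mh = 0, p_mh_treatment = 0, p_hospitalization = 0, p_medevac = 1
  )
  ps$low <- pmin(ps$low, ps$value)
  ps$high <- pmax(ps$high, ps$value)
  ps
}

# Collapse every parameter of a set to a point mass at its current value.
point_mass_params <- function(ps) {
  ps$low <- ps$value
  ps$high <- ps$value
  ps$dist <- "point"
  ps
}

# Theoretical sd of a triangular(a, m, b) distribution.
triangular_sd <- function(a, m, b) {
  sqrt((a^2 + m^2 + b^2 - a * m - a * b - m * b) / 18)
}

# Per-episode standard deviations of cost and DDL over the tree's
# categorical outcome (used for n-sigma Monte Carlo bands).
tree_sds <- function(tree) {
  mc <- sum(tree$path_probability * tree$unit_cost)
  md <- sum(tree$path_probability * tree$unit_ddl)
  c(cost = sqrt(sum(tree$path_probability * (tree$unit_cost - mc)^2)),
    ddl = sqrt(sum(tree$path_probability * (tree$unit_ddl - md)^2)))
}
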