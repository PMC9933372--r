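# Model parameters: distribution specs, moment matching, config loading.

#' Health states of the cohort model
#'
#' @return Character vector of the five health states in canonical order.
#'   `"death"` is absorbing.
#' @export
health_states <- function() {
  c("well", "complications", "index_revision", "adjacent_revision", "death")
}

#' Create a distribution specification
#'
#' A parameter is summarised by its base-case mean and a low--high range,
#' interpreted as a 95% interval for moment matching. Probabilities and
#' utilities are beta-distributed, costs gamma-distributed.
#'
#' @param family `"beta"` or `"gamma"`.
#' @param mean Base-case value.
#' @param low,high Range bounds (95% interval).
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(family, mean, low, high) {
  family <- match.arg(family, c("beta", "gamma"))
  if (!is.finite(mean) || !is.finite(low) || !is.finite(high))
    stop("dist_spec: mean, low and high must be finite")
  if (low > high) stop("dist_spec: low must not exceed high")
  if (family == "beta" && (low < 0 || high > 1))
    stop("dist_spec: beta support requires 0 <= low and high <= 1")
  if (family == "gamma" && low < 0)
    stop("dist_spec: gamma support requires low >= 0")
  structure(list(family = family, mean = mean, low = low, high = high),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s  mean %.4g  range %.4g-%.4g\n",
              x$family, x$mean, x$low, x$high))
  invisible(x)
}

# Standard-error implied by a range read as a 95% interval.
.range_se <- function(low, high) (high - low) / (2 * 1.96)

#' Beta hyperparameters by method of moments
#'
#' Treats `[low, high]` as a 95% interval, so SE = (high - low)/(2 * 1.96),
#' and matches mean and variance: with k = m(1-m)/SE^2 - 1 the shapes are
#' (k m, k (1-m)). The fitted mean equals the spec mean exactly.
#'
#' @param spec A [dist_spec()] with `family = "beta"`.
#' @return Named numeric `c(shape1, shape2)`, both positive.
#' @export
beta_hyperparameters <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family != "beta") stop("beta_hyperparameters: family is not beta")
  m <- spec$mean
  if (m <= 0 || m >= 1) stop("beta_hyperparameters: mean must lie in (0, 1)")
  if (spec$high <= spec$low)
    stop("beta_hyperparameters: degenerate zero-width range")
  v <- .range_se(spec$low, spec$high)^2
  if (v >= m * (1 - m))
    stop("beta_hyperparameters: infeasible moments (variance >= mean(1-mean))")
  k <- m * (1 - m) / v - 1
  c(shape1 = k * m, shape2 = k * (1 - m))
}

#' Gamma hyperparameters by method of moments
#'
#' SE = (high - low)/(2 * 1.96); shape = mean^2/SE^2, rate = shape/mean,
#' so the fitted mean equals the spec mean to machine precision and the
#' fitted SD equals the implied SE.
#'
#' @param spec A [dist_spec()] with `family = "gamma"`.
#' @return Named numeric `c(shape, rate)`.
#' @export
gamma_hyperparameters <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$family != "gamma") stop("gamma_hyperparameters: family is not gamma")
  if (spec$mean <= 0) stop("gamma_hyperparameters: mean must be positive")
  if (spec$high <= spec$low)
    stop("gamma_hyperparameters: degenerate zero-width range")
  se <- .range_se(spec$low, spec$high)
  shape <- spec$mean^2 / se^2
  c(shape = shape, rate = shape / spec$mean)
}

#' Draw from a parameter's fitted distribution
#'
#' With `u` supplied the draw is the inverse-CDF transform of `u`, which is
#' how the probabilistic sensitivity analysis imposes common random numbers
#' across strategies; otherwise draws come from the session RNG stream (seed
#' it with [set.seed()] for reproducibility).
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (ignored when `u` is given).
#' @param u Optional uniform(0,1) quantile(s) for inverse-CDF sampling.
#' @return Numeric vector of draws inside the family's support.
#' @export
sample_parameter <- function(spec, n = 1, u = NULL) {
  if (spec$family == "beta") {
    hp <- beta_hyperparameters(spec)
    if (is.null(u)) stats::rbeta(n, hp[1], hp[2])
    else unname(stats::qbeta(u, hp[1], hp[2]))
  } else {
    hp <- gamma_hyperparameters(spec)
    if (is.null(u)) stats::rgamma(n, shape = hp[1], rate = hp[2])
    else unname(stats::qgamma(u, shape = hp[1], rate = hp[2]))
  }
}

#' The +/-10% utility range rule
#'
#' Utility parameters estimated from the registry carry a range of mean
#' +/- 10%, with the upper bound capped at 1 (a utility cannot exceed full
#' health).
#'
#' @param mean Utility mean.
#' @return Named numeric `c(low, high)`.
#' @export
utility_range <- function(mean) {
  c(low = 0.9 * mean, high = min(1, 1.1 * mean))
}

# Targets every configuration must provide, per strategy.
.required_transitions <- c(
  "transition.well.index_revision",
  "transition.well.adjacent_revision",
  "transition.complications.index_revision",
  "transition.index_revision.well",
  "transition.index_revision.adjacent_revision",
  "transition.adjacent_revision.well",
  "transition.adjacent_revision.index_revision")
.required_utilities <- paste0("utility.",
  c("well", "complications", "index_revision", "adjacent_revision"))
.required_state_costs <- paste0("cost.state.",
  c("well", "complications", "index_revision", "adjacent_revision"))
.required_shared <- c("cost.upfront.posterior_fusion", "cost.upfront.bmp2",
                      "cost.visit.food_opd", "cost.visit.food_ipd",
                      "cost.visit.transport")

#' Load and validate a model configuration
#'
#' Reads the JSON configuration holding the full parameter table (one row
#' per printed parameter: family, mean, low, high, draw group), economic
#' settings, decision-tree allocation, visit-rate assumptions, upfront cost
#' components and the background-mortality table (CSV referenced by the
#' config, resolved relative to it).
#'
#' Structural problems (missing rows, probabilities outside `[0, 1]`,
#' unknown families) abort with the offending path. Internally inconsistent
#' rows -- a mean outside its own printed range, or a utility range that
#' violates the +/-10% rule -- are loaded verbatim and reported in
#' `$warnings`, never silently corrected.
#'
#' @param path Path to the JSON configuration.
#' @return A `cua_parameters` object: list with `table` (data frame of
#'   parameter rows with fitted hyperparameters and flags), `settings`,
#'   `tree`, `visit_rates`, `upfront`, `mortality`, `warnings`.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("load_parameters: no such file: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(normalizePath(path))

  tab <- cfg$parameters
  need <- c("id", "category", "strategy", "target", "family",
            "mean", "low", "high", "draw_group", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("load_parameters: parameter table lacks columns: ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("load_parameters: duplicated parameter ids")
  bad <- setdiff(unique(tab$family), c("beta", "gamma"))
  if (length(bad))
    stop("load_parameters: unknown distribution family: ",
         paste(bad, collapse = ", "))

  # schema completeness: every required target for both strategies
  for (strat in c("LLIF", "PLIF")) {
    have <- tab$target[tab$strategy %in% c(strat, "shared")]
    for (tgt in c(.required_transitions, .required_utilities,
                  .required_state_costs, "cost.upfront.cage")) {
      if (!tgt %in% have)
        stop("load_parameters: missing parameter '", tgt, "' for ", strat)
    }
  }
  for (tgt in .required_shared)
    if (!tgt %in% tab$target)
      stop("load_parameters: missing shared parameter '", tgt, "'")

  # range validity
  prob_like <- tab$category %in% c("transition", "utility")
  if (any(prob_like & (tab$mean < 0 | tab$mean > 1)))
    stop("load_parameters: probability/utility outside [0,1]: ",
         paste(tab$id[prob_like & (tab$mean < 0 | tab$mean > 1)],
               collapse = ", "))
  if (any(tab$mean < 0))
    stop("load_parameters: negative cost mean: ",
         paste(tab$id[tab$mean < 0], collapse = ", "))

  warnings <- character(0)
  tab$degenerate <- tab$high <= tab$low
  tab$flag_mean_outside <- tab$mean < tab$low | tab$mean > tab$high
  tab$flag_range_rule <- FALSE
  ut <- tab$category == "utility"
  rng <- utility_range(tab$mean[ut])
  # compare at the precision the table prints (3 decimals)
  tab$flag_range_rule[ut] <-
    abs(tab$low[ut] - 0.9 * tab$mean[ut]) > 5e-4 |
    abs(tab$high[ut] - pmin(1, 1.1 * tab$mean[ut])) > 5e-4
  for (i in which(tab$flag_mean_outside))
    warnings <- c(warnings, sprintf(
      "%s: base-case mean %.4g lies outside its printed range %.4g-%.4g (loaded as printed)",
      tab$id[i], tab$mean[i], tab$low[i], tab$high[i]))
  for (i in which(tab$flag_range_rule & !tab$flag_mean_outside))
    warnings <- c(warnings, sprintf(
      "%s: printed range %.4g-%.4g deviates from the mean +/- 10%% utility rule",
      tab$id[i], tab$low[i], tab$high[i]))
  for (i in which(tab$degenerate))
    warnings <- c(warnings, sprintf(
      "%s: zero-width range; parameter held fixed in sensitivity analyses",
      tab$id[i]))

  # moment-matched hyperparameters (NA where degenerate or infeasible)
  tab$hp1 <- NA_real_; tab$hp2 <- NA_real_
  tab$sample_ok <- FALSE
  for (i in seq_len(nrow(tab))) {
    if (tab$degenerate[i]) next
    sp <- dist_spec(tab$family[i], tab$mean[i], tab$low[i], tab$high[i])
    hp <- tryCatch(
      if (tab$family[i] == "beta") beta_hyperparameters(sp)
      else gamma_hyperparameters(sp),
      error = function(e) NULL)
    if (is.null(hp)) {
      warnings <- c(warnings, sprintf(
        "%s: moment fit infeasible; parameter held fixed in the PSA", tab$id[i]))
    } else {
      tab$hp1[i] <- hp[1]; tab$hp2[i] <- hp[2]; tab$sample_ok[i] <- TRUE
    }
  }

  settings <- .validate_settings(cfg$settings)

  tree <- list(
    LLIF = initial_allocation(cfg$decision_tree$LLIF),
    PLIF = initial_allocation(cfg$decision_tree$PLIF))

  vr <- cfg$visit_rates
  if (is.null(vr)) stop("load_parameters: missing visit_rates")

  mort_file <- file.path(dir, cfg$mortality_file)
  if (!file.exists(mort_file))
    stop("load_parameters: mortality table not found: ", mort_file)
  mortality <- utils::read.csv(mort_file)
  .validate_mortality(mortality, settings)

  out <- structure(list(
    table = tab, settings = settings, tree = tree,
    visit_rates = vr, upfront = cfg$upfront,
    mortality = mortality, wtp_source = cfg$wtp_source,
    warnings = warnings, path = normalizePath(path)),
    class = "cua_parameters")
  out
}

.validate_settings <- function(s) {
  if (is.null(s)) stop("load_parameters: missing settings")
  defaults <- list(discount_rate = 0.03, wtp = 5003, start_age = 62,
                   max_age = 100, cycle_length = 1,
                   half_cycle_correction = FALSE)
  for (nm in names(defaults)) if (is.null(s[[nm]])) s[[nm]] <- defaults[[nm]]
  if (s$discount_rate < 0)
    stop("settings.discount_rate: must be non-negative")
  if (s$start_age >= s$max_age)
    stop("settings.start_age: must be below max_age")
  if (s$wtp < 0) stop("settings.wtp: must be non-negative")
  s
}

.validate_mortality <- function(m, settings) {
  if (!all(c("age", "qx") %in% names(m)))
    stop("mortality table needs columns age, qx")
  ages <- settings$start_age:settings$max_age
  if (!all(ages %in% m$age))
    stop("mortality table must cover every age in [start_age, max_age]")
  if (any(m$qx < 0 | m$qx > 1))
    stop("mortality table: qx outside [0,1]")
  if (m$qx[m$age == settings$max_age] != 1)
    stop("mortality table: qx at max_age must be 1")
  invisible(m)
}

#' Packaged base-case configuration
#'
#' Loads the configuration shipped with the package: the published input
#' table, economic settings (3% discounting, WTP 5003 USD/QALY, ages
#' 62--100), the calibrated Gompertz background-mortality table and the
#' calibrated decision-tree allocation and residual index-surgery costs
#' (see the methods vignette and `analysis/01_calibrate.R`).
#'
#' @return A `cua_parameters` object.
#' @export
default_parameters <- function() {
  load_parameters(system.file("extdata", "model_parameters.json",
                              package = "lumbarCUA", mustWork = TRUE))
}

#' @export
print.cua_parameters <- function(x, ...) {
  cat("<cua_parameters>\n")
  cat(sprintf("  %d parameter rows (%d flagged, %d zero-width)\n",
              nrow(x$table),
              sum(x$table$flag_mean_outside | x$table$flag_range_rule),
              sum(x$table$degenerate)))
  cat(sprintf("  horizon: ages %d-%d, discount %.1f%%, WTP %s USD/QALY\n",
              x$settings$start_age, x$settings$max_age,
              100 * x$settings$discount_rate,
              format(x$settings$wtp, big.mark = ",")))
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' Export the resolved parameter table
#'
#' Writes one CSV row per parameter with base case, range, flags and the
#' fitted beta/gamma hyperparameters.
#'
#' @param pset A `cua_parameters` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters <- function(pset, path) {
  stopifnot(inherits(pset, "cua_parameters"))
  cols <- c("id", "label", "category", "strategy", "family", "mean", "low",
            "high", "draw_group", "degenerate", "flag_mean_outside",
            "flag_range_rule", "hp1", "hp2")
  utils::write.csv(pset$table[, cols], path, row.names = FALSE)
  invisible(path)
}

# Look up one parameter value for a strategy: strategy-specific row first,
# then a shared row. `values` (named by id) overrides the base-case mean.
.param_value <- function(tab, target, strategy, values = NULL) {
  i <- which(tab$target == target & tab$strategy == strategy)
  if (!length(i)) i <- which(tab$target == target & tab$strategy == "shared")
  if (!length(i)) stop("parameter not found: ", target, " (", strategy, ")")
  i <- i[1]
  id <- tab$id[i]
  if (!is.null(values) && !is.na(values[id])) unname(values[id]) else tab$mean[i]
}

# Assemble the engine inputs (transition vector, utilities, annual state
# costs including non-medical visit costs, total upfront cost) for one
# strategy, optionally under overridden parameter values.
.model_inputs <- function(pset, strategy, values = NULL) {
  tab <- pset$table
  g <- function(target) .param_value(tab, target, strategy, values)
  tp <- vapply(.required_transitions, g, numeric(1))
  names(tp) <- sub("^transition\\.", "", names(tp))
  util <- c(vapply(.required_utilities, g, numeric(1)), death = 0)
  names(util) <- sub("^utility\\.", "", names(util))
  st <- vapply(.required_state_costs, g, numeric(1))
  names(st) <- sub("^cost\\.state\\.", "", names(st))
  opd <- g("cost.visit.food_opd") + g("cost.visit.transport")
  ipd <- g("cost.visit.food_ipd") + g("cost.visit.transport")
  vr <- pset$visit_rates
  alive <- health_states()[1:4]
  state_cost <- st[alive] +
    unlist(vr$outpatient[alive]) * opd + unlist(vr$inpatient[alive]) * ipd
  state_cost <- c(state_cost, death = 0)
  up <- pset$upfront[[strategy]]
  upfront <- g("cost.upfront.cage") + g("cost.upfront.posterior_fusion") +
    (if (isTRUE(up$use_bmp2)) g("cost.upfront.bmp2") else 0) +
    up$residual
  list(tp = tp, util = util, state_cost = state_cost, upfront = upfront)
}
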