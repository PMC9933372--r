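# Synthetic patient-level cohort with the registry's summary structure,
# group comparisons, EQ-5D-5L scoring and state-utility estimation.

# Moments of a normal(mu, sigma) truncated to [a, b].
.tnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the [a,b]-truncated normal has the target
# mean and SD (post-truncation moment correction).
.tnorm_solve <- function(mean, sd, a, b) {
  obj <- function(p) {
    mm <- .tnorm_moments(p[1], exp(p[2]), a, b)
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

.rtnorm <- function(n, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma); pb <- stats::pnorm(b, mu, sigma)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mu, sigma)
}

# measure table: name, family and scale bounds
.measures <- function() {
  data.frame(
    name = c("age", "blood_loss_ml", "operative_time_min",
             "length_of_stay_days", "utility_preop", "utility_1y",
             "odi_preop", "odi_1y", "eqvas_preop", "eqvas_1y"),
    family = c("tnorm", "gamma", "gamma", "gamma", "tnorm", "tnorm",
               "tnorm", "tnorm", "tnorm", "tnorm"),
    lower = c(18, 0, 0, 0, -0.28, -0.28, 0, 0, 0, 0),
    upper = c(100, Inf, Inf, Inf, 1, 1, 100, 100, 100, 100))
}

#' Default cohort specification
#'
#' Per-arm sample sizes and mean/SD for every perioperative and
#' patient-reported measure, matching the surgical registry's printed
#' group summaries: 59 LLIF and 77 PLIF single-level fusions. Bounded
#' scores (utilities, ODI, EQ-VAS) are truncated normal with
#' post-truncation moment correction; positive right-skewed measures
#' (blood loss, operative time, length of stay) are gamma. The EQ-5D-5L
#' utility floor is -0.28, a conventional worst-health index value.
#'
#' @return A `cohort_spec` list: per arm, `n`, `p_female` and a
#'   measures data frame (name, family, mean, sd, lower, upper).
#' @export
cohort_spec_default <- function() {
  m <- .measures()
  llif <- cbind(m, mean = c(62.76, 167.03, 222.80, 8.80, 0.67, 0.84,
                            35.97, 21.83, 64.22, 76.27),
                sd = c(11.60, 161.90, 73.32, 9.74, 0.24, 0.15,
                       19.83, 15.53, 19.00, 18.44))
  plif <- cbind(m, mean = c(61.75, 458.96, 194.62, 8.34, 0.65, 0.89,
                            40.31, 24.79, 65.65, 76.10),
                sd = c(11.72, 304.36, 46.13, 4.95, 0.17, 0.09,
                       14.56, 10.28, 14.27, 13.44))
  structure(list(
    LLIF = list(n = 59, p_female = 42 / 59, measures = llif),
    PLIF = list(n = 77, p_female = 44 / 77, measures = plif)),
    class = "cohort_spec")
}

.validate_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  for (arm in c("LLIF", "PLIF")) {
    a <- spec[[arm]]
    if (a$n < 2) stop("cohort_spec: n must exceed 1 in arm ", arm)
    m <- a$measures
    if (any(m$sd < 0)) stop("cohort_spec: negative SD in arm ", arm)
    out <- m$mean < m$lower | m$mean > m$upper
    if (any(out))
      stop("cohort_spec: mean outside scale bounds for ",
           paste(m$name[out], collapse = ", "), " in arm ", arm)
  }
  invisible(spec)
}

#' Generate a synthetic patient-level cohort
#'
#' Draws per-arm samples for every measure under the spec's distribution
#' families; truncated-normal measures are moment-corrected so the
#' post-truncation mean and SD match the spec. Reproducible by seed.
#'
#' @param spec A [cohort_spec_default()]-shaped specification.
#' @param seed Integer seed.
#' @param n_scale Multiplier on the per-arm sample sizes (used by
#'   large-sample recovery checks).
#' @return Data frame of patient records, one row per synthetic patient.
#' @export
generate_cohort <- function(spec = cohort_spec_default(), seed = 1L,
                            n_scale = 1) {
  .validate_spec(spec)
  set.seed(seed)
  arms <- lapply(c("LLIF", "PLIF"), function(arm) {
    a <- spec[[arm]]
    n <- round(a$n * n_scale)
    cols <- lapply(seq_len(nrow(a$measures)), function(i) {
      m <- a$measures[i, ]
      if (m$sd == 0) return(rep(m$mean, n))
      if (m$family == "gamma") {
        shape <- m$mean^2 / m$sd^2
        stats::rgamma(n, shape = shape, rate = shape / m$mean)
      } else {
        p <- .tnorm_solve(m$mean, m$sd, m$lower, m$upper)
        .rtnorm(n, p["mu"], p["sigma"], m$lower, m$upper)
      }
    })
    names(cols) <- a$measures$name
    data.frame(arm = arm,
               sex = ifelse(stats::runif(n) < a$p_female, "F", "M"),
               cols)
  })
  out <- do.call(rbind, arms)
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# Two-sample t from summary statistics; the workhorse behind
# summarize_and_test and directly usable on printed group summaries.
#' Two-sample t statistic from group summaries
#'
#' @param m1,s1,n1,m2,s2,n2 Per-group mean, SD and size.
#' @param var_equal Pooled-variance (`TRUE`) or Welch (`FALSE`) variant.
#' @return Named numeric `c(t, df, p)` (two-sided p).
#' @export
t_from_summary <- function(m1, s1, n1, m2, s2, n2, var_equal = TRUE) {
  if (n1 < 2 || n2 < 2) stop("t_from_summary: need n >= 2 per group")
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- if (se == 0) 0 else (m2 - m1) / se
  p <- if (se == 0) 1 else 2 * stats::pt(-abs(t), df)
  c(t = t, df = df, p = p)
}

#' Group comparison table for a synthetic cohort
#'
#' Mean (SD) per arm and the two-sample t-test per measure. The
#' pooled-variance statistic is primary (the registry analysis reports an
#' independent-sample t-test); the Welch variant is computed alongside.
#'
#' @param records A [generate_cohort()] data frame.
#' @return A `group_comparison` data frame, one row per measure.
#' @export
summarize_and_test <- function(records) {
  if (!all(c("arm") %in% names(records)))
    stop("summarize_and_test: records need an 'arm' column")
  meas <- intersect(.measures()$name, names(records))
  a <- records[records$arm == "LLIF", ]
  b <- records[records$arm == "PLIF", ]
  if (nrow(a) < 2 || nrow(b) < 2)
    stop("summarize_and_test: need at least 2 records per arm")
  rows <- lapply(meas, function(nm) {
    t1 <- t_from_summary(mean(a[[nm]]), stats::sd(a[[nm]]), nrow(a),
                         mean(b[[nm]]), stats::sd(b[[nm]]), nrow(b), TRUE)
    t2 <- t_from_summary(mean(a[[nm]]), stats::sd(a[[nm]]), nrow(a),
                         mean(b[[nm]]), stats::sd(b[[nm]]), nrow(b), FALSE)
    data.frame(measure = nm,
               mean_llif = mean(a[[nm]]), sd_llif = stats::sd(a[[nm]]),
               mean_plif = mean(b[[nm]]), sd_plif = stats::sd(b[[nm]]),
               t_pooled = unname(t1["t"]), df_pooled = unname(t1["df"]),
               p_pooled = unname(t1["p"]),
               t_welch = unname(t2["t"]), df_welch = unname(t2["df"]),
               p_welch = unname(t2["p"]))
  })
  structure(do.call(rbind, rows),
            class = c("group_comparison", "data.frame"))
}

#' EQ-5D-5L index from an additive value set
#'
#' Evaluates 1 minus the sum of the value set's decrements for the given
#' levels; the full-health profile (1,1,1,1,1) maps to 1 exactly. The
#' value set is pluggable: any complete coefficient table for the five
#' dimensions can be supplied (a synthetic example table ships in
#' `inst/extdata/value_set_synthetic.csv`).
#'
#' @param profile Integer vector of five levels in 1..5, ordered
#'   mobility, self-care, usual activities, pain/discomfort,
#'   anxiety/depression.
#' @param value_set Data frame with columns `dimension`, `level`,
#'   `decrement`; level-1 decrements are implicitly 0.
#' @return Utility index (<= 1).
#' @export
eq5d5l_index <- function(profile, value_set) {
  dims <- c("mobility", "self_care", "usual_activities",
            "pain_discomfort", "anxiety_depression")
  if (length(profile) != 5 || any(!profile %in% 1:5))
    stop("eq5d5l_index: profile must be five levels in 1..5")
  dec <- 0
  for (k in seq_along(dims)) {
    if (profile[k] == 1) next
    i <- which(value_set$dimension == dims[k] & value_set$level == profile[k])
    if (!length(i))
      stop("eq5d5l_index: value set lacks a coefficient for ",
           dims[k], " level ", profile[k])
    dec <- dec + value_set$decrement[i[1]]
  }
  1 - dec
}

#' Estimate well-state utilities with the +/-10% range rule
#'
#' The mean 1-year utility per arm estimates the `well` state utility;
#' additional states observed too rarely for patient-level estimation
#' (complications, index and adjacent revision) are accepted as direct
#' mean inputs. Every estimate carries a range of mean +/- 10% with the
#' upper bound capped at 1, per [utility_range()]. When a reference table
#' of printed (low, high) bounds is supplied, estimates whose rule-based
#' range disagrees with it are flagged.
#'
#' @param records A [generate_cohort()] data frame (needs `arm` and
#'   `utility_1y`).
#' @param extra_states Optional named list per arm of per-state mean
#'   utilities for the unobserved states.
#' @param reference Optional data frame (`strategy`, `state`, `low`,
#'   `high`) to compare the derived ranges against.
#' @return Data frame: strategy, state, mean, low, high (and
#'   `range_mismatch` when `reference` is given).
#' @export
estimate_state_utilities <- function(records, extra_states = NULL,
                                     reference = NULL) {
  rows <- list()
  for (arm in c("LLIF", "PLIF")) {
    r <- records[records$arm == arm, ]
    if (!nrow(r))
      stop("estimate_state_utilities: no records for arm ", arm)
    states <- c(list(well = mean(r$utility_1y)), extra_states[[arm]])
    for (st in names(states)) {
      rng <- utility_range(states[[st]])
      rows[[length(rows) + 1]] <- data.frame(
        strategy = arm, state = st, mean = states[[st]],
        low = unname(rng["low"]), high = unname(rng["high"]))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(reference)) {
    out$range_mismatch <- FALSE
    for (i in seq_len(nrow(out))) {
      j <- which(reference$strategy == out$strategy[i] &
                   reference$state == out$state[i])
      if (length(j))
        out$range_mismatch[i] <-
          abs(reference$low[j[1]] - out$low[i]) > 5e-4 |
          abs(reference$high[j[1]] - out$high[i]) > 5e-4
    }
  }
  out
}
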