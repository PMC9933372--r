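# Five-state annual-cycle Markov cohort engine.
#
# Ordering convention within a cycle: background mortality claims its share
# first (probability q at the cohort's current age), and the printed annual
# disease transitions act on the survivors, i.e. are scaled by (1 - q).
# This keeps every row stochastic for any life table. Accrual is evaluated
# on the end-of-cycle occupancy and discounted once per elapsed cycle;
# upfront surgical costs enter undiscounted at t = 0.

#' Build the one-cycle transition matrix for a strategy at one age
#'
#' @param tp Named annual disease transition probabilities, names
#'   `"from.to"` as in `"well.index_revision"`; see
#'   [health_states()] for the state set.
#' @param mortality_q Annual background death probability at the current
#'   age.
#' @return 5x5 row-stochastic matrix; the death row is an identity row.
#' @export
build_transition_matrix <- function(tp, mortality_q) {
  if (mortality_q < 0 || mortality_q > 1)
    stop("build_transition_matrix: mortality_q outside [0,1]")
  states <- health_states()
  P <- matrix(0, 5, 5, dimnames = list(states, states))
  s <- 1 - mortality_q
  moves <- strsplit(names(tp), ".", fixed = TRUE)
  for (k in seq_along(tp)) {
    from <- moves[[k]][1]; to <- moves[[k]][2]
    P[from, to] <- P[from, to] + tp[[k]] * s
  }
  P[, "death"] <- mortality_q
  P["death", ] <- 0
  for (st in states[1:4]) {
    self <- 1 - sum(P[st, ])
    if (self < -1e-12)
      stop("build_transition_matrix: exit probabilities from '", st,
           "' exceed available mass (mortality_q = ", mortality_q, ")")
    P[st, st] <- P[st, st] + max(self, 0)
  }
  P["death", "death"] <- 1
  P
}

# Fast inner loop shared by the trace builder, the DSA and the PSA.
# qx: death probability per cycle (length n_cycles, last entry 1).
# Semantics identical to iterating build_transition_matrix(); the index
# arithmetic is hoisted out of the cycle loop for the PSA's benefit.
# Returns list(occ = (n_cycles+1) x 5 occupancy incl. t=0 row,
#              cost, qaly  = discounted totals incl. upfront).
.engine <- function(tp, util, state_cost, upfront, init, qx, dr,
                    half_cycle = FALSE) {
  states <- health_states()
  mv <- strsplit(names(tp), ".", fixed = TRUE)
  idx <- cbind(match(vapply(mv, `[`, "", 1), states),
               match(vapply(mv, `[`, "", 2), states))
  tpv <- as.numeric(tp)
  util <- as.numeric(util[states])
  state_cost <- as.numeric(state_cost[states])
  n <- length(qx)
  occ <- matrix(NA_real_, n + 1, 5)
  occ[1, ] <- init
  disc <- (1 + dr)^-(seq_len(n))
  cost <- upfront; qaly <- 0
  cur <- as.numeric(init)
  P <- matrix(0, 5, 5)
  P[5, 5] <- 1
  for (t in seq_len(n)) {
    q <- qx[t]
    P[cbind(1:4, 1:4)] <- 0
    P[idx] <- tpv * (1 - q)
    P[1:4, 5] <- q
    self <- 1 - rowSums(P[1:4, , drop = FALSE])
    if (any(self < -1e-12))
      stop("markov engine: exit probabilities from '",
           states[which(self < -1e-12)[1]],
           "' exceed available mass at age index ", t)
    P[cbind(1:4, 1:4)] <- pmax(self, 0)
    nxt <- as.vector(cur %*% P)
    acc <- if (half_cycle) (cur + nxt) / 2 else nxt
    cost <- cost + sum(acc * state_cost) * disc[t]
    qaly <- qaly + sum(acc * util) * disc[t]
    occ[t + 1, ] <- nxt
    cur <- nxt
  }
  list(occ = occ, cost = cost, qaly = qaly)
}

#' Run the cohort model for one strategy
#'
#' Iterates annual cycles from `start_age` until `max_age`, applying the
#' age-specific transition matrix, and records the full cohort trace with
#' per-cycle (discounted) cost and QALY accrual.
#'
#' @param pset A `cua_parameters` object.
#' @param strategy `"LLIF"` or `"PLIF"`.
#' @param init Optional initial state distribution (defaults to the
#'   configured decision-tree allocation for the strategy).
#' @param values Optional named vector (by parameter id) overriding
#'   base-case values, as used by the sensitivity analyses.
#' @return A `cohort_trace` data frame: one row per cycle with age, the
#'   five state occupancies, cycle cost/QALY, their discounted values and
#'   running discounted totals. Totals (including upfront costs) are in
#'   `attr(, "totals")`; the strategy label in `attr(, "strategy")`.
#' @export
run_cohort <- function(pset, strategy = c("LLIF", "PLIF"), init = NULL,
                       values = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(pset, "cua_parameters"))
  if (is.null(init)) init <- pset$tree[[strategy]]
  if (abs(sum(init) - 1) > 1e-9)
    stop("run_cohort: initial distribution must sum to 1")
  mi <- .model_inputs(pset, strategy, values)
  s <- pset$settings
  qx <- .qx_vector(pset)
  res <- .engine(mi$tp, mi$util, mi$state_cost, mi$upfront, init, qx,
                 s$discount_rate, isTRUE(s$half_cycle_correction))
  n <- length(qx)
  disc <- (1 + s$discount_rate)^-(seq_len(n))
  occ <- res$occ[-1, , drop = FALSE]
  cycle_cost <- occ %*% mi$state_cost
  cycle_qaly <- occ %*% mi$util
  tr <- data.frame(
    cycle = seq_len(n),
    age = s$start_age + seq_len(n) - 1,
    occ,
    cycle_cost = as.vector(cycle_cost),
    cycle_qaly = as.vector(cycle_qaly),
    disc_cost = as.vector(cycle_cost) * disc,
    disc_qaly = as.vector(cycle_qaly) * disc)
  names(tr)[3:7] <- health_states()
  tr$cum_disc_cost <- mi$upfront + cumsum(tr$disc_cost)
  tr$cum_disc_qaly <- cumsum(tr$disc_qaly)
  structure(tr, class = c("cohort_trace", "data.frame"),
            strategy = strategy,
            totals = c(cost = res$cost, qaly = res$qaly),
            upfront = mi$upfront)
}

# Per-cycle death probabilities from the configured life table.
.qx_vector <- function(pset) {
  s <- pset$settings
  ages <- s$start_age:(s$max_age - 1)
  qx <- pset$mortality$qx[match(ages, pset$mortality$age)]
  qx[length(qx)] <- 1  # the cohort is extinct at max_age
  qx
}

#' Accumulate discounted totals from a cohort trace
#'
#' Recomputes lifetime totals from the occupancy trace: cycle t contributes
#' occupancy-weighted state values discounted by (1+r)^-t, and the
#' strategy's upfront surgical costs enter undiscounted at t = 0. This is
#' the audit path; [run_cohort()] carries the same totals as an attribute.
#'
#' @param trace A `cohort_trace`.
#' @param pset The `cua_parameters` the trace came from.
#' @param strategy Strategy the trace belongs to; must match the trace's
#'   own label.
#' @param values Optional parameter overrides (must match those used for
#'   the trace to be meaningful).
#' @return Named numeric `c(cost, qaly)`.
#' @export
accumulate_outcomes <- function(trace, pset, strategy, values = NULL) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!identical(attr(trace, "strategy"), strategy))
    stop("accumulate_outcomes: trace belongs to strategy '",
         attr(trace, "strategy"), "', not '", strategy, "'")
  mi <- .model_inputs(pset, strategy, values)
  occ <- as.matrix(trace[, health_states()])
  disc <- (1 + pset$settings$discount_rate)^-(trace$cycle)
  c(cost = mi$upfront + sum((occ %*% mi$state_cost) * disc),
    qaly = sum((occ %*% mi$util) * disc))
}

#' Run one strategy end-to-end
#'
#' Convenience wrapper returning the trace together with its lifetime
#' discounted totals.
#'
#' @inheritParams run_cohort
#' @return List with `trace`, `cost`, `qaly`.
#' @export
run_strategy <- function(pset, strategy, init = NULL, values = NULL) {
  tr <- run_cohort(pset, strategy, init = init, values = values)
  tot <- attr(tr, "totals")
  list(trace = tr, cost = unname(tot["cost"]), qaly = unname(tot["qaly"]))
}

#' Write a cohort trace to CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}
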