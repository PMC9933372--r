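# Shared fixtures and independent oracles.

default_pset <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- default_parameters()
    p
  }
})

# Exhaustive path enumeration over all state sequences: the brute-force
# oracle for the cohort engine at small cycle counts. Weighs every path by
# its probability and accumulates discounted state values cycle by cycle.
enumerate_totals <- function(tp, util, state_cost, upfront, init, qx, dr) {
  states <- health_states()
  n <- length(qx)
  Ps <- lapply(qx, function(q) build_transition_matrix(tp, q))
  paths <- as.matrix(expand.grid(rep(list(1:5), n + 1)))
  cost <- upfront; qaly <- 0
  init <- unname(init)
  util <- unname(util[states]); state_cost <- unname(state_cost[states])
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    pr <- init[s[1]]
    if (pr == 0) next
    for (t in seq_len(n)) pr <- pr * Ps[[t]][s[t], s[t + 1]]
    if (pr == 0) next
    disc <- (1 + dr)^-(seq_len(n))
    cost <- cost + pr * sum(state_cost[s[-1]] * disc)
    qaly <- qaly + pr * sum(util[s[-1]] * disc)
  }
  c(cost = cost, qaly = qaly)
}

# A tiny two-state-exit transition setup reused by engine tests.
toy_tp <- function(p_wi = 0.1, p_wa = 0.05, p_ci = 0.2, p_iw = 0.3,
                   p_ia = 0.1, p_aw = 0.05, p_ai = 0.05) {
  c(well.index_revision = p_wi, well.adjacent_revision = p_wa,
    complications.index_revision = p_ci, index_revision.well = p_iw,
    index_revision.adjacent_revision = p_ia, adjacent_revision.well = p_aw,
    adjacent_revision.index_revision = p_ai)
}
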