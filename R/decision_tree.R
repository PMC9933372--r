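# Short-term decision tree: allocation of the surgical cohort at cycle 0.

#' Initial state allocation from the decision tree
#'
#' The decision tree subclassifies patients by short-term surgical outcome
#' into the four alive Markov states. Branch probabilities are configuration
#' inputs; any state omitted from `tree_config` defaults to 0, and the
#' `well` share, when omitted, is the complement of the others. An empty or
#' `NULL` config therefore allocates the whole cohort to `well`.
#'
#' @param tree_config Named list/vector of branch probabilities over
#'   `well`, `complications`, `index_revision`, `adjacent_revision`.
#' @return Named probability vector over the five states (death = 0),
#'   summing to 1.
#' @export
initial_allocation <- function(tree_config = NULL) {
  states <- health_states()
  alive <- states[1:4]
  p <- stats::setNames(rep(0, 4), alive)
  if (length(tree_config)) {
    tree_config <- unlist(tree_config)
    unknown <- setdiff(names(tree_config), alive)
    if (length(unknown))
      stop("initial_allocation: unknown state(s): ",
           paste(unknown, collapse = ", "))
    if (any(tree_config < 0 | tree_config > 1))
      stop("initial_allocation: branch probabilities must lie in [0,1]")
    p[names(tree_config)] <- tree_config
  }
  if (!"well" %in% names(tree_config)) {
    rest <- sum(p[alive != "well"])
    if (rest > 1 + 1e-12)
      stop("initial_allocation: branch probabilities sum above 1")
    p["well"] <- 1 - rest
  }
  tot <- sum(p)
  if (tot > 1 + 1e-9)
    stop("initial_allocation: branch probabilities sum above 1")
  if (abs(tot - 1) > 1e-9)
    stop("initial_allocation: allocation must sum to 1 (got ", tot, ")")
  p <- p / sum(p)
  c(p, death = 0)
}
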