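# Deterministic (tornado) and probabilistic sensitivity analyses.

# Run both strategies under overridden values and return the incremental
# summary at a WTP. `values` is a named vector by parameter id.
.incremental <- function(pset, values = NULL, wtp) {
  mL <- .model_inputs(pset, "LLIF", values)
  mP <- .model_inputs(pset, "PLIF", values)
  qx <- .qx_vector(pset)
  s <- pset$settings
  hc <- isTRUE(s$half_cycle_correction)
  rL <- .engine(mL$tp, mL$util, mL$state_cost, mL$upfront,
                pset$tree$LLIF, qx, s$discount_rate, hc)
  rP <- .engine(mP$tp, mP$util, mP$state_cost, mP$upfront,
                pset$tree$PLIF, qx, s$discount_rate, hc)
  d_cost <- rP$cost - rL$cost
  d_qaly <- rP$qaly - rL$qaly
  c(cost_llif = rL$cost, qaly_llif = rL$qaly,
    cost_plif = rP$cost, qaly_plif = rP$qaly,
    d_cost = d_cost, d_qaly = d_qaly,
    icer = if (d_qaly == 0) NA_real_ else d_cost / d_qaly,
    nmb_diff = wtp * d_qaly - d_cost)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Each parameter row is set in turn to its low and then its high bound
#' with everything else at base case, and the output metric is recorded.
#' The primary metric is the incremental net monetary benefit at `wtp`
#' (stable in sign even when the incremental effect crosses zero at a
#' bound); the ICER at each bound is reported alongside. Entries are
#' sorted by descending spread.
#'
#' Rows flagged at load time (base case outside the printed range)
#' participate with their printed bounds and carry `flagged = TRUE`: their
#' spread measures the printed inconsistency as much as parameter
#' uncertainty, so [top_drivers()] skips them by default. Zero-width rows
#' have zero spread and sort last.
#'
#' @param pset A `cua_parameters` object.
#' @param wtp Willingness-to-pay for the NMB metric (default: configured
#'   threshold).
#' @return A `tornado` data frame: id, label, strategy, bounds, outputs at
#'   both bounds, spread, flagged, rank; base-case outputs in attributes.
#' @export
one_way_dsa <- function(pset, wtp = pset$settings$wtp) {
  stopifnot(inherits(pset, "cua_parameters"))
  tab <- pset$table
  base <- .incremental(pset, NULL, wtp)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    infeasible <- FALSE
    if (tab$degenerate[i]) {
      lo <- hi <- base
    } else {
      at_bound <- function(b) {
        v <- stats::setNames(b, tab$id[i])
        tryCatch(.incremental(pset, v, wtp), error = function(e) {
          infeasible <<- TRUE
          base * NA_real_
        })
      }
      lo <- at_bound(tab$low[i])
      hi <- at_bound(tab$high[i])
    }
    data.frame(id = tab$id[i], label = tab$label[i],
               strategy = tab$strategy[i],
               low = tab$low[i], high = tab$high[i],
               out_low = unname(lo["nmb_diff"]),
               out_high = unname(hi["nmb_diff"]),
               icer_low = unname(lo["icer"]),
               icer_high = unname(hi["icer"]),
               flagged = tab$flag_mean_outside[i] | infeasible)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$out_high - out$out_low)
  out <- out[order(-out$spread), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("tornado", "data.frame"),
            base = base, wtp = wtp, metric = "nmb_diff")
}

#' Leading drivers of a tornado
#'
#' @param tornado A [one_way_dsa()] result.
#' @param n Number of drivers.
#' @param include_flagged Include rows whose base case lies outside their
#'   own printed range? Default `FALSE`: such spreads are artefacts of the
#'   inconsistent printed bounds.
#' @return Character vector of parameter ids, largest spread first.
#' @export
top_drivers <- function(tornado, n = 3, include_flagged = FALSE) {
  stopifnot(inherits(tornado, "tornado"))
  t2 <- if (include_flagged) tornado else tornado[!tornado$flagged, ]
  utils::head(t2$id, n)
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n_sims` Monte Carlo simulations. In each, every moment-feasible
#' parameter is drawn once from its fitted beta/gamma distribution and
#' both strategies' cohorts are evaluated on the same draw set.
#'
#' Draws are inverse-CDF transforms of stratified (Latin hypercube)
#' uniforms, one uniform column per *draw group*: rows sharing a group --
#' utilities of the same health state across strategies, transition rows
#' repeating the same printed source estimate within a strategy, cost rows
#' shared between strategies -- move together (common random numbers),
#' while distinct evidence sources vary independently. Zero-width and
#' moment-infeasible rows are held at base case and listed in
#' `$held_fixed`.
#'
#' @param pset A `cua_parameters` object.
#' @param n_sims Number of simulations (>= 1); 1000 in the primary
#'   analysis.
#' @param seed Integer seed; identical seeds give identical results.
#' @param wtp Threshold used for summary probabilities.
#' @param method `"lhs"` (stratified, default) or `"simple"` (plain
#'   `runif`).
#' @return A `psa_result`: `draws` data frame (per-simulation costs,
#'   QALYs, increments), `base`, `held_fixed`, `seed`, `wtp`.
#' @export
run_psa <- function(pset, n_sims = 1000, seed = 1L,
                    wtp = pset$settings$wtp,
                    method = c("lhs", "simple")) {
  stopifnot(inherits(pset, "cua_parameters"))
  if (n_sims < 1) stop("run_psa: n_sims must be at least 1")
  method <- match.arg(method)
  tab <- pset$table
  samp <- which(tab$sample_ok)
  held <- tab$id[!tab$sample_ok]
  groups <- unique(tab$draw_group[samp])
  set.seed(seed)
  U <- if (!length(groups)) matrix(numeric(0), n_sims, 0)
  else if (method == "lhs") lhs::randomLHS(n_sims, length(groups))
  else matrix(stats::runif(n_sims * length(groups)), n_sims)
  colnames(U) <- groups

  # precompute per-sampled-row quantile transforms
  gi <- match(tab$draw_group[samp], groups)
  vals_mat <- matrix(rep(tab$mean, each = n_sims), n_sims,
                     dimnames = list(NULL, tab$id))
  for (k in seq_along(samp)) {
    i <- samp[k]
    u <- U[, gi[k]]
    vals_mat[, i] <- if (tab$family[i] == "beta")
      stats::qbeta(u, tab$hp1[i], tab$hp2[i])
    else stats::qgamma(u, shape = tab$hp1[i], rate = tab$hp2[i])
  }

  draws <- matrix(NA_real_, n_sims, 8)
  for (s in seq_len(n_sims)) {
    draws[s, ] <- .incremental(pset, vals_mat[s, ], wtp)
  }
  colnames(draws) <- c("cost_llif", "qaly_llif", "cost_plif", "qaly_plif",
                       "d_cost", "d_qaly", "icer", "nmb_diff")
  draws <- data.frame(sim = seq_len(n_sims), draws)
  structure(list(draws = draws, n_sims = n_sims, seed = seed, wtp = wtp,
                 method = method,
                 base = .incremental(pset, NULL, wtp),
                 sampled = tab$id[samp], held_fixed = held),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d simulations (seed %d, %s draws)\n",
              x$n_sims, x$seed, x$method))
  cat(sprintf("  mean d_cost %.0f USD, mean d_qaly %.3f QALY\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly)))
  cat(sprintf("  P(incremental NMB > 0 at WTP %s): %.1f%%\n",
              format(x$wtp, big.mark = ","),
              100 * mean(x$draws$nmb_diff > 0)))
  if (length(x$held_fixed))
    cat("  held fixed:", paste(x$held_fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Probability a strategy is cost-effective at a threshold
#'
#' Fraction of PSA simulations in which the strategy has the higher net
#' monetary benefit at `wtp`.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Willingness-to-pay threshold.
#' @param strategy `"LLIF"` or `"PLIF"`.
#' @return Probability in `[0, 1]`.
#' @export
prob_cost_effective <- function(psa, wtp, strategy = c("LLIF", "PLIF")) {
  stopifnot(inherits(psa, "psa_result"))
  strategy <- match.arg(strategy)
  dn <- wtp * psa$draws$d_qaly - psa$draws$d_cost  # NMB(PLIF) - NMB(LLIF)
  if (strategy == "PLIF") mean(dn > 0) else mean(dn <= 0)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay on the grid, the probability that each
#' strategy is cost-effective is the fraction of simulations in which its
#' net monetary benefit is highest; the two probabilities sum to 1.
#' `prob_incremental` repeats `prob_plif` under its decision-theoretic
#' name -- the probability that the incremental NMB of the costlier,
#' more effective strategy is positive, i.e. that the per-draw ICER falls
#' below the threshold -- which is the quantity the published
#' acceptability curve reports for the intervention (see the methods
#' vignette on this labelling).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Ascending grid of thresholds (default 0--40,000 USD in
#'   steps of 100).
#' @return A `ceac` data frame: `wtp`, `prob_llif`, `prob_plif`,
#'   `prob_incremental`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 40000, by = 100)) {
  stopifnot(inherits(psa, "psa_result"))
  if (!length(wtp_grid)) stop("ceac: empty WTP grid")
  if (is.unsorted(wtp_grid)) stop("ceac: WTP grid must be ascending")
  dq <- psa$draws$d_qaly; dc <- psa$draws$d_cost
  p_plif <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_llif = 1 - p_plif,
                       prob_plif = p_plif, prob_incremental = p_plif),
            class = c("ceac", "data.frame"))
}

#' Switch-point willingness-to-pay
#'
#' The threshold at which the preferred strategy changes: the first
#' crossing of the 0.5 level by the acceptability curve, linearly
#' interpolated between the last grid point strictly below 0.5 and the
#' first strictly above (so a flat stretch at exactly 0.5 -- ties between
#' the strategies -- is bisected, which makes the estimate agree with the
#' median of the per-simulation indifference thresholds as the grid is
#' refined).
#'
#' @param curve A [ceac()] data frame.
#' @return The switch WTP in USD/QALY, or `NA` with attribute
#'   `marker = "no switch in range"` when no crossing occurs on the grid.
#' @export
switch_wtp <- function(curve) {
  stopifnot(inherits(curve, "ceac"))
  p <- curve$prob_plif
  rising <- p[1] < 0.5
  above <- if (rising) which(p > 0.5) else which(p < 0.5)
  if (!length(above) || above[1] == 1)
    return(structure(NA_real_, marker = "no switch in range"))
  iU <- above[1]
  below <- if (rising) which(p[seq_len(iU - 1)] < 0.5)
  else which(p[seq_len(iU - 1)] > 0.5)
  if (!length(below))
    return(structure(NA_real_, marker = "no switch in range"))
  iL <- max(below)
  w0 <- curve$wtp[iL]; w1 <- curve$wtp[iU]
  p0 <- p[iL]; p1 <- p[iU]
  w0 + (w1 - w0) * (0.5 - p0) / (p1 - p0)
}
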