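# Incremental cost-effectiveness: ICER, CE-plane quadrant, net monetary
# benefit, willingness-to-pay conversion.
#
# Orientation: increments are computed as PLIF minus LLIF throughout, the
# orientation under which both printed increments are positive. The
# CE-plane quadrant is labelled for LLIF relative to PLIF (the published
# plane), so the base case -- LLIF cheaper and less effective -- sits in
# the SW quadrant.

#' Compare two strategies' lifetime totals
#'
#' @param cost_llif,qaly_llif,cost_plif,qaly_plif Lifetime discounted
#'   totals per strategy.
#' @param wtp Willingness-to-pay threshold (USD/QALY) used for the net
#'   monetary benefit comparison; default 5003.
#' @return A `cea_result`: per-strategy totals, `d_cost` and `d_qaly`
#'   (PLIF - LLIF), the ICER (NA with marker `"equal effectiveness"` when
#'   `d_qaly` is 0), the CE-plane quadrant of LLIF vs PLIF, dominance
#'   label if any, per-strategy NMB at `wtp` and the NMB-preferred
#'   strategy.
#' @export
compute_icer <- function(cost_llif, qaly_llif, cost_plif, qaly_plif,
                         wtp = 5003) {
  vals <- c(cost_llif, qaly_llif, cost_plif, qaly_plif)
  if (!all(is.finite(vals))) stop("compute_icer: non-finite input")
  if (qaly_llif <= 0 || qaly_plif <= 0)
    stop("compute_icer: QALY totals must be positive")
  d_cost <- cost_plif - cost_llif
  d_qaly <- qaly_plif - qaly_llif
  icer <- if (d_qaly == 0) NA_real_ else d_cost / d_qaly
  # quadrant of LLIF relative to PLIF on the CE plane (x = d effect,
  # y = d cost, both LLIF - PLIF)
  qx <- -d_qaly; qy <- -d_cost
  quadrant <- if (qx >= 0 && qy >= 0) "NE" else if (qx < 0 && qy >= 0) "NW"
  else if (qx >= 0 && qy < 0) "SE" else "SW"
  dominance <- if (d_cost < 0 && d_qaly > 0) "PLIF dominant"
  else if (d_cost > 0 && d_qaly < 0) "LLIF dominant"
  else "none"
  nmb_l <- net_monetary_benefit(cost_llif, qaly_llif, wtp)
  nmb_p <- net_monetary_benefit(cost_plif, qaly_plif, wtp)
  structure(list(
    strategies = data.frame(
      strategy = c("LLIF", "PLIF"),
      cost = c(cost_llif, cost_plif),
      qaly = c(qaly_llif, qaly_plif)),
    d_cost = d_cost, d_qaly = d_qaly,
    icer = icer,
    icer_marker = if (d_qaly == 0) "equal effectiveness" else NA_character_,
    quadrant = quadrant, dominance = dominance,
    orientation = "PLIF minus LLIF",
    wtp = wtp, nmb = c(LLIF = nmb_l, PLIF = nmb_p),
    preferred = if (nmb_l >= nmb_p) "LLIF" else "PLIF"),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>  (increments: ", x$orientation, ")\n", sep = "")
  print(transform(x$strategies, cost = round(cost), qaly = round(qaly, 2)),
        row.names = FALSE)
  cat(sprintf("  d_cost %.0f USD, d_qaly %.4f QALY, ICER %s USD/QALY\n",
              x$d_cost, x$d_qaly,
              if (is.na(x$icer)) x$icer_marker else sprintf("%.0f", x$icer)))
  cat(sprintf("  LLIF in %s quadrant; NMB-preferred at WTP %s: %s\n",
              x$quadrant, format(x$wtp, big.mark = ","), x$preferred))
  invisible(x)
}

#' Net monetary benefit
#'
#' NMB = WTP x QALY - cost. The strategy with the higher NMB at a given
#' willingness-to-pay is preferred at that threshold.
#'
#' @param cost,qaly Lifetime totals.
#' @param wtp Willingness-to-pay (USD/QALY), non-negative.
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(cost, qaly, wtp) {
  if (wtp < 0) stop("net_monetary_benefit: wtp must be non-negative")
  if (!all(is.finite(c(cost, qaly, wtp))))
    stop("net_monetary_benefit: non-finite input")
  wtp * qaly - cost
}

#' Preferred strategy by the quadrant-aware ICER rule
#'
#' Decision rule equivalent to the NMB comparison in every CE-plane
#' quadrant: with increments oriented PLIF minus LLIF, PLIF dominates when
#' cheaper and more effective (and vice versa); in the NE quadrant (PLIF
#' costlier, more effective) PLIF is preferred iff the ICER falls below
#' the WTP; in the SW quadrant (PLIF cheaper, less effective -- i.e. LLIF
#' costlier and more effective) the cheaper PLIF is preferred iff the ICER
#' of moving back to LLIF exceeds the WTP.
#'
#' @param cea A `cea_result`.
#' @param wtp Willingness-to-pay threshold.
#' @return `"LLIF"` or `"PLIF"`.
#' @export
preferred_strategy <- function(cea, wtp) {
  stopifnot(inherits(cea, "cea_result"))
  dc <- cea$d_cost; dq <- cea$d_qaly
  if (dq == 0) return(if (dc < 0) "PLIF" else "LLIF")
  if (dc <= 0 && dq > 0) return("PLIF")
  if (dc > 0 && dq < 0) return("LLIF")
  r <- dc / dq
  if (dq > 0) {          # PLIF costlier & more effective (NE for PLIF)
    if (r < wtp) "PLIF" else "LLIF"
  } else {               # PLIF cheaper & less effective (LLIF costlier & better)
    if (r <= wtp) "LLIF" else "PLIF"
  }
}

#' Convert a willingness-to-pay threshold to USD per QALY
#'
#' @param thb_per_qaly Threshold in THB per QALY.
#' @param thb_per_usd Exchange rate, THB per USD.
#' @return Integer USD per QALY (rounded to the nearest dollar).
#' @export
wtp_threshold_usd <- function(thb_per_qaly, thb_per_usd) {
  if (thb_per_qaly <= 0 || thb_per_usd <= 0)
    stop("wtp_threshold_usd: inputs must be positive")
  round(thb_per_qaly / thb_per_usd)
}
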