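# End-to-end runs, artifact export and run manifests.

.manifest <- function(pset, seed = NULL, artifacts = character(0)) {
  list(created = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
       package_version = as.character(utils::packageVersion("lumbarCUA")),
       config_path = pset$path,
       config_md5 = unname(tools::md5sum(pset$path)),
       seed = seed,
       artifacts = artifacts,
       warnings = pset$warnings)
}

#' Run the base-case analysis
#'
#' Runs both strategies' cohorts at base-case parameter values and
#' assembles the incremental comparison. With `out_dir` set, writes the
#' base-case table (`base_case.csv`, one row per strategy mirroring the
#' published layout), both cohort traces and a JSON run manifest listing
#' every artifact and all loader warnings (flagged rows, calibrated
#' inputs); the run is deterministic, so identical configs give
#' byte-identical tables.
#'
#' @param pset A `cua_parameters` object.
#' @param out_dir Optional output directory (created if needed).
#' @return List with `cea` (a `cea_result`), `traces` (per strategy) and
#'   `manifest`.
#' @export
run_base_case <- function(pset, out_dir = NULL) {
  stopifnot(inherits(pset, "cua_parameters"))
  L <- run_strategy(pset, "LLIF")
  P <- run_strategy(pset, "PLIF")
  cea <- compute_icer(L$cost, L$qaly, P$cost, P$qaly,
                      wtp = pset$settings$wtp)
  artifacts <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(
      strategy = c("LLIF", "PLIF"),
      cost_usd = c(L$cost, P$cost),
      effectiveness_qaly = c(L$qaly, P$qaly),
      incremental_cost_usd = c(NA, cea$d_cost),
      incremental_effectiveness_qaly = c(NA, cea$d_qaly),
      icer_usd_per_qaly = c(cea$icer, NA))
    f1 <- file.path(out_dir, "base_case.csv")
    utils::write.csv(tab, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "trace_LLIF.csv")
    f3 <- file.path(out_dir, "trace_PLIF.csv")
    write_trace_csv(L$trace, f2)
    write_trace_csv(P$trace, f3)
    artifacts <- c(f1, f2, f3)
  }
  man <- .manifest(pset, artifacts = artifacts)
  if (!is.null(out_dir)) {
    mf <- file.path(out_dir, "manifest_base_case.json")
    jsonlite::write_json(man, mf, auto_unbox = TRUE, pretty = TRUE)
  }
  for (w in pset$warnings) message("note: ", w)
  list(cea = cea, traces = list(LLIF = L$trace, PLIF = P$trace),
       manifest = man)
}

#' Run the complete analysis
#'
#' Base case, one-way DSA (tornado), PSA, acceptability curves and the
#' switch-point WTP, all from one root seed. With `out_dir` set, emits
#' `base_case.csv`, `tornado.csv`, `psa_draws.csv`, `ceac.csv` and
#' `summary.json`, plus a manifest naming them.
#'
#' @param pset A `cua_parameters` object.
#' @param n_sims PSA simulations (>= 1; 1000 in the primary analysis).
#' @param seed Root seed for the PSA draws.
#' @param wtp_grid CEAC grid.
#' @param out_dir Optional output directory.
#' @return List with `base`, `tornado`, `psa`, `ceac`, `switch_wtp`,
#'   `prob_incremental_at_wtp`, `manifest`.
#' @export
run_full_analysis <- function(pset, n_sims = 1000, seed = 1L,
                              wtp_grid = seq(0, 40000, by = 100),
                              out_dir = NULL) {
  if (n_sims < 1) stop("run_full_analysis: n_sims must be at least 1")
  base <- run_base_case(pset, out_dir = out_dir)
  tor <- one_way_dsa(pset)
  psa <- run_psa(pset, n_sims = n_sims, seed = seed)
  cv <- ceac(psa, wtp_grid)
  sw <- switch_wtp(cv)
  p_inc <- prob_cost_effective(psa, pset$settings$wtp, "PLIF")
  artifacts <- base$manifest$artifacts
  if (!is.null(out_dir)) {
    f_t <- file.path(out_dir, "tornado.csv")
    utils::write.csv(as.data.frame(tor), f_t, row.names = FALSE)
    f_p <- file.path(out_dir, "psa_draws.csv")
    utils::write.csv(psa$draws, f_p, row.names = FALSE)
    f_c <- file.path(out_dir, "ceac.csv")
    utils::write.csv(as.data.frame(cv), f_c, row.names = FALSE)
    f_s <- file.path(out_dir, "summary.json")
    jsonlite::write_json(list(
      base_case = list(
        cost = stats::setNames(base$cea$strategies$cost, c("LLIF", "PLIF")),
        qaly = stats::setNames(base$cea$strategies$qaly, c("LLIF", "PLIF")),
        d_cost = base$cea$d_cost, d_qaly = base$cea$d_qaly,
        icer = base$cea$icer),
      psa = list(n_sims = n_sims, seed = seed,
                 prob_incremental_nmb_positive_at_wtp = p_inc,
                 switch_wtp = sw),
      top_drivers = top_drivers(tor)),
      f_s, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    artifacts <- c(artifacts, f_t, f_p, f_c, f_s)
    man <- .manifest(pset, seed = seed, artifacts = artifacts)
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else man <- .manifest(pset, seed = seed)
  list(base = base$cea, tornado = tor, psa = psa, ceac = cv,
       switch_wtp = sw, prob_incremental_at_wtp = p_inc, manifest = man)
}

#' Cost-effectiveness plane of the PSA draws
#'
#' Scatter of the per-simulation increments, with LLIF relative to PLIF
#' on both axes (the published orientation: most draws fall in the lower
#' left quadrant) and the WTP threshold line.
#'
#' @param psa A [run_psa()] result.
#' @param wtp Threshold line slope.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = psa$wtp) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ce_plane needs ggplot2")
  d <- data.frame(d_qaly = -psa$draws$d_qaly, d_cost = -psa$draws$d_cost)
  ggplot2::ggplot(d, ggplot2::aes(.data$d_qaly, .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental effectiveness, LLIF - PLIF (QALY)",
                  y = "Incremental cost, LLIF - PLIF (USD)")
}

#' Acceptability curves
#'
#' @param curve A [ceac()] data frame.
#' @return A ggplot object with one curve per strategy.
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ceac needs ggplot2")
  d <- rbind(
    data.frame(wtp = curve$wtp, p = curve$prob_llif, strategy = "LLIF"),
    data.frame(wtp = curve$wtp, p = curve$prob_plif, strategy = "PLIF"))
  ggplot2::ggplot(d, ggplot2::aes(.data$wtp, .data$p,
                                  colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability cost-effective")
}

#' Tornado diagram
#'
#' @param tornado A [one_way_dsa()] result.
#' @param n Number of leading parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, n = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_tornado needs ggplot2")
  base <- attr(tornado, "base")["nmb_diff"]
  d <- utils::head(as.data.frame(tornado), n)
  d$label <- factor(d$label, levels = rev(d$label))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$out_low,
                                       xend = .data$out_high,
                                       yend = .data$label), linewidth = 4,
                          colour = "steelblue") +
    ggplot2::geom_vline(xintercept = unname(base), linetype = 2) +
    ggplot2::labs(x = "Incremental NMB at threshold (USD)", y = NULL)
}
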