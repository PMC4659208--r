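#' Calibrate distal resistances to a target CBF and efferent split
#'
#' The circle segments alone are far less resistive than the distal beds
#' they feed, so the raw network over-perfuses. Calibration finds one
#' resistance scale factor per efferent territory (ACA, MCA, PCA) — applied
#' as appended distal resistive elements, i.e. multipliers on the efferent
#' segment resistances — such that the solved complete, unstenosed network
#' carries the target total cerebral blood flow split in the target
#' proportions. Each factor is found by monotone bisection on its
#' territory's flow, cycling over territories until all targets are met.
#'
#' @param network A complete, unstenosed \code{cow_network}.
#' @param boundary A [build_boundary_set()] object.
#' @param params A [carreau_parameters()] object.
#' @param total_cbf Target total flow, ml/s (default from \code{boundary}'s
#'   perfusion constants).
#' @param fractions Named fractions \code{c(ACA=, MCA=, PCA=)} (default from
#'   \code{boundary}).
#' @param settings A [solver_settings()] object.
#' @param flow_tolerance Relative tolerance on each territory flow
#'   (default 1e-3, comfortably inside 0.5 % on the total and 1 % absolute
#'   on the split).
#' @param max_cycles Maximum territory-bisection cycles.
#'
#' @return The calibrated \code{cow_network}; scale factors live in the
#'   \code{r_scale} column of \code{$segments} and are persisted by
#'   [write_segments()].
#' @export
#'
#' @examples
#' \donttest{
#' net <- build_complete_cow() |> calibrate()
#' glance(solve_flows(net))
#' }
calibrate <- function(network,
                      boundary = build_boundary_set(),
                      params = carreau_parameters(),
                      total_cbf = boundary$constants$total_cbf,
                      fractions = c(ACA = boundary$constants$fraction_aca,
                                    MCA = boundary$constants$fraction_mca,
                                    PCA = boundary$constants$fraction_pca),
                      settings = solver_settings(),
                      flow_tolerance = 1e-3,
                      max_cycles = 40) {
  stopifnot(inherits(network, "cow_network"))
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must sum to 1.")
  }
  nodes <- network$nodes
  seg <- network$segments
  eff <- seg[seg$klass == "efferent", ]
  territory_of <- setNames(nodes$territory, nodes$node)
  eff_territory <- territory_of[eff$to]
  if (any(is.na(eff_territory))) {
    abort("Every efferent segment must end at an outlet node with a territory.")
  }

  class_flow <- function(net, territory) {
    sol <- solve_flows(net, boundary, params, settings)
    if (!sol$converged) abort("Solver failed to converge during calibration.")
    ids <- eff$id[eff_territory == territory]
    sum(sol$segment_flows$flow_ml_s[sol$segment_flows$id %in% ids])
  }

  set_scale <- function(net, territory, s) {
    ids <- eff$id[eff_territory == territory]
    net$segments$r_scale[net$segments$id %in% ids] <- s
    net
  }

  targets <- total_cbf * fractions[c("ACA", "MCA", "PCA")]
  scales <- c(ACA = 1, MCA = 1, PCA = 1)
  net <- network

  for (cycle in seq_len(max_cycles)) {
    worst <- 0
    for (tr in names(targets)) {
      target <- targets[[tr]]
      # bracket: flow is strictly decreasing in the scale factor
      lo <- scales[[tr]] / 64
      hi <- scales[[tr]]
      while (class_flow(set_scale(net, tr, hi), tr) > target && hi < 1e6) {
        hi <- hi * 4
      }
      while (class_flow(set_scale(net, tr, lo), tr) < target && lo > 1e-9) {
        lo <- lo / 4
      }
      f_hi <- class_flow(set_scale(net, tr, hi), tr)
      f_lo <- class_flow(set_scale(net, tr, lo), tr)
      if (f_hi > target || f_lo < target) {
        abort(paste0("Calibration target unattainable for territory ", tr,
                     " (check that outlet pressures are below the inlet)."))
      }
      for (i in seq_len(60)) {
        mid <- sqrt(lo * hi)
        f <- class_flow(set_scale(net, tr, mid), tr)
        if (f > target) lo <- mid else hi <- mid
        if (abs(f - target) / target < flow_tolerance / 4) break
      }
      scales[[tr]] <- sqrt(lo * hi)
      net <- set_scale(net, tr, scales[[tr]])
    }
    flows <- vapply(names(targets), function(tr) class_flow(net, tr),
                    numeric(1))
    worst <- max(abs(flows - targets) / targets)
    if (worst < flow_tolerance) break
  }
  if (worst >= flow_tolerance) {
    warn(sprintf(
      "Calibration stopped at relative territory-flow error %.2e.", worst))
  }
  net
}
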