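#' Published total flow rates across configurations and stenosis degrees
#'
#' Packaged reference table of total cerebral flow rates (ml/s) for the six
#' network configurations under right-ICA stenosis degrees
#' 0/25/50/75/90/100 %, as printed in the source study this table was
#' transcribed from. Used by the percentage-change reproduction test; these
#' are 3D-CFD results on an unpublished patient geometry and are not
#' reproduced by the lumped solver.
#'
#' @return A long tibble \code{variant, degree, total_flow_ml_s}.
#' @export
#'
#' @examples
#' reference_total_flows() |> percentage_change_table()
reference_total_flows <- function() {
  path <- system.file("extdata", "table1_total_flows.csv",
                      package = "willisflow", mustWork = TRUE)
  read.csv(path, check.names = FALSE) |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(-"degree", names_to = "variant",
                        values_to = "total_flow_ml_s") |>
    dplyr::arrange(match(.data$variant, COW_VARIANTS), .data$degree)
}

#' Run the variant-by-stenosis experiment grid
#'
#' Applies each anatomical variant and each right-ICA stenosis degree to the
#' calibrated geometry, solves every cell, and collects totals, per-efferent
#' flows and signed communicating-artery flows. Solver failures in single
#' cells are flagged and the sweep continues.
#'
#' @param network A calibrated, complete \code{cow_network} (see
#'   [calibrate()]).
#' @param boundary A [build_boundary_set()] object.
#' @param params A [carreau_parameters()] object.
#' @param variants Character vector of variants (default all six).
#' @param degrees Stenosis degrees in percent (default the 0/25/50/75/90/100
#'   grid).
#' @param target_segment Stenosed segment (default \code{"RICA"}).
#' @param stenotic_length Axial stenosis extent, mm.
#' @param settings A [solver_settings()] object.
#'
#' @return An object of class \code{cow_sweep}: a list with \code{results}
#'   (one tibble row per cell: variant, degree, converged, total flow,
#'   per-efferent flows, signed ACoA/RPCoA/LPCoA flows) and the inputs.
#'   [tidy()] gives a long (variant, degree, quantity, value) view.
#' @export
run_sweep <- function(network,
                      boundary = build_boundary_set(),
                      params = carreau_parameters(),
                      variants = COW_VARIANTS,
                      degrees = c(0, 25, 50, 75, 90, 100),
                      target_segment = "RICA",
                      stenotic_length = 10,
                      settings = solver_settings()) {
  stopifnot(inherits(network, "cow_network"))
  variants <- match.arg(variants, COW_VARIANTS, several.ok = TRUE)
  if (any(degrees < 0 | degrees > 100)) {
    abort("`degrees` must lie in [0, 100].")
  }
  efferent_ids <- network$segments$id[network$segments$klass == "efferent"]

  cells <- tidyr::expand_grid(variant = variants, degree = degrees)
  rows <- purrr::pmap(cells, function(variant, degree) {
    net <- network |>
      apply_variant(variant) |>
      apply_stenosis(degree, target_segment = target_segment,
                     stenotic_length = stenotic_length)
    sol <- solve_flows(net, boundary, params, settings)
    eff <- sol$segment_flows |>
      dplyr::filter(.data$id %in% efferent_ids)
    comm <- communicating_flows(sol)
    dplyr::bind_cols(
      tibble::tibble(variant = variant, degree = degree,
                     converged = sol$converged,
                     total_flow_ml_s = total_efferent_flow(sol),
                     max_mass_residual = sol$max_mass_residual,
                     iterations = sol$iterations),
      tidyr::pivot_wider(eff[, c("id", "flow_ml_s")],
                         names_from = "id", values_from = "flow_ml_s"),
      tidyr::pivot_wider(comm[, c("segment", "flow_ml_s")],
                         names_from = "segment", values_from = "flow_ml_s")
    )
  })
  results <- dplyr::bind_rows(rows)
  if (any(!results$converged)) {
    warn(sprintf("%d sweep cell(s) did not converge; see $results$converged.",
                 sum(!results$converged)))
  }
  structure(
    list(results = results, network = network, boundary = boundary,
         params = params, settings = settings,
         reference_cell = c(variant = "COMPLETE", degree = "0")),
    class = "cow_sweep"
  )
}

#' @export
print.cow_sweep <- function(x, ...) {
  cat(sprintf("Stenosis sweep: %d cells (%d variants x %d degrees), %s\n",
              nrow(x$results),
              length(unique(x$results$variant)),
              length(unique(x$results$degree)),
              if (all(x$results$converged)) "all converged"
              else "with non-converged cells"))
  print(x$results)
  invisible(x)
}

#' Tidy a sweep into long format
#'
#' @param x A \code{cow_sweep}.
#' @param ... Unused.
#'
#' @return Tibble \code{variant, degree, quantity, value}.
#' @export
tidy.cow_sweep <- function(x, ...) {
  x$results |>
    dplyr::select(-"converged", -"iterations") |>
    tidyr::pivot_longer(-c("variant", "degree"),
                        names_to = "quantity", values_to = "value")
}

#' Percentage change of total flow against a reference cell
#'
#' Each total is compared with the reference flow (by default the complete
#' configuration at 0 % stenosis):
#' \eqn{100 (Q - Q_{ref}) / Q_{ref}}. The \code{pct_change_reported} column
#' applies two-decimal rounding (half away from zero), the convention of the
#' published tables.
#'
#' @param flow_table Long tibble \code{variant, degree, total_flow_ml_s}
#'   (e.g. [reference_total_flows()] or \code{sweep$results}).
#' @param reference Reference flow in ml/s; default the table's
#'   \code{(COMPLETE, 0)} entry.
#'
#' @return The input plus \code{pct_change} and \code{pct_change_reported}.
#' @export
#'
#' @examples
#' reference_total_flows() |> percentage_change_table()
percentage_change_table <- function(flow_table, reference = NULL) {
  flow_table <- tibble::as_tibble(flow_table)
  if (!all(c("variant", "degree", "total_flow_ml_s") %in% names(flow_table))) {
    abort("`flow_table` needs columns variant, degree, total_flow_ml_s.")
  }
  if (is.null(reference)) {
    ref_row <- flow_table |>
      dplyr::filter(.data$variant == "COMPLETE", .data$degree == 0)
    if (nrow(ref_row) != 1) {
      abort("Reference cell (COMPLETE, degree 0) not found; pass `reference`.")
    }
    reference <- ref_row$total_flow_ml_s
  }
  if (!is.numeric(reference) || reference <= 0) {
    abort("`reference` must be a positive flow in ml/s.")
  }
  flow_table |>
    dplyr::mutate(
      pct_change = 100 * (.data$total_flow_ml_s - reference) / reference,
      pct_change_reported = round_half_away(.data$pct_change, 2)
    )
}

#' Signed communicating-artery flows of a solution
#'
#' Maps the graph-oriented ACoA, right-PCoA and left-PCoA flows onto the
#' conventional signs: positive ACoA flow runs towards the right hemisphere,
#' positive PCoA flow feeds the anterior circulation. Segments absent from
#' the topology are reported as \code{NA} (not applicable), never as zero.
#'
#' @param solution A \code{cow_flow_solution}.
#'
#' @return Tibble \code{segment, flow_ml_s, present}.
#' @export
communicating_flows <- function(solution) {
  stopifnot(inherits(solution, "cow_flow_solution"))
  seg <- solution$network$segments
  # canonical positive orientations (see build_complete_cow)
  canon <- list(ACoA = c("L_ant", "R_ant"),
                RPCoA = c("R_post", "R_ICA_term"),
                LPCoA = c("L_post", "L_ICA_term"))
  purrr::map_dfr(names(canon), function(id) {
    row <- seg[seg$id == id, ]
    if (nrow(row) == 0) {
      return(tibble::tibble(segment = id, flow_ml_s = NA_real_,
                            present = FALSE))
    }
    q <- solution$segment_flows$flow_ml_s[solution$segment_flows$id == id]
    flip <- !identical(c(row$from, row$to), canon[[id]])
    tibble::tibble(segment = id,
                   flow_ml_s = if (flip) -q else q,
                   present = TRUE)
  })
}

#' Stenosis degree at which a flow changes direction
#'
#' Scans a signed flow series along increasing stenosis degree and returns
#' the first sign reversal, linearly interpolated between the last
#' same-sign and first opposite-sign samples. A sampled flow of exactly zero
#' is itself the reversal point. Returns \code{NA} when the sign never
#' changes.
#'
#' @param degrees Stenosis degrees in percent (>= 2 values).
#' @param flows Signed flows (ml/s), same length.
#'
#' @return The reversal degree in percent, or \code{NA_real_}.
#' @export
#'
#' @examples
#' find_reversal_point(c(0, 50, 100), c(1, 0.5, -0.5))
find_reversal_point <- function(degrees, flows) {
  if (length(degrees) != length(flows) || length(degrees) < 2) {
    abort("`degrees` and `flows` must have equal length >= 2.")
  }
  ord <- order(degrees)
  d <- degrees[ord]
  q <- flows[ord]
  if (any(q == 0)) {
    return(d[which(q == 0)[1]])
  }
  s <- sign(q)
  flip <- which(s[-1] != s[-length(s)])
  if (length(flip) == 0) {
    return(NA_real_)
  }
  i <- flip[1]
  d[i] + (d[i + 1] - d[i]) * abs(q[i]) / (abs(q[i]) + abs(q[i + 1]))
}

#' Rank variants by total flow at one stenosis degree
#'
#' @param sweep A \code{cow_sweep}.
#' @param degree A degree sampled in the sweep.
#'
#' @return Tibble \code{rank, variant, total_flow_ml_s}, highest flow first;
#'   ties broken alphabetically by variant.
#' @export
rank_configurations <- function(sweep, degree) {
  stopifnot(inherits(sweep, "cow_sweep"))
  rows <- dplyr::filter(sweep$results, .data$degree == !!degree)
  if (nrow(rows) == 0) {
    abort("`degree` was not sampled in this sweep.")
  }
  rows |>
    dplyr::arrange(dplyr::desc(.data$total_flow_ml_s), .data$variant) |>
    dplyr::transmute(rank = dplyr::row_number(), .data$variant,
                     .data$total_flow_ml_s)
}

#' Reversal points of the communicating arteries across a sweep
#'
#' Applies [find_reversal_point()] to each communicating artery's signed
#' flow series within each variant of a sweep.
#'
#' @param sweep A \code{cow_sweep}.
#'
#' @return Tibble \code{variant, segment, reversal_degree}.
#' @export
reversal_points <- function(sweep) {
  stopifnot(inherits(sweep, "cow_sweep"))
  sweep$results |>
    dplyr::select("variant", "degree", "ACoA", "RPCoA", "LPCoA") |>
    tidyr::pivot_longer(c("ACoA", "RPCoA", "LPCoA"),
                        names_to = "segment", values_to = "flow_ml_s") |>
    dplyr::filter(!is.na(.data$flow_ml_s)) |>
    dplyr::group_by(.data$variant, .data$segment) |>
    dplyr::summarise(
      reversal_degree = find_reversal_point(.data$degree, .data$flow_ml_s),
      .groups = "drop"
    )
}
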