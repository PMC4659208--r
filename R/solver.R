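#' Solver settings for the Picard iteration
#'
#' @param max_iterations Maximum Picard iterations.
#' @param relative_tolerance Convergence threshold on the relative change of
#'   all segment flows between iterations.
#' @param under_relaxation Flow update relaxation factor in (0, 1]; 0.5 is
#'   robust for monotone shear-thinning laws.
#'
#' @return An object of class \code{solver_settings}.
#' @export
solver_settings <- function(max_iterations = 200,
                            relative_tolerance = 1e-8,
                            under_relaxation = 0.5) {
  if (max_iterations < 1) abort("`max_iterations` must be >= 1.")
  if (relative_tolerance <= 0) abort("`relative_tolerance` must be > 0.")
  if (under_relaxation <= 0 || under_relaxation > 1) {
    abort("`under_relaxation` must lie in (0, 1].")
  }
  structure(
    list(max_iterations = as.integer(max_iterations),
         relative_tolerance = relative_tolerance,
         under_relaxation = under_relaxation),
    class = "solver_settings"
  )
}

#' Poiseuille resistance of a segment at a given flow
#'
#' \eqn{R = 128\,\mu_{eff}(Q, d)\,L / (\pi d^4)}, with the effective
#' viscosity from the Carreau law evaluated at the Poiseuille wall shear
#' rate, converted to the package's mixed unit system (mmHg per ml/s).
#' \code{r_scale} multiplies the result and is how calibrated distal
#' resistive elements are attached to efferent segments.
#'
#' @param flow Flow in ml/s (sign ignored).
#' @param length_mm Segment length, mm.
#' @param diameter_mm Segment diameter, mm.
#' @param params A [carreau_parameters()] object.
#' @param r_scale Dimensionless resistance scale (default 1).
#'
#' @return Resistance in mmHg/(ml/s). Vectorised.
#' @export
segment_resistance <- function(flow, length_mm, diameter_mm,
                               params = carreau_parameters(), r_scale = 1) {
  if (any(length_mm <= 0) || any(diameter_mm <= 0)) {
    abort("Segment lengths and diameters must be positive.")
  }
  mu <- effective_viscosity(flow, diameter_mm, params)
  # 128 mu L / (pi d^4) in SI, then Pa/(m^3/s) -> mmHg/(ml/s)
  r_si <- 128 * mu * (length_mm * .mm_m) / (pi * (diameter_mm * .mm_m)^4)
  r_si * .ml_m3 / .mmHg_Pa * r_scale
}

# Map boundary pressures onto the node table: inlets get CPP, outlets get
# their territory's outlet pressure.
node_pressure_bc <- function(network, boundary) {
  out_p <- c(ACA = boundary$outlet_pressure_aca,
             MCA = boundary$outlet_pressure_mca,
             PCA = boundary$outlet_pressure_pca)
  dplyr::mutate(
    network$nodes,
    bc_pressure = dplyr::case_when(
      .data$role == "inlet" ~ boundary$inlet_pressure,
      .data$role == "outlet" ~ unname(out_p[.data$territory]),
      TRUE ~ NA_real_
    )
  )
}

#' Solve steady flows on a network under pressure boundary conditions
#'
#' Picard (successive substitution) iteration: segment resistances are
#' evaluated at the current flows, the nodal conductance system is assembled
#' with fixed pressures at the boundary nodes and solved for the internal
#' node pressures, segment flows are recovered from the pressure drops, and
#' flows are under-relaxed before the next pass. Iteration stops when the
#' relative change of every segment flow falls below
#' \code{settings$relative_tolerance}.
#'
#' Components of the graph containing no inlet are excluded from the solve:
#' their segments report zero flow, their efferent nodes keep the outlet
#' boundary pressure, and the situation is flagged.
#'
#' @param network A \code{cow_network} (or any network built with the same
#'   schema).
#' @param boundary A [build_boundary_set()] object.
#' @param params A [carreau_parameters()] object.
#' @param settings A [solver_settings()] object.
#'
#' @return An object of class \code{cow_flow_solution}: list with
#'   \code{node_pressures} (tibble \code{node, pressure_mmhg}),
#'   \code{segment_flows} (tibble \code{id, flow_ml_s, resistance,
#'   pressure_drop_mmhg}), \code{converged}, \code{iterations},
#'   \code{max_mass_residual} (ml/s), \code{total_inflow} and \code{flags}.
#'   Use [tidy()] / [glance()] for tabular views.
#' @export
#'
#' @examples
#' sol <- build_complete_cow() |> solve_flows(build_boundary_set())
#' glance(sol)
solve_flows <- function(network,
                        boundary = build_boundary_set(),
                        params = carreau_parameters(),
                        settings = solver_settings()) {
  stopifnot(inherits(network, "cow_network"),
            inherits(boundary, "boundary_set"),
            inherits(settings, "solver_settings"))
  nodes <- node_pressure_bc(network, boundary)
  seg <- network$segments
  flags <- network$flags

  if (!all(nodes$role %in% c("inlet", "internal", "outlet"))) {
    abort("Unknown node role in the network.")
  }
  if (sum(nodes$role == "inlet") < 1) abort("Network has no inlet node.")
  out_nodes <- nodes$node[nodes$role == "outlet"]
  if (any(is.na(nodes$bc_pressure[nodes$role == "outlet"]))) {
    abort("Every efferent outlet node needs an outlet pressure.")
  }

  # live component detection: only components containing an inlet are solved
  g <- as_igraph(network)
  comp <- igraph::components(g)$membership
  inlet_comps <- unique(comp[nodes$node[nodes$role == "inlet"]])
  live_node <- names(comp)[comp %in% inlet_comps]
  dead_seg <- !(seg$from %in% live_node)  # both ends share a component
  if (any(dead_seg)) {
    flags <- union(flags, paste0(
      "zero flow reported for segment(s) in no-inlet component(s): ",
      paste(seg$id[dead_seg], collapse = ", ")))
  }
  live_seg <- seg[!dead_seg, , drop = FALSE]

  is_bc <- nodes$role != "internal" | !(nodes$node %in% live_node)
  internal <- nodes$node[!is_bc]
  bc_pressure <- setNames(nodes$bc_pressure, nodes$node)

  n_int <- length(internal)
  int_index <- setNames(seq_len(n_int), internal)
  q <- rep(0, nrow(live_seg))
  converged <- FALSE
  iterations <- 0L

  from_i <- match(live_seg$from, internal)
  to_i <- match(live_seg$to, internal)

  for (it in seq_len(settings$max_iterations)) {
    iterations <- it
    r <- segment_resistance(q, live_seg$length_mm, live_seg$diameter_mm,
                            params, live_seg$r_scale)
    gcond <- 1 / r
    p_int <- if (n_int > 0) {
      a <- matrix(0, n_int, n_int)
      b <- rep(0, n_int)
      for (k in seq_along(gcond)) {
        fi <- from_i[k]; ti <- to_i[k]; gk <- gcond[k]
        if (!is.na(fi)) a[fi, fi] <- a[fi, fi] + gk
        if (!is.na(ti)) a[ti, ti] <- a[ti, ti] + gk
        if (!is.na(fi) && !is.na(ti)) {
          a[fi, ti] <- a[fi, ti] - gk
          a[ti, fi] <- a[ti, fi] - gk
        } else if (!is.na(fi)) {
          b[fi] <- b[fi] + gk * bc_pressure[[live_seg$to[k]]]
        } else if (!is.na(ti)) {
          b[ti] <- b[ti] + gk * bc_pressure[[live_seg$from[k]]]
        }
      }
      solve(a, b)
    } else {
      numeric(0)
    }
    p_of <- function(node) {
      i <- int_index[node]
      ifelse(is.na(i), bc_pressure[node], p_int[i])
    }
    q_new <- (p_of(live_seg$from) - p_of(live_seg$to)) * gcond
    delta <- max(abs(q_new - q))
    scale <- max(max(abs(q_new)), 1e-12)
    q <- settings$under_relaxation * q_new +
      (1 - settings$under_relaxation) * q
    if (delta / scale < settings$relative_tolerance) {
      q <- q_new  # consistent with the final resistances
      converged <- TRUE
      break
    }
  }

  # final pressures and flows at the converged viscosities
  r <- segment_resistance(q, live_seg$length_mm, live_seg$diameter_mm,
                          params, live_seg$r_scale)
  p_int_named <- setNames(
    if (n_int > 0) as.numeric(p_int) else numeric(0), internal)
  pressure <- ifelse(is.na(bc_pressure[nodes$node]),
                     p_int_named[nodes$node], bc_pressure[nodes$node])

  flows <- tibble::tibble(
    id = seg$id,
    flow_ml_s = 0,
    resistance_mmhg_per_ml_s = NA_real_,
    pressure_drop_mmhg = 0
  )
  flows$flow_ml_s[!dead_seg] <- q
  flows$resistance_mmhg_per_ml_s[!dead_seg] <- r
  flows$pressure_drop_mmhg[!dead_seg] <- q * r

  # mass residual at every solved internal node
  imbalance <- vapply(internal, function(nd) {
    sum(q[live_seg$to == nd]) - sum(q[live_seg$from == nd])
  }, numeric(1))
  max_resid <- if (n_int > 0) max(abs(imbalance)) else 0
  inlet_nodes <- nodes$node[nodes$role == "inlet"]
  total_in <- sum(q[live_seg$from %in% inlet_nodes]) -
    sum(q[live_seg$to %in% inlet_nodes])

  if (!converged) {
    flags <- union(flags, sprintf(
      "Picard iteration did not converge in %d iterations (last residual %.3g)",
      settings$max_iterations, max_resid))
    warn(flags[length(flags)])
  }

  structure(
    list(
      node_pressures = tibble::tibble(node = nodes$node,
                                      role = nodes$role,
                                      pressure_mmhg = unname(pressure)),
      segment_flows = flows,
      converged = converged,
      iterations = iterations,
      max_mass_residual = max_resid,
      total_inflow = total_in,
      network = network,
      boundary = boundary,
      params = params,
      settings = settings,
      flags = flags
    ),
    class = "cow_flow_solution"
  )
}

#' @export
print.cow_flow_solution <- function(x, ...) {
  cat(sprintf(
    "Flow solution: %s in %d iterations, total inflow %.3f ml/s, max mass residual %.2e ml/s\n",
    if (x$converged) "converged" else "NOT converged",
    x$iterations, x$total_inflow, x$max_mass_residual))
  if (length(x$flags) > 0) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Tidy a flow solution into per-segment rows
#'
#' @param x A \code{cow_flow_solution}.
#' @param ... Unused.
#'
#' @return Tibble \code{id, klass, flow_ml_s, pressure_drop_mmhg,
#'   resistance_mmhg_per_ml_s}.
#' @export
tidy.cow_flow_solution <- function(x, ...) {
  x$segment_flows |>
    dplyr::left_join(
      dplyr::select(x$network$segments, "id", "klass"),
      by = "id"
    ) |>
    dplyr::select("id", "klass", "flow_ml_s", "pressure_drop_mmhg",
                  "resistance_mmhg_per_ml_s")
}

#' One-row summary of a flow solution
#'
#' @param x A \code{cow_flow_solution}.
#' @param ... Unused.
#'
#' @return Tibble with \code{converged, iterations, total_inflow_ml_s,
#'   total_efferent_ml_s, max_mass_residual_ml_s}.
#' @export
glance.cow_flow_solution <- function(x, ...) {
  tibble::tibble(
    converged = x$converged,
    iterations = x$iterations,
    total_inflow_ml_s = x$total_inflow,
    total_efferent_ml_s = total_efferent_flow(x),
    max_mass_residual_ml_s = x$max_mass_residual
  )
}

#' Total efferent outflow of a solution
#'
#' Sum of the flows leaving through efferent segments, in ml/s.
#'
#' @param solution A \code{cow_flow_solution}.
#' @return A number, ml/s.
#' @export
total_efferent_flow <- function(solution) {
  eff <- solution$network$segments$id[solution$network$segments$klass == "efferent"]
  sum(solution$segment_flows$flow_ml_s[solution$segment_flows$id %in% eff])
}

#' Per-segment Reynolds numbers of a converged solution
#'
#' \eqn{Re = \rho \bar v d / \mu_\infty} from the mean velocity
#' \eqn{\bar v = Q / (\pi d^2 / 4)}; segments at or above the laminar
#' threshold 2100 are listed in the attached warning attribute.
#'
#' @param solution A \code{cow_flow_solution}.
#' @param blood_density Blood density in kg/m^3 (default 1050; used only
#'   here).
#'
#' @return Tibble \code{id, reynolds, laminar}; attribute
#'   \code{"warnings"} holds the ids with \code{Re >= 2100}.
#' @export
reynolds_check <- function(solution, blood_density = 1050) {
  stopifnot(inherits(solution, "cow_flow_solution"))
  seg <- solution$network$segments
  fl <- solution$segment_flows[match(seg$id, solution$segment_flows$id), ]
  d_m <- seg$diameter_mm * .mm_m
  q_si <- abs(fl$flow_ml_s) * .ml_m3
  v <- q_si / (pi * d_m^2 / 4)
  re <- blood_density * v * d_m / solution$params$mu_inf
  out <- tibble::tibble(id = seg$id, reynolds = re, laminar = re < 2100)
  attr(out, "warnings") <- seg$id[re >= 2100]
  out
}
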