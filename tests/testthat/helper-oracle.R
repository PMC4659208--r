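# Independent brute-force solver used as an oracle for solve_flows().
#
# Unknowns are the internal node pressures; the residual at each internal
# node is the net mass imbalance, with every segment flow obtained by
# root-finding Q * R(Q) = dP on the segment (R written out from first
# principles here, not via segment_resistance). The nonlinear system is
# solved with pracma::fsolve -- a different algorithm from the package's
# Picard iteration with linear solves.

oracle_segment_flow <- function(dp, length_mm, diameter_mm, params,
                                r_scale = 1) {
  resist <- function(q) {
    shear <- 32 * abs(q) * 1e-6 / (pi * (diameter_mm * 1e-3)^3)
    mu <- params$mu_inf + (params$mu_zero - params$mu_inf) *
      (1 + (params$relaxation_time * shear)^2)^((params$power_index - 1) / 2)
    128 * mu * (length_mm * 1e-3) / (pi * (diameter_mm * 1e-3)^4) *
      1e-6 / 133.322 * r_scale
  }
  if (dp == 0) return(0)
  f <- function(q) q * resist(q) - dp
  hi <- abs(dp) / resist(1e6)  # resistance only decreases with |q|
  uniroot(f, lower = -hi - 1, upper = hi + 1, tol = 1e-14)$root
}

oracle_solve <- function(network, boundary, params) {
  nodes <- network$nodes
  seg <- network$segments
  out_p <- c(ACA = boundary$outlet_pressure_aca,
             MCA = boundary$outlet_pressure_mca,
             PCA = boundary$outlet_pressure_pca)
  bc <- ifelse(nodes$role == "inlet", boundary$inlet_pressure,
               ifelse(nodes$role == "outlet", out_p[nodes$territory], NA))
  names(bc) <- nodes$node
  internal <- nodes$node[nodes$role == "internal"]

  flows_at <- function(p_int) {
    p <- bc
    p[internal] <- p_int
    vapply(seq_len(nrow(seg)), function(k) {
      oracle_segment_flow(p[[seg$from[k]]] - p[[seg$to[k]]],
                          seg$length_mm[k], seg$diameter_mm[k],
                          params, seg$r_scale[k])
    }, numeric(1))
  }
  resid <- function(p_int) {
    q <- flows_at(p_int)
    vapply(internal, function(nd) {
      sum(q[seg$to == nd]) - sum(q[seg$from == nd])
    }, numeric(1))
  }
  p0 <- rep(mean(bc, na.rm = TRUE), length(internal))
  p_star <- if (length(internal) == 1) {
    rng <- range(bc, na.rm = TRUE)
    uniroot(function(p) resid(p), lower = rng[1], upper = rng[2],
            tol = 1e-14, extendInt = "yes")$root
  } else {
    pracma::fsolve(resid, p0, tol = 1e-12)$x
  }
  q <- flows_at(p_star)
  list(pressures = setNames(p_star, internal),
       flows = setNames(q, seg$id))
}

# Random small test network (<= 6 segments) in the cow_network schema:
# one inlet, two outlets (ACA / MCA territories), up to two internal nodes,
# randomized dimensions. Always connected.
random_small_network <- function() {
  template <- sample(1:3, 1)
  seg_def <- switch(
    template,
    # Y junction: inlet -> n1 -> two outlets
    list(c("in1", "n1"), c("n1", "out1"), c("n1", "out2")),
    # ladder with parallel limbs
    list(c("in1", "n1"), c("n1", "n2"), c("n1", "n2"),
         c("n2", "out1"), c("n2", "out2")),
    # bridge: two paths plus a cross-link
    list(c("in1", "n1"), c("in1", "n2"), c("n1", "n2"),
         c("n1", "out1"), c("n2", "out2"), c("n2", "out1"))
  )
  n <- length(seg_def)
  segments <- tibble::tibble(
    id = paste0("S", seq_len(n)),
    from = vapply(seg_def, `[`, "", 1),
    to = vapply(seg_def, `[`, "", 2),
    length_mm = stats::runif(n, 5, 150),
    diameter_mm = stats::runif(n, 1, 5),
    klass = ifelse(grepl("^out", vapply(seg_def, `[`, "", 2)),
                   "efferent", "circle"),
    r_scale = stats::runif(n, 0.5, 4)
  )
  segments$klass[segments$from == "in1"] <- "inlet"
  all_nodes <- unique(c(segments$from, segments$to))
  nodes <- tibble::tibble(
    node = all_nodes,
    role = dplyr::case_when(all_nodes == "in1" ~ "inlet",
                            grepl("^out", all_nodes) ~ "outlet",
                            TRUE ~ "internal"),
    territory = dplyr::case_when(all_nodes == "out1" ~ "ACA",
                                 all_nodes == "out2" ~ "MCA",
                                 TRUE ~ NA_character_)
  )
  net <- willisflow:::new_cow_network(segments, nodes)
  inlet_p <- stats::runif(1, 80, 110)
  bs <- build_boundary_set(
    vitals = vital_signs(inlet_p, inlet_p, 70),
    constants = perfusion_constants(intracranial_pressure = 0),
    outlet_pressures = c(ACA = stats::runif(1, 30, 55),
                         MCA = stats::runif(1, 30, 55), PCA = 40)
  )
  list(network = net, boundary = bs)
}
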