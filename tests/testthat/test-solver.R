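# single straight tube between one inlet and one outlet, in the network schema
single_tube <- function(length_mm = 50, diameter_mm = 3, r_scale = 1) {
  segments <- tibble::tibble(
    id = "T1", from = "in1", to = "out1",
    length_mm = length_mm, diameter_mm = diameter_mm,
    klass = "efferent", r_scale = r_scale
  )
  nodes <- tibble::tibble(
    node = c("in1", "out1"),
    role = c("inlet", "outlet"),
    territory = c(NA, "MCA")
  )
  willisflow:::new_cow_network(segments, nodes)
}

tube_boundary <- function(p_in = 90, p_out = 50) {
  build_boundary_set(
    vitals = vital_signs(p_in, p_in, 70),
    constants = perfusion_constants(intracranial_pressure = 0),
    outlet_pressures = c(ACA = p_out, MCA = p_out, PCA = p_out)
  )
}

test_that("segment resistance carries the Poiseuille scalings and frozen value", {
  p <- carreau_parameters()
  newt <- carreau_parameters(mu_zero = 0.004, mu_inf = 0.004)
  # linear in length
  expect_equal(segment_resistance(1, 20, 3, p),
               2 * segment_resistance(1, 10, 3, p))
  # d^-4 at fixed viscosity (Newtonian limit isolates the geometric factor)
  expect_equal(segment_resistance(1, 10, 6, newt),
               segment_resistance(1, 10, 3, newt) / 16)
  # r_scale is a pure multiplier
  expect_equal(segment_resistance(1, 10, 3, p, r_scale = 2.5),
               2.5 * segment_resistance(1, 10, 3, p))
  # frozen unit-checked hand computation with the composed viscosity oracle
  expect_equal(segment_resistance(2.5, 10, 4, p), 0.04736100598355083,
               tolerance = 1e-10)
  expect_error(segment_resistance(1, -5, 3, p), "positive")
})

test_that("a Newtonian single tube matches the Poiseuille closed form to 1e-10", {
  mu <- 0.0035
  newt <- carreau_parameters(mu_zero = mu, mu_inf = mu)
  net <- single_tube(length_mm = 80, diameter_mm = 3.5)
  sol <- solve_flows(net, tube_boundary(90, 50), newt)
  expect_true(sol$converged)
  r_closed <- 128 * mu * 80e-3 / (pi * 3.5e-3^4) * 1e-6 / 133.322
  q_closed <- (90 - 50) / r_closed
  expect_equal(sol$segment_flows$flow_ml_s, q_closed,
               tolerance = 1e-10)
})

test_that("Picard solutions match the brute-force root-finding oracle", {
  skip_if_not_installed("pracma")
  set.seed(2024)
  for (i in 1:8) {
    case <- random_small_network()
    sol <- solve_flows(case$network, case$boundary)
    expect_true(sol$converged)
    oracle <- oracle_solve(case$network, case$boundary, carreau_parameters())
    expect_equal(sol$segment_flows$flow_ml_s,
                 unname(oracle$flows[sol$segment_flows$id]),
                 tolerance = 1e-6)
  }
})

test_that("converged solutions conserve mass at every internal node", {
  sol <- solve_flows(calibrated_cow(), default_boundary())
  expect_true(sol$converged)
  expect_lt(sol$max_mass_residual, 1e-8 * sol$total_inflow)
  expect_equal(sol$total_inflow, total_efferent_flow(sol),
               tolerance = 1e-8)
})

test_that("the solution is invariant under node and segment reordering", {
  net <- apply_stenosis(calibrated_cow(), 75)
  set.seed(5)
  shuffled <- net
  shuffled$segments <- shuffled$segments[sample(nrow(shuffled$segments)), ]
  shuffled$nodes <- shuffled$nodes[sample(nrow(shuffled$nodes)), ]
  a <- solve_flows(net, default_boundary())
  b <- solve_flows(shuffled, default_boundary())
  ord <- match(a$segment_flows$id, b$segment_flows$id)
  expect_equal(a$segment_flows$flow_ml_s,
               b$segment_flows$flow_ml_s[ord], tolerance = 1e-9)
})

test_that("mirrored anatomy with mirrored stenosis gives mirrored flows", {
  bs <- default_boundary()
  right <- calibrated_cow() |>
    apply_variant("RA1_ABSENT") |>
    apply_stenosis(60, target_segment = "LICA")
  left <- calibrated_cow() |>
    apply_variant("LA1_ABSENT") |>
    apply_stenosis(60, target_segment = "RICA")
  sol_r <- solve_flows(right, bs)
  sol_l <- solve_flows(left, bs)
  fr <- setNames(sol_r$segment_flows$flow_ml_s, sol_r$segment_flows$id)
  fl <- setNames(sol_l$segment_flows$flow_ml_s, sol_l$segment_flows$id)
  expect_equal(fr[["LMCA"]], fl[["RMCA"]], tolerance = 1e-8)
  expect_equal(fr[["RP2"]], fl[["LP2"]], tolerance = 1e-8)
  expect_equal(fr[["LICA_sten"]], fl[["RICA_sten"]], tolerance = 1e-8)
  # cross-links swap orientation under the mirror
  cr <- communicating_flows(sol_r)
  cl <- communicating_flows(sol_l)
  expect_equal(cr$flow_ml_s[cr$segment == "ACoA"],
               -cl$flow_ml_s[cl$segment == "ACoA"], tolerance = 1e-8)
  expect_equal(cr$flow_ml_s[cr$segment == "RPCoA"],
               cl$flow_ml_s[cl$segment == "LPCoA"], tolerance = 1e-8)
})

test_that("efferents cut off from every inlet get zero flow and their outlet pressure", {
  # LA1 and ACoA both gone: the left ACA territory has no feeding path
  net <- build_complete_cow() |>
    apply_variant("LA1_ABSENT") |>
    apply_variant("ACOA_ABSENT")
  sol <- solve_flows(net, default_boundary())
  expect_true(sol$converged)
  expect_match(paste(sol$flags, collapse = " "), "LA2")
  expect_equal(sol$segment_flows$flow_ml_s[sol$segment_flows$id == "LA2"], 0)
  p <- sol$node_pressures
  expect_equal(p$pressure_mmhg[p$node == "LACA_out"], 46)
})

test_that("non-convergence is reported, never silent", {
  tight <- solver_settings(max_iterations = 2, relative_tolerance = 1e-14)
  expect_warning(
    sol <- solve_flows(build_complete_cow(), default_boundary(),
                       settings = tight),
    "did not converge")
  expect_false(sol$converged)
  expect_match(paste(sol$flags, collapse = " "), "did not converge")
})

test_that("Reynolds diagnostics scale with flow and flag turbulent designs", {
  sol <- solve_flows(calibrated_cow(), default_boundary())
  re <- reynolds_check(sol)
  expect_equal(nrow(re), 18)
  # symmetric network: the ACoA carries no flow, so Re ~ 0
  expect_lt(re$reynolds[re$id == "ACoA"], 1e-6)
  expect_true(all(re$laminar))
  expect_length(attr(re, "warnings"), 0)
  # Re per unit flow depends only on geometry
  q <- abs(sol$segment_flows$flow_ml_s[match(re$id, sol$segment_flows$id)])
  ica <- re$reynolds[re$id == "RICA"] / q[re$id == "RICA"]
  mca <- re$reynolds[re$id == "RMCA"] / q[re$id == "RMCA"]
  d <- calibrated_cow()$segments
  # per unit flow, Re scales as 1/d
  expect_equal(ica / mca,
               d$diameter_mm[d$id == "RMCA"] / d$diameter_mm[d$id == "RICA"],
               tolerance = 1e-9)
  # a deliberately narrow, high-drop tube trips the warning
  hot <- solve_flows(single_tube(length_mm = 5, diameter_mm = 1),
                     tube_boundary(110, 30))
  hot_re <- reynolds_check(hot)
  expect_equal(attr(hot_re, "warnings"), "T1")
})

test_that("calibration hits the CBF target and split, and is a near fixed point", {
  bs <- default_boundary()
  cal <- calibrated_cow()
  sol <- solve_flows(cal, bs)
  total <- total_efferent_flow(sol)
  expect_lt(abs(total - 12.5) / 12.5, 0.005)
  flows <- setNames(sol$segment_flows$flow_ml_s, sol$segment_flows$id)
  split <- c(ACA = sum(flows[c("RA2", "LA2")]),
             MCA = sum(flows[c("RMCA", "LMCA")]),
             PCA = sum(flows[c("RP2", "LP2")])) / total
  expect_true(all(abs(split - c(ACA = 0.22, MCA = 0.45, PCA = 0.33)) < 0.01))
  # calibrating an already calibrated network barely moves the scales
  recal <- calibrate(cal, bs)
  expect_equal(recal$segments$r_scale, cal$segments$r_scale,
               tolerance = 5e-3)
})

test_that("shrinking a territory's target raises its distal resistance scale", {
  bs <- default_boundary()
  # ACA target halved, the remainder renormalized over MCA and PCA
  fr <- c(0.11, 0.45, 0.33) / 0.89
  half_aca <- calibrate(build_complete_cow(), bs,
                        fractions = c(ACA = fr[1], MCA = fr[2], PCA = fr[3]))
  scale_of <- function(net, id) net$segments$r_scale[net$segments$id == id]
  expect_gt(scale_of(half_aca, "RA2"), scale_of(calibrated_cow(), "RA2"))
})
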