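#' Vital signs used to derive the inlet pressure
#'
#' @param diastolic_pressure Diastolic pressure (DP), mmHg.
#' @param systolic_pressure Systolic pressure (SP), mmHg; >= DP.
#' @param heart_rate Heart rate (HR), beats/min; > 0.
#'
#' @return An object of class \code{vital_signs}.
#' @export
vital_signs <- function(diastolic_pressure = 80,
                        systolic_pressure = 120,
                        heart_rate = 80) {
  if (!is.numeric(diastolic_pressure) || diastolic_pressure <= 0) {
    abort("`diastolic_pressure` must be positive (mmHg).")
  }
  if (!is.numeric(systolic_pressure) ||
      systolic_pressure < diastolic_pressure) {
    abort("`systolic_pressure` must be >= `diastolic_pressure`.")
  }
  if (!is.numeric(heart_rate) || heart_rate <= 0) {
    abort("`heart_rate` must be positive (beats/min).")
  }
  structure(
    list(
      diastolic_pressure = as.numeric(diastolic_pressure),
      systolic_pressure = as.numeric(systolic_pressure),
      heart_rate = as.numeric(heart_rate)
    ),
    class = "vital_signs"
  )
}

#' Perfusion constants: ICP, total CBF and the efferent split
#'
#' Defaults: ICP 3 mmHg, total cerebral blood flow 12.5 ml/s, and a
#' 22 / 45 / 33 percent split over the ACA / MCA / PCA territories.
#'
#' @param intracranial_pressure ICP, mmHg; >= 0.
#' @param total_cbf Total cerebral blood flow, ml/s; > 0.
#' @param fraction_aca,fraction_mca,fraction_pca Efferent flow fractions;
#'   must sum to 1.
#'
#' @return An object of class \code{perfusion_constants}.
#' @export
perfusion_constants <- function(intracranial_pressure = 3,
                                total_cbf = 12.5,
                                fraction_aca = 0.22,
                                fraction_mca = 0.45,
                                fraction_pca = 0.33) {
  if (!is.numeric(intracranial_pressure) || intracranial_pressure < 0) {
    abort("`intracranial_pressure` must be non-negative (mmHg).")
  }
  if (!is.numeric(total_cbf) || total_cbf <= 0) {
    abort("`total_cbf` must be positive (ml/s).")
  }
  fr <- c(fraction_aca, fraction_mca, fraction_pca)
  if (any(fr <= 0) || abs(sum(fr) - 1) > 1e-9) {
    abort("Efferent fractions must be positive and sum to 1 (within 1e-9).")
  }
  structure(
    list(
      intracranial_pressure = as.numeric(intracranial_pressure),
      total_cbf = as.numeric(total_cbf),
      fraction_aca = as.numeric(fraction_aca),
      fraction_mca = as.numeric(fraction_mca),
      fraction_pca = as.numeric(fraction_pca)
    ),
    class = "perfusion_constants"
  )
}

#' Mean arterial pressure from vital signs
#'
#' Uses the heart-rate-corrected estimate
#' \deqn{MAP \approx DP + 0.01\, e^{4.14 - 40.74/HR} (SP - DP).}
#' At the default vitals (80/120 mmHg, 80 bpm) this gives 95 mmHg after
#' rounding to the nearest integer.
#'
#' @param vitals A [vital_signs()] object.
#'
#' @return MAP in mmHg (full precision, not rounded).
#' @export
mean_arterial_pressure <- function(vitals = vital_signs()) {
  stopifnot(inherits(vitals, "vital_signs"))
  dp <- vitals$diastolic_pressure
  sp <- vitals$systolic_pressure
  hr <- vitals$heart_rate
  dp + 0.01 * exp(4.14 - 40.74 / hr) * (sp - dp)
}

#' Cerebral perfusion pressure
#'
#' \eqn{CPP = MAP - ICP}. Rejected when \code{map_value <= icp}
#' (non-physiological).
#'
#' @param map_value Mean arterial pressure, mmHg.
#' @param icp Intracranial pressure, mmHg; >= 0.
#'
#' @return CPP in mmHg.
#' @export
cerebral_perfusion_pressure <- function(map_value, icp) {
  if (!is.numeric(icp) || any(icp < 0)) {
    abort("`icp` must be non-negative (mmHg).")
  }
  if (any(map_value <= icp)) {
    abort("`map_value` must exceed `icp`: perfusion pressure would vanish.")
  }
  map_value - icp
}

#' Lumped cerebrovascular resistance of a territory
#'
#' From \eqn{CBF = CPP / CVR}: \code{cvr = cpp / regional_flow}. The
#' conventional clinical unit is mmHg per (ml/min), so \code{regional_flow}
#' is in ml/min.
#'
#' @param cpp Cerebral perfusion pressure, mmHg.
#' @param regional_flow Regional flow in ml/min; > 0.
#'
#' @return CVR in mmHg/(ml/min).
#' @export
lumped_cvr <- function(cpp, regional_flow) {
  if (!is.numeric(regional_flow) || any(regional_flow <= 0)) {
    abort("`regional_flow` must be positive (ml/min).")
  }
  cpp / regional_flow
}

#' Assemble the pressure boundary conditions
#'
#' Derives the inlet pressure as CPP = MAP(vitals) - ICP and attaches the
#' per-territory outlet pressures and lumped CVRs. The outlet pressures are
#' configured constants (defaults 46 / 56 / 43.5 mmHg for ACA / MCA / PCA
#' beds), not recomputed from the CVRs: the two derivations are not mutually
#' consistent at the default constants, and the pressures are the operative
#' boundary condition.
#'
#' @param vitals A [vital_signs()] object.
#' @param constants A [perfusion_constants()] object.
#' @param outlet_pressures Named numeric of length 3 with names
#'   \code{c("ACA", "MCA", "PCA")}, mmHg.
#'
#' @return An object of class \code{boundary_set} with fields
#'   \code{inlet_pressure}, \code{outlet_pressure_aca/mca/pca} and
#'   \code{cvr_aca/mca/pca}; use [tidy()] for the derivation chain as a
#'   tibble.
#' @export
#'
#' @examples
#' bs <- build_boundary_set()
#' tidy(bs)
build_boundary_set <- function(vitals = vital_signs(),
                               constants = perfusion_constants(),
                               outlet_pressures = c(ACA = 46, MCA = 56,
                                                    PCA = 43.5)) {
  stopifnot(inherits(vitals, "vital_signs"),
            inherits(constants, "perfusion_constants"))
  if (!is.numeric(outlet_pressures) || length(outlet_pressures) != 3 ||
      !all(c("ACA", "MCA", "PCA") %in% names(outlet_pressures))) {
    abort("`outlet_pressures` must be named c(ACA=, MCA=, PCA=) in mmHg.")
  }
  map_value <- mean_arterial_pressure(vitals)
  cpp <- cerebral_perfusion_pressure(map_value, constants$intracranial_pressure)
  if (any(outlet_pressures >= cpp)) {
    abort("Every outlet pressure must be below the inlet pressure (CPP).")
  }
  regional_ml_min <- 60 * constants$total_cbf *
    c(constants$fraction_aca, constants$fraction_mca, constants$fraction_pca)
  cvr <- lumped_cvr(cpp, regional_ml_min)
  structure(
    list(
      map = map_value,
      inlet_pressure = cpp,
      outlet_pressure_aca = unname(outlet_pressures[["ACA"]]),
      outlet_pressure_mca = unname(outlet_pressures[["MCA"]]),
      outlet_pressure_pca = unname(outlet_pressures[["PCA"]]),
      cvr_aca = cvr[[1]],
      cvr_mca = cvr[[2]],
      cvr_pca = cvr[[3]],
      vitals = vitals,
      constants = constants
    ),
    class = "boundary_set"
  )
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("Pressure boundary conditions (mmHg)\n")
  cat(sprintf("  MAP %.2f -> CPP (inlet) %.2f\n", x$map, x$inlet_pressure))
  cat(sprintf("  outlets: ACA %.1f, MCA %.1f, PCA %.1f\n",
              x$outlet_pressure_aca, x$outlet_pressure_mca,
              x$outlet_pressure_pca))
  cat(sprintf("  lumped CVR [mmHg/(ml/min)]: ACA %.3f, MCA %.3f, PCA %.3f\n",
              x$cvr_aca, x$cvr_mca, x$cvr_pca))
  invisible(x)
}

#' Tidy the boundary-condition derivation chain
#'
#' @param x A \code{boundary_set}.
#' @param ... Unused.
#'
#' @return A tibble with one row per derived quantity: name, value, units,
#'   and the value rounded the way it is conventionally reported (MAP to
#'   integer mmHg, CVR to two decimals).
#' @export
tidy.boundary_set <- function(x, ...) {
  tibble::tibble(
    quantity = c("MAP", "CPP_inlet", "outlet_ACA", "outlet_MCA", "outlet_PCA",
                 "CVR_ACA", "CVR_MCA", "CVR_PCA"),
    value = c(x$map, x$inlet_pressure, x$outlet_pressure_aca,
              x$outlet_pressure_mca, x$outlet_pressure_pca,
              x$cvr_aca, x$cvr_mca, x$cvr_pca),
    units = c(rep("mmHg", 5), rep("mmHg/(ml/min)", 3)),
    reported = c(round_half_away(x$map, 0),
                 round_half_away(x$inlet_pressure, 0),
                 x$outlet_pressure_aca, x$outlet_pressure_mca,
                 x$outlet_pressure_pca,
                 round_half_away(x$cvr_aca, 2),
                 round_half_away(x$cvr_mca, 2),
                 round_half_away(x$cvr_pca, 2))
  )
}

#' Round half away from zero
#'
#' The rounding convention of clinical reporting tables (base \code{round()}
#' rounds half to even). Used for all "reported" values in this package.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#'
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
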