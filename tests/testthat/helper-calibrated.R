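# Calibration is the slow step (repeated network solves), so the calibrated
# default network is built once per test run and shared.
.calib_cache <- new.env(parent = emptyenv())

calibrated_cow <- function() {
  if (is.null(.calib_cache$net)) {
    .calib_cache$boundary <- build_boundary_set()
    .calib_cache$net <- calibrate(build_complete_cow(), .calib_cache$boundary)
  }
  .calib_cache$net
}

default_boundary <- function() {
  invisible(calibrated_cow())
  .calib_cache$boundary
}

default_sweep <- function() {
  if (is.null(.calib_cache$sweep)) {
    .calib_cache$sweep <- run_sweep(calibrated_cow(), default_boundary())
  }
  .calib_cache$sweep
}
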