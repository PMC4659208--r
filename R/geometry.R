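## Canonical segment identifiers of the complete circle of Willis.
COW_SEGMENT_IDS <- c(
  "RICA", "LICA", "RVA", "LVA", "BA",
  "RA1", "LA1", "ACoA", "RP1", "LP1", "RPCoA", "LPCoA",
  "RMCA", "LMCA", "RA2", "LA2", "RP2", "LP2"
)

## Anatomical variants: the complete circle plus five single-segment absences.
#' @rdname apply_variant
#' @export
COW_VARIANTS <- c("COMPLETE", "ACOA_ABSENT", "RA1_ABSENT", "LA1_ABSENT",
                  "RPCOA_ABSENT", "LPCOA_ABSENT")

.variant_segment <- c(
  COMPLETE = NA_character_, ACOA_ABSENT = "ACoA", RA1_ABSENT = "RA1",
  LA1_ABSENT = "LA1", RPCOA_ABSENT = "RPCoA", LPCOA_ABSENT = "LPCoA"
)

#' Nominal circle-of-Willis segment dimensions (synthetic)
#'
#' A literature-plausible, left-right symmetric table of lengths and
#' diameters for the 18 canonical segments, in the dimension classes used by
#' one-dimensional arterial-network models (ICA about 4 mm diameter,
#' communicating arteries about 1.5 mm). These are synthetic nominal values,
#' not measurements from any particular subject; patient geometries vary
#' widely and the packaged table only anchors the synthetic-geometry
#' generator.
#'
#' @return A tibble with columns \code{id}, \code{length_mm},
#'   \code{diameter_mm}.
#' @export
#'
#' @examples
#' nominal_geometry()
nominal_geometry <- function() {
  path <- system.file("extdata", "nominal_geometry_synthetic.csv",
                      package = "willisflow", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Generate a seeded synthetic geometry table
#'
#' Starts from [nominal_geometry()] and multiplies every length and diameter
#' by an independent factor drawn uniformly in
#' \code{[1 - jitter_fraction, 1 + jitter_fraction]}. The same seed always
#' yields the same table; \code{jitter_fraction = 0} returns the exact
#' nominal (left-right symmetric) table. The global RNG state is left
#' untouched.
#'
#' @param seed Integer seed.
#' @param jitter_fraction Relative jitter amplitude in \code{[0, 0.3)}.
#'
#' @return A dimension tibble with columns \code{id}, \code{length_mm},
#'   \code{diameter_mm}.
#' @export
#'
#' @examples
#' synthetic_geometry(seed = 1, jitter_fraction = 0.05)
synthetic_geometry <- function(seed, jitter_fraction = 0) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  if (!is.numeric(jitter_fraction) || jitter_fraction < 0 ||
      jitter_fraction >= 0.3) {
    abort("`jitter_fraction` must lie in [0, 0.3).")
  }
  dims <- nominal_geometry()
  if (jitter_fraction == 0) {
    return(dims)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  n <- nrow(dims)
  dims$length_mm <- dims$length_mm *
    stats::runif(n, 1 - jitter_fraction, 1 + jitter_fraction)
  dims$diameter_mm <- dims$diameter_mm *
    stats::runif(n, 1 - jitter_fraction, 1 + jitter_fraction)
  dims
}

#' Read or write a geometry / topology table as CSV
#'
#' A topology CSV has one row per segment with columns
#' \code{id, from, to, length_mm, diameter_mm, klass} (and optionally
#' \code{r_scale}, the calibrated distal resistance scale).
#'
#' @param path File path.
#'
#' @return \code{read_segments()} returns a tibble; \code{write_segments()}
#'   returns \code{path} invisibly.
#' @export
read_segments <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_segments
#' @param segments A segment tibble (e.g. \code{network$segments}).
#' @export
write_segments <- function(segments, path) {
  write.csv(as.data.frame(segments), path, row.names = FALSE)
  invisible(path)
}
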