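#' Physical constants of the extended nucleosomal fiber
#'
#' Converts base pairs of DNA to the length of the fiber packaging them:
#' 0.34 nm of contour length per base pair, divided by the packing ratio of
#' an extended 11 nm nucleosomal array (6.8:1).
#'
#' @param nm_per_bp DNA contour length per base pair, nm.
#' @param packing_ratio DNA-length-to-fiber-length ratio of the array.
#' @return A `fiber_model` list.
#' @export
fiber_model <- function(nm_per_bp = 0.34, packing_ratio = 6.8) {
  check_that(nm_per_bp > 0, "nm_per_bp", "must be > 0")
  check_that(packing_ratio > 0, "packing_ratio", "must be > 0")
  structure(list(nm_per_bp = nm_per_bp, packing_ratio = packing_ratio),
            class = "fiber_model")
}

#' Extended fiber length of a DNA segment
#'
#' @param dna_bp DNA length in base pairs (>= 0).
#' @param model A [fiber_model()].
#' @return Length in micrometres of the segment packaged as an extended
#'   11 nm nucleosomal fiber: `dna_bp * nm_per_bp / packing_ratio / 1000`.
#' @examples
#' extended_fiber_length(360e3)  # ~18 um
#' @export
extended_fiber_length <- function(dna_bp, model = fiber_model()) {
  check_that(all(dna_bp >= 0), "dna_bp", "must be >= 0")
  check_that(inherits(model, "fiber_model"), "model", "must be a fiber_model")
  dna_bp * model$nm_per_bp / model$packing_ratio / 1000
}

#' In vivo measurements of a chromosomal fragment
#'
#' Replicate apparent lengths (and optionally diameters) of a fragment
#' measured across nuclei, plus its genomic length when known.
#'
#' @param lengths Observed lengths in micrometres, one per nucleus.
#' @param diameters Optional observed diameters in micrometres (scalar or
#'   one per nucleus).
#' @param dna_bp Optional genomic length in base pairs.
#' @param label Optional fragment name.
#' @return A `fragment_measurement` list with the replicates and their
#'   mean/SD summaries.
#' @export
fragment_measurement <- function(lengths, diameters = NULL, dna_bp = NULL,
                                 label = NULL) {
  check_that(is.numeric(lengths) && length(lengths) >= 1 && all(lengths > 0),
             "lengths", "must be positive")
  if (!is.null(diameters)) {
    check_that(all(diameters > 0), "diameters", "must be positive")
    if (length(diameters) == 1) diameters <- rep(diameters, length(lengths))
    check_that(length(diameters) == length(lengths), "diameters",
               "must match lengths")
  }
  if (!is.null(dna_bp))
    check_that(dna_bp > 0, "dna_bp", "must be positive")
  structure(list(lengths = lengths, diameters = diameters, dna_bp = dna_bp,
                 label = label,
                 mean_length = mean(lengths),
                 sd_length = if (length(lengths) > 1) sd(lengths) else NA_real_,
                 n = length(lengths)),
            class = "fragment_measurement")
}

#' Linear fold-compaction of a fragment against the extended fiber
#'
#' Fold compaction is the extended-fiber length divided by the mean observed
#' in vivo length.  The uncertainty of the fold is propagated from the
#' replicate SD by the delta method:
#' `sd(fold) ~ extended * sd(mean length) / mean(length)^2` with
#' `sd(mean length) = sd / sqrt(n)`.  Unit-invariant: both lengths in nm
#' give the same fold as both in micrometres.
#'
#' @param extended_length Extended fiber length (same units as the observed
#'   lengths; micrometres by convention).  May also be computed from
#'   `measurement$dna_bp` via [extended_fiber_length()] when `NULL`.
#' @param measurement A [fragment_measurement()].
#' @param model [fiber_model()] used when deriving `extended_length` from
#'   `dna_bp`.
#' @return List with `fold`, `fold_sd` (NA for a single replicate),
#'   `extended_length`, `observed_mean`, `observed_sd`, `n`.
#' @examples
#' fold_compaction_linear(18, fragment_measurement(0.72))$fold  # 25
#' @export
fold_compaction_linear <- function(extended_length = NULL, measurement,
                                   model = fiber_model()) {
  check_that(inherits(measurement, "fragment_measurement"), "measurement",
             "must be a fragment_measurement")
  if (is.null(extended_length)) {
    check_that(!is.null(measurement$dna_bp), "extended_length",
               "missing and no dna_bp on the measurement")
    extended_length <- extended_fiber_length(measurement$dna_bp, model)
  }
  check_that(extended_length > 0, "extended_length", "must be > 0")
  m <- measurement$mean_length
  fold <- extended_length / m
  fold_sd <- if (measurement$n > 1)
    extended_length * (measurement$sd_length / sqrt(measurement$n)) / m^2
  else NA_real_
  list(fold = fold, fold_sd = fold_sd, extended_length = extended_length,
       observed_mean = m, observed_sd = measurement$sd_length,
       n = measurement$n)
}

#' Relative volumetric condensation of two fragments
#'
#' Models each fragment as a cylinder (`volume = pi (d/2)^2 L` from the mean
#' observed length and diameter) and compares DNA densities:
#' `(bp_a / volume_a) / (bp_b / volume_b)`.  A value above 1 means fragment
#' `a` is more compacted than fragment `b`.
#'
#' @param frag_a,frag_b [fragment_measurement()]s carrying `dna_bp`,
#'   lengths and diameters.
#' @return List with `relative_condensation`, per-fragment `volume` (um^3)
#'   and `density_bp_per_um3`.
#' @export
fold_compaction_volumetric <- function(frag_a, frag_b) {
  one <- function(f, who) {
    check_that(inherits(f, "fragment_measurement"), who,
               "must be a fragment_measurement")
    check_that(!is.null(f$dna_bp), who, "needs dna_bp")
    check_that(!is.null(f$diameters), who, "needs diameter measurements")
    vol <- pi * (mean(f$diameters) / 2)^2 * f$mean_length
    list(volume = vol, density = f$dna_bp / vol)
  }
  a <- one(frag_a, "frag_a")
  b <- one(frag_b, "frag_b")
  list(relative_condensation = a$density / b$density,
       volume = c(a = a$volume, b = b$volume),
       density_bp_per_um3 = c(a = a$density, b = b$density))
}
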