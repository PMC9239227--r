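# User-facing constructors and accessors for the core containers.

#' Create a substrate environment
#'
#' @param substrate_id substrate label, e.g. `"soil"` or `"digestate"`.
#' @param carrying_capacity shared carrying capacity K (biomass units per
#'   vial), strictly positive.
#' @param duration enrichment duration in hours, strictly positive.
#' @return A [SubstrateEnv-class] object.
#' @examples
#' substrateEnv("soil", 1e10, 110)
#' @export
substrateEnv <- function(substrate_id, carrying_capacity, duration) {
  new("SubstrateEnv", substrate_id = as.character(substrate_id),
      carrying_capacity = as.numeric(carrying_capacity),
      duration = as.numeric(duration))
}

#' Create per-substrate growth/death traits for one species
#'
#' @param name species label.
#' @param growth_rate named numeric vector of growth rates (h^-1) keyed by
#'   substrate id; a single unnamed value applies to every substrate.
#' @param death_rate named numeric vector of first-order death rates (h^-1);
#'   recycling as for `growth_rate`. Default 0.
#' @return A [SpeciesTraits-class] object.
#' @examples
#' speciesTraits("S", growth_rate = c(soil = 0.1, digestate = 0),
#'               death_rate = c(soil = 0, digestate = 0.04))
#' @export
speciesTraits <- function(name, growth_rate, death_rate = 0) {
  new("SpeciesTraits", name = as.character(name),
      growth_rate = growth_rate, death_rate = death_rate)
}

## Resolve a (possibly scalar) per-substrate rate map for one substrate.
traitRate <- function(traits, which = c("growth", "death"), substrate) {
  which <- match.arg(which)
  x <- if (which == "growth") traits@growth_rate else traits@death_rate
  if (!is.null(names(x)) && substrate %in% names(x)) return(unname(x[[substrate]]))
  if (length(x) == 1L && is.null(names(x))) return(unname(x))
  stopf("species '%s' has no %s rate for substrate '%s'",
        traits@name, which, substrate)
}

#' Create a serial-transfer protocol
#'
#' @param substrate_sequence list of [SubstrateEnv-class] objects making up
#'   one passage (one full cycle), typically soil followed by digestate.
#' @param transfer_fraction fraction f of enriched material transferred into
#'   each new batch, in (0, 1]. Default 0.1 (10 weight percent).
#' @param n_passages number of repetitions of the cycle.
#' @param initial_abundance named numeric vector of species abundances in the
#'   source material before the first transfer.
#' @return A [TransferProtocol-class] object.
#' @export
transferProtocol <- function(substrate_sequence, transfer_fraction = 0.1,
                             n_passages = 7L, initial_abundance) {
  new("TransferProtocol", substrate_sequence = substrate_sequence,
      transfer_fraction = as.numeric(transfer_fraction),
      n_passages = as.integer(n_passages),
      initial_abundance = initial_abundance)
}

#' Create an incubation vial specification
#'
#' @param total_volume vial volume in mL (default 120, a crimp-sealed serum vial).
#' @param liquid_volume liquid phase in mL (default 50).
#' @param sample_volume headspace volume withdrawn (and replaced by He) per
#'   sampling event, mL (default 1).
#' @param leak_coefficient named numeric, per-gas first-order exchange
#'   coefficient with ambient air (h^-1). Default: no leakage.
#' @param ambient_amount named numeric, per-gas ambient headspace-equivalent
#'   amount (umol). Default 0.
#' @return A [VialSpec-class] object.
#' @export
vialSpec <- function(total_volume = 120, liquid_volume = 50, sample_volume = 1,
                     leak_coefficient = numeric(0), ambient_amount = numeric(0)) {
  new("VialSpec", total_volume = as.numeric(total_volume),
      liquid_volume = as.numeric(liquid_volume),
      sample_volume = as.numeric(sample_volume),
      leak_coefficient = leak_coefficient, ambient_amount = ambient_amount)
}

#' Headspace volume of a vial
#' @param vial A [VialSpec-class] object.
#' @return Headspace volume in mL.
#' @export
headspaceVolume <- function(vial) vial@total_volume - vial@liquid_volume

#' Create a raw headspace gas series
#'
#' @param times measurement times in hours, strictly increasing.
#' @param amounts gas x time matrix of headspace amounts (umol; umol N for
#'   N-containing gases, conventionally rows `"N2O-N"`, `"N2-N"`, `"NO-N"`).
#' @param sampled logical flag per timepoint: was a headspace sample withdrawn
#'   (after measurement) at this timepoint? Default: all TRUE.
#' @param injections data.frame with columns `time`, `gas`, `amount` (umol);
#'   an injection at time t takes effect in the interval starting at t.
#' @return A [GasSeries-class] object.
#' @export
gasSeries <- function(times, amounts, sampled = NULL, injections = NULL) {
  if (is.null(sampled)) sampled <- rep(TRUE, length(times))
  if (is.null(injections))
    injections <- data.frame(time = numeric(0), gas = character(0),
                             amount = numeric(0))
  new("GasSeries", times = as.numeric(times), amounts = amounts,
      sampled = as.logical(sampled), injections = injections)
}

#' Assemble an OTU experiment
#'
#' @param counts integer matrix, OTUs as rows and samples as columns.
#' @param meta data.frame of sample metadata with columns `line`, `replicate`,
#'   `cycle`, `substrate`; rownames (or a `sample_id` column) matching
#'   `colnames(counts)`.
#' @param total_copies optional named numeric vector of ddPCR 16S copies per
#'   vial, names matching sample ids.
#' @return An [OTUExperiment-class] object.
#' @export
otuExperiment <- function(counts, meta, total_copies = NULL) {
  if ("sample_id" %in% colnames(meta)) {
    rownames(meta) <- meta$sample_id
    meta$sample_id <- NULL
  }
  meta <- meta[colnames(counts), , drop = FALSE]
  if (!is.null(total_copies)) {
    missing <- setdiff(colnames(counts), names(total_copies))
    if (length(missing) > 0)
      stopf("samples missing from ddPCR totals: %s", paste(missing, collapse = ", "))
    meta$total_copies <- unname(total_copies[colnames(counts)])
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
  new("OTUExperiment", se)
}

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' Species-by-time abundance matrix of a trajectory
#' @param traj A [Trajectory-class] object.
#' @return Numeric matrix, species x time.
#' @export
abundances <- function(traj) traj@abundances

#' Indices of enrichment starts within a trajectory
#' @param traj A [Trajectory-class] object.
#' @return Integer vector of column indices.
#' @export
enrichmentBoundaries <- function(traj) traj@enrichment_boundaries

#' Trajectory time grid (hours)
#' @param traj A [Trajectory-class] object.
#' @return Numeric vector.
#' @export
trajectoryTimes <- function(traj) traj@times

#' End-of-enrichment abundance states
#'
#' @param traj A [Trajectory-class] object.
#' @return Numeric matrix, species x enrichment, the abundance state at the
#'   final timepoint of each enrichment.
#' @export
endOfEnrichmentStates <- function(traj) {
  nb <- traj@enrichment_boundaries
  ends <- c(nb[-1] - 1L, ncol(traj@abundances))
  out <- traj@abundances[, ends, drop = FALSE]
  colnames(out) <- traj@enrichment_substrate
  out
}

#' Cumulative corrected production matrix
#' @param x A [CorrectedSeries-class] object.
#' @return Numeric matrix, gas x time (umol).
#' @export
cumulativeProduction <- function(x) x@cumulative_production

#' Per-interval production rates
#' @param x A [CorrectedSeries-class] object.
#' @return Numeric matrix, gas x interval (umol h^-1).
#' @export
productionRates <- function(x) x@rates

#' Sampling-corrected headspace amounts
#' @param x A [CorrectedSeries-class] or [GasSeries-class] object.
#' @return Numeric matrix, gas x time (umol).
#' @export
gasAmounts <- function(x) x@amounts

#' ddPCR total 16S copies per sample
#' @param x An [OTUExperiment-class] object.
#' @return Named numeric vector.
#' @export
totalCopies <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"total_copies" %in% colnames(cd))
    stopf("no ddPCR totals attached to this OTUExperiment")
  setNames(cd$total_copies, colnames(x))
}

#' Clade label per OTU
#' @param x A [CladeMap-class] object.
#' @return Named factor.
#' @export
cladeAssignments <- function(x) x@clades

#' Linkage record of a clade clustering
#' @param x A [CladeMap-class] object.
#' @return An `hclust` object.
#' @export
linkageTree <- function(x) x@tree
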