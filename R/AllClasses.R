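#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# Competition-model containers
# ---------------------------------------------------------------------------

#' Substrate environment for one batch enrichment
#'
#' Describes a single enrichment batch: the substrate identity (e.g. `"soil"`
#' or `"digestate"`), the carrying capacity of the shared substrate pool
#' (biomass units per vial) and the incubation duration in hours.
#'
#' @slot substrate_id character, substrate label.
#' @slot carrying_capacity numeric, shared carrying capacity K (> 0).
#' @slot duration numeric, batch duration in hours (> 0).
#' @export
setClass("SubstrateEnv",
  slots = c(substrate_id = "character", carrying_capacity = "numeric",
            duration = "numeric"))

setValidity("SubstrateEnv", function(object) {
  if (length(object@substrate_id) != 1L || is.na(object@substrate_id))
    return("substrate_id must be a single non-missing label")
  if (!is_scalar_number(object@carrying_capacity) || object@carrying_capacity <= 0)
    return("carrying_capacity must be a single strictly positive number")
  if (!is_scalar_number(object@duration) || object@duration <= 0)
    return("duration must be a single strictly positive number")
  TRUE
})

#' Per-substrate growth and death rates of one taxon
#'
#' Growth and death rates (h^-1) of a species on each substrate it may
#' encounter. Rates are named numeric vectors keyed by substrate id; a single
#' unnamed value is recycled to every substrate.
#'
#' @slot name character, species label.
#' @slot growth_rate named numeric, growth rate mu(s) per substrate (>= 0).
#' @slot death_rate named numeric, first-order death rate d(s) per substrate (>= 0).
#' @export
setClass("SpeciesTraits",
  slots = c(name = "character", growth_rate = "numeric", death_rate = "numeric"))

setValidity("SpeciesTraits", function(object) {
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    return("name must be a single non-empty label")
  for (slot in c("growth_rate", "death_rate")) {
    x <- slot(object, slot)
    if (length(x) == 0L || any(!is.finite(x)) || any(x < 0))
      return(sprintf("%s must be non-negative and finite", slot))
    if (length(x) > 1L && is.null(names(x)))
      return(sprintf("%s of length > 1 must be named by substrate", slot))
  }
  TRUE
})

#' Serial-transfer protocol
#'
#' One cycle of enrichments (`substrate_sequence`, usually soil then
#' digestate), repeated `n_passages` times. At the start of every enrichment
#' (including the first: inoculation is itself a transfer) all abundances are
#' multiplied by the transfer fraction `f`.
#'
#' @slot substrate_sequence list of [SubstrateEnv-class] making up one passage.
#' @slot transfer_fraction numeric, f in (0, 1].
#' @slot n_passages integer, number of repetitions of the cycle.
#' @slot initial_abundance named numeric, biomass per species in the inoculum
#'   source material (before the first transfer).
#' @export
setClass("TransferProtocol",
  slots = c(substrate_sequence = "list", transfer_fraction = "numeric",
            n_passages = "integer", initial_abundance = "numeric"))

setValidity("TransferProtocol", function(object) {
  if (length(object@substrate_sequence) == 0L)
    return("substrate_sequence must be non-empty")
  if (!all(vapply(object@substrate_sequence, is, logical(1), "SubstrateEnv")))
    return("substrate_sequence must be a list of SubstrateEnv objects")
  f <- object@transfer_fraction
  if (!is_scalar_number(f) || f <= 0 || f > 1)
    return("transfer_fraction must lie in (0, 1]")
  if (length(object@n_passages) != 1L || is.na(object@n_passages) ||
      object@n_passages < 1L)
    return("n_passages must be a positive integer")
  ia <- object@initial_abundance
  if (length(ia) == 0L || is.null(names(ia)) || any(!nzchar(names(ia))))
    return("initial_abundance must be a named numeric vector")
  if (any(!is.finite(ia)) || any(ia < 0))
    return("initial abundances must be finite and >= 0")
  TRUE
})

#' Multi-enrichment abundance trajectory
#'
#' Species-by-time abundance matrix across one or more chained enrichments,
#' with the index of the first timepoint of each enrichment and the substrate
#' incubated in each.
#'
#' @slot times numeric, hours (global clock across enrichments).
#' @slot abundances numeric matrix, species x time, biomass units.
#' @slot enrichment_boundaries integer, column index at which each enrichment starts.
#' @slot enrichment_substrate character, substrate id per enrichment.
#' @export
setClass("Trajectory",
  slots = c(times = "numeric", abundances = "matrix",
            enrichment_boundaries = "integer", enrichment_substrate = "character"))

setValidity("Trajectory", function(object) {
  if (ncol(object@abundances) != length(object@times))
    return("abundances must have one column per timepoint")
  if (any(object@abundances < 0)) return("abundances must be >= 0")
  if (length(object@enrichment_boundaries) != length(object@enrichment_substrate))
    return("one substrate label per enrichment required")
  TRUE
})

#' Outcome map over generalist:specialist growth-rate ratios
#'
#' @slot ratio_grid numeric, generalist:specialist growth-rate ratios.
#' @slot outcome character, one of `"eliminated"`, `"slow_enrichment"`,
#'   `"dominant_within_limit"` per ratio.
#' @slot passages_to_dominance numeric, passages needed (NA unless dominant).
#' @slot critical_ratio numeric, bisection estimate of the elimination boundary.
#' @export
setClass("RegimeResult",
  slots = c(ratio_grid = "numeric", outcome = "character",
            passages_to_dominance = "numeric", critical_ratio = "numeric"))

setValidity("RegimeResult", function(object) {
  n <- length(object@ratio_grid)
  if (length(object@outcome) != n || length(object@passages_to_dominance) != n)
    return("outcome and passages_to_dominance must match ratio_grid in length")
  ok <- object@outcome %in% c("eliminated", "slow_enrichment", "dominant_within_limit")
  if (!all(ok)) return("invalid outcome label")
  dom <- object@outcome == "dominant_within_limit"
  if (any(dom & !is.finite(object@passages_to_dominance)) ||
      any(!dom & is.finite(object@passages_to_dominance)))
    return("passages_to_dominance must be defined iff outcome is dominant_within_limit")
  TRUE
})

# ---------------------------------------------------------------------------
# Gas-kinetics containers
# ---------------------------------------------------------------------------

#' Incubation vial geometry and exchange parameters
#'
#' @slot total_volume numeric, vial volume in mL (default 120).
#' @slot liquid_volume numeric, liquid phase volume in mL.
#' @slot sample_volume numeric, headspace volume removed (and replaced by He)
#'   at each sampling event, mL.
#' @slot leak_coefficient named numeric, first-order exchange coefficient with
#'   ambient air per gas (h^-1, default 0).
#' @slot ambient_amount named numeric, ambient headspace-equivalent amount per
#'   gas (umol, default 0).
#' @export
setClass("VialSpec",
  slots = c(total_volume = "numeric", liquid_volume = "numeric",
            sample_volume = "numeric", leak_coefficient = "numeric",
            ambient_amount = "numeric"))

setValidity("VialSpec", function(object) {
  hv <- object@total_volume - object@liquid_volume
  if (!is_scalar_number(hv) || hv <= 0)
    return("headspace volume (total - liquid) must be positive")
  sv <- object@sample_volume
  if (!is_scalar_number(sv) || sv < 0 || sv >= hv)
    return("sample_volume must satisfy 0 <= sample_volume < headspace volume")
  if (any(object@leak_coefficient < 0))
    return("leak coefficients must be >= 0")
  TRUE
})

#' Raw headspace gas time series
#'
#' Measured headspace amounts per gas over time, with a flag marking
#' timepoints at which a headspace sample was withdrawn (after measurement,
#' replaced by He) and a table of gas injections. Injection times are
#' attributed to the interval that starts at the injection time.
#'
#' @slot times numeric, hours, strictly increasing.
#' @slot amounts numeric matrix, gas x time, umol (N-containing gases are
#'   conventionally carried as umol N, e.g. rows `"N2O-N"`, `"N2-N"`, `"NO-N"`).
#' @slot sampled logical, one flag per timepoint.
#' @slot injections data.frame with columns `time`, `gas`, `amount`.
#' @export
setClass("GasSeries",
  slots = c(times = "numeric", amounts = "matrix", sampled = "logical",
            injections = "data.frame"))

setValidity("GasSeries", function(object) {
  n <- length(object@times)
  if (n < 1L || any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  if (ncol(object@amounts) != n) return("amounts must have one column per timepoint")
  if (is.null(rownames(object@amounts))) return("amounts must have gas rownames")
  if (any(object@amounts < 0)) return("amounts must be >= 0")
  if (length(object@sampled) != n) return("one sampled flag per timepoint required")
  inj <- object@injections
  if (!all(c("time", "gas", "amount") %in% names(inj)))
    return("injections needs columns time, gas, amount")
  if (nrow(inj) > 0 && any(inj$amount < 0)) return("injections must be >= 0")
  TRUE
})

#' Dilution- and leakage-corrected gas series
#'
#' `amounts` are the headspace amounts reconstructed as if no sample had ever
#' been withdrawn and nothing had leaked (injections remain included);
#' `cumulative_production` additionally nets out injections and starts at 0;
#' `rates` are per-interval production rates (umol h^-1 vial^-1).
#'
#' @slot times numeric, hours.
#' @slot amounts numeric matrix, gas x time.
#' @slot cumulative_production numeric matrix, gas x time.
#' @slot rates numeric matrix, gas x (time - 1) interval rates.
#' @export
setClass("CorrectedSeries",
  slots = c(times = "numeric", amounts = "matrix",
            cumulative_production = "matrix", rates = "matrix"))

setValidity("CorrectedSeries", function(object) {
  n <- length(object@times)
  if (ncol(object@amounts) != n || ncol(object@cumulative_production) != n)
    return("amount matrices must have one column per timepoint")
  if (ncol(object@rates) != n - 1L)
    return("rates must have one column per interval")
  if (any(abs(object@cumulative_production[, 1]) > 1e-9))
    return("cumulative production must start at 0")
  TRUE
})

#' Two-population exponential decomposition of a rate curve
#'
#' Fit of r(t) = A exp(mu1 t) + B exp(mu2 t) with mu1 < 0 < mu2, used to
#' separate a declining N2O-respiring population from one growing from
#' initially very low numbers.
#'
#' @slot amplitude_decline numeric, A (umol N h^-1).
#' @slot rate_decline numeric, mu1 (h^-1, < 0).
#' @slot amplitude_growth numeric, B (umol N h^-1).
#' @slot rate_growth numeric, mu2 (h^-1, > 0).
#' @slot residual_norm numeric, residual sum-of-squares root.
#' @slot times numeric, input times.
#' @slot fitted numeric, fitted rates at `times`.
#' @export
setClass("TwoPopFit",
  slots = c(amplitude_decline = "numeric", rate_decline = "numeric",
            amplitude_growth = "numeric", rate_growth = "numeric",
            residual_norm = "numeric", times = "numeric", fitted = "numeric"))

setValidity("TwoPopFit", function(object) {
  if (object@amplitude_decline < 0 || object@amplitude_growth < 0)
    return("amplitudes must be >= 0")
  if (!(object@rate_decline < 0) || !(object@rate_growth > 0))
    return("rate_decline must be < 0 and rate_growth > 0")
  TRUE
})

# ---------------------------------------------------------------------------
# Community containers
# ---------------------------------------------------------------------------

#' OTU count table with enrichment-series metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding an integer
#' `counts` assay (OTUs as rows, samples as columns) and per-sample metadata
#' columns `line` (enrichment line, e.g. `"D"` or `"SD"`), `replicate`
#' (letter), `cycle` (sequential enrichment number, 0 = inoculum), `substrate`
#' (`"soil"`, `"digestate"`, `"inoculum"` or `"sterile_control"`) and
#' optionally `total_copies` (ddPCR 16S copies per vial).
#'
#' @export
setClass("OTUExperiment", contains = "SummarizedExperiment")

setValidity("OTUExperiment", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("an assay named 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    return("counts must be non-negative integers")
  cd <- SummarizedExperiment::colData(object)
  need <- c("line", "replicate", "cycle", "substrate")
  missing <- setdiff(need, colnames(cd))
  if (length(missing) > 0)
    return(paste("missing sample metadata columns:", paste(missing, collapse = ", ")))
  if (any(cd$substrate == "inoculum" & cd$cycle != 0))
    return("inoculum samples must carry cycle 0")
  if (anyDuplicated(colnames(object)) || anyDuplicated(rownames(object)))
    return("sample and OTU ids must be unique")
  TRUE
})

#' OTU-to-clade assignment from hierarchical clustering
#'
#' @slot clades factor, clade label per clustered OTU (named by OTU id).
#' @slot tree the `hclust` linkage record.
#' @export
setClass("CladeMap", slots = c(clades = "factor", tree = "ANY"))

setValidity("CladeMap", function(object) {
  if (is.null(names(object@clades))) return("clades must be named by OTU id")
  if (!inherits(object@tree, "hclust")) return("tree must be an hclust object")
  TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SubstrateEnv", function(object) {
  cat(sprintf("SubstrateEnv '%s': K = %.3g, duration = %g h\n",
              object@substrate_id, object@carrying_capacity, object@duration))
})

setMethod("show", "SpeciesTraits", function(object) {
  fmt <- function(x) paste(sprintf("%s=%.3g", names(x) %||% "all", x), collapse = ", ")
  cat(sprintf("SpeciesTraits '%s'\n  growth (h^-1): %s\n  death  (h^-1): %s\n",
              object@name, fmt(object@growth_rate), fmt(object@death_rate)))
})

setMethod("show", "TransferProtocol", function(object) {
  subs <- vapply(object@substrate_sequence, function(e) e@substrate_id, character(1))
  cat(sprintf(
    "TransferProtocol: %d passage(s) of [%s], f = %g\n  species: %s\n",
    object@n_passages, paste(subs, collapse = " -> "), object@transfer_fraction,
    paste(names(object@initial_abundance), collapse = ", ")))
})

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d species x %d timepoints over %d enrichment(s), t in [%g, %g] h\n",
              nrow(object@abundances), length(object@times),
              length(object@enrichment_boundaries),
              min(object@times), max(object@times)))
})

setMethod("show", "RegimeResult", function(object) {
  cat(sprintf("RegimeResult over %d ratios in [%g, %g]; critical ratio = %.4g\n",
              length(object@ratio_grid), min(object@ratio_grid),
              max(object@ratio_grid), object@critical_ratio))
  print(table(object@outcome))
})

setMethod("show", "VialSpec", function(object) {
  cat(sprintf("VialSpec: %g mL total, %g mL liquid (headspace %g mL), %g mL per sample\n",
              object@total_volume, object@liquid_volume,
              object@total_volume - object@liquid_volume, object@sample_volume))
})

setMethod("show", "GasSeries", function(object) {
  cat(sprintf("GasSeries: %s; %d timepoints over [%g, %g] h; %d sampling event(s), %d injection(s)\n",
              paste(rownames(object@amounts), collapse = ", "),
              length(object@times), min(object@times), max(object@times),
              sum(object@sampled), nrow(object@injections)))
})

setMethod("show", "CorrectedSeries", function(object) {
  cat(sprintf("CorrectedSeries: %s; %d timepoints over [%g, %g] h\n",
              paste(rownames(object@amounts), collapse = ", "),
              length(object@times), min(object@times), max(object@times)))
})

setMethod("show", "TwoPopFit", function(object) {
  cat(sprintf(
    "TwoPopFit: r(t) = %.4g*exp(%.4g t) + %.4g*exp(%.4g t)  (residual norm %.3g)\n",
    object@amplitude_decline, object@rate_decline,
    object@amplitude_growth, object@rate_growth, object@residual_norm))
})

setMethod("show", "CladeMap", function(object) {
  cat(sprintf("CladeMap: %d OTUs in %d clade(s)\n",
              length(object@clades), nlevels(object@clades)))
  print(table(object@clades))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
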