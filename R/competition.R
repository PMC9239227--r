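# Serial-transfer Lotka-Volterra competition model.
#
# Within one batch the community follows logistic growth on a shared substrate
# pool with a separate first-order death term:
#
#   dN_i/dt = mu_i(s) * N_i * (1 - B/K_s) - d_i(s) * N_i,   B = sum_j N_j
#
# Batches are chained by multiplying every abundance by the transfer fraction
# f at the start of each enrichment (inoculation counts as a transfer).

#' Simulate one batch enrichment
#'
#' Integrates the shared-capacity logistic competition model over the duration
#' of a single enrichment.
#'
#' @param env A [SubstrateEnv-class].
#' @param traits list of [SpeciesTraits-class]; every species needs a growth
#'   and death rate resolvable for `env`'s substrate.
#' @param initial named numeric vector of initial abundances (>= 0); names
#'   must match the trait names.
#' @param times output time grid (hours, starting at 0); default 51 points
#'   over the enrichment.
#' @param rtol,atol_frac integration tolerances: relative tolerance and
#'   absolute tolerance expressed as a fraction of the carrying capacity.
#' @return A [Trajectory-class] covering one enrichment.
#' @examples
#' env <- substrateEnv("soil", 1e9, 24)
#' tr <- speciesTraits("A", growth_rate = 0.1)
#' traj <- simulateEnrichment(env, list(tr), c(A = 1e7))
#' @export
simulateEnrichment <- function(env, traits, initial, times = NULL,
                               rtol = 1e-8, atol_frac = 1e-12) {
  species <- vapply(traits, function(x) x@name, character(1))
  if (anyDuplicated(species)) stopf("duplicated species names in traits")
  if (is.null(names(initial)) || !setequal(names(initial), species))
    stopf("initial abundances must be named and match the traits")
  initial <- initial[species]
  if (any(!is.finite(initial)) || any(initial < 0))
    stopf("initial abundances must be finite and >= 0")
  if (is.null(times)) times <- seq(0, env@duration, length.out = 51L)

  s <- env@substrate_id
  mu <- vapply(traits, traitRate, numeric(1), which = "growth", substrate = s)
  dd <- vapply(traits, traitRate, numeric(1), which = "death", substrate = s)
  K <- env@carrying_capacity

  ## Species with no dynamics on this substrate stay constant; keeping them
  ## out of the solver keeps large synthetic communities cheap. Their biomass
  ## still occupies the shared pool.
  active <- mu > 0 | dd > 0
  inert_total <- sum(initial[!active])

  if (any(active)) {
    deriv <- function(t, y, p) {
      y <- pmax(y, 0)
      B <- sum(y) + inert_total
      list(mu[active] * y * (1 - B / K) - dd[active] * y)
    }
    sol <- deSolve::ode(y = initial[active], times = times, func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol_frac * K)
    state <- t(sol[, -1, drop = FALSE])
    if (any(!is.finite(state))) {
      bad <- which(!is.finite(state), arr.ind = TRUE)[1, ]
      stopf("non-finite abundance for species '%s' at t = %g h",
            species[active][bad[1]], times[bad[2]])
    }
    state <- pmax(state, 0)
  } else {
    state <- matrix(0, nrow = 0, ncol = length(times))
  }

  ab <- matrix(0, nrow = length(species), ncol = length(times),
               dimnames = list(species, NULL))
  ab[active, ] <- state
  ab[!active, ] <- initial[!active]

  new("Trajectory", times = times, abundances = ab,
      enrichment_boundaries = 1L, enrichment_substrate = s)
}

#' Run a full serial-transfer series
#'
#' Chains [simulateEnrichment()] over `n_passages` repetitions of the
#' protocol's substrate sequence. All abundances are multiplied by the
#' transfer fraction f at the start of every enrichment.
#'
#' @param protocol A [TransferProtocol-class].
#' @param traits list of [SpeciesTraits-class].
#' @param points_per_enrichment output resolution within each enrichment
#'   (>= 2). Use 2 to record only enrichment endpoints.
#' @return A [Trajectory-class] spanning all enrichments.
#' @export
runTransferSeries <- function(protocol, traits, points_per_enrichment = 25L) {
  f <- protocol@transfer_fraction
  state <- protocol@initial_abundance
  envs <- rep(protocol@substrate_sequence, protocol@n_passages)

  times <- numeric(0)
  blocks <- vector("list", length(envs))
  boundaries <- integer(length(envs))
  substrates <- character(length(envs))
  t0 <- 0

  for (k in seq_along(envs)) {
    env <- envs[[k]]
    state <- f * state
    grid <- seq(0, env@duration, length.out = max(2L, points_per_enrichment))
    traj <- simulateEnrichment(env, traits, state, times = grid)
    boundaries[k] <- length(times) + 1L
    substrates[k] <- env@substrate_id
    times <- c(times, t0 + traj@times)
    blocks[[k]] <- traj@abundances
    state <- traj@abundances[, ncol(traj@abundances)]
    t0 <- t0 + env@duration
  }

  ## Boundary timepoints repeat (end of one enrichment, start of the next at
  ## the same clock time after dilution); offset starts by a tick so the time
  ## axis stays strictly increasing for plotting and storage.
  eps <- min(vapply(envs, function(e) e@duration, numeric(1))) * 1e-9
  for (k in seq_along(envs)[-1]) times[boundaries[k]] <- times[boundaries[k]] + eps

  new("Trajectory", times = times, abundances = do.call(cbind, blocks),
      enrichment_boundaries = boundaries, enrichment_substrate = substrates)
}

#' Passages until a species dominates
#'
#' Number of completed passages after which the target species' relative
#' abundance first exceeds `threshold` at the end of an enrichment; 0 if it is
#' already dominant in the inoculum; `NA` if dominance is not reached within
#' the protocol's passage limit.
#'
#' @param protocol A [TransferProtocol-class]; its `n_passages` is the search
#'   limit.
#' @param traits list of [SpeciesTraits-class].
#' @param target_species name of the species of interest.
#' @param dominance_threshold relative-abundance threshold in (0, 1),
#'   default 0.5.
#' @param unit `"passage"` counts full cycles of the substrate sequence
#'   (default); `"enrichment"` counts individual enrichments.
#' @return Integer number of passages, or `NA_integer_`.
#' @export
passagesToDominance <- function(protocol, traits, target_species,
                                dominance_threshold = 0.5,
                                unit = c("passage", "enrichment")) {
  unit <- match.arg(unit)
  if (!is_scalar_number(dominance_threshold) ||
      dominance_threshold <= 0 || dominance_threshold >= 1)
    stopf("dominance_threshold must lie in (0, 1)")
  species <- vapply(traits, function(x) x@name, character(1))
  if (!target_species %in% species)
    stopf("unknown species '%s'", target_species)

  init <- protocol@initial_abundance
  if (sum(init) > 0 && init[[target_species]] / sum(init) > dominance_threshold)
    return(0L)

  traj <- runTransferSeries(protocol, traits, points_per_enrichment = 2L)
  ends <- endOfEnrichmentStates(traj)
  rel <- ends[target_species, ] / colSums(ends)
  hit <- which(rel > dominance_threshold)
  if (length(hit) == 0L) return(NA_integer_)
  k <- hit[1]
  if (unit == "enrichment") return(as.integer(k))
  as.integer(ceiling(k / length(protocol@substrate_sequence)))
}

#' Build generalist traits at a growth-rate ratio
#'
#' The generalist's growth rate on each substrate is `ratio` times the rate of
#' the specialist of that substrate; its death rate is zero on both.
#'
#' @param soil_specialist,digestate_specialist [SpeciesTraits-class] of the
#'   two specialists.
#' @param ratio generalist:specialist growth-rate ratio (> 0).
#' @param name generalist label, default `"G"`.
#' @param soil_id,digestate_id substrate ids, defaults `"soil"`, `"digestate"`.
#' @return A [SpeciesTraits-class] for the generalist.
#' @export
ratioTraits <- function(soil_specialist, digestate_specialist, ratio,
                        name = "G", soil_id = "soil", digestate_id = "digestate") {
  g <- c(ratio * traitRate(soil_specialist, "growth", soil_id),
         ratio * traitRate(digestate_specialist, "growth", digestate_id))
  names(g) <- c(soil_id, digestate_id)
  speciesTraits(name, growth_rate = g, death_rate = 0)
}

## Elimination test for a rare generalist: simulate cycles until the two
## specialists' end-of-cycle relative abundances stabilise (quasi-steady
## state), then judge the generalist by its per-cycle fold change.
eliminatedAtRatio <- function(protocol, traits_template, ratio,
                              max_cycles = 60L, qss_tol = 1e-6) {
  gen <- ratioTraits(traits_template$soil_specialist,
                     traits_template$digestate_specialist, ratio,
                     name = traits_template$generalist_name %||% "G")
  traits <- list(traits_template$soil_specialist,
                 traits_template$digestate_specialist, gen)
  gname <- gen@name
  spec_names <- c(traits_template$soil_specialist@name,
                  traits_template$digestate_specialist@name)
  f <- protocol@transfer_fraction
  envs <- protocol@substrate_sequence
  state <- protocol@initial_abundance

  prev_gen <- state[[gname]]
  prev_rel <- NULL
  fold <- NA_real_
  for (cycle in seq_len(max_cycles)) {
    for (env in envs) {
      state <- f * state
      traj <- simulateEnrichment(env, traits, state, times = c(0, env@duration))
      state <- traj@abundances[, 2]
    }
    g <- state[[gname]]
    if (g <= 0) return(TRUE)
    tot <- sum(state)
    if (g / tot > 0.5) return(FALSE)
    fold <- g / prev_gen
    prev_gen <- g
    rel_spec <- state[spec_names] / tot
    if (!is.null(prev_rel) && max(abs(rel_spec - prev_rel)) < qss_tol)
      return(fold < 1)
    prev_rel <- rel_spec
  }
  fold < 1
}

#' Critical generalist:specialist growth-rate ratio
#'
#' Bisection on the boundary between long-run elimination and persistence of
#' the generalist. A ratio counts as "eliminated" when the generalist's
#' per-cycle fold change is below 1 once the serial-transfer series has
#' reached a periodic quasi-steady state (end-of-cycle relative abundances of
#' the two specialists changing by less than `qss_tol` between cycles).
#'
#' @param protocol A [TransferProtocol-class] with initial abundances for both
#'   specialists and the generalist.
#' @param traits_template list with elements `soil_specialist`,
#'   `digestate_specialist` ([SpeciesTraits-class]) and optionally
#'   `generalist_name` (default `"G"`); the generalist is rebuilt at each
#'   candidate ratio via [ratioTraits()].
#' @param lo,hi bracketing ratios: the generalist must be eliminated at `lo`
#'   and persistent at `hi`.
#' @param tol bisection tolerance on the ratio, default 0.005.
#' @param max_cycles cycle limit for quasi-steady-state detection.
#' @param qss_tol stationarity tolerance on specialist relative abundances.
#' @return The boundary ratio (midpoint of the final bracket).
#' @export
criticalRatio <- function(protocol, traits_template, lo = 0.1, hi = 0.5,
                          tol = 0.005, max_cycles = 60L, qss_tol = 1e-6) {
  if (!(lo < hi)) stopf("need lo < hi")
  elim_lo <- eliminatedAtRatio(protocol, traits_template, lo, max_cycles, qss_tol)
  elim_hi <- eliminatedAtRatio(protocol, traits_template, hi, max_cycles, qss_tol)
  if (!elim_lo || elim_hi)
    stopf(paste0("invalid bracket: generalist must be eliminated at lo and ",
                 "persistent at hi (eliminated at lo: %s, at hi: %s)"),
          elim_lo, elim_hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (eliminatedAtRatio(protocol, traits_template, mid, max_cycles, qss_tol))
      lo <- mid
    else
      hi <- mid
  }
  (lo + hi) / 2
}

#' Map enrichment outcomes over a grid of growth-rate ratios
#'
#' Classifies each ratio as `"eliminated"` (per-cycle fold change < 1 at
#' quasi-steady state), `"dominant_within_limit"` (relative abundance exceeds
#' 0.5 within the protocol's passage limit) or `"slow_enrichment"` (persists
#' but does not dominate within the limit).
#'
#' @inheritParams criticalRatio
#' @param ratios numeric vector of generalist:specialist ratios to scan.
#' @param dominance_threshold threshold for dominance, default 0.5.
#' @return A [RegimeResult-class].
#' @export
regimeScan <- function(protocol, traits_template, ratios,
                       dominance_threshold = 0.5, max_cycles = 60L) {
  outcome <- character(length(ratios))
  passages <- rep(NA_real_, length(ratios))
  for (i in seq_along(ratios)) {
    gen <- ratioTraits(traits_template$soil_specialist,
                       traits_template$digestate_specialist, ratios[i],
                       name = traits_template$generalist_name %||% "G")
    traits <- list(traits_template$soil_specialist,
                   traits_template$digestate_specialist, gen)
    p <- passagesToDominance(protocol, traits, gen@name, dominance_threshold)
    if (!is.na(p)) {
      outcome[i] <- "dominant_within_limit"
      passages[i] <- p
    } else if (eliminatedAtRatio(protocol, traits_template, ratios[i], max_cycles)) {
      outcome[i] <- "eliminated"
    } else {
      outcome[i] <- "slow_enrichment"
    }
  }
  crit <- tryCatch(
    criticalRatio(protocol, traits_template, lo = min(ratios), hi = max(ratios),
                  max_cycles = max_cycles),
    error = function(e) NA_real_)
  new("RegimeResult", ratio_grid = ratios, outcome = outcome,
      passages_to_dominance = passages, critical_ratio = crit)
}
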