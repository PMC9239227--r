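# Synthetic enrichment-series and gas-curve generators with planted ground
# truth. These emulate the dual-enrichment study design: two enrichment lines
# (digestate-derived "D" and mixed "SD"), replicated serial transfers
# alternating between sterilized digestate and soil, 16S amplicon counts with
# ddPCR totals, relic-DNA pools, and robotized headspace gas monitoring with
# sampling dilution and N2O reinjection.

#' Specification of a synthetic enrichment community
#'
#' @param n_digestate_specialists,n_soil_specialists,n_generalists,n_washout
#'   taxon counts per niche category. Washout taxa have no growth and no
#'   death and decline purely by transfer dilution.
#' @param trait_ranges per-category uniform ranges for growth and death rates
#'   (h^-1): a list with elements `mu_specialist`, `d_specialist`
#'   (specialist death in the non-preferred substrate) and `mu_generalist`.
#' @param relic_pools relic-DNA pools in the sterilized materials: a list of
#'   lists with elements `material` (`"digestate"` or `"soil"`), `n` (OTUs)
#'   and `copies` (initial copies per vial, log-uniform range).
#' @param relic_decay optional additional first-order decay of relic DNA per
#'   enrichment (on top of transfer dilution), default 0.
#' @param sequencing_depth reads per sample, default 9000.
#' @param ddpcr_noise_cv lognormal coefficient of variation of ddPCR totals,
#'   default 0.1.
#' @param n_replicates replicate lines A, B, ... per enrichment line,
#'   default 7.
#' @param n_cycles sequential enrichments per line, default 7.
#' @param count_model `"multinomial"` (default) draws reads multinomially;
#'   `"expected"` uses deterministic rounded expected counts (the noise-free
#'   limit).
#' @param seed RNG seed for trait draws and sampling noise.
#' @return A list of class `CommunitySpec`.
#' @export
communitySpec <- function(n_digestate_specialists = 40L,
                          n_soil_specialists = 40L,
                          n_generalists = 20L,
                          n_washout = 250L,
                          trait_ranges = list(
                            mu_specialist = c(0.09, 0.13),
                            d_specialist = c(0.015, 0.03),
                            mu_generalist = c(0.08, 0.11)),
                          relic_pools = list(
                            list(material = "digestate", n = 100L,
                                 copies = c(1e8, 1e9)),
                            list(material = "soil", n = 50L,
                                 copies = c(1e6, 1e7))),
                          relic_decay = 0,
                          sequencing_depth = 9000L,
                          ddpcr_noise_cv = 0.1,
                          n_replicates = 7L,
                          n_cycles = 7L,
                          count_model = c("multinomial", "expected"),
                          seed = 1L) {
  counts <- c(n_digestate_specialists, n_soil_specialists, n_generalists,
              n_washout)
  if (any(counts < 0) ||
      sum(counts) + sum(vapply(relic_pools, function(p) as.numeric(p$n), 0)) < 1)
    stopf("at least one taxon is required and counts must be >= 0")
  if (sequencing_depth <= 0) stopf("sequencing_depth must be > 0")
  structure(list(
    n_digestate_specialists = as.integer(n_digestate_specialists),
    n_soil_specialists = as.integer(n_soil_specialists),
    n_generalists = as.integer(n_generalists),
    n_washout = as.integer(n_washout),
    trait_ranges = trait_ranges, relic_pools = relic_pools,
    relic_decay = relic_decay,
    sequencing_depth = as.integer(sequencing_depth),
    ddpcr_noise_cv = ddpcr_noise_cv,
    n_replicates = as.integer(n_replicates), n_cycles = as.integer(n_cycles),
    count_model = match.arg(count_model), seed = as.integer(seed)),
    class = "CommunitySpec")
}

## Draw taxon traits and line-specific inoculum abundances for a spec.
## Everything is drawn inside one seeded block so that identical seeds give
## identical communities.
plantCommunity <- function(spec) {
  tr <- spec$trait_ranges
  runifn <- function(n, range) stats::runif(n, range[1], range[2])

  ids <- character(0); category <- character(0)
  traits <- list()
  add <- function(n, prefix, cat, mu_soil, mu_dig, d_soil, d_dig) {
    if (n == 0L) return(invisible())
    for (i in seq_len(n)) {
      id <- sprintf("%s%03d", prefix, i)
      ids <<- c(ids, id); category <<- c(category, cat)
      traits[[id]] <<- speciesTraits(
        id,
        growth_rate = c(soil = mu_soil[i], digestate = mu_dig[i]),
        death_rate = c(soil = d_soil[i], digestate = d_dig[i]))
    }
  }

  withSeed(spec$seed, {
    nd <- spec$n_digestate_specialists
    ns <- spec$n_soil_specialists
    ng <- spec$n_generalists
    nw <- spec$n_washout
    add(nd, "DSP", "digestate_specialist",
        mu_soil = rep(0, nd), mu_dig = runifn(nd, tr$mu_specialist),
        d_soil = runifn(nd, tr$d_specialist), d_dig = rep(0, nd))
    add(ns, "SSP", "soil_specialist",
        mu_soil = runifn(ns, tr$mu_specialist), mu_dig = rep(0, ns),
        d_soil = rep(0, ns), d_dig = runifn(ns, tr$d_specialist))
    add(ng, "GEN", "generalist",
        mu_soil = runifn(ng, tr$mu_generalist),
        mu_dig = runifn(ng, tr$mu_generalist),
        d_soil = rep(0, ng), d_dig = rep(0, ng))
    add(nw, "WSH", "washout",
        mu_soil = rep(0, nw), mu_dig = rep(0, nw),
        d_soil = rep(0, nw), d_dig = rep(0, nw))

    relic_ids <- character(0); relic_material <- character(0)
    relic_copies <- numeric(0)
    for (pool in spec$relic_pools) {
      if (pool$n == 0L) next
      pid <- sprintf("RLC_%s_%03d", substr(pool$material, 1, 3),
                     seq_len(pool$n))
      relic_ids <- c(relic_ids, pid)
      relic_material <- c(relic_material, rep(pool$material, pool$n))
      relic_copies <- c(relic_copies,
                        exp(stats::runif(pool$n, log(pool$copies[1]),
                                         log(pool$copies[2]))))
    }

    ## Inoculum abundances: digestate-origin taxa are abundant in the D line;
    ## the SD line mixes soil- and digestate-origin organisms. Soil-origin
    ## taxa enter the D line only as a trace (carry-over/detection floor).
    lognorm <- function(n, mean_log10, sd_log10)
      10^stats::rnorm(n, mean_log10, sd_log10)
    n_tax <- length(ids)
    init <- list(D = numeric(n_tax), SD = numeric(n_tax))
    names(init$D) <- names(init$SD) <- ids
    dig_origin <- category %in% c("digestate_specialist", "generalist", "washout")
    soil_origin <- category == "soil_specialist"
    init$D[dig_origin] <- lognorm(sum(dig_origin), 7, 0.5)
    init$D[soil_origin] <- lognorm(sum(soil_origin), 3, 0.5)
    init$SD[dig_origin] <- lognorm(sum(dig_origin), 6.8, 0.5)
    init$SD[soil_origin] <- lognorm(sum(soil_origin), 6.8, 0.5)

    list(ids = ids, category = category, traits = unname(traits),
         relic = data.frame(otu_id = relic_ids, material = relic_material,
                            copies = relic_copies),
         initial = init)
  })
}

#' Generate a synthetic dual-enrichment OTU dataset
#'
#' Runs the serial-transfer competition model over all planted taxa for the
#' two enrichment lines, adds relic-DNA pools declining by transfer dilution,
#' and converts end-of-enrichment abundances into multinomial amplicon counts
#' and lognormally perturbed ddPCR totals. Sterile-material background
#' samples and cycle-0 inoculum samples are included.
#'
#' @param spec A spec from [communitySpec()].
#' @param protocol A [TransferProtocol-class] defining substrate alternation,
#'   durations, capacities and transfer fraction; defaults to the package's
#'   calibrated protocol with `n_passages` chosen to cover `spec$n_cycles`
#'   enrichments. Its `initial_abundance` is ignored (the community is
#'   planted from `spec`).
#' @return A list with elements `experiment` (an [OTUExperiment-class] with
#'   ddPCR totals), `truth` (data.frame `otu_id`, `category`) and
#'   `trajectories` (true end-of-enrichment abundance matrices per line).
#' @export
generateEnrichmentDataset <- function(spec, protocol = NULL) {
  if (!inherits(spec, "CommunitySpec")) stopf("spec must come from communitySpec()")
  if (is.null(protocol)) {
    protocol <- defaultProtocol(
      n_passages = as.integer(ceiling(spec$n_cycles / 2)))
  }
  planted <- plantCommunity(spec)
  f <- protocol@transfer_fraction
  envs <- rep(protocol@substrate_sequence, protocol@n_passages)
  if (length(envs) < spec$n_cycles)
    stopf("protocol covers %d enrichments but spec requires %d",
          length(envs), spec$n_cycles)
  envs <- envs[seq_len(spec$n_cycles)]

  ## Relic DNA: present in the sterilized material; in inoculated enrichments
  ## it declines by transfer dilution (optionally plus first-order decay).
  relic <- planted$relic
  relicAt <- function(cycle) {
    relic$copies * f^cycle * exp(-spec$relic_decay * cycle)
  }

  ## True dynamics are deterministic given traits, so one trajectory per
  ## line is shared by all replicates; replicate variation enters through
  ## sequencing and ddPCR noise.
  lines <- c("D", "SD")
  traj <- list()
  for (ln in lines) {
    state <- planted$initial[[ln]]
    ends <- matrix(0, nrow = length(state), ncol = spec$n_cycles,
                   dimnames = list(planted$ids, NULL))
    for (j in seq_len(spec$n_cycles)) {
      state <- f * state
      tr <- simulateEnrichment(envs[[j]], planted$traits, state,
                               times = c(0, envs[[j]]@duration))
      state <- tr@abundances[, 2]
      ends[, j] <- state
    }
    if (nrow(relic) > 0) {
      relic_mat <- matrix(vapply(seq_len(spec$n_cycles), relicAt,
                                 numeric(nrow(relic))),
                          nrow = nrow(relic),
                          dimnames = list(relic$otu_id, NULL))
      ends <- rbind(ends, relic_mat)
    }
    traj[[ln]] <- ends
  }

  all_ids <- c(planted$ids, relic$otu_id)
  truth <- data.frame(
    otu_id = all_ids,
    category = c(planted$category, rep("washout", nrow(relic))),
    origin = c(rep("live", length(planted$ids)),
               if (nrow(relic) > 0) paste0("relic_", relic$material)))

  ## Assemble samples: inocula (cycle 0), enrichment ends (cycles 1..n per
  ## replicate), sterile materials.
  sample_rows <- list(); meta_rows <- list()
  addSample <- function(id, abund, line, replicate, cycle, substrate) {
    sample_rows[[id]] <<- abund
    meta_rows[[id]] <<- data.frame(sample_id = id, line = line,
                                   replicate = replicate, cycle = cycle,
                                   substrate = substrate)
  }
  zeros <- setNames(rep(0, length(all_ids)), all_ids)
  reps <- LETTERS[seq_len(spec$n_replicates)]
  for (ln in lines) {
    inoc <- zeros
    inoc[planted$ids] <- planted$initial[[ln]]
    inoc[relic$otu_id] <- relic$copies
    addSample(paste0(ln, "_0"), inoc, ln, "A", 0L, "inoculum")
    for (r in reps) for (j in seq_len(spec$n_cycles)) {
      ab <- traj[[ln]][all_ids, j]
      addSample(sprintf("%s_%s_%d", ln, r, j), ab, ln, r, j,
                envs[[j]]@substrate_id)
    }
  }
  for (pool_material in unique(relic$material)) {
    ab <- zeros
    sel <- relic$material == pool_material
    ab[relic$otu_id[sel]] <- relic$copies[sel]
    addSample(paste0("sterile_", pool_material), ab, "D", "A", 0L,
              "sterile_control")
  }

  truth_mat <- do.call(cbind, sample_rows)
  rownames(truth_mat) <- all_ids

  out <- withSeed(spec$seed + 1L, {
    depth <- spec$sequencing_depth
    counts <- matrix(0L, nrow = nrow(truth_mat), ncol = ncol(truth_mat),
                     dimnames = dimnames(truth_mat))
    totals <- numeric(ncol(truth_mat))
    names(totals) <- colnames(truth_mat)
    for (s in seq_len(ncol(truth_mat))) {
      tot <- sum(truth_mat[, s])
      rel <- truth_mat[, s] / tot
      counts[, s] <- if (spec$count_model == "multinomial")
        as.integer(stats::rmultinom(1, depth, rel))
      else {
        ## deterministic noise-free limit: largest-remainder rounding to depth
        exp_cts <- rel * depth
        base_ct <- floor(exp_cts)
        short <- depth - sum(base_ct)
        if (short > 0) {
          topup <- order(exp_cts - base_ct, decreasing = TRUE)[seq_len(short)]
          base_ct[topup] <- base_ct[topup] + 1
        }
        as.integer(base_ct)
      }
      totals[s] <- if (spec$ddpcr_noise_cv > 0) {
        sdlog <- sqrt(log(1 + spec$ddpcr_noise_cv^2))
        tot * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
      } else tot
    }
    list(counts = counts, totals = totals)
  })

  meta <- do.call(rbind, meta_rows)
  experiment <- otuExperiment(out$counts, meta, total_copies = out$totals)
  list(experiment = experiment, truth = truth, trajectories = traj)
}

#' Specification of a synthetic gas incubation
#'
#' @param populations data.frame with one row per N2O-respiring population:
#'   columns `rate0` (initial N2O-N -> N2-N conversion rate, umol N h^-1) and
#'   `exponent` (h^-1; negative = declining population, positive = growing).
#' @param n2o_dose initial N2O dose, umol N2O (default 124.7, i.e. 3 mL);
#'   internally tracked as umol N2O-N (x2).
#' @param o2_dose initial O2 dose, umol (default 124.7 for enrichment
#'   cultures; 41.6 for phenotyping incubations).
#' @param o2_rate O2 consumption rate while oxygen remains (umol h^-1);
#'   N2O respiration starts only once O2 is depleted.
#' @param reinject_threshold,reinject_to reinject N2O when the headspace
#'   amount (umol N2O-N) falls below the threshold, refilling to
#'   `reinject_to`; defaults: threshold 50, refill to the initial dose.
#' @param max_reinjections error out if the policy demands more, default 50.
#' @param vial A [VialSpec-class].
#' @param sample_every sampling interval, h (default 2).
#' @param duration incubation length, h (default 100).
#' @param noise_cv multiplicative measurement noise CV (default 0 = exact).
#' @param seed RNG seed for measurement noise.
#' @return A list of class `GasSimSpec`.
#' @export
gasSimSpec <- function(populations = data.frame(rate0 = c(8, 0.001),
                                                exponent = c(-0.03, 0.1)),
                       n2o_dose = 124.7, o2_dose = 124.7, o2_rate = 10,
                       reinject_threshold = 50, reinject_to = NULL,
                       max_reinjections = 50L,
                       vial = vialSpec(), sample_every = 2, duration = 100,
                       noise_cv = 0, seed = 1L) {
  if (any(populations$rate0 < 0)) stopf("population rates must be >= 0")
  if (n2o_dose < 0 || o2_dose < 0) stopf("doses must be >= 0")
  structure(list(populations = populations, n2o_dose = n2o_dose,
                 o2_dose = o2_dose, o2_rate = o2_rate,
                 reinject_threshold = reinject_threshold,
                 reinject_to = reinject_to %||% (2 * n2o_dose),
                 max_reinjections = as.integer(max_reinjections),
                 vial = vial, sample_every = sample_every,
                 duration = duration, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "GasSimSpec")
}

#' Forward-simulate a headspace gas series
#'
#' Simulates biomass-proportional N2O respiration (N2O-N converted 1:1 to
#' N2-N, conserving N), preceded by an oxic phase during which O2 is consumed
#' and N2O respiration is repressed. The robotized monitoring is emulated:
#' at each sampling time the headspace is measured and a fixed sample volume
#' is withdrawn (replaced by He), diluting every gas; N2O is re-injected per
#' policy after sampling. Population rate integrals are computed in closed
#' form, so the true production curve is exact.
#'
#' @param spec A spec from [gasSimSpec()].
#' @return A list with `series` (the measured [GasSeries-class]), `truth`
#'   (data.frame of times and true cumulative N2-N production, undisturbed by
#'   sampling) and `n_reinjections`.
#' @export
generateGasSeries <- function(spec) {
  if (!inherits(spec, "GasSimSpec")) stopf("spec must come from gasSimSpec()")
  vh <- headspaceVolume(spec$vial)
  dil <- 1 - spec$vial@sample_volume / vh
  times <- seq(0, spec$duration, by = spec$sample_every)
  n <- length(times)
  gases <- c("O2", "N2O-N", "N2-N")

  ## closed-form integral of the total respiration rate over [t0, t1]
  rateIntegral <- function(t0, t1) {
    p <- spec$populations
    sum(ifelse(abs(p$exponent) < 1e-12,
               p$rate0 * (t1 - t0),
               p$rate0 / p$exponent *
                 (exp(p$exponent * t1) - exp(p$exponent * t0))))
  }

  state <- c(O2 = spec$o2_dose, `N2O-N` = 2 * spec$n2o_dose, `N2-N` = 0)
  measured <- matrix(0, nrow = 3, ncol = n, dimnames = list(gases, NULL))
  injections <- list()
  true_cum_n2 <- numeric(n)
  n_reinject <- 0L
  t_anoxic <- if (spec$o2_rate > 0) spec$o2_dose / spec$o2_rate else 0

  for (k in seq_len(n)) {
    if (k > 1) {
      t0 <- times[k - 1]; t1 <- times[k]
      ## oxic phase: O2 drawn down linearly, N2O untouched
      ox1 <- min(max(t_anoxic, t0), t1)
      state["O2"] <- max(0, state["O2"] - spec$o2_rate * (ox1 - t0))
      ## anoxic phase: N2O -> N2 at the populations' summed rate
      if (t1 > ox1) {
        conv <- min(rateIntegral(ox1, t1), state[["N2O-N"]])
        state["N2O-N"] <- state[["N2O-N"]] - conv
        state["N2-N"] <- state[["N2-N"]] + conv
        true_cum_n2[k] <- true_cum_n2[k - 1] + conv
      } else {
        true_cum_n2[k] <- true_cum_n2[k - 1]
      }
      if (t1 <= ox1) true_cum_n2[k] <- true_cum_n2[k - 1]
    }
    measured[, k] <- state
    ## sample: measure first, then withdraw and backfill with He
    state <- state * dil
    ## reinjection policy (after sampling, effective from this timepoint on)
    if (state[["N2O-N"]] < spec$reinject_threshold && k < n) {
      n_reinject <- n_reinject + 1L
      if (n_reinject > spec$max_reinjections)
        stopf("reinjection policy exceeded the cap of %d injections",
              spec$max_reinjections)
      dose <- spec$reinject_to - state[["N2O-N"]]
      state["N2O-N"] <- state[["N2O-N"]] + dose
      injections[[length(injections) + 1L]] <-
        data.frame(time = times[k], gas = "N2O-N", amount = dose)
    }
  }

  if (spec$noise_cv > 0) {
    measured <- withSeed(spec$seed, {
      measured * matrix(stats::rlnorm(length(measured),
                                      -log(1 + spec$noise_cv^2) / 2,
                                      sqrt(log(1 + spec$noise_cv^2))),
                        nrow = nrow(measured))
    })
  }

  inj_df <- if (length(injections) > 0) do.call(rbind, injections) else NULL
  series <- gasSeries(times, measured, sampled = rep(TRUE, n),
                      injections = inj_df)
  list(series = series,
       truth = data.frame(time = times, cumulative_N2 = true_cum_n2),
       n_reinjections = n_reinject)
}
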