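# Shared fixtures and independent oracles, built in code at test time.

## Closed-form logistic for a single death-free species sharing no pool.
logisticClosedForm <- function(K, N0, mu, t) {
  K * N0 * exp(mu * t) / (K + N0 * (exp(mu * t) - 1))
}

## Forward-simulate a monitored vial: true production `prod_fun(t0, t1)` per
## gas over an interval, scheduled samplings (measure, then withdraw and
## He-backfill), injections, and first-order leakage discretised at the
## interval midpoint (implicit form, so the corrector's midpoint rule inverts
## it exactly). Returns the raw GasSeries plus the true cumulative production.
forwardVial <- function(times, gases, prod_fun, vial,
                        sampled = rep(TRUE, length(times)),
                        injections = data.frame(time = numeric(0),
                                                gas = character(0),
                                                amount = numeric(0)),
                        initial = setNames(rep(0, length(gases)), gases)) {
  vh <- headspaceVolume(vial)
  dil <- 1 - vial@sample_volume / vh
  n <- length(times)
  A <- matrix(0, nrow = length(gases), ncol = n, dimnames = list(gases, NULL))
  true_cum <- A
  state <- initial[gases]
  for (k in seq_len(n)) {
    if (k > 1) {
      dt <- times[k] - times[k - 1]
      for (g in gases) {
        lam <- if (g %in% names(vial@leak_coefficient))
          vial@leak_coefficient[[g]] else 0
        amb <- if (g %in% names(vial@ambient_amount))
          vial@ambient_amount[[g]] else 0
        p <- prod_fun(g, times[k - 1], times[k])
        inj <- sum(injections$amount[injections$gas == g &
                                       injections$time >= times[k - 1] &
                                       injections$time < times[k]])
        ## implicit midpoint leak: A_new solves
        ## A_new = state + p + inj - lam*((A_new+state)/2 - amb)*dt
        state[g] <- (state[[g]] * (1 - lam * dt / 2) + p + inj +
                       lam * amb * dt) / (1 + lam * dt / 2)
        true_cum[g, k] <- true_cum[g, k - 1] + p
      }
    }
    A[, k] <- state
    if (sampled[k]) state <- state * dil
  }
  list(series = gasSeries(times, A, sampled = sampled,
                          injections = injections),
       true_cumulative = true_cum)
}

## Build a CorrectedSeries directly from undisturbed amount curves (no
## sampling, no injections): cumulative production = amounts - amounts[, 1].
correctedFromAmounts <- function(times, amounts) {
  raw <- gasSeries(times, amounts, sampled = rep(FALSE, length(times)))
  correctSeries(raw, vialSpec())
}

## Well-separated synthetic community: narrow within-category trait ranges
## (no within-guild competitive exclusion), observed in the noise-free limit
## (expected counts at depth 1e6, no ddPCR noise) over 4 cycles.
wellSeparatedSpec <- function(seed = 1L) {
  communitySpec(
    trait_ranges = list(mu_specialist = c(0.115, 0.125),
                        d_specialist = c(0.018, 0.022),
                        mu_generalist = c(0.09, 0.10)),
    ddpcr_noise_cv = 0, count_model = "expected",
    sequencing_depth = 1e6, n_cycles = 4L, seed = seed)
}

## Niche-label recovery of a generated dataset (rarefied if depth given).
nicheRecovery <- function(dataset, rarefy_depth = NULL, rarefy_seed = 2L) {
  expt <- dataset$experiment
  if (!is.null(rarefy_depth))
    expt <- rarefySamples(expt, depth = rarefy_depth, seed = rarefy_seed)
  niche <- classifyNiche(enrichmentRatios(expt))
  m <- merge(niche, dataset$truth, by = "otu_id", all.y = TRUE)
  m$category.x[is.na(m$category.x)] <- "washout"
  mean(m$category.x == m$category.y)
}

## Tiny two-line OTU experiment with exact pure-dilution series for OTU "W".
dilutionExperiment <- function(f = 0.1, n_cycles = 4L) {
  cycles <- 0:n_cycles
  total <- 1e9
  w0 <- 1e6
  counts <- matrix(0L, nrow = 2, ncol = length(cycles),
                   dimnames = list(c("W", "X"),
                                   paste0("D_A_", cycles)))
  totals <- numeric(length(cycles))
  for (i in seq_along(cycles)) {
    w <- w0 * f^cycles[i]
    x <- total - w
    counts[, i] <- as.integer(round(c(w, x) / total * 1e6))
    totals[i] <- total
  }
  names(totals) <- colnames(counts)
  meta <- data.frame(sample_id = colnames(counts), line = "D", replicate = "A",
                     cycle = cycles,
                     substrate = c("inoculum",
                                   rep(c("soil", "digestate"),
                                       length.out = n_cycles)))
  otuExperiment(counts, meta, total_copies = totals)
}
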