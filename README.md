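# dualenrich

Modeling and analysis tools for **dual enrichment** — serial batch culturing
that alternates between two sterilized substrates (soil and digestate) to
select **generalist** N2O-respiring bacteria: organisms that can both be
mass-produced in digestate and stay active after that digestate is spread on
soil as an N2O-mitigating inoculant.

The package is aimed at microbial ecologists running (or designing)
alternating-substrate enrichment experiments with robotized headspace gas
monitoring and 16S amplicon + ddPCR community profiling. It provides four
connected toolsets:

1. **Competition model** — a shared-pool Lotka–Volterra logistic model for a
   digestate specialist, a soil specialist and a generalist,

   dN\_i/dt = μ\_i(s)·N\_i·(1 − B/K\_s) − d\_i(s)·N\_i,  B = Σ\_j N\_j,

   chained through serial transfers (×f = 0.1 per batch). It answers: after
   how many passages does a generalist at a given growth-rate ratio
   dominate, and below which ratio is it washed out
   (`simulateEnrichment()`, `runTransferSeries()`, `passagesToDominance()`,
   `criticalRatio()`, `regimeScan()`, `calibrateDefaults()`).
2. **Gas kinetics** — dilution/leak-corrected production rates from raw
   headspace series (`correctSeries()`), two-population exponential rate
   decomposition r(t) = A·e^(μ₁t) + B·e^(μ₂t) (`twoPopulationFit()`),
   transfer survival fractions (`survivalFraction()`), electron flows
   (`electronFlow()`), nitrogen mass balance (`nMassBalance()`) and the
   emission index **I\_N2O** = ∫N2O-N dt / ∫(N2O-N + N2-N + NO-N) dt up to a
   40% or 100% N-oxyanion recovery time (`iN2O()`).
3. **Community statistics** — rarefaction, ddPCR-scaled absolute abundances,
   the per-enrichment ratio **R\_i = ln(N(i)/[N(i−1)·f])**, niche
   classification (generalist / specialist / washout by mean R\_soil and
   R\_digestate against a threshold of 2), Ward/Euclidean clade clustering
   and SIMPER contributions (`rarefySamples()`, `absoluteAbundance()`,
   `enrichmentRatios()`, `classifyNiche()`, `clusterClades()`,
   `simperContributions()`).
4. **Synthetic data** — seeded generators for dual-enrichment OTU datasets
   with planted ground truth and for monitored gas incubations with exact
   true production (`communitySpec()`, `generateEnrichmentDataset()`,
   `gasSimSpec()`, `generateGasSeries()`), plus an end-to-end pipeline
   driver (`runPipeline()`).

## Worked example

```r
library(dualenrich)

## 1. When does dual enrichment select a generalist?
prot <- defaultProtocol(n_passages = 7L)          # calibrated defaults, f = 0.1
passagesToDominance(prot, defaultTraits(0.5), "G")
#> [1] 3
criticalRatio(defaultProtocol(), defaultTraitsTemplate(), lo = 0.1, hi = 0.5,
              tol = 0.005)
#> [1] 0.2609375
```

A generalist growing at 50% of the specialists' rates, inoculated 10,000-fold
below them, exceeds 50% relative abundance after 3 full soil+digestate
passages; bisection puts the elimination boundary at a growth-rate ratio of
about 0.26 — below 26% of the specialists' rates the generalist is diluted
faster than it grows.

```r
## 2. Decompose an N2 production-rate curve into two populations
rc <- compositeRateCurve()    # declining + growing population, sampled 2-hourly
twoPopulationFit(rc$time, rc$rate)
#> TwoPopFit: r(t) = 8*exp(-0.03 t) + 0.001*exp(0.1 t)  (residual norm 8.57e-15)
```

The fit separates a waning population (decline −0.03 h⁻¹) from one growing
exponentially (0.1 h⁻¹) from initially ~1/8000 of the activity.

```r
## 3. Emission index of a denitrification incubation (50 umol NO3-N)
times <- seq(0, 100, by = 5)
n2o <- 30 * exp(-((times - 30) / 18)^2)        # transient N2O peak, umol N
n2  <- 50 * pmax(0, 1 - exp(-(times / 35)^2))  # N2 accumulating to 50 umol N
corr <- correctSeries(gasSeries(times, rbind("N2O-N" = n2o, "N2-N" = n2),
                                sampled = rep(FALSE, length(times))),
                      vialSpec())
c(iN2O(corr, 50, 0.40), iN2O(corr, 50, 1.00))
#> [1] 70.9 62.2
```

I\_N2O ≈ 71% over the window in which 40% of the nitrate is recovered as gas
(the early, N2O-dominated phase) and ≈ 62% over the full-recovery window —
the signature of an incubation that accumulates substantial N2O before
reducing it.

The methods vignette (`vignettes/dual-enrichment-methods.Rmd`) documents the
model assumptions, the calibration of the default parameter set, all
numerical conventions of the gas calculus, and what the synthetic-data tests
do and do not demonstrate.

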