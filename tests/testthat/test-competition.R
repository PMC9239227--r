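# Serial-transfer Lotka-Volterra competition model.

test_that("single-species limits: constant, logistic and exponential decay", {
  env <- substrateEnv("soil", 1e9, 24)

  # no dynamics
  still <- speciesTraits("A", growth_rate = 0, death_rate = 0)
  traj <- simulateEnrichment(env, list(still), c(A = 5e6))
  expect_true(all(abundances(traj) == 5e6))

  # death-free logistic against the closed form
  grower <- speciesTraits("A", growth_rate = 0.1, death_rate = 0)
  traj <- simulateEnrichment(env, list(grower), c(A = 1e7),
                             times = c(0, 24))
  expect_equal(unname(abundances(traj)["A", 2]),
               logisticClosedForm(1e9, 1e7, 0.1, 24),
               tolerance = 1e-6)

  # pure exponential decay
  dier <- speciesTraits("A", growth_rate = 0, death_rate = 0.05)
  traj <- simulateEnrichment(env, list(dier), c(A = 1e7), times = c(0, 24))
  expect_equal(unname(abundances(traj)["A", 2]), 1e7 * exp(-1.2), tolerance = 1e-7)

  expect_error(simulateEnrichment(env, list(grower), c(A = -1)),
               "initial abundances")
})

test_that("death-free trajectories match the logistic closed form over random draws", {
  set.seed(101)
  for (i in 1:100) {
    K <- 10^runif(1, 8, 10)
    N0 <- K * 10^runif(1, -4, -0.5)
    mu <- runif(1, 0.02, 0.3)
    T <- runif(1, 5, 100)
    env <- substrateEnv("soil", K, T)
    tr <- speciesTraits("A", growth_rate = mu)
    got <- unname(abundances(simulateEnrichment(env, list(tr), c(A = N0),
                                                times = c(0, T)))["A", 2])
    expect_equal(got, logisticClosedForm(K, N0, mu, T), tolerance = 1e-6)
  }
})

test_that("transfer series: dilution exactness, symmetry and absorbing zero", {
  soil <- substrateEnv("soil", 1e9, 48)
  dig <- substrateEnv("digestate", 1e9, 48)

  # all-zero rates: pure dilution, f^n per species after n enrichments
  inert <- lapply(c("A", "B"), function(n)
    speciesTraits(n, growth_rate = 0, death_rate = 0))
  prot <- transferProtocol(list(soil, dig), transfer_fraction = 0.1,
                           n_passages = 3L,
                           initial_abundance = c(A = 1e8, B = 3e6))
  ends <- endOfEnrichmentStates(runTransferSeries(prot, inert))
  for (k in seq_len(ncol(ends)))
    expect_equal(unname(ends[, k]), c(1e8, 3e6) * 0.1^k, tolerance = 1e-12)

  # identical traits: relative abundances unchanged at every boundary
  same <- lapply(c("A", "B"), function(n)
    speciesTraits(n, growth_rate = 0.1, death_rate = 0.01))
  ends <- endOfEnrichmentStates(runTransferSeries(prot, same))
  rel <- sweep(ends, 2, colSums(ends), "/")
  expect_equal(rel["A", ], rep(1e8 / (1e8 + 3e6), ncol(rel)),
               ignore_attr = TRUE, tolerance = 1e-9)

  # a species at zero stays at zero
  prot0 <- transferProtocol(list(soil, dig), n_passages = 2L,
                            initial_abundance = c(A = 1e8, B = 0))
  traj <- runTransferSeries(prot0, same)
  expect_true(all(abundances(traj)["B", ] == 0))
})

test_that("mirrored protocols give permuted trajectories", {
  soil <- substrateEnv("soil", 1e9, 60)
  dig <- substrateEnv("digestate", 1e9, 80)
  S <- speciesTraits("S", growth_rate = c(soil = 0.1, digestate = 0),
                     death_rate = c(soil = 0, digestate = 0.03))
  D <- speciesTraits("D", growth_rate = c(soil = 0, digestate = 0.08),
                     death_rate = c(soil = 0.02, digestate = 0))
  G <- speciesTraits("G", growth_rate = c(soil = 0.05, digestate = 0.04))
  prot <- transferProtocol(list(soil, dig), n_passages = 3L,
                           initial_abundance = c(S = 1e8, D = 2e7, G = 1e4))

  # mirror: swap substrate identities and the two specialists' roles
  soil_m <- substrateEnv("digestate", 1e9, 60)
  dig_m <- substrateEnv("soil", 1e9, 80)
  S_m <- speciesTraits("S", growth_rate = c(digestate = 0.1, soil = 0),
                       death_rate = c(digestate = 0, soil = 0.03))
  D_m <- speciesTraits("D", growth_rate = c(digestate = 0, soil = 0.08),
                       death_rate = c(digestate = 0.02, soil = 0))
  G_m <- speciesTraits("G", growth_rate = c(digestate = 0.05, soil = 0.04))
  prot_m <- transferProtocol(list(soil_m, dig_m), n_passages = 3L,
                             initial_abundance = c(S = 1e8, D = 2e7, G = 1e4))

  a <- abundances(runTransferSeries(prot, list(S, D, G)))
  b <- abundances(runTransferSeries(prot_m, list(S_m, D_m, G_m)))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("total biomass never exceeds max(initial, K) beyond tolerance", {
  prot <- defaultProtocol(n_passages = 3L)
  traj <- runTransferSeries(prot, defaultTraits(0.5),
                            points_per_enrichment = 40L)
  K <- defaultModelParams()$carrying_capacity
  B <- colSums(abundances(traj))
  expect_true(all(B <= max(B[1], K) * (1 + 1e-6)))
})

test_that("passages to dominance: edge cases and monotonicity in the ratio", {
  prot <- defaultProtocol(n_passages = 10L)
  traits <- defaultTraits(0.5)

  # already dominant at inoculation
  prot99 <- prot
  prot99@initial_abundance <- c(S = 1e4, D = 1e4, G = 1e7)
  expect_identical(passagesToDominance(prot99, traits, "G"), 0L)
  expect_error(passagesToDominance(prot, traits, "nope"), "unknown species")

  # non-increasing in the generalist:specialist ratio
  ratios <- seq(0.30, 0.75, by = 0.05)
  tpl <- defaultTraitsTemplate()
  passages <- vapply(ratios, function(r) {
    tr <- list(tpl$soil_specialist, tpl$digestate_specialist,
               ratioTraits(tpl$soil_specialist, tpl$digestate_specialist, r))
    p <- passagesToDominance(prot, tr, "G")
    if (is.na(p)) Inf else as.numeric(p)
  }, numeric(1))
  expect_true(all(diff(passages) <= 0))
})

test_that("critical ratio agrees with a brute-force grid scan", {
  prot <- defaultProtocol(n_passages = 25L)
  tpl <- defaultTraitsTemplate()
  tol <- 0.01

  crit <- criticalRatio(prot, tpl, lo = 0.2, hi = 0.35, tol = tol)

  grid <- seq(0.2, 0.35, by = tol)
  elim <- vapply(grid, function(r)
    dualenrich:::eliminatedAtRatio(prot, tpl, r), logical(1))
  # monotone outcome: last eliminated and first persistent bracket the truth
  boundary_lo <- max(grid[elim])
  boundary_hi <- min(grid[!elim])
  expect_lt(boundary_hi - boundary_lo, 1.5 * tol)
  expect_gte(crit, boundary_lo - tol)
  expect_lte(crit, boundary_hi + tol)

  # invalid bracket (persistent at both ends) is rejected
  expect_error(criticalRatio(prot, tpl, lo = 0.4, hi = 0.5, tol = 0.01),
               "bracket")
})

test_that("a generalist matching the specialists persists", {
  prot <- defaultProtocol(n_passages = 25L)
  tpl <- defaultTraitsTemplate()
  expect_false(dualenrich:::eliminatedAtRatio(prot, tpl, 1.0))
})

test_that("regime scan partitions outcomes", {
  prot <- defaultProtocol(n_passages = 6L)
  tpl <- defaultTraitsTemplate()
  res <- regimeScan(prot, tpl, ratios = c(0.15, 0.5), max_cycles = 40L)
  expect_identical(res@outcome, c("eliminated", "dominant_within_limit"))
  expect_true(is.finite(res@passages_to_dominance[2]))
  expect_true(is.na(res@passages_to_dominance[1]))
})
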