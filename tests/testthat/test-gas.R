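# Headspace gas calculus: correction, rate decomposition, survival, I_N2O,
# electron flows and N mass balance.

test_that("correction basics: identity without disturbance, sampling attribution", {
  vial <- vialSpec(total_volume = 120, liquid_volume = 50, sample_volume = 7)

  # no sampling, no leak, no injection: cumulative production = A(t) - A(0)
  times <- seq(0, 10, by = 2)
  A <- matrix(5 + 2 * times, nrow = 1, dimnames = list("N2-N", NULL))
  corr <- correctSeries(gasSeries(times, A, sampled = rep(FALSE, 6)), vial)
  expect_equal(cumulativeProduction(corr)["N2-N", ], A[1, ] - A[1, 1],
               ignore_attr = TRUE)

  # constant true amount, one sampling removing 1/10 of the headspace:
  # the 10% drop is attributed to sampling, production stays 0
  A2 <- matrix(c(100, 90), nrow = 1, dimnames = list("N2-N", NULL))
  corr2 <- correctSeries(gasSeries(c(0, 3), A2, sampled = c(TRUE, FALSE)), vial)
  expect_equal(unname(cumulativeProduction(corr2)["N2-N", 2]), 0, tolerance = 1e-12)
})

test_that("constant production through periodic sampling is recovered", {
  # 1 umol/h into a 70-mL headspace, 1 mL withdrawn every 3 h for 24 h
  vial <- vialSpec(total_volume = 120, liquid_volume = 50, sample_volume = 1)
  times <- seq(0, 24, by = 3)
  sim <- forwardVial(times, "N2-N",
                     prod_fun = function(g, t0, t1) (t1 - t0) * 1, vial)
  corr <- correctSeries(sim$series, vial)
  expect_equal(unname(cumulativeProduction(corr)["N2-N", length(times)]), 24,
               tolerance = 1e-9)
})

test_that("correction inverts 50 random sampling/leak/injection scenarios", {
  set.seed(77)
  for (i in 1:50) {
    vial <- vialSpec(total_volume = 120, liquid_volume = runif(1, 20, 70),
                     sample_volume = runif(1, 0.5, 3),
                     leak_coefficient = c("N2-N" = runif(1, 0, 0.02)),
                     ambient_amount = c("N2-N" = runif(1, 0, 5)))
    times <- sort(c(0, runif(8, 0.5, 47), 48))
    sampled <- runif(length(times)) < 0.7
    rate <- runif(1, 0.2, 5)
    kexp <- runif(1, -0.05, 0.05)
    prod_fun <- function(g, t0, t1) {
      if (abs(kexp) < 1e-9) rate * (t1 - t0)
      else rate / kexp * (exp(kexp * t1) - exp(kexp * t0))
    }
    inj <- data.frame(time = times[4], gas = "N2-N",
                      amount = runif(1, 0, 20))
    sim <- forwardVial(times, "N2-N", prod_fun, vial, sampled = sampled,
                       injections = inj,
                       initial = c("N2-N" = runif(1, 0, 50)))
    corr <- correctSeries(sim$series, vial)
    got <- cumulativeProduction(corr)["N2-N", ]
    want <- sim$true_cumulative["N2-N", ]
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("two-population fit recovers planted exponents", {
  # pure decline (growth amplitude forced to ~0)
  times <- seq(0, 100, by = 2)
  fit <- twoPopulationFit(times, 8 * exp(-0.03 * times))
  expect_equal(fit@rate_decline, -0.03, tolerance = 1e-3)
  expect_lt(fit@amplitude_growth, 1e-6)

  # reference composite fixture: both planted exponents recovered
  rc <- compositeRateCurve()
  fit <- twoPopulationFit(rc$time, rc$rate)
  expect_equal(fit@rate_decline, -0.03, tolerance = 1e-3)
  expect_equal(fit@rate_growth, 0.1, tolerance = 1e-3)

  # time-shift identity: exponents unchanged, amplitudes rescaled by e^(mu c)
  c_shift <- 10
  shifted <- compositeRateCurve(times = seq(0, 100, by = 2) + c_shift)
  fit_s <- twoPopulationFit(seq(0, 100, by = 2), shifted$rate)
  expect_equal(fit_s@rate_decline, -0.03, tolerance = 1e-4)
  expect_equal(fit_s@rate_growth, 0.1, tolerance = 1e-4)
  expect_equal(fit_s@amplitude_decline, 8 * exp(-0.03 * c_shift),
               tolerance = 1e-3)
  expect_equal(fit_s@amplitude_growth, 0.001 * exp(0.1 * c_shift),
               tolerance = 1e-3)

  expect_error(twoPopulationFit(1:4, c(1, 2, 3, 4)), "8 finite")
})

test_that("two-population fit: parameter recovery across a 3x3 exponent grid", {
  times <- seq(0, 100, by = 2)
  for (mu1 in c(-0.01, -0.03, -0.1)) {
    for (mu2 in c(0.05, 0.1, 0.2)) {
      r <- 8 * exp(mu1 * times) + 0.001 * exp(mu2 * times)
      fit <- twoPopulationFit(times, r)
      expect_equal(fit@rate_decline, mu1, tolerance = 1e-3)
      expect_equal(fit@rate_growth, mu2, tolerance = 1e-3)
    }
  }
  # 5% multiplicative noise: recovery within 10%
  set.seed(42)
  for (mu1 in c(-0.03, -0.1)) {
    for (mu2 in c(0.05, 0.1)) {
      r <- (8 * exp(mu1 * times) + 0.001 * exp(mu2 * times)) *
        exp(rnorm(length(times), 0, sqrt(log(1.0025))))
      fit <- twoPopulationFit(times, r)
      expect_equal(fit@rate_decline, mu1, tolerance = 0.1)
      expect_equal(fit@rate_growth, mu2, tolerance = 0.1)
    }
  }
})

test_that("survival fraction: identities, linearity and scale invariance", {
  expect_equal(survivalFraction(10, 1, 0.1), 100)
  expect_equal(survivalFraction(10, 0, 0.1), 0)
  expect_equal(survivalFraction(10, 0.5, 0.1), 50)
  for (c_scale in c(0.01, 3, 1e4))
    expect_equal(survivalFraction(10 * c_scale, 0.5 * c_scale, 0.1), 50)
  expect_error(survivalFraction(0, 1), "prev_end_rate")

  # estimator over corrected series: mean of first/last 3 intervals
  times <- 0:9
  prev <- correctedFromAmounts(times, matrix(10 * times, nrow = 1,
                                             dimnames = list("N2-N", NULL)))
  next_ <- correctedFromAmounts(times, matrix(0.5 * times, nrow = 1,
                                              dimnames = list("N2-N", NULL)))
  expect_equal(transferSurvival(prev, next_, f = 0.1), 50)
})

test_that("I_N2O: bounds, toy oracle, both recovery thresholds, failure", {
  times <- c(0, 10, 20)
  toy <- correctedFromAmounts(times, rbind(
    "N2O-N" = c(0, 10, 0),
    "N2-N" = c(0, 20, 40),
    "NO-N" = c(0, 0, 0)))

  # fine-grid trapezoid oracle on the piecewise-linear curves
  tg <- seq(0, 20, by = 1e-3)
  n2o_g <- approx(times, c(0, 10, 0), xout = tg)$y
  tot_g <- n2o_g + approx(times, c(0, 20, 40), xout = tg)$y
  oracle <- 100 * sum((n2o_g[-1] + n2o_g[-length(tg)]) / 2 * diff(tg)) /
    sum((tot_g[-1] + tot_g[-length(tg)]) / 2 * diff(tg))
  got <- iN2O(toy, initial_N_oxyanions = 40, recovery_fraction = 1.0)
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_equal(got, 20, tolerance = 1e-9)

  # computable at 40% recovery too, and bounded
  got40 <- iN2O(toy, initial_N_oxyanions = 40, recovery_fraction = 0.4)
  expect_true(got40 >= 0 && got40 <= 100)

  # trivial bounds
  no_n2o <- correctedFromAmounts(times, rbind("N2O-N" = c(0, 0, 0),
                                              "N2-N" = c(0, 20, 40)))
  expect_equal(iN2O(no_n2o, 40, 1.0), 0)
  only_n2o <- correctedFromAmounts(times, rbind("N2O-N" = c(0, 20, 40),
                                                "N2-N" = c(0, 0, 0)))
  expect_equal(iN2O(only_n2o, 40, 1.0), 100)

  # recovery never reached: informative error
  expect_error(iN2O(toy, initial_N_oxyanions = 1000, recovery_fraction = 1.0),
               "recovery")
})

test_that("I_N2O invariances: rescaling and N2O monotonicity", {
  times <- c(0, 5, 10, 15, 20)
  base_n2o <- c(0, 6, 9, 4, 1)
  base_n2 <- c(0, 5, 15, 30, 42)
  for (sc in c(0.1, 1, 25)) {
    corr <- correctedFromAmounts(times, rbind("N2O-N" = sc * base_n2o,
                                              "N2-N" = sc * base_n2))
    expect_equal(iN2O(corr, 40 * sc, 1.0),
                 iN2O(correctedFromAmounts(times, rbind("N2O-N" = base_n2o,
                                                        "N2-N" = base_n2)),
                      40, 1.0),
                 tolerance = 1e-9)
  }
  vals <- vapply(c(0.5, 1, 2, 4), function(up) {
    corr <- correctedFromAmounts(times, rbind("N2O-N" = up * base_n2o,
                                              "N2-N" = base_n2))
    iN2O(corr, 40, 0.9)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 100))
})

test_that("electron flows follow reduction stoichiometry", {
  expect_equal(electronFlow(1, "O2"), 4)
  expect_equal(electronFlow(2, "N2O"), 2)  # 1 e- per N
  expect_equal(electronFlow(3, "NO3"), 6)
  expect_equal(electronFlow(1, "NO2"), 1)
  expect_equal(electronFlow(1, "NO"), 1)
  expect_equal(electronFlow(0, "N2O"), 0)
  expect_error(electronFlow(1, "SO4"), "unknown electron acceptor")

  times <- 0:4
  corr <- correctedFromAmounts(times, rbind("O2" = 20 - 2 * times,
                                            "N2O-N" = 40 - 3 * times,
                                            "N2-N" = 3 * times))
  ef <- electronFlows(corr)
  expect_equal(ef["O2", ], rep(8, 4), ignore_attr = TRUE)
  expect_equal(ef["N2O", ], rep(3, 4), ignore_attr = TRUE)
})

test_that("N mass balance: closed system, gas-only and pool-only cases", {
  times <- 0:10
  gasN <- 3 * times
  corr <- correctedFromAmounts(times, rbind("N2-N" = gasN,
                                            "N2O-N" = rep(0, 11)))
  # closed system: pools decline exactly as gas N accumulates
  pools <- data.frame(time = times, NO3 = 50 - 2 * times, NO2 = 10 - times,
                      NH4 = 5)
  res <- nMassBalance(corr, pools)
  expect_true(all(abs(res$residual) <= 1e-6))

  # gas-only production with constant pools: residual equals cumulative gas N
  pools_const <- data.frame(time = times, NO3 = 50, NO2 = 10, NH4 = 5)
  res2 <- nMassBalance(corr, pools_const)
  expect_equal(res2$residual, gasN, ignore_attr = TRUE)

  # no N gas series: residual equals the pool change
  corr_o2 <- correctedFromAmounts(times, matrix(20 - times, nrow = 1,
                                                dimnames = list("O2", NULL)))
  res3 <- nMassBalance(corr_o2, pools)
  expect_equal(res3$residual, (50 - 2 * times) + (10 - times) + 5 - 65,
               ignore_attr = TRUE)
})
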