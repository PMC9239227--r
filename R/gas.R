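# Headspace gas-kinetics calculus: dilution/leak correction, rate
# decomposition, survival fractions, electron flows, N mass balance and the
# I_N2O emission index. Working currency is amounts per vial (umol; umol N
# for N-containing gases), never concentrations.

#' Correct a raw gas series for sampling dilution and leakage
#'
#' Each sampling event withdraws `sample_volume` mL of headspace (after the
#' measurement) and replaces it with He, diluting every gas by
#' `1 - sample_volume / headspace_volume`. Leakage is modelled as first-order
#' exchange towards an ambient level, evaluated at the interval midpoint.
#' The per-interval production is
#' `A(t_k) - A(t_{k-1}) * (1 - s_{k-1} v_s/V_h) - injections + leak`,
#' where `s_{k-1}` flags a sampling event at the start of the interval.
#'
#' @param raw A [GasSeries-class].
#' @param vial A [VialSpec-class].
#' @param negative_tolerance warn about corrected per-interval production more
#'   negative than this (umol) for gases that are not expected to be consumed.
#' @return A [CorrectedSeries-class] with reconstructed undisturbed amounts,
#'   cumulative net production (injections removed, starting at 0) and
#'   per-interval rates.
#' @export
correctSeries <- function(raw, vial, negative_tolerance = Inf) {
  validObject(raw); validObject(vial)
  vh <- headspaceVolume(vial)
  dil <- vial@sample_volume / vh
  times <- raw@times
  n <- length(times)
  if (n < 2L) stopf("need at least two timepoints")
  gases <- rownames(raw@amounts)

  amounts <- raw@amounts
  corr_amounts <- matrix(0, nrow = length(gases), ncol = n,
                         dimnames = list(gases, NULL))
  cumprod_ <- corr_amounts
  rates <- matrix(0, nrow = length(gases), ncol = n - 1L,
                  dimnames = list(gases, NULL))
  corr_amounts[, 1] <- amounts[, 1]

  inj <- raw@injections
  lam <- function(g) if (g %in% names(vial@leak_coefficient))
    vial@leak_coefficient[[g]] else 0
  amb <- function(g) if (g %in% names(vial@ambient_amount))
    vial@ambient_amount[[g]] else 0

  for (gi in seq_along(gases)) {
    g <- gases[gi]
    lg <- lam(g); ag <- amb(g)
    for (k in 2:n) {
      dt <- times[k] - times[k - 1]
      carry <- amounts[gi, k - 1] * (1 - (raw@sampled[k - 1]) * dil)
      mid <- (amounts[gi, k] + carry) / 2
      leak <- lg * (mid - ag) * dt
      inj_k <- if (nrow(inj) > 0)
        sum(inj$amount[inj$gas == g & inj$time >= times[k - 1] &
                         inj$time < times[k]])
      else 0
      delta <- amounts[gi, k] - carry + leak
      prod_k <- delta - inj_k
      if (is.finite(negative_tolerance) && prod_k < -negative_tolerance)
        warnf("gas '%s': corrected production %.3g umol in interval %d",
              g, prod_k, k - 1L)
      corr_amounts[gi, k] <- corr_amounts[gi, k - 1] + delta
      cumprod_[gi, k] <- cumprod_[gi, k - 1] + prod_k
      rates[gi, k - 1] <- prod_k / dt
    }
  }
  new("CorrectedSeries", times = times, amounts = corr_amounts,
      cumulative_production = cumprod_, rates = rates)
}

#' Composite two-exponential rate curve
#'
#' Rate curve of two co-existing N2O-respiring populations, one declining and
#' one growing: `r(t) = A exp(mu1 t) + B exp(mu2 t)`. The defaults plant a
#' decline exponent of -0.03 h^-1 and a growth exponent of 0.1 h^-1 with
#' amplitudes 8 and 0.001 umol N h^-1, sampled every 2 h over [0, 100] h
#' (the reference fixture used throughout the tests).
#'
#' @param times sampling times in hours.
#' @param A,mu1 amplitude (umol N h^-1) and exponent (h^-1) of the declining
#'   population.
#' @param B,mu2 amplitude and exponent of the growing population.
#' @return data.frame with columns `time` and `rate`.
#' @export
compositeRateCurve <- function(times = seq(0, 100, by = 2), A = 8,
                               mu1 = -0.03, B = 0.001, mu2 = 0.1) {
  data.frame(time = times, rate = A * exp(mu1 * times) + B * exp(mu2 * times))
}

#' Decompose a rate curve into declining and growing populations
#'
#' Nonlinear least squares of `r(t) = A exp(mu1 t) + B exp(mu2 t)` with the
#' constraint `mu1 < 0 < mu2`, multistarted from five fixed initial guesses;
#' the best fit by residual norm is returned.
#'
#' @param times numeric, hours.
#' @param rates numeric, production rates (umol N h^-1); at least 8 finite
#'   points.
#' @return A [TwoPopFit-class].
#' @export
twoPopulationFit <- function(times, rates) {
  if (length(times) != length(rates)) stopf("times and rates must align")
  if (length(rates) < 8L || any(!is.finite(rates)) || any(!is.finite(times)))
    stopf("need >= 8 finite rate points")

  df <- data.frame(t = times, r = rates)
  span <- diff(range(times))
  r0 <- max(rates[1], 1e-9)
  rT <- max(rates[length(rates)], 1e-9)

  ## Fixed multistart grid: three decline guesses x growth guesses anchored on
  ## the curve's endpoints.
  starts <- list(
    c(mu1 = -0.01, mu2 = 0.05),
    c(mu1 = -0.03, mu2 = 0.10),
    c(mu1 = -0.10, mu2 = 0.05),
    c(mu1 = -0.03, mu2 = 0.20),
    c(mu1 = -0.30, mu2 = 0.02)
  )

  best <- NULL
  for (st in starts) {
    start <- list(A = r0, mu1 = st[["mu1"]],
                  B = rT * exp(-st[["mu2"]] * max(times)), mu2 = st[["mu2"]])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ A * exp(mu1 * t) + B * exp(mu2 * t), data = df, start = start,
        lower = c(A = 0, mu1 = -10, B = 0, mu2 = 1e-8),
        upper = c(A = Inf, mu1 = -1e-8, B = Inf, mu2 = 10),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stopf(paste0("two-population fit did not converge from any of %d starts ",
                 "(n = %d points, rate range [%.3g, %.3g])"),
          length(starts), length(rates), min(rates), max(rates))

  cf <- stats::coef(best$fit)
  new("TwoPopFit",
      amplitude_decline = unname(cf["A"]), rate_decline = unname(cf["mu1"]),
      amplitude_growth = unname(cf["B"]), rate_growth = unname(cf["mu2"]),
      residual_norm = sqrt(best$rss), times = times,
      fitted = unname(stats::fitted(best$fit)))
}

#' Fraction of the N2O-respiring community surviving a transfer
#'
#' Compares the initial activity observed in a new enrichment with the
#' activity expected had all transferred N2O-respiring biomass stayed active
#' (activity proportional to biomass at a fixed cell-specific rate):
#' `100 * next_initial_rate / (f * prev_end_rate)`.
#'
#' @param prev_end_rate N2 production rate at the end of the previous
#'   enrichment (umol N h^-1), > 0.
#' @param next_initial_rate initial N2 production rate in the next enrichment.
#' @param f transfer fraction in (0, 1].
#' @return Survival percentage.
#' @export
survivalFraction <- function(prev_end_rate, next_initial_rate, f = 0.1) {
  if (any(prev_end_rate <= 0)) stopf("prev_end_rate must be > 0")
  if (f <= 0 || f > 1) stopf("f must lie in (0, 1]")
  100 * next_initial_rate / (f * prev_end_rate)
}

#' Survival fraction from two corrected series
#'
#' Convenience estimator: the end rate is the mean corrected N2 rate over the
#' last `k` measurement intervals of the previous enrichment, the initial
#' rate the mean over the first `k` intervals of the next.
#'
#' @param prev,next_ [CorrectedSeries-class] objects of consecutive
#'   enrichments.
#' @param f transfer fraction.
#' @param gas rate row to use, default `"N2-N"`.
#' @param k number of intervals averaged at each end, default 3.
#' @return Survival percentage.
#' @export
transferSurvival <- function(prev, next_, f = 0.1, gas = "N2-N", k = 3L) {
  rp <- prev@rates[gas, ]
  rn <- next_@rates[gas, ]
  if (length(rp) < k || length(rn) < k)
    stopf("need at least %d rate intervals on both sides of the transfer", k)
  end_rate <- mean(rp[(length(rp) - k + 1L):length(rp)])
  init_rate <- mean(rn[seq_len(k)])
  survivalFraction(end_rate, init_rate, f)
}

#' N2O emission index I_N2O
#'
#' The time integral of the N2O-N headspace amount divided by the integral of
#' total gaseous N (N2O-N + N2-N + NO-N), expressed as a percentage, over the
#' window `[0, T]` where `T` is the earliest time (linear interpolation) at
#' which the cumulative net production of gaseous N reaches
#' `recovery_fraction` of the initially available N oxyanions.
#'
#' @param corrected A [CorrectedSeries-class] containing rows `"N2O-N"`,
#'   `"N2-N"` and (optionally) `"NO-N"`.
#' @param initial_N_oxyanions initially available NO3- + NO2- (umol N), > 0.
#' @param recovery_fraction fraction of the oxyanion pool that must be
#'   recovered as gaseous N, canonically 0.40 or 1.00.
#' @return I_N2O as a percentage in [0, 100].
#' @export
iN2O <- function(corrected, initial_N_oxyanions, recovery_fraction = 0.40) {
  if (!is_scalar_number(initial_N_oxyanions) || initial_N_oxyanions <= 0)
    stopf("initial_N_oxyanions must be a positive amount (umol N)")
  gases <- rownames(corrected@amounts)
  need <- c("N2O-N", "N2-N")
  if (!all(need %in% gases))
    stopf("corrected series must contain rows %s", paste(need, collapse = ", "))
  has_no <- "NO-N" %in% gases
  times <- corrected@times

  gasN_prod <- corrected@cumulative_production["N2O-N", ] +
    corrected@cumulative_production["N2-N", ] +
    (if (has_no) corrected@cumulative_production["NO-N", ] else 0)
  target <- recovery_fraction * initial_N_oxyanions
  T_end <- first_crossing(times, gasN_prod, target)
  if (is.na(T_end))
    stopf(paste0("N-oxyanion recovery of %.0f%% never reached ",
                 "(maximum recovery attained: %.1f%%)"),
          100 * recovery_fraction, 100 * max(gasN_prod) / initial_N_oxyanions)

  clipCurve <- function(y) {
    keep <- times <= T_end
    x <- times[keep]; yy <- y[keep]
    if (max(x) < T_end) {
      yT <- stats::approx(times, y, xout = T_end)$y
      x <- c(x, T_end); yy <- c(yy, yT)
    }
    list(x = x, y = yy)
  }
  n2o <- clipCurve(corrected@amounts["N2O-N", ])
  tot <- clipCurve(corrected@amounts["N2O-N", ] + corrected@amounts["N2-N", ] +
                     (if (has_no) corrected@amounts["NO-N", ] else 0))
  denom <- trapz(tot$x, tot$y)
  if (denom <= 0) return(0)
  100 * trapz(n2o$x, n2o$y) / denom
}

## Electron-accepting steps and electrons accepted per umol of the unit the
## rate is expressed in: per umol N for N species, per umol O2 for oxygen.
.ELECTRON_STOICH <- c(O2 = 4, NO3 = 2, NO2 = 1, NO = 1, N2O = 1)

#' Electron flow to a terminal electron acceptor
#'
#' Multiplies consumption rates by the fixed stoichiometry of each reduction
#' step: O2 -> 2 H2O (4 e- per mol O2), NO3- -> NO2- (2 e- per mol N),
#' NO2- -> NO (1), NO -> 1/2 N2O (1), N2O -> N2 (1 e- per mol N, i.e. 2 per
#' mol N2O).
#'
#' @param consumption consumption rate(s), umol h^-1 (umol N h^-1 for N
#'   species).
#' @param acceptor one of `"O2"`, `"NO3"`, `"NO2"`, `"NO"`, `"N2O"`.
#' @return Electron flow(s), umol e- h^-1.
#' @export
electronFlow <- function(consumption, acceptor) {
  if (length(acceptor) != 1L || !acceptor %in% names(.ELECTRON_STOICH))
    stopf("unknown electron acceptor '%s' (known: %s)",
          paste(acceptor, collapse = ","),
          paste(names(.ELECTRON_STOICH), collapse = ", "))
  unname(.ELECTRON_STOICH[[acceptor]]) * consumption
}

#' Electron flows from a corrected gas series
#'
#' Derives per-acceptor electron flow series from net gas consumption rates
#' (negative production). Gas rows are mapped to acceptors as `"O2"` -> O2
#' and `"N2O-N"` -> N2O.
#'
#' @param corrected A [CorrectedSeries-class].
#' @param acceptors acceptors to report; defaults to those derivable from the
#'   series.
#' @return Matrix, acceptor x interval, umol e- h^-1 (net; negative when the
#'   gas is being produced rather than consumed).
#' @export
electronFlows <- function(corrected, acceptors = NULL) {
  gas_of <- c(O2 = "O2", N2O = "N2O-N")
  if (is.null(acceptors))
    acceptors <- names(gas_of)[gas_of %in% rownames(corrected@rates)]
  acceptors <- match.arg(acceptors, names(.ELECTRON_STOICH),
                         several.ok = TRUE)
  out <- matrix(0, nrow = length(acceptors), ncol = ncol(corrected@rates),
                dimnames = list(acceptors, NULL))
  for (a in acceptors) {
    if (!a %in% names(gas_of) || !gas_of[[a]] %in% rownames(corrected@rates))
      stopf("no gas series available for acceptor '%s'", a)
    out[a, ] <- electronFlow(-corrected@rates[gas_of[[a]], ], a)
  }
  out
}

#' Nitrogen mass balance residuals
#'
#' For a closed system, dissolved N pools (NO3-N + NO2-N + NH4-N) plus
#' cumulative gaseous N production should be conserved:
#' `residual(t) = pools(t) + cumulative gas N(t) - pools(0)`.
#'
#' @param corrected A [CorrectedSeries-class] with rows among `"N2O-N"`,
#'   `"N2-N"`, `"NO-N"`; an empty gas series (no N rows) contributes 0.
#' @param pools data.frame with columns `time` (h) and any of `NO3`, `NO2`,
#'   `NH4` (umol N), at >= 2 timepoints.
#' @return data.frame with columns `time` and `residual` (umol N) at the pool
#'   measurement times.
#' @export
nMassBalance <- function(corrected, pools) {
  if (nrow(pools) < 2L) stopf("pools must be measured at >= 2 timepoints")
  pool_cols <- intersect(c("NO3", "NO2", "NH4"), names(pools))
  pool_sum <- rowSums(pools[, pool_cols, drop = FALSE])
  n_rows <- intersect(c("N2O-N", "N2-N", "NO-N"), rownames(corrected@cumulative_production))
  gasN <- if (length(n_rows) > 0)
    colSums(corrected@cumulative_production[n_rows, , drop = FALSE])
  else rep(0, length(corrected@times))
  gas_at <- if (length(corrected@times) > 1)
    stats::approx(corrected@times, gasN, xout = pools$time, rule = 2)$y
  else rep(gasN[1], nrow(pools))
  data.frame(time = pools$time,
             residual = pool_sum + gas_at - pool_sum[1])
}
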