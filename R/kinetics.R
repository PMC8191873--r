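# Detachment-limited crossbridge kinetics. The model: the unloaded shortening
# velocity V0 is limited by the lifetime tau of the strongly attached
# (force-holding) crossbridge state, V0 = d / tau with d the working stroke;
# for slow/beta-cardiac myosin tau is set by ADP release, k-ADP = 1 / tau.
# Also: exponential fitting of stopped-flow transients, the second-order
# ATP-binding rate from k_obs vs [ATP], and ADP affinity from the
# ATP/ADP-competition assay.

#' Strongly-bound-state lifetime from the ADP release rate constant
#'
#' @param k_minus_ADP ADP release rate constant, s^-1 (> 0).
#' @return lifetime tau = 1/k, in milliseconds.
#' @export
tau_ADP <- function(k_minus_ADP) {
  if (any(k_minus_ADP <= 0)) fail("k_minus_ADP must be > 0")
  1000 / k_minus_ADP
}

#' Attached-state lifetime implied by the shortening velocity
#'
#' Under the detachment-limited model, tau = d / V0.
#'
#' @param V0 unloaded shortening velocity, um s^-1 per half-sarcomere (> 0).
#' @param d working stroke, nm (default 10).
#' @return lifetime in milliseconds (`d` nm / `V0` um/s = `d/V0` ms).
#' @export
tau_V0 <- function(V0, d = 10) {
  if (any(V0 <= 0) || any(d <= 0)) fail("V0 and d must be > 0")
  d / V0
}

#' Shortening velocity predicted from the ADP release rate constant
#'
#' `V0 = d / tau = d * k / 1000` (nm s^-1 -> um s^-1).
#'
#' @inheritParams tau_ADP
#' @inheritParams tau_V0
#' @return predicted V0, um s^-1 per half-sarcomere.
#' @export
predicted_V0 <- function(k_minus_ADP, d = 10) {
  if (any(k_minus_ADP <= 0) || any(d <= 0)) fail("inputs must be > 0")
  d * k_minus_ADP / 1000
}

#' Ratio of the ADP-release lifetime to the velocity-implied lifetime
#'
#' A ratio near 1 is the signature of detachment-limited shortening.
#'
#' @inheritParams tau_ADP
#' @inheritParams tau_V0
#' @return tau_ADP / tau_V0 (dimensionless).
#' @export
lifetime_ratio <- function(k_minus_ADP, V0, d = 10) {
  tau_ADP(k_minus_ADP) / tau_V0(V0, d)
}

#' Fold change between two measured values
#'
#' @param a,b positive values (e.g. chimera vs wild type).
#' @return `a / b`.
#' @export
fold_change <- function(a, b) {
  if (any(!is.na(b) & b == 0)) fail("denominator must be nonzero")
  a / b
}

#' Published reference measurements for four slow/beta-cardiac myosins
#'
#' Measured ADP release rate constants (solution kinetics of the S1 motor
#' fragment, 100 mM KCl, 12 degrees C; the human value extrapolated to 12
#' degrees C from an Arrhenius plot) and measured fibre shortening
#' velocities, for rat, rabbit, human and cow.
#'
#' @return data.frame with `species`, `k_minus_ADP` (s^-1) and `V0`
#'   (um s^-1 per half-sarcomere).
#' @export
beta_myosin_reference <- function() {
  data.frame(
    species = c("rat", "rabbit", "human", "cow"),
    k_minus_ADP = c(119, 63, 30, 27),
    V0 = c(1.42, 0.67, 0.33, 0.27),
    stringsAsFactors = FALSE
  )
}

#' Detachment-limited lifetime table for the reference myosins
#'
#' Regenerates the derived columns (tau_ADP, tau_V0 and their ratio) from
#' the measured rate constants and velocities, rounded half-up to the
#' customary printed precision of each cell.
#'
#' @param d working stroke, nm (default 10).
#' @param measured data.frame as from [beta_myosin_reference()].
#' @param rounded round to the printed precisions (default TRUE); when
#'   FALSE, full-precision values are returned.
#' @return data.frame: species, k_minus_ADP, V0, tau_ADP_ms, tau_V0_ms,
#'   ratio.
#' @export
detachment_limited_table <- function(d = 10, measured = beta_myosin_reference(),
                                     rounded = TRUE) {
  t_adp <- tau_ADP(measured$k_minus_ADP)
  t_v0 <- tau_V0(measured$V0, d)
  ratio <- t_adp / t_v0
  if (rounded) {
    # printed precisions: whole ms once tau exceeds ~30 ms, else 1-2 decimals
    adp_dig <- ifelse(t_adp >= 30, 0L, 1L)
    v0_dig <- ifelse(t_v0 < 10, 2L, 1L)
    t_adp <- round_half_up(t_adp, adp_dig)
    t_v0 <- round_half_up(t_v0, v0_dig)
    ratio <- round_half_up(ratio, 2L)
  }
  data.frame(species = measured$species, k_minus_ADP = measured$k_minus_ADP,
             V0 = measured$V0, tau_ADP_ms = t_adp, tau_V0_ms = t_v0,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Measured solution-kinetic parameters for rat, chimera and human S1
#'
#' ATP binding to actin.S1 (apparent second-order rate constant,
#' uM^-1 s^-1), ADP affinity for actin.S1 (uM), ADP release from
#' actin.S1.ADP (s^-1) and in vitro motility (um s^-1; not measurable for
#' the native rat S1, which lacks a surface-attachment tag). Conditions:
#' 25 mM KCl, 20 degrees C.
#'
#' @return data.frame with `parameter`, `rat`, `chimera`, `human`.
#' @export
chimera_reference <- function() {
  data.frame(
    parameter = c("atp_binding", "adp_affinity", "adp_release", "motility"),
    rat = c(5, 14, 107.2, NA),
    chimera = c(4.5, 14, 100.7, 0.90),
    human = c(4.4, 6.1, 59, 0.49),
    stringsAsFactors = FALSE
  )
}

#' Chimera/rat and chimera/human fold-change table
#'
#' @param measured data.frame as from [chimera_reference()].
#' @param digits decimals for the printed ratios (default 2).
#' @return data.frame with the measured columns plus `chimera_rat_ratio` and
#'   `chimera_human_ratio`.
#' @export
chimera_ratio_table <- function(measured = chimera_reference(), digits = 2L) {
  measured$chimera_rat_ratio <-
    round_half_up(fold_change(measured$chimera, measured$rat), digits)
  measured$chimera_human_ratio <-
    round_half_up(fold_change(measured$chimera, measured$human), digits)
  measured
}

validate_trace <- function(trace, min_points = 10L) {
  if (!all(c("time", "signal") %in% names(trace)))
    fail("trace needs columns 'time' and 'signal'")
  if (nrow(trace) < min_points) fail("trace needs >= ", min_points, " points")
  if (any(diff(trace$time) <= 0)) fail("trace times must be strictly increasing")
  trace
}

#' Read a two-column transient trace (time, signal)
#' @param path delimited file; header optional (sniffed).
#' @return data.frame with `time` and `signal`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = sniff_sep(path))
  names(df)[1:2] <- c("time", "signal")
  validate_trace(df[, 1:2])
}

# deterministic log-linear probe fit for exponential initial values
probe_rate <- function(t, y, baseline) {
  amp <- y - baseline
  s <- sign(stats::median(amp[seq_len(max(3L, length(amp) %/% 4L))]))
  ok <- s * amp > 0
  if (sum(ok) < 3L) return(NULL)
  f <- stats::lm(log(s * amp[ok]) ~ t[ok])
  k <- -unname(stats::coef(f)[2L])
  if (!is.finite(k) || k <= 0) NULL else
    list(k = k, A = s * exp(unname(stats::coef(f)[1L])))
}

#' Fit one- or two-phase exponential decays to a transient
#'
#' Least-squares fit of `A exp(-k t) + C` (one phase) or
#' `A1 exp(-k1 t) + A2 exp(-k2 t) + C` (two phases), with deterministic
#' initial values from log-linear probe fits. Two-phase fits constrain the
#' fast rate to at least 3x the slow rate to avoid exchange degeneracy.
#'
#' @param trace data.frame with `time` and `signal` (>= 10 points).
#' @param phases 1 or 2.
#' @return list: `rates` (s^-1, fast first), `amplitudes`,
#'   `amplitude_fractions` (of the total amplitude; two-phase only),
#'   `baseline`, `fitted`, `flat` flag (total amplitude indistinguishable
#'   from noise: rate(s) unidentifiable).
#' @export
fit_exponential <- function(trace, phases = 1L) {
  trace <- validate_trace(trace)
  if (!phases %in% 1:2) fail("phases must be 1 or 2")
  t <- trace$time; y <- trace$signal
  tail_c <- mean(y[t >= stats::quantile(t, 0.9)])
  amp_tot <- y[1L] - tail_c
  noise <- stats::sd(diff(y)) / sqrt(2)
  if (!is.finite(noise)) noise <- 0
  if (abs(amp_tot) <= 3 * noise || abs(amp_tot) < 1e-12 * max(1, abs(tail_c)))
    return(list(rates = NA_real_, amplitudes = 0, amplitude_fractions = NA_real_,
                baseline = mean(y), fitted = rep(mean(y), length(y)), flat = TRUE))
  pr <- probe_rate(t, y, tail_c)
  if (is.null(pr)) pr <- list(k = 1 / (max(t) / 3), A = amp_tot)
  if (phases == 1L) {
    fit <- minpack.lm::nlsLM(
      signal ~ A * exp(-k * time) + C, data = trace,
      start = list(A = pr$A, k = pr$k, C = tail_c),
      control = minpack.lm::nls.lm.control(maxiter = 500))
    cf <- stats::coef(fit)
    if (cf[["k"]] <= 0) fail("exponential fit did not converge to a positive rate")
    return(list(rates = cf[["k"]], amplitudes = cf[["A"]],
                amplitude_fractions = 1, baseline = cf[["C"]],
                fitted = stats::fitted(fit), flat = FALSE))
  }
  # two phases: parametrize slow rate as a fraction (<= 1/3) of the fast rate
  half <- t <= stats::median(t) / 4
  pf <- probe_rate(t[half], y[half], tail_c)
  k_fast0 <- if (!is.null(pf)) max(pf$k, pr$k) else pr$k * 5
  fit <- minpack.lm::nlsLM(
    signal ~ A1 * exp(-kf * time) + A2 * exp(-kf * frac * time) + C,
    data = trace,
    start = list(A1 = 0.6 * amp_tot, A2 = 0.4 * amp_tot,
                 kf = k_fast0, frac = min(pr$k / k_fast0, 0.2), C = tail_c),
    lower = c(A1 = -Inf, A2 = -Inf, kf = 1e-12, frac = 1e-6, C = -Inf),
    upper = c(A1 = Inf, A2 = Inf, kf = Inf, frac = 1 / 3, C = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 1000))
  cf <- stats::coef(fit)
  k_fast <- cf[["kf"]]; k_slow <- cf[["kf"]] * cf[["frac"]]
  amps <- c(cf[["A1"]], cf[["A2"]])
  list(rates = c(fast = k_fast, slow = k_slow),
       amplitudes = c(fast = amps[1L], slow = amps[2L]),
       amplitude_fractions = c(fast = amps[1L], slow = amps[2L]) / sum(amps),
       baseline = cf[["C"]], fitted = stats::fitted(fit), flat = FALSE)
}

#' Apparent second-order rate constant from k_obs vs concentration
#'
#' Ordinary least-squares line through the `(concentration, k_obs)` points;
#' the slope is the apparent second-order rate constant (e.g. K'1 k'+2 for
#' ATP-induced actin.S1 dissociation) and the free intercept is reported.
#'
#' @param conc_uM substrate concentrations, uM (>= 3 distinct values).
#' @param k_obs observed rate constants, s^-1.
#' @return list: `slope` (uM^-1 s^-1), `intercept` (s^-1), `r_squared`.
#' @export
second_order_rate <- function(conc_uM, k_obs) {
  if (length(conc_uM) != length(k_obs)) fail("lengths differ")
  if (length(unique(conc_uM)) < 3L) fail("need >= 3 distinct concentrations")
  fit <- stats::lm(k_obs ~ conc_uM)
  ss_tot <- sum((k_obs - mean(k_obs))^2)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else NA_real_)
}

#' ADP affinity from the ATP/ADP competition assay
#'
#' Fits `k_obs = k0 / (1 + [ADP] / K_ADP)` to observed rate constants of
#' ATP-induced dissociation measured at increasing [ADP].
#'
#' @param adp_uM ADP concentrations, uM; must include 0 and >= 4 values.
#' @param k_obs observed rate constants, s^-1.
#' @param fix_k0 fix `k0` at the mean of the 0-ADP observations (default
#'   FALSE: `k0` is a free parameter).
#' @return list: `K_ADP` (uM), `k0` (s^-1), `unbounded` flag (flat series:
#'   no measurable inhibition, `K_ADP` unidentifiably large).
#' @export
adp_affinity <- function(adp_uM, k_obs, fix_k0 = FALSE) {
  if (length(adp_uM) != length(k_obs)) fail("lengths differ")
  if (length(unique(adp_uM)) < 4L) fail("need >= 4 ADP concentrations")
  if (!any(adp_uM == 0)) fail("need a 0-ADP point")
  k0_hat <- mean(k_obs[adp_uM == 0])
  # flat series: no measurable inhibition, K unidentifiably large
  if (diff(range(k_obs)) <= 0.01 * abs(k0_hat))
    return(list(K_ADP = Inf, k0 = k0_hat, unbounded = TRUE))
  # half-inhibition probe for the starting K
  rel <- k_obs / k0_hat
  below <- which(rel <= 0.5)
  K0 <- if (length(below)) max(adp_uM[min(below)], 1e-3) else max(adp_uM)
  df <- data.frame(adp = adp_uM, k = k_obs)
  if (fix_k0) {
    fit <- minpack.lm::nlsLM(k ~ k0_hat / (1 + adp / K), data = df,
                             start = list(K = K0), lower = c(K = 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    K <- stats::coef(fit)[["K"]]; k0 <- k0_hat
  } else {
    fit <- minpack.lm::nlsLM(k ~ k0 / (1 + adp / K), data = df,
                             start = list(k0 = k0_hat, K = K0),
                             lower = c(k0 = 1e-9, K = 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 500))
    K <- stats::coef(fit)[["K"]]; k0 <- stats::coef(fit)[["k0"]]
  }
  unbounded <- K > 100 * max(adp_uM)
  list(K_ADP = K, k0 = k0, unbounded = unbounded)
}
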