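# Single-site binding isotherm: forward model for the total and
# per-injection heats of a serial-injection titration in an overflow cell.
#
# With cumulative injected volume v_i, effective concentrations follow the
# usual instrument displacement approximation
#   M_i = M0 (1 - v_i/(2 V0)),   X_i = X0 (v_i/V0)(1 - v_i/(2 V0)),
# the cumulative heat is the closed-form one-site expression
#   Q_i = (n M_i dH V0 / 2) [ S - sqrt(S^2 - 4 X_i/(n M_i)) ],
#   S = 1 + X_i/(n M_i) + 1/(n Ka M_i),
# and the per-injection heat carries the displaced-volume correction
#   dQ_i = Q_i - Q_{i-1} + (dV_i/V0) (Q_i + Q_{i-1})/2.

#' Binding parameters for the single-site model
#'
#' @param n binding stoichiometry (sites per macromolecule).
#' @param Ka association constant, l/mol.
#' @param dH_kJmol binding enthalpy, kJ/mol.
#' @return list of class `binding_params` with derived `Kd_M = 1/Ka`.
#' @export
binding_params <- function(n, Ka, dH_kJmol) {
  if (Ka <= 0)
    stop_cavitherm("Ka must be positive", "cavitherm_domain_error")
  structure(list(n = n, Ka = Ka, dH_kJmol = dH_kJmol, Kd_M = 1 / Ka),
            class = "binding_params")
}

# effective cell concentrations after cumulative injected volume v (litre)
.effective_conc <- function(tg, v_l) {
  V0 <- tg$cell_volume_ul * 1e-6
  list(M = tg$cell_conc_M * (1 - v_l / (2 * V0)),
       X = tg$syringe_conc_M * (v_l / V0) * (1 - v_l / (2 * V0)))
}

#' Predicted per-injection heats of the single-site model
#'
#' @param params a [binding_params()].
#' @param protocol a [thermogram()] (its heats, if any, are ignored).
#' @return numeric vector of per-injection heats in microjoule.
#' @export
single_site_model <- function(params, protocol) {
  stopifnot(inherits(params, "binding_params"), inherits(protocol, "thermogram"))
  if (protocol$cell_conc_M <= 0 || protocol$syringe_conc_M <= 0)
    stop_cavitherm("concentrations must be positive", "cavitherm_domain_error")
  V0 <- protocol$cell_volume_ul * 1e-6
  dV <- protocol$injection_volumes_ul * 1e-6
  v <- cumsum(dV)
  cc <- .effective_conc(protocol, v)
  n <- params$n; Ka <- params$Ka
  dH <- params$dH_kJmol * 1000            # J/mol
  S <- 1 + cc$X / (n * cc$M) + 1 / (n * Ka * cc$M)
  disc <- S^2 - 4 * cc$X / (n * cc$M)
  if (any(disc < -1e-9))
    stop_cavitherm("negative discriminant in isotherm (invalid concentrations)",
                   "cavitherm_numeric_domain_error")
  disc[disc < 0] <- 0
  Q <- (n * cc$M * dH * V0 / 2) * (S - sqrt(disc))   # J, cumulative
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  dQ * 1e6                                            # microjoule
}

#' Derive Kd, dG and dS from fitted single-site parameters
#'
#' `Kd = 1/Ka`; `dG = -R T ln(Ka)` (kJ/mol, R = 8.314 J/mol/K);
#' `dS = (dH - dG) * 1000 / T` (J/mol/K).
#'
#' @param n stoichiometry (carried through, not used in the relations).
#' @param Ka association constant, l/mol.
#' @param dH_kJmol binding enthalpy, kJ/mol.
#' @param temperature_K temperature, K.
#' @return list with `Kd_M`, `dG_kJmol`, `dS_JmolK`.
#' @export
derive_thermodynamics <- function(n, Ka, dH_kJmol, temperature_K = 298) {
  if (Ka <= 0)
    stop_cavitherm("Ka must be positive", "cavitherm_domain_error")
  if (temperature_K <= 0)
    stop_cavitherm("temperature must be positive", "cavitherm_domain_error")
  dG <- -.R_GAS * temperature_K * log(Ka) / 1000
  list(Kd_M = 1 / Ka, dG_kJmol = dG,
       dS_JmolK = (dH_kJmol - dG) * 1000 / temperature_K)
}

#' Subtract control (heat of dilution) measurements
#'
#' @param heats_uJ experimental per-injection heats, microjoule.
#' @param control_heats_uJ control per-injection heats, microjoule.
#' @return corrected heats, microjoule.
#' @export
subtract_dilution <- function(heats_uJ, control_heats_uJ) {
  if (length(heats_uJ) != length(control_heats_uJ))
    stop_cavitherm("heats and control heats differ in length",
                   "cavitherm_validation_error")
  heats_uJ - control_heats_uJ
}

#' Integrate injection peaks from a raw power trace
#'
#' Heat of injection i is the trapezoidal integral of (power - baseline)
#' over the window from its injection time to the next (the last window
#' extends to the end of the trace). The default baseline linearly
#' interpolates between per-window pre-injection medians: for each
#' injection, the median power over the trace segment immediately before
#' the injection (the final 10% of the preceding window) becomes a baseline
#' node at the injection time, and nodes are joined by linear interpolation
#' (constant extrapolation at the ends).
#'
#' @param time_s trace times, seconds, strictly increasing.
#' @param power_uW trace power, microwatt.
#' @param injection_times_s injection start times, seconds, strictly increasing.
#' @param baseline_method `"pre_injection_median"` (default) or `"none"`.
#' @return per-injection heats, microjoule.
#' @export
integrate_peaks <- function(time_s, power_uW, injection_times_s,
                            baseline_method = c("pre_injection_median", "none")) {
  baseline_method <- match.arg(baseline_method)
  if (is.unsorted(time_s, strictly = TRUE) ||
      is.unsorted(injection_times_s, strictly = TRUE))
    stop_cavitherm("times must be strictly increasing",
                   "cavitherm_validation_error")
  if (min(injection_times_s) < min(time_s) ||
      max(injection_times_s) > max(time_s))
    stop_cavitherm("injection window outside power trace",
                   "cavitherm_bounds_error")
  nin <- length(injection_times_s)
  bounds <- c(injection_times_s, max(time_s))
  baseline <- rep(0, length(time_s))
  if (baseline_method == "pre_injection_median") {
    starts <- c(min(time_s), injection_times_s[-nin])
    nodes <- vapply(seq_len(nin), function(i) {
      w0 <- starts[i]; w1 <- injection_times_s[i]
      lo <- w1 - 0.1 * (w1 - w0)
      seg <- power_uW[time_s >= lo & time_s < w1]
      if (!length(seg)) seg <- power_uW[which.min(abs(time_s - w1))]
      median(seg)
    }, 0)
    baseline <- stats::approx(injection_times_s, nodes, xout = time_s,
                              rule = 2)$y
  }
  net <- power_uW - baseline
  # half-open windows [t_i, t_{i+1}): the sample at the next injection time
  # already contains the next peak's onset
  vapply(seq_len(nin), function(i) {
    sel <- time_s >= bounds[i] &
      (if (i == nin) time_s <= bounds[i + 1L] else time_s < bounds[i + 1L])
    pracma::trapz(time_s[sel], net[sel])
  }, 0)
}
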