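#' Reference current-voltage relationship at 100% functional channels
#'
#' @param voltages test potentials, mV, strictly increasing.
#' @param current_density current density at each voltage, pA/pF, for a cell
#'   in which every channel is functional.
#' @param sex_label optional metadata ("male"/"female").
#' @return a `reference_iv` data.frame (`voltage_mV`, `density_pA_pF`).
#' @export
reference_iv <- function(voltages, current_density, sex_label = NA_character_) {
  if (length(voltages) != length(current_density) || length(voltages) < 1L)
    stopf("voltages and current_density must be equal-length, non-empty")
  if (is.unsorted(voltages, strictly = TRUE))
    stopf("voltages must be strictly increasing")
  structure(data.frame(voltage_mV = as.numeric(voltages),
                       density_pA_pF = as.numeric(current_density)),
            class = c("reference_iv", "data.frame"), sex_label = sex_label)
}

#' Built-in whole-cell KV2.1 reference densities for arterial myocytes
#'
#' Model-derived current densities at +50 mV with 100% of the KV2.1 channels
#' in the sarcolemma functional: 7006 pA/pF (male) and 17293 pA/pF (female).
#' These serve as the reference inputs for functional-fraction scaling.
#'
#' @param sex "male" or "female".
#' @return a single-voltage `reference_iv`.
#' @export
myocyte_reference_iv <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  dens <- switch(sex, male = 7006, female = 17293)
  reference_iv(50, dens, sex_label = sex)
}

# Report rounding: printed precision of whole-cell densities is integer
# pA/pF at >= 100 and one decimal below.
round_density <- function(x) {
  ifelse(abs(x) >= 100, round(x), round(x, 1))
}

#' Scale a reference IV by the fraction of functional channels
#'
#' Whole-cell current density is linear in the number of conducting
#' channels, so a fraction `f` of functional channels scales every reference
#' density by `f`. Rounding to the reported precision is applied only at
#' report time (`reported_density`); `predicted_density` is exact.
#'
#' @param ref a [reference_iv()] at 100% functional channels.
#' @param f fraction of functional channels in `[0, 1]`.
#' @return a `fraction_prediction` data.frame: `voltage_mV`,
#'   `predicted_density`, `reported_density`, with `fraction_functional`
#'   attribute.
#' @export
scale_current <- function(ref, f) {
  stopifnot(inherits(ref, "reference_iv"))
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stopf("`f` must be a single fraction in [0, 1]")
  pred <- ref$density_pA_pF * f
  structure(data.frame(voltage_mV = ref$voltage_mV,
                       predicted_density = pred,
                       reported_density = round_density(pred)),
            class = c("fraction_prediction", "data.frame"),
            fraction_functional = f, sex_label = attr(ref, "sex_label"))
}

#' Construct a voltage-step recording
#'
#' @param time_ms shared time base, ms.
#' @param traces current matrix, pA: one column per test voltage, rows on
#'   `time_ms`.
#' @param voltages test potentials, mV (one per column).
#' @param capacitance_pF cell capacitance, pF.
#' @param holding_potential_mV holding potential, mV.
#' @return a `step_recording`.
#' @export
step_recording <- function(time_ms, traces, voltages, capacitance_pF,
                           holding_potential_mV = -70) {
  traces <- as.matrix(traces)
  if (nrow(traces) != length(time_ms))
    stopf("traces rows must match time base length")
  if (ncol(traces) != length(voltages))
    stopf("traces columns must match number of voltages")
  assert_positive(capacitance_pF, "capacitance_pF")
  structure(list(time_ms = as.numeric(time_ms), traces = traces,
                 voltages = as.numeric(voltages),
                 capacitance_pF = capacitance_pF,
                 holding_potential_mV = holding_potential_mV),
            class = "step_recording")
}

#' Drug-sensitive current by trace subtraction
#'
#' The blocker-sensitive component is the pointwise difference between the
#' composite currents recorded before the blocker and the residual currents
#' after it (pre minus post), per voltage step. Protocols must match exactly
#' (voltages and time base); capacitance is propagated from the pre-drug
#' recording for density normalization.
#'
#' @param pre_drug,post_drug matched `step_recording`s.
#' @return a `step_recording` of the drug-sensitive current.
#' @export
drug_subtraction <- function(pre_drug, post_drug) {
  stopifnot(inherits(pre_drug, "step_recording"),
            inherits(post_drug, "step_recording"))
  if (!isTRUE(all.equal(pre_drug$voltages, post_drug$voltages)))
    stopf("voltage protocols differ between recordings")
  if (!isTRUE(all.equal(pre_drug$time_ms, post_drug$time_ms)))
    stopf("time bases differ between recordings")
  step_recording(pre_drug$time_ms, pre_drug$traces - post_drug$traces,
                 pre_drug$voltages, pre_drug$capacitance_pF,
                 pre_drug$holding_potential_mV)
}

#' Current-voltage relationship from a step recording
#'
#' Per voltage step, the current statistic over a measurement window
#' (default: the mean over the final 50 ms of the step) is divided by the
#' cell capacitance to give a density in pA/pF.
#'
#' @param rec a `step_recording`.
#' @param window `c(start, end)` ms within the trace; default last 50 ms.
#' @param stat summary statistic over the window (default mean).
#' @return a `reference_iv`-shaped curve (`voltage_mV`, `density_pA_pF`).
#' @export
build_iv <- function(rec, window = NULL, stat = mean) {
  stopifnot(inherits(rec, "step_recording"))
  tmax <- max(rec$time_ms)
  window <- window %||% c(tmax - 50, tmax)
  if (window[1] < min(rec$time_ms) || window[2] > tmax ||
      window[1] >= window[2])
    stopf("measurement window [%g, %g] ms outside the trace", window[1],
          window[2])
  sel <- rec$time_ms >= window[1] & rec$time_ms <= window[2]
  dens <- apply(rec$traces[sel, , drop = FALSE], 2, stat) / rec$capacitance_pF
  reference_iv(rec$voltages, dens)
}

#' Liquid-junction-potential correction of an IV curve
#'
#' Subtracts the junction potential from the voltage axis (applied offline,
#' as in whole-cell recordings: 13 mV for K+-based solutions, 9.4 mV for
#' Ba2+-based solutions). Off by default throughout the package.
#'
#' @param iv a `reference_iv`.
#' @param jp_mV junction potential, mV.
#' @return the corrected `reference_iv`.
#' @export
correct_junction_potential <- function(iv, jp_mV) {
  stopifnot(inherits(iv, "reference_iv"))
  iv$voltage_mV <- iv$voltage_mV - jp_mV
  iv
}

#' Synthetic Boltzmann-activated delayed-rectifier current traces
#'
#' Convenience generator for testing IV construction and drug subtraction:
#' conductance `g / (1 + exp(-(V - v_half)/slope))`, reversal `e_rev`, with a
#' single-exponential activation time course.
#'
#' @param voltages test potentials, mV.
#' @param g_max maximal conductance, nS.
#' @param v_half,slope Boltzmann activation parameters, mV.
#' @param e_rev reversal potential, mV.
#' @param step_ms step duration, ms; `dt_ms` sample interval.
#' @param tau_ms activation time constant, ms.
#' @param capacitance_pF cell capacitance.
#' @return a `step_recording`.
#' @export
synthetic_kv_recording <- function(voltages = seq(-70, 70, 10), g_max = 10,
                                   v_half = 0, slope = 10, e_rev = -80,
                                   step_ms = 500, dt_ms = 1, tau_ms = 20,
                                   capacitance_pF = 16) {
  time_ms <- seq(0, step_ms, by = dt_ms)
  act <- 1 - exp(-time_ms / tau_ms)
  traces <- vapply(voltages, function(v) {
    g <- g_max / (1 + exp(-(v - v_half) / slope))
    g * (v - e_rev) * act
  }, numeric(length(time_ms)))
  step_recording(time_ms, traces, voltages, capacitance_pF)
}
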