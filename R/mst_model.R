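#' MST instrument configuration
#'
#' Laser timing of a thermophoresis run: a cold baseline window before the
#' IR laser switches on, the MST-on window, and a recovery window after
#' laser-off. Defaults follow the standard instrument program (5 s / 30 s /
#' 5 s, 25 s delay between capillaries).
#'
#' @param led_power_pct,mst_power_pct Excitation LED and IR-laser power (%).
#' @param t_before_s,t_on_s,t_after_s Durations (s) of the cold window, the
#'   MST-on window, and the post-laser window.
#' @param delay_s Delay between capillaries (s); not used in analysis.
#' @param sampling_hz Sampling rate of the fluorescence trace.
#' @return Object of class `mst_config`.
#' @export
mst_config <- function(led_power_pct = 30, mst_power_pct = 40,
                       t_before_s = 5, t_on_s = 30, t_after_s = 5,
                       delay_s = 25, sampling_hz = 20) {
  stopifnot(t_before_s > 0, t_on_s > 0, t_after_s > 0, sampling_hz > 0)
  structure(list(led_power_pct = led_power_pct,
                 mst_power_pct = mst_power_pct,
                 t_before_s = t_before_s, t_on_s = t_on_s,
                 t_after_s = t_after_s, delay_s = delay_s,
                 sampling_hz = sampling_hz),
            class = "mst_config")
}

#' Single MST capillary trace
#'
#' @param ligand_conc_M Concentration (molar) of the titrated, unlabeled
#'   binding partner in this capillary.
#' @param time_s Strictly increasing time axis (s).
#' @param fluorescence Fluorescence values (raw counts or normalized), same
#'   length as `time_s`.
#' @param config An [mst_config()].
#' @param normalized Logical: has the trace been divided by its cold-window
#'   mean already?
#' @return Object of class `mst_trace`.
#' @export
mst_trace <- function(ligand_conc_M, time_s, fluorescence, config = mst_config(),
                      normalized = FALSE) {
  stopifnot(length(time_s) == length(fluorescence),
            all(diff(time_s) > 0), ligand_conc_M >= 0)
  if (max(time_s) < config$t_before_s + config$t_on_s + config$t_after_s - 1e-9)
    stop("trace must span t_before + t_on + t_after")
  structure(list(ligand_conc_M = ligand_conc_M, time_s = time_s,
                 fluorescence = fluorescence, config = config,
                 normalized = isTRUE(normalized)),
            class = "mst_trace")
}

#' MST dilution series
#'
#' @param traces List of [mst_trace()], one per capillary, ligand
#'   concentrations strictly decreasing (a dilution series).
#' @param labeled_conc_M Fixed concentration of the fluorescently labeled
#'   species (molar; instrument practice 3-25 nM).
#' @param rna_id Identifier of the labeled RNA.
#' @return Object of class `mst_series`.
#' @export
mst_series <- function(traces, labeled_conc_M, rna_id = "RNA") {
  conc <- vapply(traces, `[[`, numeric(1), "ligand_conc_M")
  if (any(diff(conc) >= 0))
    stop("ligand concentrations must be strictly decreasing across traces")
  stopifnot(labeled_conc_M > 0)
  structure(list(traces = traces, labeled_conc_M = labeled_conc_M,
                 rna_id = rna_id),
            class = "mst_series")
}

#' @export
print.mst_series <- function(x, ...) {
  conc <- vapply(x$traces, `[[`, numeric(1), "ligand_conc_M")
  cat(sprintf("MST series '%s': %d capillaries, ligand %.3g-%.3g M, labeled %.3g M\n",
              x$rna_id, length(x$traces), max(conc), min(conc),
              x$labeled_conc_M))
  invisible(x)
}

#' Equilibrium fraction bound under 1:1 mass action with ligand depletion
#'
#' Solves the quadratic mass-action equilibrium for the fraction of labeled
#' species `T` bound by titrated ligand `L`:
#' `FB = ((T + L + Kd) - sqrt((T + L + Kd)^2 - 4 T L)) / (2 T)`.
#' The numerically stable equivalent `2L / (T + L + Kd + sqrt(...))` is used
#' so small fractions do not suffer cancellation. As `T -> 0` this reduces
#' to the non-depleting hyperbola `L / (L + Kd)`.
#'
#' @param L Titrated ligand concentration(s), molar, >= 0 (vectorized).
#' @param T_conc Labeled species concentration, molar, >= 0.
#' @param kd Dissociation constant, molar, > 0.
#' @return Fraction bound in \[0, 1\], same length as `L`.
#' @export
fraction_bound <- function(L, T_conc, kd) {
  stopifnot(all(L >= 0), T_conc >= 0, kd > 0)
  if (T_conc == 0) return(L / (L + kd))
  s <- T_conc + L + kd
  disc <- sqrt(pmax(s^2 - 4 * T_conc * L, 0))
  fb <- 2 * L / (s + disc)
  pmin(pmax(fb, 0), 1)
}

# Piecewise-exponential trace model. All signal phases are expressed on the
# normalized scale (cold baseline = 1):
#   cold  [0, t0):        1
#   on    [t0, t0+t_on):  1 - a_tj (1 - e^-(t-t0)/tau_tj)
#                           - a_th (1 - e^-(t-t0)/tau_th)
#   off   [t1, end):      1 + (F(t1) - 1) e^-(t-t1)/tau_bd
# The T-jump and thermophoresis amplitudes are linear in fraction bound;
# the back-diffusion time constant grows with fraction bound (complexes are
# larger, hence diffuse back more slowly).
.mst_phase_defaults <- function() {
  list(tau_tj = 0.3, tau_th = 8,
       a_tj_free = 0.030, a_tj_bound = 0.080,
       a_th_free = 0.020, a_th_bound = 0.070,
       tau_bd_free = 2, tau_bd_bound = 6)
}

#' Noise-free normalized MST trace model
#'
#' Evaluates the piecewise-exponential three-phase trace model (T-jump,
#' thermophoresis, back diffusion) at given times for a given fraction
#' bound. Used by the synthetic generator and by closed-form tests.
#'
#' @param time_s Time points (s).
#' @param fb Fraction bound in \[0, 1\].
#' @param config An [mst_config()].
#' @param phase Named list of phase parameters; see source for defaults
#'   (time constants in s, amplitudes on the normalized scale).
#' @return Numeric vector of normalized fluorescence values.
#' @export
mst_trace_model <- function(time_s, fb, config = mst_config(),
                            phase = .mst_phase_defaults()) {
  stopifnot(fb >= 0, fb <= 1)
  t0 <- config$t_before_s
  t1 <- t0 + config$t_on_s
  a_tj <- phase$a_tj_free + (phase$a_tj_bound - phase$a_tj_free) * fb
  a_th <- phase$a_th_free + (phase$a_th_bound - phase$a_th_free) * fb
  tau_bd <- phase$tau_bd_free + (phase$tau_bd_bound - phase$tau_bd_free) * fb
  f <- rep(1, length(time_s))
  on <- time_s >= t0 & time_s < t1
  f[on] <- 1 -
    a_tj * (1 - exp(-(time_s[on] - t0) / phase$tau_tj)) -
    a_th * (1 - exp(-(time_s[on] - t0) / phase$tau_th))
  off <- time_s >= t1
  f_t1 <- 1 -
    a_tj * (1 - exp(-config$t_on_s / phase$tau_tj)) -
    a_th * (1 - exp(-config$t_on_s / phase$tau_th))
  f[off] <- 1 + (f_t1 - 1) * exp(-(time_s[off] - t1) / tau_bd)
  f
}
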