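## Sensor physics and signal preprocessing:
## reference correction, load-resistor voltage -> conductance, and QCM
## (quartz crystal microbalance) utilities: Sauerbrey mass sensitivity,
## mass change, dissipation.

#' Quartz crystal constants
#'
#' Physical constants of an AT-cut quartz resonator used by
#' [sauerbrey_sensitivity()]. Defaults are the standard room-temperature
#' values for quartz in CGS units.
#'
#' @param mu_q Shear modulus of quartz in g cm^-1 s^-2. Default 2.947e11.
#' @param rho_q Density of quartz in g cm^-3. Default 2.648.
#' @param n Harmonic number at which the crystal is driven (positive integer).
#' @param f0 Fundamental resonant frequency in Hz. Default 5 MHz.
#' @return An object of class `quartz_constants`.
#' @examples
#' q <- quartz_constants()
#' sauerbrey_sensitivity(q)
#' @export
quartz_constants <- function(mu_q = 2.947e11, rho_q = 2.648, n = 1L, f0 = 5e6) {
  stopifnot(is.numeric(mu_q), is.numeric(rho_q), is.numeric(n), is.numeric(f0))
  if (!all(is.finite(c(mu_q, rho_q, n, f0))) ||
      any(c(mu_q, rho_q, n, f0) <= 0)) {
    stop("all quartz constants must be finite and strictly positive")
  }
  if (n != as.integer(n)) stop("harmonic number 'n' must be a positive integer")
  structure(list(mu_q = mu_q, rho_q = rho_q, n = as.integer(n), f0 = f0),
            class = "quartz_constants")
}

#' Sauerbrey mass-sensitivity factor
#'
#' Computes the sensitivity factor C_f = 2 n f0^2 / sqrt(mu_q rho_q) of a
#' quartz crystal microbalance, i.e. the frequency shift per unit areal mass
#' loading under the small-load approximation (Delta f = -C_f Delta m).
#' The computation is carried out in CGS units (Hz cm^2/g) and returned in
#' the conventional Hz cm^2/ug. For a fundamental-mode 5 MHz AT-cut crystal
#' this evaluates to 56.6 Hz cm^2/ug.
#'
#' @param q A [quartz_constants()] object.
#' @return Sensitivity factor in Hz cm^2 per microgram.
#' @export
sauerbrey_sensitivity <- function(q) {
  stopifnot(inherits(q, "quartz_constants"))
  cf_cgs <- 2 * q$n * q$f0^2 / sqrt(q$mu_q * q$rho_q)  # Hz cm^2 / g
  cf_cgs / 1e6                                         # Hz cm^2 / ug
}

#' Areal mass change from a QCM frequency shift
#'
#' Inverts the Sauerbrey relation Delta f = -C_f Delta m.
#'
#' @param delta_f Frequency shift in Hz (negative for mass uptake).
#' @param C_f Sensitivity factor in Hz cm^2/ug; must be positive.
#' @return Mass change per unit area in ug cm^-2.
#' @export
mass_change <- function(delta_f, C_f) {
  if (!is.numeric(C_f) || any(C_f <= 0)) stop("C_f must be positive")
  -delta_f / C_f
}

#' Dissipation factor of a quartz resonator
#'
#' `dissipation_from_bandwidth()` computes D = w / f0 (the reciprocal quality
#' factor) from the resonance bandwidth; `dissipation_from_decay()` computes
#' D = 1 / (pi * delta_f * tau) from the decay constant of the resonator.
#'
#' @param w Resonance bandwidth in Hz.
#' @param f0 Resonant frequency in Hz.
#' @param delta_f Frequency in Hz.
#' @param tau Decay constant in seconds.
#' @return Dimensionless dissipation factor.
#' @export
dissipation_from_bandwidth <- function(w, f0) {
  if (any(f0 <= 0)) stop("f0 must be positive")
  w / f0
}

#' @rdname dissipation_from_bandwidth
#' @export
dissipation_from_decay <- function(delta_f, tau) {
  if (any(delta_f * tau <= 0)) stop("delta_f * tau must be positive")
  1 / (pi * delta_f * tau)
}

# Load resistors (Ohm) of the MOS measuring circuits, per sensor
MOS_LOAD_R <- c(TGS813 = 6000, TGS816 = 1000, TGS826 = 2000, TGS832 = 3000,
                TGS2602 = 1000, TGS2610 = 4700, TGS2612 = 2000, TGS2620 = 2000)

#' MOS sensor measuring circuit
#'
#' Describes the series load-resistor circuit of a metal-oxide-semiconductor
#' gas sensor: the sensor and a load resistor R_L form a voltage divider
#' across the circuit voltage V_C, and the voltage over R_L is recorded.
#' Defaults follow the hybrid array's wiring: TGS8xx sensors run at
#' V_C = 24 V, TGS2xxx sensors at V_C = 5 V, with per-sensor load resistors.
#'
#' @param sensor_id Sensor name, e.g. `"TGS813"`.
#' @param V_C Circuit voltage in volts; defaults by sensor family.
#' @param R_L Load resistance in Ohm; defaults to the array's wiring.
#' @return An object of class `mos_circuit`.
#' @export
mos_circuit <- function(sensor_id, V_C = NULL, R_L = NULL) {
  if (is.null(V_C)) {
    if (!sensor_id %in% MOS_SENSORS)
      stop("unknown sensor '", sensor_id, "': supply V_C and R_L explicitly")
    V_C <- if (grepl("^TGS8", sensor_id)) 24 else 5
  }
  if (is.null(R_L)) R_L <- unname(MOS_LOAD_R[[sensor_id]])
  if (V_C <= 0 || R_L <= 0) stop("V_C and R_L must be strictly positive")
  structure(list(sensor_id = sensor_id, V_C = V_C, R_L = R_L),
            class = "mos_circuit")
}

#' Reference-correct a sensor time series
#'
#' Subtracts the value at the reference time from the whole series, so the
#' output is exactly zero at `t_ref`. This anchors every channel to its state
#' at the instant the breath sample reaches the sensors. If `t_ref` does not
#' fall on the sampling grid the nearest sample is used.
#'
#' @param values Numeric series.
#' @param t Time grid in seconds, same length as `values`.
#' @param t_ref Reference time in seconds (default 130, the end of the
#'   initial clean phase).
#' @return Corrected series of the same length.
#' @export
reference_correct <- function(values, t, t_ref = 130) {
  if (length(values) == 0L) stop("empty series")
  if (length(values) != length(t)) stop("values and t must have equal length")
  if (t_ref < min(t) || t_ref > max(t))
    stop("t_ref = ", t_ref, " lies outside the time grid span [",
         min(t), ", ", max(t), "]")
  i <- which.min(abs(t - t_ref))
  values - values[i]
}

#' Convert load-resistor voltage to sensor conductance
#'
#' Computes G(t) = v(t) / ((V_C - v(t)) R_L), the conductance of a MOS sensor
#' inferred from the voltage measured across its series load resistor. The
#' map is strictly increasing in v on [0, V_C).
#'
#' @param v Voltage series in volts; must satisfy 0 <= v < V_C unless
#'   `check = FALSE`.
#' @param circuit A [mos_circuit()] object.
#' @param t Optional time grid, used only to name the offending sample in
#'   error messages.
#' @param check Validate the voltage range (default TRUE). Disabled when the
#'   conversion is deliberately applied to reference-corrected (possibly
#'   negative) voltages.
#' @return Conductance series in siemens.
#' @export
voltage_to_conductance <- function(v, circuit, t = NULL, check = TRUE) {
  stopifnot(inherits(circuit, "mos_circuit"))
  if (check) {
    bad <- which(v < 0 | v >= circuit$V_C)
    if (length(bad)) {
      at <- if (!is.null(t)) paste0(" at t = ", t[bad[1]], " s") else
        paste0(" at sample ", bad[1])
      stop("sensor ", circuit$sensor_id, ": voltage ", signif(v[bad[1]], 6),
           " V outside [0, V_C = ", circuit$V_C, " V)", at)
    }
  }
  v / ((circuit$V_C - v) * circuit$R_L)
}

#' Preprocess a breath experiment
#'
#' Applies the standard preprocessing chain to one experiment: MOS voltages
#' are converted to conductance and then reference-corrected at `t_ref`
#' (default order), and QCM frequency shifts are reference-corrected. The
#' alternative `order = "literal"` first reference-corrects the MOS voltage
#' and then applies the conductance formula to the corrected (possibly
#' negative) voltage; it is provided for comparison but the default order
#' avoids undefined or negative conductance.
#'
#' @param exp A `sensor_experiment` from [simulate_experiment()].
#' @param t_ref Reference time in seconds (default 130).
#' @param order `"conductance_first"` (default) or `"literal"`.
#' @return A `sensor_experiment` whose `mos` channels hold reference-corrected
#'   conductance (S) and whose `qcm` channels hold reference-corrected
#'   frequency shift (Hz).
#' @export
preprocess_experiment <- function(exp, t_ref = 130,
                                  order = c("conductance_first", "literal")) {
  stopifnot(inherits(exp, "sensor_experiment"))
  order <- match.arg(order)
  t <- exp$t
  mos <- exp$mos
  for (s in colnames(mos)) {
    circ <- mos_circuit(s)
    if (order == "conductance_first") {
      g <- voltage_to_conductance(mos[, s], circ, t = t)
      mos[, s] <- reference_correct(g, t, t_ref)
    } else {
      vr <- reference_correct(mos[, s], t, t_ref)
      mos[, s] <- voltage_to_conductance(vr, circ, t = t, check = FALSE)
    }
  }
  qcm <- exp$qcm
  for (s in colnames(qcm)) qcm[, s] <- reference_correct(qcm[, s], t, t_ref)
  exp$mos <- mos
  exp$qcm <- qcm
  exp$preprocessed <- TRUE
  exp
}

#' Preprocess every experiment of a breath dataset
#'
#' @param dataset A `breath_dataset` from [simulate_breath()].
#' @inheritParams preprocess_experiment
#' @return The dataset with every experiment preprocessed.
#' @export
preprocess_dataset <- function(dataset, t_ref = 130,
                               order = c("conductance_first", "literal")) {
  stopifnot(inherits(dataset, "breath_dataset"))
  order <- match.arg(order)
  dataset$experiments <- lapply(dataset$experiments, preprocess_experiment,
                                t_ref = t_ref, order = order)
  dataset
}
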