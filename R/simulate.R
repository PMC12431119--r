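## Synthetic breath-experiment generator.
##
## Each experiment is a 340 s multichannel recording: 8 MOS load-resistor
## voltages and 14 QCM frequency shifts. The experiment has four phases:
## [0,130) clean air, [130,170) sample delivery, [170,200) reaction (valves
## closed), [200,340] cleaning. Channels follow first-order kinetics: a rise
## 1 - exp(-(t-130)/tau_rise) while the sample is present, then exponential
## decay during cleaning, with class- and sensor-specific amplitudes, a
## lognormal per-subject multiplier, and iid Gaussian sensor noise.

#' Default class-amplitude table
#'
#' Returns the bundled synthetic class-response table: for each of the 22
#' channels, a baseline (V for MOS, 0 Hz for QCM) and one response amplitude
#' per class (positive volts for MOS, negative hertz for QCM). The table is a
#' fixed synthetic stand-in for class-specific breath VOC responses; it is
#' pinned in `inst/extdata/class_amplitudes.csv` so tests and examples are
#' reproducible.
#'
#' @return A data frame with columns `sensor_id`, `sensor_type`, `baseline`,
#'   `LC`, `HnS`, `HS`.
#' @export
default_amplitudes <- function() {
  path <- system.file("extdata", "class_amplitudes.csv", package = "enosefl")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Generator configuration for synthetic breath datasets
#'
#' Collects every knob of the synthetic generator. Defaults reproduce the
#' study conditions the analysis assumes: 338 experiments (219 LC, 60 HnS,
#' 59 HS), phases 130/170/200/340 s, 1 Hz sampling.
#'
#' @param n_per_class Named counts for classes `LC`, `HnS`, `HS`.
#' @param phase_times Named vector `c(clean_end, delivery_end, reaction_end,
#'   total)` in seconds, strictly increasing.
#' @param sampling_rate Samples per second (> 0). Default 1 Hz.
#' @param amplitudes Data frame as returned by [default_amplitudes()]:
#'   per-sensor baseline plus per-class response amplitudes (MOS >= 0 V,
#'   QCM <= 0 Hz).
#' @param tau_rise,tau_decay First-order rise and decay time constants in
#'   seconds.
#' @param noise_sd Named vector `c(MOS = , QCM = )` of Gaussian noise standard
#'   deviations (V and Hz respectively), each >= 0.
#' @param subject_sd Log-scale standard deviation of the lognormal
#'   per-experiment subject multiplier (>= 0).
#' @param effect_size Scalar scaling of inter-class amplitude separation:
#'   0 collapses all classes onto the across-class mean response, 1 keeps the
#'   table as-is, larger values pull the classes further apart.
#' @param seed Optional integer seed recorded in the config and used by
#'   [simulate_breath()].
#' @return An object of class `breath_config`.
#' @export
breath_config <- function(n_per_class = c(LC = 219, HnS = 60, HS = 59),
                          phase_times = c(clean_end = 130, delivery_end = 170,
                                          reaction_end = 200, total = 340),
                          sampling_rate = 1,
                          amplitudes = default_amplitudes(),
                          tau_rise = 15, tau_decay = 25,
                          noise_sd = c(MOS = 0.01, QCM = 0.5),
                          subject_sd = 0.15,
                          effect_size = 1,
                          seed = NULL) {
  n_per_class <- n_per_class[CLASS_LEVELS]
  if (any(is.na(n_per_class)) || any(n_per_class < 0))
    stop("n_per_class must give non-negative counts for LC, HnS and HS")
  if (!all(is.finite(phase_times)) || any(diff(c(0, phase_times)) <= 0))
    stop("phase_times must be finite and strictly increasing from 0")
  if (!is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0")
  if (!all(is.finite(c(tau_rise, tau_decay))) || tau_rise <= 0 || tau_decay <= 0)
    stop("tau_rise and tau_decay must be positive")
  noise_sd <- noise_sd[c("MOS", "QCM")]
  if (any(is.na(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must give non-negative values for MOS and QCM")
  if (!is.finite(subject_sd) || subject_sd < 0) stop("subject_sd must be >= 0")
  if (!is.finite(effect_size) || effect_size < 0)
    stop("effect_size must be a finite non-negative scalar")
  need <- c("sensor_id", "sensor_type", "baseline", CLASS_LEVELS)
  if (!all(need %in% names(amplitudes)))
    stop("amplitudes must have columns ", paste(need, collapse = ", "))
  if (!setequal(amplitudes$sensor_id, c(MOS_SENSORS, QCM_SENSORS)))
    stop("amplitudes must cover all 8 MOS and 14 QCM channels")
  is_mos <- amplitudes$sensor_type == "MOS"
  if (any(as.matrix(amplitudes[is_mos, CLASS_LEVELS]) < 0))
    stop("MOS amplitudes must be >= 0")
  if (any(as.matrix(amplitudes[!is_mos, CLASS_LEVELS]) > 0))
    stop("QCM amplitudes must be <= 0")
  structure(list(n_per_class = n_per_class, phase_times = phase_times,
                 sampling_rate = sampling_rate, amplitudes = amplitudes,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 noise_sd = noise_sd, subject_sd = subject_sd,
                 effect_size = effect_size, seed = seed),
            class = "breath_config")
}

# First-order response kernel k(t): 0 during the clean phase, saturating rise
# while the sample is present, exponential decay during cleaning.
response_kernel <- function(t, phase_times, tau_rise, tau_decay) {
  t0 <- phase_times[["clean_end"]]
  t2 <- phase_times[["reaction_end"]]
  k <- numeric(length(t))
  rise <- t >= t0 & t < t2
  k[rise] <- 1 - exp(-(t[rise] - t0) / tau_rise)
  peak <- 1 - exp(-(t2 - t0) / tau_rise)
  fall <- t >= t2
  k[fall] <- peak * exp(-(t[fall] - t2) / tau_decay)
  k
}

# Per-class effective amplitude matrix (class x sensor) under effect_size:
# amplitudes move linearly away from the across-class mean; the physical sign
# constraint (MOS >= 0, QCM <= 0) is enforced by clipping.
effective_amplitudes <- function(config) {
  amp <- config$amplitudes
  A <- t(as.matrix(amp[, CLASS_LEVELS]))          # class x sensor
  colnames(A) <- amp$sensor_id
  abar <- colMeans(A)
  A_eff <- sweep(sweep(A, 2, abar, "-") * config$effect_size, 2, abar, "+")
  mos <- amp$sensor_type == "MOS"
  A_eff[, mos] <- pmax(A_eff[, mos], 0)
  A_eff[, !mos] <- pmin(A_eff[, !mos], 0)
  A_eff
}

#' Simulate one breath experiment
#'
#' Generates the 22-channel time series of a single experiment of class
#' `label`. Each channel is
#' `baseline + m * A[label, sensor] * k(t) + noise`, where `m` is a lognormal
#' per-experiment subject multiplier and `k(t)` the first-order response
#' kernel. Uses the current RNG state; call `set.seed()` (or use
#' [simulate_breath()], which seeds from the config) for reproducibility.
#'
#' @param label Class label, one of `"LC"`, `"HnS"`, `"HS"`.
#' @param config A [breath_config()].
#' @param experiment_id Identifier stored in the result.
#' @return An object of class `sensor_experiment`: a list with `experiment_id`,
#'   `label`, time grid `t`, and matrices `mos` (samples x 8, volts) and
#'   `qcm` (samples x 14, hertz).
#' @export
simulate_experiment <- function(label, config, experiment_id = "exp1") {
  stopifnot(inherits(config, "breath_config"))
  if (!label %in% CLASS_LEVELS)
    stop("invalid class label '", label, "'; must be one of ",
         paste(CLASS_LEVELS, collapse = ", "))
  pt <- config$phase_times
  t <- seq(0, pt[["total"]], by = 1 / config$sampling_rate)
  k <- response_kernel(t, pt, config$tau_rise, config$tau_decay)
  A <- effective_amplitudes(config)[label, ]
  baseline <- setNames(config$amplitudes$baseline, config$amplitudes$sensor_id)
  type <- setNames(config$amplitudes$sensor_type, config$amplitudes$sensor_id)
  m <- if (config$subject_sd > 0) rlnorm(1, 0, config$subject_sd) else 1

  gen <- function(sensors) {
    out <- vapply(sensors, function(s) {
      eps <- if (config$noise_sd[[type[[s]]]] > 0)
        rnorm(length(t), 0, config$noise_sd[[type[[s]]]]) else 0
      baseline[[s]] + m * A[[s]] * k + eps
    }, numeric(length(t)))
    colnames(out) <- sensors
    out
  }
  structure(list(experiment_id = experiment_id, label = label, t = t,
                 mos = gen(MOS_SENSORS), qcm = gen(QCM_SENSORS),
                 subject_multiplier = m),
            class = "sensor_experiment")
}

#' Simulate a full synthetic breath dataset
#'
#' Generates `sum(n_per_class)` experiments (default 338: 219 LC, 60 HnS,
#' 59 HS) with the given configuration. If `config$seed` is set, the RNG is
#' seeded first, so identical configs give bitwise-identical datasets.
#'
#' @param config A [breath_config()].
#' @return An object of class `breath_dataset`: list with `experiments`
#'   (list of `sensor_experiment`), `labels` (factor with levels LC/HnS/HS)
#'   and the `config`.
#' @export
simulate_breath <- function(config = breath_config()) {
  stopifnot(inherits(config, "breath_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  labels <- rep(CLASS_LEVELS, times = config$n_per_class)
  ids <- sprintf("exp%03d", seq_along(labels))
  experiments <- Map(function(lab, id) simulate_experiment(lab, config, id),
                     labels, ids)
  names(experiments) <- ids
  structure(list(experiments = experiments,
                 labels = factor(labels, levels = CLASS_LEVELS),
                 config = config),
            class = "breath_dataset")
}

#' @export
print.breath_dataset <- function(x, ...) {
  cat("Synthetic breath dataset:", length(x$experiments), "experiments\n")
  print(table(x$labels))
  cat("channels: ", ncol(x$experiments[[1]]$mos), " MOS + ",
      ncol(x$experiments[[1]]$qcm), " QCM, ",
      length(x$experiments[[1]]$t), " samples each\n", sep = "")
  invisible(x)
}

#' Write / read a breath dataset as long-format CSV
#'
#' The on-disk format has one row per (experiment, sensor, time) with columns
#' `experiment_id, label, sensor_id, sensor_type, t_s, value`.
#'
#' @param dataset A `breath_dataset`.
#' @param path File path.
#' @return `write_breath_csv` returns `path` invisibly; `read_breath_csv`
#'   returns a `breath_dataset` (without a generator config).
#' @export
write_breath_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "breath_dataset"))
  rows <- lapply(dataset$experiments, function(e) {
    long <- function(mat, type) data.frame(
      experiment_id = e$experiment_id, label = e$label,
      sensor_id = rep(colnames(mat), each = length(e$t)),
      sensor_type = type, t_s = rep(e$t, ncol(mat)),
      value = as.vector(mat))
    rbind(long(e$mos, "MOS"), long(e$qcm, "QCM"))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_breath_csv
#' @export
read_breath_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(d$experiment_id)
  experiments <- lapply(ids, function(id) {
    di <- d[d$experiment_id == id, ]
    t <- sort(unique(di$t_s))
    wide <- function(type, sensors) {
      m <- vapply(sensors, function(s) {
        ds <- di[di$sensor_id == s, ]
        ds$value[order(ds$t_s)]
      }, numeric(length(t)))
      colnames(m) <- sensors
      m
    }
    structure(list(experiment_id = id, label = di$label[1], t = t,
                   mos = wide("MOS", intersect(MOS_SENSORS, di$sensor_id)),
                   qcm = wide("QCM", intersect(QCM_SENSORS, di$sensor_id))),
              class = "sensor_experiment")
  })
  names(experiments) <- ids
  labels <- vapply(experiments, function(e) e$label, character(1))
  structure(list(experiments = experiments,
                 labels = factor(labels, levels = CLASS_LEVELS),
                 config = NULL),
            class = "breath_dataset")
}
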