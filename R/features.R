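## Feature extraction from preprocessed experiments.
##
## The MOS matrix has 91 columns: 5 summary statistics x 8 sensors (40),
## 5 slope intervals x 8 sensors (40), 3 pairwise signed areas (3), and the
## area under each sensor (8). The QCM matrix has 7 columns: 4 pairwise
## areas, 2 slopes, 1 maximum. Concatenation gives the 98-column hybrid
## matrix. Column counts are a structural contract and hold for any dataset.

interval_idx <- function(t, interval) {
  idx <- which(t >= interval[1] & t <= interval[2])
  if (length(idx) == 0L)
    stop("interval [", interval[1], ", ", interval[2],
         "] contains no samples")
  idx
}

#' Summary statistics of a series over an interval
#'
#' Computes maximum, mean, population variance, excess kurtosis and Fisher
#' skewness of a channel over a closed time interval. A zero-variance window
#' yields skewness 0 and kurtosis 0 by convention.
#'
#' @param x Numeric series.
#' @param t Time grid in seconds.
#' @param interval `c(start, end)` in seconds; both endpoints included.
#' @return Named vector `(max, mean, var, kurtosis, skewness)`.
#' @export
summary_stats <- function(x, t, interval) {
  w <- x[interval_idx(t, interval)]
  if (length(w) < 4L) stop("need at least 4 samples in the interval")
  n <- length(w)
  v <- sum((w - mean(w))^2) / n   # population variance
  if (v > 0) {
    sk <- e1071::skewness(w, type = 1)
    ku <- e1071::kurtosis(w, type = 1)
  } else {
    sk <- 0; ku <- 0
  }
  c(max = max(w), mean = mean(w), var = v, kurtosis = ku, skewness = sk)
}

#' Least-squares slope of a series over an interval
#'
#' @inheritParams summary_stats
#' @return OLS slope in units per second.
#' @export
slope <- function(x, t, interval) {
  idx <- interval_idx(t, interval)
  if (length(idx) < 2L) stop("need at least 2 samples for a slope")
  tw <- t[idx]; w <- x[idx]
  tc <- tw - mean(tw)
  sum(tc * (w - mean(w))) / sum(tc^2)
}

#' Signed area between two series over an interval
#'
#' Trapezoid-rule integral of `a - b`; antisymmetric in its arguments.
#' `area_under()` is the special case with `b = 0`.
#'
#' @param a,b Numeric series on the same time grid.
#' @inheritParams summary_stats
#' @return Signed area in units times seconds.
#' @export
area_between <- function(a, b, t, interval) {
  if (length(a) != length(b) || length(a) != length(t))
    stop("series must share the time grid")
  idx <- interval_idx(t, interval)
  pracma::trapz(t[idx], a[idx] - b[idx])
}

#' @rdname area_between
#' @param x Numeric series.
#' @export
area_under <- function(x, t, interval) {
  idx <- interval_idx(t, interval)
  pracma::trapz(t[idx], x[idx])
}

#' Feature-set configurations
#'
#' `mos_feature_config()` fixes the MOS feature set: the summary-statistic
#' window, the five slope intervals, the three sensor pairs whose signed area
#' over the delivery window is used, and the area-under interval. One of the
#' nominal area pairs names a sensor ("TGS880") absent from the 8-sensor
#' array; the default maps that pair member to TGS816 and the substitution is
#' configurable. `qcm_feature_config()` fixes the QCM set: four area pairs
#' and two slopes over the 100-140 s window plus the maximum of QCM5.
#'
#' @param stat_interval,auc_interval,window Intervals in seconds.
#' @param slope_intervals List of intervals in seconds.
#' @param area_pairs List of length-2 sensor-name vectors.
#' @param slope_sensors,max_sensor QCM channel names.
#' @return A list of configuration entries.
#' @export
mos_feature_config <- function(stat_interval = c(130, 230),
                               slope_intervals = list(c(130, 145), c(145, 170),
                                                      c(170, 200), c(200, 215),
                                                      c(200, 230)),
                               area_pairs = list(c("TGS826", "TGS832"),
                                                 c("TGS813", "TGS2620"),
                                                 c("TGS816", "TGS2610")),
                               auc_interval = c(145, 215)) {
  list(stat_interval = stat_interval, slope_intervals = slope_intervals,
       area_pairs = area_pairs, auc_interval = auc_interval,
       area_interval = c(130, 170))
}

#' @rdname mos_feature_config
#' @export
qcm_feature_config <- function(window = c(100, 140),
                               area_pairs = list(c("QCM6", "QCM14"),
                                                 c("QCM2", "QCM11"),
                                                 c("QCM9", "QCM11"),
                                                 c("QCM14", "QCM7")),
                               slope_sensors = c("QCM11", "QCM6"),
                               max_sensor = "QCM5") {
  list(window = window, area_pairs = area_pairs,
       slope_sensors = slope_sensors, max_sensor = max_sensor)
}

new_feature_matrix <- function(x, labels) {
  if (anyNA(x)) stop("feature matrix contains missing values")
  if (anyDuplicated(colnames(x))) stop("duplicate feature column names")
  structure(list(x = x, labels = labels), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$x), "experiments x", ncol(x$x), "features\n")
  invisible(x)
}

#' Build the 91-column MOS feature matrix
#'
#' Extracts, for every experiment, 5 summary statistics and 5 interval slopes
#' per MOS channel, 3 pairwise signed areas over 130-170 s, and the area
#' under each channel over 145-215 s — 91 features in total. Expects a
#' preprocessed dataset (reference-corrected conductance channels).
#'
#' @param dataset A preprocessed `breath_dataset`.
#' @param config A [mos_feature_config()].
#' @return A `feature_matrix` with 91 columns.
#' @export
build_mos_features <- function(dataset, config = mos_feature_config()) {
  stopifnot(inherits(dataset, "breath_dataset"))
  rows <- lapply(dataset$experiments, function(e) {
    if (!all(MOS_SENSORS %in% colnames(e$mos)))
      stop("experiment ", e$experiment_id, " is missing MOS channels")
    stats <- unlist(lapply(MOS_SENSORS, function(s) {
      st <- summary_stats(e$mos[, s], e$t, config$stat_interval)
      setNames(st, paste(s, names(st), sep = "."))
    }))
    slopes <- unlist(lapply(MOS_SENSORS, function(s) {
      sl <- vapply(config$slope_intervals, function(iv)
        slope(e$mos[, s], e$t, iv), numeric(1))
      setNames(sl, vapply(config$slope_intervals, function(iv)
        paste(s, "slope", iv[1], iv[2], sep = "."), character(1)))
    }))
    areas <- vapply(config$area_pairs, function(p)
      area_between(e$mos[, p[1]], e$mos[, p[2]], e$t, config$area_interval),
      numeric(1))
    names(areas) <- vapply(config$area_pairs, function(p)
      paste("area", p[1], p[2], sep = "."), character(1))
    aucs <- vapply(MOS_SENSORS, function(s)
      area_under(e$mos[, s], e$t, config$auc_interval), numeric(1))
    names(aucs) <- paste(MOS_SENSORS, "auc", sep = ".")
    c(stats, slopes, areas, aucs)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(dataset$experiments)
  new_feature_matrix(x, dataset$labels)
}

#' Build the 7-column QCM feature matrix
#'
#' Four pairwise signed areas, slopes of QCM11 and QCM6, and the maximum of
#' QCM5, all over the configured 100-140 s window, from reference-corrected
#' frequency-shift channels.
#'
#' @param dataset A preprocessed `breath_dataset`.
#' @param config A [qcm_feature_config()].
#' @return A `feature_matrix` with 7 columns.
#' @export
build_qcm_features <- function(dataset, config = qcm_feature_config()) {
  stopifnot(inherits(dataset, "breath_dataset"))
  rows <- lapply(dataset$experiments, function(e) {
    need <- unique(c(unlist(config$area_pairs), config$slope_sensors,
                     config$max_sensor))
    if (!all(need %in% colnames(e$qcm)))
      stop("experiment ", e$experiment_id, " is missing QCM channels")
    areas <- vapply(config$area_pairs, function(p)
      area_between(e$qcm[, p[1]], e$qcm[, p[2]], e$t, config$window),
      numeric(1))
    names(areas) <- vapply(config$area_pairs, function(p)
      paste("area", p[1], p[2], sep = "."), character(1))
    slopes <- vapply(config$slope_sensors, function(s)
      slope(e$qcm[, s], e$t, config$window), numeric(1))
    names(slopes) <- paste(config$slope_sensors, "slope", sep = ".")
    mx <- max(e$qcm[interval_idx(e$t, config$window), config$max_sensor])
    c(areas, slopes, setNames(mx, paste(config$max_sensor, "max", sep = ".")))
  })
  x <- do.call(rbind, rows)
  rownames(x) <- names(dataset$experiments)
  new_feature_matrix(x, dataset$labels)
}

#' Concatenate feature matrices column-wise
#'
#' Joins two feature matrices over the same experiments (91 + 7 = 98 columns
#' for the hybrid MOS+QCM matrix). Row order, experiment ids and labels must
#' agree; column names must not collide.
#'
#' @param a,b `feature_matrix` objects.
#' @return A `feature_matrix` with `ncol(a) + ncol(b)` columns.
#' @export
concat_features <- function(a, b) {
  stopifnot(inherits(a, "feature_matrix"), inherits(b, "feature_matrix"))
  if (nrow(a$x) != nrow(b$x) || !identical(rownames(a$x), rownames(b$x)))
    stop("feature matrices are misaligned: experiment ids differ")
  if (!identical(as.character(a$labels), as.character(b$labels)))
    stop("feature matrices carry different labels")
  common <- intersect(colnames(a$x), colnames(b$x))
  if (length(common))
    stop("column name collision: ", paste(common, collapse = ", "))
  new_feature_matrix(cbind(a$x, b$x), a$labels)
}
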