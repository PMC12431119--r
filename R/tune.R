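## Encoding of a fuzzy system's membership-function parameters as a flat
## vector for the optimizers, with feasibility repair, the training-accuracy
## fitness, and the tuning driver.

# Indices of "width" parameters (must stay strictly positive) and of ordered
# breakpoint blocks, within one MF's parameter vector.
mf_param_roles <- function(family) {
  switch(family,
         gaussian = list(width = 2L, ordered = integer(0)),
         gbell = list(width = 1L, ordered = integer(0), shape = 2L),
         triangular = list(width = integer(0), ordered = 1:3),
         trapezoidal = list(width = integer(0), ordered = 1:4),
         pi = list(width = integer(0), ordered = 1:4))
}

#' Encode a fuzzy system's MF parameters as a flat vector
#'
#' Concatenates, axis by axis and set by set, each membership function's
#' parameter vector (14 MFs in total, so e.g. 42 entries for gbell, 28 for
#' gaussian). The companion `meta` object records the family, per-axis value
#' ranges and the set labels, and is what [decode_fl()] needs to rebuild a
#' system.
#'
#' @param system An `fl_system` whose 14 MFs share one family.
#' @param ranges Optional list of two `c(lo, hi)` axis ranges used for the
#'   bounds; defaults to the span of the MF parameters themselves.
#' @return List with `par` (numeric vector) and `meta`.
#' @export
encode_fl <- function(system, ranges = NULL) {
  fams <- vapply(c(system$mfs_ld1, system$mfs_ld2),
                 function(m) m$family, character(1))
  if (length(unique(fams)) != 1L)
    stop("all membership functions must share one family to be encoded")
  family <- fams[1]
  npar <- mf_n_params(family)
  if (is.null(ranges)) {
    rng <- function(mfs) range(unlist(lapply(mfs, function(m) m$params)))
    ranges <- list(rng(system$mfs_ld1), rng(system$mfs_ld2))
  }
  par <- c(unlist(lapply(system$mfs_ld1, function(m) m$params)),
           unlist(lapply(system$mfs_ld2, function(m) m$params)))
  meta <- list(family = family, npar = npar, ranges = ranges,
               tie_break = system$tie_break)
  list(par = par, meta = meta)
}

#' Rebuild a fuzzy system from a flat parameter vector
#'
#' @param par Numeric vector of length `14 * mf_n_params(family)`.
#' @param meta Metadata from [encode_fl()].
#' @param rules A `rule_base` (kept fixed during tuning).
#' @return An `fl_system`.
#' @export
decode_fl <- function(par, meta, rules) {
  npar <- meta$npar
  if (length(par) != 14 * npar)
    stop("parameter vector has length ", length(par), ", expected ", 14 * npar)
  take <- function(k) par[((k - 1) * npar + 1):(k * npar)]
  mk <- function(offset) lapply(1:7, function(i)
    mf(meta$family, take(offset + i), FL_SET_LABELS[i]))
  fl_system(mk(0L), mk(7L), rules, meta$tie_break)
}

#' Bounds for an encoded parameter vector
#'
#' Positions and breakpoints may roam half an axis range beyond the observed
#' span; width parameters are confined to `(0, range]`; the gbell shape
#' exponent to `[0.5, 10]`.
#'
#' @param meta Metadata from [encode_fl()].
#' @return List with vectors `lo` and `hi`.
#' @export
fl_bounds <- function(meta) {
  roles <- mf_param_roles(meta$family)
  npar <- meta$npar
  lo <- hi <- numeric(14 * npar)
  for (k in 1:14) {
    axis <- if (k <= 7) 1 else 2
    r <- meta$ranges[[axis]]
    span <- max(r[2] - r[1], 1e-9)
    idx <- ((k - 1) * npar + 1):(k * npar)
    lo[idx] <- r[1] - 0.5 * span
    hi[idx] <- r[2] + 0.5 * span
    if (length(roles$width)) {
      lo[idx[roles$width]] <- 1e-6 * span
      hi[idx[roles$width]] <- span
    }
    if (!is.null(roles$shape)) {
      lo[idx[roles$shape]] <- 0.5
      hi[idx[roles$shape]] <- 10
    }
  }
  list(lo = lo, hi = hi)
}

#' Repair an encoded parameter vector
#'
#' Clips every entry to its bounds, sorts ordered breakpoint blocks
#' (a <= b <= c <= d) within each membership function, and floors width and
#' scale parameters at 1e-6 of the axis range. Idempotent; an in-bounds,
#' ordered vector passes through unchanged.
#'
#' @param par Numeric vector.
#' @param meta Metadata from [encode_fl()].
#' @param bounds Bounds from [fl_bounds()].
#' @return A feasible parameter vector of the same length.
#' @export
repair_fl <- function(par, meta, bounds = fl_bounds(meta)) {
  par <- clip_bounds(par, bounds)
  roles <- mf_param_roles(meta$family)
  npar <- meta$npar
  if (length(roles$ordered)) {
    for (k in 1:14) {
      idx <- ((k - 1) * npar + 1):(k * npar)
      par[idx[roles$ordered]] <- sort(par[idx[roles$ordered]])
    }
  }
  par
}

#' Training-accuracy fitness of an encoded fuzzy system
#'
#' Decodes the vector (with the rule base held fixed), classifies the
#' training points and returns the accuracy in percent. Deterministic given
#' its inputs.
#'
#' @param par Encoded parameter vector (already repaired).
#' @param meta,rules As in [decode_fl()].
#' @param points n x 2 training coordinates.
#' @param labels True classes.
#' @return Accuracy in percent.
#' @export
fl_fitness <- function(par, meta, rules, points, labels) {
  classify_batch(decode_fl(par, meta, rules), points, labels)$accuracy
}

#' Tune a fuzzy classifier's membership functions
#'
#' Initializes a fuzzy system by equal partition of the class regions,
#' freezes the rule base, and optimizes the flattened membership-function
#' parameters with the selected metaheuristic, maximizing training accuracy.
#' The initial system is seeded into the optimizer's starting population, so
#' the tuned model's training accuracy is never below the initial model's.
#'
#' @param points n x 2 training (LD1, LD2) coordinates.
#' @param labels Training classes (at least two distinct).
#' @param family Membership-function family.
#' @param spec An [opt_spec()].
#' @param rules Optional fixed `rule_base`; default learnt from the data.
#' @param tie_break Class preference order.
#' @return List with `system` (tuned `fl_system`), `init_system`, `result`
#'   (the `opt_result`), and `meta`.
#' @export
tune_fuzzy_model <- function(points, labels, family = "gbell",
                             spec = opt_spec("GA"), rules = NULL,
                             tie_break = c("LC", "HnS", "HS")) {
  points <- as.matrix(points)
  if (length(unique(as.character(labels))) < 2L)
    stop("training data contain a single class")
  init_sys <- init_partition(points, labels, family, rules, tie_break)
  enc <- encode_fl(init_sys,
                   ranges = list(range(points[, 1]), range(points[, 2])))
  bounds <- fl_bounds(enc$meta)
  rules_fixed <- init_sys$rules
  objective <- function(v) fl_fitness(v, enc$meta, rules_fixed,
                                      points, labels)
  result <- optimize_mh(spec, objective, bounds,
                        init = matrix(repair_fl(enc$par, enc$meta, bounds),
                                      nrow = 1),
                        maximize = TRUE,
                        repair_fn = function(v) repair_fl(v, enc$meta, bounds))
  list(system = decode_fl(result$par, enc$meta, rules_fixed),
       init_system = init_sys, result = result, meta = enc$meta)
}
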