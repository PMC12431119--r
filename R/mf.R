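## Membership functions of the fuzzy classifier. Five families, each with
## the standard closed form; all outputs lie in [0, 1].

MF_FAMILIES <- c("gaussian", "gbell", "triangular", "trapezoidal", "pi")

#' Number of parameters of a membership-function family
#' @param family One of `"gaussian"` (c, sigma), `"gbell"` (a, b, c),
#'   `"triangular"` (a, b, c), `"trapezoidal"` (a, b, c, d), `"pi"`
#'   (a, b, c, d).
#' @return Integer parameter count.
#' @export
mf_n_params <- function(family) {
  switch(match.arg(family, MF_FAMILIES),
         gaussian = 2L, gbell = 3L, triangular = 3L,
         trapezoidal = 4L, pi = 4L)
}

#' Construct a membership function
#'
#' @param family One of `"gaussian"`, `"gbell"`, `"triangular"`,
#'   `"trapezoidal"`, `"pi"`.
#' @param params Ordered numeric parameter vector: gaussian `(c, sigma)`
#'   with `sigma > 0`; gbell `(a, b, c)` with `a, b > 0`; triangular
#'   `(a, b, c)` non-decreasing; trapezoidal and pi `(a, b, c, d)`
#'   non-decreasing.
#' @param label Fuzzy-set label, e.g. `"O1"`.
#' @return An object of class `memfun`.
#' @export
mf <- function(family, params, label = NA_character_) {
  family <- match.arg(family, MF_FAMILIES)
  if (length(params) != mf_n_params(family))
    stop(family, " membership function needs ", mf_n_params(family),
         " parameters")
  if (!all(is.finite(params))) stop("membership parameters must be finite")
  switch(family,
    gaussian = if (params[2] <= 0) stop("gaussian sigma must be > 0"),
    gbell = if (params[1] <= 0 || params[2] <= 0)
      stop("gbell a and b must be > 0"),
    if (is.unsorted(params)) stop(family, " breakpoints must be non-decreasing"))
  structure(list(family = family, params = unname(params), label = label),
            class = "memfun")
}

# S-shaped spline ramp: 0 below a, 1 above b, quadratic splines between.
smf <- function(x, a, b) {
  if (b <= a) return(as.numeric(x >= b))
  y <- numeric(length(x))
  mid <- (a + b) / 2
  i1 <- x > a & x <= mid
  i2 <- x > mid & x < b
  y[i1] <- 2 * ((x[i1] - a) / (b - a))^2
  y[i2] <- 1 - 2 * ((x[i2] - b) / (b - a))^2
  y[x >= b] <- 1
  y
}

zmf <- function(x, a, b) 1 - smf(x, a, b)

ramp_up <- function(x, a, b) {
  if (b > a) pmin(pmax((x - a) / (b - a), 0), 1) else as.numeric(x >= b)
}

# descending edge: 1 at and left of b, 0 at and right of c
ramp_down <- function(x, b, c) {
  if (c > b) pmin(pmax((c - x) / (c - b), 0), 1) else as.numeric(x <= c)
}

#' Evaluate a membership function
#'
#' Standard closed forms: gaussian `exp(-(x-c)^2 / (2 sigma^2))`; generalized
#' bell `1 / (1 + |(x-c)/a|^(2b))`; triangular and trapezoidal piecewise
#' linear; pi-shaped the product of an S-ramp over `(a, b)` and a Z-ramp over
#' `(c, d)` with plateau `[b, c]`. Vectorized in `x`; all values lie in
#' `[0, 1]`.
#'
#' @param m A `memfun`.
#' @param x Numeric vector.
#' @return Membership degrees in `[0, 1]`.
#' @export
mf_value <- function(m, x) {
  stopifnot(inherits(m, "memfun"))
  p <- m$params
  switch(m$family,
    gaussian = exp(-(x - p[1])^2 / (2 * p[2]^2)),
    gbell = 1 / (1 + abs((x - p[3]) / p[1])^(2 * p[2])),
    triangular = pmin(ramp_up(x, p[1], p[2]), ramp_down(x, p[2], p[3])),
    trapezoidal = pmin(ramp_up(x, p[1], p[2]), ramp_down(x, p[3], p[4])),
    pi = smf(x, p[1], p[2]) * zmf(x, p[3], p[4]))
}

# Center (peak location) of a membership function, used by the
# zero-coverage fallback and by parameter-recovery checks.
mf_center <- function(m) {
  p <- m$params
  switch(m$family,
         gaussian = p[1], gbell = p[3], triangular = p[2],
         trapezoidal = (p[2] + p[3]) / 2, pi = (p[2] + p[3]) / 2)
}

#' @export
print.memfun <- function(x, ...) {
  cat(x$family, " MF [", x$label, "]: (",
      paste(signif(x$params, 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

# n x length(mfs) membership matrix
mf_matrix <- function(mfs, x) {
  out <- vapply(mfs, function(m) mf_value(m, x), numeric(length(x)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1)
  colnames(out) <- vapply(mfs, function(m) m$label, character(1))
  out
}
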