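## Mamdani max-min inference on the (LD1, LD2) plane.
## Rule strength = min of the two antecedent memberships; a class's score is
## the max strength over the rules carrying that consequent; the predicted
## class is the argmax, with deterministic tie handling.

#' Construct a fuzzy classification system
#'
#' Bundles the seven membership functions per axis, the 7x7 rule base and
#' the tie-break order into the fuzzy classifier evaluated by [fl_infer()].
#'
#' @param mfs_ld1,mfs_ld2 Lists of 7 `memfun`s (labels `O1, O2, +1, +2, D1,
#'   D2, D3`) for the LD1 and LD2 axes.
#' @param rules A `rule_base`.
#' @param tie_break Class order used for deterministic tie breaking and as
#'   the preference order of the zero-coverage fallback.
#' @return An object of class `fl_system`.
#' @export
fl_system <- function(mfs_ld1, mfs_ld2, rules,
                      tie_break = c("LC", "HnS", "HS")) {
  stopifnot(length(mfs_ld1) == 7, length(mfs_ld2) == 7,
            inherits(rules, "rule_base"))
  stopifnot(setequal(tie_break, CLASS_LEVELS))
  lab1 <- vapply(mfs_ld1, function(m) m$label, character(1))
  lab2 <- vapply(mfs_ld2, function(m) m$label, character(1))
  if (!identical(lab1, FL_SET_LABELS) || !identical(lab2, FL_SET_LABELS))
    stop("each axis needs the seven set labels ",
         paste(FL_SET_LABELS, collapse = ", "), " in order")
  structure(list(mfs_ld1 = mfs_ld1, mfs_ld2 = mfs_ld2, rules = rules,
                 tie_break = tie_break),
            class = "fl_system")
}

#' Fuzzy inference over a batch of points
#'
#' Evaluates the Mamdani max-min classifier at each row of `points`. If all
#' 49 rule strengths vanish at a point (possible for finite-support MF
#' families), the point inherits the consequent of the cell whose pair of MF
#' centres is nearest in the LD plane, so every point receives a label.
#'
#' @param system An `fl_system`.
#' @param points n x 2 numeric matrix (or length-2 vector) of (LD1, LD2)
#'   coordinates; must be finite.
#' @return List with `scores` (n x 3 matrix of class scores in [0, 1]) and
#'   `class` (factor of predicted classes).
#' @export
fl_infer <- function(system, points) {
  stopifnot(inherits(system, "fl_system"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("points must have two columns (LD1, LD2)")
  if (!all(is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  m1 <- mf_matrix(system$mfs_ld1, points[, 1])
  m2 <- mf_matrix(system$mfs_ld2, points[, 2])
  grid <- system$rules$grid
  scores <- matrix(0, n, 3, dimnames = list(NULL, CLASS_LEVELS))
  for (i in 1:7) for (j in 1:7) {
    s <- pmin(m1[, i], m2[, j])
    k <- grid[i, j]
    scores[, k] <- pmax(scores[, k], s)
  }
  # tie-break (and argmax) in declared preference order
  ord <- match(system$tie_break, CLASS_LEVELS)
  pick <- max.col(scores[, ord, drop = FALSE], ties.method = "first")
  cls <- system$tie_break[pick]
  uncovered <- which(apply(scores, 1, max) == 0)
  if (length(uncovered)) {
    c1 <- vapply(system$mfs_ld1, mf_center, numeric(1))
    c2 <- vapply(system$mfs_ld2, mf_center, numeric(1))
    for (u in uncovered) {
      dd <- outer((c1 - points[u, 1])^2, (c2 - points[u, 2])^2, "+")
      cell <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      cls[u] <- grid[cell[1], cell[2]]
    }
  }
  list(scores = scores, class = factor(cls, levels = CLASS_LEVELS))
}

#' Classify a batch of points and score against truth
#'
#' @param system An `fl_system`.
#' @param points n x 2 matrix of (LD1, LD2) coordinates.
#' @param truth Optional true class labels; when given, accuracy (%) and a
#'   confusion matrix (rows = truth, cols = predicted) are returned.
#' @return List with `class`, `scores`, and (if `truth` given) `accuracy`
#'   and `confusion`.
#' @export
classify_batch <- function(system, points, truth = NULL) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(points) == 0L) stop("empty input")
  out <- fl_infer(system, points)
  if (!is.null(truth)) {
    truth <- factor(as.character(truth), levels = CLASS_LEVELS)
    if (length(truth) != nrow(points))
      stop("truth length does not match points")
    out$accuracy <- 100 * mean(out$class == truth)
    out$confusion <- table(truth = truth, predicted = out$class)
  }
  out
}

#' @export
print.fl_system <- function(x, ...) {
  cat("Fuzzy classifier:", x$mfs_ld1[[1]]$family,
      "membership functions, 7 sets per axis, 49 rules\n")
  cat("tie-break order:", paste(x$tie_break, collapse = " > "), "\n")
  invisible(x)
}
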