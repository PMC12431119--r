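## The user-facing model interface: fl_fit() trains the full classifier
## (optional LDA reduction + membership-function tuning) and returns a
## classed object with the usual methods.

#' Fit the fuzzy-logic breath classifier
#'
#' Trains the complete classifier on a labelled feature matrix: features are
#' projected onto the Fisher discriminant plane (LD1, LD2) unless they
#' already are two-dimensional, the seven fuzzy sets per axis are initialized
#' by equal partition of each class's region, the 49-rule base is learnt
#' from the training scatter (or supplied), and the membership-function
#' parameters are tuned by the selected nature-inspired optimizer to
#' maximize training accuracy.
#'
#' @param x A `feature_matrix` or numeric matrix (rows = experiments).
#' @param labels Class labels (`LC`, `HnS`, `HS`); defaults to the labels of
#'   a `feature_matrix`.
#' @param family Membership-function family: `"gaussian"`, `"gbell"`,
#'   `"triangular"`, `"trapezoidal"` or `"pi"`.
#' @param optimizer An [opt_spec()]; default GA at its standard settings.
#' @param reduce `"lda"` (project to the discriminant plane when the input
#'   has more than 2 columns) or `"none"` (input must already be n x 2).
#' @param rules Optional fixed `rule_base`.
#' @param tie_break Class preference order for ties.
#' @return An object of class `fl_model` with `print`, `summary`, `coef`,
#'   `predict` and `plot` methods.
#' @examples
#' set.seed(1)
#' cfg <- breath_config(n_per_class = c(LC = 30, HnS = 12, HS = 12), seed = 7)
#' ds <- preprocess_dataset(simulate_breath(cfg))
#' feats <- concat_features(build_mos_features(ds), build_qcm_features(ds))
#' fit <- fl_fit(feats, optimizer = opt_spec("GA", pop_size = 20,
#'                                           max_iter = 10, seed = 1))
#' fit
#' @export
fl_fit <- function(x, labels = NULL, family = "gbell",
                   optimizer = opt_spec("GA"),
                   reduce = c("lda", "none"), rules = NULL,
                   tie_break = c("LC", "HnS", "HS")) {
  reduce <- match.arg(reduce)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  if (is.null(labels)) stop("labels are required")
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  xm <- as_matrix_x(x)
  projection <- NULL
  if (ncol(xm) != 2) {
    if (reduce == "none")
      stop("input must be n x 2 when reduce = 'none'")
    projection <- fit_lda(xm, labels)
    scores <- predict(projection, xm)
  } else {
    scores <- xm
    colnames(scores) <- c("LD1", "LD2")
  }
  tuned <- tune_fuzzy_model(scores, labels, family, optimizer, rules,
                            tie_break)
  train <- classify_batch(tuned$system, scores, labels)
  structure(list(system = tuned$system, projection = projection,
                 family = family, optimizer = optimizer,
                 opt_result = tuned$result, init_system = tuned$init_system,
                 train_scores = scores, train_labels = labels,
                 train_accuracy = train$accuracy,
                 train_confusion = train$confusion),
            class = "fl_model")
}

#' @export
print.fl_model <- function(x, ...) {
  cat("Fuzzy-logic breath classifier\n")
  cat("  membership family:", x$family, "| optimizer:", x$optimizer$method,
      "\n")
  if (!is.null(x$projection))
    cat("  LDA reduction:", length(x$projection$mean), "features -> 2\n")
  cat("  training accuracy:", sprintf("%.2f%%", x$train_accuracy), "on",
      length(x$train_labels), "experiments\n")
  invisible(x)
}

#' @export
summary.fl_model <- function(object, ...) {
  cat("Fuzzy-logic breath classifier\n\n")
  print(object$system)
  cat("\nMembership-function parameters:\n")
  print(coef(object))
  cat("\nOptimization:", object$optimizer$method, "—",
      object$opt_result$evaluations, "fitness evaluations, best",
      sprintf("%.2f%%", object$opt_result$value), "\n")
  cat("Training confusion matrix:\n")
  print(object$train_confusion)
  invisible(object)
}

#' @export
coef.fl_model <- function(object, ...) {
  sys <- object$system
  rows <- lapply(c(LD1 = 1, LD2 = 2), function(axis) {
    mfs <- if (axis == 1) sys$mfs_ld1 else sys$mfs_ld2
    do.call(rbind, lapply(mfs, function(m) m$params))
  })
  out <- rbind(rows$LD1, rows$LD2)
  rownames(out) <- paste(rep(c("LD1", "LD2"), each = 7), FL_SET_LABELS,
                         sep = ".")
  colnames(out) <- switch(object$family,
                          gaussian = c("c", "sigma"),
                          gbell = c("a", "b", "c"),
                          triangular = c("a", "b", "c"),
                          c("a", "b", "c", "d"))
  out
}

#' Predict classes for new experiments
#'
#' @param object An `fl_model`.
#' @param newdata A `feature_matrix`, numeric matrix in the original feature
#'   space, or an n x 2 matrix of (LD1, LD2) coordinates.
#' @param type `"class"` (default) or `"scores"`.
#' @param ... Unused.
#' @return Factor of predicted classes, or the n x 3 score matrix.
#' @export
predict.fl_model <- function(object, newdata,
                             type = c("class", "scores"), ...) {
  type <- match.arg(type)
  xm <- as_matrix_x(newdata)
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1)
  if (!is.null(object$projection) &&
      ncol(xm) == length(object$projection$mean)) {
    xm <- predict(object$projection, xm)
  } else if (ncol(xm) != 2) {
    stop("newdata must match the training feature space or be n x 2")
  }
  out <- fl_infer(object$system, xm)
  if (type == "class") out$class else out$scores
}

#' Plot a fitted fuzzy classifier
#'
#' Two panels: the training scatter on the discriminant plane with the
#' decision regions of the tuned system, and the membership functions on
#' each axis.
#'
#' @param x An `fl_model`.
#' @param grid_n Resolution of the decision-region raster.
#' @param ... Passed to `plot`.
#' @export
plot.fl_model <- function(x, grid_n = 121, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sc <- x$train_scores
  cols <- c(LC = "#D55E00", HnS = "#0072B2", HS = "#009E73")
  gx <- seq(min(sc[, 1]), max(sc[, 1]), length.out = grid_n)
  gy <- seq(min(sc[, 2]), max(sc[, 2]), length.out = grid_n)
  gz <- fl_infer(x$system, as.matrix(expand.grid(gx, gy)))$class
  graphics::image(gx, gy, matrix(as.integer(gz), grid_n, grid_n),
                  col = grDevices::adjustcolor(cols, 0.25),
                  xlab = "LD1", ylab = "LD2", main = "decision regions", ...)
  graphics::points(sc, col = cols[as.character(x$train_labels)], pch = 19,
                   cex = 0.6)
  for (axis in 1:2) {
    mfs <- if (axis == 1) x$system$mfs_ld1 else x$system$mfs_ld2
    xs <- seq(min(sc[, axis]), max(sc[, axis]), length.out = 300)
    graphics::plot(NA, xlim = range(xs), ylim = c(0, 1),
                   xlab = paste0("LD", axis), ylab = "membership",
                   main = paste0("LD", axis, " fuzzy sets"))
    for (i in seq_along(mfs))
      graphics::lines(xs, mf_value(mfs[[i]], xs), col = i, lwd = 1.5)
    graphics::legend("topright", legend = FL_SET_LABELS, col = 1:7,
                     lwd = 1.5, cex = 0.6, bty = "n")
  }
  invisible(x)
}

#' Serialize a fuzzy model to JSON
#'
#' Writes the membership families, parameters, set labels, rule grid and
#' tie-break order (plus the LDA projection if present) to a JSON file that
#' [read_fl_json()] can restore.
#'
#' @param model An `fl_model` or `fl_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fl_json <- function(model, path) {
  sys <- if (inherits(model, "fl_model")) model$system else model
  stopifnot(inherits(sys, "fl_system"))
  ser_mfs <- function(mfs) lapply(mfs, function(m)
    list(family = m$family, params = m$params, label = m$label))
  obj <- list(mfs_ld1 = ser_mfs(sys$mfs_ld1), mfs_ld2 = ser_mfs(sys$mfs_ld2),
              rules = as.data.frame(sys$rules$grid),
              tie_break = sys$tie_break)
  if (inherits(model, "fl_model") && !is.null(model$projection)) {
    p <- model$projection
    obj$projection <- list(kind = p$kind, mean = p$mean,
                           components = as.data.frame(p$components),
                           explained = p$explained, k = p$k)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_fl_json
#' @export
read_fl_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  des_mfs <- function(l) lapply(seq_len(nrow(l)), function(i)
    mf(l$family[i], unlist(l$params[i]), l$label[i]))
  grid <- as.matrix(obj$rules)
  dimnames(grid) <- list(LD1 = FL_SET_LABELS, LD2 = FL_SET_LABELS)
  fl_system(des_mfs(obj$mfs_ld1), des_mfs(obj$mfs_ld2), rule_base(grid),
            obj$tie_break)
}
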