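## Evaluation harness: stratified 5-fold cross-validation repeated 10 times,
## the fuzzy-logic protocol, conventional machine-learning baselines, and
## confusion-matrix metrics.

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds so that per-fold class counts
#' differ from exact proportionality by at most one. Depends only on the
#' labels and the seed, never on feature values.
#'
#' @param labels Class labels.
#' @param k Number of folds; every class must have at least `k` members.
#' @param seed Optional integer seed for the shuffle.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_kfold <- function(labels, k = 5, seed = NULL) {
  labels <- as.character(labels)
  if (!is.null(seed)) set.seed(seed)
  folds <- integer(length(labels))
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) < k)
      stop("class '", g, "' has fewer than k = ", k, " samples")
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' One-vs-rest collapse for the designated positive class:
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP). A zero
#' denominator yields `NA` with a message.
#'
#' @param confusion Square table/matrix of counts, rows = truth, columns =
#'   predicted, identical dimnames.
#' @param positive Positive class (default `"LC"`).
#' @return Named vector `(sensitivity, specificity, accuracy)` in percent.
#' @export
metrics_from_confusion <- function(confusion, positive = "LC") {
  cm <- as.matrix(confusion)
  if (any(cm < 0)) stop("confusion counts must be non-negative")
  stopifnot(positive %in% rownames(cm))
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  div <- function(num, den) if (den == 0) {
    message("undefined metric: zero denominator"); NA_real_
  } else 100 * num / den
  c(sensitivity = div(tp, tp + fn),
    specificity = div(tn, tn + fp),
    accuracy = div(sum(diag(cm)), sum(cm)))
}

new_cv_report <- function(repeat_acc, fold_acc, confusion, meta) {
  structure(list(mean = mean(repeat_acc), max = max(repeat_acc),
                 min = min(repeat_acc), sd = stats::sd(repeat_acc),
                 repeat_accuracy = repeat_acc, fold_accuracy = fold_acc,
                 confusion = confusion,
                 metrics = metrics_from_confusion(confusion), meta = meta),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Cross-validation report")
  if (!is.null(x$meta$label)) cat(" [", x$meta$label, "]", sep = "")
  cat("\n  accuracy: mean ", sprintf("%.2f", x$mean),
      "  max ", sprintf("%.2f", x$max), "  min ", sprintf("%.2f", x$min),
      "  sd ", sprintf("%.2f", if (is.na(x$sd)) 0 else x$sd), "\n", sep = "")
  cat("  LC sensitivity ", sprintf("%.2f%%", x$metrics["sensitivity"]),
      ", specificity ", sprintf("%.2f%%", x$metrics["specificity"]),
      "\n", sep = "")
  invisible(x)
}

#' Repeated cross-validated evaluation of the fuzzy-logic classifier
#'
#' Runs the full protocol: for each of `repeats` shuffles of a stratified
#' `k`-fold assignment, and for each fold, the LDA projection (when the
#' input has more than two columns) and the fuzzy system are fitted on the
#' training folds only and evaluated once on the held-out fold. Per-repeat
#' accuracy is the mean over its folds; the summary mean/max/min/sd are
#' taken over the repeat means (set `aggregate = "fold"` to aggregate over
#' all `k * repeats` fold accuracies instead). `transductive = TRUE`
#' reproduces the alternative order in which the projection is fitted on
#' the full matrix before splitting; it leaks test information into the
#' projection and is off by default.
#'
#' @param x A `feature_matrix` or numeric matrix.
#' @param labels Class labels; defaults to those of a `feature_matrix`.
#' @param family Membership-function family.
#' @param optimizer An [opt_spec()]; its seed is re-derived per repeat/fold
#'   so every fold's tuning run is independent but reproducible.
#' @param k Folds (default 5).
#' @param repeats Protocol repetitions (default 10).
#' @param seed Master seed for fold shuffles and tuning runs.
#' @param aggregate `"repeat"` (default) or `"fold"`.
#' @param transductive Fit the projection before splitting (default FALSE).
#' @param rules Optional fixed `rule_base`.
#' @return A `cv_report`.
#' @export
run_fl_protocol <- function(x, labels = NULL, family = "gbell",
                            optimizer = opt_spec("GA"), k = 5, repeats = 10,
                            seed = 1, aggregate = c("repeat", "fold"),
                            transductive = FALSE, rules = NULL) {
  aggregate <- match.arg(aggregate)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  labels <- factor(as.character(labels), levels = CLASS_LEVELS)
  xm <- as_matrix_x(x)
  if (transductive && ncol(xm) > 2)
    xm <- predict(fit_lda(xm, labels), xm)
  fold_acc <- matrix(NA_real_, repeats, k)
  confusion <- matrix(0L, 3, 3,
                      dimnames = list(truth = CLASS_LEVELS,
                                      predicted = CLASS_LEVELS))
  for (r in seq_len(repeats)) {
    folds <- stratified_kfold(labels, k, seed = seed + 7919L * r)
    for (f in seq_len(k)) {
      tr <- folds != f
      xtr <- xm[tr, , drop = FALSE]; xte <- xm[!tr, , drop = FALSE]
      if (ncol(xm) > 2) {
        proj <- fit_lda(xtr, labels[tr])
        xtr <- predict(proj, xtr); xte <- predict(proj, xte)
      }
      spec_rf <- optimizer
      spec_rf$seed <- (if (is.null(optimizer$seed)) seed else optimizer$seed) +
        1000L * r + f
      tuned <- tune_fuzzy_model(xtr, labels[tr], family, spec_rf, rules)
      res <- classify_batch(tuned$system, xte, labels[!tr])
      fold_acc[r, f] <- res$accuracy
      confusion <- confusion + unclass(res$confusion)
    }
  }
  acc <- if (aggregate == "repeat") rowMeans(fold_acc) else as.vector(fold_acc)
  new_cv_report(acc, fold_acc, confusion,
                meta = list(label = paste0("FL-", family, "-",
                                           optimizer$method),
                            k = k, repeats = repeats, seed = seed,
                            family = family, optimizer = optimizer$method,
                            aggregate = aggregate,
                            transductive = transductive))
}

# One train/test evaluation of a named baseline classifier; returns the
# factor of predictions for the test rows.
baseline_predict <- function(classifier, xtr, ytr, xte, settings) {
  dtr <- data.frame(y = ytr, xtr, check.names = FALSE)
  dte <- data.frame(xte, check.names = FALSE)
  switch(classifier,
    DT = {
      fit <- rpart::rpart(y ~ ., dtr, method = "class",
                          control = rpart::rpart.control(
                            minsplit = settings$dt_minsplit))
      predict(fit, dte, type = "class")
    },
    `L-SVM` = predict(e1071::svm(y ~ ., dtr, kernel = "linear",
                                 cost = settings$svm_cost, scale = TRUE), dte),
    `Q-SVM` = predict(e1071::svm(y ~ ., dtr, kernel = "polynomial",
                                 degree = 2, coef0 = 1,
                                 cost = settings$svm_cost, scale = TRUE), dte),
    `C-SVM` = predict(e1071::svm(y ~ ., dtr, kernel = "polynomial",
                                 degree = 3, coef0 = 1,
                                 cost = settings$svm_cost, scale = TRUE), dte),
    `k-NN` = class::knn(scale(xtr),
                        scale(xte, center = attr(scale(xtr), "scaled:center"),
                              scale = attr(scale(xtr), "scaled:scale")),
                        ytr, k = settings$knn_k),
    RF = predict(randomForest::randomForest(xtr, ytr,
                                            ntree = settings$rf_ntree), xte),
    stop("unknown classifier '", classifier, "'"))
}

#' Baseline hyperparameter settings
#'
#' Fixed, documented defaults for the comparison classifiers: k-NN with
#' k = 5 on standardized features, SVMs at cost 1, random forests with 200
#' trees, decision trees with minsplit 10.
#'
#' @param knn_k,svm_cost,rf_ntree,dt_minsplit Overrides.
#' @return Named list of settings.
#' @export
baseline_settings <- function(knn_k = 5, svm_cost = 1, rf_ntree = 200,
                              dt_minsplit = 10) {
  list(knn_k = knn_k, svm_cost = svm_cost, rf_ntree = rf_ntree,
       dt_minsplit = dt_minsplit)
}

#' Cross-validated baselines over a set of feature matrices
#'
#' Evaluates the conventional classifiers (decision tree, linear/quadratic/
#' cubic SVM, k-nearest neighbours, random forest) on each named feature
#' matrix under the same stratified `k`-fold x `repeats` protocol as the
#' fuzzy classifier. These are comparison baselines and use the standard
#' implementations (rpart, e1071, class, randomForest).
#'
#' @param feature_sets Named list of `feature_matrix` objects sharing labels.
#' @param classifiers Subset of
#'   `c("DT", "L-SVM", "Q-SVM", "C-SVM", "k-NN", "RF")`.
#' @param k,repeats,seed Protocol settings.
#' @param settings A [baseline_settings()] list.
#' @return Object of class `baseline_table`: list of `cv_report`s indexed
#'   `[[feature_set]][[classifier]]`, printed as a mean (max-min-sd) table
#'   with one row per feature matrix.
#' @export
run_baselines <- function(feature_sets,
                          classifiers = c("DT", "L-SVM", "Q-SVM", "C-SVM",
                                          "k-NN", "RF"),
                          k = 5, repeats = 10, seed = 1,
                          settings = baseline_settings()) {
  stopifnot(is.list(feature_sets), length(feature_sets) > 0,
            !is.null(names(feature_sets)))
  lab0 <- feature_sets[[1]]$labels
  for (fs in feature_sets)
    if (!identical(as.character(fs$labels), as.character(lab0)))
      stop("feature matrices carry different labels")
  labels <- factor(as.character(lab0), levels = CLASS_LEVELS)
  reports <- lapply(names(feature_sets), function(fname) {
    xm <- as_matrix_x(feature_sets[[fname]])
    if (nrow(xm) == 0L || ncol(xm) == 0L) stop("empty feature matrix")
    per_clf <- lapply(classifiers, function(clf) {
      fold_acc <- matrix(NA_real_, repeats, k)
      confusion <- matrix(0L, 3, 3,
                          dimnames = list(truth = CLASS_LEVELS,
                                          predicted = CLASS_LEVELS))
      for (r in seq_len(repeats)) {
        folds <- stratified_kfold(labels, k, seed = seed + 7919L * r)
        for (f in seq_len(k)) {
          tr <- folds != f
          set.seed(seed + 104729L * r + f)   # stochastic fitters (RF)
          pred <- baseline_predict(clf, xm[tr, , drop = FALSE], labels[tr],
                                   xm[!tr, , drop = FALSE], settings)
          pred <- factor(as.character(pred), levels = CLASS_LEVELS)
          fold_acc[r, f] <- 100 * mean(pred == labels[!tr])
          confusion <- confusion +
            unclass(table(truth = labels[!tr], predicted = pred))
        }
      }
      new_cv_report(rowMeans(fold_acc), fold_acc, confusion,
                    meta = list(label = paste(fname, clf), k = k,
                                repeats = repeats, seed = seed))
    })
    names(per_clf) <- classifiers
    per_clf
  })
  names(reports) <- names(feature_sets)
  structure(list(reports = reports, classifiers = classifiers),
            class = "baseline_table")
}

#' @export
print.baseline_table <- function(x, ...) {
  cell <- function(rep) sprintf("%.2f (%.2f-%.2f-%.2f)", rep$mean, rep$max,
                                rep$min, if (is.na(rep$sd)) 0 else rep$sd)
  tab <- do.call(rbind, lapply(x$reports, function(row)
    vapply(row, cell, character(1))))
  cat("Baseline accuracies, mean (max-min-sd) %:\n")
  print(tab, quote = FALSE)
  invisible(x)
}
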