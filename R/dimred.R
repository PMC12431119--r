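## Dimension reduction: PCA with an explained-information threshold, and
## Fisher linear discriminant analysis. For a 3-class problem LDA yields at
## most 2 discriminants; the fuzzy classifier operates on that (LD1, LD2)
## plane.

as_matrix_x <- function(x) {
  if (inherits(x, "feature_matrix")) x$x else as.matrix(x)
}

# Deterministic sign convention: make each component's largest-magnitude
# loading positive.
fix_signs <- function(components) {
  for (j in seq_len(ncol(components))) {
    i <- which.max(abs(components[, j]))
    if (components[i, j] < 0) components[, j] <- -components[, j]
  }
  components
}

#' Principal component projection retaining a fraction of the variance
#'
#' Fits PCA (centred, unscaled) and retains the smallest number of leading
#' components whose cumulative explained-variance fraction reaches
#' `threshold` (default 0.90, i.e. at least 90% of the information in the
#' original matrix).
#'
#' @param x A `feature_matrix` or numeric matrix (rows = experiments).
#' @param threshold Fraction in (0, 1].
#' @return An object of class `projection` with fields `kind`, `mean`,
#'   `components` (features x k, orthonormal), `explained` (all variance
#'   fractions) and `k`.
#' @export
fit_pca <- function(x, threshold = 0.90) {
  xm <- as_matrix_x(x)
  if (nrow(xm) < 2L) stop("need at least 2 samples")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  p <- stats::prcomp(xm, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot == 0) stop("constant feature matrix: zero total variance")
  frac <- p$sdev^2 / tot
  k <- which(cumsum(frac) >= threshold - 1e-12)[1]
  structure(list(kind = "PCA", mean = p$center,
                 components = fix_signs(p$rotation[, seq_len(k), drop = FALSE]),
                 explained = frac, k = k),
            class = "projection")
}

#' Fisher linear discriminant projection
#'
#' Computes Fisher discriminant directions maximizing between-class over
#' within-class scatter. The number of components is at most
#' `min(classes - 1, features)` (2 for the three breath classes). The
#' within-class scatter matrix is regularized by adding
#' `lambda * I` with `lambda = 1e-6 * trace / dim` when it is singular.
#'
#' @param x A `feature_matrix` or numeric matrix.
#' @param labels Class labels (factor or character); every class needs at
#'   least 2 samples. Defaults to the labels carried by a `feature_matrix`.
#' @return An object of class `projection`; `explained` holds the eigenvalue
#'   fractions of the retained discriminants.
#' @export
fit_lda <- function(x, labels = NULL) {
  xm <- as_matrix_x(x)
  if (is.null(labels) && inherits(x, "feature_matrix")) labels <- x$labels
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("need at least 2 classes")
  if (any(table(labels) < 2L)) stop("every class needs at least 2 samples")
  d <- ncol(xm)
  mu <- colMeans(xm)
  Sw <- matrix(0, d, d)
  Sb <- matrix(0, d, d)
  for (g in levels(labels)) {
    xg <- xm[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    cg <- sweep(xg, 2, mg)
    Sw <- Sw + crossprod(cg)
    Sb <- Sb + nrow(xg) * tcrossprod(mg - mu)
  }
  lambda <- 1e-6 * sum(diag(Sw)) / d
  if (lambda <= 0) lambda <- 1e-12
  ok <- tryCatch({solve(Sw); TRUE}, error = function(e) FALSE)
  if (!ok || rcond(Sw) < 1e-12) Sw <- Sw + lambda * diag(d)
  M <- solve(Sw, Sb)
  e <- eigen(M)
  vals <- Re(e$values)
  vecs <- Re(e$vectors)
  k <- min(nlevels(labels) - 1L, d)
  ord <- order(vals, decreasing = TRUE)[seq_len(k)]
  comps <- vecs[, ord, drop = FALSE]
  comps <- sweep(comps, 2, sqrt(colSums(comps^2)), "/")
  comps <- fix_signs(comps)
  rownames(comps) <- colnames(xm)
  colnames(comps) <- paste0("LD", seq_len(k))
  vals_k <- pmax(vals[ord], 0)
  structure(list(kind = "LDA", mean = mu, components = comps,
                 explained = if (sum(pmax(vals, 0)) > 0)
                   vals_k / sum(pmax(vals, 0)) else rep(0, k),
                 k = k),
            class = "projection")
}

#' Apply a fitted projection to new data
#'
#' Centres rows with the training mean and multiplies by the component
#' matrix. Deterministic row-wise affine map.
#'
#' @param object A `projection` from [fit_pca()] or [fit_lda()].
#' @param newdata A `feature_matrix` or numeric matrix with the same feature
#'   dimension as the training data.
#' @param ... Unused.
#' @return A numeric matrix with `object$k` columns.
#' @export
predict.projection <- function(object, newdata, ...) {
  xm <- as_matrix_x(newdata)
  if (is.null(dim(xm))) xm <- matrix(xm, nrow = 1)
  if (ncol(xm) != length(object$mean))
    stop("feature dimension mismatch: got ", ncol(xm), ", expected ",
         length(object$mean))
  sweep(xm, 2, object$mean) %*% object$components
}

#' @export
print.projection <- function(x, ...) {
  cat(x$kind, "projection:", length(x$mean), "->", x$k, "dimensions\n")
  cat("explained fractions:",
      paste(signif(x$explained[seq_len(min(5, length(x$explained)))], 3),
            collapse = " "), "\n")
  invisible(x)
}
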