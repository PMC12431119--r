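## The 7x7 fuzzy rule base over the (LD1, LD2) plane. Each axis carries
## seven fuzzy sets labelled O1, O2 (healthy smoker region), +1, +2
## (healthy non-smoker region) and D1, D2, D3 (lung cancer region); each of
## the 49 (LD1 set, LD2 set) cells maps to a consequent class.

FL_SET_LABELS <- c("O1", "O2", "+1", "+2", "D1", "D2", "D3")

# symbol -> class for rule tables written with O / + / D (diamond) marks
SYMBOL_CLASS <- c("O" = "HS", "+" = "HnS", "D" = "LC")

# Number of fuzzy sets each class contributes per axis
CLASS_MF_COUNT <- c(HS = 2L, HnS = 2L, LC = 3L)

#' Construct a rule base
#'
#' @param grid 7x7 character matrix of consequent classes (`"LC"`, `"HnS"`,
#'   `"HS"`), rows indexed by the LD1 fuzzy set, columns by the LD2 fuzzy
#'   set, dimnames `FL_SET_LABELS`. Symbol marks `O`, `+`, `D` are also
#'   accepted and translated.
#' @return An object of class `rule_base` holding the fully populated 49-rule
#'   grid.
#' @export
rule_base <- function(grid) {
  grid <- as.matrix(grid)
  if (!identical(dim(grid), c(7L, 7L))) stop("rule grid must be 7x7")
  if (anyNA(grid)) stop("rule grid has missing cells")
  if (all(grid %in% names(SYMBOL_CLASS))) {
    grid[] <- SYMBOL_CLASS[grid]
  }
  if (!all(grid %in% CLASS_LEVELS))
    stop("rule consequents must be LC, HnS or HS (or O/+/D symbols)")
  dimnames(grid) <- list(LD1 = FL_SET_LABELS, LD2 = FL_SET_LABELS)
  structure(list(grid = grid), class = "rule_base")
}

#' The default expert rule base
#'
#' Loads the bundled 49-rule table used for classification on the (LD1, LD2)
#' plane. On disk the table is laid out with rows = LD2 sets and columns =
#' LD1 sets, written with the symbols O (healthy smoker), + (healthy
#' non-smoker) and D (lung cancer); for example the cell (LD1 = O2,
#' LD2 = +1) carries consequent "+" (HnS).
#'
#' @param path Optional path to a rule CSV in the same layout.
#' @return A `rule_base`.
#' @export
default_rule_base <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rule_table.csv", package = "enosefl")
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- d[[1]]
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- rn
  if (!setequal(rownames(m), FL_SET_LABELS) ||
      !setequal(colnames(m), FL_SET_LABELS))
    stop("rule CSV must be indexed by the seven set labels on both axes")
  # CSV rows are LD2 sets, columns LD1 sets; internal grid is [LD1, LD2]
  rule_base(t(m[FL_SET_LABELS, FL_SET_LABELS]))
}

#' Build a rule base from training data
#'
#' Assigns each training point to the cell selected by its maximal
#' membership on each axis, then gives every cell the majority class among
#' its points (ties broken by `tie_break`). Cells containing no training
#' points inherit the consequent of the nearest occupied cell, measured
#' between cell centres (the pair of MF peak locations) in the LD plane.
#'
#' @param points n x 2 matrix of (LD1, LD2) coordinates.
#' @param labels Class labels of the points.
#' @param mfs_ld1,mfs_ld2 Lists of 7 `memfun`s per axis.
#' @param tie_break Class order used to break majority ties (first wins).
#' @return A `rule_base`.
#' @export
rule_base_from_data <- function(points, labels, mfs_ld1, mfs_ld2,
                                tie_break = c("LC", "HnS", "HS")) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, length(mfs_ld1) == 7, length(mfs_ld2) == 7)
  labels <- as.character(labels)
  m1 <- mf_matrix(mfs_ld1, points[, 1])
  m2 <- mf_matrix(mfs_ld2, points[, 2])
  cell1 <- max.col(m1, ties.method = "first")
  cell2 <- max.col(m2, ties.method = "first")
  grid <- matrix(NA_character_, 7, 7,
                 dimnames = list(LD1 = FL_SET_LABELS, LD2 = FL_SET_LABELS))
  counts <- array(0L, dim = c(7, 7, length(tie_break)),
                  dimnames = list(NULL, NULL, tie_break))
  for (n in seq_len(nrow(points)))
    counts[cell1[n], cell2[n], labels[n]] <-
      counts[cell1[n], cell2[n], labels[n]] + 1L
  c1 <- vapply(mfs_ld1, mf_center, numeric(1))
  c2 <- vapply(mfs_ld2, mf_center, numeric(1))
  occupied <- which(apply(counts, c(1, 2), sum) > 0, arr.ind = TRUE)
  if (nrow(occupied) == 0L) stop("no training points")
  for (i in 1:7) for (j in 1:7) {
    k <- counts[i, j, ]
    if (sum(k) > 0L) {
      grid[i, j] <- tie_break[which.max(k)]  # which.max: first max wins
    } else {
      dd <- (c1[occupied[, 1]] - c1[i])^2 + (c2[occupied[, 2]] - c2[j])^2
      near <- occupied[which.min(dd), ]
      kk <- counts[near[1], near[2], ]
      grid[i, j] <- tie_break[which.max(kk)]
    }
  }
  rule_base(grid)
}

#' @export
print.rule_base <- function(x, ...) {
  cat("Fuzzy rule base: 7 x 7 grid, 49 rules (rows LD1, cols LD2)\n")
  print(x$grid)
  invisible(x)
}
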