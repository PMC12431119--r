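## Equal-partition initialization of the membership functions.
## Each class occupies a region of each axis (the min-max span of its
## training points); that region is split into as many equal sub-intervals
## as the class has fuzzy sets (HS and HnS: 2, LC: 3), and one MF is centred
## on each sub-interval with a width parameter spanning it.

# Build one MF of the requested family centred at `center`, where `w` is the
# sub-interval width. Finite-support families extend one full sub-interval
# either side of the centre so neighbouring sets overlap.
mf_from_partition <- function(family, center, w, label) {
  if (w <= 0) stop("degenerate (zero-width) class region")
  switch(family,
    gaussian = mf("gaussian", c(center, w / 2), label),
    gbell = mf("gbell", c(w / 2, 2, center), label),
    triangular = mf("triangular", c(center - w, center, center + w), label),
    trapezoidal = mf("trapezoidal",
                     c(center - w, center - w / 4, center + w / 4, center + w),
                     label),
    pi = mf("pi",
            c(center - w, center - w / 4, center + w / 4, center + w), label))
}

# Centers of `m` equal sub-intervals of [lo, hi], plus the common width
partition_axis <- function(lo, hi, m) {
  w <- (hi - lo) / m
  list(centers = lo + w * (seq_len(m) - 0.5), width = w)
}

#' Initialize a fuzzy classifier by equal partition of the class regions
#'
#' Derives each class's region on each LD axis from the training scatter
#' (min and max of its points), splits every region into equal parts (two
#' fuzzy sets for HS and HnS, three for LC) and centres one membership
#' function of the chosen family on each part. The rule base is either
#' supplied or learnt from the training points with [rule_base_from_data()].
#'
#' @param points n x 2 matrix of training (LD1, LD2) coordinates.
#' @param labels Training class labels (`LC`, `HnS`, `HS`).
#' @param family Membership-function family.
#' @param rules Optional `rule_base`; default learns it from the data.
#' @param tie_break Class preference order.
#' @return An `fl_system`.
#' @export
init_partition <- function(points, labels, family = "gbell", rules = NULL,
                           tie_break = c("LC", "HnS", "HS")) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  family <- match.arg(family, MF_FAMILIES)
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS)) stop("invalid class labels")
  axis_mfs <- function(axis) {
    mfs <- vector("list", 7)
    idx <- 1L
    for (cls in c("HS", "HnS", "LC")) {  # label order O1,O2,+1,+2,D1,D2,D3
      xs <- points[labels == cls, axis]
      if (length(xs) == 0L) stop("no training points for class ", cls)
      if (diff(range(xs)) <= 0) stop("degenerate (zero-width) region for ",
                                     cls, " on axis ", axis)
      part <- partition_axis(min(xs), max(xs), CLASS_MF_COUNT[[cls]])
      for (c0 in part$centers) {
        mfs[[idx]] <- mf_from_partition(family, c0, part$width,
                                        FL_SET_LABELS[idx])
        idx <- idx + 1L
      }
    }
    mfs
  }
  mfs1 <- axis_mfs(1)
  mfs2 <- axis_mfs(2)
  if (is.null(rules))
    rules <- rule_base_from_data(points, labels, mfs1, mfs2, tie_break)
  fl_system(mfs1, mfs2, rules, tie_break)
}
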