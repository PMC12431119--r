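test_that("membership closed forms match their defining values", {
  g <- mf("gaussian", c(1.5, 0.7))
  expect_equal(mf_value(g, 1.5), 1)
  expect_equal(mf_value(g, 1.5 + 0.7), exp(-0.5))
  b <- mf("gbell", c(2, 3, 1))
  expect_equal(mf_value(b, 1), 1)
  expect_equal(mf_value(b, 1 + 2), 0.5)   # half-width at x = c + a
  expect_equal(mf_value(b, 1 - 2), 0.5)
  tr <- mf("triangular", c(0, 1, 3))
  expect_equal(mf_value(tr, c(-1, 0.5, 1, 2, 3.5)), c(0, 0.5, 1, 0.5, 0))
  tp <- mf("trapezoidal", c(0, 1, 2, 3))
  expect_equal(mf_value(tp, 0.5), 0.5)
  expect_equal(mf_value(tp, c(1, 1.7, 2)), c(1, 1, 1))
  expect_equal(mf_value(tp, 2.25), 0.75)
  p <- mf("pi", c(0, 1, 2, 3))
  expect_equal(mf_value(p, c(1, 1.5, 2)), c(1, 1, 1))
  expect_equal(mf_value(p, 0.25), 2 * 0.25^2)
  expect_equal(mf_value(p, 2.75), 2 * 0.25^2)
})

test_that("invalid membership parameters fail at construction", {
  expect_error(mf("gaussian", c(0, -1)), "sigma")
  expect_error(mf("gbell", c(-1, 2, 0)), "a and b")
  expect_error(mf("triangular", c(2, 1, 3)), "non-decreasing")
  expect_error(mf("trapezoidal", c(0, 1, 2)), "4 parameters")
})

test_that("membership outputs stay in [0,1] across random parameters", {
  set.seed(41)
  xs <- seq(-6, 6, length.out = 400)
  for (fam in c("gaussian", "gbell", "triangular", "trapezoidal", "pi")) {
    for (i in 1:20) {
      m <- random_system(fam)$mfs_ld1[[sample(7, 1)]]
      v <- mf_value(m, xs)
      expect_true(all(v >= 0 & v <= 1))
    }
    # gaussian and gbell never vanish exactly
    if (fam %in% c("gaussian", "gbell")) {
      m <- random_system(fam)$mfs_ld1[[1]]
      expect_true(all(mf_value(m, xs) > 0))
    }
  }
})

test_that("the default rule base holds 49 rules with the worked example", {
  rb <- default_rule_base()
  expect_equal(dim(rb$grid), c(7L, 7L))
  expect_equal(sum(!is.na(rb$grid)), 49)
  # (LD1 = O2, LD2 = +1) -> healthy non-smoker
  expect_equal(unname(rb$grid["O2", "+1"]), "HnS")
  # (O1, O1) -> healthy smoker
  expect_equal(unname(rb$grid["O1", "O1"]), "HS")
  expect_error(rule_base(matrix("O", 6, 7)), "7x7")
})

test_that("an all-LC grid classifies everything as LC", {
  grid <- matrix("LC", 7, 7)
  sys <- random_system("gaussian", rule_base(grid))
  set.seed(42)
  pts <- matrix(runif(60, -3, 3), ncol = 2)
  expect_true(all(fl_infer(sys, pts)$class == "LC"))
})

test_that("majority rule construction reproduces one-point-per-cell labels", {
  # gaussian sets centred on integer grid positions 1..7 per axis
  mk <- function() lapply(1:7, function(i)
    mf("gaussian", c(i, 0.3), c("O1", "O2", "+1", "+2", "D1", "D2", "D3")[i]))
  mfs1 <- mk(); mfs2 <- mk()
  set.seed(43)
  cells <- expand.grid(i = 1:7, j = 1:7)
  truth <- matrix(sample(c("LC", "HnS", "HS"), 49, replace = TRUE), 7, 7)
  pts <- as.matrix(cells)
  labs <- truth[as.matrix(cells)]
  rb <- rule_base_from_data(pts, labs, mfs1, mfs2)
  expect_equal(unname(rb$grid), unname(truth))
})

test_that("inference peaks, ties and batch accuracy behave as contracted", {
  rb <- default_rule_base()
  mk <- function() lapply(1:7, function(i)
    mf("gaussian", c(i, 0.4), c("O1", "O2", "+1", "+2", "D1", "D2", "D3")[i]))
  sys <- fl_system(mk(), mk(), rb)
  # joint peak of the (O1, O1) sets -> HS with score 1
  out <- fl_infer(sys, c(1, 1))
  expect_equal(unname(out$scores[1, "HS"]), 1)
  expect_equal(as.character(out$class), "HS")
  # forced tie: grid half LC half HnS, symmetric point -> tie order wins
  grid <- matrix(c("LC", "HnS")[1 + (row(matrix(0, 7, 7)) %% 2)], 7, 7)
  sys2 <- fl_system(mk(), mk(), rule_base(grid),
                    tie_break = c("HnS", "LC", "HS"))
  midpoint <- c(1.5, 4)  # equidistant between two adjacent LD1 sets
  o2 <- fl_infer(sys2, matrix(midpoint, 1))
  expect_equal(unname(o2$scores[1, "LC"]), unname(o2$scores[1, "HnS"]))
  expect_equal(as.character(o2$class), "HnS")
  # batch accuracy bookkeeping
  pts <- rbind(c(1, 1), c(2, 2), c(5, 5))
  pred <- fl_infer(sys, pts)$class
  cb <- classify_batch(sys, pts, truth = pred)
  expect_equal(cb$accuracy, 100)
  single <- classify_batch(sys, matrix(c(1, 1), 1), truth = "LC")
  expect_true(single$accuracy %in% c(0, 100))
  expect_error(classify_batch(sys, matrix(numeric(0), ncol = 2)), "empty")
  expect_error(fl_infer(sys, c(NA, 1)), "finite")
})

test_that("batch inference matches the brute-force 49-rule oracle", {
  set.seed(44)
  for (fam in c("gaussian", "gbell", "triangular", "trapezoidal", "pi")) {
    sys <- random_system(fam)
    pts <- cbind(runif(300, -4, 4), runif(300, -4, 4))
    fast <- as.character(fl_infer(sys, pts)$class)
    slow <- vapply(seq_len(nrow(pts)), function(n)
      oracle_infer_point(sys, pts[n, 1], pts[n, 2]), character(1))
    expect_identical(fast, slow)
  }
})

test_that("inference is invariant to rule enumeration order", {
  set.seed(45)
  sys <- random_system("gbell")
  pts <- cbind(runif(100, -4, 4), runif(100, -4, 4))
  ref <- fl_infer(sys, pts)
  # permute both axes' sets together with the grid: same rule set
  perm <- sample(7)
  relab <- function(mfs) {
    out <- mfs[perm]
    for (i in 1:7) out[[i]]$label <- c("O1", "O2", "+1", "+2",
                                       "D1", "D2", "D3")[i]
    out
  }
  grid2 <- sys$rules$grid[perm, perm]
  dimnames(grid2) <- dimnames(sys$rules$grid)
  sys2 <- fl_system(relab(sys$mfs_ld1), relab(sys$mfs_ld2),
                    rule_base(grid2), sys$tie_break)
  out2 <- fl_infer(sys2, pts)
  expect_equal(unname(ref$scores), unname(out2$scores))
})

test_that("equal partition places MF centres at sub-interval midpoints", {
  # HS spans [0,2] and [10,12]; HnS [4,6]; LC [0,3] and [6,9] on the axes
  pts <- rbind(c(0, 10), c(2, 12),         # HS
               c(4, 4), c(6, 6),           # HnS
               c(0, 6), c(1.5, 7.5), c(3, 9))  # LC
  labs <- c("HS", "HS", "HnS", "HnS", "LC", "LC", "LC")
  sys <- init_partition(pts, labs, family = "gaussian")
  centers1 <- vapply(sys$mfs_ld1, function(m) m$params[1], numeric(1))
  expect_equal(unname(centers1[1:2]), c(0.5, 1.5))   # O1, O2 on [0,2]
  expect_equal(unname(centers1[3:4]), c(4.5, 5.5))   # +1, +2 on [4,6]
  expect_equal(unname(centers1[5:7]), c(0.5, 1.5, 2.5))  # D1-D3 on [0,3]
  centers2 <- vapply(sys$mfs_ld2, function(m) m$params[1], numeric(1))
  expect_equal(unname(centers2[1:2]), c(10.5, 11.5))
  expect_equal(unname(centers2[5:7]), c(6.5, 7.5, 8.5))
  # degenerate class region errors
  expect_error(init_partition(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1),
                                    c(2, 0), c(2, 1)),
                              c("HS", "HS", "HnS", "HnS", "LC", "LC")),
               "degenerate")
})

test_that("the initial model classifies well-separated class centroids", {
  set.seed(46)
  centres <- rbind(LC = c(0, 0), HnS = c(6, 0), HS = c(0, 6))
  pts <- do.call(rbind, lapply(rownames(centres), function(g)
    sweep(matrix(rnorm(40, sd = 0.5), 20, 2), 2, centres[g, ], "+")))
  labs <- rep(rownames(centres), each = 20)
  for (fam in c("gaussian", "gbell", "triangular")) {
    sys <- init_partition(pts, labs, family = fam)
    pred <- fl_infer(sys, centres)$class
    expect_equal(as.character(pred), rownames(centres))
  }
})

test_that("fuzzy system JSON serialization round-trips", {
  set.seed(47)
  sys <- random_system("trapezoidal")
  path <- withr::local_tempfile(fileext = ".json")
  write_fl_json(sys, path)
  back <- read_fl_json(path)
  pts <- cbind(runif(50, -4, 4), runif(50, -4, 4))
  expect_equal(fl_infer(back, pts)$scores, fl_infer(sys, pts)$scores)
  expect_identical(back$rules$grid, sys$rules$grid)
})
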