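test_that("stratified folds partition the data with balanced class counts", {
  labs <- rep(c("LC", "HS"), each = 5)
  f <- stratified_kfold(labs, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & labs == "LC"), 1)
    expect_equal(sum(f == k & labs == "HS"), 1)
  }
  # the study's cohort: per-fold LC counts are 43 or 44
  labs338 <- rep(c("LC", "HnS", "HS"), times = c(219, 60, 59))
  f5 <- stratified_kfold(labs338, k = 5, seed = 2)
  expect_equal(length(f5), 338)
  expect_equal(tabulate(f5, 5), as.vector(table(f5)))
  lc_counts <- vapply(1:5, function(k) sum(f5 == k & labs338 == "LC"),
                      integer(1))
  expect_true(all(lc_counts %in% c(43L, 44L)))
  expect_equal(sum(lc_counts), 219)
  expect_error(stratified_kfold(c("LC", "LC", "HS"), k = 2), "fewer than")
  # depends only on labels and seed
  expect_equal(stratified_kfold(labs338, 5, seed = 9),
               stratified_kfold(labs338, 5, seed = 9))
})

test_that("confusion-matrix metrics match hand arithmetic", {
  cm <- matrix(c(10, 0, 0, 0, 20, 0, 0, 0, 30), 3,
               dimnames = list(c("LC", "HnS", "HS"), c("LC", "HnS", "HS")))
  m <- metrics_from_confusion(cm)
  expect_equal(unname(m), c(100, 100, 100))
  cm2 <- matrix(c(50, 10, 5, 100), 2, byrow = TRUE,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m2 <- metrics_from_confusion(cm2, positive = "pos")
  expect_equal(unname(m2["sensitivity"]), 100 * 50 / 60, tolerance = 1e-10)
  expect_equal(unname(m2["specificity"]), 100 * 100 / 105, tolerance = 1e-10)
  # swapping the positive class swaps sensitivity and specificity
  m3 <- metrics_from_confusion(cm2, positive = "neg")
  expect_equal(unname(m3["sensitivity"]), unname(m2["specificity"]))
  expect_equal(unname(m3["specificity"]), unname(m2["sensitivity"]))
  cm0 <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE,
                dimnames = list(c("pos", "neg"), c("pos", "neg")))
  expect_message(m0 <- metrics_from_confusion(cm0, positive = "pos"),
                 "zero denominator")
  expect_true(is.na(m0["sensitivity"]))
})

fast_opt <- function(seed = NULL) opt_spec("PSO", pop_size = 10,
                                           max_iter = 10, seed = seed)

test_that("a perfectly separated fixture scores 100% across the protocol", {
  feats <- separable_fixture()
  rep <- run_fl_protocol(feats, family = "gbell", optimizer = fast_opt(),
                         k = 5, repeats = 2, seed = 5)
  expect_equal(rep$mean, 100)
  expect_equal(rep$max, 100)
  expect_equal(rep$min, 100)
  expect_equal(rep$sd, 0)
  expect_true(all(rep$confusion[row(rep$confusion) != col(rep$confusion)] == 0))
})

test_that("protocol accounting: means, confusion sums and determinism", {
  ds <- tiny_dataset(c(LC = 10, HnS = 8, HS = 8), seed = 23)
  feats <- hybrid_features(ds)
  r1 <- run_fl_protocol(feats, family = "triangular",
                        optimizer = fast_opt(), k = 2, repeats = 2, seed = 3)
  expect_equal(r1$mean, mean(r1$repeat_accuracy))
  expect_equal(r1$repeat_accuracy, rowMeans(r1$fold_accuracy))
  expect_true(r1$min <= r1$mean && r1$mean <= r1$max)
  # confusion row sums equal per-class totals across all repeat evaluations
  expect_equal(unname(rowSums(r1$confusion)),
               2 * as.vector(table(feats$labels)))
  r2 <- run_fl_protocol(feats, family = "triangular",
                        optimizer = fast_opt(), k = 2, repeats = 2, seed = 3)
  expect_identical(r1, r2)
  # fold-level aggregation uses all k * repeats accuracies
  r3 <- run_fl_protocol(feats, family = "triangular",
                        optimizer = fast_opt(), k = 2, repeats = 2, seed = 3,
                        aggregate = "fold")
  expect_length(r3$repeat_accuracy, 4)
  expect_equal(mean(r3$repeat_accuracy), r1$mean)
})

test_that("two-fold protocol equals a hand-rolled run of its documented steps", {
  feats <- separable_fixture()
  labels <- feats$labels
  seed <- 17
  rep <- run_fl_protocol(feats, family = "gaussian",
                         optimizer = fast_opt(), k = 2, repeats = 1,
                         seed = seed)
  folds <- stratified_kfold(labels, 2, seed = seed + 7919L)
  acc <- vapply(1:2, function(f) {
    tr <- folds != f
    proj <- fit_lda(feats$x[tr, ], labels[tr])
    xtr <- predict(proj, feats$x[tr, ])
    xte <- predict(proj, feats$x[!tr, ])
    tuned <- tune_fuzzy_model(xtr, labels[tr], "gaussian",
                              fast_opt(seed = seed + 1000L + f))
    classify_batch(tuned$system, xte, labels[!tr])$accuracy
  }, numeric(1))
  expect_equal(as.vector(rep$fold_accuracy), acc)
  expect_equal(rep$mean, mean(acc))
})

test_that("baselines reach 100% on separable data and chance on shuffled labels", {
  feats <- separable_fixture()
  sets <- list(hybrid = feats)
  tab <- run_baselines(sets, classifiers = c("DT", "L-SVM", "k-NN", "RF"),
                       k = 3, repeats = 1, seed = 4)
  for (clf in c("DT", "L-SVM", "k-NN", "RF"))
    expect_gte(tab$reports$hybrid[[clf]]$mean, 95)
  # shuffled labels: nothing to learn
  sh <- feats
  set.seed(6)
  sh$labels <- factor(sample(as.character(feats$labels)),
                      levels = levels(feats$labels))
  tab2 <- run_baselines(list(hybrid = sh), classifiers = c("k-NN", "DT"),
                        k = 3, repeats = 1, seed = 4)
  for (clf in c("k-NN", "DT")) {
    expect_lt(tab2$reports$hybrid[[clf]]$mean, 65)
  }
  # one row per feature-set variant in the printed table
  out <- utils::capture.output(print(tab))
  expect_true(any(grepl("hybrid", out)))
})

test_that("the fitted model object supports the standard S3 interface", {
  feats <- separable_fixture()
  fit <- fl_fit(feats, family = "gbell", optimizer = fast_opt(seed = 1))
  expect_s3_class(fit, "fl_model")
  expect_output(print(fit), "training accuracy")
  co <- coef(fit)
  expect_equal(dim(co), c(14L, 3L))
  pred <- predict(fit, feats)
  expect_equal(length(pred), nrow(feats$x))
  expect_gte(100 * mean(pred == feats$labels), 99)
  sc <- predict(fit, feats, type = "scores")
  expect_equal(dim(sc), c(nrow(feats$x), 3L))
  # prediction accepts LD-plane coordinates directly
  p2 <- predict(fit, fit$train_scores)
  expect_equal(as.character(p2), as.character(pred))
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path, width = 900, height = 300)
  plot(fit)
  grDevices::dev.off()
  expect_true(file.exists(path))
})
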