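test_that("summary statistics match hand-computed population moments", {
  t <- 0:4
  st <- summary_stats(c(1, 2, 3, 4, 5), t, c(0, 4))
  expect_equal(unname(st["mean"]), 3)
  expect_equal(unname(st["var"]), 2)         # population variance
  expect_equal(unname(st["skewness"]), 0)
  expect_equal(unname(st["kurtosis"]), 6.8 / 4 - 3)  # excess, population
  expect_equal(unname(st["max"]), 5)
  # degenerate window convention
  stc <- summary_stats(rep(7, 10), 0:9, c(0, 9))
  expect_equal(unname(stc[c("var", "skewness", "kurtosis")]), c(0, 0, 0))
  # order statistic
  set.seed(2)
  x <- rnorm(50)
  s <- summary_stats(x, seq_along(x), c(1, 50))
  expect_gte(s[["max"]], s[["mean"]])
  expect_error(summary_stats(1:3, 1:3, c(1, 3)), "4 samples")
})

test_that("slope equals the OLS fit and handles exact lines", {
  t <- seq(0, 20, by = 0.5)
  expect_equal(slope(2 * t + 1, t, c(0, 20)), 2)
  expect_equal(slope(rep(5, length(t)), t, c(0, 20)), 0)
  set.seed(9)
  y <- 1.7 * t + rnorm(length(t), 0, 0.3)
  fit <- stats::lm(y ~ t)  # independent regression oracle
  expect_equal(slope(y, t, c(0, 20)), unname(coef(fit)[2]), tolerance = 1e-10)
  se <- summary(fit)$coefficients[2, 2]
  expect_lt(abs(slope(y, t, c(0, 20)) - 1.7), 3 * se)
})

test_that("areas follow the trapezoid rule and analytic integrals", {
  t <- seq(0, 50, by = 0.5)
  a <- rep(2, length(t)); b <- rep(1, length(t))
  expect_equal(area_between(a, a, t, c(0, 50)), 0)
  expect_equal(area_between(a, b, t, c(5, 45)), 40)
  expect_equal(area_between(b, a, t, c(5, 45)), -40)  # antisymmetry
  t2 <- seq(0, 10, by = 0.01)
  expect_equal(area_between(t2, rep(0, length(t2)), t2, c(0, 10)), 50)
  ts <- seq(0, pi, length.out = 2001)
  expect_equal(area_under(sin(ts), ts, c(0, pi)), 2, tolerance = 1e-5)
  expect_equal(area_under(rep(2, 71), 0:70, c(0, 70)), 140)
})

test_that("feature matrices have the contracted 91/7/98 shapes", {
  ds <- tiny_dataset(c(LC = 3, HnS = 2, HS = 2), seed = 13)
  mos <- build_mos_features(ds)
  qcm <- build_qcm_features(ds)
  hyb <- concat_features(mos, qcm)
  expect_equal(ncol(mos$x), 91)
  expect_equal(ncol(qcm$x), 7)
  expect_equal(ncol(hyb$x), 98)
  expect_equal(nrow(hyb$x), 7)
  expect_false(anyDuplicated(colnames(hyb$x)) > 0)
  expect_equal(as.character(hyb$labels), as.character(ds$labels))
})

test_that("one experiment gives one row and rows are independent", {
  ds <- tiny_dataset(c(LC = 3, HnS = 2, HS = 2), seed = 13)
  one <- ds
  one$experiments <- ds$experiments[2]
  one$labels <- ds$labels[2]
  m1 <- build_mos_features(one)
  expect_equal(nrow(m1$x), 1)
  mall <- build_mos_features(ds)
  expect_equal(m1$x[1, ], mall$x[2, ])
  # permuting experiments permutes rows, values unchanged
  perm <- c(3, 1, 2, 5, 4, 7, 6)
  dsp <- ds
  dsp$experiments <- ds$experiments[perm]
  dsp$labels <- ds$labels[perm]
  mp <- build_mos_features(dsp)
  expect_equal(mp$x, mall$x[perm, ])
})

test_that("features are invariant to channels they do not use", {
  ds <- tiny_dataset(c(LC = 1, HnS = 1, HS = 1), seed = 17)
  qcm0 <- build_qcm_features(ds)
  ds2 <- ds
  # perturb a channel unused by the QCM feature set
  ds2$experiments <- lapply(ds$experiments, function(e) {
    e$qcm[, "QCM13"] <- e$qcm[, "QCM13"] + 100
    e
  })
  expect_equal(build_qcm_features(ds2)$x, qcm0$x)
})

test_that("zero channels give zero QCM features and pair swaps flip sign", {
  amp <- default_amplitudes()
  amp[, c("LC", "HnS", "HS")] <- 0
  cfg <- breath_config(n_per_class = c(LC = 1, HnS = 1, HS = 1),
                       amplitudes = amp, noise_sd = c(MOS = 0, QCM = 0),
                       subject_sd = 0, seed = 1)
  ds <- preprocess_dataset(simulate_breath(cfg))
  expect_true(all(build_qcm_features(ds)$x == 0))
  # swapping one area pair flips exactly that column's sign
  ds2 <- tiny_dataset(c(LC = 2, HnS = 2, HS = 2), seed = 19)
  f1 <- build_qcm_features(ds2)
  cfg_swap <- qcm_feature_config(area_pairs = list(c("QCM14", "QCM6"),
                                                   c("QCM2", "QCM11"),
                                                   c("QCM9", "QCM11"),
                                                   c("QCM14", "QCM7")))
  f2 <- build_qcm_features(ds2, cfg_swap)
  expect_equal(unname(f2$x[, 1]), -unname(f1$x[, 1]))
  expect_equal(unname(f2$x[, 2:7]), unname(f1$x[, 2:7]))
})

test_that("concatenation validates alignment and name collisions", {
  ds <- tiny_dataset(c(LC = 2, HnS = 2, HS = 2), seed = 19)
  mos <- build_mos_features(ds)
  qcm <- build_qcm_features(ds)
  expect_error(concat_features(mos, mos), "collision")
  empty <- structure(list(x = mos$x[, 0, drop = FALSE], labels = mos$labels),
                     class = "feature_matrix")
  expect_equal(concat_features(mos, empty)$x, mos$x)
  qcm_bad <- qcm
  rownames(qcm_bad$x) <- rev(rownames(qcm$x))
  expect_error(concat_features(mos, qcm_bad), "misaligned")
})

test_that("zero-noise single-experiment features match independent recomputation", {
  amp <- default_amplitudes()
  cfg <- breath_config(n_per_class = c(LC = 1, HnS = 1, HS = 1),
                       amplitudes = amp, noise_sd = c(MOS = 0, QCM = 0),
                       subject_sd = 0, seed = 1)
  ds <- preprocess_dataset(simulate_breath(cfg))
  e <- ds$experiments[[1]]
  mos <- build_mos_features(ds)
  # slope of TGS813 over 130-145 via lm on the same window
  w <- e$t >= 130 & e$t <= 145
  ref_slope <- unname(coef(stats::lm(e$mos[w, "TGS813"] ~ e$t[w]))[2])
  expect_equal(unname(mos$x[1, "TGS813.slope.130.145"]), ref_slope,
               tolerance = 1e-10)
  # area between TGS826 and TGS832 via summed trapezoids
  w2 <- which(e$t >= 130 & e$t <= 170)
  d <- e$mos[w2, "TGS826"] - e$mos[w2, "TGS832"]
  ref_area <- sum((d[-1] + d[-length(d)]) / 2 * diff(e$t[w2]))
  expect_equal(unname(mos$x[1, "area.TGS826.TGS832"]), ref_area,
               tolerance = 1e-12)
})
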