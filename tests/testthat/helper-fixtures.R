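# Shared fixtures and independent oracles for the test suite.

# Small preprocessed synthetic dataset, memoised per parameter set.
.fixture_cache <- new.env(parent = emptyenv())

tiny_dataset <- function(n = c(LC = 12, HnS = 6, HS = 6), seed = 11, ...) {
  key <- paste(c(n, seed, unlist(list(...))), collapse = "_")
  if (is.null(.fixture_cache[[key]])) {
    cfg <- breath_config(n_per_class = n, seed = seed, ...)
    .fixture_cache[[key]] <- preprocess_dataset(simulate_breath(cfg))
  }
  .fixture_cache[[key]]
}

hybrid_features <- function(ds) {
  concat_features(build_mos_features(ds), build_qcm_features(ds))
}

# The well-separated 3-class fixture used for end-to-end checks: the pinned
# amplitude table at a raised effect size with low noise and low
# between-subject spread, at a fixed seed.
separable_fixture <- function() {
  if (is.null(.fixture_cache[["separable"]])) {
    cfg <- breath_config(n_per_class = c(LC = 50, HnS = 20, HS = 20),
                         effect_size = 1.5,
                         noise_sd = c(MOS = 0.005, QCM = 0.25),
                         subject_sd = 0.03, seed = 42)
    ds <- preprocess_dataset(simulate_breath(cfg))
    .fixture_cache[["separable"]] <- hybrid_features(ds)
  }
  .fixture_cache[["separable"]]
}

## ---- Independent membership-function oracle -------------------------------
## Closed forms re-derived scalar-by-scalar, written independently of the
## package's vectorized implementations.

oracle_mf <- function(family, p, x) {
  if (family == "gaussian") {
    return(exp(-0.5 * ((x - p[1]) / p[2])^2))
  }
  if (family == "gbell") {
    return(1 / (1 + (((x - p[3]) / p[1])^2)^p[2]))
  }
  if (family == "triangular") {
    a <- p[1]; b <- p[2]; c <- p[3]
    if (x <= a || x >= c) {
      if (x == b) return(1)   # degenerate spike
      return(0)
    }
    if (x == b) return(1)
    if (x < b) return((x - a) / (b - a))
    return((c - x) / (c - b))
  }
  if (family == "trapezoidal") {
    a <- p[1]; b <- p[2]; c <- p[3]; d <- p[4]
    if (x >= b && x <= c) return(1)
    if (x <= a || x >= d) return(0)
    if (x < b) return((x - a) / (b - a))
    return((d - x) / (d - c))
  }
  if (family == "pi") {
    sp <- function(x, a, b) {
      if (b <= a) return(as.numeric(x >= b))
      if (x <= a) return(0)
      if (x >= b) return(1)
      if (x <= (a + b) / 2) return(2 * ((x - a) / (b - a))^2)
      1 - 2 * ((x - b) / (b - a))^2
    }
    return(sp(x, p[1], p[2]) * (1 - sp(x, p[3], p[4])))
  }
  stop("unknown family")
}

# Brute-force Mamdani inference: explicit loop over all 49 rules for one
# point, with the same nearest-cell fallback contract.
oracle_infer_point <- function(system, x1, x2) {
  classes <- c("LC", "HnS", "HS")
  scores <- c(LC = 0, HnS = 0, HS = 0)
  for (i in 1:7) {
    for (j in 1:7) {
      m1 <- oracle_mf(system$mfs_ld1[[i]]$family,
                      system$mfs_ld1[[i]]$params, x1)
      m2 <- oracle_mf(system$mfs_ld2[[j]]$family,
                      system$mfs_ld2[[j]]$params, x2)
      s <- min(m1, m2)
      k <- system$rules$grid[i, j]
      if (s > scores[[k]]) scores[[k]] <- s
    }
  }
  if (max(scores) == 0) {
    centr <- function(m) {
      p <- m$params
      switch(m$family, gaussian = p[1], gbell = p[3], triangular = p[2],
             trapezoidal = (p[2] + p[3]) / 2, pi = (p[2] + p[3]) / 2)
    }
    best <- Inf; cls <- NA_character_
    for (i in 1:7) for (j in 1:7) {
      dd <- (centr(system$mfs_ld1[[i]]) - x1)^2 +
        (centr(system$mfs_ld2[[j]]) - x2)^2
      if (dd < best) { best <- dd; cls <- system$rules$grid[i, j] }
    }
    return(cls)
  }
  for (k in system$tie_break) if (scores[[k]] == max(scores)) return(k)
}

# A random valid fuzzy system of the given family over roughly [-3, 3]^2.
random_system <- function(family, rules = default_rule_base()) {
  rand_mf <- function(label) {
    c0 <- runif(1, -3, 3)
    switch(family,
      gaussian = mf("gaussian", c(c0, runif(1, 0.1, 2)), label),
      gbell = mf("gbell", c(runif(1, 0.1, 2), runif(1, 0.5, 5), c0), label),
      triangular = mf("triangular", sort(runif(3, -3, 3)), label),
      trapezoidal = mf("trapezoidal", sort(runif(4, -3, 3)), label),
      pi = mf("pi", sort(runif(4, -3, 3)), label))
  }
  fl_system(lapply(FL_SET_LABELS_T, rand_mf), lapply(FL_SET_LABELS_T, rand_mf),
            rules)
}

FL_SET_LABELS_T <- c("O1", "O2", "+1", "+2", "D1", "D2", "D3")
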