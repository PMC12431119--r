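## Nature-inspired optimizers for membership-function tuning: genetic
## algorithm (GA), particle swarm (PSO), simulated annealing (SA), invasive
## weed optimization (IWO) and artificial ecosystem-based optimization
## (AEO). All five are bound-constrained, elitist (best-so-far is tracked
## and reported), and reproducible under a fixed seed. The optimizer
## maximizes `objective` by default; pass `maximize = FALSE` to minimize.

#' Optimizer specification
#'
#' Method choice plus hyperparameters. Defaults: PSO population 50 with
#' inertia decaying linearly 0.9 to 0.4, c1 = c2 = 1.5, velocity clamped to
#' half the variable range; GA population 60, mutation rate 0.05, crossover
#' rate 0.8 (single-point), tournament size 3, elitism 2; SA geometric
#' cooling alpha 0.995 with the initial temperature set for about 0.8 initial
#' acceptance and a Gaussian neighbourhood whose scale decays geometrically
#' from 0.1 to 1e-4 of the variable range; IWO 50 seeds with 2-6 offspring
#' per weed (linear in fitness rank) and dispersal spread decaying 3.0 to
#' 0.01; AEO population 50 with consumption-type probabilities 0.5/0.3/0.2
#' and environment factor 0.5. All methods run 250 iterations by default.
#'
#' @param method One of `"GA"`, `"PSO"`, `"SA"`, `"IWO"`, `"AEO"`.
#' @param pop_size Population size (ignored by SA).
#' @param max_iter Iteration budget.
#' @param seed Optional integer seed.
#' @param ... Method-specific overrides (see Details in the package
#'   vignette): GA `p_mut`, `p_cross`, `tournament`, `elitism`, `mut_sd_frac`,
#'   `crossover` (`"single"`/`"two"`); PSO `w_start`, `w_end`, `w_const`,
#'   `c1`, `c2`; SA `alpha`, `accept0`, `sigma_frac0`, `sigma_frac1`,
#'   `reanchor_every`; IWO `min_seeds`, `max_seeds`, `sigma0`, `sigma1`,
#'   `sigma_exponent`; AEO `p_herbivore`, `p_carnivore`, `env_factor`,
#'   `migration_rate`.
#' @return An object of class `opt_spec`.
#' @export
opt_spec <- function(method = c("GA", "PSO", "SA", "IWO", "AEO"),
                     pop_size = NULL, max_iter = 250, seed = NULL, ...) {
  method <- match.arg(method)
  defaults <- switch(method,
    GA = list(pop_size = 60, p_mut = 0.05, p_cross = 0.8, tournament = 3,
              elitism = 2, mut_sd_frac = 0.1, crossover = "single"),
    PSO = list(pop_size = 50, w_start = 0.9, w_end = 0.4, w_const = NA,
               c1 = 1.5, c2 = 1.5),
    SA = list(pop_size = 1, alpha = 0.995, accept0 = 0.8,
              sigma_frac0 = 0.1, sigma_frac1 = 1e-4, reanchor_every = 1),
    IWO = list(pop_size = 50, min_seeds = 2, max_seeds = 6,
               sigma0 = 3.0, sigma1 = 0.01, sigma_exponent = 3),
    AEO = list(pop_size = 50, p_herbivore = 0.5, p_carnivore = 0.3,
               env_factor = 0.5, migration_rate = 0.1))
  extra <- list(...)
  bad <- setdiff(names(extra), names(defaults))
  if (length(bad)) stop("unknown ", method, " settings: ",
                        paste(bad, collapse = ", "))
  defaults[names(extra)] <- extra
  if (!is.null(pop_size)) defaults$pop_size <- pop_size
  if (!is.numeric(max_iter) || max_iter < 1) stop("max_iter must be >= 1")
  structure(c(list(method = method, max_iter = as.integer(max_iter),
                   seed = seed), defaults),
            class = "opt_spec")
}

#' @export
print.opt_spec <- function(x, ...) {
  cat("Optimizer:", x$method, "| pop", x$pop_size, "| iterations",
      x$max_iter, if (!is.null(x$seed)) paste("| seed", x$seed), "\n")
  invisible(x)
}

clip_bounds <- function(v, bounds) pmin(pmax(v, bounds$lo), bounds$hi)

rand_vec <- function(bounds) runif(length(bounds$lo), bounds$lo, bounds$hi)

#' Run a bound-constrained metaheuristic
#'
#' Dispatches to the method selected in `spec`. Every candidate is passed
#' through `repair_fn` (default: clip to bounds) before evaluation, so the
#' objective only ever sees feasible vectors. The best-so-far value is
#' tracked across the run; its history is non-decreasing in the
#' maximization sense.
#'
#' @param spec An [opt_spec()].
#' @param objective Function of a numeric vector returning a finite scalar.
#' @param bounds List with numeric vectors `lo` and `hi` of equal length.
#' @param init Optional matrix (rows = vectors) of initial candidates seeded
#'   into the starting population (SA starts from the first row).
#' @param maximize Maximize (default) or minimize the objective.
#' @param repair_fn Function mapping a raw candidate to a feasible one.
#' @return List of class `opt_result`: `par` (best repaired vector), `value`
#'   (best raw objective), `history` (best-so-far objective after the
#'   initial evaluation and after each iteration), `evaluations`, `seed`,
#'   `method`.
#' @export
optimize_mh <- function(spec, objective, bounds, init = NULL,
                        maximize = TRUE, repair_fn = NULL) {
  stopifnot(inherits(spec, "opt_spec"))
  bounds$lo <- as.numeric(bounds$lo); bounds$hi <- as.numeric(bounds$hi)
  if (length(bounds$lo) != length(bounds$hi) ||
      any(!is.finite(c(bounds$lo, bounds$hi))) ||
      any(bounds$hi < bounds$lo)) stop("invalid bounds")
  if (is.null(repair_fn)) repair_fn <- function(v) clip_bounds(v, bounds)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  sign <- if (maximize) 1 else -1
  env <- new.env()
  env$n_eval <- 0L
  fit <- function(v) {                 # canonical: always maximized
    env$n_eval <- env$n_eval + 1L
    val <- objective(v)
    if (!is.finite(val)) stop("objective returned a non-finite value")
    sign * val
  }
  if (!is.null(init)) {
    init <- if (is.null(dim(init))) matrix(init, nrow = 1) else as.matrix(init)
    if (ncol(init) != length(bounds$lo)) stop("init dimension mismatch")
  }
  run <- switch(spec$method, GA = run_ga, PSO = run_pso, SA = run_sa,
                IWO = run_iwo, AEO = run_aeo)
  out <- run(spec, fit, bounds, init, repair_fn)
  structure(list(par = out$best_par, value = sign * out$best_fit,
                 history = sign * out$history, evaluations = env$n_eval,
                 seed = spec$seed, method = spec$method,
                 maximize = maximize),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(x$method, "result: best value", signif(x$value, 6), "after",
      x$evaluations, "evaluations\n")
  invisible(x)
}

# Initial population: uniform random in bounds, with any supplied candidates
# overwriting the first rows.
init_population <- function(npop, bounds, init, repair_fn) {
  pop <- t(vapply(seq_len(npop), function(i) rand_vec(bounds),
                  numeric(length(bounds$lo))))
  if (!is.null(init)) {
    k <- min(nrow(init), npop)
    pop[seq_len(k), ] <- init[seq_len(k), ]
  }
  t(apply(pop, 1, repair_fn))
}

## --- Genetic algorithm -----------------------------------------------------

run_ga <- function(spec, fit, bounds, init, repair_fn) {
  d <- length(bounds$lo)
  range <- bounds$hi - bounds$lo
  mut_sd <- spec$mut_sd_frac * range
  pop <- init_population(spec$pop_size, bounds, init, repair_fn)
  f <- apply(pop, 1, fit)
  best_i <- which.max(f)
  best_par <- pop[best_i, ]; best_fit <- f[best_i]
  history <- numeric(spec$max_iter + 1); history[1] <- best_fit

  tournament <- function() {
    cand <- sample.int(spec$pop_size, spec$tournament, replace = TRUE)
    cand[which.max(f[cand])]
  }
  for (it in seq_len(spec$max_iter)) {
    ord <- order(f, decreasing = TRUE)
    newpop <- pop[ord[seq_len(spec$elitism)], , drop = FALSE]
    while (nrow(newpop) < spec$pop_size) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (runif(1) < spec$p_cross && d > 1) {
        if (identical(spec$crossover, "two") && d > 2) {
          cp <- sort(sample.int(d - 1, 2))
          mid <- (cp[1] + 1):cp[2]
          tmp <- p1[mid]; p1[mid] <- p2[mid]; p2[mid] <- tmp
        } else {
          cp <- sample.int(d - 1, 1)
          tmp <- p1[1:cp]; p1[1:cp] <- p2[1:cp]; p2[1:cp] <- tmp
        }
      }
      for (child in list(p1, p2)) {
        mut <- runif(d) < spec$p_mut
        child[mut] <- child[mut] + rnorm(sum(mut), 0, mut_sd[mut])
        newpop <- rbind(newpop, repair_fn(child))
        if (nrow(newpop) == spec$pop_size) break
      }
    }
    pop <- newpop
    f <- apply(pop, 1, fit)
    if (max(f) > best_fit) {
      best_fit <- max(f); best_par <- pop[which.max(f), ]
    }
    history[it + 1] <- best_fit
  }
  list(best_par = best_par, best_fit = best_fit, history = history)
}

## --- Particle swarm --------------------------------------------------------

run_pso <- function(spec, fit, bounds, init, repair_fn) {
  d <- length(bounds$lo)
  range <- bounds$hi - bounds$lo
  vmax <- range / 2
  pop <- init_population(spec$pop_size, bounds, init, repair_fn)
  vel <- t(vapply(seq_len(spec$pop_size),
                  function(i) runif(d, -vmax, vmax) / 10, numeric(d)))
  f <- apply(pop, 1, fit)
  pbest <- pop; pbest_f <- f
  g <- which.max(f)
  best_par <- pop[g, ]; best_fit <- f[g]
  history <- numeric(spec$max_iter + 1); history[1] <- best_fit
  for (it in seq_len(spec$max_iter)) {
    w <- if (is.finite(spec$w_const) && !is.na(spec$w_const)) spec$w_const
         else spec$w_start + (spec$w_end - spec$w_start) *
              (it - 1) / max(1, spec$max_iter - 1)
    r1 <- matrix(runif(spec$pop_size * d), spec$pop_size)
    r2 <- matrix(runif(spec$pop_size * d), spec$pop_size)
    vel <- w * vel +
      spec$c1 * r1 * (pbest - pop) +
      spec$c2 * r2 * sweep(-pop, 2, best_par, "+")
    vel <- pmin(pmax(vel, matrix(-vmax, spec$pop_size, d, byrow = TRUE)),
                matrix(vmax, spec$pop_size, d, byrow = TRUE))
    pop <- t(apply(pop + vel, 1, repair_fn))
    f <- apply(pop, 1, fit)
    improved <- f > pbest_f
    pbest[improved, ] <- pop[improved, , drop = FALSE]
    pbest_f[improved] <- f[improved]
    if (max(pbest_f) > best_fit) {
      best_fit <- max(pbest_f); best_par <- pbest[which.max(pbest_f), ]
    }
    history[it + 1] <- best_fit
  }
  list(best_par = best_par, best_fit = best_fit, history = history)
}

## --- Simulated annealing ---------------------------------------------------

run_sa <- function(spec, fit, bounds, init, repair_fn) {
  d <- length(bounds$lo)
  range <- bounds$hi - bounds$lo
  cur <- if (!is.null(init)) repair_fn(init[1, ]) else repair_fn(rand_vec(bounds))
  cur_f <- fit(cur)
  best_par <- cur; best_fit <- cur_f
  history <- numeric(spec$max_iter + 1); history[1] <- best_fit
  Temp <- NA_real_
  decay <- (spec$sigma_frac1 / spec$sigma_frac0)^(1 / max(1, spec$max_iter - 1))
  for (it in seq_len(spec$max_iter)) {
    sigma <- spec$sigma_frac0 * decay^(it - 1) * range
    cand <- repair_fn(cur + rnorm(d, 0, sigma))
    cand_f <- fit(cand)
    delta <- cand_f - cur_f
    if (is.na(Temp)) {
      # calibrate T0 from the first observed step so a typical worsening of
      # that size is accepted with probability accept0
      Temp <- max(abs(delta), 1e-12) / -log(spec$accept0)
    }
    if (delta >= 0 || runif(1) < exp(delta / Temp)) {
      cur <- cand; cur_f <- cand_f
    }
    if (cur_f > best_fit) { best_fit <- cur_f; best_par <- cur }
    if (spec$reanchor_every > 0 && it %% spec$reanchor_every == 0) {
      cur <- best_par; cur_f <- best_fit   # restart chain from incumbent
    }
    Temp <- Temp * spec$alpha
    history[it + 1] <- best_fit
  }
  list(best_par = best_par, best_fit = best_fit, history = history)
}

## --- Invasive weed optimization --------------------------------------------

run_iwo <- function(spec, fit, bounds, init, repair_fn) {
  d <- length(bounds$lo)
  pop <- init_population(spec$pop_size, bounds, init, repair_fn)
  f <- apply(pop, 1, fit)
  best_i <- which.max(f)
  best_par <- pop[best_i, ]; best_fit <- f[best_i]
  history <- numeric(spec$max_iter + 1); history[1] <- best_fit
  for (it in seq_len(spec$max_iter)) {
    sigma <- ((spec$max_iter - it) / spec$max_iter)^spec$sigma_exponent *
      (spec$sigma0 - spec$sigma1) + spec$sigma1
    fr <- range(f)
    nseeds <- if (diff(fr) > 0)
      round(spec$min_seeds + (f - fr[1]) / diff(fr) *
              (spec$max_seeds - spec$min_seeds))
    else rep(spec$min_seeds, length(f))
    seeds <- do.call(rbind, lapply(seq_along(f), function(i) {
      if (nseeds[i] == 0) return(NULL)
      t(vapply(seq_len(nseeds[i]),
               function(s) repair_fn(pop[i, ] + rnorm(d, 0, sigma)),
               numeric(d)))
    }))
    fs <- apply(seeds, 1, fit)
    pop <- rbind(pop, seeds)
    f <- c(f, fs)
    keep <- order(f, decreasing = TRUE)[seq_len(min(spec$pop_size, length(f)))]
    pop <- pop[keep, , drop = FALSE]; f <- f[keep]
    if (f[1] > best_fit) { best_fit <- f[1]; best_par <- pop[1, ] }
    history[it + 1] <- best_fit
  }
  list(best_par = best_par, best_fit = best_fit, history = history)
}

## --- Artificial ecosystem-based optimization --------------------------------

run_aeo <- function(spec, fit, bounds, init, repair_fn) {
  d <- length(bounds$lo)
  npop <- spec$pop_size
  pop <- init_population(npop, bounds, init, repair_fn)
  f <- apply(pop, 1, fit)
  best_i <- which.max(f)
  best_par <- pop[best_i, ]; best_fit <- f[best_i]
  history <- numeric(spec$max_iter + 1); history[1] <- best_fit
  p_cons <- spec$p_herbivore + spec$p_carnivore
  p_dec <- max(0, 1 - p_cons)              # decomposer probability
  for (it in seq_len(spec$max_iter)) {
    ord <- order(f)                        # ascending: pop[1] worst
    pop <- pop[ord, , drop = FALSE]; f <- f[ord]
    cand <- pop
    # production: the worst individual moves between the best and a random
    # point, weighted by the environment factor and the remaining budget
    a <- spec$env_factor * (1 - it / spec$max_iter) * runif(1)
    cand[1, ] <- (1 - a) * pop[npop, ] + a * rand_vec(bounds)
    for (i in 2:npop) {
      if (runif(1) < p_dec) {
        # decomposition: resample in a Gaussian-scaled region around the best
        r3 <- runif(1)
        e <- r3 * sample(1:2, 1) - 1
        h <- 2 * r3 - 1
        D <- 3 * rnorm(1)
        cand[i, ] <- best_par + D * (e * best_par - h * pop[i, ])
      } else {
        # consumption: herbivore eats the producer, carnivore a random
        # better-ranked consumer, omnivore a mix of both
        u <- runif(1) * p_cons
        C <- 0.5 * rnorm(d) / abs(rnorm(d))
        if (u < spec$p_herbivore || i == 2) {
          cand[i, ] <- pop[i, ] + C * (pop[i, ] - cand[1, ])
        } else {
          j <- sample(2:(i - 1), 1)
          if (u < spec$p_herbivore + spec$p_carnivore / 2) {
            cand[i, ] <- pop[i, ] + C * (pop[i, ] - pop[j, ])
          } else {
            r <- runif(1)
            cand[i, ] <- pop[i, ] +
              C * (r * (pop[i, ] - cand[1, ]) + (1 - r) * (pop[i, ] - pop[j, ]))
          }
        }
      }
    }
    # migration: occasionally a fresh immigrant takes the worst spot
    if (runif(1) < spec$migration_rate) cand[1, ] <- rand_vec(bounds)
    cand <- t(apply(cand, 1, repair_fn))
    fc <- apply(cand, 1, fit)
    better <- fc > f
    pop[better, ] <- cand[better, , drop = FALSE]
    f[better] <- fc[better]
    if (max(f) > best_fit) { best_fit <- max(f); best_par <- pop[which.max(f), ] }
    history[it + 1] <- best_fit
  }
  list(best_par = best_par, best_fit = best_fit, history = history)
}
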