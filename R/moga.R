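#' Optimization configuration
#'
#' Settings of one multiobjective fit: NSGA-II population, generations,
#' simulated-binary crossover (SBX) and polynomial mutation operators,
#' number of independent repeats (each repeat forms one draw of the
#' per-subject parameter distribution), and the simulation settings used to
#' evaluate candidates.
#'
#' @param pop_size Population size (>= 4, even).
#' @param generations Number of generations.
#' @param n_repeats Independent optimization repeats (full scale: 100).
#' @param base_seed Base RNG seed; repeat `r` uses `base_seed + r`.
#' @param sim_duration Simulated-EEG duration (s) per candidate evaluation.
#' @param dt_internal Integration step (s) during fitting.
#' @param burn_in Discarded transient (s).
#' @param crossover_prob,crossover_eta SBX probability and distribution
#'   index.
#' @param mutation_prob,mutation_eta Per-gene polynomial-mutation
#'   probability and distribution index.
#' @param penalty Objective value assigned to blown-up simulations (large
#'   finite constant keeps the dominance order total).
#' @param reseed_each_generation If `FALSE` (default) one simulation-noise
#'   seed is fixed per repeat (common random numbers), so objectives are a
#'   deterministic function of parameters and elite objective traces are
#'   exactly monotone; if `TRUE` the noise seed changes each generation.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(pop_size = 64, generations = 50, n_repeats = 10,
                       base_seed = 1L, sim_duration = 30, dt_internal = 2e-4,
                       burn_in = 5, crossover_prob = 0.9, crossover_eta = 15,
                       mutation_prob = 1 / 32, mutation_eta = 20,
                       penalty = 1e6, reseed_each_generation = FALSE) {
  if (pop_size < 4) stop("pop_size must be >= 4")
  if (pop_size %% 2 != 0) stop("pop_size must be even")
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  if (generations < 1) stop("generations must be >= 1")
  structure(as.list(environment()), class = "fit_config")
}

#' Pareto front (non-dominated set) of objective pairs
#'
#' A point dominates another iff it is no worse in both objectives and
#' strictly better in at least one. Duplicated points do not dominate each
#' other and are all retained.
#'
#' @param points Numeric matrix, one row per point, columns = objectives.
#' @return Integer indices of the non-dominated rows.
#' @export
pareto_front <- function(points) {
  if (is.vector(points)) points <- matrix(points, nrow = 1)
  n <- nrow(points)
  if (n == 0) stop("empty point set")
  if (any(!is.finite(points))) stop("objective values must be finite")
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!nd[i]) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(points[j, ] <= points[i, ]) && any(points[j, ] < points[i, ])) {
        nd[i] <- FALSE
        break
      }
    }
  }
  which(nd)
}

# non-dominated sorting into successive fronts
.nds_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    idx <- pareto_front(obj[remaining, , drop = FALSE])
    rank[remaining[idx]] <- r
    remaining <- remaining[-idx]
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (m in seq_len(ncol(obj))) {
    o <- order(obj[, m])
    rng <- obj[o[n], m] - obj[o[1], m]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0) {
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], m] - obj[o[1:(n - 2)], m]) / rng
    }
  }
  d
}

.tournament <- function(rank, crowd) {
  n <- length(rank)
  pick <- function() {
    a <- sample.int(n, 1); b <- sample.int(n, 1)
    if (rank[a] < rank[b]) return(a)
    if (rank[b] < rank[a]) return(b)
    if (crowd[a] >= crowd[b]) a else b
  }
  c(pick(), pick())
}

.sbx <- function(p1, p2, lower, upper, eta, prob) {
  c1 <- p1; c2 <- p2
  if (runif(1) < prob) {
    do <- runif(length(p1)) < 0.5 & abs(p1 - p2) > 1e-14
    u <- runif(sum(do))
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    m <- (p1[do] + p2[do]) / 2
    h <- abs(p1[do] - p2[do]) / 2
    c1[do] <- m - beta * h
    c2[do] <- m + beta * h
  }
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

.poly_mutate <- function(p, lower, upper, eta, prob) {
  do <- runif(length(p)) < prob
  if (any(do)) {
    u <- runif(sum(do))
    rng <- (upper - lower)[do]
    delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                    1 - (2 * (1 - u))^(1 / (eta + 1)))
    p[do] <- p[do] + delta * rng
  }
  pmin(pmax(p, lower), upper)
}

# objective evaluation of one candidate against a feature target
.evaluate_candidate <- function(x, target, config, sim_seed) {
  p <- x
  names(p) <- nmm_param_names()
  sim <- simulate_nmm(p, duration = config$sim_duration, seed = sim_seed,
                      dt_internal = config$dt_internal,
                      burn_in = config$burn_in)
  if (sim$blown_up || sd(sim$eeg) == 0) {
    return(c(f_spec = config$penalty, f_hvg = config$penalty))
  }
  objective_pair(sim, target)
}

# one NSGA-II repeat; returns a fit_result
.nsga2_run <- function(target, config, repeat_id, seed) {
  set.seed(seed)
  b <- nmm_bounds()
  lower <- b$lower
  upper <- b$upper
  npar <- length(lower)
  np <- config$pop_size
  sim_seed <- (as.numeric(seed) * 1000) %% 2^31

  # bounds are constructed so every in-bounds draw satisfies the
  # reversal-potential ordering; no repair step needed
  pop <- matrix(runif(np * npar, rep(lower, each = np), rep(upper, each = np)),
                nrow = np)
  obj <- t(apply(pop, 1, .evaluate_candidate, target = target,
                 config = config, sim_seed = sim_seed))
  trace <- matrix(NA_real_, nrow = config$generations, ncol = 2,
                  dimnames = list(NULL, c("f_spec", "f_hvg")))
  for (g in seq_len(config$generations)) {
    if (config$reseed_each_generation) {
      sim_seed <- (as.numeric(seed) * 1000 + g) %% 2^31
      obj <- t(apply(pop, 1, .evaluate_candidate, target = target,
                     config = config, sim_seed = sim_seed))
    }
    rank <- .nds_ranks(obj)
    crowd <- numeric(np)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- .crowding(obj[idx, , drop = FALSE])
    }
    children <- matrix(NA_real_, nrow = np, ncol = npar)
    for (k in seq(1, np, by = 2)) {
      pr <- .tournament(rank, crowd)
      cs <- .sbx(pop[pr[1], ], pop[pr[2], ], lower, upper,
                 config$crossover_eta, config$crossover_prob)
      children[k, ] <- .poly_mutate(cs[[1]], lower, upper,
                                    config$mutation_eta, config$mutation_prob)
      children[k + 1, ] <- .poly_mutate(cs[[2]], lower, upper,
                                        config$mutation_eta,
                                        config$mutation_prob)
    }
    cobj <- t(apply(children, 1, .evaluate_candidate, target = target,
                    config = config, sim_seed = sim_seed))
    if (all(cobj[, 1] >= config$penalty)) {
      warning(sprintf("repeat %d generation %d: all offspring flagged",
                      repeat_id, g))
    }
    allp <- rbind(pop, children)
    allo <- rbind(obj, cobj)
    arank <- .nds_ranks(allo)
    sel <- integer(0)
    for (r in sort(unique(arank))) {
      idx <- which(arank == r)
      if (length(sel) + length(idx) <= np) {
        sel <- c(sel, idx)
      } else {
        cd <- .crowding(allo[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)[seq_len(np - length(sel))]])
        break
      }
    }
    pop <- allp[sel, , drop = FALSE]
    obj <- allo[sel, , drop = FALSE]
    trace[g, ] <- apply(obj, 2, min)
  }
  fr <- pareto_front(obj)
  pareto_params <- pop[fr, , drop = FALSE]
  colnames(pareto_params) <- nmm_param_names()
  pareto_obj <- obj[fr, , drop = FALSE]
  colnames(pareto_obj) <- c("f_spec", "f_hvg")
  best_idx <- .select_representative(pareto_obj)
  bp <- pareto_params[best_idx, ]
  structure(list(
    repeat_id = repeat_id,
    pareto_params = pareto_params,
    pareto_objectives = pareto_obj,
    best = list(params = structure(bp, class = "nmm_params"),
                objectives = pareto_obj[best_idx, ]),
    seed = seed, sim_seed = sim_seed, trace = trace
  ), class = "fit_result")
}

# representative solution: Pareto member minimizing the median-normalized
# objective sum
.select_representative <- function(pareto_obj) {
  m1 <- median(pareto_obj[, 1]); m2 <- median(pareto_obj[, 2])
  if (m1 <= 0) m1 <- max(mean(pareto_obj[, 1]), 1e-12)
  if (m2 <= 0) m2 <- max(mean(pareto_obj[, 2]), 1e-12)
  which.min(pareto_obj[, 1] / m1 + pareto_obj[, 2] / m2)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> repeat %d: %d Pareto solutions, best (f_spec=%.4g, f_hvg=%.4g)\n",
              x$repeat_id, nrow(x$pareto_params),
              x$best$objectives[1], x$best$objectives[2]))
  invisible(x)
}

#' Fit the model to a subject's feature target
#'
#' Runs `n_repeats` independent NSGA-II searches of the bounded
#' 32-parameter space, each minimizing the two objectives (spectral
#' distance, HVG mean-degree distance) against the target. Candidate
#' simulations share one noise seed per repeat (common random numbers), so
#' each repeat is fully deterministic given `base_seed`. Blown-up
#' simulations receive the penalty objectives. The repeats jointly describe
#' the subject's parameter distribution; each repeat's representative
#' solution is the Pareto member minimizing the median-normalized objective
#' sum.
#'
#' @param target A [feature_set()] built from the subject's epochs.
#' @param config A [fit_config()].
#' @return List of `fit_result`, one per repeat.
#' @export
fit_subject <- function(target, config = fit_config()) {
  stopifnot(inherits(target, "feature_set"))
  if (!inherits(config, "fit_config")) stop("config must be a fit_config")
  lapply(seq_len(config$n_repeats), function(r) {
    .nsga2_run(target, config, repeat_id = r,
               seed = as.integer(config$base_seed) + r)
  })
}

#' Fit the model to a spike-wave-discharge target
#'
#' Identical machinery to [fit_subject()], with the candidate simulation
#' duration matched to the SWD segment (2.5 s) and features computed on the
#' single short window (one Welch window on the same padded grid; HVG on
#' the full window).
#'
#' @param target An `swd_target` (see [swd_target()]) or a `feature_set`
#'   built from a 2.5-s series.
#' @param config A [fit_config()]; `sim_duration` is forced to the SWD
#'   duration.
#' @return List of `fit_result`, one per repeat.
#' @export
fit_swd <- function(target, config = fit_config()) {
  if (inherits(target, "swd_target")) {
    config$sim_duration <- length(target$samples) / target$fs
    target <- target$features
  } else {
    config$sim_duration <- 2.5
  }
  fit_subject(target, config)
}

#' Pooled per-repeat distribution of one parameter
#'
#' The named parameter's value in each repeat's representative solution:
#' the sample that forms the subject's parameter distribution (100 repeats
#' at full scale).
#'
#' @param results List of `fit_result` from [fit_subject()].
#' @param param_name One of [nmm_param_names()].
#' @return Numeric vector, one value per repeat.
#' @export
pooled_distribution <- function(results, param_name) {
  if (!length(results)) stop("no fit results")
  if (!param_name %in% nmm_param_names()) {
    stop("unknown parameter '", param_name, "'; valid names: ",
         paste(nmm_param_names(), collapse = ", "))
  }
  vapply(results, function(r) unname(r$best$params[param_name]), 0)
}
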