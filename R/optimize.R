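# ---------------------------------------------------------------------------
# Evolutionary optimization of the query's assignment-edge weights in the
# bounded raw space [-0.5, 0.5]^m: constriction PSO and three DE variants.
# Fitness is minimized; virtual-screening metrics enter as 1 - metric.
# ---------------------------------------------------------------------------

#' Constriction coefficient of the particle swarm
#'
#' Clerc-Kennedy constriction: for `phi = phi1 + phi2 > 4`,
#' `chi = 2 / |2 - phi - sqrt(phi^2 - 4 phi)|`.  At the default
#' `phi1 = phi2 = 2.05`, `chi` is 0.73 to two decimals.
#'
#' @param phi1,phi2 attraction coefficients.
#' @return the constriction factor `chi` in `(0, 1)`.
#' @export
pso_constriction <- function(phi1 = 2.05, phi2 = 2.05) {
  phi <- phi1 + phi2
  if (phi <= 4) stop("constriction requires phi1 + phi2 > 4")
  2 / abs(2 - phi - sqrt(phi^2 - 4 * phi))
}

#' PSO velocity update (constriction form)
#'
#' `v' = chi * (v + r1 * phi1 * (pbest - x) + r2 * phi2 * (nbest - x))` with
#' component-wise uniform draws `r1, r2`.  Exposed for direct verification;
#' the swarm engine calls it per particle.
#'
#' @param x,v current position and velocity.
#' @param pbest,nbest personal-history and neighborhood-history best positions.
#' @param phi1,phi2 attraction coefficients.
#' @param chi constriction factor.
#' @param r1,r2 uniform draw vectors (defaults: fresh `runif` draws).
#' @return the new velocity vector.
#' @export
pso_velocity <- function(x, v, pbest, nbest, phi1 = 2.05, phi2 = 2.05,
                         chi = pso_constriction(phi1, phi2),
                         r1 = stats::runif(length(x)),
                         r2 = stats::runif(length(x))) {
  chi * (v + r1 * phi1 * (pbest - x) + r2 * phi2 * (nbest - x))
}

# 2D-grid (torus) neighborhoods of Manhattan range `range` for a swarm of
# `n` particles; grid dimensions are the most-square factorization of n.
.grid_neighborhoods <- function(n, range = 2) {
  nr <- floor(sqrt(n))
  while (n %% nr != 0) nr <- nr - 1
  nc <- n / nr
  row <- (seq_len(n) - 1) %/% nc
  col <- (seq_len(n) - 1) %% nc
  lapply(seq_len(n), function(i) {
    dr <- pmin(abs(row - row[i]), nr - abs(row - row[i]))
    dc <- pmin(abs(col - col[i]), nc - abs(col - col[i]))
    which(dr + dc <= range)
  })
}

#' One binomial-recombination DE candidate
#'
#' Builds the mutant base per variant -- a random individual (`rand_1`), the
#' current best (`best_2`), or the arithmetic combination
#' `x_i + lambda * (x_best - x_i)` (`current_to_best_1`) -- adds `F` times the
#' sum of `b` difference pairs drawn from mutually exclusive individuals
#' (`b = 2` for `best_2`, else 1), then crosses over with `x_i` component-wise
#' at rate `CR` with one forced index `jr`.  Out-of-bounds components are
#' clipped.
#'
#' @param pop numeric matrix, one row per individual.
#' @param i index of the target individual.
#' @param variant `"rand_1"`, `"best_2"` or `"current_to_best_1"`.
#' @param best_idx index of the current best individual.
#' @param f difference amplification `F` (default 0.8).
#' @param cr crossover rate (default 0.6).
#' @param lambda arithmetic-recombination factor for `current_to_best_1`.
#' @param lower,upper box bounds.
#' @param idx optional pre-chosen donor indices (testing hook): first the base
#'   individual for `rand_1`, then the `2b` difference individuals.
#' @param jr optional forced crossover index (testing hook).
#' @return the candidate vector.
#' @export
de_mutate <- function(pop, i, variant = c("rand_1", "best_2", "current_to_best_1"),
                      best_idx, f = 0.8, cr = 0.6, lambda = 0.6,
                      lower = -0.5, upper = 0.5, idx = NULL, jr = NULL) {
  variant <- match.arg(variant)
  n <- nrow(pop); m <- ncol(pop)
  b <- if (variant == "best_2") 2L else 1L
  need <- 2L * b + if (variant == "rand_1") 1L else 0L
  if (n < 2L * b + 2L) stop("population too small for ", b, " difference pairs")
  excl <- if (variant == "rand_1") i else unique(c(i, best_idx))
  if (is.null(idx)) idx <- sample(setdiff(seq_len(n), excl), need)
  base <- switch(variant,
                 rand_1 = pop[idx[1], ],
                 best_2 = pop[best_idx, ],
                 current_to_best_1 = pop[i, ] + lambda * (pop[best_idx, ] - pop[i, ]))
  dstart <- if (variant == "rand_1") 1L else 0L
  diffsum <- 0
  for (k in seq_len(b)) {
    diffsum <- diffsum +
      pop[idx[dstart + 2 * k - 1], ] - pop[idx[dstart + 2 * k], ]
  }
  mutant <- base + f * diffsum
  if (is.null(jr)) jr <- sample.int(m, 1)
  take <- stats::runif(m) <= cr
  take[jr] <- TRUE
  cand <- ifelse(take, mutant, pop[i, ])
  pmin(upper, pmax(lower, cand))
}

# shared trace bookkeeping: best-so-far fitness after every evaluation
.trace_recorder <- function(budget) {
  env <- new.env(parent = emptyenv())
  env$trace <- numeric(budget)
  env$k <- 0L
  env$best <- Inf
  env$best_par <- NULL
  env$record <- function(fit, par) {
    if (env$k >= budget) return(FALSE)
    if (fit < env$best) { env$best <- fit; env$best_par <- par }
    env$k <- env$k + 1L
    env$trace[env$k] <- env$best
    TRUE
  }
  env
}

#' Constriction particle swarm optimization in a box
#'
#' Synchronous swarm over `[lower, upper]^m` with a 2D-grid torus neighborhood
#' of Manhattan range `grid_range` (grid dimensions: most-square factorization
#' of the population size).  Initial positions are uniform in the box; initial
#' velocity components are uniform in `[-v_init, v_init]`.  Positions are
#' clipped to the bounds after every move.  Stops when the evaluation budget
#' is exhausted.
#'
#' @param fitness function from an m-vector to a scalar (minimized).
#' @param m problem dimension.
#' @param budget total number of fitness evaluations (`>=` population size).
#' @param pop_size swarm size (default 30).
#' @param phi1,phi2,chi constriction parameters (defaults 2.05 / 2.05 /
#'   [pso_constriction()]).
#' @param v_init initial velocity amplitude (default 0.2).
#' @param grid_range neighborhood range on the grid (default 2).
#' @param lower,upper box bounds (defaults -0.5 / 0.5).
#' @return list with `best_par`, `best_fit`, `trace` (best-so-far fitness per
#'   evaluation) and `n_eval`.
#' @export
optim_pso <- function(fitness, m, budget, pop_size = 30, phi1 = 2.05,
                      phi2 = 2.05, chi = pso_constriction(phi1, phi2),
                      v_init = 0.2, grid_range = 2,
                      lower = -0.5, upper = 0.5) {
  if (budget < pop_size) stop("budget must be at least the population size")
  rec <- .trace_recorder(budget)
  nbhd <- .grid_neighborhoods(pop_size, grid_range)
  X <- matrix(stats::runif(pop_size * m, lower, upper), pop_size, m)
  V <- matrix(stats::runif(pop_size * m, -v_init, v_init), pop_size, m)
  fit <- numeric(pop_size)
  for (i in seq_len(pop_size)) {
    fit[i] <- fitness(X[i, ])
    rec$record(fit[i], X[i, ])
  }
  P <- X; pfit <- fit                       # personal bests
  while (rec$k < budget) {
    nbest <- t(vapply(seq_len(pop_size), function(i) {
      nb <- nbhd[[i]]
      P[nb[which.min(pfit[nb])], ]
    }, numeric(m)))
    for (i in seq_len(pop_size)) {
      V[i, ] <- pso_velocity(X[i, ], V[i, ], P[i, ], nbest[i, ],
                             phi1, phi2, chi)
      X[i, ] <- pmin(upper, pmax(lower, X[i, ] + V[i, ]))
    }
    for (i in seq_len(pop_size)) {
      if (rec$k >= budget) break
      fit[i] <- fitness(X[i, ])
      rec$record(fit[i], X[i, ])
      if (fit[i] < pfit[i]) { pfit[i] <- fit[i]; P[i, ] <- X[i, ] }
    }
  }
  list(best_par = rec$best_par, best_fit = rec$best, trace = rec$trace,
       n_eval = rec$k)
}

#' Differential evolution in a box
#'
#' Generational DE with binomial recombination and greedy one-to-one
#' replacement: each candidate replaces its target individual iff its fitness
#' is no worse.  Variants `rand_1`, `best_2` (two difference pairs) and
#' `current_to_best_1` (arithmetic base `x_i + lambda (x_best - x_i)`, then
#' binomial crossover against `x_i`).
#'
#' @inheritParams optim_pso
#' @inheritParams de_mutate
#' @param pop_size population size (default 30).
#' @return list with `best_par`, `best_fit`, `trace`, `n_eval`.
#' @export
optim_de <- function(fitness, m, budget,
                     variant = c("rand_1", "best_2", "current_to_best_1"),
                     pop_size = 30, f = 0.8, cr = 0.6, lambda = 0.6,
                     lower = -0.5, upper = 0.5) {
  variant <- match.arg(variant)
  if (budget < pop_size) stop("budget must be at least the population size")
  rec <- .trace_recorder(budget)
  X <- matrix(stats::runif(pop_size * m, lower, upper), pop_size, m)
  fit <- numeric(pop_size)
  for (i in seq_len(pop_size)) {
    fit[i] <- fitness(X[i, ])
    rec$record(fit[i], X[i, ])
  }
  while (rec$k < budget) {
    for (i in seq_len(pop_size)) {
      if (rec$k >= budget) break
      best_idx <- which.min(fit)
      cand <- de_mutate(X, i, variant, best_idx, f, cr, lambda, lower, upper)
      cf <- fitness(cand)
      rec$record(cf, cand)
      # immediate (in-place) greedy one-to-one replacement: improved
      # individuals serve as donors within the same generation
      if (cf <= fit[i]) { X[i, ] <- cand; fit[i] <- cf }
    }
  }
  list(best_par = rec$best_par, best_fit = rec$best, trace = rec$trace,
       n_eval = rec$k)
}

# ---------------------------------------------------------------------------
# Virtual-screening fitness
# ---------------------------------------------------------------------------

# fast AUC/BEDROC on raw score vectors, mirroring auc() and bedroc() with the
# same tie conventions (average rank for AUC, decoys-first for BEDROC)
.auc_scores <- function(scores, act) {
  nA <- sum(act); nD <- length(act) - nA
  rk <- rank(scores, ties.method = "average")
  (sum(rk[act]) - nA * (nA + 1) / 2) / (nA * nD)
}

.bedroc_scores <- function(scores, act, alpha) {
  n <- length(scores)
  ord <- order(-scores, act)               # decoys (FALSE) first within ties
  ranks <- which(act[ord])
  nA <- length(ranks)
  s <- sum(exp(-alpha * ranks / n))
  smax <- sum(exp(-alpha * seq_len(nA) / n))
  smin <- sum(exp(-alpha * seq.int(n - nA + 1L, n) / n))
  (s - smin) / (smax - smin)
}

#' Virtual-screening fitness function for weight optimization
#'
#' Returns a closure mapping a raw weight vector in `[-0.5, 0.5]^m` to
#' `1 - metric` of the screening run it induces: the raw vector is normalized
#' onto the constraint set ([normalize_weights()]), every dataset molecule is
#' scored by the weighted optimal-assignment similarity, and the ranked list
#' is evaluated with the chosen metric.  The query-vs-library atom-similarity
#' matrices are precomputed once; each call solves only the weighted
#' assignments.  The closure carries an evaluation counter
#' (`attr(fn, "count")()`) that increments exactly once per call.
#'
#' @param query `oa_mol` query.
#' @param dataset an `oa_dataset` with at least one active and one decoy.
#' @param metric `"auc"` or `"bedroc"`.
#' @param alpha BEDROC weighting parameter.
#' @return a function `raw -> fitness` with attributes `count` (closure
#'   returning the number of evaluations) and `metric`.
#' @export
oa_fitness <- function(query, dataset, metric = c("auc", "bedroc"),
                       alpha = 53.6) {
  metric <- match.arg(metric)
  stopifnot(inherits(dataset, "oa_dataset"))
  if (!any(dataset$info$label == "active") ||
      !any(dataset$info$label == "decoy"))
    stop("dataset must contain both actives and decoys")
  Smats <- precompute_sim_matrices(query, dataset$mols)
  act <- dataset$info$label == "active"
  n_eval <- 0L
  # metrics computed directly on the score vector (identical to auc()/bedroc()
  # on the ranked list; verified by tests) to keep per-evaluation cost low
  fn <- function(raw) {
    w <- normalize_weights(raw)
    scores <- cpp_screen_scores(Smats, as.numeric(w))
    val <- if (metric == "auc") .auc_scores(scores, act)
           else .bedroc_scores(scores, act, alpha)
    n_eval <<- n_eval + 1L
    1 - val
  }
  attr(fn, "count") <- function() n_eval
  attr(fn, "metric") <- metric
  fn
}

#' Evaluate the screening fitness of one raw weight vector
#'
#' Convenience wrapper over [oa_fitness()] for a single evaluation.
#'
#' @inheritParams oa_fitness
#' @param raw raw weight vector of length `n_atoms(query)`.
#' @return `1 - metric` of the induced screening run.
#' @export
fitness_vs <- function(raw, query, dataset, metric = c("auc", "bedroc"),
                       alpha = 53.6) {
  if (length(raw) != query$n) stop("raw weight length must equal query atoms")
  oa_fitness(query, dataset, metric, alpha)(raw)
}

# ---------------------------------------------------------------------------
# The fitted-model interface
# ---------------------------------------------------------------------------

#' Optimize the assignment-edge weights of a query molecule
#'
#' Fits per-atom assignment-edge weights of `query` by maximizing a
#' virtual-screening metric of the weighted optimal-assignment ranking over
#' `data`, using constriction PSO (default) or a differential evolution
#' variant.  The optimizer searches the bounded raw space `[-0.5, 0.5]^m`;
#' weights are normalized onto the constraint set (nonnegative, summing to
#' `m`) inside every fitness evaluation.
#'
#' @param query `oa_mol` query molecule.
#' @param data an `oa_dataset` of labeled actives and decoys.
#' @param metric optimized metric, `"auc"` or `"bedroc"`.
#' @param method `"pso"`, `"de_rand_1"`, `"de_best_2"` or
#'   `"de_current_to_best_1"`.
#' @param budget total fitness evaluations (default 15000).
#' @param pop_size population / swarm size (default 30).
#' @param seed integer seed; the run is fully reproducible from it.
#' @param alpha BEDROC weighting parameter.
#' @param control optional list of engine parameters overriding the defaults
#'   (`phi1`, `phi2`, `chi`, `v_init`, `grid_range` for PSO; `f`, `cr`,
#'   `lambda` for DE).
#' @return an object of class `oa_fit` with components `weights` (the
#'   normalized `oa_weights`), `raw` (best raw vector), `trace` (best-so-far
#'   fitness per evaluation), `train_metric` (the achieved metric on `data`),
#'   `metric`, `method`, `seed`, `n_eval`, `query` and `call`.  Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`.
#' @seealso [run_optimization()] for the plain-list interface.
#' @export
oa_fit <- function(query, data, metric = c("auc", "bedroc"),
                   method = c("pso", "de_rand_1", "de_best_2",
                              "de_current_to_best_1"),
                   budget = 15000, pop_size = 30, seed = NULL,
                   alpha = 53.6, control = list()) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  fn <- oa_fitness(query, data, metric, alpha)
  res <- if (method == "pso") {
    do.call(optim_pso, c(list(fitness = fn, m = query$n, budget = budget,
                              pop_size = pop_size), control))
  } else {
    variant <- sub("^de_", "", method)
    do.call(optim_de, c(list(fitness = fn, m = query$n, budget = budget,
                             variant = variant, pop_size = pop_size), control))
  }
  structure(list(weights = normalize_weights(res$best_par),
                 raw = res$best_par,
                 trace = res$trace,
                 best_fit = res$best_fit,
                 train_metric = 1 - res$best_fit,
                 metric = metric, method = method,
                 alpha = alpha,
                 seed = seed, n_eval = res$n_eval,
                 pop_size = pop_size,
                 query = query,
                 call = match.call()),
            class = "oa_fit")
}

#' Run a weight optimization from a plain configuration
#'
#' The module-level counterpart of [oa_fit()]: takes an algorithm
#' configuration list and returns the optimization-run record.
#'
#' @param query `oa_mol` query.
#' @param dataset `oa_dataset`.
#' @param config list with elements `method` (see [oa_fit()]), `metric`,
#'   `pop_size` and optional engine parameters under `control`.
#' @param budget total fitness evaluations.
#' @param seed integer seed.
#' @return the `oa_fit` object (also an optimization-run record: seed, config,
#'   best solution, fitness-vs-evaluations trace, total evaluations).
#' @export
run_optimization <- function(query, dataset, config = list(), budget = 1500,
                             seed = NULL) {
  oa_fit(query, dataset,
         metric = if (is.null(config$metric)) "auc" else config$metric,
         method = if (is.null(config$method)) "pso" else config$method,
         budget = budget,
         pop_size = if (is.null(config$pop_size)) 30 else config$pop_size,
         seed = seed,
         alpha = if (is.null(config$alpha)) 53.6 else config$alpha,
         control = if (is.null(config$control)) list() else config$control)
}

#' @export
print.oa_fit <- function(x, ...) {
  cat("Edge-weight optimization (", x$method, ", ", toupper(x$metric),
      ")\n", sep = "")
  cat("  query: ", x$query$id, " (", x$query$n, " atoms)\n", sep = "")
  cat(sprintf("  evaluations: %d   best training %s: %.4f\n",
              x$n_eval, toupper(x$metric), x$train_metric))
  invisible(x)
}

#' @export
summary.oa_fit <- function(object, ...) {
  w <- as.numeric(object$weights)
  cat("Edge-weight optimization summary\n")
  print(object)
  cat("  weight range: [", sprintf("%.3f", min(w)), ", ",
      sprintf("%.3f", max(w)), "], top atoms: ",
      paste(order(w, decreasing = TRUE)[seq_len(min(5, length(w)))],
            collapse = ", "), "\n", sep = "")
  conv <- convergence_point(1 - object$trace, mode = "relative")
  cat("  convergence point (1% of best): evaluation ", conv, "\n", sep = "")
  invisible(object)
}

#' @export
coef.oa_fit <- function(object, ...) as.numeric(object$weights)

#' Score new molecules with the fitted weights
#'
#' @param object an `oa_fit`.
#' @param newdata an `oa_dataset` or list of `oa_mol`.
#' @param ... unused.
#' @return an [ranked_list()] (for a dataset) or a data.frame of id/score.
#' @export
predict.oa_fit <- function(object, newdata, ...) {
  oa_screen(object$query, newdata, weights = object$weights)
}

#' Plot the fitness trace of a weight optimization
#'
#' @param x an `oa_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.oa_fit <- function(x, ...) {
  graphics::plot(seq_along(x$trace), 1 - x$trace, type = "l",
                 xlab = "fitness evaluations",
                 ylab = paste("best", toupper(x$metric), "so far"), ...)
  invisible(x)
}

#' Export an optimization run as JSON
#'
#' @param x an `oa_fit`.
#' @param path output path.
#' @param trace_every store every k-th trace point (the trace is monotone;
#'   default 1 stores all).
#' @export
write_run <- function(x, path, trace_every = 1L) {
  stopifnot(inherits(x, "oa_fit"))
  keep <- seq(1L, length(x$trace), by = trace_every)
  jsonlite::write_json(
    list(query_id = x$query$id, method = x$method, metric = x$metric,
         seed = x$seed, n_eval = x$n_eval, pop_size = x$pop_size,
         train_metric = x$train_metric,
         raw = x$raw, weights = as.numeric(x$weights),
         trace_eval = keep, trace = x$trace[keep]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
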