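sphere <- function(x) sum(x^2)

test_that("constriction coefficient matches the closed form", {
  chi <- pso_constriction(2.05, 2.05)
  expect_equal(chi, 2 / abs(2 - 4.1 - sqrt(4.1^2 - 4 * 4.1)), tolerance = 1e-12)
  expect_equal(round(chi, 2), 0.73)
  expect_error(pso_constriction(1, 1), "phi1")
})

test_that("PSO velocity update reproduces the 1-D worked example", {
  # x = 0, v = 0.1, both attractors at 1, r1 = r2 = 1, chi = 0.7298
  v2 <- pso_velocity(x = 0, v = 0.1, pbest = 1, nbest = 1,
                     chi = 0.7298, r1 = 1, r2 = 1)
  expect_equal(v2, 0.7298 * (0.1 + 2.05 + 2.05), tolerance = 1e-12)
  # a particle sitting at both attractors with zero velocity stays put
  expect_equal(pso_velocity(x = 0.3, v = 0, pbest = 0.3, nbest = 0.3), 0)
})

test_that("DE mutation covers the variants and crossover degenerate cases", {
  pop <- rbind(c(0, 0), c(0.1, 0.1), c(0.3, 0.3), c(-0.1, -0.1),
               c(0.2, 0.2), c(-0.3, -0.3))
  # 1-D arithmetic: base 0.1 + 0.8 * (0.3 - (-0.1)) = 0.42
  cand <- de_mutate(pop, i = 1, variant = "rand_1", best_idx = 5,
                    f = 0.8, cr = 1, idx = c(2, 3, 4), jr = 1)
  expect_equal(unname(cand), c(0.42, 0.42), tolerance = 1e-12)
  # CR = 0: exactly one component (jr) comes from the mutant
  cand0 <- de_mutate(pop, i = 1, variant = "rand_1", best_idx = 5,
                     f = 0.8, cr = 0, idx = c(2, 3, 4), jr = 2)
  expect_equal(unname(cand0), c(0, 0.42), tolerance = 1e-12)
  # best_2 uses the best individual and two difference pairs
  cand2 <- de_mutate(pop, i = 1, variant = "best_2", best_idx = 5,
                     f = 0.5, cr = 1, idx = c(2, 3, 4, 6), jr = 1)
  expect_equal(unname(cand2),
               pmin(0.5, pmax(-0.5, pop[5, ] + 0.5 *
                                ((pop[2, ] - pop[3, ]) + (pop[4, ] - pop[6, ])))),
               tolerance = 1e-12)
  # current_to_best_1 arithmetic base
  cand3 <- de_mutate(pop, i = 2, variant = "current_to_best_1", best_idx = 5,
                     f = 0.8, cr = 1, lambda = 0.6, idx = c(3, 4), jr = 1)
  base <- pop[2, ] + 0.6 * (pop[5, ] - pop[2, ])
  expect_equal(unname(cand3),
               pmin(0.5, pmax(-0.5, base + 0.8 * (pop[3, ] - pop[4, ]))),
               tolerance = 1e-12)
  # candidates are clipped into the box
  candc <- de_mutate(rbind(c(0.5), c(0.4), c(0.45), c(-0.5)), 1, "rand_1",
                     best_idx = 2, f = 0.9, cr = 1, idx = c(2, 3, 4), jr = 1)
  expect_lte(candc, 0.5); expect_gte(candc, -0.5)
  expect_error(de_mutate(pop[1:3, ], 1, "best_2", best_idx = 2),
               "too small")
})

test_that("PSO solves the sphere benchmark inside the box", {
  ok <- 0
  for (s in 1:10) {
    set.seed(s)
    res <- optim_pso(sphere, m = 10, budget = 3000)
    if (res$best_fit < 1e-4) ok <- ok + 1
    expect_true(all(res$best_par >= -0.5 & res$best_par <= 0.5))
    expect_true(all(diff(res$trace) <= 0))       # monotone best-so-far
    expect_equal(res$n_eval, 3000)
  }
  expect_gte(ok, 9)
})

test_that("DE variants minimize the sphere with monotone traces", {
  for (v in c("rand_1", "best_2", "current_to_best_1")) {
    set.seed(101)
    res <- optim_de(sphere, m = 8, budget = 2000, variant = v)
    expect_lt(res$best_fit, 0.01)    # well below random search in the box
    expect_true(all(diff(res$trace) <= 0))
    expect_true(all(res$best_par >= -0.5 & res$best_par <= 0.5))
  }
})

test_that("a budget equal to the population size evaluates one generation", {
  set.seed(5)
  res <- optim_pso(sphere, m = 3, budget = 30)
  expect_equal(res$n_eval, 30)
  expect_equal(length(res$trace), 30)
  set.seed(5)
  X <- matrix(runif(30 * 3, -0.5, 0.5), 30, 3)
  expect_equal(res$best_fit, min(apply(X, 1, sphere)), tolerance = 1e-12)
})

test_that("screening fitness is deterministic, counted, and uniform at zero", {
  fx <- small_fixture()
  opt <- fx$dataset
  fn <- oa_fitness(fx$query, opt, metric = "auc")
  z <- rep(0, fx$query$n)
  f1 <- fn(z); f2 <- fn(z)
  expect_identical(f1, f2)
  expect_equal(attr(fn, "count")(), 2L)
  expect_equal(f1, 1 - auc(oa_screen(fx$query, opt)), tolerance = 1e-12)
  expect_equal(fitness_vs(z, fx$query, opt, "auc"), f1, tolerance = 1e-12)
  # fast BEDROC path agrees with the ranked-list implementation
  fnb <- oa_fitness(fx$query, opt, metric = "bedroc")
  expect_equal(fnb(z), 1 - bedroc(oa_screen(fx$query, opt)), tolerance = 1e-12)
})

test_that("weights focused on the planted pharmacophore beat uniform weights", {
  fx <- small_fixture()
  fn <- oa_fitness(fx$query, fx$dataset, metric = "auc")
  uniform <- fn(rep(0, fx$query$n))
  raw <- rep(-0.5, fx$query$n)
  raw[fx$fragment_atoms] <- 0.5
  focused <- fn(raw)
  expect_lt(focused, uniform)
})

test_that("optimization runs are reproducible from their seed", {
  fx <- small_fixture()
  fit1 <- oa_fit(fx$query, fx$dataset, budget = 90, pop_size = 30, seed = 77)
  fit2 <- oa_fit(fx$query, fx$dataset, budget = 90, pop_size = 30, seed = 77)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(fit1$raw, fit2$raw)
  expect_equal(fit1$n_eval, 90)
  # the fitted object exposes the modelling interface
  expect_s3_class(fit1, "oa_fit")
  expect_length(coef(fit1), fx$query$n)
  expect_equal(sum(coef(fit1)), fx$query$n, tolerance = 1e-9)
  pr <- predict(fit1, fx$dataset)
  expect_s3_class(pr, "oa_ranked")
  expect_output(print(fit1), "Edge-weight optimization")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_run(fit1, tmp)
  expect_equal(jsonlite::read_json(tmp)$n_eval, 90)
})

test_that("DE engine also drives the screening fitness end to end", {
  fx <- small_fixture()
  fit <- oa_fit(fx$query, fx$dataset, method = "de_rand_1", budget = 90,
                seed = 3)
  expect_equal(fit$n_eval, 90)
  expect_true(all(diff(fit$trace) <= 0))
  expect_true(all(fit$raw >= -0.5 & fit$raw <= 0.5))
})
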