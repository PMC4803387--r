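# Genotypes, CV fitness with caching, GA and grid search.

test_that("random genotypes stay in bounds and decode to valid params", {
  set.seed(301)
  for (alg in c("svm", "nn", "rf")) {
    space <- param_space(alg, include_w = TRUE)
    for (r in 1:20) {
      g <- random_genotype(space)
      expect_true(all(g >= space$lo & g <= space$hi))
      p <- decode_genotype(g, space)
      expect_s3_class(p, "pl_params")
      expect_equal(p$w %% 2, 1)
      expect_true(p$w >= 3 && p$w <= 21)
    }
  }
  space <- param_space("svm", include_w = FALSE, fixed = list(C = 2))
  expect_equal(space$name, "sigma")
  p <- decode_genotype(c(sigma = 1), space, w_default = 5)
  expect_equal(p$C, 2)
  expect_equal(p$w, 5L)
  expect_error(decode_genotype(c(bogus = 1), space), "missing gene")
  expect_error(param_space("svm", bounds = list(zzz = c(0, 1))), "unknown")
})

test_that("fitness hits the ceiling on a strongly separable fixture", {
  ds <- separable_fixture(81, n_each = 50, w = 3, sep = 8)
  space <- param_space("svm", include_w = FALSE)
  f <- fitness(c(C = 1, sigma = 10), ds, space, folds = 5, seed = 2)
  expect_equal(f$auc, 1)
  expect_equal(f$se, 0)
})

test_that("the cache returns identical values without retraining", {
  ds <- separable_fixture(82, n_each = 30, w = 3, sep = 4)
  space <- param_space("svm", include_w = FALSE)
  cache <- eval_cache()
  g <- c(C = 2, sigma = 9)
  f1 <- fitness(g, ds, space, folds = 5, seed = 3, cache = cache)
  expect_false(f1$cached)
  expect_equal(cache_trainings(cache), 1L)
  f2 <- fitness(g, ds, space, folds = 5, seed = 3, cache = cache)
  expect_true(f2$cached)
  expect_identical(f2$auc, f1$auc)
  expect_identical(f2$se, f1$se)
  expect_equal(cache_trainings(cache), 1L) # no second training
  # keys round to 4 decimals: a formatting-level difference still hits
  f3 <- fitness(c(C = 2 + 1e-9, sigma = 9), ds, space, folds = 5, seed = 3,
                cache = cache)
  expect_true(f3$cached)
})

test_that("the cache persists through its TSV serialization", {
  ds <- separable_fixture(83, n_each = 30, w = 3, sep = 4)
  space <- param_space("svm", include_w = FALSE)
  cache <- eval_cache()
  fitness(c(C = 1, sigma = 5), ds, space, folds = 5, seed = 1, cache = cache)
  fitness(c(C = 3, sigma = 2), ds, space, folds = 5, seed = 1, cache = cache)
  tf <- tempfile(fileext = ".tsv")
  save_cache(cache, tf)
  cache2 <- load_cache(tf)
  expect_equal(cache_size(cache2), 2)
  f <- fitness(c(C = 1, sigma = 5), ds, space, folds = 5, seed = 1,
               cache = cache2)
  expect_true(f$cached)
})

test_that("run_ga respects elitism and determinism", {
  oc <- gen_offset_corpus(42, n_seqs = 40)
  space <- param_space("svm", include_w = TRUE,
                       bounds = list(sigma = c(0.5, 15)))
  res <- run_ga(oc$corpus, "svm", seed = 11, generations = 4, pop = 6,
                folds = 4, space = space)
  expect_true(all(diff(res$trace$mean_auc) >= 0))
  expect_gte(res$best$fitness, res$trace$mean_auc[1])
  # zero generations returns the evaluated initial population's best
  r0 <- run_ga(oc$corpus, "svm", seed = 11, generations = 0, pop = 6,
               folds = 4, space = space)
  expect_equal(nrow(r0$trace), 1)
  expect_equal(r0$best$fitness, r0$trace$mean_auc[1])
  # byte-identical traces under one seed (runtime column aside)
  r1 <- run_ga(oc$corpus, "svm", seed = 11, generations = 4, pop = 6,
               folds = 4, space = space)
  expect_identical(res$trace[, setdiff(names(res$trace), "runtime_s")],
                   r1$trace[, setdiff(names(r1$trace), "runtime_s")])
  expect_identical(res$best$genotype, r1$best$genotype)
})

test_that("run_grid is exhaustive and cache-aware across methods", {
  ds <- separable_fixture(84, n_each = 30, w = 3, sep = 4)
  space <- param_space("svm", include_w = FALSE)
  # 1x1 grid returns its only point
  g1 <- run_grid(ds, "svm", grid = list(C = 1, sigma = 8), seed = 2,
                 folds = 4, space = space)
  expect_equal(nrow(g1$table), 1)
  expect_equal(g1$best$genotype, c(C = 1, sigma = 8))

  g <- run_grid(ds, "svm", grid = list(C = c(0.5, 1, 5),
                                       sigma = c(1, 8, 20)),
                seed = 2, folds = 4, space = space)
  expect_equal(nrow(g$table), 9)
  expect_equal(g$best$fitness, max(g$table$mean_auc))

  # a genotype previously evaluated (by any search) is a cache hit
  cache <- g$cache
  f <- fitness(c(C = 1, sigma = 8), ds, space, folds = 4, seed = 2,
               cache = cache)
  expect_true(f$cached)
  expect_error(run_grid(ds, "svm", grid = list(C = numeric(0), sigma = 1),
                        seed = 1, space = space), "empty grid")
  expect_error(run_grid(ds, "svm", grid = list(C = 1), seed = 1,
                        space = space), "grid axes")
})

test_that("GA beats random search at equal evaluation budget in >= 8/10 trials", {
  # shared discrete space; mutation 0.15 keeps a population of 10 diverse
  # enough to exploit (the published 0.05 presumes a larger population)
  oc <- gen_offset_corpus(7)
  space <- structure(
    data.frame(name = c("C", "sigma", "w"), type = c("int", "int", "odd"),
               lo = c(1, 1, 3), hi = c(30, 60, 21)),
    algorithm = "svm", fixed = list(), class = c("pl_space", "data.frame"))
  wins <- 0
  for (trial in 1:10) {
    ga <- run_ga(oc$corpus, "svm", seed = trial, generations = 12, pop = 10,
                 p_mut = 0.15, folds = 5, space = space)
    budget <- cache_trainings(ga$cache)
    # draw the random candidates before evaluating (fitness reseeds the RNG)
    set.seed(1000 + trial)
    candidates <- replicate(budget, random_genotype(space), simplify = FALSE)
    best_rand <- 0
    cache <- eval_cache()
    for (g in candidates) {
      f <- fitness(g, oc$corpus, space, folds = 5, seed = trial,
                   cache = cache)
      best_rand <- max(best_rand, f$auc)
    }
    if (ga$best$fitness >= best_rand) wins <- wins + 1
  }
  expect_gte(wins, 8)
})
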