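test_that("population initialization is uniform, correctly sized, and seeded", {
  cfg <- ga_config(population_size = 100, rng_seed = 12)
  pop <- init_population(cfg, n_classifiers = 3, n_labels = 5)
  expect_length(pop, 100)
  expect_true(all(lengths(pop) == 15L))
  expect_true(all(unlist(pop) >= 0 & unlist(pop) <= 1))
  expect_identical(init_population(cfg, 3, 5), pop)
  # law-of-large-numbers check on U(0, 1): 1e5 genes
  big <- init_population(ga_config(population_size = 100, rng_seed = 4),
                         n_classifiers = 20, n_labels = 50)
  expect_equal(mean(unlist(big)), 0.5, tolerance = 0.01)
})

test_that("fitness of degenerate chromosomes matches single-classifier scores", {
  bank <- complementary_bank(n_sentences = 60)
  n_lab <- length(bank$labels)
  # identity chromosome of classifier m decodes exactly classifier m
  for (m in 1:2) {
    genes <- rep(0, 2 * n_lab)
    genes[((m - 1) * n_lab + 1):(m * n_lab)] <- 1
    per_fold <- sapply(seq_along(bank$folds), function(f) {
      sel <- bank$tokens$fold == f
      unname(strict_match_scores(
        data.frame(sentence = bank$tokens$sentence[sel],
                   label = bank$tokens$gold[sel]),
        bank$labels[bank$outputs[sel, m]])$overall["f"])
    })
    expect_equal(compute_fitness(genes, bank), mean(per_fold),
                 tolerance = 1e-12)
  }
  # all-zero chromosome: every token decodes to O under the tie rule
  expect_equal(compute_fitness(rep(0, 2 * n_lab), bank), 0)
  expect_error(compute_fitness(rep(0.5, 3), bank), "does not match")
})

test_that("a bank with one perfect classifier yields fitness 100 under positive weights", {
  corp <- generate_corpus(corpus_gen_config(n_sentences = 40, rng_seed = 3))
  bank <- simulate_classifier_outputs(corp, list(reliability_profile(1)),
                                      k = 4, rng_seed = 2)
  expect_equal(bank$classifier_F, 100)
  expect_equal(compute_fitness(runif(length(bank$labels), 0.2, 1), bank), 100)
})

test_that("roulette selection is fitness-proportional", {
  pop <- list(1, 2)
  set.seed(8)
  picks <- replicate(1e4, roulette_select(pop, c(75, 25)))
  expect_equal(mean(picks == 1L), 0.75, tolerance = 0.02)
  expect_equal(roulette_select(list(1), 10), 1L)
  picks_eq <- replicate(5e3, roulette_select(pop, c(40, 40)))
  expect_equal(mean(picks_eq == 1L), 0.5, tolerance = 0.03)
  picks_zero <- replicate(5e3, roulette_select(pop, c(0, 0)))
  expect_equal(mean(picks_zero == 1L), 0.5, tolerance = 0.03)
  expect_error(roulette_select(list(), numeric()))
})

test_that("adaptive operator probabilities follow the closed forms", {
  cfg <- ga_config()
  # crossover: protected best pair, below-average pair, interior value
  expect_equal(adaptive_crossover_prob(0.9, 0.5, 0.9, cfg), 0)
  expect_equal(adaptive_crossover_prob(0.9, 0.5, 0.3, cfg), 1.0)
  expect_equal(adaptive_crossover_prob(0.9, 0.5, 0.7, cfg), 0.5,
               tolerance = 1e-12)
  # mutation: protected best, below-average, interior value
  expect_equal(adaptive_mutation_prob(0.9, 0.5, 0.9, cfg), 0)
  expect_equal(adaptive_mutation_prob(0.9, 0.5, 0.3, cfg), 0.5)
  expect_equal(adaptive_mutation_prob(0.8, 0.4, 0.6, cfg), 0.25,
               tolerance = 1e-12)
  # degenerate population: probabilities fall back to k1/k2
  expect_equal(adaptive_crossover_prob(0.5, 0.5, 0.5, cfg), cfg$k1)
  expect_equal(adaptive_mutation_prob(0.5, 0.5, 0.5, cfg), cfg$k2)
  expect_error(adaptive_crossover_prob(0.5, 0.4, 0.6, cfg), "exceeds")
  expect_error(adaptive_mutation_prob(0.5, 0.4, 0.6, cfg), "exceeds")
  # custom constants propagate
  cfg2 <- ga_config(k1 = 0.8, k2 = 0.4, k3 = 0.9, k4 = 0.3)
  expect_equal(adaptive_crossover_prob(0.9, 0.5, 0.3, cfg2), 0.9)
  expect_equal(adaptive_mutation_prob(0.9, 0.5, 0.3, cfg2), 0.3)
})

test_that("single-point crossover exchanges tails and conserves genes", {
  a <- c(1, 2, 3); b <- c(10, 20, 30)
  set.seed(30)
  none <- single_point_crossover(a, b, mu_c = 0)
  expect_identical(none, list(a, b))
  expect_error(single_point_crossover(a, b[1:2], 1), "mismatch")
  # with mu_c = 1 a cut always happens; gene multiset conserved positionwise
  for (i in 1:50) {
    pa <- runif(8); pb <- runif(8)
    kids <- single_point_crossover(pa, pb, 1)
    for (j in 1:8) {
      expect_equal(sort(c(kids[[1]][j], kids[[2]][j])), sort(c(pa[j], pb[j])))
    }
    expect_false(identical(kids[[1]], pa) && identical(kids[[2]], pb))
  }
  # explicit cut semantics at length 3: cut after position 1 or 2
  set.seed(7)
  kids <- single_point_crossover(a, b, 1)
  expect_true(identical(kids[[1]], c(1, 20, 30)) ||
                identical(kids[[1]], c(1, 2, 30)))
})

test_that("Laplacian mutation perturbs with scale delta and respects bounds", {
  set.seed(55)
  g <- runif(200)
  expect_identical(laplacian_mutate(g, 0, 0.1), g)
  mutated <- laplacian_mutate(g, 1, 0.1)
  expect_true(all(mutated >= 0 & mutated <= 1))
  expect_false(identical(mutated, g))
  # genes near the boundary stay inside after clamping
  near <- rep(c(0.98, 0.02), 100)
  expect_true(all(laplacian_mutate(near, 1, 0.5) >= 0))
  expect_true(all(laplacian_mutate(near, 1, 0.5) <= 1))
  # pre-clamp kernel calibration (small n here; the full-scale calibration
  # lives in the acceptance suite)
  x <- nervote:::rlaplace(2e4, 0.5, 0.1)
  expect_equal(mean(abs(x - 0.5)), 0.1, tolerance = 0.01)
  expect_equal(median(x), 0.5, tolerance = 0.01)
})

test_that("the GA is elitist, reproducible, and respects gene bounds", {
  bank <- complementary_bank(n_sentences = 50)
  cfg <- ga_config(population_size = 12, generations = 8, rng_seed = 31)
  sol <- run_ga(bank, cfg)
  expect_s3_class(sol, "ga_ensemble")
  expect_true(all(diff(sol$fitness_trace) >= 0))
  expect_equal(sol$fitness, max(sol$fitness_trace))
  expect_true(all(sol$genes >= 0 & sol$genes <= 1))
  expect_equal(dim(sol$weights), c(2L, length(bank$labels)))
  # identical config + bank + seed -> identical solution
  sol2 <- run_ga(bank, cfg)
  expect_identical(sol$genes, sol2$genes)
  expect_identical(sol$fitness_trace, sol2$fitness_trace)
  # different seed explores differently
  sol3 <- run_ga(bank, ga_config(population_size = 12, generations = 8,
                                 rng_seed = 32))
  expect_false(identical(sol$genes, sol3$genes))
})

test_that("injecting a classifier's identity chromosome floors the GA at that classifier's fitness", {
  bank <- complementary_bank(n_sentences = 60)
  n_lab <- length(bank$labels)
  best_m <- which.max(bank$classifier_F)
  ident <- rep(0, 2 * n_lab)
  ident[((best_m - 1) * n_lab + 1):(best_m * n_lab)] <- 1
  floor_fit <- compute_fitness(ident, bank)
  sol <- run_ga(bank, ga_config(population_size = 10, generations = 6,
                                rng_seed = 2), injected = list(ident))
  expect_gte(sol$fitness, floor_fit)
})

test_that("GA recovers the grid optimum on a tiny two-classifier bank", {
  # one entity type, single-token mentions: labels {B-e, O}, N*O = 4
  corp <- generate_corpus(corpus_gen_config(
    n_sentences = 40, entity_types = "e", entity_len = c(1, 1),
    entity_density = 1, rng_seed = 19))
  profiles <- list(reliability_profile(0.95, c(e = 0.6)),
                   reliability_profile(0.65, c(e = 0.95)))
  bank <- simulate_classifier_outputs(corp, profiles, k = 5, rng_seed = 3)
  f_star <- bf_grid_fitness(bank, step = 0.25)
  sol <- run_ga(bank, ga_config(population_size = 20, generations = 15,
                                rng_seed = 6))
  expect_gte(sol$fitness, f_star - 0.01)
})
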