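test_that("prepare_stopless frees TAG/TGA and keeps TAA", {
  std <- standard_code()
  sl <- prepare_stopless(std)
  expect_equal(names(sl)[sl == "*"], "TAA")
  expect_equal(unname(sl[c("TAG", "TGA")]), c("N", "N"))
  expect_equal(sum(sl == "N"), sum(std == "N") + 2)
  expect_length(sl, 64)
  expect_true(all(c(RESIDUES <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
                  %in% sl))
  expect_equal(as.character(prepare_stopless(sl)), as.character(sl))
})

test_that("mutate_code honors rate, frozen codons and residue retention", {
  std <- standard_code()
  sl <- prepare_stopless(std)
  cfg0 <- ga_config(mutation_rate = 0, seed = 1)
  set.seed(1)
  expect_equal(as.character(mutate_code(sl, cfg0)), as.character(sl))
  cfg <- ga_config(mutation_rate = 0.3, stopless = TRUE,
                   allow_residue_loss = FALSE)
  set.seed(42)
  for (i in 1:300) {
    m <- mutate_code(sl, cfg)
    expect_equal(unname(m[["TAA"]]), "*")          # frozen sole stop
    expect_true(all(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]] %in% m))
    sl <- m  # walk the chain so constraints are tested far from the start
  }
})

test_that("evolve with an empty reassignable set returns the start code", {
  std <- standard_code()
  cfg <- ga_config(population_size = 10, rounds = 3,
                   reassignable_codons = character(0), seed = 1)
  res <- evolve(std, cfg)
  expect_equal(as.character(res$best_code),
               as.character(prepare_stopless(std)))
  expect_equal(res$reassignments, count_reassignments(
    prepare_stopless(std), std))
})

test_that("best fitness is non-decreasing for every seed (elitism)", {
  std <- standard_code()
  for (seed in 1:10) {
    res <- evolve(std, ga_config(population_size = 20, rounds = 10,
                                 seed = seed))
    expect_false(is.unsorted(res$trace), info = paste("seed", seed))
  }
})

test_that("a small seeded run improves accessibility beyond the standard
           code", {
  res <- evolve(standard_code(),
                ga_config(population_size = 100, rounds = 100, seed = 11))
  expect_gt(res$report$f_unique, 6.1)
})

test_that("native restriction keeps a native codon for every residue", {
  std <- standard_code()
  res <- evolve(std, ga_config(population_size = 40, rounds = 25,
                               native_restriction = TRUE, seed = 3))
  best <- as.character(res$best_code)
  ref <- as.character(std)
  for (r in strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
    expect_true(any(best == r & ref == r), info = r)
  }
})

test_that("GA on <= 2 freed codons equals the exhaustive optimum", {
  freed <- c("TAG", "TGA")
  ex <- optimize_free_codons(freed, config = ga_config(seed = 1),
                             exhaustive_threshold = 2)
  ga <- optimize_free_codons(freed,
                             config = ga_config(population_size = 200,
                                                rounds = 100,
                                                mutation_rate = 0.5,
                                                seed = 5),
                             exhaustive_threshold = 0)
  expect_equal(ga$report$f_combined, ex$report$f_combined, tolerance = 1e-12)
  # only the freed codons moved
  std <- standard_code()
  moved <- names(std)[as.character(ex$best_code) != as.character(std)]
  expect_true(all(moved %in% freed))
  # the diversity ratchet would exclude this optimum: a competing
  # assignment has higher f_chem but much lower combined fitness
  alt <- as_plain(std)
  alt[["TAG"]] <- "I"
  alt[["TGA"]] <- "D"
  alt <- genetic_code(alt)
  expect_gt(f_chem(alt), f_chem(ex$best_code))
  expect_lt(combined_fitness(alt)$f_combined, ex$report$f_combined)
})

test_that("optimize_free_codons with no freed codons returns the standard
           code", {
  res <- optimize_free_codons(character(0), config = ga_config(seed = 1))
  expect_equal(as.character(res$best_code),
               as.character(standard_code()))
  expect_equal(res$reassignments, 0L)
})

test_that("identical seeds give identical GA traces", {
  cfg <- ga_config(population_size = 30, rounds = 15, seed = 99)
  a <- evolve(standard_code(), cfg)
  b <- evolve(standard_code(), cfg)
  expect_identical(a$trace, b$trace)
  expect_identical(serialize_code(a$best_code), serialize_code(b$best_code))
})

test_that("penalized runs reduce reassignment counts", {
  std <- standard_code()
  free <- evolve(std, ga_config(population_size = 60, rounds = 40,
                                seed = 2))
  pen <- evolve(std, ga_config(population_size = 60, rounds = 40,
                               penalty_alpha = 0.9, penalty_exponent = 2,
                               seed = 2))
  expect_lt(pen$reassignments, free$reassignments)
})
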