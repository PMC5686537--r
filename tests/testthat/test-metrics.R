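# Expected values below marked "frozen" were computed with the string-based
# oracles in helper-oracles.R and hard-coded after verification.

constant_code <- function(res = "A") {
  genetic_code(stats::setNames(rep(res, 64), codons()), stopless = TRUE,
               require_all_residues = FALSE, name = "constant")
}

test_that("snr_neighbors enumerates the 9 Hamming-1 codons", {
  expect_setequal(snr_neighbors("AAA"),
                  c("CAA", "GAA", "TAA", "ACA", "AGA", "ATA",
                    "AAC", "AAG", "AAT"))
  expect_true(all(c("TGA", "TAG") %in% snr_neighbors("TGG")))
  for (cd in c("TTT", "GGG", "ATG", "CGC")) {
    nb <- snr_neighbors(cd)
    expect_length(nb, 9)
    expect_false(cd %in% nb)
    expect_setequal(nb, oracle_neighbors(cd))
  }
})

test_that("unique_access matches the brute-force oracle", {
  std <- standard_code()
  expect_equal(unique_access(std, "GCT"), 6)  # frozen: {P,T,S,D,G,V}
  expect_equal(unique_access(std, "TGG"), 6)  # frozen: {R,G,*,S,L,C}
  expect_equal(unique_access(constant_code(), "ATG"), 0)
  for (seed in 1:10) {
    sc <- scrambled_pair(seed)
    cd <- sample(codons(), 3)
    for (x in cd) {
      expect_equal(unique_access(sc$pkg, x),
                   oracle_unique_access(sc$plain, x))
    }
  }
})

test_that("f_unique and access_distribution reproduce the standard-code
           statistics", {
  std <- standard_code()
  expect_equal(f_unique(std), 6.109375)
  expect_equal(round(f_unique(std), 1), 6.1)
  d <- access_distribution(std)
  expect_equal(round(unname(d["sd"]), 2), 0.69)
  expect_equal(unname(d["min"]), 5)
  expect_equal(unname(d["max"]), 7)
  expect_equal(unname(d["mean"]), f_unique(std))
  expect_equal(unname(access_distribution(constant_code())),
               c(0, 0, 0, 0))
  for (seed in 1:5) {
    code <- random_code(seed = seed)
    expect_gte(f_unique(code), 0)
    expect_lte(f_unique(code), 9)
    expect_equal(f_unique(code), oracle_f_unique(as_plain(code)))
  }
})

test_that("f_ratio counts directed conversion events", {
  std <- standard_code()
  expect_equal(f_ratio(std), oracle_f_ratio(as_plain(std)))
  for (seed in 1:5) {
    sc <- scrambled_pair(seed)
    r <- f_ratio(sc$pkg)
    expect_gt(r, 0)
    expect_lte(r, 1)
    expect_equal(r, oracle_f_ratio(sc$plain))
  }
  expect_error(f_ratio(constant_code()), "at least 2")
})

test_that("f_chem reproduces the calibrated statistic and its variants", {
  std <- standard_code()
  expect_equal(f_chem(std), 5.53125)
  expect_equal(round(f_chem(std), 2), 5.53)
  expect_equal(f_chem(constant_code()), 0)
  expect_equal(f_chem(std, sigma_classes(), distinct = TRUE),
               oracle_f_chem_distinct(as_plain(std),
                                      as.character(sigma_classes()) |>
                                        stats::setNames(names(sigma_classes()))))
  for (seed in 1:5) {
    sc <- scrambled_pair(seed)
    expect_equal(f_chem(sc$pkg), oracle_f_chem_nondistinct(sc$plain))
    expect_lte(f_chem(sc$pkg, distinct = TRUE),
               min(9, length(unique(as.character(default_classes())))))
  }
})

test_that("combined fitness composes its components", {
  std <- standard_code()
  rep <- combined_fitness(std, reference = std)
  expect_equal(rep$f_combined,
               (rep$f_unique / 9) * rep$f_ratio * (rep$f_chem / 9))
  expect_lte(rep$f_combined, 1)
  expect_equal(rep$reassignments, 0)
  expect_equal(rep$f_combined, oracle_fitness(as_plain(std)))
  expect_error(combined_fitness(constant_code()), "at least 2")
})

test_that("penalized fitness applies alpha^(R^exponent)", {
  std <- standard_code()
  two <- as_plain(std)
  two[c("TAG", "TGA")] <- "N"
  two <- genetic_code(two)
  base <- combined_fitness(two)$f_combined
  expect_equal(penalized_fitness(std, std, alpha = 0.9)$penalized_f,
               combined_fitness(std)$f_combined)  # R = 0
  expect_equal(penalized_fitness(two, std, alpha = 0.9,
                                 exponent = 1)$penalized_f, base * 0.81)
  expect_equal(penalized_fitness(two, std, alpha = 0.9,
                                 exponent = 2)$penalized_f, base * 0.9^4)
  expect_error(penalized_fitness(std, std, alpha = 1.2), "alpha")
})

test_that("edge census partitions the 288 Hamming-1 pairs", {
  std <- standard_code()
  ec <- edge_census(std)
  expect_equal(ec$within_class, 109)
  expect_equal(ec$synonymous, 67)     # frozen: oracle enumeration
  expect_equal(ec$stop_involving, 25) # frozen: oracle enumeration
  expect_equal(ec$synonymous + ec$within_class + ec$between_class +
                 ec$stop_involving, 288)
  ecc <- edge_census(constant_code())
  expect_equal(ecc$synonymous, 288)
  expect_equal(ecc$within_class + ecc$between_class + ecc$stop_involving, 0)
  cls <- stats::setNames(as.character(default_classes()),
                         names(default_classes()))
  for (seed in 1:10) {
    sc <- scrambled_pair(seed)
    ec <- edge_census(sc$pkg)
    expect_equal(ec$synonymous + ec$within_class + ec$between_class +
                   ec$stop_involving, 288)
    expect_equal(unlist(unclass(ec))[names(oracle_edge_census(sc$plain, cls))],
                 oracle_edge_census(sc$plain, cls))
  }
})

test_that("min_replacements matches brute force and is symmetric", {
  std <- standard_code()
  dm <- min_replacements(std)
  expect_equal(dm["L", "L"], 0)
  expect_equal(dm["M", "W"], 2)
  expect_equal(dm["F", "K"], 3)
  expect_true(all(diag(dm) == 0))
  expect_true(isSymmetric(dm))
  expect_true(all(dm[upper.tri(dm)] %in% 1:3))
  for (seed in 1:5) {
    sc <- scrambled_pair(seed)
    dm <- min_replacements(sc$pkg)
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
    picks <- expand.grid(a = rownames(dm), b = rownames(dm),
                         stringsAsFactors = FALSE)
    picks <- picks[sample(nrow(picks), 10), ]
    for (i in seq_len(nrow(picks))) {
      expect_equal(dm[picks$a[i], picks$b[i]],
                   oracle_min_repl(sc$plain, picks$a[i], picks$b[i]))
    }
  }
})

test_that("substitution_analysis recovers the direction of SNR bias", {
  std <- standard_code()
  dm <- min_replacements(std)
  # all mass on distance-1 pairs
  pairs <- expand.grid(wt = rownames(dm)[rownames(dm) != "*"],
                       mut = rownames(dm)[rownames(dm) != "*"],
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$wt != pairs$mut, ]
  d <- dm[cbind(pairs$wt, pairs$mut)]
  pairs$count <- ifelse(d == 1, 10L, 0L)
  res <- substitution_analysis(pairs, std)
  expect_lt(res$rho, 0)
  # uniform counts: no association
  pairs$count <- 5L
  res_u <- substitution_analysis(pairs, std)
  expect_lt(abs(res_u$rho), 0.05)
  # generated with known bias
  tab <- synthetic_substitutions(std, snr_bias = 20, n = 10000, seed = 1)
  res_g <- substitution_analysis(tab, std)
  expect_lt(res_g$rho, -0.3)
  expect_lt(res_g$p.value, 1e-6)
  expect_error(substitution_analysis(pairs[0, ], std), "empty")
})

test_that("evolvability is the mean per-codon accessibility", {
  std <- standard_code()
  expect_equal(evolvability("GCTGCTGCT", std), 6)
  for (cd in c("ATG", "TGG", "GCT")) {
    expect_equal(evolvability(cd, std), unique_access(std, cd))
  }
  expect_equal(evolvability("ATGGCT", constant_code()), 0)
  # linearity: mean of single-codon scores
  g <- random_gene(30, code = std, seed = 4)
  cds <- substring(g, seq(1, nchar(g), 3), seq(3, nchar(g), 3))
  expect_equal(evolvability(g, std),
               mean(vapply(cds, function(cd) unique_access(std, cd),
                           numeric(1))))
  expect_error(evolvability("", std), "multiple of 3")
  expect_error(evolvability("ATGG", std), "multiple of 3")
})
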