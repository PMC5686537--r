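small_cfg <- function(seed = 1, ...) {
  recoding_config(candidate_cap = 30, seed = seed, ...)
}

test_that("dp folding matches the exhaustive enumeration oracle", {
  f <- fold("GGGAAACCC")
  expect_equal(f$structure, "(((...)))")
  expect_equal(f$energy, -3)
  f0 <- fold("AAAAAAAAA")
  expect_equal(f0$structure, ".........")
  expect_equal(f0$energy, 0)
  set.seed(7)
  for (i in 1:15) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(5:10, 1),
                        replace = TRUE), collapse = "")
    f <- fold(seq)
    expect_equal(nchar(f$structure), nchar(seq))
    expect_equal(-f$energy, oracle_max_pairs(seq), info = seq)
    # brackets balance
    expect_silent(structure_distance(f, f))
  }
})

test_that("thermo backend returns a parsable structure", {
  f <- fold("GGGGAAAACCCC", backend = "thermo")
  expect_equal(nchar(f$structure), 12)
  expect_true(grepl("^[.()]+$", f$structure))
  expect_true(is.numeric(f$energy))
})

test_that("structure_distance is a symmetric pair-set distance", {
  a <- fold("GGGAAACCC")
  b <- fold("AAAAAAAAA")
  expect_equal(structure_distance(a, a), 0)
  expect_equal(structure_distance(a, b), 3)
  expect_equal(structure_distance(b, a), structure_distance(a, b))
  expect_error(structure_distance(a, fold("AAAA")), "length")
})

test_that("recoding to the same code is the identity", {
  std <- standard_code()
  g <- random_gene(25, code = std, seed = 8)
  res <- recode_gene("AGGA", g, std, std, config = small_cfg(seed = 2))
  expect_identical(res$recoded, g)
  expect_true(res$translation_preserved)
})

test_that("unencodable residues give an informative error", {
  std <- standard_code()
  # target code with no codon for tryptophan
  tgt <- as_plain(std)
  tgt[["TGG"]] <- "C"
  tgt <- genetic_code(tgt, require_all_residues = FALSE, name = "noW")
  g <- paste0("TGG", random_gene(12, code = std, seed = 3))
  expect_error(recode_gene("AGGA", g, std, tgt, config = small_cfg()),
               "residue W at codon position 1")
})

test_that("translation is preserved on random gene/code pairs", {
  std <- standard_code()
  for (seed in 1:15) {
    g <- random_gene(sample(14:20, 1), code = std, seed = seed)
    tgt <- random_code(seed = seed + 500)
    res <- recode_gene("AGGA", g, std, tgt,
                       config = small_cfg(seed = seed))
    expect_true(res$translation_preserved, info = paste("seed", seed))
    expect_identical(translate(res$recoded, tgt), translate(g, std))
  }
})

test_that("recoding is deterministic under a fixed seed", {
  std <- standard_code()
  g <- random_gene(20, code = std, seed = 21)
  tgt <- random_code(seed = 22)
  a <- recode_gene("AGGA", g, std, tgt, config = small_cfg(seed = 5))
  b <- recode_gene("AGGA", g, std, tgt, config = small_cfg(seed = 5))
  expect_identical(a$recoded, b$recoded)
  expect_identical(a$regions, b$regions)
})

test_that("the returned leader scores no worse than any sampled candidate", {
  std <- standard_code()
  g <- random_gene(20, code = std, seed = 31)
  tgt <- random_code(seed = 32)
  lr <- recode_leader("AGGA", g, std, tgt, config = small_cfg(seed = 6))
  expect_lte(lr$score, min(lr$sampled_scores) + 1e-12)
  expect_lte(lr$score, lr$best_sampled_score + 1e-12)
})

test_that("full scanning of a small gene finds the exhaustive optimum", {
  std <- standard_code()
  # 4-codon leader-only gene; scan fraction 1 covers the whole product
  g <- random_gene(4, code = std, seed = 41)
  tgt <- random_code(seed = 42)
  cfg <- recoding_config(leader_cds_length = 12, leader_scan_fraction = 1,
                         candidate_cap = 1e6, seed = 7)
  lr <- recode_leader("AGGA", g, std, tgt, config = cfg)
  # independent exhaustive enumeration of every assembly
  pep <- strsplit(translate(g, std), "")[[1]]
  cand <- lapply(pep, function(r) names(tgt)[as.character(tgt) == r])
  wt <- fold(paste0("AGGA", g))
  combos <- expand.grid(cand, stringsAsFactors = FALSE)
  scores <- apply(combos, 1, function(row) {
    f <- fold(paste0("AGGA", paste(row, collapse = "")))
    abs(f$energy - wt$energy) + structure_distance(f, wt)
  })
  expect_equal(lr$score, min(scores), tolerance = 1e-12)
  expect_equal(lr$n_total, nrow(combos))
})

test_that("invalid fold input and malformed genes are rejected", {
  expect_error(fold(""), "non-empty")
  expect_error(fold("ACGX"), "non-empty|A,C,G")
  std <- standard_code()
  expect_error(recode_gene("AGGA", "ATGG", std, std,
                           config = small_cfg()), "multiple of 3")
})
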