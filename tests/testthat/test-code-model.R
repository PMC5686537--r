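test_that("standard code matches the canonical table", {
  std <- standard_code()
  expect_equal(unname(std[["ATG"]]), "M")
  expect_equal(unname(std[["TGG"]]), "W")
  expect_equal(sum(std == "*"), 3)
  expect_setequal(names(std)[std == "*"], c("TAA", "TAG", "TGA"))
  expect_equal(sum(std == "L"), 6)
  expect_equal(sum(std == "W"), 1)
  expect_equal(length(std), 64)
})

test_that("parse_code round-trips all three dialects", {
  std <- standard_code()
  for (fmt in c("string", "json", "tsv")) {
    txt <- serialize_code(std, format = fmt)
    back <- parse_code(txt)
    expect_equal(as.character(back), as.character(std), info = fmt)
    expect_equal(names(back), names(std), info = fmt)
  }
})

test_that("U-alphabet input normalizes to the T-alphabet code", {
  std <- standard_code()
  u_names <- chartr("T", "U", names(std))
  back <- parse_code(serialize_code(
    genetic_code(stats::setNames(as.character(std), u_names)), "tsv"))
  expect_equal(as.character(back), as.character(std))
})

test_that("malformed code tables are rejected", {
  std <- standard_code()
  partial <- as.list(stats::setNames(as.character(std), names(std)))[1:63]
  expect_error(parse_code(as.character(jsonlite::toJSON(partial,
                                                        auto_unbox = TRUE))),
               "missing codon")
  bad <- stats::setNames(as.character(std), names(std))
  bad[["ATG"]] <- "X"
  expect_error(genetic_code(bad), "invalid product")
  dup <- c(stats::setNames(as.character(std), names(std)),
           c(ATG = "M"))
  expect_error(genetic_code(dup), "duplicate")
  nostop <- stats::setNames(rep("A", 64), names(std))
  expect_error(genetic_code(nostop, require_all_residues = FALSE),
               "no stop codon")
  expect_silent(genetic_code(nostop, stopless = TRUE,
                             require_all_residues = FALSE))
})

test_that("count_reassignments counts differing codons symmetrically", {
  std <- standard_code()
  expect_equal(count_reassignments(std, std), 0)
  one <- as_plain(std)
  one[["TAG"]] <- "N"
  one <- genetic_code(one)
  expect_equal(count_reassignments(one, std), 1)
  two <- as_plain(std)
  two[c("TAG", "TGA")] <- "N"
  two <- genetic_code(two)
  expect_equal(count_reassignments(two, std), 2)
  # symmetry and triangle inequality over the 64-position Hamming space
  for (seed in 1:5) {
    a <- random_code(seed = seed)
    b <- random_code(seed = seed + 100)
    expect_equal(count_reassignments(a, b), count_reassignments(b, a))
    expect_lte(count_reassignments(a, b),
               count_reassignments(a, std) + count_reassignments(std, b))
  }
})

test_that("translation works and validates input", {
  std <- standard_code()
  expect_equal(translate("ATGGCTTAA", std), "MA*")
  expect_equal(translate("auggcuuaa", std), "MA*")
  expect_error(translate("ATGG", std), "multiple of 3")
  expect_error(translate("", std), "multiple of 3")
})

test_that("class tables validate coverage and round-trip", {
  def <- default_classes()
  expect_equal(unname(def[["*"]]), "STOP")
  expect_equal(length(unique(def[setdiff(names(def), "*")])), 3)
  sig <- sigma_classes()
  expect_equal(length(unique(sig[setdiff(names(sig), "*")])), 7)
  expect_error(chem_class_table(c(A = "x")), "without a class")
  tf <- tempfile(fileext = ".json")
  write_classes(def, tf, "json")
  expect_equal(as.character(read_classes(tf)), as.character(def))
  tf2 <- tempfile(fileext = ".tsv")
  write_classes(sig, tf2, "tsv")
  expect_equal(as.character(read_classes(tf2)), as.character(sig))
})
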