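# Synthetic-data generators: random genes, scrambled codes, and SNR-biased
# substitution tables. Every generator is deterministic under a fixed seed.

#' Generate a random coding sequence
#'
#' Codons are drawn per position among the code's sense codons with weights
#' `p^g * (1-p)^(3-g)` where `g` is the codon's G+C count and `p` the GC
#' target, which steers the empirical GC content toward the target without
#' modeling organism-specific codon usage.
#'
#' @param length_codons Gene length in codons.
#' @param gc GC-content target in (0, 1).
#' @param code A [genetic_code()]; internal stop codons are never emitted.
#' @param seed Random seed.
#' @param start_codon Prepend ATG (counted in `length_codons`).
#' @param stop_codon Append a stop codon of `code` (counted in
#'   `length_codons`).
#' @return Character scalar of length `3 * length_codons`.
#' @export
#' @examples
#' random_gene(10, code = standard_code(), seed = 1)
random_gene <- function(length_codons, gc = 0.5, code = standard_code(),
                        seed = NULL, start_codon = FALSE,
                        stop_codon = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n_body <- length_codons - start_codon - stop_codon
  if (n_body < 0 || (start_codon && stop_codon && length_codons < 2)) {
    stop("length_codons too small for the requested start/stop",
         call. = FALSE)
  }
  sense <- names(code)[as.character(code) != "*"]
  if (length(sense) == 0) stop("code has no sense codons", call. = FALSE)
  g <- vapply(strsplit(sense, ""), function(b) sum(b %in% c("G", "C")),
              numeric(1))
  w <- gc^g * (1 - gc)^(3 - g)
  if (sum(w) == 0) {
    stop("GC target infeasible under the code's codon set", call. = FALSE)
  }
  body <- sample(sense, n_body, replace = TRUE, prob = w)
  parts <- c(if (start_codon) "ATG", body,
             if (stop_codon) names(code)[as.character(code) == "*"][1])
  paste(parts, collapse = "")
}

#' Generate a random genetic code
#'
#' Uniformly permutes the product assignments of `base` over the 64 codons,
#' which preserves the product multiset: all residues stay encoded and the
#' stop-codon count is unchanged.
#'
#' @param seed Random seed.
#' @param base Code whose product multiset is scrambled.
#' @return A [genetic_code()].
#' @export
#' @examples
#' f_unique(random_code(seed = 1))
random_code <- function(seed = NULL, base = standard_code()) {
  if (!is.null(seed)) set.seed(seed)
  genetic_code(setNames(sample(as.character(base)), names(base)),
               name = "random", reference = attr(base, "name"))
}

#' Generate an SNR-biased substitution count table
#'
#' Samples `n` ordered residue substitutions with probability proportional
#' to `snr_bias^(1 - d)` where `d` is the minimum number of nucleotide
#' replacements the conversion requires under `code`. `snr_bias = 1` gives
#' uniform sampling over pairs; larger values concentrate events on
#' single-replacement-accessible pairs, emulating the statistical structure
#' of error-based mutagenesis data.
#'
#' @param code A [genetic_code()].
#' @param snr_bias Odds multiplier per avoided extra replacement (> 0).
#' @param n Total number of events.
#' @param seed Random seed.
#' @return Data frame with columns `wt`, `mut`, `count` (all ordered residue
#'   pairs, zero counts included).
#' @export
#' @examples
#' head(synthetic_substitutions(snr_bias = 20, n = 1000, seed = 1))
synthetic_substitutions <- function(code = standard_code(), snr_bias = 20,
                                    n = 10000, seed = NULL) {
  if (snr_bias <= 0) stop("snr_bias must be positive", call. = FALSE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  dm <- min_replacements(code)
  enc <- intersect(RESIDUES, rownames(dm))
  pairs <- expand.grid(wt = enc, mut = enc, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$wt != pairs$mut, ]
  d <- dm[cbind(pairs$wt, pairs$mut)]
  p <- snr_bias^(1 - d)
  counts <- as.vector(stats::rmultinom(1, n, p / sum(p)))
  data.frame(wt = pairs$wt, mut = pairs$mut, count = counts,
             row.names = NULL, stringsAsFactors = FALSE)
}
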