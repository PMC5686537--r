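# Accessibility and fitness metrics.
#
# All metrics are built on the 576 directed single-nucleotide-replacement
# (SNR) events of a code: each of the 64 codons has exactly 9 Hamming-1
# neighbors. Stop ("*") counts as a reachable product for unique
# accessibility, so the per-codon count lies in 0..9.

#' SNR neighbors of a codon
#'
#' @param codon Character scalar, a codon (U accepted, normalized to T).
#' @return Character vector of the 9 codons at Hamming distance 1.
#' @export
#' @examples
#' snr_neighbors("AAA")
snr_neighbors <- function(codon) {
  codon <- normalize_codon(codon)
  idx <- match(codon, codons())
  codons()[.neighbor_index_core()[idx, ]]
}

#' Unique SNR accessibility of a codon
#'
#' The number of distinct products among a codon's 9 neighbors that differ
#' from the codon's own product. Stop counts as a product.
#'
#' @param code A [genetic_code()].
#' @param codon Character scalar.
#' @return Integer in 0..9.
#' @export
#' @examples
#' unique_access(standard_code(), "GCT")
unique_access <- function(code, codon) {
  own <- as.character(code)[match(normalize_codon(codon), names(code))]
  length(setdiff(unique(as.character(code)[match(snr_neighbors(codon),
                                                 names(code))]), own))
}

per_codon_access <- function(code) {
  prod <- as.character(code)
  nb <- .neighbor_index_core()
  vapply(seq_len(64), function(k) {
    length(setdiff(unique(prod[nb[k, ]]), prod[k]))
  }, integer(1))
}

#' Mean unique SNR accessibility of a code
#'
#' Arithmetic mean of [unique_access()] over all 64 codons (stop codons
#' included as sources). For the standard code this is 6.1.
#'
#' @param code A [genetic_code()].
#' @return Numeric in \[0, 9\].
#' @export
#' @examples
#' f_unique(standard_code())
f_unique <- function(code) {
  mean(per_codon_access(code))
}

#' Distribution of per-codon unique accessibility
#'
#' @param code A [genetic_code()].
#' @return Named numeric vector with `mean`, `sd` (population SD over the 64
#'   codons), `min` and `max`.
#' @export
#' @examples
#' access_distribution(standard_code())
access_distribution <- function(code) {
  v <- per_codon_access(code)
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)),
    min = min(v), max = max(v))
}

directed_conversions <- function(code) {
  # Incoming directed SNR events per residue: pairs (C -> C') at Hamming
  # distance 1 with product(C) != product(C'), both products non-stop.
  prod <- as.character(code)
  nb <- .neighbor_index_core()
  src <- rep(prod, each = 9)
  dst <- prod[t(nb)]
  keep <- src != dst & src != "*" & dst != "*"
  counts <- table(factor(dst[keep], levels = RESIDUES))
  setNames(as.integer(counts), RESIDUES)
}

#' Evenness of incoming SNR conversions (F_ratio)
#'
#' For each encoded residue, counts the directed SNR events converting any
#' other product into that residue (stop is excluded from both ends), then
#' returns the minimum over residues divided by the maximum. Codes that
#' spread their codons evenly across residues score close to 1.
#'
#' @param code A [genetic_code()].
#' @return Numeric in \[0, 1\].
#' @export
#' @examples
#' f_ratio(standard_code())
f_ratio <- function(code) {
  enc <- intersect(RESIDUES, as.character(code))
  if (length(enc) < 2) {
    stop("f_ratio requires at least 2 encoded residues", call. = FALSE)
  }
  inc <- directed_conversions(code)[enc]
  if (max(inc) == 0) {
    stop("f_ratio undefined: no inter-residue SNR conversions", call. = FALSE)
  }
  min(inc) / max(inc)
}

#' Chemical-class accessibility (F_chem)
#'
#' Default (`distinct = FALSE`, the calibrated rule): for each sense codon,
#' the number of unique non-stop products reachable by an SNR that differ
#' from the codon's own product — one chemical-class instance per accessible
#' amino acid, counted non-distinctly, so the class partition does not enter;
#' stop has no chemical class, and stop codons contribute nothing as sources.
#' The sum is averaged over all 64 codons. For the standard code this gives
#' 5.53.
#'
#' With `distinct = TRUE`, counts the distinct classes of `classes`
#' represented among the non-synonymous accessible products (stop as its own
#' pseudo-class), averaged over the 64 codons.
#'
#' @param code A [genetic_code()].
#' @param classes A [chem_class_table()]; only consulted when
#'   `distinct = TRUE`.
#' @param distinct Switch between the two counting rules.
#' @return Numeric in \[0, 9\].
#' @export
#' @examples
#' f_chem(standard_code())
f_chem <- function(code, classes = default_classes(), distinct = FALSE) {
  prod <- as.character(code)
  nb <- .neighbor_index_core()
  cls <- setNames(as.character(classes), names(classes))
  if (anyNA(cls[unique(prod)])) {
    stop("product without a chemical class", call. = FALSE)
  }
  v <- vapply(seq_len(64), function(k) {
    u <- setdiff(unique(prod[nb[k, ]]), prod[k])
    if (distinct) {
      length(unique(cls[u]))
    } else if (prod[k] == "*") {
      0L
    } else {
      length(setdiff(u, "*"))
    }
  }, integer(1))
  mean(v)
}

#' Combined code fitness
#'
#' The product of the three components, each normalized by its theoretical
#' maximum: `(f_unique / 9) * (f_ratio / 1) * (f_chem / 9)`.
#'
#' @inheritParams f_chem
#' @param reference Optional [genetic_code()]; when given, the report also
#'   carries the reassignment count against it.
#' @return A `fitness_report` list with elements `f_unique`, `f_ratio`,
#'   `f_chem`, `f_combined` and (optionally) `reassignments`.
#' @export
#' @examples
#' combined_fitness(standard_code())
combined_fitness <- function(code, classes = default_classes(),
                             distinct = FALSE, reference = NULL) {
  rep <- list(
    f_unique = f_unique(code),
    f_ratio = f_ratio(code),
    f_chem = f_chem(code, classes, distinct = distinct))
  rep$f_combined <- (rep$f_unique / 9) * rep$f_ratio * (rep$f_chem / 9)
  if (!is.null(reference)) {
    rep$reassignments <- count_reassignments(code, reference)
  }
  structure(rep, class = "fitness_report")
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("<fitness_report>\n")
  cat(sprintf("  f_unique   %.4f\n", x$f_unique))
  cat(sprintf("  f_ratio    %.4f\n", x$f_ratio))
  cat(sprintf("  f_chem     %.4f\n", x$f_chem))
  cat(sprintf("  f_combined %.6f\n", x$f_combined))
  if (!is.null(x$reassignments)) {
    cat(sprintf("  reassignments %d\n", x$reassignments))
  }
  if (!is.null(x$penalized_f)) {
    cat(sprintf("  penalized_f %.6f\n", x$penalized_f))
  }
  invisible(x)
}

#' Reassignment-penalized fitness
#'
#' Combined fitness scaled by `alpha ^ (R ^ exponent)` where `R` is the
#' number of reassignments relative to `reference`. Linear penalties use
#' exponent 1, square penalties exponent 2.
#'
#' @inheritParams combined_fitness
#' @param reference The code against which reassignments are counted.
#' @param alpha Penalty factor in (0, 1).
#' @param exponent 1 (linear) or 2 (square).
#' @return A `fitness_report` with an additional `penalized_f` element.
#' @export
penalized_fitness <- function(code, reference, classes = default_classes(),
                              alpha = 0.95, exponent = 1,
                              distinct = FALSE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!exponent %in% c(1, 2)) {
    stop("exponent must be 1 or 2", call. = FALSE)
  }
  rep <- combined_fitness(code, classes, distinct = distinct,
                          reference = reference)
  rep$penalized_f <- rep$f_combined * alpha^(rep$reassignments^exponent)
  rep
}

#' Census of the 288 Hamming-1 codon pairs
#'
#' Every unordered codon pair at Hamming distance 1 falls in exactly one
#' category: `stop_involving` if either product is stop, `synonymous` if the
#' products are identical, `within_class` if they differ but share a
#' chemical class, `between_class` otherwise.
#'
#' @inheritParams f_chem
#' @return An `edge_census` list of the four counts (summing to 288).
#' @export
#' @examples
#' edge_census(standard_code())
edge_census <- function(code, classes = default_classes()) {
  prod <- as.character(code)
  nb <- .neighbor_index_core()
  cls <- setNames(as.character(classes), names(classes))
  syn <- within <- between <- stop_inv <- 0L
  for (k in seq_len(64)) {
    for (j in nb[k, ]) {
      if (j <= k) next  # each unordered pair once
      pa <- prod[k]; pb <- prod[j]
      if (pa == "*" || pb == "*") stop_inv <- stop_inv + 1L
      else if (pa == pb) syn <- syn + 1L
      else if (cls[[pa]] == cls[[pb]]) within <- within + 1L
      else between <- between + 1L
    }
  }
  structure(list(synonymous = syn, within_class = within,
                 between_class = between, stop_involving = stop_inv),
            class = "edge_census")
}

#' @export
print.edge_census <- function(x, ...) {
  cat("<edge_census> of 288 Hamming-1 codon pairs\n")
  cat(sprintf("  synonymous     %3d\n", x$synonymous))
  cat(sprintf("  within_class   %3d\n", x$within_class))
  cat(sprintf("  between_class  %3d\n", x$between_class))
  cat(sprintf("  stop_involving %3d\n", x$stop_involving))
  invisible(x)
}

#' Minimum nucleotide replacements between products
#'
#' Entry (a, b) is the minimum Hamming distance over all codon pairs
#' encoding a and b under `code`. The diagonal is 0 and off-diagonal entries
#' lie in 1..3.
#'
#' @param code A [genetic_code()].
#' @return Symmetric integer matrix over the products encoded by `code`
#'   (21 x 21 for a complete code, stop included).
#' @export
#' @examples
#' min_replacements(standard_code())["M", "W"]
min_replacements <- function(code) {
  prod <- as.character(code)
  enc <- PRODUCTS[PRODUCTS %in% prod]
  cd <- strsplit(names(code), "")
  ham <- outer(seq_len(64), seq_len(64), Vectorize(function(i, j) {
    sum(cd[[i]] != cd[[j]])
  }))
  out <- matrix(NA_integer_, length(enc), length(enc),
                dimnames = list(enc, enc))
  for (a in enc) {
    for (b in enc) {
      out[a, b] <- min(ham[prod == a, prod == b, drop = FALSE])
    }
  }
  out
}

#' Substitution-table analysis
#'
#' Normalizes an observed amino-acid substitution count table and computes
#' the Spearman rank correlation between the minimum number of nucleotide
#' replacements each conversion requires under `code` and its observed
#' frequency. SNR-dominated mutagenesis data show a strong anticorrelation.
#'
#' @param observed Data frame with columns `wt`, `mut` (residue one-letter
#'   codes) and `count` (non-negative).
#' @param code A [genetic_code()].
#' @param exact Passed to [stats::cor.test()]; the default uses the
#'   large-sample approximation.
#' @return List with `frequencies` (the normalized table), `rho`, `p.value`
#'   and `n_pairs`.
#' @export
substitution_analysis <- function(observed, code, exact = FALSE) {
  if (!all(c("wt", "mut", "count") %in% names(observed))) {
    stop("observed must have columns wt, mut, count", call. = FALSE)
  }
  if (nrow(observed) == 0) stop("empty substitution table", call. = FALSE)
  if (any(observed$count < 0)) stop("negative counts", call. = FALSE)
  bad <- !(observed$wt %in% RESIDUES) | !(observed$mut %in% RESIDUES)
  if (any(bad)) stop("invalid residue codes in substitution table",
                     call. = FALSE)
  observed$freq <- observed$count / sum(observed$count)
  dm <- min_replacements(code)
  d <- dm[cbind(observed$wt, observed$mut)]
  if (stats::var(observed$freq) == 0 || stats::var(d) == 0) {
    # degenerate table (e.g. exactly uniform counts): no association
    return(list(frequencies = observed, rho = 0, p.value = 1,
                n_pairs = nrow(observed)))
  }
  ct <- suppressWarnings(cor.test(d, observed$freq, method = "spearman",
                                  exact = exact))
  list(frequencies = observed, rho = unname(ct$estimate),
       p.value = ct$p.value, n_pairs = nrow(observed))
}

#' Gene-level evolvability score
#'
#' The mean, over a gene's codons, of the per-codon unique SNR accessibility
#' under `code`: how many distinct alternative products the gene's codons
#' can reach by single point mutations, averaged over the protein length.
#'
#' @param gene Character scalar, coding sequence (length divisible by 3).
#' @param code A [genetic_code()].
#' @return Numeric in \[0, 9\].
#' @export
#' @examples
#' evolvability("GCTGCTGCT", standard_code())
evolvability <- function(gene, code) {
  gene <- toupper(gsub("U", "T", toupper(gene)))
  if (nchar(gene) == 0 || nchar(gene) %% 3 != 0) {
    stop("gene length must be a positive multiple of 3", call. = FALSE)
  }
  cds <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
  acc <- per_codon_access(code)
  mean(acc[match(normalize_codon(cds), names(code))])
}
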