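# Independent brute-force oracles used to cross-check the package's metric
# and search implementations. Everything here works on plain named character
# vectors and string operations, independent of the package's C++ core.

ORACLE_BASES <- c("T", "C", "A", "G")

oracle_codons <- function() {
  out <- character(0)
  for (b1 in ORACLE_BASES) for (b2 in ORACLE_BASES) for (b3 in ORACLE_BASES) {
    out <- c(out, paste0(b1, b2, b3))
  }
  out
}

oracle_neighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(ORACLE_BASES, s[i])) {
      t <- s
      t[i] <- b
      out <- c(out, paste(t, collapse = ""))
    }
  }
  out
}

oracle_unique_access <- function(code, codon) {
  own <- code[[codon]]
  length(setdiff(unique(unname(code[oracle_neighbors(codon)])), own))
}

oracle_f_unique <- function(code) {
  mean(vapply(oracle_codons(), function(cd) oracle_unique_access(code, cd),
              numeric(1)))
}

oracle_f_ratio <- function(code) {
  # all 576 directed Hamming-1 events, both ends non-stop, products differ
  inc <- integer(0)
  for (cd in oracle_codons()) {
    if (code[[cd]] == "*") next
    for (nb in oracle_neighbors(cd)) {
      p <- code[[nb]]
      if (p != "*" && p != code[[cd]]) {
        inc[p] <- if (is.na(inc[p])) 1L else inc[p] + 1L
      }
    }
  }
  enc <- setdiff(unique(unname(code)), "*")
  counts <- vapply(enc, function(a) if (is.na(inc[a])) 0L else inc[a],
                   integer(1))
  min(counts) / max(counts)
}

oracle_f_chem_nondistinct <- function(code) {
  v <- vapply(oracle_codons(), function(cd) {
    if (code[[cd]] == "*") return(0L)
    u <- setdiff(unique(unname(code[oracle_neighbors(cd)])), code[[cd]])
    length(setdiff(u, "*"))
  }, integer(1))
  mean(v)
}

oracle_f_chem_distinct <- function(code, classes) {
  v <- vapply(oracle_codons(), function(cd) {
    u <- setdiff(unique(unname(code[oracle_neighbors(cd)])), code[[cd]])
    length(unique(unname(classes[u])))
  }, integer(1))
  mean(v)
}

oracle_edge_census <- function(code, classes) {
  cds <- oracle_codons()
  syn <- within <- between <- stop_inv <- 0L
  for (i in seq_along(cds)) {
    for (nb in oracle_neighbors(cds[i])) {
      j <- match(nb, cds)
      if (j <= i) next
      pa <- code[[cds[i]]]
      pb <- code[[nb]]
      if (pa == "*" || pb == "*") stop_inv <- stop_inv + 1L
      else if (pa == pb) syn <- syn + 1L
      else if (classes[[pa]] == classes[[pb]]) within <- within + 1L
      else between <- between + 1L
    }
  }
  c(synonymous = syn, within_class = within, between_class = between,
    stop_involving = stop_inv)
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

oracle_min_repl <- function(code, a, b) {
  ca <- names(code)[unname(code) == a]
  cb <- names(code)[unname(code) == b]
  min(outer(ca, cb, Vectorize(oracle_hamming)))
}

# Combined fitness from the oracle components (calibrated f_chem rule).
oracle_fitness <- function(code) {
  (oracle_f_unique(code) / 9) * oracle_f_ratio(code) *
    (oracle_f_chem_nondistinct(code) / 9)
}

# Maximum base-pair count over all valid secondary structures of a short
# sequence (exhaustive recursion; Watson-Crick + GT wobble, min loop 3).
oracle_max_pairs <- function(seq, min_loop = 3) {
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "CG", "GC", "GT", "TG")
  }
  ch <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      if (can_pair(ch[i], ch[k])) {
        inner <- if (i + 1 <= k - 1) rec(i + 1, k - 1) else 0L
        rest <- if (k + 1 <= j) rec(k + 1, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  if (length(ch) < 2) return(0L)
  rec(1, length(ch))
}

# A plain named character vector for the standard code, written out here
# independently of the package's constant.
oracle_standard <- function() {
  prods <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(prods, oracle_codons())
}

as_plain <- function(code) {
  stats::setNames(as.character(code), names(code))
}

# Small random scrambled code as plain vector + package object.
scrambled_pair <- function(seed) {
  code <- random_code(seed = seed)
  list(pkg = code, plain = as_plain(code))
}
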