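# RNA secondary-structure backends.
#
# The default backend is a self-contained base-pair-maximization dynamic
# program (Watson-Crick plus GU wobble, minimum hairpin loop of 3), with
# energy defined as -(number of pairs). A thermodynamic backend using the
# RNAfold program is available when that binary is on the PATH.

#' Fold a sequence
#'
#' @param sequence Character scalar over A, C, G, T/U.
#' @param backend `"dp"` (default, base-pair maximization) or `"thermo"`
#'   (RNAfold minimum free energy; requires the `RNAfold` binary).
#' @param min_loop Minimum hairpin loop length for the dp backend.
#' @return A `fold_result` list: `structure` (dot-bracket), `energy`
#'   (kcal/mol for `"thermo"`, -(pair count) for `"dp"`), `sequence`.
#' @export
#' @examples
#' fold("GGGAAACCC")
fold <- function(sequence, backend = c("dp", "thermo"), min_loop = 3) {
  backend <- match.arg(backend)
  sequence <- toupper(gsub("U", "T", toupper(sequence)))
  if (nchar(sequence) == 0 || grepl("[^ACGT]", sequence)) {
    stop("sequence must be non-empty over {A,C,G,T/U}", call. = FALSE)
  }
  if (backend == "dp") {
    res <- .nussinov_core(sequence, as.integer(min_loop))
    out <- list(structure = res$structure, energy = -res$pairs,
                sequence = sequence)
  } else {
    out <- fold_rnafold(sequence)
  }
  structure(out, class = "fold_result")
}

fold_rnafold <- function(sequence) {
  bin <- Sys.which("RNAfold")
  if (bin == "") {
    stop("thermo backend requires the RNAfold binary on the PATH",
         call. = FALSE)
  }
  rna <- chartr("T", "U", sequence)
  res <- system2(bin, args = c("--noPS"), input = rna, stdout = TRUE)
  line <- res[length(res)]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3) stop("could not parse RNAfold output", call. = FALSE)
  list(structure = m[2], energy = as.numeric(m[3]), sequence = sequence)
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "  (", x$energy, ")\n", sep = "")
  invisible(x)
}

# Dot-bracket -> set of base pairs as a 2-column matrix (i < j).
pair_set <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  pairs <- matrix(0L, nrow = 0, ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced structure", call. = FALSE)
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack) > 0) stop("unbalanced structure", call. = FALSE)
  pairs
}

#' Base-pair distance between two structures
#'
#' Size of the symmetric difference of the two structures' base-pair sets;
#' 0 iff the pair sets are identical.
#'
#' @param a,b `fold_result` objects (or lists with a `structure` element)
#'   for sequences of equal length.
#' @return Non-negative integer.
#' @export
#' @examples
#' structure_distance(fold("GGGAAACCC"), fold("AAAAAAAAA"))
structure_distance <- function(a, b) {
  if (nchar(a$structure) != nchar(b$structure)) {
    stop("structures have different lengths", call. = FALSE)
  }
  pa <- apply(pair_set(a$structure), 1, paste, collapse = "-")
  pb <- apply(pair_set(b$structure), 1, paste, collapse = "-")
  length(setdiff(pa, pb)) + length(setdiff(pb, pa))
}
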