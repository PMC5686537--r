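# Core data model: codons, genetic codes, chemical-class tables.

BASES <- c("T", "C", "A", "G")

#' The 20 standard residues (alphabetical one-letter codes)
#' @keywords internal
RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' All product symbols: 20 residues plus "*" (stop)
#' @keywords internal
PRODUCTS <- c(RESIDUES, "*")

# 64-character translation string of the standard code, canonical TCAG order
# (first position slowest: TTT, TTC, TTA, TTG, TCT, ...).
STANDARD_STRING <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

#' The 64 codons in canonical TCAG order
#'
#' Order is first position slowest: TTT, TTC, TTA, TTG, TCT, ..., GGG.
#' DNA alphabet (T, not U) is used throughout; U is accepted on input by the
#' parsers and normalized to T.
#'
#' @return Character vector of 64 codons.
#' @export
#' @examples
#' head(codons())
codons <- function() {
  as.vector(t(outer(BASES, as.vector(t(outer(BASES, BASES, paste0))),
                    paste0)))
}

normalize_codon <- function(x) {
  x <- toupper(gsub("U", "T", toupper(x)))
  bad <- !grepl("^[TCAG]{3}$", x)
  if (any(bad)) {
    stop("invalid codon(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  }
  x
}

#' Construct a genetic code
#'
#' A genetic code is a total mapping from the 64 codons to a product symbol:
#' one of the 20 standard one-letter residue codes or `"*"` for stop. Codes
#' are stored as named character vectors in canonical TCAG codon order.
#'
#' @param assignment Named character vector mapping all 64 codons to product
#'   symbols. Names may use the RNA alphabet (U); they are normalized to DNA.
#' @param name Label for the code.
#' @param reference Optional label of the code this one was derived from.
#' @param stopless Set to `TRUE` to permit a code with no stop codon
#'   (intermediate optimizer states only).
#' @param require_all_residues If `TRUE` (default) every one of the 20
#'   residues must have at least one codon.
#' @return An object of class `genetic_code`.
#' @export
#' @examples
#' std <- standard_code()
#' variant <- std
#' variant[["TAG"]] <- "Q"
#' variant <- genetic_code(variant, name = "TAG->Q")
genetic_code <- function(assignment, name = "unnamed", reference = NULL,
                         stopless = FALSE, require_all_residues = TRUE) {
  if (is.null(names(assignment))) {
    stop("assignment must be a named character vector (names are codons)",
         call. = FALSE)
  }
  nms <- normalize_codon(names(assignment))
  if (anyDuplicated(nms)) {
    stop("duplicate codon(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(codons(), nms)
  if (length(missing) > 0) {
    stop("missing codon(s): ", paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) ", ...", call. = FALSE)
  }
  prod <- as.character(assignment)
  bad <- !(prod %in% PRODUCTS)
  if (any(bad)) {
    stop("invalid product symbol(s): ",
         paste(unique(prod[bad]), collapse = ", "), call. = FALSE)
  }
  x <- setNames(prod[match(codons(), nms)], codons())
  if (!stopless && !any(x == "*")) {
    stop("code has no stop codon (use stopless = TRUE for intermediate ",
         "optimizer states)", call. = FALSE)
  }
  if (require_all_residues) {
    absent <- setdiff(RESIDUES, x)
    if (length(absent) > 0) {
      stop("residue(s) not encoded: ", paste(absent, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(x, class = "genetic_code", name = name, reference = reference)
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code>", attr(x, "name"), "\n")
  if (!is.null(attr(x, "reference"))) {
    cat("  derived from:", attr(x, "reference"), "\n")
  }
  cat("  stops:", paste(names(x)[x == "*"], collapse = " "), "\n")
  cat(" ", serialize_code(x, format = "string"), "\n")
  invisible(x)
}

#' The standard genetic code
#'
#' @return A [genetic_code()] with the canonical assignments (TAA/TAG/TGA
#'   stop, ATG -> M, TGG -> W, ...).
#' @export
#' @examples
#' standard_code()[["ATG"]]
standard_code <- function() {
  genetic_code(setNames(strsplit(STANDARD_STRING, "")[[1]], codons()),
               name = "standard")
}

#' Parse a genetic code from text or file
#'
#' Accepted dialects: a 64-character translation string in canonical TCAG
#' order; a JSON object `{"TTT": "F", ...}`; or a TSV table with columns
#' `codon` and `product`. U-alphabet codons are normalized to T.
#'
#' @param text Character scalar holding the document, or a character vector
#'   of lines.
#' @param name Label for the parsed code.
#' @param ... Passed on to [genetic_code()] (e.g. `stopless`).
#' @return A [genetic_code()].
#' @export
#' @examples
#' parse_code(serialize_code(standard_code()))
parse_code <- function(text, name = "parsed", ...) {
  if (length(text) == 1 && !grepl("[\n{]", text) && nchar(text) == 64 &&
      !grepl("\t", text)) {
    prod <- strsplit(text, "")[[1]]
    return(genetic_code(setNames(prod, codons()), name = name, ...))
  }
  doc <- paste(text, collapse = "\n")
  if (grepl("^\\s*\\{", doc)) {
    lst <- jsonlite::fromJSON(doc)
    return(genetic_code(unlist(lst), name = name, ...))
  }
  tab <- read.table(text = doc, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("codon", "product") %in% names(tab))) {
    stop("code TSV must have columns 'codon' and 'product'", call. = FALSE)
  }
  genetic_code(setNames(tab$product, tab$codon), name = name, ...)
}

#' @rdname parse_code
#' @param path File to read.
#' @export
read_code <- function(path, name = basename(path), ...) {
  parse_code(readLines(path, warn = FALSE), name = name, ...)
}

#' Serialize a genetic code
#'
#' @param code A [genetic_code()].
#' @param format One of `"string"` (64 characters, TCAG order), `"json"`, or
#'   `"tsv"`.
#' @return Character scalar.
#' @export
serialize_code <- function(code, format = c("string", "json", "tsv")) {
  format <- match.arg(format)
  switch(format,
    string = paste(code, collapse = ""),
    json = as.character(jsonlite::toJSON(as.list(setNames(as.character(code),
                                                          names(code))),
                                         auto_unbox = TRUE, pretty = TRUE)),
    tsv = paste(c("codon\tproduct",
                  paste(names(code), as.character(code), sep = "\t")),
                collapse = "\n"))
}

#' @rdname serialize_code
#' @param path File to write.
#' @export
write_code <- function(code, path,
                       format = c("string", "json", "tsv")) {
  writeLines(serialize_code(code, match.arg(format)), path)
  invisible(path)
}

#' Count codon reassignments between two codes
#'
#' The number of codons whose product differs between `code` and
#' `reference`; symmetric in its arguments.
#'
#' @param code,reference [genetic_code()] objects.
#' @return Integer count in 0..64.
#' @export
#' @examples
#' count_reassignments(standard_code(), standard_code())
count_reassignments <- function(code, reference) {
  sum(as.character(code) != as.character(reference)[match(names(code),
                                                          names(reference))])
}

#' Translate a coding sequence under a genetic code
#'
#' @param gene Character scalar, DNA (or RNA, normalized) of length divisible
#'   by 3.
#' @param code A [genetic_code()].
#' @return Character scalar of product symbols (stop rendered as `"*"`).
#' @export
#' @examples
#' translate("ATGGCTTAA", standard_code())
translate <- function(gene, code) {
  gene <- toupper(gsub("U", "T", toupper(gene)))
  if (nchar(gene) == 0 || nchar(gene) %% 3 != 0) {
    stop("gene length must be a positive multiple of 3", call. = FALSE)
  }
  cds <- substring(gene, seq(1, nchar(gene), 3), seq(3, nchar(gene), 3))
  paste(as.character(code)[match(normalize_codon(cds), names(code))],
        collapse = "")
}

# ---------------------------------------------------------------------------
# Chemical-class tables

#' Default chemical-class table
#'
#' Partition of the 20 residues into side-chain chemical classes, plus the
#' reserved pseudo-class `STOP` for `"*"`. The default table was calibrated
#' against the standard code's published accessibility statistics: it merges
#' the seven classical side-chain groups into three — aliphatic together
#' with hydroxylic and sulfur-containing side chains, aromatic, and
#' charged/amidic (acidic + basic + amide) — which reproduces the reference
#' within-class edge count of the standard code (109). The finer seven-class
#' chart is available as [sigma_classes()].
#'
#' @return Named character vector mapping each product symbol to a class
#'   label, with class `"chem_class_table"`.
#' @export
#' @examples
#' default_classes()[["W"]]
default_classes <- function() {
  chem_class_table(c(
    G = "aliphatic", A = "aliphatic", V = "aliphatic", L = "aliphatic",
    I = "aliphatic", P = "aliphatic", S = "aliphatic", T = "aliphatic",
    C = "aliphatic", M = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    D = "charged", E = "charged", K = "charged", R = "charged",
    H = "charged", N = "charged", Q = "charged",
    "*" = "STOP"))
}

#' Seven-class side-chain chart
#'
#' The classical reference-chart partition: aliphatic (G, A, V, L, I, P),
#' aromatic (F, W, Y), acidic (D, E), basic (K, R, H), hydroxylic (S, T),
#' sulfur-containing (C, M), amidic (N, Q), plus STOP.
#'
#' @return A `chem_class_table`.
#' @export
sigma_classes <- function() {
  chem_class_table(c(
    G = "aliphatic", A = "aliphatic", V = "aliphatic", L = "aliphatic",
    I = "aliphatic", P = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic",
    S = "hydroxylic", T = "hydroxylic",
    C = "sulfur", M = "sulfur",
    N = "amidic", Q = "amidic",
    "*" = "STOP"))
}

#' Construct a chemical-class table
#'
#' @param classes Named character vector mapping residues to class labels.
#'   An entry for `"*"` is added automatically (class `STOP`) if missing.
#' @return A `chem_class_table`.
#' @export
chem_class_table <- function(classes) {
  if (is.null(names(classes))) {
    stop("classes must be a named character vector", call. = FALSE)
  }
  if (!("*" %in% names(classes))) classes[["*"]] <- "STOP"
  classes[["*"]] <- "STOP"
  missing <- setdiff(RESIDUES, names(classes))
  if (length(missing) > 0) {
    stop("residue(s) without a class: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(classes), PRODUCTS)
  if (length(extra) > 0) {
    stop("unknown residue(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  x <- setNames(as.character(classes[PRODUCTS]), PRODUCTS)
  structure(x, class = "chem_class_table")
}

#' @export
print.chem_class_table <- function(x, ...) {
  cat("<chem_class_table>", length(unique(x[RESIDUES])),
      "classes + STOP\n")
  for (cl in unique(x)) {
    cat(" ", cl, ":", paste(names(x)[x == cl], collapse = " "), "\n")
  }
  invisible(x)
}

#' Read or write a chemical-class table (JSON or TSV)
#'
#' @param path File path. JSON files hold an object
#'   `{"A": "aliphatic", ...}`; TSV files have columns `residue` and
#'   `class`.
#' @return A `chem_class_table` (for `read_classes`).
#' @export
read_classes <- function(path) {
  doc <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (grepl("^\\s*\\{", doc)) {
    return(chem_class_table(unlist(jsonlite::fromJSON(doc))))
  }
  tab <- read.table(text = doc, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("residue", "class") %in% names(tab))) {
    stop("class TSV must have columns 'residue' and 'class'", call. = FALSE)
  }
  chem_class_table(setNames(tab$class, tab$residue))
}

#' @rdname read_classes
#' @param classes A `chem_class_table`.
#' @param format `"json"` or `"tsv"`.
#' @export
write_classes <- function(classes, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(as.character(jsonlite::toJSON(
      as.list(setNames(as.character(classes), names(classes))),
      auto_unbox = TRUE, pretty = TRUE)), path)
  } else {
    writeLines(paste(c("residue\tclass",
                       paste(names(classes), as.character(classes),
                             sep = "\t")), collapse = "\n"), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Internal integer encodings used by the C++ core: products 1..21 in
# PRODUCTS order, classes as integer ids with STOP last.

code_to_int <- function(code) {
  match(as.character(code), PRODUCTS)
}

int_to_code <- function(prod, name = "unnamed", reference = NULL, ...) {
  genetic_code(setNames(PRODUCTS[prod], codons()), name = name,
               reference = reference, ...)
}

classes_to_int <- function(classes) {
  labels <- unique(as.character(classes))
  match(as.character(classes)[match(PRODUCTS, names(classes))], labels)
}
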