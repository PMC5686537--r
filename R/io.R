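# FASTA and report I/O, and the code-comparison table.

#' Read a FASTA file
#'
#' @param path File path. An empty file yields an empty collection.
#' @return Named character vector of sequences. Duplicate ids are
#'   disambiguated with a numeric suffix (with a warning).
#' @export
read_fasta <- function(path) {
  if (file.info(path)$size == 0) return(setNames(character(0), character(0)))
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids disambiguated with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  setNames(toupper(as.character(x)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @export
write_fasta <- function(seqs, path, width = 70) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Compare genetic codes
#'
#' One row per code with its fitness components, combined fitness and
#' reassignment count against the standard code; when `genes` are supplied,
#' also the mean gene-level [evolvability()] after recoding each gene to
#' the code with [recode_gene()].
#'
#' @param codes List of [genetic_code()] objects (a single code is
#'   accepted).
#' @param classes A [chem_class_table()].
#' @param genes Optional named character vector of coding sequences
#'   (translated under `source`).
#' @param source Code under which `genes` are read (default standard).
#' @param config A [recoding_config()] for the per-gene recoding.
#' @param utr 5' UTR used during recoding (placeholder default).
#' @return Data frame with one row per code.
#' @export
#' @examples
#' compare_codes(list(standard_code()))
compare_codes <- function(codes, classes = default_classes(), genes = NULL,
                          source = standard_code(),
                          config = recoding_config(seed = 1),
                          utr = "AGGA") {
  if (inherits(codes, "genetic_code")) codes <- list(codes)
  if (length(codes) == 0) stop("need at least one code", call. = FALSE)
  std <- standard_code()
  rows <- lapply(codes, function(cd) {
    rep <- combined_fitness(cd, classes, reference = std)
    row <- data.frame(code = attr(cd, "name"),
                      f_unique = rep$f_unique, f_ratio = rep$f_ratio,
                      f_chem = rep$f_chem, f_combined = rep$f_combined,
                      reassignments = rep$reassignments,
                      stringsAsFactors = FALSE)
    if (!is.null(genes)) {
      ev <- vapply(genes, function(g) {
        rg <- recode_gene(utr, g, source, cd, config)
        evolvability(rg$recoded, cd)
      }, numeric(1))
      row$mean_evolvability <- mean(ev)
    }
    row
  })
  do.call(rbind, rows)
}

#' Export a report as JSON or TSV
#'
#' Works for `fitness_report`, `edge_census` and `ga_trace` objects, and
#' for plain data frames / matrices (e.g. [min_replacements()] output).
#'
#' @param x Object to export.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "ga_trace")) {
    x <- c(unclass(x$report), list(reassignments = x$reassignments))
  }
  if (inherits(x, c("fitness_report", "edge_census"))) x <- unclass(x)
  if (format == "json") {
    if (is.matrix(x)) {
      x <- as.data.frame(x)
    }
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else {
    if (is.list(x) && !is.data.frame(x)) {
      x <- data.frame(field = names(x),
                      value = vapply(x, function(v)
                        paste(format(v), collapse = ","), character(1)))
    }
    if (is.matrix(x)) {
      write.table(x, path, sep = "\t", quote = FALSE,
                  row.names = TRUE, col.names = NA)
    } else {
      write.table(x, path, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = TRUE)
    }
  }
  invisible(path)
}
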