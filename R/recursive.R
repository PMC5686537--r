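# Exhaustive single-step ("best-move") improvement of a genetic code.
#
# A move reassigns one codon to one of the 20 residues. Codons currently
# encoding stop are never moved. Each round considers all moves and keeps
# those achieving the maximal strictly positive gain in unpenalized combined
# fitness; the branching mode expands every tied move recursively
# (memoizing visited codes), the greedy mode follows the first best move in
# deterministic loop order.

#' Maximal-gain single reassignments
#'
#' The set of single codon reassignments achieving the maximal strictly
#' positive gain in combined fitness; empty if the code is locally optimal.
#' Stop codons are excluded from move generation.
#'
#' @param code A [genetic_code()] (typically [prepare_stopless()]-prepared).
#' @param classes A [chem_class_table()].
#' @param allow_residue_loss Permit moves that drop a residue's last codon.
#' @param tol Tie tolerance on fitness (all quantities are ratios of small
#'   integers, so ties are exact up to floating-point noise).
#' @return Data frame with columns `codon`, `product` and `fitness` (the
#'   common fitness all listed moves reach).
#' @export
#' @examples
#' mv <- best_moves(prepare_stopless(standard_code()))
#' head(mv)
best_moves <- function(code, classes = default_classes(),
                       allow_residue_loss = FALSE, tol = 1e-12) {
  res <- .best_moves_core(code_to_int(code), classes_to_int(classes),
                          FALSE, allow_residue_loss, tol)
  mv <- res$moves
  if (nrow(mv) == 0) {
    return(data.frame(codon = character(0), product = character(0),
                      fitness = numeric(0)))
  }
  data.frame(codon = codons()[mv[, 1]], product = PRODUCTS[mv[, 2]],
             fitness = rep(res$fitness, nrow(mv)))
}

#' Recursive best-move search
#'
#' Repeatedly applies maximal-gain single reassignments until no move
#' strictly improves the combined fitness. `mode = "greedy"` follows one
#' best move per round (first in deterministic loop order); `mode =
#' "branch"` expands all tied best moves depth-first with memoization and
#' returns the de-duplicated set of terminal codes.
#'
#' The start code is stopless-prepared by default (TAG/TGA to asparagine,
#' TAA the sole, frozen stop); stop codons take no part in the search and
#' retain their assignments in the returned codes.
#'
#' @param start A [genetic_code()].
#' @param classes A [chem_class_table()].
#' @param mode `"greedy"` or `"branch"`.
#' @param budget Node budget for the branching mode. Exceeding it raises a
#'   `codevolve_budget_error` carrying the partial result in its `partial`
#'   field.
#' @param prepare Apply [prepare_stopless()] to `start` first (default).
#' @param allow_residue_loss,tol As in [best_moves()].
#' @param max_rounds Safety cap on greedy rounds.
#' @return A `search_result` list: `terminal_codes` (list of
#'   [genetic_code()]), `depth`, `visited`, `trace` (per-depth fitness,
#'   greedy mode), `fitness` (terminal fitness values).
#' @export
#' @examples
#' res <- recursive_search(standard_code(), mode = "greedy")
#' res$depth
recursive_search <- function(start, classes = default_classes(),
                             mode = c("greedy", "branch"), budget = 1e6,
                             prepare = TRUE, allow_residue_loss = FALSE,
                             tol = 1e-12, max_rounds = 200) {
  mode <- match.arg(mode)
  if (prepare) start <- prepare_stopless(start)
  clsint <- classes_to_int(classes)
  if (mode == "greedy") {
    res <- .greedy_search_core(code_to_int(start), clsint, FALSE,
                               allow_residue_loss, tol, max_rounds)
    term <- int_to_code(res$code, name = "recursive_terminal",
                        reference = attr(start, "name"))
    out <- list(terminal_codes = list(term), depth = res$depth,
                visited = res$depth + 1L, trace = res$trace,
                fitness = res$trace[length(res$trace)])
    return(structure(out, class = "search_result"))
  }
  res <- .branch_search_core(code_to_int(start), clsint, FALSE,
                             allow_residue_loss, tol, budget)
  mk <- function(s) {
    genetic_code(setNames(PRODUCTS[utf8ToInt(s) - utf8ToInt("A") + 1L],
                          codons()),
                 name = "recursive_terminal",
                 reference = attr(start, "name"))
  }
  out <- structure(
    list(terminal_codes = lapply(res$terminals, mk),
         depth = if (length(res$depth) > 0) max(res$depth) else 0L,
         terminal_depths = res$depth,
         visited = res$visited, trace = NULL, fitness = res$fitness,
         nodes = res$nodes, max_depth = res$max_depth),
    class = "search_result")
  if (isTRUE(res$exceeded)) {
    cond <- structure(
      class = c("codevolve_budget_error", "error", "condition"),
      list(message = sprintf(
             "branching search exceeded the %g-node budget (partial result attached)",
             budget),
           call = sys.call(-1), partial = out))
    stop(cond)
  }
  out
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result> depth", x$depth, "with",
      length(x$terminal_codes), "terminal code(s)\n")
  cat("  terminal fitness:",
      paste(sprintf("%.6f", sort(unique(round(x$fitness, 10)),
                                 decreasing = TRUE)),
            collapse = " "), "\n")
  invisible(x)
}
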