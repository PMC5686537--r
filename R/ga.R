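# Genetic algorithm over codon tables.
#
# Individuals are full 64-codon assignments. Selection keeps the top
# elite_fraction; offspring i is a mutant of elite[i mod n_elite] (cyclical
# selection); the incumbent best is retained unchanged (elitism), so the
# best fitness never regresses. Offspring whose chemical-diversity component
# falls below the best-so-far f_chem are rejected and resampled a bounded
# number of times, then the parent is copied.

#' Genetic-algorithm configuration
#'
#' Defaults follow the reference simulation regime: 2,500 individuals,
#' 1,000 rounds, a 10% per-codon mutation rate and top-10% cyclical
#' selection.
#'
#' @param population_size Number of individuals (>= 2).
#' @param rounds Number of selection rounds.
#' @param mutation_rate Per-codon probability that a codon takes the product
#'   of another randomly chosen codon.
#' @param elite_fraction Fraction of the population selected each round.
#' @param penalty_alpha Penalty factor in (0, 1), or `NULL` for unpenalized
#'   runs. The default used for penalized runs is 0.95 (an arbitrary choice;
#'   the penalty factor is a free parameter of the method).
#' @param penalty_exponent 1 (linear) or 2 (square).
#' @param frozen_codons Codons whose product may never change.
#' @param reassignable_codons Codons the optimizer may touch (`NULL` = all
#'   non-frozen codons).
#' @param native_restriction Require every residue to retain at least one
#'   codon with its assignment in the reference (start) code.
#' @param allow_residue_loss Permit codes that drop residues.
#' @param stopless Prepare the start code with [prepare_stopless()] and
#'   freeze TAA as the sole stop.
#' @param operator `"copy"` (overwrite with another randomly chosen codon's
#'   product, default), `"exchange"` (swap the two products), or
#'   `"uniform"` (draw a uniform random product symbol; used for
#'   restricted-reassignment searches where the copy operator's donor
#'   distribution would make rare products nearly unreachable).
#' @param chem_acceptance Reject offspring whose chemical-diversity
#'   component falls below the best-so-far f_chem (default). This ratchet
#'   steers whole-code searches toward chemically diverse codes but can
#'   exclude the unconstrained fitness optimum; restricted-reassignment
#'   searches ([optimize_free_codons()]) switch it off.
#' @param max_retries Bounded resampling count for constraint- or
#'   acceptance-violating offspring.
#' @param seed Random seed; every stochastic draw of the run flows through
#'   it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 2500, rounds = 1000,
                      mutation_rate = 0.10, elite_fraction = 0.10,
                      penalty_alpha = NULL, penalty_exponent = 1,
                      frozen_codons = character(),
                      reassignable_codons = NULL,
                      native_restriction = FALSE,
                      allow_residue_loss = FALSE,
                      stopless = TRUE,
                      operator = c("copy", "exchange", "uniform"),
                      chem_acceptance = TRUE,
                      max_retries = 50, seed = NULL) {
  operator <- match.arg(operator)
  stopifnot(population_size >= 2, rounds >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elite_fraction > 0, elite_fraction <= 1)
  if (!is.null(penalty_alpha) &&
      (penalty_alpha <= 0 || penalty_alpha >= 1)) {
    stop("penalty_alpha must lie in (0, 1)", call. = FALSE)
  }
  if (!penalty_exponent %in% c(1, 2)) {
    stop("penalty_exponent must be 1 or 2", call. = FALSE)
  }
  structure(list(population_size = as.integer(population_size),
                 rounds = as.integer(rounds),
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction,
                 penalty_alpha = penalty_alpha,
                 penalty_exponent = penalty_exponent,
                 frozen_codons = normalize_codon(frozen_codons),
                 reassignable_codons =
                   if (is.null(reassignable_codons)) NULL
                   else normalize_codon(reassignable_codons),
                 native_restriction = native_restriction,
                 allow_residue_loss = allow_residue_loss,
                 stopless = stopless, operator = operator,
                 chem_acceptance = chem_acceptance,
                 max_retries = as.integer(max_retries), seed = seed),
            class = "ga_config")
}

#' Prepare a code for stopless optimization
#'
#' Reassigns TAG and TGA to asparagine and reserves TAA as the sole stop
#' codon, which is then frozen for the run. Idempotent.
#'
#' @param code A [genetic_code()] with standard stop codons.
#' @return A [genetic_code()] with exactly one stop (TAA).
#' @export
#' @examples
#' prepare_stopless(standard_code())
prepare_stopless <- function(code) {
  x <- setNames(as.character(code), names(code))
  x[c("TAG", "TGA")] <- "N"
  x["TAA"] <- "*"
  genetic_code(x, name = paste0(attr(code, "name"), "+stopless"),
               reference = attr(code, "name"))
}

# Which codons may the GA touch?
movable_set <- function(config, start) {
  mv <- names(start)
  if (!is.null(config$reassignable_codons)) {
    mv <- intersect(mv, config$reassignable_codons)
  }
  mv <- setdiff(mv, config$frozen_codons)
  if (config$stopless) mv <- setdiff(mv, "TAA")
  match(mv, codons())
}

# Constraint check on an integer code vector (1..21 products).
satisfies_constraints <- function(prod, config, native_ref) {
  if (!config$allow_residue_loss && !all(1:20 %in% prod)) return(FALSE)
  if (config$native_restriction) {
    for (r in 1:20) {
      if (!any(prod == r & native_ref == r)) return(FALSE)
    }
  }
  TRUE
}

mutate_int <- function(prod, config, movable, native_ref) {
  hit <- movable[runif(length(movable)) < config$mutation_rate]
  for (k in hit) {
    for (try in seq_len(config$max_retries)) {
      cand <- prod
      if (config$operator == "uniform") {
        cand[k] <- sample.int(21, 1)
      } else {
        donor <- sample.int(64, 1)
        if (donor == k) next
        if (config$operator == "copy") {
          cand[k] <- prod[donor]
        } else {
          tmp <- cand[k]; cand[k] <- cand[donor]; cand[donor] <- tmp
        }
      }
      if (config$stopless && any(cand[-match("TAA", codons())] == 21)) next
      if (satisfies_constraints(cand, config, native_ref)) {
        prod <- cand
        break
      }
    }
  }
  prod
}

#' Mutate a genetic code
#'
#' Each reassignable codon independently, with probability
#' `config$mutation_rate`, takes the product of another randomly chosen
#' codon (copy operator) or exchanges products with it (exchange operator).
#' Proposals violating the configured constraints are resampled up to
#' `config$max_retries` times, then left unchanged. Uses the current RNG
#' state.
#'
#' @param code A [genetic_code()].
#' @param config A [ga_config()].
#' @param reference Code supplying the native assignments for the
#'   `native_restriction` constraint (defaults to `code`).
#' @return A mutated [genetic_code()] (possibly stopless-intermediate).
#' @export
mutate_code <- function(code, config, reference = code) {
  prod <- mutate_int(code_to_int(code), config, movable_set(config, code),
                     code_to_int(reference))
  int_to_code(prod, name = paste0(attr(code, "name"), "+mut"),
              reference = attr(code, "name"),
              stopless = TRUE, require_all_residues = FALSE)
}

ga_fitness <- function(prods, clsint, ref_int, config) {
  # prods: 64 x n integer matrix. Returns list(fit, f_chem) where fit is the
  # (optionally penalized) combined fitness used for ranking.
  m <- .fitness_batch_core(prods, clsint, FALSE)
  fit <- m[, "f_combined"]
  if (!is.null(config$penalty_alpha)) {
    reassign <- colSums(prods != ref_int)
    fit <- fit * config$penalty_alpha^(reassign^config$penalty_exponent)
  }
  fit[is.na(fit)] <- -Inf
  list(fit = fit, f_chem = m[, "f_chem"])
}

#' Evolve a genetic code with the genetic algorithm
#'
#' Runs the select-mutate-accept loop for `config$rounds` rounds starting
#' from `start`. Offspring with a chemical-diversity component (f_chem)
#' below the best-so-far are rejected and resampled (bounded retries, then
#' the parent is copied). The incumbent best is retained each round, so the
#' best-fitness trace is non-decreasing.
#'
#' @param start A [genetic_code()] satisfying the configured constraints.
#' @param config A [ga_config()].
#' @param classes A [chem_class_table()] (used for reporting; the fitness
#'   itself uses the calibrated partition-free f_chem rule).
#' @return A `ga_trace` list: `best_code`, `report` (fitness report of the
#'   best code), `trace` (per-round best fitness), `reassignments` (vs
#'   `start`), `config`.
#' @export
#' @examples
#' cfg <- ga_config(population_size = 30, rounds = 10, seed = 1)
#' res <- evolve(standard_code(), cfg)
#' res$report$f_unique
evolve <- function(start, config = ga_config(),
                   classes = default_classes()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  reference <- start
  if (config$stopless) start <- prepare_stopless(start)
  movable <- movable_set(config, start)
  start_int <- code_to_int(start)
  native_ref <- code_to_int(reference)
  clsint <- classes_to_int(classes)
  if (!satisfies_constraints(start_int, config, native_ref)) {
    stop("start code violates the configured constraints", call. = FALSE)
  }
  n <- config$population_size
  n_elite <- max(1L, as.integer(ceiling(config$elite_fraction * n)))

  if (length(movable) == 0) {
    rep <- combined_fitness(start, classes, reference = reference)
    return(structure(list(best_code = start, report = rep,
                          trace = rep$f_combined,
                          reassignments = count_reassignments(start,
                                                              reference),
                          config = config),
                     class = "ga_trace"))
  }

  pop <- matrix(start_int, nrow = 64, ncol = n)
  for (i in seq_len(n)[-1]) {
    pop[, i] <- mutate_int(start_int, config, movable, native_ref)
  }
  sc <- ga_fitness(pop, clsint, start_int, config)
  best_i <- order(-sc$fit,
                  apply(pop, 2, paste, collapse = ","))[1]
  best <- pop[, best_i]
  best_fit <- sc$fit[best_i]
  best_chem <- sc$f_chem[best_i]
  trace <- numeric(config$rounds)

  for (round in seq_len(config$rounds)) {
    ord <- order(-sc$fit, apply(pop, 2, paste, collapse = ","))
    elite <- pop[, ord[seq_len(n_elite)], drop = FALSE]
    nxt <- .ga_round_core(elite, n, config$mutation_rate,
                          match(config$operator,
                                c("copy", "exchange", "uniform")) - 1L,
                          movable, native_ref,
                          config$native_restriction,
                          config$allow_residue_loss, config$stopless,
                          clsint, FALSE,
                          if (isTRUE(config$chem_acceptance)) best_chem
                          else -Inf,
                          config$max_retries)
    nxt[, 1] <- best  # previous winner retained
    pop <- nxt
    sc <- ga_fitness(pop, clsint, start_int, config)
    i <- order(-sc$fit, apply(pop, 2, paste, collapse = ","))[1]
    if (sc$fit[i] > best_fit) {
      best <- pop[, i]
      best_fit <- sc$fit[i]
    }
    best_chem <- max(best_chem, sc$f_chem[i])
    trace[round] <- best_fit
  }

  best_code <- int_to_code(best, name = "ga_best",
                           reference = attr(reference, "name"),
                           stopless = TRUE, require_all_residues = FALSE)
  rep <- combined_fitness(best_code, classes, reference = reference)
  if (!is.null(config$penalty_alpha)) {
    rep$penalized_f <- best_fit
  }
  structure(list(best_code = best_code, report = rep, trace = trace,
                 reassignments = count_reassignments(best_code, reference),
                 config = config),
            class = "ga_trace")
}

#' @export
print.ga_trace <- function(x, ...) {
  cat("<ga_trace>", length(x$trace), "rounds, final best fitness",
      sprintf("%.6f", max(x$trace)), "\n")
  cat("  reassignments:", x$reassignments, "\n")
  print(x$report)
  invisible(x)
}

#' Optimize the products of a set of freed codons
#'
#' All other codons keep their standard assignment. For small sets
#' (`length(freed) <= exhaustive_threshold`) the optimum is found by full
#' enumeration over all product combinations; otherwise the genetic
#' algorithm restricted to the freed codons is used.
#'
#' The default `freed` set is the seven codons synonymously removed in the
#' 57-codon E. coli genome design (AGA, AGG, AGC, AGT, TTA, TTG, TAG).
#'
#' @param freed Character vector of codons to reassign.
#' @param classes A [chem_class_table()].
#' @param config A [ga_config()]; `reassignable_codons` and `frozen_codons`
#'   are set internally.
#' @param exhaustive_threshold Largest `length(freed)` for which exhaustive
#'   enumeration is used.
#' @return A `ga_trace` (with `trace` of length 0 for exhaustive runs).
#' @export
#' @examples
#' res <- optimize_free_codons(c("TAG", "TGA"),
#'                             config = ga_config(seed = 1))
#' res$report$f_unique
optimize_free_codons <- function(freed = c("AGA", "AGG", "AGC", "AGT",
                                           "TTA", "TTG", "TAG"),
                                 classes = default_classes(),
                                 config = ga_config(),
                                 exhaustive_threshold = 2) {
  std <- standard_code()
  freed <- normalize_codon(freed)
  if (length(freed) == 0) {
    rep <- combined_fitness(std, classes, reference = std)
    return(structure(list(best_code = std, report = rep, trace = numeric(0),
                          reassignments = 0L, config = config),
                     class = "ga_trace"))
  }
  std_int <- code_to_int(std)
  clsint <- classes_to_int(classes)
  idx <- match(freed, codons())

  if (length(freed) <= exhaustive_threshold) {
    combos <- as.matrix(expand.grid(rep(list(1:21), length(freed))))
    prods <- matrix(std_int, nrow = 64, ncol = nrow(combos))
    for (i in seq_along(idx)) prods[idx[i], ] <- combos[, i]
    ok <- apply(prods, 2, function(p) all(1:20 %in% p) && any(p == 21))
    prods <- prods[, ok, drop = FALSE]
    m <- .fitness_batch_core(prods, clsint, FALSE)
    fit <- m[, "f_combined"]
    fit[is.na(fit)] <- -Inf
    i <- order(-fit, apply(prods, 2, paste, collapse = ","))[1]
    best_code <- int_to_code(prods[, i], name = "free_codon_best",
                             reference = "standard")
    rep <- combined_fitness(best_code, classes, reference = std)
    return(structure(list(best_code = best_code, report = rep,
                          trace = numeric(0),
                          reassignments = count_reassignments(best_code,
                                                              std),
                          config = config),
                     class = "ga_trace"))
  }

  config$reassignable_codons <- freed
  config$frozen_codons <- setdiff(codons(), freed)
  config$stopless <- FALSE
  config$native_restriction <- FALSE
  config$operator <- "uniform"
  config$chem_acceptance <- FALSE
  res <- evolve(std, config, classes)
  res$best_code <- genetic_code(
    setNames(as.character(res$best_code), names(res$best_code)),
    name = "free_codon_best", reference = "standard")
  res
}
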