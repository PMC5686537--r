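# Synonymous gene recoding under a new genetic code.
#
# The protein is preserved exactly; among the codon sequences that translate
# to it under the target code, the recoder picks (by sampled search) the one
# whose folding energy and secondary structure best match the wild type.
# The 5' leader (4-nt UTR + first 13 codons = 39 nt of CDS, covering the
# region whose folding most influences translation efficiency) is optimized
# first at a 1% scan fraction; the remaining CDS is processed in consecutive
# 30-nt windows at a 0.4% scan fraction, each scored in a folding context of
# the window plus the 30 preceding nucleotides.

#' Recoding configuration
#'
#' @param utr_length Length of the 5' UTR included in the leader fold (nt).
#' @param leader_cds_length Leader CDS length in nt (divisible by 3). The
#'   default 39 nt = 13 codons covers the biologically motivated first 37 nt.
#' @param leader_scan_fraction Fraction of all candidate leader assemblies
#'   scanned.
#' @param body_window Window size for the gene body (nt, divisible by 3).
#' @param body_scan_fraction Fraction of candidates scanned per body window.
#' @param candidate_cap Hard cap on sampled candidates per region.
#' @param structure_weight Trade-off lambda: candidate score is
#'   `|energy - wt energy| + lambda * bp_distance`.
#' @param seed Random seed for candidate sampling.
#' @return A `recoding_config` list.
#' @export
recoding_config <- function(utr_length = 4, leader_cds_length = 39,
                            leader_scan_fraction = 0.01, body_window = 30,
                            body_scan_fraction = 0.004,
                            candidate_cap = 1e5, structure_weight = 1.0,
                            seed = NULL) {
  stopifnot(leader_cds_length %% 3 == 0, body_window %% 3 == 0,
            leader_scan_fraction > 0, leader_scan_fraction <= 1,
            body_scan_fraction > 0, body_scan_fraction <= 1,
            candidate_cap >= 1, structure_weight >= 0)
  structure(list(utr_length = as.integer(utr_length),
                 leader_cds_length = as.integer(leader_cds_length),
                 leader_scan_fraction = leader_scan_fraction,
                 body_window = as.integer(body_window),
                 body_scan_fraction = body_scan_fraction,
                 candidate_cap = candidate_cap,
                 structure_weight = structure_weight, seed = seed),
            class = "recoding_config")
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# Candidate codon lists under `target` for each residue of `peptide`
# (a character vector of product symbols).
candidate_lists <- function(peptide, target, positions = seq_along(peptide)) {
  tgt <- as.character(target)
  lapply(seq_along(peptide), function(i) {
    cand <- names(target)[tgt == peptide[i]]
    if (length(cand) == 0) {
      stop(sprintf(
        "residue %s at codon position %d has no codon in the target code",
        peptide[i], positions[i]), call. = FALSE)
    }
    sort(cand)
  })
}

# Sample up to n distinct assemblies (index vectors) from the Cartesian
# product of cand (list of codon vectors), uniformly without replacement.
sample_assemblies <- function(cand, fraction, cap, include = NULL) {
  sizes <- lengths(cand)
  total <- prod(sizes)
  n <- min(cap, max(1, ceiling(fraction * total)), total)
  picks <- list()
  if (total <= 2^31 - 1) {
    ids <- sample.int(total, n) - 1
    for (id in ids) {
      ix <- integer(length(sizes))
      rest <- id
      for (j in rev(seq_along(sizes))) {
        ix[j] <- rest %% sizes[j] + 1
        rest <- rest %/% sizes[j]
      }
      picks[[length(picks) + 1]] <- ix
    }
  } else {
    seen <- new.env(hash = TRUE)
    tries <- 0
    while (length(picks) < n && tries < 20 * n) {
      ix <- vapply(sizes, function(s) sample.int(s, 1), integer(1))
      key <- paste(ix, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        picks[[length(picks) + 1]] <- ix
      }
      tries <- tries + 1
    }
  }
  if (!is.null(include)) {
    key_inc <- paste(include, collapse = ",")
    keys <- vapply(picks, paste, character(1), collapse = ",")
    if (!(key_inc %in% keys)) picks[[length(picks) + 1]] <- include
  }
  picks
}

assemble <- function(cand, ix) {
  paste(mapply(function(v, i) v[i], cand, ix), collapse = "")
}

score_candidate <- function(seq, wt_fold, config, backend) {
  f <- fold(seq, backend = backend)
  bp <- structure_distance(f, wt_fold)
  list(score = abs(f$energy - wt_fold$energy) +
         config$structure_weight * bp,
       energy = f$energy, bp = bp, fold = f)
}

# Pick the best assembly among sampled candidates; ties broken by lower
# bp distance, then fewer codon changes relative to the original region
# (so wild-type codons win exact ties and source = target recoding is the
# identity), then lexicographically smaller sequence.
pick_best <- function(prefix, cand, wt_fold, config, backend, fraction,
                      include = NULL, original = NULL) {
  picks <- sample_assemblies(cand, fraction, config$candidate_cap, include)
  best <- NULL
  scores <- numeric(length(picks))
  n_changes <- function(seq) {
    if (is.null(original)) return(0L)
    sum(split_codons(seq) != original)
  }
  for (i in seq_along(picks)) {
    seq <- assemble(cand, picks[[i]])
    sc <- score_candidate(paste0(prefix, seq), wt_fold, config, backend)
    scores[i] <- sc$score
    ch <- n_changes(seq)
    if (is.null(best) || sc$score < best$score - 1e-12 ||
        (abs(sc$score - best$score) <= 1e-12 &&
         (sc$bp < best$bp ||
          (sc$bp == best$bp &&
           (ch < best$changes ||
            (ch == best$changes && seq < best$seq)))))) {
      best <- c(sc, list(seq = seq, ix = picks[[i]], changes = ch))
    }
  }
  best$sampled_scores <- scores
  best$n_sampled <- length(picks)
  best$n_total <- prod(lengths(cand))
  best
}

# Disparity repair: at codon positions overlapping structure disagreements,
# try alternative codons and keep strict score improvements.
repair_disparity <- function(prefix, seq, cand, wt_fold, config, backend) {
  cur <- score_candidate(paste0(prefix, seq), wt_fold, config, backend)
  cds <- split_codons(seq)
  repeat {
    diffpos <- which(strsplit(cur$fold$structure, "")[[1]] !=
                       strsplit(wt_fold$structure, "")[[1]])
    diffpos <- diffpos[diffpos > nchar(prefix)]
    if (length(diffpos) == 0) break
    cpos <- sort(unique((diffpos - nchar(prefix) - 1) %/% 3 + 1))
    improved <- FALSE
    for (p in cpos) {
      for (alt in setdiff(cand[[p]], cds[p])) {
        trial <- cds
        trial[p] <- alt
        sc <- score_candidate(paste0(prefix, paste(trial, collapse = "")),
                              wt_fold, config, backend)
        if (sc$score < cur$score - 1e-12) {
          cds <- trial
          cur <- sc
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(seq = paste(cds, collapse = ""), score = cur$score,
       energy = cur$energy, bp = cur$bp)
}

#' Recode the 5' leader of a gene
#'
#' Translates the first `leader_cds_length` nt of the CDS under `source`,
#' builds per-position candidate codon lists under `target`, samples
#' `leader_scan_fraction` of the Cartesian product (capped, seeded,
#' uniformly without replacement; the original codons are included as the
#' identity candidate whenever they remain valid under `target`), scores
#' each candidate leader (UTR + candidate) against the wild-type fold by
#' `|delta energy| + lambda * bp_distance`, and finally applies disparity
#' repair at positions where the recoded and wild-type structures disagree.
#'
#' @param utr Character scalar, the 5' UTR (its length overrides
#'   `config$utr_length`).
#' @param cds Character scalar, coding sequence (>= `leader_cds_length` nt).
#' @param source,target [genetic_code()] objects.
#' @param config A [recoding_config()].
#' @param backend Folding backend, see [fold()].
#' @return List with `leader` (recoded leader CDS part), `score`, `energy`,
#'   `wt_energy`, `bp_distance`, `n_sampled`, `n_total`.
#' @export
recode_leader <- function(utr, cds, source, target,
                          config = recoding_config(),
                          backend = c("dp", "thermo")) {
  backend <- match.arg(backend)
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$leader_cds_length
  if (nchar(cds) < L || nchar(cds) %% 3 != 0) {
    stop(sprintf("cds must be at least %d nt and a multiple of 3", L),
         call. = FALSE)
  }
  lead <- substr(cds, 1, L)
  pep <- strsplit(translate(lead, source), "")[[1]]
  cand <- candidate_lists(pep, target)
  wt_fold <- fold(paste0(utr, lead), backend = backend)
  orig <- split_codons(lead)
  include <- NULL
  if (all(mapply(function(v, o) o %in% v, cand, orig))) {
    include <- mapply(function(v, o) match(o, v), cand, orig)
  }
  best <- pick_best(utr, cand, wt_fold, config, backend,
                    config$leader_scan_fraction, include, original = orig)
  rep <- repair_disparity(utr, best$seq, cand, wt_fold, config, backend)
  list(leader = rep$seq, score = rep$score, energy = rep$energy,
       wt_energy = wt_fold$energy, bp_distance = rep$bp,
       n_sampled = best$n_sampled, n_total = best$n_total,
       sampled_scores = best$sampled_scores, best_sampled_score = best$score)
}

#' Recode a gene under a new genetic code
#'
#' The leader is recoded with [recode_leader()]; the remaining CDS is
#' processed left to right in consecutive `body_window`-nt windows, each
#' window's candidates sampled at `body_scan_fraction` and scored in a
#' folding context of the window plus the 30 preceding (already recoded)
#' nucleotides against the wild-type fold of the same region. There is no
#' further adjustment after the windows. The translation of the result
#' under `target` always equals the translation of the input under
#' `source`.
#'
#' @inheritParams recode_leader
#' @param gene Character scalar, full coding sequence.
#' @return A `recoded_gene` list: `original`, `recoded`, `regions` (per-
#'   region diagnostics data frame), `translation_preserved` flag.
#' @export
#' @examples
#' std <- standard_code()
#' g <- random_gene(20, code = std, seed = 1)
#' res <- recode_gene("AGGA", g, std, std,
#'                    config = recoding_config(seed = 1))
#' res$translation_preserved
recode_gene <- function(utr, gene, source, target,
                        config = recoding_config(),
                        backend = c("dp", "thermo")) {
  backend <- match.arg(backend)
  gene <- toupper(gsub("U", "T", toupper(gene)))
  if (nchar(gene) %% 3 != 0) {
    stop("gene length must be a multiple of 3", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # RNG already seeded for the whole gene

  L <- min(config$leader_cds_length, nchar(gene))
  cfg_noseed$leader_cds_length <- L
  lr <- recode_leader(utr, gene, source, target, cfg_noseed, backend)
  recoded <- lr$leader
  regions <- data.frame(region = "leader", start = 1L, end = L,
                        wt_energy = lr$wt_energy, energy = lr$energy,
                        bp_distance = lr$bp_distance,
                        n_sampled = lr$n_sampled,
                        stringsAsFactors = FALSE)

  pos <- L + 1
  ctx <- 30
  while (pos <= nchar(gene)) {
    end <- min(pos + config$body_window - 1, nchar(gene))
    wseq <- substr(gene, pos, end)
    pep <- strsplit(translate(wseq, source), "")[[1]]
    cand <- candidate_lists(pep, target,
                            positions = (pos - 1) %/% 3 + seq_along(pep))
    prefix_rec <- substr(recoded, max(1, nchar(recoded) - ctx + 1),
                         nchar(recoded))
    prefix_wt <- substr(gene, max(1, pos - ctx), pos - 1)
    wt_fold <- fold(paste0(prefix_wt, wseq), backend = backend)
    orig <- split_codons(wseq)
    include <- NULL
    if (all(mapply(function(v, o) o %in% v, cand, orig))) {
      include <- mapply(function(v, o) match(o, v), cand, orig)
    }
    best <- pick_best(prefix_rec, cand, wt_fold, config, backend,
                      config$body_scan_fraction, include, original = orig)
    recoded <- paste0(recoded, best$seq)
    regions <- rbind(regions, data.frame(
      region = sprintf("window_%d", nrow(regions)),
      start = pos, end = end, wt_energy = wt_fold$energy,
      energy = best$energy, bp_distance = best$bp,
      n_sampled = best$n_sampled, stringsAsFactors = FALSE))
    pos <- end + 1
  }

  preserved <- identical(translate(recoded, target),
                         translate(gene, source))
  structure(list(original = gene, recoded = recoded, utr = utr,
                 regions = regions, translation_preserved = preserved),
            class = "recoded_gene")
}

#' @export
print.recoded_gene <- function(x, ...) {
  cat("<recoded_gene>", nchar(x$original), "nt,",
      sum(split_codons(x$original) != split_codons(x$recoded)),
      "codon(s) changed\n")
  cat("  translation preserved:", x$translation_preserved, "\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}
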