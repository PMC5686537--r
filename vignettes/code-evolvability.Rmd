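---
title: "Measuring and engineering the evolvability of genetic codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and engineering the evolvability of genetic codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codevolve)
```

## The problem

The standard genetic code buffers point mutations: codons one nucleotide
apart tend to encode the same or chemically similar amino acids. Under the
standard code a codon can reach, by single nucleotide replacements (SNRs),
only about 6.1 distinct alternative products on average (stop included),
out of a theoretical maximum of 9. For an organism this is a feature; for
directed-evolution experiments that rely on error-based mutagenesis it is a
ceiling, because most amino-acid substitutions that would need two or three
base changes within one codon are practically inaccessible.

codevolve quantifies this ceiling and searches for refactored codon tables
that raise it. Its intended users are protein engineers and genome
refactoring groups who want to (i) score codes and genes for SNR
accessibility, (ii) design alternative codon assignments under practical
constraints, and (iii) rewrite coding sequences under such assignments
without disturbing the protein or, as far as possible, the mRNA structure.

## Accessibility metrics

Every codon has exactly 9 Hamming-distance-1 neighbors, giving 576 directed
SNR events per code (288 unordered pairs).

* **F_unique** — for each codon, the number of distinct products among its
  9 neighbors that differ from its own product (stop counts as a product);
  averaged over all 64 codons, stop codons included as sources. Standard
  code: 6.1 (SD 0.69, range 5–7).
* **F_ratio** — for each encoded residue, the number of directed SNR events
  converting a different, non-stop product into it; the minimum over
  residues divided by the maximum. Codes that spread codons evenly over
  residues approach 1. Stop is not a residue here and is excluded from both
  ends of an event.
* **F_chem** — chemical-class accessibility. See the calibration note
  below; the default rule counts, per sense codon, one class instance per
  unique accessible non-stop amino acid (classes counted *non-distinctly*),
  averaged over all 64 codons. Standard code: 5.53.
* **F** — the product of the three components, each divided by its nominal
  maximum: `F = (F_unique/9) * F_ratio * (F_chem/9)`. The constant 9 for
  F_chem is nominal rather than attainable; normalization only rescales and
  never changes optimizer rankings.
* **Evolvability E of a gene** — the mean per-codon unique accessibility
  over the gene's codons: how many distinct alternative products the gene
  can reach per position by point mutations.

```{r metrics}
std <- standard_code()
access_distribution(std)
f_chem(std)
combined_fitness(std)
```

### Calibrating F_chem and the class table

The reference statistics we reproduce are 5.53 mean accessible chemical
classes per codon and 109 "conservative" (within-class) edges among the 288
Hamming-1 codon pairs. Neither is reproducible with the obvious reading —
distinct classes of the classical seven-group side-chain chart (aliphatic,
aromatic, acidic, basic, hydroxylic, sulfur, amidic): that gives 4.20 and
49. Two observations resolve the discrepancy:

1. 5.53 equals exactly 354/64, and 354 is the total number of unique
   accessible non-stop amino acids summed over the 61 sense codons. So the
   statistic counts classes *non-distinctly* — one instance per accessible
   amino acid — with stop carrying no chemical class (stop codons therefore
   contribute nothing as sources). This rule is partition-free and is the
   package default. The distinct-class rule remains available via
   `f_chem(code, classes, distinct = TRUE)`.
2. 109 within-class edges requires a coarser partition than the seven-group
   chart. Enumerating all merges of the seven groups, exactly four yield
   109; we froze the chemically most coherent one as
   `default_classes()`: {aliphatic + hydroxylic + sulfur}, {aromatic},
   {acidic + basic + amidic}, plus the STOP pseudo-class. The seven-group
   chart ships as `sigma_classes()`. Class tables are configuration, not
   constants: both can be replaced by a user file (`read_classes()`).

```{r census}
edge_census(std)
```

## The genetic algorithm

`evolve()` runs a generational GA over full 64-codon assignments:

| parameter | default | meaning |
|---|---|---|
| `population_size` | 2500 | individuals per round |
| `rounds` | 1000 | selection rounds |
| `mutation_rate` | 0.10 | per-codon probability of reassignment |
| `elite_fraction` | 0.10 | top fraction selected |
| `penalty_alpha` | none (0.95 when used) | fitness multiplier `alpha^(R^N)` for R reassignments |
| `penalty_exponent` | 1 | N = 1 linear, N = 2 square |

Before a stopless run the start code is prepared by reassigning TAG and TGA
to asparagine and freezing TAA as the sole stop (`prepare_stopless()`).
Offspring `i` is a mutant of `elite[i mod n_elite]` (cyclical selection);
the incumbent best is retained unchanged each round, so the best-fitness
trace never regresses. Constraint flags cover frozen codons, a restricted
reassignable set, a native-codon restriction (every residue keeps at least
one standard codon) and residue-loss permission. Proposals violating
constraints are resampled up to 50 times, then the parent is kept — a bound
that guarantees termination.

Three mutation operators exist. `copy` (default) overwrites a codon with
the product of another randomly chosen codon; `exchange` swaps the two
products. A pure exchange preserves the product multiset and could never
flatten the codon-count distribution the way optimized codes require, which
is why copy is the default. `uniform` draws a product uniformly from the 21
symbols; it exists because the copy operator proposes a product with
probability proportional to its codon count, which makes one-codon products
(M, W) nearly unreachable when only a handful of codons are searchable.
`optimize_free_codons()` therefore uses it.

**The diversity ratchet.** Following the original design, offspring whose
F_chem falls below the best-so-far are rejected (`chem_acceptance = TRUE`).
This steers whole-code searches toward chemically diverse codes, but it is
a genuine constraint, not a neutral heuristic: in the two-codon search over
{TAG, TGA} the global fitness optimum (TAG→W, TGA→M, F = 0.162, F_chem =
5.92) is permanently excluded once any higher-F_chem code leads the
population (e.g. TAG→I, TGA→D with F_chem = 5.98 but F = 0.107). Restricted
reassignment searches aim at plain fitness maximization, so
`optimize_free_codons()` disables the ratchet; with it disabled the GA
reproduces the exhaustive-enumeration optimum for small freed sets, which
the test suite uses as an oracle check.

```{r free2}
optimize_free_codons(c("TAG", "TGA"), config = ga_config(seed = 1))$report
```

## The recursive best-move search

`recursive_search()` iteratively applies the single codon reassignment with
the largest strictly positive gain in unpenalized F, starting from the
stopless-prepared code; stop codons take no part. Gains are compared with a
1e-12 tolerance — all quantities are ratios of small integers, so true ties
are exact up to floating-point noise. Two modes:

* `greedy` follows the first maximal-gain move per round (deterministic
  loop order: codon index, then product index) until no move improves.
* `branch` expands *every* tied maximal-gain move depth-first with
  memoization on the 64-symbol assignment (default budget 10^6 nodes;
  exceeding it raises an error carrying the partial result).

Ties among maximal-gain moves are pervasive, and the terminal depth and
accessibility of a single path depend on which tied move is taken; the
branch tree from the standard code grows far beyond any practical node
budget (the budget guard is exercised by the test suite). The greedy mode
is therefore the
reproducible reference: from the standard code it terminates after 11
rounds at a code with F_unique 7.109 (+16.4% over the standard 6.109), and
the test suite verifies each step's optimality against a full
re-enumeration. Published figures for this procedure (16 rounds, +14.8%)
fall inside the range spanned by tie-path choices but are not recoverable
without the original implementation's tie order; we document rather than
tune for them.

## Gene recoding

`recode_gene()` rewrites a coding sequence from a source to a target code,
preserving the translation exactly (a hard invariant checked on every run)
and selecting among synonymous candidates by similarity to the wild-type
mRNA fold:

* **Leader**: the 4-nt 5'UTR plus the first 13 codons (39 nt, covering the
  biologically motivated first 37 nt; 39 keeps codon alignment). All
  candidate codon assemblies form a Cartesian product; a seeded uniform
  sample without replacement of 1% of them (capped at `candidate_cap`,
  default 10^5) is scored, and the winner then undergoes *disparity
  repair*: at positions where its dot-bracket structure disagrees with the
  wild type, alternative codons are substituted whenever they strictly
  improve the score.
* **Body**: consecutive non-overlapping 30-nt windows, each sampled at
  0.4% and scored in a folding context of the window plus the 30 preceding
  (already recoded) nucleotides against the wild-type fold of the same
  region; a final partial window is its own region. No post-pass
  adjustment follows.

The score is `|E_cand − E_wt| + λ · d_bp`, with `λ = 1` by default and
`d_bp` the base-pair distance (symmetric difference of pair sets). The
combination rule and λ are configuration because no canonical choice
exists. Ties are broken by lower base-pair distance, then by fewer codon
changes relative to the original region — which makes recoding onto the
same code the exact identity — then lexicographically.

The default folding backend is a self-contained base-pair-maximization
dynamic program (Watson–Crick plus GU wobble, minimum hairpin loop 3,
energy = −pairs); it is deterministic, dependency-free and adequate for
ranking candidates by structural similarity, but its "energies" are pair
counts, not kcal/mol, and it ignores stacking thermodynamics. A
thermodynamic backend (`backend = "thermo"`) shells out to the RNAfold
binary when present and reports true minimum free energies.

## Synthetic data

The generators make the pipeline testable without external data:

* `random_gene()` draws codons with weights `p^g (1−p)^(3−g)` toward a GC
  target, rejecting internal stops. It emulates length and composition,
  not real codon-usage bias or the functional constraints of essential
  genes — so tests passing on these genes demonstrate algorithmic
  correctness, not biological performance on a real genome.
* `random_code()` permutes the standard code's 64 assignments, preserving
  the product multiset (all residues present, three stops).
* `synthetic_substitutions()` samples ordered residue pairs with
  probability ∝ `bias^(1−d)` where `d` is the minimal nucleotide
  replacement distance, mirroring the structure of error-based mutagenesis
  spectra; `substitution_analysis()` recovers the injected anticorrelation
  sign, the package's parameter-recovery check.

## Numerical and scale choices

* Population (not sample) SD in `access_distribution()`: the 64 codons are
  the whole population.
* Printed-value comparisons in tests round half-even to the printed number
  of decimals.
* Spearman p-values use the large-sample approximation by default
  (`exact = FALSE`).
* The test suite and the acceptance script run the GA at population 500 ×
  300 rounds for the seven-codon scenario and smaller sizes (15–200
  individuals, 8–100 rounds) for property checks; these sizes were chosen
  so the full suite completes in about a minute while still reaching the
  relevant optima, and they are the package's reference problem sizes.
  Whole-code production runs should use the 2500 × 1000 defaults.

## Known limitations

* The ratchet-constrained GA is a heuristic; nothing guarantees global
  optimality for whole-code searches, and different seeds give different
  (near-optimal) codes.
* The branching search is exhaustive only within its node budget.
* The recoder preserves folding proxies, not ribosome-binding sites,
  internal promoters or other sequence features, and processes genes
  independently (no operon or overlap handling).
* Evolvability scores on synthetic genes are not comparable to scores on a
  real essential-gene set.
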