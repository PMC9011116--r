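---
title: "Codon optimization, construct design and identity comparison with codonforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon optimization, construct design and identity comparison with codonforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonforge)
```

## The problem this package addresses

Heterologous expression of plant enzymes — for example the cytochrome P450s
used to decorate triterpenoid scaffolds in an oleaginous yeast cell factory
— often fails or underperforms for reasons that have nothing to do with the
enzyme's chemistry: the native coding sequence uses codons rare in the host,
the synthetic gene carries restriction sites that interfere with cloning, a
homopolymer stretch destabilises synthesis, or the N-terminal
membrane-anchor region encoded by the 5' end suits the source organism
better than the host ER. `codonforge` collects the sequence-level design
computations used in this engineering workflow:

1. **Codon-usage tables from highly expressed genes.** A host-specific
   reference set (canonically the 100 most highly expressed genes from an
   RNA-seq ranking) defines, for every amino acid, how often each
   synonymous codon is used.
2. **Strict codon optimization with constraint repair.** Back-translate a
   protein so that every residue uses the most abundant codon of its
   family, then deterministically substitute alternative codons where the
   resulting DNA violates sequence constraints (forbidden restriction
   sites, homopolymer runs, extreme GC windows).
3. **Construct operators.** N-terminal truncation (with or without
   preserving the initial methionine), Gly-Ser-Gly linker fusions with a
   repeat parameter, and chimeras that swap the N-terminal transmembrane
   (NTM) domain between two coding sequences at an exact codon boundary.
4. **Global alignment.** Needleman–Wunsch global DNA alignment with affine
   gap penalties and needle-convention percent identity, used to quantify
   how different two codon variants of the same protein are.
5. **A seeded fixture generator** that samples coding sequences from stated
   per-family codon frequencies, so everything above can be exercised and
   calibrated without downloading any external dataset.

## The model

### Codon-usage tables and CAI

For a reference CDS set, let $n_c$ be the count of codon $c$ and
$\mathrm{fam}(c)$ its synonymous family. The family frequency and the
relative adaptiveness weight are

$$f_c = \frac{n_c}{\sum_{c' \in \mathrm{fam}(c)} n_{c'}}, \qquad
  w_c = \frac{f_c}{\max_{c' \in \mathrm{fam}(c)} f_{c'}},$$

so the most used codon of every observed family has $w_c = 1$. The codon
adaptation index of a query CDS with included codons $c_1,\dots,c_L$ is the
geometric mean $\mathrm{CAI} = \left(\prod_i w_{c_i}\right)^{1/L}$,
computed in the log domain. Following the standard convention the
single-codon Met and Trp families and stop codons are excluded: they carry
no usage information and would only dilute the score. A CAI of 1 therefore
means "every informative codon is the host's favourite".

Zero counts never produce zero weights: a codon unseen within an observed
family gets the conventional floor $w_c = 0.01$, and families never
observed at all get uniform frequency and uniform weight
$1/|\mathrm{fam}|$ and are flagged in the table's provenance. A zero
weight would send CAI to 0 (log 0) for any sequence touching the codon,
which is uninformative. The "maximal weight equals 1" invariant holds for
observed families; tables built from realistically sized gene sets
observe all 20.

### The optimizer

`optimize_codons()` implements strict most-abundant-codon assignment with
deterministic constraint repair:

* **Start**: every residue gets its family's maximal-weight codon (ties
  broken lexicographically by codon text); the stop codon is the
  highest-count stop in the table and is never edited afterwards.
* **Scan**: all forbidden-motif occurrences on both strands (restriction
  enzymes cut double-stranded DNA, so a site on the reverse complement is
  just as forbidden), all homopolymer runs above the cap, every step-1
  sliding window with GC outside the allowed band, and the optional global
  GC band. Coordinates are 0-based half-open nucleotide intervals.
* **Repair**: a deterministic depth-first search over substitution moves.
  At each step the leftmost violation is attacked; the admissible moves
  are synonymous single-codon substitutions at positions overlapping its
  interval — then, when singles fail, combinations of up to
  `backtrack_depth` (default 3) substitutions at distinct positions —
  ordered by smallest weight loss, then leftmost position, then codon
  text. A move is admissible if it removes the violation without
  *creating* a violation that ends earlier. Taking the first admissible
  move at every step yields the greedy repair path; the search then
  backtracks over alternative admissible moves within a bounded rescan
  budget (`search_budget`, default 250), keeping the compliant result with
  the highest CAI. Branches are pruned by their accumulated weight-loss
  product: since the number of CAI-includable codons is fixed, a branch
  whose running product of $w_\mathrm{new}/w_\mathrm{old}$ ratios cannot
  exceed the incumbent's cannot yield a higher CAI.
* **Failure**: if no compliant assignment is found within the trial
  budget, a classed `constraint_infeasible` error carries the residual
  violation report.

Nothing here is randomised, so identical inputs give byte-identical
outputs. On small instances (proteins of up to ~7 residues and a single
forbidden motif) the search tree fits inside the budget and is explored
exhaustively up to pruning, so the result is provably optimal there — the
test suite enumerates *all* synonymous encodings independently and
confirms that the optimizer attains the maximum CAI among compliant
encodings. The look-ahead matters precisely when violations overlap: two
overlapping restriction-site hits are sometimes both removed by one
slightly costlier substitution, which a purely greedy cheapest-first rule
would miss. On large instances the budget keeps the procedure
near-greedy, which is the right trade-off because distant violations
interact only through the codons they share.

Two details are worth making explicit. Reporting *each* violating GC
window (rather than merging runs of windows into one interval) keeps the
repair loop monotone: fixing the leftmost window moves the frontier right,
and the "no earlier-ending violation" acceptance rule never blocks partial
progress. And the stop codon is deliberately out of bounds for repair — a
violation that can only be fixed by rewriting the stop is reported as
infeasible rather than silently changing termination.

### Default constraint values

The constraint defaults are the package's own choices of what a gene-
synthesis order would typically require:

| parameter | default | rationale |
|---|---|---|
| forbidden motifs | BsaI `GGTCTC`, EcoRI `GAATTC`, BamHI `GGATCC`, NotI `GCGGCCGC` | common Golden-Gate/cloning enzymes; NotI because integrative plasmids are typically NotI-linearised before transformation, so the insert must not carry a site |
| `max_homopolymer` | 8 nt | synthesis-vendor style cap on single-base runs |
| `gc_window` | 50 nt in [0.30, 0.65] | flags local AT- or GC-rich stretches at the scale synthesis screens use |
| `global_gc` | off | host-level composition is usually acceptable once windows pass |

All of these are explicit arguments; `constraint_set()` validates the
invariants (IUPAC motifs, window width ≥ 10, 0 ≤ min < max ≤ 1).

### Construct operators

Residue coordinates are 1-based inclusive, matching the Δ-notation used
for truncations (Δ1–37 removes residues 1–37; Δ2–37 preserves the initial
methionine); nucleotide coordinates in traces are 0-based half-open.
Truncation refuses to delete the C-terminus. Fusion removes the upstream
stop symbol, inserts `repeats` copies of the linker (GSG by default; linker
length is a tunable with real effects on fusion-enzyme activity, hence the
repeat parameter), and leaves the downstream sequence untouched — whether
the downstream partner keeps its initial Met is the caller's decision, and
the two Δ variants above are exactly that distinction. The NTM-domain swap
maps residue boundary $r$ to nucleotide $3r$ and concatenates donor codons
$1..r_d$ with recipient codons $r_r{+}1..$end; no junction re-optimization
is attempted, mirroring how such chimeras are actually ordered (plain
segment concatenation at the predicted TM boundary). Because whole codons
are copied, the frame is preserved by construction and no new stop can
appear at the junction; the check remains as a guard for malformed inputs.
Domain boundaries are user inputs — transmembrane-domain *prediction* is
out of scope.

### Alignment

`global_align()` is true global (Needleman–Wunsch) alignment with affine
gaps, delegated to `Biostrings::pairwiseAlignment()`; the package maps the
needle-style gap cost $g(L) = \mathrm{open} + (L-1)\,\mathrm{ext}$ onto
Biostrings' $\mathrm{opening} + L\,\mathrm{ext}$ convention. Defaults are
the needle DNA defaults (match +5, mismatch −4, open 10, extend 0.5).
Identity is matches divided by the *full* alignment length including gap
columns. End gaps are penalized; needle's default `endweight=false`
convention (free end gaps) differs here, which matters only for sequences
of very different lengths — for same-protein codon variants the effect is
nil to negligible. The independent correctness check is an exhaustive
enumeration over all monotone residue matchings (every global alignment
decomposes into matched columns plus contiguous gap runs, and contiguous
runs are optimal whenever extend ≤ open), which the dynamic-programming
score must reproduce — the suite checks ≥ 500 random short pairs plus the
closed-form limit where unit-match/free-gap score equals the longest
common subsequence length.

## What the fixture generator emulates — and what it does not

`generate_cds_set()` draws, per residue, a codon from stated per-family
frequency vectors (default: geometric decay 0.5 across each family, a
realistic strength of bias for a highly expressed gene set), uniform
amino-acid composition unless a composition vector is given, uniform body
lengths within a range, ATG starts, sampled stop codons, and no internal
stops. That is sufficient for what it is used for: parameter-recovery
calibration (with 200 genes × 300 codons, per-codon binomial error
$3\sqrt{p(1-p)/n}$ stays under the 0.03 acceptance band), optimizer
round-trips, and deterministic fixtures. It does **not** emulate real
genome statistics: no GC-content gradients, no gene-length/expression
correlation, no dinucleotide or codon-pair structure, no 5'-end ramp.
Passing tests therefore demonstrate algorithmic correctness and estimator
consistency, not that any particular biological usage table is recovered.

## Worked example

```{r example}
# a usage table from a synthetic "highly expressed" gene set
cds <- generate_cds_set(bias_spec(n_genes = 100, seed = 11))
tab <- compute_usage_table(cds, source = "synthetic top-100 set")
tab

prot <- seq_record("P450_target",
  paste0("MTFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGG",
         "CYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLV"),
  "protein")
strict <- back_translate_strict(prot, tab)
scan_violations(strict, constraint_set())

res <- optimize_codons(prot, tab)
res$cai_before
res$cai_after
res$trace

# how far did the repair move the gene from the strict encoding?
global_align(strict, res$record)$identity_pct
```

## Numerical and design choices

* **Determinism everywhere**: ties in ranking (equal expression), in
  back-translation (equal weights) and in repair (equal weight loss) are
  broken lexicographically; the fixture generator takes its seed from the
  spec object and restores the caller's RNG state.
* **Boundary tie at rank n**: `rank_top_genes()` always returns exactly
  `n` ids, breaking expression ties lexicographically rather than
  including all tied genes — a deterministic output size matters more than
  symmetry here, and the choice is documented in the function.
* **Expression units**: the ranking uses the value column as given;
  the package does not recompute TPM/RPKM, since ranking is
  scale-invariant for any monotone unit change.
* **Truncation ids** use an ASCII `d` (`_d2-37`) rather than the Δ glyph
  so FASTA ids stay portable.
* **Floating point**: family frequencies are validated to sum to 1 within
  1e-9 at construction and 1e-3 on file ingest (the TSV format rounds to
  six decimals); CAI comparisons in tests use 1e-12 against a direct
  product oracle.
* **Problem sizes in the shipped suite** (chosen to make the statistical
  assertions sharp while keeping the suite quick to run): 200 small-protein
  exhaustive-optimality instances, 1000 optimizer round-trips at 20–40
  residues, 500 brute-force alignment pairs at length ≤ 8, and 200 × 300
  codons for parameter recovery.

## Known limitations

* The optimizer repairs locally around each violation; it does not
  re-encode whole windows or perform global search, so adversarial
  constraint sets can be declared infeasible even when a distant recoding
  would comply. For realistic constraint densities this does not occur in
  practice, and small instances are provably optimal (see above).
* No mRNA secondary-structure, codon-pair-bias, ramp or harmonization
  objectives — the optimizer's objective is CAI under hard constraints,
  nothing else.
* GenBank parsing covers the flat-file subset needed for CDS extraction
  (`join`, `complement`); locations with ambiguous ends (`<`/`>`),
  `order()`, or cross-record references are rejected with an
  unsupported-location error.
* Alignment is DNA-only and global-only by design; protein matrices and
  local alignment are out of scope.
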