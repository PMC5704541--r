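---
title: "Methods: detecting site-specific selection on tumor somatic mtDNA mutations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting site-specific selection on tumor somatic mtDNA mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoselect)
```

## The question and the model

Human mtDNA is a circular 16,569-bp genome with 37 genes (13 mRNAs for
OXPHOS subunits, 22 tRNAs, 2 rRNAs) and a ~1.1-kbp control region. Tumor
somatic mtDNA substitutions, taken in bulk, look close to what
mutation-rate bias alone predicts — consistent with relaxed purifying
selection. `mitoselect` asks a finer question: do *specific* functional
units (complexes, genes, tRNA structural elements, mutant codons, amino
acids, local sequence contexts) deviate from that neutral expectation?

The inference is a calibrated-null comparison rather than a parametric
evolutionary model:

1. **Calibration.** The relative frequencies of the 12 directional base
   substitutions (reference-strand labels; `hl_label()` maps to the
   heavy/light presentation) are estimated by direct counting from the
   observed cohort. This embodies the working assumption that selection
   does not shape the *overall* substitution pattern — only deviations
   from it are interpreted.
2. **Neutral simulation.** Mutation sets of the observed size are drawn
   i.i.d.: type from the calibrated spectrum, position uniform over all
   genome positions carrying the type's source base, with replacement.
   Placement is deliberately context-free: weighting by local context
   would build into the null exactly the signal the triplet-context
   analysis is meant to detect. Default replicates R = 10, averaged
   arithmetically.
3. **Comparison.** Mutation densities (count/length, chi-square against
   length-proportional expectations), recurrence rates (F = ΣR/L),
   and standardized residuals of category counts
   (δ\* = (δ − δ̄)/σ with δ = observed − simulated, sample SD,
   two-sided flag at |δ\*| > 2).

## Tunable parameters

| Parameter | Default | Rationale |
|---|---|---|
| `n_replicates` (simulation) | 10 | stabilizes the reference counts; a single-replicate mode reproduces one-shot comparisons |
| residual threshold | 2 | the conventional two-sided standardized-residual cutoff; deficits (negative δ\*) are as meaningful as excesses |
| `min_vaf` (filter) | 0.02 | variant allele fractions below 2% are within sequencing-error range on Illumina-class platforms; records *without* a measured level are kept |
| `max_mutations_per_patient` | 12 | patients with ≥ 13 somatic mtDNA mutations are implausible hypermutators and are excluded entirely, after the VAF filter |
| heteroplasmy strata | ≤ 0.05, 0.05–0.9, ≥ 0.9 | boundary ties resolve outward, matching the printed interval labels |
| residual `method` | `"difference"` | the formula above; `"regression"` standardizes residuals about the least-squares line of observed on simulated, for trend-line-style readings. The regression mode treats simulated counts as x and observed as y; this orientation is a config choice, not a claim |

Pearson correlations are computed on untransformed counts, against the
replicate-*averaged* simulated table by default (single-replicate mode is
available by passing `n_replicates = 1`).

No multiple-testing correction is applied anywhere; every p-value is
raw and two-tailed. Users scanning many units should account for this.

## Annotation conventions

- Coordinates are 1-based rCRS numbering; the control region is one
  noncoding feature with two segments (16024–16569, 1–576); the triplet
  context wraps circularly at the origin.
- Translation is fixed to the vertebrate mitochondrial code (NCBI
  table 2) — the only valid code for human mtDNA mRNAs; no override.
- Overlapping genes (ATP8/ATP6, ND4L/ND4, and the shared ATP6/COX3
  boundary base) produce one annotation per gene, and per-gene densities
  count a mutation in each gene; genome-wide class tallies count it once
  at the most severe class (stopgain/stoploss > nonsynonymous >
  synonymous). Codon and amino-acid count tables use the *primary* frame
  — the earlier-started gene — so each mutation contributes one mutant
  codon.
- Genes whose terminal codon is completed by polyadenylation have a 1-
  or 2-base partial codon at the gene end; mutations there get an empty
  class and are excluded from codon/amino-acid tables (no mutant codon is
  well defined).
- tRNA structural classes (stem versus loop/variable) come from an
  idealized cloverleaf template (canonical 73-position layout with
  acceptor, D, anticodon and T arms, scaled linearly to each gene's
  length, read from the 3' end for L-strand genes). This is a model, not
  a per-gene experimental structure: per-position assignments near
  element boundaries are approximate, which is why the analysis uses the
  coarse binary classes.
- The codon/anticodon complementarity classes (`codon_cc_table()`)
  derive from a wobble model of the 22-tRNA decoding system: family
  boxes are read by U34 tRNAs (CC codon ends in A), two-codon NNY sets
  by G34 (CC ends in C), NNR sets by U34 (CC ends in A) except Met
  (anticodon CAU, CC codon ATG). It yields exactly one CC codon per tRNA
  species. The mapping is replaceable by users with a curated table.

## The bundled reference and the synthetic-data generator

Because the package must be fully testable offline, it ships the
authentic rCRS gene coordinates over a **synthetic** sequence
(`build_synthetic_reference()`): mtDNA-like base composition, valid open
reading frames on every primary frame (start codon, no internal stops,
full or polyadenylation-completed terminal stops), and pinned well-known
reference alleles (m.3460G, m.8993T, m.11778G, m.14484T). Analyses of
real mutation tables should load a real rCRS FASTA with
`load_reference()`.

`cohort_model()` / `generate_cohort()` produce synthetic cohorts with the
structure the analysis assumes:

- per-patient mutation counts on 1..8 with mode 1 and mean ≈ 1.8,
  matching the shape of observed per-patient burden histograms;
- the default spectrum puts 92% of mass on transitions, dominated by
  heavy-strand C>T (reference G>A, 45%) then T>C (33%) — the
  characteristic replication-bias pattern of tumor mtDNA;
- heteroplasmy is a two-component mixture: a low-frequency component on
  [0.02, 0.2] and a near-homoplasmic component on [0.9, 1.0] (Beta(1.5,3)
  shapes within each interval, equal weights), with half the records
  lacking a measured level — reproducing the observed *range*
  (2%–100%) and the prevalence of missing levels without asserting an
  unpublished distribution;
- plantable selection: `region_multipliers` scale placement rates by
  gene/ftype/complex/tRNA-unit label (a position in several matching
  features takes the product; a zero multiplier empties the region), and
  `codon_effects` scale by the mutant codon the substitution would
  create, evaluated on the primary frame — mirroring exactly what
  `residual_analysis()` measures.

What the generator does **not** emulate: per-patient clonal structure or
tumor evolution, sequencing error and read-level noise, strand-asymmetric
replication mechanics, context-dependent mutation rates, and real
linkage between tumor type and spectrum. Passing recovery tests
therefore demonstrate that the statistics detect effects *of the planted
kind and size* under realistic cohort geometry — not that real tumor
data contain such effects.

## Numerical and degenerate-input choices

- Chi-square tests use `correct = FALSE` (no Yates continuity
  correction), so 2×2 statistics equal their textbook hand-computed
  values; expected counts come from length (or margin) proportions.
- `residual_analysis()` refuses fewer than 3 categories and raises a
  distinct error when sd(δ) = 0 (e.g. observed ≡ simulated) instead of
  emitting NaNs; the category universe is the union of both tables with
  zero fill.
- Student's t-tests use pooled variance; two constant equal groups give
  p = 1 and two constant different groups give p → 0 (statistic ∞)
  rather than erroring.
- All randomness flows from one root seed; simulation replicates use
  child seeds drawn deterministically from it, so any replicate is
  reproducible independent of scheduling.
- Merging prefers WGS > WES > capture within a patient and intersects
  same-method sources by (position, ref, alt); within-source exact
  duplicates collapse with a warning; conflicting reference bases across
  sources are an error, not a silent vote.

## Validation strategy and problem sizes

The test suite validates the pipeline at three levels, with sizes chosen
to make the checks sharp while keeping the default run light:

- **Exact oracles**: hand-computed values for F = ΣR/L, δ\*, the
  12-type classifier, chi-square statistics and toy codon annotations.
- **Distributional properties** (fixed seeds): simulated type
  frequencies pass a chi-square goodness-of-fit against the spectrum and
  placement passes a Kolmogorov–Smirnov uniformity check at n = 50,000
  (α = 0.001).
- **End-to-end calibration and recovery**: 200 neutral study-scale
  cohorts (3,277 patients) yield a mean flagged-category rate well under
  10%; a planted ATP8 ×0.2 depletion is detected (density chi-square
  p < 0.01) and a planted CCC ×10 enrichment is flagged (δ\* > 2) in at
  least 90% of 100 seeds at n = 5,000 mutations, while neutral cohorts
  trigger the ATP8 comparison in at most 10%.

`scripts/acceptance.R` re-runs these end-to-end quantities from scratch
under a user-supplied seed and writes them as JSON.

## Known limitations

- The neutral null inherits any bias of the calibration cohort; strong
  genuine selection in the calibration data would partly absorb itself.
- Standardized residuals share one variance estimate across categories
  with very different counts; low-count categories are conservatively
  hard to flag.
- The synthetic reference sequence is not rCRS; position-level results
  on it are structural stand-ins, not biological statements.
- Functional-impact categories are consumed from external tables
  (MitImpact-style for mRNA, benign/deleterious for tRNA); the package
  does not compute deleteriousness scores.
- Insertions/deletions, variant calling from reads, and phylogenetic
  codon models (dN/dS) are out of scope.
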