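---
title: "stallscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{stallscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stallscan)
```

## The scientific problem

A class of bacterial arrest peptides stalls its own translating ribosome
through a short C-terminal tetrapeptide core — RAPP, RGPP, RAGP and
relatives. Because an accidental occurrence of such a motif inside an
ordinary protein would impede its synthesis, proteomes are expected to
avoid these sequences, and candidate regulatory arrest peptides should
surface as small, unannotated upstream ORFs (uORFs) carrying the motif
near their C-terminus, sitting in front of genes they plausibly regulate
(protein export, membrane insertion, metal transport, and similar).

stallscan implements the computational side of this programme:

1. a composition-normalized **tetrapeptide frequency-bias** statistic with
   clade-level aggregation and underrepresentation ranking;
2. a **motif census** with a small-protein filter, distance-to-C-terminus
   distributions and a pluggable localization classifier;
3. a **uORF → downstream-gene enrichment** test (exact hypergeometric
   Fisher test, Benjamini–Hochberg correction);
4. a **synthetic-data generator** that plants all of the above structure
   with known ground truth, so every stage is testable offline.

## The frequency-bias statistic

For a proteome with sequences $s_1, \dots, s_m$ and a pattern $w$ of
length $k$ (default $k = 4$), every sliding window of $k$ consecutive
residues is examined; overlapping windows all count. Writing $N$ for the
number of valid windows and $n_w$ for the number equal to $w$:

$$
f_{\mathrm{obs}}(w) = \frac{n_w}{N}, \qquad
f_{\mathrm{exp}}(w) = \prod_{i=1}^{k} c(w_i), \qquad
B(w) = \frac{f_{\mathrm{obs}}(w)}{f_{\mathrm{exp}}(w)},
$$

where $c(a)$ is the proteome-wide frequency of amino acid $a$ (computed
with `Biostrings::alphabetFrequency` over standard residues). $B(w) < 1$
indicates underrepresentation relative to what the proteome's amino-acid
usage alone would predict. The null model is deliberately simple —
independent residues — so $B$ conflates genuine avoidance with any
neighbour-dependence of amino acids; this is inherent to the statistic,
not an implementation choice, and is why conclusions are drawn from
extreme ranks and cross-clade consistency rather than from $B$ of a
single pattern in a single genome.

Conventions fixed once, used everywhere:

* Windows containing a non-standard letter (X, B, Z, J, U, O) are
  excluded from **both** $n_w$ and $N$, and composition uses standard
  residues only. This keeps $\sum_w f_{\mathrm{obs}}(w) = 1$ exactly over
  the $20^k$ standard patterns, instead of projecting ambiguity codes
  onto the 20-letter alphabet arbitrarily.
* A single terminal `*` is stripped on FASTA read (downloaded
  translations sometimes retain the stop, which would otherwise produce
  spurious windows).
* $B$ is *undefined* — `NA` with an explicit flag — when
  $f_{\mathrm{exp}} = 0$ or $N = 0$; it is never coerced to 0 or
  $\infty$. A pattern that simply never occurs has $B = 0$.
* Whether "occurrence" means sliding windows or motif-containing proteins
  is ambiguous when proteins carry at most one copy (the common case for
  rare motifs). Window counting is the default; a per-protein mode is
  available via `frequency_bias(..., mode = "proteins")` for sensitivity
  checks.

### Clade aggregation and ranking

Per-genome biases are aggregated by phylum (or class, for the very large
Pseudomonadota): mean, median, the fraction of genomes entirely lacking
the pattern, and the empirical cumulative distribution function of
defined biases (right-continuous; genomes with undefined bias are dropped
from the moments, never imputed). Clades larger than a cap (default
1000 genomes) are reduced by a seeded uniform draw without replacement
(default seed 214); the draw is deterministic for a fixed seed.

The underrepresentation ranking scores each pattern by the **unweighted
mean over clades of the clade means**, so a species-rich clade cannot
dominate the ranking; ties are broken lexicographically. The default
report keeps the lowest 20 (50 for the extended view).

## Motif census and localization

`scan_motifs()` reports every occurrence (overlapping allowed), with
1-based inclusive protein coordinates and
`distance_to_C = protein_length - end` (0 when the motif is flush with
the C-terminus). The census counts a protein once per motif regardless of
multiplicity and applies a strict `< 300` residue small-protein filter.
Per-protein distance summaries use the C-terminal-most occurrence; the
full occurrence table is retained so per-occurrence positional plots
remain possible — both views are emitted rather than guessing which one a
given figure style needs.

Localization (secretory SP / transmembrane TM / cytosolic CP) is a
pluggable predictor. The default is a transparent Kyte–Doolittle
heuristic: rolling hydropathy over 19-residue windows, evaluated at
window centers (residues $10 \dots n-9$); a maximal run of centers with
mean $\ge 1.6$ is a hydrophobic segment; a segment lying fully within
residues 1–35 preceded by at least one K/R is a signal anchor; SP if a
signal segment exists and no TM segment ends after residue 35, TM if one
does, CP otherwise. Proteins shorter than one window are CP with a
warning flag. Segments are defined on center runs (not full window
extents) so that an N-terminal signal anchor can still have "residues
before it" to carry the positive charge. The window means are computed
with a literal `mean()` per window rather than a cumulative-sum trick:
at the threshold boundary the classification must not depend on
floating-point summation order. This heuristic is a deliberately simple
stand-in for a trained topology predictor; `read_deeptmhmm()` ingests
externally produced DeepTMHMM output for users who run the real tool,
and all pipeline code accepts either predictor interchangeably.

## uORF → downstream-gene enrichment

Only CDS features participate. A uORF's downstream partner is the
nearest same-contig, same-strand CDS whose translation-direction start
follows the uORF's stop (minimal `start > end` on `+`, maximal
`end < start` on `-`); no intergenic distance cap is imposed by default
(`max_gap` is configurable) because adjacency in the same orientation is
the only structural requirement the biology imposes. Pairs are kept when
the uORF is small (< 300 aa) and annotated as
unknown/hypothetical/uncharacterized, while the downstream gene has a
non-empty annotation not containing "unknown".

Groups are normalized annotation strings (lowercase, collapsed
whitespace, trailing punctuation stripped) compared **exactly** — no
fuzzy matching, so "TonB-dependent receptor" and "TonB dependent
receptor" are distinct groups. Curated super-groups are a user-supplied
mapping concern, not something the package infers.

For a target/control motif pair (RGPP/AGPP or RAPP/AAPP) and each group,
the $2 \times 2$ table $(a, b, c, d)$ gives the proportion-normalized
fold enrichment $\frac{a/(a+b)}{c/(c+d)}$ — proportions, not raw counts,
so unequal motif totals remain comparable. Groups with $c = 0$ are kept
and flagged (`infinite_fold`), never dropped or pseudocounted. The
p-value is Fisher's exact test computed from hypergeometric probabilities
in log space, two-sided by the minimum-likelihood rule with a $10^{-7}$
relative slack on the probability comparison (the classical definition;
one-sided alternatives are available). Benjamini–Hochberg adjustment is
applied over all groups of one comparison family (one motif pair), and
significance is declared at adjusted $p < 0.01$.

## The synthetic-data generator

The generator defines the study conditions for all tests; its defaults
are fixed once:

* **Composition**: the Swiss-Prot–like average amino-acid composition
  (`default_composition()`).
* **Protein lengths**: lognormal with `meanlog = log(245)`,
  `sdlog = 0.55`, truncated to [50, 2000] residues — median ~245,
  matching typical bacterial proteins.
* **Motif planting**: each protein independently receives a planted copy
  with probability `p`, either at a uniform position or with its end
  confined to the last `w` residues (`c_terminal` placement).
* **Depletion**: background occurrences of a listed motif are thinned to
  a factor `d`: kept with probability `d`, otherwise one residue of the
  window is resampled from the composition until the window no longer
  matches; passes repeat until no untreated occurrence remains. This
  post-hoc thinning gives a provable target: the expected measured bias
  of the thinned pattern is `d`. (A mutation can occasionally destroy an
  adjacent kept occurrence; the effect is second-order and covered by
  the recovery tolerances.)
* **Annotated genomes**: uORF/downstream pairs laid along one contig with
  Bernoulli(0.5) strands, uniform(0, 500) nt intergenic gaps, 1000-nt
  spacers between pairs, and opposite-pattern decoy genes interleaved.
  Enrichment factors multiply the focal group's draw probability, and the
  *complement* groups are scaled down to renormalize; this makes the
  expected target:control proportion ratio equal the planted factor
  exactly, which uniform renormalization of all weights would not (it
  shrinks the realized ratio by $1/(1 + w(f-1))$ and would make factor
  recovery systematically unattainable at realistic baseline weights).
* Seeds are mandatory; a fixed seed gives byte-identical FASTA/GFF3.

What the generator does **not** emulate: codon usage, GC content,
neighbour-dependent amino-acid correlations, paralogy, and phylogenetic
correlation between genomes. Passing tests therefore demonstrate that the
pipeline recovers planted structure under an idealized independence
model, not that real proteomes satisfy that model.

## Problem sizes and numerical tolerances in the test-suite

Simulation sizes were chosen so that Monte-Carlo noise sits well inside
each assertion's tolerance at a fixed seed:

* Null calibration uses an iid proteome of 1800 proteins (~4–5×10⁵
  windows); pattern-level bias checks use the binomial standard error on
  the observed count (4 SE band).
* Depletion recovery uses 10,000 proteins (~2.8×10⁶ windows) with
  R/A/P-enriched composition: at this size the relative Monte-Carlo
  spread of the recovered factor is ~6%, so the 20% acceptance band is a
  ≥3σ margin. At a quarter of this size the spread is ~12% and the band
  would be only ~1.7σ — too fragile to be meaningful.
* Enrichment recovery uses 500 uORFs per motif over a 20-group catalog
  with a 5× factor on one group.
* Oracle-equivalence checks run at 10⁻¹² (bias) and 10⁻⁹ (Fisher)
  against naive enumeration oracles; the Fisher check is exhaustive over
  all 2×2 tables with total ≤ 40.

Clade-ranking recovery is asserted within the 81-pattern {R, A, P}
universe: at desk scale most of the 160,000 patterns have expected count
far below 1 per genome, so their bias estimates are uninformative zeros
that would swamp any ranking; restricting the universe to frequent
patterns is the honest desk-scale analogue of the full-scale ranking.

The worked single-genome reference values (an E. coli K-12 MG1655
RGPP/RAPP/RAGP bias of 0 / ~0.073 / ~0.22, B. subtilis 168 RAGP ~0.103)
require downloading the RefSeq proteomes;
`scripts/reproduce_worked_values.R` runs that reproduction against the
installed package. The offline suite exercises the same code path on a
fixed proteome with hand-computed expected values.

## Known limitations

* The composition null ignores residue autocorrelation; biases of
  patterns built from clustering-prone residues drift from 1 even in
  biologically neutral sequence.
* The hydropathy heuristic is far less accurate than a trained
  predictor; its role is to make the localization stage runnable and
  testable, with the external-predictor adapter as the production path.
* Annotation grouping is string-exact; annotation vocabulary drift
  between genomes dilutes groups and biases enrichment toward null.
* The Fisher test conditions on both margins; with very small groups the
  discrete p-value distribution makes the BH threshold conservative.
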