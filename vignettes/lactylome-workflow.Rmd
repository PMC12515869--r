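---
title: "Quantifying lysine-lactylation changes corrected for protein abundance"
author: "lactylomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lysine-lactylation changes corrected for protein abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lactylomics)
```

## The problem

Lysine lactylation (Kla) is a lactate-derived post-translational
modification. In label-free LC-MS experiments that profile both a lactylome
(site-level intensities of lactylated peptides) and the matching global
proteome (protein-level intensities), an apparent change in a site's
intensity confounds two things: a change in the modification stoichiometry
and a change in the abundance of the parent protein. `lactylomics`
implements the full analysis chain for a two-group (e.g. sham-operated
control versus myocardial-infarction case, n = 3 animals per group) design:

1. **Quantification.** Per-sample loading normalization, row centering to
   relative quantification values, and division of each site's relative
   quantification by its parent protein's, so that reported changes reflect
   stoichiometry.
2. **Differential testing.** Fold change as the ratio of linear-scale group
   means; Shapiro–Wilk and Brown–Forsythe gates on the log2 values select
   Student's or Welch's t-test; Benjamini–Hochberg q-values; calls from
   FC > 1.5 (or < 1/1.5) with raw p < 0.05.
3. **Cataloguing.** Sites per protein, the singly-modified fraction, top
   proteins, flanking windows, compartment tallies, and the Venn overlap
   between modification-changed and abundance-changed proteins.
4. **Sequence context.** Positional residue frequencies around the central
   lysine and a greedy motif-x style search against the proteome's
   K-centered background.
5. **Networks.** MCODE molecular-complex detection on a PPI edge list.
6. **Enrichment.** Hypergeometric over-representation analysis and
   preranked GSEA.

A synthetic-data generator reproduces the statistical structure such a
study assumes, with ground truth, so every stage is testable at desk scale.

## The quantification model

Let $x_{ij}$ be the raw intensity of site $i$ in sample $j$ and $y_{pj}$
the intensity of its parent protein $p$. The chain is:

* **Normalization.** One multiplicative factor $f_j$ per sample equalizes
  the protein-table column medians at the median of medians. The *same*
  $f_j$ is applied to the site table. Loading is a property of the sample,
  not of the feature class; sharing the factors also makes normalization
  exactly transparent to every ratio $x_{ij}/y_{pj}$. (Normalizing the two
  tables separately would let an asymmetric burden of modification changes
  shift the site-table medians group-dependently and leak a spurious fold
  change into *every* corrected site — we observed residual
  $|\log_2\mathrm{FC}|$ up to ~0.17 on noise-free simulations.)
* **Centering.** Each feature row is divided by the mean of its present
  values, giving unitless relative quantifications with row mean 1.
  Division (not subtraction) keeps values positive so that downstream fold
  changes remain ratios of means.
* **Correction.** $z_{ij} = \tilde x_{ij} / \tilde y_{p(i)j}$, missing
  whenever either operand is, then re-centered. Sites whose parent protein
  was not quantified ("orphan sites") are dropped with a count rather than
  passed through uncorrected.

The composition is invariant to any per-sample scaling of the raw inputs,
and on data where only protein abundance differs between groups the
corrected site fold changes are 1 to machine precision.

Whether row centering happens before or after the site/protein division is
not identifiable from the fold-change results (the two orders differ by a
row-constant factor that cancels in a ratio of means); we center first and
re-center after the division so the row-mean-one invariant holds at every
stage.

## Differential testing choices

* Fold change is computed on linear-scale relative quantifications (ratio
  of group means); tests run on log2 values. Features with fewer than 2
  present values in a group are reported `untestable`, never silently
  dropped.
* The Shapiro–Wilk gate runs per group on the log2 values. With n = 3 it
  has very little power, so the gate usually selects Student's test; this
  mirrors the described decision logic and is documented as low-power
  rather than "verifying" normality. Groups too small or constant cannot
  reject normality and pass the gate. Levene's test uses median centering
  (the Brown–Forsythe variant) for robustness; with groups of two present
  values its F statistic degenerates and the gate treats the undefined p as
  "cannot reject".
* Features with zero variance in both groups are untestable (p = 1).
* Significance calls use the raw p-value together with the FC cutoffs
  (up if FC > 1.5, down if FC < 1/1.5, p < 0.05); BH q-values are computed
  across all tested features and reported alongside. The BH implementation
  is `stats::p.adjust(method = "BH")` behind a validated wrapper that the
  test suite checks against a brute-force step-up oracle.

## What the generator emulates — and what it does not

`synthetic_design()` defaults describe the emulated study: 3 vs 3 samples;
a 1,000-protein proteome of which 47.7% carry sites (~477 modified
proteins, ~1,700 sites); 44.03% singly-modified proteins with a
heavy-tailed sites-per-protein mixture (single-site with probability
`single_site_frac`, otherwise `2 + NB` with mean proportional to the
protein's lysine count, calibrated to ~3.5 sites per modified protein);
log-normal base abundances; per-sample scaling with SD 0.25 (natural-log
space); 10% of sites spiked at a true fold change of 2 and 10% of proteins
spiked independently at 2 (half up, half down each, mirroring the
predominance of both directions in real data); residual noise SD 0.15;
5% missing values, completely at random by default (an intensity-dependent
MNAR option exists but is off — the missing-data structure of real DIA
tables is not identifiable from summary statistics alone).

Two modeling decisions deserve emphasis:

* **Shared protein-level variation.** A site's intensity is generated from
  its parent protein's *realized* per-sample quantity — including the
  protein-level log-normal variation — times a stoichiometry drawn
  uniform(0.05, 0.5), a site-level group effect, and independent site-level
  noise. In an n = 3 animal design the protein-level variation is dominated
  by biology and is therefore common to the protein measurement and its
  site peptides; the site/protein correction removes exactly this shared
  component. Under this model the corrected values carry only the
  site-level noise, and the default conditions give a spiked-site
  sensitivity of ~0.80–0.88 with an observed false-discovery proportion
  below 0.05 and a null type-I rate of ~0.04–0.05.
* **Stoichiometry is a nuisance constant.** Any positive per-site constant
  cancels in the correction; sub-stoichiometric values (0.05–0.5) are the
  norm for PTMs.

What passing tests on this generator do **not** show: robustness to
informative missingness, to peptide-level interference, to
match-between-runs artifacts, or to misassigned site localizations — none
of which the generator attempts to produce.

## Motif search

The background is the set of all K-centered `2w+1`-mers of the supplied
proteome (the motif-x convention of conditioning on the central residue),
not bulk residue composition. At each greedy step the (offset, residue)
cell with the smallest binomial upper-tail p-value of the foreground count
at the background frequency is fixed, requiring p < 1e-6 and at least 20
foreground occurrences (published motif-x defaults); the window sets are
restricted and the step repeats. Emitted motifs have their foreground
matches removed before the search restarts. Ties break by offset then
residue, so results are deterministic. The padding character `_` never
matches. Enrichment ratios add a pseudo-frequency of `0.5/n` on both sides
to stay finite; p-values always use raw counts.

## MCODE

Vertex weight = the highest k-core level of the closed neighborhood times
that core's density; seeded expansion (descending weight, lexicographic
ties) includes unvisited neighbors with weight at least
`(1 - node_score_cutoff)` of the seed's; complexes lacking a 2-core are
dropped; haircut (on by default) removes singly-connected members; fluff is
off by default; score = subgraph density x size. Two caveats discovered
while validating against brute force, both pinned in the test suite:

* Vertex weights are **not** monotone under edge addition: a new edge can
  pull a low-degree neighbor into a neighborhood's top core and dilute its
  density (a K4-plus-pendant example drops a weight from 3 to 2.7). Only
  locality holds: edges entirely outside a closed neighborhood never change
  that vertex's weight.
* Weight-threshold expansion cannot split two equal cliques joined by a
  *direct* bridge edge — the bridge endpoints have the same weight as every
  other clique member by symmetry, so the expansion crosses and reports one
  merged complex. Cliques joined through a low-weight linker node are
  separated cleanly (two K6 complexes each score exactly 6.0). For the same
  reason, planted-partition blocks are recovered reliably only when
  between-block edges are absent; with homogeneous weights even a 2%
  between-block edge probability lets the first expansion swallow several
  blocks. This is a property of the algorithm, not of the implementation.

## GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum (hits add `|metric|^w / sum`, misses subtract `1/(N - N_hits)`; the
signed extreme is the score, with exact positive/negative ties resolving
positive). Because only a preranked list exists at desk scale, the null is
built by gene-label permutation — random same-size sets — rather than
phenotype permutation; this is a documented divergence from expression-mode
GSEA. NES divides ES by the mean |null ES| of matching sign; the
permutation p is the same-sign tail fraction (zero when no permutation
reaches the observed score); FDR q pools sign-normalized null scores across
sets in the standard way. The pipeline ranks proteins by the mean `log2fc`
of their sites.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run entirely on generated
data: proteomes of 400–1,200 proteins (~700–2,100 sites) for the
statistical checks, exhaustive 4-node graphs plus sampled 5–6-node graphs
for the network oracles, 4,000-window backgrounds for motif checks, and
1,000-gene ranked lists with 1,000 permutations for GSEA — sizes chosen so
the whole suite completes in about a minute while keeping Monte-Carlo
bands (type-I error within [0.03, 0.07], sensitivity at least 0.7)
comfortably away from their thresholds. Tolerances: exact-arithmetic
quantities (BH, ES, k-cores, scores) are checked to 1e-12; simulation
quantities use the stated bands.

## Known limitations

* No imputation, no moderated-variance (empirical-Bayes) testing, no
  paired designs or covariates; with n = 3 the gated t-tests are the
  described procedure, not the most powerful available one.
* Localization predictions, GO/KEGG membership and PPI edges are consumed
  as data; no external databases are queried.
* The motif search emits fixed-residue patterns only (no degenerate
  position classes), and the GSEA null is gene-label permutation only.
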