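---
title: "Integrative species delineation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative species delineation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Delineating microbial species — yeasts in particular — cannot rest on a
single marker: ribosomal barcodes (ITS, D1/D2) saturate slowly and can be
identical between genuinely isolated lineages, while glacial-cycle
population histories leave intricate divergence patterns across the genome.
`intertaxon` implements the integrative alternative: genome-wide identity,
population-genetic divergence with a divergence-time estimate, introgression
and structural-variant evidence, postzygotic reproductive isolation measured
by spore viability, and growth phenotyping, combined by an explicit decision
table rather than an opaque score. This vignette documents the models behind
each stage, the tunable parameters (with units and defaults), the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## Genome identity by fragment orthology (OANI)

Both assemblies are cut into consecutive, non-overlapping fragments of 1020
bp (the orthology-ANI convention; trailing remainders are dropped).
Orthologous fragment pairs are *reciprocal best hits*: fragment `i` of A
paired with `j` of B when each is the other's maximal-identity alignment
partner. OANI is 100 x the mean alignment identity over those pairs, with
each pair's identity averaged over the two alignment directions, so
`OANI(A, B) == OANI(B, A)` by construction.

Identity is computed from an affine **global** (Needleman–Wunsch) alignment
— match +1, mismatch −1, gap opening 10, gap extension 4 — as matches
divided by alignment columns, gaps included. We chose global over local
alignment deliberately: local alignment trims mismatch-dense fragment ends,
which inflates identity by a few tenths of a percent exactly where the
95–96% decision band makes tenths matter; global identity is exact on the
whole fragment, and returns precisely 100 for a self-comparison. Candidate
subjects are found by shared 15-mer counting (query k-mers sampled every 7
bp, both strands, top 3 candidates aligned) so the cost is linear rather
than all-vs-all; the exhaustive path is retained and the test suite asserts
the two paths agree on small genomes.

Parameters: `fragment_length` (bp, 1020), `k` (15), `min_coverage` (aligned
query fraction, 0.35), `min_identity` (0), band `lower`/`upper` (95/96%).
The band is always reported as a zone (`distinct` / `ambiguous` /
`conspecific`), never collapsed to a binary call, because published
delineation practice treats 95–96% as a gray zone.

At 7% genome-wide divergence — the level separating the sister species this
kind of analysis targets — OANI lands near 93%, squarely in the `distinct`
zone; the acceptance suite pins this correspondence on 500-kb simulations.

## Population genetics and divergence time

The variant table holds biallelic SNPs as alt-allele dosage (haploids 0/1;
a heterozygous diploid call contributes 0.5 — diploid data are collapsed at
the frequency level and the sample count is not doubled). Filtering follows
the conventional strict depth rule (`DP > 10`), quality `>= 30`, and no
missing genotypes; thinning is the greedy `--thin`-style scan (keep first,
then every site at least 500 bp from the last kept site), which is
idempotent.

* Nucleotide diversity: `pi = sum_sites 2 p (1-p) n/(n-1) / L`, which equals
  the mean pairwise difference count per site exactly (not just in
  expectation); the tests assert equality with an all-pairs oracle.
* Watterson: `theta_w = S / (a_n L)`, `a_n = sum_{i<n} 1/i`.
* Differentiation: Hudson-style ratio-of-averages Fst,
  `sum N / sum D` with `N = (p_a - p_b)^2 - p_a(1-p_a)/(n_a-1) -
  p_b(1-p_b)/(n_b-1)` and `D = p_a(1-p_b) + p_b(1-p_a)`. Because different
  packages default to different estimators and per-site averaging
  conventions, the estimator name is mandatory metadata in the result.
* Divergence time: the mutation parameter `theta = 2 N mu` applied at the
  divergence scale gives `generations = d / (2 mu)` with the yeast
  single-base rate `mu = 1.84e-10` per site per generation by default.
  Calendar conversion needs generations per year, which no one measures
  directly in the wild; we expose it as a range (default 164–1870 per year,
  roughly 0.45–5.1 divisions/day). The generations number is exact given
  `d` and `mu`; the year bounds are explicitly soft and configurable —
  published KYA intervals for such splits cannot all be reproduced by any
  single generations-per-year range, which is precisely why the parameter
  is not hard-coded.

`L`, the callable genome length, must be supplied; defaulting to the full
reference length (with a warning) biases every per-site statistic downward
and should only be accepted for simulated data where the two coincide.

## Introgression scanning

Candidate tracts are runs of 1-kb windows with **zero** SNPs against the
donor species and mapping coverage **strictly above** 20x — sequence
recently acquired from the donor is identical to it but still fully covered
by reads. A 1-based SNP at position `p` belongs to window
`floor((p-1)/w)`; coverage is overlap-weighted into windows, so re-windowed
coverage tables and short terminal windows are handled (a tract may not
consist solely of a short terminal window). Flagged windows merge across
`max_gap_windows` (default 0) and tracts shorter than `min_tract` (default
2 kb, the smallest signal such scans are expected to report) are dropped.

The false-positive argument is quantitative: at divergence `d`, a clean
window requires zero of ~`w*d` expected SNPs, with probability
`(1-d)^w` ~ `e^{-wd}` — about `1e-18` at `d = 0.04`, `w = 1000` — so any
surviving run of two or more windows is signal, not noise. Detection power
degrades below ~1% divergence, where same-species windows start going
SNP-free by chance; at 2% and above, recovery is exact to one window.

## Structural variants from alignment blocks

The caller consumes collinear alignment blocks (9-column TSV mirroring the
`show-coords -T` layout) rather than raw assemblies; an internal anchor
aligner — k-mers unique in both genomes (k = 21), matched on both strands
and chained into consistent-diagonal runs — produces blocks for simulated
genome pairs so the pipeline runs without an external aligner. Anchor
density falls as `(1-d)^k` (about 0.23 of positions at 7% divergence),
which still anchors every few bp; the block identity reported from density
is an estimate, not an alignment statistic.

Classification per query contig: the *primary* reference chromosome holds
the majority of aligned bases; runs on non-primary chromosomes are
translocations (size = reference span); embedded minus-strand runs are
inversions; a reference gap of at least `min_size` between collinear
neighbors with query gap under `gap_tolerance` (200 bp of breakpoint fuzz)
is a deletion, the converse an insertion; two disjoint query intervals
covering one reference interval (>= 0.9 of the smaller) are a duplication.
Two translocations whose segment chromosome and contig-primary chromosome
mirror each other are linked as a reciprocal pair; the rest are
non-reciprocal. A deletion whose reference interval coincides with a
translocated segment is suppressed — it is the donor-side footprint of the
move, not an independent event. Published practice filters to events over
1 kb and ignores rDNA-locus calls; both are parameters (`min_size`,
`exclusion_regions` BED).

Known limitations: nested events (an inversion inside a translocated
segment) are not resolved, and a contig aligning entirely on the minus
strand would read as one large inversion; both are outside the intended
scale of events.

## Reproductive isolation

Spore viability is `100 * viable / dissected` with a Clopper–Pearson 95%
interval (reported, never used for classification). Classes: below 20%
`reproductively isolated`, above 50% `compatible`, between them `partial
isolation` — thresholds chosen from the published contrast between
interspecies crosses (~5–6%) and intraspecies crosses (50–81%), and
configurable because they are conventions, not estimates. The
viability-versus-identity relation is an ordinary least-squares fit of
viability (%) on nucleotide identity (%, i.e. `100 - 100 d`), with
r-squared, adjusted r-squared `1-(1-r2)(n-1)/(n-2)` and the two-sided
slope p-value; both per-cross and per-lineage-mean fits are possible since
the input is just a point table.

## Growth phenotyping

Curves are logistic, `N(t) = K / (1 + ((K-N0)/N0) e^{-rt})`, fitted by
Levenberg–Marquardt with data-driven starts; `auc_fit` is the analytic
integral `(K/r) [ln(e^{rT}+A) - ln(1+A)]` over the observation window, and
the trapezoidal empirical AUC is always computed alongside. A fit that
fails, or "converges" to a decay curve (`N0 >= K`), falls back to the
empirical AUC with `converged = FALSE`; the matrix records which cells used
which. Cells are replicate means; columns are z-scored before clustering
(average-linkage, Euclidean, rows pre-sorted by strain id so ties are
deterministic). Condition-wise differences use one-way ANOVA, with compact
letters from Holm-corrected pairwise Welch tests at 0.05 — Welch rather
than a pooled-variance post hoc because condition variances differ across
lineages, and the published figure conventions do not specify a post hoc.

## The decision table

A pair is a `distinct-species-candidate` only when the OANI zone is
`distinct` **and**, if crosses exist, they show reproductive isolation;
genomic evidence alone yields the candidate verdict annotated "genomic
evidence only". In-band OANI is `ambiguous` no matter what else is known —
the band is a gray zone by definition — and conflicting evidence (distinct
identity with fertile crosses, or conspecific identity with sterile ones)
is reported as `ambiguous` with the conflict named, rather than resolved by
a hidden weight. Phenotype separation and SV counts are carried as
corroborating context only. The verdict is monotone: improving identity or
viability can never flip a pair from conspecific toward distinct.

## The synthetic generator: what it emulates, what it does not

`simulate_study()` generates the study conditions end-to-end: a random
ancestor (default four 50-kb chromosomes, GC 0.38); a reference lineage and
two sisters via per-branch uniform substitutions (stem branches 3.25%,
sister branches 0.5%, so sisters sit near 7% from the reference and ~1%
from each other); three strains per lineage at 0.2% branch divergence
(within-lineage pi ~ 0.004, matching the diversity scale such populations
show); 7/5/3-kb donor tracts implanted into one strain; one shared
reciprocal translocation plus private non-reciprocal translocations, an
inversion and a deletion in lineage A; 30x coverage; crosses; growth
curves over eight conditions in triplicate with lineage-specific deficits
on maltose, ethanol and galactose.

The substitution model is deliberately minimal — uniform base exchange,
independent sites, no indels, no rate heterogeneity, no selection, no
recombination; back-mutation is allowed, so realized divergence between two
branches at rates `p`, `q` is `p + q - (4/3) p q` (< 2% deflation at the
relevant scale), and tests assert against that exact expectation. The
cross model, `v0 e^{-alpha d} 0.5^s` with `v0 = 95%`, `alpha = 40` per
unit divergence and a factor-2 loss per heterozygous reciprocal
translocation, is a stand-in calibrated once so that intraspecies crosses
land in the 50–81% range and ~7%-divergence crosses under 10%; the halving
is the classical expectation for unbalanced meiotic products in a
translocation heterozygote. Coverage is per-base Poisson aggregated to
window means. None of these distributions is a claim about real data;
passing recovery tests shows the *estimators* are correct and unbiased
under a known truth, not that real genomes satisfy the model. Real-data
effects the generator deliberately omits: alignment error, repeat-induced
coverage spikes (the reason the rDNA exclusion exists), indels and
assembly gaps, population structure within lineages, and mitochondrial or
subtelomeric dynamics.

Seeds derive from `(seed, operation, ordinal)` via a fixed modular hash,
so each module can be rerun independently and the whole pipeline is
byte-deterministic; every emitted coordinate is 0-based half-open
internally and 1-based inclusive in VCF/GFF3 output, with BED staying
0-based.

## Problem sizes

The validation suite runs at deliberately desk-sized scales chosen to make
the statistical assertions sharp rather than big: 500-kb genomes for the
OANI-divergence correspondence (3 seeds), 300-kb genomes for 70/49/19-kb
tract recovery with ten 50-kb introgression-free controls, a six-chromosome
270-kb genome for the five-event rearrangement architecture, and a
12-kb-per-chromosome full pipeline for determinism. At these sizes binomial
noise on divergence estimates is ~0.1% absolute, an order of magnitude
below every tolerance asserted.

## Worked example

```{r example}
library(intertaxon)
report <- run_pipeline(sim_config(seed = 7), outdir = "run7")
report
attr(report, "stages")$popgen$divtime$REF.A
```
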