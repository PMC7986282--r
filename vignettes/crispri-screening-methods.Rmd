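---
title: "Models and methods for barcoded CRISPRi growth screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for barcoded CRISPRi growth screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CRISPRiScreen)
```

This vignette is the package's account of the science it implements: the
models and procedures, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open.

## The screening problem

CRISPR interference (CRISPRi) silences a gene by parking a dead Cas9
repressor fusion on its promoter, guided by a 20-nt RNA. In a pooled
screen, a library of guide-expression plasmids — each tagged with several
random nucleotide barcodes — is transformed into yeast, guide expression
is induced, and the population grows competitively for around a dozen
doublings. Barcode abundances, measured by sequencing at timepoints,
follow exponential dynamics; the rate of decline of a barcode measures the
fitness cost imposed by its guide. Barcodes give internal replication
(several independent lineages per guide) and distinguish defective
constructs from sequencing errors.

## Guide design

### Candidate enumeration

Cas9 requires an NGG protospacer-adjacent motif (PAM). Candidates are all
23-nt windows (20-nt protospacer + PAM) on either strand whose final two
bases are GG in protospacer orientation. A candidate's position is the
offset of the central (12th) base of its 23-nt span from the gene anchor,
signed in the transcription direction; 23 being odd, the central base is
unambiguous. The anchor is the representative transcription start site
(TSS) when isoform data exist — the modal (highest read count) isoform
start, with ties broken toward the TSS nearest the CDS start and then the
smaller coordinate, so annotation is deterministic under row permutation —
and otherwise the first CDS base.

Candidates are retained when the center falls in the association window:
**[−220, +20]** around the TSS, or **[−350, 0]** for CDS-anchored genes.
CRISPRi efficacy drops steeply outside roughly 200 bp upstream of the TSS,
which these windows cover with margin on both sides.

### Classification and scoring

* **Uniqueness**: the pattern `protospacer + [ACGT]GG` must occur exactly
  once in the genome, counting both strands. Counting uses a hashed
  k-mer index of the genome; genomic `N` bases never match, which is the
  conservative direction for uniqueness. Non-unique guides remain eligible
  at the lowest priority tier rather than being discarded.
* **Specificity**: a candidate associated (by the window rule) with
  exactly one gene is specific. Yeast's many divergent promoters — two
  genes transcribed head-to-head from a shared intergenic region a few
  hundred bp wide — produce ambiguous candidates whose alternative targets
  are recorded.
* **Accessibility**: the mean ATAC-style accessibility over the 23 target
  positions, averaged across the replicate tracks (we average the two
  replicate means; the source data leave the replicate-combination rule
  open). Positions without data count 0.0 (inaccessible), the
  conservative choice for a score that rewards openness.

### Selection

Priority is lexicographic: unique first, then specific, then greater
accessibility. Remaining ties are broken by closeness of the center offset
to −50 (the empirically best position — see the position curve below),
then smaller genomic coordinate, then + strand; selection is therefore
fully deterministic. To spread guides across the promoter, the best
candidate in each positional zone is taken first — zones
[−220, −141], [−140, −61], [−60, +20] for TSS genes and
[−350, −271], [−270, −191], [−190, −111], [−110, −30] for CDS genes — and
the remaining slots are filled best-first until ten guides are chosen or
candidates run out. Offsets in (−30, 0] of CDS genes belong to no zone but
remain selectable as fill.

Ambiguous guides at divergent promoters can later be resolved with the
fitted position curve: the guide is assigned to the gene at whose TSS
offset the curve predicts the higher activity, provided the ratio exceeds
a 2:1 margin (configurable; no empirical value for this margin is
established, so it errs toward leaving guides unresolved). Offsets outside
the design window predict inactivity.

## Barcode processing

Counting trims each read at the first occurrence of the 3′ adapter and
keeps barcodes of ≥10 nt; assignment reads use a longer adapter and ≥12 nt.
Single-nucleotide sequencing errors are absorbed by greedy directional
collapsing: barcodes in descending count order either found a record or
are absorbed by an existing founder at Hamming distance 1 (equal length
only — the rule is about substitutions). This conserves total counts and
is idempotent, since founders end pairwise at distance ≥2. Count tables
are filtered to barcodes seen in ≥2 libraries with ≥33 total reads and no
XhoI site (XhoI digestion is part of library preparation, so such barcodes
are depleted artifactually).

For barcode-to-guide assignment, guide reads are trimmed between their
flanking adapters (≥20 nt residual), discarded if any base is below Q30,
and matched to the guide library by Levenshtein distance (≤3 edits;
further reads are unmatched, and reads tied between two guides are
excluded from majority computations to avoid manufacturing heterogeneity).
A scaffold-only reference entry catches "empty" constructs that lack a
guide insert; these become neutral internal controls. Fates per barcode:

* `insufficient` — fewer than 3 high-quality reads;
* `heterogeneous` — majority guide below 90% of the matched high-quality
  reads (the majority fraction is computed over matched reads; the 3-read
  support floor is applied to all high-quality reads);
* `defective` — majority alignment's modal edit distance is nonzero
  (modal, not maximal, so one stray sequencing error cannot flip a clean
  barcode; ties go to the smaller distance);
* `assigned` / `empty` — otherwise.

## Fitness inference

Barcodes with fewer than 64 pre-induction reads in every culture are
removed; below that depth, sampling noise dominates the trajectory.
For each remaining barcode the counts across samples are modeled as
negative binomial with log link:

$$\log \mu_{j} = \log s_j + \beta_0 + \beta_g \, g_j + \beta_c \, [\text{culture}_j]$$

where $g_j$ is the number of population doublings since induction (0,
3.75, 7.5, 11.25 under the default schedule) and $s_j$ a per-sample size
factor. The fitness score is $\beta_g / \ln 2$: the log2 change in
relative abundance per doubling. A neutral lineage scores 0; a persistent,
non-replicating plasmid halves in relative abundance each doubling and
scores −1, which is the biological floor — the package's estimates respect
it on simulations.

Numerical choices:

* **Size factors** are median-of-ratios (median over barcodes of the count
  divided by the barcode's geometric-mean reference; zeros excluded),
  rescaled to geometric mean 1 — and they are computed *within each
  replicate culture*. Replicate cultures are bottlenecked independently at
  transformation, so barcode frequencies carry culture-specific offsets;
  a matrix-wide median then slides across that offset distribution as
  active lineages decay, biasing every slope, whereas the within-culture
  median stays pinned to the same neutral lineages. Constant per-culture
  scale differences are absorbed by the culture coefficient.
* **Dispersion** is a per-barcode method-of-moments estimate from an
  initial Poisson fit, $\hat\alpha = \sum((y-\mu)^2 - \mu) / \sum \mu^2$,
  floored at $10^{-8}$ (clean multinomial data reduce to the Poisson
  limit). Slopes at the simulated depths are insensitive to moderate
  dispersion misspecification, which is why a simple, stated estimator is
  preferred over shrinkage machinery. Wald standard errors are taken at
  dispersion 1 and transformed to the log2 scale.
* Single-culture inputs drop the culture term; technical duplicates at a
  timepoint enter as additional samples with identical `gens`. Zeros at
  late timepoints are left to the NB likelihood — no pseudocounts, since
  zeros are informative about steep decline.

Guide-level fitness is the inverse-variance weighted mean of the converged
barcode slopes, $\hat f = \sum w_i \hat\beta_i / \sum w_i$ with
$w_i = 1/\mathrm{se}_i^2$ and $\mathrm{se} = (\sum w_i)^{-1/2}$. The
activity threshold is the 5th percentile (interpolated on the sorted
values) of the scaffold-only control fitness scores; at least 20 controls
are required.

## Guide-activity model

The position effect is modeled empirically: a local regression of guide
fitness on TSS offset over [−220, +20] — locally weighted *linear* fits
with the tricube kernel, span α = 0.25, no robustness iterations, exact
(non-interpolated) surface. Predictions outside the fitted range clamp to
the boundary instead of extrapolating a local line. A minimum of span×n ≥ 4
points is enforced.

The logistic model is
`active ~ OffsetPred + ODM + nt01 + … + nt20`: the loess prediction at the
guide's offset, the lowest nucleosome occupancy in the 33-nt window
(target ± 5 nt; missing occupancy counts 1.0 = occupied, mirroring the
0.0 fill for accessibility — pessimism in both directions), and the guide
sequence dummy-coded with base A as reference (3 contrasts × 20 positions;
the reference choice is arbitrary but fixed). The occupancy value enters
directly — low means accessible — and the coefficient absorbs the
direction. Perfect separation, which small synthetic sets can produce,
triggers a weak L2 penalty (λ = 10⁻⁴) with a warning; standard errors are
not reported in that case.

Cross-validation refits *both* the loess curve and the logistic model on
the training folds of each of k = 10 random folds (partitioning guides,
with the seed recorded in the model metadata), and pools held-out logits
into a single rank-based (Mann–Whitney) AUC; a fold containing one class
is merged into its neighbor with a warning. A strand-specific variant
(two loess curves) exists behind a flag but is not the default — in the
underlying screen data strand-specific position effects did not improve
cross-validated performance. An ATAC-based accessibility feature can
likewise be swapped in for comparison.

Calibration bins held-out logits in unit bins *centered* on integers, so
the logit-0 bin straddles zero and a well-calibrated model shows ≈50%
active guides there (the appropriate bin width is not externally fixed;
centered unit bins are this package's choice). Calibration computed on
training scores is flagged as in-sample.

## What the simulators emulate — and what they do not

`simulateGenome` packs genes on one chromosome with a configurable
fraction arranged as divergent pairs whose TSSs face each other across
200–600 bp, per-gene isoform tables whose modal start is the true TSS,
and chromatin tracks with a nucleosome-free region over [−150, 0] upstream
of each TSS (accessibility ≈ 0.9, occupancy ≈ 0.1, baseline reversed),
with independent jitter for the two ATAC replicates. Sequence content is
i.i.d. with GC 0.38; there is no codon structure, no repeats, and no
transcription-dependent chromatin beyond the planted NFRs. Passing tests
on this genome therefore validate the *geometry* of design (windows,
zones, ambiguity at divergent promoters, accessibility averaging), not
performance on real genomic sequence composition.

`simulateGrowthCounts` draws barcode counts from exponential lineage
dynamics $f_i(g) \propto f_i(0)\, 2^{f_i g}$, renormalized each timepoint
and sampled multinomially at the stated depth (an `"expected"` mode gives
rounded noise-free counts for calibration checks). Initial abundances are
log-normal (σ = 1) with a per-culture log-normal jitter (σ = 0.2)
emulating independent transformation bottlenecks. The default guide
fitness distribution is bimodal — 35% active guides uniform on
[−1, −0.2], the remainder neutral — matching the empirical situation in
which most guides are ineffective; this neutral majority is also what
anchors median-of-ratios normalization to the absolute scale. About 1% of
barcodes are scaffold-only (fitness 0) and serve as negative controls.
No PCR-duplicate, fragment-length or overdispersion modeling is included
by default; technical noise is purely multinomial.

`simulateAssignmentReads` emits paired reads with the real adapter
structure, ~10% of barcodes carrying a synthesis error in their guide,
~5% chimeric barcodes splitting reads between two guides, ~1% empty
constructs, per-base sequencing errors (Q20 at 80% of planted error
positions, confidently miscalled Q37 otherwise) and random low-quality
bases to exercise the Q30 filter. Planted synthesis errors are
substitutions and 1-nt insertions: a 1-nt deletion leaves a 19-nt residual
that the ≥20-nt trim rule removes, so deletion-bearing constructs are lost
from the data rather than observed as defective — the trim behavior itself
is unit-tested separately.

## Problem sizes and reproducibility

The shipped tests run the recovery analyses at 40–60 guides × ~4 barcodes
and depths of 10⁴–10⁶ reads per sample, the design checks on a 50-gene
genome (~90 kb), and the activity-model recovery at 2000 guides with
10-fold cross-validation — sizes at which every check completes in
seconds while the statistical assertions (guide-level MAE < 0.05 at depth
10⁶, CV AUC within ±0.05 of the generating law's optimum, logit-0 active
fraction 0.5 ± 0.1, planted fate rates within 3 binomial SDs) are
well-powered. All generators are deterministic given their seed, and every
shell run writes a JSON run-record sufficient to reproduce it.

## Known limitations

* Off-target assessment is perfect-match uniqueness only; no partial-match
  or mismatch-tolerant off-target scoring.
* The NB dispersion estimator is deliberately simple; screens with strong
  technical overdispersion would benefit from shrinkage across barcodes,
  which is out of scope here (the simulator's Dirichlet-multinomial hooks
  can exercise robustness).
* The activity model's sequence features are position-wise base
  identities; no dinucleotides, no position-weight interactions.
* Real-genome performance figures (AUCs on deposited screen data) require
  the corresponding external datasets and are not reproduced by the
  synthetic pipeline, which verifies procedure and calibration instead.
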