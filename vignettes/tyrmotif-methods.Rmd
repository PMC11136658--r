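---
title: "Models and methods behind tyrmotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tyrmotif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tyrmotif)
```

# The measurement model

Positional scanning peptide arrays (PSPA) probe a kinase with 220 peptide
mixtures: one fixed residue (20 natural amino acids plus phosphothreonine
"t" and phosphotyrosine "y") at one of 10 positions flanking a central
Tyr phosphoacceptor (-5..-1, +1..+5), with all other positions randomized
over a background mixture. The background lacks Tyr (to keep a single
phosphoacceptor) and Cys (oxidation artefacts), giving an 18-residue
background; the library used for dual-specificity Ser/Thr kinases with
convergent Tyr activity additionally lacks Ser and Thr (16 residues).
The spot intensity for mixture (r, p) is proportional to how well the
kinase phosphorylates substrates carrying residue r at position p.

# From raw intensities to a PSSM

`normalize_pspa()` applies four steps, in this order:

1. **Column normalization.** Each position's intensities are divided by
   the sum over the randomized-background residues, so those residues sum
   to 1 per column and the mean background residue has value
   1/`background_size`.
2. **Cys rescale.** Cys is absent from the randomized background, so its
   raw intensity scale is not comparable; the whole row is multiplied by
   one scalar chosen so that its median across the 10 positions equals
   1/`background_size` (neutral).
3. **Tyr := Phe.** A fixed Tyr spot reports phosphorylation of the fixed
   residue itself rather than a flanking preference, so the Tyr row is
   replaced by the structurally closest residue, Phe.
4. **Dual-specificity S/T median.** For dual-specificity kinases the
   fixed Ser/Thr spots are confounded by direct Ser/Thr phosphorylation;
   both rows are replaced by the per-position median over the 20 natural
   residues.

The order matters and is fixed as above: steps 2-4 each overwrite rows
rather than renormalize, so the background-sum property of step 1 is
preserved exactly in the output (the rows the later steps touch are never
part of the randomized background: Cys and Tyr are excluded from both
libraries, Ser/Thr from the 16-residue library that all dual-specificity
kinases use). The per-position median used by step 4 (and by logo
heights) is taken over the 20 natural residues only, after steps 1-3,
because the phospho rows live on a different intensity scale. The matrix
is deliberately **not** renormalized after steps 2-4.

Degenerate inputs: a column whose background residues are all zero is an
error (no normalization exists). Exact zero intensities elsewhere would
make downstream log2 scores undefined, so they are floored at the
smallest positive value of their column — the same zero-replacement rule
used for SH2 binding matrices; the lognormal synthetic generator never
produces them.

# Substrate scoring

The **selectivity** of residue r at position p is the PSSM value times
the background size, so the mean randomized residue has selectivity 1 and
values above 1 mark preference over random. `score_site()` reads the
flanking residues of an 11-mer (positions -5..+5, central "Y"/"y"),
rounds each selectivity to the nearest 1/10,000th, and multiplies them
into a raw score. Rounding is half-away-from-zero (spreadsheet style,
matching the provenance of distributed specificity tables); it is applied
before multiplication so scores computed from a published rounded matrix
and from the full-precision matrix agree. `log2_score()` instead sums
unrounded log2 selectivities, so a substrate preferred over random scores
positive.

Character conventions: lowercase "t"/"y" use the phospho rows; lowercase
"s" uses the pThr row by default (kinases that select pThr select pSer
similarly; set `phospho_ser_as_pthr = FALSE` to score it as plain Ser);
uppercase Tyr in a flank uses the Tyr row (identical to Phe by
construction); "_" padding at protein termini contributes a neutral
factor 1, equivalent to skipping the position.

**Percentiles.** A kinase's reference distribution is the sorted vector
of raw scores of a reference Tyr phosphoproteome (`build_reference()`).
The percentile of a new site is `100 * #(reference <= score) / N`. The
"at or below" convention is a declared choice — it makes the maximum
attainable percentile exactly 100 and is monotone; published analyses do
not state their tie handling, and any site's percentile under the
alternative strict convention differs by at most the tie mass.

**Ranking and categories.** For one substrate, kinases are ordered by
percentile, ties broken by raw score and then kinase id, so output is
reproducible. The promiscuity index of a site is the number of kinases
scoring it at or above their 90th percentile; sites with index >= 6 are
"broad", 1-5 "exclusive", 0 "suboptimal".

# Kinase enrichment from differential phosphoproteomics

Sites with |log2 fold change| >= 1 (inclusive, configurable) are
up/downregulated; the rest are the unchanged background. Multiply
phosphorylated flanks can be dropped with `strict_single_phospho`. For
every site the top-8 ranked kinases are its *biochemically favoured*
kinases; the deterministic tie-break makes the favoured set exactly size
8. For each kinase and direction a 2x2 table of favoured-vs-not against
regulated-vs-unchanged is tested with a one-sided exact test for
over-representation of favoured sites among the regulated set
(hypergeometric tail; `stats::fisher.test` agrees and is cross-checked in
the test suite). Kinases significant (p <= 0.05) in both directions are
flagged and excluded; each remaining kinase is reported in its more
significant direction.

The **frequency factor** is the favoured fraction among regulated sites
over the favoured fraction among unchanged sites. With a zero cell, the
Haldane correction enters as 0.5 added to the favoured count and to its
margin, i.e. each fraction becomes (a + 0.5)/(n + 0.5); the exact test
always runs on the uncorrected integer table, since an exact test on
half-integer counts is undefined. No multiple-testing correction is
applied across kinases in this module; the volcano table reports signed
log2 frequency factor (negative for downregulation) against -log10 p.

# SH2-domain motif overlap

SH2 binding arrays randomize 19 residues (no Cys) and read out mostly
C-terminal to the central pTyr. `normalize_sh2()` replaces zeros by the
column minimum, normalizes columns over the 19 residues, and adds a
neutral Cys row at 1/19. Scoring reuses the kinase product kernel with
background 19, restricted to the positions the matrix covers (absent
positions are neutral). Flank phospho-characters are scored as their
unmodified residues, as the arrays carry no phospho rows beyond the
central pTyr.

`sh2_enrichment()` scores the phosphoproteome with one kinase PSSM,
splits it into favoured (top 20%), neutral (middle 60%) and disfavoured
(bottom 20%) slices (ties broken by site id; identical scores across the
board are an error), marks the top-8 SH2 binders per site, and tests both
slices against the neutral background with one-sided exact tests. No
reference distribution is published for SH2 scores, so per-site ranking
uses each domain's percentile within the scored phosphoproteome itself —
a declared choice, self-consistent and deterministic.
Benjamini-Hochberg adjustment runs across SH2 domains within each
direction; each domain is reported in its more significant adjusted
direction. Domains measured only by proxy can be aliased to another
domain's matrix via `sh2_alias` (e.g. `c(PIK3R3_C = "PIK3R2_C")`) rather
than hard-coding.

# Motif clustering

Each kinase's feature vector concatenates its normalized values for the
19 unmodified amino acids excluding Tyr (redundant with Phe by
construction) plus the pThr and pTyr rows, over the 10 positions (210
features). Clustering is Ward's minimum-variance linkage on Euclidean
distances, `hclust(method = "ward.D2")` — the Ward formulation defined
on raw (unsquared) distances, matching the common scientific-Python
implementation. Feature vectors are *not* standardized: columns are
already on a common normalized scale, and standardizing would inflate
low-information positions. Kinases are sorted by id before clustering so
input order cannot affect tie resolution.

Newick export uses the ultrametric half-height convention (leaves at
depth 0, each merge at half its linkage height), so two leaves merging at
height h serialize as `(A:h/2,B:h/2);`. The number of flat groups at a
cut is a presentation parameter (`cut_motif_clusters()`), not a model
quantity.

# Synthetic data generators

The generators exist so every pipeline stage can be validated without
external data, with sampling models simple enough for closed-form
expectations:

* `gen_raw_pspa()`: intensity(r, p) = baseline x multiplier(r, p) x
  exp(N(0, sd^2)). Defaults: baseline 1000 (typical densitometry counts),
  lognormal sd 0.1 (multiplicative noise keeps intensities positive, 10%
  is a realistic spot-level variability), multipliers 1 except planted
  preferences. With no noise and no preferences, normalization provably
  returns the uniform PSSM; a planted m-fold preference appears as an
  m-fold normalized ratio in expectation.
* `gen_kinome_specs()`: random kinome emulation; each kinase receives
  2-4 planted preferences in the -2..+3 core (where real Tyr kinases
  concentrate selectivity) with folds 3-8, and half the kinases receive a
  phosphopriming preference at -1/+1/+2.
* `gen_phosphoproteome()`: flanks drawn per position proportionally to a
  kinase's planted multipliers (mixture weights) or uniformly; Cys never
  appears at flanking positions by default, mirroring the randomized
  library's composition; 5% of sites carry terminal padding and 5% a
  lowercase phospho-character so all legal symbols are exercised.
* `gen_regulated_dataset()`: fold changes N(0, 0.5) for background;
  sites favoured by the planted kinase receive N(2, 0.5) with probability
  `effect` (0 gives an exact null).

All generators restore the global RNG state and are byte-identical per
seed.

**What the synthetic data does not emulate.** Real phosphoproteomes have
strongly correlated percentile scores across kinases for a given site
(compositional biases make sites generally good or generally poor
substrates), while the generator's per-kinase scores are nearly
independent. Consequently the broad/exclusive/suboptimal proportions of
a synthetic proteome concentrate around the binomial expectation of the
90th-percentile count and do not reproduce the roughly equal three-way
split seen in curated human data; passing tests demonstrate the
correctness of the counting and classification machinery, not the
empirical class balance. The generators also ignore MS detectability,
missing values and peptide-to-site rollup, which the enrichment module
assumes were handled upstream.

# Validation scales and numerical choices

The test suite validates normalization on 120 seeded matrices, scoring
against an independent brute-force product on 120 random fixtures
(1e-9 relative), and the exact test against explicit hypergeometric
enumeration: every margin with N <= 40 at every feasible count, plus
every margin with N <= 200 at a deterministic representative count.
Calibration uses 210 null replicates (observed fixed-direction
significance ~3% at alpha 5%, conservative because the exact test is
discrete) and 110 planted-effect replicates (planted kinase recovered as
the top upregulated hit in >= 95%). The full annotation pipeline runs at
the scale of the curated human data — 78 kinase motifs, a 5,431-site
reference, a 7,315-site proteome — on synthetic input. `scripts/acceptance.R`
recomputes all of these quantities from scratch for any seed.

Other numerical conventions collected in one place: selectivity rounding
is half-away-from-zero at 4 decimals; percentile is count-at-or-below;
ranking ties break by raw score then id; tertile ties break by site id;
Haldane correction affects only frequency factors; matrix round-trips
are value-exact to 6 significant digits.

# Known limitations

Scores assume positional independence of the flanking residues; the
arrays cannot see interpositional coupling. Motif compatibility is
necessary but not sufficient for phosphorylation in cells — localization,
docking and induced proximity are outside the model, which is why
aggregate (enrichment) readouts are more reliable than single top-ranked
kinase calls. Kinases profiled with the 16-residue library carry their
background size through all scaling, but their Ser/Thr substrate scores
rest on the median imputation rather than measurement.
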