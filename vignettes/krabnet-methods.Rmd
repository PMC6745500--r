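---
title: "Methods: scoring KZFP interactomes and the companion evolutionary analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring KZFP interactomes and the companion evolutionary analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(krabnet)
```

krabnet implements the quantitative core of a KRAB zinc-finger protein
(KZFP) interactome study: probabilistic scoring of affinity-purification
mass-spectrometry (AP-MS) spectral counts against negative controls, the
filter cascade that turns scores into a high-confidence interactome, the
KAP1 recruitment statistic that stratifies baits, and the companion
analyses of genomic binding-site overlap, KRAB A-box evolution and
population-genetic constraint. This vignette records the models, the
defaults and why they are what they are, and what the synthetic data can
and cannot establish.

## The spectral-count scoring model

The input is a prey x run matrix of unique, proteotypic spectral counts.
Each MS batch contains the bait purifications (two biological x two
technical replicates per bait by default) plus negative-control runs
(GFP-expressing and untransduced cells). Counts are kept per technical
replicate; all averaging is explicit and happens downstream.

**Bait expression QC.** A biological replicate is used only if the bait
protein itself exceeded 10 spectral counts (strictly) in each of its
technical replicates; a bait is dropped only when all of its biological
replicates fail. The threshold is a count, unitless, and deliberately
strict at the boundary (a count of exactly 10 fails).

**Fold change.** For each (bait, prey) pair the average fold change is the
mean count over the bait's QC-passing runs divided by the mean over the
batch's control runs. A control mean below 0.5 is replaced by 0.5
(denominator only), so preys never seen in controls get a finite, large
enrichment rather than an infinite one; 0.5 is half the smallest nonzero
count, the usual pseudocount convention for count ratios.

**Mixture model.** Significance comes from a two-component Poisson mixture
fitted per batch by EM: a prey's counts in a bait's runs are background,
`Poisson(lambda0)` with a prey-specific rate shared with the controls, or
a true interaction, `Poisson(r * lambda0)` with a single global enrichment
factor `r > 1` and prior weight `pi`. All parameters — `pi`, `r`, and
every per-prey `lambda0` — are estimated jointly from the controls plus
all bait runs of the batch. This joint estimation is not a refinement but
a necessity: with a dozen control runs, plugging in the control mean as
`lambda0` ignores its sampling error, and preys whose controls happen to
fluctuate low acquire inflated posteriors in every bait simultaneously.
In our calibration experiments the plug-in variant yielded a ~4% realized
false discovery rate at a nominal 1% BFDR; the joint fit brings it to
~0.6%. Control means are the initialization of the background rates, with
a floor of 0.1 against degenerate zero-rate likelihoods.

Numerical choices: `pi` starts at 0.05 and is kept inside
`[1e-6, 1 - 1e-6]`; `r` starts at 5 and is kept above 1 (its M-step is a
one-dimensional maximization, solved numerically on the log scale); EM
stops when the log-likelihood (bait pairs plus controls) moves by less
than 1e-8 or after 1000 iterations; the log-likelihood is non-decreasing
by construction (projected coordinate M-steps) and the fit is
deterministic given the data. A bait's own protein is excluded from its
prey list — self-association is not an interaction.

**BFDR.** Pairs are ranked by decreasing posterior across the whole
experiment (all batches pooled, mirroring a model estimated from all
baits and all controls); the Bayesian FDR of the accept-set down to rank
k is the mean of (1 - posterior) over the set, and each pair carries the
BFDR of the smallest accept-set containing it. Along the ranking this is
automatically non-decreasing.

**Acceptance thresholds.** An interaction is called when BFDR < 0.01 and
average fold change > 2, both strict. A third, orthogonal filter removes
edges where a nuclear-only bait pulled down a prey annotated as
exclusively cytoplasmic; preys without annotation are kept, and the
filter commutes with the significance filter because both are per-edge
predicates.

**KAP1FC.** KAP1 recruitment strength is the log2 fold change of the KAP1
prey in a bait's purification, pseudocounted like any other fold change.
Baits at or above 3 are "strong" KAP1 binders — the boundary itself is
strong, because the convention is that interactomes *below* 3 are not
considered KAP1-associated.

## The synthetic AP-MS generator

`gen_apms()` emulates the study design: prey-specific background rates
drawn from gamma(shape 2, scale 1) and shared between controls and bait
runs; true interactions enriched by a fixed factor of 8; bait
self-counts at Poisson mean 60 (comfortably above QC); 50 baits, 400
generic preys, 12 control runs, 2x2 replicates per bait, 5% true-edge
probability. Any protein of the universe, including the other baits, can
be a true interactor — KZFPs genuinely co-purify other KZFPs — and the
full truth (edge list, rates, configuration) is serialized with every
draw, so confusion matrices downstream are exact. An overdispersion knob
(gamma-mixed Poisson) exists to stress the scorer outside its model
assumptions; it is off by default because the default conditions *are*
the conditions under which the calibration claims are made.

What the generator does not emulate: peptide-level identification error
(the pipeline starts at validated count matrices), run-order or
carry-over effects, correlated contaminants, and abundance-dependent
detectability. A calibrated FDR on these simulations therefore
demonstrates internal consistency of the model and its thresholds, not
performance on any particular instrument's output.

Localization annotations (`gen_localization()`) plant a controlled number
of nuclear-bait preys as exclusively cytoplasmic —
`round(rate x number of eligible preys)` distinct preys — so the filter's
recall is measurable exactly; non-conflict preys are never annotated
exclusively cytoplasmic, so its false-removal rate is zero by
construction.

## Interval statistics

Coordinates are BED-style 0-based half-open everywhere inside the
package; 1-based sources (VCF positions, TSS tables) are converted on
ingest, and strand is stored but ignored by all overlap computations.
Overlap fractions are interval-count based (an interval is "overlapped"
if it shares at least one base pair with the other set), matching the
"share of binding sites" reading; two peak sets are reciprocally
overlapping when each has at least 10% of its intervals overlapped, the
boundary included. Enrichment between two interval sets uses a Fisher
exact test on a bedtools-style 2x2 table whose "neither" cell is
estimated as `genome_size / mean interval length` minus the other three
cells — an explicit approximation of an unpublished heuristic, kept
because it reproduces the tool's behavior and is documented as such. TSS
windows span the start site plus/minus 2500 bases (5001 bp, half-open);
ChIP peaks are pre-filtered at a peak-caller score strictly above 80.

## KRAB A-box evolution

Trees are built by neighbor joining on uncorrected p-distances with
pairwise deletion of gapped columns. The NJ implementation follows the
standard Q-criterion with two determinism guarantees: ties are broken by
the lowest index pair, and negative branch-length estimates are clamped
to zero with the deficit moved to the sibling so the joined pair's total
stays equal to its distance. On additive matrices it reproduces path
lengths exactly (and agrees with an independent reference
implementation, which the tests use as a cross-check only).

The standard/variant KRAB split is, in the source analysis, a visual
cluster call on the tree. Here it is a reproducible rule: a domain is
variant (vK) when its p-distance to the consensus of designated standard
references exceeds `tau = 0.3`. The default sits between the synthetic
standard-domain divergence (0.08 expected distance to consensus) and the
variant cluster (0.45), and recovers well-separated planted clusters
exactly; it is a calibration choice, not a value inherited from any
publication, and is exposed as a parameter.

Consensus logos report per-column residue frequencies (gaps excluded)
and information content `log2(20) - H` in bits against a uniform 1/20
background (the background composition not being specified upstream,
uniform is the neutral choice); columns that are more than half gaps are
dropped.

**dN/dS.** The Nei-Gojobori (1986) estimator is implemented in full:
expected synonymous/nonsynonymous sites per codon by enumerating the
nine single-nucleotide mutants against the standard code, with
stop-producing mutants excluded from the denominator (so sites always
sum to 3 per codon); observed differences averaged over all minimal
substitution pathways, excluding pathways through stop codons (with a
fall-back to all pathways if every route is blocked); Jukes-Cantor
correction `d = -(3/4) ln(1 - 4p/3)`, which is undefined at p >= 3/4 and
raises an error naming the offending proportion — very short alignments
saturate easily, and silently returning a number would be worse. A ratio
with dS = 0 is undefined (`NA`), never infinity; averages downstream use
defined values only. When a human domain has several equally old
orthologs, the ratio is the arithmetic mean over the most distant ones.

The codon-pair simulator accepts nonsynonymous proposals with
probability omega and synonymous ones always, rejecting stop codons.
One caveat it exposes: omega = 0 does not mathematically force the NG86
nonsynonymous difference count to zero, because two synonymous hits in
one codon can create a pair whose pathway average traverses a
nonsynonymous intermediate (all-leucine paths such as CTT -> CTA -> TTA
have a phenylalanine-crossing alternative). At short branch lengths this
is rare; the tests pin it at a fixed seed and the property should be
read as "no nonsynonymous substitutions", not "Nd identically zero for
any draw".

## Loss-of-function constraint

The cascade follows a fixed order — variants within 1 kb of the
canonical transcript, PASS-only, multiallelic splitting with
minimal-representation normalization (shared suffix trimmed before the
shared prefix), coverage filtering (transcripts kept only above 20x
average, then exons below 20x removed and the coding length recomputed),
then LoF extraction (high-confidence calls only, and no calls in the
last 5% of the coding sequence, measured along strand-aware CDS
coordinates, not genomic span) — and each stage reports its attrition.
Per-gene LoF counts are divided by coding length and standardized into a
Z-score using the population (n) standard deviation: the analyzed gene
set is the whole population of interest, not a sample from a larger one.
High Z means more LoF variation per coding base, i.e. *less* constraint;
the sign convention is stated here because prose descriptions of such
scores are often ambiguous. A zero-variance rate vector yields all-zero
Z-scores with a warning rather than NaNs.

## Problem sizes and what the tests show

The test suite and the acceptance script run entirely on generated data:
FDR calibration on twenty replicates of the default 50 x 450-protein
design (about 22,000 scored pairs each, roughly half a minute
in total); neutral-evolution recovery on 150 codon pairs of 200 codons at
0.3 proposals per site; the KAP1FC boundary on a 0.001-step log2 grid;
enumeration oracles (hypergeometric tables to n = 30, rank-test
permutations to group size 7, NJ additivity to 8 taxa) at sizes where
brute force is exact. These sizes were chosen so every stochastic claim
has a comfortable Monte-Carlo margin while the whole suite stays fast
enough to run habitually.

Known limitations, beyond those noted above: the mixture assumes a
single global enrichment factor per batch, so strongly heterogeneous
enrichments widen the posterior's middle ground (the BFDR remains an
average and stays interpretable); the localization filter trusts its
annotations and will happily remove a genuinely nuclear prey that is
mis-annotated as exclusively cytoplasmic; and the bedtools-style Fisher
table inherits the coarseness of its "number of genome slots" estimate —
its p-values are for ranking and thresholding, not for publication-grade
hypothesis tests on their own.
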