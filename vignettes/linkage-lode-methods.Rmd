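---
title: "Methods: integrated linkage and LODE mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrated linkage and LODE mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`lodemap` implements the analysis chain used to build gene-based SNP
linkage maps in aquaculture breeding programs: genotype quality control
with explicit exclusion ledgers, phase-known two-point linkage mapping in
multi-family full-sib designs with grandparent tracing, sex- and
family-specific recombination statistics, and the placement of markers
that linkage cannot order by population linkage disequilibrium (LODE).
This vignette describes the models, the estimators, the tunable
parameters, and the choices made where the design was genuinely open.

## The study design and the informative-meiosis matrix

The working design is a set of independent full-sib families. Each family
has four genotyped grandparents, two F1 parents, and a set of full-sib
progeny. For a parent heterozygous at a marker, a progeny meiosis is
*informative* when two deductions succeed purely at that locus:

* **phase** — which grandparent contributed the parent's alternate
  allele, deducible unless the grandparental genotype configuration
  permits both assignments (for example both grandparents heterozygous);
* **transmission** — which allele the parent passed to the progeny,
  deducible when the progeny is homozygous or the other parent is
  homozygous.

Everything downstream operates on the resulting matrix `H` (meioses x
markers) whose entries are the grandparental origin of the transmitted
haplotype (1 = grandpaternal, 2 = grandmaternal) or `NA`. This per-locus
deduction is deliberately conservative: no multipoint or hidden-phase
inference is attempted (a stated non-goal), so roughly a quarter of
meioses are informative at a typical marker with allele frequencies in
the 0.25–0.5 range. All statistical precision statements below follow
from that fraction.

## Two-point analysis and the Kosambi scale

For a marker pair with `N` co-informative meioses and `R` recombinants,
the recombination fraction MLE is `theta = min(R/N, 0.5)` and the LOD is

```
Z = R*log10(theta) + (N - R)*log10(1 - theta) + N*log10(2)
```

Map distances use the Kosambi function `d = 25 ln((1+2θ)/(1−2θ))` cM and
its inverse `θ = 0.5 tanh(2d/100)`; fractions at or above 0.5 map to an
infinite-distance flag.

## Grouping, ordering, merging

**Grouping** is single-linkage transitive closure over edges with
`LOD ≥ 10` and Kosambi distance `≤ 30` cM. Components of fewer than three
markers join the orphan pool.

**Ordering** of each group is hierarchical: the highest-LOD pair seeds the
order; remaining markers are inserted at their best position when the
placement margin (best minus second-best insertion position, in raw LOD
units) reaches the current tier (3, then 2, then "best", which always
places). After each tier the order is refined to a fixed point by
exhaustive permutation of sliding six-marker windows ("flips 6"),
segment-reversal (2-opt) moves, relocation of two- and three-marker
segments (or-opt), and remove-and-reinsert of single markers ("polish"),
accepting only improvements.

The ordering *objective* needed care. The natural complete-data criterion
— the sum over adjacent pairs of `R log10 θ + (N−R) log10(1−θ)` — is
ill-conditioned when the number of co-informative meioses varies wildly
across pairs (as it does here, because informativeness is a property of
parents, not markers): a pair with no data contributes the maximal value
zero, so data-free adjacencies are *rewarded*. Two modifications fix
this, and both were validated by checking that the true simulated order
scores above fitted orders:

* each pair contributes its **information-balanced LOD**,
  `LOD / (N + 10)`, so support is per-meiosis with a small-sample
  shrinkage constant of 10 meioses;
* the objective sums these over adjacent pairs **and second-neighbour
  (skip-one) pairs** with equal weight. Because most meioses are
  uninformative at any given marker, a large share of the likelihood
  information about local order sits in pairs that skip one position;
  an adjacent-only criterion cannot see the local scrambles this
  information resolves.

Tier margins stay in raw LOD units, preserving their meaning as
likelihood support for a placement. The reported per-group
log10-likelihood remains the plain adjacent-pair complete-data sum.

**Merging**: after ordering, the five distal markers of every group end
are compared by two-point against every other group's ends; candidate
merges are reported, and the map-building pipeline applies them greedily
(strongest first, re-ordering the union) at `LOD ≥ 7`. The merge
threshold is a free parameter of the workflow; 7 was chosen between the
grouping threshold (10) and the orphan-insertion threshold (3) because a
genuine junction between fragments of one chromosome shows distal
support around LOD 6–13 at the meiosis counts of the default design,
while chance support between unlinked groups concentrates well below 5.

**Orphan insertion**: each orphan is tested by two-point against all
mapped markers and inserted at tier "best" when its strongest LOD reaches
3 on exactly one group; equal support on two groups leaves it an orphan
(ambiguity rule), as does an exact positional tie at the stricter tiers.
Exact ties at the final tier place the marker at the lower coordinate and
record it as co-localised.

## Interval lengths and map distances

Taking each adjacent pair's own `θ` estimate produces a biased map: the
optimizer prefers adjacencies whose estimates are small, so the selected
adjacent distances are systematically short. Interval lengths are
therefore estimated by weighted least squares over *spanning pairs*: every
pair within twelve order positions contributes its two-point distance,
modelled as the sum of the intervals it spans, weighted by `N`. Three
numerical points:

* the regression is done in **Haldane scale**, which is exactly additive
  across intervals under the generator's independent-per-interval
  recombination model (Kosambi distances are not additive under that
  model, and using them shortens long spans by up to ~15%); fitted
  intervals are converted back to Kosambi cM individually, where the two
  scales differ by under 3%;
* the Haldane transform is convex, so each observation carries a
  second-order Taylor **bias correction** `−200 θ(1−θ)/(N(1−2θ)²)`;
* **negative intervals** (local ordering noise) are pinned to zero by
  backward-elimination non-negative least squares, and the non-negative
  solution is rescaled (factor clamped to [0.5, 3]) so its total matches
  the signed-solution total, which telescopes to the end-to-end span and
  is robust to local scrambles.

Positions are cumulative sums of the estimated intervals, so map-length
additivity holds by construction. Pairs with `θ ≥ 0.4` or fewer than five
co-informative meioses are excluded from the regression; an interval with
no spanning data at all falls back on its direct adjacent estimate.

At the default simulated design (5 linkage groups x 40 markers over
100 cM each; 20 families x 16 progeny; about 26% informative meioses) the
pooled recombination-fraction information bounds any total-length
estimate to a relative standard error of roughly 6–7%, so individual
replicates can miss the truth by 10% or more without indicating a defect;
the estimator above is centred within a few percent of the truth.

## Sex-specific maps and recombination statistics

Female and male maps share the sex-average order exactly ("locked
order"); per-interval recombination fractions are recomputed from
female- and male-parent meioses separately with the same spanning
estimator, and an interval with zero direct co-informative meioses in a
sex is reported as missing, never imputed. Totals are over defined
intervals only.

`fm_ratios()` reports `R = X_f / X_m` per interval, per linkage group,
and for the genome both as a ratio of totals and as the mean of per-group
ratios (the aggregation the field uses is ambiguous, so both are given).
For recovering a *genome-wide* sex difference, interval-based totals are
noisy and compressed by ordering noise; `sex_recombination_ratio()`
instead walks each meiosis along the map, treats every gap between
consecutive informative markers as a Bernoulli observation with success
probability `kosambi_inverse(scale * gap)`, and fits one multiplicative
map-scale factor per sex by maximum likelihood. Isolated single-marker
origin flips with both flanking gaps under 8 cM are masked first: a
genuine double crossover there has probability near the product of the
two gap recombination fractions, so such flips are overwhelmingly
genotyping or phasing artefacts, and because a single phase error flips
an entire parent's meioses at one marker they otherwise distort the
switch counts noticeably.

Heterogeneity tests follow the classical goodness-of-fit form
`X² = 2 ln(10) [Z_free − Z_pooled]`: between sexes with one degree of
freedom, and between families (the M-test) with degrees of freedom one
less than the number of contributing families; families with no
co-informative meioses are dropped from both terms. The two-group
reduction of the M-test equals the sex test identically, which the test
suite asserts numerically. Segregation distortion uses the
log-likelihood-ratio G-test against Mendelian class ratios keyed on the
cross type (het x hom → 1:1 over two classes; het x het → 1:2:1), each
informative parent tested separately, with Benjamini–Hochberg FDR
(`stats::p.adjust`) applied within each scan. p-values are asymptotic
chi-squared throughout; no exact permutation option is provided in this
version.

## Quality control

Per-marker summaries include call rate, minor-allele frequency,
heterozygote frequency, Mendelian agreement
(`1 − errors / loci tested`, an error being a progeny genotype impossible
given the available parent genotypes) and an exact conditional
Hardy–Weinberg test (enumeration of heterozygote counts), computed on
non-progeny samples only so that family structure is not mistaken for
disequilibrium. The array QC pipeline applies exclusions in the
accounting order used for array performance reports — sample call rate,
no-amplification, ambiguous clusters (an annotation flag: cluster shapes
cannot be recomputed from genotypes), monomorphism (no heterozygous
calls), Hardy–Weinberg deviation, gross and residual Mendelian failure,
low MAF, duplication (genotype concordance ≥ 0.995), low call rate,
two-cluster annotation — and returns a ledger whose exclusions and
remainder always sum to the starting count. Conversion, validation,
minimal-error and final rates are derived with the genotyped count as
denominator.

The in-silico discovery filter reproduces the candidate-SNP ledger:
read-level quality (MAF ≥ 0.25, depth ≥ 10, ≥ 2 minor-allele reads, SNP
and flanking quality ≥ 25), multi-allelic sites, sites requiring Infinium
type I probes (A/T, C/G), repeat-masked probes, assay-design score
< 0.7 (ADT scores are consumed as input, never computed — they are
proprietary), non-unique probes, and finally proximity: candidates on the
same contig closer than 50 bp are both removed by default (a
`keep_better` dialect retains the higher-quality member).

Unknown-parent reconstruction is per-locus maximum likelihood over the
three candidate genotypes given the known parent and the progeny genotype
counts under Mendelian transmission. It uses no linkage information and
is flagged as such in its output metadata; loci where no candidate
explains the progeny are flagged incompatible, never silently called.

## Linkage disequilibrium and LODE

Two-locus haplotype frequencies come from the standard EM for unphased
diploids: all gametes are counted directly except the double-heterozygote
ambiguity, resolved in expectation; convergence is `1e-10` on frequencies
or 1000 iterations, and the observed-data log-likelihood trace is
returned (it is non-decreasing, which the suite asserts). `D`, `|D'|` and
`r²` follow the standard definitions. The default LD sample is the
non-progeny generation, because full-sib progeny inflate LD; an `"all"`
mode is available since production datasets often pool related samples.

LODE places an orphan in two steps. *Assignment*: per linkage group,
count mapped partners with `r² ≥ 0.1`; assign to the group with the most
qualifying pairs if it has at least three and strictly beats every other
group on the pair count and then on maximum r²; any tie leaves the marker
unassigned (a conservative rule — the source workflow's "maximum LD
score" tie-break is informal, so it is operationalized as the secondary
sort key). *Positioning*: the r²-weighted mean cM of the qualifying
partners, with the maximum-r² partner's position also reported — the
weighted mean damps single-pair noise.

## What the generator emulates — and what it does not

`simulate_study()` produces studies with full truth: a true map (even or
random spacing; strictly increasing positions), founder chromosomes
copied segment-wise from a small ancestral haplotype panel with donor
switches at `mosaic_switch_rate` per cM (so r² decays with distance down
to a 1/haplotypes sampling floor), meioses that recombine each interval
independently with probability given by the inverse Kosambi function,
optional multiplicative female map expansion, viability selection at
distortion loci, genotyping error (a flip to a uniformly chosen different
state), missingness, orphan-marker holdout and sire masking.

Default parameters are fixed once: 4 ancestral haplotypes and a switch
rate of 0.05/cM put adjacent-pair founder r² in the ~0.15–0.25 regime
reported for dense gene-based arrays in aquaculture populations;
ancestral allele frequencies are drawn from 0.25–0.5 and realized exactly
in the panel, emulating the MAF ascertainment of array design (markers
monomorphic in founders would not have been put on an array); genotyping
error 0.001 and missingness 0.01 are typical post-QC array figures. The
strong-LD scenario used for LODE validation uses 2 ancestral haplotypes
and a switch rate of 0.1/cM, chosen from the mosaic model's analytics so
that r² stays above the 0.1 qualifying threshold out to roughly 11 cM.

The distortion model needs one clarification: viability selection
multiplies a progeny's survival by `1 − s` for each disfavoured
(alternate) allele inherited *from a heterozygous parent*. Selection on
segregating transmissions is what a segregation-ratio test can detect;
a literal carrier rule would also eliminate progeny whose disfavoured
alleles came from homozygous parents, which distorts nothing and, at
`s = 1`, would leave an Aa x aa family with no survivors at all. Under
the implemented rule that cross is thinned to 1 : (1−s) and a het x het
cross to 1 : 2(1−s) : (1−s)².

Deliberate simplifications, hence limits on what passing tests show
about real data: no crossover interference (independent intervals —
which is also why Haldane additivity holds internally), sex differences
as a single multiplicative factor, no array-intensity or pooled-larvae
simulation (a pooled family is represented as a masked parent plus
genotyped progeny), and no genotyping-batch structure. Real data also
violate the clean four-grandparent design through missing and misassigned
pedigree links, which here only enter as masked parents.

## Degenerate inputs and tie-breaks

Monomorphic loci are flagged and LD against them is undefined rather than
zero. Markers with no informative meioses are orphans, never errors. An
all-missing marker has call rate 0 and undefined statistics. Exact
positional ties defer to looser tiers and finally co-localise at the
lower coordinate. Reversing a built order leaves its likelihood unchanged;
orders are reported with the lexicographically smaller terminal marker
first. The expected-length formula `Ge = L(m+1)/(m−1)` requires `m ≥ 2`
(flagged at `m = 2`, excluded below).

## Problem sizes used in validation

The shipped validation runs use the default design (200 markers, 440
samples, 640 meioses) for map recovery, a 2 x 15-marker design at 20–40
families for unit-level checks, 10,000 meioses for the recombination
calibration of a single 21.18 cM interval, and 1000 simulated intervals
for the type-I error of the sex-heterogeneity test. These sizes put every
stochastic check's expected sampling error well inside its asserted
band while keeping the full suite around a minute on one core.
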