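---
title: "Models and methods for F2 QTL mapping of perenniality and fertility in rye"
author: "ryeqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for F2 QTL mapping of perenniality and fertility in rye}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ryeqtl)
```

# The scientific setting

Crossing cultivated annual rye (*Secale cereale*) with its perennial wild
relative (*S. strictum*) yields F2 populations in which two phenomena are
entangled: quantitative variation in perenniality (regrowth after seed set,
scored 0--9) and partial fertility (percentage of florets setting seed).
Two classical explanations for low fertility compete: reciprocal
translocations that lock three chromosome pairs into a ring multivalent at
meiosis, and gametophytic self-incompatibility.  `ryeqtl` implements the
full analysis chain for such a study -- marker quality control, linkage
mapping, REML mixed models for multi-location clonal trials, single-marker
and cofactor genome scans with simpleM multiple-testing control, explained
genetic (co)variance, an epistasis scan -- together with closed-form
incompatibility models and a meiosis simulator that generates data under
exactly these selection regimes.  Because real chip data of this kind is
typically proprietary, the simulator is a first-class, tested component: it
defines the study conditions against which every statistical claim of the
package is verified.

# Genetic models

## Gametophytic self-incompatibility

Two loci act on selfing.  The pollen-side locus *Z* (chromosome 2R) is read
on the haploid pollen grain: only pollen carrying the self-fertility allele
(coded A, from the inbred annual parent) can fertilize, so selfing an A/B
F1 gives F2 genotype ratio A:H:B = 1:1:0 at *Z* -- the B homozygote class
is empty and the marker track shows extreme segregation distortion.  The
stigma-side locus *S5* (chromosome 5R) is read on the diploid stigma with
the self-fertility allele dominant: plants with at least one A allele can
be selfed, BB plants cannot.  The F1 stigma is heterozygous, so *S5*
segregates 1:2:1 in the F2; in the pooled F3 from selfing the F2, however,
the BB class contributes nothing and enumeration over the F2 classes
(1 AA : 2 AH : 1 BB, equal family sizes, Mendelian gametes) gives genotype
ratio 3:2:1 and a parental allele ratio of 2:1 (`expectedF3RatioS5()`).

## Ring-multivalent gamete viability

For the translocation hypothesis the package uses the independent
disjunction model: each of the three homologous chromosome pairs of the
hexavalent contributes exactly one chromosome to a gamete, independently
and equiprobably, and a gamete is functional only when all three
contributed chromosomes derive from the same parental species.
Enumerating the $2^3$ gamete types gives $2/8 = 25\%$ functional gametes
(`multivalentViableFraction(3)`), and $2^{1-n}$ in general.  The historical
25% figure is quoted in the literature without its derivation; independent
disjunction is the unique simple segregation model consistent with both the
number and the standard pairing diagram, and it is stated here as a model
assumption rather than a reconstruction.

## Meiosis simulator

`simulateGamete()`/`simulateF2()` implement a no-interference (Haldane)
crossover process: per chromosome the crossover count is Poisson with mean
length/100 and positions are uniform.  The Kosambi function is used only on
the estimation side (below); the deliberate mismatch between the simulated
meiosis and the estimation map function is itself useful -- it documents how
robust map construction is to the choice, and the package asserts that a
120 cM chromosome simulated under Haldane is recovered within 15% by
Kosambi-based estimation at n = 178.

Selection is implemented by rejection sampling, matching the biological
narrative of inviable gametes being lost: pollen gametes carrying B at *Z*
are discarded and redrawn (eggs are never Z-filtered), and in multivalent
mode any gamete whose ring chromosomes mix parental origins is discarded.
Redraws are batched and vectorized, so rejection stays cheap even at the
~0.5% acceptance rates of multivalent mode.  In F3 selfing, a parent
homozygous B at *Z* could produce no compatible pollen at all; such plants
are treated as leaving no selfed offspring (the guard can only trigger in
regimes where the F2 itself was not Z-selected).

The default genome preset (`ryeGenome()`) is 7 chromosomes of 120 cM with
113 evenly spaced markers each (791 in total), mirroring the scale of a rye
10K-chip F2 study after redundancy collapse (~789 unique segregating
markers, ~178 genotypes).  The default trial design (`ryeTrialDesign()`)
assesses perenniality at two locations with two clonal replicates
(variance components 0.22 location, 0.08 replicate, 1.18
genotype-by-location, 1.39 residual, 3.72 genetic) and fertility at one
location (2.6 replicate, 94.9 residual, 313.7 genetic), the magnitudes
observed in the motivating field trial.  Trait values are clipped to their
bounded scales (0--9 and 0--100) after noise, and the clip count is kept in
the truth record.  Gaussian, homoscedastic noise across the whole 0--100
fertility scale is an explicit simplification: scoring error on bounded
percentage scales is plausibly smaller near the ends, and nothing in the
package depends on that detail.

What the simulator does *not* emulate: genotyping error, segregation of
real chip redundancy structure (redundant markers are planted by tests, not
by the generator), tetraploid material, and disease or vernalization
effects on the phenotypes.  Tests passing on simulated data therefore
validate the statistical machinery under the stated models, not the
behavior of any particular chip assay.

# Marker quality control

`encodeAbh()` codes offspring calls relative to the two parents (A = inbred
annual parent homozygote, B = perennial parent homozygote, H =
heterozygote).  When one parent is missing or heterozygous at a marker the
other parent anchors the coding; markers where both parents are
uninformative, or that do not segregate, are dropped and logged.
`filterMissing()` applies the strict 10% missingness rule (a marker with
19 missing calls of 182 is dropped, 18 is kept).  `collapseRedundant()`
groups markers whose codominant-coded correlation magnitude is 1 within
1e-12 on pairwise-complete observations -- the tolerance is a numerical
guard, not a similarity threshold -- transitively, because redundancy
chains overlap; the group representative is the member with fewest missing
calls, ties resolved by input order.  `imputeByFlanks()` fills a missing
call when its nearest non-missing neighbors on both sides within the
chromosome agree; the remainder (disagreeing flanks, chromosome ends) is
filled in a documented second pass with the marker's modal state, and the
second-pass count is reported so users can audit it -- a reproducible
stand-in for what would otherwise be manual curation.  `distortionScan()`
tests each marker's counts against 1:2:1 by a df-2 chi-square without
continuity correction, and `multivalentScreen()` computes, for every pair
of distinct chromosomes, the maximum absolute inter-chromosome marker
correlation (within-chromosome pairs are excluded since linkage is expected
there); a planted co-segregating trio saturates the screen at |r| near 1,
while neutral simulation stays below the default 0.5 flag.  Duplicate
genotypes are detected by >= 99% call identity over shared non-missing
markers.

# Linkage mapping

Two-point recombination fractions for an F2 intercross in known coupling
phase are maximum-likelihood estimates via EM: all cells of the 3x3 joint
genotype table carry a known recombinant-gamete count except the double
heterozygote, which mixes 0 and 2 recombinant gametes with posterior weight
$2r^2/((1-r)^2 + r^2)$.  The EM is vectorized over all marker pairs at once
(nine indicator cross-products), so a full-genome rf matrix is cheap.  LOD
scores compare the MLE against r = 0.5.  Pairs with fewer than 10 jointly
observed genotypes are flagged rather than dropped.  Grouping is
single-linkage on edges with rf <= 0.35 and LOD >= 6; ordering builds a
minimum-spanning-tree backbone, takes its diameter path, inserts the
remaining markers by cheapest insertion and refines with 2-opt on the sum
of adjacent recombination fractions.  Whole-group orientation is
unidentifiable, so the order is anchored by requiring the group's first
input marker to sit in the first half; positions are cumulative Kosambi
distances, $d = 25\ln((1+2r)/(1-2r))$.  Distorted markers are not excluded
from mapping -- a Z-selected region maps through its distortion, and a test
asserts exactly that.

# Phenotype mixed models

The plot-level model is
$$y_{ijkl} = \mu + g_i + l_j + r_{jk} + (gl)_{ij} + e_{ijkl}$$
with genotype $g_i$ fixed for BLUEs and random for variance components;
location, replicate-in-location and genotype-by-location are random, and
all location terms are dropped for single-location traits.  REML is
implemented in-package by direct maximization of the restricted
log-likelihood through the sparse mixed-model equations, profiling the
residual variance and optimizing log variance ratios (non-negativity holds
by construction) with an analytic gradient, three starts against local
optima, and a tight polish step; variance-component standard errors come
from the curvature of the restricted likelihood in the variance components.
On balanced data the estimates agree with the closed-form ANOVA
method-of-moments estimators to better than 1e-6, and on unbalanced data
with `lme4::lmer`, which serves as an independent cross-check in the test
suite, never as the implementation.

`av.VD`, the mean variance of a difference of two BLUEs, is computed
exactly from the full fixed-effects covariance matrix over all genotype
pairs; the balanced approximation $2(\sigma^2_{GL}/L + \sigma^2_E/(LR))$ is
available as `heritabilityBalanced()`.  Entry-mean heritability is
$H^2 = \sigma^2_G/(\sigma^2_G + av.VD/2)$.  With the fertility components
313.7 and 94.9 at one location and two replicates this evaluates to 0.87;
for the perenniality components the balanced approximation gives 0.80
against a published 0.81 computed from an unprinted exact av.VD -- the
exact-definition path is the authoritative one in this package.

The bivariate model fits two traits jointly on plots observed for both
(hence no location effect), with unstructured 2x2 genotype and residual
covariance matrices and a diagonal replicate matrix.  It is parameterized
by log-Cholesky factors, which keeps both matrices positive semi-definite
by construction -- no projection step is ever needed -- and is optimized by
BFGS from three moment-based starts.  Constraining the cross-covariances to
zero decomposes the fit into the two univariate fits, which the tests
verify.  The genetic-covariance standard error is a delta-method transform
of the numeric curvature.  Fertility enters covariance analyses as
non-fertility (100 minus fertility), via `asNonFertility()`.

# Genome scans

Markers are coded codominantly (0/1/2 for A/H/B) and dominantly (0/1/0).
`scanSingleMarker()` adds the fixed effects in the order [cofactors,
$x_{cd}$, $x_d$] to the phenotypic model with genotype random, and reports
incremental (type-I) Wald chi-squares: the dominance statistic is the
last-term Wald, the codominant statistic is the backward difference against
the joint 2-df Wald, so the two increments sum exactly to the combined
cd+d statistic, which is referred to chi-square with df 2.  Asymptotic
chi-square reference distributions are used throughout (no denominator-df
correction).  For multi-location traits the marker's cd and d codes
additionally enter as random marker-by-location effects (one variance
each); when such a variance hits the zero boundary it is simply estimated
at zero.  If a genotype class is empty -- e.g. the B class at a Z-linked
marker -- the dominance term is inestimable: it is dropped from the design,
$p_d$ is reported as 1 and the row flagged, and the combined statistic
(then just the cd increment) is still referred to df 2, a deliberately
conservative choice rather than a silent reparameterization.

The simpleM threshold divides $\alpha = 0.05$ by the effective marker
number $q_{\mathrm{eff}}$: the number of eigenvalues of the marker
correlation matrix (cd coding) needed to reach 99.5% of the total
variation, computed on the post-collapse unique-marker matrix.  For
epistasis the divisor is $q_{\mathrm{eff}}(q_{\mathrm{eff}}-1)$, the number
of ordered pairs -- no PCA is run over interactions.  Genome-wide error
under strong linkage is anti-conservative for simpleM; the package's own
calibration checks target the per-test chi-square null instead, which is
exact in the limit.

Cofactor scans: CM1 takes, per chromosome, the most significant marker
passing the global threshold in a cofactor-free scan, and drops cofactors
on the tested marker's own chromosome; CM2 runs a simultaneous
forward/backward stepwise search on a plain linear model of the BLUEs
against cd-coded markers, starting from the intercept-only model, choosing
at each step the single add-or-drop move that most decreases the Schwarz
BIC (penalty $\log N$), deterministic with ties resolved to the lower
marker index.  Missing cd codes are mean-imputed for the selection step
only.  In both schemes the tested marker and its redundancy group are never
among their own cofactors.

Confidence intervals are log10-drop-1 intervals: the outermost contiguous
markers around the peak whose $-\log_{10}(p_{cd+d})$ stays within 1 of the
peak.  Explained genetic variance $p_G$ is the reduction of the REML
genotype variance when the markers' cd+d effects enter as fixed effects,
divided by the base genotype variance (negative estimates truncate to 0,
flagged).  For unlinked QTLs the joint $p_G$ equals the sum of single-marker
values in expectation; a single realized study wanders around equality by
roughly the chance inter-chromosome marker correlation
($\mathrm{sd} \approx 1/\sqrt{n}$, so about $\pm 0.1$ in $p_G$ units at
n = 178), and the tests therefore assert that the mean discrepancy over
simulated studies is within 0.02 of zero rather than demanding it of every
draw.  $p_{CovG}$ is the analogous
ratio on the genetic covariance of the bivariate model and is reported as
undefined when the base covariance is within 1e-8 of zero.  The epistasis
scan enters fixed effects in the sequence
$m1_{cd} + m2_{cd} + m1_d + m2_d + m1_{cd}{:}m2_{cd} + m1_d{:}m2_d +
m1_d{:}m2_{cd}$, with the asymmetric $d{:}cd$ interaction also tested with
roles swapped as the last term of a second fit; empty interaction cells are
flagged inestimable.

# Numerical choices and degenerate inputs

* Variance ratios are optimized on the log scale in $[e^{-16}, e^{16}]$;
  ratios below $10^{-7}$ are reported as exact zeros and their standard
  errors as `NA` (boundary).
* The redundancy tolerance (1e-12 on $1-|r|$), the rf EM convergence
  tolerance (1e-12, 200 iterations), and the 2-opt improvement threshold
  (1e-12) are numerical guards well below any data-driven scale.
* Coincident markers (rf = 0) order adjacently at zero separation; a
  zero-length chromosome yields an intact parental haplotype.
* Collinear fixed effects (including cofactors) are detected by pivoted QR
  and dropped with a warning; a fixed-genotype fit with no residual degrees
  of freedom is refused.
* All randomness flows through R's session RNG; `simulateStudy()` and
  `runPipeline()` seed it once from their integer seed, making every run
  bit-reproducible.

# Problem sizes used in the test suite

The suite verifies the statistical claims at sizes chosen to make the
Monte-Carlo bounds sharp while keeping a full run comfortably fast on one
CPU: the Haldane closed form at 100,000 gametes; neutral and Z-selected F2
ratios at 10,000 individuals; the pooled F3 ratio at ~10,000 families over
an idealized 1:2:1 F2; parameter-recovery loops at 200 simulations of the
n = 178, two-location, two-replicate design; null calibration of the
combined Wald test at 400 scans; and map construction at the full
113-marker chromosome scale.  These are the package's own choices of
experiment size, stated here so that the reported bounds can be read
against them.  Two recovery caveats are intrinsic rather than chosen: the
location (2 levels) and replicate-in-location (4 levels) variance
estimators are truncated at zero and therefore upward-biased in the mean at
these level counts, so they are checked for median-centering; and
genome-wide family-wise error of the simpleM threshold is not replayed at
the full 789-marker, 200-replicate scale (that is on the order of 10^5
mixed-model fits) — the per-test chi-square calibration that the threshold
rests on is what the suite verifies.

# Known limitations

* Two-point mapping only: no multipoint HMM refinement and no genotype-
  error correction during map construction.
* The scan tests markers, not intervals; effects between markers are
  attributed to flanking markers.
* simpleM under the extreme linkage of a mapping population is
  anti-conservative relative to a permutation threshold; the package
  implements the published rule rather than an alternative.
* The incompatibility models cover selfing only; cross-pollination
  compatibility between unrelated genotypes, pollen-tube growth and any
  additional masked stigma loci are out of scope.
* The bivariate model assumes paired plots; traits observed in disjoint
  locations cannot be fit jointly.
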