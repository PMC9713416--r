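---
title: "Simulating genomic selection under engineered recombination landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genomic selection under engineered recombination landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombgs)
```

## The question the simulator is built for

Meiotic crossovers are rare (1–2 per chromosome per meiosis in wheat) and
strongly suppressed around centromeres, so much of the genome is inherited
in large blocks. Technologies that raise crossover frequency, or retarget
crossovers into the pericentromere, could in principle break unfavorable
linkages ("repulsion": alleles of opposite effect on one haplotype) and
release genetic variance for selection. But more recombination also decays
the marker–QTL linkage disequilibrium (LD) that genomic prediction relies
on. `recombgs` simulates doubled-haploid (DH) breeding programs under
factorial combinations of recombination treatment, trait architecture,
heritability, linkage phase, QTL annotation, and predictor set, and
measures which combinations actually convert extra recombination into
extra genetic gain.

## Model components

### Founders and linkage phase

Synthetic founder panels are fully inbred biallelic lines (default 26
founders, 21 chromosomes, 1.22 M and 1,200 SNPs per chromosome, major
allele coded 1). Linkage phase is structured the way diverse inbred panels are: a fixed
minority founder group per chromosome carries most minor alleles.
Coupling-type loci draw their minor-allele carriers as (mildly perturbed)
nested subsets of that group's rank order; repulsion-type loci place
carriers on the complementary founders. Two loci are then in repulsion
essentially when their types differ, which makes the repulsion fraction
*distance-invariant*: it is the same for adjacent loci and for sparse QTL
subsets, as it must be when phase is measured on sampled QTL. The
per-locus repulsion-type rate starts at the root of 2q(1−q) =
`coupling_target` and is tuned by an empirical adjustment loop (≤ 50
iterations) until the realized fraction of neighboring loci whose minor
alleles are negatively correlated is within 2 percentage points of
`coupling_target` (default 0.33, a panel with inherently high coupling).
Inside the 0.2 M pericentromeric window the repulsion-type rate is
reduced to 30% of baseline, reflecting tighter historical linkage there,
so deleterious-variant QTL see noticeably less repulsion than random QTL.
Because same-type loci are in coupling with each other, realized
repulsion fractions saturate near 0.5; targets well above that are not
reachable (real panels are coupling-dominated, so this region is not of
interest).

What the generator does *not* emulate: coalescent-grade allele-frequency
spectra, population structure or PC-outlier founders, recombination-rate
heterogeneity beyond the single pericentromeric window, and realistic
missingness (the synthetic pipeline has none; the real-data reader fills
missing calls with the major allele — a documented simplification of
stochastic imputation — and logs when it does so). Passing tests therefore
demonstrate the *mechanisms* (repulsion release, LD decay, fixation
dynamics), not calibrated wheat-specific effect sizes.

### Deleterious-variant annotations

Per chromosome, loci are flagged "high impact" (18% baseline rate) or
"nonsynonymous" (22%), mutually exclusively, with the within-window flag
density elevated by `pericentromere_enrichment` (default 3×) using
stratified exact-count sampling so the realized density ratio matches the
request. D-group chromosomes (the last third) carry 0.23× the baseline
density. On synthetic panels the flags additionally favor coupling-phase
loci (`coupling_bias`, default 4): genetic load rides the majority
linkage phase, so neighboring deleterious-variant QTL end up in repulsion
markedly less often (≈ 15–18%) than random QTL (≈ 33%), as expected for
load concentrated in a minority lineage group. The DV candidate pool draws 90% of high-impact and 25% of
nonsynonymous loci (counts rounded half up, re-drawn each replicate),
giving a capacity of roughly 260 candidates per A/B chromosome and 60 per
D chromosome at the default density — so polygenic DV settings place 200
QTL per A/B chromosome and ~60 per D chromosome. These rates were chosen
once from the structural constraints (capacity ≥ 200 on A/B, ≈ 60 on D,
and a feasible 3× enrichment without saturating the window) and are not
tuned thereafter.

### Meiosis

Crossovers follow a stationary gamma renewal process on the Morgan scale:
chiasmata with gamma(ν, 2ν) inter-arrival distances (intensity 2 per
Morgan along the four-strand bundle), thinned by 1/2 per gamete. The
expected crossover count per gamete therefore equals the chromosome map
length in Morgans — the central lever of the design — and ν = 2.63 gives
positive interference whose two-point recombination fractions track the
Kosambi map function r = tanh(2d)/2 at distances up to ~0.5 M. The Kosambi
function itself is a two-point relation without an exact multilocus
process; the gamma renewal model is the standard process-level
approximation. Stationarity is obtained by starting the process 5 M before
the chromosome origin; no obligate crossover is enforced (a pure renewal
process, so zero-crossover gametes occur). Chromosomes assort
independently; there are no sex-specific maps, mutation, or segregation
failure.

A note on the 20× treatment: the literal rule "multiply map distances by
20" is implemented, so a 1.22 M chromosome scaled whole becomes 24.4 M and
yields ~24 crossovers per meiosis. Implementations that saturate two-point
recombination fractions would realize fewer; we keep the literal rule and
verify the expectation against map length.

### Map treatments

`scale_map()` applies a coordinate transform: the Chromosome type
multiplies all distances by the scale factor; the Pericentromere type
multiplies only distance inside the wildtype 0.2 M window, splitting
straddling intervals at the window boundary so total-length arithmetic is
exact (1.22 M → 1.22 + 19 × 0.2 = 5.02 M under 20×). WT is the identity.
The treatment is applied once, at the start of genomic selection.

### Trait architecture and phenotypes

Raw effect magnitudes are standard normal; signs are overwritten by the
linkage-phase scenario (1: all positive; 2: random 2/3 positive; 3: random
1/2; 4: deterministic alternation along map order, first sign random,
continuing across chromosome boundaries; 5: random 1/3 positive).
Magnitudes are kept identical across scenarios so only phase differs. Sign
draws for scenarios 2/3/5 are genome-wide, not stratified per chromosome.
Effects are divided by the square root of the population's realized
additive variance (founder panel, and again after burn-in) so varA = 1 at
both anchors; the environmental variance is fixed at standardization time
(σ²ₑ = (1−H²)/H²) and then held constant, so realized heritability drifts
downward as variance erodes — deliberately, mirroring a phenotyping
protocol with fixed error variance.

### Genomic prediction

RRBLUP with a grand-mean intercept: effects = (Z′Z + λI)⁻¹Z′(y − ȳ) on
column-centered doses, candidates centered by the *training* means. λ is
estimated each refit by 1-D REML, profiled over the spectrum of the
centered predictor matrix (thin SVD; the efficient mixed-model rotation —
because Z is centered, the intercept is orthogonal to the predictor space
and its BLUE is the phenotype mean). If the bounded profile ever failed,
λ = m (the shrinkage implied by h² = 0.5) is used. Predictors are either
the SnpChip markers (GW) or the causal variants themselves (CV — a
perfect-LD benchmark). No allele-frequency filtering; monomorphic columns
get zero effect by construction. When selection has fixed every predictor
in the training population, the replicate continues with a null model
(zero effects): complete fixation is an endpoint of the scheme, not an
error.

### Breeding scheme

Full-founder mode: 10 burn-in cycles of phenotypic selection (400 random
crosses among 80 parents — uniformly with replacement, selfing excluded —
1 F1 → 1 DH per cross, top 80 DHs by phenotype advance; the very first
crosses are among the founders; the final cohort of 400 advances whole as
the training population). Biparental mode: one unselected cycle from the
two most divergent founders. Then 10 GS cycles: fit RRBLUP on the TP,
predict the 400 DH candidates, top 20 EBV become parents, top 160 EBV are
phenotyped into the TP, and the 80 lowest-EBV TP members (ranked by the
current model) are dropped — net +80 per cycle, TP 400 → 1,200. The
scheme text's "drop the bottom 20% of the updated TP" converges to a
640-member TP instead, contradicting the stated 1,200; the 1,200-member
endpoint is taken as authoritative, with the literal rule available via
`tp_drop_rule = "literal20pct"`. TP pruning uses model EBVs (not
phenotypes) because pruning follows the model update; the 160 phenotyped
candidates include the 20 selected parents. All truncation selections
break ties by original order, for determinism.

### Response variables

Per cycle, on the 400 candidates: additive variance (population variance,
divisor n, of true genetic values); genic variance Σ 2pᵢ(1−pᵢ)aᵢ² (the HWE
form regardless of inbreeding, matching the convention of the routine it
mirrors — allele frequencies are computed on dose/2, i.e. line frequencies
in inbred populations); the Bulmer ratio varA/(2·genicVarA), where the
factor 2 converts the HWE expectation to its fully inbred equivalent, so
1 means linkage equilibrium and lower values mean repulsion-generated
negative LD; genetic gain relative to cycle 1; prediction accuracy
(Pearson, NA if degenerate); QTL fixation fractions by |effect| tercile
(remainders to the lower terciles, so 200 QTL split 67/67/66); and
favorable-allele frequency change by tercile (negative values expose
hitchhiking of unfavorable alleles). The minor-allele designation used in
repulsion measurements is the full-founder-set one, carried through
biparental recoding.

## The experiment layer

`factorial_design()` crosses the seven factors with the study's
restrictions (biparental: scenarios 3/4 only; DV QTL only with the full
founder panel). With the default exclusions 576 runnable settings remain;
`exclude_biparental_dv = FALSE` reproduces the published 672-cell
accounting, which counts the never-evaluated biparental × DV cells.
`run_grid()` derives each replicate's seed deterministically from the base
seed and the (setting, replicate) indices, so results are independent of
worker count and completion order, and reruns/resumes are exact.

`variance_decomposition()` fits
`response ~ (all 7 factors)^2` at one cycle, removes the between-replicate
sum of squares first (equivalent to a random replicate intercept under
balance — full REML machinery is unnecessary for share-of-variance
reporting), and reports each term's share of the total sum of squares
using Type-II sums of squares (robust to mild imbalance from failed
replicates; under balance Type-I/II/III coincide). Tukey-corrected
post-hoc contrasts are out of scope; `marginal_means()` reports
equal-weight level means over the crossed design, optionally conditioned
on a subset, and `percent_difference()` composes the usual
"% vs wildtype" contrasts.

## Numerical choices and degenerate inputs

* Co-located loci are jittered apart by 0.00001 M at map construction.
* Standardization errors on varA = 0 ("no genetic variance to
  standardize"); at reduced genome sizes oligogenic burn-ins can reach
  this legitimately — those replicates are complete fixation by
  definition.
* REML is profiled on log λ over [1e−8, 1e8]; singular values below
  10⁻¹⁰ of the largest are dropped.
* `read_founders()` applies filters in order (missingness > 60% or unknown
  chromosome → monomorphic → major-allele recode → major-allele fill),
  errors on duplicated locus ids, unsorted maps, or a table with no
  polymorphic locus, and is idempotent on its own output. Ties in the
  majority recode keep the existing coding (numeric input) or code the
  lexicographically larger letter as 1, so round trips are stable.
  PC-outlier founder removal is available but off by default; the
  synthetic generator never creates such outliers.

## Problem sizes used in the shipped checks

The package's own test suite and `scripts/acceptance.R` exercise the full
scheme on a reduced genome — 5 chromosomes, 240 SNPs and 40 QTL per
chromosome, 20 replicates per arm — which preserves every structural
constant of the breeding design (400 crosses, 80/20/160 selections, TP
400→1,200) while keeping a complete factorial arm affordable on a laptop.
Directional conclusions (20× retains more variance under repulsion + CV;
genome-wide accuracy drops as maps grow; oligogenic architectures fix
sooner) are stable at this size; the published full-scale effect
magnitudes (e.g. marginal-mean shares of variance, or percent differences
at 100 replicates × 672 settings on the real founder panel) are not
desk-reproducible and are not asserted.

## Known limitations

* No dominance, epistasis, G×E, or multi-trait selection.
* No fertility cost of extreme recombination; the 20× maps are taken at
  face value.
* The reader's major-allele imputation understates heterozygosity that
  stochastic imputation would preserve.
* The synthetic founders' minor-allele-frequency spectrum (weights ∝ 1/k
  over carrier counts) is a convenience choice, not an estimate.
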