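---
title: "Tracking strain populations across fecal microbiota transplants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking strain populations across fecal microbiota transplants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strainflow)
library(dplyr)
```

## The problem

Fecal microbiota transplantation (FMT) pits the donor's gut community against
the recipient's. For every microbial species carried by either party, the
population observed in the recipient after the intervention can be dominated
by donor strains, by the recipient's own baseline strains, by a mixture of
both, or by strains detectable in neither baseline. Resolving this requires
strain-level markers, because donor and recipient typically carry *different
strains of the same species*.

strainflow scores these outcomes from two per-species, per-sample profiles:

* an SNV table of read counts for the four nucleotides at variant positions
  of the species' pangenome, and
* a gene-cluster coverage table (horizontal coverage in bp, fraction of gene
  length covered, mean vertical depth).

Each FMT is a **D-R-P triad**: donor baseline (D), recipient pre-FMT baseline
(R), and one or more post-FMT samples (P), each scored independently.
Autologous transfers (the recipient's own stool) reuse R in the donor slot.

## Detection and filtering rules

All thresholds live in `scoring_config()` and default to the conventions of
strain-resolved gut metagenomics:

| rule | default | meaning |
|---|---|---|
| species detection | ≥ 3 of 10 marker genes | species present in a sample |
| gene presence | > 100 bp, > 20 % of length, > 0.5× depth, species detected | gene cluster present |
| confident absence | 0 bp covered while core median depth > 1× | gene truly missing, not undersampled |
| allele observed | ≥ 2 supporting reads | detection unit everywhere |
| SNV retention | ≥ 2 reads in ≥ 2 samples (gene present) | candidate variant kept |
| extended core | > 80 % of genomes (strict), else 50 most prevalent | backbone for coverage and SNVs |
| conspecific scoring | ≥ 100 informative positions | minimum evidence per triad |

Two readings deserve a note. The coverage clauses are implemented as strict
inequalities (coverage must *exceed* the thresholds). The top-50 fallback for
the extended core triggers whenever the prevalence rule yields fewer than 50
genes, making 50 the floor of the core size; prevalence ties are broken by
lexicographic gene identifier so the core is deterministic. After filtering,
positions at which fewer than two distinct alleles survive carry no variant
signal and are dropped.

## Strain population diversity (SPD)

For one species in one sample, with allele frequencies
$p_A, p_C, p_G, p_T$ at each variant position $i = 1..n_{var}$ of the
extended core and $cov_{hor}$ covered core positions,

$$\mathrm{SPD} = \frac{\sum_{i=1}^{n_{var}}\left[(p_A^2+p_C^2+p_G^2+p_T^2)^{-1} - 1\right]}{cov_{hor}}$$

i.e. the coverage-normalized sum of per-position inverse Simpson indices
minus one — the *average effective number of nondominant alleles*. SPD is 0
for a single dominant strain (no multiallelic positions) and 3 when all four
alleles occur in equal proportion at every covered position. Normalizing by
$cov_{hor}$ rather than $n_{var}$ keeps values comparable between samples
with incomplete coverage of the species.

The source coverage table should supply $cov_{hor}$; where it cannot,
`strain_diversity()` falls back to the number of variant positions covered at
≥ 1×, a lower bound. This choice (1× rather than the 2-read detection
threshold) is deliberate: $cov_{hor}$ measures how much of the core genome
was seen at all, not how much passed the detection rule.

```{r}
spd(matrix(0.25, nrow = 10, ncol = 4), cov_hor = 10)   # maximal diversity
spd(matrix(c(1, 0, 0, 0), 1), cov_hor = 10)            # one strain
```

## Allele distances (AD)

The distance between one species' strain populations in two samples is the
mean, over extended-core variant positions with shared coverage (depth ≥ 2 in
both samples, matching the two-read detection convention), of the Euclidean
distance between the two 4-dimensional frequency vectors. Raw per-position
distances live on $[0, \sqrt 2]$; we divide by $\sqrt 2$ so AD lives on
$[0, 1]$ and the convention that AD = 1 to any sample where the species is
absent is continuous with the maximum attainable conspecific distance. At
least 20 shared positions are required; below that the distance is missing
(`NA`) and must be propagated, never imputed — a present-present pair with
insufficient shared coverage is *unknown*, not maximally distant.

## Determinant alleles and outcome scoring

Donor-determinant alleles are alleles observed (≥ 2 reads) in D but not in R;
recipient-determinant alleles are the converse; post-FMT determinant alleles
are observed in P but in neither baseline. Two refinements matter:

* multiple observed alleles at one position all count, one unit per allele —
  fecal strain populations are frequently heterogeneous;
* a position inside a gene that is *confidently absent* from a sample is
  evaluable (informative) there: the absence itself is evidence, so
  differential gene content between strains contributes determinants.

Positions with unknown state in any sample of the comparison are excluded.
With at least 100 informative positions, the strain fractions of a post
sample are

* `f_donor` — donor-determinant alleles detected in P over those evaluable
  at informative positions of P (symmetrically `f_recipient`),
* `f_novel` — post-FMT determinant alleles detected over all informative
  positions.

The denominators are per-component because determinant sets can be strongly
asymmetric (e.g. a donor with many private accessory genes); positions
informative in the baselines but not evaluable in P are excluded from all
denominators. A zero denominator yields a missing fraction.

Categories are assigned presence-pattern first (donor-only species observed
post FMT → donor colonization; recipient-only retained → persistence; from
neither baseline → novel influx; recipient species lost → species loss;
donor-only not appearing → rejection). Conspecific triads (species in D, R
and P) are classified from the fractions with configurable cutoffs
`theta_present = 0.2` and `theta_dominant = 0.8` (the literature cutoffs are
cited but not printed in the primary sources, so these defaults are explicit
stand-ins — report results together with the configuration): coexistence when
both donor and recipient fractions reach `theta_present`; dominance when one
reaches `theta_dominant` with the other below `theta_present`; novel influx
at `theta_dominant` novel; otherwise the largest fraction wins with the
deterministic tie-break donor > recipient > novel. One deliberate deviation
from pure largest-wins: when *both* attribution fractions are undefined —
no determinant alleles exist at all, as in autologous triads where D and R
are the same sample — attribution is undefined and the record is
`not_scorable` (or `novel_influx` if the novel fraction is dominant), rather
than letting the tie-break invent a donor-colonization call.

## Cohort summaries and null cohorts

Per FMT, the **colonization index** is the mean `f_donor` and the
**persistence index** the mean `f_recipient` over species observed post FMT
(at the last available time point, by convention); presence-pattern outcomes
contribute degenerate fractions (a donor-only species observed post FMT
counts as `f_donor` = 1). Because coexisting populations detect both donor
and recipient determinants, the two indices need not sum to one. Outcome
fractions per category are normalized to species observed in the recipient
post FMT. Binarized outcomes (resilience, colonization, takeover, turnover)
follow fixed logic: takeover (donor dominance) implies colonization and
turnover; turnover covers donor dominance, novel influx and species loss.

Null cohorts replace, per observed triad, the donor sample, the recipient
baseline, or both, with samples from other FMTs — ten simulated triads per
observed triad by default, stratified by geography, never pairing a sample
with a triad of the same subject and never reusing the true pairing when an
alternative exists. Within one replicate, replacements are drawn without
reuse where a feasible assignment exists; draws are independent across
replicates. All draws flow from one seed.

Clinical association testing compares responders and nonresponders per
outcome metric by Wilcoxon rank-sum (exact for small samples without ties)
and, given covariates, by sequential ANOVA with the response term entering
last; every p-value computed in one invocation forms the
Benjamini–Hochberg family.

## Outcome prediction

Outcomes are modeled with ten-times five-fold cross-validated
LASSO-regularized regression (linear for indices and fractions, logistic for
binarized outcomes), via glmnet on a fixed 100-value lambda path spanning
four decades below the smallest all-zero lambda. Within every fold, training
data are median-imputed and standardized and the validation fold is
transformed with the *training* statistics, so no information flows from
validation to training; missingness indicators are added at design time.
Each repeat selects the largest lambda within one standard error of its CV
minimum; coefficients are taken from each training fold's fit at that lambda
and averaged across all 50 folds, and performance (held-out $R^2$ or AUROC)
is averaged the same way. Categorical covariates are one-hot encoded with
independent (ungrouped) indicators. Variable importance multiplies the
averaged coefficient by the model's performance above chance
(`max(AUROC - 0.5, 0)/0.5` for logistic, `max(R², 0)` for linear), so
uninformative models contribute nothing to the importance network.

One caveat the test design respects: permuting a response within a fixed
finite design does not erase chance sample correlations, and with many
candidate columns relative to observations a correct cross-validation will
genuinely detect them (at 100 observations against 60 standard-normal
decoys the largest chance correlation is ≈ 0.3, worth an AUROC near 0.65).
The leakage checks therefore run at 200 observations against the compact
covariate set, where chance association stays well inside the asserted
bounds; what they certify is the absence of information flow, not the
impossibility of finite-sample coincidence.

## The synthetic cohort generator

The generator exists so every stage is testable without external data; its
defaults are fixed study conditions, not tuning knobs.

* **Haplotype panels** place variant positions round-robin over gene
  clusters (70 % of them extended-core, carried by every strain; accessory
  genes by a random proper subset). The default *marker* layout gives every
  position a panel-wide background allele plus one strain-private
  alternative with rotating ownership — mimicking strain-diagnostic SNVs.
  The last panel strain is *divergent*, differing from the background and
  from every marker allele at every position, emulating the
  phylogenetically distinct environmental strains that produce novel-influx
  outcomes; a weakly divergent "novel" strain would be indistinguishable
  from baseline noise by construction, which is a statement about the
  planted scenario, not the scorer. A *disjoint* layout (all strains differ
  everywhere) supports maximal-divergence checks.
* **Samples** draw per-position depth as Poisson around `depth` times the
  summed weight of strains carrying the containing gene, allele counts as
  multinomial over mixture-weighted haplotype alleles with a 0.1 % per-read
  error flip, and gene coverage from the Poisson coverage model
  (covered fraction $1 - e^{-\text{depth}}$). Depth is independent across
  positions — adequate because the scoring arithmetic is
  position-exchangeable; real along-genome autocorrelation is not emulated.
* **Triads** plant each of the outcome categories as mixture weights over
  donor strains (1–2), recipient strains (3–4) and the novel strain (5),
  e.g. coexistence as a 50/50 post mixture. Default depth 50×, 400 variant
  positions; recovery checks run at 20× — chosen as typical and as a
  stressed-but-realistic coverage for strain calling, respectively.
* **Cohorts** carry procedural, community-diversity, metabolic and decoy
  covariates with planted linear effects on a per-FMT colonization
  propensity (base 0.5) and logistic effects on per-species takeover (base
  rate 0.2). With `emit_profiles = TRUE` every FMT draws an *independent*
  haplotype pool on a shared per-species scaffold, so an unrelated donor
  shares alleles with a post sample only by chance — exactly the property
  the shuffled-triad nulls probe; the null colonization index is compared
  against the attribution measured from freshly simulated unrelated
  samples, which is distributionally the same chance level.

What passing these tests shows — and does not show — about real data: the
pipeline recovers planted truths under multinomial sampling noise,
sequencing error, and gene-content differences, at realistic depths. It does
not certify behavior under read-mapping artefacts, reference bias, shared
ancestry between donor and recipient strains, or within-host evolution,
none of which the generator emulates.

## Numerical choices and degenerate inputs

* Frequencies are always re-derived from counts; rows must sum to depth
  exactly, and simplex violations on the SPD path are errors, not warnings.
* `spd` with zero coverage is `NA`; an empty variant table gives SPD 0 under
  positive coverage (a covered, monomorphic genome).
* AD with fewer than 20 shared positions is `NA`; equal-sample distance is
  exactly 0; the absence convention takes precedence over everything.
* Zero-variance design columns are dropped with a warning; in-fold constant
  columns pass through centered with unit scale (coefficient 0).
* All simulation randomness derives from one seed through stable per-entity
  sub-seeds (below 2^31), so cohorts are reproducible and stable under
  subsetting.

## Problem sizes used by the test-suite

Oracle equivalence runs on 100 random tables of 15–70 positions; category
recovery on 6 × 30 planted triads (400 positions, 20×); null-cohort checks
on an 8-FMT, 3-species profile cohort with 10 replicates per triad; the
modeling harness on 20 cohorts of 100 FMTs with 60 decoy covariates, plus a
200-FMT cohort for permutation checks. These sizes were chosen to make the
statistical assertions sound at desk scale.

## Limitations

Scoring operates on profile tables, not reads: mapping, SNV calling and
pangenome construction are upstream concerns. The categorical cutoffs are
configurable stand-ins; empirical cohort results should always be reported
with the configuration used. The indices average detection-based fractions
and are not abundance-weighted. Survival-style modeling of clinical
response, haplotype phasing and within-host evolution are out of scope.
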