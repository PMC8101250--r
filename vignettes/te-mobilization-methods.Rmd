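---
title: "Methods: modelling recent TE mobilization across an accession panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling recent TE mobilization across an accession panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temob)
```

# Scope and overall design

`temob` implements the computational chain of a population study of
transposable-element (TE) mobilization in a selfing plant: from per-sample
candidate insertion calls to a filtered species-wide genotype matrix of TE
insertion polymorphisms (TIPs); from the matrix to frequency spectra,
insertion ages, substitution rates and the strength of purifying selection;
and from per-genome counts of very recent insertions to a genotype +
environment + G×E Poisson model that can be projected onto future climates.
Alignment, split-read detection, SNP annotation and outgroup BLAST checks
are upstream of the package: their products (read-evidence columns and
boolean flags on candidate calls, synonymous-SNP counts, pre-normalised
expression) are consumed as inputs.

Because the real inputs are terabyte-scale, every stage is validated on
synthetic cohorts. The generator is not a test fixture but a model of the
study conditions: each component reproduces the statistical structure the
corresponding estimator assumes, and every generating parameter is stored in
a `truth` record so recovery tests are written against known values.

# The synthetic cohort

`simulate_cohort()` draws, under one seed:

* **Panel and kinship.** Accessions split into genetic groups; latent
  genotype factors are group centroids scaled by `kinship_strength` plus
  isotropic noise; the kinship matrix is their centred cross-product, and
  its top three principal components are the population-structure
  covariates used downstream. Defaults (300 accessions, 3 groups) keep the
  matrix algebra at desk scale while preserving the confounding that makes
  kinship correction necessary.
* **TIP sites and read evidence.** Background site frequencies follow
  Beta(`sfs_shape`, 1)/2 with `sfs_shape` = 0.25, a spectrum heavily skewed
  towards rare variants as observed for TIPs; carriers are binomial draws
  with at least one carrier. Per accession and site, positive, negative and
  flanking coverages are independent Poissons chosen so true carriers are
  callable (variant depth 3 + Poisson(5), flanking 8 + Poisson(4)) and
  uninformative genomes stay below callable depth by construction.
  Configured fractions of sites violate each genotyping filter — maximum
  supporting depth 2, exactly `min_informative` − 1 informative genomes,
  positive ≤ negative coverage in every carrier, fragmented/ancestral
  absence flags, *HELITRON* presences — to exercise every filter branch;
  the violation class of each site is recorded in `truth`.
* **Very recent insertions.** Per-accession counts are Poisson with a log
  link on the modifier allele (default fold-change 3.4, the 240% increase
  associated with the natural RdDM-defective *NRPE1* allele that motivates
  the modifier term) and on z-scored bioclimatic variables, with optional
  modifier-by-environment interactions — exactly the family the downstream
  GLM fits. Each event becomes a private presence site.
* **Divergence pairs.** Close pairs accumulate TIP differences at
  `slope_true` = `base_rate`/`snp_rate` TIPs per SNP (defaults 0.0763 and
  0.2511 per genome per generation, slope 0.304). For distant pairs,
  selection deflates observed SNP divergence by 1/κ (default κ = 1.2) —
  raising their synonymous fraction by the same factor — and retains each
  TIP with probability `retention_prob` (default 0.1), so the recoverable
  elimination fraction is 1 − `retention_prob`. A star-like genealogy is
  sufficient because the estimators consume only pairwise counts.
* **Toy genome and expression.** One linear 1-Mb chromosome (0-based
  half-open internally; GFF3 I/O converts to 1-based closed), ~120
  non-overlapping genes with UTR/exon/intron substructure, a central
  centromere. Sites sit on a 200-bp lattice so distinct planted insertions
  never merge into one another. Expression is log-normal per gene; a
  configured fraction of genic TIPs multiplies carrier expression by
  `expr_effect_size` (0 = knock-out).

What the generator does **not** emulate: read-level error profiles, linkage
and recombination, coalescent genealogies, insertion-site preferences, and
methylation. Passing tests therefore demonstrate that the estimators are
correct under their stated assumptions and recover planted parameters at
realistic noise — not that the filters have high specificity on real
sequencing artefacts.

# Genotyping and the filter cascade

Merging takes the transitive closure of interval overlap within (chromosome,
family, variant class); book-ended intervals are not merged. The
representative position is the midpoint of the intersection of member
intervals (midpoint of the union if the intersection is empty). Per-accession
evidence across member calls is aggregated with `max` by default — the
best-supported observation of a genome at a site; `sum` is available but
double-counts when a sample contributes several overlapping records. A site
must have one sample with positive coverage ≥ DP = 3.

State calling: *present* needs positive coverage ≥ DP **and** a coverage
drop, quantified as site (reference-supporting) coverage < 0.8 × mean
flanking coverage. The drop is expected over true non-reference insertions;
0.8 is a package default (configurable) since only the direction of the
effect is prescribed by the biology. Failing that, *absent* needs negative
coverage ≥ DP — the DP threshold is applied symmetrically to both calls —
otherwise the genome is NA and leaves the frequency denominator.

Population filters run in a fixed order with per-stage removal counts
logged: family blacklist (*HELITRON* presences, which the upstream detector
cannot call reliably), informative genomes < 100 (configurable so toy panels
can test the boundary), heterozygous-like presences (no carrier with
positive > negative coverage — unexpected in a selfer, suggestive of very
recent laboratory transposition), flagged absences (fragmented or ancestral
reference TE sequences, i.e. rearrangements rather than mobilization). The
separate capture-experiment filter keeps de novo insertion calls with 2–15
split+discordant reads on **each** side, not centromeric, not spanning the
donor element, and seen in exactly one library.

# Spectra, dating and rates

Frequencies are carriers / informative genomes; the folded spectrum is a
500-bin histogram of minor allele frequency on [0, 0.5], written in a
layout usable as input for external distribution-of-fitness-effects
estimation (the fitting itself is out of scope).

Ages divide the maximum pairwise carrier divergence in a 70-kb window
(per site) by μ = 7e-9. We read "divided by the mutation rate" literally —
no factor of 2 for two-lineage accumulation — and expose `two_lineage =
TRUE` as a switch. One generation is one year (the species is an annual
selfer). At these window lengths the expected SNP count is small (2.45 at
age 5000), so individual ages are noisy and the package's consistency tests
assess the **median** age over many windows, which is within a bin of the
truth from age ≈ 5000 on; single-window ages should not be over-read.

The very-recent rule (frequency < 0.002 AND (private OR age < 1000)) is kept
at its species-panel default; 0.2% assumes a ~1000-genome panel, so on a toy
panel of *n* accessions the ceiling should be scaled to roughly 2/*n*
(a private site has frequency ≈ 1/*n*).

The no-intercept slope is the closed form Σ*TS*/Σ*S*² with the standard
through-origin standard error. κ is defined as the ratio of pooled
synonymous-SNP fractions, distant over close: synonymous SNPs are assumed
neutral, so their over-representation among distant pairs measures how much
selection has thinned total SNP divergence, and multiplying observed distant
divergence by κ restores the neutral clock. The elimination fraction
1 − *b*~all~/(κ·*b*~close~) is clipped to [0, 1): sampling noise can push the
ratio above 1 in the neutral limit, where the honest report is 0.

# Gene impact and nulls

Feature assignment gives each TIP exactly one category with precedence
exon > 5′UTR > 3′UTR > intron > promoter (≤ 250 bp upstream, strand-aware) >
near (≤ 250 bp downstream) > within-2kb > intergenic. The "nearest gene" for
expression contrasts is the assignment gene. Expression ratios use a
pseudocount of 0.5 units on both means (avoids division by zero for
knock-outs); C/NC ≤ 0.1 flags an effective knock-out — the threshold is a
package choice, configurable, since only the phenomenon is prescribed.

The recurrence null redistributes the observed number of TIPs uniformly and
counts genes with ≥ 1 (and ≥ 3) TIPs inside or within 250 bp, over 10
replicates by default; it matches the analytic expectation
Σ_g 1 − (1 − p_g)^n on toy genomes. Enrichment of multi-hit genes is a
Fisher exact test of the observed table against the rounded permutation
expectation. The extreme-ratio null re-draws, per TIP, a pseudo-carrier set
of the same size among genomes with expression data; extremeness thresholds
are the 2.5%/97.5% quantiles of the pooled null ratios. Per-gene combined
effects pool carriers of any allele against genomes carrying none, tested
with a Wilcoxon rank-sum (the exact statistic behind the published
significance axis is not stated; rank-sum is the conservative
distribution-free choice), with Benjamini–Hochberg control across genes.

# Environmental modelling

PVE for GLMs is the deviance pseudo-R², 1 − D_res/D_null ("percentage of
variance explained" has no unique GLM definition; deviance-based is the
standard one and is exactly non-decreasing under nesting, which the stepwise
search relies on). Stepwise selection offers each bio-variable as a fixed
effect and (by default) as a modifier interaction entering jointly with its
main effect (hierarchy principle); the best candidate is added while its
PVE gain strictly exceeds 0.01, ties broken by candidate name for
determinism.

The restricted Mantel test residualises both the count-distance and the
bio-variable-distance matrices (absolute differences) on the kinship
distance (1 − min-max-normalised kinship) and correlates the residuals —
the partial-Mantel formulation; the original study used a custom script
whose exact formulation is unavailable, so the package states its own.
Significance uses row/column-coherent permutations with
p = (1 + b)/(n_perm + 1), never zero.

Climatic envelopes are principal components of the z-scored current-epoch
bio-variables (correlation-scale PCA), with a deterministic sign convention
(largest-magnitude loading positive). CE-shift tests fit, per recurrently
hit gene and per envelope, a logistic GLM of carrier status on the CE score
with kinship PCs as covariates — the same structure correction as the
Poisson model, since the original correction for this step is unstated —
with BH within each envelope (envelopes are nearly orthogonal, so joint FDR
across the three would mostly triple the test count); the negative control
shuffles environments once across accessions.

Forecasting holds genetic terms fixed, z-scores future bio-variables with
**current** means and SDs, and evaluates the fitted linear predictor under
both epochs; future = current implies zero change identically. Hold-out
validation draws 100 test sets of ~10% of the panel, aggregates each
accession's out-of-sample errors, and flags accessions beyond 4 SD of the
mean-error distribution; "predictive variance" is the variance of
per-accession mean prediction errors (the figure it mirrors does not define
its summary; error variance is the decision-relevant one).

# Numerical and testing choices

Problem sizes in the shipped tests are chosen for a single CPU: cohorts of
120–300 accessions with 80–300 background sites for pipeline tests; 500
pairs per divergence class over 20 seeds for rate recovery; 3000 windows per
age for dating; 1000 replicates for the recurrence-null oracle; 200 seeds at
n = 1000 for GLM coverage and stepwise recovery; 200 runs × 1000
permutations for Mantel calibration. Estimator unit tests pin results to
independent oracles: a union-find closure for merging, iterated grid
refinement for the through-origin slope and the 2-parameter Poisson ML, an
independently coded BH step-up, `vegan::mantel.partial` for the partial
Mantel statistic, and closed-form enumeration for the recurrence null.

Known limitations: the generator's independence assumptions (no LD between
sites, independent coverage draws) make the filter-specificity questions of
real data untestable here; per-window ages are noisy at young ages by
construction; and the elimination-fraction standard error treats κ as fixed,
which understates uncertainty when synonymous counts are few.
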