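# temob — population dynamics of transposable-element insertions

`temob` re-implements, as a tested R pipeline, the computational chain used
to study recent transposable-element (TE) mobilization across a large panel
of *Arabidopsis thaliana* accessions: population-level genotyping and
filtering of TE insertion polymorphisms (TIPs), folded site-frequency
spectra, insertion dating from local haplotype divergence, estimation of the
TE insertion substitution rate and of the fraction of insertions eliminated
by selection, permutation nulls for recurrent gene targeting and for
carrier/non-carrier expression effects, and a genotype + environment + G×E
Poisson model of very recent transposition with forecasting under future
climates. It is aimed at population geneticists who want to exercise,
validate or extend this analysis chain without terabyte-scale resequencing
data: a first-class synthetic-cohort generator emulates the statistical
structure of every input.

## The models at the package's core

**Genotyping.** Per-sample candidate insertion calls are merged at the
population level (transitive interval overlap within TE family and variant
class), each genome is called present / absent / NA from its positive,
negative and flanking read coverage (DP ≥ 3 plus a coverage-drop check),
and sites are filtered: ≥ 100 informative genomes, no heterozygous-like
presences (positive ≤ negative coverage in every carrier), no fragmented or
ancestral reference absences, no *HELITRON* presences.

**Rates.** With pairwise TIP differences *T* and SNP differences *S*, a
no-intercept regression gives the slope *b* = Σ*TS* / Σ*S*². Over closely
related pairs (< 500 SNPs genome-wide) the TE insertion substitution rate is
*b*<sub>close</sub> × 0.2511 (the per-genome per-generation SNP rate). Over
all pairs, observed SNP divergence is rescaled to its neutral equivalent by
κ, the ratio of synonymous-SNP fractions (distant / close), and the fraction
of insertions eventually eliminated by selection is
1 − *b*<sub>all</sub> / (κ · *b*<sub>close</sub>).

**Dating.** An insertion shared by ≥ 2 carriers is aged as the maximum
pairwise SNP divergence among carriers within a 70-kb window, per site,
divided by μ = 7 × 10⁻⁹ per site per generation. *Very recent* TIPs
segregate below 0.2% frequency and are private or younger than 1000
generations.

**G×E model.** Per-genome very-recent counts *y*ᵢ follow a Poisson GLM,
log E[*y*ᵢ] = β₀ + Σβₖ PCₖᵢ + β_m mᵢ + Σ βⱼ zᵢⱼ + Σ γⱼ mᵢ zᵢⱼ, with kinship
principal components PC1–3, a modifier allele *m* (an *NRPE1*-like RdDM
mutant; the generator's default effect is ×3.4, a 240% increase), and
z-scored bioclimatic variables BIO01–BIO19 selected greedily while each adds
more than 1% of deviance-explained (PVE). Forecasts apply the fitted model
to future climate z-scored with current-epoch statistics.

## Worked example

```r
library(temob)
cfg <- cohort_config(n_accessions = 300, seed = 1)
coh <- simulate_cohort(cfg)
tm  <- genotype_tips(coh$candidates, min_informative = 100)
tm
#> <tip_matrix> 3864 sites x 300 accessions
#>   filters applied:
#>    - dp_filter              removed    12, remaining  3906
#>    - family_blacklist       removed     2, remaining  3904
#>    - min_informative        removed    12, remaining  3892
#>    - het_like_presence      removed    18, remaining  3874
#>    - flagged_absence        removed    10, remaining  3864
estimate_rates(coh$pairs)
#> <rate_estimate>
#>   slope close pairs: 0.3026 +/- 0.0015 (n=500)
#>   slope all pairs:   0.03643 +/- 4.6e-05 (n=500)
#>   kappa (syn-frac distant/close): 1.205
#>   substitution rate: 0.07599 +/- 0.00038 per genome per generation
#>   elimination fraction: 0.9001
climatic_envelopes(zscore_climate(coh$climate))
#> <climatic_envelope> 3 envelopes over 300 accessions; variance fractions
#> 0.368, 0.320, 0.245 (total 93.3%)
```

The cohort was generated with a substitution rate of 0.0763 insertions per
genome per generation (slope 0.304 TIPs per SNP) and a long-term retention
probability of 0.1: the estimates above recover the slope (0.3026 ± 0.0015),
the substitution rate (0.0760) and the elimination fraction (0.9001 vs the
true 0.9). The filter provenance shows each planted violation class being
removed by its filter stage.

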