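---
title: "Epistasis scans in crossbred populations: model, estimation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistasis scans in crossbred populations: model, estimation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgwas)
```

## The statistical model

For each SNP (or SNP pair) the phenotype model is

$$ y = \mu 1 + X_g g + Z a + e, $$

where $y$ is the yield deviation (phenotype with fixed non-genetic effects
already removed, e.g. herd–year–season), $g$ the vector of genotypic
values of the 3 (one-locus) or 9 (two-locus) genotype classes, $a$ the
pedigree additive (breeding) values with $\mathrm{var}(a)=\sigma_a^2 A$
($A$ = numerator relationship matrix) and $e$ iid residuals. With one
record per animal, $Z$ is the identity.

Exact estimation of $g$ requires either generalized least squares with
$V^{-1}$, $V=\sigma_a^2 ZAZ' + \sigma_e^2 I$, or Henderson's mixed model
equations — per SNP pair, which is infeasible genome-wide. The package
instead uses the *approximate GLS* (AGLS) shortcut: subtract the breeding
value known from routine evaluation, $y^* = y - 2\,\mathrm{PTA}$ (a PTA is
half a breeding value), then fit class means by ordinary least squares,

$$ \hat b = (X'X)^- X' y^*. $$

Two facts make this defensible, and both are enforced by tests:

* **BLUE identity.** If the subtracted value is the *exact* BLUP $\hat a$
  from the same mixed model, the least-squares fit of $y-Z\hat a$ equals
  the GLS solution identically. `solve_mme()` and `gls_blue()` implement
  the two routes independently and the suite checks agreement to
  $10^{-8}$ on simulated data. Using the routine-evaluation PTA instead of
  the per-SNP BLUP is the first approximation; using the LS rather than
  the GLS form of the t-statistic is the second.
* **Null calibration.** Under a null simulation with a pedigree polygenic
  term and BLUP-based PTAs, the empirical type-I error at $p<0.05$ stays
  inside its 99% binomial band and epistasis p-values are
  Kolmogorov–Smirnov uniform.

The t-statistic for an effect contrast $s$ is
$t = s\hat g \,/\, \sqrt{v^2\, s (X'X)^-_{gg} s'}$ with
$v^2 = \mathrm{RSS}/(n-k)$, $k$ the number of occupied classes; for the
class-means design $(X'X)^-_{gg}$ is $\mathrm{diag}(1/n_c)$. P-values use
the $t$ distribution with $n-k$ degrees of freedom: at the population
sizes this method targets ($n \approx 40{,}000$) the difference from the
normal is immaterial, at desk scale the $t$ is the correct reference.

## Effect definitions under disequilibria

Crossbred populations are in Hardy–Weinberg disequilibrium (HWD) at most
loci and in linkage disequilibrium (LD) between close loci, so the
decomposition of genotypic values never assumes either equilibrium: all
weights are the *observed* genotype frequencies. Writing $\mu_X$ for the
frequency-weighted marginal mean of genotypic values over the individuals
carrying index $X$:

* allelic effects $a_i = \mu_i - \mu$, with allele-indexed marginals
  weighting each genotype by its frequency times the count of the indexed
  allele it carries. This is the one weighting that keeps the
  frequency-weighted mean allelic effect exactly zero under HWD; the
  property is tested on random disequilibrium draws.
* dominance values $d_{ij} = \mu_{ij} - \mu - a_i - a_j$;
* sequential epistasis residuals
  $(aa)_{ik} = \mu_{ik} - \mu - a_i - a_k$, then $(ad)_{ikl}$,
  $(da)_{ijk}$ and finally $(dd)_{ijkl}$ as the genotypic value minus all
  fourteen lower-order terms it contains. The full reconstruction of every
  genotypic value from its terms is exact by construction and asserted to
  $10^{-10}$ on 1,000 random instances, against an independently coded
  term-by-term oracle.

Under HWD+LD the decomposition is *not* variance-orthogonal — e.g. a purely
additive two-locus surface genuinely leaks into marginal interaction
values when the loci are in LD (a test documents this); at linkage
equilibrium the lower-order terms absorb additive surfaces entirely and at
HWE+LE the partition degenerates to the textbook orthogonal one (also
tested, including pairwise $f$-weighted orthogonality of the class value
assignments).

### Scalar summary effects and contrast vectors

Each effect class is reported as a single scalar:
$\alpha = a_1 - a_2$, $\delta = d_{12} - \tfrac12(d_{11}+d_{22})$, and for
the epistasis classes the tensor-product contrasts of the value grids with
the additive coefficients $(1,-1)$ over alleles and dominance coefficients
$(-\tfrac12, 1, -\tfrac12)$ over genotypes:

$$ \alpha\alpha = \textstyle\sum_{ik} c^A_i c^A_k (aa)_{ik}, \quad
   \delta\delta = \sum_{ij,kl} c^D_{ij} c^D_{kl} (dd)_{ijkl}, $$

and the mixed $\alpha\delta$, $\delta\alpha$ analogously. This was a
genuinely open design point (the reference material reports one number per
pair without defining the functional). We chose the tensor contrasts
because (a) they reproduce the *reported magnitudes*: a published D×D pair
whose individual $(dd)$ cell values span only $[-1.36, 1.22]$ carries a
printed scalar of 5.01, which is what the $\delta \otimes \delta$ contrast
of such a checkerboard grid yields, and is inconsistent with
"largest-magnitude cell value"; and (b) they are *fixed* 1-df contrasts,
so their null p-values are uniform — a data-dependent selection (e.g. the
max-|value| cell) would invalidate the t-test reference distribution and
fail the calibration suite.

Because every effect above is linear in $g$ for fixed frequencies, the
contrast row vector $s$ is obtained constructively: evaluate the partition
on the nine unit genotypic-value vectors (`contrast_vector()`,
`epistasis_contrasts()`). The suite checks $s\,g$ against the direct
partition to $10^{-10}$ and that every contrast annihilates constants.
A useful consequence of the definitions: $\delta$ and $\delta\delta$
depend only on $g$ (the contrast coefficients are frequency-free), while
$\alpha$ and $\alpha\alpha$ depend on the observed frequencies.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `maf_threshold` | 0.05 | fraction | standard marker filter for this analysis |
| `max_intra_distance_bp` | 3,000,000 | bp | covers the observed intra-chromosome interaction range (up to ≈2.7 Mb) |
| `include_inter_chromosome` | off | — | pair count grows quadratically; user opts in |
| `min_cell_count` | 5 | animals | two-locus cells thinner than this make the 9-class fit unstable; affected contrasts are flagged, not dropped |
| `threshold_single` / `threshold_pairwise` | 8 / 12 | log10(1/p) | fixed genome-wide conventions; the literal Bonferroni numbers (`0.05/(2m)`, `0.05/(4m(m-1)/2)`) are computed and reported alongside rather than substituted, because the published thresholds are rounded conventions, not the literal arithmetic |

Degrees of freedom are $n-k$ with $k$ = occupied classes. The X chromosome
is scanned exactly like an autosome: the target population is all-female,
so every animal carries two X alleles.

## Missing data and degenerate inputs

Missing genotypes are kept in storage ('.'/`NA`; PLINK `0 0` or bit-pair
`01`) and each fit drops the individuals missing at the SNP(s) under test
— complete cases per test, matching per-SNP least squares on class means.
Empty genotype classes reduce the design rank; effects whose defining
marginals have zero total weight are reported `NA` (never imputed), and a
contrast with non-zero coefficient on an empty class is non-estimable. An
undefined effect carried with zero allele incidence contributes zero to
reconstruction (so one empty corner cell does not poison the rest of the
grid). Noiseless fits ($v^2=0$) report the significance cap; log10(1/p) is
computed on the log scale and capped at 320 to keep output finite.
Rounding for display follows the publication convention (halves away from
zero).

## What the simulator emulates — and what it does not

`simulate_population()` generates a two-breed admixed population: founder
breeds "J" and "H" in proportions 0.53/0.47 (the two dominant ancestries
of the motivating population, renormalised), breed allele frequencies
diverged by a Balding–Nichols model around a shared ancestral frequency
(`fst = 0.10`, a realistic Jersey–Holstein divergence), founder
haplotypes drawn through an AR(1) Gaussian copula along each chromosome
(`ld_rho = 0.5`) to create founder LD between close SNPs, and descendants
by gene dropping over a random-mating pedigree with per-SNP independent
Mendelian segregation. Each allele's founder breed origin is tracked and
audited. Phenotypes follow the analysis model exactly:
$y = \mu + \text{planted genotypic values} + a + e$ with a gene-dropped
polygenic term, on a DPR-like scale (mean 55, phenotypic SD 33,
$h^2 = 0.04$ — fertility-trait heritability is low). PTAs are halves of
pedigree-BLUP breeding values (`pta_mode = "blup"`, as in routine
evaluation) or of the true simulated breeding values (`"true"`).

Because the generative model coincides with the analysis model, parameter
recovery is unbiased *by construction*; the recovery suites therefore test
the estimation machinery, not the realism of the generator. Features of
real cattle data the generator does **not** emulate: realistic LD decay
and recombination maps (no crossover model — LD comes from founder copulas
and admixture only), genotyping error and imputation artefacts, selection,
assortative mating, five-breed ancestry, or genotype-by-environment
structure. Passing tests say the estimators do what they claim under the
stated statistical structure; they cannot certify behaviour under
model misspecification.

Planted architectures (`plant_effects()`) and their conventions:
`additive` (slope `scale` per allele-1 copy, so $\alpha \approx$ `scale`),
`table2_dominance` (value map proportional to $(0.629, -1.280, 1.920)$:
both homozygotes positive, heterozygote negative; `scale` 1 gives
$\delta = -2.5545$ exactly, frequency-free), `fig6_axa` (one of the four
allelic combinations interacts, value proportional to the count of
allele-1/allele-1 pairings; `scale` equals the planted $\alpha\alpha$ at
balanced frequencies), `fig8_dxd` (checkerboard in the span of the
$\delta\otimes\delta$ contrast: the four het-by-homo cells negative,
double-het and homo-homo cells positive; `scale` equals the planted
$\delta\delta$ exactly), and `null`. True effects in the truth table are
always re-derived from the planted map and *realized* frequencies by the
partition functions — a single source of truth.

## Validation suite design

Problem sizes were chosen so each suite measures what it claims on a
single CPU in minutes:

* estimator identities: 20 instances of $n=200$ (BLUE identity to
  $10^{-8}$); algebraic identities on 1,000 random frequency/value draws;
* null calibration: five null populations of 2,000 cows × 200 SNPs for
  single-locus type-I error (~2,000 p-values), and one population of
  2,000 cows with 100 disjoint intra-chromosome SNP pairs × 10 phenotype
  redraws for epistasis p-value uniformity (~4,000 p-values from disjoint
  pairs, keeping the KS test's independence assumption honest);
* parameter recovery: 50 replicates of $n=5{,}000$ cows × 30 SNPs with one
  planted architecture per phenotype vector. Recovery experiments use a
  residual SD of 10 and true-value PTAs: published effect sizes
  ($\delta \approx -2.55$, $\delta\delta \approx 5$) are resolvable at
  $n=5{,}000$ under that noise, whereas at the full DPR scale (SD 33) they
  require the original population size of ≈40,000 — the suite tests
  recovery and ranking, not power at full noise. Each architecture gets
  its own phenotype vector because a planted pairwise surface also carries
  marginal single-locus effects that would legitimately lead the other
  scans.

## Known limitations

* Dense pedigree algebra only: `build_A()`/`solve_mme()` are direct
  solves, intended for correction, oracle checks and simulation at desk
  scale (thousands of animals), not national evaluation.
* Two-locus decompositions only; no variance-component estimation of
  epistatic variance; no imputation or genotype QC beyond the MAF filter.
* The single-process pairwise scan enumerates pairs within a base-pair
  window; exhaustive inter-chromosome scans are supported but the cost is
  the user's choice.
* Heterozygote phase is never represented (a biallelic SNP's two
  heterozygote orderings are indistinguishable without phased data), so
  within-locus effects attribute allelic interaction to the genotype, not
  to a parental origin.
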