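---
title: "Heritability, association and genomic prediction in full-sib fish populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heritability, association and genomic prediction in full-sib fish populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`aquagp` implements the standard quantitative-genetic workflow for a
pedigreed, genotyped full-sib population: a single-random-effect animal
model fitted by REML under either a pedigree (**A**) or genomic (**G**)
relationship matrix, a two-step mixed-model association scan, SNP-effect
follow-up, and GBLUP/PBLUP breeding-value prediction assessed by
cross-validation across marker densities.  This vignette documents the
model, the numerical choices, and the design decisions behind the
package, including what the bundled simulator does and does not emulate.

## The animal model and its REML solver

Everything rests on

$$ y = Xb + Zu + e, \qquad u \sim N(0, K\sigma^2_a), \qquad
   e \sim N(0, I\sigma^2_e), $$

with one record per individual, fixed effects restricted to an intercept
and sex, and $K$ either the tabular-method numerator relationship matrix
or VanRaden's method-1 genomic matrix
$G = WW^\top / (2\sum_k p_k(1-p_k))$, where $W$ holds dosages centred by
twice the allele frequency.  Narrow-sense heritability is
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_e)$.

With a single random effect, REML reduces exactly to a one-dimensional
problem: `reml_animal()` eigendecomposes the kinship submatrix of the
phenotyped individuals once, rotates $y$ and $X$ into the eigenbasis
(where the covariance is diagonal), profiles out $\sigma^2_e$
analytically, and maximizes the restricted likelihood over
$\log(\sigma^2_a/\sigma^2_e)$ by Brent search on $[-15, 15]$
(`optimize()`, tolerance $10^{-9}$).  This is exact, deterministic and
fast ($n = 534$ fits take a fraction of a second), at the price of not
generalizing to several random effects — a deliberate trade for this
single-term model.  Iterative average-information algorithms used by
general-purpose mixed-model software solve the same likelihood; the tests
verify our optimum against a dense-inverse grid-search oracle instead of
another package.

Numerical edge cases are made explicit rather than silent:

* a solution at the edge of the ratio range (additive variance
  effectively zero) is flagged `boundary`, and its standard errors are
  reported as `NA` rather than from a curvature that does not exist;
* a kinship numerically proportional to the identity makes
  $(\sigma^2_a, \sigma^2_e)$ non-identifiable (a flat likelihood ridge);
  the fit warns and returns `NA` components instead of an arbitrary
  point on the ridge;
* standard errors come from the observed information (central-difference
  Hessian of the unprofiled restricted likelihood, relative step
  $10^{-4}$), and the $h^2$ standard error by the delta method;
* fixed-effect columns that are aliased are dropped with a message, as
  are records lacking a phenotype or a kinship entry.

## Relationship matrices

`a_matrix()` is the tabular recursion ($A_{ii} = 1 + A_{sd}/2$,
$A_{ij} = (A_{js}+A_{jd})/2$) over a topologically sorted pedigree;
unknown parents contribute zero, so inbreeding accumulates only through
known loops.  `g_matrix_vanraden()` uses observed sample allele
frequencies by default (founder-only frequencies can be supplied through
`freqs`), and mean-imputes missing dosages with $2p_k$ before centring —
neutral at the mean and standard for VanRaden G.  Because a marker-based
G is often singular (duplicated samples, fewer informative markers than
individuals), `invert_relationship()` first attempts a plain Cholesky
inverse and only then applies an escalating diagonal ridge (from
$10^{-6}$), verifying $\|M M^{-1} - I\|_\infty < 10^{-6}$ and recording
the ridge actually used.  Blending G towards A is intentionally out of
scope.

## The GRAMMAR scan and SNP effects

The association scan is the two-step family-based score test: the
polygenic model is fitted once (with G), the covariance
$\hat V = \hat\sigma^2_a K + \hat\sigma^2_e I$ is frozen, and each SNP's
centred dosage $g$ is tested with

$$ T = \frac{(g^\top P y)^2}{g^\top P g}, \qquad
   P = \hat V^{-1} - \hat V^{-1} X (X^\top \hat V^{-1} X)^{-1}
       X^\top \hat V^{-1}, $$

referred to $\chi^2_1$.  $P$ annihilates the fixed effects, so the test
is exactly invariant to shifting the phenotype, and monomorphic SNPs are
skipped with a recorded reason.  Significance uses Bonferroni $0.05/N$
with $N$ the number of tested SNPs genome-wide and the per-chromosome
count chromosome-wide; the genomic inflation factor
$\lambda = \mathrm{median}(T)/0.4549$ is attached to every scan.  The
calibration test in the acceptance suite verifies a type-I error of
0.04–0.06 at $\alpha = 0.05$ and $\lambda \approx 1$ over 20,000 truly
null markers.

Follow-up effects refit the genotype-class means jointly with sex by GLS
under $\hat V$: $\alpha = (\mathrm{AA}-\mathrm{BB})/2$ with AA the major
homozygote, $\delta = \mathrm{AB}-(\mathrm{AA}+\mathrm{BB})/2$, and
$\mathrm{PVE} = 2pq(\alpha+\delta(q-p))^2/V_A$ with $V_A$ defaulting to
the SNP-free fit's $\hat\sigma^2_a$ (the matrix used for $V_A$ is the
caller's choice and is recorded in the returned object).  When only two
genotype classes are observed, $\delta$ is undefined and the PVE drops
the dominance term; if the observed classes do not include both
homozygotes, $\alpha$ falls back to the per-allele-copy mean difference.

## Prediction and cross-validation

`predict()` on a fitted model solves Henderson's mixed-model equations at
$\lambda = \hat\sigma^2_e/\hat\sigma^2_a$ over *all* individuals in $K$,
so unphenotyped parents and masked validation animals get breeding values
through their relationships; masked records never enter the right-hand
side (asserted by a dedicated test).  `cross_validate()` partitions the
phenotyped individuals into $k$ non-overlapping folds (the first
$n \bmod k$ folds take the extra animal), masks each fold in turn, and
scores accuracy as $r(\mathrm{EBV}, y)/h$.  Decisions worth stating:

* $h$ defaults to the full-data fit's $\sqrt{\hat h^2}$ under the same
  relationship matrix as the predictor; variance components are reused
  from the full-data fit per fold (refitting per training set is
  available via `refit = TRUE` but changes little and costs an
  eigendecomposition per fold);
* in `density_sweep()` each method gets a *single* $h$: the pedigree
  fit's for PBLUP and the full-panel genomic fit's for every GBLUP
  density.  A sparse G attenuates its own heritability estimate (we
  measure $\hat h^2 \approx 0.31$ at 500 SNPs against a simulated 0.60),
  so dividing each density's $r$ by its own $\hat h$ would make accuracy
  appear to *fall* with density — an artefact of the denominator, not of
  prediction;
* fold partitions are drawn once per replicate and reused across methods
  and densities, so all comparisons are paired, and the whole table is
  reproducible from the seed;
* marker subsets for the sweep are nested by default (each density
  contains the smaller panels), trading a little independence for much
  lower comparison variance; independent draws are a flag away.

## The simulator: what it emulates, and what it does not

`sim_population()` gene-drops a single generation: founder haplotypes are
drawn per SNP from a founder allele-frequency sampler (uniform on
0.05–0.5 by default), gametes recombine with Poisson crossovers along 29
chromosomes of 1 Morgan, and each of 61 full-sib families is a unique
sire–dam pair drawn from 28 sires and 60 dams (dams are assigned
round-robin so every founder is used; family sizes are a minimum of six
plus a multinomial remainder totalling 534 offspring).  Parents are
genotyped but not phenotyped, matching a progeny-test design where traits
are measured on juveniles.  Offspring genotypes are Mendelian-consistent
by construction, which gives the QC module an exact zero baseline.

Two traits with a genetic and environmental correlation of 0.96 emulate
juvenile weight (g) and length (mm).  Under the default `"markers"`
architecture, 500 causal SNPs inside the panel receive bivariate Gaussian
effects; effect vectors and environmental deviations are rescaled so the
*realized* offspring variances equal $h^2\sigma^2_p$ and
$(1-h^2)\sigma^2_p$ exactly (weight: $345.6$ and $230.4$ with
$\sigma_p = 24$; length: $132.2$ and $127.0$ with $\sigma_p = 16.1$), the
usual practice in breeding-program simulators — it removes nuisance
variation in the simulated truth without touching the family structure.
An optional `qtl_frac` plants one large QTL for power studies, and the
`"infinitesimal"` architecture generates breeding values from the
pedigree instead (founder draws plus Mendelian-sampling terms), leaving
every genotyped marker exactly null — that is the mode the GRAMMAR
calibration test runs on, because under the marker architecture any
tested SNP in LD with a causal one is not a null hypothesis.

Two features of real data are deliberately *not* emulated, and they bound
what passing tests show:

* **No population-level linkage disequilibrium.**  Founder haplotypes are
  drawn locus-independently, so markers carry co-segregation information
  within families but no ancestral LD.  Genomic prediction in a real
  farmed population leans on both; in the simulator GBLUP's edge over
  PBLUP comes from Mendelian-sampling terms alone and is therefore
  smaller than in comparable real datasets, even though the qualitative
  structure — GBLUP above PBLUP at every replicate, accuracy rising from
  0.5K to 5K markers and flat beyond — is reproduced.  The acceptance
  suite computes and reports exactly these quantities.
* **No genotyping error or missingness.**  The QC paths for Mendelian
  errors, call rates and imputation are exercised by constructed
  corruption in the tests, not by the generator's defaults.

Reproducibility is bit-exact: the configuration seed drives founders,
gametes, sexes, effects and environmental draws in a fixed order, and
identical configurations give identical populations.

## Quality control and marker-density panels

`filter_panel()` applies the study-style filters in a fixed, audited
order — individuals with a Mendelian error rate above 1%, then SNPs by
the same rule, then SNPs with MAF below 0.05 recomputed on the surviving
individuals — with strict inequalities at the thresholds and a report
whose removal counts reconcile exactly with the survivor count.  The
"informative tests" denominator for Mendelian rates excludes the
double-heterozygote parental pair, which can never expose an error.
`density_reduction()` mirrors a low-density panel-design pipeline: keep
SNPs polymorphic in sample, one SNP per assembly contig (the first by
position), greedy left-to-right LD pruning within chromosomes in sliding
windows (default 100 SNPs, stride 50) removing the later SNP of any pair
with $r^2 > 0.65$ (ties on position keep the higher-MAF SNP), then MAF
$\ge 0.1$ and missingness $\le 0.03$.  The pruning algorithm itself is a
design choice — the windowed greedy scan is what mainstream GWAS toolkits
do — since only the threshold, not the algorithm, is standard.

## Problem sizes in the test suite

The matched design (534 offspring, 5,000 SNPs) is used for the recovery
checks: 20 simulated replicates for each heritability target (mean
$\hat h^2$ within 0.05 of the simulated 0.60 and 0.51), five replicates
of paired five-fold cross-validation for the GBLUP/PBLUP comparison, one
20,000-SNP population for the density plateau (0.5K vs 5K vs full), and
one 20,000-marker infinitesimal population for score-test calibration.
Unit tests run on miniature designs (tens of individuals, hundreds of
SNPs) with closed-form oracles: hand-recursed A matrices including an
inbred mating, the 3-sample VanRaden toy, dense-inverse REML likelihood
grids, and a GLS closed form for the MME solve.

## Known limitations

Single trait, single random effect: genetic correlations are simulated
but not estimated (no bivariate REML), and there is no dominance or
common-environment term.  The G-matrix is VanRaden method 1 only, with
ridge regularization rather than A-blending.  PED/MAP is the only
genotype format (no binary BED, no VCF).  Accuracy statements transfer to
real populations only to the extent the generator's assumptions hold —
in particular the absence of ancestral LD discussed above.
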