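---
title: "Comparative genomic landscapes: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genomic landscapes: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landgen)
```

## The scientific problem

When many related species are resequenced against a common reference, their
per-window summary statistics — nucleotide diversity ($\pi$), Watterson's
$\theta$, Tajima's $D$, relative differentiation ($F_{ST}$), absolute
divergence ($d_{XY}$) — form genomic *landscapes*. Across species that share
a recombination and gene-density landscape, linked selection produces
correlated landscapes: the same windows are depleted of diversity in every
species. Gene flow between non-sister species perturbs these landscapes
locally, and haplotype-based selection scans plus deleterious-allele
accounting ask whether the introgressed material was adaptive or costly.
`landgen` implements this full analysis layer — windowed statistics,
ABBA-BABA-family introgression inference with a calibrated region caller,
selection scans, genetic burden, and the landscape-correlation machinery —
together with a multispecies coalescent simulator that provides ground
truth for every step.

## The simulator and what it emulates

`simulate_dataset()` draws **one non-recombining coalescent genealogy per
window** under a rooted, ultrametric species tree with branch lengths in
generations: within each population lineages coalesce at rate
$\binom{k}{2}/2N_e$, populations merge at the split times, and mutations
fall on branches as a Poisson process with rate $\mu \lambda_w L$ under the
infinite-sites model. An admixture pulse (donor, recipient, time $t$,
proportion $\gamma$) is realized backward in time by moving each
recipient-lineage to the donor population with probability $\gamma$ at
time $t$, in a designated random subset of windows; the subset is recorded
as ground truth.

The per-window scaling $\lambda_w = \exp(a\log\rho_w - b\,g_w)$, normalized
to mean 1, ties the mutation supply to a shared recombination-rate track
$\rho_w$ and gene-density track $g_w$. This is this package's own device
for inducing a *shared, heterogeneous* diversity landscape — the
statistical structure that linked selection produces in real genomes — not
a mechanistic model of selection. Consequences to keep in mind when
reading test results:

* window-to-window diversity correlations between species arise by
  construction, so the landscape-correlation suite demonstrates that the
  *machinery* recovers a known shared structure, not that real data would
  show one;
* because $\lambda_w$ scales mutation rather than local $N_e$, $F_{ST}$ is
  essentially independent of $\lambda_w$; $F_{ST}$–$d_{XY}$ coupling in the
  simulations comes from genealogical noise and admixture, which is enough
  to recover the direction of the divergence-time dynamics but not their
  real-data magnitudes;
* one genealogy per window means whole windows are concordant or
  discordant as a block. Incomplete lineage sorting therefore produces
  *window-scale* false introgression signal, the hardest case for
  window-based callers; there is no within-window haplotype structure, so
  nSL/H12 operate on ILS-scale variation only.

Defaults are chosen to resemble a long-lived outcrossing tree genus:
diploid $N_e = 10^4$, $\mu$ set so that $4N_e\mu = 0.005$ per site
(within the 0.005–0.010 range typical of such systems), 10 kb windows,
six diploids per species. REF/ALT labels are randomized at export so that
downstream outgroup polarization is genuinely exercised; the outgroup
contributes one diploid.

Deleterious and fourfold-degenerate site classes are assigned by
independent draws over polymorphic sites. Sites flagged deleterious
receive synthetic PROVEAN/SIFT scores satisfying the classifier rule
(PROVEAN $\le -2.5$ and SIFT $\ge 0.05$); an equal fraction of tolerant
nonsynonymous sites receives scores that fail exactly one conjunct, so the
classifier is exercised on both sides of both thresholds.

## Statistics

**Diversity.** Per site with $n$ non-missing alleles and derived frequency
$p$, the pairwise-difference contribution is $2p(1-p)\,n/(n-1)$; window
$\pi$ divides the sum by the accessible window length. $\theta_W = S/(a_1
L)$ with $a_1 = \sum_{i<n} 1/i$ evaluated at the window's median $n$, and
Tajima's $D$ uses the standard 1989 constants. Sites with fewer than four
non-missing alleles are excluded, and windows below a configurable minimum
of segregating sites (default 10) report `NA` rather than zero. These are
genotype-based estimators: calling error and genotype likelihoods are out
of scope because the simulator produces exact genotypes.

**Divergence.** $d_{XY}$ is the mean of $p_1(1-p_2) + p_2(1-p_1)$ over
used sites divided by accessible length. $F_{ST}$ is a ratio of sums
across sites; the default is the Hudson estimator in the Bhatia ratio-of-
averages form, with Weir & Cockerham (1984) available by flag. Net
divergence $d_a = d_{XY} - \bar\pi$ serves as the divergence-time proxy.
`mutation_rate()` implements $\mu = d/2T$.

**Introgression.** Trios $(((P1,P2),P3),O)$ are enumerated from the
species tree; Patterson's $D$ uses the frequency formulation
($ABBA = (1-p_1)p_2p_3(1-p_O)$ etc.), with significance from a delete-one
block jackknife over contiguous genomic blocks and BH-FDR across trios.
The f4-ratio splits P3's haplotypes into random halves (seeded) and forms
$f_4(P1,P2;P3a,O)/f_4(P1,P3b;P3a,O)$; the implementation orients both
$f_4$ terms so that the denominator — the shared P3a/P3b drift — is
positive in expectation, which makes the "denominator $\le 0$ → absent"
guard meaningful. The f-branch statistic takes, for branch $b$ and donor
$C$, the median over sister lineages $A$ of the minimum over descendants
$B$ of $b$ of the f4-ratio — the published tree-aware summary that
de-correlates trio results. Windowed $f_d$ (dynamic-donor denominator) and
$f_{dM}$ (symmetric variant, positive for P2–P3 flow) follow the published
per-site denominators, with a configurable minimum of informative sites
per window (default 10).

**Region calling.** The top-X% caller is calibrated by the f4-ratio:
$X = 100 \cdot f_4\mbox{-ratio}$ percent of the fdM-scored windows (the
multiplier is configurable), ties at the cutoff admitted in position
order. The genomic background for a species pair excludes windows called
in *any* trio involving either species. Enrichment of gene labels in
called regions uses the exact hypergeometric upper tail.

**Selection and burden.** H12 is the haplotype-spectrum statistic
$(f_1+f_2)^2 + \sum_{i\ge3} f_i^2$ on SNPs with MAF > 0.05. nSL measures,
for each focal SNP, mean identical-tract lengths (in SNPs, inclusive of
the focal SNP) among derived-carrying versus ancestral-carrying haplotype
pairs, $\ln(SL_A/SL_D)$, standardized within derived-allele-frequency bins
(50 by default). Burden counts derived alleles at deleterious versus
fourfold sites per genome under additive (het = 1, hom = 2) and recessive
(hom only) models, with the same model applied to numerator and
denominator; region-versus-background contrasts use the two-sided
Wilcoxon-Mann-Whitney test.

**Landscape machinery.** `summarize_pca()` z-scores each unit's window
vector (rank normalization available) and fixes the PC1 sign so the mean
loading is positive. The Mantel statistic is the Pearson correlation of
upper-triangle entries with a one-sided label-permutation p-value;
per-window tree concordance is the Mantel r (without permutation) between
window and genome distance matrices. The autocorrelation statistic — a test
for clustering of similar windows along chromosomes — is the mean
lag-1..5 Spearman
autocorrelation per chromosome, averaged across chromosomes, with
chromosome-stratified permutations; this choice is scale-free and
insensitive to the marginal distribution of the statistic. Contrasts
assign every species pair to the internal node that is its MRCA, giving
$n_{tips} - 1$ contrasts whose member pairs partition all pairs;
per-window contrast values are unweighted means over member pairs.
`dynamics()` regresses per-contrast correlation coefficients on $d_a$.

## Numerical choices and degenerate inputs

* Windows are 0-based half-open internally (BED convention); VCF positions
  are converted on read. Terminal partial windows are kept and flagged.
* Site mean depth (filter rule 3) is the mean of per-sample DP over
  non-missing genotypes; the missing-rate rule is applied after
  genotype-level filters (both switchable).
* Monomorphic windows report $\pi = \theta_W = 0$ with Tajima's $D$
  undefined; zero-variance inputs to Spearman, Mantel, PCA and the
  autocorrelation test return `NA` with a warning rather than fabricating
  a value.
* The deleterious rule is implemented exactly as printed (SIFT $\ge
  0.05$); because the conventional SIFT reading flags scores *below* the
  threshold, a `sift_direction = "conventional"` switch is provided.
* The block jackknife requires at least 20 non-empty blocks and errors
  otherwise; the delete-one variance uses equal block weights. The Z test
  is reliable when blocks carry reasonably dense ABBA/BABA information —
  the calibration suite therefore simulates a recent radiation (splits at
  $N_e$–$2N_e$ generations) where incomplete lineage sorting supplies
  informative sites densely. On sparse deep-split data the Z distribution
  is heavy-tailed and anticonservative, which is a property of the
  jackknife on near-empty blocks, not of this implementation.
* Trio de-duplication keeps the maximum-D trio per unordered P2–P3 pair,
  breaking ties by smaller p then lexicographic P1.

## Calibration results and known limitations

The test suite (and `scripts/acceptance.R`) recomputes, at desk scale:
the exact $\mu = d/2T$ worked example; oracle equivalence of every core
statistic against brute-force enumeration; the type-I error of the
jackknife D test (nominal 5% within the exact binomial 99% interval over
200 admixture-free replicates) and of the autocorrelation permutation
test; recovery of a $\gamma = 0.2$ pulse by the f4-ratio within $\pm0.05$;
and the qualitative comparative structure (positive between-species $\pi$
correlations, all-positive PC1-$\pi$ loadings, $F_{ST}$–$d_{XY}$
correlation increasing with $d_a$).

Two honest negatives are worth recording. First, mean window Tajima's $D$
on neutral constant-size simulations is slightly but systematically
negative (about $-0.1$ at $\theta = 50$ per window, $n = 20$ haplotypes;
an independent coalescent simulator reproduces the same value): Tajima's
normalization
leaves a finite-sample negative expectation on single-genealogy windows,
so a "within 3 SE of 0" check fails at 2,000 windows for any faithful
simulator under these conditions. Second, the fdM region caller's *recall*
is bounded by its own calibration: with a pulse confined to 10% of windows
at $\gamma = 0.3$, the genome-wide f4-ratio is $\approx 0.03$, so the
top-X% rule calls only $\approx 3\%$ of windows and recall cannot
materially exceed 0.3 even though precision is high. Both behaviours are
reported as-is by the acceptance suite.

The simulator does not model intra-window recombination, sequencing
error, unphased genotypes, or forward selection; passing tests
demonstrate correctness of the estimators and the internal consistency of
the pipeline under the stated generative model, not the realism of that
model for any particular empirical system.

## Problem sizes

Simulation-based checks use 40–200 windows of 10–20 kb, three to six
diploids per species and up to six ingroup species; the Tajima's-D
calibration uses 2,000 windows. These sizes were chosen so each
statistical procedure operates where its assumptions hold (enough
jackknife blocks, enough informative sites per window) while the whole
suite stays desk-scale.
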