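---
title: "Modelling and detecting a suppressor sweep against male-killing Wolbachia"
author: "mksweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and detecting a suppressor sweep against male-killing Wolbachia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mksweep)
```

## The system

A maternally transmitted *Wolbachia* strain kills the male embryos of
infected *Hypolimnas bolina* females. Where the symbiont is near
fixation the population sex ratio becomes extremely female-biased, and
Fisherian selection on any host variant that restores male survival is
correspondingly extreme. The host carries such a variant: a dominant,
zygotically acting suppressor allele *S*. Males rescued by the
suppressor remain infected and express cytoplasmic incompatibility (CI):
offspring of *uninfected* mothers sired by infected fathers die, which
keeps the symbiont at high prevalence even after male killing is
neutralized.

`mksweep` implements (i) a deterministic recursion for the spread of the
suppressor together with one or two linked neutral loci, (ii) drift null
models used to reject drift as an explanation for observed
allele-frequency change and allele loss, (iii) the sweep-detection
statistics applied to pre/post-sweep population samples, (iv) the
linkage-cross logic that localizes the suppressor, and (v) a seeded
synthetic-data generator producing every input the pipeline consumes.

## The deterministic sweep model

### State and recursion

The model tracks, separately for females and males, a frequency
distribution over ordered pairs of gametic haplotypes crossed with
infection status. Haplotypes combine the suppressor locus (*S*/*s*)
with one neutral locus (*A*/*a*) or two (*A*/*a* × *B*/*b*); with
infection this gives the familiar 18-genotype bookkeeping in the
two-locus case. One generation consists of:

1. **Gamete formation.** Females transmit their two haplotypes unchanged
   (no crossing over in female Lepidoptera). Male meiosis recombines
   with probability `rec_fractions[i]` in each adjacent interval,
   crossovers independent across intervals (no interference; the data
   the package emulates cannot resolve interference, and the Haldane map
   function used throughout makes the same assumption).
2. **Random union** of female and male gametes. Offspring inherit the
   mother's infection status.
3. **CI mortality**: a fraction `ci_level` (default 1, complete CI) of
   offspring of uninfected mothers and infected fathers die.
4. **Male killing**: infected male zygotes survive with probability
   `survival = c(ss = 0, Ss = 0.5, SS = 1)` — a fully penetrant male
   killer with partially dominant rescue, the default mirroring the
   cross data in which about 60 *Ss* sons survived against 150 expected
   (`survival_estimate(60, n_expected = 150)` = 0.4, and the model
   rounds this to one half). Females and uninfected males are
   untouched.
5. **Renormalization** within each sex; the surviving masses give the
   adult sex ratio.

Population-wide allele frequencies weight the sexes equally, since each
sex contributes half of the genes to the next generation. Linkage
disequilibrium (`ld_metrics()`) is computed on the adult chromosome pool
with the same equal weighting; both the covariance `D` and the
correlation-style `r` are reported, since the magnitude of LD is not
standardized across allele frequencies.

### Initial conditions and the immigrant fraction

The founding state is a resident population fixed for *s* (neutral loci
at their resident frequencies, in linkage equilibrium), with 99% of
females infected, into which a single infected *SS* male immigrates
carrying the complete immigrant haplotype. A deterministic model cannot
hold "a single male"; it needs the immigrant's share of the generation-0
male gamete pool. That share, `immigrant_fraction`, defaults to **0.1**:

* With ~100 females per male before the sweep, adult males are rare, and
  one immigrant male plausibly constitutes a tenth of the male pool.
* At 0.1 the model reproduces the scenario's own first-generation
  landmarks: the adult-male *S* frequency approaches one half from below
  (0.423; nearly all surviving sons are *Ss* heterozygotes, the bound
  being attained exactly as prevalence tends to 1), and the immigrant
  chromosome rises to ~0.236, approaching one quarter of the gene pool.

Sensitivity: the qualitative outcome is insensitive to this choice — the
suppressor exceeds 95% frequency by generation 15 for
`immigrant_fraction` anywhere in [0.005, 0.05] and beyond (the test
suite checks 0.005, 0.01, 0.05 and the default) — but the *breadth* of
the hitchhiking effect is not. The first generation, in which almost
every male in the mating pool is heterozygous for the immigrant
chromosome, does most of the dragging of loosely linked variation, so
the equilibrium frequency reached by a fully associated neutral allele
at recombination fraction 0.5 moves from 0.22 (at 0.01) through 0.35
(at 0.1) to 0.41 (at 0.2). The default is the value consistent with
the first-generation landmarks above; it is a single configurable
parameter, not a fitted quantity.

```{r equilibrium}
eq <- equilibrium_profile(sweep_params(), c(0, 0.01, 0.05, 0.1, 0.5))
eq
```

Equilibrium is declared when every tracked frequency changes by less
than `tol = 1e-10` between generations (cap `max_gen = 5000`,
non-convergence flagged, never silently truncated). The profile is
monotone non-increasing in r, a property the test suite asserts across a
grid.

## Drift null models

`wf_sd_bound()` evaluates k standard deviations of the neutral
Wright–Fisher frequency change, k·sqrt(p(1−p)(1−exp(−t/2N))) — the
magnitude of change drift can plausibly produce.

`kimura_loss_prob()` gives the diffusion-approximation probability that
an allele at frequency p is absent by generation t,

f(0,t) = q + Σ_{i≥1} (2i+1) p q (−1)^i ₂F₁(1−i, i+2; 2; q) exp(−i(i+1)t/4N).

Numerics: the terminating hypergeometric factors are evaluated through
the Jacobi-polynomial identity P^{(1,1)}_{i−1}(1−2q) = i·₂F₁(1−i, i+2;
2; q) with the stable three-term recurrence — direct summation of the
hypergeometric series cancels catastrophically for small t/N — and the
series is truncated when a term falls below 1e-12 (cap 10,000 terms,
non-convergence is an error).

`wf_markov_loss_prob()` is the exact finite-population counterpart: the
absorption probability at zero copies after t binomial transitions on
the 2N+1 copy-number states, started from round(2N·p₀) copies (the
rounding matters: 0.22 × 360 = 79.2). The dense transition matrix is
capped at N = 2000 by default; beyond that the error message points to
the diffusion. The two methods agree to ~0.005 absolute in the
parameter region of interest; the residual gap (0.0053 at N = 100,
0.0030 at N = 180 for p₀ = 0.22, t = 40) is genuine discreteness error
of the diffusion, shrinking with N.

```{r kimura}
kimura_loss_prob(0.22, t = 40, N = 180)
wf_markov_loss_prob(0.22, t = 40, N = 180)
```

`ne_for_loss_prob()` inverts the loss probability in N by bracketed root
search (loss is monotone decreasing in N). Interfaces count
generations; `years_to_generations()` applies the organism's ~10
generations per year.

## Sweep detection

All tests operate on allele-copy counts of phased samples
(`hap_sample()`); individuals missing at a locus are dropped locus-wise.

* **Heterogeneity** (`g_heterogeneity()`): G = 2 Σ obs·ln(obs/exp) on
  the 2 × k table of the two samples. The default p-value is
  Monte-Carlo under fixed margins (Patefield tables via `r2dtable`,
  explicit seed; 1e5 tables by default in `g_heterogeneity`, 1e4 inside
  `sweep_report`), with the asymptotic chi-square value also reported;
  the Monte-Carlo route is checked against exhaustive enumeration on
  small tables in the test suite.
* **Swept alleles** (`identify_swept_alleles()`): during a sweep one
  allele rises while the others decline proportionally, so the swept
  allele carries the largest *adjusted standardized residual*
  ((o−e)/sqrt(e(1−row/n)(1−col/n))). The procedure picks, among alleles
  whose frequency increased, the largest residual; removes it; retests;
  and stops at homogeneity or when fewer than three alleles remain (with
  two alleles each contributes equally and the question is undefined).
* **F_ST** (`fst()`): a haploid-count variance-components estimator of
  Weir–Cockerham type (one-way ANOVA of allele indicators, components
  summed over alleles), with Nei's G_ST emitted alongside and a
  permutation p-value from shuffling allele copies between samples.
  Being unbiased, the estimator is mildly negative for near-identical
  samples; that is expected behaviour, not an error.
* **Diversity** (`effective_allele_number()`, `sequence_diversity()`):
  A_E = 1/Σp²; per-site π, Watterson's θ, S, haplotype diversity with
  the n/(n−1) correction, and Tajima's D. Alignment columns containing
  a gap in any sequence are removed before any site is counted, so indel
  variation never enters the statistics.
* **LD** (`ld_significance()`): a G test of independence on the
  two-locus haplotype table, p by permutation of one locus's alleles.
  Only significance is reported — the magnitude of LD depends on the
  allele-frequency distributions and is not comparable across pairs.
* **Multiple testing** (`sequential_bonferroni()`): Holm's step-down
  procedure, the standard reading of "sequential Bonferroni".

`sweep_report()` runs everything over a locus panel, flags alleles
present only in the later sample as immigration candidates, and gates
swept-allele identification on the Holm-corrected heterogeneity
decision. Phase is taken as given (the field pipeline reconstructed
haplotypes externally); `read_iupac_genotypes()` includes a naive
counting-based phaser that resolves only unambiguous genotypes and
leaves the rest missing with a warning, never guessing silently.

## Linkage analysis

Female-informative families (heterozygous *Ss* mother) exploit
achiasmatic female meiosis: a marker linked to the suppressor is present
in *every* surviving son, and the chance of that pattern in n sons under
no linkage is 0.5ⁿ (`cosegregation_test()`; daughters are checked for
1:1 segregation as a sanity report). Male-informative families
(heterozygous father) recombine: `localize_region()` excludes every
marker at which at least one surviving son lacks the informative
parent's allele, retains the longest zero-recombinant run, and bounds
the candidate region by the nearest flanking markers with recombinants —
a marker with zero recombinants is never excluded. Marker order is
taken as input (`linkage_map()`); `estimate_map()` estimates
adjacent-interval recombination fractions from the daughters (sons are
survival-selected around the suppressor and would bias intervals near
it) and converts them with the Haldane function d = −50·ln(1−2r).
Phase of the informative parent is assumed known from the grandparental
cross; phase ambiguity is an input error, not something the package
infers.

## The synthetic-data generator

`make_panel()` builds the study design: 12 linked markers spanning 41 cM
plus 9 unlinked markers on separate linkage groups. Defaults emulate
the mapped chromosome: marker positions 0, 4, 8, 11, 11.5, 12, 17, 22,
27, 32, 36.5, 41 cM with the suppressor at 11.5 cM inside the
co-segregating cluster; pre-sweep allele frequencies drawn from a
broken-stick distribution (the field loci carried 2–8 alleles of very
uneven frequency; broken stick reproduces that shape with one knob);
four linked markers (A, F, G, I — the field configuration: three genomic
locations over ~17 cM, one inside the cluster) carry immigrant alleles
novel to the resident population, the others have the immigrant
haplotype tagging an existing resident allele chosen with probability
proportional to its frequency. Every allele receives a 500-nt sequence
template segregating at 8 SNP positions so π and Tajima's D can be
computed downstream.

`simulate_sweep_samples()` evolves each linked marker against the
suppressor at the recombination fraction implied by its map distance
(inverse Haldane), and draws n = 48 diploids per time point. Within an
individual, the two chromosomes' suppressor alleles come from the
model's adult diplotype distribution; each chromosome's marker alleles
are then generated as a Markov chain outward from the suppressor, the
transition between consecutive markers taken from a three-locus model
run (suppressor + marker pair). This preserves not only each marker's
marginal hitchhiking but the *local* LD between linked markers — which
first rises and then decays by recombination, outliving the association
with the suppressor itself — exactly as the recursion dictates; markers
on opposite sides of the suppressor are associated through the
suppressor only, a second-order approximation. The pre-sweep sample is
the resident population at linkage equilibrium (the immigrant has not
yet arrived). Default sample times are generations 0 and 25: the sweep
completes in ~10–15 generations and the post-sweep collection follows
within about a year (~10 generations/year), late enough for the
suppressor to have fixed and global LD to have decayed, early enough
that local LD between tightly linked loci persists. A later,
2010-style sample is simply a third entry in `sample_times`.

`simulate_cross_family()` generates informative crosses: whole-haplotype
transmission from heterozygous mothers, recombinant gametes from
heterozygous fathers with the suppressor inserted into the crossover
chain as a pseudo-marker at its own map position (so strand switches
across it carry their correct Haldane probability), and son survival at
the empirical 40% only when the suppressor is transmitted.

### What the generator does and does not emulate

It emulates: the marker geometry, multi-allelic frequency profiles,
novel immigrant alleles, hitchhiking at map-derived recombination
distances, local LD structure, binomial sampling noise at n = 48, and
survival-biased son genotypes in crosses. It does **not** emulate:
genetic drift during the sweep (the underlying model is deterministic),
spatial population structure, costs of the suppressor, purifying
selection against introgressed material, genotyping error, or missing
data beyond what the user injects. Passing the package's
parameter-recovery tests therefore shows that the pipeline detects the
signal the deterministic panmictic model predicts at field sample sizes;
it does not show robustness to drift, spatial spread or cost, which in
the field data all attenuated the sweep's footprint relative to this
model's predictions.

## Problem sizes used by the test suite

The suite runs the model at its natural sizes (they are cheap: a
two-locus generation is a handful of small matrix products).
Stochastic calibrations use: 100 seeded replicates for end-to-end
parameter recovery (per replicate: a fresh panel, samples of 48
diploids at generations 0 and 25, F_ST ranking and A_E comparison over
all 21 loci); 100 replicates of a 21-locus no-sweep null for the
family-wise error of Holm-corrected Monte-Carlo G tests (2,000 tables
each); and 10 replicates (660 locus pairs, 500 permutations each) for
the LD null-calibration and post-sweep association checks. Recovery is
scored as: a suppressor-proximal marker (within 5 cM) among the top
three F_ST ranks, proximal mean F_ST above the non-proximal linked mean,
and a proximal A_E reduction — a group-level reading; the single top
rank among co-swept novel-allele loci is decided largely by their random
pre-sweep allele profiles rather than by proximity, and is accordingly
not a reliable recovery signal at these sample sizes.

## Known limitations

* The deterministic model has no drift, so it cannot by itself explain
  post-sweep *loss* of introgressed variants; the drift module exists
  precisely to quantify that null separately.
* Multi-marker samples approximate the joint chromosome distribution by
  a Markov chain given the suppressor allele; three-point and
  cross-side associations beyond that structure are not represented.
* The diffusion loss probability inherits O(1/N) discreteness error
  (~0.005 at N ≈ 100 for the parameters of interest); where exactness
  matters at small N, use the Markov chain.
* `read_iupac_genotypes()` resolves only unambiguous diploid genotypes;
  proper statistical haplotype reconstruction is out of scope.
* Marker ordering is taken as given; the package estimates distances for
  a fixed order only.
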