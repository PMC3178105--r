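---
title: "Binary-trait linkage mapping in an F2 intercross: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binary-trait linkage mapping in an F2 intercross: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binqtl)
```

## The problem

Zebrafish have no heteromorphic sex chromosomes, and sex in a laboratory
cross behaves as a complex binary trait: several loci of partial effect,
plus environment, decide whether a fish develops as male or female.
`binqtl` implements the linkage-analysis machinery needed to map such a
trait in an F2 intercross — two divergent grandparental strains, one F1
brother–sister pair, and a large F2 sibship in which each locus segregates
AA : AB : BB at 1:2:1.  The package covers the whole analysis path:
building and checking a genetic map from two-point recombination
fractions, detecting suspect genotypes with a hidden-Markov error model,
scanning the genome with binary-trait interval mapping, calibrating
genome-wide significance by permutation, and comparing the genetic map
against a physical (assembly) map.

Because the motivating data set cannot be redistributed, the package
ships a calibrated simulator (`sim_cross()`) that reproduces the
*structure* of such a cross — 520 F2 progeny (1040 informative meioses),
25 chromosomes, ~1000 mapped loci at 2.0 cM mean spacing, roughly 1%
missing genotypes, 0.05% genotype errors, and 53 fish of unknown sex —
so that every stage of the pipeline is testable end to end.

## Genotype model: the F2 hidden Markov chain

All genotype-based computations share one model.  The true genotypes of
one individual along a chromosome form a Markov chain over {AA, AB, BB}
with stationary distribution (¼, ½, ¼); between adjacent loci at
recombination fraction $r$ each of the two gametes switches grandparental
origin independently with probability $r$, giving the transition matrix

$$
T(r)=\begin{pmatrix}
(1-r)^2 & 2r(1-r) & r^2\\
r(1-r) & (1-r)^2+r^2 & r(1-r)\\
r^2 & 2r(1-r) & (1-r)^2
\end{pmatrix}.
$$

Observed codes equal the true genotype with probability $1-\varepsilon$
and each of the other two codes with probability $\varepsilon/2$;
missing observations are uninformative.  Forward–backward recursion
gives genotype posteriors at any grid of positions (`genoprob()`), the
total likelihood of an individual's chromosome, and leave-one-out
posteriors used for error detection.

Two map functions appear, deliberately in different roles.  Map
*positions* are Kosambi centimorgans
($d = 25\,\ln\frac{1+2r}{1-2r}$), which is how such maps are
conventionally reported, and the simulator draws crossovers with
Kosambi-inverse interval probabilities.  HMM *transitions* use the
Haldane inverse ($r = (1-e^{-d/50})/2$) of the map distances, because
only Haldane distances compose consistently under a Markov (no
interference) chain.  This mixed convention is standard practice; at the
2 cM spacing of the default map the numerical difference is far below
sampling noise.

## Two-point estimation and map construction

`est_rf()` maximizes the F2 two-point likelihood by EM.  All cells of
the 3×3 joint genotype table carry a known number of recombinant gametes
except the double heterozygote, which mixes 0- and 2-recombinant
configurations; the E-step resolves it with
$E[\text{rec}\mid AB,AB] = 2r^2/((1-r)^2+r^2)$.  The EM starts at
$r = 0.3$, iterates to $10^{-8}$ on $r$ (at most 1000 iterations), and
clamps $r$ to $[10^{-6}, 0.5-10^{-6}]$; the linkage LOD is
$\log_{10} L(\hat r) - \log_{10} L(0.5)$.  The tests verify the EM
against a brute-force likelihood grid (step $10^{-4}$).

Map construction follows the classical recipe:

* **Linkage groups** (`group_markers()`): single-linkage clustering,
  joining marker pairs whose linkage test has $P < 10^{-6}$.  The
  P-value comes from a $\chi^2_1$ approximation on $2\ln(10)\,\mathrm{LOD}$,
  documented as an approximation.
* **Collapsing** (`collapse_identical()`): markers with *exactly* the
  same observed genotype vector (including the missingness pattern)
  carry no mutual recombination information and merge into one locus
  listing all names.  Identity is strict by design — zero observed
  recombinants with different missingness is co-location evidence, not
  identity — because collapsing is irreversible downstream.
* **Ordering** (`order_loci()`): de-novo ordering is a seriation
  heuristic — greedy chaining on smallest $\hat r$, then a ripple pass
  over windows of three accepted on the multipoint HMM likelihood with
  adjacent $\hat r$ re-estimated per candidate order.  Adjacent pairs
  whose swap changes the multipoint $\log_{10}$ likelihood by less than
  0.5 are flagged as order ambiguities rather than silently fixed,
  mirroring how real dense maps contain locally unresolvable inversions.
* **Insertion** (`insert_marker()`): a candidate position is scored by a
  multipoint profile assembled from two-point likelihoods — the sum over
  the chromosome's framework loci of the pair LOD at the recombination
  fraction implied by the map distance.  Co-location at a locus is only
  a candidate when the pair table shows no visible recombinant.  The
  support LOD compares the best placement with the best alternative
  sharing no flanking locus (within a shared-flank neighborhood the
  profile is flat by construction, so that comparison would be
  meaningless), and placements with support below 7 are reported as
  unplaced.

## Genotype error detection

`calc_error_lod()` computes, for every observed genotype at an internal
map locus, the classical error LOD: the $\log_{10}$ likelihood ratio
that the observation arose from a genotyping error versus being correct,
given everything else on that individual's chromosome,

$$
\mathrm{LOD}_{\mathrm{err}}(i,m) =
\log_{10}\frac{P(o_m \mid o_{-m}, \text{error})}
              {P(o_m \mid o_{-m}, \text{correct})},
$$

with the error spread uniformly over the two wrong codes and
$P(\cdot\mid o_{-m})$ the leave-one-out HMM posterior.  This is the
quantity that flags tight apparent double crossovers.  Defaults are
$\varepsilon = 10^{-4}$ and a flag cutoff of 4.0.  Two properties are
worth stating plainly:

* Detectability depends on local map density.  An isolated
  double-crossover genotype between flanks 1 cM away scores about 3.4;
  the cutoff of 4 is only reached below ~0.6 cM spacing.  On maps of
  SNP-scale density (0.1 cM resolution, many co-segregating loci) the
  same event scores well above 4.  The dense-map tests therefore use
  0.25 cM spacing, where essentially every injected isolated error is
  flagged and the flagged fraction tracks the injected rate.
* Flags are advisory.  The pipeline never drops flagged genotypes; the
  error-tolerant emission model already discounts them wherever the HMM
  is used.

## Binary-trait interval mapping

`scan_binary()` fits, at every grid position, the three genotype-class
penetrances $\pi_g = P(\text{male}\mid g)$ by EM over the genotype
posterior mixture: each individual's likelihood is
$\sum_g q_{ig}\,\pi_g^{y_i}(1-\pi_g)^{1-y_i}$, the E-step weights class
membership by posterior × Bernoulli likelihood, and the M-step sets
$\pi_g$ to the weighted trait mean.  The LOD compares this against a
single Bernoulli at the overall trait mean.  Unknown-sex individuals are
excluded from the scan, permutations, variance estimates and tables —
they carry no trait information.  Numerical choices: penetrances clamped
to $[10^{-6}, 1-10^{-6}]$, EM tolerance $10^{-6}$ (max 200 iterations),
monotonicity of the EM log-likelihood asserted at run time, scan step
1 cM by default (0 = marker positions only), peak ties broken leftmost.
At a fully typed marker with no missing data the EM solution equals the
closed-form 3×2-table binomial LOD, which the tests exploit as an exact
oracle.  As a sanity anchor: with 219 females and 248 males, a fully
penetrant single locus would give
$-[219\log_{10}\frac{219}{467} + 248\log_{10}\frac{248}{467}] \approx 140.2$
— the scale against which the modest LODs of a complex trait should be
read.

Genome-wide significance comes from `perm_threshold()`: phenotype labels
are permuted among phenotyped individuals, the genome rescanned, and the
$(1-\alpha)$ quantile of the per-permutation maximum LOD taken as the
threshold.  The number of permutations trades precision for time; the
package default is 1000, analyses at the 10,000 scale are a parameter
away, and the calibration tests use 200 per cross.  With $n_p$
permutations the empirical $(1-\alpha)$ quantile is exceeded by a fresh
null maximum with probability slightly above $\alpha$ (about
$(n_p(1-\alpha)+1)/(n_p+1)$), which is why small-$n_p$ thresholds run
slightly anticonservative; this is a property of the estimator, not a
bug.

Support intervals (`lod_drop_interval()`) are the widest contiguous
region around the peak within `drop` (default 1.5) LOD of it, endpoints
linearly interpolated.  Variance explained regresses the 0/1 trait on
posterior-expected additive dosage ($P(BB)-P(AA)$) and dominance
($P(AB)$) per locus — jointly for several loci — reporting
$100(1-\mathrm{RSS}/\mathrm{TSS})$; conditioning on posterior dosages
rather than observed genotypes is a documented choice that keeps
individuals with missing genotypes in the estimate.  The two-locus
analysis (`two_locus_table()`) tabulates the trait over the 3×3 classes
at the nearest well-typed markers with Wilson 95% intervals (Wilson
because classes at the $p=1$ boundary occur in practice), and tests
epistasis as $\log_{10}L(\text{9 free penetrances}) -
\log_{10}L(\text{additive+dominance per locus, ML on the probability
scale})$.

## The synthetic cross: what it emulates, and what it does not

`sim_cross()` generates gametes as independent per-chromosome Markov
chains with Kosambi-inverse interval recombination probabilities, then
applies a two-locus penetrance model, unknown-sex masking (independent
of genotype), missingness (1% default) and genotype corruption
(0.05% default, to a uniformly random wrong code).  The default map has
25 chromosomes × 40 loci at 2 cM; `reduced_map()` (4 chromosomes) is
the desk-scale stand-in used by most tests.

The default penetrance model places a recessive-male locus on
chromosome 5 (54 cM) and an additive locus on chromosome 16 (32 cM) and
uses the table

```{r}
default_penetrance()$table
```

whose three constants are the unique solution of three anchors: the
doubly male-dosed class is always male, the doubly female-dosed class is
77% female, and the marginal male fraction is 248/467.  Enumerating the
nine classes against their (¼,½,¼)⊗(¼,½,¼) F2 weights gives
variance fractions of 0.085 (locus 1), 0.094 (locus 2) and 0.179
jointly — the recovery targets for the scan and variance estimators.
The table is additive by construction, so the epistasis LOD has no
signal to find — which is itself a test.

Deliberate simplifications: no crossover interference (Markov
consistency is what makes the HMM exact on simulated data), no
sex-specific recombination, no segregation distortion, genotype errors
independent and uniform, unknown sex independent of genotype, and QTL
placed at marker positions.  Passing tests on this generator
demonstrate correctness of the estimators under the stated model, not
robustness to interference, distorted segregation or informative
missingness in real crosses.

## Map diagnostics

`recomb_rate()` profiles cM/Mb in 5 Mb windows stepped by 1 Mb
(anchored at 0; width is the conventional choice, step and anchoring are
this package's decisions), restricted to markers concordant between the
genetic and physical maps: same chromosome label, and within each
chromosome the longest increasing subsequence of physical positions in
genetic order.  Windows with fewer than two markers are undefined rather
than zero.  The genome-wide mean uses whole-chromosome spans and is
therefore window-width invariant.  `assignment_support()` compares, for
a marker whose two maps disagree on the chromosome, linkage support at
its genetic position against the best two-point linkage anywhere on its
claimed physical chromosome.  `order_lod()` compares the multipoint
likelihood of two candidate marker orders with adjacent recombination
fractions re-estimated per order (error-tolerant HMM, so single bad
genotypes cannot decide an order); it is exactly zero for identical
orders and antisymmetric.

## Problem sizes used in the test-suite studies

The packaged studies run at sizes chosen to keep the full suite in the
tens of minutes on one core while leaving Monte-Carlo error well inside
the asserted bands: penetrance/variance recovery and epistasis use 200
crosses of n = 520 on the reduced map; the class-proportion anchors use
500 such crosses; permutation calibration uses 200 null crosses of
n = 260 with 200 permutations each; scan power and interval coverage
use 50 crosses on the full 25-chromosome map with a genome-wide
threshold estimated once (the null maximum-LOD distribution depends on
the map and sample size, which are identical across replicates, so the
threshold is shared by design).  The acceptance script simulates the
full-scale cross 501 times.

## Known limitations

* De-novo ordering is a heuristic (chaining + ripple-3); it recovers
  orders up to whole-chromosome reversal and flags, rather than
  resolves, zero-recombinant ambiguities.
* Inter-locus distances are re-estimated from adjacent pairs only; no
  joint multipoint distance refinement.
* The epistasis test's reduced model is fitted on the probability scale
  with clamping; with classes at the boundary the LOD carries a
  clamp-induced error of order $10^{-4}$.
* Support for marker insertion is undefined within a shared-flank
  neighborhood of the best placement (the profile is locally flat);
  terminal placements beyond the first or last locus are reported as
  placements into the terminal interval.
* The scan fits one locus at a time plus the explicit two-locus table;
  there is no multiple-QTL model search and no covariates.
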