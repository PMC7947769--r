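---
title: "Models and methods for tetrasomic recombination analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tetrasomic recombination analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrarec)
```

This vignette is the package's own account of the statistics it
implements: the inheritance models, the estimators and their standard
errors, the interference tests, what the simulator does and does not
emulate, and the numerical and design choices a maintainer would want to
know about.

## The inheritance models

### Four phenotype classes from two linked fluorescent markers

The central object is a cross in which one homolog of an autotetraploid
carries two linked dominant markers in coupling (genotype `GBBB/RCCC`: a
green-fluorescent allele at the proximal locus and a red one at the distal
locus of the same homolog). Each diploid spore of a tetrad shows one of
four phenotypes — yellow (both markers), green, red, or black (neither) —
with probabilities

$$f_y = \tfrac{1}{12}\left[2(3-3r+r^2) - \alpha(3-6r+5r^2)\right], \qquad
  f_g = \tfrac{r}{12}\left[6-2r-\alpha(6-5r)\right],$$
$$f_r = \tfrac{1}{36}(2+\alpha)\,r(6-r), \qquad
  f_b = \tfrac{1}{36}(2+\alpha)(3-r)^2,$$

where $\alpha \in [0,1]$ is the coefficient of double reduction at the
proximal locus and $r$ the recombination fraction between the loci. Two
structural facts drive everything downstream:

* the carrier marginal at the proximal locus, $f_y + f_g = (2-\alpha)/4$,
  is free of $r$ — segregation at one locus identifies $\alpha$ alone;
* under tetrasomic inheritance $r$ is admissible up to $3/4$, not $1/2$:
  with four homologs, a chromatid that recombines has three equally likely
  partners, and free recombination corresponds to $r = 3/4$.

These four formulas contain $\alpha$ only. The distal-locus coefficient
$\beta$ is *not* a second free parameter of the class distribution; it is
estimated from the same counts by regrouping the classes around the distal
locus (see below), and the model itself explains why $\beta \ge \alpha$ is
expected (next section).

### A chromatid-level model behind the formulas

The package needs more than the printed two-locus distribution: the
three-marker interference analysis and the simulator both require a
generative model. `tetrarec` uses a chromatid-pair construction:

1. A diploid gamete is a pair of chromatids. At the proximal locus, with
   probability $\alpha$ the two are sister-derived copies of one homolog
   (that is what double reduction *is*); otherwise they come from two
   distinct homologs chosen uniformly among the $\binom{4}{2}$ pairs.
2. Across each marker interval $k$, each chromatid's homolog-of-origin
   switches with probability $r_k$, the destination uniform among the
   other three homologs; chromatids switch independently of one another
   (no chromatid interference).
3. Switches of one chromatid in adjacent intervals are coupled so that
   $P(\text{both}) = c\,r_k r_{k+1}$, where $c$ is the coincidence
   parameter ($c = 1$: independence).

This model reproduces the four-class formulas above *exactly* — all four
class probabilities, for every $(\alpha, r)$ — which is the correctness
contract enforced in the test suite (the tetrasomic three-locus
distribution, marginalised over its third locus, must equal the four-class
model to $10^{-12}$). It also makes a testable prediction: double
reduction at a *distal* locus is emergent. Even with $\alpha = 0$, two
chromatids from distinct homologs can both switch onto the same homolog
between the loci, so the distal coefficient
$\beta(\alpha, r) \ge \alpha$ ([`emergent_dr()`]), e.g.
$\beta(0.1, 0.2) = 0.169$. This is why regrouped distal estimates
systematically exceed proximal ones.

The three-locus distribution is computed by exact enumeration, not
simulation. The four-homolog origin chain is lumpable to a two-state
carrier/non-carrier chain (from the carrier homolog every switch leaves;
from a non-carrier homolog a switch hits the carrier with probability
1/3), so each chromatid contributes a $2 \times 8$ pattern-probability
matrix and the gamete phenotype is the locus-wise OR of two independent
patterns given the starting-pair mixture. The enumeration is a few dozen
floating-point operations and is re-evaluated freely inside likelihood
optimisations.

### Five tetrad classes for crossover-number prediction

For sequencing data the package uses the complementary single-interval
model: an `AB/ab/ab/ab` autotetraploid yields five distinguishable tetrad
marker phenotypes with probabilities
$$f_1 = \alpha(1-p/2),\; f_2 = (1-\alpha)(1-\tfrac{5p}{12}),\;
  f_3 = \alpha p/2,\; f_4 = (1-\alpha)\tfrac{p}{12},\;
  f_5 = (1-\alpha)\tfrac{p}{3},$$
where $p$ is the probability of one crossover in the interval. Classes 1
and 3 carry all the double-reduction mass ($f_1 + f_3 = \alpha$), so
$\hat\alpha = (n_1+n_3)/n$ and $\alpha$ separates out of the likelihood
for $p$. Summing $\hat p$ over the intervals of a chromosome estimates the
expected crossovers per meiosis for that chromosome — the route by which
crossover numbers are recovered for phase-ambiguous tetraploid sequencing
data where direct calling is impossible.

## Estimators and standard errors

**Double reduction (tetrad counts).** $\hat\alpha =
2(n_r+n_b-n_y-n_g)/n$, the MLE from the carrier marginal. Its variance is
implemented as $16(n_1+n_2)(n_3+n_4)/n^3$, the two-class binomial
information; at expected counts this equals $(4-\alpha^2)/n$, an identity
the tests check to $10^{-12}$. Negative estimates are truncated at 0 and
flagged (`truncated`), never silently.

**Recombination fraction (tetrasomic).** A two-step profile: $\hat\alpha$
first (closed form), then $\hat r = \arg\max_{r \in [0, 0.75]}
\sum_i n_i \log f_i(\hat\alpha, r)$. The score in $r$ is a degree-5
polynomial with potentially spurious roots, so the search evaluates the
log-likelihood on a 0.01-step grid and refines the best bracket with
golden-section/parabolic search (`optimize`, tolerance $10^{-10}$),
comparing the refined point against both interval ends before accepting.
The standard error is $(-\partial^2 L/\partial r^2)^{-1/2}$ at
$\hat r$ using the exact polynomial derivatives of the class
probabilities; at a boundary optimum the SE is reported as `NA` and the
estimate flagged. A joint $(\alpha, r)$ maximisation (`method = "joint"`,
L-BFGS-B) is provided as a cross-check and agrees with the profile to
$10^{-3}$ on expected counts.

**Recombination fraction (disomic).** The recombinant-spore fraction
$(n_g+n_r)/n$ with binomial SE, clipped to $[0, 1/2]$ with a flag.

**Crossover probability (five-class counts).** The profile score in $p$
reduces to the quadratic $5np^2 - (22n-10n_1-12n_2)p + 24(n-n_1-n_2) = 0$,
i.e. $\hat p = (11n-5n_1-6n_2 \pm \Delta)/(5n)$ with
$\Delta = \sqrt{n^2 + 2n(5n_1-6n_2) + (5n_1+6n_2)^2}$. The root lying in
$[0,1]$ is taken; when both qualify the one with the higher likelihood
wins, and when the smaller root exceeds 1 the score is positive on the
whole unit interval and the boundary MLE $\hat p = 1$ is returned (root
`"boundary"`). The test suite verifies the closed form against a
$10^{-5}$-step grid maximisation of the five-class likelihood on 500
random count vectors. The SE comes from the observed information of the
five-class likelihood.

**Neutral segregation.** Disomic populations use the 1-df binomial score
test of the carrier fraction against 1/2. For tetrasomic populations the
null itself contains a free parameter (any $\alpha$ gives carrier fraction
$(2-\alpha)/4$), so the test is a 1-df likelihood-ratio test of the
carrier fraction against the interval $[(2-1/6)/4,\ 1/2]$, profiling
$\alpha$ over $[0, 1/6]$ — the mechanistically attainable range under
quadrivalent pairing with equational separation. Carrier fractions inside
the band give statistic 0 by construction.

## Interference

For haploid segregants of an `ABC/abc` parent, recombination in each
interval is directly countable and the three coincidence coefficients
$$c_{AB-BC} = \frac{r_{AB\cap BC}}{r_{AB}\,r_{BC}}, \qquad
  c_{AB/BC} = \frac{r_{AB|BC}}{r_{AB|\overline{BC}}}, \qquad
  c_{BC/AB} = \frac{r_{BC|AB}}{r_{BC|\overline{AB}}}$$
are exact ratios (`cc_haploid()`), equal to 1 under independence.

Dominant phenotypes of *diploid* segregants from an `ABC/abc/abc/abc`
tetraploid do not identify double recombination by counting: a spore can
carry a phenotype by either chromatid. `cc_tetraploid()` therefore fits
$(r_1, r_2, c, \alpha)$ by maximum likelihood over the enumerated
tetrasomic three-locus model and reports the fitted chromatid-level
coincidence as $c_{AB-BC}$, with the conditional coefficients derived from
the fitted switch distribution as $c(1-r_2)/(1-c r_2)$ and
$c(1-r_1)/(1-c r_1)$. This is a deliberate reconstruction — the exact
computation used for published tetraploid coefficient tables from dominant
data is not specified anywhere we could follow — and its outputs should be
compared with such tables qualitatively, not digit by digit. The optimiser
is box-constrained L-BFGS-B on $(r_1, r_2, u, \alpha)$ where
$u \in [0,1]$ linearly parameterises the feasible range of the joint
switch probability ($\max(0, r_1+r_2-1) \le c\,r_1 r_2 \le
\min(r_1, r_2)$), started from moment-style fits of the two-locus margins
plus optional random multistarts; boundary fits are flagged.

Significance is simulation-based: `cc_null_test()` simulates populations
with $c = 1$ at the observed $(r_1, r_2, n)$, recomputes each coefficient
per replicate, and reports the add-one two-sided empirical p-value
$p = (1 + \#\{|c_{sim}-1| \ge |c_{obs}-1|\})/(n_{sim}+1)$. Two-sidedness
via the $|c-1|$ ordering was chosen because interference can in principle
act in either direction and published analyses do not state a sidedness
rule; the add-one estimator keeps $p > 0$ and is the standard
permutation-style choice. The default 1,000 replicates reproduce the
convention of permutation tests at the 0.05/0.001 levels; the test suite
verifies both that the null mean of each coefficient is 1 within
Monte-Carlo error and that the rejection rate at nominal 0.05 is
$0.05 \pm 0.03$ over 200 outer replicates.

## The simulator: what it emulates, what it does not

`sim_scenario()` fixes the study conditions: ploidy, pairing
(quadrivalent, bivalent, or a per-meiosis mixture weight), per-interval
$r$, proximal $\alpha$, coincidence $c$, and population size.

* **Calibrated tetrasomic mode** (`sim_tetraploid_gametes()`): draws
  gametes directly from the chromatid-pair model above, so $\alpha$ and
  $r$ are exact input dials. This is deliberate: estimator validation
  needs known target parameters. The cost is that a "tetrad" in this mode
  is just four independent gametes — class frequencies are exact but
  within-tetrad dosage bookkeeping is not constrained.
* **Bivalent mode**: homologs pair two by two (pairing redrawn each
  meiosis), switches toggle within a bivalent, and double reduction cannot
  occur; single-locus carrier frequency is exactly 1/2.
* **Four-strand disomic tetrads** (`sim_diploid_tetrads()`): one crossover
  per interval with probability $2r_k$ between one chromatid of each
  current allelic origin, so every registered crossover is a
  genotype-visible reciprocal exchange and the recombinant-spore fraction
  is exactly $r_k$; adjacent intervals are coupled through a Markov chain
  on crossover indicators calibrated so the spore-level double-recombinant
  rate is $c\,r_1 r_2$. The single-crossover model requires
  $r \le 1/2$ per interval, which is automatic for disomic data; it does
  not generate multiple crossovers within one marker interval (invisible
  double events inside an interval are outside its scope — use more,
  closer markers instead).
* **Mechanistic tetrasomic bundle** (inside `make_genotype_matrices()`):
  eight chromatids, quadrivalent exchanges between chromatids of opposite
  allelic content, 2|2 centromere disjunction at meiosis I and equational
  separation at meiosis II. Here double reduction is *emergent* (bounded
  by 1/6) rather than dialled, tetrad dosage totals are conserved (2:6 or
  6:2), and crossovers whose two chromatids land in the same spore are
  recorded as invisible in the truth registry. This mode backs the
  crossover-calling fixtures, where within-tetrad reciprocity is the whole
  point.

What no mode emulates: gene conversion tracts, sequencing errors beyond a
symmetric per-marker dosage-flip rate, structural variation,
chromatid interference, or pairing-partner switching along a chromosome.
Passing tests therefore demonstrate correctness of the statistics under
the stated meiosis models, not robustness to every artefact of real
sequencing data.

## Crossover calling

`select_informative_markers()` keeps markers with summed tetrad dosage 2
(disomic 2:2) or 2/6 of 8 (tetrasomic 2:6, 6:2); everything else —
genotyping errors, conversion tracts, instability — is dropped before
calling, mirroring how marker sites are chosen for sequenced tetrads.
`call_crossovers()` then calls an interval where exactly two spores change
dosage in complementary directions (+1/−1) with the other two unchanged;
any other non-zero change pattern is logged as an anomaly and skipped,
including tetraploid ±1 changes shared by more than two spores, whose
treatment published descriptions leave unspecified.

Adjacent calls closer than 10 kb (default `min_spacing_bp`) are merged, as
short double-switches are more plausibly artefacts than two real
crossovers. "Closer than" is determinised as: distance between interval
midpoints; runs of consecutive close calls are collapsed pairwise left to
right, the leftmost of each pair surviving. The pairwise rule was chosen
over "merge into the last survivor" because it makes the *number* of
surviving calls independent of scan direction (a run of $k$ always yields
$\lceil k/2 \rceil$) — an invariant the tests check — whereas sequential
merging against the last survivor does not (a run at spacings 9/9 kb
yields 2 or 1 calls depending on direction). Call positions are reported
as 0-based half-open flanking-marker intervals with no midpoint
interpolation.

## Numerical choices and degenerate inputs

* Probability-vector sums are tested to $10^{-12}$; likelihood terms with
  $n_i = 0$ use the $0\log 0 = 0$ convention.
* The $r$ grid step (0.01) bounds the bracket handed to `optimize`; with
  the degree-5 score this was chosen small enough that no secondary mode
  can hide between grid points for any counts seen in testing.
* Counts are validated as non-negative but *not* required to be integers,
  so exact expected counts can be fed to every estimator (the
  Fisher-consistency tests rely on this).
* Single-class count vectors yield a boundary estimate with a warning and
  `truncated` flag rather than an error; all-zero rows error.
* Empirical p-values use the add-one estimator, so the smallest reportable
  p at 1,000 replicates is 1/1001.
* All samplers honour a scenario seed; identical seeds give bit-identical
  output, and the pipeline writes a manifest (seed, version, config hash)
  sufficient to regenerate any table.

## Problem sizes used in validation

The recovery experiments use 10,000-spore (or 10,000-tetrad) populations —
comparable to the ~26,000 scored spores spread over 17 marked intervals in
the motivating experimental design — and 1,000-replicate interference
nulls with 200 outer replicates for calibration; simulator contracts are
checked at 40,000–100,000 gametes where a frequency must converge to a
formula. These sizes make Monte-Carlo error a small fraction of each
tolerance while keeping the full suite under half a minute.

## Known limitations

* Only simplex (single-dose) dominant markers in coupling are modelled;
  duplex/triplex configurations and repulsion phase are out of scope.
* The two-locus four-class model carries $\alpha$ only; $\beta$ is
  estimated by regrouping, not jointly, following the profile structure of
  the likelihood.
* The tetraploid coincidence fit is model-based inference from dominant
  data and inherits the enumeration model's assumptions (no chromatid
  interference, uniform partner choice).
* Gene-conversion rate estimation from tetraploid tetrads is an open
  problem and deliberately not attempted.
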