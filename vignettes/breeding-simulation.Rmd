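---
title: "Simulating honeybee breeding programmes under controlled mating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating honeybee breeding programmes under controlled mating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Honeybee (*Apis mellifera*) breeding programmes must control which drones
mate their queens. The classical instrument is the isolated mating station
(IMS): a remote site stocked with a sister group of drone-producing queens
(DPQ), where virgin queens mate freely. Suitable sites are scarce, which
makes IMS a bottleneck for effective population size. Instrumental
insemination offers an alternative: drones for one queen can be taken from a
single selected colony, which records the true sire in the pedigree and can
shorten the paternal generation interval from three years to two.

`beebreed` simulates closed breeding populations under four mating-control
strategies — IMS, and instrumental insemination stations (IIS) with
two-year (IIS2), three-year (IIS3) or mixed (IISmix) producer ages — and
tracks the two quantities any breeding scheme trades off: genetic gain in a
colony performance trait and the accumulation of inbreeding.

## Genetic model

The selection trait is purely additive over `n_loci` (default 400) unlinked
biallelic loci, with a maternal (queen) and a direct (worker) component per
locus. A finite-locus model is used deliberately instead of the
infinitesimal model: favourable alleles can be lost by drift, so genetic
variance depletes over a long programme, which matters over a 70-year
horizon.

* Founder allele frequencies are drawn from the U-shaped Beta(0.5, 0.5)
  distribution.
* Raw bivariate allele effects come from a 50/50 mixture of a bivariate
  Laplace and a bivariate normal distribution, both unit scale. The mixture
  shape is a free choice (only "heavy-tailed, L-shaped" is established for
  effect-size distributions); the package therefore calibrates the drawn
  effects with an exact linear map so that the base-population genic
  (co)variances equal the configured targets to numerical precision —
  the realized base variances are invariant to the mixture choice, which is
  why the weight is exposed but uninteresting.
* Default targets: maternal variance 1, direct variance 2, residual
  variance 4, and a maternal–direct correlation of −0.18 (a weak negative
  set) or −0.53 (medium negative), matching parameter estimates reported
  for real honeybee traits.

A queen is diploid (two haplotypes); a drone is haploid — a single maternal
gamete — and his sperm is clonal. The worker group of a mated queen is
represented by its expected allele dosage (queen dosage/2 plus the mean of
her 12 mates' alleles) rather than by sampled individual workers; the
worker-sampling noise this removes is part of what the residual variance
absorbs. Colony phenotypes are

\[ y = bv_m(\text{queen}) + bv_d(\text{worker group}) + \text{apiary} + e,
   \qquad e \sim N(0, \sigma^2_E). \]

Apiary effects are drawn i.i.d. N(0, 1) per apiary and year and estimated
as fixed effects; their scale only exercises the fixed-effect machinery.

## Two relationship matrices

The simulator maintains two kinship matrices side by side:

* **True kinship** uses the individual father drone of every queen
  (haplodiploid tabular rules: a drone's kinship row equals his dam's, his
  self-kinship is 1). It is what nature does, and it is used to *report*
  inbreeding. Individual drones shared by two daughters of one dam create
  super sisters (kinship 3/8); the incremental store handles this both
  within and across cohorts.
* **Accessible kinship** is what a breeder can compute from recorded
  pedigrees. For IMS matings the recorded sire is the pooled sister group
  (pseudo-sire): the pool's row is the member average and its diagonal is
  the probability that two independent drones from the pool carry
  identical-by-descent alleles. For IIS the recorded sire is the single
  producer queen. Worker-group entities enter the evaluation with a
  diagonal that uses the finite mate count (12 by default; the
  infinite-mates approximation is available via `finite_mates = FALSE`).
  These rules reproduce the closed-form paternal ibd probability
  \((1 + a_{ss}(N_{DPQ}-1)) / (2 N_{FertS} N_{DPQ})\) exactly when
  \(a_{ss}\) is the realized mean member relationship.

Both engines are validated against a gene-drop oracle: unique founder
alleles are dropped through the pedigree at thousands of virtual loci and
ibd frequencies are compared with the recursions.

## Genetic evaluation

Selection uses best linear unbiased prediction in the standard two-effect
honeybee animal model: each pedigree entity carries a (maternal, direct)
breeding-value pair with covariance \(G_0 \otimes A\), where \(A\) is the
accessible relationship matrix including worker-group entities, and a
colony record loads the queen's maternal and her worker group's direct
effect. Two algebraically identical solvers are implemented:

* `method = "mme"` assembles Henderson's mixed-model equations (requires
  \(A^{-1}\)); it is the reference implementation and is tested against an
  independent dense GLS oracle to 1e−8.
* `method = "gls"` solves in observation space; the linear system has the
  size of the record count, which in the year loop (a few hundred records)
  is far smaller than the entity count. The year loop uses this route; a
  test asserts the two routes coincide, so the fast path inherits the
  oracle check.

The evaluation window covers the last 4 phenotype years — every selection
candidate (ages 2 and 3) plus one older cohort. Older records add
negligible information about current candidates but grow the system
quadratically. Every 5 years the genetic covariance \(G_0\) used by BLUP is
re-estimated as the empirical covariance of the newest cohort's true
breeding values, tracking the drift-induced loss of variance; using true
values is a deliberate simplification (the alternative, REML on phenotypes,
is out of scope), and eigenvalues are floored at 1e−8 so depleted
late-stage populations keep a solvable system.

## Life cycle and strategies

Year `y` proceeds: performance test of the year `y−1` cohort → BLUP →
dam selection (best 20% of two-year-olds by the *worker-group* criterion,
the expected quality of a daughter; ties break by entity id) → producer
selection and station assembly → hatching (each dam contributes exactly 5
daughters, fathered by drones the dam stored at her own mating two years
earlier) → mating of the new virgins at this year's stations.

* **IMS**: the best `N_FertS` three-year-olds each found a station of 8
  DPQ. The DPQ are instantiated as real daughter genomes (fathers drawn
  from the founder queen's own stored mates), so the within-station
  relationship \(a_{ss}\) *emerges* from the model instead of being
  imposed. Each virgin receives 12 drones whose dams are drawn uniformly
  from the 8 DPQ. Paternal generation interval: 3 years.
* **IIS2/IIS3/IISmix**: the best `8 N_FertS` queens of the eligible age
  cohort(s) are selected by their own (queen) criterion and randomly
  partitioned into stations of 8. Each virgin is inseminated with 12 drones
  from one admissible producer on her station — never her own dam or an
  aunt (a producer sharing a dam with the queen's dam). If a station offers
  no admissible producer the sibling group moves to the next station by
  index. All daughters of one dam are mated at the same station
  (round-robin assignment balances station load).

Years 1–2 are a randomly mated founder base (within-cohort partners,
accessible sire unknown); IIS2/IISmix stations first operate in year 3,
IMS/IIS3 in year 4 when the first three-year-olds exist. The paternal
generation interval recorded each year is the mean age of the selected
producers (3 for IMS, via the station-founding queen), which makes the
bootstrap dynamics observable: under IISmix the interval oscillates in
early years and settles between 2 and 3.

A structural consequence worth knowing: under IIS2 both generation
intervals are 2 years, so queens of even and odd birth years form two
genetically separate populations. The accessible kinship between parities
is exactly zero, ensemble-mean genetic progress arrives in every second
year, and single replicates carry persistent "parity luck" — one parity
can lead for an entire run, which is why staircase diagnostics are applied
to replicate means.

## What the generator does and does not emulate

Default study conditions are those of the simulated comparison: 500 or
1000 queens per year, 70 years, 5/20/50 stations, 200 replicates. The test
suite and examples run scaled versions (100 queens, 30 years, 20
replicates, 5 stations) so the whole suite fits in minutes; the scaled runs
preserve the qualitative structure (strategy orderings of gain and
inbreeding, the IIS2 staircase, generation-interval behaviour) but not the
full-scale magnitudes, and selection intensities on the producer path are
necessarily milder at 100 queens/year. Passing scaled tests therefore
demonstrates mechanistic correctness, not numerical equality with
full-scale results; the full grid is reachable by changing `sim_config()`
arguments.

Real-world features deliberately outside the model: the csd sex locus and
diploid drone production, queen losses (none are simulated, so all age
cohorts are fully available for selection), linked loci and recombination
maps, individual workers, genomic data, mixed strategies within one
population, and within-family or optimum-contribution selection.

## Numerical choices

* Calibration uses symmetric matrix square roots, tolerating zero variance
  targets (a zero-variance "neutral" configuration yields exactly zero
  effects and a flat response — used by drift tests).
* Kinship stores are pruned to the last `eval_window + 3` birth years, the
  oldest generation any recursion can still reference; inbreeding
  coefficients are kept for all years.
* Degenerate Welch comparisons (both arms constant) return p = 1 for equal
  means by convention.
* Founder frequencies are clipped to (1e−6, 1−1e−6); fixed loci that arise
  later by drift are retained so genic variance can genuinely deplete.
* Determinism: a run is a pure function of (configuration, seed);
  replicate r of an ensemble uses seed `master + r` and is reproducible
  individually.

## Known limitations

Inbreeding depression is not modelled, so inbreeding is a bookkeeping
quantity rather than a fitness cost; the accessible matrix diagonal for
worker groups assumes exactly 12 mates; variance re-estimation from true
breeding values is optimistic relative to a REML analysis of phenotypes;
and the bootstrap's random base mating means the first two cohorts carry no
pedigree information, so early-year evaluations lean entirely on own
performance.
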