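# beebreed

Stochastic simulation of closed honeybee (*Apis mellifera*) breeding
programmes under different forms of mating control, for quantitative
geneticists and breeding-programme designers who want to compare mating
strategies before committing real populations to them.

Honeybee breeders control paternity either with **isolated mating stations
(IMS)** — remote sites stocked with a sister group of 8 drone-producing
queens (DPQ), where virgin queens mate freely with ~12 drones — or with
**instrumental insemination (IIS)**, where the 12 drones for one queen can
be taken from a single selected colony. Single-colony insemination records
the true sire in the pedigree and lets the paternal generation interval
drop from three years to two. The package simulates both, plus the
three-year and mixed-age insemination variants (IIS3, IISmix), and tracks
genetic gain and inbreeding over a multi-decade horizon.

## The model in brief

* **Trait:** purely additive over 400 unlinked biallelic loci with maternal
  (queen) and direct (worker) components; base-population genic variances
  σ²_m = 1, σ²_d = 2, residual σ²_E = 4, maternal–direct correlation
  r_md ∈ {−0.18, −0.53}. Founder frequencies are Beta(0.5, 0.5); effects
  come from a Laplace/normal mixture calibrated *exactly* to the target
  variances.
* **Colony phenotype:** y = bv_m(queen) + bv_d(worker group) + apiary + e.
* **Evaluation:** bivariate BLUP (Henderson's mixed-model equations, with
  an equivalent observation-space solver used in the year loop) on the
  *accessible* relationship matrix — the one computable from recorded
  pedigrees, in which an IMS pseudo-sire is the DPQ pool and an IIS sire is
  the recorded producer queen. Realized inbreeding is reported from the
  *true* relationship matrix with individual drone fathers known.
* **Selection:** the best 20% of two-year-old queens each produce five
  daughters; drone producers are the best N_FertS three-year-olds (IMS,
  each founding a sister group of 8 DPQ) or the best 8·N_FertS queens of
  the eligible age cohorts (IIS), with queens never inseminated by drones
  from their own dam or an aunt.
* **Analytic layer:** effective number of sires
  N_s,eff = 1 / (2 p_pat,ibd), with
  p_pat,ibd = (1 + a_ss (N_DPQ − 1)) / (2 N_FertS N_DPQ) for pooled sister
  groups; generational inbreeding rate ΔF = 1 − (1 − F_end)^(GI/(years−1));
  Wright's N_e = 4 N_d N_s / (N_d + N_s); Welch tests across replicates.

## Worked example

A scaled two-year-interval insemination programme (100 queens/year,
30 years, 5 stations, 5 replicates):

```r
library(beebreed)
cfg <- sim_config(n_queens = 100, years = 30,
                  strategy = strategy_config("IIS2", n_stations = 5))
ens <- run_replicates(cfg, replicates = 5, seed = 42)
summary(ens)
#> Strategy IIS2 (5 replicates, 100 queens/year, 30 years):
#>   genetic gain         8.271 +/- 1.079 trait units
#>   final inbreeding    0.2533 +/- 0.0420
#>   paternal GI          2.000 years
#>   inbreeding rate       2.00 % per generation
```

The programme gained 8.3 trait units of colony performance in 30 years,
but the mean inbreeding coefficient of the final cohort reached 0.25 —
a generational inbreeding rate of 2% per generation, twice the 1%
threshold conventionally regarded as sustainable. That is the known
weakness of the two-year paternal interval: both generation intervals are
2 years, so even and odd birth years form two closed subpopulations and
the effective population size halves (genetic progress also arrives only
in every second year; see `plot(ens)`).

The analytic layer answers the "how many sires is a mating station worth?"
question directly:

```r
effective_sires(5, 8)                               # 5 IIS of 8 producers
#> [1] 40
effective_sires(5, 8, a_ss = 0.4, mode = "ims_pool") # 5 IMS, sister groups
#> [1] 10.52632
generation_metrics(rep(2, 5), n_dams = 20, n_sires_eff = 40)$ne
#> [1] 53.33333
```

Per-replicate endpoints for statistical comparison come from
`final_metrics(ens)`, and `welch_compare()` tests differences between two
strategies' replicate samples.

A thin CLI for batch runs lives at `inst/cli/beebreed-cli.R`
(`run --config cfg.json --replicates N --seed S --out DIR`, then
`summarize --in DIR`).

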