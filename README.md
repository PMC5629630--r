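# trigamete

Three-point gamete frequency estimation and linkage mapping for F2
intercross populations.

## The problem

Dominant markers in an F2 population segregate 3:1 and hide their
heterozygotes. A pair of dominant markers in *repulsion* phase (dominant
alleles on opposite parental chromosomes) carries almost no two-point
linkage information, so ordinary pairwise analysis splits a chromosome
into two complementary half-maps that cannot be merged. Three-point
gamete analysis fixes this: the eight gamete haplotypes of a locus triple
form four complementary sister pairs — classes `{000,111}`, `{100,011}`,
`{110,001}`, `{101,010}` with frequencies `q1..q4`,
`2(q1+q2+q3+q4) = 1` — and once those four numbers are estimated, phase,
within-triple order, and all three recombination fractions follow
regardless of phase.

The package is aimed at people building genetic maps from intercross
data (dominant markers such as RAPDs/AFLPs, or codominant markers such as
RFLPs/SSRs/SNPs) and at methodologists benchmarking linkage estimators.

## What it implements

* **ELS** (`els_estimate()`): an expectation–least-square estimator of
  `q1..q4` from the seven informative dominant phenotype classes. `q1`
  is refined by a ±Δ line search minimizing
  `S² = Σ_{i=2..7} (Q̂i − E(Qi))²`, with `q2..q4` restored in closed form
  from complement-combined class frequencies at every step, e.g.
  `q̂3 = √(Q̂2* + q̂1²) − q̂1`. An exhaustive grid oracle
  (`els_grid_oracle()`) independently verifies the search.
* **BAT** (`bat_estimate()`): a closed-form estimator for codominant
  triples built on perfect-square class sums
  `Qij = (qi + qj)²` assembled two independent ways from the 14
  complementary zygote-pair classes.
* **Mapping** (`infer_order_phase()`, `triple_recomb_fractions()`,
  `pairwise_theta()`, `order_map()`): parental/double-crossover class
  inference, `r(x,y) = 2(p_S(x) + p_S(y))` interval fractions,
  reference-locus averaging `θij = (1/(n−2)) Σ_k r_ijk`, a 1:1:1:1
  chi-square linkage screen, and exhaustive minimum-SARF ordering.
* **Baseline and simulator** (`em_two_point()`, `sim_f2()`,
  `run_benchmark()`): the textbook two-point F2 EM, and an F2 meiosis
  simulator (independent crossovers, Haldane map function, coupling or
  per-locus random phase) with a recovery-rate / MSE benchmark harness.

See the methods vignette (`vignettes/three-point-gametes.Rmd`) for the
models, numerical choices, and limitations.

## Worked example

The package bundles the ELS-estimated, normalized gamete frequencies of
the four linked dominant triples (markers 1, 2, 3, 5) of the classic
333-individual mouse F2 RFLP panel:

```r
library(trigamete)
fx <- mouse_dominant_triples()
p <- normalize_gamete_freqs(as.numeric(fx[1, c("p1","p2","p3","p4")]),
                            loci = c("1", "2", "3"))
res <- triple_recomb_fractions(infer_order_phase(p))
res
#> triple 1-2-3: order 2-1-3, phase coupling (parental class 1, double-CO class 2)
#>   r(2,1) = 0.393268   r(1,3) = 0.361720   r(2,3) = 0.410340
```

The most frequent class (`p1 = 0.208668`, the all-recessive gamete) is
parental and the least frequent (`p2 = 0.086162`) is the double-crossover
class, so marker 1 is in the middle and the triple is in coupling. Running
all four triples and averaging each pair over its two reference loci:

```r
theta <- pairwise_theta(tab, markers = c("1", "2", "3", "5"))  # tab: all 4 triples
round(theta$theta, 6)
#>          1        2        3        5
#> 1       NA 0.387164 0.349396 0.377323
#> 2 0.387164       NA 0.390506 0.416221
#> 3 0.349396 0.390506       NA 0.436782
#> 5 0.377323 0.416221 0.436782       NA
order_map(theta, loci = c("1", "2", "3"))
#> [1] "2" "1" "3"
```

θ12 = 0.387 means an estimated recombination fraction of about 39%
between markers 1 and 2; the minimum-SARF order places marker 1 between
2 and 3, and marker 5 is only loosely linked to the rest.

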