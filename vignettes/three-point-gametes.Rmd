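---
title: "Three-point gamete analysis for F2 linkage mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-point gamete analysis for F2 linkage mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigamete)
```

## The problem

In an F2 intercross each individual is the union of two F1 gametes. For a
pair of *dominant* markers (heterozygote indistinguishable from one
homozygote, 3:1 segregation) the amount of two-point linkage information
depends dramatically on phase: pairs whose dominant alleles sit on the same
parental chromosome (coupling) are informative, pairs in repulsion are
nearly useless. Since in practice roughly half of all dominant marker pairs
are in repulsion, two-point analysis fractures a chromosome into two
complementary half-maps that cannot be joined.

Three loci change the picture. A triple heterozygote produces eight gamete
haplotypes that fall into four complementary *sister pairs* — in 0/1 allele
coding `{000,111}`, `{100,011}`, `{110,001}`, `{101,010}`, indexed 1–4 in
that order throughout the package. Without mutation, selection or
segregation distortion the two members of a pair are equally frequent, so
four frequencies `q1..q4` with `2(q1+q2+q3+q4) = 1` describe the triple.
Once the `q` vector is known, phase, within-triple order, and all three
recombination fractions follow — for dominant markers in any phase. The
package estimates `q` two ways (ELS for dominant data, BAT for codominant
data) and provides the downstream mapping machinery plus a two-point EM
baseline and an F2 simulator.

## Forward model for dominant triples

Writing `a/A`, `b/B`, `c/C` for the recessive/dominant alleles, the eight
phenotype classes have frequencies (with `Q = 2(q2q3 + q2q4 + q3q4)`):

| class | phenotype | frequency |
|---|---|---|
| Q1 | aabbcc | q1² |
| Q2 | aabbC_ | q3² + 2 q1 q3 |
| Q3 | aaB_cc | q4² + 2 q1 q4 |
| Q4 | A_bbcc | q2² + 2 q1 q2 |
| Q5 | A_B_cc | Q2 + Q |
| Q6 | A_bbC_ | Q3 + Q |
| Q7 | aaB_C_ | Q4 + Q |
| Q8 | A_B_C_ | remainder |

`expected_dominant_freqs()` implements this; the all-dominant class Q8
dissects into every gamete pair and carries no information. Note the index
crossing: the single-dominant-`C` class involves `q3` because `abC` belongs
to sister pair 3, and similarly `Q3 ↔ q4`, `Q4 ↔ q2`.

## ELS: expectation–least-square estimation

Given observed class frequencies `Q̂1..Q̂7` (from
`tally_dominant_phenotypes()`), inverting the table gives
`q̂1 = √Q̂1` and `q̂3 = √(Q̂2 + q̂1²) − q̂1` (and cyclically for `q̂2`,
`q̂4`). Because the accuracy of everything rests on `q1`, ELS refines it by
a one-dimensional search: for a trial `q1`, restore `q2..q4` in closed
form, predict `Q2..Q7`, and score the fit by
`S² = Σ_{i=2..7} (Q̂i − E(Qi))²`; then walk `q1` in steps of `delta`,
keeping the direction while `S²` falls and reversing when it rises, until
`S² ≤ tol` or a local minimum at resolution `delta` is reached.

Two refinements matter:

* **Complement re-estimation.** The two-dominant classes re-estimate the
  one-dominant classes: `Q#k = Q̂(k+3) − Q`. The excess `Q` comes from the
  observed-frequency identity `Q = (Q̂1 + Q̂5 + Q̂6 + Q̂7 − 0.25)/2`
  (a consequence of the forward model and the sum constraint) at bootstrap
  and from the model expectation afterwards. Each `Q#k` is averaged with
  the directly observed `Q̂k`; equal weights are the default (for F2 class
  frequencies the two estimates carry comparable information), with
  proportional weights as an option. Small-sample degeneracies follow fixed
  rules: `Q#k ≤ 0` falls back to `Q̂k` alone; `Q#k > 0` with `Q̂k = 0`
  uses `Q#k` alone.
* **Self-consistent expectation.** During iteration the excess `Q` must
  equal `2(q̂2q̂3 + q̂2q̂4 + q̂3q̂4)` of the current estimates, which makes
  the evaluation at a given `q1` a fixed-point condition. The naive
  recursion (plug in last iteration's value) is *not* a contraction — the
  map is decreasing in `Q` with slope below −1 on realistic sampled data
  and falls into period-2 cycles. The package therefore solves the fixed
  point exactly by bisection (the map is monotone) at every evaluation, so
  `S²(q1)` is a well-defined function shared by the line search and by the
  exhaustive grid oracle `els_grid_oracle()` used to verify it.

Numerical choices: negative radicands in the closed-form restorations clamp
to zero and `q̂2..q̂4` are confined to `[0, 0.5]`; `q̂1` is confined to
`[0, 0.5]` (with `Q̂1 = 0` the search simply starts at zero). Defaults are
`delta = 1e-4` (the resolution of the final estimate), `tol = 1e-6` on the
squared-frequency scale, `max_iter = 10000`. The search stops either at
`tol`, or at a local minimum of `S²` — once both neighbouring steps fail to
improve, further iteration provably changes nothing, and the condition is
reported as `status = "stalled"` rather than burning the iteration budget.

**Why the tolerance adapts to the sample size.** With equal weights a
little algebra shows the one-dominant-class expectations cancel exactly
against the combined frequencies, leaving
`S² = ½ Σ_k (Q̂(k+3) − Q̂k − Q(q1))²`: the criterion depends on `q1` only
through the weakly varying excess `Q(q1)`, while the direct information
about `q1` sits in `Q̂1` via the initialization. Driving `S²` below its
sampling floor therefore *overfits* — it trades the well-anchored `q1`
for spurious fit to noise in the two-dominant classes, and in simulation
triples it inflates the spread of the resulting recombination fractions
about threefold, with the search frequently coasting to the `q1 = 0.5`
boundary. When the input is a tally with known sample size `n`,
`els_estimate()` consequently raises the effective tolerance to the
expected floor `Σ Q̂i(1 − Q̂i)/n` over the six fitted classes, so the
search refines the initialization only while the residual is
statistically meaningful. Exact inputs (floor zero) are minimized fully,
which is the regime where a unique global optimum exists and the grid
oracle certifies the search.

## BAT: closed-form estimation for codominant triples

Codominant genotypes expose parent of origin, so the 27 three-locus
genotypes collapse into 14 complementary zygote-pair classes
(`tally_zygote_pairs()`), e.g. genotypes 200 and 211 both belong to class
`P12` with expectation `4 q1 q2`. Sums of the right classes are perfect
squares: both

* `Q¹ij = (Pi + Pij + Pj)/2` from the one-heterozygote classes, and
* `Q²ij` from the two-heterozygote classes (e.g.
  `Q²12 = (P1 + P1234 − P34 + P2)/2`)

equal `(qi + qj)²`. `bat_estimate()` combines the two routes with weights
`a_ij = Q̂¹ij/(Q̂¹ij + Q̂²ij)` (equal weights available), takes square
roots, and solves the resulting linear system, e.g.
`q̂1 = ½[(√Q12 + √Q13 + √Q14 − √(P2/2) − √(P3/2) − √(P4/2))/3 + √(P1/2)]`.
On exact class frequencies both routes coincide and the inversion is exact
to machine precision — the estimator is closed form, which is what the
package's exactness tests assert. In small samples `Q²ij` can go negative
(it subtracts a class frequency); it clamps to zero before weighting, a
zero denominator in the weights falls back to ½, and a negative final
estimate clamps to zero with a warning. The triple heterozygote class 222
is tallied for the sum-to-one invariant but never used.

## From gamete frequencies to maps

**Normalization.** Separately estimated `q̂` need not sum to 0.5;
`normalize_gamete_freqs()` rescales (`p_i = q̂_i / 2Σq̂`).

**Order and phase.** The most frequent class is parental; the least
frequent is the double-crossover class. Every non-parental class has
exactly one member differing from the parental gamete at exactly one
locus, and each locus is hit by exactly one class — call it `S(ℓ)`. The
middle locus is where the double-crossover class differs; phase is
coupling when the parental class is class 1, otherwise the locus at which
the parental haplotype carries the opposite parent's dominant allele is in
repulsion with the outer pair. Ties (within 1e-9) in the parental class
make phase and fractions undefined; ties in the double-crossover class
(e.g. complete linkage, where all crossover classes are empty) leave only
the order undetermined.

**Recombination fractions.** Gametes recombinant between loci `x` and `y`
are exactly the classes `S(x)` and `S(y)`, so
`r(x, y) = 2(p_S(x) + p_S(y))`. For the outer pair this *excludes* the
double-crossover class — a deliberate property of the three-point
construction. `linkage_chisq()` screens triples against the 1:1:1:1 ratio
expected without linkage (gamete counts reconstructed as
`round(4 n p_i)`, each individual carrying two gametes — a declared
construction, since only the test's p-values are standard).

**Averaging and ordering.** With `n` markers, every third locus `k` gives
an estimate `r_ijk` for the pair `(i, j)`; `pairwise_theta()` averages
over all `n − 2` references by default (a `linked` filter restricts to
references whose triple rejects the 1:1:1:1 screen at `alpha = 0.05`).
`order_map()` then searches all permutations up to reversal — feasible to
ten loci; the study designs here use six (360 orders) — for the minimum
sum of adjacent fractions (SARF), ties resolving lexicographically.
Estimates above 0.5 are kept as computed (an optional cap exists), since
inflated outer-pair estimates still order correctly.

## The two-point EM baseline

`em_two_point()` implements the textbook F2 two-point EM: the latent
variable is the gamete pair; the E-step distributes each observed class
over compatible gamete pairs (codominant data have one ambiguous class,
the double heterozygote; dominant data are ambiguous everywhere outside
the double-recessive class); the M-step sets `r` to expected recombinant
gametes over `2N`. `r` is confined to `[0, 0.5]` because beyond one half
the two phase models mirror each other (a parent-label flip maps repulsion
at `1 − r` onto coupling at `r`); with `phase_mode = "unknown"` both phase
models are fitted and the higher likelihood wins. Convergence:
`|Δr| < 1e-8` or 1000 iterations, started at `r = 0.25`; the log-likelihood
trace is retained and asserted non-decreasing in the tests.

## The F2 simulator

`make_map()` draws interval distances i.i.d. from {10, 15, 20, 25, 30} cM
by default; `sim_f2()` builds each gamete by walking loci left to right and
switching parental strand between adjacent loci with probability
`r(d) = (1 − e^(−2d/100))/2`. Haldane's function is the consistent choice
for a model with independent crossovers and no interference; an identity
map (`r = d/100`) is available for sensitivity checks. Phase handling:
`coupling` orients every locus identically; `unknown` randomizes each
locus independently — for dominant markers this decides which parent
carries the dominant allele, for codominant markers which homozygote is
labelled `A`. The hidden strand matrices are kept for calibration tests
(segregation 1:2:1 and 3:1, recombinant fractions per interval, sister
gamete symmetry).

`run_benchmark()` redraws the map every replicate (averaging over map
configurations), simulates one set of meioses, and evaluates all requested
estimators on data derived from those same meioses — ELS and EM on the
dominant coding, BAT on the codominant coding. The EM baseline runs
phase-blind (coupling model) by default: a two-point analysis of dominant
markers cannot tell coupling from repulsion, and that failure is precisely
what the benchmark quantifies. Setting `em_phase = "unknown"` instead lets
EM pick the phase per pair by likelihood — a markedly stronger baseline
(its unknown-phase recovery roughly quadruples in our runs), available for
users who want the modern comparison rather than the classical one. Recovery means the
SARF order equals the truth up to reversal; accuracy is the per-interval
squared error of the adjacent-pair estimate against the replicate's true
Haldane fraction. The bundled study conditions are 6 loci,
N ∈ {100, 200, 300}, 100 replicates per condition.

## What the simulator does not emulate

Real genotype data carry missing calls, genotyping error, segregation
distortion, and crossover interference; the simulator generates none of
these (missing data are handled at estimation time by per-triple
complete-case tallies — a package choice, made once). Passing benchmarks
therefore demonstrate correctness of the estimators under their own model
assumptions, not robustness to violations of them. The bundled worked
example (`mouse_dominant_triples()`) provides a real-data regression
anchor for the downstream pipeline; the underlying raw genotypes are not
redistributed, so gamete-frequency estimation itself is exercised on
simulated data only.

## Known limitations

* ELS's criterion can be multimodal on noisy data (the degenerate-weight
  rules introduce discontinuities); the line search finds the local
  minimum reachable from `√Q̂1`, which the oracle tests show is almost
  always the global one, but pathological tallies may differ.
* Sister-pair symmetry is assumed, so selection, distortion, or scoring
  bias at a locus propagates into all its triples.
* Exhaustive SARF ordering is limited to ten loci; no heuristic search is
  provided.
* No standard errors for `q̂` or `θ` are produced; the benchmark's
  replicate spread is the intended uncertainty summary.

## A worked call sequence

```{r example, eval = FALSE}
map <- make_map(6, marker_type = "dominant", phase_mode = "unknown",
                seed = 1)
gm <- sim_f2(map, 300, seed = 2)
triples <- estimate_triples(gm, method = "els")
theta <- pairwise_theta(triples, markers = map$loci)
order_map(theta)
```
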