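---
title: "Tetrad analysis of meiotic crossing over: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tetrad analysis of meiotic crossing over: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetradkit)
```

## The problem

In budding yeast, one meiosis yields four haploid spores that can be
recovered together by dissection. For a heterozygous marker pair, a
four-spore tetrad falls into one of three classes: **parental ditype** (PD,
no recombinant spores), **tetratype** (TT, two recombinant spores — the
signature of a single crossover), or **nonparental ditype** (NPD, four
recombinant spores — a four-strand double crossover). From the class counts
of many tetrads one estimates genetic map distances, and from the joint
classes of adjacent intervals one measures **crossover interference** — the
tendency of a crossover to suppress others nearby, which spaces crossovers
more evenly than a Poisson process would.

`tetradkit` implements this pipeline: classification, Perkins mapping,
interference statistics (Malkova partition ratio and coefficient of
coincidence), statistics for spore-autonomous fluorescence crossover
assays, and a meiosis simulator with tunable interference that provides
datasets of known truth for validating all of the above.

## Classification rules

`classify_interval()` counts, per tetrad, the spores whose two-marker
combination is non-parental: 0 → PD, 2 → TT, 4 → NPD. Everything else is
UNSCORABLE:

* **any inviable spore** — a partial tetrad cannot be ditype-classified
  unambiguously, so the whole tetrad is excluded for every interval. This is
  the conservative four-spore convention; the alternative of genotyping
  three-spore tetrads is not attempted.
* **a missing allele call** at either marker;
* **a recombinant count of 1 or 3** — non-2:2 segregation, i.e. a putative
  gene-conversion event. These are counted and reported but no
  conversion-aware correction is applied.

Parental phase (which two combinations are parental) is declared, not
guessed: simulated and conventionally coded data use phase `c(0, 0)`. An
optional `infer_phase = TRUE` takes the majority combination as parental,
but it is off by default because phase is a property of the cross, and
inference would silently mask a miscoded input.

## Perkins mapping and its standard error

The Perkins estimator corrects single-crossover distances for the
double crossovers revealed by NPDs:

$$\mathrm{cM} = 50\,\frac{TT + 6\,NPD}{PD + TT + NPD}.$$

Writing the per-tetrad score $X \in \{0, \tfrac12, 3\}$ for PD/TT/NPD, the
estimate is $100\,\bar X$, and `perkins_se()` is the multinomial
delta-method standard error $100\sqrt{(\overline{X^2}-\bar X^2)/n}$
evaluated at the observed class frequencies. This is the natural SE of a
mean of i.i.d. bounded scores; the test suite confirms it agrees with a
10,000-resample nonparametric bootstrap over tetrads to well within 5%
relative error at $n = 5000$ (observed: under 1.5%). The estimator is
reported unbounded (it can exceed 50 cM), and is known to be slightly
downward-biased for intervals beyond roughly 30 cM, where triple and higher
crossover classes fold back into TT; the closed-form oracle
`mather_frequencies()` quantifies exactly this truncation (e.g. the
expected estimate for a true 30 cM Poisson interval is 28.1 cM). Tests of
distance recovery therefore compare against either the configured truth
within sampling error (for $d \le 35$ cM) or the oracle expectation, and
single intervals larger than ~35 cM should be subdivided in experimental
designs.

Single-spore recombination frequencies use the exact two-sided
Clopper–Pearson 95% interval (`single_spore_rf()`), an exact method being
the defensible default where no method is otherwise specified. The
frequency reported is the *recombinant* fraction of spores.

## Interference statistics

`malkova()` partitions tetrads by the presence of a recombination event in
a reference interval and compares the Perkins distance of the adjacent
interval between the two subsets; "recombination event" means TT **or**
NPD, since NPD is unambiguously recombinant. The computation runs in both
directions and reports the arithmetic mean of the two directional ratios. A
ratio below 1 is positive interference. Significance per direction comes
from a plain G test (no Williams or continuity correction; columns with
zero totals are dropped) comparing the full (PD, TT, NPD) composition of
the measured interval between the subsets; a collapsed 2×2
recombinant/non-recombinant variant is available behind `collapse = TRUE`
but the 2×3 test is the default, as it uses the full class information.
The decision rule (`interference_call()`): mean ratio < 1 with at least one
directional p below α → positive interference; mean ratio > 1 with a
significant G → negative-interference candidate; otherwise no detectable
interference. α defaults to 0.05.

`coc()` is the tetrad-level coefficient of coincidence: observed tetrads
recombinant in both intervals over $n f_X f_Y$ expected from the marginal
recombinant-tetrad frequencies. It is exactly 1 on any joint table that is
an outer product of its marginals, 0 when no double crossovers are seen,
and flagged undefined when a marginal frequency is zero. A map-distance
based COC is deliberately not implemented: the tetrad-level definition
needs only the joint table the pipeline already builds.

Interval pairs are conventionally adjacent (sharing a middle marker);
non-adjacent pairs are accepted with a warning.

## The fluorescence-assay statistics

The spore-autonomous fluorescence assay scores tetrads as tetratype or
parental ditype without dissection, so its data model is a TT/PD pair per
strain (double-crossover classes are not scored). `classify_phenotype()`
tests a mutant against a wild-type and a null control; both p-values enter
one Benjamini–Hochberg family and "distinguishable" means rejected at the
stated FDR (5% default). Distinguishable from the null only → wild-type
like ("+"); from wild-type only → null-like ("−"); from both →
intermediate ("INT"); from neither → indeterminate. `assay_analysis()`
applies this across a table of strains, with the BH family being all
comparisons in the one invocation (one panel's worth) — families are never
pooled across panels.

Both a two-tailed Fisher's exact test (default, probability-mass
convention for the two-sided p, with the standard $1+10^{-7}$ tie
tolerance) and a 2×2 Pearson χ² without continuity correction are
provided; the choice is recorded in every output. The calibration property
holds by construction: for strains truly at the wild-type fraction, "−"/
"INT" calls require rejecting the vs-wild-type test, so their rate is
bounded by the FDR (measured ≈ 0.7–3% at n = 1000 tetrads per strain,
reflecting the conservativeness of the exact test).

## The meiosis simulator

The generator is a standard counting-model surrogate for crossover
interference, chosen for controllability rather than mechanistic fidelity:

* **Class I (interfering) crossovers** follow a stationary gamma renewal
  process along genetic distance with shape $\nu \ge 1$ and mean spacing
  $1/(2(1-p_2))$ Morgans at the bivalent level. $\nu = 1$ is Poisson (no
  interference); $\nu = 10$ gives strong interference.
* **Class II crossovers** are an independent Poisson process at rate
  $2 p_2$ per Morgan, $p_2 \in [0,1]$ being the non-interfering fraction of
  crossover activity.
* Total bivalent rate is 2 per Morgan for every $(\nu, p_2)$: each
  crossover involves 2 of 4 chromatids, so the per-chromatid
  (= per-spore) recombination rate matches the configured map. Interference
  redistributes crossovers; it never removes map length.
* The renewal process starts in its **equilibrium (length-biased) interval
  distribution** — in closed form
  $F_e(x) = (\beta/\nu)\,x\,(1-F_\nu(x)) + F_{\nu+1}(x)$ for
  Gamma$(\nu,\beta)$ spacings, drawn by the integer-shape mixture
  (Gamma$(k,\beta)$, $k$ uniform on $1..\nu$) when $\nu$ is integral and by
  numerical inversion otherwise — so marker position along the chromosome
  does not bias local crossover density. The test suite checks the mean
  forward-recurrence distance $(\nu+1)/(2\beta)$ directly.
* **Resolution**: each crossover joins one uniformly chosen chromatid of
  each parent, independently per event (no chromatid interference). Spores
  are obtained by tracing each of the four bivalent strands through its
  exchange points; all exchanges are defined on the original four strands,
  which is what makes one crossover in an interval always produce a
  tetratype and disjoint intervals independent under Poisson placement.
* **Viability**: independent spore death with probability `p_death`, plus
  optional meiosis-I nondisjunction for zero-crossover bivalents
  (probability `p_ndj`), which kills the two spores of the empty pole —
  reproducing the characteristic 4,2,0-viable pattern. An obligate-crossover
  mechanism is deliberately not enforced; zero-crossover meioses occur at
  the model's natural rate.

What the simulator does **not** emulate: gene conversion and heteroduplex
tracts (so simulated data contain no 3:1 segregations), chromatid
interference, crossover homeostasis/assurance, between-chromosome effects,
and locus-specific rate variation. Passing tests on simulated data
therefore validate the *statistics* — estimator calibration, interference
detectability, classifier FDR — not the biological completeness of the
generative model.

## Numerical choices and problem sizes

* `mather_frequencies()` mixes the per-event class recursion over a
  Poisson number of crossovers, truncated when the Poisson tail is below
  $10^{-12}$ relative; its $d \to \infty$ limit is the stationary
  distribution $(1/6, 2/3, 1/6)$.
* Fisher two-sided p-values sum hypergeometric masses with the
  $1+10^{-7}$ relative tie tolerance used by the standard implementations.
* G tests drop zero-total columns before computing df; df = 0 yields p = 1
  with a warning rather than an error, because an all-one-class table is a
  legitimate (if uninformative) observation.
* Undefined statistics (empty Malkova subset, zero denominator, zero
  expected double crossovers) are flagged `NA` with a reason, never
  silently dropped; pipeline warnings never abort a run, malformed input
  always does.
* Validation suites use 5,000-tetrad datasets for map recovery, 50
  replicates of 2,000 tetrads for interference behaviour, 10,000 tetrads
  for oracle-frequency checks and 1,000 simulated strains for classifier
  calibration — sizes at which Monte-Carlo error is a few percent of the
  effects being checked, chosen to mirror (and exceed) the scale of real
  dissection datasets, where a few hundred to a thousand tetrads per
  genotype is typical.
* Map distances are conventionally reported to 1 decimal place (print
  methods); internal arithmetic is full precision.

## Example

```{r example, eval = FALSE}
chrXV <- chrXV_map()
cfg <- sim_config(chrXV, n_tetrads = 2000, nu = 10, p2 = 0.1, seed = 1)
tet <- simulate_tetrads(cfg)

# map distances per interval
for (iv in intervals(chrXV)$interval)
  print(perkins_distance(tally(tet, chrXV, iv)))

# interference across adjacent pairs
interference_summary(tet, chrXV)
```

## Limitations

The Malkova ratio and COC are ratio statistics: with small subset sizes or
short intervals they are noisy, and the package flags rather than fixes
degenerate partitions. The G-test comparison uses the full three-class
composition by default; published analyses do not always state whether the
full or the collapsed comparison was used, so both are exposed and the
choice is recorded in output. No interference *parameter* (gamma-shape MLE)
is estimated from data, and no mapping functions other than Perkins
(Haldane/Kosambi) are provided — these are out of scope by design.
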