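---
title: "Crossover patterning by HEI10 coarsening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crossover patterning by HEI10 coarsening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Class I meiotic crossovers (COs) in Arabidopsis are patterned by the
pro-crossover E3 ligase HEI10, which loads as many small foci along the
synaptonemal complex (SC) and then *coarsens*: HEI10 diffuses along the SC
and is exchanged between the SC pool and the foci, so that large foci grow
at the expense of small ones.  After the roughly 10 hours of pachytene only
a few large, well-spaced foci remain; these recruit MLH1 and mature into
class I COs.  Coarsening through a shared, conserved pool is what produces
crossover interference: a large focus locally depletes the pool, starving
its neighbours.

`meiocross` integrates this model on a single SC of length $L$ (µm).  The
state is the HEI10 concentration $c(x,t)$ (a.u./µm) on the SC plus the
amounts $M_i(t)$ (a.u.) of $N$ point foci at fixed positions $x_i$:

$$c^{\mathrm{eq}}(M) = c^{\mathrm{eq}}_0 \frac{M}{1 + M^{1+\alpha}},\qquad
\frac{dM_i}{dt} = \Lambda\left[c(x_i) - c^{\mathrm{eq}}(M_i)\right],$$

$$\frac{\partial c}{\partial t} = D\,\partial_x^2 c -
\Lambda \sum_i \delta(x - x_i)\left[c(x_i) - c^{\mathrm{eq}}(M_i)\right],$$

with no-flux boundaries, so total HEI10 is conserved.  $c^{\mathrm{eq}}$
rises, peaks and falls with $M$; its decreasing branch is the coarsening
instability.  Foci whose final amount strictly exceeds
$M_{\mathrm{thresh}}$ are designated CO sites.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 1.1 | µm²/s | HEI10 diffusivity along the SC |
| `Lambda` | 2.1 | µm/s | SC–focus exchange rate |
| `alpha` | 0.25 | — | exponent of the equilibrium curve |
| `c0_eq` | 1.35 | a.u./µm | base equilibrium concentration |
| `y` | 2 | — | HEI10 dosage factor (genotype) |
| `m_init_base`, `sigma_init_base` | 3.4, 1.1 | a.u. | initial focus amounts: truncated normal, mean `y*3.4`, sd `y*1.1`, cut at ±3 sd |
| `c_init_base` | 1.4 | a.u./µm | initial SC concentration `y*1.4` |
| `focus_density` | 4 | foci/µm | initial focus density |
| `duration` | 36000 | s | pachytene duration (10 h) |
| `n_grid` | 50 | — | grid nodes spanning `[0, L]` |
| `m_thresh` | 3 | a.u. | MLH1-designation threshold |
| `dt_safety` | 0.25 | — | fraction of the Euler stability limit |

The dosage factor `y` represents genotype: 2 for wild-type Col, 6 and 8 for
heterozygous and homozygous HEI10 overexpression in Col, 1.5 for the
wild-type Col/Ler hybrid (the Ler allele is less active) and 5.5 for the
overexpressor hybrid (`genotype_presets()`).

## Numerical choices

*Discretisation.*  `n_grid` nodes span $[0, L]$ inclusive
($\Delta x = L/(n_\mathrm{grid}-1)$; "50 grid points" is read as 50 nodes,
and a grid-refinement test checks the designated-focus counts are
insensitive to this choice).  Each focus exchanges with its nearest node;
the $\delta$-function is discretised as a node-local sink of magnitude
$\Lambda/\Delta x$, so the amount a focus gains is exactly the amount its
host cell loses and $\Delta x \sum_j c_j + \sum_i M_i$ is conserved to
round-off (the suite requires relative drift < 1e−8 over a full 10 h run).
Several foci may share a node; their sinks add.

*Time stepping.*  Explicit Euler with
$dt = \texttt{dt\_safety}\cdot\min\!\big(\Delta x^2/2D,\; \Delta x/(\Lambda
k_{\max})\big)$, where $k_{\max}$ is the largest number of foci on one node
— the stability limits of the diffusion and exchange terms.  $dt$ is then
shrunk so an integer number of steps lands exactly on the duration.  At the
default `dt_safety = 0.25` the solution is effectively converged: halving
$dt$ changes final focus amounts by ~1e−12 relative (the suite asserts
< 1e−3).

*Boundaries.*  The zero-flux condition is imposed in conservative flux
form: boundary nodes receive only their single interior flux.  This is the
discretisation for which the equal-weight total
$\Delta x \sum c_j + \sum M_i$ is conserved exactly.

*Positivity.*  If a step would drive $M_i < 0$ the outgoing flux is
limited so the focus empties exactly; empty foci stay in the system and may
regrow (since $c^{\mathrm{eq}}(0)=0$, an empty focus only absorbs).  The
original description leaves removal-vs-clamping open; clamping is chosen
because it preserves conservation with no extra bookkeeping.

*Symmetry.*  The Laplacian stencil groups its neighbours symmetrically, so
mirroring a system about $L/2$ reproduces the mirrored state bit-for-bit
(when foci occupy distinct nodes; shared nodes change the floating-point
summation order).

*Initial foci.*  "Positioned uniformly" is read as i.i.d. uniform random
positions — repeated simulations are meant to vary — with an `"equal"`
spacing option for deterministic experiments.  Truncated-normal amounts are
drawn by rejection.

## From bivalents to populations

A cell is five independent SCs (`karyotype()`); designated foci summed over
them predict the cell's MLH1 count.  A transmitted chromatid keeps each
bivalent CO independently with probability 1/2, and positions map linearly
from µm to Mb.  SC lengths are *configuration*, not measurement: the
defaults (female 24, 21, 17, 15, 19 µm; male 1.6× — the measured
male:female factor) are plausible working values, and quantitative work
should substitute real ones.

The `zyp1` mutant lacks the SC, coarsening is no longer confined per
chromosome, and interference disappears.  It is modelled per chromatid:
CO counts are Poisson (means per chromosome, or a per-chromatid-set total
apportioned by genomic length) and positions i.i.d. uniform.  Cell-level
focus counts use bivalent-level draws at twice the chromatid mean.

## Interference statistics

* `two_co_distances()` — distances between the two COs of exactly-two-CO
  chromosomes.
* `permutation_null()` — the no-interference reference: pool all CO
  positions of the exactly-two-CO population per chromosome, take all
  pairwise distances, and downsample per chromosome to match the observed
  chromosome shares.  `compare_distance_distributions()` applies a
  two-sided Mann–Whitney test (exact enumeration when both groups have ≤ 8
  values, normal approximation with tie correction above).
* `coc_curve()` — each chromosome is cut into 13 equal-Mb intervals;
  occupancy is presence (≥ 1 CO) per interval per sample; for a pair of
  intervals CoC = observed double-presence frequency over the product of
  the marginals.  Pairs with zero expectation are omitted; curves from
  several chromosomes are averaged by interval separation (the per-pair
  table is also returned, so either per-chromosome or averaged curves can
  be plotted).  Chromosome 4 is conventionally excluded in the hybrid
  analyses (translocation/inversion) via `exclude = "Chr4"`.
* `co_density_profile()` — 1 Mb windows, 50 kb step, counts per sample.
* `co_count_summaries()` — per-chromosome means, Pearson correlation with
  genomic length, between-chromosome count correlations.

Because a crossover table only has rows for samples *with* COs, functions
take the sample universe from the `samples` attribute set by the
simulators/readers (or an explicit `samples =` argument) so zero-CO
chromatids count in denominators.

## Crossover calling and screening

Sliding-window genotyping (50 kb window, 25 kb step): windows classify as
homozygous-Col (Col allele frequency ≥ 0.95), heterozygous (0.25–0.75) or
ambiguous; the thresholds and the ≥ 4-window confident-run rule are
declared defaults (the published pipeline delegates them to its own
caller), exposed as arguments.  Four consecutive windows (~125 kb of
evidence at the default step) were chosen because three-window runs still
admit occasional blip blocks from transition-zone windows and
sparse-marker noise at shallow depth.  Ambiguous/empty windows are skipped without
breaking runs.  A transition between confident blocks yields one call whose
interval runs from the start of the last left-block window to the end of
the first right-block window — with dense error-free markers this interval
provably contains the breakpoint — and the point position is uniform in
the interval.  Overlapping call intervals merge.  Sample QC fails low
coverage (< 0.1×) or contamination (> 5% of informative windows with Col
allele frequency 0.8–0.9).

The aneuploidy screen compares 100 kb window depths between chromosome
pairs (Mann–Whitney, Benjamini–Hochberg across a sample's pairs) and flags
a chromosome only when both the fold change (> 1.2) and the adjusted
p-value (< 1e−20) pass against a majority of the other chromosomes; the
threshold is applied to the *adjusted* p-value (the stricter reading of the
published rule; `adjust_first = FALSE` restores the other).

## What the synthetic data do and do not emulate

`generate_population_markers()` emulates a BC1 backcross to Col: gamete
haplotypes alternate Col/Ler blocks at the true breakpoints, so samples are
mosaics of Col-homozygous and heterozygous segments (never Ler/Ler); reads
per marker are Poisson at the mean depth with binomial allele split and
per-read flip errors; recombination-suppressed masks (pericentromeres,
inversions) receive no breakpoints.  Trisomic samples carry three copies —
the two homolog-derived copies are modelled as complementary along the
whole chromosome (a simplification of meiosis I nondisjunction, which in
reality is complementary only centromere-to-first-CO), giving 1.5× depth
and a 2/3 Col allele frequency including at the centromere.  Not emulated:
alignment artefacts, depth waves (GC, mappability), structural-variant
mis-genotyping, marker ascertainment bias.  Passing recovery tests on these
data therefore validates the calling logic, not robustness to real-world
alignment noise.

## Problem sizes

Simulating one 10 h bivalent takes on the order of a second (the exchange
term, not diffusion, limits the stable step, giving ~3.7 million Euler
steps for a 24 µm SC).  The package's own experiments are therefore sized
in the hundreds of bivalents: the acceptance script uses 10,000 chromatids
for the zyp1 CoC calibration (sampling error ≪ the 0.05 tolerance), 30
cells per karyotype for the SC-length ratio (the ratio's standard error is
about 4%, against a 10% tolerance) and 200 bivalents for the wild-type
adjacent-interval CoC (whose expectation is near 0, far from the
no-interference value 1).  The test suite uses smaller sizes of the same
designs.

## Known limitations

* The coarsening model is 1-D and deterministic between exchange events; no
  Gillespie-style stochastic exchange, no nucleoplasm-mediated exchange
  variant for *zyp1* (the Poisson/uniform null is used instead, as in the
  published Methods).
* Class II (non-interfering) COs are not modelled; measured CO counts in
  genotypes where class II matters will exceed the model's class I
  prediction.
* The µm→Mb map is linear; real recombination landscapes are not, so
  simulated CO *positions* are comparable only at broad scale.
* Designation uses a hard threshold at the end of a fixed duration; the
  alternative stopping hypotheses (focus-size cap, obligate-CO checkpoint)
  are not implemented.
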