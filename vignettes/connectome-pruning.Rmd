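---
title: "Methods: constraint-based pruning of potential synapses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based pruning of potential synapses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synprune)
```

## The model

`synprune` operates on *apposition tables*: rows describing candidate
synapse sites between a presynaptic axon and a postsynaptic neurite, each
carrying the ordered neuron pair, the postsynaptic compartment, a 3D
position, the axonal arc length from the axon root, and the membrane gap.
Two generators produce such tables at different fidelity: a geometric one
(polyline morphologies plus touch detection) and a purely statistical one
that samples apposition counts per connected pair directly from the
geometric law

$$P(n = k) = (1 - p)^{k - 1}\, p, \qquad k \in \{1, 2, \dots\},$$

with $p = 1/S_m^{struc}$ the reciprocal mean apposition count. The zero
class is represented by the "not apposed" pair state, not by a count of
zero. This law is the load-bearing assumption of the whole derivation: it
is closed under independent thinning (a binomially thinned geometric,
conditioned on at least one success, is again geometric) and it is
memoryless (the excess over any threshold is again geometric). Both
properties are asserted as chi-squared tests in the suite.

### The three pruning steps and their closed forms

Given targets $S_m$ (mean synapses per connection), $S_{sd}$ (its SD) and
$B_d$ (bouton density of the presynaptic m-type, synapses per μm of axon):

1. **General pruning.** Each potential synapse survives with probability
   $f_1$. Thinning maps geometric($p$) to geometric($p'$) with
   $p' = p / (p + f_1 (1 - p))$; solving for the thinning fraction gives
   $f_1 = \frac{p}{1-p}\cdot\frac{1-p'}{p'}$. The target
   $p' = 1/(S_{sd} + 0.5)$ comes from matching the SD of the eventual
   post-cutoff distribution: after a left-tail cut at threshold $t$ the
   distribution is $t - 1 + \mathrm{geometric}(p')$, whose SD
   $\sqrt{1-p'}/p' \approx 1/p' - 0.5$ for the relevant $p'$ range.
2. **Multi-synapse pruning.** A connection with $N_s$ surviving synapses is
   kept with probability $\sigma(N_s) = (1 + e^{-(16/\mu_2)(N_s -
   \mu_2)})^{-1}$ — a sigmoid centred at $\mu_2$ with transition width
   $0.25\,\mu_2$ (slope $16/\mu_2$). Matching the post-cutoff mean
   $t - 1 + 1/p'$ to $S_m$ with $t = \mu_2$ yields
   $\mu_2 = 0.5 + S_m - S_{sd}$. Connections thinned to zero synapses in
   step 1 are dropped before this step (their pair simply remains
   unconnected; the alternative of retaining them as empty records changes
   nothing downstream and is not implemented).
3. **Plasticity-reserve pruning.** Connections become active independently
   with probability $a_3 = B_d / B^2$, where $B^2$ is the synapse density
   after steps 1–2 if every surviving connection were realized. Removal is
   independent of synapse count, so the shape of the synapse-count
   distribution is untouched; removed connections form the reserve pool.

The SD target is interpreted on the post-pruning distribution; by
memorylessness the post-step-1 and post-step-3 SDs agree in expectation,
which is the working assumption the round-trip tests verify.

### Priorities, clamps and degenerate inputs

$f_1$ is clamped to $[0, 1]$. A clamp means the input distribution is
already narrower than the target ($p' < p$); since the constraint priority
is $S_m > S_{sd} > B_d$, $\mu_2$ is then re-solved numerically so the
analytic post-step-2 mean still equals $S_m$. The post-step-2 mean is *not*
monotone in $\mu_2$ — the transition width grows with the offset, so very
large $\mu_2$ flattens the cutoff again — hence the solver scans a 60-point
log-spaced grid on $[0.5, 50]$ for a sign change on the rising flank and
bisects it to $10^{-4}$; an unattainable target returns the grid argmax
(best effort, flagged through `f1_clamped`). $a_3$ clamps to $[0, 1]$ with
its own flag, and a reserve-rule warning is raised whenever $a_3 > 0.5$,
i.e. when less than half of the viable connections would remain in reserve.
Other guards: $S_{sd} \le 0.5$ is rejected (the $p'$ formula would leave
$(0,1)$), predicted $S_{sd}$ is floored at $0.5 + 10^{-6}$, predicted
$S_m$ at 1 (the square-root fit turns negative below
$S_m^{struc} \approx 1.2$), and $\mu_2$ at $10^{-3}$.

`expected_survival()` is the analytic oracle behind $B^2$: an exact sum
over $k \sim \mathrm{geometric}(p)$ truncated at the $1 - 10^{-9}$
quantile, $j \sim \mathrm{Binomial}(k, f_1)$, and $\sigma(j)$ acceptance.
The sigmoid is evaluated through `plogis()`, which cannot overflow. The
suite checks this sum against 10⁶-draw Monte-Carlo within 3σ.

## Touch detection

Appositions between morphologies are found as segment pairs whose
surface-to-surface distance (closest centreline approach minus both radii,
floored at 0) is at most the touch distance of the presynaptic synapse
class — 2.5 μm excitatory, 0.5 μm inhibitory. Surface rather than
centreline distance is used because touch distances describe the
spine-plus-bouton gap bridged from membrane to membrane. The spatial index
is a uniform cell grid with cell size equal to the touch distance plus the
longest segment plus the largest diameters, so no true pair can span more
than one cell boundary; the suite asserts exact set equality against a
quadratic all-pairs scan. Contiguous touching segment pairs (adjacent along
both arbors, 8-connectivity on the segment-index grid) merge into one
apposition at the minimum gap: one apposition per contact region. Since the
granularity of an "apposition" is a modelling convention rather than a
measurable, the merge is a tunable (`merge_adjacent = FALSE` keeps every
segment pair).

The preparatory compartment filter is rule-based and most-specific-first.
Defaults: chandelier-type axons (m-types matching `ChC`) target exclusively
the axon initial segment of pyramidal targets; E→E appositions are allowed
on dendrites only (never somata); all other pathways may target dendrite
and soma; axonal shafts are never targets. One source convention is
genuinely ambiguous — target compartments for unexceptional pathways are
sometimes stated as "dendrite or axon", which collides with the axo-axonic
exclusivity of chandelier cells; we read it as dendrite-or-soma and make
the rule table overridable in the run configuration. The AIS is a derived
compartment: the first 40 μm of axonal arc (configurable), a documented
convention rather than a measured extent.

## Randomness and reproducibility

All stochastic operations draw from named substreams of one root seed
(placement, arbors, appositions, the three pruning steps, patch sampling),
so any stage can be re-run in isolation and reproduces bit-identically.
Rather than counter-based per-row RNG addressing, each stochastic step
sorts its input into a canonical order (pathway, pre, post, arc length)
before drawing, which makes results independent of the caller's row order —
the suite asserts this by permuting inputs.

## What the generators emulate — and what they do not

The statistical generator reproduces exactly the features the derivation
relies on: geometric apposition counts per apposed pair, a configurable
apposed fraction (optionally distance-dependent), uniform arc-length
placement along a fixed axon length. The geometric generator adds branched
random-walk arbors with a vertical orientation bias. Neither reproduces
real reconstructed morphologies: no diameter taper, no bouton clustering,
no layer-specific arborization targeting, no correlation between apposition
count and inter-soma distance beyond the apposed-fraction profile. Passing
the round-trip tests therefore shows that the closed forms invert the
pruning process correctly *under the geometric law*; it does not show that
real microcircuits satisfy that law — that is an empirical input, supported
in the literature for cortical reconstructions. The synthetic volume is a
box rather than a cylinder; all metrics take the analysis volume or region
as parameters so the choice does not leak into statistics.

Fixture growth parameters (arbor lengths of 120–200 μm, one or two
branches, 8–10 μm steps) are free choices sized so that tens-of-neuron
circuits produce a few hundred appositions — enough for set-equality
oracle tests at interactive speed.

## Problem sizes and tolerances in the suite

Parameter-recovery tests run 20 random parameterizations at 10⁵ connections
each, with tolerances 10% ($S_m$), 15% ($S_{sd}$) and 10% ($B_d$): the
closed forms are stated approximations (the sigmoid is not a hard
threshold), so their residual bias plus sampling noise at 10⁵ connections
sets the scale. "Valid" parameterizations are drawn from the regime the
package's own constraint predictor generates — $S_m^{struc} \in [2.8, 6]$,
$S_m$ within ±10% of the E–E structural fit, $S_{sd} = 0.32\,S_m$,
$a_3 \in [0.15, 0.45]$ — because the approximation demonstrably degrades
when $\mu_2 \lesssim 2.5$ (a regime the cv-coupled constraints never
produce: there the sigmoid's softness inflates the realized mean by more
than 10%). This is a documented limitation, not a hidden one: callers
deriving parameters with $S_m - S_{sd}$ below ~2 should expect upward bias
in the realized mean. Goodness-of-fit checks use chi-squared at α = 0.01
with expected bin counts ≥ 5 and a lumped tail.

## Capacity interpretation

The wiring-capacity fraction uses the normalized binary entropy
$H(a_3)/H(0.5)$: the information in the choice of active connections among
viable ones, per connection. This reproduces the reported 88% at
$a_3 = 0.3$ exactly; at $a_3 = 0.1$ it gives 46.9%, which the source
literature rounds to "50%". The mean-Hamming-distance interpretation
($4a_3(1-a_3)$) gives 84% at 0.3 and was rejected because it does not
match the reported value.

## Reference tables and their correlations

Three TSV tables bundled under `inst/extdata/` compile published
connectivity statistics for rat somatosensory cortex: synapses per
connection for 38 pathways, connection probabilities within 100 μm for 14
pathways, and bouton densities for 40 m-types, each with apposition-based,
pruned, predicted and biological columns.
`validate_reference_correlations()` recomputes the four headline Pearson
correlations from these printed columns. One of them (pruned vs. biological
connection probability, r = 0.71, N = 14) reproduces the reported value
exactly; the other three reported figure-level correlations (0.87, 0.78,
0.38) were evidently computed on unrounded or differently aggregated data
and recompute from the printed columns as 0.86, 0.71 and 0.24. The package
reports what the printed data give; the `validate-tables` CLI subcommand
exits non-zero while any recomputed value differs from its reported
counterpart at two decimals.

## Known limitations

* The closed forms assume geometric apposition counts; heavy-tailed or
  underdispersed inputs void the $f_1$/$\mu_2$ derivation (fit quality can
  be checked with `fit_geometric()` plus the bundled chi-squared helper).
* $B^2$ is computed in synapse-density units; the sub-μm bouton merge is
  applied only on the measurement side (`bouton_stats()`), so derived
  $a_3$ values are conservative by the multi-synapse-bouton fraction
  (~20% in cortical data).
* The in-silico patch protocol generates coordinate sets matching the
  published summary statistics (46 sets, sizes 8.2 ± 3.4 truncated to
  [2, 12]) rather than the unpublished recorded coordinates; real
  coordinate files can be supplied instead.
* Touch detection is exact but quadratic in neurons; it is meant for
  desk-scale fixtures and validation, not for full-scale reconstructions.
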