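---
title: "Evaluating the Productivity Susceptibility Analysis with operating-model simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating the Productivity Susceptibility Analysis with operating-model simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psasim)
```

## The question

Productivity Susceptibility Analysis (PSA) rates a fish stock on a handful
of ordinal attributes — life-history traits that proxy *productivity*
(age and size at maturity, maximum age and size, stock-recruitment
steepness) and fishery-interaction traits that proxy *susceptibility*
(spatial availability, encounterability of large fish, length-based
selectivity, discarding) — each scored 1 (low risk), 2 or 3 (high risk).
The overall productivity score $P$ is the arithmetic mean of its attribute
scores; the susceptibility score $S$ is either the arithmetic
("additive") or the geometric ("multiplicative") mean; and the
vulnerability score combines them as the Euclidean distance from the
origin,

$$V = \sqrt{P^2 + S^2}, \qquad \sqrt{2} \le V \le \sqrt{18},$$

with category thresholds at 2.64 and 3.18 (the terciles of $V$ if $P$ and
$S$ were uniform on $[1,3]$; `tercileThresholds()` reproduces them by
Monte Carlo, and the exact 2-D integral gives 2.6449 and 3.1727).

`psasim` asks the quantitative question behind this scheme: *if* every
attribute score were backed by its stated parameter range in a
conventional age-structured population model, how well would $V$ predict
the probability of the stock actually breaching a biomass reference
point? Two variants are implemented: the 9-attribute standard PSA (sPSA)
and the 12-attribute extended PSA (ePSA), which adds the intrinsic rate
of increase $r$, the von Bertalanffy growth rate $K$ (both *derived*
quantities, never free parameters) and current depletion.

## From scores to operating models

Every attribute carries one closed numeric interval per score level,
shipped as an editable YAML registry (`psaAttributes()`). Open-ended
published categories are closed at biologically motivated bounds
(size at maturity in [5, 450] cm, $K$ in [0.02, 1] yr$^{-1}$, proportions
in [0, 1]); the registry file documents each closure.

Given a score vector, parameters are drawn uniformly within their scored
intervals, subject to joint constraints reflecting empirical life-history
regularities: $M/K \in [0.3, 4]$, $L_{mat}/L_\infty \in [0.3, 0.9]$, and
age at maturity at most 60 % of maximum age. Three quantities are derived
rather than sampled:

* natural mortality from maximum age, $M = -\log(0.01)/A_{max}$ (1 % of a
  cohort reaches the maximum age);
* growth rate from the maturity schedule, $K = -\log(1 -
  L_{mat}/L_\infty)/a_{mat}$ (the von Bertalanffy curve passes through the
  maturity point, with $t_0 = 0$);
* the intrinsic rate of increase $r$ from the Euler–Lotka balance
  $1 = \sum_a \varphi_a e^{-ra}$, where $\varphi_a = \alpha_0\, e^{-Ma}\,
  \mathrm{mat}_a\, w_a$ and $\alpha_0 = 4h/((1-h)\,\mathrm{SPR}_0)$ is the
  maximum recruits-per-spawning-biomass implied by Beverton–Holt steepness
  $h$ (the compensation ratio $4h/(1-h)$ scaled by unfished
  spawners-per-recruit). The published method behind the $r$ attribute
  does not pin down the steepness-to-compensation scaling; this
  formulation is our choice, and `eulerLotkaRate()` is verified against a
  Leslie-matrix eigenvalue oracle.

For the ePSA, a candidate draw is accepted only if its derived $K$ and
$r$ also fall in their scored categories — this is what makes many ePSA
score combinations infeasible.

Qualitative attributes are mapped to two-part draws chosen once and
documented here rather than tuned: the discard score draws a (discard
rate, discard mortality) pair — score 1: rate U(0.5, 1) with mortality
U(0, 0.25); score 2: U(0.25, 0.75) twice; score 3: rate U(0, 0.5) with
mortality U(0.75, 1) — and the selectivity score places the length at 50 %
selectivity $L_c$ relative to the length at maturity (score 1:
U($L_m$, 0.95 $L_\infty$) — capture only above maturity, anywhere up to
(nearly) the asymptotic length, which is what makes the low-risk category
genuinely protective; score 2: U(0.5 $L_m$, $L_m$); score 3:
U(0.1 $L_m$, 0.5 $L_m$)). Encounterability is the selectivity of
the largest individuals: the dome of the selectivity curve descends
quadratically from full selection at $1.1 L_c$ to the scored height at
$L_\infty$. Availability is modelled as the fraction of the stock in the
fished area of a two-area system. Because the stock is assumed fully
mixed between the areas, an area closure confers no protection: the
stock-level exploitation rate is realized regardless of the fished-area
fraction, so under the default `spatial = "mixed"` treatment availability
does not scale removals (it still enters the susceptibility score). The
alternative `spatial = "proportional"` treatment, in which removals scale
with availability, is retained as an option; it corresponds to the
opposite limit of no within-year mixing and makes availability the
dominant susceptibility lever. Length–weight uses
$w = 10^{-5} L^3$; since recruitment is normalized ($R_0 = 1$) and all
risk metrics are ratios, the length–weight scale cancels everywhere.

## Population dynamics

The simulator is an annual, age-structured model with ages $0 \dots
A_{max}$ and a plus group. Within a year: spawning biomass is computed
from start-of-year numbers; recruitment is Beverton–Holt,
$R = \alpha S/(1+\beta S)$, parameterized by steepness with multiplicative
lognormal AR(1) deviates, $\epsilon_t = \rho\,\epsilon_{t-1} +
\sqrt{1-\rho^2}\,\eta_t$, bias-corrected so deviates have mean 1, with the
recruitment CV drawn U(0.3, 0.9) and autocorrelation U(0, 0.9); removals
(exploitation rate $U$ times the effective vulnerability-at-age) are taken
before natural survival $e^{-M}$. Deterministic projections converge to
the closed-form Beverton–Holt equilibrium — with spawning potential ratio
$p$, relative recruitment is $(4hp - (1-h))/((5h-1)p)$ — which the test
suite checks to $10^{-3}$ in depletion across a steepness–exploitation
grid.

Each simulation runs 50 historical years from the unfished state under a
linearly increasing exploitation ramp whose terminal height is solved by
bisection so that final-year depletion $SSB/SSB_0$ hits a target within
±0.005 (the ramp is the simplest monotone history; the depletion, not the
path, is the controlled quantity). Per-age removal fractions on the ramp
are clamped at 0.99, so the ramp intensity may exceed 1 while
vulnerability is below 1 — under full mixing, sustained effort can remove
more than the instantaneous available fraction; without this, stocks with
low susceptibility could never reach the Low-status depletion targets and
that scenario would degenerate. Genuinely unreachable targets (effective
vulnerability ~0) keep the closest achievable depletion and are counted
(`nUnconditioned`) rather than silently redrawn, since redrawing
recruitment deviates cannot fix a deterministic shortfall. The stock is
then projected 50 years at a fixed exploitation rate (0.2, 0.4 or 0.6).

Risk is the fraction of simulations in which spawning biomass falls
below a reference point — $0.5\,B_{MSY}$, $0.2\,B_0$ or $0.1\,B_0$, with
$B_{MSY}$ from a grid-plus-refinement search over equilibrium yield — in
projection years 41–50. "Below the reference points in years 41–50" is
ambiguous between a simulation dipping below at any point in the window,
staying below throughout, or a per-replicate-year average; the
per-simulation any-year indicator is the default (it is the only reading
under which the metric is literally a fraction of simulations), and the
`rule` argument of `riskProbability()` exposes the other two.

### Parameter uncertainty within a scoring combination

Two simulation modes are provided. The scalar mode
(`sampleOperatingModel()` + `simulatePopulation()`) fixes one parameter
set per scoring combination, with replicates differing only in
recruitment deviates; it is the transparent object for unit testing and
diagnostics. The ensemble mode (`sampleEnsemble()` +
`simulateEnsemble()`, the default in `simulateDesign()`) draws a fresh
parameter set *per replicate* — including the depletion target, the
recruitment CV and autocorrelation, and per-replicate unfished and MSY
reference points. The ensemble mode is the faithful reading of the
simulation design this analysis replicates (its operating models carry
parameter *ranges*, resampled each simulation): a combination's risk then
integrates over the parameter uncertainty its scores leave open.
Empirically this matters a great deal — with fixed parameters the risk
probabilities are nearly binary (over half the combinations have risk
exactly 0 at low exploitation) and the risk surface is far from the
smooth published pattern, while the ensemble reproduces it.

## The experimental design

Evaluating all $3^9 = 19{,}683$ (sPSA) or $3^{12} = 531{,}441$ (ePSA)
scoring permutations is unnecessary; instead the design enumerates them,
drops combinations for which no jointly feasible parameter set exists
(decided by bounded rejection sampling, 1,000 draws per combination under
a fixed internal RNG substream so the predicate is pure; feasibility
depends only on the productivity scores, so results are memoised), bins
the $(P, S)$ pairs into an 8×8 grid of equal-width classes (1–1.25, …,
2.75–3.0; half-open with a closed top class) and samples up to 10
combinations per cell without replacement. Cells left with fewer feasible
members contribute all of them, so a design may hold slightly fewer than
640 rows (the additive sPSA design has 630). Binning uses the same
aggregation method as the downstream scoring — the only self-consistent
choice.

## Evaluation

Four analyses quantify how the simulated risk relates to the PSA scores:

1. **Risk-surface similarity.** Mean risk per 8×8 cell, min–max
   standardized, is compared with the additive expected surface
   $E_{ij} \propto c_i + c_j$ (bin centers) via the Frobenius norm
   $F = \sqrt{\mathrm{trace}(AA^*)}$, $A = E - O$; missing cells are
   excluded pairwise, and a constant observed surface standardizes to
   zeros and is flagged. $F$ is rescaled to a similarity score: 1 when
   $O = E$, 0 at the mean distance of 1,000 uniform random matrices with
   the same mask.
2. **Relative importance.** A linear model of risk on the individual
   attribute scores, decomposed by the LMG method (sequential $R^2$
   averaged over all predictor orderings, computed exactly by subset
   enumeration over $\le 2^{12}$ subsets). Shares are non-negative and
   sum to the model $R^2$, which the tests assert.
3. **Pairwise interactions.** Mean risk per 3×3 grid of score pairs for
   any two attributes; empty cells mark infeasible pairings.
4. **Classification.** The PSA category of $V$ (thresholds 2.64/3.18)
   against terciles of the simulated risk (0.33/0.66; boundary values go
   to the lower category, a convention the published inequalities leave
   open): 3×3 confusion matrix, overall accuracy and per-class
   sensitivity, plus re-scoring with reduced attribute subsets
   (`subsetRescoring()`).

## Problem sizes, defaults and reproducibility

The default experiment mirrors the published grid: one shared design per
variant and aggregation method, 10 combinations per cell, 100
replicates per combination, exploitation rates 0.2/0.4/0.6, sPSA
initial-status scenarios Low/Medium/High (terminal depletion U(0.025,
0.25), U(0.25, 0.4), U(0.4, 0.8)), three risk metrics — 54 sPSA and 18
ePSA analysis cells. A full design-scenario simulation (≈640 models ×
100 replicates × 100 years) takes a few minutes on one core; the unit
tests use reduced designs (1–2 per cell) and replicate counts.

All randomness flows from a master seed through stable label hashes
(`design`, per-row `om`/`sim` substreams), so adding scenarios never
perturbs existing cells and every cell can be re-run in isolation from
the manifest. Feasibility screening uses its own fixed substream and is
unaffected by the master seed.

## What the generator does and does not emulate

The synthetic design spans the full scoring space evenly, which real PSA
applications do not — most real stocks score mid-range, precisely where
the vulnerability score discriminates worst. Scores are assumed known
without observation error, an optimistic simplification. Excluded by
construction: the trophic-level attribute (no defensible mapping to the
dynamics), the ePSA management, migration/schooling, morphology and
fishery-value attributes, non-equal attribute weights, multi-fleet and
time-varying selectivity, and explicit two-box movement. Passing tests
therefore speak to the internal logic of the scoring system under its own
stated parameter ranges, not to the accuracy of any particular real-world
PSA application.

## Numerical choices

* Threshold conventions: values exactly at a category boundary (V at
  2.64/3.18, risk at 0.33/0.66, bin edges) go to the lower class.
* Bisection budgets: 20 iterations for the conditioning scaler; MSY by a
  48-point coarse grid plus three shrinking local grids (resolution
  ~$3\times10^{-4}$ in $U$) in the ensemble engine, `optimize()` to
  $10^{-5}$ in the scalar engine.
* Degenerate parameter draws (effectively unfishable fleets with zero
  vulnerability at every age) are dropped from an ensemble with a
  warning; a combination fails only if every draw is degenerate, and
  failed design rows are reported as gaps rather than imputed.
* The geometric mean of integer scores is clamped to [1, 3] against
  floating-point drift at the boundary.
* Missing-attribute policies (`score-as-3`, `drop`) exist in
  `scorePsa()` for completeness but are unused in the simulation design,
  which always has full scores.

## Known limitations

Accuracy and similarity values inherit Monte-Carlo noise from the design
sampling, the per-replicate parameter draws and the recruitment deviates;
with 640 combinations the standard error of an accuracy estimate is about
2 percentage points. The historical effort ramp is one of many plausible
histories; since depletion is controlled, alternatives mainly affect the
age structure at the start of the projection. The upper vulnerability
threshold is quoted as 3.18 in the literature, but the exact tercile
under the uniform assumption is 3.1727; the package keeps the published
2.64/3.18 as classification defaults while `tercileThresholds()` reports
the Monte-Carlo values.
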