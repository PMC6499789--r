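---
title: "Mediator-explicit simulation of microbial coexistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mediator-explicit simulation of microbial coexistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medcoex)
```

## The model

medcoex simulates communities of microbial species whose only coupling is
through chemical mediators — metabolites, toxins, signals — that cells
produce and (sometimes) consume. Shared external resources are assumed to
be supplied in excess, so species are never resource-limited; instead,
each species $i$ grows at a net per-capita rate set by its basal rate and
the concentrations $C_l$ of the $M$ mediators:

$$\frac{dS_i}{dt} = \Big[r_{0i}
  + \sum_l \rho^{+}_{il}\,\frac{C_l}{C_l + K_{il}}
  - \sum_l \rho^{-}_{il}\,\frac{C_l}{K_{il}}\Big] S_i,$$

$$\frac{dC_l}{dt} = \sum_i \beta_{li} S_i
  - \sum_i \alpha_{li}\,\frac{C_l}{C_l + K_{il}} S_i - \lambda_l C_l.$$

Facilitation saturates (Monod form by default; a Moser form with exponent
$n$ is available, and reduces to Monod at $n = 1$). Inhibition is linear
in concentration by default — the form repeatedly seen when growth rates
are measured against increasing concentrations of organic-acid byproducts
— with threshold and saturating ("growth inhibition") alternatives.
Influences of different mediators are additive, and net rates may be
negative. Consumption applies only on *depletable* links
($\alpha_{li} > 0$, with the recipient flagged as a consumer); a
*reusable* mediator influences its recipients without being removed
($\alpha_{li} = 0$), as for a signalling molecule. Mediator decay
$\lambda_l$ defaults to 0; outcomes are insensitive to it except at
extreme rates, so it is exposed but off.

Only live cells produce and consume; death is absorbed into the net basal
rate $r_{0i}$.

### Units and defaults

| quantity | unit | default |
|---|---|---|
| $S_i$ | cells/ml | $10^4$ total at a transfer |
| $C_l$ | fmol/ml | 0 at the start |
| $r_{0i}$ | 1/h | $U(0.08, 0.12)$ |
| $\rho_{il}$ | 1/h | magnitude $U(0, 0.2)$ |
| $K_{il}$ | fmol/ml | $U(0.5, 1.5)\times 10^4$ |
| $\alpha_{li}$ | fmol/cell/h | $U(0.5, 1.5)\times 1$ on depletable links |
| $\beta_{li}$ | fmol/cell/h | $U(0.5, 1.5)\times 0.1$ on production links |
| $dt$ | h | 0.01 |

### The integrator is part of the model

Dynamics advance by forward Euler at $dt = 0.01$ h (the "growth update
and uptake timescale"): densities update multiplicatively,
$S \leftarrow S\,(1 + r\,dt)$ floored at 0, and concentrations clamp at 0
when a step would over-consume. This matters more than it may appear.
Once densities exceed $\sim 10^7$/ml, the consumption term makes the
mediator equations stiff (their relaxation time $K/(\alpha S)$ falls
below $dt$), and the clamped-Euler update equilibrates fully-consumed
mediators slightly differently from the continuous-time limit. We
therefore treat the discrete update as the model itself, and verify
robustness by timestep refinement: on random 5-species communities,
survivor sets are identical at $dt = 0.01$ versus $dt = 0.001$ and
frequencies typically agree to well under one percent — except for a
minority of communities sitting near a boundary between alternative
outcomes (bistability induced by strong inhibition), where any
perturbation, including refinement, can tip the winner. The test suite
measures and reports exactly this.

## Enrichment and the operational definition of coexistence

`run_enrichment()` emulates serial enrichment: all pool members start at
equal proportions at a total density of $10^4$/ml in fresh medium, grow
until the community reaches $10^{10}$/ml (about 20 generations), and are
diluted back to $10^4$/ml, mediators co-diluted; ten rounds make roughly
200 generations. A species whose density falls below 0.1/ml (one cell in
a 10-ml inoculum) at any point is extinct and stays so. A growth round
that fails to reach the dilution trigger within `t_max_per_round`
($10^4$ h) marks the run stalled, scored as no coexistence.

Persistence alone is too generous an endpoint: a species declining
slowly at the end of the run is on its way out even though it has not
crossed the extinction threshold. `coexistence_filter()` therefore
removes, from the final survivors, any species whose final post-dilution
density sits more than 10% (strictly) below a reference level. Two
references are offered:

* `"peak"` (default): the species' running maximum post-dilution density
  over the run. A sustained slow decline — say 4% per round — accumulates
  against this reference and is caught.
* `"previous"`: the density one round (about 20 generations) earlier.
  This is the narrowest reading of a decline test over the final
  20 generations, but a species can decline just under the threshold
  every round and still pass indefinitely.

We made the peak reference the default after comparing both against the
ensemble statistics this class of model is known to produce. Under the
single-round reading, a no-interaction control pool (where near-ties in
basal rate are the only route to coexistence) keeps two or more species
about half the time, because basal rates drawn 20 at a time from
$U(0.08, 0.12)$ routinely contain gaps below $10^{-3}$/h, and such a gap
produces less than 10% decline per round. The peak reference removes the
slowly-declining members of these marginal ties as well as transient
species in interacting pools, and the package's knock-out and
influence-category screens then land where a stabilizing-interaction
analysis says they should. The remaining survivors of the filter define
the *derived community*.

`stability_check()` re-runs a derived community alone, from equal
proportions, for another full enrichment and asks whether the same set
coexists again; `perturbation_recovery()` instead kicks the steady
frequency pattern and asks whether it returns, distinguishing stabilized
coexistence from neutral ties.

## Random pools

`sample_pool()` draws binomial bipartite networks: each species→mediator
production link is present with probability $q_p = 0.2$, each
mediator→species influence link with $q_c = 0.2$; influence signs are
facilitative with probability `fac_fraction`, magnitudes uniform on
$(0, \rho_{\max})$, and each influence link is depletable with
probability `depletable_fraction`. Consumption is attached only to
influence links: a species consumes a mediator only if the mediator
influences it. Self-links are allowed and uncorrelated — a species may
produce a mediator that influences itself (self-facilitation or
self-restraint) — so that sampling is unbiased across the four influence
categories.

The draw order is fixed and full matrices are drawn before masking, so
two specs sharing a seed but differing in one parameter (say,
`depletable_fraction`) produce pools identical except where that
parameter bites. The matched-seed construction is what
`mechanism_screen()` and `strength_sweep()` use to isolate the swept
parameter.

Two defaults deserve a note. The number of mediators defaults to 15, the
value used by the screen conditions this package reproduces (a smaller
pool of 10 appears in some parameter listings; pass `n_mediators`
explicitly to change it). And `rho_max` is the *maximum* influence
magnitude; the realized mean strength is $\rho_{\max}/2$, which is the
scale `strength_sweep()` reports against the basal-rate spread
$\sigma_{r0} = 0.04/\sqrt{12} \approx 0.0115$/h.

## Screens

`enrich_ensemble()` runs enrichment plus the filter over hundreds of
sampled pools and tabulates per-pool richness and influence-category
fractions. Derived-community influence links are counted as *active*
when the recipient survives, at least one producer of the mediator
survives, and the mediator's end-state concentration is nonzero — a link
whose mediator is consumed to exactly zero exerts no influence on the
realized dynamics and is excluded from category statistics (this is a
0-versus-nonzero distinction, not a tunable threshold). Category
statistics condition on qualifying pools: a derived community of at
least two species with at least one active influence, since a community
with no active influence has no defined category fractions (these are
the neutral near-ties).

`mer()` summarizes an ensemble as mean excess richness,
$\sum_i (i-1) p_i$ — the average richness beyond the single survivor
competitive exclusion predicts — with a nonparametric bootstrap interval
(3000 resamples).

`knockout_screen()` removes one influence at a time. From the initial
pool, it reruns the whole enrichment and records the richness change;
from the derived community, it re-simulates the (stability-verified)
community without the link and records disruption. Both the stability
pre-check and the disruption call default to the persistence reading —
the community is stable, and a knock-out harmless, when every original
member still persists after another full enrichment (stalls and
collapses count against) — with the stricter filter-level reading
(`disruption = "filter"`, `criterion = "coexistence"`) available. Under
the peak-referenced filter the stricter reading flags any member that
ever dips below its running maximum, which conflates slow transients
with loss of coexistence; asking the same persistence question in both
places keeps the screen self-consistent.

Ensemble sizes in the tests and the acceptance script are desk-scale:
300–1,500 pools per condition for category statistics, ~2,600 pools for
the knock-out screen (yielding >100 tested self-restraint links), 250
matched pools per strength level, and 120 matched pools per depletable
fraction. Published screens of this kind use $10^4$–$3\times 10^4$
pools; at desk scale the sampling standard deviation on a fraction near
90% over ~150 qualifying pools is 2–3 percentage points, and subgroup
statistics (communities retaining inhibition; the remainder where
facilitation is not favored) carry proportionally wider error.

## Chemostat analysis

For continuous growth at dilution rate $\delta$, with each mediator
either accumulated far above saturation ($\theta_l = 1$) or depleted
($\theta_l = 0$), the dynamics linearize to
$d\mathbf{S}/dt = (-\delta + \mathbf{r}_0 + \mathbf{P}\Theta)\mathbf{S}$.
`fastest_consistent_subcommunity()` enumerates species subsets (brute
force, capped at 12 species), assigns $\theta$ by a consistency rule —
a mediator accumulates iff some subset member produces it and no subset
member consumes it — and builds the effective growth matrix at mediator
resolution: for each accumulating mediator, its net influence on each
recipient is attributed equally to the mediator's producers *within the
subset* (producer attribution depends on the subset, which is why no
global species-by-species matrix is formed). The winning subset is the
one with the largest leading eigenvalue whose leading eigenvector is
strictly positive; singletons are always consistent, so the best single
species is the automatic fallback. The steady-state chemical fates are
not truly known a priori; this closure is validated only against
simulation on small communities, where it agrees in 9 of 10 hand-built
archetypes (the miss is a transient: a broadly toxic producer kills its
victim on the way to its own exclusion, which no steady-state analysis
can see).

## Growth-curve utilities

`growth_rate_from_od()` implements the standard plate-reader protocol:
per-well background estimated as the mean of readings at time-points
3–10 (the first two dropped), a window of background-subtracted OD
between 0.002 and 0.02 to dodge noise floor and saturation, and a
log-linear fit whose slope is the rate. Because the background window
contains the (small) live-cell signal, the estimate carries an upward
bias that grows with the inoculum-to-window ratio: on a noiseless
exponential with inoculum signal 0.001, the procedure returns 0.357 for
a true 0.300/h. Supplying the known blank via `background=` removes the
bias entirely; a `t_cap` argument restricts the fit to early readings
for assays (e.g. fluorescence-based) where the mediator depletes.

`fit_dose_response()` fits the five response laws to (concentration,
rate) pairs — closed-form for linear inhibition, Levenberg–Marquardt
otherwise, with the Moser exponent constrained to $[1, 3]$. For the
linear law only the slope $r_{inh}/K_{inh}$ is identifiable and is what
`strength_hat` reports. `make_od_fixture()` and
`make_dose_response_fixture()` generate synthetic data with known ground
truth so every procedure is testable without instrument files.

## What the synthetic ensembles do and do not capture

The generator emulates unstructured chemical-interaction networks:
binomial connectivity, signs and strengths independent across links, no
trade-off between producing and being influenced, no energetic ordering
of byproducts, no spatial structure, no evolution within a run, and
shared resources always in excess. Passing screens therefore say that
*under these assumptions* facilitation and self-restraint are what
survives enrichment and that depletable mediators stabilize coexistence;
they do not say that real communities have binomial networks, and
richness in real enrichments (where resource partitioning and spatial
refuges also operate) is expected to exceed what this model yields.

## Numerical choices, edge cases

* Dilution requires a live community; an all-extinct culture raises a
  collapse condition, and screens score collapsed or stalled runs as no
  coexistence.
* A species exactly at the decline threshold (final density exactly 90%
  of the reference) is retained — removal requires a strict `>10%` drop.
* `c_th` (threshold laws) defaults to 0, making the threshold law
  coincide with the linear law.
* Consumption clamping: if an Euler step would drive $C_l < 0$ it is set
  to 0 for that step; mass cannot go negative.
* Eigenvector positivity uses a $10^{-9}$ tolerance after normalizing by
  the largest-magnitude component; complex leading pairs are treated as
  inconsistent.
* `mer()` excludes nothing: stalled/collapsed pools enter as richness
  ≤ 1 so the statistic cannot be inflated by discarding failures.

## A small worked example

```{r}
p <- sample_pool(pool_spec(fac_fraction = 0.8, depletable_fraction = 1,
                           seed = 7))
dc <- derive_community(p)
dc$result
dc$derived
active_influences(p, dc$derived, C = dc$result$final_state$C)
```
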