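# medcoex

Mediator-explicit simulation of microbial community coexistence under
serial enrichment.

## The problem

Microbes with different intrinsic growth rates routinely coexist in
communities — in bioreactors, enrichment cultures and host-associated
microbiota — even though simple competition predicts a single winner.
One candidate explanation is interaction through the chemical
environment: cells secrete metabolites, toxins and signals that raise or
lower the growth rates of other cells, and may consume those chemicals
in turn. medcoex is for researchers who want to ask, by simulation,
*which interaction structures permit coexistence* when species are
coupled only through such mediators and shared resources stay in excess.

## The model

Species densities `S_i` (cells/ml) and mediator concentrations `C_l`
(fmol/ml) follow

    dS_i/dt = [ r0_i + Σ_l ρ⁺_il C_l/(C_l + K_il) − Σ_l ρ⁻_il C_l/K_il ] S_i
    dC_l/dt = Σ_i β_li S_i − Σ_i α_li C_l/(C_l + K_il) S_i

with saturating (Monod or Moser) facilitation, linear (or threshold, or
saturating) inhibition, additive influences, and consumption `α_li > 0`
only on *depletable* links (reusable mediators act without being
removed). Communities are passaged by growth from 10⁴ to 10¹⁰ cells/ml
(~20 generations) and million-fold dilution, ten rounds (~200
generations); species below 0.1 cells/ml go extinct, and species in
sustained decline at the end are filtered out of the *derived
community*. On top of the core dynamics the package provides:

* random binomial interaction-network pools (`pool_spec()`,
  `sample_pool()`) with matched-seed perturbations (sign flips, strength
  scaling, depletable fraction, link knock-outs);
* ensemble screens: richness distributions and mean excess richness with
  bootstrap intervals, influence-category enrichment (self-/other-
  facilitation, self-restraint, other-inhibition), in-silico knock-out
  screens, depletable-vs-reusable comparisons, interaction-strength
  sweeps (`richness_screen()`, `category_enrichment()`,
  `knockout_screen()`, `mechanism_screen()`, `strength_sweep()`);
* a chemostat steady-state analysis that brute-forces the species subset
  with the largest consistent growth eigenvalue
  (`fastest_consistent_subcommunity()`);
* plate-reader utilities: log-linear growth-rate extraction from OD
  series and least-squares fits of five dose-response laws
  (`growth_rate_from_od()`, `fit_dose_response()`), plus synthetic
  fixture generators so everything is testable without instrument data.

## A worked example

```r
library(medcoex)
p <- sample_pool(pool_spec(fac_fraction = 0.8, depletable_fraction = 1,
                           seed = 1))
p
#> <community_params> 20 species, 15 mediators
#>   influence links: 59 (42 facilitative, 17 inhibitory)
#>   production links: 55; depletable links: 59
#>   laws: facilitation = monod, inhibition = linear

dc <- derive_community(p)
dc$result
#> <enrichment_result> 10 rounds, 199.3 generations
#>   survivors: 2, 3, 9, 17, 18

dc$derived
#> [1]  2  9 17

active_influences(p, dc$derived, C = dc$result$final_state$C)
#>    species mediator         sign locus           category   strength depletable
#> 30       2        9   inhibition  self     self-restraint 0.18143975       TRUE
#> 43       2       13 facilitation other other-facilitation 0.08958145       TRUE
#> 27       9        8 facilitation other other-facilitation 0.14333332       TRUE
#> 34      17        9 facilitation other other-facilitation 0.18803044       TRUE
```

Out of a 20-species pool, ten grow–dilute rounds leave five species, of
which the decline filter keeps three as the derived community. The
influences still active among them are three facilitations and one
self-restraint — the two interaction categories that enrichment
characteristically selects for. An ensemble-level summary of the same
question:

```r
pools <- enrich_ensemble(pool_spec(fac_fraction = 0.5,
                                   depletable_fraction = 1),
                         n_pools = 50, seed = 1)
m <- mer(pools$richness, seed = 1)
#> MER = 0.44 (95% CI 0.26-0.64)
```

i.e. these pools support on average ~0.4 coexisting species beyond the
single survivor that competitive exclusion would predict.

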