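# scatcomp

Dietary-competition analysis for sympatric large carnivores from scat
contents and camera-trap surveys.

Community ecologists studying guilds of large predators — African wild
dog, cheetah, leopard, lion, spotted hyaena — need to know how much the
predators' diets overlap, whether diet composition differs between park
areas and seasons, and whether each predator selects prey or simply
takes what is available. The raw data are indirect: prey remains
identified in scats, and camera-trap detection rates standing in for
prey abundance. `scatcomp` implements the full analysis chain, plus a
synthetic-study generator with known ground truth so every stage can be
validated end to end.

## What it computes

- **Ingestion and filtering** — long-format scat tables, prey-trait
  tables, camera and effort tables; pseudo-replication filtering (one
  scat per 24 h within 1 km for lions/hyaenas, one per 24 h per pack
  for wild dogs); season assignment (wet–early dry Nov–Jun vs late dry
  Jul–Oct; nomadic Sep–Apr vs breeding May–Aug); prey size classes
  (XS < 5 kg … XL ≥ 350 kg); exclusion of analysis cells with < 21
  scats.
- **Diet composition** — frequency of occurrence (item and scat
  conventions) and biomass-corrected proportions via the Weaver
  (0.439 + 0.008 m) and Ackerman (1.980 + 0.035 m) kg-per-scat
  regressions with stomach-capacity caps (10/24/50 kg for
  leopard/hyaena/lion); aggregation by water dependency, feeding guild
  and size class.
- **Dissimilarity and PERMANOVA** — scat-level Jaccard
  (A + B − 2J)/(A + B − J) and Bray–Curtis Σ|x−y|/Σ(x+y) matrices and a
  from-scratch one-factor PERMANOVA,
  pseudo-F = (SS_among/(a−1))/(SS_within/(N−a)), with permutations
  stratified by calendar year and an exhaustive-enumeration mode for
  small samples.
- **Overlap and breadth** — Pianka's index
  O_jk = Σ p_ij p_ik / √(Σ p_ij² Σ p_ik²) with a richness-preserving
  randomization null (per-pair seeded streams), and standardised Levins
  breadth B = 1/Σp², Bs = (B−1)/(n−1).
- **Prey preference** — camera-trap RAI (independent records per trap
  day, 30-min chained independence, sector-then-area averaging) and
  Jacobs' index D = (r − p)/(r + p − 2rp) against RAI or a supplied
  density table.
- **Species accumulation** — permutation curves with a closed-form
  hypergeometric expectation as cross-check.
- **Synthetic studies** — `synthetic_config()` / `generate_study()`
  draw a complete study (scats, traits, cameras, effort) from known
  true diets and densities; `recovery_report()` scores pipeline
  estimates against that truth.

## Worked example

```r
library(scatcomp)
study <- generate_study(synthetic_config(), seed = 42)
run <- run_study(study$scats, study$items, study$traits,
                 study$cameras, study$effort,
                 n_perm = 1000, n_iter = 10000, seed = 42)
print(run)
```

```
Dietary-competition analysis
  11 scats dropped by pseudo-replication filter
  12 analysis cells excluded (< 21 scats)
  composition rows: 169; PERMANOVA comparisons: 11
  overall Pianka overlaps:
    cheetah - hyaena: 0.52 (p = 0.106)
    ...
    hyaena - lion: 0.83 (p = 0.0011)
    hyaena - wild_dog: 0.82 (p = 0.0028)
    lion - wild_dog: 0.66 (p = 0.0165)
```

The wild dog's diet overlaps most with the hyaena's (Pianka 0.82) and
the lion's (0.66), and both overlaps are higher than expected under the
richness-preserving null (p < 0.05 at 10,000 iterations). Composition
rows give, per predator and stratum, occurrence counts, both FO
conventions, and the (indicative) biomass proportion — for this seed the
wild dog's diet is dominated by kudu (FO 0.45, biomass 0.66) and impala
(FO 0.25):

```r
subset(run$composition, predator == "wild_dog" & stratum == "All")
#>    predator stratum   species n_items   fo_items   fo_scats biomass_prop
#> 46 wild_dog     All    impala      14 0.25000000 0.26415094   0.16514360
#> 47 wild_dog     All      kudu      25 0.44642857 0.45283019   0.65856956
#> ...
subset(run$breadth, stratum == "All")
#>   predator stratum        B        Bs  n
#> 1  cheetah     All 3.609442 0.1449690 19
#> 5 wild_dog     All 3.364807 0.1313782 19
```

The standardised Levins breadth shows the wild dog as the narrowest
forager of the guild (Bs = 0.13 vs 0.38–0.39 for lion and hyaena).
PERMANOVA comparisons (Jaccard on per-scat species presence, year
strata) test whether the wild dog's diet differs from each competitor
within each area:

```r
run$permanova[1:2, ]
#>               comparison pseudo_F df_between df_within         r2     p_value
#> 1 wild_dog_vs_cheetah:NW 3.983226          1        50 0.07378636 0.003996004
#> 2 wild_dog_vs_leopard:NW 2.377572          1        50 0.04539294 0.051948052
```

and `run$preference` holds Jacobs' selectivity per predator, area and
prey species (here the wild dog prefers kudu, D = +0.49, and avoids the
abundant impala, D = −0.47, in the NW area):

```r
subset(run$preference, predator == "wild_dog" & stratum == "NW")
#>    predator stratum  species          r    p_avail          D
#> 59 wild_dog      NW   impala 0.29629630 0.53968254 -0.4715262
#> 60 wild_dog      NW     kudu 0.37037037 0.16666667  0.4925373
#> ...
```

`recovery_report(study$truth, run)` compares every estimate against the
generating truth.

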