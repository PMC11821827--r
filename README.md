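# benthovuln

Trait vulnerability of benthic communities to mass mortality events (MMEs).

Marine heatwaves, storms, pollution, disease and mucilage outbreaks kill
benthic invertebrates and macrophytes in episodic mass mortality events.
Which *trait combinations* those events remove matters more for ecosystem
function than which species: losing the last tree-like calcifier is not
the same as losing one of twelve encrusting sponges. `benthovuln` is an R
package plus a scripted analysis workflow for ecologists who compile MME
records and species trait tables and want to quantify that vulnerability.

## What it computes

1. **Functional entities (FEs).** Species scored on ten nominal/ordinal
   traits (feeding, longevity, coloniality, morphology, carbon storage,
   energetic resource, height, growth rate, calcification, motility) are
   grouped by exact trait signature. Redundancy summaries (mean/max
   species per FE, singleton share) measure how much insurance the
   community carries.
2. **Trait space.** Gower dissimilarity between FE signatures
   (d = (1/10) Σ_t δ_t; δ = 0/1 for nominal traits,
   |r_i − r_j|/(K−1) for ordinal ranks), embedded by principal
   coordinates; the retained dimensionality m minimizes the mean absolute
   deviation (mAD) between Gower and embedded Euclidean distances.
3. **Impacted trait volumes.** V = convex-hull volume of FE coordinates
   in the m-dimensional space; an FE is impacted if any member species
   appears in a record subset. Reported as fractions of the global hull
   across severity bins (≥10% … =100% mortality), a 12-driver-class × year
   heatmap, decade/5-year means, and regional summaries under balanced
   resampling (100 records × 1000 repetitions, without replacement) to
   neutralize unbalanced survey effort.
4. **Zero-one-inflated beta (ZOIB) Bayesian regressions.** Mortality
   fractions y ∈ [0,1] mix point masses at {0,1} (weight p01, conditional
   one-probability coi) with a Beta(μφ, (1−μ)φ) interior; logit link on μ.
   Ten per-trait severity models and one annual volume model, sampled by a
   conjugate-Gibbs + calibrated MCMC scheme with rank-normalized split
   R-hat ≤ 1.01 and Bayesian R².
5. **Synthetic data generator.** A seeded generator emulating the
   structure of the Mediterranean MME compilation (389 species, a
   1986–2020 stream rising from 88 to 997 records per five-year period,
   nine drivers, trait-dependent mortality), providing ground truth for
   every downstream stage.

## Worked example

```r
library(benthovuln)

cfg <- synthetic_config(seed = 101)          # study-scale defaults
tbl <- generate_trait_table(cfg)
gen <- generate_mortality_records(tbl, cfg)

fes <- build_functional_entities(tbl)
summarize_redundancy(fes)$n_fes
#> [1] 385

space <- select_dimension(gower_distance(fes))
space
#> trait_space: 385 points, 35 positive axes; m_selected = 7 (mAD = 0.06104)

imp <- impacted_fe_ids(gen$records, fes)
impacted_fraction(space, imp)$fraction
#> [1] 0.2001
```

Read: the 389 synthetic species collapse into 385 FEs (independent traits
carry little redundancy); the mAD criterion keeps a 7-dimensional trait
space (profile minimum 0.061); the species hit by the simulated record
stream cover about 20% of the community's total trait volume. On real
compilations the same calls yield the published-style quantities (FE
counts, mAD profile, impacted-volume fractions, regional x̄ ± sd under
resampling, per-category posterior mortality).

The scripted workflow under `analysis/` runs the same pipeline end to end
and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # traits.csv, mortality.csv, truth.json
Rscript analysis/02_functional_entities.R
Rscript analysis/03_trait_space.R
Rscript analysis/04_trait_volumes.R   # severity bins, heatmap, resampling
Rscript analysis/05_models.R          # ZOIB severity + volume models
```

`run_full_analysis(run_config(...))` composes all stages in one call.
See the methods vignette (`vignettes/trait-vulnerability-methods.Rmd`)
for the models, priors, numerical choices and generator assumptions.

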