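# paleocomm

Quantitative community ecology for census-mapped benthic
palaeocommunities — the in-situ, sessile assemblages preserved on
Ediacaran-style bedding planes, where every specimen's position and part
measurements (holdfast disc, stem, frond) are recorded. The package is
aimed at palaeoecologists who have per-surface census tables and want
reproducible succession, composition and tiering analyses, and at
methodologists who want those estimators exercised against synthetic
communities with known structure.

## What it computes

* **Surface handling** — validated specimen tables (`read_surface_map`),
  derived geometry (height, uptake interval, areal coverage as a biomass
  proxy), and **retrodeformation**: tectonic shear is undone by an
  area-preserving inverse pure shear calibrated on elongated holdfast
  discs > 10 mm in diameter.
* **Spatial jackknife** — replicated 66%-of-area subsamples grown as
  edge-frozen expanding boxes around random seed points
  (`generate_jackknife_samples`), the resampling unit for all
  between-surface inference.
* **Composition** — count tables at species/genus/morphogroup level with
  four sensitivity treatments for effaced (unidentifiable) fronds;
  Bray–Curtis dissimilarity; NMDS ordination; UPGMA clustering into
  Community Types; LDA prediction of successional stage from
  composition.
* **Succession** — abundance–biomass comparison (ABC) curves and the
  W statistic,

  `W = sum_i (A_i - B_i) / (50 (S - 1))  in [-1, 1]`,

  with cumulative percent abundance `A` and biomass `B` over their own
  descending ranks; positive W = abundance dominance = earlier
  succession. Jackknife W distributions are compared pairwise with
  percentile confidence intervals (alpha 0.05) and surfaces staged as
  earlier / intermediate / later.
* **Tiering** — distinct vertical stratification (DVS) per taxon by
  exact interval arithmetic on uptake zones (DVS-u) and height envelopes
  (DVS-h), combined as plain and abundance-weighted community means,
  classed high (> 0.70) / medium (0.40–0.70) / low (< 0.40); morphogroup
  tiering; stem-prevalence and succession associations.
* **Synthetic data** — a generator planting Community Types, succession
  states (via the covariance of abundance rank and body size), tier
  bands, effacement and tectonic shear, so every estimator is testable
  against ground truth.

## Worked example

```r
library(paleocomm)

abc_curve(c(Fractofusus = 70, Charnia = 20, Bradgatia = 10),   # % abundance
          c(Fractofusus = 10, Charnia = 30, Bradgatia = 60))   # % biomass
#> <abc_curve> S = 3, W = +0.1000 (abundance_positive)
```

The abundance curve dominates the biomass curve (A = 70, 90, 100 against
B = 60, 90, 100), giving W = +0.10: a mildly abundance-dominated, i.e.
earlier-succession, community.

A synthetic six-surface study, end to end:

```r
fx  <- generate_study_fixture(seed = 1, n_surfaces = 6,
                              total_n_range = c(300, 800))
res <- run_pipeline(fx$surfaces, "results/demo",
                    pipeline_config(jackknife = jackknife_config(
                      n_samples = 200, seed = 1)))
res$stages
#>                              surface_id     mean_w        stage  resolution
#>            S01_fractofusus_misrai_early 0.56579273      earlier significant
#>         S02_fractofusus_andersoni_early 0.44647805      earlier significant
#>                     S03_bradgatia_early 0.41592560 intermediate significant
#>                         S04_frond_early 0.14690420 intermediate significant
#>     S05_fractofusus_misrai_intermediate 0.08318904        later significant
#>  S06_fractofusus_andersoni_intermediate 0.28586953 intermediate significant
```

Each surface's jackknife W distribution was compared with every other;
surfaces whose significant differences are all positive are staged
earlier, all negative later, mixed intermediate (staging is relative to
the surfaces in hand, which is why "early"-generated surfaces span the
earlier/intermediate labels here). Tiering for the same run:

```r
res$tiering[, c("surface_id", "dvs_u", "dvs_u_weighted",
                "dvs_u_weighted_class", "stem_proportion")]
#>                              surface_id      dvs_u dvs_u_weighted class  stem
#>            S01_fractofusus_misrai_early 0.30784507     0.78488842  high 0.254
#>         S02_fractofusus_andersoni_early 0.34550176     0.83230537  high 0.179
#>                     S03_bradgatia_early 0.16331468     0.05085920   low 0.889
#>                         S04_frond_early 0.03177191     0.04629012   low 1.000
#>     S05_fractofusus_misrai_intermediate 0.25931396     0.66092243 medium 0.251
#>  S06_fractofusus_andersoni_intermediate 0.28606279     0.87060403  high 0.137
```

Recliner-dominated communities are strongly tiered once taxon scores are
abundance-weighted (the dominant recliner occupies a vertical band no
other taxon touches), while frond-dominated communities — whose
branching crowns overlap freely — are not; the proportion of stemmed
specimens runs opposite to weighted DVS-u. `run_pipeline` also writes
the composition matrix, NMDS coordinates and stress, Newick dendrogram,
W distributions and pairwise comparisons, regression tables and a config
echo as CSV/YAML under the output directory.

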