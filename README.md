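# phagemetrics

Quantitative analysis of bacteriophage infection assays in R, for
microbiologists phenotyping phage-host interactions and defence systems
(e.g. CRISPR-Cas interference) from plate-reader and plaque-count data.

The package covers three liquid-culture workhorses plus the comparative
analyses built on them:

- **One-step growth curves.** From a pfu/ml time series with adsorption dip,
  eclipse plateau and burst rise, the package extracts the three classic
  point estimates: burst size
  `(max pfu/ml − min pfu/ml) / (t0 pfu/ml − min pfu/ml)` (new phage per
  infected cell), adsorption fraction `(t0 − min) / t0`, and the eclipse
  period, read off at the pre-burst minimum of the curve.
- **Virulence assays.** Over a ten-fold phage dilution series, local
  virulence at each multiplicity of infection (MOI) is
  `1 − AUC(phage) / AUC(no-phage control)`, computed over a window censored
  at the time the highest-dose wells overtake the second-highest (the
  signature of resistant-mutant regrowth). The scalar **virulence index** is
  the area under local virulence vs log10 MOI, normalized by its theoretical
  maximum, giving a value in [0, 1].
- **Protection assays.** Area under the growth curve (AUGC), normalized to
  the mean AUGC of a defence-system knock-out strain without phage, is
  compared across high / low / no phage doses (Welch t-tests,
  Benjamini-Hochberg FDR within strain) and classified as **complete**,
  **intermediate** or **none** protection depending on which doses restore
  growth to control levels.
- **Phylogenetic signal.** An entropy-based delta statistic with permutation
  p-values asks whether a categorical phenotype (e.g. sensitivity to
  CRISPR-Cas interference) tracks a phage phylogeny, using marginal
  ancestral-state reconstruction under an equal-rates Mk model implemented
  via the pruning algorithm.
- **A mechanistic simulator.** A nutrient-explicit
  bacteria-phage-CRISPR ODE model (Monod growth, mass-action adsorption,
  Erlang-staged latent period, interference probability `c`, surface-mutant
  emergence) generates every input format the pipeline reads, with ground
  truth frozen as JSON — so the estimators can be validated by parameter
  recovery, and qualitative phenotypes (dose- and nutrient-dependent
  protection) can be reproduced synthetically from named scenario configs.

## Worked example

Simulate a one-step growth experiment (burst size 100, eclipse ~30 min) and
recover its metrics from the written plaque-count table:

```r
library(phagemetrics)

p <- sim_params(S0 = 4e8, P0 = 4e6, a = 2.5e-9, mu = 0, delta_P = 1e-3,
                B = 100, tau = 30, m = 20, c = 0)
fx <- write_onestep_fixture(p, "onestep_demo", seed = 1, noise = FALSE)
records <- read_titre_table(fx$titres)
onestep_metrics(titre_series(records, "onestep", channel = "total_mature"))
#> One-step growth metrics [onestep]
#>   burst size           97.5 phage/cell
#>   adsorption fraction 1.000
#>   eclipse period      10 min
#>   t0 = 4e+06, min = 0 @ 10 min, max = 3.9e+08 @ 50 min
```

The burst size lands within 2.5% of the generating value, and the eclipse
estimate sits at the sampling point nearest the true first-maturation time
(9.5 min on the dense trajectory, recorded in the fixture's `truth.json`;
samples are 10 min apart).

The protection workflow runs the same way from a scenario config:

```r
sc <- load_scenario("lbp1_intermediate_LB")
fx <- write_protection_fixture(sc, "protection_demo", seed = 7)
plate <- read_od_table(fx$od, read_plate_layout(fx$layout))
protection_calls(plate, reference_strain = "KO")
#> Protection phenotype calls (AUGC normalized to reference strain, no phage):
#>  strain phage        medium augc_high augc_low augc_none p_high_vs_none
#>      KO  lbp1 high_nutrient     0.593    0.575         1       3.23e-24
#>  CRISPR  lbp1 high_nutrient     0.674    0.979         1       7.06e-28
#>  p_low_vs_none p_high_vs_low    phenotype restored_threshold_used
#>       6.40e-24      1.92e-15         none                     0.9
#>       1.84e-15      3.32e-25 intermediate                     0.9
```

The knock-out control collapses at both doses ("none"); the spacer-carrying
strain restores growth at low dose (0.979 of the no-phage control, above the
0.9 restoration threshold) but not at high dose (0.674): "intermediate"
protection. The p-values are FDR-adjusted Welch tests within the strain; with
near-deterministic replicates they are all tiny, which is exactly why the
classification combines significance with an effect-size floor.

A shell entry point wraps the same functions
(`inst/exec/phagemetrics simulate|onestep|virulence|protect|eop|delta`).

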