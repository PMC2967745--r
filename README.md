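# clinarica

Latent physiological factors from clinical laboratory data, by independent
component analysis of *clinarrays*.

Hospitals accumulate large volumes of quantitative laboratory measurements —
serum sodium, platelet counts, liver enzymes — across many visits per
patient. A clinarray condenses this record into one vector per patient: the
median value of each biomarker across all of that patient's visits. Stacking
clinarrays column-wise gives a biomarkers × patients matrix **X**, and the
package models it as a linear mixture of a small number of mutually
independent, non-Gaussian latent physiological sources:

```
X = A S,      Y = W X ≈ S
```

where **S** (k × n) holds the latent sources, **A** (m × k) the mixing
matrix whose column entries are the biomarker *loadings* of each component,
and **W** the unmixing matrix estimated by FastICA (symmetric fixed-point
iteration, log-cosh negentropy contrast). Because FastICA depends on its
random initialization and returns components in no particular order, the
decomposition is repeated over an ensemble of runs (500 by default) and
*significant biomarkers* — the biomarkers that carry the latent factors —
are extracted by two consensus rules:

1. **top fraction** — biomarkers whose mean absolute loading across
   components and runs reaches the upper quantile of the loading
   distribution, and
2. **argmax consistency** — biomarkers that carry the highest absolute
   loading on some component in *every* run,

together with a flag recording whether the two rules agree. The package is
aimed at anyone who wants to run, extend, or stress-test this analysis:
it covers clinarray construction from long-format lab records, cohort
pruning, k-nearest-neighbour imputation of unmeasured cells, row
standardization, scree-based component-count selection, the FastICA
ensemble, the consensus rules, a file-based pipeline, and a synthetic-data
generator with planted latent structure for end-to-end validation against a
known answer.

## Worked example

Simulate a cohort with three planted dominant biomarkers, decompose with a
50-run ensemble, and extract the consensus:

```r
library(clinarica)

cfg <- sim_config(n_patients = 1500, n_biomarkers = 30, n_sources = 3,
                  visits_per_patient = 1, visit_noise_sd = 0,
                  observation_noise_sd = 2, missing_rate = 0,
                  n_planted = 3, planted_gain = 5, seed = 1)
sim <- sim_lab_records(cfg)
sim$truth$planted_biomarkers
#> [1] "B10" "B14" "B16"

X <- standardize_biomarkers(build_clinarray(sim$records))
ens <- ica_ensemble(X, n_runs = 50, n_components = 3, master_seed = 1)
cons <- consensus_biomarkers(ens, fraction = 0.1, threshold_basis = "means")
cons
#> Consensus significant biomarkers
#>   runs used: 50 of 50 converged; 3 components
#>   top-fraction rule (fraction 0.1, basis means, threshold 0.399404):
#>     B10, B16, B14
#>   argmax-consistency rule:
#>     B10, B14, B16
#>   methods agree: yes
```

Both rules recover exactly the planted set and agree. The tidy accessors
expose the underlying statistics — `mean_abs_loading` is each biomarker's
mean absolute loading over all components and converged runs, and
`argmax_count` counts the runs in which it carried a component's highest
loading (50 of 50 for all three planted markers):

```r
head(tidy(cons), 5)
#> # A tibble: 5 × 6
#>   biomarker mean_abs_loading argmax_count argmax_events significant_topfrac significant_argmax
#>   <chr>                <dbl>        <int>         <int> <lgl>               <lgl>
#> 1 B10                  0.511           50            50 TRUE                TRUE
#> 2 B16                  0.500           50            50 TRUE                TRUE
#> 3 B14                  0.483           50            50 TRUE                TRUE
#> 4 B22                  0.390            0             0 FALSE               FALSE
#> 5 B19                  0.369            0             0 FALSE               FALSE
```

`autoplot(cons)` draws the loading profile with the threshold,
`plot_scree(ens)` the eigenvalue curve. For file-based runs,
`run_pipeline(pipeline_config(records = "records.tsv", ...))` executes the
whole chain (pruning → imputation → standardization → ensemble → consensus)
and writes every artifact plus a manifest; `inst/scripts/run-pipeline.R` is
a command-line wrapper around it. The methods vignette
(`vignettes/clinarray-ica.Rmd`) documents the model, every tunable
parameter, and the numerical choices.

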