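# oncofed

Federated analysis of oncological basic dataset (oBDS) exports — a desk-scale,
fully testable implementation of the hospital-to-federation pipeline:

```
oBDS XML collections  →  single reports  →  FHIR-style bundles
     →  pseudonymized bundles  →  per-site case tables
     →  disclosure-controlled site aggregates  →  combined federated result
```

German hospitals must report cancer cases to state registries in the oBDS XML
format. Research federations want to analyze those cases *across* hospitals
without ever pooling patient-level data. `oncofed` implements every stage of
that pipeline as composable R functions: parsing and validating oBDS
collections, decomposing them into single-case reports, mapping each case to an
HL7-FHIR-shaped `Patient` + `Condition` bundle, replacing identifiers with
keyed one-way pseudonyms under configurable deidentification rules, flattening
to per-site analysis tables with ICD-10 entity grouping, and finally computing
small-cell-suppressed aggregates per site that are combined centrally.

Because real exports are protected, the package ships a first-class
synthetic-data generator: a *federation profile* fixes per-site
entity × gender cell counts exactly (or as multinomial weights), and the
generated XML is indistinguishable to the pipeline from a real export.

## The statistics

Two epidemiological questions drive the aggregation:

* **Q1 — entity distribution.** For scope *s* (a site or the combined
  federation) and entity group *e*, the share is
  `100 · n_{s,e} / N_s`, rounded half-up to one decimal.
* **Q2 — gender distribution per entity.** Two estimators: *pooled*
  (`n_{e,g} / n_e` on combined counts) and *mean-of-sites* (unweighted mean of
  the per-site shares), reported side by side.

Disclosure control: any cell or marginal with `0 < count < min_cell`
(default 5) is suppressed before it leaves the site; true zeros are reported;
totals are computed pre-suppression and never shrink.

Validation uses the entity-wise deviation against a gold-standard count table
(for example the tumor documentation system itself):

```
deviation_e = |ŷ_e − y_e| / y_e        MAPE = mean over entities with y_e > 0
```

## Worked example

Two synthetic hospitals, three entity groups, the full pipeline in memory:

```r
library(oncofed)

map   <- read_entity_map()                      # 24 groups + fallback
rules <- read_deident_config()                  # pseudonymize / remove / keep
prov  <- pseudonym_provider(secret = "readme")

profiles <- list(
  site_profile("berlin", 2022,
               list(melanoma = list(M = 60, W = 40),
                    breast   = list(W = 80, M = 6),
                    prostate = list(M = 90)), seed = 11),
  site_profile("munich", 2022,
               list(melanoma = list(M = 96, W = 24),
                    breast   = list(W = 150),
                    prostate = list(M = 40)), seed = 12)
)

tables <- lapply(profiles, function(p) {
  generate_site(p, map) |>
    decompose_collection() |>
    map_reports_to_fhir() |>
    deidentify_bundles(rules, prov) |>
    flatten_bundles(map, year_filter = 2022)
})

result <- tables |>
  lapply(aggregate_site, policy = disclosure_policy(min_cell = 5)) |>
  combine_aggregates()
result
#> <federated_result> 2 sites, 586 cases
#>   top entities (combined):
#>     breast                236   40.3%
#>     melanoma              220   37.5%
#>     prostate              130   22.2%

entity_shares(result)          # Q1, combined scope
#> # A tibble: 3 × 3
#>   entity_group count share
#>   <chr>        <int> <dbl>
#> 1 breast         236  40.3
#> 2 melanoma       220  37.5
#> 3 prostate       130  22.2

gender_shares(result, "mean_of_sites")   # Q2
#> # A tibble: 5 × 5
#>   entity_group gender share n_sites_used n_sites_excluded
#>   <chr>        <chr>  <dbl>        <int>            <int>
#> 1 breast       female  96.5            2                0
#> 2 breast       male     3.5            2                0
#> 3 melanoma     female  30              2                0
#> 4 melanoma     male    70              2                0
#> 5 prostate     male   100              2                0
```

The shares read exactly as in a registry report: breast cancer is 40.3% of the
586 combined cases, and averaged over the two sites 96.5% of breast cases are
female. Validating against a gold-standard count table:

```r
gold <- tibble::tibble(entity_group = c("melanoma", "breast", "prostate"),
                       count = c(225, 240, 131))
mape_report(entity_shares(result)[, c("entity_group", "count")], gold)
#> <deviation_report> MAPE 1.55% over 3 entities
#>   melanoma           predicted    220  gold    225  deviation   2.2%
#>   breast             predicted    236  gold    240  deviation   1.7%
#>   prostate           predicted    130  gold    131  deviation   0.8%
```

`autoplot(result)`, `autoplot(result, "gender")` and `autoplot()` on a
deviation report give the corresponding ggplot figures; `tidy()` and
`glance()` return the underlying tibbles.

For folder-based runs (one artifact directory per stage, each with a manifest
of hashes and counts), see `run_pipeline()` / `run_stage()` and the
`inst/exec/oncofed` command-line wrapper.

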