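---
title: "Methods: federated oncology analysis on oBDS exports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: federated oncology analysis on oBDS exports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncofed)
```

## The pipeline model

`oncofed` models the data flow of a hospital research federation that analyzes
cancer cases without pooling patient-level records. The unit of observation is
the *report*: one oBDS XML report corresponds to one cancer case and one
patient. Multiple reports per patient are representable (a shared
`patient_id`), but every report is counted as a distinct case — this matches
how registry exports are counted and is the package's fixed convention.

Stages hand off through folders, one per stage, each writing a JSON manifest
(input/output hashes, configuration hash, in/out/rejection counts). The
manifest chain makes a run auditable: cases generated must equal rows
flattened plus rejections plus year-filtered cases, and re-running a stage on
unchanged inputs reproduces identical output hashes.

Assumptions baked into the model:

* a collection's reports all share its `site_id` and `obds_version`;
* the diagnosis date, ICD-10 code and administrative gender are present and
  syntactically valid (reports violating this are quarantined with a coded
  reason, never silently dropped);
* schema versions outside the supported set (default `"2.2.2"`) abort the run
  at the decompose gate — a mis-parsed newer schema is worse than a loud
  failure;
* the FHIR slice is deliberately minimal: one `Patient` (identifier, gender)
  and one `Condition` (ICD-10 coding, onset date) per case, the three data
  elements the analysis consumes. Resource ids derive deterministically from
  `(site_id, report_id)`, so re-processing is idempotent.

## Pseudonymization

A pseudonym is HMAC-SHA-256 of the identifier value under a key derived from
the provider secret and the domain name, truncated to 24 bytes and
base64url-encoded: a fixed 32-character URL-safe token. The construction is
deterministic per `(domain, value)` — the same patient maps to the same token,
preserving within-site linkability — and one-way without the secret.
Collisions require a 192-bit birthday event and are negligible at any
realistic corpus size. The provider is an interface (domains + secret +
`pseudonym_for()`); a networked pseudonymization service can be substituted
without touching pipeline code.

Deidentification is rule-driven (`resource_type`, `field_path`, action in
{pseudonymize, remove, keep}); rules are validated against the known resource
fields at load time. The shipped default pseudonymizes `Patient.identifier`,
removes the free-text quasi-identifier, and keeps gender, diagnosis coding and
onset date. Diagnosis dates are kept at full precision through
deidentification and generalized to the calendar *year* only at the flattening
boundary, since the analyses need only the year.

## Entity grouping

ICD-10 codes are grouped into 24 tumor entities plus a fallback (`other`).
Matching is on the three-character category — subcodes inherit their
category's group — except for explicit four-character specs (`D09.0`), which
match only exactly. The first matching spec in list order wins; this
first-match-wins order is the tie-break rule and is part of the map contract.
The shipped map (breast = C50 + D05, colorectum = C18–C21, melanoma = C43, …)
is an editable *reconstruction* of a common registry grouping: published
analyses name example groups but not the full list, and real boundaries (is
C21 colorectal? is D09 bladder?) vary by convention. The synthetic generator
draws codes from the map itself, so analyses of generated data never depend on
the contested boundaries.

## Disclosure control and combination

Per site, cases are cross-tabulated by entity × gender; cells and marginals
with `0 < count < min_cell` are suppressed before the aggregate leaves the
site, and the suppressed value is discarded (stored as `NA`), not merely
hidden. Choices worth stating:

* **min_cell = 5** by default — a common registry small-cell rule; it is a
  policy parameter, not a property of the method.
* **True zeros are reported as 0.** A zero cell reveals only absence; strict
  mode (`suppress_zero = TRUE`) is available where policy demands it.
* **Totals never shrink.** `total_cases` is computed pre-suppression; the
  combined total is the sum of site totals. (Consequently a suppressed
  marginal can sometimes be bounded by subtraction from the total — with one
  suppressed gender among three this is inherent to publishing exact totals,
  as it is in published reports.)
* A combined cell is the sum over sites only if *every* site reported it
  unsuppressed (absent cells count as true zeros); otherwise it is suppressed,
  since a partial sum would leak bounds on the suppressed site.

Q1 shares are percentages of the scope total. Q2 offers two estimators because
they answer different questions: *pooled* weights sites by size and equals a
centralized recount when nothing is suppressed; *mean-of-sites* (the default)
gives each site equal weight, matching how multi-site federated reports
typically present "mean results across sites". In the mean-of-sites estimator
a site that holds an entity but has no cases of some gender contributes a
true-zero share of 0% — skipping it would make per-entity shares sum to more
than 100%. Sites whose cell is suppressed are excluded from the mean and
counted in `n_sites_excluded`.

## Validation metric

The entity-wise deviation between a federated count `ŷ_e` and a gold-standard
count `y_e` is `|ŷ_e − y_e| / y_e`; the MAPE is the unweighted arithmetic mean
over entities with `y_e > 0`, reported as a percentage. Zero-gold entities
have no defined relative deviation and are excluded with a warning rather than
mapped to infinity — this keeps the mean finite and the exclusions auditable.
Entities missing from the prediction count as predicted 0 (deviation 1).
Display rounding is one decimal, or two below 2% where the extra digit is
informative; full precision is retained internally.

`perturb_gold()` models the dominant real-world source of deviation:
retrospectively documented cases that enter the documentation system after the
export was taken. It leaves the pipeline input untouched and injects
`add_late` extra cases into the gold table at seeded random entities, so
deviation is zero at `add_late = 0` and grows from there.

## What the synthetic generator does and does not emulate

A site profile fixes entity × gender cell counts exactly or as multinomial
weights; the generator emits one report per case with a per-site
zero-padded patient id, a seeded uniform ICD-10 code from the entity's
configured codes, a seeded uniform diagnosis date within the profile year, and
a synthetic quasi-identifier for the stripping rules to remove. Identical
profile and seed give byte-identical files.

It does **not** emulate: heterogeneous documentation practice, missing or
contradictory fields beyond the validation-rule violations tests inject,
therapy/histology/TNM content, longitudinal corrections or deletions, multiple
reports per patient, or realistic names and birthdates. Passing tests
therefore demonstrate the pipeline's *logic* — conservation, privacy
properties, exact aggregation — on structurally faithful inputs, not
robustness to the full messiness of hospital RWD.

The packaged `paper_federation.yaml` encodes a 6-site federation of 17,885
cases whose per-entity totals and gender marginals match published federated
oncology counts, with site 5 fixed at 2045 cases of which 500 are melanoma.
Only those constraints are externally given; the split of the remaining cases
across sites 1–4 and 6, and the counts of the 14 unnamed entity groups, are
the package's own documented choices (plausible relative magnitudes, all
nonzero site cells ≥ 5 so that exact-mode aggregation is undisturbed by
suppression). The three diverse-gender cases sit in one site's melanoma cell,
below the default threshold, so their gender marginal is suppressed — visible
in reports as a 3-case gap between the total and the published gender counts.
The packaged registry table carries the ten printed 2019 registry counts plus
a synthetic `other` remainder row so shares are computed against the full
published total.

## Numerical choices and degenerate inputs

* Percentages round half-up (`floor(x·10 + 0.5)/10`), not banker's rounding:
  registry reports round 24.45 to 24.5, `round()` would not.
* Empty collections decompose to an empty list with a warning; empty
  federations generate no files with a warning; an empty case table writes a
  header-only CSV.
* Duplicate report ids within a site are rejected (first occurrence kept) —
  registry correction/deletion semantics are out of scope, and a loud
  rejection beats a silent double count.
* XML writing uses a fixed template with escaping so identical collections
  produce byte-identical files; parsing is xml2 throughout.
* All randomness flows through explicit seeds; generation restores the
  caller's RNG state.

## Problem sizes

The test suite runs the full 17,885-case federation end-to-end once (about
45 s), 1000 random table pairs against the brute-force MAPE oracle, 100 random
federations against the centralized recount oracle, 500 serialization
round-trips, and 100 multinomial draws for the sampling-error check — sizes
chosen so the whole suite completes in under two minutes while every property
is exercised at a scale where failures would be visible.

## Known limitations

* Real per-site deviations against tumor documentation systems cannot be
  reproduced here — they depend on protected hospital data; the package
  demonstrates the metric's behavior on perturbed synthetic gold standards
  instead.
* The entity map is a reconstruction; analyses on real data should review its
  boundaries first.
* Cell suppression is the only statistical disclosure control implemented; no
  rounding or perturbation schemes, and no protection against differencing
  attacks across overlapping queries.
* The folder-based transport preserves the streaming contract (one message
  per report, idempotent by stable ids) but not the operational properties of
  a message broker.
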