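# programmatic fixtures: everything random is seeded by the caller

test_map <- function() read_entity_map()

random_icd10 <- function(n) {
  cat3 <- sprintf("%s%02d", sample(c("C", "D"), n, replace = TRUE),
                  sample(0:97, n, replace = TRUE))
  sub <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ifelse(sub, sprintf("%s.%d", cat3, sample(0:9, n, replace = TRUE)), cat3)
}

random_reports <- function(n, years = 2021:2022, qi = TRUE) {
  dates <- sample(seq(as.Date(sprintf("%d-01-01", min(years))),
                      as.Date(sprintf("%d-12-31", max(years))), by = "day"),
                  n, replace = TRUE)
  tibble::tibble(
    report_id = sprintf("R%04d", seq_len(n)),
    patient_id = sprintf("P%04d", seq_len(n)),
    gender = sample(c("M", "W", "D", "U"), n, replace = TRUE,
                    prob = c(.45, .45, .05, .05)),
    icd10_code = random_icd10(n),
    icd10_version = "10-GM-2022",
    diagnosis_date = dates,
    quasi_identifier = if (qi) sprintf("QI-%04d", sample.int(9999, n)) else
      NA_character_
  )
}

random_collection <- function(n = 10, site_id = "s1", ...) {
  obds_collection(random_reports(n, ...), site_id = site_id)
}

# a small two-site federation profile built in code
small_profile <- function(site_id = "sA", year = 2022, seed = 7,
                          cells = list(melanoma = list(M = 12, W = 9),
                                       breast = list(W = 15),
                                       prostate = list(M = 20))) {
  site_profile(site_id, year, cells, mode = "exact", seed = seed)
}

# run bundles through mapping + deidentification in one go
deidentified_corpus <- function(collection, secret = "test-secret") {
  docs <- decompose_collection(collection)
  bundles <- map_reports_to_fhir(docs)
  deidentify_bundles(bundles, read_deident_config(),
                     pseudonym_provider(secret = secret))
}

# centralized cross-tabulation oracle: what the federation would count if all
# rows were pooled (test-only; the pipeline itself never concatenates rows)
central_crosstab <- function(tables) {
  all <- dplyr::bind_rows(lapply(tables, tibble::as_tibble))
  dplyr::count(all, entity_group, gender, name = "count")
}
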