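#' Flatten deidentified bundles into a per-site case table
#'
#' The federated analysis consumes flat per-case rows, one per bundle:
#' pseudonym, FHIR gender, ICD-10 code, diagnosis *year* (dates are
#' generalized to the year at this boundary as a privacy measure), assigned
#' entity group, and site id. Bundles whose diagnosis year falls outside
#' `year_filter` are counted and logged, not silently dropped; every bundle
#' therefore maps to exactly one row or one recorded filter event.
#'
#' Only deidentified bundles are accepted: a bundle without the
#' `deidentified` flag aborts the call (privacy gate -- identified data must
#' never reach the analysis boundary).
#'
#' @param bundles A list of deidentified `fhir_bundle` objects from one site.
#' @param map An [read_entity_map()] entity group map.
#' @param year_filter Integer vector of diagnosis years to retain.
#' @return A `case_table`: a tibble with columns `pseudonym`, `gender`,
#'   `icd10_code`, `diagnosis_year`, `entity_group`, `site_id`, carrying
#'   attributes `site_id`, `n_filtered` (rows outside the year filter) and
#'   `provenance` (corpus and config hashes).
#' @export
flatten_bundles <- function(bundles, map, year_filter) {
  stopifnot(inherits(map, "entity_map"), length(year_filter) >= 1)
  if (!length(bundles)) {
    return(new_case_table(empty_case_rows(), site_id = NA_character_,
                          n_filtered = 0L, map = map))
  }
  not_deid <- !vapply(bundles, function(b) isTRUE(b$deidentified), logical(1))
  if (any(not_deid)) {
    abort(paste0(sum(not_deid), " identified bundle(s) reached flatten(); ",
                 "run deidentify_bundles() first"))
  }
  field <- function(get) vapply(bundles, get, character(1))
  rows <- tibble(
    pseudonym = field(function(b) {
      p <- bundle_patient(b)
      if (is.null(p$identifier)) NA_character_ else p$identifier[[1]]$value
    }),
    gender = field(function(b) bundle_patient(b)$gender %||% NA_character_),
    icd10_code = field(function(b) bundle_condition(b)$code$coding[[1]]$code),
    diagnosis_year = NA_integer_,
    site_id = field(function(b) b$site_id)
  )
  rows$diagnosis_year <- as.integer(substr(
    field(function(b) bundle_condition(b)$onsetDateTime), 1, 4
  ))
  site_ids <- unique(rows$site_id)
  if (length(site_ids) != 1) {
    abort(paste0("flatten_bundles() expects a single site, got: ",
                 paste(site_ids, collapse = ", ")))
  }
  rows$entity_group <- assign_entity_group(rows$icd10_code, map)
  keep <- rows$diagnosis_year %in% as.integer(year_filter)
  n_filtered <- sum(!keep)
  if (n_filtered > 0) {
    inform(paste0(n_filtered, " case(s) outside year filter {",
                  paste(sort(year_filter), collapse = ", "), "} at site ",
                  site_ids))
  }
  rows <- rows[keep, c("pseudonym", "gender", "icd10_code", "diagnosis_year",
                       "entity_group", "site_id")]
  new_case_table(rows, site_id = site_ids, n_filtered = n_filtered, map = map)
}

empty_case_rows <- function() {
  tibble(pseudonym = character(), gender = character(),
         icd10_code = character(), diagnosis_year = integer(),
         entity_group = character(), site_id = character())
}

new_case_table <- function(rows, site_id, n_filtered, map = NULL) {
  structure(
    as_tibble(rows),
    site_id = site_id,
    n_filtered = n_filtered,
    provenance = list(corpus_hash = object_hash(rows),
                      config_hash = if (!is.null(map)) object_hash(map$specs)),
    class = c("case_table", class(tibble()))
  )
}

case_table_header <- c("pseudonym", "gender", "icd10_code",
                       "diagnosis_year", "entity_group", "site_id")

#' Case-table CSV serialization
#'
#' The per-site CSV handed to the site's analysis server. Header is exactly
#' `pseudonym,gender,icd10_code,diagnosis_year,entity_group,site_id`,
#' RFC-4180 quoting, UTF-8; reading back a written table reproduces it.
#'
#' @param table A `case_table` from [flatten_bundles()].
#' @param path CSV file path.
#' @export
write_case_table <- function(table, path) {
  stopifnot(is.data.frame(table), identical(names(table), case_table_header))
  readr::write_csv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_case_table
#' @export
read_case_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(gsub('"', "", header), case_table_header)) {
    abort(paste0("case table header mismatch in ", path))
  }
  rows <- readr::read_csv(
    path, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      pseudonym = "c", gender = "c", icd10_code = "c",
      diagnosis_year = "i", entity_group = "c", site_id = "c"
    )
  )
  site <- unique(rows$site_id)
  new_case_table(rows, site_id = if (length(site) == 1) site else NA_character_,
                 n_filtered = NA_integer_)
}
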