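#' Map an oBDS report to a FHIR-style resource bundle
#'
#' The ETL stage turns each single-case report into an HL7-FHIR-shaped bundle
#' of one `Patient` and one `Condition` resource -- the slice of the oncology
#' FHIR model that the downstream analysis consumes (diagnosis code, date of
#' diagnosis, administrative gender). Administrative gender codes map
#' `M -> male`, `W -> female`, `D -> other`, `U -> unknown`; the ICD-10 code
#' and catalog version are copied verbatim into `Condition.code`; the
#' diagnosis date becomes `Condition.onsetDateTime`. Resource ids are derived
#' deterministically from `(site_id, report_id)`, so mapping the same report
#' twice yields identical bundles (idempotent re-processing).
#'
#' @param doc An `obds_report_doc` from [decompose_collection()].
#' @param coding_system URI recorded on the ICD-10 coding.
#' @return A list of class `fhir_bundle` mirroring FHIR JSON structure, with
#'   provenance fields `site_id` and `report_id` and a `deidentified` flag
#'   (initially `FALSE`).
#' @export
map_report_to_fhir <- function(doc,
                               coding_system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm") {
  stopifnot(inherits(doc, "obds_report_doc"))
  r <- doc$report
  if (!(r$gender %in% names(fhir_gender_map))) {
    abort(paste0("MAPPING_ERROR: unmapped gender code '", r$gender,
                 "' in report ", r$report_id))
  }
  if (is.na(r$diagnosis_date)) {
    abort(paste0("MAPPING_ERROR: missing diagnosis date in report ",
                 r$report_id))
  }
  new_fhir_bundle(
    site_id = doc$site_id, report_id = r$report_id,
    patient_id = r$patient_id, gender = unname(fhir_gender_map[[r$gender]]),
    icd10_code = r$icd10_code, icd10_version = r$icd10_version,
    onset = format(r$diagnosis_date, "%Y-%m-%d"),
    quasi_identifier = r$quasi_identifier, coding_system = coding_system
  )
}

new_fhir_bundle <- function(site_id, report_id, patient_id, gender,
                            icd10_code, icd10_version, onset,
                            quasi_identifier, coding_system) {
  pid <- paste0("pt-", site_id, "-", report_id)
  patient <- list(
    resourceType = "Patient",
    id = pid,
    identifier = list(list(
      system = "https://oncofed.example.org/identifiers/patient-id",
      value = patient_id
    )),
    gender = gender
  )
  if (!is.na(quasi_identifier)) {
    patient$quasi_identifier <- quasi_identifier
  }
  condition <- list(
    resourceType = "Condition",
    id = paste0("cd-", site_id, "-", report_id),
    subject = list(reference = paste0("Patient/", pid)),
    code = list(coding = list(list(
      system = coding_system,
      code = icd10_code,
      version = icd10_version
    ))),
    onsetDateTime = onset
  )
  structure(
    list(
      resourceType = "Bundle",
      id = paste0("bnd-", site_id, "-", report_id),
      site_id = site_id,
      report_id = report_id,
      deidentified = FALSE,
      entry = list(list(resource = patient), list(resource = condition))
    ),
    class = "fhir_bundle"
  )
}

# vectorized mapping over a reports tibble (as from read_obds_reports())
map_reports_tbl_to_fhir <- function(df,
                                    coding_system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm") {
  bad <- !(df$gender %in% names(fhir_gender_map))
  if (any(bad)) {
    abort(paste0("MAPPING_ERROR: unmapped gender code(s): ",
                 paste(unique(df$gender[bad]), collapse = ", ")))
  }
  if (anyNA(df$diagnosis_date)) {
    abort("MAPPING_ERROR: missing diagnosis date")
  }
  gender <- unname(fhir_gender_map[df$gender])
  onset <- format(df$diagnosis_date, "%Y-%m-%d")
  lapply(seq_len(nrow(df)), function(i) {
    new_fhir_bundle(
      site_id = df$site_id[i], report_id = df$report_id[i],
      patient_id = df$patient_id[i], gender = gender[i],
      icd10_code = df$icd10_code[i], icd10_version = df$icd10_version[i],
      onset = onset[i], quasi_identifier = df$quasi_identifier[i],
      coding_system = coding_system
    )
  })
}

#' @rdname map_report_to_fhir
#' @param docs A list of `obds_report_doc` objects.
#' @export
map_reports_to_fhir <- function(docs,
                                coding_system = "http://fhir.de/CodeSystem/bfarm/icd-10-gm") {
  lapply(docs, map_report_to_fhir, coding_system = coding_system)
}

#' @export
print.fhir_bundle <- function(x, ...) {
  p <- bundle_patient(x); cnd <- bundle_condition(x)
  cat("<fhir_bundle> ", x$id, if (isTRUE(x$deidentified)) " [deidentified]",
      "\n  Patient ", p$id, " gender=", p$gender,
      "\n  Condition ", cnd$code$coding[[1]]$code, " onset=", cnd$onsetDateTime,
      "\n", sep = "")
  invisible(x)
}

bundle_patient <- function(bundle) bundle$entry[[1]]$resource
bundle_condition <- function(bundle) bundle$entry[[2]]$resource

#' Read and write bundle corpora as NDJSON
#'
#' One FHIR-JSON object per line, one file per site
#' (`<stage dir>/<site_id>.ndjson`). `read_fhir_bundles(write_fhir_bundles(x))`
#' is the identity; malformed lines are skipped with a recorded rejection
#' rather than aborting the file.
#'
#' @param bundles A list of `fhir_bundle` objects.
#' @param path Output (input) NDJSON file path.
#' @return `write_fhir_bundles()` returns `path` invisibly;
#'   `read_fhir_bundles()` returns a list of `fhir_bundle` objects with an
#'   attribute `rejections` (tibble of `line`, `message`) when lines failed.
#' @export
write_fhir_bundles <- function(bundles, path) {
  lines <- vapply(bundles, function(b) {
    jsonlite::toJSON(unclass(b), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_fhir_bundles
#' @export
read_fhir_bundles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rejections <- tibble(line = integer(), message = character())
  bundles <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    b <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                  error = function(e) e)
    if (inherits(b, "error")) {
      rejections <- add_row(rejections, line = i,
                            message = conditionMessage(b))
    } else {
      bundles[[i]] <- structure(b, class = "fhir_bundle")
      keep[i] <- TRUE
    }
  }
  structure(bundles[keep], rejections = rejections)
}
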