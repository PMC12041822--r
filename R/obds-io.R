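#' oBDS collections and reports
#'
#' The oncological basic dataset (oBDS) is Germany's standardized dataset for
#' mandatory cancer-case reporting. Tumor documentation systems export it as
#' XML *collections* -- one file per site export, holding many single-case
#' *reports*. This package works with a minimal dialect of that format
#' carrying exactly the fields the downstream analysis consumes: patient
#' identifier, administrative gender (`M`/`W`/`D`/`U`), ICD-10 diagnosis code
#' and catalog version, diagnosis date, and the oBDS schema version.
#'
#' `obds_collection()` constructs a collection from a tibble of reports;
#' `parse_obds_collection()` reads one from XML, validating every report and
#' quarantining (not dropping) invalid ones.
#'
#' @param reports A tibble with columns `report_id`, `patient_id`, `gender`,
#'   `icd10_code`, `icd10_version`, `diagnosis_date` (Date), and optionally
#'   `quasi_identifier`.
#' @param site_id Site label shared by all reports.
#' @param obds_version oBDS schema version string, e.g. `"2.2.2"`.
#' @param rejections A tibble of per-report rejection records (usually filled
#'   by [parse_obds_collection()]).
#' @return An object of class `obds_collection`: a list with `obds_version`,
#'   `site_id`, a `reports` tibble, and a `rejections` tibble.
#' @seealso [parse_obds_collection()], [write_obds_collection()],
#'   [decompose_collection()], [check_obds_version()]
#' @export
obds_collection <- function(reports, site_id, obds_version = "2.2.2",
                            rejections = empty_rejections()) {
  reports <- as_tibble(reports)
  required <- c("report_id", "patient_id", "gender", "icd10_code",
                "icd10_version", "diagnosis_date")
  missing <- setdiff(required, names(reports))
  if (length(missing)) {
    abort(paste0("reports is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!"quasi_identifier" %in% names(reports)) {
    reports$quasi_identifier <- NA_character_
  }
  reports <- reports[, c(required, "quasi_identifier")]
  if (anyDuplicated(reports$report_id)) {
    abort("report_ids must be unique within a collection")
  }
  structure(
    list(obds_version = obds_version, site_id = site_id,
         reports = reports, rejections = as_tibble(rejections)),
    class = "obds_collection"
  )
}

empty_rejections <- function() {
  tibble(report_id = character(), code = character(), message = character())
}

empty_reports <- function() {
  tibble(report_id = character(), patient_id = character(), gender = character(),
         icd10_code = character(), icd10_version = character(),
         diagnosis_date = as.Date(character()), quasi_identifier = character())
}

#' @export
print.obds_collection <- function(x, ...) {
  cat("<obds_collection> site ", x$site_id, ", oBDS ", x$obds_version, "\n",
      "  reports:    ", nrow(x$reports), "\n",
      "  rejections: ", nrow(x$rejections), "\n", sep = "")
  invisible(x)
}

#' @export
format.obds_collection <- function(x, ...) {
  sprintf("<obds_collection site=%s obds=%s n=%d>", x$site_id, x$obds_version,
          nrow(x$reports))
}

validate_report_fields <- function(df, reference_date) {
  checks <- list(
    EMPTY_REPORT_ID = is.na(df$report_id) | !nzchar(df$report_id),
    INVALID_GENDER  = !(df$gender %in% obds_gender_codes),
    INVALID_ICD10   = is.na(df$icd10_code) |
      !grepl(icd10_pattern, df$icd10_code),
    INVALID_DATE    = is.na(df$diagnosis_date),
    FUTURE_DATE     = !is.na(df$diagnosis_date) &
      df$diagnosis_date > reference_date
  )
  dup <- duplicated(df$report_id) | duplicated(df$report_id, fromLast = TRUE)
  # keep the first occurrence of a duplicated id, reject the rest
  checks$DUPLICATE_REPORT_ID <- dup & duplicated(df$report_id)
  checks
}

#' Parse an oBDS collection from XML
#'
#' Reads a collection document, validates every report against the field
#' invariants (gender code set, ICD-10 syntax, parseable non-future diagnosis
#' date, nonempty unique report id) and returns the valid reports alongside a
#' per-report rejection record for the invalid ones. Parsing is lossless for
#' retained fields: [write_obds_collection()] followed by
#' `parse_obds_collection()` reproduces the collection.
#'
#' @param x Path to an XML file, or a length-one character scalar of XML text.
#' @param reference_date Diagnosis dates after this date are rejected as
#'   implausible (`FUTURE_DATE`). Defaults to today.
#' @return An [obds_collection()] whose `rejections` tibble has one row per
#'   rejected report (`report_id`, `code`, `message`).
#' @export
parse_obds_collection <- function(x, reference_date = Sys.Date()) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) abort(paste0("malformed XML: ", conditionMessage(e)))
  )
  root <- xml2::xml_name(doc)
  if (!identical(root, "oBDSCollection")) {
    abort(paste0("unknown root element <", root,
                 ">; expected <oBDSCollection>"))
  }
  obds_version <- xml2::xml_attr(doc, "obds_version")
  site_id <- xml2::xml_attr(doc, "site_id")
  nodes <- xml2::xml_find_all(doc, "./Report")
  df <- report_nodes_to_tibble(nodes)
  split_valid_reports(df, site_id, obds_version, reference_date)
}

report_nodes_to_tibble <- function(nodes) {
  if (!length(nodes)) return(empty_reports())
  diag <- xml2::xml_find_first(nodes, "./Diagnosis")
  qi <- xml2::xml_text(xml2::xml_find_first(nodes, "./QuasiIdentifier"))
  qi[!nzchar(qi) | is.na(qi)] <- NA_character_
  tibble(
    report_id = xml2::xml_attr(nodes, "id"),
    patient_id = xml2::xml_text(xml2::xml_find_first(nodes, "./PatientID")),
    gender = xml2::xml_text(xml2::xml_find_first(nodes, "./Gender")),
    icd10_code = xml2::xml_attr(diag, "icd10"),
    icd10_version = xml2::xml_attr(diag, "icd10_version"),
    diagnosis_date = as.Date(xml2::xml_attr(diag, "date"), format = "%Y-%m-%d"),
    quasi_identifier = qi
  )
}

split_valid_reports <- function(df, site_id, obds_version, reference_date) {
  checks <- validate_report_fields(df, reference_date)
  bad <- Reduce(`|`, checks)
  rej <- empty_rejections()
  if (any(bad)) {
    first_code <- apply(do.call(cbind, checks), 1, function(r) {
      names(checks)[which(r)[1]]
    })
    rej <- tibble(
      report_id = df$report_id[bad],
      code = unlist(first_code[bad]),
      message = paste0("report failed invariant ", unlist(first_code[bad]))
    )
  }
  obds_collection(df[!bad, , drop = FALSE], site_id = site_id,
                  obds_version = obds_version, rejections = rej)
}

#' Check a collection's oBDS schema version against the supported set
#'
#' The pipeline processes a fixed set of oBDS schema versions (by default only
#' `"2.2.2"`). A site that exports a newer version -- for example a registry
#' that has moved on to `2.2.3` -- must be rejected up front rather than
#' mis-parsed downstream. The check is pure: the caller decides whether a
#' failure is fatal.
#'
#' @param collection An [obds_collection()].
#' @param supported Character vector of accepted schema versions.
#' @return A list of class `obds_version_check` with elements `pass`
#'   (logical), `version` (the collection's version) and `supported`.
#' @export
check_obds_version <- function(collection, supported = obds_supported_versions()) {
  stopifnot(inherits(collection, "obds_collection"), length(supported) >= 1)
  structure(
    list(pass = collection$obds_version %in% supported,
         version = collection$obds_version,
         supported = supported),
    class = "obds_version_check"
  )
}

#' @export
print.obds_version_check <- function(x, ...) {
  if (x$pass) {
    cat("oBDS version", x$version, "is supported\n")
  } else {
    cat("unsupported oBDS version ", x$version, " (supported: ",
        paste(x$supported, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' @rdname check_obds_version
#' @export
obds_supported_versions <- function() "2.2.2"

#' Decompose a collection into single-report documents
#'
#' Registry exports arrive as multi-report collections, but the downstream
#' FHIR mapping consumes one report at a time. Decomposition emits exactly one
#' single-report document per report, copying the collection's `obds_version`
#' and `site_id` down, preserving order, never duplicating or dropping a
#' report.
#'
#' @param collection A version-checked [obds_collection()].
#' @return A list of `obds_report_doc` objects.
#' @export
decompose_collection <- function(collection) {
  stopifnot(inherits(collection, "obds_collection"))
  n <- nrow(collection$reports)
  if (n == 0) {
    warn(paste0("collection for site ", collection$site_id, " is empty"))
    return(list())
  }
  lapply(seq_len(n), function(i) {
    structure(
      list(obds_version = collection$obds_version,
           site_id = collection$site_id,
           report = collection$reports[i, , drop = FALSE]),
      class = "obds_report_doc"
    )
  })
}

#' @export
print.obds_report_doc <- function(x, ...) {
  cat("<obds_report_doc> ", x$site_id, "/", x$report$report_id,
      " (", x$report$icd10_code, ")\n", sep = "")
  invisible(x)
}

report_xml_lines <- function(df, indent = "  ") {
  qi <- ifelse(
    is.na(df$quasi_identifier), "",
    sprintf("%s  <QuasiIdentifier>%s</QuasiIdentifier>\n", indent,
            xml_escape(df$quasi_identifier))
  )
  sprintf(
    paste0(
      "%s<Report id=\"%s\">\n",
      "%s  <PatientID>%s</PatientID>\n",
      "%s  <Gender>%s</Gender>\n",
      "%s  <Diagnosis icd10=\"%s\" icd10_version=\"%s\" date=\"%s\"/>\n",
      "%s%s</Report>"
    ),
    indent, xml_escape(df$report_id),
    indent, xml_escape(df$patient_id),
    indent, xml_escape(df$gender),
    indent, xml_escape(df$icd10_code), xml_escape(df$icd10_version),
    format(df$diagnosis_date, "%Y-%m-%d"),
    qi, indent
  )
}

#' Write oBDS XML
#'
#' `write_obds_collection()` serializes a collection to the XML dialect read
#' by [parse_obds_collection()]; output is byte-deterministic for a given
#' collection. `write_obds_report()` writes a decomposed single-report
#' document into `dir`, named `<site_id>_<report_id>.xml`.
#'
#' @param collection An [obds_collection()].
#' @param path Output file path.
#' @return The output path, invisibly.
#' @export
write_obds_collection <- function(collection, path) {
  stopifnot(inherits(collection, "obds_collection"))
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<oBDSCollection obds_version=\"%s\" site_id=\"%s\">",
            xml_escape(collection$obds_version), xml_escape(collection$site_id)),
    if (nrow(collection$reports)) report_xml_lines(collection$reports),
    "</oBDSCollection>"
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_obds_collection
#' @param doc An `obds_report_doc` from [decompose_collection()].
#' @param dir Output directory (created if absent).
#' @export
write_obds_report <- function(doc, dir) {
  stopifnot(inherits(doc, "obds_report_doc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, sprintf("%s_%s.xml", doc$site_id, doc$report$report_id))
  df <- doc$report
  qi <- if (is.na(df$quasi_identifier)) "" else
    sprintf("  <QuasiIdentifier>%s</QuasiIdentifier>\n",
            xml_escape(df$quasi_identifier))
  body <- sprintf(
    paste0(
      "<oBDSReport obds_version=\"%s\" site_id=\"%s\" id=\"%s\">\n",
      "  <PatientID>%s</PatientID>\n",
      "  <Gender>%s</Gender>\n",
      "  <Diagnosis icd10=\"%s\" icd10_version=\"%s\" date=\"%s\"/>\n",
      "%s</oBDSReport>"
    ),
    xml_escape(doc$obds_version), xml_escape(doc$site_id),
    xml_escape(df$report_id), xml_escape(df$patient_id),
    xml_escape(df$gender), xml_escape(df$icd10_code),
    xml_escape(df$icd10_version), format(df$diagnosis_date, "%Y-%m-%d"), qi
  )
  writeLines(c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>", body), path,
             useBytes = TRUE)
  invisible(path)
}

#' Read a folder of decomposed single-report documents
#'
#' Batch counterpart of [read_obds_report()] for the folder-import contract:
#' the documents are parsed in one pass and field invariants are validated
#' vectorized. Any invariant failure aborts (decomposed reports already
#' passed collection-level validation upstream).
#'
#' @param paths Character vector of `oBDSReport` XML file paths.
#' @param reference_date Passed through to field validation.
#' @return A tibble with `site_id`, `obds_version` and the report fields,
#'   one row per document, in input order.
#' @export
read_obds_reports <- function(paths, reference_date = Sys.Date()) {
  if (!length(paths)) {
    return(mutate(empty_reports(), site_id = character(),
                  obds_version = character()))
  }
  texts <- vapply(paths, function(p) {
    paste(readLines(p, warn = FALSE), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  texts <- sub("^<\\?xml[^>]*\\?>\\s*", "", texts)
  doc <- xml2::read_xml(paste0("<batch>", paste(texts, collapse = ""),
                               "</batch>"))
  nodes <- xml2::xml_find_all(doc, "./oBDSReport")
  if (length(nodes) != length(paths)) {
    abort("unexpected root element in single-report folder")
  }
  diag <- xml2::xml_find_first(nodes, "./Diagnosis")
  qi <- xml2::xml_text(xml2::xml_find_first(nodes, "./QuasiIdentifier"))
  qi[!nzchar(qi) | is.na(qi)] <- NA_character_
  df <- tibble(
    report_id = xml2::xml_attr(nodes, "id"),
    patient_id = xml2::xml_text(xml2::xml_find_first(nodes, "./PatientID")),
    gender = xml2::xml_text(xml2::xml_find_first(nodes, "./Gender")),
    icd10_code = xml2::xml_attr(diag, "icd10"),
    icd10_version = xml2::xml_attr(diag, "icd10_version"),
    diagnosis_date = as.Date(xml2::xml_attr(diag, "date"), format = "%Y-%m-%d"),
    quasi_identifier = qi,
    site_id = xml2::xml_attr(nodes, "site_id"),
    obds_version = xml2::xml_attr(nodes, "obds_version")
  )
  checks <- validate_report_fields(
    df |> mutate(report_id = paste(.data$site_id, .data$report_id)),
    reference_date
  )
  checks$DUPLICATE_REPORT_ID <- NULL  # ids are only unique within a site
  dup <- duplicated(paste(df$site_id, df$report_id))
  bad <- Reduce(`|`, checks) | dup
  if (any(bad)) {
    abort(paste0(sum(bad), " decomposed report(s) fail field invariants"))
  }
  df
}

#' Read a decomposed single-report document
#'
#' @param path Path to an `oBDSReport` XML file.
#' @param reference_date Passed through to field validation.
#' @return An `obds_report_doc`, or an error if the single report fails its
#'   invariants (decomposed reports have already passed collection-level
#'   validation, so this indicates tampering or corruption).
#' @export
read_obds_report <- function(path, reference_date = Sys.Date()) {
  doc <- xml2::read_xml(path)
  if (!identical(xml2::xml_name(doc), "oBDSReport")) {
    abort(paste0("unknown root element <", xml2::xml_name(doc),
                 ">; expected <oBDSReport>"))
  }
  diag <- xml2::xml_find_first(doc, "./Diagnosis")
  qi <- xml2::xml_text(xml2::xml_find_first(doc, "./QuasiIdentifier"))
  if (is.na(qi) || !nzchar(qi)) qi <- NA_character_
  df <- tibble(
    report_id = xml2::xml_attr(doc, "id"),
    patient_id = xml2::xml_text(xml2::xml_find_first(doc, "./PatientID")),
    gender = xml2::xml_text(xml2::xml_find_first(doc, "./Gender")),
    icd10_code = xml2::xml_attr(diag, "icd10"),
    icd10_version = xml2::xml_attr(diag, "icd10_version"),
    diagnosis_date = as.Date(xml2::xml_attr(diag, "date"), format = "%Y-%m-%d"),
    quasi_identifier = qi
  )
  checks <- validate_report_fields(df, reference_date)
  bad <- names(checks)[vapply(checks, any, logical(1))]
  if (length(bad)) {
    abort(paste0("single report ", df$report_id, " fails invariant(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(
    list(obds_version = xml2::xml_attr(doc, "obds_version"),
         site_id = xml2::xml_attr(doc, "site_id"), report = df),
    class = "obds_report_doc"
  )
}
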