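#' Tumor entity grouping of ICD-10 codes
#'
#' Epidemiological reporting groups ICD-10 diagnosis codes into tumor
#' *entities* (breast = C50 + D05, colorectum = C18--C21, ...). An entity
#' group map is an ordered list of `(label, specs)` pairs where each spec is a
#' three-character category (`"C50"`), a category range (`"C18-C21"`), or an
#' explicit four-character code (`"D09.0"`). Matching is on the
#' three-character category -- subcodes inherit the category's group -- except
#' for four-character specs, which match only that exact code. The first
#' matching spec in list order wins; unmatched codes fall into the fallback
#' group.
#'
#' The packaged default map (`entity_groups_default.yaml`) has 24 labeled
#' groups and fallback `"other"`. It is an editable reconstruction of a common
#' registry grouping, not a normative list.
#'
#' @param path Path to an entity-map YAML, or `NULL` for the packaged default.
#' @return An object of class `entity_map`: a list with `specs` (ordered
#'   tibble of `label`, `spec`, `category`, `exact_code`), `labels` and
#'   `fallback`.
#' @examples
#' map <- read_entity_map()
#' assign_entity_group(c("C50.1", "C61", "C97"), map)
#' @export
read_entity_map <- function(path = NULL) {
  path <- path %||% system.file("extdata", "entity_groups_default.yaml",
                                package = "oncofed", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups) || !length(raw$groups)) {
    abort("entity map has no groups")
  }
  specs <- purrr::map_dfr(raw$groups, function(g) {
    tibble(label = g$label, spec = as.character(g$icd10))
  })
  parsed <- purrr::pmap_dfr(specs, parse_icd10_spec)
  structure(
    list(specs = parsed,
         labels = unique(parsed$label),
         fallback = raw$fallback %||% "other"),
    class = "entity_map"
  )
}

# expand one spec into category and/or exact-code match rows
parse_icd10_spec <- function(label, spec) {
  if (grepl("^[A-Z][0-9]{2}\\.[0-9]{1,2}$", spec)) {
    return(tibble(label = label, spec = spec,
                  category = NA_character_, exact_code = spec))
  }
  if (grepl("^[A-Z][0-9]{2}$", spec)) {
    return(tibble(label = label, spec = spec,
                  category = spec, exact_code = NA_character_))
  }
  m <- regmatches(spec, regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", spec))[[1]]
  if (length(m)) {
    if (m[2] != m[4]) abort(paste0("range spans letters: ", spec))
    lo <- as.integer(m[3]); hi <- as.integer(m[5])
    if (lo > hi) abort(paste0("empty range: ", spec))
    return(tibble(label = label, spec = spec,
                  category = sprintf("%s%02d", m[2], lo:hi),
                  exact_code = NA_character_))
  }
  abort(paste0("malformed ICD-10 spec: ", spec))
}

#' @export
print.entity_map <- function(x, ...) {
  cat("<entity_map> ", length(x$labels), " groups + fallback \"",
      x$fallback, "\"\n", sep = "")
  invisible(x)
}

#' @rdname read_entity_map
#' @param icd10_code Character vector of syntactically valid ICD-10 codes.
#' @param map An `entity_map`.
#' @return `assign_entity_group()`: a character vector of group labels, same
#'   length as `icd10_code`.
#' @export
assign_entity_group <- function(icd10_code, map) {
  stopifnot(inherits(map, "entity_map"))
  bad <- !grepl(icd10_pattern, icd10_code)
  if (any(bad)) {
    abort(paste0("malformed ICD-10 code(s): ",
                 paste(unique(icd10_code[bad]), collapse = ", ")))
  }
  specs <- map$specs
  category <- substr(icd10_code, 1, 3)
  # rank of first matching spec, by exact code and by category
  exact_idx <- match(icd10_code, specs$exact_code)
  cat_idx <- match(category, specs$category)
  idx <- pmin(exact_idx, cat_idx, na.rm = TRUE)
  out <- ifelse(is.na(idx), map$fallback, specs$label[idx])
  out
}

# concrete codes a generator may draw for each group: all category specs plus
# exact-code specs, e.g. breast -> C50, D05
entity_map_codes <- function(map) {
  specs <- map$specs
  codes <- ifelse(is.na(specs$category), specs$exact_code, specs$category)
  split(codes, specs$label)[map$labels]
}
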