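#' Site profiles and federation profiles
#'
#' The generator emulates per-site tumor-documentation exports: one report
#' per cancer case carrying a synthetic patient identifier, administrative
#' gender, an ICD-10 code drawn from the configured entity group, a diagnosis
#' date inside the profile year, and the oBDS schema version. A *site
#' profile* fixes the `(entity_group, gender)` cell structure either exactly
#' (`mode = "exact"`: the generated collection, flattened and grouped,
#' reproduces `cell_counts` bit-exactly) or stochastically
#' (`mode = "multinomial"`: `cell_counts` act as weights for a seeded
#' multinomial draw of size `total`). A *federation profile* is a list of
#' site profiles sharing one entity map.
#'
#' The packaged profile `paper_federation.yaml` encodes a 6-site federation
#' with 17,885 cases whose per-entity totals match published federated
#' oncology counts (prostate 2476, breast 2006, melanoma 1921, ...), with
#' site 5 holding 2045 cases of which 500 are melanoma. Only site 5's total
#' is externally constrained; the split across the other sites is an
#' arbitrary, documented choice.
#'
#' @param site_id Site label.
#' @param year Calendar year all diagnosis dates fall in.
#' @param cell_counts Named list: `cell_counts[[entity]][[gender]]` is a
#'   nonnegative count (exact mode) or weight (multinomial mode); gender codes
#'   are oBDS administrative codes `M`/`W`/`D`/`U`.
#' @param mode `"exact"` or `"multinomial"`.
#' @param total Draw size (multinomial mode only).
#' @param seed Integer seed for the site's own RNG stream.
#' @return A `site_profile` object.
#' @export
site_profile <- function(site_id, year, cell_counts, mode = c("exact", "multinomial"),
                         total = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cells <- profile_cells(cell_counts)
  if (mode == "exact" && sum(cells$count) < 1) {
    abort(paste0("exact-mode profile for ", site_id, " has all-zero counts"))
  }
  if (mode == "multinomial") {
    if (is.null(total) || total < 1) abort("multinomial mode needs a positive total")
    if (sum(cells$count) <= 0) abort("multinomial weights must sum to a positive value")
  }
  structure(
    list(site_id = site_id, year = as.integer(year), cells = cells,
         mode = mode, total = total, seed = as.integer(seed)),
    class = "site_profile"
  )
}

profile_cells <- function(cell_counts) {
  purrr::imap_dfr(cell_counts, function(by_gender, entity) {
    tibble(entity_group = entity, gender = names(by_gender),
           count = as.numeric(unlist(by_gender)))
  })
}

#' Generate one site's oBDS collection from a profile
#'
#' Patient ids are `"P"` plus a zero-padded per-site counter; report ids
#' likewise with `"R"`. Each report also carries a synthetic
#' `quasi_identifier` string so deidentification stripping rules have
#' something to strip. ICD-10 codes are drawn uniformly (seeded) from the
#' codes configured for the report's entity group; diagnosis dates uniformly
#' within the profile year. Identical profile and seed give identical
#' collections.
#'
#' @param profile A [site_profile()].
#' @param map An [read_entity_map()]; every entity label in the profile must
#'   exist in the map.
#' @param obds_version Schema version stamped on the collection.
#' @return An [obds_collection()].
#' @export
generate_site <- function(profile, map, obds_version = "2.2.2") {
  stopifnot(inherits(profile, "site_profile"), inherits(map, "entity_map"))
  codes_by_group <- entity_map_codes(map)
  unknown <- setdiff(profile$cells$entity_group, names(codes_by_group))
  if (length(unknown)) {
    abort(paste0("profile for ", profile$site_id,
                 " names entity group(s) not in the map: ",
                 paste(unknown, collapse = ", ")))
  }
  cells <- profile$cells
  with_seed(profile$seed, {
    if (profile$mode == "multinomial") {
      cells$count <- as.numeric(
        stats::rmultinom(1, size = profile$total, prob = cells$count)
      )
    }
    cells <- cells[cells$count > 0, , drop = FALSE]
    n <- sum(cells$count)
    entity <- rep(cells$entity_group, cells$count)
    gender <- rep(cells$gender, cells$count)
    code <- vapply(entity, function(e) {
      pool <- codes_by_group[[e]]
      pool[sample.int(length(pool), 1)]
    }, character(1), USE.NAMES = FALSE)
    origin <- as.Date(sprintf("%d-01-01", profile$year))
    ndays <- as.integer(as.Date(sprintf("%d-12-31", profile$year)) - origin) + 1L
    dates <- origin + (sample.int(ndays, n, replace = TRUE) - 1L)
    qi <- sprintf("QI-%s-%s", profile$site_id,
                  apply(matrix(sample(LETTERS, 8 * n, replace = TRUE), nrow = n),
                        1, paste, collapse = ""))
    reports <- tibble(
      report_id = sprintf("R%06d", seq_len(n)),
      patient_id = sprintf("P%06d", seq_len(n)),
      gender = gender,
      icd10_code = code,
      icd10_version = "10-GM-2022",
      diagnosis_date = dates,
      quasi_identifier = qi
    )
    obds_collection(reports, site_id = profile$site_id,
                    obds_version = obds_version)
  })
}

#' Read a federation profile from YAML
#'
#' @param path Path to a federation YAML (see the packaged
#'   `paper_federation.yaml` for the schema), or `NULL` for that packaged
#'   profile.
#' @param seed Federation-level seed; site seeds default to `seed + site
#'   index` unless the profile sets one explicitly.
#' @return A `federation_profile`: list of [site_profile()]s plus the entity
#'   map path.
#' @export
read_federation_profile <- function(path = NULL, seed = 1L) {
  path <- path %||% system.file("extdata", "paper_federation.yaml",
                                package = "oncofed", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$sites) || !length(raw$sites)) {
    abort("federation profile has no sites")
  }
  map_path <- raw$entity_map %||% "entity_groups_default.yaml"
  if (!file.exists(map_path)) {
    local <- file.path(dirname(path), map_path)
    pkg <- system.file("extdata", map_path, package = "oncofed")
    map_path <- if (file.exists(local)) local else pkg
    if (!nzchar(map_path) || !file.exists(map_path)) {
      abort(paste0("entity map not found: ", raw$entity_map))
    }
  }
  sites <- purrr::imap(raw$sites, function(s, i) {
    site_profile(
      site_id = s$site_id, year = s$year, cell_counts = s$cell_counts,
      mode = s$mode %||% "exact", total = s$total,
      seed = s$seed %||% (seed + i)
    )
  })
  ids <- vapply(sites, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) abort("site_ids must be unique in a federation")
  structure(list(sites = sites, entity_map_path = map_path),
            class = "federation_profile")
}

#' @export
print.federation_profile <- function(x, ...) {
  cat("<federation_profile>", length(x$sites), "sites\n")
  invisible(x)
}

#' Generate a federation: one collection file per site
#'
#' @param fed A [read_federation_profile()].
#' @param dir Output directory for `<site_id>.xml` files.
#' @return A tibble with `site_id`, `path`, `n_reports`, invisibly.
#' @export
generate_federation <- function(fed, dir) {
  stopifnot(inherits(fed, "federation_profile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!length(fed$sites)) {
    warn("empty federation: no files generated")
    return(invisible(tibble(site_id = character(), path = character(),
                            n_reports = integer())))
  }
  map <- read_entity_map(fed$entity_map_path)
  out <- purrr::map_dfr(fed$sites, function(p) {
    coll <- tryCatch(
      generate_site(p, map),
      error = function(e) abort(paste0("site ", p$site_id, ": ",
                                       conditionMessage(e)))
    )
    path <- file.path(dir, paste0(p$site_id, ".xml"))
    write_obds_collection(coll, path)
    tibble(site_id = p$site_id, path = path, n_reports = nrow(coll$reports))
  })
  invisible(out)
}

#' Perturb a gold standard with retrospectively documented cases
#'
#' Validation compares pipeline output against the counts held in the tumor
#' documentation system (the gold standard). In practice the gold standard
#' drifts upward between data extraction and evaluation: cases diagnosed in
#' the study period but documented late appear in the documentation system
#' while being absent from the earlier export. `perturb_gold()` models
#' exactly that: it returns the pipeline-input collection *unchanged*
#' together with a gold count table into which `add_late` extra cases have
#' been injected at seeded random entities. With `add_late = 0` the gold
#' table equals the collection's own counts and the downstream deviation is
#' zero.
#'
#' @param collection An [obds_collection()].
#' @param map Entity map used to group the collection's codes.
#' @param add_late Number of late-documented cases to inject (>= 0).
#' @param seed RNG seed for the entity assignment of injected cases.
#' @return A list with `collection` (unmodified) and `gold` (tibble of
#'   `entity_group`, `count`).
#' @export
perturb_gold <- function(collection, map, add_late = 0L, seed = 1L) {
  stopifnot(inherits(collection, "obds_collection"), add_late >= 0)
  groups <- assign_entity_group(collection$reports$icd10_code, map)
  gold <- tibble(entity_group = groups) |>
    count(entity_group, name = "count")
  if (add_late > 0) {
    extra <- with_seed(seed, {
      sample(gold$entity_group, add_late, replace = TRUE,
             prob = gold$count)
    })
    extra_tbl <- tibble(entity_group = extra) |>
      count(entity_group, name = "extra")
    gold <- left_join(gold, extra_tbl, by = "entity_group") |>
      mutate(count = .data$count + coalesce(.data$extra, 0L)) |>
      select("entity_group", "count")
  }
  list(collection = collection, gold = gold)
}
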