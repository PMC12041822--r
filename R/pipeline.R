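#' Pipeline run configuration
#'
#' One configuration object drives all stages: where the stage folders live,
#' which schema versions pass the gate, which entity map and
#' deidentification rules apply, the disclosure policy, the diagnosis-year
#' filter, and the seed. `read_run_config()` loads it from YAML and
#' validates that every referenced file exists; `run_config()` builds one
#' programmatically (all paths `NULL` default to the packaged fixtures).
#'
#' @param workdir Directory that receives the stage folders.
#' @param profile Federation profile YAML ([read_federation_profile()]).
#' @param entity_map Entity map YAML ([read_entity_map()]).
#' @param deident_rules Deidentification rules YAML ([read_deident_config()]).
#' @param pseudonym_secret Secret for the pseudonym provider (falls back to
#'   the `ONCOFED_PSEUDONYM_SECRET` environment variable).
#' @param min_cell Disclosure threshold ([disclosure_policy()]).
#' @param years Integer vector of diagnosis years to retain (must be
#'   nonempty).
#' @param supported_versions oBDS schema versions accepted by the gate.
#' @param gold Optional gold-standard count CSV for the evaluate stage.
#' @param seed Integer seed for generation.
#' @return A `run_config` object.
#' @export
run_config <- function(workdir, profile = NULL, entity_map = NULL,
                       deident_rules = NULL, pseudonym_secret = NULL,
                       min_cell = 5L, years = c(2021L, 2022L),
                       supported_versions = obds_supported_versions(),
                       gold = NULL, seed = 1L) {
  if (!length(years)) abort("year filter must be nonempty")
  for (p in c(profile, entity_map, deident_rules, gold)) {
    if (!file.exists(p)) abort(paste0("configured file does not exist: ", p))
  }
  structure(
    list(workdir = workdir, profile = profile, entity_map = entity_map,
         deident_rules = deident_rules, pseudonym_secret = pseudonym_secret,
         min_cell = as.integer(min_cell), years = as.integer(years),
         supported_versions = supported_versions, gold = gold,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path Path to a run-configuration YAML.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(p)
    file.path(base, p)
  }
  run_config(
    workdir = resolve(raw$workdir) %||% file.path(base, "pipeline"),
    profile = resolve(raw$profile),
    entity_map = resolve(raw$entity_map),
    deident_rules = resolve(raw$deident_rules),
    pseudonym_secret = raw$pseudonym_secret,
    min_cell = raw$min_cell %||% 5L,
    years = raw$years %||% c(2021L, 2022L),
    supported_versions = raw$supported_versions %||% obds_supported_versions(),
    gold = resolve(raw$gold),
    seed = raw$seed %||% 1L
  )
}

pipeline_stages <- c("generate", "decompose", "to-fhir", "deidentify",
                     "flatten", "aggregate", "combine", "evaluate", "report")

stage_dirs <- c(
  generate = "stage0_input", decompose = "stage1_decomposed",
  `to-fhir` = "stage2_fhir", deidentify = "stage3_pseudonymized",
  flatten = "stage4_tables", aggregate = "stage5_aggregates",
  combine = "stage6_federated", evaluate = "stage7_evaluation",
  report = "stage8_report"
)

stage_dir <- function(config, stage) file.path(config$workdir, stage_dirs[[stage]])

write_manifest <- function(dir, stage, inputs, outputs, config_hash,
                           n_in, n_out, rejections = 0L, notes = NULL) {
  manifest <- list(
    stage = stage,
    config_hash = config_hash,
    inputs = inputs, outputs = outputs,
    n_in = n_in, n_out = n_out, rejections = rejections,
    notes = notes,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "_manifest.json"),
                       auto_unbox = TRUE, na = "null", digits = NA)
  invisible(manifest)
}

#' @rdname run_stage
#' @export
read_manifest <- function(config, stage) {
  path <- file.path(stage_dir(config, stage), "_manifest.json")
  if (!file.exists(path)) return(NULL)
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

require_upstream <- function(config, stage, upstream) {
  m <- read_manifest(config, upstream)
  if (is.null(m)) {
    abort(paste0("stage '", stage, "' needs the '", upstream,
                 "' stage first: no manifest at ",
                 stage_dir(config, upstream),
                 " -- run run_stage(\"", upstream, "\", config)"))
  }
  m
}

stage_files <- function(dir, pattern) {
  # lexicographic filename order is the folder-import contract
  files <- list.files(dir, pattern = pattern, full.names = TRUE,
                      recursive = FALSE)
  files <- files[!startsWith(basename(files), "_")]
  files[order(basename(files), method = "radix")]
}

#' Run one pipeline stage
#'
#' Stages communicate exclusively through folders under the configured
#' `workdir`, one folder per stage, each with a `_manifest.json` recording
#' input/output file hashes, a configuration hash, and in/out/rejection
#' counts. Re-running a stage on unchanged inputs reproduces identical
#' output hashes; a missing upstream manifest is an ordering error with a
#' remediation hint. Stage names follow the pipeline:
#' `generate` (synthetic site exports), `decompose` (folder import +
#' version gate + per-report split), `to-fhir`, `deidentify`, `flatten`,
#' `aggregate`, `combine`, `evaluate` (optional, needs a gold table),
#' `report`.
#'
#' @param stage One of `oncofed_stages()`.
#' @param config A [run_config()].
#' @return The stage's manifest, invisibly.
#' @export
run_stage <- function(stage, config) {
  stopifnot(inherits(config, "run_config"))
  stage <- match.arg(stage, pipeline_stages)
  fn <- switch(stage,
    generate = stage_generate, decompose = stage_decompose,
    `to-fhir` = stage_to_fhir, deidentify = stage_deidentify,
    flatten = stage_flatten, aggregate = stage_aggregate,
    combine = stage_combine, evaluate = stage_evaluate,
    report = stage_report
  )
  dir <- stage_dir(config, stage)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  inform(paste0("[", stage, "] -> ", dir))
  fn(config, dir)
}

#' @rdname run_stage
#' @export
oncofed_stages <- function() pipeline_stages

#' @rdname run_stage
#' @param stages Stages to run, in pipeline order.
#' @return `run_pipeline()`: a named list of stage manifests, invisibly.
#' @export
run_pipeline <- function(config, stages = pipeline_stages) {
  stages <- intersect(pipeline_stages, stages)
  out <- lapply(stages, run_stage, config = config)
  invisible(stats::setNames(out, stages))
}

stage_generate <- function(config, dir) {
  fed <- read_federation_profile(config$profile, seed = config$seed)
  res <- generate_federation(fed, dir)
  write_manifest(dir, "generate",
                 inputs = file_hashes(config$profile %||% character()),
                 outputs = file_hashes(res$path),
                 config_hash = object_hash(list(config$seed, config$profile)),
                 n_in = length(fed$sites), n_out = sum(res$n_reports))
}

stage_decompose <- function(config, dir) {
  require_upstream(config, "decompose", "generate")
  in_dir <- stage_dir(config, "generate")
  files <- stage_files(in_dir, "\\.xml$")
  rej_dir <- file.path(dir, "rejected")
  if (!dir.exists(rej_dir)) dir.create(rej_dir)
  n_in <- 0L; n_out <- 0L; n_rej <- 0L
  out_paths <- character()
  for (f in files) {
    coll <- parse_obds_collection(f)
    gate <- check_obds_version(coll, config$supported_versions)
    if (!gate$pass) {
      abort(paste0("collection ", basename(f), " has unsupported oBDS version ",
                   gate$version, " (supported: ",
                   paste(gate$supported, collapse = ", "), ")"))
    }
    n_in <- n_in + nrow(coll$reports) + nrow(coll$rejections)
    if (nrow(coll$rejections)) {
      # quarantine, never silently drop
      rp <- file.path(rej_dir, paste0(coll$site_id, "_rejections.csv"))
      readr::write_csv(coll$rejections, rp, progress = FALSE)
      n_rej <- n_rej + nrow(coll$rejections)
    }
    docs <- decompose_collection(coll)
    out_paths <- c(out_paths,
                   vapply(docs, write_obds_report, character(1), dir = dir))
    n_out <- n_out + length(docs)
  }
  write_manifest(dir, "decompose", inputs = file_hashes(files),
                 outputs = file_hashes(out_paths),
                 config_hash = object_hash(config$supported_versions),
                 n_in = n_in, n_out = n_out, rejections = n_rej)
}

stage_to_fhir <- function(config, dir) {
  require_upstream(config, "to-fhir", "decompose")
  files <- stage_files(stage_dir(config, "decompose"), "\\.xml$")
  reports <- read_obds_reports(files)
  bundles <- map_reports_tbl_to_fhir(reports)
  sites <- vapply(bundles, `[[`, character(1), "site_id")
  out_paths <- vapply(split(bundles, sites), function(bs) {
    path <- file.path(dir, paste0(bs[[1]]$site_id, ".ndjson"))
    write_fhir_bundles(bs, path)
    path
  }, character(1))
  write_manifest(dir, "to-fhir", inputs = file_hashes(files),
                 outputs = file_hashes(out_paths),
                 config_hash = object_hash("fhir-mapping-v1"),
                 n_in = nrow(reports), n_out = length(bundles))
}

stage_deidentify <- function(config, dir) {
  require_upstream(config, "deidentify", "to-fhir")
  rules <- read_deident_config(config$deident_rules)
  provider <- pseudonym_provider(
    secret = config$pseudonym_secret,
    domains = unique(stats::na.omit(rules$rules$domain))
  )
  files <- stage_files(stage_dir(config, "to-fhir"), "\\.ndjson$")
  n <- 0L
  out_paths <- vapply(files, function(f) {
    bundles <- read_fhir_bundles(f)
    deid <- deidentify_bundles(bundles, rules, provider)
    n <<- n + length(deid)
    path <- file.path(dir, basename(f))
    write_fhir_bundles(deid, path)
    path
  }, character(1), USE.NAMES = FALSE)
  write_manifest(dir, "deidentify", inputs = file_hashes(files),
                 outputs = file_hashes(out_paths),
                 config_hash = object_hash(rules$rules),
                 n_in = n, n_out = n)
}

stage_flatten <- function(config, dir) {
  require_upstream(config, "flatten", "deidentify")
  map <- read_entity_map(config$entity_map)
  files <- stage_files(stage_dir(config, "deidentify"), "\\.ndjson$")
  n_in <- 0L; n_out <- 0L; n_filtered <- 0L
  out_paths <- vapply(files, function(f) {
    bundles <- read_fhir_bundles(f)
    n_in <<- n_in + length(bundles)
    tbl <- flatten_bundles(bundles, map, config$years)
    n_out <<- n_out + nrow(tbl)
    n_filtered <<- n_filtered + attr(tbl, "n_filtered")
    path <- file.path(dir, sub("\\.ndjson$", ".csv", basename(f)))
    write_case_table(tbl, path)
    path
  }, character(1), USE.NAMES = FALSE)
  write_manifest(dir, "flatten", inputs = file_hashes(files),
                 outputs = file_hashes(out_paths),
                 config_hash = object_hash(list(map$specs, config$years)),
                 n_in = n_in, n_out = n_out,
                 notes = list(n_filtered = n_filtered))
}

stage_aggregate <- function(config, dir) {
  require_upstream(config, "aggregate", "flatten")
  policy <- disclosure_policy(config$min_cell)
  files <- stage_files(stage_dir(config, "flatten"), "\\.csv$")
  n <- 0L
  out_paths <- vapply(files, function(f) {
    tbl <- read_case_table(f)
    agg <- aggregate_site(tbl, policy)
    n <<- n + agg$total_cases
    path <- file.path(dir, sub("\\.csv$", ".json", basename(f)))
    write_site_aggregate(agg, path)
    path
  }, character(1), USE.NAMES = FALSE)
  write_manifest(dir, "aggregate", inputs = file_hashes(files),
                 outputs = file_hashes(out_paths),
                 config_hash = object_hash(unclass(policy)),
                 n_in = n, n_out = n)
}

stage_combine <- function(config, dir) {
  require_upstream(config, "combine", "aggregate")
  files <- stage_files(stage_dir(config, "aggregate"), "\\.json$")
  aggs <- lapply(files, read_site_aggregate)
  result <- combine_aggregates(aggs)
  path <- file.path(dir, "federated.json")
  write_federated_result(result, path)
  write_manifest(dir, "combine", inputs = file_hashes(files),
                 outputs = file_hashes(path),
                 config_hash = object_hash(config$min_cell),
                 n_in = length(aggs), n_out = result$combined_total)
}

stage_evaluate <- function(config, dir) {
  require_upstream(config, "evaluate", "combine")
  if (is.null(config$gold)) {
    inform("no gold table configured; skipping evaluate stage")
    return(write_manifest(dir, "evaluate", inputs = list(), outputs = list(),
                          config_hash = object_hash(NULL), n_in = 0L,
                          n_out = 0L, notes = list(skipped = TRUE)))
  }
  fed_path <- file.path(stage_dir(config, "combine"), "federated.json")
  result <- read_federated_result(fed_path)
  predicted <- result$entity_marginals |>
    filter(!.data$suppressed) |>
    select("entity_group", "count")
  gold <- read_count_table(config$gold)
  report <- mape_report(predicted, gold)
  path <- file.path(dir, "deviation.json")
  jsonlite::write_json(
    list(mape_percent = report$mape, n_entities = report$n_entities,
         excluded = report$excluded, table = report$table),
    path, auto_unbox = TRUE, na = "null", digits = NA
  )
  write_manifest(dir, "evaluate",
                 inputs = file_hashes(c(fed_path, config$gold)),
                 outputs = file_hashes(path),
                 config_hash = object_hash(config$gold),
                 n_in = nrow(report$table), n_out = report$n_entities,
                 notes = list(mape_percent = report$mape))
}

stage_report <- function(config, dir) {
  require_upstream(config, "report", "combine")
  result <- read_federated_result(
    file.path(stage_dir(config, "combine"), "federated.json")
  )
  q1_combined <- entity_shares(result)
  q1_sites <- purrr::map_dfr(names(result$per_site), function(s) {
    mutate(entity_shares(result, s), site_id = s, .before = 1)
  })
  q2_mean <- gender_shares(result, "mean_of_sites")
  q2_pooled <- gender_shares(result, "pooled")
  paths <- c(
    q1_combined = file.path(dir, "q1_entity_shares_combined.csv"),
    q1_sites = file.path(dir, "q1_entity_shares_per_site.csv"),
    q2_mean = file.path(dir, "q2_gender_shares_mean_of_sites.csv"),
    q2_pooled = file.path(dir, "q2_gender_shares_pooled.csv"),
    summary = file.path(dir, "summary.md")
  )
  readr::write_csv(q1_combined, paths[["q1_combined"]], progress = FALSE)
  readr::write_csv(q1_sites, paths[["q1_sites"]], progress = FALSE)
  readr::write_csv(q2_mean, paths[["q2_mean"]], progress = FALSE)
  readr::write_csv(q2_pooled, paths[["q2_pooled"]], progress = FALSE)
  writeLines(report_markdown(result, q1_combined, q2_mean), paths[["summary"]])
  write_manifest(dir, "report", inputs = file_hashes(
    file.path(stage_dir(config, "combine"), "federated.json")),
    outputs = file_hashes(unname(paths)),
    config_hash = object_hash("report-v1"),
    n_in = 1L, n_out = length(paths))
}

report_markdown <- function(result, q1, q2) {
  gm <- result$gender_marginals
  fmt_count <- function(x) ifelse(is.na(x), "suppressed",
                                  format(x, big.mark = ","))
  c(
    "# Federated analysis summary",
    "",
    sprintf("- sites: %d", length(result$per_site)),
    sprintf("- combined cases: %s", format(result$combined_total, big.mark = ",")),
    sprintf("- gender marginals: %s",
            paste(sprintf("%s %s", gm$gender, fmt_count(gm$count)),
                  collapse = ", ")),
    "",
    "## Q1: entity distribution (combined)",
    "",
    "| entity | cases | share % |",
    "|---|---:|---:|",
    sprintf("| %s | %s | %s |", q1$entity_group, fmt_count(q1$count),
            ifelse(is.na(q1$share), "suppressed", q1$share)),
    "",
    "## Q2: gender share per entity (mean of sites)",
    "",
    "| entity | gender | share % |",
    "|---|---|---:|",
    sprintf("| %s | %s | %s |", q2$entity_group, q2$gender,
            ifelse(is.na(q2$share), "suppressed", q2$share))
  )
}
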