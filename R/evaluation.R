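#' Entity-wise deviation
#'
#' Per-entity relative deviation between the federated analysis result
#' (predicted) and the tumor-documentation gold standard:
#' `|predicted - gold| / gold`. A gold count of zero has no defined relative
#' deviation; such entities yield `NA` with a warning and are excluded from
#' the mean downstream.
#'
#' @param predicted Numeric vector of predicted counts.
#' @param gold Numeric vector of gold-standard counts (same length).
#' @return Numeric vector of deviation fractions (`NA` where `gold == 0`).
#' @examples
#' entity_deviation(110, 100)  # 0.10
#' entity_deviation(90, 120)   # 0.25
#' @export
entity_deviation <- function(predicted, gold) {
  stopifnot(length(predicted) == length(gold))
  zero <- !is.na(gold) & gold == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " entity(ies) have gold count 0; deviation is NA"))
  }
  ifelse(zero, NA_real_, abs(predicted - gold) / gold)
}

#' Mean absolute percentage error between count tables
#'
#' Joins two entity-keyed count tables, computes the entity-wise deviation
#' for each entity and averages (unweighted arithmetic mean) over entities
#' with a positive gold count. Entities present in the prediction but absent
#' from the gold standard count as gold 0 and are excluded with a warning;
#' entities absent from the prediction count as predicted 0 (deviation 1).
#' The mean is reported as a percentage.
#'
#' @param predicted,gold Data frames with columns `entity_group` and `count`.
#' @return A `deviation_report`: list with `table` (per-entity tibble of
#'   `entity_group`, `predicted`, `gold`, `deviation`), `mape` (percent),
#'   `n_entities` (included in the mean) and `excluded` (zero-gold labels).
#' @export
mape_report <- function(predicted, gold) {
  stopifnot(all(c("entity_group", "count") %in% names(predicted)),
            all(c("entity_group", "count") %in% names(gold)))
  tbl <- full_join(
    as_tibble(predicted) |> select("entity_group", predicted = "count"),
    as_tibble(gold) |> select("entity_group", gold = "count"),
    by = "entity_group"
  ) |>
    mutate(predicted = coalesce(as.numeric(.data$predicted), 0),
           gold = coalesce(as.numeric(.data$gold), 0))
  tbl$deviation <- withCallingHandlers(
    entity_deviation(tbl$predicted, tbl$gold),
    rlang_warning = function(w) invokeRestart("muffleWarning"),
    warning = function(w) invokeRestart("muffleWarning")
  )
  excluded <- tbl$entity_group[tbl$gold == 0]
  if (length(excluded)) {
    warn(paste0("excluded from MAPE (gold count 0): ",
                paste(excluded, collapse = ", ")))
  }
  included <- tbl$gold > 0
  structure(
    list(table = tbl,
         mape = 100 * mean(tbl$deviation[included]),
         n_entities = sum(included),
         excluded = excluded),
    class = "deviation_report"
  )
}

# one decimal, except below 2% where two decimals are kept
format_mape <- function(mape) {
  if (is.nan(mape)) return("NaN%")
  digits <- if (abs(mape) < 2) 2 else 1
  paste0(formatC(round_half_up(mape, digits), format = "f", digits = digits), "%")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("<deviation_report> MAPE ", format_mape(x$mape), " over ",
      x$n_entities, " entities", sep = "")
  if (length(x$excluded)) {
    cat(" (excluded: ", paste(x$excluded, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  worst <- x$table |> filter(.data$gold > 0) |> arrange(desc(.data$deviation)) |>
    utils::head(3)
  for (i in seq_len(nrow(worst))) {
    cat(sprintf("  %-18s predicted %6.0f  gold %6.0f  deviation %5.1f%%\n",
                worst$entity_group[i], worst$predicted[i], worst$gold[i],
                100 * worst$deviation[i]))
  }
  invisible(x)
}

#' Compare two entity distributions
#'
#' Side-by-side per-entity shares of two count tables (for example the
#' federated 2021/2022 result against a cancer registry's 2019 annual
#' report), each computed against its own total, with share differences.
#' Sorted by the first table's share, descending.
#'
#' @param table_a,table_b Data frames with `entity_group` and `count`.
#' @param labels Length-2 character vector naming the two tables.
#' @return A `registry_comparison`: tibble `entity_group`, `count_a`,
#'   `share_a`, `count_b`, `share_b`, `share_diff` (percent, one decimal),
#'   with the labels and totals as attributes.
#' @export
compare_distributions <- function(table_a, table_b, labels = c("A", "B")) {
  stopifnot(nrow(table_a) > 0, nrow(table_b) > 0, length(labels) == 2)
  total_a <- sum(table_a$count)
  total_b <- sum(table_b$count)
  out <- full_join(
    as_tibble(table_a) |> select("entity_group", count_a = "count"),
    as_tibble(table_b) |> select("entity_group", count_b = "count"),
    by = "entity_group"
  ) |>
    mutate(
      count_a = coalesce(.data$count_a, 0),
      count_b = coalesce(.data$count_b, 0),
      share_a = round_half_up(100 * .data$count_a / total_a, 1),
      share_b = round_half_up(100 * .data$count_b / total_b, 1),
      share_diff = round_half_up(.data$share_a - .data$share_b, 1)
    ) |>
    select("entity_group", "count_a", "share_a", "count_b", "share_b",
           "share_diff") |>
    arrange(desc(.data$share_a))
  structure(out, labels = labels, totals = c(a = total_a, b = total_b),
            class = c("registry_comparison", class(tibble())))
}

#' Load a gold-standard count table
#'
#' A two-column CSV `entity_group,count`, as produced by querying a tumor
#' documentation system. The packaged `bavarian_registry_2019.csv` carries
#' the ten most frequent entity counts of the Bavarian Cancer Registry's
#' 2019 annual report plus an `other` remainder row so that shares are
#' computed against the report's full total of 63,771 diagnoses.
#'
#' @param path CSV path, or `NULL` for the packaged registry table.
#' @return A tibble `entity_group`, `count`.
#' @export
read_count_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "bavarian_registry_2019.csv",
                                package = "oncofed", mustWork = TRUE)
  readr::read_csv(path, progress = FALSE, show_col_types = FALSE,
                  col_types = readr::cols(entity_group = "c", count = "i"))
}
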