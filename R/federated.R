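#' Disclosure policy for aggregate statistics
#'
#' Small-cell suppression: any aggregate cell or marginal whose count is
#' positive but below `min_cell` is withheld before anything leaves the
#' site. The default threshold of 5 is a common registry small-cell rule.
#' True zeros are reported as 0 by default (a zero reveals only absence);
#' `suppress_zero = TRUE` switches to strict mode where zeros are withheld
#' too. Totals are computed before suppression and are never reduced by it.
#'
#' @param min_cell Positive integer suppression threshold.
#' @param suppress_zero Withhold true-zero cells as well.
#' @return A `disclosure_policy` object.
#' @export
disclosure_policy <- function(min_cell = 5L, suppress_zero = FALSE) {
  min_cell <- as.integer(min_cell)
  if (is.na(min_cell) || min_cell < 1) abort("min_cell must be >= 1")
  structure(list(min_cell = min_cell, suppress_zero = suppress_zero),
            class = "disclosure_policy")
}

suppress_counts <- function(count, policy) {
  sup <- (count > 0 & count < policy$min_cell) |
    (policy$suppress_zero & count == 0)
  list(count = ifelse(sup, NA_integer_, as.integer(count)), suppressed = sup)
}

#' Aggregate one site's case table under disclosure control
#'
#' Cross-tabulates the site's cases by entity group and gender, then applies
#' small-cell suppression to the cells and to the entity and gender
#' marginals. The returned aggregate is the *only* object a site exports:
#' raw rows never leave this function's scope, suppressed counts are stored
#' as `NA` (the true value is discarded, not hidden), and `total_cases` is
#' the pre-suppression row count.
#'
#' @param table A single-site `case_table`.
#' @param policy A [disclosure_policy()].
#' @return A `site_aggregate`: list with `site_id`, `total_cases`, `cells`
#'   (tibble `entity_group`, `gender`, `count`, `suppressed`),
#'   `entity_marginals`, `gender_marginals`, and the policy.
#' @export
aggregate_site <- function(table, policy = disclosure_policy()) {
  stopifnot(is.data.frame(table), inherits(policy, "disclosure_policy"))
  sites <- unique(table$site_id)
  if (length(sites) != 1) {
    abort(paste0("aggregate_site() expects exactly one site_id, got ",
                 length(sites)))
  }
  cells <- as_tibble(table) |>
    count(.data$entity_group, .data$gender, name = "n")
  cs <- suppress_counts(cells$n, policy)
  ent <- as_tibble(table) |> count(.data$entity_group, name = "n")
  es <- suppress_counts(ent$n, policy)
  gen <- as_tibble(table) |> count(.data$gender, name = "n")
  gs <- suppress_counts(gen$n, policy)
  structure(
    list(
      site_id = sites,
      total_cases = nrow(table),
      cells = tibble(entity_group = cells$entity_group, gender = cells$gender,
                     count = cs$count, suppressed = cs$suppressed),
      entity_marginals = tibble(entity_group = ent$entity_group,
                                count = es$count, suppressed = es$suppressed),
      gender_marginals = tibble(gender = gen$gender,
                                count = gs$count, suppressed = gs$suppressed),
      policy = policy
    ),
    class = "site_aggregate"
  )
}

#' @export
print.site_aggregate <- function(x, ...) {
  cat("<site_aggregate> ", x$site_id, ": ", x$total_cases, " cases, ",
      nrow(x$cells), " cells (", sum(x$cells$suppressed), " suppressed, ",
      "min_cell=", x$policy$min_cell, ")\n", sep = "")
  invisible(x)
}

# sum a count column across sites: suppressed anywhere -> suppressed overall;
# a site that lacks the key contributes a true zero
combine_counts <- function(tbls, key_cols) {
  all <- bind_rows(tbls)
  all |>
    group_by(across(all_of(key_cols))) |>
    summarise(
      suppressed = any(.data$suppressed),
      count = if (any(.data$suppressed)) NA_integer_ else
        as.integer(sum(.data$count)),
      .groups = "drop"
    ) |>
    select(all_of(key_cols), "count", "suppressed")
}

#' Combine site aggregates into a federated result
#'
#' The central-client step: combined totals are sums of site totals; a
#' combined cell or marginal is the sum over sites if every site reported it
#' unsuppressed (sites without the cell contribute a true zero), otherwise
#' it is suppressed. Per-site aggregates are retained so site-scoped shares
#' (research question Q1) can be derived without re-contacting sites.
#'
#' @param aggregates A list of [aggregate_site()] results with distinct
#'   `site_id`s.
#' @return A `federated_result`: list with `per_site`, `combined_total`,
#'   `cells`, `entity_marginals`, `gender_marginals`.
#' @seealso [entity_shares()], [gender_shares()]
#' @export
combine_aggregates <- function(aggregates) {
  if (!length(aggregates)) abort("no site aggregates to combine")
  stopifnot(all(vapply(aggregates, inherits, logical(1), "site_aggregate")))
  ids <- vapply(aggregates, `[[`, character(1), "site_id")
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate site_id in combine: ",
                 paste(ids[duplicated(ids)], collapse = ", ")))
  }
  structure(
    list(
      per_site = stats::setNames(aggregates, ids),
      combined_total = sum(vapply(aggregates, `[[`, integer(1), "total_cases")),
      cells = combine_counts(lapply(aggregates, `[[`, "cells"),
                             c("entity_group", "gender")),
      entity_marginals = combine_counts(
        lapply(aggregates, `[[`, "entity_marginals"), "entity_group"),
      gender_marginals = combine_counts(
        lapply(aggregates, `[[`, "gender_marginals"), "gender")
    ),
    class = "federated_result"
  )
}

#' @export
print.federated_result <- function(x, ...) {
  cat("<federated_result> ", length(x$per_site), " sites, ",
      format(x$combined_total, big.mark = ","), " cases\n", sep = "")
  top <- entity_shares(x) |> utils::head(5)
  cat("  top entities (combined):\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %-18s %6s  %5.1f%%\n", top$entity_group[i],
                format(top$count[i], big.mark = ","), top$share[i]))
  }
  invisible(x)
}

#' Entity distribution (research question Q1)
#'
#' Relative frequency of each entity group as a percentage of the scope's
#' total cases -- either a single site or the combined federation. Shares of
#' suppressed entity marginals are `NA`; percentages are rounded half-up to
#' one decimal. Because suppressed and fallback cases still count toward the
#' total, reported shares sum to at most 100%.
#'
#' @param result A [combine_aggregates()] result.
#' @param scope `"combined"` or one of the site ids.
#' @return A tibble `entity_group`, `count`, `share`, sorted by decreasing
#'   share.
#' @export
entity_shares <- function(result, scope = "combined") {
  stopifnot(inherits(result, "federated_result"))
  if (identical(scope, "combined")) {
    marg <- result$entity_marginals
    total <- result$combined_total
  } else {
    if (!scope %in% names(result$per_site)) {
      abort(paste0("unknown scope: ", scope))
    }
    agg <- result$per_site[[scope]]
    marg <- agg$entity_marginals
    total <- agg$total_cases
  }
  marg |>
    mutate(share = round_half_up(100 * .data$count / total, 1)) |>
    select("entity_group", "count", "share") |>
    arrange(desc(.data$share))
}

#' Gender distribution per entity (research question Q2)
#'
#' Two estimators of the gender share within each entity group:
#' * `pooled` -- combined cell count divided by the combined entity marginal
#'   (equivalent to a centralized recount when nothing is suppressed);
#' * `mean_of_sites` -- the unweighted arithmetic mean over sites of each
#'   site's own gender share for the entity; sites whose cell or entity
#'   marginal is suppressed are excluded from the mean and counted in
#'   `n_sites_excluded`.
#'
#' @param result A [combine_aggregates()] result.
#' @param estimator `"pooled"` or `"mean_of_sites"`.
#' @return A tibble `entity_group`, `gender`, `share` (percent, one
#'   decimal), plus `n_sites_used`/`n_sites_excluded` for `mean_of_sites`.
#' @export
gender_shares <- function(result, estimator = c("mean_of_sites", "pooled")) {
  stopifnot(inherits(result, "federated_result"))
  estimator <- match.arg(estimator)
  if (estimator == "pooled") {
    out <- result$cells |>
      left_join(result$entity_marginals |>
                  select("entity_group", marg = "count",
                         marg_sup = "suppressed"),
                by = "entity_group") |>
      mutate(share = ifelse(
        .data$suppressed | .data$marg_sup, NA_real_,
        round_half_up(100 * .data$count / .data$marg, 1)
      )) |>
      select("entity_group", "gender", "share")
    return(arrange(out, .data$entity_group, .data$gender))
  }
  # the (entity, gender) grid observed anywhere in the federation: a site
  # holding the entity but none of some gender contributes a true-zero share
  combos <- distinct(result$cells, .data$entity_group, .data$gender)
  per_site <- purrr::imap_dfr(result$per_site, function(agg, sid) {
    em <- agg$entity_marginals |>
      filter(!.data$suppressed, .data$count > 0) |>
      select("entity_group", marg = "count")
    combos |>
      inner_join(em, by = "entity_group") |>
      left_join(agg$cells, by = c("entity_group", "gender")) |>
      mutate(
        site_id = sid,
        usable = !isTRUE_vec(.data$suppressed),
        site_share = ifelse(.data$usable,
                            100 * coalesce(.data$count, 0L) / .data$marg,
                            NA_real_)
      )
  })
  per_site |>
    group_by(.data$entity_group, .data$gender) |>
    summarise(
      share = if (any(.data$usable))
        round_half_up(mean(.data$site_share[.data$usable]), 1) else NA_real_,
      n_sites_used = sum(.data$usable),
      n_sites_excluded = sum(!.data$usable),
      .groups = "drop"
    ) |>
    arrange(.data$entity_group, .data$gender)
}

#' Serialize aggregates and federated results as JSON
#'
#' The disclosure-controlled JSON handed across the site boundary: only
#' suppressed-aware counts appear; no pseudonym, raw row, or sub-threshold
#' count is present in the serialization by construction.
#'
#' @param x A `site_aggregate` or `federated_result`.
#' @param path JSON file path.
#' @export
write_site_aggregate <- function(x, path) {
  stopifnot(inherits(x, "site_aggregate"))
  obj <- list(
    site_id = x$site_id, total_cases = x$total_cases,
    min_cell = x$policy$min_cell, suppress_zero = x$policy$suppress_zero,
    cells = x$cells, entity_marginals = x$entity_marginals,
    gender_marginals = x$gender_marginals
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}

#' @rdname write_site_aggregate
#' @export
read_site_aggregate <- function(path) {
  obj <- jsonlite::fromJSON(path)
  fix <- function(df) {
    df$count <- as.integer(df$count)
    df$suppressed <- as.logical(df$suppressed)
    as_tibble(df)
  }
  structure(
    list(
      site_id = obj$site_id, total_cases = obj$total_cases,
      cells = fix(obj$cells),
      entity_marginals = fix(obj$entity_marginals),
      gender_marginals = fix(obj$gender_marginals),
      policy = disclosure_policy(obj$min_cell, isTRUE(obj$suppress_zero))
    ),
    class = "site_aggregate"
  )
}

#' @rdname write_site_aggregate
#' @export
read_federated_result <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  fix <- function(df) {
    df$count <- as.integer(df$count)
    df$suppressed <- as.logical(df$suppressed)
    as_tibble(df)
  }
  per_site <- lapply(seq_len(nrow(obj$per_site)), function(i) {
    structure(
      list(
        site_id = obj$per_site$site_id[i],
        total_cases = obj$per_site$total_cases[i],
        cells = fix(obj$per_site$cells[[i]]),
        entity_marginals = fix(obj$per_site$entity_marginals[[i]]),
        gender_marginals = fix(obj$per_site$gender_marginals[[i]]),
        policy = disclosure_policy(obj$per_site$min_cell[i],
                                   isTRUE(obj$per_site$suppress_zero[i]))
      ),
      class = "site_aggregate"
    )
  })
  names(per_site) <- vapply(per_site, `[[`, character(1), "site_id")
  structure(
    list(per_site = per_site, combined_total = obj$combined_total,
         cells = fix(obj$cells),
         entity_marginals = fix(obj$entity_marginals),
         gender_marginals = fix(obj$gender_marginals)),
    class = "federated_result"
  )
}

#' @rdname write_site_aggregate
#' @export
write_federated_result <- function(x, path) {
  stopifnot(inherits(x, "federated_result"))
  obj <- list(
    combined_total = x$combined_total,
    sites = names(x$per_site),
    cells = x$cells,
    entity_marginals = x$entity_marginals,
    gender_marginals = x$gender_marginals,
    per_site = lapply(unname(x$per_site), function(a) list(
      site_id = a$site_id, total_cases = a$total_cases,
      min_cell = a$policy$min_cell, suppress_zero = a$policy$suppress_zero,
      cells = a$cells, entity_marginals = a$entity_marginals,
      gender_marginals = a$gender_marginals
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
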