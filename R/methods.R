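#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for federated results and deviation reports
#'
#' `tidy()` returns the per-cell (or per-entity) tibble underlying an
#' object; `glance()` returns a one-row summary.
#'
#' @param x A `federated_result`, `site_aggregate` or `deviation_report`.
#' @param ... Unused.
#' @return A tibble.
#' @name oncofed-tidiers
NULL

#' @rdname oncofed-tidiers
#' @exportS3Method generics::tidy
tidy.federated_result <- function(x, ...) {
  x$cells
}

#' @rdname oncofed-tidiers
#' @exportS3Method generics::glance
glance.federated_result <- function(x, ...) {
  tibble(
    n_sites = length(x$per_site),
    combined_total = x$combined_total,
    n_cells = nrow(x$cells),
    n_suppressed_cells = sum(x$cells$suppressed)
  )
}

#' @rdname oncofed-tidiers
#' @exportS3Method generics::tidy
tidy.site_aggregate <- function(x, ...) {
  mutate(x$cells, site_id = x$site_id, .before = 1)
}

#' @rdname oncofed-tidiers
#' @exportS3Method generics::glance
glance.site_aggregate <- function(x, ...) {
  tibble(
    site_id = x$site_id,
    total_cases = x$total_cases,
    n_cells = nrow(x$cells),
    n_suppressed_cells = sum(x$cells$suppressed),
    min_cell = x$policy$min_cell
  )
}

#' @rdname oncofed-tidiers
#' @exportS3Method generics::tidy
tidy.deviation_report <- function(x, ...) {
  x$table
}

#' @rdname oncofed-tidiers
#' @exportS3Method generics::glance
glance.deviation_report <- function(x, ...) {
  tibble(mape = x$mape, n_entities = x$n_entities,
         n_excluded = length(x$excluded))
}

#' Plot a federated result
#'
#' `type = "entities"` shows the entity distribution per site and combined
#' (research question Q1); `type = "gender"` shows the gender share within
#' each entity under the chosen estimator (Q2). Suppressed values are simply
#' absent from the plot.
#'
#' @param object A `federated_result`.
#' @param type `"entities"` or `"gender"`.
#' @param estimator Passed to [gender_shares()] when `type = "gender"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.federated_result <- function(object, type = c("entities", "gender"),
                                      estimator = "mean_of_sites", ...) {
  type <- match.arg(type)
  if (type == "entities") {
    scopes <- c(names(object$per_site), "combined")
    df <- purrr::map_dfr(scopes, function(s) {
      mutate(entity_shares(object, s), scope = s)
    })
    df <- filter(df, !is.na(.data$share))
    lv <- entity_shares(object) |> arrange(.data$share)
    df$entity_group <- factor(df$entity_group, levels = lv$entity_group)
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$share, y = .data$entity_group)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::facet_wrap(~scope) +
        ggplot2::labs(x = "share of cases (%)", y = NULL,
                      title = "Tumor entity distribution (Q1)") +
        ggplot2::theme_minimal()
    )
  }
  df <- gender_shares(object, estimator) |> filter(!is.na(.data$share))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$share, y = .data$entity_group,
                                   fill = .data$gender)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = "share within entity (%)", y = NULL, fill = "gender",
                  title = paste0("Gender distribution per entity (Q2, ",
                                 estimator, ")")) +
    ggplot2::theme_minimal()
}

#' Plot a deviation report
#'
#' Per-entity deviation between federated result and gold standard, with the
#' MAPE in the title.
#'
#' @param object A `deviation_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.deviation_report <- function(object, ...) {
  df <- object$table |> filter(.data$gold > 0)
  df$entity_group <- stats::reorder(df$entity_group, df$deviation)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$deviation,
                                   y = .data$entity_group)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::labs(x = "entity-wise deviation (%)", y = NULL,
                  title = paste0("Deviation vs gold standard (MAPE ",
                                 format_mape(object$mape), ")")) +
    ggplot2::theme_minimal()
}
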