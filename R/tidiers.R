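#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection report
#'
#' @param x an `egc_report`.
#' @param ... unused.
#' @return A plain tibble with one row per energy currency (`label`,
#'   `integration`, `optimum`, `has_egc`, `status`).
#' @export
tidy.egc_report <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))[, c("label", "integration", "optimum",
                                          "has_egc", "status")]
}

#' One-row summary of a detection report
#'
#' @param x an `egc_report`.
#' @param ... unused.
#' @return A one-row tibble: `model_id`, `n_targets`, `n_active`, `n_egc`,
#'   `has_egcs`, `aggregate_optimum`.
#' @export
glance.egc_report <- function(x, ...) {
  tibble::tibble(model_id = attr(x, "model_id"),
                 n_targets = nrow(x),
                 n_active = sum(x$status != "not integrated"),
                 n_egc = sum(x$has_egc),
                 has_egcs = any(x$has_egc),
                 aggregate_optimum = attr(x, "aggregate_optimum"))
}

#' Tidy a removal solution
#'
#' @param x a `removal_solution`.
#' @param ... unused.
#' @return The removal tibble (`reaction_id`, `direction`, `weight`).
#' @export
tidy.removal_solution <- function(x, ...) x$removals

#' One-row summary of a removal solution
#'
#' @param x a `removal_solution`.
#' @param ... unused.
#' @return A one-row tibble with the objective, biomass before/after, the
#'   biomass ratio, certification flags and solver status.
#' @export
glance.removal_solution <- function(x, ...) {
  tibble::tibble(model_id = x$model_id, status = x$status,
                 objective = x$objective, n_removals = nrow(x$removals),
                 biomass_before = x$biomass_before,
                 biomass_after = x$biomass_after,
                 biomass_ratio = x$biomass_after / x$biomass_before,
                 certified_egc_free = x$certified_egc_free,
                 growth_ok = x$growth_ok)
}

#' Plot a detection report
#'
#' Bar chart of the per-currency dissipation optima; currencies whose
#' template could not be integrated are shown as missing.
#'
#' @param object an `egc_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.egc_report <- function(object, ...) {
  df <- tidy(object)
  df$label <- factor(df$label, levels = rev(df$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$optimum, y = .data$label,
                                   fill = .data$has_egc)) +
    ggplot2::geom_col(na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#b0357f"),
                               name = "cycle") +
    ggplot2::labs(x = "maximal dissipation flux (clamp units)",
                  y = NULL,
                  title = paste0("Energy-generating cycles: ",
                                 attr(object, "model_id"))) +
    ggplot2::theme_minimal()
}

#' Plot biomass impact across a batch
#'
#' Histogram of the after/before biomass ratios of corrected models.
#'
#' @param summary a [run_batch()] result.
#' @param bins number of histogram bins.
#' @return A ggplot object.
#' @export
plot_biomass_impact <- function(summary, bins = 20) {
  df <- summary[!is.na(summary$biomass_ratio), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$biomass_ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "#2c7fb8", colour = "white") +
    ggplot2::labs(x = "biomass optimum after / before correction",
                  y = "models") +
    ggplot2::theme_minimal()
}
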