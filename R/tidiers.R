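# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux solution into a reaction/flux table
#'
#' @param x a `flux_solution` from [solve_fba()].
#' @param ... unused.
#' @return tibble with `reaction_id`, `flux`, `is_exchange`.
#' @export
tidy.flux_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(reaction_id = character(0), flux = numeric(0),
                  is_exchange = logical(0)))
  }
  tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes),
         is_exchange = names(x$fluxes) %in% x$exchange_ids)
}

#' One-row summary of a flux solution
#'
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return tibble with `status`, `objective_value`, `max_residual`.
#' @export
glance.flux_solution <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         max_residual = x$max_residual %||% NA_real_)
}

#' Tidy a strain clustering into its label table
#'
#' @param x a `strain_clustering` from [cluster_strains()].
#' @param ... unused.
#' @return tibble with `strain`, `cluster`, `group`, `subgroup`, `n_positive`.
#' @export
tidy.strain_clustering <- function(x, ...) x$labels

#' One-row summary of a strain clustering
#'
#' @param x a `strain_clustering`.
#' @param ... unused.
#' @return tibble with strain counts per group and the settings used.
#' @export
glance.strain_clustering <- function(x, ...) {
  tibble(n_strains = nrow(x$labels),
         n_hmv = sum(x$labels$group == "HMV", na.rm = TRUE),
         n_lmv = sum(x$labels$group == "LMV", na.rm = TRUE),
         degenerate = x$degenerate,
         distance = x$distance, linkage = x$linkage, layer = x$layer)
}

#' Heatmap of a growth matrix
#'
#' @param object a `growth_matrix` from [build_growth_matrix()].
#' @param layer `"normalized"`, `"raw"` or `"binary"`.
#' @param clustering optional `strain_clustering` used to order the strains by
#'   dendrogram leaves.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.growth_matrix <- function(object, layer = c("normalized", "raw",
                                                     "binary"),
                                   clustering = NULL, ...) {
  layer <- match.arg(layer)
  col <- switch(layer, normalized = "normalized_growth", raw = "growth_rate",
                binary = "grows")
  dat <- as_tibble(object)
  if (!is.null(clustering)) {
    dat$strain <- factor(dat$strain, levels = leaf_order(clustering))
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$carbon_source, y = .data$strain,
                                    fill = .data[[col]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = layer) +
    ggplot2::labs(x = "carbon source", y = "strain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Predicted-versus-measured flux scatter
#'
#' @param object a `flux_comparison` from [compare_flux_sets()].
#' @param ... unused.
#' @return a ggplot object, one panel per pathway, annotated with bicor.
#' @export
autoplot.flux_comparison <- function(object, ...) {
  pairs <- bind_rows(lapply(seq_len(nrow(object)), function(i) {
    mutate(object$pairs[[i]], panel = object$pathway[i])
  }))
  labels <- mutate(as_tibble(object),
                   label = sprintf("bicor = %.2f (p = %.2g)",
                                   .data$bicor, .data$p_value))
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$measured_flux,
                                      y = .data$predicted_flux)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::geom_text(data = mutate(labels, panel = .data$pathway),
                       ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.05, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::labs(x = expression(measured~flux~(mmol~gDW^-1~h^-1)),
                  y = expression(predicted~flux~(mmol~gDW^-1~h^-1))) +
    ggplot2::theme_bw()
}

#' Carbon-source classification bar chart
#'
#' @param object a `source_classification` from [classify_sources()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.source_classification <- function(object, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(
      x = stats::reorder(.data$carbon_source, -.data$growth_fraction),
      y = .data$growth_fraction, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(attr(object, "specific"),
                                       attr(object, "universal")),
                        linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "carbon source", y = "fraction of strains with growth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
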