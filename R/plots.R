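#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_point
#'   geom_hline facet_grid facet_wrap labs scale_fill_gradient2
#'   position_dodge theme_minimal element_blank theme
#' @export
ggplot2::autoplot

#' Heatmap of a residual association network
#'
#' @param object An [compute_association_network()] result.
#' @param supported_only Blank out unsupported correlations (default `TRUE`)
#'   so only the statistically supported associations are shown.
#' @param ... Unused.
#' @return A ggplot object: species-by-species posterior-mean residual
#'   correlations, ordered by guild.
#' @export
autoplot.association_network <- function(object, supported_only = TRUE, ...) {
  ord <- order(object$species$guild, object$species$otu_id)
  R <- object$R_mean[ord, ord]
  sup <- object$support[ord, ord]
  keep <- pmax(sup, 1 - sup) >= object$support_level
  if (supported_only) R[!keep] <- NA
  diag(R) <- NA
  df <- tibble(
    source = factor(rep(rownames(R), times = ncol(R)), levels = rownames(R)),
    target = factor(rep(colnames(R), each = nrow(R)), levels = colnames(R)),
    correlation = as.vector(R))
  ggplot(df, aes(x = .data$source, y = .data$target,
                 fill = .data$correlation)) +
    geom_tile() +
    scale_fill_gradient2(low = "#b2182b", mid = "white", high = "#2166ac",
                         limits = c(-1, 1), na.value = "grey95") +
    labs(title = sprintf("Residual associations (%s part)", object$part),
         x = NULL, y = NULL, fill = "correlation") +
    theme_minimal() +
    theme(axis.text = element_blank(), panel.grid = element_blank())
}

#' Stacked bars of the variance partition
#'
#' @param object A [variance_partition()] result.
#' @param ... Unused.
#' @return A ggplot object: per-species proportions of explained variance by
#'   component, faceted by guild and model part, species ordered by the
#'   chemical share within each facet.
#' @export
autoplot.variance_partition <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$guild, .data$part, .data$otu_id) |>
    dplyr::mutate(order_key = sum(
      .data$proportion[.data$group == "chemical"])) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$guild, .data$part, dplyr::desc(.data$order_key)) |>
    dplyr::mutate(otu = factor(.data$otu_id, levels = unique(.data$otu_id)))
  ggplot(df, aes(x = .data$otu, y = .data$proportion, fill = .data$group)) +
    geom_col(width = 1) +
    facet_grid(part ~ guild, scales = "free_x") +
    labs(x = NULL, y = "proportion of explained variance", fill = NULL) +
    theme_minimal() +
    theme(axis.text.x = element_blank(), panel.grid = element_blank())
}

#' Guild-mean predictive power by regime
#'
#' @param object An [two_fold_cv()] evaluation report.
#' @param ... Unused.
#' @return A ggplot object: guild means per model and regime, faceted by
#'   model part (AUC for occurrence, R-squared for abundance).
#' @export
autoplot.evaluation_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$model, .data$regime, .data$guild, .data$part,
                    .data$metric) |>
    dplyr::summarise(power = mean(.data$value, na.rm = TRUE),
                     .groups = "drop")
  p <- ggplot(df, aes(x = .data$guild, y = .data$power, colour = .data$regime,
                      shape = .data$model)) +
    geom_point(position = position_dodge(width = 0.5), size = 3) +
    facet_wrap(~ .data$part, scales = "free_y") +
    labs(x = NULL, y = "guild-mean predictive power") +
    theme_minimal()
  ref <- dplyr::distinct(dplyr::filter(df, .data$metric == "auc"), .data$part)
  if (nrow(ref) > 0) {
    ref$yintercept <- 0.5      # chance level for AUC facets
    p <- p + geom_hline(data = ref, aes(yintercept = .data$yintercept),
                        linetype = 2, colour = "grey40")
  }
  p
}
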