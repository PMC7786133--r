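#' Residual species-to-species association network
#'
#' For each posterior draw the residual covariance is `Omega = Lambda
#' Lambda'` with the part's residual variance on the diagonal (1 for the
#' probit part, `sigma^2` for the lognormal part); its correlation form `R`
#' is averaged over draws, and the posterior probability that each
#' correlation is positive gives the support level of every candidate edge.
#' An edge is "supported" when the posterior probability of a common sign
#' reaches `support_level`.
#'
#' @param fit A [fit_jsdm()] object (at least 2 species).
#' @param support_level Posterior probability of a common sign required to
#'   call an edge supported (default 0.95).
#' @param part `"occurrence"`, `"abundance"`, or `"combined"` (the mean of
#'   the two parts' correlation matrices within each draw, a display
#'   convenience).
#' @return Object of class `association_network`: `R_mean`, `support`
#'   (posterior probability of a positive correlation), `edges` (tibble of
#'   all species pairs with `supported` flag and `scope`
#'   within/between-guild), plus the species table and settings.
#' @export
compute_association_network <- function(fit, support_level = 0.95,
                                        part = c("occurrence", "abundance",
                                                 "combined")) {
  stopifnot(inherits(fit, "jsdm_fit"))
  part <- match.arg(part)
  S <- nrow(fit$species)
  if (S < 2) abort("association networks need at least 2 species")
  if (support_level <= 0.5 || support_level > 1)
    abort("support_level must be in (0.5, 1]")

  draw_R <- function(lam, resid_diag) {
    stats::cov2cor(tcrossprod(lam) + diag(resid_diag, length(resid_diag)))
  }
  Rsum <- matrix(0, S, S)
  Ppos <- matrix(0, S, S)
  ndraw <- 0L
  for (ch in fit$chains) {
    for (d in seq_len(ch$n_draws)) {
      lam <- matrix(ch$lambda[, , d], 2L * S)
      if (fit$n_factors == 0) lam <- matrix(0, 2L * S, 1)
      R_occ <- draw_R(lam[seq_len(S), , drop = FALSE], rep(1, S))
      R <- switch(part,
        occurrence = R_occ,
        abundance = draw_R(lam[S + seq_len(S), , drop = FALSE], ch$sigma2[, d]),
        combined = (R_occ +
          draw_R(lam[S + seq_len(S), , drop = FALSE], ch$sigma2[, d])) / 2)
      Rsum <- Rsum + R
      Ppos <- Ppos + (R > 0) + 0.5 * (R == 0)   # exact zeros split evenly
      ndraw <- ndraw + 1L
    }
  }
  R_mean <- Rsum / ndraw
  support <- Ppos / ndraw
  ids <- fit$species$otu_id
  dimnames(R_mean) <- dimnames(support) <- list(ids, ids)

  ut <- which(upper.tri(R_mean), arr.ind = TRUE)
  g <- fit$species$guild
  edges <- tibble(
    source_otu = ids[ut[, 1]], target_otu = ids[ut[, 2]],
    source_guild = g[ut[, 1]], target_guild = g[ut[, 2]],
    mean_correlation = R_mean[ut],
    support_positive = support[ut]) |>
    dplyr::mutate(
      support = pmax(.data$support_positive, 1 - .data$support_positive),
      sign = ifelse(.data$support_positive >= 0.5, 1L, -1L),
      supported = .data$support >= support_level,
      scope = ifelse(.data$source_guild == .data$target_guild,
                     "within_guild", "between_guild"))

  structure(
    list(R_mean = R_mean, support = support, edges = edges,
         species = fit$species, support_level = support_level, part = part,
         n_draws = ndraw),
    class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf(
    "<association_network> %s part: %d species, %d/%d supported edges at %.2f support\n",
    x$part, nrow(x$species), sum(x$edges$supported), nrow(x$edges),
    x$support_level))
  invisible(x)
}

#' Contrast the null-model and full-model association networks
#'
#' Classifies every supported null-model edge as `retained` (supported with
#' the same sign in the full model), `sign_flipped` (supported with the
#' opposite sign) or `lost` (no longer supported once environmental
#' covariates are accounted for), separately within and between guilds.
#' Edges lost in the full model indicate co-occurrence driven by shared (or
#' opposite) habitat use rather than residual association.
#'
#' @param null_net,full_net [compute_association_network()] results on the
#'   same species set (typically from the depth-only and full-covariate
#'   models).
#' @return Object of class `network_contrast`: `edges` (classified
#'   null-model supported edges) and `summary` (counts and fractions by
#'   scope).
#' @export
compare_networks <- function(null_net, full_net) {
  stopifnot(inherits(null_net, "association_network"),
            inherits(full_net, "association_network"))
  if (!identical(null_net$species$otu_id, full_net$species$otu_id))
    abort("networks must be built on the same species set")
  fe <- full_net$edges |>
    dplyr::select("source_otu", "target_otu",
                  full_sign = "sign", full_supported = "supported")
  edges <- null_net$edges |>
    dplyr::filter(.data$supported) |>
    dplyr::left_join(fe, by = c("source_otu", "target_otu")) |>
    dplyr::mutate(status = dplyr::case_when(
      full_supported & full_sign == sign ~ "retained",
      full_supported & full_sign != sign ~ "sign_flipped",
      TRUE ~ "lost"))
  summary <- edges |>
    dplyr::count(.data$scope, .data$status) |>
    tidyr::complete(scope = c("within_guild", "between_guild"),
                    status = c("retained", "sign_flipped", "lost"),
                    fill = list(n = 0L)) |>
    dplyr::group_by(.data$scope) |>
    dplyr::mutate(fraction = ifelse(sum(.data$n) > 0, .data$n / sum(.data$n), NA_real_)) |>
    dplyr::ungroup()
  structure(list(edges = edges, summary = summary), class = "network_contrast")
}

#' @export
print.network_contrast <- function(x, ...) {
  cat("<network_contrast>\n")
  print(x$summary)
  invisible(x)
}

#' Write an association network as an edge-list TSV
#'
#' @param x An [compute_association_network()] result.
#' @param path Output path.
#' @param supported_only Keep only supported edges (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(x, path, supported_only = TRUE) {
  stopifnot(inherits(x, "association_network"))
  e <- x$edges
  if (supported_only) e <- dplyr::filter(e, .data$supported)
  readr::write_tsv(
    dplyr::select(e, "source_otu", "target_otu",
                  posterior_mean_correlation = "mean_correlation", "support"),
    path)
  invisible(path)
}
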