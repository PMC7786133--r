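#' Partition explained variance among covariate groups and the random effect
#'
#' For every species, model part and posterior draw, the fixed-effect
#' variance is the variance over samples of each covariate group's linear
#' predictor (`chemical`, `physical`, `depth`, per the design's group map),
#' with cross-group covariances split equally between the two groups
#' involved; the random-effect (association-network) component is the sum of
#' squared factor loadings.  Shares are normalized by the total explained
#' variance -- residual variance is not part of the partition -- and averaged
#' over draws.  Tiny negative shares that the covariance split can produce
#' under near-collinearity are clamped to zero and renormalized.
#'
#' @param fit A [fit_jsdm()] object fitted with designs that carry a
#'   `group_map` (see [build_design_matrix()]).
#' @return Tibble of class `variance_partition` with columns `otu_id`,
#'   `guild`, `part`, `group`, `proportion`.  The attribute `guild_summary`
#'   holds the species-averaged shares per guild and part, and averaged over
#'   parts (the "text box" summary).
#' @export
variance_partition <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  S <- nrow(fit$species)
  groups_all <- unique(unlist(lapply(fit$designs, function(d) d$group_map)))
  groups_all <- intersect(c("chemical", "physical", "depth"), groups_all)
  comp_names <- c(groups_all, "random")
  parts <- c("occurrence", "abundance")

  # accumulate per species x part x component, averaged over draws
  acc <- array(0, c(S, length(parts), length(comp_names)),
               dimnames = list(fit$species$otu_id, parts, comp_names))
  ndraw <- 0L
  for (ch in fit$chains) {
    D <- ch$n_draws
    for (d in seq_len(D)) {
      lam <- matrix(ch$lambda[, , d], 2L * S)
      if (fit$n_factors == 0) lam <- matrix(0, 2L * S, 1)
      for (pi in seq_along(parts)) {
        offset <- if (parts[pi] == "occurrence") 0L else S
        rand_var <- rowSums(lam[offset + seq_len(S), , drop = FALSE]^2)
        shares <- matrix(0, S, length(groups_all),
                         dimnames = list(NULL, groups_all))
        for (g in fit$guilds) {
          d_g <- fit$designs[[g]]
          cols_g <- which(fit$species$guild == g)
          beta <- matrix(ch$beta[, offset + cols_g, d], ncol = length(cols_g))
          X <- d_g$values
          Fg <- lapply(groups_all, function(grp) {
            cn <- names(d_g$group_map)[d_g$group_map == grp]
            if (length(cn) == 0) return(matrix(0, nrow(X), length(cols_g)))
            X[, cn, drop = FALSE] %*% beta[match(cn, colnames(X)), , drop = FALSE]
          })
          n <- nrow(X)
          for (a in seq_along(groups_all)) for (b in a:length(groups_all)) {
            cv <- colMeans(Fg[[a]] * Fg[[b]]) - colMeans(Fg[[a]]) * colMeans(Fg[[b]])
            cv <- cv * n / (n - 1)
            if (a == b) {
              shares[cols_g, a] <- shares[cols_g, a] + cv
            } else {
              shares[cols_g, a] <- shares[cols_g, a] + cv
              shares[cols_g, b] <- shares[cols_g, b] + cv
            }
          }
        }
        comp <- cbind(shares, random = rand_var)
        comp[comp < 0] <- 0
        tot <- rowSums(comp)
        tot[tot == 0] <- 1
        acc[, pi, ] <- acc[, pi, ] + comp / tot
      }
      ndraw <- ndraw + 1L
    }
  }
  acc <- acc / ndraw

  out <- tidyr::expand_grid(
    otu_id = fit$species$otu_id, part = parts, group = comp_names) |>
    dplyr::left_join(fit$species, by = "otu_id") |>
    dplyr::mutate(proportion = as.vector(acc[cbind(
      match(.data$otu_id, fit$species$otu_id),
      match(.data$part, parts),
      match(.data$group, comp_names))])) |>
    dplyr::select("otu_id", "guild", "part", "group", "proportion")

  guild_summary <- out |>
    dplyr::group_by(.data$guild, .data$part, .data$group) |>
    dplyr::summarise(proportion = mean(.data$proportion), .groups = "drop")
  overall <- out |>
    dplyr::group_by(.data$guild, .data$group) |>
    dplyr::summarise(proportion = mean(.data$proportion), .groups = "drop") |>
    dplyr::mutate(part = "both_parts", .before = "group")
  attr(out, "guild_summary") <- dplyr::bind_rows(guild_summary, overall)
  class(out) <- c("variance_partition", class(out))
  out
}

#' Species-averaged variance shares
#'
#' @param x A [variance_partition()] result.
#' @return Tibble of shares averaged over species, per guild and model part
#'   (plus `both_parts` rows averaging the two hurdle parts).
#' @export
guild_summary <- function(x) {
  stopifnot(inherits(x, "variance_partition"))
  attr(x, "guild_summary")
}

#' Write a variance partition to TSV
#'
#' @param x A [variance_partition()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variance_partition <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
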