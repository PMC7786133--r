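#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy posterior summaries of a fitted model
#'
#' @param x A [fit_jsdm()] object.
#' @param block Parameter block: `"beta"` (niche coefficients, original
#'   covariate scale), `"lambda"` (factor loadings) or `"sigma2"` (lognormal
#'   residual variances).
#' @param conf_level Width of the posterior credible interval.
#' @param ... Unused.
#' @return Tibble with one row per parameter: identifiers (`otu_id`,
#'   `guild`, `part`, `term`), posterior `estimate` (mean), `std.error`
#'   (posterior sd) and credible bounds `conf.low` / `conf.high`.
#' @export
tidy.jsdm_fit <- function(x, block = c("beta", "lambda", "sigma2"),
                          conf_level = 0.95, ...) {
  block <- match.arg(block)
  draws <- param_draws(x, block)
  S <- nrow(x$species)
  K <- max(x$n_factors, 1)
  p <- ncol(x$designs[[1]]$values)
  terms <- colnames(x$designs[[1]]$values)
  a <- (1 - conf_level) / 2
  # identifiers in the column-major order of the stored arrays
  id <- switch(block,
    beta = tibble(            # array p x 2S: term fastest, then part/species
      otu_id = rep(rep(x$species$otu_id, 2), each = p),
      part = rep(c("occurrence", "abundance"), each = p * S),
      term = rep(terms, times = 2 * S)),
    lambda = tibble(          # array 2S x K: species/part fastest
      otu_id = rep(rep(x$species$otu_id, 2), times = K),
      part = rep(rep(c("occurrence", "abundance"), each = S), times = K),
      term = rep(paste0("factor", seq_len(K)), each = 2 * S)),
    sigma2 = tibble(otu_id = x$species$otu_id, part = "abundance",
                    term = "sigma2"))
  qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
  id |>
    dplyr::left_join(x$species, by = "otu_id") |>
    dplyr::mutate(estimate = colMeans(draws),
                  std.error = apply(draws, 2, stats::sd),
                  conf.low = qs[1, ], conf.high = qs[2, ]) |>
    dplyr::select("otu_id", "guild", "part", "term", "estimate",
                  "std.error", "conf.low", "conf.high")
}

#' One-row model overview
#'
#' @param x A [fit_jsdm()] object.
#' @param ... Unused.
#' @return Tibble with dimensions, draw counts and (when at least two
#'   chains were run) worst-case convergence summaries for the niche
#'   coefficients.
#' @export
glance.jsdm_fit <- function(x, ...) {
  out <- tibble(
    n_samples = length(x$sample_ids), n_species = nrow(x$species),
    n_guilds = length(x$guilds), n_factors = x$n_factors,
    n_chains = length(x$chains),
    n_draws = sum(vapply(x$chains, function(ch) ch$n_draws, 1L)))
  if (length(x$chains) >= 2) {
    ch <- param_draws(x, "beta", split = TRUE)
    keep <- apply(do.call(rbind, ch), 2, stats::sd) > 0
    ch <- lapply(ch, function(m) m[, keep, drop = FALSE])
    out$max_psrf_beta <- max(compute_psrf(ch), na.rm = TRUE)
    out$min_ess_beta <- min(compute_ess(ch))
  }
  out
}

#' @export
tidy.association_network <- function(x, ...) x$edges

#' @export
glance.association_network <- function(x, ...) {
  tibble(part = x$part, n_species = nrow(x$species),
         n_pairs = nrow(x$edges), n_supported = sum(x$edges$supported),
         support_level = x$support_level, n_draws = x$n_draws)
}
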