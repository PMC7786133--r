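#' Cross-guild diversity diagnostics
#'
#' Two standard checks on paired community tables before joint modelling:
#' (i) per-guild species richness is regressed on log sequencing depth and
#' the depth-corrected residuals are correlated between guilds (Pearson);
#' (ii) pairwise between-sample dissimilarities (Bray-Curtis on relative
#' abundances by default) are correlated between guilds over the lower
#' triangle.  The beta-diversity correlation is reported with its parametric
#' t statistic for comparability, together with a Mantel permutation p value
#' (the recommended inference, since pairwise distances are not
#' independent).
#'
#' @param tables Named list of two [community_table()]s on matched samples.
#' @param method Dissimilarity index passed to [vegan::vegdist()].
#' @param n_perm Mantel permutations.
#' @param seed Seed for the permutation test.
#' @return List of class `diversity_diagnostics` with tibbles `richness`
#'   (`cor`, `t`, `p`) and `beta` (`cor`, `t`, `p`, `mantel_p`, `method`).
#' @export
diversity_diagnostics <- function(tables, method = "bray", n_perm = 999,
                                  seed = 1L) {
  stopifnot(length(tables) == 2)
  g1 <- names(tables)[1]; g2 <- names(tables)[2]
  if (!identical(tables[[1]]$sample_ids, tables[[2]]$sample_ids))
    abort("the two tables must cover identical samples in identical order")

  res <- lapply(tables, function(x) {
    rich <- rowSums(x$counts > 0)
    stats::resid(stats::lm(rich ~ log(pmax(x$depth, 1))))
  })
  ct <- stats::cor.test(res[[1]], res[[2]], method = "pearson")
  richness <- tibble(guild_x = g1, guild_y = g2,
                     cor = unname(ct$estimate),
                     t = unname(ct$statistic), p = ct$p.value)

  dists <- lapply(tables, function(x) {
    ra <- sweep(x$counts, 1, pmax(rowSums(x$counts), 1), "/")
    vegan::vegdist(ra, method = method)
  })
  v1 <- as.vector(dists[[1]]); v2 <- as.vector(dists[[2]])
  bt <- stats::cor.test(v1, v2, method = "pearson")
  set.seed(seed)
  mant <- vegan::mantel(dists[[1]], dists[[2]], method = "pearson",
                        permutations = n_perm)
  beta <- tibble(guild_x = g1, guild_y = g2, method = method,
                 cor = unname(bt$estimate), t = unname(bt$statistic),
                 p = bt$p.value, mantel_p = mant$signif)

  structure(list(richness = richness, beta = beta),
            class = "diversity_diagnostics")
}

#' @export
print.diversity_diagnostics <- function(x, ...) {
  cat("<diversity_diagnostics>\n  depth-corrected richness correlation:\n")
  print(x$richness)
  cat("  beta-diversity correlation:\n")
  print(x$beta)
  invisible(x)
}
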