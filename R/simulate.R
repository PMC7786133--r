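#' Configuration for simulating paired-guild communities
#'
#' The generator mirrors the fitted model: species occurrences follow a
#' probit regression on wood covariates plus sample-level latent factors, and
#' abundances given presence follow a lognormal regression on the same terms.
#' Defaults emulate a deadwood survey: 118 sampling units (logs), two guilds
#' of 150 OTUs, three shared latent factors, and per-sample sequencing depths
#' drawn lognormally within the read ranges typical of amplicon runs.
#'
#' @param n_samples Number of sampling units (default 118).
#' @param n_species Named vector, species per guild.
#' @param n_factors Number of shared sample-level latent factors.
#' @param loading_scale Named vector per guild: expected norm of a species'
#'   factor-loading vector (entries are drawn `N(0, loading_scale^2 /
#'   n_factors)`); controls how much community variation the random effect
#'   carries.
#' @param niche_scale Named vector per guild: total standard deviation of the
#'   covariate (niche) part of the linear predictor, spread evenly over the
#'   environmental columns of the standardized design.
#' @param occ_intercept_mean,occ_intercept_sd Distribution of occurrence
#'   intercepts, controlling the prevalence spectrum.
#' @param abund_intercept_sd Spread of species' mean log abundances.
#' @param depth_effect Probit coefficient on standardized log reads
#'   (sequencing-depth detection effect, occurrence part only).
#' @param sigma_range Range of the lognormal residual sd, drawn uniformly.
#' @param depth_meanlog,depth_sdlog Lognormal parameters of per-sample reads.
#' @param niche_group_weights `NULL` (niche variance spread evenly over the
#'   environmental design columns) or a named vector such as
#'   `c(chemical = 2, physical = 1)` allocating the total niche variance to
#'   covariate groups in the given proportions (split evenly within each
#'   group).
#' @param n_niche_archetypes If positive, species' environmental coefficients
#'   are drawn around this many shared niche archetypes (per guild), creating
#'   environmentally driven co-occurrence; 0 gives independent niches.
#' @param archetype_noise Relative sd of species' deviation from their
#'   archetype.
#' @param exact_design If `TRUE` (and `n_samples = 118`), tree species and
#'   decay classes follow the study design's exact cross-tabulation
#'   (39/36/43 beech/fir/spruce logs) instead of being drawn multinomially.
#' @param seed Master seed; fixes all randomness of the generator.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples = 118,
                              n_species = c(fungi = 150, bacteria = 150),
                              n_factors = 3,
                              loading_scale = c(fungi = 0.7, bacteria = 0.7),
                              niche_scale = c(fungi = 1.0, bacteria = 1.0),
                              occ_intercept_mean = -0.7,
                              occ_intercept_sd = 0.8,
                              abund_intercept_sd = 0.7,
                              depth_effect = 0.3,
                              sigma_range = c(0.6, 1.2),
                              depth_meanlog = log(6000),
                              depth_sdlog = 0.45,
                              niche_group_weights = NULL,
                              n_niche_archetypes = 0,
                              archetype_noise = 0.25,
                              exact_design = FALSE,
                              seed = 1L) {
  if (n_samples < 1) abort("n_samples must be positive")
  if (any(n_species < 1)) abort("n_species must be positive")
  if (n_factors < 0) abort("n_factors must be >= 0")
  if (any(loading_scale < 0)) abort("loading_scale must be >= 0")
  guilds <- names(n_species)
  if (is.null(guilds)) abort("n_species must be a named vector (one entry per guild)")
  structure(
    list(n_samples = n_samples, n_species = n_species, n_factors = n_factors,
         loading_scale = loading_scale, niche_scale = niche_scale,
         occ_intercept_mean = occ_intercept_mean,
         occ_intercept_sd = occ_intercept_sd,
         abund_intercept_sd = abund_intercept_sd,
         depth_effect = depth_effect, sigma_range = sigma_range,
         depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
         niche_group_weights = niche_group_weights,
         n_niche_archetypes = n_niche_archetypes,
         archetype_noise = archetype_noise,
         exact_design = exact_design, seed = as.integer(seed),
         guilds = guilds),
    class = "simulation_config")
}

#' Asymmetric-loading scenario
#'
#' Returns a configuration in which the bacterial guild loads strongly on the
#' shared sample-level factors (3x the fungal loading scale) while fungal
#' variation is dominated by the environmental covariates.  Under this
#' scenario the random effect carries most bacterial variance, so knowing the
#' fungal community (which still tracks the shared factors) is far more
#' informative for predicting bacteria than vice versa -- the generative
#' analogue of a fungi-to-bacteria directional signal.
#'
#' @param config A [simulation_config()] to modify.
#' @return The modified `simulation_config`.
#' @export
make_asymmetric_scenario <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  config$loading_scale <- c(fungi = 0.5, bacteria = 1.5)
  config$niche_scale <- c(fungi = 1.2, bacteria = 0.6)
  config
}

# design-frequency constants of the emulated survey: 118 logs,
# tree species x decay length cross-tabulation
.design_crosstab <- function() {
  m <- matrix(c(9, 13, 12, 5,
                2, 14, 13, 7,
                10, 12, 11, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("beech", "fir", "spruce"),
                              c("<5", "5-15", "16-38", ">38")))
  m
}

#' Simulate sample covariates
#'
#' Draws wood chemistry (water, pH, C, N, lignin), physical covariates (tree
#' species, decay class, DBH) and per-guild sequencing depths from ranges
#' plausible for decomposing deadwood.  Deterministic under the config seed.
#'
#' @param config A [simulation_config()].
#' @return A `sample_metadata` tibble with `reads_<guild>` columns.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_samples
  set.seed(derive_seed(config$seed, 1L))
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tab <- .design_crosstab()
  if (isTRUE(config$exact_design)) {
    if (n != sum(tab)) abort("exact_design requires n_samples = 118")
    idx <- which(tab > 0, arr.ind = TRUE)
    tree <- rep(rownames(tab)[idx[, 1]], times = tab[idx])
    decay <- rep(colnames(tab)[idx[, 2]], times = tab[idx])
    ord <- sample.int(n)
    tree <- tree[ord]; decay <- decay[ord]
  } else {
    tree <- sample(rownames(tab), n, replace = TRUE, prob = rowSums(tab))
    decay <- sample(colnames(tab), n, replace = TRUE, prob = colSums(tab))
  }
  md <- tibble(
    sample_id = sprintf("log%03d", seq_len(n)),
    water = clamp(rnorm(n, 45, 15), 5, 90),
    ph = clamp(rnorm(n, 4.6, 0.6), 3.2, 6.8),
    c = clamp(rnorm(n, 48, 2), 40, 55),
    n = clamp(exp(rnorm(n, log(0.25), 0.5)), 0.03, 2),
    lignin = clamp(rnorm(n, 28, 6), 10, 50),
    tree_species = tree,
    decay_class = decay,
    dbh = runif(n, 30, 100))
  for (g in config$guilds) {
    md[[paste0("reads_", g)]] <-
      pmax(round(exp(rnorm(n, config$depth_meanlog, config$depth_sdlog))), 500)
  }
  validate_sample_metadata(md)
}

# Apportion a sample's depth among present species proportionally to their
# lognormal weights: one read guaranteed per present species, the remainder
# split by largest remainder so counts sum exactly to the depth.
.apportion_counts <- function(weights, present, depth) {
  counts <- numeric(length(weights))
  idx <- which(present)
  if (length(idx) == 0) return(counts)
  base <- length(idx)
  if (depth <= base) {
    counts[idx[seq_len(depth)]] <- 1
    return(counts)
  }
  w <- weights[idx] / sum(weights[idx])
  quota <- w * (depth - base)
  fl <- floor(quota)
  left <- (depth - base) - sum(fl)
  if (left > 0) {
    extra <- order(quota - fl, decreasing = TRUE)[seq_len(left)]
    fl[extra] <- fl[extra] + 1
  }
  counts[idx] <- 1 + fl
  counts
}

#' Simulate paired-guild communities with known ground truth
#'
#' For each species the occurrence liability is `X beta + eta lambda + eps`
#' (probit), and the log abundance given presence is normal with its own
#' coefficients and residual sd.  Counts are formed by exponentiating the log
#' abundances of the present species and apportioning the sample's
#' sequencing depth to them (minimum one read per present species), which
#' preserves the lognormal structure the fitted model assumes without
#' imposing a multinomial likelihood.
#'
#' @param config A [simulation_config()].
#' @param meta Optional metadata from [simulate_covariates()]; generated from
#'   the config when omitted.
#' @return List with `tables` (named list of [community_table()] per guild),
#'   `meta`, and `truth` (class `ground_truth`): standardized-design
#'   coefficients `beta`, loadings `lambda`, factor scores `eta`, residual
#'   sds `sigma`, and the implied true residual correlation matrices
#'   `R_occurrence` / `R_abundance` over all species (both guilds).
#' @export
simulate_community <- function(config, meta = simulate_covariates(config)) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(derive_seed(config$seed, 2L))
  n <- config$n_samples
  K <- config$n_factors
  guilds <- config$guilds
  eta <- matrix(rnorm(n * K), n, K)

  designs <- lapply(guilds, function(g) {
    d <- build_design_matrix(meta, "full", g)
    d$values_std <- standardize_design(d$values)
    d
  })
  names(designs) <- guilds

  env_cols <- function(d) {
    cn <- colnames(d$values)
    setdiff(cn, c("(Intercept)", "log_reads"))
  }

  truth <- list(beta = list(), lambda = list(), sigma = list(), eta = eta,
                designs = designs, config = config)
  tables <- list()
  all_lam_occ <- list(); all_lam_ab <- list(); all_sig <- list()
  species_guild <- c()

  for (g in guilds) {
    S <- config$n_species[[g]]
    d <- designs[[g]]
    Xs <- d$values_std
    cn <- colnames(Xs)
    ec <- env_cols(d)
    m <- length(ec)
    ns <- config$niche_scale[[g]]
    ls <- config$loading_scale[[g]]

    # per-column variance shares: even split, or group-weighted allocation
    col_share <- rep(1 / m, m)
    if (!is.null(config$niche_group_weights)) {
      gw <- config$niche_group_weights
      grp <- d$group_map[ec]
      w_col <- gw[grp] / as.numeric(table(grp)[grp])
      w_col[is.na(w_col)] <- 0
      col_share <- as.numeric(w_col / sum(w_col))
    }
    draw_env_beta <- function(scale_total) {
      per <- scale_total * sqrt(col_share)
      if (config$n_niche_archetypes > 0) {
        arch <- matrix(rnorm(config$n_niche_archetypes * m, 0,
                             rep(per, each = config$n_niche_archetypes)),
                       config$n_niche_archetypes, m)
        asg <- sample.int(config$n_niche_archetypes, S, replace = TRUE)
        arch[asg, , drop = FALSE] +
          matrix(rnorm(S * m, 0, rep(per, each = S) * config$archetype_noise),
                 S, m)
      } else {
        matrix(rnorm(S * m, 0, rep(per, each = S)), S, m)
      }
    }

    beta_occ <- matrix(0, length(cn), S, dimnames = list(cn, NULL))
    beta_occ["(Intercept)", ] <- rnorm(S, config$occ_intercept_mean,
                                       config$occ_intercept_sd)
    beta_occ[ec, ] <- t(draw_env_beta(ns))
    beta_occ["log_reads", ] <- config$depth_effect

    beta_ab <- matrix(0, length(cn), S, dimnames = list(cn, NULL))
    beta_ab["(Intercept)", ] <- rnorm(S, 0, config$abund_intercept_sd)
    beta_ab[ec, ] <- t(draw_env_beta(ns))

    lam_occ <- matrix(rnorm(S * K, 0, if (K > 0) ls / sqrt(K) else 1), S, K)
    lam_ab <- matrix(rnorm(S * K, 0, if (K > 0) ls / sqrt(K) else 1), S, K)
    sigma <- runif(S, config$sigma_range[1], config$sigma_range[2])

    L_occ <- Xs %*% beta_occ + eta %*% t(lam_occ)
    y <- (L_occ + matrix(rnorm(n * S), n, S)) > 0
    L_ab <- Xs %*% beta_ab + eta %*% t(lam_ab)
    a <- L_ab + matrix(rnorm(n * S), n, S) %*% diag(sigma, S)

    # guard: a sample with nothing present gets its most likely species
    empty <- rowSums(y) == 0
    if (any(empty)) {
      for (i in which(empty)) y[i, which.max(L_occ[i, ])] <- TRUE
    }

    depth <- meta[[paste0("reads_", g)]]
    counts <- t(vapply(seq_len(n), function(i) {
      .apportion_counts(exp(a[i, ]), y[i, ], depth[i])
    }, numeric(S)))
    dimnames(counts) <- list(meta$sample_id,
                             sprintf("%s_otu%04d", g, seq_len(S)))
    tables[[g]] <- community_table(counts, g)

    truth$beta[[g]] <- list(occurrence = beta_occ, abundance = beta_ab)
    truth$lambda[[g]] <- list(occurrence = lam_occ, abundance = lam_ab)
    truth$sigma[[g]] <- sigma
    all_lam_occ[[g]] <- lam_occ; all_lam_ab[[g]] <- lam_ab
    all_sig[[g]] <- sigma
    species_guild <- c(species_guild, rep(g, S))
  }

  Locc <- do.call(rbind, all_lam_occ)
  Lab <- do.call(rbind, all_lam_ab)
  sig <- unlist(all_sig)
  ids <- unlist(lapply(guilds, function(g) colnames(tables[[g]]$counts)))
  R_occ <- stats::cov2cor(tcrossprod(Locc) + diag(nrow(Locc)))
  R_ab <- stats::cov2cor(tcrossprod(Lab) + diag(sig^2))
  dimnames(R_occ) <- dimnames(R_ab) <- list(ids, ids)
  truth$R_occurrence <- R_occ
  truth$R_abundance <- R_ab
  truth$species_guild <- stats::setNames(species_guild, ids)
  class(truth) <- "ground_truth"
  list(tables = tables, meta = meta, truth = truth)
}

#' Generative variance shares implied by a ground truth
#'
#' Decomposes each species' linear-predictor variance into the environmental
#' (niche) component, `Var(X beta)` over the simulated samples, and the
#' random-effect component `sum(lambda^2)`; averages the random-effect share
#' per guild and model part.
#'
#' @param truth A `ground_truth` from [simulate_community()].
#' @return Tibble with columns `guild`, `part`, `niche_var`, `random_var`,
#'   `random_share`.
#' @export
true_variance_shares <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  guilds <- names(truth$beta)
  purrr::map_dfr(guilds, function(g) {
    Xs <- truth$designs[[g]]$values_std
    purrr::map_dfr(c("occurrence", "abundance"), function(part) {
      B <- truth$beta[[g]][[part]]
      B_env <- B; B_env["(Intercept)", ] <- 0
      nv <- apply(Xs %*% B_env, 2, stats::var)
      rv <- rowSums(truth$lambda[[g]][[part]]^2)
      tibble(guild = g, part = part,
             niche_var = mean(nv), random_var = mean(rv),
             random_share = mean(rv / (rv + nv)))
    })
  })
}
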