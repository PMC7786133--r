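#' Area under the ROC curve (Mann-Whitney form, ties count one half)
#'
#' @param labels Binary vector (0/1 or logical).
#' @param scores Numeric prediction scores.
#' @return AUC in `[0, 1]`, or `NA` (with a notice) when only one class is
#'   present.
#' @export
#' @examples
#' compute_auc(c(0, 1, 0, 1), c(0.4, 0.3, 0.2, 0.6))  # 0.75
compute_auc <- function(labels, scores) {
  keep <- !is.na(labels) & !is.na(scores)
  labels <- as.integer(labels[keep] > 0)
  scores <- scores[keep]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    inform("single-class labels: AUC undefined, returning NA")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination
#'
#' `1 - SSE/SST` on the scale of the inputs; can be negative out of sample.
#'
#' @param observed,predicted Paired numeric vectors (`NA`s dropped pairwise);
#'   at least 3 pairs required.
#' @return R squared (possibly negative), `NA` if the observed values are
#'   constant.
#' @export
compute_r2 <- function(observed, predicted) {
  keep <- !is.na(observed) & !is.na(predicted)
  o <- observed[keep]; p <- predicted[keep]
  if (length(o) < 3) abort("compute_r2 needs at least 3 paired values")
  sst <- sum((o - mean(o))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((o - p)^2) / sst
}

# per-draw linear predictors for a set of species columns
.xb_part <- function(fit, beta_draw, designs, part = c("occurrence", "abundance")) {
  part <- match.arg(part)
  S <- nrow(fit$species)
  offset <- if (part == "occurrence") 0L else S
  n <- nrow(designs[[1]]$values)
  out <- matrix(0, n, S)
  for (g in fit$guilds) {
    cols <- which(fit$species$guild == g)
    out[, cols] <- designs[[g]]$values %*%
      matrix(beta_draw[, offset + cols], ncol = length(cols))
  }
  out
}

# iterate over all retained draws of a fit, calling f(beta, lambda, sigma2, eta)
.each_draw <- function(fit, f) {
  S <- nrow(fit$species)
  for (ch in fit$chains) {
    for (d in seq_len(ch$n_draws)) {
      lam <- matrix(ch$lambda[, , d], 2L * S)
      if (fit$n_factors == 0) lam <- matrix(0, 2L * S, 0)
      f(beta = matrix(ch$beta[, , d], nrow = dim(ch$beta)[1]),
        lambda = lam, sigma2 = ch$sigma2[, d],
        eta = matrix(ch$eta[, , d], ncol = max(fit$n_factors, 1)))
    }
  }
}

#' Unconditional predictions for new samples
#'
#' Uses only the environmental predictors: for each posterior draw the
#' latent factor scores of the new samples are integrated over their
#' standard-normal prior (in closed form for the probit part), and
#' predictions are averaged over draws.  Occurrence predictions are presence
#' probabilities; abundance predictions are on each species' standardized
#' log-abundance scale.
#'
#' @param fit A [fit_jsdm()] object.
#' @param designs Named list of [build_design_matrix()] objects for the new
#'   samples (same models/guilds as the fit).
#' @return List with matrices `occurrence` (n_new x S presence
#'   probabilities) and `abundance` (n_new x S expected standardized log
#'   abundances), plus `species`.
#' @export
predict_unconditional <- function(fit, designs) {
  stopifnot(inherits(fit, "jsdm_fit"))
  if (inherits(designs, "design_matrix"))
    designs <- stats::setNames(rep(list(designs), length(fit$guilds)), fit$guilds)
  S <- nrow(fit$species)
  n <- nrow(designs[[1]]$values)
  Pocc <- matrix(0, n, S); Aab <- matrix(0, n, S); nd <- 0L
  .each_draw(fit, function(beta, lambda, sigma2, eta) {
    lam_occ <- lambda[seq_len(S), , drop = FALSE]
    scale <- sqrt(1 + rowSums(lam_occ^2))
    Mocc <- .xb_part(fit, beta, designs, "occurrence")
    Pocc <<- Pocc + pnorm(sweep(Mocc, 2, scale, "/"))
    Aab <<- Aab + .xb_part(fit, beta, designs, "abundance")
    nd <<- nd + 1L
  })
  list(occurrence = Pocc / nd, abundance = Aab / nd, species = fit$species)
}

#' Explanatory (in-sample) predictions
#'
#' Predictions for the training samples conditional on the fitted latent
#' factor scores: the model's own estimate of the data it was fitted to.
#'
#' @param fit A [fit_jsdm()] object.
#' @return As [predict_unconditional()].
#' @export
predict_explanatory <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  S <- nrow(fit$species)
  n <- length(fit$sample_ids)
  Pocc <- matrix(0, n, S); Aab <- matrix(0, n, S); nd <- 0L
  .each_draw(fit, function(beta, lambda, sigma2, eta) {
    if (fit$n_factors == 0) eta <- matrix(0, n, 0)
    lam_occ <- lambda[seq_len(S), , drop = FALSE]
    lam_ab <- lambda[S + seq_len(S), , drop = FALSE]
    Pocc <<- Pocc + pnorm(.xb_part(fit, beta, fit$designs, "occurrence") +
                            eta %*% t(lam_occ))
    Aab <<- Aab + .xb_part(fit, beta, fit$designs, "abundance") +
      eta %*% t(lam_ab)
    nd <<- nd + 1L
  })
  list(occurrence = Pocc / nd, abundance = Aab / nd, species = fit$species)
}

# standardize new counts for the conditioning guilds against the fit's
# training scaling; returns pa / abund matrices over the fit's species
# (NA columns for focal species)
.conditioning_matrices <- function(fit, tables) {
  S <- nrow(fit$species)
  n <- nrow(tables[[1]]$counts)
  pa <- matrix(NA_real_, n, S); ab <- matrix(NA_real_, n, S)
  for (g in names(tables)) {
    cols <- which(fit$species$guild == g)
    ids <- fit$species$otu_id[cols]
    cnt <- tables[[g]]$counts[, ids, drop = FALSE]
    sc <- fit$scaling[[g]][match(ids, fit$scaling[[g]]$otu_id), ]
    std <- apply_hurdle_scaling(cnt, sc)
    pa[, cols] <- std$pa
    ab[, cols] <- std$abund
  }
  list(pa = pa, abund = ab)
}

#' Conditional predictions: the non-focal guild is observed
#'
#' For each (subsampled) posterior draw, the latent factor scores of the new
#' samples are sampled from their conditional posterior given the observed
#' occurrences and abundances of the non-focal guild(s): observed
#' presence-absence enters through truncated-normal resampling of the probit
#' liabilities, observed standardized abundances through their normal
#' residuals.  Focal predictions are then averaged over the inner draws and
#' over posterior draws.  With an empty conditioning set this reproduces
#' [predict_unconditional()] up to Monte-Carlo error.
#'
#' @param fit A [fit_jsdm()] object.
#' @param designs Designs for the new samples, as in
#'   [predict_unconditional()].
#' @param conditioning_tables Named list of [community_table()] objects for
#'   the non-focal guild(s), rows matching the new samples; may be `NULL`.
#' @param focal_guild Guild whose species are predicted.
#' @param n_outer Number of posterior draws to condition on (subsampled
#'   evenly from all retained draws).
#' @param n_inner,n_inner_burn Inner Gibbs draws (after burn-in) per
#'   posterior draw used to sample the conditional factor scores.
#' @param seed Seed for the conditioning sampler.
#' @return As [predict_unconditional()], but only the focal species' columns
#'   are populated.
#' @export
predict_conditional <- function(fit, designs, conditioning_tables,
                                focal_guild, n_outer = 100, n_inner = 100,
                                n_inner_burn = 50, seed = 1L) {
  stopifnot(inherits(fit, "jsdm_fit"))
  if (inherits(designs, "design_matrix"))
    designs <- stats::setNames(rep(list(designs), length(fit$guilds)), fit$guilds)
  if (is.null(conditioning_tables) || length(conditioning_tables) == 0 ||
      fit$n_factors == 0) {
    return(predict_unconditional(fit, designs))
  }
  stopifnot(!focal_guild %in% names(conditioning_tables))
  set.seed(seed)
  S <- nrow(fit$species)
  K <- fit$n_factors
  n <- nrow(designs[[1]]$values)
  cond <- .conditioning_matrices(fit, conditioning_tables)
  nf <- which(!is.na(cond$pa[1, ]))            # non-focal columns
  fc <- which(fit$species$guild == focal_guild)

  # pool draws across chains and subsample evenly
  D_tot <- sum(vapply(fit$chains, function(ch) ch$n_draws, 1L))
  pick <- unique(round(seq(1, D_tot, length.out = min(n_outer, D_tot))))
  chain_of <- rep(seq_along(fit$chains),
                  vapply(fit$chains, function(ch) ch$n_draws, 1L))
  idx_in <- unlist(lapply(fit$chains, function(ch) seq_len(ch$n_draws)))

  Pocc <- matrix(0, n, length(fc)); Aab <- matrix(0, n, length(fc))
  y_nf <- cond$pa[, nf, drop = FALSE] == 1
  ab_nf <- cond$abund[, nf, drop = FALSE]
  obs_nf <- !is.na(ab_nf)
  ab0 <- ab_nf; ab0[!obs_nf] <- 0

  for (dd in pick) {
    ch <- fit$chains[[chain_of[dd]]]; d <- idx_in[dd]
    beta <- matrix(ch$beta[, , d], nrow = dim(ch$beta)[1])
    lam <- matrix(ch$lambda[, , d], 2L * S)
    sigma2 <- ch$sigma2[, d]
    lam_occ_nf <- lam[nf, , drop = FALSE]
    lam_ab_nf <- lam[S + nf, , drop = FALSE]
    lam_occ_f <- lam[fc, , drop = FALSE]
    lam_ab_f <- lam[S + fc, , drop = FALSE]
    sig_nf <- sigma2[nf]

    Mocc <- .xb_part(fit, beta, designs, "occurrence")
    Mab <- .xb_part(fit, beta, designs, "abundance")
    Mocc_nf <- Mocc[, nf, drop = FALSE]
    Mab_nf <- Mab[, nf, drop = FALSE]
    Mocc_f <- Mocc[, fc, drop = FALSE]
    Mab_f <- Mab[, fc, drop = FALSE]

    # per-sample conditional precision of eta (fixed within this draw)
    P0 <- diag(K) + crossprod(lam_occ_nf)
    W <- lam_ab_nf / sqrt(sig_nf)
    Varr <- array(0, c(n, K, K))   # covariance (inverse precision)
    Larr <- array(0, c(n, K, K))   # chol factors of the covariance
    Cmat <- matrix(0, n, K * K)
    for (k in seq_len(K)) for (l in k:K) {
      v <- obs_nf %*% (W[, k] * W[, l])
      Cmat[, (k - 1) * K + l] <- v
      Cmat[, (l - 1) * K + k] <- v
    }
    for (i in seq_len(n)) {
      A <- P0 + matrix(Cmat[i, ], K, K)
      V <- chol2inv(chol(A))
      Varr[i, , ] <- V
      Larr[i, , ] <- t(chol(V))
    }
    # abundance contribution to the conditional mean (fixed)
    resid_ab <- (ab0 - Mab_nf) * obs_nf
    b_ab <- resid_ab %*% sweep(lam_ab_nf, 1, sig_nf, "/")   # lambda / sigma^2

    eta <- matrix(0, n, K)
    Pacc <- matrix(0, n, length(fc)); Aacc <- matrix(0, n, length(fc))
    for (t in seq_len(n_inner_burn + n_inner)) {
      Z <- matrix(rtnorm_sign(as.vector(Mocc_nf + eta %*% t(lam_occ_nf)),
                              as.vector(y_nf)), n, length(nf))
      b <- (Z - Mocc_nf) %*% lam_occ_nf + b_ab
      # eta_i = V_i b_i + L_i e_i, vectorized over samples
      E <- matrix(rnorm(n * K), n, K)
      for (k in seq_len(K)) {
        mk <- rep(0, n); nk <- rep(0, n)
        for (l in seq_len(K)) {
          mk <- mk + b[, l] * Varr[, l, k]
          nk <- nk + E[, l] * Larr[, k, l]
        }
        eta[, k] <- mk + nk
      }
      if (t > n_inner_burn) {
        Pacc <- Pacc + pnorm(Mocc_f + eta %*% t(lam_occ_f))
        Aacc <- Aacc + Mab_f + eta %*% t(lam_ab_f)
      }
    }
    Pocc <- Pocc + Pacc / n_inner
    Aab <- Aab + Aacc / n_inner
  }
  occurrence <- matrix(NA_real_, n, S)
  abundance <- matrix(NA_real_, n, S)
  occurrence[, fc] <- Pocc / length(pick)
  abundance[, fc] <- Aab / length(pick)
  list(occurrence = occurrence, abundance = abundance, species = fit$species)
}
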