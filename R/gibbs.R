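#' Prior hyperparameters for the hurdle latent-factor model
#'
#' Regression coefficients get independent `N(0, v_beta)` priors on the
#' internally standardized covariate scale.  Factor loadings get the
#' multiplicative gamma process shrinkage prior (local precisions
#' `phi ~ Gamma(nu/2, nu/2)`, column multipliers `delta_1 ~ Gamma(a1, 1)`,
#' `delta_h ~ Gamma(a2, 1)` with cumulative products `tau`), which shrinks
#' higher-numbered factors towards zero.  Lognormal residual variances get an
#' inverse-gamma prior; the probit residual variance is fixed at 1 for
#' identifiability.
#'
#' @param v_beta Prior variance of regression coefficients.
#' @param nu Local shrinkage degrees of freedom.
#' @param a1,a2 Shape parameters of the column-multiplier gammas.
#' @param a_sigma,b_sigma Inverse-gamma shape/rate for the lognormal
#'   residual variance.
#' @return A `jsdm_priors` list.
#' @export
jsdm_priors <- function(v_beta = 1, nu = 3, a1 = 2.1, a2 = 3.1,
                        a_sigma = 1, b_sigma = 1) {
  stopifnot(v_beta > 0, nu > 0, a1 > 0, a2 > 0, a_sigma > 0, b_sigma > 0)
  structure(list(v_beta = v_beta, nu = nu, a1 = a1, a2 = a2,
                 a_sigma = a_sigma, b_sigma = b_sigma),
            class = "jsdm_priors")
}

#' MCMC sampling settings
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded from each chain.
#' @param thin Thinning interval applied after burn-in.
#' @param seed Master seed; per-chain seeds are derived deterministically.
#' @return An `mcmc_control` list.
#' @export
#' @examples
#' # the field-scale profile: 4 chains x 150,000 iterations, 50,000 burn-in,
#' # thinned by 100 -> 1,000 retained draws per chain, 4,000 in total
#' ctl <- mcmc_control(4, 150000, 50000, 100)
#' n_retained(ctl)
mcmc_control <- function(n_chains = 2, n_iter = 5000, n_burn = n_iter %/% 2,
                         thin = 10, seed = 1L) {
  if (n_burn >= n_iter) abort("n_burn must be smaller than n_iter")
  if ((n_iter - n_burn) %% thin != 0)
    abort("thin must divide n_iter - n_burn")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Retained draw count implied by an MCMC control
#'
#' @param mcmc An [mcmc_control()].
#' @param total If `TRUE` (default) the count over all chains, else per chain.
#' @return Integer number of retained posterior draws.
#' @export
n_retained <- function(mcmc, total = TRUE) {
  per <- (mcmc$n_iter - mcmc$n_burn) %/% mcmc$thin
  if (total) per * mcmc$n_chains else per
}

# ---------------------------------------------------------------------------
# internal data container: aligns the duplicated response (each species once
# in the probit part, once in the lognormal part) with per-guild designs
# ---------------------------------------------------------------------------
make_gibbs_data <- function(X_list, Ypa, Yab, species_guild) {
  n <- nrow(Ypa); S <- ncol(Ypa)
  stopifnot(ncol(Yab) == S, nrow(Yab) == n, length(species_guild) == S)
  guilds <- unique(species_guild)
  p <- ncol(X_list[[1]])
  for (g in guilds) stopifnot(ncol(X_list[[g]]) == p, nrow(X_list[[g]]) == n)
  obs <- lapply(seq_len(S), function(s) which(!is.na(Yab[, s])))
  Xo <- lapply(seq_len(S), function(s) {
    o <- obs[[s]]
    if (length(o) == 0) NULL else t(X_list[[species_guild[s]]][o, , drop = FALSE])
  })
  XtX_ab <- lapply(seq_len(S), function(s) {
    if (is.null(Xo[[s]])) NULL else tcrossprod(Xo[[s]])
  })
  cols_by_guild <- lapply(guilds, function(g) which(species_guild == g))
  names(cols_by_guild) <- guilds
  list(n = n, S = S, p = p, guilds = guilds, species_guild = species_guild,
       X = X_list, Ypa = Ypa, Yab = Yab, obs = obs, Xo = Xo, XtX_ab = XtX_ab,
       XtX = lapply(X_list, crossprod), cols_by_guild = cols_by_guild)
}

# draw an initial state from the prior (also the Geweke prior-draw kernel)
gibbs_prior_draw <- function(dat, K, pr) {
  S2 <- 2L * dat$S
  delta <- c(if (K > 0) rgamma(1, pr$a1, 1), if (K > 1) rgamma(K - 1, pr$a2, 1))
  tau <- if (K > 0) cumprod(delta) else numeric(0)
  phi <- matrix(rgamma(S2 * K, pr$nu / 2, pr$nu / 2), S2, K)
  lambda <- matrix(0, S2, K)
  if (K > 0) {
    sdm <- 1 / sqrt(sweep(phi, 2, tau, "*"))
    lambda <- matrix(rnorm(S2 * K), S2, K) * sdm
  }
  list(
    beta = matrix(rnorm(dat$p * S2, 0, sqrt(pr$v_beta)), dat$p, S2),
    lambda = lambda,
    eta = matrix(rnorm(dat$n * K), dat$n, K),
    sigma2 = 1 / rgamma(dat$S, pr$a_sigma, pr$b_sigma),
    phi = phi, delta = delta,
    Z = matrix(0, dat$n, dat$S))
}

# simulate response data from the model given a state (Geweke data kernel);
# returns a new `dat` built from the same designs
gibbs_simulate_data <- function(state, dat) {
  n <- dat$n; S <- dat$S
  Xb_occ <- matrix(0, n, S); Xb_ab <- matrix(0, n, S)
  for (g in dat$guilds) {
    cols <- dat$cols_by_guild[[g]]
    Xb_occ[, cols] <- dat$X[[g]] %*% state$beta[, cols, drop = FALSE]
    Xb_ab[, cols] <- dat$X[[g]] %*% state$beta[, S + cols, drop = FALSE]
  }
  K <- ncol(state$lambda)
  Eocc <- state$eta %*% t(state$lambda[seq_len(S), , drop = FALSE])
  Eab <- state$eta %*% t(state$lambda[S + seq_len(S), , drop = FALSE])
  Ypa <- ((Xb_occ + Eocc + matrix(rnorm(n * S), n, S)) > 0) * 1L
  Yab <- Xb_ab + Eab +
    matrix(rnorm(n * S), n, S) %*% diag(sqrt(state$sigma2), S)
  Yab[Ypa == 0] <- NA_real_
  make_gibbs_data(dat$X, Ypa, Yab, dat$species_guild)
}

# chol-based draw from N(A^{-1} b, A^{-1}) given upper chol R of A
draw_mvn_prec <- function(Rch, b) {
  m <- backsolve(Rch, backsolve(Rch, b, transpose = TRUE))
  m + backsolve(Rch, if (is.matrix(b)) matrix(rnorm(length(b)), nrow(b), ncol(b))
                     else rnorm(length(b)))
}

# One full Gibbs sweep.  Sweep order: (1) probit liabilities z by
# Albert-Chib truncated-normal augmentation; (2) conjugate beta; (3) loadings
# lambda under the shrinkage prior; (4) factor scores eta; (5) lognormal
# residual variances; (6) shrinkage hyperparameters.  Missing abundance
# entries (absences) contribute nothing to any likelihood term.
gibbs_sweep <- function(state, dat, pr, chol_occ = NULL) {
  n <- dat$n; S <- dat$S; p <- dat$p
  K <- ncol(state$lambda)
  lam_occ <- state$lambda[seq_len(S), , drop = FALSE]
  lam_ab <- state$lambda[S + seq_len(S), , drop = FALSE]

  Xb_occ <- matrix(0, n, S)
  for (g in dat$guilds) {
    cols <- dat$cols_by_guild[[g]]
    Xb_occ[, cols] <- dat$X[[g]] %*% state$beta[, cols, drop = FALSE]
  }

  # (1) truncated-normal liabilities
  M <- Xb_occ + state$eta %*% t(lam_occ)
  state$Z <- matrix(rtnorm_sign(as.vector(M), as.vector(dat$Ypa == 1)), n, S)

  # (2a) beta, probit part: shared posterior precision per guild
  if (is.null(chol_occ)) {
    chol_occ <- lapply(dat$XtX, function(xtx) chol(xtx + diag(p) / pr$v_beta))
  }
  Eocc <- state$eta %*% t(lam_occ)
  for (g in dat$guilds) {
    cols <- dat$cols_by_guild[[g]]
    rhs <- crossprod(dat$X[[g]], state$Z[, cols, drop = FALSE] -
                       Eocc[, cols, drop = FALSE])
    state$beta[, cols] <- draw_mvn_prec(chol_occ[[g]], rhs)
  }

  # (2b) beta, lognormal part: per-species row sets (missingness varies)
  Eab <- state$eta %*% t(lam_ab)
  for (s in seq_len(S)) {
    o <- dat$obs[[s]]
    if (length(o) == 0) {
      state$beta[, S + s] <- rnorm(p, 0, sqrt(pr$v_beta))
      next
    }
    s2 <- state$sigma2[s]
    A <- dat$XtX_ab[[s]] / s2 + diag(p) / pr$v_beta
    rhs <- dat$Xo[[s]] %*% (dat$Yab[o, s] - Eab[o, s]) / s2
    state$beta[, S + s] <- draw_mvn_prec(chol(A), rhs)
  }

  # recompute fixed-effect parts with the new beta
  Xb_ab <- matrix(0, n, S)
  for (g in dat$guilds) {
    cols <- dat$cols_by_guild[[g]]
    Xb_occ[, cols] <- dat$X[[g]] %*% state$beta[, cols, drop = FALSE]
    Xb_ab[, cols] <- dat$X[[g]] %*% state$beta[, S + cols, drop = FALSE]
  }

  if (K > 0) {
    tau <- cumprod(state$delta)

    # (3) loadings
    EtE <- crossprod(state$eta)
    for (s in seq_len(S)) {
      D <- diag(state$phi[s, ] * tau, K)
      A <- EtE + D
      rhs <- crossprod(state$eta, state$Z[, s] - Xb_occ[, s])
      state$lambda[s, ] <- draw_mvn_prec(chol(A), rhs)
      o <- dat$obs[[s]]
      D2 <- diag(state$phi[S + s, ] * tau, K)
      if (length(o) == 0) {
        state$lambda[S + s, ] <- rnorm(K) / sqrt(diag(D2))
      } else {
        Eo <- state$eta[o, , drop = FALSE]
        s2 <- state$sigma2[s]
        A2 <- crossprod(Eo) / s2 + D2
        rhs2 <- crossprod(Eo, dat$Yab[o, s] - Xb_ab[o, s]) / s2
        state$lambda[S + s, ] <- draw_mvn_prec(chol(A2), rhs2)
      }
    }
    lam_occ <- state$lambda[seq_len(S), , drop = FALSE]
    lam_ab <- state$lambda[S + seq_len(S), , drop = FALSE]

    # (4) factor scores: per-sample precision depends on which abundances
    # are observed there
    P0 <- diag(K) + crossprod(lam_occ)
    W <- lam_ab / sqrt(state$sigma2)
    Obs <- !is.na(dat$Yab)
    Carr <- matrix(0, n, K * K)
    for (k in seq_len(K)) for (l in k:K) {
      v <- Obs %*% (W[, k] * W[, l])
      Carr[, (k - 1) * K + l] <- v
      Carr[, (l - 1) * K + k] <- v
    }
    RZ <- state$Z - Xb_occ
    RA <- dat$Yab - Xb_ab
    RA[!Obs] <- 0
    b <- RZ %*% lam_occ + RA %*% (lam_ab / state$sigma2)
    for (i in seq_len(n)) {
      A <- P0 + matrix(Carr[i, ], K, K)
      state$eta[i, ] <- draw_mvn_prec(chol(A), b[i, ])
    }
  }

  # (5) lognormal residual variances
  RES <- dat$Yab - Xb_ab - state$eta %*% t(lam_ab)
  sse <- colSums(RES^2, na.rm = TRUE)
  n_o <- lengths(dat$obs)
  state$sigma2 <- 1 / rgamma(S, pr$a_sigma + n_o / 2, pr$b_sigma + sse / 2)

  # (6) shrinkage hyperparameters
  if (K > 0) {
    tau <- cumprod(state$delta)
    lam2 <- state$lambda^2
    rate <- (pr$nu + sweep(lam2, 2, tau, "*")) / 2
    state$phi <- matrix(rgamma(length(rate), (pr$nu + 1) / 2, as.vector(rate)),
                        nrow(rate), K)
    S2 <- 2L * S
    m_l <- colSums(state$phi * lam2)
    for (h in seq_len(K)) {
      tau_all <- cumprod(state$delta)
      tau_mh <- tau_all / state$delta[h]
      idx <- h:K
      shape <- (if (h == 1) pr$a1 else pr$a2) + S2 * (K - h + 1) / 2
      rrate <- 1 + 0.5 * sum(tau_mh[idx] * m_l[idx])
      state$delta[h] <- rgamma(1, shape, rrate)
    }
  }
  state
}

run_gibbs_chain <- function(dat, K, pr, n_iter, n_burn, thin, seed,
                            init = NULL) {
  set.seed(seed)
  state <- init %||% gibbs_prior_draw(dat, K, pr)
  chol_occ <- lapply(dat$XtX, function(xtx) chol(xtx + diag(dat$p) / pr$v_beta))
  D <- (n_iter - n_burn) %/% thin
  S2 <- 2L * dat$S
  out <- list(beta = array(NA_real_, c(dat$p, S2, D)),
              lambda = array(NA_real_, c(S2, max(K, 1L), D)),
              eta = array(NA_real_, c(dat$n, max(K, 1L), D)),
              sigma2 = matrix(NA_real_, dat$S, D))
  d <- 0L
  for (it in seq_len(n_iter)) {
    state <- gibbs_sweep(state, dat, pr, chol_occ)
    if (!all(is.finite(state$beta)) || !all(is.finite(state$lambda)))
      abort(sprintf("non-finite sampler state at iteration %d", it))
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      d <- d + 1L
      out$beta[, , d] <- state$beta
      if (K > 0) {
        out$lambda[, , d] <- state$lambda
        out$eta[, , d] <- state$eta
      } else {
        out$lambda[, , d] <- 0
        out$eta[, , d] <- 0
      }
      out$sigma2[, d] <- state$sigma2
    }
  }
  out$n_draws <- D
  out
}

#' Fit the hurdle latent-factor joint species distribution model
#'
#' Gibbs sampler for the duplicated-response hurdle model: every OTU enters
#' the response matrix twice, once as presence-absence (probit link,
#' Albert-Chib truncated-normal augmentation, residual variance fixed at 1)
#' and once as standardized log abundance conditional on presence (normal
#' likelihood; absences are missing and contribute nothing).  Both parts and
#' both guilds share one set of sample-level latent factors, whose loadings
#' induce the residual species-to-species association matrix.  Covariates
#' are standardized internally; coefficients are reported on the original
#' scale.
#'
#' @param responses Named list of [assemble_hurdle_response()] objects, one
#'   per guild (a single `hurdle_response` is also accepted).
#' @param designs Named list of [build_design_matrix()] objects matching the
#'   guilds (or a single design used for every guild).
#' @param n_factors Number of latent factors (default 5; use fewer for small
#'   simulated communities).
#' @param priors A [jsdm_priors()].
#' @param mcmc An [mcmc_control()].
#' @param standardize Standardize covariates internally (default `TRUE`;
#'   disable only when the prior is meant to apply to raw coefficients).
#' @return Object of class `jsdm_fit` with elements `chains` (per-chain
#'   arrays of `beta` (original scale), `lambda`, `eta`, `sigma2`),
#'   `species` (tibble of OTU ids/guilds), `designs`, `scaling`, `priors`,
#'   `mcmc`, `n_factors`.
#' @export
fit_jsdm <- function(responses, designs, n_factors = 5,
                     priors = jsdm_priors(), mcmc = mcmc_control(),
                     standardize = TRUE) {
  if (inherits(responses, "hurdle_response")) {
    responses <- stats::setNames(list(responses), responses$guild)
  }
  if (inherits(designs, "design_matrix")) {
    designs <- stats::setNames(rep(list(designs), length(responses)),
                               names(responses))
  }
  guilds <- names(responses)
  stopifnot(all(guilds %in% names(designs)))
  sample_ids <- responses[[1]]$sample_ids
  for (g in guilds) {
    if (!identical(responses[[g]]$sample_ids, sample_ids))
      abort("responses must cover identical samples in identical order")
    if (!identical(rownames(designs[[g]]$values), sample_ids))
      abort(sprintf("design rows for guild '%s' are not aligned with the response", g))
    if (qr(designs[[g]]$values)$rank < ncol(designs[[g]]$values))
      abort(sprintf("design matrix for guild '%s' is rank deficient", g))
  }

  Ypa <- do.call(cbind, lapply(responses, function(r) r$pa))
  Yab <- do.call(cbind, lapply(responses, function(r) r$abund))
  species_guild <- unlist(lapply(guilds, function(g)
    rep(g, ncol(responses[[g]]$pa))))
  otu_ids <- unlist(lapply(responses, function(r) r$otu_ids))
  colnames(Ypa) <- colnames(Yab) <- otu_ids

  X_std <- lapply(designs[guilds], function(d) {
    if (standardize) standardize_design(d$values) else {
      x <- d$values; attr(x, "center") <- rep(0, ncol(x))
      attr(x, "scale") <- rep(1, ncol(x)); x
    }
  })
  dat <- make_gibbs_data(X_std, Ypa, Yab, species_guild)

  chains <- vector("list", mcmc$n_chains)
  for (ch in seq_len(mcmc$n_chains)) {
    chains[[ch]] <- run_gibbs_chain(
      dat, n_factors, priors, mcmc$n_iter, mcmc$n_burn, mcmc$thin,
      seed = derive_seed(mcmc$seed, ch))
    # map coefficients back to the original covariate scale, per guild
    S <- dat$S
    for (g in guilds) {
      cols <- dat$cols_by_guild[[g]]
      ctr <- attr(X_std[[g]], "center"); scl <- attr(X_std[[g]], "scale")
      int <- match("(Intercept)", colnames(designs[[g]]$values))
      for (d in seq_len(chains[[ch]]$n_draws)) {
        chains[[ch]]$beta[, cols, d] <-
          unstandardize_beta(chains[[ch]]$beta[, cols, d, drop = TRUE],
                             ctr, scl, intercept_row = int)
        chains[[ch]]$beta[, S + cols, d] <-
          unstandardize_beta(chains[[ch]]$beta[, S + cols, d, drop = TRUE],
                             ctr, scl, intercept_row = int)
      }
    }
  }

  structure(
    list(chains = chains,
         species = tibble(otu_id = otu_ids, guild = species_guild),
         sample_ids = sample_ids,
         designs = designs[guilds],
         scaling = lapply(responses, function(r) r$scaling),
         responses = responses,
         priors = priors, mcmc = mcmc, n_factors = n_factors,
         guilds = guilds),
    class = "jsdm_fit")
}

#' @export
print.jsdm_fit <- function(x, ...) {
  cat(sprintf(
    "<jsdm_fit> %d samples, %d species (%s), %d factors, %d chains x %d draws\n",
    length(x$sample_ids), nrow(x$species),
    paste(sprintf("%s: %d", x$guilds,
                  vapply(x$guilds, function(g) sum(x$species$guild == g), 1L)),
          collapse = ", "),
    x$n_factors, length(x$chains), x$chains[[1]]$n_draws))
  invisible(x)
}

# stack all chains' draws of one parameter block into a draws x params matrix
# (or return per-chain matrices when split = TRUE)
param_draws <- function(fit, block = c("beta", "lambda", "sigma2", "eta"),
                        split = FALSE) {
  block <- match.arg(block)
  mats <- lapply(fit$chains, function(ch) {
    x <- ch[[block]]
    if (length(dim(x)) == 3) {
      t(matrix(x, prod(dim(x)[1:2]), dim(x)[3]))
    } else {
      t(x)
    }
  })
  if (split) mats else do.call(rbind, mats)
}

#' Persist posterior draws as flat binary arrays plus a JSON index
#'
#' @param fit A [fit_jsdm()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_fit_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(n_chains = length(fit$chains),
                n_factors = fit$n_factors,
                mcmc = unclass(fit$mcmc),
                species = fit$species$otu_id, guild = fit$species$guild,
                blocks = list())
  for (block in c("beta", "lambda", "eta", "sigma2")) {
    for (ch in seq_along(fit$chains)) {
      x <- fit$chains[[ch]][[block]]
      f <- file.path(dir, sprintf("%s_chain%d.bin", block, ch))
      con <- file(f, "wb"); writeBin(as.vector(x), con); close(con)
      index$blocks[[sprintf("%s_chain%d", block, ch)]] <-
        list(file = basename(f), dim = dim(x) %||% length(x))
    }
  }
  jsonlite::write_json(index, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Reload posterior draws saved by [save_fit_draws()]
#'
#' @param dir Directory written by [save_fit_draws()].
#' @return List with `chains` (the numeric arrays) and the stored `index`.
#' @export
load_fit_draws <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  chains <- vector("list", index$n_chains)
  for (ch in seq_len(index$n_chains)) {
    chains[[ch]] <- list()
    for (block in c("beta", "lambda", "eta", "sigma2")) {
      meta <- index$blocks[[sprintf("%s_chain%d", block, ch)]]
      f <- file.path(dir, meta$file)
      con <- file(f, "rb")
      v <- readBin(con, "double", n = prod(meta$dim))
      close(con)
      chains[[ch]][[block]] <- array(v, dim = meta$dim)
    }
    chains[[ch]]$n_draws <- utils::tail(index$blocks[[sprintf("beta_chain%d", ch)]]$dim, 1)
  }
  list(chains = chains, index = index)
}
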