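#' Potential scale reduction factor (split-chain Gelman-Rubin)
#'
#' @param chains List of numeric matrices (draws x parameters), one per
#'   chain, all of equal dimension; vectors are treated as one-column
#'   matrices.
#' @param split Split each chain in half before comparing (default `TRUE`),
#'   so that within-chain drift also inflates the statistic.
#' @return Numeric vector of PSRF values, one per parameter.  `NA` for
#'   parameters with zero variance everywhere.
#' @export
compute_psrf <- function(chains, split = TRUE) {
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(x))
  if (length(chains) < 2 && !split) abort("need at least 2 chains")
  nd <- unique(vapply(chains, nrow, 1L))
  if (length(nd) != 1) abort("chains must have equal length")
  if (split) {
    h <- nd %/% 2
    chains <- unlist(lapply(chains, function(x) {
      list(x[seq_len(h), , drop = FALSE],
           x[(nrow(x) - h + 1):nrow(x), , drop = FALSE])
    }), recursive = FALSE)
  }
  m <- length(chains)
  n <- nrow(chains[[1]])
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(x) apply(x, 2, stats::var),
                 numeric(ncol(chains[[1]])))
  means <- matrix(means, ncol = m)
  vars <- matrix(vars, ncol = m)
  W <- rowMeans(vars)
  B <- n * apply(means, 1, stats::var)
  var_plus <- (n - 1) / n * W + B / n
  out <- sqrt(var_plus / W)
  out[W == 0 & B == 0] <- NA_real_
  out
}

# Geyer initial-monotone-positive-sequence ESS for a single scalar chain
.ess_one <- function(x, max_lag = 2000L) {
  n <- length(x)
  if (stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 1L, max_lag)
  rho <- stats::acf(x, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  n_pairs <- (length(rho)) %/% 2
  if (n_pairs == 0) return(n)
  G <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  # initial positive sequence
  stop_at <- which(G <= 0)
  if (length(stop_at) > 0) G <- G[seq_len(stop_at[1] - 1)]
  # enforce monotone decrease
  if (length(G) > 1) G <- cummin(G)
  tau <- max(2 * sum(G) - 1, 1e-8)
  min(n / tau, n)
}

#' Effective sample size (initial monotone sequence)
#'
#' Autocorrelation-based effective sample size per scalar parameter, using
#' Geyer's initial-monotone-positive-sequence truncation, computed per chain
#' and summed over chains.
#'
#' @param chains As in [compute_psrf()]; a single matrix or vector is also
#'   accepted.
#' @return Numeric vector of ESS values per parameter (capped at the total
#'   number of retained draws).  Constant chains yield 0 with a warning.
#' @export
compute_ess <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  chains <- lapply(chains, function(x) if (is.matrix(x)) x else cbind(x))
  P <- ncol(chains[[1]])
  out <- numeric(P)
  any_const <- FALSE
  for (j in seq_len(P)) {
    vals <- vapply(chains, function(x) .ess_one(x[, j]), numeric(1))
    if (all(is.na(vals))) {
      any_const <- TRUE
      out[j] <- 0
    } else {
      out[j] <- sum(vals, na.rm = TRUE)
    }
  }
  if (any_const)
    warn("constant chain(s): effective sample size undefined, reported as 0")
  out
}

# draws x (pairs) matrix of residual-correlation entries, per chain
.omega_draws <- function(fit, part = c("occurrence", "abundance"),
                         max_pairs = 1500L) {
  part <- match.arg(part)
  S <- nrow(fit$species)
  rows <- if (part == "occurrence") seq_len(S) else S + seq_len(S)
  pairs <- which(upper.tri(matrix(0, S, S)), arr.ind = TRUE)
  if (nrow(pairs) > max_pairs) {
    set.seed(derive_seed(fit$mcmc$seed, 997L))
    pairs <- pairs[sample.int(nrow(pairs), max_pairs), , drop = FALSE]
  }
  lapply(fit$chains, function(ch) {
    D <- ch$n_draws
    out <- matrix(NA_real_, D, nrow(pairs))
    for (d in seq_len(D)) {
      lam <- matrix(ch$lambda[rows, , d], length(rows))
      om <- tcrossprod(lam)
      out[d, ] <- om[cbind(pairs[, 1], pairs[, 2])]
    }
    out
  })
}

#' MCMC convergence report for a fitted model
#'
#' Computes effective sample sizes and potential scale reduction factors for
#' the species-niche coefficients (beta) and the species-to-species
#' association entries (omega, from the factor loadings), per model part.
#'
#' @param fit A [fit_jsdm()] object with at least two chains.
#' @return Tibble with one row per parameter block: `block`, `n_parameters`,
#'   `min_ess`, `median_ess`, `max_psrf`, `median_psrf`.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "jsdm_fit"))
  blocks <- list(beta = param_draws(fit, "beta", split = TRUE))
  if (fit$n_factors > 0) {
    blocks$omega_occurrence <- .omega_draws(fit, "occurrence")
    blocks$omega_abundance <- .omega_draws(fit, "abundance")
  }
  purrr::map_dfr(names(blocks), function(b) {
    ch <- blocks[[b]]
    keep <- apply(do.call(rbind, ch), 2, stats::sd) > 0
    ch <- lapply(ch, function(x) x[, keep, drop = FALSE])
    ess <- compute_ess(ch)
    psrf <- compute_psrf(ch)
    tibble(block = b, n_parameters = sum(keep),
           min_ess = min(ess), median_ess = stats::median(ess),
           max_psrf = max(psrf, na.rm = TRUE),
           median_psrf = stats::median(psrf, na.rm = TRUE))
  })
}
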