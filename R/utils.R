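# Internal numerical helpers.

#' @importFrom stats pnorm qnorm rnorm runif rgamma rexp rbinom sd var cor
#' @importFrom rlang abort warn inform %||%
NULL

# Draw from N(mean, 1) truncated to (0, Inf) when `positive`, (-Inf, 0] otherwise.
# Inverse-CDF sampling with an exponential-rejection fallback for deep tails,
# where the CDF underflows (|mean| beyond ~8).
rtnorm_sign <- function(mean, positive) {
  stopifnot(length(mean) == length(positive))
  n <- length(mean)
  # reduce to lower-truncation at 0 of N(m, 1): for y = 0 draw from the
  # positive tail of N(-m, 1) and negate
  m <- ifelse(positive, mean, -mean)
  a <- -m                      # standardized lower bound
  out <- numeric(n)
  easy <- a < 6
  if (any(easy)) {
    p0 <- pnorm(a[easy])
    u <- p0 + runif(sum(easy)) * (1 - p0)
    u <- pmin(u, 1 - 1e-16)
    out[easy] <- m[easy] + qnorm(u)
  }
  if (any(!easy)) {
    # Robert (1995) translated-exponential rejection, standardized scale
    ah <- a[!easy]
    x <- vapply(ah, function(aa) {
      lam <- (aa + sqrt(aa^2 + 4)) / 2
      repeat {
        z <- aa + rexp(1, rate = lam)
        if (runif(1) <= exp(-(z - lam)^2 / 2)) return(z)
      }
    }, numeric(1))
    out[!easy] <- m[!easy] + x
  }
  ifelse(positive, out, -out)
}

# Deterministic child seeds below 2^31 from one master seed.
derive_seed <- function(master, k) {
  as.integer((as.double(master) * 48271 + 11 * k) %% 2147483629 + 1)
}

# Column-standardize the non-intercept columns of a design matrix; returns the
# scaled matrix with centers/scales stored as attributes.  Constant columns are
# left untouched (scale 1, center 0) apart from the intercept.
standardize_design <- function(X) {
  ctr <- rep(0, ncol(X))
  scl <- rep(1, ncol(X))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  keep[colnames(X) %in% "(Intercept)"] <- FALSE
  ctr[keep] <- colMeans(X[, keep, drop = FALSE])
  scl[keep] <- apply(X[, keep, drop = FALSE], 2, stats::sd)
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

# Map coefficients fitted on a standardized design back to the original scale.
# beta is p x m (columns are species).
unstandardize_beta <- function(beta, center, scale, intercept_row = 1L) {
  b <- beta / scale
  if (!is.null(intercept_row)) {
    shift <- colSums(beta * (center / scale))
    b[intercept_row, ] <- beta[intercept_row, ] - shift
  }
  b
}
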