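#' Assemble the two-part hurdle response from a community table
#'
#' Truncates counts to presence-absence for the probit part and, for the
#' lognormal part, sets zeros to missing and standardizes the natural log of
#' the remaining counts per OTU to zero mean and unit variance over the
#' samples where the OTU is present.  The per-OTU centering and scaling
#' parameters are stored so that standardized abundances can be mapped back
#' to log counts exactly.
#'
#' @param x A (typically filtered) [community_table()].
#' @return Object of class `hurdle_response`: list with `pa` (binary matrix),
#'   `abund` (standardized log counts, `NA` where absent), `scaling` (tibble
#'   with per-OTU `mean`, `sd`, `n_present` and `degenerate` flag), `guild`,
#'   `sample_ids`, `otu_ids`.
#' @details OTUs present in fewer than two samples, or whose log counts have
#'   zero variance over presences, have no identifiable abundance part; they
#'   are flagged `degenerate` and their `abund` column is left `NA` (they
#'   still contribute to the presence-absence part).  An all-zero OTU is an
#'   error: it cannot survive any prevalence filter.
#' @export
assemble_hurdle_response <- function(x) {
  stopifnot(inherits(x, "community_table"))
  counts <- x$counts
  pa <- (counts > 0) * 1L
  n_present <- colSums(pa)
  if (any(n_present == 0)) {
    abort(paste0("all-zero OTU(s) in the table (e.g. '",
                 x$otu_ids[which(n_present == 0)[1]],
                 "'); filter the table before assembling the hurdle response"))
  }
  logc <- log(counts)
  logc[counts == 0] <- NA_real_
  mu <- colMeans(logc, na.rm = TRUE)
  sdv <- apply(logc, 2, stats::sd, na.rm = TRUE)   # sample sd over presences
  degenerate <- n_present < 2 | !is.finite(sdv) | sdv == 0
  abund <- sweep(logc, 2, mu, "-")
  abund <- sweep(abund, 2, ifelse(degenerate, 1, sdv), "/")
  abund[, degenerate] <- NA_real_
  structure(
    list(pa = pa, abund = abund,
         scaling = tibble(otu_id = x$otu_ids, mean = mu,
                          sd = ifelse(degenerate, NA_real_, sdv),
                          n_present = as.integer(n_present),
                          degenerate = degenerate),
         guild = x$guild, sample_ids = x$sample_ids, otu_ids = x$otu_ids),
    class = "hurdle_response")
}

#' @export
print.hurdle_response <- function(x, ...) {
  cat(sprintf(
    "<hurdle_response> guild '%s': %d samples x %d OTUs (%d degenerate abundance parts)\n",
    x$guild, nrow(x$pa), ncol(x$pa), sum(x$scaling$degenerate)))
  invisible(x)
}

#' Back-transform standardized abundances to log counts
#'
#' @param x A [assemble_hurdle_response()] result.
#' @return Matrix of natural-log counts (`NA` where absent or degenerate).
#' @export
unscale_abundance <- function(x) {
  stopifnot(inherits(x, "hurdle_response"))
  sdv <- ifelse(is.na(x$scaling$sd), 1, x$scaling$sd)
  sweep(sweep(x$abund, 2, sdv, "*"), 2, x$scaling$mean, "+")
}

# Standardize a test-fold table against a training fit's scaling parameters
# (per-OTU mean/sd estimated on the training presences).
apply_hurdle_scaling <- function(counts, scaling) {
  logc <- log(counts)
  logc[counts == 0] <- NA_real_
  sdv <- ifelse(is.na(scaling$sd), 1, scaling$sd)
  ab <- sweep(sweep(logc, 2, scaling$mean, "-"), 2, sdv, "/")
  ab[, scaling$degenerate] <- NA_real_
  list(pa = (counts > 0) * 1L, abund = ab)
}
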