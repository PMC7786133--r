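#' Construct a community count table
#'
#' A community table holds non-negative integer sequence counts for one guild
#' (e.g. fungi or bacteria) with samples as rows and OTUs as columns.  The
#' per-sample sequencing depth is the row sum and is stored alongside the
#' counts.
#'
#' @param counts Non-negative integer matrix, samples x OTUs.  Row and column
#'   names are used as sample and OTU identifiers when `sample_ids` /
#'   `otu_ids` are not given.
#' @param guild Guild label, typically `"fungi"` or `"bacteria"`.
#' @param sample_ids,otu_ids Optional identifier vectors overriding dimnames.
#' @return An object of class `community_table`: a list with elements
#'   `counts`, `sample_ids`, `otu_ids`, `guild` and `depth` (row sums).
#' @export
#' @examples
#' m <- matrix(c(3L, 0L, 1L, 5L), 2, 2, byrow = TRUE,
#'             dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
#' ct <- community_table(m, "fungi")
#' ct$depth
community_table <- function(counts, guild, sample_ids = NULL, otu_ids = NULL) {
  counts <- as.matrix(counts)
  sample_ids <- sample_ids %||% rownames(counts) %||%
    paste0("sample", seq_len(nrow(counts)))
  otu_ids <- otu_ids %||% colnames(counts) %||%
    paste0("otu", seq_len(ncol(counts)))
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | counts != floor(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell sample '%s', OTU '%s' (value %s)",
      sample_ids[bad[1, 1]], otu_ids[bad[1, 2]], counts[bad[1, 1], bad[1, 2]]))
  }
  if (anyDuplicated(sample_ids)) abort("duplicated sample identifiers")
  if (anyDuplicated(otu_ids)) abort("duplicated OTU identifiers")
  if (nrow(counts) < 2) abort("a community table needs at least 2 samples")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, otu_ids)
  structure(
    list(counts = counts, sample_ids = sample_ids, otu_ids = otu_ids,
         guild = as.character(guild), depth = rowSums(counts)),
    class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> guild '%s': %d samples x %d OTUs, depth %d-%d\n",
              x$guild, nrow(x$counts), ncol(x$counts),
              min(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
dim.community_table <- function(x) dim(x$counts)

#' Coerce a community table to a long tibble
#'
#' @param x A [community_table()].
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `otu_id`, `guild`, `count`,
#'   `depth` and `relabund`.
#' @importFrom tibble as_tibble tibble
#' @export
as_tibble.community_table <- function(x, ...) {
  tibble(
    sample_id = rep(x$sample_ids, times = ncol(x$counts)),
    otu_id = rep(x$otu_ids, each = nrow(x$counts)),
    guild = x$guild,
    count = as.integer(x$counts),
    depth = rep(x$depth, times = ncol(x$counts))
  ) |>
    dplyr::mutate(relabund = .data$count / .data$depth)
}

#' Read a community count table from a TSV file
#'
#' Expects a UTF-8 tab-separated file with the first column holding sample
#' identifiers and the header row holding OTU identifiers.  Cells must be
#' non-negative integer sequence counts.
#'
#' @param path Path to the TSV file.
#' @param guild Guild label for the table.
#' @param transposed If `TRUE` the file stores OTUs as rows and samples as
#'   columns and is transposed after reading.
#' @return A validated [community_table()] with `depth` set to the row sums.
#' @export
read_community_table <- function(path, guild, transposed = FALSE) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transposed) m <- t(m)
  community_table(m, guild)
}

#' Write a community table to TSV
#'
#' @param x A [community_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_table <- function(x, path) {
  df <- tibble::as_tibble(as.data.frame(x$counts), rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Rare-OTU filter thresholds
#'
#' OTUs are retained when their prevalence (fraction of samples with a
#' non-zero count) is strictly greater than `min_prevalence` *and* their
#' maximum per-sample relative abundance is at least `min_max_relabund`.
#' The defaults (10% prevalence, 0.5% relative abundance) correspond to the
#' standard screen for OTUs too rare to support species-specific models; a
#' threshold of exactly 0 disables the corresponding screen.
#'
#' @param min_prevalence Fraction of samples, in `[0, 1)`.
#' @param min_max_relabund Fraction, in `[0, 1)`.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(min_prevalence = 0.10, min_max_relabund = 0.005) {
  if (!is.numeric(min_prevalence) || min_prevalence < 0 || min_prevalence >= 1)
    abort("min_prevalence must be in [0, 1)")
  if (!is.numeric(min_max_relabund) || min_max_relabund < 0 || min_max_relabund >= 1)
    abort("min_max_relabund must be in [0, 1)")
  structure(list(min_prevalence = min_prevalence,
                 min_max_relabund = min_max_relabund),
            class = "filter_spec")
}

#' Filter rare OTUs from a community table
#'
#' @param x A [community_table()].
#' @param spec A [filter_spec()].
#' @return A [community_table()] with the retained OTUs; sample rows are
#'   unchanged (and so are depths, which remain the *original* row sums --
#'   sequencing depth is a property of the sample, not of the retained OTUs).
#' @details Prevalence is compared strictly (`>`), maximum relative abundance
#'   inclusively (`>=`); relative abundance is computed against the sample's
#'   total depth.  Setting a threshold to 0 disables that screen.
#' @export
filter_otus <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "community_table"))
  if (!inherits(spec, "filter_spec")) spec <- do.call(filter_spec, as.list(spec))
  present <- x$counts > 0
  prevalence <- colMeans(present)
  relabund <- sweep(x$counts, 1, pmax(x$depth, 1L), "/")
  max_ra <- apply(relabund, 2, max)
  keep_prev <- if (spec$min_prevalence > 0) prevalence > spec$min_prevalence
               else rep(TRUE, ncol(x$counts))
  keep_ra <- max_ra >= spec$min_max_relabund
  keep <- keep_prev & keep_ra
  if (!any(keep)) {
    abort(paste0("all OTUs were removed by the filter (prevalence > ",
                 spec$min_prevalence, ", max relative abundance >= ",
                 spec$min_max_relabund, "); relax the thresholds"))
  }
  out <- x
  out$counts <- x$counts[, keep, drop = FALSE]
  out$otu_ids <- x$otu_ids[keep]
  # depth deliberately kept as the pre-filter sequencing depth
  out
}
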