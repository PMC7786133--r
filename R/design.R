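#' Read and validate a sample metadata table
#'
#' The metadata table carries the wood chemistry and physical covariates plus
#' per-guild sequencing read counts.  Expected columns: `sample_id`, `water`
#' (percent), `ph`, `c` (percent C), `n` (percent N), `lignin` (percent),
#' `tree_species` (beech/spruce/fir), `decay_class` (`<5`, `5-15`, `16-38`,
#' `>38` years), `dbh` (cm), and one `reads_<guild>` column per guild.
#'
#' @param path TSV file path.
#' @return A validated tibble of class `sample_metadata`.
#' @export
read_sample_metadata <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_sample_metadata(df)
}

#' Validate sample metadata
#'
#' @param df Data frame of per-sample covariates (see
#'   [read_sample_metadata()] for the expected columns).
#' @return The validated tibble, with `tree_species` and `decay_class` as
#'   factors (reference levels `beech` and `<5`).
#' @export
validate_sample_metadata <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("sample_id", "water", "ph", "c", "n", "lignin",
            "tree_species", "decay_class", "dbh")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    abort(paste0("metadata is missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) abort("duplicated sample identifiers in metadata")
  for (col in c("water", "c", "n", "lignin")) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0 | v > 100))
      abort(sprintf("column '%s' must be a percentage in [0, 100]", col))
  }
  if (any(!is.finite(df$ph)) || any(df$ph <= 0 | df$ph >= 14))
    abort("pH must lie in (0, 14)")
  df$tree_species <- factor(as.character(df$tree_species),
                            levels = c("beech", "spruce", "fir"))
  if (anyNA(df$tree_species)) abort("tree_species must be beech, spruce or fir")
  df$decay_class <- factor(as.character(df$decay_class),
                           levels = c("<5", "5-15", "16-38", ">38"),
                           ordered = TRUE)
  if (anyNA(df$decay_class)) abort("decay_class must be one of <5, 5-15, 16-38, >38")
  class(df) <- c("sample_metadata", class(df))
  df
}

#' Build a fixed-effect design matrix
#'
#' The null model carries sequencing depth as the sole explanatory variable
#' (intercept + log reads).  The full model adds the wood chemistry block
#' (water, pH, C, log N, lignin) and the physical block (tree species, decay
#' class, DBH).  C/N ratio is never included: it is almost perfectly
#' collinear with N content, and any `cn` column found in the metadata is
#' dropped with a notice.  Categorical covariates use treatment contrasts
#' with reference levels `beech` and `<5` years.
#'
#' @param meta A validated metadata table (see [validate_sample_metadata()]).
#' @param model `"null"` or `"full"`.
#' @param guild Guild whose `reads_<guild>` column supplies the depth
#'   covariate (each guild's model uses its own depths).
#' @return An object of class `design_matrix`: list with `values` (numeric
#'   matrix), `group_map` (named character vector assigning each non-intercept
#'   column to `chemical`, `physical` or `depth`) and `encoding` (reference
#'   levels used).
#' @export
#' @examples
#' md <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), water = c(40, 50, 60), ph = c(4, 5, 4.5),
#'   c = c(48, 49, 50), n = c(0.2, 0.4, 0.3), lignin = c(25, 30, 28),
#'   tree_species = c("beech", "spruce", "fir"),
#'   decay_class = c("<5", "5-15", ">38"), dbh = c(35, 60, 80),
#'   reads_fungi = c(5000, 8000, 6500))
#' ncol(build_design_matrix(md, "null", "fungi")$values)   # 2
build_design_matrix <- function(meta, model = c("full", "null"),
                                guild = "fungi") {
  model <- match.arg(model)
  meta <- validate_sample_metadata(meta)
  cn_cols <- grep("^c[._/ ]?n([._ ]?ratio)?$", names(meta), ignore.case = TRUE,
                  value = TRUE)
  if (length(cn_cols) > 0) {
    inform(paste0("ignoring C/N ratio column(s) ",
                  paste(sQuote(cn_cols), collapse = ", "),
                  ": collinear with N content, never used as a covariate"))
    meta <- meta[, setdiff(names(meta), cn_cols)]
  }
  reads_col <- paste0("reads_", guild)
  if (!reads_col %in% names(meta))
    abort(paste0("metadata lacks the per-guild read-count column '", reads_col, "'"))
  reads <- meta[[reads_col]]
  if (any(!is.finite(reads)) || any(reads <= 0))
    abort("read counts must be positive before log transformation")
  if (model == "full" && (any(!is.finite(meta$n)) || any(meta$n <= 0)))
    abort("percent N must be positive before log transformation")

  if (model == "null") {
    X <- cbind("(Intercept)" = 1, log_reads = log(reads))
    group_map <- c(log_reads = "depth")
  } else {
    # dummies built against the fixed level sets (treatment contrasts,
    # references beech and "<5"), independent of which levels happen to be
    # present in this particular sample set
    X <- cbind(
      "(Intercept)" = rep(1, nrow(meta)),
      water = meta$water, ph = meta$ph, c = meta$c, log_n = log(meta$n),
      lignin = meta$lignin,
      tree_speciesspruce = as.numeric(meta$tree_species == "spruce"),
      tree_speciesfir = as.numeric(meta$tree_species == "fir"),
      "decay_class5-15" = as.numeric(meta$decay_class == "5-15"),
      "decay_class16-38" = as.numeric(meta$decay_class == "16-38"),
      "decay_class>38" = as.numeric(meta$decay_class == ">38"),
      dbh = meta$dbh, log_reads = log(reads))
    group_map <- c(
      water = "chemical", ph = "chemical", c = "chemical",
      log_n = "chemical", lignin = "chemical",
      tree_speciesspruce = "physical", tree_speciesfir = "physical",
      `decay_class5-15` = "physical", `decay_class16-38` = "physical",
      `decay_class>38` = "physical",
      dbh = "physical", log_reads = "depth")
    # degenerate categorical encodings for this particular sample set:
    # (i) a dummy that is constant carries no information; (ii) when the
    # reference level itself is absent, the remaining dummies partition the
    # samples and collide with the intercept, so the block is re-referenced
    # on its first present level
    blocks <- list(
      list(col = "tree_species", levels = c("beech", "spruce", "fir"),
           values = as.character(meta$tree_species)),
      list(col = "decay_class", levels = c("<5", "5-15", "16-38", ">38"),
           values = as.character(meta$decay_class)))
    drop_cols <- character(0)
    for (b in blocks) {
      present <- b$levels[b$levels %in% unique(b$values)]
      ref <- if (b$levels[1] %in% present) b$levels[1] else present[1]
      keep_lv <- setdiff(present, ref)
      all_dummies <- paste0(b$col, b$levels[-1])
      drop_cols <- c(drop_cols,
                     setdiff(all_dummies, paste0(b$col, keep_lv)))
    }
    if (length(drop_cols) > 0) {
      inform(paste0("re-referencing degenerate categorical column(s) for ",
                    "this sample set: dropping ",
                    paste(drop_cols, collapse = ", ")))
      X <- X[, setdiff(colnames(X), drop_cols), drop = FALSE]
      group_map <- group_map[setdiff(names(group_map), drop_cols)]
    }
  }
  rownames(X) <- meta$sample_id
  structure(
    list(values = X, group_map = group_map,
         encoding = list(tree_species_ref = "beech", decay_class_ref = "<5"),
         model = model, guild = guild),
    class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("<design_matrix> %s model, guild '%s': %d samples x %d columns\n",
              x$model, x$guild, nrow(x$values), ncol(x$values)))
  invisible(x)
}
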