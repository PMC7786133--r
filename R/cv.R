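#' Cross-validation settings
#'
#' @param n_folds Number of folds over sampling units (default 2).
#' @param seed Seed for the fold assignment and conditional sampler.
#' @param n_outer Posterior draws subsampled for conditional prediction.
#' @param n_inner,n_inner_burn Inner Gibbs draws (after burn-in) for the
#'   conditional factor-score sampler.
#' @return A `cv_spec` list.
#' @export
cv_spec <- function(n_folds = 2, seed = 1L, n_outer = 100, n_inner = 100,
                    n_inner_burn = 50) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 n_outer = n_outer, n_inner = n_inner,
                 n_inner_burn = n_inner_burn),
            class = "cv_spec")
}

#' Seeded fold assignment
#'
#' @param n Number of sampling units.
#' @param n_folds Number of folds.
#' @param seed Seed.
#' @return Integer vector of fold labels, sizes as equal as possible.
#' @export
make_folds <- function(n, n_folds = 2, seed = 1L) {
  set.seed(seed)
  sample(rep(seq_len(n_folds), length.out = n))
}

# subset rows of a community table
subset_ct <- function(x, idx) {
  out <- x
  out$counts <- x$counts[idx, , drop = FALSE]
  out$sample_ids <- x$sample_ids[idx]
  out$depth <- x$depth[idx]
  out
}

# subset columns of a community table by OTU id
select_otus <- function(x, ids) {
  out <- x
  out$counts <- x$counts[, ids, drop = FALSE]
  out$otu_ids <- ids
  out
}

auc_quiet <- function(labels, scores) {
  suppressMessages(compute_auc(labels, scores))
}

# map abundance predictions from the training fold's standardized scale to
# the global standardized scale used for evaluation
.rescale_pred <- function(pred, sc_train, sc_glob) {
  sd_tr <- sc_train$sd; mu_tr <- sc_train$mean
  sd_gl <- sc_glob$sd; mu_gl <- sc_glob$mean
  out <- sweep(sweep(pred, 2, ifelse(is.na(sd_tr), NA, sd_tr), "*"),
               2, mu_tr, "+")
  sweep(sweep(out, 2, mu_gl, "-"), 2, ifelse(is.na(sd_gl), NA, sd_gl), "/")
}

#' Explanatory, unconditional and conditional predictive power by
#' cross-validation
#'
#' Runs the full evaluation procedure over the sampling units: models are
#' fitted to each training fold and predict the held-out fold (i)
#' unconditionally, using the environmental predictors only, and (ii)
#' conditionally, additionally treating the occurrences and abundances of
#' the non-focal guild as known in the testing fold.  Explanatory power
#' refits on all data and predicts the same data.  Occurrence predictions
#' are scored per species by AUC, abundance predictions by R-squared on the
#' standardized log-abundance scale; held-out predictions are pooled across
#' folds before scoring.
#'
#' @param tables Named list of filtered [community_table()]s, one per guild.
#' @param meta Sample metadata covering the tables' samples, in order.
#' @param models Character subset of `c("null", "full")`.
#' @param n_factors,priors,mcmc Passed to [fit_jsdm()].
#' @param cv A [cv_spec()].
#' @param regimes Character subset of
#'   `c("explanatory", "unconditional", "conditional")`.
#' @param verbose Print per-stage progress.
#' @return Tibble of class `evaluation_report` with columns `model`,
#'   `regime`, `guild`, `part`, `otu_id`, `metric`, `value` (per-species AUC
#'   or R2; `NA` where a species could not be evaluated, e.g. single-class
#'   test labels).  Species absent from a training fold are dropped from
#'   that fold's model and from its evaluation.
#' @export
two_fold_cv <- function(tables, meta, models = c("null", "full"),
                        n_factors = 3, priors = jsdm_priors(),
                        mcmc = mcmc_control(), cv = cv_spec(),
                        regimes = c("explanatory", "unconditional",
                                    "conditional"),
                        verbose = FALSE) {
  guilds <- names(tables)
  meta <- validate_sample_metadata(meta)
  n <- nrow(tables[[1]]$counts)
  if (n < 2 * cv$n_folds * 2)
    abort("too few samples: need at least 4 per fold")
  folds <- make_folds(n, cv$n_folds, cv$seed)

  species <- purrr::map_dfr(guilds, function(g)
    tibble(otu_id = tables[[g]]$otu_ids, guild = g))
  S <- nrow(species)
  resp_glob <- lapply(tables, assemble_hurdle_response)
  pa_glob <- do.call(cbind, lapply(resp_glob, function(r) r$pa))
  ab_glob <- do.call(cbind, lapply(resp_glob, function(r) r$abund))
  sc_glob <- lapply(resp_glob, function(r) r$scaling)

  say <- function(...) if (verbose) message(sprintf(...))
  empty_pred <- function() list(occ = matrix(NA_real_, n, S),
                                ab = matrix(NA_real_, n, S))
  preds <- list()

  for (model in models) {
    preds[[model]] <- list()
    designs_all <- lapply(stats::setNames(guilds, guilds), function(g)
      build_design_matrix(meta, model, g))

    if ("explanatory" %in% regimes) {
      say("fitting %s model to all data (explanatory power)", model)
      fit_all <- fit_jsdm(resp_glob, designs_all, n_factors, priors, mcmc)
      pe <- predict_explanatory(fit_all)
      preds[[model]]$explanatory <- list(occ = pe$occurrence,
                                         ab = pe$abundance)
    }

    need_cv <- intersect(c("unconditional", "conditional"), regimes)
    if (length(need_cv) > 0) {
      for (r in need_cv) preds[[model]][[r]] <- empty_pred()
      for (k in seq_len(cv$n_folds)) {
        train <- which(folds != k); test <- which(folds == k)
        say("%s model, fold %d: %d train / %d test", model, k,
            length(train), length(test))
        kept <- lapply(stats::setNames(guilds, guilds), function(g) {
          cnt <- tables[[g]]$counts[train, , drop = FALSE]
          tables[[g]]$otu_ids[colSums(cnt > 0) > 0]
        })
        tr_tables <- lapply(stats::setNames(guilds, guilds), function(g)
          select_otus(subset_ct(tables[[g]], train), kept[[g]]))
        resp_tr <- lapply(tr_tables, assemble_hurdle_response)
        meta_tr <- meta[train, , drop = FALSE]
        meta_te <- meta[test, , drop = FALSE]
        des_tr <- lapply(stats::setNames(guilds, guilds), function(g)
          build_design_matrix(meta_tr, model, g))
        des_te <- lapply(stats::setNames(guilds, guilds), function(g)
          build_design_matrix(meta_te, model, g))
        mcmc_k <- mcmc
        mcmc_k$seed <- derive_seed(mcmc$seed, 100L + k)
        fit_k <- fit_jsdm(resp_tr, des_tr, n_factors, priors, mcmc_k)

        col_map <- match(fit_k$species$otu_id, species$otu_id)
        sc_tr_all <- do.call(rbind, lapply(fit_k$scaling, function(x) x))
        sc_gl_all <- do.call(rbind, sc_glob)[
          match(fit_k$species$otu_id, species$otu_id), ]

        if ("unconditional" %in% need_cv) {
          pu <- predict_unconditional(fit_k, des_te)
          preds[[model]]$unconditional$occ[test, col_map] <- pu$occurrence
          preds[[model]]$unconditional$ab[test, col_map] <-
            .rescale_pred(pu$abundance, sc_tr_all, sc_gl_all)
        }
        if ("conditional" %in% need_cv) {
          for (focal in guilds) {
            others <- setdiff(guilds, focal)
            cond_tabs <- lapply(stats::setNames(others, others), function(g)
              select_otus(subset_ct(tables[[g]], test), kept[[g]]))
            pc <- predict_conditional(
              fit_k, des_te, cond_tabs, focal,
              n_outer = cv$n_outer, n_inner = cv$n_inner,
              n_inner_burn = cv$n_inner_burn,
              seed = derive_seed(cv$seed, 1000L * k + match(focal, guilds)))
            fcols <- which(fit_k$species$guild == focal)
            preds[[model]]$conditional$occ[test, col_map[fcols]] <-
              pc$occurrence[, fcols, drop = FALSE]
            preds[[model]]$conditional$ab[test, col_map[fcols]] <-
              .rescale_pred(pc$abundance[, fcols, drop = FALSE],
                            sc_tr_all[fcols, ], sc_gl_all[fcols, ])
          }
        }
      }
    }
  }

  out <- purrr::map_dfr(names(preds), function(model) {
    purrr::map_dfr(names(preds[[model]]), function(regime) {
      p <- preds[[model]][[regime]]
      purrr::map_dfr(seq_len(S), function(s) {
        rows_o <- which(!is.na(p$occ[, s]))
        auc <- if (length(rows_o) > 1)
          auc_quiet(pa_glob[rows_o, s], p$occ[rows_o, s]) else NA_real_
        rows_a <- which(!is.na(p$ab[, s]) & !is.na(ab_glob[, s]))
        r2 <- if (length(rows_a) >= 3)
          compute_r2(ab_glob[rows_a, s], p$ab[rows_a, s]) else NA_real_
        tibble(model = model, regime = regime,
               guild = species$guild[s], otu_id = species$otu_id[s],
               part = c("occurrence", "abundance"),
               metric = c("auc", "r2"), value = c(auc, r2))
      })
    })
  })
  class(out) <- c("evaluation_report", class(out))
  attr(out, "folds") <- folds
  out
}

#' Guild-averaged predictive power in the layout of a power table
#'
#' @param report An [two_fold_cv()] evaluation report.
#' @return Tibble with one row per category (occurrence/abundance) x guild x
#'   model: number of evaluated species and guild-mean explanatory,
#'   unconditional and conditional power (`NA` when a regime was not run).
#' @export
report_table1 <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  report |>
    dplyr::group_by(.data$part, .data$guild, .data$model, .data$regime) |>
    dplyr::summarise(n_species = sum(!is.na(.data$value)),
                     power = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "regime",
                       values_from = c("power", "n_species")) |>
    dplyr::rename_with(~ sub("^power_", "", .x)) |>
    dplyr::mutate(category = ifelse(.data$part == "occurrence",
                                    "Occurrence", "Abundance"),
                  .before = 1) |>
    dplyr::arrange(dplyr::desc(.data$part), .data$guild, .data$model)
}

#' Directional information value of one guild for the other
#'
#' The gain of a guild is the difference between its conditional and
#' unconditional guild-mean predictive power: how much better the focal
#' guild is predicted when the non-focal guild's occurrences and abundances
#' are known.  The environment gain (full-model unconditional minus
#' null-model unconditional) is attached so the two information sources can
#' be compared directly.
#'
#' @param report An [two_fold_cv()] evaluation report containing the
#'   unconditional and conditional regimes.
#' @return Tibble with columns `guild`, `part`, `model`, `unconditional`,
#'   `conditional`, `gain`; attribute `environment_gain` holds the per-guild
#'   full-vs-null unconditional contrast when both models are present.
#' @export
directionality_gain <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  means <- report |>
    dplyr::filter(.data$regime %in% c("unconditional", "conditional")) |>
    dplyr::group_by(.data$guild, .data$part, .data$model, .data$regime) |>
    dplyr::summarise(power = mean(.data$value, na.rm = TRUE),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "regime", values_from = "power")
  if (!all(c("unconditional", "conditional") %in% names(means)))
    abort("report must contain both the unconditional and conditional regimes")
  out <- dplyr::mutate(means, gain = .data$conditional - .data$unconditional)
  if (all(c("null", "full") %in% unique(report$model))) {
    env <- report |>
      dplyr::filter(.data$regime == "unconditional") |>
      dplyr::group_by(.data$guild, .data$part, .data$model) |>
      dplyr::summarise(power = mean(.data$value, na.rm = TRUE),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "model", values_from = "power") |>
      dplyr::mutate(environment_gain = .data$full - .data$null)
    attr(out, "environment_gain") <- env
  }
  class(out) <- c("directionality_gain", class(out))
  out
}
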