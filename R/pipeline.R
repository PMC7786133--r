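#' Assemble and validate a pipeline run configuration
#'
#' Exactly one of `data` (paths to real count/metadata TSVs) or `simulation`
#' (arguments for [simulation_config()]) must be supplied.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param data `NULL`, or a list with `counts` (named list of per-guild TSV
#'   paths) and `metadata` (TSV path).
#' @param simulation `NULL`, or a list of [simulation_config()] arguments.
#' @param filter List with `min_prevalence` and `min_max_relabund` (see
#'   [filter_spec()]).
#' @param n_factors,priors Model settings (see [fit_jsdm()],
#'   [jsdm_priors()]).
#' @param mcmc List of [mcmc_control()] arguments.
#' @param cv List of [cv_spec()] arguments; `NULL` or `FALSE` skips
#'   cross-validation.
#' @param support_level Edge support level for the association networks.
#' @param seed Master seed, propagated to every stochastic stage.
#' @param verbose Print per-stage progress.
#' @return A validated `run_config` list.
#' @export
run_config <- function(output_dir, data = NULL, simulation = NULL,
                       filter = list(), n_factors = 3,
                       priors = jsdm_priors(), mcmc = list(),
                       cv = list(), support_level = 0.95, seed = 1L,
                       verbose = FALSE) {
  if (is.null(data) == is.null(simulation))
    abort("exactly one of `data` and `simulation` must be given")
  if (!is.null(data)) {
    paths <- c(unlist(data$counts), data$metadata)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0)
      abort(paste0("input file(s) not found: ", paste(missing, collapse = ", ")))
  }
  if (isFALSE(cv)) cv <- NULL
  cfg <- list(output_dir = output_dir, data = data, simulation = simulation,
              filter = filter, n_factors = n_factors, priors = priors,
              mcmc = mcmc, cv = cv, support_level = support_level,
              seed = as.integer(seed), verbose = isTRUE(verbose))
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pri <- do.call(jsdm_priors, y$priors %||% list())
  y$priors <- pri
  do.call(run_config, y)
}

# stable hash of the scientific part of a config (output dir and verbosity
# excluded), used for resumability bookkeeping
config_hash <- function(config) {
  core <- config[setdiff(names(config), c("output_dir", "verbose"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(utils::capture.output(utils::str(core, digits.d = 12)),
                   collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full paired-guild analysis pipeline
#'
#' Sequences the complete analysis from one configuration: load or simulate
#' the paired tables, filter rare OTUs, run diversity diagnostics, fit the
#' null (depth-only) and full (environmental) models, compute convergence
#' reports, build and contrast the residual association networks, partition
#' explained variance under the full model, evaluate explanatory /
#' unconditional / conditional predictive power by cross-validation, and
#' derive the directional information gains.  All artifacts are written as
#' TSV under `output_dir`, with a JSON manifest recording the config hash,
#' seeds, stage timings and status.  Completed stages are cached
#' (`stages/*.rds`) and reused when the pipeline is rerun with an unchanged
#' configuration.
#'
#' @param config A [run_config()] (or path to a YAML file for
#'   [read_run_config()]).
#' @return The manifest, invisibly (a list; also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dir <- file.path(config$output_dir, "stages")
  dir.create(stage_dir, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (config$verbose) message(sprintf(...))

  manifest <- list(config_hash = hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("crossguild")),
                   stages = list())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    f <- file.path(stage_dir, paste0(name, ".rds"))
    t0 <- Sys.time()
    if (file.exists(f)) {
      cached <- readRDS(f)
      if (identical(cached$hash, hash)) {
        say("stage %s: reusing cached result", name)
        manifest$stages[[name]] <<- list(status = "cached", seconds = 0)
        return(cached$value)
      }
    }
    say("stage %s: running", name)
    value <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest,
                           file.path(config$output_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    saveRDS(list(hash = hash, value = value), f)
    manifest$stages[[name]] <<- list(
      status = "done",
      seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    value
  }
  out_tsv <- function(df, name) {
    readr::write_tsv(tibble::as_tibble(df), file.path(config$output_dir, name))
  }

  inputs <- stage("load", {
    if (!is.null(config$simulation)) {
      sim_args <- config$simulation
      sim_args$seed <- sim_args$seed %||% config$seed
      sim <- simulate_community(do.call(simulation_config, sim_args))
      list(tables = sim$tables, meta = sim$meta, truth = sim$truth)
    } else {
      tables <- purrr::imap(config$data$counts, function(p, g)
        read_community_table(p, g))
      list(tables = tables,
           meta = read_sample_metadata(config$data$metadata), truth = NULL)
    }
  })
  guilds <- names(inputs$tables)

  filtered <- stage("filter", {
    fs <- do.call(filter_spec, config$filter)
    lapply(inputs$tables, filter_otus, spec = fs)
  })
  for (g in guilds) {
    out_tsv(tibble::as_tibble(as.data.frame(filtered[[g]]$counts),
                              rownames = "sample_id"),
            sprintf("filtered_counts_%s.tsv", g))
  }

  div <- stage("diversity", diversity_diagnostics(
    filtered, seed = derive_seed(config$seed, 5L)))
  out_tsv(dplyr::bind_rows(richness = div$richness, beta = div$beta,
                           .id = "diagnostic"), "diversity_diagnostics.tsv")

  mcmc_args <- config$mcmc
  mcmc_args$seed <- mcmc_args$seed %||% config$seed
  mcmc <- do.call(mcmc_control, mcmc_args)
  resp <- lapply(filtered, assemble_hurdle_response)

  fits <- list()
  for (model in c("null", "full")) {
    fits[[model]] <- stage(paste0("fit_", model), {
      designs <- lapply(stats::setNames(guilds, guilds), function(g)
        build_design_matrix(inputs$meta, model, g))
      fit_jsdm(resp, designs, config$n_factors, config$priors, mcmc)
    })
  }

  conv <- stage("convergence", dplyr::bind_rows(
    lapply(fits, convergence_report), .id = "model"))
  out_tsv(conv, "convergence_report.tsv")

  nets <- list()
  for (model in c("null", "full")) {
    for (part in c("occurrence", "abundance")) {
      nm <- paste(model, part, sep = "_")
      nets[[nm]] <- stage(paste0("network_", nm), compute_association_network(
        fits[[model]], config$support_level, part))
      write_edge_list(nets[[nm]],
                      file.path(config$output_dir,
                                sprintf("edges_%s.tsv", nm)))
      out_tsv(tibble::as_tibble(as.data.frame(nets[[nm]]$R_mean),
                                rownames = "otu_id"),
              sprintf("association_matrix_%s.tsv", nm))
    }
  }

  contrast <- stage("network_contrast", {
    lapply(stats::setNames(c("occurrence", "abundance"),
                           c("occurrence", "abundance")), function(part)
      compare_networks(nets[[paste0("null_", part)]],
                       nets[[paste0("full_", part)]]))
  })
  out_tsv(dplyr::bind_rows(lapply(contrast, `[[`, "summary"), .id = "part"),
          "network_contrast.tsv")

  vp <- stage("variance_partition", variance_partition(fits$full))
  out_tsv(vp, "variance_partition.tsv")
  out_tsv(guild_summary(vp), "variance_partition_summary.tsv")

  gains <- NULL
  if (!is.null(config$cv)) {
    report <- stage("cross_validation", {
      cv_args <- config$cv
      cv_args$seed <- cv_args$seed %||% derive_seed(config$seed, 9L)
      two_fold_cv(filtered, inputs$meta, models = c("null", "full"),
                  n_factors = config$n_factors, priors = config$priors,
                  mcmc = mcmc, cv = do.call(cv_spec, cv_args),
                  verbose = config$verbose)
    })
    out_tsv(report, "evaluation_report.tsv")
    out_tsv(report_table1(report), "power_table.tsv")
    gains <- stage("directionality", directionality_gain(report))
    out_tsv(gains, "directionality_gains.tsv")
    env <- attr(gains, "environment_gain")
    if (!is.null(env)) out_tsv(env, "environment_gains.tsv")
  }

  manifest$seconds_total <- round(as.numeric(Sys.time() - t_all,
                                             units = "secs"), 2)
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
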