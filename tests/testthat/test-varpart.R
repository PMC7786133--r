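vp_fixture <- function(beta, lambda, X, group_map, guild = rep("fungi", nrow(lambda) / 2)) {
  designs <- lapply(stats::setNames(unique(guild), unique(guild)),
                    function(g) fake_design(X, group_map, g))
  make_fake_fit(beta = beta, lambda = lambda,
                sigma2 = rep(1, nrow(lambda) / 2),
                eta = matrix(0, nrow(X), ncol(lambda)),
                designs = designs, guild = guild)
}

test_that("an intercept-plus-random-effect model assigns all variance to the random effect", {
  n <- 8
  X <- cbind("(Intercept)" = rep(1, n))
  rownames(X) <- paste0("s", 1:n)
  fit <- vp_fixture(beta = matrix(0.7, 1, 4),
                    lambda = matrix(c(1, 0.5, 1, 0.5), 4, 1),
                    X = X, group_map = stats::setNames(character(0), character(0)),
                    guild = c("fungi", "fungi"))
  vp <- variance_partition(fit)
  expect_true(all(vp$proportion[vp$group == "random"] == 1))
})

test_that("a single covariate with no factors gets all variance in its group", {
  n <- 8
  X <- cbind("(Intercept)" = 1, ph = seq(-1, 1, length.out = n))
  rownames(X) <- paste0("s", 1:n)
  fit <- vp_fixture(beta = matrix(c(0, 2), 2, 4),
                    lambda = matrix(0, 4, 1),
                    X = X, group_map = c(ph = "chemical"),
                    guild = c("fungi", "fungi"))
  fit$n_factors <- 0
  vp <- variance_partition(fit)
  expect_true(all(vp$proportion[vp$group == "chemical"] == 1))
  expect_true(all(vp$proportion[vp$group == "random"] == 0))
})

test_that("per-species proportions sum to one within 1e-8", {
  fx <- small_sim_fit()
  vp <- variance_partition(fx$fit)
  sums <- tibble::as_tibble(vp) |>
    dplyr::group_by(.data$otu_id, .data$part) |>
    dplyr::summarise(s = sum(.data$proportion), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-8))
  expect_true(all(vp$proportion >= 0))
})

test_that("guild summaries average species shares per part and overall", {
  fx <- small_sim_fit()
  vp <- variance_partition(fx$fit)
  gs <- guild_summary(vp)
  # overall rows are the mean of the two part rows
  both <- gs[gs$part == "both_parts" & gs$guild == "fungi" &
               gs$group == "chemical", "proportion", drop = TRUE]
  per_part <- gs[gs$part != "both_parts" & gs$guild == "fungi" &
                   gs$group == "chemical", "proportion", drop = TRUE]
  expect_equal(both, mean(per_part))
})

test_that("recovered chemical-to-physical variance ratio tracks the generative 2:1 ratio", {
  cfg <- simulation_config(
    n_samples = 150, n_species = c(fungi = 25), n_factors = 0,
    loading_scale = c(fungi = 0), niche_scale = c(fungi = 1.4),
    niche_group_weights = c(chemical = 2, physical = 1), seed = 60)
  sim <- simulate_community(cfg)
  resp <- assemble_hurdle_response(sim$tables$fungi)
  des <- build_design_matrix(sim$meta, "full", "fungi")
  fit <- fit_jsdm(resp, des, n_factors = 0,
                  mcmc = mcmc_control(n_chains = 1, n_iter = 1500,
                                      n_burn = 750, thin = 15, seed = 2))
  gs <- guild_summary(variance_partition(fit))
  chem <- gs$proportion[gs$part == "occurrence" & gs$group == "chemical"]
  phys <- gs$proportion[gs$part == "occurrence" & gs$group == "physical"]
  ratio <- chem / phys
  expect_gt(ratio, 2 * 0.7)
  expect_lt(ratio, 2 * 1.3)
})
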