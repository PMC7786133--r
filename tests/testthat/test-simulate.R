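test_that("covariate simulation is deterministic and respects the survey design", {
  cfg <- simulation_config(seed = 7)
  md1 <- simulate_covariates(cfg)
  md2 <- simulate_covariates(cfg)
  expect_identical(md1, md2)
  expect_equal(nrow(md1), 118)
  expect_true(all(md1$ph > 0 & md1$ph < 14))
  expect_true(all(md1$water >= 0 & md1$water <= 100))

  exact <- simulate_covariates(simulation_config(exact_design = TRUE, seed = 7))
  expect_equal(as.integer(table(exact$tree_species)[c("beech", "fir", "spruce")]),
               c(39L, 36L, 43L))
  expect_equal(as.integer(table(exact$decay_class)), c(21L, 39L, 36L, 22L))

  expect_error(simulation_config(n_samples = 0), "positive")
  expect_error(simulate_covariates(
    simulation_config(n_samples = 50, exact_design = TRUE)), "118")
})

test_that("simulated tables are reproducible with row sums equal to depths", {
  cfg <- simulation_config(n_samples = 30, n_species = c(fungi = 12, bacteria = 9),
                           n_factors = 2, seed = 5)
  sim1 <- simulate_community(cfg)
  sim2 <- simulate_community(cfg)
  expect_identical(sim1$tables$fungi$counts, sim2$tables$fungi$counts)
  expect_identical(sim1$tables$bacteria$counts, sim2$tables$bacteria$counts)
  for (g in c("fungi", "bacteria")) {
    expect_equal(unname(rowSums(sim1$tables[[g]]$counts)),
                 unname(sim1$meta[[paste0("reads_", g)]]))
  }
})

test_that("zero loadings imply an identity true association matrix", {
  cfg <- simulation_config(n_samples = 20, n_species = c(fungi = 5, bacteria = 5),
                           loading_scale = c(fungi = 0, bacteria = 0),
                           n_factors = 3, seed = 2)
  sim <- simulate_community(cfg)
  expect_equal(sim$truth$R_occurrence, diag(10), ignore_attr = TRUE)
})

test_that("prevalence converges to the probit of the linear predictor without factors", {
  # no covariate or factor variation: prevalence_j -> Phi(intercept_j)
  cfg <- simulation_config(n_samples = 1500, n_species = c(fungi = 20, bacteria = 5),
                           n_factors = 0, niche_scale = c(fungi = 0, bacteria = 0),
                           loading_scale = c(fungi = 0, bacteria = 0),
                           depth_effect = 0, seed = 31)
  sim <- simulate_community(cfg)
  prev <- colMeans(sim$tables$fungi$counts > 0)
  expected <- pnorm(sim$truth$beta$fungi$occurrence["(Intercept)", ])
  expect_lt(max(abs(prev - expected)), 0.05)
})

test_that("true R matches the residual correlation of simulated liabilities", {
  cfg <- simulation_config(n_samples = 10, n_species = c(fungi = 6, bacteria = 6),
                           n_factors = 2, seed = 13)
  sim <- simulate_community(cfg)
  lam <- rbind(sim$truth$lambda$fungi$occurrence,
               sim$truth$lambda$bacteria$occurrence)
  set.seed(99)
  eta <- matrix(rnorm(10000 * 2), 10000, 2)
  liab <- eta %*% t(lam) + matrix(rnorm(10000 * 12), 10000, 12)
  emp <- cor(liab)
  expect_lt(max(abs(emp - sim$truth$R_occurrence)), 0.05)
})

test_that("the asymmetric scenario gives bacteria the larger random-effect share", {
  cfg <- make_asymmetric_scenario(simulation_config(
    n_samples = 60, n_species = c(fungi = 15, bacteria = 15), seed = 8))
  sim <- simulate_community(cfg)
  sh <- true_variance_shares(sim$truth)
  mean_share <- function(g) mean(sh$random_share[sh$guild == g])
  expect_gt(mean_share("bacteria"), mean_share("fungi") + 0.2)

  # symmetric override: equal generative shares in expectation
  sym <- simulation_config(n_samples = 60,
                           n_species = c(fungi = 40, bacteria = 40), seed = 8)
  shs <- true_variance_shares(simulate_community(sym)$truth)
  expect_lt(abs(mean(shs$random_share[shs$guild == "bacteria"]) -
                  mean(shs$random_share[shs$guild == "fungi"])), 0.1)
})

test_that("a strong positive niche coefficient raises prevalence along its gradient", {
  # plant a large pH effect by reusing the generator's machinery: simulate,
  # then check the sign of the fitted occurrence trend for species whose true
  # pH coefficient is large
  cfg <- simulation_config(n_samples = 1000, n_species = c(fungi = 30, bacteria = 2),
                           n_factors = 0, niche_scale = c(fungi = 2, bacteria = 0.1),
                           seed = 17)
  sim <- simulate_community(cfg)
  bt <- sim$truth$beta$fungi$occurrence["ph", ]
  strong <- which(bt > quantile(bt, 0.8))
  ph <- sim$meta$ph
  for (j in strong) {
    y <- sim$tables$fungi$counts[, j] > 0
    trend <- coef(glm(y ~ ph, family = binomial()))["ph"]
    expect_gt(trend, 0)
  }
})
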