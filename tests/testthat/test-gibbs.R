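test_that("MCMC bookkeeping yields chains x (iter - burn) / thin retained draws", {
  ctl <- mcmc_control(n_chains = 4, n_iter = 150000, n_burn = 50000,
                      thin = 100)
  expect_equal(n_retained(ctl, total = FALSE), 1000)
  expect_equal(n_retained(ctl), 4000)
  expect_error(mcmc_control(n_iter = 100, n_burn = 100), "smaller")
  expect_error(mcmc_control(n_iter = 100, n_burn = 37, thin = 10), "divide")
})

test_that("a rank-deficient design is rejected before sampling", {
  ct <- random_table(n = 10, S = 4, seed = 1)
  hr <- assemble_hurdle_response(ct)
  X <- cbind("(Intercept)" = 1, a = 1:10, b = 2 * (1:10))
  rownames(X) <- hr$sample_ids
  d <- fake_design(X, c(a = "chemical", b = "chemical"))
  expect_error(fit_jsdm(hr, d, n_factors = 0,
                        mcmc = mcmc_control(n_chains = 1, n_iter = 20,
                                            n_burn = 10, thin = 1)),
               "rank deficient")
})

test_that("misaligned samples between response and design are rejected", {
  ct <- random_table(n = 10, S = 4, seed = 1)
  hr <- assemble_hurdle_response(ct)
  X <- cbind("(Intercept)" = 1, a = rnorm(10))
  rownames(X) <- paste0("zz", 1:10)
  d <- fake_design(X, c(a = "chemical"))
  expect_error(fit_jsdm(hr, d, n_factors = 0), "not aligned")
})

test_that("fitting is deterministic under the master seed", {
  ct <- random_table(n = 12, S = 4, seed = 6, lambda_mean = 4)
  hr <- assemble_hurdle_response(ct)
  set.seed(2); X <- cbind("(Intercept)" = 1, a = rnorm(12))
  rownames(X) <- hr$sample_ids
  d <- fake_design(X, c(a = "chemical"))
  ctl <- mcmc_control(n_chains = 2, n_iter = 60, n_burn = 20, thin = 4,
                      seed = 77)
  f1 <- fit_jsdm(hr, d, n_factors = 1, mcmc = ctl)
  f2 <- fit_jsdm(hr, d, n_factors = 1, mcmc = ctl)
  expect_identical(f1$chains[[1]]$beta, f2$chains[[1]]$beta)
  expect_identical(f1$chains[[2]]$lambda, f2$chains[[2]]$lambda)
})

test_that("permuting the sample order leaves posterior summaries unchanged", {
  ct <- random_table(n = 16, S = 4, seed = 8, lambda_mean = 5)
  hr <- assemble_hurdle_response(ct)
  set.seed(3); xcov <- rnorm(16)
  make_d <- function(ids, x) {
    X <- cbind("(Intercept)" = 1, a = x)
    rownames(X) <- ids
    fake_design(X, c(a = "chemical"))
  }
  ctl <- mcmc_control(n_chains = 1, n_iter = 800, n_burn = 400, thin = 4,
                      seed = 5)
  fit1 <- fit_jsdm(hr, make_d(hr$sample_ids, xcov), n_factors = 0, mcmc = ctl)
  perm <- sample(16)
  hr_p <- hr
  hr_p$pa <- hr$pa[perm, ]; hr_p$abund <- hr$abund[perm, ]
  hr_p$sample_ids <- hr$sample_ids[perm]
  fit2 <- fit_jsdm(hr_p, make_d(hr_p$sample_ids, xcov[perm]), n_factors = 0,
                   mcmc = ctl)
  b1 <- colMeans(param_draws <- crossguild:::param_draws(fit1, "beta"))
  b2 <- colMeans(crossguild:::param_draws(fit2, "beta"))
  se <- apply(crossguild:::param_draws(fit1, "beta"), 2, sd) / sqrt(50)
  expect_lt(max(abs(b1 - b2) / (se * sqrt(2))), 6)
})

test_that("posterior draws persist to flat binary arrays and reload exactly", {
  fx <- small_sim_fit()
  dir <- withr::local_tempdir()
  save_fit_draws(fx$fit, dir)
  expect_true(file.exists(file.path(dir, "index.json")))
  back <- load_fit_draws(dir)
  expect_equal(back$chains[[1]]$beta, fx$fit$chains[[1]]$beta,
               ignore_attr = TRUE)
  expect_equal(back$chains[[2]]$sigma2, fx$fit$chains[[2]]$sigma2,
               ignore_attr = TRUE)
})

test_that("tidy and glance expose posterior summaries in standard form", {
  fx <- small_sim_fit()
  td <- tidy(fx$fit, "beta")
  expect_true(all(c("otu_id", "guild", "part", "term", "estimate",
                    "std.error", "conf.low", "conf.high") %in% names(td)))
  p <- ncol(fx$fit$designs[[1]]$values)
  expect_equal(nrow(td), 2 * nrow(fx$fit$species) * p)
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  # spot-check one entry against the raw draws
  dr <- crossguild:::param_draws(fx$fit, "beta")
  expect_equal(td$estimate[1], mean(dr[, 1]))

  gl <- glance(fx$fit)
  expect_equal(gl$n_draws, n_retained(fx$fit$mcmc))
  expect_equal(gl$n_species, 16)
  expect_true(gl$max_psrf_beta > 0.9)

  ts <- tidy(fx$fit, "sigma2")
  expect_equal(nrow(ts), 16)
  expect_true(all(ts$estimate > 0))
})
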