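test_that("AUC follows the Mann-Whitney formulation with half-weight ties", {
  expect_equal(compute_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(compute_auc(c(0, 1), c(0.5, 0.5)), 0.5)
  # brute force over the 4 positive-negative pairs: 3 wins, no ties
  expect_equal(compute_auc(c(0, 1, 0, 1), c(0.4, 0.3, 0.2, 0.6)), 0.75)
  expect_equal(auc_bruteforce(c(0, 1, 0, 1), c(0.4, 0.3, 0.2, 0.6)), 0.75)
  expect_message(out <- compute_auc(c(1, 1), c(0.2, 0.8)), "single-class")
  expect_true(is.na(out))
})

test_that("AUC equals brute-force pair counting on vectors up to length 50", {
  set.seed(123)
  for (r in 1:25) {
    n <- sample(3:50, 1)
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    expect_equal(compute_auc(labels, scores),
                 auc_bruteforce(labels, scores))
  }
})

test_that("AUC agrees with the reference ROC implementation", {
  set.seed(7)
  labels <- rbinom(40, 1, 0.4); labels[1:2] <- c(0, 1)
  scores <- rnorm(40)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(compute_auc(labels, scores), ref)
})

test_that("R2 is one for perfect fit, zero for the mean, negative when worse", {
  obs <- c(1, 2, 3)
  expect_equal(compute_r2(obs, obs), 1)
  expect_equal(compute_r2(obs, rep(2, 3)), 0)
  expect_equal(compute_r2(obs, c(3, 2, 1)), -3)
  expect_error(compute_r2(c(1, 2), c(1, 2)), "at least 3")
})

test_that("zero loadings make unconditional predictions purely environmental", {
  n <- 12
  X <- cbind("(Intercept)" = 1, x = seq(-2, 2, length.out = n))
  rownames(X) <- paste0("s", 1:n)
  d <- fake_design(X, c(x = "chemical"))
  beta <- matrix(c(0.3, 1, 0.1, -0.5,     # occurrence part, 2 species
                   0, 0.8, 0.2, 0.4), 2, 4)
  fit <- make_fake_fit(beta = beta, lambda = matrix(0, 4, 1),
                       sigma2 = c(1, 1), eta = matrix(0, n, 1),
                       designs = list(fungi = d), guild = c("fungi", "fungi"))
  p <- predict_unconditional(fit, list(fungi = d))
  expect_equal(p$occurrence, pnorm(X %*% beta[, 1:2]), ignore_attr = TRUE)
  expect_equal(p$abundance, X %*% beta[, 3:4], ignore_attr = TRUE)
})

test_that("factor variance flattens unconditional presence probabilities", {
  n <- 6
  X <- cbind("(Intercept)" = rep(1, n))
  rownames(X) <- paste0("s", 1:n)
  d <- fake_design(X, stats::setNames(character(0), character(0)))
  beta <- matrix(c(1, 1, 0, 0), 1, 4)
  fit <- make_fake_fit(beta = beta, lambda = matrix(c(2, 0, 0, 0), 4, 1),
                       sigma2 = c(1, 1), eta = matrix(0, n, 1),
                       designs = list(fungi = d), guild = c("fungi", "fungi"))
  p <- predict_unconditional(fit, list(fungi = d))
  # species 1 loads on the factor: Phi(1 / sqrt(1 + 4)); species 2: Phi(1)
  expect_equal(p$occurrence[1, ], c(pnorm(1 / sqrt(5)), pnorm(1)),
               ignore_attr = TRUE)
})

test_that("an empty conditioning set reproduces unconditional predictions", {
  fx <- small_sim_fit()
  p1 <- predict_unconditional(fx$fit, fx$designs)
  p2 <- predict_conditional(fx$fit, fx$designs, NULL, "fungi")
  expect_identical(p1$occurrence, p2$occurrence)
})

test_that("conditioning on a zero-loading guild changes nothing beyond Monte-Carlo error", {
  fx <- small_sim_fit()
  fit <- fx$fit
  # zero out the bacterial loadings in every draw: no information can flow
  S <- nrow(fit$species)
  bcols <- which(fit$species$guild == "bacteria")
  for (ch in seq_along(fit$chains)) {
    fit$chains[[ch]]$lambda[bcols, , ] <- 0
    fit$chains[[ch]]$lambda[S + bcols, , ] <- 0
  }
  pu <- predict_unconditional(fit, fx$designs)
  pc <- predict_conditional(fit, fx$designs,
                            list(bacteria = fx$sim$tables$bacteria), "fungi",
                            n_outer = n_retained(fit$mcmc), n_inner = 60,
                            n_inner_burn = 20, seed = 3)
  fcols <- which(fit$species$guild == "fungi")
  expect_lt(max(abs(pu$occurrence[, fcols] - pc$occurrence[, fcols])), 0.06)
})

test_that("conditioning on a high-loading guild recovers the latent factor scores", {
  # perfect-information limit: one factor, conditioning species with large
  # loadings pin eta near its true value, so focal predictions approach the
  # oracle that knows eta
  n <- 40; S_nf <- 12
  set.seed(44)
  eta_true <- matrix(rnorm(n), n, 1)
  X <- cbind("(Intercept)" = rep(1, n))
  rownames(X) <- paste0("s", 1:n)
  d <- fake_design(X, stats::setNames(character(0), character(0)))
  lam_nf <- matrix(3, S_nf, 1)
  lam_f <- matrix(1.5, 1, 1)
  # non-focal observed abundances: tight around eta * lambda
  ab_nf <- eta_true %*% t(lam_nf) + matrix(rnorm(n * S_nf, 0, 0.2), n, S_nf)
  cnt_nf <- matrix(pmax(1L, as.integer(round(exp(ab_nf - min(ab_nf) + 2.5)))),
                   n, S_nf, dimnames = list(rownames(X), paste0("bacteria_sp", 1:S_nf)))
  guild <- c("fungi", rep("bacteria", S_nf))
  lam <- rbind(lam_f, lam_nf)
  fit <- make_fake_fit(beta = matrix(0, 1, 2 * (S_nf + 1)),
                       lambda = rbind(lam, lam),
                       sigma2 = c(1, rep(0.04, S_nf)),
                       eta = matrix(0, n, 1),
                       designs = list(fungi = d, bacteria = d),
                       guild = guild, n_draws = 2)
  # conditioning table uses the fit's unit scaling, so observed std
  # abundances equal log counts; rebuild them so they carry the eta signal
  fit$scaling$bacteria$mean <- colMeans(log(cnt_nf))
  fit$scaling$bacteria$sd <- apply(log(cnt_nf), 2, sd)
  ct_nf <- community_table(cnt_nf, "bacteria")
  pc <- predict_conditional(fit, list(fungi = d, bacteria = d),
                            list(bacteria = ct_nf), "fungi",
                            n_outer = 2, n_inner = 100, n_inner_burn = 30,
                            seed = 5)
  # oracle: eta known exactly (up to the standardization of the conditioning
  # data the direction of eta is what matters)
  pred <- pc$occurrence[, 1]
  eta_hat <- qnorm(pmin(pmax(pred, 1e-6), 1 - 1e-6)) / lam_f[1, 1]
  expect_gt(cor(eta_hat, eta_true[, 1]), 0.9)
})

test_that("explanatory predictions use the fitted factor scores", {
  fx <- small_sim_fit()
  pe <- predict_explanatory(fx$fit)
  pu <- predict_unconditional(fx$fit, fx$designs)
  pa <- do.call(cbind, lapply(fx$resp, function(r) r$pa))
  # in-sample predictions should separate presences better than covariate-only
  auc_e <- mean(vapply(seq_len(ncol(pa)), function(j)
    auc_quiet_or_na(pa[, j], pe$occurrence[, j]), 1), na.rm = TRUE)
  auc_u <- mean(vapply(seq_len(ncol(pa)), function(j)
    auc_quiet_or_na(pa[, j], pu$occurrence[, j]), 1), na.rm = TRUE)
  expect_gt(auc_e, auc_u)
})
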