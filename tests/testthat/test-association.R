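# helper: fake fit with given loadings (occurrence part) on a trivial design
net_fixture <- function(lam_occ, lam_ab = lam_occ, sigma2 = NULL,
                        guild = NULL, n_draws = 4) {
  S <- nrow(lam_occ)
  guild <- guild %||% rep(c("fungi", "bacteria"), length.out = S)
  n <- 6
  X <- cbind("(Intercept)" = rep(1, n))
  rownames(X) <- paste0("s", 1:n)
  designs <- lapply(stats::setNames(unique(guild), unique(guild)),
                    function(g) fake_design(X, stats::setNames(character(0), character(0)), g))
  make_fake_fit(beta = matrix(0, 1, 2 * S),
                lambda = rbind(lam_occ, lam_ab),
                sigma2 = sigma2 %||% rep(1, S),
                eta = matrix(0, n, ncol(lam_occ)),
                designs = designs, guild = guild, n_draws = n_draws)
}

test_that("zero loadings give the identity network with no supported edges", {
  fit <- net_fixture(matrix(0, 4, 2))
  net <- compute_association_network(fit, 0.95, "occurrence")
  expect_equal(net$R_mean, diag(4), ignore_attr = TRUE)
  expect_equal(sum(net$edges$supported), 0)
})

test_that("identical unit single-factor loadings give residual correlation 1/2", {
  fit <- net_fixture(matrix(1, 2, 1), guild = c("fungi", "bacteria"))
  net <- compute_association_network(fit, 0.95, "occurrence")
  # lambda^2 / (lambda^2 + 1) = 0.5 exactly for the probit part
  expect_equal(net$R_mean[1, 2], 0.5)
  expect_equal(net$edges$scope, "between_guild")
})

test_that("the abundance-part correlation is invariant to common rescaling", {
  lam <- matrix(c(1.2, -0.4, 0.7, 0.1, 0.5, -0.9), 3, 2)
  f1 <- net_fixture(lam, lam, sigma2 = c(0.5, 1.5, 0.8), guild = rep("fungi", 3))
  f2 <- net_fixture(lam * 3, lam * 3, sigma2 = 9 * c(0.5, 1.5, 0.8),
                    guild = rep("fungi", 3))
  n1 <- compute_association_network(f1, 0.95, "abundance")
  n2 <- compute_association_network(f2, 0.95, "abundance")
  expect_equal(n1$R_mean, n2$R_mean)
})

test_that("per-draw R matrices are symmetric, unit-diagonal and PSD", {
  fx <- small_sim_fit()
  S <- nrow(fx$fit$species)
  for (d in c(1, 5, 10)) {
    lam <- matrix(fx$fit$chains[[1]]$lambda[, , d], 2 * S)
    R <- cov2cor(tcrossprod(lam[1:S, ]) + diag(S))
    expect_equal(R, t(R))
    expect_equal(diag(R), rep(1, S))
    expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
  net <- compute_association_network(fx$fit, 0.95, "occurrence")
  expect_equal(net$R_mean, t(net$R_mean))
  expect_true(all(abs(net$R_mean) <= 1 + 1e-12))
  # support bookkeeping: P(positive) + P(negative) = 1
  expect_true(all(net$support >= 0 & net$support <= 1))
})

test_that("network contrast classifies retained, flipped and lost edges", {
  lam <- matrix(c(2, 2, -2, 0), 4, 1)
  fit_null <- net_fixture(lam, guild = rep(c("fungi", "bacteria"), 2))
  net_null <- compute_association_network(fit_null, 0.9, "occurrence")

  # identical networks: everything retained
  ctr_same <- compare_networks(net_null, net_null)
  expect_true(all(ctr_same$edges$status == "retained"))

  # zero-loading full model: everything lost
  fit_zero <- net_fixture(matrix(0, 4, 1), guild = rep(c("fungi", "bacteria"), 2))
  net_zero <- compute_association_network(fit_zero, 0.9, "occurrence")
  ctr_lost <- compare_networks(net_null, net_zero)
  expect_true(all(ctr_lost$edges$status == "lost"))
  s <- ctr_lost$summary
  expect_equal(sum(s$n[s$status == "lost"]), nrow(ctr_lost$edges))

  # sign flip detected
  lam_flip <- lam; lam_flip[2] <- -2
  net_flip <- compute_association_network(
    net_fixture(lam_flip, guild = rep(c("fungi", "bacteria"), 2)), 0.9,
    "occurrence")
  ctr_flip <- compare_networks(net_null, net_flip)
  expect_true("sign_flipped" %in% ctr_flip$edges$status)
})

test_that("edge lists export with the expected columns", {
  fit <- net_fixture(matrix(c(2, 2), 2, 1), guild = c("fungi", "bacteria"))
  net <- compute_association_network(fit, 0.9, "occurrence")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(names(back), c("source_otu", "target_otu",
                              "posterior_mean_correlation", "support"))
  expect_equal(nrow(back), 1)
})

test_that("fewer than two species is an error", {
  fit <- net_fixture(matrix(1, 2, 1), guild = c("fungi", "bacteria"))
  fit$species <- fit$species[1, ]
  expect_error(compute_association_network(fit), "at least 2")
})
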