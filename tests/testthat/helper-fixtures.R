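# Shared fixture builders: everything is generated in code at test time.

toy_counts <- function() {
  m <- matrix(c(3L, 0L,
                1L, 5L), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("otu1", "otu2")))
  m
}

toy_metadata <- function(n_samples = 6, seed = 1) {
  set.seed(seed)
  k <- n_samples
  tibble::tibble(
    sample_id = paste0("s", seq_len(k)),
    water = seq(30, 60, length.out = k),
    ph = seq(4, 5.5, length.out = k),
    c = rep(48, k),
    n = seq(0.1, 0.5, length.out = k),
    lignin = seq(20, 35, length.out = k),
    tree_species = rep(c("beech", "spruce", "fir"), length.out = k),
    decay_class = rep(c("<5", "5-15", "16-38", ">38"), length.out = k),
    dbh = seq(35, 90, length.out = k),
    reads_fungi = seq(4000, 9000, length.out = k),
    reads_bacteria = seq(3000, 8000, length.out = k))
}

random_table <- function(n = 10, S = 6, guild = "fungi", seed = 1,
                         lambda_mean = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * S, lambda_mean), n, S,
              dimnames = list(paste0("s", seq_len(n)),
                              paste0(guild, "_otu", seq_len(S))))
  community_table(m, guild)
}

# a hand-built jsdm_fit whose "posterior" is a fixed set of draws; used to
# test the deterministic post-processing (networks, variance partition,
# predictions) independently of the sampler
make_fake_fit <- function(beta, lambda, sigma2, eta, designs, guild,
                          n_draws = 4, sample_ids = NULL) {
  S2 <- nrow(lambda)
  S <- S2 / 2
  K <- ncol(lambda)
  p <- nrow(beta)
  n <- nrow(eta)
  otu_ids <- paste0(guild, "_sp", stats::ave(seq_len(S), guild, FUN = seq_along))
  chain <- list(
    beta = array(rep(beta, n_draws), c(p, S2, n_draws)),
    lambda = array(rep(lambda, n_draws), c(S2, max(K, 1), n_draws)),
    eta = array(rep(eta, n_draws), c(n, max(K, 1), n_draws)),
    sigma2 = matrix(rep(sigma2, n_draws), S, n_draws),
    n_draws = as.integer(n_draws))
  guilds <- unique(guild)
  scaling <- lapply(stats::setNames(guilds, guilds), function(g) {
    idx <- which(guild == g)
    tibble::tibble(otu_id = otu_ids[idx], mean = 0, sd = 1,
                   n_present = n, degenerate = FALSE)
  })
  structure(
    list(chains = list(chain),
         species = tibble::tibble(otu_id = otu_ids, guild = guild),
         sample_ids = sample_ids %||% paste0("s", seq_len(n)),
         designs = designs, scaling = scaling,
         priors = jsdm_priors(), mcmc = mcmc_control(seed = 1L),
         n_factors = K, guilds = guilds),
    class = "jsdm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal one-guild design with explicit group map
fake_design <- function(X, group_map, guild = "fungi", model = "full") {
  structure(list(values = X, group_map = group_map,
                 encoding = list(), model = model, guild = guild),
            class = "design_matrix")
}

auc_quiet_or_na <- function(labels, scores) {
  suppressMessages(compute_auc(labels, scores))
}

# brute-force AUC over all positive-negative pairs (independent oracle)
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# small simulated fit shared by several deterministic post-processing tests;
# cached so the sampler runs once per test session
.fixture_env <- new.env(parent = emptyenv())
small_sim_fit <- function() {
  if (!is.null(.fixture_env$fit)) return(.fixture_env$fit)
  cfg <- simulation_config(n_samples = 50, n_species = c(fungi = 8, bacteria = 8),
                           n_factors = 2, seed = 421)
  sim <- simulate_community(cfg)
  resp <- lapply(sim$tables, assemble_hurdle_response)
  des <- lapply(stats::setNames(names(sim$tables), names(sim$tables)),
                function(g) build_design_matrix(sim$meta, "full", g))
  fit <- fit_jsdm(resp, des, n_factors = 2,
                  mcmc = mcmc_control(n_chains = 2, n_iter = 600, n_burn = 300,
                                      thin = 10, seed = 5))
  .fixture_env$fit <- list(fit = fit, sim = sim, resp = resp, designs = des)
  .fixture_env$fit
}
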