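test_that("build_model resolves phi and the residual parameter count", {
  tab <- data.frame(genotype = c("G1", "G2"), block = "B1",
                    harvest = c("H1", "H1"), yield = c(20, 38))
  tab$block <- c("B1", "B2")
  spec <- build_model(tab, bayes_config("homogeneous"))
  expect_equal(spec$phi, 380)

  sim <- simulate_trial(trial_design(), truth_preset_heterogeneous(),
                        seed = 2)
  cfg <- bayes_config("diagonal", n_chains = 2, n_iterations = 50, seed = 1)
  dr <- fit_bayes(sim$table, cfg)
  expect_equal(ncol(dr$sigma_e), 12L)
  dr2 <- fit_bayes(sim$table, bayes_config("homogeneous", n_chains = 2,
                                           n_iterations = 50, seed = 1))
  expect_equal(ncol(dr2$sigma_e), 1L)

  expect_error(build_model(tab[0, ], bayes_config()), "empty")
})

test_that("retained draw counts follow chains, burn-in and thinning", {
  sim <- small_sim()
  cfg <- bayes_config("homogeneous", n_chains = 3, n_iterations = 10,
                      burn_in_fraction = 0.5, thin = 2, seed = 1)
  dr <- fit_bayes(sim$table, cfg)
  expect_equal(n_draws(dr), 3L * floor(10 * 0.5 / 2))
  expect_equal(as.integer(table(dr$chain_index)), rep(2L, 3))
  # default configuration arithmetic: 4 chains x 4000 iters, 50% burn-in
  expect_equal(harvestprob:::n_retained(bayes_config()) * 4L, 8000L)
})

test_that("log_posterior matches a hand-summed toy evaluation", {
  tab <- data.frame(genotype = c("G1", "G2", "G1", "G2"),
                    block = c("B1", "B1", "B2", "B2"),
                    harvest = c("H1", "H1", "H2", "H2"),
                    yield = c(10, 12, 9, 13))
  spec <- build_model(tab, bayes_config("diagonal", phi = 50))
  pt <- list(mu = 10.5, g = c(-0.5, 0.8), r = c(0.1, -0.2), h = c(0.3, -0.1),
             gh = matrix(c(0.2, -0.3, 0.1, 0.4), 2, 2),
             p = matrix(c(0.05, -0.05, 0.1, 0), 2, 2),
             sigma_mu = 5, sigma_g = 1.2, sigma_r = 0.8, sigma_h = 1.5,
             sigma_gh = 0.6, sigma_p = 0.4, sigma_e = c(1.1, 2.2))
  got <- log_posterior(spec, tab, pt)

  # independent term-by-term sum
  i <- c(1, 2, 1, 2); j <- c(1, 1, 2, 2); k <- c(1, 1, 2, 2)
  eta <- pt$mu + pt$g[i] + pt$r[j] + pt$h[k] +
    pt$gh[cbind(i, k)] + pt$p[cbind(i, j)]
  ll <- sum(dnorm(tab$yield, eta, pt$sigma_e[k], log = TRUE))
  pr <- dnorm(pt$mu, 0, pt$sigma_mu, log = TRUE) +
    sum(dnorm(pt$g, 0, pt$sigma_g, log = TRUE)) +
    sum(dnorm(pt$r, 0, pt$sigma_r, log = TRUE)) +
    sum(dnorm(pt$h, 0, pt$sigma_h, log = TRUE)) +
    sum(dnorm(pt$gh, 0, pt$sigma_gh, log = TRUE)) +
    sum(dnorm(pt$p, 0, pt$sigma_p, log = TRUE)) +
    sum(log(2) + dcauchy(c(pt$sigma_mu, pt$sigma_g, pt$sigma_r, pt$sigma_h,
                           pt$sigma_gh, pt$sigma_p, pt$sigma_e),
                         0, 50, log = TRUE))
  expect_equal(as.numeric(got), ll + pr, tolerance = 1e-12)
  expect_equal(unname(attr(got, "parts")["loglik"]), ll, tolerance = 1e-12)

  # invariant to record order
  perm <- c(3, 1, 4, 2)
  got2 <- log_posterior(spec, tab[perm, ], pt)
  expect_equal(as.numeric(got2), as.numeric(got), tolerance = 1e-12)

  # doubling the residual scale with zero residuals costs n * log(2)
  tab0 <- tab; tab0$yield <- eta
  spec0 <- build_model(tab0, bayes_config("homogeneous", phi = 50))
  pt0 <- pt; pt0$sigma_e <- 1.5
  pt0b <- pt0; pt0b$sigma_e <- 3
  d_ll <- attr(log_posterior(spec0, tab0, pt0b), "parts")["loglik"] -
    attr(log_posterior(spec0, tab0, pt0), "parts")["loglik"]
  expect_equal(unname(d_ll), -4 * log(2), tolerance = 1e-12)

  pt_bad <- pt; pt_bad$sigma_g <- 0
  expect_error(log_posterior(spec, tab, pt_bad), "nonpositive")
})

test_that("pointwise log-likelihood is consistent with log_posterior", {
  sim <- small_sim()
  cfg <- bayes_config("diagonal", n_chains = 2, n_iterations = 100, seed = 8)
  dr <- fit_bayes(sim$table, cfg)
  ll <- pointwise_loglik(dr, sim$table)
  expect_equal(dim(ll), c(n_draws(dr), nrow(sim$table)))
  for (s in c(1L, 37L, n_draws(dr))) {
    lp <- log_posterior(dr$spec, sim$table, harvestprob:::draw_point(dr, s))
    expect_equal(sum(ll[s, ]), unname(attr(lp, "parts")["loglik"]),
                 tolerance = 1e-10)
  }
})

test_that("a record at its linear predictor attains the density mode", {
  tab <- data.frame(genotype = "G1", block = "B1", harvest = "H1", yield = 5)
  spec <- build_model(tab, bayes_config("homogeneous", phi = 100))
  dr <- structure(list(mu = 5, g = NULL, gh = NULL,
                       sigma_e = matrix(2, 1, 1), chain_index = 1L,
                       labels = spec$labels, spec = spec,
                       effects = character(0)),
                  class = "posterior_draws")
  ll <- pointwise_loglik(dr, tab)
  expect_equal(ll[1, 1], -log(2 * sqrt(2 * pi)), tolerance = 1e-12)
})

test_that("posterior predictive replicates behave and are seeded", {
  sim <- small_sim()
  cfg <- bayes_config("homogeneous", n_chains = 2, n_iterations = 200,
                      seed = 8)
  dr <- fit_bayes(sim$table, cfg)
  y1 <- sample_posterior_predictive(dr, sim$table, 50, seed = 5)
  y2 <- sample_posterior_predictive(dr, sim$table, 50, seed = 5)
  expect_identical(y1, y2)
  y3 <- sample_posterior_predictive(dr, sim$table, 50, seed = 6)
  expect_false(identical(y1, y3))
  expect_error(sample_posterior_predictive(dr, sim$table, n_draws(dr) + 1),
               "exceeds")

  # residual scale forced to ~0: replicates equal the fitted means
  dr0 <- dr
  dr0$sigma_e <- matrix(1e-12, n_draws(dr), 1)
  yr <- sample_posterior_predictive(dr0, sim$table, n_draws(dr), seed = 1)
  lp <- harvestprob:::linear_predictor_matrix(dr0, sim$table)
  expect_equal(yr, lp, tolerance = 1e-9, ignore_attr = TRUE)

  # PPC calibration: the observed mean sits well inside the replicate means
  yr2 <- sample_posterior_predictive(dr, sim$table, 200, seed = 2)
  mm <- rowMeans(yr2)
  expect_gt(mean(sim$table$yield), quantile(mm, 0.005))
  expect_lt(mean(sim$table$yield), quantile(mm, 0.995))
})

test_that("the half-Cauchy augmentation reproduces the half-Cauchy law", {
  set.seed(31)
  x <- rhalfcauchy_mix(4000, phi = 3)
  ks <- suppressWarnings(
    ks.test(x, function(q) 2 * (pcauchy(q, 0, 3) - 0.5))
  )
  expect_gt(ks$p.value, 0.001)
})

test_that("genotype relabelling carries through to the draws", {
  sim <- small_sim()
  cfg <- bayes_config("homogeneous", n_chains = 2, n_iterations = 100,
                      seed = 12)
  dr <- fit_bayes(sim$table, cfg)

  relab <- setNames(sprintf("X%d", 8:1), sprintf("G%d", 1:8))
  tab2 <- sim$table
  lev <- levels(tab2$genotype)
  levels(tab2$genotype) <- unname(relab[lev])
  dr2 <- fit_bayes(tab2, cfg)
  expect_identical(unname(dr2$g), unname(dr$g))
  expect_identical(colnames(dr2$g), unname(relab[colnames(dr$g)]))
})

test_that("reduced models drop the corresponding parameters", {
  sim <- small_sim()
  cfg <- bayes_config("homogeneous", n_chains = 1, n_iterations = 40,
                      seed = 3)
  dr <- fit_bayes(sim$table, cfg, effects = c("g", "h"))
  expect_null(dr$gh)
  expect_null(dr$p)
  expect_null(dr$sigma_gh)
  expect_true(all(c("sigma_g", "sigma_h", "sigma_mu") %in% names(dr)))
})
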