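balanced_single_harvest <- function(seed = 19, I = 12, J = 4) {
  sim <- simulate_trial(trial_design(I, J, 2, grand_mean = 25),
                        variance_truth(3, 0, 0, 1, 0, 2), seed = seed)
  subset_harvests(sim$table, "H1")
}

test_that("REML equals the ANOVA moment estimator on balanced data", {
  tab <- balanced_single_harvest()
  fit <- reml_fit(tab, "homogeneous")
  av <- anova(aov(yield ~ block + genotype, data = tab))
  msg <- av["genotype", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  J <- nlevels(droplevels(tab$block))
  expect_lt(abs(fit$var_g - (msg - mse) / J), 1e-6)
  expect_lt(abs(fit$var_e - mse), 1e-6)
})

test_that("BLUPs shrink genotype means toward zero on balanced data", {
  tab <- balanced_single_harvest(seed = 31)
  fit <- reml_fit(tab, "homogeneous")
  gm <- tapply(tab$yield, droplevels(tab$genotype), mean)
  dev <- gm - mean(gm)
  expect_true(all(abs(fit$blup_g) <= abs(dev[names(fit$blup_g)]) + 1e-10))
  expect_gt(cor(fit$blup_g, dev[names(fit$blup_g)]), 0.999)
})

test_that("the diagonal REML fit tracks heterogeneous residual truth", {
  sim <- simulate_trial(trial_design(), truth_preset_heterogeneous(),
                        seed = 11)
  fit <- reml_fit(sim$table, "diagonal")
  expect_true(fit$converged)
  expect_equal(length(fit$var_e), 12L)
  truth <- truth_preset_heterogeneous()$var_e
  # per-harvest residual variances track the truth over 2.5 orders of magnitude
  expect_gt(cor(log(fit$var_e), log(truth)), 0.98)
  expect_gt(fit$var_g, 0)
  expect_equal(dim(fit$blup_gh), c(24L, 12L))
  # the REML fit is invariant to the fixed-effect contrast choice: variance
  # components match exactly and the restricted likelihood shifts only by
  # the parameterization constant, so LRT statistics are unchanged
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit2 <- reml_fit(sim$table, "diagonal")
  expect_equal(fit2$var_g, fit$var_g, tolerance = 1e-6)
  expect_equal(fit2$var_gh, fit$var_gh, tolerance = 1e-6)
  expect_equal(unname(fit2$var_e), unname(fit$var_e), tolerance = 1e-5)
})

test_that("variance simulated as zero is estimated at the boundary", {
  sims <- vapply(1:5, function(r) {
    sim <- simulate_trial(trial_design(12, 3, 4),
                          variance_truth(0, 0.3, 0.1, 0.5, 4, 2),
                          seed = 600 + r)
    reml_fit(sim$table, "homogeneous")$var_g
  }, 0)
  expect_lt(median(sims), 0.05 * 2)
})

test_that("likelihood-ratio tests separate null from real effects", {
  # effect simulated with zero variance: statistic near 0, large p
  sim0 <- simulate_trial(trial_design(10, 3, 4),
                         variance_truth(2, 0, 0.1, 0.5, 4, 2), seed = 77)
  lr0 <- lrt_random_effect(sim0$table, "gh", "homogeneous")
  expect_lt(lr0$statistic, 3)
  expect_gt(lr0$p_value, 0.05)

  # strong genotypic variance: decisively significant
  lrg <- lrt_random_effect(sim0$table, "g", "homogeneous")
  expect_lt(lrg$p_value, 0.01)

  # invariance to record order
  perm <- sample(nrow(sim0$table))
  lr2 <- lrt_random_effect(sim0$table[perm, ], "g", "homogeneous")
  expect_equal(lr2$statistic, lrg$statistic, tolerance = 1e-6)
})

test_that("interaction variance at the reference regime is detected", {
  sim <- simulate_trial(trial_design(), truth_preset_heterogeneous(),
                        seed = 321)
  lr <- lrt_random_effect(sim$table, "gh", "diagonal")
  expect_lt(lr$p_value, 0.05)
})

test_that("persistence index follows the inverse-squared-distance formula", {
  # genotype A at the ideotype in every harvest, B at squared distance 1
  v <- rbind(A = c(5, 6), B = c(4.5, 5.13))
  v["B", ] <- v["A", ] - c(0.6, 0.8)   # d_B = 0.36 + 0.64 = 1
  p <- persistence_index(v, eps = 1e-8)
  expect_equal(unname(p$distance), c(0, 1), tolerance = 1e-12)
  expect_equal(unname(p$persistence["A"]), 1e8 / (1e8 + 1 / (1 + 1e-8)),
               tolerance = 1e-9)
  expect_lt(unname(p$persistence["B"]), 2e-8)

  # equidistant genotypes share persistence equally
  p2 <- persistence_index(rbind(c(2, 0), c(0, 2)))
  expect_equal(unname(p2$persistence), c(0.5, 0.5), tolerance = 1e-9)

  # 3 x 2 toy matrix against a hand computation
  v3 <- rbind(G1 = c(4, 7), G2 = c(5, 5), G3 = c(3, 6))
  d3 <- c(G1 = (4 - 5)^2, G2 = (7 - 5)^2, G3 = (5 - 3)^2 + (7 - 6)^2)
  d3 <- c(1 + 0, 0 + 4, 4 + 1)
  raw <- 1 / (d3 + 1e-8)
  p3 <- persistence_index(v3)
  expect_equal(unname(p3$persistence), raw / sum(raw), tolerance = 1e-12)
  expect_equal(sum(p3$persistence), 1, tolerance = 1e-12)
  expect_equal(p3$ideotype_by_harvest, c(H1 = 5, H2 = 7),
               ignore_attr = TRUE)
  expect_equal(p3$ranking[1], "G1")

  expect_warning(pu <- persistence_index(rbind(c(1, 1), c(1, 1))), "uniform")
  expect_equal(unname(pu$persistence), c(0.5, 0.5))
})

test_that("spearman_rho reproduces the rank-difference formula", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)
  # ranks (1,2,3) vs (2,1,3): 1 - 6*2 / (3*8) = 0.5
  expect_equal(spearman_rho(c(1, 2, 3), c(2, 1, 3)), 0.5, tolerance = 1e-12)
  # ties: average-rank fallback agrees with the standard implementation
  a <- c(1, 2, 2, 4, 7); b <- c(3, 3, 1, 5, 6)
  expect_equal(spearman_rho(a, b),
               cor(a, b, method = "spearman"), tolerance = 1e-12)
  expect_warning(out <- spearman_rho(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(out))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("ranking comparison aligns labels and delegates to spearman", {
  set.seed(41)
  v <- matrix(rnorm(12 * 4), 12, 4, dimnames = list(sprintf("G%d", 1:12)))
  pers <- persistence_index(v)
  # a strictly increasing transform of persistence correlates perfectly
  stab <- setNames(pers$persistence^2 / (1 + pers$persistence^2),
                   names(pers$persistence))
  expect_equal(compare_rankings(pers, stab), 1)
  # shuffled label order must not matter
  expect_equal(compare_rankings(pers, stab[sample(names(stab))]), 1)
  expect_equal(compare_rankings(pers, stab),
               spearman_rho(pers$persistence, stab[names(pers$persistence)]))
  expect_error(compare_rankings(pers, setNames(stab, sprintf("X%d", 1:12))),
               "label")
})

test_that("stability rankings agree across paradigms on matched draws", {
  # genotypes with strongly different interaction spread: the Bayesian
  # stability probability and the frequentist persistence of the
  # posterior-mean values should rank them concordantly
  hits <- 0L
  for (r in 1:10) {
    set.seed(900 + r)
    S <- 300; I <- 24; K <- 12
    # genotype-specific interaction spread, persistent across draws: the
    # located interaction pattern m_ik is what both paradigms can see
    sd_i <- seq(0.2, 3, length.out = I)[sample(I)]
    m_ik <- matrix(rnorm(I * K, 0, rep(sd_i, K)), I, K)
    gh <- array(rep(m_ik, each = S), c(S, I, K)) +
      array(rnorm(S * I * K, 0, 0.1), c(S, I, K))
    g <- matrix(rnorm(S * I, 0, 0.1), S, I) +
      rep(rnorm(I, 0, 0.3), each = S)
    d <- make_draws(g = g, gh = gh)
    stab <- prob_superior_stability(d, selection_config(4))
    vals <- apply(d$gh, c(2, 3), mean) + colMeans(d$g)
    rownames(vals) <- colnames(d$g)
    pers <- persistence_index(vals)
    if (compare_rankings(pers, named_probs(stab)) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("posterior-mean genotype effects track BLUPs on the same data", {
  sim <- small_sim(seed = 77)
  dr <- fit_bayes(sim$table, bayes_config("homogeneous", n_chains = 2,
                                          n_iterations = 1000, seed = 5))
  fit <- reml_fit(sim$table, "homogeneous")
  post_g <- colMeans(dr$g)
  expect_gte(spearman_rho(post_g, fit$blup_g[names(post_g)]), 0.90)
})
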