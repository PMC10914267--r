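# Bayesian hierarchical engine for multi-harvest trials.
#
# Model (B-ID / B-DG):
#   y_ijk ~ N(mu + g_i + r_j + h_k + gh_ik + p_ij, sigma_e)  [B-ID]
#   y_ijk ~ N(mu + g_i + r_j + h_k + gh_ik + p_ij, sigma_k)  [B-DG]
# with independent zero-mean normal priors on mu and every effect vector,
# each with its own scale, and half-Cauchy(0, phi) hyperpriors on all scales
# (including the residual scale(s)), phi = 10 * max(y) by default.
#
# Sampling uses a blocked Gibbs scheme: effect blocks have conjugate normal
# full conditionals; every half-Cauchy scale is handled by the exact
# inverse-gamma scale-mixture augmentation
#   sigma^2 | a ~ IG(1/2, 1/a),  a ~ IG(1/2, 1/phi^2)
# so all scale updates are conjugate as well.  The contract is
# distributional: the draws target exactly the posterior defined by
# build_model().

EFFECTS_ALL <- c("g", "r", "h", "gh", "p")

#' MCMC configuration for the Bayesian models
#'
#' @param residual_structure `"diagonal"` for one residual scale per harvest
#'   (B-DG) or `"homogeneous"` for a single residual scale (B-ID).
#' @param n_chains number of independent Markov chains (default 4).
#' @param n_iterations iterations per chain, including burn-in (default 4000).
#' @param burn_in_fraction fraction of each chain discarded (default 0.5).
#' @param thin keep every `thin`-th post-burn-in draw (default 1).
#' @param phi positive scale of the half-Cauchy hyperpriors, or `"auto"` for
#'   `10 * max(yield)`, a weakly informative choice that lets the data
#'   dominate the posterior.
#' @param seed integer base seed; chain `c` uses a seed derived from it.
#'   The default, 2015, is recorded in all outputs.
#' @return an object of class `bayes_config`.
#' @export
bayes_config <- function(residual_structure = c("diagonal", "homogeneous"),
                         n_chains = 4, n_iterations = 4000,
                         burn_in_fraction = 0.5, thin = 1,
                         phi = "auto", seed = 2015) {
  residual_structure <- match.arg(residual_structure)
  stop_if_not_scalar_count(n_chains, "n_chains")
  stop_if_not_scalar_count(n_iterations, "n_iterations", min = 2L)
  stop_if_not_scalar_count(thin, "thin")
  stopifnot(burn_in_fraction >= 0, burn_in_fraction < 1)
  if (!identical(phi, "auto")) {
    stopifnot(is.numeric(phi), length(phi) == 1L, phi > 0)
  }
  structure(
    list(residual_structure = residual_structure,
         n_chains = as.integer(n_chains),
         n_iterations = as.integer(n_iterations),
         burn_in_fraction = burn_in_fraction,
         thin = as.integer(thin), phi = phi, seed = as.integer(seed)),
    class = "bayes_config"
  )
}

n_retained <- function(config) {
  floor(config$n_iterations * (1 - config$burn_in_fraction) / config$thin)
}

#' Resolve the model specification for a phenotype table
#'
#' Computes everything the sampler and the density functions need: design
#' dimensions, factor labels, the residual structure, and the value of the
#' half-Cauchy hyperprior scale phi actually used (`10 * max(yield)` when the
#' configuration says `"auto"`).  The normal priors are parameterized by
#' scale (standard deviation); variances are derived quantities.
#'
#' @param table a phenotype table.
#' @param config a [bayes_config()].
#' @return an object of class `model_spec`.
#' @export
build_model <- function(table, config = bayes_config()) {
  table <- as_phenotype_table(table)
  if (!nrow(table)) stop("empty phenotype table", call. = FALSE)
  if (anyNA(table$genotype) || anyNA(table$block) || anyNA(table$harvest)) {
    stop("records with missing factor labels", call. = FALSE)
  }
  phi <- if (identical(config$phi, "auto")) 10 * max(table$yield) else config$phi
  if (!is.finite(phi) || phi <= 0) {
    stop("resolved phi must be positive; got ", phi, call. = FALSE)
  }
  labs <- list(genotype = levels(droplevels(table$genotype)),
               block = levels(droplevels(table$block)),
               harvest = levels(droplevels(table$harvest)))
  structure(
    list(residual_structure = config$residual_structure,
         n_genotypes = length(labs$genotype),
         n_blocks = length(labs$block),
         n_harvests = length(labs$harvest),
         n_records = nrow(table),
         labels = labs, phi = phi,
         parameterization = "normal priors use scale (sd); half-Cauchy(0, phi) on every scale",
         config = config),
    class = "model_spec"
  )
}

# integer index vectors for a table against a spec's labels
spec_indices <- function(spec, table) {
  i <- match(as.character(table$genotype), spec$labels$genotype)
  j <- match(as.character(table$block), spec$labels$block)
  k <- match(as.character(table$harvest), spec$labels$harvest)
  if (anyNA(i) || anyNA(j) || anyNA(k)) {
    stop("table contains labels unknown to the model spec", call. = FALSE)
  }
  I <- spec$n_genotypes
  list(i = i, j = j, k = k,
       gh = (k - 1L) * I + i,
       p = (j - 1L) * I + i)
}

#' Log posterior density (up to a constant)
#'
#' Evaluates log(likelihood x priors x hyperpriors) at a given parameter
#' point, up to an additive constant fixed for a given spec.  Serves as an
#' analytic oracle for validating the sampler.
#'
#' @param spec a [build_model()] result.
#' @param table the phenotype table the spec was built from.
#' @param point named list with elements `mu`, active effect vectors among
#'   `g`, `r`, `h` (vectors), `gh` (genotype x harvest matrix), `p`
#'   (genotype x block matrix), scales `sigma_mu`, `sigma_g`, ...,
#'   `sigma_p`, and `sigma_e` (length 1 or one per harvest).  Effects absent
#'   from the list are treated as dropped from the model (their prior terms
#'   are skipped too).
#' @return the log density, with attribute `"parts"` giving the likelihood
#'   and prior contributions separately.
#' @export
log_posterior <- function(spec, table, point) {
  stopifnot(inherits(spec, "model_spec"))
  table <- as_phenotype_table(table)
  idx <- spec_indices(spec, table)
  K <- spec$n_harvests

  sig_e <- point$sigma_e
  n_sig_e <- if (spec$residual_structure == "diagonal") K else 1L
  if (length(sig_e) != n_sig_e) {
    stop(sprintf("sigma_e must have length %d for the %s residual structure",
                 n_sig_e, spec$residual_structure), call. = FALSE)
  }
  scales <- c(list(sigma_e = sig_e),
              point[intersect(names(point),
                              c("sigma_mu", "sigma_g", "sigma_r", "sigma_h",
                                "sigma_gh", "sigma_p"))])
  if (any(unlist(scales) <= 0)) {
    stop("nonpositive scale entry in parameter point", call. = FALSE)
  }

  eta <- rep(point$mu, spec$n_records)
  if (!is.null(point$g)) eta <- eta + point$g[idx$i]
  if (!is.null(point$r)) eta <- eta + point$r[idx$j]
  if (!is.null(point$h)) eta <- eta + point$h[idx$k]
  if (!is.null(point$gh)) eta <- eta + as.numeric(point$gh)[idx$gh]
  if (!is.null(point$p)) eta <- eta + as.numeric(point$p)[idx$p]
  sd_obs <- if (n_sig_e == 1L) rep(sig_e, spec$n_records) else sig_e[idx$k]
  loglik <- sum(stats::dnorm(table$yield, eta, sd_obs, log = TRUE))

  logprior <- stats::dnorm(point$mu, 0, point$sigma_mu, log = TRUE)
  for (ef in EFFECTS_ALL) {
    if (!is.null(point[[ef]])) {
      logprior <- logprior +
        sum(stats::dnorm(as.numeric(point[[ef]]), 0,
                         point[[paste0("sigma_", ef)]], log = TRUE))
    }
  }
  logprior <- logprior + sum(dhalfcauchy_log(unlist(scales), spec$phi))

  structure(loglik + logprior, parts = c(loglik = loglik, logprior = logprior))
}

# One Gibbs chain.  Returns kept draws as plain matrices.
gibbs_chain <- function(y, idx, dims, spec, config, effects,
                        fixed_residual_sd, mu_prior_sd, chain_seed) {
  set.seed(chain_seed)
  N <- length(y); K <- dims$K
  diagres <- spec$residual_structure == "diagonal" && is.null(fixed_residual_sd)
  sample_res <- is.null(fixed_residual_sd)
  sample_mu_scale <- is.null(mu_prior_sd)
  phi <- spec$phi

  m_of <- c(g = dims$I, r = dims$J, h = dims$K, gh = dims$I * dims$K,
            p = dims$I * dims$J)
  idx_of <- list(g = idx$i, r = idx$j, h = idx$k, gh = idx$gh, p = idx$p)

  # per-effect crosstabs against harvest (for fast weighted level counts)
  n_k <- tabulate(idx$k, K)
  cnt <- lapply(effects, function(ef) {
    m <- m_of[[ef]]
    tab <- matrix(0, m, K)
    tt <- table(factor(idx_of[[ef]], levels = seq_len(m)),
                factor(idx$k, levels = seq_len(K)))
    tab[] <- as.numeric(tt)
    tab
  })
  names(cnt) <- effects
  present <- lapply(effects, function(ef) sort(unique(idx_of[[ef]])))
  names(present) <- effects

  # initial state (overdispersed across chains)
  mu <- mean(y) + stats::rnorm(1, 0, max(stats::sd(y), 1e-3) / 2)
  eff <- lapply(effects, function(ef) {
    stats::rnorm(m_of[[ef]], 0, max(stats::sd(y), 1e-3) / 10)
  })
  names(eff) <- effects
  v0 <- max(stats::var(y), 1e-6)
  s2 <- lapply(effects, function(ef) v0 * stats::runif(1, 0.25, 2))
  names(s2) <- effects
  a_aux <- lapply(effects, function(ef) 1)
  names(a_aux) <- effects
  s2_mu <- if (sample_mu_scale) v0 * stats::runif(1, 0.25, 2) else mu_prior_sd^2
  a_mu <- 1
  n_res <- if (diagres) K else 1L
  s2_e <- if (sample_res) rep(v0 * stats::runif(1, 0.5, 2), n_res)
          else rep(fixed_residual_sd^2, n_res)
  a_e <- rep(1, n_res)

  eta <- rep(mu, N)
  for (ef in effects) eta <- eta + eff[[ef]][idx_of[[ef]]]
  e <- y - eta

  burn <- floor(config$n_iterations * config$burn_in_fraction)
  keep_at <- seq.int(burn + config$thin, config$n_iterations, by = config$thin)
  n_keep <- length(keep_at)
  out_mu <- numeric(n_keep)
  out_eff <- lapply(effects, function(ef) matrix(NA_real_, n_keep, m_of[[ef]]))
  names(out_eff) <- effects
  out_s <- matrix(NA_real_, n_keep, length(effects) + 1L,
                  dimnames = list(NULL,
                                  c("sigma_mu",
                                    paste0("sigma_", effects,
                                           recycle0 = TRUE))))
  out_se <- matrix(NA_real_, n_keep, n_res)

  keep_ptr <- 1L
  for (t in seq_len(config$n_iterations)) {
    winv <- if (diagres) 1 / s2_e else rep(1 / s2_e, K)  # per-harvest precision
    w <- winv[idx$k]
    sw_k <- n_k * winv

    # mu
    res <- e + mu
    prec <- 1 / s2_mu + sum(sw_k)
    mu <- stats::rnorm(1, sum(w * res) / prec, sqrt(1 / prec))
    e <- res - mu

    # effect blocks
    for (ef in effects) {
      ix <- idx_of[[ef]]; m <- m_of[[ef]]
      res <- e + eff[[ef]][ix]
      swr <- numeric(m)
      swr[present[[ef]]] <- rowsum(w * res, ix, reorder = TRUE)
      sw <- as.numeric(cnt[[ef]] %*% winv)
      prec <- 1 / s2[[ef]] + sw
      eff[[ef]] <- stats::rnorm(m, swr / prec, sqrt(1 / prec))
      e <- res - eff[[ef]][ix]
    }

    # scale parameters (half-Cauchy via inverse-gamma augmentation)
    for (ef in effects) {
      s2[[ef]] <- rinvgamma(1, (m_of[[ef]] + 1) / 2,
                            1 / a_aux[[ef]] + sum(eff[[ef]]^2) / 2)
      a_aux[[ef]] <- rinvgamma(1, 1, 1 / phi^2 + 1 / s2[[ef]])
    }
    if (sample_mu_scale) {
      s2_mu <- rinvgamma(1, 1, 1 / a_mu + mu^2 / 2)
      a_mu <- rinvgamma(1, 1, 1 / phi^2 + 1 / s2_mu)
    }
    if (sample_res) {
      if (diagres) {
        sse <- numeric(K)
        sse[sort(unique(idx$k))] <- rowsum(e^2, idx$k, reorder = TRUE)
        s2_e <- rinvgamma(K, (n_k + 1) / 2, 1 / a_e + sse / 2)
        a_e <- rinvgamma(K, 1, 1 / phi^2 + 1 / s2_e)
      } else {
        s2_e <- rinvgamma(1, (N + 1) / 2, 1 / a_e + sum(e^2) / 2)
        a_e <- rinvgamma(1, 1, 1 / phi^2 + 1 / s2_e)
      }
    }

    if (keep_ptr <= n_keep && t == keep_at[keep_ptr]) {
      out_mu[keep_ptr] <- mu
      for (ef in effects) out_eff[[ef]][keep_ptr, ] <- eff[[ef]]
      out_s[keep_ptr, ] <- sqrt(c(s2_mu, unlist(s2)))
      out_se[keep_ptr, ] <- sqrt(s2_e)
      keep_ptr <- keep_ptr + 1L
    }
  }
  list(mu = out_mu, eff = out_eff, scales = out_s, sigma_e = out_se)
}

#' Fit a Bayesian hierarchical model by MCMC
#'
#' Runs `n_chains` independent blocked Gibbs chains targeting the posterior
#' defined by [build_model()] and returns the retained post-burn-in draws of
#' every model quantity.  With a fixed seed the output is fully reproducible.
#' Non-convergence is not an error here; it is reported by the diagnostics
#' functions ([split_rhat()], [diagnostics_report()]).
#'
#' @param table a phenotype table with at least two levels of each factor
#'   carried by an active effect.
#' @param config a [bayes_config()].
#' @param effects character subset of `c("g","r","h","gh","p")` naming the
#'   effect blocks to include; the default is the full model.  Reduced
#'   models (e.g. intercept-only, for closed-form validation) are obtained
#'   by shrinking this set.
#' @param fixed_residual_sd optional known residual scale; when supplied the
#'   residual scale is held fixed instead of sampled (homogeneous only).
#' @param mu_prior_sd optional fixed prior scale for the intercept; when
#'   `NULL` the intercept scale gets the usual half-Cauchy hyperprior.
#' @return an object of class `posterior_draws` with elements `mu` (vector
#'   S), `g`, `r`, `h` (matrices S x levels), `gh` (array S x I x K), `p`
#'   (matrix S x I*J, plot order genotype-within-block), scale draws
#'   `sigma_mu`, `sigma_g`, ..., `sigma_p` (vectors) and `sigma_e` (matrix
#'   S x 1 or S x K), `chain_index`, `labels`, `spec`.
#' @examples
#' sim <- simulate_trial(trial_design(6, 2, 3, grand_mean = 30),
#'                       variance_truth(2, 0.5, 0.2, 0.5, 9, 4), seed = 1)
#' cfg <- bayes_config("diagonal", n_chains = 2, n_iterations = 400, seed = 7)
#' draws <- fit_bayes(sim$table, cfg)
#' draws
#' @export
fit_bayes <- function(table, config = bayes_config(),
                      effects = EFFECTS_ALL,
                      fixed_residual_sd = NULL, mu_prior_sd = NULL) {
  table <- as_phenotype_table(table)
  stopifnot(inherits(config, "bayes_config"))
  effects <- if (length(effects)) {
    match.arg(effects, EFFECTS_ALL, several.ok = TRUE)
  } else character(0)
  if (!is.null(fixed_residual_sd) && config$residual_structure == "diagonal") {
    stop("fixed_residual_sd requires the homogeneous residual structure",
         call. = FALSE)
  }
  spec <- build_model(table, config)
  lev_need <- c(g = "genotype", r = "block", h = "harvest")
  for (ef in intersect(effects, names(lev_need))) {
    if (length(spec$labels[[lev_need[[ef]]]]) < 2L) {
      stop(sprintf("effect '%s' needs >= 2 %s levels", ef, lev_need[[ef]]),
           call. = FALSE)
    }
  }
  idx <- spec_indices(spec, table)
  dims <- list(I = spec$n_genotypes, J = spec$n_blocks, K = spec$n_harvests)

  chains <- lapply(seq_len(config$n_chains), function(cc) {
    gibbs_chain(table$yield, idx, dims, spec, config, effects,
                fixed_residual_sd, mu_prior_sd,
                chain_seed = derive_seed(config$seed, cc))
  })
  n_keep <- n_retained(config)
  S <- n_keep * config$n_chains
  labs <- spec$labels

  bindv <- function(get) do.call(c, lapply(chains, get))
  bindm <- function(get) do.call(rbind, lapply(chains, get))

  out <- list(mu = bindv(function(ch) ch$mu))
  gnames <- list(g = labs$genotype, r = labs$block, h = labs$harvest)
  for (ef in effects) {
    m <- bindm(function(ch) ch$eff[[ef]])
    if (ef == "gh") {
      m <- array(m, dim = c(S, dims$I, dims$K),
                 dimnames = list(NULL, labs$genotype, labs$harvest))
    } else if (ef == "p") {
      colnames(m) <- as.vector(outer(labs$genotype, labs$block, paste,
                                     sep = ":"))
    } else {
      colnames(m) <- gnames[[ef]]
    }
    out[[ef]] <- m
  }
  sc <- bindm(function(ch) ch$scales)
  for (nm in colnames(sc)) out[[nm]] <- sc[, nm]
  if (!is.null(mu_prior_sd)) out$sigma_mu <- NULL
  se <- bindm(function(ch) ch$sigma_e)
  colnames(se) <- if (ncol(se) == dims$K && spec$residual_structure == "diagonal")
    labs$harvest else "all"
  out$sigma_e <- se
  out$chain_index <- rep(seq_len(config$n_chains), each = n_keep)
  out$labels <- labs
  out$spec <- spec
  out$effects <- effects
  class(out) <- "posterior_draws"
  out
}

#' Number of retained posterior draws
#' @param draws a `posterior_draws` object.
#' @return integer count of retained draws across chains.
#' @export
n_draws <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  length(draws$mu)
}

#' @export
print.posterior_draws <- function(x, ...) {
  cfg <- x$spec$config
  cat(sprintf("Posterior draws: %d retained (%d chains), %s residual model\n",
              n_draws(x), cfg$n_chains, x$spec$residual_structure))
  cat(sprintf("  %d genotypes x %d blocks x %d harvests; phi = %.4g; seed %d\n",
              x$spec$n_genotypes, x$spec$n_blocks, x$spec$n_harvests,
              x$spec$phi, cfg$seed))
  invisible(x)
}

# Extract a single draw as a parameter point for log_posterior().
draw_point <- function(draws, s) {
  stopifnot(inherits(draws, "posterior_draws"))
  pt <- list(mu = draws$mu[s])
  for (ef in draws$effects) {
    pt[[ef]] <- if (ef == "gh") draws$gh[s, , ] else
      if (is.matrix(draws[[ef]])) draws[[ef]][s, ] else draws[[ef]][s]
    pt[[paste0("sigma_", ef)]] <- draws[[paste0("sigma_", ef)]][s]
  }
  if (!is.null(draws$sigma_mu)) pt$sigma_mu <- draws$sigma_mu[s]
  pt$sigma_e <- draws$sigma_e[s, ]
  pt
}

# S x N matrix of linear predictors for a table under every retained draw
linear_predictor_matrix <- function(draws, table) {
  idx <- spec_indices(draws$spec, table)
  S <- n_draws(draws); N <- nrow(table)
  lp <- matrix(draws$mu, S, N)
  if (!is.null(draws$g)) lp <- lp + draws$g[, idx$i, drop = FALSE]
  if (!is.null(draws$r)) lp <- lp + draws$r[, idx$j, drop = FALSE]
  if (!is.null(draws$h)) lp <- lp + draws$h[, idx$k, drop = FALSE]
  if (!is.null(draws$gh)) {
    ghm <- matrix(draws$gh, S, dim(draws$gh)[2] * dim(draws$gh)[3])
    lp <- lp + ghm[, idx$gh, drop = FALSE]
  }
  if (!is.null(draws$p)) lp <- lp + draws$p[, idx$p, drop = FALSE]
  lp
}

residual_sd_matrix <- function(draws, table) {
  idx <- spec_indices(draws$spec, table)
  S <- n_draws(draws); N <- nrow(table)
  if (ncol(draws$sigma_e) == 1L) {
    matrix(draws$sigma_e[, 1L], S, N)
  } else {
    draws$sigma_e[, idx$k, drop = FALSE]
  }
}

#' Pointwise log-likelihood matrix
#'
#' Entry `(s, n)` is the log normal density of record `n` at the linear
#' predictor and residual scale of retained draw `s` (harvest-specific scale
#' under the diagonal structure).  This is the input to [waic2()].
#'
#' @param draws a `posterior_draws` object.
#' @param table the phenotype table the model was fitted to (same labels).
#' @return an `S x n_records` numeric matrix.
#' @export
pointwise_loglik <- function(draws, table) {
  table <- as_phenotype_table(table)
  lp <- linear_predictor_matrix(draws, table)
  sdm <- residual_sd_matrix(draws, table)
  Y <- matrix(table$yield, nrow(lp), ncol(lp), byrow = TRUE)
  stats::dnorm(Y, lp, sdm, log = TRUE)
}

#' Posterior predictive replicates (ancestral sampling)
#'
#' Generates `n_replicates` replicated datasets `y_gen`, each produced by
#' taking one distinct retained posterior draw and adding normal residual
#' noise at that draw's residual scale(s) to its linear predictor.  The
#' subset of draws used is sampled without replacement under `seed`.
#'
#' @param draws a `posterior_draws` object.
#' @param table the phenotype table the model was fitted to.
#' @param n_replicates number of replicated datasets, at most [n_draws()].
#' @param seed integer seed for draw selection and noise.
#' @return an `n_replicates x n_records` matrix; row `r` is one `y_gen`.
#' @export
sample_posterior_predictive <- function(draws, table, n_replicates,
                                        seed = draws$spec$config$seed) {
  table <- as_phenotype_table(table)
  S <- n_draws(draws)
  if (n_replicates > S) {
    stop(sprintf("n_replicates (%d) exceeds the number of draws (%d)",
                 n_replicates, S), call. = FALSE)
  }
  with_seed(seed, {
    pick <- if (n_replicates == S) seq_len(S) else sample.int(S, n_replicates)
    lp <- linear_predictor_matrix(draws, table)[pick, , drop = FALSE]
    sdm <- residual_sd_matrix(draws, table)[pick, , drop = FALSE]
    yrep <- lp + stats::rnorm(length(lp), 0, sdm)
    dim(yrep) <- dim(lp)
    yrep
  })
}
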