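# Convergence and fit diagnostics: split R-hat, WAIC2, posterior predictive
# p-values, HPD intervals.

#' Split potential scale reduction factor (split R-hat)
#'
#' Each chain is split in half, giving `2 * n_chains` sequences of equal
#' length `N`; with `W` the mean within-sequence variance and
#' `B = N * Var(sequence means)`, the statistic is
#' `sqrt(((N - 1)/N * W + B/N) / W)`.  Values near 1 indicate good mixing;
#' values well above 1 mean the chains have not converged.  No
#' rank-normalization is applied.
#'
#' @param chains numeric matrix, one row per chain, one column per draw
#'   (at least 4 draws), for a single scalar parameter.
#' @return the split R-hat; `NaN` with a warning when every sequence is
#'   constant (the statistic is undefined there, not silently 1).
#' @export
split_rhat <- function(chains) {
  if (is.numeric(chains) && is.null(dim(chains))) {
    chains <- matrix(chains, nrow = 1L)
  }
  stopifnot(is.matrix(chains), ncol(chains) >= 4L)
  half <- floor(ncol(chains) / 2)
  seqs <- rbind(chains[, seq_len(half), drop = FALSE],
                chains[, ncol(chains) - half + seq_len(half), drop = FALSE])
  N <- ncol(seqs)
  vars <- apply(seqs, 1L, stats::var)
  W <- mean(vars)
  if (W == 0) {
    warning("all split sequences are constant; split R-hat is undefined")
    return(NaN)
  }
  B <- N * stats::var(rowMeans(seqs))
  sqrt(((N - 1) / N * W + B / N) / W)
}

# chains matrix (n_chains x n_draws) for one scalar from a posterior_draws
chain_matrix <- function(values, chain_index) {
  ch <- split(values, chain_index)
  do.call(rbind, ch)
}

#' Split R-hat for every scalar parameter of a fit
#'
#' @param draws a `posterior_draws` object.
#' @return named numeric vector of split R-hat values, one per sampled
#'   scalar (intercept, each effect level, each scale parameter).
#' @export
rhat_map <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  ci <- draws$chain_index
  out <- c(mu = split_rhat(chain_matrix(draws$mu, ci)))
  for (ef in draws$effects) {
    m <- if (ef == "gh") {
      matrix(draws$gh, length(draws$mu), prod(dim(draws$gh)[-1]),
             dimnames = list(NULL, outer(dimnames(draws$gh)[[2]],
                                         dimnames(draws$gh)[[3]],
                                         paste, sep = ":")))
    } else draws[[ef]]
    r <- vapply(seq_len(ncol(m)),
                function(jj) split_rhat(chain_matrix(m[, jj], ci)), 0)
    names(r) <- paste0(ef, "[", colnames(m), "]")
    out <- c(out, r)
  }
  for (nm in scale_parameter_names(draws)) {
    vals <- if (startsWith(nm, "sigma_e")) {
      col <- sub("^sigma_e\\[?([^]]*)\\]?$", "\\1", nm)
      draws$sigma_e[, if (nzchar(col)) col else 1L]
    } else draws[[nm]]
    out[nm] <- split_rhat(chain_matrix(vals, ci))
  }
  out
}

# names of the scale (variance) parameters carried by a fit
scale_parameter_names <- function(draws) {
  nms <- intersect(c("sigma_mu", paste0("sigma_", draws$effects)),
                   names(draws))
  if (!is.null(draws$sigma_e)) {
    nms <- c(nms, if (ncol(draws$sigma_e) == 1L) "sigma_e"
             else paste0("sigma_e[", colnames(draws$sigma_e), "]"))
  }
  nms
}

#' Mean split R-hat over the variance (scale) parameters
#'
#' @param draws a `posterior_draws` object.
#' @return mean of the per-scale split R-hat values, skipping any undefined
#'   (NaN) entries with a note of how many were skipped.
#' @export
mean_rhat_scales <- function(draws) {
  r <- rhat_map(draws)
  r <- r[scale_parameter_names(draws)]
  n_bad <- sum(is.nan(r))
  if (n_bad) message(n_bad, " undefined R-hat value(s) skipped")
  mean(r[!is.nan(r)])
}

#' Watanabe-Akaike information criterion (variance penalty form)
#'
#' Computes, from an `S x n` pointwise log-likelihood matrix,
#' `lppd = sum_n log(mean_s exp(loglik[s, n]))` (via log-sum-exp),
#' the effective-parameter penalty `p_waic2 = sum_n Var_s(loglik[s, n])`
#' (sample variance over draws), and `waic2 = -2 * (lppd - p_waic2)`.
#' Lower WAIC2 indicates better expected predictive fit.
#'
#' @param loglik matrix from [pointwise_loglik()].
#' @return list with components `waic2`, `lppd`, `p_waic2`.
#' @export
waic2 <- function(loglik) {
  stopifnot(is.matrix(loglik))
  if (any(!is.finite(loglik))) {
    stop("non-finite entries in the log-likelihood matrix", call. = FALSE)
  }
  S <- nrow(loglik)
  mx <- apply(loglik, 2L, max)
  lppd <- sum(mx + log(colMeans(exp(sweep(loglik, 2L, mx)))))
  p_waic2 <- sum(apply(loglik, 2L, stats::var))
  list(waic2 = -2 * (lppd - p_waic2), lppd = lppd, p_waic2 = p_waic2)
}

#' Posterior predictive p-values
#'
#' For each test statistic `T` in maximum, minimum, median, mean and
#' standard deviation, computes `p_T = Pr(T(y_gen) >= T(y) | y)` as the
#' fraction of replicated datasets whose statistic is at least (inclusive)
#' the observed one.  Values near 0.5 indicate that the model replicates
#' that feature of the data well; values near 0 or 1 flag misfit.
#'
#' @param observed numeric vector of observed yields.
#' @param replicates matrix from [sample_posterior_predictive()], one row
#'   per replicated dataset, columns matching `observed`.
#' @return named numeric vector with elements `max`, `min`, `median`,
#'   `mean`, `sd`, each in `[0, 1]`.
#' @export
ppc_pvalues <- function(observed, replicates) {
  if (is.null(dim(replicates))) replicates <- matrix(replicates, nrow = 1L)
  if (ncol(replicates) != length(observed)) {
    stop("replicate record count does not match the observed data",
         call. = FALSE)
  }
  stats_fun <- list(max = max, min = min, median = stats::median,
                    mean = mean, sd = stats::sd)
  vapply(stats_fun, function(f) {
    t_obs <- f(observed)
    t_rep <- apply(replicates, 1L, f)
    mean(t_rep >= t_obs)
  }, 0)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval of sorted draws containing the requested
#' posterior mass; among tied-width windows the lowest-starting one is
#' returned.
#'
#' @param draws numeric vector of at least 10 posterior draws.
#' @param mass probability mass in (0, 1) (default 0.95).
#' @return list with `lower`, `upper`, `mass` (class `hpd_interval`).
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  stopifnot(length(draws) >= 10L, mass > 0, mass < 1)
  x <- sort(draws)
  S <- length(x)
  gap <- max(1L, min(S - 1L, as.integer(ceiling(mass * S))))
  widths <- x[(gap + 1L):S] - x[seq_len(S - gap)]
  i <- which.min(widths)  # ties -> lowest start
  structure(list(lower = x[i], upper = x[i + gap], mass = mass),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("%.1f%% HPD: [%.6g, %.6g]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Combined convergence and fit report for one fitted model
#'
#' Bundles the per-parameter split R-hat map, its mean, the WAIC2
#' decomposition and the posterior predictive p-values for one fit.
#'
#' @param draws a `posterior_draws` object.
#' @param table the phenotype table the model was fitted to.
#' @param n_replicates number of posterior predictive replicates used for
#'   the p-values (default 1000, capped at the number of draws).
#' @param seed seed for the predictive replicates.
#' @return an object of class `diagnostics_report`: list with `rhat`,
#'   `mean_rhat` (over all sampled scalars), `mean_rhat_scales` (variance
#'   parameters only), `waic2`, `lppd`, `p_waic2`, `ppc_pvalues`.
#' @export
diagnostics_report <- function(draws, table, n_replicates = 1000,
                               seed = draws$spec$config$seed) {
  table <- as_phenotype_table(table)
  rh <- rhat_map(draws)
  ll <- pointwise_loglik(draws, table)
  w <- waic2(ll)
  yrep <- sample_posterior_predictive(draws, table,
                                      min(n_replicates, n_draws(draws)),
                                      seed = seed)
  ppc <- ppc_pvalues(table$yield, yrep)
  structure(
    list(rhat = rh,
         mean_rhat = mean(rh[!is.nan(rh)]),
         mean_rhat_scales = mean(rh[scale_parameter_names(draws)],
                                 na.rm = TRUE),
         waic2 = w$waic2, lppd = w$lppd, p_waic2 = w$p_waic2,
         ppc_pvalues = ppc),
    class = "diagnostics_report"
  )
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("WAIC2 %.2f (lppd %.2f, p_waic2 %.2f); mean R-hat %.3f (scales %.3f)\n",
              x$waic2, x$lppd, x$p_waic2, x$mean_rhat, x$mean_rhat_scales))
  cat("PPC p-values:",
      paste(sprintf("%s %.3f", names(x$ppc_pvalues), x$ppc_pvalues),
            collapse = ", "), "\n")
  invisible(x)
}

#' Export a diagnostics report as JSON
#' @param report a `diagnostics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(report, path) {
  stopifnot(inherits(report, "diagnostics_report"))
  x <- unclass(report)
  x$rhat <- as.list(x$rhat)
  x$ppc_pvalues <- as.list(x$ppc_pvalues)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "string")
  invisible(path)
}
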