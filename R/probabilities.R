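# Posterior counting probabilities of superior performance and stability.
#
# All probabilities are exact counting fractions over the S retained draws:
# per draw the genotypes are ranked, a subset is selected, and membership is
# averaged over draws.  Ties (possible only for degenerate inputs) are
# broken by genotype input order.  Each result carries the raw counts and S
# as attributes so the fractions are exactly reproducible.

#' Selection configuration
#'
#' @param n_selected number of genotypes retained per draw (the selected
#'   fraction); default 4, i.e. a 16% selection proportion among 24
#'   candidates.
#' @param direction `"higher-is-better"` (yield-type traits, default) or
#'   `"lower-is-better"`.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(n_selected = 4,
                             direction = c("higher-is-better",
                                           "lower-is-better")) {
  stop_if_not_scalar_count(n_selected, "n_selected")
  structure(list(n_selected = as.integer(n_selected),
                 direction = match.arg(direction)),
            class = "selection_config")
}

# genotype draw matrix S x I from posterior_draws or a plain matrix
g_matrix <- function(draws) {
  if (inherits(draws, "posterior_draws")) {
    if (is.null(draws$g)) stop("fit carries no genotype effects", call. = FALSE)
    draws$g
  } else {
    stopifnot(is.matrix(draws))
    draws
  }
}

gh_array <- function(draws) {
  if (inherits(draws, "posterior_draws")) {
    if (is.null(draws$gh)) {
      stop("fit carries no genotype-by-harvest effects", call. = FALSE)
    }
    draws$gh
  } else {
    stopifnot(is.array(draws), length(dim(draws)) == 3L)
    draws
  }
}

# per-draw membership frequencies of the top n_selected columns of `value`
# (S x I), ordered by `decreasing`; ties broken by column (input) order.
membership_frequencies <- function(value, n_selected, decreasing) {
  I <- ncol(value); S <- nrow(value)
  if (n_selected >= I) {
    stop(sprintf("n_selected (%d) must be smaller than the number of genotypes (%d)",
                 n_selected, I), call. = FALSE)
  }
  counts <- integer(I)
  for (s in seq_len(S)) {
    sel <- order(value[s, ], decreasing = decreasing)[seq_len(n_selected)]
    counts[sel] <- counts[sel] + 1L
  }
  structure(counts / S, names = colnames(value), count = counts, S = S)
}

# pairwise strict-win frequencies: entry (i, i') = fraction of draws where
# value[s, i] beats value[s, i'] (beat = ">" if decreasing else "<")
pairwise_frequencies <- function(value, decreasing) {
  I <- ncol(value); S <- nrow(value)
  if (I < 2L) stop("need at least 2 genotypes", call. = FALSE)
  counts <- matrix(0L, I, I, dimnames = list(colnames(value), colnames(value)))
  for (a in seq_len(I - 1L)) {
    for (b in (a + 1L):I) {
      wins <- sum(if (decreasing) value[, a] > value[, b]
                  else value[, a] < value[, b])
      ties <- sum(value[, a] == value[, b])
      counts[a, b] <- wins
      counts[b, a] <- S - wins - ties
    }
  }
  out <- counts / S
  diag(out) <- NA_real_
  structure(out, count = counts, S = S)
}

#' Marginal probability of superior performance
#'
#' For each retained draw the genotypes are ranked by their genotypic value
#' `g_i` and the top `n_selected` form the superior subset; the probability
#' for genotype `i` is the fraction of draws in which it belongs to that
#' subset.  Probabilities sum to `n_selected` exactly (each draw selects
#' exactly that many genotypes).
#'
#' @param draws a `posterior_draws` object (or a plain `S x I` matrix of
#'   genotypic-value draws).
#' @param config a [selection_config()].
#' @return named probability vector with attributes `count` (integer
#'   numerators) and `S` (the denominator).
#' @export
prob_superior_performance <- function(draws, config = selection_config()) {
  membership_frequencies(g_matrix(draws), config$n_selected,
                         decreasing = config$direction == "higher-is-better")
}

#' Per-draw genotype-by-harvest interaction variance
#'
#' Entry `(s, i)` is the sample variance (divisor `K - 1`) across the `K`
#' harvests of the interaction effects `gh_ik` of genotype `i` in draw `s`.
#' Genotypes with smaller interaction variance fluctuate less across
#' harvests and are considered more stable.
#'
#' @param draws a `posterior_draws` object (or an `S x I x K` array of
#'   interaction draws), `K >= 2`.
#' @return an `S x I` matrix of variances.
#' @export
gh_variance_per_draw <- function(draws) {
  gh <- gh_array(draws)
  K <- dim(gh)[3]
  if (K < 2L) stop("need at least 2 harvests to compute a variance",
                   call. = FALSE)
  m <- apply(gh, c(1L, 2L), mean)
  sq <- apply(gh^2, c(1L, 2L), sum)
  v <- (sq - K * m^2) / (K - 1)
  v[v < 0] <- 0  # guard tiny negative rounding
  colnames(v) <- dimnames(gh)[[2]]
  v
}

#' Marginal probability of superior stability
#'
#' Mirrors [prob_superior_performance()], but ranks genotypes per draw by
#' their interaction variance ([gh_variance_per_draw()]): the `n_selected`
#' genotypes with the smallest variance form the stable subset.
#'
#' @inheritParams prob_superior_performance
#' @return named probability vector with `count` and `S` attributes.
#' @export
prob_superior_stability <- function(draws, config = selection_config()) {
  membership_frequencies(gh_variance_per_draw(draws), config$n_selected,
                         decreasing = FALSE)
}

#' Pairwise probability of superior performance
#'
#' Entry `(i, i')` is the fraction of draws in which genotype `i`'s value
#' strictly exceeds genotype `i''`s.  Off-diagonal entries of the result and
#' its transpose sum to 1 whenever no draw ties exactly; the diagonal is
#' masked as `NA`.
#'
#' @inheritParams prob_superior_performance
#' @return an `I x I` probability matrix with `count` and `S` attributes.
#' @export
pairwise_prob_performance <- function(draws) {
  pairwise_frequencies(g_matrix(draws), decreasing = TRUE)
}

#' Pairwise probability of superior stability
#'
#' Entry `(i, i')` is the fraction of draws in which genotype `i` has
#' strictly smaller interaction variance than genotype `i'`.
#'
#' @inheritParams prob_superior_performance
#' @return an `I x I` probability matrix with `count` and `S` attributes.
#' @export
pairwise_prob_stability <- function(draws) {
  pairwise_frequencies(gh_variance_per_draw(draws), decreasing = FALSE)
}

# S x I matrix of within-harvest genotypic values g_i + gh_ik for harvest k.
# The harvest main effect is common to all genotypes and cancels in ranking.
within_harvest_value <- function(g, gh, k) {
  g + matrix(gh[, , k], nrow(g), ncol(g))
}

#' Probability of superior performance within each harvest
#'
#' The within-harvest genotypic value of genotype `i` at harvest `k` is
#' `g_i + gh_ik`; per harvest and per draw the top `n_selected` genotypes
#' are selected, and membership frequencies are reported per harvest.
#'
#' @inheritParams prob_superior_performance
#' @return an `I x K` probability matrix (genotypes x harvests); each column
#'   sums to `n_selected`.
#' @export
prob_superior_performance_within <- function(draws,
                                             config = selection_config()) {
  g <- g_matrix(draws); gh <- gh_array(draws)
  K <- dim(gh)[3]
  dec <- config$direction == "higher-is-better"
  out <- sapply(seq_len(K), function(k) {
    membership_frequencies(within_harvest_value(g, gh, k),
                           config$n_selected, decreasing = dec)
  })
  dimnames(out) <- list(colnames(g), dimnames(gh)[[3]])
  out
}

#' Pairwise probability of superior performance within each harvest
#'
#' @inheritParams prob_superior_performance
#' @return a `K x I x I` array; slice `k` is the pairwise win-probability
#'   matrix on the within-harvest values `g_i + gh_ik`.
#' @export
pairwise_prob_performance_within <- function(draws) {
  g <- g_matrix(draws); gh <- gh_array(draws)
  K <- dim(gh)[3]; I <- ncol(g)
  out <- array(NA_real_, c(K, I, I),
               dimnames = list(dimnames(gh)[[3]], colnames(g), colnames(g)))
  for (k in seq_len(K)) {
    out[k, , ] <- pairwise_frequencies(within_harvest_value(g, gh, k),
                                       decreasing = TRUE)
  }
  out
}

#' Probability of superior stability within each harvest
#'
#' The within-harvest dispersion of genotype `i` at harvest `k` in draw `s`
#' is taken as the squared interaction magnitude `(gh_ik)^2` - the per-draw,
#' per-harvest analogue of the across-harvest interaction variance, with the
#' same smaller-is-more-stable reading.  Per harvest, the `n_selected`
#' genotypes with the smallest value are selected and membership frequencies
#' reported.
#'
#' @inheritParams prob_superior_performance
#' @return an `I x K` probability matrix; columns sum to `n_selected`.
#' @export
prob_superior_stability_within <- function(draws,
                                           config = selection_config()) {
  gh <- gh_array(draws)
  K <- dim(gh)[3]; S <- dim(gh)[1]; I <- dim(gh)[2]
  out <- sapply(seq_len(K), function(k) {
    membership_frequencies(matrix(gh[, , k]^2, S, I,
                                  dimnames = list(NULL, dimnames(gh)[[2]])),
                           config$n_selected, decreasing = FALSE)
  })
  dimnames(out) <- list(dimnames(gh)[[2]], dimnames(gh)[[3]])
  out
}

#' Full probability report
#'
#' Computes every selection probability in one pass: marginal and pairwise
#' probabilities of superior performance and stability, and their
#' within-harvest variants.
#'
#' @inheritParams prob_superior_performance
#' @return an object of class `probability_report`.
#' @export
probability_report <- function(draws, config = selection_config()) {
  structure(
    list(perf_marginal = prob_superior_performance(draws, config),
         stab_marginal = prob_superior_stability(draws, config),
         perf_pairwise = pairwise_prob_performance(draws),
         stab_pairwise = pairwise_prob_stability(draws),
         perf_within = prob_superior_performance_within(draws, config),
         perf_pairwise_within = pairwise_prob_performance_within(draws),
         stab_within = prob_superior_stability_within(draws, config),
         config = config),
    class = "probability_report"
  )
}

#' @export
print.probability_report <- function(x, ...) {
  ord <- order(x$perf_marginal, decreasing = TRUE)
  top <- names(x$perf_marginal)[ord][seq_len(min(4L, length(ord)))]
  cat(sprintf("Probability report (top %d of %d genotypes per draw, S = %d)\n",
              x$config$n_selected, length(x$perf_marginal),
              attr(x$perf_marginal, "S")))
  cat("  highest performance probabilities:",
      paste(sprintf("%s %.3f", top, x$perf_marginal[ord][seq_along(top)]),
            collapse = ", "), "\n")
  so <- order(x$stab_marginal, decreasing = TRUE)
  tops <- names(x$stab_marginal)[so][seq_len(min(4L, length(so)))]
  cat("  highest stability probabilities:  ",
      paste(sprintf("%s %.3f", tops, x$stab_marginal[so][seq_along(tops)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a probability report as tidy CSV files plus a JSON summary
#'
#' One CSV per metric (long format: genotype \[, harvest, opponent\],
#' probability, count, S) and a `probabilities.json` summary, written into
#' `dir`.
#'
#' @param report a `probability_report`.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_probability_report <- function(report, dir) {
  stopifnot(inherits(report, "probability_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(dir, paste0(name, ".csv"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    files <<- c(files, path)
  }
  marg <- function(v) {
    data.frame(genotype = names(v), probability = as.numeric(v),
               count = attr(v, "count"), S = attr(v, "S"))
  }
  put(marg(report$perf_marginal), "performance_marginal")
  put(marg(report$stab_marginal), "stability_marginal")
  pair <- function(m) {
    cnt <- attr(m, "count")
    df <- expand.grid(genotype = rownames(m), opponent = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$probability <- as.vector(m)
    df$count <- as.vector(cnt)
    df$S <- attr(m, "S")
    df[df$genotype != df$opponent, ]
  }
  put(pair(report$perf_pairwise), "performance_pairwise")
  put(pair(report$stab_pairwise), "stability_pairwise")
  within_df <- function(m) {
    df <- expand.grid(genotype = rownames(m), harvest = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    df$probability <- as.vector(m)
    df
  }
  put(within_df(report$perf_within), "performance_within")
  put(within_df(report$stab_within), "stability_within")
  jsonlite::write_json(
    list(n_selected = report$config$n_selected,
         S = attr(report$perf_marginal, "S"),
         performance = as.list(report$perf_marginal),
         stability = as.list(report$stab_marginal)),
    file.path(dir, "probabilities.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(dir, "probabilities.json")))
}
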