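# Frequentist baseline: REML variance components and BLUPs for the mixed
# model
#   y = 1 mu + X1 r + X2 h + Z1 g + Z2 gh + Z3 p + e
# with block and harvest fixed, genotype, genotype-by-harvest and
# permanent-environment (plot) effects random, and a residual covariance
# that is either a single variance (homogeneous) or one variance per
# harvest (diagonal, the F-DG model).  Homogeneous fits use lme4; diagonal
# fits use glmmTMB with a per-harvest dispersion model.  Both maximize the
# restricted likelihood.

#' Fit the frequentist mixed model by REML
#'
#' Estimates the variance components and predicts the random effects (BLUP)
#' for a multi-harvest trial.  With a single harvest in the table the model
#' degenerates to `yield ~ block + (1 | genotype)`: the interaction and the
#' permanent-environment effect are not identifiable and are dropped.
#'
#' @param table a phenotype table.
#' @param residual_structure `"diagonal"` (per-harvest residual variances,
#'   F-DG) or `"homogeneous"`.
#' @return an object of class `freq_fit`: variance components `var_g`,
#'   `var_gh`, `var_p`, `var_e` (length K under the diagonal structure),
#'   `fixed_effects`, BLUPs `blup_g` (length I), `blup_gh` (I x K matrix),
#'   `blup_p` (named vector), `reml_loglik`, `converged`, and the underlying
#'   fitted model object in `$fit`.
#' @export
reml_fit <- function(table, residual_structure = c("diagonal",
                                                   "homogeneous")) {
  table <- as_phenotype_table(table)
  residual_structure <- match.arg(residual_structure)
  d <- droplevels(as.data.frame(table))
  I <- nlevels(d$genotype); J <- nlevels(d$block); K <- nlevels(d$harvest)
  if (I < 2L || J < 2L) {
    stop("need at least 2 genotypes and 2 blocks", call. = FALSE)
  }
  glabs <- levels(d$genotype); hlabs <- levels(d$harvest)
  multi_harvest <- K >= 2L

  form <- if (multi_harvest) {
    yield ~ block + harvest + (1 | genotype) + (1 | genotype:harvest) +
      (1 | genotype:block)
  } else {
    yield ~ block + (1 | genotype)
  }

  if (residual_structure == "homogeneous" || !multi_harvest) {
    fit <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        optCtrl = list(xtol_abs = 1e-10, ftol_abs = 1e-10)))
    vc <- as.data.frame(lme4::VarCorr(fit))
    getv <- function(grp) {
      v <- vc$vcov[vc$grp == grp]
      if (length(v)) v else 0
    }
    var_e <- getv("Residual")
    re <- lme4::ranef(fit)
    fe <- lme4::fixef(fit)
    ll <- as.numeric(stats::logLik(fit))
    conv <- length(fit@optinfo$conv$lme4) == 0L ||
      is.null(fit@optinfo$conv$lme4$code) || fit@optinfo$conv$lme4$code == 0L
  } else {
    fit <- glmmTMB::glmmTMB(form, dispformula = ~ 0 + harvest, data = d,
                            REML = TRUE, family = stats::gaussian())
    vc <- glmmTMB::VarCorr(fit)$cond
    getv <- function(grp) {
      if (!is.null(vc[[grp]])) as.numeric(vc[[grp]][1, 1]) else 0
    }
    # gaussian dispformula coefficients are log residual SDs per harvest
    var_e <- exp(glmmTMB::fixef(fit)$disp)^2
    names(var_e) <- hlabs
    re <- glmmTMB::ranef(fit)$cond
    fe <- glmmTMB::fixef(fit)$cond
    ll <- as.numeric(stats::logLik(fit))
    conv <- isTRUE(fit$fit$convergence == 0)
  }

  pick_re <- function(name) {
    if (!is.null(re[[name]])) {
      stats::setNames(re[[name]][[1]], rownames(re[[name]]))
    } else NULL
  }
  blup_g <- pick_re("genotype")
  blup_g <- blup_g[glabs]
  names(blup_g) <- glabs

  blup_gh <- NULL
  if (multi_harvest) {
    v <- pick_re("genotype:harvest")
    blup_gh <- matrix(0, I, K, dimnames = list(glabs, hlabs))
    if (!is.null(v)) {
      parts <- strsplit(names(v), ":", fixed = TRUE)
      gi <- match(vapply(parts, `[`, "", 1L), glabs)
      hi <- match(vapply(parts, `[`, "", 2L), hlabs)
      blup_gh[cbind(gi, hi)] <- v
    }
  }
  blup_p <- if (multi_harvest) pick_re("genotype:block") else NULL

  structure(
    list(residual_structure = if (multi_harvest) residual_structure
         else "homogeneous",
         var_g = getv("genotype"),
         var_gh = if (multi_harvest) getv("genotype:harvest") else NA_real_,
         var_p = if (multi_harvest) getv("genotype:block") else NA_real_,
         var_e = var_e,
         fixed_effects = fe,
         blup_g = blup_g, blup_gh = blup_gh, blup_p = blup_p,
         reml_loglik = ll, converged = conv,
         labels = list(genotype = glabs, block = levels(d$block),
                       harvest = hlabs),
         fit = fit),
    class = "freq_fit"
  )
}

#' @export
print.freq_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s residuals)%s\n", x$residual_structure,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  var_g %.4g  var_gh %.4g  var_p %.4g\n",
              x$var_g, x$var_gh, x$var_p))
  cat("  var_e:", paste(signif(x$var_e, 4), collapse = " "), "\n")
  invisible(x)
}

#' Likelihood-ratio test for one random effect
#'
#' Refits the model without the requested random effect and compares
#' restricted log-likelihoods: `statistic = 2 * (logLik_full -
#' logLik_reduced)`, referred to a chi-square with 1 degree of freedom.
#' This reference is conservative at the variance boundary.
#'
#' @param table a phenotype table (at least 2 harvests).
#' @param effect which random effect to test: `"g"` (genotype), `"gh"`
#'   (interaction) or `"p"` (permanent environment).
#' @param residual_structure passed to [reml_fit()].
#' @return list with `statistic` (clamped at 0), `p_value`, and both
#'   log-likelihoods.
#' @export
lrt_random_effect <- function(table, effect = c("g", "gh", "p"),
                              residual_structure = c("diagonal",
                                                     "homogeneous")) {
  effect <- match.arg(effect)
  residual_structure <- match.arg(residual_structure)
  table <- as_phenotype_table(table)
  full <- reml_fit(table, residual_structure)
  if (!full$converged) warning("full model did not converge cleanly")
  d <- droplevels(as.data.frame(table))
  term <- c(g = "(1 | genotype)", gh = "(1 | genotype:harvest)",
            p = "(1 | genotype:block)")[[effect]]
  keep <- setdiff(c("(1 | genotype)", "(1 | genotype:harvest)",
                    "(1 | genotype:block)"), term)
  form <- stats::as.formula(paste("yield ~ block + harvest +",
                                  paste(keep, collapse = " + ")))
  if (residual_structure == "homogeneous") {
    red <- lme4::lmer(form, data = d, REML = TRUE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore"))
    ll_red <- as.numeric(stats::logLik(red))
  } else {
    red <- glmmTMB::glmmTMB(form, dispformula = ~ 0 + harvest, data = d,
                            REML = TRUE, family = stats::gaussian())
    if (!isTRUE(red$fit$convergence == 0)) {
      stop("reduced model did not converge", call. = FALSE)
    }
    ll_red <- as.numeric(stats::logLik(red))
  }
  stat <- max(0, 2 * (full$reml_loglik - ll_red))
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       loglik_full = full$reml_loglik, loglik_reduced = ll_red)
}

#' Genotype-by-harvest genotypic values from a REML fit
#'
#' The per-harvest genotypic value of genotype `i` at harvest `k`, defined
#' as `BLUP(g_i) + BLUP(gh_ik)` - the quantity whose per-harvest maximum
#' defines the ideotype for the persistence index.
#'
#' @param fit a `freq_fit` from a multi-harvest table.
#' @return an `I x K` matrix.
#' @export
genotype_harvest_values <- function(fit) {
  stopifnot(inherits(fit, "freq_fit"))
  if (is.null(fit$blup_gh)) {
    stop("fit has a single harvest; per-harvest values are undefined",
         call. = FALSE)
  }
  fit$blup_g + fit$blup_gh
}

#' Persistence index
#'
#' An ecological-stability measure: per harvest the ideotype is the maximum
#' genotypic value over genotypes; each genotype accumulates the squared
#' distance to the ideotype over harvests,
#' `d_i = sum_k (v_ik - max_i' v_i'k)^2`, and persistence is the normalized
#' reciprocal `P_i = (1/(d_i + eps)) / sum_i' (1/(d_i' + eps))`.  Larger
#' `P_i` means the genotype tracks the best performer more closely across
#' harvests.  The `P_i` sum to 1; a `percent` column (x100) is also
#' reported.
#'
#' @param values `I x K` matrix of per-harvest genotypic values, typically
#'   [genotype_harvest_values()] output (rows named by genotype).
#' @param eps small positive guard against division by zero when a genotype
#'   sits exactly at the ideotype in every harvest (default `1e-8`).
#' @return an object of class `persistence_report`: `persistence` (named,
#'   sums to 1), `percent`, `distance` (the `d_i`), `ideotype_by_harvest`,
#'   `ranking` (labels, most persistent first).
#' @export
persistence_index <- function(values, eps = 1e-8) {
  stopifnot(is.matrix(values), nrow(values) >= 2L, ncol(values) >= 1L)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%d", seq_len(nrow(values)))
  }
  gmax <- apply(values, 2L, max)
  d <- rowSums((values - matrix(gmax, nrow(values), ncol(values),
                                byrow = TRUE))^2)
  if (all(d == 0)) {
    warning("all genotypes sit at the ideotype; persistence is uniform")
    P <- rep(1 / nrow(values), nrow(values))
    names(P) <- rownames(values)
  } else {
    raw <- 1 / (d + eps)
    P <- raw / sum(raw)
  }
  structure(
    list(persistence = P, percent = 100 * P, distance = d,
         ideotype_by_harvest = gmax,
         ranking = names(sort(P, decreasing = TRUE))),
    class = "persistence_report"
  )
}

#' @export
print.persistence_report <- function(x, ...) {
  top <- x$ranking[seq_len(min(4L, length(x$ranking)))]
  cat("Persistence (sums to 1); most persistent:",
      paste(sprintf("%s %.3f", top, x$persistence[top]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Ranks both vectors (average ranks for ties) and returns their Pearson
#' correlation, which reduces to `1 - 6 * sum(d^2) / (n (n^2 - 1))` when
#' there are no ties.
#'
#' @param values_a,values_b numeric vectors of equal length `n >= 2`.
#' @return the correlation in `[-1, 1]`; `NA` with a warning when either
#'   vector is constant (undefined).
#' @export
spearman_rho <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("vectors must have equal length", call. = FALSE)
  }
  stopifnot(length(values_a) >= 2L)
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0) {
    warning("constant vector; Spearman correlation is undefined")
    return(NA_real_)
  }
  stats::cor(rank(values_a), rank(values_b))
}

#' Rank agreement between frequentist persistence and Bayesian stability
#'
#' Aligns the persistence values with the posterior stability probabilities
#' by genotype label and returns their Spearman correlation.  Both measures
#' read "larger = more stable", so positive correlation means the two
#' paradigms rank the genotypes similarly.
#'
#' @param freq a `persistence_report`.
#' @param bayes_stab named vector of stability probabilities
#'   ([prob_superior_stability()]).
#' @return Spearman correlation.
#' @export
compare_rankings <- function(freq, bayes_stab) {
  stopifnot(inherits(freq, "persistence_report"))
  a <- freq$persistence
  if (is.null(names(a)) || is.null(names(bayes_stab)) ||
      !setequal(names(a), names(bayes_stab))) {
    stop("genotype label sets do not match", call. = FALSE)
  }
  spearman_rho(as.numeric(a), as.numeric(bayes_stab[names(a)]))
}
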