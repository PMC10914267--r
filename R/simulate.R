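#' Multi-harvest trial design
#'
#' Describes a randomized complete-block perennial trial in which every
#' genotype appears in every block and is measured at every harvest.  The
#' defaults mirror a typical advanced citrus rootstock-by-scion evaluation:
#' 24 selection candidates, 4 blocks, 12 harvests, plot-mean fruit yield in
#' kg/tree.
#'
#' @param n_genotypes,n_blocks,n_harvests factor level counts, each >= 2.
#' @param grand_mean overall mean yield (kg/tree).
#' @return an object of class `trial_design`.
#' @seealso [variance_truth()], [simulate_trial()]
#' @export
trial_design <- function(n_genotypes = 24, n_blocks = 4, n_harvests = 12,
                         grand_mean = 40) {
  stop_if_not_scalar_count(n_genotypes, "n_genotypes", min = 2L)
  stop_if_not_scalar_count(n_blocks, "n_blocks", min = 2L)
  stop_if_not_scalar_count(n_harvests, "n_harvests", min = 2L)
  stopifnot(is.numeric(grand_mean), length(grand_mean) == 1L,
            is.finite(grand_mean))
  structure(
    list(n_genotypes = as.integer(n_genotypes),
         n_blocks = as.integer(n_blocks),
         n_harvests = as.integer(n_harvests),
         grand_mean = as.numeric(grand_mean)),
    class = "trial_design"
  )
}

#' True variance components for trial simulation
#'
#' Bundles the variance components of the simulation model
#' `y_ijk = mu + g_i + r_j + h_k + gh_ik + p_ij + e_ijk`:
#' genotypic variance, genotype-by-harvest interaction variance, permanent
#' environment (plot) variance, block and harvest variances, and the residual
#' variance, which may be a single value (homogeneous) or one value per
#' harvest (heterogeneous, the situation that motivates the diagonal residual
#' models).
#'
#' @param var_g,var_gh,var_p,var_block,var_harvest nonnegative variances
#'   (kg^2/tree^2).
#' @param var_e nonnegative residual variance(s); length 1 or `n_harvests`.
#' @return an object of class `variance_truth`.
#' @export
variance_truth <- function(var_g, var_gh, var_p, var_block, var_harvest,
                           var_e) {
  comps <- list(var_g = var_g, var_gh = var_gh, var_p = var_p,
                var_block = var_block, var_harvest = var_harvest)
  for (nm in names(comps)) {
    v <- comps[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single nonnegative number", nm),
           call. = FALSE)
    }
  }
  if (length(var_e) < 1L || any(!is.finite(var_e)) || any(var_e < 0)) {
    stop("`var_e` must be nonnegative and finite", call. = FALSE)
  }
  structure(
    list(var_g = as.numeric(var_g), var_gh = as.numeric(var_gh),
         var_p = as.numeric(var_p), var_block = as.numeric(var_block),
         var_harvest = as.numeric(var_harvest), var_e = as.numeric(var_e)),
    class = "variance_truth"
  )
}

#' Reference variance regime for a 12-harvest citrus yield trial
#'
#' The default simulation regime used throughout the package: a genotypic
#' variance of 2.44, genotype-by-harvest interaction variance of 0.76,
#' permanent-environment variance of 0.26, and strongly heterogeneous
#' per-harvest residual variances spanning roughly 0.9 to 493 kg^2/tree^2,
#' the magnitudes reported for mature multi-harvest acid lime yield trials.
#' Residual variance grows steeply over harvests as trees mature and yields
#' (and their noise) increase.
#'
#' Block and harvest variances are not estimated quantities in that setting
#' (both are treated as fixed in the frequentist analysis); the simulator
#' uses moderate values: block variance 0.5 and harvest variance 100
#' (harvest-to-harvest mean swings of about +/- 10 kg/tree, consistent with
#' the strong seasonal and ontogenetic trends of young orchards).
#'
#' @return a [variance_truth()] object with 12 residual variances.
#' @export
truth_preset_heterogeneous <- function() {
  variance_truth(
    var_g = 2.44, var_gh = 0.76, var_p = 0.26,
    var_block = 0.5, var_harvest = 100,
    var_e = c(1.24, 0.91, 0.97, 5.88, 3.60, 4.52,
              11.23, 26.71, 418.67, 146.63, 413.08, 492.71)
  )
}

default_labels <- function(design) {
  list(
    genotype = sprintf("G%d", seq_len(design$n_genotypes)),
    block = sprintf("B%d", seq_len(design$n_blocks)),
    harvest = sprintf("H%d", seq_len(design$n_harvests))
  )
}

#' Simulate a multi-harvest phenotype table with known ground truth
#'
#' Generates one record per genotype x block x harvest combination from the
#' additive model `y_ijk = mu + g_i + r_j + h_k + gh_ik + p_ij + e_ijk`.
#' Every effect is drawn independently from a zero-mean normal with the
#' corresponding variance in `truth`; residuals use the harvest-specific
#' variance `var_e[k]` (recycled when `var_e` has length 1).  The
#' permanent-environment effect `p_ij` is attached to the genotype-block
#' combination (the plot) and is constant across harvests.  Effects carry no
#' sum-to-zero constraint; the grand mean absorbs location, matching the
#' exchangeable-effect assumption of the hierarchical model that analyses
#' such data.
#'
#' @param design a [trial_design()].
#' @param truth a [variance_truth()]; `var_e` must have length 1 or
#'   `design$n_harvests`.
#' @param seed integer seed; the same `(design, truth, seed)` always yields
#'   an identical table.
#' @param missing_rate optional fraction in `[0, 1)` of records dropped at
#'   random after generation, to exercise unbalanced fits (default 0).
#' @return a list with components
#'   \describe{
#'     \item{table}{a `data.frame` with columns `genotype`, `block`,
#'       `harvest` (factors) and `yield` (numeric, kg/tree); complete
#'       crossing unless `missing_rate > 0`.}
#'     \item{ledger}{the simulated truth: vectors `g`, `r`, `h`, matrices
#'       `gh` (genotype x harvest) and `p` (genotype x block), the
#'       `variance_truth`, the design and the seed.}
#'   }
#' @examples
#' sim <- simulate_trial(trial_design(6, 2, 3, grand_mean = 30),
#'                       variance_truth(2, 0.5, 0.2, 0.5, 9, 4), seed = 1)
#' head(sim$table)
#' @export
simulate_trial <- function(design, truth, seed, missing_rate = 0) {
  stopifnot(inherits(design, "trial_design"), inherits(truth, "variance_truth"))
  I <- design$n_genotypes; J <- design$n_blocks; K <- design$n_harvests
  if (!length(truth$var_e) %in% c(1L, K)) {
    stop(sprintf("`var_e` must have length 1 or n_harvests (%d), got %d",
                 K, length(truth$var_e)), call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("`missing_rate` must be in [0, 1)", call. = FALSE)
  }
  labs <- default_labels(design)
  var_e <- rep_len(truth$var_e, K)

  with_seed(seed, {
    g <- stats::rnorm(I, 0, sqrt(truth$var_g))
    r <- stats::rnorm(J, 0, sqrt(truth$var_block))
    h <- stats::rnorm(K, 0, sqrt(truth$var_harvest))
    gh <- matrix(stats::rnorm(I * K, 0, sqrt(truth$var_gh)), I, K,
                 dimnames = list(labs$genotype, labs$harvest))
    p <- matrix(stats::rnorm(I * J, 0, sqrt(truth$var_p)), I, J,
                dimnames = list(labs$genotype, labs$block))

    tab <- expand.grid(genotype = factor(labs$genotype, levels = labs$genotype),
                       block = factor(labs$block, levels = labs$block),
                       harvest = factor(labs$harvest, levels = labs$harvest),
                       KEEP.OUT.ATTRS = FALSE)
    i <- as.integer(tab$genotype); j <- as.integer(tab$block)
    k <- as.integer(tab$harvest)
    e <- stats::rnorm(nrow(tab), 0, sqrt(var_e)[k])
    tab$yield <- design$grand_mean + g[i] + r[j] + h[k] +
      gh[cbind(i, k)] + p[cbind(i, j)] + e
    if (missing_rate > 0) {
      keep <- stats::runif(nrow(tab)) >= missing_rate
      tab <- tab[keep, , drop = FALSE]
      rownames(tab) <- NULL
    }

    names(g) <- labs$genotype; names(r) <- labs$block; names(h) <- labs$harvest
    ledger <- structure(
      list(g = g, r = r, h = h, gh = gh, p = p,
           variance_truth = truth, design = design, seed = as.integer(seed)),
      class = "truth_ledger"
    )
    list(table = as_phenotype_table(tab), ledger = ledger)
  })
}

#' Restrict a phenotype table to selected harvests
#'
#' Keeps only the records whose harvest label appears in `harvest_ids`,
#' preserving record order and the table schema.  Useful for analysing the
#' first few harvests of a long trial.
#'
#' @param table a phenotype table (see [simulate_trial()], [read_phenotypes()]).
#' @param harvest_ids character vector of harvest labels to keep (may be
#'   empty, giving an empty table with the same columns).
#' @return the filtered phenotype table.
#' @export
subset_harvests <- function(table, harvest_ids) {
  table <- as_phenotype_table(table)
  harvest_ids <- as.character(harvest_ids)
  known <- levels(table$harvest)
  bad <- setdiff(harvest_ids, known)
  if (length(bad)) {
    stop("unknown harvest id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- table[as.character(table$harvest) %in% harvest_ids, , drop = FALSE]
  out$harvest <- factor(as.character(out$harvest),
                        levels = intersect(known, harvest_ids))
  out$genotype <- factor(as.character(out$genotype),
                         levels = levels(table$genotype))
  out$block <- factor(as.character(out$block), levels = levels(table$block))
  rownames(out) <- NULL
  class(out) <- class(table)
  out
}

#' Serialize a simulation truth ledger to JSON
#'
#' @param ledger a `truth_ledger` from [simulate_trial()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "truth_ledger"))
  x <- list(
    design = unclass(ledger$design),
    variance_truth = unclass(ledger$variance_truth),
    seed = ledger$seed,
    g = as.list(ledger$g), r = as.list(ledger$r), h = as.list(ledger$h),
    gh = apply(ledger$gh, 1, as.list, simplify = FALSE),
    p = apply(ledger$p, 1, as.list, simplify = FALSE)
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: %d genotypes x %d blocks x %d harvests (mean %.2f kg/tree)\n",
              x$n_genotypes, x$n_blocks, x$n_harvests, x$grand_mean))
  invisible(x)
}

#' @export
print.variance_truth <- function(x, ...) {
  cat("True variance components (kg^2/tree^2):\n")
  cat(sprintf("  g: %.4g  gh: %.4g  p: %.4g  block: %.4g  harvest: %.4g\n",
              x$var_g, x$var_gh, x$var_p, x$var_block, x$var_harvest))
  cat("  residual:", paste(signif(x$var_e, 4), collapse = " "), "\n")
  invisible(x)
}
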