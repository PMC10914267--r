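# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a stream-specific 32-bit seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %%
               2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inverse-gamma random draws
#'
#' Draws from the inverse-gamma distribution with the given shape and scale
#' (the distribution of 1/X when X ~ Gamma(shape, rate = scale)).
#'
#' @param n number of draws.
#' @param shape,scale positive parameters.
#' @return numeric vector of positive draws.
#' @keywords internal
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' Half-Cauchy draws via the inverse-gamma scale mixture
#'
#' Samples sigma ~ half-Cauchy(0, phi) using the two-level inverse-gamma
#' representation sigma^2 | a ~ IG(1/2, 1/a), a ~ IG(1/2, 1/phi^2).  The same
#' augmentation drives the Gibbs updates of every scale parameter in
#' [fit_bayes()], so this function doubles as a direct check that the mixture
#' reproduces the half-Cauchy law.
#'
#' @param n number of draws.
#' @param phi positive scale of the half-Cauchy.
#' @return numeric vector of positive draws.
#' @export
rhalfcauchy_mix <- function(n, phi) {
  stopifnot(phi > 0)
  a <- rinvgamma(n, 1 / 2, 1 / phi^2)
  sqrt(rinvgamma(n, 1 / 2, 1 / a))
}

# log density of half-Cauchy(0, phi) at sigma > 0
dhalfcauchy_log <- function(sigma, phi) {
  ifelse(sigma > 0, log(2) + stats::dcauchy(sigma, 0, phi, log = TRUE), -Inf)
}

stop_if_not_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
}
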