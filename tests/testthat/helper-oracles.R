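# Shared fixtures and independent brute-force oracles.
#
# The naive_* functions re-derive every selection probability with explicit
# loops and no shared code with the package internals; agreement must be
# exact because both sides count integer events over the same S draws.

# Minimal posterior_draws-like object built from explicit arrays.
make_draws <- function(g = NULL, gh = NULL, mu = NULL,
                       genotypes = NULL, harvests = NULL) {
  S <- if (!is.null(g)) nrow(g) else dim(gh)[1]
  I <- if (!is.null(g)) ncol(g) else dim(gh)[2]
  genotypes <- genotypes %||% sprintf("G%d", seq_len(I))
  if (!is.null(g)) colnames(g) <- genotypes
  if (!is.null(gh)) {
    harvests <- harvests %||% sprintf("H%d", seq_len(dim(gh)[3]))
    dimnames(gh) <- list(NULL, genotypes, harvests)
  }
  structure(list(mu = mu %||% numeric(S), g = g, gh = gh,
                 effects = c(if (!is.null(g)) "g", if (!is.null(gh)) "gh")),
            class = "posterior_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random draws fixture of given size under a fixed seed.
random_draws <- function(S, I, K, seed) {
  set.seed(seed)
  make_draws(g = matrix(rnorm(S * I), S, I),
             gh = array(rnorm(S * I * K), c(S, I, K)))
}

naive_top <- function(v, n, decreasing) {
  # explicit selection-sort; ties to lowest index
  chosen <- integer(0)
  cand <- seq_along(v)
  for (step in seq_len(n)) {
    best <- cand[1]
    for (x in cand) {
      if ((decreasing && v[x] > v[best]) || (!decreasing && v[x] < v[best])) {
        best <- x
      }
    }
    chosen <- c(chosen, best)
    cand <- setdiff(cand, best)
  }
  chosen
}

naive_gh_var <- function(gh) {
  S <- dim(gh)[1]; I <- dim(gh)[2]
  v <- matrix(0, S, I)
  for (s in seq_len(S)) {
    for (i in seq_len(I)) v[s, i] <- var(gh[s, i, ])
  }
  v
}

naive_marginal <- function(value, n, decreasing) {
  S <- nrow(value); I <- ncol(value)
  counts <- integer(I)
  for (s in seq_len(S)) {
    sel <- naive_top(value[s, ], n, decreasing)
    counts[sel] <- counts[sel] + 1L
  }
  counts / S
}

naive_pairwise <- function(value, decreasing) {
  S <- nrow(value); I <- ncol(value)
  out <- matrix(NA_real_, I, I)
  for (a in seq_len(I)) {
    for (b in seq_len(I)) {
      if (a == b) next
      wins <- 0L
      for (s in seq_len(S)) {
        ok <- if (decreasing) value[s, a] > value[s, b]
              else value[s, a] < value[s, b]
        if (ok) wins <- wins + 1L
      }
      out[a, b] <- wins / S
    }
  }
  out
}

naive_perf_marginal <- function(d, n) naive_marginal(d$g, n, TRUE)
naive_stab_marginal <- function(d, n) naive_marginal(naive_gh_var(d$gh), n, FALSE)
naive_perf_pairwise <- function(d) naive_pairwise(d$g, TRUE)
naive_stab_pairwise <- function(d) naive_pairwise(naive_gh_var(d$gh), FALSE)

naive_perf_within <- function(d, n) {
  K <- dim(d$gh)[3]
  sapply(seq_len(K), function(k) {
    naive_marginal(d$g + d$gh[, , k], n, TRUE)
  })
}

naive_pairwise_within <- function(d) {
  K <- dim(d$gh)[3]; I <- ncol(d$g)
  out <- array(NA_real_, c(K, I, I))
  for (k in seq_len(K)) out[k, , ] <- naive_pairwise(d$g + d$gh[, , k], TRUE)
  out
}

naive_stab_within <- function(d, n) {
  K <- dim(d$gh)[3]
  sapply(seq_len(K), function(k) {
    naive_marginal(d$gh[, , k]^2, n, FALSE)
  })
}

# small trial fixture used by several fitting tests
small_sim <- function(seed = 42) {
  simulate_trial(trial_design(8, 2, 3, grand_mean = 30),
                 variance_truth(var_g = 2, var_gh = 0.5, var_p = 0.2,
                                var_block = 0.5, var_harvest = 9,
                                var_e = c(1, 2, 4)),
                 seed = seed)
}

# drop all attributes except dim (compare against plain naive matrices)
strip <- function(m) {
  attributes(m) <- list(dim = dim(m))
  m
}

# keep dim + dimnames, drop bookkeeping attributes (count, S)
strip_named <- function(m) {
  dn <- dimnames(m)
  attributes(m) <- list(dim = dim(m), dimnames = dn)
  m
}

# named numeric vector without bookkeeping attributes
named_probs <- function(v) setNames(as.numeric(v), names(v))
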