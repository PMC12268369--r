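# Shared fixtures and independent oracles for the suite.

# A tiny hand-written long table: 2 samples, 2 segments, 3 formulas.
tiny_long <- function() {
  tibble::tribble(
    ~sample_id, ~segment_start, ~formula, ~intensity,
    "S1", 12.3, "C6H12O6", 2,
    "S1", 13.3, "C6H12O6", 4,
    "S1", 12.3, "C10H16O8", 5,
    "S2", 12.3, "C6H12O6", 6,
    "S2", 13.3, "C16H26N2O8", 1,
    "S2", 13.3, "C10H16O8", 3
  )
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("S1", "S2"),
    c475 = c(0.01, 0.05),
    doc = c(50, 100)
  )
}

# Small but fully featured synthetic dataset, memoised per session.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(
        generator_config(n_samples = 40, n_formulas = 60, seed = 101)
      )
    }
    cache
  }
})

# Path-dependent conditional expectation of a flat tree for a coalition S
# (1-based feature indices): follow the split when its feature is in S,
# otherwise average the children weighted by training cover.
tree_expvalue <- function(tr, x, S) {
  rec <- function(nd) {
    if (tr$left[nd + 1] < 0) return(tr$value[nd + 1])
    f <- tr$feature[nd + 1] + 1
    if (f %in% S) {
      if (x[f] <= tr$threshold[nd + 1]) rec(tr$left[nd + 1]) else rec(tr$right[nd + 1])
    } else {
      (tr$cover[tr$left[nd + 1] + 1] * rec(tr$left[nd + 1]) +
         tr$cover[tr$right[nd + 1] + 1] * rec(tr$right[nd + 1])) /
        tr$cover[nd + 1]
    }
  }
  rec(0)
}

# Brute-force Shapley values by enumerating all coalitions.
brute_force_shapley <- function(tr, x, p) {
  subsets <- function(v) {
    if (length(v) == 0) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(u) c(v[1], u)))
  }
  phi <- numeric(p)
  for (i in seq_len(p)) {
    for (S in subsets(setdiff(seq_len(p), i))) {
      w <- factorial(length(S)) * factorial(p - length(S) - 1) / factorial(p)
      phi[i] <- phi[i] + w * (tree_expvalue(tr, x, c(S, i)) -
                                tree_expvalue(tr, x, S))
    }
  }
  phi
}

# Exact two-sided signed-rank p-value by enumerating all sign assignments.
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
}

# Noise-free linear regression problem: y exactly linear in a few features.
linear_problem <- function(n = 60, p = 8, informative = 3, seed = 1,
                           noise_sd = 0) {
  withr::with_seed(seed, {
    X <- matrix(runif(n * p), nrow = n,
                dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
    beta <- c(seq(2, 1, length.out = informative), rep(0, p - informative))
    y <- as.numeric(X %*% beta) + rnorm(n, 0, noise_sd)
    list(X = X, y = y, beta = beta, informative = colnames(X)[seq_len(informative)])
  })
}
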