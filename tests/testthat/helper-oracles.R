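# Independent brute-force oracles used across the suite. These never call
# the package's forward/Viterbi/EM code paths.

log_mvnorm <- function(x, mean, cov) {
  d <- length(mean)
  L <- chol(cov)
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(L))) + sum(z^2))
}

# log marginal likelihood by summation over all K^T paths
enum_forward_loglik <- function(X, means, covs, A, pi0) {
  T_ <- nrow(X); K <- nrow(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi0[s[1]]) + log_mvnorm(X[1, ], means[s[1], ], covs[, , s[1]])
    if (T_ > 1) for (t in 2:T_)
      v <- v + log(A[s[t - 1], s[t]]) +
        log_mvnorm(X[t, ], means[s[t], ], covs[, , s[t]])
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most probable path by exhaustive enumeration (first maximum kept, and
# expand.grid enumerates the first time index fastest, so ties would go to
# low-index-early paths; test data are continuous so ties do not occur)
enum_viterbi <- function(X, means, covs, A, pi0) {
  T_ <- nrow(X); K <- nrow(means)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1, function(s) {
    v <- log(pi0[s[1]]) + log_mvnorm(X[1, ], means[s[1], ], covs[, , s[1]])
    if (T_ > 1) for (t in 2:T_)
      v <- v + log(A[s[t - 1], s[t]]) +
        log_mvnorm(X[t, ], means[s[t], ], covs[, , s[t]])
    v
  })
  as.integer(paths[which.max(lp), ])
}

# hand-rolled hmm_model construction for oracle comparisons
make_model <- function(means, covs, A, pi0) {
  structure(list(n_states = nrow(means), means = means, covariances = covs,
                 transition_matrix = A, initial_distribution = pi0,
                 restart_scores = NA_real_, selected_restart = 1L,
                 loglik_trace = NA_real_, converged = TRUE, n_iter = 0L),
            class = "hmm_model")
}

random_hmm <- function(K, d, sticky = 0.7) {
  A <- matrix(runif(K * K), K, K) + diag(K) * sticky * K
  A <- A / rowSums(A)
  pi0 <- rep(1 / K, K)
  means <- matrix(rnorm(K * d, sd = 2), K, d)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    W <- matrix(rnorm(d * d, sd = 0.3), d, d)
    covs[, , k] <- diag(d) * 0.5 + crossprod(W)
  }
  list(means = means, covs = covs, A = A, pi0 = pi0)
}

sample_hmm_data <- function(par, T_) {
  K <- nrow(par$means); d <- ncol(par$means)
  s <- integer(T_)
  s[1] <- sample.int(K, 1, prob = par$pi0)
  if (T_ > 1) for (t in 2:T_)
    s[t] <- sample.int(K, 1, prob = par$A[s[t - 1], ])
  X <- matrix(0, T_, d)
  for (t in seq_len(T_))
    X[t, ] <- par$means[s[t], ] + t(chol(par$covs[, , s[t]])) %*% rnorm(d)
  list(X = X, states = s)
}

# exact two-sided signed-rank p-value by enumeration of all sign patterns
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W_all <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  # two-sided: double the smaller tail (classic exact convention)
  2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs))
}

# tiny cohort used by several end-to-end tests
small_cohort_config <- function(...) {
  simulation_config(n_subjects = 4, n_states = 3, n_parcels = 6,
                    session_duration = 30, seed = 42, ...)
}
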