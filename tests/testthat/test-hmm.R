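test_that("single-state fit reduces to sample moments and iid likelihood", {
  set.seed(1)
  X <- matrix(rnorm(500 * 3, mean = 2), 500, 3)   # samples x channels
  m <- fit_hmm(t(X), n_states = 1, n_restarts = 1, seed = 1, ridge = 0)
  expect_equal(as.numeric(m$means), colMeans(X), tolerance = 1e-8)
  S <- crossprod(sweep(X, 2, colMeans(X))) / nrow(X)
  expect_lt(max(abs(m$covariances[, , 1] - S)), 1e-6)

  ll <- log_likelihood(m, t(X))
  direct <- sum(vapply(seq_len(nrow(X)), function(t)
    log_mvnorm(X[t, ], as.numeric(m$means), m$covariances[, , 1]),
    numeric(1)))
  expect_equal(ll, direct, tolerance = 1e-8)
})

test_that("forward log-likelihood equals brute-force path enumeration", {
  set.seed(2)
  for (case in list(c(K = 2, T = 6, d = 2), c(K = 3, T = 5, d = 1))) {
    par <- random_hmm(case["K"], case["d"])
    X <- matrix(rnorm(case["T"] * case["d"]), case["T"], case["d"])
    model <- make_model(par$means, par$covs, par$A, par$pi0)
    expect_equal(log_likelihood(model, t(X)),
                 enum_forward_loglik(X, par$means, par$covs, par$A, par$pi0),
                 tolerance = 1e-8)
  }
})

test_that("viterbi path equals the enumerated most probable path", {
  set.seed(3)
  for (rep in 1:5) {
    K <- sample(2:3, 1)
    T_ <- sample(5:8, 1)
    par <- random_hmm(K, 2)
    sim <- sample_hmm_data(par, T_)
    model <- make_model(par$means, par$covs, par$A, par$pi0)
    decoded <- viterbi_decode(model, t(sim$X))
    expect_equal(decoded$labels,
                 enum_viterbi(sim$X, par$means, par$covs, par$A, par$pi0))
  }
})

test_that("sticky dynamics smooth the decoded path", {
  set.seed(4)
  K <- 2
  A <- matrix(c(0.999, 0.001, 0.001, 0.999), 2, 2)
  means <- matrix(c(-0.3, 0.3), 2, 1)           # weak emissions
  covs <- array(1, c(1, 1, 2))
  par <- list(means = means, covs = covs, A = A, pi0 = c(0.5, 0.5))
  sim <- sample_hmm_data(par, 2000)
  model <- make_model(means, covs, A, c(0.5, 0.5))
  decoded <- viterbi_decode(model, t(sim$X))
  ml_class <- apply(cbind(dnorm(sim$X, -0.3), dnorm(sim$X, 0.3)), 1,
                    which.max)
  expect_lt(sum(diff(decoded$labels) != 0), sum(diff(ml_class) != 0))
})

test_that("EM log-likelihood is monotone and the best restart is kept", {
  set.seed(5)
  par <- random_hmm(2, 2)
  sim <- sample_hmm_data(par, 800)
  m <- fit_hmm(t(sim$X), n_states = 2, n_restarts = 4, seed = 3)
  expect_true(all(diff(m$loglik_trace) > -1e-6 * abs(m$loglik_trace[-1])))
  expect_equal(max(m$restart_scores),
               m$restart_scores[m$selected_restart])
  expect_true(all(m$restart_scores[m$selected_restart] >=
                  m$restart_scores))
})

test_that("two well-separated states are recovered across seeds", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  means <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)   # 5 SD apart
  covs <- array(c(diag(2), diag(2)), c(2, 2, 2))
  for (seed in 1:5) {
    set.seed(seed)
    par <- list(means = means, covs = covs, A = A, pi0 = c(0.5, 0.5))
    sim <- sample_hmm_data(par, 3000)
    m <- fit_hmm(t(sim$X), n_states = 2, n_restarts = 3, seed = seed)
    decoded <- viterbi_decode(m, t(sim$X))
    mm <- match_states(sim$states, decoded$labels, 2)
    expect_gte(mm$accuracy, 0.99)
    ord <- order(mm$permutation)
    A_hat <- m$transition_matrix[ord, ord]
    expect_lt(max(abs(diag(A_hat) - 0.9)), 0.03)
  }
})

test_that("state relabelling permutes the decoded path identically", {
  set.seed(6)
  par <- random_hmm(3, 2)
  sim <- sample_hmm_data(par, 300)
  model <- make_model(par$means, par$covs, par$A, par$pi0)
  base <- viterbi_decode(model, t(sim$X))
  perm <- c(3L, 1L, 2L)
  permuted <- viterbi_decode(permute_model(model, perm), t(sim$X))
  expect_equal(perm[permuted$labels], base$labels)
})

test_that("decoding agrees with an independent reference implementation", {
  # same fitted model, Viterbi run by hmmlearn (python) on the same data
  set.seed(7)
  par <- random_hmm(2, 3)
  sim <- sample_hmm_data(par, 1500)
  m <- fit_hmm(t(sim$X), n_states = 2, n_restarts = 3, seed = 2)
  decoded <- viterbi_decode(m, t(sim$X))

  td <- tempfile(); dir.create(td)
  write.csv(sim$X, file.path(td, "X.csv"), row.names = FALSE)
  write.csv(m$means, file.path(td, "means.csv"), row.names = FALSE)
  write.csv(m$transition_matrix, file.path(td, "A.csv"), row.names = FALSE)
  write.csv(rbind(m$covariances[, , 1], m$covariances[, , 2]),
            file.path(td, "covs.csv"), row.names = FALSE)
  write.csv(data.frame(p = m$initial_distribution),
            file.path(td, "pi.csv"), row.names = FALSE)
  script <- sprintf('
import numpy as np, hmmlearn.hmm as hh
d = "%s"
X = np.loadtxt(d + "/X.csv", delimiter=",", skiprows=1)
means = np.loadtxt(d + "/means.csv", delimiter=",", skiprows=1)
A = np.loadtxt(d + "/A.csv", delimiter=",", skiprows=1)
covs = np.loadtxt(d + "/covs.csv", delimiter=",", skiprows=1).reshape(2, 3, 3)
pi = np.loadtxt(d + "/pi.csv", delimiter=",", skiprows=1)
m = hh.GaussianHMM(n_components=2, covariance_type="full",
                   init_params="", params="")
m.startprob_, m.transmat_, m.means_, m.covars_ = pi, A, means, covs
np.savetxt(d + "/path.csv", m.predict(X) + 1, fmt="%%d")
with open(d + "/ll.txt", "w") as f: f.write(repr(m.score(X)) + "\\n")
', td)
  status <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                    stderr = TRUE)
  ref_path <- scan(file.path(td, "path.csv"), what = integer(),
                   quiet = TRUE)
  agree <- mean(ref_path == decoded$labels)
  expect_gte(agree, 0.98)
  ref_ll <- as.numeric(readLines(file.path(td, "ll.txt")))
  expect_equal(log_likelihood(m, t(sim$X)), ref_ll, tolerance = 1e-6)
  unlink(td, recursive = TRUE)
})

test_that("dimension mismatches are rejected", {
  set.seed(8)
  par <- random_hmm(2, 2)
  model <- make_model(par$means, par$covs, par$A, par$pi0)
  expect_error(log_likelihood(model, matrix(0, 3, 10)), "dimension")
  expect_error(viterbi_decode(model, matrix(0, 3, 10)), "dimension")
})
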