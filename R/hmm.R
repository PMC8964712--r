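#' Fit a Gaussian-observation hidden Markov model
#'
#' Maximum-likelihood fitting by expectation-maximization (Baum-Welch)
#' with multiple random restarts; the restart attaining the highest
#' log-likelihood is retained. Each state emits from a multivariate
#' Gaussian with free mean and full covariance. Restart \code{r} is
#' initialized from a k-means clustering of a random observation
#' subsample, seeded with \code{seed + r - 1}. Covariances are
#' ridge-regularized every M-step (\code{ridge} times the mean diagonal)
#' to prevent collapse.
#'
#' @param observations a \code{concatenated_observations} (component or
#'   parcel space) or a channels x samples numeric matrix.
#' @param n_states number of states K (default 8).
#' @param n_restarts number of EM restarts (default 10).
#' @param seed integer seed for the restart initializations.
#' @param max_iter maximum EM iterations per restart (default 500).
#' @param tol relative log-likelihood gain below which EM stops
#'   (default 1e-6).
#' @param min_iter EM iterations run before the convergence criterion is
#'   consulted (default 10).
#' @param ridge covariance ridge fraction (default 1e-6).
#' @return object of class \code{hmm_model}: state means (K x d),
#'   covariances (d x d x K array), transition matrix, initial
#'   distribution, per-restart scores and the selected restart's
#'   log-likelihood trace.
#' @export
fit_hmm <- function(observations, n_states = 8, n_restarts = 10, seed = 1L,
                    max_iter = 500, tol = 1e-6, ridge = 1e-6,
                    min_iter = 10) {
  X <- .obs_matrix(observations)   # T x d
  K <- as.integer(n_states)
  T_ <- nrow(X); d <- ncol(X)
  if (n_restarts < 1) .stopf("n_restarts must be >= 1")
  if (T_ < K * d)
    warning("few samples relative to K x d; estimates may be unstable")

  best <- NULL
  scores <- numeric(n_restarts)
  for (r in seq_len(n_restarts)) {
    init <- .local_seed(seed + r - 1L, .kmeans_init(X, K))
    fit <- cpp_hmm_em(X, init$means, init$covariances, init$transition_matrix,
                      init$initial_distribution, max_iter, tol, ridge,
                      min_iter)
    scores[r] <- tail(fit$loglik_trace, 1)
    if (is.null(best) || scores[r] > max(scores[seq_len(r - 1)])) best <- fit
  }
  sel <- which.max(scores)
  structure(list(n_states = K,
                 means = best$means,
                 covariances = best$covariances,
                 transition_matrix = best$transition_matrix,
                 initial_distribution = as.numeric(best$initial_distribution),
                 restart_scores = scores, selected_restart = sel,
                 loglik_trace = best$loglik_trace,
                 converged = best$converged, n_iter = best$n_iter),
            class = "hmm_model")
}

# Per-restart k-means initialization on a random subsample. Random
# per-sample responsibilities would place every initial state mean at the
# global mean on long recordings (an exact EM saddle); k-means centers
# break the symmetry decisively, and the subsample draw plus k-means'
# random starting centers give seedable restart diversity.
.kmeans_init <- function(X, K, p_stay = 0.9, max_sub = 10000L) {
  T_ <- nrow(X); d <- ncol(X)
  idx <- if (T_ > max_sub) sample.int(T_, max_sub) else seq_len(T_)
  Xs <- X[idx, , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(Xs, centers = K, iter.max = 10,
                                       nstart = 1))
  means <- unname(km$centers)
  glob <- stats::cov(Xs)
  covs <- array(0, c(d, d, K))
  for (k in seq_len(K)) {
    xk <- Xs[km$cluster == k, , drop = FALSE]
    S <- if (nrow(xk) > d + 2) stats::cov(xk) else glob
    diag(S) <- diag(S) * (1 + 1e-6) + 1e-10
    covs[, , k] <- (S + t(S)) / 2
  }
  A <- matrix(if (K == 1) 1 else (1 - p_stay) / (K - 1), K, K)
  diag(A) <- if (K == 1) 1 else p_stay
  list(means = means, covariances = covs, transition_matrix = A,
       initial_distribution = rep(1 / K, K))
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("hmm_model: %d states, %d components\n", x$n_states,
              ncol(x$means)))
  cat(sprintf("  selected restart %d/%d, loglik %.2f, %s after %d iters\n",
              x$selected_restart, length(x$restart_scores),
              max(x$restart_scores),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Forward-algorithm log marginal likelihood
#'
#' @param model an \code{hmm_model}.
#' @param observations observations matching the model dimension.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(model, observations) {
  X <- .obs_matrix(observations)
  .check_model_dim(model, X)
  cpp_forward_loglik(X, model$means, model$covariances,
                     model$transition_matrix, model$initial_distribution)
}

#' Viterbi decoding of mutually exclusive state visits
#'
#' Returns the single most probable joint state path; ties are broken
#' toward the lower state index, so the result is deterministic given the
#' model and data.
#'
#' @param model an \code{hmm_model}.
#' @param observations a \code{concatenated_observations} or channels x
#'   samples matrix.
#' @return object of class \code{state_path} with per-sample labels in
#'   \code{1:K} and, when available, the segment table and sampling rate
#'   carried over from the observations.
#' @export
viterbi_decode <- function(model, observations) {
  X <- .obs_matrix(observations)
  .check_model_dim(model, X)
  labels <- cpp_viterbi(X, model$means, model$covariances,
                        model$transition_matrix, model$initial_distribution)
  segments <- NULL; fs <- NULL
  if (inherits(observations, "concatenated_observations")) {
    segments <- observations$segments
    fs <- observations$fs
  }
  state_path(labels, n_states = model$n_states, segments = segments, fs = fs)
}

#' Construct a state path
#' @param labels integer labels in \code{1:n_states}.
#' @param n_states number of states.
#' @param segments optional segment table (subject_id, session, first,
#'   last) partitioning the samples.
#' @param fs optional sampling rate in Hz.
#' @return object of class \code{state_path}.
#' @export
state_path <- function(labels, n_states, segments = NULL, fs = NULL) {
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > n_states))
    .stopf("labels must lie in 1..%d", n_states)
  if (!is.null(segments)) .check_segments(segments, length(labels))
  structure(list(labels = labels, n_states = as.integer(n_states),
                 segments = segments, fs = fs), class = "state_path")
}

.check_segments <- function(segments, n) {
  o <- order(segments$first)
  s <- segments[o, ]
  if (s$first[1] != 1L || s$last[nrow(s)] != n ||
      (nrow(s) > 1 && any(s$first[-1] != s$last[-nrow(s)] + 1L)))
    .stopf("segments must partition 1..%d without gaps or overlaps", n)
  invisible(TRUE)
}

#' Permute the state indices of a model
#' @param model an \code{hmm_model}.
#' @param permutation integer vector; new state k is old state
#'   \code{permutation[k]}.
#' @return the permuted \code{hmm_model}.
#' @export
permute_model <- function(model, permutation) {
  stopifnot(sort(permutation) == seq_len(model$n_states))
  model$means <- model$means[permutation, , drop = FALSE]
  model$covariances <- model$covariances[, , permutation, drop = FALSE]
  model$transition_matrix <-
    model$transition_matrix[permutation, permutation, drop = FALSE]
  model$initial_distribution <- model$initial_distribution[permutation]
  model
}

#' Optimal label matching between two state labelings
#'
#' Finds the permutation of decoded labels maximizing agreement with the
#' reference labels (exhaustive search over permutations; K up to 8).
#'
#' @param reference integer reference labels in \code{1:K}.
#' @param labels integer decoded labels in \code{1:K}.
#' @param n_states number of states K.
#' @return list with \code{permutation} (decoded label k corresponds to
#'   reference state \code{permutation[k]}), \code{accuracy}, and
#'   \code{relabelled} (decoded labels mapped onto reference indices).
#' @export
match_states <- function(reference, labels, n_states) {
  K <- n_states
  conf <- table(factor(labels, seq_len(K)), factor(reference, seq_len(K)))
  perms <- .all_permutations(K)
  agree <- vapply(perms, function(p)
    sum(conf[cbind(seq_len(K), p)]), numeric(1))
  best <- perms[[which.max(agree)]]
  list(permutation = best, accuracy = max(agree) / length(labels),
       relabelled = best[labels])
}

.all_permutations <- function(K) {
  if (K == 1) return(list(1L))
  sub <- .all_permutations(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(K)) {
    i <- i + 1L
    out[[i]] <- append(p, K, after = pos - 1L)
  }
  out
}

.obs_matrix <- function(observations) {
  if (inherits(observations, "concatenated_observations"))
    return(t(observations$data))
  if (is.matrix(observations)) return(t(observations))
  if (is.numeric(observations)) return(matrix(observations, ncol = 1))
  .stopf("observations must be a matrix or concatenated_observations")
}

.check_model_dim <- function(model, X) {
  if (ncol(X) != ncol(model$means))
    .stopf("observation dimension (%d) does not match model (%d)",
           ncol(X), ncol(model$means))
  invisible(TRUE)
}
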