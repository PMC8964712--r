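#' Configuration for a synthetic resting-state cohort
#'
#' Defines the generative model for a multi-subject, two-session cohort of
#' parcel-space power envelopes with planted transient states, plus the
#' finger-tapping behaviour coupled to one state's dwell dynamics.
#'
#' Observations are generated in a latent Gaussian space (state-specific
#' mean and covariance plus isotropic noise) and mapped through a softplus
#' so envelopes are non-negative amplitude-like signals. Dwell times are
#' geometric, matching the first-order Markov assumption of the downstream
#' model. The default transition matrix gives a mean dwell of
#' \code{mean_dwell_s} seconds (150 ms, i.e. in the 100--200 ms range
#' typical of transient resting-state networks).
#'
#' Subject-level variation: each subject's self-transition probability of
#' \code{coupling_state} is shifted on the logit scale by a latent normal
#' score, and a second latent score drives motor skill; the two scores form
#' a Gaussian copula whose correlation is chosen so that the Spearman
#' correlation between the state's subject-level mean life time and best
#' motor performance targets \code{coupling_rho}. The planted learning
#' effect reduces the self-transition probability of \code{effect_state} by
#' \code{effect_size} in the post session only, which lowers its mean life
#' time and fractional occupancy and raises its mean interval length.
#'
#' @param n_subjects number of subjects (default 27).
#' @param n_sessions sessions per subject (default 2: \code{"pre"}, \code{"post"}).
#' @param session_duration session length in seconds (default 300).
#' @param fs envelope sampling rate in Hz (default 40).
#' @param n_parcels number of parcels (default 20).
#' @param n_states number of planted states K (default 8).
#' @param transition_matrix K x K row-stochastic matrix; default built from
#'   \code{mean_dwell_s} with uniform off-diagonal mass.
#' @param state_means K x n_parcels latent-space state means; default gives
#'   each state an elevated block of parcels on a common positive baseline.
#' @param state_covariances list of K positive-definite n_parcels x
#'   n_parcels matrices; default low-rank-plus-diagonal, distinct per state.
#' @param noise_sd isotropic latent noise standard deviation.
#' @param mean_dwell_s mean state dwell in seconds used to build the
#'   default transition matrix.
#' @param coupling_rho target Spearman correlation in [-1, 1] between the
#'   coupling state's subject-level mean life time and BMP.
#' @param coupling_state state whose dwell couples to behaviour.
#' @param subject_sd logit-scale SD of the coupling state's subject-level
#'   self-transition probability.
#' @param subject_jitter_sd logit-scale SD of independent subject-level
#'   jitter on the other states' self-transitions.
#' @param effect_state state receiving the planted pre-to-post change.
#' @param effect_size reduction of the effect state's self-transition
#'   probability in the post session (0 = no effect).
#' @param seed integer seed controlling all randomness of the cohort.
#' @return object of class \code{simulation_config}.
#' @export
simulation_config <- function(n_subjects = 27, n_sessions = 2,
                              session_duration = 300, fs = 40,
                              n_parcels = 20, n_states = 8,
                              transition_matrix = NULL, state_means = NULL,
                              state_covariances = NULL, noise_sd = 0.2,
                              mean_dwell_s = 0.15,
                              coupling_rho = -0.5, coupling_state = 1,
                              subject_sd = 0.3, subject_jitter_sd = 0.1,
                              effect_state = 1, effect_size = 0,
                              seed = 1L) {
  K <- as.integer(n_states)
  if (K < 1) .stopf("n_states must be >= 1")
  n_samples <- session_duration * fs
  if (abs(n_samples - round(n_samples)) > 1e-9)
    .stopf("session_duration * fs must be an integer number of samples")
  if (abs(coupling_rho) > 1) .stopf("coupling_rho must be in [-1, 1]")

  if (is.null(transition_matrix)) {
    p_stay <- if (K == 1) 1 else 1 - 1 / (mean_dwell_s * fs)
    transition_matrix <- matrix(if (K == 1) 0 else (1 - p_stay) / (K - 1), K, K)
    diag(transition_matrix) <- p_stay
  }
  .check_stochastic(transition_matrix)
  if (nrow(transition_matrix) != K)
    .stopf("transition_matrix must be %d x %d", K, K)

  if (is.null(state_means) || is.null(state_covariances)) {
    def <- .default_state_parameters(K, n_parcels, seed)
    if (is.null(state_means)) state_means <- def$means
    if (is.null(state_covariances)) state_covariances <- def$covariances
  }
  if (!is.matrix(state_means) || nrow(state_means) != K ||
      ncol(state_means) != n_parcels)
    .stopf("state_means must be a %d x %d matrix", K, n_parcels)
  if (length(state_covariances) != K)
    .stopf("state_covariances must list %d matrices", K)
  for (k in seq_len(K))
    .check_spd(state_covariances[[k]], sprintf("state_covariances[[%d]]", k))

  structure(list(
    n_subjects = as.integer(n_subjects), n_sessions = as.integer(n_sessions),
    session_duration = session_duration, fs = fs,
    n_parcels = as.integer(n_parcels), n_states = K,
    n_samples = as.integer(round(n_samples)),
    transition_matrix = transition_matrix, state_means = state_means,
    state_covariances = state_covariances, noise_sd = noise_sd,
    mean_dwell_s = mean_dwell_s,
    coupling_rho = coupling_rho, coupling_state = as.integer(coupling_state),
    subject_sd = subject_sd, subject_jitter_sd = subject_jitter_sd,
    effect_state = as.integer(effect_state), effect_size = effect_size,
    seed = as.integer(seed)), class = "simulation_config")
}

# Deterministic default spatial parameters: common positive baseline (keeps
# the softplus near-linear so state covariances survive the transform),
# one elevated parcel block per state, distinct low-rank covariance.
.default_state_parameters <- function(K, n_parcels, seed) {
  means <- matrix(5, K, n_parcels)
  block <- max(1L, ceiling(n_parcels / K))
  covs <- vector("list", K)
  .local_seed(seed * 1000L + 17L, {
    for (k in seq_len(K)) {
      idx <- (((k - 1L) * block):((k * block) - 1L)) %% n_parcels + 1L
      means[k, idx] <- means[k, idx] + 1.5
      W <- matrix(rnorm(n_parcels * 2, sd = 0.4), n_parcels, 2)
      covs[[k]] <- 0.25 * diag(n_parcels) + tcrossprod(W)
    }
  })
  list(means = means, covariances = covs)
}

#' Stationary distribution of a row-stochastic matrix
#' @param A K x K row-stochastic matrix.
#' @return probability vector of length K.
#' @export
stationary_distribution <- function(A) {
  .check_stochastic(A)
  e <- eigen(t(A))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

#' Simulate a first-order Markov chain of state labels
#'
#' @param transition_matrix K x K row-stochastic matrix.
#' @param initial initial state distribution (default: stationary).
#' @param n_samples chain length.
#' @param seed optional integer seed; when \code{NULL} the current RNG
#'   stream is used.
#' @return integer vector of labels in \code{1:K}.
#' @export
simulate_markov_chain <- function(transition_matrix, initial = NULL,
                                  n_samples, seed = NULL) {
  .check_stochastic(transition_matrix)
  if (n_samples < 1) .stopf("n_samples must be >= 1")
  K <- nrow(transition_matrix)
  if (is.null(initial)) initial <- stationary_distribution(transition_matrix)
  if (length(initial) != K || abs(sum(initial) - 1) > 1e-8)
    .stopf("initial must be a length-%d probability vector", K)
  .local_seed(seed, {
    u <- runif(n_samples)
    cpp_markov_chain(t(apply(transition_matrix, 1, cumsum)),
                     cumsum(initial), u)
  })
}

#' Generate parcel-space envelopes from a planted state sequence
#'
#' At each sample an observation is drawn from the active state's Gaussian
#' (latent space), isotropic noise is added, and the result is mapped
#' through a softplus so the output is a non-negative envelope.
#'
#' @param state_sequence integer labels in \code{1:K}.
#' @param config a \code{\link{simulation_config}}.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @return n_parcels x n_samples envelope matrix.
#' @export
simulate_envelopes <- function(state_sequence, config, seed = NULL) {
  K <- config$n_states
  if (any(state_sequence < 1 | state_sequence > K))
    .stopf("state_sequence labels must lie in 1..%d", K)
  p <- config$n_parcels
  T_ <- length(state_sequence)
  .local_seed(seed, {
    X <- matrix(0, p, T_)
    for (k in seq_len(K)) {
      idx <- which(state_sequence == k)
      if (!length(idx)) next
      S <- config$state_covariances[[k]]
      L <- tryCatch(chol(S), error = function(e)
        .stopf("covariance of state %d is not positive-definite", k))
      Z <- matrix(rnorm(length(idx) * p), length(idx), p)
      X[, idx] <- t(Z %*% L) + config$state_means[k, ]
    }
    if (config$noise_sd > 0)
      X <- X + matrix(rnorm(p * T_, sd = config$noise_sd), p, T_)
    .softplus(X)
  })
}

#' Simulate a finger-tapping key-press log
#'
#' Generates key presses for the cyclic 5-element sequence 4-1-3-2-4.
#' Inter-press intervals shrink and the error probability falls
#' exponentially across blocks toward skill-determined asymptotes, so the
#' global performance index rises monotonically in expectation. On an
#' error the intended sequence position does not advance (the subject
#' corrects with the intended key next).
#'
#' @param skill latent skill scalar in [0, 1].
#' @param n_blocks number of blocks.
#' @param block_duration block length in seconds.
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @param target_sequence cyclic target key sequence.
#' @param learning_rate exponential approach rate per block.
#' @param ipi_start initial mean inter-press interval (s).
#' @param ipi_floor asymptotic interval at zero skill (s).
#' @param ipi_skill_gain interval reduction at full skill (s).
#' @param error_start initial per-press error probability.
#' @param error_floor asymptotic error probability at zero skill.
#' @param error_skill_gain error reduction at full skill.
#' @param ipi_jitter_sd lognormal sd of interval jitter (0 = deterministic).
#' @param block_offset practice blocks already performed before block 1
#'   (used for post-learning test blocks).
#' @param boost fractional speed-up applied to the interval asymptote
#'   (models the offline boost at retest).
#' @return data.frame with columns block, press_index, time_s, key.
#' @export
simulate_ftt <- function(skill, n_blocks = 20, block_duration = 30,
                         seed = NULL, target_sequence = c(4, 1, 3, 2, 4),
                         learning_rate = 0.35, ipi_start = 0.5,
                         ipi_floor = 0.40, ipi_skill_gain = 0.15,
                         error_start = 0.25, error_floor = 0.10,
                         error_skill_gain = 0.06, ipi_jitter_sd = 0.15,
                         block_offset = 0, boost = 0) {
  if (block_duration <= 0) .stopf("block_duration must be positive")
  if (n_blocks < 1) .stopf("n_blocks must be >= 1")
  ipi_asym <- (ipi_floor - ipi_skill_gain * skill) * (1 - boost)
  err_asym <- max(0, error_floor - error_skill_gain * skill)
  L <- length(target_sequence)
  .local_seed(seed, {
    rows <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      prog <- 1 - exp(-learning_rate * (b - 1 + block_offset))
      ipi_b <- ipi_start - (ipi_start - ipi_asym) * prog
      err_b <- error_start - (error_start - err_asym) * prog
      t <- 0; pos <- 1L
      times <- numeric(0); keys <- integer(0)
      repeat {
        dt <- if (ipi_jitter_sd > 0)
          ipi_b * rlnorm(1, -ipi_jitter_sd^2 / 2, ipi_jitter_sd) else ipi_b
        if (t + dt > block_duration) break
        t <- t + dt
        intended <- target_sequence[pos]
        if (err_b > 0 && runif(1) < err_b) {
          key <- sample(setdiff(1:4, intended), 1)
        } else {
          key <- intended
          pos <- pos %% L + 1L
        }
        times <- c(times, t); keys <- c(keys, key)
      }
      rows[[b]] <- data.frame(block = b, press_index = seq_along(times),
                              time_s = times, key = keys)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Draws per-subject latent dwell and skill scores from a Gaussian copula
#' targeting \code{coupling_rho} (copula correlation
#' \code{2 sin(pi rho / 6)}), builds subject- and session-specific
#' transition matrices (planted effect applied in the post session),
#' simulates state chains and envelopes, and generates finger-tapping logs
#' (20 learning + 2 test blocks of 30 s by default).
#'
#' @param config a \code{\link{simulation_config}}.
#' @param generate_envelopes set \code{FALSE} to skip envelope synthesis
#'   and keep only state chains and behaviour (fast ground-truth studies).
#' @return list of class \code{envhmm_cohort} with elements
#'   \code{dataset} (an \code{\link{envelope_dataset}} or \code{NULL}),
#'   \code{behaviour} (key-press log), and \code{ground_truth}
#'   (state sequences, subject transition matrices, skill, config).
#' @export
simulate_cohort <- function(config, generate_envelopes = TRUE) {
  stopifnot(inherits(config, "simulation_config"))
  K <- config$n_states
  n <- config$n_subjects
  sessions <- c("pre", "post")[seq_len(config$n_sessions)]
  rho_g <- 2 * sin(pi * config$coupling_rho / 6)

  .local_seed(config$seed, {
    z1 <- rnorm(n)
    z2 <- rho_g * z1 + sqrt(1 - rho_g^2) * rnorm(n)
    skill <- pnorm(z2)
    subject_ids <- sprintf("S%02d", seq_len(n))

    base_A <- config$transition_matrix
    jitter <- matrix(rnorm(n * K, sd = config$subject_jitter_sd), n, K)
    recordings <- list()
    truth_seq <- list()
    subj_A <- list()
    beh <- vector("list", n)

    for (i in seq_len(n)) {
      diag_i <- plogis(qlogis(diag(base_A)) + jitter[i, ])
      if (K > 1)
        diag_i[config$coupling_state] <-
          plogis(qlogis(diag(base_A))[config$coupling_state] +
                 config$subject_sd * z1[i])
      for (ses in sessions) {
        d <- diag_i
        if (ses == "post" && config$effect_size != 0)
          d[config$effect_state] <-
            min(max(d[config$effect_state] - config$effect_size, 0.02), 0.995)
        A <- .retarget_diagonal(base_A, d)
        key <- paste(subject_ids[i], ses, sep = ".")
        subj_A[[key]] <- A
        labels <- simulate_markov_chain(A, n_samples = config$n_samples)
        truth_seq[[key]] <- labels
        if (generate_envelopes)
          recordings[[key]] <- list(subject_id = subject_ids[i], session = ses,
                                    data = simulate_envelopes(labels, config))
      }
      learn <- simulate_ftt(skill[i])
      test <- simulate_ftt(skill[i], n_blocks = 2, block_offset = 20,
                           boost = 0.03)
      learn$session <- "learning"; test$session <- "test"
      both <- rbind(learn, test)
      both$subject_id <- subject_ids[i]
      beh[[i]] <- both[, c("subject_id", "session", "block", "press_index",
                           "time_s", "key")]
    }

    dataset <- if (generate_envelopes)
      envelope_dataset(recordings, fs = config$fs) else NULL
    structure(list(
      dataset = dataset,
      behaviour = do.call(rbind, beh),
      ground_truth = list(state_sequences = truth_seq,
                          subject_transition_matrices = subj_A,
                          subject_skill = setNames(skill, subject_ids),
                          subject_dwell_score = setNames(z1, subject_ids),
                          config = config)),
      class = "envhmm_cohort")
  })
}

# rescale off-diagonal mass of each row so the diagonal equals `d`
.retarget_diagonal <- function(A, d) {
  K <- nrow(A)
  if (K == 1) return(A)
  out <- A
  for (i in seq_len(K)) {
    off <- A[i, -i]
    out[i, -i] <- off / sum(off) * (1 - d[i])
    out[i, i] <- d[i]
  }
  out
}
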