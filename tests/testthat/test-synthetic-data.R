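test_that("markov chain simulation handles degenerate dynamics", {
  A <- diag(2)
  s <- simulate_markov_chain(A, initial = c(1, 0), n_samples = 50, seed = 1)
  expect_equal(s, rep(1L, 50))

  s1 <- simulate_markov_chain(matrix(1, 1, 1), n_samples = 20, seed = 7)
  expect_equal(s1, rep(1L, 20))

  bad <- matrix(c(0.5, 0.4, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_error(simulate_markov_chain(bad, n_samples = 5), "row")
})

test_that("long chains reproduce transition, dwell and occupancy laws", {
  p_stay <- 0.9
  A <- matrix(c(p_stay, 1 - p_stay, 1 - p_stay, p_stay), 2, 2, byrow = TRUE)
  s <- simulate_markov_chain(A, n_samples = 1e5, seed = 2)
  # empirical transition frequencies against the generator
  emp <- transition_matrix_empirical(s, 2)
  expect_lt(max(abs(emp - A)), 0.01)
  # geometric dwell law: mean run length = 1/(1 - p_kk) within 5%
  runs <- rle(s)
  for (k in 1:2) {
    m <- mean(runs$lengths[runs$values == k])
    expect_lt(abs(m - 1 / (1 - p_stay)) / (1 / (1 - p_stay)), 0.05)
  }
  # occupancy matches the stationary distribution
  pi_st <- stationary_distribution(A)
  expect_lt(max(abs(tabulate(s, 2) / length(s) - pi_st)), 0.02)
})

test_that("chains and envelopes are reproducible given the seed", {
  A <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  expect_identical(simulate_markov_chain(A, n_samples = 500, seed = 9),
                   simulate_markov_chain(A, n_samples = 500, seed = 9))
  cfg <- small_cohort_config()
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$dataset$recordings[[1]]$data,
                   c2$dataset$recordings[[1]]$data)
  expect_identical(c1$behaviour, c2$behaviour)
})

test_that("noiseless near-degenerate envelopes switch exactly with the state", {
  K <- 2; p <- 3
  means <- matrix(c(2, 2, 2, 6, 6, 6), K, p, byrow = TRUE)
  covs <- list(diag(p) * 1e-18, diag(p) * 1e-18)
  cfg <- simulation_config(n_subjects = 1, n_states = K, n_parcels = p,
                           session_duration = 1, fs = 40, noise_sd = 0,
                           state_means = means, state_covariances = covs,
                           seed = 1)
  s <- rep(c(1L, 2L), each = 20)
  E <- simulate_envelopes(s, cfg, seed = 3)
  expected <- log1p(exp(means))[s, 1]
  expect_lt(max(abs(E[1, ] - expected)), 1e-6)
  expect_true(all(E >= 0))
})

test_that("within-state sample moments match the generating distribution", {
  cfg <- simulation_config(n_subjects = 1, n_states = 2, n_parcels = 5,
                           session_duration = 500, fs = 40, noise_sd = 0,
                           seed = 4)
  s <- rep(1L, 2e4)
  E <- simulate_envelopes(s, cfg, seed = 5)
  S_hat <- cov(t(E))
  S_true <- cfg$state_covariances[[1]]
  rel <- norm(S_hat - S_true, "F") / norm(S_true, "F")
  expect_lt(rel, 0.10)
  # whole-recording mean approximates the transformed state mean
  expect_lt(max(abs(rowMeans(E) - log1p(exp(cfg$state_means[1, ])))), 0.05)
})

test_that("cohort coupling targets the requested rank correlation", {
  gt_mlt_bmp <- function(cfg) {
    coh <- simulate_cohort(cfg, generate_envelopes = FALSE)
    ids <- names(coh$ground_truth$subject_skill)
    mlt <- vapply(ids, function(id) {
      lab <- coh$ground_truth$state_sequences[[paste0(id, ".pre")]]
      temporal_metrics(as.integer(lab == cfg$coupling_state), cfg$fs)$MLT_s
    }, numeric(1))
    bmp <- behavioural_indices_table(coh$behaviour)
    cor(rank(mlt), rank(bmp$BMP[match(ids, bmp$subject_id)]))
  }
  rs0 <- gt_mlt_bmp(simulation_config(n_subjects = 500, n_states = 4,
                                      n_parcels = 4, session_duration = 60,
                                      coupling_rho = 0, seed = 6))
  expect_lt(abs(rs0), 0.1)
  rs6 <- gt_mlt_bmp(simulation_config(n_subjects = 200, n_states = 4,
                                      n_parcels = 4, session_duration = 300,
                                      coupling_rho = 0.6, seed = 7))
  expect_gt(rs6, 0.45)
  expect_lt(rs6, 0.75)
})

test_that("planted pre-to-post effect lowers the effect state's dwell", {
  cfg <- simulation_config(n_subjects = 8, n_states = 3, n_parcels = 4,
                           session_duration = 120, effect_state = 2,
                           effect_size = 0.15, seed = 8)
  coh <- simulate_cohort(cfg, generate_envelopes = FALSE)
  fo <- function(ses) vapply(sprintf("S%02d", 1:8), function(id) {
    lab <- coh$ground_truth$state_sequences[[paste0(id, ".", ses)]]
    mean(lab == 2L)
  }, numeric(1))
  expect_gt(mean(fo("pre")) - mean(fo("post")), 0.02)
})

test_that("ftt generator obeys its deterministic limits", {
  # zero error probability: every press continues the cyclic target
  log0 <- simulate_ftt(0.5, n_blocks = 3, seed = 1, error_start = 0,
                       error_floor = 0)
  seq5 <- c(4, 1, 3, 2, 4)
  for (b in 1:3) {
    keys <- log0$key[log0$block == b]
    expect_equal(keys, rep_len(seq5, length(keys)))
  }
  # deterministic 0.5-s clock: exactly 60 presses in a 30-s block
  logc <- simulate_ftt(0, n_blocks = 1, block_duration = 30, seed = 2,
                       ipi_start = 0.5, ipi_floor = 0.5, ipi_skill_gain = 0,
                       ipi_jitter_sd = 0, error_start = 0, error_floor = 0)
  expect_equal(nrow(logc), 60)
  expect_equal(logc$time_s, seq(0.5, 30, by = 0.5))
})

test_that("higher skill yields higher mean performance at every seed", {
  mean_gpi <- function(skill, seed) {
    log <- simulate_ftt(skill, n_blocks = 10, seed = seed)
    mean(vapply(1:10, function(b) {
      d <- log[log$block == b, ]
      gpi(d$time_s, d$key)
    }, numeric(1)))
  }
  for (seed in 1:20)
    expect_gt(mean_gpi(0.9, seed), mean_gpi(0.1, seed))
})
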