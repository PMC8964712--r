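#' Paired Wilcoxon signed-rank test
#'
#' Classic signed-rank convention: zero differences are discarded, tied
#' absolute differences receive average ranks, and the statistic W is the
#' sum of the ranks of positive differences (\code{post - pre}). The
#' two-sided p-value is exact (signed-rank distribution) when n <= 15 and
#' there are no ties; otherwise a normal approximation with continuity
#' and tie correction is used.
#'
#' @param pre,post paired measurement vectors.
#' @param alpha significance level.
#' @return list with test_name, statistic (W), n (non-zero differences),
#'   p_raw, method, and significance at \code{alpha}.
#' @export
paired_wilcoxon <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post)) .stopf("pre and post must be paired")
  keep <- complete.cases(pre, post)
  d <- post[keep] - pre[keep]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("all differences are zero; test undefined")
    return(list(test_name = "paired_wilcoxon", statistic = NA_real_, n = 0L,
                p_raw = NA_real_, method = "undefined", significant = NA))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 15 && !ties) {
    p <- 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal_approx"
  }
  p <- min(1, p)
  list(test_name = "paired_wilcoxon", statistic = W, n = n, p_raw = p,
       method = method, significant = p < alpha)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks after pairwise deletion of missing
#' values; two-sided p-value from the t approximation with n - 2 degrees
#' of freedom.
#'
#' @param x,y measurement vectors.
#' @param alpha significance level.
#' @return list with test_name, statistic (r_s), n, p_raw, significant.
#' @export
spearman <- function(x, y, alpha = 0.05) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) .stopf("need at least 4 complete pairs")
  if (var(x) == 0 || var(y) == 0) {
    warning("constant input; correlation undefined")
    return(list(test_name = "spearman", statistic = NA_real_, n = n,
                p_raw = NA_real_, significant = NA))
  }
  rs <- cor(rank(x), rank(y))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    t <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  list(test_name = "spearman", statistic = rs, n = n, p_raw = p,
       significant = p < alpha)
}

#' One-sample t-test
#' @param values measurement vector.
#' @param mu null-hypothesis mean.
#' @param alpha significance level.
#' @return list with statistic (t), df, n, p_raw, significant.
#' @export
one_sample_t <- function(values, mu = 0, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) .stopf("need at least 2 values")
  s <- sd(values)
  if (s == 0) {
    warning("zero variance; test undefined")
    return(list(test_name = "one_sample_t", statistic = NA_real_,
                df = n - 1, n = n, p_raw = NA_real_, significant = NA))
  }
  t <- (mean(values) - mu) / (s / sqrt(n))
  p <- 2 * pt(-abs(t), n - 1)
  list(test_name = "one_sample_t", statistic = t, df = n - 1, n = n,
       p_raw = p, significant = p < alpha)
}

#' t statistic from a printed group summary
#' @param mean group mean.
#' @param se standard error of the mean.
#' @return t = mean / se.
#' @export
t_from_summary <- function(mean, se) {
  if (se <= 0) .stopf("se must be positive")
  mean / se
}

#' Bonferroni correction
#' @param p_raw raw p-value(s).
#' @param factor correction factor (family size).
#' @return corrected p, capped at 1.
#' @export
bonferroni <- function(p_raw, factor) {
  if (any(factor < 1)) .stopf("factor must be >= 1")
  pmin(1, p_raw * factor)
}

#' Bonferroni family factors for exclusive-state analyses
#'
#' With K mutually exclusive states, knowledge of K - 1 activation courses
#' determines the last, so the state-wise family counts K - 1 independent
#' states. The full family additionally multiplies by the number of
#' temporal parameters.
#'
#' @param n_states number of HMM states K.
#' @param n_parameters number of temporal parameters (default 4: MLT, FO,
#'   MIL, NO).
#' @return \code{state_family_factor}: K - 1;
#'   \code{full_family_factor}: n_parameters x (K - 1).
#' @export
state_family_factor <- function(n_states) {
  if (n_states < 2) .stopf("n_states must be >= 2")
  as.integer(n_states) - 1L
}

#' @rdname state_family_factor
#' @export
full_family_factor <- function(n_states, n_parameters = 4L) {
  as.integer(n_parameters) * state_family_factor(n_states)
}

#' Bootstrap comparison of two dependent Spearman correlations
#'
#' Tests whether \code{cor_s(x, y1)} differs from \code{cor_s(x, y2)} by a
#' subject-level bootstrap of the difference; the two-sided p-value is
#' twice the smaller tail of the bootstrap distribution around zero (with
#' the usual +1 correction).
#'
#' @param x shared variable (e.g. a behavioural index).
#' @param y1,y2 session-specific variables measured on the same subjects.
#' @param n_boot number of bootstrap resamples (>= 1000).
#' @param seed optional seed; \code{NULL} uses the current RNG stream.
#' @param alpha significance level.
#' @return list with statistic (observed difference in r_s), n, p_raw,
#'   n_boot_used (degenerate resamples excluded), significant.
#' @export
compare_dependent_correlations <- function(x, y1, y2, n_boot = 2000,
                                           seed = NULL, alpha = 0.05) {
  if (length(x) != length(y1) || length(x) != length(y2))
    .stopf("x, y1 and y2 must have equal length")
  if (n_boot < 1000) .stopf("n_boot must be >= 1000")
  keep <- complete.cases(x, y1, y2)
  x <- x[keep]; y1 <- y1[keep]; y2 <- y2[keep]
  n <- length(x)
  rs <- function(a, b) cor(rank(a), rank(b))
  d_obs <- rs(x, y1) - rs(x, y2)
  .local_seed(seed, {
    d_boot <- numeric(n_boot)
    ok <- logical(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      xb <- x[idx]
      if (var(xb) == 0 || var(y1[idx]) == 0 || var(y2[idx]) == 0) next
      d_boot[b] <- rs(xb, y1[idx]) - rs(xb, y2[idx])
      ok[b] <- TRUE
    }
    d_boot <- d_boot[ok]
    B <- length(d_boot)
    if (B < n_boot) message(sprintf("%d degenerate resamples excluded",
                                    n_boot - B))
    p <- 2 * min((1 + sum(d_boot <= 0)) / (1 + B),
                 (1 + sum(d_boot >= 0)) / (1 + B))
    p <- min(1, p)
    list(test_name = "dependent_correlation_bootstrap", statistic = d_obs,
         n = n, p_raw = p, n_boot_used = B, significant = p < alpha)
  })
}

.metric_parameters <- c("MLT_s", "FO", "MIL_s", "NO")

#' Pre/post contrast battery over states and temporal parameters
#'
#' Runs the paired Wilcoxon signed-rank test per state and temporal
#' parameter between the pre and post sessions, Bonferroni-corrected
#' across the K - 1 independent states. Subjects missing a session and
#' pairs with missing metric values (e.g. MIL with fewer than two visits)
#' are dropped pairwise, with the effective n reported per test.
#'
#' @param metrics metrics table from \code{\link{metrics_by_segment}}.
#' @param alpha significance level.
#' @return data.frame with one row per state x parameter: W, n, p_raw,
#'   factor, p_corrected, significant.
#' @export
prepost_contrast_battery <- function(metrics, alpha = 0.05) {
  K <- max(metrics$state)
  fac <- state_family_factor(K)
  subs <- intersect(unique(metrics$subject_id[metrics$session == "pre"]),
                    unique(metrics$subject_id[metrics$session == "post"]))
  dropped <- setdiff(unique(metrics$subject_id), subs)
  if (length(dropped))
    message("dropping subjects without both sessions: ",
            paste(dropped, collapse = ", "))
  rows <- list()
  for (k in seq_len(K)) for (param in .metric_parameters) {
    mk <- metrics[metrics$state == k & metrics$subject_id %in% subs, ]
    pre <- mk[[param]][mk$session == "pre"][match(subs,
      mk$subject_id[mk$session == "pre"])]
    post <- mk[[param]][mk$session == "post"][match(subs,
      mk$subject_id[mk$session == "post"])]
    w <- paired_wilcoxon(pre, post, alpha = alpha)
    rows[[length(rows) + 1]] <- data.frame(
      state = k, parameter = param, W = w$statistic, n = w$n,
      p_raw = w$p_raw, factor = fac,
      p_corrected = bonferroni(w$p_raw, fac),
      significant = !is.na(w$p_raw) && bonferroni(w$p_raw, fac) < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Brain-behaviour correlation battery
#'
#' Spearman correlation of each state's temporal parameters in one session
#' against a behavioural index (BMP by default), corrected within each
#' state's family of temporal parameters (factor 4) and, additionally, for
#' the family-wide factor 4 x (K - 1).
#'
#' @param metrics metrics table from \code{\link{metrics_by_segment}}.
#' @param indices behavioural indices table
#'   (\code{\link{behavioural_indices_table}}).
#' @param session \code{"pre"} or \code{"post"}.
#' @param target behavioural column to correlate against (default
#'   \code{"BMP"}).
#' @param alpha significance level.
#' @return data.frame with one row per state x parameter: r_s, n, p_raw,
#'   factor, p_corrected, factor_full, p_corrected_full, significant.
#' @export
brain_behaviour_battery <- function(metrics, indices, session = "pre",
                                    target = "BMP", alpha = 0.05) {
  if (!target %in% names(indices)) .stopf("indices lack column '%s'", target)
  K <- max(metrics$state)
  m <- metrics[metrics$session == session, ]
  unmatched <- setdiff(unique(m$subject_id), indices$subject_id)
  if (length(unmatched))
    .stopf("subjects without behavioural indices: %s",
           paste(unmatched, collapse = ", "))
  fac <- 4L
  fac_full <- full_family_factor(K)
  rows <- list()
  for (k in seq_len(K)) for (param in .metric_parameters) {
    mk <- m[m$state == k, ]
    y <- indices[[target]][match(mk$subject_id, indices$subject_id)]
    s <- spearman(mk[[param]], y, alpha = alpha)
    rows[[length(rows) + 1]] <- data.frame(
      state = k, parameter = param, session = session, target = target,
      r_s = s$statistic, n = s$n, p_raw = s$p_raw, factor = fac,
      p_corrected = bonferroni(s$p_raw, fac), factor_full = fac_full,
      p_corrected_full = bonferroni(s$p_raw, fac_full),
      significant = !is.na(s$p_raw) && bonferroni(s$p_raw, fac) < alpha)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
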