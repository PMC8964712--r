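#' Global performance index of one finger-tapping block
#'
#' The GPI used here is the number of correct presses per second, a
#' monotone speed-accuracy composite. A press is correct iff it continues
#' the cyclic target sequence from the previous correct press; the first
#' correct press of a block may start at any position of the cycle
#' (earliest matching position, since the task is continuous and the block
#' has no stated anchor). An alternative composite can be supplied via
#' \code{score}, which receives the correct-press count, total press
#' count and duration.
#'
#' @param times press times in seconds, strictly increasing within
#'   \code{[0, duration]}.
#' @param keys pressed keys (integers in 1..4).
#' @param duration block duration in seconds.
#' @param target_sequence cyclic target key sequence (default 4-1-3-2-4).
#' @param score optional function \code{(n_correct, n_presses, duration)}
#'   returning the block score; default \code{n_correct / duration}.
#' @return block score (correct presses per second by default).
#' @export
gpi <- function(times, keys, duration = 30,
                target_sequence = c(4, 1, 3, 2, 4), score = NULL) {
  if (!length(target_sequence)) .stopf("target_sequence is empty")
  if (duration <= 0) .stopf("duration must be positive")
  if (length(times) != length(keys)) .stopf("times and keys disagree")
  n_correct <- .count_correct(keys, target_sequence)
  if (is.null(score)) n_correct / duration
  else score(n_correct, length(keys), duration)
}

.count_correct <- function(keys, target_sequence) {
  L <- length(target_sequence)
  pos <- NA_integer_   # position of the last correct press in the cycle
  n_correct <- 0L
  for (key in keys) {
    if (is.na(pos)) {
      hit <- match(key, target_sequence)
      if (!is.na(hit)) { pos <- hit; n_correct <- n_correct + 1L }
    } else {
      nxt <- pos %% L + 1L
      if (key == target_sequence[nxt]) {
        pos <- nxt; n_correct <- n_correct + 1L
      }
    }
  }
  n_correct
}

#' Behavioural indices of motor performance and learning
#'
#' From per-block GPI scores of the learning session and the post-learning
#' test blocks: baseline \code{BL} (mean GPI of learning blocks 2 and 3;
#' block 1 is excluded because of initial task habituation), best motor
#' performance \code{BMP} (mean of the two highest learning-block GPIs,
#' block 1 eligible), learning index \code{LI = 100 (BMP - BL) / BL}, and
#' boost effect \code{BE = 100 (best test GPI - BMP) / BMP}.
#'
#' @param presses data.frame of key presses with columns \code{session}
#'   (\code{"learning"} or \code{"test"}), \code{block}, \code{time_s},
#'   \code{key}, for one subject.
#' @param block_duration block duration in seconds.
#' @param target_sequence cyclic target key sequence.
#' @param score optional alternative block scoring hook (see
#'   \code{\link{gpi}}).
#' @return list with \code{GPI_learning}, \code{GPI_test} (per-block
#'   scores), \code{BL}, \code{BMP}, \code{LI_pct}, \code{BE_pct}.
#'   \code{LI_pct} is \code{NA} with a warning when \code{BL} is 0.
#' @export
behavioural_indices <- function(presses, block_duration = 30,
                                target_sequence = c(4, 1, 3, 2, 4),
                                score = NULL) {
  stopifnot(all(c("session", "block", "time_s", "key") %in% names(presses)))
  block_gpi <- function(session) {
    df <- presses[presses$session == session, ]
    blocks <- sort(unique(df$block))
    vapply(blocks, function(b) {
      d <- df[df$block == b, ]
      gpi(d$time_s, d$key, duration = block_duration,
          target_sequence = target_sequence, score = score)
    }, numeric(1))
  }
  g_learn <- block_gpi("learning")
  g_test <- block_gpi("test")
  if (length(g_learn) < 3) .stopf("need at least 3 learning blocks")
  if (!length(g_test)) .stopf("need at least 1 test block")
  BL <- mean(g_learn[2:3])
  BMP <- mean(sort(g_learn, decreasing = TRUE)[1:2])
  LI <- if (BL > 0) 100 * (BMP - BL) / BL else {
    warning("baseline GPI is 0; learning index undefined")
    NA_real_
  }
  BE <- if (BMP > 0) 100 * (max(g_test) - BMP) / BMP else NA_real_
  list(GPI_learning = g_learn, GPI_test = g_test, BL = BL, BMP = BMP,
       LI_pct = LI, BE_pct = BE)
}

#' Behavioural indices for every subject of a cohort press log
#'
#' @param presses key-press log with columns subject_id, session, block,
#'   time_s, key.
#' @param ... passed to \code{\link{behavioural_indices}}.
#' @return data.frame with one row per subject: subject_id, BL, BMP,
#'   LI_pct, BE_pct.
#' @export
behavioural_indices_table <- function(presses, ...) {
  ids <- unique(presses$subject_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    b <- behavioural_indices(presses[presses$subject_id == id, ], ...)
    data.frame(subject_id = id, BL = b$BL, BMP = b$BMP,
               LI_pct = b$LI_pct, BE_pct = b$BE_pct)
  }))
  rownames(out) <- NULL
  out
}
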