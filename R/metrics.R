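#' Binary activation time courses of a state path
#'
#' @param path a \code{\link{state_path}} or integer label vector.
#' @param n_states number of states (taken from the path if omitted).
#' @return samples x K 0/1 matrix; course k is 1 exactly where the label
#'   equals k, so the rows sum to 1 (mutual exclusivity).
#' @export
binarize_states <- function(path, n_states = NULL) {
  labels <- if (inherits(path, "state_path")) path$labels else as.integer(path)
  if (is.null(n_states)) {
    if (inherits(path, "state_path")) n_states <- path$n_states
    else n_states <- max(labels)
  }
  out <- matrix(0L, length(labels), n_states)
  out[cbind(seq_along(labels), labels)] <- 1L
  out
}

#' Temporal parameters of one binary activation course
#'
#' Visits are maximal runs of 1. Mean life time (MLT) is the mean visit
#' duration, fractional occupancy (FO) the fraction of samples active,
#' mean interval length (MIL) the mean duration of the gaps strictly
#' between consecutive visits (edges excluded), and NO the number of
#' visits. MLT and MIL are \code{NA} when undefined (no visits; fewer than
#' two visits, respectively).
#'
#' @param course 0/1 vector.
#' @param fs sampling rate in Hz.
#' @return named list with MLT_s, FO, MIL_s, NO.
#' @export
temporal_metrics <- function(course, fs) {
  if (!length(course)) .stopf("course is empty")
  if (fs <= 0) .stopf("fs must be positive")
  if (any(!course %in% c(0, 1))) .stopf("course must be binary")
  r <- rle(as.integer(course))
  on <- r$values == 1L
  NO <- sum(on)
  FO <- sum(r$lengths[on]) / length(course)
  MLT <- if (NO > 0) mean(r$lengths[on]) / fs else NA_real_
  MIL <- NA_real_
  if (NO > 1) {
    # gaps strictly between visits: drop leading/trailing zero runs
    inner <- r$values[seq(which(on)[1], tail(which(on), 1))]
    lens <- r$lengths[seq(which(on)[1], tail(which(on), 1))]
    MIL <- mean(lens[inner == 0L]) / fs
  }
  list(MLT_s = MLT, FO = FO, MIL_s = MIL, NO = NO)
}

#' State temporal metrics per subject, session and state
#'
#' De-concatenates the decoded path along its segment table and computes
#' the four temporal parameters within each segment independently; visits
#' never span segment boundaries.
#'
#' @param path a \code{\link{state_path}} carrying a segment table.
#' @param fs sampling rate in Hz (defaults to the path's).
#' @return data.frame with columns subject_id, session, state, MLT_s, FO,
#'   MIL_s, NO.
#' @export
metrics_by_segment <- function(path, fs = NULL) {
  stopifnot(inherits(path, "state_path"))
  if (is.null(path$segments)) .stopf("path carries no segment table")
  if (is.null(fs)) fs <- path$fs
  if (is.null(fs)) .stopf("fs must be supplied")
  .check_segments(path$segments, length(path$labels))
  K <- path$n_states
  rows <- vector("list", nrow(path$segments) * K)
  i <- 0L
  for (s in seq_len(nrow(path$segments))) {
    seg <- path$segments[s, ]
    lab <- path$labels[seg$first:seg$last]
    for (k in seq_len(K)) {
      m <- temporal_metrics(as.integer(lab == k), fs)
      i <- i + 1L
      rows[[i]] <- data.frame(subject_id = seg$subject_id,
                              session = seg$session, state = k,
                              MLT_s = m$MLT_s, FO = m$FO, MIL_s = m$MIL_s,
                              NO = m$NO)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical transition probability matrix of a decoded path
#'
#' Entry (i, j) is the number of observed i to j steps divided by the
#' number of steps leaving i. Rows of states never left are \code{NA}.
#'
#' @param path a \code{\link{state_path}} or integer label vector.
#' @param n_states number of states.
#' @param within_segments when \code{TRUE} (default if the path has a
#'   segment table), transitions across segment boundaries are excluded.
#' @return K x K row-stochastic matrix (NA rows where undefined).
#' @export
transition_matrix_empirical <- function(path, n_states = NULL,
                                        within_segments = NULL) {
  labels <- if (inherits(path, "state_path")) path$labels else as.integer(path)
  if (is.null(n_states))
    n_states <- if (inherits(path, "state_path")) path$n_states
                else max(labels)
  segments <- if (inherits(path, "state_path")) path$segments else NULL
  if (is.null(within_segments)) within_segments <- !is.null(segments)
  if (!length(labels)) .stopf("path is empty")
  from <- labels[-length(labels)]
  to <- labels[-1]
  if (within_segments && !is.null(segments) && nrow(segments) > 1) {
    drop <- segments$last[-nrow(segments)]  # step crossing each boundary
    keep <- setdiff(seq_along(from), drop)
    from <- from[keep]; to <- to[keep]
  }
  counts <- table(factor(from, seq_len(n_states)),
                  factor(to, seq_len(n_states)))
  counts <- matrix(as.numeric(counts), n_states, n_states)
  rs <- rowSums(counts)
  out <- counts / rs
  out[rs == 0, ] <- NA_real_
  out
}

#' Partial-correlation state maps
#'
#' For each state k and parcel p, the correlation between the state's
#' binary activation course and the parcel's envelope, controlling for the
#' other states' courses. Because the K courses sum to one, one course must
#' be dropped from the controlling set to remove exact collinearity; the
#' convention here is fixed (the last course, or the first when mapping the
#' last state itself) since the choice does slightly affect the
#' conditioned-on set. Positive values mean increased
#' envelope power during visits of the state; negative values decreased
#' power.
#'
#' @param courses samples x K binary matrix (see
#'   \code{\link{binarize_states}}).
#' @param envelopes parcels x samples envelope matrix (parcel space).
#' @param drop_state course excluded from the controlling set (default K;
#'   when mapping that state itself, course \code{drop_alt} is dropped
#'   instead).
#' @param drop_alt alternative dropped course (default 1).
#' @return parcels x K matrix of partial correlations in [-1, 1]; columns
#'   for constant courses (occupancy 0 or 1) are \code{NA}.
#' @export
partial_correlation_map <- function(courses, envelopes, drop_state = NULL,
                                    drop_alt = 1L) {
  K <- ncol(courses)
  if (K < 2) .stopf("at least two states are required")
  if (ncol(envelopes) != nrow(courses))
    .stopf("courses (%d samples) and envelopes (%d samples) disagree",
           nrow(courses), ncol(envelopes))
  if (is.null(drop_state)) drop_state <- K
  E <- t(envelopes)                      # samples x parcels
  out <- matrix(NA_real_, ncol(E), K)
  for (k in seq_len(K)) {
    ck <- courses[, k]
    if (var(ck) == 0) {
      warning(sprintf("state %d course is constant; map undefined", k))
      next
    }
    dropk <- if (k == drop_state) drop_alt else drop_state
    ctrl <- courses[, setdiff(seq_len(K), c(k, dropk)), drop = FALSE]
    Q <- qr(cbind(1, ctrl))
    rk <- qr.resid(Q, ck)
    rE <- qr.resid(Q, E)
    out[, k] <- as.numeric(cor(rk, rE))
  }
  rownames(out) <- rownames(envelopes)
  colnames(out) <- paste0("state", seq_len(K))
  out
}

#' Display-threshold mask for state maps
#'
#' Figure convention for map rendering: flags parcels whose absolute
#' partial correlation lies between \code{lower} and 100\% of each
#' state's maximum absolute value.
#'
#' @param maps parcels x K matrix from
#'   \code{\link{partial_correlation_map}}.
#' @param lower lower threshold as a fraction of the per-state maximum
#'   absolute value (default 0.6).
#' @return logical matrix of the same shape.
#' @export
map_display_threshold <- function(maps, lower = 0.6) {
  apply(maps, 2, function(v) {
    m <- max(abs(v))
    !is.na(v) & abs(v) >= lower * m
  })
}
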