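#' Preprocessing configuration
#'
#' @param band_low,band_high band-pass edges in Hz (default 4--30).
#' @param window_width moving-average window width in seconds (default
#'   0.100).
#' @param window_step window step in seconds (default 0.025; with a 100 ms
#'   window this is 75\% overlap and an effective 40 Hz output rate).
#' @param n_components principal components retained after whitening
#'   (default 40).
#' @param filter_order Butterworth order of the zero-phase band-pass.
#' @return object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(band_low = 4, band_high = 30,
                              window_width = 0.100, window_step = 0.025,
                              n_components = 40, filter_order = 4) {
  if (band_low >= band_high) .stopf("band_low must be below band_high")
  if (window_step > window_width)
    .stopf("window_step must not exceed window_width")
  structure(list(band_low = band_low, band_high = band_high,
                 window_width = window_width, window_step = window_step,
                 n_components = as.integer(n_components),
                 filter_order = as.integer(filter_order)),
            class = "preprocess_config")
}

# discrete analytic-signal amplitude via the frequency-domain construction
.analytic_amplitude <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

#' Band-limited Hilbert envelope
#'
#' Zero-phase (forward-backward) Butterworth band-pass followed by the
#' analytic-signal amplitude of each channel.
#'
#' @param x parcels x samples real matrix (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param band length-2 band edges in Hz.
#' @param filter_order Butterworth order.
#' @return non-negative matrix of the same dimensions.
#' @export
hilbert_envelope <- function(x, fs, band = c(4, 30), filter_order = 4) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (any(!is.finite(x))) .stopf("signal contains non-finite values")
  if (band[2] >= fs / 2)
    .stopf("band upper edge (%g Hz) must be below the Nyquist rate (%g Hz)",
           band[2], fs / 2)
  bf <- signal::butter(filter_order, band / (fs / 2), type = "pass")
  out <- x
  for (i in seq_len(nrow(x)))
    out[i, ] <- .analytic_amplitude(signal::filtfilt(bf, x[i, ]))
  out
}

#' Moving-window average downsampling
#'
#' Each output sample is the arithmetic mean of one left-aligned full
#' window; trailing partial windows are discarded, giving
#' \code{floor((N - W) / S) + 1} outputs. With 100 ms windows sliding every
#' 25 ms over a 1 kHz signal the output rate is 40 Hz.
#'
#' @param envelope parcels x samples matrix.
#' @param fs_in input sampling rate in Hz.
#' @param window_width window width in seconds.
#' @param window_step window step in seconds.
#' @return list with \code{data} (parcels x windows) and \code{fs_out}.
#' @export
moving_window_downsample <- function(envelope, fs_in, window_width = 0.100,
                                     window_step = 0.025) {
  if (is.vector(envelope)) envelope <- matrix(envelope, nrow = 1)
  W <- round(window_width * fs_in)
  S <- round(window_step * fs_in)
  if (W < 1 || S < 1) .stopf("window and step must span at least one sample")
  N <- ncol(envelope)
  if (W > N) .stopf("window (%d samples) longer than signal (%d samples)", W, N)
  n_out <- (N - W) %/% S + 1L
  cs <- cbind(0, t(apply(envelope, 1, cumsum)))
  starts <- (seq_len(n_out) - 1L) * S
  out <- (cs[, starts + W + 1L, drop = FALSE] -
          cs[, starts + 1L, drop = FALSE]) / W
  list(data = out, fs_out = fs_in / S)
}

#' Standardize recordings and concatenate across subjects and sessions
#'
#' Each recording's channels are demeaned and all channels of the
#' recording are divided by one global standard deviation (computed over
#' all elements of the demeaned matrix), then recordings are concatenated
#' in time. A segment table records the provenance of every sample so the
#' decoded path can later be de-concatenated.
#'
#' @param dataset an \code{\link{envelope_dataset}}.
#' @return object of class \code{concatenated_observations} with elements
#'   \code{data} (channels x samples), \code{segments} (subject_id,
#'   session, first, last; 1-based inclusive), \code{fs},
#'   \code{channel_space}, and \code{global_sd} per recording.
#' @export
standardize_concatenate <- function(dataset) {
  stopifnot(inherits(dataset, "envelope_dataset"))
  mats <- vector("list", length(dataset$recordings))
  seg <- vector("list", length(dataset$recordings))
  gsd <- numeric(length(dataset$recordings))
  pos <- 0L
  for (i in seq_along(dataset$recordings)) {
    r <- dataset$recordings[[i]]
    Xc <- r$data - rowMeans(r$data)
    g <- stats::sd(as.vector(Xc))
    if (g == 0) .stopf("recording %s.%s is constant", r$subject_id, r$session)
    mats[[i]] <- Xc / g
    gsd[i] <- g
    n <- ncol(Xc)
    seg[[i]] <- data.frame(subject_id = r$subject_id, session = r$session,
                           first = pos + 1L, last = pos + n)
    pos <- pos + n
  }
  structure(list(data = do.call(cbind, mats),
                 segments = do.call(rbind, seg),
                 fs = dataset$fs, channel_space = "parcel",
                 global_sd = setNames(gsd, names(dataset$recordings)),
                 whitening_transform = NULL),
            class = "concatenated_observations")
}

#' PCA whitening of concatenated observations
#'
#' Projects the channels onto their leading principal components scaled to
#' unit variance. Components are ordered by decreasing explained variance
#' and the sign of each is fixed so its largest-magnitude loading is
#' positive. If the data have lower rank than requested, the component
#' count is reduced with a warning.
#'
#' @param observations a \code{concatenated_observations} in parcel space.
#' @param n_components components to retain.
#' @return a \code{concatenated_observations} in component space carrying
#'   \code{whitening_transform} (components x parcels) and
#'   \code{eigenvalues}.
#' @export
pca_whiten <- function(observations, n_components = 40) {
  stopifnot(inherits(observations, "concatenated_observations"))
  X <- observations$data
  n <- ncol(X)
  if (n_components > min(nrow(X), n))
    .stopf("n_components exceeds min(channels, samples)")
  C <- tcrossprod(X) / (n - 1)
  e <- eigen(C, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-12)
  k <- as.integer(n_components)
  if (k > rank) {
    warning(sprintf("requested %d components but rank is %d; reducing", k,
                    rank))
    k <- rank
  }
  V <- e$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
  V <- sweep(V, 2, flip, `*`)
  W <- sweep(t(V), 1, sqrt(e$values[seq_len(k)]), `/`)
  out <- observations
  out$data <- W %*% X
  out$channel_space <- "component"
  out$whitening_transform <- W
  out$eigenvalues <- e$values
  out
}
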