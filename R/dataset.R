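#' Per-subject, per-session envelope dataset
#'
#' Container for parcel x sample envelope matrices with sampling-rate
#' metadata. Recordings are stored in a named list keyed
#' \code{"<subject>.<session>"}.
#'
#' @param recordings list; each element a list with \code{subject_id},
#'   \code{session} (\code{"pre"} or \code{"post"}) and \code{data}
#'   (parcels x samples numeric matrix).
#' @param fs sampling rate in Hz, shared by all recordings.
#' @return object of class \code{envelope_dataset}.
#' @export
envelope_dataset <- function(recordings, fs) {
  if (fs <= 0) .stopf("fs must be positive")
  if (!length(recordings)) .stopf("recordings must be non-empty")
  p <- vapply(recordings, function(r) nrow(r$data), integer(1))
  if (length(unique(p)) != 1)
    .stopf("all recordings must share the parcel count; found: %s",
           paste(unique(p), collapse = ", "))
  keys <- vapply(recordings, function(r)
    paste(r$subject_id, r$session, sep = "."), character(1))
  names(recordings) <- keys
  structure(list(recordings = recordings, fs = fs,
                 n_parcels = p[[1]]), class = "envelope_dataset")
}

#' @export
print.envelope_dataset <- function(x, ...) {
  ns <- vapply(x$recordings, function(r) ncol(r$data), integer(1))
  cat(sprintf("envelope_dataset: %d recordings, %d parcels, fs = %g Hz\n",
              length(x$recordings), x$n_parcels, x$fs))
  cat(sprintf("  samples per recording: %s\n",
              paste(range(ns), collapse = "-")))
  invisible(x)
}

#' Manifest table of an envelope dataset
#' @param dataset an \code{\link{envelope_dataset}}.
#' @return data.frame with subject_id, session, n_samples, fs.
#' @export
dataset_manifest <- function(dataset) {
  do.call(rbind, lapply(dataset$recordings, function(r)
    data.frame(subject_id = r$subject_id, session = r$session,
               n_samples = ncol(r$data), fs = dataset$fs,
               row.names = NULL)))
}

#' Write / read an envelope dataset as delimited tables
#'
#' The dataset is laid out as a directory holding one matrix file per
#' recording (\code{env_<subject>_<session>.csv}, samples in rows) and a
#' \code{manifest.csv} with subject, session, sample count and sampling
#' rate.
#'
#' @param dataset an \code{\link{envelope_dataset}}.
#' @param dir target/source directory.
#' @return \code{write_envelope_dataset}: the directory, invisibly;
#'   \code{read_envelope_dataset}: an \code{\link{envelope_dataset}}.
#' @export
write_envelope_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- dataset_manifest(dataset)
  data.table::fwrite(manifest, file.path(dir, "manifest.csv"))
  for (r in dataset$recordings)
    data.table::fwrite(data.table::as.data.table(t(r$data)),
                       file.path(dir, sprintf("env_%s_%s.csv",
                                              r$subject_id, r$session)))
  invisible(dir)
}

#' @rdname write_envelope_dataset
#' @export
read_envelope_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) .stopf("no manifest.csv in %s", dir)
  manifest <- data.table::fread(mf, data.table = FALSE)
  fs <- unique(manifest$fs)
  if (length(fs) != 1)
    .stopf("manifest lists inconsistent sampling rates: %s",
           paste(fs, collapse = ", "))
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    f <- file.path(dir, sprintf("env_%s_%s.csv", manifest$subject_id[i],
                                manifest$session[i]))
    list(subject_id = manifest$subject_id[i], session = manifest$session[i],
         data = t(as.matrix(data.table::fread(f))))
  })
  envelope_dataset(recordings, fs = fs)
}
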