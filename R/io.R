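#' Read and write spike trains as CSV
#'
#' Plain-text interchange format: a CSV with header `electrode_id,time_s`,
#' sorted by electrode then time. Times round-trip at microsecond precision.
#'
#' @param spikes a [spike_train_set()]
#' @param path file path
#' @export
write_spike_trains <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  ids <- as.integer(names(spikes$trains))
  df <- data.frame(
    electrode_id = rep(ids, lengths(spikes$trains)),
    time_s = sprintf("%.6f", unlist(spikes$trains, use.names = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  # sidecar metadata so the recording interval round-trips
  meta <- sprintf("# t_start_s=%.6f t_stop_s=%.6f n_electrodes=%d",
                  spikes$t_start, spikes$t_stop, length(spikes$trains))
  writeLines(c(meta, readLines(path)), path)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param n_electrodes number of analysis slots; electrodes absent from the
#'   file get empty trains. Defaults to the value stored in the file header.
#' @return `read_spike_trains`: a [spike_train_set()]
#' @export
read_spike_trains <- function(path, n_electrodes = NULL) {
  lines <- readLines(path)
  meta <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    meta <- lines[1]
    lines <- lines[-1]
  }
  df <- utils::read.csv(text = lines, colClasses = c("integer", "numeric"))
  if (!identical(names(df), c("electrode_id", "time_s"))) {
    stop("malformed spike file: expected header 'electrode_id,time_s'")
  }
  t_start <- 0; t_stop <- NA; n_meta <- NA
  if (!is.null(meta)) {
    kv <- regmatches(meta, gregexpr("[a-z_]+=[-0-9.]+", meta))[[1]]
    vals <- stats::setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
    t_start <- vals[["t_start_s"]]; t_stop <- vals[["t_stop_s"]]
    n_meta <- as.integer(vals[["n_electrodes"]])
  }
  if (is.null(n_electrodes)) {
    n_electrodes <- if (!is.na(n_meta)) n_meta else max(df$electrode_id) + 1L
  }
  if (nrow(df) && (min(df$electrode_id) < 0 ||
                   max(df$electrode_id) >= n_electrodes)) {
    bad <- which(df$electrode_id < 0 | df$electrode_id >= n_electrodes)[1]
    stop("electrode id out of range at data line ", bad,
         " (id ", df$electrode_id[bad], ")")
  }
  if (is.na(t_stop)) t_stop <- if (nrow(df)) max(df$time_s) + 1e-6 else 1
  trains <- rep(list(numeric(0)), n_electrodes)
  names(trains) <- as.character(seq_len(n_electrodes) - 1L)
  sp <- split(df$time_s, factor(df$electrode_id, levels = 0:(n_electrodes - 1)))
  for (id in names(sp)) {
    tr <- sp[[id]]
    if (length(tr) && is.unsorted(tr, strictly = TRUE)) {
      stop("spike times of electrode ", id, " are not strictly increasing in ",
           path)
    }
    trains[[id]] <- tr
  }
  spike_train_set(trains, t_start, t_stop)
}

#' Read and write stimulation records as CSV
#'
#' Format: CSV with header `site,onset_s`, one row per stimulus.
#'
#' @param stim a [stimulation_record()]
#' @param path file path
#' @export
write_stimulation <- function(stim, path) {
  stopifnot(inherits(stim, "stimulation_record"))
  df <- data.frame(site = stim$site,
                   onset_s = sprintf("%.6f", stim$onsets))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulation
#' @return `read_stimulation`: a [stimulation_record()]
#' @export
read_stimulation <- function(path) {
  df <- utils::read.csv(path, colClasses = c("integer", "numeric"))
  if (!identical(names(df), c("site", "onset_s"))) {
    stop("malformed stimulation file: expected header 'site,onset_s'")
  }
  site <- unique(df$site)
  if (length(site) != 1) stop("stimulation file must contain a single site")
  stimulation_record(site, df$onset_s)
}
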