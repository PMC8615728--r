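#' Multichannel spike-train set
#'
#' The substrate of all multi-unit analyses: one sorted spike-time vector per
#' electrode, a common recording interval, and the electrode layout. Times are
#' in seconds, 0-based from recording start; each train must be strictly
#' increasing and lie in `[t_start, t_stop)`.
#'
#' @param trains list of numeric spike-time vectors (seconds), one per
#'   electrode. Either unnamed with `length(trains)` electrodes (ids
#'   `0:(n-1)`) or named by 0-based electrode id.
#' @param t_start,t_stop recording interval bounds in seconds
#'   (`t_stop > t_start`).
#' @param layout an [electrode_layout()]; defaults to the 60-slot MEA grid
#'   when the number of trains allows it.
#' @return object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, t_start = 0, t_stop, layout = NULL) {
  if (t_stop <= t_start) stop("t_stop must exceed t_start")
  n <- length(trains)
  if (is.null(names(trains))) names(trains) <- as.character(seq_len(n) - 1L)
  ids <- suppressWarnings(as.integer(names(trains)))
  if (anyNA(ids) || anyDuplicated(ids) || any(ids < 0)) {
    stop("train names must be unique non-negative electrode ids")
  }
  for (i in seq_len(n)) {
    tr <- as.numeric(trains[[i]])
    if (length(tr)) {
      if (is.unsorted(tr, strictly = TRUE)) {
        stop("spike times of electrode ", ids[i], " are not strictly increasing")
      }
      if (tr[1] < t_start || tr[length(tr)] >= t_stop) {
        stop("spike times of electrode ", ids[i],
             " fall outside [t_start, t_stop)")
      }
    }
    trains[[i]] <- tr
  }
  if (is.null(layout) && n == 60L) layout <- electrode_layout()
  structure(list(trains = trains, t_start = t_start, t_stop = t_stop,
                 layout = layout),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$trains)
  cat("Spike train set:", length(x$trains), "electrodes,",
      sprintf("[%.3f, %.3f) s,", x$t_start, x$t_stop),
      sum(ns), "spikes\n")
  invisible(x)
}

#' @export
summary.spike_train_set <- function(object, ...) {
  dur <- object$t_stop - object$t_start
  ns <- lengths(object$trains)
  out <- data.frame(electrode = as.integer(names(object$trains)),
                    n_spikes = as.integer(ns),
                    mfr = ns / dur)
  class(out) <- c("summary.spike_train_set", "data.frame")
  out
}

#' Raster plot of a spike-train set
#'
#' @param x a [spike_train_set()]
#' @param interval optional `c(t0, t1)` window to display.
#' @param ... passed to [graphics::plot()]
#' @export
plot.spike_train_set <- function(x, interval = NULL, ...) {
  if (is.null(interval)) interval <- c(x$t_start, x$t_stop)
  graphics::plot(NA, xlim = interval, ylim = c(0, length(x$trains)),
                 xlab = "time (s)", ylab = "electrode", ...)
  for (i in seq_along(x$trains)) {
    tt <- x$trains[[i]]
    tt <- tt[tt >= interval[1] & tt < interval[2]]
    if (length(tt)) {
      graphics::segments(tt, i - 0.9, tt, i - 0.1)
    }
  }
  invisible(x)
}

#' Restrict a spike-train set to a sub-interval
#'
#' @param spikes a [spike_train_set()]
#' @param interval numeric `c(t0, t1)` with `t0 < t1`, inside the recording.
#' @param rebase if `TRUE`, shift times so the cropped set starts at 0.
#' @return a new `spike_train_set` over the interval.
#' @export
crop_spikes <- function(spikes, interval, rebase = FALSE) {
  stopifnot(inherits(spikes, "spike_train_set"), length(interval) == 2)
  t0 <- interval[1]; t1 <- interval[2]
  if (t1 <= t0) stop("empty interval")
  trains <- lapply(spikes$trains, function(tr) tr[tr >= t0 & tr < t1])
  if (rebase) {
    trains <- lapply(trains, function(tr) tr - t0)
    spike_train_set(trains, 0, t1 - t0, layout = spikes$layout)
  } else {
    spike_train_set(trains, t0, t1, layout = spikes$layout)
  }
}

n_spikes_total <- function(spikes) sum(lengths(spikes$trains))

#' Session phase annotation
#'
#' Splits a recording into the protocol phases used throughout the analysis:
#' a basal interval, a discarded settling interval right after drug
#' administration, and two drug phases (the first 30 min, `cch1`, and the last
#' 20 min, `cch2`, of the treated recording). Intervals must be disjoint and
#' ordered.
#'
#' @param basal,cch1,cch2 numeric `c(t0, t1)` intervals in seconds.
#' @param discard optional discarded interval (e.g. the first 10 min after
#'   drug administration).
#' @return object of class `session_phases` (named list of intervals).
#' @export
session_phases <- function(basal, cch1, cch2, discard = NULL) {
  phases <- list(basal = basal, discard = discard, cch1 = cch1, cch2 = cch2)
  phases <- phases[!vapply(phases, is.null, logical(1))]
  for (p in phases) {
    if (length(p) != 2 || p[2] <= p[1]) stop("phases must be c(t0, t1) with t1 > t0")
  }
  bounds <- do.call(rbind, phases)
  ord <- order(bounds[, 1])
  if (any(diff(bounds[ord, 1]) <= 0) ||
      any(bounds[ord, 2][-nrow(bounds)] > bounds[ord, 1][-1])) {
    stop("phase intervals must be disjoint and ordered")
  }
  structure(phases, class = "session_phases")
}
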