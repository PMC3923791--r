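#' Spike train pairs as tidy tables
#'
#' A pre/post spike train pair is stored as a tibble with columns `train`
#' (`"pre"` or `"post"`) and `time_s` (spike onset time in seconds, biological
#' timescale), carrying a `pulse_width` attribute (seconds; default 1 ms
#' biological, corresponding to 1 us at the 1000x accelerated circuit scale).
#'
#' Invariants enforced: within each train, times are strictly increasing,
#' non-negative, and consecutive onsets are separated by at least one pulse
#' width (pulses must not overlap).
#'
#' @param pre,post Numeric vectors of spike onset times (seconds).
#' @param pulse_width Pulse duration in seconds (biological timescale).
#' @return A `spike_trains` tibble.
#' @examples
#' spike_trains(pre = c(0, 1), post = c(0.01, 1.01))
#' @export
spike_trains <- function(pre = numeric(), post = numeric(),
                         pulse_width = 1e-3) {
  stopifnot(is.numeric(pre), is.numeric(post), pulse_width > 0)
  out <- tibble::tibble(
    train = c(rep("pre", length(pre)), rep("post", length(post))),
    time_s = c(as.numeric(pre), as.numeric(post))
  )
  out <- dplyr::arrange(out, .data$time_s, .data$train == "post")
  attr(out, "pulse_width") <- pulse_width
  class(out) <- c("spike_trains", class(out))
  validate_spike_trains(out)
  out
}

#' @rdname spike_trains
#' @param x An object to check/convert.
#' @export
is_spike_trains <- function(x) inherits(x, "spike_trains")

validate_spike_trains <- function(x) {
  pw <- pulse_width(x)
  for (tr in c("pre", "post")) {
    tt <- x$time_s[x$train == tr]
    if (length(tt) == 0) next
    if (any(tt < 0)) abort(paste0(tr, " train has negative spike times"))
    if (length(tt) > 1) {
      gaps <- diff(tt)
      if (any(gaps <= 0)) {
        abort(paste0(tr, " train times must be strictly increasing"))
      }
      if (any(gaps < pw - 1e-15)) {
        abort(paste0(tr, " train has onsets closer than one pulse width"))
      }
    }
  }
  invisible(x)
}

#' Pulse width of a spike-train table
#' @param trains A [spike_trains()] tibble.
#' @return Pulse width in seconds.
#' @export
pulse_width <- function(trains) {
  pw <- attr(trains, "pulse_width", exact = TRUE)
  pw %||% 1e-3
}

#' Extract one train's times
#' @param trains A [spike_trains()] tibble.
#' @param which `"pre"` or `"post"`.
#' @return Numeric vector of onset times (seconds), sorted.
#' @export
train_times <- function(trains, which = c("pre", "post")) {
  which <- match.arg(which)
  sort(trains$time_s[trains$train == which])
}

#' Delay a spike-train table
#'
#' Shifts all spike onsets by a fixed non-negative delay. Used internally to
#' derive the delayed pre(n-1)/post(n-1) inputs the circuit needs (one pulse
#' width late).
#'
#' @param trains A [spike_trains()] tibble.
#' @param delay Delay in seconds, `>= 0`.
#' @return A shifted `spike_trains` tibble.
#' @examples
#' tr <- make_pairing(dt = 0.01, n_reps = 2, rho = 1)
#' delay_train(tr, 1e-3)
#' @export
delay_train <- function(trains, delay) {
  stopifnot(is.numeric(delay), length(delay) == 1, delay >= 0)
  out <- dplyr::mutate(trains, time_s = .data$time_s + delay)
  attr(out, "pulse_width") <- pulse_width(trains)
  class(out) <- unique(c("spike_trains", class(out)))
  out
}

#' Read/write spike trains as two-column CSV
#'
#' The on-disk format is `train,time_s` with `train` in `{pre, post}`.
#'
#' @param trains A [spike_trains()] tibble.
#' @param path File path.
#' @param pulse_width Pulse width to attach on read (seconds).
#' @return `write_spike_trains()` returns `path` invisibly;
#'   `read_spike_trains()` returns a `spike_trains` tibble.
#' @export
write_spike_trains <- function(trains, path) {
  write.csv(trains[, c("train", "time_s")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @export
read_spike_trains <- function(path, pulse_width = 1e-3) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("train", "time_s") %in% names(df)))
  spike_trains(pre = df$time_s[df$train == "pre"],
               post = df$time_s[df$train == "post"],
               pulse_width = pulse_width)
}

# internal: shift both trains so the earliest spike sits at t = 0
shift_to_origin <- function(pre, post) {
  m <- min(c(pre, post, Inf))
  if (!is.finite(m) || m == 0) return(list(pre = pre, post = post))
  list(pre = pre - m, post = post - m)
}
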