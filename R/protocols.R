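#' Pairing protocol
#'
#' Generates the classical STDP pairing protocol: `n_reps` pre/post spike
#' pairs with fixed lag `dt`, repeated at frequency `rho`. The sign convention
#' is `dt = t_post - t_pre` everywhere in this package, so `dt > 0` is the
#' causal pre-before-post order. Both trains are shifted so the earliest spike
#' sits at time 0.
#'
#' @param dt Pair lag in seconds (signed, non-zero; `|dt| < 1/rho`).
#' @param n_reps Number of repetitions (default 60 pairs).
#' @param rho Repetition frequency in Hz (default 1 Hz).
#' @param pulse_width Pulse width in seconds (biological scale).
#' @return A [spike_trains()] tibble.
#' @examples
#' make_pairing(dt = 0.01, n_reps = 60, rho = 1)
#' @export
make_pairing <- function(dt, n_reps = 60, rho = 1, pulse_width = 1e-3) {
  stopifnot(is.numeric(dt), length(dt) == 1, is.finite(dt))
  if (rho <= 0) abort("`rho` must be > 0")
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  if (dt == 0) abort("`dt` must be non-zero (coincident pulses)")
  if (abs(dt) >= 1 / rho) {
    abort("|dt| must be < 1/rho: pairs would interleave ambiguously")
  }
  base <- (seq_len(n_reps) - 1) / rho
  tr <- shift_to_origin(pre = base, post = base + dt)
  spike_trains(pre = tr$pre, post = tr$post, pulse_width = pulse_width)
}

#' Triplet protocol
#'
#' Generates `n_reps` spike triplets at repetition frequency `rho`. For
#' `combo = "pre_post_pre"` each repetition holds pre at the base time, post
#' at `base + dt1` and a second pre at `base + dt1 + dt2`;
#' `"post_pre_post"` is the mirrored pattern. `dt1` and `dt2` are the two
#' (positive) timing gaps of the triplet.
#'
#' @param dt1,dt2 Positive gaps in seconds; `dt1 + dt2 < 1/rho`.
#' @param combo `"pre_post_pre"` or `"post_pre_post"`.
#' @inheritParams make_pairing
#' @return A [spike_trains()] tibble.
#' @examples
#' make_triplet(5e-3, 5e-3, "pre_post_pre", n_reps = 1)
#' @export
make_triplet <- function(dt1, dt2, combo = c("pre_post_pre", "post_pre_post"),
                         n_reps = 60, rho = 1, pulse_width = 1e-3) {
  combo <- match.arg(combo)
  if (!(dt1 > 0 && dt2 > 0)) abort("`dt1` and `dt2` must be > 0")
  if (rho <= 0) abort("`rho` must be > 0")
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  if (dt1 + dt2 >= 1 / rho) abort("triplet span must be < 1/rho")
  base <- (seq_len(n_reps) - 1) / rho
  outer_ <- sort(c(base, base + dt1 + dt2))
  mid <- base + dt1
  if (combo == "pre_post_pre") {
    spike_trains(pre = outer_, post = mid, pulse_width = pulse_width)
  } else {
    spike_trains(pre = mid, post = outer_, pulse_width = pulse_width)
  }
}

extra_triplet_combos <- c("pre_pre_post", "pre_post_pre", "pre_post_post",
                          "post_pre_pre", "post_pre_post", "post_post_pre")

#' Extra-triplet protocol (all six spike-order combinations)
#'
#' Triplets formed by adding a third spike to a pre/post pair, covering all
#' six orderings, repeated (by default) 60 times at 0.2 Hz. `dt1` is the
#' timing of the leftmost adjacent spike pair and `dt2` of the rightmost;
#' their magnitudes are the two inter-spike gaps. Positive values are read as
#' gap magnitudes (the ordering is carried by `combo`); a negative value is
#' honoured as the signed `t_post - t_pre` convention and must then be
#' consistent with the combo's order for that pair, otherwise an error is
#' raised.
#'
#' @param dt1,dt2 Pair timings in seconds (see Details above; non-zero).
#' @param combo One of `"pre_pre_post"`, `"pre_post_pre"`, `"pre_post_post"`,
#'   `"post_pre_pre"`, `"post_pre_post"`, `"post_post_pre"`.
#' @inheritParams make_pairing
#' @return A [spike_trains()] tibble.
#' @examples
#' make_extra_triplet(5e-3, 5e-3, "pre_post_post", n_reps = 1)
#' @export
make_extra_triplet <- function(dt1, dt2, combo = extra_triplet_combos,
                               n_reps = 60, rho = 0.2, pulse_width = 1e-3) {
  combo <- match.arg(combo)
  stopifnot(is.numeric(dt1), is.numeric(dt2))
  if (dt1 == 0 || dt2 == 0) abort("`dt1` and `dt2` must be non-zero")
  if (rho <= 0) abort("`rho` must be > 0")
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  types <- strsplit(combo, "_", fixed = TRUE)[[1]]
  # sign consistency for mixed adjacent pairs under dt = t_post - t_pre
  check_pair <- function(dt, a, b, which) {
    if (a != b && dt < 0 && a == "pre") {
      abort(sprintf("%s = %g s contradicts the %s order of combo '%s'",
                    which, dt, paste(a, b, sep = "->"), combo))
    }
  }
  check_pair(dt1, types[1], types[2], "dt1")
  check_pair(dt2, types[2], types[3], "dt2")
  g1 <- abs(dt1); g2 <- abs(dt2)
  if (g1 + g2 >= 1 / rho) abort("triplet span must be < 1/rho")
  base <- (seq_len(n_reps) - 1) / rho
  offs <- c(0, g1, g1 + g2)
  pre <- sort(unlist(lapply(which(types == "pre"), function(i) base + offs[i])))
  post <- sort(unlist(lapply(which(types == "post"), function(i) base + offs[i])))
  spike_trains(pre = pre, post = post, pulse_width = pulse_width)
}

#' Grid of extra-triplet protocol points
#'
#' Enumerates `(combo, dt1, dt2)` cells over a grid of gap magnitudes for all
#' six (or a chosen subset of) spike-order combinations, the layout explored
#' by multi-spike interaction experiments.
#'
#' @param dt_values_ms Vector of positive gap magnitudes in milliseconds.
#' @param combos Combinations to include (default all six).
#' @return A tibble with columns `combo`, `dt1_ms`, `dt2_ms`.
#' @export
extra_triplet_grid <- function(dt_values_ms = c(1, 5, 10, 15, 20, 25),
                               combos = extra_triplet_combos) {
  stopifnot(all(dt_values_ms > 0))
  combos <- match.arg(combos, extra_triplet_combos, several.ok = TRUE)
  tidyr::expand_grid(combo = combos, dt1_ms = dt_values_ms,
                     dt2_ms = dt_values_ms)
}

#' Quadruplet protocol
#'
#' Generates `n_reps` spike quadruplets at repetition frequency `rho`. For
#' `T > 0` a post-pre pair (lag `dt`) precedes a pre-post pair (lag `dt`),
#' with `T` the interval between the two inner (pre) spikes; for `T < 0` the
#' order is mirrored (pre-post precedes post-pre). The full quadruplet span is
#' `2 dt + |T|`.
#'
#' @param T_sep Signed quadruplet separation in seconds (non-zero).
#' @param dt Intra-pair lag in seconds (default 5 ms, the value used for all
#'   quadruplet experiments here).
#' @inheritParams make_pairing
#' @return A [spike_trains()] tibble.
#' @examples
#' make_quadruplet(T_sep = 0.02, n_reps = 1)
#' @export
make_quadruplet <- function(T_sep, dt = 5e-3, n_reps = 60, rho = 1,
                            pulse_width = 1e-3) {
  stopifnot(is.numeric(T_sep), length(T_sep) == 1, dt > 0)
  if (T_sep == 0) abort("`T_sep` must be non-zero (coincident inner spikes)")
  if (rho <= 0) abort("`rho` must be > 0")
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  span <- 2 * dt + abs(T_sep)
  if (span >= 1 / rho) abort("quadruplet span must be < 1/rho")
  base <- (seq_len(n_reps) - 1) / rho
  if (T_sep > 0) {
    post <- sort(c(base, base + span))
    pre <- sort(c(base + dt, base + dt + T_sep))
  } else {
    pre <- sort(c(base, base + span))
    post <- sort(c(base + dt, base + dt + abs(T_sep)))
  }
  spike_trains(pre = pre, post = post, pulse_width = pulse_width)
}

#' Poissonian pre/post spike-train pair
#'
#' Two independent homogeneous Poisson trains with the given rates, thinned
#' so that consecutive onsets in each train are at least one pulse width
#' apart (overlapping pulses are physically meaningless for the circuit).
#' Reproducible under a fixed seed.
#'
#' @param rho_pre,rho_post Rates in Hz, `>= 0`.
#' @param duration Train duration in seconds, `> 0`.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @inheritParams make_pairing
#' @return A [spike_trains()] tibble.
#' @examples
#' make_poisson_pair(10, 10, duration = 1, seed = 1)
#' @export
make_poisson_pair <- function(rho_pre, rho_post, duration, seed = NULL,
                              pulse_width = 1e-3) {
  stopifnot(rho_pre >= 0, rho_post >= 0, duration > 0)
  gen <- function(rate) {
    if (rate == 0) return(numeric())
    n_guess <- ceiling(rate * duration + 10 * sqrt(rate * duration) + 10)
    tt <- cumsum(rexp(n_guess, rate))
    while (length(tt) && tt[length(tt)] < duration) {
      tt <- c(tt, tt[length(tt)] + cumsum(rexp(n_guess, rate)))
    }
    tt <- tt[tt < duration]
    if (length(tt) < 2) return(tt)
    # enforce the refractory gap of one pulse width
    keep <- tt[1]
    for (t in tt[-1]) if (t - keep[length(keep)] >= pulse_width) keep <- c(keep, t)
    keep
  }
  with_seed(seed, {
    pre <- gen(rho_pre)
    post <- gen(rho_post)
    spike_trains(pre = pre, post = post, pulse_width = pulse_width)
  })
}

#' Protocol specification rows
#'
#' A protocol specification is a one-row tibble describing a stimulation
#' protocol; datasets are stacks of such rows with measured weight changes
#' attached. Timing columns are in milliseconds (the reporting convention of
#' the experimental literature); rates in Hz.
#'
#' @param protocol One of `"pairing"`, `"triplet"`, `"extra_triplet"`,
#'   `"quadruplet"`, `"poisson_pair"`.
#' @param dt_ms Pairing lag (ms, signed).
#' @param dt1_ms,dt2_ms Triplet gaps/timings (ms).
#' @param T_ms Quadruplet separation (ms, signed).
#' @param combo Spike-order label for triplet protocols.
#' @param n_reps Repetition count.
#' @param rho_Hz Repetition frequency (Hz).
#' @param rho_pre_Hz,rho_post_Hz Poisson rates (Hz).
#' @param duration_s Poisson train duration (s).
#' @param seed Seed for stochastic protocols.
#' @return A one-row tibble.
#' @examples
#' protocol_spec("pairing", dt_ms = 10)
#' @export
protocol_spec <- function(protocol, dt_ms = NA_real_, dt1_ms = NA_real_,
                          dt2_ms = NA_real_, T_ms = NA_real_,
                          combo = NA_character_, n_reps = 60, rho_Hz = 1,
                          rho_pre_Hz = NA_real_, rho_post_Hz = NA_real_,
                          duration_s = NA_real_, seed = NA_integer_) {
  protocol <- match.arg(protocol, c("pairing", "triplet", "extra_triplet",
                                    "quadruplet", "poisson_pair"))
  if (n_reps < 1) abort("`n_reps` must be >= 1")
  tibble::tibble(
    protocol = protocol, dt_ms = dt_ms, dt1_ms = dt1_ms, dt2_ms = dt2_ms,
    T_ms = T_ms, combo = combo, n_reps = as.integer(n_reps), rho_Hz = rho_Hz,
    rho_pre_Hz = rho_pre_Hz, rho_post_Hz = rho_post_Hz,
    duration_s = duration_s, seed = as.integer(seed)
  )
}

#' Build the spike trains for a protocol specification
#'
#' @param spec A one-row tibble as returned by [protocol_spec()].
#' @param pulse_width Pulse width in seconds.
#' @return A [spike_trains()] tibble.
#' @export
protocol_trains <- function(spec, pulse_width = 1e-3) {
  stopifnot(is.data.frame(spec), nrow(spec) == 1)
  ms <- function(x) x / 1000
  switch(
    spec$protocol,
    pairing = make_pairing(ms(spec$dt_ms), spec$n_reps, spec$rho_Hz,
                           pulse_width),
    triplet = make_triplet(ms(spec$dt1_ms), ms(spec$dt2_ms), spec$combo,
                           spec$n_reps, spec$rho_Hz, pulse_width),
    extra_triplet = make_extra_triplet(ms(spec$dt1_ms), ms(spec$dt2_ms),
                                       spec$combo, spec$n_reps, spec$rho_Hz,
                                       pulse_width),
    quadruplet = make_quadruplet(ms(spec$T_ms),
                                 dt = if (is.na(spec$dt_ms)) 5e-3 else ms(spec$dt_ms),
                                 n_reps = spec$n_reps, rho = spec$rho_Hz,
                                 pulse_width = pulse_width),
    poisson_pair = make_poisson_pair(spec$rho_pre_Hz, spec$rho_post_Hz,
                                     spec$duration_s,
                                     seed = if (is.na(spec$seed)) NULL else spec$seed,
                                     pulse_width = pulse_width),
    abort(paste0("unknown protocol: ", spec$protocol))
  )
}
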