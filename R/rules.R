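#' Weight-change logs
#'
#' Rule applications return a `dw_log`: a tibble with one row per triggered
#' update (`time_s`, `train` of the triggering spike, signed `contribution`),
#' whose `total_dw` attribute equals the sum of contributions.
#'
#' @param log A `dw_log` tibble.
#' @return `total_dw()` returns the summed weight change (dimensionless).
#' @export
total_dw <- function(log) {
  attr(log, "total_dw", exact = TRUE) %||% sum(log$contribution)
}

new_dw_log <- function(time_s, train, contribution) {
  out <- tibble::tibble(time_s = time_s, train = train,
                        contribution = contribution)
  attr(out, "total_dw") <- sum(contribution)
  class(out) <- c("dw_log", class(out))
  out
}

# internal: merged event table with tie-break pre-first at equal times
merge_events <- function(pre, post) {
  ev <- tibble::tibble(
    time_s = c(pre, post),
    is_post = c(rep(FALSE, length(pre)), rep(TRUE, length(post)))
  )
  ev[order(ev$time_s, ev$is_post), ]
}

#' Apply the pair-based STDP rule
#'
#' Event-driven application of the nearest-spike PSTDP rule: each
#' post-synaptic spike with at least one preceding pre-synaptic spike adds
#' `A_plus * exp(-dt / tau_plus)` (with `dt` the lag to the nearest pre);
#' each pre-synaptic spike with a preceding post subtracts
#' `A_minus * exp(-dt' / tau_minus)`. Only the nearest opposite-train spike
#' interacts: every spike supersedes earlier spikes of its own train.
#' Simultaneous pre and post spikes are processed pre-first, so a coincident
#' pair contributes a potentiation at zero lag.
#'
#' @param trains A [spike_trains()] tibble.
#' @param params A [pair_params()] object.
#' @return A `dw_log` tibble (see [total_dw()]).
#' @examples
#' tr <- make_pairing(dt = 0.01, n_reps = 60, rho = 1)
#' total_dw(pstdp_apply(tr, pair_params()))
#' @export
pstdp_apply <- function(trains, params) {
  stopifnot(inherits(params, "pair_params"))
  ev <- merge_events(train_times(trains, "pre"), train_times(trains, "post"))
  n <- nrow(ev)
  if (n == 0) return(new_dw_log(numeric(), character(), numeric()))
  t_pre <- NA_real_; t_post <- NA_real_
  times <- numeric(n); who <- character(n); dw <- numeric(n); k <- 0
  for (i in seq_len(n)) {
    t <- ev$time_s[i]
    if (ev$is_post[i]) {
      if (!is.na(t_pre)) {
        k <- k + 1
        times[k] <- t; who[k] <- "post"
        dw[k] <- params$A_plus * exp(-(t - t_pre) / params$tau_plus)
      }
      t_post <- t
    } else {
      if (!is.na(t_post)) {
        k <- k + 1
        times[k] <- t; who[k] <- "pre"
        dw[k] <- -params$A_minus * exp(-(t - t_post) / params$tau_minus)
      }
      t_pre <- t
    }
  }
  new_dw_log(times[seq_len(k)], who[seq_len(k)], dw[seq_len(k)])
}

#' Apply the triplet STDP rule
#'
#' Event-driven application of the nearest-spike TSTDP rule via decaying
#' trace variables that reset to 1 on each same-train spike (the trace-reset
#' formulation of nearest-spike interaction). At each post-synaptic spike at
#' time `t` with at least one prior pre spike the weight gains
#' `exp(-(t - t_pre)/tau_plus) * (A2_plus + A3_plus * exp(-(t - t_prevpost -
#' epsilon)/tau_y))`, the triplet term present only when a previous post
#' exists; each pre spike mirrors this with the depression amplitudes and
#' `tau_minus`, `tau_x`. Simultaneous pre/post spikes are processed
#' pre-first.
#'
#' `form` selects between the factorized arrangement above and the expanded
#' arrangement that accumulates the pair and triplet terms as separate
#' contributions; the two are algebraically identical and are cross-checked
#' in the package tests.
#'
#' @param trains A [spike_trains()] tibble.
#' @param params A [triplet_params()] object.
#' @param form `"factorized"` or `"expanded"` evaluation order.
#' @return A `dw_log` tibble (see [total_dw()]).
#' @examples
#' tr <- make_triplet(5e-3, 5e-3, "post_pre_post", n_reps = 1)
#' total_dw(tstdp_apply(tr, hippocampal_params()))
#' @export
tstdp_apply <- function(trains, params, form = c("factorized", "expanded")) {
  stopifnot(inherits(params, "triplet_params"))
  form <- match.arg(form)
  ev <- merge_events(train_times(trains, "pre"), train_times(trains, "post"))
  n <- nrow(ev)
  if (n == 0) return(new_dw_log(numeric(), character(), numeric()))
  p <- params
  # last same/opposite spike times carry the reset traces:
  # r1 = exp(-(t - t_pre)/tau_plus), o1 = exp(-(t - t_post)/tau_minus),
  # r2, o2 analogous with tau_x, tau_y.
  t_pre <- NA_real_; t_post <- NA_real_
  times <- numeric(n); who <- character(n); dw <- numeric(n); k <- 0
  for (i in seq_len(n)) {
    t <- ev$time_s[i]
    if (ev$is_post[i]) {
      if (!is.na(t_pre)) {
        r1 <- exp(-(t - t_pre) / p$tau_plus)
        o2 <- if (!is.na(t_post)) exp(-(t - t_post - p$epsilon) / p$tau_y) else 0
        d <- if (form == "factorized") {
          r1 * (p$A2_plus + p$A3_plus * o2)
        } else {
          p$A2_plus * r1 + p$A3_plus * r1 * o2
        }
        k <- k + 1; times[k] <- t; who[k] <- "post"; dw[k] <- d
      }
      t_post <- t
    } else {
      if (!is.na(t_post)) {
        o1 <- exp(-(t - t_post) / p$tau_minus)
        r2 <- if (!is.na(t_pre)) exp(-(t - t_pre - p$epsilon) / p$tau_x) else 0
        d <- if (form == "factorized") {
          -o1 * (p$A2_minus + p$A3_minus * r2)
        } else {
          -(p$A2_minus * o1 + p$A3_minus * o1 * r2)
        }
        k <- k + 1; times[k] <- t; who[k] <- "pre"; dw[k] <- d
      }
      t_pre <- t
    }
  }
  new_dw_log(times[seq_len(k)], who[seq_len(k)], dw[seq_len(k)])
}

#' Run a stimulation protocol through a plasticity rule
#'
#' Generates the trains for a [protocol_spec()] row and returns the total
#' weight change under the requested rule.
#'
#' @param spec A one-row [protocol_spec()] tibble.
#' @param params A [pair_params()] or [triplet_params()] object.
#' @param pulse_width Pulse width in seconds.
#' @return Total weight change (dimensionless scalar).
#' @examples
#' run_protocol(protocol_spec("pairing", dt_ms = 10), hippocampal_params())
#' @export
run_protocol <- function(spec, params, pulse_width = 1e-3) {
  trains <- protocol_trains(spec, pulse_width = pulse_width)
  log <- if (inherits(params, "pair_params")) {
    pstdp_apply(trains, params)
  } else {
    tstdp_apply(trains, params)
  }
  total_dw(log)
}

#' BCM-like rate sweep under Poissonian stimulation
#'
#' Sweeps the post-synaptic Poisson rate over `rho_post_grid` with the
#' pre-synaptic rate fixed (default 10 Hz), running `trials` independent
#' Poisson pairs per grid point, and returns per-rate mean and standard
#' deviation of the total weight change. Fresh pre- and post-synaptic trains
#' are drawn for every trial. With suitable triplet parameters the mean curve
#' is the BCM-like shape: depression at low post rates, potentiation at high
#' rates, with a sliding crossover threshold.
#'
#' @param params A [triplet_params()] (or [pair_params()]) object.
#' @param rho_pre Fixed pre-synaptic rate (Hz).
#' @param rho_post_grid Vector of post-synaptic rates (Hz, `>= 0`).
#' @param duration Train duration per trial (seconds; default 20 s).
#' @param trials Independent trials per grid point (default 10).
#' @param seed Integer seed; every trial derives its own stream from it.
#' @param pulse_width Pulse width in seconds.
#' @return A tibble of class `bcm_sweep`: `rho_post_Hz`, `mean_dw`, `sd_dw`,
#'   `trials` (and `rho_pre_Hz`).
#' @examples
#' bcm_sweep(visual_cortex_params(), rho_post_grid = c(0, 10, 40),
#'           duration = 2, trials = 2, seed = 1)
#' @export
bcm_sweep <- function(params, rho_pre = 10, rho_post_grid = seq(0, 50, by = 5),
                      duration = 20, trials = 10, seed = 1,
                      pulse_width = 1e-3) {
  stopifnot(all(rho_post_grid >= 0), trials >= 1, duration > 0)
  res <- purrr::map_dfr(seq_along(rho_post_grid), function(i) {
    rp <- rho_post_grid[i]
    dws <- vapply(seq_len(trials), function(j) {
      tr <- make_poisson_pair(rho_pre, rp, duration,
                              seed = derive_seed(seed, i, j),
                              pulse_width = pulse_width)
      total_dw(tstdp_or_pstdp(tr, params))
    }, numeric(1))
    tibble::tibble(rho_pre_Hz = rho_pre, rho_post_Hz = rp,
                   mean_dw = mean(dws),
                   sd_dw = if (trials > 1) sd(dws) else 0,
                   trials = trials)
  })
  class(res) <- c("bcm_sweep", class(res))
  res
}

#' @rdname bcm_sweep
#' @param rho_grid Vector of rates (Hz) applied to both trains
#'   (`rho_post = rho_pre`, the linear-neuron simplification).
#' @export
bcm_sweep_pre_driven <- function(params, rho_grid = seq(0, 50, by = 5),
                                 duration = 20, trials = 10, seed = 1,
                                 pulse_width = 1e-3) {
  stopifnot(all(rho_grid >= 0), trials >= 1, duration > 0)
  res <- purrr::map_dfr(seq_along(rho_grid), function(i) {
    r <- rho_grid[i]
    dws <- vapply(seq_len(trials), function(j) {
      tr <- make_poisson_pair(r, r, duration,
                              seed = derive_seed(seed, 7L, i, j),
                              pulse_width = pulse_width)
      total_dw(tstdp_or_pstdp(tr, params))
    }, numeric(1))
    tibble::tibble(rho_pre_Hz = r, rho_post_Hz = r,
                   mean_dw = mean(dws),
                   sd_dw = if (trials > 1) sd(dws) else 0,
                   trials = trials)
  })
  class(res) <- c("bcm_sweep", class(res))
  res
}

tstdp_or_pstdp <- function(trains, params) {
  if (inherits(params, "pair_params")) pstdp_apply(trains, params)
  else tstdp_apply(trains, params)
}

#' Locate the LTD-to-LTP crossing of a BCM sweep
#'
#' Linear interpolation of the first sign change (negative to positive) of
#' the mean weight-change curve; the BCM modification threshold.
#'
#' @param sweep A [bcm_sweep()] result.
#' @return Crossing rate in Hz (`NA` if the curve does not cross).
#' @export
bcm_crossing <- function(sweep) {
  x <- sweep$rho_post_Hz; y <- sweep$mean_dw
  ord <- order(x); x <- x[ord]; y <- y[ord]
  for (i in seq_len(length(x) - 1)) {
    if (x[i] > 0 && y[i] < 0 && y[i + 1] >= 0) {
      return(x[i] + (0 - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i]))
    }
  }
  NA_real_
}

#' STDP learning-window sweep
#'
#' Runs the pairing protocol over a grid of lags and returns the total weight
#' change per lag: the classical STDP window (LTP for positive lags, LTD for
#' negative lags).
#'
#' @param params Rule parameters ([pair_params()] or [triplet_params()]).
#' @param dt_grid_ms Vector of signed pairing lags in milliseconds.
#' @param n_reps,rho Pairing protocol settings.
#' @param pulse_width Pulse width in seconds.
#' @return A tibble of class `stdp_window`: `dt_ms`, `dw`.
#' @examples
#' stdp_window(hippocampal_params(), dt_grid_ms = c(-20, -10, 10, 20))
#' @export
stdp_window <- function(params, dt_grid_ms = seq(-100, 100, by = 5),
                        n_reps = 60, rho = 1, pulse_width = 1e-3) {
  dt_grid_ms <- dt_grid_ms[dt_grid_ms != 0]
  res <- purrr::map_dfr(dt_grid_ms, function(dtm) {
    spec <- protocol_spec("pairing", dt_ms = dtm, n_reps = n_reps,
                          rho_Hz = rho)
    tibble::tibble(dt_ms = dtm, dw = run_protocol(spec, params, pulse_width))
  })
  class(res) <- c("stdp_window", class(res))
  res
}
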