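# Event-driven and ramp-based simulators of the synapse circuit.

# internal: accelerated pre/post times with overlap checks
accelerate_trains <- function(trains, device) {
  pre <- train_times(trains, "pre") / device$time_accel
  post <- train_times(trains, "post") / device$time_accel
  pw <- device$pulse_width_accel
  for (tt in list(pre, post)) {
    if (length(tt) > 1 && any(diff(tt) < pw - 1e-18)) {
      abort("pulses overlap within a train after time acceleration")
    }
  }
  if (length(pre) && length(post)) {
    idx <- findInterval(post, pre)
    near <- c(-Inf, pre)[idx + 1]
    if (any(post - near < pw & post - near > 0)) {
      abort("pre and post pulses overlap after time acceleration")
    }
    idx2 <- findInterval(pre, post)
    near2 <- c(-Inf, post)[idx2 + 1]
    if (any(pre - near2 < pw & pre - near2 > 0)) {
      abort("pre and post pulses overlap after time acceleration")
    }
  }
  list(pre = pre, post = post, pw = pw)
}

# internal: per-trigger timing table (accelerated timescale)
# d1 = lag to nearest opposite-train predecessor (NA if none)
# d2 = lag to previous same-train spike (NA if none)
circuit_event_table <- function(trains, device) {
  acc <- accelerate_trains(trains, device)
  pre <- acc$pre; post <- acc$post
  lag_opposite <- function(t, opp, strict) {
    if (!length(t)) return(numeric())
    idx <- findInterval(t, opp)
    if (strict) {
      eq <- idx > 0 & opp[pmax(idx, 1)] == t
      idx[eq] <- idx[eq] - 1
    }
    prev <- ifelse(idx > 0, opp[pmax(idx, 1)], NA_real_)
    t - prev
  }
  lag_same <- function(t) {
    if (length(t) < 2) return(rep(NA_real_, length(t)))
    c(NA_real_, diff(t))
  }
  tibble::tibble(
    time = c(post, pre),
    type = c(rep("pot", length(post)), rep("dep", length(pre))),
    # pre-first tie-break: a post at t sees a pre at t, not vice versa
    d1 = c(lag_opposite(post, pre, strict = FALSE),
           lag_opposite(pre, post, strict = TRUE)),
    d2 = c(lag_same(post), lag_same(pre))
  )
}

# internal: per-event weight-capacitor voltage increments (volts)
circuit_event_dv <- function(evtab, eff, device, eps_c = device$pulse_width_accel) {
  scale <- device$pulse_width_accel / device$Cw
  dv <- numeric(nrow(evtab))
  pot <- evtab$type == "pot"
  f1 <- function(rows, tau, window) {
    d1 <- evtab$d1[rows]
    out <- ifelse(!is.na(d1) & d1 <= window, exp(-d1 / tau), 0)
    ifelse(is.na(out), 0, out)
  }
  f2 <- function(rows, tau, window) {
    d2 <- evtab$d2[rows]
    out <- ifelse(!is.na(d2) & d2 <= window, exp(-(d2 - eps_c) / tau), 0)
    ifelse(is.na(out), 0, out)
  }
  dv[pot] <- scale * f1(pot, eff$tau_plus, eff$window_plus) *
    (eff$I_A2p + eff$I_A3p * f2(pot, eff$tau_y, eff$window_y))
  dv[!pot] <- -scale * f1(!pot, eff$tau_minus, eff$window_minus) *
    (eff$I_A2m + eff$I_A3m * f2(!pot, eff$tau_x, eff$window_x))
  dv
}

# internal: clamp a cumulative trajectory to the supply rails; returns the
# trajectory plus an exact total (avoiding w0-cancellation when unclamped)
clamp_cumsum <- function(w0, dv, lo, hi) {
  traj <- w0 + cumsum(dv)
  if (all(traj >= lo & traj <= hi)) {
    return(list(traj = traj, total = sum(dv)))
  }
  w <- w0
  for (i in seq_along(dv)) {
    w <- min(max(w + dv[i], lo), hi)
    traj[i] <- w
  }
  list(traj = traj, total = w - w0)
}

#' Event-driven circuit simulation
#'
#' Simulates the synapse circuit's weight-capacitor voltage on the
#' accelerated timescale by evaluating the analytical subthreshold current
#' expressions at each spike. At a post-synaptic spike with lag `d1` to the
#' nearest pre spike (and `d2` to the previous post spike) the weight gains
#' `(pulse_width_accel / Cw) * exp(-d1/tau_plus) * (I_A2p + I_A3p *
#' exp(-(d2 - pulse_width_accel)/tau_y))`, each branch gated off beyond its
#' ramp window; pre-synaptic spikes mirror this with the depression branch.
#' The one-pulse-width offset in the triplet term reflects the delayed
#' pre(n-1)/post(n-1) inputs the circuit receives. `V_w` is clamped to
#' `[0, Vdd]`. Nearest-spike semantics throughout (each spike supersedes
#' earlier same-train spikes); simultaneous pre/post spikes are processed
#' pre-first.
#'
#' @param trains A [spike_trains()] tibble (biological timescale).
#' @param biases A [circuit_biases()] object (ignored when `effective` is
#'   supplied).
#' @param device A [device_params()] object.
#' @param variant Circuit variant (`"full18"`, `"minimal14"`, `"minimal13"`).
#' @param w_init Initial weight voltage (V, within `[0, Vdd]`); default
#'   mid-rail.
#' @param effective Optional [effective_params()] overriding the bias mapping.
#' @return An object of class `circuit_sim` with elements `trajectory`
#'   (tibble: `time_s` biological, `V_w`), `dV_w` (total change, V),
#'   `effective`, `w_init`.
#' @examples
#' tr <- make_pairing(dt = 0.01, n_reps = 10)
#' sim <- simulate_event(tr, circuit_biases(), variant = "minimal14")
#' sim$dV_w
#' @export
simulate_event <- function(trains, biases = circuit_biases(),
                           device = device_params(),
                           variant = circuit_variants,
                           w_init = device$Vdd / 2, effective = NULL) {
  variant <- match.arg(variant)
  if (w_init < 0 || w_init > device$Vdd) abort("`w_init` must lie in [0, Vdd]")
  eff <- effective %||% biases_to_effective(biases, device, variant)
  evtab <- circuit_event_table(trains, device)
  ord <- order(evtab$time, evtab$type == "pot")
  evtab <- evtab[ord, ]
  dv <- circuit_event_dv(evtab, eff, device)
  cl <- clamp_cumsum(w_init, dv, 0, device$Vdd)
  out <- list(
    trajectory = tibble::tibble(
      time_s = evtab$time * device$time_accel,
      V_w = cl$traj
    ),
    dV_w = if (length(dv)) cl$total else 0,
    effective = eff, w_init = w_init, device = device, variant = variant
  )
  class(out) <- "circuit_sim"
  out
}

#' Ramp-based (time-stepped) circuit simulation
#'
#' Simulates the circuit's internal node dynamics explicitly: each ramp node
#' is pulled to ground by its triggering pulse and then rises linearly toward
#' `Vdd` at its bias-set slope (`UT / (kappa * tau)` per second), clamping at
#' the supply; while a gating pulse of the opposite train is high, the branch
#' current follows the subthreshold exponential of the instantaneous node
#' voltage and is integrated onto the weight capacitor at resolution `step`.
#' Between pulses the nodes are advanced analytically (they are exactly
#' piecewise linear), so `step` only controls the in-pulse integration. Node
#' ramps are referenced to their triggering pulse's midpoint, which removes
#' the order-`pulse_width/tau` timing bias relative to [simulate_event()];
#' the triplet nodes are driven by the internally delayed (one pulse width)
#' spike trains.
#'
#' @inheritParams simulate_event
#' @param step Integration step (s, accelerated timescale); must be at most
#'   `pulse_width_accel / 10`.
#' @return An object of class `circuit_ramp_sim` with `trajectory` (tibble:
#'   `time_s` biological, `V_w` after each pulse), `dV_w`, `effective`, node
#'   slopes/reset times, and `w_init`. Node waveforms can be queried with
#'   [ramp_node_voltage()].
#' @examples
#' tr <- make_pairing(dt = 0.01, n_reps = 2)
#' sim <- simulate_ramp_ode(tr, circuit_biases(), variant = "minimal14")
#' sim$dV_w
#' @export
simulate_ramp_ode <- function(trains, biases = circuit_biases(),
                              device = device_params(),
                              variant = circuit_variants,
                              w_init = device$Vdd / 2, effective = NULL,
                              step = device$pulse_width_accel / 20) {
  variant <- match.arg(variant)
  if (step > device$pulse_width_accel / 10) {
    abort("`step` must be <= pulse_width_accel / 10")
  }
  if (w_init < 0 || w_init > device$Vdd) abort("`w_init` must lie in [0, Vdd]")
  eff <- effective %||% biases_to_effective(biases, device, variant)
  acc <- accelerate_trains(trains, device)
  pw <- acc$pw
  d <- device
  # node ramp zero-crossings: triggering pulse midpoints; triplet nodes are
  # reset by the delayed trains (one pulse width late)
  nodes <- list(
    pot = list(zeros = acc$pre + pw / 2, slope = d$UT / (d$kappa * eff$tau_plus)),
    dep = list(zeros = acc$post + pw / 2, slope = d$UT / (d$kappa * eff$tau_minus)),
    y = list(zeros = acc$post + 3 * pw / 2, slope = d$UT / (d$kappa * eff$tau_y)),
    x = list(zeros = acc$pre + 3 * pw / 2, slope = d$UT / (d$kappa * eff$tau_x))
  )
  node_v <- function(node, u) ramp_node_value(nodes[[node]], u, pw, d$Vdd)
  efac <- function(node, u) exp(-d$kappa * node_v(node, u) / d$UT)
  gate <- rbind(
    if (length(acc$post)) data.frame(t = acc$post, pot = TRUE) else NULL,
    if (length(acc$pre)) data.frame(t = acc$pre, pot = FALSE) else NULL
  )
  w <- w_init; tot <- 0
  times <- numeric(0); vw <- numeric(0)
  if (!is.null(gate) && nrow(gate)) {
    gate <- gate[order(gate$t, gate$pot), ]
    nsub <- max(2L, ceiling(pw / step))
    h <- pw / nsub
    for (i in seq_len(nrow(gate))) {
      t0 <- gate$t[i]
      u <- t0 + (seq_len(nsub) - 0.5) * h   # midpoint rule over the pulse
      cur <- if (gate$pot[i]) {
        # potentiation branch gated by the post pulse; the triplet node still
        # holds the previous-post ramp because its reset pulse is delayed
        efac("pot", u) * (eff$I_A2p + eff$I_A3p * efac("y", u))
      } else {
        -efac("dep", u) * (eff$I_A2m + eff$I_A3m * efac("x", u))
      }
      for (dvi in cur * h / d$Cw) {
        w_new <- min(max(w + dvi, 0), d$Vdd)
        tot <- tot + (w_new - w)
        w <- w_new
      }
      times <- c(times, t0 + pw); vw <- c(vw, w)
    }
  }
  out <- list(
    trajectory = tibble::tibble(time_s = times * d$time_accel, V_w = vw),
    dV_w = tot, effective = eff, w_init = w_init,
    nodes = nodes, device = d, variant = variant
  )
  class(out) <- "circuit_ramp_sim"
  out
}

#' Query internal node waveforms of a ramp simulation
#'
#' @param sim A [simulate_ramp_ode()] result.
#' @param node One of `"pot"`, `"dep"`, `"y"`, `"x"`.
#' @param times_s Biological times at which to evaluate the node voltage.
#' @return Numeric vector of node voltages (V).
#' @export
ramp_node_voltage <- function(sim, node = c("pot", "dep", "y", "x"), times_s) {
  node <- match.arg(node)
  d <- sim$device
  ramp_node_value(sim$nodes[[node]], times_s / d$time_accel,
                  d$pulse_width_accel, d$Vdd)
}

# internal: piecewise-linear node waveform. The node rests at Vdd before its
# first reset, is held at ground while its triggering pulse is high (ramp
# zero-crossings sit at pulse midpoints, so the grounded window is
# [zero - pw/2, zero]), and otherwise ramps linearly from its last zero,
# clamped to the rails.
ramp_node_value <- function(node, u, pw, Vdd) {
  z <- node$zeros
  idx <- findInterval(u, z)
  v <- ifelse(idx > 0, node$slope * (u - z[pmax(idx, 1)]), Vdd)
  nxt <- z[pmin(idx + 1, length(z))]
  grounded <- idx < length(z) & (nxt - u) <= pw / 2 & (nxt - u) >= 0
  v[grounded] <- 0
  pmin(pmax(v, 0), Vdd)
}
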