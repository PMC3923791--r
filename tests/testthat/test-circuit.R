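dev <- device_params()

ref_effective <- function() {
  effective_params(I_A2p = 1e-9, I_A2m = 0.7e-9, I_A3p = 2e-9, I_A3m = 0,
                   tau_plus = 16.8e-6, tau_minus = 33.7e-6,
                   tau_x = 101e-6, tau_y = 48e-6)
}

test_that("bias mapping follows the subthreshold exponential", {
  b <- circuit_biases(V_A2p = 0.4)
  e1 <- biases_to_effective(b, dev, "minimal14")
  b2 <- b; b2$V_A2p <- 0.4 + dev$UT / dev$kappa
  e2 <- biases_to_effective(b2, dev, "minimal14")
  expect_equal(e2$I_A2p / e1$I_A2p, exp(1), tolerance = 1e-12)

  # raising V_tp slows the ramp and lengthens tau_plus, monotonically
  taus <- vapply(c(2.7, 2.9, 3.1), function(v) {
    bb <- b; bb$V_tp <- v
    biases_to_effective(bb, dev, "minimal14")$tau_plus
  }, numeric(1))
  expect_true(all(diff(taus) > 0))

  # variant constraints
  expect_equal(biases_to_effective(b, dev, "minimal13")$I_A2p, 0)
  expect_equal(biases_to_effective(b, dev, "minimal14")$I_A3m, 0)
  expect_gt(biases_to_effective(circuit_biases(V_A3m = 0.4), dev,
                                "full18")$I_A3m, 0)

  bad <- circuit_biases(V_A2p = 4)
  expect_error(biases_to_effective(bad, dev, "minimal14"), "Vdd")

  # windows sit beyond their time constants
  e <- biases_to_effective(circuit_biases(), dev, "full18")
  expect_true(all(c(e$window_plus >= e$tau_plus,
                    e$window_minus >= e$tau_minus,
                    e$window_x >= e$tau_x, e$window_y >= e$tau_y)))
})

test_that("biases_for_effective inverts the mapping", {
  p <- hippocampal_params()
  b <- biases_for_effective(p, dev)
  eff <- biases_to_effective(b, dev, "minimal14")
  expect_equal(eff$tau_plus, p$tau_plus / dev$time_accel, tolerance = 1e-9)
  expect_equal(eff$tau_minus, p$tau_minus / dev$time_accel, tolerance = 1e-9)
  expect_equal(eff$tau_y, p$tau_y / dev$time_accel, tolerance = 1e-9)
  # amplitude currents proportional to the rule amplitudes
  expect_equal(eff$I_A2p / eff$I_A3p, p$A2_plus / p$A3_plus, tolerance = 1e-9)
  expect_equal(eff$I_A2p, 2e-7 * p$A2_plus, tolerance = 1e-9)
})

test_that("event simulator reproduces the single-pair closed form", {
  eff <- ref_effective()
  for (dtm in c(5e-3, 16.8e-3, 60e-3)) {
    sim <- simulate_event(spike_trains(pre = 0, post = dtm),
                          effective = eff, device = dev,
                          variant = "minimal14")
    expect_equal(sim$dV_w,
                 (dev$pulse_width_accel / dev$Cw) * eff$I_A2p *
                   exp(-(dtm / dev$time_accel) / eff$tau_plus),
                 tolerance = 1e-12)
  }
  # no spikes: flat trajectory
  s0 <- simulate_event(spike_trains(), effective = ref_effective(),
                       device = dev, variant = "minimal14")
  expect_equal(s0$dV_w, 0)
})

test_that("pairing sweep yields an exponential STDP window in the circuit", {
  eff <- ref_effective()
  dts <- c(seq(-100e-3, -2e-3, by = 7e-3), seq(2e-3, 100e-3, by = 7e-3))
  dv <- vapply(dts, function(d) {
    simulate_event(make_pairing(d, n_reps = 2), effective = eff,
                   device = dev, variant = "minimal14")$dV_w
  }, numeric(1))
  expect_true(all(dv[dts > 0] > 0))
  expect_true(all(dv[dts < 0] < 0))
  # |dV| decreases with |dt| on each side (negative lags are in ascending
  # order, so |dt| shrinks and |dV| grows along that half)
  expect_true(all(diff(dv[dts > 0]) < 0))
  expect_true(all(diff(abs(dv[dts < 0])) > 0))
})

test_that("weight voltage is clamped to the rails and scales with 1/Cw", {
  eff_big <- effective_params(I_A2p = 1e-3, I_A2m = 0, I_A3p = 0,
                              tau_plus = 16.8e-6, tau_minus = 33.7e-6)
  tr <- make_pairing(5e-3, n_reps = 20)
  sim <- simulate_event(tr, effective = eff_big, device = dev,
                        variant = "minimal14", w_init = 3.0)
  expect_true(all(sim$trajectory$V_w <= dev$Vdd & sim$trajectory$V_w >= 0))
  expect_equal(max(sim$trajectory$V_w), dev$Vdd)

  eff <- ref_effective()
  dev2 <- device_params(Cw = 2e-12)
  a <- simulate_event(tr, effective = eff, device = dev,
                      variant = "minimal14")$dV_w
  b <- simulate_event(tr, effective = eff, device = dev2,
                      variant = "minimal14")$dV_w
  expect_equal(b, a / 2, tolerance = 1e-12)
})

test_that("with infinite windows the circuit equals the rule up to scale", {
  p <- triplet_params(A2_plus = 4.6e-3, A2_minus = 3e-3, A3_plus = 9.1e-3,
                      A3_minus = 2e-3, epsilon = 1e-3,
                      tau_plus = 16.8e-3, tau_minus = 33.7e-3,
                      tau_x = 101e-3, tau_y = 48e-3)
  I_per_amp <- 1e-9
  eff <- effective_params(
    I_A2p = I_per_amp * p$A2_plus, I_A2m = I_per_amp * p$A2_minus,
    I_A3p = I_per_amp * p$A3_plus, I_A3m = I_per_amp * p$A3_minus,
    tau_plus = p$tau_plus / dev$time_accel,
    tau_minus = p$tau_minus / dev$time_accel,
    tau_x = p$tau_x / dev$time_accel, tau_y = p$tau_y / dev$time_accel,
    window_plus = Inf, window_minus = Inf, window_x = Inf, window_y = Inf
  )
  scale <- dev$pulse_width_accel * I_per_amp / dev$Cw
  set.seed(11)   # random non-overlapping pair: jittered grid, random labels
  tt <- cumsum(runif(30, 2.5e-3, 30e-3))
  lab <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  protos <- list(make_pairing(10e-3, n_reps = 5),
                 make_triplet(5e-3, 5e-3, "post_pre_post", n_reps = 5),
                 make_quadruplet(20e-3, n_reps = 5),
                 spike_trains(pre = tt[lab], post = tt[!lab]))
  for (tr in protos) {
    dv <- simulate_event(tr, effective = eff, device = dev,
                         variant = "full18")$dV_w
    dw <- total_dw(tstdp_apply(tr, p))
    expect_equal(dv / scale, dw, tolerance = 1e-12)
  }
})

test_that("ramp simulator rests at Vdd and ramps nodes linearly", {
  eff <- ref_effective()
  s0 <- simulate_ramp_ode(spike_trains(), effective = eff, device = dev,
                          variant = "minimal14")
  expect_equal(s0$dV_w, 0)
  expect_equal(ramp_node_voltage(s0, "pot", c(0, 1)), c(dev$Vdd, dev$Vdd))

  # one pre pulse: pot node near ground during the pulse, then a linear rise
  # at UT/(kappa tau) per second (accelerated), clamped at Vdd
  tr <- spike_trains(pre = 0, post = 200e-3)
  s1 <- simulate_ramp_ode(tr, effective = eff, device = dev,
                          variant = "minimal14")
  t_bio <- c(0.25e-3, 2e-3, 4e-3, 6e-3)   # after the 1 ms (bio) pulse
  v <- ramp_node_voltage(s1, "pot", t_bio)
  expect_lt(v[1], 0.05)
  slope <- dev$UT / (dev$kappa * eff$tau_plus)
  expect_equal(diff(v[2:4]), rep(slope * 2e-3 / dev$time_accel, 2),
               tolerance = 1e-9)
  expect_equal(ramp_node_voltage(s1, "pot", 5), dev$Vdd)

  expect_error(simulate_ramp_ode(tr, effective = eff, device = dev,
                                 variant = "minimal14", step = 1e-6),
               "step")
})

test_that("event and ramp simulators agree within 5% across protocols", {
  eff <- ref_effective()
  protos <- c(
    lapply(c(-50e-3, -20e-3, -5e-3, -2e-3, 2e-3, 5e-3, 20e-3, 50e-3),
           function(d) make_pairing(d, n_reps = 2)),
    list(make_triplet(5e-3, 5e-3, "pre_post_pre", n_reps = 2),
         make_triplet(5e-3, 5e-3, "post_pre_post", n_reps = 2),
         make_quadruplet(20e-3, n_reps = 2),
         make_quadruplet(-20e-3, n_reps = 2))
  )
  for (tr in protos) {
    a <- simulate_event(tr, effective = eff, device = dev,
                        variant = "minimal14")$dV_w
    b <- simulate_ramp_ode(tr, effective = eff, device = dev,
                           variant = "minimal14")$dV_w
    expect_lt(abs(b - a), 0.05 * abs(a))
  }
})

test_that("overlapping pulses are rejected by the circuit simulators", {
  tr <- spike_trains(pre = 0, post = 0.5e-3)  # closer than one pulse width
  expect_error(simulate_event(tr, effective = ref_effective(), device = dev,
                              variant = "minimal14"), "overlap")
  expect_error(simulate_ramp_ode(tr, effective = ref_effective(), device = dev,
                                 variant = "minimal14"), "overlap")
})

test_that("mismatch application follows the fixed transistor map", {
  eff <- ref_effective()
  expect_equal(unclass(apply_mismatch(eff, c(M5 = 0, M7 = 0), dev, "minimal14")),
               unclass(eff))

  # +UT/kappa on the pair-potentiation amplitude transistor divides I_A2p by e
  e7 <- apply_mismatch(eff, c(M7 = dev$UT / dev$kappa), dev, "minimal14")
  expect_equal(e7$I_A2p, eff$I_A2p / exp(1), tolerance = 1e-12)
  expect_equal(e7$I_A2m, eff$I_A2m)
  expect_equal(e7$tau_plus, eff$tau_plus)

  # the tau_plus ramp transistor touches tau_plus and window_plus only
  e5 <- apply_mismatch(eff, c(M5 = 0.01), dev, "minimal14")
  f <- exp(dev$kappa * 0.01 / dev$UT)
  expect_equal(e5$tau_plus, eff$tau_plus * f, tolerance = 1e-12)
  expect_equal(e5$window_plus, eff$window_plus * f, tolerance = 1e-12)
  expect_equal(e5$tau_minus, eff$tau_minus)
  expect_equal(e5$I_A2p, eff$I_A2p)

  expect_error(apply_mismatch(eff, c(M99 = 0.01), dev, "minimal14"), "unknown")
  expect_error(apply_mismatch(eff, c(M7 = 0.01), dev, "minimal13"), "M7")
  expect_error(apply_mismatch(eff, setNames(0.01, ""), dev, "minimal14"))

  expect_length(active_transistors("full18"), 18)
  expect_length(active_transistors("minimal14"), 14)
  expect_length(active_transistors("minimal13"), 13)
})
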