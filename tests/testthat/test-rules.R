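test_that("single-pair weight changes match the closed form", {
  p <- triplet_params(A2_plus = 4.6e-3, A2_minus = 3e-3, A3_plus = 9.1e-3)

  # potentiation branch, no earlier post: triplet term absent
  tr <- spike_trains(pre = 0, post = 0.010)
  expect_equal(total_dw(tstdp_apply(tr, p)),
               p$A2_plus * exp(-0.010 / p$tau_plus), tolerance = 1e-14)

  # depression branch
  tr2 <- spike_trains(pre = 0.010, post = 0)
  expect_equal(total_dw(tstdp_apply(tr2, p)),
               -p$A2_minus * exp(-0.010 / p$tau_minus), tolerance = 1e-14)

  # pair-based rule at exactly one time constant
  pp <- pair_params(A_plus = 2e-3, A_minus = 1e-3)
  tr3 <- spike_trains(pre = 0, post = pp$tau_plus)
  expect_equal(total_dw(pstdp_apply(tr3, pp)), pp$A_plus * exp(-1),
               tolerance = 1e-14)

  # empty trains contribute nothing
  expect_equal(total_dw(tstdp_apply(spike_trains(), p)), 0)
  expect_equal(total_dw(pstdp_apply(spike_trains(), pp)), 0)
})

test_that("log totals equal the sum of event contributions", {
  log <- tstdp_apply(make_quadruplet(0.02, n_reps = 5), hippocampal_params())
  expect_equal(total_dw(log), sum(log$contribution))
  expect_true(all(log$train %in% c("pre", "post")))
})

test_that("the factorized and expanded rule arrangements agree", {
  for (s in 1:40) {
    tr <- random_trains(s)
    p <- random_triplet_params(1000 + s)
    a <- total_dw(tstdp_apply(tr, p, form = "factorized"))
    b <- total_dw(tstdp_apply(tr, p, form = "expanded"))
    expect_lt(abs(a - b), 1e-12 * max(abs(a), 1e-12))
  }
})

test_that("trace-reset implementation matches the explicit-search oracle", {
  protos <- list(
    make_pairing(10e-3, n_reps = 10),
    make_pairing(-10e-3, n_reps = 10),
    make_triplet(5e-3, 5e-3, "pre_post_pre", n_reps = 10),
    make_triplet(5e-3, 15e-3, "post_pre_post", n_reps = 10),
    make_extra_triplet(5e-3, 5e-3, "pre_pre_post", n_reps = 10),
    make_quadruplet(20e-3, n_reps = 10),
    make_quadruplet(-20e-3, n_reps = 10)
  )
  p <- random_triplet_params(77)
  for (tr in protos) {
    expect_equal(total_dw(tstdp_apply(tr, p)), oracle_tstdp(tr, p),
                 tolerance = 1e-12)
  }
  for (s in 1:25) {
    tr <- random_trains(200 + s)
    p <- random_triplet_params(300 + s)
    expect_equal(total_dw(tstdp_apply(tr, p)), oracle_tstdp(tr, p),
                 tolerance = 1e-12)
  }
})

test_that("zeroing the triplet amplitudes reduces TSTDP to PSTDP", {
  for (s in 1:10) {
    tr <- random_trains(s)
    tp <- triplet_params(A2_plus = 3e-3, A2_minus = 2e-3,
                         A3_plus = 0, A3_minus = 0,
                         tau_plus = 20e-3, tau_minus = 40e-3)
    pp <- pair_params(A_plus = 3e-3, A_minus = 2e-3,
                      tau_plus = 20e-3, tau_minus = 40e-3)
    expect_equal(total_dw(tstdp_apply(tr, tp)), total_dw(pstdp_apply(tr, pp)),
                 tolerance = 1e-14)
  }
})

test_that("total weight change is translation invariant and linear in amplitudes", {
  p <- random_triplet_params(5)
  tr <- random_trains(6)
  base <- total_dw(tstdp_apply(tr, p))
  for (shift in c(0.5, 3, 100)) {
    expect_equal(total_dw(tstdp_apply(delay_train(tr, shift), p)), base,
                 tolerance = 1e-12)
  }
  for (c_ in c(0.25, 2, 10)) {
    ps <- triplet_params(A2_plus = c_ * p$A2_plus, A2_minus = c_ * p$A2_minus,
                         A3_plus = c_ * p$A3_plus, A3_minus = c_ * p$A3_minus,
                         tau_plus = p$tau_plus, tau_minus = p$tau_minus,
                         tau_x = p$tau_x, tau_y = p$tau_y)
    expect_equal(total_dw(tstdp_apply(tr, ps)), c_ * base, tolerance = 1e-12)
  }
})

test_that("single-pair |dw| decreases strictly with |dt|", {
  p <- hippocampal_params()
  dts <- seq(2e-3, 80e-3, by = 2e-3)
  pot <- vapply(dts, function(d) {
    total_dw(tstdp_apply(spike_trains(pre = 0, post = d), p))
  }, numeric(1))
  dep <- vapply(dts, function(d) {
    total_dw(tstdp_apply(spike_trains(pre = d, post = 0), p))
  }, numeric(1))
  expect_true(all(diff(pot) < 0))
  expect_true(all(diff(abs(dep)) < 0))
})

test_that("well-separated repetitions accumulate additively", {
  p <- hippocampal_params()
  single <- run_protocol(protocol_spec("pairing", dt_ms = 10, n_reps = 1,
                                       rho_Hz = 0.1), p)
  sixty <- run_protocol(protocol_spec("pairing", dt_ms = 10, n_reps = 60,
                                      rho_Hz = 0.1), p)
  expect_equal(sixty, 60 * single, tolerance = 1e-6)
})

test_that("PSTDP cannot separate the two triplet orders but TSTDP can", {
  pp <- pair_params(A_plus = 5e-3, A_minus = 5e-3)
  a <- total_dw(pstdp_apply(make_triplet(5e-3, 5e-3, "pre_post_pre", 1), pp))
  b <- total_dw(pstdp_apply(make_triplet(5e-3, 5e-3, "post_pre_post", 1), pp))
  expect_equal(a, b, tolerance = 1e-12)

  hp <- hippocampal_params()  # A3_plus > 0, A3_minus = 0
  ta <- total_dw(tstdp_apply(make_triplet(5e-3, 5e-3, "pre_post_pre", 60), hp))
  tb <- total_dw(tstdp_apply(make_triplet(5e-3, 5e-3, "post_pre_post", 60), hp))
  expect_gt(tb, ta)
})

test_that("BCM sweeps are zero at zero post rate and reproducible", {
  vc <- visual_cortex_params()
  sw <- bcm_sweep(vc, rho_post_grid = c(0, 20), duration = 5, trials = 2,
                  seed = 9)
  expect_identical(sw$mean_dw[sw$rho_post_Hz == 0], 0)
  expect_identical(sw$sd_dw[sw$rho_post_Hz == 0], 0)
  sw2 <- bcm_sweep(vc, rho_post_grid = c(0, 20), duration = 5, trials = 2,
                   seed = 9)
  expect_identical(sw$mean_dw, sw2$mean_dw)

  pd <- bcm_sweep_pre_driven(vc, rho_grid = c(0, 20), duration = 5,
                             trials = 1, seed = 9)
  pd2 <- bcm_sweep_pre_driven(vc, rho_grid = c(0, 20), duration = 5,
                              trials = 1, seed = 9)
  expect_identical(pd$mean_dw, pd2$mean_dw)
  expect_identical(pd$mean_dw[pd$rho_post_Hz == 0], 0)
})

test_that("variant constraints are enforced on parameters", {
  expect_error(triplet_params(A3_minus = 1e-3,
                              variant = "tstdp_minimal_hippocampal"),
               "A3_minus")
  expect_error(triplet_params(A2_plus = 1e-3, A3_minus = 0,
                              variant = "tstdp_minimal_visual_cortex"),
               "A2_plus")
  expect_error(triplet_params(epsilon = 1), "epsilon")
})
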