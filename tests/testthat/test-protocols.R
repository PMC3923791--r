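test_that("pairing protocol places pairs at the repetition grid", {
  tr <- make_pairing(dt = 10e-3, n_reps = 60, rho = 1)
  expect_equal(train_times(tr, "pre"), as.numeric(0:59))
  expect_equal(train_times(tr, "post"), 0:59 + 0.010)

  # reversed order is shifted so the earliest spike sits at zero
  tr2 <- make_pairing(dt = -10e-3, n_reps = 1, rho = 1)
  expect_equal(train_times(tr2, "pre"), 0.010)
  expect_equal(train_times(tr2, "post"), 0)

  # 50 Hz endpoint of the frequency sweep still fits in the pair period
  tr3 <- make_pairing(dt = 10e-3, n_reps = 60, rho = 50)
  expect_equal(diff(train_times(tr3, "pre"))[1], 0.020)

  expect_error(make_pairing(dt = 0), "non-zero")
  expect_error(make_pairing(dt = 25e-3, rho = 50), "1/rho")
  expect_error(make_pairing(dt = 10e-3, rho = 0), "rho")
})

test_that("pairing with dt and -dt are time reversals within a repetition", {
  for (dtm in c(5e-3, 12e-3, 40e-3)) {
    a <- make_pairing(dt = dtm, n_reps = 1, rho = 1)
    b <- make_pairing(dt = -dtm, n_reps = 1, rho = 1)
    span <- max(a$time_s)
    # reflecting about the span reverses the spike order of each train
    expect_equal(sort(span - train_times(a, "pre")), train_times(b, "pre"))
    expect_equal(sort(span - train_times(a, "post")), train_times(b, "post"))
  }
})

test_that("triplet protocol assigns spikes per combo", {
  tr <- make_triplet(5e-3, 5e-3, "pre_post_pre", n_reps = 1, rho = 1)
  expect_equal(train_times(tr, "pre"), c(0, 0.010))
  expect_equal(train_times(tr, "post"), 0.005)

  tr2 <- make_triplet(5e-3, 5e-3, "post_pre_post", n_reps = 1, rho = 1)
  expect_equal(train_times(tr2, "pre"), 0.005)
  expect_equal(train_times(tr2, "post"), c(0, 0.010))

  tr3 <- make_triplet(15e-3, 5e-3, "pre_post_pre", n_reps = 1, rho = 1)
  expect_equal(train_times(tr3, "pre"), c(0, 0.020))
  expect_equal(train_times(tr3, "post"), 0.015)

  expect_error(make_triplet(-5e-3, 5e-3, "pre_post_pre"), "> 0")
  expect_error(make_triplet(5e-3, 0, "pre_post_pre"), "> 0")
})

test_that("extra-triplet protocol covers all six orders and checks signs", {
  tr <- make_extra_triplet(5e-3, 5e-3, "pre_post_post", n_reps = 1)
  expect_equal(train_times(tr, "pre"), 0)
  expect_equal(train_times(tr, "post"), c(0.005, 0.010))

  tr2 <- make_extra_triplet(5e-3, 5e-3, "post_post_pre", n_reps = 1)
  expect_equal(train_times(tr2, "post"), c(0, 0.005))
  expect_equal(train_times(tr2, "pre"), 0.010)

  # a negative timing on a pre->post adjacent pair contradicts the label
  expect_error(make_extra_triplet(-5e-3, 5e-3, "pre_post_pre"), "contradicts")
  expect_error(make_extra_triplet(5e-3, -5e-3, "post_pre_post"), "contradicts")

  # enumeration over the six-combination grid yields valid trains throughout
  grid <- extra_triplet_grid(dt_values_ms = c(1, 5, 25))
  expect_equal(nrow(grid), 6 * 9)
  for (i in seq_len(nrow(grid))) {
    tr <- make_extra_triplet(grid$dt1_ms[i] / 1000, grid$dt2_ms[i] / 1000,
                             grid$combo[i], n_reps = 2, rho = 0.2)
    expect_s3_class(tr, "spike_trains")
    expect_equal(nrow(tr), 6)
  }
})

test_that("quadruplet protocol uses the inner-spike anchor for T", {
  tr <- make_quadruplet(T_sep = 20e-3, dt = 5e-3, n_reps = 1, rho = 1)
  expect_equal(train_times(tr, "post"), c(0, 0.030))
  expect_equal(train_times(tr, "pre"), c(0.005, 0.025))

  # T < 0 mirrors the order: pre-post pair first, then post-pre
  tr2 <- make_quadruplet(T_sep = -20e-3, dt = 5e-3, n_reps = 1, rho = 1)
  expect_equal(train_times(tr2, "pre"), c(0, 0.030))
  expect_equal(train_times(tr2, "post"), c(0.005, 0.025))

  # total span is 2 dt + |T| for either sign
  for (Ts in c(0.012, -0.047, 0.1)) {
    tr <- make_quadruplet(T_sep = Ts, dt = 5e-3, n_reps = 1, rho = 1)
    expect_equal(max(tr$time_s), 2 * 5e-3 + abs(Ts))
  }

  expect_error(make_quadruplet(T_sep = 0), "non-zero")
  expect_error(make_quadruplet(T_sep = 1.2, rho = 1), "span")
})

test_that("poisson pairs honour rates, seeds and the refractory gap", {
  expect_equal(nrow(dplyr::filter(
    make_poisson_pair(0, 10, duration = 1, seed = 1), train == "pre")), 0)

  tr <- make_poisson_pair(10, 10, duration = 100, seed = 42)
  n_pre <- length(train_times(tr, "pre"))
  expect_lt(abs(n_pre - 1000), 4 * sqrt(1000))
  expect_true(all(diff(train_times(tr, "pre")) >= 1e-3))

  tr2 <- make_poisson_pair(10, 10, duration = 100, seed = 42)
  expect_identical(tr$time_s, tr2$time_s)

  # empirical rate converges to nominal (10% tolerance at rate*duration 1e4)
  tr3 <- make_poisson_pair(100, 0, duration = 100, seed = 7)
  rate <- length(train_times(tr3, "pre")) / 100
  expect_lt(abs(rate - 100) / 100, 0.10)
})

test_that("delay_train shifts times and composes additively", {
  tr <- make_pairing(dt = 10e-3, n_reps = 3, rho = 1)
  expect_equal(delay_train(tr, 0)$time_s, tr$time_s)
  expect_equal(delay_train(tr, 1e-3)$time_s, tr$time_s + 1e-3)
  expect_equal(delay_train(delay_train(tr, 2e-3), 2e-3)$time_s,
               delay_train(tr, 4e-3)$time_s)
  expect_error(delay_train(tr, -1))
})

test_that("every generator satisfies the spike-train invariants", {
  set.seed(1)
  specs <- list()
  for (i in 1:20) {
    rho <- runif(1, 0.1, 5)
    specs <- c(specs, list(
      make_pairing(dt = runif(1, 1e-3, 0.9 / rho) * sample(c(-1, 1), 1),
                   n_reps = sample(1:60, 1), rho = rho),
      make_triplet(runif(1, 1e-3, 0.05), runif(1, 1e-3, 0.05),
                   sample(c("pre_post_pre", "post_pre_post"), 1),
                   n_reps = sample(1:60, 1), rho = rho),
      make_quadruplet(T_sep = runif(1, 0.011, 0.08) * sample(c(-1, 1), 1),
                      n_reps = sample(1:30, 1), rho = rho)
    ))
  }
  for (tr in specs) {
    for (side in c("pre", "post")) {
      tt <- train_times(tr, side)
      expect_true(all(tt >= 0))
      if (length(tt) > 1) expect_true(all(diff(tt) >= pulse_width(tr)))
    }
  }
})

test_that("spike trains round-trip through the two-column CSV format", {
  tr <- make_triplet(5e-3, 7e-3, "post_pre_post", n_reps = 2)
  path <- tempfile(fileext = ".csv")
  write_spike_trains(tr, path)
  back <- read_spike_trains(path)
  expect_equal(train_times(back, "pre"), train_times(tr, "pre"))
  expect_equal(train_times(back, "post"), train_times(tr, "post"))
})

test_that("protocol_spec rows rebuild their trains", {
  spec <- protocol_spec("triplet", dt1_ms = 5, dt2_ms = 5,
                        combo = "pre_post_pre", n_reps = 2)
  tr <- protocol_trains(spec)
  expect_equal(train_times(tr, "post"), c(0.005, 1.005))
  expect_error(protocol_spec("pairing", dt_ms = 10, n_reps = 0), "n_reps")
})
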