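# Independent brute-force oracle for the nearest-spike TSTDP rule: for every
# triggering spike it explicitly searches the full opposite train for the
# nearest predecessor (and the full same train for the previous spike),
# instead of carrying trace state.
oracle_tstdp <- function(trains, p) {
  pre <- train_times(trains, "pre")
  post <- train_times(trains, "post")
  dw <- 0
  for (t in post) {
    prior_pre <- pre[pre <= t]           # pre-first tie-break at equal times
    if (!length(prior_pre)) next
    d1 <- t - max(prior_pre)
    prior_post <- post[post < t]
    trip <- if (length(prior_post)) {
      exp(-(t - max(prior_post) - p$epsilon) / p$tau_y)
    } else 0
    dw <- dw + exp(-d1 / p$tau_plus) * (p$A2_plus + p$A3_plus * trip)
  }
  for (t in pre) {
    prior_post <- post[post < t]         # a post at the same instant is later
    if (!length(prior_post)) next
    d1 <- t - max(prior_post)
    prior_pre <- pre[pre < t]
    trip <- if (length(prior_pre)) {
      exp(-(t - max(prior_pre) - p$epsilon) / p$tau_x)
    } else 0
    dw <- dw - exp(-d1 / p$tau_minus) * (p$A2_minus + p$A3_minus * trip)
  }
  dw
}

# random non-overlapping spike-train pair with a fixed seed
random_trains <- function(seed, n_pre = 15, n_post = 15, span = 0.5,
                          pulse_width = 1e-3) {
  set.seed(seed)
  thin <- function(tt) {
    tt <- sort(tt)
    keep <- numeric(0)
    for (t in tt) {
      if (!length(keep) || t - keep[length(keep)] >= pulse_width) {
        keep <- c(keep, t)
      }
    }
    keep
  }
  spike_trains(pre = thin(runif(n_pre, 0, span)),
               post = thin(runif(n_post, 0, span)),
               pulse_width = pulse_width)
}

random_triplet_params <- function(seed) {
  set.seed(seed)
  triplet_params(
    A2_plus = runif(1, 0, 0.02), A2_minus = runif(1, 0, 0.02),
    A3_plus = runif(1, 0, 0.05), A3_minus = runif(1, 0, 0.05),
    tau_plus = runif(1, 5e-3, 50e-3), tau_minus = runif(1, 5e-3, 50e-3),
    tau_x = runif(1, 20e-3, 200e-3), tau_y = runif(1, 20e-3, 200e-3),
    variant = "tstdp_full"
  )
}
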