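# ggplot2 displays for the package's result types.

#' Plot an STDP learning window
#'
#' @param object A [stdp_window()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stdp_window <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dt_ms, y = .data$dw)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(Delta * t ~ "(ms)"),
                  y = expression(Delta * w),
                  title = "STDP learning window (pairing protocol)")
}

#' Plot a BCM-like rate sweep
#'
#' Mean weight change versus post-synaptic Poisson rate with +-1 SD bars;
#' the zero crossing is the BCM-like modification threshold.
#'
#' @param object A [bcm_sweep()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bcm_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho_post_Hz, y = .data$mean_dw)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_dw - .data$sd_dw,
                                          ymax = .data$mean_dw + .data$sd_dw)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(rho[post] ~ "(Hz)"),
                  y = expression(bar(Delta * w)),
                  title = "BCM-like rate dependence (Poissonian protocol)")
}

#' Plot a circuit weight-voltage trajectory
#'
#' @param object A [simulate_event()] or [simulate_ramp_ode()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.circuit_sim <- function(object, ...) {
  traj <- dplyr::bind_rows(
    tibble::tibble(time_s = 0, V_w = object$w_init),
    object$trajectory
  )
  ggplot2::ggplot(traj, ggplot2::aes(x = .data$time_s, y = .data$V_w)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time (s, biological)", y = expression(V[w] ~ "(V)"),
                  title = "Synaptic weight voltage")
}

#' @rdname autoplot.circuit_sim
#' @export
autoplot.circuit_ramp_sim <- autoplot.circuit_sim

#' Plot the Monte-Carlo mismatch NMSE distribution
#'
#' @param object An [run_mc()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_result <- function(object, bins = 40, ...) {
  ggplot2::ggplot(object$runs, ggplot2::aes(x = .data$nmse)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$baseline_nmse, colour = "red",
                        linetype = 2) +
    ggplot2::labs(x = "NMSE", y = "runs",
                  title = sprintf("Mismatch Monte Carlo (%d runs, sigma = %g V)",
                                  object$config$n_runs, object$config$sigma_vth))
}
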