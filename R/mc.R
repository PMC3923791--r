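#' Monte-Carlo transistor-mismatch configuration
#'
#' Configuration of the mismatch study: `n_runs` independent draws of
#' per-transistor threshold deviations `Normal(0, sigma_vth)` (default
#' 10 mV, so the three-sigma point is 30 mV), applied to the circuit with
#' FIXED bias voltages, evaluated on every protocol of a dataset, and scored
#' by NMSE against the dataset's measurements.
#'
#' @param dataset An [stdp_dataset()] tibble.
#' @param biases A [circuit_biases()] object (fixed across runs).
#' @param variant Circuit variant.
#' @param n_runs Number of Monte-Carlo runs (default 1000).
#' @param sigma_vth Per-transistor threshold standard deviation (V).
#' @param seed Integer seed.
#' @param device A [device_params()] object.
#' @param scale Volt-to-fraction scale; default: profiled once at the
#'   unperturbed baseline and then held fixed for all runs.
#' @param pulse_width Biological pulse width (s).
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(dataset, biases, variant = "minimal13", n_runs = 1000,
                      sigma_vth = 0.010, seed = 1, device = device_params(),
                      scale = NULL, pulse_width = 1e-3) {
  stopifnot(inherits(dataset, "stdp_dataset"), n_runs >= 1, sigma_vth >= 0)
  structure(
    list(dataset = dataset, biases = biases, variant = variant,
         n_runs = as.integer(n_runs), sigma_vth = sigma_vth,
         seed = as.integer(seed), device = device, scale = scale,
         pulse_width = pulse_width),
    class = "mc_config"
  )
}

#' Run the Monte-Carlo mismatch study
#'
#' For each run, draws i.i.d. threshold deviations for every transistor
#' active in the variant, perturbs the effective parameters with
#' [apply_mismatch()], re-simulates every dataset protocol with the fixed
#' biases, and records the NMSE. Fully reproducible under the config seed.
#'
#' @param config An [mc_config()] object.
#' @return An object of class `mc_result`: tibble `runs` (`run`, `nmse`),
#'   `baseline_nmse`, the config, and a [summarize_mc()] summary.
#' @examples
#' ds <- make_synthetic_dataset(visual_cortex_params(),
#'                              protocol_grid = freq_pairing_grid(),
#'                              noise_scale = 1, seed = 1)
#' b <- biases_for_effective(visual_cortex_params())
#' res <- run_mc(mc_config(ds, b, "minimal13", n_runs = 20, seed = 1))
#' res$baseline_nmse
#' @export
run_mc <- function(config) {
  stopifnot(inherits(config, "mc_config"))
  cfg <- config
  d <- cfg$device
  eff0 <- biases_to_effective(cfg$biases, d, cfg$variant)
  evtabs <- lapply(seq_len(nrow(cfg$dataset)), function(i) {
    circuit_event_table(protocol_trains(cfg$dataset[i, ], cfg$pulse_width), d)
  })
  dv_for <- function(eff) {
    vapply(evtabs, function(ev) sum(circuit_event_dv(ev, eff, d)), numeric(1))
  }
  dv0 <- dv_for(eff0)
  scale <- cfg$scale %||% profile_scale(dv0, cfg$dataset$dw_exp, cfg$dataset$sem)
  baseline <- nmse(dv0 * scale, cfg$dataset)
  nmse_values <- vapply(seq_len(cfg$n_runs), function(r) {
    sample <- with_seed(derive_seed(cfg$seed, 101L, r),
                        draw_mismatch(cfg$sigma_vth, cfg$variant))
    eff_r <- apply_mismatch(eff0, sample, d, cfg$variant)
    nmse(dv_for(eff_r) * scale, cfg$dataset)
  }, numeric(1))
  out <- list(
    runs = tibble::tibble(run = seq_len(cfg$n_runs), nmse = nmse_values),
    baseline_nmse = baseline, scale = scale, config = cfg
  )
  class(out) <- "mc_result"
  out$summary <- summarize_mc(out)
  out
}

#' Summarize a Monte-Carlo mismatch result
#'
#' Deterministic summary of the NMSE distribution: quantiles, mean, and the
#' fraction of runs whose NMSE stays within `closeness_factor` times the
#' unperturbed baseline.
#'
#' @param result An [run_mc()] result.
#' @param closeness_factor Multiple of the baseline counted as "close".
#' @return A one-row tibble.
#' @export
summarize_mc <- function(result, closeness_factor = 2) {
  stopifnot(inherits(result, "mc_result"), closeness_factor > 0)
  v <- result$runs$nmse
  q <- quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  tibble::tibble(
    n_runs = length(v), baseline_nmse = result$baseline_nmse,
    min = q[1], q25 = q[2], median = q[3], q75 = q[4], max = q[5],
    mean = mean(v), iqr = q[4] - q[2],
    closeness_factor = closeness_factor,
    frac_within = mean(v <= closeness_factor * result$baseline_nmse)
  )
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %d runs, sigma_vth = %g V, variant %s\n",
              x$config$n_runs, x$config$sigma_vth, x$config$variant))
  cat(sprintf("  baseline NMSE = %.4g; median = %.4g; frac within %gx = %.2f\n",
              x$baseline_nmse, x$summary$median, x$summary$closeness_factor,
              x$summary$frac_within))
  invisible(x)
}
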