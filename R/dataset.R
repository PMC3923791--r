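#' Weight-change datasets
#'
#' A dataset is a tibble of stimulation-protocol rows (the [protocol_spec()]
#' columns) with two measurement columns attached: `dw_exp`, the measured
#' mean fractional weight change, and `sem`, its standard error of the mean
#' (`> 0`). The classical hippocampal set has 13 points (2 pairing +
#' 3 quadruplet + 8 triplet) and the visual-cortex set 10 points (two lags
#' across five pairing frequencies); neither table is shipped here — they can
#' be transcribed from the literature into the CSV format below, or emulated
#' with [make_synthetic_dataset()].
#'
#' The CSV format has columns `protocol, dt_ms, dt1_ms, dt2_ms, T_ms,
#' rho_Hz, combo, n_reps, dw_exp, sem`.
#'
#' @param points A tibble with protocol columns plus `dw_exp` and `sem`.
#' @param name Dataset label.
#' @return A tibble of class `stdp_dataset`.
#' @export
stdp_dataset <- function(points, name = "dataset") {
  stopifnot(is.data.frame(points), nrow(points) >= 1)
  req <- c("protocol", "dw_exp", "sem")
  missing_cols <- setdiff(req, names(points))
  if (length(missing_cols)) {
    abort(paste0("dataset lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(points$sem)) || any(points$sem <= 0)) {
    abort("all `sem` values must be finite and > 0")
  }
  out <- tibble::as_tibble(points)
  attr(out, "name") <- name
  class(out) <- unique(c("stdp_dataset", class(out)))
  out
}

#' @rdname stdp_dataset
#' @param path CSV file path.
#' @export
read_dataset <- function(path, name = basename(path)) {
  stdp_dataset(tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE)),
               name = name)
}

#' @rdname stdp_dataset
#' @param dataset A `stdp_dataset` tibble.
#' @export
write_dataset <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Default protocol grids
#'
#' `hippocampal_grid()` mirrors the 13-point hippocampal composition: pairing
#' at `dt = +-10` ms, quadruplets at `T = -100, -30, +30` ms and triplets at
#' `(dt1, dt2)` in `{(5,5), (10,10), (5,15), (15,5)}` ms for both the
#' pre-post-pre and post-pre-post orders, all 60 repetitions at 1 Hz.
#' `freq_pairing_grid()` mirrors the 10-point visual-cortex composition:
#' pairing at `dt = +-10` ms across five repetition frequencies.
#'
#' @return A tibble of protocol rows (no measurement columns).
#' @export
hippocampal_grid <- function() {
  dplyr::bind_rows(
    protocol_spec("pairing", dt_ms = 10),
    protocol_spec("pairing", dt_ms = -10),
    purrr::map_dfr(c(-100, -30, 30),
                   function(Tm) protocol_spec("quadruplet", T_ms = Tm, dt_ms = 5)),
    purrr::map_dfr(c("pre_post_pre", "post_pre_post"), function(cb) {
      purrr::map_dfr(list(c(5, 5), c(10, 10), c(5, 15), c(15, 5)), function(g) {
        protocol_spec("triplet", dt1_ms = g[1], dt2_ms = g[2], combo = cb)
      })
    })
  )
}

#' @rdname hippocampal_grid
#' @param freqs_Hz Pairing repetition frequencies (Hz).
#' @export
freq_pairing_grid <- function(freqs_Hz = c(0.1, 10, 20, 40, 50)) {
  purrr::map_dfr(c(10, -10), function(dtm) {
    purrr::map_dfr(freqs_Hz, function(f) {
      protocol_spec("pairing", dt_ms = dtm, n_reps = 60, rho_Hz = f)
    })
  })
}

#' Predict weight changes for every dataset row
#'
#' Runs each protocol row through the mathematical rule (`engine = "rule"`)
#' or the circuit event simulator (`engine = "circuit"`). For the circuit
#' engine the weight-capacitor voltage changes (V) are multiplied by `scale`
#' to land on the dimensionless fractional weight-change axis of the data;
#' if `scale = NULL` the weighted-least-squares optimal scale for the
#' dataset is used (and returned as the `scale` attribute).
#'
#' @param dataset A tibble of protocol rows ([stdp_dataset()] or a grid).
#' @param params A [triplet_params()] / [pair_params()] object (rule engine).
#' @param engine `"rule"` or `"circuit"`.
#' @param biases,device,variant Circuit configuration (circuit engine).
#' @param effective Optional [effective_params()] overriding `biases`.
#' @param scale Volt-to-fraction conversion for the circuit engine.
#' @param pulse_width Biological pulse width (s).
#' @return Numeric vector of predicted weight changes, one per row.
#' @export
predict_dataset <- function(dataset, params = NULL,
                            engine = c("rule", "circuit"),
                            biases = NULL, device = device_params(),
                            variant = "minimal14", effective = NULL,
                            scale = NULL, pulse_width = 1e-3) {
  engine <- match.arg(engine)
  if (engine == "rule") {
    if (is.null(params)) abort("`params` is required for the rule engine")
    vapply(seq_len(nrow(dataset)), function(i) {
      run_protocol(dataset[i, ], params, pulse_width = pulse_width)
    }, numeric(1))
  } else {
    eff <- effective %||% {
      if (is.null(biases)) abort("`biases` (or `effective`) is required for the circuit engine")
      biases_to_effective(biases, device, variant)
    }
    dv <- vapply(seq_len(nrow(dataset)), function(i) {
      tr <- protocol_trains(dataset[i, ], pulse_width = pulse_width)
      simulate_event(tr, device = device, variant = variant,
                     effective = eff)$dV_w
    }, numeric(1))
    if (is.null(scale)) {
      if (!all(c("dw_exp", "sem") %in% names(dataset))) {
        abort("`scale` must be given when the dataset has no measurements")
      }
      scale <- profile_scale(dv, dataset$dw_exp, dataset$sem)
    }
    out <- dv * scale
    attr(out, "scale") <- scale
    out
  }
}

# weighted-least-squares optimal volt -> fraction scale
profile_scale <- function(dv, dw_exp, sem) {
  den <- sum((dv / sem)^2)
  if (den == 0) return(0)
  sum(dw_exp * dv / sem^2) / den
}

#' Generate a synthetic weight-change dataset
#'
#' Computes the true weight change of every protocol in `protocol_grid` from
#' `true_params`, assigns each point a standard error (`sem_frac` of the
#' absolute weight change, floored at `sem_floor`), and perturbs the means
#' with Gaussian noise of standard deviation `noise_scale * sem`. With
#' `noise_scale = 1` the expected NMSE of the generating parameters is 1
#' (a reduced chi-square at truth); with `noise_scale = 0` it is exactly 0.
#'
#' @param true_params A [triplet_params()] or [pair_params()] object.
#' @param protocol_grid Tibble of protocol rows; default [hippocampal_grid()]
#'   (the 2 pairing + 3 quadruplet + 8 triplet composition).
#' @param noise_scale Noise standard deviation in units of `sem` (`>= 0`).
#' @param seed Integer seed.
#' @param sem_frac,sem_floor Standard-error model (fraction of `|dw|`, floor).
#' @param pulse_width Biological pulse width (s).
#' @return An [stdp_dataset()] tibble with attribute `true_dw`.
#' @examples
#' make_synthetic_dataset(hippocampal_params(), noise_scale = 1, seed = 1)
#' @export
make_synthetic_dataset <- function(true_params,
                                   protocol_grid = hippocampal_grid(),
                                   noise_scale = 1, seed = 1,
                                   sem_frac = 0.1, sem_floor = 0.01,
                                   pulse_width = 1e-3) {
  stopifnot(noise_scale >= 0, sem_frac >= 0, sem_floor > 0)
  dw_true <- predict_dataset(protocol_grid, true_params, engine = "rule",
                             pulse_width = pulse_width)
  sem <- pmax(sem_frac * abs(dw_true), sem_floor)
  noise <- with_seed(derive_seed(seed, 11L),
                     rnorm(length(dw_true), 0, noise_scale * sem))
  out <- dplyr::mutate(protocol_grid, dw_exp = dw_true + noise, sem = sem)
  out <- stdp_dataset(out, name = "synthetic")
  attr(out, "true_dw") <- dw_true
  out
}
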