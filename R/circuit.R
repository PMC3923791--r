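#' Subthreshold device parameters
#'
#' Behavioral device constants for the synapse circuit. Transistors are
#' modelled only through the saturation-region subthreshold exponential
#' `I = I0 * exp(kappa * Vg / UT)`; the defaults are representative
#' subthreshold values and every one is configurable. The circuit runs on an
#' accelerated timescale (default 1000x): spike pulses are
#' `pulse_width_accel` wide (1 us, modelling 1 ms biological pulses) and all
#' biological spike times are divided by `time_accel` before simulation.
#'
#' @param I0 Subthreshold pre-exponential current (A).
#' @param kappa Subthreshold slope factor (dimensionless).
#' @param UT Thermal voltage (V).
#' @param Vdd Supply voltage (V).
#' @param Cw Weight capacitor (F).
#' @param Cp_pot,Cp_dep,Cp_y,Cp_x Gate/parasitic node capacitances (F) of the
#'   potentiation, depression, triplet-potentiation and triplet-depression
#'   ramp nodes.
#' @param pulse_width_accel Spike pulse width at the circuit timescale (s).
#' @param time_accel Acceleration factor (`>= 1`).
#' @return An object of class `device_params`.
#' @export
device_params <- function(I0 = 1e-15, kappa = 0.7, UT = 0.02585, Vdd = 3.3,
                          Cw = 1e-12, Cp_pot = 5e-15, Cp_dep = 5e-15,
                          Cp_y = 5e-15, Cp_x = 5e-15,
                          pulse_width_accel = 1e-6, time_accel = 1000) {
  vals <- c(I0, kappa, UT, Vdd, Cw, Cp_pot, Cp_dep, Cp_y, Cp_x,
            pulse_width_accel, time_accel)
  if (any(vals <= 0)) abort("all device parameters must be strictly positive")
  if (time_accel < 1) abort("`time_accel` must be >= 1")
  structure(
    list(I0 = I0, kappa = kappa, UT = UT, Vdd = Vdd, Cw = Cw,
         Cp_pot = Cp_pot, Cp_dep = Cp_dep, Cp_y = Cp_y, Cp_x = Cp_x,
         pulse_width_accel = pulse_width_accel, time_accel = time_accel),
    class = "device_params"
  )
}

circuit_variants <- c("full18", "minimal14", "minimal13")

#' Circuit bias voltages
#'
#' Gate bias voltages of the synapse circuit, all in `[0, Vdd]`. `V_A2p`,
#' `V_A2m`, `V_A3p`, `V_A3m` set the amplitude currents of the pair
#' potentiation, pair depression, triplet potentiation and triplet depression
#' branches; `V_tp`, `V_td`, `V_ty`, `V_tx` set the ramp rates that realize
#' the time constants `tau_plus`, `tau_minus`, `tau_y`, `tau_x`. The minimal
#' 14-transistor circuit drops the triplet-depression branch (`V_tx`,
#' `V_A3m` ignored); the 13-transistor circuit additionally removes the pair
#' potentiation branch (`V_A2p` ignored).
#'
#' @param V_A2p,V_A2m,V_A3p,V_A3m Amplitude-branch gate biases (V).
#' @param V_tp,V_td,V_ty,V_tx Ramp-control gate biases (V).
#' @return An object of class `circuit_biases`.
#' @seealso [biases_to_effective()], [biases_for_effective()], [table1_biases()]
#' @export
circuit_biases <- function(V_A2p = 0.5, V_A2m = 0.5, V_A3p = 0.5,
                           V_A3m = 0, V_tp = 2.95, V_td = 2.95,
                           V_ty = 2.95, V_tx = 2.95) {
  structure(
    list(V_A2p = V_A2p, V_A2m = V_A2m, V_A3p = V_A3p, V_A3m = V_A3m,
         V_tp = V_tp, V_td = V_td, V_ty = V_ty, V_tx = V_tx),
    class = "circuit_biases"
  )
}

#' Example optimised bias sextets
#'
#' The six printed bias voltages for each of the two data sets, as optimised
#' for the minimal circuits. The column-to-bias mapping of the printed table
#' is not fully recoverable (the published column headers are figure
#' placeholders), so these are example configurations with uncertain labels;
#' the assignment used here puts them in the order `V_A2p`, `V_A2m`,
#' `V_A3p`, `V_tp`, `V_td`, `V_ty` (the visual-cortex first entry of 0 V is
#' at least consistent with the pair-potentiation branch being off in the
#' 13-transistor circuit).
#'
#' @param dataset `"hippocampal"` or `"visual_cortex"`.
#' @return A [circuit_biases()] object.
#' @export
table1_biases <- function(dataset = c("hippocampal", "visual_cortex")) {
  dataset <- match.arg(dataset)
  v <- switch(dataset,
              hippocampal = c(3.2, 0.32, 2.7, 2.75, 0.35, 2.65),
              visual_cortex = c(0, 0.29, 2.7, 2.7, 0.17, 2.86))
  circuit_biases(V_A2p = v[1], V_A2m = v[2], V_A3p = v[3],
                 V_tp = v[4], V_td = v[5], V_ty = v[6])
}

#' Effective circuit parameters
#'
#' The realized amplitude currents, time constants and ramp windows of the
#' circuit, on the accelerated (circuit) timescale. A branch contributes
#' nothing once its ramp node has reached the supply, which happens after
#' `window = tau * kappa * Vdd / UT` (the current is then below
#' `I0 * exp(-kappa * Vdd / UT)` and treated as zero).
#'
#' @param I_A2p,I_A2m,I_A3p,I_A3m Amplitude currents (A, `>= 0`).
#' @param tau_plus,tau_minus,tau_x,tau_y Realized time constants (s, circuit
#'   timescale, `> 0`).
#' @param window_plus,window_minus,window_x,window_y Ramp saturation times
#'   (s); default `tau * kappa * Vdd / UT`.
#' @param kappa,Vdd,UT Device constants used for the default windows.
#' @return An object of class `effective_params`.
#' @export
effective_params <- function(I_A2p, I_A2m, I_A3p, I_A3m = 0,
                             tau_plus, tau_minus, tau_x = tau_plus,
                             tau_y = tau_plus,
                             window_plus = NULL, window_minus = NULL,
                             window_x = NULL, window_y = NULL,
                             kappa = 0.7, Vdd = 3.3, UT = 0.02585) {
  stopifnot(I_A2p >= 0, I_A2m >= 0, I_A3p >= 0, I_A3m >= 0,
            tau_plus > 0, tau_minus > 0, tau_x > 0, tau_y > 0)
  wfac <- kappa * Vdd / UT
  w <- function(given, tau) if (is.null(given)) tau * wfac else given
  out <- list(
    I_A2p = I_A2p, I_A2m = I_A2m, I_A3p = I_A3p, I_A3m = I_A3m,
    tau_plus = tau_plus, tau_minus = tau_minus, tau_x = tau_x, tau_y = tau_y,
    window_plus = w(window_plus, tau_plus),
    window_minus = w(window_minus, tau_minus),
    window_x = w(window_x, tau_x), window_y = w(window_y, tau_y)
  )
  if (with(out, window_plus < tau_plus || window_minus < tau_minus ||
                window_x < tau_x || window_y < tau_y)) {
    abort("windows must be >= the corresponding time constants")
  }
  structure(out, class = "effective_params")
}

#' Map bias voltages to effective circuit parameters
#'
#' Amplitude currents follow the subthreshold law
#' `I_X = I0 * exp(kappa * V_X / UT)`; ramp-control transistors source
#' `I_ramp = I0 * exp(kappa * (Vdd - V_t) / UT)` onto their node capacitor,
#' giving `tau = C_node * UT / (kappa * I_ramp)` and a saturation window
#' `C_node * Vdd / I_ramp`. Variant constraints are applied here: the
#' 14-transistor circuit has no triplet-depression branch (`I_A3m = 0`), the
#' 13-transistor circuit additionally has `I_A2p = 0`.
#'
#' @param biases A [circuit_biases()] object.
#' @param device A [device_params()] object.
#' @param variant `"full18"`, `"minimal14"` or `"minimal13"`.
#' @return An [effective_params()] object.
#' @examples
#' biases_to_effective(circuit_biases(), device_params(), "minimal14")
#' @export
biases_to_effective <- function(biases, device = device_params(),
                                variant = circuit_variants) {
  variant <- match.arg(variant)
  stopifnot(inherits(biases, "circuit_biases"), inherits(device, "device_params"))
  d <- device
  vb <- unlist(biases[c("V_A2p", "V_A2m", "V_A3p", "V_A3m",
                        "V_tp", "V_td", "V_ty", "V_tx")])
  if (any(vb < 0 | vb > d$Vdd)) abort("bias voltages must lie in [0, Vdd]")
  amp <- function(v) d$I0 * exp(d$kappa * v / d$UT)
  ramp <- function(v) d$I0 * exp(d$kappa * (d$Vdd - v) / d$UT)
  tau <- function(C, Ir) C * d$UT / (d$kappa * Ir)
  I_tp <- ramp(biases$V_tp); I_td <- ramp(biases$V_td)
  I_ty <- ramp(biases$V_ty); I_tx <- ramp(biases$V_tx)
  effective_params(
    I_A2p = if (variant == "minimal13") 0 else amp(biases$V_A2p),
    I_A2m = amp(biases$V_A2m),
    I_A3p = amp(biases$V_A3p),
    I_A3m = if (variant == "full18") amp(biases$V_A3m) else 0,
    tau_plus = tau(d$Cp_pot, I_tp), tau_minus = tau(d$Cp_dep, I_td),
    tau_y = tau(d$Cp_y, I_ty), tau_x = tau(d$Cp_x, I_tx),
    kappa = d$kappa, Vdd = d$Vdd, UT = d$UT
  )
}

#' Derive bias voltages that realize given rule parameters
#'
#' Inverts the bias-to-effective mapping: time constants (biological seconds)
#' are divided by the acceleration factor and converted to ramp biases;
#' dimensionless rule amplitudes are converted to amplitude currents via
#' `I_X = amp_current_scale * A_X`. The implied conversion from weight-
#' capacitor voltage change to dimensionless weight change is returned as the
#' `dw_per_volt` attribute (`Cw / (pulse_width_accel * amp_current_scale)`).
#'
#' @param params A [triplet_params()] object (biological timescale).
#' @param device A [device_params()] object.
#' @param variant Circuit variant; defaults to the variant matching the rule.
#' @param amp_current_scale Amperes of amplitude current per unit of
#'   dimensionless rule amplitude (default `2e-7`, placing typical amplitudes
#'   in the nanoampere subthreshold range).
#' @return A [circuit_biases()] object with attribute `dw_per_volt`.
#' @examples
#' biases_for_effective(hippocampal_params())
#' @export
biases_for_effective <- function(params, device = device_params(),
                                 variant = NULL, amp_current_scale = 2e-7) {
  stopifnot(inherits(params, "triplet_params"))
  d <- device
  variant <- variant %||% switch(params$variant,
    tstdp_full = "full18",
    tstdp_minimal_hippocampal = "minimal14",
    tstdp_minimal_visual_cortex = "minimal13",
    "full18")
  v_amp <- function(A) {
    if (A <= 0) return(0)
    v <- d$UT / d$kappa * log(amp_current_scale * A / d$I0)
    if (v < 0 || v > d$Vdd) abort("amplitude bias outside supply rails")
    v
  }
  v_ramp <- function(C, tau_bio) {
    tau_c <- tau_bio / d$time_accel
    Ir <- C * d$UT / (d$kappa * tau_c)
    v <- d$Vdd - d$UT / d$kappa * log(Ir / d$I0)
    if (v < 0 || v > d$Vdd) abort("ramp bias outside supply rails")
    v
  }
  b <- circuit_biases(
    V_A2p = v_amp(params$A2_plus), V_A2m = v_amp(params$A2_minus),
    V_A3p = v_amp(params$A3_plus), V_A3m = v_amp(params$A3_minus),
    V_tp = v_ramp(d$Cp_pot, params$tau_plus),
    V_td = v_ramp(d$Cp_dep, params$tau_minus),
    V_ty = v_ramp(d$Cp_y, params$tau_y),
    V_tx = v_ramp(d$Cp_x, params$tau_x)
  )
  attr(b, "dw_per_volt") <- d$Cw / (d$pulse_width_accel * amp_current_scale)
  attr(b, "variant") <- variant
  b
}

# ---- transistor mismatch ------------------------------------------------

# Fixed label -> effect mapping of the behavioral model. Amplitude and
# series transistors scale the current they carry by exp(-kappa dVth / UT);
# ramp-control transistors scale their ramp current the same way, so tau and
# window scale by exp(+kappa dVth / UT). Pure pulse switches are inert here.
transistor_effects <- list(
  M1 = character(), M4 = character(), M6 = character(), M9 = character(),
  M10 = character(), M13 = character(), M18 = character(),
  M2 = c(tau = "tau_x"),
  M3 = c(amp = "I_A3m"),
  M5 = c(tau = "tau_plus"),
  M7 = c(amp = "I_A2p"),
  M8 = c(amp = "I_A2p", amp = "I_A3p"),
  M11 = c(amp = "I_A2m", amp = "I_A3m"),
  M12 = c(amp = "I_A2m"),
  M14 = c(tau = "tau_minus"),
  M15 = c(amp = "I_A3p"),
  M16 = c(amp = "I_A3p"),
  M17 = c(tau = "tau_y")
)

#' Transistors present in a circuit variant
#' @param variant `"full18"`, `"minimal14"` or `"minimal13"`.
#' @return Character vector of transistor labels.
#' @export
active_transistors <- function(variant = circuit_variants) {
  variant <- match.arg(variant)
  all18 <- paste0("M", 1:18)
  switch(variant,
         full18 = all18,
         minimal14 = setdiff(all18, paste0("M", 1:4)),
         minimal13 = setdiff(all18, c(paste0("M", 1:4), "M7")))
}

#' Apply a transistor-mismatch sample to effective parameters
#'
#' Each transistor's threshold-voltage deviation multiplies the current it
#' carries by `exp(-kappa * dVth / UT)`. Amplitude-branch deviations rescale
#' the corresponding amplitude current; ramp-control deviations rescale the
#' ramp current and hence the realized `tau` and `window` (both multiplied by
#' `exp(+kappa * dVth / UT)`); pulse-switch transistors have no effect in the
#' behavioral model. The label-to-parameter mapping is fixed (see
#' [active_transistors()] and the package vignette).
#'
#' @param effective An [effective_params()] object.
#' @param sample Named numeric vector of threshold deviations in volts,
#'   names among the active transistor labels (e.g. `c(M7 = 0.01)`).
#' @param device A [device_params()] object.
#' @param variant Circuit variant.
#' @return A perturbed [effective_params()] object.
#' @examples
#' eff <- biases_to_effective(circuit_biases(), variant = "minimal14")
#' apply_mismatch(eff, c(M7 = 0.01), device_params(), "minimal14")
#' @export
apply_mismatch <- function(effective, sample, device = device_params(),
                           variant = circuit_variants) {
  variant <- match.arg(variant)
  stopifnot(inherits(effective, "effective_params"))
  labs <- names(sample)
  if (is.null(labs) || any(!nzchar(labs))) abort("`sample` must be named")
  bad <- setdiff(labs, active_transistors(variant))
  if (length(bad)) {
    abort(paste0("unknown or inactive transistor label(s): ",
                 paste(bad, collapse = ", ")))
  }
  out <- unclass(effective)
  for (lab in labs) {
    eff <- transistor_effects[[lab]]
    if (!length(eff)) next
    f_amp <- exp(-device$kappa * sample[[lab]] / device$UT)
    f_tau <- 1 / f_amp
    for (j in seq_along(eff)) {
      field <- eff[[j]]
      if (names(eff)[j] == "amp") {
        out[[field]] <- out[[field]] * f_amp
      } else {
        out[[field]] <- out[[field]] * f_tau
        wfield <- sub("^tau", "window", field)
        out[[wfield]] <- out[[wfield]] * f_tau
      }
    }
  }
  class(out) <- "effective_params"
  out
}

#' Draw an i.i.d. threshold-mismatch sample
#'
#' Independent `Normal(0, sigma_vth)` threshold deviations for every
#' transistor active in the variant.
#'
#' @param sigma_vth Per-transistor threshold standard deviation (V).
#' @param variant Circuit variant.
#' @return Named numeric vector of deviations.
#' @export
draw_mismatch <- function(sigma_vth, variant = circuit_variants) {
  variant <- match.arg(variant)
  stopifnot(sigma_vth >= 0)
  labs <- active_transistors(variant)
  setNames(rnorm(length(labs), 0, sigma_vth), labs)
}
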