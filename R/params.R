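#' Pair-based STDP parameters
#'
#' Amplitudes and time constants for the classical pair-based STDP (PSTDP)
#' learning window. A causal pre-before-post pair at lag `dt > 0` potentiates
#' by `A_plus * exp(-dt / tau_plus)`; an acausal post-before-pre pair at lag
#' `dt' > 0` depresses by `A_minus * exp(-dt' / tau_minus)`. Only the nearest
#' opposite-train spike interacts (nearest-spike scheme).
#'
#' @param A_plus,A_minus Dimensionless weight-change amplitudes, `>= 0`.
#' @param tau_plus,tau_minus Time constants in seconds, `> 0`. The defaults
#'   (16.8 ms and 33.7 ms) are the values commonly used for cortical and
#'   hippocampal STDP windows.
#' @return An object of class `pair_params` (a named list).
#' @examples
#' pair_params(A_plus = 5e-3, A_minus = 3e-3)
#' @export
pair_params <- function(A_plus = 5e-3, A_minus = 5e-3,
                        tau_plus = 16.8e-3, tau_minus = 33.7e-3) {
  stopifnot(A_plus >= 0, A_minus >= 0, tau_plus > 0, tau_minus > 0)
  structure(
    list(A_plus = A_plus, A_minus = A_minus,
         tau_plus = tau_plus, tau_minus = tau_minus),
    class = "pair_params"
  )
}

#' Triplet STDP parameters
#'
#' Amplitudes and time constants of the triplet STDP (TSTDP) rule. On each
#' post-synaptic spike the weight is potentiated by
#' `exp(-dt1/tau_plus) * (A2_plus + A3_plus * exp(-(dt2 - epsilon)/tau_y))`,
#' where `dt1` is the lag since the nearest pre-synaptic spike and `dt2` the
#' lag since the previous post-synaptic spike (the triplet term is present
#' only when a previous post exists). Each pre-synaptic spike depresses by the
#' mirrored expression with `A2_minus`, `A3_minus`, `tau_minus`, `tau_x`.
#'
#' Rule variants impose zero constraints: `"tstdp_minimal_hippocampal"` forces
#' `A3_minus = 0`; `"tstdp_minimal_visual_cortex"` additionally forces
#' `A2_plus = 0`. `triplet_params()` enforces the constraints of the variant
#' passed to it.
#'
#' @param A2_plus,A2_minus Pair-interaction amplitudes (dimensionless, `>= 0`).
#' @param A3_plus,A3_minus Triplet-interaction amplitudes (dimensionless, `>= 0`).
#' @param tau_plus,tau_minus,tau_x,tau_y Time constants in seconds, `> 0`.
#' @param epsilon Small positive offset (seconds) ensuring the triplet trace
#'   is read just before the current spike. Default `1e-6` s.
#' @param variant One of `"tstdp_full"`, `"tstdp_minimal_hippocampal"`,
#'   `"tstdp_minimal_visual_cortex"`.
#' @return An object of class `triplet_params`.
#' @seealso [hippocampal_params()], [visual_cortex_params()]
#' @export
triplet_params <- function(A2_plus = 5e-3, A2_minus = 5e-3,
                           A3_plus = 5e-3, A3_minus = 0,
                           tau_plus = 16.8e-3, tau_minus = 33.7e-3,
                           tau_x = 101e-3, tau_y = 48e-3,
                           epsilon = 1e-6,
                           variant = c("tstdp_full",
                                       "tstdp_minimal_hippocampal",
                                       "tstdp_minimal_visual_cortex")) {
  variant <- match.arg(variant)
  stopifnot(
    A2_plus >= 0, A2_minus >= 0, A3_plus >= 0, A3_minus >= 0,
    tau_plus > 0, tau_minus > 0, tau_x > 0, tau_y > 0,
    epsilon > 0
  )
  if (epsilon >= min(tau_plus, tau_minus, tau_x, tau_y)) {
    abort("`epsilon` must be much smaller than the smallest time constant.")
  }
  if (variant %in% c("tstdp_minimal_hippocampal", "tstdp_minimal_visual_cortex") &&
      A3_minus != 0) {
    abort("minimal variants require A3_minus = 0")
  }
  if (variant == "tstdp_minimal_visual_cortex" && A2_plus != 0) {
    abort("the minimal visual-cortex variant requires A2_plus = 0")
  }
  structure(
    list(A2_plus = A2_plus, A2_minus = A2_minus,
         A3_plus = A3_plus, A3_minus = A3_minus,
         tau_plus = tau_plus, tau_minus = tau_minus,
         tau_x = tau_x, tau_y = tau_y,
         epsilon = epsilon, variant = variant),
    class = "triplet_params"
  )
}

#' Representative parameter sets
#'
#' Ready-made [triplet_params()] sets in the style of published nearest-spike
#' fits to the two classical data sets. `hippocampal_params()` is a minimal
#' hippocampal-style set (pair potentiation, pair depression and triplet
#' potentiation; `A3_minus = 0`) suited to pairing, triplet and quadruplet
#' protocols. `visual_cortex_params()` is a minimal visual-cortex-style set
#' (`A2_plus = 0` as well) suited to frequency-dependent pairing and BCM-like
#' rate experiments.
#'
#' These are representative defaults, not fitted constants: the experimental
#' weight-change tables they would be fitted to are external to this package.
#'
#' @return A [triplet_params()] object.
#' @examples
#' hippocampal_params()
#' @export
hippocampal_params <- function() {
  triplet_params(
    A2_plus = 4.6e-3, A2_minus = 3.0e-3,
    A3_plus = 9.1e-3, A3_minus = 0,
    tau_plus = 16.8e-3, tau_minus = 33.7e-3,
    tau_x = 101e-3, tau_y = 48e-3,
    variant = "tstdp_minimal_hippocampal"
  )
}

#' @rdname hippocampal_params
#' @export
visual_cortex_params <- function() {
  triplet_params(
    A2_plus = 0, A2_minus = 8.0e-3,
    A3_plus = 5.0e-2, A3_minus = 0,
    tau_plus = 16.8e-3, tau_minus = 33.7e-3,
    tau_x = 101e-3, tau_y = 40e-3,
    variant = "tstdp_minimal_visual_cortex"
  )
}

rule_variants <- c("pstdp", "tstdp_full",
                   "tstdp_minimal_hippocampal", "tstdp_minimal_visual_cortex")

#' @export
print.triplet_params <- function(x, ...) {
  cat("<triplet_params> variant:", x$variant, "\n")
  cat(sprintf("  A2+ = %.3g  A2- = %.3g  A3+ = %.3g  A3- = %.3g\n",
              x$A2_plus, x$A2_minus, x$A3_plus, x$A3_minus))
  cat(sprintf("  tau+ = %.3g s  tau- = %.3g s  tau_x = %.3g s  tau_y = %.3g s  eps = %.1g s\n",
              x$tau_plus, x$tau_minus, x$tau_x, x$tau_y, x$epsilon))
  invisible(x)
}

#' @export
print.pair_params <- function(x, ...) {
  cat("<pair_params>\n")
  cat(sprintf("  A+ = %.3g  A- = %.3g  tau+ = %.3g s  tau- = %.3g s\n",
              x$A_plus, x$A_minus, x$tau_plus, x$tau_minus))
  invisible(x)
}

# internal: scale a seed component into [0, 2^31) reproducibly
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  x <- 0
  for (p in parts) x <- (x * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(x)
}

# internal: run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
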