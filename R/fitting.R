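#' Normalized mean square error
#'
#' `NMSE = (1/N) * sum(((dw_exp_i - dw_sim_i) / sem_i)^2)`: the mean squared
#' residual between measured and simulated weight changes, each residual
#' scaled by that point's standard error of the mean. Invariant under joint
#' rescaling of `dw_exp`, `dw_sim` and `sem`.
#'
#' @param dw_sim Simulated weight changes.
#' @param dataset An [stdp_dataset()] tibble (columns `dw_exp`, `sem`), or a
#'   numeric vector of measured weight changes (then supply `sem`).
#' @param sem Standard errors when `dataset` is a bare numeric vector.
#' @return Scalar NMSE (`>= 0`).
#' @examples
#' nmse(c(0.5, 0.2), tibble::tibble(dw_exp = c(0.5, 0.3), sem = c(0.1, 0.1)))
#' @export
nmse <- function(dw_sim, dataset, sem = NULL) {
  if (is.data.frame(dataset)) {
    dw_exp <- dataset$dw_exp
    sem <- dataset$sem
  } else {
    dw_exp <- dataset
    if (is.null(sem)) abort("`sem` is required when `dataset` is a vector")
  }
  if (length(dw_sim) != length(dw_exp)) {
    abort("`dw_sim` and the dataset must have the same length")
  }
  if (any(!is.finite(sem)) || any(sem <= 0)) abort("all `sem` must be > 0")
  mean(((dw_exp - dw_sim) / sem)^2)
}

# ---- objectives ---------------------------------------------------------

triplet_amp_names <- c("A2_plus", "A2_minus", "A3_plus", "A3_minus")
triplet_tau_names <- c("tau_plus", "tau_minus", "tau_x", "tau_y")

# coefficients of dw in the four amplitudes at fixed time constants:
# dw = X %*% c(A2_plus, A2_minus, A3_plus, A3_minus) (depression columns
# carry their negative sign). Used as a fast path because the rule is linear
# in its amplitudes.
dataset_design_matrix <- function(dataset, params, pulse_width = 1e-3) {
  X <- matrix(0, nrow(dataset), 4, dimnames = list(NULL, triplet_amp_names))
  for (j in seq_len(4)) {
    amps <- setNames(as.list(as.numeric(seq_len(4) == j)), triplet_amp_names)
    pj <- triplet_params(
      A2_plus = amps$A2_plus, A2_minus = amps$A2_minus,
      A3_plus = amps$A3_plus, A3_minus = amps$A3_minus,
      tau_plus = params$tau_plus, tau_minus = params$tau_minus,
      tau_x = params$tau_x, tau_y = params$tau_y,
      epsilon = params$epsilon, variant = "tstdp_full"
    )
    X[, j] <- predict_dataset(dataset, pj, engine = "rule",
                              pulse_width = pulse_width)
  }
  X
}

# replace fields of a triplet_params with values from a named vector,
# bypassing variant zero-constraints during optimisation moves
set_params <- function(params, values) {
  p <- unclass(params)
  for (nm in names(values)) p[[nm]] <- values[[nm]]
  class(p) <- "triplet_params"
  p
}

#' Build an NMSE objective over rule parameters or circuit biases
#'
#' Returns a function `f(par)` mapping a named parameter vector to the NMSE
#' of the simulated dataset. For `engine = "rule"` the free parameters are
#' fields of [triplet_params()] (amplitudes and/or time constants); when all
#' free parameters are amplitudes the linearity of the rule in its
#' amplitudes is exploited through a precomputed design matrix. For
#' `engine = "circuit"` the free parameters are bias voltages of
#' [circuit_biases()]; each evaluation maps biases to effective parameters,
#' simulates every protocol, profiles the single global volt-to-fraction
#' scale factor by weighted least squares, and returns the NMSE.
#' Deterministic protocols give a deterministic objective; Poisson-protocol
#' rows use their per-row fixed seeds.
#'
#' @param dataset An [stdp_dataset()] tibble.
#' @param engine `"rule"` or `"circuit"`.
#' @param base_params A [triplet_params()] providing the fixed fields
#'   (rule engine).
#' @param base_biases A [circuit_biases()] providing fixed biases (circuit).
#' @param free Names of the free parameters (rule: parameter fields;
#'   circuit: bias fields).
#' @param device,variant Circuit configuration.
#' @param pulse_width Biological pulse width (s).
#' @return A function of a named numeric vector returning the scalar NMSE;
#'   it carries the attribute `free`.
#' @export
nmse_objective <- function(dataset, engine = c("rule", "circuit"),
                           base_params = hippocampal_params(),
                           base_biases = circuit_biases(),
                           free = c("A2_plus", "A2_minus", "A3_plus"),
                           device = device_params(), variant = "minimal14",
                           pulse_width = 1e-3) {
  engine <- match.arg(engine)
  stopifnot(inherits(dataset, "stdp_dataset"))
  if (engine == "rule") {
    stopifnot(all(free %in% c(triplet_amp_names, triplet_tau_names, "epsilon")))
    amps_only <- all(free %in% triplet_amp_names)
    if (amps_only) {
      X <- dataset_design_matrix(dataset, base_params, pulse_width)
      base_amp <- unlist(unclass(base_params)[triplet_amp_names])
      f <- function(par) {
        a <- base_amp
        a[names(par)] <- par
        nmse(drop(X %*% a), dataset)
      }
    } else {
      f <- function(par) {
        p <- set_params(base_params, par)
        nmse(predict_dataset(dataset, p, engine = "rule",
                             pulse_width = pulse_width), dataset)
      }
    }
  } else {
    bias_names <- names(unclass(circuit_biases()))
    stopifnot(all(free %in% bias_names))
    # precompute the per-protocol event tables once; only the effective
    # parameters change between evaluations
    evtabs <- lapply(seq_len(nrow(dataset)), function(i) {
      circuit_event_table(protocol_trains(dataset[i, ], pulse_width), device)
    })
    f <- function(par) {
      b <- unclass(base_biases)
      b[names(par)] <- par
      class(b) <- "circuit_biases"
      eff <- biases_to_effective(b, device, variant)
      dv <- vapply(evtabs, function(ev) sum(circuit_event_dv(ev, eff, device)),
                   numeric(1))
      s <- profile_scale(dv, dataset$dw_exp, dataset$sem)
      nmse(dv * s, dataset)
    }
  }
  attr(f, "free") <- free
  f
}

#' Derivative-free simplex minimisation with bounds and multi-start
#'
#' Nelder-Mead simplex descent (reflection/expansion/contraction/shrink) of
#' a scalar objective, with box bounds handled by projection of each
#' candidate onto the feasible region, and optional seeded multi-start
#' (restarts jitter the initial point uniformly within a fraction of the box).
#' The best result across starts is returned.
#'
#' @param fn Objective function of a named numeric vector.
#' @param start Named numeric start vector (within bounds).
#' @param lower,upper Bounds (recycled to `length(start)`).
#' @param n_restarts Number of starts (first one is `start` itself).
#' @param seed Integer seed for the restart jitter.
#' @param max_evals Total objective-evaluation budget.
#' @param reltol Convergence tolerance passed to the simplex.
#' @return A list with `par`, `value`, `n_evaluations`, `converged`.
#' @examples
#' optimize_simplex(function(p) sum((p - c(a = 1, b = 2))^2),
#'                  start = c(a = 0, b = 0), lower = -5, upper = 5)
#' @export
optimize_simplex <- function(fn, start, lower = -Inf, upper = Inf,
                             n_restarts = 1, seed = 1, max_evals = 2000,
                             reltol = 1e-10) {
  stopifnot(length(start) >= 1, n_restarts >= 1)
  lower <- rep_len(lower, length(start))
  upper <- rep_len(upper, length(start))
  if (any(start < lower | start > upper)) abort("`start` must lie within bounds")
  nm <- names(start)
  project <- function(p) pmin(pmax(p, lower), upper)
  evals <- 0L
  wrapped <- function(p) {
    evals <<- evals + 1L
    fn(setNames(project(p), nm))
  }
  per_start <- max(20L, floor(max_evals / n_restarts))
  starts <- list(start)
  if (n_restarts > 1) {
    width <- ifelse(is.finite(upper - lower), upper - lower,
                    pmax(abs(start), 1))
    jitters <- with_seed(derive_seed(seed, 23L), {
      lapply(seq_len(n_restarts - 1), function(i) {
        project(start + runif(length(start), -0.3, 0.3) * width)
      })
    })
    starts <- c(starts, jitters)
  }
  best <- NULL
  for (s0 in starts) {
    if (length(start) == 1) {
      # 1-D: coarse scan to bracket the basin, then golden-section refinement
      if (!all(is.finite(c(lower, upper)))) abort("1-D search needs finite bounds")
      grid <- unique(sort(c(s0, seq(lower, upper, length.out = 41))))
      fg <- vapply(grid, wrapped, numeric(1))
      k <- which.min(fg)
      o <- stats::optimize(wrapped,
                           lower = grid[max(k - 1, 1)],
                           upper = grid[min(k + 1, length(grid))])
      res <- if (o$objective <= fg[k]) {
        list(par = o$minimum, value = o$objective, convergence = 0L)
      } else {
        list(par = grid[k], value = fg[k], convergence = 0L)
      }
    } else {
      # repeated Nelder-Mead restarts from the incumbent: a fresh simplex
      # recovers from collapse against the projection boundary
      cur <- s0; cur_val <- wrapped(cur); conv <- FALSE
      for (cycle in 1:10) {
        res_i <- suppressWarnings(
          optim(cur, wrapped, method = "Nelder-Mead",
                control = list(maxit = per_start, reltol = reltol))
        )
        improved <- res_i$value < cur_val - reltol * (abs(cur_val) + reltol)
        if (res_i$value < cur_val) {
          # restart from the projected incumbent: outside-the-box iterates sit
          # in the projection's flat region and stall the next simplex
          cur <- project(res_i$par); cur_val <- res_i$value
        }
        conv <- res_i$convergence == 0L
        if (!improved || evals >= max_evals) break
      }
      res <- list(par = cur, value = cur_val,
                  convergence = if (conv) 0L else 1L)
    }
    cand <- list(par = setNames(project(res$par), nm), value = res$value,
                 converged = res$convergence == 0L)
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  list(par = best$par, value = best$value, n_evaluations = evals,
       converged = best$converged && evals <= max_evals)
}

#' Fit rule parameters or circuit biases to a weight-change dataset
#'
#' Minimises the NMSE of [nmse_objective()] by projected Nelder-Mead simplex
#' search ([optimize_simplex()]). Default bounds follow typical STDP ranges:
#' amplitudes in `[0, 0.1]`, time constants in `[1, 200]` ms; circuit bias
#' voltages are bounded by the supply rails.
#'
#' @inheritParams nmse_objective
#' @param start Named start vector; defaults to the `base_params` /
#'   `base_biases` values of the free parameters.
#' @param lower,upper Optional named bounds overriding the defaults.
#' @param n_restarts,seed,max_evals Passed to [optimize_simplex()].
#' @return An object of class `stdp_fit` with the best parameters, the
#'   reached `nmse`, the evaluation count and a convergence flag. Supports
#'   [tidy()] and [glance()].
#' @examples
#' ds <- make_synthetic_dataset(hippocampal_params(), noise_scale = 0, seed = 1)
#' fit <- fit_stdp(ds, free = c("A2_plus", "A3_plus"), max_evals = 400)
#' glance(fit)
#' @export
fit_stdp <- function(dataset, engine = c("rule", "circuit"),
                     base_params = hippocampal_params(),
                     base_biases = circuit_biases(),
                     free = c("A2_plus", "A2_minus", "A3_plus"),
                     device = device_params(), variant = "minimal14",
                     start = NULL, lower = NULL, upper = NULL,
                     n_restarts = 1, seed = 1, max_evals = 2000,
                     pulse_width = 1e-3) {
  engine <- match.arg(engine)
  obj <- nmse_objective(dataset, engine, base_params, base_biases, free,
                        device, variant, pulse_width)
  if (engine == "rule") {
    defaults <- unlist(unclass(base_params)[free])
    lo <- ifelse(free %in% triplet_amp_names, 0, 1e-3)
    hi <- ifelse(free %in% triplet_amp_names, 0.1, 0.2)
  } else {
    defaults <- unlist(unclass(base_biases)[free])
    lo <- rep(0, length(free))
    hi <- rep(device$Vdd, length(free))
  }
  start <- start %||% defaults
  lower <- (lower %||% setNames(lo, free))[free]
  upper <- (upper %||% setNames(hi, free))[free]
  res <- optimize_simplex(obj, start = start[free], lower = lower,
                          upper = upper, n_restarts = n_restarts,
                          seed = seed, max_evals = max_evals)
  out <- list(
    par = res$par, nmse = res$value, n_evaluations = res$n_evaluations,
    converged = res$converged, engine = engine, variant = variant,
    free = free, n_points = nrow(dataset),
    dataset_name = attr(dataset, "name", exact = TRUE) %||% "dataset"
  )
  if (engine == "rule") {
    out$params <- set_params(base_params, res$par)
  } else {
    b <- unclass(base_biases); b[names(res$par)] <- res$par
    class(b) <- "circuit_biases"
    out$biases <- b
    eff <- biases_to_effective(b, device, variant)
    dv <- predict_dataset(dataset, engine = "circuit", effective = eff,
                          device = device, variant = variant, scale = NULL,
                          pulse_width = pulse_width)
    out$scale <- attr(dv, "scale")
  }
  class(out) <- "stdp_fit"
  out
}

#' @export
print.stdp_fit <- function(x, ...) {
  cat(sprintf("<stdp_fit> engine: %s  variant: %s  points: %d\n",
              x$engine, x$variant, x$n_points))
  cat(sprintf("  NMSE = %.4g after %d evaluations (converged: %s)\n",
              x$nmse, x$n_evaluations, x$converged))
  print(round(x$par, 6))
  invisible(x)
}

#' Tidy a fitted STDP object
#' @param x An [fit_stdp()] result.
#' @param ... Unused.
#' @return `tidy()`: tibble with `term`, `estimate`. `glance()`: one-row
#'   tibble with `nmse`, `n_evaluations`, `converged`, `n_points`.
#' @export
tidy.stdp_fit <- function(x, ...) {
  tibble::tibble(term = names(x$par), estimate = unname(x$par))
}

#' @rdname tidy.stdp_fit
#' @export
glance.stdp_fit <- function(x, ...) {
  tibble::tibble(nmse = x$nmse, n_evaluations = x$n_evaluations,
                 converged = x$converged, n_points = x$n_points)
}
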