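# Two-layer elasto-visco-plastic rheological model -------------------------
#
# The model is the parallel coupling of
#   * a Prandtl layer: spring (E_pr) in series with a plastic slider whose
#     yield stress hardens exponentially (Voce saturation) from sigma_y
#     towards the ultimate stress sigma_u with exponent p, and
#   * a Maxwell layer: spring (E_mx) in series with a dashpot (eta),
#     giving stress relaxation with time constant tau = eta / E_mx.
#
# Internal canonical units are MPa / s / dimensionless strain; moduli and
# viscosity are expressed in GPa and GPa.s at the user interface because the
# literature reports them that way.

#' Material parameter set of the two-layer rheological model
#'
#' Bundles the six parameters \code{[E_pr, sigma_y, p, sigma_u, E_mx, eta]}
#' of one trabecula and validates their invariants. \code{E_pr} is the
#' long-term (quasistatic) elastic modulus \eqn{E_\infty}; \code{E_pr + E_mx}
#' is the instantaneous modulus \eqn{E_0}; the two bound any apparent
#' stiffness at finite strain rate. The hardening stress reserve is
#' \eqn{R = \sigma_u - \sigma_y}.
#'
#' @param E_pr long-term elastic modulus, GPa.
#' @param E_mx Maxwell-layer elastic modulus, GPa.
#' @param sigma_y initial yield stress, MPa.
#' @param sigma_u ultimate (saturation) stress, MPa; must be >= sigma_y.
#' @param p dimensionless exponential hardening exponent.
#' @param eta Maxwell-layer viscosity, GPa s.
#'
#' @return An object of class \code{"material_params"}: a named list with the
#'   six parameters plus derived quantities \code{R} (MPa), \code{E_0} (GPa)
#'   and \code{tau} (s, \code{NA} if the Maxwell layer is off).
#' @export
#' @examples
#' mp <- material_params(E_pr = 5.0, E_mx = 2.4, sigma_y = 30.8,
#'                       sigma_u = 84.3, p = 62.7, eta = 4.8)
#' mp$tau   # relaxation time constant eta / E_mx = 2 s
material_params <- function(E_pr, E_mx, sigma_y, sigma_u, p, eta) {
  vals <- c(E_pr = E_pr, E_mx = E_mx, sigma_y = sigma_y,
            sigma_u = sigma_u, p = p, eta = eta)
  if (any(!is.finite(vals)))
    stop("material parameters must be finite numbers", call. = FALSE)
  # E_mx = 0 or eta = 0 switches the Maxwell layer off (purely
  # elasto-plastic limit); the remaining parameters are strictly positive
  strict <- vals[c("E_pr", "sigma_y", "sigma_u", "p")]
  if (any(strict <= 0) || E_mx < 0 || eta < 0)
    stop("material parameters must be positive (E_mx, eta may be zero)",
         call. = FALSE)
  if (sigma_u < sigma_y)
    stop("sigma_u must be >= sigma_y (hardening stress R >= 0)",
         call. = FALSE)
  structure(list(E_pr = E_pr, E_mx = E_mx, sigma_y = sigma_y,
                 sigma_u = sigma_u, p = p, eta = eta,
                 R = sigma_u - sigma_y,
                 E_0 = E_pr + E_mx,
                 tau = if (E_mx > 0 && eta > 0) eta / E_mx else NA_real_),
            class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat("Two-layer rheological model parameters\n")
  cat(sprintf("  E_pr    = %8.3f GPa   (long-term modulus E_inf)\n", x$E_pr))
  cat(sprintf("  E_mx    = %8.3f GPa   (E_0 = E_pr + E_mx = %.3f GPa)\n",
              x$E_mx, x$E_0))
  cat(sprintf("  sigma_y = %8.3f MPa\n", x$sigma_y))
  cat(sprintf("  sigma_u = %8.3f MPa   (R = %.3f MPa)\n", x$sigma_u, x$R))
  cat(sprintf("  p       = %8.3f\n", x$p))
  cat(sprintf("  eta     = %8.3f GPa.s (tau = %.3f s)\n", x$eta, x$tau))
  invisible(x)
}

#' Displacement-controlled cyclic loading protocol
#'
#' Parameters of the incremental cyclic tensile protocol: each cycle ramps
#' the machine displacement at a constant rate to a peak that grows by a
#' fixed increment per cycle, holds, unloads to the previous cycle's peak
#' (to zero in the first cycle) and holds again. The first two holds are
#' long (default 60 s) to ensure complete relaxation; all later holds are
#' short (default 10 s).
#'
#' @param displacement_rate ramp rate, mm/s (default 0.01).
#' @param displacement_increment per-cycle peak growth, mm (default 0.025).
#' @param first_hold duration of the first two holds, s (default 60).
#' @param later_hold duration of all later holds, s (default 10).
#' @param first_peak_displacement peak of cycle 1, mm (default one increment).
#' @param max_cycles safety cap on cycle count (default 20).
#' @param sampling_rate output sampling rate, Hz (default 10, the frame rate
#'   of the optical strain camera).
#' @return An object of class \code{"loading_protocol"}.
#' @export
loading_protocol <- function(displacement_rate = 0.01,
                             displacement_increment = 0.025,
                             first_hold = 60,
                             later_hold = 10,
                             first_peak_displacement = displacement_increment,
                             max_cycles = 20,
                             sampling_rate = 10) {
  vals <- c(displacement_rate = displacement_rate,
            displacement_increment = displacement_increment,
            first_hold = first_hold, later_hold = later_hold,
            first_peak_displacement = first_peak_displacement,
            max_cycles = max_cycles, sampling_rate = sampling_rate)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("invalid protocol: all fields must be positive finite numbers",
         call. = FALSE)
  if (first_hold < later_hold)
    stop("invalid protocol: first_hold must be >= later_hold", call. = FALSE)
  structure(as.list(vals), class = "loading_protocol")
}

#' Strain-stress history container
#'
#' Time-aligned record of one cyclic tensile test: machine displacement,
#' (logarithmic) strain, and true stress. Stress may be \code{NA} when a
#' protocol has been built but not yet simulated or measured.
#'
#' @param time time stamps, s, strictly increasing.
#' @param displacement machine displacement, mm.
#' @param strain dimensionless strain.
#' @param stress true stress, MPa (may be NA).
#' @param failure_index optional sample index of fracture; the record is
#'   considered valid up to and including this index.
#' @return Object of class \code{"strain_stress_history"} (a data.frame with
#'   columns time, displacement, strain, stress and attribute failure_index).
#' @export
strain_stress_history <- function(time, displacement, strain,
                                  stress = rep(NA_real_, length(time)),
                                  failure_index = NULL) {
  n <- length(time)
  if (length(displacement) != n || length(strain) != n || length(stress) != n)
    stop("all channels must have equal length", call. = FALSE)
  if (n > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  if (!is.null(failure_index)) {
    failure_index <- as.integer(failure_index)
    if (failure_index < 1L || failure_index > n)
      stop("failure_index out of range", call. = FALSE)
  }
  structure(data.frame(time = time, displacement = displacement,
                       strain = strain, stress = stress),
            failure_index = failure_index,
            class = c("strain_stress_history", "data.frame"))
}

#' Generate the displacement schedule of the cyclic protocol
#'
#' Builds the piecewise-linear machine displacement signal of
#' \code{n_cycles} cycles of the incremental protocol, uniformly sampled at
#' the protocol's sampling rate, and fills the nominal strain channel
#' (displacement / gauge length). Stress is left \code{NA}.
#'
#' @param protocol a \code{\link{loading_protocol}}.
#' @param n_cycles number of complete cycles (>= 1).
#' @param gauge_length specimen gauge length, mm.
#' @return A \code{\link{strain_stress_history}} with empty stress channel.
#'   The attribute \code{"knots"} holds the exact ramp/hold switch times and
#'   displacements (useful as a segmentation oracle in tests).
#' @export
#' @examples
#' h <- build_protocol(loading_protocol(), n_cycles = 3, gauge_length = 0.687)
#' max(h$displacement)  # 3 * 0.025 mm
build_protocol <- function(protocol, n_cycles, gauge_length) {
  stopifnot(inherits(protocol, "loading_protocol"))
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  if (!is.finite(gauge_length) || gauge_length <= 0)
    stop("gauge_length must be positive", call. = FALSE)

  rate <- protocol$displacement_rate
  inc <- protocol$displacement_increment
  # knot schedule: (time, displacement) at every ramp/hold transition
  kt <- 0; kd <- 0
  t <- 0; d <- 0
  hold_count <- 0L
  for (k in seq_len(n_cycles)) {
    peak <- protocol$first_peak_displacement + (k - 1L) * inc
    unload_to <- max(peak - inc, 0)
    # ramp up
    t <- t + (peak - d) / rate; d <- peak
    kt <- c(kt, t); kd <- c(kd, d)
    # hold at peak
    hold_count <- hold_count + 1L
    t <- t + if (hold_count <= 2L) protocol$first_hold else protocol$later_hold
    kt <- c(kt, t); kd <- c(kd, d)
    # ramp down to previous cycle's peak
    t <- t + (d - unload_to) / rate; d <- unload_to
    kt <- c(kt, t); kd <- c(kd, d)
    # hold at bottom
    hold_count <- hold_count + 1L
    t <- t + if (hold_count <= 2L) protocol$first_hold else protocol$later_hold
    kt <- c(kt, t); kd <- c(kd, d)
  }

  ts <- seq(0, t, by = 1 / protocol$sampling_rate)
  ds <- approx(kt, kd, xout = ts, method = "linear", rule = 2)$y
  h <- strain_stress_history(time = ts, displacement = ds,
                             strain = ds / gauge_length)
  attr(h, "knots") <- data.frame(time = kt, displacement = kd)
  attr(h, "protocol") <- protocol
  attr(h, "gauge_length") <- gauge_length
  h
}

#' Current yield stress under Voce exponential hardening
#'
#' \deqn{\sigma_Y(\kappa) = \sigma_u - (\sigma_u - \sigma_y) e^{-p \kappa}}
#' i.e. the yield stress hardens exponentially with accumulated plastic
#' strain \eqn{\kappa} and plateaus at the ultimate stress.
#'
#' @param params a \code{\link{material_params}}.
#' @param kappa accumulated plastic strain, >= 0 (vectorized).
#' @return Yield stress, MPa.
#' @export
hardening_stress <- function(params, kappa) {
  stopifnot(inherits(params, "material_params"))
  if (any(!is.finite(kappa)) || any(kappa < 0))
    stop("kappa must be non-negative and finite", call. = FALSE)
  params$sigma_u - (params$sigma_u - params$sigma_y) * exp(-params$p * kappa)
}

#' Forward-simulate the two-layer model under a strain history
#'
#' Integrates the model stress response \eqn{\sigma = \sigma_{pr} +
#' \sigma_{mx}} along a prescribed strain history. The Prandtl layer uses a
#' radial-return update with Voce hardening on accumulated plastic strain;
#' the Maxwell layer a backward-Euler update (unconditionally stable). The
#' integrator sub-steps each sampling interval.
#'
#' @param params a \code{\link{material_params}}.
#' @param time time stamps, s, strictly increasing.
#' @param strain dimensionless strain history (same length as time).
#' @param substeps integration substeps per sampling interval (default 4).
#' @param tol optional relative sup-norm tolerance; when given, substeps are
#'   doubled (from \code{substeps} up to \code{max_substeps}) until two
#'   consecutive refinements agree within \code{tol}, else an error.
#' @param max_substeps refinement cap (default 256).
#' @param return_state if TRUE, also return accumulated plastic strain
#'   (kappa) and plastic strain paths.
#' @return Stress vector, MPa; or, with \code{return_state = TRUE}, a list
#'   with elements \code{stress}, \code{kappa}, \code{plastic_strain}.
#' @export
#' @examples
#' mp <- material_params(5, 2.4, 30.8, 84.3, 62.7, 4.8)
#' t <- seq(0, 10, by = 0.1)
#' eps <- pmin(t * 4e-4, 2e-3)  # ramp then hold below yield
#' s <- simulate_forward(mp, t, eps)
simulate_forward <- function(params, time, strain, substeps = 4L,
                             tol = NULL, max_substeps = 256L,
                             return_state = FALSE) {
  stopifnot(inherits(params, "material_params"))
  if (any(!is.finite(strain)))
    stop("strain history contains non-finite values", call. = FALSE)
  if (length(time) != length(strain))
    stop("time and strain must have equal length", call. = FALSE)
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)

  run <- function(ss) {
    cpp_simulate_forward(as.numeric(time), as.numeric(strain),
                         E_pr = params$E_pr * 1000, sigma_y = params$sigma_y,
                         p = params$p, sigma_u = params$sigma_u,
                         E_mx = params$E_mx * 1000,
                         eta = params$eta * 1000, substeps = as.integer(ss))
  }

  if (is.null(tol)) {
    out <- run(substeps)
  } else {
    ss <- as.integer(substeps)
    out <- run(ss)
    repeat {
      ss2 <- ss * 2L
      out2 <- run(ss2)
      ref <- max(abs(out2$stress), 1e-12)
      if (max(abs(out2$stress - out$stress)) / ref < tol) {
        out <- out2
        break
      }
      if (ss2 >= max_substeps)
        stop("integration did not reach requested accuracy within ",
             max_substeps, " substeps", call. = FALSE)
      ss <- ss2
      out <- out2
    }
  }
  if (return_state) out else out$stress
}

#' Loss tangent of the model in the pre-yield linear regime
#'
#' Closed-form damping of the model under small sinusoidal strain (Prandtl
#' slider inactive): with \eqn{\tau = \eta / E_{mx}} and \eqn{\omega = 2\pi
#' f}, storage modulus \eqn{E' = E_{pr} + E_{mx}\omega^2\tau^2 / (1 +
#' \omega^2\tau^2)}, loss modulus \eqn{E'' = E_{mx}\omega\tau / (1 +
#' \omega^2\tau^2)}, and \eqn{\tan\delta = E''/E'}. Evaluated at 1 Hz by
#' convention (approximate gait frequency).
#'
#' @param params a \code{\link{material_params}}.
#' @param frequency excitation frequency, Hz (default 1).
#' @return Dimensionless loss tangent.
#' @export
loss_tangent <- function(params, frequency = 1) {
  stopifnot(inherits(params, "material_params"))
  if (!is.finite(frequency) || frequency <= 0)
    stop("frequency must be positive", call. = FALSE)
  if (params$E_mx <= 0 || params$eta <= 0) return(0)
  omega <- 2 * pi * frequency
  wt <- omega * params$eta / params$E_mx
  storage <- params$E_pr + params$E_mx * wt^2 / (1 + wt^2)
  loss <- params$E_mx * wt / (1 + wt^2)
  loss / storage
}

#' Table-2-style group mean parameter sets
#'
#' Convenience constructors for the reported group-mean material parameters
#' of the control (CTRL) and osteoporotic-fracture (FRAC) groups, used as
#' defaults throughout the synthetic cohort generator and tests.
#'
#' @param group "CTRL" or "FRAC".
#' @return A \code{\link{material_params}}.
#' @export
reference_params <- function(group = c("CTRL", "FRAC")) {
  group <- match.arg(group)
  if (group == "CTRL")
    material_params(E_pr = 5.0, E_mx = 2.4, sigma_y = 30.8,
                    sigma_u = 84.3, p = 62.7, eta = 4.8)
  else
    material_params(E_pr = 4.9, E_mx = 2.6, sigma_y = 31.9,
                    sigma_u = 93.8, p = 63.3, eta = 4.3)
}
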