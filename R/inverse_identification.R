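# Inverse identification of the rheological model --------------------------

#' Root-mean-square error between model and measured stress
#'
#' @param model_stress,measured_stress equal-length stress vectors, MPa.
#' @return RMSE, MPa.
#' @export
stress_rmse <- function(model_stress, measured_stress) {
  if (length(model_stress) != length(measured_stress))
    stop("stress vectors must have equal length", call. = FALSE)
  if (!length(model_stress)) stop("empty stress vectors", call. = FALSE)
  sqrt(mean((model_stress - measured_stress)^2))
}

# data-driven initial guess: cycle-1 loading tangent for E_pr, envelope
# yield stress for sigma_y, 1.1 x peak envelope stress for sigma_u, hold
# relaxation for eta.
identify_init <- function(history, protocol) {
  guess <- list(E_pr = 5, E_mx = 2.5, sigma_y = 30, sigma_u = 90,
                p = 50, eta = 5, label = "fallback")
  seg <- tryCatch(segment_cycles(history, protocol), error = function(e) NULL)
  if (is.null(seg)) return(guess)

  ld1 <- seg[seg$cycle == 1L & seg$phase == "loading", ]
  if (nrow(ld1) == 1L) {
    idx <- seq(ld1$i_start, ld1$i_end)
    f <- tryCatch(fit_loading_phase(history$strain[idx], history$stress[idx]),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      m <- tryCatch(tangent_modulus(f), error = function(e) NA_real_)
      if (is.finite(m) && m > 0.1 && m < 50) guess$E_pr <- m
    }
  }
  guess$E_mx <- 0.5 * guess$E_pr

  env <- tryCatch(build_envelope(history, seg), error = function(e) NULL)
  if (!is.null(env) && length(env$strain) >= 10L) {
    ap <- tryCatch(apparent_properties(env), error = function(e) NULL)
    if (!is.null(ap)) {
      sy <- env$stress[ap$yield_index]
      if (is.finite(sy) && sy > 1) guess$sigma_y <- sy
    }
    smax <- max(env$stress)
    if (is.finite(smax) && smax > guess$sigma_y)
      guess$sigma_u <- 1.1 * smax
  }
  if (guess$sigma_u <= guess$sigma_y) guess$sigma_u <- 2 * guess$sigma_y

  # eta from the stress decay during the first top hold: time for the
  # relaxing part to fall to 1/e of its amplitude estimates tau = eta/E_mx
  h1 <- seg[seg$cycle == 1L & seg$phase == "hold_top", ]
  if (nrow(h1) == 1L && h1$i_end - h1$i_start > 5L) {
    idx <- seq(h1$i_start, h1$i_end)
    s <- history$stress[idx]; tt <- history$time[idx]
    amp <- s[1] - s[length(s)]
    if (is.finite(amp) && amp > 1e-3) {
      target <- s[length(s)] + amp / exp(1)
      below <- which(s <= target)
      if (length(below)) {
        tau <- tt[below[1]] - tt[1]
        if (tau > 0.05) guess$eta <- guess$E_mx * tau
      }
    }
  }
  guess$label <- "data-driven"
  guess
}

#' Identify material parameters from a cyclic record
#'
#' Recovers the six model parameters by downhill-simplex (Nelder-Mead)
#' minimization of the stress RMSE between \code{\link{simulate_forward}}
#' and the measured stress, over log-transformed parameters with soft box
#' bounds (quadratic penalty outside). Positivity and \eqn{\sigma_u \ge
#' \sigma_y} are built into the parametrization
#' \code{log(c(E_pr, E_mx, sigma_y, R, p, eta))} with \eqn{R = \sigma_u -
#' \sigma_y}. Starts from a data-driven initial guess (cycle-1 loading
#' tangent, envelope yield/ultimate stress, hold-phase relaxation time)
#' plus deterministic perturbed restarts.
#'
#' @param history a \code{\link{strain_stress_history}} with stress data.
#' @param protocol the \code{\link{loading_protocol}} used (for
#'   segmentation-based initialization).
#' @param n_starts number of simplex starts (default 3: one data-driven +
#'   two deterministic perturbations).
#' @param substeps integration substeps forwarded to the simulator.
#' @param maxit maximum function evaluations per start (default 5000).
#' @param reltol relative convergence tolerance (default 1e-6).
#' @param init_params optional \code{\link{material_params}} used as the
#'   primary start instead of the data-driven guess (e.g. to restart the
#'   simplex from a previous optimum).
#' @param bounds named list of soft \code{c(lo, hi)} bounds; defaults
#'   \code{E_pr}, \code{E_mx} in [0.1, 30] GPa, \code{sigma_y}, \code{R} in
#'   [1, 500] MPa, \code{p} in [1, 500], \code{eta} in [1e-3, 100] GPa s (the low end
#'   admits the effectively inviscid, purely elasto-plastic limit).
#' @return Object of class \code{"fit_result"}: list with \code{params}
#'   (a \code{\link{material_params}}), \code{rmse} (MPa),
#'   \code{n_complete_cycles}, \code{converged}, \code{n_evals},
#'   \code{init_strategy}.
#' @export
identify <- function(history, protocol = loading_protocol(),
                     n_starts = 3L, substeps = 4L,
                     maxit = 5000L, reltol = 1e-6, init_params = NULL,
                     bounds = list(E_pr = c(0.1, 30), E_mx = c(0.1, 30),
                                   sigma_y = c(1, 500), R = c(0.5, 500),
                                   p = c(1, 500), eta = c(1e-3, 100))) {
  stopifnot(inherits(history, "strain_stress_history"))
  fi <- attr(history, "failure_index")
  n <- if (is.null(fi)) nrow(history) else fi
  tt <- history$time[seq_len(n)]
  eps <- history$strain[seq_len(n)]
  sig <- history$stress[seq_len(n)]
  if (any(!is.finite(sig)))
    stop("stress channel contains non-finite values before failure",
         call. = FALSE)

  seg <- tryCatch(segment_cycles(history, protocol), error = function(e) NULL)
  n_cyc <- if (is.null(seg)) 0L else attr(seg, "n_complete")
  if (n_cyc < 1L)
    stop("record has no complete cycle; cannot identify", call. = FALSE)

  lb <- log(vapply(bounds, `[`, numeric(1), 1L))
  ub <- log(vapply(bounds, `[`, numeric(1), 2L))

  unpack <- function(theta) {
    v <- exp(theta)
    material_params(E_pr = v[1], E_mx = v[2], sigma_y = v[3],
                    sigma_u = v[3] + v[4], p = v[5], eta = v[6])
  }
  objective <- function(theta) {
    pen <- sum(pmax(lb - theta, 0)^2 + pmax(theta - ub, 0)^2)
    th <- pmin(pmax(theta, lb), ub)
    mp <- unpack(th)
    s <- cpp_simulate_forward(tt, eps, E_pr = mp$E_pr * 1000,
                              sigma_y = mp$sigma_y, p = mp$p,
                              sigma_u = mp$sigma_u, E_mx = mp$E_mx * 1000,
                              eta = mp$eta * 1000,
                              substeps = as.integer(substeps))$stress
    stress_rmse(s, sig) * (1 + pen)
  }

  if (is.null(init_params)) {
    init <- identify_init(history, protocol)
  } else {
    stopifnot(inherits(init_params, "material_params"))
    init <- list(E_pr = init_params$E_pr,
                 E_mx = max(init_params$E_mx, 0.1),
                 sigma_y = init_params$sigma_y,
                 sigma_u = init_params$sigma_u, p = init_params$p,
                 eta = max(init_params$eta, 0.05), label = "user")
  }
  base <- log(c(init$E_pr, init$E_mx, init$sigma_y,
                max(init$sigma_u - init$sigma_y, 1), init$p, init$eta))
  base <- pmin(pmax(base, lb), ub)
  # deterministic restarts (no RNG: identify must be a pure function of
  # its inputs): multiplicative perturbations of the data-driven guess,
  # plus a low-viscosity corner (small E_mx, long tau) that fits records
  # whose holds show no relaxation (elasto-plastic limit)
  corner <- pmin(pmax(log(c(exp(base[1]), 0.12, exp(base[3]),
                            exp(base[4]), exp(base[5]), 20)), lb), ub)
  perturb <- list(c(1, 1, 1, 1, 1, 1),
                  c(1.5, 0.6, 0.7, 1.4, 0.3, 2.0),
                  NULL,  # corner start
                  c(2.0, 2.0, 0.5, 2.0, 0.1, 1.0),
                  c(0.5, 0.5, 2.0, 0.5, 10, 0.2))
  n_starts <- min(as.integer(n_starts), length(perturb))

  best <- NULL
  evals <- 0L
  for (k in seq_len(n_starts)) {
    th0 <- if (is.null(perturb[[k]])) corner
           else pmin(pmax(base + log(perturb[[k]]), lb), ub)
    o <- tryCatch(
      optim(th0, objective, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(o)) next
    evals <- evals + o$counts[["function"]]
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    return(structure(list(params = NULL, rmse = Inf,
                          n_complete_cycles = n_cyc, converged = FALSE,
                          n_evals = evals, init_strategy = init$label),
                     class = "fit_result"))
  th <- pmin(pmax(best$par, lb), ub)
  params <- unpack(th)
  s <- simulate_forward(params, tt, eps, substeps = substeps)
  structure(list(params = params,
                 rmse = stress_rmse(s, sig),
                 n_complete_cycles = n_cyc,
                 converged = best$convergence == 0,
                 n_evals = evals,
                 init_strategy = init$label),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Rheological model fit: RMSE = %.4f MPa over %d complete ",
              x$rmse, x$n_complete_cycles),
      sprintf("cycle(s); %sconverged (%d evals, %s start)\n",
              if (x$converged) "" else "NOT ", x$n_evals, x$init_strategy),
      sep = "")
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' Quality-control filter for a cohort of fits
#'
#' Applies the study's three sequential screening rules to a table of fit
#' results: (1) drop samples whose stress RMSE is an IQR outlier of the
#' pooled RMSE distribution; (2) drop samples with fewer than the minimum
#' number of complete cycles before failure; (3) flag per-variable IQR
#' outliers among the surviving samples and set those values (not the whole
#' sample) to \code{NA}.
#'
#' @param results data.frame with columns \code{rmse}, \code{n_cycles} and
#'   the parameter/property columns named in \code{variables}.
#' @param variables character vector of column names screened by rule 3
#'   (default: all numeric columns except rmse and n_cycles).
#' @param rmse_fence IQR fence multiplier for rule 1 (default 1.5).
#' @param min_cycles minimum complete cycles for rule 2 (default 3; the
#'   stricter 4-cycle regime is a configuration away).
#' @param var_fence IQR fence multiplier for rule 3 (default 1.5).
#' @return Object of class \code{"qc_report"}: list with \code{flags}
#'   (per-sample logicals \code{rmse_outlier}, \code{too_few_cycles}),
#'   \code{value_flags} (sample x variable matrix of rule-3 flags),
#'   \code{retained} (logical), \code{data} (the filtered table with
#'   flagged values set to NA), and \code{counts} per rule.
#' @export
qc_filter <- function(results, variables = NULL, rmse_fence = 1.5,
                      min_cycles = 3L, var_fence = 1.5) {
  if (!is.data.frame(results) || !nrow(results))
    stop("results must be a non-empty data.frame", call. = FALSE)
  if (!all(c("rmse", "n_cycles") %in% names(results)))
    stop("results must contain 'rmse' and 'n_cycles' columns", call. = FALSE)
  if (nrow(results) < 4L)
    stop("need >= 4 samples for IQR-based screening", call. = FALSE)
  if (is.null(variables)) {
    num <- vapply(results, is.numeric, logical(1))
    variables <- setdiff(names(results)[num], c("rmse", "n_cycles"))
  }

  rule1 <- iqr_outliers(results$rmse, fence_multiplier = rmse_fence)
  rule2 <- results$n_cycles < min_cycles
  retained <- !rule1 & !rule2

  data <- results
  value_flags <- matrix(FALSE, nrow(results), length(variables),
                        dimnames = list(NULL, variables))
  for (v in variables) {
    vals <- results[[v]][retained]
    if (sum(is.finite(vals)) >= 4L) {
      fl <- rep(FALSE, nrow(results))
      fl[retained][is.finite(vals)] <-
        iqr_outliers(vals[is.finite(vals)], fence_multiplier = var_fence)
      value_flags[, v] <- fl
      data[[v]][fl] <- NA
    }
  }
  data <- data[retained, , drop = FALSE]

  structure(list(flags = data.frame(rmse_outlier = rule1,
                                    too_few_cycles = rule2),
                 value_flags = value_flags,
                 retained = retained,
                 data = data,
                 counts = list(n_input = nrow(results),
                               dropped_rmse = sum(rule1),
                               dropped_cycles = sum(rule2 & !rule1),
                               values_flagged = sum(value_flags[retained, ]),
                               n_retained = sum(retained))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cn <- x$counts
  cat(sprintf(
    "QC report: %d samples in; %d dropped (RMSE), %d dropped (cycles), %d values flagged; %d retained\n",
    cn$n_input, cn$dropped_rmse, cn$dropped_cycles, cn$values_flagged,
    cn$n_retained))
  invisible(x)
}
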