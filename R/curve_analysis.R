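# Cyclic stress-strain curve analytics -------------------------------------

#' Segment a cyclic record into loading / holding / unloading phases
#'
#' Classifies each sampling interval of the machine displacement signal as
#' ramp-up, hold, or ramp-down by comparing its rate against a tolerance
#' (a fraction of the protocol ramp rate), merges short spurious runs, and
#' assembles cycles of the form loading, hold-top, unloading, hold-bottom.
#' The record is truncated at its failure index if set.
#'
#' @param history a \code{\link{strain_stress_history}} with the machine
#'   displacement channel.
#' @param protocol the \code{\link{loading_protocol}} used (supplies the
#'   nominal ramp rate for the rate tolerance).
#' @param rate_tol fraction of the ramp rate below which an interval counts
#'   as a hold (default 0.5).
#' @param min_run minimum run length in samples; shorter runs are absorbed
#'   into the preceding phase (default 3).
#' @return Object of class \code{"cycle_segmentation"}: a data.frame with
#'   columns \code{cycle}, \code{phase} (loading / hold_top / unloading /
#'   hold_bottom), \code{i_start}, \code{i_end} (inclusive sample indices);
#'   attributes \code{n_complete} (complete cycle count) and \code{partial}
#'   (TRUE when the record ends mid-cycle).
#' @export
segment_cycles <- function(history, protocol, rate_tol = 0.5, min_run = 3L) {
  stopifnot(inherits(history, "strain_stress_history"),
            inherits(protocol, "loading_protocol"))
  fi <- attr(history, "failure_index")
  n <- if (is.null(fi)) nrow(history) else fi
  if (n < 4L) stop("record too short to segment", call. = FALSE)
  t <- history$time[seq_len(n)]
  d <- history$displacement[seq_len(n)]

  # rate per interval from a widened central difference (span 3 intervals
  # where available) so per-sample displacement noise does not flip the
  # ramp/hold classification
  j <- seq_len(n - 1L)
  hi <- pmin(j + 2L, n)
  lo <- pmax(j - 1L, 1L)
  rate <- (d[hi] - d[lo]) / (t[hi] - t[lo])
  thr <- rate_tol * protocol$displacement_rate
  cls <- ifelse(rate > thr, 1L, ifelse(rate < -thr, -1L, 0L))

  # run-length encode and absorb runs shorter than min_run
  r <- rle(cls)
  if (length(r$lengths) > 1L) {
    repeat {
      short <- which(r$lengths < min_run)
      short <- short[short > 1L]
      if (!length(short)) break
      i <- short[1]
      r$values[i] <- r$values[i - 1L]
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  # interval j spans samples j..j+1; phase sample range [starts, ends + 1]
  phases <- data.frame(kind = r$values, i_start = starts, i_end = ends + 1L)

  lab <- function(k) c(`-1` = "unloading", `0` = "hold", `1` = "loading")[
    as.character(k)]
  out <- NULL
  cyc <- 0L
  j <- 1L
  partial <- FALSE
  while (j <= nrow(phases)) {
    if (phases$kind[j] == 1L) {
      cyc <- cyc + 1L
      block <- phases[j, ]
      row <- data.frame(cycle = cyc, phase = "loading",
                        i_start = block$i_start, i_end = block$i_end)
      # expect hold, unloading, hold
      expect <- c(0L, -1L, 0L)
      names_ <- c("hold_top", "unloading", "hold_bottom")
      jj <- j + 1L
      for (e in seq_along(expect)) {
        if (jj <= nrow(phases) && phases$kind[jj] == expect[e]) {
          row <- rbind(row, data.frame(cycle = cyc, phase = names_[e],
                                       i_start = phases$i_start[jj],
                                       i_end = phases$i_end[jj]))
          jj <- jj + 1L
        } else {
          partial <- TRUE
          break
        }
      }
      out <- rbind(out, row)
      j <- jj
    } else {
      j <- j + 1L  # leading hold or noise before first ramp
    }
  }
  if (is.null(out) || !any(out$phase == "loading"))
    stop("record contains no complete loading phase before failure",
         call. = FALSE)
  complete <- vapply(split(out$phase, out$cycle),
                     function(p) all(c("loading", "hold_top", "unloading",
                                       "hold_bottom") %in% p), logical(1))
  if (!any(complete))
    stop("fewer than one complete cycle before failure", call. = FALSE)
  structure(out,
            n_complete = sum(complete),
            partial = partial || !all(complete),
            class = c("cycle_segmentation", "data.frame"))
}

# shared machinery for the two exponential phase fits ----------------------

exp_fit_objective <- function(theta, x, y, kind) {
  yhat <- if (kind == "loading")
    theta[1] * (1 - exp(x / theta[2])) + theta[3]
  else
    (theta[1] / theta[2]) * (exp(theta[2] * x) - 1)
  if (any(!is.finite(yhat))) return(1e30)
  sum((y - yhat)^2)
}

finish_exp_fit <- function(theta, x, y, kind, x0, y0, converged) {
  theta <- unname(theta)
  yhat <- if (kind == "loading")
    theta[1] * (1 - exp(x / theta[2])) + theta[3]
  else
    (theta[1] / theta[2]) * (exp(theta[2] * x) - 1)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(kind = kind,
                 a = theta[1], b = theta[2],
                 c = if (kind == "loading") theta[3] else NA_real_,
                 x0 = x0, y0 = y0,
                 strain_range = range(x),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 rmse = sqrt(ss_res / length(y)),
                 converged = converged),
            class = "exp_fit")
}

#' Exponential fit of a loading phase
#'
#' Nonlinear least squares of \eqn{f(x) = a (1 - e^{x/b}) + c} on a loading
#' phase, with phase-local strain origin (\code{x = strain - strain[1]}).
#' For a concave tensile loading branch \eqn{a > 0, b < 0}; the initial
#' tangent is \eqn{f'(0) = -a/b}. Multi-start Nelder-Mead on the residual
#' sum of squares; a degenerate or non-convergent fit is returned flagged
#' (\code{converged = FALSE}) rather than raising.
#'
#' @param strain,stress phase samples (>= 5, strain non-constant).
#' @return Object of class \code{"exp_fit"} with coefficients \code{a}
#'   (MPa), \code{b} (strain units), \code{c} (MPa), the phase-local origin
#'   \code{x0}, goodness (\code{r_squared}, \code{rmse} in MPa) and a
#'   \code{converged} flag.
#' @export
fit_loading_phase <- function(strain, stress) {
  if (length(strain) < 5L || length(stress) != length(strain))
    stop("need >= 5 samples with equal-length strain and stress",
         call. = FALSE)
  if (diff(range(strain)) == 0)
    stop("strain must be non-constant", call. = FALSE)
  x0 <- strain[1]
  x <- strain - x0
  y <- stress

  span <- diff(range(x))
  m <- coef(lm(y ~ x))[[2]]  # secant-ish slope for starts
  starts <- list()
  for (scale in c(0.5, 1, 2, 5, 50)) {
    b0 <- -span * scale
    starts[[length(starts) + 1L]] <- c(a = -m * b0, b = b0, c = y[1])
  }
  best <- NULL
  for (s in starts) {
    o <- tryCatch(
      optim(s, exp_fit_objective, x = x, y = y, kind = "loading",
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(finish_exp_fit(c(0, -1, mean(y)), x, y, "loading", x0, NA_real_,
                          FALSE))
  finish_exp_fit(best$par, x, y, "loading", x0, NA_real_,
                 best$convergence == 0)
}

#' Exponential fit of an unloading phase
#'
#' Nonlinear least squares of \eqn{f(x) = (a/b)(e^{bx} - 1)} on an
#' unloading phase with phase-local origins (\code{x = strain - strain[1]},
#' \code{y = stress - stress[1]}); the form passes through the local origin
#' and its initial tangent is \eqn{f'(0) = a}.
#'
#' @inheritParams fit_loading_phase
#' @return An \code{"exp_fit"} (coefficient \code{c} is \code{NA}; the
#'   stress offset is stored in \code{y0}).
#' @export
fit_unloading_phase <- function(strain, stress) {
  if (length(strain) < 5L || length(stress) != length(strain))
    stop("need >= 5 samples with equal-length strain and stress",
         call. = FALSE)
  if (diff(range(strain)) == 0)
    stop("strain must be non-constant", call. = FALSE)
  x0 <- strain[1]; y0 <- stress[1]
  x <- strain - x0
  y <- stress - y0

  m <- coef(lm(y ~ x + 0))[[1]]
  if (!is.finite(m) || m == 0) m <- 1
  span <- diff(range(x))
  best <- NULL
  for (b0 in c(-2, -0.5, 0.5, 2, 10) / max(span, 1e-8)) {
    s <- c(a = m, b = b0)
    o <- tryCatch(
      optim(s, exp_fit_objective, x = x, y = y, kind = "unloading",
            method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best))
    return(finish_exp_fit(c(m, 1e-6), x, y, "unloading", x0, y0, FALSE))
  finish_exp_fit(best$par, x, y, "unloading", x0, y0,
                 best$convergence == 0)
}

#' Analytic tangent modulus of a fitted phase
#'
#' Evaluates the analytic first derivative of the fitted exponential at a
#' strain within the fitted range and converts it to GPa. The default
#' evaluation point is the first strain sample of the phase (the initial
#' part of the cycle), where the loading form gives \eqn{-a/b} and the
#' unloading form gives \eqn{a}.
#'
#' @param fit an \code{"exp_fit"}.
#' @param at_strain absolute strain at which to evaluate (default: phase
#'   start). Must lie within the fitted strain range.
#' @return Tangent modulus, GPa.
#' @export
tangent_modulus <- function(fit, at_strain = NULL) {
  stopifnot(inherits(fit, "exp_fit"))
  x <- if (is.null(at_strain)) 0 else at_strain - fit$x0
  rng <- fit$strain_range
  eps <- 1e-12 + 1e-9 * diff(rng)
  if (x < min(rng) - eps || x > max(rng) + eps)
    stop("evaluation strain outside the fitted phase range", call. = FALSE)
  deriv <- if (fit$kind == "loading")
    -fit$a / fit$b * exp(x / fit$b)
  else
    fit$a * exp(fit$b * x)
  deriv / 1000  # MPa -> GPa
}

#' Per-cycle loading and unloading moduli
#'
#' Fits the exponential forms on every loading and unloading phase of a
#' segmented record and tabulates their tangent moduli at the phase start.
#' Failed fits are recorded as \code{NA} rather than raising.
#'
#' @param history a \code{\link{strain_stress_history}} with stress data.
#' @param segmentation its \code{\link{segment_cycles}} result.
#' @return data.frame with one row per cycle: \code{cycle},
#'   \code{loading_modulus_GPa}, \code{unloading_modulus_GPa}, per-phase
#'   \code{r_squared} and convergence flags.
#' @export
modulus_evolution <- function(history, segmentation) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  cycles <- sort(unique(segmentation$cycle))
  one <- function(cy, ph, fitter) {
    row <- segmentation[segmentation$cycle == cy & segmentation$phase == ph, ]
    if (nrow(row) != 1L) return(list(mod = NA_real_, r2 = NA_real_, ok = FALSE))
    idx <- seq(row$i_start, row$i_end)
    idx <- idx[is.finite(history$stress[idx])]
    if (length(idx) < 5L) return(list(mod = NA_real_, r2 = NA_real_, ok = FALSE))
    f <- tryCatch(fitter(history$strain[idx], history$stress[idx]),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged)
      return(list(mod = NA_real_, r2 = if (is.null(f)) NA_real_ else f$r_squared,
                  ok = FALSE))
    list(mod = tangent_modulus(f), r2 = f$r_squared, ok = TRUE)
  }
  res <- lapply(cycles, function(cy) {
    lo <- one(cy, "loading", fit_loading_phase)
    un <- one(cy, "unloading", fit_unloading_phase)
    data.frame(cycle = cy,
               loading_modulus_GPa = lo$mod, loading_r2 = lo$r2,
               loading_ok = lo$ok,
               unloading_modulus_GPa = un$mod, unloading_r2 = un$r2,
               unloading_ok = un$ok)
  })
  do.call(rbind, res)
}

#' Monotone stress-strain envelope of a cyclic record
#'
#' Concatenates the loading-phase samples whose strain exceeds all
#' previously attained strain (a strict running maximum), i.e. the outer
#' boundary of the hysteresis loops. Hold and unloading samples are never
#' part of the envelope.
#'
#' @param history a \code{\link{strain_stress_history}}.
#' @param segmentation its \code{\link{segment_cycles}} result.
#' @return Object of class \code{"envelope_curve"}: list with strictly
#'   increasing \code{strain}, matching \code{stress}, and source sample
#'   \code{index}.
#' @export
build_envelope <- function(history, segmentation) {
  stopifnot(inherits(segmentation, "cycle_segmentation"))
  loads <- segmentation[segmentation$phase == "loading", ]
  idx <- unlist(mapply(seq, loads$i_start, loads$i_end, SIMPLIFY = FALSE))
  idx <- idx[is.finite(history$stress[idx])]
  if (!length(idx)) stop("no loading-phase stress samples", call. = FALSE)
  eps <- history$strain[idx]
  keep <- eps > cummax(c(-Inf, head(eps, -1L)))
  idx <- idx[keep]
  structure(list(strain = history$strain[idx],
                 stress = history$stress[idx],
                 index = idx),
            class = "envelope_curve")
}

#' Apparent mechanical properties from the envelope curve
#'
#' Apparent stiffness is the slope of the linear regression (with
#' intercept) over the initial envelope segment whose end point maximizes
#' the regression R-squared; that end point defines the apparent yield
#' strain. The apparent ultimate strain is the last envelope strain.
#' Elastic work is the trapezoidal area under the envelope up to yield;
#' postyield work the area from yield to failure. With stress in MPa and
#' dimensionless strain the areas are in MJ/m^3.
#'
#' @param envelope an \code{"envelope_curve"}.
#' @param min_window minimum regression window in samples (default 10); the
#'   R-squared scan runs from this window to the envelope end. Ties in
#'   R-squared resolve to the largest end index.
#' @return Object of class \code{"apparent_props"}: list with
#'   \code{E_hat_GPa}, \code{eps_y_hat_pct}, \code{eps_u_hat_pct},
#'   \code{W_el_MJm3}, \code{W_py_MJm3}, plus the yield sample index and
#'   the winning R-squared.
#' @export
apparent_properties <- function(envelope, min_window = 10L) {
  stopifnot(inherits(envelope, "envelope_curve"))
  x <- envelope$strain; y <- envelope$stress
  n <- length(x)
  min_window <- max(3L, as.integer(min_window))
  if (n < min_window)
    stop("envelope has fewer samples (", n, ") than the minimum regression ",
         "window (", min_window, ")", call. = FALSE)

  # cumulative-sum scan of R^2 of y ~ x over [1, j]
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x * x); cyy <- cumsum(y * y); cxy <- cumsum(x * y)
  j <- seq_len(n)
  sxx <- cxx - cx^2 / j
  syy <- cyy - cy^2 / j
  sxy <- cxy - cx * cy / j
  r2 <- ifelse(sxx > 0 & syy > 0, sxy^2 / (sxx * syy), NA_real_)
  r2[seq_len(min_window - 1L)] <- NA_real_
  if (all(is.na(r2)))
    stop("degenerate envelope: R-squared undefined everywhere", call. = FALSE)
  best <- max(r2, na.rm = TRUE)
  jy <- max(which(!is.na(r2) & r2 >= best - 1e-12))  # tie -> largest index
  slope <- sxy[jy] / sxx[jy]  # MPa per unit strain

  trapz <- function(i0, i1) {
    if (i1 <= i0) return(0)
    ii <- i0:i1
    sum(diff(x[ii]) * (head(y[ii], -1L) + tail(y[ii], -1L)) / 2)
  }
  w_el <- trapz(1L, jy)
  w_py <- trapz(jy, n)
  structure(list(E_hat_GPa = slope / 1000,
                 eps_y_hat_pct = x[jy] * 100,
                 eps_u_hat_pct = x[n] * 100,
                 W_el_MJm3 = w_el,
                 W_py_MJm3 = w_py,
                 yield_index = jy,
                 r_squared = r2[jy]),
            class = "apparent_props")
}

#' @export
print.apparent_props <- function(x, ...) {
  cat("Apparent (envelope) mechanical properties\n")
  cat(sprintf("  E_hat    = %8.3f GPa\n", x$E_hat_GPa))
  cat(sprintf("  eps_y    = %8.4f %%\n", x$eps_y_hat_pct))
  cat(sprintf("  eps_u    = %8.4f %%\n", x$eps_u_hat_pct))
  cat(sprintf("  W_el     = %8.5f MJ/m^3\n", x$W_el_MJm3))
  cat(sprintf("  W_py     = %8.5f MJ/m^3\n", x$W_py_MJm3))
  invisible(x)
}
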