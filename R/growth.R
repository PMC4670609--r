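# ---------------------------------------------------------------------------
# Stretch-driven finite-growth laws.
#
# Transverse growth (concentric hypertrophy, parallel sarcomere deposition):
#   Fg = theta I + (1 - theta) f0 x f0      det Fg = theta^2
# Longitudinal growth (eccentric hypertrophy, serial sarcomere deposition):
#   Fg = I + (theta - 1) f0 x f0            det Fg = theta
# Kinetics: theta_dot = <lambda - lambda_crit> / tau, with lambda the TOTAL
# fiber stretch |F f0| and lambda_crit the homeostatic stretch recorded under
# baseline load. The Macaulay bracket makes growth irreversible.
# ---------------------------------------------------------------------------

.check_unit <- function(f0, tol = 1e-8) {
  if (length(f0) != 3 || abs(sqrt(sum(f0^2)) - 1) > tol) {
    stop("frame error: f0 must be a unit 3-vector")
  }
  invisible(f0)
}

#' Orthonormal fiber/sheet/normal frame
#'
#' @param f0 referential fiber direction (myocyte long axis), unit 3-vector.
#' @param s0 sheet direction; if missing, an arbitrary unit vector orthogonal
#'   to `f0` is constructed.
#' @param n0 sheet-normal; defaults to `f0 x s0` (right-handed frame).
#' @param tol orthonormality tolerance.
#' @return Object of class `"fiber_frame"` with fields `f0`, `s0`, `n0`.
#' @export
fiber_frame <- function(f0, s0 = NULL, n0 = NULL, tol = 1e-8) {
  .check_unit(f0, tol)
  if (is.null(s0)) {
    aux <- if (abs(f0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    s0 <- aux - sum(aux * f0) * f0
    s0 <- s0 / sqrt(sum(s0^2))
  }
  if (is.null(n0)) {
    n0 <- c(f0[2] * s0[3] - f0[3] * s0[2],
            f0[3] * s0[1] - f0[1] * s0[3],
            f0[1] * s0[2] - f0[2] * s0[1])
  }
  fr <- structure(list(f0 = as.numeric(f0), s0 = as.numeric(s0),
                       n0 = as.numeric(n0)), class = "fiber_frame")
  Q <- cbind(fr$f0, fr$s0, fr$n0)
  if (max(abs(crossprod(Q) - I3)) > tol) {
    stop("frame error: frame is not orthonormal")
  }
  if (tensor_det(Q) < 0) stop("frame error: frame is not right-handed")
  fr
}

#' Transverse (concentric) growth tensor
#'
#' `Fg = theta I + (1 - theta) f0 x f0`: isotropic in-plane thickening of the
#' myocyte cross-section perpendicular to the fiber axis, no growth along the
#' fiber. Eigenvalues: 1 along `f0`, `theta` (twice) transverse, so
#' `det(Fg) = theta^2` and the grown volume ratio is `Jg = theta^2`.
#'
#' @param theta growth multiplier (> 0); `theta = 1.4` means 40% myocyte
#'   thickening.
#' @param f0 unit fiber direction.
#' @return 3x3 growth tensor.
#' @export
transverse_growth_tensor <- function(theta, f0) {
  .check_unit(f0)
  if (!is.finite(theta) || theta <= 0) {
    stop("invalid-growth-state: theta must be > 0")
  }
  theta * I3 + (1 - theta) * tcrossprod(f0)
}

#' Closed-form elastic tensor under transverse growth
#'
#' Sherman-Morrison inverse of the rank-one-updated growth tensor:
#' `Fe = F / theta + (theta - 1) / theta * f x f0`, with `f = F f0` the
#' deformed fiber direction. Equals `F %*% solve(Fg)` to machine precision.
#'
#' @param F total deformation gradient.
#' @inheritParams transverse_growth_tensor
#' @return 3x3 elastic deformation gradient.
#' @export
transverse_elastic_tensor <- function(F, theta, f0) {
  .check_unit(f0)
  if (!is.finite(theta) || theta == 0) stop("invalid-growth-state: singular growth (theta = 0)")
  f <- as.numeric(F %*% f0)
  F / theta + (theta - 1) / theta * tcrossprod(f, f0)
}

#' Longitudinal (eccentric) growth tensor
#'
#' `Fg = I + (theta - 1) f0 x f0`: serial sarcomere deposition lengthens the
#' myocyte along its axis. Eigenvalues: `theta` along `f0`, 1 transverse, so
#' `det(Fg) = theta`.
#'
#' @inheritParams transverse_growth_tensor
#' @return 3x3 growth tensor.
#' @export
longitudinal_growth_tensor <- function(theta, f0) {
  .check_unit(f0)
  if (!is.finite(theta) || theta <= 0) {
    stop("invalid-growth-state: theta must be > 0")
  }
  I3 + (theta - 1) * tcrossprod(f0)
}

#' Closed-form elastic tensor under longitudinal growth
#'
#' `Fe = F + (1 - theta) / theta * f x f0` (Sherman-Morrison), with
#' `f = F f0`. Equals `F %*% solve(Fg)` to machine precision.
#'
#' @inheritParams transverse_elastic_tensor
#' @return 3x3 elastic deformation gradient.
#' @export
longitudinal_elastic_tensor <- function(F, theta, f0) {
  .check_unit(f0)
  if (!is.finite(theta) || theta == 0) stop("invalid-growth-state: singular growth (theta = 0)")
  f <- as.numeric(F %*% f0)
  F + (1 - theta) / theta * tcrossprod(f, f0)
}

#' Growth tensor for a given mode
#' @inheritParams transverse_growth_tensor
#' @param mode `"transverse"` or `"longitudinal"`.
#' @return 3x3 growth tensor.
#' @export
growth_tensor <- function(theta, f0, mode = c("transverse", "longitudinal")) {
  mode <- match.arg(mode)
  if (mode == "transverse") transverse_growth_tensor(theta, f0)
  else longitudinal_growth_tensor(theta, f0)
}

#' Total fiber stretch
#'
#' `lambda = sqrt(f0 . t(F) F f0) = |F f0|`, the stretch of the myocyte long
#' axis under the TOTAL deformation. This is the driving quantity of the
#' growth kinetics.
#'
#' @param F deformation gradient.
#' @param f0 unit fiber direction.
#' @return Positive scalar stretch.
#' @export
fiber_stretch <- function(F, f0) {
  .check_unit(f0)
  sqrt(sum((F %*% f0)^2))
}

#' Growth kinetic state
#'
#' @param mode `"transverse"` (concentric) or `"longitudinal"` (eccentric).
#' @param lambda_crit homeostatic fiber stretch threshold(s), > 0; scalar or
#'   per-point vector. Growth activates only above this stretch.
#' @param theta current growth multiplier(s), >= min(1, initial value).
#' @param tau growth time constant in normalized time (> 0). Growth time is
#'   normalized; one unit corresponds to months-to-years of physical time.
#' @param theta_max optional cap on the growth multiplier (default `Inf`,
#'   i.e. the plain linear kinetics).
#' @return Object of class `"growth_state"`.
#' @export
growth_state <- function(mode = c("transverse", "longitudinal"),
                         lambda_crit = 1, theta = 1, tau = 1,
                         theta_max = Inf) {
  mode <- match.arg(mode)
  if (any(lambda_crit <= 0)) stop("invalid-growth-state: lambda_crit must be > 0")
  if (!is.finite(tau) || tau <= 0) stop("invalid-growth-state: tau must be > 0")
  if (any(theta <= 0)) stop("invalid-growth-state: theta must be > 0")
  structure(list(mode = mode, lambda_crit = lambda_crit, theta = theta,
                 tau = tau, theta_max = theta_max), class = "growth_state")
}

#' Stretch-driven growth rate
#'
#' `theta_dot = <lambda - lambda_crit> / tau`; the Macaulay bracket `< >`
#' returns zero for sub-threshold stretch, so growth is one-way.
#'
#' @param lambda current total fiber stretch (scalar or vector).
#' @param state a [growth_state()].
#' @return Growth rate(s) in 1/normalized-time, >= 0.
#' @export
growth_rate <- function(lambda, state) {
  pmax(lambda - state$lambda_crit, 0) / state$tau
}

#' Explicit growth update
#'
#' First-order explicit update
#' `theta = theta_n + <lambda - lambda_crit> dt / tau`, clamped at
#' `theta_max` when configured. The multiplier never decreases.
#'
#' @param theta_n growth multiplier(s) at the previous time step.
#' @param lambda current total fiber stretch(es).
#' @param state a [growth_state()].
#' @param dt time increment in normalized time (> 0).
#' @return Updated growth multiplier(s).
#' @export
update_growth <- function(theta_n, lambda, state, dt) {
  if (!is.finite(dt) || dt <= 0) stop("invalid-growth-state: dt must be > 0")
  pmin(theta_n + pmax(lambda - state$lambda_crit, 0) * dt / state$tau,
       state$theta_max)
}

#' Calibrate the homeostatic stretch threshold
#'
#' Records the converged baseline fiber-stretch field pointwise as the
#' per-integration-point growth threshold. By the Macaulay bracket an
#' immediate re-run of the baseline load then produces exactly zero growth
#' rate everywhere.
#'
#' @param baseline_stretch_field numeric vector of converged fiber stretches.
#' @param converged logical flag from the baseline solve.
#' @return The per-point `lambda_crit` field (a copy of the input).
#' @export
calibrate_lambda_crit <- function(baseline_stretch_field, converged = TRUE) {
  if (!isTRUE(converged)) {
    stop("calibration error: baseline solve did not converge")
  }
  if (any(!is.finite(baseline_stretch_field)) ||
      any(baseline_stretch_field <= 0)) {
    stop("calibration error: invalid baseline stretch field")
  }
  baseline_stretch_field
}
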