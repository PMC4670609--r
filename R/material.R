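# ---------------------------------------------------------------------------
# Quasi-incompressible orthotropic Fung-type myocardium.
#
# psi(Je, Ebar_e) = U(Je) + psibar(Ebar_e)
#   U(Je)        = [Je^2 - 2 ln Je] / (2 D0)
#   psibar(E)    = C0/2 [exp(E : B0 : E) - 1]
#
# The quadratic form is evaluated in the local fiber/sheet/normal frame. With
# E expressed there, E : B0 : E = sum_ij W_ij E_ij^2 where the symmetric
# weight matrix W carries Bff, Bss, Bnn on the diagonal and the shear weights
# Bfs, Bfn, Bsn on BOTH off-diagonal entries — this reproduces the Voigt
# representation diag{Bff, Bss, Bnn, 2Bfs, 2Bfn, 2Bsn} without any
# engineering shear-factor bookkeeping.
# ---------------------------------------------------------------------------

#' Material parameters of the orthotropic Fung model
#'
#' @param C0 stress scale in kPa (> 0).
#' @param D0 compressibility penalty parameter in kPa^-1 (> 0); the volumetric
#'   stiffness at the unstrained state is `2 / D0` kPa, i.e. 2000 kPa at the
#'   default `D0 = 0.001`.
#' @param Bff,Bss,Bnn,Bfs,Bfn,Bsn dimensionless stiffness weights (>= 0);
#'   `Bff` weighs fiber-fiber normal strain, `Bfs` etc. the shear strains.
#' @return An object of class `"material_parameters"`.
#' @seealso [scale_weights()] for the reduced two-parameter scaling.
#' @export
material_parameters <- function(C0 = 0.115, D0 = 0.001,
                                Bff = 14.4, Bss = 5.76, Bnn = 5.76,
                                Bfs = 5.04, Bfn = 5.04, Bsn = 2.88) {
  B <- c(Bff = Bff, Bss = Bss, Bnn = Bnn, Bfs = Bfs, Bfn = Bfn, Bsn = Bsn)
  if (!is.finite(C0) || C0 <= 0) stop("parameter error: C0 must be > 0")
  if (!is.finite(D0) || D0 <= 0) stop("parameter error: D0 must be > 0")
  if (any(!is.finite(B)) || any(B < 0)) {
    stop("parameter error: all stiffness weights must be >= 0")
  }
  W <- matrix(c(Bff, Bfs, Bfn,
                Bfs, Bss, Bsn,
                Bfn, Bsn, Bnn), 3, 3)
  structure(list(C0 = C0, D0 = D0, B = as.list(B), W = W),
            class = "material_parameters")
}

#' Two-parameter transversely isotropic weight scaling
#'
#' Reduces the six Fung stiffness weights to a single nonlinearity parameter
#' `B0` via the fixed ratios `Bff = B0`, `Bss = Bnn = 0.4 B0`,
#' `Bfs = Bfn = 0.35 B0`, `Bsn = 0.2 B0`, which yields the healthy-human
#' defaults `Bff = 14.4`, `Bss = Bnn = 5.76`, `Bfs = Bfn = 5.04`,
#' `Bsn = 2.88` at `B0 = 14.4`.
#'
#' @param C0 stress scale in kPa.
#' @param B0 dimensionless fiber stiffness weight (>= 0).
#' @param D0 compressibility penalty in kPa^-1.
#' @return A `"material_parameters"` object.
#' @examples
#' p <- scale_weights(0.115, 14.4)
#' p$B$Bss  # 5.76
#' @export
scale_weights <- function(C0 = 0.115, B0 = 14.4, D0 = 0.001) {
  if (!is.finite(B0) || B0 < 0) stop("parameter error: B0 must be >= 0")
  material_parameters(C0 = C0, D0 = D0,
                      Bff = B0, Bss = 0.4 * B0, Bnn = 0.4 * B0,
                      Bfs = 0.35 * B0, Bfn = 0.35 * B0, Bsn = 0.2 * B0)
}

#' Volumetric strain energy and its derivatives
#'
#' `U(Je) = [(Je)^2 - 2 ln(Je)] / (2 D0)`. The energy is defined up to a
#' constant (`U(1) = 1/(2 D0)`, not zero); its first derivative vanishes at
#' `Je = 1`, so the reference state is stress free.
#'
#' @param Je elastic Jacobian (> 0), scalar or vector.
#' @param params a `"material_parameters"` object.
#' @return List with `U`, `dU` and `d2U` (kPa), evaluated elementwise.
#' @export
volumetric_energy <- function(Je, params) {
  if (any(!is.finite(Je)) || any(Je <= 0)) {
    stop("inverted-element: Je must be positive")
  }
  D0 <- params$D0
  list(U   = (Je^2 - 2 * log(Je)) / (2 * D0),
       dU  = (Je - 1 / Je) / D0,
       d2U = (1 + 1 / Je^2) / D0)
}

#' Validate a fiber frame and return its rotation matrix
#' @keywords internal
frame_matrix <- function(frame, tol = 1e-8) {
  Q <- cbind(frame$f0, frame$s0, frame$n0)
  if (max(abs(crossprod(Q) - I3)) > tol) {
    stop("frame error: fiber frame is not orthonormal")
  }
  Q
}

#' Isochoric Fung strain energy
#'
#' Evaluates `psibar = C0/2 [exp(Ebar : B0 : Ebar) - 1]` with the strain
#' rotated into the fiber/sheet/normal frame.
#'
#' @param Ebar_e symmetric isochoric elastic Green-Lagrange strain (3x3).
#' @param frame a [fiber_frame()] object.
#' @param params a `"material_parameters"` object.
#' @return Strain energy density in kPa (>= 0).
#' @export
fung_energy <- function(Ebar_e, frame, params) {
  Q <- frame_matrix(frame)
  El <- crossprod(Q, Ebar_e %*% Q)
  q <- sum(params$W * El * El)
  params$C0 / 2 * (exp(q) - 1)
}

# Second Piola-Kirchhoff stress as a function of the elastic right
# Cauchy-Green tensor Ce, pulled back through Fg. Shared by stresses(),
# material_tangent() and the finite-difference oracles in the test suite
# operate against stresses() independently.
#' @keywords internal
.se_of_Ce <- function(Ce, Q, params) {
  Je2 <- tensor_det(Ce)
  if (!is.finite(Je2) || Je2 <= 0) stop("inverted-element: det(Ce) <= 0")
  Je <- sqrt(Je2)
  Ceinv <- tensor_inverse(Ce)
  Ebar <- (Je^(-2 / 3) * Ce - I3) / 2
  El <- crossprod(Q, Ebar %*% Q)
  q <- sum(params$W * El * El)
  Sbar_l <- params$C0 * exp(q) * (params$W * El)
  Sbar <- Q %*% Sbar_l %*% t(Q)
  dU <- (Je - 1 / Je) / params$D0
  Se_vol <- dU * Je * Ceinv
  Se_iso <- Je^(-2 / 3) * (Sbar - sum(Sbar * Ce) / 3 * Ceinv)
  psi <- (Je2 - 2 * log(Je)) / (2 * params$D0) + params$C0 / 2 * (exp(q) - 1)
  list(Se = Se_vol + Se_iso, psi = psi, Je = Je)
}

#' Stresses of the grown, elastically loaded material point
#'
#' Computes the elastic second Piola-Kirchhoff stress `Se` (intermediate
#' configuration) from the volumetric/isochoric split, pulls it back to the
#' reference configuration via `S = solve(Fg) Se solve(t(Fg))`, and pushes
#' forward to the Cauchy stress `sigma = F S t(F) / J`. Only the elastic part
#' of the deformation generates stress: at `F == Fg` all stresses vanish.
#'
#' @param F total deformation gradient (3x3, `det > 0`).
#' @param Fg growth tensor (3x3, `det > 0`).
#' @param frame a [fiber_frame()] object.
#' @param params a `"material_parameters"` object.
#' @return Object of class `"stress_result"`: list with symmetric tensors
#'   `S`, `Se`, `sigma` (kPa) and the strain energy density `psi` (kPa).
#' @export
stresses <- function(F, Fg, frame, params) {
  Q <- frame_matrix(frame)
  Fe <- multiplicative_split(F, Fg)
  Ce <- crossprod(Fe)
  res <- .se_of_Ce(Ce, Q, params)
  Fgi <- tensor_inverse(Fg)
  S <- Fgi %*% res$Se %*% t(Fgi)
  S <- (S + t(S)) / 2
  J <- tensor_det(F)
  sigma <- F %*% S %*% t(F) / J
  structure(list(S = S, Se = (res$Se + t(res$Se)) / 2,
                 sigma = (sigma + t(sigma)) / 2, psi = res$psi),
            class = "stress_result")
}

#' Consistent material tangent (numerically differentiated)
#'
#' Fourth-order referential tangent `dS/dE` obtained by forward finite
#' differences of the stress with respect to the total Green-Lagrange strain
#' (relative perturbation `1e-7`). The stress is evaluated through the same
#' code path as [stresses()], so the tangent is consistent by construction;
#' minor symmetries hold because both the stress and the strain perturbations
#' are symmetric.
#'
#' @inheritParams stresses
#' @param h relative finite-difference perturbation.
#' @return A `3 x 3 x 3 x 3` array `A` with `A[i, j, k, l] = dS_ij / dE_kl`.
#' @export
material_tangent <- function(F, Fg, frame, params, h = 1e-7) {
  Q <- frame_matrix(frame)
  Fgi <- tensor_inverse(Fg)
  C <- crossprod(F)
  S_of_C <- function(Cm) {
    Ce <- t(Fgi) %*% Cm %*% Fgi
    Se <- .se_of_Ce((Ce + t(Ce)) / 2, Q, params)$Se
    S <- Fgi %*% Se %*% t(Fgi)
    (S + t(S)) / 2
  }
  S0 <- S_of_C(C)
  A <- array(0, c(3, 3, 3, 3))
  hh <- h * max(1, max(abs(C)))
  for (k in 1:3) for (l in k:3) {
    dC <- matrix(0, 3, 3)
    dC[k, l] <- dC[k, l] + hh
    dC[l, k] <- dC[l, k] + hh
    # dE_kl = dE_lk = hh/2 for k != l; dE_kk = hh
    Sp <- S_of_C(C + dC)
    dS <- (Sp - S0) / hh
    # dS is the response to a unit symmetric strain pair; storing it in
    # both (k,l) and (l,k) slots makes the contraction A : dE (which sums
    # over both) reproduce the directional derivative
    A[, , k, l] <- dS
    if (k != l) A[, , l, k] <- dS
  }
  A
}
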