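# ---------------------------------------------------------------------------
# Finite-growth kinematics: multiplicative elastic/growth split of the
# deformation gradient and volumetric/isochoric elastic strain measures.
# ---------------------------------------------------------------------------

#' Multiplicative elastic/growth split of the deformation gradient
#'
#' Within finite growth theory the total deformation gradient decomposes as
#' `F = Fe %*% Fg`: only the total tensor derives from a continuous mapping,
#' while the growth part `Fg` maps into an (in general incompatible)
#' stress-free grown configuration and the elastic part `Fe` alone generates
#' stress. This function recovers `Fe = F %*% solve(Fg)`.
#'
#' @param F total deformation gradient, 3x3 with positive determinant.
#' @param Fg growth tensor, 3x3 with positive determinant.
#' @return The elastic deformation gradient `Fe` (3x3).
#' @examples
#' F <- diag(c(1.1, 1, 1))
#' multiplicative_split(F, diag(3))  # identity growth: Fe == F
#' @export
multiplicative_split <- function(F, Fg) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)),
            is.matrix(Fg), all(dim(Fg) == c(3, 3)))
  if (!all(is.finite(F)) || tensor_det(F) <= 0) {
    stop("inverted-element: det(F) must be positive")
  }
  dg <- tensor_det(Fg)
  if (!all(is.finite(Fg)) || !is.finite(dg) || dg <= 1e-14) {
    stop("invalid-growth-state: growth tensor is singular or inverted")
  }
  F %*% tensor_inverse(Fg)
}

#' Total Green-Lagrange strain
#'
#' `E = (t(F) %*% F - I) / 2`; identically zero for any rigid rotation.
#'
#' @param F deformation gradient, 3x3 with positive determinant.
#' @return Symmetric 3x3 strain tensor.
#' @export
green_lagrange <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(3, 3)))
  E <- (crossprod(F) - I3) / 2
  (E + t(E)) / 2
}

#' Elastic Jacobian and isochoric elastic Green-Lagrange strain
#'
#' Splits the elastic deformation into volumetric and isochoric parts. The
#' independent variables of the quasi-incompressible strain energy are the
#' elastic Jacobian `Je = det(Fe)` and the isochoric elastic Green-Lagrange
#' strain `Ebar_e = (Je^(-2/3) t(Fe) Fe - I) / 2`; the isochoric part of `Fe`
#' has unit determinant by construction.
#'
#' @param Fe elastic deformation gradient, 3x3 with positive determinant.
#' @return A list of class `"elastic_decomposition"` with elements
#'   `Fe`, `Je` (scalar) and `Ebar_e` (symmetric 3x3).
#' @export
elastic_measures <- function(Fe) {
  stopifnot(is.matrix(Fe), all(dim(Fe) == c(3, 3)))
  Je <- tensor_det(Fe)
  if (!is.finite(Je) || Je <= 0) {
    stop("inverted-element: det(Fe) must be positive")
  }
  Ebar <- (Je^(-2 / 3) * crossprod(Fe) - I3) / 2
  Ebar <- (Ebar + t(Ebar)) / 2
  structure(list(Fe = Fe, Je = Je, Ebar_e = Ebar),
            class = "elastic_decomposition")
}
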