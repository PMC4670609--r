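# ---------------------------------------------------------------------------
# Reference-element shape functions and quadrature.
#
# Tetrahedra use barycentric coordinates L1 = 1 - x1 - x2 - x3, L2 = x1,
# L3 = x2, L4 = x3. Quadratic (10-node) tets keep midside nodes at edge
# midpoints, so the geometry map stays affine and the reference Jacobian is
# constant per element. Node ordering: corners 1:4, then edge midpoints on
# (1,2), (2,3), (3,1), (1,4), (2,4), (3,4).
# ---------------------------------------------------------------------------

TET10_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L),
                     c(1L, 4L), c(2L, 4L), c(3L, 4L))
TRI6_EDGES <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))

# barycentric gradients w.r.t. (x1, x2, x3)
.dL_tet <- rbind(c(-1, -1, -1), diag(3))

#' Shape-function gradients of the 4-node tetrahedron (constant)
#' @keywords internal
tet4_grads <- function() .dL_tet

#' Quadrature rule on the reference tetrahedron
#' @param order element order (1 or 2).
#' @return list(points = n x 3 matrix, weights = n-vector); weights sum to
#'   the reference volume 1/6.
#' @keywords internal
tet_quadrature <- function(order) {
  if (order == 1L) {
    list(points = matrix(0.25, 1, 3), weights = 1 / 6)
  } else {
    a <- 0.585410196624968515
    b <- 0.138196601125010504
    list(points = rbind(c(b, b, b), c(a, b, b), c(b, a, b), c(b, b, a)),
         weights = rep(1 / 24, 4))
  }
}

#' Shape functions and gradients of the 10-node tetrahedron at a point
#' @param xi length-3 reference coordinates.
#' @return list(N = 10-vector, dN = 10 x 3 matrix of reference gradients).
#' @keywords internal
tet10_shape <- function(xi) {
  L <- c(1 - sum(xi), xi)
  N <- numeric(10)
  dN <- matrix(0, 10, 3)
  for (a in 1:4) {
    N[a] <- L[a] * (2 * L[a] - 1)
    dN[a, ] <- (4 * L[a] - 1) * .dL_tet[a, ]
  }
  for (e in 1:6) {
    a <- TET10_EDGES[e, 1]; b <- TET10_EDGES[e, 2]
    N[4 + e] <- 4 * L[a] * L[b]
    dN[4 + e, ] <- 4 * (L[a] * .dL_tet[b, ] + L[b] * .dL_tet[a, ])
  }
  list(N = N, dN = dN)
}

#' Shape functions/gradients for surface facets (3- or 6-node triangles)
#' @param xi length-2 reference coordinates.
#' @param n_nodes 3 or 6.
#' @return list(N, dN) with dN an `n_nodes x 2` matrix.
#' @keywords internal
tri_shape <- function(xi, n_nodes) {
  L <- c(1 - sum(xi), xi)
  dL <- rbind(c(-1, -1), diag(2))
  if (n_nodes == 3L) {
    return(list(N = L, dN = dL))
  }
  N <- numeric(6)
  dN <- matrix(0, 6, 2)
  for (a in 1:3) {
    N[a] <- L[a] * (2 * L[a] - 1)
    dN[a, ] <- (4 * L[a] - 1) * dL[a, ]
  }
  for (e in 1:3) {
    a <- TRI6_EDGES[e, 1]; b <- TRI6_EDGES[e, 2]
    N[3 + e] <- 4 * L[a] * L[b]
    dN[3 + e, ] <- 4 * (L[a] * dL[b, ] + L[b] * dL[a, ])
  }
  list(N = N, dN = dN)
}

#' Facet quadrature on the reference triangle (degree 2, 3 points)
#' @return list(points = 3 x 2, weights summing to 1/2).
#' @keywords internal
tri_quadrature <- function() {
  list(points = rbind(c(1 / 6, 1 / 6), c(2 / 3, 1 / 6), c(1 / 6, 2 / 3)),
       weights = rep(1 / 6, 3))
}
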