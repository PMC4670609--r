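# ---------------------------------------------------------------------------
# Geometric diagnostics on (deformed) meshes: cavity volume via the
# divergence theorem, wall volume via element Jacobians, and the basal-ring
# perimeter as the idealized analog of an annular perimeter.
# ---------------------------------------------------------------------------

.deformed_nodes <- function(mesh, displacement = NULL) {
  if (is.null(displacement)) return(mesh$nodes)
  stopifnot(length(displacement) == 3L * nrow(mesh$nodes))
  mesh$nodes + matrix(displacement, ncol = 3L, byrow = TRUE)
}

#' Deformed chamber (cavity) volume
#'
#' Closes the tagged endocardial surface with a flat fan cap over the ordered
#' basal ring and evaluates the enclosed volume by the divergence theorem on
#' the deformed configuration.
#'
#' @param mesh a `"ventricular_mesh"` with the chamber facet tag.
#' @param displacement nodal displacement vector (mm), or `NULL` for the
#'   reference configuration.
#' @param chamber facet tag, default `"endocardium_lv"`.
#' @return Cavity volume in mL.
#' @export
chamber_volume <- function(mesh, displacement = NULL,
                           chamber = "endocardium_lv") {
  facets <- mesh$facets[[chamber]]
  if (is.null(facets)) stop("config error: no facet tag '", chamber, "'")
  ring <- mesh$node_sets$basal_ring
  if (is.null(ring)) stop("diagnostic error: chamber surface is not closed (no basal ring)")
  x <- .deformed_nodes(mesh, displacement)
  # divergence theorem: V = (1/3) surface integral of x . n dA, with the
  # facet orientation flipped so normals point outward from the cavity
  # (stored orientation is outward from the solid, i.e. into the cavity)
  fn <- ncol(facets)
  flip <- if (fn == 3L) facets[, c(1L, 3L, 2L), drop = FALSE]
          else facets[, c(1L, 3L, 2L, 6L, 5L, 4L), drop = FALSE]
  qr <- tri_quadrature()
  xs <- lapply(seq_len(fn), function(a) x[flip[, a], , drop = FALSE])
  vol6 <- 0
  for (q in seq_len(nrow(qr$points))) {
    sh <- tri_shape(qr$points[q, ], fn)
    xq <- g1 <- g2 <- 0
    for (a in seq_len(fn)) {
      xq <- xq + sh$N[a] * xs[[a]]
      g1 <- g1 + sh$dN[a, 1] * xs[[a]]
      g2 <- g2 + sh$dN[a, 2] * xs[[a]]
    }
    cr <- cbind(g1[, 2] * g2[, 3] - g1[, 3] * g2[, 2],
                g1[, 3] * g2[, 1] - g1[, 1] * g2[, 3],
                g1[, 1] * g2[, 2] - g1[, 2] * g2[, 1])
    vol6 <- vol6 + 2 * qr$weights[q] * sum(xq * cr)
  }
  # flat cap: fan from the deformed ring centroid, outward normal +long-axis
  rx <- x[ring, , drop = FALSE]
  cen <- colMeans(rx)
  nxt <- rbind(rx[-1, , drop = FALSE], rx[1, , drop = FALSE])
  vol6 <- vol6 + sum(cen[1] * (rx[, 2] * nxt[, 3] - rx[, 3] * nxt[, 2]) -
                     cen[2] * (rx[, 1] * nxt[, 3] - rx[, 3] * nxt[, 1]) +
                     cen[3] * (rx[, 1] * nxt[, 2] - rx[, 2] * nxt[, 1]))
  vol6 / 6 / 1000
}

#' Deformed wall volume
#'
#' Sum of deformed element volumes over a region. In a stress-free purely
#' grown state this equals the reference volume times the mean grown volume
#' ratio `Jg`.
#'
#' @param mesh a `"ventricular_mesh"`.
#' @param displacement nodal displacement vector or `NULL`.
#' @param region region label, or `"all"`.
#' @return Wall volume in mL.
#' @export
wall_volume <- function(mesh, displacement = NULL, region = "all") {
  keep <- if (identical(region, "all")) rep(TRUE, nrow(mesh$elems))
          else mesh$region == region
  x <- .deformed_nodes(mesh, displacement)
  el <- mesh$elems[keep, , drop = FALSE]
  if (mesh$order == 1L || is.null(displacement)) {
    el <- el[, 1:4, drop = FALSE]
    v1 <- x[el[, 2], , drop = FALSE] - x[el[, 1], , drop = FALSE]
    v2 <- x[el[, 3], , drop = FALSE] - x[el[, 1], , drop = FALSE]
    v3 <- x[el[, 4], , drop = FALSE] - x[el[, 1], , drop = FALSE]
    vol <- (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
            v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
            v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
    return(sum(vol) / 1000)
  }
  # quadratic elements with displacement: integrate det(dx/dxi) by quadrature
  qr <- tet_quadrature(2L)
  tot <- 0
  for (q in seq_along(qr$weights)) {
    dN <- tet10_shape(qr$points[q, ])$dN
    Jx <- array(0, c(nrow(el), 3, 3))
    for (a in 1:10) {
      xa <- x[el[, a], , drop = FALSE]
      for (i in 1:3) for (J in 1:3) {
        Jx[, i, J] <- Jx[, i, J] + xa[, i] * dN[a, J]
      }
    }
    detJ <- Jx[, 1, 1] * (Jx[, 2, 2] * Jx[, 3, 3] - Jx[, 2, 3] * Jx[, 3, 2]) -
            Jx[, 1, 2] * (Jx[, 2, 1] * Jx[, 3, 3] - Jx[, 2, 3] * Jx[, 3, 1]) +
            Jx[, 1, 3] * (Jx[, 2, 1] * Jx[, 3, 2] - Jx[, 2, 2] * Jx[, 3, 1])
    tot <- tot + qr$weights[q] * sum(detJ)
  }
  tot / 1000
}

#' Deformed basal-ring perimeter
#'
#' Total length of the closed polyline through the ordered basal-ring nodes;
#' an idealized stand-in for an annular perimeter.
#'
#' @param mesh a `"ventricular_mesh"` with an ordered `basal_ring` node set.
#' @param displacement nodal displacement vector or `NULL`.
#' @return Perimeter in mm.
#' @export
basal_ring_perimeter <- function(mesh, displacement = NULL) {
  ring <- mesh$node_sets$basal_ring
  if (is.null(ring) || !isTRUE(attr(ring, "ordered"))) {
    stop("diagnostic error: basal ring node set is missing or unordered")
  }
  x <- .deformed_nodes(mesh, displacement)
  rx <- x[ring, , drop = FALSE]
  nxt <- rbind(rx[-1, , drop = FALSE], rx[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - rx)^2)))
}
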