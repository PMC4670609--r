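# ---------------------------------------------------------------------------
# Rule-based myocardial fiber architecture.
#
# The helix angle of the myocyte long axis rotates transmurally from the
# endocardium to the epicardium (default +60 deg -> -60 deg, linear in the
# transmural coordinate), measured from the local circumferential direction
# toward the local longitudinal direction. Sheets point transmurally
# outward. One orthonormal frame is stored per element.
# ---------------------------------------------------------------------------

#' Fiber rule parameters
#'
#' @param endo_angle,epi_angle helix angle (degrees, in `[-90, 90]`) at the
#'   endocardial and epicardial surfaces.
#' @param law transmural interpolation law; only `"linear"` is supported.
#' @return Object of class `"fiber_rule_params"`.
#' @export
fiber_rule_params <- function(endo_angle = 60, epi_angle = -60,
                              law = "linear") {
  if (abs(endo_angle) > 90 || abs(epi_angle) > 90) {
    stop("parameter error: helix angles must lie in [-90, 90] degrees")
  }
  law <- match.arg(law, "linear")
  structure(list(endo_angle = endo_angle, epi_angle = epi_angle, law = law),
            class = "fiber_rule_params")
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Assign helical fiber/sheet/normal frames to a mesh
#'
#' Builds one orthonormal frame per element: the transmural direction is the
#' gradient of the nodal transmural coordinate, the circumferential and
#' longitudinal directions follow from the mesh long axis, and the fiber
#' direction is rotated by the transmurally interpolated helix angle. At
#' (near-)degenerate apex elements, where the circumferential direction is
#' undefined, the frame falls back to a long-axis-aligned fiber; the number
#' of fallbacks is recorded and reported.
#'
#' @param mesh a `"ventricular_mesh"`.
#' @param rule a [fiber_rule_params()] object.
#' @return The mesh with a `fibers` component: matrices `f0`, `s0`, `n0`
#'   (one row per element), the helix angle (degrees), the element
#'   transmural coordinate, and the fallback count.
#' @export
assign_fibers <- function(mesh, rule = fiber_rule_params()) {
  el <- mesh$elems
  m <- nrow(el)
  zhat <- mesh$long_axis / sqrt(sum(mesh$long_axis^2))
  f0 <- s0 <- n0 <- matrix(0, m, 3)
  helix <- numeric(m)
  te <- numeric(m)
  n_fallback <- 0L
  dN <- tet4_grads()
  for (e in seq_len(m)) {
    corners <- el[e, 1:4]
    X <- mesh$nodes[corners, , drop = FALSE]
    tv <- mesh$transmural[corners]
    te[e] <- mean(tv)
    J <- t(X[2:4, , drop = FALSE] - matrix(X[1, ], 3, 3, byrow = TRUE))
    gt_ref <- as.numeric(crossprod(dN, tv))
    gt <- solve(t(J), gt_ref)
    ng <- sqrt(sum(gt^2))
    et <- if (ng > 1e-10) gt / ng else zhat
    ec_raw <- .cross3(zhat, et)
    nc_ <- sqrt(sum(ec_raw^2))
    alpha <- (rule$endo_angle +
              (rule$epi_angle - rule$endo_angle) * te[e]) * pi / 180
    if (nc_ < 1e-6) {
      # degenerate (apex): long-axis-aligned fallback
      n_fallback <- n_fallback + 1L
      fa <- zhat - sum(zhat * et) * et
      if (sqrt(sum(fa^2)) < 1e-6) fa <- c(1, 0, 0) - et[1] * et
      f <- fa / sqrt(sum(fa^2))
      helix[e] <- 90
    } else {
      ec <- ec_raw / nc_
      el_ <- .cross3(et, ec)
      f <- cos(alpha) * ec + sin(alpha) * el_
      helix[e] <- alpha * 180 / pi
    }
    s <- et - sum(et * f) * f
    s <- s / sqrt(sum(s^2))
    f0[e, ] <- f
    s0[e, ] <- s
    n0[e, ] <- .cross3(f, s)
  }
  if (n_fallback > 0L) {
    message("assign_fibers: long-axis fallback frame at ", n_fallback,
            " degenerate apex element(s)")
  }
  mesh$fibers <- list(f0 = f0, s0 = s0, n0 = n0, helix = helix,
                      transmural = te, n_fallback = n_fallback)
  mesh
}
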