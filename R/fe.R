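# ---------------------------------------------------------------------------
# Quasi-static nonlinear finite elements (total Lagrangian).
#
# Displacement-based tetrahedra (linear: 1 integration point, the element
# barycenter, one growth internal variable per element; quadratic: 4 points)
# with the quasi-incompressible Fung material and closed-form growth-tensor
# inverses evaluated in a batched loop over all integration points. The
# penalty formulation is displacement-only; quadratic elements are the
# accurate choice near incompressibility, linear elements match the
# one-internal-variable-per-element bookkeeping of coarse clinical meshes.
#
# The global tangent is assembled from element-level central differences of
# the internal force (relative perturbation 1e-7) plus facet-level
# differences of the follower pressure load. Central differences keep the
# tangent error far below the soft shear stiffness even though the penalty
# (volumetric) stiffness is ~1000x larger, preserving quadratic-like Newton
# convergence; forward differences were measurably too inaccurate for that
# stiffness contrast.
# ---------------------------------------------------------------------------

#' Solver settings
#'
#' @param newton_tol relative residual norm for convergence.
#' @param newton_max_iter maximum Newton iterations per load level.
#' @param ramp non-decreasing load fractions ending at 1 (both pressures and
#'   prescribed displacements are scaled).
#' @param max_halvings maximum times a failed load increment is halved.
#' @param fd_h relative perturbation of the finite-difference tangents.
#' @return Object of class `"solver_settings"`.
#' @export
solver_settings <- function(newton_tol = 1e-9, newton_max_iter = 60L,
                            ramp = c(0.25, 0.5, 0.75, 1), max_halvings = 6L,
                            fd_h = 1e-7) {
  if (newton_tol <= 0) stop("solver error: newton_tol must be > 0")
  if (is.unsorted(ramp) || any(ramp <= 0) || abs(ramp[length(ramp)] - 1) > 0) {
    stop("solver error: ramp must be non-decreasing positive fractions ending at 1")
  }
  structure(list(newton_tol = newton_tol,
                 newton_max_iter = as.integer(newton_max_iter),
                 ramp = ramp, max_halvings = as.integer(max_halvings),
                 fd_h = fd_h), class = "solver_settings")
}

#' Precompute the finite-element discretization
#'
#' Builds per-integration-point referential shape-function gradients,
#' quadrature weights, element dof maps, batched fiber frames and facet data
#' for a fibered mesh. Must be called after [assign_fibers()].
#'
#' @param mesh a `"ventricular_mesh"` with fibers assigned.
#' @return Object of class `"fe_model"`.
#' @export
fe_discretize <- function(mesh) {
  if (is.null(mesh$fibers)) stop("fe error: call assign_fibers() first")
  validate_mesh(mesh)
  el <- mesh$elems
  m <- nrow(el)
  nn <- if (mesh$order == 1L) 4L else 10L
  qr <- tet_quadrature(mesh$order)
  nqp <- length(qr$weights)
  # affine corner Jacobian J[i,K] = dX_i/dxi_K (constant per element)
  Jb <- matrix(0, m, 9L)
  X1 <- mesh$nodes[el[, 1], , drop = FALSE]
  for (K in 1:3) {
    dX <- mesh$nodes[el[, K + 1L], , drop = FALSE] - X1
    for (i in 1:3) Jb[, bcol(i, K)] <- dX[, i]
  }
  grads <- vector("list", nqp)
  wdetJ <- vector("list", nqp)
  for (q in seq_len(nqp)) {
    dNref <- if (mesh$order == 1L) tet4_grads()
             else tet10_shape(qr$points[q, ])$dN
    if (mesh$order == 1L) {
      Jq <- Jb
    } else {
      # isoparametric: midside nodes may be curved onto the true surface,
      # so the geometry Jacobian varies over the element
      Jq <- matrix(0, m, 9L)
      for (a in seq_len(nn)) {
        xa <- mesh$nodes[el[, a], , drop = FALSE]
        for (i in 1:3) for (K in 1:3) {
          Jq[, bcol(i, K)] <- Jq[, bcol(i, K)] + xa[, i] * dNref[a, K]
        }
      }
    }
    detJq <- bdet(Jq)
    if (any(detJq <= 0)) stop("fe error: non-positive Jacobian at quadrature point")
    Jinvq <- binv(Jq, detJq)
    G <- matrix(0, m, 3L * nn)
    for (a in seq_len(nn)) for (i in 1:3) {
      acc <- 0
      for (K in 1:3) acc <- acc + dNref[a, K] * Jinvq[, bcol(K, i)]
      G[, 3L * (a - 1L) + i] <- acc
    }
    grads[[q]] <- G
    wdetJ[[q]] <- qr$weights[q] * detJq
  }
  edof <- matrix(0L, m, 3L * nn)
  for (a in seq_len(nn)) for (i in 1:3) {
    edof[, 3L * (a - 1L) + i] <- 3L * (el[, a] - 1L) + i
  }
  fib <- mesh$fibers
  Qb <- matrix(0, m, 9L)
  for (i in 1:3) {
    Qb[, bcol(i, 1L)] <- fib$f0[, i]
    Qb[, bcol(i, 2L)] <- fib$s0[, i]
    Qb[, bcol(i, 3L)] <- fib$n0[, i]
  }
  facet_data <- lapply(mesh$facets, function(f) {
    if (nrow(f) == 0L) return(NULL)
    fn <- ncol(f)
    fdof <- matrix(0L, nrow(f), 3L * fn)
    for (a in seq_len(fn)) for (i in 1:3) {
      fdof[, 3L * (a - 1L) + i] <- 3L * (f[, a] - 1L) + i
    }
    list(nodes = f, dofs = fdof, n_nodes = fn)
  })
  grow_mask <- mesh$region %in% c("lv_wall", "rv_wall", "septum")
  structure(list(mesh = mesh, m = m, nn = nn, nqp = nqp,
                 ndof = 3L * nrow(mesh$nodes),
                 grads = grads, wdetJ = wdetJ, edof = edof,
                 f0 = fib$f0, Qb = Qb, facet_data = facet_data,
                 grow_mask = grow_mask),
            class = "fe_model")
}

# ---------------------------------------------------------------------------
# Batched material-point evaluation at all integration points of one
# quadrature index: first Piola-Kirchhoff stress, fiber stretch, energy.
# ---------------------------------------------------------------------------
#' @keywords internal
.batch_stress <- function(Fb, theta, mode, f0, Qb, params,
                          want_sigma = FALSE) {
  m <- nrow(Fb)
  fdef <- bmv(Fb, f0)                     # deformed fiber direction F f0
  ff0 <- bouter(f0, f0)
  if (mode == "transverse") {
    Fe <- Fb / theta + ((theta - 1) / theta) * bouter(fdef, f0)
    Fgi <- (1 / theta) * bident(m) + (1 - 1 / theta) * ff0
  } else {
    Fe <- Fb + ((1 - theta) / theta) * bouter(fdef, f0)
    Fgi <- bident(m) + (1 / theta - 1) * ff0
  }
  Je <- bdet(Fe)
  if (any(!is.finite(Je)) || any(Je <= 0)) return(list(ok = FALSE))
  Ce <- bmm(bt(Fe), Fe)
  sc <- Je^(-2 / 3)
  Ebar <- 0.5 * (sc * Ce - bident(m))
  Eloc <- bmm(bt(Qb), bmm(Ebar, Qb))
  Wv <- as.numeric(params$W)
  q <- as.numeric((Eloc * Eloc) %*% Wv)
  expq <- exp(q)
  if (any(!is.finite(expq))) return(list(ok = FALSE))
  Sbar_loc <- params$C0 * expq * (Eloc * rep(Wv, each = m))
  Sbar <- bmm(Qb, bmm(Sbar_loc, bt(Qb)))
  Ceinv <- binv(Ce, Je^2)
  dU <- (Je - 1 / Je) / params$D0
  Se <- (dU * Je) * Ceinv + sc * (Sbar - (bddot(Sbar, Ce) / 3) * Ceinv)
  S <- bmm(Fgi, bmm(Se, bt(Fgi)))
  P <- bmm(Fb, S)
  lambda <- sqrt(rowSums(fdef^2))
  psi <- (Je^2 - 2 * log(Je)) / (2 * params$D0) + params$C0 / 2 * (expq - 1)
  out <- list(ok = TRUE, P = P, S = S, lambda = lambda, psi = psi, Je = Je)
  if (want_sigma) {
    Jt <- bdet(Fb)
    out$sigma <- bmm(Fb, bmm(S, bt(Fb))) / Jt
  }
  out
}

# deformation gradients at quadrature index q for all elements
#' @keywords internal
.batch_F <- function(model, Uel, q) {
  Fb <- bident(model$m)
  G <- model$grads[[q]]
  for (a in seq_len(model$nn)) for (i in 1:3) {
    ua <- Uel[, 3L * (a - 1L) + i]
    for (J in 1:3) {
      Fb[, bcol(i, J)] <- Fb[, bcol(i, J)] + ua * G[, 3L * (a - 1L) + J]
    }
  }
  Fb
}

# element internal force matrix (m x 3nn) for given element displacements
#' @keywords internal
.elem_internal <- function(model, Uel, theta, mode, params,
                           want_extras = FALSE) {
  fel <- matrix(0, model$m, 3L * model$nn)
  extras <- NULL
  if (want_extras) {
    extras <- list(lambda = matrix(0, model$m, model$nqp), psi = 0,
                   sigma = vector("list", model$nqp),
                   Je = matrix(0, model$m, model$nqp))
  }
  for (q in seq_len(model$nqp)) {
    Fb <- .batch_F(model, Uel, q)
    st <- .batch_stress(Fb, theta[, q], mode, model$f0, model$Qb, params,
                        want_sigma = want_extras)
    if (!st$ok) return(list(ok = FALSE))
    w <- model$wdetJ[[q]]
    G <- model$grads[[q]]
    for (a in seq_len(model$nn)) for (i in 1:3) {
      acc <- st$P[, bcol(i, 1L)] * G[, 3L * (a - 1L) + 1L] +
             st$P[, bcol(i, 2L)] * G[, 3L * (a - 1L) + 2L] +
             st$P[, bcol(i, 3L)] * G[, 3L * (a - 1L) + 3L]
      fel[, 3L * (a - 1L) + i] <- fel[, 3L * (a - 1L) + i] + w * acc
    }
    if (want_extras) {
      extras$lambda[, q] <- st$lambda
      extras$psi <- extras$psi + sum(w * st$psi)
      extras$sigma[[q]] <- st$sigma
      extras$Je[, q] <- st$Je
    }
  }
  list(ok = TRUE, fel = fel, extras = extras)
}

# scatter element values into a global vector
#' @keywords internal
.scatter <- function(values, dofs, ndof) {
  out <- numeric(ndof)
  s <- rowsum(as.numeric(values), as.integer(dofs))
  out[as.integer(rownames(s))] <- s
  out
}

#' Internal force vector and field diagnostics
#' @keywords internal
.internal_force <- function(model, u, theta, mode, params,
                            want_extras = FALSE) {
  Uel <- matrix(u[model$edof], model$m, 3L * model$nn)
  r <- .elem_internal(model, Uel, theta, mode, params, want_extras)
  if (!r$ok) return(list(ok = FALSE))
  list(ok = TRUE, f = .scatter(r$fel, model$edof, model$ndof),
       extras = r$extras)
}

#' Follower pressure load vector
#'
#' Integrates the cavity pressure over the deformed tagged surface along its
#' current normal (follower load): `f_a = -p * sum_q w_q N_a (g1 x g2)`,
#' with facet orientation outward from the solid. The resultant over any
#' closed surface vanishes identically.
#'
#' @param model an `"fe_model"`.
#' @param displacement nodal displacement vector.
#' @param chamber facet tag.
#' @param p pressure in kPa.
#' @return Global external force vector (length `ndof`).
#' @export
apply_pressure <- function(model, displacement, chamber, p) {
  fd <- model$facet_data[[chamber]]
  if (is.null(fd) && !chamber %in% names(model$facet_data)) {
    stop("config error: no facet tag '", chamber, "'")
  }
  if (is.null(fd)) return(numeric(model$ndof))
  x <- .deformed_nodes(model$mesh, displacement)
  .scatter(.facet_force_local(fd, .facet_coords(fd, x), p),
           fd$dofs, model$ndof)
}

# gather per-slot deformed facet coordinates
#' @keywords internal
.facet_coords <- function(fd, x) {
  lapply(seq_len(fd$n_nodes), function(a) x[fd$nodes[, a], , drop = FALSE])
}

# local facet force matrix (nfacet x 3*fn) from per-slot coordinates
#' @keywords internal
.facet_force_local <- function(fd, xs, p) {
  fn <- fd$n_nodes
  nf <- nrow(fd$nodes)
  qr <- tri_quadrature()
  fel <- matrix(0, nf, 3L * fn)
  if (p == 0) return(fel)
  for (q in seq_len(nrow(qr$points))) {
    sh <- tri_shape(qr$points[q, ], fn)
    g1 <- g2 <- matrix(0, nf, 3L)
    for (a in seq_len(fn)) {
      g1 <- g1 + sh$dN[a, 1] * xs[[a]]
      g2 <- g2 + sh$dN[a, 2] * xs[[a]]
    }
    cr <- cbind(g1[, 2] * g2[, 3] - g1[, 3] * g2[, 2],
                g1[, 3] * g2[, 1] - g1[, 1] * g2[, 3],
                g1[, 1] * g2[, 2] - g1[, 2] * g2[, 1])
    for (a in seq_len(fn)) for (i in 1:3) {
      fel[, 3L * (a - 1L) + i] <- fel[, 3L * (a - 1L) + i] -
        p * qr$weights[q] * sh$N[a] * cr[, i]
    }
  }
  fel
}

# facet-level central-difference tangent of the follower pressure load
# (exact up to roundoff: the facet force is quadratic in the coordinates);
# returns triplets of d f_ext / d u
#' @keywords internal
.pressure_tangent_triplets <- function(model, u, pressures, h) {
  ti <- tj <- tx <- list()
  n <- 0L
  x0 <- .deformed_nodes(model$mesh, u)
  for (tag in names(pressures)) {
    p <- pressures[[tag]]
    fd <- model$facet_data[[tag]]
    if (is.null(fd) || p == 0) next
    xs0 <- .facet_coords(fd, x0)
    fn <- fd$n_nodes
    for (d in seq_len(3L * fn)) {
      a <- (d - 1L) %/% 3L + 1L
      i <- (d - 1L) %% 3L + 1L
      xs <- xs0
      xs[[a]][, i] <- xs[[a]][, i] + h
      fp <- .facet_force_local(fd, xs, p)
      xs[[a]][, i] <- xs[[a]][, i] - 2 * h
      fm <- .facet_force_local(fd, xs, p)
      Kcol <- (fp - fm) / (2 * h)
      n <- n + 1L
      ti[[n]] <- as.integer(fd$dofs)
      tj[[n]] <- rep(fd$dofs[, d], times = 3L * fn)
      tx[[n]] <- as.numeric(Kcol)
    }
  }
  list(i = as.integer(unlist(ti)), j = as.integer(unlist(tj)),
       x = as.numeric(unlist(tx)))
}

#' Assemble the residual and consistent tangent
#'
#' Residual = internal force - follower pressure force; tangent by
#' element-level central differences of the internal force plus facet-level
#' differences of the pressure load. Dirichlet handling is performed by the
#' caller through row/column reduction.
#'
#' @param model an `"fe_model"`.
#' @param u nodal displacement vector.
#' @param theta growth multipliers, `m x nqp` matrix.
#' @param mode growth mode.
#' @param params `"material_parameters"`.
#' @param pressures named list of chamber pressures (kPa).
#' @param want_tangent assemble the sparse tangent matrix as well.
#' @param fd_h relative finite-difference perturbation.
#' @return List with `ok`, `R` (residual), `fext`, and optionally `K`
#'   (a `dgCMatrix`).
#' @export
assemble <- function(model, u, theta, mode, params, pressures = list(),
                     want_tangent = TRUE, fd_h = 1e-7) {
  Uel <- matrix(u[model$edof], model$m, 3L * model$nn)
  base <- .elem_internal(model, Uel, theta, mode, params)
  if (!base$ok) return(list(ok = FALSE))
  fint <- .scatter(base$fel, model$edof, model$ndof)
  fext <- numeric(model$ndof)
  for (tag in names(pressures)) {
    fext <- fext + apply_pressure(model, u, tag, pressures[[tag]])
  }
  out <- list(ok = TRUE, R = fint - fext, fext = fext, fint = fint)
  if (!want_tangent) return(out)
  h <- fd_h * (1 + max(abs(u)))
  ncols <- 3L * model$nn
  nent <- model$m * ncols * ncols
  ti <- integer(nent); tj <- integer(nent); tx <- numeric(nent)
  pos <- 0L
  for (d in seq_len(ncols)) {
    Up <- Uel
    Up[, d] <- Up[, d] + h
    pert_p <- .elem_internal(model, Up, theta, mode, params)
    Up[, d] <- Up[, d] - 2 * h
    pert_m <- .elem_internal(model, Up, theta, mode, params)
    if (!pert_p$ok || !pert_m$ok) return(list(ok = FALSE))
    Kd <- (pert_p$fel - pert_m$fel) / (2 * h)
    block <- model$m * ncols
    rng <- pos + seq_len(block)
    ti[rng] <- as.integer(model$edof)
    tj[rng] <- rep(model$edof[, d], times = ncols)
    tx[rng] <- as.numeric(Kd)
    pos <- pos + block
  }
  pt <- .pressure_tangent_triplets(model, u, pressures, h)
  K <- Matrix::sparseMatrix(i = c(ti, pt$i), j = c(tj, pt$j),
                            x = c(tx, -pt$x),
                            dims = c(model$ndof, model$ndof))
  out$K <- K
  out
}

#' Dirichlet boundary conditions from mesh node sets
#'
#' `"clamped_ring"` (idealized-LV default): basal-plane nodes fixed along
#' the long axis, epicardial basal-ring nodes additionally fixed in-plane.
#' `"symmetry_pins"`: basal-plane nodes fixed along the long axis plus three
#' in-plane pins on the basal ring that are compatible with any radially
#' symmetric deformation (used for spherical-shell benchmarks).
#'
#' @param mesh a `"ventricular_mesh"`.
#' @param mode constraint mode.
#' @return List with `dofs` (constrained dof indices) and `values`
#'   (prescribed values, zeros).
#' @export
dirichlet_bc <- function(mesh, mode = c("clamped_ring", "symmetry_pins")) {
  mode <- match.arg(mode)
  zset <- mesh$node_sets$base_plane
  dofs <- 3L * (zset - 1L) + 3L   # long-axis (z) components
  if (mode == "clamped_ring") {
    ring <- mesh$node_sets$fixed
    dofs <- c(dofs, 3L * (ring - 1L) + 1L, 3L * (ring - 1L) + 2L)
  } else {
    ring <- mesh$node_sets$basal_ring
    rx <- mesh$nodes[ring, , drop = FALSE]
    pick <- function(dir) ring[which.max(rx %*% dir)]
    npx <- pick(c(1, 0, 0)); nmx <- pick(c(-1, 0, 0)); npy <- pick(c(0, 1, 0))
    dofs <- c(dofs,
              3L * (npx - 1L) + 2L,  # u_y = 0 on +x node
              3L * (nmx - 1L) + 2L,  # u_y = 0 on -x node
              3L * (npy - 1L) + 1L)  # u_x = 0 on +y node
  }
  dofs <- sort(unique(dofs))
  list(dofs = dofs, values = numeric(length(dofs)))
}

# Newton iteration at one fixed load level. Full Newton steps with
# overflow backtracking: a step that produces an inverted element or a
# non-finite residual is halved (up to 6 times) before the level is
# declared failed. Returns list(ok, u, iters, hist).
#' @keywords internal
.newton_level <- function(model, u, theta, mode, params, pressures, bc,
                          settings) {
  u[bc$dofs] <- bc$values
  free <- setdiff(seq_len(model$ndof), bc$dofs)
  asm <- assemble(model, u, theta, mode, params, pressures,
                  want_tangent = FALSE)
  # norms of huge (but finite) residual entries can overflow; any
  # non-finite norm marks the evaluation as failed
  bad <- function(a) {
    !a$ok || !all(is.finite(a$R)) || !is.finite(sqrt(sum(a$R^2)))
  }
  if (bad(asm)) return(list(ok = FALSE, u = u, iters = 0L, hist = numeric(0)))
  resnorm <- function(a) sqrt(sum(a$R[free]^2))
  refnorm <- function(a) {
    max(sqrt(sum(a$fext[free]^2)), sqrt(sum(a$fint^2)), 1e-10)
  }
  rn <- resnorm(asm)
  hist <- rn
  n_stall <- 0L
  for (iter in seq_len(settings$newton_max_iter)) {
    ref <- refnorm(asm)
    if (is.finite(rn) && is.finite(ref) && rn <= settings$newton_tol * ref) {
      return(list(ok = TRUE, u = u, iters = iter - 1L, hist = hist))
    }
    asmK <- assemble(model, u, theta, mode, params, pressures,
                     want_tangent = TRUE, fd_h = settings$fd_h)
    if (!asmK$ok) return(list(ok = FALSE, u = u, iters = iter, hist = hist))
    du <- .solve_newton_system(asmK$K[free, free, drop = FALSE],
                               -asmK$R[free])
    if (is.null(du) || any(!is.finite(du))) {
      return(list(ok = FALSE, u = u, iters = iter, hist = hist))
    }
    # damped Newton: try the full step first, halving while it inverts
    # elements, overflows, or fails to decrease the residual; keep the best
    # finite evaluation. Occasional residual growth is tolerated (Newton on
    # strongly stiffening materials is not monotone), but several
    # non-decreasing iterations in a row abort the level.
    alpha <- 1
    best <- NULL
    for (ls in 1:7) {
      u_try <- u
      u_try[free] <- u[free] + alpha * du
      asm_try <- assemble(model, u_try, theta, mode, params, pressures,
                          want_tangent = FALSE)
      if (!bad(asm_try)) {
        rn_try <- resnorm(asm_try)
        if (is.null(best) || rn_try < best$rn) {
          best <- list(u = u_try, asm = asm_try, rn = rn_try)
        }
        if (rn_try < rn) break
      }
      alpha <- alpha / 2
    }
    if (is.null(best)) {
      return(list(ok = FALSE, u = u, iters = iter, hist = hist))
    }
    n_stall <- if (best$rn >= rn) n_stall + 1L else 0L
    if (n_stall >= 4L) {
      return(list(ok = FALSE, u = u, iters = iter, hist = hist))
    }
    # creeping progress (< 10% reduction over eight iterations) will not
    # reach the tolerance within the budget; bail out so the caller can cut
    # the load increment or restart instead
    nh <- length(hist)
    if (nh >= 9L && best$rn > 0.9 * hist[nh - 8L]) {
      return(list(ok = FALSE, u = best$u, iters = iter, hist = hist))
    }
    u <- best$u
    asm <- best$asm
    rn <- best$rn
    hist <- c(hist, rn)
  }
  ref <- refnorm(asm)
  ok <- is.finite(rn) && is.finite(ref) && rn <= settings$newton_tol * ref
  list(ok = ok, u = u, iters = settings$newton_max_iter, hist = hist)
}

#' Quasi-static Newton solve
#'
#' Solves equilibrium at the full load: a direct Newton attempt when
#' resuming from a nearby equilibrium, otherwise (or on failure) a load
#' ramp through the configured fractions with adaptive halving of failed
#' increments. The calibrated myocardium is extremely soft at low strain,
#' so from-zero solves genuinely need many small early increments.
#'
#' @param model an `"fe_model"`.
#' @param state a field state as returned by [fe_state()] (or `NULL` for
#'   zero initial displacement).
#' @param params `"material_parameters"`.
#' @param loads list with `pressures` (named list, kPa, at full load) and
#'   optionally `bc` (list of `dofs`, `values`) at full load; defaults to
#'   the mesh's clamped-ring conditions.
#' @param settings a [solver_settings()].
#' @return Updated `"fe_state"` with convergence history.
#' @export
newton_solve <- function(model, state = NULL, params, loads,
                         settings = solver_settings()) {
  state <- state %||% fe_state(model)
  bc_full <- loads$bc %||% dirichlet_bc(model$mesh)
  pressures_full <- loads$pressures %||% list()
  th <- state$growth$theta
  mode <- state$growth$mode

  # direct attempt first when resuming from a nearby equilibrium
  if (any(state$u != 0)) {
    res <- .newton_level(model, state$u, th, mode, params, pressures_full,
                         bc_full, settings)
    if (res$ok) {
      state$u <- res$u
      state$converged <- TRUE
      state$log <- list(list(fraction = 1, iters = res$iters,
                             residuals = res$hist))
      return(state)
    }
  }

  # load ramp from zero with adaptive halving
  u <- state$u
  log <- list()
  f_done <- 0
  targets <- settings$ramp
  min_df <- min(diff(c(0, targets))) / 2^settings$max_halvings
  k <- 1L
  while (f_done < 1 - 1e-12) {
    f_try <- if (k <= length(targets)) targets[k] else 1
    f_try <- min(max(f_try, f_done + min_df), 1)
    repeat {
      bc <- list(dofs = bc_full$dofs, values = bc_full$values * f_try)
      prs <- lapply(pressures_full, function(p) p * f_try)
      res <- .newton_level(model, u, th, mode, params, prs, bc, settings)
      if (res$ok) break
      df <- (f_try - f_done) / 2
      if (df < min_df) {
        stop("solver failure: Newton did not converge at load fraction ",
             signif(f_try, 4), " (residual history: ",
             paste(signif(res$hist, 3), collapse = ", "), ")")
      }
      f_try <- f_done + df
    }
    u <- res$u
    log[[length(log) + 1L]] <- list(fraction = f_try, iters = res$iters,
                                    residuals = res$hist)
    f_done <- f_try
    while (k <= length(targets) && targets[k] <= f_done + 1e-12) k <- k + 1L
  }
  state$u <- u
  state$converged <- TRUE
  state$log <- log
  state
}

#' Continuation solve between two pressure levels
#'
#' Warm-started Newton continuation from the current displacement: the
#' chamber pressures are moved from `p_from` to `p_to` in one step, and the
#' increment is bisected adaptively whenever Newton fails, down to 1/64 of
#' the interval. Robust for loading, unloading and probe sweeps where the
#' start state is already in equilibrium nearby.
#'
#' @param model an `"fe_model"`.
#' @param state an `"fe_state"` in equilibrium at `p_from`.
#' @param params material parameters.
#' @param p_from,p_to named lists of chamber pressures (kPa).
#' @param bc Dirichlet conditions.
#' @param settings solver settings.
#' @return The state in equilibrium at `p_to`.
#' @export
pressure_continuation <- function(model, state, params, p_from, p_to, bc,
                                  settings = solver_settings()) {
  tags <- union(names(p_from), names(p_to))
  at <- function(s) {
    prs <- lapply(tags, function(tg) {
      a <- p_from[[tg]] %||% 0
      b <- p_to[[tg]] %||% 0
      a + s * (b - a)
    })
    names(prs) <- tags
    prs
  }
  u <- state$u
  th <- state$growth$theta
  s_done <- 0
  log <- list()
  while (s_done < 1 - 1e-12) {
    ds <- 1 - s_done
    repeat {
      res <- .newton_level(model, u, th, state$growth$mode, params,
                           at(s_done + ds), bc, settings)
      if (res$ok) break
      ds <- ds / 2
      if (ds < 1 / 64) {
        # deflation (and other stiff transitions) can pass a limit point of
        # the warm-started path even though the target state is benign:
        # restart at the full target from a rescaled displacement
        for (beta in c(0.5, 0.25, 0.1, 0)) {
          u_try <- u * beta
          res <- .newton_level(model, u_try, th, state$growth$mode, params,
                               at(1), bc, settings)
          if (res$ok) break
        }
        if (!res$ok) {
          # last resort: full load ramp from zero displacement at the target
          st0 <- state
          st0$u <- numeric(model$ndof)
          st1 <- tryCatch(
            newton_solve(model, st0, params,
                         list(pressures = at(1), bc = bc), settings),
            error = function(e) NULL)
          if (!is.null(st1)) res <- list(ok = TRUE, u = st1$u, iters = NA,
                                         hist = numeric(0))
        }
        if (res$ok) {
          ds <- 1 - s_done
          break
        }
        stop("solver failure: pressure continuation stalled at s = ",
             signif(s_done, 4), " (residuals: ",
             paste(signif(res$hist, 3), collapse = ", "), ")")
      }
    }
    u <- res$u
    s_done <- s_done + ds
    log[[length(log) + 1L]] <- list(fraction = s_done, iters = res$iters,
                                    residuals = res$hist)
  }
  state$u <- u
  state$converged <- TRUE
  state$log <- log
  state
}

#' Create an empty field state
#'
#' @param model an `"fe_model"`.
#' @param mode growth mode.
#' @param tau growth time constant (normalized time).
#' @param theta_max optional growth cap.
#' @return Object of class `"fe_state"`: nodal displacements (zero), one
#'   growth multiplier and homeostatic threshold per integration point.
#' @export
fe_state <- function(model, mode = c("transverse", "longitudinal"),
                     tau = 1, theta_max = Inf) {
  mode <- match.arg(mode)
  structure(list(
    u = numeric(model$ndof),
    growth = list(theta = matrix(1, model$m, model$nqp), mode = mode,
                  lambda_crit = matrix(1, model$m, model$nqp),
                  tau = tau, theta_max = theta_max),
    converged = FALSE, log = NULL), class = "fe_state")
}

#' Fiber stretch field at the current displacement
#'
#' @param model an `"fe_model"`.
#' @param u nodal displacement vector.
#' @return `m x nqp` matrix of total fiber stretches.
#' @export
fiber_stretch_field <- function(model, u) {
  Uel <- matrix(u[model$edof], model$m, 3L * model$nn)
  lam <- matrix(0, model$m, model$nqp)
  for (q in seq_len(model$nqp)) {
    Fb <- .batch_F(model, Uel, q)
    lam[, q] <- sqrt(rowSums(bmv(Fb, model$f0)^2))
  }
  lam
}

#' Total strain energy of the current state
#' @param model an `"fe_model"`.
#' @param state an `"fe_state"`.
#' @param params material parameters.
#' @return Strain energy in kPa mm^3 (nJ).
#' @export
total_strain_energy <- function(model, state, params) {
  r <- .internal_force(model, state$u, state$growth$theta,
                       state$growth$mode, params, want_extras = TRUE)
  if (!r$ok) stop("inverted-element during energy evaluation")
  r$extras$psi
}

#' One staggered equilibrium/growth step
#'
#' Freezes the growth field, solves equilibrium at constant load, evaluates
#' the total fiber stretch per integration point, and explicitly updates the
#' growth multiplier where the region mask allows growth. The chamber
#' pressure is held at its maximum during the growth phase.
#'
#' @param model an `"fe_model"`.
#' @param state an `"fe_state"`.
#' @param params material parameters.
#' @param loads load specification (see [newton_solve()]).
#' @param settings solver settings.
#' @param dt growth time increment (normalized time).
#' @return The updated state, with attributes `max_dtheta` and `max_excess`.
#' @export
staggered_growth_step <- function(model, state, params, loads,
                                  settings = solver_settings(), dt = 0.1) {
  # equilibrium at frozen theta, no ramp (continue from current u)
  bc <- loads$bc %||% dirichlet_bc(model$mesh)
  prs <- loads$pressures %||% list()
  res <- .newton_level(model, state$u, state$growth$theta,
                       state$growth$mode, params, prs, bc, settings)
  if (!res$ok) {
    stop("solver failure during staggered growth step (residuals: ",
         paste(signif(res$hist, 3), collapse = ", "), ")")
  }
  state$u <- res$u
  lam <- fiber_stretch_field(model, state$u)
  g <- state$growth
  gs <- growth_state(g$mode, lambda_crit = g$lambda_crit, theta = g$theta,
                     tau = g$tau, theta_max = g$theta_max)
  th_new <- update_growth(g$theta, lam, gs, dt)
  th_new[!model$grow_mask, ] <- g$theta[!model$grow_mask, ]
  excess <- pmax(lam - g$lambda_crit, 0)
  excess[!model$grow_mask, ] <- 0
  state$growth$theta <- th_new
  attr(state, "max_dtheta") <- max(th_new - g$theta)
  attr(state, "max_excess") <- max(excess)
  attr(state, "lambda") <- lam
  state
}

# Linear solve of the Newton system. The tangent is symmetric up to the
# (small) follower-load asymmetry, so the cheap route is a CHOLMOD LDL
# factorization of the symmetrized matrix -- an inexact Newton step with a
# contraction factor around the relative asymmetry (~1e-1 at high cavity
# pressure, far less elsewhere). Falls back to unsymmetric sparse LU when
# the factorization fails.
#' @keywords internal
.solve_newton_system <- function(K, b) {
  bn <- sqrt(sum(b^2))
  # small systems: exact unsymmetric sparse LU is cheap and restores
  # quadratic convergence (the symmetrized LDL step is only worth its
  # factorization speed on large systems)
  if (nrow(K) < 1500L) {
    du <- tryCatch(as.numeric(Matrix::solve(K, b)), error = function(e) NULL)
    return(du)
  }
  du <- tryCatch({
    Ks <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
    ch <- suppressWarnings(Matrix::Cholesky(Ks, LDL = TRUE, super = FALSE))
    x <- as.numeric(Matrix::solve(ch, b))
    # unpivoted LDL can silently lose accuracy on indefinite tangents
    ok <- all(is.finite(x)) &&
      sqrt(sum((as.numeric(Ks %*% x) - b)^2)) <= 1e-8 * max(bn, 1e-300)
    if (ok) x else NULL
  }, error = function(e) NULL)
  if (is.null(du) || any(!is.finite(du))) {
    du <- tryCatch(as.numeric(Matrix::solve(K, b)),
                   error = function(e) NULL)
  }
  du
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
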