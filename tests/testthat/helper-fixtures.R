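# Shared fixtures: random admissible tensors, frames, small meshes, and a
# cache so expensive objects are built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# random deformation gradient with det > 0, moderate strain
random_F <- function(scale = 0.15) {
  repeat {
    F <- diag(3) + scale * matrix(stats::rnorm(9), 3, 3)
    if (tensor_det(F) > 0.3) return(F)
  }
}

# uniform random rotation (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

random_frame <- function() {
  f0 <- random_unit()
  fiber_frame(f0)
}

default_params <- function() material_parameters()

# replace rule-based fibers by one uniform frame (homogeneous material)
uniform_fibers <- function(mesh, f0 = c(1, 0, 0), s0 = c(0, 1, 0)) {
  m <- nrow(mesh$elems)
  fr <- fiber_frame(f0, s0)
  mesh$fibers <- list(f0 = matrix(fr$f0, m, 3, byrow = TRUE),
                      s0 = matrix(fr$s0, m, 3, byrow = TRUE),
                      n0 = matrix(fr$n0, m, 3, byrow = TRUE),
                      helix = rep(0, m), transmural = rep(0.5, m),
                      n_fallback = 0L)
  mesh
}

# small box model with uniform fibers, all-component clamp on zmin
box_model <- function(order = 1L, n = 2L) {
  cached(paste0("box_model_", order, "_", n), {
    mesh <- uniform_fibers(make_box_mesh(n, n, n, 2, 2, 2, order = order))
    fe_discretize(mesh)
  })
}

# single positively oriented tetrahedron with uniform fibers
single_tet_model <- function() {
  cached("single_tet", {
    mesh <- make_box_mesh(1, 1, 1, 1, 1, 1)
    mesh$elems <- mesh$elems[1, , drop = FALSE]
    mesh$region <- "lv_wall"
    mesh$facets <- list()
    mesh <- uniform_fibers(mesh)
    fe_discretize(mesh)
  })
}

all_boundary_bc <- function(mesh, values_fun) {
  bnodes <- sort(unique(as.vector(mesh$facets$boundary)))
  dofs <- sort(c(3 * (bnodes - 1) + 1, 3 * (bnodes - 1) + 2,
                 3 * (bnodes - 1) + 3))
  vals <- values_fun(mesh$nodes)
  list(dofs = dofs, values = vals[dofs])
}

# nodal displacement vector for an affine map u = A x
affine_u <- function(nodes, A) as.numeric(t(nodes %*% t(A)))

# tiny LV scenario configuration used in smoke/determinism tests
# Protocol/machinery tests do not depend on the physiological stiffness;
# a firmer wall and milder penalty keep the coarse shell well conditioned
# and the solves fast. Physiological parameters are exercised by the
# constitutive tests and the acceptance scenarios.
tiny_scenario <- function(...) {
  args <- utils::modifyList(list(
    geometry = lv_geometry_params(nc = 8, nl = 4, nt = 1),
    material = material_parameters(C0 = 2, D0 = 0.01),
    mode = "transverse", dt = 0.1, n_steps = 2,
    probe_pressures = c(2.5, 5),
    settings = solver_settings(newton_tol = 1e-9, ramp = c(0.5, 1))), list(...))
  do.call(scenario_config, args)
}
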