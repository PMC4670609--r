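# Synthetic LV geometry, fiber rules, and geometric diagnostics.

test_that("geometry parameters are validated", {
  expect_error(lv_geometry_params(a_endo = -1), "geometry error")
  expect_error(lv_geometry_params(t_eq = 25, b_endo = 22), "geometry error")
  expect_error(lv_geometry_params(trunc = 1), "geometry error")
})

test_that("generated meshes satisfy the solver invariants", {
  mesh <- cached("lv_coarse", make_ellipsoid_lv(lv_geometry_params(nc = 12, nl = 6, nt = 2)))
  expect_true(validate_mesh(mesh))
  expect_true(all(element_volumes(mesh) > 0))
  expect_gt(nrow(mesh$facets$endocardium_lv), 0)
  expect_gt(nrow(mesh$facets$base), 0)

  # closed boundary surface: Euler characteristic V - E + F = 2
  bf <- do.call(rbind, mesh$facets)
  V <- length(unique(as.vector(bf)))
  ed <- rbind(bf[, 1:2], bf[, 2:3], bf[, c(3, 1)])
  E <- nrow(unique(t(apply(ed, 1, sort))))
  expect_equal(V - E + nrow(bf), 2)
})

test_that("spherical degenerate wall volume matches the analytic shell", {
  r <- 20; t <- 8; f <- 0.4
  mesh <- make_ellipsoid_lv(lv_geometry_params(
    a_endo = r, b_endo = r, t_eq = t, t_apex = t, trunc = f,
    nc = 24, nl = 12, nt = 3))
  # exact truncated-shell volume: cap integral per radius
  vcap <- function(R, zb) pi * (R^2 * zb - zb^3 / 3 + 2 * R^3 / 3)
  zb <- f * r
  v_exact <- (vcap(r + t, zb) - vcap(r, zb)) / 1000
  expect_lt(abs(wall_volume(mesh) - v_exact) / v_exact, 0.02)
})

test_that("halving the target edge length scales the element count by ~8", {
  # wall thick enough that the transmural count also scales with edge length
  n1 <- nrow(make_ellipsoid_lv(lv_geometry_params(t_eq = 16, edge_length = 8))$elems)
  n2 <- nrow(make_ellipsoid_lv(lv_geometry_params(t_eq = 16, edge_length = 4))$elems)
  expect_gte(n2 / n1, 6)
  expect_lte(n2 / n1, 10)
})

test_that("chamber volume reproduces the analytic sphere", {
  # nearly-complete sphere of cavity radius 20 mm: 33.51 mL
  mesh <- make_ellipsoid_lv(lv_geometry_params(
    a_endo = 20, b_endo = 20, t_eq = 6, t_apex = 6, trunc = 0.98,
    nc = 24, nl = 20, nt = 2), order = 2)
  v <- chamber_volume(mesh)
  expect_lt(abs(v - 33.51) / 33.51, 0.01)

  # uniform inflation: scaling all coordinates by 1.1 scales volume by 1.331
  u <- 0.1 * as.numeric(t(mesh$nodes))
  expect_equal(chamber_volume(mesh, u) / v, 1.331, tolerance = 1e-6)
  # determinism
  expect_identical(chamber_volume(mesh), chamber_volume(mesh))
})

test_that("wall volume tracks deformed element Jacobians", {
  model <- single_tet_model()
  mesh <- model$mesh
  expect_equal(wall_volume(mesh), wall_volume(mesh, numeric(model$ndof)))
  # uniform Jg = 1.21 stress-free grown state: volume ratio exactly 1.21
  A <- diag(c(0.1, 0.1, 0)) + diag(3)
  A <- A / 1  # F = diag(1.1, 1.1, 1), det = 1.21
  u <- affine_u(mesh$nodes, A - diag(3))
  expect_equal(wall_volume(mesh, u) / wall_volume(mesh), 1.21,
               tolerance = 1e-10)

  # additivity over a region partition
  mesh2 <- cached("lv_coarse", make_ellipsoid_lv(lv_geometry_params(nc = 12, nl = 6, nt = 2)))
  mesh2$region <- rep(c("a", "b"), length.out = nrow(mesh2$elems))
  expect_equal(wall_volume(mesh2, region = "a") + wall_volume(mesh2, region = "b"),
               wall_volume(mesh2), tolerance = 1e-10)
})

test_that("basal ring perimeter approximates the analytic circumference", {
  r <- 22; f <- 0.5
  mesh <- make_ellipsoid_lv(lv_geometry_params(
    a_endo = 40, b_endo = r, t_eq = 8, t_apex = 6, trunc = f,
    nc = 50, nl = 6, nt = 2), order = 2)
  # endocardial ring radius at the truncation plane
  rho <- r * sqrt(1 - (f * 40)^2 / 40^2)
  per <- basal_ring_perimeter(mesh)
  expect_lt(abs(per - 2 * pi * rho) / (2 * pi * rho), 0.005)
  # rigid translation leaves the perimeter unchanged; scaling scales it
  u_t <- rep(c(3, -2, 5), nrow(mesh$nodes))
  expect_equal(basal_ring_perimeter(mesh, u_t), per, tolerance = 1e-12)
  u_s <- 0.25 * as.numeric(t(mesh$nodes))
  expect_equal(basal_ring_perimeter(mesh, u_s), 1.25 * per, tolerance = 1e-12)
  # unordered ring is rejected
  mesh_bad <- mesh
  attr(mesh_bad$node_sets$basal_ring, "ordered") <- NULL
  expect_error(basal_ring_perimeter(mesh_bad), "diagnostic error")
})

test_that("fiber rule produces orthonormal, transmurally rotating frames", {
  p <- lv_geometry_params(nc = 16, nl = 8, nt = 1)
  mesh0 <- make_ellipsoid_lv(p)
  # zero helix angles: fibers circumferential away from the apex
  suppressMessages(m0 <- assign_fibers(mesh0, fiber_rule_params(0, 0)))
  apex_z <- -(p$a_endo + p$t_apex) + 6
  away <- sapply(seq_len(nrow(m0$elems)), function(e) {
    mean(m0$nodes[m0$elems[e, 1:4], 3]) > apex_z
  })
  expect_lt(max(abs(m0$fibers$f0[away, 3])), 1e-6)

  # +60/-60: midwall elements interpolate to ~0 degrees
  suppressMessages(m1 <- assign_fibers(mesh0, fiber_rule_params(60, -60)))
  mid <- abs(m1$fibers$transmural - 0.5) < 1e-9 &
    seq_len(nrow(m1$elems)) %in% which(away)
  expect_true(any(mid))
  expect_lt(max(abs(m1$fibers$helix[mid])), 2)

  # orthonormality everywhere
  fb <- m1$fibers
  for (pair in list(c("f0", "s0"), c("f0", "n0"), c("s0", "n0"))) {
    expect_lt(max(abs(rowSums(fb[[pair[1]]] * fb[[pair[2]]]))), 1e-10)
  }
  for (v in c("f0", "s0", "n0")) {
    expect_lt(max(abs(sqrt(rowSums(fb[[v]]^2)) - 1)), 1e-10)
  }

  expect_error(fiber_rule_params(120, 0), "parameter error")
})

test_that("fiber field is continuous across faces at default refinement", {
  mesh <- suppressMessages(assign_fibers(make_ellipsoid_lv(lv_geometry_params())))
  el <- mesh$elems
  fb <- mesh$fibers
  loc <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  fmap <- new.env(parent = emptyenv())
  worst_layer <- 0
  worst_trans <- 0
  for (e in seq_len(nrow(el))) for (r in 1:4) {
    k <- paste(sort(el[e, loc[r, ]]), collapse = "_")
    other <- fmap[[k]]
    if (is.null(other)) {
      fmap[[k]] <- e
    } else {
      ang <- acos(pmin(1, abs(sum(fb$f0[e, ] * fb$f0[other, ])))) * 180 / pi
      if (abs(fb$transmural[e] - fb$transmural[other]) < 1e-9) {
        worst_layer <- max(worst_layer, ang)
      } else {
        worst_trans <- max(worst_trans, ang)
      }
    }
  }
  expect_lt(worst_layer, 15)
  # transmural neighbors differ by the helix interpolation increment
  nt <- mesh$params$nt
  expect_lt(worst_trans, 120 / (2 * nt) + 1)
})

test_that("bi-ventricular generation and septal diagnostics are unsupported", {
  expect_error(make_biventricular(list()), "not implemented")
  mesh <- cached("lv_coarse", make_ellipsoid_lv(lv_geometry_params(nc = 12, nl = 6, nt = 2)))
  expect_error(septal_curvature_sign(mesh), "no septum")
})

test_that("MSH v4.1 round trip preserves the mesh and its tags", {
  mesh <- assign_fibers(make_ellipsoid_lv(lv_geometry_params(nc = 10, nl = 5, nt = 2)))
  path <- withr::local_tempfile(fileext = ".msh")
  write_msh(mesh, path)
  back <- read_msh(path)
  expect_equal(back$nodes, mesh$nodes, tolerance = 1e-12)
  expect_equal(back$elems, mesh$elems)
  expect_equal(back$region, mesh$region)
  for (tag in names(mesh$facets)) {
    a <- apply(mesh$facets[[tag]], 1, function(r) paste(sort(r), collapse = "_"))
    b <- apply(back$facets[[tag]], 1, function(r) paste(sort(r), collapse = "_"))
    expect_setequal(a, b)
  }
  # reconstructed basal ring is the closed boundary loop of the endo patch
  expect_setequal(back$node_sets$basal_ring, mesh$node_sets$basal_ring)
  # a re-read mesh supports the solver pipeline
  expect_true(validate_mesh(back))
})

test_that("VTU output is well-formed XML with the right counts", {
  mesh <- cached("lv_coarse", make_ellipsoid_lv(lv_geometry_params(nc = 12, nl = 6, nt = 2)))
  path <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(mesh, path, displacement = numeric(3 * nrow(mesh$nodes)),
            cell_data = list(theta = rep(1, nrow(mesh$elems))))
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, "//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(mesh$nodes))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(mesh$elems))
})
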