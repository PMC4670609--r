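# ---------------------------------------------------------------------------
# Synthetic ventricular geometry: parameterized truncated-ellipsoid LV wall
# with tagged surfaces, rule-based helical fiber architecture, and geometric
# diagnostics (chamber volume, wall volume, basal-ring perimeter).
#
# The generator is fully deterministic: a structured (longitudinal x
# circumferential x transmural) grid of hexahedral cells is subdivided into
# tetrahedra with the Freudenthal/Kuhn pattern, which is face-consistent
# across the structured grid including the periodic circumferential seam.
# Cells touching the apex collapse into wedges (3 tets each).
# ---------------------------------------------------------------------------

#' Geometry parameters of the idealized left ventricle
#'
#' A truncated prolate ellipsoid: endocardial semi-axes `a_endo` (long,
#' along +z/-z) and `b_endo` (short), wall thickness `t_eq` at the equator
#' and `t_apex` at the apex, truncated by the flat basal plane
#' `z = trunc * a_endo`. Discretization counts are derived from the target
#' edge length unless given explicitly.
#'
#' @param a_endo,b_endo endocardial long and short semi-axes (mm).
#' @param t_eq,t_apex wall thickness at equator and apex (mm);
#'   `t_eq < b_endo`.
#' @param trunc truncation height as a fraction of `a_endo`, in `[0, 1)`;
#'   `0` gives a hemispherical domain (useful for symmetric benchmarks).
#' @param edge_length target element edge length (mm).
#' @param nc,nl,nt circumferential / longitudinal / transmural cell counts;
#'   derived from `edge_length` when `NULL`.
#' @return Object of class `"lv_geometry_params"`.
#' @export
lv_geometry_params <- function(a_endo = 45, b_endo = 22, t_eq = 10,
                               t_apex = 6, trunc = 0.4, edge_length = 6,
                               nc = NULL, nl = NULL, nt = NULL) {
  if (any(c(a_endo, b_endo, t_eq, t_apex, edge_length) <= 0)) {
    stop("geometry error: all dimensions must be positive")
  }
  if (t_eq >= b_endo) stop("geometry error: wall thickness must be < short semi-axis")
  if (trunc < 0 || trunc >= 1) stop("geometry error: trunc must be in [0, 1)")
  bm <- b_endo + t_eq / 2
  am <- a_endo + t_apex / 2
  if (is.null(nc)) nc <- max(8L, as.integer(round(2 * pi * bm / edge_length)))
  if (is.null(nl)) {
    arc <- (pi - acos(trunc)) * (am + bm) / 2
    nl <- max(4L, as.integer(round(arc / edge_length)))
  }
  if (is.null(nt)) nt <- max(2L, as.integer(round(t_eq / edge_length)))
  structure(list(a_endo = a_endo, b_endo = b_endo, t_eq = t_eq,
                 t_apex = t_apex, trunc = trunc, edge_length = edge_length,
                 nc = as.integer(nc), nl = as.integer(nl), nt = as.integer(nt)),
            class = "lv_geometry_params")
}

# Kuhn/Freudenthal subdivision: vertex-step orders of the six tetrahedra
.KUHN_PERMS <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                    c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))

# positively orient each tet (swap last two corners when needed)
.orient_tets <- function(elems, nodes) {
  v1 <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  v2 <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  v3 <- nodes[elems[, 4], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  vol6 <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  if (any(abs(vol6) < 1e-12)) stop("geometry error: degenerate tetrahedron")
  flip <- vol6 < 0
  if (any(flip)) {
    tmp <- elems[flip, 3]
    elems[flip, 3] <- elems[flip, 4]
    elems[flip, 4] <- tmp
  }
  elems
}

# boundary faces (appear in exactly one tet), oriented outward from the solid
.boundary_facets <- function(elems, nodes) {
  loc <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  m <- nrow(elems)
  faces <- matrix(0L, 4L * m, 3L)
  owner <- rep(seq_len(m), each = 4L)
  for (r in 1:4) faces[seq(r, by = 4L, length.out = m), ] <- elems[, loc[r, ]]
  skey <- apply(faces, 1L, function(f) paste(sort.int(f), collapse = "_"))
  cnt <- table(skey)
  bd <- which(cnt[skey] == 1L)
  bfaces <- faces[bd, , drop = FALSE]
  bowner <- owner[bd]
  # orient: normal away from the owning tet's centroid
  ctet <- (nodes[elems[bowner, 1], ] + nodes[elems[bowner, 2], ] +
           nodes[elems[bowner, 3], ] + nodes[elems[bowner, 4], ]) / 4
  x1 <- nodes[bfaces[, 1], , drop = FALSE]
  x2 <- nodes[bfaces[, 2], , drop = FALSE]
  x3 <- nodes[bfaces[, 3], , drop = FALSE]
  e1 <- x2 - x1; e2 <- x3 - x1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  cf <- (x1 + x2 + x3) / 3
  inward <- rowSums(nrm * (cf - ctet)) < 0
  if (any(inward)) {
    tmp <- bfaces[inward, 2]
    bfaces[inward, 2] <- bfaces[inward, 3]
    bfaces[inward, 3] <- tmp
  }
  bfaces
}

#' Generate a truncated-ellipsoid left-ventricle mesh
#'
#' Builds a watertight tagged tetrahedral wall with surface sets
#' `endocardium_lv`, `epicardium` and `base`, node sets `fixed` (epicardial
#' basal ring), `basal_ring` (ordered endocardial basal ring) and
#' `base_plane`, a per-node transmural coordinate (0 at endocardium, 1 at
#' epicardium) and the region label `lv_wall` on every element. Quadratic
#' (10-node) meshes keep midside nodes at edge midpoints.
#'
#' @param params an [lv_geometry_params()] object.
#' @param order element order: 1 (linear) or 2 (quadratic tets).
#' @return Object of class `"ventricular_mesh"`.
#' @examples
#' mesh <- make_ellipsoid_lv(lv_geometry_params(nc = 8, nl = 4, nt = 2))
#' nrow(mesh$elems)
#' @export
make_ellipsoid_lv <- function(params = lv_geometry_params(), order = 1L) {
  p <- params
  if (!inherits(p, "lv_geometry_params")) stop("geometry error: invalid params")
  nc <- p$nc; nl <- p$nl; nt <- p$nt
  zb <- p$trunc * p$a_endo
  n_reg <- (nt + 1L) * nl * nc
  id <- function(i, j, k) {
    if (i == nl) n_reg + k + 1L else k * (nl * nc) + i * nc + (j %% nc) + 1L
  }
  n_nodes <- n_reg + nt + 1L
  nodes <- matrix(0, n_nodes, 3L)
  node_k <- integer(n_nodes)
  node_i <- integer(n_nodes)
  for (k in 0:nt) {
    tk <- k / nt
    ak <- p$a_endo + p$t_apex * tk
    bk <- p$b_endo + p$t_eq * tk
    mu0 <- acos(zb / ak)
    for (i in 0:(nl - 1L)) {
      mu <- mu0 + (pi - mu0) * i / nl
      for (j in 0:(nc - 1L)) {
        nid <- id(i, j, k)
        phi <- 2 * pi * j / nc
        nodes[nid, ] <- c(bk * sin(mu) * cos(phi),
                          bk * sin(mu) * sin(phi),
                          ak * cos(mu))
        node_k[nid] <- k; node_i[nid] <- i
      }
    }
    aid <- n_reg + k + 1L
    nodes[aid, ] <- c(0, 0, -ak)
    node_k[aid] <- k; node_i[aid] <- nl
  }
  # hexahedral cells -> Kuhn tetrahedra (dimension order: i, j, k)
  steps <- diag(3L)
  elems <- vector("list", nl * nc * nt * 6L)
  ne <- 0L
  for (k in 0:(nt - 1L)) for (i in 0:(nl - 1L)) for (j in 0:(nc - 1L)) {
    vid <- function(d) id(i + d[1], j + d[2], k + d[3])
    for (perm in .KUHN_PERMS) {
      d0 <- c(0L, 0L, 0L)
      d1 <- d0 + steps[perm[1], ]
      d2 <- d1 + steps[perm[2], ]
      ids <- c(vid(d0), vid(d1), vid(d2), vid(c(1L, 1L, 1L)))
      if (length(unique(ids)) == 4L) {
        ne <- ne + 1L
        elems[[ne]] <- ids
      }
    }
  }
  elems <- do.call(rbind, elems[seq_len(ne)])
  elems <- .orient_tets(elems, nodes)

  endo_set <- which(node_k == 0L)
  epi_set <- which(node_k == nt)
  base_set <- which(node_i == 0L)
  bfaces <- .boundary_facets(elems, nodes)
  in_endo <- matrix(bfaces %in% endo_set, ncol = 3L)
  in_epi <- matrix(bfaces %in% epi_set, ncol = 3L)
  in_base <- matrix(bfaces %in% base_set, ncol = 3L)
  is_base <- rowSums(in_base) == 3L
  is_endo <- rowSums(in_endo) == 3L & !is_base
  is_epi <- rowSums(in_epi) == 3L & !is_base
  if (any(!(is_base | is_endo | is_epi))) {
    stop("geometry error: unclassified boundary facet")
  }
  ring <- vapply(0:(nc - 1L), function(j) id(0L, j, 0L), integer(1))
  attr(ring, "ordered") <- TRUE
  fixed <- vapply(0:(nc - 1L), function(j) id(0L, j, nt), integer(1))
  mesh <- structure(list(
    nodes = nodes,
    elems = elems,
    order = 1L,
    facets = list(endocardium_lv = bfaces[is_endo, , drop = FALSE],
                  epicardium = bfaces[is_epi, , drop = FALSE],
                  base = bfaces[is_base, , drop = FALSE]),
    node_sets = list(fixed = fixed, basal_ring = ring,
                     base_plane = base_set,
                     endocardium_lv = endo_set, epicardium = epi_set),
    region = rep("lv_wall", nrow(elems)),
    transmural = node_k / nt,
    long_axis = c(0, 0, 1),
    params = p), class = "ventricular_mesh")
  if (order == 2L) {
    n_lin <- nrow(mesh$nodes)
    mesh <- mesh_to_quadratic(mesh)
    mesh <- .project_midside_nodes(mesh, p, n_lin, zb)
  }
  validate_mesh(mesh)
  mesh
}

# Curve quadratic elements onto the true wall geometry: each midside node is
# scaled radially onto the ellipsoid of its interpolated transmural
# coordinate; midside nodes of basal-plane edges stay in the basal plane and
# are scaled onto the in-plane ellipse instead.
#' @keywords internal
.project_midside_nodes <- function(mesh, p, n_lin, zb) {
  n <- nrow(mesh$nodes)
  mid <- (n_lin + 1L):n
  t <- mesh$transmural[mid]
  a <- p$a_endo + p$t_apex * t
  b <- p$b_endo + p$t_eq * t
  x <- mesh$nodes[mid, , drop = FALSE]
  on_base <- abs(x[, 3] - zb) < 1e-9 * max(p$a_endo, 1)
  s <- 1 / sqrt((x[, 1]^2 + x[, 2]^2) / b^2 + x[, 3]^2 / a^2)
  # base-plane edges: scale in-plane onto the ellipse at z = zb
  rho <- b * sqrt(pmax(1 - zb^2 / a^2, 0))
  s_base <- rho / sqrt(x[, 1]^2 + x[, 2]^2)
  mesh$nodes[mid, 1] <- x[, 1] * ifelse(on_base, s_base, s)
  mesh$nodes[mid, 2] <- x[, 2] * ifelse(on_base, s_base, s)
  mesh$nodes[mid, 3] <- ifelse(on_base, x[, 3], x[, 3] * s)
  mesh
}

#' Convert a linear tetrahedral mesh to quadratic (10-node) elements
#'
#' Inserts midside nodes at edge midpoints (the geometry map stays affine),
#' upgrades facet sets to 6-node triangles, and extends node sets to include
#' midside nodes whose parent edge lies entirely in the set.
#'
#' @param mesh a linear `"ventricular_mesh"`.
#' @return The quadratic mesh.
#' @export
mesh_to_quadratic <- function(mesh) {
  if (mesh$order != 1L) stop("mesh is already quadratic")
  elems <- mesh$elems
  m <- nrow(elems)
  # unique edges over all elements
  ea <- ec <- NULL
  for (e in 1:6) {
    ea <- c(ea, elems[, TET10_EDGES[e, 1]])
    ec <- c(ec, elems[, TET10_EDGES[e, 2]])
  }
  lo <- pmin(ea, ec); hi <- pmax(ea, ec)
  key <- paste(lo, hi)
  uk <- !duplicated(key)
  n0 <- nrow(mesh$nodes)
  mid_id <- setNames(n0 + seq_len(sum(uk)), key[uk])
  mid_lo <- lo[uk]; mid_hi <- hi[uk]
  new_nodes <- (mesh$nodes[mid_lo, , drop = FALSE] +
                mesh$nodes[mid_hi, , drop = FALSE]) / 2
  nodes <- rbind(mesh$nodes, new_nodes)
  elems10 <- cbind(elems, matrix(0L, m, 6L))
  for (e in 1:6) {
    a <- elems[, TET10_EDGES[e, 1]]; b <- elems[, TET10_EDGES[e, 2]]
    elems10[, 4L + e] <- unname(mid_id[paste(pmin(a, b), pmax(a, b))])
  }
  edge_mid <- function(a, b) unname(mid_id[paste(pmin(a, b), pmax(a, b))])
  facets <- lapply(mesh$facets, function(f) {
    cbind(f,
          edge_mid(f[, 1], f[, 2]),
          edge_mid(f[, 2], f[, 3]),
          edge_mid(f[, 3], f[, 1]))
  })
  in_set <- function(set) {
    keep <- (mid_lo %in% set) & (mid_hi %in% set)
    c(set, unname(mid_id[keep]))
  }
  ns <- mesh$node_sets
  ring <- ns$basal_ring
  nr <- length(ring)
  ring2 <- integer(2L * nr)
  ring2[seq(1L, by = 2L, length.out = nr)] <- ring
  ring2[seq(2L, by = 2L, length.out = nr)] <-
    edge_mid(ring, ring[c(2:nr, 1L)])
  attr(ring2, "ordered") <- TRUE
  node_sets <- list(fixed = in_set(ns$fixed),
                    basal_ring = ring2,
                    base_plane = in_set(ns$base_plane),
                    endocardium_lv = in_set(ns$endocardium_lv),
                    epicardium = in_set(ns$epicardium))
  transmural <- c(mesh$transmural,
                  (mesh$transmural[mid_lo] + mesh$transmural[mid_hi]) / 2)
  out <- mesh
  out$nodes <- nodes
  out$elems <- elems10
  out$order <- 2L
  out$facets <- facets
  out$node_sets <- node_sets
  out$transmural <- transmural
  out
}

#' Structured tetrahedral box mesh (testing and benchmark helper)
#'
#' A `[0, lx] x [0, ly] x [0, lz]` block subdivided into Kuhn tetrahedra,
#' with facet sets on all six faces plus `boundary` (the full closed
#' surface). The transmural coordinate is `x / lx`; the region label is
#' `lv_wall` so growth applies everywhere.
#'
#' @param nx,ny,nz cells per direction.
#' @param lx,ly,lz box dimensions (mm).
#' @param order element order (1 or 2).
#' @return A `"ventricular_mesh"`-like object (no endocardial tags).
#' @export
make_box_mesh <- function(nx = 2L, ny = 2L, nz = 2L,
                          lx = 1, ly = 1, lz = 1, order = 1L) {
  id <- function(i, j, k) k * ((nx + 1L) * (ny + 1L)) + j * (nx + 1L) + i + 1L
  n_nodes <- (nx + 1L) * (ny + 1L) * (nz + 1L)
  nodes <- matrix(0, n_nodes, 3L)
  for (k in 0:nz) for (j in 0:ny) for (i in 0:nx) {
    nodes[id(i, j, k), ] <- c(lx * i / nx, ly * j / ny, lz * k / nz)
  }
  steps <- diag(3L)
  elems <- vector("list", nx * ny * nz * 6L)
  ne <- 0L
  for (k in 0:(nz - 1L)) for (j in 0:(ny - 1L)) for (i in 0:(nx - 1L)) {
    vid <- function(d) id(i + d[1], j + d[2], k + d[3])
    for (perm in .KUHN_PERMS) {
      d0 <- c(0L, 0L, 0L)
      d1 <- d0 + steps[perm[1], ]
      d2 <- d1 + steps[perm[2], ]
      ne <- ne + 1L
      elems[[ne]] <- c(vid(d0), vid(d1), vid(d2), vid(c(1L, 1L, 1L)))
    }
  }
  elems <- .orient_tets(do.call(rbind, elems), nodes)
  bfaces <- .boundary_facets(elems, nodes)
  xc <- (nodes[bfaces[, 1], ] + nodes[bfaces[, 2], ] + nodes[bfaces[, 3], ]) / 3
  tol <- 1e-9 * max(lx, ly, lz)
  facets <- list(
    xmin = bfaces[abs(xc[, 1]) < tol, , drop = FALSE],
    xmax = bfaces[abs(xc[, 1] - lx) < tol, , drop = FALSE],
    ymin = bfaces[abs(xc[, 2]) < tol, , drop = FALSE],
    ymax = bfaces[abs(xc[, 2] - ly) < tol, , drop = FALSE],
    zmin = bfaces[abs(xc[, 3]) < tol, , drop = FALSE],
    zmax = bfaces[abs(xc[, 3] - lz) < tol, , drop = FALSE],
    boundary = bfaces)
  mesh <- structure(list(
    nodes = nodes, elems = elems, order = 1L, facets = facets,
    node_sets = list(fixed = integer(0)),
    region = rep("lv_wall", nrow(elems)),
    transmural = nodes[, 1] / lx,
    long_axis = c(0, 0, 1),
    params = list(lx = lx, ly = ly, lz = lz)), class = "ventricular_mesh")
  if (order == 2L) mesh <- mesh_to_quadratic(mesh)
  mesh
}

#' Validate mesh invariants
#'
#' Checks positively oriented tetrahedra, facet/node index validity, and
#' non-empty `endocardium_lv` and `base` tags (when present as a ventricular
#' mesh).
#'
#' @param mesh a `"ventricular_mesh"`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (any(mesh$elems < 1L) || any(mesh$elems > n)) {
    stop("mesh error: element references invalid node")
  }
  vols <- element_volumes(mesh)
  if (any(vols <= 0)) stop("mesh error: non-positive element volume")
  for (nm in names(mesh$facets)) {
    f <- mesh$facets[[nm]]
    if (length(f) && (any(f < 1L) || any(f > n))) {
      stop("mesh error: facet references invalid node")
    }
  }
  if (!is.null(mesh$facets$endocardium_lv)) {
    if (nrow(mesh$facets$endocardium_lv) == 0L || nrow(mesh$facets$base) == 0L) {
      stop("mesh error: endocardium_lv and base tags must be non-empty")
    }
  }
  invisible(TRUE)
}

#' Reference element volumes (mm^3)
#' @param mesh a `"ventricular_mesh"`.
#' @return Vector of signed corner-tet volumes.
#' @keywords internal
element_volumes <- function(mesh) {
  el <- mesh$elems
  v1 <- mesh$nodes[el[, 2], , drop = FALSE] - mesh$nodes[el[, 1], , drop = FALSE]
  v2 <- mesh$nodes[el[, 3], , drop = FALSE] - mesh$nodes[el[, 1], , drop = FALSE]
  v3 <- mesh$nodes[el[, 4], , drop = FALSE] - mesh$nodes[el[, 1], , drop = FALSE]
  (v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
   v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
   v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])) / 6
}

#' Idealized bi-ventricular geometry (not provided)
#'
#' Right-overload scenarios require a bi-ventricular mesh with
#' `endocardium_rv` tags and a septal region. The built-in generator only
#' produces single-LV geometries; supply an external tagged mesh via
#' [read_msh()] to run right-sided scenarios.
#'
#' @param params geometry parameters (unused).
#' @export
make_biventricular <- function(params) {
  stop("geometry error: bi-ventricular generation is not implemented; ",
       "supply an external tagged mesh (read_msh) with endocardium_rv ",
       "and septum labels")
}

#' Septal curvature diagnostic (bi-ventricular meshes only)
#' @param mesh mesh with a `septum` region.
#' @param displacement nodal displacement vector.
#' @export
septal_curvature_sign <- function(mesh, displacement = NULL) {
  if (!any(mesh$region == "septum")) {
    stop("diagnostic error: mesh has no septum region")
  }
  stop("diagnostic error: septal curvature requires a bi-ventricular mesh ",
       "with a structured septal surface; not available for this mesh")
}
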