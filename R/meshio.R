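# ---------------------------------------------------------------------------
# Mesh exchange: Gmsh MSH v4.1 ASCII (physical groups <-> tags) and VTK XML
# unstructured-grid (VTU) ASCII output for fields. Node indices are 1-based
# in both formats; internal storage is 1-based R indexing throughout, with
# element-node orderings converted at the boundary (Gmsh swaps the last two
# midside nodes of 10-node tetrahedra relative to the VTK convention used
# internally).
# ---------------------------------------------------------------------------

.GMSH_TET10_PERM <- c(1:8, 10L, 9L)  # internal <-> gmsh second-order tets

#' Write a mesh to Gmsh MSH v4.1 (ASCII)
#'
#' Surface facet tags and volume region labels are written as physical
#' groups on discrete entities.
#'
#' @param mesh a `"ventricular_mesh"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  surf_tags <- names(mesh$facets)
  regions <- unique(mesh$region)
  n_surf <- length(surf_tags)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")
  w("$PhysicalNames", as.character(n_surf + length(regions)))
  for (s in seq_along(surf_tags)) w(sprintf('2 %d "%s"', s, surf_tags[s]))
  for (r in seq_along(regions)) {
    w(sprintf('3 %d "%s"', n_surf + r, regions[r]))
  }
  w("$EndPhysicalNames")
  # discrete entities: one surface per facet tag, one volume per region
  w("$Entities", sprintf("0 0 %d %d", n_surf, length(regions)))
  for (s in seq_along(surf_tags)) {
    w(sprintf("%d 0 0 0 0 0 0 1 %d 0", s, s))
  }
  for (r in seq_along(regions)) {
    w(sprintf("%d 0 0 0 0 0 0 1 %d 0", r, n_surf + r))
  }
  w("$EndEntities")
  n <- nrow(mesh$nodes)
  w("$Nodes", sprintf("1 %d 1 %d", n, n))
  w(sprintf("3 1 0 %d", n))  # all nodes on the (first) volume entity
  writeLines(as.character(seq_len(n)), con)
  writeLines(sprintf("%.17g %.17g %.17g",
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("$EndNodes")
  tri_type <- if (mesh$order == 1L) 2L else 9L
  tet_type <- if (mesh$order == 1L) 4L else 11L
  blocks <- list()
  eid <- 0L
  for (s in seq_along(surf_tags)) {
    f <- mesh$facets[[surf_tags[s]]]
    if (nrow(f) == 0L) next
    rows <- sprintf("%d %s", eid + seq_len(nrow(f)),
                    apply(f, 1L, paste, collapse = " "))
    blocks[[length(blocks) + 1L]] <-
      c(sprintf("2 %d %d %d", s, tri_type, nrow(f)), rows)
    eid <- eid + nrow(f)
  }
  for (r in seq_along(regions)) {
    sel <- mesh$region == regions[r]
    el <- mesh$elems[sel, , drop = FALSE]
    if (mesh$order == 2L) el <- el[, .GMSH_TET10_PERM, drop = FALSE]
    rows <- sprintf("%d %s", eid + seq_len(nrow(el)),
                    apply(el, 1L, paste, collapse = " "))
    blocks[[length(blocks) + 1L]] <-
      c(sprintf("3 %d %d %d", r, tet_type, nrow(el)), rows)
    eid <- eid + nrow(el)
  }
  w("$Elements", sprintf("%d %d 1 %d", length(blocks), eid, eid))
  for (b in blocks) w(b)
  w("$EndElements")
  invisible(path)
}

.msh_section <- function(lines, name) {
  i0 <- match(paste0("$", name), lines)
  i1 <- match(paste0("$End", name), lines)
  if (is.na(i0) || is.na(i1)) return(NULL)
  lines[(i0 + 1L):(i1 - 1L)]
}

#' Read a tagged tetrahedral mesh from Gmsh MSH v4.1 (ASCII)
#'
#' Expects volume elements (types 4 or 11) carrying region physical names
#' and surface triangles (types 2 or 9) carrying the facet tags
#' `endocardium_lv`, `epicardium`, `base` (plus optional `endocardium_rv`).
#' Node sets (basal ring, fixed ring, base plane) and an approximate
#' transmural coordinate are reconstructed from the tagged surfaces.
#'
#' @param path MSH file path.
#' @return A `"ventricular_mesh"`.
#' @export
read_msh <- function(path) {
  lines <- readLines(path)
  fmt <- strsplit(.msh_section(lines, "MeshFormat")[1], " ")[[1]]
  if (substr(fmt[1], 1, 1) != "4") stop("mesh error: need MSH format 4.x")
  phys <- .msh_section(lines, "PhysicalNames")
  pn <- list()
  if (!is.null(phys)) {
    for (ln in phys[-1]) {
      pm <- regmatches(ln, regexec('^(\\d+) (\\d+) "(.*)"$', ln))[[1]]
      if (length(pm) == 4L) {
        pn[[paste(pm[2], pm[3])]] <- pm[4]
      }
    }
  }
  # entity tag -> physical tag, per dimension
  ent <- .msh_section(lines, "Entities")
  ent_phys <- list()
  if (!is.null(ent)) {
    counts <- as.integer(strsplit(ent[1], " ")[[1]])
    row <- 2L
    for (dim in 0:3) {
      for (e in seq_len(counts[dim + 1L])) {
        v <- strsplit(trimws(ent[row]), " +")[[1]]
        row <- row + 1L
        if (dim == 0L) next  # points: tag x y z numPhys ...
        nph <- as.integer(v[8])
        if (!is.na(nph) && nph >= 1L) {
          ent_phys[[paste(dim, v[1])]] <- as.integer(v[9])
        }
      }
    }
  }
  # nodes
  nsec <- .msh_section(lines, "Nodes")
  hdr <- as.numeric(strsplit(nsec[1], " ")[[1]])
  n_blocks <- hdr[1]; n_nodes <- hdr[2]
  nodes <- matrix(0, n_nodes, 3L)
  row <- 2L
  for (b in seq_len(n_blocks)) {
    bh <- as.numeric(strsplit(nsec[row], " ")[[1]])
    nb <- bh[4]
    row <- row + 1L
    ids <- as.integer(nsec[row:(row + nb - 1L)])
    row <- row + nb
    xyz <- do.call(rbind, lapply(nsec[row:(row + nb - 1L)], function(s) {
      as.numeric(strsplit(trimws(s), " +")[[1]][1:3])
    }))
    nodes[ids, ] <- xyz
    row <- row + nb
  }
  # elements
  esec <- .msh_section(lines, "Elements")
  hdr <- as.numeric(strsplit(esec[1], " ")[[1]])
  n_blocks <- hdr[1]
  row <- 2L
  tets <- list(); tet_region <- list()
  tris <- list(); tri_tag <- list()
  order <- 1L
  for (b in seq_len(n_blocks)) {
    bh <- as.integer(strsplit(esec[row], " ")[[1]])
    dim <- bh[1]; etag <- bh[2]; etype <- bh[3]; nb <- bh[4]
    row <- row + 1L
    dat <- do.call(rbind, lapply(esec[row:(row + nb - 1L)], function(s) {
      as.integer(strsplit(trimws(s), " +")[[1]])
    }))
    row <- row + nb
    ph <- ent_phys[[paste(dim, etag)]]
    nm <- if (!is.null(ph)) pn[[paste(dim, ph)]] else NULL
    conn <- dat[, -1L, drop = FALSE]
    if (etype %in% c(4L, 11L)) {
      if (etype == 11L) {
        order <- 2L
        conn <- conn[, .GMSH_TET10_PERM, drop = FALSE]
      }
      tets[[length(tets) + 1L]] <- conn
      tet_region[[length(tet_region) + 1L]] <-
        rep(nm %||% "lv_wall", nrow(conn))
    } else if (etype %in% c(2L, 9L)) {
      tris[[length(tris) + 1L]] <- conn
      tri_tag[[length(tri_tag) + 1L]] <- rep(nm %||% "untagged", nrow(conn))
    }
  }
  if (length(tets) == 0L) stop("mesh error: no tetrahedra in file")
  elems <- do.call(rbind, tets)
  region <- unlist(tet_region)
  tri <- do.call(rbind, tris)
  tag <- unlist(tri_tag)
  facets <- lapply(split(seq_along(tag), tag), function(ix) {
    tri[ix, , drop = FALSE]
  })
  if (is.null(facets$endocardium_lv) || is.null(facets$base)) {
    stop("mesh error: endocardium_lv and base surface tags are required")
  }
  elems <- .orient_tets(elems, nodes)
  set_of <- function(f) sort(unique(as.integer(f[, 1:3])))
  endo_set <- set_of(facets$endocardium_lv)
  epi_set <- if (!is.null(facets$epicardium)) set_of(facets$epicardium) else integer(0)
  base_set <- set_of(facets$base)
  ring <- .ordered_patch_boundary(facets$endocardium_lv[, 1:3, drop = FALSE])
  fixed <- if (length(epi_set)) intersect(epi_set, base_set) else integer(0)
  # approximate transmural coordinate from surface distances
  dmin <- function(set) {
    if (!length(set)) return(rep(1, nrow(nodes)))
    sq <- nodes[set, , drop = FALSE]
    apply(nodes, 1L, function(x) {
      sqrt(min(rowSums((sq - matrix(x, nrow(sq), 3L, byrow = TRUE))^2)))
    })
  }
  de <- dmin(endo_set); dp <- dmin(epi_set)
  structure(list(nodes = nodes, elems = elems, order = order,
                 facets = facets,
                 node_sets = list(fixed = fixed, basal_ring = ring,
                                  base_plane = base_set,
                                  endocardium_lv = endo_set,
                                  epicardium = epi_set),
                 region = region, transmural = de / pmax(de + dp, 1e-12),
                 long_axis = c(0, 0, 1), params = list(source = path)),
            class = "ventricular_mesh")
}

# ordered closed boundary loop of a triangulated surface patch
#' @keywords internal
.ordered_patch_boundary <- function(tri) {
  ed <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(3L, 1L)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  bd <- ed[cnt[key] == 1L, , drop = FALSE]
  if (nrow(bd) == 0L) return(integer(0))
  nxt <- bd[, 2]
  names(nxt) <- bd[, 1]
  ring <- integer(nrow(bd))
  ring[1] <- bd[1, 1]
  for (s in 2:length(ring)) {
    ring[s] <- nxt[[as.character(ring[s - 1L])]]
  }
  attr(ring, "ordered") <- TRUE
  ring
}

#' Write a mesh with cell/point fields to VTK XML (VTU, ASCII)
#'
#' @param mesh a `"ventricular_mesh"`.
#' @param path output path.
#' @param displacement nodal displacement vector (written as point data and
#'   used for the deformed points when `deformed = TRUE`).
#' @param cell_data named list of per-element numeric vectors.
#' @param deformed write deformed coordinates.
#' @return The path, invisibly.
#' @export
write_vtu <- function(mesh, path, displacement = NULL, cell_data = list(),
                      deformed = FALSE) {
  x <- if (deformed) .deformed_nodes(mesh, displacement) else mesh$nodes
  n <- nrow(x); m <- nrow(mesh$elems)
  nn <- ncol(mesh$elems)
  vtk_type <- if (mesh$order == 1L) 10L else 24L
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w('<?xml version="1.0"?>',
    '<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">',
    '  <UnstructuredGrid>',
    sprintf('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', n, m))
  w('      <Points>',
    '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(sprintf("%.10g %.10g %.10g", x[, 1], x[, 2], x[, 3]))
  w('        </DataArray>', '      </Points>')
  w('      <Cells>',
    '        <DataArray type="Int64" Name="connectivity" format="ascii">')
  w(apply(mesh$elems - 1L, 1L, paste, collapse = " "))
  w('        </DataArray>',
    '        <DataArray type="Int64" Name="offsets" format="ascii">')
  w(as.character(seq_len(m) * nn))
  w('        </DataArray>',
    '        <DataArray type="UInt8" Name="types" format="ascii">')
  w(as.character(rep(vtk_type, m)))
  w('        </DataArray>', '      </Cells>')
  if (!is.null(displacement)) {
    ud <- matrix(displacement, ncol = 3L, byrow = TRUE)
    w('      <PointData Vectors="displacement">',
      '        <DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
    w(sprintf("%.10g %.10g %.10g", ud[, 1], ud[, 2], ud[, 3]))
    w('        </DataArray>', '      </PointData>')
  }
  if (length(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w(sprintf('        <DataArray type="Float64" Name="%s" format="ascii">', nm))
      w(sprintf("%.10g", cell_data[[nm]]))
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>', '  </UnstructuredGrid>', '</VTKFile>')
  invisible(path)
}
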