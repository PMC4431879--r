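## Fixture generators: hexagonal tissues built analytically on the half-edge
## mesh, cell doublets, and free disks. All fixtures are relaxed to force
## balance (unless relax = FALSE) so tests start from stationary states.

## Build a half-edge mesh from a list of simple CCW polygons (one per cell).
## Shared vertices and walls are identified by coordinates; unmatched walls
## become free (arc) boundaries with zero initial bulge. Consecutive free
## walls of one cell are merged so every vertex is a degree-3 junction.
mesh_from_polygons <- function(ts, polys, types = NULL, colors = NULL,
                               target_area = NULL) {
  if (is.null(types)) types <- rep("default", length(polys))
  if (is.null(colors)) colors <- rep("#cccccc", length(polys))
  vkey <- new.env(parent = emptyenv())
  get_vertex <- function(p) {
    key <- paste(as.integer(round(p[1] * 1e6)), as.integer(round(p[2] * 1e6)))
    id <- vkey[[key]]
    if (is.null(id)) {
      id <- new_vertex(ts, p[1], p[2])
      vkey[[key]] <- id
    }
    id
  }
  edge_map <- new.env(parent = emptyenv())
  cids <- integer(length(polys))
  for (k in seq_along(polys)) {
    poly <- polys[[k]]
    nv <- nrow(poly)
    cid <- new_cell(ts, type = types[k], color = colors[k])
    cids[k] <- cid
    vids <- vapply(seq_len(nv), function(i) get_vertex(poly[i, ]), integer(1))
    hes <- vapply(seq_len(nv), function(i)
      new_halfedge(ts, vids[i], cid, KIND_INNER), integer(1))
    for (i in seq_len(nv)) {
      ts$he_next[hes[i]] <- hes[if (i == nv) 1L else i + 1L]
      ts$vx_out[vids[i]] <- hes[i]
      edge_map[[paste(vids[i], vids[if (i == nv) 1L else i + 1L])]] <- hes[i]
    }
    ts$cl_boundary[cid] <- hes[1]
  }
  ## twin resolution
  for (key in ls(edge_map)) {
    h <- edge_map[[key]]
    if (ts$he_twin[h] != 0L) next
    ab <- as.integer(strsplit(key, " ")[[1]])
    rev_key <- paste(ab[2], ab[1])
    t <- edge_map[[rev_key]]
    if (!is.null(t)) {
      set_twins(ts, h, t)
    } else {
      e <- new_halfedge(ts, ab[2], EXTERIOR, KIND_OUTER)
      ts$he_kind[h] <- KIND_OUTER
      set_twins(ts, h, e)
    }
  }
  rebuild_exterior_next(ts)
  merge_all_consecutive_outer(ts)
  rebuild_exterior_next(ts)
  rebuild_vertex_out(ts)
  for (cid in cids) {
    ts$cl_target[cid] <- if (is.null(target_area)) cell_area(ts, cid) else target_area
  }
  refit_all_arcs(ts)
  update_centers(ts)
  cids
}

hex_lattice_centers <- function(rings) {
  pts <- list()
  for (i in -rings:rings) for (j in -rings:rings) {
    if ((abs(i) + abs(j) + abs(i + j)) / 2 > rings) next
    pts[[length(pts) + 1L]] <- c(i + j / 2, j * sqrt(3) / 2)
  }
  do.call(rbind, pts)
}

hexagon_poly <- function(center, s = 1) {
  ang <- pi / 6 + (0:5) * pi / 3
  cbind(center[1] + s / sqrt(3) * cos(ang),
        center[2] + s / sqrt(3) * sin(ang))
}

#' Build a relaxed hexagonal tissue
#'
#' A honeycomb of 1 + 3 r (r + 1) equal cells (r = number of rings around the
#' central cell), built analytically on the half-edge mesh and relaxed to
#' stationarity. `rings = 0` gives one isolated cell of the same area.
#'
#' @param rings number of rings (>= 0).
#' @param params,tensions simulation parameters and tension table.
#' @param relax relax to force balance after construction (default TRUE).
#' @param types optional character vector of cell type labels, one per cell
#'   in lattice order.
#' @return a [tissue_state()].
#' @export
build_hex_tissue <- function(rings, params = sim_params(),
                             tensions = tension_table(), relax = TRUE,
                             types = NULL) {
  ts <- tissue_state(params, tensions)
  if (rings == 0) {
    make_isolated_cell(ts, c(0, 0), sqrt(sqrt(3) / 2 / pi))
    return(ts)
  }
  centers <- hex_lattice_centers(rings)
  polys <- lapply(seq_len(nrow(centers)), function(i) hexagon_poly(centers[i, ]))
  mesh_from_polygons(ts, polys, types = types, target_area = sqrt(3) / 2)
  if (relax) relax(ts)
  ts
}

#' Build a roughly circular hexagonal patch of n cells
#'
#' The n lattice cells closest to the origin (ties broken by angle), meshed
#' and optionally relaxed. Used as the generic many-cell fixture and as the
#' scaffold of the lineage model's initial tissue.
#'
#' @param n number of cells.
#' @inheritParams build_hex_tissue
#' @return a [tissue_state()].
#' @export
build_hex_blob <- function(n, params = sim_params(),
                           tensions = tension_table(), relax = TRUE,
                           types = NULL) {
  rings <- 1
  while (1 + 3 * rings * (rings + 1) < n) rings <- rings + 1
  centers <- hex_lattice_centers(rings + 1)
  d <- sqrt(centers[, 1]^2 + centers[, 2]^2)
  ang <- atan2(centers[, 2], centers[, 1])
  ord <- order(d, ang)
  centers <- centers[ord[seq_len(n)], , drop = FALSE]
  ts <- tissue_state(params, tensions)
  polys <- lapply(seq_len(nrow(centers)), function(i) hexagon_poly(centers[i, ]))
  mesh_from_polygons(ts, polys, types = types, target_area = sqrt(3) / 2)
  if (relax) relax(ts)
  ts
}

#' Two isolated disks
#'
#' @param dist center distance.
#' @param r disk radius (both disks).
#' @inheritParams build_hex_tissue
#' @return a [tissue_state()] with two isolated cells.
#' @export
build_two_disks <- function(dist, r = 0.5, params = sim_params(),
                            tensions = tension_table()) {
  ts <- tissue_state(params, tensions)
  make_isolated_cell(ts, c(-dist / 2, 0), r)
  make_isolated_cell(ts, c(dist / 2, 0), r)
  ts
}

#' An equal two-cell doublet in contact
#'
#' Two equal disks placed overlapping, joined by a contact edge and relaxed:
#' the classic soap-bubble doublet whose junction angles follow the tension
#' ratio.
#'
#' @param r disk radius.
#' @param overlap fraction of the radius by which the disks initially
#'   interpenetrate.
#' @inheritParams build_hex_tissue
#' @return a [tissue_state()] with two lens-shaped cells.
#' @export
build_doublet <- function(r = 0.5, overlap = 0.3, params = sim_params(),
                          tensions = tension_table(), relax = TRUE) {
  ts <- build_two_disks(dist = 2 * r * (1 - overlap / 2), r = r,
                        params = params, tensions = tensions)
  insert_contact_edge(ts, 1L, 2L)
  if (relax) relax(ts)
  ts
}
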