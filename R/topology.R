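## Topological primitives of the cell complex: cell-cell contact (edge
## insertion), T2 void removal, T1 edge flip, cell division, cell removal
## (apoptosis), plus event detection. Every primitive performs local mesh
## surgery and leaves the state structurally valid (validate_tissue()).

topo_event <- function(kind, cells, created = integer(0), removed = integer(0),
                       step = NA_integer_, iteration = NA_integer_) {
  list(kind = kind, cells = as.integer(cells), created = as.integer(created),
       removed = as.integer(removed), step = step, iteration = iteration)
}

log_event <- function(ts, ev) {
  ev$step <- ts$step
  ts$events[[length(ts$events) + 1L]] <- ev
  invisible(ts)
}

## Split half-edge pair (h, twin(h)) at point pt, inserting a vertex (or
## reusing `vertex`). Works for INNER (interior twin) and OUTER (exterior
## twin) edges. Returns the ids of the pieces.
split_edge <- function(ts, h, pt, vertex = NULL) {
  t <- ts$he_twin[h]
  w <- if (is.null(vertex)) new_vertex(ts, pt[1], pt[2]) else vertex
  h2 <- new_halfedge(ts, w, ts$he_cell[h], ts$he_kind[h])
  t2 <- new_halfedge(ts, w, ts$he_cell[t], ts$he_kind[t])
  ts$he_next[h2] <- ts$he_next[h]
  ts$he_next[h] <- h2
  ts$he_next[t2] <- ts$he_next[t]
  ts$he_next[t] <- t2
  set_twins(ts, h, t2)
  set_twins(ts, h2, t)
  ts$vx_out[w] <- h2
  list(w = w, h1 = h, h2 = h2, t1 = t, t2 = t2)
}

## Merge two consecutive OUTER half-edges of the same cell (h, next(h)) into
## one arc, removing the shared degree-2 vertex. Exterior next pointers are
## NOT fixed here; callers rebuild them via rebuild_exterior_next().
merge_outer_pair <- function(ts, h) {
  h2 <- ts$he_next[h]
  stopifnot(ts$he_cell[h2] == ts$he_cell[h],
            ts$he_kind[h] == KIND_OUTER, ts$he_kind[h2] == KIND_OUTER)
  b <- ts$he_origin[h2]
  e1 <- ts$he_twin[h]
  e2 <- ts$he_twin[h2]
  ts$he_next[h] <- ts$he_next[h2]
  set_twins(ts, h, e2)
  kill_halfedge(ts, h2)
  kill_halfedge(ts, e1)
  kill_vertex(ts, b)
  cid <- ts$he_cell[h]
  if (ts$cl_boundary[cid] == h2) ts$cl_boundary[cid] <- h
  invisible(ts)
}

## Rebuild next pointers of all exterior (cell 0) half-edges from the twin
## structure: each boundary vertex has exactly one outgoing exterior
## half-edge, so next(e) is the exterior half-edge leaving dest(e).
rebuild_exterior_next <- function(ts) {
  ext <- which(ts$he_alive & ts$he_cell == EXTERIOR)
  if (!length(ext)) return(invisible(ts))
  origin_map <- integer(ts$nvx)
  if (anyDuplicated(ts$he_origin[ext]))
    stop("vertex with two outgoing exterior half-edges")
  origin_map[ts$he_origin[ext]] <- ext
  dest <- ts$he_origin[ts$he_twin[ext]]
  nxt <- origin_map[dest]
  if (any(nxt == 0L)) stop("exterior boundary cannot be closed")
  ts$he_next[ext] <- nxt
  invisible(ts)
}

## Reset vx_out of every vertex to some alive outgoing half-edge.
rebuild_vertex_out <- function(ts, verts = NULL) {
  hes <- halfedge_ids(ts)
  org <- ts$he_origin[hes]
  if (is.null(verts)) {
    ts$vx_out[org] <- hes      # last writer wins; any outgoing edge is fine
  } else {
    sel <- org %in% verts
    ts$vx_out[org[sel]] <- hes[sel]
  }
  invisible(ts)
}

## Merge all consecutive same-cell OUTER pairs anywhere in the mesh.
merge_all_consecutive_outer <- function(ts) {
  repeat {
    hes <- halfedge_ids(ts)
    hes <- hes[ts$he_kind[hes] == KIND_OUTER & ts$he_cell[hes] != EXTERIOR]
    cand <- hes[ts$he_next[hes] != hes &
                ts$he_kind[ts$he_next[hes]] == KIND_OUTER &
                ts$he_cell[ts$he_next[hes]] == ts$he_cell[hes]]
    if (!length(cand)) break
    merge_outer_pair(ts, cand[1])
  }
  invisible(ts)
}

## Transactional surgery support: snapshot the mutable mesh fields so a
## primitive that discovers a geometric problem mid-surgery can restore the
## state and report failure instead of leaving a corrupt mesh.
save_mesh_state <- function(ts) {
  list(nhe = ts$nhe, nvx = ts$nvx, ncl = ts$ncl,
       he_origin = ts$he_origin, he_twin = ts$he_twin,
       he_next = ts$he_next, he_cell = ts$he_cell,
       he_kind = ts$he_kind, he_alive = ts$he_alive,
       vx_x = ts$vx_x, vx_y = ts$vx_y, vx_out = ts$vx_out,
       vx_alive = ts$vx_alive, cl_boundary = ts$cl_boundary,
       cl_radius = ts$cl_radius, cl_arc_r = ts$cl_arc_r,
       cl_arc_major = ts$cl_arc_major, cl_alive = ts$cl_alive,
       n_events = length(ts$events))
}

restore_mesh_state <- function(ts, saved) {
  for (f in setdiff(names(saved), "n_events")) ts[[f]] <- saved[[f]]
  ts$events <- ts$events[seq_len(saved$n_events)]
  invisible(ts)
}

## ---- contact (edge insertion) ---------------------------------------------

## Descriptors of all free boundaries, one row per arc (isolated cells are a
## single full circle). Vectorized: this runs once per relaxation chunk.
free_boundary_arcs <- function(ts) {
  cids <- cell_ids(ts)
  iso <- cids[ts$cl_boundary[cids] == 0L]
  hes <- halfedge_ids(ts)
  hes <- hes[ts$he_kind[hes] == KIND_OUTER & ts$he_cell[hes] != EXTERIOR]
  ## inward bulges cannot contact; near-flat arcs (huge radius) have no
  ## meaningful circle geometry and cannot initiate contact either
  hes <- hes[ts$cl_arc_r[ts$he_cell[hes]] > 0 &
             ts$cl_arc_r[ts$he_cell[hes]] < 25]
  n_iso <- length(iso); n_arc <- length(hes)
  out <- data.frame(
    cell = c(iso, ts$he_cell[hes]),
    he = c(rep(NA_integer_, n_iso), hes),
    cx = numeric(n_iso + n_arc), cy = numeric(n_iso + n_arc),
    r = numeric(n_iso + n_arc),
    full = c(rep(TRUE, n_iso), rep(FALSE, n_arc)),
    a0 = NA_real_, span = 2 * pi)
  if (n_iso) {
    out$cx[seq_len(n_iso)] <- ts$cl_cx[iso]
    out$cy[seq_len(n_iso)] <- ts$cl_cy[iso]
    out$r[seq_len(n_iso)] <- ts$cl_radius[iso]
  }
  if (n_arc) {
    ii <- n_iso + seq_len(n_arc)
    av <- ts$he_origin[hes]
    bv <- ts$he_origin[ts$he_twin[hes]]
    ax <- ts$vx_x[av]; ay <- ts$vx_y[av]
    bx <- ts$vx_x[bv]; by <- ts$vx_y[bv]
    L <- sqrt((bx - ax)^2 + (by - ay)^2)
    r <- pmax(ts$cl_arc_r[ts$he_cell[hes]], L / 2)
    major <- ts$cl_arc_major[ts$he_cell[hes]]
    h2 <- sqrt(pmax(r^2 - (L / 2)^2, 0)) * ifelse(major, -1, 1)
    nx <- -(by - ay) / L; ny <- (bx - ax) / L  # interior-side normal
    cx <- (ax + bx) / 2 + h2 * nx
    cy <- (ay + by) / 2 + h2 * ny
    th_minor <- 2 * asin(pmin(1, L / (2 * r)))
    out$cx[ii] <- cx; out$cy[ii] <- cy; out$r[ii] <- r
    out$a0[ii] <- atan2(ay - cy, ax - cx)
    out$span[ii] <- ifelse(major, 2 * pi - th_minor, th_minor)
  }
  out
}

arc_row <- function(i, df) as.list(df[i, ])

angle_on_arc <- function(arc, pt, margin = 0) {
  if (arc$full) return(TRUE)
  ang <- atan2(pt[2] - arc$cy, pt[1] - arc$cx)
  d <- (ang - arc$a0) %% (2 * pi)
  d > margin && d < arc$span - margin
}

## Intersection points of two arc circles, or NULL when they do not overlap
## deeply enough (or one contains the other).
circle_overlap <- function(a, b, tol) {
  d2 <- (a$cx - b$cx)^2 + (a$cy - b$cy)^2
  d <- sqrt(d2)
  if (d >= a$r + b$r - tol) return(NULL)
  if (d <= abs(a$r - b$r) + 1e-12) return(NULL)
  l <- (d2 + a$r^2 - b$r^2) / (2 * d)
  h2 <- a$r^2 - l^2
  if (h2 <= 0) return(NULL)
  hh <- sqrt(h2)
  ux <- (b$cx - a$cx) / d; uy <- (b$cy - a$cy) / d
  p1 <- c(a$cx + l * ux - hh * uy, a$cy + l * uy + hh * ux)
  p2 <- c(a$cx + l * ux + hh * uy, a$cy + l * uy - hh * ux)
  list(p1 = p1, p2 = p2, depth = a$r + b$r - d)
}

## Build an isolated cell's first boundary: a chord between vertices w1, w2
## plus one arc around the far side. Returns the chord half-edge (cell side).
isolated_to_lens <- function(ts, cid, w1, w2) {
  z <- c(ts$cl_cx[cid], ts$cl_cy[cid])
  p1 <- c(ts$vx_x[w1], ts$vx_y[w1])
  p2 <- c(ts$vx_x[w2], ts$vx_y[w2])
  ## orient chord so the cell interior is on its left
  crossz <- (p2[1] - p1[1]) * (z[2] - p1[2]) - (p2[2] - p1[2]) * (z[1] - p1[1])
  if (crossz < 0) { tmp <- w1; w1 <- w2; w2 <- tmp }
  chord <- new_halfedge(ts, w1, cid, KIND_INNER)
  arc <- new_halfedge(ts, ts$he_origin[chord], cid, KIND_OUTER)
  ## chord w1 -> w2, arc w2 -> w1
  ts$he_origin[arc] <- w2
  ts$he_next[chord] <- arc
  ts$he_next[arc] <- chord
  ext <- new_halfedge(ts, w1, EXTERIOR, KIND_OUTER)
  set_twins(ts, arc, ext)
  ts$cl_boundary[cid] <- chord
  ts$cl_arc_r[cid] <- ts$cl_radius[cid]
  ts$cl_arc_major[cid] <- TRUE    # free boundary wraps the far side
  ts$cl_radius[cid] <- NA_real_
  chord
}

#' Insert a contact edge between two touching cells
#'
#' Edge insertion: when the free boundaries (arcs) of two cells overlap, the
#' intersection plane is represented by a new inner edge between the two
#' circle intersection points. Both cells' boundary cycles are rewired; two
#' new vertices appear (degree 3: the two cells plus the exterior).
#'
#' @param ts a tissue state.
#' @param cell_i,cell_j the two contacting cell ids.
#' @return TRUE if the contact was inserted, FALSE if it was skipped (cells
#'   already adjacent, or intersection too close to an existing vertex).
#' @export
insert_contact_edge <- function(ts, cell_i, cell_j) {
  if (cell_i == cell_j) return(FALSE)
  if (!is_isolated(ts, cell_i) && cell_j %in% neighbors(ts, cell_i)) {
    warning("cells ", cell_i, " and ", cell_j, " are already adjacent")
    return(FALSE)
  }
  ## the surgery is transactional: arbitrary free-boundary geometry can
  ## defeat it (e.g. intersection points straddling an arc endpoint); a
  ## failed insertion restores the state and the contact is retried once
  ## the geometry has evolved
  saved <- save_mesh_state(ts)
  res <- tryCatch(insert_contact_edge_impl(ts, cell_i, cell_j),
                  error = function(e) e)
  if (inherits(res, "error")) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  res
}

insert_contact_edge_impl <- function(ts, cell_i, cell_j) {
  arcs_df <- free_boundary_arcs(ts)
  ai <- lapply(which(arcs_df$cell == cell_i), arc_row, df = arcs_df)
  aj <- lapply(which(arcs_df$cell == cell_j), arc_row, df = arcs_df)
  pick <- NULL
  for (a in ai) for (b in aj) {
    ov <- circle_overlap(a, b, 0)
    if (is.null(ov)) next
    ma <- max(0.02, 0.06 / a$r); mb <- max(0.02, 0.06 / b$r)
    if (angle_on_arc(a, ov$p1, ma) && angle_on_arc(a, ov$p2, ma) &&
        angle_on_arc(b, ov$p1, mb) && angle_on_arc(b, ov$p2, mb)) {
      pick <- list(a = a, b = b, ov = ov); break
    }
  }
  if (is.null(pick)) return(FALSE)
  a <- pick$a; b <- pick$b; ov <- pick$ov
  old_he <- sum(ts$he_alive); old_vx <- sum(ts$vx_alive)

  split_arc_two <- function(arc, q1, q2, v1 = NULL, v2 = NULL) {
    ## split the arc half-edge at q1 and q2 (ordered along the cell's travel
    ## direction); returns the middle piece he and the two vertices.
    a1 <- (atan2(q1[2] - arc$cy, q1[1] - arc$cx) - arc$a0) %% (2 * pi)
    a2 <- (atan2(q2[2] - arc$cy, q2[1] - arc$cx) - arc$a0) %% (2 * pi)
    if (a1 > a2) { tmp <- q1; q1 <- q2; q2 <- tmp; tmp <- v1; v1 <- v2; v2 <- tmp }
    s1 <- split_edge(ts, arc$he, q1, vertex = v1)
    s2 <- split_edge(ts, s1$h2, q2, vertex = v2)
    list(mid = s2$h1, w_first = s1$w, w_second = s2$w,
         ext_mid = ts$he_twin[s2$h1])
  }

  iso_i <- is_isolated(ts, cell_i)
  iso_j <- is_isolated(ts, cell_j)
  if (iso_i && iso_j) {
    w1 <- new_vertex(ts, ov$p1[1], ov$p1[2])
    w2 <- new_vertex(ts, ov$p2[1], ov$p2[2])
    ch_i <- isolated_to_lens(ts, cell_i, w1, w2)
    ch_j <- isolated_to_lens(ts, cell_j, w1, w2)
    set_twins(ts, ch_i, ch_j)
  } else if (!iso_i && !iso_j) {
    si <- split_arc_two(a, ov$p1, ov$p2)
    sj <- split_arc_two(b, ov$p1, ov$p2, v1 = NULL, v2 = NULL)
    ## reuse vertices: sj created two new vertices at the same points; glue by
    ## collapsing them onto si's vertices
    glue <- function(v_from, v_to) {
      hes <- halfedge_ids(ts)
      sel <- hes[ts$he_origin[hes] == v_from]
      ts$he_origin[sel] <- v_to
      kill_vertex(ts, v_from)
    }
    ## match by position
    d11 <- (ts$vx_x[sj$w_first] - ts$vx_x[si$w_first])^2 +
           (ts$vx_y[sj$w_first] - ts$vx_y[si$w_first])^2
    d12 <- (ts$vx_x[sj$w_first] - ts$vx_x[si$w_second])^2 +
           (ts$vx_y[sj$w_first] - ts$vx_y[si$w_second])^2
    if (d11 <= d12) {
      glue(sj$w_first, si$w_first); glue(sj$w_second, si$w_second)
    } else {
      glue(sj$w_first, si$w_second); glue(sj$w_second, si$w_first)
    }
    ## middle pieces become the inner edge pair
    kill_halfedge(ts, si$ext_mid)
    kill_halfedge(ts, sj$ext_mid)
    ts$he_kind[si$mid] <- KIND_INNER
    ts$he_kind[sj$mid] <- KIND_INNER
    set_twins(ts, si$mid, sj$mid)
  } else {
    if (iso_i) { # make cell_i the meshed one
      tmp <- cell_i; cell_i <- cell_j; cell_j <- tmp
      tmpa <- a; a <- b; b <- tmpa
    }
    si <- split_arc_two(a, ov$p1, ov$p2)
    ch_j <- isolated_to_lens(ts, cell_j, si$w_first, si$w_second)
    kill_halfedge(ts, si$ext_mid)
    ts$he_kind[si$mid] <- KIND_INNER
    set_twins(ts, si$mid, ch_j)
    ## the isolated side may have created its own arc/ext pair; fine
  }
  rebuild_vertex_out(ts)
  rebuild_exterior_next(ts)
  refit_cell_arcs(ts, cell_i)
  refit_cell_arcs(ts, cell_j)
  update_centers(ts, c(cell_i, cell_j))
  created_he <- setdiff(which(ts$he_alive), seq_len(old_he))
  log_event(ts, topo_event("CONTACT", c(cell_i, cell_j),
                           created = created_he))
  TRUE
}

## ---- void removal (T2) ----------------------------------------------------

## Enumerate exterior boundary components; returns list of integer vectors of
## exterior half-edge ids (each a closed cycle).
exterior_components <- function(ts) {
  ext <- which(ts$he_alive & ts$he_cell == EXTERIOR)
  comps <- list()
  seen <- rep(FALSE, ts$nhe)
  for (e in ext) {
    if (seen[e]) next
    cyc <- cycle_halfedges(ts, e)
    seen[cyc] <- TRUE
    comps[[length(comps) + 1L]] <- cyc
  }
  comps
}

## Area enclosed by an exterior component: signed chord polygon (positive for
## voids, traversed counterclockwise) minus the arc segments bulging inward.
void_area <- function(ts, comp) {
  a <- cycle_polygon_area(ts, comp)
  for (e in comp) {
    h <- ts$he_twin[e]
    if (ts$he_kind[h] == KIND_OUTER && ts$he_cell[h] != EXTERIOR) {
      g <- arc_geometry(ts, h)
      a <- a - g$seg_sign * circular_segment_area(g$radius, g$angle)
    }
  }
  a
}

void_surgery_ok <- function(ts, comp) {
  ## the component must still be a closed 3-cycle of exterior half-edges
  ## bounded by three distinct cells (earlier events in the same batch may
  ## have rewired it), and the collapse assumes three degree-3 corners
  ## whose non-void edges are walls
  if (any(!ts$he_alive[comp]) || any(ts$he_cell[comp] != EXTERIOR)) return(FALSE)
  if (!all(ts$he_next[comp] %in% comp) || anyDuplicated(ts$he_next[comp]))
    return(FALSE)
  if (anyDuplicated(ts$he_cell[ts$he_twin[comp]])) return(FALSE)
  for (e in comp) {
    arc <- ts$he_twin[e]
    cid <- ts$he_cell[arc]
    if (!ts$cl_alive[cid]) return(FALSE)
    cyc <- cell_cycle(ts, cid)
    pos <- match(arc, cyc)
    if (is.na(pos)) return(FALSE)
    wall_in <- cyc[if (pos == 1) length(cyc) else pos - 1]
    wall_out <- ts$he_next[arc]
    if (ts$he_kind[wall_in] != KIND_INNER ||
        ts$he_kind[wall_out] != KIND_INNER) return(FALSE)
  }
  for (v in ts$he_origin[comp]) {
    star <- tryCatch(vertex_star(ts, v), error = function(e) NULL)
    if (is.null(star) || length(star) != 3L) return(FALSE)
  }
  TRUE
}

#' Remove a small three-sided void (T2 transition)
#'
#' The curved triangular empty space bounded by the free boundaries of three
#' cells collapses to a single degree-3 vertex at the centroid of its three
#' corners. Neighboring cell adjacency is unchanged; the vertex count drops
#' by 2 and the half-edge pair count by 3.
#'
#' @param ts a tissue state.
#' @param comp integer vector of the void's three exterior half-edge ids (as
#'   returned in a VOID_REMOVAL event or from detection).
#' @return TRUE on success; signals an error for voids with more than 3 sides.
#' @export
remove_void <- function(ts, comp) {
  if (length(comp) != 3L) stop("void has ", length(comp), " sides; only 3-sided voids collapse")
  if (!void_surgery_ok(ts, comp)) return(FALSE)
  saved <- save_mesh_state(ts)
  verts <- ts$he_origin[comp]
  cells <- ts$he_cell[ts$he_twin[comp]]
  w <- new_vertex(ts, mean(ts$vx_x[verts]), mean(ts$vx_y[verts]))
  for (e in comp) {
    arc <- ts$he_twin[e]       # cell-side arc to delete
    cid <- ts$he_cell[arc]
    cyc <- cell_cycle(ts, cid)
    pos <- match(arc, cyc)
    wall_in <- cyc[if (pos == 1) length(cyc) else pos - 1]
    wall_out <- ts$he_next[arc]
    ts$he_next[wall_in] <- wall_out
    ts$he_origin[wall_out] <- w
    if (ts$cl_boundary[cid] == arc) ts$cl_boundary[cid] <- wall_out
    kill_halfedge(ts, arc)
    kill_halfedge(ts, e)
    ts$vx_out[w] <- wall_out
  }
  for (v in verts) kill_vertex(ts, v)
  for (cid in cells) refit_cell_arcs(ts, cid)
  ## postcondition: the three cells still close and keep positive area
  ok <- all(vapply(cells, function(cid) {
    a <- tryCatch(cell_area(ts, cid), error = function(e) NA_real_)
    is.finite(a) && a > 1e-9
  }, logical(1)))
  if (!ok) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  log_event(ts, topo_event("VOID_REMOVAL", cells, created = w,
                           removed = verts))
  TRUE
}

## ---- edge flip (T1) --------------------------------------------------------

## The three cells meeting at a vertex (by rotation around it).
cells_at_vertex <- function(ts, v) {
  ts$he_cell[vertex_star(ts, v)]
}

#' Flip a short inner edge (T1 transition)
#'
#' Neighbor exchange: the inner edge between cells (a, b) is removed and a
#' new inner edge of length `t1_length` is created perpendicular to it at its
#' midpoint, joining the two cells (c, d) that previously met the edge only
#' at its endpoints. When exactly one endpoint touches the exterior, the
#' boundary variant applies instead: the collapsing margin wall is replaced
#' by a small free boundary of the third cell, which thereby reaches the
#' tissue margin (a and b detach). An edge with the exterior at both
#' endpoints (a two-cell bridge) is ineligible.
#'
#' @param ts a tissue state.
#' @param h an INNER half-edge of the edge to flip.
#' @return TRUE on success, FALSE if the edge is ineligible.
#' @export
flip_edge <- function(ts, h) {
  if (ts$he_kind[h] != KIND_INNER) return(FALSE)
  t <- ts$he_twin[h]
  A <- ts$he_cell[h]; B <- ts$he_cell[t]
  u <- ts$he_origin[h]; v <- ts$he_origin[t]
  cu <- cells_at_vertex(ts, u); cv <- cells_at_vertex(ts, v)
  C <- setdiff(cu, c(A, B)); D <- setdiff(cv, c(A, B))
  if (length(C) != 1L || length(D) != 1L) return(FALSE)
  if (C == D) return(FALSE)
  if (C == EXTERIOR && D == EXTERIOR) return(FALSE)
  if (xor(C == EXTERIOR, D == EXTERIOR)) {
    hh <- if (D == EXTERIOR) h else t
    return(flip_edge_boundary(ts, hh))
  }
  ## cells losing the edge must keep at least 3 boundary elements after the
  ## flip (triangle cells shed edges through the T2 path, not T1)
  if (length(cell_cycle(ts, A)) < 4L || length(cell_cycle(ts, B)) < 4L)
    return(FALSE)
  ## surrounding half-edges
  cycA <- cell_cycle(ts, A); cycB <- cell_cycle(ts, B)
  he_prev <- cycA[match(h, cycA) - 1 + (match(h, cycA) == 1) * length(cycA)]
  he_next <- ts$he_next[h]
  t_prev <- cycB[match(t, cycB) - 1 + (match(t, cycB) == 1) * length(cycB)]
  t_next <- ts$he_next[t]
  c1 <- ts$he_twin[t_next]      # cell C, ends at u
  c_next <- ts$he_twin[he_prev] # cell C, starts at u
  d1 <- ts$he_twin[he_next]     # cell D, ends at v
  d_next <- ts$he_twin[t_prev]  # cell D, starts at v
  stopifnot(ts$he_cell[c1] == C, ts$he_cell[c_next] == C,
            ts$he_cell[d1] == D, ts$he_cell[d_next] == D)
  saved <- save_mesh_state(ts)
  pu <- c(ts$vx_x[u], ts$vx_y[u]); pv <- c(ts$vx_x[v], ts$vx_y[v])
  m <- (pu + pv) / 2
  L <- ts$params$t1_length
  dir <- pv - pu
  nd <- sqrt(sum(dir^2))
  nA <- if (nd > 1e-12) perp(dir / nd) else c(0, 1)  # toward cell A
  ## vertex u becomes the B-side endpoint v*, vertex v becomes the A-side u*
  ts$vx_x[u] <- m[1] - (L / 2) * nA[1]; ts$vx_y[u] <- m[2] - (L / 2) * nA[2]
  ts$vx_x[v] <- m[1] + (L / 2) * nA[1]; ts$vx_y[v] <- m[2] + (L / 2) * nA[2]
  g <- new_halfedge(ts, u, C, KIND_INNER)   # v* -> u* on the C side
  g2 <- new_halfedge(ts, v, D, KIND_INNER)  # u* -> v* on the D side
  set_twins(ts, g, g2)
  ## relink cycles
  ts$he_next[he_prev] <- he_next            # A loses the edge
  ts$he_next[t_prev] <- t_next              # B loses the edge
  ts$he_next[c1] <- g; ts$he_next[g] <- c_next
  ts$he_next[d1] <- g2; ts$he_next[g2] <- d_next
  ## origin relinks: C continues from u*, D continues from v*
  ts$he_origin[c_next] <- v
  ts$he_origin[d_next] <- u
  if (ts$cl_boundary[A] == h) ts$cl_boundary[A] <- he_next
  if (ts$cl_boundary[B] == t) ts$cl_boundary[B] <- t_next
  kill_halfedge(ts, h); kill_halfedge(ts, t)
  ts$vx_out[u] <- g; ts$vx_out[v] <- g2
  for (cid in c(A, B, C, D)) refit_cell_arcs(ts, cid)
  ## geometric postcondition: all four cells keep a positive area (the
  ## relocated endpoints can invert a thin neighbor, and a boundary cell
  ## with an inward bulge can lose its whole area even though its chord
  ## polygon stays positive)
  areas <- vapply(c(A, B, C, D), function(cid) {
    tryCatch(cell_area(ts, cid), error = function(e) -1)
  }, numeric(1))
  if (any(!is.finite(areas)) || any(areas <= 1e-9)) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  log_event(ts, topo_event("EDGE_FLIP", c(A, B, C, D), created = c(g, g2),
                           removed = c(h, t)))
  TRUE
}

## Boundary T1: half-edge h runs u -> v with cell A on its left, B on its
## right, cell C the third cell at u, and the exterior at v. The wall
## between A and B is removed; A and B detach and C gains a short free
## boundary reaching the tissue margin.
flip_edge_boundary <- function(ts, h) {
  t <- ts$he_twin[h]
  A <- ts$he_cell[h]; B <- ts$he_cell[t]
  u <- ts$he_origin[h]; v <- ts$he_origin[t]
  cycA <- cell_cycle(ts, A); cycB <- cell_cycle(ts, B)
  if (length(cycA) < 4L || length(cycB) < 4L) return(FALSE)
  saved <- save_mesh_state(ts)
  pA <- cycA[match(h, cycA) - 1 + (match(h, cycA) == 1) * length(cycA)]
  nA <- ts$he_next[h]
  pB <- cycB[match(t, cycB) - 1 + (match(t, cycB) == 1) * length(cycB)]
  nB <- ts$he_next[t]
  if (ts$he_kind[nA] != KIND_OUTER || ts$he_kind[pB] != KIND_OUTER)
    return(FALSE)
  cC_out <- ts$he_twin[pA]
  cC_in <- ts$he_twin[nB]
  C <- ts$he_cell[cC_out]
  if (C == EXTERIOR || ts$he_cell[cC_in] != C) return(FALSE)
  pu <- c(ts$vx_x[u], ts$vx_y[u]); pv <- c(ts$vx_x[v], ts$vx_y[v])
  m <- (pu + pv) / 2
  L <- ts$params$t1_length
  dir <- pv - pu
  nd <- sqrt(sum(dir^2))
  nA_dir <- if (nd > 1e-12) perp(dir / nd) else c(0, 1)  # toward cell A
  ts$vx_x[u] <- m[1] + (L / 2) * nA_dir[1]; ts$vx_y[u] <- m[2] + (L / 2) * nA_dir[2]
  ts$vx_x[v] <- m[1] - (L / 2) * nA_dir[1]; ts$vx_y[v] <- m[2] - (L / 2) * nA_dir[2]
  ts$he_next[pA] <- nA; ts$he_origin[nA] <- u
  ts$he_next[pB] <- nB; ts$he_origin[nB] <- v
  g <- new_halfedge(ts, v, C, KIND_OUTER)
  g_ext <- new_halfedge(ts, u, EXTERIOR, KIND_OUTER)
  set_twins(ts, g, g_ext)
  ts$he_next[cC_in] <- g; ts$he_next[g] <- cC_out
  if (ts$cl_boundary[A] == h) ts$cl_boundary[A] <- nA
  if (ts$cl_boundary[B] == t) ts$cl_boundary[B] <- nB
  kill_halfedge(ts, h); kill_halfedge(ts, t)
  ts$vx_out[u] <- nA; ts$vx_out[v] <- nB
  rebuild_exterior_next(ts)
  for (cid in c(A, B, C)) refit_cell_arcs(ts, cid)
  areas <- vapply(c(A, B, C), function(cid) {
    tryCatch(cell_area(ts, cid), error = function(e) -1)
  }, numeric(1))
  if (any(!is.finite(areas)) || any(areas <= 1e-9)) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  log_event(ts, topo_event("EDGE_FLIP", c(A, B, C), created = c(g, g_ext),
                           removed = c(h, t)))
  TRUE
}

## Margin closure: the inverse of the boundary T1. A tiny free arc of cell C
## between its walls to A and to B collapses; A and B come into contact and
## gain an inner wall of length t1_length, C retreats from the margin at
## this point. Half-edge g is the cell-side arc (travelling v -> u with A
## the third cell at u and B at v).
close_margin_arc <- function(ts, g) {
  if (ts$he_kind[g] != KIND_OUTER || ts$he_cell[g] == EXTERIOR) return(FALSE)
  saved <- save_mesh_state(ts)
  C <- ts$he_cell[g]
  v <- ts$he_origin[g]; u <- he_dest(ts, g)
  cu <- cells_at_vertex(ts, u); cv <- cells_at_vertex(ts, v)
  A <- setdiff(cu, c(C, EXTERIOR)); B <- setdiff(cv, c(C, EXTERIOR))
  if (length(A) != 1L || length(B) != 1L || A == B) return(FALSE)
  cycC <- cell_cycle(ts, C)
  if (length(cycC) < 4L) return(FALSE)
  cC_out <- ts$he_next[g]
  cC_in <- cycC[match(g, cycC) - 1 + (match(g, cycC) == 1) * length(cycC)]
  if (ts$he_kind[cC_out] != KIND_INNER || ts$he_kind[cC_in] != KIND_INNER)
    return(FALSE)
  pA <- ts$he_twin[cC_out]     # A side wall, ends at u
  nB <- ts$he_twin[cC_in]      # B side wall, starts at v
  if (ts$he_cell[pA] != A || ts$he_cell[nB] != B) return(FALSE)
  nA <- ts$he_next[pA]         # A's free boundary leaving u
  cycB <- cell_cycle(ts, B)
  pB <- cycB[match(nB, cycB) - 1 + (match(nB, cycB) == 1) * length(cycB)]
  if (ts$he_kind[nA] != KIND_OUTER || ts$he_kind[pB] != KIND_OUTER)
    return(FALSE)
  g_ext <- ts$he_twin[g]
  pu <- c(ts$vx_x[u], ts$vx_y[u]); pv <- c(ts$vx_x[v], ts$vx_y[v])
  m <- (pu + pv) / 2
  zc <- cell_centroid(ts, C)
  n_dir <- zc - m
  nd <- sqrt(sum(n_dir^2))
  n_dir <- if (nd > 1e-12) n_dir / nd else c(0, 1)
  L <- ts$params$t1_length
  ts$vx_x[u] <- m[1] + (L / 2) * n_dir[1]; ts$vx_y[u] <- m[2] + (L / 2) * n_dir[2]
  ts$vx_x[v] <- m[1] - (L / 2) * n_dir[1]; ts$vx_y[v] <- m[2] - (L / 2) * n_dir[2]
  h <- new_halfedge(ts, u, A, KIND_INNER)
  h2 <- new_halfedge(ts, v, B, KIND_INNER)
  set_twins(ts, h, h2)
  ts$he_next[pA] <- h; ts$he_next[h] <- nA; ts$he_origin[nA] <- v
  ts$he_next[pB] <- h2; ts$he_next[h2] <- nB; ts$he_origin[nB] <- u
  ts$he_next[cC_in] <- cC_out
  if (ts$cl_boundary[C] == g) ts$cl_boundary[C] <- cC_out
  kill_halfedge(ts, g); kill_halfedge(ts, g_ext)
  ts$vx_out[u] <- h; ts$vx_out[v] <- h2
  rebuild_exterior_next(ts)
  for (cid in c(A, B, C)) refit_cell_arcs(ts, cid)
  areas <- vapply(c(A, B, C), function(cid) {
    tryCatch(cell_area(ts, cid), error = function(e) -1)
  }, numeric(1))
  if (any(!is.finite(areas)) || any(areas <= 1e-9)) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  log_event(ts, topo_event("EDGE_FLIP", c(A, B, C), created = c(h, h2),
                           removed = c(g, g_ext)))
  TRUE
}

## ---- division --------------------------------------------------------------

## Crossings of the line {p : (p - p0) . n = 0} with the boundary of cell cid,
## plus the area of the part on the positive-n side. Returns NULL when the
## line does not cut the boundary in exactly two regular points.
split_geometry <- function(ts, cid, theta, offset) {
  u <- c(cos(theta), sin(theta)); n <- perp(u)
  cen <- cell_centroid(ts, cid)
  if (any(!is.finite(cen))) return(NULL)
  p0 <- cen + offset * n
  sdist <- function(px, py) (px - p0[1]) * n[1] + (py - p0[2]) * n[2]
  hes <- cell_cycle(ts, cid)
  tol <- 1e-9
  crossings <- list()
  for (i in seq_along(hes)) {
    h <- hes[i]
    av <- ts$he_origin[h]; bv <- he_dest(ts, h)
    pa <- c(ts$vx_x[av], ts$vx_y[av]); pb <- c(ts$vx_x[bv], ts$vx_y[bv])
    sa <- sdist(pa[1], pa[2]); sb <- sdist(pb[1], pb[2])
    if (abs(sa) < tol || abs(sb) < tol) return("degenerate")
    if (ts$he_kind[h] == KIND_INNER) {
      if (sa * sb < 0) {
        tt <- sa / (sa - sb)
        pt <- pa + tt * (pb - pa)
        crossings[[length(crossings) + 1L]] <-
          list(i = i, h = h, pt = pt, s = tt, enter_left = sb > 0)
      }
    } else {
      g <- arc_geometry(ts, h)
      hc <- sdist(g$center[1], g$center[2])
      if (abs(hc) < g$radius) {
        foot <- g$center - hc * n
        dd <- sqrt(g$radius^2 - hc^2)
        a0 <- atan2(pa[2] - g$center[2], pa[1] - g$center[1])
        for (sgn in c(-1, 1)) {
          q <- foot + sgn * dd * u
          aq <- (g$sweep * (atan2(q[2] - g$center[2], q[1] - g$center[1]) - a0)) %% (2 * pi)
          if (aq > 1e-6 && aq < g$angle - 1e-6) {
            ## direction of travel at q decides entering side
            tv <- g$sweep * perp(q - g$center)  # travel tangent
            crossings[[length(crossings) + 1L]] <-
              list(i = i, h = h, pt = q, s = aq / g$angle,
                   enter_left = (tv[1] * n[1] + tv[2] * n[2]) > 0)
          }
        }
      }
    }
  }
  if (length(crossings) != 2L) return(NULL)
  ord <- order(vapply(crossings, function(cr) cr$i + cr$s, numeric(1)))
  crossings <- crossings[ord]
  if (crossings[[1]]$enter_left == crossings[[2]]$enter_left) return(NULL)
  cin <- if (crossings[[1]]$enter_left) crossings[[1]] else crossings[[2]]
  cout <- if (crossings[[1]]$enter_left) crossings[[2]] else crossings[[1]]
  ## walk the left part: from cin$pt along the cycle to cout$pt
  pts <- list(cin$pt)
  seg_area <- 0
  i <- cin$i
  first <- TRUE
  repeat {
    h <- hes[i]
    arc_piece_seg <- function(g, p_from, p_to) {
      th <- (g$sweep * (atan2(p_to[2] - g$center[2], p_to[1] - g$center[1]) -
             atan2(p_from[2] - g$center[2], p_from[1] - g$center[1]))) %% (2 * pi)
      g$seg_sign * circular_segment_area(g$radius, th)
    }
    if (i == cout$i && (cin$i != cout$i || (first && cout$s > cin$s) || !first)) {
      ## partial element ending at cout
      if (ts$he_kind[h] == KIND_OUTER) {
        g <- arc_geometry(ts, h)
        seg_area <- seg_area + arc_piece_seg(g, pts[[length(pts)]], cout$pt)
      }
      pts[[length(pts) + 1L]] <- cout$pt
      break
    }
    ## full remainder of element i (from current point to its end vertex)
    if (ts$he_kind[h] == KIND_OUTER) {
      g <- arc_geometry(ts, h)
      bv <- he_dest(ts, h)
      pb <- c(ts$vx_x[bv], ts$vx_y[bv])
      seg_area <- seg_area + arc_piece_seg(g, pts[[length(pts)]], pb)
    }
    bv <- he_dest(ts, h)
    pts[[length(pts) + 1L]] <- c(ts$vx_x[bv], ts$vx_y[bv])
    i <- if (i == length(hes)) 1L else i + 1L
    first <- FALSE
    if (length(pts) > length(hes) + 3L) return(NULL)
  }
  px <- vapply(pts, `[`, numeric(1), 1)
  py <- vapply(pts, `[`, numeric(1), 2)
  a_poly <- sum(px * c(py[-1], py[1]) - c(px[-1], px[1]) * py) / 2
  list(cin = cin, cout = cout, area_left = a_poly + seg_area, p0 = p0,
       u = u, n = n)
}

#' Divide a cell
#'
#' Inserts a division wall: a chord at the given orientation, translated
#' along its normal until the two parts have equal areas (bisection, relative
#' difference below 0.1%). The mother keeps its id (one daughter); a new cell
#' id is created for the other daughter. Daughter areas sum to the mother
#' area exactly at insertion.
#'
#' @param ts a tissue state.
#' @param cid id of the dividing cell.
#' @param orientation chord direction in radians, or NULL ("AUTO") for a
#'   uniform random direction from the topology random stream.
#' @return the id of the new daughter cell.
#' @export
divide_cell <- function(ts, cid, orientation = NULL) {
  for (attempt in 1:10) {
    theta <- if (!is.null(orientation) && attempt == 1) orientation else
      with_substream(ts, "topology", function() stats::runif(1, 0, pi))
    res <- divide_cell_at(ts, cid, theta)
    if (!is.null(res)) return(res)
  }
  ## highly non-convex transients can defeat the chord search; the cell
  ## keeps growing and division is retried at the next step
  warning("no valid division plane for cell ", cid, "; deferred")
  NA_integer_
}

divide_cell_at <- function(ts, cid, theta) {
  if (is_isolated(ts, cid)) {
    r <- ts$cl_radius[cid]
    z <- c(ts$cl_cx[cid], ts$cl_cy[cid])
    u <- c(cos(theta), sin(theta))
    w1 <- new_vertex(ts, z[1] + r * u[1], z[2] + r * u[2])
    w2 <- new_vertex(ts, z[1] - r * u[1], z[2] - r * u[2])
    tgt <- ts$cl_target[cid]
    nrm <- c(-u[2], u[1])
    ## provisional daughter centers on opposite sides of the division plane
    ts$cl_cx[cid] <- z[1] + r / 2 * nrm[1]; ts$cl_cy[cid] <- z[2] + r / 2 * nrm[2]
    ch_a <- isolated_to_lens(ts, cid, w1, w2)
    did <- new_cell(ts, type = ts$cl_type[cid], color = ts$cl_color[cid],
                    cx = z[1] - r / 2 * nrm[1], cy = z[2] - r / 2 * nrm[2])
    ts$cl_radius[did] <- r
    ch_b <- isolated_to_lens(ts, did, w1, w2)
    set_twins(ts, ch_a, ch_b)
    ts$cl_target[cid] <- tgt / 2
    ts$cl_target[did] <- tgt / 2
    rebuild_vertex_out(ts, c(w1, w2))
    rebuild_exterior_next(ts)
    refit_cell_arcs(ts, cid); refit_cell_arcs(ts, did)
    update_centers(ts, c(cid, did))
    log_event(ts, topo_event("DIVISION", c(cid, did), created = did))
    return(did)
  }
  area <- cell_area(ts, cid)
  if (!is.finite(area) || area <= 0) return(NULL)
  ## bracket the equal-area offset
  hes <- cell_cycle(ts, cid)
  vs <- unique(ts$he_origin[hes])
  n <- perp(c(cos(theta), sin(theta)))
  cen <- cell_centroid(ts, cid)
  if (any(!is.finite(cen))) return(NULL)
  proj <- (ts$vx_x[vs] - cen[1]) * n[1] + (ts$vx_y[vs] - cen[2]) * n[2]
  lo <- min(proj); hi <- max(proj)
  f <- function(o) {
    sg <- split_geometry(ts, cid, theta, o)
    if (is.null(sg)) return(NULL)
    if (identical(sg, "degenerate")) return("degenerate")
    sg$area_left - area / 2
  }
  ## area left of the line decreases as offset grows; find a valid bracket
  o_lo <- lo + 0.02 * (hi - lo); o_hi <- hi - 0.02 * (hi - lo)
  f_lo <- f(o_lo); f_hi <- f(o_hi)
  nudge <- 1e-4 * (hi - lo)
  tries <- 0
  while ((is.null(f_lo) || identical(f_lo, "degenerate")) && tries < 8) {
    o_lo <- o_lo + nudge; f_lo <- f(o_lo); tries <- tries + 1
  }
  tries <- 0
  while ((is.null(f_hi) || identical(f_hi, "degenerate")) && tries < 8) {
    o_hi <- o_hi - nudge; f_hi <- f(o_hi); tries <- tries + 1
  }
  if (is.null(f_lo) || is.null(f_hi) ||
      identical(f_lo, "degenerate") || identical(f_hi, "degenerate") ||
      f_lo * f_hi > 0) return(NULL)
  for (it in 1:60) {
    o_mid <- (o_lo + o_hi) / 2
    f_mid <- f(o_mid)
    if (is.null(f_mid)) return(NULL)
    if (identical(f_mid, "degenerate")) { o_mid <- o_mid + nudge * 1e-3; f_mid <- f(o_mid) }
    if (is.null(f_mid) || identical(f_mid, "degenerate")) return(NULL)
    if (abs(f_mid) < 1e-3 * 0.5 * area && it > 20) break
    if (sign(f_mid) == sign(f_lo)) { o_lo <- o_mid; f_lo <- f_mid } else { o_hi <- o_mid; f_hi <- f_mid }
  }
  sg <- split_geometry(ts, cid, theta, o_mid)
  if (is.null(sg) || identical(sg, "degenerate")) return(NULL)

  tgt <- ts$cl_target[cid]
  ## perform the splits; cin first in cycle order or not -- handle both
  s_in <- split_edge(ts, sg$cin$h, sg$cin$pt)
  ## if both crossings are on the same element and cout comes after cin, the
  ## cout point now lies on the second piece
  h_out <- sg$cout$h
  if (sg$cout$h == sg$cin$h && sg$cout$s > sg$cin$s) h_out <- s_in$h2
  s_out <- split_edge(ts, h_out, sg$cout$pt)
  w_in <- s_in$w; w_out <- s_out$w
  ## left part: s_in$h2 ... s_out$h1 ; right part: s_out$h2 ... s_in$h1
  g_left <- new_halfedge(ts, w_out, cid, KIND_INNER)
  did <- new_cell(ts, type = ts$cl_type[cid], color = ts$cl_color[cid])
  g_right <- new_halfedge(ts, w_in, did, KIND_INNER)
  set_twins(ts, g_left, g_right)
  ts$he_next[s_out$h1] <- g_left
  ts$he_next[g_left] <- s_in$h2
  ts$he_next[s_in$h1] <- g_right
  ts$he_next[g_right] <- s_out$h2
  ## assign right cycle to the daughter
  rc <- cycle_halfedges(ts, g_right)
  ts$he_cell[rc[rc != g_right]] <- did
  ts$cl_boundary[cid] <- g_left
  ts$cl_boundary[did] <- g_right
  ts$cl_arc_r[did] <- ts$cl_arc_r[cid]
  ts$cl_arc_major[did] <- FALSE
  ts$vx_out[w_in] <- g_right
  ts$vx_out[w_out] <- g_left
  ## daughter areas from the split geometry itself (the arc branch flags of
  ## the pieces are not inherited reliably); refitting to these areas then
  ## reconstructs each daughter's bulge on the correct branch
  a_left <- sg$area_left
  a_right <- area - a_left
  ts$cl_target[cid] <- a_left
  ts$cl_target[did] <- a_right
  refit_cell_arcs(ts, cid)
  refit_cell_arcs(ts, did)
  ts$cl_target[cid] <- tgt * a_left / area
  ts$cl_target[did] <- tgt * a_right / area
  update_centers(ts, c(cid, did))
  log_event(ts, topo_event("DIVISION", c(cid, did), created = did))
  did
}

## ---- cell removal (death) --------------------------------------------------

#' Remove a cell from the tissue (apoptosis completion)
#'
#' The cell's free boundaries are deleted and every neighbor's wall facing
#' the dead cell becomes a free (arc) boundary bulging into the hole left
#' behind; mechanics subsequently closes the hole (or the boundary indents,
#' for a peripheral cell). Degree-2 vertices created on former junctions with
#' the exterior are eliminated by merging the neighbor's consecutive arcs.
#'
#' @param ts a tissue state.
#' @param cid id of the cell to remove.
#' @return TRUE.
#' @export
remove_cell <- function(ts, cid, force = FALSE) {
  if (is_isolated(ts, cid)) {
    kill_cell(ts, cid)
    log_event(ts, topo_event("DEATH", cid, removed = cid))
    return(TRUE)
  }
  saved <- save_mesh_state(ts)
  res <- tryCatch(remove_cell_impl(ts, cid, force), error = function(e) e)
  if (inherits(res, "error") || !isTRUE(res)) {
    restore_mesh_state(ts, saved)
    return(FALSE)
  }
  TRUE
}

remove_cell_impl <- function(ts, cid, force = FALSE) {
  cyc <- cell_cycle(ts, cid)
  nbs <- neighbors(ts, cid)
  for (h in cyc) {
    t <- ts$he_twin[h]
    if (ts$he_kind[h] == KIND_INNER) {
      ## the neighbor's wall becomes a free boundary
      ts$he_kind[t] <- KIND_OUTER
      ts$he_kind[h] <- KIND_OUTER
      ts$he_cell[h] <- EXTERIOR
    } else {
      ## the dead cell's arc and its exterior twin disappear
      kill_halfedge(ts, h)
      kill_halfedge(ts, t)
    }
  }
  kill_cell(ts, cid)
  merge_all_consecutive_outer(ts)
  ## drop vertices no longer referenced
  alive_org <- unique(ts$he_origin[halfedge_ids(ts)])
  gone <- setdiff(vertex_ids(ts), alive_org)
  for (v in gone) kill_vertex(ts, v)
  rebuild_vertex_out(ts)
  rebuild_exterior_next(ts)
  for (nb in nbs) if (ts$cl_alive[nb]) refit_cell_arcs(ts, nb)
  ## postcondition: every former neighbor still closes (and, unless the
  ## removal is forced to excise an already-degenerate sliver, keeps a
  ## positive area)
  for (nb in nbs) {
    if (!ts$cl_alive[nb]) next
    a <- tryCatch(cell_area(ts, nb), error = function(e) NA_real_)
    if (!is.finite(a)) return(FALSE)
    if (!force && a <= 1e-9) return(FALSE)
  }
  log_event(ts, topo_event("DEATH", cid, removed = cid))
  TRUE
}

## ---- detection -------------------------------------------------------------

#' Detect pending topological events
#'
#' Scans the state for: contacts (two free-boundary circles overlapping by
#' more than `contact_tol`, intersection points on both arcs), T1 edge flips
#' (inner edges shorter than `t1_length` that are not being stretched open),
#' and T2 void removals (3-sided voids below `t2_area`).
#'
#' @param ts a tissue state.
#' @param forces optional vertex force matrix (rows indexed by vertex id)
#'   used for the extension check on short edges; without it any short edge
#'   is flip-eligible.
#' @return list of event descriptors (kind plus identifying ids).
#' @export
detect_events <- function(ts, forces = NULL, exclude = integer(0)) {
  out <- list()
  params <- ts$params
  ## contacts: vectorized circle-overlap prefilter, exact checks on candidates
  arcs_df <- free_boundary_arcs(ts)
  nA <- nrow(arcs_df)
  if (nA >= 2) {
    d2 <- outer(arcs_df$cx, arcs_df$cx, "-")^2 + outer(arcs_df$cy, arcs_df$cy, "-")^2
    rsum <- outer(arcs_df$r, arcs_df$r, "+") - params$contact_tol
    cand <- which(upper.tri(d2) & d2 < rsum^2 &
                  outer(arcs_df$cell, arcs_df$cell, "!="), arr.ind = TRUE)
    seen_pairs <- character(0)
    if (nrow(cand)) for (k in seq_len(nrow(cand))) {
      a <- arc_row(cand[k, 1], arcs_df); b <- arc_row(cand[k, 2], arcs_df)
      key <- paste(min(a$cell, b$cell), max(a$cell, b$cell))
      if (key %in% seen_pairs) next
      ov <- circle_overlap(a, b, params$contact_tol)
      if (is.null(ov)) next
      ma <- max(0.02, 0.06 / a$r); mb <- max(0.02, 0.06 / b$r)
      if (!(angle_on_arc(a, ov$p1, ma) && angle_on_arc(a, ov$p2, ma) &&
            angle_on_arc(b, ov$p1, mb) && angle_on_arc(b, ov$p2, mb))) next
      adj <- if (is_isolated(ts, a$cell)) FALSE else b$cell %in% neighbors(ts, a$cell)
      if (adj) next
      seen_pairs <- c(seen_pairs, key)
      out[[length(out) + 1L]] <- list(kind = "CONTACT",
                                      cells = c(a$cell, b$cell),
                                      depth = ov$depth)
    }
  }
  ## T1 flips
  hes <- halfedge_ids(ts)
  inner <- hes[ts$he_kind[hes] == KIND_INNER & hes < ts$he_twin[hes] &
               ts$he_cell[hes] != EXTERIOR]
  if (length(inner)) {
    a <- ts$he_origin[inner]; b <- ts$he_origin[ts$he_twin[inner]]
    len <- sqrt((ts$vx_x[a] - ts$vx_x[b])^2 + (ts$vx_y[a] - ts$vx_y[b])^2)
    short <- inner[len < params$t1_length]
    short <- setdiff(short, c(exclude, ts$he_twin[exclude]))
    for (h in short) {
      u <- ts$he_origin[h]; v <- ts$he_origin[ts$he_twin[h]]
      if (!is.null(forces) && nrow(forces) >= max(u, v)) {
        ev_dir <- c(ts$vx_x[v] - ts$vx_x[u], ts$vx_y[v] - ts$vx_y[u])
        stretch <- sum((forces[v, ] - forces[u, ]) * ev_dir)
        if (stretch > 0) next   # being pulled open; no flip
      }
      out[[length(out) + 1L]] <- list(kind = "EDGE_FLIP", he = h)
    }
  }
  ## margin closures: a free arc whose chord has collapsed (the wedge of
  ## tissue boundary between two walls closing up)
  arcs_cells <- hes[ts$he_kind[hes] == KIND_OUTER & ts$he_cell[hes] != EXTERIOR]
  if (length(arcs_cells)) {
    a <- ts$he_origin[arcs_cells]; b <- ts$he_origin[ts$he_twin[arcs_cells]]
    clen <- sqrt((ts$vx_x[a] - ts$vx_x[b])^2 + (ts$vx_y[a] - ts$vx_y[b])^2)
    for (h in setdiff(arcs_cells[clen < params$t1_length],
                      c(exclude, ts$he_twin[exclude]))) {
      u <- ts$he_origin[h]; v <- ts$he_origin[ts$he_twin[h]]
      if (!is.null(forces) && nrow(forces) >= max(u, v)) {
        ev_dir <- c(ts$vx_x[v] - ts$vx_x[u], ts$vx_y[v] - ts$vx_y[u])
        stretch <- sum((forces[v, ] - forces[u, ]) * ev_dir)
        if (stretch > 0) next
      }
      out[[length(out) + 1L]] <- list(kind = "EDGE_FLIP", he = h)
    }
  }
  ## T2 voids
  comps <- exterior_components(ts)
  for (comp in comps) {
    if (length(comp) != 3L) next
    if (anyDuplicated(ts$he_cell[ts$he_twin[comp]])) next
    ## voids (bounded components) traverse counterclockwise: positive chord
    ## polygon; the unbounded outer boundary is clockwise
    if (cycle_polygon_area(ts, comp) <= 0) next
    a <- void_area(ts, comp)
    if (a < params$t2_area) {
      out[[length(out) + 1L]] <- list(kind = "VOID_REMOVAL", comp = comp)
    }
  }
  out
}

## Apply detected events in the canonical order (contacts, flips, voids),
## each in ascending id order; returns number applied.
apply_events <- function(ts, events) {
  n_applied <- 0L
  dbg <- isTRUE(getOption("epitissue.validate_events"))
  if (dbg && length(events)) {
    bad0 <- validate_tissue(ts)
    if (length(bad0)) stop("state invalid before event batch: ", bad0[1])
  }
  after <- function(label, e) {
    if (dbg) {
      bad <- validate_tissue(ts)
      if (length(bad)) {
        stop("invalid state after ", label, " involving cells ",
             paste(e$cells, collapse = ","), ": ", bad[1])
      }
    }
  }
  kinds <- vapply(events, function(e) e$kind, character(1))
  for (e in events[kinds == "CONTACT"]) {
    if (!all(ts$cl_alive[e$cells])) next
    ci <- min(e$cells); cj <- max(e$cells)
    if (!is_isolated(ts, ci) && cj %in% neighbors(ts, ci)) next
    if (isTRUE(insert_contact_edge(ts, ci, cj))) {
      n_applied <- n_applied + 1L
      after("CONTACT", e)
    }
  }
  for (e in events[kinds == "EDGE_FLIP"]) {
    if (!ts$he_alive[e$he]) next
    outer <- ts$he_kind[e$he] == KIND_OUTER
    ok <- if (outer) close_margin_arc(ts, e$he) else flip_edge(ts, e$he)
    if (isTRUE(ok)) {
      n_applied <- n_applied + 1L
      after(if (outer) "MARGIN_CLOSURE" else "EDGE_FLIP", e)
    }
  }
  for (e in events[kinds == "VOID_REMOVAL"]) {
    if (!all(ts$he_alive[e$comp])) next
    if (isTRUE(remove_void(ts, e$comp))) {
      n_applied <- n_applied + 1L
      after("VOID_REMOVAL", e)
    }
  }
  n_applied
}
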