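## Geometry of polygon-plus-arc cells.
##
## A non-isolated cell is bounded by a counterclockwise cycle of half-edges.
## INNER edges are straight; OUTER edges are circular arcs bulging outward,
## all arcs of one cell sharing one radius (one pressure per cell). The cell
## area is the shoelace area of the vertex cycle plus one circular-segment
## correction per arc.

#' Area of a circular segment
#'
#' The area enclosed between a chord and its arc, r^2 (theta - sin theta)/2,
#' for central angle theta in [0, 2*pi].
#'
#' @param radius arc radius (>= 0).
#' @param angle signed central angle in radians, within [0, 2*pi].
#' @return the segment area.
#' @export
circular_segment_area <- function(radius, angle) {
  if (any(radius < 0)) stop("radius must be >= 0")
  if (any(angle < 0 | angle > 2 * pi + 1e-12)) {
    stop("angle must lie in [0, 2*pi]")
  }
  radius^2 * (angle - sin(angle)) / 2
}

perp <- function(v) c(-v[2], v[1])

## Geometry of the arc carried by OUTER half-edge h (cell side): circle
## center, radius, chord endpoints a -> b in the cell's travel direction
## (always counterclockwise around the circle center), and central angle.
## Minor arcs (angle <= pi; the usual bulge of a tissue boundary cell) have
## the center on the interior side of the chord; major arcs (a single free
## boundary wrapping most of the way around, e.g. a lens cell after first
## contact) have it on the exterior side.
## A negative stored radius denotes an inward bulge (the free boundary
## curves into the cell; Laplace pressure eta / r is then negative), as for
## an overfull boundary cell or a cell bulging into a hole left by a dead
## neighbor. `sweep` is +1 when the boundary travels counterclockwise
## around the circle center (outward bulges, minor or major) and -1 for the
## clockwise travel of inward bulges; `seg_sign` says whether the segment
## area is added to or subtracted from the chord polygon.
arc_geometry <- function(ts, h) {
  if (ts$he_cell[h] == EXTERIOR) h <- ts$he_twin[h]
  cid <- ts$he_cell[h]
  a <- c(ts$vx_x[ts$he_origin[h]], ts$vx_y[ts$he_origin[h]])
  bv <- he_dest(ts, h)
  b <- c(ts$vx_x[bv], ts$vx_y[bv])
  r_signed <- ts$cl_arc_r[cid]
  inward <- r_signed < 0
  r <- abs(r_signed)
  L <- sqrt(sum((b - a)^2))
  r <- max(r, L / 2)            # half circle is the tightest chord fit
  mid <- (a + b) / 2
  major <- isTRUE(ts$cl_arc_major[cid]) && !inward
  n_in <- perp((b - a) / L)     # interior is left of a->b
  h_off <- sqrt(max(r^2 - (L / 2)^2, 0))
  cen <- mid + (if (major || inward) -h_off else h_off) * n_in
  th_minor <- 2 * asin(min(1, L / (2 * r)))
  theta <- if (major) 2 * pi - th_minor else th_minor
  list(cell = cid, a = a, b = b, center = cen, radius = r, chord = L,
       angle = theta, sweep = if (inward) -1 else 1,
       seg_sign = if (inward) -1 else 1)
}

## Central angle of the arc of OUTER half-edge h (2*pi only for a full disk).
arc_angle <- function(ts, h) arc_geometry(ts, h)$angle

## Shoelace area of the (chord) polygon of a half-edge cycle.
cycle_polygon_area <- function(ts, hes) {
  vs <- ts$he_origin[hes]
  x <- ts$vx_x[vs]; y <- ts$vx_y[vs]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Cell area
#'
#' Isolated cells: pi r^2. Otherwise the signed shoelace area of the vertex
#' cycle plus a circular-segment correction for every outer (arc) edge.
#'
#' @param ts a tissue state.
#' @param cid cell id.
#' @return the area, always > 0 for a valid cell.
#' @export
cell_area <- function(ts, cid) {
  if (is_isolated(ts, cid)) return(pi * ts$cl_radius[cid]^2)
  hes <- cell_cycle(ts, cid)
  a <- cycle_polygon_area(ts, hes)
  for (h in hes[ts$he_kind[hes] == KIND_OUTER]) {
    g <- arc_geometry(ts, h)
    a <- a + g$seg_sign * circular_segment_area(g$radius, g$angle)
  }
  a
}

#' Cell centroid
#'
#' Area centroid of the polygon-plus-arcs region (exact center for isolated
#' cells). This is the nominal cell center z_i.
#'
#' @param ts a tissue state.
#' @param cid cell id.
#' @return numeric length-2 centroid.
#' @export
cell_centroid <- function(ts, cid) {
  if (is_isolated(ts, cid)) return(c(ts$cl_cx[cid], ts$cl_cy[cid]))
  hes <- cell_cycle(ts, cid)
  vs <- ts$he_origin[hes]
  x <- ts$vx_x[vs]; y <- ts$vx_y[vs]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a_poly <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / 6
  cy <- sum((y + yn) * cr) / 6
  a_tot <- a_poly
  for (h in hes[ts$he_kind[hes] == KIND_OUTER]) {
    g <- arc_geometry(ts, h)
    a_seg <- circular_segment_area(g$radius, g$angle)
    if (a_seg > 0) {
      ## centroid of a circular segment: distance from circle center along
      ## the arc-midpoint direction (origin direction rotated by angle/2)
      d <- (4 * g$radius * sin(g$angle / 2)^3) / (3 * (g$angle - sin(g$angle)))
      u0 <- g$a - g$center
      half <- g$sweep * g$angle / 2
      dir <- c(cos(half) * u0[1] - sin(half) * u0[2],
               sin(half) * u0[1] + cos(half) * u0[2])
      dir <- dir / sqrt(sum(dir^2))
      cseg <- g$center + d * dir
      w <- g$seg_sign * a_seg
      cx <- cx + w * cseg[1]
      cy <- cy + w * cseg[2]
      a_tot <- a_tot + w
    }
  }
  c(cx, cy) / a_tot
}

## Refresh cached centers of all (or given) cells.
update_centers <- function(ts, cids = cell_ids(ts)) {
  for (cid in cids[!vapply(cids, function(c) is_isolated(ts, c), logical(1))]) {
    cc <- cell_centroid(ts, cid)
    ts$cl_cx[cid] <- cc[1]
    ts$cl_cy[cid] <- cc[2]
  }
  invisible(ts)
}

#' Neighbors of a cell, in boundary order
#'
#' Cells sharing at least one inner edge with `cid`, each reported once, in
#' the order their shared walls are met along the boundary cycle. The
#' traversal touches only the cell's own cycle and twin pointers.
#'
#' @param ts a tissue state.
#' @param cid cell id.
#' @return integer vector of neighbor cell ids (empty for isolated cells).
#' @export
neighbors <- function(ts, cid) {
  if (is_isolated(ts, cid)) return(integer(0))
  hes <- cell_cycle(ts, cid)
  nb <- ts$he_cell[ts$he_twin[hes]]
  unique(nb[nb != EXTERIOR])
}

#' Cells within a number of layers
#'
#' Breadth-first closure of the cell adjacency graph: all cells at graph
#' distance 1..L from `cid` (excluding `cid` itself). Layer 1 equals
#' [neighbors()].
#'
#' @param ts a tissue state.
#' @param cid cell id.
#' @param L number of layers (>= 0).
#' @return integer vector of cell ids.
#' @export
neighbor_layers <- function(ts, cid, L) {
  stopifnot(L >= 0)
  if (L == 0) return(integer(0))
  seen <- c(cid)
  frontier <- cid
  out <- integer(0)
  for (layer in seq_len(L)) {
    nxt <- unique(unlist(lapply(frontier, function(c) neighbors(ts, c))))
    nxt <- setdiff(nxt, seen)
    if (length(nxt) == 0) break
    out <- c(out, nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  out
}

## Adjacency list over all cells (used by brute-force checks and the
## patterning models; one pass over the half-edges).
adjacency_pairs <- function(ts) {
  hes <- halfedge_ids(ts)
  hes <- hes[ts$he_kind[hes] == KIND_INNER & hes < ts$he_twin[hes]]
  ci <- ts$he_cell[hes]
  cj <- ts$he_cell[ts$he_twin[hes]]
  unique(cbind(pmin(ci, cj), pmax(ci, cj)))
}

#' Structural validation
#'
#' Checks every mesh invariant and reports violations instead of throwing:
#' twin involution, closed next-cycles, half-edge/cell consistency, inner
#' edges pairing the same vertex pair in opposite order, degree-3 junction
#' vertices, finite positions, positive cell areas, and isolated-cell
#' bookkeeping.
#'
#' @param ts a tissue state.
#' @return character vector of violation messages (empty if the state is
#'   structurally sound).
#' @export
validate_tissue <- function(ts) {
  bad <- character(0)
  hes <- halfedge_ids(ts)
  for (h in hes) {
    tw <- ts$he_twin[h]
    if (is.na(tw) || tw <= 0L || tw > ts$nhe || !ts$he_alive[tw]) {
      bad <- c(bad, sprintf("halfedge %d: dead or missing twin", h))
      next
    }
    if (ts$he_twin[tw] != h) bad <- c(bad, sprintf("halfedge %d: twin involution broken", h))
    if (tw == h) bad <- c(bad, sprintf("halfedge %d: is its own twin", h))
    inner <- ts$he_kind[h] == KIND_INNER
    twin_interior <- ts$he_cell[tw] != EXTERIOR
    if (inner && !twin_interior)
      bad <- c(bad, sprintf("halfedge %d: INNER but twin is exterior", h))
    if (!inner && ts$he_cell[h] != EXTERIOR && ts$he_cell[tw] != EXTERIOR)
      bad <- c(bad, sprintf("halfedge %d: OUTER between two cells", h))
    if (inner && twin_interior) {
      if (ts$he_origin[h] == ts$he_origin[tw])
        bad <- c(bad, sprintf("halfedge %d: twin shares origin", h))
    }
    nx <- ts$he_next[h]
    if (is.na(nx) || nx <= 0L || nx > ts$nhe || !ts$he_alive[nx]) {
      bad <- c(bad, sprintf("halfedge %d: dead or missing next", h))
    } else if (ts$he_cell[nx] != ts$he_cell[h]) {
      bad <- c(bad, sprintf("halfedge %d: next crosses into another cell", h))
    } else if (ts$he_origin[nx] != ts$he_origin[tw]) {
      bad <- c(bad, sprintf("halfedge %d: next does not start at destination", h))
    }
  }
  ## next-cycles close
  if (length(hes)) {
    seen <- rep(FALSE, ts$nhe)
    for (h in hes) {
      if (seen[h]) next
      cyc <- tryCatch(cycle_halfedges(ts, h), error = function(e) NULL)
      if (is.null(cyc)) {
        bad <- c(bad, sprintf("halfedge %d: next-cycle does not close", h))
      } else {
        seen[cyc] <- TRUE
      }
    }
  }
  ## vertices
  for (v in vertex_ids(ts)) {
    if (!is.finite(ts$vx_x[v]) || !is.finite(ts$vx_y[v]))
      bad <- c(bad, sprintf("vertex %d: non-finite position", v))
    h0 <- ts$vx_out[v]
    if (is.na(h0) || h0 <= 0L || h0 > ts$nhe || !ts$he_alive[h0] ||
        ts$he_origin[h0] != v) {
      bad <- c(bad, sprintf("vertex %d: bad outgoing half-edge", v))
      next
    }
    star <- tryCatch(vertex_star(ts, v), error = function(e) NULL)
    if (is.null(star)) {
      bad <- c(bad, sprintf("vertex %d: rotation does not close", v))
    } else if (length(star) != 3L) {
      bad <- c(bad, sprintf("vertex %d: degree %d (must be 3)", v, length(star)))
    }
  }
  ## cells
  for (cid in cell_ids(ts)) {
    if (is_isolated(ts, cid)) {
      if (!is.finite(ts$cl_radius[cid]) || ts$cl_radius[cid] <= 0)
        bad <- c(bad, sprintf("cell %d: isolated without positive radius", cid))
      next
    }
    b <- ts$cl_boundary[cid]
    if (!ts$he_alive[b] || ts$he_cell[b] != cid) {
      bad <- c(bad, sprintf("cell %d: boundary pointer invalid", cid))
      next
    }
    a <- tryCatch(cell_area(ts, cid), error = function(e) NA_real_)
    if (!is.finite(a) || a <= 0)
      bad <- c(bad, sprintf("cell %d: non-positive or invalid area", cid))
    hes_c <- tryCatch(cell_cycle(ts, cid), error = function(e) integer(0))
    if (length(hes_c) && any(ts$he_cell[hes_c] != cid))
      bad <- c(bad, sprintf("cell %d: cycle contains foreign half-edges", cid))
  }
  bad
}

## Total tissue area (sum of cell areas).
total_area <- function(ts) {
  sum(vapply(cell_ids(ts), function(c) cell_area(ts, c), numeric(1)))
}

## ---- arc refitting --------------------------------------------------------

## Refit the free-boundary arcs of a cell so its area equals the target.
## All arcs of one cell share one radius (one pressure). A cell with a
## single arc solves for the central angle theta in (0, 2*pi), so the arc
## may be minor or major (segment area strictly increasing in theta). Cells
## with several arcs use the minor branch: segment sum monotone decreasing
## in r on [Lmax/2, Inf), clamped at half circles if even those cannot
## supply the needed bulge.
refit_cell_arcs <- function(ts, cid, target = ts$cl_target[cid]) {
  if (is_isolated(ts, cid)) {
    ts$cl_radius[cid] <- sqrt(max(target, 1e-12) / pi)
    return(invisible(ts))
  }
  hes <- cell_cycle(ts, cid)
  outer <- hes[ts$he_kind[hes] == KIND_OUTER]
  if (length(outer) == 0L) {
    ts$cl_arc_major[cid] <- FALSE
    return(invisible(ts))
  }
  a_poly <- cycle_polygon_area(ts, hes)
  chords <- vapply(outer, function(h) {
    a <- ts$he_origin[h]; b <- he_dest(ts, h)
    sqrt((ts$vx_x[b] - ts$vx_x[a])^2 + (ts$vx_y[b] - ts$vx_y[a])^2)
  }, numeric(1))
  need <- target - a_poly
  sgn <- if (need < 0) -1 else 1     # negative: inward bulge, P < 0
  mag <- abs(need)
  if (length(outer) == 1L) {
    L <- chords[1]
    if (mag < 1e-14) {
      ts$cl_arc_r[cid] <- R_FLAT
      ts$cl_arc_major[cid] <- FALSE
      return(invisible(ts))
    }
    seg_of <- function(th) {
      r <- L / (2 * sin(th / 2))
      r^2 * (th - sin(th)) / 2
    }
    hi_cap <- if (sgn > 0) 2 * pi - 0.05 else pi  # inward arcs stay minor
    lo <- 1e-6; hi <- hi_cap
    if (seg_of(hi) <= mag) {
      th <- hi    # clamp
    } else {
      for (i in 1:70) {
        th <- (lo + hi) / 2
        if (seg_of(th) < mag) lo <- th else hi <- th
      }
      th <- (lo + hi) / 2
    }
    ts$cl_arc_r[cid] <- sgn * min(L / (2 * sin(th / 2)), R_FLAT)
    ts$cl_arc_major[cid] <- sgn > 0 && th > pi
    return(invisible(ts))
  }
  ts$cl_arc_major[cid] <- FALSE
  lmax <- max(chords)
  seg_sum <- function(r) {
    th <- 2 * asin(pmin(1, chords / (2 * r)))
    sum(r^2 * (th - sin(th)) / 2)
  }
  if (mag < 1e-14) {
    ts$cl_arc_r[cid] <- R_FLAT
  } else if (seg_sum(lmax / 2) <= mag) {
    ts$cl_arc_r[cid] <- sgn * lmax / 2   # clamped at half circles
  } else {
    lo <- lmax / 2
    hi <- R_FLAT
    for (i in 1:80) {
      mid <- sqrt(lo * hi)
      if (seg_sum(mid) > mag) lo <- mid else hi <- mid
      if (hi / lo < 1 + 1e-14) break
    }
    ts$cl_arc_r[cid] <- sgn * sqrt(lo * hi)
  }
  invisible(ts)
}

refit_all_arcs <- function(ts) {
  for (cid in cell_ids(ts)) refit_cell_arcs(ts, cid)
  invisible(ts)
}
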