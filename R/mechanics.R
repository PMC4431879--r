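## Vertex mechanics: tension and pressure force laws, force assembly, the
## first-order volume/force relation, and the interior-pressure solve.
##
## This file is the reference (pure R) implementation of the force model;
## the relaxation engine uses an equivalent compiled core (src/) for speed.
## Tests compare the two on small fixtures.
##
## Conventions: a physical edge contributes once (not once per half-edge).
## In the default "constant" tension mode the tension magnitude at each edge
## end is eta, i.e. the wall energy is eta times wall length; this is the
## soap-film convention under which a boundary cell obeys the Laplace law
## P = eta(i,0)/r and an equal doublet meets at 2*acos(eta_in/(2*eta_out)).
## The "length" mode scales the magnitude by the wall length instead.

#' Laplace pressure of a boundary cell
#'
#' P = eta(i,0) / r with r the cell's free-boundary arc radius (the disk
#' radius for an isolated cell). The exterior pressure is the zero reference.
#'
#' @param ts a tissue state.
#' @param cid cell id; must have at least one free boundary.
#' @return scalar pressure.
#' @export
laplace_pressure <- function(ts, cid) {
  eo <- eta_outer(ts$tensions, ts$cl_type[cid])
  if (is_isolated(ts, cid)) {
    r <- ts$cl_radius[cid]
  } else {
    hes <- cell_cycle(ts, cid)
    if (!any(ts$he_kind[hes] == KIND_OUTER))
      stop("cell ", cid, " has no free boundary; its pressure is determined by the interior solve")
    r <- ts$cl_arc_r[cid]
  }
  if (!is.finite(r) || r == 0) stop("degenerate arc radius for cell ", cid)
  eo / r   # signed: inward-curving free boundaries give negative pressure
}

## Physical eta of the edge carried by half-edge h.
edge_eta <- function(ts, h) {
  cid <- ts$he_cell[h]
  if (cid == EXTERIOR) h <- ts$he_twin[h]
  cid <- ts$he_cell[h]
  if (ts$he_kind[h] == KIND_OUTER) {
    eta_outer(ts$tensions, ts$cl_type[cid])
  } else {
    other <- ts$he_cell[ts$he_twin[h]]
    eta_inner(ts$tensions, ts$cl_type[cid], ts$cl_type[other])
  }
}

#' Tension force of one physical edge at its two endpoints
#'
#' Inner edges: a force of magnitude m at each endpoint, directed along the
#' edge toward the other endpoint (shortening). Outer edges: magnitude m
#' along the arc tangent at each endpoint, directed to shorten the arc. In
#' mode "constant" m = eta; in mode "length" m = eta times the edge (or arc)
#' length.
#'
#' @param ts a tissue state.
#' @param h a half-edge of the physical edge.
#' @param mode "constant" or "length" (defaults to the state's parameter).
#' @return list with `vertices` (the two endpoint ids) and `F` (2 x 2 matrix
#'   of force vectors, one row per endpoint).
#' @export
edge_tension_forces <- function(ts, h, mode = ts$params$tension_scaling) {
  if (ts$he_cell[h] == EXTERIOR) h <- ts$he_twin[h]
  eta <- edge_eta(ts, h)
  a <- ts$he_origin[h]; b <- he_dest(ts, h)
  pa <- c(ts$vx_x[a], ts$vx_y[a]); pb <- c(ts$vx_x[b], ts$vx_y[b])
  if (ts$he_kind[h] == KIND_INNER) {
    ev <- pb - pa
    L <- sqrt(sum(ev^2))
    if (L < 1e-14) {
      return(list(vertices = c(a, b), F = matrix(0, 2, 2), degenerate = TRUE))
    }
    u <- ev / L
    m <- if (mode == "length") eta * L else eta
    list(vertices = c(a, b), F = rbind(m * u, -m * u), degenerate = FALSE)
  } else {
    g <- arc_geometry(ts, h)
    ta <- g$sweep * perp(pa - g$center); ta <- ta / sqrt(sum(ta^2))  # travel tangent
    tb <- g$sweep * perp(pb - g$center); tb <- tb / sqrt(sum(tb^2))
    m <- if (mode == "length") eta * g$radius * g$angle else eta
    ## shortening: start pulled forward along travel, end pulled backward
    list(vertices = c(a, b), F = rbind(m * ta, -m * tb), degenerate = FALSE)
  }
}

#' Pressure force of one inner edge at its two endpoints
#'
#' The pressure difference across an inner wall pushes the wall toward the
#' lower-pressure cell: each endpoint receives (P_i - P_j) |e| / 2 along the
#' wall normal pointing out of cell i. Outer edges contribute no pressure
#' force (the internal pressure is balanced by the arc curvature).
#'
#' @param ts a tissue state.
#' @param h an INNER half-edge (owned by cell i).
#' @param pressures numeric vector of cell pressures indexed by cell id.
#' @return list with `vertices` and `F` as in [edge_tension_forces()].
#' @export
edge_pressure_forces <- function(ts, h, pressures) {
  stopifnot(ts$he_kind[h] == KIND_INNER)
  i <- ts$he_cell[h]; j <- ts$he_cell[ts$he_twin[h]]
  a <- ts$he_origin[h]; b <- he_dest(ts, h)
  pa <- c(ts$vx_x[a], ts$vx_y[a]); pb <- c(ts$vx_x[b], ts$vx_y[b])
  ev <- pb - pa
  L <- sqrt(sum(ev^2))
  if (L < 1e-14) return(list(vertices = c(a, b), F = matrix(0, 2, 2)))
  n_out <- c(ev[2], -ev[1]) / L   # outward normal of cell i (interior on left)
  f <- (pressures[i] - pressures[j]) * L / 2 * n_out
  list(vertices = c(a, b), F = rbind(f, f))
}

## Full per-cell pressure vector: Laplace for boundary/isolated cells,
## supplied values for interior cells, 0 otherwise.
full_pressures <- function(ts, interior = NULL) {
  P <- numeric(ts$ncl)
  for (cid in cell_ids(ts)) {
    if (is_isolated(ts, cid)) {
      P[cid] <- laplace_pressure(ts, cid)
    } else {
      hes <- cell_cycle(ts, cid)
      if (any(ts$he_kind[hes] == KIND_OUTER)) {
        P[cid] <- laplace_pressure(ts, cid)
      } else if (!is.null(interior) && !is.na(interior[cid])) {
        P[cid] <- interior[cid]
      }
    }
  }
  P
}

interior_cells <- function(ts) {
  Filter(function(cid) {
    if (is_isolated(ts, cid)) return(FALSE)
    hes <- cell_cycle(ts, cid)
    !any(ts$he_kind[hes] == KIND_OUTER)
  }, cell_ids(ts))
}

#' Assemble vertex forces
#'
#' Sums the tension and pressure contributions of every physical edge at each
#' junction vertex (Newton pairs: each edge contributes once).
#'
#' @param ts a tissue state.
#' @param pressures numeric vector of cell pressures indexed by cell id
#'   (e.g. from [solve_pressures()]); missing entries are an error.
#' @return matrix (n_max_vertex x 2) of force vectors, rows indexed by
#'   vertex id; rows of dead vertices are zero.
#' @export
assemble_forces <- function(ts, pressures = NULL) {
  if (is.null(pressures)) pressures <- full_pressures(ts)
  if (length(pressures) < ts$ncl) stop("pressure entries missing")
  F <- matrix(0, nrow = max(ts$nvx, 1L), ncol = 2)
  hes <- halfedge_ids(ts)
  hes <- hes[hes < ts$he_twin[hes]]   # one half-edge per physical edge
  for (h in hes) {
    tf <- edge_tension_forces(ts, h)
    F[tf$vertices[1], ] <- F[tf$vertices[1], ] + tf$F[1, ]
    F[tf$vertices[2], ] <- F[tf$vertices[2], ] + tf$F[2, ]
    hh <- if (ts$he_cell[h] == EXTERIOR) ts$he_twin[h] else h
    if (ts$he_kind[hh] == KIND_INNER) {
      pf <- edge_pressure_forces(ts, hh, pressures)
      F[pf$vertices[1], ] <- F[pf$vertices[1], ] + pf$F[1, ]
      F[pf$vertices[2], ] <- F[pf$vertices[2], ] + pf$F[2, ]
    }
  }
  F
}

#' First-order volume (area) change of a cell under vertex forces
#'
#' The signed area change of the cell when every vertex moves by sigma times
#' its force: (sigma/2) * sum over boundary edges of (F_a + F_b) x e (cross
#' products, signed). Positive for outward motion of a counterclockwise
#' boundary; this is the triangle construction of the quadrilateral swept by
#' a displaced edge.
#'
#' @param ts a tissue state.
#' @param cid cell id.
#' @param forces vertex force matrix as from [assemble_forces()].
#' @param sigma step constant.
#' @return predicted signed area change.
#' @export
volume_rate <- function(ts, cid, forces, sigma = ts$params$sigma) {
  if (is_isolated(ts, cid)) return(0)
  hes <- cell_cycle(ts, cid)
  vs <- ts$he_origin[hes]
  xs <- ts$vx_x[vs]; ys <- ts$vx_y[vs]
  xn <- c(xs[-1], xs[1]); yn <- c(ys[-1], ys[1])
  fa <- forces[vs, , drop = FALSE]
  fb <- forces[c(vs[-1], vs[1]), , drop = FALSE]
  ex <- xn - xs; ey <- yn - ys
  sigma / 2 * sum((fa[, 1] + fb[, 1]) * ey - (fa[, 2] + fb[, 2]) * ex)
}

## Area gradient of cell cid at its vertices: dA/dv = perp(v_next - v_prev)/2
## (chord polygon part). Returns list(vertices, gx, gy).
area_gradients <- function(ts, cid) {
  hes <- cell_cycle(ts, cid)
  vs <- ts$he_origin[hes]
  xs <- ts$vx_x[vs]; ys <- ts$vx_y[vs]
  nv <- length(vs)
  nxt <- c(2:nv, 1); prv <- c(nv, 1:(nv - 1))
  gx <- (ys[nxt] - ys[prv]) / 2
  gy <- (xs[prv] - xs[nxt]) / 2
  list(vertices = vs, gx = gx, gy = gy)
}

#' Solve interior cell pressures for a growth increment
#'
#' Boundary-cell pressures are fixed by the Laplace law; interior (fully
#' polygonal) cell pressures are the unique values for which the first-order
#' volume rate of every interior cell equals its per-increment target. Since
#' vertex forces are affine in the pressures, this is a linear system; it is
#' symmetric positive-definite (a Gram matrix of area gradients) and small
#' fixtures are solved densely here.
#'
#' @param ts a tissue state.
#' @param plan a [growth_plan()]; cells not listed have target 0 (area
#'   conservation). Targets are interpreted per increment (dV/k).
#' @return numeric vector of pressures indexed by cell id (class
#'   `pressure_assignment`), covering all cells.
#' @export
solve_pressures <- function(ts, plan = growth_plan()) {
  sigma <- ts$params$sigma
  ic <- interior_cells(ts)
  P0 <- full_pressures(ts)
  if (length(ic) == 0) {
    class(P0) <- "pressure_assignment"
    return(P0)
  }
  F0 <- assemble_forces(ts, P0)
  grads <- lapply(ic, function(cid) area_gradients(ts, cid))
  n <- length(ic)
  G <- matrix(0, n, n)
  b <- numeric(n)
  dv <- plan_targets(plan, ts, per_increment = TRUE)
  for (a in seq_len(n)) {
    ga <- grads[[a]]
    b[a] <- dv[ic[a]] / sigma -
      sum(ga$gx * F0[ga$vertices, 1] + ga$gy * F0[ga$vertices, 2])
    for (cc in seq_len(a)) {
      gc <- grads[[cc]]
      common <- intersect(ga$vertices, gc$vertices)
      if (length(common)) {
        ia <- match(common, ga$vertices); ic2 <- match(common, gc$vertices)
        G[a, cc] <- sum(ga$gx[ia] * gc$gx[ic2] + ga$gy[ia] * gc$gy[ic2])
        G[cc, a] <- G[a, cc]
      }
    }
  }
  sol <- tryCatch(solve(G, b), error = function(e)
    stop("singular pressure system involving cells ",
         paste(ic, collapse = ", ")))
  P0[ic] <- sol
  class(P0) <- "pressure_assignment"
  P0
}

#' Growth plan
#'
#' Per-step prescribed area changes dV (signed) and optional tension-table
#' overrides applied at the start of the step.
#'
#' @param dV named numeric vector: names are cell ids, values the full-step
#'   area change. Cells not listed keep their area.
#' @param dEta optional [tension_table()] replacing the state's table for
#'   this and subsequent steps.
#' @return an object of class `growth_plan`.
#' @export
growth_plan <- function(dV = numeric(), dEta = NULL) {
  structure(list(dV = dV, dEta = dEta), class = "growth_plan")
}

## Per-cell per-increment (or per-step) targets as a vector indexed by cell id.
plan_targets <- function(plan, ts, per_increment = FALSE) {
  out <- numeric(ts$ncl)
  if (length(plan$dV)) {
    ids <- as.integer(names(plan$dV))
    if (any(is.na(ids)) || any(!ts$cl_alive[ids]))
      stop("growth plan refers to unknown or dead cells")
    out[ids] <- plan$dV
  }
  if (per_increment) out <- out / ts$params$k
  out
}
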