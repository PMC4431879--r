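## Relaxation engine: incremental application of a growth plan, vertex
## updates v' = v + sigma * F, convergence to stationarity, and dispatch of
## topological events. The numerical inner loop runs in the compiled core
## (src/relax_core.cpp); this file owns increments, event dispatch and
## reporting.

isTRUE_vec <- function(x) !is.na(x) & x

## Compact the live mesh into dense 0-based arrays for the core.
compact_state <- function(ts) {
  hes <- which(ts$he_alive)
  vxs <- which(ts$vx_alive)
  cls <- which(ts$cl_alive)
  map_he <- integer(ts$nhe); map_he[hes] <- seq_along(hes)
  map_vx <- integer(ts$nvx); map_vx[vxs] <- seq_along(vxs)
  map_cl <- integer(max(ts$ncl, 1L)); map_cl[cls] <- seq_along(cls)
  cell0 <- ts$he_cell[hes]
  ccomp <- ifelse(cell0 == EXTERIOR, 0L, map_cl[pmax(cell0, 1L)])
  ## physical eta per half-edge (cell side only; exterior side unused)
  eta <- numeric(length(hes))
  own <- cell0 != EXTERIOR
  if (any(own)) {
    h_own <- hes[own]
    outer_own <- ts$he_kind[h_own] == KIND_OUTER
    ty <- ts$cl_type[ts$he_cell[h_own]]
    eta_own <- numeric(length(h_own))
    if (any(outer_own)) eta_own[outer_own] <- eta_outer(ts$tensions, ty[outer_own])
    if (any(!outer_own)) {
      other <- ts$cl_type[ts$he_cell[ts$he_twin[h_own[!outer_own]]]]
      eta_own[!outer_own] <- eta_inner(ts$tensions, ty[!outer_own], other)
    }
    eta[own] <- eta_own
  }
  if (is.null(ts$cl_pressure)) ts$cl_pressure <- numeric(ts$ncl)
  length(ts$cl_pressure) <- ts$ncl
  ts$cl_pressure[is.na(ts$cl_pressure)] <- 0
  list(
    hes = hes, vxs = vxs, cls = cls,
    he_origin = map_vx[ts$he_origin[hes]] - 1L,
    he_twin = map_he[ts$he_twin[hes]] - 1L,
    he_next = map_he[ts$he_next[hes]] - 1L,
    he_cell = ccomp - 1L,
    he_kind = ts$he_kind[hes],
    he_eta = eta,
    vx = ts$vx_x[vxs], vy = ts$vx_y[vxs],
    cl_boundary = ifelse(ts$cl_boundary[cls] == 0L, 0L,
                         map_he[pmax(ts$cl_boundary[cls], 1L)]) - 1L,
    cl_eta_out = eta_outer(ts$tensions, ts$cl_type[cls]),
    cl_target = ts$cl_target[cls],
    cl_arc_r = ts$cl_arc_r[cls],
    cl_radius = ifelse(is.na(ts$cl_radius[cls]), 0, ts$cl_radius[cls]),
    cl_arc_major = isTRUE_vec(ts$cl_arc_major[cls]),
    P_warm = ts$cl_pressure[cls],
    map_he = map_he)
}

## One compiled relaxation chunk on fixed topology; writes results back.
## Short-edge events are detected between chunks (the per-vertex
## displacement cap, a fraction of the local element length, keeps geometry
## from inverting within a chunk), so the core never stops mid-chunk.
relax_chunk <- function(ts, iters, short_ok_he = integer(0)) {
  cs <- compact_state(ts)
  short_ok <- rep(TRUE, length(cs$hes))
  if (is.null(ts$vx_velx)) { ts$vx_velx <- numeric(0); ts$vx_vely <- numeric(0) }
  length(ts$vx_velx) <- ts$nvx; length(ts$vx_vely) <- ts$nvx
  ts$vx_velx[is.na(ts$vx_velx)] <- 0; ts$vx_vely[is.na(ts$vx_vely)] <- 0
  p <- ts$params
  res <- relax_core(cs$he_origin, cs$he_twin, cs$he_next, cs$he_cell,
                    cs$he_kind, cs$he_eta, cs$vx, cs$vy,
                    cs$cl_boundary, cs$cl_eta_out, cs$cl_target,
                    cs$cl_arc_r, cs$cl_radius, cs$cl_arc_major, cs$P_warm,
                    p$sigma, p$epsilon, as.integer(iters),
                    if (p$tension_scaling == "length") 1L else 0L,
                    0.15, 0.05 * p$a0, 1e-6 * p$a0,
                    p$t1_length, short_ok,
                    ts$vx_velx[cs$vxs], ts$vx_vely[cs$vxs],
                    if (is.null(ts$fire_state)) numeric(0) else ts$fire_state)
  ts$vx_x[cs$vxs] <- res$vx
  ts$vx_y[cs$vxs] <- res$vy
  ts$vx_velx[cs$vxs] <- res$vel_x
  ts$vx_vely[cs$vxs] <- res$vel_y
  ts$fire_state <- res$fire_state
  ts$cl_arc_r[cs$cls] <- res$arc_r
  ts$cl_arc_major[cs$cls] <- res$arc_major
  rad <- res$radius
  iso <- cs$cl_boundary < 0L
  ts$cl_radius[cs$cls[iso]] <- rad[iso]
  ts$cl_pressure[cs$cls] <- res$pressure
  if (is.null(ts$cl_area_cache)) ts$cl_area_cache <- numeric(0)
  length(ts$cl_area_cache) <- ts$ncl
  ts$cl_area_cache[cs$cls] <- res$area
  if (is.null(ts$cl_poly_cache)) ts$cl_poly_cache <- numeric(0)
  length(ts$cl_poly_cache) <- ts$ncl
  ts$cl_poly_cache[cs$cls] <- res$poly_area
  res$guard_he_id <- if (res$guard_he >= 0) cs$hes[res$guard_he + 1L] else NA_integer_
  res
}

#' Move vertices along their forces
#'
#' The basic update v(t+1) = v(t) + sigma F_v for every vertex, after which
#' free-boundary arcs are refit through their (moved) endpoints. No topology
#' changes happen here.
#'
#' @param ts a tissue state.
#' @param forces vertex force matrix (rows indexed by vertex id), e.g. from
#'   [assemble_forces()].
#' @param sigma step constant (defaults to the state's parameter).
#' @return the state, invisibly.
#' @export
update_vertex_positions <- function(ts, forces, sigma = ts$params$sigma) {
  vs <- vertex_ids(ts)
  if (length(vs)) {
    ts$vx_x[vs] <- ts$vx_x[vs] + sigma * forces[vs, 1]
    ts$vx_y[vs] <- ts$vx_y[vs] + sigma * forces[vs, 2]
  }
  refit_all_arcs(ts)
  invisible(ts)
}

## Detect and apply events; returns number applied. Forces for the
## extension check on short edges are taken from the last core evaluation
## (an edge being pulled open is not flipped; this is also what keeps a
## freshly flipped edge from immediately flipping back).
dispatch_events <- function(ts, res = NULL, exclude = integer(0)) {
  forces <- NULL
  if (!is.null(res) && !is.null(res$fx)) {
    forces <- matrix(0, max(ts$nvx, 1L), 2)
    vs <- which(ts$vx_alive)
    if (length(vs) == length(res$fx)) {
      forces[vs, 1] <- res$fx
      forces[vs, 2] <- res$fy
    } else {
      forces <- NULL
    }
  }
  n <- 0L
  ## extrusion first: a cell crushed to (near) zero or inverted area during
  ## the relaxation chunk is removed before any other surgery runs on it,
  ## the standard fate of a sliver whose short elements cannot legally
  ## flip. Candidates come from degenerate elements and from the per-cell
  ## areas the core evaluated during the last chunk.
  hes <- which(ts$he_alive & ts$he_cell != EXTERIOR)
  if (length(hes)) {
    a <- ts$he_origin[hes]; b <- ts$he_origin[ts$he_twin[hes]]
    len <- sqrt((ts$vx_x[a] - ts$vx_x[b])^2 + (ts$vx_y[a] - ts$vx_y[b])^2)
    cand <- unique(ts$he_cell[hes[len < ts$params$t1_length]])
    if (!is.null(ts$cl_area_cache) && length(ts$cl_area_cache) >= ts$ncl) {
      small <- which(ts$cl_alive &
                     !is.na(ts$cl_area_cache) &
                     ts$cl_area_cache < 0.05 * ts$params$a0)
      cand <- unique(c(cand, small))
    }
    if (!is.null(ts$cl_poly_cache) && length(ts$cl_poly_cache) >= ts$ncl) {
      inv <- which(ts$cl_alive &
                   !is.na(ts$cl_poly_cache) &
                   ts$cl_poly_cache < 0.02 * ts$params$a0 &
                   ts$cl_boundary > 0L)
      cand <- unique(c(cand, inv))
    }
    for (cid in cand) {
      if (!ts$cl_alive[cid] || is_isolated(ts, cid)) next
      poly <- tryCatch(cycle_polygon_area(ts, cell_cycle(ts, cid)),
                       error = function(e) NA_real_)
      area <- tryCatch(cell_area(ts, cid), error = function(e) NA_real_)
      if (!is.finite(poly) || !is.finite(area) ||
          area <= 0.01 * ts$params$a0 || poly <= 0) {
        if (isTRUE(remove_cell(ts, cid, force = TRUE))) n <- n + 1L
      }
    }
  }
  evs <- detect_events(ts, forces, exclude = exclude)
  n <- n + apply_events(ts, evs)
  ## deaths: dying cells below the removal threshold
  for (cid in cell_ids(ts)) {
    at <- ts$cl_attrs[[cid]]
    if (isTRUE(at$dying) && cell_area(ts, cid) < 0.05 * ts$params$a0) {
      remove_cell(ts, cid)
      n <- n + 1L
    }
  }
  n
}

#' Apply a growth plan for one time step
#'
#' The step algorithm: tension overrides are applied first; the prescribed
#' area changes are introduced in k equal increments, each followed by a
#' pressure solve, force evaluation, vertex updates and dispatch of any
#' topological events; after the last increment, iteration continues at
#' constant volume until the maximum vertex force drops below epsilon or the
#' iteration budget is exhausted. Non-convergence is reported, not thrown.
#'
#' @param ts a tissue state (validate_tissue(ts) clean).
#' @param plan a [growth_plan()].
#' @return a `step_report` list: iterations, max_force, converged, realized
#'   per-cell area changes (named by cell id), and the events of the step.
#' @export
update_cell_pattern <- function(ts, plan = growth_plan()) {
  p <- ts$params
  if (!is.null(plan$dEta)) ts$tensions <- plan$dEta
  cells_before <- cell_ids(ts)
  areas_before <- vapply(cells_before, function(c) cell_area(ts, c), numeric(1))
  ev_start <- length(ts$events)
  dv <- plan_targets(plan, ts)
  total_iter <- 0L
  short_seen <- integer(0)
  maxF <- Inf
  chunk <- 200L
  quench <- function() {
    if (!is.null(ts$vx_velx)) { ts$vx_velx[] <- 0; ts$vx_vely[] <- 0 }
    ts$fire_state <- NULL
  }
  ## elements created by a flip (walls and the short free boundaries of the
  ## margin variants) are exempt from further flip-type events for the rest
  ## of the step: frustrated junctions otherwise cycle through the inverse
  ## surgeries indefinitely
  cooldown <- function(ev_from) {
    evs <- ts$events
    if (length(evs) <= ev_from) return(invisible(NULL))
    for (e in evs[(ev_from + 1L):length(evs)]) {
      if (identical(e$kind, "EDGE_FLIP") && length(e$created)) {
        keep <- e$created[ts$he_alive[e$created]]
        if (length(keep)) short_seen <<- c(short_seen, keep)
      }
    }
  }

  diag_guards <- 0L; diag_chunks <- 0L; diag_events <- 0L
  run_until <- function(budget, need_converged) {
    used <- 0L
    events_fired <- 0L
    repeat {
      if (used >= budget) return(list(converged = FALSE, used = used))
      diag_chunks <<- diag_chunks + 1L
      res <- relax_chunk(ts, min(chunk, max(budget - used, 1L)), short_seen)
      used <- used + res$iterations + 1L
      if (res$guard) {
        diag_guards <<- diag_guards + 1L
        ev0 <- length(ts$events)
        napp <- dispatch_events(ts, res, exclude = short_seen)
        diag_events <<- diag_events + napp
        events_fired <- events_fired + napp
        if (napp > 0) { quench(); cooldown(ev0) }
        if (!is.na(res$guard_he_id) && ts$he_alive[res$guard_he_id]) {
          ## short but ineligible (e.g. a two-cell bridge): tolerate it
          short_seen <<- c(short_seen, res$guard_he_id)
        }
        next
      }
      ev0 <- length(ts$events)
      napp <- dispatch_events(ts, res, exclude = short_seen)
      diag_events <<- diag_events + napp
      events_fired <- events_fired + napp
      if (napp > 0) { quench(); cooldown(ev0); next }
      maxF <<- res$max_force
      if (res$converged || used >= budget) return(list(converged = res$converged, used = used))
    }
  }

  for (inc in seq_len(p$k)) {
    ids <- which(dv != 0)
    if (length(ids)) ts$cl_target[ids] <- ts$cl_target[ids] + dv[ids] / p$k
    r <- run_until(25L, FALSE)
    total_iter <- total_iter + r$used
  }
  r <- run_until(max(p$max_iter - total_iter, 100L), TRUE)
  total_iter <- total_iter + r$used

  cells_now <- cell_ids(ts)
  realized <- numeric(0)
  keep <- cells_before[ts$cl_alive[cells_before]]
  if (length(keep)) {
    areas_after <- vapply(keep, function(c) cell_area(ts, c), numeric(1))
    realized <- areas_after - areas_before[match(keep, cells_before)]
    names(realized) <- keep
  }
  ts$step <- ts$step + 1L
  report <- list(iterations = total_iter, max_force = maxF,
                 converged = r$converged, realized_dV = realized,
                 n_chunks = diag_chunks, n_guards = diag_guards,
                 n_events = diag_events,
                 events = ts$events[seq_len(length(ts$events) - ev_start) + ev_start])
  class(report) <- "step_report"
  report
}

#' Relax a tissue to stationarity
#'
#' [update_cell_pattern()] with an all-zero plan: a gradient search for the
#' nearest local minimum of the tissue's boundary energy at fixed cell
#' areas.
#'
#' @param ts a tissue state.
#' @return a `step_report` (see [update_cell_pattern()]).
#' @export
relax <- function(ts) {
  update_cell_pattern(ts, growth_plan())
}

#' @export
print.step_report <- function(x, ...) {
  cat(sprintf("step report: %d iterations, max|F| = %.3g, %s, %d events\n",
              x$iterations, x$max_force,
              if (x$converged) "converged" else "NOT converged",
              length(x$events)))
  invisible(x)
}
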