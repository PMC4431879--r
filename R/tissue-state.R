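## Core state container: cells + half-edge mesh + parameters.
##
## The tissue is stored column-wise in an environment (mutable by reference,
## like an external pointer) holding parallel vectors indexed by element id.
## Ids are assigned monotonically and never reused within a run. The exterior
## medium is cell id 0.

EXTERIOR <- 0L
KIND_INNER <- 0L
KIND_OUTER <- 1L

## Flat-arc guard: radii are clamped to this when a boundary cell needs no
## outward bulge (pressure ~ 0).
R_FLAT <- 1e6

#' Simulation parameters
#'
#' Numerical parameters of the quasi-static relaxation scheme and the
#' topological event thresholds. Lengths are in units of the nominal cell
#' diameter d0 (1 unit = 10 um); areas in d0^2.
#'
#' @param sigma step constant of the gradient relaxation (vertex displacement
#'   per unit force per iteration).
#' @param epsilon force-convergence threshold: a state is stationary when the
#'   largest vertex force magnitude is below this.
#' @param k number of equal increments a per-step volume change is split into.
#' @param contact_tol minimum overlap depth of two free boundaries before a
#'   contact event fires.
#' @param t1_length inner edges shorter than this trigger a T1 edge flip.
#' @param t2_area three-sided voids smaller than this collapse to a vertex.
#' @param max_iter iteration budget of one relaxation step.
#' @param tension_scaling "constant" (force magnitude eta per edge end; the
#'   soap-film convention consistent with the Laplace law) or "length"
#'   (magnitude eta times edge length).
#' @param a0 nominal cell area, the area of a disk of diameter 1.
#' @param seed integer seed for the run's random streams.
#' @return an object of class `sim_params` (a named list).
#' @export
sim_params <- function(sigma = 0.01, epsilon = 1e-3, k = 20L,
                       contact_tol = 0.02, t1_length = 0.05,
                       t2_area = NULL, max_iter = 5000L,
                       tension_scaling = c("constant", "length"),
                       a0 = pi / 4, seed = 1L) {
  tension_scaling <- match.arg(tension_scaling)
  if (is.null(t2_area)) t2_area <- 1e-3 * a0
  stopifnot(sigma > 0, epsilon > 0, k >= 1, contact_tol > 0,
            t1_length > 0, t2_area > 0, max_iter >= 1)
  structure(list(sigma = sigma, epsilon = epsilon, k = as.integer(k),
                 contact_tol = contact_tol, t1_length = t1_length,
                 t2_area = t2_area, max_iter = as.integer(max_iter),
                 tension_scaling = tension_scaling, a0 = a0,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Tension coefficient table
#'
#' Line tensions eta(i,j) of cell-cell walls and eta(i,0) of free (outer)
#' walls, looked up by the `type_label` of the cells involved. Pairs not
#' listed fall back to the defaults.
#'
#' @param default_inner default eta for any cell-cell wall.
#' @param default_outer default eta for any free wall (must be > 0).
#' @param inner named numeric vector of overrides; names are "a|b" with the
#'   two type labels in sorted order.
#' @param outer named numeric vector of per-type outer-wall overrides.
#' @return an object of class `tension_table`.
#' @export
tension_table <- function(default_inner = 1, default_outer = 1,
                          inner = numeric(), outer = numeric()) {
  stopifnot(default_outer > 0, default_inner >= 0,
            all(is.finite(c(default_inner, default_outer, inner, outer))),
            all(outer > 0), all(inner >= 0))
  structure(list(default_inner = default_inner, default_outer = default_outer,
                 inner = inner, outer = outer),
            class = "tension_table")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' @export
eta_inner <- function(tensions, type_a, type_b) {
  key <- pair_key(type_a, type_b)
  out <- rep(tensions$default_inner, length(key))
  hit <- match(key, names(tensions$inner))
  ok <- !is.na(hit)
  out[ok] <- tensions$inner[hit[ok]]
  out
}

#' @export
eta_outer <- function(tensions, type) {
  out <- rep(tensions$default_outer, length(type))
  hit <- match(type, names(tensions$outer))
  ok <- !is.na(hit)
  out[ok] <- tensions$outer[hit[ok]]
  out
}

#' Create an empty tissue state
#'
#' The full state of a tissue: cells, vertices, half-edges, tension table and
#' simulation parameters. The state is an environment and is modified in
#' place by all operations; functions also return it invisibly for chaining.
#'
#' @param params a [sim_params()] object.
#' @param tensions a [tension_table()] object.
#' @return an object of class `tissue_state`.
#' @export
tissue_state <- function(params = sim_params(), tensions = tension_table()) {
  ts <- new.env(parent = emptyenv())
  ts$params <- params
  ts$tensions <- tensions
  ts$step <- 0L
  ## half-edges
  ts$nhe <- 0L
  ts$he_origin <- integer(0)
  ts$he_twin <- integer(0)
  ts$he_next <- integer(0)
  ts$he_cell <- integer(0)
  ts$he_kind <- integer(0)
  ts$he_alive <- logical(0)
  ## vertices
  ts$nvx <- 0L
  ts$vx_x <- numeric(0)
  ts$vx_y <- numeric(0)
  ts$vx_out <- integer(0)
  ts$vx_alive <- logical(0)
  ## cells
  ts$ncl <- 0L
  ts$cl_boundary <- integer(0)   # 0 = isolated (no half-edges)
  ts$cl_radius <- numeric(0)     # isolated cells only
  ts$cl_arc_r <- numeric(0)      # shared radius of all arcs of a boundary cell
  ts$cl_arc_major <- logical(0)  # single-arc cells: arc spans more than pi
  ts$cl_cx <- numeric(0)
  ts$cl_cy <- numeric(0)
  ts$cl_target <- numeric(0)     # target (prescribed) area
  ts$cl_type <- character(0)
  ts$cl_color <- character(0)
  ts$cl_alive <- logical(0)
  ts$cl_attrs <- list()
  ## event log (cumulative; one entry per event)
  ts$events <- list()
  ts$rng <- new.env(parent = emptyenv())
  class(ts) <- "tissue_state"
  ts
}

new_vertex <- function(ts, x, y, out = 0L) {
  id <- ts$nvx + 1L
  ts$nvx <- id
  ts$vx_x[id] <- x
  ts$vx_y[id] <- y
  ts$vx_out[id] <- out
  ts$vx_alive[id] <- TRUE
  id
}

new_halfedge <- function(ts, origin, cell, kind) {
  id <- ts$nhe + 1L
  ts$nhe <- id
  ts$he_origin[id] <- origin
  ts$he_twin[id] <- 0L
  ts$he_next[id] <- 0L
  ts$he_cell[id] <- cell
  ts$he_kind[id] <- kind
  ts$he_alive[id] <- TRUE
  id
}

new_cell <- function(ts, type = "default", color = "#cccccc",
                     boundary = 0L, radius = NA_real_,
                     cx = NA_real_, cy = NA_real_, target = NA_real_) {
  id <- ts$ncl + 1L
  ts$ncl <- id
  ts$cl_boundary[id] <- boundary
  ts$cl_radius[id] <- radius
  ts$cl_arc_r[id] <- R_FLAT
  ts$cl_arc_major[id] <- FALSE
  ts$cl_cx[id] <- cx
  ts$cl_cy[id] <- cy
  ts$cl_target[id] <- target
  ts$cl_type[id] <- type
  ts$cl_color[id] <- color
  ts$cl_alive[id] <- TRUE
  ts$cl_attrs[[id]] <- list()
  id
}

set_twins <- function(ts, a, b) {
  ts$he_twin[a] <- b
  ts$he_twin[b] <- a
  invisible(ts)
}

kill_halfedge <- function(ts, h) {
  ts$he_alive[h] <- FALSE
  invisible(ts)
}

kill_vertex <- function(ts, v) {
  ts$vx_alive[v] <- FALSE
  invisible(ts)
}

kill_cell <- function(ts, c) {
  ts$cl_alive[c] <- FALSE
  invisible(ts)
}

cell_ids <- function(ts) which(ts$cl_alive)
vertex_ids <- function(ts) which(ts$vx_alive)
halfedge_ids <- function(ts) which(ts$he_alive)

#' Add an isolated cell (a disk)
#'
#' An isolated cell is represented analytically by its center and radius; no
#' vertices or half-edges are created until it first contacts another cell.
#'
#' @param ts a [tissue_state()].
#' @param center numeric length-2 center position.
#' @param radius disk radius (> 0).
#' @param type_label cell type label used for tension lookup.
#' @param color fill color used by [render_svg()].
#' @return the id of the new cell.
#' @export
make_isolated_cell <- function(ts, center, radius, type_label = "default",
                               color = "#cccccc") {
  if (!is.numeric(radius) || length(radius) != 1L || !is.finite(radius) ||
      radius <= 0) {
    stop("radius must be a single positive finite number")
  }
  stopifnot(length(center) == 2L, all(is.finite(center)))
  new_cell(ts, type = type_label, color = color, boundary = 0L,
           radius = radius, cx = center[1], cy = center[2],
           target = pi * radius^2)
}

is_isolated <- function(ts, cid) ts$cl_boundary[cid] == 0L

## Ordered half-edge cycle starting at h.
cycle_halfedges <- function(ts, h) {
  out <- integer(0)
  cur <- h
  repeat {
    out <- c(out, cur)
    cur <- ts$he_next[cur]
    if (is.na(cur) || cur == 0L) stop("broken next chain at half-edge ", out[length(out)])
    if (cur == h) break
    if (length(out) > ts$nhe) stop("next chain does not close at half-edge ", h)
  }
  out
}

cell_cycle <- function(ts, cid) {
  if (is_isolated(ts, cid)) return(integer(0))
  cycle_halfedges(ts, ts$cl_boundary[cid])
}

he_dest <- function(ts, h) ts$he_origin[ts$he_twin[h]]

## Outgoing half-edges at a vertex (rotation: next(twin(h)) has the same origin).
vertex_star <- function(ts, v) {
  h0 <- ts$vx_out[v]
  out <- integer(0)
  cur <- h0
  repeat {
    out <- c(out, cur)
    cur <- ts$he_next[ts$he_twin[cur]]
    if (cur == h0) break
    if (length(out) > 12L) stop("vertex star does not close at vertex ", v)
  }
  out
}

#' Number of living cells
#' @param ts a tissue state.
#' @export
n_cells <- function(ts) sum(ts$cl_alive)

#' @export
print.tissue_state <- function(x, ...) {
  cat(sprintf("<tissue_state> %d cells, %d vertices, %d half-edges, step %d\n",
              sum(x$cl_alive), sum(x$vx_alive), sum(x$he_alive), x$step))
  invisible(x)
}

#' @export
summary.tissue_state <- function(object, ...) {
  cids <- cell_ids(object)
  areas <- vapply(cids, function(c) cell_area(object, c), numeric(1))
  res <- list(n_cells = length(cids),
              n_vertices = sum(object$vx_alive),
              n_halfedges = sum(object$he_alive),
              step = object$step,
              total_area = sum(areas),
              mean_area = mean(areas),
              types = table(object$cl_type[cids]))
  class(res) <- "summary.tissue_state"
  res
}

#' @export
print.summary.tissue_state <- function(x, ...) {
  cat(sprintf("tissue: %d cells (%d vertices), step %d\n",
              x$n_cells, x$n_vertices, x$step))
  cat(sprintf("total area %.4f, mean cell area %.4f\n", x$total_area, x$mean_area))
  print(x$types)
  invisible(x)
}

## ---- seeded substreams ----------------------------------------------------

## Named substreams derived from the run seed, so that drawing from one stream
## (or adding diagnostics) never perturbs another.
rng_init <- function(ts, seed) {
  ts$rng <- new.env(parent = emptyenv())
  ts$rng$base <- as.integer(seed) %% .Machine$integer.max
  invisible(ts)
}

with_substream <- function(ts, name, fun) {
  if (is.null(ts$rng$base)) rng_init(ts, ts$params$seed)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  state <- ts$rng[[name]]
  if (is.null(state)) {
    ## derive a distinct deterministic seed per stream name
    h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 2147480000
    set.seed((ts$rng$base + as.integer(h)) %% 2147480000)
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  res <- fun()
  ts$rng[[name]] <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}
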