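## Snapshot serialization (sectioned text, lossless float round trip),
## SVG rendering, and summary metrics.

SNAPSHOT_VERSION <- 1L

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a tissue snapshot
#'
#' A structured text document (one file per step) holding the complete
#' state: parameters, tension table, vertices, half-edges, cells (with
#' attributes as JSON) and the event log. Floats are written with 17
#' significant digits so a read-back state is bitwise identical.
#'
#' @param ts a tissue state.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_snapshot <- function(ts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("epitissue-snapshot ", SNAPSHOT_VERSION)
  w("step\t", ts$step)
  p <- ts$params
  w("[params]")
  for (key in c("sigma", "epsilon", "contact_tol", "t1_length", "t2_area", "a0")) {
    w(key, "\t", fmt_num(p[[key]]))
  }
  w("k\t", p$k); w("max_iter\t", p$max_iter)
  w("tension_scaling\t", p$tension_scaling); w("seed\t", p$seed)
  tt <- ts$tensions
  w("[tensions]")
  w("default_inner\t", fmt_num(tt$default_inner))
  w("default_outer\t", fmt_num(tt$default_outer))
  for (k in names(tt$inner)) w("inner\t", k, "\t", fmt_num(tt$inner[[k]]))
  for (k in names(tt$outer)) w("outer\t", k, "\t", fmt_num(tt$outer[[k]]))
  w("[vertices]")
  for (v in vertex_ids(ts)) {
    w(v, "\t", fmt_num(ts$vx_x[v]), "\t", fmt_num(ts$vx_y[v]), "\t", ts$vx_out[v])
  }
  w("[halfedges]")
  for (h in halfedge_ids(ts)) {
    cellv <- if (ts$he_cell[h] == EXTERIOR) -1L else ts$he_cell[h]
    ang <- r <- ""
    if (ts$he_kind[h] == KIND_OUTER && ts$he_cell[h] != EXTERIOR) {
      g <- arc_geometry(ts, h)
      ang <- fmt_num(g$angle); r <- fmt_num(g$radius)
    }
    w(h, "\t", cellv, "\t", ts$he_origin[h], "\t", ts$he_twin[h], "\t",
      ts$he_next[h], "\t", if (ts$he_kind[h] == KIND_INNER) "INNER" else "OUTER",
      "\t", ang, "\t", r)
  }
  w("[cells]")
  for (cid in cell_ids(ts)) {
    attrs <- jsonlite::toJSON(ts$cl_attrs[[cid]], auto_unbox = TRUE, digits = NA)
    w(cid, "\t", ts$cl_type[cid], "\t", ts$cl_color[cid], "\t",
      ts$cl_boundary[cid], "\t",
      if (is.na(ts$cl_radius[cid])) "NA" else fmt_num(ts$cl_radius[cid]), "\t",
      fmt_num(ts$cl_arc_r[cid]), "\t",
      fmt_num(ts$cl_cx[cid]), "\t", fmt_num(ts$cl_cy[cid]), "\t",
      fmt_num(ts$cl_target[cid]), "\t", as.character(attrs))
  }
  w("[events]")
  for (ev in ts$events) {
    w(as.character(jsonlite::toJSON(ev, auto_unbox = TRUE, digits = NA)))
  }
  invisible(path)
}

#' Read a tissue snapshot
#'
#' @param path file written by [write_snapshot()].
#' @return a [tissue_state()] identical to the one written (validated on
#'   read; a tampered file fails with the offending element named).
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "epitissue-snapshot"))
    stop("not an epitissue snapshot: ", path)
  ver <- as.integer(sub("epitissue-snapshot ", "", lines[1]))
  if (is.na(ver) || ver != SNAPSHOT_VERSION)
    stop("snapshot version mismatch: found ", lines[1])
  sect <- ""
  params <- list(); tens <- list(inner = numeric(), outer = numeric())
  step <- 0L
  vx <- list(); he <- list(); cl <- list(); evs <- list()
  for (i in seq_along(lines)[-1]) {
    ln <- lines[i]
    if (ln == "") next
    if (startsWith(ln, "[")) { sect <- ln; next }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (sect == "" && f[1] == "step") { step <- as.integer(f[2]); next }
    if (sect == "[params]") { params[[f[1]]] <- f[2]; next }
    if (sect == "[tensions]") {
      if (f[1] %in% c("default_inner", "default_outer")) {
        tens[[f[1]]] <- as.numeric(f[2])
      } else {
        tens[[f[1]]][f[2]] <- as.numeric(f[3])
      }
      next
    }
    if (sect == "[vertices]") { vx[[length(vx) + 1L]] <- f; next }
    if (sect == "[halfedges]") { he[[length(he) + 1L]] <- f; next }
    if (sect == "[cells]") { cl[[length(cl) + 1L]] <- f; next }
    if (sect == "[events]") { evs[[length(evs) + 1L]] <- jsonlite::fromJSON(ln); next }
    stop("malformed snapshot line ", i, ": ", ln)
  }
  p <- sim_params(sigma = as.numeric(params$sigma),
                  epsilon = as.numeric(params$epsilon),
                  k = as.integer(params$k),
                  contact_tol = as.numeric(params$contact_tol),
                  t1_length = as.numeric(params$t1_length),
                  t2_area = as.numeric(params$t2_area),
                  max_iter = as.integer(params$max_iter),
                  tension_scaling = params$tension_scaling,
                  a0 = as.numeric(params$a0),
                  seed = as.integer(params$seed))
  tt <- tension_table(default_inner = tens$default_inner,
                      default_outer = tens$default_outer,
                      inner = tens$inner, outer = tens$outer)
  ts <- tissue_state(p, tt)
  ts$step <- step
  if (length(vx)) {
    ids <- as.integer(vapply(vx, `[`, character(1), 1))
    n <- max(ids)
    ts$nvx <- n
    ts$vx_x <- rep(NA_real_, n); ts$vx_y <- rep(NA_real_, n)
    ts$vx_out <- rep(0L, n); ts$vx_alive <- rep(FALSE, n)
    ts$vx_x[ids] <- as.numeric(vapply(vx, `[`, character(1), 2))
    ts$vx_y[ids] <- as.numeric(vapply(vx, `[`, character(1), 3))
    ts$vx_out[ids] <- as.integer(vapply(vx, `[`, character(1), 4))
    ts$vx_alive[ids] <- TRUE
  }
  if (length(he)) {
    ids <- as.integer(vapply(he, `[`, character(1), 1))
    n <- max(ids)
    ts$nhe <- n
    ts$he_origin <- ts$he_twin <- ts$he_next <- ts$he_cell <- ts$he_kind <-
      rep(0L, n)
    ts$he_alive <- rep(FALSE, n)
    cells <- as.integer(vapply(he, `[`, character(1), 2))
    ts$he_cell[ids] <- ifelse(cells < 0, EXTERIOR, cells)
    ts$he_origin[ids] <- as.integer(vapply(he, `[`, character(1), 3))
    ts$he_twin[ids] <- as.integer(vapply(he, `[`, character(1), 4))
    ts$he_next[ids] <- as.integer(vapply(he, `[`, character(1), 5))
    ts$he_kind[ids] <- ifelse(vapply(he, `[`, character(1), 6) == "INNER",
                              KIND_INNER, KIND_OUTER)
    ts$he_alive[ids] <- TRUE
  }
  if (length(cl)) {
    ids <- as.integer(vapply(cl, `[`, character(1), 1))
    n <- max(ids)
    ts$ncl <- n
    ts$cl_boundary <- rep(0L, n)
    ts$cl_radius <- ts$cl_arc_r <- ts$cl_cx <- ts$cl_cy <- ts$cl_target <-
      rep(NA_real_, n)
    ts$cl_type <- ts$cl_color <- rep("", n)
    ts$cl_alive <- rep(FALSE, n)
    ts$cl_attrs <- vector("list", n)
    for (f in cl) {
      id <- as.integer(f[1])
      ts$cl_type[id] <- f[2]; ts$cl_color[id] <- f[3]
      ts$cl_boundary[id] <- as.integer(f[4])
      ts$cl_radius[id] <- if (f[5] == "NA") NA_real_ else as.numeric(f[5])
      ts$cl_arc_r[id] <- as.numeric(f[6])
      ts$cl_cx[id] <- as.numeric(f[7]); ts$cl_cy[id] <- as.numeric(f[8])
      ts$cl_target[id] <- as.numeric(f[9])
      ts$cl_attrs[[id]] <- if (length(f) >= 10 && nzchar(f[10]))
        jsonlite::fromJSON(f[10]) else list()
      ts$cl_alive[id] <- TRUE
    }
  }
  ts$events <- evs
  bad <- validate_tissue(ts)
  if (length(bad)) stop("snapshot failed validation: ", bad[1])
  ts
}

#' Render a tissue as SVG
#'
#' One closed path per meshed cell (line commands for inner edges, arc
#' commands for outer edges), a circle per isolated cell, filled with the
#' cell color; optionally a stripe-band underlay.
#'
#' @param ts a tissue state.
#' @param path output file.
#' @param stripes optional [stripe_spec()] to draw band underlays.
#' @param scale pixels per length unit.
#' @return the path, invisibly.
#' @export
render_svg <- function(ts, path, stripes = NULL, scale = 40) {
  cids <- cell_ids(ts)
  ## bounding box
  xs <- ys <- numeric(0)
  for (cid in cids) {
    if (is_isolated(ts, cid)) {
      xs <- c(xs, ts$cl_cx[cid] + c(-1, 1) * ts$cl_radius[cid])
      ys <- c(ys, ts$cl_cy[cid] + c(-1, 1) * ts$cl_radius[cid])
    }
  }
  vs <- vertex_ids(ts)
  xs <- c(xs, ts$vx_x[vs]); ys <- c(ys, ts$vx_y[vs])
  if (!length(xs)) { xs <- c(0, 1); ys <- c(0, 1) }
  pad <- 1
  x0 <- min(xs) - pad; x1 <- max(xs) + pad
  y0 <- min(ys) - pad; y1 <- max(ys) + pad
  sx <- function(x) fmt_svg((x - x0) * scale)
  sy <- function(y) fmt_svg((y1 - y) * scale)
  fmt_svg <- function(v) sprintf("%.3f", v)
  out <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%.0f" height="%.0f" viewBox="0 0 %.3f %.3f">',
    (x1 - x0) * scale, (y1 - y0) * scale, (x1 - x0) * scale, (y1 - y0) * scale))
  if (!is.null(stripes)) {
    w <- stripes$width_cells; period <- stripes$period_cells
    b0 <- floor(x0 / w)
    for (b in b0:ceiling(x1 / w)) {
      band <- b %% (period / w)
      col <- if (band == stripes$permissive_band) "#d8ecff" else "#f4f4f4"
      out <- c(out, sprintf('<rect x="%s" y="0" width="%.3f" height="%.3f" fill="%s"/>',
                            sx(b * w), w * scale, (y1 - y0) * scale, col))
    }
  }
  for (cid in cids) {
    if (is_isolated(ts, cid)) {
      out <- c(out, sprintf(
        '<circle cx="%s" cy="%s" r="%.3f" fill="%s" stroke="#333" stroke-width="0.8"/>',
        sx(ts$cl_cx[cid]), sy(ts$cl_cy[cid]), ts$cl_radius[cid] * scale,
        ts$cl_color[cid]))
      next
    }
    hes <- cell_cycle(ts, cid)
    v1 <- ts$he_origin[hes[1]]
    d <- sprintf("M %s %s", sx(ts$vx_x[v1]), sy(ts$vx_y[v1]))
    for (h in hes) {
      bv <- he_dest(ts, h)
      if (ts$he_kind[h] == KIND_INNER) {
        d <- paste(d, sprintf("L %s %s", sx(ts$vx_x[bv]), sy(ts$vx_y[bv])))
      } else {
        g <- arc_geometry(ts, h)
        large <- if (g$angle > pi) 1 else 0
        ## math-CCW arcs render with sweep flag 0 in the flipped y axis
        sweep <- if (g$sweep > 0) 0 else 1
        d <- paste(d, sprintf("A %.3f %.3f 0 %d %d %s %s",
                              g$radius * scale, g$radius * scale, large, sweep,
                              sx(ts$vx_x[bv]), sy(ts$vx_y[bv])))
      }
    }
    d <- paste(d, "Z")
    out <- c(out, sprintf('<path d="%s" fill="%s" stroke="#333" stroke-width="0.8"/>',
                          d, ts$cl_color[cid]))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Summary metrics of a tissue
#'
#' Population counts by type label, total area, and (if stripes are given or
#' bristles present) the bristle fraction and alignment statistics.
#'
#' @param ts a tissue state.
#' @param stripes optional [stripe_spec()] for alignment statistics.
#' @return a list of metrics.
#' @export
tissue_metrics <- function(ts, stripes = NULL) {
  cids <- cell_ids(ts)
  out <- list(n_cells = length(cids),
              total_area = total_area(ts),
              counts = table(ts$cl_type[cids]))
  nb <- sum(is_bristle(ts, cids))
  if (nb > 0) {
    out$bristle_fraction <- nb / length(cids)
    if (!is.null(stripes)) out$alignment <- alignment_index(ts, stripes)
  }
  out
}
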