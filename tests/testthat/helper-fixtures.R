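## Shared fixtures and small oracles used across the test files.

## brute-force adjacency: all cell pairs sharing at least one INNER edge
brute_force_adjacency <- function(ts) {
  hes <- which(ts$he_alive)
  hes <- hes[ts$he_kind[hes] == 0L & hes < ts$he_twin[hes]]
  ci <- ts$he_cell[hes]
  cj <- ts$he_cell[ts$he_twin[hes]]
  unique(cbind(pmin(ci, cj), pmax(ci, cj)))
}

neighbors_brute <- function(ts, cid) {
  ad <- brute_force_adjacency(ts)
  sort(unique(c(ad[ad[, 1] == cid, 2], ad[ad[, 2] == cid, 1])))
}

## graph distances from one cell by breadth-first search on the brute-force
## adjacency (independent of the half-edge traversal)
bfs_distances <- function(ts, from) {
  cids <- which(ts$cl_alive)
  ad <- brute_force_adjacency(ts)
  dist <- setNames(rep(Inf, length(cids)), cids)
  dist[as.character(from)] <- 0
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (c in frontier) {
      nb <- c(ad[ad[, 1] == c, 2], ad[ad[, 2] == c, 1])
      nb <- nb[is.infinite(dist[as.character(nb)])]
      dist[as.character(nb)] <- d
      nxt <- c(nxt, nb)
    }
    frontier <- unique(nxt)
  }
  dist
}

## minimum pairwise graph distance between labeled cells (brute force)
min_pairwise_distance <- function(ts, cids) {
  if (length(cids) < 2) return(Inf)
  best <- Inf
  for (i in seq_len(length(cids) - 1)) {
    d <- bfs_distances(ts, cids[i])
    best <- min(best, min(d[as.character(cids[(i + 1):length(cids)])]))
  }
  best
}

## Monte-Carlo area of a cell by point-in-region sampling (geometric oracle
## independent of the shoelace + segment decomposition)
mc_cell_area <- function(ts, cid, n = 2e5, seed = 42) {
  set.seed(seed)
  hes <- epitissue:::cell_cycle(ts, cid)
  vs <- ts$he_origin[hes]
  ## bounding box including arc bulges
  xs <- ts$vx_x[vs]; ys <- ts$vx_y[vs]
  pad <- max(abs(ts$cl_arc_r[cid]), 1)
  box <- c(min(xs) - pad, max(xs) + pad, min(ys) - pad, max(ys) + pad)
  px <- runif(n, box[1], box[2]); py <- runif(n, box[3], box[4])
  inside <- rep(TRUE, n)
  ## a point is in the cell iff it is on the interior side of every element
  ## (valid for convex-ish cells used in the fixture)
  for (h in hes) {
    a <- ts$he_origin[h]; b <- epitissue:::he_dest(ts, h)
    ax <- ts$vx_x[a]; ay <- ts$vx_y[a]; bx <- ts$vx_x[b]; by <- ts$vx_y[b]
    if (ts$he_kind[h] == 0L) {
      inside <- inside & ((bx - ax) * (py - ay) - (by - ay) * (px - ax) >= 0)
    } else {
      g <- epitissue:::arc_geometry(ts, h)
      d2 <- (px - g$center[1])^2 + (py - g$center[2])^2
      if (g$seg_sign > 0) {
        ## outward bulge: inside chord-halfplane OR inside the circle
        chord_ok <- (bx - ax) * (py - ay) - (by - ay) * (px - ax) >= 0
        inside <- inside & (chord_ok | d2 <= g$radius^2)
      } else {
        chord_ok <- (bx - ax) * (py - ay) - (by - ay) * (px - ax) >= 0
        inside <- inside & chord_ok & d2 >= g$radius^2
      }
    }
  }
  mean(inside) * (box[2] - box[1]) * (box[4] - box[3])
}

## total boundary energy: eta-weighted length of all walls and arcs
boundary_energy <- function(ts) {
  en <- 0
  hes <- which(ts$he_alive)
  hes <- hes[ts$he_cell[hes] != 0L]
  for (h in hes) {
    if (ts$he_kind[h] == 0L && h > ts$he_twin[h] &&
        ts$he_cell[ts$he_twin[h]] != 0L) next  # count walls once
    eta <- epitissue:::edge_eta(ts, h)
    if (ts$he_kind[h] == 0L) {
      a <- ts$he_origin[h]; b <- epitissue:::he_dest(ts, h)
      len <- sqrt((ts$vx_x[a] - ts$vx_x[b])^2 + (ts$vx_y[a] - ts$vx_y[b])^2)
    } else {
      g <- epitissue:::arc_geometry(ts, h)
      len <- g$radius * g$angle
    }
    en <- en + eta * len
  }
  en
}

## pull-direction tangents of the two free arcs at a doublet junction
doublet_junction_angle <- function(ts) {
  h <- which(ts$he_alive & ts$he_kind == 0L & ts$he_cell != 0L)[1]
  v <- ts$he_origin[h]
  pulls <- list()
  for (cid in c(1L, 2L)) {
    hes <- epitissue:::cell_cycle(ts, cid)
    arcs <- hes[ts$he_kind[hes] == 1L]
    g <- epitissue:::arc_geometry(ts, arcs[1])
    p <- c(ts$vx_x[v], ts$vx_y[v])
    tv <- g$sweep * epitissue:::perp(p - g$center)
    tv <- tv / sqrt(sum(tv^2))
    pulls[[cid]] <- if (ts$he_origin[arcs[1]] == v) tv else -tv
  }
  acos(pmin(1, pmax(-1, sum(pulls[[1]] * pulls[[2]])))) * 180 / pi
}

expect_valid <- function(ts) {
  testthat::expect_length(validate_tissue(ts), 0)
}
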