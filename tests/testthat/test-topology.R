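test_that("contact insertion turns two disks into chord-sharing lens cells", {
  ts <- build_two_disks(dist = 0.9, r = 0.5)
  ev <- detect_events(ts)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "CONTACT")
  expect_true(insert_contact_edge(ts, 1L, 2L))
  expect_valid(ts)
  ## each cell: one chord + one (major) free arc
  for (cid in 1:2) {
    hes <- epitissue:::cell_cycle(ts, cid)
    expect_equal(sum(ts$he_kind[hes] == 0L), 1)
    expect_equal(sum(ts$he_kind[hes] == 1L), 1)
  }
  ## symmetric disks: the chord is the perpendicular bisector (x = 0)
  ch <- which(ts$he_alive & ts$he_kind == 0L & ts$he_cell == 1L)
  a <- ts$he_origin[ch]; b <- epitissue:::he_dest(ts, ch)
  expect_equal(ts$vx_x[a], 0, tolerance = 1e-9)
  expect_equal(ts$vx_x[b], 0, tolerance = 1e-9)
  ## areas preserved within 1% after relaxing
  relax(ts)
  expect_equal(cell_area(ts, 1), pi * 0.25, tolerance = 0.01)
  ## repeated insertion is a no-op with warning
  expect_warning(res <- insert_contact_edge(ts, 1L, 2L), "adjacent")
  expect_false(res)
})

test_that("disks at a distance do not trigger contacts", {
  ts <- build_two_disks(dist = 2.1, r = 1)
  expect_length(detect_events(ts), 0)
  ts2 <- build_two_disks(dist = 1.9, r = 1)
  ev <- detect_events(ts2)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$kind, "CONTACT")
})

test_that("three mutually contacting disks collapse their void to one vertex", {
  ts <- tissue_state()
  r <- 0.56
  ang <- c(pi / 2, pi / 2 + 2 * pi / 3, pi / 2 + 4 * pi / 3)
  for (aa in ang) make_isolated_cell(ts, c(cos(aa), sin(aa)) * 0.58, r)
  expect_true(insert_contact_edge(ts, 1L, 2L))
  expect_true(insert_contact_edge(ts, 2L, 3L))
  expect_true(insert_contact_edge(ts, 1L, 3L))
  expect_valid(ts)
  comps <- epitissue:::exterior_components(ts)
  is_void <- vapply(comps, function(cc)
    length(cc) == 3 && epitissue:::cycle_polygon_area(ts, cc) > 0, logical(1))
  expect_true(any(is_void))          # central three-sided void
  void <- comps[[which(is_void)[1]]]
  nv0 <- sum(ts$vx_alive); ne0 <- sum(ts$he_alive)
  ## Euler audit around the collapse: V - E changes by -2 - (-3) = +1
  expect_true(remove_void(ts, void))
  expect_valid(ts)
  expect_equal(sum(ts$vx_alive), nv0 - 2)
  expect_equal(sum(ts$he_alive), ne0 - 6)     # three half-edge pairs
  ## the junction vertex touches all three cells
  v <- which(ts$vx_alive & seq_len(ts$nvx) > 0)
  center_v <- v[vapply(v, function(vv)
    length(epitissue:::vertex_star(ts, vv)) == 3 &&
      setequal(ts$he_cell[epitissue:::vertex_star(ts, vv)], 1:3), logical(1))]
  expect_length(center_v, 1)
  ## a too-large void is not eligible
  ts2 <- tissue_state()
  for (aa in ang) make_isolated_cell(ts2, c(cos(aa), sin(aa)) * 0.75, 0.68)
  insert_contact_edge(ts2, 1L, 2L)
  insert_contact_edge(ts2, 2L, 3L)
  insert_contact_edge(ts2, 1L, 3L)
  comps2 <- epitissue:::exterior_components(ts2)
  void2 <- comps2[[which(vapply(comps2, function(cc)
    length(cc) == 3 && epitissue:::cycle_polygon_area(ts2, cc) > 0,
    logical(1)))[1]]]
  expect_gt(epitissue:::void_area(ts2, void2), ts2$params$t2_area)
  ev <- detect_events(ts2)
  expect_false(any(vapply(ev, function(e) e$kind == "VOID_REMOVAL", logical(1))))
})

test_that("edge flip swaps neighbors and is an involution on adjacency", {
  ## 3-ring hexagonal tissue: flip an interior edge
  ts <- build_hex_tissue(3, relax = FALSE)
  ic <- epitissue:::interior_cells(ts)
  ## find an inner edge between two interior cells whose endpoints also only
  ## touch interior cells
  hes <- which(ts$he_alive & ts$he_kind == 0L & ts$he_cell != 0L)
  pick <- NA
  for (h in hes) {
    cu <- epitissue:::cells_at_vertex(ts, ts$he_origin[h])
    cv <- epitissue:::cells_at_vertex(ts, ts$he_origin[ts$he_twin[h]])
    if (all(c(cu, cv) %in% ic)) { pick <- h; break }
  }
  adj0 <- brute_force_adjacency(ts)
  A <- ts$he_cell[pick]; B <- ts$he_cell[ts$he_twin[pick]]
  C <- setdiff(epitissue:::cells_at_vertex(ts, ts$he_origin[pick]), c(A, B))
  D <- setdiff(epitissue:::cells_at_vertex(ts, ts$he_origin[ts$he_twin[pick]]), c(A, B))
  n0 <- n_cells(ts); area0 <- epitissue:::total_area(ts)
  expect_true(flip_edge(ts, pick))
  expect_valid(ts)
  ## adjacency swap exactly as the T1 rule prescribes
  expect_false(B %in% neighbors(ts, A))
  expect_true(D %in% neighbors(ts, C))
  expect_equal(n_cells(ts), n0)
  expect_equal(epitissue:::total_area(ts), area0, tolerance = 0.01 * area0)
  ## reverse flip restores the original adjacency graph
  newh <- which(ts$he_alive & ts$he_kind == 0L)
  ge <- newh[(ts$he_cell[newh] == C & ts$he_cell[ts$he_twin[newh]] == D) |
             (ts$he_cell[newh] == D & ts$he_cell[ts$he_twin[newh]] == C)][1]
  expect_true(flip_edge(ts, ge))
  expect_valid(ts)
  adj1 <- brute_force_adjacency(ts)
  expect_equal(adj1[order(adj1[, 1], adj1[, 2]), ],
               adj0[order(adj0[, 1], adj0[, 2]), ])
})

test_that("division conserves area, increments the count and keeps adjacency", {
  ts <- build_hex_tissue(2)
  ic <- epitissue:::interior_cells(ts)[1]
  nbs0 <- neighbors(ts, ic)
  a0 <- cell_area(ts, ic)
  n0 <- n_cells(ts)
  did <- divide_cell(ts, ic, orientation = 1.1)
  expect_valid(ts)
  expect_equal(n_cells(ts), n0 + 1)
  ## daughters sum exactly to the mother at insertion
  expect_equal(cell_area(ts, ic) + cell_area(ts, did), a0, tolerance = 1e-10)
  ## split is equal to within 0.1%
  expect_lt(abs(cell_area(ts, ic) - cell_area(ts, did)), 2e-3 * a0)
  ## every old neighbor is adjacent to at least one daughter
  nbs_after <- union(neighbors(ts, ic), neighbors(ts, did))
  expect_true(all(nbs0 %in% nbs_after))
  ## daughters are adjacent to each other and inherit the type label
  expect_true(did %in% neighbors(ts, ic))
  expect_equal(ts$cl_type[did], ts$cl_type[ic])
})

test_that("dividing an isolated disk gives two exact half-disks", {
  ts <- tissue_state()
  make_isolated_cell(ts, c(1, 2), 1)
  did <- divide_cell(ts, 1, orientation = 0.3)
  expect_valid(ts)
  expect_equal(cell_area(ts, 1), pi / 2, tolerance = 1e-10)
  expect_equal(cell_area(ts, did), pi / 2, tolerance = 1e-10)
})

test_that("cell removal converts neighbor walls to free boundaries", {
  ts <- build_hex_tissue(2)
  ic <- epitissue:::interior_cells(ts)
  ## a cell whose neighbors are all distinct: the central cell
  center <- which(abs(ts$cl_cx) < 0.2 & abs(ts$cl_cy) < 0.2 & ts$cl_alive)[1]
  nbs <- neighbors(ts, center)
  a_dead <- cell_area(ts, center)
  n0 <- n_cells(ts)
  expect_true(remove_cell(ts, center))
  expect_valid(ts)
  expect_equal(n_cells(ts), n0 - 1)
  ## each former neighbor gained a free boundary facing the hole
  for (nb in nbs) {
    hes <- epitissue:::cell_cycle(ts, nb)
    expect_gte(sum(ts$he_kind[hes] == 1L), 1)
  }
  ## the hole is an exterior component of about the dead cell's area
  comps <- epitissue:::exterior_components(ts)
  expect_length(comps, 2)
  holes <- Filter(function(cc) epitissue:::cycle_polygon_area(ts, cc) > 0, comps)
  expect_length(holes, 1)
  hole <- epitissue:::void_area(ts, holes[[1]])
  expect_equal(hole, a_dead, tolerance = 0.05 * a_dead)
  ## mechanics then shrinks the hole
  relax(ts)
  expect_valid(ts)
})

test_that("boundary cell removal indents the margin without crashing", {
  ts <- build_hex_tissue(2)
  bd <- setdiff(cids <- which(ts$cl_alive), epitissue:::interior_cells(ts))[1]
  expect_true(remove_cell(ts, bd))
  expect_valid(ts)
  relax(ts)
  expect_valid(ts)
})

test_that("removing an isolated cell empties the state", {
  ts <- tissue_state()
  make_isolated_cell(ts, c(0, 0), 1)
  remove_cell(ts, 1)
  expect_equal(n_cells(ts), 0)
})

test_that("two-phase death: shrinkage below threshold triggers removal", {
  ts <- build_hex_tissue(2)
  victim <- epitissue:::interior_cells(ts)[1]
  ts$cl_attrs[[victim]]$dying <- TRUE
  for (i in 1:12) {
    if (!ts$cl_alive[victim]) break
    dv <- setNames(-0.45 * cell_area(ts, victim), victim)
    update_cell_pattern(ts, growth_plan(dV = dv))
  }
  expect_false(ts$cl_alive[victim])
  expect_valid(ts)
  kinds <- vapply(ts$events, function(e) e$kind, character(1))
  expect_true("DEATH" %in% kinds)
})

test_that("random event sequences keep the mesh valid (fuzz)", {
  set.seed(99)
  ts <- build_hex_tissue(2)
  rng_init(ts, 99)
  n_ops <- 120
  for (i in seq_len(n_ops)) {
    op <- sample(c("divide", "flip", "remove", "relax"), 1,
                 prob = c(0.45, 0.25, 0.1, 0.2))
    cids <- which(ts$cl_alive)
    if (length(cids) < 4) break
    if (op == "divide") {
      cid <- sample(cids, 1)
      try(divide_cell(ts, cid), silent = TRUE)
    } else if (op == "flip") {
      hes <- which(ts$he_alive & ts$he_kind == 0L & ts$he_cell != 0L)
      if (length(hes)) flip_edge(ts, sample(hes, 1))
    } else if (op == "remove") {
      remove_cell(ts, sample(cids, 1))
    } else {
      update_cell_pattern(ts, growth_plan())
    }
    expect_length(validate_tissue(ts), 0)
  }
})
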