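test_that("Laplace pressure is tension over radius, exactly, signed", {
  ts <- tissue_state(tensions = tension_table(default_outer = 1))
  make_isolated_cell(ts, c(0, 0), 1)
  expect_equal(laplace_pressure(ts, 1), 1)
  ts2 <- tissue_state(tensions = tension_table(default_outer = 2))
  make_isolated_cell(ts2, c(0, 0), 4)
  expect_equal(laplace_pressure(ts2, 1), 0.5)
  ## flat arc limit: a boundary cell whose free wall needs no bulge
  ts3 <- build_doublet(relax = FALSE)
  ts3$cl_arc_r[1] <- 1e6
  expect_lt(abs(laplace_pressure(ts3, 1)), 1e-5)
  ## interior cells have no Laplace pressure
  ts4 <- build_hex_tissue(2, relax = FALSE)
  ic <- epitissue:::interior_cells(ts4)[1]
  expect_error(laplace_pressure(ts4, ic), "interior")
})

test_that("inner-edge tension pulls endpoints together with magnitude eta", {
  ts <- tissue_state(tensions = tension_table(default_inner = 2))
  v1 <- epitissue:::new_vertex(ts, 0, 0)
  v2 <- epitissue:::new_vertex(ts, 3, 4)
  c1 <- epitissue:::new_cell(ts); c2 <- epitissue:::new_cell(ts)
  h <- epitissue:::new_halfedge(ts, v1, c1, 0L)
  t <- epitissue:::new_halfedge(ts, v2, c2, 0L)
  epitissue:::set_twins(ts, h, t)
  tf <- edge_tension_forces(ts, h, mode = "constant")
  expect_equal(tf$F[1, ], 2 * c(0.6, 0.8))
  expect_equal(tf$F[2, ], -2 * c(0.6, 0.8))
  ## Newton pair: contributions sum to zero
  expect_equal(colSums(tf$F), c(0, 0))
  ## length scaling: magnitude eta * |e| = 2 * 5 = 10
  tf_len <- edge_tension_forces(ts, h, mode = "length")
  expect_equal(sqrt(sum(tf_len$F[1, ]^2)), 10)
  ## zero tension, zero force
  ts$tensions <- tension_table(default_inner = 0)
  tf0 <- edge_tension_forces(ts, h)
  expect_equal(tf0$F, matrix(0, 2, 2))
})

test_that("pressure force acts normal to the wall, split between endpoints", {
  ts <- tissue_state()
  v1 <- epitissue:::new_vertex(ts, 0, 0)
  v2 <- epitissue:::new_vertex(ts, 2, 0)
  c1 <- epitissue:::new_cell(ts); c2 <- epitissue:::new_cell(ts)
  h <- epitissue:::new_halfedge(ts, v1, c1, 0L)  # cell 1 above (interior left)
  t <- epitissue:::new_halfedge(ts, v2, c2, 0L)
  epitissue:::set_twins(ts, h, t)
  P <- c(1, 0)
  pf <- edge_pressure_forces(ts, h, P)
  ## edge along +x, interior of cell 1 on the left (+y): outward normal -y;
  ## each endpoint gets (P1-P2)*|e|/2 = 1 toward cell 2
  expect_equal(pf$F[1, ], c(0, -1))
  expect_equal(pf$F[2, ], c(0, -1))
  ## equal pressures: zero
  expect_equal(unname(edge_pressure_forces(ts, h, c(3, 3))$F), matrix(0, 2, 2))
  ## swapping the two pressures flips the force
  expect_equal(edge_pressure_forces(ts, h, c(0, 1))$F, -pf$F)
  ## evaluating on the twin gives the same physical force
  expect_equal(unname(edge_pressure_forces(ts, t, P)$F), unname(pf$F))
})

test_that("assembled forces vanish at stationary states and respect symmetry", {
  ## isolated cell: no vertices, empty assignment
  ts <- tissue_state()
  make_isolated_cell(ts, c(0, 0), 1)
  F <- assemble_forces(ts)
  expect_true(all(F == 0))
  ## relaxed equal doublet: junction forces below epsilon
  ts2 <- build_doublet()
  P <- epitissue:::full_pressures(ts2)
  F2 <- assemble_forces(ts2, P)
  fn <- sqrt(rowSums(F2^2))[which(ts2$vx_alive)]
  expect_lt(max(fn), 5 * ts2$params$epsilon)
})

test_that("volume rate equals finite-difference area change to O(sigma^2)", {
  ts <- build_hex_tissue(2, relax = FALSE)
  ic <- epitissue:::interior_cells(ts)[1]
  set.seed(3)
  F <- matrix(0, ts$nvx, 2)
  vs <- which(ts$vx_alive)
  F[vs, ] <- matrix(rnorm(2 * length(vs)), ncol = 2)
  err_of <- function(sigma) {
    pred <- volume_rate(ts, ic, F, sigma)
    a0 <- cell_area(ts, ic)
    x0 <- ts$vx_x; y0 <- ts$vx_y
    ts$vx_x[vs] <- x0[vs] + sigma * F[vs, 1]
    ts$vx_y[vs] <- y0[vs] + sigma * F[vs, 2]
    a1 <- epitissue:::cycle_polygon_area(ts, epitissue:::cell_cycle(ts, ic))
    ts$vx_x <- x0; ts$vx_y <- y0
    abs(pred - (a1 - a0))
  }
  e1 <- err_of(0.02); e2 <- err_of(0.01)
  expect_lt(e2, e1 / 3)   # halving sigma cuts the error ~4x
  ## all-zero forces: zero rate
  expect_equal(volume_rate(ts, ic, matrix(0, ts$nvx, 2), 0.01), 0)
  ## signed: outward displacement of one wall grows, inward shrinks
  hes <- epitissue:::cell_cycle(ts, ic)
  h <- hes[1]
  a <- ts$he_origin[h]; b <- epitissue:::he_dest(ts, h)
  ev <- c(ts$vx_x[b] - ts$vx_x[a], ts$vx_y[b] - ts$vx_y[a])
  n_out <- c(ev[2], -ev[1]) / sqrt(sum(ev^2))
  Fd <- matrix(0, ts$nvx, 2)
  Fd[c(a, b), ] <- rep(n_out, each = 2)
  expect_gt(volume_rate(ts, ic, Fd, 0.01), 0)
  expect_lt(volume_rate(ts, ic, -Fd, 0.01), 0)
})

test_that("pressure solve reproduces per-increment targets to 1e-8", {
  ts <- build_hex_tissue(2)     # relaxed, has 7 interior cells
  set.seed(11)
  ic <- epitissue:::interior_cells(ts)
  dv <- setNames(runif(length(ic), -0.01, 0.01), ic)
  plan <- growth_plan(dV = dv)
  P <- solve_pressures(ts, plan)
  F <- assemble_forces(ts, P)
  for (cid in ic) {
    got <- volume_rate(ts, cid, F, ts$params$sigma)
    want <- dv[as.character(cid)] / ts$params$k
    expect_equal(got, unname(want), tolerance = 1e-8)
  }
  ## symmetric doublet with equal targets: equal pressures by symmetry
  ts2 <- build_doublet()
  P2 <- solve_pressures(ts2, growth_plan())
  expect_equal(P2[1], P2[2], tolerance = 1e-9)
  ## relaxed uniform hexagonal tissue, zero growth: all interior pressures
  ## equal and inner-edge pressure forces between interior cells vanish
  P3 <- solve_pressures(ts, growth_plan())
  expect_lt(diff(range(P3[ic])), 0.02 * abs(mean(P3[ic])))
})

test_that("compiled core and R reference agree on forces", {
  for (fix in list(build_doublet(), build_hex_tissue(1))) {
    res <- epitissue:::relax_chunk(fix, 1L)
    cs <- epitissue:::compact_state(fix)
    ## R reference at the same positions/pressures
    P <- numeric(fix$ncl)
    P[cs$cls] <- res$pressure
    F <- assemble_forces(fix, P)
    fn_r <- sqrt(rowSums(F^2))
    fn_c <- sqrt(res$fx^2 + res$fy^2)
    expect_equal(fn_c, fn_r[cs$vxs], tolerance = 1e-6)
  }
})

test_that("doublet junction angle follows 2 acos(eta_in / 2 eta_out)", {
  for (ei in c(0.001, 1, 1.5)) {
    tt <- tension_table(default_inner = ei, default_outer = 1)
    ts <- build_doublet(r = 0.5, tensions = tt)
    expect_equal(doublet_junction_angle(ts), 2 * acos(ei / 2) * 180 / pi,
                 tolerance = 1 / 120)  # within 1 degree of up to 180
  }
})

test_that("isolated-then-separated disk obeys the Laplace law exactly", {
  ts <- tissue_state(tensions = tension_table(default_outer = 1.7))
  make_isolated_cell(ts, c(0, 0), 2)
  relax(ts)
  expect_equal(laplace_pressure(ts, 1), 1.7 / ts$cl_radius[1])
  expect_equal(ts$cl_radius[1], 2, tolerance = 1e-9)
})
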