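test_that("vertex updates move by sigma times force and nothing else", {
  ts <- build_doublet(relax = FALSE)
  F <- matrix(0, ts$nvx, 2)
  x0 <- ts$vx_x; y0 <- ts$vx_y
  update_vertex_positions(ts, F)
  expect_equal(ts$vx_x, x0)
  expect_equal(ts$vx_y, y0)
  v <- which(ts$vx_alive)[1]
  F[v, ] <- c(1, 0)
  update_vertex_positions(ts, F, sigma = 0.1)
  expect_equal(ts$vx_x[v], x0[v] + 0.1)
  expect_equal(ts$vx_y[v], y0[v])
  ## sigma = 0: no motion
  update_vertex_positions(ts, F, sigma = 0)
  expect_equal(ts$vx_x[v], x0[v] + 0.1)
})

test_that("a stationary doublet is a fixed point of the zero plan", {
  ts <- build_doublet()
  x0 <- ts$vx_x[ts$vx_alive]
  rep <- update_cell_pattern(ts, growth_plan())
  expect_true(rep$converged)
  expect_length(rep$events, 0)
  expect_lt(max(abs(ts$vx_x[ts$vx_alive] - x0)), 0.02)
  expect_lt(rep$max_force, ts$params$epsilon)
})

test_that("isolated disk growth follows the closed form", {
  ts <- tissue_state()
  make_isolated_cell(ts, c(0, 0), 1)
  rep <- update_cell_pattern(ts, growth_plan(dV = c(`1` = 0.1 * pi)))
  expect_equal(ts$cl_radius[1], sqrt(1.1), tolerance = 1e-9)
  expect_equal(unname(rep$realized_dV["1"]), 0.1 * pi, tolerance = 1e-9)
})

test_that("equal doublet growth realizes the plan within 1%", {
  ts <- build_doublet()
  a0 <- c(cell_area(ts, 1), cell_area(ts, 2))
  dv <- 0.10 * a0
  rep <- update_cell_pattern(ts, growth_plan(dV = setNames(dv, 1:2)))
  a1 <- c(cell_area(ts, 1), cell_area(ts, 2))
  expect_equal(a1, a0 * 1.10, tolerance = 0.01)
  expect_equal(unname(rep$realized_dV[c("1", "2")]), dv, tolerance = 0.01 * a0[1])
  ## by symmetry the interface stays on the perpendicular bisector
  ch <- which(ts$he_alive & ts$he_kind == 0L & ts$he_cell == 1L)[1]
  a <- ts$he_origin[ch]; b <- epitissue:::he_dest(ts, ch)
  expect_lt(abs(ts$vx_x[a]), 0.01)
  expect_lt(abs(ts$vx_x[b]), 0.01)
  expect_equal(ts$step, 2L)   # doublet build relaxed once already
})

test_that("relax restores a perturbed hexagonal tissue", {
  ts <- build_hex_tissue(2)
  areas0 <- vapply(which(ts$cl_alive), function(c) cell_area(ts, c), numeric(1))
  v <- which(ts$vx_alive)[10]
  ts$vx_x[v] <- ts$vx_x[v] + 0.01
  ts$vx_y[v] <- ts$vx_y[v] - 0.01
  rep <- relax(ts)
  expect_true(rep$converged)
  expect_lt(rep$max_force, ts$params$epsilon)
  areas1 <- vapply(which(ts$cl_alive), function(c) cell_area(ts, c), numeric(1))
  expect_equal(areas1, areas0, tolerance = 0.01)
  ## already-relaxed state converges immediately
  rep2 <- relax(ts)
  expect_true(rep2$converged)
  expect_lte(rep2$iterations, 30)
})

test_that("two overlapping disks end as a connected force-balanced doublet", {
  ts <- build_two_disks(dist = 0.9, r = 0.5)
  rep <- update_cell_pattern(ts, growth_plan())
  kinds <- vapply(rep$events, function(e) e$kind, character(1))
  expect_true("CONTACT" %in% kinds)
  expect_equal(neighbors(ts, 1), 2L)
  expect_true(rep$converged)
  expect_valid(ts)
})

test_that("growth is deterministic for identical state, plan and seed", {
  run <- function() {
    p <- sim_params(seed = 5)
    ts <- build_doublet(r = sqrt(p$a0 / pi), params = p)
    rng_init(ts, 5)
    for (cid in which(ts$cl_alive))
      ts$cl_attrs[[cid]]$birth_area <- cell_area(ts, cid)
    grow_tissue(ts, until_cells = 12, growth_rate = 0.1)
    ts
  }
  a <- run(); b <- run()
  expect_identical(a$vx_x[a$vx_alive], b$vx_x[b$vx_alive])
  expect_identical(a$vx_y[a$vx_alive], b$vx_y[b$vx_alive])
  expect_identical(vapply(a$events, `[[`, character(1), "kind"),
                   vapply(b$events, `[[`, character(1), "kind"))
})

test_that("area audit: realized volume changes sum to the tissue area change", {
  ts <- build_hex_tissue(1)
  a0 <- epitissue:::total_area(ts)
  cids <- which(ts$cl_alive)
  dv <- setNames(rep(0.05 * ts$params$a0, length(cids)), cids)
  rep <- update_cell_pattern(ts, growth_plan(dV = dv))
  a1 <- epitissue:::total_area(ts)
  expect_equal(sum(rep$realized_dV), a1 - a0, tolerance = 1e-6)
  expect_equal(a1 - a0, sum(dv), tolerance = 0.01 * sum(dv))
})

test_that("boundary energy does not increase under relaxation at fixed areas", {
  ts <- build_hex_tissue(2)
  ## perturb several vertices, then relax: eta-weighted boundary length is a
  ## Lyapunov function of the constrained descent
  set.seed(4)
  vs <- which(ts$vx_alive)
  ts$vx_x[vs] <- ts$vx_x[vs] + runif(length(vs), -0.02, 0.02)
  ts$vx_y[vs] <- ts$vx_y[vs] + runif(length(vs), -0.02, 0.02)
  epitissue:::refit_all_arcs(ts)
  e0 <- boundary_energy(ts)
  relax(ts)
  e1 <- boundary_energy(ts)
  expect_lt(e1, e0 + 1e-6)
})

test_that("tension scaling mode length is honored end to end", {
  p <- sim_params(tension_scaling = "length")
  ts <- build_doublet(params = p)
  expect_true(validate_tissue(ts) |> length() == 0)
  ## junction angle differs from the constant-tension prediction
  ang <- doublet_junction_angle(ts)
  expect_true(is.finite(ang))
})
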