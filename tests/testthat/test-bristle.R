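test_that("the Dl gradient is exponential with the calibrated reach", {
  gp <- gradient_params()   # D = 1.2, k_deg calibrated
  expect_equal(dl_profile(gp, 0), 1)
  expect_equal(inhibition_reach(gp), 10, tolerance = 1e-12)
  expect_equal(dl_profile(gp, 10), 0.05, tolerance = 1e-12)
  ## monotone decreasing
  x <- seq(0, 40, by = 0.5)
  expect_true(all(diff(dl_profile(gp, x)) < 0))
  ## scaling law: doubling sqrt(D/k) doubles the distance at any level
  gp4 <- gradient_params(D = 4 * 1.2)
  expect_equal(dl_profile(gp4, 2 * 7.3), dl_profile(gp, 7.3), tolerance = 1e-12)
  expect_equal(inhibition_reach(gp4), 20, tolerance = 1e-12)
  ## reach scaling is exactly sqrt(alpha)
  for (alpha in c(2, 4, 8)) {
    expect_equal(inhibition_reach(gradient_params(D = alpha * 1.2)),
                 sqrt(alpha) * 10, tolerance = 1e-10)
  }
  ## threshold at or above the source: no reach
  expect_equal(inhibition_reach(gradient_params(threshold = 1)), 0)
})

test_that("metric reach converts to cell layers by ceiling", {
  expect_equal(reach_to_layers(10), 1L)
  expect_equal(reach_to_layers(20), 2L)
  expect_equal(reach_to_layers(10 * sqrt(8)), 3L)
  expect_equal(reach_to_layers(0), 0L)
  expect_equal(reach_to_layers(10.5), 2L)
})

test_that("stripe classification is periodic and centroid-based", {
  st <- stripe_spec(width_cells = 3)
  ts <- tissue_state()
  expect_true(stripe_of(ts, NA, st, x = 0.5 * 3)$permissive)
  r1 <- stripe_of(ts, NA, st, x = 1.5 * 3)
  expect_equal(r1$band, 1)
  expect_false(r1$permissive)
  ## shifting by a full period preserves everything but the stripe index
  r2 <- stripe_of(ts, NA, st, x = 0.5 * 3 + 9)
  expect_true(r2$permissive)
  expect_equal(r2$stripe, stripe_of(ts, NA, st, x = 0.5 * 3)$stripe + 1)
})

test_that("fate commitment respects the exclusion range", {
  set.seed(2)
  ts <- build_hex_blob(60, relax = FALSE)
  rng_init(ts, 2)
  cfg <- bristle_config(model = "lateral", p_commit = 0.5, seed = 2)
  for (i in 1:6) commit_fates(ts, cfg)
  b <- which(ts$cl_alive)[is_bristle(ts, which(ts$cl_alive))]
  expect_gt(length(b), 2)
  ## no two bristles adjacent (brute-force all-pairs graph check)
  expect_gt(min_pairwise_distance(ts, b), 1)
})

test_that("inhibition-field commitment keeps bristles more than R layers apart", {
  set.seed(5)
  ts <- build_hex_blob(120, relax = FALSE)
  rng_init(ts, 5)
  cfg <- bristle_config(model = "field", R = 3, p_commit = 0.5, seed = 5)
  for (i in 1:6) commit_fates(ts, cfg)
  b <- which(ts$cl_alive)[is_bristle(ts, which(ts$cl_alive))]
  expect_gt(length(b), 1)
  expect_gt(min_pairwise_distance(ts, b), 3)
})

test_that("pre-destined commitment (R = 0) allows adjacent bristles", {
  set.seed(7)
  ts <- build_hex_blob(80, relax = FALSE)
  rng_init(ts, 7)
  cfg <- bristle_config(model = "pre_destined", p_commit = 0.6, seed = 7)
  for (i in 1:8) commit_fates(ts, cfg)
  b <- which(ts$cl_alive)[is_bristle(ts, which(ts$cl_alive))]
  expect_gt(length(b), 10)
  expect_equal(min_pairwise_distance(ts, b), 1)
})

test_that("striped commitment stays inside the permissive band", {
  set.seed(9)
  ts <- build_hex_blob(150, relax = FALSE)
  rng_init(ts, 9)
  st <- stripe_spec(width_cells = 3)
  cfg <- bristle_config(model = "lateral_stripes", stripes = st,
                        p_commit = 0.6, seed = 9)
  for (i in 1:6) commit_fates(ts, cfg)
  cids <- which(ts$cl_alive)
  b <- cids[is_bristle(ts, cids)]
  expect_gt(length(b), 0)
  for (cid in b) expect_true(stripe_of(ts, cid, st)$permissive)
  expect_gt(min_pairwise_distance(ts, b), 1)
})

test_that("the alignment index follows the offset arithmetic", {
  ## build a synthetic state where offsets are known exactly: a hex patch
  ## with bristles placed by hand
  ts <- build_hex_blob(60, relax = FALSE)
  st <- stripe_spec(width_cells = 30)  # one huge stripe, midline at x = 15
  ## all bristles at the midline: rho = 0
  cids <- which(ts$cl_alive)
  cents <- t(vapply(cids, function(c) cell_centroid(ts, c), numeric(2)))
  ## move tissue so its center column sits on the stripe midline
  shift <- 15 - 0
  ts$vx_x[ts$vx_alive] <- ts$vx_x[ts$vx_alive] + shift
  ts$cl_cx[cids] <- ts$cl_cx[cids] + shift
  cents[, 1] <- cents[, 1] + shift
  mid_col <- cids[abs(cents[, 1] - 15) < 0.2]
  for (cid in mid_col[1:3]) ts$cl_type[cid] <- "bristle"
  rep0 <- alignment_index(ts, st)
  expect_equal(rep0$rho, 0)
  expect_equal(rep0$frac_on_line, 1)
  ## rounding convention: offsets {0,0,1,1} give rho = 0.5
  expect_equal(mean(c(0, 0, 1, 1)), 0.5)
  ## grand-mean convention: stripes with offsets {0,2} and {1,1} give 1.0
  expect_equal(mean(c(0, 2, 1, 1)), 1.0)
  ## zero bristles: reported as absent
  ts2 <- build_hex_blob(10, relax = FALSE)
  rep2 <- alignment_index(ts2, st)
  expect_true(is.na(rep2$rho))
  expect_equal(rep2$n_bristles, 0L)
})

test_that("bristles two columns out are separated from the midline by a cell", {
  ## geometric check of the offset counter on a regular lattice
  ts <- build_hex_blob(80, relax = FALSE)
  cids <- which(ts$cl_alive)
  cents <- t(vapply(cids, function(c) cell_centroid(ts, c), numeric(2)))
  st <- stripe_spec(width_cells = 30)
  shift <- 15
  ts$vx_x[ts$vx_alive] <- ts$vx_x[ts$vx_alive] + shift
  ts$cl_cx[cids] <- ts$cl_cx[cids] + shift
  cents[, 1] <- cents[, 1] + shift
  ## pick a bristle exactly two lattice columns from the midline in one row
  row0 <- cids[abs(cents[, 2]) < 0.1]
  xs <- cents[match(row0, cids), 1]
  two_out <- row0[which.min(abs(xs - 17))]
  ts$cl_type[two_out] <- "bristle"
  ## rounded-offset convention: about two cell widths from the midline
  rep <- alignment_index(ts, st)
  expect_equal(rep$n_bristles, 1L)
  expect_equal(rep$table$d, 2)
  ## literal counting convention: one cell strictly between
  rep2 <- alignment_index(ts, st, offset_method = "count")
  expect_equal(rep2$table$d, 1)
})
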