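test_that("Hill feedback reduces to the basal state without neighbors", {
  lp <- lineage_params()
  f0 <- feedback(0, lp)
  expect_equal(f0$vS, lp$vS0)
  expect_equal(f0$vP, lp$vP0)
  expect_equal(unname(f0$probs_S), rep(1 / 3, 3))
  expect_equal(unname(f0$probs_P), rep(1 / 3, 3))
})

test_that("Hill feedback applies basal/(1 + coeff N_D) then renormalizes", {
  lp <- lineage_params(gS = 1)
  expect_equal(feedback(2, lp)$vS, lp$vS0 / 3)
  ## hand arithmetic: only self-renewal inhibited, hSr = 1, N_D = 1:
  ## raw (1/6, 1/3, 1/3) -> (0.2, 0.4, 0.4)
  lp2 <- lineage_params(hSr = 1, hSs = 0, hSa = 0)
  f <- feedback(1, lp2)
  expect_equal(unname(f$probs_S), c(0.2, 0.4, 0.4))
  ## probabilities always sum to one exactly
  for (nd in c(0, 1, 5, 40)) {
    f <- feedback(nd, lineage_params(hSr = 0.3, hSs = 0.9, hSa = 0.1,
                                     hPr = 2, hPs = 0, hPa = 0.5))
    expect_equal(sum(f$probs_S), 1)
    expect_equal(sum(f$probs_P), 1)
  }
})

test_that("division types follow the lineage rules", {
  ts <- build_hex_blob(19)
  cids <- which(ts$cl_alive)
  rng_init(ts, 1)
  epitissue:::set_lineage_kind(ts, cids[1], "S")
  epitissue:::set_lineage_kind(ts, cids[2], "P")
  epitissue:::set_lineage_kind(ts, cids[3], "D")
  ## deterministic triple: probability mass on one type
  f <- feedback(0, lineage_params())
  f$probs_S <- c(r = 1, s = 0, a = 0)
  expect_equal(choose_division_type(ts, cids[1], f), "SELF_RENEWAL")
  ## a progenitor's second division is always symmetric
  ts$cl_attrs[[cids[2]]]$divisions_used <- 1L
  f$probs_P <- c(r = 1, s = 0, a = 0)
  expect_equal(choose_division_type(ts, cids[2], f), "SYMMETRIC")
  ## differentiated cells never divide
  expect_error(choose_division_type(ts, cids[3], f), "do not divide")
})

test_that("apply_division assigns daughter kinds per the division table", {
  combos <- list(
    list(kind = "S", type = "SELF_RENEWAL", want = c("S", "S")),
    list(kind = "S", type = "SYMMETRIC", want = c("P", "P")),
    list(kind = "S", type = "ASYMMETRIC", want = c("S", "P")),
    list(kind = "P", type = "SELF_RENEWAL", want = c("P", "P")),
    list(kind = "P", type = "SYMMETRIC", want = c("D", "D")),
    list(kind = "P", type = "ASYMMETRIC", want = c("P", "D")))
  for (cb in combos) {
    ts <- build_hex_blob(7, relax = FALSE)
    rng_init(ts, 3)
    cid <- which(ts$cl_alive)[1]
    epitissue:::set_lineage_kind(ts, cid, cb$kind)
    ds <- apply_division(ts, cid, cb$type)
    expect_setequal(ts$cl_type[ds], cb$want)
  }
  ## division counters: P daughters of P inherit the incremented count
  ts <- build_hex_blob(7, relax = FALSE)
  rng_init(ts, 3)
  cid <- which(ts$cl_alive)[1]
  epitissue:::set_lineage_kind(ts, cid, "P", divisions_used = 0L)
  ds <- apply_division(ts, cid, "SELF_RENEWAL")
  for (d in ds) expect_equal(ts$cl_attrs[[d]]$divisions_used, 1L)
  ## fresh P from a stem cell starts at zero
  ts2 <- build_hex_blob(7, relax = FALSE)
  rng_init(ts2, 3)
  cid2 <- which(ts2$cl_alive)[1]
  epitissue:::set_lineage_kind(ts2, cid2, "S")
  ds2 <- apply_division(ts2, cid2, "ASYMMETRIC")
  pd <- ds2[ts2$cl_type[ds2] == "P"]
  expect_equal(ts2$cl_attrs[[pd]]$divisions_used, 0L)
})

test_that("a progenitor lineage yields at most 4 terminal differentiated cells", {
  ## exhaustive enumeration of the division-rule automaton: state = (kind,
  ## divisions_used); count the maximum D descendants over all choice trees
  max_D <- function(kind, used) {
    if (kind == "D") return(1)
    if (kind == "P") {
      if (used >= 2) stop("P divided more than twice")
      if (used == 1) return(2 * max_D("D", 0))   # forced symmetric: (D, D)
      ## first division: renewal (P,P), symmetric (D,D), asymmetric (P,D)
      return(max(2 * max_D("P", 1),
                 2 * max_D("D", 0),
                 max_D("P", 1) + max_D("D", 0)))
    }
    stop("only P lineages terminate")
  }
  expect_equal(max_D("P", 0), 4)
})

test_that("the initial tissue has the canonical 10/16/38 composition", {
  ts <- build_initial_tissue()
  cids <- which(ts$cl_alive)
  kinds <- ts$cl_type[cids]
  expect_equal(sum(kinds == "S"), 10)
  expect_equal(sum(kinds == "P"), 16)
  expect_equal(sum(kinds == "D"), 38)
  expect_equal(length(cids), 64)
  ## no stem cell touches a differentiated cell
  for (cid in cids[kinds == "S"]) {
    expect_false(any(ts$cl_type[neighbors(ts, cid)] == "D"))
  }
  expect_valid(ts)
})

test_that("zero basal rates freeze the population", {
  lp <- lineage_params(vS0 = 0, vP0 = 0)
  res <- simulate_size_control(lp, steps = 5, seed = 2)
  tc <- res$time_course
  expect_true(all(tc$total == tc$total[1]))
  expect_true(all(tc$N_S == tc$N_S[1]))
})

test_that("a short default run grows the tissue and keeps stem cells", {
  res <- simulate_size_control(lineage_params(), steps = 60, seed = 4)
  tc <- res$time_course
  expect_gt(tail(tc$total, 1), 64)
  expect_gt(tail(tc$N_S, 1), 0)
  expect_true(all(tc$N_S + tc$N_P + tc$N_D == tc$total))
  expect_valid(res$state)
})
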