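## Stem-cell-lineage control of homeostatic tissue size.
##
## Three cell kinds: stem (S), progenitor (P), differentiated (D). S divide
## without limit; P divide at most twice (the second division always
## symmetric); D never divide. Three division types: self-renewal (X ->
## X, X), symmetric differentiation (S -> P,P; P -> D,D) and asymmetric
## division (S -> S,P; P -> P,D). Growth rates and division-type
## probabilities are inhibited by the number N_D of differentiated cells
## within a set number of cell layers via Hill factors basal/(1 + coeff N_D);
## probability triples are renormalized to sum to one. Cells divide when
## their area doubles relative to birth.

#' Lineage model parameters
#'
#' @param vS0,vP0 basal area growth rates of stem / progenitor cells, per
#'   step, in units of the nominal cell area a0.
#' @param gS,hSr,hSs,hSa Hill coefficients (per differentiated neighbor) for
#'   the stem growth rate and the probabilities of self-renewal, symmetric
#'   differentiation and asymmetric division.
#' @param gP,hPr,hPs,hPa the corresponding progenitor coefficients.
#' @param inhibition_layers L: differentiated cells within this many layers
#'   inhibit.
#' @param max_P_divisions progenitor division budget.
#' @param seed run seed.
#' @return an object of class `lineage_params`. Basal division-type
#'   probabilities are fixed at 1/3 each (no inhibition).
#' @export
lineage_params <- function(vS0 = 1, vP0 = 1,
                           gS = 2, hSr = 0, hSs = 2, hSa = 2,
                           gP = 2, hPr = 0, hPs = 2, hPa = 2,
                           inhibition_layers = 3L, max_P_divisions = 2L,
                           seed = 1L) {
  stopifnot(vS0 >= 0, vP0 >= 0, inhibition_layers >= 0,
            all(c(gS, hSr, hSs, hSa, gP, hPr, hPs, hPa) >= 0))
  structure(list(vS0 = vS0, vP0 = vP0,
                 pSr0 = 1 / 3, pSs0 = 1 / 3, pSa0 = 1 / 3,
                 pPr0 = 1 / 3, pPs0 = 1 / 3, pPa0 = 1 / 3,
                 gS = gS, hSr = hSr, hSs = hSs, hSa = hSa,
                 gP = gP, hPr = hPr, hPs = hPs, hPa = hPa,
                 inhibition_layers = as.integer(inhibition_layers),
                 max_P_divisions = as.integer(max_P_divisions),
                 seed = as.integer(seed)),
            class = "lineage_params")
}

#' Hill feedback from differentiated neighbors
#'
#' Applies the eight Hill factors basal/(1 + coeff N_D) to the two growth
#' rates and the two probability triples, then renormalizes each triple to
#' sum to one. With N_D = 0 all probabilities are exactly 1/3.
#'
#' @param N_D number of differentiated cells in the neighborhood (>= 0).
#' @param params a [lineage_params()].
#' @return list(vS, vP, probs_S, probs_P); the triples are ordered
#'   (self-renewal, symmetric, asymmetric).
#' @export
feedback <- function(N_D, params) {
  stopifnot(N_D >= 0)
  hill <- function(base, coef) base / (1 + coef * N_D)
  probs_S <- c(r = hill(params$pSr0, params$hSr),
               s = hill(params$pSs0, params$hSs),
               a = hill(params$pSa0, params$hSa))
  probs_P <- c(r = hill(params$pPr0, params$hPr),
               s = hill(params$pPs0, params$hPs),
               a = hill(params$pPa0, params$hPa))
  list(vS = hill(params$vS0, params$gS),
       vP = hill(params$vP0, params$gP),
       probs_S = probs_S / sum(probs_S),
       probs_P = probs_P / sum(probs_P))
}

DIV_TYPES <- c("SELF_RENEWAL", "SYMMETRIC", "ASYMMETRIC")

#' Choose a division type
#'
#' Stem cells sample from probs_S; progenitors with one division used divide
#' symmetrically unconditionally (their second and last division);
#' first-division progenitors sample from probs_P. Differentiated cells do
#' not divide (contract violation).
#'
#' @param ts a tissue state.
#' @param cid id of the dividing cell (kind "S" or "P").
#' @param probs list as returned by [feedback()].
#' @return one of "SELF_RENEWAL", "SYMMETRIC", "ASYMMETRIC".
#' @export
choose_division_type <- function(ts, cid, probs) {
  kind <- ts$cl_type[cid]
  if (kind == "D") stop("Differentiated cells do not divide")
  if (kind == "P") {
    used <- ts$cl_attrs[[cid]]$divisions_used %||% 0L
    if (used >= 1L) return("SYMMETRIC")
    p <- probs$probs_P
  } else if (kind == "S") {
    p <- probs$probs_S
  } else {
    stop("cell ", cid, " is not part of the lineage model")
  }
  with_substream(ts, "lineage", function() sample(DIV_TYPES, 1, prob = p))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lineage_colors <- c(S = "#d62728", P = "#1f77b4", D = "#ffffff")

set_lineage_kind <- function(ts, cid, kind, divisions_used = 0L) {
  ts$cl_type[cid] <- kind
  ts$cl_color[cid] <- lineage_colors[[kind]]
  ts$cl_attrs[[cid]]$divisions_used <- as.integer(divisions_used)
  ts$cl_attrs[[cid]]$birth_area <- cell_area(ts, cid)
  invisible(ts)
}

#' Divide a lineage cell and assign daughter kinds
#'
#' Performs the geometric division (random orientation) and labels the
#' daughters: self-renewal X -> (X, X); symmetric differentiation S -> (P,
#' P), P -> (D, D); asymmetric S -> (S, P), P -> (P, D). Progenitor
#' daughters of a progenitor inherit the incremented division count; fresh
#' progenitors born of a stem cell start at zero.
#'
#' @param ts a tissue state.
#' @param cid id of the dividing S or P cell.
#' @param div_type a division type from [choose_division_type()].
#' @return integer vector of the two daughter ids (the first is the mother's
#'   id, reused).
#' @export
apply_division <- function(ts, cid, div_type) {
  kind <- ts$cl_type[cid]
  stopifnot(kind %in% c("S", "P"), div_type %in% DIV_TYPES)
  used <- ts$cl_attrs[[cid]]$divisions_used %||% 0L
  did <- suppressWarnings(divide_cell(ts, cid))
  if (is.na(did)) return(invisible(NULL))   # deferred: retried next step
  if (kind == "S") {
    kinds <- switch(div_type,
                    SELF_RENEWAL = c("S", "S"),
                    SYMMETRIC = c("P", "P"),
                    ASYMMETRIC = c("S", "P"))
    uses <- c(0L, 0L)
  } else {
    kinds <- switch(div_type,
                    SELF_RENEWAL = c("P", "P"),
                    SYMMETRIC = c("D", "D"),
                    ASYMMETRIC = c("P", "D"))
    uses <- ifelse(kinds == "P", used + 1L, 0L)
  }
  set_lineage_kind(ts, cid, kinds[1], uses[1])
  set_lineage_kind(ts, did, kinds[2], uses[2])
  c(cid, did)
}

#' Initial tissue of the size-control experiments
#'
#' A small planar tissue of 64 cells: 10 stem cells in the center,
#' surrounded by a shell of 16 progenitor cells, with 38 differentiated
#' cells outside, relaxed to stationarity. No stem cell touches a
#' differentiated cell.
#'
#' @param params a [sim_params()].
#' @param tensions a [tension_table()].
#' @return a [tissue_state()].
#' @export
build_initial_tissue <- function(params = sim_params(),
                                 tensions = tension_table()) {
  ts <- build_hex_blob(64, params = params, tensions = tensions,
                       relax = FALSE)
  cids <- cell_ids(ts)
  cents <- t(vapply(cids, function(c) cell_centroid(ts, c), numeric(2)))
  d <- sqrt(cents[, 1]^2 + cents[, 2]^2)
  ord <- order(d, atan2(cents[, 2], cents[, 1]))
  S <- cids[ord[1:10]]
  ## progenitors: all cells adjacent to the stem block, then nearest others
  shell <- setdiff(unique(unlist(lapply(S, function(c) neighbors(ts, c)))), S)
  rest <- setdiff(cids[ord], c(S, shell))
  P <- c(shell, rest)[1:16]
  D <- setdiff(cids, c(S, P))
  for (c in S) set_lineage_kind(ts, c, "S")
  for (c in P) set_lineage_kind(ts, c, "P")
  for (c in D) set_lineage_kind(ts, c, "D")
  relax(ts)
  for (c in cell_ids(ts)) ts$cl_attrs[[c]]$birth_area <- cell_area(ts, c)
  ts
}

#' Simulate homeostatic tissue size control
#'
#' Each step: every S/P cell counts differentiated cells within
#' `inhibition_layers`, obtains its growth rate and division-type
#' probabilities from [feedback()], and grows by its rate; cells whose area
#' has doubled since birth divide per [choose_division_type()] /
#' [apply_division()]. Differentiated cells neither grow nor divide. The
#' population time course is recorded every step.
#'
#' @param params a [lineage_params()].
#' @param steps number of steps.
#' @param seed run seed (overrides `params$seed`).
#' @param ts optional starting tissue (default [build_initial_tissue()]).
#' @param sim optional [sim_params()].
#' @return list(time_course = data.frame(step, N_S, N_P, N_D, total, area),
#'   state = final tissue state).
#' @export
simulate_size_control <- function(params = lineage_params(), steps = 300L,
                                  seed = params$seed, ts = NULL,
                                  sim = NULL) {
  if (is.null(sim)) sim <- sim_params(seed = seed)
  if (is.null(ts)) ts <- build_initial_tissue(params = sim)
  rng_init(ts, seed)
  a0 <- ts$params$a0
  L <- params$inhibition_layers
  tc <- vector("list", steps)
  for (s in seq_len(steps)) {
    cids <- cell_ids(ts)
    kinds <- ts$cl_type[cids]
    live <- cids[kinds %in% c("S", "P")]
    dv <- numeric(0)
    fb_cache <- new.env(parent = emptyenv())
    fb_of <- function(nd) {
      key <- as.character(nd)
      f <- fb_cache[[key]]
      if (is.null(f)) {
        f <- feedback(nd, params)
        fb_cache[[key]] <- f
      }
      f
    }
    nd_map <- integer(0)
    if (length(live)) {
      nd_vals <- vapply(live, function(c) {
        nb <- neighbor_layers(ts, c, L)
        sum(ts$cl_type[nb] == "D")
      }, integer(1))
      nd_map <- setNames(nd_vals, live)
      rates <- vapply(seq_along(live), function(i) {
        f <- fb_of(nd_vals[i])
        if (ts$cl_type[live[i]] == "S") f$vS else f$vP
      }, numeric(1))
      dv <- setNames(rates * a0, live)
      dv <- dv[dv > 0]
    }
    update_cell_pattern(ts, growth_plan(dV = dv))
    ## divisions on volume doubling
    cids <- cell_ids(ts)
    for (cid in cids[ts$cl_type[cids] %in% c("S", "P")]) {
      birth <- ts$cl_attrs[[cid]]$birth_area %||% cell_area(ts, cid)
      if (cell_area(ts, cid) >= 2 * birth) {
        nd <- nd_map[as.character(cid)]
        if (is.na(nd) || is.null(nd)) {
          nb <- neighbor_layers(ts, cid, L)
          nd <- sum(ts$cl_type[nb] == "D")
        }
        f <- fb_of(nd)
        dtype <- choose_division_type(ts, cid, f)
        apply_division(ts, cid, dtype)
      }
    }
    cids <- cell_ids(ts)
    kinds <- ts$cl_type[cids]
    tc[[s]] <- data.frame(step = s,
                          N_S = sum(kinds == "S"),
                          N_P = sum(kinds == "P"),
                          N_D = sum(kinds == "D"),
                          total = length(cids),
                          area = total_area(ts))
  }
  list(time_course = do.call(rbind, tc), state = ts)
}
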