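## Bristle patterning on a growing epidermis.
##
## Five mechanisms, differing only in the inhibition range R (in cell
## layers) and in whether commitment is restricted to permissive expression
## stripes: pre-destined (R = 0), lateral inhibition (R = 1), lateral
## inhibition with stripes, inhibition field (R = 2..4), inhibition field
## with stripes. Commitment is seeded sequential stochastic adsorption with
## exclusion: each step, every uncommitted permissive cell with no bristle
## within R layers becomes a bristle with probability p_commit, in random
## order; a committed cell immediately inhibits its neighborhood. Committed
## bristle cells leave the cell cycle (no further growth or division).

#' Parameters of the Dl morphogen gradient
#'
#' Steady state of 1D diffusion with linear degradation over the tissue:
#' c(x) = c0 exp(-x sqrt(k_deg / D)). The degradation rate default is
#' calibrated once so that D = 1.2 um^2/s gives a 10 um reach at the 0.05
#' response threshold.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param k_deg degradation rate (1/s).
#' @param threshold dimensionless cell response threshold in (0, 1].
#' @param c0 source concentration (dimensionless).
#' @return an object of class `gradient_params`.
#' @export
gradient_params <- function(D = 1.2, k_deg = NULL, threshold = 0.05, c0 = 1) {
  if (is.null(k_deg)) {
    ## reach = sqrt(D/k) log(c0/threshold) = 10 um at D = 1.2
    k_deg <- 1.2 * (log(1 / 0.05) / 10)^2
  }
  stopifnot(D > 0, k_deg > 0, threshold > 0, threshold <= 1, c0 > 0)
  structure(list(D = D, k_deg = k_deg, threshold = threshold, c0 = c0),
            class = "gradient_params")
}

#' Steady-state Dl concentration profile
#'
#' @param params a [gradient_params()].
#' @param x distance from the source (um), >= 0.
#' @return concentration at x (monotone decreasing, c(0) = c0).
#' @export
dl_profile <- function(params, x) {
  stopifnot(all(x >= 0))
  params$c0 * exp(-x * sqrt(params$k_deg / params$D))
}

#' Inhibition reach of the Dl gradient
#'
#' The distance at which the steady-state profile falls to the response
#' threshold: sqrt(D/k_deg) log(c0/threshold); 0 if the threshold is not
#' below the source concentration.
#'
#' @param params a [gradient_params()].
#' @return distance in um.
#' @export
inhibition_reach <- function(params) {
  if (params$threshold >= params$c0) return(0)
  sqrt(params$D / params$k_deg) * log(params$c0 / params$threshold)
}

#' Convert a metric reach to cell layers
#'
#' @param reach distance in um (>= 0).
#' @param diameter nominal cell diameter in um (default 10).
#' @return integer number of layers, ceiling(reach / diameter).
#' @export
reach_to_layers <- function(reach, diameter = 10) {
  stopifnot(all(reach >= 0))
  as.integer(ceiling(reach / diameter - 1e-9))
}

#' Stripe specification
#'
#' Vertical expression bands of width `width_cells` cell diameters repeating
#' with period `period_cells` (default three bands: the proneural stripe
#' with high ac/Dl and low N expression, where bristles may form, plus two
#' non-permissive bands).
#'
#' @param width_cells band width W in cell columns (>= 1); the paper's
#'   stripes are measured in cells, not micrometers.
#' @param period_cells repeat period (default 3 W).
#' @param permissive_band index (0-based, within one period of
#'   `period_cells / width_cells` bands) of the band hosting bristles.
#' @param cell_diameter mean cell diameter in d0 units used to convert cell
#'   columns to spatial width; the default 1 gives the nominal bands of
#'   W * d0. (Under division at volume doubling the steady-state mean cell
#'   diameter is nearer 1.2 d0; pass that to make bands exactly W columns.)
#' @return an object of class `stripe_spec`.
#' @export
stripe_spec <- function(width_cells = 3L, period_cells = 3L * width_cells,
                        permissive_band = 0L, cell_diameter = 1) {
  stopifnot(width_cells >= 1, period_cells >= width_cells, cell_diameter > 0)
  structure(list(width_cells = as.integer(width_cells),
                 period_cells = as.integer(period_cells),
                 permissive_band = as.integer(permissive_band),
                 cell_diameter = cell_diameter),
            class = "stripe_spec")
}

#' Band classification of a cell
#'
#' @param ts a tissue state.
#' @param cid cell id (classified by centroid x position; `x` may be given
#'   directly instead).
#' @param stripes a [stripe_spec()].
#' @param x optional x coordinate overriding the centroid lookup.
#' @return list(stripe = period index, band = band index within the period,
#'   permissive = flag).
#' @export
stripe_of <- function(ts, cid, stripes, x = NULL) {
  if (is.null(x)) x <- cell_centroid(ts, cid)[1]
  w <- stripes$width_cells * stripes$cell_diameter
  period <- stripes$period_cells * stripes$cell_diameter
  band <- floor(x / w) %% round(period / w)
  stripe <- floor(x / period)
  ## normalized position within the band, -0.5 (left edge) .. 0.5 (right)
  xi <- (x %% w) / w - 0.5
  list(stripe = stripe, band = band,
       permissive = band == stripes$permissive_band, xi = xi)
}

#' Bristle model configuration
#'
#' @param model one of "pre_destined", "lateral", "lateral_stripes",
#'   "field", "field_stripes".
#' @param R inhibition range in cell layers; defaults to the model's
#'   canonical value (0, 1, 1, 3, 3).
#' @param stripes a [stripe_spec()] (stripe models only).
#' @param p_commit per-step commitment probability of an eligible cell.
#' @param target_cells grow until at least this many cells.
#' @param commit_after start commitment passes once the tissue exceeds this
#'   many cells. Unstriped mechanisms default to 50 (commitment interleaved
#'   with growth, which dilutes the bristle fraction); striped mechanisms
#'   default to committing only on the full-grown tissue, because the
#'   expression stripes are a feature of the late epithelium and radial
#'   growth would otherwise drag early bristles across the pattern.
#' @param final_passes commitment passes run on the full-grown tissue.
#' @param growth_rate per-step area increase of a cycling cell, as a
#'   fraction of the nominal cell area.
#' @param seed run seed.
#' @return an object of class `bristle_config`.
#' @export
bristle_config <- function(model = c("lateral", "pre_destined",
                                     "lateral_stripes", "field",
                                     "field_stripes"),
                           R = NULL, stripes = NULL, p_commit = 0.02,
                           target_cells = 2000L, commit_after = NULL,
                           final_passes = NULL, growth_rate = 0.1,
                           seed = 1L) {
  model <- match.arg(model)
  if (is.null(R)) {
    R <- switch(model, pre_destined = 0L, lateral = 1L, lateral_stripes = 1L,
                field = 3L, field_stripes = 3L)
  }
  striped <- model %in% c("lateral_stripes", "field_stripes")
  if (striped && is.null(stripes)) stripes <- stripe_spec()
  if (!striped) stripes <- NULL
  if (model == "pre_destined" && R != 0) stop("pre_destined implies R = 0")
  if (model %in% c("lateral", "lateral_stripes") && R != 1)
    stop("lateral inhibition implies R = 1")
  if (model %in% c("field", "field_stripes") && !(R %in% 2:4))
    stop("inhibition field uses R in 2..4")
  if (is.null(commit_after)) commit_after <- if (striped) Inf else 50L
  if (is.null(final_passes)) final_passes <- if (striped) 120L else 5L
  structure(list(model = model, R = as.integer(R), stripes = stripes,
                 p_commit = p_commit, target_cells = as.integer(target_cells),
                 commit_after = commit_after,
                 final_passes = as.integer(final_passes),
                 growth_rate = growth_rate, seed = as.integer(seed)),
            class = "bristle_config")
}

is_bristle <- function(ts, cids) ts$cl_type[cids] == "bristle"

## Expression stripes are material: cells are assigned to a band once (by
## centroid position, the first time commitment sees them) and daughters
## inherit the label, so the bands deform and stretch with tissue growth
## exactly as gene-expression stripes would. Returns the ids tagged.
assign_stripe_labels <- function(ts, stripes, cids = cell_ids(ts)) {
  for (cid in cids) {
    if (is.null(ts$cl_attrs[[cid]]$band)) {
      sf <- stripe_of(ts, cid, stripes)
      ts$cl_attrs[[cid]]$band <- sf$band
      ts$cl_attrs[[cid]]$stripe <- sf$stripe
    }
  }
  invisible(cids)
}

cell_band <- function(ts, cid) ts$cl_attrs[[cid]]$band
cell_stripe <- function(ts, cid) ts$cl_attrs[[cid]]$stripe

#' One commitment pass
#'
#' Every uncommitted cell that is permissive (stripe models) and has no
#' bristle within R layers becomes a bristle with probability p_commit,
#' processed in seeded random order; each commitment immediately inhibits
#' its R-layer neighborhood. On exit no two bristles lie within R layers of
#' each other (for R >= 1).
#'
#' @param ts a tissue state.
#' @param config a [bristle_config()].
#' @param reuse_blocked reuse the inhibition set computed by the previous
#'   pass (valid only while the topology is unchanged; used for the
#'   commitment passes on the full-grown tissue).
#' @return the ids of newly committed cells, invisibly.
#' @export
commit_fates <- function(ts, config, reuse_blocked = FALSE) {
  cids <- cell_ids(ts)
  R <- config$R
  bristles <- cids[is_bristle(ts, cids)]
  if (reuse_blocked && !is.null(ts$commit_blocked) &&
      length(ts$commit_blocked) == ts$ncl) {
    blocked <- ts$commit_blocked
  } else {
    blocked <- rep(FALSE, ts$ncl)
    if (R >= 1) {
      for (b in bristles) blocked[c(b, neighbor_layers(ts, b, R))] <- TRUE
    }
  }
  cand <- cids[!is_bristle(ts, cids)]
  wgt <- rep(1, length(cand))
  if (!is.null(config$stripes)) {
    assign_stripe_labels(ts, config$stripes, cids)
    xs <- vapply(cand, function(c) cell_centroid(ts, c)[1], numeric(1))
    sf <- lapply(seq_along(cand), function(i)
      stripe_of(ts, cand[i], config$stripes, x = xs[i]))
    perm <- vapply(sf, `[[`, logical(1), "permissive")
    ## proneural expression peaks at the stripe midline and fades toward
    ## the edges; commitment probability follows the profile
    xi <- vapply(sf, `[[`, numeric(1), "xi")
    wgt <- pmax(0, 1 - (2 * xi)^2)
    cand <- cand[perm]; wgt <- wgt[perm]
  }
  if (!length(cand)) return(invisible(integer(0)))
  committed <- integer(0)
  ord_and_draws <- with_substream(ts, "fates", function() {
    list(ord = sample(length(cand)), u = stats::runif(length(cand)))
  })
  cand <- cand[ord_and_draws$ord]
  wgt <- wgt[ord_and_draws$ord]
  u <- ord_and_draws$u
  for (i in seq_along(cand)) {
    cid <- cand[i]
    if (R >= 1 && blocked[cid]) next
    if (u[i] < config$p_commit * wgt[i]) {
      ts$cl_type[cid] <- "bristle"
      ts$cl_color[cid] <- "#222222"
      committed <- c(committed, cid)
      if (R >= 1) blocked[c(cid, neighbor_layers(ts, cid, R))] <- TRUE
    }
  }
  ts$commit_blocked <- blocked
  invisible(committed)
}

#' Grow a tissue by uniform growth and division on volume doubling
#'
#' Cells grow by `growth_rate * a0` per step and divide (random orientation)
#' when their area reaches twice their birth area. `hold` names types that
#' neither grow nor divide.
#'
#' @param ts a tissue state.
#' @param steps number of steps, or run until `until_cells` is reached.
#' @param growth_rate per-step area increment as a fraction of a0.
#' @param until_cells stop once the tissue has at least this many cells.
#' @param hold character vector of non-cycling type labels.
#' @param jitter relative spread of the per-cell growth rate: each cell draws
#'   a fixed factor uniform in 1 +/- jitter when first seen (seeded), which
#'   desynchronizes divisions across the tissue.
#' @param on_step optional callback function(ts, step_index) run after each
#'   step (used for fate commitment).
#' @return the state, invisibly.
#' @export
grow_tissue <- function(ts, steps = Inf, growth_rate = 0.1,
                        until_cells = NULL, hold = "bristle",
                        jitter = 0.25, on_step = NULL) {
  a0 <- ts$params$a0
  step_i <- 0L
  repeat {
    step_i <- step_i + 1L
    if (step_i > steps) break
    if (!is.null(until_cells) && n_cells(ts) >= until_cells) break
    cids <- cell_ids(ts)
    grow <- cids[!(ts$cl_type[cids] %in% hold)]
    if (length(grow)) {
      fac <- vapply(grow, function(cid) {
        f <- ts$cl_attrs[[cid]]$growth_factor
        if (is.null(f)) {
          f <- with_substream(ts, "growth", function()
            stats::runif(1, 1 - jitter, 1 + jitter))
          ts$cl_attrs[[cid]]$growth_factor <- f
        }
        f
      }, numeric(1))
      dv <- setNames(growth_rate * a0 * fac, grow)
      update_cell_pattern(ts, growth_plan(dV = dv))
    } else {
      update_cell_pattern(ts, growth_plan())
    }
    ## divisions on volume doubling
    cids <- cell_ids(ts)
    for (cid in cids[!(ts$cl_type[cids] %in% hold)]) {
      birth <- ts$cl_attrs[[cid]]$birth_area
      if (is.null(birth)) {
        birth <- cell_area(ts, cid)
        ts$cl_attrs[[cid]]$birth_area <- birth
      }
      if (cell_area(ts, cid) >= 2 * birth) {
        did <- suppressWarnings(divide_cell(ts, cid))
        if (!is.na(did)) {
          ts$cl_attrs[[cid]]$birth_area <- cell_area(ts, cid)
          ts$cl_attrs[[did]]$birth_area <- cell_area(ts, did)
          ## daughters inherit material labels (expression stripes)
          ts$cl_attrs[[did]]$band <- ts$cl_attrs[[cid]]$band
          ts$cl_attrs[[did]]$stripe <- ts$cl_attrs[[cid]]$stripe
          ts$cl_attrs[[did]]$growth_factor <- NULL
        }
      }
    }
    if (!is.null(on_step)) on_step(ts, step_i)
  }
  invisible(ts)
}

#' Run a bristle patterning experiment
#'
#' Grows a tissue from a two-cell doublet to the configured size with fate
#' commitment interleaved (one pass per growth step once the tissue exceeds
#' `commit_after` cells), then runs a few final commitment passes on the
#' full-grown tissue.
#'
#' @param config a [bristle_config()].
#' @param params,tensions optional simulation parameter overrides.
#' @param tissue optional pre-grown tissue to commit fates on. Only valid
#'   for mechanisms whose commitment runs entirely on the full-grown tissue
#'   (the striped ones by default); the tissue is reseeded from the
#'   configuration and modified in place.
#' @return the final [tissue_state()].
#' @export
run_bristle_experiment <- function(config = bristle_config(),
                                   params = NULL, tensions = tension_table(),
                                   tissue = NULL) {
  if (is.null(tissue)) {
    if (is.null(params)) params <- sim_params(seed = config$seed)
    ts <- build_doublet(r = sqrt(params$a0 / pi), params = params,
                        tensions = tensions)
    rng_init(ts, config$seed)
    for (cid in cell_ids(ts)) ts$cl_attrs[[cid]]$birth_area <- cell_area(ts, cid)
    grow_tissue(ts, growth_rate = config$growth_rate,
                until_cells = config$target_cells,
                on_step = function(ts, i) {
                  if (n_cells(ts) > config$commit_after) commit_fates(ts, config)
                })
  } else {
    if (is.finite(config$commit_after))
      stop("a pre-grown tissue can only be used when commitment is post-growth")
    ts <- tissue
    rng_init(ts, config$seed)
    ts$commit_blocked <- NULL
  }
  for (i in seq_len(config$final_passes)) {
    commit_fates(ts, config, reuse_blocked = i > 1)
  }
  ts
}

#' Bristle alignment statistics
#'
#' The alignment index of the striped patterns: for each bristle, d(i,j) is
#' the number of cells lying between the bristle and the vertical midline of
#' its stripe j, counted along the bristle's own horizontal row of cells;
#' rho is the grand mean of d over all bristles and frac_on_line the
#' fraction with d = 0.
#'
#' @param ts a tissue state.
#' @param stripes a [stripe_spec()].
#' @param offset_method "count" (count cells whose centroid falls strictly
#'   between, in a metric row window; the default) or "round" (offset in
#'   mean-cell-width units).
#' @return an `alignment_report` list: rho, frac_on_line, bristle_fraction,
#'   n_bristles, and the per-bristle table.
#' @export
alignment_index <- function(ts, stripes,
                            offset_method = c("round", "count")) {
  offset_method <- match.arg(offset_method)
  cids <- cell_ids(ts)
  cents <- t(vapply(cids, function(c) cell_centroid(ts, c), numeric(2)))
  areas <- vapply(cids, function(c) cell_area(ts, c), numeric(1))
  bsel <- is_bristle(ts, cids)
  if (!any(bsel)) {
    return(structure(list(rho = NA_real_, frac_on_line = NA_real_,
                          bristle_fraction = 0, n_bristles = 0L,
                          table = NULL), class = "alignment_report"))
  }
  wbar <- mean(2 * sqrt(areas / pi))  # mean cell diameter
  w <- stripes$width_cells * stripes$cell_diameter
  period <- stripes$period_cells * stripes$cell_diameter
  ## material stripes: if cells carry band labels, the midline of a stripe
  ## is drawn through its own (possibly deformed, grown) permissive cells,
  ## row by row; otherwise the fixed spatial bands apply
  bands <- vapply(cids, function(c) {
    b <- ts$cl_attrs[[c]]$band
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  stripes_id <- vapply(cids, function(c) {
    b <- ts$cl_attrs[[c]]$stripe
    if (is.null(b)) NA_integer_ else as.integer(b)
  }, integer(1))
  material <- any(!is.na(bands))
  rows <- lapply(which(bsel), function(i) {
    x <- cents[i, 1]; y <- cents[i, 2]
    if (material && !is.na(stripes_id[i])) {
      stripe <- stripes_id[i]
      member <- !is.na(stripes_id) & stripes_id == stripe &
        bands == stripes$permissive_band
      inrow <- member & abs(cents[, 2] - y) < 1.2 * wbar
      x_mid <- if (sum(inrow) >= 3) mean(cents[inrow, 1]) else
        mean(cents[member, 1])
    } else {
      off <- stripes$permissive_band * w + w / 2
      stripe <- round((x - off) / period)
      x_mid <- stripe * period + off
    }
    if (offset_method == "round") {
      d <- round(abs(x - x_mid) / wbar)
    } else {
      lo <- min(x, x_mid); hi <- max(x, x_mid)
      inrow2 <- abs(cents[, 2] - y) < 0.55 * wbar & cids != cids[i]
      d <- sum(inrow2 & cents[, 1] > lo & cents[, 1] < hi)
    }
    c(stripe = stripe, bristle = cids[i], d = d)
  })
  tab <- do.call(rbind, rows)
  structure(list(rho = mean(tab[, "d"]),
                 frac_on_line = mean(tab[, "d"] == 0),
                 bristle_fraction = mean(bsel),
                 n_bristles = sum(bsel),
                 table = as.data.frame(tab)),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf("alignment: rho = %.3f, %.1f%% on line, %d bristles (%.1f%% of cells)\n",
              x$rho, 100 * x$frac_on_line, x$n_bristles,
              100 * x$bristle_fraction))
  invisible(x)
}
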