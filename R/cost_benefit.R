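# -- phosphorus economics of the root system ---------------------------------
#
# Cost of a root class = its weight times the tissue P concentration
# (0.8 ug P per mg root at 28 DAE).  Benefits are the cumulative P uptake per
# class; efficiencies are uptake per length/surface/weight; cost recovery is
# evaluated under three scenarios (static daily rate, growing single-class
# system with and without hairs).

LEDGER_CLASSES <- c("hairs", "stype", "ltype", "nodal", "total")

#' Derive the economic columns of a class ledger
#'
#' Given the base columns (`P_uptake_ug`, `length_m`, `surface_cm2`,
#' `weight_mg`), computes cost (`weight * tissue_P_conc`), the three uptake
#' efficiencies and the benefit-to-cost ratio as exact quotients of each
#' row's own entries.  Zero denominators yield 0 efficiencies/ratios for
#' rows with zero uptake and `NA` otherwise.
#'
#' @param base data.frame with columns `class`, `P_uptake_ug`, `length_m`,
#'   `surface_cm2`, `weight_mg`.
#' @param tissue_P_conc Tissue P concentration, ug P per mg root (= mg/g).
#' @return `base` with columns `cost_ug`, `eff_length_ug_m`,
#'   `eff_surface_ug_cm2`, `eff_weight_ug_mg`, `benefit_cost` appended.
#' @export
ledger_derive <- function(base, tissue_P_conc = 0.8) {
  q <- function(num, den) ifelse(den > 0, num / den, ifelse(num == 0, 0, NA))
  base$cost_ug <- base$weight_mg * tissue_P_conc
  base$eff_length_ug_m <- q(base$P_uptake_ug, base$length_m)
  base$eff_surface_ug_cm2 <- q(base$P_uptake_ug, base$surface_cm2)
  base$eff_weight_ug_mg <- q(base$P_uptake_ug, base$weight_mg)
  base$benefit_cost <- q(base$P_uptake_ug, base$cost_ug)
  base
}

#' Benefit-to-cost ratio of a ledger row
#'
#' @param row One row of a class ledger (needs `P_uptake_ug` and `cost_ug`).
#' @return `P_uptake_ug / cost_ug`.
#' @export
benefit_cost <- function(row) {
  if (row$cost_ug <= 0) stop("benefit-cost undefined at zero cost")
  row$P_uptake_ug / row$cost_ug
}

#' Build the per-class cost-benefit ledger
#'
#' Collapses the geometry, hair and uptake records of a simulation into the
#' five-row economics ledger (hairs / S-type / L-type / nodal / total).  The
#' primary root is folded into the nodal row, as the nodal class groups all
#' main axes.
#'
#' @param geometry Output of [class_geometry()].
#' @param hair_ledger Output of [hair_geometry()].
#' @param uptake A `rhizo_uptake` object (or a data.frame shaped like its
#'   `class_totals`).
#' @param at Day of evaluation (default 31, i.e. 28 DAE).
#' @param tissue_P_conc Tissue P concentration, ug/mg.
#' @return A data.frame of class ledger rows with all derived columns.
#' @export
build_ledger <- function(geometry, hair_ledger, uptake, at = 31,
                         tissue_P_conc = 0.8) {
  ct <- if (inherits(uptake, "rhizo_uptake")) uptake$class_totals else uptake
  nodal_ids <- c("primary", "nodal_branched", "nodal_fast", "nodal_tiller")
  pick <- function(ids) {
    g <- geometry[geometry$class %in% ids, ]
    u <- ct[ct$class %in% ids & ct$structure == "root", ]
    c(uptake = sum(u$uptake_ug), length = sum(g$length_cm) / 100,
      surface = sum(g$surface_cm2), weight = sum(g$weight_g) * 1000)
  }
  hl <- hair_ledger[hair_ledger$class != "total", ]
  hu <- ct[ct$structure == "hair", ]
  rows <- rbind(
    hairs = c(uptake = sum(hu$uptake_ug), length = sum(hl$hair_length_cm) / 100,
              surface = sum(hl$hair_surface_cm2),
              weight = sum(hl$hair_weight_g) * 1000),
    stype = pick("stype"),
    ltype = pick("ltype"),
    nodal = pick(nodal_ids))
  rows <- rbind(rows, total = colSums(rows))
  base <- data.frame(class = rownames(rows),
                     P_uptake_ug = rows[, "uptake"],
                     length_m = rows[, "length"],
                     surface_cm2 = rows[, "surface"],
                     weight_mg = rows[, "weight"],
                     row.names = NULL, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(base)))
    if (base$weight_mg[i] <= 0 && base$P_uptake_ug[i] > 1e-9)
      warning("class '", base$class[i],
              "' has zero weight but nonzero uptake")
  out <- ledger_derive(base, tissue_P_conc)
  attr(out, "at") <- at
  out
}

#' Write a ledger CSV in the published column order
#'
#' One decimal for the microgram quantities and ratios, mirroring the
#' published per-class table so that differences are directly readable.
#'
#' @param ledger A ledger data.frame from [build_ledger()].
#' @param file Output CSV path.
#' @return `file`, invisibly.
#' @export
write_ledger_csv <- function(ledger, file) {
  out <- ledger
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 1))
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' Cost recovery, Case 1: static rates at 28 DAE
#'
#' Days needed to recover the construction cost of a class at its current
#' daily uptake, both held static at the evaluation day.
#'
#' @param cost_ug Class cost, ug P.
#' @param daily_uptake_ug Daily P uptake of the class at the evaluation day,
#'   ug/day.
#' @return Days (0 for zero cost, `Inf` = "never" for zero daily uptake).
#' @export
recovery_case1 <- function(cost_ug, daily_uptake_ug) {
  if (cost_ug < 0 || daily_uptake_ug < 0) stop("negative input")
  if (cost_ug == 0) return(0)
  if (daily_uptake_ug <= 0) return(Inf)
  cost_ug / daily_uptake_ug
}

# Synthetic continuously growing single-class system: one axis of the class
# elongating along its growth curve at multiplier 1, re-initiating as soon as
# it reaches the class maximum length.  Axes are laid out along parallel
# lines far enough apart that their uptake domains do not share voxels.
single_class_system <- function(class_id, params, horizon, dt = 0.2) {
  cp <- params$classes[[class_id]]
  gc <- cp$growth_curve
  tau <- class_tau(cp)
  stopf <- class_stop_frac(cp)
  sys <- new.env(parent = emptyenv())
  sys$clock <- horizon
  sys$n <- 0L
  segs <- list()
  t0 <- 0; axis <- 1L; row0 <- 0
  nstep <- ceiling(horizon / dt)
  lenprev <- 0
  for (k in seq_len(nstep)) {
    tk <- k * dt
    len <- cum_length(tk - t0, cp$peak_growth_rate, 1, cp$max_length,
                      gc$ramp_days, gc$ramp_exp, tau)
    ext <- len - lenprev
    if (ext > 1e-12) {
      segs[[length(segs) + 1]] <-
        c(axis, class_code(class_id), tk, lenprev, row0, 5,
          len, row0, 5, ext)
    }
    lenprev <- len
    if (len >= stopf * cp$max_length - 1e-9) {  # re-initiate a fresh axis
      axis <- axis + 1L
      t0 <- tk
      row0 <- row0 + 5                      # 5 cm apart: no voxel sharing
      lenprev <- 0
    }
  }
  sys$n <- axis
  sys$nseg <- length(segs)
  sys$segs <- do.call(rbind, segs)
  colnames(sys$segs) <- c("axis", "cls", "tb", "x0", "y0", "z0",
                          "x1", "y1", "z1", "len")
  class(sys) <- "root_system"
  sys
}

# Cumulative cost (ug P) of a growing system at the uptake time grid,
# including hair construction cost.
system_cost_ts <- function(sys, params, times) {
  s <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
  diam <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "diameter")
  rho <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "tissue_density")
  tp <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "tissue_P_conc")
  hl <- vapply(params$classes[RHIZO_CLASSES],
               function(cp) cp$hair$length, 0)
  hd <- vapply(params$classes[RHIZO_CLASSES],
               function(cp) cp$hair$max_density, 0)
  hdi <- vapply(params$classes[RHIZO_CLASSES],
                function(cp) cp$hair$diameter, 0)
  cls <- s[, "cls"]
  root_cost <- pi * (diam[cls] / 2)^2 * s[, "len"] * rho[cls] * 1000 *
    tp[cls]
  # hairs appear with the segment at the ceiling density; their retirement
  # does not refund cost
  hair_cost <- hd[cls] * s[, "len"] * hl[cls] *
    pi * (hdi[cls] / 2)^2 * 0.1 * 1000 * tp[cls]
  cost <- root_cost + hair_cost
  vapply(times, function(tk) sum(cost[s[, "tb"] <= tk + 1e-9]), 0)
}

#' Cost recovery, Case 2: growing single-class system
#'
#' Break-even time of a hypothetical root system made up entirely of one
#' root class: a single axis elongates along the class growth curve and
#' re-initiates at its maximum length, so the system grows continuously;
#' class-default hairs are attached.  The break-even point is the first day
#' at which cumulative P uptake is at least the cumulative construction cost.
#'
#' @param class_id Root class id.
#' @param params A `rhizo_params` object (use a calibrated `soil$Imax`).
#' @param horizon Days to search (default 60).
#' @param dt,n_radial Solver resolution.
#' @param include_hairs Hairs attached (`TRUE`; Case 3 sets `FALSE`).
#' @return Break-even day, or `Inf` ("never") if not reached by `horizon`.
#' @export
recovery_case2 <- function(class_id, params = dj123_params(), horizon = 60,
                           dt = 0.2, n_radial = params$uptake$n_radial,
                           include_hairs = TRUE) {
  p <- params
  if (!include_hairs)
    for (nm in names(p$classes)) p$classes[[nm]]$hair$max_density <- 0
  sys <- single_class_system(class_id, p, horizon, dt)
  up <- system_uptake(sys, p, horizon = horizon, dt = dt,
                      n_radial = n_radial, include_hairs = include_hairs)
  times <- up$content_ts$time
  uptake <- up$content_ts$P_ug
  cost <- system_cost_ts(sys, p, times)
  ok <- which(uptake >= cost & cost > 0)
  if (length(ok) == 0) Inf else times[min(ok)]
}

#' Cost recovery, Case 3: growing single-class system without hairs
#'
#' As [recovery_case2()], with hair density forced to zero (no hair uptake
#' and no hair cost).  Hairs add benefit at negligible cost, so Case 3 break
#' even times are never earlier than Case 2.
#'
#' @inheritParams recovery_case2
#' @return Break-even day, or `Inf` ("never").
#' @export
recovery_case3 <- function(class_id, params = dj123_params(), horizon = 60,
                           dt = 0.2, n_radial = params$uptake$n_radial) {
  recovery_case2(class_id, params, horizon, dt, n_radial,
                 include_hairs = FALSE)
}

#' Compare hypothetical root architectures
#'
#' Re-runs the full pipeline for hypothetical variants of the base
#' parameterization - shorter (0.5x) or longer (2x) S-type or L-type lateral
#' roots, and thinner fast nodal roots (diameter 0.065 -> 0.050 cm) - and
#' reports whole-plant changes in P uptake and cost plus the per-class
#' benefit-to-cost ratios.
#'
#' @param params Base `rhizo_params` (use a calibrated `soil$Imax`).
#' @param variants Character vector out of `"base"`, `"stype_half"`,
#'   `"stype_double"`, `"ltype_half"`, `"ltype_double"`, `"nodal_thin"`.
#' @param seed Seed shared by all runs (paired comparison).
#' @param horizon Evaluation day.
#' @param dt,n_radial Solver resolution.
#' @return data.frame: one row per variant with `P_uptake_ug`, `cost_ug`,
#'   `d_uptake_pct`, `d_cost_pct` and per-class `bcr_*` columns.
#' @export
hypothetical_scan <- function(params = dj123_params(),
                              variants = c("stype_half", "stype_double",
                                           "ltype_half", "ltype_double",
                                           "nodal_thin"),
                              seed = 1, horizon = 31, dt = 0.2,
                              n_radial = params$uptake$n_radial) {
  variant_params <- function(v) {
    switch(v,
      base = params,
      stype_half = apply_scan_factor(params, "stype_length", 0.5),
      stype_double = apply_scan_factor(params, "stype_length", 2),
      ltype_half = apply_scan_factor(params, "ltype_length", 0.5),
      ltype_double = apply_scan_factor(params, "ltype_length", 2),
      nodal_thin = {
        p <- params
        p$classes$nodal_fast$diameter <- 0.050
        p
      },
      stop("unknown variant: ", v))
  }
  run_one <- function(p) {
    sys <- grow_root_system(p, horizon = horizon, seed = seed)
    up <- system_uptake(sys, p, horizon = horizon, dt = dt,
                        n_radial = n_radial)
    build_ledger(class_geometry(sys, horizon, p),
                 hair_geometry(sys, horizon, p), up, at = horizon)
  }
  base_led <- run_one(params)
  tot <- function(led) led[led$class == "total", ]
  rows <- lapply(unique(c("base", variants)), function(v) {
    led <- if (v == "base") base_led else run_one(variant_params(v))
    t <- tot(led)
    bcr <- stats::setNames(led$benefit_cost[led$class != "total"],
                           paste0("bcr_", led$class[led$class != "total"]))
    cbind(data.frame(variant = v, P_uptake_ug = t$P_uptake_ug,
                     cost_ug = t$cost_ug,
                     d_uptake_pct = 100 * (t$P_uptake_ug /
                       tot(base_led)$P_uptake_ug - 1),
                     d_cost_pct = 100 * (t$cost_ug /
                       tot(base_led)$cost_ug - 1),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(bcr)))
  })
  do.call(rbind, rows)
}
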