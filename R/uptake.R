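# -- radial advection-diffusion-reaction phosphate uptake --------------------
#
# Each root (or hair) cohort owns a radial soil domain: a hollow cylinder
# from the structure surface r0 to an outer no-flux radius r1, holding the
# solution concentration profile C(r) of a buffered soil (buffer power b,
# effective diffusivity De).  The governing form is
#
#   b dC/dt = (1/r) d/dr ( r b De dC/dr + r v(r) C ),   v(r) = v0 r0 / r,
#
# with Michaelis-Menten influx at r0 and zero flux (or a fixed concentration,
# for verification) at r1.  Dividing by b gives a conservation law for C with
# diffusivity De; b re-enters through the boundary sink and mass accounting.
# Discretization: finite volumes on logarithmically spaced nodes (dense near
# r0), implicit Euler with Newton iteration on the nonlinear boundary flux.
# The scheme is discretely conservative: soil P lost equals the flux through
# r0 to the Newton tolerance.

#' Michaelis-Menten influx
#'
#' Influx per unit surface: `Imax * (C - Cmin) / (Km + C - Cmin)`, clamped to
#' zero at and below the uptake threshold `Cmin`.
#'
#' @param C_surface Solution concentration at the surface (umol/mL, >= 0,
#'   vectorized).
#' @param kinetics List with `Imax` (umol cm^-2 day^-1), `Km`, `Cmin`
#'   (umol/mL); `dj123_params()$soil` works directly.
#' @return Influx in umol cm^-2 day^-1.
#' @export
mm_influx <- function(C_surface, kinetics) {
  if (any(C_surface < 0)) stop("concentration must be non-negative")
  x <- pmax(C_surface - kinetics$Cmin, 0)
  kinetics$Imax * x / (kinetics$Km + x)
}

mm_influx_deriv <- function(C, kin) {
  x <- C - kin$Cmin
  ifelse(x > 0, kin$Imax * kin$Km / (kin$Km + x)^2, 0)
}

# Batch of G radial domains sharing the node count N; all state is G x N.
batch_init <- function(r0, r1, n, C0, b, De, v0 = 0) {
  G <- length(r0)
  ratio <- r1 / r0
  expo <- matrix(seq(0, 1, length.out = n), G, n, byrow = TRUE)
  r <- r0 * ratio^expo                      # log-spaced nodes
  e <- sqrt(r[, -n, drop = FALSE] * r[, -1, drop = FALSE])  # interior edges
  edges <- cbind(r0, e, r1)
  V <- pi * (edges[, -1, drop = FALSE]^2 - edges[, -(n + 1), drop = FALSE]^2)
  A <- 2 * pi * e * De /
    (r[, -1, drop = FALSE] - r[, -n, drop = FALSE])  # face conductance
  list(G = G, N = n, r = r, V = V, A = A,
       C = matrix(C0, G, n), C0 = C0, r0 = r0, r1 = r1,
       b = b, De = De, v0 = v0,
       uptake_cum = numeric(G))               # umol per cm of structure
}

# Vectorized Thomas solve of G independent tridiagonal systems.
thomas_batch <- function(lo, dg, up, rhs) {
  N <- ncol(dg)
  cp <- matrix(0, nrow(dg), N - 1)
  dp <- matrix(0, nrow(dg), N)
  cp[, 1] <- up[, 1] / dg[, 1]
  dp[, 1] <- rhs[, 1] / dg[, 1]
  for (i in 2:N) {
    m <- dg[, i] - lo[, i - 1] * cp[, i - 1]
    if (i < N) cp[, i] <- up[, i] / m
    dp[, i] <- (rhs[, i] - lo[, i - 1] * dp[, i - 1]) / m
  }
  x <- dp
  for (i in (N - 1):1) x[, i] <- dp[, i] - cp[, i] * x[, i + 1]
  x
}

# One implicit step for all domains in the batch.  `sink_on` masks domains
# whose boundary sink is active (unborn cohorts keep an undisturbed profile).
# Returns the batch and the per-cm uptake (umol of P per cm) of the step.
batch_step <- function(bat, kin, dt, tol = 1e-10, sink_on = NULL,
                       outer_bc = c("noflux", "fixed"), outer_value = NULL,
                       maxit = 40) {
  outer_bc <- match.arg(outer_bc)
  G <- bat$G; N <- bat$N
  if (is.null(sink_on)) sink_on <- rep(TRUE, G)
  V <- bat$V; A <- bat$A; C <- bat$C
  fac <- 2 * pi * bat$r0 / bat$b            # sink scale in C-units
  adv <- 2 * pi * bat$r0 * bat$v0 / bat$b   # advective delivery (upwinded)
  lo <- -A
  up <- -A
  dg <- V / dt
  dg[, 1] <- dg[, 1] + A[, 1]
  if (N > 2) dg[, 2:(N - 1)] <- dg[, 2:(N - 1)] + A[, 1:(N - 2)] +
      A[, 2:(N - 1)]
  dg[, N] <- dg[, N] + A[, N - 1]
  if (any(adv != 0)) {
    # inward flow v0 > 0 carries solute toward the root: upwind on the
    # outer cell of each face
    up <- up - adv
    dg[, -1] <- dg[, -1] + adv
  }
  rhs0 <- V / dt * C
  if (outer_bc == "fixed") {
    dg[, N] <- 1; lo[, N - 1] <- 0
    rhs0[, N] <- outer_value
  }
  Cs <- C[, 1]
  Cnew <- C
  for (it in seq_len(maxit)) {
    J <- mm_influx(pmax(Cs, 0), kin) * sink_on
    dJ <- mm_influx_deriv(pmax(Cs, 0), kin) * sink_on
    sink0 <- fac * (J - dJ * Cs)            # linearized: s = sink0 + fac*dJ*C1
    dg1 <- dg
    dg1[, 1] <- dg[, 1] + fac * dJ + adv * sink_on
    rhs <- rhs0
    rhs[, 1] <- rhs[, 1] - sink0
    Cnew <- thomas_batch(lo, dg1, up, rhs)
    delta <- max(abs(Cnew[, 1] - Cs))
    Cs <- Cnew[, 1]
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("boundary Newton iteration did not converge (residual ",
         format(delta), ")")
  J <- mm_influx(pmax(Cs, 0), kin) * sink_on
  u <- (2 * pi * bat$r0 * (J + bat$v0 * pmax(Cs, 0) * sink_on)) * dt
  bat$C <- Cnew
  bat$uptake_cum <- bat$uptake_cum + u
  list(bat = bat, uptake = u)
}

# Total P in soil per cm of structure for every domain (umol/cm).
batch_soil_P <- function(bat) bat$b * rowSums(bat$V * bat$C)

#' Create a single radial uptake domain
#'
#' @param r0 Structure (root or hair) surface radius, cm.
#' @param r1 Outer no-flux radius, cm (> r0).
#' @param n Number of radial nodes (>= 20 recommended to resolve the
#'   depletion length scale).
#' @param soil Soil list (`dj123_params()$soil`).
#' @param C0 Initial uniform solution concentration (default
#'   `soil$c_solution_init`).
#' @return An object of class `radial_domain`.
#' @export
radial_domain <- function(r0, r1 = 0.2, n = 25, soil = dj123_params()$soil,
                          C0 = soil$c_solution_init) {
  stopifnot(r0 > 0, r1 > r0, n >= 4)
  bat <- batch_init(r0, r1, n, C0, soil$buffer_power, soil$De, soil$v0)
  structure(list(bat = bat, soil = soil), class = "radial_domain")
}

#' Advance a radial domain by one time step
#'
#' @param domain A `radial_domain`.
#' @param kinetics Michaelis-Menten constants (default: the domain's soil).
#' @param dt Time step in days (<= 0.2).
#' @param outer_bc `"noflux"` (default) or `"fixed"` (Dirichlet at `r1`, used
#'   for verification against the steady cylindrical solution).
#' @param outer_value Outer concentration when `outer_bc = "fixed"`.
#' @param tol Newton tolerance on the surface concentration.
#' @return List with the updated `domain` and `uptake_per_cm` (umol of P per
#'   cm of structure taken up during the step).
#' @export
step_radial <- function(domain, kinetics = NULL, dt,
                        outer_bc = c("noflux", "fixed"), outer_value = NULL,
                        tol = 1e-10) {
  if (dt <= 0 || dt > 0.2 + 1e-12)
    stop("dt must lie in (0, 0.2] days")
  if (is.null(kinetics)) kinetics <- domain$soil
  res <- batch_step(domain$bat, kinetics, dt, tol = tol,
                    outer_bc = match.arg(outer_bc),
                    outer_value = outer_value)
  domain$bat <- res$bat
  list(domain = domain, uptake_per_cm = res$uptake)
}

#' Soil P inventory of a domain
#'
#' @param domain A `radial_domain`.
#' @return Total (buffered + solution) P in the domain, umol per cm of
#'   structure.
#' @export
domain_soil_P <- function(domain) batch_soil_P(domain$bat)[1]

# Outer radius of the depletion domain of a root segment from the local
# root-length density (half the mean inter-root spacing), floored and capped.
r1_from_density <- function(rld, floor, cap) {
  pmin(pmax(1 / sqrt(pi * pmax(rld, 1e-9)), floor), cap)
}

# Hair-domain outer radius: half the mean spacing between hairs inside the
# hair shell around the root, at the class ceiling density.
hair_r1 <- function(r0_root, hair, min_mult) {
  if (hair$max_density <= 0 || hair$length <= 0) return(NA_real_)
  shell <- (r0_root + hair$length)^2 - r0_root^2
  r1 <- sqrt(shell / (hair$max_density * hair$length))
  max(r1, min_mult * hair$diameter / 2 * 1.0001)
}

# Segment table with voxel-local density and quantized outer radius.
segment_r1 <- function(segs, params) {
  u <- params$uptake
  dt_ <- data.table::as.data.table(segs)
  dt_[, `:=`(mx = (x0 + x1) / 2, my = (y0 + y1) / 2, mz = (z0 + z1) / 2)]
  dt_[, `:=`(cx = floor(mx), cy = floor(my), cz = floor(mz))]
  data.table::setorder(dt_, tb)
  dt_[, rld := cumsum(len), by = .(cx, cy, cz)]  # cm root per cm^3 at birth
  dt_[, r1 := r1_from_density(rld, u$r1_floor, u$r1_cap)]
  bins <- c(0.2, 0.3, 0.45, 0.7, 1.0, 1.4, 2.0)
  dt_[, r1b := bins[pmax(findInterval(r1, bins), 1)]]
  dt_[]
}

#' Phosphate uptake of a root system over time
#'
#' Assigns every root segment a radial uptake domain (outer radius from the
#' local root-length density in a 1 cm^3 voxel grid, floored at
#' `uptake$r1_floor` and capped at `uptake$r1_cap`) and every hair cohort its
#' own independent hair-radius domain, then integrates the radial solver over
#' time.  Segments are pooled into cohorts of equal class, birth day and
#' outer-radius bin; all members of a cohort share one domain (the soil is
#' homogeneous, so domains differ only by geometry and age).  Plant P content
#' is the cumulative influx times the molar mass of P (30.97 ug/umol).
#'
#' @param sys A `root_system` (or a synthetic system with a segment table).
#' @param params A `rhizo_params` object; `params$soil` supplies
#'   concentration, transport and kinetic constants.
#' @param horizon Last day to integrate to (default `params$sim$report_day`).
#' @param dt Uptake time step, days (<= 0.2).
#' @param n_radial Radial nodes per domain.
#' @param include_hairs Logical; set `FALSE` for a bald-root simulation.
#' @return An object of class `rhizo_uptake`: `content_ts` (data.frame,
#'   cumulative plant P in ug per time), `class_totals` (uptake in ug per
#'   root class and structure), the cohort tables and final domain batches
#'   (for diagnostics), and the step records.
#' @export
system_uptake <- function(sys, params = dj123_params(),
                          horizon = params$sim$report_day,
                          dt = params$uptake$dt,
                          n_radial = params$uptake$n_radial,
                          include_hairs = TRUE) {
  if (dt <= 0 || dt > 0.2 + 1e-12) stop("dt must lie in (0, 0.2] days")
  u <- params$uptake
  soil <- params$soil
  segs <- system_segments(sys, at = horizon)
  if (nrow(segs) == 0) stop("system has no segments to take up P")
  sdt <- segment_r1(segs, params)

  groups <- sdt[, .(L = sum(len), bmid = sum(tb * len) / sum(len)),
                by = .(cls, bday = floor(pmax(tb - 1e-9, 0) / u$cohort_days),
                       r1b)]
  diam <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "diameter")
  groups[, r0 := diam[cls] / 2]
  rbat <- batch_init(groups$r0, groups$r1b, n_radial, soil$c_solution_init,
                     soil$buffer_power, soil$De, soil$v0)

  hgroups <- NULL; hbat <- NULL
  if (include_hairs) {
    hgroups <- sdt[, .(L = sum(len), bmid = sum(tb * len) / sum(len)),
                   by = .(cls, bday = floor(pmax(tb - 1e-9, 0) /
                                              u$cohort_days))]
    hr1 <- vapply(seq_along(RHIZO_CLASSES), function(ci)
      hair_r1(diam[ci] / 2, params$classes[[ci]]$hair, u$hair_r1_min_mult),
      0)
    hlen <- vapply(params$classes[RHIZO_CLASSES],
                   function(cp) cp$hair$length, 0)
    hgroups[, `:=`(r1 = hr1[cls], hlen = hlen[cls])]
    hgroups <- hgroups[!is.na(r1) & hlen > 0]
    if (nrow(hgroups)) {
      hd <- params$classes[[1]]$hair$diameter / 2
      hbat <- batch_init(rep(hd, nrow(hgroups)), hgroups$r1, n_radial,
                         soil$c_solution_init, soil$buffer_power, soil$De,
                         soil$v0)
    }
  }

  times <- seq(dt, horizon, by = dt)
  ncls <- length(RHIZO_CLASSES)
  rec_root <- matrix(0, length(times), ncls,
                     dimnames = list(NULL, RHIZO_CLASSES))
  rec_hair <- rec_root
  step_total <- numeric(length(times))
  for (k in seq_along(times)) {
    tk <- times[k]
    on_r <- groups$bmid <= tk - dt / 2
    res <- batch_step(rbat, soil, dt, tol = u$tol, sink_on = on_r)
    rbat <- res$bat
    ur <- res$uptake * groups$L
    if (any(on_r))
      rec_root[k, ] <- rec_root[k, ] +
        vapply(seq_len(ncls), function(ci) sum(ur[groups$cls == ci]), 0)
    if (!is.null(hbat)) {
      on_h <- hgroups$bmid <= tk - dt / 2
      resh <- batch_step(hbat, soil, dt, tol = u$tol, sink_on = on_h)
      hbat <- resh$bat
      age <- pmax(tk - hgroups$bmid, 0)
      dens <- vapply(seq_len(nrow(hgroups)), function(g)
        hair_density(params$classes[[hgroups$cls[g]]], age[g]), 0)
      hcm <- hgroups$L * dens * hgroups$hlen     # cm of hair alive now
      uh <- resh$uptake * hcm
      rec_hair[k, ] <- vapply(seq_len(ncls), function(ci)
        sum(uh[hgroups$cls == ci]), 0)
    }
    step_total[k] <- sum(rec_root[k, ]) + sum(rec_hair[k, ])
  }
  mm <- u$molar_mass_P
  content <- cumsum(step_total) * mm
  totals <- rbind(
    data.frame(class = RHIZO_CLASSES, structure = "root",
               uptake_ug = colSums(rec_root) * mm),
    data.frame(class = RHIZO_CLASSES, structure = "hair",
               uptake_ug = colSums(rec_hair) * mm))
  structure(list(
    content_ts = data.frame(time = c(0, times), P_ug = c(0, content)),
    class_totals = totals,
    rec_root = rec_root * mm, rec_hair = rec_hair * mm, times = times,
    groups = groups[], hair_groups = if (!is.null(hgroups)) hgroups[],
    root_bat = rbat, hair_bat = hbat,
    seg_table = sdt, horizon = horizon, dt = dt,
    cohort_days = u$cohort_days,
    soil = soil, molar_mass = mm), class = "rhizo_uptake")
}

#' Plant P content at a given day
#'
#' @param up A `rhizo_uptake` object.
#' @param at Day (defaults to the integration horizon).
#' @return Cumulative plant P content in ug.
#' @export
plant_P_content <- function(up, at = up$horizon) {
  ts <- up$content_ts
  if (at > max(ts$time) + 1e-9) stop("'at' exceeds the uptake horizon")
  stats::approx(ts$time, ts$P_ug, xout = at, rule = 2)$y
}

#' Uptake per unit root length
#'
#' Plant P content divided by total root length (root hairs excluded from
#' the denominator), in ug P per metre.
#'
#' @param up A `rhizo_uptake` object.
#' @param sys The root system the uptake was computed for.
#' @param at Day of evaluation.
#' @param params A `rhizo_params` object.
#' @return ug P per metre of root.
#' @export
uptake_per_length <- function(up, sys, at = up$horizon,
                              params = dj123_params()) {
  len_m <- sum(class_geometry(sys, at, params)$length_cm) / 100
  if (len_m <= 0) stop("total root length is zero; uptake per length undefined")
  plant_P_content(up, at) / len_m
}

#' Mass-balance error of the uptake solution
#'
#' For every radial domain the soil P lost (solution times buffer, integrated
#' over the annulus) must equal the cumulative flux through the structure
#' surface.  Returns the maximum relative error over all root and hair
#' domains; the implicit finite-volume scheme satisfies this to the Newton
#' tolerance.
#'
#' @param up A `rhizo_uptake` object.
#' @return Maximum relative mass-balance error (dimensionless).
#' @export
uptake_mass_balance <- function(up) {
  err <- function(bat) {
    if (is.null(bat)) return(0)
    pool0 <- bat$b * rowSums(bat$V) * bat$C0
    deficit <- pool0 - batch_soil_P(bat)
    max(abs(deficit - bat$uptake_cum) / pool0)
  }
  max(err(up$root_bat), err(up$hair_bat))
}

# Depletion radius per domain: outermost radius at which the concentration
# drawdown still exceeds 5% of the drawdown at the surface.
depletion_radii <- function(bat) {
  dep <- bat$C0 - bat$C
  thr <- 0.05 * pmax(dep[, 1], 0)
  out <- bat$r0
  has <- thr > 0
  if (any(has)) {
    idx <- apply(dep[has, , drop = FALSE] >=
                   thr[has] - .Machine$double.eps, 1,
                 function(z) max(which(z)))
    out[has] <- bat$r[cbind(which(has), idx)]
  }
  out
}

#' Fraction of root length with overlapping depletion zones
#'
#' Two segments' depletion zones overlap when the distance between them is
#' smaller than the sum of their depletion radii (the radius where the
#' concentration drawdown falls below 5% of the surface drawdown).  Segments
#' of the same axis are not compared with each other.  Computed on segment
#' midpoints with a spatial hash.
#'
#' @param sys A `root_system`.
#' @param up The `rhizo_uptake` object for the system.
#' @param at Day of evaluation.
#' @return Length-weighted fraction in `[0, 1]`.
#' @export
depletion_overlap <- function(sys, up, at = up$horizon) {
  sdt <- up$seg_table[tb <= at + 1e-9]
  rd <- depletion_radii(up$root_bat)
  g <- up$groups
  cd <- up$cohort_days
  gkey <- paste(g$cls, g$bday, g$r1b)
  sdt2 <- data.table::copy(sdt)
  sdt2[, Rd := rd[match(paste(cls, floor(pmax(tb - 1e-9, 0) / cd), r1b),
                        gkey)]]
  sdt2[is.na(Rd), Rd := 0]
  segment_overlap_fraction(sdt2[, .(axis, len, mx, my, mz, Rd)])
}

#' Overlap fraction of a segment table
#'
#' Low-level worker behind [depletion_overlap()]: takes segment midpoints
#' with per-segment depletion radii and returns the length fraction of
#' segments whose zone intersects a zone of a different axis.
#'
#' @param segs data.frame/data.table with columns `axis`, `len`, `mx`, `my`,
#'   `mz` (midpoint, cm) and `Rd` (depletion radius, cm).
#' @return Fraction in `[0, 1]`.
#' @export
segment_overlap_fraction <- function(segs) {
  s <- data.table::as.data.table(segs)
  if (nrow(s) == 0) return(0)
  h <- max(2 * max(s$Rd), 0.05)
  s[, id := .I]
  s[, `:=`(cx = floor(mx / h), cy = floor(my / h), cz = floor(mz / h))]
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  hit <- rep(FALSE, nrow(s))
  base <- s[, .(id, axis, mx, my, mz, Rd, cx, cy, cz)]
  data.table::setkey(base, cx, cy, cz)
  for (o in seq_len(nrow(offs))) {
    probe <- s[, .(id2 = id, axis2 = axis, mx2 = mx, my2 = my, mz2 = mz,
                   Rd2 = Rd,
                   cx = cx + offs[o, 1], cy = cy + offs[o, 2],
                   cz = cz + offs[o, 3])]
    cand <- base[probe, on = c("cx", "cy", "cz"), nomatch = NULL,
                 allow.cartesian = TRUE]
    cand <- cand[axis != axis2]
    if (nrow(cand) == 0) next
    d2 <- (cand$mx - cand$mx2)^2 + (cand$my - cand$my2)^2 +
      (cand$mz - cand$mz2)^2
    ov <- d2 < (cand$Rd + cand$Rd2)^2
    hit[unique(c(cand$id[ov], cand$id2[ov]))] <- TRUE
  }
  sum(s$len[hit]) / sum(s$len)
}

#' Calibrate Imax against a measured plant P content
#'
#' Adjusts the single Michaelis-Menten capacity scalar `Imax` so that the
#' simulated plant P content at `at` days matches `target` (default: the
#' measured 774.3 ug at 28 DAE, i.e. simulation day 31).  Uptake is monotone
#' in `Imax`, so a log-space secant iteration with bisection safeguards
#' converges in a handful of solver runs.
#'
#' @param sys A grown `root_system`.
#' @param params A `rhizo_params` object (its `soil$Imax` is the starting
#'   point).
#' @param target Target plant P content, ug.
#' @param at Day of comparison.
#' @param dt,n_radial Solver resolution passed to [system_uptake()].
#' @param rel_tol Relative tolerance on the match (default 0.5%).
#' @param max_iter Maximum number of solver runs.
#' @return The calibrated `rhizo_params` object, with attributes
#'   `achieved_P_ug` and `iterations` on its `soil$Imax`.
#' @export
calibrate_imax <- function(sys, params = dj123_params(),
                           target = calibration_targets()$measured_P_28DAE,
                           at = params$sim$report_day,
                           dt = params$uptake$dt,
                           n_radial = params$uptake$n_radial,
                           rel_tol = 0.005, max_iter = 12) {
  eval_P <- function(imax) {
    p2 <- params
    p2$soil$Imax <- imax
    plant_P_content(system_uptake(sys, p2, horizon = at, dt = dt,
                                  n_radial = n_radial), at)
  }
  x1 <- log(params$soil$Imax)
  y1 <- log(eval_P(exp(x1)) / target)
  best_x <- x1; best_y <- y1; it <- 1
  x2 <- x1 - y1                  # unit-slope guess in log-log space
  while (it < max_iter && abs(best_y) >= log(1 + rel_tol)) {
    y2 <- log(eval_P(exp(x2)) / target)
    it <- it + 1
    if (abs(y2) < abs(best_y)) {
      best_x <- x2; best_y <- y2
    }
    slope <- (y2 - y1) / (x2 - x1)
    if (!is.finite(slope) || abs(slope) < 0.05) slope <- 1
    xn <- x2 - y2 / slope
    x1 <- x2; y1 <- y2; x2 <- xn
  }
  if (abs(best_y) > log(1 + 5 * rel_tol))
    warning("Imax calibration stopped before reaching tolerance")
  out <- params
  out$soil$Imax <- exp(best_x)
  attr(out$soil$Imax, "achieved_P_ug") <- target * exp(best_y)
  attr(out$soil$Imax, "iterations") <- it
  out
}
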