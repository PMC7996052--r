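# -- stochastic 3D root-system growth engine ---------------------------------
#
# The root system is a growing set of axes; each axis keeps its tip position
# and heading, and leaves fixed segments behind as it elongates.  All state
# lives in an environment of parallel vectors so that per-step updates are
# vectorized over axes.

class_code <- function(x) match(x, RHIZO_CLASSES)

# Integral of the emergence ramp (a/rd)^e from 0 to age, with an optional
# exponential decline phase of time constant tau after the ramp (vectorized).
ramp_integral <- function(age, rd, e, tau = Inf) {
  post <- ifelse(is.finite(tau),
                 tau * (1 - exp(-pmax(age - rd, 0) / tau)),
                 pmax(age - rd, 0))
  ifelse(age <= rd,
         rd * pmax(age / rd, 0)^(e + 1) / (e + 1),
         rd / (e + 1) + post)
}

# Deterministic cumulative length of an axis at a given age, capped at the
# per-axis maximum length.
cum_length <- function(age, peak, mult, maxlen, rd, e, tau = Inf) {
  pmin(peak * mult * ramp_integral(pmax(age, 0), rd, e, tau), maxlen)
}

# Decline time constant of a class growth curve.  Lateral classes decline
# exponentially after the emergence ramp, with tau solved so that the
# lifetime growth integral equals the class maximum length (so a length
# factor stretches the decline phase while the peak rate is unchanged);
# main-axis classes hold the peak until the maximum-length cutoff.
class_tau <- function(cp) {
  gc <- cp$growth_curve
  if (!isTRUE(gc$decline)) return(Inf)
  max(cp$max_length / cp$peak_growth_rate - gc$ramp_days / (gc$ramp_exp + 1),
      0.25)
}

# Fraction of the maximum length at which an axis stops being advanced;
# asymptotically declining classes are retired at 95% to bound step counts.
class_stop_frac <- function(cp) if (isTRUE(cp$growth_curve$decline)) 0.95 else 1

#' Class-specific elongation rate
#'
#' Elongation is slow during emergence, rises to the class peak rate within
#' the first days of axis age (power-law ramp over `growth_curve$ramp_days`),
#' then stays at the peak until the axis saturates at its maximum length,
#' where the rate drops to zero.  The lifetime integral therefore never
#' exceeds `max_length * multiplier`.
#'
#' @param class_params One element of `dj123_params()$classes`.
#' @param axis_age Axis age in days (vectorized, must be >= 0).
#' @param multiplier Per-axis growth-rate multiplier (default 1).
#' @return Elongation rate in cm/day.
#' @examples
#' cp <- dj123_params()$classes$nodal_fast
#' elongation_rate(cp, axis_age = 5)  # 2.14 cm/day at the plateau
#' @export
elongation_rate <- function(class_params, axis_age, multiplier = 1) {
  if (any(axis_age < 0)) stop("axis_age must be non-negative")
  gc <- class_params$growth_curve
  peak <- class_params$peak_growth_rate
  tau <- class_tau(class_params)
  maxlen <- class_params$max_length * multiplier
  decay <- exp(-pmax(axis_age - gc$ramp_days, 0) / tau)
  rate <- peak * multiplier * pmin(axis_age / gc$ramp_days, 1)^gc$ramp_exp *
    decay
  len <- cum_length(axis_age, peak, multiplier, maxlen, gc$ramp_days,
                    gc$ramp_exp, tau)
  ifelse(len >= class_stop_frac(class_params) * maxlen - 1e-12, 0, rate)
}

#' Nodal root emergence schedule
#'
#' Nodal (crown) roots emerge from the hypocotyl at a rapid rate during early
#' development and at a reduced rate thereafter, which makes the cumulative
#' count concave in time.  Events before `fast_onset` are all of the branched
#' class; afterwards the fast class appears with a share that grows with
#' time.  Tiller nodes each contribute their own slower emission stream from
#' the time the tiller appears.
#'
#' @param horizon Simulation horizon in days (> 0).
#' @param params A `rhizo_params` object.
#' @return A data.frame with columns `time` (day) and `class`, sorted by time.
#'   Class assignment of post-onset events is random, so call under a set
#'   seed for reproducibility.
#' @export
nodal_emergence_times <- function(horizon, params = dj123_params()) {
  stopifnot(horizon > 0)
  e <- params$emergence
  rapid_n <- max(0, (min(horizon, e$rapid_until) - e$start)) * e$rapid_rate
  slow_n <- max(0, horizon - e$rapid_until) * e$slow_rate
  n <- floor(rapid_n + slow_n)
  times <- numeric(0)
  if (n >= 1) {
    k <- seq_len(n)
    times <- ifelse(k <= rapid_n, e$start + k / e$rapid_rate,
                    e$rapid_until + (k - rapid_n) / e$slow_rate)
  }
  cls <- rep("nodal_branched", length(times))
  late <- which(times > e$fast_onset)
  if (length(late)) {
    share <- pmin(e$fast_share_max,
                  e$fast_share_slope * (times[late] - e$fast_onset))
    cls[late] <- ifelse(runif(length(late)) < share, "nodal_fast",
                        "nodal_branched")
  }
  for (tau in e$tiller_times) {
    if (tau >= horizon) next
    m <- floor((horizon - tau) * e$tiller_rate)
    if (m >= 1) {
      times <- c(times, tau + seq_len(m) / e$tiller_rate)
      cls <- c(cls, rep("nodal_tiller", m))
    }
  }
  ord <- order(times)
  data.frame(time = times[ord], class = cls[ord], stringsAsFactors = FALSE)
}

#' Sample an inter-branching distance
#'
#' IBDs are drawn from parent/child-specific truncated normal distributions
#' (inverse-CDF sampling, exact).  Fast nodal roots carry a branching
#' schedule: the sampled IBD is doubled while the system is younger than two
#' weeks, and afterwards grows with distance from the root base (lateral
#' densities are higher in the basal half).  Truncation applies to the base
#' draw, before the schedule multiplier.
#'
#' @param parent_class,child_class Class ids; the pair must be permitted.
#' @param position_on_parent Attachment position along the parent (cm).
#' @param clock Current simulation time (day).
#' @param params A `rhizo_params` object.
#' @param n Number of draws.
#' @return IBD draw(s) in cm.
#' @export
sample_ibd <- function(parent_class, child_class, position_on_parent = 0,
                       clock = 0, params = dj123_params(), n = 1) {
  if (!child_class %in% RHIZO_CHILDREN[[parent_class]])
    stop("class ", parent_class, " cannot bear child class ", child_class)
  d <- params$classes[[parent_class]]$ibd_by_child[[child_class]]
  x <- rtruncnorm(n, d$mean, d$sd, d$min, d$max)
  sched <- params$classes[[parent_class]]$ibd_schedule
  if (!is.null(sched)) {
    f <- if (clock < sched$early_until) sched$early_factor
         else 1 + sched$basal_gradient * position_on_parent
    x <- x * f
  }
  x
}

# Exact truncated-normal sampling by inverse CDF; degenerate sd returns the
# (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd < 1e-12) return(rep(min(max(mean, lo), hi), n))
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

rtrunclnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

#' Initial heading of a new main axis
#'
#' The primary root starts straight down.  Nodal roots start at a root growth
#' angle (RGA, measured from the horizontal soil surface) drawn from a scaled
#' beta distribution supported on 8-90 degrees with mode near 25-30 degrees
#' and about 62% of draws at or below 45 degrees, at a uniformly random
#' azimuth.
#'
#' @param class_id `"primary"` or one of the nodal classes.
#' @param params A `rhizo_params` object.
#' @return Unit heading vector `c(x, y, depth)` (depth positive downward).
#' @export
initial_angle <- function(class_id, params = dj123_params()) {
  if (class_id == "primary") return(c(0, 0, 1))
  if (!class_id %in% c("nodal_branched", "nodal_fast", "nodal_tiller"))
    stop("initial_angle applies to primary and nodal classes only")
  ab <- params$tropism$rga_beta
  rg <- params$tropism$rga_range
  theta <- (rg[1] + diff(rg) * stats::rbeta(1, ab[1], ab[2])) * pi / 180
  phi <- runif(1, 0, 2 * pi)
  c(cos(theta) * cos(phi), cos(theta) * sin(phi), sin(theta))
}

#' Update a heading by the tropism vector
#'
#' Combines class-specific gravitropism (deflection toward the vertical per
#' cm grown; the printed rates are negative numbers whose magnitude pulls the
#' heading downward), a bounded random impedance perturbation, and the
#' `cannotgrowup` correction that flattens upward-growing lateral (L/S-type)
#' headings to horizontal.
#'
#' @param heading Unit heading vector (x, y, depth+down).
#' @param class_params One element of `dj123_params()$classes`.
#' @param dist Distance grown over the update (cm); scales both components.
#' @param impedance Heading noise standard deviation per sqrt(cm) (default
#'   from `dj123_params()$tropism$impedance` when `NULL`).
#' @param params A `rhizo_params` object (for the default impedance).
#' @return New unit heading.
#' @export
tropism_update <- function(heading, class_params, dist = 0.2,
                           impedance = NULL, params = dj123_params()) {
  nrm <- sqrt(sum(heading^2))
  if (nrm < 1e-12) stop("heading must have non-zero norm")
  heading <- heading / nrm
  if (is.null(impedance)) impedance <- params$tropism$impedance
  h <- heading
  h[3] <- h[3] + abs(class_params$gravitropism) * dist
  if (impedance > 0 && dist > 0)
    h <- h + rnorm(3, 0, impedance * sqrt(dist))
  h <- h / sqrt(sum(h^2))
  if (class_params$class_id %in% c("ltype", "stype") && h[3] < 0) {
    h[3] <- 0
    n2 <- sqrt(sum(h^2))
    if (n2 < 1e-9) {
      phi <- runif(1, 0, 2 * pi)
      h <- c(cos(phi), sin(phi), 0)
    } else h <- h / n2
  }
  h
}

# -- system construction ------------------------------------------------------

#' Create an empty root system
#'
#' Initializes the system at simulation day 0 with the primary root attached
#' to the seed (a point at `sim$seed_depth` cm below the surface) and the
#' nodal emergence event queue precomputed to `sim$horizon`.  Call under a
#' set seed, or use [grow_root_system()].
#'
#' @param params A `rhizo_params` object.
#' @return An environment of class `root_system`.
#' @export
new_root_system <- function(params = dj123_params()) {
  sys <- new.env(parent = emptyenv())
  sys$clock <- 0
  sys$tiller_count <- 0L
  sys$n <- 0L
  cap <- 256L
  sys$cls <- integer(cap); sys$parent <- integer(cap)
  sys$ppos <- numeric(cap); sys$birth <- numeric(cap)
  sys$mult <- numeric(cap); sys$len <- numeric(cap)
  sys$maxlen <- numeric(cap); sys$peak <- numeric(cap)
  sys$rd <- numeric(cap); sys$re <- numeric(cap)
  sys$tau <- numeric(cap); sys$stopf <- numeric(cap)
  sys$grav <- numeric(cap)
  sys$tip <- matrix(0, cap, 3); sys$head <- matrix(0, cap, 3)
  sys$nb_l <- rep(NA_real_, cap); sys$nb_s <- rep(NA_real_, cap)
  sys$active <- logical(cap)
  sys$nseg <- 0L
  sys$segs <- matrix(0, 4096L, 10L,
                     dimnames = list(NULL, c("axis", "cls", "tb", "x0", "y0",
                                             "z0", "x1", "y1", "z1", "len")))
  sys$events <- nodal_emergence_times(params$sim$horizon, params)
  sys$eptr <- 1L
  class(sys) <- "root_system"
  seedpos <- c(0, 0, params$sim$seed_depth)
  add_axes(sys, "primary", parent = 0L, ppos = 0, birth = 0,
           pos = matrix(seedpos, 1), head = matrix(c(0, 0, 1), 1), params)
  sys
}

grow_arrays <- function(sys, need) {
  cap <- length(sys$cls)
  if (sys$n + need <= cap) return(invisible())
  ncap <- max(cap * 2L, sys$n + need)
  for (f in c("cls", "parent")) {
    v <- sys[[f]]; length(v) <- ncap; sys[[f]] <- v
  }
  for (f in c("ppos", "birth", "mult", "len", "maxlen", "peak", "rd", "re",
              "tau", "stopf", "grav", "nb_l", "nb_s")) {
    v <- sys[[f]]; length(v) <- ncap; sys[[f]] <- v
  }
  sys$tip <- rbind(sys$tip, matrix(0, ncap - cap, 3))
  sys$head <- rbind(sys$head, matrix(0, ncap - cap, 3))
  v <- sys$active; length(v) <- ncap; v[is.na(v)] <- FALSE; sys$active <- v
}

# Append axes (vectorized over rows of pos/head).  Draws the growth-rate
# multiplier and initial branch counters for each new axis.
add_axes <- function(sys, class_id, parent, ppos, birth, pos, head, params,
                     clock = 0) {
  k <- nrow(pos)
  if (length(class_id) == 1) class_id <- rep(class_id, k)
  grow_arrays(sys, k)
  idx <- sys$n + seq_len(k)
  sys$n <- sys$n + k
  for (j in seq_len(k)) {
    cid <- class_id[j]
    cp <- params$classes[[cid]]
    i <- idx[j]
    rm_ <- cp$rate_multiplier
    m <- rtrunclnorm(1, rm_$meanlog, rm_$sdlog, rm_$min, rm_$max)
    sys$cls[i] <- class_code(cid)
    sys$parent[i] <- parent[min(j, length(parent))]
    sys$ppos[i] <- ppos[min(j, length(ppos))]
    sys$birth[i] <- birth[min(j, length(birth))]
    sys$mult[i] <- m
    sys$len[i] <- 0
    sys$maxlen[i] <- cp$max_length * m
    sys$peak[i] <- cp$peak_growth_rate
    sys$rd[i] <- cp$growth_curve$ramp_days
    sys$re[i] <- cp$growth_curve$ramp_exp
    sys$tau[i] <- class_tau(cp)
    sys$stopf[i] <- class_stop_frac(cp)
    sys$grav[i] <- cp$gravitropism
    sys$tip[i, ] <- pos[j, ]
    sys$head[i, ] <- head[j, ]
    sys$active[i] <- TRUE
    sys$nb_l[i] <- if ("ltype" %in% RHIZO_CHILDREN[[cid]])
      sample_ibd(cid, "ltype", 0, clock, params) else NA_real_
    sys$nb_s[i] <- if ("stype" %in% RHIZO_CHILDREN[[cid]])
      sample_ibd(cid, "stype", 0, clock, params) else NA_real_
  }
  idx
}

append_segments <- function(sys, rows) {
  k <- nrow(rows)
  if (k == 0) return(invisible())
  cap <- nrow(sys$segs)
  if (sys$nseg + k > cap) {
    ncap <- max(cap * 2L, sys$nseg + k)
    segs <- matrix(0, ncap, 10L, dimnames = dimnames(sys$segs))
    segs[seq_len(sys$nseg), ] <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
    sys$segs <- segs
  }
  sys$segs[sys$nseg + seq_len(k), ] <- rows
  sys$nseg <- sys$nseg + k
}

# Unit row-normalization of a 3-column matrix.
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n < 1e-12] <- 1
  m / n
}

#' Advance the root system by one time step
#'
#' Each active tip extends by the closed-form increment of its growth curve
#' along its heading, the heading being updated by gravitropism, random
#' impedance and the `cannotgrowup` rule; fixed segments are laid behind the
#' tip.  When a tip's cumulative extension crosses a pending inter-branching
#' distance, a child axis is created perpendicular to the parent at a
#' uniformly random radial angle (within-step crossing positions resolved by
#' linear interpolation) and a fresh IBD is drawn.  Nodal emergence events
#' falling inside the step create new main axes at the seed.
#'
#' @param sys A `root_system`.
#' @param dt Time step in days; `0 <= dt <= params$sim$max_step`.
#' @param params A `rhizo_params` object.
#' @return The updated system (modified in place and returned).
#' @export
advance <- function(sys, dt, params) {
  if (dt < 0) stop("dt must be non-negative")
  if (dt > params$sim$max_step + 1e-12)
    stop("dt exceeds the maximum time step (", params$sim$max_step, " day)")
  if (dt == 0) return(invisible(sys))
  t0 <- sys$clock; t1 <- t0 + dt

  # tillering
  sys$tiller_count <- sum(params$emergence$tiller_times <= t1)

  # nodal emergence events inside (t0, t1]
  ev <- sys$events
  while (sys$eptr <= nrow(ev) && ev$time[sys$eptr] <= t1 + 1e-12) {
    e <- ev[sys$eptr, ]
    h <- initial_angle(e$class, params)
    add_axes(sys, e$class, parent = 0L, ppos = 0, birth = e$time,
             pos = matrix(c(0, 0, params$sim$seed_depth), 1),
             head = matrix(h, 1), params, clock = e$time)
    sys$eptr <- sys$eptr + 1L
  }

  n <- sys$n
  idx <- which(sys$active[seq_len(n)])
  if (length(idx)) {
    age0 <- t0 - sys$birth[idx]
    age1 <- t1 - sys$birth[idx]
    ext <- cum_length(age1, sys$peak[idx], sys$mult[idx], sys$maxlen[idx],
                      sys$rd[idx], sys$re[idx], sys$tau[idx]) -
           cum_length(age0, sys$peak[idx], sys$mult[idx], sys$maxlen[idx],
                      sys$rd[idx], sys$re[idx], sys$tau[idx])
    ext[ext < 0] <- 0
    done <- sys$len[idx] + ext >=
      sys$stopf[idx] * sys$maxlen[idx] - 1e-10 & age1 > sys$rd[idx]
    grow <- ext > 1e-12
    gi <- idx[grow]; gext <- ext[grow]
    if (length(gi)) {
      # tropism: gravitropic pull + impedance noise, per cm grown
      h <- sys$head[gi, , drop = FALSE]
      h[, 3] <- h[, 3] + abs(sys$grav[gi]) * gext
      imp <- params$tropism$impedance
      if (imp > 0)
        h <- h + matrix(rnorm(3 * length(gi), 0, imp), ncol = 3) *
          sqrt(gext)
      h <- normalize_rows(h)
      lat <- sys$cls[gi] >= class_code("ltype")
      up <- lat & h[, 3] < 0
      if (any(up)) {
        h[up, 3] <- 0
        h[up, ] <- normalize_rows(h[up, , drop = FALSE])
      }
      # no axis grows above the soil surface
      surf <- sys$tip[gi, 3] <= 1e-9 & h[, 3] < 0
      if (any(surf)) {
        h[surf, 3] <- 0
        h[surf, ] <- normalize_rows(h[surf, , drop = FALSE])
      }
      old <- sys$tip[gi, , drop = FALSE]
      new <- old + h * gext
      below <- new[, 3] < 0
      if (any(below)) new[below, 3] <- 0
      sys$head[gi, ] <- h
      sys$tip[gi, ] <- new
      append_segments(sys, cbind(gi, sys$cls[gi], t1, old, new, gext))

      # branching: IBD counters cross within the step
      spawn_children(sys, gi, gext, old, new, t1, params)
      sys$len[gi] <- sys$len[gi] + gext
    }
    sys$active[idx[done]] <- FALSE
  }
  sys$clock <- t1
  invisible(sys)
}

# Decrement branch counters of the extended axes and create child axes at the
# crossing points (perpendicular emission, uniform radial angle).
spawn_children <- function(sys, gi, gext, old, new, t1, params) {
  for (childfield in c("nb_l", "nb_s")) {
    child <- if (childfield == "nb_l") "ltype" else "stype"
    nb <- sys[[childfield]][gi]
    hit <- which(!is.na(nb) & nb <= gext)
    if (length(hit) == 0) {
      sys[[childfield]][gi] <- nb - gext
      next
    }
    specs_pos <- list(); specs_head <- list()
    specs_parent <- integer(0); specs_ppos <- numeric(0)
    specs_birth <- numeric(0)
    for (j in hit) {
      i <- gi[j]
      pclass <- RHIZO_CLASSES[sys$cls[i]]
      dist <- nb[j]
      dirstep <- (new[j, ] - old[j, ]) / gext[j]
      while (dist <= gext[j]) {
        at <- old[j, ] + dirstep * dist
        ch <- perp_heading(dirstep, child)
        specs_pos[[length(specs_pos) + 1]] <- at
        specs_head[[length(specs_head) + 1]] <- ch
        specs_parent <- c(specs_parent, i)
        specs_ppos <- c(specs_ppos, sys$len[i] + dist)
        specs_birth <- c(specs_birth, t1)
        dist <- dist + sample_ibd(pclass, child, sys$len[i] + dist, t1,
                                  params)
      }
      nb[j] <- dist - gext[j]
    }
    nb[-hit] <- nb[-hit] - gext[-hit]
    sys[[childfield]][gi] <- nb
    if (length(specs_parent))
      add_axes(sys, child, specs_parent, specs_ppos, specs_birth,
               do.call(rbind, specs_pos), do.call(rbind, specs_head),
               params, clock = t1)
  }
}

# A unit vector perpendicular to `dir` at a uniformly random radial angle;
# lateral classes are corrected to horizontal if pointing upward.
perp_heading <- function(dir, child_class) {
  a <- if (abs(dir[3]) > 0.99) c(1, 0, 0) else c(0, 0, 1)
  u <- c(dir[2] * a[3] - dir[3] * a[2],
         dir[3] * a[1] - dir[1] * a[3],
         dir[1] * a[2] - dir[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2],
         dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  psi <- runif(1, 0, 2 * pi)
  h <- cos(psi) * u + sin(psi) * v
  if (h[3] < 0) {
    h[3] <- 0
    n2 <- sqrt(sum(h^2))
    if (n2 < 1e-9) {
      phi <- runif(1, 0, 2 * pi)
      h <- c(cos(phi), sin(phi), 0)
    } else h <- h / n2
  }
  h
}

#' Grow a complete root system
#'
#' Runs [advance()] from day 0 to `horizon` at fixed step `dt` under a single
#' seed; identical seed and parameters give bit-identical systems.
#'
#' @param params A `rhizo_params` object.
#' @param horizon Final simulation day (default `params$sim$horizon`).
#' @param dt Time step (default `params$sim$max_step`).
#' @param seed Integer seed.
#' @return A `root_system` environment.
#' @examples
#' \donttest{
#' sys <- grow_root_system(dj123_params(), horizon = 10, seed = 1)
#' class_geometry(sys, at = 10)
#' }
#' @export
grow_root_system <- function(params = dj123_params(),
                             horizon = params$sim$horizon,
                             dt = params$sim$max_step, seed = 1) {
  set.seed(seed)
  sys <- new_root_system(params)
  nstep <- ceiling(horizon / dt - 1e-9)
  for (k in seq_len(nstep))
    advance(sys, min(dt, horizon - sys$clock), params)
  sys
}

#' Segments of a root system
#'
#' @param sys A `root_system`.
#' @param at Optional day; only segments laid at or before `at` are returned.
#' @return A data.frame with axis id, class, birth time `tb`, start/end
#'   coordinates (cm; depth positive downward) and segment length (cm).
#' @export
system_segments <- function(sys, at = NULL) {
  s <- as.data.frame(sys$segs[seq_len(sys$nseg), , drop = FALSE])
  s$class <- RHIZO_CLASSES[s$cls]
  if (!is.null(at)) s <- s[s$tb <= at + 1e-9, ]
  s
}

#' Per-class geometry ledger
#'
#' Aggregates segment length per class and derives surface (lateral cylinder
#' area, no caps), volume and weight from the class diameter and tissue
#' density.
#'
#' @param sys A `root_system`.
#' @param at Day at which to evaluate (<= current clock).
#' @param params A `rhizo_params` object.
#' @return A data.frame with one row per root class: `length_cm`,
#'   `surface_cm2`, `volume_cm3`, `weight_g`.
#' @export
class_geometry <- function(sys, at = sys$clock, params = dj123_params()) {
  if (at > sys$clock + 1e-9) stop("'at' exceeds the system clock")
  len <- numeric(length(RHIZO_CLASSES))
  if (sys$nseg > 0) {
    s <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
    keep <- s[, "tb"] <= at + 1e-9
    if (any(keep)) {
      agg <- tapply(s[keep, "len"], s[keep, "cls"], sum)
      len[as.integer(names(agg))] <- agg
    }
  }
  d <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "diameter")
  rho <- vapply(params$classes[RHIZO_CLASSES], `[[`, 0, "tissue_density")
  data.frame(class = RHIZO_CLASSES,
             length_cm = len,
             surface_cm2 = pi * d * len,
             volume_cm3 = pi * (d / 2)^2 * len,
             weight_g = pi * (d / 2)^2 * len * rho,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of root length above a depth
#'
#' @param sys A `root_system`.
#' @param depth Depth in cm below the soil surface.
#' @param at Day at which to evaluate.
#' @return Length-weighted fraction of the root system at or above `depth`
#'   (segment midpoint criterion).
#' @export
depth_fraction <- function(sys, depth = 25, at = sys$clock) {
  s <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
  s <- s[s[, "tb"] <= at + 1e-9, , drop = FALSE]
  if (nrow(s) == 0) return(NA_real_)
  zmid <- (s[, "z0"] + s[, "z1"]) / 2
  sum(s[zmid <= depth, "len"]) / sum(s[, "len"])
}

#' Axis counts per class
#'
#' @param sys A `root_system`.
#' @param at Optional day; counts axes born at or before `at`.
#' @return Named integer vector over the six root classes.
#' @export
axis_counts <- function(sys, at = NULL) {
  i <- seq_len(sys$n)
  if (!is.null(at)) i <- i[sys$birth[i] <= at + 1e-9]
  out <- table(factor(RHIZO_CLASSES[sys$cls[i]], levels = RHIZO_CLASSES))
  stats::setNames(as.integer(out), names(out))
}

#' @export
print.root_system <- function(x, ...) {
  cat("<root_system> day", format(x$clock, digits = 4), "-", x$n, "axes,",
      x$nseg, "segments\n")
  cnt <- axis_counts(x)
  cat("  axes:", paste(names(cnt), cnt, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  total length: %.1f cm, tillers: %d\n",
              sum(x$len[seq_len(x$n)]), x$tiller_count))
  invisible(x)
}
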