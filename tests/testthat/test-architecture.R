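test_that("elongation rises to the class peak and integrates to max length", {
  p <- dj123_params()
  cp <- p$classes$nodal_fast
  expect_equal(elongation_rate(cp, 5), 2.14)          # at the plateau
  expect_equal(elongation_rate(cp, 5, multiplier = 0), 0)
  expect_error(elongation_rate(cp, -1), "non-negative")
  # emergence is slower than the peak and monotone over the ramp
  r <- elongation_rate(cp, c(0.1, 0.5, 1, 2))
  expect_true(all(diff(r) >= 0) && r[1] < 2.14)
  # a fast nodal axis unconstrained for 21 days accumulates ~45 cm
  len21 <- integrate(function(a) elongation_rate(cp, a), 0, 21,
                     subdivisions = 500L)$value
  expect_lt(abs(len21 - 45) / 45, 0.02)
  # lateral curves decline after the ramp and never exceed max length
  for (cl in c("ltype", "stype")) {
    cpl <- p$classes[[cl]]
    mid <- cpl$growth_curve$ramp_days + 1
    expect_lt(elongation_rate(cpl, mid * 4), elongation_rate(cpl, mid))
    for (m in c(0.5, 1, 2)) {
      life <- integrate(function(a) elongation_rate(cpl, a, m), 0, 400,
                        subdivisions = 1000L)$value
      expect_lte(life, cpl$max_length * m * (1 + 1e-6))
    }
  }
})

test_that("nodal emergence is rapid then slow, branched first, fast later", {
  p <- dj123_params()
  set.seed(1)
  ev5 <- nodal_emergence_times(5, p)
  expect_gt(nrow(ev5), 0)
  expect_true(all(ev5$class == "nodal_branched"))
  expect_lte(nrow(nodal_emergence_times(0.1, p)), 1)
  ev <- nodal_emergence_times(35, p)
  n_at <- function(t) sum(ev$time <= t)
  # cumulative count is concave across the slowdown
  expect_lte((n_at(20) - n_at(15)) - (n_at(15) - n_at(10)), 0)
  fast <- ev$time[ev$class == "nodal_fast"]
  expect_gt(length(fast), 0)
  expect_true(all(fast > p$emergence$fast_onset))
  # the fast share increases as the system matures
  late <- ev[ev$time > 10, ]
  half <- median(late$time)
  expect_gte(mean(late$class[late$time > half] == "nodal_fast"),
             mean(late$class[late$time <= half] == "nodal_fast"))
  tiller <- ev$time[ev$class == "nodal_tiller"]
  expect_true(all(tiller > min(p$emergence$tiller_times)))
})

test_that("IBD draws respect truncation, schedule and published moments", {
  p <- dj123_params()
  d <- p$classes$ltype$ibd_by_child$stype
  set.seed(7)
  x <- sample_ibd("ltype", "stype", 0, 0, p, n = 1e4)
  expect_true(all(x >= d$min & x <= d$max))
  # Monte-Carlo mean against the truncated-normal mean from numerical
  # integration (independent oracle)
  z <- integrate(function(v) v * dnorm(v, d$mean, d$sd), d$min, d$max)$value /
    diff(pnorm(c(d$min, d$max), d$mean, d$sd))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - z), 3 * se)
  # degenerate sd returns the mean exactly; fast-nodal doubles it early
  p0 <- p
  p0$classes$nodal_fast$ibd_by_child$stype <-
    list(mean = 0.5, sd = 1e-14, min = 0.5, max = 0.5)
  early <- sample_ibd("nodal_fast", "stype", 0, clock = 5, p0)
  late <- sample_ibd("nodal_fast", "stype", 0, clock = 20, p0)
  expect_equal(early, 1.0)
  expect_equal(late, 0.5)
  # basal gradient: sparser branching away from the base after week two
  far <- sample_ibd("nodal_fast", "stype", 30, clock = 20, p0)
  expect_gt(far, late)
  expect_error(sample_ibd("stype", "ltype", 0, 0, p), "cannot bear")
})

test_that("initial angles reproduce the measured RGA distribution", {
  p <- dj123_params()
  expect_equal(initial_angle("primary", p), c(0, 0, 1))
  set.seed(3)
  h <- t(replicate(1e4, initial_angle("nodal_branched", p)))
  expect_equal(unname(rowSums(h^2)[1:5]), rep(1, 5), tolerance = 1e-9)
  rga <- asin(pmin(h[, 3], 1)) * 180 / pi
  expect_true(all(rga >= 8 - 1e-6 & rga <= 90 + 1e-6))
  frac45 <- mean(rga <= 45)
  expect_gte(frac45, 0.57)
  expect_lte(frac45, 0.67)
  expect_error(initial_angle("stype", p), "nodal")
})

test_that("tropism keeps unit headings, pulls main axes down, laterals flat", {
  p <- dj123_params()
  # no forces: heading unchanged
  h0 <- c(1, 0, 0)
  expect_equal(tropism_update(h0, p$classes$ltype, dist = 1, impedance = 0,
                              params = p), h0)
  # upward-heading S-type is corrected to horizontal
  hup <- tropism_update(c(0.6, 0, -0.8), p$classes$stype, dist = 0.1,
                        impedance = 0, params = p)
  expect_equal(hup[3], 0)
  expect_equal(sum(hup^2), 1)
  expect_error(tropism_update(c(0, 0, 0), p$classes$stype), "non-zero")
  # a horizontally started primary root turns downward monotonically
  h <- c(1, 0, 0)
  z <- numeric(25)
  for (k in 1:25) {
    h <- tropism_update(h, p$classes$primary, dist = 0.4, impedance = 0,
                        params = p)
    z[k] <- h[3]
  }
  expect_true(all(diff(z) > 0))
  expect_gt(z[25], 0.5)
  # impedance perturbs but preserves the norm
  set.seed(9)
  hn <- tropism_update(c(0, 1, 0), p$classes$nodal_branched, dist = 0.3,
                       impedance = 0.1, params = p)
  expect_equal(sum(hn^2), 1)
})

test_that("advance respects the step contract and the crossing rule", {
  p <- dj123_params()
  set.seed(2)
  sys <- new_root_system(p)
  advance(sys, 0.2, p)
  expect_error(advance(sys, 0.5, p), "maximum time step")
  clock0 <- sys$clock
  n0 <- sys$n
  advance(sys, 0, p)
  expect_equal(sys$clock, clock0)
  expect_equal(sys$n, n0)
  # forced crossing: primary with a degenerate 0.4 cm S-type IBD places the
  # first child exactly 0.4 cm from the base
  pdet <- p
  pdet$tropism$impedance <- 0
  pdet$classes$primary$ibd_by_child$stype <-
    list(mean = 0.4, sd = 1e-14, min = 0.4, max = 0.4)
  pdet$classes$primary$ibd_by_child$ltype <-
    list(mean = 50, sd = 1e-14, min = 50, max = 50)
  set.seed(4)
  sys2 <- new_root_system(pdet)
  for (k in 1:10) advance(sys2, 0.2, pdet)
  kids <- which(sys2$parent[seq_len(sys2$n)] == 1)
  expect_gt(length(kids), 0)
  expect_equal(sys2$ppos[kids[1]], 0.4, tolerance = 1e-9)
  # the child emerges on the parent's vertical path, 0.4 cm below the seed
  segs <- system_segments(sys2)
  first <- segs[segs$axis == kids[1], ][1, ]
  expect_equal(unname(unlist(first[c("x0", "y0", "z0")])),
               c(0, 0, dj123_params()$sim$seed_depth + 0.4),
               tolerance = 1e-9)
  expect_equal(sys2$ppos[kids[2]], 0.8, tolerance = 1e-9)
})

test_that("grown systems are topologically sound and conserve length", {
  sys <- small_sys()
  n <- sys$n
  parents <- sys$parent[seq_len(n)]
  expect_true(all(parents < seq_len(n)))           # acyclic, parents first
  expect_equal(sum(RHIZO_CLASSES[sys$cls[seq_len(n)]] == "primary"), 1)
  nonroot <- which(parents > 0)
  expect_true(all(sys$ppos[nonroot] <= sys$len[parents[nonroot]] + 1e-6))
  # attachment positions are non-decreasing along each parent's emission
  # history (per child class; classes are emitted in independent streams)
  for (pa in unique(parents[nonroot])) {
    for (cc in unique(sys$cls[nonroot])) {
      kids <- nonroot[parents[nonroot] == pa & sys$cls[nonroot] == cc]
      if (length(kids) > 1)
        expect_true(all(diff(sys$ppos[kids][order(kids)]) > -1e-9))
    }
  }
  # total segment length equals total axis length
  expect_equal(sum(sys$segs[seq_len(sys$nseg), "len"]),
               sum(sys$len[seq_len(n)]), tolerance = 1e-9)
  # no axis exceeds its multiplier-scaled maximum length
  expect_true(all(sys$len[seq_len(n)] <= sys$maxlen[seq_len(n)] + 1e-8))
  # no aerial segments
  expect_true(all(sys$segs[seq_len(sys$nseg), c("z0", "z1")] >= -1e-9))
})

test_that("identical seeds give bit-identical systems, different seeds differ", {
  p <- dj123_params()
  a <- grow_root_system(p, horizon = 6, seed = 42)
  b <- grow_root_system(p, horizon = 6, seed = 42)
  expect_identical(a$n, b$n)
  expect_identical(a$len[seq_len(a$n)], b$len[seq_len(b$n)])
  expect_identical(a$segs[seq_len(a$nseg), ], b$segs[seq_len(b$nseg), ])
  c <- grow_root_system(p, horizon = 6, seed = 43)
  expect_false(identical(a$len[seq_len(a$n)], c$len[seq_len(c$n)]))
})

test_that("class geometry applies the cylinder formulas", {
  p <- dj123_params()
  one <- synth_system(straight_segs("stype", 1))
  g <- class_geometry(one, at = 0, params = p)
  expect_equal(g$surface_cm2[g$class == "stype"], pi * 0.0045)
  expect_equal(g$volume_cm3[g$class == "stype"], pi * (0.0045 / 2)^2)
  expect_equal(g$weight_g[g$class == "stype"], pi * (0.0045 / 2)^2 * 0.1)
  # 33.7 m of S-type laterals: surface close to the published 47.7 cm^2
  big <- synth_system(straight_segs("stype", 3370, n = 50))
  gb <- class_geometry(big, 0, p)
  expect_equal(gb$surface_cm2[gb$class == "stype"], pi * 0.0045 * 3370)
  expect_equal(round(gb$surface_cm2[gb$class == "stype"], 1), 47.6)
  # empty system: all-zero ledger
  sys0 <- new_root_system(p)
  g0 <- class_geometry(sys0, 0, p)
  expect_true(all(g0$length_cm == 0) && all(g0$weight_g == 0))
})

test_that("S-type axes outnumber L-types which outnumber nodal axes", {
  sys <- memo("sys21", grow_root_system(dj123_params(), horizon = 21,
                                        seed = 2))
  cnt <- axis_counts(sys)
  nodal <- sum(cnt[c("nodal_branched", "nodal_fast", "nodal_tiller")])
  expect_gt(cnt[["stype"]], cnt[["ltype"]])
  expect_gt(cnt[["ltype"]], nodal)
})
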