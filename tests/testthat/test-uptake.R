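test_that("Michaelis-Menten influx satisfies its defining identities", {
  kin <- list(Imax = 0.12, Km = 5.8e-3, Cmin = 1e-5)
  expect_equal(mm_influx(kin$Cmin, kin), 0)
  expect_equal(mm_influx(0, kin), 0)                      # clamp below Cmin
  expect_equal(mm_influx(1e6, kin), kin$Imax, tolerance = 1e-6)
  expect_equal(mm_influx(kin$Cmin + kin$Km, kin), kin$Imax / 2)
  expect_error(mm_influx(-1e-3, kin), "non-negative")
})

test_that("a single radial step depletes, bounds and conserves", {
  soil <- dj123_params()$soil
  dom <- radial_domain(0.0325, 0.3, n = 25, soil = soil)
  # no sink: nothing happens
  soil0 <- soil
  soil0$Imax <- 0
  r0 <- step_radial(dom, soil0, dt = 0.2)
  expect_equal(r0$uptake_per_cm, 0)
  expect_equal(r0$domain$bat$C, dom$bat$C)
  # uniform start: one step takes at most the undepleted-surface flux
  r1 <- step_radial(dom, soil, dt = 0.2)
  expect_lte(r1$uptake_per_cm,
             2 * pi * 0.0325 * mm_influx(soil$c_solution_init, soil) * 0.2 +
               1e-15)
  expect_gt(r1$uptake_per_cm, 0)
  expect_error(step_radial(dom, soil, dt = 0.5), "0.2")
  # per-step discrete mass balance to the Newton tolerance
  pool0 <- domain_soil_P(dom)
  d <- dom
  cum <- 0
  for (k in 1:25) {
    res <- step_radial(d, soil, dt = 0.2)
    d <- res$domain
    cum <- cum + res$uptake_per_cm
    bal <- abs((pool0 - domain_soil_P(d)) - cum) / pool0
    expect_lt(bal, 1e-8)
  }
  # concentrations stay at or above the uptake threshold
  expect_true(all(d$bat$C >= soil$Cmin - 1e-9))
  # the profile is monotone non-decreasing away from the root
  expect_true(all(diff(d$bat$C[1, ]) >= -1e-15))
})

test_that("linear-kinetics steady state matches the closed-form solution", {
  # fixed outer concentration, Robin (linear) inner boundary
  r0 <- 0.05; r1 <- 0.5; De <- 0.01; b <- 2; kappa <- 0.05; C_out <- 5e-4
  soil <- list(c_solution_init = C_out, buffer_power = b, De = De,
               Imax = kappa * 1e6, Km = 1e6, Cmin = 0, v0 = 0)
  dom <- radial_domain(r0, r1, n = 40, soil = soil)
  for (k in 1:3000)
    dom <- step_radial(dom, soil, dt = 0.2, outer_bc = "fixed",
                       outer_value = C_out)$domain
  C1 <- dom$bat$C[1, 1]
  C1_exact <- C_out / (1 + r0 * kappa * log(r1 / r0) / (b * De))
  expect_lt(abs(C1 - C1_exact) / C1_exact, 0.005)
  # and the full profile is logarithmic in r
  prof_exact <- C1_exact + (2 * pi * r0 * kappa * C1_exact) *
    log(dom$bat$r[1, ] / r0) / (2 * pi * b * De)
  expect_lt(max(abs(dom$bat$C[1, ] - prof_exact)) / C_out, 0.005)
})

test_that("the transient solver agrees with an independent method-of-lines
           reference", {
  skip_if_not_installed("deSolve")
  r0 <- 0.05; r1 <- 0.3; De <- 1e-3; b <- 10; kappa <- 0.02; C0 <- 5.4e-4
  soil <- list(c_solution_init = C0, buffer_power = b, De = De,
               Imax = kappa * 1e6, Km = 1e6, Cmin = 0, v0 = 0)
  # reference: uniform-grid finite differences integrated by lsoda
  M <- 240
  r <- seq(r0, r1, length.out = M)
  h <- r[2] - r[1]
  rhs <- function(t, C, parms) {
    Cg0 <- C[1] - h * kappa * C[1] / (b * De)     # ghost at r0 (Robin)
    CgN <- C[M - 1]                               # ghost at r1 (no flux)
    Cm <- c(Cg0, C, CgN)
    d2 <- (Cm[1:M] - 2 * Cm[2:(M + 1)] + Cm[3:(M + 2)]) / h^2
    d1 <- (Cm[3:(M + 2)] - Cm[1:M]) / (2 * h)
    list(De * (d2 + d1 / r))
  }
  times <- c(0, 1, 2, 4)
  ref <- deSolve::ode(rep(C0, M), times, rhs, NULL, method = "lsoda",
                      atol = 1e-12, rtol = 1e-10)
  dom <- radial_domain(r0, r1, n = 60, soil = soil)
  dt <- 0.01
  for (ti in 2:length(times)) {
    for (k in seq_len((times[ti] - times[ti - 1]) / dt))
      dom <- step_radial(dom, soil, dt = dt)$domain
    C1_ref <- ref[ti, 2]
    expect_lt(abs(dom$bat$C[1, 1] - C1_ref) / C1_ref, 0.005)
    # compare the whole profile on the solver nodes
    Cref_interp <- approx(r, ref[ti, -1], xout = dom$bat$r[1, ])$y
    expect_lt(max(abs(dom$bat$C[1, ] - Cref_interp)) / C0, 0.005)
  }
})

test_that("system uptake is monotone in soil P, Imax and hair traits", {
  p <- dj123_params()
  sys <- synth_system(straight_segs("nodal_branched", 10, n = 5))
  content <- function(pp, hairs = TRUE)
    plant_P_content(system_uptake(sys, pp, horizon = 4, dt = 0.2,
                                  n_radial = 15, include_hairs = hairs), 4)
  lv <- c(0.5, 1, 2)
  for (path in c("soil.c_solution_init", "soil.Imax",
                 "classes.nodal_branched.hair.length",
                 "classes.nodal_branched.hair.max_density")) {
    vals <- vapply(lv, function(f) content(perturb_params(p, path, f)), 0)
    expect_true(all(diff(vals) > 0), info = path)
  }
  # soil at the uptake threshold: no uptake at all
  pmin_ <- p
  pmin_$soil$c_solution_init <- pmin_$soil$Cmin * (1 + 1e-12)
  expect_lt(content(pmin_), 1e-10)
})

test_that("uptake is near-linear in soil concentration at study conditions", {
  p <- dj123_params()
  sys <- synth_system(rbind(straight_segs("nodal_branched", 15, n = 5),
                            straight_segs("ltype", 15, n = 5, axis = 2,
                                          z = 6)))
  content <- function(f)
    plant_P_content(system_uptake(sys, perturb_params(p, "soil.c_solution_init", f),
                                  horizon = 8, dt = 0.2, n_radial = 15), 8)
  ratio <- content(4) / content(1)
  expect_gte(ratio, 3)
  expect_lte(ratio, 4.2)
})

test_that("uptake per length behaves like a ratio and doubles with soil P
           under linear kinetics", {
  p <- dj123_params()
  p$soil$Km <- 10                       # Km >> C: linear regime
  sys <- synth_system(straight_segs("ltype", 20, n = 5), clock = 5)
  up1 <- system_uptake(sys, p, horizon = 5, dt = 0.2, n_radial = 15)
  u1 <- uptake_per_length(up1, sys, 5, p)
  expect_gt(u1, 0)
  p2 <- perturb_params(p, "soil.c_solution_init", 2)
  up2 <- system_uptake(sys, p2, horizon = 5, dt = 0.2, n_radial = 15)
  u2 <- uptake_per_length(up2, sys, 5, p2)
  expect_equal(u2 / u1, 2, tolerance = 0.03)
  # zero-length system is signalled
  empty <- synth_system(straight_segs("ltype", 1), clock = 1)
  emptyg <- system_uptake(empty, p, horizon = 1, dt = 0.2, n_radial = 10)
  expect_error(uptake_per_length(emptyg, synth_system(
    transform(straight_segs("ltype", 1), len = 0), clock = 1), 1, p),
    "zero")
})

test_that("global mass balance holds over a full system run", {
  p <- dj123_params()
  sys <- memo("sys8", grow_root_system(p, horizon = 8, seed = 7))
  up <- memo("up8", system_uptake(sys, p, horizon = 8, n_radial = 15))
  expect_lt(uptake_mass_balance(up), 1e-6)
  # per-class attribution sums exactly to the total content
  expect_equal(sum(up$class_totals$uptake_ug),
               plant_P_content(up, 8), tolerance = 1e-9)
})

test_that("depletion-zone overlap is 0 for an isolated axis, 1 for twins", {
  p <- dj123_params()
  iso <- synth_system(straight_segs("nodal_branched", 10, n = 5))
  upi <- system_uptake(iso, p, horizon = 2, dt = 0.2, n_radial = 15)
  expect_equal(depletion_overlap(iso, upi, 2), 0)
  twins <- data.frame(axis = c(1, 2), len = 1, mx = c(0, 0.05), my = 0,
                      mz = 5, Rd = 0.1)
  expect_equal(segment_overlap_fraction(twins), 1)
  # far apart: no overlap
  twins$mx <- c(0, 10)
  expect_equal(segment_overlap_fraction(twins), 0)
})

test_that("the uptake pipeline is deterministic under a fixed seed", {
  p <- dj123_params()
  one <- function() {
    sys <- grow_root_system(p, horizon = 6, seed = 31)
    system_uptake(sys, p, horizon = 6, n_radial = 12)$content_ts$P_ug
  }
  expect_identical(one(), one())
})
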