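test_that("default parameterization carries the published class constants", {
  p <- dj123_params()
  expect_setequal(names(p$classes),
                  c("primary", "nodal_branched", "nodal_fast", "nodal_tiller",
                    "ltype", "stype"))
  d <- vapply(p$classes, `[[`, 0, "diameter")
  expect_equal(unname(d[c("primary", "nodal_fast", "nodal_branched",
                          "nodal_tiller", "ltype", "stype")]),
               c(0.065, 0.065, 0.05, 0.06, 0.02, 0.0045))
  peaks <- vapply(p$classes, `[[`, 0, "peak_growth_rate")
  expect_equal(unname(peaks[c("primary", "nodal_branched", "nodal_fast",
                              "ltype", "stype")]),
               c(2.19, 1.46, 2.14, 0.73, 0.14))
  maxlen <- vapply(p$classes, `[[`, 0, "max_length")
  expect_equal(unname(maxlen[c("primary", "nodal_branched", "nodal_fast",
                               "ltype", "stype")]),
               c(46, 35, 45, 14.6, 1.08))
  expect_equal(p$classes$primary$hair$max_density, 1400)
  expect_equal(p$classes$primary$hair$length, 0.02)
  expect_equal(p$classes$ltype$hair$max_density, 700)
  expect_equal(p$classes$stype$hair$length, 0.012)
  expect_equal(p$classes$stype$hair$diameter, 5e-4)
  rho <- vapply(p$classes, `[[`, 0, "tissue_density")
  expect_equal(unname(rho[c("nodal_branched", "ltype", "stype")]),
               c(0.06, 0.07, 0.1))
  expect_equal(p$soil$buffer_power, 6000)
  expect_equal(p$soil$De, 9.227e-6)
  expect_equal(p$soil$c_solution_init, 5.4e-4)
  expect_equal(p$soil$c_solution_measured, 8.3e-5)
})

test_that("parameter validation enforces the structural invariants", {
  p <- dj123_params()
  expect_silent(validate_params(p))
  # every IBD child is a defined, permitted class with ordered bounds
  for (nm in names(p$classes))
    for (child in names(p$classes[[nm]]$ibd_by_child)) {
      expect_true(child %in% names(p$classes))
      d <- p$classes[[nm]]$ibd_by_child[[child]]
      expect_true(d$min <= d$mean && d$mean <= d$max && d$sd > 0)
    }
  bad <- p
  bad$classes$ltype$ibd_by_child$stype$min <- 99
  expect_error(validate_params(bad), "min <= mean <= max")
  bad2 <- p
  bad2$soil$Cmin <- 1
  expect_error(validate_params(bad2), "c_solution_init")
  bad3 <- p
  bad3$classes$stype$ibd_by_child <- list(ltype = list(mean = 1, sd = 1,
                                                       min = 0, max = 2))
  expect_error(validate_params(bad3), "cannot bear")
})

test_that("parameter sets round-trip losslessly through the config file", {
  p <- dj123_params()
  f <- withr::local_tempfile(fileext = ".yml")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2, p, tolerance = 1e-12)
})

test_that("perturbing by a factor and its inverse restores the base values", {
  p <- dj123_params()
  paths <- c("soil.c_solution_init", "classes.ltype.max_length",
             "classes.stype.hair.length", "soil.buffer_power")
  for (path in paths) {
    p2 <- perturb_params(perturb_params(p, path, 3.7), path, 1 / 3.7)
    expect_equal(p2, p, tolerance = 1e-12)
  }
  for (nm in RHIZO_SCAN_PARAMS) {
    p2 <- apply_scan_factor(apply_scan_factor(p, nm, 2.5), nm, 0.4)
    expect_equal(p2, p, tolerance = 1e-12)
  }
})

test_that("buffer-power perturbation keeps De * b constant", {
  p <- dj123_params()
  p2 <- perturb_params(p, "soil.buffer_power", 4)
  expect_equal(p2$soil$buffer_power, 24000)
  expect_equal(p2$soil$De * p2$soil$buffer_power,
               p$soil$De * p$soil$buffer_power)
})

test_that("scenarios resolve factors deterministically", {
  p <- dj123_params()
  sc <- make_scenario(p, c(soil_c = 1), replicates = 3, seed = 5)
  expect_equal(sc$params, p)                      # identity factor
  sc4 <- make_scenario(p, c(soil_c = 4), seed = 5)
  expect_equal(sc4$params$soil$c_solution_init, 2.16e-3)
  thin <- make_scenario(p, c("classes.nodal_fast.diameter" = 0.050 / 0.065),
                        seed = 5)
  expect_equal(thin$params$classes$nodal_fast$diameter, 0.050)
  expect_error(make_scenario(p, c("classes.nodal_fast.thickness" = 2)),
               "unknown parameter path")
  sc2 <- make_scenario(p, c(soil_c = 1), replicates = 3, seed = 5)
  expect_identical(sc$seeds, sc2$seeds)           # same seed, same seed list
  expect_false(identical(sc$seeds,
                         make_scenario(p, NULL, 3, seed = 6)$seeds))
})

test_that("printed calibration anchors are available to the pipeline", {
  ct <- calibration_targets()
  expect_equal(ct$measured_P_28DAE, 774.3)
  expect_equal(ct$sim_P_83nM_28DAE, 150.6)
  expect_equal(ct$day_offset, 3)
  expect_equal(ct$tissue_P_conc, 0.8)
  t3 <- published_class_table()
  expect_equal(t3$length_m[t3$class == "stype"], 33.7)
  expect_equal(t3$P_uptake_ug[t3$class == "total"], 689.2)
  expect_true(is.infinite(t3$recovery_case3[t3$class == "nodal"]))
})

test_that("the flat data dictionary covers every numeric leaf", {
  dict <- params_dictionary(dj123_params())
  expect_true(all(c("classes.stype.diameter", "soil.De",
                    "sim.horizon") %in% dict$path))
  expect_equal(dict$value[dict$path == "classes.stype.diameter"], 0.0045)
  expect_false(any(duplicated(dict$path)))
})
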