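# Shared fixtures.  Heavy simulations are memoised so that several test
# files can reuse the same runs.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A synthetic root system built directly from a segment table; enough of the
# `root_system` contract for geometry, hair and uptake computations.
synth_system <- function(df, clock = max(df$tb)) {
  sys <- new.env(parent = emptyenv())
  m <- as.matrix(df[, c("axis", "cls", "tb", "x0", "y0", "z0",
                        "x1", "y1", "z1", "len")])
  sys$segs <- m
  sys$nseg <- nrow(m)
  sys$clock <- clock
  sys$n <- max(df$axis)
  class(sys) <- "root_system"
  sys
}

# n straight segments of one class laid along x at day tb
straight_segs <- function(class_id, total_len, n = 10, tb = 0, z = 5,
                          axis = 1) {
  l <- total_len / n
  x <- seq(0, by = l, length.out = n)
  data.frame(axis = axis, cls = match(class_id, names(dj123_params()$classes)),
             tb = tb, x0 = x, y0 = 0, z0 = z, x1 = x + l, y1 = 0, z1 = z,
             len = l)
}

# small day-10 default system (architecture-level tests)
small_sys <- function() memo("small_sys", {
  grow_root_system(dj123_params(), horizon = 10, seed = 101)
})

# calibrated day-31 study runs shared by the acceptance tests
study_params <- function() memo("study_params", {
  p <- dj123_params()
  sys <- grow_root_system(p, horizon = 31, seed = 1)
  calibrate_imax(sys, p)
})

study_scan <- function() memo("study_scan", {
  pc <- study_params()
  soil <- run_scan(pc, "soil_c", levels = c(0.25, 0.5, 1, 1.5, 2, 4),
                   replicates = 3, seed = 1, horizon = 31, n_radial = 15)
  four <- run_scan(pc, c("hair_length", "hair_density", "ltype_length",
                         "stype_length"),
                   levels = c(1, 4), replicates = 3, seed = 1,
                   horizon = 31, n_radial = 15)
  list(soil = soil, four = four)
})

study_run <- function(seed) memo(paste0("study_run_", seed), {
  p <- study_params()
  sys <- grow_root_system(p, horizon = 31, seed = seed)
  up <- system_uptake(sys, p, horizon = 31)
  list(sys = sys, up = up,
       ledger = build_ledger(class_geometry(sys, 31, p),
                             hair_geometry(sys, 31, p), up, at = 31))
})
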