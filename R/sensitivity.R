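# -- one-at-a-time sensitivity scan ------------------------------------------

#' Run a factor-level sensitivity scan
#'
#' One-at-a-time scan over the two soil parameters (solution P
#' concentration, buffer power with coupled diffusivity) and the six root
#' parameters (L-/S-type length and inter-branching distance, hair length
#' and density), at multiplicative factor levels, with replicate stochastic
#' runs.  Baseline (level 1) runs are shared across parameters, and every
#' replicate reuses its seed across parameters and levels, so responses are
#' paired.  A failed run is recorded with `NA` content and the scan
#' continues.
#'
#' @param base_params Base `rhizo_params` (use a calibrated `soil$Imax` for
#'   absolute contents; percent-of-baseline is robust to the calibration).
#' @param parameters Subset of
#'   `c("soil_c", "soil_buffer", "ltype_length", "stype_length",
#'   "ltype_ibd", "stype_ibd", "hair_length", "hair_density")`.
#' @param levels Positive factor levels (default the published
#'   25-400% set).
#' @param replicates Replicate runs per cell (default 5).
#' @param seed Master seed; replicate seeds derive deterministically.
#' @param horizon Evaluation day (default 31 = 28 DAE).
#' @param dt,n_radial Solver resolution (scans typically run at reduced
#'   radial resolution; the resolution used is recorded in the result).
#' @return data.frame of class `rhizo_scan`: `parameter`, `level`,
#'   `replicate`, `seed`, `P_ug`, `pct_baseline`, `n_radial`.
#' @export
run_scan <- function(base_params = dj123_params(),
                     parameters = RHIZO_SCAN_PARAMS,
                     levels = c(0.25, 0.5, 1, 1.5, 2, 4),
                     replicates = 5, seed = 1, horizon = 31,
                     dt = base_params$uptake$dt, n_radial = 15) {
  parameters <- match.arg(parameters, RHIZO_SCAN_PARAMS, several.ok = TRUE)
  stopifnot(all(levels > 0), replicates >= 1)
  seeds <- derive_seeds(seed, replicates)
  run_one <- function(p, s) {
    tryCatch({
      sys <- grow_root_system(p, horizon = horizon, seed = s)
      up <- system_uptake(sys, p, horizon = horizon, dt = dt,
                          n_radial = n_radial)
      plant_P_content(up, horizon)
    }, error = function(e) {
      warning("scan run failed (seed ", s, "): ", conditionMessage(e))
      NA_real_
    })
  }
  base_P <- vapply(seeds, function(s) run_one(base_params, s), 0)
  base_mean <- mean(base_P, na.rm = TRUE)
  rows <- list()
  for (par in parameters) {
    for (lv in levels) {
      P <- if (lv == 1) base_P else
        vapply(seeds, function(s)
          run_one(apply_scan_factor(base_params, par, lv), s), 0)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = par, level = lv, replicate = seq_along(seeds),
        seed = seeds, P_ug = P, pct_baseline = 100 * P / base_mean,
        n_radial = n_radial, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("rhizo_scan", "data.frame")
  out
}

#' Down/up response asymmetry of a scanned parameter
#'
#' The scan responds asymmetrically to proportional decreases and increases;
#' this reports both sides: `down = |100 - pct(0.25)|` and
#' `up = |pct(4) - 100|`, averaged over replicates.
#'
#' @param result A `rhizo_scan` result containing levels 0.25 and 4.
#' @param parameter Parameter name to summarise.
#' @return Named numeric vector `c(down, up)` in percentage points.
#' @export
asymmetry_index <- function(result, parameter) {
  r <- result[result$parameter == parameter, ]
  if (nrow(r) == 0) stop("parameter '", parameter, "' not in scan result")
  p25 <- r$pct_baseline[abs(r$level - 0.25) < 1e-9]
  p4 <- r$pct_baseline[abs(r$level - 4) < 1e-9]
  if (length(p25) == 0 || length(p4) == 0)
    stop("levels 0.25 and 4 are required for the asymmetry index")
  c(down = abs(100 - mean(p25, na.rm = TRUE)),
    up = abs(mean(p4, na.rm = TRUE) - 100))
}
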