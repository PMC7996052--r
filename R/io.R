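# -- RSML export, run manifest, pipeline -------------------------------------

#' Export a root system to RSML
#'
#' Writes the full architecture in Root System Markup Language: one nested
#' `<root>` per axis with its polyline (point coordinates in cm; RSML `z` is
#' the downward depth coordinate), and per-root properties carrying the root
#' class label and birth time.
#'
#' @param sys A `root_system`.
#' @param file Output path.
#' @param label Plant label in the metadata.
#' @return `file`, invisibly.
#' @export
export_rsml <- function(sys, file, label = "DJ123") {
  n <- sys$n
  segs <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
  ax <- segs[, "axis"]
  # polyline per axis: the segment start points plus the final tip
  pts <- lapply(seq_len(n), function(i) {
    s <- segs[ax == i, , drop = FALSE]
    if (nrow(s) == 0)
      matrix(sys$tip[i, ], 1, 3)
    else
      rbind(s[, c("x0", "y0", "z0")], s[nrow(s), c("x1", "y1", "z1")])
  })
  poly <- vapply(pts, function(m)
    paste0(sprintf('<point x="%.4f" y="%.4f" z="%.4f"/>',
                   m[, 1], m[, 2], m[, 3]), collapse = ""), "")
  props <- sprintf(
    '<properties><class>%s</class><birth_time>%.3f</birth_time></properties>',
    RHIZO_CLASSES[sys$cls[seq_len(n)]], sys$birth[seq_len(n)])
  root_xml <- sprintf(
    '<root ID="%d" label="%s">%s<geometry><polyline>%s</polyline></geometry>%s</root>',
    seq_len(n), RHIZO_CLASSES[sys$cls[seq_len(n)]], props, poly,
    rep("", n))
  # nest children inside their parent root
  children <- split(seq_len(n), sys$parent[seq_len(n)])
  assemble <- function(i) {
    kids <- children[[as.character(i)]]
    inner <- if (is.null(kids)) "" else
      paste0(vapply(kids, assemble, ""), collapse = "")
    sub("</root>$", paste0(inner, "</root>"), root_xml[i])
  }
  top <- children[["0"]]
  body <- paste0(vapply(top, assemble, ""), collapse = "")
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<rsml xmlns:po="http://www.plantontology.org/xml-dtd/po.dtd">',
    '<metadata><version>1</version><unit>cm</unit><resolution>1</resolution>',
    '<last-modified>today</last-modified><software>rhizoP</software>',
    '</metadata>',
    '<scene><plant label="', label, '">', body, '</plant></scene></rsml>')
  xml2::write_xml(xml2::read_xml(doc), file)  # validates well-formedness
  invisible(file)
}

#' Write a run manifest
#'
#' Records the master seed, derived stage seeds, package version, key
#' calibration scalars actually used (soil solution concentration, horizon)
#' and the files written, so that a run can be reproduced bit-identically.
#'
#' @param path Output JSON path.
#' @param params The parameter set used.
#' @param seed Master seed.
#' @param outputs Named character vector of files written.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, params, seed, outputs = character()) {
  man <- list(
    package = "rhizoP",
    version = as.character(utils::packageVersion("rhizoP")),
    master_seed = seed,
    stage_seeds = list(architecture = derive_seeds(seed, 1, 1L),
                       sensitivity = derive_seeds(seed, 1, 2L)),
    soil_c_solution_uM = params$soil$c_solution_init * 1000,
    horizon_days = params$sim$horizon,
    outputs = as.list(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full simulation pipeline
#'
#' Grows the root system, solves P uptake, builds the geometry/hair/economic
#' ledgers and writes the standard outputs (RSML architecture, CSV ledgers
#' and uptake time series, config snapshot, JSON manifest) to `outdir`.
#'
#' @param params A `rhizo_params` object.
#' @param seed Master seed.
#' @param outdir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param horizon Evaluation day for the ledgers (default
#'   `params$sim$report_day`).
#' @param dt,n_radial Solver resolution.
#' @param calibrate If `TRUE`, calibrate `Imax` against the measured plant P
#'   content before the uptake stage.
#' @return List with `system`, `uptake`, `geometry`, `hairs`, `ledger`,
#'   `params` (possibly calibrated), invisibly when writing files.
#' @export
run_pipeline <- function(params = dj123_params(), seed = 1, outdir = NULL,
                         horizon = params$sim$report_day,
                         dt = params$uptake$dt,
                         n_radial = params$uptake$n_radial,
                         calibrate = FALSE) {
  sys <- grow_root_system(params, horizon = horizon, seed = seed)
  if (calibrate)
    params <- calibrate_imax(sys, params, at = horizon, dt = dt,
                             n_radial = n_radial)
  up <- system_uptake(sys, params, horizon = horizon, dt = dt,
                      n_radial = n_radial)
  geom <- class_geometry(sys, horizon, params)
  hl <- hair_geometry(sys, horizon, params)
  led <- build_ledger(geom, hl, up, at = horizon)
  res <- list(system = sys, uptake = up, geometry = geom, hairs = hl,
              ledger = led, params = params)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    f <- function(x) file.path(outdir, x)
    export_rsml(sys, f("architecture.rsml"))
    utils::write.csv(geom, f("class_geometry.csv"), row.names = FALSE)
    utils::write.csv(hl, f("hair_ledger.csv"), row.names = FALSE)
    write_ledger_csv(led, f("cost_benefit_ledger.csv"))
    utils::write.csv(up$content_ts, f("plant_P_timeseries.csv"),
                     row.names = FALSE)
    utils::write.csv(up$class_totals, f("uptake_by_class.csv"),
                     row.names = FALSE)
    write_params(params, f("params.yml"))
    outs <- c("architecture.rsml", "class_geometry.csv", "hair_ledger.csv",
              "cost_benefit_ledger.csv", "plant_P_timeseries.csv",
              "uptake_by_class.csv", "params.yml")
    write_run_manifest(f("manifest.json"), params, seed,
                       stats::setNames(file.path(outdir, outs), outs))
    message(sprintf(
      "pipeline: seed %d, horizon %g d, soil C %.3g uM, plant P %.1f ug",
      seed, horizon, params$soil$c_solution_init * 1000,
      plant_P_content(up, horizon)))
    return(invisible(res))
  }
  res
}
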