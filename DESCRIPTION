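Package: rhizoP
Title: 3D Upland-Rice Root Architecture and Phosphate Uptake Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic 3D simulation of the root system architecture of the
    upland rice genotype DJ123 (primary, branched/fast/tiller nodal, L-type and
    S-type lateral roots) with root hairs represented as explicit cylinder
    cohorts.  Phosphate uptake is computed per root segment with a radial
    advection-diffusion-reaction (Barber-Cushman type) solver in buffered soil
    and Michaelis-Menten influx kinetics at the root and hair surfaces.
    Downstream analyses cover one-at-a-time parameter sensitivity scans,
    per-class cost-benefit ledgers based on tissue phosphorus investment, and
    cost-recovery (pay-off time) scenarios, including hypothetical root
    architectures.  Root systems export to RSML; ledgers and scans to CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
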