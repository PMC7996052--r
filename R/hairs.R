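# -- explicit root-hair cohorts ----------------------------------------------
#
# Every root segment carries a cohort of identical hair cylinders: class
# ceiling density declining linearly with host-segment age, class hair length
# and a 5 um diameter.  Cohort totals (count x identical cylinder) are exact
# for uptake and cost purposes because all hairs of a cohort share geometry.

#' Root-hair density at a given root age
#'
#' Hair density starts at the class ceiling and declines linearly with root
#' age: the reference decline runs from the full density on a 3-day-old root
#' to 55% of it on a 40-day-old root (-1.216% of the age-3 value per day),
#' the same relative shape being applied to every class ceiling.  Density is
#' clamped at zero and never increases with age.
#'
#' @param class_params One element of `dj123_params()$classes`.
#' @param root_age Age of the host root in days (vectorized, >= 0).
#' @return Hair density in hairs per cm of root.
#' @examples
#' cp <- dj123_params()$classes$ltype
#' cp$hair$max_density <- 600     # the published reference decline
#' hair_density(cp, 3)            # 600
#' hair_density(cp, 40)           # 330
#' @export
hair_density <- function(class_params, root_age) {
  if (any(root_age < 0)) stop("root_age must be non-negative")
  h <- class_params$hair
  d <- h$decline
  slope <- (1 - d$end_frac) / (d$end_age - d$ref_age)  # fraction per day
  frac <- 1 - slope * pmax(root_age - d$ref_age, 0)
  h$max_density * pmax(frac, 0)
}

# Internal: hair ledger rows per host class at a given day.  Cohort age is
# evaluated per segment from its birth time.
hair_ledger_rows <- function(sys, at, params) {
  out <- data.frame(class = RHIZO_CLASSES, hair_length_cm = 0,
                    hair_surface_cm2 = 0, hair_volume_cm3 = 0,
                    hair_weight_g = 0, stringsAsFactors = FALSE)
  if (sys$nseg == 0) return(out)
  s <- sys$segs[seq_len(sys$nseg), , drop = FALSE]
  keep <- s[, "tb"] <= at + 1e-9
  if (!any(keep)) return(out)
  s <- s[keep, , drop = FALSE]
  age <- pmax(at - s[, "tb"], 0)
  for (ci in seq_along(RHIZO_CLASSES)) {
    cp <- params$classes[[RHIZO_CLASSES[ci]]]
    m <- s[, "cls"] == ci
    if (!any(m)) next
    n_hairs <- hair_density(cp, age[m]) * s[m, "len"]
    tot_len <- sum(n_hairs) * cp$hair$length
    out$hair_length_cm[ci] <- tot_len
    out$hair_surface_cm2[ci] <- pi * cp$hair$diameter * tot_len
    out$hair_volume_cm3[ci] <- pi * (cp$hair$diameter / 2)^2 * tot_len
  }
  # hairs weigh in at the S-type/hair tissue density (0.1 g cm^-3)
  out$hair_weight_g <- out$hair_volume_cm3 * 0.1
  out
}

#' Root-hair geometry ledger
#'
#' Totals the explicit hair cylinders attached to every segment: hair length
#' is `sum(n_hairs) * hair_length` per host class, surface `pi * d * length`,
#' volume `pi * d^2/4 * length`, weight `volume * 0.1 g cm^-3`.
#'
#' @param sys A `root_system`.
#' @param at Day at which to evaluate (<= current clock).
#' @param params A `rhizo_params` object.
#' @return A data.frame per host class plus a `total` row.
#' @export
hair_geometry <- function(sys, at = sys$clock, params = dj123_params()) {
  if (at > sys$clock + 1e-9) stop("'at' exceeds the system clock")
  rows <- hair_ledger_rows(sys, at, params)
  tot <- data.frame(class = "total",
                    hair_length_cm = sum(rows$hair_length_cm),
                    hair_surface_cm2 = sum(rows$hair_surface_cm2),
                    hair_volume_cm3 = sum(rows$hair_volume_cm3),
                    hair_weight_g = sum(rows$hair_weight_g),
                    stringsAsFactors = FALSE)
  rbind(rows, tot)
}

#' Per-class shares of root-hair geometry
#'
#' Reports each host class's share of total hair length, surface and volume,
#' together with the hair fraction of whole-system (root + hair) length,
#' surface and volume, and the hair-to-root length ratio.
#'
#' @param sys A `root_system`.
#' @param at Day at which to evaluate.
#' @param params A `rhizo_params` object.
#' @return A list with `shares` (data.frame, percent per host class, summing
#'   to 100 within each geometry column) and `hair_fraction` (named vector:
#'   percent of whole-system length/surface/volume due to hairs, plus
#'   `length_ratio`, total hair length over total root length).
#' @export
hair_share_report <- function(sys, at = sys$clock, params = dj123_params()) {
  h <- hair_ledger_rows(sys, at, params)
  g <- class_geometry(sys, at, params)
  tot <- colSums(h[, -1])
  shares <- h
  for (col in c("hair_length_cm", "hair_surface_cm2", "hair_volume_cm3")) {
    s <- sum(h[[col]])
    shares[[col]] <- if (s > 0) 100 * h[[col]] / s else 0 * h[[col]]
  }
  names(shares) <- c("class", "length_pct", "surface_pct", "volume_pct",
                     "weight_g")
  shares$weight_g <- NULL
  root <- c(length = sum(g$length_cm), surface = sum(g$surface_cm2),
            volume = sum(g$volume_cm3))
  hair <- c(length = tot[["hair_length_cm"]],
            surface = tot[["hair_surface_cm2"]],
            volume = tot[["hair_volume_cm3"]])
  frac <- 100 * hair / (hair + root)
  ratio <- if (root[["length"]] > 0) hair[["length"]] / root[["length"]]
           else NA_real_
  list(shares = shares,
       hair_fraction = c(frac, length_ratio = ratio))
}
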