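# Stochastic terminal-arteriole blockade. Microspheres lodge independently;
# conditional on entering the modelled tissue a sphere lands in a supply unit
# with probability proportional to the unit's capillary count (flow-weighted
# lodging), silencing every capillary the unit feeds.

F_EDL_REF <- 2.0e-4     # capture probability for the reference section area
AREA_REF_MM2 <- 2.56    # default control section, mm^2

#' Microsphere dose specification
#'
#' @param n_spheres Number of injected microspheres (>= 0).
#' @param f_edl Probability that one sphere lodges within the modelled
#'   section. Default `NULL` scales the reference calibration (2.0e-4 for a
#'   2.56 mm^2 section) by the section area, so dose-response behaviour does
#'   not depend on how much tissue is simulated.
#' @param seed Integer seed.
#' @return Object of class `dose_spec`.
#' @export
dose_spec <- function(n_spheres, f_edl = NULL, seed = 1L) {
  stopifnot(n_spheres >= 0, is.null(f_edl) || (f_edl >= 0 && f_edl <= 1))
  structure(list(n_spheres = as.double(n_spheres), f_edl = f_edl,
                 seed = seed), class = "dose_spec")
}

section_f_edl <- function(section, f_edl = NULL) {
  if (!is.null(f_edl)) return(f_edl)
  b <- section$bounds
  area_mm2 <- unname((b["xmax"] - b["xmin"]) * (b["ymax"] - b["ymin"])) / 1e6
  min(F_EDL_REF * area_mm2 / AREA_REF_MM2, 1)
}

unit_sizes <- function(section) {
  u <- section$capillaries$unit_id
  if (is.null(u) || !length(u) || anyNA(u)) {
    stop("section has no supply-unit assignment; regenerate it with ",
         "generate_section() or assign unit ids before dosing")
  }
  table(u)
}

occlusion_result <- function(section, occluded_units, dose = NULL) {
  caps <- section$capillaries
  occ <- caps$unit_id %in% occluded_units
  caps$perfused <- !occ
  section$capillaries <- caps
  structure(list(
    occluded_units = sort(as.integer(occluded_units)),
    section = section,
    perfusion_index = mean(caps$perfused),
    dose = dose), class = "occlusion_result")
}

#' @export
print.occlusion_result <- function(x, ...) {
  cat("<occlusion_result>", length(x$occluded_units), "units occluded;",
      sprintf("perfusion index %.3f\n", x$perfusion_index))
  invisible(x)
}

#' Apply a microsphere dose to a section
#'
#' Each sphere independently lodges in the modelled tissue with probability
#' `f_edl`; conditional on lodging it lands in a supply unit with probability
#' proportional to the unit's capillary count. Repeated hits on an occluded
#' unit have no further effect. All capillaries of occluded units are marked
#' unperfused.
#'
#' @param section A `capillary_section` with supply-unit assignment.
#' @param dose A [dose_spec()].
#' @return An `occlusion_result`: occluded unit ids, the updated section,
#'   the realised perfusion index, and the dose.
#' @export
apply_microsphere_dose <- function(section, dose) {
  stopifnot(inherits(dose, "dose_spec"))
  sizes <- unit_sizes(section)
  f <- section_f_edl(section, dose$f_edl)
  set.seed(derive_seed(dose$seed, 505L))
  m <- rbinom(1L, round(dose$n_spheres), f)
  hit <- if (m > 0L) {
    unique(sample(names(sizes), m, replace = TRUE,
                  prob = as.numeric(sizes)))
  } else character(0)
  occlusion_result(section, as.integer(hit), dose)
}

#' Expected number of occluded units (closed form)
#'
#' Occupancy expectation for independent flow-weighted lodging: unit u with
#' capillary count s_u among total S survives n spheres with probability
#' `(1 - f s_u / S)^n`, so `E[occluded] = sum_u (1 - (1 - f s_u / S)^n)`.
#'
#' @param sizes Integer vector of unit capillary counts.
#' @param n_spheres Number of spheres.
#' @param f_edl Lodging probability.
#' @return Expected occluded-unit count.
#' @export
expected_occluded_units <- function(sizes, n_spheres, f_edl) {
  S <- sum(sizes)
  sum(1 - (1 - f_edl * sizes / S)^n_spheres)
}

#' Occlude an explicit set of supply units
#'
#' Deterministic helper (e.g. to force a known occluded fraction).
#' @param section A `capillary_section`.
#' @param units Unit ids to occlude.
#' @return An `occlusion_result`.
#' @export
occlude_units <- function(section, units) {
  sizes <- unit_sizes(section)
  occlusion_result(section, intersect(as.integer(units),
                                      as.integer(names(sizes))))
}

#' Apply femoral ligation
#'
#' Phenomenological model of acute femoral-artery ligation: supply units are
#' occluded in random order until the perfused capillary fraction falls to or
#' below `collateral_fraction`, the proportion kept open by collateral artery
#' flow (default 0.30).
#'
#' @param section A `capillary_section`.
#' @param collateral_fraction Proportion of capillaries remaining perfused,
#'   in `[0, 1]`.
#' @param seed Integer seed.
#' @return An `occlusion_result`.
#' @export
apply_ligation <- function(section, collateral_fraction = 0.30, seed = 1L) {
  stopifnot(collateral_fraction >= 0, collateral_fraction <= 1)
  sizes <- unit_sizes(section)
  set.seed(derive_seed(seed, 606L))
  ord <- sample(names(sizes))
  S <- sum(sizes)
  occluded <- character(0)
  perfused <- 1
  for (u in ord) {
    if (perfused <= collateral_fraction + 1e-12) break
    occluded <- c(occluded, u)
    perfused <- perfused - sizes[[u]] / S
  }
  occlusion_result(section, as.integer(occluded))
}

#' Monte-Carlo dose-response of the perfusion index
#'
#' Replicated microsphere dosing over a vector of doses. Within a replicate,
#' sphere streams are nested: the hit sequence for a lower dose is a prefix
#' of that for a higher dose, so the perfusion index is non-increasing in
#' dose pathwise, not only in expectation.
#'
#' @param section A `capillary_section`.
#' @param doses Numeric vector of sphere counts.
#' @param reps Replicates per dose (>= 1).
#' @param seed Integer seed.
#' @param f_edl Optional lodging probability override.
#' @return Data frame: dose, mean, sd of the perfusion index, and mean
#'   occluded capillary fraction.
#' @export
dose_response <- function(section, doses, reps = 100L, seed = 1L,
                          f_edl = NULL) {
  stopifnot(reps >= 1, all(doses >= 0))
  sizes <- unit_sizes(section)
  ids <- names(sizes)
  S <- sum(sizes)
  f <- section_f_edl(section, f_edl)
  ord <- order(doses)
  d_sorted <- doses[ord]
  pi_mat <- matrix(NA_real_, reps, length(doses))
  for (r in seq_len(reps)) {
    set.seed(derive_seed(seed, 707L, r))
    occ <- logical(length(sizes))
    prev <- 0
    for (k in seq_along(d_sorted)) {
      m <- rbinom(1L, round(d_sorted[k] - prev), f)
      if (m > 0L) {
        hit <- sample(seq_along(sizes), m, replace = TRUE,
                      prob = as.numeric(sizes))
        occ[hit] <- TRUE
      }
      prev <- d_sorted[k]
      pi_mat[r, ord[k]] <- 1 - sum(sizes[occ]) / S
    }
  }
  data.frame(dose = doses,
             mean_perfusion_index = colMeans(pi_mat),
             sd_perfusion_index = apply(pi_mat, 2L, sd),
             mean_occluded_fraction = 1 - colMeans(pi_mat))
}
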