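# Synthetic muscle-section and physiology generator. Group presets carry the
# published control / chronic-microsphere / overload group statistics that the
# generator is calibrated to emulate; everything downstream (morphometry,
# rarefaction, oxygen transport, metrics, stats) is exercised on its output.

FIBRE_TYPES <- c("I", "IIa", "IIb/IIx")

# Per-group calibration surface. Flow/pressure values are mass-normalised
# (ml min^-1 g^-1, mmHg); fibre CSAs in um^2; densities in mm^-2.
group_presets <- function() {
  list(
    control = list(
      cd = 665, cf = 1.47, p_default = 564 / 617,
      fractions = c(0.038, 0.214, 0.748),
      csa_mean = c(922, 933, 1644), csa_sd = c(217, 99, 189),
      fi_mean = 0.47, fi_sd = 0.09,
      a0_mean = 0.35, a0_sd = 0.10,
      flow = list(rest = c(mean = 8.13, peak = 27.00, amp = 25.22),
                  stim = c(mean = 11.70, peak = 34.46, amp = 31.40),
                  sd   = c(mean = 1.62, peak = 6.79, amp = 7.00)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(257, 15), edl_mg_per_g = c(0.57, 0.05),
      hypertrophy = c(1.02, 0.09), dose = 0
    ),
    chronic_MS = list(
      cd = 556, cf = 1.29, p_default = 420 / 556,
      fractions = c(0.039, 0.199, 0.762),
      csa_mean = c(1008, 1012, 2085), csa_sd = c(138, 133, 310),
      fi_mean = 0.36, fi_sd = 0.03,
      a0_mean = 0.35, a0_sd = 0.07,
      flow = list(rest = c(mean = 5.37, peak = 14.82, amp = 13.39),
                  stim = c(mean = 7.81, peak = 19.26, amp = 16.46),
                  sd   = c(mean = 1.12, peak = 2.63, amp = 2.92)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(302, 9), edl_mg_per_g = c(0.59, 0.06),
      hypertrophy = c(1.06, 0.10), dose = 700000
    ),
    OV_MS = list(
      cd = 813, cf = 1.66, p_default = 512 / 813,
      fractions = c(0.033, 0.215, 0.751) / 0.999,
      csa_mean = c(1042, 1169, 2269), csa_sd = c(180, 120, 182),
      fi_mean = 0.65, fi_sd = 0.11,
      a0_mean = 0.52, a0_sd = 0.10,
      flow = list(rest = c(mean = 6.38, peak = 20.52, amp = 18.95),
                  stim = c(mean = 10.56, peak = 29.48, amp = 25.60),
                  sd   = c(mean = 2.77, peak = 5.24, amp = 4.80)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(283, 17), edl_mg_per_g = c(0.68, 0.06),
      hypertrophy = c(1.19, 0.07), dose = 350000
    ),
    OV = list(
      cd = 836, cf = 1.63, p_default = 728 / 836,
      fractions = c(0.035, 0.232, 0.733),
      csa_mean = c(1010, 1113, 2121), csa_sd = c(173, 120, 223),
      fi_mean = 0.64, fi_sd = 0.08,
      a0_mean = 0.48, a0_sd = 0.08,
      flow = list(rest = c(mean = 5.58, peak = 17.64, amp = 16.50),
                  stim = c(mean = 10.44, peak = 28.20, amp = 24.92),
                  sd   = c(mean = 1.47, peak = 4.17, amp = 4.25)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(281, 20), edl_mg_per_g = c(0.67, 0.03),
      hypertrophy = c(1.19, 0.06), dose = 0
    ),
    ligation = list(
      cd = 665, cf = 1.47, p_default = 0.30,
      fractions = c(0.038, 0.214, 0.748),
      csa_mean = c(922, 933, 1644), csa_sd = c(217, 99, 189),
      fi_mean = NA_real_, fi_sd = 0.09,
      a0_mean = 0.35, a0_sd = 0.10,
      # collateral flow only: an order of magnitude below control
      flow = list(rest = c(mean = 0.81, peak = 2.70, amp = 2.52),
                  stim = c(mean = 1.17, peak = 3.45, amp = 3.14),
                  sd   = c(mean = 0.16, peak = 0.68, amp = 0.70)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(258, 16), edl_mg_per_g = c(0.57, 0.05),
      hypertrophy = c(1.00, 0.05), dose = 0
    ),
    acute_MS = list(
      cd = 665, cf = 1.47, p_default = 564 / 617,
      fractions = c(0.038, 0.214, 0.748),
      csa_mean = c(922, 933, 1644), csa_sd = c(217, 99, 189),
      fi_mean = 0.47, fi_sd = 0.09,
      a0_mean = 0.35, a0_sd = 0.10,
      flow = list(rest = c(mean = 8.13, peak = 27.00, amp = 25.22),
                  stim = c(mean = 11.70, peak = 34.46, amp = 31.40),
                  sd   = c(mean = 1.62, peak = 6.79, amp = 7.00)),
      map = c(rest = 123, stim = 119), map_sd = c(10, 15),
      pp = c(rest = 12.2, stim = 13.0), pp_sd = c(8.2, 8.4),
      body_mass = c(258, 16), edl_mg_per_g = c(0.57, 0.05),
      hypertrophy = c(1.02, 0.09), dose = c(100000, 1400000)
    )
  )
}

#' Generator configuration
#'
#' Assembles the full parameter set driving the synthetic-data module. Most
#' defaults come from a per-group calibration preset (control, chronic
#' microsphere, overload with/without microspheres, femoral ligation, and an
#' acute microsphere group used for dose sweeps); any field can be overridden.
#'
#' @param group_preset One of `"control"`, `"chronic_MS"`, `"OV_MS"`, `"OV"`,
#'   `"ligation"`, `"acute_MS"`.
#' @param section_width,section_height Section extent in micrometres.
#' @param target_capillary_density Anatomical capillary density target,
#'   capillaries per mm^2.
#' @param target_cf_ratio Capillary-to-fibre ratio target.
#' @param fibre_type_fractions Length-3 proportions for type I / IIa /
#'   IIb-IIx fibres; must sum to 1 within 1e-9.
#' @param fibre_csa_means,fibre_csa_sds Type-specific fibre cross-sectional
#'   area means and SDs, um^2.
#' @param supply_unit_mean_size Mean capillaries per terminal-arteriole supply
#'   unit (truncated-Poisson mean; minimum unit size is
#'   `supply_unit_min_size`).
#' @param supply_unit_min_size Minimum unit size (default 2).
#' @param perfusion_index Baseline proportion of capillaries flagged perfused
#'   at generation time (preset default is the group's perfused/anatomical
#'   capillary-density ratio).
#' @param tension_noise_sd Additive tension trace noise, N.
#' @param flow_noise_sd Additive flow trace noise, ml min^-1 g^-1.
#' @param fi_sd Between-animal fatigue-index SD.
#' @param heart_rate Cardiac frequency in Hz (default 6 Hz = 360 min^-1).
#' @param sampling_rate Trace sampling rate, Hz.
#' @param fatigue_tau Twitch-amplitude decay time constant, s.
#' @param rest_duration,warmup_duration,fatigue_duration Durations (s) of the
#'   pre-stimulation rest window, the 1 Hz activation phase and the 10 Hz
#'   fatigue test.
#' @param lattice_jitter Fibre-lattice perturbation as a fraction of lattice
#'   spacing.
#' @param min_capillary_sep Minimum capillary separation, um.
#' @param seed Optional default seed recorded in the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(group_preset = "control",
                             section_width = 1600,
                             section_height = 1600,
                             target_capillary_density = NULL,
                             target_cf_ratio = NULL,
                             fibre_type_fractions = NULL,
                             fibre_csa_means = NULL,
                             fibre_csa_sds = NULL,
                             supply_unit_mean_size = 6,
                             supply_unit_min_size = 2,
                             perfusion_index = NULL,
                             tension_noise_sd = 0.002,
                             flow_noise_sd = 0.05,
                             fi_sd = NULL,
                             heart_rate = 6,
                             sampling_rate = 1000,
                             fatigue_tau = 50,
                             rest_duration = 30,
                             warmup_duration = 30,
                             fatigue_duration = 180,
                             lattice_jitter = 0.12,
                             min_capillary_sep = 3,
                             seed = NULL) {
  presets <- group_presets()
  if (!group_preset %in% names(presets)) {
    stop("unknown group preset: '", group_preset, "' (expected one of ",
         paste(names(presets), collapse = ", "), ")")
  }
  pr <- presets[[group_preset]]
  cfg <- list(
    group_preset = group_preset,
    section_width = section_width,
    section_height = section_height,
    target_capillary_density = target_capillary_density %||% pr$cd,
    target_cf_ratio = target_cf_ratio %||% pr$cf,
    fibre_type_fractions = fibre_type_fractions %||% pr$fractions,
    fibre_csa_means = fibre_csa_means %||% pr$csa_mean,
    fibre_csa_sds = fibre_csa_sds %||% pr$csa_sd,
    supply_unit_mean_size = supply_unit_mean_size,
    supply_unit_min_size = supply_unit_min_size,
    perfusion_index = perfusion_index %||% pr$p_default,
    tension_noise_sd = tension_noise_sd,
    flow_noise_sd = flow_noise_sd,
    fi_sd = fi_sd %||% pr$fi_sd,
    heart_rate = heart_rate,
    sampling_rate = sampling_rate,
    fatigue_tau = fatigue_tau,
    rest_duration = rest_duration,
    warmup_duration = warmup_duration,
    fatigue_duration = fatigue_duration,
    lattice_jitter = lattice_jitter,
    min_capillary_sep = min_capillary_sep,
    twitch_duration = 0.06,
    preset = pr,
    seed = seed
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  fr <- cfg$fibre_type_fractions
  if (length(fr) != 3L || abs(sum(fr) - 1) > 1e-9 || any(fr < 0)) {
    stop("fibre_type_fractions must be 3 non-negative proportions summing to 1")
  }
  pos <- c(cfg$section_width, cfg$section_height, cfg$target_cf_ratio,
           cfg$fibre_csa_means, cfg$supply_unit_mean_size,
           cfg$heart_rate, cfg$sampling_rate, cfg$fatigue_tau)
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    stop("all geometric and physiological targets must be strictly positive")
  }
  if (cfg$target_capillary_density < 0) {
    stop("target_capillary_density must be non-negative")
  }
  if (cfg$tension_noise_sd < 0 || cfg$flow_noise_sd < 0 || cfg$fi_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  if (cfg$perfusion_index < 0 || cfg$perfusion_index > 1) {
    stop("perfusion_index must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> preset:", x$group_preset, "\n")
  cat(sprintf("  section %g x %g um; CD target %g mm^-2; C:F %g\n",
              x$section_width, x$section_height,
              x$target_capillary_density, x$target_cf_ratio))
  cat(sprintf("  fibre fractions I/IIa/IIb-IIx: %s\n",
              paste(signif(x$fibre_type_fractions, 3), collapse = "/")))
  invisible(x)
}

# Poisson conditioned on >= min
rtpois <- function(n, mean, min) {
  out <- integer(0)
  while (length(out) < n) {
    d <- rpois(max(n, 16L), mean)
    out <- c(out, d[d >= min])
  }
  out[seq_len(n)]
}

#' Relative fatigue-index linkage
#'
#' Monotone (Fritsch-Carlson) interpolation mapping the capillary perfusion
#' index p to the relative fatigue index. Anchors encode: rarefaction of up to
#' ~10% is tolerated without functional deficit (relFI = 1 for p >= 0.9); the
#' chronic microsphere condition (p ~ 0.755) shows relFI ~ 0.77; and severe
#' rarefaction floors at relFI = 0.3 (the ligation limit, where collateral
#' perfusion keeps ~30% of capillaries open).
#'
#' @param p Perfusion index in `[0, 1]` (vectorised).
#' @param anchors Two-column matrix (p, relFI) of non-decreasing anchor
#'   points; override to change the linkage shape.
#' @return Relative FI values, non-decreasing in `p`.
#' @export
#' @examples
#' rel_fi_linkage(c(0.3, 0.755, 1))
rel_fi_linkage <- function(p, anchors = NULL) {
  if (any(p < -1e-12 | p > 1 + 1e-12, na.rm = TRUE)) {
    stop("perfusion index must lie in [0, 1]")
  }
  a <- anchors %||% cbind(p = c(0, 0.30, 0.755, 0.90, 1),
                          rel_fi = c(0.30, 0.30, 0.77, 1, 1))
  if (is.unsorted(a[, 1L]) || is.unsorted(a[, 2L])) {
    stop("linkage anchors must be non-decreasing in both columns")
  }
  f <- splinefun(a[, 1L], a[, 2L], method = "monoH.FC")
  f(pmin(pmax(p, 0), 1))
}

# ---------------------------------------------------------------------------
# Section generation

#' Generate a synthetic muscle cross-section
#'
#' Builds a typed fibre mosaic from a jitter-perturbed hexagonal lattice
#' tessellation, shrinks each cell about its centroid so realised fibre
#' cross-sectional areas match the type-specific targets, places capillaries
#' at fibre-boundary corners until the density and C:F targets are met, and
#' clusters capillaries into spatially contiguous terminal-arteriole supply
#' units by nearest-neighbour accretion (truncated-Poisson sizes).
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   sections.
#' @return An object of class `capillary_section` with components `fibres`
#'   (list of vertex matrices), `fibre_meta` (type, CSA, centroid),
#'   `capillaries` (x, y, perfused, unit_id) and `bounds`.
#' @export
generate_section <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(derive_seed(seed, 101L))
  W <- config$section_width
  H <- config$section_height
  area_mm2 <- W * H / 1e6
  cd <- config$target_capillary_density
  cf <- config$target_cf_ratio
  fibre_density <- cd / cf          # mm^-2; capillary-free sections keep the
  if (cd == 0) fibre_density <- 450 # control fibre packing
  cell_area <- 1e6 / fibre_density  # um^2 per mosaic cell

  mean_csa <- sum(config$fibre_type_fractions * config$fibre_csa_means)
  if (mean_csa > 0.99 * cell_area) {
    stop("infeasible targets: mean fibre CSA ", round(mean_csa),
         " um^2 cannot fit the mosaic cell area ", round(cell_area),
         " um^2 implied by capillary density and C:F ratio")
  }

  # perturbed hexagonal lattice with margin so border cells are well formed
  h <- sqrt(2 * cell_area / sqrt(3))
  margin <- 2 * h
  xs <- seq(-margin, W + margin, by = h)
  ys <- seq(-margin, H + margin, by = h * sqrt(3) / 2)
  gx <- rep(xs, times = length(ys)) +
    rep(ifelse(seq_along(ys) %% 2 == 0, h / 2, 0), each = length(xs))
  gy <- rep(ys, each = length(xs))
  gx <- gx + rnorm(length(gx), 0, config$lattice_jitter * h)
  gy <- gy + rnorm(length(gy), 0, config$lattice_jitter * h)

  near <- gx > -1.2 * h & gx < W + 1.2 * h & gy > -1.2 * h & gy < H + 1.2 * h
  gx <- gx[near]; gy <- gy[near]
  inside <- which(gx >= -0.6 * h & gx <= W + 0.6 * h &
                  gy >= -0.6 * h & gy <= H + 0.6 * h)
  cells <- voronoi_cells(gx, gy, c(0, W), c(0, H), which = inside)
  # drop boundary slivers too small to hold a fibre profile
  keep <- vapply(cells, function(p) {
    nrow(p) >= 3L && poly_area(p) >= 0.35 * cell_area
  }, TRUE)
  cells <- cells[keep]
  nf <- length(cells)

  type_idx <- sample.int(3L, nf, replace = TRUE,
                         prob = config$fibre_type_fractions)
  csa_target <- rnorm(nf, config$fibre_csa_means[type_idx],
                      config$fibre_csa_sds[type_idx])
  csa_target <- pmax(csa_target, 0.3 * config$fibre_csa_means[type_idx])
  # rank-match CSA draws to mosaic cell areas so that large fibres land in
  # large cells; keeps realised type means on target even at dense packing.
  # Matching is stratified into boundary-clipped vs interior cells so small
  # fibre types do not pile up along the section edge.
  areas0 <- vapply(cells, poly_area, 0)
  on_edge <- vapply(cells, function(p) {
    any(p[, 1L] < 1e-6 | p[, 1L] > W - 1e-6 |
        p[, 2L] < 1e-6 | p[, 2L] > H - 1e-6)
  }, TRUE)
  for (stratum in list(which(on_edge), which(!on_edge))) {
    if (length(stratum) < 2L) next
    rk <- order(order(areas0[stratum]))
    ord_t <- stratum[order(csa_target[stratum])]
    type_idx[stratum] <- type_idx[ord_t][rk]
    csa_target[stratum] <- csa_target[ord_t][rk]
  }

  fibres <- vector("list", nf)
  csa_real <- numeric(nf)
  cx <- numeric(nf); cy <- numeric(nf)
  for (i in seq_len(nf)) {
    poly <- cells[[i]]
    a0 <- areas0[i]
    cen <- poly_centroid(poly)
    s <- sqrt(min(csa_target[i], 0.99 * a0) / a0)
    shr <- sweep(sweep(poly, 2L, cen) * s, 2L, cen, `+`)
    fibres[[i]] <- shr
    csa_real[i] <- poly_area(shr)
    cx[i] <- cen[1L]; cy[i] <- cen[2L]
  }

  fibre_meta <- data.frame(id = seq_len(nf), type = FIBRE_TYPES[type_idx],
                           csa = csa_real, cx = cx, cy = cy,
                           stringsAsFactors = FALSE)

  n_target <- round(cd * area_mm2)
  if (n_target == 0) {
    caps <- data.frame(x = numeric(0), y = numeric(0),
                       perfused = logical(0), unit_id = integer(0))
  } else {
    sites <- do.call(rbind, fibres)
    sites <- sites + matrix(rnorm(length(sites), 0, 0.4), ncol = 2L)
    ok <- sites[, 1L] >= 0.5 & sites[, 1L] <= W - 0.5 &
          sites[, 2L] >= 0.5 & sites[, 2L] <= H - 0.5
    sites <- sites[ok, , drop = FALSE]
    pick <- thin_min_sep(sites, config$min_capillary_sep, n_target,
                         W = W, H = H)
    if (nrow(pick) < ceiling(0.95 * n_target)) {
      stop("infeasible targets: only ", nrow(pick), " capillary sites of ",
           n_target, " requested can be placed at min separation ",
           config$min_capillary_sep, " um; lower the density target or the ",
           "separation")
    }
    perf <- runif(nrow(pick)) < config$perfusion_index
    unit <- assign_supply_units(pick[, 1L], pick[, 2L],
                                config$supply_unit_mean_size,
                                config$supply_unit_min_size)
    caps <- data.frame(x = pick[, 1L], y = pick[, 2L],
                       perfused = perf, unit_id = unit)
  }

  structure(list(fibres = fibres, fibre_meta = fibre_meta,
                 capillaries = caps,
                 bounds = c(xmin = 0, ymin = 0, xmax = W, ymax = H),
                 config = config, seed = seed),
            class = "capillary_section")
}

# Greedy random thinning to a minimum separation using a bucket grid,
# stratified over ~200 um blocks so the realised capillary density is
# spatially uniform (the candidate-site pool is denser along the section
# boundary, where the mosaic cells are clipped).
thin_min_sep <- function(sites, min_sep, n_target, W, H, block = 200) {
  n <- nrow(sites)
  cellw <- max(min_sep, 1e-6)
  ix <- floor(sites[, 1L] / cellw)
  iy <- floor(sites[, 2L] / cellw)
  key <- paste(ix, iy)
  grid <- new.env(hash = TRUE, parent = emptyenv())
  sep2 <- min_sep^2
  admissible <- function(i) {
    for (dx in -1:1) {
      for (dy in -1:1) {
        occ <- grid[[paste(ix[i] + dx, iy[i] + dy)]]
        if (!is.null(occ)) {
          d2 <- (sites[occ, 1L] - sites[i, 1L])^2 +
                (sites[occ, 2L] - sites[i, 2L])^2
          if (any(d2 < sep2)) return(FALSE)
        }
      }
    }
    TRUE
  }
  kept <- integer(0)
  used <- logical(n)
  nbx <- max(1L, round(W / block))
  nby <- max(1L, round(H / block))
  bid <- pmin(floor(sites[, 1L] / (W / nbx)), nbx - 1L) * nby +
         pmin(floor(sites[, 2L] / (H / nby)), nby - 1L) + 1L
  nb <- nbx * nby
  quota <- rep(n_target %/% nb, nb)
  extra <- sample.int(nb, n_target %% nb)
  quota[extra] <- quota[extra] + 1L
  for (b in sample.int(nb)) {
    cand <- which(bid == b)
    for (i in cand[sample.int(length(cand))]) {
      if (quota[b] == 0L) break
      used[i] <- TRUE
      if (admissible(i)) {
        kept <- c(kept, i)
        grid[[key[i]]] <- c(grid[[key[i]]], i)
        quota[b] <- quota[b] - 1L
      }
    }
  }
  if (length(kept) < n_target) {      # fill shortfall from any free site
    for (i in sample(which(!used))) {
      if (length(kept) == n_target) break
      if (admissible(i)) {
        kept <- c(kept, i)
        grid[[key[i]]] <- c(grid[[key[i]]], i)
      }
    }
  }
  sites[kept, , drop = FALSE]
}

# Contiguous supply units grown by nearest-neighbour accretion.
assign_supply_units <- function(x, y, mean_size, min_size) {
  n <- length(x)
  unit <- integer(n)
  unassigned <- rep(TRUE, n)
  next_id <- 0L
  while (any(unassigned)) {
    next_id <- next_id + 1L
    size <- min(rtpois(1L, mean_size, min_size), sum(unassigned))
    idx <- which(unassigned)
    s <- idx[sample.int(length(idx), 1L)]
    unit[s] <- next_id
    unassigned[s] <- FALSE
    dmin <- (x - x[s])^2 + (y - y[s])^2
    for (k in seq_len(size - 1L)) {
      if (!any(unassigned)) break
      cand <- which(unassigned)
      j <- cand[which.min(dmin[cand])]
      unit[j] <- next_id
      unassigned[j] <- FALSE
      dj <- (x - x[j])^2 + (y - y[j])^2
      dmin <- pmin(dmin, dj)
    }
  }
  # a trailing unit can end up below the minimum size: merge it into the
  # unit of its nearest capillary
  sizes <- table(unit)
  small <- as.integer(names(sizes)[sizes < min_size])
  for (u in small) {
    mem <- which(unit == u)
    other <- which(!(unit %in% small))
    if (!length(other)) break
    d2 <- outer(mem, other, function(a, b) (x[a] - x[b])^2 + (y[a] - y[b])^2)
    unit[mem] <- unit[other[which.min(apply(d2, 2L, min))]]
  }
  unit
}

#' @export
print.capillary_section <- function(x, ...) {
  cat("<capillary_section>", nrow(x$fibre_meta), "fibres,",
      nrow(x$capillaries), "capillaries (",
      sum(x$capillaries$perfused), "perfused ),",
      length(unique(x$capillaries$unit_id)), "supply units\n")
  cat(sprintf("  bounds: %g x %g um; preset: %s\n",
              x$bounds["xmax"], x$bounds["ymax"], x$config$group_preset))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Physiology recording generation

# mean of the systolic pulse shape ((1+cos(phi))/2)^k over one cycle
pulse_shape_mean <- function(k) {
  phi <- seq(0, 2 * pi, length.out = 2049L)[-2049L]
  vapply(k, function(kk) mean(((1 + cos(phi)) / 2)^kk), 0)
}

# inverse of pulse_shape_mean, built once
pulse_k_fun <- local({
  kk <- exp(seq(log(0.05), log(60), length.out = 160L))
  mw <- pulse_shape_mean(kk)
  f <- splinefun(rev(mw), rev(kk), method = "monoH.FC")
  lo <- min(mw); hi <- max(mw)
  function(m) f(pmin(pmax(m, lo), hi))
})

#' Generate a synthetic physiology recording
#'
#' Produces tension, femoral-flow and arterial-pressure traces on a common
#' time base for one limb: a rest window, 30 s of 1 Hz twitches, then a 180 s
#' fatigue test at 10 Hz. Twitch amplitude decays as
#' `A(t) = A_end + (A0 - A_end) exp(-t / tau)` with the end/start ratio set so
#' that the downstream 5-twitch fatigue index equals the group FI scaled by
#' the perfusion-FI linkage at `perfusion_index`. Flow is pulsatile (systolic
#' pulse shape matched to the preset mean/peak/amplitude), pressure carries
#' the preset MAP and pulse pressure.
#'
#' @param config A [generator_config()].
#' @param perfusion_index Proportion of capillaries perfused, in `[0, 1]`.
#' @param seed Integer seed.
#' @param fi_baseline Optional unimpaired (fully perfused) FI for this
#'   animal; when supplied, the target FI is `fi_baseline * relFI(p)` with no
#'   further between-animal noise, so paired pre/post recordings of one limb
#'   share their baseline.
#' @return An object of class `physiology_recording`.
#' @export
generate_recording <- function(config, perfusion_index = NULL, seed = 1L,
                               fi_baseline = NULL) {
  stopifnot(inherits(config, "generator_config"))
  p <- perfusion_index %||% config$perfusion_index
  if (p < 0 || p > 1) stop("perfusion_index must lie in [0, 1]")
  set.seed(derive_seed(seed, 202L))
  pr <- config$preset
  fs <- config$sampling_rate
  dt <- 1 / fs
  t_rest <- config$rest_duration
  t_warm <- config$warmup_duration
  t_fat <- config$fatigue_duration
  total <- t_rest + t_warm + t_fat
  tt <- seq(0, total - dt, by = dt)
  n <- length(tt)
  fat_on <- t_rest + t_warm

  # --- per-animal draws -----------------------------------------------------
  # group FI scaled through the linkage, referenced to the preset's own p so
  # that the preset mean reproduces the printed group FI
  base_rel <- rel_fi_linkage(pr$p_default)
  fi_target <- if (!is.null(fi_baseline)) {
    fi_baseline * rel_fi_linkage(p)
  } else {
    fi_mean <- if (is.na(pr$fi_mean)) 0.47 * rel_fi_linkage(p) else
      pr$fi_mean / base_rel * rel_fi_linkage(p)
    rnorm(1L, fi_mean, config$fi_sd)
  }
  fi_target <- min(max(fi_target, 0.06), 1)
  a0 <- max(rnorm(1L, pr$a0_mean, pr$a0_sd), 0.05)
  mb <- max(rnorm(1L, pr$body_mass[1L], pr$body_mass[2L]), 150)
  mass <- max(rnorm(1L, pr$edl_mg_per_g[1L], pr$edl_mg_per_g[2L]), 0.3) *
    mb / 1000

  z <- rnorm(1L)
  fl_rest <- pr$flow$rest + pr$flow$sd * z
  fl_stim <- pr$flow$stim + pr$flow$sd * z
  fix_flow <- function(f) {
    f["mean"] <- max(f["mean"], 0.3)
    f["peak"] <- max(f["peak"], 1.35 * f["mean"])
    f["amp"] <- min(max(f["amp"], 0.2 * f["mean"]),
                    f["peak"] - 0.05 * f["mean"])
    f
  }
  fl_rest <- fix_flow(fl_rest)
  fl_stim <- fix_flow(fl_stim)
  map_rest <- max(rnorm(1L, pr$map[1L], pr$map_sd[1L]), 70)
  map_stim <- max(rnorm(1L, pr$map[2L], pr$map_sd[2L]), 70)
  pp_rest <- min(max(rnorm(1L, pr$pp[1L], pr$pp_sd[1L]), 3), 0.5 * map_rest)
  pp_stim <- min(max(rnorm(1L, pr$pp[2L], pr$pp_sd[2L]), 3), 0.5 * map_stim)

  # --- tension --------------------------------------------------------------
  tau <- config$fatigue_tau
  twd <- config$twitch_duration
  t_f <- seq(0, t_fat - 0.1, by = 0.1)
  e <- exp(-t_f / tau)
  m_pk <- mean(e[1:5])
  m_end <- mean(tail(e, 5L))
  a_frac <- (fi_target * m_pk - m_end) /
    (1 - m_end - fi_target * (1 - m_pk))
  a_frac <- min(max(a_frac, 0), 1)
  amp_f <- a0 * (a_frac + (1 - a_frac) * e)

  tension <- numeric(n)
  in_warm <- tt >= t_rest & tt < fat_on
  off_w <- (tt[in_warm] - t_rest) %% 1
  tension[in_warm] <- a0 * sin(pi * pmin(off_w, twd) / twd) * (off_w <= twd)
  in_fat <- tt >= fat_on & tt < fat_on + t_fat
  off_f <- (tt[in_fat] - fat_on) %% 0.1
  idx_f <- pmin(floor((tt[in_fat] - fat_on) / 0.1) + 1L, length(amp_f))
  tension[in_fat] <- amp_f[idx_f] * sin(pi * pmin(off_f, twd) / twd) *
    (off_f <= twd)
  if (config$tension_noise_sd > 0) {
    tension <- pmax(tension + rnorm(n, 0, config$tension_noise_sd), 0)
  }

  # --- flow (absolute ml min^-1 = per-gram preset values * EDL mass) -------
  hr <- config$heart_rate
  cyc_len <- 1 / hr
  cyc_idx <- floor(tt / cyc_len)
  cyc_t <- cyc_idx * cyc_len
  u <- ifelse(cyc_t < fat_on, 0, 1 - exp(-(cyc_t - fat_on) / 45))
  m_g <- fl_rest["mean"] + (fl_stim["mean"] - fl_rest["mean"]) * u
  pk_g <- fl_rest["peak"] + (fl_stim["peak"] - fl_rest["peak"]) * u
  am_g <- fl_rest["amp"] + (fl_stim["amp"] - fl_rest["amp"]) * u
  mw <- (m_g - (pk_g - am_g)) / am_g
  kshape <- pulse_k_fun(mw)
  phi <- 2 * pi * (tt - cyc_t) / cyc_len
  w <- ((1 + cos(phi)) / 2)^kshape
  flow_g <- (pk_g - am_g) + am_g * w
  if (config$flow_noise_sd > 0) {
    flow_g <- flow_g + rnorm(n, 0, config$flow_noise_sd)
  }
  flow <- pmax(flow_g, 0.01) * mass

  # --- pressure -------------------------------------------------------------
  map_t <- map_rest + (map_stim - map_rest) * u
  pp_t <- pp_rest + (pp_stim - pp_rest) * u
  pressure <- map_t + pp_t / 2 * sin(phi)

  structure(list(
    time = tt, tension = tension, flow = flow, pressure = pressure,
    fs = fs,
    stim = data.frame(
      phase = c("rest", "warmup", "fatigue"),
      onset = c(0, t_rest, fat_on),
      duration = c(t_rest, t_warm, t_fat),
      rate_hz = c(0, 1, 10), stringsAsFactors = FALSE),
    muscle_mass = mass, limb = "ipsilateral",
    meta = list(group = config$group_preset, perfusion_index = p,
                fi_target = fi_target, a0 = a0, tau = tau, a_frac = a_frac,
                heart_rate = hr,
                flow_rest = fl_rest, flow_stim = fl_stim,
                map = c(rest = map_rest, stim = map_stim),
                pulse_pressure = c(rest = pp_rest, stim = pp_stim),
                seed = seed)),
    class = "physiology_recording")
}

#' @export
print.physiology_recording <- function(x, ...) {
  cat("<physiology_recording>", x$meta$group, "preset,",
      sprintf("%.0f s at %g Hz,", max(x$time) + 1 / x$fs, x$fs),
      sprintf("EDL mass %.3f g, perfusion index %.3f\n",
              x$muscle_mass, x$meta$perfusion_index))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cohorts

#' Generate a cohort of synthetic animals
#'
#' Applies the per-group presets: chronic microsphere animals carry the fixed
#' 700,000-sphere dose and reduced perfused capillarity; overload groups the
#' 1.19 mass-hypertrophy ratio and elevated capillarity; acute microsphere
#' animals draw doses uniformly within the published 100,000-1,400,000 range
#' and their perfusion index from the flow-weighted occlusion model.
#'
#' @param n_per_group Animals per group (>= 1).
#' @param seed Integer seed.
#' @param groups Character vector of presets to include.
#' @param with_recordings If `TRUE`, full pre/post physiology recordings are
#'   attached per animal (heavier); otherwise only their seeds are stored.
#' @return An object of class `cohort_dataset` whose `animals` data frame has
#'   one row per animal (group, dose, masses, perfusion index, seeds, and
#'   NA placeholders for derived metrics).
#' @export
generate_cohort <- function(n_per_group, seed = 1L,
                            groups = c("control", "chronic_MS", "OV_MS",
                                       "OV", "ligation"),
                            with_recordings = FALSE) {
  stopifnot(n_per_group >= 1)
  presets <- group_presets()
  bad <- setdiff(groups, names(presets))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  rows <- list()
  recordings <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    pr <- presets[[g]]
    for (j in seq_len(n_per_group)) {
      aseed <- derive_seed(seed, gi, j)
      set.seed(aseed)
      id <- sprintf("%s_%02d", g, j)
      mb <- max(rnorm(1L, pr$body_mass[1L], pr$body_mass[2L]), 150)
      edl_contra <- max(rnorm(1L, pr$edl_mg_per_g[1L],
                              pr$edl_mg_per_g[2L]), 0.3) * mb / 1000
      hyp <- max(rnorm(1L, pr$hypertrophy[1L], pr$hypertrophy[2L]), 0.8)
      edl_ipsi <- edl_contra * hyp
      if (length(pr$dose) == 2L) {
        dose <- round(runif(1L, pr$dose[1L], pr$dose[2L]))
        p <- simulated_expected_perfusion(dose, seed = derive_seed(aseed, 7L))
      } else {
        dose <- pr$dose
        p <- if (g == "ligation") runif(1L, 0.24, 0.30) else pr$p_default
      }
      rows[[length(rows) + 1L]] <- data.frame(
        animal = id, group = g, dose_spheres = dose,
        dose_per_g = dose / edl_ipsi,
        body_mass_g = mb, edl_mass_g = edl_ipsi,
        edl_mass_contra_g = edl_contra, hypertrophy = hyp,
        perfusion_index = p,
        section_seed = derive_seed(aseed, 1L),
        recording_seed = derive_seed(aseed, 2L),
        fi = NA_real_, rel_fi = NA_real_,
        fvc_rest = NA_real_, fvc_stim = NA_real_,
        hyperaemic_scope = NA_real_,
        stringsAsFactors = FALSE)
      if (with_recordings) {
        cfg <- generator_config(group_preset = g)
        recordings[[id]] <- list(
          pre = generate_recording(cfg, perfusion_index = pr$p_default,
                                   seed = derive_seed(aseed, 3L)),
          post = generate_recording(cfg, perfusion_index = p,
                                    seed = derive_seed(aseed, 4L)))
      }
    }
  }
  animals <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(animals$animal), all(animals$dose_spheres >= 0,
                                                na.rm = TRUE))
  structure(list(animals = animals, groups = groups, seed = seed,
                 recordings = if (with_recordings) recordings else NULL),
            class = "cohort_dataset")
}

# Expected perfused capillary fraction for a dose applied to the default
# control section geometry: units sampled from the truncated-Poisson size
# distribution, spheres lodging flow-weighted. Used for lightweight cohort
# perfusion draws; the per-section simulation lives in apply_microsphere_dose.
simulated_expected_perfusion <- function(n_spheres, f_edl = 2.0e-4,
                                         n_caps = 1700, mean_size = 6,
                                         min_size = 2, seed = 1L) {
  set.seed(seed)
  sizes <- integer(0)
  while (sum(sizes) < n_caps) {
    sizes <- c(sizes, rtpois(64L, mean_size, min_size))
  }
  sizes <- sizes[cumsum(sizes) <= n_caps + mean_size]
  S <- sum(sizes)
  surv <- (1 - f_edl * sizes / S)^n_spheres
  sum(sizes * surv) / S
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset>", nrow(x$animals), "animals in",
      length(x$groups), "groups:", paste(x$groups, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a cohort from a known quadratic perfusion-FI linkage
#'
#' Lightweight generator for linkage-recovery studies: per-animal perfusion
#' indices are drawn uniformly and relative FI follows the supplied quadratic
#' with additive Gaussian noise.
#'
#' @param n Number of animals.
#' @param coefs Quadratic coefficients `c(c0, c1, c2)` of
#'   `relFI = c0 + c1 p + c2 p^2`.
#' @param noise_sd Additive noise SD (default 0.05).
#' @param seed Integer seed.
#' @param p_range Range of perfusion indices sampled.
#' @return Data frame with columns `perfusion_index`, `rel_fi`.
#' @export
generate_linkage_cohort <- function(n, coefs = c(-0.1, 0.5, 0.6),
                                    noise_sd = 0.05, seed = 1L,
                                    p_range = c(0.3, 1)) {
  stopifnot(length(coefs) == 3L, noise_sd >= 0)
  set.seed(derive_seed(seed, 303L))
  p <- runif(n, p_range[1L], p_range[2L])
  rel <- coefs[1L] + coefs[2L] * p + coefs[3L] * p^2 +
    rnorm(n, 0, noise_sd)
  data.frame(perfusion_index = p, rel_fi = rel)
}
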