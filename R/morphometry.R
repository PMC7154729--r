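# Capillary-domain morphometry within unbiased counting frames: Voronoi
# capillary domains clipped to the frame, capillarity indices, spacing
# heterogeneity (logSD) and the capillary perfusion index.

#' Construct a counting frame
#'
#' @param origin Numeric length-2, bottom-left corner in um.
#' @param side Frame side length, um (default 475).
#' @return Object of class `counting_frame`. Exclusion edges are left and
#'   bottom, inclusion edges right and top (Gundersen convention).
#' @export
counting_frame <- function(origin, side = 475) {
  stopifnot(length(origin) == 2L, side > 0)
  structure(list(origin = as.numeric(origin), side = side,
                 exclusion = c("left", "bottom"),
                 inclusion = c("right", "top")),
            class = "counting_frame")
}

frame_xlim <- function(frame) frame$origin[1L] + c(0, frame$side)
frame_ylim <- function(frame) frame$origin[2L] + c(0, frame$side)

#' Place counting frames by systematic random sampling
#'
#' Frames are spaced equidistantly along the medial-lateral (x) axis with one
#' random common offset, the standard systematic-random design for unbiased
#' sampling of a muscle cross-section.
#'
#' @param section A `capillary_section`.
#' @param n Number of frames (default 3).
#' @param side Frame side length, um (default 475).
#' @param seed Integer seed for the common offset.
#' @return List of [counting_frame()] objects.
#' @export
place_counting_frames <- function(section, n = 3, side = 475, seed = 1L) {
  W <- unname(section$bounds["xmax"] - section$bounds["xmin"])
  H <- unname(section$bounds["ymax"] - section$bounds["ymin"])
  if (n * side > W + 1e-9 || side > H + 1e-9) {
    stop("section too small: ", n, " frames of side ", side,
         " um do not fit a ", W, " x ", H, " um section")
  }
  set.seed(derive_seed(seed, 404L))
  spacing <- W / n
  offset <- runif(1L, 0, max(spacing - side, 0))
  y0 <- section$bounds["ymin"] + (H - side) / 2
  lapply(seq_len(n) - 1L, function(i) {
    counting_frame(c(section$bounds["xmin"] + offset + i * spacing, y0), side)
  })
}

# Unbiased counting rule for points: exclusion edges (left, bottom) exclude,
# inclusion edges (right, top) include.
frame_includes <- function(x, y, frame) {
  xl <- frame_xlim(frame); yl <- frame_ylim(frame)
  x > xl[1L] & x <= xl[2L] & y > yl[1L] & y <= yl[2L]
}

#' Compute capillary domains within a counting frame
#'
#' Partitions the frame into nearest-capillary (Euclidean Voronoi) domains of
#' the capillaries admitted by the unbiased counting rule: capillaries on the
#' two exclusion edges (left, bottom) are excluded, those on the inclusion
#' edges (right, top) included. Domain polygons are clipped to the frame, so
#' their areas sum to the frame area.
#'
#' @param capillaries Data frame with columns `x`, `y` (um) and optionally
#'   `perfused`; or a `capillary_section`.
#' @param frame A [counting_frame()].
#' @return Object of class `domain_set`: data frame `domains` (x, y, area,
#'   eq_radius, perfused), list `polygons`, and the frame.
#' @export
compute_domains <- function(capillaries, frame) {
  if (inherits(capillaries, "capillary_section")) {
    capillaries <- capillaries$capillaries
  }
  stopifnot(all(c("x", "y") %in% names(capillaries)))
  if (is.null(capillaries$perfused)) capillaries$perfused <- TRUE
  inc <- frame_includes(capillaries$x, capillaries$y, frame)
  caps <- capillaries[inc, , drop = FALSE]
  if (nrow(caps) == 0L) {
    stop("no capillaries inside the counting frame after the edge rule; ",
         "domains are undefined for an empty frame")
  }
  polys <- voronoi_cells(caps$x, caps$y, frame_xlim(frame), frame_ylim(frame))
  areas <- vapply(polys, poly_area, 0)
  structure(list(
    domains = data.frame(x = caps$x, y = caps$y, area = areas,
                         eq_radius = sqrt(areas / pi),
                         perfused = caps$perfused),
    polygons = polys, frame = frame),
    class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat("<domain_set>", nrow(x$domains), "domains; mean area",
      round(mean(x$domains$area), 1), "um^2\n")
  invisible(x)
}

# logSD convention: SD of log10 of equivalent domain radii.
log_sd <- function(eq_radius, base = 10, on = c("radius", "area")) {
  on <- match.arg(on)
  v <- if (on == "radius") eq_radius else pi * eq_radius^2
  if (length(v) < 2L) return(0)
  sd(log(v, base = base))
}

#' Summarise capillarity within a counting frame
#'
#' Computes anatomical and perfused capillary density (CD), capillary-to-fibre
#' ratio (C:F), mean capillary domain area (CDA), spacing heterogeneity
#' (logSD: SD of log10 equivalent domain radii), the capillary perfusion
#' index, and fibre-type composition. Perfused-domain statistics are obtained
#' by re-tessellating the frame from the perfused subset alone.
#'
#' @param section A `capillary_section` (capillaries and fibres), or a
#'   `domain_set` plus `fibres`.
#' @param frame A [counting_frame()].
#' @param fibres Optional fibre metadata data frame (columns `type`, `csa`,
#'   `cx`, `cy`) when `section` is a `domain_set`.
#' @return Object of class `morphometry_summary` (a list of named scalars and
#'   small tables; see fields in the source).
#' @export
summarize_morphometry <- function(section, frame, fibres = NULL) {
  if (inherits(section, "capillary_section")) {
    dom <- compute_domains(section$capillaries, frame)
    fibres <- section$fibre_meta
  } else if (inherits(section, "domain_set")) {
    dom <- section
  } else {
    stop("section must be a capillary_section or a domain_set")
  }
  d <- dom$domains
  frame <- dom$frame
  frame_area_mm2 <- (frame$side / 1000)^2
  n_anat <- nrow(d)
  n_perf <- sum(d$perfused)

  # fibre counting: representative (centroid) point rule on the same frame
  if (is.null(fibres) || nrow(fibres) == 0L) {
    stop("no fibres supplied: capillary-to-fibre ratio is undefined")
  }
  fin <- frame_includes(fibres$cx, fibres$cy, frame)
  n_fib <- sum(fin)
  if (n_fib == 0L) {
    stop("no fibres counted in frame: capillary-to-fibre ratio is undefined")
  }
  ftab <- table(factor(fibres$type[fin], levels = FIBRE_TYPES))
  fpct <- 100 * as.numeric(ftab) / n_fib
  fcsa <- vapply(FIBRE_TYPES, function(tp) {
    v <- fibres$csa[fin & fibres$type == tp]
    if (length(v)) mean(v) else NA_real_
  }, 0)

  perf_stats <- if (n_perf >= 1L) {
    pd <- compute_domains(d[d$perfused, c("x", "y")], frame)
    list(cda = mean(pd$domains$area), logsd = log_sd(pd$domains$eq_radius))
  } else {
    list(cda = NA_real_, logsd = NA_real_)
  }

  structure(list(
    cd_anatomical = n_anat / frame_area_mm2,
    cd_perfused = n_perf / frame_area_mm2,
    cf_anatomical = n_anat / n_fib,
    cf_perfused = n_perf / n_fib,
    cda_anatomical = mean(d$area),
    cda_perfused = perf_stats$cda,
    logsd_anatomical = log_sd(d$eq_radius),
    logsd_perfused = perf_stats$logsd,
    perfusion_index = n_perf / n_anat,
    perfusion_ratio = if (n_anat > n_perf) n_perf / (n_anat - n_perf)
                      else Inf,
    n_capillaries = n_anat,
    n_fibres = n_fib,
    fibre_type_pct = setNames(fpct, FIBRE_TYPES),
    fcsa_mean = fcsa,
    frame = frame),
    class = "morphometry_summary")
}

#' @export
print.morphometry_summary <- function(x, ...) {
  cat("<morphometry_summary>\n")
  cat(sprintf("  CD (anat/perf): %.0f / %.0f mm^-2;  C:F: %.2f / %.2f\n",
              x$cd_anatomical, x$cd_perfused,
              x$cf_anatomical, x$cf_perfused))
  cat(sprintf("  CDA (anat/perf): %.0f / %.0f um^2;  logSD: %.3f / %.3f\n",
              x$cda_anatomical, x$cda_perfused,
              x$logsd_anatomical, x$logsd_perfused))
  cat(sprintf("  perfusion index: %.3f;  fibres: %d (IIb/IIx %.1f%%)\n",
              x$perfusion_index, x$n_fibres, x$fibre_type_pct["IIb/IIx"]))
  invisible(x)
}

#' Bin a capillary-domain area distribution
#'
#' Half-open 200 um^2 bins `(k w, (k+1) w]`, reported as the percentage of
#' all domains analysed (the conventional presentation of domain-area
#' histograms).
#'
#' @param domains A `domain_set` or numeric vector of domain areas (um^2).
#' @param bin_width Bin width in um^2 (default 200).
#' @return Data frame with columns `bin` (label, e.g. "201-400"), `lower`,
#'   `upper`, `count`, `percent`; percentages sum to 100.
#' @export
bin_domain_distribution <- function(domains, bin_width = 200) {
  stopifnot(bin_width > 0)
  areas <- if (inherits(domains, "domain_set")) domains$domains$area
           else as.numeric(domains)
  if (length(areas) == 0L) {
    return(data.frame(bin = character(0), lower = numeric(0),
                      upper = numeric(0), count = integer(0),
                      percent = numeric(0)))
  }
  k <- pmax(ceiling(areas / bin_width), 1L)
  tab <- table(k)
  kk <- as.integer(names(tab))
  data.frame(
    bin = sprintf("%d-%d", (kk - 1L) * bin_width + 1L, kk * bin_width),
    lower = (kk - 1L) * bin_width,
    upper = kk * bin_width,
    count = as.integer(tab),
    percent = 100 * as.integer(tab) / length(areas))
}
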