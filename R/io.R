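# Readers/writers for the package's file formats. Units are fixed at file
# level (um, N, ml min^-1, mmHg) and declared in headers; coordinates are
# continuous with the origin at the bottom-left. All writes are atomic
# (temp file + rename).

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

write_json_atomic <- function(x, path) {
  atomic_write(path, function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  })
}

#' Write a capillary section to disk
#'
#' Capillaries go to `capillaries.csv` (columns x_um, y_um, perfused in
#' {0,1}, unit_id), fibres to `fibres.geojson` (Polygon features with `type`
#' and `csa_um2` properties), and bounds/preset to `section.json`.
#'
#' @param section A `capillary_section`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  caps <- section$capillaries
  df <- data.frame(x_um = caps$x, y_um = caps$y,
                   perfused = as.integer(caps$perfused),
                   unit_id = caps$unit_id)
  atomic_write(file.path(dir, "capillaries.csv"), function(p) {
    write.csv(df, p, row.names = FALSE)
  })
  feats <- lapply(seq_along(section$fibres), function(i) {
    ring <- section$fibres[[i]]
    ring <- rbind(ring, ring[1L, ])          # closed GeoJSON ring
    list(type = "Feature",
         properties = list(id = i,
                           type = section$fibre_meta$type[i],
                           csa_um2 = section$fibre_meta$csa[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(r) ring[r, ]))))
  })
  write_json_atomic(list(type = "FeatureCollection",
                         crs_units = "um", features = feats),
                    file.path(dir, "fibres.geojson"))
  write_json_atomic(list(bounds = as.list(section$bounds),
                         group_preset = section$config$group_preset,
                         seed = section$seed, units = "um"),
                    file.path(dir, "section.json"))
  invisible(dir)
}

#' Read a capillary section written by [write_section()]
#'
#' @param dir Directory containing `capillaries.csv`, `fibres.geojson`,
#'   `section.json`.
#' @param on_open_polygon `"repair"` (close the ring, default) or
#'   `"reject"` (error) for fibre polygons whose first and last vertices
#'   differ.
#' @return A `capillary_section` (config reduced to the stored preset).
#' @export
read_section <- function(dir, on_open_polygon = c("repair", "reject")) {
  on_open_polygon <- match.arg(on_open_polygon)
  capf <- file.path(dir, "capillaries.csv")
  df <- read.csv(capf)
  need <- c("x_um", "y_um", "perfused", "unit_id")
  if (!all(need %in% names(df))) {
    stop("malformed ", capf, ": expected columns ",
         paste(need, collapse = ", "))
  }
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad)) {
    stop("malformed coordinate in ", capf, " at data line ",
         bad[1L], " (row ", bad[1L] + 1L, " of file)")
  }
  gj <- jsonlite::read_json(file.path(dir, "fibres.geojson"))
  fibres <- list()
  meta <- list()
  for (i in seq_along(gj$features)) {
    ft <- gj$features[[i]]
    ring <- do.call(rbind, lapply(ft$geometry$coordinates[[1L]],
                                  function(v) unlist(v)))
    closed <- all(abs(ring[1L, ] - ring[nrow(ring), ]) < 1e-9)
    if (!closed) {
      if (on_open_polygon == "reject") {
        stop("fibre polygon ", i, " is not closed (first and last vertices ",
             "differ); rerun with on_open_polygon = 'repair' to close it")
      }
    } else {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    fibres[[i]] <- unname(ring)
    cen <- poly_centroid(ring)
    meta[[i]] <- data.frame(id = i,
                            type = ft$properties$type %||% NA_character_,
                            csa = ft$properties$csa_um2 %||% poly_area(ring),
                            cx = cen[1L], cy = cen[2L],
                            stringsAsFactors = FALSE)
  }
  sj <- jsonlite::read_json(file.path(dir, "section.json"))
  bounds <- unlist(sj$bounds)
  structure(list(
    fibres = fibres,
    fibre_meta = if (length(meta)) do.call(rbind, meta) else
      data.frame(id = integer(0), type = character(0), csa = numeric(0),
                 cx = numeric(0), cy = numeric(0)),
    capillaries = data.frame(x = df$x_um, y = df$y_um,
                             perfused = df$perfused == 1L,
                             unit_id = df$unit_id),
    bounds = bounds[c("xmin", "ymin", "xmax", "ymax")],
    config = generator_config(group_preset = sj$group_preset %||% "control"),
    seed = sj$seed %||% NA_integer_), class = "capillary_section")
}

#' Write a physiology recording as CSV
#'
#' One row per sample (time_s, tension_N, flow_ml_min, pressure_mmHg); the
#' first line is a `#caprare-recording` comment holding the metadata
#' (sampling rate, muscle mass, stimulation timeline) as JSON.
#'
#' @param rec A `physiology_recording`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_recording <- function(rec, path) {
  hdr <- jsonlite::toJSON(list(fs = rec$fs, muscle_mass = rec$muscle_mass,
                               limb = rec$limb, stim = rec$stim,
                               meta = rec$meta[c("group", "perfusion_index",
                                                 "heart_rate")]),
                          auto_unbox = TRUE, digits = NA)
  atomic_write(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste0("#caprare-recording ", hdr), con)
    write.csv(data.frame(time_s = rec$time, tension_N = rec$tension,
                         flow_ml_min = rec$flow,
                         pressure_mmHg = rec$pressure),
              con, row.names = FALSE)
  })
  invisible(path)
}

#' Read a recording written by [write_recording()]
#' @param path CSV path.
#' @return A `physiology_recording`.
#' @export
read_recording <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#caprare-recording ")) {
    stop("not a caprare recording file: ", path)
  }
  hdr <- jsonlite::fromJSON(sub("^#caprare-recording ", "", first))
  df <- read.csv(path, comment.char = "#")
  bad <- which(!is.finite(df$time_s) | !is.finite(df$tension_N) |
               !is.finite(df$flow_ml_min) | !is.finite(df$pressure_mmHg))
  if (length(bad)) {
    stop("malformed sample in ", path, " at data line ", bad[1L])
  }
  structure(list(time = df$time_s, tension = df$tension_N,
                 flow = df$flow_ml_min, pressure = df$pressure_mmHg,
                 fs = hdr$fs, stim = as.data.frame(hdr$stim),
                 muscle_mass = hdr$muscle_mass, limb = hdr$limb,
                 meta = as.list(hdr$meta)), class = "physiology_recording")
}

#' Export a PO2 field as float TIFF
#'
#' Values are stored scaled to `[0, 1]` by `P_cap` (declared, with the grid
#' spacing, in a JSON sidecar `<path>.json`).
#' @param field A `po2_field`.
#' @param path Output TIFF path.
#' @return The path, invisibly.
#' @export
write_po2_tiff <- function(field, path) {
  m <- t(field$po2[, ncol(field$po2):1])   # row-major, top row = max y
  m <- pmin(pmax(m / field$params$P_cap, 0), 1)
  atomic_write(path, function(p) {
    tiff::writeTIFF(m, p, bits.per.sample = 32L)
  })
  write_json_atomic(list(scale_mmHg = field$params$P_cap,
                         um_per_px = field$h, row_order = "top_to_bottom"),
                    paste0(path, ".json"))
  invisible(path)
}

#' Read and validate a pipeline configuration (YAML)
#'
#' @param path YAML config path.
#' @return Validated config list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  schema <- list(
    seed = "integer", n_per_group = "integer", groups = "character",
    section = c("width", "height", "frames"),
    recordings = c("enabled"),
    oxygen = c("enabled", "frame_side", "grid_um", "demands"),
    stats = c("enabled"),
    exclusions = c("animals"))
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown)) {
    stop("unknown config key: '", unknown[1L], "'")
  }
  for (blk in c("section", "recordings", "oxygen", "stats", "exclusions")) {
    if (!is.null(cfg[[blk]])) {
      bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
      if (length(bad)) {
        stop("unknown config key: '", blk, ".", bad[1L], "'")
      }
    }
  }
  if (is.null(cfg$n_per_group) || cfg$n_per_group < 1) {
    stop("config must set n_per_group >= 1")
  }
  cfg$groups <- cfg$groups %||% c("control", "chronic_MS", "OV_MS", "OV",
                                  "ligation")
  cfg$seed <- cfg$seed %||% 1L
  cfg
}
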