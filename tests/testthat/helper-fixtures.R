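# Fixtures built in code: hand-assembled sections and recordings with known
# structure, used as oracles for the simulation modules.

# A section with n_units supply units of exactly unit_size capillaries each,
# laid out on a grid; units are contiguous row-blocks.
make_unit_section <- function(n_units, unit_size, side = 1000) {
  n <- n_units * unit_size
  ncol <- ceiling(sqrt(n))
  i <- seq_len(n) - 1L
  gx <- (i %% ncol + 0.5) * side / ncol
  gy <- (i %/% ncol + 0.5) * side / ncol
  caps <- data.frame(x = gx, y = gy, perfused = TRUE,
                     unit_id = rep(seq_len(n_units), each = unit_size))
  structure(list(
    fibres = list(),
    fibre_meta = data.frame(id = integer(0), type = character(0),
                            csa = numeric(0), cx = numeric(0),
                            cy = numeric(0)),
    capillaries = caps,
    bounds = c(xmin = 0, ymin = 0, xmax = side, ymax = side),
    config = generator_config(), seed = 0L), class = "capillary_section")
}

# Recording with half-sine twitches whose amplitudes follow amp_fun(t) during
# the 10 Hz fatigue phase (t measured from fatigue onset), constant flow and
# pressure. No noise.
make_twitch_recording <- function(amp_fun, flow = 1.2, pressure = 100,
                                  mass = 0.15, fs = 1000,
                                  rest = 30, warm = 30, fat = 180) {
  dt <- 1 / fs
  tt <- seq(0, rest + warm + fat - dt, by = dt)
  twd <- 0.06
  tension <- numeric(length(tt))
  in_warm <- tt >= rest & tt < rest + warm
  offw <- (tt[in_warm] - rest) %% 1
  tension[in_warm] <- amp_fun(0) * sin(pi * pmin(offw, twd) / twd) *
    (offw <= twd)
  in_fat <- tt >= rest + warm
  offf <- (tt[in_fat] - rest - warm) %% 0.1
  tfat <- floor((tt[in_fat] - rest - warm) / 0.1) * 0.1
  tension[in_fat] <- amp_fun(tfat) * sin(pi * pmin(offf, twd) / twd) *
    (offf <= twd)
  structure(list(
    time = tt, tension = tension,
    flow = rep(flow, length(tt)), pressure = rep(pressure, length(tt)),
    fs = fs,
    stim = data.frame(phase = c("rest", "warmup", "fatigue"),
                      onset = c(0, rest, rest + warm),
                      duration = c(rest, warm, fat),
                      rate_hz = c(0, 1, 10), stringsAsFactors = FALSE),
    muscle_mass = mass, limb = "ipsilateral",
    meta = list(heart_rate = 5)), class = "physiology_recording")
}

# minimum distance from a point to any edge of any fibre polygon
min_dist_to_fibre_edge <- function(px, py, fibres) {
  best <- Inf
  for (poly in fibres) {
    n <- nrow(poly)
    j <- c(2:n, 1L)
    ax <- poly[, 1L]; ay <- poly[, 2L]
    bx <- poly[j, 1L]; by <- poly[j, 2L]
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(pmax(((px - ax) * vx + (py - ay) * vy) /
                      pmax(vx^2 + vy^2, 1e-12), 0), 1)
    d2 <- (ax + tt * vx - px)^2 + (ay + tt * vy - py)^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}
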