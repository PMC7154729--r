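# Physiological endpoints from tension / flow / pressure traces: fatigue
# index, relative FI, vascular conductance metrics and hyperaemic scope.

phase_row <- function(rec, phase) {
  r <- rec$stim[rec$stim$phase == phase, ]
  if (nrow(r) != 1L) stop("recording has no '", phase, "' stimulation phase")
  r
}

# cycle-based twitch amplitudes at the known stimulation times:
# amplitude = in-cycle peak minus the quiet-tail baseline of the same cycle
twitch_amplitudes <- function(rec, phase = "fatigue") {
  ph <- phase_row(rec, phase)
  cyc <- 1 / ph$rate_hz
  onsets <- seq(ph$onset, ph$onset + ph$duration - cyc / 2, by = cyc)
  idx0 <- round(onsets * rec$fs) + 1L
  ncyc <- round(cyc * rec$fs)
  tail_from <- round(0.8 * ncyc)
  vapply(idx0, function(i0) {
    seg <- rec$tension[i0:min(i0 + ncyc - 1L, length(rec$tension))]
    max(seg) - mean(seg[tail_from:length(seg)])
  }, 0)
}

#' Fatigue index of a twitch-tension trace
#'
#' FI = mean amplitude of the final five consecutive twitches of the 10 Hz
#' fatigue test divided by the mean amplitude of the five consecutive
#' twitches around the detected peak. The peak is located as the maximum
#' 5-twitch running mean within the first 30 s of the fatigue phase (tension
#' often potentiates before declining); set `peak_window = "first"` to use
#' strictly the first five twitches.
#'
#' @param rec A `physiology_recording`.
#' @param peak_window `"first30s"` (default) or `"first"`.
#' @return Fatigue index (dimensionless); in `(0, 1]` for decaying traces.
#' @export
fatigue_index <- function(rec, peak_window = c("first30s", "first")) {
  peak_window <- match.arg(peak_window)
  amps <- twitch_amplitudes(rec, "fatigue")
  if (length(amps) < 10L) {
    stop("fewer than 10 twitches detected in the fatigue phase")
  }
  noise <- mad(diff(rec$tension[seq_len(round(
    phase_row(rec, "rest")$duration * rec$fs))]), na.rm = TRUE)
  if (median(amps) < 5 * max(noise, 1e-12)) {
    stop("twitches not detectable above trace noise (median amplitude ",
         signif(median(amps), 3), " N, noise scale ", signif(noise, 3),
         " N)")
  }
  run5 <- stats::filter(amps, rep(1 / 5, 5L), sides = 1L)
  run5 <- as.numeric(run5)[-(1:4)]          # mean of twitches (i-4):i
  n_in_30s <- min(length(run5), round(30 * phase_row(rec, "fatigue")$rate_hz))
  peak <- if (peak_window == "first") run5[1L] else max(run5[seq_len(n_in_30s)])
  end <- mean(tail(amps, 5L))
  end / peak
}

#' Relative fatigue index
#'
#' Ratio of post-intervention to pre-intervention FI (1 = no change, < 1 =
#' impairment). The literal reading of "ratio of pre- to post-" is available
#' with `direction = "pre_over_post"`.
#'
#' @param pre,post Fatigue indices in `(0, 1]`.
#' @param direction `"post_over_pre"` (default) or `"pre_over_post"`.
#' @return The ratio.
#' @export
relative_fi <- function(pre, post,
                        direction = c("post_over_pre", "pre_over_post")) {
  direction <- match.arg(direction)
  if (any(pre <= 0) || any(pre > 1) || any(post <= 0) || any(post > 1)) {
    stop("fatigue indices must lie in (0, 1]")
  }
  if (direction == "post_over_pre") post / pre else pre / post
}

window_indices <- function(rec, window = c("rest", "end_stim"),
                           width = 10) {
  window <- match.arg(window)
  if (window == "rest") {
    r <- phase_row(rec, "rest")
    to <- r$onset + r$duration
  } else {
    r <- phase_row(rec, "fatigue")
    to <- r$onset + r$duration
  }
  from <- to - width
  if (from < min(rec$time) - 1e-9) stop("analysis window outside the trace")
  which(rec$time >= from - 1e-9 & rec$time < to - 1e-9)
}

estimate_heart_rate <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))[2:floor(n / 2)]
  fr <- (seq_along(sp)) * fs / n
  band <- fr >= 2 & fr <= 15          # physiologic cardiac range
  fr[band][which.max(sp[band])]
}

#' Vascular metrics over an analysis window
#'
#' Mean flow, peak systolic flow (mean of per-cardiac-cycle maxima), flow
#' amplitude (mean of per-cycle max - min), MAP, pulse pressure, and femoral
#' vascular conductance FVC = mean flow / MAP, all normalised to muscle mass
#' where labelled per gram.
#'
#' @param rec A `physiology_recording`.
#' @param window `"rest"` (last 10 s before the 1 Hz phase) or `"end_stim"`
#'   (last 10 s of the 10 Hz phase).
#' @param muscle_mass Mass in g (default: the recording's).
#' @param heart_rate Cardiac frequency in Hz; default the recording's
#'   metadata, estimated spectrally if absent.
#' @return List of metrics: `mean_flow`, `peak_flow`, `flow_amplitude`
#'   (ml min^-1 g^-1), `map`, `pulse_pressure` (mmHg), `fvc`
#'   (ml min^-1 mmHg^-1 g^-1).
#' @export
vascular_metrics <- function(rec, window = c("rest", "end_stim"),
                             muscle_mass = NULL, heart_rate = NULL) {
  window <- match.arg(window)
  mass <- muscle_mass %||% rec$muscle_mass
  if (is.null(mass) || mass <= 0) stop("muscle mass must be positive")
  idx <- window_indices(rec, window)
  fl <- rec$flow[idx]
  pr <- rec$pressure[idx]
  hr <- heart_rate %||% rec$meta$heart_rate %||%
    estimate_heart_rate(fl, rec$fs)
  ncyc_len <- round(rec$fs / hr)
  ncyc <- floor(length(idx) / ncyc_len)
  cyc_of <- rep(seq_len(ncyc), each = ncyc_len)[seq_along(idx)]
  cyc_of[is.na(cyc_of)] <- ncyc
  cmax <- tapply(fl, cyc_of, max)
  cmin <- tapply(fl, cyc_of, min)
  pmx <- tapply(pr, cyc_of, max)
  pmn <- tapply(pr, cyc_of, min)
  map <- mean(pr)
  list(mean_flow = mean(fl) / mass,
       peak_flow = mean(cmax) / mass,
       flow_amplitude = mean(cmax - cmin) / mass,
       map = map,
       pulse_pressure = mean(pmx - pmn),
       fvc = mean(fl) / map / mass,
       window = window, mass = mass, heart_rate = hr)
}

#' Hyperaemic scope
#'
#' End-stimulation FVC divided by resting FVC; values above 1 indicate
#' functional hyperaemia.
#'
#' @param rest_fvc,stim_fvc Conductances (same units).
#' @return The ratio.
#' @export
hyperaemic_scope <- function(rest_fvc, stim_fvc) {
  if (any(rest_fvc <= 0)) stop("resting FVC must be positive")
  stim_fvc / rest_fvc
}

#' Full metrics summary for one recording
#'
#' @param rec A `physiology_recording`.
#' @param pre_fi Optional pre-intervention FI for relative FI.
#' @return Object of class `metrics_summary`.
#' @export
analyze_recording <- function(rec, pre_fi = NULL) {
  fi <- fatigue_index(rec)
  vr <- vascular_metrics(rec, "rest")
  vs <- vascular_metrics(rec, "end_stim")
  amps <- twitch_amplitudes(rec, "fatigue")
  structure(list(
    fi = fi,
    rel_fi = if (!is.null(pre_fi)) relative_fi(pre_fi, fi) else NA_real_,
    max_twitch_tension = max(amps),
    max_twitch_tension_per_g = max(amps) / rec$muscle_mass,
    rest = vr, end_stim = vs,
    hyperaemic_scope = hyperaemic_scope(vr$fvc, vs$fvc),
    muscle_mass = rec$muscle_mass), class = "metrics_summary")
}

#' @export
print.metrics_summary <- function(x, ...) {
  cat("<metrics_summary>\n")
  cat(sprintf("  FI %.3f (relative %.3f); max twitch %.3f N (%.2f N/g)\n",
              x$fi, x$rel_fi, x$max_twitch_tension,
              x$max_twitch_tension_per_g))
  cat(sprintf("  FVC rest %.4f, end-stim %.4f ml/min/mmHg/g; scope %.3f\n",
              x$rest$fvc, x$end_stim$fvc, x$hyperaemic_scope))
  invisible(x)
}
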