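# End-to-end pipeline: generate -> occlude -> morphometry -> oxygen ->
# metrics -> stats, with a reproducibility manifest.

stage_error <- function(stage, e, out_dir) {
  writeLines(paste0("stage ", stage, " failed: ", conditionMessage(e)),
             file.path(out_dir, "INCOMPLETE"))
  stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
}

#' Run the full analysis pipeline from a config file
#'
#' Executes, per animal: section generation, group-specific occlusion
#' (microsphere dose or ligation), counting-frame morphometry, pre/post
#' physiology recordings and their metrics; then an optional oxygen-transport
#' stage (one animal per group) and the statistics stage (group ANOVA on FI,
#' perfusion-FI linkage fit). Emits per-stage CSV/JSON and a run manifest
#' with file hashes; outputs are deterministic for a fixed config.
#'
#' @param config_path Path to a YAML configuration (see [read_config()]).
#' @param out_dir Output directory (created; pre-existing files overwritten).
#' @param seed Optional seed overriding the config's.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config_path, out_dir, seed = NULL) {
  cfg <- read_config(config_path)
  if (!is.null(seed)) cfg$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out_dir, "INCOMPLETE"))
  sec_w <- cfg$section$width %||% 1600
  sec_h <- cfg$section$height %||% 1600
  n_frames <- cfg$section$frames %||% 3
  rec_on <- cfg$recordings$enabled %||% TRUE
  oxy_on <- cfg$oxygen$enabled %||% FALSE

  cohort <- tryCatch(
    generate_cohort(cfg$n_per_group, seed = cfg$seed, groups = cfg$groups),
    error = function(e) stage_error("generate", e, out_dir))
  an <- cohort$animals

  morpho_rows <- list()
  metric_rows <- list()
  oxy_rows <- list()
  oxy_done <- character(0)

  for (i in seq_len(nrow(an))) {
    a <- an[i, ]
    gcfg <- generator_config(group_preset = a$group,
                             section_width = sec_w, section_height = sec_h)
    sec <- tryCatch(generate_section(gcfg, a$section_seed),
                    error = function(e) stage_error("generate", e, out_dir))
    occ <- tryCatch({
      if (a$group == "ligation") {
        apply_ligation(sec, seed = derive_seed(a$section_seed, 9L))
      } else if (a$dose_spheres > 0) {
        apply_microsphere_dose(sec, dose_spec(a$dose_spheres,
                                              seed = derive_seed(
                                                a$section_seed, 9L)))
      } else NULL
    }, error = function(e) stage_error("rarefy", e, out_dir))
    if (!is.null(occ)) {
      sec <- occ$section
      an$perfusion_index[i] <- occ$perfusion_index
    } else {
      an$perfusion_index[i] <- mean(sec$capillaries$perfused)
    }

    frames <- tryCatch(
      place_counting_frames(sec, n = n_frames,
                            side = min(475, sec_w / n_frames, sec_h),
                            seed = derive_seed(a$section_seed, 10L)),
      error = function(e) stage_error("morphometry", e, out_dir))
    for (fi in seq_along(frames)) {
      ms <- tryCatch(summarize_morphometry(sec, frames[[fi]]),
                     error = function(e) stage_error("morphometry", e,
                                                     out_dir))
      morpho_rows[[length(morpho_rows) + 1L]] <- data.frame(
        animal = a$animal, group = a$group, frame = fi,
        cd_anatomical = ms$cd_anatomical, cd_perfused = ms$cd_perfused,
        cf_anatomical = ms$cf_anatomical, cda_anatomical = ms$cda_anatomical,
        cda_perfused = ms$cda_perfused,
        logsd_anatomical = ms$logsd_anatomical,
        perfusion_index = ms$perfusion_index,
        pct_IIb_IIx = ms$fibre_type_pct[["IIb/IIx"]])
    }

    if (rec_on) {
      gpr <- group_presets()[[a$group]]
      base_rel <- rel_fi_linkage(gpr$p_default)
      fb_mean <- if (is.na(gpr$fi_mean)) 0.47 else gpr$fi_mean / base_rel
      set.seed(derive_seed(a$recording_seed, 0L))
      fb <- min(max(rnorm(1L, fb_mean, gcfg$fi_sd / base_rel), 0.1), 1)
      pre <- tryCatch(
        generate_recording(gcfg, perfusion_index = gpr$p_default,
                           seed = derive_seed(a$recording_seed, 1L),
                           fi_baseline = fb),
        error = function(e) stage_error("metrics", e, out_dir))
      post <- tryCatch(
        generate_recording(gcfg, perfusion_index = an$perfusion_index[i],
                           seed = derive_seed(a$recording_seed, 2L),
                           fi_baseline = fb),
        error = function(e) stage_error("metrics", e, out_dir))
      msum <- tryCatch(analyze_recording(post, pre_fi = fatigue_index(pre)),
                       error = function(e) stage_error("metrics", e,
                                                       out_dir))
      an$fi[i] <- msum$fi
      an$rel_fi[i] <- msum$rel_fi
      an$fvc_rest[i] <- msum$rest$fvc
      an$fvc_stim[i] <- msum$end_stim$fvc
      an$hyperaemic_scope[i] <- msum$hyperaemic_scope
      metric_rows[[length(metric_rows) + 1L]] <- data.frame(
        animal = a$animal, group = a$group, fi = msum$fi,
        rel_fi = msum$rel_fi,
        max_twitch_N = msum$max_twitch_tension,
        mean_flow_rest = msum$rest$mean_flow,
        mean_flow_stim = msum$end_stim$mean_flow,
        fvc_rest = msum$rest$fvc, fvc_stim = msum$end_stim$fvc,
        hyperaemic_scope = msum$hyperaemic_scope)
    }

    if (oxy_on && !(a$group %in% oxy_done)) {
      oxy_done <- c(oxy_done, a$group)
      side <- cfg$oxygen$frame_side %||% 100
      grid <- cfg$oxygen$grid_um %||% 2
      fr <- counting_frame(c((sec_w - side) / 2, (sec_h - side) / 2), side)
      perf <- sec$capillaries[sec$capillaries$perfused, ]
      sweep_df <- tryCatch(
        demand_sweep(perf, fr, transport_params(),
                     demands = cfg$oxygen$demands %||% c("rest", "max"),
                     h = grid),
        error = function(e) stage_error("oxygen", e, out_dir))
      sweep_df$animal <- a$animal
      sweep_df$group <- a$group
      oxy_rows[[length(oxy_rows) + 1L]] <- sweep_df
    }
  }

  write_df <- function(rows, name) {
    if (!length(rows)) return(NULL)
    df <- do.call(rbind, rows)
    atomic_write(file.path(out_dir, name), function(p) {
      write.csv(df, p, row.names = FALSE)
    })
    df
  }
  write_df(morpho_rows, "morphometry.csv")
  write_df(metric_rows, "metrics.csv")
  write_df(oxy_rows, "oxygen.csv")
  atomic_write(file.path(out_dir, "animals.csv"), function(p) {
    write.csv(an, p, row.names = FALSE)
  })

  excl <- cfg$exclusions$animals %||% character(0)
  stats_out <- NULL
  if ((cfg$stats$enabled %||% TRUE) && rec_on) {
    stats_out <- tryCatch({
      keep <- !(an$animal %in% excl) & is.finite(an$fi)
      res <- list(exclusions = excl)
      if (length(unique(an$group[keep])) >= 2L &&
          all(table(an$group[keep]) >= 2L)) {
        cmp <- anova_tukey(an$fi[keep], an$group[keep])
        res$fi_anova <- list(f = cmp$f, p = cmp$p,
                             letters = as.list(cmp$letters))
      }
      rare <- keep & an$perfusion_index < 0.9
      if (sum(rare) >= 5L) {
        lf <- recover_linkage(an[keep, ])
        res$linkage_fit <- list(coefficients = as.list(lf$coefficients),
                                r_squared = lf$r_squared,
                                p_value = lf$p_value)
      }
      res
    }, error = function(e) stage_error("stats", e, out_dir))
    write_json_atomic(stats_out, file.path(out_dir, "stats.json"))
  }

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest <- list(
    package = "caprare",
    version = as.character(packageVersion("caprare")),
    seed = cfg$seed,
    config = cfg,
    exclusions = excl,
    hashes = as.list(setNames(unname(md5sum(files)), basename(files))))
  write_json_atomic(manifest, file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
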