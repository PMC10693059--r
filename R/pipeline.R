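pipeline_schema <- function() {
  list(
    seed = NULL, out_dir = NULL, stages = NULL,
    sleep = c("n_epochs", "epoch_len_s", "fs_hz", "theta_delta_rem",
              "artifact_amp", "range_hi"),
    calcium = c("n_neurites", "frac_overload", "noise", "image_size",
                "n_control"),
    plaque = c("image_size", "n_plaques", "noise", "min_size_px"),
    microglia = c("n_plaques", "n_microglia", "radius_um"),
    flow = c("n_events", "methoxy_pos_frac", "quantile"),
    behavior = c("n_entries", "p_alternate", "duration_s", "n_frames",
                 "step_cm"))
}

validate_config <- function(config) {
  schema <- pipeline_schema()
  unknown_top <- setdiff(names(config), names(schema))
  if (length(unknown_top))
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "))
  for (stage in setdiff(names(schema), c("seed", "out_dir", "stages"))) {
    if (is.null(config[[stage]])) next
    bad <- setdiff(names(config[[stage]]), schema[[stage]])
    if (length(bad))
      stop("unknown key(s) in '", stage, "' block: ",
           paste(bad, collapse = ", "))
  }
  stages <- config$stages %||%
    c("sleep", "calcium", "plaque", "microglia", "flow", "behavior")
  bad <- setdiff(stages, setdiff(names(schema), c("seed", "out_dir", "stages")))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$stages <- stages
  config$seed <- as.integer(config$seed %||% 1L)
  config
}

#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates the analysis stages on generated data with known ground
#' truth, writing one CSV per stage plus a provenance JSON (config hash,
#' package version, seed, per-file checksums) to `out_dir`. The run is a
#' deterministic function of the config: identical configs give
#' byte-identical tables. Config validation happens before any stage runs
#' and unknown keys are rejected.
#'
#' @param config named list, or path to a YAML file. Keys: `seed`,
#'   `out_dir`, `stages` (subset of sleep/calcium/plaque/microglia/flow/
#'   behavior), and per-stage parameter blocks.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return named list of the per-stage result tables (invisibly, also
#'   written to disk).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  config <- validate_config(config)
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  results <- list()
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    results[[name]] <<- df
  }

  for (stage in config$stages) {
    res <- tryCatch(switch(stage,
      sleep = pipeline_sleep(config$sleep %||% list(), seed, emit),
      calcium = pipeline_calcium(config$calcium %||% list(), seed, emit),
      plaque = pipeline_plaque(config$plaque %||% list(), seed, emit),
      microglia = pipeline_microglia(config$microglia %||% list(), seed, emit),
      flow = pipeline_flow(config$flow %||% list(), seed, emit),
      behavior = pipeline_behavior(config$behavior %||% list(), seed, emit)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  cfg_clean <- config
  yaml::write_yaml(cfg_clean, cfg_file)
  prov <- list(
    package = "somnoplaque",
    version = as.character(utils::packageVersion("somnoplaque")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = lapply(stats::setNames(files, basename(files)),
                     function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

pipeline_sleep <- function(p, seed, emit) {
  n_epochs <- p$n_epochs %||% 360L
  sp <- sleep_sim_params(epoch_len_s = p$epoch_len_s %||% 10,
                         fs_hz = p$fs_hz %||% 100, seed = seed)
  truth <- simulate_hypnogram(sp, n_epochs)
  rec <- simulate_polysomnography(truth, sp)
  ep <- epochize(rec, sp$epoch_len_s)
  feats <- compute_features(rec, ep,
                            range = c(0.5, p$range_hi %||% 24),
                            artifact_amp = p$artifact_amp %||% 400)
  thr <- derive_thresholds(feats,
                           theta_delta_rem = p$theta_delta_rem %||% 3)
  hyp <- classify_epochs(feats, thr, epoch_len_s = sp$epoch_len_s)
  emit(data.frame(epoch_index = ep$index, t_start_s = ep$t_start_s,
                  phase = ep$phase, state = hyp$states,
                  true_state = as.character(truth)), "hypnogram")
  emit(architecture_summary(hyp, ep$phase), "architecture")
  spec <- state_psd(rec, hyp, "NREM", ep)
  if (!spec$empty)
    emit(data.frame(freq_hz = spec$freq, relative_power = spec$relative_psd),
         "psd_nrem")
  bands <- sleep_bands()[c("delta", "theta_wide", "alpha", "sigma", "beta",
                           "swa")]
  emit(data.frame(band = names(bands),
                  relative_power = vapply(names(bands), function(b)
                    relative_band_power(spec, bands[[b]]), 0)),
       "band_summary")
  invisible(NULL)
}

pipeline_calcium <- function(p, seed, emit) {
  fp <- fret_sim_params(n_neurites = p$n_neurites %||% 200,
                        frac_overload = p$frac_overload %||% 0.15,
                        noise = p$noise %||% 0.5,
                        image_size = p$image_size %||% 256, seed = seed)
  sim <- simulate_fret_pair(fp)
  meas <- measure_label_ratios(sim$yfp, sim$cfp, sim$labels)
  ctrl_p <- fret_sim_params(n_neurites = p$n_control %||% 200,
                            frac_overload = 0, noise = p$noise %||% 0.5,
                            image_size = p$image_size %||% 256,
                            seed = seed + 1L)
  ctrl <- simulate_fret_pair(ctrl_p)
  ctrl_meas <- measure_label_ratios(ctrl$yfp, ctrl$cfp, ctrl$labels)
  tau <- overload_threshold(ctrl_meas$R)
  calib <- yc36_synthetic_calibration()
  ca <- ratio_to_calcium(meas$R, calib)
  emit(data.frame(neurite_id = meas$neurite_id, R = meas$R,
                  ca_nM = as.numeric(ca),
                  overload = !is.na(meas$R) & meas$R > tau$tau),
       "calcium")
  emit(data.frame(control_mean = tau$control_mean,
                  control_sd = tau$control_sd, tau = tau$tau,
                  overload_pct = overload_fraction(meas$R, tau),
                  true_overload_pct =
                    100 * mean(sim$truth$overload)), "calcium_summary")
  invisible(NULL)
}

pipeline_plaque <- function(p, seed, emit) {
  sim <- simulate_plaque_image(image_size = p$image_size %||% 128,
                               n_plaques = p$n_plaques %||% 5,
                               noise = p$noise %||% 5, seed = seed)
  seg <- segment_plaques(sim$image, min_size_px = p$min_size_px %||% 10)
  s <- plaque_summary(seg)
  s$true_count <- sim$truth$count
  s$true_burden_pct <- sim$truth$burden_pct
  emit(s, "plaque_summary")
  invisible(NULL)
}

pipeline_microglia <- function(p, seed, emit) {
  vp <- volume_sim_params(n_plaques = p$n_plaques %||% 3,
                          n_microglia = p$n_microglia %||% 40,
                          attraction = "exponential", seed = seed)
  sim <- simulate_microglia_volume(vp)
  cl <- distance_to_plaques(sim$soma_points, sim$plaque_mask,
                            vp$voxel_size_um,
                            radius_um = p$radius_um %||% 25)
  emit(as.data.frame(cl), "microglia")
  ac <- associated_count(cl, p$radius_um %||% 25)
  emit(data.frame(n_cells = nrow(cl), n_associated = ac$total,
                  fraction_associated = ac$fraction), "microglia_summary")
  invisible(NULL)
}

pipeline_flow <- function(p, seed, emit) {
  n <- p$n_events %||% 20000
  exp_s <- simulate_flow_sample(n, methoxy_pos_frac =
                                  p$methoxy_pos_frac %||% 0.2, seed = seed)
  ctl_s <- simulate_flow_sample(n, role = "control", seed = seed + 1L)
  tr_exp <- flow_transform(exp_s$events)
  tr_ctl <- flow_transform(ctl_s$events)
  gate_def <- list(cd11b_min = asinh(10^3.2 / 150),
                   cd45_bounds = c(0, asinh(10^3.1 / 150)))
  g_exp <- gate_microglia(tr_exp, gate_def$cd11b_min, gate_def$cd45_bounds)
  g_ctl <- gate_microglia(tr_ctl, gate_def$cd11b_min, gate_def$cd45_bounds)
  thr <- control_threshold(apply_gate(tr_ctl, g_ctl), "Methoxy",
                           p$quantile %||% 0.995)
  gated <- apply_gate(tr_exp, g_exp)
  gated_raw <- apply_gate(exp_s$events, g_exp)
  truth_gated <- exp_s$truth[g_exp$index, ]
  emit(data.frame(
    gated_fraction = g_exp$fraction,
    methoxy_pos_pct = positive_fraction(gated, "Methoxy", thr),
    true_methoxy_pos_pct = 100 * mean(truth_gated$methoxy_pos),
    cd36_mfi = median_intensity(gated_raw, "CD36"),
    cd68_mfi = median_intensity(gated_raw, "CD68"),
    csf1r_mfi = median_intensity(gated_raw, "CSF1R")), "flow_summary")
  invisible(NULL)
}

pipeline_behavior <- function(p, seed, emit) {
  mt <- simulate_motion_trace(duration_s = p$duration_s %||% 100,
                              seed = seed)
  es <- simulate_entry_sequence(n_entries = p$n_entries %||% 30,
                                p_alternate = p$p_alternate %||% 0.7,
                                seed = seed)
  tk <- simulate_track(n_frames = p$n_frames %||% 3000,
                       step_cm = p$step_cm %||% 1, seed = seed)
  ofm <- open_field_metrics(tk)
  emit(data.frame(
    freezing_pct = freezing_percentage(mt$trace, mt$fps, mt$threshold),
    true_freezing_pct = 100 * mt$truth$freeze_fraction,
    alternation_pct = alternation_percentage(es$entries),
    true_alternation_pct = es$truth$alternation_pct,
    distance_cm = ofm$distance_cm,
    true_distance_cm = tk$truth$distance_cm,
    center_pct = ofm$center_pct), "behavior")
  invisible(NULL)
}

#' End-to-end demo on synthetic data
#'
#' Runs every stage of [run_pipeline()] with default parameters.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @return the [run_pipeline()] result list, invisibly.
#' @export
demo_pipeline <- function(out_dir, seed = 1L) {
  run_pipeline(list(seed = seed), out_dir = out_dir)
}
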