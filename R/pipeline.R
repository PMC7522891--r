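#' Default run configuration for the end-to-end pipeline
#'
#' A complete, validated configuration describing a small synthetic
#' experiment: two markers (a chromosomal locus and a cytosolic
#' aggregate), a control plus three treatments whose mobility scales
#' inversely with their crowding change, sampled at two treatment times in
#' three replicates. All values can be overridden from a YAML file via
#' [validate_config()].
#'
#' @return A `run_config` list of documented defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    output_dir = "crowdmsd-run",
    control_condition = "control",
    stages = list(simulate = TRUE, render_and_track = FALSE,
                  msd = TRUE, stats = TRUE, crowding = TRUE),
    experiment = list(
      treatment_times = c(30, 60),
      n_replicates = 3L,
      markers = list(
        Ori2 = list(amplitude = 4.0e-3 / 10^0.4, hurst = 0.2),
        muNS = list(amplitude = 8.0e-2 / 10^0.4, hurst = 0.2)
      ),
      conditions = list(
        control = list(mobility_scale = 1.0, crowding_scale = 1.0),
        ciprofloxacin = list(mobility_scale = 1 / 0.90, crowding_scale = 0.90),
        rifampicin = list(mobility_scale = 1 / 0.95, crowding_scale = 0.95),
        sorbitol = list(mobility_scale = 1 / 1.30, crowding_scale = 1.30)
      )
    ),
    simulation = list(
      n_tracks = 20L, n_frames = 150L, frame_interval = 0.1,
      loc_noise_sigma = 0.02, initial_intensity = 2000, bleach_tau = 50,
      cell_length = 3.0, cell_radius = 0.5, pixel_size = 0.1,
      psf_sigma = 0.13, background = 100
    ),
    tracking = list(
      snr_threshold = 5, max_disp_um = 0.5, max_gap_frames = 1L,
      min_length_frames = 20L, min_mean_intensity = 0
    ),
    msd = list(
      target_lag_s = 10, fit_window = c(0.1, 10), min_pairs = 5L,
      correct_markers = FALSE
    ),
    stats = list(log_base = 10, test = "mann_whitney"),
    crowding = list(
      biomass_per_od_control = 0.45, protein_fraction = 0.55,
      cell_ri = 1.388, medium_ri = 1.335, bsa_ri_increment = 0.185,
      cv = 0.05, n_replicates = 3L, n_technical = 3L, od_nominal = 0.4,
      n_titration = 7L
    )
  )
}

# Recursive merge of user values into defaults, rejecting unknown keys.
# `open` marks paths whose child names are user-defined (the marker and
# condition maps): supplying such a map replaces the default map entirely,
# with each child filled against the schema of the first default entry.
merge_config <- function(defaults, user, path = "",
                         open = c("experiment.markers", "experiment.conditions")) {
  clean <- sub("^\\.", "", path)
  if (!is.list(user)) {
    stop(sprintf("config entry `%s` must be a mapping", clean), call. = FALSE)
  }
  if (is.null(names(user)) && length(user) > 0) {
    stop(sprintf("config entry `%s` must have named keys", clean), call. = FALSE)
  }
  if (clean %in% open) {
    if (length(user) == 0) return(defaults)
    proto <- if (length(defaults) > 0) defaults[[1]] else list()
    out <- lapply(names(user), function(nm) {
      merge_config(proto, user[[nm]], paste0(path, ".", nm), open = character(0))
    })
    names(out) <- names(user)
    return(out)
  }
  out <- defaults
  for (key in names(user)) {
    child_path <- paste0(path, ".", key)
    if (!(key %in% names(defaults))) {
      stop(sprintf("unknown config key `%s`", sub("^\\.", "", child_path)),
           call. = FALSE)
    }
    dval <- defaults[[key]]
    uval <- user[[key]]
    if (is.list(dval) && !is.null(names(dval))) {
      out[[key]] <- merge_config(dval, uval, child_path, open)
    } else {
      out[[key]] <- uval
    }
  }
  out
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a YAML string, or a list; fills documented
#' defaults ([default_run_config()]), rejects unknown keys with
#' path-qualified messages, and checks physical validity (Hurst exponents
#' inside (0,1), positive scales, a control condition present so every
#' treated condition has its counterpart at each treatment time).
#'
#' @param config `NULL` (all defaults), a path to a YAML file, a YAML
#'   string, or a named list of overrides.
#' @return A validated `run_config` list.
#' @export
validate_config <- function(config = NULL) {
  defaults <- default_run_config()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config) && length(config) == 1) {
    parsed <- if (file.exists(config)) yaml::read_yaml(config) else
      yaml::yaml.load(config)
    if (is.null(parsed)) list() else parsed
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be NULL, a YAML path/string, or a list", call. = FALSE)
  }
  cfg <- merge_config(defaults, user)
  if (length(cfg$experiment$markers) == 0) {
    stop("config must define at least one marker under `experiment.markers`",
         call. = FALSE)
  }
  for (nm in names(cfg$experiment$markers)) {
    mk <- cfg$experiment$markers[[nm]]
    assert_scalar_num(mk$amplitude, paste0("experiment.markers.", nm, ".amplitude"),
                      0, strict_lower = TRUE)
    assert_scalar_num(mk$hurst, paste0("experiment.markers.", nm, ".hurst"),
                      0, 1, strict_lower = TRUE, strict_upper = TRUE)
  }
  for (nm in names(cfg$experiment$conditions)) {
    cd <- cfg$experiment$conditions[[nm]]
    assert_scalar_num(cd$mobility_scale, paste0("experiment.conditions.", nm, ".mobility_scale"),
                      0, strict_lower = TRUE)
    assert_scalar_num(cd$crowding_scale, paste0("experiment.conditions.", nm, ".crowding_scale"),
                      0, strict_lower = TRUE)
  }
  if (!(cfg$control_condition %in% names(cfg$experiment$conditions))) {
    stop(sprintf(
      "control condition '%s' missing from `experiment.conditions`: every treated condition needs a control counterpart at each treatment time",
      cfg$control_condition), call. = FALSE)
  }
  if (length(cfg$experiment$treatment_times) < 1 ||
      any(!is.finite(cfg$experiment$treatment_times)) ||
      any(cfg$experiment$treatment_times < 0)) {
    stop("`experiment.treatment_times` must be non-negative numbers", call. = FALSE)
  }
  cfg$experiment$n_replicates <- assert_count(cfg$experiment$n_replicates,
                                              "experiment.n_replicates")
  cfg$seed <- assert_count(cfg$seed, "seed", min = 0L)
  # sim_config() re-validates the physical simulation block
  invisible(do.call(sim_config, c(cfg$simulation, list(seed = cfg$seed))))
  structure(cfg, class = "run_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[crowdmsd] ", fmt), ...))
}

write_csv_out <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full synthetic-experiment pipeline
#'
#' Executes the enabled stages in order -- simulate trajectories (or
#' render movies and re-track them when `stages$render_and_track` is on),
#' per-track MSD analysis, condition statistics with fold changes and
#' cross-marker consistency, and the crowding assays -- writing all
#' interchange CSVs, JSON reports and a manifest to `output_dir`.
#' Rerunning with the same configuration reproduces byte-identical
#' outputs: all randomness derives from the master seed and stable unit
#' labels, and the manifest carries no timestamps.
#'
#' @param config Anything accepted by [validate_config()].
#' @param output_dir Optional override of the configured output directory.
#' @param verbose Emit per-stage progress messages.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = NULL, output_dir = NULL, verbose = TRUE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  counts <- list()
  failed <- function(stage, e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  ex <- cfg$experiment
  units <- expand.grid(marker = names(ex$markers),
                       condition = names(ex$conditions),
                       treatment_time = ex$treatment_times,
                       replicate = seq_len(ex$n_replicates),
                       stringsAsFactors = FALSE)
  units <- units[order(units$marker, units$condition, units$treatment_time,
                       units$replicate), ]

  # ---- simulate (and optionally render + re-track) --------------------
  all_tracks <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    tryCatch({
      pieces <- vector("list", nrow(units))
      for (u in seq_len(nrow(units))) {
        row <- units[u, ]
        mk <- ex$markers[[row$marker]]
        cd <- ex$conditions[[row$condition]]
        scfg <- do.call(sim_config, c(cfg$simulation, list(
          hurst = mk$hurst,
          amplitude = mk$amplitude * cd$mobility_scale,
          seed = cfg$seed)))
        trk <- generate_tracks(scfg, marker = row$marker,
                               condition = row$condition,
                               treatment_time = row$treatment_time,
                               replicate = row$replicate,
                               start = "random")
        if (isTRUE(cfg$stages$render_and_track)) {
          stack <- render_movie(trk, scfg,
                                seed = derive_seed(cfg$seed, "shot", row$marker,
                                                   row$condition,
                                                   row$treatment_time,
                                                   row$replicate))
          trk <- track_movie(stack,
                             psf_sigma_px = scfg$psf_sigma / scfg$pixel_size,
                             snr_threshold = cfg$tracking$snr_threshold,
                             max_disp_um = cfg$tracking$max_disp_um,
                             max_gap_frames = cfg$tracking$max_gap_frames,
                             min_length_frames = cfg$tracking$min_length_frames,
                             min_mean_intensity = cfg$tracking$min_mean_intensity)
          if (nrow(trk) > 0) {
            trk <- data.frame(marker = row$marker, condition = row$condition,
                              treatment_time = row$treatment_time,
                              replicate = row$replicate, trk)
            # re-centre field-of-view coordinates on the cell centre
            trk$x_um <- trk$x_um - stack$fov_um[1] / 2
            trk$y_um <- trk$y_um - stack$fov_um[2] / 2
            trk <- trk[, c("track_id", "marker", "condition", "treatment_time",
                           "replicate", "frame", "time_s", "x_um", "y_um",
                           "intensity", "gap_flag")]
          } else trk <- NULL
        }
        if (!is.null(trk) && nrow(trk) > 0) {
          trk$unit <- paste(row$marker, row$condition, row$treatment_time,
                            row$replicate, sep = "/")
          pieces[[u]] <- trk
        }
      }
      all_tracks <- do.call(rbind, pieces)
      attr(all_tracks, "frame_interval") <- cfg$simulation$frame_interval
      files <- c(files, write_csv_out(all_tracks, out_dir, "tracks.csv"))
      counts$tracks_rows <- nrow(all_tracks)
      counts$n_units <- nrow(units)
      pipeline_log(verbose, "simulate: %d units, %d track rows",
                   nrow(units), nrow(all_tracks))
    }, error = function(e) failed("simulate", e))
  }

  # ---- msd ------------------------------------------------------------
  per_track <- NULL
  if (isTRUE(cfg$stages$msd)) {
    tryCatch({
      if (is.null(all_tracks)) stop("msd stage needs the simulate stage")
      dtv <- cfg$simulation$frame_interval
      curves_rows <- list(); pt_rows <- list(); fit_rows <- list()
      for (unit in unique(all_tracks$unit)) {
        d <- all_tracks[all_tracks$unit == unit, ]
        attr(d, "frame_interval") <- dtv
        tlist <- split_tracks(d)
        curves <- lapply(tlist, time_averaged_msd, min_pairs = cfg$msd$min_pairs)
        if (isTRUE(cfg$msd$correct_markers)) {
          ints <- vapply(tlist, function(tr) mean(tr$intensity, na.rm = TRUE),
                         numeric(1))
          curves <- suppressWarnings(
            correct_marker_effects(curves, ints,
                                   reference_intensity = cfg$simulation$initial_intensity,
                                   fit_window = cfg$msd$fit_window))
        }
        meta <- d[1, c("marker", "condition", "treatment_time", "replicate")]
        for (ti in seq_along(curves)) {
          v <- tryCatch(msd_at_lag(curves[[ti]], cfg$msd$target_lag_s),
                        error = function(e) NA_real_)
          pt_rows[[length(pt_rows) + 1L]] <- data.frame(
            meta, track_id = names(curves)[ti], value = v,
            row.names = NULL)
        }
        ens <- ensemble_msd(d, min_pairs = cfg$msd$min_pairs)
        curves_rows[[length(curves_rows) + 1L]] <- data.frame(
          meta, ens, row.names = NULL)
        ft <- tryCatch(fit_power_law(ens, cfg$msd$fit_window),
                       error = function(e) NULL)
        if (!is.null(ft)) {
          fit_rows[[length(fit_rows) + 1L]] <- data.frame(
            meta, alpha = ft$alpha, amplitude = ft$amplitude,
            r_squared = ft$r_squared, window_lo = ft$lag_window[1],
            window_hi = ft$lag_window[2], row.names = NULL)
        }
      }
      per_track <- do.call(rbind, pt_rows)
      per_track <- per_track[is.finite(per_track$value), ]
      curves_df <- do.call(rbind, curves_rows)
      fits_df <- do.call(rbind, fit_rows)
      files <- c(files,
                 write_csv_out(curves_df, out_dir, "msd_curves.csv"),
                 write_csv_out(fits_df, out_dir, "power_law_fits.csv"),
                 write_csv_out(per_track, out_dir, "msd_at_target_lag.csv"))
      counts$msd_curve_rows <- nrow(curves_df)
      counts$per_track_values <- nrow(per_track)
      pipeline_log(verbose, "msd: %d per-track MSD(%g s) values",
                   nrow(per_track), cfg$msd$target_lag_s)
    }, error = function(e) failed("msd", e))
  }

  # ---- stats ----------------------------------------------------------
  stats_out <- NULL
  if (isTRUE(cfg$stages$stats)) {
    tryCatch({
      if (is.null(per_track)) stop("stats stage needs the msd stage")
      stats_out <- summarize_experiment(per_track,
                                        control = cfg$control_condition,
                                        log_base = cfg$stats$log_base,
                                        lag_s = cfg$msd$target_lag_s)
      files <- c(files,
                 write_csv_out(stats_out$summary, out_dir, "condition_summary.csv"),
                 write_csv_out(stats_out$fold_changes, out_dir, "fold_changes.csv"))
      counts$summary_rows <- nrow(stats_out$summary)
      # cross-marker consistency between the first two markers
      mk <- names(ex$markers)
      if (length(mk) >= 2) {
        fcs <- stats_out$fold_changes
        a <- fcs[fcs$marker == mk[1], ]
        b <- fcs[fcs$marker == mk[2], ]
        key <- function(d) paste(d$condition, d$treatment_time)
        common <- intersect(key(a), key(b))
        if (length(common) >= 3) {
          cons <- cross_marker_consistency(
            a$log_fold_change[match(common, key(a))],
            b$log_fold_change[match(common, key(b))])
          cons$marker_a <- mk[1]; cons$marker_b <- mk[2]
          p <- file.path(out_dir, "cross_marker_consistency.json")
          jsonlite::write_json(cons, p, auto_unbox = TRUE, digits = NA)
          files <- c(files, p)
        }
      }
      pipeline_log(verbose, "stats: %d groups, %d fold changes",
                   nrow(stats_out$summary), nrow(stats_out$fold_changes))
    }, error = function(e) failed("stats", e))
  }

  # ---- crowding -------------------------------------------------------
  if (isTRUE(cfg$stages$crowding)) {
    tryCatch({
      cw <- cfg$crowding
      conds <- lapply(names(ex$conditions), function(nm) {
        list(biomass_per_od = cw$biomass_per_od_control *
               ex$conditions[[nm]]$crowding_scale,
             protein_fraction = cw$protein_fraction,
             cell_ri = cw$cell_ri)
      })
      names(conds) <- names(ex$conditions)
      acfg <- assay_config(conditions = conds, medium_ri = cw$medium_ri,
                           bsa_ri_increment = cw$bsa_ri_increment,
                           cv = cw$cv, n_replicates = cw$n_replicates,
                           n_technical = cw$n_technical,
                           od_nominal = cw$od_nominal,
                           n_titration = cw$n_titration,
                           seed = derive_seed(cfg$seed, "assay"))
      tab <- generate_assay_table(acfg)
      files <- c(files, write_csv_out(tab, out_dir, "assay_table.csv"))
      ctrl_ratio <- biomass_od_ratio(tab, cfg$control_condition)
      ri_rows <- list(); ratio_rows <- list()
      for (nm in names(conds)) {
        br <- biomass_od_ratio(tab, nm)
        pf <- protein_fraction(tab, nm)
        fc <- crowding_fold_change(br, ctrl_ratio)
        titr <- tab[tab$condition == nm & is.finite(tab$bsa_g_per_ml), ]
        ri <- ri_match(titr, medium_ri = cw$medium_ri,
                       bsa_ri_increment = cw$bsa_ri_increment)
        pv <- if (nm == cfg$control_condition) NA_real_ else {
          tr <- replicate_means(tab, nm, "dry_mass_mg_ml") /
            replicate_means(tab, nm, "od600")
          cr <- replicate_means(tab, cfg$control_condition, "dry_mass_mg_ml") /
            replicate_means(tab, cfg$control_condition, "od600")
          compare_to_control(tr, cr, method = "welch_t")
        }
        ratio_rows[[nm]] <- data.frame(
          condition = nm, biomass_per_od = br$value, biomass_per_od_se = br$standard_error,
          protein_fraction = pf$value, protein_fraction_se = pf$standard_error,
          crowding_fold_change = fc$value, crowding_fold_change_se = fc$standard_error,
          crowding_log2_fold_change = fc$log2, p_value_vs_control = pv)
        ri_rows[[nm]] <- data.frame(condition = nm, cell_ri = ri$cell_ri,
                                    c0_g_per_ml = ri$c0_g_per_ml)
      }
      ratios_df <- do.call(rbind, ratio_rows); rownames(ratios_df) <- NULL
      ri_df <- do.call(rbind, ri_rows); rownames(ri_df) <- NULL
      files <- c(files, write_csv_out(ratios_df, out_dir, "crowding_ratios.csv"))
      p <- file.path(out_dir, "ri_estimates.json")
      jsonlite::write_json(ri_df, p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
      files <- c(files, p)
      # correlate with the mobility fold changes at the last treatment time
      if (!is.null(stats_out) && nrow(stats_out$fold_changes) > 0) {
        fcs <- stats_out$fold_changes
        tmax <- max(fcs$treatment_time)
        fcs <- fcs[fcs$treatment_time == tmax, ]
        mfc <- tapply(log2(fcs$treated_mean / fcs$control_mean), fcs$condition, mean)
        treated <- ratios_df[ratios_df$condition != cfg$control_condition, ]
        common <- intersect(names(mfc), treated$condition)
        if (length(common) >= 3) {
          corr <- crowding_mobility_correlation(
            as.numeric(mfc[common]),
            treated$crowding_log2_fold_change[match(common, treated$condition)],
            crowding_scale = "log2")
          corr$treatment_time <- tmax
          p <- file.path(out_dir, "crowding_mobility_correlation.json")
          jsonlite::write_json(corr, p, auto_unbox = TRUE, digits = NA)
          files <- c(files, p)
        }
      }
      counts$crowding_conditions <- nrow(ratios_df)
      pipeline_log(verbose, "crowding: %d conditions assayed", nrow(ratios_df))
    }, error = function(e) failed("crowding", e))
  }

  # ---- manifest -------------------------------------------------------
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "crowdmsd",
    version = as.character(utils::packageVersion("crowdmsd")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(local({
      tf <- tempfile(); writeLines(cfg_json, tf); tf
    }))),
    counts = counts,
    files = lapply(sort(basename(files)), function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(verbose, "done: %d files in %s", length(files) + 1L, out_dir)
  invisible(manifest)
}
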