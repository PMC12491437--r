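# End-to-end driver: a JSON run configuration selects stages (palm, poses,
# bret), each stage simulates its inputs with a child seed derived from the
# global seed, runs the corresponding analysis, and writes its tables; a
# combined JSON report records outputs, the parameter echo and versions.

.default_run_config <- function() {
  list(
    stages = c("palm", "poses", "bret"),
    seed = 1L,
    output_dir = "pipeline_out",
    palm = list(
      sim = list(counts_per_size = list(`1` = 50, `2` = 30, `3` = 15,
                                        `5` = 5),
                 cluster_radius_nm = 10, loc_error_sd_nm = 5,
                 blink_rate = 0, min_center_sep_nm = 300),
      census = list(dedup_radius_nm = 20, search_radius_nm = 50,
                    assignment_mode = "greedy_seed",
                    density_threshold_per_um2 = 100,
                    max_reported_size = 10),
      apply_dedup = FALSE),
    poses = list(
      sim = list(n_poses = 500, tilt_range = c(0, 0.8),
                 zoffset_range = c(-12, 12)),
      filter = list(tilt_max_rad = 0.4, z_offset_max_A = 6.0,
                    keep_best = 4000),
      rmsd_cutoff_A = 3.0),
    bret = list(
      kinetics = list(k_per_s = 0.02, plateau = 0.05, dt_s = 3,
                      t_max_s = 300, noise_sd = 0.002),
      saturation = list(BRETmax = 0.3, BRET50 = 0.05, n_x = 12,
                        x_max = 0.6, noise_sd = 0.01),
      dose_response = list(neg_log_ec50 = 5.362, Emax = 100, baseline = 0,
                           noise_sd = 2))
  )
}

#' Validate a pipeline run configuration
#'
#' Schema-checks every block of a run configuration and returns every
#' violation found (not just the first). A configuration is a named list as
#' read from JSON; see `system.file("extdata", "demo_run.json", package =
#' "gpcrdimer")` for the shipped demo.
#'
#' @param config a configuration list, or a path to a JSON file.
#' @return character vector of error messages; `character(0)` means ok.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file '%s' not readable", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)
  known <- c("palm", "poses", "bret")
  stages <- unlist(config$stages)
  if (is.null(stages) || !length(stages)) note("no stages selected")
  for (s in setdiff(stages, known))
    note(sprintf("unknown stage '%s'", s))
  if (is.null(config$seed) || !is.finite(config$seed) ||
      config$seed != round(config$seed))
    note("seed must be an integer")
  pc <- config$palm$census
  if (!is.null(pc)) {
    if (!is.null(pc$dedup_radius_nm) && !is.null(pc$search_radius_nm) &&
        pc$dedup_radius_nm >= pc$search_radius_nm)
      note("palm.census: dedup_radius_nm must be < search_radius_nm")
    for (f in c("dedup_radius_nm", "search_radius_nm",
                "density_threshold_per_um2"))
      if (!is.null(pc[[f]]) && pc[[f]] <= 0)
        note(sprintf("palm.census: %s must be > 0", f))
    if (!is.null(pc$assignment_mode) &&
        !pc$assignment_mode %in% c("greedy_seed", "single_linkage"))
      note("palm.census: unknown assignment_mode")
  }
  ps <- config$palm$sim
  if (!is.null(ps$counts_per_size) &&
      any(unlist(ps$counts_per_size) < 0))
    note("palm.sim: counts_per_size must be >= 0")
  pf <- config$poses$filter
  for (f in c("tilt_max_rad", "z_offset_max_A", "keep_best"))
    if (!is.null(pf[[f]]) && pf[[f]] <= 0)
      note(sprintf("poses.filter: %s must be > 0", f))
  if (!is.null(config$poses$sim$n_poses) && config$poses$sim$n_poses <= 0)
    note("poses.sim: n_poses must be > 0")
  bk <- config$bret$kinetics
  for (f in c("k_per_s", "plateau"))
    if (!is.null(bk[[f]]) && bk[[f]] < 0)
      note(sprintf("bret.kinetics: %s must be >= 0", f))
  errs
}

# synthetic three-helix probe used by the pose stage when no PDB is given:
# an idealized Calpha bundle spanning the membrane, adequate for RMSD and
# topology geometry (the stage is transform arithmetic, not chemistry)
.demo_probe <- function(n_res_per_helix = 12L) {
  z <- seq(-16, 16, length.out = n_res_per_helix)
  helix <- function(cx, cy, chain_off) {
    data.frame(chain = "A",
               resno = chain_off + seq_len(n_res_per_helix),
               resid = "ALA", atom = "CA", element = "C",
               x = cx + 2 * cos(seq(0, 4 * pi, length.out = n_res_per_helix)),
               y = cy + 2 * sin(seq(0, 4 * pi, length.out = n_res_per_helix)),
               z = z)
  }
  structure_model(rbind(helix(0, 0, 0L), helix(8, 0, 100L),
                        helix(4, 7, 200L)))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in order (`palm`: simulate localizations,
#' optional dedup, census; `poses`: simulate poses, topology filter, RMSD
#' leader clustering; `bret`: simulate kinetics/saturation/dose-response
#' data and fit each), writing every table under `output_dir` and a
#' combined `report.json`. Stage seeds are derived from the global seed via
#' [stage_seed()], so identical config + seed gives byte-identical data
#' outputs. Any stage failure aborts with the stage name and cause and
#' leaves a `FAILED` marker in the output directory.
#'
#' @param config configuration list or path to a JSON file; missing entries
#'   fall back to the built-in demo defaults.
#' @param output_dir overrides `config$output_dir` when non-`NULL`.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  errs <- validate_config(.merge_config(.default_run_config(), config))
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  cfg <- .merge_config(.default_run_config(), config)
  out_dir <- output_dir %||% cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  report <- list(seed = cfg$seed, stages = list(),
                 config_echo = cfg,
                 versions = list(gpcrdimer = as.character(
                   utils::packageVersion("gpcrdimer")),
                   R = R.version.string))
  run_stage <- function(name, fn) {
    message(sprintf("[%s] running (child seed %d)",
                    name, stage_seed(cfg$seed, name)))
    tryCatch(fn(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  stages <- unlist(cfg$stages)
  if ("palm" %in% stages) {
    report$stages$palm <- run_stage("palm", function() {
      p <- cfg$palm
      sim <- simulate_localizations(palm_sim_config(
        counts_per_size = unlist(p$sim$counts_per_size),
        cluster_radius_nm = p$sim$cluster_radius_nm,
        loc_error_sd_nm = p$sim$loc_error_sd_nm,
        blink_rate = p$sim$blink_rate,
        min_center_sep_nm = p$sim$min_center_sep_nm,
        seed = stage_seed(cfg$seed, "palm")))
      ccfg <- census_config(
        dedup_radius_nm = p$census$dedup_radius_nm,
        search_radius_nm = p$census$search_radius_nm,
        assignment_mode = p$census$assignment_mode,
        density_threshold_per_um2 = p$census$density_threshold_per_um2,
        max_reported_size = p$census$max_reported_size)
      map <- sim$map
      if (isTRUE(p$apply_dedup))
        map <- deduplicate(map, ccfg$dedup_radius_nm)
      asg <- assign_complexes(map, ccfg)
      cen <- census(asg, map, ccfg)
      locs <- file.path(out_dir, "localizations.csv")
      write_localizations(sim$map, locs)
      tsv <- file.path(out_dir, "census.tsv")
      js <- file.path(out_dir, "census_summary.json")
      write_census(cen, tsv, js)
      asg_csv <- file.path(out_dir, "assignment.csv")
      utils::write.csv(asg$points, asg_csv, row.names = FALSE, quote = FALSE)
      list(outputs = c(locs, tsv, js, asg_csv),
           total_receptors = cen$total_receptors,
           pct_monomer = cen$pct_monomer,
           density_class = cen$density_class)
    })
  }
  if ("poses" %in% stages) {
    report$stages$poses <- run_stage("poses", function() {
      p <- cfg$poses
      probe <- .demo_probe()
      sim <- simulate_poses(pose_sim_config(
        n_poses = p$sim$n_poses,
        tilt_range = unlist(p$sim$tilt_range),
        zoffset_range = unlist(p$sim$zoffset_range),
        seed = stage_seed(cfg$seed, "poses")),
        probe,
        tilt_max_rad = p$filter$tilt_max_rad,
        z_offset_max_A = p$filter$z_offset_max_A)
      fcfg <- topology_filter_config(p$filter$tilt_max_rad,
                                     p$filter$z_offset_max_A,
                                     p$filter$keep_best)
      kept <- filter_poses(sim$poses, probe, fcfg)
      cl <- cluster_poses(kept, probe, p$rmsd_cutoff_A)
      tab <- cl$assignment
      tab$tilt_rad <- vapply(kept[match(tab$pose_id,
                                        vapply(kept, `[[`, integer(1),
                                               "pose_id"))],
                             `[[`, numeric(1), "tilt_rad")
      tab$z_offset_A <- vapply(kept[match(tab$pose_id,
                                          vapply(kept, `[[`, integer(1),
                                                 "pose_id"))],
                               `[[`, numeric(1), "z_offset_A")
      poses_tsv <- file.path(out_dir, "poses.tsv")
      write_pose_table(sim$poses, poses_tsv)
      filt_tsv <- file.path(out_dir, "filtered_clustered.tsv")
      utils::write.table(tab, filt_tsv, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      list(outputs = c(poses_tsv, filt_tsv),
           n_input = length(sim$poses), n_accepted = length(kept),
           n_clusters = length(cl$clusters))
    })
  }
  if ("bret" %in% stages) {
    report$stages$bret <- run_stage("bret", function() {
      b <- cfg$bret
      sd_b <- stage_seed(cfg$seed, "bret")
      kin_grid <- seq(b$kinetics$dt_s, b$kinetics$t_max_s,
                      by = b$kinetics$dt_s)
      kin <- simulate_bret(bret_sim_config(
        "kinetics", list(k_per_s = b$kinetics$k_per_s,
                         plateau = b$kinetics$plateau),
        kin_grid, b$kinetics$noise_sd, seed = sd_b))
      kfit <- fit_kinetics(data.frame(time_s = kin$x, y = kin$y))
      sat_grid <- seq(b$saturation$x_max / b$saturation$n_x,
                      b$saturation$x_max, length.out = b$saturation$n_x)
      sat <- simulate_bret(bret_sim_config(
        "saturation", list(BRETmax = b$saturation$BRETmax,
                           BRET50 = b$saturation$BRET50),
        sat_grid, b$saturation$noise_sd,
        seed = (sd_b + 1) %% 2147483647))
      sfit <- fit_saturation(sat$x, sat$y)
      dose_grid <- 10^seq(-8, -3, length.out = 9)
      dr <- simulate_bret(bret_sim_config(
        "dose_response",
        list(EC50_M = 10^(-b$dose_response$neg_log_ec50),
             Emax = b$dose_response$Emax,
             baseline = b$dose_response$baseline),
        dose_grid, b$dose_response$noise_sd,
        seed = (sd_b + 2) %% 2147483647))
      dfit <- fit_dose_response(dr$x, dr$y)
      dat_tsv <- file.path(out_dir, "bret_data.tsv")
      utils::write.table(rbind(kin, sat, dr), dat_tsv, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      fits <- list(
        kinetics = kfit[c("k_per_s", "plateau", "halftime_s",
                          "initial_rate", "converged")],
        saturation = sfit[c("BRETmax", "BRET50", "converged")],
        dose_response = dfit[c("neg_log_ec50", "Emax", "baseline",
                               "converged")])
      fit_json <- file.path(out_dir, "bret_fits.json")
      jsonlite::write_json(fits, fit_json, auto_unbox = TRUE, digits = NA)
      list(outputs = c(dat_tsv, fit_json), fits = fits)
    })
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(report)
}
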