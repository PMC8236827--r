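pipeline_defaults <- function() {
  list(msa_format = "fasta", methods = "all", permutations = 200,
       alpha = 0.05, pseudocount = 0, seed = 1,
       contact_type = "saltbridge",
       hydrophobic_cutoff = 4.4, hbond_cutoff = 2.5, hbond_min_angle = 120,
       saltbridge_cutoff = 4.0,
       equilibration_binder = 0, equilibration_control = 0,
       stability_threshold = 25, require_all = TRUE,
       core_burial = 0.95, delta_tol = 0.1, sasa_points = 960,
       whisker_iqr_mult = 2, energy_dialect = "haddock_disp",
       min_ortholog_identity = 1.0)
}

pipeline_log <- function(quiet, stage, msg) {
  if (!quiet) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full SDP-mapping pipeline from one configuration
#'
#' Executes whichever stages the configuration provides inputs for -
#' sequence scoring, interface classification, per-replica contact
#' occupancy (binder and control), refinement energetics, consensus -
#' in dependency order, writes every stage's TSV/JSON artifacts into
#' `out_dir`, and returns the final [build_report()] result. Stages
#' without inputs are recorded as skipped; referenced paths are checked
#' before any computation. Re-running with an identical configuration
#' and seed reproduces identical outputs.
#'
#' Configuration keys (flat; defaults in parentheses): `msa`,
#' `msa_format` (fasta), `groups` (TSV id/group), `reference_id`,
#' `methods` (all), `permutations` (200), `alpha` (0.05), `seed` (1);
#' `binder_structure` (PDB for interface classification), `sides` (named
#' chain -> receptor/ligand map); `binder_replicas`, `control_replicas`
#' (vectors of multi-model PDB files or frame directories),
#' `equilibration_binder`/`_control` (frames, 0), `contact_type`
#' (saltbridge), the four contact cutoffs, `stability_threshold` (25),
#' `core_burial` (0.95), `sasa_points` (960); `energy_table`,
#' `energy_dialect` (haddock_disp), `whisker_iqr_mult` (2);
#' `paralog_map` (TSV pos/ref/...), `ortholog_msa`,
#' `ortholog_reference_id`, `min_ortholog_identity` (1.0); `out_dir`.
#'
#' @param config Named list or path to a YAML file.
#' @param quiet Suppress stage messages.
#' @return The `sdp_report` (invisibly also written to `out_dir`), with
#'   stage artifacts and a full configuration echo on disk.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("configuration error: no such file: ",
                                   config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  path_keys <- c("msa", "groups", "binder_structure", "energy_table",
                 "paralog_map", "ortholog_msa")
  for (k in path_keys)
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
      stop("configuration error: path for '", k, "' does not exist: ",
           cfg[[k]])
  for (k in c("binder_replicas", "control_replicas"))
    for (p in cfg[[k]])
      if (!file.exists(p) && !dir.exists(p))
        stop("configuration error: replica path does not exist: ", p)
  if (is.null(cfg$out_dir)) cfg$out_dir <- tempfile("sdpmapper_run_")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- contact_params(hydrophobic_cutoff = cfg$hydrophobic_cutoff,
                           hbond_cutoff = cfg$hbond_cutoff,
                           hbond_min_angle = cfg$hbond_min_angle,
                           saltbridge_cutoff = cfg$saltbridge_cutoff)
  sides <- if (!is.null(cfg$sides)) unlist(cfg$sides) else NULL
  stages <- list()
  tic <- function() proc.time()[["elapsed"]]

  seq_candidates <- NULL
  if (!is.null(cfg$msa)) {
    t0 <- tic()
    pipeline_log(quiet, "seqscore", "scoring grouped alignment")
    aln <- read_alignment(cfg$msa, cfg$msa_format)
    grouped <- assign_groups(aln, read_group_spec(cfg$groups))
    scores <- score_columns(grouped, method = "all",
                            reference_id = cfg$reference_id,
                            permutations = cfg$permutations,
                            alpha = cfg$alpha, seed = cfg$seed,
                            pseudocount = cfg$pseudocount)
    for (m in names(scores))
      utils::write.table(as.data.frame(scores[[m]]),
                         file.path(cfg$out_dir,
                                   sprintf("seqscores_%s.tsv", m)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    to_cand <- function(st, method) {
      cols <- if (!is.null(st$flag)) st$column[st$flag]
              else rank_and_select(st, top_k = min(5L, nrow(st)))
      pos <- if (!is.null(st$reference_position))
        st$reference_position[match(cols, st$column)] else cols
      candidate_set(pos[!is.na(pos)], provenance = method)
    }
    seq_candidates <- Map(to_cand, scores, names(scores))
    stages$seqscore <- list(status = "run", seconds = tic() - t0)
  } else stages$seqscore <- list(status = "skipped: no msa input")

  classification <- NULL
  if (!is.null(cfg$binder_structure)) {
    t0 <- tic()
    pipeline_log(quiet, "interface", "classifying binder interface")
    fs <- read_frames(cfg$binder_structure, sides)
    classification <- classify_interface(get_frame(fs, 1L),
                                         core_burial = cfg$core_burial,
                                         delta_tol = cfg$delta_tol,
                                         points = cfg$sasa_points)
    write_interface_tsv(classification,
                        file.path(cfg$out_dir, "interface.tsv"))
    stages$interface <- list(status = "run", seconds = tic() - t0)
  } else stages$interface <- list(status = "skipped: no binder structure")

  run_traj <- function(paths, equil, label) {
    t0 <- tic()
    pipeline_log(quiet, "traj", paste("occupancy for", label))
    framesets <- lapply(paths, read_frames, side_spec = sides)
    names(framesets) <- paste0("replica", seq_along(framesets))
    occ <- occupancy(framesets, type = cfg$contact_type, params = params,
                     equilibration = equil)
    write_occupancy_tsv(occ, file.path(cfg$out_dir,
                                       sprintf("occupancy_%s.tsv", label)))
    stages[[paste0("traj_", label)]] <<-
      list(status = "run", seconds = tic() - t0)
    classify_stability(occ, threshold = cfg$stability_threshold,
                       require_all = cfg$require_all)
  }
  binder_calls <- if (!is.null(cfg$binder_replicas))
    run_traj(cfg$binder_replicas, cfg$equilibration_binder, "binder")
  else {
    stages$traj_binder <- list(status = "skipped: no binder replicas")
    NULL
  }
  control_calls <- if (!is.null(cfg$control_replicas))
    run_traj(cfg$control_replicas, cfg$equilibration_control, "control")
  else {
    stages$traj_control <- list(status = "skipped: no control replicas")
    NULL
  }

  if (!is.null(cfg$energy_table)) {
    t0 <- tic()
    pipeline_log(quiet, "energetics", "flagging electrostatic outliers")
    et <- read_residue_energies(cfg$energy_table, cfg$energy_dialect)
    flagged <- flag_electrostatic_outliers(et, cfg$whisker_iqr_mult)
    utils::write.table(flagged,
                       file.path(cfg$out_dir, "energetics_flagged.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    stages$energetics <- list(status = "run", seconds = tic() - t0)
  } else stages$energetics <- list(status = "skipped: no energy table")

  paralog_map <- if (!is.null(cfg$paralog_map))
    utils::read.table(cfg$paralog_map, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  ortho <- if (!is.null(cfg$ortholog_msa))
    read_alignment(cfg$ortholog_msa, cfg$msa_format) else NULL

  t0 <- tic()
  report <- build_report(
    binder_calls = binder_calls, control_calls = control_calls,
    paralog_map = paralog_map, interface = classification,
    sequence_candidates = seq_candidates,
    ortholog_alignment = ortho,
    reference_id = cfg$ortholog_reference_id,
    metadata = list(config = cfg[order(names(cfg))],
                    config_hash = config_hash(cfg),
                    hbond_mode = params$hbond_mode,
                    stages = stages))
  stages$consensus <- list(status = "run", seconds = tic() - t0)
  report$metadata$stages <- stages
  # timings go to their own file so analysis artifacts stay byte-identical
  # across reruns of one config
  timings <- data.frame(stage = names(stages),
                        status = vapply(stages, `[[`, "", "status"),
                        seconds = vapply(stages, function(s)
                          if (is.null(s$seconds)) NA_real_
                          else round(s$seconds, 3), numeric(1)))
  utils::write.table(timings, file.path(cfg$out_dir, "timings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  disk <- report
  disk$metadata$stages <- lapply(stages, function(s) s["status"])
  write_report(disk, cfg$out_dir)
  jsonlite::write_json(cfg[order(names(cfg))],
                       file.path(cfg$out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(quiet, "done", paste("artifacts in", cfg$out_dir))
  report
}

config_hash <- function(cfg) {
  # hash the analysis-relevant configuration only: where the artifacts
  # land must not change what they contain
  cfg <- cfg[setdiff(names(cfg), "out_dir")]
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  # small stable polynomial hash; avoids a digest dependency
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
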