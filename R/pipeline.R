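# Pipeline orchestration: one validated config drives simulate -> cluster
# -> polarity -> hotspots -> assemble -> ionsites, writing one JSON report
# per stage plus a combined summary. Stage outputs are pure functions of
# inputs + config, so a fixed seed gives byte-identical reports.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "gagposelab_run",
    stages = c("simulate", "cluster", "polarity", "hotspots", "assemble",
               "ionsites"),
    simulate = list(n_poses = 200, sizes = c(19, 6, 4), spread = 1,
                    polarity_fractions = c(1, 1, 1), dp = 6,
                    n_residues = 150, n_hotspots = 10,
                    ion_occupancies_ns = c(65), length_ns = 100,
                    frame_interval_ps = 500),
    cluster = list(n_top = 50, tune = TRUE, m = 3, eps = 2.0,
                   target_range = c(2, 4), m_grid = c(2, 3, 4),
                   eps_grid = seq(1, 8, by = 0.5)),
    polarity = list(reference = "top-pose"),
    hotspots = list(top_n = 10, stability_threshold = -15),
    assemble = list(target_dp = 11, overlap_rmsd_cutoff = 1.0,
                    dedup_rmsd = 4.0, jitter = 0.3, n_decoys = 50,
                    beam_cap = 1e5),
    ionsites = list(coordination_cutoff = 3.2, min_oxygens = 2,
                    min_report_ns = 10)
  )
}

.merge_config <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    if (!nm %in% names(defaults)) {
      stop("unknown config key: ", paste0(path, nm), call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]])) {
      defaults[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Validate and resolve a pipeline configuration
#'
#' @param config named list (or path to a YAML file) overriding the
#'   package defaults; unknown keys are rejected before any stage runs.
#' @return the resolved config list.
#' @export
resolve_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- .merge_config(.pipeline_defaults(), config)
  if (!all(cfg$stages %in% .pipeline_defaults()$stages)) {
    stop("unknown stage name in config", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

.stage_log <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pose-analysis pipeline
#'
#' Executes the enabled stages in fixed order on synthetic inputs
#' generated from the config seed, writing `<stage>.json` reports and a
#' combined `summary.json` (cluster number, size, binding energy,
#' top-10 residues, polarity — the layout of a docking summary table)
#' under `config$outdir`, plus a `resolved_config.json` copy for
#' provenance.
#'
#' @param config named list or YAML path, see [resolve_config()].
#' @return the report bundle (named list of stage reports), invisibly;
#'   reports are also written as JSON.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- resolve_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  write_report_json(cfg[setdiff(names(cfg), "")],
                    file.path(cfg$outdir, "resolved_config.json"))
  reports <- list()
  seed <- cfg$seed

  # -- simulate ------------------------------------------------------------
  receptor <- make_receptor(n_res = cfg$simulate$n_residues, seed = seed)
  chain <- build_ideal_chain(hp_sequence(cfg$simulate$dp))
  planted <- make_pose_ensemble(receptor, chain, sizes = cfg$simulate$sizes,
                                spread = cfg$simulate$spread,
                                polarity_fractions = cfg$simulate$polarity_fractions,
                                seed = seed)
  scored <- make_scored_poses(n = cfg$simulate$n_poses, seed = seed + 1,
                              receptor = receptor, chain = chain)
  if ("simulate" %in% cfg$stages) {
    write_pose_ensemble(planted$ensemble,
                        file.path(cfg$outdir, "planted_ensemble.pdb"))
    reports$simulate <- list(
      n_planted_poses = length(planted$ensemble$poses),
      n_scored_poses = length(scored$poses),
      planted_sizes = cfg$simulate$sizes
    )
    write_report_json(reports$simulate, file.path(cfg$outdir, "simulate.json"))
    .stage_log("simulate", sprintf("%d planted + %d scored poses",
                                   length(planted$ensemble$poses),
                                   length(scored$poses)))
  }

  # -- cluster -------------------------------------------------------------
  clustered <- NULL
  if ("cluster" %in% cfg$stages) {
    top <- select_top_scored(planted$ensemble, n = cfg$cluster$n_top)
    tuned <- if (isTRUE(cfg$cluster$tune)) {
      tune_clustering(top, target_range = cfg$cluster$target_range,
                      m_grid = cfg$cluster$m_grid,
                      eps_grid = cfg$cluster$eps_grid)
    } else {
      res <- cluster_poses(top, m = cfg$cluster$m, eps = cfg$cluster$eps)
      list(params = res$params, result = res, warning_flag = FALSE)
    }
    clustered <- list(ensemble = top, tuned = tuned)
    reports$cluster <- list(
      params = tuned$params, sizes = tuned$result$sizes,
      n_noise = sum(tuned$result$labels == 0L),
      warning_flag = tuned$warning_flag,
      members = split(names(tuned$result$labels), tuned$result$labels)
    )
    write_report_json(reports$cluster, file.path(cfg$outdir, "cluster.json"))
    .stage_log("cluster", sprintf("m=%d eps=%.2f -> %d clusters (%s)",
                                  tuned$params$m, tuned$params$eps,
                                  length(tuned$result$sizes),
                                  paste(tuned$result$sizes, collapse = "/")))
  }

  # -- polarity ------------------------------------------------------------
  if ("polarity" %in% cfg$stages && !is.null(clustered)) {
    pol <- polarity_report(clustered$ensemble, clustered$tuned$result,
                           reference = cfg$polarity$reference)
    reports$polarity <- pol
    write_report_json(pol, file.path(cfg$outdir, "polarity.json"))
    .stage_log("polarity", paste(pol$polarity, collapse = " "))
  }

  # -- hotspots ------------------------------------------------------------
  if ("hotspots" %in% cfg$stages) {
    res_tab <- receptor_residues(receptor)
    res_df <- data.frame(
      resname = unname(AA_THREE_TO_ONE[res_tab$resname]),
      resno = res_tab$resno, stringsAsFactors = FALSE)
    res_df <- res_df[!is.na(res_df$resname), ]
    k <- max(1L, length(cfg$simulate$sizes))
    tables <- lapply(seq_len(k), function(i) {
      hot <- paste0(res_df$resname, res_df$resno)[
        seq.int(1 + (i - 1) * 2, length.out = cfg$simulate$n_hotspots)]
      tab <- make_energy_table(res_df, hot, seed = seed + 10 + i,
                               id = paste0("c", i))
      attr(tab, "n_poses") <- cfg$simulate$sizes[i]
      tab
    })
    sets <- lapply(tables, top_residues, n = cfg$hotspots$top_n)
    names(sets) <- paste0("cluster", seq_len(k))
    om <- overlap_matrix(sets)
    agg <- aggregate_per_gag(tables)
    reports$hotspots <- list(
      top10 = lapply(sets, function(s) s$residues),
      overlap = om,
      aggregated_top10 = top_residues(agg, n = cfg$hotspots$top_n)$residues
    )
    write_report_json(reports$hotspots, file.path(cfg$outdir, "hotspots.json"))
    .stage_log("hotspots", sprintf("%d hotspot sets, diagonal %s", k,
                                   paste(diag(om), collapse = "/")))
  }

  # -- assemble ------------------------------------------------------------
  if ("assemble" %in% cfg$stages) {
    dp11 <- .offset_dp11_chain(receptor)
    lib <- make_fragment_library(dp11, jitter = cfg$assemble$jitter,
                                 n_decoys = cfg$assemble$n_decoys,
                                 seed = seed + 20)
    chains <- assemble_chains(lib$phaseA, lib$phaseB,
                              target_dp = cfg$assemble$target_dp,
                              overlap_rmsd_cutoff = cfg$assemble$overlap_rmsd_cutoff,
                              beam_cap = cfg$assemble$beam_cap)
    kept <- clash_filter(chains, receptor)
    reps <- dedup_chains(kept, rmsd_cutoff = cfg$assemble$dedup_rmsd)
    reports$assemble <- list(
      n_assembled = length(chains), n_after_clash = length(kept),
      n_representatives = length(reps),
      best = if (length(reps)) list(score = reps[[1]]$score,
                                    fragments = reps[[1]]$fragment_ids)
             else NULL
    )
    write_report_json(reports$assemble, file.path(cfg$outdir, "assemble.json"))
    .stage_log("assemble", sprintf("%d chains -> %d representatives",
                                   length(chains), length(reps)))
  }

  # -- ionsites ------------------------------------------------------------
  if ("ionsites" %in% cfg$stages) {
    site_res <- .default_ion_sites(receptor)
    planted_traj <- make_ion_trajectory(
      receptor, sites = site_res,
      occupancies_ns = rep_len(cfg$simulate$ion_occupancies_ns,
                               length(site_res)),
      length_ns = cfg$simulate$length_ns,
      frame_interval_ps = cfg$simulate$frame_interval_ps,
      seed = seed + 30)
    found <- detect_sites(planted_traj$traj,
                          cutoff = cfg$ionsites$coordination_cutoff,
                          min_oxygens = cfg$ionsites$min_oxygens,
                          min_report_ns = cfg$ionsites$min_report_ns)
    reports$ionsites <- list(
      sites = lapply(found, function(s)
        list(residues = s$residues, occupancy_ns = s$occupancy_ns))
    )
    write_report_json(reports$ionsites, file.path(cfg$outdir, "ionsites.json"))
    .stage_log("ionsites", sprintf("%d sites", length(found)))
  }

  write_report_json(list(stages_run = cfg$stages, seed = cfg$seed),
                    file.path(cfg$outdir, "summary.json"))
  invisible(reports)
}

# dp11 chain placed outside the receptor so assembled chains pass the
# clash filter.
.offset_dp11_chain <- function(receptor) {
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rad <- max(sqrt(rowSums(sweep(rxyz, 2, colMeans(rxyz))^2)))
  build_ideal_chain(hp_sequence(11),
                    seed_origin = colMeans(rxyz) + c(rad + 6, 0, -22.5))
}

# Two clean planted sites: adjacent acidic/amide residues on opposite
# poles of the lattice.
.default_ion_sites <- function(receptor) {
  res <- receptor_residues(receptor)
  keys <- .residue_key(res$resname, res$resno)
  ok <- res$resname %in% c("GLU", "ASP", "ASN", "GLN")
  idx <- which(ok)
  first <- idx[seq_len(min(3, length(idx)))]
  last <- rev(idx)[seq_len(min(3, length(idx)))]
  list(keys[first], keys[last])
}
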