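#!/usr/bin/env Rscript
# Step 1: generate every synthetic input the downstream analyses consume,
# with planted ground truth, into results/fixtures/. All later steps read
# only these files.

suppressPackageStartupMessages(library(gagposelab))

seed <- 2026L
outdir <- "results/fixtures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

receptor <- make_receptor(n_res = 150, seed = 1)
chain <- build_ideal_chain(hp_sequence(6))   # heparin-like dp6 ligand

# Docked-pose ensemble: three planted binding sites of 19/6/4 poses with a
# mixed-polarity major site, plus a 1000-pose raw scored list.
planted <- make_pose_ensemble(receptor, chain, sizes = c(19, 6, 4),
                              spread = 1, polarity_fractions = c(0.9, 1, 0.5),
                              seed = seed)
write_pose_ensemble(planted$ensemble, file.path(outdir, "planted_poses.pdb"))
write_report_json(list(true_labels = as.list(planted$true_labels),
                       true_polarity = as.list(planted$true_polarity)),
                  file.path(outdir, "planted_truth.json"))

raw <- make_scored_poses(n = 1000, seed = seed + 1, receptor = receptor,
                         chain = chain)
write_pose_ensemble(raw, file.path(outdir, "raw_scored_poses.pdb"))

# Per-cluster energy decomposition tables with planted hotspots (partially
# overlapping across clusters, as binding-site residue sets are in practice).
res_df <- receptor_residues(receptor)
aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", GLN = "Q", GLU = "E",
         GLY = "G", LEU = "L", LYS = "K", PHE = "F", SER = "S", THR = "T",
         TYR = "Y", VAL = "V")
res_df <- data.frame(resname = unname(aa1[res_df$resname]),
                     resno = res_df$resno)
res_df <- res_df[!is.na(res_df$resname), ]
keys <- paste0(res_df$resname, res_df$resno)
for (i in 1:3) {
  hot <- keys[seq(1 + 3 * (i - 1), length.out = 10)]   # shifted, overlapping
  tab <- make_energy_table(res_df, hot, seed = seed + 10 + i,
                           id = paste0("c", i))
  write_energy_table(tab, file.path(outdir, sprintf("energy_cluster%d.csv", i)))
}

# Five MD replicas of a Ca2+ trajectory with one consensus site plus one
# replica-specific site.
consensus_site <- c("E1", "E2", "N3")
alt_site <- c("D124", "Q125", "E121")
for (r in 1:5) {
  sites <- if (r == 2) list(consensus_site, alt_site) else list(consensus_site)
  occ <- if (r == 2) c(65, 40) else c(45 + 10 * r)
  mk <- make_ion_trajectory(receptor, sites, occ, length_ns = 100,
                            frame_interval_ps = 100, seed = seed + 20 + r)
  write_ion_trajectory(mk$traj, file.path(outdir, sprintf("ca_replica%d.csv", r)))
  write_pose_ensemble(new_pose_ensemble(mk$traj$receptor, list(
    list(id = "pocket", chain = chain, score = 0))),
    file.path(outdir, sprintf("ca_receptor%d.pdb", r)))
}

message("fixtures written to ", outdir)
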