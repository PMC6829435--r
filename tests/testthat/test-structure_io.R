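# PDB ensemble round trips, energy-table CSV parsing, trajectory CSV.

make_test_ensemble <- function(n_poses = 5, dp = 4, seed = 3) {
  rec <- small_receptor()
  ch <- build_ideal_chain(hp_sequence(dp))
  withr::with_seed(seed, {
    poses <- lapply(seq_len(n_poses), function(i) {
      moved <- transform_chain(ch, rotation = random_rotation(),
                               translation = rnorm(3, 0, 10))
      list(id = sprintf("p%03d", i), chain = moved,
           score = round(rnorm(1, -40, 5), 3))
    })
    new_pose_ensemble(rec, poses)
  })
}

test_that("pose ensembles round-trip through multi-MODEL PDB", {
  ens <- make_test_ensemble(n_poses = 50)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens, path)
  back <- read_pose_ensemble(path)

  expect_length(back$poses, 50L)
  expect_identical(vapply(back$poses, `[[`, character(1), "id"),
                   vapply(ens$poses, `[[`, character(1), "id"))
  expect_equal(ensemble_scores(back), ensemble_scores(ens))
  # coordinates exact at PDB 3-decimal precision
  for (k in c(1, 25, 50)) {
    a <- chain_atoms(ens$poses[[k]]$chain)
    b <- chain_atoms(back$poses[[k]]$chain)
    expect_identical(paste(b$ring_index, b$name), paste(a$ring_index, a$name))
    expect_equal(as.matrix(b[, c("x", "y", "z")]),
                 as.matrix(round(a[, c("x", "y", "z")], 3)),
                 ignore_attr = TRUE)
  }
  # receptor residue numbering preserved
  expect_equal(receptor_residues(back$receptor), receptor_residues(ens$receptor),
               ignore_attr = TRUE)

  # write -> read -> write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("single-pose files contain one MODEL/ENDMDL pair", {
  ens <- make_test_ensemble(n_poses = 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "MODEL")), 1L)
  expect_equal(sum(startsWith(lines, "ENDMDL")), 1L)
})

test_that("malformed ensemble input is rejected with context", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), path)
  expect_error(read_pose_ensemble(path), "empty")

  # receptor only, no MODEL records
  writeLines(c("ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
               "END"), path)
  expect_error(read_pose_ensemble(path), "MODEL")

  # two models with different ring counts -> inconsistent ligand
  ens2 <- make_test_ensemble(n_poses = 1, dp = 4)
  ens3 <- make_test_ensemble(n_poses = 1, dp = 6)
  p1 <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens2, p1)
  l1 <- readLines(p1)
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens3, p2)
  l2 <- readLines(p2)
  mixed <- c(l1[-length(l1)],
             l2[which(startsWith(l2, "MODEL")):which(startsWith(l2, "ENDMDL"))],
             "END")
  p3 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(mixed, p3)
  expect_error(read_pose_ensemble(p3), "inconsistent ligand|must be the same ligand")
})

test_that("coordinates beyond the PDB fixed width are an error, not truncation", {
  rec <- small_receptor()
  ch <- transform_chain(build_ideal_chain(hp_sequence(4)),
                        translation = c(99999, 0, 0))
  ens <- new_pose_ensemble(rec, list(list(id = "p1", chain = ch, score = -1)))
  path <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pose_ensemble(ens, path), "range")
})

test_that("energy tables parse residue tokens and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,residue,mean,sd", "c1,K436,-5.2,0.4", "c1,LYS437,-1.0,0.2",
               "c1,TOTAL,-42.0,6.6"), path)
  tab <- read_energy_table(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$resname, c("K", "K"))
  expect_equal(tab$resno, c(436L, 437L))
  expect_equal(tab$mean[1], -5.2)
  expect_equal(attr(tab, "totals")$dG_mean, -42.0)

  # negative sd rejected with the row number
  writeLines(c("id,residue,mean,sd", "c1,K436,-5.2,-1"), path)
  expect_error(read_energy_table(path), "row 1.*negative sd|negative sd")

  writeLines(c("id,residue,mean,sd", "c1,436K,-5.2,0.1"), path)
  expect_error(read_energy_table(path), "row")
})

test_that("a top-10 residue list survives the CSV round trip in order", {
  c1 <- c("R435", "K436", "R275", "R288", "K279", "K299", "K365", "K434",
          "N331", "K295")
  parsed <- parse_residue_token(c1)
  tab <- new_energy_table(data.frame(
    id = "c1", resname = parsed$resname, resno = parsed$resno,
    mean = seq(-6, by = 0.3, length.out = 10), sd = 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_energy_table(tab, path)
  back <- read_energy_table(path)
  expect_identical(paste0(back$resname, back$resno), c1)
  expect_identical(top_residues(back, 10)$residues, c1)
})

test_that("ion trajectories round-trip through CSV", {
  rec <- small_receptor()
  mk <- make_ion_trajectory(rec, list(c("E1", "E2", "N3")), 10,
                            length_ns = 20, frame_interval_ps = 500, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ion_trajectory(mk$traj, path)
  back <- read_ion_trajectory(path, mk$traj$receptor)
  expect_equal(back$interval_ps, mk$traj$interval_ps)
  expect_equal(back$length_ns, mk$traj$length_ns)
  expect_equal(back$frames$x, mk$traj$frames$x, tolerance = 1e-9)
})

test_that("an independent PDB parser reads the writer's records", {
  ens <- make_test_ensemble(n_poses = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pose_ensemble(ens, path)
  # receptor block: fixed-width columns parse identically in bio3d
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  rec_atoms <- pdb$atom[pdb$atom$type == "ATOM", ]
  expect_equal(nrow(rec_atoms), nrow(ens$receptor$atoms))
  expect_equal(rec_atoms$x, round(ens$receptor$atoms$x, 3))
  expect_equal(rec_atoms$resno, ens$receptor$atoms$resno)
  expect_equal(rec_atoms$elety, ens$receptor$atoms$atom)
  # ligand block of the first pose, re-read as a standalone PDB
  lines <- readLines(path)
  block <- lines[(which(startsWith(lines, "MODEL"))[1] + 1):
                   (which(startsWith(lines, "ENDMDL"))[1] - 1)]
  lig_path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(grep("^HETATM", block, value = TRUE), "END"), lig_path)
  lig <- bio3d::read.pdb(lig_path, verbose = FALSE)$atom
  a1 <- chain_atoms(ens$poses[[1]]$chain)
  expect_equal(lig$x, round(a1$x, 3))
  expect_equal(lig$elety, a1$name)
  expect_equal(lig$resno, a1$ring_index + 1L)
})
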