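# Ca2+ coordination detection, site occupancy, replica consensus and
# reference matching.

test_that("frame coordination applies the oxygen cutoff and minimum count", {
  # hand-built micro-receptor: one Glu OE1 and one Asn OD1 near the origin
  at <- data.frame(
    chain = "A", resno = c(10L, 10L, 20L, 20L, 30L, 30L),
    resname = c("GLU", "GLU", "ASN", "ASN", "GLY", "GLY"),
    atom = c("CA", "OE1", "CA", "OD1", "CA", "O"),
    element = c("C", "O", "C", "O", "C", "O"),
    x = c(5, 2.4, -5, -2.4, 0, 0), y = c(0, 0, 0, 0, 30, 31), z = 0,
    stringsAsFactors = FALSE)
  rec <- new_receptor(at)
  expect_setequal(frame_coordination(c(0, 0, 0), rec), c("E10", "N20"))
  # far ion: empty set
  expect_length(frame_coordination(c(0, -20, 0), rec), 0L)
  # one oxygen only: below min_oxygens -> unbound
  expect_length(frame_coordination(c(2.4, 1.5, 0), rec), 0L)
  expect_error(frame_coordination(c(0, NA, 0), rec), "finite")
})

test_that("planted occupancies are reproduced exactly", {
  rec <- small_receptor()
  mk <- make_ion_trajectory(rec, list(c("E1", "E2", "N3")), 65,
                            length_ns = 100, frame_interval_ps = 100, seed = 5)
  found <- detect_sites(mk$traj)
  expect_length(found, 1L)
  expect_setequal(found[[1]]$residues, c("E1", "E2", "N3"))
  expect_equal(found[[1]]$occupancy_ns, 65)

  # two sites in one run, different ions
  mk2 <- make_ion_trajectory(rec, list(c("E1", "E2", "N3"),
                                       c("D49", "Q50", "E46")),
                             c(85, 90), length_ns = 100,
                             frame_interval_ps = 100, seed = 6)
  f2 <- detect_sites(mk2$traj)
  expect_length(f2, 2L)
  occ <- sort(vapply(f2, function(s) s$occupancy_ns, numeric(1)))
  expect_equal(occ, c(85, 90))

  # zero occupancy -> site absent
  mk0 <- make_ion_trajectory(rec, list(c("E1", "E2", "N3")), 0,
                             length_ns = 50, frame_interval_ps = 500, seed = 7)
  expect_length(detect_sites(mk0$traj), 0L)

  # generator determinism
  mk_again <- make_ion_trajectory(rec, list(c("E1", "E2", "N3")), 65,
                                  length_ns = 100, frame_interval_ps = 100,
                                  seed = 5)
  expect_identical(mk$traj$frames, mk_again$traj$frames)
})

test_that("per-ion occupancy never exceeds the trajectory length", {
  rec <- small_receptor()
  mk <- make_ion_trajectory(rec, list(c("E1", "E2", "N3"),
                                      c("D49", "Q50", "E46")),
                            c(40, 35), length_ns = 50,
                            frame_interval_ps = 250, seed = 11)
  found <- detect_sites(mk$traj, min_report_ns = 0)
  for (ion in unique(mk$traj$frames$ion)) {
    # frames of this ion assigned anywhere
    sub <- mk$traj$frames[mk$traj$frames$ion == ion, ]
    bound <- sum(vapply(seq_len(nrow(sub)), function(i)
      length(frame_coordination(c(sub$x[i], sub$y[i], sub$z[i]),
                                mk$traj$receptor)) > 0, logical(1)))
    expect_lte(bound * mk$traj$interval_ps / 1000, mk$traj$length_ns)
  }
  expect_lte(sum(vapply(found, function(s) s$occupancy_ns, numeric(1))),
             2 * mk$traj$length_ns)
})

test_that("replica consensus reports support across repetitions", {
  rec <- small_receptor()
  reps <- lapply(1:5, function(r) {
    mk <- make_ion_trajectory(rec, list(c("E1", "E2", "N3")), 15,
                              length_ns = 20, frame_interval_ps = 500,
                              seed = 100 + r)
    detect_sites(mk$traj)
  })
  cons <- replica_consensus(reps)
  expect_length(cons, 1L)
  expect_equal(cons[[1]]$support, 5L)
  expect_setequal(cons[[1]]$residues, c("E1", "E2", "N3"))

  # a site present once gets support 1
  extra <- make_ion_trajectory(rec, list(c("D49", "Q50", "E46")), 15,
                               length_ns = 20, frame_interval_ps = 500,
                               seed = 200)
  cons2 <- replica_consensus(c(reps, list(detect_sites(extra$traj))))
  sup <- vapply(cons2, function(s) s$support, integer(1))
  expect_setequal(sup, c(5L, 1L))

  expect_length(replica_consensus(list(list(), list())), 0L)
})

test_that("slightly varying coordination sets merge into one site", {
  # Jaccard 3/5 >= 0.5: a replica where two extra residues join the site
  a <- list(list(residues = c("E405", "E406", "N407"), occupancy_ns = 65))
  b <- list(list(residues = c("E405", "E406", "N407", "G367", "D370"),
                 occupancy_ns = 25))
  cons <- replica_consensus(list(a, b))
  expect_length(cons, 1L)
  expect_equal(cons[[1]]$support, 2L)
  # disjoint sets do not merge
  c3 <- list(list(residues = c("Y180", "E208", "D216"), occupancy_ns = 90))
  expect_length(replica_consensus(list(a, c3)), 2L)
})

test_that("reference matching is greedy, one-to-one and identity-complete", {
  sites <- lapply(1:9, function(i)
    list(residues = paste0(c("E", "D", "N"), 10 * i + 0:2)))
  self <- match_reference_sites(sites, sites)
  expect_equal(self$matched, 9L)
  expect_equal(self$mapping$predicted, self$mapping$reference)

  # planted 6-of-9 recovery
  shifted <- lapply(1:9, function(i) {
    if (i <= 6) sites[[i]]
    else list(residues = paste0(c("E", "D", "N"), 1000 + 10 * i + 0:2))
  })
  expect_equal(match_reference_sites(shifted, sites)$matched, 6L)

  expect_equal(match_reference_sites(list(), sites)$matched, 0L)

  # position fallback when residue sets are unavailable
  p <- list(list(residues = character(0), position = c(0, 0, 0)))
  r_near <- list(list(residues = character(0), position = c(0, 0, 3)))
  r_far <- list(list(residues = character(0), position = c(0, 0, 10)))
  expect_equal(match_reference_sites(p, r_near)$matched, 1L)
  expect_equal(match_reference_sites(p, r_far)$matched, 0L)
})
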