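# Fragment compatibility, beam assembly, clash filtering, deduplication.

test_that("fragment compatibility follows the two-ring overlap RMSD", {
  ch <- build_ideal_chain(hp_sequence(11))
  tr <- split_into_trimers(ch)
  f1 <- new_trimer_pose(tr[[1]]$chain, "A", -8, "f1")
  f2 <- new_trimer_pose(tr[[2]]$chain, "B", -8, "f2")
  ok <- fragment_compatible(f1, f2)
  expect_true(ok$compatible)
  expect_equal(ok$rmsd, 0)

  moved <- new_trimer_pose(transform_chain(tr[[2]]$chain,
                                           translation = c(5, 0, 0)),
                           "B", -8, "f2m")
  far <- fragment_compatible(f1, moved)
  expect_false(far$compatible)
  expect_equal(far$rmsd, 5, tolerance = 1e-9)

  # jittered overlap equals the direct pairwise formula
  set.seed(61)
  jit <- tr[[2]]$chain
  for (r in 1:3) {
    jit$rings[[r]]$atoms[, c("x", "y", "z")] <-
      jit$rings[[r]]$atoms[, c("x", "y", "z")] + rnorm(12, 0, 0.3)
  }
  f2j <- new_trimer_pose(jit, "B", -8, "f2j")
  got <- fragment_compatible(f1, f2j)$rmsd
  a <- chain_atoms(tr[[1]]$chain); b <- chain_atoms(jit)
  a <- a[a$ring_index >= 1, ]; b <- b[b$ring_index <= 1, ]
  want <- sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
  expect_equal(got, want, tolerance = 1e-9)

  expect_error(fragment_compatible(f1, f1), "same phase")
})

test_that("a noiseless fragment library reassembles the source chain exactly", {
  ch <- build_ideal_chain(hp_sequence(11))
  lib <- make_fragment_library(ch, jitter = 0, n_decoys = 0, seed = 1)
  out <- assemble_chains(lib$phaseA, lib$phaseB)
  expect_length(out, 1L)
  expect_equal(out[[1]]$chain$dp, 11L)
  expect_identical(chain_atoms(out[[1]]$chain)[, c("x", "y", "z")],
                   chain_atoms(ch)[, c("x", "y", "z")])
  expect_identical(out[[1]]$fragment_ids, lib$truth)
  expect_equal(out[[1]]$max_overlap_rmsd, 0)
})

test_that("assembled chains always satisfy the ring-count and phase scheme", {
  ch <- build_ideal_chain(hp_sequence(11))
  lib <- make_fragment_library(ch, jitter = 0.3, n_decoys = 20, seed = 4)
  out <- assemble_chains(lib$phaseA, lib$phaseB, target_dp = 11)
  expect_gt(length(out), 0L)
  for (a in out) {
    expect_equal(a$chain$dp, 11L)
    expect_length(a$fragment_ids, 9L)
  }
  # no compatible partner -> empty result, not an error
  lone <- assemble_chains(lib$phaseA[1],
                          list(new_trimer_pose(
                            transform_chain(lib$phaseB[[1]]$chain,
                                            translation = c(100, 0, 0)),
                            "B", -8, "farB")))
  expect_length(lone, 0L)
})

test_that("tightening the overlap cutoff never adds assembled chains", {
  ch <- build_ideal_chain(hp_sequence(11))
  lib <- make_fragment_library(ch, jitter = 0.4, n_decoys = 10, seed = 13)
  counts <- vapply(c(2.0, 1.0, 0.5, 0.2), function(cut)
    length(assemble_chains(lib$phaseA, lib$phaseB,
                           overlap_rmsd_cutoff = cut)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the clash filter agrees with a brute-force all-pairs check", {
  rec <- small_receptor()
  ch_far <- offset_dp11(rec)
  # chain threaded exactly through one receptor atom (ring-5 centroid on it)
  hit <- unlist(rec$atoms[1, c("x", "y", "z")])
  ch_through <- build_ideal_chain(hp_sequence(11),
                                  seed_origin = hit - c(0, 0, 22.5))
  wrap <- function(ch) structure(list(chain = ch, fragment_ids = "x",
                                      score = 0, max_overlap_rmsd = 0),
                                 class = "assembled_chain")
  chains <- list(wrap(ch_far), wrap(ch_through))
  kept <- clash_filter(chains, rec)
  expect_length(kept, 1L)
  expect_identical(kept[[1]]$chain$rings[[1]]$atoms,
                   ch_far$rings[[1]]$atoms)

  # brute-force oracle over every chain
  rxyz <- as.matrix(rec$atoms[, c("x", "y", "z")])
  oracle_keep <- vapply(chains, function(a) {
    at <- chain_atoms(a$chain)
    ok <- TRUE
    for (i in seq_len(nrow(at))) {
      di <- sqrt((rxyz[, 1] - at$x[i])^2 + (rxyz[, 2] - at$y[i])^2 +
                   (rxyz[, 3] - at$z[i])^2)
      if (any(di < 2.0)) { ok <- FALSE; break }
      if (ok) for (j in seq_len(nrow(at))) {
        if (abs(at$ring_index[i] - at$ring_index[j]) >= 2) {
          dj <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                       (at$z[i] - at$z[j])^2)
          if (dj < 1.5) { ok <- FALSE; break }
        }
      }
      if (!ok) break
    }
    ok
  }, logical(1))
  expect_equal(length(kept), sum(oracle_keep))

  # self-clash: fold a chain back onto itself
  bent <- ch_far
  a1 <- bent$rings[[1]]$atoms[, c("x", "y", "z")]
  bent$rings[[5]]$atoms[, c("x", "y", "z")] <- a1 + 0.5
  expect_length(clash_filter(list(wrap(bent)), rec), 0L)
})

test_that("RMSD deduplication keeps one representative per basin", {
  ch <- build_ideal_chain(hp_sequence(11))
  wrap <- function(chain, score, id) structure(
    list(chain = chain, fragment_ids = id, score = score,
         max_overlap_rmsd = 0), class = "assembled_chain")
  copies <- lapply(1:100, function(i)
    wrap(transform_chain(ch, translation = rnorm(3, 0, 0.05)), -50 + i / 100,
         sprintf("c%03d", i)))
  reps <- dedup_chains(copies)
  expect_length(reps, 1L)
  expect_equal(reps[[1]]$n_members, 100L)

  two <- list(wrap(ch, -50, "a"),
              wrap(transform_chain(ch, translation = c(10, 0, 0)), -40, "b"))
  reps2 <- dedup_chains(two)
  expect_length(reps2, 2L)
  # representatives ordered by score
  expect_equal(vapply(reps2, function(r) r$score, numeric(1)), c(-50, -40))

  expect_error(dedup_chains(list(wrap(ch, -1, "a"),
                                 wrap(build_ideal_chain(hp_sequence(9)), -1, "b"))),
               "same dp")
})

test_that("a jittered decoy-laden library still recovers the true chain", {
  rec <- small_receptor()
  src <- offset_dp11(rec)
  lib <- make_fragment_library(src, jitter = 0.3, n_decoys = 50, seed = 7)
  # generator determinism
  lib_again <- make_fragment_library(src, jitter = 0.3, n_decoys = 50, seed = 7)
  expect_identical(lib, lib_again)

  out <- assemble_chains(lib$phaseA, lib$phaseB)
  all_true <- vapply(out, function(a) all(grepl("^true_", a$fragment_ids)),
                     logical(1))
  expect_true(any(all_true))
  truth_chain <- out[[which(all_true)[1]]]$chain
  expect_lt(pose_rmsd(truth_chain, src), 1.0)

  reps <- dedup_chains(clash_filter(out, rec), rmsd_cutoff = 4.0)
  expect_gte(length(reps), 1L)
  expect_lte(length(reps), 40L)
})
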