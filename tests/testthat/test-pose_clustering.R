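# Top-scored selection, the periodic nearest-same-type metric, DBSCAN and
# the 2-4-cluster parameter scan.

test_that("top-scored selection keeps the n best with deterministic ties", {
  ens <- make_scored_poses(n = 200, seed = 5)
  top <- select_top_scored(ens, 50)
  expect_length(top$poses, 50L)
  sc <- ensemble_scores(ens)
  expect_setequal(names(ensemble_scores(top)), names(sort(sc)[1:50]))

  # clamp when fewer poses than requested
  small <- make_scored_poses(n = 30, seed = 6)
  expect_length(select_top_scored(small, 50)$poses, 30L)

  # idempotence
  expect_identical(ensemble_scores(select_top_scored(top, 50)),
                   ensemble_scores(top))

  # tie at the boundary: lower pose id wins
  rec <- small_receptor()
  ch <- build_ideal_chain(hp_sequence(4))
  poses <- list(list(id = "a", chain = ch, score = -5),
                list(id = "b", chain = ch, score = -3),
                list(id = "c", chain = ch, score = -3))
  tied <- select_top_scored(new_pose_ensemble(rec, poses), 2)
  expect_identical(names(ensemble_scores(tied)), c("a", "b"))

  expect_error(select_top_scored(ens, 0), ">= 1")
})

test_that("pose distance is zero at identity and exact under translation", {
  ch <- build_ideal_chain(hp_sequence(6))
  expect_equal(pose_distance(ch, ch), 0)

  shifted <- transform_chain(ch, translation = c(2, 0, 0))
  expect_equal(pose_distance(ch, shifted), 2.0, tolerance = 1e-9)

  expect_error(pose_distance(ch, build_ideal_chain(hp_sequence(4))),
               "identical ligands")
})

test_that("pose distance is a symmetric rigid-motion-invariant premetric", {
  ch <- build_ideal_chain(hp_sequence(5))
  set.seed(31)
  for (i in 1:8) {
    a <- transform_chain(ch, random_rotation(), rnorm(3, 0, 5))
    b <- transform_chain(ch, random_rotation(), rnorm(3, 0, 5))
    dab <- pose_distance(a, b)
    expect_gte(dab, 0)
    expect_equal(dab, pose_distance(b, a), tolerance = 1e-12)
    # joint rigid motion leaves the metric unchanged
    rot <- random_rotation(); tr <- rnorm(3, 0, 10)
    ctr <- c(0, 0, 0)
    a2 <- transform_chain(a, rot, tr, center = ctr)
    b2 <- transform_chain(b, rot, tr, center = ctr)
    expect_equal(pose_distance(a2, b2), dab, tolerance = 1e-9)
  }
})

test_that("register shift of a periodic chain scores below index-matched RMSD", {
  # shifting an alternating heparin-like chain by one disaccharide period
  # lets nearest-same-type matching re-register rings, unlike classical RMSD
  ch <- build_ideal_chain(hp_sequence(10))
  period <- 2 * 4.5
  shifted <- transform_chain(ch, translation = c(0, 0, period))
  d_metric <- pose_distance(ch, shifted)
  d_rmsd <- oracle_index_rmsd(ch, shifted)
  expect_equal(d_rmsd, period, tolerance = 1e-9)
  expect_lt(d_metric, d_rmsd)
  expect_lt(d_metric, 0.6 * d_rmsd)
})

test_that("dbscan recovers planted blob structure and labels noise", {
  # two blobs + deterministic construction straight from the definition
  set.seed(41)
  pts <- rbind(matrix(rnorm(20 * 3, 0, 0.3), ncol = 3),
               matrix(rnorm(12 * 3, 10, 0.3), ncol = 3))
  d <- as.matrix(dist(pts))
  labels <- dbscan_matrix(d, m = 3, eps = 2)
  expect_equal(sort(unique(labels)), c(1L, 2L))
  expect_equal(as.integer(table(labels)), c(20L, 12L))

  # all points mutually within eps -> one cluster
  labels1 <- dbscan_matrix(as.matrix(dist(matrix(rnorm(15), ncol = 3))), 5, 100)
  expect_equal(unique(labels1), 1L)

  # isolated point with m >= 2 -> noise
  pts2 <- rbind(matrix(rnorm(30, 0, 0.2), ncol = 3), c(50, 50, 50))
  labels2 <- dbscan_matrix(as.matrix(dist(pts2)), 2, 1.5)
  expect_equal(labels2[11], 0L)
})

test_that("dbscan equals the brute-force oracle over random draws", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(20:100, 1)
    k <- sample(1:4, 1)
    centers <- matrix(runif(k * 3, -20, 20), ncol = 3)
    pts <- do.call(rbind, lapply(seq_len(k), function(j)
      sweep(matrix(rnorm(3 * ceiling(n / k), 0, runif(1, 0.3, 2)), ncol = 3),
            2, centers[j, ], "+")))[seq_len(n), , drop = FALSE]
    d <- as.matrix(dist(pts))
    m <- sample(2:5, 1)
    eps <- runif(1, 0.5, 6)
    expect_dbscan_matches_oracle(dbscan_matrix(d, m, eps), d, m, eps)
  }
})

test_that("dbscan labelling is invariant to input order up to relabeling", {
  set.seed(55)
  pts <- rbind(matrix(rnorm(30, 0, 0.5), ncol = 3),
               matrix(rnorm(30, 8, 0.5), ncol = 3))
  d <- as.matrix(dist(pts))
  ref <- dbscan_matrix(d, 3, 2)
  perm <- sample(nrow(pts))
  permuted <- dbscan_matrix(d[perm, perm], 3, 2)
  # same partition: co-membership matrices agree after undoing the permutation
  back <- integer(length(perm)); back[perm] <- seq_along(perm)
  expect_identical(outer(permuted[back], permuted[back], "=="),
                   outer(ref, ref, "=="))
})

test_that("planted pose clusters are recovered exactly", {
  rec <- small_receptor()
  ch <- build_ideal_chain(hp_sequence(6))
  planted <- make_pose_ensemble(rec, ch, sizes = c(19, 6, 4), spread = 1,
                                seed = 42)
  res <- cluster_poses(planted$ensemble, m = 3, eps = 3)
  expect_equal(res$sizes, c(19L, 6L, 4L))
  expect_equal(sum(res$labels == 0L), 0L)
  # membership matches the planted truth, not just the size profile
  truth <- planted$true_labels[names(res$labels)]
  expect_equal(length(unique(paste(res$labels, truth))), 3L)
})

test_that("parameter tuning lands in the 2-4 cluster target band", {
  rec <- small_receptor()
  ch <- build_ideal_chain(hp_sequence(6))
  for (k in 2:4) {
    planted <- make_pose_ensemble(rec, ch, sizes = c(14, 8, 5, 4)[seq_len(k)],
                                  spread = 1, seed = k)
    tuned <- tune_clustering(planted$ensemble)
    expect_false(tuned$warning_flag)
    expect_gte(length(tuned$result$sizes), 2L)
    expect_lte(length(tuned$result$sizes), 4L)
  }

  # degenerate: all poses identical -> 1 cluster everywhere, flagged
  same <- new_pose_ensemble(rec, lapply(1:6, function(i)
    list(id = sprintf("p%d", i), chain = ch, score = -i)))
  tuned1 <- tune_clustering(same)
  expect_true(tuned1$warning_flag)
  expect_equal(length(tuned1$result$sizes), 1L)
})
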