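# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately written as direct transcriptions of the
# definitions, independent of the package's implementation paths.

fixture_env <- new.env(parent = emptyenv())

small_receptor <- function() {
  if (is.null(fixture_env$rec)) fixture_env$rec <- make_receptor(n_res = 60, seed = 1)
  fixture_env$rec
}

full_receptor <- function() {
  if (is.null(fixture_env$rec150)) fixture_env$rec150 <- make_receptor(seed = 1)
  fixture_env$rec150
}

# dp11 chain placed clear of the receptor so assembled chains survive the
# clash filter.
offset_dp11 <- function(receptor) {
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rad <- max(sqrt(rowSums(sweep(rxyz, 2, colMeans(rxyz))^2)))
  build_ideal_chain(hp_sequence(11),
                    seed_origin = colMeans(rxyz) + c(rad + 6, 0, -22.5))
}

# One-letter residue table of a receptor for energy-table generators.
receptor_residue_df <- function(receptor) {
  three_to_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
                    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
                    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
                    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  res <- receptor_residues(receptor)
  df <- data.frame(resname = unname(three_to_one[res$resname]),
                   resno = res$resno, stringsAsFactors = FALSE)
  df[!is.na(df$resname), ]
}

# Direct-definition radius of gyration via the pairwise-distance identity
# Rg^2 = sum_ij d_ij^2 / (2 n^2); an independent route to the same value.
oracle_rg <- function(xyz) {
  n <- nrow(xyz)
  d2 <- as.matrix(stats::dist(xyz))^2
  sqrt(sum(d2) / (2 * n^2))
}

# Brute-force DBSCAN facts from a distance matrix:
#   core points, connected components of core points, noise set,
#   and for each border point the set of admissible components.
oracle_dbscan_facts <- function(d, m, eps) {
  n <- nrow(d)
  nbr <- d <= eps
  core <- rowSums(nbr) >= m
  comp <- rep(0L, n)
  cid <- 0L
  for (i in which(core)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    frontier <- i
    while (length(frontier) > 0L) {
      comp[frontier] <- cid
      nxt <- unique(unlist(lapply(frontier, function(p)
        which(core & nbr[p, ] & comp == 0L))))
      frontier <- nxt
    }
  }
  border_opts <- lapply(seq_len(n), function(i) {
    if (core[i]) return(integer(0))
    unique(comp[core & nbr[i, ]])
  })
  noise <- !core & vapply(border_opts, length, integer(1)) == 0L
  list(core = core, comp = comp, noise = noise, border_opts = border_opts)
}

# Check a label vector against the brute-force facts: core partition must
# match exactly (up to renaming), noise must match, and every border
# point must carry the label of one of its core neighbours' components.
expect_dbscan_matches_oracle <- function(labels, d, m, eps) {
  facts <- oracle_dbscan_facts(d, m, eps)
  expect_identical(unname(labels == 0L), unname(facts$noise))
  core_idx <- which(facts$core)
  if (length(core_idx) > 0L) {
    same_impl <- outer(labels[core_idx], labels[core_idx], "==")
    same_oracle <- outer(facts$comp[core_idx], facts$comp[core_idx], "==")
    expect_identical(same_impl, same_oracle)
  }
  border <- which(!facts$core & !facts$noise)
  for (i in border) {
    opts <- facts$border_opts[[i]]
    impl_comp <- unique(facts$comp[facts$core & labels == labels[i]])
    expect_true(length(impl_comp) == 1L && impl_comp %in% opts)
  }
}

# Index-matched all-atom RMSD computed directly from coordinates.
oracle_index_rmsd <- function(chainA, chainB) {
  a <- chain_atoms(chainA); b <- chain_atoms(chainB)
  stopifnot(identical(paste(a$ring_index, a$name), paste(b$ring_index, b$name)))
  sqrt(mean((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2))
}

# Closed-form Welch t-test (statistic, Welch-Satterthwaite df, p).
oracle_welch <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- runif(1, 0, 2 * pi)
  k <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * k + (1 - cos(ang)) * (k %*% k)
}
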