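# Synthetic inputs with planted ground truth for every pipeline stage:
# receptor pseudo-globule, pose ensembles with planted clusters and
# polarity bias, scored pose lists, per-residue energy tables with planted
# hotspots, trimer fragment libraries, and ion trajectories with planted
# coordination sites. Every generator is a pure function of its seed.
#
# Default numeric choices (documented package constants):
#   * cluster jitter spread      1 A RMS rigid displacement
#   * planted hotspot mean      -5 kcal/mol over a 0 kcal/mol background
#   * energy noise sd            0.5 kcal/mol
#   * ion coordination placement 2.4 A from the site oxygens
#   * unbound ion excursions     >= 8 A from every site

#' Deterministic pseudo-globular receptor
#'
#' Places `n_res` residues with their CA atoms on a Fibonacci sphere
#' lattice of the given radius (roughly even ~3.5 A spacing at the
#' defaults), a backbone carbonyl oxygen next to each CA, and, for
#' D/E/N/Q/Y/S/T residues, side-chain oxygen pseudo-atoms pointing
#' radially outwards — the atoms Ca2+ site detection needs. Residue names
#' cycle through a fixed pattern unless `resnames` overrides them.
#'
#' @param n_res number of residues, default 150.
#' @param seed integer seed (residue-name shuffling uses it; geometry is
#'   lattice-deterministic).
#' @param radius sphere radius, Angstrom; default 12.
#' @param resnames optional character vector of three-letter residue
#'   names, length `n_res`.
#' @param start_resno first residue number, default 1.
#' @return a `receptor`.
#' @export
make_receptor <- function(n_res = 150, seed = 1, radius = 12,
                          resnames = NULL, start_resno = 1L) {
  if (is.null(resnames)) {
    pattern <- c("GLU", "GLU", "ASN", "ASP", "GLN", "TYR", "LYS", "ARG",
                 "SER", "GLY", "LEU", "ALA", "THR", "VAL", "PHE")
    resnames <- rep_len(pattern, n_res)
  }
  stopifnot(length(resnames) == n_res)
  golden <- pi * (3 - sqrt(5))
  rows <- list()
  side_ox <- c(ASP = "OD1", GLU = "OE1", ASN = "OD1", GLN = "OE1",
               TYR = "OH", SER = "OG", THR = "OG1")
  for (i in seq_len(n_res)) {
    z <- 1 - 2 * (i - 0.5) / n_res
    r <- sqrt(max(0, 1 - z^2))
    th <- golden * (i - 1)
    u <- c(r * cos(th), r * sin(th), z)      # unit radial direction
    ca <- radius * u
    resno <- start_resno + i - 1L
    nm <- resnames[i]
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = resno, resname = nm, atom = "CA", element = "C",
      x = ca[1], y = ca[2], z = ca[3], stringsAsFactors = FALSE)
    bo <- (radius + 0.8) * u + c(0.4, 0, 0)  # backbone carbonyl O
    rows[[length(rows) + 1L]] <- data.frame(
      chain = "A", resno = resno, resname = nm, atom = "O", element = "O",
      x = bo[1], y = bo[2], z = bo[3], stringsAsFactors = FALSE)
    if (nm %in% names(side_ox)) {
      so <- (radius + 1.5) * u
      rows[[length(rows) + 1L]] <- data.frame(
        chain = "A", resno = resno, resname = nm, atom = side_ox[[nm]],
        element = "O", x = so[1], y = so[2], z = so[3], stringsAsFactors = FALSE)
      if (nm %in% c("ASP", "GLU")) {  # second carboxylate oxygen
        so2 <- (radius + 1.5) * u + c(0, 0.6, 0)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", resno = resno, resname = nm,
          atom = if (nm == "ASP") "OD2" else "OE2", element = "O",
          x = so2[1], y = so2[2], z = so2[3], stringsAsFactors = FALSE)
      }
    }
  }
  new_receptor(do.call(rbind, rows))
}

#' Alternating heparin-like ring sequence
#' @param dp chain length.
#' @param start first ring type, default `"GlcNS6S"`.
#' @return character vector of ring types alternating GlcNS6S/IdoA2S.
#' @export
hp_sequence <- function(dp, start = "GlcNS6S") {
  other <- if (start == "GlcNS6S") "IdoA2S" else "GlcNS6S"
  rep_len(c(start, other), dp)
}

# Apply a seeded random rigid jitter with RMS displacement ~ spread.
.jitter_chain <- function(chain, spread, angle_sd = 2) {
  rot <- random_small_rotation(angle_sd)
  trans <- stats::rnorm(3, 0, spread / sqrt(3))
  transform_chain(chain, rotation = rot, translation = trans)
}

# Deterministic well-separated directions for cluster centers.
.center_directions <- matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0,
                               0, 0, 1, 0, 0, -1), ncol = 3, byrow = TRUE)

#' Pose ensemble with planted clusters and polarity bias
#'
#' Each planted cluster is a rigid placement of `chain` at a distinct
#' site just outside the receptor surface (centers at least 15 A apart at
#' the defaults); members are perturbed by random rigid jitter with RMS
#' displacement about `spread` and, per cluster, a stated fraction keeps
#' the reference chain direction while the rest are flipped end-over-end
#' (180 degrees about an axis perpendicular to the chain axis). Scores
#' are drawn from cluster-specific normal laws, more favorable for
#' earlier clusters. Fully reproducible from `seed`.
#'
#' @param receptor a `receptor`, e.g. [make_receptor()].
#' @param chain the ligand `gag_chain` template.
#' @param sizes integer vector of cluster sizes (its length sets the
#'   number of clusters; at most 6).
#' @param spread RMS rigid jitter, Angstrom; default 1.
#' @param polarity_fractions fraction of each cluster keeping the
#'   reference direction; default 1 (no flips).
#' @param seed integer seed (mandatory).
#' @param score_means optional per-cluster score means, kcal/mol.
#' @param standoff distance of cluster centers beyond the receptor
#'   surface, default 8 A.
#' @return list with `ensemble` (a `pose_ensemble`), `true_labels`
#'   (named integer vector) and `true_polarity` (named character vector,
#'   `"parallel"` for unflipped members).
#' @export
make_pose_ensemble <- function(receptor, chain, sizes, spread = 1,
                               polarity_fractions = rep(1, length(sizes)),
                               seed, score_means = NULL, standoff = 8) {
  stopifnot(all(sizes >= 1), spread > 0, length(sizes) <= nrow(.center_directions))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  polarity_fractions <- rep_len(polarity_fractions, length(sizes))
  if (is.null(score_means)) score_means <- -45 + 5 * (seq_along(sizes) - 1)
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rad <- max(sqrt(rowSums(sweep(rxyz, 2, colMeans(rxyz))^2)))
  ctr <- colMeans(rxyz)
  withr::with_seed(seed, {
    poses <- list(); labels <- integer(0); polarity <- character(0)
    pid <- 0L
    for (k in seq_along(sizes)) {
      dir_k <- .center_directions[k, ]
      center <- ctr + (rad + standoff) * dir_k
      # orient the chain tangentially to the surface, deterministically per cluster
      tangent <- if (abs(dir_k[3]) < 0.9) {
        v <- c(-dir_k[2], dir_k[1], 0); v / sqrt(sum(v^2))
      } else c(1, 0, 0)
      base <- .place_chain(chain, center, tangent)
      flip_axis <- dir_k  # perpendicular to the (tangential) chain axis
      n_keep <- round(polarity_fractions[k] * sizes[k])
      for (j in seq_len(sizes[k])) {
        pid <- pid + 1L
        flipped <- j > n_keep
        pc <- base
        if (flipped) {
          pc <- transform_chain(pc, rotation_about_axis(flip_axis, pi))
        }
        pc <- .jitter_chain(pc, spread)
        id <- sprintf("p%04d", pid)
        poses[[length(poses) + 1L]] <- list(
          id = id, chain = pc, score = stats::rnorm(1, score_means[k], 1)
        )
        labels[id] <- k
        polarity[id] <- if (flipped) "antiparallel" else "parallel"
      }
    }
    list(ensemble = new_pose_ensemble(receptor, poses),
         true_labels = labels, true_polarity = polarity)
  })
}

# Rigidly place a chain: centroid at `center`, chain axis along `axis_dir`.
.place_chain <- function(chain, center, axis_dir) {
  ax <- chain_axis(chain)
  axis_dir <- axis_dir / sqrt(sum(axis_dir^2))
  v <- .cross3(ax, axis_dir)
  s <- sqrt(sum(v^2)); cth <- sum(ax * axis_dir)
  rot <- if (s < 1e-12) {
    if (cth > 0) diag(3) else rotation_about_axis(.any_perp(ax), pi)
  } else rotation_about_axis(v / s, atan2(s, cth))
  cur <- colMeans(as.matrix(chain_atoms(chain)[, c("x", "y", "z")]))
  transform_chain(chain, rotation = rot, translation = center - cur,
                  center = cur)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.any_perp <- function(v) {
  p <- if (abs(v[1]) < 0.9) .cross3(v, c(1, 0, 0)) else .cross3(v, c(0, 1, 0))
  p / sqrt(sum(p^2))
}

#' Large scored pose list
#'
#' Emulates the raw output of a docking run: `n` poses of one ligand
#' scattered around the receptor with strictly orderable scores (unless
#' planted ties are requested).
#'
#' @param n number of poses, default 1000.
#' @param seed integer seed (mandatory).
#' @param receptor,chain optional fixtures; defaults are a small
#'   [make_receptor()] globule and an HP dp4 ideal chain.
#' @param plant_ties if `TRUE`, the two worst-scored poses share one
#'   score exactly.
#' @return a `pose_ensemble` with `n` poses.
#' @export
make_scored_poses <- function(n = 1000, seed, receptor = NULL, chain = NULL,
                              plant_ties = FALSE) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (is.null(receptor)) receptor <- make_receptor(n_res = 60, seed = 1)
  if (is.null(chain)) chain <- build_ideal_chain(hp_sequence(4))
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  rad <- max(sqrt(rowSums(sweep(rxyz, 2, colMeans(rxyz))^2)))
  ctr <- colMeans(rxyz)
  withr::with_seed(seed, {
    scores <- stats::rnorm(n, -35, 8)
    while (anyDuplicated(scores)) {                      # strictly orderable
      scores[duplicated(scores)] <-
        scores[duplicated(scores)] + stats::runif(sum(duplicated(scores)), 0, 1e-6)
    }
    if (plant_ties && n >= 2L) {
      w <- order(scores, decreasing = TRUE)[1:2]
      scores[w[2]] <- scores[w[1]]
    }
    poses <- lapply(seq_len(n), function(i) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      placed <- .place_chain(chain, ctr + (rad + 6) * u, .any_perp(u))
      list(id = sprintf("p%04d", i), chain = .jitter_chain(placed, 1),
           score = scores[i])
    })
    new_pose_ensemble(receptor, poses)
  })
}

#' Per-residue energy table with planted hotspot residues
#'
#' Hotspot residues draw mean energies near `hotspot_mean`, background
#' residues near `background_mean`, both with Gaussian noise `sd`. At the
#' defaults (-5 vs 0 kcal/mol, sd 0.5) the planted set is separated from
#' the background by 10 standard deviations, so top-N recovery is
#' essentially certain.
#'
#' @param residues data.frame with columns `resname` (one-letter) and
#'   `resno`, e.g. from a receptor via [receptor_residues()]; duplicates
#'   are rejected.
#' @param hotspot_ids character residue tokens (`"K436"`) to plant.
#' @param hotspot_mean kcal/mol, default -5 (must be below
#'   `background_mean`).
#' @param background_mean kcal/mol, default 0.
#' @param sd noise, kcal/mol, default 0.5.
#' @param seed integer seed (mandatory).
#' @param id table id, default `"c1"`.
#' @return an `energy_table`.
#' @export
make_energy_table <- function(residues, hotspot_ids, hotspot_mean = -5,
                              background_mean = 0, sd = 0.5, seed, id = "c1") {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (hotspot_mean > background_mean) {
    stop("hotspot_mean must be <= background_mean (more favorable)",
         call. = FALSE)
  }
  key <- paste0(residues$resname, residues$resno)
  if (anyDuplicated(key)) stop("duplicate residues", call. = FALSE)
  if (!all(hotspot_ids %in% key)) {
    stop("hotspot_ids must be a subset of the residues", call. = FALSE)
  }
  withr::with_seed(seed, {
    mu <- ifelse(key %in% hotspot_ids, hotspot_mean, background_mean)
    new_energy_table(data.frame(
      id = id, resname = residues$resname, resno = residues$resno,
      mean = stats::rnorm(length(key), mu, sd),
      sd = abs(stats::rnorm(length(key), 0.4, 0.1)),
      stringsAsFactors = FALSE
    ))
  })
}

#' Trimer fragment library from an ideal long chain
#'
#' Splits a dp-11 chain into its 9 overlapping trimers (the "true"
#' fragment poses, optionally jittered rigidly), then adds `n_decoys`
#' randomly placed trimer poses per phase. True fragments receive more
#' favorable scores than decoys so score-based beam pruning retains them.
#'
#' @param chain_dp11 a dp-11 `gag_chain`.
#' @param jitter RMS rigid jitter of true fragments, Angstrom; default 0.
#' @param n_decoys decoys per phase, default 50.
#' @param seed integer seed (mandatory).
#' @return list with `phaseA`, `phaseB` (lists of `trimer_pose`),
#'   and `truth` (the ordered true fragment ids).
#' @export
make_fragment_library <- function(chain_dp11, jitter = 0, n_decoys = 50, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (chain_dp11$dp != 11L) stop("chain must have dp 11", call. = FALSE)
  if (jitter < 0) stop("jitter must be >= 0", call. = FALSE)
  trimers <- split_into_trimers(chain_dp11)
  withr::with_seed(seed, {
    phaseA <- list(); phaseB <- list(); truth <- character(0)
    for (t in trimers) {
      ch <- t$chain
      if (jitter > 0) ch <- .jitter_chain(ch, jitter, angle_sd = 1)
      id <- sprintf("true_%s%02d", t$phase, t$start_index)
      pose <- new_trimer_pose(ch, t$phase, stats::rnorm(1, -8, 0.5), id)
      if (t$phase == "A") phaseA[[length(phaseA) + 1L]] <- pose
      else phaseB[[length(phaseB) + 1L]] <- pose
      truth <- c(truth, id)
    }
    all_xyz <- as.matrix(chain_atoms(chain_dp11)[, c("x", "y", "z")])
    ctr <- colMeans(all_xyz)
    span <- max(sqrt(rowSums(sweep(all_xyz, 2, ctr)^2)))
    for (ph in c("A", "B")) {
      proto <- if (ph == "A") trimers[[1]]$chain else trimers[[2]]$chain
      for (j in seq_len(n_decoys)) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        pos <- ctr + stats::runif(1, span + 5, span + 25) * u
        ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
        dc <- .place_chain(proto, pos, ax)
        pose <- new_trimer_pose(dc, ph, stats::rnorm(1, -4, 0.5),
                                sprintf("decoy_%s%03d", ph, j))
        if (ph == "A") phaseA[[length(phaseA) + 1L]] <- pose
        else phaseB[[length(phaseB) + 1L]] <- pose
      }
    }
    list(phaseA = phaseA, phaseB = phaseB, truth = truth)
  })
}

#' Ion trajectory with planted coordination sites
#'
#' One ion per planted site. Each ion sits in a 2.4 A coordination shell
#' of its site's side-chain oxygens for contiguous residence blocks
#' totalling the planned occupancy, and wanders at least 8 A away from
#' every site otherwise. To guarantee the planted geometry, the site
#' residues' side-chain oxygens are drawn into a pocket around the
#' bound-ion position (side chains reorienting to coordinate the ion);
#' the repositioned receptor is returned with the trajectory.
#'
#' @param receptor a `receptor` from [make_receptor()].
#' @param sites list of character vectors of residue tokens (`"E5"`
#'   style); each residue must exist and carry a side-chain oxygen.
#' @param occupancies_ns planned occupancy per site; each must be
#'   expressible as a whole number of frames and fit in the trajectory.
#' @param length_ns trajectory length, default 100.
#' @param frame_interval_ps frame interval, default 100 ps; must divide
#'   the trajectory length and each occupancy.
#' @param seed integer seed (mandatory).
#' @return list with `traj` (an `ion_trajectory` whose receptor carries
#'   the pocket geometry) and `true_sites` (list of `residues`,
#'   `occupancy_ns`, `position`).
#' @export
make_ion_trajectory <- function(receptor, sites, occupancies_ns,
                                length_ns = 100, frame_interval_ps = 100,
                                seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(length(sites) == length(occupancies_ns), frame_interval_ps > 0)
  n_frames <- length_ns * 1000 / frame_interval_ps
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop("frame interval must divide the trajectory length", call. = FALSE)
  }
  n_frames <- as.integer(round(n_frames))
  occ_frames <- occupancies_ns * 1000 / frame_interval_ps
  if (any(abs(occ_frames - round(occ_frames)) > 1e-9)) {
    stop("occupancies must be whole numbers of frames", call. = FALSE)
  }
  occ_frames <- as.integer(round(occ_frames))
  if (any(occ_frames > n_frames)) {
    stop("planned occupancy exceeds trajectory length", call. = FALSE)
  }
  res <- receptor_residues(receptor)
  res_key <- .residue_key(res$resname, res$resno)
  at <- receptor$atoms
  side_names <- setdiff(CA_COORDINATING_OXYGENS, "O")
  site_pos <- list()
  ctr <- colMeans(as.matrix(at[, c("x", "y", "z")]))
  for (s in seq_along(sites)) {
    toks <- sites[[s]]
    if (!all(toks %in% res_key)) {
      stop("site residues absent from receptor: ",
           paste(setdiff(toks, res_key), collapse = ", "), call. = FALSE)
    }
    resnos <- as.integer(sub("^[A-Z]", "", toks))
    sel <- at$resno %in% resnos & at$atom %in% side_names
    if (sum(sel) < 2L) {
      stop("site needs >= 2 side-chain oxygens on its residues", call. = FALSE)
    }
    # bound-ion position: radially beyond the site residues' CA centroid
    ca <- at[at$resno %in% resnos & at$atom == "CA", c("x", "y", "z")]
    u <- colMeans(as.matrix(ca)) - ctr
    u <- u / sqrt(sum(u^2))
    ion <- ctr + u * (max(sqrt(rowSums(sweep(as.matrix(at[, c("x", "y", "z")]),
                                             2, ctr)^2))) + 4)
    # draw the site's side-chain oxygens into a 2.4 A shell around it
    ox_idx <- which(sel)
    for (q in seq_along(ox_idx)) {
      ang <- 2 * pi * (q - 1) / length(ox_idx)
      perp1 <- .any_perp(u); perp2 <- .cross3(u, perp1)
      shell <- ion + 2.4 * (cos(ang) * perp1 + sin(ang) * perp2)
      at$x[ox_idx[q]] <- shell[1]; at$y[ox_idx[q]] <- shell[2]
      at$z[ox_idx[q]] <- shell[3]
    }
    site_pos[[s]] <- ion
  }
  pocket_receptor <- new_receptor(at, receptor$numbering_scheme)
  withr::with_seed(seed, {
    rows <- list()
    for (s in seq_along(sites)) {
      bound <- rep(FALSE, n_frames)
      nb <- occ_frames[s]
      if (nb > 0L) {
        # one or two contiguous residence blocks
        n_blocks <- if (nb >= 4L && stats::runif(1) < 0.5) 2L else 1L
        lens <- if (n_blocks == 2L) {
          l1 <- sample(seq_len(nb - 1L), 1); c(l1, nb - l1)
        } else nb
        free <- n_frames - nb
        gaps <- if (n_blocks == 2L && free >= 1L) {
          g <- sort(sample(0:free, 2)); c(g[1], g[2] - g[1])
        } else c(if (free > 0L) sample(0:free, 1) else 0L, 0L)
        pos <- gaps[1]
        for (b in seq_len(n_blocks)) {
          bound[(pos + 1L):(pos + lens[b])] <- TRUE
          pos <- pos + lens[b] + gaps[min(b + 1L, length(gaps))]
        }
      }
      ion_id <- sprintf("CA%d", s)
      away_dir <- .any_perp(site_pos[[s]] / sqrt(sum(site_pos[[s]]^2)))
      for (f in seq_len(n_frames)) {
        xyz <- if (bound[f]) {
          site_pos[[s]] + stats::rnorm(3, 0, 0.05)
        } else {
          # >= 8 A from every planted site
          site_pos[[s]] + away_dir * (15 + stats::runif(1, 0, 10)) +
            stats::rnorm(3, 0, 0.5)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          time_ps = (f - 1L) * frame_interval_ps, ion = ion_id,
          x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
      }
    }
    frames <- do.call(rbind, rows)
    true_sites <- lapply(seq_along(sites), function(s) {
      list(residues = sites[[s]], occupancy_ns = occupancies_ns[s],
           position = site_pos[[s]])
    })
    list(traj = new_ion_trajectory(pocket_receptor, frames,
                                   interval_ps = frame_interval_ps,
                                   length_ns = length_ns),
         true_sites = true_sites)
  })
}
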