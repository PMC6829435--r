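# Fragment-based assembly of long GAG chains (target dp11) from docked
# trimer poses: overlap compatibility, beam-limited breadth-first growth,
# clash filtering and 4 A RMSD deduplication.
#
# Scheme: trimer fragments overlap by two rings (one shared disaccharide),
# so consecutive fragments come from alternating phases A/B and a dp-11
# chain uses 9 fragments (3 rings + 8 extensions of one new ring each).

#' Construct a trimer fragment pose
#'
#' @param chain a dp-3 `gag_chain`.
#' @param phase `"A"` or `"B"`.
#' @param score docking score, kcal/mol.
#' @param id fragment identifier.
#' @return a `trimer_pose` object.
#' @export
new_trimer_pose <- function(chain, phase, score, id) {
  if (chain$dp != 3L) stop("trimer poses must have dp 3", call. = FALSE)
  if (!phase %in% c("A", "B")) stop("phase must be 'A' or 'B'", call. = FALSE)
  structure(list(chain = chain, phase = phase, score = score, id = id),
            class = "trimer_pose")
}

.ring_xyz <- function(ring) as.matrix(ring$atoms[, c("x", "y", "z")])

# RMSD over the two overlapping rings: f1 rings (2,3) vs f2 rings (1,2),
# atoms matched by name within each ring, receptor frame, no superposition.
.overlap_rmsd <- function(f1, f2) {
  sq <- 0; nat <- 0L
  for (k in 1:2) {
    r1 <- f1$chain$rings[[k + 1L]]; r2 <- f2$chain$rings[[k]]
    if (r1$chem_type != r2$chem_type) return(NA_real_)
    idx <- match(r1$atoms$name, r2$atoms$name)
    if (anyNA(idx)) return(NA_real_)
    d <- .ring_xyz(r1) - .ring_xyz(r2)[idx, , drop = FALSE]
    sq <- sq + sum(d^2); nat <- nat + nrow(d)
  }
  sqrt(sq / nat)
}

#' Geometric compatibility of two trimer fragments
#'
#' Fragments are compatible when `f2` can extend `f1` by one ring: they
#' come from opposite phases, the two overlapping rings match in chemical
#' type, and the RMSD between `f1`'s last two rings and `f2`'s first two
#' rings (atoms matched by name, receptor frame, no superposition) is at
#' most `overlap_rmsd_cutoff`.
#'
#' @param f1,f2 `trimer_pose` objects; `f1$phase != f2$phase`.
#' @param overlap_rmsd_cutoff Angstrom, default 1.0.
#' @return list with `compatible` (logical) and `rmsd` (NA when the ring
#'   types do not match).
#' @export
fragment_compatible <- function(f1, f2, overlap_rmsd_cutoff = 1.0) {
  if (f1$phase == f2$phase) {
    stop("fragments of the same phase cannot overlap by two rings",
         call. = FALSE)
  }
  r <- .overlap_rmsd(f1, f2)
  list(compatible = !is.na(r) && r <= overlap_rmsd_cutoff, rmsd = r)
}

#' Assemble long GAG chains from trimer fragment poses
#'
#' Breadth-first growth over the fragment compatibility graph, starting
#' from every phase-A pose and alternating phases. Each extension appends
#' the new fragment's third ring; overlapping-ring coordinates are taken
#' from the earlier fragment. Partial chains are pruned to `beam_cap` by
#' best (lowest) combined score, ties broken by the fragment-id tuple.
#' The combined score is the sum of member fragment scores.
#'
#' @param phaseA,phaseB lists of `trimer_pose` objects.
#' @param target_dp odd target chain length, default 11.
#' @param overlap_rmsd_cutoff Angstrom, default 1.0.
#' @param beam_cap maximum number of partial chains kept per growth step,
#'   default 1e5.
#' @return list of `assembled_chain` objects (fields `chain`,
#'   `fragment_ids`, `score`, `max_overlap_rmsd`), ordered by score.
#'   Empty when the target is unreachable.
#' @export
assemble_chains <- function(phaseA, phaseB, target_dp = 11,
                            overlap_rmsd_cutoff = 1.0, beam_cap = 1e5) {
  if (length(phaseA) == 0L || length(phaseB) == 0L) {
    stop("both phase pose sets must be non-empty", call. = FALSE)
  }
  if (target_dp < 3L || target_dp %% 2L == 0L) {
    stop("target_dp must be odd and >= 3", call. = FALSE)
  }
  n_frag <- target_dp - 2L
  pools <- list(A = phaseA, B = phaseB)
  # Precompute compatible extensions for each fragment in each pool.
  ext <- list(
    A = .extension_table(phaseA, phaseB, overlap_rmsd_cutoff),
    B = .extension_table(phaseB, phaseA, overlap_rmsd_cutoff)
  )
  beam <- lapply(seq_along(phaseA), function(i) {
    list(frags = i, phase = "A", score = phaseA[[i]]$score, max_rmsd = 0,
         chain = phaseA[[i]]$chain)
  })
  step <- 1L
  while (step < n_frag && length(beam) > 0L) {
    nxt <- list()
    for (st in beam) {
      cand <- ext[[st$phase]][[st$frags[length(st$frags)]]]
      if (length(cand$idx) == 0L) next
      other <- if (st$phase == "A") "B" else "A"
      for (k in seq_along(cand$idx)) {
        j <- cand$idx[k]
        frag <- pools[[other]][[j]]
        nxt[[length(nxt) + 1L]] <- list(
          frags = c(st$frags, j), phase = other,
          score = st$score + frag$score,
          max_rmsd = max(st$max_rmsd, cand$rmsd[k]),
          chain = .append_ring(st$chain, frag)
        )
      }
    }
    if (length(nxt) > beam_cap) {
      sc <- vapply(nxt, function(s) s$score, numeric(1))
      key <- vapply(nxt, function(s) paste(s$frags, collapse = ","), character(1))
      nxt <- nxt[order(sc, key)[seq_len(beam_cap)]]
    }
    beam <- nxt
    step <- step + 1L
  }
  if (step < n_frag) return(list())
  ids <- list(A = vapply(phaseA, function(f) as.character(f$id), character(1)),
              B = vapply(phaseB, function(f) as.character(f$id), character(1)))
  out <- lapply(beam, function(st) {
    phases <- rep(c("A", "B"), length.out = length(st$frags))
    structure(
      list(chain = st$chain,
           fragment_ids = mapply(function(ph, i) ids[[ph]][i], phases, st$frags,
                                 USE.NAMES = FALSE),
           score = st$score, max_overlap_rmsd = st$max_rmsd),
      class = "assembled_chain"
    )
  })
  sc <- vapply(out, function(a) a$score, numeric(1))
  out[order(sc, vapply(out, function(a) paste(a$fragment_ids, collapse = ","),
                       character(1)))]
}

.extension_table <- function(from, to, cutoff) {
  lapply(from, function(f1) {
    rmsd <- vapply(to, function(f2) {
      r <- .overlap_rmsd(f1, f2)
      if (is.na(r)) Inf else r
    }, numeric(1))
    ok <- which(rmsd <= cutoff)
    list(idx = ok, rmsd = rmsd[ok])
  })
}

# Extend a growing chain by the third ring of `frag` (overlap rings keep
# the earlier fragment's coordinates).
.append_ring <- function(chain, frag) {
  new_gag_chain(c(chain$rings, list(frag$chain$rings[[3]])),
                gag_class = chain$gag_class)
}

#' Remove assembled chains that clash with the receptor or themselves
#'
#' A chain is dropped when any of its atoms lies closer than
#' `protein_clash` to any receptor atom, or when atoms of two
#' non-adjacent rings (|i - j| >= 2) come closer than `self_clash`.
#'
#' @param chains list of `assembled_chain` (or `gag_chain`) objects.
#' @param receptor a `receptor`.
#' @param protein_clash Angstrom, default 2.0.
#' @param self_clash Angstrom, default 1.5.
#' @return the surviving subset of `chains`.
#' @export
clash_filter <- function(chains, receptor, protein_clash = 2.0,
                         self_clash = 1.5) {
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  keep <- vapply(chains, function(a) {
    ch <- if (inherits(a, "assembled_chain")) a$chain else a
    at <- chain_atoms(ch)
    gxyz <- as.matrix(at[, c("x", "y", "z")])
    cross <- outer(rowSums(gxyz^2), rowSums(rxyz^2), "+") - 2 * gxyz %*% t(rxyz)
    if (min(cross) < protein_clash^2) return(FALSE)
    ri <- at$ring_index
    self <- outer(rowSums(gxyz^2), rowSums(gxyz^2), "+") - 2 * gxyz %*% t(gxyz)
    nonadj <- abs(outer(ri, ri, "-")) >= 2L
    !any(self[nonadj] < self_clash^2)
  }, logical(1))
  chains[keep]
}

#' Deduplicate assembled chains by RMSD leader clustering
#'
#' Greedy leader clustering in the receptor frame: chains are visited by
#' ascending combined score; a chain joins the first existing
#' representative within `rmsd_cutoff` (all-atom index-matched RMSD, no
#' superposition), otherwise it founds a new representative. This is the
#' duplicate filter applied to the assembled-chain library.
#'
#' @param chains list of `assembled_chain` objects of one dp.
#' @param rmsd_cutoff Angstrom, default 4.0.
#' @return list of representative `assembled_chain`s, ordered by score,
#'   each annotated with `n_members` (cluster occupancy).
#' @export
dedup_chains <- function(chains, rmsd_cutoff = 4.0) {
  if (length(chains) == 0L) return(list())
  dps <- vapply(chains, function(a) a$chain$dp, integer(1))
  if (length(unique(dps)) > 1L) {
    stop("all chains must have the same dp", call. = FALSE)
  }
  sc <- vapply(chains, function(a) a$score, numeric(1))
  key <- vapply(chains, function(a) paste(a$fragment_ids, collapse = ","),
                character(1))
  ord <- order(sc, key)
  reps <- list(); members <- integer(0)
  for (i in ord) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (pose_rmsd(chains[[i]]$chain, reps[[r]]$chain) <= rmsd_cutoff) {
        members[r] <- members[r] + 1L
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- chains[[i]]
      members <- c(members, 1L)
    }
  }
  for (r in seq_along(reps)) reps[[r]]$n_members <- members[r]
  reps
}
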