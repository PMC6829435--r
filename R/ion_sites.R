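# Ca2+ coordination-site detection from trajectory frames: per-frame
# coordination sets, site grouping with occupancy in ns, replica
# consensus, and comparison against reference site lists.

# Oxygen atom names recognised as Ca2+ coordination partners: side-chain
# carboxylate / amide / hydroxyl oxygens plus the backbone carbonyl.
CA_COORDINATING_OXYGENS <- c("OD1", "OD2", "OE1", "OE2", "OH", "OG", "OG1", "O")

.residue_key <- function(resname3, resno) {
  one <- AA_THREE_TO_ONE[resname3]
  one[is.na(one)] <- "X"
  paste0(one, resno)
}

#' Residues coordinating an ion in one frame
#'
#' Returns the residues contributing at least one oxygen atom (side-chain
#' carboxylate, amide, hydroxyl, or backbone carbonyl) within `cutoff` of
#' the ion. When fewer than `min_oxygens` coordinating oxygens are found
#' in total, the ion is considered unbound and the empty set is returned:
#' genuine Ca2+ coordination engages several oxygens at once.
#'
#' @param ion_xyz 3-vector, ion position.
#' @param receptor a `receptor`.
#' @param cutoff coordination distance, Angstrom; default 3.2 (the upper
#'   end of the Ca-O coordination range).
#' @param min_oxygens minimum number of coordinating oxygens, default 2.
#' @return character vector of residue tokens (`"E405"` style), sorted by
#'   residue number; empty when unbound.
#' @export
frame_coordination <- function(ion_xyz, receptor, cutoff = 3.2, min_oxygens = 2) {
  if (length(ion_xyz) != 3L || anyNA(ion_xyz)) {
    stop("ion position must be a finite 3-vector", call. = FALSE)
  }
  at <- receptor$atoms
  ox <- at[at$element == "O" & at$atom %in% CA_COORDINATING_OXYGENS, , drop = FALSE]
  if (nrow(ox) == 0L) return(character(0))
  d2 <- (ox$x - ion_xyz[1])^2 + (ox$y - ion_xyz[2])^2 + (ox$z - ion_xyz[3])^2
  hit <- ox[d2 <= cutoff^2, , drop = FALSE]
  if (nrow(hit) < min_oxygens) return(character(0))
  hit <- hit[order(hit$resno), ]
  unique(.residue_key(hit$resname, hit$resno))
}

.jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Detect ion binding sites and their occupancy from a trajectory
#'
#' Computes the coordination residue set for every (frame, ion) pair and
#' groups non-empty sets into sites: a frame set joins the first site
#' whose founding residue set it matches with Jaccard similarity >= 0.5,
#' otherwise it founds a new site. Site occupancy is the number of
#' assigned frames times the frame interval, in ns. Sites below
#' `min_report_ns` are dropped.
#'
#' @param traj an `ion_trajectory`.
#' @param cutoff,min_oxygens passed to [frame_coordination()].
#' @param jaccard_min site-identity threshold, default 0.5.
#' @param min_report_ns minimum occupancy to report, default 10 ns.
#' @param round_ns optional rounding granularity for table-style output
#'   (e.g. 5 ns); default `NULL` reports exact frame-count x interval.
#' @return list of `ion_site` objects: `residues` (union over assigned
#'   frames), `occupancy_ns`, `n_frames`, `position` (mean ion position),
#'   ordered by decreasing occupancy.
#' @export
detect_sites <- function(traj, cutoff = 3.2, min_oxygens = 2,
                         jaccard_min = 0.5, min_report_ns = 10,
                         round_ns = NULL) {
  fr <- traj$frames
  fr <- fr[order(fr$time_ps, fr$ion), ]
  sites <- list()
  for (i in seq_len(nrow(fr))) {
    res <- frame_coordination(c(fr$x[i], fr$y[i], fr$z[i]), traj$receptor,
                              cutoff = cutoff, min_oxygens = min_oxygens)
    if (length(res) == 0L) next
    assigned <- FALSE
    for (s in seq_along(sites)) {
      if (.jaccard(res, sites[[s]]$founding) >= jaccard_min) {
        sites[[s]]$residues <- union(sites[[s]]$residues, res)
        sites[[s]]$n_frames <- sites[[s]]$n_frames + 1L
        sites[[s]]$pos_sum <- sites[[s]]$pos_sum + c(fr$x[i], fr$y[i], fr$z[i])
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      sites[[length(sites) + 1L]] <- list(
        founding = res, residues = res, n_frames = 1L,
        pos_sum = c(fr$x[i], fr$y[i], fr$z[i])
      )
    }
  }
  out <- lapply(sites, function(s) {
    occ <- s$n_frames * traj$interval_ps / 1000
    if (!is.null(round_ns)) occ <- round(occ / round_ns) * round_ns
    structure(
      list(residues = s$residues[order(as.integer(sub("^[A-Z]", "", s$residues)))],
           occupancy_ns = occ, n_frames = s$n_frames,
           position = s$pos_sum / s$n_frames),
      class = "ion_site"
    )
  })
  out <- Filter(function(s) s$occupancy_ns >= min_report_ns, out)
  occ <- vapply(out, function(s) s$occupancy_ns, numeric(1))
  out[order(-occ)]
}

#' @export
print.ion_site <- function(x, ...) {
  cat(sprintf("<ion_site> %s: %.1f ns (%d frames)\n",
              paste(x$residues, collapse = ", "), x$occupancy_ns, x$n_frames))
  invisible(x)
}

#' Merge ion sites across simulation replicas
#'
#' Sites from different replicas are merged when their residue sets match
#' with Jaccard similarity >= `jaccard_min`; the support of a merged site
#' is the number of replicas contributing to it. A site found in every
#' replica (support n/n) is the consensus outcome.
#'
#' @param replica_sites list (one entry per replica) of lists of
#'   `ion_site` objects, e.g. from [detect_sites()] per replica.
#' @param jaccard_min default 0.5.
#' @return list of merged sites: `residues` (union), `support`
#'   (replicas), `occupancy_ns` (per-replica vector), ordered by
#'   decreasing support.
#' @export
replica_consensus <- function(replica_sites, jaccard_min = 0.5) {
  if (length(replica_sites) < 1L) stop("need at least one replica", call. = FALSE)
  merged <- list()
  for (r in seq_along(replica_sites)) {
    for (site in replica_sites[[r]]) {
      hit <- 0L
      for (k in seq_along(merged)) {
        if (.jaccard(site$residues, merged[[k]]$founding) >= jaccard_min) {
          hit <- k
          break
        }
      }
      if (hit == 0L) {
        merged[[length(merged) + 1L]] <- list(
          founding = site$residues, residues = site$residues,
          replicas = r, occupancy_ns = stats::setNames(site$occupancy_ns,
                                                       paste0("MD", r))
        )
      } else {
        merged[[hit]]$residues <- union(merged[[hit]]$residues, site$residues)
        merged[[hit]]$replicas <- union(merged[[hit]]$replicas, r)
        merged[[hit]]$occupancy_ns <- c(merged[[hit]]$occupancy_ns,
                                        stats::setNames(site$occupancy_ns,
                                                        paste0("MD", r)))
      }
    }
  }
  out <- lapply(merged, function(m) {
    list(residues = m$residues, support = length(m$replicas),
         n_replicas = length(replica_sites), occupancy_ns = m$occupancy_ns)
  })
  sup <- vapply(out, function(m) m$support, integer(1))
  out[order(-sup)]
}

#' Match predicted ion sites against a reference site list
#'
#' Greedy one-to-one matching in prediction order: a predicted site
#' matches a reference site when their residue sets share at least
#' `min_shared` residues, or — when either side carries no residue set —
#' when their ion positions are within `position_tol`. Each reference
#' site is consumed by at most one prediction.
#'
#' @param predicted,reference lists of sites (each with `residues` and
#'   optionally `position`).
#' @param min_shared default 2.
#' @param position_tol Angstrom, default 3.5.
#' @return list with `matched` (count) and `mapping` (data.frame of
#'   predicted index -> reference index).
#' @export
match_reference_sites <- function(predicted, reference, min_shared = 2,
                                  position_tol = 3.5) {
  used <- rep(FALSE, length(reference))
  pairs <- list()
  for (i in seq_along(predicted)) {
    p <- predicted[[i]]
    for (j in seq_along(reference)) {
      if (used[j]) next
      r <- reference[[j]]
      by_res <- length(p$residues) > 0L && length(r$residues) > 0L
      ok <- if (by_res) {
        length(intersect(p$residues, r$residues)) >= min_shared
      } else if (!is.null(p$position) && !is.null(r$position)) {
        sqrt(sum((p$position - r$position)^2)) <= position_tol
      } else FALSE
      if (ok) {
        used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- data.frame(predicted = i, reference = j)
        break
      }
    }
  }
  list(matched = length(pairs),
       mapping = if (length(pairs)) do.call(rbind, pairs)
                 else data.frame(predicted = integer(0), reference = integer(0)))
}
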