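# Binding-energy analysis: hotspot residues from per-residue decomposition
# tables, top-10 overlap matrices, the pose-stability filter, and Welch's
# t-test for comparing binding energies between models.

#' Top binding residues of an energy table
#'
#' The `n` residues with the most favorable (lowest) mean per-residue
#' binding energy, ordered from most favorable. Ties are broken by
#' ascending residue number, then residue name, so the set is
#' reproducible. If the table holds fewer than `n` residues all are
#' returned and the result is flagged.
#'
#' @param table an `energy_table` with one row per residue.
#' @param n number of residues, default 10.
#' @return a `hotspot_set`: list with `residues` (character vector like
#'   `"K436"`, most favorable first), `energies`, `source`,
#'   `warning_flag`.
#' @export
top_residues <- function(table, n = 10) {
  key <- paste0(table$resname, table$resno)
  if (anyDuplicated(key)) {
    stop("energy table has duplicate residues; aggregate before ranking",
         call. = FALSE)
  }
  ord <- order(table$mean, table$resno, table$resname)
  flag <- nrow(table) < n
  take <- ord[seq_len(min(n, nrow(table)))]
  structure(
    list(residues = key[take], energies = table$mean[take],
         source = if (length(unique(table$id)) == 1L) table$id[1] else NA_character_,
         warning_flag = flag),
    class = "hotspot_set"
  )
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("<hotspot_set> %s%s\n", paste(x$residues, collapse = ", "),
              if (isTRUE(x$warning_flag)) " [short]" else ""))
  invisible(x)
}

#' Overlap matrix of hotspot sets
#'
#' Entry (i, j) is the number of residues (identified by name + number)
#' shared by sets i and j; the diagonal is the set size. This is the
#' "common residues in the top 10" similarity summary used to compare
#' binding poses across clusters or across GAG types.
#'
#' @param sets list of `hotspot_set` objects (or plain character vectors
#'   of residue tokens); optionally named.
#' @return symmetric integer matrix with set labels as dimnames.
#' @export
overlap_matrix <- function(sets) {
  if (length(sets) < 1L) stop("need at least one hotspot set", call. = FALSE)
  res <- lapply(sets, function(s) if (inherits(s, "hotspot_set")) s$residues else s)
  labs <- names(sets)
  if (is.null(labs) || any(labs == "")) labs <- paste0("set", seq_along(sets))
  k <- length(res)
  m <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    m[i, j] <- length(intersect(res[[i]], res[[j]]))
  }
  m
}

#' Pose-weighted aggregation of per-cluster energy tables
#'
#' Averages per-residue energies over all analysed poses of all clusters
#' of one GAG. Each table is weighted by the number of poses it averages
#' (its `n_poses` attribute), i.e. the aggregation is pose-weighted, not
#' cluster-weighted; `weighting = "cluster"` gives the unweighted
#' cluster mean for comparison.
#'
#' @param tables list of `energy_table`s sharing one residue universe.
#' @param weighting `"pose"` (default) or `"cluster"`.
#' @return an `energy_table` with id `"aggregate"`; sd columns combine as
#'   the weighted RMS of member sds.
#' @export
aggregate_per_gag <- function(tables, weighting = c("pose", "cluster")) {
  weighting <- match.arg(weighting)
  if (length(tables) < 1L) stop("need at least one table", call. = FALSE)
  keys <- lapply(tables, function(t) sort(paste0(t$resname, t$resno)))
  if (length(unique(vapply(keys, paste, character(1), collapse = ","))) > 1L) {
    stop("tables do not share a residue universe", call. = FALSE)
  }
  w <- vapply(tables, function(t) {
    np <- attr(t, "n_poses"); if (is.null(np)) 1 else as.numeric(np)
  }, numeric(1))
  if (weighting == "cluster") w <- rep(1, length(tables))
  ref <- tables[[1]][order(tables[[1]]$resno, tables[[1]]$resname), ]
  key0 <- paste0(ref$resname, ref$resno)
  means <- sapply(tables, function(t) {
    t$mean[match(key0, paste0(t$resname, t$resno))]
  })
  sds <- sapply(tables, function(t) {
    t$sd[match(key0, paste0(t$resname, t$resno))]
  })
  means <- matrix(means, nrow = length(key0))
  sds <- matrix(sds, nrow = length(key0))
  wm <- as.vector(means %*% w) / sum(w)
  wsd <- sqrt(as.vector(sds^2 %*% w) / sum(w))
  new_energy_table(
    data.frame(id = "aggregate", resname = ref$resname, resno = ref$resno,
               mean = wm, sd = wsd, stringsAsFactors = FALSE),
    n_poses = sum(w)
  )
}

#' Stability of a binding pose from its MM-GBSA binding energy
#'
#' A pose is `"unstable"` when its mean binding free energy is higher
#' (less favorable) than the threshold, strictly: a pose exactly at the
#' threshold counts as stable. The default threshold of -15 kcal/mol is
#' the filter applied to docked poses after MD rescoring.
#'
#' @param dG_mean mean binding free energy, kcal/mol (vectorised).
#' @param threshold kcal/mol, default -15.
#' @return character vector of `"stable"` / `"unstable"`.
#' @export
stability_flag <- function(dG_mean, threshold = -15) {
  ifelse(dG_mean > threshold, "unstable", "stable")
}

#' Welch's two-sided t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' used to compare binding free energies between structural models.
#' The degenerate case of two zero-variance samples with equal means
#' (where the statistic is 0/0) returns t = 0, p = 1.
#'
#' @param samplesA,samplesB numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_ttest <- function(samplesA, samplesB) {
  if (length(samplesA) < 2L || length(samplesB) < 2L) {
    stop("each sample needs n >= 2", call. = FALSE)
  }
  if (!all(is.finite(c(samplesA, samplesB)))) {
    stop("samples must be finite", call. = FALSE)
  }
  vA <- stats::var(samplesA); vB <- stats::var(samplesB)
  if (vA == 0 && vB == 0) {
    if (mean(samplesA) == mean(samplesB)) {
      return(list(t = 0, df = length(samplesA) + length(samplesB) - 2, p = 1))
    }
    return(list(t = sign(mean(samplesA) - mean(samplesB)) * Inf,
                df = length(samplesA) + length(samplesB) - 2, p = 0))
  }
  ht <- stats::t.test(samplesA, samplesB, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
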