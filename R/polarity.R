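# Binding-pose polarity: orientation of a docked GAG relative to its
# reducing / non-reducing ends, summarised per cluster.

#' Orientation of one pose relative to a reference axis
#'
#' A pose is `"parallel"` when the dot product of its chain axis (the
#' non-reducing -> reducing direction, [chain_axis()]) with the reference
#' axis is >= 0, `"antiparallel"` otherwise. The zero boundary maps to
#' `"parallel"` by convention.
#'
#' @param pose a `gag_chain` with dp >= 2.
#' @param reference_axis unit 3-vector.
#' @return `"parallel"` or `"antiparallel"`.
#' @export
pose_orientation <- function(pose, reference_axis) {
  nrm <- sqrt(sum(reference_axis^2))
  if (abs(nrm - 1) > 1e-6) {
    stop("reference_axis must be a unit vector", call. = FALSE)
  }
  if (sum(chain_axis(pose) * reference_axis) >= 0) "parallel" else "antiparallel"
}

#' Polarity summary of one pose cluster
#'
#' The reference axis is the chain axis of the cluster's top-scored pose
#' (deterministic and cluster-local); every member is classified
#' parallel/antiparallel against it and the counts are reported as
#' (majority, minority) — the `"17/2"`-style presentation used for
#' docking summaries. The fixed-direction (parallel, antiparallel) pair
#' is returned alongside.
#'
#' @param ensemble a `pose_ensemble` holding the poses of one cluster.
#' @param reference one of `"top-pose"` (default) or `"principal-axis"`
#'   (mean of member axes, majority-sign-aligned).
#' @return list with `majority`, `minority`, `parallel`, `antiparallel`,
#'   `reference_axis`, `orientations` (named character vector), and
#'   `label` (the `"a/b"` majority/minority string).
#' @export
cluster_polarity <- function(ensemble, reference = c("top-pose", "principal-axis")) {
  reference <- match.arg(reference)
  poses <- ensemble$poses
  if (length(poses) == 0L) stop("cluster is empty", call. = FALSE)
  axes <- t(vapply(poses, function(p) chain_axis(p$chain), numeric(3)))
  ref <- if (reference == "top-pose") {
    scores <- vapply(poses, function(p) p$score, numeric(1))
    axes[order(scores, seq_along(scores))[1], ]
  } else {
    first <- axes[1, ]
    signs <- sign(axes %*% first)
    signs[signs == 0] <- 1
    v <- colSums(axes * as.vector(signs))
    v / sqrt(sum(v^2))
  }
  orient <- vapply(poses, function(p) pose_orientation(p$chain, ref), character(1))
  names(orient) <- vapply(poses, function(p) as.character(p$id), character(1))
  par <- sum(orient == "parallel"); anti <- length(orient) - par
  list(
    majority = max(par, anti), minority = min(par, anti),
    parallel = par, antiparallel = anti,
    reference_axis = ref, orientations = orient,
    label = sprintf("%d/%d", max(par, anti), min(par, anti))
  )
}

#' Polarity summaries for every cluster of a clustering result
#'
#' @param ensemble a `pose_ensemble`.
#' @param result a `cluster_result` over the same poses.
#' @param reference passed to [cluster_polarity()].
#' @return data.frame with one row per cluster: `cluster`, `size`,
#'   `majority`, `minority`, `polarity` (the `"a/b"` label).
#' @export
polarity_report <- function(ensemble, result, reference = "top-pose") {
  groups <- split_by_cluster(ensemble, result)
  ks <- setdiff(names(groups), "noise")
  rows <- lapply(ks, function(k) {
    p <- cluster_polarity(groups[[k]], reference = reference)
    data.frame(cluster = as.integer(k), size = length(groups[[k]]$poses),
               majority = p$majority, minority = p$minority,
               polarity = p$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
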