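# GAG chain model: rings, chains, geometric primitives.
#
# Conventions used throughout the package:
#   * coordinates are in Angstrom,
#   * ring 0 is the NON-REDUCING end of the chain; the chain axis points
#     from the non-reducing end towards the reducing end,
#   * residue numbers are 1-based as in PDB files.

#' Monosaccharide vocabulary
#'
#' The closed set of monosaccharide ring types the package understands,
#' covering heparin (HP), chondroitin-6-sulfate (CS6) and dermatan
#' sulfate (DS) building blocks.
#'
#' @format Character vector of chemical type labels.
#' @export
GAG_RING_TYPES <- c("GlcNS6S", "IdoA2S", "IdoA", "GlcA", "GalNAc6S", "GlcNS")

# Families used by the HP alternation invariant.
.glcn_family <- c("GlcNS6S", "GlcNS")
.idoa_family <- c("IdoA2S", "IdoA")

#' Pseudo-atom template of one monosaccharide ring
#'
#' Each ring carries a small fixed set of named pseudo-atoms arranged in a
#' plane around the ring centroid. The names are shared across ring types;
#' an atom's *type* for distance metrics is the pair (ring chemical type,
#' atom name), so atoms of chemically different rings never match.
#'
#' @param radius placement radius of the template atoms around the
#'   centroid, Angstrom.
#' @return data.frame with columns `name`, `element`, `x`, `y`, `z`.
#' @keywords internal
ring_template <- function(radius = 1.2) {
  data.frame(
    name = c("C1", "C3", "C5", "O5"),
    element = c("C", "C", "C", "O"),
    x = radius * c(1, -1, 0, 0),
    y = radius * c(0, 0, -1, 1),
    z = c(0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

new_ring <- function(chem_type, atoms, index_in_chain) {
  stopifnot(chem_type %in% GAG_RING_TYPES)
  if (nrow(atoms) < 1L) stop("ring must contain at least one atom", call. = FALSE)
  if (anyDuplicated(atoms$name)) {
    stop("atom names must be unique within a ring", call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("ring atom coordinates must be finite", call. = FALSE)
  }
  structure(
    list(chem_type = chem_type, atoms = atoms, index_in_chain = index_in_chain),
    class = "gag_ring"
  )
}

#' Construct a GAG chain from rings
#'
#' @param rings list of ring objects ordered from the non-reducing end.
#' @param gag_class one of `"HP"`, `"CS6"`, `"DS"`.
#' @return a `gag_chain` object with fields `rings`, `dp`, `gag_class`.
#' @export
new_gag_chain <- function(rings, gag_class = "HP") {
  stopifnot(gag_class %in% c("HP", "CS6", "DS"))
  if (length(rings) < 1L) stop("chain must contain at least one ring", call. = FALSE)
  for (i in seq_along(rings)) rings[[i]]$index_in_chain <- i - 1L
  chain <- structure(
    list(rings = rings, dp = length(rings), gag_class = gag_class),
    class = "gag_chain"
  )
  if (gag_class == "HP") .check_hp_alternation(chain)
  chain
}

.check_hp_alternation <- function(chain) {
  types <- ring_sequence(chain)
  fam <- ifelse(types %in% .glcn_family, "G", ifelse(types %in% .idoa_family, "I", NA))
  if (anyNA(fam)) stop("HP chains may only contain GlcNS- and IdoA-family rings",
                       call. = FALSE)
  if (chain$dp >= 2L && any(fam[-1] == fam[-length(fam)])) {
    stop("HP chains must strictly alternate GlcNS-family and IdoA-family rings",
         call. = FALSE)
  }
  invisible(chain)
}

#' @export
print.gag_chain <- function(x, ...) {
  cat(sprintf("<gag_chain> %s dp%d: %s\n", x$gag_class, x$dp,
              paste(ring_sequence(x), collapse = "-")))
  invisible(x)
}

#' Ring chemical-type sequence of a chain (non-reducing end first)
#' @param chain a `gag_chain`.
#' @return character vector of length `dp`.
#' @export
ring_sequence <- function(chain) {
  vapply(chain$rings, function(r) r$chem_type, character(1))
}

#' All atoms of a chain as one table
#'
#' @param chain a `gag_chain`.
#' @return data.frame with columns `ring_index`, `chem_type`, `name`,
#'   `element`, `x`, `y`, `z`.
#' @export
chain_atoms <- function(chain) {
  parts <- lapply(chain$rings, function(r) {
    cbind(
      data.frame(ring_index = r$index_in_chain, chem_type = r$chem_type,
                 stringsAsFactors = FALSE),
      r$atoms
    )
  })
  do.call(rbind, parts)
}

ring_centroid <- function(ring) {
  unname(colMeans(as.matrix(ring$atoms[, c("x", "y", "z")])))
}

#' Ring centroids of a chain
#' @param chain a `gag_chain`.
#' @return `dp` x 3 matrix of centroids, non-reducing end first.
#' @export
chain_centroids <- function(chain) {
  t(vapply(chain$rings, ring_centroid, numeric(3)))
}

#' Build an ideal helical GAG chain
#'
#' Places ring centroids on a regular helix axis (the z axis through
#' `seed_origin`): consecutive centroids are separated by `rise` along the
#' axis and the ring template is rotated by `twist` degrees per ring.
#' Used as the deterministic geometry source for fixtures and for the
#' fragment-assembly workflow.
#'
#' @param sequence character vector of ring chemical types (non-reducing
#'   end first), drawn from [GAG_RING_TYPES].
#' @param rise axial rise per ring, Angstrom (> 0). Default 4.5.
#' @param twist rotation per ring about the helix axis, degrees. Default 90.
#' @param seed_origin 3-vector, centroid of ring 0.
#' @param gag_class chain class label; default `"HP"` when the sequence
#'   alternates GlcNS/IdoA families, `"CS6"` otherwise.
#' @return a `gag_chain` of dp `length(sequence)`.
#' @examples
#' ch <- build_ideal_chain(c("GlcNS6S", "IdoA2S", "GlcNS6S"))
#' ch$dp
#' @export
build_ideal_chain <- function(sequence, rise = 4.5, twist = 90,
                              seed_origin = c(0, 0, 0), gag_class = NULL) {
  if (length(sequence) < 1L) stop("sequence must be non-empty", call. = FALSE)
  if (!all(sequence %in% GAG_RING_TYPES)) {
    stop("unknown ring chemical type in sequence", call. = FALSE)
  }
  if (!is.numeric(rise) || rise <= 0) stop("rise must be > 0", call. = FALSE)
  if (is.null(gag_class)) {
    alternating <- length(sequence) < 2L ||
      all(ifelse(sequence %in% .glcn_family, "G", "I")[-1] !=
            ifelse(sequence %in% .glcn_family, "G", "I")[-length(sequence)])
    gag_class <- if (all(sequence %in% c(.glcn_family, .idoa_family)) && alternating)
      "HP" else "CS6"
  }
  tmpl <- ring_template()
  rings <- vector("list", length(sequence))
  for (i in seq_along(sequence)) {
    ang <- (i - 1) * twist * pi / 180
    rot <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
    xyz <- as.matrix(tmpl[, c("x", "y", "z")]) %*% t(rot)
    centroid <- seed_origin + c(0, 0, (i - 1) * rise)
    atoms <- tmpl
    atoms$x <- xyz[, 1] + centroid[1]
    atoms$y <- xyz[, 2] + centroid[2]
    atoms$z <- xyz[, 3] + centroid[3]
    rings[[i]] <- new_ring(sequence[i], atoms, i - 1L)
  }
  new_gag_chain(rings, gag_class = gag_class)
}

#' Chain axis from the non-reducing to the reducing end
#'
#' Unit vector from the centroid of ring 0 (non-reducing end) to the
#' centroid of the last ring (reducing end). This axis defines binding-pose
#' polarity.
#'
#' @param chain a `gag_chain` with dp >= 2.
#' @return unit 3-vector.
#' @export
chain_axis <- function(chain) {
  if (chain$dp < 2L) stop("chain axis requires dp >= 2", call. = FALSE)
  v <- ring_centroid(chain$rings[[chain$dp]]) - ring_centroid(chain$rings[[1]])
  n <- sqrt(sum(v^2))
  if (n < 1e-12) {
    stop("degenerate geometry: end-ring centroids coincide", call. = FALSE)
  }
  v / n
}

#' Mass-unweighted radius of gyration
#'
#' `Rg = sqrt(mean of squared distances of atoms from their centroid)`,
#' all atoms weighted equally.
#'
#' @param atoms data.frame with columns `x`, `y`, `z` (e.g. from
#'   [chain_atoms()]), or a `gag_chain`.
#' @return radius of gyration, Angstrom.
#' @export
radius_of_gyration <- function(atoms) {
  if (inherits(atoms, "gag_chain")) atoms <- chain_atoms(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(xyz) < 1L) stop("at least one atom required", call. = FALSE)
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Reverse the ring order of a chain
#'
#' Swaps the reducing and non-reducing ends without moving any atom;
#' the chain axis is exactly negated.
#'
#' @param chain a `gag_chain`.
#' @return the reversed `gag_chain`.
#' @export
reverse_chain <- function(chain) {
  new_gag_chain(rev(chain$rings), gag_class = chain$gag_class)
}

#' Apply a rigid motion to a chain
#'
#' @param chain a `gag_chain`.
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation 3-vector (default zero).
#' @param center rotation center; default the chain's atom centroid.
#' @return the transformed `gag_chain`.
#' @export
transform_chain <- function(chain, rotation = diag(3), translation = c(0, 0, 0),
                            center = NULL) {
  if (is.null(center)) {
    all_xyz <- as.matrix(chain_atoms(chain)[, c("x", "y", "z")])
    center <- colMeans(all_xyz)
  }
  rings <- lapply(chain$rings, function(r) {
    xyz <- as.matrix(r$atoms[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, center) %*% t(rotation)
    xyz <- sweep(xyz, 2, center + translation, FUN = "+")
    r$atoms$x <- xyz[, 1]; r$atoms$y <- xyz[, 2]; r$atoms$z <- xyz[, 3]
    r
  })
  new_gag_chain(rings, gag_class = chain$gag_class)
}

#' Split a chain into overlapping trimers
#'
#' Returns all `dp - 2` windows of three consecutive rings; consecutive
#' windows share exactly two rings (one disaccharide). Each window carries
#' a phase label from the parity of its starting ring index: even start
#' -> phase `"A"`, odd start -> phase `"B"`. This is the fragment scheme
#' used by long-chain assembly.
#'
#' @param chain a `gag_chain` with dp >= 3.
#' @return list of `list(phase, start_index, chain)` entries, where
#'   `chain` is a dp-3 `gag_chain` preserving the window's coordinates.
#' @export
split_into_trimers <- function(chain) {
  if (chain$dp < 3L) stop("splitting into trimers requires dp >= 3", call. = FALSE)
  lapply(seq_len(chain$dp - 2L) - 1L, function(s) {
    rings <- chain$rings[(s + 1L):(s + 3L)]
    list(
      phase = if (s %% 2L == 0L) "A" else "B",
      start_index = s,
      chain = new_gag_chain(rings, gag_class = chain$gag_class)
    )
  })
}

# Small helpers shared by modules -------------------------------------------

#' Random rotation matrix with a bounded angle
#' @param angle_sd standard deviation of the rotation angle, degrees.
#' @return 3x3 rotation matrix.
#' @keywords internal
random_small_rotation <- function(angle_sd = 2) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::rnorm(1, 0, angle_sd) * pi / 180
  rotation_about_axis(ax, ang)
}

#' Rotation matrix about an arbitrary axis (Rodrigues)
#' @param axis unit 3-vector.
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1], axis[2], -axis[1], 0),
              3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}
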