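# File I/O: multi-MODEL PDB pose ensembles, receptor PDB, energy CSV,
# ion-trajectory CSV, JSON reports.
#
# All readers validate and refuse malformed input (with file/line context)
# rather than silently repairing it; write -> read -> write is byte-stable.

# Three-letter residue codes used for ring types in PDB output. The labels
# are package conventions for round-tripping, not force-field names.
RING_PDB_CODES <- c(
  GlcNS6S = "SGN", IdoA2S = "IDS", IdoA = "IDY",
  GlcA = "BDP", GalNAc6S = "ASG", GlcNS = "GNS"
)

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))

#' Construct a receptor structure
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`,
#'   `atom`, `element`, `x`, `y`, `z` (one row per atom).
#' @param numbering_scheme free-text label for the residue numbering
#'   convention; default `"UniProt Q15113"`.
#' @return a `receptor` object.
#' @export
new_receptor <- function(atoms, numbering_scheme = "UniProt Q15113") {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("receptor atoms need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(atoms$resno < 1L)) stop("residue numbers must be positive", call. = FALSE)
  structure(list(atoms = atoms, numbering_scheme = numbering_scheme),
            class = "receptor")
}

#' Residue table of a receptor
#' @param receptor a `receptor`.
#' @return data.frame with one row per residue: `chain`, `resno`, `resname`.
#' @export
receptor_residues <- function(receptor) {
  unique(receptor$atoms[, c("chain", "resno", "resname")])
}

#' Construct a pose ensemble
#'
#' One receptor plus a set of docked poses of one ligand, each pose a
#' `gag_chain` in the receptor coordinate frame with a docking score.
#'
#' @param receptor a `receptor`.
#' @param poses list of `list(id, chain, score)` entries; ids must be
#'   unique and all chains must share one ring sequence.
#' @return a `pose_ensemble` object.
#' @export
new_pose_ensemble <- function(receptor, poses) {
  ids <- vapply(poses, function(p) as.character(p$id), character(1))
  if (anyDuplicated(ids)) stop("pose ids must be unique", call. = FALSE)
  if (length(poses) > 0L) {
    seqs <- vapply(poses, function(p) paste(ring_sequence(p$chain), collapse = "-"),
                   character(1))
    if (length(unique(seqs)) > 1L) {
      stop("all poses in an ensemble must be the same ligand (identical ring sequence)",
           call. = FALSE)
    }
  }
  structure(list(receptor = receptor, poses = poses), class = "pose_ensemble")
}

#' @export
print.pose_ensemble <- function(x, ...) {
  cat(sprintf("<pose_ensemble> %d poses, receptor of %d residues\n",
              length(x$poses), nrow(receptor_residues(x$receptor))))
  invisible(x)
}

#' Docking scores of an ensemble
#' @param ensemble a `pose_ensemble`.
#' @return named numeric vector (names = pose ids), kcal/mol.
#' @export
ensemble_scores <- function(ensemble) {
  stats::setNames(
    vapply(ensemble$poses, function(p) p$score, numeric(1)),
    vapply(ensemble$poses, function(p) as.character(p$id), character(1))
  )
}

# --- PDB records -----------------------------------------------------------

.fmt_atom_name <- function(name) {
  # PDB columns 13-16; names up to 3 characters start in column 14.
  if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
}

.pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                           x, y, z, element) {
  if (any(abs(c(x, y, z)) >= 10000)) {
    stop("coordinate out of PDB fixed-width range (|v| >= 10000 A)", call. = FALSE)
  }
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, .fmt_atom_name(name), resname, chain,
          resno, x, y, z, 1, 0, element)
}

.receptor_pdb_lines <- function(receptor, serial0 = 0L) {
  at <- receptor$atoms
  vapply(seq_len(nrow(at)), function(i) {
    .pdb_atom_line("ATOM", serial0 + i, at$atom[i], at$resname[i], at$chain[i],
                   at$resno[i], at$x[i], at$y[i], at$z[i], at$element[i])
  }, character(1))
}

.chain_pdb_lines <- function(chain, serial0 = 0L, pdb_chain = "G") {
  at <- chain_atoms(chain)
  vapply(seq_len(nrow(at)), function(i) {
    .pdb_atom_line("HETATM", serial0 + i, at$name[i],
                   RING_PDB_CODES[[at$chem_type[i]]], pdb_chain,
                   at$ring_index[i] + 1L, at$x[i], at$y[i], at$z[i], at$element[i])
  }, character(1))
}

#' Write a pose ensemble as a multi-MODEL PDB file
#'
#' The receptor is written once as ATOM records, followed by one
#' MODEL/ENDMDL block per pose holding the ligand HETATM records. Each
#' MODEL carries `REMARK 900 POSE_ID <id>` and `REMARK 900 SCORE <value>`
#' (3 decimals) records.
#'
#' @param ensemble a `pose_ensemble`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pose_ensemble"))
  lines <- c("REMARK 900 GAGPOSELAB POSE ENSEMBLE",
             sprintf("REMARK 900 NUMBERING %s", ensemble$receptor$numbering_scheme),
             .receptor_pdb_lines(ensemble$receptor), "TER")
  for (k in seq_along(ensemble$poses)) {
    p <- ensemble$poses[[k]]
    lines <- c(lines,
               sprintf("MODEL     %4d", k),
               sprintf("REMARK 900 POSE_ID %s", p$id),
               sprintf("REMARK 900 SCORE %.3f", p$score),
               .chain_pdb_lines(p$chain),
               "ENDMDL")
  }
  lines <- c(lines, "END")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

.parse_pdb_atom <- function(line, lineno, path) {
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38), substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz)) {
    stop(sprintf("%s:%d: unparsable coordinates in '%s'", path, lineno,
                 trimws(line)), call. = FALSE)
  }
  list(
    name = trimws(substr(line, 13, 16)),
    resname = trimws(substr(line, 18, 20)),
    chain = substr(line, 22, 22),
    resno = as.integer(substr(line, 23, 26)),
    x = xyz[1], y = xyz[2], z = xyz[3],
    element = trimws(substr(line, 77, 78))
  )
}

.ring_type_from_code <- function(code, lineno, path) {
  hit <- names(RING_PDB_CODES)[RING_PDB_CODES == code]
  if (length(hit) != 1L) {
    stop(sprintf("%s:%d: unknown ligand residue code '%s'", path, lineno, code),
         call. = FALSE)
  }
  hit
}

.chain_from_model_atoms <- function(rows, gag_class, path) {
  resnos <- sort(unique(vapply(rows, function(a) a$resno, integer(1))))
  rings <- lapply(seq_along(resnos), function(i) {
    sel <- Filter(function(a) a$resno == resnos[i], rows)
    atoms <- data.frame(
      name = vapply(sel, `[[`, character(1), "name"),
      element = vapply(sel, `[[`, character(1), "element"),
      x = vapply(sel, `[[`, numeric(1), "x"),
      y = vapply(sel, `[[`, numeric(1), "y"),
      z = vapply(sel, `[[`, numeric(1), "z"),
      stringsAsFactors = FALSE
    )
    new_ring(sel[[1]]$chem_type, atoms, i - 1L)
  })
  new_gag_chain(rings, gag_class = gag_class)
}

#' Read a pose ensemble from a multi-MODEL PDB file
#'
#' Inverse of [write_pose_ensemble()]; the round trip is exact at PDB's
#' 3-decimal coordinate precision. Files without MODEL records and models
#' with inconsistent ligand composition are rejected.
#'
#' @param path file written by [write_pose_ensemble()] (or following the
#'   same conventions).
#' @param gag_class class label to attach to the ligand chains.
#' @return a `pose_ensemble`.
#' @export
read_pose_ensemble <- function(path, gag_class = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop(sprintf("%s:0: empty file, expected PDB records", path), call. = FALSE)
  }
  numbering <- "UniProt Q15113"
  rec_rows <- list(); poses <- list()
  in_model <- FALSE
  model_rows <- NULL; model_id <- NULL; model_score <- NA_real_
  n_models <- 0L
  finish_model <- function(lineno) {
    if (length(model_rows) == 0L) {
      stop(sprintf("%s:%d: MODEL block contains no ligand atoms", path, lineno),
           call. = FALSE)
    }
    if (is.na(model_score)) {
      stop(sprintf("%s:%d: MODEL block missing 'REMARK 900 SCORE'", path, lineno),
           call. = FALSE)
    }
    gc <- if (is.null(gag_class)) {
      types <- unique(vapply(model_rows, `[[`, character(1), "chem_type"))
      if (all(types %in% c(.glcn_family, .idoa_family))) "HP" else "CS6"
    } else gag_class
    list(id = model_id, chain = .chain_from_model_atoms(model_rows, gc, path),
         score = model_score)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    rec <- substr(line, 1, 6)
    if (startsWith(line, "MODEL")) {
      n_models <- n_models + 1L
      in_model <- TRUE
      model_rows <- list()
      model_id <- sprintf("m%04d", n_models)
      model_score <- NA_real_
    } else if (startsWith(line, "ENDMDL")) {
      if (!in_model) stop(sprintf("%s:%d: ENDMDL without MODEL", path, i),
                          call. = FALSE)
      poses[[length(poses) + 1L]] <- finish_model(i)
      in_model <- FALSE
    } else if (grepl("^REMARK 900 POSE_ID ", line)) {
      model_id <- trimws(sub("^REMARK 900 POSE_ID ", "", line))
    } else if (grepl("^REMARK 900 SCORE ", line)) {
      model_score <- as.numeric(sub("^REMARK 900 SCORE ", "", line))
    } else if (grepl("^REMARK 900 NUMBERING ", line)) {
      numbering <- trimws(sub("^REMARK 900 NUMBERING ", "", line))
    } else if (rec == "ATOM  " && !in_model) {
      rec_rows[[length(rec_rows) + 1L]] <- .parse_pdb_atom(line, i, path)
    } else if (rec == "HETATM") {
      if (!in_model) {
        stop(sprintf("%s:%d: ligand HETATM outside a MODEL block", path, i),
             call. = FALSE)
      }
      a <- .parse_pdb_atom(line, i, path)
      a$chem_type <- .ring_type_from_code(a$resname, i, path)
      model_rows[[length(model_rows) + 1L]] <- a
    }
  }
  if (n_models == 0L) {
    stop(sprintf("%s:1: no MODEL records found; pose ensembles require MODEL/ENDMDL blocks",
                 path), call. = FALSE)
  }
  if (in_model) stop(sprintf("%s:%d: unterminated MODEL block", path,
                             length(lines)), call. = FALSE)
  atoms <- data.frame(
    chain = vapply(rec_rows, `[[`, character(1), "chain"),
    resno = vapply(rec_rows, `[[`, integer(1), "resno"),
    resname = vapply(rec_rows, `[[`, character(1), "resname"),
    atom = vapply(rec_rows, `[[`, character(1), "name"),
    element = vapply(rec_rows, `[[`, character(1), "element"),
    x = vapply(rec_rows, `[[`, numeric(1), "x"),
    y = vapply(rec_rows, `[[`, numeric(1), "y"),
    z = vapply(rec_rows, `[[`, numeric(1), "z"),
    stringsAsFactors = FALSE
  )
  receptor <- new_receptor(atoms, numbering_scheme = numbering)
  seqs <- vapply(poses, function(p) paste(ring_sequence(p$chain), collapse = "-"),
                 character(1))
  if (length(unique(seqs)) > 1L) {
    stop(sprintf("%s: inconsistent ligand composition across MODEL blocks", path),
         call. = FALSE)
  }
  new_pose_ensemble(receptor, poses)
}

# --- residue tokens and energy tables --------------------------------------

#' Parse a residue token such as "K436" or "LYS436"
#' @param token character vector of residue tokens.
#' @return data.frame with columns `resname` (one-letter) and `resno`.
#' @export
parse_residue_token <- function(token) {
  out <- data.frame(resname = character(length(token)),
                    resno = integer(length(token)), stringsAsFactors = FALSE)
  for (i in seq_along(token)) {
    tok <- trimws(token[i])
    if (grepl("^[A-Z][0-9]+$", tok)) {
      out$resname[i] <- substr(tok, 1, 1)
      out$resno[i] <- as.integer(substr(tok, 2, nchar(tok)))
    } else if (grepl("^[A-Z]{3}[0-9]+$", tok)) {
      three <- substr(tok, 1, 3)
      if (!three %in% names(AA_THREE_TO_ONE)) {
        stop("unknown three-letter residue code in token: ", tok, call. = FALSE)
      }
      out$resname[i] <- AA_THREE_TO_ONE[[three]]
      out$resno[i] <- as.integer(substr(tok, 4, nchar(tok)))
    } else {
      stop("unparsable residue token: '", tok, "'", call. = FALSE)
    }
  }
  out
}

#' Construct a per-residue binding-energy table
#'
#' Emulates the shape of MM-GBSA per-residue decomposition summaries:
#' one row per (id, residue) with mean energy and standard deviation.
#'
#' @param df data.frame with columns `id`, `resname` (one-letter),
#'   `resno`, `mean`, `sd`.
#' @param totals optional data.frame of per-id totals with columns `id`,
#'   `dG_mean`, `dG_sd`, `n_frames`.
#' @param n_poses number of poses averaged into this table (weight used
#'   by pose-weighted aggregation); default 1.
#' @return an `energy_table` (a data.frame subclass).
#' @export
new_energy_table <- function(df, totals = NULL, n_poses = 1L) {
  need <- c("id", "resname", "resno", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop("energy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$sd < 0)) stop("energy sd must be >= 0", call. = FALSE)
  structure(df, totals = totals, n_poses = n_poses,
            class = c("energy_table", "data.frame"))
}

#' Read a per-residue energy table from CSV
#'
#' Expects a header `id,residue,mean,sd`; residue tokens like `"K436"`
#' (three-letter form `"LYS436"` also accepted). Rows with residue token
#' `"TOTAL"` are collected as per-id binding-energy totals.
#'
#' @param path CSV file.
#' @return an `energy_table`.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "residue", "mean", "sd")
  if (!all(need %in% names(raw))) {
    stop(path, ": expected CSV header 'id,residue,mean,sd'", call. = FALSE)
  }
  if (any(!is.finite(raw$mean)) || any(!is.finite(raw$sd))) {
    stop(path, ": non-numeric mean/sd values", call. = FALSE)
  }
  if (any(raw$sd < 0)) {
    bad <- which(raw$sd < 0)[1]
    stop(sprintf("%s: row %d: negative sd (%g)", path, bad, raw$sd[bad]),
         call. = FALSE)
  }
  is_total <- toupper(raw$residue) == "TOTAL"
  totals <- NULL
  if (any(is_total)) {
    tot <- raw[is_total, ]
    totals <- data.frame(id = tot$id, dG_mean = tot$mean, dG_sd = tot$sd,
                         n_frames = if ("n_frames" %in% names(tot))
                           tot$n_frames else NA_integer_,
                         stringsAsFactors = FALSE)
  }
  per_res <- raw[!is_total, , drop = FALSE]
  parsed <- tryCatch(parse_residue_token(per_res$residue), error = function(e) {
    bad <- which(vapply(per_res$residue, function(tok)
      inherits(try(parse_residue_token(tok), silent = TRUE), "try-error"),
      logical(1)))[1]
    stop(sprintf("%s: row %d: %s", path, bad, conditionMessage(e)), call. = FALSE)
  })
  df <- data.frame(id = per_res$id, resname = parsed$resname,
                   resno = parsed$resno, mean = per_res$mean, sd = per_res$sd,
                   stringsAsFactors = FALSE)
  new_energy_table(df, totals = totals)
}

#' Write a per-residue energy table as CSV
#'
#' Inverse of [read_energy_table()]; totals (if any) are appended as rows
#' with residue token `"TOTAL"`.
#'
#' @param table an `energy_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(table, path) {
  df <- data.frame(id = table$id,
                   residue = paste0(table$resname, table$resno),
                   mean = table$mean, sd = table$sd, stringsAsFactors = FALSE)
  totals <- attr(table, "totals")
  if (!is.null(totals)) {
    df <- rbind(df, data.frame(id = totals$id, residue = "TOTAL",
                               mean = totals$dG_mean, sd = totals$dG_sd,
                               stringsAsFactors = FALSE))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- ion trajectories ------------------------------------------------------

#' Construct an ion trajectory
#'
#' Frames of ion positions at a fixed interval over a receptor held rigid
#' (the container post-processes trajectories; it does not simulate).
#'
#' @param receptor a `receptor`.
#' @param frames data.frame with columns `time_ps`, `ion`, `x`, `y`, `z`
#'   (one row per ion per frame).
#' @param interval_ps frame interval, picoseconds (> 0).
#' @param length_ns trajectory length, nanoseconds.
#' @return an `ion_trajectory` object.
#' @export
new_ion_trajectory <- function(receptor, frames, interval_ps, length_ns) {
  if (interval_ps <= 0) stop("frame interval must be > 0", call. = FALSE)
  need <- c("time_ps", "ion", "x", "y", "z")
  if (!all(need %in% names(frames))) {
    stop("frames need columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(receptor = receptor, frames = frames,
                 interval_ps = interval_ps, length_ns = length_ns),
            class = "ion_trajectory")
}

#' Write ion-trajectory frames as CSV
#' @param traj an `ion_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ion_trajectory <- function(traj, path) {
  df <- traj$frames
  attr(df, "interval_ps") <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read ion-trajectory frames from CSV
#' @param path CSV with columns `time_ps`, `ion`, `x`, `y`, `z`.
#' @param receptor the `receptor` the frames refer to.
#' @return an `ion_trajectory`; interval and length are inferred from the
#'   time stamps.
#' @export
read_ion_trajectory <- function(path, receptor) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ps", "ion", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop(path, ": expected CSV header 'time_ps,ion,x,y,z'", call. = FALSE)
  }
  times <- sort(unique(df$time_ps))
  if (length(times) < 2L) stop(path, ": need at least two frames", call. = FALSE)
  ivals <- unique(round(diff(times), 9))
  if (length(ivals) != 1L) {
    stop(path, ": frames are not at a fixed interval", call. = FALSE)
  }
  new_ion_trajectory(receptor, df, interval_ps = ivals,
                     length_ns = (max(times) + ivals) / 1000)
}

#' Write an analysis report as JSON
#' @param report a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
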