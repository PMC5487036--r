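# Fixed-column PDB reading/writing. Policies (altloc, first MODEL only,
# solvent handling) are pinned here so that round-trips are exact.

parse_pdb_lines <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(is_atom)
  if (length(idx) == 0) stop("no ATOM/HETATM records found")
  rec <- lines[idx]
  # pad short lines so fixed-column substring extraction is safe
  rec <- formatC(rec, width = 80, flag = "-")
  xs <- substr(rec, 31, 38); ys <- substr(rec, 39, 46); zs <- substr(rec, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  resseq <- suppressWarnings(as.integer(substr(rec, 23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resseq))
  if (length(bad) > 0) {
    stop("malformed ATOM/HETATM record at line ", idx[bad[1]], ": ",
         trimws(lines[idx[bad[1]]]))
  }
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ[!is.finite(occ)] <- 1
  tibble::tibble(
    line      = idx,
    record    = substr(rec, 1, 6),
    serial    = suppressWarnings(as.integer(substr(rec, 7, 11))),
    atom      = trimws(substr(rec, 13, 16)),
    alt_loc   = trimws(substr(rec, 17, 17)),
    res_name  = trimws(substr(rec, 18, 20)),
    chain     = substr(rec, 22, 22),
    res_seq   = resseq,
    i_code    = trimws(substr(rec, 27, 27)),
    x = x, y = y, z = z,
    occupancy = occ,
    element   = trimws(substr(rec, 77, 78))
  )
}

# element fallback from the atom name when columns 77-78 are blank
infer_element <- function(atom, element) {
  miss <- is.na(element) | element == ""
  if (any(miss)) {
    nm <- gsub("[0-9']", "", atom[miss])
    element[miss] <- toupper(substr(nm, 1, 1))
  }
  element
}

# altloc policy: keep highest occupancy per (chain,res,icode,name);
# ties broken by lexicographically first alt_loc
apply_altloc_policy <- function(at) {
  key <- paste(at$chain, at$res_seq, at$i_code, at$atom, sep = "|")
  if (!anyDuplicated(key)) {
    at$alt_loc <- ""
    return(at)
  }
  ord <- order(factor(key, levels = unique(key)), -at$occupancy, at$alt_loc)
  at <- at[ord, ]
  key <- key[ord]
  at <- at[!duplicated(key), ]
  at <- at[order(at$line), ]
  at$alt_loc <- ""
  at
}

#' Read a structure from a PDB file or PDB-format text
#'
#' Loads all `ATOM`/`HETATM` records of the first `MODEL` (files with
#' several models are trajectories and must go through
#' [read_trajectory()]). Author residue numbering and insertion codes are
#' preserved. When alternate locations exist, the highest-occupancy
#' conformer is kept (ties: lexicographically first `altLoc`). Waters and
#' simple ions are dropped unless `keep_solvent = TRUE`; HETATM amino
#' acids such as selenomethionine are retained.
#'
#' @param source Path to a PDB file, or a character vector of PDB lines.
#' @param keep_solvent Keep water/ion records? Default `FALSE`.
#' @param header_id Identifier for the model; defaults to the `HEADER`
#'   idCode or the file name.
#' @return A `cna_structure`.
#' @export
read_structure <- function(source, keep_solvent = FALSE, header_id = NULL) {
  lines <- pdb_source_lines(source)
  if (length(lines) == 0 || all(!nzchar(lines))) stop("empty PDB input")
  if (is.null(header_id)) header_id <- pdb_header_id(source, lines)
  # first MODEL only
  m1 <- grep("^MODEL", lines)
  if (length(m1) > 0) {
    e1 <- grep("^ENDMDL", lines)
    e1 <- if (length(e1) > 0) e1[1] else length(lines)
    keep <- rep(FALSE, length(lines))
    keep[seq(m1[1], e1)] <- TRUE
    lines[!keep & grepl("^(ATOM  |HETATM)", lines)] <- ""
  }
  at <- parse_pdb_lines(lines)
  if (!keep_solvent) at <- at[!(at$res_name %in% SOLVENT_RES), ]
  if (nrow(at) == 0) stop("no atoms left after solvent filtering")
  at$element <- infer_element(at$atom, at$element)
  at <- apply_altloc_policy(at)
  at$line <- NULL
  at$record <- NULL
  new_structure(at, header_id = header_id)
}

pdb_source_lines <- function(source) {
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1 && grepl("\n", source)) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(source)
  }
}

pdb_header_id <- function(source, lines) {
  h <- grep("^HEADER", lines, value = TRUE)
  if (length(h) > 0 && nchar(h[1]) >= 66) {
    id <- trimws(substr(h[1], 63, 66))
    if (nzchar(id)) return(id)
  }
  if (length(source) == 1 && !grepl("\n", source) && file.exists(source)) {
    return(sub("\\.[^.]*$", "", basename(source)))
  }
  NA_character_
}

format_atom_name <- function(atom, element) {
  if (nchar(atom) > 4) stop("atom name '", atom, "' exceeds the 4-character PDB field")
  # names of atoms with 1-letter elements start in column 14
  if (nchar(atom) < 4 && nchar(element) <= 1) {
    formatC(paste0(" ", atom), width = -4)
  } else {
    formatC(atom, width = -4)
  }
}

pdb_atom_lines <- function(at, serial_start = 1L) {
  n <- nrow(at)
  serials <- seq(serial_start, length.out = n)
  names4 <- vapply(seq_len(n),
                   function(i) format_atom_name(at$atom[i], at$element[i]),
                   character(1))
  het <- !(at$res_name %in% names(AA_3TO1)) & !(at$res_name %in% c("ACE", "NME"))
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(het, "HETATM", "ATOM"),
          serials, names4, "", at$res_name, at$chain, at$res_seq, at$i_code,
          at$x, at$y, at$z, at$occupancy, 0, at$element)
}

#' Write a structure as PDB text
#'
#' Coordinates are stored at the format's 3-decimal precision; chains are
#' separated by `TER` records. Re-reading the output yields an
#' atom-identical model.
#'
#' @param model A `cna_structure`.
#' @param dest Optional path; when `NULL` the lines are returned invisibly
#'   only.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_structure <- function(model, dest = NULL) {
  at <- as_atom_tbl(model)
  out <- character(0)
  hid <- attr(model, "header_id")
  if (!is.na(hid)) out <- sprintf("REMARK 250 CNASPLIT MODEL %s", hid)
  serial <- 1L
  for (ch in unique(at$chain)) {
    sub <- at[at$chain == ch, ]
    out <- c(out, pdb_atom_lines(sub, serial))
    serial <- serial + nrow(sub)
    last <- sub[nrow(sub), ]
    out <- c(out, sprintf("TER   %5d      %-3s %1s%4d%1s",
                          serial, last$res_name, last$chain, last$res_seq,
                          last$i_code))
    serial <- serial + 1L
  }
  out <- c(out, "END")
  if (!is.null(dest)) writeLines(out, dest)
  invisible(out)
}

#' Create a trajectory object
#'
#' @param topology A `cna_structure` shared by all frames.
#' @param coords Array `n_frames x n_atoms x 3` of coordinates.
#' @param frame_times Optional numeric vector of frame times (ns).
#' @return A `cna_trajectory`.
#' @export
new_trajectory <- function(topology, coords, frame_times = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) stop("a trajectory needs at least one frame")
  if (dim(coords)[2] != nrow(topology)) {
    stop("coordinate frames have ", dim(coords)[2],
         " atoms but the topology has ", nrow(topology))
  }
  structure(list(topology = topology, coords = coords,
                 frame_times = frame_times),
            class = "cna_trajectory")
}

#' @export
print.cna_trajectory <- function(x, ...) {
  cat("<cna_trajectory>", dim(x$coords)[1], "frames x",
      dim(x$coords)[2], "atoms\n")
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj A `cna_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one trajectory frame as a structure
#' @param traj A `cna_trajectory`.
#' @param i Frame index (1-based).
#' @return A `cna_structure`.
#' @export
trajectory_frame <- function(traj, i) {
  at <- as_atom_tbl(traj$topology)
  at$x <- traj$coords[i, , 1]
  at$y <- traj$coords[i, , 2]
  at$z <- traj$coords[i, , 3]
  restore_structure(at, traj$topology)
}

#' Read a multi-model PDB file as a trajectory
#'
#' Every `MODEL` block must contain exactly one coordinate triple per
#' topology atom, in topology order; frames are ordered by `MODEL` number.
#'
#' @param topology A `cna_structure` describing the atoms.
#' @param source Path to a multi-model PDB file or its text.
#' @return A `cna_trajectory`.
#' @export
read_trajectory <- function(topology, source) {
  lines <- pdb_source_lines(source)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) starts <- 0  # single implicit model
  ends <- grep("^ENDMDL", lines)
  n_atoms <- nrow(topology)
  n <- length(starts)
  coords <- array(NA_real_, dim = c(n, n_atoms, 3))
  times <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    lo <- if (starts[1] == 0) 1 else starts[k]
    hi <- if (starts[1] == 0) length(lines) else {
      e <- ends[ends > starts[k]]
      if (length(e) == 0) length(lines) else e[1]
    }
    block <- lines[lo:hi]
    at <- parse_pdb_lines(block)
    at <- at[!(at$res_name %in% SOLVENT_RES), ]
    if (nrow(at) != n_atoms) {
      stop("frame ", k, " has ", nrow(at), " atoms; topology has ", n_atoms)
    }
    if (any(at$atom != topology$atom)) {
      stop("frame ", k, " atom names do not match the topology")
    }
    coords[k, , ] <- cbind(at$x, at$y, at$z)
  }
  new_trajectory(topology, coords, frame_times = NULL)
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param traj A `cna_trajectory`.
#' @param dest Optional output path.
#' @return Character vector of PDB lines, invisibly.
#' @export
write_trajectory <- function(traj, dest = NULL) {
  out <- character(0)
  for (k in seq_len(n_frames(traj))) {
    frame <- trajectory_frame(traj, k)
    body <- write_structure(frame)
    body <- body[body != "END" & !grepl("^REMARK", body)]
    out <- c(out, sprintf("MODEL %8d", k), body, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(dest)) writeLines(out, dest)
  invisible(out)
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param dest Output path.
#' @return `dest`, invisibly.
#' @export
write_fasta <- function(seqs, dest) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(set, dest)
  invisible(dest)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
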