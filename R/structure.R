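# Atom-level structure container: one row per atom, author numbering kept.

#' Create a structure from an atom table
#'
#' A structure is an atom-level tibble with one row per atom and class
#' `cna_structure`. Residues are identified by `(chain, res_seq, i_code)`
#' exactly as deposited (author numbering, never renumbered); file order is
#' preserved.
#'
#' @param atoms Data frame with columns `serial`, `atom`, `alt_loc`,
#'   `res_name`, `chain`, `res_seq`, `i_code`, `x`, `y`, `z`, `occupancy`,
#'   `element`.
#' @param header_id Optional identifier string (e.g. a PDB code).
#' @return A `cna_structure` tibble.
#' @export
new_structure <- function(atoms, header_id = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "atom", "alt_loc", "res_name", "chain", "res_seq",
              "i_code", "x", "y", "z", "occupancy", "element")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    stop("atom table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) > 0) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
      stop("non-finite coordinates in atom table")
    }
    if (any(is.na(atoms$atom) | atoms$atom == "")) stop("empty atom name")
  }
  structure(atoms,
            class = c("cna_structure", class(tibble::tibble())),
            header_id = header_id)
}

#' @export
print.cna_structure <- function(x, ...) {
  hid <- attr(x, "header_id")
  cat("<cna_structure", if (!is.na(hid)) paste0("'", hid, "'"), ">",
      nrow(x), "atoms,", nrow(dplyr::distinct(as_atom_tbl(x),
        .data$chain, .data$res_seq, .data$i_code)), "residues,",
      length(unique(x$chain)), "chain(s)\n")
  NextMethod()
}

# drop the structure class so dplyr verbs behave plainly
as_atom_tbl <- function(model) {
  class(model) <- class(tibble::tibble())
  model
}

restore_structure <- function(atoms, template) {
  new_structure(atoms, header_id = attr(template, "header_id"))
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$res_seq, atoms$i_code, sep = "|")
}

#' Residue-level summary of a structure
#'
#' @param model A `cna_structure`.
#' @return Tibble with one row per residue in file order (`chain`,
#'   `res_seq`, `i_code`, `res_name`, `n_atoms`).
#' @export
residue_table <- function(model) {
  at <- as_atom_tbl(model)
  at$.key <- residue_key(at)
  at |>
    dplyr::group_by(.key = factor(.data$.key, levels = unique(.data$.key))) |>
    dplyr::summarise(chain = .data$chain[1], res_seq = .data$res_seq[1],
                     i_code = .data$i_code[1], res_name = .data$res_name[1],
                     n_atoms = dplyr::n(), .groups = "drop") |>
    dplyr::select(-".key")
}

#' Select an inclusive author-numbered residue range
#'
#' Ranges are 1-based, inclusive on both ends, and interpreted in the
#' author numbering of the deposited file. When `chain` is `NULL`, the
#' first chain containing any residue of the range is used.
#'
#' @param model A `cna_structure`.
#' @param chain Chain identifier (single character) or `NULL`.
#' @param first,last First and last residue numbers (inclusive).
#' @return A `cna_structure` with the selected residues, order preserved.
#' @export
select_residues <- function(model, chain = NULL, first, last) {
  stopifnot(first <= last)
  at <- as_atom_tbl(model)
  if (is.null(chain)) {
    hit <- unique(at$chain[at$res_seq >= first & at$res_seq <= last])
    if (length(hit) == 0) {
      stop("no residue in range ", first, "-", last, " on any chain")
    }
    chain <- hit[1]
  }
  sel <- at[at$chain == chain & at$res_seq >= first & at$res_seq <= last, ]
  if (nrow(sel) == 0) {
    stop("no residue in range ", first, "-", last, " on chain '", chain, "'")
  }
  restore_structure(sel, model)
}

# 3-letter -> 1-letter, incl. common modified residues seen in deposits
AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  MSE = "M", SEC = "U", PYL = "O", HYP = "P", SEP = "S", TPO = "T",
  PTR = "Y", CSO = "C", MLY = "K"
)

AA_1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Extract the one-letter amino-acid sequence of a residue range
#'
#' Unknown residue types map to `"X"`; selenomethionine and a few other
#' frequent modified residues map to their parent letter.
#'
#' @inheritParams select_residues
#' @return Single character string, one letter per residue selected.
#' @export
residue_sequence <- function(model, chain = NULL, first = -Inf, last = Inf) {
  sel <- if (is.finite(first) || is.finite(last) || !is.null(chain)) {
    select_residues(model, chain,
                    if (is.finite(first)) first else min(model$res_seq),
                    if (is.finite(last)) last else max(model$res_seq))
  } else model
  res <- residue_table(sel)
  letters1 <- AA_3TO1[res$res_name]
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

# water / simple ion residue names dropped by default on read
SOLVENT_RES <- c("HOH", "WAT", "DOD", "NA", "CL", "K", "MG", "ZN", "CA",
                 "MN", "SO4", "PO4", "GOL", "EDO")

#' Coordinates of a structure (or of selected atom names) as a matrix
#'
#' @param model A `cna_structure`.
#' @param atoms Optional character vector of atom names to keep.
#' @return Numeric matrix with 3 columns (x, y, z).
#' @export
coords_matrix <- function(model, atoms = NULL) {
  at <- as_atom_tbl(model)
  if (!is.null(atoms)) at <- at[at$atom %in% atoms, ]
  as.matrix(at[, c("x", "y", "z")])
}
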