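# Geometric detection of the reactive isopeptide triad
# (Lys NZ -- Asn/Asp CG, with a nearby catalytic Glu/Asp).

#' Detection thresholds for isopeptide triads
#'
#' The lysine NZ to acceptor (Asn/Asp) CG distance classifies the bond
#' state: `covalent` at or below `covalent_max` (deposited bonds sit
#' around 1.3-1.4 Angstrom), `proximal` (reaction-competent pose) up to
#' `proximal_max`. A Glu CD / Asp CG within `catalytic_max` of NZ is
#' attached as the catalytic residue.
#'
#' @param covalent_max,proximal_max,catalytic_max Distances in Angstrom.
#' @return List of class `cna_detection_params`.
#' @export
detection_params <- function(covalent_max = 1.8, proximal_max = 4.0,
                             catalytic_max = 5.0) {
  stopifnot(covalent_max > 0, covalent_max < proximal_max, catalytic_max > 0)
  structure(list(covalent_max = covalent_max, proximal_max = proximal_max,
                 catalytic_max = catalytic_max),
            class = "cna_detection_params")
}

#' Detect intramolecular isopeptide-bond triads
#'
#' For every lysine NZ within `proximal_max` of an Asn/Asp side-chain
#' carbon (CG), the nearest such acceptor is reported together with the
#' nearest catalytic Glu/Asp carboxylate carbon within `catalytic_max`
#' of NZ (`NA` if none). Each lysine appears at most once; rows are
#' sorted by NZ-CG distance. Lysines lacking an NZ atom are skipped with
#' a warning. Hydrogens are ignored throughout.
#'
#' @param model A `cna_structure`.
#' @param params A [detection_params()] list.
#' @return Tibble with one row per detected bond: lysine, acceptor and
#'   catalytic residue identifiers, `nz_cg_distance`, `nz_cat_distance`
#'   and `state` (`"covalent"` or `"proximal"`).
#' @export
detect_isopeptide <- function(model, params = detection_params()) {
  at <- as_atom_tbl(model)
  empty <- tibble::tibble(
    chain = character(0), lys_res = integer(0),
    acceptor_res = integer(0), acceptor_name = character(0),
    catalytic_res = integer(0), catalytic_name = character(0),
    nz_cg_distance = numeric(0), nz_cat_distance = numeric(0),
    state = character(0))

  lys <- at[at$res_name == "LYS" & at$atom == "CA", ]
  if (nrow(lys) > 0) {
    nz <- at[at$res_name == "LYS" & at$atom == "NZ", ]
    missing_nz <- dplyr::anti_join(
      lys[, c("chain", "res_seq", "i_code")],
      nz[, c("chain", "res_seq", "i_code")],
      by = c("chain", "res_seq", "i_code"))
    if (nrow(missing_nz) > 0) {
      warning("skipping Lys without NZ atom: ",
              paste(missing_nz$chain, missing_nz$res_seq, collapse = ", "))
    }
  } else {
    nz <- at[0, ]
  }
  if (nrow(nz) == 0) return(empty)

  acc <- at[at$res_name %in% c("ASN", "ASP") & at$atom == "CG", ]
  if (nrow(acc) == 0) return(empty)
  cat_at <- at[(at$res_name == "GLU" & at$atom == "CD") |
                 (at$res_name == "ASP" & at$atom == "CG"), ]

  dmat <- cross_distances(as.matrix(nz[, c("x", "y", "z")]),
                          as.matrix(acc[, c("x", "y", "z")]))
  rows <- list()
  for (i in seq_len(nrow(nz))) {
    cand <- which(dmat[i, ] <= params$proximal_max)
    # the reactive Lys never bonds its own residue's atoms; acceptors are
    # other residues by construction (different res_name)
    if (length(cand) == 0) next
    # nearest acceptor; ties broken by lower res_seq
    ord <- cand[order(dmat[i, cand], acc$res_seq[cand])]
    j <- ord[1]
    d_cg <- dmat[i, j]

    cat_res <- NA_integer_; cat_name <- NA_character_; d_cat <- NA_real_
    if (nrow(cat_at) > 0) {
      # a catalytic Asp must not be the acceptor itself
      keep <- !(cat_at$res_name == "ASP" & cat_at$chain == acc$chain[j] &
                  cat_at$res_seq == acc$res_seq[j] &
                  cat_at$i_code == acc$i_code[j])
      cc <- cat_at[keep, ]
      if (nrow(cc) > 0) {
        dc <- cross_distances(matrix(unlist(nz[i, c("x", "y", "z")]), 1),
                              as.matrix(cc[, c("x", "y", "z")]))[1, ]
        hit <- which(dc <= params$catalytic_max)
        if (length(hit) > 0) {
          k <- hit[order(dc[hit], cc$res_seq[hit])][1]
          cat_res <- cc$res_seq[k]; cat_name <- cc$res_name[k]
          d_cat <- dc[k]
        }
      }
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      chain = nz$chain[i], lys_res = nz$res_seq[i],
      acceptor_res = acc$res_seq[j], acceptor_name = acc$res_name[j],
      catalytic_res = cat_res, catalytic_name = cat_name,
      nz_cg_distance = d_cg, nz_cat_distance = d_cat,
      state = if (d_cg <= params$covalent_max) "covalent" else "proximal")
  }
  if (length(rows) == 0) return(empty)
  out <- dplyr::bind_rows(rows)
  out[order(out$nz_cg_distance), ]
}

#' Report where the triad members fall relative to a split
#'
#' Classifies the reactive Lys, the acceptor and the catalytic residue of
#' a detected triad as lying in the catcher range, the tag range, the
#' deleted linker range, or outside the split altogether.
#'
#' @param triad One row of a [detect_isopeptide()] result (or a list with
#'   `lys_res`, `acceptor_res`, `catalytic_res`).
#' @param split A [split_spec()].
#' @return Tibble with columns `member`, `res_seq`, `placement`.
#' @export
triad_in_ranges <- function(triad, split) {
  place <- function(r) {
    if (is.na(r)) return(NA_character_)
    if (r >= split$catcher_first && r <= split$catcher_last) return("catcher")
    if (r >= split$tag_first && r <= split$tag_last) return("tag")
    if (r > split$catcher_last && r < split$tag_first) return("deleted")
    "outside"
  }
  res <- c(lys = triad$lys_res[1], acceptor = triad$acceptor_res[1],
           catalytic = triad$catalytic_res[1])
  tibble::tibble(member = names(res),
                 res_seq = as.integer(res),
                 placement = vapply(res, place, character(1),
                                    USE.NAMES = FALSE))
}
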