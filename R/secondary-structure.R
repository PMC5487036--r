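# Kabsch-Sander-style secondary-structure assignment on backbone
# geometry, and beta-sheet content of a residue window.

# electrostatic H-bond energy model constants: q1*q2 = 0.42*0.20 = 0.084,
# dimensional factor 332 kcal*A/mol, bond if E < -0.5 kcal/mol
HB_Q1Q2 <- 0.084
HB_F <- 332
HB_CUTOFF <- -0.5

# amide H rebuilt on N along the previous residue's C=O direction,
# 1.0 A from N (crystal structures and stripped MD frames lack H)
build_amide_h <- function(n_xyz, c_prev, o_prev) {
  n_xyz + unit(c_prev - o_prev) * 1.0
}

backbone_frames <- function(model) {
  at <- as_atom_tbl(model)
  res <- residue_table(model)
  get1 <- function(i, name) {
    hit <- at[at$chain == res$chain[i] & at$res_seq == res$res_seq[i] &
                at$i_code == res$i_code[i] & at$atom == name, ]
    if (nrow(hit) == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  n <- nrow(res)
  out <- list(res = res,
              N = t(vapply(seq_len(n), get1, numeric(3), name = "N")),
              CA = t(vapply(seq_len(n), get1, numeric(3), name = "CA")),
              C = t(vapply(seq_len(n), get1, numeric(3), name = "C")),
              O = t(vapply(seq_len(n), get1, numeric(3), name = "O")))
  out
}

# n_res x n_res matrix: TRUE if the NH of residue i H-bonds the C=O of j
hbond_matrix <- function(bb) {
  n <- nrow(bb$res)
  e <- matrix(Inf, n, n)
  same_chain_prev <- c(FALSE, bb$res$chain[-1] == bb$res$chain[-n])
  for (i in seq_len(n)) {
    if (!same_chain_prev[i]) next        # no preceding residue: no H built
    if (bb$res$res_name[i] == "PRO") next  # proline has no amide H
    if (anyNA(bb$N[i, ]) || anyNA(bb$C[i - 1, ]) || anyNA(bb$O[i - 1, ])) next
    h <- build_amide_h(bb$N[i, ], bb$C[i - 1, ], bb$O[i - 1, ])
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 && bb$res$chain[i] == bb$res$chain[j]) next
      if (anyNA(bb$O[j, ]) || anyNA(bb$C[j, ])) next
      r_on <- vnorm(bb$N[i, ] - bb$O[j, ])
      if (r_on > 5.2) next               # beyond plausible H-bond range
      r_ch <- vnorm(h - bb$C[j, ])
      r_oh <- vnorm(h - bb$O[j, ])
      r_cn <- vnorm(bb$N[i, ] - bb$C[j, ])
      e[i, j] <- HB_Q1Q2 * HB_F * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
    }
  }
  e < HB_CUTOFF
}

#' Assign secondary structure from backbone geometry
#'
#' Kabsch-Sander-style assignment: backbone N-H...O=C hydrogen bonds are
#' scored with the electrostatic model
#' `E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN)` (kcal/mol), with
#' the amide hydrogen rebuilt from ideal geometry; a bond exists when
#' `E < -0.5`. Parallel and antiparallel bridges are grown into ladders
#' and labelled `E`; helices are recognised through consecutive
#' `(i, i+4)` bonds and labelled `H`; everything else is `C`. Chains
#' shorter than 3 residues are all `C`.
#'
#' @param model A `cna_structure` with backbone N, CA, C, O atoms.
#' @return Tibble: `chain`, `res_seq`, `i_code`, `res_name`, `ss`.
#' @export
assign_secondary_structure <- function(model) {
  bb <- backbone_frames(model)
  res <- bb$res
  n <- nrow(res)
  ss <- rep("C", n)
  chain_len <- table(res$chain)
  big <- res$chain %in% names(chain_len)[chain_len >= 3]
  if (n >= 3 && any(big)) {
    hb <- hbond_matrix(bb)
    bridge <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3 && res$chain[i] == res$chain[j]) next
        para <- (hb[i, j - 1] && hb[j + 1, i]) || (hb[j, i - 1] && hb[i + 1, j])
        anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (para || anti) bridge[i, j] <- bridge[j, i] <- TRUE
      }
    }
    has_bridge <- apply(bridge, 1, any)
    # ladders: a bridge residue whose sequence neighbour also bridges
    for (i in which(has_bridge)) {
      nb <- (i > 1 && has_bridge[i - 1] && res$chain[i - 1] == res$chain[i]) ||
        (i < n && has_bridge[i + 1] && res$chain[i + 1] == res$chain[i])
      if (nb) ss[i] <- "E"
    }
    # helices: 4-turns at i-1 and i label i..i+3
    turn4 <- vapply(seq_len(n), function(i) {
      i + 4 <= n && res$chain[i] == res$chain[i + 4] && hb[i + 4, i]
    }, logical(1))
    for (i in 2:n) {
      if (turn4[i] && turn4[i - 1]) {
        ss[seq(i, min(n, i + 3))] <- "H"
      }
    }
  }
  tibble::tibble(chain = res$chain, res_seq = res$res_seq,
                 i_code = res$i_code, res_name = res$res_name, ss = ss)
}

#' Beta-sheet strand segments of an assignment
#'
#' Maximal runs of `E`-labelled residues, optionally only those of at
#' least `min_length` residues.
#'
#' @param labels Output of [assign_secondary_structure()].
#' @param min_length Minimum run length (default 3).
#' @return Tibble: `chain`, `first`, `last`, `length`.
#' @export
strand_segments <- function(labels, min_length = 3) {
  r <- rle(paste(labels$chain, labels$ss == "E"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- grepl("TRUE$", r$values) & r$lengths >= min_length
  tibble::tibble(chain = labels$chain[starts[keep]],
                 first = labels$res_seq[starts[keep]],
                 last = labels$res_seq[ends[keep]],
                 length = r$lengths[keep])
}

#' Beta-sheet content of a residue window, in percent
#'
#' `100 * (#E residues in range) / (#residues in range)`, rounded to the
#' nearest integer percent for reporting.
#'
#' @param labels Output of [assign_secondary_structure()].
#' @param first,last Residue window (author numbering); defaults to all.
#' @param chain Optional chain restriction.
#' @return Integer percent.
#' @export
sheet_content <- function(labels, first = -Inf, last = Inf, chain = NULL) {
  keep <- labels$res_seq >= first & labels$res_seq <= last
  if (!is.null(chain)) keep <- keep & labels$chain == chain
  if (!any(keep)) stop("empty residue range for sheet content")
  round(100 * mean(labels$ss[keep] == "E"))
}
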