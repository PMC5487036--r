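# Loading the deposited reference entries (candidate domains + template)
# and the checks that depend on their real coordinates/sequences. The
# package does not bundle these entries; they are read from a local
# directory or downloaded on demand.

REFERENCE_ENTRIES <- c("3phs", "4oq1", "3kpt", "2x5p")

#' Load a deposited PDB entry from a local cache (or download it)
#'
#' Looks for `<id>.pdb` in `dir`; when absent and `download = TRUE`,
#' attempts to fetch it from the RCSB file server. Offline with an empty
#' cache this fails with an informative error.
#'
#' @param id 4-character PDB identifier.
#' @param dir Directory with `<id>.pdb` files.
#' @param download Attempt a download on a cache miss?
#' @return A `cna_structure`.
#' @export
fetch_pdb_entry <- function(id, dir = getOption("cnasplit.pdb_dir", "."),
                            download = TRUE) {
  id <- tolower(id)
  path <- file.path(dir, paste0(id, ".pdb"))
  if (!file.exists(path)) {
    if (!download) stop("PDB entry ", id, " not found under ", dir)
    url <- paste0("https://files.rcsb.org/download/", toupper(id), ".pdb")
    ok <- tryCatch({
      utils::download.file(url, path, quiet = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(path)) {
      stop("PDB entry ", id, " is not cached under ", dir,
           " and could not be downloaded")
    }
  }
  read_structure(path, header_id = id)
}

#' Coordinate- and sequence-level checks on the deposited entries
#'
#' Recomputes, from the real deposited structures, the candidate-selection
#' and fold-similarity quantities: all pairwise sequence identities among
#' the four domain sequences and the template CnaB domain; all pairwise
#' backbone (CA) RMSDs among the parent domains after sequence-alignment-
#' guided superposition; the number of beta-strands assigned in the
#' template domain; and the beta-sheet content of the 4oq1 catcher range.
#'
#' @param dir Directory holding `3phs.pdb`, `4oq1.pdb`, `3kpt.pdb`,
#'   `2x5p.pdb` (fetched on demand when a connection exists).
#' @param chains Named chain overrides per entry (defaults to the first
#'   chain containing each domain range).
#' @param download Passed to [fetch_pdb_entry()].
#' @return List: `identity` (a [screen_candidates()] result),
#'   `rmsd_pairs` (tibble of pairwise CA RMSDs), `template_strands`
#'   (strand count), `catcher_sheet_content` (percent).
#' @export
screen_reference_entries <- function(dir = getOption("cnasplit.pdb_dir",
                                                     "."),
                                     chains = NULL, download = TRUE) {
  entries <- list()
  for (id in REFERENCE_ENTRIES) {
    entries[[id]] <- fetch_pdb_entry(id, dir, download)
  }
  sys <- cna_systems()
  pick_chain <- function(model, first, last, id) {
    if (!is.null(chains) && id %in% names(chains)) return(chains[[id]])
    hit <- unique(model$chain[model$res_seq >= first &
                                model$res_seq <= last])
    if (length(hit) == 0) stop("no chain covers ", first, "-", last,
                               " in ", id)
    hit[1]
  }
  domains <- lapply(sys$system, function(s) {
    row <- sys[sys$system == s, ]
    id <- if (grepl("^3kpt", s)) "3kpt" else s
    ch <- pick_chain(entries[[id]], row$catcher_first, row$tag_last, id)
    select_residues(entries[[id]], ch, row$catcher_first, row$tag_last)
  })
  names(domains) <- sys$system
  # template CnaB domain of the Spy system
  t_ch <- unique(entries[["2x5p"]]$chain)[1]
  domains[["spy"]] <- select_residues(entries[["2x5p"]], t_ch,
                                      min(entries[["2x5p"]]$res_seq),
                                      max(entries[["2x5p"]]$res_seq))

  seqs <- vapply(domains, residue_sequence, character(1))
  identity <- screen_candidates(seqs, threshold = 30)

  # pairwise CA RMSD after alignment-guided superposition
  parents <- names(domains)[names(domains) != "spy"]
  combos <- utils::combn(parents, 2)
  rmsd_pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    tibble::tibble(a = a, b = b,
                   rmsd = aligned_ca_rmsd(domains[[a]], domains[[b]]))
  })

  labels <- assign_secondary_structure(domains[["spy"]])
  template_strands <- nrow(strand_segments(labels, min_length = 3))

  lab4 <- assign_secondary_structure(domains[["4oq1"]])
  content <- sheet_content(lab4, first = sys$catcher_first[sys$system ==
                                                             "4oq1"],
                           last = sys$catcher_last[sys$system == "4oq1"])
  list(identity = identity, rmsd_pairs = rmsd_pairs,
       template_strands = template_strands,
       catcher_sheet_content = content)
}

#' CA RMSD of two domains after sequence-alignment-guided superposition
#'
#' Globally aligns the two sequences, superposes the CA atoms of the
#' aligned (ungapped) residue pairs with the Kabsch algorithm and
#' returns the RMSD over those atoms.
#'
#' @param model_a,model_b Single-chain `cna_structure` domains.
#' @return RMSD in Angstrom.
#' @export
aligned_ca_rmsd <- function(model_a, model_b) {
  sa <- residue_sequence(model_a)
  sb <- residue_sequence(model_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ra <- residue_table(model_a); rb <- residue_table(model_b)
  ia <- cumsum(pa != "-"); ib <- cumsum(pb != "-")
  keep <- pa != "-" & pb != "-"
  ca_of <- function(model, res, rows) {
    at <- as_atom_tbl(model)
    m <- matrix(NA_real_, length(rows), 3)
    for (i in seq_along(rows)) {
      r <- res[rows[i], ]
      hit <- at[at$chain == r$chain & at$res_seq == r$res_seq &
                  at$i_code == r$i_code & at$atom == "CA", ]
      if (nrow(hit) > 0) m[i, ] <- c(hit$x[1], hit$y[1], hit$z[1])
    }
    m
  }
  ma <- ca_of(model_a, ra, ia[keep])
  mb <- ca_of(model_b, rb, ib[keep])
  ok <- stats::complete.cases(ma) & stats::complete.cases(mb)
  kabsch_superpose(ma[ok, , drop = FALSE], mb[ok, , drop = FALSE])$rmsd
}
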