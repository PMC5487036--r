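# Synthetic stand-in parent domains for the four candidate systems.
# These carry the documented author numbering, split boundaries, core
# regions and (where reported) active-site residue numbers, on top of a
# geometric scaffold: a parallel two-strand sheet pairing the first
# catcher residues with the tag, a connecting coil, and a planted triad.
# They are stand-ins for the deposited crystal structures, which this
# toolkit does not bundle; coordinate-dependent properties of the real
# entries (fold, loop structure, strand count) are NOT reproduced.

#' Candidate tag/catcher systems and their documented boundaries
#'
#' One row per system: split boundaries and rigid-core windows in author
#' numbering, plus active-site (triad) residue numbers.
#' `triad_source = "reported"` marks triads taken from the published
#' mutant lists; `"stand-in"` marks positions invented for the synthetic
#' scaffolds where no triad numbering is on record (the detector is
#' there to report them from a real structure).
#'
#' @return Tibble with columns `system`, `chain`, `catcher_first`,
#'   `catcher_last`, `tag_first`, `tag_last`, `core_first`, `core_last`,
#'   `lys`, `acceptor`, `catalytic`, `triad_source`.
#' @export
cna_systems <- function() {
  tibble::tibble(
    system = c("3phs", "4oq1", "3kptN", "3kptC"),
    chain = "A",
    catcher_first = c(152L, 146L, 164L, 409L),
    catcher_last  = c(245L, 240L, 255L, 500L),
    tag_first     = c(248L, 246L, 258L, 505L),
    tag_last      = c(263L, 259L, 272L, 518L),
    core_first    = c(167L, 183L, 186L, 429L),
    core_last     = c(207L, 223L, 225L, 469L),
    lys       = c(161L, 155L, 173L, 417L),
    acceptor  = c(256L, 252L, 266L, 512L),
    catalytic = c(230L, 222L, 240L, 472L),
    triad_source = c("stand-in", "reported", "stand-in", "reported"))
}

# residue identities documented for variant design, keyed by author number
KNOWN_IDENTITIES <- list(
  `4oq1` = c(`239` = "Q", `240` = "L", `241` = "V", `243` = "H",
             `244` = "Q", `245` = "L", `246` = "V", `257` = "R",
             `258` = "G", `259` = "N"),
  `3kptC` = c(`501` = "E", `502` = "N", `503` = "N", `504` = "Q",
              `505` = "T", `506` = "V", `515` = "S", `516` = "P",
              `517` = "T", `518` = "K"))

system_seed <- function(system) sum(utf8ToInt(system)) + 7L

#' Build a synthetic stand-in parent domain for one system
#'
#' See the file-level description: the result has the documented
#' residue numbering, a parallel sheet pairing the first catcher
#' residues with the tag strand, a coil carrying the remaining
#' residues, and a planted triad at the system's active-site numbers
#' (NZ-CG at `triad_nz_cg`, covalent by default, as in the deposited
#' entries). Residue identities documented in the construct designs are
#' honoured; all other identities are sampled deterministically per
#' system.
#'
#' @param system One of `"3phs"`, `"4oq1"`, `"3kptN"`, `"3kptC"`.
#' @param triad_nz_cg Planted NZ-CG distance (default 1.33, covalent).
#' @param hbond_distance Sheet ladder N...O distance.
#' @return A `cna_structure` (single chain `A`), attribute `ladder` from
#'   the sheet construction.
#' @export
make_synthetic_domain <- function(system = c("4oq1", "3phs", "3kptN",
                                             "3kptC"),
                                  triad_nz_cg = 1.33,
                                  hbond_distance = 2.9) {
  system <- match.arg(system)
  sys <- cna_systems()[cna_systems()$system == system, ]
  seed <- system_seed(system)
  n_tag <- sys$tag_last - sys$tag_first + 1
  dom_first <- sys$catcher_first
  dom_last <- sys$tag_last

  # sequence over the whole domain span, documented identities enforced
  span <- seq(dom_first, dom_last)
  letters1 <- strsplit(sample_fixture_seq(length(span), seed), "")[[1]]
  names(letters1) <- span
  known <- KNOWN_IDENTITIES[[system]]
  if (!is.null(known)) letters1[names(known)] <- known

  strand_a_res <- seq(dom_first, length.out = n_tag)
  strand_b_res <- seq(sys$tag_first, sys$tag_last)
  loop_res <- setdiff(span, c(strand_a_res, strand_b_res))

  sheet <- make_two_strand_parallel(
    n_residues = n_tag, hbond_distance = hbond_distance,
    chain_a = "A", chain_b = "B",
    start_a = dom_first, start_b = sys$tag_first,
    seq_a = paste(letters1[as.character(strand_a_res)], collapse = ""),
    seq_b = paste(letters1[as.character(strand_b_res)], collapse = ""),
    seed = seed)
  ladder <- attr(sheet, "ladder")
  at <- as_atom_tbl(sheet)
  at$chain <- "A"
  ladder$donor_chain <- "A"; ladder$acceptor_chain <- "A"

  # connecting coil on a circle well away from the sheet plane
  n_loop <- length(loop_res)
  radius <- max(12, 3.8 * n_loop / (2 * pi))
  theta <- 2 * pi * (seq_len(n_loop) - 1) / max(n_loop, 1)
  template <- build_strand_coords(1)
  loop_at <- purrr::map_dfr(seq_len(n_loop), function(i) {
    ctr <- c(radius * cos(theta[i]) + 10, radius * sin(theta[i]) + 15, 30)
    xyz <- rbind(template$N[1, ], template$CA[1, ], template$C[1, ],
                 template$O[1, ]) + matrix(ctr, 4, 3, byrow = TRUE)
    tibble::tibble(serial = NA_integer_, atom = c("N", "CA", "C", "O"),
                   alt_loc = "",
                   res_name = AA_1TO3[[letters1[[as.character(loop_res[i])]]]],
                   chain = "A", res_seq = loop_res[i], i_code = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, element = c("N", "C", "C", "O"))
  })
  at <- dplyr::bind_rows(at, loop_at)
  at <- at[order(at$res_seq), ]
  model <- new_structure(at, header_id = paste0("synthetic-", system))
  model <- plant_triad(model,
                       lys = list(chain = "A", res_seq = sys$lys),
                       acceptor = list(chain = "A", res_seq = sys$acceptor),
                       catalytic = list(chain = "A", res_seq = sys$catalytic),
                       triad_nz_cg = triad_nz_cg, seed = seed)
  model <- complete_lys_sidechains(model)
  attr(model, "ladder") <- ladder
  model
}

#' Split specification of a documented system
#' @param system System label (see [cna_systems()]).
#' @return A [split_spec()] with the Table-of-systems boundaries.
#' @export
system_split_spec <- function(system) {
  sys <- cna_systems()[cna_systems()$system == system, ]
  if (nrow(sys) == 0) stop("unknown system: ", system)
  split_spec("A", sys$catcher_first, sys$catcher_last, sys$tag_first,
             sys$tag_last)
}
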