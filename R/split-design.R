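# Turning a parent CnaB domain plus a residue-range split specification
# into validated tag/catcher constructs, variants, mutants and fusions.

#' Residue-range split specification
#'
#' Defines the catcher and tag ranges in author numbering. The deleted
#' linker range is always derived, never user-supplied:
#' `(catcher_last+1) ... (tag_first-1)`, possibly empty. The domain span
#' runs from the first catcher residue to the last tag residue.
#'
#' @param chain Chain identifier.
#' @param catcher_first,catcher_last,tag_first,tag_last Author residue
#'   numbers, inclusive; `catcher_first <= catcher_last < tag_first <=
#'   tag_last`.
#' @return List of class `cna_split_spec` with the four boundaries plus
#'   `deleted_first`/`deleted_last` (`NA` when nothing is deleted).
#' @export
split_spec <- function(chain, catcher_first, catcher_last, tag_first,
                       tag_last) {
  if (!(catcher_first <= catcher_last && catcher_last < tag_first &&
          tag_first <= tag_last)) {
    stop("require catcher_first <= catcher_last < tag_first <= tag_last")
  }
  del <- if (tag_first - catcher_last > 1) {
    c(catcher_last + 1, tag_first - 1)
  } else c(NA_integer_, NA_integer_)
  structure(list(chain = chain,
                 catcher_first = catcher_first, catcher_last = catcher_last,
                 tag_first = tag_first, tag_last = tag_last,
                 deleted_first = del[1], deleted_last = del[2]),
            class = "cna_split_spec")
}

#' Deleted residue numbers of a split
#' @param split A [split_spec()].
#' @return Integer vector (possibly empty).
#' @export
deleted_range <- function(split) {
  if (is.na(split$deleted_first)) return(integer(0))
  seq(split$deleted_first, split$deleted_last)
}

#' Split a parent domain into tag and catcher constructs
#'
#' Extracts the catcher range as one chain and the tag range as a second
#' chain, removes the deleted linker residues, and validates the triad
#' placement: the reactive Lys and the catalytic residue must lie in the
#' catcher range and the acceptor Asn/Asp in the tag range (the Spy-like
#' topology with a C-terminal tag; N-terminal-tag designs are rejected);
#' no triad member may fall in the deleted range.
#'
#' @param parent A `cna_structure` containing the domain.
#' @param split A [split_spec()].
#' @param triad A one-row triad as returned by [detect_isopeptide()].
#' @return List of class `cna_constructs`: `catcher` and `tag`
#'   structures (separate chain ids), `deleted` residue table,
#'   `catcher_seq`, `tag_seq`, `deleted_seq`, `caps` descriptors and the
#'   `split`/`triad` used.
#' @export
make_split <- function(parent, split, triad) {
  placement <- triad_in_ranges(triad, split)
  bad <- placement[!is.na(placement$placement) &
                     !(placement$member == "lys" & placement$placement == "catcher") &
                     !(placement$member == "catalytic" & placement$placement == "catcher") &
                     !(placement$member == "acceptor" & placement$placement == "tag"), ]
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    hint <- if (b$member == "acceptor" && b$placement == "catcher")
      " (N-terminal-tag topology is not supported; tags carry the acceptor)"
    else ""
    stop("triad member '", b$member, "' (residue ", b$res_seq,
         ") falls in the ", b$placement, " range", hint)
  }

  catcher <- select_residues(parent, split$chain, split$catcher_first,
                             split$catcher_last)
  tag <- select_residues(parent, split$chain, split$tag_first, split$tag_last)
  for (rng in list(c(split$catcher_first, split$catcher_last),
                   c(split$tag_first, split$tag_last))) {
    present <- sort(unique(parent$res_seq[parent$chain == split$chain &
                                            parent$res_seq >= rng[1] &
                                            parent$res_seq <= rng[2]]))
    gaps <- setdiff(seq(rng[1], rng[2]), present)
    if (length(gaps) > 0) {
      warning("non-contiguous numbering in range ", rng[1], "-", rng[2],
              "; missing residues: ", paste(gaps, collapse = ", "))
    }
  }
  # tag becomes its own chain; author numbering untouched
  tag_chain <- setdiff(LETTERS, split$chain)[1]
  tag$chain <- tag_chain

  del <- deleted_range(split)
  deleted_tbl <- residue_table(parent) |>
    dplyr::filter(.data$chain == split$chain, .data$res_seq %in% del)
  deleted_seq <- if (nrow(deleted_tbl) > 0) {
    letters1 <- AA_3TO1[deleted_tbl$res_name]
    letters1[is.na(letters1)] <- "X"
    paste(letters1, collapse = "")
  } else ""

  structure(list(
    catcher = catcher, tag = tag, deleted = deleted_tbl,
    catcher_seq = residue_sequence(catcher),
    tag_seq = residue_sequence(tag),
    deleted_seq = deleted_seq,
    # original domain termini get capped for simulation, new split
    # termini stay ionic
    caps = list(catcher = list(n = "acetyl", c = "ionic"),
                tag = list(n = "ionic", c = "n_methyl")),
    split = split, triad = triad), class = "cna_constructs")
}

#' @export
print.cna_constructs <- function(x, ...) {
  cat("<cna_constructs> catcher ", x$split$catcher_first, "-",
      x$split$catcher_last, " (", nchar(x$catcher_seq), " aa), tag ",
      x$split$tag_first, "-", x$split$tag_last, " (", nchar(x$tag_seq),
      " aa), deleted {", paste(deleted_range(x$split), collapse = ","),
      "}\n", sep = "")
  invisible(x)
}

# ideal internal coordinates for cap construction
CAP_GEOM <- list(c_n = 1.335, c_o = 1.229, c_ch3 = 1.520, n_ch3 = 1.449)

#' Cap chain termini with acetyl / N-methyl groups
#'
#' `acetyl` prepends an `ACE` residue before the N-terminus, `n_methyl`
#' appends an `NME` residue after the C-terminus; `ionic` leaves a
#' terminus unmodified (charged). Cap heavy atoms are placed
#' deterministically by extending the terminal peptide-bond geometry with
#' ideal bond lengths and angles.
#'
#' @param model A single-chain `cna_structure`.
#' @param scheme List with elements `n` and `c`, each one of
#'   `"acetyl"`/`"n_methyl"`/`"ionic"` as appropriate for the terminus.
#' @return The capped `cna_structure`.
#' @export
cap_termini <- function(model, scheme = list(n = "ionic", c = "ionic")) {
  at <- as_atom_tbl(model)
  res <- residue_table(model)
  get_xyz <- function(rrow, name) {
    hit <- at[at$chain == rrow$chain & at$res_seq == rrow$res_seq &
                at$i_code == rrow$i_code & at$atom == name, ]
    if (nrow(hit) == 0) {
      stop("terminal residue ", rrow$res_seq, " lacks backbone atom ", name)
    }
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  mk_atoms <- function(names, xyz, res_name, chain, res_seq) {
    tibble::tibble(serial = NA_integer_, atom = names, alt_loc = "",
                   res_name = res_name, chain = chain, res_seq = res_seq,
                   i_code = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, element = substr(names, 1, 1))
  }
  out <- at
  if (identical(scheme$n, "acetyl")) {
    r1 <- res[1, ]
    n1 <- get_xyz(r1, "N"); ca1 <- get_xyz(r1, "CA"); c1 <- get_xyz(r1, "C")
    c_ace <- place_atom(c1, ca1, n1, CAP_GEOM$c_n, 121.7, 180)
    o_ace <- place_atom(ca1, n1, c_ace, CAP_GEOM$c_o, 122.9, 0)
    ch3 <- place_atom(ca1, n1, c_ace, CAP_GEOM$c_ch3, 116.6, 180)
    ace <- mk_atoms(c("CH3", "C", "O"), rbind(ch3, c_ace, o_ace),
                    "ACE", r1$chain, r1$res_seq - 1L)
    ace$element <- c("C", "C", "O")
    out <- dplyr::bind_rows(ace, out)
  } else if (!identical(scheme$n, "ionic") && !is.null(scheme$n)) {
    stop("unknown N-terminal cap scheme: ", scheme$n)
  }
  if (identical(scheme$c, "n_methyl")) {
    rl <- res[nrow(res), ]
    nl <- get_xyz(rl, "N"); cal <- get_xyz(rl, "CA"); cl <- get_xyz(rl, "C")
    n_nme <- place_atom(nl, cal, cl, CAP_GEOM$c_n, 116.6, 180)
    ch3 <- place_atom(cal, cl, n_nme, CAP_GEOM$n_ch3, 121.7, 180)
    nme <- mk_atoms(c("N", "CH3"), rbind(n_nme, ch3),
                    "NME", rl$chain, rl$res_seq + 1L)
    nme$element <- c("N", "C")
    out <- dplyr::bind_rows(out, nme)
  } else if (!identical(scheme$c, "ionic") && !is.null(scheme$c)) {
    stop("unknown C-terminal cap scheme: ", scheme$c)
  }
  restore_structure(out, model)
}

#' Variant specification for a construct sequence
#'
#' @param n_extension Either a literal sequence to prepend (e.g. `"L"`,
#'   `"NQ"`) or a numeric `c(first, last)` range taken from the parent in
#'   author numbering.
#' @param c_truncation Number of residues removed from the C-terminus.
#' @param c_replacement Literal sequence replacing the same number of
#'   C-terminal residues (e.g. `"GWI"` for a PTK -> GWI swap). At most
#'   one C-terminal edit per variant.
#' @return List of class `cna_variant_spec`.
#' @export
variant_spec <- function(n_extension = NULL, c_truncation = 0,
                         c_replacement = NULL) {
  if (c_truncation > 0 && !is.null(c_replacement)) {
    stop("at most one C-terminal edit per variant")
  }
  structure(list(n_extension = n_extension, c_truncation = c_truncation,
                 c_replacement = c_replacement),
            class = "cna_variant_spec")
}

#' Apply a tag/catcher length or sequence variant
#'
#' @param construct_seq Construct sequence to edit.
#' @param parent Parent `cna_structure` (needed when the N-extension is
#'   given as a residue-number range).
#' @param v A [variant_spec()].
#' @return The edited sequence.
#' @export
apply_variant <- function(construct_seq, parent = NULL, v) {
  seq <- construct_seq
  if (v$c_truncation > 0) {
    if (v$c_truncation >= nchar(seq)) stop("truncation longer than sequence")
    seq <- substr(seq, 1, nchar(seq) - v$c_truncation)
  }
  if (!is.null(v$c_replacement)) {
    k <- nchar(v$c_replacement)
    if (k > nchar(seq)) stop("replacement longer than sequence")
    seq <- paste0(substr(seq, 1, nchar(seq) - k), v$c_replacement)
  }
  if (!is.null(v$n_extension)) {
    ext <- if (is.numeric(v$n_extension)) {
      if (is.null(parent)) stop("numeric N-extension needs the parent model")
      residue_sequence(parent, NULL, v$n_extension[1],
                       v$n_extension[length(v$n_extension)])
    } else v$n_extension
    seq <- paste0(ext, seq)
  }
  seq
}

#' Apply a point mutation given in parent numbering
#'
#' @param seq Construct sequence.
#' @param mutation String like `"K155A"` (wild type, author-numbered
#'   position, replacement).
#' @param numbering_offset Author number of sequence position 1, minus 1
#'   (i.e. `pos = number - numbering_offset`).
#' @return Mutated sequence.
#' @export
make_point_mutant <- function(seq, mutation, numbering_offset = 0) {
  m <- regmatches(mutation,
                  regexec("^([A-Z])([0-9]+)([A-Z])$", mutation))[[1]]
  if (length(m) != 4) stop("mutation must look like 'K155A'")
  wt <- m[2]; num <- as.integer(m[3]); mut <- m[4]
  pos <- num - numbering_offset
  if (pos < 1 || pos > nchar(seq)) {
    stop("position ", num, " falls outside the construct")
  }
  found <- substr(seq, pos, pos)
  if (found != wt) {
    stop("wild-type mismatch at ", num, ": expected ", wt, ", found ", found)
  }
  substr(seq, pos, pos) <- mut
  seq
}

part_checksum <- function(seq) {
  v <- utf8ToInt(seq)
  sprintf("%08x", sum(v * seq_along(v)) %% 4294967291)
}

#' Load the fusion-part sequence library
#'
#' Parts used to assemble expression constructs: His6 tag, HA tag, the
#' glycine-serine linkers `GSGSGSG` and `GSGESG`, maltose binding protein
#' and mCherry. The default library ships in
#' `inst/extdata/synthetic_parts.fasta`; the MBP and mCherry entries there
#' are synthetic stand-in sequences that reproduce the length and average
#' mass of the real parts (see the file header). Reports echo per-part
#' checksums so any edited library is identifiable.
#'
#' @param path Optional FASTA path overriding the shipped library.
#' @return Named list of sequences with attribute `checksums`.
#' @export
fusion_part_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_parts.fasta",
                        package = "cnasplit", mustWork = TRUE)
  }
  seqs <- read_fasta(path)
  if (any(!nzchar(seqs))) stop("empty part sequence in library")
  lib <- as.list(seqs)
  attr(lib, "checksums") <- vapply(lib, part_checksum, character(1))
  lib
}

#' Assemble a fusion construct from named parts
#'
#' Concatenates parts in order and reports per-part spans, checksums and
#' the total average mass.
#'
#' @param parts Character vector of part names and/or literal sequences
#'   (entries not found in the library are treated as literal amino-acid
#'   sequences, e.g. a tag peptide).
#' @param library A [fusion_part_library()].
#' @return List of class `cna_fusion`: `sequence`, `parts` tibble
#'   (`part`, `start`, `end`, `mass`), `mass` (Da).
#' @export
assemble_fusion <- function(parts, library = fusion_part_library()) {
  seqs <- lapply(parts, function(p) {
    if (p %in% names(library)) return(library[[p]])
    if (grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", p)) return(p)
    stop("unknown fusion part: ", p)
  })
  lens <- vapply(seqs, nchar, integer(1))
  ends <- cumsum(lens)
  tbl <- tibble::tibble(part = parts, start = ends - lens + 1L, end = ends,
                        mass = vapply(seqs, compute_mass, numeric(1)),
                        checksum = vapply(unlist(seqs), part_checksum,
                                          character(1), USE.NAMES = FALSE))
  sequence <- paste(unlist(seqs), collapse = "")
  structure(list(sequence = sequence, parts = tbl,
                 mass = compute_mass(sequence)), class = "cna_fusion")
}

#' @export
print.cna_fusion <- function(x, ...) {
  cat("<cna_fusion>", nchar(x$sequence), "aa,",
      sprintf("%.1f kDa", x$mass / 1000), "\n")
  print(x$parts)
  invisible(x)
}

#' Simulation preparation protocol constants
#'
#' Defaults mirror a standard explicit-solvent NPT protocol for these
#' systems: TIP3P water with a 10 Angstrom margin, neutralising
#' counter-ions, three-stage restrained heating to 310 K (5 kcal/mol/A^2
#' all-protein restraints for 0.1 ns, CA-only for 0.4 ns, unrestrained
#' for 0.5 ns) and 200 ns production with a 2 fs step under bond-length
#' constraints on hydrogens.
#'
#' @param solvent_margin,water_model,temperature,production_ns,timestep_fs
#'   Override individual constants.
#' @return List of class `cna_prep_protocol`.
#' @export
prep_protocol <- function(solvent_margin = 10, water_model = "TIP3P",
                          temperature = 310, production_ns = 200,
                          timestep_fs = 2) {
  stopifnot(temperature > 0)
  structure(list(
    solvent_margin = solvent_margin, water_model = water_model,
    temperature = temperature,
    restraint_stages = list(
      list(restraint = "all-protein", force_constant = 5, duration_ns = 0.1),
      list(restraint = "backbone-CA", force_constant = 5, duration_ns = 0.4),
      list(restraint = "none", force_constant = 0, duration_ns = 0.5)),
    production_ns = production_ns, ensemble = "NPT",
    timestep_fs = timestep_fs,
    constraints = "bond lengths involving hydrogen"),
    class = "cna_prep_protocol")
}

#' Emit a machine-readable MD preparation recipe
#'
#' Describes everything a simulation package needs to set the system up:
#' capping scheme, solvation and neutralisation, the restrained-heating
#' stages and production length. Split (tag/catcher) systems are prepared
#' without the isopeptide bond, mimicking the initial recognition stage;
#' the flag records this.
#'
#' @param constructs A `cna_constructs` (split system) or a
#'   `cna_structure` (intact domain).
#' @param protocol A [prep_protocol()].
#' @param dest Optional YAML output path.
#' @return The recipe as a list, invisibly when written.
#' @export
emit_md_recipe <- function(constructs, protocol = prep_protocol(),
                           dest = NULL) {
  is_split <- inherits(constructs, "cna_constructs")
  recipe <- list(
    kind = if (is_split) "tag_catcher" else "intact_domain",
    isopeptide_bond_present = !is_split,
    chains = if (is_split) {
      list(catcher = list(chain = constructs$catcher$chain[1],
                          first = constructs$split$catcher_first,
                          last = constructs$split$catcher_last,
                          caps = constructs$caps$catcher),
           tag = list(chain = constructs$tag$chain[1],
                      first = constructs$split$tag_first,
                      last = constructs$split$tag_last,
                      caps = constructs$caps$tag))
    } else {
      list(domain = list(chain = constructs$chain[1],
                         first = min(constructs$res_seq),
                         last = max(constructs$res_seq),
                         caps = list(n = "acetyl", c = "n_methyl")))
    },
    solvation = list(box = "truncated_octahedron",
                     water_model = protocol$water_model,
                     margin = protocol$solvent_margin,
                     neutralize = "monovalent counter ions"),
    equilibration = list(target_temperature = protocol$temperature,
                         stages = protocol$restraint_stages),
    production = list(length_ns = protocol$production_ns,
                      ensemble = protocol$ensemble,
                      timestep_fs = protocol$timestep_fs,
                      constraints = protocol$constraints))
  if (!is.null(dest)) {
    yaml::write_yaml(recipe, dest)
    return(invisible(recipe))
  }
  recipe
}

#' Read back an MD preparation recipe
#' @param path YAML path written by [emit_md_recipe()].
#' @return Recipe list.
#' @export
read_md_recipe <- function(path) yaml::read_yaml(path)
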