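# Stability read-outs on trajectories: core-region backbone RMSD,
# tag<->catcher 12-6 van der Waals energy, beta-sheet hydrogen-bond
# distances, and a contact-based dissociation monitor.

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Built-in rigid core regions of the four candidate systems
#'
#' The residue windows comprising the rigid secondary-structure elements
#' used as superposition/RMSD selections, in author numbering.
#'
#' @return Tibble with columns `system`, `first`, `last`.
#' @export
core_regions <- function() {
  tibble::tibble(system = c("3phs", "4oq1", "3kptN", "3kptC"),
                 first = c(167L, 183L, 186L, 429L),
                 last  = c(207L, 223L, 225L, 469L))
}

frame_coords <- function(traj, k, idx) {
  matrix(traj$coords[k, idx, ], ncol = 3)
}

new_series <- function(values, unit, label, frame_times = NULL) {
  out <- tibble::tibble(frame = seq_along(values), value = values)
  if (!is.null(frame_times)) out$time <- frame_times
  structure(out, class = c("cna_series", class(tibble::tibble())),
            unit = unit, label = label)
}

#' @export
print.cna_series <- function(x, ...) {
  cat("<cna_series>", attr(x, "label"), "-", nrow(x), "frames, mean",
      sprintf("%.3f", mean(x$value)), attr(x, "unit"), "\n")
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
glance.cna_series <- function(x, ...) {
  tibble::tibble(label = attr(x, "label"), n_frames = nrow(x),
                 mean = mean(x$value), sd = stats::sd(x$value),
                 unit = attr(x, "unit"))
}

#' @export
tidy.cna_series <- function(x, ...) tibble::as_tibble(x)

select_series_atoms <- function(topology, chain = NULL, first, last, atoms) {
  at <- as_atom_tbl(topology)
  idx <- which((if (is.null(chain)) TRUE else at$chain == chain) &
                 at$res_seq >= first & at$res_seq <= last &
                 at$atom %in% atoms)
  if (length(idx) == 0) stop("no atoms selected in ", first, "-", last)
  idx
}

#' Core-region backbone RMSD time series
#'
#' The first frame (the initial structure) is the reference; each frame
#' is superposed on the core backbone (`N`, `CA`, `C`, `O`) with the
#' Kabsch algorithm, and the RMSD over the same atoms is reported.
#'
#' @param traj A `cna_trajectory`.
#' @param core_first,core_last Core residue window (author numbering).
#' @param chain Optional chain restriction.
#' @param atoms Backbone atom set.
#' @return A `cna_series` (Angstrom).
#' @export
core_rmsd_series <- function(traj, core_first, core_last, chain = NULL,
                             atoms = BACKBONE_ATOMS) {
  top <- traj$topology
  idx <- select_series_atoms(top, chain, core_first, core_last, atoms)
  res <- residue_table(select_residues(top, chain, core_first, core_last))
  have <- as_atom_tbl(top)[idx, ]
  counts <- table(have$res_seq)
  short <- res$res_seq[!(res$res_seq %in% names(counts)[counts == length(atoms)])]
  if (length(short) > 0 && all(res$res_name %in% names(AA_3TO1))) {
    stop("missing backbone atoms in core residues: ",
         paste(short, collapse = ", "))
  }
  ref <- frame_coords(traj, 1, idx)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    kabsch_superpose(ref, frame_coords(traj, k, idx))$rmsd
  }, numeric(1))
  new_series(vals, "Angstrom", "core backbone RMSD", traj$frame_times)
}

# AMBER-like generic heavy-atom 12-6 classes, keyed by element
DEFAULT_LJ_CLASSES <- tibble::tibble(
  class = c("C", "N", "O", "S", "H", "P"),
  epsilon = c(0.0860, 0.1700, 0.2100, 0.2500, 0.0157, 0.2000),
  rmin_half = c(1.9080, 1.8240, 1.6612, 2.0000, 0.6000, 2.1000))

#' Lennard-Jones parameter table
#'
#' Per-class well depth (kcal/mol) and `Rmin/2` (Angstrom), combined as
#' `eps_ij = sqrt(eps_i * eps_j)` and `rmin_ij = rmin_half_i +
#' rmin_half_j`. The default ships generic element-keyed values; a
#' user-supplied force-field table can replace it, and reports always
#' name the table used.
#'
#' @param classes Tibble with columns `class`, `epsilon`, `rmin_half`.
#' @param name Table identifier echoed in reports.
#' @return List of class `cna_lj_params`.
#' @export
lj_param_table <- function(classes = DEFAULT_LJ_CLASSES,
                           name = "generic-elements") {
  stopifnot(all(c("class", "epsilon", "rmin_half") %in% names(classes)),
            all(classes$epsilon >= 0), all(classes$rmin_half > 0))
  structure(list(classes = tibble::as_tibble(classes), name = name),
            class = "cna_lj_params")
}

lj_class_of <- function(atoms_tbl, params) {
  cl <- match(atoms_tbl$element, params$classes$class)
  if (any(is.na(cl))) {
    stop("no LJ class for element(s): ",
         paste(unique(atoms_tbl$element[is.na(cl)]), collapse = ", "))
  }
  cl
}

#' 12-6 van der Waals energy between two atom groups
#'
#' `E = sum eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` over all
#' cross-pairs, no cutoff, deterministic summation order. `exclusions`
#' is an optional two-column matrix of (group A row, group B row) pairs
#' to skip (bonded paths across the tag/catcher junction in the intact
#' domain).
#'
#' @param coords_a,coords_b `n x 3` coordinate matrices.
#' @param class_a,class_b Integer rows into `params$classes` per atom.
#' @param params A [lj_param_table()].
#' @param exclusions Optional 2-column integer matrix.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(coords_a, coords_b, class_a, class_b,
                      params = lj_param_table(), exclusions = NULL) {
  eps <- sqrt(outer(params$classes$epsilon[class_a],
                    params$classes$epsilon[class_b]))
  rmin <- outer(params$classes$rmin_half[class_a],
                params$classes$rmin_half[class_b], "+")
  r <- cross_distances(coords_a, coords_b)
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    r[exclusions] <- NA
  }
  if (any(r[!is.na(r)] == 0)) stop("zero interatomic distance in LJ sum")
  q <- (rmin / r)^6
  e <- eps * (q^2 - 2 * q)
  sum(e[!is.na(e)])
}

# covalent bonds inferred from heavy-atom distances in one frame
infer_bonds <- function(coords, elements, cutoff = 1.85, s_cutoff = 2.1) {
  d <- cross_distances(coords, coords)
  diag(d) <- Inf
  cut <- matrix(cutoff, nrow(d), ncol(d))
  s <- elements == "S"
  cut[s, ] <- s_cutoff; cut[, s] <- s_cutoff
  h <- elements == "H"
  cut[h, ] <- 1.3; cut[, h] <- 1.3
  which(d <= cut & upper.tri(d), arr.ind = TRUE)
}

#' Bonded-path exclusions across the tag/catcher junction
#'
#' For the intact domain, atom pairs connected by at most `max_bonds`
#' covalent bonds across the junction are excluded from the cross-group
#' LJ sum (standard 1-2/1-3 exclusion; 1-4 pairs are kept at full
#' weight). Bonds are inferred from heavy-atom distances in the reference
#' frame. For split systems there is no covalent connection and no
#' exclusion applies.
#'
#' @param topology A `cna_structure`.
#' @param idx_a,idx_b Atom row indices of the two groups.
#' @param frame_coords `n x 3` matrix of reference coordinates.
#' @param max_bonds Bond-path cutoff (default 3).
#' @return 2-column matrix of (A-row, B-row) exclusions.
#' @export
junction_exclusions <- function(topology, idx_a, idx_b, frame_coords,
                                max_bonds = 3) {
  # only spatially close cross pairs can be <= 3 bonds apart
  near <- which(cross_distances(frame_coords[idx_a, , drop = FALSE],
                                frame_coords[idx_b, , drop = FALSE]) < 6,
                arr.ind = TRUE)
  if (nrow(near) == 0) return(matrix(integer(0), 0, 2))
  bonds <- infer_bonds(frame_coords, topology$element)
  g <- igraph::graph_from_edgelist(bonds, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(topology) - igraph::vcount(g)))
  va <- idx_a[unique(near[, 1])]
  dists <- igraph::distances(g, v = va, to = idx_b[unique(near[, 2])])
  hit <- which(dists <= max_bonds, arr.ind = TRUE)
  if (nrow(hit) == 0) return(matrix(integer(0), 0, 2))
  cbind(match(va[hit[, 1]], idx_a),
        match(idx_b[unique(near[, 2])][hit[, 2]], idx_b))
}

#' Tag-catcher van der Waals energy time series
#'
#' Per-frame [lj_energy()] between the tag atom group and the catcher
#' atom group. For intact domains, pass the `exclusions` produced by
#' [junction_exclusions()] so covalently connected junction pairs are
#' skipped.
#'
#' @param traj A `cna_trajectory`.
#' @param idx_tag,idx_catcher Atom row indices into the topology.
#' @param params A [lj_param_table()].
#' @param exclusions Optional exclusion matrix (tag-row, catcher-row).
#' @return A `cna_series` (kcal/mol).
#' @export
lj_energy_series <- function(traj, idx_tag, idx_catcher,
                             params = lj_param_table(), exclusions = NULL) {
  top <- as_atom_tbl(traj$topology)
  ca <- lj_class_of(top[idx_tag, ], params)
  cb <- lj_class_of(top[idx_catcher, ], params)
  vals <- vapply(seq_len(n_frames(traj)), function(k) {
    lj_energy(frame_coords(traj, k, idx_tag),
              frame_coords(traj, k, idx_catcher),
              ca, cb, params, exclusions)
  }, numeric(1))
  new_series(vals, "kcal/mol",
             paste0("tag-catcher vdW energy [", params$name, "]"),
             traj$frame_times)
}

#' Atom row indices for a residue range
#'
#' @param model A `cna_structure`.
#' @param chain Optional chain restriction.
#' @param first,last Residue range (author numbering).
#' @param atoms Optional atom-name restriction; `heavy = TRUE` drops
#'   hydrogens.
#' @param heavy Drop hydrogens?
#' @return Integer row indices.
#' @export
atom_indices <- function(model, chain = NULL, first = -Inf, last = Inf,
                         atoms = NULL, heavy = TRUE) {
  at <- as_atom_tbl(model)
  keep <- (if (is.null(chain)) TRUE else at$chain == chain) &
    at$res_seq >= first & at$res_seq <= last
  if (!is.null(atoms)) keep <- keep & at$atom %in% atoms
  if (heavy) keep <- keep & at$element != "H"
  which(keep)
}

#' Beta-sheet backbone hydrogen-bond pairs in a reference structure
#'
#' All (tag backbone N, catcher backbone O) and (catcher N, tag O) pairs
#' with an N...O distance at or below `d_max`, each atom used at most
#' once per direction (the nearest partner wins).
#'
#' @param ref A `cna_structure`.
#' @param tag_sel,catcher_sel Lists `list(chain=, first=, last=)`
#'   selecting the two regions.
#' @param d_max Distance cutoff in Angstrom (default 3.5).
#' @return Tibble of class pairs: donor/acceptor chain + residue,
#'   direction, `ref_distance`.
#' @export
find_sheet_hbond_pairs <- function(ref, tag_sel, catcher_sel, d_max = 3.5) {
  at <- as_atom_tbl(ref)
  pick <- function(sel, name) {
    keep <- (if (is.null(sel$chain)) TRUE else at$chain == sel$chain) &
      at$res_seq >= sel$first & at$res_seq <= sel$last & at$atom == name
    at[keep, ]
  }
  one_direction <- function(don, acc, direction) {
    if (nrow(don) == 0 || nrow(acc) == 0) return(NULL)
    d <- cross_distances(as.matrix(don[, c("x", "y", "z")]),
                         as.matrix(acc[, c("x", "y", "z")]))
    pairs <- which(d <= d_max, arr.ind = TRUE)
    if (nrow(pairs) == 0) return(NULL)
    pairs <- pairs[order(d[pairs]), , drop = FALSE]
    used_d <- used_a <- integer(0)
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      if (!(pairs[i, 1] %in% used_d) && !(pairs[i, 2] %in% used_a)) {
        keep[i] <- TRUE
        used_d <- c(used_d, pairs[i, 1]); used_a <- c(used_a, pairs[i, 2])
      }
    }
    pairs <- pairs[keep, , drop = FALSE]
    tibble::tibble(
      donor_chain = don$chain[pairs[, 1]],
      donor_res = don$res_seq[pairs[, 1]],
      acceptor_chain = acc$chain[pairs[, 2]],
      acceptor_res = acc$res_seq[pairs[, 2]],
      direction = direction,
      ref_distance = d[pairs])
  }
  out <- dplyr::bind_rows(
    one_direction(pick(tag_sel, "N"), pick(catcher_sel, "O"),
                  "tagN->catcherO"),
    one_direction(pick(catcher_sel, "N"), pick(tag_sel, "O"),
                  "catcherN->tagO"))
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(donor_chain = character(0), donor_res = integer(0),
                          acceptor_chain = character(0),
                          acceptor_res = integer(0), direction = character(0),
                          ref_distance = numeric(0)))
  }
  out[order(out$donor_res), ]
}

#' Hydrogen-bond N...O distance time series per pair
#'
#' @param traj A `cna_trajectory`.
#' @param pairs Output of [find_sheet_hbond_pairs()].
#' @return Tibble: `donor_res`, `acceptor_res`, `direction`, `frame`,
#'   `distance`; summarise with [hbond_means()].
#' @export
hbond_distance_series <- function(traj, pairs) {
  top <- as_atom_tbl(traj$topology)
  find_atom <- function(chain, res, name) {
    i <- which(top$chain == chain & top$res_seq == res & top$atom == name)
    if (length(i) != 1) {
      stop("atom ", name, " of residue ", chain, ":", res,
           " not found (or ambiguous) in topology")
    }
    i
  }
  di <- mapply(find_atom, pairs$donor_chain, pairs$donor_res,
               MoreArgs = list(name = "N"))
  ai <- mapply(find_atom, pairs$acceptor_chain, pairs$acceptor_res,
               MoreArgs = list(name = "O"))
  nf <- n_frames(traj)
  out <- lapply(seq_len(nrow(pairs)), function(p) {
    dx <- traj$coords[, di[p], , drop = TRUE] -
      traj$coords[, ai[p], , drop = TRUE]
    if (nf == 1) dx <- matrix(dx, nrow = 1)
    tibble::tibble(donor_res = pairs$donor_res[p],
                   acceptor_res = pairs$acceptor_res[p],
                   direction = pairs$direction[p],
                   frame = seq_len(nf),
                   distance = sqrt(rowSums(dx^2)))
  })
  dplyr::bind_rows(out)
}

#' Per-pair mean hydrogen-bond distances
#' @param series Output of [hbond_distance_series()].
#' @return Tibble with one row per pair: mean and sd distance.
#' @export
hbond_means <- function(series) {
  series |>
    dplyr::group_by(.data$donor_res, .data$acceptor_res, .data$direction) |>
    dplyr::summarise(mean_distance = mean(.data$distance),
                     sd_distance = stats::sd(.data$distance),
                     .groups = "drop")
}

#' Fraction of frames with the two groups in contact
#'
#' A frame counts as "in contact" when the minimum inter-group
#' heavy-atom distance is at or below `cutoff`. A low fraction flags tag
#' dissociation.
#'
#' @param traj A `cna_trajectory`.
#' @param idx_a,idx_b Atom row indices (heavy atoms).
#' @param cutoff Angstrom, default 4.5.
#' @return Fraction in `[0, 1]`.
#' @export
contact_fraction <- function(traj, idx_a, idx_b, cutoff = 4.5) {
  stopifnot(length(idx_a) > 0, length(idx_b) > 0)
  hits <- vapply(seq_len(n_frames(traj)), function(k) {
    min_cross_distance(frame_coords(traj, k, idx_a),
                       frame_coords(traj, k, idx_b)) <= cutoff
  }, logical(1))
  mean(hits)
}
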