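# Seedable synthetic structures and trajectories with known, configurable
# geometry. Fixtures exist to exercise measurement code without any
# downloaded data: backbones use ideal internal coordinates, planted side
# chains are geometric scaffolds (not physically minimised), and every
# random choice is controlled by an explicit seed.

# ideal backbone internal coordinates (bond lengths A, angles deg)
BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                ang_ca_c_o = 120.8)

# extended parallel-sheet backbone dihedrals
SHEET_PHI <- -119
SHEET_PSI <- 113

# residue letters sampled for unspecified fixture positions; reactive
# residue types (K/N/D/E) and Cys are excluded so planted triads are the
# only detectable chemistry
FIXTURE_ALPHABET <- c(A = 10, V = 9, I = 7, L = 11, F = 5, G = 9, S = 8,
                      T = 7, P = 5, Y = 4, W = 2, Q = 5, H = 3, R = 6,
                      M = 3)

sample_fixture_seq <- function(n, seed) {
  withr_seed(seed, {
    paste(sample(names(FIXTURE_ALPHABET), n, replace = TRUE,
                 prob = FIXTURE_ALPHABET), collapse = "")
  })
}

# evaluate expr under a local RNG seed without disturbing the caller's RNG
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# build one ideal extended strand; returns list of per-residue backbone
# coordinate rows (N, CA, C, O)
build_strand_coords <- function(n, phi = SHEET_PHI, psi = SHEET_PSI) {
  g <- BB_GEOM
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$n_ca, 0, 0)
  C[1, ] <- CA[1, ] + g$ca_c * c(cos(pi * (180 - g$ang_n_ca_c) / 180),
                                 sin(pi * (180 - g$ang_n_ca_c) / 180), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_n,
                               g$ang_ca_c_n, psi)
      CA[i + 1, ] <- place_atom(CA[i, ], C[i, ], N[i + 1, ], g$n_ca,
                                g$ang_c_n_ca, 180)
      C[i + 1, ] <- place_atom(C[i, ], N[i + 1, ], CA[i + 1, ], g$ca_c,
                               g$ang_n_ca_c, phi)
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                           psi - 180)
    } else {
      O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], g$c_o, g$ang_ca_c_o,
                           psi - 180)
    }
  }
  list(N = N, CA = CA, C = C, O = O)
}

strand_atom_rows <- function(bb, chain, res_seq, res_names) {
  res_names <- unname(res_names)
  n <- nrow(bb$N)
  purrr::map_dfr(seq_len(n), function(i) {
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    tibble::tibble(serial = NA_integer_, atom = c("N", "CA", "C", "O"),
                   alt_loc = "", res_name = res_names[i], chain = chain,
                   res_seq = res_seq[i], i_code = "",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, element = c("N", "C", "C", "O"))
  })
}

rigid_apply <- function(coords, par) {
  # par: 3 rotation angles (rad) + 3 translation
  cx <- cos(par[1]); sx <- sin(par[1])
  cy <- cos(par[2]); sy <- sin(par[2])
  cz <- cos(par[3]); sz <- sin(par[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  ctr <- colMeans(coords)
  sweep(sweep(coords, 2, ctr) %*% t(Rz %*% Ry %*% Rx), 2,
        ctr + par[4:6], "+")
}

#' Two parallel extended strands with a backbone hydrogen-bond ladder
#'
#' Builds a catcher strand (chain `chain_a`) and a tag strand (chain
#' `chain_b`) in ideal extended geometry and places the tag strand so
#' that the parallel-sheet hydrogen-bond ladder holds at the declared
#' N...O distance: bonding tag residues donate their backbone N to the
#' catcher residue one position back and accept at their O from the
#' catcher residue one position forward, at alternating sequence
#' positions exactly as in a parallel beta-sheet. The declared pairs are
#' attached as attribute `"ladder"` and each is accurate to well under
#' 0.01 Angstrom.
#'
#' @param n_residues Residues per strand (>= 4).
#' @param hbond_distance Declared N...O distance in Angstrom (>= 2).
#' @param chain_a,chain_b Chain identifiers.
#' @param start_a,start_b First residue numbers.
#' @param seq_a,seq_b Optional explicit sequences (one-letter).
#' @param seed Seed for the sampled residue identities.
#' @return A `cna_structure` with attribute `ladder`.
#' @export
make_two_strand_parallel <- function(n_residues = 8, hbond_distance = 2.9,
                                     chain_a = "A", chain_b = "B",
                                     start_a = 1, start_b = 1,
                                     seq_a = NULL, seq_b = NULL, seed = 1) {
  if (n_residues < 4) stop("need at least 4 residues per strand")
  if (hbond_distance < 2) {
    stop("hbond_distance below 2 Angstrom is geometrically impossible")
  }
  d <- hbond_distance
  bbA <- build_strand_coords(n_residues)
  bbB <- build_strand_coords(n_residues)

  # side of strand A that its odd-parity carbonyls point to
  odd <- seq(1, n_residues, by = 2)
  side <- unit(colMeans(bbA$O[odd, , drop = FALSE] -
                          bbA$C[odd, , drop = FALSE]))
  shift <- side * (d + 1.9)

  # declared ladder: bonding tag residues k (k even), donor N_B[k] to
  # O_A[k-1], acceptor O_B[k] from N_A[k+1]
  ks <- seq(2, n_residues - 1, by = 2)
  objective <- function(par) {
    m <- lapply(bbB, function(x) rigid_apply(x, par))
    err <- 0
    for (k in ks) {
      err <- err + (vnorm(m$N[k, ] - bbA$O[k - 1, ]) - d)^2 +
        (vnorm(m$O[k, ] - bbA$N[k + 1, ]) - d)^2
      # near-linear N-H...O: H lies along C(k-1)->O(k-1) reversed
      h <- m$N[k, ] + unit(m$C[k - 1, ] - m$O[k - 1, ])
      err <- err + 0.2 * (vnorm(h - bbA$O[k - 1, ]) - (d - 1))^2
    }
    err
  }
  fit <- stats::optim(c(0, 0, 0, shift), objective, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  bbB <- lapply(bbB, function(x) rigid_apply(x, fit$par))

  # per-residue refinement: solve each bonding residue's two distance
  # constraints exactly (6 dof, 2 constraints, stay-close regulariser)
  for (k in ks) {
    rows <- rbind(bbB$N[k, ], bbB$CA[k, ], bbB$C[k, ], bbB$O[k, ])
    obj_k <- function(par) {
      m <- rigid_apply(rows, par)
      1e6 * ((vnorm(m[1, ] - bbA$O[k - 1, ]) - d)^2 +
               (vnorm(m[4, ] - bbA$N[k + 1, ]) - d)^2) + sum(par^2)
    }
    fk <- stats::optim(rep(0, 6), obj_k, method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-16))
    rows <- rigid_apply(rows, fk$par)
    bbB$N[k, ] <- rows[1, ]; bbB$CA[k, ] <- rows[2, ]
    bbB$C[k, ] <- rows[3, ]; bbB$O[k, ] <- rows[4, ]
  }

  res_a <- seq(start_a, length.out = n_residues)
  res_b <- seq(start_b, length.out = n_residues)
  sa <- if (is.null(seq_a)) sample_fixture_seq(n_residues, seed) else seq_a
  sb <- if (is.null(seq_b)) sample_fixture_seq(n_residues, seed + 1) else seq_b
  names_a <- AA_1TO3[strsplit(sa, "")[[1]]]
  names_b <- AA_1TO3[strsplit(sb, "")[[1]]]
  at <- dplyr::bind_rows(strand_atom_rows(bbA, chain_a, res_a, names_a),
                         strand_atom_rows(bbB, chain_b, res_b, names_b))
  model <- new_structure(at, header_id = "two-strand-parallel")
  ladder <- dplyr::bind_rows(
    tibble::tibble(donor_chain = chain_b, donor_res = res_b[ks],
                   acceptor_chain = chain_a, acceptor_res = res_a[ks - 1],
                   direction = "tagN->catcherO", declared = d),
    tibble::tibble(donor_chain = chain_a, donor_res = res_a[ks + 1],
                   acceptor_chain = chain_b, acceptor_res = res_b[ks],
                   direction = "catcherN->tagO", declared = d))
  attr(model, "ladder") <- ladder
  model
}

mutate_residue_name <- function(at, chain, res_seq, new_name) {
  sel <- at$chain == chain & at$res_seq == res_seq
  if (!any(sel)) stop("residue ", chain, ":", res_seq, " not in model")
  at$res_name[sel] <- new_name
  at
}

add_sidechain_atoms <- function(at, chain, res_seq, res_name, names, xyz,
                                elements) {
  tibble::add_row(at,
                  serial = NA_integer_, atom = names, alt_loc = "",
                  res_name = res_name, chain = chain, res_seq = res_seq,
                  i_code = "", x = unname(xyz[, 1]), y = unname(xyz[, 2]),
                  z = unname(xyz[, 3]), occupancy = 1, element = elements)
}

residue_backbone <- function(at, chain, res_seq) {
  get1 <- function(name) {
    hit <- at[at$chain == chain & at$res_seq == res_seq & at$atom == name, ]
    if (nrow(hit) == 0) stop("residue ", res_seq, " lacks atom ", name)
    c(hit$x[1], hit$y[1], hit$z[1])
  }
  list(N = get1("N"), CA = get1("CA"), C = get1("C"))
}

ideal_cb <- function(bb) place_atom(bb$N, bb$C, bb$CA, 1.53, 110.5, 122.5)

# CB branch (of the two tetrahedral options) facing a target point;
# fixtures may take the mirror branch so planted side chains point into
# the inter-strand space
cb_toward <- function(bb, target) {
  c1 <- place_atom(bb$N, bb$C, bb$CA, 1.53, 110.5, 122.5)
  c2 <- place_atom(bb$N, bb$C, bb$CA, 1.53, 110.5, -122.5)
  if (vnorm(c1 - target) <= vnorm(c2 - target)) c1 else c2
}

#' Plant a reactive isopeptide triad into a fixture
#'
#' Rebuilds the chosen residues as Lys, Asn and Glu and constructs their
#' side chains geometrically so that the Lys NZ sits exactly
#' `triad_nz_cg` Angstrom from the Asn CG, and the Glu CD lies
#' `catalytic_distance` from NZ. Side chains are scaffolds for detector
#' tests, not minimised conformers. Placement retries with jitter (up to
#' 10 attempts) if a built atom clashes with an existing one.
#'
#' @param model A `cna_structure`.
#' @param lys,acceptor,catalytic Lists `list(chain=, res_seq=)` naming the
#'   residues to rebuild.
#' @param triad_nz_cg Target NZ-CG distance (Angstrom).
#' @param catalytic_distance Target NZ-CD distance (Angstrom).
#' @param seed Jitter seed for clash retries.
#' @return The modified `cna_structure`.
#' @export
plant_triad <- function(model, lys, acceptor, catalytic = NULL,
                        triad_nz_cg = 1.33, catalytic_distance = 3.0,
                        seed = 1) {
  at <- as_atom_tbl(model)
  at <- mutate_residue_name(at, lys$chain, lys$res_seq, "LYS")
  at <- mutate_residue_name(at, acceptor$chain, acceptor$res_seq, "ASN")
  if (!is.null(catalytic)) {
    at <- mutate_residue_name(at, catalytic$chain, catalytic$res_seq, "GLU")
  }
  # re-planting a residue replaces any side chain it already carries
  planted <- rbind(c(lys$chain, lys$res_seq),
                   c(acceptor$chain, acceptor$res_seq),
                   if (!is.null(catalytic)) c(catalytic$chain,
                                              catalytic$res_seq))
  drop <- rep(FALSE, nrow(at))
  for (r in seq_len(nrow(planted))) {
    drop <- drop | (at$chain == planted[r, 1] &
                      at$res_seq == as.integer(planted[r, 2]) &
                      !(at$atom %in% c("N", "CA", "C", "O")))
  }
  at <- at[!drop, ]
  bb_l <- residue_backbone(at, lys$chain, lys$res_seq)
  bb_a <- residue_backbone(at, acceptor$chain, acceptor$res_seq)
  cb_l <- cb_toward(bb_l, bb_a$CA)
  cb_a <- cb_toward(bb_a, bb_l$CA)

  heavy <- as.matrix(at[, c("x", "y", "z")])
  clash <- function(xyz) {
    min(cross_distances(matrix(xyz, ncol = 3), heavy)) < 1.2
  }
  # local sheet plane around the planted pair: the side-chain bridge is
  # routed above it, clear of the backbone hydrogen-bond ladder
  near <- at$atom == "CA" &
    ((at$chain == lys$chain & abs(at$res_seq - lys$res_seq) <= 3) |
       (at$chain == acceptor$chain &
          abs(at$res_seq - acceptor$res_seq) <= 3))
  ca_local <- as.matrix(at[near, c("x", "y", "z")])
  normal <- svd(sweep(ca_local, 2, colMeans(ca_local)))$v[, 3]
  build <- function(jit, lift_len = 2.2) {
    lift <- lift_len * normal
    cg_a <- cb_a + 1.52 * unit((cb_l + lift) - cb_a) + jit
    # NZ along CG -> (lifted Lys CB) when the span allows it; otherwise
    # away from the sheet so large (undetectable) distances stay
    # clash-free
    dir <- if (triad_nz_cg < vnorm(cb_l + lift - cg_a) - 1) {
      unit(cb_l + lift - cg_a)
    } else {
      unit(cg_a - cb_a + lift)
    }
    nz <- cg_a + triad_nz_cg * dir
    # Asn amide plane atoms off CG, perpendicular to the CB->CG axis
    perp <- unit(pracma_cross(cg_a - cb_a, c(0, 0, 1) + jit))
    od1 <- cg_a + 1.23 * perp
    nd2 <- cg_a - 1.33 * perp
    # Lys chain interpolated CB -> NZ
    fr <- c(0.25, 0.5, 0.75)
    mids <- t(vapply(fr, function(f) cb_l + f * (nz - cb_l), numeric(3)))
    list(cg_a = cg_a, nz = nz, od1 = od1, nd2 = nd2, mids = mids)
  }
  got <- NULL
  jitters <- withr_seed(seed, replicate(10, stats::rnorm(3, 0, 0.25),
                                        simplify = FALSE))
  jitters[[1]] <- c(0, 0, 0)
  # raise the side-chain bridge further above the sheet plane (and only
  # then jitter) until it clears all existing atoms
  for (lift_len in c(2.2, 3.2, 4.5, 6, 8)) {
    for (attempt in seq_len(10)) {
      cand <- build(jitters[[attempt]], lift_len)
      if (!clash(cand$nz) && !clash(cand$cg_a)) { got <- cand; break }
    }
    if (!is.null(got)) break
  }
  if (is.null(got)) stop("could not place triad without clashes")

  at <- add_sidechain_atoms(at, acceptor$chain, acceptor$res_seq, "ASN",
                            c("CB", "CG", "OD1", "ND2"),
                            rbind(cb_a, got$cg_a, got$od1, got$nd2),
                            c("C", "C", "O", "N"))
  at <- add_sidechain_atoms(at, lys$chain, lys$res_seq, "LYS",
                            c("CB", "CG", "CD", "CE", "NZ"),
                            rbind(cb_l, got$mids, got$nz),
                            c("C", "C", "C", "C", "N"))
  if (!is.null(catalytic)) {
    bb_e <- residue_backbone(at, catalytic$chain, catalytic$res_seq)
    cb_e <- cb_toward(bb_e, got$nz)
    cd_e <- got$nz + catalytic_distance * unit(cb_e - got$nz)
    cg_e <- (cb_e + cd_e) / 2
    perp <- unit(pracma_cross(cd_e - cg_e, c(0, 0, 1.1)))
    at <- add_sidechain_atoms(at, catalytic$chain, catalytic$res_seq, "GLU",
                              c("CB", "CG", "CD", "OE1", "OE2"),
                              rbind(cb_e, cg_e, cd_e, cd_e + 1.25 * perp,
                                    cd_e - 1.25 * perp),
                              c("C", "C", "C", "O", "O"))
  }
  # keep atoms of one residue contiguous in file order
  at <- at[order(match(residue_key(at), unique(residue_key(at)))), ]
  out <- restore_structure(at, model)
  attr(out, "ladder") <- attr(model, "ladder")
  out
}

# give any side-chain-less Lys a minimal geometric side chain so that
# detectors see a complete residue (NZ pointing away from the backbone)
complete_lys_sidechains <- function(model) {
  at <- as_atom_tbl(model)
  res <- residue_table(model)
  lys <- res[res$res_name == "LYS", ]
  for (i in seq_len(nrow(lys))) {
    key <- at$chain == lys$chain[i] & at$res_seq == lys$res_seq[i] &
      at$i_code == lys$i_code[i]
    if ("NZ" %in% at$atom[key]) next
    bb <- residue_backbone(at, lys$chain[i], lys$res_seq[i])
    cb <- ideal_cb(bb)
    dir <- unit(cb - bb$CA)
    xyz <- rbind(cb, cb + 1.3 * dir, cb + 2.6 * dir, cb + 3.9 * dir,
                 cb + 5.2 * dir)
    at <- add_sidechain_atoms(at, lys$chain[i], lys$res_seq[i], "LYS",
                              c("CB", "CG", "CD", "CE", "NZ"), xyz,
                              c("C", "C", "C", "C", "N"))
  }
  at <- at[order(match(residue_key(at), unique(residue_key(at)))), ]
  out <- restore_structure(at, model)
  attr(out, "ladder") <- attr(model, "ladder")
  out
}

#' Gaussian-jitter trajectory around a structure
#'
#' `n_frames` copies of the model with i.i.d. Gaussian displacement of
#' standard deviation `sigma` per coordinate; the first frame is the
#' unperturbed structure. Bit-reproducible under `seed`.
#'
#' @param model A `cna_structure`.
#' @param n_frames Number of frames (>= 1).
#' @param sigma Displacement sd in Angstrom (>= 0).
#' @param seed RNG seed.
#' @return A `cna_trajectory`.
#' @export
make_jitter_trajectory <- function(model, n_frames = 100, sigma = 0.5,
                                   seed = 1) {
  stopifnot(n_frames >= 1, sigma >= 0)
  base <- coords_matrix(model)
  na <- nrow(base)
  coords <- array(NA_real_, dim = c(n_frames, na, 3))
  coords[1, , ] <- base
  if (n_frames > 1) {
    noise <- withr_seed(seed,
                        stats::rnorm(3 * na * (n_frames - 1), 0, sigma))
    noise <- array(noise, dim = c(n_frames - 1, na, 3))
    for (k in 2:n_frames) coords[k, , ] <- base + noise[k - 1, , ]
  }
  new_trajectory(model, coords)
}

#' Drift trajectory emulating tag dissociation
#'
#' The drifting chain is translated by `(i-1) * drift_vector` in frame
#' `i` (the first frame is unperturbed), with optional Gaussian jitter
#' on all atoms on top.
#'
#' @param model A `cna_structure`.
#' @param drift_chain Chain that drifts away (the tag).
#' @param drift_vector Length-3 translation per frame (Angstrom/frame),
#'   non-zero.
#' @param n_frames Number of frames.
#' @param sigma Jitter sd (Angstrom).
#' @param seed RNG seed.
#' @return A `cna_trajectory`.
#' @export
make_drift_trajectory <- function(model, drift_chain = "B",
                                  drift_vector = c(0.5, 0, 0),
                                  n_frames = 100, sigma = 0, seed = 1) {
  if (all(drift_vector == 0)) stop("drift_vector must be non-zero")
  traj <- make_jitter_trajectory(model, n_frames, sigma, seed)
  moving <- which(traj$topology$chain == drift_chain)
  if (length(moving) == 0) stop("no atoms on drift chain ", drift_chain)
  for (k in seq_len(n_frames)) {
    shift <- (k - 1) * drift_vector
    traj$coords[k, moving, ] <-
      sweep(matrix(traj$coords[k, moving, ], ncol = 3), 2, shift, "+")
  }
  traj
}
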