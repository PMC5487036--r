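test_that("a minimal one-residue PDB parses into the expected model", {
  m <- read_structure(MINIMAL_GLY)
  expect_s3_class(m, "cna_structure")
  expect_equal(nrow(m), 4)
  expect_equal(unique(m$chain), "A")
  expect_equal(residue_table(m)$res_name, "GLY")
  expect_equal(m$atom, c("N", "CA", "C", "O"))
})

test_that("alternate locations keep the highest-occupancy conformer", {
  lines <- c(
    "ATOM      1  N  AGLY A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BGLY A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "END")
  m <- read_structure(lines)
  expect_equal(nrow(m), 2)
  expect_equal(m$x[m$atom == "N"], 9)  # the B conformer (occupancy 0.6)

  # tie on occupancy: lexicographically first altloc wins
  lines2 <- sub("0.40", "0.60", lines, fixed = TRUE)
  m2 <- read_structure(lines2)
  expect_equal(m2$x[m2$atom == "N"], 0)
})

test_that("malformed and empty inputs raise informative parse errors", {
  bad <- MINIMAL_GLY
  bad[2] <- "ATOM      2  CA  GLY A   1      xx.xxx   6.071  -5.147  1.00  0.00           C"
  expect_error(read_structure(bad), "line 2")
  expect_error(read_structure(""), "empty")
  expect_error(read_structure(c("HEADER    NOTHING", "END")),
               "no ATOM/HETATM")
})

test_that("write -> read round-trips preserve atoms, order and coordinates", {
  m <- sheet_with_triad(3.4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, path)
  m2 <- read_structure(path)
  expect_equal(nrow(m2), nrow(m))
  expect_equal(m2$atom, m$atom)
  expect_equal(m2$res_name, m$res_name)
  expect_equal(m2$res_seq, m$res_seq)
  expect_equal(m2$x, round(m$x, 3))
  expect_equal(m2$y, round(m$y, 3))
  expect_equal(m2$z, round(m$z, 3))

  # independent reader agrees on the written file
  skip_if_not_installed("bio3d")
  bb <- suppressWarnings(bio3d::read.pdb(path))
  expect_equal(nrow(bb$atom), nrow(m))
  expect_equal(bb$atom$x, m2$x)
  expect_equal(trimws(bb$atom$elety), m2$atom)
})

test_that("coordinates are stored at format precision with TER-separated chains", {
  at <- tibble::as_tibble(read_structure(MINIMAL_GLY))
  at$x[1] <- 1.23456
  m <- new_structure(at)
  out <- write_structure(m)
  expect_match(out[grep("^ATOM", out)[1]], "   1.235", fixed = TRUE)

  two <- sheet_with_triad(3.4)     # chains A and B
  lines <- write_structure(two)
  expect_equal(sum(grepl("^TER", lines)), 2)
  expect_error(write_structure(new_structure(dplyr::mutate(at,
    atom = replace(atom, 1, "ABCDE")))), "4-character")
})

test_that("multi-model files become trajectories with frames in MODEL order", {
  m <- sheet_with_triad(3.4)
  path <- withr::local_tempfile(fileext = ".pdb")

  # single model: one frame equal to the topology coordinates
  write_trajectory(make_jitter_trajectory(m, 1, 0, seed = 1), path)
  t1 <- read_trajectory(m, path)
  expect_equal(n_frames(t1), 1)
  expect_equal(t1$coords[1, , ], unname(coords_matrix(m)),
               tolerance = 1e-3)

  tr <- make_jitter_trajectory(m, 11, 0.4, seed = 7)
  write_trajectory(tr, path)
  t2 <- read_trajectory(m, path)
  expect_equal(n_frames(t2), 11)
  expect_equal(t2$coords, round(tr$coords, 3), ignore_attr = TRUE)

  # a frame with a missing atom is reported by frame number
  lines <- readLines(path)
  drop <- grep("^ATOM", lines)
  # remove one atom line of MODEL 3
  starts <- grep("^MODEL", lines)
  victim <- drop[drop > starts[3]][1]
  expect_error(read_trajectory(m, lines[-victim]), "frame 3")
})

test_that("structure reading keeps only the first MODEL", {
  m <- sheet_with_triad(3.4)
  tr <- make_jitter_trajectory(m, 4, 1.0, seed = 3)
  lines <- write_trajectory(tr)
  m1 <- read_structure(paste(lines, collapse = "\n"))
  expect_equal(nrow(m1), nrow(m))
  expect_equal(m1$x, round(tr$coords[1, , 1], 3))
})

test_that("residue-range selection is inclusive, idempotent and chain-aware", {
  dom <- make_synthetic_domain("4oq1")
  sel <- select_residues(dom, "A", 146, 240)
  expect_equal(sort(unique(sel$res_seq)), 146:240)
  sel2 <- select_residues(sel, "A", 146, 240)
  expect_identical(tibble::as_tibble(sel2), tibble::as_tibble(sel))
  one <- select_residues(dom, "A", 155, 155)
  expect_equal(nrow(residue_table(one)), 1)
  expect_error(select_residues(dom, "A", 1000, 1001), "no residue")
  expect_error(select_residues(dom, "A", 10, 5))
})

test_that("sequences extract with author numbering and modified residues map", {
  at <- tibble::as_tibble(read_structure(MINIMAL_GLY))
  ala <- dplyr::mutate(at, res_seq = 2L, res_name = "ALA")
  lys <- dplyr::mutate(at, res_seq = 3L, res_name = "LYS")
  m <- new_structure(dplyr::bind_rows(at, ala, lys))
  expect_equal(residue_sequence(m), "GAK")

  mse <- new_structure(dplyr::mutate(at, res_name = "MSE"))
  expect_equal(residue_sequence(mse), "M")
  unk <- new_structure(dplyr::mutate(at, res_name = "XYZ"))
  expect_equal(residue_sequence(unk), "X")

  dom <- make_synthetic_domain("4oq1")
  expect_equal(nchar(residue_sequence(dom, "A", 246, 259)), 14)
})

test_that("FASTA output round-trips named sequences", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(tagA = "AHIVMVDA", tagB = "GAKLY")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
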