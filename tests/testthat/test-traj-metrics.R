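test_that("Kabsch superposition is exact on congruent point sets", {
  set.seed(1)
  pts <- matrix(rnorm(15, sd = 5), 5, 3)
  fit <- kabsch_superpose(pts, pts)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  mob <- pts %*% t(Rz) + matrix(c(3, -7, 11), 5, 3, byrow = TRUE)
  fit2 <- kabsch_superpose(pts, mob)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit2$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("Kabsch matches the quaternion-method oracle on random sets", {
  set.seed(99)
  for (k in 1:25) {
    n <- sample(4:40, 1)
    ref <- matrix(rnorm(3 * n, sd = 8), n, 3)
    mob <- ref %*% t(random_rotation()) +
      matrix(rnorm(3 * n, sd = 0.7), n, 3)
    expect_equal(kabsch_superpose(ref, mob)$rmsd,
                 quaternion_rmsd(ref, mob), tolerance = 1e-8)
  }
})

test_that("core RMSD series uses frame one as reference", {
  m <- sheet_with_triad(3.4)
  frozen <- make_jitter_trajectory(m, 10, 0, seed = 1)
  s <- core_rmsd_series(frozen, 1, 8, chain = "A")
  expect_equal(s$value, rep(0, 10), tolerance = 1e-10)

  tr <- make_jitter_trajectory(m, 20, 0.5, seed = 5)
  s2 <- core_rmsd_series(tr, 1, 8, chain = "A")
  idx <- atom_indices(m, "A", 1, 8,
                      atoms = c("N", "CA", "C", "O"), heavy = FALSE)
  ref <- matrix(tr$coords[1, idx, ], ncol = 3)
  oracle <- vapply(1:20, function(k) {
    quaternion_rmsd(ref, matrix(tr$coords[k, idx, ], ncol = 3))
  }, numeric(1))
  expect_equal(s2$value, oracle, tolerance = 1e-8)
  expect_equal(nrow(s2), n_frames(tr))

  # a residue without full backbone is reported
  at <- tibble::as_tibble(m)
  at <- at[!(at$chain == "A" & at$res_seq == 3 & at$atom == "O"), ]
  broken <- make_jitter_trajectory(new_structure(at), 2, 0, seed = 1)
  expect_error(core_rmsd_series(broken, 1, 8, chain = "A"), "3")
})

test_that("jitter RMSD means grow monotonically with sigma", {
  m <- sheet_with_triad(3.4)
  means <- vapply(c(0.1, 0.5, 1.0), function(sg) {
    mean(core_rmsd_series(make_jitter_trajectory(m, 200, sg, seed = 31),
                          1, 8, chain = "A")$value)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("the 12-6 energy has its analytic minimum and asymptotics", {
  p <- lj_param_table()
  cls <- match(c("C", "O"), p$classes$class)
  rmin <- sum(p$classes$rmin_half[cls])
  eps <- sqrt(prod(p$classes$epsilon[cls]))
  e_min <- lj_energy(matrix(c(0, 0, 0), 1), matrix(c(rmin, 0, 0), 1),
                     cls[1], cls[2], p)
  expect_equal(e_min, -eps, tolerance = 1e-12)

  rs <- seq(rmin, 30, length.out = 50)
  es <- vapply(rs, function(r) {
    lj_energy(matrix(c(0, 0, 0), 1), matrix(c(r, 0, 0), 1),
              cls[1], cls[2], p)
  }, numeric(1))
  expect_true(all(es <= 0))
  expect_true(all(diff(es) > 0))      # rises monotonically toward zero
  expect_lt(abs(es[length(es)]), 1e-6)
  expect_error(lj_energy(matrix(0, 1, 3), matrix(0, 1, 3),
                         cls[1], cls[2], p), "zero")
})

test_that("the vectorised LJ sum equals a brute-force double loop", {
  p <- lj_param_table()
  set.seed(7)
  for (k in 1:10) {
    na <- sample(5:20, 1); nb <- sample(5:20, 1)
    A <- matrix(rnorm(3 * na, sd = 4), na, 3)
    B <- matrix(rnorm(3 * nb, sd = 4), nb, 3) +
      matrix(c(10, 0, 0), nb, 3, byrow = TRUE)
    ca <- sample(seq_len(nrow(p$classes)), na, replace = TRUE)
    cb <- sample(seq_len(nrow(p$classes)), nb, replace = TRUE)
    excl <- if (k %% 2 == 0) cbind(sample(na, 2), sample(nb, 2)) else NULL
    expect_equal(lj_energy(A, B, ca, cb, p, excl),
                 brute_lj(A, B, ca, cb, p, excl),
                 tolerance = 1e-10)
  }
})

test_that("junction exclusions drop only short bonded paths", {
  # four collinear bonded atoms: A1-A2 | B1-B2 with a 1.5 A junction bond
  at <- tibble::tibble(
    serial = 1:4, atom = c("C1", "C2", "C3", "C4"), alt_loc = "",
    res_name = "GLY", chain = "A", res_seq = c(1L, 1L, 2L, 2L),
    i_code = "", x = c(0, 1.5, 3.0, 4.5), y = 0, z = 0,
    occupancy = 1, element = "C")
  top <- new_structure(at)
  excl <- junction_exclusions(top, c(1L, 2L), c(3L, 4L), coords_matrix(top))
  # all four cross pairs are within 3 bonds on this chain
  expect_equal(nrow(excl), 4)
})

test_that("energy series freeze, vanish at separation and track frames", {
  m <- sheet_with_triad(3.4)
  it <- atom_indices(m, "B"); ic <- atom_indices(m, "A")
  frozen <- make_jitter_trajectory(m, 6, 0, seed = 1)
  s <- lj_energy_series(frozen, it, ic)
  expect_equal(length(unique(round(s$value, 10))), 1)

  far <- tibble::as_tibble(m)
  far$z[far$chain == "B"] <- far$z[far$chain == "B"] + 50
  tr <- make_jitter_trajectory(new_structure(far), 5, 0, seed = 1)
  s2 <- lj_energy_series(tr, it, ic)
  expect_true(all(abs(s2$value) < 1e-3))
})

test_that("sheet hydrogen-bond pairs are recovered and bounded", {
  m <- make_two_strand_parallel(8, 2.9, seed = 1)
  tag <- list(chain = "B", first = 1, last = 8)
  cat <- list(chain = "A", first = 1, last = 8)
  pairs <- find_sheet_hbond_pairs(m, tag, cat)
  lad <- attr(m, "ladder")
  joined <- dplyr::inner_join(
    lad, pairs,
    by = c("donor_chain", "donor_res", "acceptor_chain", "acceptor_res",
           "direction"))
  expect_equal(nrow(joined), nrow(lad))  # full declared ladder found
  expect_true(all(abs(joined$ref_distance - joined$declared) < 0.01))

  sep <- tibble::as_tibble(m)
  sep$y[sep$chain == "B"] <- sep$y[sep$chain == "B"] + 10
  expect_equal(nrow(find_sheet_hbond_pairs(new_structure(sep), tag, cat)),
               0)
})

test_that("hydrogen-bond distance series summarise per pair", {
  m <- make_two_strand_parallel(8, 2.9, seed = 1)
  tag <- list(chain = "B", first = 1, last = 8)
  cat <- list(chain = "A", first = 1, last = 8)
  pairs <- find_sheet_hbond_pairs(m, tag, cat)

  frozen <- make_jitter_trajectory(m, 4, 0, seed = 1)
  means <- hbond_means(hbond_distance_series(frozen, pairs))
  ord <- order(pairs$donor_res, pairs$acceptor_res)
  ord2 <- order(means$donor_res, means$acceptor_res)
  expect_equal(means$mean_distance[ord2], pairs$ref_distance[ord],
               tolerance = 1e-12)

  # constructed oscillation: one donor N alternates between two offsets
  tr <- make_jitter_trajectory(m, 10, 0, seed = 1)
  ni <- atom_indices(m, "B", 2, 2, atoms = "N", heavy = FALSE)
  oi <- atom_indices(m, "A", 1, 1, atoms = "O", heavy = FALSE)
  dir <- unit_vec <- (tr$coords[1, ni, ] - tr$coords[1, oi, ])
  unit_vec <- dir / sqrt(sum(dir^2))
  base <- tr$coords[1, oi, ]
  for (k in 1:10) {
    tr$coords[k, ni, ] <- base + unit_vec * ifelse(k %% 2 == 0, 2.8, 3.2)
  }
  one <- pairs[pairs$donor_res == 2 & pairs$acceptor_res == 1, ]
  series <- hbond_distance_series(tr, one)
  expect_equal(mean(series$distance), 3.0, tolerance = 1e-9)

  # drifting tags produce growing distances once the drift dominates
  # the initial axial offsets of each pair
  dr <- make_drift_trajectory(m, "B", c(0, 0, 0.5), n_frames = 30)
  sd2 <- hbond_distance_series(dr, pairs)
  for (p in unique(paste(sd2$donor_res, sd2$acceptor_res))) {
    sub <- sd2[paste(sd2$donor_res, sd2$acceptor_res) == p, ]
    expect_true(all(diff(sub$distance[10:30]) > 0))
    expect_gt(sub$distance[30], sub$distance[1])
  }
})

test_that("contact fraction tracks bound, separated and drifting groups", {
  m <- sheet_with_triad(3.4)
  it <- atom_indices(m, "B"); ic <- atom_indices(m, "A")
  frozen <- make_jitter_trajectory(m, 8, 0, seed = 1)
  expect_equal(contact_fraction(frozen, it, ic), 1.0)

  far <- tibble::as_tibble(m)
  far$x[far$chain == "B"] <- far$x[far$chain == "B"] + 100
  gone <- make_jitter_trajectory(new_structure(far), 8, 0, seed = 1)
  expect_equal(contact_fraction(gone, it, ic), 0.0)

  dr <- make_drift_trajectory(m, "B", c(0, 0, 0.5), n_frames = 100)
  # predicted from frame-one geometry and the drift step alone
  d0 <- cnasplit:::cross_distances(coords_matrix(trajectory_frame(dr, 1))[it, ],
                                   coords_matrix(trajectory_frame(dr, 1))[ic, ])
  dz <- outer(dr$coords[1, it, 3], dr$coords[1, ic, 3], "-")
  in_contact <- vapply(1:100, function(k) {
    min(sqrt(d0^2 - dz^2 + (dz + (k - 1) * 0.5)^2)) <= 4.5
  }, logical(1))
  expect_equal(contact_fraction(dr, it, ic), mean(in_contact),
               tolerance = 1e-12)
})
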