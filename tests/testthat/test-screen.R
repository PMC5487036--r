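make_screen_config <- function(split_traj_kind = c("bound", "drift",
                                                   "none"),
                               n_frames = 30, sigma = 0.25) {
  split_traj_kind <- match.arg(split_traj_kind)
  dom <- make_synthetic_domain("4oq1")
  # split simulated without the bond: proximal parent for the topology
  prox <- make_synthetic_domain("4oq1", triad_nz_cg = 3.4)
  cs <- make_split(prox, system_split_spec("4oq1"),
                   detect_isopeptide(prox)[1, ])
  top <- split_topology(cs)
  dt <- make_jitter_trajectory(dom, n_frames, sigma, seed = 201)
  st <- switch(split_traj_kind,
               bound = make_jitter_trajectory(top, n_frames, sigma,
                                              seed = 202),
               drift = make_drift_trajectory(top, "B", c(0, 0, 0.6),
                                             n_frames, sigma, seed = 203),
               none = NULL)
  tibble::tibble(label = "4oq1", parent = list(dom), chain = "A",
                 catcher_first = 146L, catcher_last = 240L,
                 tag_first = 246L, tag_last = 259L,
                 core_first = 183L, core_last = 223L,
                 domain_traj = list(dt), split_traj = list(st))
}

test_that("verdict precedence is dissociated > destabilized > comparable", {
  th <- screen_thresholds()
  same <- list(rmsd_mean = 1.2, lj_mean = -70)
  expect_equal(compare_domain_vs_split(same, c(same, contact = 1), th),
               "comparable")
  expect_equal(compare_domain_vs_split(
    list(rmsd_mean = 1.2, lj_mean = -70),
    list(rmsd_mean = 3.0, lj_mean = -70, contact = 1), th),
    "destabilized")
  # less than half the binding energy retained
  expect_equal(compare_domain_vs_split(
    list(rmsd_mean = 1.2, lj_mean = -70),
    list(rmsd_mean = 1.2, lj_mean = -20, contact = 1), th),
    "destabilized")
  # dissociation dominates everything else
  expect_equal(compare_domain_vs_split(
    list(rmsd_mean = 1.2, lj_mean = -70),
    list(rmsd_mean = 1.2, lj_mean = -70, contact = 0.4), th),
    "dissociated")
  expect_error(compare_domain_vs_split(
    list(rmsd_mean = 1.2), list(rmsd_mean = 1, lj_mean = 1, contact = 1),
    th), "lj_mean")
})

test_that("thresholds change verdicts but never metric values", {
  cfg <- make_screen_config("bound")
  lax <- run_screen(cfg, screen_thresholds(contact_min = 0.5))
  strict <- run_screen(cfg, screen_thresholds(contact_min = 0.5,
                                              delta_rmsd_max = 1e-9))
  t1 <- tidy(lax); t2 <- tidy(strict)
  num <- c("rmsd_domain", "rmsd_split", "lj_domain", "lj_split", "contact")
  expect_equal(t1[num], t2[num])
  expect_false(identical(t1$verdict, t2$verdict))
})

test_that("the full pipeline runs structure-only and with trajectories", {
  sys <- cna_systems()
  cfg <- purrr::map_dfr(sys$system, function(s) {
    row <- sys[sys$system == s, ]
    tibble::tibble(label = s, parent = list(make_synthetic_domain(s)),
                   chain = "A",
                   catcher_first = row$catcher_first,
                   catcher_last = row$catcher_last,
                   tag_first = row$tag_first, tag_last = row$tag_last,
                   core_first = row$core_first, core_last = row$core_last)
  })
  rep <- run_screen(cfg)
  tb <- tidy(rep)
  expect_equal(tb$system, sys$system)
  expect_true(all(is.na(tb$verdict)))
  expect_equal(tb$deleted,
               c("246-247", "241-245", "256-257", "501-504"))
  expect_true(all(is.na(tb$error)))

  bound <- run_screen(make_screen_config("bound"))
  expect_equal(tidy(bound)$verdict, "comparable")
  drift <- run_screen(make_screen_config("drift"))
  expect_equal(tidy(drift)$verdict, "dissociated")
})

test_that("one failing system does not abort the others", {
  good <- make_screen_config("none")
  bare <- make_two_strand_parallel(8, 2.9, seed = 5)  # no triad anywhere
  bad <- good
  bad$label <- "no-triad"
  bad$parent <- list(bare)
  bad$catcher_first <- 1L; bad$catcher_last <- 4L
  bad$tag_first <- 5L; bad$tag_last <- 8L
  rep <- run_screen(dplyr::bind_rows(good, bad))
  tb <- tidy(rep)
  expect_true(is.na(tb$error[tb$system == "4oq1"]))
  expect_match(tb$error[tb$system == "no-triad"], "triad")
})

test_that("report rendering is deterministic and self-describing", {
  rep <- run_screen(make_screen_config("bound"))
  tsv1 <- render_report(rep, "tsv")
  tsv2 <- render_report(rep, "tsv")
  expect_identical(tsv1, tsv2)
  expect_match(tsv1[1], "contact_min=0.95")
  expect_match(tsv1[1], "lj_table=generic-elements")
  expect_match(tsv1[1], "proximal_max=4.00")
  md <- render_report(rep, "markdown")
  expect_match(md[3], "^\\| system \\|")

  empty <- run_screen(make_screen_config("bound")[0, ])
  expect_length(render_report(empty, "tsv"), 2)  # header lines only
})

test_that("series and screens expose broom-style summaries and plots", {
  cfg <- make_screen_config("bound", n_frames = 10)
  rep <- run_screen(cfg)
  g <- glance(rep)
  expect_equal(g$n_systems, 1)
  expect_equal(g$n_comparable, 1)

  dom <- cfg$parent[[1]]
  tr <- cfg$domain_traj[[1]]
  s <- core_rmsd_series(tr, 183, 223)
  expect_s3_class(autoplot(s), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  gs <- glance(s)
  expect_equal(gs$n_frames, 10)
  expect_equal(gs$unit, "Angstrom")
  expect_equal(tidy(s)$value, s$value)
})

test_that("the CLI dispatches detect, synth and screen-seq", {
  tmp <- withr::local_tempdir()
  pdb <- file.path(tmp, "dom.pdb")
  out <- file.path(tmp, "triads.tsv")
  expect_equal(cna_cli(c("synth", "--kind", "domain", "--system", "4oq1",
                         "--out", pdb)), 0L)
  expect_true(file.exists(pdb))
  expect_equal(cna_cli(c("detect", "--pdb", pdb, "--out", out)), 0L)
  tsv <- readLines(out)
  expect_match(tsv[2], "155")

  fa <- file.path(tmp, "seqs.fasta")
  write_fasta(c(a = "GAKLVWDTS", b = "PPPPGGGGW"), fa)
  expect_equal(cna_cli(c("screen-seq", "--fasta", fa, "--out",
                         file.path(tmp, "id.tsv"))), 0L)
  expect_equal(cna_cli("nonsense"), 1L)
})
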