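test_that("deleted linkers derive from the split boundaries alone", {
  expect_equal(deleted_range(split_spec("A", 152, 245, 248, 263)), 246:247)
  expect_equal(deleted_range(split_spec("A", 146, 240, 246, 259)), 241:245)
  expect_equal(deleted_range(split_spec("A", 164, 255, 258, 272)), 256:257)
  expect_equal(deleted_range(split_spec("A", 409, 500, 505, 518)), 501:504)
  expect_length(deleted_range(split_spec("A", 1, 10, 11, 20)), 0)
  expect_error(split_spec("A", 10, 5, 11, 20), "catcher_first")
  expect_error(split_spec("A", 1, 12, 11, 20), "catcher_first")
})

test_that("splitting conserves residues and reconstructs the parent range", {
  for (s in cna_systems()$system) {
    dom <- make_synthetic_domain(s)
    spec <- system_split_spec(s)
    triad <- detect_isopeptide(dom)[1, ]
    cs <- make_split(dom, spec, triad)
    span <- spec$tag_last - spec$catcher_first + 1
    expect_equal(nchar(cs$catcher_seq) + nrow(cs$deleted) +
                   nchar(cs$tag_seq), span)
    expect_equal(paste0(cs$catcher_seq, cs$deleted_seq, cs$tag_seq),
                 residue_sequence(dom, "A", spec$catcher_first,
                                  spec$tag_last))
    # tag is its own chain, identifiers disjoint from the catcher
    expect_false(cs$tag$chain[1] == cs$catcher$chain[1])
  }
})

test_that("a split placing a triad member in the deleted range is rejected", {
  dom <- make_synthetic_domain("4oq1")
  triad <- detect_isopeptide(dom)[1, ]
  # acceptor N252 inside the deleted range 247...252
  bad <- split_spec("A", 146, 246, 253, 259)
  expect_error(make_split(dom, bad, triad), "acceptor")
  # N-terminal-tag (Snoop-like) topology: acceptor in catcher
  bad2 <- split_spec("A", 146, 253, 255, 259)
  expect_error(make_split(dom, bad2, triad), "N-terminal-tag")
})

test_that("capping adds ACE/NME with ideal peptide-bond geometry", {
  dom <- select_residues(make_synthetic_domain("4oq1"), "A", 146, 159)
  capped <- cap_termini(dom, list(n = "acetyl", c = "n_methyl"))
  rt <- residue_table(capped)
  expect_equal(rt$res_name[1], "ACE")
  expect_equal(rt$res_name[nrow(rt)], "NME")
  expect_equal(nrow(rt), nrow(residue_table(dom)) + 2)

  at <- tibble::as_tibble(capped)
  ace_c <- unlist(at[at$res_name == "ACE" & at$atom == "C",
                     c("x", "y", "z")])
  n1 <- unlist(at[at$res_seq == 146 & at$atom == "N", c("x", "y", "z")])
  expect_equal(sqrt(sum((ace_c - n1)^2)), 1.33, tolerance = 0.01)
  nme_n <- unlist(at[at$res_name == "NME" & at$atom == "N",
                     c("x", "y", "z")])
  c_last <- unlist(at[at$res_seq == 159 & at$atom == "C", c("x", "y", "z")])
  expect_equal(sqrt(sum((c_last - nme_n)^2)), 1.33, tolerance = 0.01)

  # ionic scheme leaves the model untouched
  same <- cap_termini(dom, list(n = "ionic", c = "ionic"))
  expect_identical(tibble::as_tibble(same), tibble::as_tibble(dom))
})

test_that("tag and catcher variants edit sequences as specified", {
  dom <- make_synthetic_domain("4oq1")
  cs <- make_split(dom, system_split_spec("4oq1"),
                   detect_isopeptide(dom)[1, ])
  tag <- cs$tag_seq
  expect_equal(nchar(tag), 14)
  expect_equal(substr(tag, 1, 1), "V")  # tag starts at V246

  ext1 <- apply_variant(tag, dom, variant_spec(n_extension = c(245, 245)))
  expect_equal(nchar(ext1), 15)
  expect_equal(substr(ext1, 1, 1), "L")  # L245

  ext3 <- apply_variant(tag, dom, variant_spec(n_extension = c(243, 245)))
  expect_equal(substr(ext3, 1, 3), "HQL")  # H243-Q244-L245

  trunc <- apply_variant(tag, dom, variant_spec(c_truncation = 3))
  expect_equal(nchar(trunc), 11)  # minus R257-G258-N259

  catcher_ext <- apply_variant(cs$catcher_seq, dom,
                               variant_spec(n_extension = NULL))
  expect_equal(catcher_ext, cs$catcher_seq)

  dom3 <- make_synthetic_domain("3kptC")
  cs3 <- make_split(dom3, system_split_spec("3kptC"),
                    detect_isopeptide(dom3)[1, ])
  expect_equal(substr(cs3$tag_seq, 12, 14), "PTK")
  gwi <- apply_variant(cs3$tag_seq, v = variant_spec(c_replacement = "GWI"))
  expect_equal(nchar(gwi), nchar(cs3$tag_seq))
  expect_equal(substr(gwi, 12, 14), "GWI")
  nq <- apply_variant(cs3$tag_seq, v = variant_spec(n_extension = "NQ"))
  expect_equal(nchar(nq), 16)

  expect_error(apply_variant("GAK", v = variant_spec(c_truncation = 5)),
               "truncation")
  expect_error(variant_spec(c_truncation = 2, c_replacement = "GWI"),
               "one C-terminal edit")
})

test_that("N-extension and C-edit commute", {
  tag <- "VMLSHLNGLMHRGN"
  v_n <- variant_spec(n_extension = "HQL")
  v_c <- variant_spec(c_truncation = 3)
  both1 <- apply_variant(apply_variant(tag, v = v_n), v = v_c)
  both2 <- apply_variant(apply_variant(tag, v = v_c), v = v_n)
  expect_equal(both1, both2)
})

test_that("point mutants check the wild type and are involutions", {
  dom <- make_synthetic_domain("4oq1")
  cs <- make_split(dom, system_split_spec("4oq1"),
                   detect_isopeptide(dom)[1, ])
  mut <- make_point_mutant(cs$catcher_seq, "K155A", numbering_offset = 145)
  expect_equal(substr(mut, 10, 10), "A")
  expect_error(make_point_mutant(cs$catcher_seq, "W155A", 145),
               "expected W, found K")
  expect_equal(make_point_mutant(mut, "A155K", 145), cs$catcher_seq)
  expect_error(make_point_mutant("GAK", "K999A", 0), "outside")
  expect_error(make_point_mutant("GAK", "bad"), "K155A")
})

test_that("fusion assembly concatenates parts and reports spans and mass", {
  lib <- fusion_part_library()
  f <- assemble_fusion(c("his6", "gs_linker", "AHIVMVDA"), lib)
  expect_equal(nchar(f$sequence), 6 + 7 + 8)
  expect_equal(f$parts$start, c(1L, 7L, 14L))
  expect_equal(f$parts$end, c(6L, 13L, 21L))
  expect_equal(f$mass, compute_mass(f$sequence))
  expect_error(assemble_fusion(c("his6", "not a part!"), lib), "unknown")
  expect_equal(lib$gs_linker, "GSGSGSG")
  expect_equal(lib$gse_linker, "GSGESG")
  expect_true(all(nzchar(attr(lib, "checksums"))))
})

test_that("MD recipes carry the protocol constants and round-trip", {
  dom <- make_synthetic_domain("4oq1")
  cs <- make_split(dom, system_split_spec("4oq1"),
                   detect_isopeptide(dom)[1, ])
  path <- withr::local_tempfile(fileext = ".yaml")
  emit_md_recipe(cs, dest = path)
  r <- read_md_recipe(path)
  expect_false(r$isopeptide_bond_present)
  expect_equal(length(r$equilibration$stages), 3)
  expect_equal(vapply(r$equilibration$stages, `[[`, numeric(1),
                      "duration_ns"), c(0.1, 0.4, 0.5))
  expect_equal(r$production$length_ns, 200)
  expect_equal(r$solvation$margin, 10)
  expect_equal(r$equilibration$target_temperature, 310)
  expect_equal(r$chains$catcher$caps$n, "acetyl")
  expect_equal(r$chains$tag$caps$c, "n_methyl")

  dom_recipe <- emit_md_recipe(select_residues(dom, "A", 146, 259))
  expect_true(dom_recipe$isopeptide_bond_present)
  # round-trip through the reader is lossless
  r2 <- read_md_recipe(path)
  expect_identical(r, r2)
})
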