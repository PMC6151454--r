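test_that("write/parse round-trip preserves labels and coordinates", {
  ens <- make_toy_complex(toy_complex_params(n_models = 2L,
                                             noise_sigma = 0.2, seed = 4L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, f)
  back <- parse_structure(f)
  expect_equal(n_models(back), 2L)
  expect_equal(back$atoms$elety, ens$atoms$elety)
  expect_equal(back$atoms$resno, ens$atoms$resno)
  expect_equal(back$atoms$chain, ens$atoms$chain)
  expect_lt(max(abs(back$xyz - ens$xyz)), 1e-3)
})

test_that("author numbering 391-414 and chain id survive a round-trip", {
  cp <- canp_peptide()
  pep <- build_ideal_helix(cp$sequence, chain_id = "B",
                           start_resno = cp$start)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep, f)
  back <- parse_structure(f)
  expect_equal(range(back$atoms$resno), c(391L, 414L))
  expect_equal(unique(back$atoms$chain), "B")
  expect_equal(sum(back$atoms$elety == "CA"), 24L)
})

test_that("a file without MODEL records parses as a single model", {
  lines <- unlist(lapply(1:10, function(i) {
    c(pdb_line(2L * i - 1L, "N", "ALA", "A", i, i * 1.0, 0, 0),
      pdb_line(2L * i, "CA", "ALA", "A", i, i * 1.0, 1.4, 0))
  }))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  ens <- parse_structure(f)
  expect_equal(n_models(ens), 1L)
  expect_equal(length(unique(ens$atoms$resno)), 10L)
})

test_that("malformed coordinates and insertion codes raise naming errors", {
  good <- pdb_line(1L, "CA", "ALA", "A", 1L, 1, 2, 3)
  bad <- sub("   1.000", "  x1.000", good, fixed = TRUE)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(good, bad, "END"), f)
  expect_error(parse_structure(f), "line 2")

  ins <- good
  substr(ins, 27L, 27L) <- "A"
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(good, ins), f2)
  expect_error(parse_structure(f2), "insertion")
})

test_that("inconsistent model composition is rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("MODEL        1",
               pdb_line(1L, "CA", "ALA", "A", 1L, 0, 0, 0),
               pdb_line(2L, "CB", "ALA", "A", 1L, 1, 0, 0),
               "ENDMDL", "MODEL        2",
               pdb_line(1L, "CA", "ALA", "A", 1L, 0, 0, 0),
               "ENDMDL", "END"), f)
  expect_error(parse_structure(f), "composition")
})

test_that("alternate locations resolve to highest occupancy, ties to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1L, "CA", "ALA", "A", 1L, 0, 0, 0, alt = "A", occ = 0.4),
    pdb_line(2L, "CA", "ALA", "A", 1L, 9, 9, 9, alt = "B", occ = 0.6),
    pdb_line(3L, "CA", "ALA", "A", 2L, 1, 1, 1, alt = "A", occ = 0.5),
    pdb_line(4L, "CA", "ALA", "A", 2L, 8, 8, 8, alt = "B", occ = 0.5),
    "END"), f)
  ens <- parse_structure(f)
  expect_equal(nrow(ens$atoms), 2L)
  co <- model_coords(ens)
  expect_equal(co[1L, ], c(9, 9, 9))  # occupancy 0.6 wins
  expect_equal(co[2L, ], c(1, 1, 1))  # tie -> altLoc A
})

test_that("selection modes count atoms correctly and are idempotent", {
  pep <- build_ideal_helix("AGA")  # Gly has no CB
  bb <- select_atoms(pep, selection_spec("P", atoms = "backbone"))
  expect_equal(nrow(bb$coords), 12L)  # 4 backbone atoms per residue
  one <- select_atoms(pep, selection_spec("P", c(2L, 2L), atoms = "CA"))
  expect_equal(nrow(one$coords), 1L)
  heavy <- select_atoms(pep, selection_spec("P", atoms = "heavy"))
  expect_equal(nrow(heavy$coords), 14L)  # 4+4+4 backbone + 2 CB
  # repeated selection is deterministic and order-stable
  all1 <- select_atoms(pep, selection_spec("P"))
  all2 <- select_atoms(pep, selection_spec("P"))
  expect_identical(all1$labels, all2$labels)
  expect_identical(all1$coords, all2$coords)
  expect_true(!is.unsorted(all1$labels$resno))
  expect_error(select_atoms(pep, selection_spec("Z")), "empty")
})

test_that("heavy-atom counts match a brute-force line scan of the file", {
  ens <- make_toy_complex(toy_complex_params())
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(ens, f)
  sel <- select_atoms(parse_structure(f), selection_spec("P", atoms = "heavy"))
  lines <- readLines(f)
  atom_lines <- lines[startsWith(lines, "ATOM")]
  on_p <- atom_lines[substr(atom_lines, 22L, 22L) == "P"]
  elems <- trimws(substr(on_p, 77L, 78L))
  expect_equal(nrow(sel$coords), sum(elems != "H"))
})

test_that("hetero atoms are excluded by default but selectable", {
  f <- withr::local_tempfile(fileext = ".pdb")
  ca_het <- sub("^ATOM  ", "HETATM",
                pdb_line(3L, "CA", "CA", "A", 150L, 5, 5, 5, elem = "CA"))
  writeLines(c(pdb_line(1L, "N", "ALA", "A", 1L, 0, 0, 0),
               pdb_line(2L, "CA", "ALA", "A", 1L, 1.4, 0, 0),
               ca_het, "END"), f)
  ens <- parse_structure(f)
  expect_equal(nrow(ens$atoms), 3L)
  no_het <- select_atoms(ens, selection_spec("A"))
  expect_equal(nrow(no_het$coords), 2L)
  with_het <- select_atoms(ens, selection_spec("A", include_het = TRUE))
  expect_equal(nrow(with_het$coords), 3L)
})
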