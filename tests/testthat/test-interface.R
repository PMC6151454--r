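two_atom_ensemble <- function(d) {
  atoms <- data.frame(type = "ATOM", elety = c("CB", "CB"),
                      resid = c("ILE", "LEU"), chain = c("P", "A"),
                      resno = c(1L, 10L), elesy = "C",
                      stringsAsFactors = FALSE)
  structure_ensemble(atoms, matrix(c(0, 0, 0, d, 0, 0), nrow = 1L),
                     id = "pair")
}

test_that("contact detection honours the cutoff", {
  ens <- two_atom_ensemble(3.0)
  hits <- heavy_atom_contacts(ens, selection_spec("P"),
                              selection_spec("A"), cutoff = 4.5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$n_atom_pairs, 1L)
  expect_equal(hits$min_distance, 3.0)
  expect_equal(nrow(heavy_atom_contacts(ens, selection_spec("P"),
                                        selection_spec("A"),
                                        cutoff = 2.5)), 0L)
  expect_error(heavy_atom_contacts(ens, selection_spec("P"),
                                   selection_spec("P"), 4.5), "overlap")
})

test_that("contacts match the brute-force all-pairs oracle exactly", {
  ens <- make_toy_complex(toy_complex_params())
  ga <- selection_spec("P", c(1L, 24L))
  gb <- selection_spec("R")
  for (cutoff in c(4.0, 4.5, 6.0)) {
    fast <- heavy_atom_contacts(ens, ga, gb, cutoff)
    slow <- oracle_contacts(ens, ga, gb, cutoff)
    expect_equal(nrow(fast), nrow(slow))
    expect_equal(fast$resno_a, slow$resno_a)
    expect_equal(fast$resno_b, slow$resno_b)
    expect_equal(fast$min_distance, slow$min_distance, tolerance = 1e-12)
    expect_equal(fast$n_atom_pairs, slow$n_atom_pairs)
  }
  # monotonicity: smaller cutoff never adds contacts
  small <- heavy_atom_contacts(ens, ga, gb, 4.0)
  big <- heavy_atom_contacts(ens, ga, gb, 4.5)
  expect_true(all(paste(small$resno_a, small$resno_b) %in%
                    paste(big$resno_a, big$resno_b)))
})

test_that("salt bridges: constructed pair, cutoff, and symmetry", {
  close <- make_arg_glu(3.5)
  sb <- find_salt_bridges(close, "P", "A")
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$basic_resno, 392L)
  expect_equal(sb$acidic_resno, 47L)
  expect_equal(sb$min_NO_distance, 3.5, tolerance = 1e-9)
  far <- make_arg_glu(6.0)
  expect_equal(nrow(find_salt_bridges(far, "P", "A", cutoff = 4.0)), 0L)
  # symmetric in chain order
  sb2 <- find_salt_bridges(close, "A", "P")
  expect_equal(sb2$basic_resno, sb$basic_resno)
  expect_equal(sb2$min_NO_distance, sb$min_NO_distance)
  expect_error(find_salt_bridges(close, "P", "P"), "distinct")
})

test_that("salt bridges match the brute-force oracle", {
  close <- make_arg_glu(3.9)
  fast <- find_salt_bridges(close, "P", "A", cutoff = 4.0)
  slow <- oracle_salt_bridges(close, "P", "A", cutoff = 4.0)
  expect_equal(nrow(fast), nrow(slow))
  expect_equal(fast$min_NO_distance, slow$min_NO_distance,
               tolerance = 1e-12)
})

test_that("anchor identification and ranking on the toy complex", {
  ens <- make_toy_complex(toy_complex_params())
  an <- identify_anchors(ens, selection_spec("P", c(1L, 24L)),
                         domain_spec("R", c(1L, 30L), "N-domain"),
                         domain_spec("R", c(101L, 130L), "C-domain"))
  expect_equal(an$resno, c(1L, 5L, 15L, 18L))
  expect_equal(an$buried_domain, c("N-domain", "N-domain",
                                   "C-domain", "C-domain"))
  expect_true(all(an$rank == "minor"))  # one pocket residue each
  # with threshold 1 every anchor ranks major
  an2 <- identify_anchors(ens, selection_spec("P", c(1L, 24L)),
                          domain_spec("R", c(1L, 30L), "N-domain"),
                          domain_spec("R", c(101L, 130L), "C-domain"),
                          major_threshold = 1L)
  expect_true(all(an2$rank == "major"))
  # a Ser/Gly-only peptide yields no anchors
  ser <- make_toy_complex(toy_complex_params(anchor_positions = 2L))
  ser$atoms$resid[ser$atoms$chain == "P" & ser$atoms$resno == 2L] <- "SER"
  none <- identify_anchors(ser, selection_spec("P", c(1L, 24L)),
                           domain_spec("R", c(1L, 30L), "N-domain"),
                           domain_spec("R", c(101L, 130L), "C-domain"))
  expect_equal(nrow(none), 0L)
})

test_that("spacing pattern arithmetic and invariances", {
  an <- data.frame(chain = "P", resno = c(396L, 400L, 410L, 413L),
                   resid = c("ILE", "ILE", "PHE", "LEU"),
                   contact_count = c(9L, 3L, 3L, 8L),
                   buried_domain = c("N-domain", "N-domain",
                                     "C-domain", "C-domain"),
                   rank = c("major", "minor", "minor", "major"))
  pat <- spacing_pattern(an)
  expect_equal(pat$indices, c(1L, 5L, 15L, 18L))
  expect_equal(pat$mode_label, "1-18")
  expect_equal(pat$orientation, "parallel")
  # translation invariance of the numbering
  an2 <- an
  an2$resno <- an$resno + 57L
  expect_equal(spacing_pattern(an2)$indices, pat$indices)
  # single anchor and the 1-14 arithmetic
  expect_equal(spacing_pattern(an[1L, ])$mode_label, "1-1")
  an14 <- an[c(1L, 2L), ]
  an14$resno <- c(100L, 113L)
  an14$buried_domain <- c("C-domain", "N-domain")
  pat14 <- spacing_pattern(an14)
  expect_equal(pat14$mode_label, "1-14")
  expect_equal(pat14$orientation, "antiparallel")
  multi <- an
  multi$chain <- c("P", "P", "Q", "Q")
  expect_error(spacing_pattern(multi), "multiple chains")
})

test_that("consensus contacts keep pairs present in enough models", {
  ens <- make_toy_complex(toy_complex_params(noise_sigma = 0.15,
                                             n_models = 10L, seed = 21L))
  cons <- consensus_contacts(ens, selection_spec("P", c(1L, 24L)),
                             selection_spec("R"), cutoff = 4.5,
                             min_fraction = 0.5)
  expect_true(all(cons$fraction_of_models >= 0.5))
  expect_true(all(c(1L, 5L, 15L, 18L) %in% cons$resno_a))
})
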