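test_that("Eq.-1 style perturbation values are exact for analytic cases", {
  mk <- function(hn, nn, label) {
    out <- data.frame(resno = seq_along(hn), resid = "ALA",
                      delta_HN = hn, delta_N = nn)
    attr(out, "label") <- label
    class(out) <- c("shift_table", "data.frame")
    out
  }
  free <- mk(c(8, 8, 8), c(120, 120, 120), "free")
  bound <- mk(c(8, 8.1, 8), c(120, 120, 120.5), "bound")
  cs <- compute_csp(free, bound)
  expect_equal(cs$records$delta_residue[1L], 0)
  expect_equal(cs$records$delta_residue[2L], 0.1 / sqrt(2),
               tolerance = 1e-12)
  # the 1/5 nitrogen scaling makes dN = 0.5 equal dHN = 0.1
  expect_equal(cs$records$delta_residue[3L], cs$records$delta_residue[2L],
               tolerance = 1e-12)
  # sign-flip invariance and linear scaling
  bound_neg <- mk(c(8, 7.9, 8), c(120, 120, 119.5), "bound")
  expect_equal(compute_csp(free, bound_neg)$records$delta_residue,
               cs$records$delta_residue, tolerance = 1e-12)
  bound_x3 <- mk(c(8, 8.3, 8), c(120, 120, 121.5), "bound")
  cs3 <- compute_csp(free, bound_x3)
  expect_equal(cs3$records$delta_residue, 3 * cs$records$delta_residue,
               tolerance = 1e-12)
  expect_equal(cs3$mean_csp, 3 * cs$mean_csp, tolerance = 1e-12)
  # no shared residues
  late <- mk(c(8, 8), c(120, 120), "bound")
  late$resno <- c(50L, 51L)
  expect_error(compute_csp(free, late), "no residues")
})

test_that("shift-table reader handles CSV/TSV, missing rows, round-trip", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("resno,resid,delta_HN,delta_N",
               "1,ALA,8.10,120.5", "2,GLY,8.35,109.2",
               "3,LEU,7.95,122.1"), f)
  tab <- read_shift_table(f, "free")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$delta_N[2L], 109.2)
  # blank value dropped with a warning
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("resno,resid,delta_HN,delta_N",
               "1,ALA,8.10,120.5", "2,GLY,8.35,"), f2)
  expect_warning(tab2 <- read_shift_table(f2, "bound"), "dropped")
  expect_equal(nrow(tab2), 1L)
  # unrecognizable header
  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b,c", "1,2,3"), f3)
  expect_error(read_shift_table(f3), "format error")
  # generator output round-trips through write/read
  tabs <- simulate_shift_tables(n_residues = 30L,
                                hotspot_ranges = list(c(10L, 12L)),
                                seed = 2L)
  f4 <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(tabs$free, f4)
  back <- read_shift_table(f4, "free")
  expect_equal(back$delta_HN, tabs$free$delta_HN, tolerance = 1e-12)
  expect_equal(back$resno, tabs$free$resno)
})

test_that("perturbed regions: thresholds, nesting and gap bridging", {
  rec <- data.frame(resno = c(1:30, 32:40),
                    delta_residue = 0.05)
  rec$delta_residue[rec$resno %in% c(19, 20)] <- 0.9
  rec$delta_residue[rec$resno %in% c(28:30, 32:34)] <- 0.8
  regions <- perturbed_regions(rec, multiplier = 3)
  # residue 31 is unassigned: the run bridges across it
  expect_equal(regions$start, c(19L, 28L))
  expect_equal(regions$end, c(20L, 34L))
  # a present-but-cold residue breaks a run
  rec2 <- rec
  rec2 <- rbind(rec2, data.frame(resno = 31L, delta_residue = 0.01))
  rec2 <- rec2[order(rec2$resno), ]
  regions2 <- perturbed_regions(rec2, multiplier = 3)
  expect_equal(regions2$start, c(19L, 28L, 32L))
  # no bridging when disabled
  r3 <- perturbed_regions(rec, multiplier = 3, bridge_gaps = FALSE)
  expect_equal(r3$start, c(19L, 28L, 32L))
  # monotone thresholds: 3x calls are a subset of 2x calls
  tabs <- simulate_shift_tables(seed = 8L)
  cs <- compute_csp(tabs$free, tabs$bound)
  in_regions <- function(regs, rn) {
    any(rn >= regs$start & rn <= regs$end)
  }
  r2x <- perturbed_regions(cs, 2)
  r3x <- perturbed_regions(cs, 3)
  hot3 <- cs$records$resno[cs$records$over_3x]
  expect_true(all(vapply(hot3, in_regions, logical(1L), regs = r2x)))
  # all-cold map yields no regions
  cold <- data.frame(resno = 1:20, delta_residue = rep(0.1, 20))
  expect_equal(nrow(perturbed_regions(cold, multiplier = 3)), 0L)
})
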