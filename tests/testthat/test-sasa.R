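# Shrake-Rupley SASA and buried-surface-area decomposition.

test_that("an isolated atom recovers the analytic sphere area", {
  a <- atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0)
  got <- shrake_rupley(a, n_points = 960)$atom_sasa
  expect_equal(got, 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-6)
})

test_that("an atom fully inside a larger expanded sphere has zero SASA", {
  # tiny offset inside a sulfur sphere: carbon's expanded sphere (r 3.10)
  # entirely within the sulfur's (r 3.20) when centres are 0.05 apart
  a <- rbind(atom_row("A", 1, "CYS", "CB", "C", 0.05, 0, 0),
             atom_row("A", 2, "CYS", "SG", "S", 0, 0, 0))
  got <- shrake_rupley(a)$atom_sasa
  expect_equal(got[1], 0)
})

test_that("unknown elements raise an error instead of a silent default", {
  a <- atom_row("A", 1, "XXX", "FE", "FE", 0, 0, 0)
  expect_error(shrake_rupley(a), "radius")
})

test_that("per-atom SASA agrees with a dense-sampling oracle on small fixtures", {
  fixtures <- list(
    rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
          atom_row("A", 2, "ALA", "CB", "C", 2.5, 0, 0),
          atom_row("A", 3, "ALA", "N", "N", 1.2, 2.2, 0)),
    rbind(atom_row("A", 1, "SER", "OG", "O", 0, 0, 0),
          atom_row("A", 2, "CYS", "SG", "S", 3.1, 0.5, -0.5),
          atom_row("A", 3, "ALA", "CA", "C", 1.4, -2.4, 1.0)))
  for (atoms in fixtures) {
    got <- shrake_rupley(atoms, n_points = 960)$atom_sasa
    want <- oracle_sasa(atoms)
    expect_lt(max(abs(got - want) / want), 0.02)
  }
})

test_that("sampling is converged: doubling points twice changes SASA < 1%", {
  atoms <- rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                 atom_row("A", 2, "ALA", "CB", "C", 2.0, 1.0, 0),
                 atom_row("A", 3, "ALA", "N", "N", -1.5, 1.8, 0.5),
                 atom_row("A", 4, "ALA", "O", "O", 0.5, -2.2, -1.0))
  s1 <- shrake_rupley(atoms, n_points = 960)$atom_sasa
  s2 <- shrake_rupley(atoms, n_points = 3840)$atom_sasa
  expect_lt(max(abs(s1 - s2) / pmax(s2, 1)), 0.01)
})

test_that("grid neighbour search equals the all-pairs computation", {
  set.seed(42)
  xyz <- matrix(runif(3 * 60, 0, 15), ncol = 3)
  R <- runif(60, 2.9, 3.3)
  grid <- pmhcprofiler:::expanded_neighbors(xyz, R)
  for (i in seq_len(60)) {
    d <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    brute <- setdiff(which(d < R + R[i]), i)
    expect_setequal(grid[[i]], brute)
  }
})

test_that("residue SASA sums atom SASA and totals match molecular SASA", {
  atoms <- rbind(atom_row("A", 1, "ALA", "CA", "C", 0, 0, 0),
                 atom_row("A", 1, "ALA", "CB", "C", 1.5, 0, 0),
                 atom_row("A", 2, "GLY", "CA", "C", 3.5, 1, 0))
  sr <- shrake_rupley(atoms)
  expect_equal(sum(sr$residue_sasa), sum(sr$atom_sasa))
  expect_equal(unname(sr$residue_sasa["A:1:"]), sum(sr$atom_sasa[1:2]))
})

two_sphere_complex <- function(gap = 2.0) {
  atoms <- rbind(atom_row("H", 23, "ALA", "CA", "C", 0, 0, 0),
                 atom_row("L", 23, "ALA", "CA", "C", 50, 50, 50),
                 atom_row("P", 1, "GLY", "CA", "C", gap, 0, 0))
  num <- data.frame(chain = c("H", "L"), resno = c(23L, 23L), icode = "",
                    number = c(23L, 23L))
  make_test_complex(atoms, c(H = "HEAVY", L = "LIGHT", P = "PEPTIDE"), num)
}

test_that("distant partners bury nothing; touching spheres bury symmetrically", {
  far <- burial_profile(two_sphere_complex(gap = 100))
  expect_equal(far$totals$interface_bsa, 0)
  expect_equal(far$buried_peptide_residue_count, 0)

  near <- burial_profile(two_sphere_complex(gap = 2.0))
  pr <- near$per_residue
  d_h <- pr$delta[pr$chain == "H"]
  d_p <- pr$delta[pr$chain == "P"]
  expect_gt(d_h, 0)
  # identical spheres occlude each other equally, up to lattice resolution
  expect_equal(d_h, d_p, tolerance = 0.01)
  expect_equal(near$totals$interface_bsa,
               near$totals$immunoglobulin_bsa + near$totals$antigen_bsa)
})

test_that("burial is monotone and decomposition exact on random two-sided fixtures", {
  set.seed(7)
  for (rep in 1:20) {
    nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    atoms <- rbind(
      atom_row("H", seq_len(nA), "ALA", "CA", "C",
               runif(nA, 0, 8), runif(nA, 0, 8), runif(nA, 0, 4)),
      atom_row("L", 1, "ALA", "CA", "C", -30, 0, 0),
      atom_row("P", seq_len(nB), "GLY", "CA", "C",
               runif(nB, 0, 8), runif(nB, 0, 8), runif(nB, 3, 7)))
    num <- data.frame(chain = c(rep("H", nA), "L"),
                      resno = c(seq_len(nA), 1L), icode = "",
                      number = c(seq_len(nA), 23L))
    cx <- make_test_complex(atoms, c(H = "HEAVY", L = "LIGHT", P = "PEPTIDE"),
                            num)
    bp <- burial_profile(cx, config = profiler_config(n_sphere_points = 240L))
    expect_true(all(bp$per_residue$delta >= 0))
    expect_equal(bp$totals$interface_bsa,
                 sum(bp$per_residue$delta))
    expect_equal(bp$totals$antigen_bsa,
                 bp$totals$peptide_bsa + bp$totals$mhc_bsa)
  }
})

test_that("planted peptide occlusion is recovered exactly", {
  occ <- c(2L, 4L, 6L)
  fx <- make_groove_complex(groove_fixture_spec(occluded_positions = occ,
                                                seed = 5))
  bp <- burial_profile(fx$complex)
  pr <- bp$per_residue[bp$per_residue$role == "PEPTIDE", ]
  expect_identical(sort(pr$resno[pr$buried]), occ)
  expect_equal(bp$buried_peptide_residue_count, 3)
  expect_equal(bp$peptide_fraction, 1.0)  # binder touches no MHC by design
})

test_that("CDR fractions follow per-residue arithmetic on a constructed split", {
  # CDRH3 and CDRL3 single residues contacting the peptide from different
  # distances: fractions must equal the delta ratio, whatever it is
  atoms <- rbind(atom_row("H", 107, "ALA", "CA", "C", 0, 0, 3.0),
                 atom_row("L", 107, "ALA", "CA", "C", 10, 0, 4.5),
                 atom_row("P", 1, "GLY", "CA", "C", 0, 0, 0),
                 atom_row("P", 2, "GLY", "CA", "C", 10, 0, 0))
  num <- data.frame(chain = c("H", "L"), resno = c(107L, 107L), icode = "",
                    number = c(107L, 107L))
  cx <- make_test_complex(atoms, c(H = "HEAVY", L = "LIGHT", P = "PEPTIDE"),
                          num)
  bp <- burial_profile(cx)
  pr <- bp$per_residue
  dh <- pr$delta[pr$chain == "H"]; dl <- pr$delta[pr$chain == "L"]
  expect_equal(cdr_fraction(bp, "CDRH3"), dh / (dh + dl))
  expect_equal(cdr_fraction(bp, "CDRH3", "cdr3_pair"), dh / (dh + dl))
  expect_equal(cdr_fraction(bp, "CDRL3", "cdr3_pair"), dl / (dh + dl))
  expect_equal(bp$cdr3_pair_fraction, dh / (dh + dl))
  # a loop with no buried residues contributes zero
  expect_equal(cdr_fraction(bp, "CDRH1"), 0)
})

test_that("cdr_fraction flags a zero denominator", {
  bp <- burial_profile(two_sphere_complex(gap = 100))
  expect_warning(f <- cdr_fraction(bp, "CDRH3"), "zero")
  expect_true(is.na(f))
})
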