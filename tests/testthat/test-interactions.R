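# Interface interaction typing and residue-pair consolidation.

# Complexes here put the immunoglobulin side on chain H and the antigen on
# chains M (MHC) / P (peptide).
ig_roles <- c(H = "HEAVY", L = "LIGHT", M = "MHC_ALPHA", P = "PEPTIDE")

with_l_chain <- function(atoms) {
  rbind(atoms, atom_row("L", 1, "ALA", "CA", "C", 99, 99, 99))
}

base_numbering <- function(extra = NULL) {
  num <- data.frame(chain = c("H", "L"), resno = c(1L, 1L), icode = "",
                    number = c(107L, 107L), stringsAsFactors = FALSE)
  rbind(num, extra)
}

test_that("apolar carbon pairs within 4.5 A are hydrophobic, far pairs nothing", {
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "LEU", "CD1", "C", 0, 0, 0),
    atom_row("P", 1, "VAL", "CG1", "C", 4.0, 0, 0),
    atom_row("P", 2, "GLY", "N", "N", 8, 8, 8),
    atom_row("H", 2, "ALA", "O", "O", 8, 8, 16)))
  cx <- make_test_complex(atoms, ig_roles,
                          base_numbering(data.frame(chain = "H", resno = 2L,
                                                    icode = "", number = 40L)))
  contacts <- detect_atom_contacts(cx)
  expect_equal(nrow(contacts), 1)
  expect_identical(contacts$type, "hydrophobic")
  expect_equal(contacts$distance, 4.0)
})

test_that("polar carbons are not hydrophobic partners", {
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "SER", "CB", "C", 0, 0, 0),   # bonded to OG: polar
    atom_row("P", 1, "VAL", "CG1", "C", 4.0, 0, 0)))
  cx <- make_test_complex(atoms, ig_roles, base_numbering())
  expect_equal(nrow(detect_atom_contacts(cx)), 0)
})

test_that("carboxylate-guanidino geometry yields both candidate salt bridge and hydrogen bond", {
  # Asp OD1 3.2 A from Arg NH1; CZ placed behind NH1 so the donor angle
  # opens towards the acceptor
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "ARG", "NH1", "N", 0, 0, 0),
    atom_row("H", 1, "ARG", "CZ", "C", -1.33, 0, 0),
    atom_row("P", 1, "ASP", "OD1", "O", 3.2, 0, 0)))
  cx <- make_test_complex(atoms, ig_roles, base_numbering())
  contacts <- detect_atom_contacts(cx)
  expect_setequal(contacts$type, c("hydrogen_bond", "salt_bridge_candidate"))
  expect_true(all(abs(contacts$distance - 3.2) < 1e-9))
})

test_that("a bent donor geometry suppresses the hydrogen bond", {
  # antecedent on the same side as the acceptor: angle ~0 degrees
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "SER", "OG", "O", 0, 0, 0),
    atom_row("H", 1, "SER", "CB", "C", 1.5, 0, 0),
    atom_row("P", 1, "GLY", "O", "O", 3.2, 0, 0)))
  cx <- make_test_complex(atoms, ig_roles, base_numbering())
  contacts <- detect_atom_contacts(cx)
  expect_false("hydrogen_bond" %in% contacts$type)
})

test_that("aromatic ring centroids within 5 A register one aromatic contact", {
  ring <- function(chain, resno, resname, cx, cy, cz, r = 1.4) {
    ang <- seq(0, 300, by = 60) * pi / 180
    names6 <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
    do.call(rbind, lapply(1:6, function(i)
      atom_row(chain, resno, resname, names6[i], "C",
               cx + r * cos(ang[i]), cy + r * sin(ang[i]), cz)))
  }
  atoms <- with_l_chain(rbind(ring("H", 1, "PHE", 0, 0, 0),
                              ring("P", 1, "PHE", 0, 0, 4.5)))
  cx <- make_test_complex(atoms, ig_roles, base_numbering())
  contacts <- detect_atom_contacts(cx)
  arom <- contacts[contacts$type == "aromatic", ]
  expect_equal(nrow(arom), 1)
  expect_equal(arom$distance, 4.5)
})

test_that("multiple atom contacts consolidate to one interaction per type (rules 1-3)", {
  # five hydrophobic atom contacts between one Leu/Val pair
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "LEU", "CB", "C", 0, 0, 0),
    atom_row("H", 1, "LEU", "CG", "C", 1.5, 0, 0),
    atom_row("H", 1, "LEU", "CD1", "C", 0, 1.5, 0),
    atom_row("P", 1, "VAL", "CG1", "C", 0, 0, 3.9),
    atom_row("P", 1, "VAL", "CG2", "C", 1.5, 0, 3.9)))
  cx <- make_test_complex(atoms, ig_roles, base_numbering())
  contacts <- detect_atom_contacts(cx)
  expect_gte(nrow(contacts), 5)
  prof <- consolidate(contacts)
  expect_equal(nrow(prof$pairs), 1)
  expect_identical(prof$pairs$type, "hydrophobic")
})

test_that("a residue pair can carry both hydrophobic and aromatic interactions", {
  contacts <- data.frame(
    uid_a = "H:1:", atom_a = c("CG", "RING"),
    uid_b = "P:1:", atom_b = c("CG", "RING"),
    distance = c(4.2, 4.8), type = c("hydrophobic", "aromatic"),
    stringsAsFactors = FALSE)
  prof <- consolidate(contacts)
  expect_equal(nrow(prof$pairs), 2)
  expect_setequal(prof$pairs$type, c("hydrophobic", "aromatic"))
})

test_that("the closest charge pair takes the salt bridge, others demote to hydrogen bonds", {
  contacts <- data.frame(
    uid_a = c("H:10:", "H:20:"), atom_a = c("NH1", "NH2"),
    uid_b = c("P:5:", "P:5:"), atom_b = c("OD1", "OD2"),
    distance = c(2.9, 3.4),
    type = "salt_bridge_candidate", stringsAsFactors = FALSE)
  prof <- consolidate(contacts)
  sb <- prof$pairs[prof$pairs$type == "salt_bridge", ]
  hb <- prof$pairs[prof$pairs$type == "hydrogen_bond", ]
  expect_equal(sb$uid_a, "H:10:")
  expect_equal(sb$min_distance, 2.9)
  expect_equal(hb$uid_a, "H:20:")
})

test_that("consolidation is idempotent under re-expansion", {
  set.seed(31)
  contacts <- data.frame(
    uid_a = paste0("H:", sample(1:5, 30, TRUE), ":"),
    atom_a = "NH1",
    uid_b = paste0("P:", sample(1:5, 30, TRUE), ":"),
    atom_b = "OD1",
    distance = round(runif(30, 2.5, 4.0), 3),
    type = sample(c("hydrophobic", "hydrogen_bond", "salt_bridge_candidate"),
                  30, TRUE),
    stringsAsFactors = FALSE)
  prof1 <- consolidate(contacts)
  # expand back: each pair interaction as a single atom contact
  back <- prof1$pairs
  back <- data.frame(uid_a = back$uid_a, atom_a = "X", uid_b = back$uid_b,
                     atom_b = "Y", distance = back$min_distance,
                     type = ifelse(back$type == "salt_bridge",
                                   "salt_bridge_candidate", back$type),
                     stringsAsFactors = FALSE)
  prof2 <- consolidate(back)
  expect_equal(prof1$pairs, prof2$pairs)
})

test_that("salt-bridge uniqueness per charge group holds on random candidate sets", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    contacts <- data.frame(
      uid_a = paste0("H:", sample(1:4, n, TRUE), ":"),
      atom_a = "NZ",
      uid_b = paste0("P:", sample(1:4, n, TRUE), ":"),
      atom_b = "OE1",
      distance = round(runif(n, 2.5, 4.0), 3),
      type = "salt_bridge_candidate", stringsAsFactors = FALSE)
    prof <- consolidate(contacts)
    sb <- prof$pairs[prof$pairs$type == "salt_bridge", ]
    expect_false(any(duplicated(sb$uid_a)))
    expect_false(any(duplicated(sb$uid_b)))
    expect_gte(nrow(sb), 1)
  }
})

test_that("empty contact lists give an empty profile", {
  prof <- consolidate(pmhcprofiler:::empty_contacts())
  expect_equal(nrow(prof$pairs), 0)
})

test_that("interaction summary books counts by antigen region", {
  # 3 CDRH3 residues touch the peptide; 2 CDRH3 contacts to MHC
  atoms <- with_l_chain(rbind(
    atom_row("H", 1, "LEU", "CD1", "C", 0, 0, 0),
    atom_row("H", 2, "VAL", "CG1", "C", 4, 0, 0),
    atom_row("H", 3, "ILE", "CD1", "C", 8, 0, 0),
    atom_row("H", 4, "ALA", "CB", "C", 20, 0, 0),
    atom_row("P", 1, "VAL", "CG2", "C", 0, 0, 4),
    atom_row("P", 2, "LEU", "CD2", "C", 4, 0, 4),
    atom_row("P", 3, "ILE", "CG2", "C", 8, 0, 4),
    atom_row("M", 60, "LEU", "CD1", "C", 20, 0, 4),
    atom_row("M", 61, "VAL", "CG1", "C", 20, 0, -4)))
  num <- data.frame(chain = c("H", "H", "H", "H", "L", "M", "M"),
                    resno = c(1L, 2L, 3L, 4L, 1L, 60L, 61L), icode = "",
                    number = c(107L, 108L, 109L, 110L, 107L, 60L, 61L),
                    stringsAsFactors = FALSE)
  cx <- make_test_complex(atoms, ig_roles, num)
  prof <- consolidate(detect_atom_contacts(cx))
  s <- interaction_summary(prof, cx)
  expect_equal(s$peptide_residues_contacted, 3)
  expect_equal(s$ig_residues_contacting_peptide, 3)
  expect_equal(s$n_ig_peptide_interactions, 3)
  expect_equal(s$n_ig_mhc_interactions, 2)
  expect_equal(s$n_cdr3_mhc_interactions, 2)
  expect_equal(s$n_total_interactions, 5)
  expect_equal(s$n_hydrophobic, 5)
})

test_that("summaries and totals are invariant under contact row order", {
  set.seed(5)
  contacts <- data.frame(
    uid_a = paste0("H:", sample(1:6, 40, TRUE), ":"), atom_a = "CB",
    uid_b = paste0("P:", sample(1:6, 40, TRUE), ":"), atom_b = "CB",
    distance = round(runif(40, 3, 4.4), 3), type = "hydrophobic",
    stringsAsFactors = FALSE)
  p1 <- consolidate(contacts)
  p2 <- consolidate(contacts[rev(seq_len(nrow(contacts))), ])
  expect_equal(p1$pairs, p2$pairs)
  expect_equal(nrow(p1$pairs),
               nrow(unique(contacts[, c("uid_a", "uid_b", "type")])))
})

test_that("external contact files import through the same consolidation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chain_a\tresno_a\ticode_a\tatom_a\tchain_b\tresno_b\ticode_b\tatom_b\tdistance\ttype",
    "H\t10\t.\tNH1\tP\t5\t.\tOD1\t2.9\tsalt_bridge",
    "H\t20\t.\tNH2\tP\t5\t.\tOD2\t3.4\tsalt_bridge"), f)
  contacts <- read_contacts(f)
  prof <- consolidate(contacts)
  expect_equal(prof$pairs$type[prof$pairs$uid_a == "H:10:"], "salt_bridge")
  expect_equal(prof$pairs$type[prof$pairs$uid_a == "H:20:"], "hydrogen_bond")
})
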