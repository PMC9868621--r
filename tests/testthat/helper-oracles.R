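# Test helpers: independent oracles and hand-built complex assembly.

# Assemble an annotated_complex directly from parts (test-only constructor).
make_test_complex <- function(atoms, roles, numbering = NULL,
                              ig_class = "TCRM", mhc_class = NA_character_,
                              complex_id = "test") {
  if (is.null(numbering))
    numbering <- data.frame(chain = character(0), resno = integer(0),
                            icode = character(0), number = integer(0),
                            stringsAsFactors = FALSE)
  structure(list(complex_id = complex_id, atoms = atoms, chain_roles = roles,
                 numbering = numbering, ig_class = ig_class,
                 mhc_class = mhc_class),
            class = "annotated_complex")
}

atom_row <- function(chain, resno, resname, atom, element, x, y, z,
                     icode = "") {
  data.frame(chain = chain, resno = as.integer(resno), icode = icode,
             resname = resname, atom = atom, element = element,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

# Dense-sampling SASA oracle: equal-area latitude/longitude grid, all-pairs
# occlusion test. Independent of the golden-spiral lattice and grid search
# used by the implementation.
oracle_sasa <- function(atoms, probe = 1.4, n_theta = 316, n_phi = 316,
                        radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- unname(radii[atoms$element]) + probe
  ct <- 1 - (seq_len(n_theta) - 0.5) * 2 / n_theta   # cos(theta), equal-area
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- (seq_len(n_phi) - 0.5) * 2 * pi / n_phi
  pts <- cbind(rep(st, each = n_phi) * cos(ph),
               rep(st, each = n_phi) * sin(ph),
               rep(ct, each = n_phi))
  n <- nrow(xyz)
  vapply(seq_len(n), function(i) {
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, nrow(p))
    for (j in setdiff(seq_len(n), i)) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      free <- free & d2 >= R[j]^2
    }
    4 * pi * R[i]^2 * mean(free)
  }, 0)
}

# Needleman-Wunsch oracle (match +1, mismatch 0, gap 0) with traceback;
# identity/coverage per the package's definitions but computed from an
# independent dynamic program.
nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  F <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m))
    F[i + 1, j + 1] <- max(F[i, j] + (A[i] == B[j]), F[i, j + 1], F[i + 1, j])
  # traceback, preferring diagonal, then up, then left
  i <- n; j <- m; pa <- character(0); pb <- character(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && F[i + 1, j + 1] == F[i, j] + (A[i] == B[j])) {
      pa <- c(A[i], pa); pb <- c(B[j], pb); i <- i - 1; j <- j - 1
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1]) {
      pa <- c(A[i], pa); pb <- c("-", pb); i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j], pb); j <- j - 1
    }
  }
  gap_a <- pa == "-"; gap_b <- pb == "-"
  L <- length(pa)
  lead <- max(which.min(gap_a), which.min(gap_b)) - 1
  if (all(gap_a) || all(gap_b)) return(c(identity = 0, coverage = 0))
  trail <- max(which.min(rev(gap_a)), which.min(rev(gap_b))) - 1
  keep <- seq_len(L); keep <- keep[keep > lead & keep <= L - trail]
  matches <- sum(pa[keep] == pb[keep] & pa[keep] != "-")
  c(identity = matches / length(keep),
    coverage = min(1, length(keep) / min(n, m)))
}

# Independent greedy clustering on the oracle identity.
oracle_greedy_cluster <- function(sequences, threshold, min_coverage = 0) {
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]; seqs <- unname(sequences[ord])
  seeds <- integer(0); rep_of <- character(0)
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (s in seeds) {
      m <- nw_identity(seqs[i], seqs[s])
      if (m[["identity"]] >= threshold && m[["coverage"]] >= min_coverage) {
        rep_of[ids[i]] <- ids[s]; placed <- TRUE; break
      }
    }
    if (!placed) { seeds <- c(seeds, i); rep_of[ids[i]] <- ids[i] }
  }
  rep_of
}

random_rotation <- function() {
  qr_m <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_m)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3,
               byrow = TRUE)
  diag(3) * cos(th) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
}

# Minimal fixed-width PDB line (test-only; exercises the reader on raw text)
pdb_line <- function(record, serial, atom, resname, chain, resno, x, y, z,
                     occ = 1, b = 0, element = substr(atom, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, atom, "", resname, chain, resno, "", x, y, z,
          occ, b, element)
}
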