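## Residue-level interface interaction typing (hydrophobic, aromatic,
## hydrogen bond, salt bridge) with residue-pair consolidation.

# Heavy-atom chemistry tables. Apolar carbons exclude carbons directly
# bonded to N/O (backbone C, CA, and polar-adjacent side-chain carbons).
APOLAR_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG", "CD"), TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  THR = "CG2", LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLN = c("CB", "CG"), GLU = c("CB", "CG"), ASN = "CB", ASP = "CB",
  HIS = "CB", CYS = "CB", GLY = character(0), SER = character(0))

AROMATIC_RINGS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

# donor atom -> covalent antecedent used for the donor-angle test
HBOND_DONORS <- list(
  backbone = c(N = "CA"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"), LYS = c(NZ = "CE"),
  HIS = c(ND1 = "CG", NE2 = "CD2"), ASN = c(ND2 = "CG"), GLN = c(NE2 = "CD"),
  SER = c(OG = "CB"), THR = c(OG1 = "CB"), TYR = c(OH = "CZ"),
  TRP = c(NE1 = "CD1"))

HBOND_ACCEPTORS <- list(
  backbone = "O",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

SB_NEGATIVE <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
SB_POSITIVE <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                    HIS = c("ND1", "NE2"))

#' Geometric interaction criteria
#'
#' Distance/angle thresholds for the four attractive interaction types.
#' Defaults: hydrophobic, apolar-carbon pairs within 4.5 A; aromatic,
#' ring-centroid pairs (Phe/Tyr/Trp/His) within 5.0 A; hydrogen bond, donor
#' heavy atom to acceptor within 3.5 A and antecedent-donor-acceptor angle
#' of at least 90 degrees (weak, angle-failing geometries are never
#' emitted); salt-bridge candidate, Asp/Glu carboxylate oxygen to Lys NZ /
#' Arg NH1-NH2-NE / His ND1-NE2 within 4.0 A. His is treated as positively
#' charged by default (no protonation model); disable with
#' `his_positive = FALSE`.
#'
#' @param hydrophobic_cutoff,aromatic_cutoff,hbond_cutoff,salt_bridge_cutoff
#'   distances in Angstrom.
#' @param hbond_min_angle degrees.
#' @param his_positive logical.
#' @return List of criteria.
#' @export
interaction_criteria <- function(hydrophobic_cutoff = 4.5,
                                 aromatic_cutoff = 5.0,
                                 hbond_cutoff = 3.5,
                                 hbond_min_angle = 90,
                                 salt_bridge_cutoff = 4.0,
                                 his_positive = TRUE) {
  list(hydrophobic_cutoff = hydrophobic_cutoff,
       aromatic_cutoff = aromatic_cutoff,
       hbond_cutoff = hbond_cutoff, hbond_min_angle = hbond_min_angle,
       salt_bridge_cutoff = salt_bridge_cutoff, his_positive = his_positive)
}

empty_contacts <- function() {
  data.frame(uid_a = character(0), atom_a = character(0),
             uid_b = character(0), atom_b = character(0),
             distance = numeric(0), type = character(0),
             stringsAsFactors = FALSE)
}

#' Detect typed atom-level contacts across the interface
#'
#' Enumerates atom pairs between the immunoglobulin side and the antigen
#' side and types them by the geometric criteria. Aromatic contacts are
#' recorded between ring centroids (one pseudo-contact per ring pair, atom
#' label "RING"). Polar geometries satisfying both the hydrogen-bond and
#' the salt-bridge criteria yield both a `hydrogen_bond` and a
#' `salt_bridge_candidate` row; candidates are resolved to actual salt
#' bridges by [consolidate()].
#'
#' @param complex an `annotated_complex` (hydrogens already stripped).
#' @param criteria see [interaction_criteria()].
#' @return data.frame of contacts: uid_a (immunoglobulin residue,
#'   "chain:resno:icode"), atom_a, uid_b (antigen residue), atom_b,
#'   distance, type.
#' @export
detect_atom_contacts <- function(complex, criteria = interaction_criteria()) {
  sides <- interface_sides(complex)
  A <- sides$ig; B <- sides$antigen
  if (!nrow(A) || !nrow(B)) return(empty_contacts())
  A$uid <- residue_uid(A); B$uid <- residue_uid(B)
  out <- list()

  pair_rows <- function(ia, ib, type, d) {
    data.frame(uid_a = A$uid[ia], atom_a = A$atom[ia],
               uid_b = B$uid[ib], atom_b = B$atom[ib],
               distance = d, type = type, stringsAsFactors = FALSE)
  }
  cross_dist <- function(ia, ib) {
    sqrt((A$x[ia] - B$x[ib])^2 + (A$y[ia] - B$y[ib])^2 + (A$z[ia] - B$z[ib])^2)
  }
  # all cross pairs within the loosest cutoff, as candidate index pairs
  maxcut <- max(criteria$hydrophobic_cutoff, criteria$hbond_cutoff,
                criteria$salt_bridge_cutoff)
  idx <- close_cross_pairs(A, B, maxcut)

  if (nrow(idx)) {
    d <- cross_dist(idx[, 1], idx[, 2])
    # hydrophobic: apolar carbons both sides
    apA <- is_apolar(A); apB <- is_apolar(B)
    sel <- d <= criteria$hydrophobic_cutoff & apA[idx[, 1]] & apB[idx[, 2]]
    if (any(sel)) out[[length(out) + 1]] <-
        pair_rows(idx[sel, 1], idx[sel, 2], "hydrophobic", d[sel])
    # hydrogen bonds, both donor orientations
    hb <- detect_hbonds(A, B, idx, d, criteria)
    if (nrow(hb)) out[[length(out) + 1]] <- hb
    # salt-bridge candidates
    chgA <- charge_tag(A, criteria$his_positive)
    chgB <- charge_tag(B, criteria$his_positive)
    sel <- d <= criteria$salt_bridge_cutoff &
      ((chgA[idx[, 1]] == "+" & chgB[idx[, 2]] == "-") |
         (chgA[idx[, 1]] == "-" & chgB[idx[, 2]] == "+"))
    if (any(sel)) out[[length(out) + 1]] <-
        pair_rows(idx[sel, 1], idx[sel, 2], "salt_bridge_candidate", d[sel])
  }
  # aromatic: ring-centroid distance
  ringsA <- ring_centroids(A); ringsB <- ring_centroids(B)
  if (nrow(ringsA) && nrow(ringsB)) {
    for (i in seq_len(nrow(ringsA))) for (j in seq_len(nrow(ringsB))) {
      d <- sqrt(sum((as.numeric(ringsA[i, c("x", "y", "z")]) -
                       as.numeric(ringsB[j, c("x", "y", "z")]))^2))
      if (d <= criteria$aromatic_cutoff)
        out[[length(out) + 1]] <- data.frame(
          uid_a = ringsA$uid[i], atom_a = "RING",
          uid_b = ringsB$uid[j], atom_b = "RING",
          distance = d, type = "aromatic", stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_contacts())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

close_cross_pairs <- function(A, B, cutoff) {
  # block-wise distance filtering; fine at interface scale
  nA <- nrow(A); nB <- nrow(B)
  ax <- A$x; ay <- A$y; az <- A$z
  keep_i <- integer(0); keep_j <- integer(0)
  for (j in seq_len(nB)) {
    d2 <- (ax - B$x[j])^2 + (ay - B$y[j])^2 + (az - B$z[j])^2
    hit <- which(d2 <= cutoff^2)
    if (length(hit)) { keep_i <- c(keep_i, hit); keep_j <- c(keep_j, rep(j, length(hit))) }
  }
  cbind(keep_i, keep_j)
}

is_apolar <- function(df) {
  mapply(function(rn, at) at %in% (APOLAR_CARBONS[[rn]] %||% character(0)),
         df$resname, df$atom, USE.NAMES = FALSE)
}

charge_tag <- function(df, his_positive) {
  pos <- SB_POSITIVE
  if (!his_positive) pos$HIS <- NULL
  tag <- rep("", nrow(df))
  for (i in seq_len(nrow(df))) {
    rn <- df$resname[i]; at <- df$atom[i]
    if (at %in% (pos[[rn]] %||% character(0))) tag[i] <- "+"
    else if (at %in% (SB_NEGATIVE[[rn]] %||% character(0))) tag[i] <- "-"
  }
  tag
}

ring_centroids <- function(df) {
  out <- list()
  for (uid in unique(df$uid)) {
    sub <- df[df$uid == uid, , drop = FALSE]
    ring <- AROMATIC_RINGS[[sub$resname[1]]]
    if (is.null(ring)) next
    hit <- sub[sub$atom %in% ring, , drop = FALSE]
    if (nrow(hit) >= 3)  # needs enough of the ring to place a centroid
      out[[length(out) + 1]] <- data.frame(
        uid = uid, x = mean(hit$x), y = mean(hit$y), z = mean(hit$z),
        stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(uid = character(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0)))
  do.call(rbind, out)
}

donor_antecedent <- function(df, i) {
  rn <- df$resname[i]; at <- df$atom[i]
  ante <- NULL
  if (at == "N" && rn != "PRO") ante <- "CA"
  else {
    map <- HBOND_DONORS[[rn]]
    if (!is.null(map) && at %in% names(map)) ante <- unname(map[[at]])
  }
  if (is.null(ante)) return(NULL)
  sub <- df[df$uid == df$uid[i] & df$atom == ante, , drop = FALSE]
  if (!nrow(sub)) return(NULL)
  as.numeric(sub[1, c("x", "y", "z")])
}

is_acceptor <- function(df, i) {
  rn <- df$resname[i]; at <- df$atom[i]
  at == "O" || at %in% (HBOND_ACCEPTORS[[rn]] %||% character(0))
}

is_donor <- function(df, i) {
  rn <- df$resname[i]; at <- df$atom[i]
  (at == "N" && rn != "PRO") ||
    (at %in% names(HBOND_DONORS[[rn]] %||% character(0)))
}

detect_hbonds <- function(A, B, idx, d, criteria) {
  rows <- list()
  sel <- which(d <= criteria$hbond_cutoff)
  for (k in sel) {
    ia <- idx[k, 1]; ib <- idx[k, 2]
    ok <- FALSE
    # donor on side A
    if (is_donor(A, ia) && is_acceptor(B, ib)) {
      ante <- donor_antecedent(A, ia)
      ok <- is.null(ante) ||  # antecedent unresolved: accept distance-only
        vec_angle(ante - c(A$x[ia], A$y[ia], A$z[ia]),
                  c(B$x[ib], B$y[ib], B$z[ib]) - c(A$x[ia], A$y[ia], A$z[ia])) >=
        criteria$hbond_min_angle
    }
    if (!ok && is_donor(B, ib) && is_acceptor(A, ia)) {
      ante <- donor_antecedent(B, ib)
      ok <- is.null(ante) ||
        vec_angle(ante - c(B$x[ib], B$y[ib], B$z[ib]),
                  c(A$x[ia], A$y[ia], A$z[ia]) - c(B$x[ib], B$y[ib], B$z[ib])) >=
        criteria$hbond_min_angle
    }
    if (ok) rows[[length(rows) + 1]] <- data.frame(
      uid_a = A$uid[ia], atom_a = A$atom[ia],
      uid_b = B$uid[ib], atom_b = B$atom[ib],
      distance = d[k], type = "hydrogen_bond", stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_contacts())
  do.call(rbind, rows)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Import externally produced atom contacts
#'
#' Reads a TSV with columns chain_a, resno_a, icode_a, atom_a, chain_b,
#' resno_b, icode_b, atom_b, distance, type (types as produced by
#' [detect_atom_contacts()]; `salt_bridge` rows are treated as candidates).
#' Lets users feed contact assignments from an external typing tool through
#' the same consolidation rules.
#'
#' @param path TSV path.
#' @return Contact data.frame as from [detect_atom_contacts()].
#' @export
read_contacts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_a", "resno_a", "icode_a", "atom_a",
            "chain_b", "resno_b", "icode_b", "atom_b", "distance", "type")
  if (!all(need %in% names(tab)))
    stop("contact file must have columns: ", paste(need, collapse = ", "))
  tab$icode_a[tab$icode_a %in% c(".", NA)] <- ""
  tab$icode_b[tab$icode_b %in% c(".", NA)] <- ""
  tab$type[tab$type == "salt_bridge"] <- "salt_bridge_candidate"
  data.frame(uid_a = paste(tab$chain_a, tab$resno_a, tab$icode_a, sep = ":"),
             atom_a = tab$atom_a,
             uid_b = paste(tab$chain_b, tab$resno_b, tab$icode_b, sep = ":"),
             atom_b = tab$atom_b, distance = tab$distance, type = tab$type,
             stringsAsFactors = FALSE)
}

#' Consolidate atom contacts to residue-pair interactions
#'
#' Applies the residue-level consolidation rules: (1) multiple hydrophobic
#' atom contacts between two residues collapse to one hydrophobic
#' interaction; (2) likewise for aromatic contacts; (3) a pair may carry
#' both a hydrophobic and an aromatic interaction; (4) among salt-bridge
#' candidates, each positive/negative charge pairing yields exactly one
#' salt bridge, assigned to the residue pair with the closest atom-atom
#' distance (tie: lexicographically smaller residue pair); the candidate
#' contacts of losing pairs are recorded as hydrogen bonds instead.
#'
#' @param contacts data.frame from [detect_atom_contacts()] or
#'   [read_contacts()].
#' @return Object of class `interaction_profile`: data.frame `pairs` with
#'   columns uid_a, uid_b, type, min_distance (one row per residue pair and
#'   interaction type).
#' @export
consolidate <- function(contacts) {
  if (!nrow(contacts)) {
    return(structure(list(pairs = data.frame(
      uid_a = character(0), uid_b = character(0), type = character(0),
      min_distance = numeric(0), stringsAsFactors = FALSE)),
      class = "interaction_profile"))
  }
  plain <- contacts[contacts$type %in%
                      c("hydrophobic", "aromatic", "hydrogen_bond"), , drop = FALSE]
  cand <- contacts[contacts$type == "salt_bridge_candidate", , drop = FALSE]

  rows <- list()
  if (nrow(plain)) {
    key <- paste(plain$uid_a, plain$uid_b, plain$type, sep = "|")
    agg <- tapply(plain$distance, key, min)
    parts <- strsplit(names(agg), "|", fixed = TRUE)
    rows[[1]] <- data.frame(
      uid_a = vapply(parts, `[`, "", 1), uid_b = vapply(parts, `[`, "", 2),
      type = vapply(parts, `[`, "", 3), min_distance = as.numeric(agg),
      stringsAsFactors = FALSE)
  }
  if (nrow(cand)) {
    # per residue pair: closest candidate atom distance
    key <- paste(cand$uid_a, cand$uid_b, sep = "|")
    agg <- tapply(cand$distance, key, min)
    parts <- strsplit(names(agg), "|", fixed = TRUE)
    pc <- data.frame(uid_a = vapply(parts, `[`, "", 1),
                     uid_b = vapply(parts, `[`, "", 2),
                     min_distance = as.numeric(agg), stringsAsFactors = FALSE)
    # greedy matching: closest residue pair claims both charge groups
    ord <- order(pc$min_distance, pc$uid_a, pc$uid_b)
    used <- character(0)
    pc$sb <- FALSE
    for (k in ord) {
      if (!(pc$uid_a[k] %in% used) && !(pc$uid_b[k] %in% used)) {
        pc$sb[k] <- TRUE
        used <- c(used, pc$uid_a[k], pc$uid_b[k])
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      uid_a = pc$uid_a, uid_b = pc$uid_b,
      type = ifelse(pc$sb, "salt_bridge", "hydrogen_bond"),
      min_distance = pc$min_distance, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  # demoted candidates may duplicate detected hydrogen bonds: keep one
  key <- paste(pairs$uid_a, pairs$uid_b, pairs$type, sep = "|")
  agg <- tapply(pairs$min_distance, key, min)
  parts <- strsplit(names(agg), "|", fixed = TRUE)
  pairs <- data.frame(
    uid_a = vapply(parts, `[`, "", 1), uid_b = vapply(parts, `[`, "", 2),
    type = vapply(parts, `[`, "", 3), min_distance = as.numeric(agg),
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$uid_a, pairs$uid_b, pairs$type), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs), class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("interaction_profile:", nrow(x$pairs), "residue-pair interactions\n")
  print(table(x$pairs$type))
  invisible(x)
}

#' Region-level interaction summary for a pMHC complex
#'
#' Counts, from a consolidated [interaction_profile][consolidate()]:
#' peptide residues with at least one interaction; immunoglobulin residues
#' interacting with the peptide; immunoglobulin-peptide and
#' immunoglobulin-MHC interaction counts; interactions from the VDJ-chain
#' CDR3 loop to MHC residues; the grand total; and the hydrophobic /
#' aromatic / polar balance (polar pools hydrogen bonds and salt bridges).
#' A residue pair carrying both a hydrophobic and an aromatic interaction
#' contributes two to the counts, one per type.
#'
#' @param profile an `interaction_profile`.
#' @param complex the `annotated_complex` the contacts came from.
#' @param regions region map from [assign_regions()]; computed if `NULL`.
#' @return Named list of counts.
#' @export
interaction_summary <- function(profile, complex, regions = NULL) {
  if (is.null(regions)) regions <- assign_regions(complex)
  p <- profile$pairs
  reg_of <- setNames(regions$region, regions$uid)
  loop_of <- setNames(regions$loop, regions$uid)
  role_of <- setNames(regions$role, regions$uid)

  b_region <- unname(reg_of[p$uid_b])
  to_pep <- b_region == "PEPTIDE"
  to_mhc <- !to_pep

  pm <- chain_pairing_map(complex)
  vdj_letter <- ROLE_LETTER[[complex$chain_roles[[pm[["VDJ_CHAIN"]]]]]]
  vdj3 <- paste0("CDR", vdj_letter, "3")
  a_loop <- unname(loop_of[p$uid_a])

  list(
    peptide_residues_contacted = length(unique(p$uid_b[to_pep])),
    ig_residues_contacting_peptide = length(unique(p$uid_a[to_pep])),
    n_ig_peptide_interactions = sum(to_pep),
    n_ig_mhc_interactions = sum(to_mhc),
    n_cdr3_mhc_interactions = sum(to_mhc & a_loop == vdj3),
    n_total_interactions = nrow(p),
    n_hydrophobic = sum(p$type == "hydrophobic"),
    n_aromatic = sum(p$type == "aromatic"),
    n_polar = sum(p$type %in% c("hydrogen_bond", "salt_bridge")))
}
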