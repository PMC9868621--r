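## Post-processing of per-residue binding-energy decomposition tables:
## hotspot calling, regional fractions, CDR energy fractions.

HOTSPOT_CUTOFF <- -7      # kcal/mol, attractive contribution at or beyond
SEMI_HOTSPOT_CUTOFF <- -4 # kcal/mol

#' Build a per-residue energy-decomposition table
#'
#' @param chain,resno,icode,energy parallel vectors; energies in kcal/mol,
#'   negative = attractive.
#' @param side "PMHC" or "IMMUNOGLOBULIN": which binding partner the rows
#'   describe.
#' @param source_id complex identifier.
#' @return data.frame of class `decomp_table` with attributes `side` and
#'   `source_id`; columns chain, resno, icode, energy, uid.
#' @export
decomp_table <- function(chain, resno, icode = "", energy,
                         side = c("PMHC", "IMMUNOGLOBULIN"),
                         source_id = NA_character_) {
  side <- match.arg(side)
  if (any(!is.finite(energy))) stop("non-finite energy value")
  df <- data.frame(chain = as.character(chain), resno = as.integer(resno),
                   icode = as.character(icode), energy = as.numeric(energy),
                   stringsAsFactors = FALSE)
  df$icode[df$icode %in% c(".", NA)] <- ""
  df$uid <- paste(df$chain, df$resno, df$icode, sep = ":")
  attr(df, "side") <- side
  attr(df, "source_id") <- source_id
  class(df) <- c("decomp_table", "data.frame")
  df
}

#' Read an energy-decomposition TSV
#'
#' Expected columns: chain, resnum, icode, energy_kcal_mol (a documented
#' flat export of per-residue decomposition output; "." or empty icode
#' means none).
#'
#' @param path TSV path.
#' @inheritParams decomp_table
#' @return A [decomp_table()].
#' @export
read_decomp <- function(path, side = c("PMHC", "IMMUNOGLOBULIN"),
                        source_id = NA_character_) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "integer", "character", "numeric"))
  need <- c("chain", "resnum", "icode", "energy_kcal_mol")
  if (!all(need %in% names(tab)))
    stop("decomp file must have columns: ", paste(need, collapse = ", "))
  decomp_table(tab$chain, tab$resnum, tab$icode, tab$energy_kcal_mol,
               side = side, source_id = source_id)
}

#' Average an ensemble of decomposition tables
#'
#' Per-frame tables from an ensemble of simulations are averaged per
#' residue before any thresholding, so hotspots are called on ensemble
#' means.
#'
#' @param tables list of [decomp_table()]s over the same residues/side.
#' @return A single averaged `decomp_table`.
#' @export
average_decomp <- function(tables) {
  stopifnot(length(tables) >= 1)
  base <- tables[[1]]
  uids <- base$uid
  for (t in tables[-1]) {
    if (!identical(sort(t$uid), sort(uids)))
      stop("ensemble tables cover different residue sets")
  }
  e <- rowMeans(vapply(tables, function(t) t$energy[match(uids, t$uid)],
                       numeric(length(uids))))
  decomp_table(base$chain, base$resno, base$icode, e,
               side = attr(base, "side"), source_id = attr(base, "source_id"))
}

#' Call energetic hotspots
#'
#' A residue is a HOTSPOT if its decomposed contribution is -7 kcal/mol or
#' stronger (energy <= -7), a SEMI_HOTSPOT if between -4 and -7
#' (-7 < energy <= -4), otherwise NONE. Boundaries are inclusive towards
#' the stronger category.
#'
#' @param table a [decomp_table()].
#' @return data.frame: uid, chain, resno, icode, energy, category.
#' @export
#' @examples
#' t <- decomp_table("P", 1:3, energy = c(-7.5, -5, 2))
#' call_hotspots(t)$category
call_hotspots <- function(table) {
  cat <- ifelse(table$energy <= HOTSPOT_CUTOFF, "HOTSPOT",
                ifelse(table$energy <= SEMI_HOTSPOT_CUTOFF, "SEMI_HOTSPOT",
                       "NONE"))
  data.frame(uid = table$uid, chain = table$chain, resno = table$resno,
             icode = table$icode, energy = table$energy, category = cat,
             stringsAsFactors = FALSE)
}

region_of_uid <- function(regions) setNames(regions$region, regions$uid)

#' Regional fractions of the pMHC binding energy
#'
#' Sums per-residue energies over the peptide, MHC alpha-1 helix and MHC
#' alpha-2 helix regions. A repulsive (positive-sum) region is clipped to
#' zero contribution and flagged; the fractions are the attractive regional
#' magnitudes normalised by their total, so they are in `[0, 1]` and sum
#' to 1.
#'
#' @param table a PMHC-side [decomp_table()].
#' @param regions region map (data.frame with uid, region), e.g. from
#'   [assign_regions()].
#' @return List: `f_peptide`, `f_alpha1`, `f_alpha2`, `regional_sums`
#'   (kcal/mol, unclipped), `clipped` (character vector of clipped
#'   regions).
#' @export
regional_fractions <- function(table, regions) {
  if (!identical(attr(table, "side"), "PMHC"))
    stop("regional_fractions expects a PMHC-side table")
  reg <- region_of_uid(regions)[table$uid]
  if (anyNA(reg))
    stop("residues missing from region map: ",
         paste(head(table$uid[is.na(reg)]), collapse = ", "))
  s <- function(lab) sum(table$energy[reg == lab])
  sums <- c(peptide = s("PEPTIDE"), alpha1 = s("MHC_A1_HELIX"),
            alpha2 = s("MHC_A2_HELIX"))
  attract <- pmax(-sums, 0)   # attractive magnitude; repulsive regions -> 0
  clipped <- names(sums)[sums > 0]
  total <- sum(attract)
  if (total <= 0) stop("regional fractions undefined: no attractive energy ",
                       "in peptide/alpha1/alpha2 regions")
  f <- attract / total
  list(f_peptide = unname(f["peptide"]), f_alpha1 = unname(f["alpha1"]),
       f_alpha2 = unname(f["alpha2"]), regional_sums = sums,
       clipped = clipped)
}

#' Fractional CDR contributions to binding energy
#'
#' Per-loop energy sums divided by the total over all six CDR loops
#' (f_DECOMP). Loops with a repulsive (positive) energy sum would yield a
#' negative fraction and are passed to zero after normalisation, so the
#' reported fractions may sum to slightly less than one.
#'
#' @param table an IMMUNOGLOBULIN-side [decomp_table()].
#' @param regions region map with `uid` and `loop` columns (from
#'   [assign_regions()]).
#' @return List: `fractions` (named by loop, clipped), `raw_fractions`
#'   (unclipped), `loop_sums` (kcal/mol), `clipped` (loops passed to
#'   zero).
#' @export
cdr_energy_fractions <- function(table, regions) {
  if (!identical(attr(table, "side"), "IMMUNOGLOBULIN"))
    stop("cdr_energy_fractions expects an immunoglobulin-side table")
  loop_of <- setNames(regions$loop, regions$uid)
  lp <- loop_of[table$uid]
  loops <- sort(unique(regions$loop[nzchar(regions$loop)]))
  sums <- vapply(loops, function(l)
    sum(table$energy[!is.na(lp) & lp == l]), 0)
  total <- sum(sums)
  if (total >= 0) stop("CDR energy fractions undefined: total CDR energy ",
                       "is not attractive")
  raw <- sums / total
  clipped_frac <- pmax(raw, 0)
  list(fractions = clipped_frac, raw_fractions = raw, loop_sums = sums,
       clipped = loops[raw < 0])
}

#' Hotspot counts by pMHC region
#'
#' Counts HOTSPOT calls in the peptide, MHC alpha-1 helix and MHC alpha-2
#' helix for each supplied pMHC-side table, the "n_peptide/n_alpha1/
#' n_alpha2" summary used to compare complexes.
#'
#' @param tables a [decomp_table()] or list of them (one per complex).
#' @param regions region map (shared, or a list parallel to `tables`).
#' @return data.frame: source_id, n_peptide, n_alpha1, n_alpha2, pattern
#'   ("p/a1/a2").
#' @export
peptide_hotspot_summary <- function(tables, regions) {
  if (inherits(tables, "decomp_table")) tables <- list(tables)
  shared_regions <- !is.null(regions) && is.data.frame(regions)
  out <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    reg <- if (shared_regions) regions else regions[[i]]
    hs <- call_hotspots(t)
    r <- region_of_uid(reg)[hs$uid]
    hot <- hs$category == "HOTSPOT"
    n <- c(sum(hot & r == "PEPTIDE", na.rm = TRUE),
           sum(hot & r == "MHC_A1_HELIX", na.rm = TRUE),
           sum(hot & r == "MHC_A2_HELIX", na.rm = TRUE))
    data.frame(source_id = attr(t, "source_id") %||% NA_character_,
               n_peptide = n[1], n_alpha1 = n[2], n_alpha2 = n[3],
               pattern = paste(n, collapse = "/"), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
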