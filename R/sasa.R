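## Solvent-accessible surface area (Shrake-Rupley) and buried-surface-area
## decomposition of the immunoglobulin:antigen interface.

#' Deterministic quasi-uniform sphere lattice (golden-spiral)
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  cosphi <- 1 - 2 * i / n
  sinphi <- sqrt(pmax(0, 1 - cosphi^2))
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sinphi * cos(theta), sinphi * sin(theta), cosphi)
}

# Cell-grid neighbour list: for every atom, indices of atoms whose expanded
# spheres can intersect its own. Cell size = max expanded diameter, so all
# candidates live in the 27 surrounding cells. Contract (tested): identical
# to the all-pairs computation.
expanded_neighbors <- function(xyz, radii) {
  n <- nrow(xyz)
  if (n <= 1) return(rep(list(integer(0)), n))
  cell <- 2 * max(radii)
  idx <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  key <- idx[, 1] * 73856093 + idx[, 2] * 19349663 + idx[, 3] * 83492791
  buckets <- split(seq_len(n), key)
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = keymap)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- integer(0)
    for (o in seq_len(nrow(offs))) {
      ci <- idx[i, ] + offs[o, ]
      k <- as.character(ci[1] * 73856093 + ci[2] * 19349663 + ci[3] * 83492791)
      if (exists(k, envir = keymap, inherits = FALSE))
        cand <- c(cand, get(k, envir = keymap, inherits = FALSE))
    }
    cand <- cand[cand != i]
    if (length(cand)) {
      d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
        (xyz[cand, 3] - xyz[i, 3])^2
      cand <- cand[d2 < (radii[cand] + radii[i])^2]
    }
    out[[i]] <- cand
  }
  out
}

atom_radii <- function(atoms, radii_table) {
  r <- radii_table[atoms$element]
  if (anyNA(r)) {
    bad <- unique(atoms$element[is.na(r)])
    stop("no van der Waals radius defined for element(s): ",
         paste(bad, collapse = ", "))
  }
  unname(r)
}

#' Per-atom and per-residue SASA by the Shrake-Rupley method
#'
#' Places a deterministic golden-spiral lattice of `n_points` on each atom's
#' expanded sphere (vdW radius + probe radius); a lattice point is accessible
#' iff it lies outside every other atom's expanded sphere. Atom SASA is
#' `4 pi (r + probe)^2` times the accessible fraction; residue SASA sums the
#' atoms of the residue.
#'
#' @param atoms data.frame with columns element, x, y, z and (for residue
#'   aggregation) chain, resno, icode.
#' @param probe_radius probe radius in Angstrom (default 1.4, a water).
#' @param n_points lattice points per atom (>= 60).
#' @param radii_table named vdW radius table; unknown elements are an error.
#' @return List of class `sasa_result`: `atom_sasa` (numeric per input atom,
#'   Angstrom^2), `residue_sasa` (named by "chain:resno:icode"),
#'   `probe_radius`, `n_points`.
#' @export
#' @examples
#' a <- data.frame(chain = "A", resno = 1, icode = "", element = "C",
#'                 x = 0, y = 0, z = 0)
#' shrake_rupley(a)$atom_sasa  # isolated sphere: 4*pi*(1.7+1.4)^2
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960L,
                          radii_table = default_vdw_radii()) {
  stopifnot(n_points >= 60)
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  R <- atom_radii(atoms, radii_table) + probe_radius
  S <- golden_spiral_points(n_points)
  nb <- expanded_neighbors(xyz, R)
  area <- numeric(n)
  for (i in seq_len(n)) {
    js <- nb[[i]]
    if (!length(js)) { area[i] <- 4 * pi * R[i]^2; next }
    pts <- S * R[i]
    pts <- sweep(pts, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    # nearest blockers first: shrinks the live set fastest
    d2 <- (xyz[js, 1] - xyz[i, 1])^2 + (xyz[js, 2] - xyz[i, 2])^2 +
      (xyz[js, 3] - xyz[i, 3])^2
    for (j in js[order(d2)]) {
      if (!any(free)) break
      dd <- (pts[free, 1] - xyz[j, 1])^2 + (pts[free, 2] - xyz[j, 2])^2 +
        (pts[free, 3] - xyz[j, 3])^2
      free[free] <- dd >= R[j]^2
    }
    area[i] <- 4 * pi * R[i]^2 * sum(free) / n_points
  }
  res <- NULL
  if (all(c("chain", "resno", "icode") %in% names(atoms))) {
    uid <- residue_uid(atoms)
    res <- tapply(area, factor(uid, levels = unique(uid)), sum)
    res <- setNames(as.numeric(res), names(res))
  }
  structure(list(atom_sasa = area, residue_sasa = res,
                 probe_radius = probe_radius, n_points = as.integer(n_points)),
            class = "sasa_result")
}

## ---- burial profile --------------------------------------------------------

#' Buried-surface-area profile of a complex
#'
#' Computes per-residue SASA in the complex and in artificial apo states
#' (each binding partner with the other's coordinates deleted). The
#' per-residue difference (apo minus complex) is the buried surface area
#' (BSA); a residue is buried upon binding iff its SASA decreased by more
#' than `config$burial_epsilon`. Aggregates: total interface BSA and its
#' immunoglobulin / antigen / peptide / MHC components, fractional CDR-loop
#' contributions to immunoglobulin BSA, the VDJ-chain CDR3 share of the
#' CDR3-pair BSA, the peptide share of pMHC BSA, and the number of buried
#' peptide residues.
#'
#' @param complex an `annotated_complex` containing both binding partners.
#' @param regions region map from [assign_regions()]; computed if `NULL`.
#' @param config see [profiler_config()].
#' @return Object of class `burial_profile`: `per_residue` data.frame
#'   (residue table + sasa_complex, sasa_apo, delta, buried), `totals`
#'   (interface_bsa, immunoglobulin_bsa, antigen_bsa, peptide_bsa, mhc_bsa),
#'   `cdr_fractions` (named, of immunoglobulin BSA), `cdr3_pair_fraction`
#'   (VDJ CDR3 / (CDR3 pair)), `peptide_fraction`,
#'   `buried_peptide_residue_count`.
#' @export
burial_profile <- function(complex, regions = NULL,
                           config = profiler_config()) {
  sides <- interface_sides(complex)
  if (!nrow(sides$ig) || !nrow(sides$antigen))
    stop("burial_profile requires both binding partners")
  if (is.null(regions)) regions <- assign_regions(complex, config)

  sr <- function(a) shrake_rupley(a, probe_radius = config$probe_radius,
                                  n_points = config$n_sphere_points,
                                  radii_table = config$vdw_radii)
  holo <- sr(complex$atoms)
  apo_ig <- sr(sides$ig)
  apo_ag <- sr(sides$antigen)

  res <- regions
  holo_res <- holo$residue_sasa[res$uid]
  apo_res <- c(apo_ig$residue_sasa, apo_ag$residue_sasa)[res$uid]
  res$sasa_complex <- unname(holo_res)
  res$sasa_apo <- unname(apo_res)
  res$delta <- res$sasa_apo - res$sasa_complex
  res$buried <- res$delta > config$burial_epsilon

  is_ig <- res$role %in% IG_ROLES
  ig_bsa <- sum(res$delta[is_ig])
  ag_bsa <- sum(res$delta[!is_ig])
  pep_bsa <- sum(res$delta[res$role == "PEPTIDE"])
  mhc_bsa <- sum(res$delta[!is_ig & res$role != "PEPTIDE"])

  loops <- sort(unique(res$loop[nzchar(res$loop)]))
  cdr_fr <- setNames(rep(NA_real_, length(loops)), loops)
  if (ig_bsa > 0) {
    for (lp in loops) cdr_fr[lp] <- sum(res$delta[res$loop == lp]) / ig_bsa
  }
  pm <- chain_pairing_map(complex)
  vdj_letter <- ROLE_LETTER[[complex$chain_roles[[pm[["VDJ_CHAIN"]]]]]]
  vj_letter <- ROLE_LETTER[[complex$chain_roles[[pm[["VJ_CHAIN"]]]]]]
  cdr3_vdj <- sum(res$delta[res$loop == paste0("CDR", vdj_letter, "3")])
  cdr3_vj <- sum(res$delta[res$loop == paste0("CDR", vj_letter, "3")])
  cdr3_pair_fraction <- if ((cdr3_vdj + cdr3_vj) > 0)
    cdr3_vdj / (cdr3_vdj + cdr3_vj) else NA_real_

  peptide_fraction <- if ((pep_bsa + mhc_bsa) > 0)
    pep_bsa / (pep_bsa + mhc_bsa) else NA_real_

  structure(list(
    complex_id = complex$complex_id,
    per_residue = res,
    totals = list(interface_bsa = ig_bsa + ag_bsa,
                  immunoglobulin_bsa = ig_bsa, antigen_bsa = ag_bsa,
                  peptide_bsa = pep_bsa, mhc_bsa = mhc_bsa),
    cdr_fractions = cdr_fr,
    cdr3_pair_fraction = cdr3_pair_fraction,
    peptide_fraction = peptide_fraction,
    buried_peptide_residue_count =
      sum(res$buried[res$role == "PEPTIDE"])),
    class = "burial_profile")
}

#' Fractional BSA contribution of one CDR loop
#'
#' With `denominator = "immunoglobulin"` the loop's summed per-residue BSA is
#' divided by the whole immunoglobulin-side BSA; with `"cdr3_pair"` it is
#' divided by the summed BSA of the two CDR3 loops (the VDJ-vs-VJ CDR3
#' balance).
#'
#' @param profile a `burial_profile`.
#' @param loop loop identifier such as "CDRH3", "CDRA2".
#' @param denominator "immunoglobulin" or "cdr3_pair".
#' @return Fraction in `[0, 1]`, or `NA` (with a warning) when the
#'   denominator is zero.
#' @export
cdr_fraction <- function(profile, loop,
                         denominator = c("immunoglobulin", "cdr3_pair")) {
  denominator <- match.arg(denominator)
  res <- profile$per_residue
  num <- sum(res$delta[res$loop == loop])
  den <- if (denominator == "immunoglobulin") {
    profile$totals$immunoglobulin_bsa
  } else {
    sum(res$delta[grepl("^CDR[A-Z]3$", res$loop)])
  }
  if (!is.finite(den) || den <= 0) {
    warning("cdr_fraction undefined: zero ", denominator, " BSA")
    return(NA_real_)
  }
  num / den
}

#' @export
print.burial_profile <- function(x, ...) {
  t <- x$totals
  cat(sprintf("burial_profile '%s': interface %.1f A^2 (ig %.1f, antigen %.1f)\n",
              x$complex_id, t$interface_bsa, t$immunoglobulin_bsa, t$antigen_bsa))
  if (t$peptide_bsa + t$mhc_bsa > 0)
    cat(sprintf("  peptide fraction of pMHC BSA %.3f; %d peptide residue(s) buried\n",
                x$peptide_fraction, x$buried_peptide_residue_count))
  invisible(x)
}
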