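## Binding-geometry metrics: groove frame, docking/crossing angle, polarity,
## diagonality, and the arginine guanidino-plane tilt.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate-geometry error: zero-length vector")
  v / n
}

# Cα coordinate of the residue with a given renumbered/IMGT number on `chain`
ca_of_number <- function(complex, chain, number) {
  num <- complex$numbering
  hit <- num[num$chain == chain & num$number == number, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  a <- complex$atoms
  sel <- a[a$chain == chain & a$resno == hit$resno[1] &
             a$icode == hit$icode[1] & a$atom == "CA", , drop = FALSE]
  if (!nrow(sel)) return(NULL)
  as.numeric(sel[1, c("x", "y", "z")])
}

helix_window_ca <- function(complex, which = c("alpha1", "alpha2"),
                            config = profiler_config()) {
  which <- match.arg(which)
  win <- config$mhc_helix_windows[[which]]
  chain_role <- if (which == "alpha2" && identical(complex$mhc_class, "II"))
    "MHC_BETA" else "MHC_ALPHA"
  chain <- names(complex$chain_roles)[complex$chain_roles == chain_role][1]
  if (is.na(chain)) stop("degenerate-geometry error: no ", chain_role, " chain")
  num <- complex$numbering
  rows <- num[num$chain == chain & num$number >= win[1] & num$number <= win[2], ,
              drop = FALSE]
  rows <- rows[order(rows$number), , drop = FALSE]
  a <- complex$atoms
  key <- paste(a$chain, a$resno, a$icode, a$atom, sep = ":")
  xyz <- t(vapply(seq_len(nrow(rows)), function(i) {
    j <- match(paste(chain, rows$resno[i], rows$icode[i], "CA", sep = ":"), key)
    if (is.na(j)) rep(NA_real_, 3) else c(a$x[j], a$y[j], a$z[j])
  }, numeric(3)))
  xyz[stats::complete.cases(xyz), , drop = FALSE]
}

peptide_ca <- function(complex) {
  chain <- names(complex$chain_roles)[complex$chain_roles == "PEPTIDE"][1]
  if (is.na(chain)) stop("degenerate-geometry error: no PEPTIDE chain")
  a <- complex$atoms
  sel <- a[a$chain == chain & a$atom == "CA", , drop = FALSE]
  as.matrix(sel[, c("x", "y", "z")])
}

#' Reference frame of the peptide-binding groove
#'
#' `helix_axis` mode takes the groove axis as the principal axis of the
#' combined Cα atoms of the two configured helix windows; `anchor_ca` mode
#' takes the vector through the Cα atoms of the first and last peptide
#' anchor residues (defaults: position 2 and the C-terminal residue, the
#' class-I anchor convention). The axis is oriented N-to-C along the
#' peptide. The groove-platform plane normal is the best-fit plane through
#' the helix-window Cα atoms (both helices by default: a single straight
#' helix constrains its own plane poorly).
#'
#' @param complex an `annotated_complex` with MHC chains.
#' @param mode "helix_axis" or "anchor_ca".
#' @param anchors peptide anchor positions (indices along the peptide) for
#'   `anchor_ca` mode; `NULL` means `c(2, n_peptide)`.
#' @param plane_window "both_helices" or "alpha1".
#' @param config see [profiler_config()].
#' @return Object of class `groove_frame`: `axis`, `origin`,
#'   `helix_plane_normal` (unit vectors / 3-vector origin).
#' @export
groove_frame <- function(complex, mode = c("helix_axis", "anchor_ca"),
                         anchors = NULL,
                         plane_window = c("both_helices", "alpha1"),
                         config = profiler_config()) {
  mode <- match.arg(mode)
  plane_window <- match.arg(plane_window)
  h1 <- helix_window_ca(complex, "alpha1", config)
  h2 <- helix_window_ca(complex, "alpha2", config)
  if (nrow(h1) + nrow(h2) < 4)
    stop("degenerate-geometry error: fewer than 4 helix reference atoms")
  pep <- peptide_ca(complex)
  pep_dir <- unit(pep[nrow(pep), ] - pep[1, ])

  if (mode == "helix_axis") {
    pts <- rbind(h1, h2)
    pc <- prcomp(pts, center = TRUE)
    axis <- unit(pc$rotation[, 1])
  } else {
    if (is.null(anchors)) anchors <- c(2L, nrow(pep))
    if (any(anchors < 1 | anchors > nrow(pep)))
      stop("degenerate-geometry error: anchor index outside peptide")
    axis <- unit(pep[anchors[2], ] - pep[anchors[1], ])
  }
  if (sum(axis * pep_dir) < 0) axis <- -axis

  plane_pts <- if (plane_window == "alpha1") h1 else rbind(h1, h2)
  ctr <- colMeans(plane_pts)
  sv <- svd(sweep(plane_pts, 2, ctr))
  normal <- unit(sv$v[, 3])

  structure(list(axis = axis, origin = ctr, helix_plane_normal = normal),
            class = "groove_frame")
}

# Disulfide midpoint of a variable domain: midpoint of the Cα atoms of the
# conserved IMGT-23 and IMGT-104 cysteines (configurable anchor numbers).
domain_centre <- function(complex, chain, anchor_numbers = c(23L, 104L)) {
  pts <- lapply(anchor_numbers, function(n) ca_of_number(complex, chain, n))
  missing <- anchor_numbers[vapply(pts, is.null, TRUE)]
  if (length(missing))
    stop("missing reference residue(s) on chain ", chain, ": IMGT ",
         paste(missing, collapse = ", "))
  colMeans(do.call(rbind, pts))
}

project_onto_plane <- function(v, normal) v - sum(v * normal) * normal

#' Docking/crossing angle of an immunoglobulin over the groove
#'
#' The angle between the line connecting the conserved centres of the two
#' variable domains (each taken as the midpoint of the Cα atoms of the
#' IMGT-23/IMGT-104 conserved cysteines) and the groove axis, measured
#' after projecting both onto the groove-platform plane. The inter-domain
#' vector points from the VJ-chain centre to the VDJ-chain centre, so
#' canonically docked TCRs fall near 45 degrees and reverse-polarity
#' binders near 135; swapping the chain labels maps an angle t to 180 - t.
#'
#' @param complex an `annotated_complex`.
#' @param frame a [groove_frame()].
#' @param anchor_numbers conserved IMGT anchors defining domain centres.
#' @return Angle in degrees, in `[0, 180)`.
#' @export
docking_angle <- function(complex, frame, anchor_numbers = c(23L, 104L)) {
  pm <- chain_pairing_map(complex)
  c_vdj <- domain_centre(complex, pm[["VDJ_CHAIN"]], anchor_numbers)
  c_vj <- domain_centre(complex, pm[["VJ_CHAIN"]], anchor_numbers)
  v <- project_onto_plane(c_vdj - c_vj, frame$helix_plane_normal)
  ax <- project_onto_plane(frame$axis, frame$helix_plane_normal)
  ang <- vec_angle(unit(v), unit(ax))
  if (ang >= 180) ang <- ang - 180
  ang
}

#' Classify binding polarity over the MHC helices
#'
#' Canonical polarity places the VDJ-chain (heavy/beta) domain over the
#' C-terminal half of the MHC alpha-1 helix and the VJ-chain (light/alpha)
#' domain over the C-terminal half of the alpha-2 helix; the reverse
#' assignment is REVERSE. Decided by which assignment of the two domain
#' centres to the two helix C-terminal-half centroids gives the smaller
#' total distance, so relabelling the chains flips the call.
#'
#' @inheritParams docking_angle
#' @param config see [profiler_config()].
#' @return "CANONICAL" or "REVERSE".
#' @export
classify_polarity <- function(complex, frame, anchor_numbers = c(23L, 104L),
                              config = profiler_config()) {
  pm <- chain_pairing_map(complex)
  c_vdj <- domain_centre(complex, pm[["VDJ_CHAIN"]], anchor_numbers)
  c_vj <- domain_centre(complex, pm[["VJ_CHAIN"]], anchor_numbers)
  h1 <- helix_window_ca(complex, "alpha1", config)
  h2 <- helix_window_ca(complex, "alpha2", config)
  cterm_half <- function(h) colMeans(h[seq(ceiling(nrow(h) / 2) + 1, nrow(h)), ,
                                       drop = FALSE])
  t1 <- cterm_half(h1); t2 <- cterm_half(h2)
  d <- function(p, q) sqrt(sum((p - q)^2))
  canonical_cost <- d(c_vdj, t1) + d(c_vj, t2)
  reverse_cost <- d(c_vdj, t2) + d(c_vj, t1)
  if (canonical_cost <= reverse_cost) "CANONICAL" else "REVERSE"
}

#' Fold a docking angle to absolute diagonality
#'
#' Canonical and reverse polarity binders with the same degree of
#' diagonality sit at t and 180 - t; pooling them uses `min(t, 180 - t)`.
#'
#' @param angle degrees in `[0, 180)`.
#' @return Folded angle in `[0, 90]`.
#' @export
fold_angle <- function(angle) pmin(angle, 180 - angle)

#' Is a docking angle diagonal by a reference cohort's standards?
#'
#' TRUE iff the absolute (folded) docking angle lies within the inclusive
#' range of absolute docking angles observed in a reference cohort
#' (typically TCRs).
#'
#' @param angle query docking angle, degrees.
#' @param tcr_reference_angles numeric vector of cohort docking angles, or
#'   a length-2 `c(min, max)` range of already-folded angles.
#' @return Logical.
#' @export
classify_diagonal <- function(angle, tcr_reference_angles) {
  if (!length(tcr_reference_angles))
    stop("empty reference cohort")
  folded <- fold_angle(tcr_reference_angles)
  rng <- range(folded)
  q <- fold_angle(angle)
  q >= rng[1] & q <= rng[2]
}

#' Tilt of an arginine guanidino plane against the groove platform
#'
#' Best-fit plane through the NE, CZ, NH1, NH2 atoms of the arginine versus
#' the groove-platform plane of the frame; the angle between the two plane
#' normals is folded to `[0, 90]` (0 = guanidino group lying in the helix
#' plane, 90 = fully protruding).
#'
#' @param complex an `annotated_complex`.
#' @param residue_uid residue identifier "chain:resno:icode" of an arginine.
#' @param frame a [groove_frame()].
#' @return Tilt in degrees, `[0, 90]`.
#' @export
guanidino_tilt <- function(complex, residue_uid, frame) {
  a <- complex$atoms
  uid <- paste(a$chain, a$resno, a$icode, sep = ":")
  sub <- a[uid == residue_uid, , drop = FALSE]
  if (!nrow(sub) || sub$resname[1] != "ARG")
    stop("guanidino_tilt requires an arginine residue")
  need <- c("NE", "CZ", "NH1", "NH2")
  hit <- sub[sub$atom %in% need, , drop = FALSE]
  if (nrow(hit) < 4)
    stop("missing guanidino atom(s): ",
         paste(setdiff(need, hit$atom), collapse = ", "))
  pts <- as.matrix(hit[, c("x", "y", "z")])
  sv <- svd(sweep(pts, 2, colMeans(pts)))
  normal <- unit(sv$v[, 3])
  ang <- vec_angle(normal, frame$helix_plane_normal)
  if (ang > 90) ang <- 180 - ang
  ang
}

#' Full geometry report for one complex
#'
#' @param complex an `annotated_complex`.
#' @param mode groove-axis mode, see [groove_frame()].
#' @param tcr_reference_angles optional cohort for the diagonality call.
#' @param config see [profiler_config()].
#' @return Object of class `geometry_report`: `docking_angle`, `polarity`,
#'   `diagonal` (NA without a reference cohort), `frame`.
#' @export
#' @examples
#' fx <- make_groove_complex(groove_fixture_spec(docking_angle = 45))
#' geometry_report(fx$complex)$docking_angle
geometry_report <- function(complex, mode = "helix_axis",
                            tcr_reference_angles = NULL,
                            config = profiler_config()) {
  frame <- groove_frame(complex, mode = mode, config = config)
  ang <- docking_angle(complex, frame)
  pol <- classify_polarity(complex, frame, config = config)
  diag <- if (is.null(tcr_reference_angles)) NA
  else classify_diagonal(ang, tcr_reference_angles)
  structure(list(docking_angle = ang, polarity = pol, diagonal = diag,
                 frame = frame),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("geometry_report: docking angle %.1f deg, %s polarity",
              x$docking_angle, tolower(x$polarity)))
  if (!is.na(x$diagonal))
    cat(",", if (x$diagonal) "diagonal" else "non-diagonal")
  cat("\n")
  invisible(x)
}
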