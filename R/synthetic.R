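## Deterministic synthetic fixtures: idealised MHC-groove complexes,
## planted-cluster sequence sets, and energy-decomposition tables with
## planted hotspots. All generators are pure functions of (spec, seed),
## using a pinned internal PRNG (xorshift + Box-Muller) so outputs are
## byte-stable across platforms and never touch R's global RNG state.

prng_new <- function(seed) {
  state <- as.integer(seed)
  if (is.na(state) || state == 0L) state <- 88172645L
  env <- new.env(parent = emptyenv())
  env$s <- state
  env
}

prng_next <- function(g) {
  # 32-bit xorshift in double arithmetic (exact below 2^53)
  x <- g$s
  x <- bitwXor(x, bitwAnd(bitwShiftL(x, 13L), -1L))
  x <- bitwXor(x, bitwShiftR(x, 17L))
  x <- bitwXor(x, bitwAnd(bitwShiftL(x, 5L), -1L))
  g$s <- x
  (x + 2^31) / 2^32   # uniform in [0, 1)
}

prng_unif <- function(g, n = 1) vapply(seq_len(n), function(i) prng_next(g), 0)

prng_norm <- function(g, n = 1, mean = 0, sd = 1) {
  vapply(seq_len(n), function(i) {
    u1 <- max(prng_next(g), 1e-12); u2 <- prng_next(g)
    mean + sd * sqrt(-2 * log(u1)) * cos(2 * pi * u2)
  }, 0)
}

prng_int <- function(g, n, max) pmin(max, 1L + as.integer(floor(prng_unif(g, n) * max)))

## ---- groove complex fixture ------------------------------------------------

#' Specification of an idealised groove-complex fixture
#'
#' Describes a synthetic pMHC-like scaffold (two idealised poly-Ala
#' alpha-helices flanking an extended peptide) plus a two-domain binder
#' whose variable-domain anchor geometry realises a requested docking
#' angle, and whose CDR3 pseudo-atoms occlude exactly the requested
#' peptide positions. Fixtures are C-alpha/pseudo-atom resolution: they
#' exercise the geometric code paths, not energetics.
#'
#' @param peptide_length 8 to 15 residues.
#' @param helix_rise rise per residue along the groove axis (Angstrom).
#' @param groove_width distance between the two helix axes (Angstrom).
#' @param docking_angle requested docking angle, degrees in `[0, 180)`
#'   (implies polarity: below 90 canonical, above 90 reverse).
#' @param polarity optional "CANONICAL"/"REVERSE"; must agree with the
#'   angle-implied polarity, else the pose is unsatisfiable.
#' @param elevation height of the binder domain centres above the groove
#'   plane (Angstrom).
#' @param occluded_positions peptide positions (1-based) the binder must
#'   bury; all others stay unburied by construction.
#' @param binder_class "TCRM", "ANTIBODY" or "TCR" (sets chain ids/roles).
#' @param seed integer, fixes the pseudo-atom jitter bit-exactly.
#' @return List of class `groove_fixture_spec`.
#' @export
groove_fixture_spec <- function(peptide_length = 9L, helix_rise = 1.5,
                                groove_width = 18, docking_angle = 45,
                                polarity = NULL, elevation = 12,
                                occluded_positions = integer(0),
                                binder_class = "TCRM", seed = 1L) {
  stopifnot(peptide_length >= 8, peptide_length <= 15,
            docking_angle >= 0, docking_angle < 180)
  implied <- if (docking_angle < 90) "CANONICAL" else "REVERSE"
  if (is.null(polarity)) polarity <- implied
  if (!identical(polarity, implied))
    stop("unsatisfiable pose: docking angle ", docking_angle,
         " implies ", implied, " polarity in this scaffold")
  if (length(occluded_positions) &&
      (min(occluded_positions) < 1 || max(occluded_positions) > peptide_length))
    stop("unsatisfiable occlusion request: positions outside the peptide")
  structure(list(peptide_length = as.integer(peptide_length),
                 helix_rise = helix_rise, groove_width = groove_width,
                 docking_angle = docking_angle, polarity = polarity,
                 elevation = elevation,
                 occluded_positions = sort(unique(as.integer(occluded_positions))),
                 binder_class = toupper(binder_class), seed = as.integer(seed)),
            class = "groove_fixture_spec")
}

ideal_helix <- function(resnos, rise, y0, reverse = FALSE) {
  k <- seq_along(resnos) - 1
  x <- (k - (length(k) - 1) / 2) * rise
  if (reverse) x <- -x         # N-to-C along -x: antiparallel second helix
  ang <- k * 100 * pi / 180
  data.frame(resno = resnos, x = x, y = y0 + 2.3 * cos(ang),
             z = 2.3 * sin(ang))
}

#' Generate an idealised groove-complex fixture
#'
#' Builds the scaffold described by a [groove_fixture_spec()]: MHC chain
#' "M" carrying both helices (renumbered 50-86 and 138-176, the second
#' running antiparallel), peptide chain "P" extended along the groove
#' axis, and a two-domain binder whose conserved-cysteine anchors realise
#' the requested docking angle and polarity, with CDR3 pseudo-residues
#' placed 5.2 Angstrom above each requested peptide position (close enough
#' to occlude it, far enough not to touch its neighbours). Occluded
#' positions are therefore recovered exactly by the burial stage, and the
#' construction angle by the geometry stage.
#'
#' @param spec a [groove_fixture_spec()].
#' @param dir optional directory; when given, writes `<id>.pdb` and
#'   `<id>.tsv` (sidecar) there.
#' @return List: `complex` (an `annotated_complex`), `annotation`, and
#'   when `dir` is given `pdb_file`, `annotation_file`.
#' @export
#' @examples
#' fx <- make_groove_complex(groove_fixture_spec(occluded_positions = c(2, 4, 6)))
#' fx$complex
make_groove_complex <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "groove_fixture_spec"))
  g <- prng_new(spec$seed)
  w2 <- spec$groove_width / 2

  h1 <- ideal_helix(50:86, spec$helix_rise, y0 = +w2)
  h2 <- ideal_helix(138:176, spec$helix_rise, y0 = -w2, reverse = TRUE)
  mhc <- rbind(h1, h2)
  mhc_atoms <- data.frame(chain = "M", resno = mhc$resno, icode = "",
                          resname = "ALA", atom = "CA", element = "C",
                          x = mhc$x, y = mhc$y, z = mhc$z,
                          stringsAsFactors = FALSE)

  np <- spec$peptide_length
  px <- (seq_len(np) - (np + 1) / 2) * 3.8
  pep_atoms <- data.frame(chain = "P", resno = seq_len(np), icode = "",
                          resname = "GLY", atom = "CA", element = "C",
                          x = px, y = 0, z = 0, stringsAsFactors = FALSE)

  chains <- switch(spec$binder_class,
                   TCR = c(vdj = "B", vj = "A"), c(vdj = "H", vj = "L"))
  vdj_role <- if (spec$binder_class == "TCR") "TCR_BETA" else "HEAVY"
  vj_role <- if (spec$binder_class == "TCR") "TCR_ALPHA" else "LIGHT"

  th <- spec$docking_angle * pi / 180
  # canonical poses run VJ -> VDJ towards the alpha1 (y > 0) helix; reverse
  # poses mirror across the groove axis so the VDJ domain sits over alpha2.
  # The unsigned in-plane angle to the axis is the requested angle either way.
  v <- c(cos(th), if (spec$polarity == "CANONICAL") sin(th) else -sin(th), 0)
  sep <- 20
  centre <- c(0, 0, spec$elevation)
  c_vdj <- centre + v * sep / 2
  c_vj <- centre - v * sep / 2

  domain_atoms <- function(chain_id, ctr) {
    # conserved-cysteine anchors symmetric about the centre (midpoint exact)
    anchors <- data.frame(chain = chain_id, resno = c(23L, 104L), icode = "",
                          resname = "CYS", atom = "CA", element = "C",
                          x = ctr[1], y = ctr[2], z = ctr[3] + c(2.5, -2.5),
                          stringsAsFactors = FALSE)
    # framework bulk with seeded jitter (never used as a reference point)
    nb <- 6L
    jit <- matrix(prng_unif(g, 3 * nb) * 2 - 1, ncol = 3)
    bulk <- data.frame(chain = chain_id, resno = 39L + seq_len(nb), icode = "",
                       resname = "ALA", atom = "CA", element = "C",
                       x = ctr[1] + jit[, 1], y = ctr[2] + jit[, 2],
                       z = ctr[3] + 2 + jit[, 3], stringsAsFactors = FALSE)
    rbind(anchors, bulk)
  }
  vdj_atoms <- domain_atoms(chains[["vdj"]], c_vdj)
  vj_atoms <- domain_atoms(chains[["vj"]], c_vj)

  occ <- spec$occluded_positions
  if (length(occ)) {
    occ_atoms <- data.frame(chain = chains[["vdj"]], resno = 106L + seq_along(occ),
                            icode = "", resname = "GLY", atom = "CA",
                            element = "C", x = px[occ], y = 0, z = 5.2,
                            stringsAsFactors = FALSE)
    vdj_atoms <- rbind(vdj_atoms, occ_atoms)
  }

  atoms <- rbind(vdj_atoms, vj_atoms, mhc_atoms, pep_atoms)
  roles <- setNames(c(vdj_role, vj_role, "MHC_ALPHA", "PEPTIDE"),
                    c(chains[["vdj"]], chains[["vj"]], "M", "P"))
  ig_num <- rbind(
    data.frame(chain = chains[["vdj"]], resno = vdj_atoms$resno, icode = "",
               number = vdj_atoms$resno, stringsAsFactors = FALSE),
    data.frame(chain = chains[["vj"]], resno = vj_atoms$resno, icode = "",
               number = vj_atoms$resno, stringsAsFactors = FALSE),
    data.frame(chain = "M", resno = mhc_atoms$resno, icode = "",
               number = mhc_atoms$resno, stringsAsFactors = FALSE))
  cid <- sprintf("groove_a%03d_%s_s%d", round(spec$docking_angle),
                 tolower(spec$polarity), spec$seed)
  annotation <- list(complex_id = cid,
                     ig_class = spec$binder_class, mhc_class = "I",
                     chain_roles = roles, numbering = ig_num)
  x <- structure(list(complex_id = cid, atoms = atoms, chain_roles = roles,
                      numbering = ig_num, ig_class = spec$binder_class,
                      mhc_class = "I"),
                 class = "annotated_complex")
  validate_complex(x)
  out <- list(complex = x, annotation = annotation, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pdb_file <- file.path(dir, paste0(cid, ".pdb"))
    write_complex_pdb(x, pdb_file)
    ann_file <- file.path(dir, paste0(cid, ".tsv"))
    write_annotation(annotation, ann_file)
    out$pdb_file <- pdb_file
    out$annotation_file <- ann_file
  }
  out
}

#' Write an annotated complex to a PDB file
#'
#' @param complex an `annotated_complex`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  a <- complex$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(a)), resno = a$resno,
                   resid = a$resname, eleno = seq_len(nrow(a)),
                   elety = a$atom, chain = a$chain,
                   insert = ifelse(nzchar(a$icode), a$icode, NA),
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = a$element)
  invisible(path)
}

#' Apply a rigid-body transform to a complex
#'
#' Utility for invariance testing: rotates by `rotation` and then
#' translates by `translation`.
#'
#' @param complex an `annotated_complex`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return The transformed `annotated_complex`.
#' @export
transform_complex <- function(complex, rotation = diag(3),
                              translation = c(0, 0, 0)) {
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  complex$atoms$x <- xyz[, 1]; complex$atoms$y <- xyz[, 2]
  complex$atoms$z <- xyz[, 3]
  complex
}

## ---- decomposition fixture -------------------------------------------------

#' Specification of a planted-hotspot decomposition fixture
#'
#' @param peptide_length peptide residues.
#' @param hotspot_positions list with optional elements `peptide`,
#'   `alpha1`, `alpha2`: residue numbers to plant hotspots at (peptide
#'   1-based; helices in renumbered coordinates 50-86 / 138-176).
#' @param hotspot_energy kcal/mol, must be <= -7.
#' @param background_mean,background_sd background energy distribution
#'   (kcal/mol), truncated above zero.
#' @param seed integer.
#' @return List of class `decomp_fixture_spec`.
#' @export
decomp_fixture_spec <- function(peptide_length = 9L,
                                hotspot_positions = list(),
                                hotspot_energy = -8,
                                background_mean = -1, background_sd = 0.5,
                                seed = 1L) {
  if (length(hotspot_positions) &&
      !all(names(hotspot_positions) %in% c("peptide", "alpha1", "alpha2")))
    stop("hotspot_positions regions must be peptide/alpha1/alpha2")
  if (length(hotspot_positions) && hotspot_energy > HOTSPOT_CUTOFF)
    stop("hotspot_energy must be <= ", HOTSPOT_CUTOFF, " kcal/mol")
  structure(list(peptide_length = as.integer(peptide_length),
                 hotspot_positions = hotspot_positions,
                 hotspot_energy = hotspot_energy,
                 background_mean = background_mean,
                 background_sd = background_sd, seed = as.integer(seed)),
            class = "decomp_fixture_spec")
}

#' Generate a pMHC decomposition table with planted hotspots
#'
#' Residues: peptide chain "P" (1..n), MHC chain "M" helices 50-86 and
#' 138-176. Background energies are drawn from the truncated-above-zero
#' Gaussian of the spec; planted positions receive `hotspot_energy`
#' exactly. Deterministic given the seed.
#'
#' @param spec a [decomp_fixture_spec()].
#' @return List: `table` (PMHC [decomp_table()]), `regions` (region map
#'   data.frame with uid, region, loop).
#' @export
#' @examples
#' fx <- make_decomp_table(decomp_fixture_spec(
#'   hotspot_positions = list(alpha1 = 65)))
#' peptide_hotspot_summary(fx$table, fx$regions)$pattern
make_decomp_table <- function(spec) {
  stopifnot(inherits(spec, "decomp_fixture_spec"))
  g <- prng_new(spec$seed)
  res <- rbind(
    data.frame(chain = "P", resno = seq_len(spec$peptide_length),
               region = "PEPTIDE", stringsAsFactors = FALSE),
    data.frame(chain = "M", resno = 50:86, region = "MHC_A1_HELIX",
               stringsAsFactors = FALSE),
    data.frame(chain = "M", resno = 138:176, region = "MHC_A2_HELIX",
               stringsAsFactors = FALSE))
  draw_bg <- function() {
    repeat {
      e <- prng_norm(g, 1, spec$background_mean, spec$background_sd)
      if (e <= 0) return(e)
    }
  }
  energy <- vapply(seq_len(nrow(res)), function(i) draw_bg(), 0)
  plant <- spec$hotspot_positions
  region_key <- c(peptide = "PEPTIDE", alpha1 = "MHC_A1_HELIX",
                  alpha2 = "MHC_A2_HELIX")
  for (rg in names(plant)) {
    sel <- res$region == region_key[[rg]] & res$resno %in% plant[[rg]]
    if (sum(sel) != length(plant[[rg]]))
      stop("hotspot position(s) outside region '", rg, "'")
    energy[sel] <- spec$hotspot_energy
  }
  tab <- decomp_table(res$chain, res$resno, "", energy, side = "PMHC",
                      source_id = sprintf("decomp_s%d", spec$seed))
  regions <- data.frame(uid = paste(res$chain, res$resno, "", sep = ":"),
                        region = res$region, loop = "",
                        stringsAsFactors = FALSE)
  list(table = tab, regions = regions, spec = spec)
}

## ---- planted-cluster sequence sets ----------------------------------------

#' Generate a sequence set with planted cluster structure
#'
#' Builds `n_clusters` cluster-base sequences by mutating a common random
#' ancestor so that between-cluster identity lands near
#' `between_identity`, then mutates each base at an exact number of
#' positions so members sit near `within_identity` to their base.
#' Sequences are equal length, so targeted identities are hit within a few
#' percentage points under the package's alignment-based definition.
#'
#' @param n_clusters,members_per_cluster,length design sizes.
#' @param within_identity,between_identity target pairwise identities;
#'   the design is infeasible (error) unless within > between.
#' @param seed integer.
#' @return List: `sequences` (named character vector), `labels` (named
#'   integer vector, true cluster of each sequence).
#' @export
#' @examples
#' s <- make_sequence_set(n_clusters = 3, members_per_cluster = 4, seed = 7)
#' length(s$sequences)
make_sequence_set <- function(n_clusters = 3L, members_per_cluster = 4L,
                              length = 60L, within_identity = 0.95,
                              between_identity = 0.40, seed = 1L) {
  if (within_identity <= between_identity)
    stop("infeasible identity design: within_identity must exceed between_identity")
  if (within_identity > 1 || between_identity < 0)
    stop("infeasible identity design: identities must lie in [0, 1]")
  g <- prng_new(seed)
  alphabet <- AA1
  rand_seq <- function(L) paste(alphabet[prng_int(g, L, 20L)], collapse = "")
  mutate_at <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- integer(0)
    while (base::length(pos) < k) pos <- unique(c(pos, prng_int(g, 1, base::length(ch))))
    for (p in pos[seq_len(k)]) {
      repeat {
        new <- alphabet[prng_int(g, 1, 20L)]
        if (new != ch[p]) { ch[p] <- new; break }
      }
    }
    paste(ch, collapse = "")
  }
  ancestor <- rand_seq(length)
  # base-vs-base expected identity ~ q^2 for independent retention q
  n_mut_base <- round(length * (1 - sqrt(between_identity)))
  n_mut_member <- round(length * (1 - within_identity))
  sequences <- character(0); labels <- integer(0)
  for (k in seq_len(n_clusters)) {
    base <- mutate_at(ancestor, n_mut_base)
    for (j in seq_len(members_per_cluster)) {
      id <- sprintf("c%02d_m%02d", k, j)
      sequences[id] <- if (j == 1) base else mutate_at(base, n_mut_member)
      labels[id] <- k
    }
  }
  list(sequences = sequences, labels = labels)
}
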