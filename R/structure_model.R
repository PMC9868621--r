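#' @importFrom stats setNames sd prcomp
#' @importFrom utils read.delim write.table head
NULL

## ---- role / region vocabularies -------------------------------------------

CHAIN_ROLES <- c("HEAVY", "LIGHT", "TCR_BETA", "TCR_ALPHA",
                 "MHC_ALPHA", "MHC_BETA", "B2M", "PEPTIDE", "ANTIGEN_OTHER")

IG_ROLES  <- c("HEAVY", "LIGHT", "TCR_BETA", "TCR_ALPHA")
VDJ_ROLES <- c("HEAVY", "TCR_BETA")   # heavy/beta: V(D)J-recombined chain
VJ_ROLES  <- c("LIGHT", "TCR_ALPHA")  # light/alpha: VJ-recombined chain

REGION_LABELS <- c("CDR1", "CDR2", "CDR3", "FRAMEWORK",
                   "MHC_A1_HELIX", "MHC_A2_HELIX", "MHC_OTHER", "PEPTIDE")

# IMGT CDR windows shared by antibody and TCR variable domains
IMGT_CDR_RANGES <- list(CDR1 = c(27L, 38L),
                        CDR2 = c(56L, 65L),
                        CDR3 = c(105L, 117L))

# One-letter tag used to name loops by chain: CDRH3, CDRB3, ...
ROLE_LETTER <- c(HEAVY = "H", LIGHT = "L", TCR_BETA = "B", TCR_ALPHA = "A")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
         "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

#' Default van der Waals radius table
#'
#' Heavy-atom radii (Angstrom) used by the Shrake-Rupley solvent-accessible
#' surface area computation. Structures are analysed without hydrogens, so
#' only the elements occurring in protein heavy atoms are pinned. Elements
#' absent from the table raise an error rather than receiving a silent
#' default, because the radius table directly scales every SASA value.
#'
#' @return Named numeric vector, element symbol to radius in Angstrom.
#' @export
#' @examples
#' default_vdw_radii()[["C"]]
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
}

#' Default analysis configuration
#'
#' Central knobs shared by the profiling stages:
#' \describe{
#'   \item{vdw_radii}{named radius table, see [default_vdw_radii()].}
#'   \item{probe_radius}{solvent probe radius in Angstrom (1.4, a water).}
#'   \item{n_sphere_points}{Shrake-Rupley lattice size per atom.}
#'   \item{burial_epsilon}{minimum SASA decrease (Angstrom^2) counted as
#'     burial; absorbs lattice noise around exactly-zero differences.}
#'   \item{mhc_helix_windows}{renumbered-MHC residue windows delimiting the
#'     two groove helices. For class I both windows live on the MHC alpha
#'     chain; for class II the second window is taken on the MHC beta chain.}
#' }
#'
#' @param ... name-value overrides of the defaults.
#' @return List of configuration values.
#' @export
#' @examples
#' profiler_config(n_sphere_points = 240)$n_sphere_points
profiler_config <- function(...) {
  cfg <- list(
    vdw_radii = default_vdw_radii(),
    probe_radius = 1.4,
    n_sphere_points = 960L,
    burial_epsilon = 0.01,
    mhc_helix_windows = list(alpha1 = c(50L, 86L), alpha2 = c(138L, 176L))
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

## ---- sidecar annotation ----------------------------------------------------

#' Read a chain-annotation sidecar
#'
#' The sidecar is a TSV with a comment header block assigning roles:
#' ```
#' #complex  <id>
#' #ig_class ANTIBODY|TCR|TCRM
#' #mhc_class I|II
#' #role  <chain_id>  <ROLE>
#' chain  author_number  insertion_code  number
#' H      31             .               27
#' ```
#' Numbering rows carry IMGT numbers for immunoglobulin chains and
#' renumbered-MHC positions for MHC chains; other chains need no rows.
#' Insertion code "." or "" means none.
#'
#' @param path path to the sidecar TSV.
#' @return List with `complex_id`, `ig_class`, `mhc_class`, `chain_roles`
#'   (named character vector) and `numbering` (data.frame chain, resno,
#'   icode, number).
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  roles <- character(0)
  complex_id <- NA_character_; ig_class <- NA_character_; mhc_class <- NA_character_
  for (h in hdr) {
    tok <- strsplit(sub("^#", "", h), "[\t ]+")[[1]]
    tok <- tok[nzchar(tok)]
    if (!length(tok)) next
    key <- tolower(tok[1])
    if (key == "role" && length(tok) >= 3) {
      roles[tok[2]] <- toupper(tok[3])
    } else if (key == "complex" && length(tok) >= 2) {
      complex_id <- tok[2]
    } else if (key == "ig_class" && length(tok) >= 2) {
      ig_class <- toupper(tok[2])
    } else if (key == "mhc_class" && length(tok) >= 2) {
      mhc_class <- toupper(tok[2])
    }
  }
  if (!length(roles)) stop("annotation error: sidecar declares no chain roles")
  bad <- setdiff(unname(roles), CHAIN_ROLES)
  if (length(bad)) stop("annotation error: unknown chain role(s): ",
                        paste(bad, collapse = ", "))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  numbering <- NULL
  if (length(body) > 1) {
    con <- textConnection(body)
    on.exit(close(con), add = TRUE)
    tab <- read.delim(con, stringsAsFactors = FALSE,
                      colClasses = c("character", "integer", "character", "integer"))
    names(tab) <- c("chain", "resno", "icode", "number")[seq_along(names(tab))]
    tab$icode[tab$icode %in% c(".", NA)] <- ""
    numbering <- tab
  } else {
    numbering <- data.frame(chain = character(0), resno = integer(0),
                            icode = character(0), number = integer(0),
                            stringsAsFactors = FALSE)
  }
  extra <- setdiff(unique(numbering$chain), names(roles))
  if (length(extra)) stop("annotation error: numbering rows reference chains ",
                          "without a role: ", paste(extra, collapse = ", "))
  list(complex_id = complex_id, ig_class = ig_class, mhc_class = mhc_class,
       chain_roles = roles, numbering = numbering)
}

#' Write a chain-annotation sidecar
#'
#' Inverse of [read_annotation()]; used by the fixture generators.
#'
#' @param annotation list as returned by [read_annotation()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(annotation$complex_id))
    writeLines(paste0("#complex\t", annotation$complex_id), con)
  if (!is.null(annotation$ig_class) && !is.na(annotation$ig_class))
    writeLines(paste0("#ig_class\t", annotation$ig_class), con)
  if (!is.null(annotation$mhc_class) && !is.na(annotation$mhc_class))
    writeLines(paste0("#mhc_class\t", annotation$mhc_class), con)
  for (ch in names(annotation$chain_roles))
    writeLines(paste0("#role\t", ch, "\t", annotation$chain_roles[[ch]]), con)
  num <- annotation$numbering
  writeLines("chain\tauthor_number\tinsertion_code\tnumber", con)
  if (!is.null(num) && nrow(num)) {
    ic <- ifelse(nzchar(num$icode), num$icode, ".")
    writeLines(paste(num$chain, num$resno, ic, num$number, sep = "\t"), con)
  }
  invisible(path)
}

## ---- complex loading -------------------------------------------------------

#' Load and annotate an immunoglobulin:antigen complex
#'
#' Reads a PDB or mmCIF file (via bio3d), sanitizes it (drops hydrogens,
#' waters, heteroatoms and alternate locations, keeping the highest-occupancy
#' altloc, ties to the first record) and attaches the chain roles and
#' IMGT / renumbered-MHC numbering supplied by the sidecar annotation.
#' Chains present in the file but absent from the annotation are dropped
#' with a warning; non-protein chains on the antigen side are rejected.
#'
#' @param coordinate_file path to a `.pdb` or `.cif` file.
#' @param annotation sidecar path, or a list as from [read_annotation()].
#' @param config see [profiler_config()].
#' @return An object of class `annotated_complex`: list with `complex_id`,
#'   `atoms` (data.frame chain, resno, icode, resname, atom, element,
#'   x, y, z), `chain_roles`, `numbering`, `ig_class`, `mhc_class`.
#' @export
load_complex <- function(coordinate_file, annotation,
                         config = profiler_config()) {
  if (is.character(annotation)) annotation <- read_annotation(annotation)
  atoms <- read_structure_atoms(coordinate_file)
  atoms <- sanitize_atoms(atoms)

  known <- names(annotation$chain_roles)
  drop <- setdiff(unique(atoms$chain), known)
  if (length(drop)) {
    warning("dropping unannotated chain(s): ", paste(drop, collapse = ", "))
    atoms <- atoms[atoms$chain %in% known, , drop = FALSE]
  }
  missing <- setdiff(known, unique(atoms$chain))
  if (length(missing))
    stop("annotation error: annotation references missing chain(s): ",
         paste(missing, collapse = ", "))

  roles <- annotation$chain_roles[unique(atoms$chain)]
  # antigen-side chains must be protein
  nonprot <- atoms$resname[!(atoms$resname %in% AA3)]
  if (length(nonprot))
    stop("format error: non-protein residues after sanitization: ",
         paste(unique(nonprot), collapse = ", "))

  ig_chains <- names(roles)[roles %in% IG_ROLES]
  for (ch in ig_chains) {
    if (!any(annotation$numbering$chain == ch))
      stop("numbering error: immunoglobulin chain '", ch,
           "' has no IMGT numbering rows")
  }

  cid <- annotation$complex_id
  if (is.na(cid)) cid <- sub("\\.(pdb|cif|ent)$", "", basename(coordinate_file))
  x <- list(complex_id = cid,
            atoms = atoms,
            chain_roles = roles,
            numbering = annotation$numbering,
            ig_class = annotation$ig_class,
            mhc_class = annotation$mhc_class)
  class(x) <- "annotated_complex"
  validate_complex(x)
  x
}

read_structure_atoms <- function(path) {
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, verbose = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("format error: cannot parse '", path, "': ",
                             conditionMessage(e)))
  a <- pdb$atom
  icode <- a$insert
  icode[is.na(icode)] <- ""
  alt <- a$alt
  alt[is.na(alt)] <- ""
  occ <- a$o
  occ[is.na(occ)] <- 1
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem) | !nzchar(elem)))
    elem <- guess_element(a$elety)
  elem[is.na(elem) | !nzchar(elem)] <- guess_element(a$elety[is.na(elem) | !nzchar(elem)])
  data.frame(type = a$type, chain = as.character(a$chain),
             resno = as.integer(a$resno), icode = as.character(icode),
             resname = toupper(as.character(a$resid)),
             atom = as.character(a$elety), element = toupper(trimws(elem)),
             alt = as.character(alt), occ = as.numeric(occ),
             x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
}

guess_element <- function(atom_names) {
  nm <- gsub("[0-9']", "", toupper(atom_names))
  ifelse(substr(nm, 1, 1) %in% c("C", "N", "O", "S", "H", "P"),
         substr(nm, 1, 1), substr(nm, 1, 1))
}

# Strip hydrogens, waters and heteroatoms; resolve altlocs to the
# highest-occupancy record (tie: first in file order).
sanitize_atoms <- function(atoms) {
  keep <- atoms$type == "ATOM" &
    !(atoms$resname %in% WATER_RESNAMES) &
    !(atoms$element %in% c("H", "D"))
  atoms <- atoms[keep, , drop = FALSE]
  if (any(nzchar(atoms$alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$atom, sep = "|")
    ord <- order(key, -atoms$occ, seq_len(nrow(atoms)))
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$icode,
                                     atoms$atom, sep = "|")), , drop = FALSE]
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  atoms[, c("chain", "resno", "icode", "resname", "atom", "element",
            "x", "y", "z")]
}

validate_complex <- function(x) {
  stopifnot(inherits(x, "annotated_complex"))
  if (!all(is.finite(as.matrix(x$atoms[, c("x", "y", "z")]))))
    stop("format error: non-finite coordinates")
  roles <- x$chain_roles
  n_vdj <- sum(roles %in% VDJ_ROLES); n_vj <- sum(roles %in% VJ_ROLES)
  if (n_vdj + n_vj == 0) stop("annotation error: no immunoglobulin chains")
  if (sum(roles == "PEPTIDE") > 1)
    stop("annotation error: more than one PEPTIDE chain")
  invisible(x)
}

#' @export
print.annotated_complex <- function(x, ...) {
  cat("annotated_complex '", x$complex_id, "' (", x$ig_class, ")\n", sep = "")
  for (ch in names(x$chain_roles)) {
    n <- length(unique(residue_uid(x$atoms[x$atoms$chain == ch, ])))
    cat(sprintf("  chain %s  %-13s %4d residues\n", ch, x$chain_roles[[ch]], n))
  }
  invisible(x)
}

## ---- residue bookkeeping ---------------------------------------------------

residue_uid <- function(df) paste(df$chain, df$resno, df$icode, sep = ":")

#' Residue table of an annotated complex
#'
#' One row per residue with chain role and (where annotated) the IMGT or
#' renumbered-MHC number, in file order.
#'
#' @param complex an `annotated_complex`.
#' @return data.frame: chain, resno, icode, resname, role, number, uid.
#' @export
residue_table <- function(complex) {
  a <- complex$atoms
  uid <- residue_uid(a)
  first <- !duplicated(uid)
  res <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    stringsAsFactors = FALSE)
  res$role <- unname(complex$chain_roles[res$chain])
  num <- complex$numbering
  if (!is.null(num) && nrow(num)) {
    key <- paste(num$chain, num$resno, num$icode, sep = ":")
    res$number <- num$number[match(paste(res$chain, res$resno, res$icode,
                                         sep = ":"), key)]
  } else res$number <- NA_integer_
  res$uid <- paste(res$chain, res$resno, res$icode, sep = ":")
  res
}

#' Assign structural region labels to every residue
#'
#' Immunoglobulin residues are labelled by their IMGT number (CDR1 27-38,
#' CDR2 56-65, CDR3 105-117, otherwise FRAMEWORK). MHC residues are labelled
#' by the configured renumbered helix windows (`MHC_A1_HELIX` /
#' `MHC_A2_HELIX`, otherwise `MHC_OTHER`); for class II complexes the second
#' window is looked up on the MHC beta chain. Peptide residues are labelled
#' PEPTIDE; any other antigen residue is labelled MHC_OTHER only if on an
#' MHC chain, else FRAMEWORK does not apply and the label is `NA`-free
#' "ANTIGEN" bucket folded into MHC_OTHER for aggregation simplicity.
#'
#' @param complex an `annotated_complex`.
#' @param config see [profiler_config()].
#' @return data.frame: the [residue_table()] plus columns `region` and,
#'   for immunoglobulin residues, `loop` (e.g. "CDRH3", "" when none).
#' @export
#' @examples
#' fx <- make_groove_complex(groove_fixture_spec())
#' table(assign_regions(fx$complex)$region)
assign_regions <- function(complex, config = profiler_config()) {
  res <- residue_table(complex)
  win <- config$mhc_helix_windows
  region <- character(nrow(res))
  loop <- character(nrow(res))
  for (i in seq_len(nrow(res))) {
    role <- res$role[i]; n <- res$number[i]
    if (role %in% IG_ROLES) {
      lab <- "FRAMEWORK"
      if (!is.na(n)) {
        for (cdr in names(IMGT_CDR_RANGES)) {
          rg <- IMGT_CDR_RANGES[[cdr]]
          if (n >= rg[1] && n <= rg[2]) { lab <- cdr; break }
        }
      }
      region[i] <- lab
      if (lab != "FRAMEWORK")
        loop[i] <- paste0("CDR", ROLE_LETTER[[role]], substr(lab, 4, 4))
    } else if (role == "PEPTIDE") {
      region[i] <- "PEPTIDE"
    } else if (role %in% c("MHC_ALPHA", "MHC_BETA")) {
      lab <- "MHC_OTHER"
      if (!is.na(n)) {
        a1_chain <- "MHC_ALPHA"
        a2_chain <- if (identical(complex$mhc_class, "II")) "MHC_BETA" else "MHC_ALPHA"
        if (role == a1_chain && n >= win$alpha1[1] && n <= win$alpha1[2])
          lab <- "MHC_A1_HELIX"
        if (role == a2_chain && n >= win$alpha2[1] && n <= win$alpha2[2])
          lab <- "MHC_A2_HELIX"
      }
      region[i] <- lab
    } else {
      region[i] <- "MHC_OTHER"  # B2M / other antigen: aggregated with MHC frame
    }
  }
  res$region <- region
  res$loop <- loop
  res
}

#' Map genetic chain classes to chain identifiers
#'
#' Antibody heavy and TCR beta chains are V(D)J-recombined; light and alpha
#' chains are VJ-recombined. This pairing underlies every heavy-vs-beta,
#' light-vs-alpha comparison in the profiling outputs.
#'
#' @param complex an `annotated_complex`.
#' @return Named character vector with entries `VDJ_CHAIN` and `VJ_CHAIN`.
#' @export
chain_pairing_map <- function(complex) {
  roles <- complex$chain_roles
  vdj <- names(roles)[roles %in% VDJ_ROLES]
  vj <- names(roles)[roles %in% VJ_ROLES]
  if (length(vdj) != 1 || length(vj) != 1)
    stop("pairing error: expected exactly one VDJ and one VJ chain, found ",
         length(vdj), " and ", length(vj))
  c(VDJ_CHAIN = vdj, VJ_CHAIN = vj)
}

# Split atoms into immunoglobulin side and antigen side
interface_sides <- function(complex) {
  roles <- complex$chain_roles
  ig_chains <- names(roles)[roles %in% IG_ROLES]
  ag_chains <- names(roles)[!(roles %in% IG_ROLES)]
  list(ig = complex$atoms[complex$atoms$chain %in% ig_chains, , drop = FALSE],
       antigen = complex$atoms[complex$atoms$chain %in% ag_chains, , drop = FALSE],
       ig_chains = ig_chains, antigen_chains = ag_chains)
}
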