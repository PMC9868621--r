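## Cohort orchestration: run burial, interaction and geometry profiling
## over a set of complexes and aggregate by immunoglobulin class.

#' Profile a cohort of complexes
#'
#' Runs [burial_profile()], [detect_atom_contacts()] + [consolidate()] +
#' [interaction_summary()] and [geometry_report()] for every complex, and
#' [regional_fractions()] where a pMHC decomposition table is supplied.
#' Failures are caught and logged per complex and never abort the batch.
#' Group summaries report mean, sample standard deviation (n-1) and n over
#' non-missing values per immunoglobulin class; class I and class II pMHC
#' binders are pooled within a class.
#'
#' @param complexes list of `annotated_complex` objects, or of lists
#'   `(coordinate_file, annotation)` to be loaded.
#' @param decomp_tables optional named list (by complex id) of PMHC-side
#'   [decomp_table()]s.
#' @param config see [profiler_config()].
#' @return Object of class `cohort_profile`: `per_complex` (data.frame,
#'   one row per successfully profiled complex), `group_summaries`
#'   (data.frame class, metric, mean, sd, n), `failures` (named character
#'   vector of error messages).
#' @export
profile_cohort <- function(complexes, decomp_tables = NULL,
                           config = profiler_config()) {
  rows <- list(); failures <- character(0)
  for (i in seq_along(complexes)) {
    cx <- complexes[[i]]
    row <- tryCatch({
      if (!inherits(cx, "annotated_complex"))
        cx <- load_complex(cx$coordinate_file, cx$annotation, config)
      regions <- assign_regions(cx, config)
      bp <- burial_profile(cx, regions, config)
      ip <- consolidate(detect_atom_contacts(cx))
      is_pmhc <- any(cx$chain_roles == "PEPTIDE")
      isum <- if (is_pmhc) interaction_summary(ip, cx, regions) else NULL
      geo <- tryCatch(geometry_report(cx, config = config),
                      error = function(e) NULL)
      dt <- decomp_tables[[cx$complex_id]]
      rf <- if (!is.null(dt)) regional_fractions(dt, regions) else NULL
      data.frame(
        complex_id = cx$complex_id, ig_class = cx$ig_class,
        mhc_class = cx$mhc_class %||% NA_character_,
        interface_bsa = bp$totals$interface_bsa,
        immunoglobulin_bsa = bp$totals$immunoglobulin_bsa,
        antigen_bsa = bp$totals$antigen_bsa,
        peptide_bsa = bp$totals$peptide_bsa,
        mhc_bsa = bp$totals$mhc_bsa,
        peptide_fraction = bp$peptide_fraction,
        cdr3_pair_fraction = bp$cdr3_pair_fraction,
        buried_peptide_residue_count = bp$buried_peptide_residue_count,
        n_total_interactions = if (is.null(isum)) NA_integer_ else isum$n_total_interactions,
        n_ig_peptide_interactions = if (is.null(isum)) NA_integer_ else isum$n_ig_peptide_interactions,
        n_ig_mhc_interactions = if (is.null(isum)) NA_integer_ else isum$n_ig_mhc_interactions,
        docking_angle = if (is.null(geo)) NA_real_ else geo$docking_angle,
        polarity = if (is.null(geo)) NA_character_ else geo$polarity,
        f_peptide = if (is.null(rf)) NA_real_ else rf$f_peptide,
        f_alpha1 = if (is.null(rf)) NA_real_ else rf$f_alpha1,
        f_alpha2 = if (is.null(rf)) NA_real_ else rf$f_alpha2,
        stringsAsFactors = FALSE)
    }, error = function(e) {
      id <- if (inherits(cx, "annotated_complex")) cx$complex_id
      else if (!is.null(cx$coordinate_file)) basename(cx$coordinate_file)
      else paste0("complex_", i)
      failures[[id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  if (!length(rows)) stop("no complex could be profiled")
  per_complex <- do.call(rbind, rows)

  metrics <- setdiff(names(per_complex),
                     c("complex_id", "ig_class", "mhc_class", "polarity"))
  gs <- list()
  for (cl in unique(per_complex$ig_class)) {
    sub <- per_complex[per_complex$ig_class == cl, , drop = FALSE]
    for (m in metrics) {
      v <- sub[[m]]; v <- v[!is.na(v)]
      gs[[length(gs) + 1]] <- data.frame(
        ig_class = cl, metric = m,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE)
    }
  }
  structure(list(per_complex = per_complex,
                 group_summaries = do.call(rbind, gs),
                 failures = failures),
            class = "cohort_profile")
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("cohort_profile:", nrow(x$per_complex), "complex(es) profiled")
  if (length(x$failures)) cat(",", length(x$failures), "failed")
  cat("\n")
  tab <- table(x$per_complex$ig_class)
  for (cl in names(tab)) cat("  ", cl, ": n =", tab[[cl]], "\n")
  invisible(x)
}

#' Fraction of complexes burying at least k peptide residues
#'
#' Restricts the cohort to a peptide length (and optionally MHC class) and
#' reports the fraction of complexes whose buried-peptide-residue count
#' reaches `min_buried` (at least, or exactly with `mode = "exact"`),
#' together with the numerator and denominator.
#'
#' @param profile a `cohort_profile`.
#' @param peptide_length restrict to complexes whose peptide has this many
#'   residues (`NA` = no restriction); requires `peptide_lengths` lookup.
#' @param min_buried threshold k.
#' @param mode "at_least" or "exact".
#' @param ig_class,mhc_class optional further restrictions.
#' @param peptide_lengths named integer vector (by complex id); needed
#'   only when `peptide_length` is given.
#' @return List: `fraction`, `numerator`, `denominator`, `label`
#'   ("13/29 (44.8%)"-style).
#' @export
peptide_burial_fraction_stats <- function(profile, peptide_length = NA,
                                          min_buried,
                                          mode = c("at_least", "exact"),
                                          ig_class = NULL, mhc_class = NULL,
                                          peptide_lengths = NULL) {
  mode <- match.arg(mode)
  pc <- profile$per_complex
  if (!is.null(ig_class)) pc <- pc[pc$ig_class %in% ig_class, , drop = FALSE]
  if (!is.null(mhc_class)) pc <- pc[!is.na(pc$mhc_class) &
                                      pc$mhc_class %in% mhc_class, , drop = FALSE]
  if (!is.na(peptide_length)) {
    if (is.null(peptide_lengths))
      stop("peptide_lengths lookup required to restrict by peptide length")
    pc <- pc[peptide_lengths[pc$complex_id] %in% peptide_length, , drop = FALSE]
  }
  if (!nrow(pc)) {
    warning("empty cohort subset; fraction undefined")
    return(list(fraction = NA_real_, numerator = 0L, denominator = 0L,
                label = "0/0"))
  }
  hit <- if (mode == "at_least") pc$buried_peptide_residue_count >= min_buried
  else pc$buried_peptide_residue_count == min_buried
  num <- sum(hit); den <- nrow(pc)
  list(fraction = num / den, numerator = num, denominator = den,
       label = sprintf("%d/%d (%.1f%%)", num, den, 100 * num / den))
}

#' Write cohort outputs to disk
#'
#' Emits `<prefix>_per_complex.tsv` and `<prefix>_group_summaries.json`.
#'
#' @param profile a `cohort_profile`.
#' @param prefix output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(profile, prefix) {
  tsv <- paste0(prefix, "_per_complex.tsv")
  js <- paste0(prefix, "_group_summaries.json")
  write.table(profile$per_complex, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(profile$group_summaries, js, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, js))
}
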