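## Dataset curation: quality filters and cd-hit-style two-round greedy
## clustering to non-redundant representative complexes.

#' Pairwise sequence identity and coverage
#'
#' Global alignment (Needleman-Wunsch via Biostrings) scoring match +1,
#' mismatch 0, gaps 0, so the optimal alignment maximises the number of
#' matched columns. Identity is matches divided by alignment columns after
#' stripping terminal-gap columns; coverage is that aligned span divided by
#' the shorter sequence length (capped at 1). This approximates the
#' identity notion used by greedy clustering tools without reproducing any
#' particular tool's word-filter internals.
#'
#' @param a,b character scalars (amino-acid sequences).
#' @return Named numeric vector: `identity`, `coverage` (both fractions).
#' @export
#' @examples
#' sequence_identity("ACDEFGHIKL", "ACDEFGHIKL")
sequence_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = match_matrix(), type = "global",
    gapOpening = 0, gapExtension = 0)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap_a <- pa == "-"; gap_b <- pb == "-"
  ncol_all <- length(pa)
  # strip columns inside a terminal gap run of either sequence
  lead <- max(match(FALSE, gap_a) %||na% (ncol_all + 1),
              match(FALSE, gap_b) %||na% (ncol_all + 1)) - 1
  trail <- max(match(FALSE, rev(gap_a)) %||na% (ncol_all + 1),
               match(FALSE, rev(gap_b)) %||na% (ncol_all + 1)) - 1
  keep <- seq_len(ncol_all)
  keep <- keep[keep > lead & keep <= ncol_all - trail]
  if (!length(keep)) return(c(identity = 0, coverage = 0))
  matches <- sum(pa[keep] == pb[keep] & pa[keep] != "-")
  span <- length(keep)
  c(identity = matches / span,
    coverage = min(1, span / min(nchar(a), nchar(b))))
}

`%||na%` <- function(a, b) if (is.na(a)) b else a

match_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c(Biostrings::AA_ALPHABET)
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

#' Greedy sequence-identity clustering
#'
#' cd-hit-style scheme: sequences are sorted by descending length (ties by
#' identifier); the longest unassigned sequence seeds a cluster; each
#' subsequent sequence joins the first seed it matches at
#' `identity >= threshold` with `coverage >= min_coverage`, else seeds its
#' own cluster. Deterministic given the input set (independent of input
#' ordering, because of the canonical sort).
#'
#' @param sequences named character vector (names are identifiers).
#' @param threshold identity threshold in `(0, 1]`.
#' @param min_coverage minimum alignment coverage of the shorter sequence.
#' @return Object of class `cluster_set`: list `clusters` of
#'   `(representative, members)` (representative = seed), plus `threshold`
#'   and `min_coverage`.
#' @export
#' @examples
#' greedy_cluster(c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "WWWWWWWWWW"),
#'                threshold = 0.8)
greedy_cluster <- function(sequences, threshold = 0.8, min_coverage = 0) {
  stopifnot(threshold > 0, threshold <= 1, length(sequences) > 0)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must have unique names")
  if (any(!nzchar(sequences))) stop("empty sequence")
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  seeds <- integer(0)           # indices into ids/seqs
  assign <- integer(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (s in seq_along(seeds)) {
      m <- sequence_identity(seqs[i], seqs[seeds[s]])
      if (m[["identity"]] >= threshold && m[["coverage"]] >= min_coverage) {
        assign[i] <- s; placed <- TRUE; break
      }
    }
    if (!placed) { seeds <- c(seeds, i); assign[i] <- length(seeds) }
  }
  clusters <- lapply(seq_along(seeds), function(s)
    list(representative = ids[seeds[s]], members = ids[assign == s]))
  structure(list(clusters = clusters, threshold = threshold,
                 min_coverage = min_coverage),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("cluster_set:", length(x$clusters), "cluster(s) at identity >=",
      x$threshold, "\n")
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param cs a `cluster_set`.
#' @return Named character vector mapping member id to representative id.
#' @export
cluster_membership <- function(cs) {
  out <- character(0)
  for (cl in cs$clusters) out[cl$members] <- cl$representative
  out
}

## ---- complex records and filtering ----------------------------------------

#' Build a table of complex records
#'
#' @param complex_id,method,resolution,immunoglobulin_class vectors.
#' @param cdr_sequences character: the six IMGT CDR sequences concatenated
#'   in a consistent order (H1,H2,H3,L1,L2,L3 or the B/A equivalent).
#' @param antigen_sequences character: antigen chain sequences joined by
#'   ";" in descending length order (the presented peptide for TCRs).
#' @return data.frame of class `complex_records`.
#' @export
complex_records <- function(complex_id, method, resolution, cdr_sequences,
                            antigen_sequences, immunoglobulin_class) {
  df <- data.frame(complex_id = complex_id, method = method,
                   resolution = resolution, cdr_sequences = cdr_sequences,
                   antigen_sequences = antigen_sequences,
                   immunoglobulin_class = immunoglobulin_class,
                   stringsAsFactors = FALSE)
  class(df) <- c("complex_records", "data.frame")
  df
}

#' Quality-filter complex records
#'
#' Retains X-ray structures at or better than the resolution cutoff, in
#' input order. Structures solved by other methods are dropped regardless
#' of nominal resolution.
#'
#' @param records data.frame from [complex_records()] or with the same
#'   columns.
#' @param max_resolution Angstrom (default 2.5).
#' @return Filtered records.
#' @export
filter_records <- function(records, max_resolution = 2.5) {
  keep <- toupper(records$method) %in% c("X-RAY", "XRAY", "X-RAY DIFFRACTION") &
    !is.na(records$resolution) & records$resolution <= max_resolution
  records[keep, , drop = FALSE]
}

#' Two-round clustering to non-redundant representatives
#'
#' Round 1 clusters the concatenated CDR sequences at 80% identity
#' ("paratope clusters"). Round 2 re-clusters each paratope cluster's
#' members on the concatenated antigen sequences at 80% identity with a
#' minimum alignment coverage of 20% of the shorter sequence, so a
#' truncated antigen groups with its full-length form rather than counting
#' as a different target. One representative is kept per
#' (paratope, antigen) cluster: best (lowest) resolution, ties broken by
#' lexicographic complex id.
#'
#' @param records pre-filtered records (see [filter_records()]).
#' @param paratope_threshold,antigen_threshold identity thresholds.
#' @param antigen_min_coverage round-2 coverage floor.
#' @return List: `representatives` (records subset, one row per cluster
#'   pair, ordered by complex id), `assignments` (data.frame complex_id,
#'   paratope_cluster, antigen_cluster, representative).
#' @export
two_round_representatives <- function(records, paratope_threshold = 0.8,
                                      antigen_threshold = 0.8,
                                      antigen_min_coverage = 0.2) {
  if (!nrow(records)) stop("no records to cluster")
  cdr <- setNames(records$cdr_sequences, records$complex_id)
  r1 <- greedy_cluster(cdr, threshold = paratope_threshold)
  para_of <- cluster_membership(r1)

  # antigen sequences: chains joined ";" -> concatenated descending length
  antigen_concat <- vapply(records$antigen_sequences, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    paste(parts[order(-nchar(parts), parts)], collapse = "")
  }, "", USE.NAMES = FALSE)
  names(antigen_concat) <- records$complex_id

  assignments <- NULL
  reps <- character(0)
  for (cl in r1$clusters) {
    mem <- cl$members
    r2 <- greedy_cluster(antigen_concat[mem], threshold = antigen_threshold,
                         min_coverage = antigen_min_coverage)
    ag_of <- cluster_membership(r2)
    for (cl2 in r2$clusters) {
      sub <- records[match(cl2$members, records$complex_id), , drop = FALSE]
      best <- sub[order(sub$resolution, sub$complex_id), , drop = FALSE][1, ]
      reps <- c(reps, best$complex_id)
      assignments <- rbind(assignments, data.frame(
        complex_id = cl2$members,
        paratope_cluster = cl$representative,
        antigen_cluster = cl2$representative,
        representative = best$complex_id, stringsAsFactors = FALSE))
    }
  }
  reps <- sort(reps)
  list(representatives = records[match(reps, records$complex_id), , drop = FALSE],
       assignments = assignments[order(assignments$complex_id), , drop = FALSE])
}
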