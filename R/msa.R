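#' Extract adenylation-domain subsequences for phylogeny
#'
#' One record per (non-degenerate, by default) A domain, with id
#' `"<protein_id>|m<k>"` where `k` is the 1-based module index of the domain
#' within its protein (degenerate A domains count as modules for numbering).
#' Domains shorter than `min_length` residues are dropped (partial domains
#' that would not align).
#'
#' @param proteins `AAStringSet` of the scanned proteins.
#' @param architectures result of [call_architectures()] (its `"hits"`
#'   attribute supplies the resolved hit coordinates).
#' @param include_degenerate also emit degenerate A domains.
#' @param min_length minimum domain length in residues.
#' @return `AAStringSet` of A-domain subsequences; attribute `"meta"` is a
#'   data.frame (label, protein_id, module, prof_start, prof_end, degenerate).
#' @export
extract_a_domains <- function(proteins, architectures,
                              include_degenerate = FALSE, min_length = 150L) {
  hits <- attr(architectures, "hits")
  if (is.null(hits)) stop("architectures lack the resolved hit attribute")
  ids <- seq_ids(proteins)
  missing <- setdiff(unique(hits$protein_id), ids)
  if (length(missing) > 0)
    stop("architecture references missing protein(s): ",
         paste(missing, collapse = ", "))
  seqs <- setNames(as.character(proteins), ids)
  a_hits <- hits[hits$domain_type == "A", , drop = FALSE]
  if (nrow(a_hits) == 0) {
    out <- Biostrings::AAStringSet()
    attr(out, "meta") <- data.frame(label = character(0),
                                    protein_id = character(0),
                                    module = integer(0),
                                    prof_start = integer(0),
                                    prof_end = integer(0),
                                    degenerate = logical(0))
    return(out)
  }
  a_hits <- a_hits[order(a_hits$protein_id, a_hits$start), , drop = FALSE]
  a_hits$module <- stats::ave(seq_len(nrow(a_hits)), a_hits$protein_id,
                              FUN = seq_along)
  keep <- (include_degenerate | !a_hits$degenerate) &
    (a_hits$end - a_hits$start >= min_length)
  a_hits <- a_hits[keep, , drop = FALSE]
  labels <- sprintf("%s|m%d", a_hits$protein_id, a_hits$module)
  res <- vapply(seq_len(nrow(a_hits)), function(i)
    substr(seqs[[a_hits$protein_id[i]]], a_hits$start[i] + 1L, a_hits$end[i]),
    character(1))
  out <- Biostrings::AAStringSet(setNames(res, labels))
  attr(out, "meta") <- data.frame(label = labels,
                                  protein_id = a_hits$protein_id,
                                  module = a_hits$module,
                                  prof_start = a_hits$prof_start,
                                  prof_end = a_hits$prof_end,
                                  degenerate = a_hits$degenerate,
                                  stringsAsFactors = FALSE)
  out
}

#' Stack extracted domains into an alignment by profile coordinates
#'
#' Places each extracted domain at its matched profile interval, padding the
#' flanks with gaps, so all rows share the profile's coordinate system. When
#' a hit's residue span differs from its profile span (gapped local
#' alignments), the residues are left-justified within the span and padded
#' or truncated to fit.
#'
#' @param domains result of [extract_a_domains()] (with `"meta"` attribute).
#' @param profile_length number of profile match states (columns).
#' @return an `AAStringSet` alignment of width `profile_length`.
#' @export
align_to_profile <- function(domains, profile_length) {
  meta <- attr(domains, "meta")
  if (is.null(meta)) stop("domains lack extraction metadata")
  rows <- vapply(seq_along(domains), function(i) {
    s <- as.character(domains[[i]])
    span <- meta$prof_end[i] - meta$prof_start[i]
    if (nchar(s) > span) s <- substr(s, 1L, span)
    if (nchar(s) < span)
      s <- paste0(s, strrep("-", span - nchar(s)))
    paste0(strrep("-", meta$prof_start[i]), s,
           strrep("-", profile_length - meta$prof_end[i]))
  }, character(1))
  as_alignment(Biostrings::AAStringSet(setNames(rows, names(domains))))
}

#' Mask gap-rich alignment columns
#'
#' A column is removed iff its gap fraction strictly exceeds
#' `max_gap_fraction` (so a column with exactly 30% gaps survives a 0.30
#' threshold). Row order and ids are unchanged; masking is idempotent at a
#' fixed threshold.
#'
#' @param alignment an `AAStringSet` alignment.
#' @param max_gap_fraction threshold in (0, 1].
#' @return object of class `nps_mask`: `masked` (the masked alignment),
#'   `kept_columns` (1-based original column indices, strictly increasing),
#'   and `threshold`.
#' @export
mask_columns <- function(alignment, max_gap_fraction = 0.30) {
  if (max_gap_fraction <= 0 || max_gap_fraction > 1)
    stop("max_gap_fraction must be in (0, 1]")
  m <- alignment_matrix(alignment)
  gapfrac <- colMeans(m == "-")
  kept <- which(gapfrac <= max_gap_fraction)
  if (length(kept) == 0) stop("empty masked alignment")
  rows <- apply(m[, kept, drop = FALSE], 1, paste, collapse = "")
  masked <- Biostrings::AAStringSet(setNames(rows, names(alignment)))
  structure(list(masked = masked,
                 kept_columns = kept,
                 threshold = max_gap_fraction),
            class = "nps_mask")
}

#' @export
print.nps_mask <- function(x, ...) {
  cat("nps_mask: kept", length(x$kept_columns), "columns at gap threshold >",
      x$threshold, "\n")
  invisible(x)
}
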