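#' Call the modular domain architecture of one protein
#'
#' Resolves overlapping hits from all profiles greedily by bit score (two
#' hits overlap when the shared interval exceeds `overlap_fraction` of the
#' shorter hit; score ties are broken by earlier start, then by the domain
#' type order A < T < C < R). Survivors are sorted by start; degenerate
#' adenylation domains are rendered `dA`. The module count is the number of
#' A plus dA domains.
#'
#' @param hits data.frame of [scan_protein()] hits for a single protein.
#' @param protein_id id used when `hits` is empty.
#' @param overlap_fraction overlap threshold as a fraction of the shorter hit.
#' @return list of class `nps_architecture` with `protein_id`, `hits` (the
#'   resolved, sorted hits), `architecture` (hyphen-joined labels, `""` when
#'   empty), and `module_count`.
#' @export
call_architecture <- function(hits, protein_id = NULL,
                              overlap_fraction = 0.3) {
  if (is.null(protein_id)) {
    protein_id <- if (nrow(hits) > 0) hits$protein_id[1] else "protein"
  }
  if (nrow(hits) > 0 && length(unique(hits$protein_id)) > 1L)
    stop("call_architecture takes hits of a single protein")
  type_rank <- function(tp) {
    r <- match(tp, c("A", "T", "C", "R"))
    ifelse(is.na(r), 5L, r)
  }
  kept <- hits[0, , drop = FALSE]
  if (nrow(hits) > 0) {
    ord <- order(-hits$bit_score, hits$start, type_rank(hits$domain_type))
    cand <- hits[ord, , drop = FALSE]
    for (i in seq_len(nrow(cand))) {
      h <- cand[i, , drop = FALSE]
      if (nrow(kept) > 0) {
        ov <- pmin(kept$end, h$end) - pmax(kept$start, h$start)
        shorter <- pmin(kept$end - kept$start, h$end - h$start)
        if (any(ov > overlap_fraction * shorter)) next
      }
      kept <- rbind(kept, h)
    }
    kept <- kept[order(kept$start), , drop = FALSE]
    rownames(kept) <- NULL
  }
  labels <- if (nrow(kept) > 0) {
    ifelse(kept$domain_type == "A" & kept$degenerate, "dA", kept$domain_type)
  } else character(0)
  structure(list(protein_id = protein_id,
                 hits = kept,
                 architecture = paste(labels, collapse = "-"),
                 module_count = sum(labels %in% c("A", "dA"))),
            class = "nps_architecture")
}

#' @export
print.nps_architecture <- function(x, ...) {
  cat(x$protein_id, ": ",
      if (nzchar(x$architecture)) x$architecture else "(no domains)",
      " [", x$module_count, " module(s)]\n", sep = "")
  invisible(x)
}

#' Call architectures for every protein in a hit table
#'
#' @param hits combined data.frame from [scan_proteome()].
#' @param protein_ids proteins to report (defaults to those present in
#'   `hits`); proteins without hits get an empty architecture.
#' @param overlap_fraction passed to [call_architecture()].
#' @return data.frame (protein_id, architecture, module_count) with the
#'   resolved per-protein hit table in attribute `"hits"`.
#' @export
call_architectures <- function(hits, protein_ids = NULL,
                               overlap_fraction = 0.3) {
  if (is.null(protein_ids)) protein_ids <- unique(hits$protein_id)
  archs <- lapply(protein_ids, function(id)
    call_architecture(hits[hits$protein_id == id, , drop = FALSE], id,
                      overlap_fraction))
  out <- data.frame(
    protein_id = protein_ids,
    architecture = vapply(archs, `[[`, character(1), "architecture"),
    module_count = vapply(archs, `[[`, integer(1), "module_count"),
    stringsAsFactors = FALSE)
  resolved <- do.call(rbind, lapply(archs, `[[`, "hits"))
  rownames(resolved) <- NULL
  attr(out, "hits") <- resolved
  out
}

#' Screen candidate NRPSs by phylogenetic placement
#'
#' Implements the candidate-retention rule of the screening phylogeny: after
#' rooting on the outgroup, query leaves are accepted when they fall inside
#' the smallest clade that contains all reference labels (the known NRPSs),
#' excludes every outgroup label, and has bootstrap support at or above
#' `support_cutoff` on its subtending edge.
#'
#' @param a_domain_tree a `phylo` tree with supports in `node.label` (rooted
#'   or rootable on the outgroup).
#' @param reference_labels leaves of known NRPS reference domains.
#' @param outgroup_labels leaves of the outgroup adenylating enzymes.
#' @param support_cutoff minimum support (default 90, the candidate
#'   screening criterion).
#' @return character vector of accepted query leaf labels (references and
#'   outgroups excluded); empty when no clade qualifies.
#' @export
screen_candidates <- function(a_domain_tree, reference_labels,
                              outgroup_labels, support_cutoff = 90) {
  stopifnot(inherits(a_domain_tree, "phylo"))
  tips <- a_domain_tree$tip.label
  if (!all(reference_labels %in% tips))
    stop("reference labels missing from tree: ",
         paste(setdiff(reference_labels, tips), collapse = ", "))
  if (length(outgroup_labels) == 0 || !all(outgroup_labels %in% tips))
    stop("outgroup labels missing from tree")
  tr <- root_with_outgroup(a_domain_tree, outgroup_labels)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  mrca <- if (length(reference_labels) == 1L) {
    match(reference_labels, tr$tip.label)
  } else {
    ape::getMRCA(tr, reference_labels)
  }
  if (mrca == root)
    stop("no qualifying clade: references split across the root")
  sup <- support_values(tr)
  # walk rootward from the reference MRCA while the clade stays outgroup-free
  node <- mrca
  best <- NULL
  while (node != root) {
    leaves <- if (node <= ntip) tr$tip.label[node] else
      ape::extract.clade(tr, node)$tip.label
    if (any(outgroup_labels %in% leaves)) break
    s <- if (node <= ntip) NA_real_ else sup[node - ntip]
    if (node > ntip && all(reference_labels %in% leaves) &&
        !is.na(s) && s >= support_cutoff) {
      best <- leaves
      break  # smallest qualifying clade
    }
    node <- tr$edge[tr$edge[, 2] == node, 1]
  }
  if (is.null(best)) return(character(0))
  setdiff(best, c(reference_labels, outgroup_labels))
}
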