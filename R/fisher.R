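#' Build the species-by-subfamily gene count matrix from assignments
#'
#' @param gene_assignments data.frame from [assign_genes()] (protein_id,
#'   subfamily).
#' @param species_of named character vector: protein id -> species.
#' @param group_of named character vector: species -> taxonomic group.
#' @param subfamilies optional column order (defaults to those observed);
#'   species present in `group_of` but without genes appear as zero rows.
#' @return an [nps_counts] object.
#' @export
build_count_matrix <- function(gene_assignments, species_of, group_of,
                               subfamilies = NULL) {
  missing_sp <- setdiff(gene_assignments$protein_id, names(species_of))
  if (length(missing_sp) > 0)
    stop("gene(s) without species: ", paste(missing_sp, collapse = ", "))
  sp <- unname(species_of[gene_assignments$protein_id])
  no_group <- setdiff(unique(c(sp, unname(species_of))), names(group_of))
  if (length(no_group) > 0)
    stop("species missing from group map: ",
         paste(no_group, collapse = ", "))
  species <- unique(c(unname(species_of)))
  if (is.null(subfamilies))
    subfamilies <- sort(unique(gene_assignments$subfamily))
  counts <- matrix(0L, length(species), length(subfamilies),
                   dimnames = list(species, subfamilies))
  if (nrow(gene_assignments) > 0) {
    tab <- table(factor(sp, levels = species),
                 factor(gene_assignments$subfamily, levels = subfamilies))
    counts[] <- as.integer(tab)
  }
  nps_counts(counts, group_of[species])
}

#' Fisher's exact test of subfamily overrepresentation in a taxonomic group
#'
#' Builds the 2x2 table (a = genes in the subfamily and group, b = in the
#' subfamily outside the group, c = other genes in the group, d = the rest)
#' over the gene universe of the count matrix (optionally restricted to a
#' set of groups) and computes the exact hypergeometric tail. One-sided
#' "greater" tests overrepresentation; the two-sided p sums all tables with
#' point probability at or below the observed. The odds ratio is the sample
#' odds ratio `ad/bc` with Haldane +0.5 continuity applied when any cell is
#' zero.
#'
#' @param count_matrix an [nps_counts] object.
#' @param group taxonomic group to test.
#' @param subfamily subfamily to test.
#' @param sided `"greater"` (default) or `"two.sided"`.
#' @param universe optional character vector of groups forming the
#'   comparison universe (default: all species in the matrix).
#' @return list of class `nps_fisher`: `odds_ratio`, `p_value`, `table`
#'   (named vector a, b, c, d), `sided`.
#' @export
fisher_overrepresentation <- function(count_matrix, group, subfamily,
                                      sided = c("greater", "two.sided"),
                                      universe = NULL) {
  sided <- match.arg(sided)
  stopifnot(inherits(count_matrix, "nps_counts"))
  cm <- count_matrix$counts
  grp <- count_matrix$group
  if (!subfamily %in% colnames(cm)) stop("unknown subfamily: ", subfamily)
  if (!group %in% grp) stop("unknown group: ", group)
  if (!is.null(universe)) {
    keep <- grp %in% universe
    cm <- cm[keep, , drop = FALSE]
    grp <- grp[keep]
    if (!group %in% grp) stop("group not in restricted universe")
  }
  in_grp <- grp == group
  a <- sum(cm[in_grp, subfamily])
  b <- sum(cm[!in_grp, subfamily])
  cc <- sum(cm[in_grp, colnames(cm) != subfamily])
  d <- sum(cm[!in_grp, colnames(cm) != subfamily])
  total <- a + b + cc + d
  if (total < 1) stop("empty gene universe")
  tab <- c(a = a, b = b, c = cc, d = d)
  if (a + b == 0L || a + cc == 0L) {
    warning("empty margin: p = 1")
    return(structure(list(odds_ratio = NA_real_, p_value = 1, table = tab,
                          sided = sided), class = "nps_fisher"))
  }
  # hypergeometric: a successes among draws of size (a+c) from (a+b) marked
  p <- if (sided == "greater") {
    phyper(a - 1, a + b, cc + d, a + cc, lower.tail = FALSE)
  } else {
    support <- max(0, (a + cc) - (cc + d)):min(a + b, a + cc)
    dens <- dhyper(support, a + b, cc + d, a + cc)
    sum(dens[dens <= dhyper(a, a + b, cc + d, a + cc) * (1 + 1e-7)])
  }
  orr <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  structure(list(odds_ratio = orr, p_value = min(p, 1), table = tab,
                 sided = sided), class = "nps_fisher")
}

#' @export
print.nps_fisher <- function(x, ...) {
  cat(sprintf("Fisher exact (%s): p = %.4g, OR = %.3g, table (a,b,c,d) = %s\n",
              x$sided, x$p_value, x$odds_ratio,
              paste(x$table, collapse = ", ")))
  invisible(x)
}

#' Test every group x subfamily combination
#'
#' @param count_matrix an [nps_counts] object.
#' @param groups groups to test (default all); also the universe when
#'   `restrict_universe` is `TRUE`.
#' @param sided passed to [fisher_overrepresentation()].
#' @param adjust `"none"` (default: raw significance, as the original
#'   analysis reports) or `"BH"` for Benjamini-Hochberg across all tests.
#' @param alpha significance level for the `significant` flag.
#' @param restrict_universe restrict the gene universe to `groups`.
#' @return data.frame (group, subfamily, a, b, c, d, odds_ratio, p_value,
#'   p_adj, significant).
#' @export
fisher_scan <- function(count_matrix, groups = NULL,
                        sided = "greater", adjust = c("none", "BH"),
                        alpha = 0.05, restrict_universe = FALSE) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(count_matrix, "nps_counts"))
  if (is.null(groups)) groups <- unique(unname(count_matrix$group))
  universe <- if (restrict_universe) groups else NULL
  combos <- expand.grid(group = groups,
                        subfamily = colnames(count_matrix$counts),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    ft <- suppressWarnings(
      fisher_overrepresentation(count_matrix, combos$group[i],
                                combos$subfamily[i], sided = sided,
                                universe = universe))
    data.frame(group = combos$group[i], subfamily = combos$subfamily[i],
               a = ft$table[["a"]], b = ft$table[["b"]],
               c = ft$table[["c"]], d = ft$table[["d"]],
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust == "BH") stats::p.adjust(out$p_value, "BH") else
    out$p_value
  out$significant <- out$p_adj < alpha
  out
}
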