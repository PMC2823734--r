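# Tip-label sets of every node (tips + internal), by postorder accumulation.
node_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

# Map from canonical leaf-set keys to supports for all clades of a rooted
# tree (keyed with leafset_key).
clade_support_map <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- support_values(tree)
  sets <- node_leafsets(tree)
  keys <- vapply((ntip + 1L):(ntip + tree$Nnode), function(n)
    leafset_key(sets[[n]]), character(1))
  setNames(sup, keys)
}

#' Extract consensus subfamilies from three bootstrap-annotated trees
#'
#' A clade of the first tree is promoted to a subfamily when (i) its
#' subtending-edge support reaches `cutoff`, (ii) a clade with the identical
#' leaf set exists in the second and third trees with support at or above
#' their (per-tree configurable) cutoffs, and (iii) it contains at least one
#' reference label. Traversal is preorder from the root and stops descending
#' once a clade is promoted, so each subfamily is the most internal (most
#' rootward) qualifying branch and promoted clades are pairwise disjoint.
#' Clades failing the support criteria in the full trees are rescued when a
#' clade with the corresponding leaf set is supported at `rescue_cutoff` in
#' every reduced-dataset rescue tree.
#'
#' @param trees list of three rooted `phylo` trees with identical leaf sets
#'   and supports in `node.label`.
#' @param reference_labels leaf labels of reference members with known
#'   function (used for criterion (iii) and for naming).
#' @param cutoff support cutoff; a single value (default 70) or one value
#'   per tree (e.g. a lower NJ cutoff).
#' @param rescue_trees optional list of reduced-dataset trees (their leaf
#'   sets may be subsets of the full leaf set).
#' @param rescue_cutoff support cutoff applied in every rescue tree.
#' @param names_map optional named character vector mapping a reference
#'   label to a subfamily name.
#' @param exclude_universal when several references are supplied, a clade
#'   containing every reference is not eligible for promotion (default
#'   `TRUE`): subfamilies partition the known references, and with outgroup
#'   rooting the clade of all candidates reflects the rooting, not a
#'   subfamily.
#' @return object of class `nps_subfamilies`: a list of calls (each with
#'   `name`, `members`, `supports`, `references`, `rescued`) with the
#'   unplaced leaf labels in attribute `"unplaced"`.
#' @export
extract_subfamilies <- function(trees, reference_labels, cutoff = 70,
                                rescue_trees = NULL, rescue_cutoff = 80,
                                names_map = NULL, exclude_universal = TRUE) {
  stopifnot(is.list(trees), length(trees) == 3)
  lapply(trees, function(t) stopifnot(inherits(t, "phylo")))
  cutoff <- rep(cutoff, length.out = 3)
  leaves1 <- trees[[1]]$tip.label
  for (i in 2:3) {
    if (!setequal(leaves1, trees[[i]]$tip.label)) {
      diff <- c(setdiff(leaves1, trees[[i]]$tip.label),
                setdiff(trees[[i]]$tip.label, leaves1))
      stop("leaf sets differ across trees: ", paste(diff, collapse = ", "))
    }
  }
  if (!all(reference_labels %in% leaves1))
    stop("reference labels missing from trees: ",
         paste(setdiff(reference_labels, leaves1), collapse = ", "))
  maps <- lapply(trees[2:3], clade_support_map)
  rescue_maps <- if (!is.null(rescue_trees)) {
    lapply(rescue_trees, clade_support_map)
  }
  rescue_leaves <- if (!is.null(rescue_trees)) {
    Reduce(intersect, lapply(rescue_trees, function(t) t$tip.label))
  }
  tr <- trees[[1]]
  ntip <- length(tr$tip.label)
  sup1 <- support_values(tr)
  calls <- list()

  qualifies_full <- function(leaves, node) {
    s1 <- sup1[node - ntip]
    if (is.na(s1) || s1 < cutoff[1]) return(NULL)
    key <- leafset_key(leaves)
    s2 <- maps[[1]][key]; s3 <- maps[[2]][key]
    if (is.na(s2) || s2 < cutoff[2]) return(NULL)
    if (is.na(s3) || s3 < cutoff[3]) return(NULL)
    c(s1, unname(s2), unname(s3))
  }
  qualifies_rescue <- function(leaves) {
    if (is.null(rescue_maps)) return(FALSE)
    # identical taxon composition across the full trees is still required;
    # only the support comes from the reduced-dataset trees
    full_key <- leafset_key(leaves)
    if (!all(vapply(maps, function(m) full_key %in% names(m), logical(1))))
      return(FALSE)
    sub <- intersect(leaves, rescue_leaves)
    if (length(sub) < 2) return(FALSE)
    key <- leafset_key(sub)
    all(vapply(rescue_maps, function(m) {
      s <- m[key]
      !is.na(s) && s >= rescue_cutoff
    }, logical(1)))
  }
  promote <- function(leaves, node, supports, rescued) {
    refs <- intersect(reference_labels, leaves)
    name <- if (!is.null(names_map) && any(refs %in% names(names_map))) {
      names_map[[intersect(refs, names(names_map))[1]]]
    } else sort(refs)[1]
    calls[[length(calls) + 1L]] <<- list(
      name = name, members = sort(leaves),
      supports = supports, references = sort(refs), rescued = rescued)
  }

  visit <- function(node) {
    if (node <= ntip) return(invisible())
    leaves <- ape::extract.clade(tr, node)$tip.label
    is_root <- node == ntip + 1L
    universal <- exclude_universal && length(reference_labels) > 1L &&
      all(reference_labels %in% leaves)
    if (!is_root && !universal && any(reference_labels %in% leaves)) {
      full <- qualifies_full(leaves, node)
      if (!is.null(full)) {
        promote(leaves, node, full, FALSE)
        return(invisible())
      }
      if (qualifies_rescue(leaves)) {
        s1 <- sup1[node - ntip]
        key <- leafset_key(leaves)
        promote(leaves, node,
                c(s1, unname(maps[[1]][key]), unname(maps[[2]][key])), TRUE)
        return(invisible())
      }
    }
    for (child in tr$edge[tr$edge[, 1] == node, 2]) visit(child)
    invisible()
  }
  visit(ntip + 1L)

  members_all <- unlist(lapply(calls, `[[`, "members"))
  if (anyDuplicated(members_all) > 0)
    stop("internal error: promoted clades overlap")
  # deterministic output order, invariant to tree input order when all agree
  calls <- calls[order(vapply(calls, `[[`, character(1), "name"))]
  structure(calls, class = "nps_subfamilies",
            unplaced = sort(setdiff(leaves1, members_all)))
}

#' @export
print.nps_subfamilies <- function(x, ...) {
  cat("nps_subfamilies:", length(x), "subfamily call(s);",
      length(attr(x, "unplaced")), "unplaced leaves\n")
  for (cl in x) {
    cat(sprintf("  %s: %d members, supports (%s)%s\n", cl$name,
                length(cl$members), paste(cl$supports, collapse = ", "),
                if (cl$rescued) ", rescued" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.nps_subfamilies <- function(x, ...) {
  do.call(rbind, lapply(x, function(cl) {
    data.frame(subfamily = cl$name, label = cl$members,
               rescued = cl$rescued, stringsAsFactors = FALSE)
  }))
}

# Parse "<protein>|m<k>" A-domain leaf labels.
parse_domain_label <- function(labels) {
  m <- regmatches(labels, regexec("^(.*)\\|m([0-9]+)$", labels))
  bad <- vapply(m, length, integer(1)) != 3
  if (any(bad))
    stop("unparseable A-domain label(s): ",
         paste(labels[bad], collapse = ", "))
  data.frame(label = labels,
             protein_id = vapply(m, `[`, character(1), 2),
             module = as.integer(vapply(m, `[`, character(1), 3)),
             stringsAsFactors = FALSE)
}

#' Assign genes to subfamilies from their A-domain placements
#'
#' Each gene is assigned to the subfamily holding the majority of its placed
#' A domains. Ties go to the subfamily of the most N-terminal placed A
#' domain. Genes whose placed domains span more than one subfamily are
#' flagged recombinant; genes with no placed domains are assigned to
#' `"Other"`.
#'
#' @param subfamilies an [extract_subfamilies()] result.
#' @param architectures data.frame from [call_architectures()] (defines the
#'   known proteins and their module counts).
#' @return data.frame (protein_id, subfamily, recombinant, n_modules,
#'   n_placed).
#' @export
assign_genes <- function(subfamilies, architectures) {
  memb <- as.data.frame(subfamilies)
  labels <- unlist(lapply(subfamilies, `[[`, "members"))
  parsed <- if (length(labels) > 0) parse_domain_label(labels) else
    data.frame(label = character(0), protein_id = character(0),
               module = integer(0))
  unknown <- setdiff(parsed$protein_id, architectures$protein_id)
  if (length(unknown) > 0)
    stop("A-domain label(s) reference unknown protein(s): ",
         paste(unknown, collapse = ", "))
  sub_of <- setNames(memb$subfamily, memb$label)
  out <- lapply(architectures$protein_id, function(pid) {
    rows <- parsed[parsed$protein_id == pid, , drop = FALSE]
    n_mod <- architectures$module_count[architectures$protein_id == pid]
    if (nrow(rows) == 0) {
      return(data.frame(protein_id = pid, subfamily = "Other",
                        recombinant = FALSE, n_modules = n_mod,
                        n_placed = 0L, stringsAsFactors = FALSE))
    }
    rows <- rows[order(rows$module), , drop = FALSE]
    subs <- unname(sub_of[rows$label])
    tab <- sort(table(subs), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    pick <- if (length(top) == 1L) top else subs[min(which(subs %in% top))]
    data.frame(protein_id = pid, subfamily = pick,
               recombinant = length(unique(subs)) > 1L,
               n_modules = n_mod, n_placed = nrow(rows),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
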