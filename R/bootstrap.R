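#' Neighbor-joining tree with column-bootstrap support
#'
#' Builds the full-data NJ tree from ML pairwise distances, then resamples
#' alignment columns with replacement (to the original length) for each
#' replicate, rebuilds the replicate tree the same way, and annotates every
#' internal edge of the full-data tree with the percentage of replicate
#' trees containing the identical leaf-set bipartition (rounded to the
#' nearest integer). Supports are invariant to the row order of the
#' alignment and reproducible per seed.
#'
#' @param alignment an `AAStringSet` alignment.
#' @param n_replicates bootstrap replicates (>= 1; 200 is the conventional
#'   choice for distance/NJ analyses).
#' @param seed integer seed.
#' @param model [wag_gamma_model()] used for the distances.
#' @param tol distance tolerance for the full-data tree.
#' @return unrooted `phylo` tree with integer supports in `node.label`
#'   (`""` at the root trifurcation).
#' @export
bootstrap_support <- function(alignment, n_replicates = 200L, seed = 1L,
                              model = wag_gamma_model(), tol = 1e-6) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  alignment <- as_alignment(alignment)
  codes <- alignment_codes(alignment)
  main_D <- distance_matrix(alignment, model, tol = tol, method = "golden")
  main <- neighbor_joining(main_D)
  nsites <- ncol(codes)
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(b) {
      cols <- sample.int(nsites, nsites, replace = TRUE)
      sub <- codes[, cols, drop = FALSE]
      D <- dist_ml_core(sub, model$V, model$lambda, model$Vinv, model$rates,
                        1e-6, 10, 1e-3, 1L)
      dimnames(D) <- list(rownames(codes), rownames(codes))
      neighbor_joining(D)
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  sup <- as.character(as.integer(round(100 * counts / n_replicates)))
  # the root of the trifurcating representation carries no subtending edge
  sup[1] <- ""
  main$node.label <- sup
  main
}

#' Root a tree on an outgroup
#'
#' Places the root on the edge subtending the smallest clade containing all
#' outgroup labels, splitting that edge at its midpoint. Supports are
#' re-attached to the same bipartitions. When no single edge separates the
#' outgroup labels (they span the root trifurcation), the root is placed
#' above their most recent common ancestor.
#'
#' @param tree a `phylo` tree (supports in `node.label`).
#' @param outgroup_labels non-empty subset of the tip labels.
#' @return a rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  stopifnot(inherits(tree, "phylo"))
  if (length(outgroup_labels) == 0) stop("empty outgroup")
  if (!all(outgroup_labels %in% tree$tip.label))
    stop("outgroup labels missing from tree: ",
         paste(setdiff(outgroup_labels, tree$tip.label), collapse = ", "))
  if (setequal(outgroup_labels, tree$tip.label))
    stop("outgroup cannot be the whole tree")
  has_labels <- !is.null(tree$node.label)
  # ape's support-preserving rerooting (edgelabel) expects an unrooted tree
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2L)
    tree <- ape::unroot(tree)
  rooted <- tryCatch(
    ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE,
              edgelabel = has_labels),
    error = function(e) {
      node <- ape::getMRCA(tree, outgroup_labels)
      ape::root(tree, node = node, resolve.root = TRUE,
                edgelabel = has_labels)
    })
  # split the original edge at its midpoint: ape::root leaves one of the two
  # root edges at zero length
  ntip <- length(rooted$tip.label)
  root <- ntip + 1L
  kids_e <- which(rooted$edge[, 1] == root)
  if (length(kids_e) == 2 && !is.null(rooted$edge.length)) {
    total <- sum(rooted$edge.length[kids_e])
    rooted$edge.length[kids_e] <- total / 2
  }
  if (has_labels) {
    if (length(rooted$node.label) < rooted$Nnode)
      rooted$node.label <- c(rooted$node.label,
                             rep("", rooted$Nnode - length(rooted$node.label)))
    rooted$node.label[1] <- ""
    # both root children subtend the same bipartition: if the split edge's
    # support landed on only one side, mirror it to the other
    kid_nodes <- rooted$edge[kids_e, 2]
    kid_nodes <- kid_nodes[kid_nodes > ntip]
    if (length(kid_nodes) == 2) {
      labs <- rooted$node.label[kid_nodes - ntip]
      have <- nzchar(labs) & !is.na(labs)
      if (sum(have) == 1)
        rooted$node.label[kid_nodes - ntip][!have] <- labs[have]
    }
  }
  rooted
}
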