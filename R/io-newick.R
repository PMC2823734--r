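#' Read a newick tree
#'
#' Numeric internal-node labels are interpreted as bootstrap support values
#' (the convention used by distance/NJ and ML bootstrap pipelines). Unrooted
#' trees are represented with a trifurcating root node.
#'
#' @param path path to a newick file (exactly one of `path`/`text`).
#' @param text newick string.
#' @return an [ape::phylo] tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(path)) stop("supply 'path' or 'text'")
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("newick parse failure")
  tr
}

# Cheap structural validation giving a character offset, which ape does not.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  prev <- ""
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("unbalanced ')' at character ", i)
      if (prev == ",") stop("dangling comma at character ", i - 1L)
    }
    if (ch == "," && prev %in% c(",", "(")) {
      stop("dangling comma at character ", i)
    }
    if (!ch %in% c(" ", "\t")) prev <- ch
  }
  if (depth != 0L) stop("unbalanced '(' : ", depth, " unclosed at end of input")
  invisible(TRUE)
}

#' Write a tree in newick format
#'
#' Internal-node labels (supports) are emitted on internal edges only; leaf
#' labels are never written as supports.
#'
#' @param tree a `phylo` tree.
#' @param path output path; if `NULL` the newick string is returned.
#' @return the newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Per-node bootstrap support values
#'
#' @param tree a `phylo` tree whose `node.label` holds numeric supports
#'   (empty or non-numeric labels give `NA`).
#' @return numeric vector of length `tree$Nnode`, in internal-node order.
#' @export
support_values <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  out <- suppressWarnings(as.numeric(tree$node.label))
  length(out) <- tree$Nnode  # pads with NA if rooting added a node
  out
}

#' Support of the clade spanned by a set of leaves
#'
#' Returns the support attached to the most recent common ancestor of
#' `labels`, or `NA` if that node is the root or unlabelled. The clade is
#' only reported when its leaf set is exactly `labels`.
#'
#' @param tree rooted `phylo` tree with supports in `node.label`.
#' @param labels leaf labels.
#' @return list with `node`, `support`, and `exact` (leaf set identity).
#' @export
clade_support <- function(tree, labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!all(labels %in% tree$tip.label)) stop("labels not in tree")
  node <- if (length(labels) == 1L) {
    match(labels, tree$tip.label)
  } else {
    ape::getMRCA(tree, labels)
  }
  ntip <- length(tree$tip.label)
  leaves <- if (node <= ntip) tree$tip.label[node] else
    ape::extract.clade(tree, node)$tip.label
  sup <- if (node <= ntip) NA_real_ else support_values(tree)[node - ntip]
  list(node = node, support = sup,
       exact = setequal(leaves, labels))
}
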