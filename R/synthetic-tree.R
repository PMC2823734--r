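#' Simulate an ultrametric Yule species tree
#'
#' Pure-birth tree on `n_taxa` tips, rescaled so every root-to-tip path equals
#' `height` (time units, e.g. millions of years). Reproducible per seed.
#'
#' @param n_taxa number of tips (>= 2).
#' @param height root-to-tip depth, > 0.
#' @param seed integer seed.
#' @param tip_prefix prefix for tip labels (`s1`, `s2`, ...).
#' @return an ultrametric, binary `phylo` tree.
#' @export
simulate_yule_tree <- function(n_taxa, height, seed, tip_prefix = "s") {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (height <= 0) stop("height must be > 0")
  tr <- with_seed(seed, {
    if (n_taxa == 2L) {
      ape::read.tree(text = "(t1:1,t2:1);")
    } else {
      ape::rphylo(n_taxa, birth = 1, death = 0)
    }
  })
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (height / depth)
  tr$tip.label <- paste0(tip_prefix, seq_len(n_taxa))
  tr$node.label <- NULL
  tr
}

# Relative ultrametricity deviation: (max - min root-to-tip depth) / max.
ultrametric_deviation <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) / max(d)
}
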