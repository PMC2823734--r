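#' Generate a triplet of bootstrap-annotated trees with planted clades
#'
#' Emulates trees produced by three phylogenetic methods that agree on a set
#' of planted clades (identical leaf sets, per-tree support values as
#' requested) while differing elsewhere. A base topology is built with the
#' planted clades collapsed to placeholder tips; each of the three trees
#' applies its own random NNI moves to that background (so planted clades and
#' the outgroup can never be broken) before the planted subtrees are grafted
#' back.
#'
#' @param n_background_leaves number of background (unplanted) leaves.
#' @param planted_clades named list of leaf-label character vectors; must be
#'   pairwise disjoint and disjoint from background/outgroup labels.
#' @param supports numeric matrix (3 x n_clades) of support values in
#'   \[0, 100\], or a vector of length 3 recycled across clades, or a single
#'   value.
#' @param seed integer seed.
#' @param n_nni number of random NNI moves applied to each tree's background.
#' @param outgroup optional character vector of outgroup leaf labels, kept
#'   together as an intact clade.
#' @param background_support support range (integer bounds) assigned to
#'   non-planted internal edges.
#' @return list of three `phylo` trees (identical leaf sets).
#' @export
synth_method_trees <- function(n_background_leaves, planted_clades, supports,
                               seed, n_nni = 5L, outgroup = character(0),
                               background_support = c(20L, 60L)) {
  stopifnot(is.list(planted_clades), length(planted_clades) >= 1)
  if (is.null(names(planted_clades)))
    names(planted_clades) <- paste0("clade", seq_along(planted_clades))
  all_planted <- unlist(planted_clades)
  if (anyDuplicated(all_planted) > 0)
    stop("overlapping planted clades")
  k <- length(planted_clades)
  if (is.matrix(supports)) {
    stopifnot(nrow(supports) == 3, ncol(supports) == k)
  } else {
    supports <- matrix(rep(supports, length.out = 3 * k), nrow = 3)
  }
  if (any(supports < 0 | supports > 100)) stop("supports must be in [0, 100]")

  grafts <- planted_clades
  if (length(outgroup) > 0) {
    if (any(outgroup %in% all_planted))
      stop("outgroup labels overlap planted clades")
    grafts <- c(grafts, list(.outgroup. = outgroup))
  }
  placeholders <- paste0(".ph.", names(grafts))
  bg <- if (n_background_leaves > 0) {
    paste0("bg", seq_len(n_background_leaves))
  } else character(0)

  with_seed(seed, {
    base <- ape::rtree(length(placeholders) + length(bg),
                       tip.label = sample(c(placeholders, bg)))
    subtrees <- lapply(grafts, function(labs) {
      if (length(labs) == 1L) return(labs)
      ape::rtree(length(labs), tip.label = sample(labs))
    })
    trees <- lapply(1:3, function(i) {
      bk <- base
      if (n_nni > 0 && bk$Nnode > 2) bk <- phangorn::rNNI(bk, moves = n_nni)
      for (j in seq_along(grafts)) {
        ph <- placeholders[j]
        st <- subtrees[[j]]
        where <- match(ph, bk$tip.label)
        if (is.character(st)) {
          bk$tip.label[where] <- st
        } else {
          bk <- ape::bind.tree(bk, st, where = where)
        }
      }
      bk
    })
    # support annotation: planted clade MRCAs get the requested values,
    # everything else (including the outgroup stem) gets background draws
    # so that only the planted clades qualify at typical cutoffs.
    lapply(seq_along(trees), function(i) {
      tr <- trees[[i]]
      ntip <- length(tr$tip.label)
      lab <- as.character(sample(seq(background_support[1],
                                     background_support[2]),
                                 tr$Nnode, replace = TRUE))
      lab[1] <- ""  # root has no subtending edge
      set_clade <- function(lab, labs, value) {
        if (length(labs) < 2L) return(lab)
        node <- ape::getMRCA(tr, labs)
        lab[node - ntip] <- as.character(value)
        lab
      }
      for (j in seq_len(k)) {
        lab <- set_clade(lab, planted_clades[[j]], round(supports[i, j]))
      }
      tr$node.label <- lab
      tr
    })
  })
}
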