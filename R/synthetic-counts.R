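#' Simulate gene-family counts under a linear birth-death process
#'
#' Evolves integer gene counts along an ultrametric tree under a linear
#' birth-death process with equal per-gene birth and death rate `lambda`
#' (events per gene per time unit). Count 0 is absorbing. Exact Gillespie
#' simulation: along a branch of length t a family with n genes waits an
#' exponential time with rate 2*lambda*n, then gains or loses one gene with
#' equal probability. All internal-node states are recorded as ground truth.
#'
#' @param tree ultrametric `phylo` tree (time-scaled branch lengths).
#' @param lambda birth = death rate per gene per time unit, >= 0.
#' @param root_count integer count at the root, >= 1.
#' @param n_families number of independent families to simulate.
#' @param seed integer seed.
#' @return list with `counts` (an [nps_counts]: species x family, all species
#'   in group "simulated"), `ancestral` (integer matrix, internal nodes x
#'   family, rownames = ape node numbers), `lambda_true`, `root_count`, `seed`.
#' @export
simulate_family_counts <- function(tree, lambda, root_count, n_families, seed) {
  stopifnot(inherits(tree, "phylo"))
  if (lambda < 0) stop("lambda must be >= 0")
  if (root_count < 1) stop("root_count must be >= 1")
  if (n_families < 1) stop("n_families must be >= 1")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  state <- matrix(NA_integer_, ntip + nnode, n_families)
  state[root, ] <- as.integer(root_count)
  # preorder: parents before children
  ord <- rev(ape::postorder(tree))
  with_seed(seed, {
    for (e in ord) {
      par <- tree$edge[e, 1L]
      child <- tree$edge[e, 2L]
      state[child, ] <- gillespie_bd(state[par, ], tree$edge.length[e], lambda)
    }
  })
  # nps_counts orientation: rows species, columns families
  counts <- state[seq_len(ntip), , drop = FALSE]
  dimnames(counts) <- list(tree$tip.label, paste0("fam", seq_len(n_families)))
  cm <- nps_counts(counts, setNames(rep("simulated", ntip), tree$tip.label))
  anc <- state[(ntip + 1L):(ntip + nnode), , drop = FALSE]
  rownames(anc) <- as.character((ntip + 1L):(ntip + nnode))
  colnames(anc) <- colnames(counts)
  list(counts = cm, ancestral = anc, lambda_true = lambda,
       root_count = as.integer(root_count), seed = as.integer(seed))
}

# Vectorized Gillespie for the linear BDP with equal rates: advances a vector
# of counts through time t. Uses the caller's RNG stream.
gillespie_bd <- function(n, t, lambda) {
  n <- as.integer(n)
  if (lambda == 0 || t == 0) return(n)
  remaining <- rep(t, length(n))
  alive <- n > 0L
  while (any(alive)) {
    idx <- which(alive)
    wait <- rexp(length(idx), rate = 2 * lambda * n[idx])
    remaining[idx] <- remaining[idx] - wait
    hit <- idx[remaining[idx] > 0]
    if (length(hit) > 0) {
      step <- ifelse(runif(length(hit)) < 0.5, 1L, -1L)
      n[hit] <- n[hit] + step
    }
    alive[idx] <- remaining[idx] > 0 & n[idx] > 0L
  }
  n
}
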