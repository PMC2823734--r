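#' Neighbor joining with deterministic tie-breaking
#'
#' Standard NJ agglomeration (Saitou & Nei, as in PHYLIP's NEIGHBOR) with two
#' documented contracts: when two pairs minimize the Q criterion within
#' 1e-12, the lexicographically smallest label pair is joined
#' (determinism); negative intermediate branch lengths are clamped to zero
#' with the deficit moved to the sister edge. The returned tree is unrooted,
#' represented with a trifurcating root.
#'
#' @param D symmetric distance matrix (zero diagonal, n >= 3, labels as
#'   dimnames).
#' @param tol asymmetry tolerance.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D, tol = 1e-9) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  }
  if (max(abs(D - t(D))) > tol) stop("asymmetric distance matrix")
  if (any(diag(D) != 0)) stop("nonzero diagonal")
  labels <- rownames(D)
  frag <- setNames(labels, labels)  # newick fragment per active cluster
  active <- D
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (nrow(active) > 3) {
    m <- nrow(active)
    r <- rowSums(active)
    Q <- (m - 2) * active - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(rownames(active)[cand[k, 1]],
                     rownames(active)[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(keys)[1], ]
    i <- min(pick); j <- max(pick)
    dij <- active[i, j]
    vi <- 0.5 * dij + (r[i] - r[j]) / (2 * (m - 2))
    vj <- dij - vi
    # clamp negatives, moving the deficit to the sister edge
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    vi <- max(vi, 0); vj <- max(vj, 0)
    li <- rownames(active)[i]; lj <- rownames(active)[j]
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[li], fmt(vi), frag[lj], fmt(vj))
    dnew <- 0.5 * (active[i, -c(i, j)] + active[j, -c(i, j)] - dij)
    dnew <- pmax(dnew, 0)
    keepn <- rownames(active)[-c(i, j)]
    newlab <- paste0(".nj", m)
    active <- rbind(cbind(active[-c(i, j), -c(i, j), drop = FALSE], dnew),
                    c(dnew, 0))
    rownames(active) <- colnames(active) <- c(keepn, newlab)
    frag <- c(frag[keepn], setNames(newfrag, newlab))
  }
  # final trifurcation
  labs <- rownames(active)
  va <- 0.5 * (active[1, 2] + active[1, 3] - active[2, 3])
  vb <- 0.5 * (active[1, 2] + active[2, 3] - active[1, 3])
  vc <- 0.5 * (active[1, 3] + active[2, 3] - active[1, 2])
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    frag[labs[1]], fmt(va), frag[labs[2]], fmt(vb),
                    frag[labs[3]], fmt(vc))
  ape::read.tree(text = newick)
}
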