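#' Transition probability of the linear birth-death process (equal rates)
#'
#' Probability that a family with `s` genes has `c` genes after time `t`
#' under per-gene birth = death rate `lambda`. Closed form (Bailey): with
#' `alpha = lambda*t / (1 + lambda*t)`,
#' `P(c|s) = sum_{j=0..min(s,c)} C(s,j) C(s+c-j-1, s-1) alpha^(s+c-2j) (1-2*alpha)^j`,
#' with `P(0|0) = 1` and state 0 absorbing. `alpha` is also the extinction
#' probability of a single gene.
#'
#' @param s,c non-negative integer states (vectorized over `c`).
#' @param t elapsed time, >= 0.
#' @param lambda rate per gene per time unit, >= 0.
#' @return probability (same length as `c`).
#' @export
bdp_transition <- function(s, c, t, lambda) {
  if (any(s < 0) || any(c < 0) || t < 0 || lambda < 0)
    stop("negative inputs")
  s <- as.integer(s)
  stopifnot(length(s) == 1L, length(t) == 1L)
  c <- as.integer(c)
  if (lambda == 0 || t == 0) return(as.numeric(c == s))
  if (s == 0L) return(as.numeric(c == 0L))
  a <- lambda * t / (1 + lambda * t)
  one_m2a <- 1 - 2 * a
  vapply(c, function(ci) {
    j <- 0:min(s, ci)
    ljterm <- ifelse(j == 0, 0, j * log(abs(one_m2a)))  # 0*log(0) guard
    terms <- exp(lchoose(s, j) + lchoose(s + ci - j - 1, s - 1) +
                   (s + ci - 2 * j) * log(a) + ljterm)
    terms[!is.finite(terms)] <- 0
    signs <- if (one_m2a < 0) (-1)^j else rep(1, length(j))
    p <- sum(terms * signs)
    min(max(p, 0), 1)
  }, numeric(1))
}

# Full transition matrix over states 0..c_max, rows = starting state. Rows
# are renormalized to correct for state-space truncation when `renormalize`.
bdp_transition_matrix <- function(t, lambda, c_max, renormalize = TRUE) {
  n <- c_max + 1L
  P <- matrix(0, n, n)
  if (lambda == 0 || t == 0) {
    diag(P) <- 1
    return(P)
  }
  a <- lambda * t / (1 + lambda * t)
  one_m2a <- 1 - 2 * a
  la <- log(a)
  labs2a <- if (one_m2a != 0) log(abs(one_m2a)) else -Inf
  P[1, 1] <- 1
  ss <- rep(1:c_max, each = n)
  cc <- rep(0:c_max, times = c_max)
  acc <- numeric(length(ss))
  for (j in 0:c_max) {
    idx <- which(pmin(ss, cc) >= j)
    if (length(idx) == 0) break
    sj <- ss[idx]; cj <- cc[idx]
    lt <- lchoose(sj, j) + lchoose(sj + cj - j - 1, sj - 1) +
      (sj + cj - 2 * j) * la + (if (j == 0) 0 else j * labs2a)
    sign <- if (one_m2a < 0) (-1)^j else 1
    term <- exp(lt) * sign
    term[!is.finite(term)] <- 0
    acc[idx] <- acc[idx] + term
  }
  P[cbind(ss + 1L, cc + 1L)] <- pmin(pmax(acc, 0), 1)
  if (renormalize) P <- P / pmax(rowSums(P), 1e-300)
  P
}

#' Birth-death model specification
#'
#' @param lambda per-gene birth = death rate (events per gene per time unit,
#'   in the time units of the species-tree branch lengths).
#' @param c_max state-space truncation bound (must cover the observed tip
#'   counts; the default used by the fitting functions is twice the maximum
#'   tip count plus 10).
#' @param root_prior prior over root states `1..c_max` (zero is excluded:
#'   an observed family must have existed at the root). Default uniform.
#' @return object of class `nps_bdp`.
#' @export
bdp_model <- function(lambda, c_max, root_prior = NULL) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (c_max < 1) stop("c_max must be >= 1")
  if (is.null(root_prior)) {
    root_prior <- c(0, rep(1 / c_max, c_max))
  } else {
    stopifnot(length(root_prior) == c_max + 1)
    if (root_prior[1] != 0) stop("root prior must exclude state 0")
    if (abs(sum(root_prior) - 1) > 1e-9) stop("root prior must sum to 1")
  }
  structure(list(lambda = lambda, c_max = as.integer(c_max),
                 root_prior = root_prior,
                 cache = new.env(parent = emptyenv())),
            class = "nps_bdp")
}

#' @export
print.nps_bdp <- function(x, ...) {
  cat("birth-death model: lambda =", signif(x$lambda, 4),
      "per gene per time unit, states 0..", x$c_max, "\n")
  invisible(x)
}

# Cached transition matrix for a branch length under a model.
bdp_branch_matrix <- function(model, t) {
  key <- sprintf("%.12g", t)
  if (is.null(model$cache[[key]])) {
    model$cache[[key]] <- bdp_transition_matrix(t, model$lambda, model$c_max)
  }
  model$cache[[key]]
}

check_ultrametric <- function(tree, rel_tol = 1e-6) {
  if (ultrametric_deviation(tree) > rel_tol)
    stop("tree is not ultrametric within tolerance ", rel_tol)
  invisible(TRUE)
}

# Pruning (post-order) likelihoods for a batch of families. counts: matrix
# (tips x families), rows ordered/named by tree$tip.label. Returns the
# per-family log-likelihood vector.
family_loglik_batch <- function(tree, counts, model) {
  ntip <- length(tree$tip.label)
  nfam <- ncol(counts)
  nstate <- model$c_max + 1L
  if (any(counts > model$c_max))
    stop("tip count exceeds c_max; enlarge the state space")
  L <- vector("list", ntip + tree$Nnode)
  logscale <- matrix(0, 1, nfam)
  po <- ape::postorder(tree)
  for (e in po) {
    child <- tree$edge[e, 2L]
    if (child <= ntip && is.null(L[[child]])) {
      M <- matrix(0, nstate, nfam)
      M[cbind(counts[child, ] + 1L, seq_len(nfam))] <- 1
      L[[child]] <- M
    }
  }
  for (e in po) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    Tm <- bdp_branch_matrix(model, tree$edge.length[e])
    contrib <- Tm %*% L[[child]]
    if (is.null(L[[parent]])) {
      L[[parent]] <- contrib
    } else {
      L[[parent]] <- L[[parent]] * contrib
    }
    mx <- apply(L[[parent]], 2, max)
    mx[mx <= 0] <- 1
    L[[parent]] <- sweep(L[[parent]], 2, mx, "/")
    logscale <- logscale + log(mx)
  }
  root <- ntip + 1L
  lik <- as.numeric(model$root_prior %*% L[[root]])
  log(lik) + as.numeric(logscale)
}

#' Log-likelihood of one family's tip counts under a birth-death model
#'
#' Felsenstein pruning over the truncated state space `0..c_max`: leaf
#' vectors are indicators of the observed counts, internal vectors multiply
#' the children's transition-weighted sums, and the root is integrated over
#' the root prior.
#'
#' @param tree ultrametric rooted `phylo` tree (checked to relative
#'   tolerance 1e-6).
#' @param tip_counts named integer vector (all tips present).
#' @param model an [bdp_model()] object.
#' @return the log-likelihood.
#' @export
family_loglikelihood <- function(tree, tip_counts, model) {
  check_ultrametric(tree)
  missing <- setdiff(tree$tip.label, names(tip_counts))
  if (length(missing) > 0)
    stop("tip(s) without count: ", paste(missing, collapse = ", "))
  counts <- matrix(as.integer(tip_counts[tree$tip.label]), ncol = 1,
                   dimnames = list(tree$tip.label, NULL))
  family_loglik_batch(tree, counts, model)
}

#' Estimate the global birth-death rate from a gene count matrix
#'
#' Maximizes the summed family log-likelihoods over `lambda` by bounded
#' scalar search on `[1e-8, 10 / tree height]` (tolerance 1e-8). One global
#' rate is fitted across all families.
#'
#' @param count_matrix an [nps_counts] (rows = species = tree tips, columns
#'   = families) or a plain matrix with species rownames.
#' @param tree ultrametric rooted `phylo` tree.
#' @param c_max state-space bound; default `2 * max(counts) + 10`.
#' @return list of class `nps_bdp_fit`: `lambda_hat`, `loglik`, `model` (an
#'   [bdp_model()] at the estimate), `c_max`.
#' @export
estimate_lambda <- function(count_matrix, tree, c_max = NULL) {
  counts <- if (inherits(count_matrix, "nps_counts")) count_matrix$counts
  else as.matrix(count_matrix)
  check_ultrametric(tree)
  missing <- setdiff(tree$tip.label, rownames(counts))
  if (length(missing) > 0)
    stop("species missing from count matrix: ",
         paste(missing, collapse = ", "))
  counts <- counts[tree$tip.label, , drop = FALSE]
  if (ncol(counts) < 1) stop("need at least one family")
  extinct <- colSums(counts) == 0
  if (any(extinct))
    stop("family extinct at every tip: ",
         paste(colnames(counts)[extinct], collapse = ", "))
  if (is.null(c_max)) c_max <- 2L * max(counts) + 10L
  height <- max(ape::node.depth.edgelength(tree))
  obj <- function(lam) {
    model <- bdp_model(lam, c_max)
    -sum(family_loglik_batch(tree, counts, model))
  }
  lower <- 1e-8
  upper <- 10 / height
  opt <- optimize(obj, c(lower, upper), tol = 1e-8)
  lambda_hat <- opt$minimum
  all_const <- all(apply(counts, 2, function(x) length(unique(x)) == 1))
  if (all_const && lambda_hat <= 1e-6) {
    warning("all families constant and equal: lambda at the lower bound")
  }
  structure(list(lambda_hat = lambda_hat, loglik = -opt$objective,
                 model = bdp_model(lambda_hat, c_max), c_max = c_max,
                 height = height),
            class = "nps_bdp_fit")
}

#' @export
print.nps_bdp_fit <- function(x, ...) {
  cat("birth-death fit: lambda_hat =", signif(x$lambda_hat, 4),
      " (log-likelihood", round(x$loglik, 2), ")\n")
  invisible(x)
}

#' Parsimony ancestral count at the root
#'
#' Sankoff dynamic programming with cost `|change|` per edge; returns the
#' minimum-cost root state (the smallest state on ties). Families inferred
#' to have zero genes at the root violate the birth-death model's assumption
#' of presence in the common ancestor and are excluded from fitting.
#'
#' @param tree rooted `phylo` tree.
#' @param tip_counts named integer vector.
#' @param max_state cap of the evaluated state range (default: max count).
#' @return integer root state.
#' @export
parsimony_root_count <- function(tree, tip_counts, max_state = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(max_state)) max_state <- max(tip_counts)
  states <- 0:max_state
  nn <- ntip + tree$Nnode
  cost <- matrix(Inf, nn, length(states))
  for (i in seq_len(ntip)) {
    cost[i, ] <- abs(states - tip_counts[[tree$tip.label[i]]])
  }
  cost_edge <- outer(states, states, function(a, b) abs(a - b))
  po <- ape::postorder(tree)
  seen <- rep(FALSE, nn)
  for (e in po) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    trans <- apply(cost_edge + rep(cost[child, ], each = length(states)),
                   1, min)
    if (!seen[parent]) {
      cost[parent, ] <- 0
      seen[parent] <- TRUE
    }
    cost[parent, ] <- cost[parent, ] + trans
  }
  root <- ntip + 1L
  states[which.min(cost[root, ])]
}

# Simulate tip-count columns for n families from the model's root prior
# down the tree (transition-row sampling). Returns matrix tips x n.
simulate_bdp_tips <- function(tree, model, n) {
  ntip <- length(tree$tip.label)
  nstate <- model$c_max + 1L
  state <- matrix(NA_integer_, ntip + tree$Nnode, n)
  state[ntip + 1L, ] <- sample.int(nstate, n, replace = TRUE,
                                   prob = model$root_prior) - 1L
  for (e in rev(ape::postorder(tree))) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    Tm <- bdp_branch_matrix(model, tree$edge.length[e])
    ps <- state[parent, ]
    out <- integer(n)
    for (s in unique(ps)) {
      idx <- which(ps == s)
      out[idx] <- sample.int(nstate, length(idx), replace = TRUE,
                             prob = Tm[s + 1L, ]) - 1L
    }
    state[child, ] <- out
  }
  m <- state[seq_len(ntip), , drop = FALSE]
  rownames(m) <- tree$tip.label
  m
}

#' Monte-Carlo family p-value under the fitted birth-death model
#'
#' Simulates `n_resamples` families from the root prior under the fitted
#' rate on the same tree (conditioned on non-extinction, like observable
#' families) and reports the proportion whose log-likelihood is at or below
#' the observed family's, with the add-one rule so p lies in
#' `[1/(n+1), 1]`.
#'
#' @param tree ultrametric rooted `phylo` tree.
#' @param tip_counts named integer vector for the observed family.
#' @param model fitted [bdp_model()].
#' @param n_resamples number of simulated families (>= 100).
#' @param seed integer seed.
#' @param null_logliks optional pre-computed vector of simulated-family
#'   log-likelihoods (shared across families for speed).
#' @return the p-value.
#' @export
family_pvalue <- function(tree, tip_counts, model, n_resamples = 1000L,
                          seed = 1L, null_logliks = NULL) {
  if (is.null(null_logliks)) {
    if (n_resamples < 100) stop("n_resamples must be >= 100")
    null_logliks <- bdp_null_logliks(tree, model, n_resamples, seed)
  }
  obs <- family_loglikelihood(tree, tip_counts, model)
  n <- length(null_logliks)
  (1 + sum(null_logliks <= obs)) / (n + 1)
}

#' Null log-likelihood sample for [family_pvalue()]
#'
#' @inheritParams family_pvalue
#' @param n number of non-extinct simulated families.
#' @return numeric vector of length `n`.
#' @export
bdp_null_logliks <- function(tree, model, n, seed) {
  check_ultrametric(tree)
  sims <- with_seed(seed, {
    acc <- NULL
    tries <- 0L
    while (is.null(acc) || ncol(acc) < n) {
      tries <- tries + 1L
      if (tries > 1000L) stop("could not simulate non-extinct families")
      m <- simulate_bdp_tips(tree, model, n)
      m <- m[, colSums(m) > 0, drop = FALSE]
      acc <- if (is.null(acc)) m else cbind(acc, m)
    }
    acc[, seq_len(n), drop = FALSE]
  })
  family_loglik_batch(tree, sims, model)
}

#' Viterbi ancestral counts and per-branch transition p-values
#'
#' Most probable joint assignment of ancestral counts (max-product dynamic
#' programming over the truncated state space; ties resolved to the smaller
#' state). For each edge with parent state `s`, child state `c` and length
#' `t`, the branch p-value is the total probability of child states no more
#' probable than the observed one, `sum over c' with P(c'|s,t) <= P(c|s,t)`;
#' the direction is `expansion` when `c > s`, `contraction` when `c < s`.
#'
#' @param tree ultrametric rooted `phylo` tree.
#' @param tip_counts named integer vector.
#' @param model fitted [bdp_model()].
#' @return list with `ancestral_counts` (named by internal node number) and
#'   `branch_p` (data.frame: parent, child, child_label, time,
#'   parent_count, child_count, p_value, direction).
#' @export
viterbi_branch_pvalues <- function(tree, tip_counts, model) {
  check_ultrametric(tree)
  ntip <- length(tree$tip.label)
  nstate <- model$c_max + 1L
  missing <- setdiff(tree$tip.label, names(tip_counts))
  if (length(missing) > 0)
    stop("tip(s) without count: ", paste(missing, collapse = ", "))
  nn <- ntip + tree$Nnode
  best <- matrix(-Inf, nn, nstate)      # best log-prob of subtree given state
  for (i in seq_len(ntip)) {
    best[i, ] <- -Inf
    best[i, tip_counts[[tree$tip.label[i]]] + 1L] <- 0
  }
  argmax <- vector("list", nn)          # per child: best child state by parent state
  po <- ape::postorder(tree)
  seen <- rep(FALSE, nn)
  for (e in po) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    logT <- log(bdp_branch_matrix(model, tree$edge.length[e]))
    tot <- sweep(logT, 2, best[child, ], "+")  # parent x childstate
    am <- max.col(replace(tot, !is.finite(tot), -1e300), ties.method = "first")
    mx <- tot[cbind(seq_len(nstate), am)]
    argmax[[child]] <- am
    if (!seen[parent]) {
      best[parent, ] <- 0
      seen[parent] <- TRUE
    }
    best[parent, ] <- best[parent, ] + mx
  }
  root <- ntip + 1L
  root_score <- log(model$root_prior) + best[root, ]
  state <- integer(nn)
  state[root] <- which.max(root_score) - 1L
  for (e in rev(po)) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    state[child] <- argmax[[child]][state[parent] + 1L] - 1L
  }
  anc <- setNames(state[(ntip + 1L):nn], as.character((ntip + 1L):nn))
  rows <- lapply(seq_len(nrow(tree$edge)), function(e) {
    parent <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    s <- state[parent]; cst <- state[child]
    row <- bdp_branch_matrix(model, t_e)[s + 1L, ]
    p <- sum(row[row <= row[cst + 1L] * (1 + 1e-12)])
    data.frame(parent = parent, child = child,
               child_label = if (child <= ntip) tree$tip.label[child] else
                 as.character(child),
               time = t_e, parent_count = s, child_count = cst,
               p_value = min(p, 1),
               direction = if (cst > s) "expansion" else
                 if (cst < s) "contraction" else "none",
               stringsAsFactors = FALSE)
  })
  list(ancestral_counts = anc, branch_p = do.call(rbind, rows))
}

#' Full birth-death analysis of a gene count matrix
#'
#' Applies the parsimony root filter (families with parsimony root count 0
#' are excluded), fits the global rate, and computes per-family Monte-Carlo
#' p-values and per-branch Viterbi p-values.
#'
#' @param count_matrix an [nps_counts] (species x families).
#' @param tree ultrametric rooted `phylo` over the species.
#' @param n_resamples resamples for the family p-values.
#' @param seed integer seed.
#' @param significance flag threshold for branches and families.
#' @return list of class `nps_bdp_report`: `fit`, `families` (data.frame
#'   with log-likelihoods and p-values), `branches` (per family list of
#'   branch tables), `excluded` (families failing the root filter), `seed`,
#'   `n_resamples`.
#' @export
bd_analyze <- function(count_matrix, tree, n_resamples = 1000L, seed = 1L,
                       significance = 0.05) {
  stopifnot(inherits(count_matrix, "nps_counts"))
  counts <- count_matrix$counts[tree$tip.label, , drop = FALSE]
  root0 <- vapply(colnames(counts), function(f)
    parsimony_root_count(tree, setNames(counts[, f], rownames(counts))),
    numeric(1))
  excluded <- colnames(counts)[root0 == 0]
  keep <- setdiff(colnames(counts), excluded)
  if (length(keep) == 0) stop("no families with nonzero parsimony root")
  fit <- estimate_lambda(counts[, keep, drop = FALSE], tree)
  null_ll <- bdp_null_logliks(tree, fit$model, n_resamples,
                              derive_seed(seed, 71L))
  fams <- lapply(keep, function(f) {
    tc <- setNames(counts[, f], rownames(counts))
    ll <- family_loglikelihood(tree, tc, fit$model)
    p <- (1 + sum(null_ll <= ll)) / (length(null_ll) + 1)
    vit <- viterbi_branch_pvalues(tree, tc, fit$model)
    list(family = f, loglik = ll, p_value = p, viterbi = vit)
  })
  families <- data.frame(
    family = keep,
    loglik = vapply(fams, `[[`, numeric(1), "loglik"),
    p_value = vapply(fams, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  families$significant <- families$p_value < significance
  branches <- setNames(lapply(fams, function(x) x$viterbi$branch_p), keep)
  ancestral <- setNames(lapply(fams, function(x) x$viterbi$ancestral_counts),
                        keep)
  structure(list(fit = fit, families = families, branches = branches,
                 ancestral = ancestral, excluded = excluded,
                 seed = as.integer(seed),
                 n_resamples = as.integer(n_resamples),
                 significance = significance),
            class = "nps_bdp_report")
}

#' @export
print.nps_bdp_report <- function(x, ...) {
  cat("birth-death report: lambda_hat =", signif(x$fit$lambda_hat, 4), "\n")
  cat("  families:", nrow(x$families), "analyzed,",
      sum(x$families$significant), "significant at p <", x$significance,
      ";", length(x$excluded), "excluded by the parsimony root filter\n")
  invisible(x)
}
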