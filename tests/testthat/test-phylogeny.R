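test_that("WAG+gamma model is a proper scaled reversible model", {
  m <- wag_gamma_model(1)
  expect_equal(sum(m$frequencies), 1, tolerance = 1e-12)
  expect_equal(mean(m$rates), 1, tolerance = 1e-9)
  expect_equal(-sum(m$frequencies * diag(m$Q)), 1, tolerance = 1e-9)
  P <- npsphylome:::model_transition(m, 0.7)
  expect_equal(rowSums(P), rep(1, 20), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("pairwise ML distance behaves on identical and symmetric input", {
  m <- wag_gamma_model(1)
  s <- "ACDEFGHIKLMNPQRSTVWY"
  expect_lte(wag_gamma_distance(s, s, m), 1e-5)
  pair <- simulate_wag_pair(300, 0.8, m, seed = 4)
  expect_equal(wag_gamma_distance(pair$seq1, pair$seq2, m),
               wag_gamma_distance(pair$seq2, pair$seq1, m), tolerance = 1e-6)
  expect_error(wag_gamma_distance("-X", "A-", m), "zero comparable")
})

test_that("distance estimator recovers the simulated distance", {
  m <- wag_gamma_model(1)
  pair <- simulate_wag_pair(10000, 0.5, m, seed = 42)
  d <- wag_gamma_distance(pair$seq1, pair$seq2, m)
  expect_lt(abs(d - 0.5), 0.05)
  # estimator error shrinks with alignment length
  err_at <- function(n) {
    median(vapply(1:5, function(r) {
      p <- simulate_wag_pair(n, 0.5, m, seed = 100 * n + r)
      abs(wag_gamma_distance(p$seq1, p$seq2, m) - 0.5)
    }, numeric(1)))
  }
  errs <- c(err_at(500), err_at(2000), err_at(8000))
  expect_lt(errs[3], errs[1])
})

test_that("distance matrix agrees with an independent ML implementation", {
  m <- wag_gamma_model(1)
  set.seed(8)
  rows <- lapply(1:5, function(i) simulate_wag_pair(400, 0.4, m,
                                                    seed = 70 + i)$seq2)
  aln <- Biostrings::AAStringSet(setNames(unlist(rows), paste0("s", 1:5)))
  D <- distance_matrix(aln, m)
  pd <- phangorn::dist.ml(
    phangorn::phyDat(strsplit(setNames(as.character(aln), names(aln)), ""),
                     type = "AA"),
    model = "WAG", k = 4, shape = 1)
  expect_equal(D[lower.tri(D)], as.vector(pd), tolerance = 0.01)
  # grid method is topology-grade close to the golden-section result
  Dg <- distance_matrix(aln, m, method = "grid")
  expect_equal(Dg, D, tolerance = 0.05)
})

test_that("NJ reproduces the closed-form 3-taxon solution exactly", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 1)
  expect_equal(el[["B"]], 1)
  expect_equal(el[["C"]], 3)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  Dbad <- D; Dbad[1, 2] <- 3
  expect_error(neighbor_joining(Dbad), "asymmetric")
})

test_that("NJ recovers additive 4-taxon trees with exact edge lengths", {
  # AB|CD with internal edge 0.5
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  pend <- c(a = 1, b = 2, c = 1.5, d = 0.7)
  D["a", "b"] <- D["b", "a"] <- pend["a"] + pend["b"]
  for (x in c("a", "b")) for (y in c("c", "d")) {
    D[x, y] <- D[y, x] <- pend[[x]] + pend[[y]] + 0.5
  }
  D["c", "d"] <- D["d", "c"] <- pend["c"] + pend["d"]
  tr <- neighbor_joining(D)
  expect_equal(stats::cophenetic(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-8)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))
})

test_that("NJ is topology-consistent on additive matrices (oracle loop)", {
  for (seed in 1:50) {
    ra <- random_additive(8, seed)
    tr <- neighbor_joining(ra$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ra$tree), tr)), 0)
  }
  # cross-check against ape's reference NJ on a larger instance
  ra <- random_additive(12, 1234)
  expect_equal(as.numeric(ape::dist.topo(neighbor_joining(ra$D),
                                         ape::nj(ra$D))), 0)
})

test_that("bootstrap supports are valid, deterministic, and strong for
           well-separated planted clades", {
  pb <- synth_proteome(c(X = "A", Y = "A"), c(X = 5, Y = 5),
                       divergence = 0.05, seed = 3, species = "s1",
                       outgroup_count = 3)
  alns <- pb$seed_alignments
  pA <- build_profile(do.call(c, unname(alns[grep("^A_", names(alns))])),
                      "A", calib_seed = 2)
  hits <- scan_proteome(list(A = pA), pb$proteins)
  archs <- call_architectures(hits, seq_ids(pb$proteins))
  ad <- extract_a_domains(pb$proteins, archs)
  aln <- align_to_profile(ad, pA$length)
  bt <- bootstrap_support(aln, n_replicates = 100, seed = 9)
  sup <- support_values(bt)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  rooted <- root_with_outgroup(bt, grep("OUTGROUP", bt$tip.label,
                                        value = TRUE))
  for (grp in c("_X_", "_Y_")) {
    cs <- clade_support(rooted, grep(grp, rooted$tip.label, value = TRUE))
    expect_true(cs$exact)
    expect_gte(cs$support, 95)
  }
  # determinism and row-order invariance
  bt2 <- bootstrap_support(aln, n_replicates = 100, seed = 9)
  expect_identical(write_newick(bt), write_newick(bt2))
  perm <- rev(seq_along(aln))
  bt3 <- bootstrap_support(aln[perm], n_replicates = 100, seed = 9)
  key <- function(t) {
    m <- npsphylome:::clade_support_map(t)
    m[order(names(m))]
  }
  expect_equal(key(bt3), key(bt))
})

test_that("outgroup rooting splits the subtending edge at its midpoint", {
  tr <- read_newick(text = "(A:1,B:1,(C:1,D:1)77:2);")
  r1 <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(r1))
  expect_true(ape::is.monophyletic(r1, c("B", "C", "D")))
  r2 <- root_with_outgroup(tr, c("C", "D"))
  kids <- which(r2$edge[, 1] == length(r2$tip.label) + 1)
  expect_equal(r2$edge.length[kids][1], r2$edge.length[kids][2])
  expect_equal(sum(r2$edge.length[kids]), 2)
  expect_setequal(r2$tip.label, tr$tip.label)
  # support stays with its bipartition
  cs <- clade_support(r2, c("C", "D"))
  expect_true(cs$exact)
  expect_equal(cs$support, 77)
  expect_error(root_with_outgroup(tr, character(0)), "empty outgroup")
})
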