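make_triplet <- function(clades, supports, seed, outgroup = c("og1", "og2"),
                         n_nni = 3, n_bg = 6) {
  trs <- synth_method_trees(n_bg, clades, supports, seed = seed,
                            n_nni = n_nni, outgroup = outgroup)
  lapply(trs, root_with_outgroup, outgroup_labels = outgroup)
}

test_that("a consistently supported reference clade yields one call", {
  clades <- list(EAS = paste0("e", 1:5, "|m1"))
  trs <- make_triplet(clades, 90, seed = 21, n_nni = 0)
  sf <- extract_subfamilies(trs, "e1|m1", cutoff = 70)
  expect_length(sf, 1)
  expect_setequal(sf[[1]]$members, clades$EAS)
  expect_false(sf[[1]]$rescued)
  expect_equal(sf[[1]]$supports, c(90, 90, 90))
})

test_that("a clade must reach the cutoff in every tree", {
  clades <- list(EAS = paste0("e", 1:5, "|m1"))
  trs <- make_triplet(clades, matrix(c(90, 90, 65), 3, 1), seed = 22)
  expect_length(extract_subfamilies(trs, "e1|m1", cutoff = 70), 0)
  # per-tree cutoffs cover the lenient NJ reading
  sf <- extract_subfamilies(trs, "e1|m1", cutoff = c(70, 70, 50))
  expect_length(sf, 1)
})

test_that("reduced-dataset rescue promotes the borderline clade", {
  clades <- list(SID = paste0("h", 1:4, "|m1"))
  # enough background NNI moves that the three methods genuinely disagree
  # outside the planted clade
  full <- make_triplet(clades, matrix(c(68, 74, 45), 3, 1), seed = 6,
                       n_nni = 8)
  rescue <- make_triplet(clades, matrix(c(85, 88, 90), 3, 1), seed = 7,
                         outgroup = "og1", n_bg = 2)
  expect_length(extract_subfamilies(full, "h1|m1", cutoff = 70), 0)
  sf <- extract_subfamilies(full, "h1|m1", cutoff = 70,
                            rescue_trees = rescue, rescue_cutoff = 80)
  expect_length(sf, 1)
  expect_true(sf[[1]]$rescued)
  expect_setequal(sf[[1]]$members, clades$SID)
  # rescue at a higher cutoff than the rescue supports fails
  expect_length(extract_subfamilies(full, "h1|m1", cutoff = 70,
                                    rescue_trees = rescue,
                                    rescue_cutoff = 95), 0)
})

test_that("planted triplets are recovered with precision and recall 1", {
  clades <- list(EAS = paste0("e", 1:6, "|m1"), SID = paste0("s", 1:5, "|m1"),
                 CYC = paste0("c", 1:4, "|m1"), AAR = paste0("a", 1:3, "|m1"))
  trs <- make_triplet(clades, 92, seed = 4, n_nni = 4)
  refs <- vapply(clades, `[`, character(1), 1)
  sf <- extract_subfamilies(trs, unname(refs), cutoff = 70)
  got <- lapply(sf, `[[`, "members")
  hits <- vapply(clades, function(cl)
    any(vapply(got, function(g) setequal(g, cl), logical(1))), logical(1))
  recall <- mean(hits)
  precision <- mean(vapply(got, function(g)
    any(vapply(clades, function(cl) setequal(g, cl), logical(1))),
    logical(1)))
  expect_equal(recall, 1)
  expect_equal(precision, 1)
  # promoted clades are pairwise disjoint
  expect_equal(anyDuplicated(unlist(got)), 0L)
  # result is invariant to the order of the (agreeing) trees
  sf2 <- extract_subfamilies(trs[c(3, 1, 2)], unname(refs), cutoff = 70)
  expect_identical(lapply(sf2, `[[`, "members"), got)
})

test_that("leaf-set mismatches across trees are reported", {
  clades <- list(EAS = paste0("e", 1:4, "|m1"))
  trs <- make_triplet(clades, 90, seed = 30)
  trs[[2]] <- ape::drop.tip(trs[[2]], "bg1")
  expect_error(extract_subfamilies(trs, "e1|m1"), "bg1")
})

test_that("gene assignment handles majority, ties, and recombinants", {
  calls <- structure(list(
    list(name = "EAS", members = c("g1|m1", "g1|m3", "e1|m1"),
         supports = c(90, 90, 90), references = "e1|m1", rescued = FALSE),
    list(name = "CYCLO", members = c("g1|m2", "c1|m1"),
         supports = c(90, 90, 90), references = "c1|m1", rescued = FALSE)),
    class = "nps_subfamilies", unplaced = character(0))
  archs <- data.frame(protein_id = c("g1", "e1", "c1", "t2", "lone"),
                      architecture = "A", module_count = c(3L, 1L, 1L, 2L, 1L))
  # 3-module gene with modules (EAS, CYCLO, EAS): majority EAS, recombinant
  asg <- assign_genes(calls, archs)
  g1 <- asg[asg$protein_id == "g1", ]
  expect_equal(g1$subfamily, "EAS")
  expect_true(g1$recombinant)
  # monomodular reference gene
  expect_equal(asg$subfamily[asg$protein_id == "c1"], "CYCLO")
  expect_false(asg$recombinant[asg$protein_id == "c1"])
  # unplaced gene goes to Other
  expect_equal(asg$subfamily[asg$protein_id == "lone"], "Other")
  # 2-module tie: the N-terminal module's subfamily wins, flagged recombinant
  calls2 <- calls
  calls2[[1]]$members <- c(calls2[[1]]$members, "t2|m2")
  calls2[[2]]$members <- c(calls2[[2]]$members, "t2|m1")
  asg2 <- assign_genes(calls2, archs)
  t2 <- asg2[asg2$protein_id == "t2", ]
  expect_equal(t2$subfamily, "CYCLO")
  expect_true(t2$recombinant)
  # labels referencing unknown proteins are an error
  calls3 <- calls
  calls3[[1]]$members <- c(calls3[[1]]$members, "ghost|m1")
  expect_error(assign_genes(calls3, archs), "ghost")
})
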