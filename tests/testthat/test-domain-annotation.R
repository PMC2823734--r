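test_that("profiles score their own consensus far above the null", {
  tb <- tiny_bundle()
  for (p in tb$profiles) {
    cal <- p$calibration
    expect_gt(p$self_score, cal[["mu"]] + 5 * cal[["scale"]])
  }
  # single-sequence alignment: pseudocount smoothing, positive on observed
  p1 <- build_profile(Biostrings::AAStringSet(c(s = "ACD")), "other:tiny",
                      calibrate = FALSE)
  expect_equal(p1$length, 3L)
  expect_gt(p1$match["A", 1], 0)
  expect_gt(p1$match["C", 2], 0)
  expect_gt(p1$match["D", 3], 0)
  expect_lt(p1$match["W", 1], 0)
  # gap-rich columns are dropped from match states
  p2 <- build_profile(Biostrings::AAStringSet(c(a = "A-C", b = "A-C",
                                                c = "A-C")),
                      "other:gappy", calibrate = FALSE)
  expect_equal(p2$length, 2L)
  expect_error(build_profile(Biostrings::AAStringSet(), "A"), "empty")
})

test_that("scanning recovers planted domains at their coordinates", {
  tb <- tiny_bundle()
  truth <- tb$bundle$truth
  hits <- tb$hits
  a_truth <- truth[truth$domain_type == "A" & !truth$degenerate, ]
  found <- 0
  for (i in seq_len(nrow(a_truth))) {
    h <- hits[hits$protein_id == a_truth$protein_id[i] &
                hits$domain_type == "A", ]
    ov <- pmin(h$end, a_truth$end[i]) - pmax(h$start, a_truth$start[i])
    if (any(ov >= 0.9 * (a_truth$end[i] - a_truth$start[i]))) found <- found + 1
  }
  expect_gte(found / nrow(a_truth), 0.95)
  # coordinates in bounds and sorted by start per protein
  widths <- setNames(Biostrings::width(tb$bundle$proteins),
                     seq_ids(tb$bundle$proteins))
  for (pid in unique(hits$protein_id)) {
    h <- hits[hits$protein_id == pid, ]
    expect_true(all(h$start >= 0 & h$end <= widths[[pid]]))
  }
  # trivially short protein
  expect_equal(nrow(scan_protein(tb$profiles$A, "ACDEF")), 0L)
})

test_that("e-values decrease monotonically with bit score", {
  tb <- tiny_bundle()
  p <- tb$profiles$A
  scores <- seq(10, 500, by = 10)
  ev <- profile_evalue(p, scores, protein_length = 1000)
  expect_true(all(diff(ev) < 0))
  expect_error(profile_evalue(build_profile(
    Biostrings::AAStringSet(c(s = "ACD")), "x", calibrate = FALSE), 10, 100),
    "not calibrated")
})

test_that("shuffled sequences rarely produce e < 1 hits", {
  tb <- tiny_bundle()
  p <- tb$profiles$A
  prot <- as.character(tb$bundle$proteins[[1]])
  set.seed(777)
  n_hit <- 0
  for (i in 1:100) {
    shuf <- paste(sample(strsplit(prot, "")[[1]]), collapse = "")
    h <- scan_protein(p, shuf, e_value_max = 1)
    if (nrow(h) > 0) n_hit <- n_hit + 1
  }
  expect_lte(n_hit, 10)
})

test_that("architecture calling resolves overlaps and renders dA", {
  # manufactured hit sets
  mk <- function(type, s, e, score, degen = FALSE)
    data.frame(protein_id = "p", domain_type = type, start = s, end = e,
               prof_start = 0L, prof_end = e - s, bit_score = score,
               e_value = 1e-9, degenerate = degen)
  h <- rbind(mk("A", 0, 480, 900), mk("T", 500, 580, 300),
             mk("C", 600, 1030, 800))
  arch <- call_architecture(h)
  expect_equal(arch$architecture, "A-T-C")
  expect_equal(arch$module_count, 1L)
  # overlapping hits: higher score wins when overlap > 30% of the shorter
  h2 <- rbind(mk("A", 0, 480, 900), mk("C", 100, 530, 500))
  expect_equal(call_architecture(h2)$architecture, "A")
  # <=30% overlap of the shorter hit: both kept
  h3 <- rbind(mk("A", 0, 480, 900), mk("T", 456, 536, 300))
  expect_equal(call_architecture(h3)$architecture, "A-T")
  # degenerate A renders dA and counts as a module
  h4 <- rbind(mk("A", 0, 480, 900), mk("A", 500, 740, 300, degen = TRUE))
  a4 <- call_architecture(h4)
  expect_equal(a4$architecture, "A-dA")
  expect_equal(a4$module_count, 2L)
  # empty
  a0 <- call_architecture(mk("A", 0, 1, 1)[0, ], protein_id = "none")
  expect_equal(a0$architecture, "")
  expect_equal(a0$module_count, 0L)
})

test_that("planted architectures are called exactly", {
  tb <- tiny_bundle()
  want <- truth_archs(tb$bundle$truth)
  got <- setNames(tb$archs$architecture, tb$archs$protein_id)[names(want)]
  ok <- mean(got == want)
  expect_gte(ok, 0.95)
  # the degenerate-A module architecture and standalone A in particular
  expect_identical(unname(got["s1_EAS_g1"]), "A-T-C-dA-T-C")
  expect_identical(unname(got["s1_NPS12_g1"]), "A")
  expect_equal(tb$archs$module_count[tb$archs$protein_id == "s1_EAS_g1"], 2L)
})

test_that("candidate screening follows the support and outgroup rules", {
  mk_tree <- function(support) read_newick(text = sprintf(
    "(((ref1:1,(q1:1,(q2:1,q3:1)40:1)50:1)55:1,ref2:1)%d:1,(og1:1,og2:1)60:1,bg1:2);",
    support))
  tr <- mk_tree(95)
  acc <- screen_candidates(tr, c("ref1", "ref2"), c("og1", "og2"), 90)
  expect_setequal(acc, c("q1", "q2", "q3"))
  # qualifying clade support 85 at cutoff 90: nothing accepted
  tr85 <- mk_tree(85)
  expect_length(screen_candidates(tr85, c("ref1", "ref2"),
                                  c("og1", "og2"), 90), 0)
  # a leaf inside the outgroup clade is never accepted
  expect_false(any(c("og1", "og2") %in% acc))
  # a reference nested inside the outgroup clade splits the references
  # across the root after rooting
  tr2 <- read_newick(
    text = "(((og1:1,(og2:1,ref2:1)50:1)90:1,ref1:1)90:1,q1:1,q2:1);")
  expect_error(screen_candidates(tr2, c("ref1", "ref2"), c("og1", "og2")),
               "no qualifying clade")
})
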