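test_that("count matrices are built from assignments with zero rows kept", {
  asg <- data.frame(protein_id = c("p1", "p2", "p3"),
                    subfamily = c("EAS", "EAS", "SID"))
  species_of <- c(p1 = "spA", p2 = "spB", p3 = "spA", p4 = "spC")
  group_of <- c(spA = "G1", spB = "G1", spC = "G2")
  cm <- build_count_matrix(asg, species_of, group_of)
  expect_equal(cm$counts["spA", "EAS"], 1L)
  expect_equal(cm$counts["spB", "EAS"], 1L)
  expect_equal(sum(cm$counts["spC", ]), 0L)   # species with no genes
  expect_error(build_count_matrix(asg, species_of[-1], group_of), "p1")
  expect_error(build_count_matrix(asg, species_of,
                                  group_of[c("spA", "spB")]), "spC")
})

test_that("the 3,0,0,3 table gives exactly p = 0.05 one-sided", {
  cm <- nps_counts(matrix(c(3L, 0L, 0L, 3L), 2, 2,
                          dimnames = list(c("x", "y"), c("S", "o"))),
                   c(x = "G1", y = "G2"))
  ft <- fisher_overrepresentation(cm, "G1", "S")
  expect_equal(ft$p_value, 1 / 20)   # C(3,3)*C(3,0)/C(6,3)
  expect_equal(unname(ft$table), c(3, 0, 0, 3))
})

test_that("one-sided p equals exhaustive hypergeometric enumeration", {
  brute_greater <- function(a, b, cc, d) {
    # all tables with the same margins and a' >= a
    lo <- max(0, (a + cc) - (cc + d)); hi <- min(a + b, a + cc)
    sum(vapply(lo:hi, function(ap)
      if (ap >= a) dhyper(ap, a + b, cc + d, a + cc) else 0, numeric(1)))
  }
  set.seed(2024)
  for (i in 1:300) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b == 0 || a + cc == 0 || a + b + cc + d == 0) next
    cm <- nps_counts(matrix(c(a, b, cc, d), 2, 2, byrow = TRUE,
                            dimnames = list(c("x", "y"), c("S", "o"))),
                     c(x = "G1", y = "G2"))
    ft <- fisher_overrepresentation(cm, "G1", "S")
    expect_equal(ft$p_value, brute_greater(a, b, cc, d), tolerance = 1e-12)
    # and equals the reference implementation
    ref <- stats::fisher.test(matrix(c(a, cc, b, d), 2),
                              alternative = "greater")$p.value
    expect_equal(ft$p_value, ref, tolerance = 1e-9)
    ref2 <- stats::fisher.test(matrix(c(a, cc, b, d), 2))$p.value
    ft2 <- fisher_overrepresentation(cm, "G1", "S", sided = "two.sided")
    expect_equal(ft2$p_value, ref2, tolerance = 1e-7)
  }
})

test_that("p is invariant under transposing group and subfamily", {
  cm <- nps_counts(matrix(c(5L, 2L, 1L, 9L), 2, 2, byrow = TRUE,
                          dimnames = list(c("x", "y"), c("S", "o"))),
                   c(x = "G1", y = "G2"))
  p1 <- fisher_overrepresentation(cm, "G1", "S")$p_value
  # transposed table: species <-> subfamily roles swapped
  cmT <- nps_counts(matrix(c(5L, 1L, 2L, 9L), 2, 2, byrow = TRUE,
                           dimnames = list(c("x", "y"), c("S", "o"))),
                    c(x = "G1", y = "G2"))
  p2 <- fisher_overrepresentation(cmT, "G1", "S")$p_value
  expect_equal(p1, p2)
})

test_that("empty margins give p = 1 with a warning, not an error", {
  cm <- nps_counts(matrix(c(0L, 3L, 0L, 4L), 2, 2, byrow = TRUE,
                          dimnames = list(c("x", "y"), c("S", "o"))),
                   c(x = "G1", y = "G2"))
  expect_warning(ft <- fisher_overrepresentation(cm, "G1", "S"),
                 "empty margin")
  expect_equal(ft$p_value, 1)
})

test_that("cells always sum to the gene universe", {
  t1 <- nps_table1()
  ft <- fisher_overrepresentation(t1, "Euascomycota", "EAS")
  expect_equal(sum(ft$table), sum(t1$counts))
  ftu <- fisher_overrepresentation(t1, "Euascomycota", "EAS",
                                   universe = c("Euascomycota",
                                                "Basidiomycota"))
  expect_equal(sum(ftu$table), 174)   # 144 euascomycete + 30 basidiomycete
})

test_that("EAS is overrepresented in euascomycetes in the packaged table", {
  t1 <- nps_table1()
  ft <- fisher_overrepresentation(t1, "Euascomycota", "EAS",
                                  universe = c("Euascomycota",
                                               "Basidiomycota"))
  expect_equal(unname(ft$table), c(64, 0, 80, 30))
  expect_lt(ft$p_value, 1e-6)
  # brute-force hypergeometric tail agrees
  brute <- sum(dhyper(64:64, 64, 110, 144))
  expect_equal(ft$p_value, brute, tolerance = 1e-12)
  # the scan flags the printed overrepresentation calls
  fs <- fisher_scan(t1, groups = c("Euascomycota", "Basidiomycota"),
                    restrict_universe = TRUE)
  sig <- fs[fs$significant, ]
  expect_true(all(c("EAS", "PKS;NRPS") %in%
                    sig$subfamily[sig$group == "Euascomycota"]))
  expect_true("NPS12/ETP mod 2" %in%
                sig$subfamily[sig$group == "Basidiomycota"])
  # BH adjustment is available and monotone
  fsb <- fisher_scan(t1, groups = c("Euascomycota", "Basidiomycota"),
                     restrict_universe = TRUE, adjust = "BH")
  expect_true(all(fsb$p_adj >= fsb$p_value - 1e-12))
})
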