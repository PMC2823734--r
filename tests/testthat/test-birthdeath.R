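test_that("transition probabilities match the closed form's special cases", {
  # t = 0: identity
  expect_equal(bdp_transition(3, 0:6, 0, 0.7), c(0, 0, 0, 1, 0, 0, 0))
  # state 0 absorbing
  expect_equal(bdp_transition(0, 0:3, 2, 1), c(1, 0, 0, 0))
  # alpha = lambda t / (1 + lambda t) is the single-gene extinction
  # probability: lambda = 0.5, t = 1 gives alpha = 1/3
  expect_equal(bdp_transition(1, 0, 1, 0.5), 1 / 3, tolerance = 1e-12)
  expect_error(bdp_transition(1, 1, -1, 0.5), "negative")
  expect_error(bdp_transition(1, 1, 1, -0.5), "negative")
})

test_that("transition rows sum to one, including the alpha = 1/2 edge case", {
  for (s in c(1, 2, 5, 10)) {
    for (lt in c(0.2, 0.5, 1, 2)) {   # lt = 1 makes alpha = 1/2 exactly
      P <- npsphylome:::bdp_transition_matrix(lt, 1, 150,
                                              renormalize = FALSE)
      expect_lt(abs(sum(P[s + 1, ]) - 1), 1e-9)
    }
  }
})

test_that("transitions agree with the generator of the process (expm)", {
  skip_if_not_installed("Matrix")
  cmax <- 60; lam <- 0.8; tt <- 0.9
  Q <- matrix(0, cmax + 1, cmax + 1)
  for (n in 1:cmax) {
    Q[n + 1, n] <- lam * n
    if (n < cmax) Q[n + 1, n + 2] <- lam * n
    Q[n + 1, n + 1] <- -2 * lam * n
  }
  Q[cmax + 1, cmax + 1] <- -lam * cmax
  Pe <- as.matrix(Matrix::expm(Q * tt))
  Pm <- npsphylome:::bdp_transition_matrix(tt, lam, cmax, renormalize = FALSE)
  expect_lt(max(abs(Pe[1:20, 1:20] - Pm[1:20, 1:20])), 1e-10)
})

test_that("transitions agree with Gillespie simulation (Monte-Carlo oracle)", {
  tr2 <- simulate_yule_tree(2, 1, seed = 1)   # both pendant edges length 1
  grid <- list(c(s = 2, lambda = 0.5), c(s = 1, lambda = 1),
               c(s = 4, lambda = 0.25))
  for (g in grid) {
    n <- 20000
    sim <- simulate_family_counts(tr2, g[["lambda"]], g[["s"]], n, seed = 8)
    emp <- tabulate(sim$counts$counts[1, ] + 1L, nbins = 26) / n
    theo <- bdp_transition(g[["s"]], 0:25, 1, g[["lambda"]])
    sds <- sqrt(theo * (1 - theo) / n)
    check <- theo > 5 / n
    expect_true(all(abs(emp[check] - theo[check]) <= 3.3 * sds[check]))
  }
})

test_that("pruning likelihood equals exhaustive state enumeration", {
  model <- bdp_model(0.3, 10)
  # degenerate case: pruning on a cherry reduces to the closed form
  tr2 <- read_newick(text = "(A:1.5,B:1.5);")
  tc2 <- c(A = 2, B = 0)
  ll2 <- family_loglikelihood(tr2, tc2, model)
  Tm <- npsphylome:::bdp_branch_matrix(model, 1.5)
  brute2 <- sum(model$root_prior * Tm[, tc2[["A"]] + 1] * Tm[, tc2[["B"]] + 1])
  expect_equal(ll2, log(brute2), tolerance = 1e-10, ignore_attr = TRUE)
  # 3 and 4 leaf trees vs full enumeration over internal states
  tr3 <- read_newick(text = "((A:1,B:1):1,C:2);")
  tc3 <- c(A = 2, B = 1, C = 3)
  ll3 <- family_loglikelihood(tr3, tc3, model)
  T1 <- npsphylome:::bdp_branch_matrix(model, 1)
  T2 <- npsphylome:::bdp_branch_matrix(model, 2)
  brute3 <- 0
  for (r in 1:10) for (i in 0:10) {
    brute3 <- brute3 + model$root_prior[r + 1] * T1[r + 1, i + 1] *
      T2[r + 1, tc3[["C"]] + 1] * T1[i + 1, tc3[["A"]] + 1] *
      T1[i + 1, tc3[["B"]] + 1]
  }
  expect_equal(ll3, log(brute3), tolerance = 1e-10, ignore_attr = TRUE)
  tr4 <- read_newick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  tc4 <- c(A = 1, B = 2, C = 0, D = 1)
  ll4 <- family_loglikelihood(tr4, tc4, model)
  brute4 <- 0
  for (r in 1:10) for (i in 0:10) for (j in 0:10) {
    brute4 <- brute4 + model$root_prior[r + 1] * T1[r + 1, i + 1] *
      T1[r + 1, j + 1] * T1[i + 1, tc4[["A"]] + 1] *
      T1[i + 1, tc4[["B"]] + 1] * T1[j + 1, tc4[["C"]] + 1] *
      T1[j + 1, tc4[["D"]] + 1]
  }
  expect_equal(ll4, log(brute4), tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(family_loglikelihood(tr3, c(A = 1, B = 1), model), "C")
})

test_that("likelihood plateaus as the state-space bound grows", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  tc <- c(A = 2, B = 1, C = 3)
  # fixed root state so only the truncation bound varies
  point_prior <- function(cm) {
    p <- rep(0, cm + 1); p[3] <- 1; p
  }
  lls <- vapply(c(10, 20, 40, 80), function(cm)
    family_loglikelihood(tr, tc, bdp_model(0.3, cm, point_prior(cm))),
    numeric(1))
  expect_lt(abs(lls[4] - lls[3]) / abs(lls[4]), 1e-10)
})

test_that("the global rate is recovered from simulated families", {
  tr <- simulate_yule_tree(10, 1000, seed = 21)
  sim <- simulate_family_counts(tr, 0.002, root_count = 2, n_families = 100,
                                seed = 22)
  keep <- colSums(sim$counts$counts) > 0
  fit <- estimate_lambda(sim$counts$counts[, keep, drop = FALSE], tr)
  expect_lt(abs(fit$lambda_hat - 0.002) / 0.002, 0.3)
  # optimality of the estimate
  obj <- function(l) sum(npsphylome:::family_loglik_batch(
    tr, sim$counts$counts[tr$tip.label, keep, drop = FALSE],
    bdp_model(l, fit$c_max)))
  expect_gte(fit$loglik + 1e-6, obj(fit$lambda_hat * 1.1))
  expect_gte(fit$loglik + 1e-6, obj(fit$lambda_hat * 0.9))
  # constant, equal families drive the estimate to the lower bound
  cm_const <- matrix(2L, 10, 3,
                     dimnames = list(tr$tip.label, paste0("f", 1:3)))
  expect_warning(fit0 <- estimate_lambda(cm_const, tr), "lower bound")
  expect_lte(fit0$lambda_hat, 1e-6)
  expect_error(estimate_lambda(matrix(0L, 10, 1,
                                      dimnames = list(tr$tip.label, "f")),
                               tr), "extinct")
})

test_that("parsimony root counts follow Sankoff with smallest-state ties", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  # single-lineage gain: root 0 (the exclusion filter case)
  expect_equal(parsimony_root_count(tr, c(A = 1, B = 0, C = 0)), 0)
  expect_equal(parsimony_root_count(tr, c(A = 1, B = 1, C = 1)), 1)
  star <- read_newick(text = "(A:1,B:1,C:1);")
  expect_equal(parsimony_root_count(star, c(A = 2, B = 2, C = 1)), 2)
  # tie between 1 and 2 resolves to the smaller state
  expect_equal(parsimony_root_count(tr, c(A = 2, B = 2, C = 1)), 1)
})

test_that("family p-values behave at the extremes and under the null", {
  tr <- simulate_yule_tree(6, 50, seed = 3)
  model <- bdp_model(0.001, 12)
  p_const <- family_pvalue(tr, setNames(rep(2, 6), tr$tip.label), model,
                           n_resamples = 200, seed = 5)
  expect_gt(p_const, 0.5)
  p_ext <- family_pvalue(tr, setNames(c(10, 1, 1, 1, 1, 1), tr$tip.label),
                         model, n_resamples = 200, seed = 5)
  expect_lte(p_ext, 0.05)
  expect_gte(p_ext, 1 / 201)
  # null calibration: p-values of null families are uniform
  tru <- simulate_yule_tree(6, 200, seed = 13)
  modelu <- bdp_model(0.002, 16)
  nulls <- npsphylome:::simulate_bdp_tips(tru, modelu, 2000)
  nulls <- nulls[, colSums(nulls) > 0, drop = FALSE][, 1:400]
  ps <- vapply(1:400, function(i)
    family_pvalue(tru, setNames(nulls[, i], rownames(nulls)), modelu,
                  n_resamples = 199, seed = 1000 + i), numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Viterbi states and branch p-values flag planted expansions", {
  tr <- simulate_yule_tree(6, 400, seed = 31)
  model <- bdp_model(4e-4, 20)
  tc <- setNames(c(8, 1, 1, 1, 1, 1), tr$tip.label)
  vit <- viterbi_branch_pvalues(tr, tc, model)
  expect_true(all(vit$ancestral_counts >= 0 &
                    vit$ancestral_counts <= model$c_max))
  bp <- vit$branch_p
  expect_true(all(bp$p_value > 0 & bp$p_value <= 1))
  hit <- bp[bp$child_label == tr$tip.label[1], ]
  expect_lt(hit$p_value, 0.05)
  expect_equal(hit$direction, "expansion")
  # modal transition on a near-zero branch has p = 1
  tr0 <- read_newick(text = "((A:1e-7,B:1e-7):1,C:1.0000001);")
  v0 <- viterbi_branch_pvalues(tr0, c(A = 2, B = 2, C = 2), bdp_model(0.1, 8))
  short <- v0$branch_p[v0$branch_p$time < 1e-6, ]
  expect_equal(short$p_value, rep(1, nrow(short)), tolerance = 1e-9)
  expect_true(all(short$direction == "none"))
})

test_that("the full analysis applies the parsimony root filter", {
  tr <- simulate_yule_tree(5, 300, seed = 41)
  counts <- matrix(1L, 5, 3, dimnames = list(tr$tip.label,
                                             c("steady", "acv", "grown")))
  counts[, "acv"] <- c(1L, 0L, 0L, 0L, 0L)   # single-lineage presence
  counts[, "grown"] <- c(6L, 1L, 1L, 1L, 1L)
  cm <- nps_counts(counts, setNames(rep("g", 5), tr$tip.label))
  rep <- bd_analyze(cm, tr, n_resamples = 200, seed = 2)
  expect_identical(rep$excluded, "acv")
  expect_setequal(rep$families$family, c("steady", "grown"))
  expect_true(all(rep$families$p_value >= 0 & rep$families$p_value <= 1))
})
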