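# Shared synthetic fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

# Small planted proteome with all architecture styles, plus profiles built
# from its emitted seed alignments.
tiny_bundle <- function() {
  fixture("tiny_bundle", function() {
    tpl <- c(SID = "A-T-C-A-T-C", EAS = "A-T-C-dA-T-C", AAR = "A-T-R",
             NPS12 = "A", HYB = "KS-AT-ACP-C-A-T-R")
    cnt <- c(SID = 2, EAS = 2, AAR = 2, NPS12 = 2, HYB = 1)
    pb <- synth_proteome(tpl, cnt, divergence = 0.08, seed = 11,
                         species = "s1", outgroup_count = 3)
    alns <- pb$seed_alignments
    profiles <- list(
      A = build_profile(do.call(c, unname(alns[grep("^A_", names(alns))])),
                        "A", calib_seed = 101),
      T = build_profile(alns$T, "T", calib_seed = 102),
      C = build_profile(alns$C, "C", calib_seed = 103),
      R = build_profile(alns$R, "R", calib_seed = 104))
    hits <- scan_proteome(profiles, pb$proteins)
    archs <- call_architectures(hits, protein_ids = seq_ids(pb$proteins))
    list(bundle = pb, profiles = profiles, hits = hits, archs = archs,
         templates = tpl, counts = cnt)
  })
}

# Ground-truth architecture strings per protein from generator truth.
truth_archs <- function(truth) {
  ids <- unique(truth$protein_id)
  setNames(vapply(ids, function(id)
    npsphylome:::truth_architecture(truth, id), character(1)), ids)
}

# Random additive distance matrix from a random tree (for NJ oracles).
random_additive <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1.2)
  list(tree = tr, D = stats::cophenetic(tr))
}
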