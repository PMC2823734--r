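#' Pipeline configuration
#'
#' Validates and assembles the thresholds and seeds for the full analysis
#' chain. Defaults are the screening conventions for this gene family:
#' candidate e-value 1,
#' screening support 90, masking gap fraction 0.30 (0.50 for the reduced
#' set), subfamily cutoff 70 with rescue cutoff 80, 200 NJ bootstrap
#' replicates, 1000 birth-death resamplings, significance 0.05.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param e_value_max domain-hit e-value threshold.
#' @param candidate_support screening-support cutoff.
#' @param mask_fraction,reduced_mask_fraction gap-masking thresholds.
#' @param subfamily_cutoff,rescue_cutoff consensus-clade support cutoffs.
#' @param alpha gamma shape of the distance model.
#' @param bootstrap_replicates replicates per tree.
#' @param bdp_resamples birth-death Monte-Carlo resamples.
#' @param significance p-value flag threshold.
#' @param min_domain_length minimum A-domain length retained.
#' @param degeneracy_fraction degenerate-domain score threshold (see
#'   [scan_protein()]).
#' @param synthetic list describing the synthetic input bundle (see
#'   [nps_demo_config()]); the demo pipeline generates its inputs from it.
#' @return validated list of class `nps_config`.
#' @export
nps_config <- function(seed = 1L, e_value_max = 1.0, candidate_support = 90,
                       mask_fraction = 0.30, reduced_mask_fraction = 0.50,
                       subfamily_cutoff = 70, rescue_cutoff = 80,
                       alpha = 1.0, bootstrap_replicates = 200L,
                       bdp_resamples = 1000L, significance = 0.05,
                       min_domain_length = 150L, degeneracy_fraction = 0.5,
                       synthetic = NULL) {
  chk <- function(x, lo, hi, name) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
      stop("config: ", name, " must be in [", lo, ", ", hi, "]")
  }
  chk(e_value_max, 1e-12, 1e6, "e_value_max")
  chk(candidate_support, 0, 100, "candidate_support")
  chk(mask_fraction, 0, 1, "mask_fraction")
  chk(reduced_mask_fraction, 0, 1, "reduced_mask_fraction")
  chk(subfamily_cutoff, 0, 100, "subfamily_cutoff")
  chk(rescue_cutoff, 0, 100, "rescue_cutoff")
  chk(alpha, 1e-3, 100, "alpha")
  chk(bootstrap_replicates, 1, 1e5, "bootstrap_replicates")
  chk(bdp_resamples, 100, 1e6, "bdp_resamples")
  chk(significance, 0, 1, "significance")
  chk(degeneracy_fraction, 0, 1, "degeneracy_fraction")
  structure(list(seed = as.integer(seed), e_value_max = e_value_max,
                 candidate_support = candidate_support,
                 mask_fraction = mask_fraction,
                 reduced_mask_fraction = reduced_mask_fraction,
                 subfamily_cutoff = subfamily_cutoff,
                 rescue_cutoff = rescue_cutoff, alpha = alpha,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 bdp_resamples = as.integer(bdp_resamples),
                 significance = significance,
                 min_domain_length = as.integer(min_domain_length),
                 degeneracy_fraction = degeneracy_fraction,
                 synthetic = synthetic),
            class = "nps_config")
}

#' Demo configuration on a synthetic study
#'
#' Describes a small synthetic study: an ultrametric species tree, one
#' proteome per species with planted subfamily architectures (including a
#' siderophore-synthetase-like two-module family with a degenerate second A
#' domain and a lineage-specific expansion of one subfamily in one species),
#' outgroup adenylating proteins, and all pipeline thresholds at their
#' defaults scaled to run in minutes.
#'
#' @param seed master seed.
#' @param scale `"demo"` (default) or `"test"` (smaller, for unit tests).
#' @return an [nps_config].
#' @export
nps_demo_config <- function(seed = 1L, scale = c("demo", "test")) {
  scale <- match.arg(scale)
  templates <- c(SIDlike = "A-T-C-A-T-C",
                 EASlike = "A-T-C-dA-T-C",
                 AARlike = "A-T-R",
                 NPS12like = "A",
                 CYCLOlike = "(A-T-C)x3")
  if (scale == "test") {
    n_species <- 4L
    counts <- rbind(SIDlike = c(1, 1, 1, 1),
                    EASlike = c(6, 1, 1, 1),
                    AARlike = c(1, 1, 1, 1),
                    NPS12like = c(1, 1, 1, 1))
    templates <- templates[rownames(counts)]
    reps <- 30L
    resamples <- 200L
  } else {
    n_species <- 6L
    counts <- rbind(SIDlike = c(1, 1, 1, 1, 1, 1),
                    EASlike = c(8, 1, 1, 1, 1, 1),
                    AARlike = c(1, 1, 1, 1, 1, 1),
                    NPS12like = c(1, 1, 1, 1, 1, 1),
                    CYCLOlike = c(1, 1, 1, 1, 1, 1))
    reps <- 50L
    resamples <- 500L
  }
  colnames(counts) <- paste0("s", seq_len(n_species))
  groups <- setNames(rep(c("GroupA", "GroupB"), length.out = n_species),
                     colnames(counts))
  nps_config(seed = seed,
             bootstrap_replicates = reps,
             bdp_resamples = resamples,
             synthetic = list(
               n_species = n_species,
               tree_height = 400,
               templates = templates,
               counts = counts,           # subfamily x species
               groups = groups,
               divergence = 0.08,
               outgroup_count = 4L))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(unclass(config)), tmp)
  unname(tools::md5sum(tmp))
}

# TSV writer with the provenance header every pipeline output carries.
write_stage_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# npsphylome config=%s seed=%d", hash, seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes, in order: proteome generation, profile building and calibration,
#' domain scanning, architecture calling, candidate screening, A-domain
#' extraction and masking, three bootstrap-annotated NJ trees (different
#' bootstrap streams and gamma shapes), outgroup rooting, consensus subfamily
#' extraction, gene assignment, the species-by-subfamily count matrix,
#' Fisher overrepresentation tests, and the birth-death expansion analysis.
#' Every output TSV carries a header naming the config hash and seed; a run
#' log records stage timings and seeds. Identical configs and seeds give
#' byte-identical outputs. A stage failure halts the run with the stage name;
#' outputs of completed stages are retained.
#'
#' @param config an [nps_config] with a `synthetic` bundle description.
#' @param outdir output directory (created if needed).
#' @return list of class `nps_run`: paths of the stage outputs, the in-memory
#'   results, and the generator ground truth.
#' @export
run_nps_pipeline <- function(config, outdir = tempfile("npsrun")) {
  stopifnot(inherits(config, "nps_config"))
  if (is.null(config$synthetic))
    stop("config has no synthetic bundle description")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  log_path <- file.path(outdir, "run_log.txt")
  logcon <- file(log_path, "w")
  on.exit(close(logcon), add = TRUE)
  logline <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S"), " ", ...), logcon)
  }
  logline("npsphylome pipeline; config ", hash, "; seed ", seed)
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    logline(sprintf("stage %-12s done in %.1fs", name, proc.time()[3] - t0))
    res
  }
  syn <- config$synthetic
  paths <- list()

  # --- generate inputs -----------------------------------------------------
  gen <- stage("generate", {
    tree <- simulate_yule_tree(syn$n_species, syn$tree_height,
                               derive_seed(seed, 1L))
    consensus <- nps_consensus(rownames(syn$counts), derive_seed(seed, 2L))
    bundles <- lapply(seq_len(syn$n_species), function(i) {
      synth_proteome(syn$templates,
                     setNames(syn$counts[, i], rownames(syn$counts)),
                     divergence = syn$divergence,
                     seed = derive_seed(seed, 100L + i),
                     species = colnames(syn$counts)[i],
                     consensus = consensus,
                     outgroup_count = if (i == 1L) syn$outgroup_count else 0L)
    })
    proteins <- do.call(c, lapply(bundles, `[[`, "proteins"))
    truth <- do.call(rbind, lapply(bundles, `[[`, "truth"))
    list(tree = tree, consensus = consensus, bundles = bundles,
         proteins = proteins, truth = truth)
  })
  paths$proteome <- file.path(outdir, "proteins.fasta")
  write_fasta(gen$proteins, paths$proteome)
  paths$species_tree <- file.path(outdir, "species_tree.nwk")
  write_newick(gen$tree, paths$species_tree)

  # --- profiles and scan ---------------------------------------------------
  profiles <- stage("profiles", {
    alns <- gen$bundles[[1]]$seed_alignments
    a_rows <- do.call(c, unname(alns[grep("^A_", names(alns))]))
    list(A = build_profile(a_rows, "A", calib_seed = derive_seed(seed, 3L)),
         T = build_profile(alns$T, "T", calib_seed = derive_seed(seed, 4L)),
         C = build_profile(alns$C, "C", calib_seed = derive_seed(seed, 5L)),
         R = build_profile(alns$R, "R", calib_seed = derive_seed(seed, 6L)))
  })
  hits <- stage("scan", {
    h <- scan_proteome(profiles, gen$proteins,
                       e_value_max = config$e_value_max,
                       degeneracy_fraction = config$degeneracy_fraction)
    if (nrow(h) == 0) stop("no domain hits")
    h
  })
  paths$hits <- file.path(outdir, "domain_hits.tsv")
  write_stage_tsv(hits, paths$hits, hash, seed)

  # --- architectures -------------------------------------------------------
  archs <- stage("architect", {
    call_architectures(hits, protein_ids = seq_ids(gen$proteins))
  })
  paths$architectures <- file.path(outdir, "architectures.tsv")
  write_stage_tsv(archs, paths$architectures, hash, seed)

  # --- A domains, alignment, masking --------------------------------------
  adoms <- stage("a_domains", {
    extract_a_domains(gen$proteins, archs,
                      min_length = config$min_domain_length)
  })
  paths$a_domains <- file.path(outdir, "a_domains.fasta")
  write_fasta(adoms, paths$a_domains)
  masked <- stage("mask", {
    aln <- align_to_profile(adoms, profiles$A$length)
    mask_columns(aln, config$mask_fraction)
  })
  paths$masked <- file.path(outdir, "a_domains_masked.fasta")
  write_fasta(masked$masked, paths$masked)
  paths$mask_report <- file.path(outdir, "mask_report.tsv")
  write_stage_tsv(data.frame(kept_column = masked$kept_columns),
                  paths$mask_report, hash, seed)

  # --- trees ---------------------------------------------------------------
  outgroup_labels <- grep("OUTGROUP", names(masked$masked), value = TRUE)
  trees <- stage("trees", {
    if (length(outgroup_labels) == 0) stop("no outgroup leaves in alignment")
    alphas <- c(config$alpha, config$alpha * 0.7, config$alpha * 1.5)
    lapply(1:3, function(i) {
      tr <- bootstrap_support(masked$masked,
                              n_replicates = config$bootstrap_replicates,
                              seed = derive_seed(seed, 10L + i),
                              model = wag_gamma_model(alphas[i]))
      root_with_outgroup(tr, outgroup_labels)
    })
  })
  paths$trees <- file.path(outdir, paste0("a_domain_tree_", 1:3, ".nwk"))
  for (i in 1:3) write_newick(trees[[i]], paths$trees[i])

  # --- candidate screening -------------------------------------------------
  reference_labels <- stage("references", {
    meta <- attr(adoms, "meta")
    fam_of <- sub("^s[0-9]+_([A-Za-z0-9]+)_g.*$", "\\1", meta$protein_id)
    refs <- vapply(split(meta$label, fam_of), function(x) sort(x)[1],
                   character(1))
    refs[setdiff(names(refs), "OUTGROUP")]
  })
  screened <- stage("screen", {
    screen_candidates(trees[[1]], unname(reference_labels), outgroup_labels,
                      support_cutoff = config$candidate_support)
  })
  paths$candidates <- file.path(outdir, "candidates.tsv")
  write_stage_tsv(data.frame(label = screened), paths$candidates, hash, seed)

  # --- subfamilies ---------------------------------------------------------
  subfam <- stage("subfamilies", {
    extract_subfamilies(trees, unname(reference_labels),
                        cutoff = config$subfamily_cutoff,
                        rescue_cutoff = config$rescue_cutoff,
                        names_map = setNames(names(reference_labels),
                                             unname(reference_labels)))
  })
  paths$subfamilies <- file.path(outdir, "subfamilies.tsv")
  write_stage_tsv(as.data.frame(subfam), paths$subfamilies, hash, seed)

  # --- gene assignment and counts -----------------------------------------
  assignments <- stage("assign", assign_genes(subfam, archs))
  paths$assignments <- file.path(outdir, "gene_assignments.tsv")
  write_stage_tsv(assignments, paths$assignments, hash, seed)
  cm <- stage("counts", {
    ids <- archs$protein_id
    species_of <- setNames(sub("^(s[0-9]+)_.*$", "\\1", ids), ids)
    ingroup <- !grepl("OUTGROUP", ids)
    build_count_matrix(assignments[ingroup[match(assignments$protein_id,
                                                 ids)], , drop = FALSE],
                       species_of[ingroup], syn$groups)
  })
  paths$counts <- file.path(outdir, "count_matrix.tsv")
  write_count_table(cm, paths$counts,
                    header = sprintf("npsphylome config=%s seed=%d",
                                     hash, seed))

  # --- Fisher --------------------------------------------------------------
  fisher <- stage("fisher", fisher_scan(cm, alpha = config$significance))
  paths$fisher <- file.path(outdir, "fisher_tests.tsv")
  write_stage_tsv(fisher, paths$fisher, hash, seed)

  # --- birth-death ---------------------------------------------------------
  bdp <- stage("birth_death", {
    keep <- setdiff(colnames(cm$counts), "Other")
    bd_analyze(nps_counts(cm$counts[, keep, drop = FALSE], cm$group),
               gen$tree, n_resamples = config$bdp_resamples,
               seed = derive_seed(seed, 40L),
               significance = config$significance)
  })
  paths$bd_families <- file.path(outdir, "bd_families.tsv")
  write_stage_tsv(bdp$families, paths$bd_families, hash, seed)
  paths$bd_branches <- file.path(outdir, "bd_branches.tsv")
  branch_df <- do.call(rbind, lapply(names(bdp$branches), function(f) {
    cbind(family = f, bdp$branches[[f]])
  }))
  write_stage_tsv(branch_df, paths$bd_branches, hash, seed)
  logline("pipeline complete")

  structure(list(paths = paths, config = config, hash = hash,
                 truth = gen$truth, tree = gen$tree,
                 profiles = profiles, hits = hits, architectures = archs,
                 a_domains = adoms, masked = masked, trees = trees,
                 references = reference_labels, screened = screened,
                 subfamilies = subfam, assignments = assignments,
                 counts = cm, fisher = fisher, bdp = bdp),
            class = "nps_run")
}

#' @export
print.nps_run <- function(x, ...) {
  cat("nps_run:", length(x$subfamilies), "subfamilies;",
      nrow(x$counts$counts), "species;",
      sum(x$bdp$families$significant), "significant families\n")
  invisible(x)
}
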