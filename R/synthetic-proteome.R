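# Consensus lengths approximating real NRPS domain sizes (residues), plus the
# non-NRPS megasynthase domains emitted as inert linker segments.
NRPS_DOMAIN_LENGTHS <- c(A = 480L, T = 80L, C = 430L, R = 340L)
INERT_DOMAIN_LENGTHS <- c(KS = 420L, AT = 300L, ACP = 80L, M = 300L,
                          KR = 180L, E = 400L)

#' Shared domain consensus set for a synthetic study
#'
#' Builds the per-domain-type consensus sequences and the subfamily-specific
#' adenylation-domain consensus variants that [synth_proteome()] mutates into
#' protein instances. Each subfamily (and the always-included `OUTGROUP`
#' variant used for rooting and candidate screening) substitutes its own
#' disjoint, interleaved block of A-consensus positions with residues that
#' differ from the base. Disjoint blocks make every pair of variants exactly
#' equidistant: the planted subfamilies form a star radiation with no
#' resolving signal between them (mimicking the unresolved deep relationships
#' among real NRPS subfamilies), while between-subfamily distance always
#' exceeds within-subfamily divergence.
#'
#' @param subfamilies character vector of subfamily names.
#' @param seed integer seed (the consensus set is a pure function of
#'   `subfamilies` and `seed`).
#' @param subfamily_offset upper bound on the fraction of A-consensus
#'   positions substituted per variant; the realized block size is
#'   `min(round(offset * L), floor(L / n_variants))` so blocks stay disjoint.
#' @param outgroup_offset upper bound for the outgroup variant's block.
#' @return an object of class `nps_consensus`.
#' @export
nps_consensus <- function(subfamilies, seed, subfamily_offset = 0.3,
                          outgroup_offset = 0.45) {
  stopifnot(length(subfamilies) >= 1, !anyDuplicated(subfamilies))
  if (subfamily_offset <= 0 || subfamily_offset >= 0.5)
    stop("subfamily_offset must be in (0, 0.5)")
  with_seed(derive_seed(seed, 11L), {
    types <- lapply(NRPS_DOMAIN_LENGTHS, function(L)
      sample(AA_ORDER, L, replace = TRUE))
    a_base <- types[["A"]]
    L <- length(a_base)
    groups <- c(subfamilies, "OUTGROUP")
    k <- length(groups)
    # interleaved disjoint position blocks (round-robin), so degenerate
    # half-domains retain half of every subfamily's marker positions
    block_of <- rep_len(seq_len(k), L)
    a_variants <- lapply(seq_len(k), function(i) {
      offset <- if (groups[i] == "OUTGROUP") outgroup_offset else
        subfamily_offset
      pos <- which(block_of == i)
      n_sub <- min(round(offset * L), length(pos))
      pos <- pos[seq_len(n_sub)]
      v <- a_base
      v[pos] <- vapply(v[pos], function(aa)
        sample(setdiff(AA_ORDER, aa), 1L), character(1))
      v
    })
    names(a_variants) <- groups
    structure(list(types = types, a_variants = a_variants,
                   subfamilies = subfamilies, seed = as.integer(seed)),
              class = "nps_consensus")
  })
}

# Expand repeat syntax "(A-T-C)x3" and split a template into tokens.
parse_template <- function(template) {
  expand_one <- function(t) {
    m <- regexpr("\\(([^)]*)\\)x([0-9]+)", t)
    if (m == -1L) return(t)
    whole <- regmatches(t, m)
    unit <- sub("^\\(([^)]*)\\)x[0-9]+$", "\\1", whole)
    k <- as.integer(sub("^\\([^)]*\\)x([0-9]+)$", "\\1", whole))
    expand_one(sub("\\(([^)]*)\\)x[0-9]+",
                   paste(rep(unit, k), collapse = "-"), t))
  }
  tokens <- strsplit(expand_one(template), "-", fixed = TRUE)[[1]]
  known <- c(names(NRPS_DOMAIN_LENGTHS), "dA", names(INERT_DOMAIN_LENGTHS))
  bad <- setdiff(tokens, known)
  if (length(bad) > 0) {
    stop("unknown template token(s): ", paste(bad, collapse = ", "))
  }
  tokens
}

# Substitute a fraction `divergence` of positions with different residues.
mutate_seq <- function(x, divergence) {
  if (divergence == 0) return(x)
  hit <- which(runif(length(x)) < divergence)
  x[hit] <- vapply(x[hit], function(aa)
    sample(setdiff(AA_ORDER, aa), 1L), character(1))
  x
}

#' Generate a synthetic proteome with planted NRPS domain architectures
#'
#' Assembles proteins from per-domain-type consensus sequences into modular
#' architectures (templates such as `"A-T-C"`, `"A-T-R"`, `"A"`,
#' `"(A-T-C)x3"`, `"A-T-C-dA-T-C"`, `"KS-AT-ACP-C-A-T-R"`), separated by
#' random inert linkers. Each domain instance is the relevant consensus
#' mutated at per-site substitution probability `divergence`. Adenylation
#' domains use the subfamily-specific consensus variant; degenerate A domains
#' (`dA`) are the N-terminal half of the variant (C-terminal half deleted),
#' giving detectable-but-low profile scores. Ground-truth coordinates use
#' 0-based half-open intervals.
#'
#' @param architecture_templates named character vector: subfamily name ->
#'   template string.
#' @param counts_per_subfamily named integer vector: subfamily -> number of
#'   genes to generate (names must match the templates).
#' @param divergence per-site substitution probability in \[0, 0.5).
#' @param seed integer seed.
#' @param species species label used as the protein-id prefix.
#' @param consensus optional shared [nps_consensus] (so several species draw
#'   from the same consensus set); built from `seed` when `NULL`.
#' @param outgroup_count number of standalone outgroup adenylating proteins.
#' @param seed_copies rows per emitted seed alignment.
#' @param seed_divergence divergence of seed-alignment copies (light, so
#'   profiles built from them recover the planted domains).
#' @param linker_range integer range of inter-domain linker lengths.
#' @return list with `proteins` (`AAStringSet`), `truth` (data.frame:
#'   protein_id, subfamily, domain_type, start, end, degenerate), and
#'   `seed_alignments` (named list of `AAStringSet`: one `A_<subfamily>`
#'   alignment per subfamily plus `T`, `C`, `R`, and `A_OUTGROUP` when
#'   outgroups are requested), plus the `consensus` used and the `seed`.
#' @export
synth_proteome <- function(architecture_templates, counts_per_subfamily,
                           divergence = 0.05, seed = 1L, species = "sp1",
                           consensus = NULL, outgroup_count = 0L,
                           seed_copies = 10L, seed_divergence = 0.02,
                           linker_range = c(10L, 50L)) {
  if (divergence < 0 || divergence >= 0.5)
    stop("divergence must be in [0, 0.5)")
  subs <- names(architecture_templates)
  if (is.null(subs) || is.null(names(counts_per_subfamily)))
    stop("templates and counts must be named by subfamily")
  if (!setequal(subs, names(counts_per_subfamily)))
    stop("subfamily names of templates and counts disagree")
  tokens_by_sub <- lapply(architecture_templates, parse_template)
  if (is.null(consensus)) consensus <- nps_consensus(subs, seed)
  stopifnot(inherits(consensus, "nps_consensus"))
  missing_sub <- setdiff(subs, names(consensus$a_variants))
  if (length(missing_sub) > 0)
    stop("consensus lacks subfamilies: ", paste(missing_sub, collapse = ", "))

  gen <- new.env()
  gen$seqs <- character(0)
  gen$truth <- list()
  emit_protein <- function(id, tokens, subfam, div) {
    parts <- character(0)
    pos <- 0L
    rows <- list()
    linker <- function(n) paste(sample(AA_ORDER, n, replace = TRUE),
                                collapse = "")
    for (i in seq_along(tokens)) {
      tok <- tokens[i]
      if (i > 1L) {
        n <- sample(seq(linker_range[1], linker_range[2]), 1L)
        parts <- c(parts, linker(n))
        pos <- pos + n
      }
      if (tok %in% names(INERT_DOMAIN_LENGTHS)) {
        n <- INERT_DOMAIN_LENGTHS[[tok]]
        parts <- c(parts, linker(n))
        pos <- pos + n
        next
      }
      degen <- tok == "dA"
      base <- if (tok %in% c("A", "dA")) {
        consensus$a_variants[[subfam]]
      } else {
        consensus$types[[tok]]
      }
      if (degen) base <- base[seq_len(length(base) %/% 2L)]
      inst <- mutate_seq(base, div)
      parts <- c(parts, paste(inst, collapse = ""))
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, subfamily = subfam,
        domain_type = if (degen) "A" else tok,
        start = pos, end = pos + length(inst),
        degenerate = degen, stringsAsFactors = FALSE)
      pos <- pos + length(inst)
    }
    gen$seqs[id] <- paste(parts, collapse = "")
    gen$truth[[length(gen$truth) + 1L]] <- do.call(rbind, rows)
  }

  with_seed(derive_seed(seed, 23L), {
    for (s in subs) {
      k <- counts_per_subfamily[[s]]
      if (k > 0) {
        for (g in seq_len(k)) {
          emit_protein(sprintf("%s_%s_g%d", species, s, g),
                       tokens_by_sub[[s]], s, divergence)
        }
      }
    }
    if (outgroup_count > 0) {
      for (g in seq_len(outgroup_count)) {
        emit_protein(sprintf("%s_OUTGROUP_g%d", species, g), "A",
                     "OUTGROUP", divergence)
      }
    }
  })

  seed_alns <- with_seed(derive_seed(seed, 37L), {
    alns <- list()
    grp <- subs
    if (outgroup_count > 0) grp <- c(grp, "OUTGROUP")
    for (s in grp) {
      rows <- vapply(seq_len(seed_copies), function(i)
        paste(mutate_seq(consensus$a_variants[[s]], seed_divergence),
              collapse = ""), character(1))
      aln <- Biostrings::AAStringSet(rows)
      names(aln) <- sprintf("seedA_%s_%02d", s, seq_len(seed_copies))
      alns[[paste0("A_", s)]] <- aln
    }
    for (tp in c("T", "C", "R")) {
      rows <- vapply(seq_len(seed_copies), function(i)
        paste(mutate_seq(consensus$types[[tp]], seed_divergence),
              collapse = ""), character(1))
      aln <- Biostrings::AAStringSet(rows)
      names(aln) <- sprintf("seed%s_%02d", tp, seq_len(seed_copies))
      alns[[tp]] <- aln
    }
    alns
  })

  proteins <- Biostrings::AAStringSet(gen$seqs)
  truth <- if (length(gen$truth) > 0) {
    do.call(rbind, gen$truth)
  } else {
    data.frame(protein_id = character(0), subfamily = character(0),
               domain_type = character(0), start = integer(0),
               end = integer(0), degenerate = logical(0))
  }
  rownames(truth) <- NULL
  list(proteins = proteins, truth = truth, seed_alignments = seed_alns,
       consensus = consensus, species = species, seed = as.integer(seed))
}

# Truth architecture string for one protein (same rendering rules as
# call_architecture): degenerate A printed as "dA".
truth_architecture <- function(truth, protein_id) {
  rows <- truth[truth$protein_id == protein_id, , drop = FALSE]
  rows <- rows[order(rows$start), , drop = FALSE]
  lab <- ifelse(rows$degenerate & rows$domain_type == "A", "dA",
                rows$domain_type)
  paste(lab, collapse = "-")
}
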