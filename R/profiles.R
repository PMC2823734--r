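#' Build a position-specific scoring profile from a seed alignment
#'
#' Alignment columns with more than 50% gaps are dropped from the match
#' states. Match scores are log2 odds of the observed residue frequency
#' (with a total pseudocount of 1 distributed by the uniform background,
#' i.e. +0.05 per residue) against the uniform background 0.05, in bits.
#' The null score distribution is calibrated by locally aligning at least
#' `calib_n` random background sequences and fitting a Gumbel by the method
#' of moments.
#'
#' @param seed_alignment an `AAStringSet` alignment (>= 1 row; single-row
#'   alignments are allowed and smoothed by the pseudocounts).
#' @param domain_type label such as `"A"`, `"T"`, `"C"`, `"R"` or
#'   `"other:<name>"`.
#' @param gap_open,gap_extend affine gap penalties in bits (>= 0).
#' @param calib_n number of random calibration sequences (>= 200 enforced
#'   unless `calibrate = FALSE`).
#' @param calib_seed seed for the calibration draw.
#' @param calibrate set `FALSE` to skip calibration (profile cannot be used
#'   for e-value scanning until [calibrate_profile()] is called).
#' @return an object of class `nps_profile`: match score matrix (20 x
#'   length, rows in the canonical residue order), gap penalties, trusted
#'   self score (the median profile score of the seed sequences themselves,
#'   the anchor for the degenerate-domain flag), and Gumbel calibration
#'   `(mu, scale)`.
#' @export
build_profile <- function(seed_alignment, domain_type, gap_open = 11,
                          gap_extend = 1, calib_n = 200L, calib_seed = 1L,
                          calibrate = TRUE) {
  if (length(seed_alignment) == 0) stop("empty alignment")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  m <- alignment_matrix(seed_alignment)
  gapfrac <- colMeans(m == "-")
  keep <- which(gapfrac <= 0.5)
  if (length(keep) == 0) stop("no match-state columns after gap filtering")
  m <- m[, keep, drop = FALSE]
  q <- 1 / 20
  match_scores <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    col <- col[col %in% AA_ORDER]
    counts <- table(factor(col, levels = AA_ORDER))
    p <- (as.numeric(counts) + q) / (sum(counts) + 1)
    log2(p / q)
  }, numeric(20))
  rownames(match_scores) <- AA_ORDER
  # null composition: the seed alignment's residue frequencies (smoothed),
  # so the calibration matches shuffles of domain-bearing proteins
  res <- m[m %in% AA_ORDER]
  comp <- (table(factor(res, levels = AA_ORDER)) + 1) / (length(res) + 20)
  # trusted self score: the median profile score of the seed sequences
  # themselves (a trusted-cutoff-style anchor: what a genuine full-length
  # member scores, rather than the unattainable per-column maximum)
  row_scores <- vapply(seq_len(nrow(m)), function(i) {
    idx <- match(m[i, ], AA_ORDER)
    ok <- !is.na(idx)
    sum(match_scores[cbind(idx[ok], which(ok))])
  }, numeric(1))
  prof <- structure(list(domain_type = domain_type,
                         match = match_scores,
                         length = ncol(match_scores),
                         gap_open = gap_open,
                         gap_extend = gap_extend,
                         self_score = stats::median(row_scores),
                         null_composition = as.numeric(comp),
                         calibration = NULL),
                    class = "nps_profile")
  if (calibrate) prof <- calibrate_profile(prof, calib_n, calib_seed)
  prof
}

#' @export
print.nps_profile <- function(x, ...) {
  cat("nps_profile <", x$domain_type, ">: ", x$length, " match states, ",
      "trusted self score ", round(x$self_score, 1), " bits",
      if (!is.null(x$calibration))
        sprintf("; null Gumbel mu=%.1f scale=%.2f", x$calibration[["mu"]],
                x$calibration[["scale"]]),
      "\n", sep = "")
  invisible(x)
}

#' Calibrate the null score distribution of a profile
#'
#' Aligns `calib_n` random background sequences (length matched to the
#' profile) and fits a Gumbel location/scale by the method of moments.
#'
#' @param profile an `nps_profile`.
#' @param calib_n number of random sequences, >= 200.
#' @param calib_seed integer seed.
#' @return the profile with `calibration = c(mu, scale, length)` filled in.
#' @export
calibrate_profile <- function(profile, calib_n = 200L, calib_seed = 1L) {
  stopifnot(inherits(profile, "nps_profile"))
  if (calib_n < 200L) stop("calibration needs >= 200 shuffled scores")
  L0 <- profile$length
  comp <- profile$null_composition
  if (is.null(comp)) comp <- rep(1 / 20, 20)
  scores <- with_seed(calib_seed, {
    vapply(seq_len(calib_n), function(i) {
      codes <- sample.int(20L, L0, replace = TRUE, prob = comp) - 1L
      sw_pssm_core(codes, profile$match, profile$gap_open,
                   profile$gap_extend)[1]
    }, numeric(1))
  })
  beta <- sd(scores) * sqrt(6) / pi
  mu <- mean(scores) - 0.5772156649 * beta
  if (beta <= 0) stop("degenerate calibration (zero score variance)")
  profile$calibration <- c(mu = mu, scale = beta, length = L0)
  profile
}

# Null inflation factor of the e-value scale. With E(S) anchored this far
# into the null tail, an unrelated sequence produces a spurious e < 1 hit in
# about one scan in twenty in expectation, keeping the realized rate (which
# also carries Gumbel-fit sampling noise) comfortably below one in ten.
EVALUE_NULL_FACTOR <- 20

#' E-value of a bit score under a profile's Gumbel calibration
#'
#' `E(S) = 20 * (L / L0) * exp(-(S - mu) / scale)`, where `(mu, scale)` is
#' the Gumbel fit to null maxima over length-`L0` background sequences and
#' `L` is the scanned protein length. The twentyfold null inflation keeps
#' the chance of a spurious `e < 1` hit on an unrelated protein at roughly
#' 5% per scan in expectation (comfortably below one in ten even with
#' calibration sampling noise); genuine domains score hundreds of bits above
#' the null, so sensitivity is unaffected. E-values decrease monotonically as
#' the bit score increases for a fixed search space.
#'
#' @param profile calibrated `nps_profile`.
#' @param score bit score(s).
#' @param protein_length length of the scanned protein.
#' @return numeric e-value(s).
#' @export
profile_evalue <- function(profile, score, protein_length) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated")
  space <- max(1, protein_length / cal[["length"]])
  EVALUE_NULL_FACTOR * space * exp(-(score - cal[["mu"]]) / cal[["scale"]])
}

#' Scan a protein for domain hits with a calibrated profile
#'
#' Optimal and sub-optimal non-overlapping local alignments of the protein
#' against the profile's position-specific scores (affine gaps). Hits are
#' reported while their e-value is below `e_value_max`; after each hit the
#' matched residues are masked and the scan repeats. Hits scoring below
#' `degeneracy_fraction` of the profile's trusted self score are flagged
#' degenerate (detectable but incomplete domains).
#'
#' @param profile calibrated `nps_profile`.
#' @param protein a single protein: character string, named character, or a
#'   length-one `AAStringSet`.
#' @param e_value_max report hits with e-value strictly below this (default
#'   1, the screening threshold for candidate NRPSs).
#' @param degeneracy_fraction degenerate-domain threshold on the ratio of
#'   hit score to trusted self score. The default 0.5 sits midway between
#'   the score a complete but diverged domain attains (about 0.65 of the
#'   trusted score at 15% divergence) and what a half-length degenerate
#'   domain attains (about 0.33).
#' @param max_hits cap on reported hits per protein.
#' @param protein_id id used in the output (defaults to the protein's name).
#' @return data.frame with columns protein_id, domain_type, start, end
#'   (0-based half-open residue coordinates), prof_start, prof_end,
#'   bit_score, e_value, degenerate -- sorted by start. Zero rows for empty
#'   or hit-free proteins.
#' @export
scan_protein <- function(profile, protein, e_value_max = 1.0,
                         degeneracy_fraction = 0.5, max_hits = 64L,
                         protein_id = NULL) {
  stopifnot(inherits(profile, "nps_profile"))
  if (is.null(profile$calibration)) stop("profile is not calibrated")
  if (inherits(protein, "AAStringSet")) {
    if (length(protein) != 1L) stop("scan_protein takes a single protein")
    if (is.null(protein_id)) protein_id <- seq_ids(protein)
    protein <- as.character(protein)
  }
  if (is.null(protein_id)) {
    protein_id <- if (!is.null(names(protein))) names(protein) else "protein"
  }
  empty <- data.frame(protein_id = character(0), domain_type = character(0),
                      start = integer(0), end = integer(0),
                      prof_start = integer(0), prof_end = integer(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      degenerate = logical(0))
  codes <- encode_residues(unname(protein))
  L <- length(codes)
  if (L == 0L) return(empty)
  hits <- list()
  repeat {
    res <- sw_pssm_core(codes, profile$match, profile$gap_open,
                        profile$gap_extend)
    score <- res[1]
    if (score <= 0) break
    ev <- profile_evalue(profile, score, L)
    if (ev >= e_value_max) break
    start <- as.integer(res[2]); end <- as.integer(res[3])
    hits[[length(hits) + 1L]] <- data.frame(
      protein_id = protein_id, domain_type = profile$domain_type,
      start = start, end = end,
      prof_start = as.integer(res[4]), prof_end = as.integer(res[5]),
      bit_score = score, e_value = ev,
      degenerate = score < degeneracy_fraction * profile$self_score)
    if (length(hits) >= max_hits) break
    codes[(start + 1L):end] <- -2L  # mask matched residues
  }
  if (length(hits) == 0L) return(empty)
  out <- do.call(rbind, hits)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$start >= 0L), all(out$end <= L), all(out$start < out$end))
  out
}

#' Scan a proteome with a set of profiles
#'
#' @param profiles named list of calibrated `nps_profile`s.
#' @param proteins an `AAStringSet`.
#' @param ... passed to [scan_protein()].
#' @return combined hit data.frame across all proteins and profiles.
#' @export
scan_proteome <- function(profiles, proteins, ...) {
  stopifnot(inherits(proteins, "AAStringSet"))
  ids <- seq_ids(proteins)
  seqs <- as.character(proteins)
  res <- lapply(seq_along(seqs), function(i) {
    per <- lapply(profiles, function(p)
      scan_protein(p, seqs[i], protein_id = ids[i], ...))
    do.call(rbind, per)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Export profile to / import profile from a plain-text serialization
#'
#' A simple whitespace-delimited text format: a header line with the domain
#' type, gap penalties and calibration, then one line per match state with
#' 20 bit scores in the canonical residue order.
#'
#' @param profile an `nps_profile`.
#' @param path file path.
#' @return `write_profile`: `path` invisibly; `read_profile`: the profile.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cal <- profile$calibration
  writeLines(sprintf("npsprofile\t%s\t%g\t%g\t%g\t%g\t%g\t%g",
                     profile$domain_type, profile$gap_open,
                     profile$gap_extend,
                     if (is.null(cal)) NA else cal[["mu"]],
                     if (is.null(cal)) NA else cal[["scale"]],
                     if (is.null(cal)) NA else cal[["length"]],
                     profile$self_score), con)
  writeLines(paste(AA_ORDER, collapse = "\t"), con)
  write.table(t(signif(profile$match, 8)), con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "npsprofile") stop("not an npsprofile file: ", path)
  mat <- t(as.matrix(read.delim(text = lines[-(1:2)], header = FALSE)))
  dimnames(mat) <- list(AA_ORDER, NULL)
  cal <- suppressWarnings(as.numeric(hdr[5:7]))
  self <- if (length(hdr) >= 8) as.numeric(hdr[8]) else
    sum(apply(mat, 2, max))
  structure(list(domain_type = hdr[2], match = mat,
                 length = ncol(mat),
                 gap_open = as.numeric(hdr[3]),
                 gap_extend = as.numeric(hdr[4]),
                 self_score = self,
                 calibration = if (any(is.na(cal))) NULL else
                   c(mu = cal[1], scale = cal[2], length = cal[3])),
            class = "nps_profile")
}

#' Import a HMMER2 profile file as a native profile
#'
#' Adapter for legacy HMMER2 (`HMMER2.0`) ASCII `.hmm` files: match-state
#' emission log-odds (in the file's 1/1000-bit units) are mapped onto the
#' native position-specific score matrix; insert states and transition
#' probabilities are ignored, and affine gap penalties are supplied by the
#' caller. The result must be calibrated before scanning.
#'
#' @param path a HMMER2 ASCII profile file.
#' @param domain_type label for the imported profile.
#' @param gap_open,gap_extend affine gap penalties in bits.
#' @return an uncalibrated `nps_profile`.
#' @export
read_hmmer2_profile <- function(path, domain_type = NULL, gap_open = 11,
                                gap_extend = 1) {
  lines <- readLines(path)
  if (!grepl("^HMMER2", lines[1]))
    stop("not a HMMER2 ASCII profile: ", path)
  name_line <- grep("^NAME ", lines, value = TRUE)
  if (is.null(domain_type)) {
    domain_type <- if (length(name_line) > 0)
      paste0("other:", trimws(sub("^NAME +", "", name_line[1]))) else "other:hmm"
  }
  hmm_at <- grep("^HMM ", lines)[1]
  if (is.na(hmm_at)) stop("no HMM block in ", path)
  aa_cols <- strsplit(trimws(sub("^HMM +", "", lines[hmm_at])), " +")[[1]]
  body <- lines[(hmm_at + 2L):length(lines)]
  body <- body[!grepl("^//", body)]
  # match-state lines start with the 1-based node number
  mlines <- body[grepl("^ *[0-9]+ ", body)]
  mlines <- mlines[seq(1, length(mlines), by = 3)]  # m, i, t line triplets
  scores <- t(vapply(mlines, function(l) {
    f <- strsplit(trimws(l), " +")[[1]][2:21]
    suppressWarnings(as.numeric(sub("\\*", "-99000", f))) / 1000
  }, numeric(20)))
  mat <- matrix(0, 20, nrow(scores), dimnames = list(AA_ORDER, NULL))
  mat[aa_cols[seq_len(20)], ] <- t(scores)
  mat <- mat[AA_ORDER, , drop = FALSE]
  structure(list(domain_type = domain_type, match = mat, length = ncol(mat),
                 gap_open = gap_open, gap_extend = gap_extend,
                 self_score = sum(apply(mat, 2, max)), calibration = NULL),
            class = "nps_profile")
}
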