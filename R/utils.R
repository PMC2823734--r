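#' @useDynLib npsphylome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize rexp runif sd pgamma qgamma phyper dhyper setNames
#' @importFrom utils read.delim write.table head tail
NULL

# Canonical amino-acid ordering used throughout (matches the published WAG matrix).
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHARS <- c("-", ".")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator functions are pure functions of their arguments.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from a base seed and a stage offset, kept within 32-bit range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587L) + 1L
}

# Encode residues as 0-based integer codes in AA_ORDER; gaps and non-standard
# letters (X etc.) become -1L.
encode_residues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  codes <- match(chars, AA_ORDER) - 1L
  codes[is.na(codes)] <- -1L
  codes
}

decode_residues <- function(codes) {
  paste(ifelse(codes < 0L, "X", AA_ORDER[codes + 1L]), collapse = "")
}

# Stable key for a set of leaf labels (used to compare clades across trees).
leafset_key <- function(labels) paste(sort(labels), collapse = "\r")
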