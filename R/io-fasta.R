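#' Read a FASTA file of protein sequences
#'
#' Records are returned as a [Biostrings::AAStringSet] whose names carry the
#' full header line (`id description`). Residues are upper-cased on read.
#' Record ids (the first whitespace-delimited token of each header) must be
#' unique within a file.
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet`; zero-length (with a warning) for an empty file.
#' @seealso [write_fasta()], [seq_ids()], [seq_descriptions()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    warning("empty FASTA file: ", path)
    return(Biostrings::AAStringSet())
  }
  x <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(x) == 0) {
    warning("empty FASTA file: ", path)
    return(Biostrings::AAStringSet())
  }
  out <- Biostrings::AAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  ids <- seq_ids(out)
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  out
}

#' Write sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: `read_fasta(write_fasta(x, f))` preserves ids,
#' descriptions and residues regardless of line wrapping.
#'
#' @param x an `AAStringSet` (names may include a description after the id).
#' @param path output path.
#' @param width residues per sequence line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta",
                              width = as.integer(width))
  invisible(path)
}

#' Record ids and descriptions of a sequence set
#'
#' The id is the first whitespace-delimited token of the FASTA header; the
#' description is everything after it (possibly empty).
#'
#' @param x an `AAStringSet`.
#' @return character vector.
#' @export
seq_ids <- function(x) {
  nm <- names(x)
  if (is.null(nm)) stop("sequence set has no names")
  sub("\\s.*$", "", nm)
}

#' @rdname seq_ids
#' @export
seq_descriptions <- function(x) {
  nm <- names(x)
  if (is.null(nm)) stop("sequence set has no names")
  ifelse(grepl("\\s", nm), sub("^\\S+\\s+", "", nm), "")
}

#' Validate and normalize a multiple alignment
#'
#' Checks that all rows have equal length and normalizes both accepted gap
#' characters (`-` and `.`) to `-`.
#'
#' @param x an `AAStringSet` of aligned rows.
#' @return the normalized `AAStringSet`.
#' @export
as_alignment <- function(x) {
  if (!inherits(x, "AAStringSet")) x <- Biostrings::AAStringSet(x)
  if (length(x) == 0) stop("empty alignment")
  w <- Biostrings::width(x)
  if (length(unique(w)) != 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(range(w), collapse = "-"))
  }
  s <- chartr(".", "-", as.character(x))
  out <- Biostrings::AAStringSet(s)
  names(out) <- names(x)
  out
}

#' Alignment as a character matrix
#'
#' @param x an alignment (`AAStringSet` of equal widths).
#' @return character matrix, rows = sequences, columns = alignment columns.
#' @export
alignment_matrix <- function(x) {
  x <- as_alignment(x)
  m <- do.call(rbind, strsplit(as.character(x), "", fixed = TRUE))
  rownames(m) <- seq_ids(x)
  m
}

# Integer-coded alignment (rows = sequences): 0..19 in AA_ORDER, -1 for gaps
# and non-standard letters.
alignment_codes <- function(x) {
  m <- alignment_matrix(x)
  codes <- match(m, AA_ORDER) - 1L
  codes[is.na(codes)] <- -1L
  matrix(codes, nrow = nrow(m), dimnames = dimnames(m))
}
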