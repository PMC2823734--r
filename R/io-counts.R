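#' Species-by-subfamily gene count matrix
#'
#' Container for non-negative integer gene counts per species and subfamily,
#' with a taxonomic group attached to every species.
#'
#' @param counts integer matrix, rows = species, columns = subfamilies.
#' @param group named character vector mapping every species to its group.
#' @return an object of class `nps_counts`.
#' @export
nps_counts <- function(counts, group) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0) {
    if (is.null(rownames(counts))) stop("count matrix needs species rownames")
    if (anyDuplicated(rownames(counts))) stop("duplicate species labels")
  }
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stop("count matrix needs subfamily colnames")
  if (anyDuplicated(colnames(counts))) stop("duplicate subfamily labels")
  storage.mode(counts) <- "integer"
  if (any(is.na(counts))) stop("NA counts")
  if (any(counts < 0L)) stop("negative counts")
  missing_grp <- setdiff(rownames(counts), names(group))
  if (length(missing_grp) > 0) {
    stop("species without taxonomic group: ",
         paste(missing_grp, collapse = ", "))
  }
  structure(list(counts = counts,
                 group = group[rownames(counts)]),
            class = "nps_counts")
}

#' @export
print.nps_counts <- function(x, ...) {
  cat("nps_counts:", nrow(x$counts), "species x", ncol(x$counts),
      "subfamilies;", length(unique(x$group)), "taxonomic groups\n")
  invisible(x)
}

#' Read a TSV gene count table
#'
#' Expects a header row of subfamily names, species in the first column and a
#' taxonomic-group column. Cells may carry superscript footnote markers
#' (`2^c^`); the integer prefix is taken as the count. An optional total
#' column is validated against the row sums and dropped.
#'
#' @param path TSV path.
#' @param species_col name of the species column (default first column).
#' @param group_col name of the taxonomic-group column.
#' @param total_col name of an optional row-total column to validate and drop.
#' @return an [nps_counts] object.
#' @export
read_count_table <- function(path, species_col = NULL, group_col = "Group",
                             total_col = "Total") {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   comment.char = "#")
  if (nrow(df) == 0) {
    return(nps_counts(matrix(integer(0), 0, max(0L, ncol(df) - 2L),
                             dimnames = list(NULL, setdiff(names(df), c(names(df)[1], group_col, total_col)))),
                      group = character(0)))
  }
  if (is.null(species_col)) species_col <- names(df)[1]
  if (!species_col %in% names(df)) stop("missing species column: ", species_col)
  if (!group_col %in% names(df)) {
    stop("missing taxonomic-group column: ", group_col)
  }
  species <- trimws(df[[species_col]])
  group <- setNames(trimws(df[[group_col]]), species)
  if (any(group == "" | is.na(group))) {
    stop("missing group for species: ",
         paste(species[group == "" | is.na(group)], collapse = ", "))
  }
  sub_cols <- setdiff(names(df), c(species_col, group_col, total_col))
  counts <- matrix(0L, nrow(df), length(sub_cols),
                   dimnames = list(species, sub_cols))
  for (j in sub_cols) {
    counts[, j] <- parse_count_cells(df[[j]], species, j)
  }
  if (!is.null(total_col) && total_col %in% names(df)) {
    tot <- parse_count_cells(df[[total_col]], species, total_col)
    bad <- which(rowSums(counts) != tot)
    if (length(bad) > 0) {
      stop("row totals disagree with cell sums for: ",
           paste(species[bad], collapse = ", "))
    }
  }
  nps_counts(counts, group)
}

# Strip footnote markers like "2^c^" and coerce to integer, with informative
# errors naming the offending row and column.
parse_count_cells <- function(x, species, column) {
  x <- trimws(as.character(x))
  stripped <- sub("^([0-9]+)\\^[^^]*\\^$", "\\1", x)
  bad <- !grepl("^[0-9]+$", stripped)
  if (any(bad)) {
    stop("non-integer count in column '", column, "', row '",
         species[which(bad)[1]], "': '", x[which(bad)[1]], "'")
  }
  as.integer(stripped)
}

#' Write a count matrix as TSV
#'
#' @param x an [nps_counts] object.
#' @param path output path.
#' @param header optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "nps_counts"))
  df <- data.frame(Species = rownames(x$counts),
                   Group = unname(x$group),
                   x$counts, check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged fungal NRPS gene count table
#'
#' Loads the packaged species-by-subfamily count fixture: numbers of NRPS
#' genes per subfamily across 26 fungal taxa (the hemiascomycete yeasts are
#' aggregated as one pseudo-species), with taxonomic groups. Footnote markers
#' in the published table are stripped on ingestion; the "Other" column is
#' stored verbatim as a subfamily-like column.
#'
#' @return an [nps_counts] object.
#' @export
nps_table1 <- function() {
  read_count_table(system.file("extdata", "table1_nps_counts.tsv",
                               package = "npsphylome", mustWork = TRUE))
}
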