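#' Aligned sequences with per-sequence coverage intervals
#'
#' A `partial_alignment` holds aligned nucleotide sequences that may cover
#' only part of a common coordinate system, as happens when marker fragments
#' of heterogeneous length (e.g. ~350, ~530 and ~800 bp SSU rDNA amplicons
#' sharing a 5' primer) are placed on one alignment. Each sequence carries a
#' half-open, 0-based coverage interval `[start, end)`; columns outside the
#' interval hold the padding character `?` ("not sequenced"). Inside the
#' interval, `-` is an alignment gap (an indel, excluded pairwise from
#' distances) and `N`/`?` are unknown bases. The distinction matters:
#' padding is missing data introduced by fragment length, not by indels.
#'
#' @param residues Character vector of aligned sequences, all the same
#'   number of characters, over the alphabet `A,C,G,T,-,N,?` (case
#'   insensitive).
#' @param labels Sequence identifiers; defaults to `names(residues)`. Must
#'   be unique and non-empty.
#'
#' @return An object of class `partial_alignment` with components `labels`,
#'   `columns` (alignment length), `residues` (named uppercase strings) and
#'   `coverage` (integer matrix with columns `start`, `end`; 0-based,
#'   half-open).
#' @export
#' @examples
#' aln <- partial_alignment(c(s1 = "ACGTACGTAC", s2 = "?????CGTAC"))
#' aln$coverage
partial_alignment <- function(residues, labels = NULL) {
  if (length(residues) == 0L) stop_format("alignment is empty")
  labels <- labels %||% names(residues)
  if (is.null(labels)) stop_format("sequence labels are required")
  labels <- as.character(labels)
  residues <- toupper(as.character(residues))
  if (length(labels) != length(residues))
    stop_format("got %d labels for %d sequences", length(labels), length(residues))
  if (anyDuplicated(labels))
    stop_format("duplicate sequence label(s): %s",
                paste(unique(labels[duplicated(labels)]), collapse = ", "))
  nc <- nchar(residues)
  if (length(unique(nc)) != 1L)
    stop_format("aligned sequences differ in length (e.g. '%s': %d vs '%s': %d)",
                labels[1L], nc[1L], labels[which(nc != nc[1L])[1L]],
                nc[which(nc != nc[1L])[1L]])
  columns <- nc[1L]
  if (columns == 0L) stop_format("alignment has zero columns")

  bad <- grepl("[^ACGTN?-]", residues)
  if (any(bad)) {
    ch <- regmatches(residues[bad][1L], regexpr("[^ACGTN?-]", residues[bad][1L]))
    stop_format("record '%s' contains invalid character '%s'",
                labels[bad][1L], ch)
  }

  # coverage = span after trimming leading/trailing padding ('?') and
  # flanking gaps; the trimmed flanks are normalised to '?'
  cov <- t(vapply(residues, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    inside <- which(!chars %in% c("?", "-"))
    if (length(inside) == 0L) c(NA_integer_, NA_integer_)
    else c(inside[1L] - 1L, inside[length(inside)])
  }, integer(2)))
  if (anyNA(cov))
    stop_format("record '%s' has empty coverage (no called bases)",
                labels[which(is.na(cov[, 1L]))[1L]])
  dimnames(cov) <- list(labels, c("start", "end"))

  residues <- vapply(seq_along(residues), function(i) {
    s <- residues[[i]]
    pre <- cov[i, 1L]
    post <- columns - cov[i, 2L]
    paste0(strrep("?", pre),
           substr(s, pre + 1L, cov[i, 2L]),
           strrep("?", post))
  }, character(1))
  names(residues) <- labels

  structure(
    list(labels = labels, columns = columns, residues = residues,
         coverage = cov),
    class = "partial_alignment"
  )
}

#' @export
print.partial_alignment <- function(x, ...) {
  cat(sprintf("partial_alignment: %d sequences, %d columns\n",
              length(x$labels), x$columns))
  cl <- x$coverage[, "end"] - x$coverage[, "start"]
  cat(sprintf("coverage lengths: min %d, median %d, max %d\n",
              min(cl), as.integer(stats::median(cl)), max(cl)))
  invisible(x)
}

# character matrix view (sequences x columns); internal workhorse
aln_char_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$residues, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$labels), ncol = aln$columns, byrow = TRUE)
  rownames(m) <- aln$labels
  m
}

coverage_length <- function(aln) {
  aln$coverage[, "end"] - aln$coverage[, "start"]
}

#' Read an aligned FASTA file with padding support
#'
#' Reads an aligned FASTA file in which all records have equal length and
#' short fragments may be padded with `?` (or flanking `-`) outside their
#' sequenced span. Coverage intervals are inferred from the non-padding
#' span of each record.
#'
#' @param path Path to the FASTA file.
#' @return A [partial_alignment].
#' @seealso [write_fasta_alignment()]
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop_format("cannot parse FASTA '%s': %s",
                                    path, conditionMessage(e))
  )
  if (length(recs) == 0L) stop_format("FASTA file '%s' contains no records", path)
  residues <- vapply(recs, function(r) as.character(r)[1L], character(1))
  partial_alignment(residues, labels = names(recs))
}

#' Write a partial alignment to FASTA
#'
#' @param aln A [partial_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "partial_alignment"))
  seqinr::write.fasta(as.list(aln$residues), names = aln$labels,
                      file.out = path, nbchar = 70)
  invisible(path)
}
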