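#' Protein alignments as character matrices
#'
#' Alignments are plain character matrices: one row per taxon (rownames are
#' taxon names), one column per site, entries in [aa_alphabet] plus `-`
#' (gap) and `X` (unknown). [read_alignment()]/[write_alignment()] go
#' through FASTA via \pkg{ape}.
#'
#' @param x a named list/vector of equal-length sequences, or a character
#'   matrix with rownames.
#' @return character matrix of class use throughout the package.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    seqs <- vapply(x, function(s) paste(s, collapse = ""), character(1))
    n <- nchar(seqs)
    if (length(unique(n)) != 1L)
      stop("sequences have unequal lengths: ",
           paste(range(n), collapse = "-"), call. = FALSE)
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) stop("alignment rows must be named", call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate taxon names in alignment", call. = FALSE)
  m[] <- toupper(m)
  check_aa_symbols(as.vector(m), "alignment")
  m
}

#' @param path FASTA file path.
#' @rdname as_alignment
#' @export
read_alignment <- function(path) {
  aa <- ape::read.FASTA(path, type = "AA")
  as_alignment(lapply(as.character(aa), toupper))
}

#' @param aln alignment matrix.
#' @rdname as_alignment
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

# collapse identical columns; returns list(columns = matrix of unique
# patterns, weights, map = column -> pattern index)
compress_patterns <- function(aln) {
  key <- apply(aln, 2, paste, collapse = "\r")
  u <- !duplicated(key)
  map <- match(key, key[u])
  list(columns = aln[, u, drop = FALSE],
       weights = as.numeric(table(factor(map, levels = seq_len(sum(u))))),
       map = map)
}
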