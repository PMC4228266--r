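#' Amino-acid alphabet
#'
#' The 20 standard residues in the order used throughout the package for
#' every rate matrix, partial-likelihood vector and posterior table:
#' \code{A R N D C Q E G H I L K M F P S T W Y V}. This is the ordering of
#' the classic empirical replacement-matrix files (Dayhoff/PAML layout), so
#' the bundled LG/WAG/JTT tables can be read without permutation.
#'
#' @format Character vector of length 20.
#' @export
aa_alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' @rdname aa_alphabet
#' @export
aa_gap <- "-"

#' @rdname aa_alphabet
#' @export
aa_unknown <- "X"

# residue -> index in aa_alphabet; gap/unknown -> NA
aa_index <- function(x) {
  idx <- match(toupper(x), aa_alphabet)
  idx
}

# TRUE where the symbol carries no state information for the likelihood
aa_is_missing <- function(x) {
  toupper(x) %in% c(aa_gap, aa_unknown, "?", ".")
}

# validate a vector of alignment symbols; returns invisibly or stops
check_aa_symbols <- function(x, what = "sequence") {
  bad <- !(toupper(x) %in% c(aa_alphabet, aa_gap, aa_unknown, "?", "."))
  if (any(bad)) {
    stop("invalid residue symbol(s) in ", what, ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
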