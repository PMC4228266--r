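# Positional scanning peptide library (PSPL) bookkeeping and
# quantification. Peptides follow the 16-position scaffold
# Y-A-x-x-x-x-x-[S/T]-x-x-x-x-A-G-K-K with the phosphoacceptor at scaffold
# index 8 (position 0); the nine degenerate 'x' positions are -5..-1 and
# +1..+4 relative to the acceptor. Degenerate positions are equimolar in
# the 17 proteogenic residues excluding Ser, Thr and Cys.

pspl_positions <- c("-5", "-4", "-3", "-2", "-1", "+1", "+2", "+3", "+4")

# scaffold index (1-based) of each degenerate position
pspl_scaffold_index <- stats::setNames(c(3:7, 9:12), pspl_positions)

#' Design the positional-scanning peptide library
#'
#' Enumerates the 182 peptide mixtures of the standard kinase PSPL: for
#' each of the nine degenerate positions, twenty mixtures fixing that
#' position to each residue (180), plus two acceptor mixtures with every
#' 'x' position degenerate and the phosphoacceptor fixed to Ser or Thr.
#'
#' @return data.frame with one row per mixture: `fixed_position`
#'   (`"-5"`..`"+4"` or `"acceptor"`), `fixed_residue`, `template` (the
#'   16-character scaffold, `x` marking degenerate positions, `B` the S/T
#'   acceptor mix).
#' @export
design_library <- function() {
  base <- strsplit("YAxxxxxBxxxxAGKK", "")[[1]]  # B = S/T acceptor mix
  rows <- list()
  for (pos in pspl_positions) {
    for (res in aa_alphabet) {
      tpl <- base
      tpl[pspl_scaffold_index[[pos]]] <- res
      rows[[length(rows) + 1L]] <- data.frame(
        fixed_position = pos, fixed_residue = res,
        template = paste(tpl, collapse = ""))
    }
  }
  for (res in c("S", "T")) {
    tpl <- base
    tpl[8L] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      fixed_position = "acceptor", fixed_residue = res,
      template = paste(tpl, collapse = ""))
  }
  do.call(rbind, rows)
}

# validate a raw-array data.frame (one replicate)
check_raw_array <- function(raw) {
  need <- c("fixed_position", "fixed_residue", "intensity")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("raw array lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(raw$intensity)) || any(raw$intensity < 0))
    stop("intensities must be finite and >= 0", call. = FALSE)
  invisible(raw)
}

#' Normalize a PSPL spot-intensity array
#'
#' Divides each spot intensity by the mean intensity of its position group:
#' the twenty mixtures sharing a fixed position form one group, and the two
#' acceptor mixtures form their own group. After normalization the mean of
#' every group is exactly 1, and the result is invariant to global exposure
#' scaling of the array.
#'
#' @param raw data.frame with columns `fixed_position`, `fixed_residue`,
#'   `intensity` (plus any others, carried through).
#' @return the input with an added `normalized` column.
#' @export
normalize_array <- function(raw) {
  check_raw_array(raw)
  grp <- as.character(raw$fixed_position)
  means <- tapply(raw$intensity, grp, mean)
  if (any(means == 0))
    stop("all-zero intensity in position group(s): ",
         paste(names(means)[means == 0], collapse = ", "), call. = FALSE)
  raw$normalized <- as.numeric(raw$intensity / means[grp])
  raw
}

#' Combine replicate arrays into a specificity profile
#'
#' Averages position-normalized intensities across replicates and log2
#' transforms (the standard order of operations: normalize each replicate,
#' average, then log). Zero means are floored at `eps` with a warning
#' before the log. The alternative order (log2 each replicate, then
#' average) is available via `log_first`, and `center = "zero"` re-centers
#' the final profile (including acceptor entries) to overall mean zero,
#' matching whole-kinase-centred displays.
#'
#' @param replicates list of >= 1 normalized arrays (from
#'   [normalize_array()]) sharing identical descriptors.
#' @param eps floor applied to zero pre-log values.
#' @param log_first average log2 values instead of logging the average.
#' @param center `"none"` (default) or `"zero"`.
#' @return Object of class `specificity_profile`: list with `log2` (9 x 20
#'   matrix, rows `-5`..`+4`, columns [aa_alphabet]), `acceptor` (named
#'   numeric, S and T), `mask` (logical matrix, all `FALSE` initially),
#'   `n_replicates`, `floored` (logical matrix of floored entries).
#' @export
combine_replicates <- function(replicates, eps = 1e-6,
                               log_first = FALSE,
                               center = c("none", "zero")) {
  center <- match.arg(center)
  if (inherits(replicates, "data.frame")) replicates <- list(replicates)
  if (!length(replicates)) stop("no replicates given", call. = FALSE)
  key0 <- NULL
  vals <- NULL
  for (j in seq_along(replicates)) {
    r <- replicates[[j]]
    if (is.null(r$normalized))
      stop("replicates must be normalized (see normalize_array)",
           call. = FALSE)
    key <- paste(r$fixed_position, r$fixed_residue)
    ord <- order(key)
    if (is.null(key0)) {
      key0 <- key[ord]
      vals <- matrix(NA_real_, length(key0), length(replicates))
    } else if (!identical(key[ord], key0)) {
      stop("replicates have mismatched mixture descriptors", call. = FALSE)
    }
    vals[, j] <- r$normalized[ord]
  }
  combined <- if (log_first) {
    v <- pmax(vals, eps)
    rowMeans(log2(v))
  } else {
    m <- rowMeans(vals)
    fl <- m < eps
    if (any(fl))
      warning(sum(fl), " zero mean value(s) floored at ", eps,
              " before log2")
    log2(pmax(m, eps))
  }
  names(combined) <- key0

  L <- matrix(NA_real_, 9L, 20L, dimnames = list(pspl_positions, aa_alphabet))
  for (pos in pspl_positions)
    for (res in aa_alphabet)
      L[pos, res] <- combined[paste(pos, res)]
  acc <- c(S = unname(combined["acceptor S"]),
           T = unname(combined["acceptor T"]))
  if (center == "zero") {
    mu <- mean(c(L, acc))
    L <- L - mu
    acc <- acc - mu
  }
  structure(list(log2 = L, acceptor = acc,
                 mask = matrix(FALSE, 9L, 20L,
                               dimnames = dimnames(L)),
                 n_replicates = length(replicates),
                 center = center),
            class = "specificity_profile")
}

#' @export
print.specificity_profile <- function(x, ...) {
  cat("PSPL specificity profile (", x$n_replicates, "replicate(s) )\n")
  cat("  log2 selectivity range:",
      paste(format(range(x$log2[!x$mask]), digits = 3), collapse = " to "),
      "\n")
  cat("  acceptor (S,T):", paste(format(x$acceptor, digits = 3),
                                 collapse = ", "), "\n")
  if (any(x$mask)) cat("  masked entries:", sum(x$mask), "\n")
  invisible(x)
}

#' Heat-map of a specificity profile
#'
#' @param x a `specificity_profile`.
#' @param ... passed to [graphics::image()].
#' @export
plot.specificity_profile <- function(x, ...) {
  z <- x$log2
  z[x$mask] <- NA
  graphics::image(seq_len(ncol(z)), seq_len(nrow(z)), t(z[rev(seq_len(nrow(z))), ]),
                  axes = FALSE, xlab = "residue", ylab = "position",
                  col = grDevices::hcl.colors(41, "Blue-Yellow"), ...)
  graphics::axis(1, seq_len(ncol(z)), colnames(z), las = 1, cex.axis = 0.7)
  graphics::axis(2, seq_len(nrow(z)), rev(rownames(z)), las = 1)
  graphics::box()
  invisible(x)
}

#' Mask fixed-Ser/Thr mixtures
#'
#' Peptide mixtures with Ser or Thr fixed at a degenerate position carry an
#' extra phosphoacceptor and give spuriously high signal; this flags those
#' 18 entries (9 positions x S/T) as excluded. The two acceptor-pair
#' entries are retained. Idempotent; masked entries are excluded from
#' downstream statistics, never dropped silently.
#'
#' @param profile a `specificity_profile`.
#' @return the profile with its `mask` updated.
#' @export
exclude_phosphoacceptor_rows <- function(profile) {
  stopifnot(inherits(profile, "specificity_profile"))
  profile$mask[, c("S", "T")] <- TRUE
  profile
}

#' +1 arginine/proline log-ratio
#'
#' The package's ratiometric +1 statistic from array data:
#' \eqn{\log_2} selectivity of fixed +1 Arg minus fixed +1 Pro. Positive
#' values mean arginine preference; `2^` of the value is the fold
#' preference as read from the array.
#'
#' @param profile a `specificity_profile`.
#' @return numeric log2(R/P) at the +1 position.
#' @export
plus1_log_ratio <- function(profile) {
  stopifnot(inherits(profile, "specificity_profile"))
  if (profile$mask["+1", "R"] || profile$mask["+1", "P"])
    stop("+1 R or P entry is masked; cannot form the ratio", call. = FALSE)
  unname(profile$log2["+1", "R"] - profile$log2["+1", "P"])
}
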