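#' Fit a marginal ancestral sequence reconstruction
#'
#' The package's umbrella fitting function: given an alignment, a tree and a
#' substitution model it (optionally) roots the tree with an outgroup,
#' optimizes branch lengths on the fixed topology, computes marginal
#' ancestral posteriors at every internal node (inside-outside recursion,
#' gamma categories mixed with equal prior weight), places ancestral
#' insertion/deletion characters by Fitch parsimony, and assembles
#' maximum-likelihood ancestor sequences and per-node support summaries.
#'
#' @param aln alignment matrix (see [as_alignment()]).
#' @param tree ape `phylo`; rooted, or rootable via `outgroup`.
#' @param model a `subst_model` (default LG with 4-category gamma,
#'   shape 1).
#' @param outgroup optional character vector of outgroup taxa used to root
#'   the tree first (see [root_with_outgroup()]).
#' @param optimize_lengths re-estimate branch lengths before
#'   reconstruction.
#' @param tol branch-length optimization tolerance.
#' @return Object of class `asr_fit`: list with `tree` (branch lengths as
#'   used), `model`, `loglik`, `posteriors` (named list of
#'   `ancestral_posterior`, one per internal node), `indels`
#'   (`indel_states`), `ml_sequences` (named character vector, gaps placed
#'   from the indel states), `supports` (named list of `support_summary`).
#' @seealso [marginal_ancestral_posterior()], [fitch_indels()],
#'   [sample_alternate_ancestors()]
#' @export
asr <- function(aln, tree, model = subst_model("LG", alpha = 1, k = 4),
                outgroup = NULL, optimize_lengths = TRUE, tol = 1e-4) {
  aln <- as_alignment(aln)
  if (!is.null(outgroup)) tree <- root_with_outgroup(tree, outgroup)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (or provide an outgroup)", call. = FALSE)
  check_taxa(tree, rownames(aln))
  if (optimize_lengths)
    tree <- optimize_branch_lengths(tree, aln, model, tol = tol)

  cache <- lik_cache(tree, aln)
  res <- cache_loglik(cache, model, keep_pass = TRUE)
  K <- length(res$rates)

  # one outside pass per category covers every node at once
  outs <- lapply(seq_len(K), function(k)
    outside_pass(cache, model, res$passes[[k]], res$rates[k],
                 cache$po$length))

  ids <- internal_ids(tree)
  posteriors <- lapply(ids, function(id) {
    S <- length(cache$patterns$weights)
    joint <- matrix(0, 20L, S)
    for (k in seq_len(K))
      joint <- joint + outs[[k]][, , id] * res$passes[[k]]$down[, , id] / K
    post <- t(joint) / colSums(joint)
    post <- post[cache$patterns$map, , drop = FALSE]
    colnames(post) <- aa_alphabet
    ml_idx <- apply(post, 1, which.max)
    structure(list(node = id, node_label = node_label(tree, id),
                   prob = post, ml_residue = aa_alphabet[ml_idx],
                   pp = post[cbind(seq_len(nrow(post)), ml_idx)]),
              class = "ancestral_posterior")
  })
  names(posteriors) <- vapply(posteriors, `[[`, "", "node_label")

  indels <- fitch_indels(tree, aln)
  ml_seq <- vapply(posteriors, ml_ancestral_sequence, "", indels = indels)
  supports <- lapply(posteriors, support_summary)

  structure(list(tree = tree, model = model, loglik = res$loglik,
                 posteriors = posteriors, indels = indels,
                 ml_sequences = ml_seq, supports = supports,
                 n_sites = cache$n_sites),
            class = "asr_fit")
}

#' @export
print.asr_fit <- function(x, ...) {
  cat("Marginal ancestral sequence reconstruction\n")
  cat("  model:", x$model$name, " taxa:", n_tips(x$tree),
      " sites:", x$n_sites, "\n")
  cat("  log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("  internal nodes reconstructed:", length(x$posteriors), "\n")
  invisible(x)
}

#' @export
logLik.asr_fit <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- nrow(object$tree$edge) + object$model$free_params
  class(val) <- "logLik"
  val
}

#' @export
summary.asr_fit <- function(object, ...) {
  tab <- data.frame(
    node = names(object$posteriors),
    mean_pp = vapply(object$supports, `[[`, 0, "mean"),
    var_pp = vapply(object$supports, `[[`, 0, "variance"),
    prop_pp95 = vapply(object$supports, function(s) s$proportion[20], 0),
    row.names = NULL)
  cat("ASR fit:", object$model$name, ", logLik",
      format(object$loglik, digits = 8), "\n\n")
  print(tab, digits = 4)
  invisible(tab)
}

#' Write reconstructed ancestors and posteriors to files
#'
#' @param fit an `asr_fit`.
#' @param fasta,csv optional output paths: ancestor sequences as FASTA and
#'   the per-node, per-site posterior table as CSV (columns: node, site, the
#'   20 residue probabilities, ml_residue, pp).
#' @return invisibly, the posterior table data.frame.
#' @export
export_asr <- function(fit, fasta = NULL, csv = NULL) {
  if (!is.null(fasta)) {
    con <- file(fasta, "w")
    for (nm in names(fit$ml_sequences))
      writeLines(c(paste0(">", nm), fit$ml_sequences[[nm]]), con)
    close(con)
  }
  tab <- do.call(rbind, lapply(fit$posteriors, function(p) {
    data.frame(node = p$node_label, site = seq_len(nrow(p$prob)),
               p$prob, ml_residue = p$ml_residue, pp = p$pp,
               row.names = NULL, check.names = FALSE)
  }))
  rownames(tab) <- NULL
  if (!is.null(csv)) utils::write.csv(tab, csv, row.names = FALSE)
  invisible(tab)
}
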