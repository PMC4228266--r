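# Marginal ancestral reconstruction by the inside-outside (re-rooting)
# recursion, mixing discrete-gamma categories with equal prior weight.

# outside (upward) partials for one category pass. out[, s, v] is the
# probability of all data outside the subtree of v given the state at v,
# weighted by the root prior. At the root out = pi.
outside_pass <- function(cache, model, pass, rate, lengths) {
  tree <- cache$tree
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  S <- dim(pass$down)[2]
  edge <- cache$po$edge
  pi <- model$matrix$frequencies
  out <- array(NA_real_, c(20L, S, nn))
  out[, , root_id(tree)] <- pi
  children_of <- split(seq_len(nrow(edge)), edge[, 1])
  # preorder: reverse postorder guarantees parents before children
  for (e in rev(seq_len(nrow(edge)))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    excl <- out[, , par]
    for (e2 in children_of[[as.character(par)]]) {
      if (e2 != e) excl <- excl * pass$msg[, , e2]
    }
    P <- transition_matrix(model, lengths[e], rate)
    out[, , ch] <- crossprod(P, excl)   # t(P) %*% excl
  }
  out
}

#' Marginal ancestral posterior at an internal node
#'
#' Per site, the posterior probability of each of the 20 residues at `node`
#' is proportional to the likelihood of the full alignment given that
#' residue at that node, computed by combining inside (pruning) and outside
#' partials; gamma rate categories are mixed with equal prior weight and the
#' per-site vectors normalized to 1. Gapped/unknown tips contribute no
#' information. Ancestral gap placement is handled separately by
#' [fitch_indels()].
#'
#' @param tree rooted ape `phylo`.
#' @param aln alignment matrix.
#' @param model a `subst_model`.
#' @param node internal node (ape id or node label).
#' @return Object of class `ancestral_posterior`: list with `node`,
#'   `node_label`, `prob` (sites x 20 matrix), `ml_residue` (character,
#'   ties broken by [aa_alphabet] order), `pp` (posterior probability of the
#'   ML residue).
#' @export
marginal_ancestral_posterior <- function(tree, aln, model, node) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  id <- resolve_node(tree, node)
  if (id <= n_tips(tree))
    stop("node must be internal, got leaf ", node_label(tree, id),
         call. = FALSE)
  cache <- lik_cache(tree, as_alignment(aln))
  res <- cache_loglik(cache, model, keep_pass = TRUE)
  posterior_from_passes(cache, model, res, id)
}

# shared with asr(): posterior at node id from retained category passes
posterior_from_passes <- function(cache, model, res, id) {
  tree <- cache$tree
  K <- length(res$rates)
  S <- length(cache$patterns$weights)
  joint <- matrix(0, 20L, S)
  for (k in seq_len(K)) {
    out_k <- outside_pass(cache, model, res$passes[[k]], res$rates[k],
                          cache$po$length)
    joint <- joint + out_k[, , id] * res$passes[[k]]$down[, , id] / K
  }
  post <- t(joint) / colSums(joint)        # patterns x 20
  post <- post[cache$patterns$map, , drop = FALSE]
  colnames(post) <- aa_alphabet
  ml_idx <- apply(post, 1, which.max)      # first max = alphabet-order tie-break
  structure(list(node = id,
                 node_label = node_label(tree, id),
                 prob = post,
                 ml_residue = aa_alphabet[ml_idx],
                 pp = post[cbind(seq_len(nrow(post)), ml_idx)]),
            class = "ancestral_posterior")
}

#' @export
print.ancestral_posterior <- function(x, ...) {
  cat("Ancestral posterior at node", x$node_label,
      "(", nrow(x$prob), "sites )\n")
  cat("  mean PP(ML):", format(mean(x$pp), digits = 4),
      " min:", format(min(x$pp), digits = 4), "\n")
  invisible(x)
}

#' Maximum-likelihood ancestral sequence
#'
#' Combines a marginal posterior with Fitch indel states: a site whose indel
#' character is absent at the node becomes a gap regardless of the residue
#' posterior; otherwise the ML residue is used (ties already resolved toward
#' the alphabetically earlier residue).
#'
#' @param posterior an `ancestral_posterior`.
#' @param indels optional `indel_states` matrix from [fitch_indels()]; when
#'   `NULL` no sites are gapped.
#' @return character string of length = number of sites.
#' @export
ml_ancestral_sequence <- function(posterior, indels = NULL) {
  res <- posterior$ml_residue
  if (!is.null(indels)) {
    pres <- indels$presence[as.character(posterior$node), ]
    if (length(pres) != length(res))
      stop("posterior and indel matrix cover different site counts",
           call. = FALSE)
    res[!pres] <- aa_gap
  }
  paste(res, collapse = "")
}

#' Sample alternate ancestral sequences from the posterior
#'
#' Draws each site independently from its marginal posterior distribution
#' (sites whose indel state is absent stay gaps) and reports, per sample,
#' the number of sites differing from the ML sequence.
#'
#' @param posterior an `ancestral_posterior`.
#' @param n number of sequences to draw.
#' @param seed integer seed (reproducible draws).
#' @param indels optional `indel_states` from [fitch_indels()].
#' @return list with `sequences` (character vector length `n`) and
#'   `n_diff_from_ml` (integer vector).
#' @export
sample_alternate_ancestors <- function(posterior, n, seed = 1L,
                                       indels = NULL) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  S <- nrow(posterior$prob)
  present <- rep(TRUE, S)
  if (!is.null(indels))
    present <- indels$presence[as.character(posterior$node), ]
  ml <- posterior$ml_residue
  seqs <- character(n)
  ndiff <- integer(n)
  for (i in seq_len(n)) {
    draw <- vapply(seq_len(S), function(s) {
      if (!present[s]) return(aa_gap)
      sample(aa_alphabet, 1L, prob = posterior$prob[s, ])
    }, character(1))
    ndiff[i] <- sum(draw != ml & present)
    draw[!present] <- aa_gap
    seqs[i] <- paste(draw, collapse = "")
  }
  list(sequences = seqs, n_diff_from_ml = ndiff)
}

#' Summarize reconstruction support
#'
#' Bins the per-site posterior probabilities of the ML residues into twenty
#' 5%-wide bins over \[0, 1\] and reports the proportion of sites per bin
#' together with the mean and variance of PP(ML).
#'
#' @param posterior an `ancestral_posterior`, or a numeric vector of PP(ML)
#'   values.
#' @return Object of class `support_summary`: list with `breaks`,
#'   `proportion` (length 20, sums to 1), `mean`, `variance`, `n_sites`.
#' @export
support_summary <- function(posterior) {
  pp <- if (inherits(posterior, "ancestral_posterior")) posterior$pp
        else as.numeric(posterior)
  if (!length(pp)) stop("empty posterior", call. = FALSE)
  breaks <- seq(0, 1, by = 0.05)
  bin <- findInterval(pp, breaks, rightmost.closed = TRUE)
  prop <- tabulate(bin, nbins = 20L) / length(pp)
  structure(list(breaks = breaks, proportion = prop,
                 mean = mean(pp),
                 variance = stats::var(pp) * (length(pp) - 1) / length(pp),
                 n_sites = length(pp)),
            class = "support_summary")
}

#' @export
print.support_summary <- function(x, ...) {
  cat("Reconstruction support over", x$n_sites, "sites\n")
  cat("  mean PP(ML):", format(x$mean, digits = 4),
      " variance:", format(x$variance, digits = 4), "\n")
  top <- x$proportion[20]
  cat("  proportion with PP(ML) in [0.95, 1]:", format(top, digits = 4), "\n")
  invisible(x)
}
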