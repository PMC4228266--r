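# Felsenstein pruning over an amino-acid alignment, with discrete-gamma
# rate mixing. Partials are 20 x S matrices per node; gaps and unknowns are
# missing data (all-ones tip partials).

# tip partial matrix for a vector of symbols (one per site)
tip_partials <- function(symbols) {
  S <- length(symbols)
  M <- matrix(0, 20L, S)
  idx <- aa_index(symbols)
  miss <- aa_is_missing(symbols)
  bad <- is.na(idx) & !miss
  if (any(bad))
    stop("invalid symbol(s): ", paste(unique(symbols[bad]), collapse = ", "),
         call. = FALSE)
  M[, miss] <- 1
  obs <- which(!miss)
  if (length(obs)) M[cbind(idx[obs], obs)] <- 1
  M
}

# one-time setup shared by every likelihood evaluation on a fixed topology:
# pattern compression, tip partials, postorder edge list
lik_cache <- function(tree, aln, validate = TRUE) {
  aln <- as_alignment(aln)
  if (validate) check_taxa(tree, rownames(aln))
  cp <- compress_patterns(aln)
  tipmats <- lapply(tree$tip.label, function(tx) tip_partials(cp$columns[tx, ]))
  po <- postorder_edges(tree)
  list(tree = tree, patterns = cp, tipmats = tipmats, po = po,
       n_sites = ncol(aln))
}

# downward pass for one rate category. Returns list(down = [20,S,nodes],
# msg = [20,S,edges]) where msg[, , e] is P_e %*% down[child(e)].
category_pass <- function(cache, model, rate, lengths) {
  tree <- cache$tree
  nt <- n_tips(tree)
  nn <- nt + tree$Nnode
  S <- ncol(cache$tipmats[[1]])
  edge <- cache$po$edge
  down <- array(NA_real_, c(20L, S, nn))
  msg <- array(NA_real_, c(20L, S, nrow(edge)))
  for (i in seq_len(nt)) down[, , i] <- cache$tipmats[[i]]
  init <- rep(FALSE, nn)
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1]; ch <- edge[e, 2]
    P <- transition_matrix(model, lengths[e], rate)
    m <- P %*% down[, , ch]
    msg[, , e] <- m
    if (!init[par]) {
      down[, , par] <- m
      init[par] <- TRUE
    } else {
      down[, , par] <- down[, , par] * m
    }
  }
  list(down = down, msg = msg)
}

# log-likelihood from a cache; lengths defaults to the tree's own lengths.
# keep_pass = TRUE retains per-category passes for the posterior code.
cache_loglik <- function(cache, model, lengths = cache$po$length,
                         keep_pass = FALSE) {
  rates <- model_rates(model)
  K <- length(rates)
  pi <- model$matrix$frequencies
  rid <- root_id(cache$tree)
  sitelik <- 0
  passes <- if (keep_pass) vector("list", K) else NULL
  for (k in seq_len(K)) {
    ps <- category_pass(cache, model, rates[k], lengths)
    sitelik <- sitelik + crossprod(pi, ps$down[, , rid])[1, ] / K
    if (keep_pass) passes[[k]] <- ps
  }
  out <- list(loglik = sum(cache$patterns$weights * log(sitelik)),
              site_likelihood = sitelik, passes = passes, rates = rates)
  out
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Computes the log-likelihood of an alignment on a fixed tree under a
#' reversible amino-acid model with optional discrete-gamma rate mixing:
#' per site, \eqn{\sum_k \frac{1}{K}\sum_a \pi_a L_k(a)} with partial
#' likelihoods accumulated in postorder. Gap and `X` symbols contribute
#' all-ones partials (missing data), so an all-gap column has likelihood 1.
#'
#' @param tree ape `phylo` with branch lengths in substitutions/site.
#' @param aln alignment matrix (see [as_alignment()]); taxa must match the
#'   tree's tips.
#' @param model a `subst_model`.
#' @param per_site if `TRUE`, also return the per-site log-likelihoods.
#' @return total log-likelihood (numeric scalar), or a list with `loglik`
#'   and `site_loglik` when `per_site = TRUE`.
#' @export
prune_loglik <- function(tree, aln, model, per_site = FALSE) {
  cache <- lik_cache(tree, aln)
  res <- cache_loglik(cache, model)
  if (!per_site) return(res$loglik)
  list(loglik = res$loglik,
       site_loglik = log(res$site_likelihood)[cache$patterns$map])
}

#' Log-likelihood of a single alignment column
#'
#' @param tree ape `phylo`.
#' @param column named character vector of symbols, one per tree tip.
#' @param model a `subst_model`.
#' @return log-likelihood of the column.
#' @rdname prune_loglik
#' @export
prune_site_likelihood <- function(tree, column, model) {
  if (is.null(names(column)))
    stop("column must be named by taxon", call. = FALSE)
  aln <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  prune_loglik(tree, aln, model)
}
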