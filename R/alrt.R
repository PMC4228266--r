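#' Approximate likelihood-ratio branch support
#'
#' Support for an internal branch expressed as the ratio of the likelihood
#' of the input topology to the better of the two nearest-neighbour
#' interchange (NNI) rearrangements of that branch, all three with branch
#' lengths re-optimized. Values below 1 indicate the input tree is not
#' locally optimal for that branch and are reported as-is.
#'
#' @param tree rooted ape `phylo`.
#' @param aln alignment matrix.
#' @param model a `subst_model`.
#' @param branch the internal branch, identified by its child node (ape id
#'   or internal-node label).
#' @param tol branch-length optimization tolerance.
#' @return the aLR value, with attribute `logliks` giving the three
#'   optimized log-likelihoods (input, nni1, nni2).
#' @export
approx_likelihood_ratio <- function(tree, aln, model, branch, tol = 1e-3) {
  v <- resolve_node(tree, branch)
  if (v <= n_tips(tree))
    stop("branch must be internal (its child node is a leaf)", call. = FALSE)
  u <- tree$edge[match(v, tree$edge[, 2]), 1]
  if (is.na(u)) stop("node has no parent branch (root?)", call. = FALSE)

  kids_v <- tree$edge[tree$edge[, 1] == v, 2]
  sib <- setdiff(tree$edge[tree$edge[, 1] == u, 2], v)
  if (length(kids_v) < 2L || length(sib) < 1L)
    stop("branch does not admit an NNI rearrangement", call. = FALSE)
  if (u == root_id(tree) && length(sib) == 1L) {
    # a two-child root is not a real vertex of the unrooted tree: the
    # branch u-v corresponds to the unrooted edge v-sibling, so the swap
    # partner is a child of the sibling
    if (sib <= n_tips(tree))
      stop("branch is terminal on the unrooted tree", call. = FALSE)
    w_par <- sib
    w <- tree$edge[tree$edge[, 1] == sib, 2][1]
  } else {
    w_par <- u
    w <- sib[1]
  }

  swap_tree <- function(a) {
    tr <- tree
    e1 <- which(tr$edge[, 1] == v & tr$edge[, 2] == a)
    e2 <- which(tr$edge[, 1] == w_par & tr$edge[, 2] == w)
    tr$edge[e1, 2] <- w
    tr$edge[e2, 2] <- a
    tr
  }
  cands <- list(tree, swap_tree(kids_v[1]), swap_tree(kids_v[2]))
  ll <- vapply(cands, function(tr) {
    attr(optimize_branch_lengths(tr, aln, model, tol = tol), "loglik")
  }, numeric(1))
  alr <- exp(ll[1] - max(ll[2], ll[3]))
  attr(alr, "logliks") <- ll
  alr
}

#' Rank substitution models by AIC
#'
#' For each candidate model, computes the alignment log-likelihood on the
#' fixed tree (when the candidate has gamma rates, its shape is first
#' optimized by bounded search on \[0.05, 50\]) and scores
#' \eqn{AIC = 2k - 2\ln L}, where \eqn{k} counts the model's free
#' parameters (+1 for an estimated gamma shape; 0 for fixed empirical
#' exchangeabilities and frequencies) plus the number of branch lengths.
#' Input branch lengths are held fixed across candidates so rankings are
#' comparable.
#'
#' @param aln alignment matrix.
#' @param tree ape `phylo`.
#' @param candidates non-empty list of `subst_model` objects.
#' @param alpha_tol tolerance of the gamma-shape search.
#' @return data.frame sorted by ascending AIC, with columns `model`,
#'   `alpha`, `k`, `loglik`, `aic`; the (possibly alpha-updated) model
#'   objects are in attribute `models`, best first.
#' @export
aic_select <- function(aln, tree, candidates, alpha_tol = 1e-4) {
  if (!length(candidates)) stop("candidates must be non-empty", call. = FALSE)
  aln <- as_alignment(aln)
  check_taxa(tree, rownames(aln))
  cache <- lik_cache(tree, aln)
  n_branch <- nrow(tree$edge)

  rows <- lapply(candidates, function(m) {
    alpha <- NA_real_
    if (!is.null(m$gamma)) {
      f <- function(a) {
        m2 <- subst_model(m$matrix, alpha = a, k = m$gamma$k)
        cache_loglik(cache, m2)$loglik
      }
      op <- stats::optimize(f, c(0.05, 50), maximum = TRUE, tol = alpha_tol)
      alpha <- op$maximum
      m <- subst_model(m$matrix, alpha = alpha, k = m$gamma$k)
      ll <- op$objective
    } else {
      ll <- cache_loglik(cache, m)$loglik
    }
    k <- m$free_params + n_branch
    list(model = m, row = data.frame(model = m$name, alpha = alpha, k = k,
                                     loglik = ll, aic = 2 * k - 2 * ll))
  })
  tab <- do.call(rbind, lapply(rows, `[[`, "row"))
  ord <- order(tab$aic)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "models") <- lapply(rows, `[[`, "model")[ord]
  tab
}
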