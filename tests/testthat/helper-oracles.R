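# Brute-force oracles and small fixtures, independent of the pruning /
# Fitch implementations they check.

# random rooted binary tree with labelled internals
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 0.6))
  tr$node.label <- paste0("i", seq_len(tr$Nnode))
  tr
}

# random alignment column (possibly with gaps) for the tree's tips
random_column <- function(tree, seed, p_gap = 0.15) {
  set.seed(seed)
  syms <- ifelse(stats::runif(length(tree$tip.label)) < p_gap, "-",
                 sample(aa_alphabet, length(tree$tip.label), replace = TRUE))
  stats::setNames(syms, tree$tip.label)
}

# exhaustive likelihood and marginal posteriors for one column by direct
# summation over all internal-node state assignments (one rate category,
# or a small gamma mixture summed category by category)
enum_column <- function(tree, column, model) {
  nt <- length(tree$tip.label)
  n_int <- tree$Nnode
  rid <- nt + 1L
  pi <- model$matrix$frequencies
  rates <- if (is.null(model$gamma)) 1 else model$gamma$rates
  K <- length(rates)
  grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  tip_idx <- match(toupper(column[tree$tip.label]), aa_alphabet)  # NA = missing
  total_w <- 0
  post <- matrix(0, n_int, 20L)
  for (k in seq_len(K)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
      transition_matrix(model, tree$edge.length[e], rates[k]))
    w <- pi[grid[, rid - nt]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      a <- grid[, par - nt]
      if (ch <= nt) {
        if (!is.na(tip_idx[ch])) w <- w * Ps[[e]][cbind(a, tip_idx[ch])]
        # missing tip: sums to 1, no factor
      } else {
        w <- w * Ps[[e]][cbind(a, grid[, ch - nt])]
      }
    }
    w <- w / K
    total_w <- total_w + sum(w)
    for (j in seq_len(n_int))
      post[j, ] <- post[j, ] + tapply(w, factor(grid[, j], levels = 1:20), sum)
  }
  post[is.na(post)] <- 0
  list(loglik = log(total_w), posterior = post / rowSums(post))
}

# exhaustive Fitch cost for one binary presence column
enum_fitch_cost <- function(tree, present_leaf) {
  n_int <- tree$Nnode
  nt <- length(tree$tip.label)
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    pres <- c(present_leaf,
              as.logical(bitwAnd(mask, 2L^(0:(n_int - 1L)))))
    best <- min(best, sum(pres[tree$edge[, 1]] != pres[tree$edge[, 2]]))
  }
  best
}

# labelling cost of a presence assignment
labelling_cost <- function(tree, presence_col) {
  sum(presence_col[tree$edge[, 1]] != presence_col[tree$edge[, 2]])
}
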