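# Rate-matrix construction, gamma discretization, transition probabilities
# and AIC model ranking.

test_that("rate matrix invariants hold for uniform, bundled and random inputs", {
  # uniform exchangeabilities + frequencies: all off-diagonals equal
  S <- matrix(1, 20, 20)
  rm <- build_rate_matrix(S, rep(1 / 20, 20))
  off <- rm$Q[row(rm$Q) != col(rm$Q)]
  expect_lt(diff(range(off)), 1e-12)
  expect_lt(max(abs(rowSums(rm$Q))), 1e-12)

  for (nm in c("LG", "WAG", "JTT")) {
    em <- empirical_matrix(nm)
    pi <- em$frequencies
    expect_equal(sum(pi), 1, tolerance = 1e-12)
    expect_equal(-sum(pi * diag(em$Q)), 1, tolerance = 1e-9)
    expect_lt(max(abs(rowSums(em$Q))), 1e-9)
    # detailed balance over all 380 ordered pairs
    flux <- pi * em$Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
  }

  set.seed(11)
  for (i in 1:5) {
    S <- matrix(stats::rexp(400), 20, 20)
    S <- S + t(S)
    f <- stats::rgamma(20, 2); f <- f / sum(f)
    rm <- build_rate_matrix(S, f)
    flux <- rm$frequencies * rm$Q
    expect_lt(max(abs(flux - t(flux))), 1e-12)
  }
})

test_that("rate matrix construction rejects bad input naming the culprit", {
  S <- matrix(1, 20, 20)
  S[2, 1] <- 5                           # asymmetric
  expect_error(build_rate_matrix(S, rep(1 / 20, 20)), "symmetric")
  f <- rep(1 / 20, 20)
  f[match("W", aa_alphabet)] <- 0
  expect_error(build_rate_matrix(matrix(1, 20, 20), f / sum(f)), "W")
})

test_that("gamma discretization matches a quadrature oracle and its limits", {
  # vanishing heterogeneity: spread scales as 1/sqrt(alpha)
  expect_lt(max(abs(discretize_gamma(1e6, 4)$rates - 1)), 2e-3)
  expect_lt(max(abs(discretize_gamma(1e8, 4)$rates - 1)), 2e-4)
  # unit mean for assorted shapes
  for (a in c(0.1, 0.5, 1, 3, 20)) {
    g <- discretize_gamma(a, 4)
    expect_equal(sum(g$rates * g$weights), 1, tolerance = 1e-9)
    expect_true(all(diff(g$rates) >= 0))
  }
  # quadrature oracle: numeric integration of the category means
  a <- 0.5; K <- 4
  qb <- stats::qgamma(seq(0, 1, length.out = K + 1), shape = a, rate = a)
  oracle <- vapply(seq_len(K), function(k) {
    K * stats::integrate(function(x) x * stats::dgamma(x, a, rate = a),
                         qb[k], qb[k + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(discretize_gamma(a, K)$rates, oracle, tolerance = 1e-6)
  # increasing alpha shrinks the rate spread
  spread <- vapply(c(0.2, 0.5, 1, 2, 8),
                   function(a) diff(range(discretize_gamma(a, 4)$rates)), 0)
  expect_true(all(diff(spread) < 0))
  expect_error(discretize_gamma(0, 4), "alpha")
  expect_error(discretize_gamma(1, 0), "positive integer")
})

test_that("transition matrices are stochastic, consistent and stationary", {
  m <- subst_model("LG")
  expect_equal(transition_matrix(m, 0), diag(20), ignore_attr = TRUE,
               tolerance = 1e-12)
  pi <- m$matrix$frequencies
  P100 <- transition_matrix(m, 100)
  expect_lt(max(abs(sweep(P100, 2, pi))), 1e-6)
  set.seed(3)
  for (i in 1:5) {
    s <- stats::runif(1, 0, 2); t <- stats::runif(1, 0, 2)
    r <- stats::runif(1, 0.2, 3)
    expect_equal(transition_matrix(m, s, r) %*% transition_matrix(m, t, r),
                 transition_matrix(m, s + t, r), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
  for (t in c(0, 1e-4, 0.01, 0.5, 5, 100)) {
    P <- transition_matrix(m, t)
    expect_true(all(P >= 0 & P <= 1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  }
  expect_error(transition_matrix(m, -0.1), "t must be")
})

test_that("AIC ranks gamma over single-rate on heterogeneous data and is order-invariant", {
  tr <- simulate_tree(12, seed = 41, height = 1.5)
  truth <- subst_model("LG", alpha = 0.5, k = 4)
  sim <- simulate_evolution(tr, truth, 300, seed = 42)
  cands <- list(subst_model("LG"), subst_model("LG", alpha = 1, k = 4))
  sel <- aic_select(sim$alignment, tr, cands)
  expect_equal(sel$model[1], "LG+G4")
  expect_equal(sel$aic, 2 * sel$k - 2 * sel$loglik)
  # single candidate comes back as best
  one <- aic_select(sim$alignment, tr, cands[1])
  expect_equal(nrow(one), 1L)
  # invariance to taxon order and column order
  aln2 <- sim$alignment[rev(rownames(sim$alignment)), ]
  set.seed(9); aln3 <- aln2[, sample(ncol(aln2))]
  sel3 <- aic_select(aln3, tr, cands)
  expect_equal(sel3$aic, sel$aic, tolerance = 1e-6)
  # taxa mismatch names the offenders
  bad <- sim$alignment
  rownames(bad)[1] <- "nosuch"
  expect_error(aic_select(bad, tr, cands), "nosuch")
})
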