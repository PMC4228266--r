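# Pruning likelihood, branch-length optimization, marginal posteriors,
# indel parsimony, alternate-ancestor sampling, supports, rooting, aLR.

m_lg <- subst_model("LG")

test_that("pruning likelihood agrees with simple closed forms", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  pi <- m_lg$matrix$frequencies
  expect_equal(prune_site_likelihood(tr, c(A = "A", B = "A"), m_lg),
               log(pi[["A"]]), tolerance = 1e-12, ignore_attr = TRUE)
  # all-gap column carries no information
  tr2 <- random_tree(5, seed = 1)
  col <- stats::setNames(rep("-", 5), tr2$tip.label)
  expect_equal(prune_site_likelihood(tr2, col, m_lg), 0, tolerance = 1e-12)
  expect_error(prune_site_likelihood(tr2, unname(col), m_lg), "named")
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (i in 1:6) {
    n <- 3 + (i %% 3)
    tr <- random_tree(n, seed = 100 + i)
    col <- random_column(tr, seed = 200 + i)
    oracle <- enum_column(tr, col, m_lg)
    expect_equal(prune_site_likelihood(tr, col, m_lg), oracle$loglik,
                 tolerance = 1e-10)
  }
  # with a 2-category gamma mixture too
  mg <- subst_model("LG", alpha = 0.7, k = 2)
  tr <- random_tree(4, seed = 300)
  col <- random_column(tr, seed = 301)
  expect_equal(prune_site_likelihood(tr, col, mg),
               enum_column(tr, col, mg)$loglik, tolerance = 1e-10)
})

test_that("full-alignment likelihood matches phangorn", {
  skip_if_not_installed("phangorn")
  tr <- simulate_tree(6, seed = 3, height = 0.8)
  mg <- subst_model("LG", alpha = 0.7, k = 4)
  sim <- simulate_evolution(tr, mg, 80, indel_rate = 0.02, seed = 11)
  ours <- prune_loglik(tr, sim$alignment, mg)
  pd <- phangorn::phyDat(sim$alignment, type = "AA")
  ref <- phangorn::pml(tr, pd, model = "LG", k = 4, shape = 0.7)$logLik
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("branch-length optimization is monotone and recovers truth", {
  set.seed(2)
  tr <- simulate_tree(8, seed = 9, height = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  sim <- simulate_evolution(tr, m_lg, 600, seed = 21)
  tr0 <- tr
  tr0$edge.length <- rep(0.2, nrow(tr$edge))
  before <- prune_loglik(tr0, sim$alignment, m_lg)
  opt <- optimize_branch_lengths(tr0, sim$alignment, m_lg)
  expect_gte(attr(opt, "loglik"), before)
  expect_equal(attr(opt, "loglik"), prune_loglik(opt, sim$alignment, m_lg),
               tolerance = 1e-8)
  key <- paste(tr$edge[, 1], tr$edge[, 2])
  est <- opt$edge.length[match(key, paste(opt$edge[, 1], opt$edge[, 2]))]
  relerr <- abs(est - tr$edge.length) / tr$edge.length
  expect_lt(stats::median(relerr), 0.25)
  expect_gt(stats::cor(est, tr$edge.length), 0.5)
})

test_that("identical sequences drive branch lengths to the lower clamp", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  aln <- as_alignment(c(A = strrep("ACDEF", 10), B = strrep("ACDEF", 10)))
  opt <- optimize_branch_lengths(tr, aln, m_lg)
  expect_true(all(opt$edge.length < 1e-6))
})

test_that("marginal posteriors equal enumeration and behave in the concordant limit", {
  for (i in 1:5) {
    n <- 4 + (i %% 2)
    tr <- random_tree(n, seed = 400 + i)
    col <- random_column(tr, seed = 500 + i)
    oracle <- enum_column(tr, col, m_lg)
    for (j in seq_len(tr$Nnode)) {
      mp <- marginal_ancestral_posterior(
        tr, matrix(col, ncol = 1, dimnames = list(names(col), NULL)),
        m_lg, n + j)
      expect_equal(unname(mp$prob[1, ]), unname(oracle$posterior[j, ]),
                   tolerance = 1e-10)
      expect_equal(sum(mp$prob[1, ]), 1, tolerance = 1e-9)
    }
  }
  # concordant data on short branches: reconstruction is near-certain
  star <- ape::read.tree(
    text = "(((A:0.01,B:0.01)i:0.01,C:0.01)j:0.01,D:0.01)root;")
  aln <- as_alignment(c(A = "A", B = "A", C = "A", D = "A"))
  mp <- marginal_ancestral_posterior(star, aln, m_lg, "root")
  expect_equal(mp$ml_residue, "A")
  expect_gt(mp$pp, 0.99)
  expect_error(marginal_ancestral_posterior(star, aln, m_lg, "A"), "leaf")
})

test_that("ML sequence assembly respects indels and the tie rule", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.1)i1:0.1,(C:0.1,D:0.1)i2:0.1)r;")
  aln <- as_alignment(c(A = "K-", B = "K-", C = "K-", D = "KA"))
  fit <- asr(aln, tr, m_lg, optimize_lengths = FALSE)
  # site 2 is absent in i1's subtree -> gap wins over any posterior
  expect_equal(substr(fit$ml_sequences[["i1"]], 2, 2), "-")
  expect_equal(substr(fit$ml_sequences[["i1"]], 1, 1), "K")
  # exact two-way tie resolves to the alphabetically earlier residue
  post <- structure(list(node = 6L, node_label = "i1",
                         prob = matrix(c(0.5, 0.5, rep(0, 18)), 1, 20,
                                       dimnames = list(NULL, aa_alphabet)),
                         ml_residue = "A", pp = 0.5),
                    class = "ancestral_posterior")
  idx <- max.col(post$prob, ties.method = "first")
  expect_equal(aa_alphabet[idx], "A")
  expect_equal(ml_ancestral_sequence(post), "A")
})

test_that("alternate-ancestor sampling is reproducible and calibrated", {
  prob <- matrix(rep(c(0.7, 0.3, rep(0, 18)), 10), nrow = 10, byrow = TRUE,
                 dimnames = list(NULL, aa_alphabet))
  post <- structure(list(node = 6L, node_label = "x", prob = prob,
                         ml_residue = rep("A", 10), pp = rep(0.7, 10)),
                    class = "ancestral_posterior")
  s1 <- sample_alternate_ancestors(post, 5, seed = 42)
  s2 <- sample_alternate_ancestors(post, 5, seed = 42)
  expect_identical(s1, s2)
  # degenerate posterior: every draw equals the ML sequence
  prob1 <- matrix(rep(c(1, rep(0, 19)), 10), nrow = 10, byrow = TRUE,
                  dimnames = list(NULL, aa_alphabet))
  post1 <- structure(list(node = 6L, node_label = "x", prob = prob1,
                          ml_residue = rep("A", 10), pp = rep(1, 10)),
                     class = "ancestral_posterior")
  s3 <- sample_alternate_ancestors(post1, 3, seed = 1)
  expect_true(all(s3$sequences == strrep("A", 10)))
  expect_true(all(s3$n_diff_from_ml == 0))
  # binomial check: 10,000 draws of a 0.7/0.3 site
  one <- structure(list(node = 6L, node_label = "x",
                        prob = prob[1, , drop = FALSE],
                        ml_residue = "A", pp = 0.7),
                   class = "ancestral_posterior")
  s4 <- sample_alternate_ancestors(one, 10000, seed = 7)
  phat <- mean(s4$sequences == "A")
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))
})

test_that("Fitch indel placement equals the exhaustive minimum", {
  tr <- random_tree(6, seed = 600)
  # cherry with one gapped leaf: ancestors present, one change
  aln <- matrix("A", 6, 1, dimnames = list(tr$tip.label, NULL))
  fi0 <- fitch_indels(tr, aln)
  expect_equal(fi0$cost, 0L)
  expect_true(all(fi0$presence))
  set.seed(601)
  for (i in 1:20) {
    pres <- stats::runif(6) > 0.4
    if (!any(pres)) pres[1] <- TRUE
    aln <- matrix(ifelse(pres, "A", "-"), 6, 1,
                  dimnames = list(tr$tip.label, NULL))
    fi <- fitch_indels(tr, aln)
    best <- enum_fitch_cost(tr, pres)
    expect_equal(fi$cost[1], best)
    expect_equal(labelling_cost(tr, fi$presence[, 1]), best)
    expect_equal(unname(fi$presence[1:6, 1]), unname(pres))
  }
})

test_that("support summaries bin PP(ML) into twenty 5% bins", {
  s <- support_summary(c(0.52, 0.57, 0.98))
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$proportion[c(11, 12, 20)], rep(1 / 3, 3))
  expect_equal(s$mean, mean(c(0.52, 0.57, 0.98)))
  sall <- support_summary(rep(1, 50))
  expect_equal(sall$proportion[20], 1)
  expect_equal(sall$mean, 1)
  expect_equal(sall$variance, 0)
  set.seed(5)
  for (i in 1:5)
    expect_equal(sum(support_summary(stats::runif(30))$proportion), 1)
})

test_that("outgroup rooting splits the attachment branch equally", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,(C:0.15,D:0.25):0.3);")
  rt <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rt))
  kids <- rt$edge[rt$edge[, 1] == length(rt$tip.label) + 1L, 2]
  expect_true(match("A", rt$tip.label) %in% kids)
  # conservation: the two root-adjacent lengths sum to the original branch
  ridx <- which(rt$edge[, 1] == length(rt$tip.label) + 1L)
  expect_equal(sum(rt$edge.length[ridx]), 0.1, tolerance = 1e-12)
  expect_equal(diff(rt$edge.length[ridx]), 0, tolerance = 1e-12)
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")), "all taxa")
  # non-monophyletic outgroup is refused with the taxa listed
  expect_error(root_with_outgroup(tr, c("A", "C")), "monophyletic")
})

test_that("aLR supports a real internal branch and stays near 1 without signal", {
  tr <- ape::read.tree(
    text = "((A:0.2,B:0.2)n6:0.5,(C:0.2,D:0.2)n7:0.01)n5;")
  sim <- simulate_evolution(tr, m_lg, 1500, seed = 31)
  alr <- approx_likelihood_ratio(tr, sim$alignment, m_lg, "n6")
  expect_gt(alr, 10)
  ll <- attr(alr, "logliks")
  expect_gte(ll[1], max(ll[2:3]))       # input is the best configuration
  star <- ape::read.tree(
    text = "((A:0.2,B:0.2)n6:0.00000001,(C:0.2,D:0.2)n7:0.00000001)n5;")
  sim2 <- simulate_evolution(star, m_lg, 400, seed = 32)
  alr2 <- approx_likelihood_ratio(star, sim2$alignment, m_lg, "n6")
  expect_gt(alr2, 0.5)
  expect_lt(alr2, 2)
  expect_error(approx_likelihood_ratio(tr, sim$alignment, m_lg, "A"),
               "leaf|internal")
})

test_that("likelihood and posteriors are invariant to taxon order", {
  tr <- random_tree(5, seed = 700)
  mg <- subst_model("LG", alpha = 1, k = 2)
  sim <- simulate_evolution(tr, mg, 40, seed = 701)
  aln2 <- sim$alignment[rev(rownames(sim$alignment)), ]
  expect_equal(prune_loglik(tr, sim$alignment, mg),
               prune_loglik(tr, aln2, mg), tolerance = 1e-12)
  p1 <- marginal_ancestral_posterior(tr, sim$alignment, mg, 6L)
  p2 <- marginal_ancestral_posterior(tr, aln2, mg, 6L)
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)
})
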