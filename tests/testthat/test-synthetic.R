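# Generators: reproducibility, legal outputs, statistical structure.

test_that("Yule trees have the requested size, height and reproducibility", {
  tr2 <- simulate_tree(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  for (n in c(3, 8, 16)) {
    tr <- simulate_tree(n, seed = n, height = 0.7)
    expect_equal(length(tr$tip.label), n)
    expect_equal(max(ape::node.depth.edgelength(tr)[1:n]), 0.7,
                 tolerance = 1e-9)
  }
  expect_identical(ape::write.tree(simulate_tree(7, seed = 5)),
                   ape::write.tree(simulate_tree(7, seed = 5)))
  expect_error(simulate_tree(1), "n_taxa")
})

test_that("sequence evolution respects zero branches, the alphabet and seeds", {
  m <- subst_model("LG")
  tr <- random_tree(5, seed = 900)
  tr0 <- tr
  tr0$edge.length[] <- 0
  sim0 <- simulate_evolution(tr0, m, 50, seed = 1)
  root_seq <- sim0$truth$node_sequences[["i1"]]
  expect_true(all(apply(sim0$alignment, 1, paste, collapse = "") == root_seq))
  sim <- simulate_evolution(tr, m, 200, indel_rate = 0.05, seed = 2)
  expect_true(all(sim$alignment %in% c(aa_alphabet, "-")))
  expect_identical(simulate_evolution(tr, m, 50, seed = 3)$alignment,
                   simulate_evolution(tr, m, 50, seed = 3)$alignment)
})

test_that("evolved composition approaches equilibrium and per-branch rates match theory", {
  m <- subst_model("LG")
  pi <- m$matrix$frequencies
  # one long branch: chi-square against pi, and substitution fraction
  tr <- ape::read.tree(text = "(A:6,B:6);")
  sim <- simulate_evolution(tr, m, 10000, seed = 4)
  counts <- table(factor(sim$alignment["A", ], levels = aa_alphabet))
  expect_gt(stats::chisq.test(counts, p = pi)$p.value, 0.001)
  # substitution fraction on a t=0.3 branch vs 1 - sum(pi_a P_aa)
  tr3 <- ape::read.tree(text = "(A:0.3,B:0.0000001);")
  sim3 <- simulate_evolution(tr3, m, 10000, seed = 5)
  root_chars <- strsplit(sim3$truth$node_sequences[[3]], "")[[1]]
  frac <- mean(sim3$alignment["A", ] != root_chars)
  P <- transition_matrix(m, 0.3)
  expected <- 1 - sum(pi * diag(P))
  expect_lt(abs(frac - expected), 3 * sqrt(expected * (1 - expected) / 10000))
  # indel fraction tracks the requested toggle probability
  tr4 <- ape::read.tree(text = "(A:1,B:1);")
  sim4 <- simulate_evolution(tr4, m, 10000, indel_rate = 0.2, seed = 6)
  p_flip <- (1 - exp(-2 * 0.2 * 1)) / 2
  gapfrac <- mean(sim4$alignment["A", ] == "-")
  expect_lt(abs(gapfrac - p_flip), 3 * sqrt(p_flip * (1 - p_flip) / 10000))
})

test_that("PSPL simulation is exact at zero noise and seed-reproducible", {
  w <- matrix(1, 9, 20, dimnames = list(kinasr:::pspl_positions, aa_alphabet))
  reps <- simulate_pspl(w, 1, noise_cv = 0, seed = 1, scale = 250)
  expect_true(all(reps[[1]]$intensity == 250))
  expect_identical(simulate_pspl(w, 2, 0.2, seed = 9),
                   simulate_pspl(w, 2, 0.2, seed = 9))
  expect_error(simulate_pspl(w * 0, 1, 0, 1), "positive")
})

test_that("kinetic simulation matches the rate law and fit recovery is exact", {
  d <- simulate_kinetics(3, 12, enzyme_nM = 10, concs = 3, noise_cv = 0,
                         seed = 1)
  # at [S] = K_M the velocity is half of kcat*[E]
  expect_equal(d$v0, 12 * (10 / 1000) / 2, tolerance = 1e-12)
  d8 <- simulate_kinetics(2, 10, enzyme_nM = 10,
                          concs = c(0.25, 0.5, 1, 2, 5, 10, 25, 50),
                          noise_cv = 0, seed = 1)
  f <- fit_mm(d8$conc_uM, d8$v0, enzyme_nM = 10)
  expect_equal(f$K_M, 2, tolerance = 1e-6)
  expect_equal(f$k_cat, 10, tolerance = 1e-6)
  # estimator spread grows with noise
  spread <- vapply(c(0.02, 0.10, 0.30), function(cv) {
    est <- vapply(1:60, function(i) {
      d <- simulate_kinetics(2, 10, 10, c(0.25, 0.5, 1, 2, 5, 10, 25, 50),
                             noise_cv = cv, seed = 3000 + i)
      fit_mm(d$conc_uM, d$v0, enzyme_nM = 10)$K_M
    }, numeric(1))
    stats::mad(est)
  }, numeric(1))
  expect_true(all(diff(spread) > 0))
})

test_that("the fixture bundle is self-consistent and file-round-trippable", {
  dir <- withr::local_tempdir()
  b <- generate_fixture_study(seed = 2, dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("tree.nwk", "alignment.fasta", "pspl.csv", "kinetics.csv",
           "velocities.csv", "manifest.json")))))
  aln <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(aln, b$alignment)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_equal(sort(tr$tip.label), sort(b$tree$tip.label))
  # every node sequence carries the planted DFGx character
  for (nm in names(b$truth$dfgx)) {
    s <- gsub("-", "", b$sim$truth$node_sequences[[nm]])
    expect_equal(extract_dfgx(s)$residue, unname(b$truth$dfgx[[nm]]))
  }
  # pspl arrays parse and normalize
  raw <- utils::read.csv(file.path(dir, "pspl.csv"))
  expect_equal(nrow(raw), 182L * 2L * length(b$pspl))
  expect_silent(normalize_array(raw[raw$kinase == "AncRoot" &
                                      raw$replicate == 1, ]))
})
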