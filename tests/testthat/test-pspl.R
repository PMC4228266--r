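# Library design, normalization, replicate combination, masking and the
# +1 R/P statistic.

test_that("the library enumerates 182 mixtures on the standard scaffold", {
  lib <- design_library()
  expect_equal(nrow(lib), 182L)
  expect_equal(sum(lib$fixed_position != "acceptor"), 180L)
  expect_equal(sum(lib$fixed_position == "acceptor"), 2L)
  expect_true(all(nchar(lib$template) == 16L))
  # phosphoacceptor sits at scaffold index 8 (0-based 7)
  acc_chars <- substr(lib$template, 8, 8)
  expect_true(all(acc_chars %in% c("B", "S", "T")))
  expect_equal(sort(unique(lib$fixed_residue[lib$fixed_position == "acceptor"])),
               c("S", "T"))
  # each degenerate position fixed once per residue
  tab <- table(lib$fixed_position[lib$fixed_position != "acceptor"])
  expect_true(all(tab == 20L))
})

test_that("position-group normalization has unit group means and scale invariance", {
  lib <- design_library()
  set.seed(21)
  raw <- data.frame(lib, intensity = stats::rexp(nrow(lib), 1 / 100))
  norm <- normalize_array(raw)
  gm <- tapply(norm$normalized, norm$fixed_position, mean)
  expect_equal(as.numeric(gm), rep(1, length(gm)), tolerance = 1e-12)
  raw10 <- raw
  raw10$intensity <- raw$intensity * 10
  expect_equal(normalize_array(raw10)$normalized, norm$normalized,
               tolerance = 1e-12)
  # constant array -> all ones
  rawc <- data.frame(lib, intensity = 7)
  expect_true(all(normalize_array(rawc)$normalized == 1))
  # hand-computed 3-spot toy group
  toy <- data.frame(fixed_position = "+1", fixed_residue = c("A", "R", "N"),
                    intensity = c(2, 1, 1))
  expect_equal(normalize_array(toy)$normalized, c(1.5, 0.75, 0.75))
  # all-zero group is refused with the position named
  raw0 <- raw
  raw0$intensity[raw0$fixed_position == "-3"] <- 0
  expect_error(normalize_array(raw0), "-3")
})

test_that("replicate combination averages then logs, with hand-checked values", {
  lib <- design_library()
  ones <- normalize_array(data.frame(lib, intensity = 1))
  prof <- combine_replicates(list(ones, ones))
  expect_true(all(prof$log2 == 0))
  expect_true(all(prof$acceptor == 0))
  # {0.5, 2.0} at one entry -> log2(1.25)
  r1 <- ones; r2 <- ones
  i <- which(r1$fixed_position == "+2" & r1$fixed_residue == "G")
  r1$normalized[i] <- 0.5
  r2$normalized[i] <- 2.0
  prof2 <- combine_replicates(list(r1, r2))
  expect_equal(unname(prof2$log2["+2", "G"]), log2(1.25), tolerance = 1e-12)
  # mismatched descriptors are refused
  r3 <- ones[-1, ]
  expect_error(combine_replicates(list(ones, r3)), "mismatch")
  # whole-profile centering mode has mean zero
  set.seed(4)
  rr <- normalize_array(data.frame(lib, intensity = stats::rexp(182)))
  profc <- combine_replicates(list(rr), center = "zero")
  expect_equal(mean(c(profc$log2, profc$acceptor)), 0, tolerance = 1e-9)
})

test_that("phosphoacceptor masking flags 18 entries, idempotently", {
  lib <- design_library()
  prof <- combine_replicates(list(normalize_array(
    data.frame(lib, intensity = 1))))
  masked <- exclude_phosphoacceptor_rows(prof)
  expect_equal(sum(masked$mask), 18L)
  expect_true(all(masked$mask[, c("S", "T")]))
  expect_identical(exclude_phosphoacceptor_rows(masked)$mask, masked$mask)
  # masked operands block the +1 statistic
  m2 <- masked
  m2$mask["+1", "R"] <- TRUE
  expect_error(plus1_log_ratio(m2), "masked")
})

test_that("the +1 log-ratio is antisymmetric and recovers a planted fold", {
  lib <- design_library()
  prof <- combine_replicates(list(normalize_array(
    data.frame(lib, intensity = 5))))
  expect_equal(plus1_log_ratio(prof), 0)
  # swapping the R and P entries negates the statistic
  w <- kinasr:::plus1_preference_matrix(4)
  reps <- simulate_pspl(w, 2, noise_cv = 0, seed = 1)
  p <- combine_replicates(lapply(reps, normalize_array))
  wsw <- w
  wsw["+1", c("R", "P")] <- w["+1", c("P", "R")]
  psw <- combine_replicates(lapply(simulate_pspl(wsw, 2, 0, seed = 1),
                                   normalize_array))
  expect_equal(plus1_log_ratio(psw), -plus1_log_ratio(p), tolerance = 1e-9)
  expect_equal(plus1_log_ratio(p), 2, tolerance = 1e-9)
  # with 10% noise the planted 4-fold ratio is recovered within noise
  repsN <- simulate_pspl(w, 2, noise_cv = 0.1, seed = 8)
  pN <- exclude_phosphoacceptor_rows(
    combine_replicates(lapply(repsN, normalize_array)))
  expect_lt(abs(plus1_log_ratio(pN) - 2), 0.45)
})

test_that("simulate -> normalize -> combine round-trips the preference matrix", {
  set.seed(5)
  w <- matrix(exp(stats::rnorm(180, 0, 0.8)), 9, 20,
              dimnames = list(kinasr:::pspl_positions, aa_alphabet))
  reps <- simulate_pspl(w, n_replicates = 2, noise_cv = 0.1, seed = 7)
  prof <- combine_replicates(lapply(reps, normalize_array))
  truth <- log2(w / rowMeans(w))
  expect_gt(stats::cor(as.vector(prof$log2), as.vector(truth)), 0.95)
  # per-replicate exposure scaling does not change the profile
  reps2 <- reps
  reps2[[1]]$intensity <- reps2[[1]]$intensity * 3.7
  prof2 <- combine_replicates(lapply(reps2, normalize_array))
  expect_equal(prof2$log2, prof$log2, tolerance = 1e-12)
})
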