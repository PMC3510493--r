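test_that("trivial ensembles collapse to the open chain", {
  pf <- partition_function("AAAAAAA", model_default)
  expect_equal(pf$Z, 1)
  expect_true(all(pf$pair_prob == 0))
  expect_equal(partition_function("G", model_default)$Z, 1)
  expect_error(partition_function("", model_default), "non-ACGU|length")
})

test_that("partition function, pair probabilities and Pu match enumeration", {
  set.seed(101)
  for (k in 1:30) {
    n <- sample(8:16, 1)
    s <- random_rna(n)
    span <- sample(c(Inf, 8, 12), 1)
    cons <- if (k %% 3 == 0) sample.int(n, 2) else integer(0)
    br <- brute_ensemble(s, model_default, span, cons)
    pf <- partition_function(s, model_default, span, cons)
    expect_equal(pf$Z, br$Z, tolerance = 1e-9)
    expect_lt(max(abs(pf$pair_prob - br$pair_prob)), 1e-9)
    iv <- sort(sample.int(n, 2))
    expect_equal(unpaired_probability(s, iv, model_default, span, cons),
                 br$pu(iv), tolerance = 1e-9)
  }
  # worked examples
  for (s in c("GGGGAAAACCCC", "GCGCAAAAGCGC")) {
    br <- brute_ensemble(s, model_default)
    pf <- partition_function(s, model_default)
    expect_equal(pf$Z, br$Z, tolerance = 1e-9)
    expect_lt(max(abs(pf$pair_prob - br$pair_prob)), 1e-9)
  }
  expect_equal(unpaired_probability("GCGCAAAAGCGC", c(5, 8), model_default),
               brute_ensemble("GCGCAAAAGCGC", model_default)$pu(c(5, 8)),
               tolerance = 1e-9)
})

test_that("forced-unpaired constraints never increase Z and force Pu to 1", {
  set.seed(17)
  for (k in 1:10) {
    s <- random_rna(14)
    z0 <- partition_function(s, model_default, pair_prob = FALSE)$Z
    cons <- sample.int(14, 3)
    z1 <- partition_function(s, model_default, constraint = cons,
                             pair_prob = FALSE)$Z
    z2 <- partition_function(s, model_default,
                             constraint = c(cons, sample.int(14, 2)),
                             pair_prob = FALSE)$Z
    expect_lte(z1, z0 + 1e-12)
    expect_lte(z2, z1 + 1e-12)
  }
  expect_equal(unpaired_probability("GCGCAAAAGCGC", c(2, 3), model_default,
                                    constraint = 1:4), 1)
  expect_equal(unpaired_probability("GCGC", c(2, 1), model_default), 1)
  expect_error(unpaired_probability("GCGC", c(1, 9), model_default),
               "bounds")
})

test_that("Pu of an interval never exceeds Pu of its sub-intervals", {
  set.seed(23)
  for (k in 1:8) {
    s <- random_rna(16)
    iv <- sort(sample.int(16, 2))
    sub <- c(iv[1], max(iv[1], iv[2] - 2))
    expect_lte(unpaired_probability(s, iv, model_default),
               unpaired_probability(s, sub, model_default) + 1e-12)
  }
})

test_that("with all energies zero every legal structure is equiprobable", {
  set.seed(31)
  for (k in 1:6) {
    s <- random_rna(sample(10:14, 1))
    structs <- enumerate_structures(s, model_zero)
    pf <- partition_function(s, model_zero, pair_prob = FALSE)
    expect_equal(pf$Z, length(structs), tolerance = 1e-9)
    iv <- sort(sample.int(nchar(s), 2))
    paired_free <- vapply(structs, function(m) {
      nrow(m) == 0 || !any(c(m) %in% iv[1]:iv[2])
    }, logical(1))
    expect_equal(unpaired_probability(s, iv, model_zero),
                 mean(paired_free), tolerance = 1e-9)
  }
})

test_that("opening energies follow -RT log Pu", {
  expect_equal(opening_energy(1, model_default), 0)
  expect_equal(opening_energy(0.5, model_default),
               model_default$RT * log(2))
  expect_equal(opening_energy(0.5, model_default), 0.4272, tolerance = 1e-4)
  expect_identical(opening_energy(0, model_default), Inf)
  expect_error(opening_energy(1.2, model_default), "\\[0, 1\\]")
})

test_that("accessibility profiles follow the local-folding window scheme", {
  # unstructured sequence: Pu = 1 everywhere
  p <- local_accessibility_profile(strrep("A", 160), model_default,
                                   window = 100, max_span = 50,
                                   probe_len = 5)
  expect_true(all(p$Pu == 1))

  # shorter than the window: identical to a global computation with the
  # span cap
  s <- random_rna(60)
  p2 <- local_accessibility_profile(s, model_default, window = 100,
                                    max_span = 50, probe_len = 4)
  direct <- vapply(seq_len(57), function(i)
    unpaired_probability(s, c(i, i + 3), model_default, max_span = 50),
    numeric(1))
  expect_equal(p2$Pu, direct, tolerance = 1e-12)

  # longer than the window, averaged mode: matches direct per-window
  # recomputation
  set.seed(71)
  carrier <- paste0(random_rna(40), "GGGGGAAAACCCCC", random_rna(66))
  w <- 60L
  p3 <- local_accessibility_profile(carrier, model_default, window = w,
                                    max_span = 50, probe_len = 6,
                                    mode = "average")
  n <- nchar(carrier)
  for (i in c(1, 38, 44, 80, n - 5)) {
    starts <- seq.int(max(1, i + 5 - w + 1), min(i, n - w + 1))
    ref <- mean(vapply(starts, function(ws) {
      unpaired_probability(substr(carrier, ws, ws + w - 1),
                           c(i - ws + 1, i - ws + 6), model_default,
                           max_span = 50)
    }, numeric(1)))
    expect_equal(p3$Pu[i], ref, tolerance = 1e-12)
  }
  expect_error(local_accessibility_profile("ACGU", model_default,
                                           probe_len = 10), "probe_len")
})
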