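test_that("explicit duplex evaluation sums initiation, stacks and loops", {
  m <- model_default
  s1 <- "GGGGGGGG"; s2 <- "CCCCCCCC"
  p <- cbind(pos1 = 1:8, pos2 = 8:1)
  expect_equal(duplex_energy(s1, s2, p, m),
               m$duplex_init + 7 * m$stack["GC", "GC"])

  # one 1-nt bulge on side 1
  s1b <- "GGGGAGGGG"
  pb <- cbind(pos1 = c(1:4, 6:9), pos2 = 8:1)
  expect_equal(duplex_energy(s1b, s2, pb, m),
               m$duplex_init + 6 * m$stack["GC", "GC"] + m$bulge_init)

  expect_error(duplex_energy("AG", "GG", cbind(1, 2), m), "non-canonical")
  expect_error(duplex_energy("GG", "CC", cbind(c(1, 2), c(1, 2)), m),
               "crossing|parallel")
})

test_that("hybridize honours the seed boundary and finds full complements", {
  s <- hybridize("CCCCUUUU", "AAAAGGGG", model_default, seed_len = 8)
  expect_identical(nrow(s$pairing), 8L)
  expect_lt(s$E_hybrid, 0)
  expect_null(hybridize(strrep("A", 10), strrep("A", 10), model_default))
  # exactly 7 complementary pairs, no extension possible
  expect_null(hybridize("CCCCUUU", "AAAGGGG", model_default, seed_len = 8))
  expect_s3_class(hybridize("CCCCUUU", "AAAGGGG", model_default,
                            seed_len = 7), "interaction_site")
})

test_that("hybridize equals exhaustive duplex enumeration on random pairs", {
  set.seed(202)
  n_sites <- 0
  for (k in 1:60) {
    a <- random_rna(sample(8:15, 1))
    b <- random_rna(sample(8:15, 1))
    sl <- sample(c(4L, 6L, 8L), 1)
    h <- hybridize(a, b, model_default, seed_len = sl)
    o <- enumerate_duplex_optimum(a, b, model_default, seed_len = sl)
    expect_identical(is.null(h), is.null(o))
    if (is.null(h)) next
    n_sites <- n_sites + 1
    expect_equal(h$E_hybrid, o$E, tolerance = 1e-9)
    hp <- norm_pairing(h$pairing)
    expect_true(any(vapply(o$sites, function(ss)
      identical(norm_pairing(ss), hp), logical(1))))
  }
  expect_gt(n_sites, 10)
})

test_that("hybridization is symmetric in its two strands", {
  set.seed(77)
  for (k in 1:10) {
    a <- paste0(random_rna(3), rc(b0 <- random_rna(9)), random_rna(3))
    h1 <- hybridize(a, b0, model_default, seed_len = 6)
    h2 <- hybridize(b0, a, model_default, seed_len = 6)
    expect_equal(h1$E_hybrid, h2$E_hybrid)
    expect_identical(h1$srna_interval, h2$mrna_interval)
  }
})

test_that("weakening the seed never worsens the optimal energy", {
  set.seed(88)
  for (k in 1:20) {
    a <- paste0(random_rna(2), rc(core <- random_rna(10)), random_rna(2))
    h8 <- hybridize(a, core, model_default, seed_len = 8)
    h4 <- hybridize(a, core, model_default, seed_len = 4)
    if (is.null(h8)) next
    expect_false(is.null(h4))
    expect_lte(h4$E_hybrid, h8$E_hybrid + 1e-12)
  }
})

test_that("every reported site structurally contains the seed run", {
  set.seed(99)
  n_checked <- 0
  for (k in 1:20) {
    core <- random_rna(9)
    a <- paste0(random_rna(4), core, random_rna(4))
    b <- paste0(random_rna(4), rc(core), random_rna(4))
    h <- hybridize(a, b, model_default, seed_len = 8)
    if (is.null(h)) next
    n_checked <- n_checked + 1
    expect_gte(longest_stacked_run(h, a, b), 8L)
  }
  expect_gt(n_checked, 10)
})

test_that("accessibility attachment preserves the energy decomposition", {
  s <- hybridize("CCCCUUUU", "AAAAGGGG", model_default, seed_len = 8)
  s1 <- attach_accessibility(s, pu_srna = 1, pu_mrna = 1,
                             model = model_default)
  expect_equal(s1$E_total, s1$E_hybrid)
  s2 <- attach_accessibility(s, pu_srna = 1, pu_mrna = 0.5,
                             model = model_default)
  expect_equal(s2$E_total, s2$E_hybrid + model_default$RT * log(2))
  expect_equal(s2$E_total - s2$E_hybrid - s2$ED_srna - s2$ED_mrna, 0)
  s3 <- attach_accessibility(s, pu_srna = 0, pu_mrna = 1,
                             model = model_default)
  expect_true(s3$unusable)
})

test_that("transcript scans report planted sites ranked by total energy", {
  srna <- make_srna(rng_seed = 3)
  lnk <- substr(srna$seq, srna$linker[1], srna$linker[2])
  sub1 <- substr(lnk, 20, 31) # 12 nt
  sub2 <- substr(lnk, 16, 31) # 16 nt, stronger
  set.seed(12)
  utr <- 40L
  bg <- random_rna(utr + 130)
  seqc <- bg
  substr(seqc, 5, 16) <- rc(sub1)
  substr(seqc, 80, 95) <- rc(sub2)
  substr(seqc, 41, 43) <- "AUG"
  tr <- transcript_model("two_sites", seqc, utr_length = utr)
  sites <- scan_transcript(srna$seq, tr, model_default, screen_config())
  expect_gte(length(sites), 2L)
  ets <- vapply(sites, function(s) s$E_total, numeric(1))
  expect_true(all(diff(ets) >= -1e-12))
  expect_true(all(ets < 0))
  covers <- function(iv) any(vapply(sites, function(s)
    s$mrna_interval[1] <= iv[1] && s$mrna_interval[2] >= iv[2] - 2,
    logical(1)))
  expect_true(covers(c(5, 16)))
  expect_true(covers(c(80, 95)))
  # the stronger (longer) site ranks first
  expect_true(sites[[1]]$mrna_interval[1] >= 70)

  # destroying the sites removes all reported interactions
  set.seed(13)
  shuf <- paste(sample(strsplit(seqc, "")[[1]]), collapse = "")
  substr(shuf, 41, 43) <- "AUG"
  tr2 <- transcript_model("shuffled", shuf, utr_length = utr)
  sites2 <- scan_transcript(srna$seq, tr2, model_default, screen_config())
  expect_true(all(vapply(sites2, function(s) s$E_total < 0, logical(1))))
})
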