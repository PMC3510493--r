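test_that("the synthetic sRNA realizes its declared architecture", {
  srna <- make_srna(rng_seed = 1)
  expect_identical(nchar(srna$seq), 191L)
  expect_identical(srna$linker[2] - srna$linker[1] + 1L, 39L)
  # determinism
  expect_identical(make_srna(rng_seed = 1)$seq, srna$seq)
  expect_false(identical(make_srna(rng_seed = 2)$seq, srna$seq))
  # the linker cannot pair internally (purine alphabet)
  lnk <- strsplit(substr(srna$seq, srna$linker[1], srna$linker[2]), "")[[1]]
  expect_true(all(lnk %in% c("A", "G")))
  # segment bookkeeping covers the full length contiguously
  f <- srna$features
  expect_identical(f$start[1], 1L)
  expect_identical(f$end[nrow(f)], 191L)
  expect_true(all(f$start[-1] == f$end[-nrow(f)] + 1L))
  # architecture that does not sum is rejected
  expect_error(srna_architecture(total_length = 100), "sum")
})

test_that("the sRNA folds as designed: open linker, closed stems", {
  srna <- make_srna(rng_seed = 1)
  prof <- local_accessibility_profile(srna$seq, model_default, window = 100,
                                      max_span = 50, probe_len = 1,
                                      mode = "center")
  lk <- srna$linker
  expect_gte(mean(prof$Pu[lk[1]:lk[2]]), 0.9)
  arms <- srna$features[grepl("arm", srna$features$segment), ]
  stem_pu <- unlist(lapply(seq_len(nrow(arms)), function(i)
    prof$Pu[arms$start[i]:arms$end[i]]))
  expect_lte(mean(stem_pu), 0.3)
})

test_that("planted sites are exactly reverse-complementary to their linker subsequence", {
  srna <- make_srna(rng_seed = 5)
  for (pl in list(c(-20L, -7L), c(-12L, 6L), c(50L, 65L))) {
    pt <- plant_trans_target(srna, pl, utr_length = 36L, rng_seed = 9,
                             kind = if (pl[1] > 0) "decoy" else "repression")
    tr <- pt$transcript
    tru <- pt$truth
    offset <- tr$start_codon_offset
    loc <- function(r) ifelse(r > 0, offset + r - 1L, offset + r)
    comp <- substr(tr$seq, loc(tru$comp_rel_start), loc(tru$comp_rel_end))
    lnk_sub <- substr(srna$seq, tru$srna_start, tru$srna_end)
    expect_identical(comp, rc(lnk_sub))
    # the start codon survives planting
    expect_identical(substr(tr$seq, offset, offset + 2), "AUG")
  }
  expect_error(plant_trans_target(srna, c(-50L, -40L), utr_length = 36L,
                                  rng_seed = 1), "outside")
})

test_that("scrambled planting removes designed complementarity", {
  srna <- make_srna(rng_seed = 5)
  pt <- plant_trans_target(srna, c(-20L, -7L), utr_length = 36L,
                           rng_seed = 9, kind = "repression",
                           scramble = TRUE)
  runs <- srnascreen:::.pair_runs_cpp(
    srnascreen:::encode_rna(srna$seq),
    srnascreen:::encode_rna(pt$transcript$seq), 7L)
  expect_identical(nrow(runs), 0L)
})

test_that("simulated expression plants exact effects and lognormal noise", {
  spec0 <- benchmark_spec(n_genes = 9, n_repression_targets = 2,
                          n_activation_targets = 2,
                          n_decoys_with_offwindow_sites = 2,
                          effect_fold = 5, noise_sigma = 0)
  truth <- data.frame(gene_id = sprintf("g%d", 1:9),
                      role = c("repression", "repression", "activation",
                               "activation", "decoy", "decoy",
                               "background", "background", "background"))
  ex <- simulate_expression(truth, spec0)
  expect_equal(ex$fold_change,
               c(0.2, 0.2, 5, 5, 1, 1, 1, 1, 1))
  # determinism at fixed seed
  expect_identical(simulate_expression(truth, spec0), ex)

  # lognormal tail: fraction of null genes beyond the 3-fold cutoff
  specn <- benchmark_spec(n_genes = 1000, n_repression_targets = 0,
                          n_activation_targets = 0,
                          n_decoys_with_offwindow_sites = 0,
                          noise_sigma = 0.5, rng_seed = 3)
  trn <- data.frame(gene_id = sprintf("d%d", 1:1000),
                    role = rep("background", 1000))
  exn <- simulate_expression(trn, specn)
  frac <- mean(pmax(exn$fold_change, 1 / exn$fold_change) >= 3)
  expected <- 2 * (1 - pnorm(log(3) / 0.5))
  expect_lt(abs(frac - expected), 3 * sqrt(expected / 1000))
})

test_that("benchmarks are reproducible, well-formed, and file-round-trippable", {
  spec <- benchmark_spec(n_genes = 8, n_repression_targets = 2,
                         n_activation_targets = 1,
                         n_decoys_with_offwindow_sites = 2,
                         noise_sigma = 0, rng_seed = 6)
  bm <- make_benchmark(spec)
  bm2 <- make_benchmark(spec)
  expect_identical(bm$genome, bm2$genome)
  expect_identical(bm$expression, bm2$expression)
  # transcripts rebuilt from the genome carry the planted AUG
  for (g in names(bm$transcripts)) {
    tr <- bm$transcripts[[g]]
    expect_identical(substr(tr$seq, tr$start_codon_offset,
                            tr$start_codon_offset + 2), "AUG")
  }
  # both strands are represented
  expect_setequal(unique(bm$annotations$strand), c("+", "-"))
  # write and re-read through seqio without warnings
  d <- withr::local_tempdir()
  bm3 <- make_benchmark(spec, dir = d)
  expect_silent(g <- read_fasta(file.path(d, "genome.fasta")))
  expect_silent(a <- read_annotations(file.path(d, "annotations.tsv")))
  expect_silent(e <- read_expression(file.path(d, "expression.tsv")))
  expect_identical(nrow(a), 8L)
  expect_identical(unname(g), unname(bm3$genome))
  tr1 <- build_transcript(a[1, ], g)
  expect_identical(tr1$seq, bm3$transcripts[[a$gene_id[1]]]$seq)
})

test_that("the cis-antisense pair reproduces the head-to-head geometry", {
  cp <- make_cis_pair(overlap_len = 65)
  ov <- antisense_overlap(cp$annotations[1, ], cp$annotations[2, ])
  expect_identical(ov$overlap, 65L)
  expect_identical(ov$class, "5p5p")
  # the overlap is exactly reverse-complementary between the transcripts
  t1 <- build_transcript(cp$annotations[1, ], cp$contig)
  t2 <- build_transcript(cp$annotations[2, ], cp$contig)
  expect_identical(substr(t1$seq, 1, 65), rc(substr(t2$seq, 1, 65)))
  # the antisense gene has the long 5'UTR of the arrangement
  expect_identical(t2$utr_length, 184L)
  expect_identical(t2$start_codon_offset, 185L)
  ov0 <- local({
    cp0 <- make_cis_pair(overlap_len = 0)
    antisense_overlap(cp0$annotations[1, ], cp0$annotations[2, ])
  })
  expect_identical(ov0$overlap, 0L)
  expect_identical(ov0$class, "none")
})
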