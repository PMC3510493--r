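ann_row <- function(gene_id, operon_id = NA, operon_rank = NA) {
  data.frame(gene_id = gene_id, contig = "c", start = 1, end = 300,
             strand = "+", start_codon = 101, tss = 1,
             operon_id = operon_id, operon_rank = operon_rank,
             stringsAsFactors = FALSE)
}

test_that("candidate selection is boundary-inclusive and symmetric", {
  ex <- expression_records(c("a", "b", "c", "d"), c(3.0, 0.30, 2.9, 0.34))
  ann <- validate_annotations(rbind(ann_row("a"), ann_row("b"),
                                    ann_row("c"), ann_row("d")))
  sel <- select_candidates(ex, ann)
  expect_setequal(sel$gene_id, c("a", "b")) # 3.0 in, 0.30 (3.33x) in
  expect_identical(sel$direction[sel$gene_id == "b"], "down")
})

test_that("the first ORF of an operon joins its selected members", {
  ex <- expression_records(c("g1", "g2", "g3"), c(1.1, 4.0, 1.0))
  ann <- validate_annotations(rbind(ann_row("g1", "op", 1),
                                    ann_row("g2", "op", 2),
                                    ann_row("g3")))
  sel <- select_candidates(ex, ann)
  expect_setequal(sel$gene_id, c("g1", "g2"))
  expect_identical(sel$selection[sel$gene_id == "g1"], "operon_first_orf")
  # first ORF inherits the trigger's direction; its own fold is reported
  expect_identical(sel$direction[sel$gene_id == "g1"], "up")
  expect_equal(sel$fold_change[sel$gene_id == "g1"], 1.1)
  # selected genes without annotation are reported, not fatal
  ex2 <- expression_records(c("g2", "nope"), c(4, 5))
  sel2 <- select_candidates(ex2, ann)
  expect_identical(attr(sel2, "skipped"), "nope")
})

test_that("search regions follow the UTR-known / fallback rules", {
  set.seed(3)
  tr <- transcript_model("g", random_rna(36 + 130), utr_length = 36)
  r <- expect_silent(build_search_region(tr))
  expect_identical(nchar(r$seq), 136L)
  expect_identical(r$start_codon_offset, 37L)

  tru <- transcript_model("g", random_rna(230), utr_length = NA,
                          start_codon_offset = 201)
  expect_warning(r2 <- build_search_region(tru), "truncated")
  # fallback region: 200 upstream + as much CDS as exists (here 30)
  expect_identical(nchar(r2$seq), 230L)
  tru2 <- transcript_model("g", random_rna(310), utr_length = NA,
                           start_codon_offset = 201)
  expect_identical(nchar(build_search_region(tru2)$seq), 300L)

  # leaderless gene: region is CDS only, all positions >= +1
  tr0 <- transcript_model("g", random_rna(120), utr_length = 0)
  r3 <- build_search_region(tr0)
  expect_identical(nchar(r3$seq), 100L)
  expect_identical(r3$start_codon_offset, 1L)
})

test_that("the ribosome-window filter is exact at its boundaries", {
  cfg <- screen_config()
  expect_true(repression_filter(fake_site(c(-39, -39)), cfg))
  expect_true(repression_filter(fake_site(c(19, 19)), cfg))
  expect_false(repression_filter(fake_site(c(-40, -40)), cfg))
  expect_false(repression_filter(fake_site(c(20, 20)), cfg))
  expect_true(repression_filter(fake_site(c(-10, 5)), cfg))
  expect_false(repression_filter(fake_site(c(20, 35)), cfg))
  expect_true(repression_filter(fake_site(c(-45, -39)), cfg))
  # containment mode
  cfgc <- screen_config(contained = TRUE)
  expect_false(repression_filter(fake_site(c(-45, -39)), cfgc))
  expect_true(repression_filter(fake_site(c(-39, 19)), cfgc))
})

test_that("RBS accessibility change captures the sequestration mechanism", {
  # anti-RBS tract (1..6) sequesters the RBS (11..16); opening the tract
  # frees it; enumeration-checkable scale
  toy <- "CCUCCUAAAAAGGAGGAAUGG"
  tr <- transcript_model("toy", toy, utr_length = 17)
  site <- fake_site(c(-17, -12), mrna = c(1, 6))
  rbs <- list(interval = c(-7L, -2L), interval_local = c(11L, 16L),
              energy = -10, significant = TRUE)
  cfg <- screen_config()
  d <- rbs_accessibility_change(tr, site, rbs, model_default, cfg)
  expect_gt(d, 0.001)
  # exact against the enumeration oracle
  br0 <- brute_ensemble(toy, model_default, max_span = 50)
  br1 <- brute_ensemble(toy, model_default, max_span = 50, constraint = 1:6)
  expect_equal(d, br1$pu(c(11, 16)) - br0$pu(c(11, 16)), tolerance = 1e-9)

  # no structural coupling: an A-spacer site (U-free context) cannot change
  # the RBS
  toy2 <- "AAAAAACCCCAGGAGGCCC"
  tr2 <- transcript_model("toy2", toy2, utr_length = 18)
  site2 <- fake_site(c(-18, -13), mrna = c(1, 6))
  rbs2 <- list(interval = c(-8L, -3L), interval_local = c(11L, 16L),
               energy = -10, significant = TRUE)
  expect_lt(abs(rbs_accessibility_change(tr2, site2, rbs2, model_default,
                                         cfg)), 1e-6)

  # overlapping sites belong to the repression branch
  site3 <- fake_site(c(-9, -4), mrna = c(9, 14))
  expect_error(rbs_accessibility_change(tr, site3, rbs, model_default, cfg),
               "upstream")
})

test_that("classification follows the direction-conditional branches", {
  cfg <- screen_config()
  tr <- transcript_model("g", paste0(strrep("C", 40), "AUG", strrep("A", 40)),
                         utr_length = 40)
  s_in <- fake_site(c(-12, 3), mrna = c(29, 43))
  s_out <- fake_site(c(25, 38), mrna = c(65, 78))
  down_hit <- classify_candidate(tr, list(s_in), NULL, "down", config = cfg)
  expect_identical(down_hit$verdict, "repression_candidate")
  down_miss <- classify_candidate(tr, list(s_out), NULL, "down", config = cfg)
  expect_identical(down_miss$verdict, "none")
  expect_identical(down_miss$rationale, "no_site_in_ribosome_window")
  no_rbs <- classify_candidate(tr, list(s_out), NULL, "up", config = cfg)
  expect_identical(no_rbs$rationale, "no_rbs")
  expect_identical(classify_candidate(tr, list(), NULL, "down",
                                      config = cfg)$rationale, "no_site")
})

test_that("antisense overlap classification covers the arrangement classes", {
  mk <- function(start, end, strand)
    data.frame(gene_id = "x", contig = "c", start = start, end = end,
               strand = strand, stringsAsFactors = FALSE)
  # head-to-head 5' overlap (sRNA on +, antisense TSS inside it)
  r <- antisense_overlap(mk(101, 291, "+"), mk(40, 165, "-"))
  expect_identical(r$overlap, 65L)
  expect_identical(r$class, "5p5p")
  expect_identical(antisense_overlap(mk(1, 50, "+"), mk(60, 90, "-"))$class,
                   "none")
  ident <- antisense_overlap(mk(10, 60, "+"), mk(10, 60, "-"))
  expect_identical(ident$overlap, 51L)
  expect_identical(ident$class, "internal")
  expect_identical(antisense_overlap(mk(1, 50, "+"),
                                     mk(30, 90, "+"))$class,
                   "not_antisense")
  conv <- antisense_overlap(mk(1, 60, "+"), mk(50, 120, "-"))
  expect_identical(conv$class, "3p3p")
})

test_that("ddCt fold changes match hand arithmetic and are shift-invariant", {
  ct <- data.frame(gene_id = rep(c("t", "r1", "r2", "r3"), each = 2),
                   condition = rep(c("wt", "mut"), 4),
                   ct = c(20, 18, 15, 15, 15, 15, 15, 15))
  fc <- fold_change_from_ct(ct, c("r1", "r2", "r3"))
  expect_equal(fc$fold_change, 4.0)
  expect_equal(fc$ddct, -2)
  # ddCt = 0 -> fold 1
  ct0 <- ct; ct0$ct[ct0$gene_id == "t"] <- 15
  expect_equal(fold_change_from_ct(ct0, c("r1", "r2", "r3"))$fold_change, 1)
  # adding a constant to every Ct changes nothing
  ct2 <- ct; ct2$ct <- ct2$ct + 7.3
  expect_equal(fold_change_from_ct(ct2, c("r1", "r2", "r3"))$fold_change,
               fc$fold_change)
  expect_error(fold_change_from_ct(ct[ct$condition == "wt", ],
                                   c("r1", "r2", "r3")), "condition")
})

test_that("run_screen produces a ranked, evidence-backed report", {
  spec <- benchmark_spec(n_genes = 14, n_repression_targets = 2,
                         n_activation_targets = 1,
                         n_decoys_with_offwindow_sites = 3,
                         noise_sigma = 0, rng_seed = 2)
  bm <- make_benchmark(spec)
  scr <- run_screen(bm$srna_screen_seq, bm$transcripts, bm$expression,
                    bm$annotations)
  sc <- score_screen(scr, bm$truth)
  expect_equal(sc$repression_precision, 1)
  expect_equal(sc$repression_recall, 1)
  expect_equal(sc$activation_recall, 1)
  expect_equal(sc$decoy_false_positives, 0)
  # verdict soundness: re-check every call against its recorded evidence
  for (call in scr$details) {
    if (call$verdict == "repression_candidate") {
      expect_true(repression_filter(call$best_site, scr$config))
      dirn <- scr$calls$direction[scr$calls$gene_id == call$gene_id]
      expect_identical(dirn, "down")
    }
    if (call$verdict == "activation_candidate") {
      expect_gt(call$dPu, scr$config$dpu_threshold)
      expect_lt(call$best_site$mrna_interval[2],
                call$rbs$interval_local[1])
    }
  }
  # energy decomposition holds exactly on all reported sites
  hits <- scr$calls[!is.na(scr$calls$E_total), ]
  expect_equal(hits$E_total, hits$E_hybrid + hits$ED_srna + hits$ED_mrna)
  # empty expression table gives an empty report
  scr0 <- run_screen(bm$srna_screen_seq, bm$transcripts,
                     bm$expression[0, ], bm$annotations)
  expect_identical(nrow(scr0$calls), 0L)
})
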