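# Seeded synthetic-data generation: an sRNA with stem-loop/linker
# architecture, transcripts with planted complementary sites at controlled
# start-codon-relative positions, a cis-antisense gene pair, and expression
# tables with planted fold changes.
#
# Composition design (see the methods vignette for the full rationale):
# the single-stranded linker is purine-only ({A,G}, runs capped) so it cannot
# base-pair internally; stem arms are G/C with capped G-runs; stem loops are
# all-A; leader/spacer/tail segments are C/U. Planted mRNA sites (reverse
# complements of linker subsequences) are therefore C/U strings, and the
# negative-control sRNA (linker replaced by a C homopolymer, mirroring
# linker-replacement mutants) cannot form a single base pair with any planted
# site. Backgrounds are uniform A/C/G/U but are sanitized against chance
# complementarity to the sRNA, so the planted ground truth is exact.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

# random string over `alphabet` with no run longer than max_run
run_capped_string <- function(n, alphabet, max_run = 4L) {
  out <- character(n)
  run <- 0L
  last <- ""
  for (i in seq_len(n)) {
    choices <- if (run >= max_run) setdiff(alphabet, last) else alphabet
    out[i] <- sample(choices, 1L)
    run <- if (out[i] == last) run + 1L else 1L
    last <- out[i]
  }
  paste(out, collapse = "")
}

#' sRNA architecture specification
#'
#' Describes the stem-loop/linker architecture emulated by [make_srna()]:
#' three stem-loops (SL1-SL3) with a single-stranded linker region (SLR)
#' between SL2 and SL3, short unstructured leader/spacer/tail segments, and
#' annotated 5'-fragment cut sites. Defaults give a 191-nt transcript with a
#' 39-nt linker; every stem-loop spans at most the 50-nt local base-pair
#' limit, so the designed helices can form under local folding.
#'
#' @param total_length transcript length in nt.
#' @param stems list of three `c(stem, loop)` length pairs for SL1-SL3.
#' @param linker_length linker (SLR) length in nt.
#' @param leader,spacer,tail unstructured segment lengths (5' leader, the
#'   SL1-SL2 spacer, and the 3' tail).
#' @param fragment_cut_sites annotated 5'-fragment ends (positions).
#' @param sd_motif purine motif planted inside the linker, whose reverse
#'   complement is the anti-RBS tract used by activation targets.
#' @param sd_offset 1-based offset of the motif within the linker.
#' @return an object of class `srna_architecture`.
#' @export
srna_architecture <- function(total_length = 191L,
                              stems = list(c(17L, 8L), c(18L, 8L),
                                           c(20L, 9L)),
                              linker_length = 39L,
                              leader = 2L, spacer = 3L, tail = 12L,
                              fragment_cut_sites = c(65L, 60L, 55L),
                              sd_motif = "AGGAGG",
                              sd_offset = 8L) {
  stopifnot(length(stems) == 3)
  sl <- vapply(stems, function(s) 2L * s[1] + s[2], integer(1))
  total <- leader + sl[1] + spacer + sl[2] + linker_length + sl[3] + tail
  if (total != total_length)
    stop("segment lengths sum to ", total, ", not total_length = ",
         total_length)
  span_cap <- vapply(stems, function(s) 2L * s[1] + s[2], integer(1))
  if (sd_offset + nchar(sd_motif) - 1L > linker_length)
    stop("sd_motif does not fit in the linker")
  out <- list(total_length = as.integer(total_length), stems = stems,
              linker_length = as.integer(linker_length),
              leader = as.integer(leader), spacer = as.integer(spacer),
              tail = as.integer(tail),
              fragment_cut_sites = as.integer(fragment_cut_sites),
              sd_motif = sd_motif, sd_offset = as.integer(sd_offset),
              stem_spans = span_cap)
  class(out) <- "srna_architecture"
  out
}

#' Generate a synthetic sRNA with known structure
#'
#' Builds a sequence realizing the [srna_architecture()]: stems are
#' complementary G/C arms enclosing all-A loops, the linker is purine-only
#' (hence free of intramolecular pairs), and connecting segments are C/U.
#' The returned feature map records every segment interval, the linker, the
#' planted purine motif, and the annotated fragment cut sites.
#'
#' @param arch an [srna_architecture()].
#' @param rng_seed integer seed; the output is a pure function of
#'   (arch, rng_seed).
#' @return an object of class `synthetic_srna`: list with `seq`, `features`
#'   (data.frame segment/start/end), `linker` (interval), `sd_interval`,
#'   `arch`.
#' @export
make_srna <- function(arch = srna_architecture(), rng_seed = 1L) {
  with_seed(rng_seed, {
    seg <- function(n, alphabet, cap = 4L) run_capped_string(n, alphabet, cap)
    # run cap 2 keeps any helix between a window-cut arm fragment and the
    # purine linker at <= 2 bp (negligible), and bounds chance pairing runs
    # against planted C/U sites at 2
    stem_arm <- function(n) seg(n, c("G", "C"), cap = 2L)
    pieces <- list()
    add <- function(name, s) pieces[[name]] <<- s
    add("leader", seg(arch$leader, c("C", "U")))
    for (k in 1:3) {
      st <- arch$stems[[k]]
      arm <- stem_arm(st[1])
      add(paste0("SL", k, "_5arm"), arm)
      add(paste0("SL", k, "_loop"), strrep("A", st[2]))
      add(paste0("SL", k, "_3arm"), revcomp_rna(arm))
      if (k == 1) add("spacer", seg(arch$spacer, c("C", "U")))
      if (k == 2) {
        linker <- seg(arch$linker_length, c("A", "G"))
        substr(linker, arch$sd_offset,
               arch$sd_offset + nchar(arch$sd_motif) - 1L) <- arch$sd_motif
        add("linker", linker)
      }
    }
    add("tail", seg(arch$tail, c("C", "U")))
    ord <- c("leader", "SL1_5arm", "SL1_loop", "SL1_3arm", "spacer",
             "SL2_5arm", "SL2_loop", "SL2_3arm", "linker",
             "SL3_5arm", "SL3_loop", "SL3_3arm", "tail")
    lens <- vapply(pieces[ord], nchar, integer(1))
    ends <- cumsum(lens)
    starts <- ends - lens + 1L
    seqc <- paste(unlist(pieces[ord]), collapse = "")
    features <- data.frame(segment = ord, start = starts, end = ends,
                           stringsAsFactors = FALSE, row.names = NULL)
    linker_iv <- unname(c(starts[ord == "linker"], ends[ord == "linker"]))
    # invariant: the linker can form no internal canonical pair
    lv <- strsplit(pieces$linker, "", fixed = TRUE)[[1]]
    for (i in seq_along(lv)) for (j in seq_along(lv))
      if (j > i && !is.na(pair_type(lv[i], lv[j])))
        stop("internal error: self-complementary linker")
    out <- list(seq = seqc, features = features, linker = linker_iv,
                sd_interval = linker_iv[1] + arch$sd_offset - 1L +
                  c(0L, nchar(arch$sd_motif) - 1L),
                fragment_cut_sites = arch$fragment_cut_sites,
                arch = arch)
    class(out) <- "synthetic_srna"
    out
  })
}

#' @export
print.synthetic_srna <- function(x, ...) {
  cat("<synthetic_srna>", nchar(x$seq), "nt; linker", x$linker[1], "-",
      x$linker[2], "\n")
  invisible(x)
}

#' Negative-control variant of a synthetic sRNA
#'
#' `"linker_null"` replaces the single-stranded linker by a C homopolymer
#' (the in-silico analogue of linker-replacement mutants), abolishing all
#' complementarity to planted target sites while leaving the stem-loops
#' untouched.
#'
#' @param srna a `synthetic_srna`.
#' @param mode currently `"linker_null"`.
#' @return the modified `synthetic_srna`.
#' @export
srna_variant <- function(srna, mode = c("linker_null")) {
  mode <- match.arg(mode)
  s <- srna$seq
  substr(s, srna$linker[1], srna$linker[2]) <-
    strrep("C", srna$linker[2] - srna$linker[1] + 1L)
  srna$seq <- s
  srna$mode <- mode
  srna
}

# Break chance complementarity: mutate unprotected positions of `seqc` until
# no antiparallel run of >= min_run consecutive canonical pairs (incl. GU)
# remains against any sequence in `against` (min_run recycled per sequence).
# Planted features are protected.
sanitize_against <- function(seqc, against, protected = integer(0),
                             min_run = 7L, max_iter = 100L) {
  prot <- logical(nchar(seqc))
  prot[protected] <- TRUE
  enc_b <- encode_rna(seqc)
  min_run <- rep_len(min_run, length(against))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (ai in seq_along(against)) {
      a <- against[ai]
      enc_a <- encode_rna(a)
      runs <- .pair_runs_cpp(enc_a, enc_b, min_run[ai])
      if (nrow(runs) == 0) next
      for (r in seq_len(nrow(runs))) {
        ai <- runs[r, 1] + seq_len(runs[r, 3]) - 1L
        bj <- runs[r, 2] - seq_len(runs[r, 3]) + 1L
        free <- which(!prot[bj])
        if (length(free) == 0) next # fully planted (intended) complementarity
        pick <- free[ceiling(length(free) / 2)]
        partner <- enc_a[ai[pick]]
        # replace with a base that cannot pair the sRNA partner at this cell
        repl <- which(vapply(0:3, function(bse)
          pair_index_r(partner, bse), integer(1)) < 0) - 1L
        repl <- setdiff(repl, enc_b[bj[pick]])
        enc_b[bj[pick]] <- repl[1]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  paste(BASES[enc_b + 1L], collapse = "")
}

# Generator hygiene for activation targets: with the planted sRNA site
# forced unpaired, the RBS must become accessible (that is the planted
# mechanism). Chance intramolecular partners of RBS nucleotides are removed
# by mutating, at each step, the highest-probability unprotected partner
# position under the constrained ensemble, until Pu(RBS | site open)
# reaches `pu_target`. Replacement base A pairs nothing in a purine RBS.
clear_rbs_partners <- function(seqc, rbs_local, site_local,
                               protected = integer(0), pu_target = 0.25,
                               max_span = 50L, max_mut = 40L) {
  prot <- logical(nchar(seqc))
  prot[protected] <- TRUE
  cons <- seq.int(site_local[1], site_local[2])
  rbs_pos <- seq.int(rbs_local[1], rbs_local[2])
  for (k in seq_len(max_mut)) {
    pu <- unpaired_probability(seqc, rbs_local, max_span = max_span,
                               constraint = cons)
    if (pu >= pu_target) break
    bp <- partition_function(seqc, max_span = max_span, constraint = cons,
                             pair_prob = TRUE)$pair_prob
    sub <- bp[rbs_pos, , drop = FALSE]
    sub[, c(rbs_pos, which(prot))] <- 0
    if (max(sub) <= 0) break
    q <- (which.max(sub) - 1L) %/% length(rbs_pos) + 1L
    rbs_bases <- unique(strsplit(substr(seqc, rbs_local[1], rbs_local[2]),
                                 "")[[1]])
    ok <- vapply(BASES, function(b)
      all(vapply(rbs_bases, function(r) is.na(pair_type(r, b)), logical(1))),
      logical(1))
    repl <- setdiff(BASES[ok], substr(seqc, q, q))
    if (length(repl) == 0) break
    substr(seqc, q, q) <- repl[1]
  }
  seqc
}

# R mirror of the C++ pair_index (A=0 C=1 G=2 U=3)
pair_index_r <- function(x, y) {
  key <- paste0(BASES[x + 1L], BASES[y + 1L])
  ifelse(key %in% PAIR_TYPES, 1L, -1L)
}

#' Plant an sRNA-complementary site into a synthetic transcript
#'
#' Builds a random transcript (5'UTR plus CDS, uniform A/C/G/U background,
#' AUG at the start codon) carrying the reverse complement of an sRNA linker
#' subsequence at a controlled start-codon-relative placement. Activation
#' targets additionally get a Shine-Dalgarno motif upstream of the start
#' codon whose anti-SD tract lies inside the planted site, physically
#' realizing the RBS-sequestration mechanism. Sites straddling the start
#' codon have the AUG re-imposed (the patched positions are excluded from
#' the exactly-complementary stretch recorded in the truth record). The
#' background is sanitized against chance complementarity to the sRNA and
#' its negative-control variant.
#'
#' @param srna a `synthetic_srna` from [make_srna()].
#' @param placement start-codon-relative interval `c(start, end)` for the
#'   site (positions skip 0).
#' @param utr_length actual 5'UTR length of the transcript.
#' @param rng_seed integer seed.
#' @param kind `"repression"`, `"activation"`, or `"decoy"` (a decoy is a
#'   planted site outside the ribosome window).
#' @param cds_length CDS length in nt.
#' @param utr_known if `FALSE` the transcript is flagged UTR-unknown (the
#'   screen then uses the upstream fallback).
#' @param scramble plant a shuffled (same composition) version of the site
#'   and do not protect it from sanitization: a negative control with no
#'   designed complementarity.
#' @param rbs_rel start-codon-relative interval of the planted SD motif for
#'   activation targets.
#' @return list with `transcript` (a [transcript_model()]) and `truth` (a
#'   one-row data.frame recording the planted geometry).
#' @export
plant_trans_target <- function(srna, placement, utr_length, rng_seed,
                               kind = c("repression", "activation", "decoy"),
                               cds_length = 130L, utr_known = TRUE,
                               scramble = FALSE,
                               rbs_rel = c(-13L, -8L)) {
  kind <- match.arg(kind)
  stopifnot(placement[1] != 0, placement[2] != 0,
            placement[1] <= placement[2])
  offset <- utr_length + 1L
  n <- utr_length + cds_length
  lstart <- local_from_rel(placement[1], offset)
  lend <- local_from_rel(placement[2], offset)
  if (lstart < 1 || lend > n)
    stop("placement outside the buildable region")
  site_len <- lend - lstart + 1L
  with_seed(rng_seed, {
    bg <- paste(sample(BASES, n, replace = TRUE), collapse = "")
    # choose the linker subsequence
    lnk <- substr(srna$seq, srna$linker[1], srna$linker[2])
    if (kind == "activation") {
      # subsequence centred on the planted purine motif
      mstart <- srna$sd_interval[1] - srna$linker[1] + 1L
      mlen <- srna$sd_interval[2] - srna$sd_interval[1] + 1L
      pad <- site_len - mlen
      before <- min(mstart - 1L, ceiling(pad / 2))
      sub_start <- mstart - before
    } else {
      # subsequence downstream of the motif, position varied by seed
      lo <- srna$sd_interval[2] - srna$linker[1] + 2L
      hi <- nchar(lnk) - site_len + 1L
      if (hi < lo) lo <- 1L
      sub_start <- sample(seq.int(lo, hi), 1L)
    }
    if (sub_start + site_len - 1L > nchar(lnk))
      stop("placement wider than the linker allows")
    sub <- substr(lnk, sub_start, sub_start + site_len - 1L)
    site_seq <- revcomp_rna(sub)
    if (scramble)
      site_seq <- paste(sample(strsplit(site_seq, "")[[1]]), collapse = "")
    seqc <- bg
    substr(seqc, lstart, lend) <- site_seq
    # re-impose the start codon
    substr(seqc, offset, offset + 2L) <- "AUG"
    protected <- seq.int(lstart, lend)
    if (scramble) protected <- integer(0)
    if (kind == "activation") {
      rlo <- local_from_rel(rbs_rel[1], offset)
      rhi <- local_from_rel(rbs_rel[2], offset)
      substr(seqc, rlo, rhi) <- srna$arch$sd_motif
      protected <- c(protected, seq.int(rlo, rhi))
    }
    protected <- c(protected, seq.int(offset, offset + 2L))
    against <- c(srna$seq, srna_variant(srna)$seq)
    seqc <- sanitize_against(seqc, against, protected = protected)
    if (kind == "activation") {
      # The designed anti-RBS tract must be the RBS's only strong
      # intramolecular partner, or the planted activation mechanism is
      # confounded by chance RBS-sequestering helices (including composite
      # hairpins that clip single RBS nucleotides, and partners freed only
      # once the screen's *detected* site -- which may extend beyond the
      # planted one -- is opened). Enforce the mechanism thermodynamically
      # against the site the default screen actually detects, iterating to a
      # fixed point, and re-sanitize against the sRNA after each pass.
      for (round in 1:4) {
        det <- c(lstart, lend)
        tr_tmp <- transcript_model("tmp", seqc, utr_length = utr_length,
                                   start_codon_offset = offset)
        sts <- scan_transcript(srna$seq, tr_tmp, config = screen_config())
        up <- Filter(function(s) s$mrna_interval[2] < rlo, sts)
        if (length(up)) det <- up[[1]]$mrna_interval
        seqc2 <- clear_rbs_partners(seqc, rbs_local = c(rlo, rhi),
                                    site_local = det,
                                    protected = protected)
        seqc2 <- sanitize_against(seqc2, against, protected = protected)
        if (identical(seqc2, seqc)) break
        seqc <- seqc2
      }
    }
    # exactly reverse-complementary stretch (excludes the AUG patch)
    comp_rel_end <- if (lend >= offset) -1L else placement[2]
    comp_len <- if (lend >= offset) offset - lstart else site_len
    # sRNA coordinates of the complementary stretch: position lstart pairs
    # the *last* nt of the linker subsequence
    srna_sub <- srna$linker[1] + sub_start - 1L + c(0L, site_len - 1L)
    srna_comp <- c(srna_sub[2] - comp_len + 1L, srna_sub[2])
    tr <- transcript_model(gene_id = "planted", seq = seqc,
                           utr_length = if (utr_known) utr_length else NA,
                           start_codon_offset = offset)
    truth <- data.frame(kind = kind,
                        rel_start = placement[1], rel_end = placement[2],
                        comp_rel_start = placement[1],
                        comp_rel_end = comp_rel_end,
                        srna_start = srna_comp[1], srna_end = srna_comp[2],
                        utr_length = utr_length, utr_known = utr_known,
                        scrambled = scramble,
                        stringsAsFactors = FALSE)
    list(transcript = tr, truth = truth)
  })
}

#' Benchmark specification
#'
#' Parameters of the synthetic screening benchmark: gene counts per role,
#' planted effect size and multiplicative expression noise.
#'
#' @param n_genes total number of genes.
#' @param n_repression_targets,n_activation_targets planted true targets.
#' @param n_decoys_with_offwindow_sites decoys carrying planted sites outside
#'   the ribosome window.
#' @param effect_fold planted expression effect (ratio).
#' @param noise_sigma sd of the lognormal multiplicative noise (sdlog).
#' @param rng_seed integer seed.
#' @return an object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_genes = 50L, n_repression_targets = 5L,
                           n_activation_targets = 3L,
                           n_decoys_with_offwindow_sites = 10L,
                           effect_fold = 5, noise_sigma = 0.2,
                           rng_seed = 1L) {
  stopifnot(n_repression_targets + n_activation_targets +
              n_decoys_with_offwindow_sites <= n_genes,
            effect_fold > 1, noise_sigma >= 0)
  out <- list(n_genes = as.integer(n_genes),
              n_repression_targets = as.integer(n_repression_targets),
              n_activation_targets = as.integer(n_activation_targets),
              n_decoys_with_offwindow_sites =
                as.integer(n_decoys_with_offwindow_sites),
              effect_fold = effect_fold, noise_sigma = noise_sigma,
              rng_seed = as.integer(rng_seed))
  class(out) <- "benchmark_spec"
  out
}

#' Simulate a planted-effect expression table
#'
#' Planted repression targets get fold changes near `1/effect_fold`,
#' activation targets near `effect_fold`, all other genes near 1, each
#' multiplied by lognormal noise `exp(N(0, noise_sigma))`.
#'
#' @param truth truth data.frame (from [make_benchmark()]) with columns
#'   `gene_id` and `role`.
#' @param spec a [benchmark_spec()].
#' @param rng_seed integer seed (defaults to `spec$rng_seed + 1`).
#' @return data.frame with `gene_id`, `fold_change`, `direction`.
#' @export
simulate_expression <- function(truth, spec, rng_seed = spec$rng_seed + 1L) {
  base <- ifelse(truth$role == "repression", 1 / spec$effect_fold,
                 ifelse(truth$role == "activation", spec$effect_fold, 1))
  with_seed(rng_seed, {
    noise <- exp(stats::rnorm(length(base), 0, spec$noise_sigma))
    expression_records(truth$gene_id, base * noise)
  })
}

#' Generate a complete synthetic screening benchmark
#'
#' Builds an sRNA ([make_srna()]), a single-contig genome carrying planted
#' target genes on alternating strands, annotations (including one bicistronic
#' operon whose rank-2 gene is a repression target), an expression table with
#' planted fold changes, and a truth table sufficient to score any screen
#' run. Repression targets have known 36-nt 5'UTRs with sites overlapping the
#' ribosome-covered region (one straddling the start codon); activation
#' targets have 60-nt UTRs with an upstream site covering the anti-RBS tract;
#' decoys carry off-window sites at +50..+65 (half with unknown TSS, which
#' exercises the upstream fallback).
#'
#' @param spec a [benchmark_spec()].
#' @param arch an [srna_architecture()].
#' @param srna_mode `"wt"` or `"linker_null"` (negative control: the screen
#'   receives the linker-replaced sRNA; transcripts and truth are unchanged).
#' @param dir optional directory to write FASTA/TSV files into.
#' @return list with `srna` (`synthetic_srna`), `srna_screen_seq` (the
#'   sequence handed to the screen, after `srna_mode`), `genome`,
#'   `annotations`, `transcripts`, `expression`, `truth`, `spec`, `arch`.
#' @export
make_benchmark <- function(spec = benchmark_spec(),
                           arch = srna_architecture(),
                           srna_mode = c("wt", "linker_null"),
                           dir = NULL) {
  srna_mode <- match.arg(srna_mode)
  srna <- make_srna(arch, spec$rng_seed)
  n <- spec$n_genes
  roles <- c(rep("repression", spec$n_repression_targets),
             rep("activation", spec$n_activation_targets),
             rep("decoy", spec$n_decoys_with_offwindow_sites))
  roles <- c(roles, rep("background", n - length(roles)))
  gene_ids <- sprintf("g%03d", seq_len(n))
  rep_placements <- list(c(-20L, -7L), c(-12L, 6L), c(-30L, -17L),
                         c(-36L, -23L), c(-16L, -3L))
  pad5 <- 210L
  pad3 <- 30L
  cds_len <- 130L
  cassettes <- character(n)
  rows <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    role <- roles[i]
    seed_i <- spec$rng_seed * 1000L + i
    if (role == "repression") {
      pl <- rep_placements[[(i - 1L) %% length(rep_placements) + 1L]]
      pt <- plant_trans_target(srna, pl, utr_length = 36L, rng_seed = seed_i,
                               kind = "repression", cds_length = cds_len)
    } else if (role == "activation") {
      pt <- plant_trans_target(srna, c(-45L, -30L), utr_length = 60L,
                               rng_seed = seed_i, kind = "activation",
                               cds_length = cds_len)
    } else if (role == "decoy") {
      known <- (i %% 2L) == 0L
      pt <- plant_trans_target(srna, c(50L, 65L), utr_length = 36L,
                               rng_seed = seed_i, kind = "decoy",
                               cds_length = cds_len, utr_known = known)
    } else {
      # background: no planted site; sanitized random transcript
      pt <- plant_trans_target(srna, c(50L, 61L), utr_length = 36L,
                               rng_seed = seed_i, kind = "decoy",
                               cds_length = cds_len, scramble = TRUE)
      pt$truth$kind <- "background"
    }
    utr_len <- pt$truth$utr_length
    # embed the transcript in a cassette with sanitized flanks
    with_seed(seed_i + 1L, {
      up <- paste(sample(BASES, pad5 - utr_len, replace = TRUE),
                  collapse = "")
      dn <- paste(sample(BASES, pad3, replace = TRUE), collapse = "")
      cassette <- paste0(up, pt$transcript$seq, dn)
    })
    prot <- (pad5 - utr_len) + seq_len(nchar(pt$transcript$seq))
    cassette <- sanitize_against(cassette,
                                 c(srna$seq, srna_variant(srna)$seq),
                                 protected = prot)
    cassettes[i] <- cassette
    tr <- pt$truth
    tr$gene_id <- gene_ids[i]
    tr$role <- if (tr$kind[1] == "background") "background" else role
    tr$cassette_start_codon <- pad5 + 1L
    tr$cds_len <- cds_len
    truth[[i]] <- tr
  }
  # assemble the genome, alternating strands
  annots <- vector("list", n)
  genome_parts <- character(n)
  pos <- 0L
  for (i in seq_len(n)) {
    L <- nchar(cassettes[i])
    tr <- truth[[i]]
    plus <- (i %% 2L) == 1L
    sc_cas <- tr$cassette_start_codon
    utr_len <- tr$utr_length
    cds_end_cas <- sc_cas + tr$cds_len - 1L
    tss_cas <- sc_cas - utr_len
    if (plus) {
      genome_parts[i] <- cassettes[i]
      start_codon <- pos + sc_cas
      tss <- pos + tss_cas
      span <- c(pos + tss_cas, pos + cds_end_cas)
      strand <- "+"
    } else {
      genome_parts[i] <- revcomp_rna(cassettes[i])
      start_codon <- pos + L + 1L - sc_cas
      tss <- pos + L + 1L - tss_cas
      span <- c(pos + L + 1L - cds_end_cas, pos + L + 1L - tss_cas)
      strand <- "-"
    }
    annots[[i]] <- data.frame(gene_id = tr$gene_id, contig = "synth_contig",
                              start = span[1], end = span[2],
                              strand = strand, start_codon = start_codon,
                              tss = if (tr$utr_known) tss else NA_integer_,
                              operon_id = NA_character_,
                              operon_rank = NA_integer_,
                              stringsAsFactors = FALSE)
    truth[[i]]$strand <- strand
    pos <- pos + L
  }
  annotations <- do.call(rbind, annots)
  truth <- do.call(rbind, truth)
  # one bicistronic operon: the first repression target is rank 2, a
  # background gene rank 1 (exercises the first-ORF inclusion rule)
  rep_idx <- which(truth$role == "repression")
  bg_idx <- which(truth$role == "background")
  if (length(rep_idx) >= 1 && length(bg_idx) >= 1) {
    annotations$operon_id[c(bg_idx[1], rep_idx[1])] <- "op1"
    annotations$operon_rank[c(bg_idx[1], rep_idx[1])] <- c(1L, 2L)
  }
  annotations <- validate_annotations(annotations)
  genome <- c(synth_contig = paste(genome_parts, collapse = ""))
  expression <- simulate_expression(truth, spec)
  transcripts <- lapply(seq_len(nrow(annotations)), function(i)
    build_transcript(annotations[i, ], genome))
  names(transcripts) <- annotations$gene_id
  srna_screen_seq <- if (srna_mode == "wt") srna$seq
                     else srna_variant(srna)$seq
  out <- list(srna = srna, srna_mode = srna_mode,
              srna_screen_seq = srna_screen_seq,
              genome = genome, annotations = annotations,
              transcripts = transcripts, expression = expression,
              truth = truth, spec = spec, arch = arch)
  class(out) <- "srna_benchmark"
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(c(sRNA_synth = srna_screen_seq),
                file.path(dir, "srna.fasta"))
    write_fasta(genome, file.path(dir, "genome.fasta"))
    write_annotations(annotations, file.path(dir, "annotations.tsv"))
    utils::write.table(expression, file.path(dir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

#' @export
print.srna_benchmark <- function(x, ...) {
  cat("<srna_benchmark>", x$spec$n_genes, "genes (",
      sum(x$truth$role == "repression"), "repression,",
      sum(x$truth$role == "activation"), "activation,",
      sum(x$truth$role == "decoy"), "decoys ), sRNA mode", x$srna_mode, "\n")
  invisible(x)
}

#' Score a screen result against benchmark truth
#'
#' @param screen an `srna_screen` from [run_screen()].
#' @param truth the benchmark truth table.
#' @return list with repression/activation precision and recall, and decoy /
#'   background false-positive counts.
#' @export
score_screen <- function(screen, truth) {
  calls <- screen$calls
  pred_rep <- calls$gene_id[calls$verdict == "repression_candidate"]
  pred_act <- calls$gene_id[calls$verdict == "activation_candidate"]
  true_rep <- truth$gene_id[truth$role == "repression"]
  true_act <- truth$gene_id[truth$role == "activation"]
  prec <- function(pred, pos) if (length(pred) == 0) 1
                              else mean(pred %in% pos)
  rec <- function(pred, pos) if (length(pos) == 0) 1
                             else mean(pos %in% pred)
  decoys <- truth$gene_id[truth$role == "decoy"]
  backg <- truth$gene_id[truth$role == "background"]
  list(repression_precision = prec(pred_rep, true_rep),
       repression_recall = rec(pred_rep, true_rep),
       activation_precision = prec(pred_act, true_act),
       activation_recall = rec(pred_act, true_act),
       decoy_false_positives = sum(c(pred_rep, pred_act) %in% decoys),
       background_false_positives = sum(c(pred_rep, pred_act) %in% backg),
       n_repression_calls = length(pred_rep),
       n_activation_calls = length(pred_act))
}

#' Generate a cis-antisense gene pair
#'
#' Places the synthetic sRNA on the plus strand of a contig and an antisense
#' gene on the minus strand whose transcript 5' end overlaps the sRNA's 5'
#' end by exactly `overlap_len` nt (default 65), with the antisense gene's
#' TSS `utr_len` nt (default 184) upstream of its translation start --- the
#' head-to-head arrangement of a cis-encoded antisense RNA and its flanking
#' gene. On the shared contig the two transcripts are exactly reverse
#' complementary over the overlap by construction.
#'
#' @param overlap_len overlap length in nt (0 gives a disjoint pair).
#' @param utr_len 5'UTR length of the antisense gene.
#' @param cds_len CDS length of the antisense gene.
#' @param rng_seed integer seed.
#' @param arch an [srna_architecture()] for the embedded sRNA.
#' @return list with `contig` (named character), `annotations` (2-row
#'   data.frame: the sRNA feature and the antisense gene), `srna`.
#' @export
make_cis_pair <- function(overlap_len = 65L, utr_len = 184L, cds_len = 60L,
                          rng_seed = 1L, arch = srna_architecture()) {
  srna <- make_srna(arch, rng_seed)
  slen <- nchar(srna$seq)
  stopifnot(overlap_len < slen, overlap_len < utr_len + cds_len)
  tx_len <- utr_len + cds_len
  srna_start <- max(201L, tx_len + 10L - overlap_len)
  tss_b <- srna_start + overlap_len - 1L # genomic 5' end of the minus gene
  span_b <- c(tss_b - tx_len + 1L, tss_b)
  start_codon_b <- tss_b - utr_len
  contig_len <- srna_start + slen + 50L
  contig <- with_seed(rng_seed + 1L, {
    paste(sample(BASES, contig_len, replace = TRUE), collapse = "")
  })
  substr(contig, srna_start, srna_start + slen - 1L) <- srna$seq
  # give the minus gene an AUG at its start codon (genomic revcomp: CAU)
  substr(contig, start_codon_b - 2L, start_codon_b) <- "CAU"
  ann <- data.frame(
    gene_id = c("sRNA_synth", "as_gene"),
    contig = "cis_contig",
    start = c(srna_start, span_b[1]),
    end = c(srna_start + slen - 1L, span_b[2]),
    strand = c("+", "-"),
    start_codon = c(srna_start, start_codon_b),
    tss = c(srna_start, tss_b),
    operon_id = NA_character_, operon_rank = NA_integer_,
    stringsAsFactors = FALSE)
  ann <- validate_annotations(ann)
  list(contig = c(cis_contig = contig), annotations = ann, srna = srna)
}
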