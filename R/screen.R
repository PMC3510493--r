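# The candidate-screening logic: expression filtering, search-region
# construction, repression/activation classification, cis-antisense overlap
# analysis, and qRT-PCR fold-change computation.

#' Screening configuration
#'
#' Collects the thresholds and folding parameters of the target screen.
#' Defaults follow the screening procedure this package implements: a 3-fold
#' expression-change cutoff, the ribosome-covered mRNA region from -39 (5'UTR)
#' to +19 (CDS) around the translation start, an RBS unpaired-probability
#' change threshold of 0.001 for the activation branch, a 200-nt upstream
#' fallback when the 5'UTR is unknown, a 100-nt CDS extension of the search
#' region, an interaction seed of 8 consecutive base pairs, and local folding
#' in 100-nt windows with a 50-nt maximal base-pair span.
#'
#' @param fold_threshold minimum fold change (ratio, either direction).
#' @param ribosome_window start-codon-relative interval covered by an
#'   initiating ribosome, `c(-39, 19)`.
#' @param dpu_threshold minimum RBS accessibility gain for activation calls.
#' @param utr_fallback upstream nt used when the TSS is unknown.
#' @param cds_extension nt of CDS included in the search region.
#' @param seed interaction seed: required consecutive base pairs.
#' @param seed_gu whether GU pairs may form part of the seed.
#' @param window,max_span local-folding window and maximal base-pair span.
#' @param window_mode accessibility evaluation mode: `"center"` (single
#'   window centred on the queried site) or `"average"` (mean over all
#'   windows containing it).
#' @param contained if `TRUE`, the repression filter requires the site to lie
#'   entirely inside the ribosome window instead of merely overlapping it.
#' @param anti_sd,rbs_scan_window,rbs_threshold,rbs_seed RBS-scan settings,
#'   see [locate_rbs()].
#' @param max_sites maximum number of non-overlapping sites reported per
#'   transcript.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(fold_threshold = 3,
                          ribosome_window = c(-39L, 19L),
                          dpu_threshold = 0.001,
                          utr_fallback = 200L,
                          cds_extension = 100L,
                          seed = 8L,
                          seed_gu = TRUE,
                          window = 100L,
                          max_span = 50L,
                          window_mode = c("center", "average"),
                          contained = FALSE,
                          anti_sd = "CCUCCU",
                          rbs_scan_window = c(-20L, -4L),
                          rbs_threshold = -3.5,
                          rbs_seed = 4L,
                          max_sites = 3L) {
  window_mode <- match.arg(window_mode)
  stopifnot(fold_threshold > 1, dpu_threshold > 0,
            ribosome_window[1] < 0, ribosome_window[2] > 0)
  out <- list(fold_threshold = fold_threshold,
              ribosome_window = as.integer(ribosome_window),
              dpu_threshold = dpu_threshold,
              utr_fallback = as.integer(utr_fallback),
              cds_extension = as.integer(cds_extension),
              seed = as.integer(seed), seed_gu = seed_gu,
              window = as.integer(window), max_span = as.integer(max_span),
              window_mode = window_mode, contained = contained,
              anti_sd = anti_sd,
              rbs_scan_window = as.integer(rbs_scan_window),
              rbs_threshold = rbs_threshold, rbs_seed = as.integer(rbs_seed),
              max_sites = as.integer(max_sites))
  class(out) <- "screen_config"
  out
}

#' Select candidate genes by expression change
#'
#' Keeps genes whose fold change satisfies
#' `max(fold_change, 1/fold_change) >= fold_threshold` (boundary inclusive)
#' and, for every operon containing a selected gene, adds the operon's
#' rank-1 ORF as well (regulation of a polycistronic transcript acts through
#' its shared 5' end). Added first-ORFs inherit the screening direction of
#' the operon member that crossed the threshold; their own fold change is
#' reported. Output is deduplicated with input order preserved.
#'
#' @param expression data.frame from [read_expression()].
#' @param annotations data.frame from [read_annotations()] (provides
#'   `operon_id`/`operon_rank`); genes without annotation are reported in the
#'   `skipped` attribute rather than failing.
#' @param config a [screen_config()].
#' @return data.frame with columns `gene_id`, `fold_change`, `direction`,
#'   `selection` (`"fold_change"` or `"operon_first_orf"`), and attribute
#'   `skipped`.
#' @export
select_candidates <- function(expression, annotations,
                              config = screen_config()) {
  fc <- expression$fold_change
  hit <- pmax(fc, 1 / fc) >= config$fold_threshold
  sel <- expression[hit, , drop = FALSE]
  sel$selection <- rep("fold_change", nrow(sel))
  ann <- annotations[match(sel$gene_id, annotations$gene_id), , drop = FALSE]
  skipped <- sel$gene_id[is.na(ann$gene_id)]
  # first ORF of each operon containing a selected gene
  extra <- list()
  in_operons <- unique(stats::na.omit(ann$operon_id))
  for (op in in_operons) {
    first <- annotations$gene_id[which(annotations$operon_id %in% op &
                                         annotations$operon_rank == 1L)]
    if (length(first) == 0) next
    first <- first[1]
    if (first %in% sel$gene_id) next
    trigger <- sel$gene_id[which(ann$operon_id %in% op)][1]
    efc <- expression$fold_change[match(first, expression$gene_id)]
    extra[[length(extra) + 1L]] <-
      data.frame(gene_id = first,
                 fold_change = if (is.na(efc)) NA_real_ else efc,
                 direction = sel$direction[sel$gene_id == trigger][1],
                 selection = "operon_first_orf",
                 stringsAsFactors = FALSE)
  }
  if (length(extra)) sel <- rbind(sel, do.call(rbind, extra))
  sel <- sel[!duplicated(sel$gene_id), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "skipped") <- skipped
  sel
}

#' Build the search region of a transcript
#'
#' The region used for interaction prediction: the full 5'UTR (from the TSS)
#' plus `cds_extension` nt of CDS when the UTR is known, otherwise
#' `utr_fallback` nt upstream of the translation start plus the CDS
#' extension. A CDS shorter than the extension truncates the region with a
#' warning.
#'
#' @param transcript a [transcript_model()].
#' @param config a [screen_config()].
#' @return list with `seq`, `region_start` (transcript coordinate of the
#'   region's first nt), `start_codon_offset` (position of +1 within the
#'   region), `gene_id`.
#' @export
build_search_region <- function(transcript, config = screen_config()) {
  offset <- transcript$start_codon_offset
  n <- nchar(transcript$seq)
  from <- if (is.na(transcript$utr_length))
    max(1L, offset - config$utr_fallback) else 1L
  to <- offset + config$cds_extension - 1L
  if (to > n) {
    warning("CDS of ", transcript$gene_id, " shorter than the ",
            config$cds_extension, "-nt extension; region truncated")
    to <- n
  }
  list(seq = substr(transcript$seq, from, to),
       region_start = from,
       start_codon_offset = offset - from + 1L,
       gene_id = transcript$gene_id)
}

#' Ribosome-window (repression) filter
#'
#' `TRUE` when the site's start-codon-relative mRNA interval intersects the
#' ribosome-covered region (default -39..+19); with `config$contained`, the
#' site must lie entirely inside it.
#'
#' @param site an `interaction_site` carrying `mrna_rel`.
#' @param config a [screen_config()].
#' @return logical flag.
#' @export
repression_filter <- function(site, config = screen_config()) {
  if (is.null(site$mrna_rel))
    stop("site lacks start-codon-relative coordinates")
  w <- config$ribosome_window
  r <- site$mrna_rel
  if (config$contained) r[1] >= w[1] && r[2] <= w[2]
  else r[1] <= w[2] && r[2] >= w[1]
}

#' Change in RBS accessibility caused by an upstream interaction
#'
#' Computes the unpaired probability of the RBS sequence before and after the
#' putative sRNA interaction; "after" is modelled as constrained folding with
#' the site's mRNA positions forced unpaired (the bound sRNA occupies them).
#' The site must lie strictly upstream of the RBS (sites overlapping the RBS
#' belong to the repression branch and raise an error).
#'
#' @param transcript a [transcript_model()].
#' @param site an `interaction_site` with transcript-local `mrna_interval`.
#' @param rbs an `rbs_location` from [locate_rbs()].
#' @param model an [energy_model()].
#' @param config a [screen_config()] (folding window, span, window mode).
#' @return signed probability change `Pu_after - Pu_before`.
#' @export
rbs_accessibility_change <- function(transcript, site, rbs,
                                     model = energy_model(),
                                     config = screen_config()) {
  rbs_local <- rbs$interval_local
  if (site$mrna_interval[2] >= rbs_local[1])
    stop("site is not strictly upstream of the RBS; ",
         "use the repression branch for overlapping sites")
  seqc <- transcript$seq
  occupied <- seq.int(site$mrna_interval[1], site$mrna_interval[2])
  # fold a common window containing both the site and the RBS so the two
  # evaluations differ only by the constraint
  span_int <- c(site$mrna_interval[1], rbs_local[2])
  before <- pu_with_window(seqc, rbs_local, span_int, model, config,
                           constraint = integer(0))
  after <- pu_with_window(seqc, rbs_local, span_int, model, config,
                          constraint = occupied)
  after - before
}

# Pu of `interval` evaluated in windows sized/placed for `anchor_int`
# (an interval that must be covered together with `interval`).
pu_with_window <- function(seqc, interval, anchor_int, model, config,
                           constraint) {
  window <- max(config$window, anchor_int[2] - anchor_int[1] + 1L)
  pu_anchor <- function(ws, we) {
    loc <- function(p) p - ws + 1L
    cons <- constraint[constraint >= ws & constraint <= we]
    unpaired_probability(substr(seqc, ws, we), loc(interval), model,
                         config$max_span, loc(cons))
  }
  n <- nchar(seqc)
  if (n <= window) return(pu_anchor(1L, n))
  if (config$window_mode == "center") {
    mid <- (anchor_int[1] + anchor_int[2]) / 2
    ws <- as.integer(round(mid - window / 2 + 0.5))
    ws <- max(1L, min(ws, n - window + 1L, anchor_int[1]))
    we <- min(n, ws + window - 1L)
    return(pu_anchor(ws, we))
  }
  starts <- seq.int(max(1L, anchor_int[2] - window + 1L),
                    min(anchor_int[1], n - window + 1L))
  mean(vapply(starts, function(ws) pu_anchor(ws, ws + window - 1L),
              numeric(1)))
}

#' Classify one candidate gene
#'
#' Applies the direction-conditional screening branches: down-regulated genes
#' become `repression_candidate` when any reported site passes the
#' ribosome-window filter (the best passing site is recorded); up-regulated
#' genes become `activation_candidate` when the best site strictly upstream
#' of the RBS increases the RBS unpaired probability by more than the
#' threshold. Otherwise the verdict is `none` with a rationale code.
#'
#' @param transcript a [transcript_model()].
#' @param sites list of `interaction_site` (ranked by `E_total`).
#' @param rbs an `rbs_location` or `NULL`.
#' @param direction `"up"` or `"down"`.
#' @param model an [energy_model()].
#' @param config a [screen_config()].
#' @return an object of class `target_call`: list with `gene_id`, `verdict`,
#'   `best_site`, `rbs`, `dPu`, `rationale`.
#' @export
classify_candidate <- function(transcript, sites, rbs, direction,
                               model = energy_model(),
                               config = screen_config()) {
  call <- list(gene_id = transcript$gene_id, verdict = "none",
               best_site = NULL, rbs = rbs, dPu = NA_real_,
               rationale = "")
  class(call) <- "target_call"
  if (length(sites) == 0) {
    call$rationale <- "no_site"
    return(call)
  }
  if (direction == "down") {
    pass <- vapply(sites, repression_filter, logical(1), config = config)
    if (any(pass)) {
      call$verdict <- "repression_candidate"
      call$best_site <- sites[[which(pass)[1]]]
      call$rationale <- "site_in_ribosome_window"
    } else {
      call$rationale <- "no_site_in_ribosome_window"
    }
    return(call)
  }
  # up-regulated branch
  if (is.null(rbs)) {
    call$rationale <- "no_rbs"
    return(call)
  }
  upstream <- Filter(function(s) s$mrna_interval[2] < rbs$interval_local[1],
                     sites)
  if (length(upstream) == 0) {
    call$rationale <- "no_upstream_site"
    return(call)
  }
  best <- upstream[[1]]
  dpu <- rbs_accessibility_change(transcript, best, rbs, model, config)
  call$dPu <- dpu
  call$best_site <- best
  if (dpu > config$dpu_threshold) {
    call$verdict <- "activation_candidate"
    call$rationale <- "rbs_accessibility_gain"
  } else {
    call$rationale <- "dPu_below_threshold"
  }
  call
}

#' @export
print.target_call <- function(x, ...) {
  cat("<target_call>", x$gene_id, "->", x$verdict,
      paste0("(", x$rationale, ")"), "\n")
  invisible(x)
}

#' Run the full sRNA target screen
#'
#' The end-to-end screening procedure: candidate genes are selected by
#' expression change (plus operon first-ORFs), a search region is built for
#' each, interaction sites are predicted with the seed constraint and scored
#' with accessibility-corrected energies, and each candidate is classified
#' into the repression branch (site within the ribosome-covered region,
#' down-regulated genes) or the activation branch (upstream site increasing
#' RBS accessibility, up-regulated genes).
#'
#' @param srna sRNA sequence (character) or a named length-1 vector from
#'   [read_fasta()].
#' @param transcripts list of [transcript_model()] objects (named by gene).
#' @param expression data.frame from [read_expression()].
#' @param annotations data.frame from [read_annotations()].
#' @param config a [screen_config()].
#' @param model an [energy_model()].
#' @return an object of class `srna_screen`: list with `calls` (one row per
#'   candidate, ranked by verdict class then `E_total`), `details` (the
#'   underlying `target_call` objects), `candidates`, `config`, `warnings`.
#' @export
run_screen <- function(srna, transcripts, expression, annotations,
                       config = screen_config(), model = energy_model()) {
  srna <- unname(srna[[1]])
  cand <- select_candidates(expression, annotations, config)
  warn <- character(0)
  if (length(attr(cand, "skipped")))
    warn <- c(warn, paste0("no annotation for selected gene(s): ",
                           paste(attr(cand, "skipped"), collapse = ", ")))
  details <- list()
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    gid <- cand$gene_id[k]
    tr <- transcripts[[gid]]
    if (is.null(tr)) {
      warn <- c(warn, paste0("no transcript for candidate ", gid))
      next
    }
    sites <- withCallingHandlers(
      scan_transcript(srna, tr, model, config),
      warning = function(w) {
        warn <<- c(warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    rbs <- suppressWarnings(
      locate_rbs(tr, config$anti_sd, model, config$rbs_scan_window,
                 config$rbs_threshold, config$rbs_seed))
    call <- classify_candidate(tr, sites, rbs, cand$direction[k], model,
                               config)
    details[[gid]] <- call
    bs <- call$best_site
    if (is.null(bs) && length(sites)) bs <- sites[[1]]
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gid,
      fold_change = cand$fold_change[k],
      direction = cand$direction[k],
      selection = cand$selection[k],
      verdict = call$verdict,
      rationale = call$rationale,
      srna_start = if (is.null(bs)) NA_integer_ else bs$srna_interval[1],
      srna_end = if (is.null(bs)) NA_integer_ else bs$srna_interval[2],
      mrna_start = if (is.null(bs)) NA_integer_ else bs$mrna_interval[1],
      mrna_end = if (is.null(bs)) NA_integer_ else bs$mrna_interval[2],
      rel_start = if (is.null(bs)) NA_integer_ else bs$mrna_rel[1],
      rel_end = if (is.null(bs)) NA_integer_ else bs$mrna_rel[2],
      E_hybrid = if (is.null(bs)) NA_real_ else bs$E_hybrid,
      ED_srna = if (is.null(bs)) NA_real_ else bs$ED_srna,
      ED_mrna = if (is.null(bs)) NA_real_ else bs$ED_mrna,
      E_total = if (is.null(bs)) NA_real_ else bs$E_total,
      rbs_start = if (is.null(call$rbs)) NA_integer_ else call$rbs$interval[1],
      rbs_end = if (is.null(call$rbs)) NA_integer_ else call$rbs$interval[2],
      rbs_energy = if (is.null(call$rbs)) NA_real_ else call$rbs$energy,
      dPu = call$dPu,
      stringsAsFactors = FALSE)
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), verdict = character(0))
  if (nrow(calls)) {
    vclass <- match(calls$verdict,
                    c("repression_candidate", "activation_candidate", "none"))
    calls <- calls[order(vclass, calls$E_total, na.last = TRUE), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  out <- list(calls = calls, details = details, candidates = cand,
              config = config, warnings = unique(warn))
  class(out) <- "srna_screen"
  out
}

#' @export
print.srna_screen <- function(x, ...) {
  cat("<srna_screen>", nrow(x$calls), "candidate gene(s):",
      sum(x$calls$verdict == "repression_candidate"), "repression,",
      sum(x$calls$verdict == "activation_candidate"), "activation\n")
  if (nrow(x$calls))
    print(utils::head(x$calls[, c("gene_id", "fold_change", "direction",
                                  "verdict", "rel_start", "rel_end",
                                  "E_total")], 10))
  if (length(x$warnings))
    cat(length(x$warnings), "warning(s); see $warnings\n")
  invisible(x)
}

#' @export
summary.srna_screen <- function(object, ...) {
  v <- table(factor(object$calls$verdict,
                    levels = c("repression_candidate",
                               "activation_candidate", "none")))
  cat("sRNA target screen:", nrow(object$calls), "candidates\n")
  print(v)
  if (nrow(object$calls)) {
    hits <- object$calls[object$calls$verdict != "none", , drop = FALSE]
    if (nrow(hits)) {
      cat("\nCalls (ascending E_total):\n")
      print(hits[, c("gene_id", "direction", "verdict", "rel_start",
                     "rel_end", "E_hybrid", "E_total", "dPu")])
    }
  }
  invisible(object)
}

#' Classify the overlap of an antisense gene pair
#'
#' Coordinate arithmetic for cis-encoded antisense arrangements: computes the
#' overlap length of two features on the same contig and classifies which
#' ends meet, in each feature's own orientation: `5p5p` (5' ends overlap,
#' head-to-head), `3p3p` (tails overlap), `internal` (one feature inside the
#' other, or identical spans), or `none`. Same-strand input is classified
#' `not_antisense`.
#'
#' @param a,b single-row annotations (data.frame rows with `contig`,
#'   `start`, `end`, `strand`).
#' @return list with `overlap` (nt) and `class`.
#' @export
antisense_overlap <- function(a, b) {
  a <- as.list(a[1, , drop = FALSE]); b <- as.list(b[1, , drop = FALSE])
  if (a$contig != b$contig) return(list(overlap = 0L, class = "none"))
  lo <- max(a$start, b$start)
  hi <- min(a$end, b$end)
  ov <- as.integer(max(0, hi - lo + 1))
  if (a$strand == b$strand)
    return(list(overlap = ov, class = "not_antisense"))
  if (ov == 0L) return(list(overlap = 0L, class = "none"))
  end5 <- function(x) if (x$strand == "+") x$start else x$end
  end3 <- function(x) if (x$strand == "+") x$end else x$start
  inside <- function(p) p >= lo && p <= hi
  a_in <- a$start >= b$start && a$end <= b$end
  b_in <- b$start >= a$start && b$end <= a$end
  cls <- if (a_in || b_in) "internal"
  else if (inside(end5(a)) && inside(end5(b))) "5p5p"
  else if (inside(end3(a)) && inside(end3(b))) "3p3p"
  else "internal"
  list(overlap = ov, class = cls)
}

#' Relative quantification from qRT-PCR threshold cycles
#'
#' Implements the 2^-ddCt method: per condition, dCt is the target's Ct minus
#' the mean Ct of the reference genes; ddCt is dCt in the test condition
#' (e.g. mutant) minus dCt in the control condition (wild type); the fold
#' change is `2^-ddCt`. Replicate Ct values are averaged per gene and
#' condition first. Adding a constant to all Ct values leaves the result
#' unchanged.
#'
#' @param ct data.frame with columns `gene_id`, `condition`, `ct` (one row
#'   per measurement; replicates allowed).
#' @param reference_genes character vector of reference gene ids (>= 1).
#' @param conditions length-2 character vector: control and test condition,
#'   in that order (defaults to `c("wt", "mut")`).
#' @return data.frame with columns `gene_id`, `ddct`, `fold_change` for each
#'   non-reference gene.
#' @examples
#' ct <- data.frame(gene_id = rep(c("t", "r1", "r2", "r3"), each = 2),
#'                  condition = rep(c("wt", "mut"), 4),
#'                  ct = c(20, 18, 15, 15, 15, 15, 15, 15))
#' fold_change_from_ct(ct, c("r1", "r2", "r3")) # fold change 4
#' @export
fold_change_from_ct <- function(ct, reference_genes,
                                conditions = c("wt", "mut")) {
  stopifnot(length(reference_genes) >= 1, length(conditions) == 2)
  if (!all(conditions %in% ct$condition))
    stop("both conditions must be present in the Ct table")
  if (any(!is.finite(ct$ct))) stop("Ct values must be finite")
  mean_ct <- function(gene, cond) {
    v <- ct$ct[ct$gene_id == gene & ct$condition == cond]
    if (length(v) == 0)
      stop("missing Ct for gene ", gene, " in condition ", cond)
    mean(v)
  }
  ref_mean <- function(cond)
    mean(vapply(reference_genes, mean_ct, numeric(1), cond = cond))
  targets <- setdiff(unique(ct$gene_id), reference_genes)
  ddct <- vapply(targets, function(g) {
    dct_ctrl <- mean_ct(g, conditions[1]) - ref_mean(conditions[1])
    dct_test <- mean_ct(g, conditions[2]) - ref_mean(conditions[2])
    dct_test - dct_ctrl
  }, numeric(1))
  data.frame(gene_id = targets, ddct = unname(ddct),
             fold_change = unname(2^-ddct), stringsAsFactors = FALSE)
}
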