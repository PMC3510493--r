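# Intermolecular hybridization: seed-constrained duplex prediction and total
# interaction energies combining hybridization with opening energies.

#' Evaluate the hybridization energy of an explicit duplex pairing
#'
#' Direct evaluator (also used as a cross-check for [hybridize()]):
#' `duplex_init` plus, for each consecutive pair step, the stacking energy
#' (adjacent pairs) or the interior/bulge penalty. Validates that all pairs
#' are canonical, monotone (antiparallel, non-crossing) and within the duplex
#' loop cap.
#'
#' @param s1,s2 RNA sequences (5'->3').
#' @param pairing integer matrix with columns `pos1`, `pos2`.
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(s1, s2, pairing, model = energy_model()) {
  if (nrow(pairing) == 0) stop("empty pairing")
  v1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  p <- pairing[order(pairing[, 1]), , drop = FALSE]
  if (anyDuplicated(p[, 1]) || anyDuplicated(p[, 2]))
    stop("positions may pair at most once")
  if (nrow(p) > 1 && any(diff(p[, 2]) >= 0))
    stop("crossing or parallel pairs: pos2 must strictly decrease")
  pt <- pair_type(v1[p[, 1]], v2[p[, 2]])
  if (anyNA(pt))
    stop("non-canonical pair ", v1[p[which(is.na(pt))[1], 1]], "-",
         v2[p[which(is.na(pt))[1], 2]])
  e <- model$duplex_init
  if (nrow(p) > 1) {
    for (t in seq_len(nrow(p) - 1)) {
      ga <- p[t + 1, 1] - p[t, 1] - 1L
      gb <- p[t, 2] - p[t + 1, 2] - 1L
      st <- duplex_step_energy(model, pt[t], pt[t + 1], ga, gb)
      if (is.na(st))
        stop("interior/bulge loop exceeds the duplex cap of ",
             model$max_bulge, " nt per side")
      e <- e + st
    }
  }
  unname(e)
}

#' Predict the optimal seed-containing sRNA-mRNA duplex
#'
#' Dynamic program over antiparallel, non-crossing intermolecular duplexes
#' (no intramolecular pairs inside the site; interior/bulge loops up to the
#' model's cap per side) that returns the minimum-energy duplex containing at
#' least `seed_len` consecutive base pairs, or `NULL` if no such duplex with
#' negative hybridization energy exists. Accessibility (opening-energy) terms
#' are attached separately with [attach_accessibility()].
#'
#' @param srna,region RNA sequences (5'->3').
#' @param model an [energy_model()].
#' @param seed_len required number of consecutive base pairs (default 8).
#' @param seed_gu whether GU pairs may participate in the seed run.
#' @param forbidden integer vector of region positions excluded from pairing
#'   (used for iterative non-overlapping site scans).
#' @param extension maximal extension of the duplex beyond the seed run, in
#'   nt per side and molecule (keeps interaction sites compact, the standard
#'   assumption of site-level accessibility models). Sequences shorter than
#'   the extension are searched exhaustively.
#' @return an `interaction_site` (list with `srna_interval`, `mrna_interval`,
#'   `pairing`, `E_hybrid`, `ED_srna`, `ED_mrna`, `E_total`) or `NULL`.
#' @export
hybridize <- function(srna, region, model = energy_model(), seed_len = 8L,
                      seed_gu = TRUE, forbidden = integer(0),
                      extension = 20L) {
  if (nchar(srna) < 1 || nchar(region) < 1)
    stop("both sequences must be nonempty")
  ea <- encode_rna(srna)
  eb <- encode_rna(region)
  m <- length(ea); n <- length(eb)
  fb <- logical(n)
  fb[forbidden] <- TRUE
  # seed anchors: maximal runs of consecutive (seed-eligible) pairs
  runs <- .pair_runs_cpp(ea, eb, as.integer(seed_len), seed_gu, fb)
  if (nrow(runs) == 0) return(NULL)
  best <- NULL
  for (r in seq_len(nrow(runs))) {
    L <- runs[r, 3]
    alo <- max(1L, runs[r, 1] - extension)
    ahi <- min(m, runs[r, 1] + L - 1L + extension)
    blo <- max(1L, runs[r, 2] - L + 1L - extension)
    bhi <- min(n, runs[r, 2] + extension)
    res <- .duplex_cpp(ea[alo:ahi], eb[blo:bhi], unclass(model),
                       as.integer(seed_len), seed_gu, model$max_bulge,
                       fb[blo:bhi])
    if (!res$found) next
    pairing <- res$pairing
    pairing[, 1] <- pairing[, 1] + alo - 1L
    pairing[, 2] <- pairing[, 2] + blo - 1L
    cand <- list(E = res$E, pairing = pairing)
    if (is.null(best) || better_site(cand, best)) best <- cand
  }
  if (is.null(best)) return(NULL)
  pairing <- best$pairing
  colnames(pairing) <- c("pos1", "pos2")
  interaction_site(srna_interval = range(pairing[, 1]),
                   mrna_interval = range(pairing[, 2]),
                   pairing = pairing, E_hybrid = best$E)
}

# Accessibility-aware site refinement: the E_hybrid-optimal duplex tends to
# pick up marginal helices far from the seed whose hybridization gain does
# not pay their opening-energy cost. The duplex is split into stacked blocks
# (maximal gap-free runs); every contiguous block range still containing a
# seed run is scored as E_hybrid + ED_srna + ED_mrna, and the range with the
# lowest total energy is reported.
trim_site_blocks <- function(site, srna, mrna_seq, model, config) {
  p <- site$pairing
  np <- nrow(p)
  brk <- which(diff(p[, 1]) != 1L | diff(p[, 2]) != -1L)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, np)
  nb <- length(starts)
  score_range <- function(a, b) {
    rows <- seq.int(starts[a], ends[b])
    sub <- p[rows, , drop = FALSE]
    s <- interaction_site(srna_interval = range(sub[, 1]),
                          mrna_interval = range(sub[, 2]),
                          pairing = sub,
                          E_hybrid = duplex_energy(srna, mrna_seq, sub,
                                                   model))
    attach_accessibility(s, srna = srna, mrna = mrna_seq, model = model,
                         window = config$window, max_span = config$max_span,
                         mode = config$window_mode)
  }
  has_seed <- function(a, b) {
    rows <- seq.int(starts[a], ends[b])
    sub <- site
    sub$pairing <- p[rows, , drop = FALSE]
    longest_stacked_run(sub, srna, mrna_seq, seed_gu = config$seed_gu) >=
      config$seed
  }
  best <- NULL
  for (a in seq_len(nb)) {
    for (b in seq.int(a, nb)) {
      if (!has_seed(a, b)) next
      cand <- score_range(a, b)
      if (is.null(best) ||
          (is.finite(cand$E_total) &&
           (cand$E_total < best$E_total - 1e-12 ||
            (abs(cand$E_total - best$E_total) <= 1e-12 &&
             better_site(list(E = cand$E_hybrid, pairing = cand$pairing),
                         list(E = best$E_hybrid,
                              pairing = best$pairing))))))
        best <- cand
    }
  }
  if (is.null(best)) { site$unusable <- TRUE; return(site) }
  best
}

# deterministic preference: lower energy, then longer pairing, then leftmost
# mRNA start, then smallest sRNA start
better_site <- function(a, b) {
  if (a$E < b$E - 1e-12) return(TRUE)
  if (a$E > b$E + 1e-12) return(FALSE)
  if (nrow(a$pairing) != nrow(b$pairing))
    return(nrow(a$pairing) > nrow(b$pairing))
  if (min(a$pairing[, 2]) != min(b$pairing[, 2]))
    return(min(a$pairing[, 2]) < min(b$pairing[, 2]))
  min(a$pairing[, 1]) < min(b$pairing[, 1])
}

interaction_site <- function(srna_interval, mrna_interval, pairing, E_hybrid,
                             ED_srna = 0, ED_mrna = 0) {
  out <- list(srna_interval = as.integer(srna_interval),
              mrna_interval = as.integer(mrna_interval),
              pairing = pairing,
              E_hybrid = E_hybrid,
              ED_srna = ED_srna, ED_mrna = ED_mrna,
              E_total = E_hybrid + ED_srna + ED_mrna,
              mrna_rel = NULL, unusable = FALSE)
  class(out) <- "interaction_site"
  out
}

#' @export
print.interaction_site <- function(x, ...) {
  cat("<interaction_site> sRNA", x$srna_interval[1], "-", x$srna_interval[2],
      " mRNA", x$mrna_interval[1], "-", x$mrna_interval[2],
      if (!is.null(x$mrna_rel))
        paste0(" (rel ", x$mrna_rel[1], "..", x$mrna_rel[2], ")"),
      "\n  E_hybrid =", round(x$E_hybrid, 2),
      " ED_srna =", round(x$ED_srna, 3),
      " ED_mrna =", round(x$ED_mrna, 3),
      " E_total =", round(x$E_total, 2), "kcal/mol\n")
  invisible(x)
}

#' Number of consecutive base pairs in the longest stacked run of a site
#'
#' Structural seed verification: counts the longest run of pairs
#' `(i, j), (i+1, j-1), ...` with no interruption, optionally ignoring GU
#' pairs, directly from the reported pairing.
#'
#' @param site an `interaction_site`.
#' @param s1,s2 the two sequences (needed to type pairs when `seed_gu` is
#'   `FALSE`).
#' @param seed_gu whether GU pairs count towards the run.
#' @return integer run length.
#' @export
longest_stacked_run <- function(site, s1 = NULL, s2 = NULL, seed_gu = TRUE) {
  p <- site$pairing
  elig <- rep(TRUE, nrow(p))
  if (!seed_gu) {
    v1 <- strsplit(s1, "", fixed = TRUE)[[1]]
    v2 <- strsplit(s2, "", fixed = TRUE)[[1]]
    elig <- !pair_type(v1[p[, 1]], v2[p[, 2]]) %in% c("GU", "UG")
  }
  best <- 0L
  run <- 0L
  for (t in seq_len(nrow(p))) {
    contiguous <- t > 1 && p[t, 1] == p[t - 1, 1] + 1L &&
      p[t, 2] == p[t - 1, 2] - 1L
    run <- if (elig[t]) (if (contiguous) run + 1L else 1L) else 0L
    best <- max(best, run)
  }
  best
}

#' Attach opening energies to an interaction site
#'
#' Completes the interaction energy decomposition
#' `E_total = E_hybrid + ED_srna + ED_mrna`, where each `ED` is the opening
#' energy of the paired interval in its own molecule under the local-folding
#' scheme. The unpaired probabilities can be supplied directly (`pu_srna`,
#' `pu_mrna`), taken from [local_accessibility_profile()] objects, or
#' computed from the sequences.
#'
#' @param site an `interaction_site` from [hybridize()].
#' @param srna,mrna the sRNA and transcript sequences (used when
#'   probabilities are not supplied). `mrna` must be the same sequence
#'   coordinate system as `site$mrna_interval`.
#' @param model an [energy_model()].
#' @param window,max_span local-folding parameters.
#' @param mode accessibility window mode (see [local_accessibility_profile()]).
#' @param pu_srna,pu_mrna optional precomputed unpaired probabilities.
#' @return the site with `ED_srna`, `ED_mrna`, `E_total` filled in; a site
#'   with zero unpaired probability on either side is marked `unusable`.
#' @export
attach_accessibility <- function(site, srna = NULL, mrna = NULL,
                                 model = energy_model(), window = 100L,
                                 max_span = 50L, mode = "center",
                                 pu_srna = NULL, pu_mrna = NULL) {
  if (is.null(pu_srna))
    pu_srna <- pu_interval(srna, site$srna_interval, model, window, max_span,
                           mode)
  if (is.null(pu_mrna))
    pu_mrna <- pu_interval(mrna, site$mrna_interval, model, window, max_span,
                           mode)
  site$ED_srna <- opening_energy(pu_srna, model)
  site$ED_mrna <- opening_energy(pu_mrna, model)
  site$E_total <- site$E_hybrid + site$ED_srna + site$ED_mrna
  site$unusable <- !is.finite(site$E_total)
  site
}

#' Scan a transcript for ranked sRNA interaction sites
#'
#' Builds the search region of the screening procedure (full 5'UTR when the
#' TSS is known, else the configured upstream fallback, plus the leading CDS
#' extension), then repeatedly calls [hybridize()] while masking previously
#' reported mRNA intervals, yielding non-overlapping sites. Opening energies
#' are computed on the full transcript so folding context is not lost at
#' region edges. Sites are returned in ascending `E_total`; mRNA coordinates
#' are reported both transcript-local and start-codon-relative.
#'
#' @param srna sRNA sequence.
#' @param transcript a [transcript_model()].
#' @param model an [energy_model()].
#' @param config a [screen_config()].
#' @return list of `interaction_site` objects (possibly empty), each with a
#'   `mrna_rel` field `c(start, end)` in start-codon-relative coordinates.
#' @export
scan_transcript <- function(srna, transcript, model = energy_model(),
                            config = screen_config()) {
  region <- build_search_region(transcript, config)
  masked <- integer(0)
  sites <- list()
  for (it in seq_len(config$max_sites)) {
    s <- hybridize(srna, region$seq, model, config$seed, config$seed_gu,
                   forbidden = masked)
    if (is.null(s)) break
    # map region coordinates to transcript and start-codon-relative
    tr_int <- s$mrna_interval + region$region_start - 1L
    s$mrna_interval <- tr_int
    s$pairing[, 2] <- s$pairing[, 2] + region$region_start - 1L
    s$mrna_rel <- rel_from_local(tr_int, transcript$start_codon_offset)
    s <- trim_site_blocks(s, srna, transcript$seq, model, config)
    s$mrna_rel <- rel_from_local(s$mrna_interval,
                                 transcript$start_codon_offset)
    sites[[length(sites) + 1L]] <- s
    masked <- c(masked, seq.int(tr_int[1], tr_int[2]) -
                  region$region_start + 1L)
  }
  sites <- Filter(function(s) !s$unusable && s$E_total < 0, sites)
  if (length(sites) > 1) {
    ord <- order(vapply(sites, function(s) s$E_total, numeric(1)),
                 -vapply(sites, function(s) nrow(s$pairing), numeric(1)),
                 vapply(sites, function(s) s$mrna_interval[1], numeric(1)),
                 vapply(sites, function(s) s$srna_interval[1], numeric(1)))
    sites <- sites[ord]
  }
  sites
}
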