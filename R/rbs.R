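# Ribosome-binding-site location by anti-Shine-Dalgarno hybridization
# scanning upstream of the start codon.

#' Locate the ribosome binding site of a transcript
#'
#' Scans a window upstream of the start codon for the minimum-energy duplex
#' with the anti-Shine-Dalgarno sequence (the 3' tail of 16S rRNA, written
#' 5'->3'), using the intermolecular duplex program with a short seed. The
#' call is flagged significant when the duplex energy is at or below the
#' threshold.
#'
#' @param transcript a [transcript_model()].
#' @param anti_sd anti-SD sequence, 5'->3' (default `"CCUCCU"`, the
#'   complement of the canonical AGGAGG Shine-Dalgarno motif).
#' @param model an [energy_model()].
#' @param scan_window start-codon-relative interval scanned (default
#'   `c(-20, -4)`; positions are negative, upstream of +1).
#' @param threshold significance threshold in kcal/mol (default -3.5).
#' @param seed_len seed length for the anti-SD duplex (default 4).
#' @return an object of class `rbs_location` (list with `interval`
#'   start-codon-relative, `interval_local`, `energy`, `significant`) or
#'   `NULL` if no duplex is found.
#' @examples
#' tr <- transcript_model("g", "CCCCCCCAGGAGGCCCCCCAUGGGG", utr_length = 19)
#' locate_rbs(tr)
#' @export
locate_rbs <- function(transcript, anti_sd = "CCUCCU",
                       model = energy_model(), scan_window = c(-20L, -4L),
                       threshold = -3.5, seed_len = 4L) {
  stopifnot(scan_window[1] < 0, scan_window[2] < 0,
            scan_window[1] <= scan_window[2])
  offset <- transcript$start_codon_offset
  lo <- local_from_rel(scan_window[1], offset)
  hi <- local_from_rel(scan_window[2], offset)
  if (hi < 1) return(NULL)
  if (lo < 1) {
    warning("transcript ", transcript$gene_id,
            " lacks upstream sequence for the full RBS scan window; ",
            "scanning a truncated window")
    lo <- 1L
  }
  sub <- substr(transcript$seq, lo, hi)
  s <- hybridize(anti_sd, sub, model, seed_len = seed_len)
  if (is.null(s)) return(NULL)
  local <- s$mrna_interval + lo - 1L
  out <- list(interval = rel_from_local(local, offset),
              interval_local = local,
              energy = s$E_hybrid,
              significant = s$E_hybrid <= threshold)
  class(out) <- "rbs_location"
  out
}

#' @export
print.rbs_location <- function(x, ...) {
  cat("<rbs_location>", x$interval[1], "..", x$interval[2],
      "(rel. start codon), E =", round(x$energy, 2), "kcal/mol,",
      if (x$significant) "significant" else "not significant", "\n")
  invisible(x)
}
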