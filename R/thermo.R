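# Intramolecular ensemble thermodynamics: partition function, unpaired
# probabilities (accessibility), local-folding windows, opening energies.

#' Partition function over nested secondary structures
#'
#' Computes the Boltzmann partition function `Z` (open chain included, so
#' `Z >= 1`) and, optionally, base-pair probabilities for the ensemble of
#' nested secondary structures with canonical pairs (including GU), a minimum
#' hairpin loop of `model$min_hairpin` nt, base-pair span limited to
#' `max_span` nt, and any positions in `constraint` forced to stay unpaired.
#'
#' @param seq RNA sequence (character scalar over A, C, G, U).
#' @param model an [energy_model()].
#' @param max_span maximum base-pair span `j - i + 1` in nt; `Inf` for
#'   unlimited.
#' @param constraint integer vector of 1-based positions forced unpaired.
#' @param pair_prob if `TRUE`, also compute the base-pair probability matrix
#'   by the outside recursion.
#' @return an object of class `rna_ensemble`: a list with elements `Z`,
#'   `pair_prob` (n x n matrix or `NULL`), `n`, `seq`.
#' @examples
#' partition_function("AAAAAAA")$Z # 1: no canonical pair possible
#' @export
partition_function <- function(seq, model = energy_model(), max_span = Inf,
                               constraint = integer(0), pair_prob = TRUE) {
  enc <- encode_rna(seq)
  n <- length(enc)
  forced <- logical(n)
  constraint <- as.integer(constraint)
  if (length(constraint)) {
    if (any(constraint < 1L | constraint > n))
      stop("constraint positions out of bounds")
    forced[constraint] <- TRUE
  }
  span <- if (is.finite(max_span)) as.integer(max_span) else 0L
  res <- .pf_cpp(enc, unclass(model), span, forced, pair_prob)
  out <- list(Z = res$Z,
              pair_prob = if (pair_prob) res$bp else NULL,
              n = n, seq = seq,
              max_span = max_span, constraint = constraint)
  class(out) <- "rna_ensemble"
  out
}

#' @export
print.rna_ensemble <- function(x, ...) {
  cat("<rna_ensemble> n =", x$n, " Z =", format(x$Z, digits = 8), "\n")
  invisible(x)
}

#' Probability that an interval is free of intramolecular pairs
#'
#' The unpaired probability Pu of an interval is the ensemble probability
#' that every position of the interval is unpaired. It is computed exactly as
#' the ratio of the constrained partition function (interval forced unpaired,
#' on top of any pre-existing constraint) to the unconstrained one.
#'
#' @inheritParams partition_function
#' @param interval integer vector `c(start, end)` (1-based, inclusive);
#'   an empty interval (`end < start`) returns 1 by convention.
#' @return a probability in `[0, 1]`.
#' @export
unpaired_probability <- function(seq, interval, model = energy_model(),
                                 max_span = Inf, constraint = integer(0)) {
  n <- nchar(seq)
  if (length(interval) != 2L) stop("interval must be c(start, end)")
  if (interval[2] < interval[1]) return(1)
  if (interval[1] < 1 || interval[2] > n) stop("interval out of bounds")
  z0 <- partition_function(seq, model, max_span, constraint,
                           pair_prob = FALSE)$Z
  z1 <- partition_function(seq, model, max_span,
                           union(constraint,
                                 seq.int(interval[1], interval[2])),
                           pair_prob = FALSE)$Z
  z1 / z0
}

# Accessibility of an interval under the local-folding scheme.
#
# mode "center": a single window of `window` nt centred on the interval
#   (clipped at the sequence ends) is folded; Pu is computed in that window.
# mode "average": Pu is averaged over every full-length window containing
#   the interval (windows slide by 1 nt); if the sequence is shorter than the
#   window, the single truncated window [1, n] is used.
#
# `constraint` positions (global coordinates) are applied inside each window.
pu_interval <- function(seq, interval, model = energy_model(), window = 100L,
                        max_span = 50L, mode = c("center", "average"),
                        constraint = integer(0)) {
  mode <- match.arg(mode)
  n <- nchar(seq)
  if (interval[2] < interval[1]) return(1)
  if (interval[1] < 1 || interval[2] > n) stop("interval out of bounds")
  len <- interval[2] - interval[1] + 1L
  if (len > window) stop("interval longer than the folding window")
  win_pu <- function(ws, we) {
    sub <- substr(seq, ws, we)
    loc <- function(p) p - ws + 1L
    cons <- loc(constraint[constraint >= ws & constraint <= we])
    unpaired_probability(sub, loc(interval), model, max_span, cons)
  }
  if (n <= window) return(win_pu(1L, n))
  if (mode == "center") {
    mid <- (interval[1] + interval[2]) / 2
    ws <- as.integer(round(mid - window / 2 + 0.5))
    ws <- max(1L, min(ws, n - window + 1L))
    we <- ws + window - 1L
    # ensure the interval is inside the window (guaranteed by len <= window)
    ws <- min(ws, interval[1])
    we <- max(we, interval[2])
    we <- min(we, ws + window - 1L)
    return(win_pu(ws, we))
  }
  starts <- seq.int(max(1L, interval[2] - window + 1L),
                    min(interval[1], n - window + 1L))
  mean(vapply(starts, function(ws) win_pu(ws, ws + window - 1L), numeric(1)))
}

#' Local accessibility profile
#'
#' Slides folding windows of `window` nt (step 1) along the sequence and, for
#' every interval of `probe_len` nt, reports the unpaired probability averaged
#' over all full windows containing the interval. Sequences shorter than the
#' window are folded as a single (truncated) window, which makes the profile
#' identical to a global computation capped at `max_span`.
#'
#' @inheritParams partition_function
#' @param window folding window size in nt.
#' @param probe_len length of the probed intervals in nt.
#' @param mode `"average"` (window-averaged, the default) or `"center"`
#'   (single centred window per interval).
#' @return a data.frame of class `unpaired_profile` with columns `start`,
#'   `end`, `Pu`, and attributes `window`, `max_span`, `probe_len`.
#' @export
local_accessibility_profile <- function(seq, model = energy_model(),
                                        window = 100L, max_span = 50L,
                                        probe_len,
                                        mode = c("average", "center"),
                                        constraint = integer(0)) {
  mode <- match.arg(mode)
  n <- nchar(seq)
  if (probe_len > n) stop("probe_len exceeds the sequence length")
  if (window < max_span)
    warning("window smaller than max_span; span is effectively the window")
  starts <- seq_len(n - probe_len + 1L)
  pu <- vapply(starts, function(s) {
    pu_interval(seq, c(s, s + probe_len - 1L), model, window, max_span,
                mode = mode, constraint = constraint)
  }, numeric(1))
  out <- data.frame(start = starts, end = starts + probe_len - 1L, Pu = pu)
  attr(out, "window") <- window
  attr(out, "max_span") <- max_span
  attr(out, "probe_len") <- probe_len
  class(out) <- c("unpaired_profile", "data.frame")
  out
}

#' Opening energy of a site
#'
#' The free-energy cost of making a site single-stranded,
#' `ED = -RT * log(Pu)`. `Pu = 0` marks the site as unusable (`Inf`).
#'
#' @param pu unpaired probability in `[0, 1]`.
#' @param model an [energy_model()] (supplies RT).
#' @return opening energy in kcal/mol (`>= 0`; `Inf` for `pu = 0`).
#' @examples
#' opening_energy(1)            # 0
#' opening_energy(0.5)          # RT * log(2) ~ 0.4272 at 310.15 K
#' @export
opening_energy <- function(pu, model = energy_model()) {
  if (any(pu < 0 | pu > 1)) stop("Pu must lie in [0, 1]")
  ifelse(pu == 0, Inf, -model$RT * log(pu))
}
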