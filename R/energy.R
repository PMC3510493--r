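#' @useDynLib srnascreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")
BASES <- c("A", "C", "G", "U")

#' Thermodynamic energy model for folding and hybridization
#'
#' Defines the self-contained nearest-neighbour parameterization used by all
#' folding and hybridization routines: a symmetric stacking table over the six
#' canonical pair types (AU, UA, GC, CG, GU, UG), affine hairpin, interior and
#' bulge loop penalties, a duplex initiation penalty, and the thermodynamic
#' temperature. Multiloops and exterior-loop bases carry no energy. Hairpin
#' loops shorter than `min_hairpin` nucleotides are structurally forbidden
#' (equivalent to an infinite penalty).
#'
#' The default stacking energy of two adjacent pairs is
#' `-(strength(p1) + strength(p2)) / 2` with per-pair-type strengths
#' `GC = CG = 3.3`, `AU = UA = 2.2`, `GU = UG = 1.1` kcal/mol, giving
#' stacks between -1.1 and -3.3 kcal/mol, the magnitude range of measured
#' nearest-neighbour stacks. All parameters can be overridden, e.g. to build
#' the zero-energy model used for combinatorial checks.
#'
#' @param temperature temperature in Kelvin (default 310.15, i.e. 37 C).
#' @param stack 6x6 numeric stacking matrix (kcal/mol) in pair-type order
#'   AU, UA, GC, CG, GU, UG; `stack[p, q]` is the energy of pair `q` stacked
#'   directly inside pair `p`. Default derived from `pair_strength`.
#' @param pair_strength named numeric vector of per-pair-type strengths used
#'   to build the default stacking table.
#' @param hairpin_init,hairpin_slope affine hairpin penalty
#'   `hairpin_init + hairpin_slope * (size - min_hairpin)` (kcal/mol).
#' @param interior_init,interior_slope affine interior-loop penalty
#'   `interior_init + interior_slope * (s1 + s2)`.
#' @param bulge_init,bulge_slope affine bulge penalty
#'   `bulge_init + bulge_slope * (size - 1)`.
#' @param duplex_init intermolecular duplex initiation penalty (kcal/mol).
#' @param min_hairpin minimum number of unpaired nt in a hairpin loop.
#' @param max_bulge maximum unpaired nt per side in a duplex interior/bulge
#'   loop (intramolecular loops are unbounded).
#' @return an object of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$RT # 0.0019872 * 310.15
#' zero <- energy_model(stack = matrix(0, 6, 6), hairpin_init = 0,
#'                      hairpin_slope = 0, interior_init = 0,
#'                      interior_slope = 0, bulge_init = 0, bulge_slope = 0,
#'                      duplex_init = 0)
#' @export
energy_model <- function(temperature = 310.15,
                         stack = NULL,
                         pair_strength = c(AU = 2.2, UA = 2.2, GC = 3.3,
                                           CG = 3.3, GU = 1.1, UG = 1.1),
                         hairpin_init = 5.0, hairpin_slope = 0.3,
                         interior_init = 1.8, interior_slope = 0.4,
                         bulge_init = 3.2, bulge_slope = 0.4,
                         duplex_init = 4.1,
                         min_hairpin = 3L,
                         max_bulge = 10L) {
  stopifnot(temperature > 0, min_hairpin >= 0, max_bulge >= 0)
  if (is.null(stack)) {
    ps <- pair_strength[PAIR_TYPES]
    stack <- -outer(ps, ps, function(a, b) (a + b) / 2)
  }
  stack <- as.matrix(stack)
  stopifnot(identical(dim(stack), c(6L, 6L)))
  dimnames(stack) <- list(PAIR_TYPES, PAIR_TYPES)
  if (any(stack > 0))
    stop("stacking energies must be <= 0 for canonical stacks")
  m <- list(temperature = temperature,
            RT = 0.0019872 * temperature,
            stack = stack,
            hairpin_init = hairpin_init, hairpin_slope = hairpin_slope,
            interior_init = interior_init, interior_slope = interior_slope,
            bulge_init = bulge_init, bulge_slope = bulge_slope,
            duplex_init = duplex_init,
            min_hairpin = as.integer(min_hairpin),
            max_bulge = as.integer(max_bulge))
  class(m) <- "energy_model"
  m
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> T =", x$temperature, "K, RT =",
      format(x$RT, digits = 5), "kcal/mol\n")
  cat("  stack range [", min(x$stack), ",", max(x$stack),
      "] kcal/mol; hairpin", x$hairpin_init, "+", x$hairpin_slope,
      "/nt; duplex_init", x$duplex_init, "\n")
  invisible(x)
}

# -- internal helpers ---------------------------------------------------------

# encode an RNA string as integers A=0, C=1, G=2, U=3
encode_rna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  i <- match(v, BASES) - 1L
  if (anyNA(i))
    stop("non-ACGU character in sequence: ",
         paste(unique(v[is.na(i)]), collapse = ", "))
  i
}

pair_type <- function(x, y) {
  pt <- paste0(x, y)
  ifelse(pt %in% PAIR_TYPES, pt, NA_character_)
}

# stacking energy of pair `inner` directly inside pair `outer`
stack_energy <- function(model, outer, inner) model$stack[outer, inner]

# interior/bulge loop penalty with s1, s2 unpaired nt on the two sides
loop_penalty <- function(model, s1, s2) {
  stopifnot(s1 >= 0, s2 >= 0, s1 + s2 > 0)
  if (s1 == 0 || s2 == 0)
    model$bulge_init + model$bulge_slope * (s1 + s2 - 1)
  else
    model$interior_init + model$interior_slope * (s1 + s2)
}

hairpin_penalty <- function(model, size) {
  if (size < model$min_hairpin) return(Inf)
  model$hairpin_init + model$hairpin_slope * (size - model$min_hairpin)
}
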