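# shared fixtures: models, random sequences, fabricated sites

model_default <- energy_model()

# zero-energy model: every legal structure equiprobable
model_zero <- energy_model(stack = matrix(0, 6, 6), hairpin_init = 0,
                           hairpin_slope = 0, interior_init = 0,
                           interior_slope = 0, bulge_init = 0,
                           bulge_slope = 0, duplex_init = 0)

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                       replace = TRUE), collapse = "")

# a minimal interaction-site stand-in for positional-filter tests
fake_site <- function(rel, mrna = NULL, pairing = NULL, E_total = -10) {
  s <- list(mrna_rel = as.integer(rel),
            mrna_interval = if (is.null(mrna)) as.integer(abs(rel))
                            else as.integer(mrna),
            srna_interval = c(1L, 2L),
            pairing = pairing, E_hybrid = E_total, ED_srna = 0, ED_mrna = 0,
            E_total = E_total, unusable = FALSE)
  class(s) <- "interaction_site"
  s
}

rc <- function(x) chartr("ACGU", "UGCA",
                         paste(rev(strsplit(x, "")[[1]]), collapse = ""))

norm_pairing <- function(m) {
  m <- unname(as.matrix(m))
  storage.mode(m) <- "integer"
  m
}
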