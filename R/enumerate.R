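# Brute-force enumeration references. These are deliberately independent of
# the dynamic-programming engines: structures and duplexes are generated
# explicitly and scored by direct loop decomposition, so they can serve as
# exhaustive oracles for the recursions on small inputs.

#' Enumerate all legal secondary structures of a short sequence
#'
#' Explicitly generates every nested secondary structure (as a matrix of pair
#' coordinates) under the same structural conventions as
#' [partition_function()]: canonical pairs, minimum hairpin loop, optional
#' span limit and forced-unpaired constraint. Intended as an exhaustive
#' reference for sequences of up to ~20 nt; the number of structures grows
#' quickly beyond that.
#'
#' @inheritParams partition_function
#' @return a list of integer matrices with columns `i`, `j` (the empty
#'   structure is the 0-row matrix).
#' @export
enumerate_structures <- function(seq, model = energy_model(), max_span = Inf,
                                 constraint = integer(0)) {
  enc <- encode_rna(seq)
  n <- length(enc)
  forced <- logical(n)
  forced[constraint] <- TRUE
  mh <- model$min_hairpin
  can <- function(i, j) {
    if (forced[i] || forced[j]) return(FALSE)
    if (j - i - 1 < mh || j - i + 1 > max_span) return(FALSE)
    !is.na(pair_type(BASES[enc[i] + 1], BASES[enc[j] + 1]))
  }
  memo <- new.env(parent = emptyenv())
  gen <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- gen(i + 1L, j) # i unpaired
    for (k in seq.int(i + mh + 1L, j, length.out = max(0L, j - i - mh))) {
      if (!can(i, k)) next
      inner <- gen(i + 1L, k - 1L)
      after <- gen(k + 1L, j)
      for (a in inner) for (b in after)
        out[[length(out) + 1L]] <- rbind(cbind(i, k), a, b)
    }
    memo[[key]] <- out
    out
  }
  structs <- gen(1L, n)
  lapply(structs, function(m) {
    m <- matrix(as.integer(m), ncol = 2)
    colnames(m) <- c("i", "j")
    m[order(m[, 1]), , drop = FALSE]
  })
}

#' Energy of an explicit secondary structure
#'
#' Scores a structure (pair list) by direct loop decomposition: each pair
#' closes exactly one loop, scored as a hairpin, a stack, an interior/bulge
#' loop, or a (free) multiloop; exterior bases are free.
#'
#' @param seq RNA sequence.
#' @param pairs integer matrix with columns `i`, `j` (1-based positions).
#' @param model an [energy_model()].
#' @return energy in kcal/mol.
#' @export
structure_energy <- function(seq, pairs, model = energy_model()) {
  if (nrow(pairs) == 0) return(0)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  ptype <- function(i, j) {
    pt <- pair_type(v[i], v[j])
    if (is.na(pt)) stop("non-canonical pair ", v[i], "-", v[j])
    pt
  }
  e <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    # direct children: pairs inside (i,j) not nested in another inside pair
    ins <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    if (nrow(ins) > 0) {
      top <- vapply(seq_len(nrow(ins)), function(q) {
        !any(ins[, 1] < ins[q, 1] & ins[, 2] > ins[q, 2])
      }, logical(1))
      ins <- ins[top, , drop = FALSE]
    }
    if (nrow(ins) == 0) {
      e <- e + hairpin_penalty(model, j - i - 1)
    } else if (nrow(ins) == 1) {
      k <- ins[1, 1]; l <- ins[1, 2]
      if (k == i + 1 && l == j - 1)
        e <- e + stack_energy(model, ptype(i, j), ptype(k, l))
      else
        e <- e + loop_penalty(model, k - i - 1, j - l - 1)
    } # multiloop: free
  }
  e
}

#' Exhaustive ensemble summary for a short sequence
#'
#' Enumerates all structures, scores each with [structure_energy()], and
#' returns the Boltzmann sum `Z`, the pair-probability matrix, and a function
#' `pu(interval)` giving exact unpaired probabilities. This is the
#' enumeration oracle for [partition_function()] and
#' [unpaired_probability()].
#'
#' @inheritParams enumerate_structures
#' @return a list with elements `Z`, `pair_prob`, `pu` (a function of
#'   `c(start, end)`), and `n_structures`.
#' @export
brute_ensemble <- function(seq, model = energy_model(), max_span = Inf,
                           constraint = integer(0)) {
  structs <- enumerate_structures(seq, model, max_span, constraint)
  n <- nchar(seq)
  w <- vapply(structs, function(s)
    exp(-structure_energy(seq, s, model) / model$RT), numeric(1))
  Z <- sum(w)
  bp <- matrix(0, n, n)
  paired <- matrix(FALSE, length(structs), n)
  for (q in seq_along(structs)) {
    s <- structs[[q]]
    if (nrow(s)) {
      bp[s] <- bp[s] + w[q]
      paired[q, c(s[, 1], s[, 2])] <- TRUE
    }
  }
  bp <- (bp + t(bp)) / Z
  pu <- function(interval) {
    if (interval[2] < interval[1]) return(1)
    idx <- seq.int(interval[1], interval[2])
    sum(w[!apply(paired[, idx, drop = FALSE], 1, any)]) / Z
  }
  list(Z = Z, pair_prob = bp, pu = pu, n_structures = length(structs))
}

# -- duplex oracle ------------------------------------------------------------

# Energy of one inter-pair step of a duplex: stack if adjacent, else
# interior/bulge penalty; gaps above the duplex loop cap are illegal (NA).
duplex_step_energy <- function(model, p_from, p_to, ga, gb) {
  if (ga == 0 && gb == 0) return(stack_energy(model, p_from, p_to))
  if (ga > model$max_bulge || gb > model$max_bulge) return(NA_real_)
  loop_penalty(model, ga, gb)
}

#' Exhaustive search for the optimal seeded duplex
#'
#' Brute-force reference for [hybridize()]: every duplex containing a run of
#' `seed_len` consecutive (stacked) pairs is generated by anchoring each
#' possible seed placement and exhaustively enumerating all left and right
#' chain extensions (stacks and loops within the bulge cap). Returns the
#' minimum hybridization energy and every co-optimal duplex.
#'
#' Practical for sequences up to ~15 nt each.
#'
#' @param s1,s2 RNA sequences (both 5'->3').
#' @param model an [energy_model()].
#' @param seed_len required number of consecutive base pairs.
#' @param seed_gu if `FALSE`, GU/UG pairs do not count towards the seed run.
#' @return `NULL` if no seeded duplex with negative energy exists, else a
#'   list with `E` and `sites` (a list of pairing matrices with columns
#'   `pos1`, `pos2`).
#' @export
enumerate_duplex_optimum <- function(s1, s2, model = energy_model(),
                                     seed_len = 8L, seed_gu = TRUE) {
  seed_len <- as.integer(seed_len)
  v1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  v2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  m <- length(v1); n <- length(v2)
  pt <- matrix(NA_character_, m, n)
  for (i in seq_len(m)) for (j in seq_len(n))
    pt[i, j] <- pair_type(v1[i], v2[j])
  elig <- !is.na(pt) & (seed_gu | !(pt %in% c("GU", "UG")))
  mb <- model$max_bulge

  # all chains ending at (i,j), moving left/up-right: list of (denergy, pairs)
  chains_left <- function(i, j) {
    out <- list(list(e = 0, p = cbind(i, j)))
    for (k in rev(seq_len(i - 1L))) {
      if (i - k - 1L > mb) break
      for (l in seq.int(j + 1L, length.out = min(n - j, mb + 1L))) {
        if (is.na(pt[k, l])) next
        st <- duplex_step_energy(model, pt[k, l], pt[i, j],
                                 i - k - 1L, l - j - 1L)
        if (is.na(st)) next
        for (ch in chains_left(k, l))
          out[[length(out) + 1L]] <- list(e = ch$e + st,
                                          p = rbind(ch$p, cbind(i, j)))
      }
    }
    out
  }
  chains_right <- function(i, j) {
    out <- list(list(e = 0, p = cbind(i, j)))
    for (k in seq.int(i + 1L, length.out = min(m - i, mb + 1L))) {
      for (l in rev(seq_len(j - 1L))) {
        if (j - l - 1L > mb) break
        if (is.na(pt[k, l])) next
        st <- duplex_step_energy(model, pt[i, j], pt[k, l],
                                 k - i - 1L, j - l - 1L)
        if (is.na(st)) next
        for (ch in chains_right(k, l))
          out[[length(out) + 1L]] <- list(e = ch$e + st,
                                          p = rbind(cbind(i, j), ch$p))
      }
    }
    out
  }

  best <- Inf
  sites <- list()
  for (i in seq_len(max(0L, m - seed_len + 1L))) {
    for (j in seq_len(n)) {
      if (j < seed_len) next
      tt <- seq_len(seed_len) - 1L
      if (!all(elig[cbind(i + tt, j - tt)])) next
      anchor <- cbind(i + tt, j - tt)
      eanchor <- sum(vapply(seq_len(seed_len - 1L), function(t)
        stack_energy(model, pt[anchor[t, 1], anchor[t, 2]],
                     pt[anchor[t + 1, 1], anchor[t + 1, 2]]), numeric(1)))
      lefts <- chains_left(i, j)
      rights <- chains_right(i + seed_len - 1L, j - seed_len + 1L)
      for (L in lefts) for (R in rights) {
        e <- model$duplex_init + eanchor + L$e + R$e
        if (e > best + 1e-12) next
        p <- unique(rbind(L$p, anchor, R$p))
        p <- p[order(p[, 1]), , drop = FALSE]
        colnames(p) <- c("pos1", "pos2")
        if (e < best - 1e-12) {
          best <- e
          sites <- list(p)
        } else if (!any(vapply(sites, identical, logical(1), y = p))) {
          sites[[length(sites) + 1L]] <- p
        }
      }
    }
  }
  if (!is.finite(best) || best >= 0) return(NULL)
  list(E = best, sites = sites)
}
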