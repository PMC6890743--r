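#' Minimum free energy secondary structure
#'
#' Zuker-style dynamic program over the stacking energy model, restricted to
#' nested structures with hairpin loops of at least
#' `model$min_hairpin_loop` unpaired nucleotides. Traceback is deterministic:
#' on ties the paired branch wins, pairs with smaller 5' index are chosen
#' first, and stacked continuations are preferred.
#'
#' @param sequence RNA sequence over A/C/G/U (T accepted and converted)
#' @param model an [energy_model()]
#' @return object of class `rna_structure`: list with `sequence`,
#'   `dot_bracket`, `partner` (1-based partner index or NA), `pairs`
#'   (two-column matrix, 5' index first), and `mfe`
#' @export
fold_mfe <- function(sequence, model = default_energy_model()) {
  sequence <- as_rna(sequence, allow_n = FALSE)
  n <- nchar(sequence)
  if (n < 1) stop("empty sequence")
  res <- cpp_fold_mfe(seq_to_int(sequence), model$stack,
                      model$min_hairpin_loop)
  partner <- res$partner + 1L
  partner[partner == 0L] <- NA_integer_
  new_structure(sequence, partner, res$energy)
}

new_structure <- function(sequence, partner, mfe) {
  n <- nchar(sequence)
  db <- rep(".", n)
  paired <- which(!is.na(partner))
  db[paired[partner[paired] > paired]] <- "("
  db[paired[partner[paired] < paired]] <- ")"
  i <- which(!is.na(partner) & partner > seq_len(n))
  structure(list(sequence = sequence,
                 dot_bracket = paste(db, collapse = ""),
                 partner = partner,
                 pairs = cbind(i = i, j = partner[i]),
                 mfe = mfe),
            class = "rna_structure")
}

#' @export
print.rna_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$dot_bracket, " (", sprintf("%.2f", x$mfe), ")\n",
      sep = "")
  invisible(x)
}

#' Parse a dot-bracket string into a partner vector
#' @param db dot-bracket string (round brackets, no pseudoknots)
#' @return 1-based partner vector with NA for unpaired positions
#' @export
dot_bracket_partners <- function(db) {
  s <- seq_chars(db)
  n <- length(s)
  partner <- rep(NA_integer_, n)
  open <- integer(0)
  for (k in seq_len(n)) {
    if (s[k] == "(") open <- c(open, k)
    else if (s[k] == ")") {
      if (length(open) == 0) stop("unbalanced brackets at position ", k)
      i <- open[length(open)]
      open <- open[-length(open)]
      partner[i] <- k
      partner[k] <- i
    } else if (s[k] != ".") stop("invalid dot-bracket character: ", s[k])
  }
  if (length(open) > 0) stop("unbalanced brackets: unmatched '('")
  partner
}

# energy of an explicit structure (partner vector) under the stacking model
structure_energy <- function(sequence, partner, model = default_energy_model()) {
  s <- seq_chars(sequence)
  i <- which(!is.na(partner) & partner > seq_along(partner))
  if (length(i) == 0) return(0)
  j <- partner[i]
  e <- 0
  for (k in seq_along(i)) {
    ii <- i[k]; jj <- j[k]
    # stack with directly nested pair (ii+1, jj-1)
    if (!is.na(partner[ii + 1]) && partner[ii + 1] == jj - 1 && ii + 1 < jj - 1) {
      e <- e + model$stack[pair_type_chr(s[ii], s[jj]),
                           pair_type_chr(s[ii + 1], s[jj - 1])]
    }
  }
  e
}

#' Exhaustively enumerate nested secondary structures
#'
#' Complete enumeration of loop-constrained nested structures, used as the
#' ground-truth oracle for [fold_mfe()] and [partition_function()]. Intended
#' for short sequences only.
#'
#' @param sequence RNA sequence
#' @param model an [energy_model()]
#' @param max_len refuse sequences longer than this
#' @return list with `partners` (list of partner vectors), `energies`, and
#'   `dot_brackets`
#' @export
enumerate_structures <- function(sequence, model = default_energy_model(),
                                 max_len = 22L) {
  sequence <- as_rna(sequence, allow_n = FALSE)
  n <- nchar(sequence)
  if (n > max_len) stop("sequence longer than enumeration cap (", max_len, ")")
  s <- seq_chars(sequence)
  min_loop <- model$min_hairpin_loop
  memo <- new.env(parent = emptyenv())
  # returns list of pair matrices (each a 2-col matrix) for region [i, j]
  enum <- function(i, j) {
    if (j - i + 1 < min_loop + 2) return(list(cbind(i = integer(0), j = integer(0))))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- enum(i, j - 1)                      # j unpaired
    for (k in i:(j - min_loop - 1)) {
      if (!can_pair(s[k], s[j])) next
      left <- if (k - 1 >= i) enum(i, k - 1) else
        list(cbind(i = integer(0), j = integer(0)))
      inner <- enum(k + 1, j - 1)
      for (L in left) for (Io in inner) {
        out <- c(out, list(rbind(L, Io, cbind(i = k, j = j))))
      }
    }
    memo[[key]] <- out
    out
  }
  mats <- enum(1L, n)
  partners <- lapply(mats, function(m) {
    p <- rep(NA_integer_, n)
    if (nrow(m) > 0) { p[m[, 1]] <- m[, 2]; p[m[, 2]] <- m[, 1] }
    p
  })
  energies <- vapply(partners, structure_energy, numeric(1),
                     sequence = sequence, model = model)
  dbs <- vapply(partners, function(p) {
    db <- rep(".", n)
    db[!is.na(p) & p > seq_len(n)] <- "("
    db[!is.na(p) & p < seq_len(n)] <- ")"
    paste(db, collapse = "")
  }, character(1))
  list(partners = partners, energies = energies, dot_brackets = dbs)
}

#' Count nested structures by the region recursion
#'
#' Independent counter used to cross-check [enumerate_structures()]:
#' `N(i,j) = N(i,j-1) + sum_k N(i,k-1) * N(k+1,j-1)` over pairable `(k,j)`.
#'
#' @inheritParams enumerate_structures
#' @return structure count (double)
#' @export
count_structures <- function(sequence, model = default_energy_model()) {
  sequence <- as_rna(sequence, allow_n = FALSE)
  s <- seq_chars(sequence)
  n <- length(s)
  min_loop <- model$min_hairpin_loop
  N <- matrix(1, n + 1, n + 1) # N[i, j+1]; empty/short regions count 1
  get <- function(i, j) if (j < i) 1 else N[i, j + 1]
  for (len in seq_len(n)) {
    for (i in seq_len(n - len + 1)) {
      j <- i + len - 1
      if (len < min_loop + 2) { N[i, j + 1] <- 1; next }
      tot <- get(i, j - 1)
      for (k in i:(j - min_loop - 1)) {
        if (can_pair(s[k], s[j])) tot <- tot + get(i, k - 1) * get(k + 1, j - 1)
      }
      N[i, j + 1] <- tot
    }
  }
  get(1, n)
}

#' Boltzmann ensemble statistics via the partition function
#'
#' McCaskill-style inside/outside dynamic program over the stacking model.
#' Returns the partition function `Z`, the base-pair probability matrix, and
#' the ensemble indices used by the pre-miRNA screen: normalized Shannon
#' entropy `NQ = -(1/L) * sum_{i<j} p_ij log2 p_ij` and normalized base-pair
#' distance `ND = (1/L) * sum_{i<j} p_ij (1 - p_ij)`.
#'
#' @param sequence RNA sequence
#' @param model an [energy_model()]
#' @param kT Boltzmann scale; defaults to the model's
#' @return object of class `rna_ensemble`: list with `Z`, `p` (L x L
#'   symmetric matrix), `NQ`, `ND`
#' @export
partition_function <- function(sequence, model = default_energy_model(),
                               kT = model$kT) {
  sequence <- as_rna(sequence, allow_n = FALSE)
  n <- nchar(sequence)
  if (n < 1) stop("empty sequence")
  if (n > 2000) stop("sequence too long for the partition function engine")
  res <- cpp_partition(seq_to_int(sequence), model$stack, kT,
                       model$min_hairpin_loop)
  stats <- ensemble_stats_from_p(res$p)
  structure(list(sequence = sequence, Z = res$Z, p = res$p,
                 NQ = stats["NQ"], ND = stats["ND"]),
            class = "rna_ensemble")
}

# NQ/ND from an upper-triangular pair probability matrix
ensemble_stats_from_p <- function(p) {
  L <- nrow(p)
  up <- p[upper.tri(p)]
  up <- up[up > 0]
  nq <- if (length(up)) -sum(up * log2(up)) / L else 0
  nd <- if (length(up)) sum(up * (1 - up)) / L else 0
  c(NQ = nq, ND = nd)
}

#' Hairpin descriptor block
#'
#' Computes the length-normalized indices used by the pre-miRNA screen from
#' a folded structure: `AMFE = (|MFE| / L) * 100`, `MFEI = AMFE / GC%` (GC
#' expressed in percent), and `Npb` = base pairs in the MFE structure / L.
#' The SSR signature score `R` is computed separately by
#' [ssr_signature_score()] and can be attached by callers.
#'
#' @param struct an `rna_structure` from [fold_mfe()]
#' @return data.frame with one row: `L`, `gc_pct`, `au_pct`, `AMFE`, `MFEI`,
#'   `Npb`, `mfe`, and `gc_zero` flag (MFEI undefined, candidate must be
#'   rejected)
#' @export
hairpin_descriptors <- function(struct) {
  stopifnot(inherits(struct, "rna_structure"))
  L <- nchar(struct$sequence)
  comp <- base_composition(struct$sequence)
  gc_pct <- 100 * comp["gc"]
  amfe <- abs(struct$mfe) / L * 100
  gc_zero <- gc_pct == 0
  mfei <- if (gc_zero) NA_real_ else amfe / gc_pct
  npb <- nrow(struct$pairs) / L
  data.frame(L = L, gc_pct = unname(gc_pct), au_pct = unname(100 * comp["au"]),
             AMFE = amfe, MFEI = mfei, Npb = npb, mfe = struct$mfe,
             gc_zero = gc_zero)
}

#' Intermolecular duplex energy
#'
#' Minimum-energy antiparallel hybridization of two RNAs (no intramolecular
#' pairs), in the spirit of RNAplex: stacks score the model's table, interior
#' loops and bulges pay `duplex_loop_cost` per unpaired nucleotide, with at
#' most `duplex_max_loop` unpaired per strand between consecutive pairs. An
#' energy of 0 means no stabilizing duplex exists.
#'
#' @param seq_a,seq_b RNA sequences, both 5'->3'
#' @param model an [energy_model()]
#' @return list with `energy` and `alignment` (data.frame of paired
#'   positions `a_pos`, `b_pos`, 1-based)
#' @export
duplex_score <- function(seq_a, seq_b, model = default_energy_model()) {
  seq_a <- as_rna(seq_a, allow_n = FALSE)
  seq_b <- as_rna(seq_b, allow_n = FALSE)
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) stop("empty sequence")
  res <- cpp_duplex(seq_to_int(seq_a), seq_to_int(seq_b), model$stack,
                    model$duplex_loop_cost, model$duplex_max_loop)
  aln <- data.frame(a_pos = res$a_pos, b_pos = res$b_pos)
  if (res$energy >= 0) aln <- aln[0, ]
  list(energy = min(res$energy, 0), alignment = aln)
}

# brute-force duplex oracle: enumerate all monotone pairings under the same
# loop-size cap; exponential, short inputs only
duplex_bruteforce <- function(seq_a, seq_b, model = default_energy_model(),
                              max_len = 12L) {
  a <- seq_chars(as_rna(seq_a, allow_n = FALSE))
  b <- seq_chars(as_rna(seq_b, allow_n = FALSE))
  if (length(a) > max_len || length(b) > max_len) {
    stop("input above brute-force cap")
  }
  best <- 0
  recurse <- function(i, j, last_i, last_j, acc) {
    # try extending with a pair (i', j') with i' >= i, j' <= j
    for (ii in i:length(a)) {
      if (ii > length(a)) break
      for (jj in rev(seq_len(j))) {
        if (!can_pair(a[ii], b[jj])) next
        if (last_i > 0) {
          di <- ii - last_i - 1
          dj <- last_j - jj - 1
          if (di > model$duplex_max_loop || dj > model$duplex_max_loop) next
          cost <- if (di == 0 && dj == 0) {
            model$stack[pair_type_chr(a[last_i], b[last_j]),
                        pair_type_chr(a[ii], b[jj])]
          } else model$duplex_loop_cost * (di + dj)
          e <- acc + cost
        } else e <- 0
        if (e < best) best <<- e
        if (ii < length(a) && jj > 1) recurse(ii + 1, jj - 1, ii, jj, e)
      }
    }
  }
  recurse(1, length(b), 0L, 0L, 0)
  best
}
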