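PAIR_NAMES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Simplified nearest-neighbour RNA energy model
#'
#' The engine scores a nested secondary structure as the sum of stacking
#' terms over adjacent base pairs (i,j)/(i+1,j-1); isolated pairs contribute
#' nothing, so the empty structure has energy zero and every minimum free
#' energy is non-positive. Stack energies are derived from per-pair bond
#' strengths (GC > AU > GU) as `-(s_outer + s_inner)/2`, which makes the
#' table symmetric under duplex reversal by construction. Units are model
#' units on a kcal/mol-like scale; all published thresholds used by the
#' hairpin filters (MFEI and friends) are length- and composition-normalized
#' indices, not raw energies.
#'
#' @param pair_strength named numeric: stabilizing strength of AU, GC and GU
#'   pairs (positive; larger = more stable)
#' @param min_hairpin_loop minimum unpaired nucleotides closed by a pair
#' @param kT Boltzmann temperature scale used by the partition function
#' @param duplex_loop_cost destabilization per unpaired nucleotide inside an
#'   intermolecular interior loop or bulge
#' @param duplex_max_loop maximum unpaired nucleotides per strand between
#'   consecutive intermolecular pairs
#' @return an object of class `rna_energy_model`
#' @export
energy_model <- function(pair_strength = c(AU = 1.2, GC = 2.0, GU = 0.6),
                         min_hairpin_loop = 3L,
                         kT = 0.6,
                         duplex_loop_cost = 1.0,
                         duplex_max_loop = 10L) {
  stopifnot(all(c("AU", "GC", "GU") %in% names(pair_strength)),
            all(pair_strength > 0), min_hairpin_loop >= 0, kT > 0)
  s <- c(AU = unname(pair_strength["AU"]), UA = unname(pair_strength["AU"]),
         GC = unname(pair_strength["GC"]), CG = unname(pair_strength["GC"]),
         GU = unname(pair_strength["GU"]), UG = unname(pair_strength["GU"]))
  stack <- -outer(s, s, function(a, b) (a + b) / 2)
  dimnames(stack) <- list(PAIR_NAMES, PAIR_NAMES)
  structure(list(stack = stack,
                 pair_strength = s,
                 min_hairpin_loop = as.integer(min_hairpin_loop),
                 kT = kT,
                 duplex_loop_cost = duplex_loop_cost,
                 duplex_max_loop = as.integer(duplex_max_loop)),
            class = "rna_energy_model")
}

#' @export
print.rna_energy_model <- function(x, ...) {
  cat("RNA energy model (stacking-only nearest neighbour)\n")
  cat("  pair strengths:",
      paste(sprintf("%s=%.2f", c("AU", "GC", "GU"),
                    x$pair_strength[c("AU", "GC", "GU")]), collapse = " "),
      "\n")
  cat("  min hairpin loop:", x$min_hairpin_loop, "  kT:", x$kT, "\n")
  invisible(x)
}

default_energy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- energy_model()
    cache
  }
})

# pair type of two encoded bases (1..6 as in PAIR_NAMES, 0 if unpairable)
pair_type_chr <- function(a, b) {
  match(paste0(a, b), PAIR_NAMES, nomatch = 0L)
}

can_pair <- function(a, b) pair_type_chr(a, b) > 0L

# stacking energy for outer pair name on inner pair name
stack_energy <- function(model, outer, inner) model$stack[outer, inner]
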