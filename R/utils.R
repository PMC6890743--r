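#' @useDynLib lncmir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor rnorm runif rlnorm setNames p.adjust poisson.test sd
#' @importFrom utils write.table read.table head
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide sequence to RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside A/C/G/U/N raise an
#' error.
#'
#' @param x character scalar or vector of sequences
#' @param allow_n allow ambiguous N characters
#' @return normalized character vector
#' @export
as_rna <- function(x, allow_n = TRUE) {
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  ok_chars <- if (allow_n) "ACGUN" else "ACGU"
  bad <- grepl(sprintf("[^%s]", ok_chars), x)
  if (any(bad)) {
    stop("sequence contains characters outside {", ok_chars, "}: ",
         substr(x[bad][1], 1, 40))
  }
  x
}

#' Reverse complement of an RNA sequence
#' @param x RNA sequence (character scalar or vector)
#' @return reverse complement, RNA alphabet
#' @export
revcomp_rna <- function(x) {
  x <- as_rna(x)
  vapply(x, function(s) {
    chartr("ACGUN", "UGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

complement_rna <- function(x) chartr("ACGUN", "UGCAN", as_rna(x))

# integer encoding used by the C++ kernels: A=0, C=1, G=2, U=3
seq_to_int <- function(x) {
  s <- strsplit(as_rna(x, allow_n = FALSE), "")[[1]]
  match(s, RNA_BASES) - 1L
}

seq_chars <- function(x) strsplit(x, "")[[1]]

#' Base composition fractions
#'
#' @param x sequence (DNA or RNA alphabet)
#' @return named vector with `gc` and `au` fractions (N excluded from the
#'   denominator)
#' @export
base_composition <- function(x) {
  s <- seq_chars(as_rna(x))
  s <- s[s != "N"]
  n <- length(s)
  if (n == 0) return(c(gc = NA_real_, au = NA_real_))
  gc <- sum(s %in% c("G", "C")) / n
  c(gc = gc, au = 1 - gc)
}

# mononucleotide shuffle preserving composition
shuffle_sequence <- function(x, rng = NULL) {
  s <- seq_chars(x)
  paste(sample(s), collapse = "")
}

random_rna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(RNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# WC/GU classification of one RNA base pair (5' base, 3' base)
pair_state <- function(a, b) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
  gu <- (a == "G" & b == "U") | (a == "U" & b == "G")
  ifelse(wc, "WC", ifelse(gu, "GU", "mismatch"))
}

stopifnot_scalar <- function(x, what) {
  if (length(x) != 1 || is.na(x)) stop(what, " must be a non-missing scalar")
  invisible(x)
}

# stable hash of an R object via its canonical JSON serialization
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null"), f)
  unname(tools::md5sum(f))
}
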