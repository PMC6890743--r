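#' Longest open reading frame in the forward frames
#'
#' Scans the three forward reading frames for AUG...stop spans and returns
#' the longest ORF in amino acids (stop codon excluded). ORFs without an
#' in-frame stop codon inside the sequence are not counted. `orf_coverage`
#' is the fraction of the transcript covered by the longest ORF including
#' its stop codon.
#'
#' @param sequence nucleotide sequence over A/C/G/U/T/N
#' @return list with `longest_orf_aa` and `orf_coverage`
#' @export
longest_orf <- function(sequence) {
  sequence <- as_rna(sequence)
  L <- nchar(sequence)
  if (L == 0) stop("empty sequence")
  stops <- c("UAA", "UAG", "UGA")
  best_aa <- 0L
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3
    if (n_codon < 2) next
    starts_nt <- frame + 3 * (seq_len(n_codon) - 1) + 1
    codons <- substring(sequence, starts_nt, starts_nt + 2)
    start_idx <- which(codons == "AUG")
    stop_idx <- which(codons %in% stops)
    if (length(start_idx) == 0 || length(stop_idx) == 0) next
    # for each start codon, the first stop at or after it
    nxt <- stop_idx[findInterval(start_idx, stop_idx) + 1L]
    ok <- !is.na(nxt)
    if (!any(ok)) next
    aa <- nxt[ok] - start_idx[ok]
    aa <- aa[aa > 0]
    if (length(aa)) best_aa <- max(best_aa, max(aa))
  }
  list(longest_orf_aa = best_aa,
       orf_coverage = if (best_aa > 0) (3 * best_aa + 3) / L else 0)
}

#' Train hexamer frequency tables for the coding-potential score
#'
#' Builds overlapping k-mer frequency tables (pseudocount 1 over the full
#' k-mer space) from a coding and a noncoding training set, e.g. the
#' labelled classes of a synthetic fixture or user-curated transcript sets.
#'
#' @param coding_seqs,noncoding_seqs character vectors of sequences
#' @param k k-mer size (default 6, hexamers)
#' @return list with `coding` and `noncoding` named frequency vectors and `k`
#' @export
train_hexamer_tables <- function(coding_seqs, noncoding_seqs, k = 6L) {
  count_kmers <- function(seqs) {
    kmers <- unlist(lapply(as_rna(seqs), function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      substring(s, 1:(n - k + 1), k:n)
    }))
    kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    table(kmers)
  }
  universe <- do.call(paste0, expand.grid(rep(list(RNA_BASES), k),
                                          stringsAsFactors = FALSE))
  freq_of <- function(tab) {
    counts <- setNames(rep(1, length(universe)), universe) # pseudocount
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    counts / sum(counts)
  }
  list(coding = freq_of(count_kmers(coding_seqs)),
       noncoding = freq_of(count_kmers(noncoding_seqs)),
       k = as.integer(k))
}

# mean per-hexamer log2 likelihood ratio (coding vs noncoding)
hexamer_llr <- function(sequence, tables) {
  s <- as_rna(sequence)
  k <- tables$k
  n <- nchar(s)
  if (n < k) stop("sequence shorter than ", k, " nt")
  kmers <- substring(s, 1:(n - k + 1), k:n)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0) return(0)
  mean(log2(tables$coding[kmers] / tables$noncoding[kmers]))
}

#' Internal coding-potential score
#'
#' CPAT-like stand-in for external coding-potential classifiers: a weighted
#' combination of the mean hexamer log-likelihood ratio (coding vs noncoding
#' usage) and the fraction of the transcript covered by its longest ORF.
#' Higher values are more coding-like; the lncRNA cascade keeps transcripts
#' scoring below its cutoff.
#'
#' @param sequence nucleotide sequence (>= 6 nt)
#' @param hexamer_tables output of [train_hexamer_tables()]
#' @param weights numeric weights `c(llr, coverage)`
#' @return data.frame with `longest_orf_aa`, `orf_coverage`, `hexamer_llr`,
#'   `combined_score`
#' @export
coding_potential_score <- function(sequence, hexamer_tables,
                                   weights = c(llr = 2, coverage = 1)) {
  orf <- longest_orf(sequence)
  llr <- hexamer_llr(sequence, hexamer_tables)
  data.frame(longest_orf_aa = orf$longest_orf_aa,
             orf_coverage = orf$orf_coverage,
             hexamer_llr = unname(llr),
             combined_score = unname(weights[1] * llr +
                                       weights[2] * orf$orf_coverage))
}

#' Default thresholds of the lncRNA filter cascade
#'
#' `min_length` 200 nt, `min_fpkm` 1 (strict >), `max_orf_aa` 99 (<100
#' amino acids), `coding_cutoff` 0 for the internal combined score (keep if
#' below), `external_coding_cutoff` -0.5 with keep-if-below semantics for
#' user-supplied classifier scores.
#'
#' @return named list of thresholds
#' @export
lncrna_thresholds <- function() {
  list(min_length = 200L, min_fpkm = 1, max_orf_aa = 99L,
       coding_cutoff = 0, external_coding_cutoff = -0.5)
}

CASCADE_STAGES <- c("length", "fpkm", "orf", "coding_score",
                    "protein_homology", "ncrna_family")

#' lncRNA candidate filter cascade
#'
#' Applies the lncRNA identification stages in order: length >= 200 nt,
#' FPKM > 1 in at least one sample, longest ORF < 100 aa, coding-potential
#' score below cutoff, absence from the protein-homology exclusion list,
#' absence from the housekeeping-ncRNA exclusion list. Each stage is a pure
#' predicate, so the surviving set does not depend on stage order; the
#' `first_fail` column records the first failing stage in the order above.
#'
#' @param transcripts named character vector of transcript sequences
#' @param expression numeric matrix, rows = transcript ids, columns = stages
#' @param exclusion_lists list with character vectors `protein_homology`
#'   and `ncrna_family` of transcript ids to remove
#' @param hexamer_tables from [train_hexamer_tables()]; required unless
#'   `coding_scores` supplied
#' @param coding_scores optional named numeric of externally computed
#'   coding-potential scores (CPC/CNCI-like); used instead of the internal
#'   score with the `external_coding_cutoff` keep-if-below rule
#' @param thresholds see [lncrna_thresholds()]
#' @return data.frame with one row per transcript: per-stage pass columns,
#'   `pass` (survivor flag) and `first_fail`
#' @export
filter_lncrna_candidates <- function(transcripts, expression,
                                     exclusion_lists = list(),
                                     hexamer_tables = NULL,
                                     coding_scores = NULL,
                                     thresholds = lncrna_thresholds()) {
  ids <- names(transcripts)
  if (is.null(ids)) stop("transcripts must be a named vector")
  missing_expr <- setdiff(ids, rownames(expression))
  if (length(missing_expr)) {
    stop("expression table missing transcript id(s): ",
         paste(head(missing_expr, 5), collapse = ", "))
  }
  len <- nchar(transcripts)
  max_fpkm <- apply(expression[ids, , drop = FALSE], 1, max)
  orf_aa <- vapply(transcripts, function(s) longest_orf(s)$longest_orf_aa,
                   numeric(1))
  if (!is.null(coding_scores)) {
    miss <- setdiff(ids, names(coding_scores))
    if (length(miss)) stop("coding_scores missing ids: ",
                           paste(head(miss, 5), collapse = ", "))
    score_pass <- coding_scores[ids] < thresholds$external_coding_cutoff
  } else {
    if (is.null(hexamer_tables)) {
      stop("supply hexamer_tables or coding_scores")
    }
    cps <- vapply(transcripts, function(s) {
      coding_potential_score(s, hexamer_tables)$combined_score
    }, numeric(1))
    score_pass <- cps < thresholds$coding_cutoff
  }
  prot <- exclusion_lists$protein_homology %||% character(0)
  ncr <- exclusion_lists$ncrna_family %||% character(0)

  stage_pass <- cbind(length = len >= thresholds$min_length,
                      fpkm = max_fpkm > thresholds$min_fpkm,
                      orf = orf_aa <= thresholds$max_orf_aa,
                      coding_score = unname(score_pass),
                      protein_homology = !(ids %in% prot),
                      ncrna_family = !(ids %in% ncr))
  first_fail <- apply(stage_pass, 1, function(p) {
    f <- which(!p)
    if (length(f)) CASCADE_STAGES[f[1]] else NA_character_
  })
  out <- data.frame(id = ids, stage_pass, pass = apply(stage_pass, 1, all),
                    first_fail = first_fail, row.names = NULL,
                    stringsAsFactors = FALSE)
  out$length_nt <- unname(len)
  out$max_fpkm <- unname(max_fpkm)
  out$longest_orf_aa <- unname(orf_aa)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

models_to_granges <- function(models) {
  GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(start = models$start, end = models$end),
    strand = ifelse(models$strand %in% c("+", "-"), models$strand, "*"),
    transcript_id = models$transcript_id,
    gene_id = if ("gene_id" %in% names(models)) models$gene_id
              else models$transcript_id)
}

transcript_spans <- function(models) {
  sp <- do.call(rbind, lapply(split(models, models$transcript_id), function(m) {
    data.frame(transcript_id = m$transcript_id[1], chrom = m$chrom[1],
               start = min(m$start), end = max(m$end),
               strand = m$strand[1], stringsAsFactors = FALSE)
  }))
  rownames(sp) <- NULL
  sp
}

#' Classify lncRNA candidates by genomic locus
#'
#' Assigns each candidate a positional class relative to a set of gene
#' models: `lncNAT` when a candidate exon overlaps a gene exon on the
#' opposite strand; `intragenic` when the candidate span lies within a gene
#' span on the same strand; `lincRNA` otherwise. Ties are broken in that
#' priority order. Candidates without strand information (".") cannot be
#' natural antisense calls; they are classified from position only and
#' flagged.
#'
#' @param candidate_models exon-level data.frame (`transcript_id`, `chrom`,
#'   `start`, `end`, `strand`; 1-based inclusive coordinates)
#' @param gene_models exon-level data.frame of protein-coding gene models
#'   with a `gene_id` column, same coordinate system
#' @return data.frame with `transcript_id`, `class`, `no_strand` flag
#' @export
classify_by_locus <- function(candidate_models, gene_models) {
  if (nrow(candidate_models) == 0) {
    return(data.frame(transcript_id = character(0), class = character(0),
                      no_strand = logical(0)))
  }
  if (any(is.na(candidate_models$start))) stop("candidate without coordinates")
  cand <- models_to_granges(candidate_models)
  gene <- models_to_granges(gene_models)
  gene_spans <- transcript_spans(gene_models)
  gene_spans$gene_id <- gene_models$gene_id[
    match(gene_spans$transcript_id, gene_models$transcript_id)]
  cand_spans <- transcript_spans(candidate_models)

  out <- lapply(seq_len(nrow(cand_spans)), function(i) {
    cs <- cand_spans[i, ]
    has_strand <- cs$strand %in% c("+", "-")
    cls <- "lincRNA"
    # lncNAT: exon overlap with a gene exon on the opposite strand
    if (has_strand) {
      ce <- cand[S4Vectors::mcols(cand)$transcript_id == cs$transcript_id]
      opp <- gene[as.character(GenomicRanges::strand(gene)) !=
                    cs$strand &
                  as.character(GenomicRanges::strand(gene)) %in% c("+", "-")]
      if (length(opp) &&
          length(GenomicRanges::findOverlaps(ce, opp,
                                             ignore.strand = TRUE)) > 0) {
        cls <- "lncNAT"
      }
    }
    if (cls == "lincRNA") {
      same <- gene_spans[gene_spans$chrom == cs$chrom &
                           (!has_strand | gene_spans$strand == cs$strand), ]
      inside <- same$start <= cs$start & same$end >= cs$end
      if (any(inside)) cls <- "intragenic"
    }
    data.frame(transcript_id = cs$transcript_id, class = cls,
               no_strand = !has_strand, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Summary statistics of an lncRNA set
#'
#' Length histogram (200-1000 first bin, then 1 kb bins), exon-count
#' distribution, AU/GC composition compared to a coding reference set, and
#' per-chromosome counts.
#'
#' @param sequences named character vector of lncRNA sequences
#' @param models exon-level data.frame for the same transcripts (optional;
#'   enables exon and chromosome summaries)
#' @param coding_reference optional character vector of coding sequences for
#'   the composition comparison
#' @return list of summary data.frames
#' @export
summarize_lncrna_features <- function(sequences, models = NULL,
                                      coding_reference = NULL) {
  if (length(sequences) == 0) stop("empty input")
  len <- nchar(sequences)
  breaks <- c(0, 200, 1000, 2000, 3000, 4000, 5000, Inf)
  lens <- data.frame(bin = cut(len, breaks = breaks, right = FALSE),
                     stringsAsFactors = FALSE)
  length_hist <- as.data.frame(table(bin = lens$bin),
                               stringsAsFactors = FALSE)
  comp <- t(vapply(sequences, base_composition, numeric(2)))
  out <- list(
    n = length(sequences),
    mean_length = mean(len),
    length_hist = length_hist,
    composition = data.frame(set = "lncRNA",
                             mean_gc_pct = 100 * mean(comp[, "gc"]),
                             mean_au_pct = 100 * mean(comp[, "au"])))
  if (!is.null(coding_reference) && length(coding_reference)) {
    ccomp <- t(vapply(coding_reference, base_composition, numeric(2)))
    out$composition <- rbind(out$composition,
      data.frame(set = "coding", mean_gc_pct = 100 * mean(ccomp[, "gc"]),
                 mean_au_pct = 100 * mean(ccomp[, "au"])))
  }
  if (!is.null(models)) {
    keep <- models[models$transcript_id %in% names(sequences), ]
    exon_counts <- table(keep$transcript_id)
    out$exon_distribution <- as.data.frame(table(exons = as.integer(exon_counts)),
                                           stringsAsFactors = FALSE)
    spans <- transcript_spans(keep)
    out$per_chromosome <- as.data.frame(table(chrom = spans$chrom),
                                        stringsAsFactors = FALSE)
  }
  out
}
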