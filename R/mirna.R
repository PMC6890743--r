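#' Parse miRNA family labels from miRBase-style identifiers
#'
#' Accepts `family_memberID` headers or miRBase names like `ath-miR160a`;
#' falls back to the full identifier when no family pattern is found.
#'
#' @param ids character vector of mature identifiers
#' @return character vector of family labels
#' @export
parse_mirna_family <- function(ids) {
  fam <- ifelse(grepl("_", ids, fixed = TRUE), sub("_.*$", "", ids), ids)
  m <- regmatches(fam, regexpr("(miR|MIR|let|lin)-?[0-9]+", fam))
  has <- grepl("(miR|MIR|let|lin)-?[0-9]+", fam)
  fam[has] <- m
  fam
}

hamming <- function(a_chars, b_chars) sum(a_chars != b_chars)

#' Scan transcripts for known mature miRNAs
#'
#' Seed-and-extend search for ungapped, full-length matches of known mature
#' miRNAs in a transcript set, on both strands, keeping matches with fewer
#' than `max_mismatch + 1` substitutions. Seeding uses exact words of length
#' `min(word, floor(len / (max_mismatch + 1)))`; by the pigeonhole principle
#' this guarantees every qualifying match contains an exact seed word, so
#' the scan is exactly equivalent to a full Hamming scan over all positions.
#'
#' @param transcripts named character vector of transcript sequences
#' @param known_matures named character vector of mature miRNA sequences
#'   (14-25 nt, miRBase-style names)
#' @param max_mismatch maximum substitutions (default 2, i.e. "fewer than 3")
#' @param word seed word size (default 7)
#' @return data.frame of hits: `transcript_id`, `mature_id`, `family`,
#'   `start`, `end` (0-based half-open on the oriented transcript), `strand`,
#'   `mismatches`
#' @export
scan_known_matures <- function(transcripts, known_matures,
                               max_mismatch = 2L, word = 7L) {
  if (length(known_matures) == 0) stop("empty mature library")
  transcripts <- vapply(transcripts, as_rna, character(1))
  known_matures <- vapply(known_matures, function(m) as_rna(m, allow_n = FALSE),
                          character(1))
  fam <- parse_mirna_family(names(known_matures))
  hits <- list()
  for (ti in seq_along(transcripts)) {
    tid <- names(transcripts)[ti]
    for (strand in c("+", "-")) {
      tseq <- if (strand == "+") transcripts[[ti]] else
        revcomp_rna(transcripts[[ti]])
      tlen <- nchar(tseq)
      tchars <- seq_chars(tseq)
      for (mi in seq_along(known_matures)) {
        m <- known_matures[[mi]]
        mlen <- nchar(m)
        if (tlen < mlen) next
        w <- min(word, mlen %/% (max_mismatch + 1L))
        if (w < 1) next
        # disjoint seed blocks covering the mature
        block_starts <- unique(c(seq(1, mlen - w + 1, by = w), mlen - w + 1))
        cand <- integer(0)
        for (bs in block_starts) {
          seed <- substr(m, bs, bs + w - 1)
          found <- gregexpr(seed, tseq, fixed = TRUE)[[1]]
          if (found[1] == -1) next
          # overlapping occurrences: rescan shifted
          occ <- found
          k <- found[length(found)] + 1
          while (k + w - 1 <= tlen) {
            nx <- regexpr(seed, substr(tseq, k, tlen), fixed = TRUE)
            if (nx == -1) break
            occ <- c(occ, k + nx - 1)
            k <- k + nx
          }
          cand <- c(cand, occ - bs + 1L)
        }
        cand <- unique(cand[cand >= 1 & cand + mlen - 1 <= tlen])
        if (length(cand) == 0) next
        mchars <- seq_chars(m)
        for (s in cand) {
          mm <- hamming(mchars, tchars[s:(s + mlen - 1)])
          if (mm <= max_mismatch) {
            hits[[length(hits) + 1]] <- data.frame(
              transcript_id = tid, mature_id = names(known_matures)[mi],
              family = fam[mi], start = s - 1L, end = s - 1L + mlen,
              strand = strand, mismatches = mm, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(transcript_id = character(0), mature_id = character(0),
                      family = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

#' Candidate precursor windows around a mature hit
#'
#' For each configured (upstream, downstream) flank pair, emits the
#' transcript window containing the mature hit, clipped at the transcript
#' bounds.
#'
#' @param hit one row of [scan_known_matures()] output
#' @param transcript_seq the (plus-strand) transcript sequence
#' @param window_set list of `c(upstream, downstream)` flank sizes in nt
#' @return data.frame with `start`, `end` (0-based half-open, oriented
#'   coordinates), `sequence`, `mature_offset` (0-based within window)
#' @export
extract_precursor_windows <- function(hit, transcript_seq,
                                      window_set = list(c(0, 60), c(20, 60),
                                                        c(60, 20), c(60, 0))) {
  tseq <- as_rna(transcript_seq)
  if (hit$strand == "-") tseq <- revcomp_rna(tseq)
  tlen <- nchar(tseq)
  if (hit$start < 0 || hit$end > tlen) stop("hit outside transcript")
  out <- lapply(window_set, function(w) {
    s <- max(0L, hit$start - w[1])
    e <- min(tlen, hit$end + w[2])
    data.frame(start = s, end = e,
               sequence = substr(tseq, s + 1, e),
               mature_offset = hit$start - s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[!duplicated(out[, c("start", "end")]), , drop = FALSE]
}

#' Default pre-miRNA hairpin thresholds
#'
#' The published screening cutoffs: MFEI >= 0.41, AU content within
#' 22-77 percent, at most 6 mature:star mismatches, normalized Shannon
#' entropy NQ <= 0.45, normalized base-pair distance ND <= 0.15, base-pairing
#' propensity Npb >= 0.25, SSR signature R >= 2.5.
#'
#' @return named list of thresholds
#' @export
hairpin_thresholds <- function() {
  list(min_mfei = 0.41, au_range = c(22, 77), max_star_mismatch = 6L,
       max_nq = 0.45, max_nd = 0.15, min_npb = 0.25, min_ssr_r = 2.5)
}

HAIRPIN_CHECKS <- c("stem_loop", "mfei", "au_content", "mature_in_arm",
                    "star_intact", "star_mismatches", "nq", "nd", "npb")

#' Validate a candidate pre-miRNA hairpin
#'
#' Folds the precursor, derives the miRNA* region from the MFE structure
#' with the canonical 2-nt 3' overhang, and evaluates the hairpin screen:
#' a single terminal loop across the mature/star duplex region; MFEI >=
#' 0.41; AU content 22-77%; mature entirely in one arm (not spanning the
#' terminal loop); no loop or branch inside the miRNA* region; at most 6
#' mature:star mismatches (mature positions unpaired or paired outside the
#' star); NQ <= 0.45; ND <= 0.15; Npb >= 0.25. A precursor with zero GC
#' content has an undefined MFEI and fails that check.
#'
#' @param precursor precursor sequence
#' @param mature_offset 0-based start of the mature within the precursor
#' @param mature_len mature length in nt
#' @param thresholds see [hairpin_thresholds()]
#' @param model an [energy_model()]
#' @return object of class `hairpin_candidate`: list with the folded
#'   `structure`, `ensemble`, `descriptors`, `arm`, `star` span (1-based),
#'   `mature_star_mismatches`, named logical `checks`, and `pass`
#' @export
validate_hairpin <- function(precursor, mature_offset, mature_len,
                             thresholds = hairpin_thresholds(),
                             model = default_energy_model()) {
  precursor <- as_rna(precursor, allow_n = FALSE)
  L <- nchar(precursor)
  if (mature_offset < 0 || mature_offset + mature_len > L) {
    stop("mature placement outside precursor")
  }
  struct <- fold_mfe(precursor, model)
  ens <- partition_function(precursor, model)
  desc <- hairpin_descriptors(struct)

  checks <- setNames(rep(FALSE, length(HAIRPIN_CHECKS)), HAIRPIN_CHECKS)
  partner <- struct$partner
  mat_idx <- (mature_offset + 1):(mature_offset + mature_len)
  partners_m <- partner[mat_idx]
  paired_m <- which(!is.na(partners_m))
  arm <- NA_character_
  star <- c(NA_integer_, NA_integer_)
  n_mm <- mature_len

  if (length(paired_m) > 0) {
    region <- range(c(mat_idx, partners_m[paired_m]))
    # terminal (hairpin) loops: pairs whose interior is fully unpaired
    prs <- struct$pairs
    in_region <- prs[, 1] >= region[1] & prs[, 2] <= region[2]
    term <- prs[in_region & apply(prs, 1, function(pq) {
      pq[1] + 1 > pq[2] - 1 ||
        all(is.na(partner[(pq[1] + 1):(pq[2] - 1)]))
    }), , drop = FALSE]
    checks["stem_loop"] <- nrow(term) == 1
    if (nrow(term) == 1) {
      apex <- term[1, ]
      loop_idx <- if (apex[1] + 1 <= apex[2] - 1)
        (apex[1] + 1):(apex[2] - 1) else integer(0)
      checks["mature_in_arm"] <- length(intersect(mat_idx, loop_idx)) == 0
      if (checks["mature_in_arm"]) {
        arm <- if (max(mat_idx) <= apex[1]) "5p"
               else if (min(mat_idx) >= apex[2]) "3p" else NA_character_
        checks["mature_in_arm"] <- !is.na(arm)
      }
    }
    pr <- range(partners_m[paired_m])
    if (!is.na(arm) && arm == "5p") {
      star <- c(pr[1], min(L, pr[2] + 2L))
    } else if (!is.na(arm) && arm == "3p") {
      star <- c(max(1L, pr[1] - 2L), pr[2])
    } else {
      star <- pr
    }
    star_idx <- star[1]:star[2]
    if (length(intersect(star_idx, mat_idx)) == 0) {
      sp <- partner[star_idx]
      sp_ok <- is.na(sp) | (sp >= min(mat_idx) - 4 & sp <= max(mat_idx) + 4)
      no_self <- !any(!is.na(sp) & sp %in% star_idx)
      # "no loop or break in miRNA*": paired star positions must keep a
      # constant register against the mature arm -- symmetric internal
      # loops (mismatches) are allowed, asymmetric bulges are a break
      paired_s <- star_idx[!is.na(partner[star_idx])]
      in_register <- TRUE
      if (length(paired_s) >= 2) {
        gap_star <- diff(paired_s)
        gap_mate <- -diff(partner[paired_s])
        in_register <- all(gap_star == gap_mate)
      }
      checks["star_intact"] <- all(sp_ok) && no_self && in_register
    }
    n_mm <- sum(is.na(partners_m) | partners_m < star[1] |
                  partners_m > star[2])
  }
  checks["star_mismatches"] <- n_mm <= thresholds$max_star_mismatch
  checks["mfei"] <- !desc$gc_zero && !is.na(desc$MFEI) &&
    desc$MFEI >= thresholds$min_mfei
  checks["au_content"] <- desc$au_pct >= thresholds$au_range[1] &&
    desc$au_pct <= thresholds$au_range[2]
  checks["nq"] <- ens$NQ <= thresholds$max_nq
  checks["nd"] <- ens$ND <= thresholds$max_nd
  checks["npb"] <- desc$Npb >= thresholds$min_npb

  structure(list(precursor = precursor, mature_offset = mature_offset,
                 mature_len = mature_len, structure = struct, ensemble = ens,
                 descriptors = desc, arm = arm, star = star,
                 mature_star_mismatches = n_mm, checks = checks,
                 pass = all(checks)),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat("hairpin candidate (", nchar(x$precursor), " nt), arm ", x$arm,
      ", MFEI ", sprintf("%.3f", x$descriptors$MFEI), "\n", sep = "")
  cat("checks:", paste(names(x$checks)[!x$checks], collapse = " "),
      if (x$pass) "(all pass)" else "(failing listed)", "\n")
  invisible(x)
}

#' SSR signature score of a mature miRNA
#'
#' Observed/expected score of the family's modal length-`k` repeat motif in
#' a mature sequence: the motif is the most frequent k-mer across the
#' family's matures (lexicographic tie-break); the observed count is its
#' overlapping occurrence count in the mature; the expected count is
#' `(L - k + 1)` times the product of the mature's mononucleotide
#' frequencies over the motif. R = 0 when the motif is absent.
#'
#' @param mature mature miRNA sequence (length >= k)
#' @param family_matures character vector of the family's mature sequences
#' @param k motif length (default 3)
#' @return the signature score R
#' @export
ssr_signature_score <- function(mature, family_matures, k = 3L) {
  mature <- as_rna(mature, allow_n = FALSE)
  if (nchar(mature) < k) stop("mature shorter than k")
  if (length(family_matures) == 0) stop("empty family")
  fam_kmers <- unlist(lapply(as_rna(family_matures), function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  tab <- table(fam_kmers)
  motif <- sort(names(tab)[tab == max(tab)])[1]
  L <- nchar(mature)
  mk <- substring(mature, 1:(L - k + 1), k:L)
  observed <- sum(mk == motif)
  if (observed == 0) return(0)
  chars <- seq_chars(mature)
  p <- table(factor(chars, levels = RNA_BASES)) / L
  expected <- (L - k + 1) * prod(p[seq_chars(motif)])
  observed / expected
}

#' Select the best hairpin candidate for a mature locus
#'
#' Among candidates passing every check, picks the one with maximum MFEI;
#' ties broken by maximum SSR signature R, then shortest precursor, then
#' lexicographic candidate id. Returns NULL when nothing passes.
#'
#' @param candidates list of `hairpin_candidate` objects with `ssr_r` and
#'   `candidate_id` fields attached
#' @return the selected candidate or NULL
#' @export
select_best_candidate <- function(candidates) {
  pass <- Filter(function(x) isTRUE(x$pass), candidates)
  if (length(pass) == 0) return(NULL)
  mfei <- vapply(pass, function(x) x$descriptors$MFEI, numeric(1))
  r <- vapply(pass, function(x) x$ssr_r %||% 0, numeric(1))
  len <- vapply(pass, function(x) nchar(x$precursor), numeric(1))
  id <- vapply(pass, function(x) x$candidate_id %||% "", character(1))
  ord <- order(-mfei, -r, len, id)
  pass[[ord[1]]]
}

#' Homology-seeded miRNA prediction
#'
#' End-to-end prediction: scan transcripts for known matures, extract
#' candidate precursor windows around each hit, validate each window's
#' hairpin (structure, MFEI, AU content, arm placement, miRNA* integrity,
#' ensemble statistics), require the family SSR signature R >= `min_ssr_r`,
#' and keep, per mature locus, the all-pass candidate with maximum MFEI
#' (ties by R).
#'
#' @param transcripts named character vector of transcript sequences
#' @param known_matures named character vector of known mature sequences
#' @param thresholds see [hairpin_thresholds()]
#' @param model an [energy_model()]
#' @param window_set see [extract_precursor_windows()]
#' @param max_mismatch,word homology scan parameters
#' @param mature_len_range acceptable mature lengths (nt)
#' @return list with `records` (one row per predicted miRNA: ids, family,
#'   mature sequence, precursor window and sequence, arm, descriptors, R)
#'   and `candidates` (all validated windows with their check maps)
#' @export
predict_mirnas <- function(transcripts, known_matures,
                           thresholds = hairpin_thresholds(),
                           model = default_energy_model(),
                           window_set = list(c(0, 60), c(20, 60),
                                             c(60, 20), c(60, 0)),
                           max_mismatch = 2L, word = 7L,
                           mature_len_range = c(14L, 25L)) {
  known_matures <- vapply(known_matures, function(m) as_rna(m, allow_n = FALSE),
                          character(1))
  mlen <- nchar(known_matures)
  keep <- mlen >= mature_len_range[1] & mlen <= mature_len_range[2]
  known_matures <- known_matures[keep]
  if (length(known_matures) == 0) stop("empty mature library")
  fam_of <- parse_mirna_family(names(known_matures))
  fam_seqs <- split(unname(known_matures), fam_of)

  hits <- scan_known_matures(transcripts, known_matures,
                             max_mismatch = max_mismatch, word = word)
  records <- list()
  all_cands <- list()
  if (nrow(hits) > 0) {
    hits$locus <- paste(hits$transcript_id, hits$strand, hits$start, hits$end,
                        sep = ":")
    for (loc in unique(hits$locus)) {
      lhits <- hits[hits$locus == loc, , drop = FALSE]
      lhits <- lhits[order(lhits$mismatches, lhits$mature_id), , drop = FALSE]
      cands <- list()
      for (hi in seq_len(nrow(lhits))) {
        hit <- lhits[hi, ]
        wins <- extract_precursor_windows(hit, transcripts[[hit$transcript_id]],
                                          window_set)
        tseq <- if (hit$strand == "+") as_rna(transcripts[[hit$transcript_id]])
                else revcomp_rna(transcripts[[hit$transcript_id]])
        mature_seq <- substr(tseq, hit$start + 1, hit$end)
        r_val <- ssr_signature_score(mature_seq, fam_seqs[[hit$family]])
        for (wi in seq_len(nrow(wins))) {
          hc <- validate_hairpin(wins$sequence[wi], wins$mature_offset[wi],
                                 hit$end - hit$start, thresholds, model)
          hc$ssr_r <- r_val
          hc$checks <- c(hc$checks, ssr_r = r_val >= thresholds$min_ssr_r)
          hc$pass <- all(hc$checks)
          hc$candidate_id <- paste(loc, hit$mature_id, wins$start[wi],
                                   wins$end[wi], sep = ":")
          hc$hit <- hit
          hc$window <- wins[wi, c("start", "end")]
          hc$mature_sequence <- mature_seq
          cands[[length(cands) + 1]] <- hc
        }
      }
      all_cands <- c(all_cands, cands)
      best <- select_best_candidate(cands)
      if (!is.null(best)) {
        records[[length(records) + 1]] <- data.frame(
          transcript_id = best$hit$transcript_id,
          mature_id = best$hit$mature_id, family = best$hit$family,
          strand = best$hit$strand,
          mature_sequence = best$mature_sequence,
          mature_start = best$hit$start, mature_end = best$hit$end,
          precursor_start = best$window$start,
          precursor_end = best$window$end,
          precursor = best$precursor, arm = best$arm,
          mfe = best$descriptors$mfe, AMFE = best$descriptors$AMFE,
          MFEI = best$descriptors$MFEI, Npb = best$descriptors$Npb,
          NQ = unname(best$ensemble$NQ), ND = unname(best$ensemble$ND),
          ssr_r = best$ssr_r,
          mature_star_mismatches = best$mature_star_mismatches,
          mismatches = best$hit$mismatches, stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(transcript_id = character(0), mature_id = character(0),
               family = character(0), strand = character(0),
               mature_sequence = character(0))
  list(records = records, candidates = all_cands)
}
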