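#' Default parameters of the miRNA/UTR expectation scan
#'
#' Penalty scheme per miRNA position: mismatch +1, G:U wobble +0.5, 1-nt
#' target bulge +2, every penalty doubled inside the seed-proximal region
#' (miRNA positions 2-13 from the 5' end). A site is reported when the
#' cumulative expectation-like score E is at most `cutoff` (default 5).
#'
#' @return named list of parameters
#' @export
target_scan_params <- function() {
  list(cutoff = 5, mismatch = 1, gu = 0.5, bulge = 2,
       seed_lo = 2L, seed_hi = 13L, max_bulges = 2L)
}

# per-position penalty weight: doubled within the seed-proximal region
seed_weight <- function(i, params) {
  ifelse(i >= params$seed_lo & i <= params$seed_hi, 2, 1)
}

# expectation score of miRNA against target, miRNA position 1 pairing
# target position e (1-based), reading the target 3'->5'; target bulges
# only; returns min score over bulge placements or NA when out of bounds
expectation_score_at <- function(mchars, tchars, e, params) {
  n <- length(mchars)
  maxb <- params$max_bulges
  # E[i, b+1]: best penalty for miRNA 1..i with b target bulges
  E <- matrix(Inf, n, maxb + 1)
  pen <- function(i, tpos) {
    if (tpos < 1 || tpos > length(tchars)) return(Inf)
    st <- pair_state(mchars[i], tchars[tpos])
    w <- seed_weight(i, params)
    if (st == "WC") 0 else if (st == "GU") params$gu * w else params$mismatch * w
  }
  E[1, 1] <- pen(1, e)
  if (!is.finite(E[1, 1])) return(NA_real_)
  for (i in 2:n) {
    for (b in 0:maxb) {
      p <- pen(i, e - (i - 1) - b)
      if (!is.finite(p)) next
      best <- E[i - 1, b + 1]
      if (b > 0) {
        wb <- seed_weight(i, params)
        alt <- E[i - 1, b] + params$bulge * wb
        if (alt < best) best <- alt
      }
      E[i, b + 1] <- best + p
    }
  }
  res <- suppressWarnings(min(E[n, ]))
  if (!is.finite(res)) NA_real_ else res
}

#' miRNA target scan over UTR sequences
#'
#' Expectation-scored complementarity scan of each miRNA against each UTR:
#' sites are alignments of the full miRNA (read 5'->3') against the target
#' (read 3'->5') with mismatches, G:U pairs, and up to `max_bulges` single-
#' nucleotide target bulges, scored by [target_scan_params()]. Reports, per
#' miRNA/target pair, all non-overlapping sites with score at most `cutoff`,
#' best score first.
#'
#' @param mirnas named character vector of mature miRNA sequences
#' @param utr_sequences named character vector; names may carry region
#'   labels as `id|5UTR` / `id|3UTR`
#' @param params see [target_scan_params()]
#' @return data.frame of hits: `mirna_id`, `target_id`, `region`,
#'   `site_start`, `site_end` (1-based inclusive on the target),
#'   `expectation`
#' @export
mirna_target_scan <- function(mirnas, utr_sequences,
                              params = target_scan_params()) {
  if (length(mirnas) == 0) stop("empty miRNA set")
  out <- list()
  for (mid in names(mirnas)) {
    mchars <- seq_chars(as_rna(mirnas[[mid]], allow_n = FALSE))
    n <- length(mchars)
    for (uid in names(utr_sequences)) {
      tchars <- seq_chars(as_rna(utr_sequences[[uid]]))
      tl <- length(tchars)
      if (tl < n) next
      cand <- list()
      for (e in n:tl) {
        sc <- expectation_score_at(mchars, tchars, e, params)
        if (!is.na(sc) && sc <= params$cutoff) {
          # site span: conservative full extent including possible bulges
          lo <- max(1, e - n + 1 - params$max_bulges)
          cand[[length(cand) + 1]] <- data.frame(
            e = e, lo = lo, expectation = sc)
        }
      }
      if (length(cand) == 0) next
      cand <- do.call(rbind, cand)
      cand <- cand[order(cand$expectation, cand$e), , drop = FALSE]
      taken <- cand[0, ]
      for (ri in seq_len(nrow(cand))) {
        row <- cand[ri, ]
        if (nrow(taken) == 0 ||
            all(row$e < taken$lo | row$lo > taken$e)) {
          taken <- rbind(taken, row)
        }
      }
      parts <- strsplit(uid, "|", fixed = TRUE)[[1]]
      region <- if (length(parts) > 1) parts[2] else NA_character_
      out[[length(out) + 1]] <- data.frame(
        mirna_id = mid, target_id = parts[1], region = region,
        site_start = taken$lo, site_end = taken$e,
        expectation = taken$expectation, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      region = character(0), site_start = integer(0),
                      site_end = integer(0), expectation = numeric(0)))
  }
  do.call(rbind, out)
}

# brute-force oracle: enumerate every alignment (recursion over positions
# and bulge placements) and score it literally; short inputs only
target_scan_bruteforce_scores <- function(mirna, target,
                                          params = target_scan_params()) {
  mchars <- seq_chars(as_rna(mirna, allow_n = FALSE))
  tchars <- seq_chars(as_rna(target))
  n <- length(mchars)
  tl <- length(tchars)
  scores <- rep(NA_real_, tl)
  pen1 <- function(i, tpos) {
    st <- pair_state(mchars[i], tchars[tpos])
    w <- if (i >= params$seed_lo && i <= params$seed_hi) 2 else 1
    if (st == "WC") 0 else if (st == "GU") params$gu * w else params$mismatch * w
  }
  for (e in seq_len(tl)) {
    best <- Inf
    recurse <- function(i, tpos, b, acc) {
      if (tpos < 1) return()
      acc <- acc + pen1(i, tpos)
      if (i == n) { if (acc < best) best <<- acc; return() }
      recurse(i + 1, tpos - 1, b, acc)
      if (b < params$max_bulges && tpos - 2 >= 1) {
        w <- if ((i + 1) >= params$seed_lo && (i + 1) <= params$seed_hi) 2 else 1
        recurse(i + 1, tpos - 2, b + 1, acc + params$bulge * w)
      }
    }
    if (e >= 1) recurse(1, e, 0, 0)
    if (is.finite(best)) scores[e] <- best
  }
  scores
}

#' Cis target genes of lncRNAs
#'
#' Emits every (lncRNA, gene) pair whose genomic spans lie within `window`
#' nucleotides of each other on the same chromosome (upstream, downstream,
#' or overlapping), strand-agnostic.
#'
#' @param lncrna_models,gene_models exon-level model data.frames
#' @param window distance cutoff in nt (default 10 kb)
#' @return data.frame `lncrna_id`, `gene_id`, `distance`
#' @export
lncrna_cis_targets <- function(lncrna_models, gene_models, window = 10000L) {
  if (nrow(lncrna_models) == 0 || nrow(gene_models) == 0) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  }
  lsp <- transcript_spans(lncrna_models)
  gsp <- transcript_spans(gene_models)
  gsp$gene_id <- gene_models$gene_id[
    match(gsp$transcript_id, gene_models$transcript_id)]
  gsp <- gsp[!duplicated(gsp$gene_id), , drop = FALSE]
  lg <- GenomicRanges::GRanges(lsp$chrom,
                               IRanges::IRanges(lsp$start, lsp$end))
  gg <- GenomicRanges::GRanges(gsp$chrom,
                               IRanges::IRanges(gsp$start, gsp$end))
  hits <- GenomicRanges::findOverlaps(lg, gg, maxgap = window,
                                      ignore.strand = TRUE)
  if (length(hits) == 0) {
    return(data.frame(lncrna_id = character(0), gene_id = character(0),
                      distance = integer(0)))
  }
  d <- GenomicRanges::distance(lg[S4Vectors::queryHits(hits)],
                               gg[S4Vectors::subjectHits(hits)])
  data.frame(lncrna_id = lsp$transcript_id[S4Vectors::queryHits(hits)],
             gene_id = gsp$gene_id[S4Vectors::subjectHits(hits)],
             distance = d, stringsAsFactors = FALSE)
}

#' Trans target prediction for lncRNAs
#'
#' Stage 1 finds complementarity candidates: maximal exact reverse-
#' complement seed matches of at least `seed_len` nt between the lncRNA and
#' each mRNA, extended along the diagonal while the aligned identity stays
#' at or above `min_identity`, kept when the extended span reaches
#' `min_span`. Stage 2 scores each candidate with [duplex_score()] and
#' keeps hits with hybridization energy at most `energy_cutoff` (model
#' units). Genes listed in `exclude_gene_ids` (e.g. genes already within
#' the cis window) are skipped.
#'
#' @param lncrna_seqs,mrna_seqs named character vectors
#' @param seed_len minimum exact seed (default 20 nt)
#' @param min_identity identity gate over the extended span (default 0.95)
#' @param min_span minimum candidate span (default 50 nt)
#' @param energy_cutoff duplex energy cutoff (default -50 model units)
#' @param exclude_gene_ids optional character vector or a data.frame of cis
#'   pairs with columns `lncrna_id`, `gene_id`
#' @param model an [energy_model()]
#' @return data.frame of hits: `lncrna_id`, `target_id`, spans on both
#'   sequences (1-based inclusive), `identity`, `energy`
#' @export
lncrna_trans_targets <- function(lncrna_seqs, mrna_seqs, seed_len = 20L,
                                 min_identity = 0.95, min_span = 50L,
                                 energy_cutoff = -50,
                                 exclude_gene_ids = NULL,
                                 model = default_energy_model()) {
  out <- list()
  cis_df <- if (is.data.frame(exclude_gene_ids)) exclude_gene_ids else NULL
  for (lid in names(lncrna_seqs)) {
    lseq <- as_rna(lncrna_seqs[[lid]])
    lch <- seq_chars(lseq)
    ln <- length(lch)
    for (gid in names(mrna_seqs)) {
      if (!is.null(cis_df)) {
        if (any(cis_df$lncrna_id == lid & cis_df$gene_id == gid)) next
      } else if (!is.null(exclude_gene_ids) && gid %in% exclude_gene_ids) next
      rc <- revcomp_rna(mrna_seqs[[gid]])
      rch <- seq_chars(rc)
      rn <- length(rch)
      if (ln < seed_len || rn < seed_len) next
      # k-mer join to find shared exact seed_len-mers
      lk <- substring(lseq, 1:(ln - seed_len + 1), seed_len:ln)
      rk <- substring(rc, 1:(rn - seed_len + 1), seed_len:rn)
      common <- intersect(lk, rk)
      if (length(common) == 0) next
      diags <- unique(unlist(lapply(common, function(km) {
        lp <- which(lk == km)
        rp <- which(rk == km)
        as.vector(outer(lp, rp, "-"))
      })))
      seen <- list()
      for (d in diags) {
        # overlap of the diagonal: l = r + d
        r0 <- max(1, 1 - d)
        r1 <- min(rn, ln - d)
        if (r1 - r0 + 1 < min_span) next
        match_vec <- lch[(r0:r1) + d] == rch[r0:r1]
        runs <- rle(match_vec)
        ends <- cumsum(runs$lengths)
        starts <- ends - runs$lengths + 1
        seed_runs <- which(runs$values & runs$lengths >= seed_len)
        for (sr in seed_runs) {
          a <- starts[sr]; b <- ends[sr]
          # greedy two-sided extension keeping identity >= min_identity
          repeat {
            grew <- FALSE
            if (a > 1) {
              na <- a - 1
              if (mean(match_vec[na:b]) >= min_identity) { a <- na; grew <- TRUE }
            }
            if (b < length(match_vec)) {
              nb <- b + 1
              if (mean(match_vec[a:nb]) >= min_identity) { b <- nb; grew <- TRUE }
            }
            if (!grew) break
          }
          if (b - a + 1 < min_span) next
          lstart <- r0 + a - 1 + d
          lend <- r0 + b - 1 + d
          rstart <- r0 + a - 1
          rend <- r0 + b - 1
          key <- paste(lstart, lend)
          if (!is.null(seen[[key]])) next
          seen[[key]] <- TRUE
          # map rc coordinates back to the mRNA (5'->3')
          mlen <- rn
          mstart <- mlen - rend + 1
          mend <- mlen - rstart + 1
          lsub <- substr(lseq, lstart, lend)
          msub <- substr(as_rna(mrna_seqs[[gid]]), mstart, mend)
          dx <- duplex_score(lsub, msub, model)
          if (dx$energy <= energy_cutoff) {
            out[[length(out) + 1]] <- data.frame(
              lncrna_id = lid, target_id = gid,
              lnc_start = lstart, lnc_end = lend,
              target_start = mstart, target_end = mend,
              identity = mean(match_vec[a:b]), energy = dx$energy,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(lncrna_id = character(0), target_id = character(0),
                      lnc_start = integer(0), lnc_end = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      identity = numeric(0), energy = numeric(0)))
  }
  unique(do.call(rbind, out))
}

#' Default endogenous-target-mimic rule parameters
#'
#' R1: exactly one bulge, on the lncRNA side, between the nucleotides
#' pairing miRNA positions p and p+1 with p in 9..12 (5' end numbering,
#' position 1 = first nucleotide). R2: bulge length 1-3 nt (set
#' `strict_bulge_3 = TRUE` to require exactly 3). R3: Watson-Crick pairing
#' at every miRNA position 2-8 (G:U disallowed there). R4: mismatches plus
#' G:U pairs fewer than 3 over all other positions.
#'
#' @return named list of parameters
#' @export
etm_params <- function() {
  list(bulge_len_range = c(1L, 3L), bulge_pos_range = c(9L, 12L),
       max_mm_gu = 2L, strict_bulge_3 = FALSE, require_bulge = TRUE)
}

# partner mapping of an eTM site: miRNA position i (1-based, 5' end) pairs
# lncRNA position s + n + b - i for i <= p, s + n - i for i > p, where the
# site occupies lncRNA [s, s + n + b - 1] and the b-nt bulge sits between
# the partners of positions p and p + 1
etm_partner_map <- function(s, n, b, p) {
  i <- seq_len(n)
  ifelse(i <= p, s + n + b - i, s + n - i)
}

#' Evaluate a putative eTM site against the rule set
#'
#' Scores a specific alignment (site start, bulge length and position) of a
#' miRNA on a lncRNA and reports a complete rule trace. Used by
#' [detect_etm()] and directly when diagnosing why a site is rejected.
#'
#' @param mirna miRNA sequence (>= 13 nt)
#' @param lncrna lncRNA sequence
#' @param site_start 1-based start of the site on the lncRNA
#' @param bulge_len bulge length in nt (0 = no bulge)
#' @param bulge_pos bulge sits between the partners of miRNA positions
#'   `bulge_pos` and `bulge_pos + 1`
#' @param params see [etm_params()]
#' @return list with `states` (per-miRNA-position pairing state),
#'   `n_mismatch`, `n_gu`, `rule_trace` (named logical: `r1_single_bulge`,
#'   `r2_bulge_len`, `r3_seed_wc`, `r4_mm_gu`), and `pass`
#' @export
evaluate_etm_site <- function(mirna, lncrna, site_start, bulge_len,
                              bulge_pos, params = etm_params()) {
  m <- seq_chars(as_rna(mirna, allow_n = FALSE))
  l <- seq_chars(as_rna(lncrna, allow_n = FALSE))
  n <- length(m)
  if (n < 13) stop("miRNA shorter than 13 nt")
  s <- site_start; b <- bulge_len; p <- bulge_pos
  if (s < 1 || s + n + b - 1 > length(l)) stop("site outside lncRNA")
  partners <- etm_partner_map(s, n, b, p)
  states <- pair_state(m, l[partners])
  seed <- 2:8
  others <- setdiff(seq_len(n), seed)
  n_mm <- sum(states[others] == "mismatch")
  n_gu <- sum(states[others] == "GU")
  r1 <- (if (params$require_bulge) b >= 1 else TRUE) &&
    (b == 0 || (p >= params$bulge_pos_range[1] &&
                  p <= params$bulge_pos_range[2]))
  r2 <- if (params$strict_bulge_3) (b == 0 || b == 3) else
    (b <= params$bulge_len_range[2])
  r3 <- all(states[seed] == "WC")
  r4 <- (n_mm + n_gu + sum(states[seed] != "WC")) <= params$max_mm_gu
  trace <- c(r1_single_bulge = r1, r2_bulge_len = r2, r3_seed_wc = r3,
             r4_mm_gu = r4)
  list(states = states, n_mismatch = n_mm, n_gu = n_gu,
       rule_trace = trace, pass = all(trace))
}

#' Detect endogenous target mimic sites
#'
#' Slides a miRNA over a lncRNA and reports every site satisfying the eTM
#' rule set (see [etm_params()]). The search is seed-anchored: candidate
#' positions are occurrences of the reverse complement of miRNA positions
#' 2-8 (rule R3 requires perfect Watson-Crick pairing there), then each
#' admissible bulge length and bulge position is evaluated.
#'
#' One physical site can admit several equivalent bulge placements (the
#' bulge position is ambiguous when flanking nucleotides happen to pair
#' either way); all are reported by default, matching the brute-force
#' oracle. With `collapse = TRUE` one row per distinct site span is kept
#' (fewest mismatches + G:U, then smallest bulge position).
#'
#' @param mirna miRNA sequence (>= 13 nt)
#' @param lncrna lncRNA sequence
#' @param params see [etm_params()]
#' @param collapse report one row per distinct site span
#' @return data.frame of accepted sites: `site_start`, `site_end` (1-based
#'   inclusive), `bulge_len`, `bulge_pos`, `n_mismatch`, `n_gu`
#' @export
detect_etm <- function(mirna, lncrna, params = etm_params(),
                       collapse = FALSE) {
  m <- as_rna(mirna, allow_n = FALSE)
  l <- as_rna(lncrna, allow_n = FALSE)
  n <- nchar(m)
  if (n < 13) stop("miRNA shorter than 13 nt")
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      bulge_len = integer(0), bulge_pos = integer(0),
                      n_mismatch = integer(0), n_gu = integer(0))
  if (nchar(l) < n) return(empty)
  seed_rc <- revcomp_rna(substr(m, 2, 8))
  # all (possibly overlapping) occurrences of the seed anchor
  occ <- integer(0)
  k <- 1
  while (k + 6 <= nchar(l)) {
    nx <- regexpr(seed_rc, substr(l, k, nchar(l)), fixed = TRUE)
    if (nx == -1) break
    occ <- c(occ, k + nx - 1)
    k <- k + nx
  }
  if (length(occ) == 0) return(empty)
  bl <- params$bulge_len_range
  bp <- params$bulge_pos_range
  b_vals <- if (params$require_bulge) bl[1]:bl[2] else 0:bl[2]
  if (params$strict_bulge_3) b_vals <- intersect(b_vals, c(0L, 3L))
  out <- list()
  for (q in occ) {
    for (b in b_vals) {
      # seed anchor occupies partners of positions 2..8: q = s + n + b - 8
      s <- q - n - b + 8
      if (s < 1 || s + n + b - 1 > nchar(l)) next
      p_vals <- if (b == 0) NA_integer_ else bp[1]:min(bp[2], n - 1)
      for (p in p_vals) {
        ev <- evaluate_etm_site(m, l, s, b, if (is.na(p)) n else p, params)
        if (ev$pass) {
          out[[length(out) + 1]] <- data.frame(
            site_start = s, site_end = s + n + b - 1,
            bulge_len = b, bulge_pos = if (is.na(p)) NA_integer_ else p,
            n_mismatch = ev$n_mismatch, n_gu = ev$n_gu)
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- unique(do.call(rbind, out))
  if (collapse && nrow(res)) {
    res <- res[order(res$site_start, res$site_end,
                     res$n_mismatch + res$n_gu, res$bulge_pos), ]
    res <- res[!duplicated(res[, c("site_start", "site_end")]), ]
  }
  rownames(res) <- NULL
  res
}

#' Brute-force eTM oracle
#'
#' Literal enumeration of every window, bulge placement and bulge length,
#' applying the eTM rules by explicit string comparison. Reference
#' implementation for [detect_etm()]; capped input size.
#'
#' @inheritParams detect_etm
#' @param max_lncrna_len refuse longer hosts
#' @return data.frame in the same shape as [detect_etm()]
#' @export
etm_bruteforce_oracle <- function(mirna, lncrna, params = etm_params(),
                                  max_lncrna_len = 500L) {
  m <- as_rna(mirna, allow_n = FALSE)
  l <- as_rna(lncrna, allow_n = FALSE)
  if (nchar(l) > max_lncrna_len) stop("lncRNA above oracle cap")
  n <- nchar(m)
  if (n < 13) stop("miRNA shorter than 13 nt")
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      bulge_len = integer(0), bulge_pos = integer(0),
                      n_mismatch = integer(0), n_gu = integer(0))
  if (nchar(l) < n) return(empty)
  mch <- seq_chars(m)
  bl <- params$bulge_len_range
  bp <- params$bulge_pos_range
  b_vals <- if (params$require_bulge) bl[1]:bl[2] else 0:bl[2]
  if (params$strict_bulge_3) b_vals <- intersect(b_vals, c(0L, 3L))
  out <- list()
  for (b in b_vals) {
    site_len <- n + b
    if (nchar(l) < site_len) next
    p_set <- if (b == 0) n else bp[1]:min(bp[2], n - 1)
    for (s in 1:(nchar(l) - site_len + 1)) {
      site <- substr(l, s, s + site_len - 1)
      # read the site 3'->5' opposite the miRNA 5'->3'
      rev_site <- rev(seq_chars(site))
      for (p in p_set) {
        # remove the b bulged nucleotides (after miRNA position p)
        opp <- if (b > 0) rev_site[-(p + seq_len(b))] else rev_site
        states <- pair_state(mch, opp)
        seed_ok <- all(states[2:8] == "WC")
        mm_gu <- sum(states[-(2:8)] %in% c("mismatch", "GU")) +
          sum(states[2:8] != "WC")
        r1 <- (!params$require_bulge || b >= 1) &&
          (b == 0 || (p >= bp[1] && p <= bp[2]))
        r2 <- if (params$strict_bulge_3) (b == 0 || b == 3) else b <= bl[2]
        r4 <- mm_gu <= params$max_mm_gu
        if (r1 && r2 && seed_ok && r4) {
          out[[length(out) + 1]] <- data.frame(
            site_start = s, site_end = s + site_len - 1,
            bulge_len = b, bulge_pos = if (b == 0) NA_integer_ else p,
            n_mismatch = sum(states[-(2:8)] == "mismatch"),
            n_gu = sum(states[-(2:8)] == "GU"))
        }
      }
    }
  }
  if (length(out) == 0) return(empty)
  unique(do.call(rbind, out))
}

#' Export an interaction network
#'
#' Writes the miRNA/lncRNA/mRNA interaction graph as SIF and GraphML.
#' Nodes carry a `type` attribute; edges are typed `targets` (miRNA ->
#' mRNA), `lnc_targets` (lncRNA -> mRNA, cis or trans), and `mimics`
#' (lncRNA -| miRNA).
#'
#' @param target_hits data.frame from [mirna_target_scan()] (may be empty)
#' @param etm_sites data.frame with `lncrna_id` and `mirna_id` columns
#' @param lnc_targets optional data.frame with `lncrna_id` and target id
#'   column (`gene_id` or `target_id`)
#' @param sif_path,graphml_path output file paths (NULL to skip either)
#' @return the igraph object, invisibly
#' @export
export_interaction_network <- function(target_hits, etm_sites,
                                       lnc_targets = NULL,
                                       sif_path = NULL, graphml_path = NULL) {
  edges <- list()
  if (!is.null(target_hits) && nrow(target_hits)) {
    edges[[length(edges) + 1]] <- data.frame(
      from = target_hits$mirna_id, to = target_hits$target_id,
      interaction = "targets", from_type = "miRNA", to_type = "mRNA",
      stringsAsFactors = FALSE)
  }
  if (!is.null(etm_sites) && nrow(etm_sites)) {
    edges[[length(edges) + 1]] <- data.frame(
      from = etm_sites$lncrna_id, to = etm_sites$mirna_id,
      interaction = "mimics", from_type = "lncRNA", to_type = "miRNA",
      stringsAsFactors = FALSE)
  }
  if (!is.null(lnc_targets) && nrow(lnc_targets)) {
    tcol <- if ("gene_id" %in% names(lnc_targets)) "gene_id" else "target_id"
    edges[[length(edges) + 1]] <- data.frame(
      from = lnc_targets$lncrna_id, to = lnc_targets[[tcol]],
      interaction = "lnc_targets", from_type = "lncRNA", to_type = "mRNA",
      stringsAsFactors = FALSE)
  }
  if (length(edges) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
  } else {
    ed <- unique(do.call(rbind, edges))
    verts <- unique(rbind(data.frame(name = ed$from, type = ed$from_type),
                          data.frame(name = ed$to, type = ed$to_type)))
    verts <- verts[!duplicated(verts$name), ]
    g <- igraph::graph_from_data_frame(
      ed[, c("from", "to", "interaction")], directed = TRUE,
      vertices = verts)
  }
  if (!is.null(sif_path)) {
    if (igraph::ecount(g) > 0) {
      ed <- igraph::as_data_frame(g, what = "edges")
      writeLines(paste(ed$from, ed$interaction, ed$to, sep = "\t"), sif_path)
    } else writeLines(character(0), sif_path)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(g)
}
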