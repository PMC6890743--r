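# quadratic-time reference: scan every AUG in all 3 forward frames
orf_oracle <- function(seq) {
  s <- strsplit(chartr("Tt", "UU", toupper(seq)), "")[[1]]
  best <- 0
  for (start in seq_along(s)) {
    if (start + 2 > length(s)) break
    if (paste(s[start:(start + 2)], collapse = "") != "AUG") next
    k <- start + 3
    aa <- 1
    while (k + 2 <= length(s)) {
      cod <- paste(s[k:(k + 2)], collapse = "")
      if (cod %in% c("UAA", "UAG", "UGA")) {
        best <- max(best, aa)
        break
      }
      aa <- aa + 1
      k <- k + 3
    }
  }
  best
}

test_that("longest ORF is found and measured in amino acids", {
  expect_equal(longest_orf("AUGUUUUAA")$longest_orf_aa, 2)
  expect_equal(longest_orf("AUGUUUUAA")$orf_coverage, 1)
  expect_equal(longest_orf("CCCCCCUUUCCC")$longest_orf_aa, 0)
  expect_error(longest_orf(""), "empty")
  set.seed(31)
  for (i in 1:15) {
    s <- random_rna_str(2000)
    expect_equal(longest_orf(s)$longest_orf_aa, orf_oracle(s), info = i)
  }
})

test_that("coding-potential score separates coding from shuffled decoys", {
  tabs <- fixture_hexamer_tables()
  sim <- fixture_training()
  lab <- sim$truth$labels
  coding <- sim$sequences[lab$id[lab$label == "coding"]]
  set.seed(9)
  wins <- 0
  for (i in 1:100) {
    cs <- coding[[(i - 1) %% length(coding) + 1]]
    sh <- lncmir:::shuffle_sequence(cs)
    if (coding_potential_score(cs, tabs)$combined_score >
        coding_potential_score(sh, tabs)$combined_score) wins <- wins + 1
  }
  expect_gte(wins, 90)
})

test_that("coding score is non-positive without ORF or hexamer signal", {
  # uniform tables make the LLR vanish; no AUG means zero coverage
  uni <- train_hexamer_tables(character(0), character(0))
  sc <- coding_potential_score(strrep("CCCCUU", 30), uni)
  expect_equal(sc$orf_coverage, 0)
  expect_lte(sc$combined_score, 0)
  # determinism
  tabs <- fixture_hexamer_tables()
  s <- fixture_training()$sequences[[1]]
  expect_identical(coding_potential_score(s, tabs),
                   coding_potential_score(s, tabs))
  expect_error(coding_potential_score("ACG", tabs), "shorter")
})

test_that("filter cascade applies the published gates in order", {
  tabs <- fixture_hexamer_tables()
  expr <- matrix(10, 2, 2, dimnames = list(c("short", "low"), c("s1", "s2")))
  expr["low", ] <- 0.5
  seqs <- c(short = paste(rep("AT", 75), collapse = ""), # 150 nt
            low = lncmir:::random_dna(400, c(.35, .15, .15, .35)))
  set.seed(1)
  res <- filter_lncrna_candidates(seqs, expr, hexamer_tables = tabs)
  expect_equal(res$first_fail[res$id == "short"], "length")
  expect_equal(res$first_fail[res$id == "low"], "fpkm")
  # exclusion lists dominate later stages
  res2 <- filter_lncrna_candidates(
    seqs["low"], expr["low", , drop = FALSE] * 10,
    exclusion_lists = list(ncrna_family = "low"), hexamer_tables = tabs)
  expect_equal(res2$first_fail, "ncrna_family")
  expect_error(
    filter_lncrna_candidates(c(seqs, other = "ACGU"), expr,
                             hexamer_tables = tabs),
    "missing transcript")
})

test_that("cascade stages are pure predicates: pass = conjunction", {
  sim <- fixture_cascade()
  res <- filter_lncrna_candidates(sim$sequences, sim$expression,
                                  hexamer_tables = fixture_hexamer_tables())
  stage_cols <- c("length", "fpkm", "orf", "coding_score",
                  "protein_homology", "ncrna_family")
  conj <- apply(as.matrix(res[, stage_cols]), 1, all)
  expect_equal(unname(conj), res$pass)
  # the surviving set is invariant under any stage permutation
  set.seed(5)
  for (perm in 1:5) {
    cols <- sample(stage_cols)
    expect_equal(unname(apply(as.matrix(res[, cols]), 1, all)), res$pass)
  }
})

test_that("noiseless fixture cascade recovers exactly the planted lncRNAs", {
  sim <- fixture_cascade()
  res <- filter_lncrna_candidates(sim$sequences, sim$expression,
                                  hexamer_tables = fixture_hexamer_tables())
  truth <- sim$truth$labels
  expect_setequal(res$id[res$pass], truth$id[truth$label == "lncrna"])
  fates <- merge(res, truth, by = "id")
  failed <- fates[!fates$pass, ]
  expect_equal(failed$first_fail, failed$designed_fail_stage)
})

# naive O(n*m) interval arithmetic for locus classes
locus_oracle <- function(cand, genes) {
  out <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cls <- "lincRNA"
    for (j in seq_len(nrow(genes))) {
      same_chr <- cand$chrom[i] == genes$chrom[j]
      overlap <- same_chr && cand$start[i] <= genes$end[j] &&
        genes$start[j] <= cand$end[i]
      if (overlap && cand$strand[i] != genes$strand[j]) cls <- "lncNAT"
    }
    if (cls == "lincRNA") {
      for (j in seq_len(nrow(genes))) {
        if (cand$chrom[i] == genes$chrom[j] &&
            cand$strand[i] == genes$strand[j] &&
            genes$start[j] <= cand$start[i] &&
            genes$end[j] >= cand$end[i]) cls <- "intragenic"
      }
    }
    out[i] <- cls
  }
  out
}

test_that("locus classification matches the brute-force overlap oracle", {
  genes <- data.frame(transcript_id = c("g1", "g2"),
                      gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(1000L, 50000L), end = c(5000L, 60000L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  inside_nat <- data.frame(transcript_id = "c1", chrom = "chr1",
                           start = 2000L, end = 2500L, strand = "-",
                           stringsAsFactors = FALSE)
  expect_equal(classify_by_locus(inside_nat, genes)$class, "lncNAT")
  far <- data.frame(transcript_id = "c2", chrom = "chr1",
                    start = 150000L, end = 150500L, strand = "+",
                    stringsAsFactors = FALSE)
  expect_equal(classify_by_locus(far, genes)$class, "lincRNA")
  set.seed(12)
  cand <- data.frame(transcript_id = sprintf("c%03d", 1:200),
                     chrom = "chr1",
                     start = sample(1:80000, 200), stringsAsFactors = FALSE)
  cand$end <- cand$start + sample(200:2000, 200, replace = TRUE)
  cand$strand <- sample(c("+", "-"), 200, replace = TRUE)
  got <- classify_by_locus(cand, genes)
  expect_equal(got$class[match(cand$transcript_id, got$transcript_id)],
               locus_oracle(cand, genes))
})

test_that("strand-less candidates are flagged and never called lncNAT", {
  genes <- data.frame(transcript_id = "g1", gene_id = "g1", chrom = "chr1",
                      start = 1000L, end = 5000L, strand = "+",
                      stringsAsFactors = FALSE)
  cand <- data.frame(transcript_id = "c1", chrom = "chr1",
                     start = 2000L, end = 2500L, strand = ".",
                     stringsAsFactors = FALSE)
  got <- classify_by_locus(cand, genes)
  expect_true(got$no_strand)
  expect_false(got$class == "lncNAT")
})

test_that("feature summaries report the fixture's designed composition", {
  expect_equal(summarize_lncrna_features(
    c(a = strrep("A", 300), b = strrep("A", 500)))$mean_length, 400)
  sim <- fixture_training()
  lab <- sim$truth$labels
  lnc <- sim$sequences[lab$id[lab$label == "lncrna"]]
  cod <- sim$sequences[lab$id[lab$label == "coding"]]
  sm <- summarize_lncrna_features(lnc, models = sim$models,
                                  coding_reference = cod)
  expect_gt(sm$composition$mean_au_pct[sm$composition$set == "lncRNA"],
            sm$composition$mean_au_pct[sm$composition$set == "coding"])
  # fixture transcripts are mono-exonic by construction
  expect_equal(sm$exon_distribution$exons, "1")
  expect_error(summarize_lncrna_features(character(0)), "empty")
})
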