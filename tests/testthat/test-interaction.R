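test_that("expectation scoring: perfect site 0, wobble and seed doubling", {
  mi <- "UGGACGAGGAUCUAGCUAGCU"
  ut <- paste0("CCCC", chartr("U", "T", revcomp_rna(mi)), "AAAA")
  hits <- mirna_target_scan(c(m = mi), c("g|3UTR" = ut))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$expectation, 0)
  expect_equal(hits$region, "3UTR")
  # G:U at miRNA position 3 (inside 2-13): 0.5 doubled = 1.0
  rc <- strsplit(revcomp_rna(mi), "")[[1]]
  mch <- strsplit(mi, "")[[1]]
  # target base faces position 3 at rc index length-3+1 = 19
  stopifnot(mch[3] == "G") # G:U needs a G or U on the miRNA side
  rc[length(rc) - 3 + 1] <- "U"
  ut2 <- paste(rc, collapse = "")
  h2 <- mirna_target_scan(c(m = mi), c(g = ut2))
  expect_equal(h2$expectation, 1.0)
  expect_error(mirna_target_scan(character(0), c(g = ut)), "empty")
})

test_that("window scores equal the all-alignments brute-force scorer", {
  p <- target_scan_params()
  set.seed(14)
  for (i in 1:12) {
    mi <- random_rna_str(21)
    ut <- random_rna_str(45)
    ora <- lncmir:::target_scan_bruteforce_scores(mi, ut, p)
    mch <- strsplit(mi, "")[[1]]
    tch <- strsplit(ut, "")[[1]]
    dp <- vapply(seq_len(45), function(e) {
      if (e < 21) return(NA_real_)
      lncmir:::expectation_score_at(mch, tch, e, p)
    }, numeric(1))
    comparable <- !is.na(dp) & !is.na(ora)
    expect_equal(dp[comparable], ora[comparable], tolerance = 1e-12)
  }
})

test_that("reported sites are non-overlapping, best first", {
  mi <- "UGGACGAGGAUCUAGCUAGCU"
  site <- chartr("U", "T", revcomp_rna(mi))
  ut <- paste0(site, "CCCCC", site)
  h <- mirna_target_scan(c(m = mi), c(g = ut))
  expect_equal(nrow(h), 2)
  expect_true(all(h$expectation == 0))
  expect_true(h$site_end[1] < h$site_start[2] || h$site_end[2] < h$site_start[1])
})

# naive all-pairs distance check
cis_oracle <- function(lnc, genes, window) {
  out <- list()
  for (i in seq_len(nrow(lnc))) for (j in seq_len(nrow(genes))) {
    if (lnc$chrom[i] != genes$chrom[j]) next
    gap <- max(0, max(lnc$start[i], genes$start[j]) -
                 min(lnc$end[i], genes$end[j]) - 1)
    if (gap <= window) {
      out[[length(out) + 1]] <- data.frame(lncrna_id = lnc$transcript_id[i],
                                           gene_id = genes$gene_id[j])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(lncrna_id = character(0), gene_id = character(0))
}

test_that("cis targets respect the 10 kb window", {
  lnc <- data.frame(transcript_id = "L1", chrom = "chr1", start = 100000L,
                    end = 101000L, strand = "+", stringsAsFactors = FALSE)
  genes <- data.frame(transcript_id = c("g1", "g2"),
                      gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(106000L, 116001L), end = c(108000L, 118000L),
                      strand = "+", stringsAsFactors = FALSE)
  got <- lncrna_cis_targets(lnc, genes)
  expect_equal(got$gene_id, "g1") # 5 kb away in, 15 kb away out
  set.seed(23)
  lnc2 <- data.frame(transcript_id = sprintf("L%02d", 1:30), chrom = "chr1",
                     start = sample(1:200000, 30), strand = "+",
                     stringsAsFactors = FALSE)
  lnc2$end <- lnc2$start + 500L
  genes2 <- data.frame(transcript_id = sprintf("g%02d", 1:30),
                       gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
                       start = sample(1:200000, 30), strand = "+",
                       stringsAsFactors = FALSE)
  genes2$end <- genes2$start + 2000L
  got2 <- lncrna_cis_targets(lnc2, genes2)
  ora <- cis_oracle(lnc2, genes2, 10000)
  key <- function(d) sort(paste(d$lncrna_id, d$gene_id))
  expect_equal(key(got2), key(ora))
})

test_that("trans targets require a long near-perfect complement", {
  set.seed(44)
  lnc <- random_rna_str(300)
  # mRNA with a 60 nt exact reverse complement of lncRNA positions 101-160
  insert <- revcomp_rna(substr(lnc, 101, 160))
  mrna <- paste0(random_rna_str(80), insert, random_rna_str(80))
  got <- lncrna_trans_targets(c(L = lnc), c(M = mrna))
  expect_gte(nrow(got), 1)
  expect_lte(got$energy[1], -50)
  expect_gte(got$identity[1], 0.95)
  # no complementary stretch at all
  none <- lncrna_trans_targets(c(L = strrep("A", 200)),
                               c(M = strrep("A", 200)))
  expect_equal(nrow(none), 0)
  # cis-window genes are excluded
  cis <- data.frame(lncrna_id = "L", gene_id = "M")
  excl <- lncrna_trans_targets(c(L = lnc), c(M = mrna),
                               exclude_gene_ids = cis)
  expect_equal(nrow(excl), 0)
})

test_that("identity gate keeps 97% spans and the planted site survives mismatches", {
  set.seed(45)
  lnc <- random_rna_str(300)
  insert <- strsplit(revcomp_rna(substr(lnc, 101, 200)), "")[[1]]
  # 3 substitutions in 100 nt -> 97% identity
  pos <- c(30, 55, 80)
  for (k in pos) insert[k] <- lncmir:::complement_rna(insert[k])
  mrna <- paste0(random_rna_str(50), paste(insert, collapse = ""),
                 random_rna_str(50))
  got <- lncrna_trans_targets(c(L = lnc), c(M = mrna))
  expect_gte(nrow(got), 1)
  expect_gte(max(got$identity), 0.95)
})

test_that("planted eTM sites are accepted and single-rule violations named", {
  cfg <- simulation_config(seed = 21)
  set.seed(77)
  mi <- random_rna_str(21)
  host <- lncmir:::random_dna(300, c(.35, .15, .15, .35))
  pl <- plant_etm_site(mi, host, cfg)
  found <- detect_etm(mi, pl$sequence)
  expect_true(any(found$site_start == pl$site_start &
                    found$bulge_len == pl$bulge_len &
                    found$bulge_pos == pl$bulge_pos))
  # R3 violation: break a seed pair at miRNA position 5
  lch <- strsplit(pl$sequence, "")[[1]]
  n <- nchar(mi)
  seed5 <- pl$site_start + n + pl$bulge_len - 5 # partner of position 5
  lch[seed5] <- chartr("ACGT", "GGAA", lch[seed5]) # never pairs with original partner
  ev <- evaluate_etm_site(mi, paste(lch, collapse = ""), pl$site_start,
                          pl$bulge_len, pl$bulge_pos)
  expect_false(ev$rule_trace["r3_seed_wc"])
  # R1 violation: bulge outside positions 9-12
  ev1 <- evaluate_etm_site(mi, pl$sequence, pl$site_start, pl$bulge_len, 5)
  expect_false(ev1$rule_trace["r1_single_bulge"])
  # R2 violation: overlong bulge
  ev2 <- evaluate_etm_site(mi, paste0(pl$sequence, "AAAA"), pl$site_start,
                           5, pl$bulge_pos)
  expect_false(ev2$rule_trace["r2_bulge_len"])
  # R4 violation: three non-seed mismatches
  lch2 <- strsplit(pl$sequence, "")[[1]]
  for (i in c(14, 16, 18)) {
    pp <- pl$site_start + n - i # partner of position i > bulge_pos
    lch2[pp] <- switch(substr(mi, i, i), A = "G", C = "T", G = "G", U = "T")
  }
  ev4 <- evaluate_etm_site(mi, paste(lch2, collapse = ""), pl$site_start,
                           pl$bulge_len, pl$bulge_pos)
  expect_false(ev4$rule_trace["r4_mm_gu"])
})

test_that("eTM detector equals the brute-force oracle on random pairs", {
  set.seed(88)
  for (i in 1:60) {
    mi <- random_rna_str(21)
    ln <- random_rna_str(200)
    expect_equal(sort_sites(detect_etm(mi, ln)),
                 sort_sites(etm_bruteforce_oracle(mi, ln)), info = i)
  }
  # host shorter than the miRNA
  expect_equal(nrow(detect_etm(random_rna_str(21), random_rna_str(10))), 0)
  expect_error(detect_etm(random_rna_str(10), random_rna_str(100)),
               "shorter than 13")
})

test_that("interaction network export writes typed edges and round-trips", {
  th <- data.frame(mirna_id = "m1", target_id = c("g1", "g2", "g3"),
                   region = "5UTR", site_start = 1, site_end = 21,
                   expectation = 0)
  etm <- data.frame(lncrna_id = "L1", mirna_id = "m1")
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  g <- export_interaction_network(th, etm, sif_path = sif,
                                  graphml_path = gml)
  lines <- readLines(sif)
  expect_length(grep("\ttargets\t", lines), 3)
  expect_length(grep("\tmimics\t", lines), 1)
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(g))
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_setequal(igraph::V(g2)$type, c("miRNA", "mRNA", "lncRNA"))
})
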