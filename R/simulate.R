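#' Configuration of the synthetic transcriptome generator
#'
#' Defines the study conditions emulated by the fixtures: a ten-sample
#' stage design (leaf; flower bud at 0 days after anthesis; seed at
#' 5/10/20/30 days; pod at 5/10/20/30 days), planted coding / lncRNA /
#' decoy transcripts, stem-loop precursors harbouring known matures,
#' lncRNAs carrying rule-conformant eTM sites, and a stage-wise FPKM
#' matrix with planted fold changes and lncRNA-target correlations.
#'
#' @param seed integer RNG seed
#' @param n_coding,n_lncrna,n_decoy transcript class counts
#' @param n_hairpins planted precursor transcripts
#' @param n_hairpin_decoys composition-shuffled precursor decoys
#' @param n_etm_sites planted endogenous-target-mimic sites
#' @param n_target_sites planted perfect miRNA sites in synthetic UTRs
#' @param n_de lncRNAs planted as differentially expressed
#' @param n_corr_pairs (lncRNA, mRNA) pairs planted with correlation
#'   `planted_rho`
#' @param stages ordered sample labels (>= 2)
#' @param reference_stage reference for fold changes (default the 0 DAA bud)
#' @param contrast_stage stage carrying the planted fold change
#' @param noise_sd lognormal sigma of multiplicative expression noise
#' @param planted_log2fc planted log2 fold change effect size
#' @param planted_rho planted Pearson correlation of pair profiles
#' @param profile_sd per-stage log2 profile spread of correlated pairs
#' @param base_fpkm baseline FPKM of expressed transcripts
#' @param mature_len planted mature miRNA length (nt, within 14-25)
#' @param star_substitutions pairing-breaking substitutions planted in the
#'   miRNA* arm (must be <= 6 for viable precursors)
#' @param flank_len,loop_len precursor flank and terminal loop lengths (nt)
#' @param bulge_len,bulge_pos planted eTM bulge length and position
#' @param intergenic_gap genomic spacing between planted loci (nt)
#' @param max_retries resampling attempts for self-validating planters
#' @return validated list of class `simulation_config`
#' @export
simulation_config <- function(seed = 1L,
                              n_coding = 20L, n_lncrna = 20L, n_decoy = 10L,
                              n_hairpins = 30L, n_hairpin_decoys = 300L,
                              n_etm_sites = 20L, n_target_sites = 10L,
                              n_de = 10L, n_corr_pairs = 20L,
                              stages = c("leaf", "DAA0", "DAS5", "DAS10",
                                         "DAS20", "DAS30", "DAP5", "DAP10",
                                         "DAP20", "DAP30"),
                              reference_stage = "DAA0",
                              contrast_stage = stages[length(stages)],
                              noise_sd = 0.25, planted_log2fc = 2,
                              planted_rho = 0.9, profile_sd = 1.5,
                              base_fpkm = 100,
                              mature_len = 21L, star_substitutions = 2L,
                              flank_len = 8L, loop_len = 6L,
                              bulge_len = 3L, bulge_pos = 10L,
                              intergenic_gap = 12000L, max_retries = 50L) {
  cfg <- list(seed = as.integer(seed), n_coding = as.integer(n_coding),
              n_lncrna = as.integer(n_lncrna), n_decoy = as.integer(n_decoy),
              n_hairpins = as.integer(n_hairpins),
              n_hairpin_decoys = as.integer(n_hairpin_decoys),
              n_etm_sites = as.integer(n_etm_sites),
              n_target_sites = as.integer(n_target_sites),
              n_de = as.integer(n_de), n_corr_pairs = as.integer(n_corr_pairs),
              stages = stages, reference_stage = reference_stage,
              contrast_stage = contrast_stage,
              noise_sd = noise_sd, planted_log2fc = planted_log2fc,
              planted_rho = planted_rho, profile_sd = profile_sd,
              base_fpkm = base_fpkm, mature_len = as.integer(mature_len),
              star_substitutions = as.integer(star_substitutions),
              flank_len = as.integer(flank_len),
              loop_len = as.integer(loop_len),
              bulge_len = as.integer(bulge_len),
              bulge_pos = as.integer(bulge_pos),
              intergenic_gap = as.integer(intergenic_gap),
              max_retries = as.integer(max_retries))
  counts <- cfg[c("n_coding", "n_lncrna", "n_decoy", "n_hairpins",
                  "n_hairpin_decoys", "n_etm_sites", "n_target_sites",
                  "n_de", "n_corr_pairs")]
  if (any(unlist(counts) < 0)) stop("all counts must be >= 0")
  if (length(stages) < 2) stop("need at least 2 stages")
  if (anyDuplicated(stages)) stop("stage labels must be unique")
  if (abs(planted_rho) > 1) stop("planted_rho must lie in [-1, 1]")
  if (!(reference_stage %in% stages) || !(contrast_stage %in% stages)) {
    stop("reference/contrast stage must be among the stage labels")
  }
  structure(cfg, class = "simulation_config")
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# strongly biased sense-codon pool: one preferred codon per residue class
# dominates, giving coding sequences a distinctive hexamer signature
codon_pool <- local({
  bases <- c("A", "C", "G", "T")
  all_codons <- do.call(paste0, expand.grid(bases, bases, bases,
                                            stringsAsFactors = FALSE))
  sense <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  w <- ifelse(substr(sense, 3, 3) %in% c("C", "G"), 4, 0.4)
  list(codons = sense, weights = w / sum(w))
})

random_coding_sequence <- function(n_codons, utr5, utr3) {
  body <- paste(sample(codon_pool$codons, n_codons, replace = TRUE,
                       prob = codon_pool$weights), collapse = "")
  paste0(random_dna(utr5), "ATG", body, sample(c("TAA", "TAG", "TGA"), 1),
         random_dna(utr3))
}

AU_RICH <- c(0.35, 0.15, 0.15, 0.35) # A, C, G, T

#' Simulate a transcript set with planted class labels
#'
#' Coding transcripts carry a biased-codon ORF of at least 100 amino acids
#' flanked by short UTRs; lncRNA-like transcripts are AU-rich with every
#' ORF shorter than 100 amino acids; decoys are mononucleotide shuffles of
#' coding transcripts. Transcripts are laid out as mono-exonic loci on a
#' synthetic chromosome, lncRNAs on alternating strands. Deterministic
#' given the config seed.
#'
#' @param config a [simulation_config()]
#' @return list with `sequences` (named DNA strings), `models` (exon-level
#'   data.frame), `truth` (list with `labels` data.frame)
#' @export
simulate_transcriptome <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_coding + config$n_lncrna + config$n_decoy == 0) {
    stop("zero total records requested")
  }
  set.seed(config$seed)
  out <- simulate_transcriptome_impl(config)
  out
}

simulate_transcriptome_impl <- function(config) {
  seqs <- character(0)
  labels <- list()
  add <- function(id, seq, label, fate) {
    seqs[[id]] <<- seq
    labels[[length(labels) + 1]] <<- data.frame(
      id = id, label = label, designed_fail_stage = fate,
      stringsAsFactors = FALSE)
  }
  coding_ids <- sprintf("CODING_%03d", seq_len(config$n_coding))
  for (id in coding_ids) {
    add(id, random_coding_sequence(sample(120:250, 1), sample(30:80, 1),
                                   sample(50:120, 1)),
        "coding", "orf")
  }
  for (i in seq_len(config$n_lncrna)) {
    for (attempt in seq_len(config$max_retries)) {
      s <- random_dna(sample(300:1200, 1), AU_RICH)
      if (longest_orf(s)$longest_orf_aa < 100) break
      s <- NULL
    }
    if (is.null(s)) stop("failed to draw an ORF-free lncRNA")
    add(sprintf("LNC_%03d", i), s, "lncrna", NA_character_)
  }
  for (i in seq_len(config$n_decoy)) {
    src <- seqs[[coding_ids[(i - 1) %% config$n_coding + 1]]]
    add(sprintf("DECOY_%03d", i), shuffle_sequence(src), "decoy", "fpkm")
  }
  labels <- do.call(rbind, labels)
  models <- layout_models(seqs, labels)
  list(sequences = seqs, models = models,
       truth = list(labels = labels))
}

# sequential mono-exonic layout on one synthetic chromosome; lncRNAs get
# alternating strands so minus-strand splicing is exercised downstream
layout_models <- function(seqs, labels) {
  ids <- names(seqs)
  if (length(ids) == 0) {
    return(data.frame(transcript_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  }
  len <- nchar(seqs)
  gap <- attr(seqs, "gap") %||% 12000L
  starts <- cumsum(c(1L, head(len + gap, -1)))
  lnc_idx <- which(labels$label[match(ids, labels$id)] == "lncrna")
  strand <- rep("+", length(ids))
  strand[lnc_idx[seq_along(lnc_idx) %% 2 == 0]] <- "-"
  data.frame(transcript_id = ids,
             gene_id = paste0(ids, "_g"),
             chrom = "chr1", start = starts, end = starts + len - 1L,
             strand = strand, stringsAsFactors = FALSE)
}

# substitute star positions with bases that can form neither a Watson-Crick
# nor a G:U pair with the mature position they face
nonpairing_base <- function(mature_base) {
  switch(mature_base,
         A = sample(c("A", "C", "G"), 1),
         C = sample(c("A", "C", "T"), 1),
         G = sample(c("A", "G"), 1),
         T = sample(c("C", "T"), 1),
         sample(DNA_BASES, 1))
}

#' Plant a stem-loop precursor around a mature miRNA
#'
#' Builds a precursor as 5' flank + mature + terminal loop + near-reverse-
#' complement star + 3' flank. Star substitutions (the configured count)
#' are placed at random non-terminal positions and always break pairing
#' (never create a G:U wobble), so the planted mature:star mismatch count
#' is what was asked for. The precursor is self-validating: it must pass
#' [validate_hairpin()] at default thresholds and carry an SSR signature
#' R >= 2.5 against its own family; otherwise flanks, loop, and
#' substitution placement are resampled up to `max_retries` times before
#' erroring.
#'
#' @param mature mature miRNA sequence (14-25 nt)
#' @param config a [simulation_config()]
#' @param model an [energy_model()]
#' @return list with `precursor` (DNA string), `mature_offset` (0-based),
#'   `arm`, `star` span (1-based), and the `hairpin_candidate` validation
#' @export
plant_hairpin_precursor <- function(mature, config = simulation_config(),
                                    model = default_energy_model()) {
  mature <- as_rna(mature, allow_n = FALSE)
  mlen <- nchar(mature)
  if (mlen < 14 || mlen > 25) stop("mature length outside 14-25 nt")
  mature_dna <- chartr("U", "T", mature)
  mchars <- seq_chars(mature_dna)
  thr <- hairpin_thresholds()
  for (attempt in seq_len(config$max_retries)) {
    star <- rev(chartr("ACGT", "TGCA", mchars)) # reverse complement chars
    if (config$star_substitutions > 0) {
      # keep the stem ends intact so the duplex stays anchored
      interior <- 3:(mlen - 2)
      pos <- sample(interior, min(config$star_substitutions,
                                  length(interior)))
      for (sp in pos) {
        # star position sp faces mature position mlen - sp + 1
        star[sp] <- nonpairing_base(mchars[mlen - sp + 1])
      }
    }
    precursor <- paste0(random_dna(config$flank_len, AU_RICH),
                        mature_dna,
                        random_dna(config$loop_len, c(.4, .1, .1, .4)),
                        paste(star, collapse = ""),
                        random_dna(config$flank_len, AU_RICH))
    hc <- validate_hairpin(precursor, config$flank_len, mlen,
                           thresholds = thr, model = model)
    r <- ssr_signature_score(mature, mature)
    if (hc$pass && r >= thr$min_ssr_r) {
      return(list(precursor = precursor, mature_offset = config$flank_len,
                  mature_len = mlen, arm = hc$arm, star = hc$star,
                  ssr_r = r, validation = hc))
    }
  }
  stop("failed to plant a passing hairpin after ", config$max_retries,
       " attempts (mature ", mature, ")")
}

#' Plant an endogenous-target-mimic site in a host lncRNA
#'
#' Inserts a site that pairs the miRNA perfectly except for one lncRNA-side
#' bulge of the configured length opposite the configured position
#' (default 3 nt between positions 10 and 11). The modified host is
#' self-validating: [detect_etm()] must report the planted site, else the
#' insertion point and bulge fill are resampled.
#'
#' @param mirna miRNA sequence (>= 13 nt)
#' @param host_lncrna host sequence (DNA or RNA alphabet)
#' @param config a [simulation_config()]
#' @return list with `sequence` (modified host, DNA), `site_start` (1-based),
#'   `site_end`, `bulge_len`, `bulge_pos`
#' @export
plant_etm_site <- function(mirna, host_lncrna, config = simulation_config()) {
  mirna <- as_rna(mirna, allow_n = FALSE)
  n <- nchar(mirna)
  if (n < 13) stop("miRNA shorter than 13 nt")
  b <- config$bulge_len
  p <- config$bulge_pos
  host <- chartr("U", "T", toupper(host_lncrna))
  site_len <- n + b
  if (nchar(host) < site_len + 2) stop("host too short to accept the site")
  rc <- chartr("U", "T", revcomp_rna(mirna))
  for (attempt in seq_len(config$max_retries)) {
    bulge_fill <- random_dna(b)
    site <- paste0(substr(rc, 1, n - p), bulge_fill,
                   substr(rc, n - p + 1, n))
    s <- sample.int(nchar(host) - site_len + 1, 1)
    mod <- paste0(substr(host, 1, s - 1), site,
                  substr(host, s + site_len, nchar(host)))
    found <- detect_etm(mirna, mod)
    hit <- found[found$site_start == s & found$bulge_len == b &
                   !is.na(found$bulge_pos) & found$bulge_pos == p, ]
    if (nrow(hit) == 1) {
      return(list(sequence = mod, site_start = s, site_end = s + site_len - 1,
                  bulge_len = b, bulge_pos = p))
    }
  }
  stop("failed to plant a detectable eTM site after ", config$max_retries,
       " attempts")
}

#' Simulate the stage-wise expression matrix
#'
#' Lognormal FPKM around a common baseline. Designed decoys sit at FPKM 0.5
#' (their planted cascade fate). DE-designated transcripts carry the
#' planted log2 fold change at the contrast stage relative to the reference
#' stage; correlation-designated (lncRNA, target) pairs receive per-stage
#' log2 profiles drawn with correlation `planted_rho` across the
#' non-reference, non-leaf stages. Deterministic given the config seed.
#'
#' @param truth truth list from [simulate_dataset()] /
#'   [simulate_transcriptome()] (uses `labels`, `de`, `corr_pairs`)
#' @param config a [simulation_config()]
#' @param ids transcript ids to emit (default: the label table's)
#' @return FPKM matrix, rows = transcripts, columns = stages
#' @export
simulate_expression_matrix <- function(truth, config = simulation_config(),
                                       ids = truth$labels$id) {
  if (length(config$stages) < 2) stop("fewer than 2 stages")
  set.seed(config$seed + 104729L) # decouple from sequence generation
  stages <- config$stages
  mat <- matrix(config$base_fpkm, nrow = length(ids), ncol = length(stages),
                dimnames = list(ids, stages))
  lab <- truth$labels$label[match(ids, truth$labels$id)]
  mat[lab == "decoy", ] <- 0.5
  profile_stages <- setdiff(stages, c(config$reference_stage, stages[1]))
  if (!is.null(truth$corr_pairs) && nrow(truth$corr_pairs %||% data.frame())) {
    for (i in seq_len(nrow(truth$corr_pairs))) {
      lid <- truth$corr_pairs$lncrna_id[i]
      tid <- truth$corr_pairs$target_id[i]
      z_l <- rnorm(length(profile_stages), 0, config$profile_sd)
      z_e <- rnorm(length(profile_stages), 0, config$profile_sd)
      rho <- config$planted_rho
      z_t <- rho * z_l + sqrt(1 - rho^2) * z_e
      mat[lid, profile_stages] <- config$base_fpkm * 2^z_l
      mat[tid, profile_stages] <- config$base_fpkm * 2^z_t
    }
  }
  if (!is.null(truth$de) && nrow(truth$de %||% data.frame())) {
    mat[truth$de$id, config$contrast_stage] <-
      config$base_fpkm * 2^truth$de$planted_log2fc
  }
  noise <- matrix(stats::rlnorm(length(mat), 0, config$noise_sd),
                  nrow = nrow(mat))
  mat * noise
}

#' Simulate a complete fixture dataset with planted ground truth
#'
#' Composes the full study emulation: labelled coding/lncRNA/decoy
#' transcripts, planted stem-loop precursor transcripts with a matching
#' known-mature library, shuffled precursor decoys, eTM sites planted into
#' lncRNA hosts, synthetic UTRs carrying perfect miRNA target sites, and
#' the stage-wise expression matrix with planted DE and correlation
#' structure. All planters are self-validating; every planted entity is
#' recorded in the truth tables.
#'
#' @param config a [simulation_config()]
#' @return list of class `lncmir_simulation`: `sequences`, `models`,
#'   `known_matures`, `utrs`, `expression`, `truth` (labels, hairpins, etm,
#'   targets, de, corr_pairs), `config`
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  base <- simulate_transcriptome_impl(config)
  seqs <- base$sequences
  labels <- base$truth$labels

  # planted precursors + known-mature library
  matures <- character(0)
  hairpins <- list()
  for (i in seq_len(config$n_hairpins)) {
    rec <- NULL
    for (attempt in seq_len(config$max_retries)) {
      mature <- random_rna(config$mature_len)
      rec <- tryCatch(plant_hairpin_precursor(mature, config),
                      error = function(e) NULL)
      if (!is.null(rec)) break
    }
    if (is.null(rec)) stop("could not plant hairpin ", i)
    hid <- sprintf("HPIN_%03d", i)
    mid <- sprintf("miRsim%03d_a", i)
    matures[[mid]] <- mature
    seqs[[hid]] <- rec$precursor
    labels <- rbind(labels, data.frame(id = hid, label = "hairpin",
                                       designed_fail_stage = NA_character_,
                                       stringsAsFactors = FALSE))
    hairpins[[i]] <- data.frame(
      hairpin_id = hid, mature_id = mid, mature = mature,
      arm = rec$arm, mature_offset = rec$mature_offset,
      star_start = rec$star[1], star_end = rec$star[2],
      stringsAsFactors = FALSE)
  }
  hairpins <- if (length(hairpins)) do.call(rbind, hairpins) else NULL
  for (i in seq_len(config$n_hairpin_decoys)) {
    src <- seqs[[sprintf("HPIN_%03d", (i - 1) %% max(config$n_hairpins, 1) + 1)]]
    hid <- sprintf("HDEC_%03d", i)
    seqs[[hid]] <- shuffle_sequence(src)
    labels <- rbind(labels, data.frame(id = hid, label = "hairpin_decoy",
                                       designed_fail_stage = NA_character_,
                                       stringsAsFactors = FALSE))
  }

  # eTM sites planted into lncRNA hosts (extra hosts created if needed)
  etm <- list()
  if (config$n_etm_sites > 0) {
    if (config$n_hairpins == 0) stop("eTM planting needs planted miRNAs")
    lnc_ids <- labels$id[labels$label == "lncrna"]
    for (i in seq_len(config$n_etm_sites)) {
      if (i <= length(lnc_ids)) {
        host_id <- lnc_ids[i]
      } else {
        host_id <- sprintf("ETMLNC_%03d", i)
        for (attempt in seq_len(config$max_retries)) {
          s <- random_dna(sample(300:1200, 1), AU_RICH)
          if (longest_orf(s)$longest_orf_aa < 100) break
        }
        seqs[[host_id]] <- s
        labels <- rbind(labels, data.frame(id = host_id, label = "lncrna",
                                           designed_fail_stage = NA_character_,
                                           stringsAsFactors = FALSE))
      }
      mid <- names(matures)[(i - 1) %% length(matures) + 1]
      planted <- plant_etm_site(matures[[mid]], seqs[[host_id]], config)
      seqs[[host_id]] <- planted$sequence
      etm[[i]] <- data.frame(
        lncrna_id = host_id, mirna_id = mid,
        site_start = planted$site_start, site_end = planted$site_end,
        bulge_len = planted$bulge_len, bulge_pos = planted$bulge_pos,
        stringsAsFactors = FALSE)
    }
  }
  etm <- if (length(etm)) do.call(rbind, etm) else NULL

  # synthetic UTRs with perfect target sites
  utrs <- character(0)
  targets <- list()
  if (config$n_target_sites > 0 && config$n_hairpins > 0) {
    for (i in seq_len(config$n_target_sites)) {
      mid <- names(matures)[(i - 1) %% length(matures) + 1]
      region <- if (i %% 2 == 1) "5UTR" else "3UTR"
      uid <- sprintf("UTRGENE_%03d|%s", i, region)
      site <- chartr("U", "T", revcomp_rna(matures[[mid]]))
      u <- random_dna(200)
      at <- sample.int(200 - nchar(site) + 1, 1)
      utrs[[uid]] <- paste0(substr(u, 1, at - 1), site,
                            substr(u, at + nchar(site), 200))
      targets[[i]] <- data.frame(
        utr_id = uid, mirna_id = mid, site_start = at,
        site_end = at + nchar(site) - 1, stringsAsFactors = FALSE)
    }
  }
  targets <- if (length(targets)) do.call(rbind, targets) else NULL

  # expression truth: DE lncRNAs and correlated (lncRNA, coding) pairs
  lnc_ids <- labels$id[labels$label == "lncrna"]
  cod_ids <- labels$id[labels$label == "coding"]
  de <- NULL
  if (config$n_de > 0 && length(lnc_ids)) {
    de_ids <- lnc_ids[seq_len(min(config$n_de, length(lnc_ids)))]
    de <- data.frame(id = de_ids, contrast = paste(config$reference_stage,
                                                   "vs", config$contrast_stage),
                     planted_log2fc = config$planted_log2fc,
                     stringsAsFactors = FALSE)
  }
  corr_pairs <- NULL
  if (config$n_corr_pairs > 0 && length(lnc_ids) && length(cod_ids)) {
    # keep correlation hosts disjoint from DE-designated lncRNAs
    pool <- setdiff(lnc_ids, de$id %||% character(0))
    if (length(pool) == 0) pool <- lnc_ids
    k <- config$n_corr_pairs
    corr_pairs <- data.frame(
      lncrna_id = pool[(seq_len(k) - 1) %% length(pool) + 1],
      target_id = cod_ids[(seq_len(k) - 1) %% length(cod_ids) + 1],
      planted_rho = config$planted_rho, stringsAsFactors = FALSE)
    corr_pairs <- corr_pairs[!duplicated(corr_pairs[, 1:2]), ]
  }

  models <- layout_models(seqs, labels)
  truth <- list(labels = labels, hairpins = hairpins, etm = etm,
                targets = targets, de = de, corr_pairs = corr_pairs)
  expr <- simulate_expression_matrix(truth, config, ids = names(seqs))
  structure(list(sequences = seqs, models = models,
                 known_matures = matures, utrs = utrs,
                 expression = expr, truth = truth, config = config),
            class = "lncmir_simulation")
}

#' @export
print.lncmir_simulation <- function(x, ...) {
  cat("synthetic fixture:", length(x$sequences), "transcripts,",
      length(x$known_matures), "matures,",
      nrow(x$truth$etm %||% data.frame()), "eTM sites,",
      length(x$config$stages), "stages (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a fixture bundle to disk
#'
#' Writes the genome FASTA, transcript FASTA, GTF models, expression TSV,
#' known-mature FASTA, UTR FASTA, truth tables (TSV) and a JSON manifest
#' recording the seed, the config and per-file MD5 checksums. Re-running
#' the generator with the same config reproduces identical files.
#'
#' @param sim a [simulate_dataset()] result
#' @param dir output directory (created if missing)
#' @return the manifest, invisibly
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "lncmir_simulation"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("unwritable directory: ", dir)
  }
  paths <- list()
  wf <- function(name) {
    p <- file.path(dir, name)
    paths[[name]] <<- p
    p
  }
  write_fasta(sim$sequences, wf("transcripts.fasta"))
  write_fasta(build_genome(sim), wf("genome.fasta"))
  write_gtf_models(sim$models, wf("models.gtf"))
  write_fasta(chartr("ACGU", "ACGT", sim$known_matures),
              wf("known_matures.fasta"))
  if (length(sim$utrs)) write_fasta(sim$utrs, wf("utrs.fasta"))
  expr <- data.frame(id = rownames(sim$expression),
                     round(sim$expression, 6), check.names = FALSE)
  write.table(expr, wf("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(sim$truth)) {
    if (!is.null(sim$truth[[nm]])) {
      write.table(sim$truth[[nm]], wf(sprintf("truth_%s.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  manifest <- list(seed = sim$config$seed,
                   config = unclass(sim$config),
                   files = lapply(paths, function(p)
                     unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# assemble the synthetic chromosome implied by the model layout:
# plus-strand loci carry the transcript sequence, minus-strand loci its
# reverse complement; gaps are deterministic low-complexity filler
build_genome <- function(sim) {
  models <- sim$models
  spans <- transcript_spans(models)
  spans <- spans[order(spans$start), ]
  glen <- max(spans$end) + 100L
  genome <- rep("T", glen)
  # deterministic filler pattern avoids spending RNG state on the genome
  genome[seq(1, glen, by = 2)] <- "A"
  for (i in seq_len(nrow(spans))) {
    s <- chartr("U", "T", toupper(sim$sequences[[spans$transcript_id[i]]]))
    if (spans$strand[i] == "-") s <- chartr("U", "T", revcomp_rna(s))
    genome[spans$start[i]:spans$end[i]] <- seq_chars(s)
  }
  c(chr1 = paste(genome, collapse = ""))
}
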