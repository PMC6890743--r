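#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a named character vector to FASTA
#'
#' @param sequences named character vector
#' @param path output file
#' @return path, invisibly
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop("sequences must be named")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(sequences), path,
                              width = 70L)
  invisible(path)
}

#' Write exon-level transcript models as GTF
#'
#' One `exon` feature per row, 1-based inclusive coordinates, with
#' `gene_id` and `transcript_id` attributes.
#'
#' @param models data.frame with `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`
#' @param path output file
#' @return path, invisibly
#' @export
write_gtf_models <- function(models, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = models$chrom,
    ranges = IRanges::IRanges(models$start, models$end),
    strand = ifelse(models$strand %in% c("+", "-"), models$strand, "*"),
    type = "exon",
    gene_id = models$gene_id %||% paste0(models$transcript_id, "_g"),
    transcript_id = models$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF
#'
#' Parses exon features (1-based inclusive) into the exon-level model
#' data.frame used throughout the package. Lines failing a basic
#' nine-column / numeric-coordinate validation are reported with their line
#' number. GFF3 input is accepted: `Parent`/`ID` attributes are mapped to
#' `transcript_id`/`gene_id`.
#'
#' @param path GTF or GFF3 file
#' @return data.frame `transcript_id`, `gene_id`, `chrom`, `start`, `end`,
#'   `strand`
#' @export
read_gtf_models <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (ln in body) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GTF line ", ln, ": expected 9 tab-separated fields")
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop("malformed GTF line ", ln, ": non-numeric coordinates")
    }
  }
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- rtracklayer::import(path, format = fmt)
  gr <- gr[S4Vectors::mcols(gr)$type %in% c("exon", "Exon"), ]
  mc <- S4Vectors::mcols(gr)
  tid <- if ("transcript_id" %in% names(mc)) mc$transcript_id else
    as.character(mc$Parent)
  gid <- if ("gene_id" %in% names(mc)) mc$gene_id else
    if ("ID" %in% names(mc)) as.character(mc$ID) else tid
  if (any(is.na(tid) | !nzchar(tid))) {
    stop("GTF exons without transcript_id attribute")
  }
  data.frame(transcript_id = tid, gene_id = gid,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Load spliced transcript sequences from a genome FASTA and GTF models
#'
#' Assembles each transcript exon-by-exon from the chromosome sequence
#' (exons sorted by coordinate, concatenated, reverse-complemented for
#' minus-strand transcripts). Transcripts referring to chromosomes absent
#' from the FASTA are an error.
#'
#' @param fasta_path genome FASTA
#' @param gtf_path GTF/GFF3 transcript models
#' @return list with `models` (exon-level data.frame) and `sequences`
#'   (named character vector of spliced transcript sequences, DNA alphabet)
#' @export
load_sequences_and_models <- function(fasta_path, gtf_path) {
  genome <- read_fasta(fasta_path)
  models <- read_gtf_models(gtf_path)
  missing <- setdiff(unique(models$chrom), names(genome))
  if (length(missing)) {
    stop("FASTA/GTF id mismatch: chromosome(s) not in FASTA: ",
         paste(missing, collapse = ", "))
  }
  seqs <- vapply(split(models, models$transcript_id), function(m) {
    m <- m[order(m$start), ]
    chrom <- genome[[m$chrom[1]]]
    sp <- paste(substring(chrom, m$start, m$end), collapse = "")
    if (m$strand[1] == "-") sp <- chartr("U", "T", revcomp_rna(sp))
    sp
  }, character(1))
  list(models = models, sequences = seqs[unique(models$transcript_id)])
}

#' Load and validate a stage-wise expression table
#'
#' TSV with an `id` column and one column per stage. Duplicate transcript
#' ids, negative values, and missing required stages are errors.
#'
#' @param tsv_path expression TSV
#' @param stage_order optional required stage ordering
#' @return numeric matrix, rows = transcript ids, columns = stages
#' @export
load_expression <- function(tsv_path, stage_order = NULL) {
  df <- read.table(tsv_path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("expression table needs an 'id' column")
  if (anyDuplicated(df$id)) {
    stop("duplicate transcript id: ", df$id[duplicated(df$id)][1])
  }
  mat <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  rownames(mat) <- df$id
  if (!is.numeric(mat)) stop("non-numeric expression values")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop("negative expression value at row ", rownames(mat)[neg[1, 1]],
         ", column ", colnames(mat)[neg[1, 2]])
  }
  if (!is.null(stage_order)) {
    miss <- setdiff(stage_order, colnames(mat))
    if (length(miss)) stop("missing stage(s): ", paste(miss, collapse = ", "))
    mat <- mat[, stage_order, drop = FALSE]
  }
  mat
}

#' Pipeline configuration
#'
#' Bundles input paths, all module thresholds at their published defaults,
#' and the RNG seed. The configuration (and its hash) is serialized into
#' the run-metadata block of every pipeline output.
#'
#' @param fasta transcript FASTA path (transcript sequences, not genome)
#' @param gtf GTF models path (optional; enables locus classification and
#'   cis targets)
#' @param expression expression TSV path
#' @param known_matures known-mature FASTA path
#' @param utrs UTR FASTA path (optional; enables the miRNA target scan)
#' @param exclusion_protein,exclusion_ncrna optional plain-text ID list
#'   paths (one id per line)
#' @param out_dir output directory
#' @param seed RNG seed recorded in metadata
#' @param lncrna thresholds from [lncrna_thresholds()]
#' @param hairpin thresholds from [hairpin_thresholds()]
#' @param target_scan parameters from [target_scan_params()]
#' @param etm parameters from [etm_params()]
#' @param cis_window cis-target window (nt)
#' @param trans list of trans-target gates (`seed_len`, `min_identity`,
#'   `min_span`, `energy_cutoff`)
#' @param de list of DE gates (`fc_thresh`, `p_thresh`, `q_thresh`)
#' @param reference_stage reference stage for fold changes and correlations
#' @param contrast_stage stage contrasted against the reference for DE
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(fasta, expression, known_matures,
                            gtf = NULL, utrs = NULL,
                            exclusion_protein = NULL, exclusion_ncrna = NULL,
                            out_dir = tempfile("lncmir_run_"),
                            seed = 1L,
                            lncrna = lncrna_thresholds(),
                            hairpin = hairpin_thresholds(),
                            target_scan = target_scan_params(),
                            etm = etm_params(),
                            cis_window = 10000L,
                            trans = list(seed_len = 20L, min_identity = 0.95,
                                         min_span = 50L, energy_cutoff = -50),
                            de = list(fc_thresh = 1, p_thresh = 0.005,
                                      q_thresh = 0.01),
                            reference_stage = "DAA0",
                            contrast_stage = NULL) {
  cfg <- list(fasta = fasta, gtf = gtf, expression = expression,
              known_matures = known_matures, utrs = utrs,
              exclusion_protein = exclusion_protein,
              exclusion_ncrna = exclusion_ncrna,
              out_dir = out_dir, seed = as.integer(seed),
              lncrna = lncrna, hairpin = hairpin,
              target_scan = target_scan, etm = etm,
              cis_window = as.integer(cis_window), trans = trans, de = de,
              reference_stage = reference_stage,
              contrast_stage = contrast_stage)
  for (p in c("fasta", "expression", "known_matures", "gtf", "utrs",
              "exclusion_protein", "exclusion_ncrna")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input path does not exist: ", p, " = ", cfg[[p]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

write_tsv_out <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 10, trim = TRUE,
                                scientific = FALSE))
  })
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full discovery pipeline
#'
#' Executes the stages in order: lncRNA filter cascade (+ locus
#' classification when models are supplied), homology-seeded miRNA
#' prediction with hairpin validation, miRNA target scan over UTRs (when
#' supplied), lncRNA cis targets, eTM detection restricted to identified
#' lncRNAs x identified miRNAs, and the expression layer (DE filter against
#' the reference stage; Pearson correlation of lncRNA cis-pair fold-change
#' profiles). Writes one TSV per stage, SIF/GraphML network exports, and a
#' run-metadata JSON carrying the config and its hash. Outputs are
#' byte-identical across reruns of the same config.
#'
#' @param config a [pipeline_config()]
#' @return list of result tables (also written under `config$out_dir`)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  transcripts <- read_fasta(config$fasta)
  expr <- load_expression(config$expression)
  known <- read_fasta(config$known_matures)
  models <- if (!is.null(config$gtf)) read_gtf_models(config$gtf) else NULL
  read_ids <- function(p) if (is.null(p)) character(0) else readLines(p)
  excl <- list(protein_homology = read_ids(config$exclusion_protein),
               ncrna_family = read_ids(config$exclusion_ncrna))

  # stage 1: lncRNA cascade; hexamer tables are trained on the extremes of
  # the input itself (long-ORF transcripts vs AU-rich ORF-poor transcripts)
  orf_aa <- vapply(transcripts, function(s) longest_orf(s)$longest_orf_aa,
                   numeric(1))
  coding_like <- transcripts[orf_aa >= 100]
  noncoding_like <- transcripts[orf_aa < 30 & nchar(transcripts) >= 200]
  if (length(coding_like) < 2 || length(noncoding_like) < 2) {
    stop("too few training transcripts for the coding-potential score")
  }
  tables <- train_hexamer_tables(coding_like, noncoding_like)
  cascade <- filter_lncrna_candidates(transcripts, expr, excl,
                                      hexamer_tables = tables,
                                      thresholds = config$lncrna)
  lnc_ids <- cascade$id[cascade$pass]
  classes <- NULL
  if (!is.null(models) && length(lnc_ids)) {
    lnc_models <- models[models$transcript_id %in% lnc_ids, , drop = FALSE]
    gene_ids <- cascade$id[!cascade$pass & cascade$orf == FALSE]
    gene_models <- models[models$transcript_id %in% gene_ids, , drop = FALSE]
    if (nrow(gene_models)) {
      classes <- classify_by_locus(lnc_models, gene_models)
    }
  }

  # stage 2: miRNA prediction on the non-coding side of the input
  mir_input <- transcripts[orf_aa < 100]
  mir <- predict_mirnas(mir_input, known, thresholds = config$hairpin)

  # stage 3: interactions
  target_hits <- NULL
  if (!is.null(config$utrs) && nrow(mir$records)) {
    utrs <- read_fasta(config$utrs)
    mir_seqs <- setNames(mir$records$mature_sequence, mir$records$mature_id)
    mir_seqs <- mir_seqs[!duplicated(names(mir_seqs))]
    target_hits <- mirna_target_scan(mir_seqs, utrs, config$target_scan)
  }
  cis <- NULL
  if (!is.null(models) && length(lnc_ids)) {
    lnc_models <- models[models$transcript_id %in% lnc_ids, , drop = FALSE]
    gene_ids <- cascade$id[!cascade$pass & cascade$orf == FALSE]
    gene_models <- models[models$transcript_id %in% gene_ids, , drop = FALSE]
    if (nrow(gene_models)) {
      cis <- lncrna_cis_targets(lnc_models, gene_models, config$cis_window)
    }
  }
  trans <- NULL
  if (length(lnc_ids)) {
    mrna_ids <- cascade$id[!cascade$pass & cascade$orf == FALSE]
    if (length(mrna_ids)) {
      trans <- lncrna_trans_targets(
        transcripts[lnc_ids], transcripts[mrna_ids],
        seed_len = config$trans$seed_len,
        min_identity = config$trans$min_identity,
        min_span = config$trans$min_span,
        energy_cutoff = config$trans$energy_cutoff,
        exclude_gene_ids = if (!is.null(cis) && nrow(cis) && !is.null(models))
          data.frame(lncrna_id = cis$lncrna_id,
                     gene_id = models$transcript_id[
                       match(cis$gene_id, models$gene_id)])
        else NULL)
    }
  }
  etm_sites <- NULL
  if (length(lnc_ids) && nrow(mir$records)) {
    mir_seqs <- setNames(mir$records$mature_sequence, mir$records$mature_id)
    mir_seqs <- mir_seqs[!duplicated(names(mir_seqs))]
    rows <- list()
    for (lid in lnc_ids) {
      for (mid in names(mir_seqs)) {
        found <- detect_etm(mir_seqs[[mid]], transcripts[[lid]], config$etm,
                            collapse = TRUE)
        if (nrow(found)) {
          found$lncrna_id <- lid
          found$mirna_id <- mid
          rows[[length(rows) + 1]] <- found
        }
      }
    }
    etm_sites <- if (length(rows)) do.call(rbind, rows) else NULL
  }

  # stage 4: expression layer
  de <- NULL
  contrast <- config$contrast_stage %||% colnames(expr)[ncol(expr)]
  if (config$reference_stage %in% colnames(expr)) {
    de <- de_poisson_test(expr, config$reference_stage, contrast)
    de <- differential_filter(de, config$de$fc_thresh, config$de$p_thresh,
                              config$de$q_thresh)
  }
  correlations <- NULL
  pairs <- list()
  if (!is.null(cis) && nrow(cis) && !is.null(models)) {
    pairs[[1]] <- data.frame(lncrna_id = cis$lncrna_id,
                             target_id = models$transcript_id[
                               match(cis$gene_id, models$gene_id)])
  }
  if (!is.null(trans) && nrow(trans)) {
    pairs[[length(pairs) + 1]] <- unique(trans[, c("lncrna_id", "target_id")])
  }
  if (length(pairs) && config$reference_stage %in% colnames(expr)) {
    correlations <- correlate_pairs(expr, unique(do.call(rbind, pairs)),
                                    config$reference_stage)
  }

  # outputs
  out <- list(cascade = cascade, lncrna_classes = classes,
              mirna_records = mir$records, target_hits = target_hits,
              cis_targets = cis, trans_targets = trans,
              etm_sites = etm_sites, de = de,
              correlations = correlations)
  hash_cfg <- unclass(config)
  hash_cfg$out_dir <- NULL # outputs must not depend on where they land
  meta <- list(config = unclass(config), config_hash = config_hash(hash_cfg),
               n_input_transcripts = length(transcripts),
               n_lncrna = length(lnc_ids), n_mirna = nrow(mir$records),
               n_etm = nrow(etm_sites %||% data.frame()))
  for (nm in names(out)) {
    if (!is.null(out[[nm]]) && is.data.frame(out[[nm]])) {
      df <- out[[nm]]
      df$config_hash <- rep(meta$config_hash, nrow(df))
      write_tsv_out(df, file.path(config$out_dir, paste0(nm, ".tsv")))
    }
  }
  export_interaction_network(target_hits, etm_sites, cis,
                             sif_path = file.path(config$out_dir, "network.sif"),
                             graphml_path = file.path(config$out_dir,
                                                      "network.graphml"))
  jsonlite::write_json(meta, file.path(config$out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}
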