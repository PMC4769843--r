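# Standard-format I/O and pipeline orchestration. All outputs are written
# with fixed ordering and no timestamps so that identical inputs, config and
# seeds regenerate byte-identical files.

#' Read a multi-FASTA file
#'
#' Record ids are truncated at the first whitespace; empty records are
#' rejected. CRLF line endings are accepted.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readDNAStringSet(path)
  as_seq_set(x, paste0("FASTA ", basename(path)))
}

#' Write sequences as multi-FASTA
#'
#' @param seqs Sequence set (named character or DNAStringSet).
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_seq_set(seqs)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = width)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Write gene models as GFF3
#'
#' One `gene -> mRNA -> exon` hierarchy per model, in model-sequence
#' coordinates (1-based inclusive), plus one `match_part` feature per
#' contributing contig segment carrying a `Target` attribute
#' (`contig_id start end`, 1-based inclusive contig coordinates in seed
#' orientation) and the HSP score. Models are written in seed-id order;
#' output is deterministic.
#'
#' @param models List of `gene_model` objects from [build_gene_model()].
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path, source = "genecap") {
  models <- models[!vapply(models, is.null, logical(1))]
  ord <- order(vapply(models, `[[`, character(1), "seed_id"))
  models <- models[ord]
  lines <- "##gff-version 3"
  for (m in models) {
    if (is.null(m$blocks)) stop("model for ", m$seed_id,
                                " has no layout; use build_gene_model()")
    sid <- m$seed_id
    ref <- paste0(sid, ".model")
    L <- nchar(m$model_sequence)
    if (L < 1L) stop("empty model sequence for ", sid)
    lines <- c(lines, sprintf("##sequence-region %s 1 %d", ref, L))
    gff_row <- function(type, start1, end1, score, attrs) {
      if (start1 < 1L) stop("GFF3 coordinate < 1 for ", sid)
      sprintf("%s\t%s\t%s\t%d\t%d\t%s\t+\t.\t%s",
              ref, source, type, start1, end1, score, attrs)
    }
    lines <- c(lines,
               gff_row("gene", 1L, L, ".",
                       sprintf("ID=gene:%s;Name=%s", sid, sid)),
               gff_row("mRNA", 1L, L, ".",
                       sprintf("ID=mrna:%s;Parent=gene:%s", sid, sid)))
    b <- m$blocks
    for (i in seq_len(nrow(b))) {
      lines <- c(lines, gff_row(
        "exon", b$start[i] + 1L, b$end[i], ".",
        sprintf("ID=exon:%s.%d;Parent=mrna:%s", sid, i, sid)))
    }
    for (i in seq_len(nrow(b))) {
      lines <- c(lines, gff_row(
        "match_part", b$start[i] + 1L, b$end[i],
        as.character(b$score[i]),
        sprintf("ID=mp:%s.%d;Parent=gene:%s;Target=%s %d %d",
                sid, i, sid, b$contig_id[i], b$contig_start[i] + 1L,
                b$contig_end[i])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds of the pipeline with their defaults; a run resolves its
#' configuration by overlaying a user config file on these values.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    min_identity = 0.9, min_hsp_len = 30L, ambiguity_ratio = 0.9,
    overlap_tolerance = 15L,
    min_upstream = 100L, max_codon = 10L,
    bin_edges = c(100L, 500L, 1000L, 1500L),
    probe_len = 120L, step_first = 19L, step_rest = 29L,
    min_intron = 20L,
    rng_seed = 1L,
    contigs_fasta = NULL, seeds_fasta = NULL, cds_tsv = NULL, outdir = NULL)
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys are rejected; missing keys take their defaults. The resolved
#' configuration round-trips losslessly through the file.
#'
#' @param path Config file path.
#' @return `read_run_config()`: the resolved config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  for (k in names(user)) cfg[k] <- list(user[[k]])  # keeps explicit NULLs
  cfg
}

#' @rdname read_run_config
#' @param config Config list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[order(names(config))], path)
  invisible(path)
}

#' Run the full reconstruction pipeline in memory
#'
#' Assigns contigs to seeds, clusters them, builds and selects the best gene
#' model per seed, scores all models, and (when CDS coordinates are known)
#' extracts promoter-proximal upstream candidates and their length
#' distribution.
#'
#' @param contigs,seeds Sequence sets.
#' @param seed_cds Optional data.frame `seed_id, cds_start, cds_end`.
#' @param config Parameter list as from [default_config()].
#' @return List with `assignment`, `clusters`, `models` (named list of
#'   `gene_model`), `scores` (data.frame), `promoters`, `histogram`.
#' @export
run_pipeline <- function(contigs, seeds, seed_cds = NULL,
                         config = default_config()) {
  contigs <- as_seq_set(contigs, "contigs")
  seeds <- as_seq_set(seeds, "seeds")
  asn <- assign_contigs(contigs, seeds,
                        min_identity = config$min_identity,
                        min_hsp_len = config$min_hsp_len,
                        ambiguity_ratio = config$ambiguity_ratio)
  clusters <- cluster_by_gene(asn)
  models <- list()
  for (sid in names(clusters)) {
    h <- asn$hsps[asn$hsps$seed_id == sid &
                    asn$hsps$contig_id %in% clusters[[sid]], , drop = FALSE]
    m <- build_gene_model(sid, seeds[[sid]], h, contigs,
                          overlap_tolerance = config$overlap_tolerance)
    if (!is.null(m)) models[[sid]] <- m
  }
  scores <- do.call(rbind, lapply(models, function(m) data.frame(
    seed_id = m$seed_id,
    recovery_pct = round(m$score$recovery_pct, 4),
    union_recovery_pct = round(m$score$union_recovery_pct, 4),
    exon_overlap_pct = round(m$score$exon_overlap_pct, 4),
    fragmentation_index = m$score$fragmentation_index,
    suspect_repeat = m$suspect_repeat,
    stringsAsFactors = FALSE)))
  if (is.null(scores)) {
    scores <- data.frame(seed_id = character(0), recovery_pct = numeric(0),
                         union_recovery_pct = numeric(0),
                         exon_overlap_pct = numeric(0),
                         fragmentation_index = integer(0),
                         suspect_repeat = logical(0), stringsAsFactors = FALSE)
  }
  rownames(scores) <- NULL

  promoters <- NULL; histogram <- NULL
  if (!is.null(seed_cds) && nrow(asn$hsps)) {
    promoters <- extract_upstream_candidates(
      asn$hsps, seed_cds, min_upstream = config$min_upstream,
      max_codon = config$max_codon, contigs = contigs)
    histogram <- upstream_length_distribution(promoters,
                                              bin_edges = config$bin_edges)
  }
  list(assignment = asn, clusters = clusters, models = models,
       scores = scores, promoters = promoters, histogram = histogram)
}

#' Run the pipeline on files and write all reports
#'
#' Reads contigs and seeds from FASTA (paths in `config`), optionally a CDS
#' table (TSV: seed_id, cds_start, cds_end), runs [run_pipeline()] and writes
#' to `config$outdir`: `assignments.tsv` (the contig-to-gene index),
#' `unassigned.txt`, `gene_models.gff3`, `gene_models.fasta`,
#' `model_scores.tsv`, `promoter_candidates.tsv` and
#' `promoter_histogram.tsv` (when a CDS table is given), and the resolved
#' configuration `resolved_config.yaml`. Identical inputs and config
#' regenerate byte-identical outputs.
#'
#' @param config Config list; `contigs_fasta`, `seeds_fasta` and `outdir`
#'   are required.
#' @param quiet Suppress log messages.
#' @return The [run_pipeline()] result, invisibly.
#' @export
run_all <- function(config, quiet = FALSE) {
  for (key in c("contigs_fasta", "seeds_fasta", "outdir")) {
    if (is.null(config[[key]])) stop("config is missing ", key)
  }
  log <- function(...) if (!quiet) message("[genecap] ", ...)
  contigs <- read_fasta(config$contigs_fasta)
  seeds <- read_fasta(config$seeds_fasta)
  seed_cds <- NULL
  if (!is.null(config$cds_tsv)) {
    seed_cds <- read.table(config$cds_tsv, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "resolved_config.yaml")
  write_run_config(config, cfg_path)
  log("resolved config written (md5 ", unname(tools::md5sum(cfg_path)), ")")
  log(length(contigs), " contigs vs ", length(seeds), " seeds")

  res <- run_pipeline(contigs, seeds, seed_cds, config)
  out <- function(f) file.path(config$outdir, f)
  write_tsv(res$assignment$assignments, out("assignments.tsv"))
  writeLines(sort(res$assignment$unassigned), out("unassigned.txt"))
  write_gff3(res$models, out("gene_models.gff3"))
  if (length(res$models)) {
    write_fasta(setNames(
      vapply(res$models, `[[`, character(1), "model_sequence"),
      paste0(names(res$models), ".model")), out("gene_models.fasta"))
  } else {
    writeLines(character(0), out("gene_models.fasta"))
  }
  write_tsv(res$scores, out("model_scores.tsv"))
  if (!is.null(res$promoters)) {
    write_tsv(res$promoters[, c("seed_id", "contig_id", "upstream_length",
                                "covers_codon")],
              out("promoter_candidates.tsv"))
    write_tsv(res$histogram, out("promoter_histogram.tsv"))
  }
  log(nrow(res$scores), " gene models written to ", config$outdir)
  invisible(res)
}
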