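# Synthetic gene and capture-contig simulator. Every downstream stage is
# validated against the ground truth this module records, so generation is
# fully deterministic for a given seed (withr::with_seed keeps the caller's
# RNG state untouched).

#' Generate a synthetic multi-exon gene with known structure
#'
#' Builds a genomic sequence `flank5 | exon1 | intron1 | ... | exonN | flank3`
#' together with its spliced transcript and protein. The CDS starts with ATG,
#' ends with a stop codon, contains no internal in-frame stop, and every intron
#' begins `GT` and ends `AG`. Background composition is ~38% GC, matching the
#' GC level of conifer BAC sequence.
#'
#' @param exon_lengths Integer vector of exon lengths (nt), 5' to 3'.
#' @param intron_lengths Integer vector of intron lengths (nt);
#'   `length(intron_lengths) == length(exon_lengths) - 1`. Introns must be
#'   at least 4 nt (room for the GT...AG dinucleotides).
#' @param utr5,utr3 Untranslated transcript lengths (nt) at either end.
#'   `utr5` must fit inside the first exon and `utr3` inside the last;
#'   the CDS length `sum(exon_lengths) - utr5 - utr3` must be a positive
#'   multiple of 3 (at least 9 nt: start, one codon, stop).
#' @param flank5,flank3 Genomic flank lengths (nt) outside the transcript.
#' @param rng_seed Integer seed; identical seeds give byte-identical sequences.
#' @param gene_id Identifier for the gene.
#' @param gc Background GC fraction.
#' @return An object of class `synthetic_gene`: a list with the requested
#'   lengths, the `genomic`, `transcript` and `protein` sequences, transcript
#'   CDS coordinates (`cds_start`, `cds_end`, 0-based half-open), and 0-based
#'   genomic exon coordinates (`exon_g_start`, `exon_g_end`).
#' @examples
#' g <- make_gene(c(100, 100), 200, utr5 = 20, utr3 = 30, rng_seed = 1)
#' nchar(g$genomic)     # 400 gene body
#' nchar(g$transcript)  # 200
#' @export
make_gene <- function(exon_lengths, intron_lengths = integer(0), utr5 = 0L,
                      utr3 = 0L, flank5 = 0L, flank3 = 0L, rng_seed = 1L,
                      gene_id = "gene", gc = 0.38) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(exon_lengths) < 1L || any(exon_lengths < 1L)) {
    stop("exon_lengths must be positive")
  }
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop("need exactly length(exon_lengths) - 1 introns")
  }
  if (length(intron_lengths) && any(intron_lengths < 4L)) {
    stop("introns must be at least 4 nt (GT...AG)")
  }
  cds_len <- sum(exon_lengths) - utr5 - utr3
  if (cds_len < 9L || cds_len %% 3L != 0L) {
    stop("CDS length (sum(exons) - utr5 - utr3) must be a multiple of 3, >= 9; got ",
         cds_len)
  }
  if (utr5 >= exon_lengths[1]) stop("utr5 must be shorter than the first exon")
  if (utr3 >= exon_lengths[length(exon_lengths)]) {
    stop("utr3 must be shorter than the last exon")
  }

  withr::with_seed(rng_seed, {
    n_codon <- cds_len %/% 3L
    stops <- c("TAA", "TAG", "TGA")
    body <- character(n_codon - 2L)
    if (length(body)) {
      for (i in seq_along(body)) {
        repeat {
          cod <- random_dna(3L, gc)
          if (!cod %in% stops) break
        }
        body[i] <- cod
      }
    }
    cds <- paste0("ATG", paste(body, collapse = ""), sample(stops, 1L))
    transcript <- paste0(random_dna(utr5, gc), cds, random_dna(utr3, gc))

    ends <- cumsum(exon_lengths)
    starts <- c(0L, head(ends, -1L))
    exons <- substr0(transcript, starts, ends)
    introns <- vapply(intron_lengths, function(n) {
      s <- random_dna(n, gc)
      paste0("GT", substr(s, 3L, n - 2L), "AG")
    }, character(1))

    body_seq <- exons[1]
    for (i in seq_along(introns)) {
      body_seq <- paste0(body_seq, introns[i], exons[i + 1L])
    }
    genomic <- paste0(random_dna(flank5, gc), body_seq, random_dna(flank3, gc))
  })

  # genomic exon coordinates, 0-based half-open
  g_start <- flank5 + c(0L, cumsum(exon_lengths[-length(exon_lengths)] +
                                     intron_lengths))
  g_end <- g_start + exon_lengths

  gene <- structure(list(
    gene_id = gene_id,
    exon_lengths = exon_lengths,
    intron_lengths = intron_lengths,
    utr5 = as.integer(utr5), utr3 = as.integer(utr3),
    flank5 = as.integer(flank5), flank3 = as.integer(flank3),
    genomic = genomic,
    transcript = transcript,
    protein = translate_cds(substr0(transcript, utr5, utr5 + cds_len)),
    cds_start = as.integer(utr5),
    cds_end = as.integer(utr5 + cds_len),
    exon_g_start = g_start,
    exon_g_end = g_end,
    rng_seed = as.integer(rng_seed)
  ), class = "synthetic_gene")
  stopifnot(identical(splice_genomic(gene), gene$transcript))
  gene
}

# Re-splice the genomic sequence from the recorded exon coordinates
# (invariant check: must reproduce the transcript).
splice_genomic <- function(gene) {
  paste(substr0(gene$genomic, gene$exon_g_start, gene$exon_g_end),
        collapse = "")
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat("synthetic_gene", x$gene_id, "\n",
      " exons:  ", paste(x$exon_lengths, collapse = ","), "\n",
      " introns:", paste(x$intron_lengths, collapse = ","), "\n",
      " CDS: ", x$cds_end - x$cds_start, "nt  protein:",
      nchar(x$protein) - 1L, "aa\n", sep = " ")
  invisible(x)
}

#' Packaged asparagine synthetase (AS1) fixture gene
#'
#' A synthetic gene whose exon and intron lengths are the published structure
#' of the maritime pine *AS1* gene determined from BAC sequencing: 14 exons
#' (808, 139, 96, 142, 96, 98, 162, 81, 222, 135, 81, 87, 108, 252 nt) and 13
#' introns (225, 101, 426, 119, 88, 132, 219, 104, 87, 92, 139, 89, 95 nt).
#' The UTR split (5'UTR 500 nt, 3'UTR 225 nt) is a declared convention chosen
#' so that the CDS is 1782 nt and the protein 593 aa, the published values for
#' this gene; the UTR lengths themselves are not published. Flanks are 1000 nt
#' each and the sequence content is generated from a fixed seed.
#'
#' @return A [make_gene()] `synthetic_gene` object.
#' @examples
#' g <- as1_fixture()
#' sum(g$exon_lengths)          # 2507
#' g$cds_end - g$cds_start      # 1782
#' @export
as1_fixture <- function() {
  make_gene(
    exon_lengths = c(808L, 139L, 96L, 142L, 96L, 98L, 162L, 81L, 222L,
                     135L, 81L, 87L, 108L, 252L),
    intron_lengths = c(225L, 101L, 426L, 119L, 88L, 132L, 219L, 104L,
                       87L, 92L, 139L, 89L, 95L),
    utr5 = 500L, utr3 = 225L, flank5 = 1000L, flank3 = 1000L,
    rng_seed = 20160227L, gene_id = "AS1"
  )
}

#' Simulation configuration for capture contigs
#'
#' Scenario flags mirror the contig classes observed in real capture data:
#' exon-centred fragments (hybridization bias pulls fragments overlapping the
#' probes, i.e. the exons), fragments spanning exon/intron junctions,
#' intronless diverged pseudogene copies, contigs carrying a tandem exon
#' duplication, and contigs extending into the 5' flank (promoter capture).
#'
#' @param coverage Number of exon-centred fragments per gene (round-robin over
#'   exons, so `coverage >= n_exons` covers every exon).
#' @param fragment_mean,fragment_sd Capture fragment length distribution (nt);
#'   libraries are sheared to ~1.5 kb, so the defaults are 1500/300.
#' @param exon_fragments,junction_spanning,intronless_pseudogene,repeat_duplication,upstream_flank_capture
#'   Scenario switches.
#' @param divergence Substitution rate of the pseudogene copy.
#' @param repeat_exon 1-based index of the exon duplicated in the repeat
#'   scenario (clipped to the number of exons). While the repeat scenario is
#'   active the exon-fragment round robin skips this exon: the repeated locus
#'   is assumed to have been assembled into the single repeat-bearing contig.
#' @param flank_min,flank_max Range (nt, uniform) of 5' flank carried by the
#'   upstream-capture contig.
#' @param rng_seed Integer seed; fixed seed gives byte-identical contigs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(coverage = 30L, fragment_mean = 1500, fragment_sd = 300,
                       exon_fragments = TRUE, junction_spanning = FALSE,
                       intronless_pseudogene = FALSE, divergence = 0.05,
                       repeat_duplication = FALSE, repeat_exon = 2L,
                       upstream_flank_capture = FALSE,
                       flank_min = 0, flank_max = 1500, rng_seed = 1L) {
  stopifnot(coverage >= 0, fragment_mean > 0, fragment_sd >= 0,
            divergence >= 0, divergence <= 1, flank_min >= 0,
            flank_max >= flank_min)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate capture contigs over a synthetic gene
#'
#' Emits contigs for each enabled scenario in `config` together with a truth
#' table recording, per contig, the scenario, the true source interval on the
#' genomic sequence (0-based half-open; `NA` for the spliced pseudogene copy)
#' and the strand the contig was emitted on.
#'
#' @param gene A [make_gene()] object.
#' @param config A [sim_config()] object.
#' @return List with `contigs` (named character vector) and `truth`
#'   (data.frame: contig_id, scenario, start, end, strand, detail).
#' @export
simulate_capture_contigs <- function(gene, config = sim_config()) {
  stopifnot(inherits(gene, "synthetic_gene"), inherits(config, "sim_config"))
  n_ex <- length(gene$exon_lengths)
  glen <- nchar(gene$genomic)
  contigs <- character(0)
  truth <- list()
  ctr <- 0L

  emit <- function(seq, scenario, start, end, strand, detail) {
    ctr <<- ctr + 1L
    id <- sprintf("%s_c%03d", gene$gene_id, ctr)
    if (strand == "-") seq <- revcomp(seq)
    contigs[id] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      contig_id = id, scenario = scenario, start = start, end = end,
      strand = strand, detail = detail, stringsAsFactors = FALSE)
  }

  withr::with_seed(config$rng_seed, {
    rep_exon <- min(max(1L, as.integer(config$repeat_exon)), n_ex)

    if (config$exon_fragments && config$coverage > 0) {
      exon_pool <- seq_len(n_ex)
      if (config$repeat_duplication && n_ex > 1L) {
        exon_pool <- setdiff(exon_pool, rep_exon)
      }
      for (i in seq_len(config$coverage)) {
        e <- exon_pool[((i - 1L) %% length(exon_pool)) + 1L]
        left_max <- if (e == 1L) gene$flank5 else gene$intron_lengths[e - 1L] - 1L
        right_max <- if (e == n_ex) gene$flank3 else gene$intron_lengths[e] - 1L
        ext5 <- sample.int(max(left_max, 0L) + 1L, 1L) - 1L
        ext3 <- sample.int(max(right_max, 0L) + 1L, 1L) - 1L
        s <- gene$exon_g_start[e] - ext5
        e2 <- gene$exon_g_end[e] + ext3
        emit(substr0(gene$genomic, s, e2), "exon_fragment", s, e2,
             sample(c("+", "-"), 1L), sprintf("exon=%d", e))
      }
    }

    if (config$junction_spanning && n_ex > 1L) {
      # fragment spanning junction j covers exons j and j+1 entirely plus a
      # random extension into the bounding introns/flanks, so the intron at
      # the junction is physically contained in one contig
      for (j in seq_len(n_ex - 1L)) {
        left_max <- if (j == 1L) gene$flank5 else gene$intron_lengths[j - 1L] - 1L
        right_max <- if (j + 1L == n_ex) gene$flank3 else
          gene$intron_lengths[j + 1L] - 1L
        ext5 <- sample.int(max(left_max, 0L) + 1L, 1L) - 1L
        ext3 <- sample.int(max(right_max, 0L) + 1L, 1L) - 1L
        s <- gene$exon_g_start[j] - ext5
        e2 <- gene$exon_g_end[j + 1L] + ext3
        emit(substr0(gene$genomic, s, e2), "junction_spanning", s, e2,
             sample(c("+", "-"), 1L), sprintf("junction=%d", j))
      }
    }

    if (config$intronless_pseudogene) {
      seq <- gene$transcript
      n <- nchar(seq)
      nmut <- round(config$divergence * n)
      if (nmut > 0) {
        pos <- sample.int(n, nmut)
        v <- strsplit(seq, "", fixed = TRUE)[[1]]
        for (p in pos) {
          v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
        }
        seq <- paste(v, collapse = "")
      }
      emit(seq, "pseudogene", NA_integer_, NA_integer_,
           sample(c("+", "-"), 1L), sprintf("divergence=%g", config$divergence))
    }

    if (config$repeat_duplication) {
      e <- rep_exon
      left_max <- if (e == 1L) gene$flank5 else gene$intron_lengths[e - 1L] - 1L
      right_max <- if (e == n_ex) gene$flank3 else gene$intron_lengths[e] - 1L
      ext5 <- min(left_max, 60L)
      ext3 <- min(right_max, 60L)
      exon_seq <- substr0(gene$genomic, gene$exon_g_start[e], gene$exon_g_end[e])
      left <- substr0(gene$genomic, gene$exon_g_start[e] - ext5,
                      gene$exon_g_start[e])
      right <- substr0(gene$genomic, gene$exon_g_end[e],
                       gene$exon_g_end[e] + ext3)
      emit(paste0(left, exon_seq, exon_seq, right), "repeat_duplication",
           gene$exon_g_start[e] - ext5, gene$exon_g_end[e] + ext3,
           "+", sprintf("duplicated_exon=%d", e))
    }

    if (config$upstream_flank_capture) {
      flank_len <- min(round(runif(1, config$flank_min, config$flank_max)),
                       gene$flank5)
      s <- gene$flank5 - flank_len
      into_cds <- min(gene$exon_lengths[1] - gene$utr5, 30L + sample.int(60L, 1L))
      e2 <- gene$exon_g_start[1] + gene$utr5 + into_cds
      emit(substr0(gene$genomic, s, e2), "upstream_flank", s, e2,
           sample(c("+", "-"), 1L), sprintf("flank_len=%d", flank_len))
    }
  })

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig_id = character(0), scenario = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  list(contigs = contigs, truth = truth)
}

#' Generate a deterministic set of random synthetic genes
#'
#' Convenience generator for multi-gene simulations: each gene gets 2-6 exons
#' of 80-250 nt and introns of 80-400 nt (uniform), a 60-nt 5'UTR, a 3'UTR
#' adjusted so the CDS is a multiple of 3, and 1500-nt flanks.
#'
#' @param n_genes Number of genes.
#' @param rng_seed Integer seed; gene structures and sequences are fully
#'   determined by it.
#' @param flank Flank length (nt) on both sides.
#' @return List with `genes` (list of [make_gene()] objects), `seeds` (named
#'   character vector of transcripts) and `seed_cds` (data.frame
#'   `seed_id, cds_start, cds_end`).
#' @export
random_gene_set <- function(n_genes = 5L, rng_seed = 1L, flank = 1500L) {
  genes <- withr::with_seed(rng_seed, {
    lapply(seq_len(n_genes), function(i) {
      n_ex <- sample(2:6, 1L)
      ex <- sample(80:250, n_ex, replace = TRUE)
      it <- sample(80:400, max(n_ex - 1L, 0L), replace = TRUE)
      utr5 <- 60L
      utr3 <- 45L
      rem <- (sum(ex) - utr5 - utr3) %% 3L
      utr3 <- utr3 + rem
      make_gene(ex, it, utr5 = utr5, utr3 = utr3, flank5 = flank,
                flank3 = flank, rng_seed = sample.int(2^30, 1L),
                gene_id = sprintf("g%02d", i))
    })
  })
  seeds <- setNames(vapply(genes, `[[`, character(1), "transcript"),
                    vapply(genes, `[[`, character(1), "gene_id"))
  seed_cds <- data.frame(
    seed_id = names(seeds),
    cds_start = vapply(genes, `[[`, integer(1), "cds_start"),
    cds_end = vapply(genes, `[[`, integer(1), "cds_end"),
    stringsAsFactors = FALSE)
  list(genes = genes, seeds = seeds, seed_cds = seed_cds)
}
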