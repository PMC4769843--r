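# Exon/intron structure annotation by spliced comparison of a genomic
# sequence against its transcript, plus cross-gene structure tables and
# intron-length statistics.
#
# The annotator walks the transcript left to right, extending exact matches
# into the genomic sequence. Small genomic insertions (shorter than
# `min_intron`) and isolated substitutions are absorbed into the current exon
# (up to the configured mismatch tolerance); larger gaps are intron
# candidates. Because a spliced junction can be locally ambiguous (the first
# intron bases may coincide with the next exon's bases), candidate junction
# placements within a small shift window are ranked by: GT...AG intron
# dinucleotides first, then smallest shift, then leftmost genomic placement.

#' Annotate exon/intron structure by spliced transcript comparison
#'
#' @param genomic Character scalar genomic sequence containing the gene.
#' @param transcript Character scalar spliced transcript of that gene (the
#'   transcript must be the spliced product of the genomic sequence up to the
#'   mismatch tolerance).
#' @param cds_start,cds_end Optional CDS coordinates on the transcript
#'   (0-based half-open); used to report CDS and protein lengths.
#' @param min_intron Minimum intron length (nt); shorter genomic gaps are
#'   absorbed into the surrounding exon.
#' @param max_shift Junction ambiguity window (nt).
#' @param min_cover Minimum fraction of the transcript that must be placed,
#'   otherwise annotation fails with diagnostics.
#' @param gene_id Identifier for the output.
#' @return Object of class `gene_structure`: exon and intron lengths (genomic
#'   extents, 5' to 3'), `incomplete` flags per intron (always `FALSE` here;
#'   model-derived structures may mark unknown introns), genomic exon
#'   coordinates, `cds_len`, `protein_len` (excluding the stop codon, `NA`
#'   without CDS annotation), `span` and splice-site dinucleotides.
#' @examples
#' g <- make_gene(c(120, 90), 60, utr5 = 10, utr3 = 20, rng_seed = 7)
#' annotate_gene_structure(g$genomic, g$transcript, g$cds_start, g$cds_end)
#' @export
annotate_gene_structure <- function(genomic, transcript, cds_start = NA,
                                    cds_end = NA, min_intron = 20L,
                                    max_shift = 12L, min_cover = 0.9,
                                    gene_id = "gene") {
  genomic <- as_seq_set(setNames(unname(genomic[1]), "g"), "genomic")[[1]]
  transcript <- as_seq_set(setNames(unname(transcript[1]), "t"),
                           "transcript")[[1]]
  gi <- utf8ToInt(genomic); ti <- utf8ToInt(transcript)
  ng <- length(gi); nt <- length(ti)
  k <- min(20L, nt)
  look <- 8L   # lookahead used to confirm a substitution / resumed match

  occurrences <- function(pat, from = 1L) {
    m <- gregexpr(pat, genomic, fixed = TRUE)[[1]]
    m <- m[m >= from]
    as.integer(m)
  }

  # extend an exact match from transcript pos t0 / genomic pos g0 (1-based
  # positions where matching starts), absorbing isolated substitutions and
  # sub-min_intron genomic insertions; (t, g) track the last matched pair.
  extend <- function(t0, g0) {
    t <- t0 - 1L; g <- g0 - 1L; mism <- 0L
    repeat {
      len <- min(nt - t, ng - g)
      if (len <= 0L) break
      bad <- which(gi[(g + 1L):(g + len)] != ti[(t + 1L):(t + len)])
      if (!length(bad)) { t <- t + len; g <- g + len; break }
      adv <- bad[1L] - 1L
      t <- t + adv; g <- g + adv
      tm <- t + 1L; gm <- g + 1L   # mismatching position pair
      # substitution?
      if (tm + look <= nt && gm + look <= ng &&
          all(gi[(gm + 1L):(gm + look)] == ti[(tm + 1L):(tm + look)])) {
        mism <- mism + 1L
        t <- tm; g <- gm
        next
      }
      # small genomic insertion (< min_intron)?
      ins_found <- FALSE
      if (tm + look <= nt) {
        for (d in seq_len(min_intron - 1L)) {
          if (gm + d + look > ng) break
          if (all(gi[(gm + d):(gm + d + look)] == ti[tm:(tm + look)])) {
            g <- gm + d - 1L   # resume just before the re-match
            ins_found <- TRUE
            break
          }
        }
      }
      if (ins_found) next
      break
    }
    list(t_end = t, g_end = g, mismatches = mism)
  }

  # first exon anchor: longest-extending occurrence of the transcript prefix
  anchor <- substr(transcript, 1L, k)
  occ <- occurrences(anchor)
  if (!length(occ)) {
    stop("annotation failure: transcript prefix not found in genomic sequence")
  }
  best <- NULL
  for (g0 in occ) {
    e <- extend(1L, g0)
    if (is.null(best) || e$t_end > best$t_end) best <- c(e, g_start = g0)
  }
  exon_t_start <- 1L; exon_g_start <- best$g_start
  cur <- best
  exons <- list(); introns <- list(); splice <- list()

  repeat {
    if (cur$t_end >= nt) {   # transcript fully placed
      exons[[length(exons) + 1L]] <- c(exon_g_start, cur$g_end)
      break
    }
    # junction search with shift window
    found <- NULL
    for (s in 0:min(max_shift, cur$t_end - exon_t_start)) {
      t2 <- cur$t_end - s          # last transcript pos of this exon
      if (t2 + k > nt) next
      a <- substr(transcript, t2 + 1L, t2 + min(k, nt - t2))
      g_end <- cur$g_end - s       # genomic end of this exon for this shift
      occ2 <- occurrences(a, from = g_end + min_intron + 1L)
      for (g2 in occ2) {
        intron_seq_start <- g_end + 1L
        gtag <- (gi[intron_seq_start] == utf8ToInt("G") &&
                 gi[intron_seq_start + 1L] == utf8ToInt("T") &&
                 gi[g2 - 2L] == utf8ToInt("A") &&
                 gi[g2 - 1L] == utf8ToInt("G"))
        cand <- list(s = s, t2 = t2, g_end = g_end, g2 = g2, gtag = gtag)
        if (is.null(found) ||
            (cand$gtag && !found$gtag) ||
            (cand$gtag == found$gtag &&
             (cand$s < found$s || (cand$s == found$s && cand$g2 < found$g2)))) {
          found <- cand
        }
      }
      if (!is.null(found) && found$gtag && found$s == s) break
    }
    if (is.null(found)) break   # cannot continue the chain
    exons[[length(exons) + 1L]] <- c(exon_g_start, found$g_end)
    introns[[length(introns) + 1L]] <- found$g2 - found$g_end - 1L
    splice[[length(splice) + 1L]] <- paste0(
      substr(genomic, found$g_end + 1L, found$g_end + 2L), "..",
      substr(genomic, found$g2 - 2L, found$g2 - 1L))
    exon_t_start <- found$t2 + 1L
    exon_g_start <- found$g2
    cur <- extend(found$t2 + 1L, found$g2)
  }

  covered <- cur$t_end / nt
  if (covered < min_cover) {
    stop(sprintf(paste0("annotation failure: only %.1f%% of the transcript ",
                        "could be placed (%d exons found, stopped at ",
                        "transcript position %d)"),
                 100 * covered, length(exons), cur$t_end))
  }

  ex <- do.call(rbind, exons)
  exon_lengths <- as.integer(ex[, 2L] - ex[, 1L] + 1L)
  intron_lengths <- as.integer(unlist(introns))
  cds_len <- if (!is.na(cds_start) && !is.na(cds_end))
    as.integer(cds_end - cds_start) else NA_integer_
  protein_len <- if (!is.na(cds_len)) {
    cds <- substr(transcript, cds_start + 1L, cds_end)
    aa <- translate_cds(cds)
    nchar(sub("\\*$", "", aa))
  } else NA_integer_

  structure(list(
    gene_id = gene_id,
    exon_lengths = exon_lengths,
    intron_lengths = intron_lengths,
    incomplete = rep(FALSE, length(intron_lengths)),
    exon_g_start = as.integer(ex[, 1L] - 1L),
    exon_g_end = as.integer(ex[, 2L]),
    splice_sites = unlist(splice),
    cds_len = cds_len,
    protein_len = protein_len,
    span = sum(exon_lengths) + sum(intron_lengths)
  ), class = "gene_structure")
}

#' Construct a gene structure from known lengths
#'
#' Companion constructor for structures taken from annotation databases or
#' derived from capture gene models (where unspanned junctions leave introns
#' of unknown, "incomplete" length).
#'
#' @param gene_id Identifier.
#' @param exon_lengths,intron_lengths Lengths in nt; `NA` intron entries are
#'   marked incomplete automatically.
#' @param incomplete Logical vector flagging incomplete introns.
#' @param cds_len,protein_len Optional coding lengths.
#' @return A `gene_structure` object.
#' @export
gene_structure <- function(gene_id, exon_lengths, intron_lengths = integer(0),
                           incomplete = is.na(intron_lengths),
                           cds_len = NA_integer_, protein_len = NA_integer_) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop("need exactly length(exon_lengths) - 1 introns")
  }
  incomplete <- as.logical(incomplete) | is.na(intron_lengths)
  structure(list(gene_id = gene_id, exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths, incomplete = incomplete,
                 exon_g_start = NULL, exon_g_end = NULL, splice_sites = NULL,
                 cds_len = as.integer(cds_len),
                 protein_len = as.integer(protein_len),
                 span = sum(exon_lengths) + sum(intron_lengths)),
            class = "gene_structure")
}

#' Gene structure implied by a capture gene model
#'
#' Exon lengths are the model's segment blocks in model-sequence order;
#' introns spanned by a single contig carry their inferred length, unspanned
#' junctions are marked incomplete.
#'
#' @param model A `gene_model` from [build_gene_model()].
#' @return A `gene_structure`.
#' @export
model_structure <- function(model) {
  stopifnot(inherits(model, "gene_model"), !is.null(model$blocks))
  gene_structure(
    gene_id = paste0(model$seed_id, ".model"),
    exon_lengths = model$blocks$end - model$blocks$start,
    intron_lengths = model$introns$intron_length,
    incomplete = !model$introns$spanned)
}

#' @export
print.gene_structure <- function(x, ...) {
  cat("gene_structure", x$gene_id, "-", length(x$exon_lengths), "exons,",
      length(x$intron_lengths), "introns, span", x$span, "nt\n")
  if (!is.na(x$cds_len)) {
    cat("  CDS", x$cds_len, "nt, protein", x$protein_len, "aa\n")
  }
  invisible(x)
}

#' Compare exon/intron structures across genes
#'
#' Builds index-aligned exon-length and intron-length tables across genes,
#' with per-row equality flags. Incomplete introns are marked with `*` in the
#' printed table and excluded from the equality comparison and from
#' [intron_length_summary()].
#'
#' @param structures List of at least two `gene_structure` objects.
#' @return Object of class `structure_table`: list with `exons` and `introns`
#'   data.frames (`index`, one column per gene, `equal`), and an
#'   `incomplete` logical matrix for the introns.
#' @export
compare_structures <- function(structures) {
  stopifnot(length(structures) >= 2L,
            all(vapply(structures, inherits, logical(1), "gene_structure")))
  ids <- vapply(structures, `[[`, character(1), "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene ids in structures")

  pad <- function(x, n) c(x, rep(NA_integer_, n - length(x)))
  n_ex <- max(vapply(structures, function(s) length(s$exon_lengths),
                     integer(1)))
  n_in <- max(vapply(structures, function(s) length(s$intron_lengths),
                     integer(1)))
  exm <- vapply(structures, function(s) pad(s$exon_lengths, n_ex),
                integer(n_ex))
  inm <- vapply(structures, function(s) pad(s$intron_lengths, n_in),
                integer(n_in))
  inc <- vapply(structures, function(s) pad(ifelse(s$incomplete, 1L, 0L),
                                            n_in) == 1L, logical(n_in))
  if (n_ex == 1L) { exm <- matrix(exm, nrow = 1L) }
  if (n_in == 1L) { inm <- matrix(inm, nrow = 1L); inc <- matrix(inc, nrow = 1L) }
  if (n_in == 0L) {
    inm <- matrix(integer(0), 0L, length(ids))
    inc <- matrix(logical(0), 0L, length(ids))
  }
  colnames(exm) <- ids
  colnames(inm) <- ids; colnames(inc) <- ids

  row_equal <- function(v, skip = rep(FALSE, length(v))) {
    v <- v[!skip & !is.na(v)]
    length(v) >= 2L && length(unique(v)) == 1L
  }
  exons <- data.frame(index = seq_len(n_ex), exm,
                      equal = apply(exm, 1L, row_equal),
                      check.names = FALSE)
  introns <- if (n_in > 0L) {
    data.frame(index = seq_len(n_in), inm,
               equal = vapply(seq_len(n_in), function(i)
                 row_equal(inm[i, ], inc[i, ]), logical(1)),
               check.names = FALSE)
  } else {
    data.frame(index = integer(0), equal = logical(0))
  }
  structure(list(exons = exons, introns = introns, incomplete = inc),
            class = "structure_table")
}

#' @export
print.structure_table <- function(x, ...) {
  cat("exon lengths:\n"); print(x$exons)
  cat("intron lengths (* incomplete):\n")
  it <- x$introns
  if (nrow(it)) {
    for (cn in colnames(x$incomplete)) {
      it[[cn]] <- ifelse(!is.na(it[[cn]]) & x$incomplete[, cn],
                         paste0(it[[cn]], "*"), as.character(it[[cn]]))
    }
  }
  print(it)
  invisible(x)
}

#' Pooled intron-length statistics
#'
#' Pools the complete introns of the given structures that are at most
#' `max_len` nt and reports count, mean, median, quartiles and Tukey outliers
#' (outside 1.5 IQR from the quartiles).
#'
#' @param structures List of `gene_structure` objects (or a single one).
#' @param max_len Upper intron length bound (nt); longer introns are excluded.
#' @return Object of class `intron_stats`: list with `n, mean, median, q1,
#'   q3, outliers, n_excluded`.
#' @export
intron_length_summary <- function(structures, max_len = 2600L) {
  if (inherits(structures, "gene_structure")) structures <- list(structures)
  stopifnot(all(vapply(structures, inherits, logical(1), "gene_structure")))
  pooled <- unlist(lapply(structures, function(s)
    s$intron_lengths[!s$incomplete & !is.na(s$intron_lengths)]))
  n_all <- length(pooled)
  x <- pooled[pooled <= max_len]
  if (!length(x)) {
    return(structure(list(n = 0L, mean = NA_real_, median = NA_real_,
                          q1 = NA_real_, q3 = NA_real_, outliers = integer(0),
                          n_excluded = n_all),
                     class = "intron_stats"))
  }
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2L] - q[1L]
  structure(list(
    n = length(x), mean = mean(x), median = median(x),
    q1 = q[1L], q3 = q[2L],
    outliers = sort(x[x < q[1L] - 1.5 * iqr | x > q[2L] + 1.5 * iqr]),
    n_excluded = n_all - length(x)
  ), class = "intron_stats")
}

#' @export
print.intron_stats <- function(x, ...) {
  cat(sprintf("intron lengths: n=%d mean=%.1f median=%.1f Q1=%.1f Q3=%.1f (%d excluded)\n",
              x$n, x$mean, x$median, x$q1, x$q3, x$n_excluded))
  if (length(x$outliers)) cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
  invisible(x)
}
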