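# Gene model building: tile contig HSP segments over a seed transcript,
# score candidate tilings, select the best model, flag repeat suspects and
# optionally annotate junction support against an ortholog structure.
#
# A candidate model is a maximal set of contigs whose segments are pairwise
# compatible: any two segments from *different* contigs overlap on the seed by
# at most `overlap_tolerance` nt (multiple placements of the same contig --
# the tandem-repeat case -- always travel together). Maximal compatible sets
# are maximal cliques of the compatibility graph. Because retained segments
# are at least `min_hsp_len` (> tolerance) long, a contig compatible with a
# model always adds uncovered seed positions, so some maximal clique always
# dominates every subset under the lexicographic selection score; the oracle
# tests enumerate subsets to confirm this.

#' Build candidate gene models from a contig cluster
#'
#' @param seed_id Seed (gene) identifier.
#' @param seed_len Seed transcript length (nt), > 0.
#' @param cluster_hsps Data.frame of retained HSPs of the cluster's contigs
#'   against this seed (as produced by [assign_contigs()], filtered to one
#'   seed).
#' @param overlap_tolerance Maximum seed-level overlap (nt) between segments
#'   of different contigs within one model.
#' @return List of `gene_model` objects (possibly empty), deterministically
#'   ordered by their sorted contig-id lists. Each model carries unscored
#'   segments; see [score_model()] and [select_best_model()].
#' @export
build_candidate_models <- function(seed_id, seed_len, cluster_hsps,
                                   overlap_tolerance = 15L) {
  if (seed_len <= 0) stop("seed_len must be positive")
  h <- cluster_hsps
  if (is.null(h) || !nrow(h)) return(list())
  h <- h[h$seed_id == seed_id, , drop = FALSE]
  if (!nrow(h)) return(list())
  contig_ids <- sort(unique(h$contig_id))
  n <- length(contig_ids)
  segs <- split(h, h$contig_id)

  compatible <- function(a, b) {
    ha <- segs[[a]]; hb <- segs[[b]]
    for (i in seq_len(nrow(ha))) {
      ov <- pmin(ha$seed_end[i], hb$seed_end) - pmax(ha$seed_start[i],
                                                     hb$seed_start)
      if (any(ov > overlap_tolerance)) return(FALSE)
    }
    TRUE
  }

  if (n == 1L) {
    cliques <- list(contig_ids)
  } else {
    adj <- matrix(FALSE, n, n, dimnames = list(contig_ids, contig_ids))
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        adj[i, j] <- adj[j, i] <- compatible(contig_ids[i], contig_ids[j])
      }
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cliques <- lapply(igraph::max_cliques(g), function(v)
      sort(contig_ids[as.integer(v)]))
  }
  cliques <- unique(cliques)
  cliques <- cliques[order(vapply(cliques, paste, character(1),
                                  collapse = "\r"))]
  lapply(cliques, function(ids) {
    m <- h[h$contig_id %in% ids, , drop = FALSE]
    m <- m[order(m$seed_start, m$contig_id, m$contig_start), , drop = FALSE]
    m <- trim_tolerated_overlaps(m, overlap_tolerance)
    rownames(m) <- NULL
    structure(list(seed_id = seed_id, seed_len = as.integer(seed_len),
                   segments = m, contig_ids = ids, score = NULL,
                   suspect_repeat = NA),
              class = "gene_model")
  })
}

# Canonicalize a candidate's segments: a seed overlap within the tolerance
# between segments of different contigs is alignment jitter at a junction
# (local extension can overshoot an exon boundary by a few chance-matching
# bases), not evidence of a repeat; the shared bases are assigned to the
# upstream segment and trimmed from the downstream one (seed and contig
# coordinates move together, keeping junction arithmetic consistent).
# Same-contig multiple placements -- the tandem-repeat signal -- exceed the
# tolerance and are never trimmed.
trim_tolerated_overlaps <- function(m, overlap_tolerance) {
  if (nrow(m) < 2L) return(m)
  for (i in 2L:nrow(m)) {
    prev_end <- max(m$seed_end[seq_len(i - 1L)][
      m$contig_id[seq_len(i - 1L)] != m$contig_id[i]], -Inf)
    ov <- prev_end - m$seed_start[i]
    if (is.finite(ov) && ov > 0 && ov <= overlap_tolerance) {
      ov <- as.integer(ov)
      m$seed_start[i] <- m$seed_start[i] + ov
      m$contig_start[i] <- m$contig_start[i] + ov
      m$length[i] <- m$length[i] - ov
      m$matches[i] <- max(m$matches[i] - ov, 0L)
      m$score[i] <- max(m$score[i] - ov, 0L)
      m$identity[i] <- m$matches[i] / m$length[i]
    }
  }
  m[order(m$seed_start, m$contig_id, m$contig_start), , drop = FALSE]
}

#' Score a gene model
#'
#' Computes the selection metrics of a model over its seed:
#' * `recovery_pct`: 100 x (sum of segment seed-span lengths) / seed length,
#'   counted with multiplicity -- repeats push it above 100;
#' * `union_recovery_pct`: 100 x (seed positions covered at least once) /
#'   seed length, never above 100;
#' * `exon_overlap_pct`: 100 x (redundantly covered length) / (union length);
#' * `fragmentation_index`: number of distinct contigs in the model.
#'
#' @param model A `gene_model`.
#' @return The model with its `score` list filled in.
#' @export
score_model <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  seg <- model$segments
  if (!nrow(seg)) stop("cannot score an empty model")
  total <- sum(seg$seed_end - seg$seed_start)
  un <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(seg$seed_start + 1L, seg$seed_end))))
  model$score <- list(
    recovery_pct = 100 * total / model$seed_len,
    union_recovery_pct = 100 * un / model$seed_len,
    exon_overlap_pct = 100 * (total - un) / un,
    fragmentation_index = length(unique(seg$contig_id)))
  model
}

#' Flag repeat-suspect models
#'
#' A model whose multiplicity recovery exceeds 100% of the seed can only
#' arise from repeated placements (sequence repeats) and is flagged suspect.
#'
#' @param model A scored `gene_model`.
#' @return The model with `suspect_repeat` set.
#' @export
flag_suspect <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  if (is.null(model$score)) model <- score_model(model)
  model$suspect_repeat <- model$score$recovery_pct > 100
  model
}

# lexicographic selection key; smaller is better
model_rank_key <- function(model) {
  s <- model$score
  list(-s$union_recovery_pct, s$exon_overlap_pct, s$fragmentation_index,
       paste(model$contig_ids, collapse = "\r"))
}

#' Select the best gene model among candidates
#'
#' Lexicographic criteria: (i) highest union recovery of the seed,
#' (ii) lowest exon-level overlap percentage, (iii) lowest fragmentation
#' index; remaining ties broken by the sorted contig-id list for determinism.
#' Candidates are scored on the fly if needed.
#'
#' @param candidates List of `gene_model` objects.
#' @return The winning model, scored and repeat-flagged.
#' @export
select_best_model <- function(candidates) {
  if (!length(candidates)) {
    stop(structure(class = c("genecap_no_model", "error", "condition"),
                   list(message = "no candidate gene model", call = NULL)))
  }
  candidates <- lapply(candidates, function(m)
    if (is.null(m$score)) score_model(m) else m)
  keys <- lapply(candidates, model_rank_key)
  ord <- do.call(order, lapply(seq_len(4L), function(i)
    unlist(lapply(keys, `[[`, i))))
  flag_suspect(candidates[[ord[1]]])
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model for", x$seed_id, "-", nrow(x$segments), "segments from",
      length(x$contig_ids), "contigs\n")
  if (!is.null(x$score)) {
    cat(sprintf("  recovery %.1f%% (union %.1f%%), overlap %.1f%%, fragmentation %d%s\n",
                x$score$recovery_pct, x$score$union_recovery_pct,
                x$score$exon_overlap_pct, x$score$fragmentation_index,
                if (isTRUE(x$suspect_repeat)) ", REPEAT SUSPECT" else ""))
  }
  invisible(x)
}

# Junction/intron inference and model-sequence layout. Adjacent segments in
# seed order are joined either through the intervening contig sequence (when
# both come from the same contig: the intron is physically spanned and its
# length is contig gap minus seed gap) or through a 50-N spacer (junction not
# spanned; intron length unknown). Returns the model sequence, the exon block
# layout in model-sequence coordinates, and the inferred introns.
SPACER_N <- 50L

model_layout <- function(model, contigs, min_intron = 1L) {
  seg <- model$segments
  contigs <- as_seq_set(contigs, "contigs")
  oriented <- list()
  get_seq <- function(cid, strand) {
    key <- paste0(cid, strand)
    if (is.null(oriented[[key]])) {
      oriented[[key]] <<- oriented_sequence(contigs[[cid]], strand)
    }
    oriented[[key]]
  }
  pieces <- character(0)
  blocks <- data.frame(start = integer(0), end = integer(0),
                       contig_id = character(0), seed_start = integer(0),
                       seed_end = integer(0), contig_start = integer(0),
                       contig_end = integer(0), strand = character(0),
                       score = integer(0), stringsAsFactors = FALSE)
  introns <- data.frame(after_block = integer(0), intron_length = integer(0),
                        spanned = logical(0), stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_len(nrow(seg))) {
    if (i > 1L) {
      prev <- seg[i - 1L, ]
      cur <- seg[i, ]
      sgap <- cur$seed_start - prev$seed_end
      spanned <- identical(prev$contig_id, cur$contig_id) &&
        identical(prev$strand, cur$strand) &&
        cur$contig_start > prev$contig_end
      if (spanned) {
        gap_seq <- substr0(get_seq(cur$contig_id, cur$strand),
                           prev$contig_end, cur$contig_start)
        pieces <- c(pieces, gap_seq)
        introns <- rbind(introns, data.frame(
          after_block = i - 1L,
          intron_length = (cur$contig_start - prev$contig_end) - sgap,
          spanned = TRUE))
        pos <- pos + nchar(gap_seq)
      } else {
        pieces <- c(pieces, strrep("N", SPACER_N))
        introns <- rbind(introns, data.frame(
          after_block = i - 1L, intron_length = NA_integer_, spanned = FALSE))
        pos <- pos + SPACER_N
      }
    }
    sseq <- substr0(get_seq(seg$contig_id[i], seg$strand[i]),
                    seg$contig_start[i], seg$contig_end[i])
    pieces <- c(pieces, sseq)
    blocks <- rbind(blocks, data.frame(
      start = pos, end = pos + nchar(sseq), contig_id = seg$contig_id[i],
      seed_start = seg$seed_start[i], seed_end = seg$seed_end[i],
      contig_start = seg$contig_start[i], contig_end = seg$contig_end[i],
      strand = seg$strand[i], score = seg$score[i], stringsAsFactors = FALSE))
    pos <- pos + nchar(sseq)
  }
  list(model_sequence = paste(pieces, collapse = ""), blocks = blocks,
       introns = introns)
}

# Exact best-model search by dynamic programming over contig interval chains.
# For contigs whose retained segments merge into a single seed interval
# (contiguous capture fragments -- the usual case), a set of contigs is
# pairwise compatible iff, sorted by interval end, each contig starts no more
# than `overlap_tolerance` before the previous maximum end; every compatible
# set is therefore a chain, and the chain DP maximizing
# (union, -redundancy, -count, lexicographic ids) finds the same optimum as
# exhaustive maximal-clique enumeration in O(n^2) instead of exponential
# time. Contigs with several disjoint seed intervals are handled
# conservatively through their overall span.
best_model_chain <- function(seed_id, seed_len, h, overlap_tolerance = 15L) {
  ids <- sort(unique(h$contig_id))
  info <- lapply(ids, function(cid) {
    hc <- h[h$contig_id == cid, , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(hc$seed_start + 1L, hc$seed_end))
    un <- sum(IRanges::width(ir))
    list(id = cid, s = min(hc$seed_start), e = max(hc$seed_end), un = un,
         extra = sum(hc$seed_end - hc$seed_start) - un)
  })
  ord <- order(vapply(info, `[[`, numeric(1), "e"),
               vapply(info, `[[`, numeric(1), "s"),
               vapply(info, `[[`, character(1), "id"))
  info <- info[ord]
  n <- length(info)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$union != b$union) return(a$union > b$union)
    if (a$extra != b$extra) return(a$extra < b$extra)
    if (a$count != b$count) return(a$count < b$count)
    a$key < b$key
  }
  dp <- vector("list", n)
  best <- NULL
  for (i in seq_len(n)) {
    ci <- info[[i]]
    cand <- list(union = ci$un, extra = ci$extra, count = 1L, ids = ci$id,
                 key = ci$id, cov_end = ci$e)
    for (j in seq_len(i - 1L)) {
      cj <- dp[[j]]
      if (ci$s < cj$cov_end - overlap_tolerance) next   # incompatible
      ov <- max(0L, cj$cov_end - ci$s)
      ids2 <- c(cj$ids, ci$id)
      ext <- list(union = cj$union + ci$un - ov,
                  extra = cj$extra + ci$extra,
                  count = cj$count + 1L, ids = ids2,
                  key = paste(sort(ids2), collapse = "\r"),
                  cov_end = max(cj$cov_end, ci$e))
      if (better(ext, cand)) cand <- ext
    }
    dp[[i]] <- cand
    if (better(cand, best)) best <- cand
  }
  sel <- sort(best$ids)
  m <- h[h$contig_id %in% sel, , drop = FALSE]
  m <- m[order(m$seed_start, m$contig_id, m$contig_start), , drop = FALSE]
  m <- trim_tolerated_overlaps(m, overlap_tolerance)
  rownames(m) <- NULL
  flag_suspect(score_model(structure(
    list(seed_id = seed_id, seed_len = as.integer(seed_len), segments = m,
         contig_ids = sel, score = NULL, suspect_repeat = NA),
    class = "gene_model")))
}

#' Build, score and select the gene model for one seed
#'
#' Convenience wrapper selecting the best model and laying out its sequence:
#' segments concatenated in seed order, junctions spanned by a single contig
#' include the intervening (intronic) contig sequence, and unspanned
#' junctions are joined by a 50-N spacer. Small clusters are solved by
#' exhaustive enumeration of maximal compatible contig sets
#' ([build_candidate_models()] + [select_best_model()]); larger clusters use
#' an equivalent interval-chain dynamic program whose optimum coincides with
#' the exhaustive search for contiguous capture fragments.
#'
#' @inheritParams build_candidate_models
#' @param seed_seq Seed transcript sequence (character scalar).
#' @param contigs Sequence set containing at least the cluster's contigs.
#' @param method `"auto"` (exhaustive up to `exhaustive_limit` contigs, chain
#'   DP above), `"exhaustive"`, or `"chain"`.
#' @param exhaustive_limit Cluster size at which `"auto"` switches to the
#'   chain DP.
#' @return A scored `gene_model` with `model_sequence`, `blocks` (exon blocks
#'   in model-sequence coordinates) and `introns` (inferred intron table)
#'   attached, or `NULL` when the cluster yields no candidate.
#' @export
build_gene_model <- function(seed_id, seed_seq, cluster_hsps, contigs,
                             overlap_tolerance = 15L,
                             method = c("auto", "exhaustive", "chain"),
                             exhaustive_limit = 15L) {
  method <- match.arg(method)
  h <- cluster_hsps
  if (is.null(h) || !nrow(h)) return(NULL)
  h <- h[h$seed_id == seed_id, , drop = FALSE]
  if (!nrow(h)) return(NULL)
  n_contigs <- length(unique(h$contig_id))
  if (method == "auto") {
    method <- if (n_contigs <= exhaustive_limit) "exhaustive" else "chain"
  }
  best <- if (method == "exhaustive") {
    cands <- build_candidate_models(seed_id, nchar(seed_seq), h,
                                    overlap_tolerance)
    if (!length(cands)) return(NULL)
    select_best_model(cands)
  } else {
    best_model_chain(seed_id, nchar(seed_seq), h, overlap_tolerance)
  }
  lay <- model_layout(best, contigs)
  best$model_sequence <- lay$model_sequence
  best$blocks <- lay$blocks
  best$introns <- lay$introns
  best
}

#' Describe an ortholog exon/intron structure
#'
#' @param species,gene_id Identifiers.
#' @param exon_lengths,intron_lengths Structure of the ortholog gene (nt);
#'   `length(intron_lengths) == length(exon_lengths) - 1`.
#' @param cds_offset Offset (nt) of the CDS start within the ortholog's
#'   spliced transcript (its 5'UTR length).
#' @param cds_len CDS length (nt); defaults to the remainder of the spliced
#'   transcript after `cds_offset`.
#' @return List of class `ortholog_structure`.
#' @export
ortholog_structure <- function(species, gene_id, exon_lengths, intron_lengths,
                               cds_offset = 0L, cds_len = NULL) {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop("need exactly length(exon_lengths) - 1 introns")
  }
  if (is.null(cds_len)) cds_len <- sum(exon_lengths) - cds_offset
  structure(list(species = species, gene_id = gene_id,
                 exon_lengths = exon_lengths, intron_lengths = intron_lengths,
                 cds_offset = as.integer(cds_offset),
                 cds_len = as.integer(cds_len)),
            class = "ortholog_structure")
}

#' Annotate a gene model's junctions against an ortholog structure
#'
#' Projects the ortholog's exon boundaries onto seed transcript coordinates
#' (positions inside the ortholog CDS are scaled by the ratio of CDS lengths;
#' the seed CDS start anchors the projection) and classifies each expected
#' junction:
#' * `supported` -- the model infers a junction (adjacent segments of one
#'   contig) within `tol` nt of the projected position;
#' * `unsupported` -- the projected position lies in the interior of a
#'   single aligned segment, i.e. the evidence shows contiguous sequence
#'   where the ortholog has an intron (pseudogene-like);
#' * `missing` -- no contig spans the position, so the model carries no
#'   evidence either way.
#'
#' Guidance is annotation only: segment selection is never altered.
#'
#' @param model A `gene_model`.
#' @param ortholog An [ortholog_structure()].
#' @param seed_cds_start,seed_cds_len CDS coordinates of the seed transcript
#'   (0-based start, length in nt).
#' @param tol Matching tolerance (nt).
#' @return The model with a `guidance` data.frame attached
#'   (`junction, projected_pos, status`).
#' @export
apply_ortholog_guidance <- function(model, ortholog, seed_cds_start,
                                    seed_cds_len, tol = 10L) {
  stopifnot(inherits(model, "gene_model"),
            inherits(ortholog, "ortholog_structure"))
  n_j <- length(ortholog$exon_lengths) - 1L
  if (n_j == 0L) {
    model$guidance <- data.frame(junction = integer(0),
                                 projected_pos = integer(0),
                                 status = character(0),
                                 stringsAsFactors = FALSE)
    return(model)
  }
  orth_junc <- cumsum(ortholog$exon_lengths)[seq_len(n_j)]
  scale <- seed_cds_len / ortholog$cds_len
  projected <- vapply(orth_junc, function(p) {
    rel <- p - ortholog$cds_offset
    if (rel < 0) seed_cds_start + rel
    else if (rel > ortholog$cds_len) seed_cds_start + seed_cds_len +
      (rel - ortholog$cds_len)
    else seed_cds_start + round(rel * scale)
  }, numeric(1))

  seg <- model$segments
  model_junc <- numeric(0)
  if (nrow(seg) > 1L) {
    for (i in 2L:nrow(seg)) {
      if (identical(seg$contig_id[i], seg$contig_id[i - 1L]) &&
          identical(seg$strand[i], seg$strand[i - 1L]) &&
          seg$contig_start[i] > seg$contig_end[i - 1L]) {
        model_junc <- c(model_junc, seg$seed_end[i - 1L])
      }
    }
  }
  status <- vapply(projected, function(p) {
    if (length(model_junc) && any(abs(model_junc - p) <= tol)) return("supported")
    interior <- seg$seed_start + tol <= p & seg$seed_end - tol >= p
    if (any(interior)) "unsupported" else "missing"
  }, character(1))
  model$guidance <- data.frame(junction = seq_len(n_j),
                               projected_pos = as.integer(projected),
                               status = status, stringsAsFactors = FALSE)
  model
}
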