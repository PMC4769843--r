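# Contig-vs-seed HSP alignment, gene assignment and clustering.
#
# The aligner is a k-mer seeded, ungapped diagonal scanner: exact 12-mer
# matches nominate diagonals, each diagonal is scored +1/match, -3/mismatch,
# and all maximal positive-scoring segments are extracted and trimmed to their
# score optimum. Capture contigs come from the same species as the seeds, so
# retained segments are near-exact and an ungapped model suffices; segments
# below the identity or length threshold are dropped. HSP score is the number
# of identical bases. All coordinates are 0-based half-open; minus-strand HSPs
# report contig coordinates on the reverse-complemented ("seed orientation")
# contig, with the flip recorded in `strand`.

MISMATCH_PENALTY <- 3L

empty_hsps <- function() {
  data.frame(contig_id = character(0), seed_id = character(0),
             strand = character(0), contig_start = integer(0),
             contig_end = integer(0), seed_start = integer(0),
             seed_end = integer(0), length = integer(0), matches = integer(0),
             identity = numeric(0), score = integer(0),
             stringsAsFactors = FALSE)
}

# k-mer vector of a sequence (1-based start positions implicit in order)
kmer_vector <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

# seed-side index: kmer -> 1-based positions
seed_kmer_index <- function(seq, k) {
  km <- kmer_vector(seq, k)
  split(seq_along(km), km)
}

# Maximal positive-scoring segments along one diagonal, given the logical
# match vector. Returns a matrix with 1-based [start, end] offsets into `eq`
# and match counts. Ruzzo-Tompa style: accumulate runs, close a segment when
# the running score from its start drops below zero, trim to the score
# maximum.
diagonal_segments <- function(eq) {
  r <- rle(eq)
  out <- list()
  pos <- 0L              # 0-based offset of current run start
  seg_start <- NA_integer_
  run_score <- 0L; run_matches <- 0L
  best_score <- 0L; best_end <- NA_integer_; best_matches <- 0L
  flush <- function() {
    if (!is.na(seg_start) && best_score > 0L) {
      out[[length(out) + 1L]] <<- c(seg_start, best_end, best_matches)
    }
    seg_start <<- NA_integer_
    run_score <<- 0L; run_matches <<- 0L
    best_score <<- 0L; best_end <<- NA_integer_; best_matches <<- 0L
  }
  for (i in seq_along(r$lengths)) {
    len <- r$lengths[i]
    if (r$values[i]) {
      if (is.na(seg_start)) seg_start <- pos
      run_score <- run_score + len
      run_matches <- run_matches + len
      if (run_score > best_score) {
        best_score <- run_score
        best_end <- pos + len
        best_matches <- run_matches
      }
    } else if (!is.na(seg_start)) {
      run_score <- run_score - MISMATCH_PENALTY * len
      if (run_score < 0L) flush()
    }
    pos <- pos + len
  }
  flush()
  if (!length(out)) return(matrix(integer(0), ncol = 3L))
  do.call(rbind, out)
}

# Scan one orientation of a contig against one seed. cints/sints are
# utf8ToInt vectors; ckmers the contig k-mer vector; sidx the seed index.
scan_orientation <- function(cints, sints, ckmers, sidx, k, strand,
                             min_identity, min_hsp_len) {
  hits <- sidx[ckmers]
  nh <- lengths(hits)
  if (!any(nh > 0L)) return(empty_hsps())
  cpos <- rep(which(nh > 0L), nh[nh > 0L])
  spos <- unlist(hits[nh > 0L], use.names = FALSE)
  diags <- sort(unique(cpos - spos))
  nc <- length(cints); ns <- length(sints)
  res <- list()
  for (d in diags) {
    s_lo <- max(1L, 1L - d)
    s_hi <- min(ns, nc - d)
    if (s_hi - s_lo + 1L < min_hsp_len) next
    srange <- s_lo:s_hi
    eq <- cints[srange + d] == sints[srange]
    segs <- diagonal_segments(eq)
    if (!nrow(segs)) next
    for (row in seq_len(nrow(segs))) {
      a <- segs[row, 1L]; b <- segs[row, 2L]; m <- segs[row, 3L]
      len <- b - a
      if (len < min_hsp_len) next
      ident <- m / len
      if (ident < min_identity) next
      seed_start <- (s_lo - 1L) + a       # 0-based
      res[[length(res) + 1L]] <- data.frame(
        contig_id = NA_character_, seed_id = NA_character_, strand = strand,
        contig_start = seed_start + d, contig_end = seed_start + d + len,
        seed_start = seed_start, seed_end = seed_start + len,
        length = len, matches = m, identity = ident, score = m,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_hsps())
  do.call(rbind, res)
}

# Drop HSPs contained (on both sequences, same strand) in a better-scoring HSP.
drop_contained <- function(h) {
  if (nrow(h) < 2L) return(h)
  ord <- order(-h$score, h$seed_start, h$contig_start)
  h <- h[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (h$strand[j] == h$strand[i] &&
          h$seed_start[j] <= h$seed_start[i] && h$seed_end[j] >= h$seed_end[i] &&
          h$contig_start[j] <= h$contig_start[i] &&
          h$contig_end[j] >= h$contig_end[i]) {
        keep[i] <- FALSE
        break
      }
    }
  }
  h[keep, , drop = FALSE]
}

#' Find high-scoring segment pairs between a contig and a seed transcript
#'
#' Reports maximal ungapped local alignment segments (HSPs) on either strand,
#' in seed orientation: minus-strand hits carry contig coordinates on the
#' reverse-complemented contig. Segments shorter than `min_hsp_len` or below
#' `min_identity` are dropped, as are segments contained in a better one.
#'
#' @param contig,seed Character scalars (optionally named; names become ids)
#'   or length-1 sequence sets.
#' @param min_identity Minimum identity fraction of a retained HSP.
#' @param min_hsp_len Minimum HSP length (nt), at least 1.
#' @param k Seeding k-mer size; HSPs with no exact `k`-mer match are invisible,
#'   so `k` must not exceed `min_hsp_len`.
#' @param contig_id,seed_id Ids used in the output (default: names of the
#'   inputs, else "contig"/"seed").
#' @return A data.frame with one row per HSP: `contig_id, seed_id, strand,
#'   contig_start, contig_end, seed_start, seed_end, length, matches,
#'   identity, score` (coordinates 0-based half-open, score = matched bases),
#'   sorted by `seed_start`.
#' @examples
#' find_hsps(c(ctg = "ACGTACGTAC"), c(seed = "ACGTACGTAC"),
#'           min_hsp_len = 5, k = 4)
#' @export
find_hsps <- function(contig, seed, min_identity = 0.9, min_hsp_len = 30L,
                      k = 12L, contig_id = NULL, seed_id = NULL) {
  if (is.null(contig_id)) contig_id <- if (!is.null(names(contig))) names(contig)[1] else "contig"
  if (is.null(seed_id)) seed_id <- if (!is.null(names(seed))) names(seed)[1] else "seed"
  contig <- as_seq_set(setNames(unname(contig[1]), contig_id), "contig")
  seed <- as_seq_set(setNames(unname(seed[1]), seed_id), "seed")
  if (min_hsp_len < 1L) stop("min_hsp_len must be >= 1")
  if (k > min_hsp_len) k <- max(4L, min_hsp_len)
  sidx <- seed_kmer_index(seed[[1]], k)
  sints <- utf8ToInt(seed[[1]])
  hsps_for_pair(contig[[1]], sints, sidx, k, min_identity, min_hsp_len,
                contig_id, seed_id)
}

# Core shared by find_hsps and assign_contigs (seed index precomputed).
hsps_for_pair <- function(cseq, sints, sidx, k, min_identity, min_hsp_len,
                          contig_id, seed_id) {
  fwd <- cseq
  rev <- revcomp(cseq)
  cints_f <- utf8ToInt(fwd)
  cints_r <- utf8ToInt(rev)
  h <- rbind(
    scan_orientation(cints_f, sints, kmer_vector(fwd, k), sidx, k, "+",
                     min_identity, min_hsp_len),
    scan_orientation(cints_r, sints, kmer_vector(rev, k), sidx, k, "-",
                     min_identity, min_hsp_len))
  h <- drop_contained(h)
  if (nrow(h)) {
    h$contig_id <- contig_id
    h$seed_id <- seed_id
    h <- h[order(h$seed_start, h$contig_start), , drop = FALSE]
    rownames(h) <- NULL
  }
  h
}

#' Contig sequence in seed orientation
#'
#' @param contig_seq Character scalar contig sequence as assembled.
#' @param strand `"+"` or `"-"`; minus returns the reverse complement, the
#'   orientation in which minus-strand HSP contig coordinates are expressed.
#' @return Character scalar.
#' @export
oriented_sequence <- function(contig_seq, strand) {
  if (identical(strand, "-")) revcomp(contig_seq) else contig_seq
}

#' Assign contigs to genes by total HSP score
#'
#' Aligns every contig against every seed, keeps HSPs passing the thresholds,
#' and assigns each contig to the seed with the highest total retained HSP
#' score (ties broken by lexicographic seed id). Other seeds whose total score
#' is at least `ambiguity_ratio` times the best are recorded as ambiguous.
#' Contigs with no retained HSP against any seed are reported as unassigned
#' (the discard class).
#'
#' @param contigs,seeds Sequence sets (named character or DNAStringSet).
#' @param min_identity,min_hsp_len,k See [find_hsps()].
#' @param ambiguity_ratio Fraction of the best total score at or above which a
#'   competing seed is recorded as ambiguous.
#' @return Object of class `gene_assignment`: list with
#'   * `assignments`: data.frame `contig_id, seed_id, total_score, n_hsps,
#'     n_seed_intervals, ambiguous_ids` (comma-separated),
#'   * `hsps`: retained HSPs of each contig against its assigned seed,
#'   * `unassigned`: character vector of contig ids.
#' @export
assign_contigs <- function(contigs, seeds, min_identity = 0.9,
                           min_hsp_len = 30L, ambiguity_ratio = 0.9,
                           k = 12L) {
  contigs <- as_seq_set(contigs, "contigs")
  seeds <- as_seq_set(seeds, "seeds")
  if (k > min_hsp_len) k <- max(4L, min_hsp_len)
  sidx <- lapply(seeds, seed_kmer_index, k = k)
  sints <- lapply(seeds, utf8ToInt)
  seed_ids <- sort(names(seeds))

  rows <- list(); hsps_keep <- list(); unassigned <- character(0)
  for (cid in names(contigs)) {
    per_seed <- list()
    for (sid in seed_ids) {
      h <- hsps_for_pair(contigs[[cid]], sints[[sid]], sidx[[sid]], k,
                         min_identity, min_hsp_len, cid, sid)
      if (nrow(h)) per_seed[[sid]] <- h
    }
    if (!length(per_seed)) {
      unassigned <- c(unassigned, cid)
      next
    }
    totals <- vapply(per_seed, function(h) sum(h$score), numeric(1))
    best_sid <- names(totals)[order(-totals, names(totals))][1]
    ambig <- setdiff(names(totals)[totals >= ambiguity_ratio * totals[best_sid]],
                     best_sid)
    h_best <- per_seed[[best_sid]]
    ir <- IRanges::reduce(IRanges::IRanges(h_best$seed_start + 1L,
                                           h_best$seed_end))
    rows[[cid]] <- data.frame(
      contig_id = cid, seed_id = best_sid,
      total_score = unname(totals[best_sid]), n_hsps = nrow(h_best),
      n_seed_intervals = length(ir),
      ambiguous_ids = paste(sort(ambig), collapse = ","),
      stringsAsFactors = FALSE)
    hsps_keep[[cid]] <- h_best
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), seed_id = character(0),
               total_score = numeric(0), n_hsps = integer(0),
               n_seed_intervals = integer(0), ambiguous_ids = character(0),
               stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  hsps <- if (length(hsps_keep)) do.call(rbind, hsps_keep) else empty_hsps()
  rownames(hsps) <- NULL
  structure(list(assignments = assignments, hsps = hsps,
                 unassigned = unassigned),
            class = "gene_assignment")
}

#' @export
print.gene_assignment <- function(x, ...) {
  cat("gene_assignment:", nrow(x$assignments), "contigs assigned to",
      length(unique(x$assignments$seed_id)), "seeds;",
      length(x$unassigned), "unassigned\n")
  invisible(x)
}

#' Cluster assigned contigs by gene
#'
#' Partitions assigned contigs into per-seed clusters. Every assigned contig
#' appears in exactly one cluster; empty clusters are omitted.
#'
#' @param assignments A `gene_assignment` object or its `assignments`
#'   data.frame.
#' @return Named list: seed_id -> character vector of contig ids (both sorted).
#' @export
cluster_by_gene <- function(assignments) {
  df <- if (inherits(assignments, "gene_assignment")) assignments$assignments
        else assignments
  stopifnot(is.data.frame(df), all(c("contig_id", "seed_id") %in% names(df)))
  if (anyDuplicated(df$contig_id)) {
    stop("duplicate contig_id in assignments: ",
         paste(unique(df$contig_id[duplicated(df$contig_id)]), collapse = ", "))
  }
  if (!nrow(df)) return(setNames(list(), character(0)))
  cl <- split(df$contig_id, df$seed_id)
  cl <- lapply(cl, sort)
  cl[order(names(cl))]
}
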