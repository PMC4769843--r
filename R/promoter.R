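# Promoter-proximal upstream extraction. A contig carries usable 5' upstream
# sequence when one of its HSPs to the assigned seed reaches the beginning of
# the coding region (a position within codon `max_codon` or earlier) and the
# contig, in seed orientation, extends at least `min_upstream` nt 5' of that
# alignment start. Both thresholds are strict boundaries: 100 nt passes, 99
# fails; codon 10 passes, 11 fails.

#' Extract promoter-proximal upstream candidates
#'
#' @param hsps Data.frame of retained HSPs (contigs against their assigned
#'   seeds), e.g. `assign_contigs(...)$hsps`.
#' @param seed_cds Data.frame `seed_id, cds_start, cds_end` (0-based half-open
#'   transcript coordinates). Seeds present in `hsps` but absent here are
#'   skipped with a warning.
#' @param min_upstream Minimum contig sequence (nt) 5' of the first-exon
#'   alignment start.
#' @param max_codon Latest CDS codon (1-based) the qualifying HSP may start
#'   in; codon k covers CDS positions `[3(k-1), 3k)`.
#' @param contigs Optional sequence set; when given, the upstream sequence of
#'   each candidate is returned in an `upstream_seq` column.
#' @return Data.frame `seed_id, contig_id, upstream_length, covers_codon`
#'   (one row per qualifying contig, sorted by seed then contig id), plus
#'   `upstream_seq` when `contigs` is supplied.
#' @export
extract_upstream_candidates <- function(hsps, seed_cds, min_upstream = 100L,
                                        max_codon = 10L, contigs = NULL) {
  empty <- data.frame(seed_id = character(0), contig_id = character(0),
                      upstream_length = integer(0), covers_codon = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hsps) || !nrow(hsps)) return(empty)
  stopifnot(all(c("seed_id", "cds_start") %in% names(seed_cds)))
  no_cds <- setdiff(unique(hsps$seed_id), seed_cds$seed_id)
  if (length(no_cds)) {
    warning("skipping seeds without CDS annotation: ",
            paste(no_cds, collapse = ", "))
  }
  if (!is.null(contigs)) contigs <- as_seq_set(contigs, "contigs")

  rows <- list()
  for (i in seq_len(nrow(seed_cds))) {
    sid <- seed_cds$seed_id[i]
    cds_start <- seed_cds$cds_start[i]
    window_end <- cds_start + 3L * max_codon   # exclusive
    h <- hsps[hsps$seed_id == sid, , drop = FALSE]
    if (!nrow(h)) next
    for (cid in unique(h$contig_id)) {
      hc <- h[h$contig_id == cid, , drop = FALSE]
      qual <- hc$seed_start < window_end & hc$seed_end > cds_start
      if (!any(qual)) next
      hq <- hc[qual, , drop = FALSE]
      first <- hq[which.min(hq$seed_start), , drop = FALSE]
      upstream <- first$contig_start
      if (upstream < min_upstream) next
      codon <- (max(first$seed_start, cds_start) - cds_start) %/% 3L + 1L
      row <- data.frame(seed_id = sid, contig_id = cid,
                        upstream_length = as.integer(upstream),
                        covers_codon = as.integer(codon),
                        stringsAsFactors = FALSE)
      if (!is.null(contigs)) {
        row$upstream_seq <- substr0(
          oriented_sequence(contigs[[cid]], first$strand), 0L, upstream)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$seed_id, out$contig_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upstream-length frequency distribution across gene models
#'
#' Retains the single best (longest-upstream) candidate per gene (ties broken
#' by lexicographic contig id) and counts genes per half-open length bin
#' `[lo, hi)`. A final open bin `[last_edge, Inf)` is appended so that the
#' counts always sum to the number of genes with at least one candidate.
#'
#' @param candidates Output of [extract_upstream_candidates()].
#' @param bin_edges Increasing bin edges (nt); e.g. `c(100, 500, 1000)` gives
#'   bins `[100,500)`, `[500,1000)` and `[1000,Inf)`.
#' @return Data.frame `bin_lo, bin_hi, count`.
#' @export
upstream_length_distribution <- function(candidates,
                                         bin_edges = c(100, 500, 1000, 1500)) {
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges, strictly = TRUE))
  lo <- bin_edges
  hi <- c(bin_edges[-1L], Inf)
  out <- data.frame(bin_lo = lo, bin_hi = hi,
                    count = integer(length(lo)))
  if (is.null(candidates) || !nrow(candidates)) return(out)
  best <- do.call(rbind, lapply(split(candidates, candidates$seed_id),
    function(d) {
      d <- d[order(-d$upstream_length, d$contig_id), , drop = FALSE]
      d[1L, , drop = FALSE]
    }))
  if (any(best$upstream_length < lo[1L])) {
    stop("candidate upstream length below the first bin edge")
  }
  idx <- findInterval(best$upstream_length, lo)
  tab <- tabulate(idx, nbins = length(lo))
  out$count <- as.integer(tab)
  stopifnot(sum(out$count) == nrow(best))
  out
}
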