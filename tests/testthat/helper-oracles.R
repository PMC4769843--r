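# Independent oracles and deterministic fixtures used across the suite.

# ---- brute-force HSP oracle -------------------------------------------------
# All maximal exact-match runs between two sequences on every diagonal of one
# orientation, by direct character comparison; used to bound the aligner's
# output on error-free fixtures.
oracle_exact_runs <- function(contig, seed, min_len) {
  ci <- utf8ToInt(contig); si <- utf8ToInt(seed)
  nc <- length(ci); ns <- length(si)
  out <- list()
  for (d in (-(ns - 1L)):(nc - 1L)) {
    s_lo <- max(1L, 1L - d); s_hi <- min(ns, nc - d)
    if (s_hi < s_lo) next
    run_start <- NA_integer_
    for (s in s_lo:(s_hi + 1L)) {
      ok <- s <= s_hi && ci[s + d] == si[s]
      if (ok && is.na(run_start)) run_start <- s
      if (!ok && !is.na(run_start)) {
        len <- s - run_start
        if (len >= min_len) {
          out[[length(out) + 1L]] <- data.frame(
            seed_start = run_start - 1L, seed_end = s - 1L,
            contig_start = run_start - 1L + d, contig_end = s - 1L + d)
        }
        run_start <- NA_integer_
      }
    }
  }
  if (!length(out)) return(data.frame(seed_start = integer(0),
                                      seed_end = integer(0),
                                      contig_start = integer(0),
                                      contig_end = integer(0)))
  do.call(rbind, out)
}

# ---- brute-force model scoring ----------------------------------------------
# Position-count scoring of a set of seed spans (0-based half-open).
oracle_score_spans <- function(starts, ends, seed_len) {
  cov <- integer(seed_len)
  for (i in seq_along(starts)) {
    cov[(starts[i] + 1L):ends[i]] <- cov[(starts[i] + 1L):ends[i]] + 1L
  }
  total <- sum(cov)
  un <- sum(cov > 0L)
  list(recovery_pct = 100 * total / seed_len,
       union_recovery_pct = 100 * un / seed_len,
       exon_overlap_pct = 100 * (total - un) / un)
}

# ---- exhaustive model selection oracle --------------------------------------
# Enumerates every non-empty subset of contigs whose raw segments are pairwise
# compatible (inter-contig seed overlap <= tol), scores each subset by
# coverage counting under the canonical overlap-trimming convention
# (inter-contig overlaps <= tol are assigned to the upstream segment, so they
# contribute no multiplicity; same-contig placements keep multiplicity), and
# returns the lexicographically best subset under
# (-union, overlap, n_contigs, sorted id string).
oracle_best_subset <- function(hsps, seed_len, tol) {
  ids <- sort(unique(hsps$contig_id))
  stopifnot(length(ids) <= 12L)
  segs <- split(hsps, hsps$contig_id)
  compatible <- function(a, b) {
    ha <- segs[[a]]; hb <- segs[[b]]
    for (i in seq_len(nrow(ha))) {
      ov <- pmin(ha$seed_end[i], hb$seed_end) -
        pmax(ha$seed_start[i], hb$seed_start)
      if (any(ov > tol)) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  n <- length(ids)
  for (mask in seq_len(2^n - 1L)) {
    sel <- ids[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L]
    ok <- TRUE
    if (length(sel) > 1L) {
      for (i in seq_len(length(sel) - 1L)) {
        for (j in (i + 1L):length(sel)) {
          if (!compatible(sel[i], sel[j])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    h <- hsps[hsps$contig_id %in% sel, , drop = FALSE]
    # union from raw spans; multiplicity only from same-contig redundancy
    cov <- integer(seed_len)
    for (i in seq_len(nrow(h))) {
      cov[(h$seed_start[i] + 1L):h$seed_end[i]] <-
        cov[(h$seed_start[i] + 1L):h$seed_end[i]] + 1L
    }
    un <- sum(cov > 0L)
    same_contig_extra <- 0L
    for (cid in sel) {
      hc <- h[h$contig_id == cid, , drop = FALSE]
      covc <- integer(seed_len)
      for (i in seq_len(nrow(hc))) {
        covc[(hc$seed_start[i] + 1L):hc$seed_end[i]] <-
          covc[(hc$seed_start[i] + 1L):hc$seed_end[i]] + 1L
      }
      same_contig_extra <- same_contig_extra + sum(covc) - sum(covc > 0L)
    }
    key <- list(-100 * un / seed_len,
                100 * same_contig_extra / un,
                length(sel),
                paste(sel, collapse = "\r"))
    if (is.null(best) || key_less(key, best$key)) {
      best <- list(key = key, ids = sel)
    }
  }
  best
}

key_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (is.character(a[[i]])) {
      if (a[[i]] < b[[i]]) return(TRUE)
      if (a[[i]] > b[[i]]) return(FALSE)
    } else {
      if (a[[i]] < b[[i]] - 1e-9) return(TRUE)
      if (a[[i]] > b[[i]] + 1e-9) return(FALSE)
    }
  }
  FALSE
}

# ---- brute-force probe start rule -------------------------------------------
oracle_probe_starts <- function(L, probe_len, step_first, step_rest) {
  boundary <- ceiling(L / 3)
  starts <- 0L
  repeat {
    nxt <- starts[length(starts)] + step_first
    if (nxt >= boundary) break
    starts <- c(starts, nxt)
  }
  repeat {
    nxt <- starts[length(starts)] + step_rest
    if (nxt + probe_len > L) break
    starts <- c(starts, nxt)
  }
  starts <- starts[starts + probe_len <= L]
  if (max(starts) + probe_len < L) starts <- c(starts, L - probe_len)
  sort(unique(starts))
}

# ---- handcrafted three-exon mini gene ---------------------------------------
# A small gene whose exon2/intron2 and intron2/exon3 junction bases are
# guaranteed unambiguous (no chance continuation of the alignment across the
# junction), so HSP spans must abut exactly at the junction.
three_exon_fixture <- function() {
  g <- make_gene(c(90L, 60L, 75L), c(120L, 80L), utr5 = 12L, utr3 = 12L,
                 flank5 = 40L, flank3 = 40L, rng_seed = 2L,
                 gene_id = "mini")
  tr <- g$transcript
  e2_start_t <- g$exon_lengths[1]
  e3_start_t <- g$exon_lengths[1] + g$exon_lengths[2]
  intron2 <- substr0(g$genomic, g$exon_g_end[2], g$exon_g_start[3])
  # junction ambiguity guards (fixture construction invariants):
  # forward: first intron2 base must differ from first exon3 base, so an HSP
  # ending at the exon2/exon3 junction cannot extend by a chance match;
  # backward: last intron2 base must differ from last exon2 base, so the
  # exon3 HSP cannot start a base early.
  stopifnot(
    substr(intron2, 1L, 1L) != substr(tr, e3_start_t + 1L, e3_start_t + 1L),
    substr(intron2, nchar(intron2), nchar(intron2)) !=
      substr(tr, e3_start_t, e3_start_t))
  g
}

substr0 <- function(seq, start0, end0) substring(seq, start0 + 1L, end0)

# Deterministic random DNA for test-local sequences.
test_dna <- function(n, seed, gc = 0.4) {
  withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

# Clean multi-gene simulation shared by several files.
clean_capture_sim <- function(n_genes = 5L, rng_seed = 3L,
                              junctions = TRUE, upstream = TRUE) {
  set <- random_gene_set(n_genes, rng_seed = rng_seed)
  contigs <- character(0)
  truth <- list()
  for (i in seq_along(set$genes)) {
    sim <- simulate_capture_contigs(set$genes[[i]], sim_config(
      coverage = 2L * length(set$genes[[i]]$exon_lengths),
      junction_spanning = junctions, upstream_flank_capture = upstream,
      rng_seed = 100L + i))
    contigs <- c(contigs, sim$contigs)
    truth[[i]] <- sim$truth
  }
  list(set = set, contigs = contigs, truth = do.call(rbind, truth))
}
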