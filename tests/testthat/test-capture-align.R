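test_that("identical sequences yield a single full-length HSP", {
  s <- test_dna(300L, seed = 1L)
  h <- find_hsps(c(ctg = s), c(seed = s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(c(h$contig_start, h$contig_end, h$seed_start, h$seed_end),
               c(0L, 300L, 0L, 300L))
  expect_equal(h$identity, 1)
  expect_equal(h$score, 300L)
})

test_that("reverse-complement contigs give identical seed coordinates on -", {
  s <- test_dna(300L, seed = 2L)
  fwd <- find_hsps(c(ctg = s), c(seed = s))
  rev <- find_hsps(c(ctg = revcomp(s)), c(seed = s))
  expect_equal(rev$strand, "-")
  expect_equal(rev[, c("seed_start", "seed_end", "contig_start",
                       "contig_end")],
               fwd[, c("seed_start", "seed_end", "contig_start",
                       "contig_end")])
})

test_that("orientation canonicalization holds for multi-HSP contigs", {
  g <- three_exon_fixture()
  ctg <- substr0(g$genomic, g$exon_g_start[2], g$exon_g_end[3])
  fwd <- find_hsps(c(ctg = ctg), c(mini = g$transcript))
  rev <- find_hsps(c(ctg = revcomp(ctg)), c(mini = g$transcript))
  cols <- c("seed_start", "seed_end", "contig_start", "contig_end", "length")
  expect_equal(rev[, cols], fwd[, cols])
  expect_true(all(fwd$strand == "+"))
  expect_true(all(rev$strand == "-"))
})

test_that("an exon-intron-exon contig yields two HSPs abutting at the junction", {
  g <- three_exon_fixture()
  ctg <- substr0(g$genomic, g$exon_g_start[2], g$exon_g_end[3])
  h <- find_hsps(c(ctg = ctg), c(mini = g$transcript))
  expect_equal(nrow(h), 2L)
  junction <- g$exon_lengths[1] + g$exon_lengths[2]
  expect_equal(h$seed_end[1], junction)
  expect_equal(h$seed_start[2], junction)         # seed spans abut
  expect_equal(h$contig_start[2] - h$contig_end[1],
               g$intron_lengths[2])               # contig spans split by intron
  # confirmed by the brute-force exact-run oracle
  runs <- oracle_exact_runs(ctg, g$transcript, min_len = 30L)
  runs <- runs[order(runs$seed_start), ]
  expect_equal(h$seed_start, runs$seed_start)
  expect_equal(h$seed_end, runs$seed_end)
  expect_equal(h$contig_start, runs$contig_start)
})

test_that("HSP spans agree with the brute-force scan on error-free fragments", {
  g <- make_gene(c(120L, 90L, 110L), c(150L, 90L), utr5 = 20L, utr3 = 21L,
                 flank5 = 60L, flank3 = 60L, rng_seed = 17L, gene_id = "o")
  frags <- list(c(0L, 260L), c(100L, 450L), c(250L, 500L),
                c(30L, 330L))  # assorted genomic windows <= 500 nt
  for (f in frags) {
    ctg <- substr0(g$genomic, f[1], f[2])
    h <- find_hsps(c(ctg = ctg), c(o = g$transcript))
    runs <- oracle_exact_runs(ctg, g$transcript, min_len = 30L)
    # every oracle run is inside an implementation HSP on the same diagonal,
    # and extensions past the exact run are at most a few chance matches
    for (i in seq_len(nrow(runs))) {
      cover <- h$seed_start <= runs$seed_start[i] &
        h$seed_end >= runs$seed_end[i] &
        (h$contig_start - h$seed_start) ==
          (runs$contig_start[i] - runs$seed_start[i])
      expect_true(any(cover))
      j <- which(cover)[1]
      expect_lte((runs$seed_start[i] - h$seed_start[j]) +
                   (h$seed_end[j] - runs$seed_end[i]), 6L)
    }
    expect_true(all(h$identity >= 0.9), info = paste(f, collapse = "-"))
  }
})

test_that("input validation rejects empty sequences and bad thresholds", {
  expect_error(find_hsps(c(a = ""), c(b = "ACGT")), "empty")
  expect_error(find_hsps(c(a = "ACGT"), c(b = "ACGTT"), min_hsp_len = 0),
               "min_hsp_len")
})

test_that("assignment picks the best seed and records paralog ambiguity", {
  withr::with_seed(31L, {
    exonA <- paste(sample(c("A", "C", "G", "T"), 300L, TRUE), collapse = "")
    seedA <- paste0(test_dna(200L, 41L), exonA, test_dna(200L, 42L))
    # paralog: same exon at 95% identity embedded in different context
    v <- strsplit(exonA, "")[[1]]
    pos <- sample(300L, 15L)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    seedB <- paste0(test_dna(180L, 43L), paste(v, collapse = ""),
                    test_dna(220L, 44L))
  })
  asn <- assign_contigs(c(ctg = exonA), c(A = seedA, B = seedB),
                        ambiguity_ratio = 0.9)
  expect_equal(asn$assignments$seed_id, "A")
  expect_equal(asn$assignments$ambiguous_ids, "B")
  expect_equal(asn$assignments$total_score, 300)
  # and the scores agree with direct identity counting
  hB <- find_hsps(c(ctg = exonA), c(B = seedB))
  expect_equal(sum(hB$matches), 285L)
})

test_that("contigs matching a single seed have an empty ambiguity set", {
  s <- clean_capture_sim(2L, rng_seed = 6L, junctions = FALSE,
                         upstream = FALSE)
  asn <- assign_contigs(s$contigs, s$set$seeds)
  expect_true(all(asn$assignments$ambiguous_ids == ""))
})

test_that("random contigs are reported as unassigned debris", {
  seeds <- setNames(vapply(1:3, function(i) test_dna(800L, 50L + i),
                           character(1)), c("s1", "s2", "s3"))
  junk <- setNames(vapply(1:5, function(i) test_dna(500L, 60L + i),
                          character(1)), paste0("junk", 1:5))
  asn <- assign_contigs(junk, seeds)
  expect_equal(nrow(asn$assignments), 0L)
  expect_setequal(asn$unassigned, names(junk))
})

test_that("clusters partition exactly the assigned contigs", {
  s <- clean_capture_sim(3L, rng_seed = 9L)
  asn <- assign_contigs(s$contigs, s$set$seeds)
  cl <- cluster_by_gene(asn)
  members <- unlist(cl, use.names = FALSE)
  expect_equal(sort(members), sort(asn$assignments$contig_id))  # disjoint cover
  expect_equal(anyDuplicated(members), 0L)
  expect_true(all(lengths(cl) > 0L))
  # cluster membership matches the per-contig assignment
  for (sid in names(cl)) {
    expect_setequal(cl[[sid]],
                    asn$assignments$contig_id[asn$assignments$seed_id == sid])
  }
  # every seed with simulated coverage got a cluster
  expect_setequal(names(cl), names(s$set$seeds))
  dup <- asn$assignments[c(1, 1), ]
  expect_error(cluster_by_gene(dup), "duplicate")
})
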