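# helper: hand-built HSP rows (identity segments) for synthetic span tests
mk_hsps <- function(seed_id, spans, contig_ids,
                    contig_starts = rep(0L, length(contig_ids))) {
  do.call(rbind, lapply(seq_along(contig_ids), function(i) {
    len <- spans[[i]][2] - spans[[i]][1]
    data.frame(contig_id = contig_ids[i], seed_id = seed_id, strand = "+",
               contig_start = contig_starts[i],
               contig_end = contig_starts[i] + len,
               seed_start = spans[[i]][1], seed_end = spans[[i]][2],
               length = len, matches = len, identity = 1,
               score = len, stringsAsFactors = FALSE)
  }))
}

test_that("a full-cover contig yields exactly one single-segment candidate", {
  h <- mk_hsps("s", list(c(0L, 100L)), "c1")
  cands <- build_candidate_models("s", 100L, h)
  expect_length(cands, 1L)
  expect_equal(nrow(cands[[1]]$segments), 1L)
  expect_equal(cands[[1]]$contig_ids, "c1")
  expect_length(build_candidate_models("s", 100L, h[0, ]), 0L)
})

test_that("overlapping spans within tolerance tile into one candidate", {
  h <- mk_hsps("s", list(c(0L, 50L), c(40L, 100L)), c("c1", "c2"))
  cands <- build_candidate_models("s", 100L, h, overlap_tolerance = 15L)
  expect_length(cands, 1L)
  expect_setequal(cands[[1]]$contig_ids, c("c1", "c2"))
  # above tolerance the contigs are incompatible: two candidates
  cands2 <- build_candidate_models("s", 100L, h, overlap_tolerance = 5L)
  expect_length(cands2, 2L)
  expect_equal(sort(vapply(cands2, function(m) m$contig_ids, character(1))),
               c("c1", "c2"))
})

test_that("score_model implements the recovery/overlap/fragmentation formulas", {
  # raw (untrimmed) spans scored directly: 110/100/10/2
  m <- structure(list(seed_id = "s", seed_len = 100L,
                      segments = mk_hsps("s", list(c(0L, 50L), c(40L, 100L)),
                                         c("c1", "c2")),
                      score = NULL, suspect_repeat = NA,
                      contig_ids = c("c1", "c2")),
                 class = "gene_model")
  m <- score_model(m)
  expect_equal(m$score$recovery_pct, 110)
  expect_equal(m$score$union_recovery_pct, 100)
  expect_equal(m$score$exon_overlap_pct, 10)
  expect_equal(m$score$fragmentation_index, 2L)
  o <- oracle_score_spans(c(0L, 40L), c(50L, 100L), 100L)
  expect_equal(m$score$recovery_pct, o$recovery_pct)
  expect_equal(m$score$union_recovery_pct, o$union_recovery_pct)
  expect_equal(m$score$exon_overlap_pct, o$exon_overlap_pct)

  full <- score_model(structure(list(
    seed_id = "s", seed_len = 100L,
    segments = mk_hsps("s", list(c(0L, 100L)), "c1"),
    score = NULL, suspect_repeat = NA, contig_ids = "c1"),
    class = "gene_model"))
  expect_equal(full$score$recovery_pct, 100)
  expect_equal(full$score$union_recovery_pct, 100)
  expect_equal(full$score$exon_overlap_pct, 0)
  expect_equal(full$score$fragmentation_index, 1L)

  part <- score_model(structure(list(
    seed_id = "s", seed_len = 100L,
    segments = mk_hsps("s", list(c(0L, 30L)), "c1"),
    score = NULL, suspect_repeat = NA, contig_ids = "c1"),
    class = "gene_model"))
  expect_equal(part$score$recovery_pct, 30)
  expect_equal(part$score$exon_overlap_pct, 0)
})

test_that("selection is lexicographic in union recovery, overlap, fragmentation", {
  mk_model <- function(union, overlap, frag, ids) {
    structure(list(seed_id = "s", seed_len = 100L, segments = NULL,
                   score = list(recovery_pct = union + overlap,
                                union_recovery_pct = union,
                                exon_overlap_pct = overlap,
                                fragmentation_index = frag),
                   suspect_repeat = NA, contig_ids = ids),
              class = "gene_model")
  }
  # criterion (i): recovery dominates everything
  best <- select_best_model(list(mk_model(80, 0, 1, "a"),
                                 mk_model(95, 20, 9, "b")))
  expect_equal(best$contig_ids, "b")
  # criterion (ii): equal union -> lowest overlap
  best <- select_best_model(list(mk_model(90, 10, 1, "a"),
                                 mk_model(90, 0, 5, "b")))
  expect_equal(best$contig_ids, "b")
  # criterion (iii): equal union and overlap -> fewest contigs
  best <- select_best_model(list(mk_model(90, 0, 3, c("a", "b", "c")),
                                 mk_model(90, 0, 2, c("d", "e"))))
  expect_equal(best$contig_ids, c("d", "e"))
  expect_error(select_best_model(list()), class = "genecap_no_model")
})

test_that("recovery above 100% flags the model as repeat suspect", {
  over <- flag_suspect(score_model(structure(list(
    seed_id = "s", seed_len = 100L,
    segments = mk_hsps("s", list(c(0L, 50L), c(40L, 100L)), c("c1", "c2")),
    score = NULL, suspect_repeat = NA, contig_ids = c("c1", "c2")),
    class = "gene_model")))
  expect_true(over$suspect_repeat)   # recovery 110
  at100 <- flag_suspect(score_model(structure(list(
    seed_id = "s", seed_len = 100L,
    segments = mk_hsps("s", list(c(0L, 100L)), "c1"),
    score = NULL, suspect_repeat = NA, contig_ids = "c1"),
    class = "gene_model")))
  expect_false(at100$suspect_repeat)  # boundary: exactly 100 is clean
})

test_that("a tandem exon duplication keeps both placements and gets flagged", {
  g <- make_gene(c(150L, 120L, 180L), c(200L, 150L), utr5 = 30L, utr3 = 30L,
                 flank5 = 200L, flank3 = 200L, rng_seed = 23L, gene_id = "r")
  sim <- simulate_capture_contigs(g, sim_config(
    coverage = 6L, repeat_duplication = TRUE, repeat_exon = 2L,
    rng_seed = 5L))
  res <- run_pipeline(sim$contigs, setNames(g$transcript, "r"))
  m <- res$models[["r"]]
  rep_id <- sim$truth$contig_id[sim$truth$scenario == "repeat_duplication"]
  expect_equal(sum(m$segments$contig_id == rep_id), 2L)  # both placements
  expect_true(m$suspect_repeat)
  expect_gt(m$score$recovery_pct, 100)
  # clean run of the same gene is not flagged
  sim2 <- simulate_capture_contigs(g, sim_config(coverage = 6L, rng_seed = 5L))
  res2 <- run_pipeline(sim2$contigs, setNames(g$transcript, "r"))
  expect_false(res2$models[["r"]]$suspect_repeat)
})

test_that("best model matches exhaustive subset enumeration (<= 6 contigs)", {
  cases <- list(c(genes = 1L, seed = 101L), c(genes = 1L, seed = 102L),
                c(genes = 1L, seed = 103L))
  for (cs in cases) {
    set <- random_gene_set(1L, rng_seed = cs[["seed"]])
    g <- set$genes[[1]]
    sim <- simulate_capture_contigs(g, sim_config(
      coverage = 4L, junction_spanning = TRUE, rng_seed = cs[["seed"]]))
    contigs <- sim$contigs[seq_len(min(6L, length(sim$contigs)))]
    asn <- assign_contigs(contigs, set$seeds)
    h <- asn$hsps
    if (!nrow(h)) next
    cands <- build_candidate_models(g$gene_id, nchar(set$seeds[[1]]), h)
    best <- select_best_model(cands)
    oracle <- oracle_best_subset(h, nchar(set$seeds[[1]]), tol = 15L)
    expect_equal(best$contig_ids, oracle$ids)
    expect_equal(best$score$union_recovery_pct, -oracle$key[[1]],
                 tolerance = 1e-9)
  }
})

test_that("adding a contig never decreases the best union recovery", {
  set <- random_gene_set(1L, rng_seed = 77L)
  g <- set$genes[[1]]
  sim <- simulate_capture_contigs(g, sim_config(coverage = 8L,
                                                rng_seed = 19L))
  asn <- assign_contigs(sim$contigs, set$seeds)
  h <- asn$hsps
  ids <- unique(h$contig_id)
  prev <- 0
  for (n in seq_along(ids)) {
    hn <- h[h$contig_id %in% ids[seq_len(n)], , drop = FALSE]
    best <- select_best_model(
      build_candidate_models(g$gene_id, nchar(set$seeds[[1]]), hn))
    expect_gte(best$score$union_recovery_pct, prev - 1e-9)
    prev <- best$score$union_recovery_pct
  }
})

test_that("clean simulated capture recovers structure and intron lengths", {
  s <- clean_capture_sim(3L, rng_seed = 15L, upstream = FALSE)
  res <- run_pipeline(s$contigs, s$set$seeds, s$set$seed_cds)
  expect_equal(nrow(res$scores), 3L)
  expect_true(all(res$scores$union_recovery_pct == 100))
  expect_false(any(res$scores$suspect_repeat))
  for (i in seq_along(s$set$genes)) {
    g <- s$set$genes[[i]]
    m <- res$models[[g$gene_id]]
    sp <- m$introns[m$introns$spanned, ]
    if (nrow(sp)) {
      expect_equal(sp$intron_length, g$intron_lengths[sp$after_block],
                   info = g$gene_id)
    }
  }
  # a single contig spanning the whole gene body recovers every intron
  g <- s$set$genes[[1]]
  body <- substr0(g$genomic, g$flank5, nchar(g$genomic) - g$flank3)
  res1 <- run_pipeline(setNames(body, "full"),
                       s$set$seeds[g$gene_id])
  m1 <- res1$models[[g$gene_id]]
  expect_true(all(m1$introns$spanned))
  expect_equal(m1$introns$intron_length, g$intron_lengths)
  expect_equal(m1$score$fragmentation_index, 1L)
})

test_that("ortholog guidance classifies junctions as supported/unsupported/missing", {
  g <- three_exon_fixture()
  body <- substr0(g$genomic, g$flank5, nchar(g$genomic) - g$flank3)
  seeds <- setNames(g$transcript, "mini")
  res <- run_pipeline(setNames(body, "full"), seeds)
  m <- res$models[["mini"]]
  orth_same <- ortholog_structure("sp", "o1", g$exon_lengths,
                                  g$intron_lengths, cds_offset = g$utr5,
                                  cds_len = g$cds_end - g$cds_start)
  m <- apply_ortholog_guidance(m, orth_same, g$cds_start,
                               g$cds_end - g$cds_start)
  expect_equal(m$guidance$status, rep("supported", 2L))
  # expected junction positions project exactly for an identical structure
  expect_equal(m$guidance$projected_pos,
               cumsum(g$exon_lengths)[1:2])

  # drop junction evidence: exon-only fragments -> both junctions missing
  exon_ctgs <- setNames(
    substr0(g$genomic, g$exon_g_start, g$exon_g_end),
    paste0("e", seq_along(g$exon_lengths)))
  res2 <- run_pipeline(exon_ctgs, seeds)
  m2 <- apply_ortholog_guidance(res2$models[["mini"]], orth_same,
                                g$cds_start, g$cds_end - g$cds_start)
  expect_equal(m2$guidance$status, rep("missing", 2L))

  # pseudogene-like evidence: spliced transcript as contig -> unsupported
  res3 <- run_pipeline(setNames(g$transcript, "ps"), seeds)
  m3 <- apply_ortholog_guidance(res3$models[["mini"]], orth_same,
                                g$cds_start, g$cds_end - g$cds_start)
  expect_equal(m3$guidance$status, rep("unsupported", 2L))

  # single-exon ortholog: zero junctions, trivially complete
  m4 <- apply_ortholog_guidance(m, ortholog_structure("sp", "o2", 300L,
                                                      integer(0)),
                                g$cds_start, g$cds_end - g$cds_start)
  expect_equal(nrow(m4$guidance), 0L)
})

test_that("guidance never alters segment selection", {
  g <- three_exon_fixture()
  body <- substr0(g$genomic, g$flank5, nchar(g$genomic) - g$flank3)
  res <- run_pipeline(setNames(body, "full"), setNames(g$transcript, "mini"))
  m <- res$models[["mini"]]
  orth <- ortholog_structure("sp", "o1", c(100L, 125L), 50L, cds_offset = 5L)
  m2 <- apply_ortholog_guidance(m, orth, g$cds_start,
                                g$cds_end - g$cds_start)
  expect_identical(m2$segments, m$segments)
  expect_identical(m2$score, m$score)
})

test_that("chain DP and exhaustive enumeration select equivalent models", {
  for (seed in c(131L, 132L, 133L)) {
    set <- random_gene_set(1L, rng_seed = seed)
    g <- set$genes[[1]]
    sim <- simulate_capture_contigs(g, sim_config(
      coverage = 2L * length(g$exon_lengths), junction_spanning = TRUE,
      rng_seed = seed))
    asn <- assign_contigs(sim$contigs, set$seeds)
    a <- build_gene_model(g$gene_id, set$seeds[[1]], asn$hsps, sim$contigs,
                          method = "exhaustive")
    b <- build_gene_model(g$gene_id, set$seeds[[1]], asn$hsps, sim$contigs,
                          method = "chain")
    expect_equal(b$score$union_recovery_pct, a$score$union_recovery_pct,
                 info = seed)
    expect_equal(b$score$exon_overlap_pct, a$score$exon_overlap_pct,
                 info = seed)
    expect_equal(b$score$fragmentation_index, a$score$fragmentation_index,
                 info = seed)
  }
})

test_that("high-coverage clusters build in polynomial time via the chain DP", {
  g <- as1_fixture()
  sim <- simulate_capture_contigs(g, sim_config(
    coverage = 28L, junction_spanning = TRUE, rng_seed = 42L))
  asn <- assign_contigs(sim$contigs, setNames(g$transcript, "AS1"))
  t0 <- Sys.time()
  m <- build_gene_model("AS1", g$transcript, asn$hsps, sim$contigs)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 30)
  expect_equal(m$score$union_recovery_pct, 100)
  expect_false(m$suspect_repeat)
})
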