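small_genome <- function(seed = 601, n = 2, len = 3000) {
  set.seed(seed)
  g <- vapply(seq_len(n), function(i) rand_dna(len), character(1))
  names(g) <- sprintf("c%d", seq_len(n))
  structure(g, class = "genome_set")
}

test_that("every genomic position's k-mer is retrievable from the index", {
  set.seed(602)
  g <- structure(c(x = rand_dna(100)), class = "genome_set")
  idx <- build_kmer_index(g, k = 12)
  for (p in seq_len(100 - 12 + 1)) {
    km <- substr(g[["x"]], p, p + 11)
    hits <- query_kmer_index(idx, km)
    expect_true(p %in% hits$pos)
  }
  # absent k-mer (contains no match by construction)
  absent <- query_kmer_index(build_kmer_index(
    structure(c(x = strrep("A", 100)), class = "genome_set")), "ACGTACGTACGT")
  expect_identical(nrow(absent), 0L)
})

test_that("index positions equal a naive scan", {
  g <- small_genome(603, n = 1, len = 10000)
  idx <- build_kmer_index(g, k = 12)
  set.seed(604)
  for (i in 1:20) {
    p <- sample(10000 - 11, 1)
    km <- substr(g[["c1"]], p, p + 11)
    naive <- integer(0)
    for (q in seq_len(10000 - 11)) {
      if (substr(g[["c1"]], q, q + 11) == km) naive <- c(naive, q)
    }
    expect_identical(query_kmer_index(idx, km)$pos, naive)
  }
})

test_that("planted primers are found with the right strand and position", {
  set.seed(605)
  g <- small_genome(605)
  primer <- rand_dna(22)
  # plant verbatim at c1:1001 and as reverse complement at c2:2001
  substr(g[["c1"]], 1001, 1022) <- primer
  substr(g[["c2"]], 2001, 2022) <- revcomp(primer)
  idx <- build_kmer_index(g)
  h <- find_hits(primer, idx)
  planted <- h[h$mismatches == 0, ]
  expect_identical(planted$contig, c("c1", "c2"))
  expect_identical(planted$start, c(1001L, 2001L))
  expect_identical(planted$strand, c("+", "-"))
})

test_that("mismatch budget and 3'-exact zone are enforced", {
  set.seed(606)
  g <- small_genome(606, n = 1)
  primer <- rand_dna(24)
  mutate_at <- function(s, i) {
    old <- substr(s, i, i)
    substr(s, i, i) <- setdiff(c("A", "C", "G", "T"), old)[1]
    s
  }
  # three internal mismatches: beyond the budget of 2
  bad3 <- mutate_at(mutate_at(mutate_at(primer, 3), 9), 15)
  substr(g[["c1"]], 501, 524) <- bad3
  idx <- build_kmer_index(g)
  expect_identical(nrow(find_hits(primer, idx, max_mismatch = 2)), 0L)
  # two mismatches are found, and max_mismatch is monotone
  bad2 <- mutate_at(mutate_at(primer, 3), 9)
  substr(g[["c1"]], 501, 524) <- bad2
  idx <- build_kmer_index(g)
  expect_identical(nrow(find_hits(primer, idx, max_mismatch = 1)), 0L)
  h2 <- find_hits(primer, idx, max_mismatch = 2)
  expect_identical(h2$start, 501L)
  expect_identical(h2$mismatches, 2L)
  # a single mismatch inside the 3'-terminal 5 bases kills the hit
  bad3p <- mutate_at(primer, 23)
  substr(g[["c1"]], 501, 524) <- bad3p
  idx <- build_kmer_index(g)
  expect_identical(nrow(find_hits(primer, idx, max_mismatch = 2)), 0L)
  expect_identical(nrow(find_hits(primer, idx, max_mismatch = 2,
                                  three_prime_exact = 0)), 1L)
})

test_that("hit sets equal the exhaustive per-offset oracle", {
  g <- small_genome(607, n = 3, len = 5000)
  idx <- build_kmer_index(g)
  set.seed(608)
  for (r in 1:25) {
    ct <- sample(names(g), 1)
    L <- sample(20:26, 1)
    at <- sample(nchar(g[[ct]]) - L, 1)
    primer <- substr(g[[ct]], at, at + L - 1)
    nmut <- sample(0:2, 1)
    if (nmut > 0) {
      for (i in sample(L - 5, nmut)) {
        old <- substr(primer, i, i)
        substr(primer, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                               old), 1)
      }
    }
    mm <- sample(0:2, 1)
    got <- find_hits(primer, idx, max_mismatch = mm)
    want <- hits_oracle(primer, g, max_mm = mm)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("hits classify as target, allelic or off-target by geometry", {
  map <- set_contig_lengths(
    subgenome_map(c("g1", "g1", "g2"), c("c1a", "c1b", "c2a"), c(1, 0, 1)),
    structure(c(c1a = strrep("A", 10000), c1b = strrep("A", 10000),
                c2a = strrep("A", 10000)), class = "genome_set"))
  hits <- data.frame(contig = c("c1a", "c1b", "c1b", "c2a"),
                     start = c(5000L, 5000L, 5000L, 5000L),
                     strand = "+", mismatches = 0L,
                     stringsAsFactors = FALSE)
  cls <- classify_hits(hits, bind_start = 5000L, bind_strand = "+",
                       marker_contig = "c1a", map = map)
  expect_identical(cls, c("TARGET", "ALLELIC", "ALLELIC", "OFF_TARGET"))
  # wrong position or strand on the marker contig is not TARGET
  h2 <- data.frame(contig = "c1a", start = 4999L, strand = "+",
                   mismatches = 0L)
  expect_identical(
    classify_hits(h2, 5000L, "+", "c1a", map), "OFF_TARGET")
  h3 <- data.frame(contig = "c1a", start = 5000L, strand = "-",
                   mismatches = 0L)
  expect_identical(
    classify_hits(h3, 5000L, "+", "c1a", map), "OFF_TARGET")
  # shrinking the window demotes ALLELIC to OFF_TARGET, never the reverse
  far <- data.frame(contig = "c1b", start = 5600L, strand = "+",
                    mismatches = 0L)
  expect_identical(classify_hits(far, 5000L, "+", "c1a", map,
                                 window = 1000), "ALLELIC")
  expect_identical(classify_hits(far, 5000L, "+", "c1a", map,
                                 window = 100), "OFF_TARGET")
  # unknown contig warns and is off-target
  expect_warning(
    cls4 <- classify_hits(data.frame(contig = "zz", start = 1L,
                                     strand = "+", mismatches = 0L),
                          5000L, "+", "c1a", map),
    "absent")
  expect_identical(cls4, "OFF_TARGET")
})

test_that("amplicons are predicted for convergent hit pairs only", {
  fwd <- data.frame(contig = "c1", start = 100L, strand = "+",
                    mismatches = 0L, stringsAsFactors = FALSE)
  rev <- data.frame(contig = "c1", start = 230L, strand = "-",
                    mismatches = 0L, stringsAsFactors = FALSE)
  amp <- predict_amplicons(fwd, rev, fwd_len = 20, rev_len = 20)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$size, 230L + 20L - 100L)
  # divergent orientation: no amplicon
  expect_identical(nrow(predict_amplicons(rev, fwd, 20, 20)), 0L)
  # two forward hits in range of one reverse hit: two amplicons
  fwd2 <- rbind(fwd, data.frame(contig = "c1", start = 150L,
                                strand = "+", mismatches = 0L))
  expect_identical(nrow(predict_amplicons(fwd2, rev, 20, 20)), 2L)
  # out of size range
  revfar <- transform(rev, start = 99000L)
  expect_identical(nrow(predict_amplicons(fwd, revfar, 20, 20)), 0L)
})

test_that("screening retains clean markers and rejects spiked ones", {
  cfg <- sim_config(n_groups = 3, copies_per_group = 6, contig_len = 6e4,
                    n_indels = 20, n_samples = 20, frac_len = 0,
                    frac_maf = 0, frac_het = 0, frac_multi = 0, seed = 609)
  ref <- simulate_reference(cfg)
  sim <- simulate_variants(cfg, ref)
  sp <- spike_off_target(ref, sim, k = 5, seed = 610)
  cand <- marker_candidate_filter(sim$variants)
  des <- design_primers(sp$genome, cand)
  idx <- build_kmer_index(sp$genome)
  scr <- screen_pairs(des$pairs, idx, ref$map)
  retained_marker <- tapply(scr$retained, scr$marker_id, any)
  spiked <- sp$truth$marker_id[sp$truth$spiked]
  for (m in names(retained_marker)) {
    expect_identical(unname(retained_marker[m]), !(m %in% spiked))
  }
  # spiked markers fail for the off-target reason
  expect_true(all(scr$reason[scr$marker_id %in% spiked] == "OFF_TARGET"))
  # a primer pair absent from the genome has no target hit
  fake <- des$pairs[1, ]
  fake$fwd_seq <- "ACGTACGTACGTACGTACGTAC"
  rep1 <- screen_pair(fake, idx, ref$map)
  expect_false(rep1$retained)
  expect_identical(rep1$reason, "NO_TARGET_HIT")
})

test_that("strict-mode retention implies amplicon-mode retention", {
  cfg <- sim_config(n_groups = 2, copies_per_group = 6, contig_len = 6e4,
                    n_indels = 12, n_samples = 10, frac_len = 0,
                    frac_maf = 0, frac_het = 0, frac_multi = 0, seed = 611)
  ref <- simulate_reference(cfg)
  sim <- simulate_variants(cfg, ref)
  sp <- spike_off_target(ref, sim, k = 3, seed = 612)
  cand <- marker_candidate_filter(sim$variants)
  des <- design_primers(sp$genome, cand)
  idx <- build_kmer_index(sp$genome)
  strict <- screen_pairs(des$pairs, idx, ref$map, mode = "strict")
  amp <- screen_pairs(des$pairs, idx, ref$map, mode = "amplicon")
  expect_true(all(!strict$retained | amp$retained))
})
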