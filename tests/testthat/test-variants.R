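vcf_text <- function(records, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

test_that("VCF genotypes parse as unphased diploid pairs", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text(c(
    "c1\t100\t.\tA\tAT\t50\t.\tQD=12.5\tGT\t0/1\t./.\t1/1",
    "c1\t200\t.\tGTTTTT\tG\t99\t.\t.\tGT\t0/0\t0|1\t./.")), f)
  vs <- read_vcf(f)
  expect_identical(length(vs), 2L)
  expect_identical(vs$samples, c("S1", "S2", "S3"))
  expect_identical(vs$a1[1, ], c(0L, NA, 1L))
  expect_identical(vs$a2[1, ], c(1L, NA, 1L))
  expect_identical(vs$a1[2, ], c(0L, 0L, NA))  # phased bar normalized
  expect_identical(vs$sites$QD, c(12.5, NA))
  expect_identical(vs$sites$pos, c(100L, 200L))
})

test_that("non-diploid genotypes are rejected", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_text("c1\t100\t.\tA\tAT\t50\t.\t.\tGT\t0/1\t0/1/1\t1/1"),
             f)
  expect_error(read_vcf(f), "ploidy")
})

test_that("variant sets round-trip through VCF text", {
  vs <- make_vs(ref = c("ATCTCTC", "A"), alt = c("AT", "AGGGGG"),
                genotypes = list(c("0/0", "0/1", "1/1", "./."),
                                 c("0/1", "0/1", "0/0", "1/1")),
                pos = c(500L, 900L), QD = c(10, 1.2), FS = c(5, NA),
                dp = matrix(c(20, 20, 2, 0, 15, 15, 15, 15), 2,
                            byrow = TRUE))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vs, f)
  vs2 <- read_vcf(f)
  expect_identical(vs2$sites$ref, vs$sites$ref)
  expect_identical(vs2$a1, vs$a1)
  expect_identical(vs2$a2, vs$a2)
  expect_equal(vs2$sites$QD, vs$sites$QD)
  expect_equal(unname(vs2$dp), unname(vs$dp))
})

test_that("hard filter applies the printed per-class inequalities", {
  # SNP with QD below threshold fails on QD
  snp <- make_vs("A", "T", list(c("0/1", "0/1", "0/0")), QD = 1.5)
  r <- hard_filter(snp)
  expect_identical(r$status, "FAIL")
  expect_identical(r$reasons, "QD")
  # InDel metrics are judged on the InDel thresholds (FS > 200, not > 60)
  ind <- make_vs("ATTTTTT", "A", list(c("0/1", "0/1", "0/0")),
                 QD = 10, FS = 100)
  expect_identical(hard_filter(ind)$status, "PASS")
  expect_identical(hard_filter(ind, "SNP")$status, "FAIL")
  # absent metrics never trigger a failure
  none <- make_vs("A", "T", list(c("0/1", "0/1", "0/0")))
  expect_identical(hard_filter(none)$status, "PASS")
  # multiple reasons accumulate
  worst <- make_vs("A", "T", list(c("0/1", "0/1", "0/0")),
                   QD = 1.0, FS = 70, MQ = 20)
  expect_identical(hard_filter(worst)$reasons, "QD;FS;MQ")
})

test_that("class dispatch is total over mixed SNP/InDel input", {
  vs <- make_vs(c("A", "AT", "G", "GCCCCC"), c("T", "A", "GA", "G"),
                genotypes = rep(list(c("0/1", "0/1", "0/0")), 4),
                pos = c(10L, 20L, 30L, 40L), FS = 100)
  expect_identical(variant_class(vs), c("SNP", "INDEL", "INDEL", "INDEL"))
  r <- hard_filter(vs)
  expect_identical(r$status, c("FAIL", "PASS", "PASS", "PASS"))
})

test_that("allele statistics match direct counting", {
  vs <- make_vs("ATCTCTC", "AT",
                list(c("0/0", "0/1", "1/1", "0/1", "./.")))
  st <- allele_stats(vs)
  expect_equal(st$call_rate, 0.8)
  expect_equal(st$maf, 0.5)
  expect_equal(st$het_fraction, 0.5)
  expect_equal(st$mac, 4)
  # monomorphic
  st0 <- allele_stats(make_vs("ATCTCTC", "AT",
                              list(c("0/0", "0/0", "0/0"))))
  expect_equal(st0$maf, 0)
  expect_equal(st0$het_fraction, 0)
  # no calls -> undefined, flagged by NA
  stNA <- allele_stats(make_vs("ATCTCTC", "AT",
                               list(c("./.", "./.", "./."))))
  expect_true(is.na(stNA$maf))
  expect_equal(stNA$call_rate, 0)
})

test_that("realized MAF of Hardy-Weinberg draws matches the counting oracle", {
  set.seed(401)
  p <- 0.3
  n <- 100
  g <- replicate(n, sort(stats::rbinom(2, 1, p)))
  gt <- apply(g, 2, paste, collapse = "/")
  vs <- make_vs("ATCTCTC", "AT", list(gt))
  st <- allele_stats(vs)
  ac <- sum(g)
  expect_equal(st$maf, min(ac, 2 * n - ac) / (2 * n))
  # within the binomial 99% band around p
  expect_lt(abs(st$maf - p), 2.58 * sqrt(p * (1 - p) / (2 * n)))
})

test_that("site filter masks low-depth genotypes before site statistics", {
  # 10 samples, 6 genotypes fall below dp_min -> call rate 0.4 < 0.5
  gt <- rep("0/1", 10)
  dp <- matrix(c(rep(2, 6), rep(20, 4)), 1)
  vs <- make_vs("ATTTTTT", "A", list(gt), dp = dp, qual = 100)
  out <- site_filter(vs)
  expect_identical(length(out), 0L)
  expect_false(attr(out, "retained"))
  # same site with adequate depth is kept
  vs2 <- make_vs("ATTTTTT", "A", list(gt),
                 dp = matrix(20, 1, 10), qual = 100)
  expect_identical(length(site_filter(vs2)), 1L)
})

test_that("site filter applies QUAL and MAF thresholds inclusively", {
  gt <- list(c(rep("0/1", 5), rep("0/0", 5)))
  low <- make_vs("ATTTTTT", "A", gt, qual = 29.9)
  hi <- make_vs("ATTTTTT", "A", gt, qual = 30)
  expect_identical(length(site_filter(low, dp_min = 0)), 0L)
  expect_identical(length(site_filter(hi, dp_min = 0)), 1L)
  # all-zero thresholds are the identity on called records
  vs <- make_vs(c("ATTTTTT", "A"), c("A", "ACCCCCC"),
                rep(list(c("0/1", "0/0", "1/1")), 2), pos = c(1L, 2L))
  out <- site_filter(vs, max_missing = 0, mac_min = 0, qual_min = 0,
                     maf_min = 0, dp_min = 0)
  expect_identical(length(out), 2L)
})

test_that("candidacy filter enforces the three marker rules", {
  mk <- function(ref, alt, gt) make_vs(ref, alt, list(gt))
  het4 <- c("0/0", "0/1", "0/1", "1/1", "0/0", "1/1", "0/0", "0/1",
            "0/0", "1/1") # het 0.3, maf 0.45
  # delta = 5, moderate het/maf -> retained
  expect_identical(length(marker_candidate_filter(
    mk("ATCTCTC", "AT", het4))), 1L)
  # delta = 3 -> rejected
  out <- marker_candidate_filter(mk("ACGT", "A", het4))
  expect_identical(length(out), 0L)
  expect_identical(attr(out, "reason"), "length_difference")
  # excess heterozygosity -> rejected
  het_all <- rep("0/1", 10)
  out <- marker_candidate_filter(mk("ATCTCTCTC", "A", het_all))
  expect_identical(attr(out, "reason"), "heterozygosity")
  # low MAF -> rejected
  rare <- c(rep("0/0", 9), "0/1") # maf 0.05
  out <- marker_candidate_filter(mk("ATCTCTCTC", "A", rare))
  expect_identical(attr(out, "reason"), "maf")
  # boundary values are retained: het exactly 0.80, maf exactly 0.2
  het8 <- c(rep("0/1", 8), "0/0", "1/1") # het 0.8, maf 0.5
  expect_identical(length(marker_candidate_filter(
    mk("ATCTCTC", "AT", het8))), 1L)
  maf2 <- c(rep("0/0", 6), rep("1/1", 2), rep("0/0", 2)) # maf 0.2
  expect_identical(length(marker_candidate_filter(
    mk("ATCTCTC", "AT", maf2))), 1L)
  # SNPs and multi-allelic records always rejected
  expect_identical(attr(marker_candidate_filter(mk("A", "T", het4)),
                        "reason"), "not_indel")
  expect_identical(attr(marker_candidate_filter(
    mk("A", "ATTTTT,ACCCCCC", het4)), "reason"), "multi_allelic")
})

test_that("candidacy filter is idempotent, order-preserving and a subset", {
  set.seed(402)
  cfg <- sim_config(n_groups = 2, copies_per_group = 2, contig_len = 6e4,
                    n_indels = 40, n_samples = 15, seed = 402)
  sim <- simulate_variants(cfg, simulate_reference(cfg))
  vs <- sim$variants
  once <- marker_candidate_filter(vs)
  twice <- marker_candidate_filter(once)
  expect_identical(once$sites, twice$sites)
  expect_true(all(attr(twice, "retained")))
  # subset + order preserved
  expect_true(all(once$sites$id %in% vs$sites$id))
  expect_identical(once$sites$id,
                   vs$sites$id[vs$sites$id %in% once$sites$id])
  # retained stats recomputed brute-force match the filter's decision
  st <- allele_stats(once)
  expect_true(all(st$het_fraction <= 0.80 & st$maf >= 0.2))
})

test_that("region classification prioritizes exon over intron", {
  gm <- list(gene_model("gA", "c1", "+", c(100, 300), c(200, 400)))
  vs <- make_vs(c("A", "A", "A"), c("T", "T", "T"),
                rep(list(c("0/1", "0/1")), 3), contig = "c1",
                pos = c(150L, 250L, 999L))
  expect_identical(classify_region(vs, gm),
                   c("exonic", "intronic", "intergenic"))
  expect_identical(classify_region(vs, list()),
                   rep("intergenic", 3))
})

test_that("coding effects follow frame arithmetic and the genetic code", {
  # gene on c1: CDS 11..40, plus strand; sequence designed by hand
  seq <- paste0(strrep("T", 10),
                "ATGGAAGCTTGGCCAGATAAACGCTTTACC", strrep("A", 10))
  genome <- structure(c(c1 = seq), class = "genome_set")
  g <- gene_model("g1", "c1", "+", 11, 40)
  # 4 bp deletion -> frameshift; 3 bp -> inframe
  expect_identical(coding_effect("c1", 15, "AAGCT", "A", g, genome),
                   "frameshift")
  expect_identical(coding_effect("c1", 15, "AAGC", "A", g, genome),
                   "inframe")
  # GAA -> GAG is synonymous (Glu); codon 2 is positions 14-16
  expect_identical(coding_effect("c1", 16, "A", "G", g, genome),
                   "synonymous")
  # GAA -> TAA is a stop gain
  expect_identical(coding_effect("c1", 14, "G", "T", g, genome),
                   "stopgain")
  # GAA -> GTA (Glu -> Val) nonsynonymous
  expect_identical(coding_effect("c1", 15, "A", "T", g, genome),
                   "nonsynonymous")
  # deletion spanning the CDS boundary
  expect_warning(
    eff <- coding_effect("c1", 38, "ACCAAAA", "A", g, genome),
    "boundary")
  expect_identical(eff, "not_applicable")
})

test_that("coding effects are strand-aware", {
  # minus-strand gene whose mRNA reads ATG GAA TAG on the revcomp
  # genomic plus strand 11..19 must be CTA TTC CAT
  seq <- paste0(strrep("G", 10), "CTATTCCAT", strrep("G", 10))
  genome <- structure(c(c1 = seq), class = "genome_set")
  g <- gene_model("g1", "c1", "-", 11, 19)
  # plus-strand T>C at pos 15 -> codon GAA becomes GGA (Glu->Gly)
  expect_identical(coding_effect("c1", 15, "T", "C", g, genome),
                   "nonsynonymous")
  # plus-strand T>C at pos 14 -> GAA becomes GAG (synonymous)
  expect_identical(coding_effect("c1", 14, "T", "C", g, genome),
                   "synonymous")
})

test_that("frameshift labels equal the length-mod-3 oracle on implanted InDels", {
  set.seed(403)
  seq <- paste0(strrep("C", 50), rand_dna(90), strrep("C", 50))
  genome <- structure(c(c1 = seq), class = "genome_set")
  g <- gene_model("g1", "c1", "+", 51, 140)
  for (i in 1:25) {
    d <- sample(1:9, 1)
    at <- sample(60:120, 1)
    ref <- substr(seq, at, at + d)
    eff <- coding_effect("c1", at, ref, substr(ref, 1, 1), g, genome)
    expect_identical(eff, if (d %% 3 == 0) "inframe" else "frameshift")
  }
})
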