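#' Variant set container
#'
#' In-memory representation of a multi-sample VCF: a site table plus
#' per-sample diploid allele-index matrices. Genotypes are diploid-style
#' even for polyploids, mirroring a diploid caller run on a hexaploid
#' (allele dosage is deliberately ignored).
#'
#' @param sites Data frame with columns `contig`, `pos`, `id`, `ref`, `alt`
#'   (comma-separated for multi-allelic records), `qual`, and the INFO
#'   metrics `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum` (NA when
#'   absent).
#' @param a1,a2 Integer matrices (sites x samples) of allele indices
#'   (0 = REF), `NA` for missing genotypes.
#' @param dp Optional numeric matrix of per-genotype read depths.
#' @param samples Character vector of sample names.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(sites, a1, a2, dp = NULL, samples = colnames(a1)) {
  stopifnot(nrow(sites) == nrow(a1), identical(dim(a1), dim(a2)))
  if (any(sites$pos < 1)) stop("POS must be >= 1")
  if (any(!nzchar(sites$ref))) stop("REF allele must be nonempty")
  n_alt <- lengths(strsplit(sites$alt, ",", fixed = TRUE))
  if (nrow(a1) > 0 && ncol(a1) > 0) {
    mx <- pmax(a1, a2, na.rm = TRUE)
    rmax <- suppressWarnings(apply(mx, 1, max, na.rm = TRUE))
    bad <- which(is.finite(rmax) & rmax > n_alt)
    if (length(bad)) {
      stop("genotype allele index exceeds allele count at record ", bad[1])
    }
  }
  structure(list(sites = sites, a1 = a1, a2 = a2, dp = dp,
                 samples = samples, n_alt = n_alt),
            class = "variant_set")
}

#' @exportS3Method print variant_set
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$sites), "record(s),",
      length(x$samples), "sample(s)\n")
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$sites)

#' Subset a variant set by record index
#' @param x A `variant_set`.
#' @param i Row indices (integer or logical).
#' @param ... Ignored.
#' @export
`[.variant_set` <- function(x, i, ...) {
  variant_set(x$sites[i, , drop = FALSE],
              x$a1[i, , drop = FALSE], x$a2[i, , drop = FALSE],
              dp = if (!is.null(x$dp)) x$dp[i, , drop = FALSE],
              samples = x$samples)
}

info_keys <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read a VCF into a variant set
#'
#' Parses a VCF 4.x file via vcfR, keeping record order and multi-allelic
#' records as-is. `./.` genotypes become missing; any genotype whose ploidy
#' is not 2 is an error (the pipeline's diploid-style contract).
#'
#' @param path VCF path (plain or gzipped text).
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt %in% c(".", "./.", ".|.")] <- NA_character_
  nfield <- stringi::stri_count_fixed(gsub("\\|", "/", gt), "/") + 1L
  dim(nfield) <- dim(gt)
  if (any(nfield != 2L, na.rm = TRUE)) {
    bad <- which(nfield != 2L, arr.ind = TRUE)[1, ]
    stop("genotype ploidy != 2 at record ", bad[1], ", sample ",
         colnames(gt)[bad[2]], " (diploid-style calls required)",
         call. = FALSE)
  }
  norm <- gsub("\\|", "/", gt)
  a1 <- matrix(NA_integer_, nrow(gt), ncol(gt))
  a2 <- a1
  ok <- !is.na(norm)
  parts <- stringi::stri_split_fixed(norm[ok], "/", simplify = TRUE)
  v1 <- suppressWarnings(as.integer(parts[, 1]))
  v2 <- suppressWarnings(as.integer(parts[, 2]))
  a1[ok] <- v1
  a2[ok] <- v2
  half <- is.na(a1) != is.na(a2) | (ok & (is.na(a1) | is.na(a2)))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_
  dp <- NULL
  fmt <- v@gt[, "FORMAT"]
  if (any(grepl("(^|:)DP(:|$)", fmt))) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                            as.numeric = TRUE))
  }
  info <- as.data.frame(lapply(stats::setNames(info_keys, info_keys),
    function(k) {
      suppressWarnings(as.numeric(vcfR::extract.info(v, element = k)))
    }))
  sites <- data.frame(
    contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE)
  sites <- cbind(sites, info)
  variant_set(sites, a1, a2, dp = dp, samples = colnames(gt))
}

#' Write a variant set as VCF 4.2
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param filter Optional character vector for the FILTER column
#'   (default `PASS`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, filter = NULL) {
  n <- length(vs)
  if (is.null(filter)) filter <- rep("PASS", n)
  info <- vapply(seq_len(n), function(i) {
    vals <- unlist(vs$sites[i, info_keys])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(info_keys[keep], "=", format(vals[keep], trim = TRUE)),
          collapse = ";")
  }, character(1))
  gt <- matrix(".", n, length(vs$samples))
  called <- !is.na(vs$a1)
  gt[called] <- paste0(vs$a1[called], "/", vs$a2[called])
  gt[!called] <- "./."
  has_dp <- !is.null(vs$dp)
  if (has_dp) {
    dp <- vs$dp
    dp[is.na(dp)] <- 0
    gt <- matrix(paste0(gt, ":", as.integer(dp)), n)
  }
  hdr <- c("##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            info_keys, info_keys),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (has_dp)
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t"))
  qual <- ifelse(is.na(vs$sites$qual), ".",
                 format(vs$sites$qual, trim = TRUE))
  body <- paste(vs$sites$contig, vs$sites$pos, vs$sites$id, vs$sites$ref,
                vs$sites$alt, qual, filter, info,
                if (has_dp) "GT:DP" else "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Classify each record as SNP or INDEL
#' @param vs A [variant_set()].
#' @return Character vector, `"SNP"` when REF and every ALT have length 1,
#'   else `"INDEL"`.
#' @export
variant_class <- function(vs) {
  alt_max <- vapply(strsplit(vs$sites$alt, ",", fixed = TRUE),
                    function(a) max(nchar(a)), integer(1))
  ifelse(nchar(vs$sites$ref) == 1L & alt_max == 1L, "SNP", "INDEL")
}

#' GATK-style hard filter
#'
#' Applies the per-class INFO-metric thresholds used for variant quality
#' control: SNPs fail on `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -12.5` or `ReadPosRankSum < -8.0`; InDels fail on
#' `QD < 2.0`, `FS > 200.0` or `ReadPosRankSum < -20.0`. A metric absent
#' from a record never triggers a failure (its clause is skipped).
#'
#' @param vs A [variant_set()].
#' @param vclass `"auto"` (dispatch per record on allele lengths), `"SNP"`
#'   or `"INDEL"`.
#' @return Data frame with columns `status` (`"PASS"`/`"FAIL"`) and
#'   `reasons` (semicolon-joined failing metric names, `""` on pass).
#' @export
hard_filter <- function(vs, vclass = c("auto", "SNP", "INDEL")) {
  vclass <- match.arg(vclass)
  cls <- if (vclass == "auto") variant_class(vs) else
    rep(vclass, length(vs))
  s <- vs$sites
  fails <- function(metric, op, thr) {
    x <- s[[metric]]
    !is.na(x) & op(x, thr)
  }
  reasons <- vector("list", length(vs))
  snp <- cls == "SNP"
  rules_snp <- list(QD = fails("QD", `<`, 2.0), FS = fails("FS", `>`, 60.0),
                    MQ = fails("MQ", `<`, 40.0),
                    MQRankSum = fails("MQRankSum", `<`, -12.5),
                    ReadPosRankSum = fails("ReadPosRankSum", `<`, -8.0))
  rules_ind <- list(QD = fails("QD", `<`, 2.0), FS = fails("FS", `>`, 200.0),
                    ReadPosRankSum = fails("ReadPosRankSum", `<`, -20.0))
  for (i in seq_len(length(vs))) {
    rules <- if (snp[i]) rules_snp else rules_ind
    reasons[[i]] <- names(rules)[vapply(rules, `[`, logical(1), i)]
  }
  reason <- vapply(reasons, paste, character(1), collapse = ";")
  data.frame(status = ifelse(nzchar(reason), "FAIL", "PASS"),
             reasons = reason, stringsAsFactors = FALSE)
}

#' Per-site allele statistics
#'
#' Call rate, minor allele count/frequency and heterozygous fraction,
#' computed over called genotypes only. For multi-allelic records the minor
#' count pools every non-major allele; heterozygosity is "the two allele
#' indices differ". Records with zero called genotypes get `NA` statistics
#' and automatically fail downstream threshold filters.
#'
#' @param vs A [variant_set()].
#' @return Data frame with columns `call_rate`, `mac`, `maf`,
#'   `het_fraction`, `n_called`.
#' @export
allele_stats <- function(vs) {
  ns <- length(vs$samples)
  called <- !is.na(vs$a1)
  n_called <- rowSums(called)
  het <- rowSums(vs$a1 != vs$a2, na.rm = TRUE)
  het_fraction <- ifelse(n_called > 0, het / n_called, NA_real_)
  mac <- maf <- rep(NA_real_, length(vs))
  multi <- vs$n_alt > 1L
  # bi-allelic fast path
  bi <- !multi & n_called > 0
  if (any(bi)) {
    ac <- rowSums(vs$a1 == 1L, na.rm = TRUE) +
      rowSums(vs$a2 == 1L, na.rm = TRUE)
    tot <- 2 * n_called
    mac[bi] <- pmin(ac, tot - ac)[bi]
    maf[bi] <- (mac / tot)[bi]
  }
  for (i in which(multi & n_called > 0)) {
    al <- c(vs$a1[i, ], vs$a2[i, ])
    al <- al[!is.na(al)]
    mac[i] <- length(al) - max(tabulate(al + 1L))
    maf[i] <- mac[i] / length(al)
  }
  data.frame(call_rate = n_called / ns, mac = mac, maf = maf,
             het_fraction = het_fraction, n_called = n_called)
}

#' Cohort site filter
#'
#' vcftools-style site filtering. Genotypes whose depth is below `dp_min`
#' are set missing before site statistics are computed (disable with
#' `mask_depth = FALSE`); a site is then retained iff its call rate is at
#' least `max_missing` (vcftools `--max-missing` semantics: the minimum
#' fraction of called samples), `mac >= mac_min`, `qual >= qual_min`
#' (missing QUAL tolerated) and `maf >= maf_min`. Defaults reproduce
#' `--max-missing 0.5 --mac 3 --minQ 30 --maf 0.05 --minDP 3`.
#'
#' @param vs A [variant_set()].
#' @param max_missing Minimum call-rate fraction.
#' @param mac_min Minimum minor allele count.
#' @param qual_min Minimum site QUAL.
#' @param maf_min Minimum minor allele frequency.
#' @param dp_min Per-genotype depth below which a genotype is masked.
#' @param mask_depth Apply the depth mask before computing statistics?
#' @return The retained records as a [variant_set()] (with the depth mask
#'   applied), carrying a logical attribute `retained` over the input.
#' @export
site_filter <- function(vs, max_missing = 0.5, mac_min = 3, qual_min = 30,
                        maf_min = 0.05, dp_min = 3, mask_depth = TRUE) {
  stopifnot(max_missing >= 0, mac_min >= 0, qual_min >= 0, maf_min >= 0,
            dp_min >= 0)
  if (mask_depth && !is.null(vs$dp)) {
    low <- !is.na(vs$dp) & vs$dp < dp_min & !is.na(vs$a1)
    vs$a1[low] <- NA_integer_
    vs$a2[low] <- NA_integer_
  }
  st <- allele_stats(vs)
  qual_ok <- is.na(vs$sites$qual) | vs$sites$qual >= qual_min
  keep <- st$call_rate >= max_missing &
    !is.na(st$mac) & st$mac >= mac_min &
    qual_ok &
    !is.na(st$maf) & st$maf >= maf_min
  out <- vs[keep]
  attr(out, "retained") <- keep
  out
}

#' Marker-candidacy filter for InDels
#'
#' Screens variants down to PCR-marker candidates by three rules: (i) only
#' bi-allelic InDels are kept (SNPs and multi-allelic records rejected);
#' (ii) the REF/ALT length difference must be at least `delta_min` bases
#' (default 5, the smallest difference resolvable on PAGE); (iii) records
#' with heterozygosity above `het_max` or minor allele frequency below
#' `maf_min` are removed (boundary values retained). Record order is
#' preserved and the operation is idempotent.
#'
#' @param vs A [variant_set()].
#' @param delta_min Minimum `abs(nchar(ref) - nchar(alt))`.
#' @param het_max Maximum heterozygous fraction (retained when `<=`).
#' @param maf_min Minimum minor allele frequency (retained when `>=`).
#' @return Retained records as a [variant_set()], with attributes
#'   `retained` (logical over the input) and `reason` (first failing rule
#'   per record, `""` when retained).
#' @export
marker_candidate_filter <- function(vs, delta_min = 5, het_max = 0.80,
                                    maf_min = 0.2) {
  st <- allele_stats(vs)
  ref_len <- nchar(vs$sites$ref)
  alt_len <- nchar(vs$sites$alt) # single allele when bi-allelic
  biallelic <- vs$n_alt == 1L
  is_snp <- biallelic & ref_len == 1L & alt_len == 1L
  delta <- abs(ref_len - alt_len)
  reason <- character(length(vs))
  reason[!biallelic] <- "multi_allelic"
  reason[is_snp] <- "not_indel"
  ok_len <- biallelic & !is_snp & delta >= delta_min
  reason[biallelic & !is_snp & !ok_len] <- "length_difference"
  undef <- is.na(st$maf)
  het_bad <- !undef & st$het_fraction > het_max
  maf_bad <- !undef & st$maf < maf_min
  sel <- ok_len & reason == ""
  reason[sel & undef] <- "no_called_genotypes"
  reason[sel & het_bad] <- "heterozygosity"
  reason[sel & !het_bad & maf_bad] <- "maf"
  keep <- reason == ""
  out <- vs[keep]
  attr(out, "retained") <- keep
  attr(out, "reason") <- reason
  out
}

#' Classify variant positions by genomic region
#'
#' A variant is `exonic` when its POS falls inside any CDS interval,
#' `intronic` when inside a gene span but no CDS, else `intergenic`
#' (priority exonic > intronic across overlapping genes).
#'
#' @param vs A [variant_set()].
#' @param gene_models List of [gene_model()] objects (possibly empty).
#' @return Character vector over
#'   `c("exonic", "intronic", "intergenic")`.
#' @export
classify_region <- function(vs, gene_models) {
  out <- rep("intergenic", length(vs))
  if (!length(gene_models)) return(out)
  pts <- GenomicRanges::GRanges(vs$sites$contig,
                                IRanges::IRanges(vs$sites$pos, vs$sites$pos))
  cds <- do.call(c, lapply(gene_models, function(g) {
    GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$cds$start, g$cds$end))
  }))
  spans <- do.call(c, lapply(gene_models, function(g) {
    GenomicRanges::GRanges(g$contig, IRanges::IRanges(g$span[1], g$span[2]))
  }))
  suppressWarnings({
    in_gene <- IRanges::overlapsAny(pts, spans)
    in_cds <- IRanges::overlapsAny(pts, cds)
  })
  out[in_gene] <- "intronic"
  out[in_cds] <- "exonic"
  out
}

#' Coding effect of an exonic variant
#'
#' InDels are `frameshift` when the REF/ALT length difference is not a
#' multiple of 3, else `inframe`. SNPs are translated strand-aware through
#' the standard genetic code on the affected codon: `synonymous`,
#' `nonsynonymous`, or `stopgain`. A variant whose REF allele crosses a CDS
#' boundary is `not_applicable` (with a warning).
#'
#' @param contig,pos,ref,alt One variant (bi-allelic).
#' @param gene A [gene_model()] containing the position.
#' @param genome A `genome_set` for codon lookup.
#' @return One of `"frameshift"`, `"inframe"`, `"synonymous"`,
#'   `"nonsynonymous"`, `"stopgain"`, `"not_applicable"`.
#' @export
coding_effect <- function(contig, pos, ref, alt, gene, genome) {
  stopifnot(identical(contig, gene$contig))
  cds <- gene$cds
  hit <- which(cds$start <= pos & pos <= cds$end)
  if (!length(hit)) return("not_applicable")
  ref_end <- pos + nchar(ref) - 1L
  if (ref_end > cds$end[hit[1]]) {
    warning("variant spans a CDS boundary; effect not applicable")
    return("not_applicable")
  }
  if (nchar(ref) != nchar(alt)) {
    delta <- abs(nchar(ref) - nchar(alt))
    return(if (delta %% 3L != 0L) "frameshift" else "inframe")
  }
  if (nchar(ref) != 1L) return("not_applicable")
  # CDS-relative coordinate in transcription order
  seq <- genome[[gene$contig]]
  ord <- seq_len(nrow(cds))
  cpos <- 0L
  for (i in ord) {
    if (cds$start[i] <= pos && pos <= cds$end[i]) {
      cpos <- cpos + if (gene$strand == "+") pos - cds$start[i] + 1L else
        cds$end[i] - pos + 1L
      break
    }
    cpos <- cpos + cds$end[i] - cds$start[i] + 1L
  }
  cpos <- cpos - gene$phase
  if (cpos < 1L) return("not_applicable")
  codon_idx <- (cpos - 1L) %/% 3L
  within <- (cpos - 1L) %% 3L + 1L
  cds_seq <- paste(vapply(ord, function(i) {
    s <- substr(seq, cds$start[i], cds$end[i])
    if (gene$strand == "-") revcomp(s) else s
  }, character(1)), collapse = "")
  cds_seq <- substr(cds_seq, gene$phase + 1L, nchar(cds_seq))
  codon <- substr(cds_seq, codon_idx * 3L + 1L, codon_idx * 3L + 3L)
  if (nchar(codon) < 3L) return("not_applicable")
  base <- if (gene$strand == "+") alt else revcomp(alt)
  codon_alt <- codon
  substr(codon_alt, within, within) <- base
  aa <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  if (identical(aa, aa_alt)) "synonymous"
  else if (aa_alt == "*") "stopgain"
  else "nonsynonymous"
}
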