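#' Simulation configuration
#'
#' Conditions for the synthetic hexaploid-like fixture: `n_groups`
#' homology groups of `copies_per_group` near-identical copies derived
#' from one ancestral sequence by independent substitutions (no
#' inter-copy indels, so copy coordinates stay collinear), with bi-allelic
#' InDels implanted on the reference copy of each group and diploid-style
#' genotypes drawn per sample. A configured fraction of InDels violates
#' each marker-candidacy rule so every filter branch is exercised:
#' `frac_len` (length difference below 5), `frac_maf` (low minor allele
#' frequency), `frac_het` (excess heterozygosity), `frac_multi`
#' (multi-allelic); the remainder are clean candidates.
#'
#' @param n_groups Homology groups.
#' @param copies_per_group Copies per group (six mirrors a hexaploid).
#' @param contig_len Copy length (bp).
#' @param divergence Per-base substitution rate of each copy from its
#'   ancestor.
#' @param n_samples Cohort size.
#' @param n_indels InDels to implant (templates are kept >= 450 bp apart).
#' @param indel_len_range REF/ALT length-difference range (bp) across all
#'   categories; clean markers use `[max(5, min), max]`.
#' @param maf_clean,maf_low Minor-allele-frequency ranges for clean and
#'   MAF-violating markers.
#' @param het_high Heterozygosity range for het-violating markers.
#' @param missing_rate Per-genotype missingness.
#' @param frac_len,frac_maf,frac_het,frac_multi Violation fractions.
#' @param spike_off_target Number of clean templates to duplicate at
#'   non-homologous positions (tests the specificity screen).
#' @param seed Integer seed; all outputs are byte-stable under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_groups = 3, copies_per_group = 6,
                       contig_len = 1e6, divergence = 0.01,
                       n_samples = 50, n_indels = 5000,
                       indel_len_range = c(1, 30),
                       maf_clean = c(0.25, 0.5), maf_low = c(0.05, 0.15),
                       het_high = c(0.85, 0.95), missing_rate = 0.05,
                       frac_len = 0.2, frac_maf = 0.2, frac_het = 0.2,
                       frac_multi = 0.2, spike_off_target = 0, seed = 1) {
  stopifnot(divergence >= 0, divergence <= 1, missing_rate >= 0,
            missing_rate <= 1, frac_len + frac_maf + frac_het +
              frac_multi <= 1, n_indels >= 1, spike_off_target >= 0)
  structure(as.list(environment()), class = "sim_config")
}

slot_width <- function(config) 450L + max(config$indel_len_range) + 20L

rand_bases <- function(n) {
  c("A", "C", "G", "T")[sample.int(4L, n, replace = TRUE)]
}

#' Simulate a multi-subgenome reference
#'
#' Per homology group one ancestral sequence is drawn; each copy then
#' receives independent substitutions at the configured per-base
#' divergence (never to the same base). Copy `a` of each group is flagged
#' as the reference. Copies are mutually collinear, so coordinate
#' projection between them is the identity.
#'
#' @param config A [sim_config()].
#' @return List: `genome` (a `genome_set`), `map` (a `subgenome_map` with
#'   lengths).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  bases <- charToRaw("ACGT")
  seqs <- character(0)
  rows <- list()
  for (g in seq_len(config$n_groups)) {
    anc <- bases[sample.int(4L, config$contig_len, replace = TRUE)]
    for (cp in seq_len(config$copies_per_group)) {
      nm <- sprintf("chr%02d%s", g, letters[cp])
      copy <- anc
      nmut <- stats::rbinom(1L, config$contig_len, config$divergence)
      if (nmut > 0) {
        at <- sample.int(config$contig_len, nmut)
        cur <- match(copy[at], bases)
        copy[at] <- bases[(cur + sample.int(3L, nmut, replace = TRUE) - 1L)
                          %% 4L + 1L]
      }
      seqs[nm] <- rawToChar(copy)
      rows[[length(rows) + 1L]] <-
        data.frame(group_id = sprintf("g%d", g), contig_id = nm,
                   is_reference = as.integer(cp == 1L),
                   stringsAsFactors = FALSE)
    }
  }
  rows <- do.call(rbind, rows)
  map <- subgenome_map(rows$group_id, rows$contig_id, rows$is_reference)
  genome <- structure(seqs, class = "genome_set")
  list(genome = genome, map = set_contig_lengths(map, genome))
}

# direct-counting candidacy truth on the *realized* genotype matrix;
# deliberately a separate code path from allele_stats()
truth_decision <- function(a1_row, a2_row, n_alt, delta) {
  if (n_alt != 1L) return(list(ok = FALSE, maf = NA, het = NA))
  called <- which(!is.na(a1_row))
  if (!length(called)) return(list(ok = FALSE, maf = NA, het = NA))
  alleles <- c(a1_row[called], a2_row[called])
  ac <- sum(alleles == 1L)
  maf <- min(ac, length(alleles) - ac) / length(alleles)
  het <- sum(a1_row[called] != a2_row[called]) / length(called)
  list(ok = delta >= 5 && het <= 0.80 && maf >= 0.2, maf = maf, het = het)
}

#' Simulate an InDel cohort VCF with ground truth
#'
#' Implants `n_indels` InDels on the reference copies at mutually disjoint
#' template slots, draws diploid-style genotypes per sample from
#' per-marker target minor-allele-frequency/heterozygosity models, masks
#' genotypes at the configured missing rate, and records a truth table.
#' The truth candidacy decision is computed from the genotypes actually
#' emitted (by direct counting, an independent code path from the
#' filters), since finite cohorts can realize a statistic across a
#' threshold.
#'
#' @param config A [sim_config()].
#' @param reference Output of [simulate_reference()].
#' @return List: `variants` (a [variant_set()]), `truth` (data frame with
#'   per-marker category, realized statistics and `candidate`), `bands`
#'   (expected band-state matrix, samples x bi-allelic markers).
#' @export
simulate_variants <- function(config, reference) {
  set.seed(config$seed + 1L)
  genome <- reference$genome
  map <- reference$map
  refs <- map$contig_id[map$is_reference == 1L]
  sw <- slot_width(config)
  slots <- lapply(refs, function(ct) {
    len <- nchar(genome[[ct]])
    seq(250L + sw, len - sw - 250L, by = sw)
  })
  total <- sum(lengths(slots))
  if (config$n_indels > total) {
    stop("placement infeasible: ", config$n_indels, " InDels need ",
         config$n_indels, " disjoint ", sw, " bp template slots but only ",
         total, " fit; reduce n_indels or raise contig_len")
  }
  # spread markers over reference copies proportionally to slot counts
  n_per <- floor(lengths(slots) * config$n_indels / total)
  while (sum(n_per) < config$n_indels) {
    k <- which.max(lengths(slots) - n_per)
    n_per[k] <- n_per[k] + 1L
  }
  contig <- character(0)
  pos <- integer(0)
  for (k in seq_along(refs)) {
    at <- sort(sample(slots[[k]], n_per[k]))
    contig <- c(contig, rep(refs[k], n_per[k]))
    pos <- c(pos, at)
  }
  n <- config$n_indels
  counts <- floor(n * c(len = config$frac_len, maf = config$frac_maf,
                        het = config$frac_het, multi = config$frac_multi))
  category <- sample(rep(c(names(counts), "clean"),
                         c(counts, n - sum(counts))))
  lo <- config$indel_len_range[1]
  hi <- config$indel_len_range[2]
  d_ok <- function(m) sample(seq(max(5L, lo), hi), m, replace = TRUE)
  delta <- integer(n)
  delta[category == "len"] <- sample(seq(max(1L, lo), 4L),
                                     sum(category == "len"), replace = TRUE)
  delta[category != "len"] <- d_ok(sum(category != "len"))
  is_del <- sample(c(TRUE, FALSE), n, replace = TRUE)

  ref <- alt <- character(n)
  n_alt <- rep(1L, n)
  for (i in seq_len(n)) {
    s <- genome[[contig[i]]]
    if (category[i] == "multi") {
      anchor <- substr(s, pos[i], pos[i])
      d2 <- delta[i] + sample(c(-2L, -1L, 1L, 2L), 1L)
      d2 <- max(1L, d2)
      ref[i] <- anchor
      alt[i] <- paste0(anchor, paste(rand_bases(delta[i]), collapse = ""),
                       ",",
                       paste0(anchor, paste(rand_bases(d2), collapse = "")))
      n_alt[i] <- 2L
    } else if (is_del[i]) {
      ref[i] <- substr(s, pos[i], pos[i] + delta[i])
      alt[i] <- substr(s, pos[i], pos[i])
    } else {
      ref[i] <- substr(s, pos[i], pos[i])
      alt[i] <- paste0(ref[i], paste(rand_bases(delta[i]), collapse = ""))
    }
  }

  # per-marker genotype model: P(het) = h, P(hom-alt) = m - h/2
  m <- stats::runif(n, config$maf_clean[1], config$maf_clean[2])
  h <- 2 * m * (1 - m)
  low <- category == "maf"
  m[low] <- stats::runif(sum(low), config$maf_low[1], config$maf_low[2])
  h[low] <- 2 * m[low] * (1 - m[low])
  hh <- category == "het"
  h[hh] <- stats::runif(sum(hh), config$het_high[1], config$het_high[2])
  m[hh] <- stats::runif(sum(hh), h[hh] / 2, 0.5)

  ns <- config$n_samples
  a1 <- matrix(NA_integer_, n, ns)
  a2 <- matrix(NA_integer_, n, ns)
  for (i in seq_len(n)) {
    if (n_alt[i] == 2L) {
      g1 <- sample(0:2, ns, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      g2 <- sample(0:2, ns, replace = TRUE, prob = c(0.5, 0.3, 0.2))
    } else {
      p_aa <- m[i] - h[i] / 2
      p_rr <- 1 - h[i] - p_aa
      g <- sample(0:2, ns, replace = TRUE, prob = c(p_rr, h[i], p_aa))
      g1 <- ifelse(g == 2L, 1L, ifelse(g == 1L, 0L, 0L))
      g2 <- ifelse(g >= 1L, 1L, 0L)
    }
    a1[i, ] <- pmin(g1, g2)
    a2[i, ] <- pmax(g1, g2)
  }
  if (config$missing_rate > 0) {
    miss <- matrix(stats::runif(n * ns) < config$missing_rate, n, ns)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }
  dp <- matrix(sample(10:60, n * ns, replace = TRUE), n, ns)
  dp[is.na(a1)] <- 0

  samples <- sprintf("S%03d", seq_len(ns))
  marker_id <- sprintf("M%05d", seq_len(n))
  sites <- data.frame(
    contig = contig, pos = pos, id = marker_id, ref = ref, alt = alt,
    qual = round(stats::runif(n, 100, 999), 1),
    QD = round(stats::runif(n, 10, 30), 2),
    FS = round(stats::runif(n, 0, 20), 3),
    MQ = round(stats::runif(n, 50, 60), 2),
    MQRankSum = round(stats::runif(n, -1, 1), 3),
    ReadPosRankSum = round(stats::runif(n, -1, 1), 3),
    stringsAsFactors = FALSE)
  vs <- variant_set(sites, a1, a2, dp = dp, samples = samples)

  truth <- data.frame(marker_id = marker_id, contig = contig, pos = pos,
                      category = category, delta = delta,
                      maf_real = NA_real_, het_real = NA_real_,
                      candidate = NA, spiked = FALSE,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    td <- truth_decision(a1[i, ], a2[i, ], n_alt[i], delta[i])
    truth$candidate[i] <- td$ok
    truth$maf_real[i] <- td$maf
    truth$het_real[i] <- td$het
  }
  bi <- n_alt == 1L
  bands <- matrix("N", ns, sum(bi), dimnames = list(samples, marker_id[bi]))
  b1 <- t(a1[bi, , drop = FALSE])
  b2 <- t(a2[bi, , drop = FALSE])
  called <- !is.na(b1)
  bands[called & b1 == 0L & b2 == 0L] <- "R"
  bands[called & b1 == 1L & b2 == 1L] <- "A"
  bands[called & b1 != b2] <- "H"
  list(variants = vs, truth = truth, bands = bands)
}

#' Spike marker templates at off-target positions
#'
#' Copies the full template (both flanks plus the REF allele) of `k`
#' randomly chosen truth-candidate markers onto a contig of a *different*
#' homology group, overwriting the destination sequence. Spiked markers
#' acquire genuine off-target primer binding sites and must be rejected by
#' the specificity screen; destinations avoid every existing template
#' region, so no other marker is disturbed.
#'
#' @param reference Output of [simulate_reference()] (or the modified
#'   result of a previous spike).
#' @param sim Output of [simulate_variants()].
#' @param k Number of templates to spike.
#' @param seed Seed for the choice of markers and destinations.
#' @return List: `genome` (modified `genome_set`), `manifest` (data frame
#'   `marker_id`, `src_contig`, `dest_contig`, `dest_start`), `truth` (the
#'   input truth table with `spiked` updated).
#' @export
spike_off_target <- function(reference, sim, k, seed = 1) {
  truth <- sim$truth
  genome <- reference$genome
  map <- reference$map
  if (k == 0) {
    return(list(genome = genome, manifest = data.frame(
      marker_id = character(), src_contig = character(),
      dest_contig = character(), dest_start = integer(),
      stringsAsFactors = FALSE), truth = truth))
  }
  cand <- which(truth$candidate)
  stopifnot(k <= length(cand))
  set.seed(seed)
  chosen <- sort(sample(cand, k))
  manifest <- list()
  used <- list() # dest starts already spiked, per contig
  for (i in chosen) {
    src_ct <- truth$contig[i]
    ref_allele <- sim$variants$sites$ref[i]
    span_start <- truth$pos[i] - 200L
    span_end <- truth$pos[i] + nchar(ref_allele) - 1L + 200L
    tpl <- substr(genome[[src_ct]], span_start, span_end)
    src_grp <- map$group_id[match(src_ct, map$contig_id)]
    dest_cts <- map$contig_id[map$group_id != src_grp]
    placed <- FALSE
    for (dest_ct in sample(dest_cts)) {
      dlen <- nchar(genome[[dest_ct]])
      # occupied = projected template regions of markers on this group's
      # reference copy (copies are collinear), padded
      dest_grp <- map$group_id[match(dest_ct, map$contig_id)]
      ref_of_grp <- map$contig_id[map$group_id == dest_grp &
                                    map$is_reference == 1L]
      occ_pos <- truth$pos[truth$contig == ref_of_grp]
      starts <- seq(300L, dlen - nchar(tpl) - 300L, by = nchar(tpl) + 50L)
      taken <- used[[dest_ct]]
      free <- starts[vapply(starts, function(s) {
        !any(occ_pos >= s - 700L & occ_pos <= s + nchar(tpl) + 700L) &&
          (is.null(taken) ||
             !any(abs(taken - s) < nchar(tpl) + 700L))
      }, logical(1))]
      if (!length(free)) next
      at <- sample(free, 1L)
      used[[dest_ct]] <- c(taken, at)
      substr(genome[[dest_ct]], at, at + nchar(tpl) - 1L) <- tpl
      manifest[[length(manifest) + 1L]] <-
        data.frame(marker_id = truth$marker_id[i], src_contig = src_ct,
                   dest_contig = dest_ct, dest_start = at,
                   stringsAsFactors = FALSE)
      truth$spiked[i] <- TRUE
      placed <- TRUE
      break
    }
    if (!placed) stop("no free destination slot for spiked template")
  }
  list(genome = genome, manifest = do.call(rbind, manifest), truth = truth)
}
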