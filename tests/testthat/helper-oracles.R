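# Independent oracles and fixture builders shared across the suite.
# Each oracle is deliberately coded from scratch (plain loops, its own
# parameter table) so it never shares a code path with the implementation
# it checks.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- melting temperature: term-by-term nearest-neighbor summation --------
# dH kcal/mol, dS cal/(mol K); duplexes keyed by their printed orientation,
# the complementary orientation resolved by reverse complement.
tm_oracle <- function(seq, mono_mM = 50, ct_nM = 50) {
  tab <- list(AA = c(-7.9, -22.2), AT = c(-7.2, -20.4),
              TA = c(-7.2, -21.3), CA = c(-8.5, -22.7),
              GT = c(-8.4, -22.4), CT = c(-7.8, -21.0),
              GA = c(-8.2, -22.2), CG = c(-10.6, -27.2),
              GC = c(-9.8, -24.4), GG = c(-8.0, -19.9))
  rc2 <- function(x) {
    b <- rev(strsplit(x, "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A")[b], collapse = "")
  }
  b <- strsplit(seq, "")[[1]]
  dh <- 0
  ds <- 0
  for (term in c(b[1], b[length(b)])) {
    if (term %in% c("A", "T")) {
      dh <- dh + 2.3
      ds <- ds + 4.1
    } else {
      dh <- dh + 0.1
      ds <- ds - 2.8
    }
  }
  for (i in seq_len(length(b) - 1)) {
    key <- paste0(b[i], b[i + 1])
    v <- tab[[key]]
    if (is.null(v)) v <- tab[[rc2(key)]]
    dh <- dh + v[1]
    ds <- ds + v[2]
  }
  ds <- ds + 0.368 * (length(b) - 1) * log(mono_mM / 1000)
  1000 * dh / (ds + 1.987 * log(ct_nM * 1e-9 / 4)) - 273.15
}

# --- primer-pair enumeration: exhaustive (start, len) search -------------
enumerate_oracle <- function(template, constraints = design_constraints(),
                             thermo = thermo_params()) {
  one_side <- function(flank_seq, reverse) {
    rows <- list()
    for (L in seq(constraints$primer_len[1], constraints$primer_len[2])) {
      for (s in seq_len(max(0L, nchar(flank_seq) - L + 1L))) {
        p <- substr(flank_seq, s, s + L - 1L)
        if (reverse) p <- revcomp(p)
        gc <- sum(strsplit(p, "")[[1]] %in% c("G", "C")) / L
        if (gc < constraints$gc_range[1] || gc > constraints$gc_range[2])
          next
        if (grepl("A{5}|C{5}|G{5}|T{5}", p)) next
        tm <- melting_temperature(p, thermo)
        if (tm < constraints$tm_range[1] || tm > constraints$tm_range[2])
          next
        if (!dimer_screen(p, p)$pass) next
        rows[[length(rows) + 1L]] <-
          data.frame(start = s, len = L, seq = p, tm = tm)
      }
    }
    do.call(rbind, rows)
  }
  fwd <- one_side(template$upstream, FALSE)
  rv <- one_side(template$downstream, TRUE)
  if (is.null(fwd) || is.null(rv)) return(NULL)
  fl <- nchar(template$upstream)
  rl <- nchar(template$ref_allele)
  rows <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rv))) {
      prod <- (fl - fwd$start[i] + 1L) + (rl - 1L) +
        (rv$start[j] + rv$len[j] - 1L)
      if (prod < constraints$product_len[1] ||
            prod > constraints$product_len[2]) next
      dtm <- abs(fwd$tm[i] - rv$tm[j])
      if (dtm >= constraints$max_tm_diff) next
      if (!dimer_screen(fwd$seq[i], rv$seq[j])$pass) next
      pen <- abs(fwd$tm[i] - 61) + abs(rv$tm[j] - 61) +
        0.5 * (abs(fwd$len[i] - 23) + abs(rv$len[j] - 23)) + dtm
      rows[[length(rows) + 1L]] <-
        data.frame(fwd_seq = fwd$seq[i], rev_seq = rv$seq[j],
                   fwd_start = fwd$start[i],
                   product_len_ref = prod, penalty = pen)
    }
  }
  if (!length(rows)) return(NULL)
  all <- do.call(rbind, rows)
  all <- all[order(all$penalty, all$fwd_start, all$product_len_ref,
                   all$fwd_seq), , drop = FALSE]
  head(all, constraints$max_pairs_per_template)
}

# --- primer hits: exhaustive per-offset matching via Biostrings ----------
hits_oracle <- function(primer, genome, max_mm = 2, t3 = 5) {
  out <- list()
  for (ct in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ct]])
    for (std in c("+", "-")) {
      pat <- if (std == "+") primer else revcomp(primer)
      m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                    max.mismatch = max_mm)
      if (!length(m)) next
      starts <- Biostrings::start(m)
      keep <- logical(length(m))
      mm <- integer(length(m))
      for (i in seq_along(m)) {
        reg <- as.character(subj[starts[i]:(starts[i] + nchar(pat) - 1L)])
        mm[i] <- sum(strsplit(reg, "")[[1]] != strsplit(pat, "")[[1]])
        zone_ok <- if (std == "+") {
          substr(reg, nchar(pat) - t3 + 1L, nchar(pat)) ==
            substr(pat, nchar(pat) - t3 + 1L, nchar(pat))
        } else {
          substr(reg, 1L, t3) == substr(pat, 1L, t3)
        }
        keep[i] <- mm[i] <= max_mm && zone_ok
      }
      if (any(keep)) {
        out[[length(out) + 1L]] <-
          data.frame(contig = ct, start = starts[keep], strand = std,
                     mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  o <- do.call(rbind, out)
  o <- o[order(o$contig, o$start, o$strand), , drop = FALSE]
  rownames(o) <- NULL
  o
}

# --- minimal discriminating subset: exhaustive search --------------------
optimal_subset_size <- function(bands) {
  pr <- utils::combn(nrow(bands), 2)
  resolved_by <- function(cols) {
    any_res <- rep(FALSE, ncol(pr))
    for (m in cols) {
      s <- bands[, m]
      any_res <- any_res | (s[pr[1, ]] != s[pr[2, ]] &
                              s[pr[1, ]] != "N" & s[pr[2, ]] != "N")
    }
    any_res
  }
  full <- resolved_by(seq_len(ncol(bands)))
  for (k in seq_len(ncol(bands))) {
    for (cols in utils::combn(ncol(bands), k, simplify = FALSE)) {
      if (all(resolved_by(cols) == full)) return(k)
    }
  }
  ncol(bands)
}

# --- small hand-built variant sets ---------------------------------------
# genotypes: character vector like c("0/0", "0/1", "./.") per sample
make_vs <- function(ref, alt, genotypes, contig = "chr01a", pos = 500L,
                    qual = 100, QD = NA, FS = NA, MQ = NA, MQRankSum = NA,
                    ReadPosRankSum = NA, dp = NULL) {
  n <- length(ref)
  ns <- length(genotypes[[1]])
  a1 <- matrix(NA_integer_, n, ns)
  a2 <- matrix(NA_integer_, n, ns)
  for (i in seq_len(n)) {
    g <- genotypes[[i]]
    ok <- g != "./."
    sp <- do.call(rbind, strsplit(g[ok], "/"))
    a1[i, ok] <- as.integer(sp[, 1])
    a2[i, ok] <- as.integer(sp[, 2])
  }
  sites <- data.frame(
    contig = rep_len(contig, n), pos = rep_len(pos, n),
    id = sprintf("V%03d", seq_len(n)), ref = ref, alt = alt,
    qual = rep_len(qual, n), QD = rep_len(QD, n), FS = rep_len(FS, n),
    MQ = rep_len(MQ, n), MQRankSum = rep_len(MQRankSum, n),
    ReadPosRankSum = rep_len(ReadPosRankSum, n), stringsAsFactors = FALSE)
  variant_set(sites, a1, a2, dp = dp,
              samples = sprintf("S%02d", seq_len(ns)))
}

# a template whose flanks are drawn GC-balanced so pairs usually exist
random_template <- function(flank = 200, ref_len = 8, alt_len = 2) {
  structure(list(marker_id = "T1", contig = "c", indel_pos = flank,
                 upstream = rand_dna(flank), downstream = rand_dna(flank),
                 ref_allele = rand_dna(ref_len),
                 alt_allele = rand_dna(alt_len), flank = flank),
            class = "template_window")
}
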