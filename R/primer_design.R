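#' Primer design constraints
#'
#' The printed acceptance windows every emitted pair must satisfy: product
#' length 100-200 bp, melting temperature 58-64 degrees C, forward/reverse
#' Tm difference strictly below 2 degrees C, GC content 35-65%, primer
#' length 20-26 bp. All bounds are inclusive except the Tm difference.
#'
#' @param product_len Product length range (bp), on the REF allele.
#' @param tm_range Primer Tm range (degrees C).
#' @param max_tm_diff Strict upper bound on `|Tm_fwd - Tm_rev|`.
#' @param gc_range GC fraction range.
#' @param primer_len Primer length range (bp).
#' @param max_pairs_per_template Pairs returned per template.
#' @param max_homopolymer Primers with a single-base run of this length or
#'   more are rejected (stability heuristic).
#' @return A `design_constraints` list.
#' @export
design_constraints <- function(product_len = c(100, 200),
                               tm_range = c(58, 64),
                               max_tm_diff = 2,
                               gc_range = c(0.35, 0.65),
                               primer_len = c(20, 26),
                               max_pairs_per_template = 5,
                               max_homopolymer = 5) {
  stopifnot(product_len[1] <= product_len[2], tm_range[1] <= tm_range[2],
            gc_range[1] <= gc_range[2], primer_len[1] <= primer_len[2],
            max_tm_diff > 0, max_pairs_per_template >= 1)
  structure(list(product_len = product_len, tm_range = tm_range,
                 max_tm_diff = max_tm_diff, gc_range = gc_range,
                 primer_len = primer_len,
                 max_pairs_per_template = max_pairs_per_template,
                 max_homopolymer = max_homopolymer),
            class = "design_constraints")
}

#' Thermodynamic model parameters
#'
#' Conditions for the nearest-neighbor melting-temperature engine:
#' monovalent cation and total oligo concentrations (conventional defaults
#' 50 mM / 50 nM).
#'
#' @param monovalent_mM Monovalent cation concentration (mM).
#' @param primer_nM Total oligo concentration (nM).
#' @return A `thermo_params` list.
#' @export
thermo_params <- function(monovalent_mM = 50, primer_nM = 50) {
  stopifnot(monovalent_mM > 0, primer_nM > 0)
  structure(list(monovalent_mM = monovalent_mM, primer_nM = primer_nM),
            class = "thermo_params")
}

#' GC content of a sequence
#'
#' @param seq Character vector of nonempty ACGT sequences.
#' @return Numeric vector of `(#G + #C) / length` fractions.
#' @export
gc_content <- function(seq) {
  if (any(!nzchar(seq))) stop("empty sequence")
  if (any(stringi::stri_detect_regex(seq, "[^ACGT]"))) {
    stop("gc_content requires ACGT-only sequences")
  }
  stringi::stri_count_regex(seq, "[GC]") / nchar(seq)
}

#' Oligo melting temperature
#'
#' Nearest-neighbor duplex Tm: the unified dH/dS parameter set is summed
#' over dinucleotide stacks with terminal initiation terms, the entropy is
#' salt-corrected by `0.368 (n-1) ln[Na+]`, and
#' `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15` for a non-self-complementary
#' oligo at total strand concentration `Ct`.
#'
#' @param seq Character vector of ACGT sequences, 8-36 bases.
#' @param params A [thermo_params()].
#' @return Numeric vector of Tm in degrees C.
#' @export
melting_temperature <- function(seq, params = thermo_params()) {
  n <- nchar(seq)
  if (any(n < 8 | n > 36)) {
    stop("melting_temperature requires lengths in [8, 36]")
  }
  if (any(stringi::stri_detect_regex(seq, "[^ACGT]"))) {
    stop("melting_temperature requires ACGT-only sequences")
  }
  tm_nn_cpp(seq, params$monovalent_mM, params$primer_nM)
}

#' Primer-dimer screen
#'
#' Computes the longest ungapped antiparallel complementary run between two
#' oligos (the longest common substring of `seq_a` and the reverse
#' complement of `seq_b`) and the runs anchored at either 3' end. Fails
#' when any run reaches 8 bases or a 3'-anchored run reaches 5. Use
#' `seq_b = seq_a` for a self-dimer screen.
#'
#' @param seq_a,seq_b ACGT oligo sequences (5' to 3').
#' @param run_thresh Failing overall run length.
#' @param end_thresh Failing 3'-anchored run length.
#' @return List with `pass`, `max_run`, `three_prime_run` (the larger of
#'   the two 3'-anchored runs).
#' @export
dimer_screen <- function(seq_a, seq_b, run_thresh = 8, end_thresh = 5) {
  st <- dimer_stats_cpp(seq_a, seq_b)
  list(pass = !(st[1] >= run_thresh || st[2] >= end_thresh ||
                  st[3] >= end_thresh),
       max_run = st[1], three_prime_run = max(st[2], st[3]))
}

#' Extract the flanking template of a candidate InDel
#'
#' The template is the `flank` bases upstream of and including the InDel's
#' anchor base (POS) plus the `flank` bases immediately after the REF
#' allele. Markers too close to a contig end, or whose flanks contain `N`,
#' are skipped rather than clamped.
#'
#' @param genome A `genome_set`.
#' @param contig,pos,ref,alt One retained marker candidate.
#' @param marker_id Identifier carried through the design.
#' @param flank Flank length in bp (default 200).
#' @return A `template_window` list, or a `template_skip` with a `reason`
#'   (`"edge"` or `"ambiguous_base"`).
#' @export
extract_template <- function(genome, contig, pos, ref, alt,
                             marker_id = paste0(contig, "_", pos),
                             flank = 200) {
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' absent from genome", call. = FALSE)
  }
  seq <- genome[[contig]]
  len <- nchar(seq)
  up_start <- pos - flank + 1L
  down_start <- pos + nchar(ref)
  down_end <- down_start + flank - 1L
  if (up_start < 1L || down_end > len) {
    return(structure(list(marker_id = marker_id, reason = "edge"),
                     class = "template_skip"))
  }
  up <- substr(seq, up_start, pos)
  down <- substr(seq, down_start, down_end)
  if (grepl("N", up, fixed = TRUE) || grepl("N", down, fixed = TRUE)) {
    return(structure(list(marker_id = marker_id, reason = "ambiguous_base"),
                     class = "template_skip"))
  }
  structure(list(marker_id = marker_id, contig = contig, indel_pos = pos,
                 upstream = up, downstream = down,
                 ref_allele = ref, alt_allele = alt, flank = flank),
            class = "template_window")
}

# All primer candidates from one flank: every (start, len) substring within
# the allowed length range that individually passes GC, Tm, homopolymer and
# self-dimer screens.  For the downstream flank the primer is the reverse
# complement of the genomic substring.
flank_candidates <- function(flank_seq, constraints, thermo,
                             reverse = FALSE) {
  fl <- nchar(flank_seq)
  lens <- seq(constraints$primer_len[1], constraints$primer_len[2])
  starts <- unlist(lapply(lens, function(L) seq_len(max(0L, fl - L + 1L))))
  lens_all <- rep(lens, vapply(lens, function(L) max(0L, fl - L + 1L),
                               integer(1)))
  if (!length(starts)) return(NULL)
  seqs <- stringi::stri_sub(flank_seq, starts, length = lens_all)
  if (reverse) seqs <- revcomp(seqs)
  gc <- stringi::stri_count_regex(seqs, "[GC]") / lens_all
  keep <- gc >= constraints$gc_range[1] & gc <= constraints$gc_range[2]
  hp <- sprintf("A{%1$d}|C{%1$d}|G{%1$d}|T{%1$d}",
                constraints$max_homopolymer)
  keep <- keep & !stringi::stri_detect_regex(seqs, hp)
  if (!any(keep)) return(NULL)
  idx <- which(keep)
  tm <- tm_nn_cpp(seqs[idx], thermo$monovalent_mM, thermo$primer_nM)
  ok <- tm >= constraints$tm_range[1] & tm <= constraints$tm_range[2]
  idx <- idx[ok]
  if (!length(idx)) return(NULL)
  cand <- data.frame(start = starts[idx], len = lens_all[idx],
                     seq = seqs[idx], tm = tm[ok],
                     gc = gc[idx], stringsAsFactors = FALSE)
  selfp <- dimer_pass_cpp(cand$seq, cand$seq, 8L, 5L)
  cand[selfp, , drop = FALSE]
}

#' Enumerate primer pairs on a template
#'
#' Exhaustively enumerates forward primers in the upstream flank and
#' reverse primers (reverse complements) in the downstream flank over all
#' allowed lengths, keeps the pairs in which both primers pass the
#' individual length/Tm/GC/homopolymer screens, the Tm difference is
#' strictly below the limit, the REF-allele product length is in range (the
#' product always spans the InDel by construction), and the self/cross
#' dimer screen passes; pairs are ranked by ascending penalty
#' `|Tm - 61| + 0.5 |len - 23|` summed over both primers plus `|dTm|`, with
#' deterministic tie-breaking by `(penalty, fwd_start, product_len_ref,
#' fwd_seq)`.
#'
#' @param template A `template_window` from [extract_template()].
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_params()].
#' @return Data frame of at most `max_pairs_per_template` pairs (possibly
#'   empty) with primer sequences, template coordinates, Tm, GC, REF/ALT
#'   product lengths and penalty.
#' @export
enumerate_primer_pairs <- function(template,
                                   constraints = design_constraints(),
                                   thermo = thermo_params()) {
  stopifnot(inherits(template, "template_window"))
  empty <- data.frame(marker_id = character(), fwd_seq = character(),
                      rev_seq = character(), fwd_start = integer(),
                      rev_start = integer(), fwd_len = integer(),
                      rev_len = integer(), tm_fwd = numeric(),
                      tm_rev = numeric(), gc_fwd = numeric(),
                      gc_rev = numeric(), product_len_ref = integer(),
                      product_len_alt = integer(), penalty = numeric(),
                      stringsAsFactors = FALSE)
  fwd <- flank_candidates(template$upstream, constraints, thermo)
  rev <- flank_candidates(template$downstream, constraints, thermo,
                          reverse = TRUE)
  if (is.null(fwd) || is.null(rev)) return(empty)
  fl <- nchar(template$upstream)
  ref_len <- nchar(template$ref_allele)
  alt_len <- nchar(template$alt_allele)
  # product on the REF allele: fwd_start..upstream end, the REF allele past
  # its anchor base, then downstream through the reverse primer's 3' end
  i <- rep(seq_len(nrow(fwd)), times = nrow(rev))
  j <- rep(seq_len(nrow(rev)), each = nrow(fwd))
  prod_len <- (fl - fwd$start[i] + 1L) + (ref_len - 1L) +
    (rev$start[j] + rev$len[j] - 1L)
  dtm <- abs(fwd$tm[i] - rev$tm[j])
  ok <- prod_len >= constraints$product_len[1] &
    prod_len <= constraints$product_len[2] &
    dtm < constraints$max_tm_diff
  if (!any(ok)) return(empty)
  i <- i[ok]; j <- j[ok]
  prod_len <- prod_len[ok]; dtm <- dtm[ok]
  penalty <- abs(fwd$tm[i] - 61) + abs(rev$tm[j] - 61) +
    0.5 * (abs(fwd$len[i] - 23) + abs(rev$len[j] - 23)) + dtm
  ord <- order(penalty, fwd$start[i], prod_len, fwd$seq[i])
  picked <- integer(0)
  for (p in ord) {
    if (dimer_pass_cpp(fwd$seq[i[p]], rev$seq[j[p]], 8L, 5L)) {
      picked <- c(picked, p)
      if (length(picked) >= constraints$max_pairs_per_template) break
    }
  }
  if (!length(picked)) return(empty)
  data.frame(marker_id = template$marker_id,
             fwd_seq = fwd$seq[i[picked]], rev_seq = rev$seq[j[picked]],
             fwd_start = fwd$start[i[picked]],
             rev_start = rev$start[j[picked]],
             fwd_len = fwd$len[i[picked]], rev_len = rev$len[j[picked]],
             tm_fwd = fwd$tm[i[picked]], tm_rev = rev$tm[j[picked]],
             gc_fwd = fwd$gc[i[picked]], gc_rev = rev$gc[j[picked]],
             product_len_ref = prod_len[picked],
             product_len_alt = prod_len[picked] + (alt_len - ref_len),
             penalty = penalty[picked], stringsAsFactors = FALSE)
}

#' Design primers for every marker candidate
#'
#' Extracts the flanking template of each record of `vs` (assumed already
#' screened by [marker_candidate_filter()]) and enumerates its primer
#' pairs. Genomic binding coordinates of both primers (plus-strand start of
#' the forward primer; plus-strand start of the reverse primer's binding
#' site) are added for specificity classification.
#'
#' @param genome A `genome_set` holding the reference copies.
#' @param vs Retained marker candidates as a [variant_set()].
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_params()].
#' @param flank Template flank length (bp).
#' @return List with `pairs` (one row per emitted pair, with `contig`,
#'   `pos`, binding coordinates and all pair attributes) and `skipped`
#'   (data frame of marker_id/reason for unusable templates).
#' @export
design_primers <- function(genome, vs, constraints = design_constraints(),
                           thermo = thermo_params(), flank = 200) {
  res <- vector("list", length(vs))
  skipped <- list()
  for (k in seq_len(length(vs))) {
    s <- vs$sites[k, ]
    tpl <- extract_template(genome, s$contig, s$pos, s$ref, s$alt,
                            marker_id = marker_id_of(s), flank = flank)
    if (inherits(tpl, "template_skip")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(marker_id = tpl$marker_id, reason = tpl$reason,
                   stringsAsFactors = FALSE)
      next
    }
    pairs <- enumerate_primer_pairs(tpl, constraints, thermo)
    if (!nrow(pairs)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(marker_id = tpl$marker_id, reason = "no_valid_pair",
                   stringsAsFactors = FALSE)
      next
    }
    pairs$contig <- s$contig
    pairs$pos <- s$pos
    pairs$ref <- s$ref
    pairs$alt <- s$alt
    # plus-strand binding starts in genome coordinates
    pairs$fwd_bind_start <- s$pos - flank + pairs$fwd_start
    pairs$rev_bind_start <- s$pos + nchar(s$ref) + pairs$rev_start - 1L
    res[[k]] <- pairs
  }
  list(pairs = do.call(rbind, c(res, list(make.row.names = FALSE))),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(marker_id = character(), reason = character()))
}

marker_id_of <- function(site_row) {
  id <- site_row$id
  if (!is.null(id) && !is.na(id) && id != ".") id else
    paste0(site_row$contig, "_", site_row$pos)
}

#' Write a designed-pair table as TSV
#' @param pairs The `pairs` data frame from [design_primers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(pairs, path) {
  cols <- c("marker_id", "contig", "pos", "fwd_seq", "rev_seq", "tm_fwd",
            "tm_rev", "gc_fwd", "gc_rev", "product_len_ref",
            "product_len_alt", "penalty")
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
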