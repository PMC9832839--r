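#' Build a k-mer index over a genome
#'
#' Positional exact k-mer index used to seed primer alignment. Plus-strand
#' k-mers are stored; minus-strand queries are answered through the
#' reverse-complement k-mer, so both strands are searchable. k-mers
#' containing `N` are not indexed.
#'
#' @param genome A `genome_set`.
#' @param k K-mer size (8-15).
#' @return A `kmer_index` object (valid for the current session).
#' @export
build_kmer_index <- function(genome, k = 12) {
  stopifnot(k >= 8, k <= 15)
  ptr <- kindex_build_cpp(unclass(genome), names(genome), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), contigs = names(genome),
                 lengths = stats::setNames(nchar(genome), names(genome))),
            class = "kmer_index")
}

#' @exportS3Method print kmer_index
print.kmer_index <- function(x, ...) {
  info <- kindex_info_cpp(x$ptr)
  cat("kmer_index: k =", info$k, "over", length(info$contigs),
      "contig(s),", format(info$n_kmers, big.mark = ","), "k-mers\n")
  invisible(x)
}

#' Query exact occurrences of one k-mer
#'
#' @param index A `kmer_index`.
#' @param kmer ACGT string of length `k`.
#' @param strand `"+"` for plus-strand occurrences of `kmer`; `"-"` for
#'   positions whose minus strand reads `kmer` (equivalently, plus-strand
#'   occurrences of its reverse complement).
#' @return Data frame `contig`, `pos` (1-based plus-strand start).
#' @export
query_kmer_index <- function(index, kmer, strand = "+") {
  stopifnot(inherits(index, "kmer_index"), strand %in% c("+", "-"))
  if (strand == "-") kmer <- revcomp(kmer)
  kindex_query_cpp(index$ptr, kmer)
}

#' Find genomic binding sites of a primer
#'
#' A hit is a full-length ungapped alignment of the primer on either
#' strand with at most `max_mismatch` mismatches overall and none in the
#' 3'-terminal `three_prime_exact` bases (polymerase extension requires a
#' matched 3' end). Candidates are seeded from the index by the primer's
#' 3'-terminal k-mer - every k-mer within `max_mismatch` substitutions of
#' it outside the exact zone is looked up, which makes the seeding lossless
#' - then verified base by base. `start` is the 1-based plus-strand
#' position of the 5'-most matched base; results are sorted by
#' `(contig, start)`.
#'
#' @param primer ACGT primer sequence (5' to 3'), length at least
#'   `k + three_prime_exact`.
#' @param index A `kmer_index` from [build_kmer_index()].
#' @param max_mismatch Maximum mismatches per hit.
#' @param three_prime_exact 3'-terminal bases that must match exactly.
#' @return Data frame `contig`, `start`, `strand`, `mismatches`.
#' @export
find_hits <- function(primer, index, max_mismatch = 2,
                      three_prime_exact = 5) {
  stopifnot(inherits(index, "kmer_index"))
  if (stringi::stri_detect_regex(primer, "[^ACGT]")) {
    stop("primer must be ACGT only")
  }
  if (nchar(primer) < index$k + three_prime_exact) {
    stop("primer length must be >= k + three_prime_exact")
  }
  find_hits_cpp(index$ptr, primer, as.integer(max_mismatch),
                as.integer(three_prime_exact))
}

#' Classify primer hits against a marker's homology group
#'
#' `TARGET`: the hit lies on the marker's own contig at the designed
#' binding start with the designed orientation. `ALLELIC`: the hit lies on
#' another contig of the same homology group within `window` bp of the
#' designed position projected by contig-length ratio
#' (`projected = bind_pos * len(hit_contig) / len(marker_contig)`).
#' Anything else - including contigs absent from the map, with a warning -
#' is `OFF_TARGET`.
#'
#' @param hits Data frame from [find_hits()].
#' @param bind_start Designed plus-strand binding start of this primer.
#' @param bind_strand Designed binding strand (`"+"` forward primer,
#'   `"-"` reverse primer).
#' @param marker_contig Contig the marker was designed on.
#' @param map A `subgenome_map` with contig lengths
#'   (see [set_contig_lengths()]).
#' @param window Allelic-locus coordinate tolerance (bp).
#' @return Character vector of labels, one per hit.
#' @export
classify_hits <- function(hits, bind_start, bind_strand, marker_contig,
                          map, window = 1e6) {
  if (is.null(map$length)) {
    stop("subgenome map lacks contig lengths; call set_contig_lengths()")
  }
  grp <- map$group_id[match(marker_contig, map$contig_id)]
  if (is.na(grp)) stop("marker contig '", marker_contig, "' not in map")
  mlen <- map$length[match(marker_contig, map$contig_id)]
  out <- rep("OFF_TARGET", nrow(hits))
  hit_grp <- map$group_id[match(hits$contig, map$contig_id)]
  unknown <- is.na(hit_grp)
  if (any(unknown)) {
    warning("hit contig(s) absent from subgenome map treated as OFF_TARGET: ",
            paste(unique(hits$contig[unknown]), collapse = ", "))
  }
  target <- hits$contig == marker_contig & hits$start == bind_start &
    hits$strand == bind_strand
  out[target] <- "TARGET"
  same_grp <- !is.na(hit_grp) & hit_grp == grp & hits$contig != marker_contig
  if (any(same_grp)) {
    hlen <- map$length[match(hits$contig, map$contig_id)]
    projected <- bind_start * (hlen / mlen)
    allelic <- same_grp & abs(hits$start - projected) <= window
    out[allelic] <- "ALLELIC"
  }
  out
}

#' Predict amplicons from hit sets
#'
#' Pairs every convergent forward-plus / reverse-minus hit combination on
#' one contig whose product (reverse hit end minus forward hit start plus
#' one) is positive and at most `max_amplicon` bp.
#'
#' @param fwd_hits,rev_hits Hit data frames from [find_hits()] for the
#'   forward and reverse primer.
#' @param fwd_len,rev_len Primer lengths (to place hit ends).
#' @param max_amplicon Maximum product size considered amplifiable.
#' @return Data frame `contig`, `start`, `end`, `size`, `fwd_idx`,
#'   `rev_idx` (row indices into the input hit frames).
#' @export
predict_amplicons <- function(fwd_hits, rev_hits, fwd_len, rev_len,
                              max_amplicon = 2000) {
  out <- data.frame(contig = character(), start = integer(),
                    end = integer(), size = integer(),
                    fwd_idx = integer(), rev_idx = integer(),
                    stringsAsFactors = FALSE)
  fwd_len <- as.integer(fwd_len)
  rev_len <- as.integer(rev_len)
  f <- which(fwd_hits$strand == "+")
  r <- which(rev_hits$strand == "-")
  if (!length(f) || !length(r)) return(out)
  for (fi in f) {
    for (ri in r) {
      if (fwd_hits$contig[fi] != rev_hits$contig[ri]) next
      start <- fwd_hits$start[fi]
      end <- rev_hits$start[ri] + rev_len - 1L
      size <- end - start + 1L
      if (start > rev_hits$start[ri]) next # 3' ends must face inward
      if (size < max(fwd_len, rev_len) || size > max_amplicon) next
      out <- rbind(out, data.frame(contig = fwd_hits$contig[fi],
                                   start = start, end = end, size = size,
                                   fwd_idx = fi, rev_idx = ri,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Screen one primer pair for subgenome specificity
#'
#' Both primers are aligned against every subgenome copy. In `strict` mode
#' the pair is retained iff every hit of both primers classifies as
#' `TARGET` or `ALLELIC` and the designed target site is actually hit by
#' both primers in the designed orientation (a missing target hit signals
#' an inconsistency and rejects with `NO_TARGET_HIT`). In `amplicon` mode
#' the pair is retained iff every predicted amplicon lies at a target or
#' allelic locus (both of its hits so classify) and the designed target
#' amplicon exists.
#'
#' @param pair One row of the `pairs` frame from [design_primers()].
#' @param index A `kmer_index` over all subgenome copies.
#' @param map A `subgenome_map` with lengths.
#' @param mode `"strict"` or `"amplicon"`.
#' @param max_mismatch,three_prime_exact Passed to [find_hits()].
#' @param window Allelic window, passed to [classify_hits()].
#' @param max_amplicon Passed to [predict_amplicons()].
#' @return A one-row data frame: `marker_id`, `retained`, `n_target`,
#'   `n_allelic`, `n_off_target`, `reason`.
#' @export
screen_pair <- function(pair, index, map, mode = c("strict", "amplicon"),
                        max_mismatch = 2, three_prime_exact = 5,
                        window = 1e6, max_amplicon = 2000) {
  mode <- match.arg(mode)
  fh <- find_hits(pair$fwd_seq, index, max_mismatch, three_prime_exact)
  rh <- find_hits(pair$rev_seq, index, max_mismatch, three_prime_exact)
  fcls <- classify_hits(fh, pair$fwd_bind_start, "+", pair$contig, map,
                        window)
  rcls <- classify_hits(rh, pair$rev_bind_start, "-", pair$contig, map,
                        window)
  cls <- c(fcls, rcls)
  counts <- c(n_target = sum(cls == "TARGET"),
              n_allelic = sum(cls == "ALLELIC"),
              n_off_target = sum(cls == "OFF_TARGET"))
  has_target <- any(fcls == "TARGET") && any(rcls == "TARGET")
  if (!has_target) {
    retained <- FALSE
    reason <- "NO_TARGET_HIT"
  } else if (mode == "strict") {
    retained <- unname(counts["n_off_target"] == 0)
    reason <- if (retained) "" else "OFF_TARGET"
  } else {
    amp <- predict_amplicons(fh, rh, nchar(pair$fwd_seq),
                             nchar(pair$rev_seq), max_amplicon)
    ok <- fcls[amp$fwd_idx] != "OFF_TARGET" &
      rcls[amp$rev_idx] != "OFF_TARGET"
    target_amp <- fcls[amp$fwd_idx] == "TARGET" &
      rcls[amp$rev_idx] == "TARGET"
    if (!any(target_amp)) {
      retained <- FALSE
      reason <- "NO_TARGET_HIT"
    } else {
      retained <- all(ok)
      reason <- if (retained) "" else "OFF_TARGET"
    }
  }
  data.frame(marker_id = pair$marker_id, retained = retained,
             n_target = unname(counts["n_target"]),
             n_allelic = unname(counts["n_allelic"]),
             n_off_target = unname(counts["n_off_target"]),
             reason = reason, stringsAsFactors = FALSE)
}

#' Screen every designed pair
#'
#' @param pairs The `pairs` frame from [design_primers()].
#' @param index A `kmer_index` over all subgenome copies.
#' @param map A `subgenome_map` with lengths.
#' @param ... Passed to [screen_pair()].
#' @return Data frame with one [screen_pair()] row per input pair, plus a
#'   `pair_idx` column indexing into `pairs`.
#' @export
screen_pairs <- function(pairs, index, map, ...) {
  if (is.null(pairs) || !nrow(pairs)) {
    return(data.frame(marker_id = character(), retained = logical(),
                      n_target = integer(), n_allelic = integer(),
                      n_off_target = integer(), reason = character(),
                      pair_idx = integer(), stringsAsFactors = FALSE))
  }
  reports <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- screen_pair(pairs[i, ], index, map, ...)
    r$pair_idx <- i
    r
  })
  do.call(rbind, reports)
}

#' Write a screen report as TSV
#' @param report Data frame from [screen_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_tsv <- function(report, path) {
  cols <- c("marker_id", "retained", "n_target", "n_allelic",
            "n_off_target", "reason")
  utils::write.table(report[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
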