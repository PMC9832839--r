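#' Assemble the core marker set
#'
#' Keeps the lowest-penalty retained pair per marker, sorts markers by
#' `(contig, pos)` and summarizes marker density: per-contig counts and
#' mean/median spacing between adjacent markers.
#'
#' @param pairs The `pairs` frame from [design_primers()].
#' @param report The screen report from [screen_pairs()] (must carry
#'   `pair_idx`); only `retained` pairs enter the core set.
#' @param page_resolution Minimum REF/ALT product-size difference (bp)
#'   resolvable on a gel; markers below it are flagged `resolvable =
#'   FALSE` and excluded from band prediction.
#' @return List of class `core_set`: `markers` (one row per marker) and
#'   `summary` (per-contig `n`, `mean_spacing`, `median_spacing`).
#' @export
assemble_core_set <- function(pairs, report, page_resolution = 5) {
  empty <- structure(list(
    markers = data.frame(), summary = data.frame(contig = character(),
      n = integer(), mean_spacing = numeric(), median_spacing = numeric(),
      stringsAsFactors = FALSE)), class = "core_set")
  if (is.null(pairs) || !nrow(pairs) || !any(report$retained)) return(empty)
  kept <- pairs[report$pair_idx[report$retained], , drop = FALSE]
  kept <- kept[order(kept$penalty, kept$fwd_start, kept$product_len_ref,
                     kept$fwd_seq), , drop = FALSE]
  kept <- kept[!duplicated(kept$marker_id), , drop = FALSE]
  kept <- kept[order(kept$contig, kept$pos), , drop = FALSE]
  kept$resolvable <-
    abs(kept$product_len_ref - kept$product_len_alt) >= page_resolution
  rownames(kept) <- NULL
  summ <- do.call(rbind, lapply(split(kept$pos, kept$contig), function(p) {
    sp <- if (length(p) > 1) diff(sort(p)) else numeric(0)
    data.frame(n = length(p),
               mean_spacing = if (length(sp)) mean(sp) else NA_real_,
               median_spacing = if (length(sp))
                 stats::median(sp) else NA_real_)
  }))
  summ$contig <- rownames(summ)
  rownames(summ) <- NULL
  structure(list(markers = kept,
                 summary = summ[, c("contig", "n", "mean_spacing",
                                    "median_spacing")]),
            class = "core_set")
}

#' @exportS3Method print core_set
print.core_set <- function(x, ...) {
  cat("core_set:", nrow(x$markers), "marker(s) on",
      nrow(x$summary), "contig(s)\n")
  invisible(x)
}

#' Predicted PAGE bands of one marker for one genotype
#'
#' The markers are co-dominant: both homozygotes give one band each (REF or
#' ALT product size), the heterozygote gives both bands, a missing
#' genotype gives no band (`NULL` state).
#'
#' @param product_len_ref,product_len_alt REF/ALT product sizes (bp).
#' @param genotype Integer vector `c(a1, a2)` over alleles `{0, 1}`, or
#'   `NA` for missing.
#' @return List with `state` (`"REF"`, `"ALT"`, `"HET"`, `"NULL"`) and
#'   `bands` (integer vector of band sizes, possibly empty).
#' @export
in_silico_bands <- function(product_len_ref, product_len_alt, genotype) {
  if (any(is.na(genotype))) {
    return(list(state = "NULL", bands = integer(0)))
  }
  if (any(genotype > 1L | genotype < 0L)) {
    stop("bi-allelic contract violated: allele index > 1")
  }
  if (genotype[1] != genotype[2]) {
    list(state = "HET", bands = sort(c(product_len_ref, product_len_alt)))
  } else if (genotype[1] == 0L) {
    list(state = "REF", bands = product_len_ref)
  } else {
    list(state = "ALT", bands = product_len_alt)
  }
}

#' Band-state matrix of a core set over a cohort
#'
#' @param core A `core_set` from [assemble_core_set()].
#' @param vs The [variant_set()] the markers came from.
#' @return Character matrix (samples x markers) over
#'   `{"R", "A", "H", "N"}`; markers flagged unresolvable are dropped with
#'   a message.
#' @export
band_matrix <- function(core, vs) {
  mk <- core$markers
  if (!nrow(mk)) {
    return(matrix(character(0), nrow = length(vs$samples), ncol = 0,
                  dimnames = list(vs$samples, NULL)))
  }
  if (any(!mk$resolvable)) {
    message(sum(!mk$resolvable),
            " marker(s) below PAGE resolution excluded from band prediction")
    mk <- mk[mk$resolvable, , drop = FALSE]
  }
  key <- paste(vs$sites$contig, vs$sites$pos)
  idx <- match(paste(mk$contig, mk$pos), key)
  if (any(is.na(idx))) stop("core-set marker absent from variant set")
  a1 <- t(vs$a1[idx, , drop = FALSE])
  a2 <- t(vs$a2[idx, , drop = FALSE])
  if (any(pmax(a1, a2, na.rm = TRUE) > 1L, na.rm = TRUE)) {
    stop("bi-allelic contract violated: allele index > 1")
  }
  st <- matrix("N", nrow(a1), ncol(a1))
  called <- !is.na(a1)
  st[called & a1 == 0L & a2 == 0L] <- "R"
  st[called & a1 == 1L & a2 == 1L] <- "A"
  st[called & a1 != a2] <- "H"
  dimnames(st) <- list(vs$samples, mk$marker_id)
  st
}

# unordered sample-pair resolution: TRUE where the two samples' states
# differ and neither is missing
pair_resolution <- function(bands) {
  n <- nrow(bands)
  pr <- utils::combn(n, 2)
  res <- matrix(FALSE, ncol(pr), ncol(bands))
  for (m in seq_len(ncol(bands))) {
    s <- bands[, m]
    res[, m] <- s[pr[1, ]] != s[pr[2, ]] & s[pr[1, ]] != "N" &
      s[pr[2, ]] != "N"
  }
  list(pairs = pr, resolved = res)
}

#' Select a minimal discriminating marker subset
#'
#' Greedy set cover over unordered sample pairs: iteratively picks the
#' marker resolving the most currently-unresolved pairs (a pair is
#' resolved when the two samples differ in band state and neither is
#' `N` - a missing band is never evidence of difference), until every
#' resolvable pair is resolved or no marker adds coverage. Ties are broken
#' by column order of the band matrix (i.e. genome order), making the
#' selection deterministic.
#'
#' @param bands Band-state matrix from [band_matrix()] (>= 2 samples).
#' @return List: `selected` (marker ids in selection order), `gains`
#'   (pairs newly resolved by each pick), `unresolved_pairs` (data frame of
#'   sample pairs no marker distinguishes), `all_resolved` (logical).
#' @export
select_discriminating_set <- function(bands) {
  stopifnot(nrow(bands) >= 2)
  pr <- pair_resolution(bands)
  resolvable <- rowSums(pr$resolved) > 0
  unresolved <- resolvable
  selected <- character(0)
  gains <- integer(0)
  while (any(unresolved)) {
    gain <- colSums(pr$resolved & unresolved)
    if (max(gain) == 0) break
    pick <- which.max(gain) # first max: genome-order tie-break
    selected <- c(selected, colnames(bands)[pick])
    gains <- c(gains, max(gain))
    unresolved <- unresolved & !pr$resolved[, pick]
  }
  never <- !resolvable
  list(selected = selected, gains = gains,
       unresolved_pairs = data.frame(
         sample_a = rownames(bands)[pr$pairs[1, never]],
         sample_b = rownames(bands)[pr$pairs[2, never]],
         stringsAsFactors = FALSE),
       all_resolved = !any(unresolved))
}

#' Encode per-sample molecular IDs
#'
#' Builds the fingerprint string of every sample over an ordered marker
#' subset, one symbol per marker (`R`/`A`/`H`/`N`), and reports duplicate
#' IDs (samples the subset does not distinguish).
#'
#' @param bands Band-state matrix from [band_matrix()].
#' @param subset Ordered marker ids (e.g. `selected` from
#'   [select_discriminating_set()]); default all markers in matrix order.
#' @return List of class `molecular_ids`: `ids` (data frame `sample_id`,
#'   `id_string`), `marker_order`, `duplicates` (list of sample groups
#'   sharing one ID).
#' @export
encode_ids <- function(bands, subset = colnames(bands)) {
  stopifnot(all(subset %in% colnames(bands)))
  sub <- bands[, subset, drop = FALSE]
  idstr <- apply(sub, 1, paste, collapse = "")
  dup_groups <- unname(Filter(function(g) length(g) > 1,
                              split(rownames(bands), idstr)))
  structure(list(ids = data.frame(sample_id = rownames(bands),
                                  id_string = unname(idstr),
                                  stringsAsFactors = FALSE),
                 marker_order = subset, duplicates = dup_groups),
            class = "molecular_ids")
}

#' @exportS3Method print molecular_ids
print.molecular_ids <- function(x, ...) {
  cat("molecular_ids:", nrow(x$ids), "sample(s) over",
      length(x$marker_order), "marker(s);",
      length(x$duplicates), "duplicate group(s)\n")
  invisible(x)
}

#' Write molecular IDs as TSV
#' @param ids A `molecular_ids` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_tsv <- function(ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# marker_order: ",
                    paste(ids$marker_order, collapse = ",")), con)
  utils::write.table(ids$ids, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
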