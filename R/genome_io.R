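#' Read a multi-FASTA genome
#'
#' Loads every record of a (multi-)FASTA file, uppercases soft-masked
#' sequence and validates the alphabet. Only `A`, `C`, `G`, `T` and `N` are
#' accepted after normalization; any other character is a parse error.
#' Record order follows file order.
#'
#' @param path Path to a FASTA file (plain or gzipped).
#' @return A named character vector of class `genome_set`: one element per
#'   record, names are the contig ids (first whitespace-delimited token of
#'   each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # byte-level read: DNA-alphabet readers silently drop foreign letters,
  # which would defeat the alphabet contract below
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  bad <- stringi::stri_detect_regex(seqs, "[^ACGTN]")
  if (any(bad)) {
    stop("FASTA parse error: contig '", names(seqs)[which(bad)[1]],
         "' contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  structure(seqs, class = "genome_set")
}

#' Write a genome to FASTA
#'
#' Sequences are wrapped at 60 columns, preserving input order, so that
#' `write_fasta(read_fasta(f))` round-trips sequence content and ordering.
#'
#' @param genome Named character vector of sequences (a `genome_set`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' @exportS3Method print genome_set
print.genome_set <- function(x, ...) {
  cat("genome_set:", length(x), "contig(s),",
      format(sum(nchar(x)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' @param seq Character vector of sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(seq))
}

#' Extract a genomic region
#'
#' Inclusive 1-based slice of one contig sequence; the reverse complement is
#' applied after slicing when requested. Out-of-bounds coordinates are an
#' error, never silently clamped.
#'
#' @param seq A single contig sequence (character scalar, or one element of a
#'   `genome_set`).
#' @param start,end 1-based inclusive coordinates.
#' @param revcomp Reverse-complement the slice?
#' @return Character scalar.
#' @export
extract_region <- function(seq, start, end, revcomp = FALSE) {
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L)
  len <- nchar(seq)
  if (start < 1 || end > len || start > end) {
    stop("region [", start, ", ", end, "] out of bounds for sequence of ",
         "length ", len, call. = FALSE)
  }
  out <- substr(seq, start, end)
  if (revcomp) out <- revcomp(out)
  out
}

#' Read a subgenome homology map
#'
#' The map declares which contigs are homologous copies of one ancestral
#' chromosome (a homology group) and which copy is the reference used for
#' variant calling and marker design. Expected TSV columns: `group_id`,
#' `contig_id`, `is_reference` (0/1).
#'
#' @param path TSV path.
#' @return A `subgenome_map`: data frame with those three columns plus an
#'   optional `length` column (see [set_contig_lengths()]).
#' @export
read_subgenome_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(group_id = "character",
                                         contig_id = "character"))
  subgenome_map(df$group_id, df$contig_id, df$is_reference)
}

#' Construct a subgenome map
#'
#' @param group_id,contig_id Character vectors, one entry per contig.
#' @param is_reference 0/1 flag: the reference copy of each group.
#' @return A `subgenome_map` data frame.
#' @export
subgenome_map <- function(group_id, contig_id, is_reference) {
  df <- data.frame(group_id = as.character(group_id),
                   contig_id = as.character(contig_id),
                   is_reference = as.integer(is_reference),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$contig_id)) {
    dup <- df$contig_id[duplicated(df$contig_id)][1]
    stop("contig '", dup, "' appears in more than one homology group",
         call. = FALSE)
  }
  nref <- tapply(df$is_reference, df$group_id, sum)
  bad <- names(nref)[nref != 1L]
  if (length(bad)) {
    stop("group '", bad[1], "' must have exactly one reference copy (has ",
         nref[bad[1]], ")", call. = FALSE)
  }
  class(df) <- c("subgenome_map", "data.frame")
  df
}

#' Write a subgenome map as TSV
#' @param map A `subgenome_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subgenome_map <- function(map, path) {
  utils::write.table(map[, c("group_id", "contig_id", "is_reference")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach contig lengths to a subgenome map
#'
#' Allelic-locus classification projects coordinates between homologous
#' copies by their length ratio, so the map must know contig lengths.
#'
#' @param map A `subgenome_map`.
#' @param genome A `genome_set` covering the map's contigs.
#' @return The map with a `length` column filled in.
#' @export
set_contig_lengths <- function(map, genome) {
  missing <- setdiff(map$contig_id, names(genome))
  if (length(missing)) {
    stop("contig(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  map$length <- unname(nchar(genome[map$contig_id]))
  map
}

#' Gene model
#'
#' A minimal strand-aware gene structure: the gene span plus its ordered CDS
#' intervals (1-based inclusive, sorted 5' to 3' in transcription order).
#'
#' @param gene_id Gene identifier.
#' @param contig Contig the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end Parallel vectors of CDS interval bounds in
#'   genomic coordinates.
#' @param phase Phase of the first CDS (0, 1 or 2).
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, contig, strand, cds_start, cds_end,
                       phase = 0L) {
  stopifnot(strand %in% c("+", "-"), length(cds_start) == length(cds_end),
            all(cds_start <= cds_end), phase %in% 0:2)
  o <- order(cds_start)
  cds <- data.frame(start = cds_start[o], end = cds_end[o])
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stop("CDS intervals overlap", call. = FALSE)
  }
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  if (sum(cds$end - cds$start + 1) < 3) stop("total CDS length < 3")
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 cds = cds, phase = as.integer(phase),
                 span = c(min(cds$start), max(cds$end))),
            class = "gene_model")
}

#' Read gene models from GFF3
#'
#' Consumes only `gene`, `mRNA` and `CDS` features; everything else is
#' ignored. CDS features are grouped by parent transcript and mapped to the
#' enclosing gene; when a gene has several transcripts the one with the
#' longest total CDS is kept.
#'
#' @param path GFF3 path.
#' @return A list of [gene_model()] objects.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  typ <- as.character(gr$type)
  cds <- gr[typ == "CDS"]
  mrna <- gr[typ == "mRNA"]
  if (!length(cds)) return(list())
  parent <- vapply(cds$Parent, function(p) as.character(p)[1], character(1))
  tx2gene <- stats::setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], character(1)),
    as.character(mrna$ID))
  out <- list()
  for (tx in unique(parent)) {
    sel <- cds[parent == tx]
    gid <- if (tx %in% names(tx2gene)) tx2gene[[tx]] else tx
    ph <- if (!is.null(sel$phase)) as.integer(sel$phase[1]) else 0L
    if (is.na(ph)) ph <- 0L
    gm <- gene_model(gid, as.character(GenomicRanges::seqnames(sel))[1],
                     as.character(BiocGenerics::strand(sel))[1],
                     GenomicRanges::start(sel), GenomicRanges::end(sel),
                     phase = ph)
    keep <- is.null(out[[gid]]) ||
      sum(gm$cds$end - gm$cds$start + 1) >
        sum(out[[gid]]$cds$end - out[[gid]]$cds$start + 1)
    if (keep) out[[gid]] <- gm
  }
  unname(out)
}
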