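#' Pipeline parameters
#'
#' One bundle of every stage parameter, with defaults equal to the printed
#' study values where printed (200 bp flanks; length difference >= 5;
#' heterozygosity <= 0.80; MAF >= 0.2; product 100-200 bp; Tm 58-64 with
#' difference < 2; GC 35-65%; primer length 20-26 bp; hard-filter and site
#' thresholds of [hard_filter()] / [site_filter()]) and to the package's
#' documented choices otherwise.
#'
#' @param flank Template flank length (bp).
#' @param delta_min,het_max,maf_min Candidacy thresholds
#'   ([marker_candidate_filter()]).
#' @param max_missing,mac_min,qual_min,site_maf_min,dp_min Site filter
#'   thresholds ([site_filter()]).
#' @param constraints A [design_constraints()].
#' @param thermo A [thermo_params()].
#' @param k K-mer size of the specificity index.
#' @param max_mismatch,three_prime_exact,window,screen_mode Specificity
#'   screen knobs ([screen_pair()]).
#' @param page_resolution Gel resolution (bp) for band prediction.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(flank = 200, delta_min = 5, het_max = 0.80,
                            maf_min = 0.2, max_missing = 0.5, mac_min = 3,
                            qual_min = 30, site_maf_min = 0.05, dp_min = 3,
                            constraints = design_constraints(),
                            thermo = thermo_params(), k = 12,
                            max_mismatch = 2, three_prime_exact = 5,
                            window = 1e6,
                            screen_mode = c("strict", "amplicon"),
                            page_resolution = 5) {
  screen_mode <- match.arg(screen_mode)
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full marker-construction pipeline
#'
#' Executes filter (hard filter, cohort site filter, marker candidacy),
#' design (template extraction plus primer-pair enumeration), screen
#' (subgenome specificity), core-set assembly and molecular-ID
#' construction, collecting per-stage counts in a manifest. Inputs can be
#' file paths (VCF / FASTA / subgenome-map TSV) or in-memory objects.
#'
#' @param vcf A VCF path or a [variant_set()].
#' @param fasta A FASTA path or a `genome_set` containing every subgenome
#'   copy.
#' @param map A subgenome-map TSV path or a `subgenome_map`.
#' @param params A [pipeline_params()].
#' @param outdir Optional output directory; when given, the retained-site
#'   VCF, primer TSV, screen TSV, core-set TSV, molecular-ID TSV and a
#'   JSON manifest are written under it.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return List of class `pipeline_run`: `manifest`, `candidates`
#'   (variant_set), `pairs`, `screen`, `core`, `bands`, `subset`, `ids`.
#' @export
run_pipeline <- function(vcf, fasta, map, params = pipeline_params(),
                         outdir = NULL, seed = 1) {
  checksums <- list()
  if (is.character(vcf)) {
    checksums$vcf <- unname(tools::md5sum(vcf))
    vcf <- read_vcf(vcf)
  }
  if (is.character(fasta) && !inherits(fasta, "genome_set")) {
    checksums$fasta <- unname(tools::md5sum(fasta))
    fasta <- read_fasta(fasta)
  }
  if (is.character(map)) {
    checksums$map <- unname(tools::md5sum(map))
    map <- read_subgenome_map(map)
  }
  if (is.null(map$length)) map <- set_contig_lengths(map, fasta)

  hf <- hard_filter(vcf, "auto")
  vs1 <- vcf[hf$status == "PASS"]
  vs2 <- site_filter(vs1, max_missing = params$max_missing,
                     mac_min = params$mac_min, qual_min = params$qual_min,
                     maf_min = params$site_maf_min, dp_min = params$dp_min)
  cand <- marker_candidate_filter(vs2, delta_min = params$delta_min,
                                  het_max = params$het_max,
                                  maf_min = params$maf_min)
  design <- design_primers(fasta, cand, constraints = params$constraints,
                           thermo = params$thermo, flank = params$flank)
  index <- build_kmer_index(fasta, k = params$k)
  screen <- screen_pairs(design$pairs, index, map,
                         mode = params$screen_mode,
                         max_mismatch = params$max_mismatch,
                         three_prime_exact = params$three_prime_exact,
                         window = params$window)
  core <- assemble_core_set(design$pairs, screen,
                            page_resolution = params$page_resolution)
  bands <- NULL
  subset <- NULL
  ids <- NULL
  if (nrow(core$markers) && length(vcf$samples) >= 2) {
    bands <- band_matrix(core, cand)
    subset <- select_discriminating_set(bands)
    ids <- encode_ids(bands, subset$selected)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("coreindel")),
    seed = seed,
    checksums = checksums,
    parameters = list(
      flank = params$flank, delta_min = params$delta_min,
      het_max = params$het_max, maf_min = params$maf_min,
      product_len = params$constraints$product_len,
      tm_range = params$constraints$tm_range,
      max_tm_diff = params$constraints$max_tm_diff,
      gc_range = params$constraints$gc_range,
      primer_len = params$constraints$primer_len,
      k = params$k, max_mismatch = params$max_mismatch,
      three_prime_exact = params$three_prime_exact,
      window = params$window, screen_mode = params$screen_mode),
    counts = list(
      n_input = length(vcf),
      n_hard_pass = length(vs1),
      n_site_retained = length(vs2),
      n_candidates = length(cand),
      n_templates_skipped = nrow(design$skipped),
      n_markers_designable = if (is.null(design$pairs)) 0L else
        length(unique(design$pairs$marker_id)),
      n_pairs_designed = if (is.null(design$pairs)) 0L else
        nrow(design$pairs),
      n_pairs_retained = sum(screen$retained),
      n_core_markers = nrow(core$markers),
      id_subset_size = if (is.null(subset)) 0L else
        length(subset$selected),
      n_indistinguishable_pairs = if (is.null(subset)) NA_integer_ else
        nrow(subset$unresolved_pairs)))
  run <- structure(list(manifest = manifest, candidates = cand,
                        pairs = design$pairs, skipped = design$skipped,
                        screen = screen, core = core, bands = bands,
                        subset = subset, ids = ids),
                   class = "pipeline_run")
  if (!is.null(outdir)) write_pipeline_outputs(run, outdir)
  run
}

#' @exportS3Method print pipeline_run
print.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("pipeline_run:\n")
  for (nm in names(cts)) cat(sprintf("  %-26s %s\n", nm, cts[[nm]]))
  invisible(x)
}

write_pipeline_outputs <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_vcf(run$candidates, file.path(outdir, "candidates.vcf"))
  if (!is.null(run$pairs) && nrow(run$pairs)) {
    write_primer_tsv(run$pairs, file.path(outdir, "primer_pairs.tsv"))
  }
  write_screen_tsv(run$screen, file.path(outdir, "screen_report.tsv"))
  if (nrow(run$core$markers)) {
    utils::write.table(run$core$markers,
                       file.path(outdir, "core_set.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$ids)) {
    write_id_tsv(run$ids, file.path(outdir, "molecular_ids.tsv"))
    utils::write.table(run$subset$unresolved_pairs,
                       file.path(outdir, "indistinguishable_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(outdir)
}
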