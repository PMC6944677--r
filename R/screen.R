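#' Screening run configuration
#'
#' Bundles every input path and threshold of an end-to-end screen. The
#' threshold defaults are the screening criteria: control frequency below
#' 1 percent, conservation index above 75 percent.
#'
#' @param reference path to the reference FASTA (single record).
#' @param annotation path to the gene-map TSV.
#' @param sample path to the index-case genome FASTA.
#' @param controls path to a multi-record control-cohort FASTA.
#' @param alignment path to the tRNA alignment TSV.
#' @param markers path to the haplogroup marker DB.
#' @param out_dir output directory.
#' @param freq_threshold,ci_threshold criterion thresholds (percent).
#' @param seed integer seed recorded in the manifest.
#' @return a `screen_config` list.
#' @export
screen_config <- function(reference, annotation, sample, controls = NULL,
                          alignment = NULL, markers = NULL,
                          out_dir = ".", freq_threshold = 1,
                          ci_threshold = 75, seed = 1L) {
  stopifnot(freq_threshold > 0, ci_threshold > 0)
  structure(list(reference = reference, annotation = annotation,
                 sample = sample, controls = controls,
                 alignment = alignment, markers = markers,
                 out_dir = out_dir, freq_threshold = freq_threshold,
                 ci_threshold = ci_threshold, seed = as.integer(seed)),
            class = "screen_config")
}

read_sample_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 1L) stopf("sample FASTA must have exactly one record")
  as.character(seqs[[1L]])
}

#' Annotate an index-case genome against the reference
#'
#' Extracts variants, annotates them and writes the annotated table (and a
#' minimal VCF) under the configured output directory.
#'
#' @param config a `screen_config`.
#' @return the annotated variant data.frame, invisibly; side effect:
#'   `variants_annotated.tsv` and `variants.vcf` in `out_dir`.
#' @export
run_annotate <- function(config) {
  ref <- load_reference(config$reference, config$annotation)
  smp <- read_sample_genome(config$sample)
  annotated <- annotate_variants(extract_variants(smp, ref), ref)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(annotated,
                      file.path(config$out_dir, "variants_annotated.tsv"))
  write_vcf(annotated, file.path(config$out_dir, "variants.vcf"))
  invisible(annotated)
}

#' Run the full candidate-mutation screen
#'
#' Annotates the index case, computes per-variant control carrier counts
#' from the cohort FASTA, applies the three-criterion filter (conservation
#' and structure via the tRNA alignment), matches haplogroup markers, and
#' writes the report.
#'
#' @param config a `screen_config` with `controls` and `alignment` set.
#' @return list with `annotated`, `report`, `candidates` (notations of
#'   verdict-candidate variants), `haplogroups` (ranked matches, if a
#'   marker DB was configured), `partition`; side effects: TSV report
#'   files in `out_dir`.
#' @export
run_screen <- function(config) {
  ref <- load_reference(config$reference, config$annotation)
  smp <- read_sample_genome(config$sample)
  variants <- extract_variants(smp, ref)
  annotated <- annotate_variants(variants, ref)

  control_sets <- list()
  if (!is.null(config$controls)) {
    ctl <- Biostrings::readDNAStringSet(config$controls)
    control_sets <- lapply(seq_along(ctl), function(i) {
      extract_variants(as.character(ctl[[i]]), ref)
    })
  }
  alignment <- if (!is.null(config$alignment)) {
    parse_trna_alignment(config$alignment)
  }
  report <- screen_variants(annotated, control_sets, ref, alignment,
                            freq_threshold = config$freq_threshold,
                            ci_threshold = config$ci_threshold)
  haplogroups <- NULL
  if (!is.null(config$markers)) {
    haplogroups <- match_haplogroup(variants, read_marker_db(config$markers))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(annotated,
                      file.path(config$out_dir, "variants_annotated.tsv"))
  write.table(report, file.path(config$out_dir, "screen_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(haplogroups)) {
    write.table(haplogroups, file.path(config$out_dir, "haplogroups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  candidates <- report$notation[report$verdict == "candidate"]
  summary_lines <- c(
    sprintf("variants: %d", nrow(annotated)),
    sprintf("candidates: %s",
            if (length(candidates)) paste(candidates, collapse = ", ")
            else "(none)"),
    if (!is.null(haplogroups)) {
      sprintf("top haplogroup: %s (score %.2f)",
              haplogroups$haplogroup[1L], haplogroups$score[1L])
    }
  )
  writeLines(summary_lines, file.path(config$out_dir, "screen_summary.txt"))
  list(annotated = annotated, report = report, candidates = candidates,
       haplogroups = haplogroups, partition = partition_variants(annotated))
}

#' Simulate a complete screening fixture bundle
#'
#' Writes everything [run_screen()] consumes: a surrogate reference pinned
#' to the family variant table, its gene map, the index-case genome
#' (reference plus all family variants), a control cohort, the bundled
#' tRNA alignment and marker DB, and a JSON manifest recording seed and
#' sizes. Byte-identical for a fixed seed.
#'
#' @param config a `sim_config`.
#' @param out_dir output directory.
#' @param variant_table family variant table (default the bundled one).
#' @return a `screen_config` pointing at the written bundle.
#' @export
run_simulate <- function(config, out_dir,
                         variant_table = read_variant_table(family_variant_table_path())) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_surrogate_reference(variant_table, seed = config$seed)
  candidate_rows <- variant_table$previously_reported == "No"
  backbone <- variant_table[!candidate_rows, ]
  candidate <- variant_table[candidate_rows, ]

  ref_path <- file.path(out_dir, "reference.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(ref$sequence), ref$name), ref_path)
  map_path <- file.path(out_dir, "genes.tsv")
  file.copy(human_gene_map_path(), map_path, overwrite = TRUE)

  proband <- apply_variants(ref, variant_table)
  sample_path <- file.path(out_dir, "proband.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(proband), "proband"), sample_path)

  controls <- generate_controls(config, ref, backbone, candidate)
  controls_path <- file.path(out_dir, "controls.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(unlist(controls)), names(controls)),
    controls_path)

  aln_path <- file.path(out_dir, "trna_alignment.tsv")
  file.copy(trna_cys_alignment_path(), aln_path, overwrite = TRUE)
  markers_path <- file.path(out_dir, "markers.tsv")
  file.copy(demo_marker_db_path(), markers_path, overwrite = TRUE)

  manifest <- list(seed = config$seed, genome_length = config$genome_length,
                   n_controls = config$n_controls,
                   control_carrier_freq = config$control_carrier_freq,
                   n_variants = nrow(variant_table))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  screen_config(reference = ref_path, annotation = map_path,
                sample = sample_path, controls = controls_path,
                alignment = aln_path, markers = markers_path,
                out_dir = file.path(out_dir, "reports"),
                seed = config$seed)
}
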