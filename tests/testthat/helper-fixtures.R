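# shared fixtures, built in code at test time

family_table <- function() read_variant_table(family_variant_table_path())

# surrogate reference pinned to the family table (memoised per session)
.fixture_env <- new.env(parent = emptyenv())
surrogate_ref <- function(seed = 101L) {
  key <- paste0("ref", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_surrogate_reference(family_table(),
                                                        seed = seed)
  }
  .fixture_env[[key]]
}

cys_alignment <- function() {
  if (is.null(.fixture_env$aln)) {
    .fixture_env$aln <- parse_trna_alignment(trna_cys_alignment_path())
  }
  .fixture_env$aln
}

# small reference with a full synthetic feature set, for cheap tests
small_ref <- function(seed = 5L, len = 2000L) {
  generate_reference(sim_config(seed = seed, genome_length = len))
}

write_temp_fasta <- function(seqs, names = paste0("seq", seq_along(seqs))) {
  path <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(seqs), names), path)
  path
}

# positions spaced >= gap apart, away from the origin
spaced_positions <- function(n, len, gap = 30L) {
  stopifnot(n * gap + 60L < len)
  sort(sample(seq(30L, len - 30L, by = gap), n))
}
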