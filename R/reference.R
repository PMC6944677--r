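#' Construct a circular mitochondrial reference
#'
#' Coordinates throughout the package are 1-based, inclusive, on the
#' reference (heavy-strand) orientation, matching `m.<pos>` notation;
#' position arithmetic wraps modulo the genome length.
#'
#' @param sequence uppercase DNA string (A/C/G/T only; the reference must
#'   be fully determined, so N is not allowed here).
#' @param name sequence name.
#' @param features optional gene feature table (see [read_gene_map()]).
#' @return an object of class `mt_reference`.
#' @export
mt_reference <- function(sequence, name = "chrM", features = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence) || !is_dna(sequence, allow_n = FALSE)) {
    stopf("reference sequence must be non-empty A/C/G/T DNA (no N)")
  }
  ref <- structure(
    list(name = name, sequence = sequence, length = nchar(sequence),
         features = NULL),
    class = "mt_reference"
  )
  if (!is.null(features)) ref <- set_features(ref, features)
  ref
}

#' @export
print.mt_reference <- function(x, ...) {
  cat(sprintf("<mt_reference> %s: %d bp (circular), %d features\n",
              x$name, x$length,
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

FEATURE_CLASSES <- c("control_region", "rRNA", "tRNA", "protein_coding",
                     "intergenic")

# precedence used to resolve overlapping annotations into the single gene
# a variant table reports per position
CLASS_PRIORITY <- c(tRNA = 1, rRNA = 2, protein_coding = 3,
                    control_region = 4, intergenic = 5)

validate_features <- function(features, genome_length) {
  required <- c("gene", "start", "end", "strand", "feature_class")
  if (!all(required %in% names(features))) {
    stopf("gene map needs columns: %s", paste(required, collapse = ", "))
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyDuplicated(features$gene)) {
    stopf("duplicate gene names in annotation: %s",
          paste(unique(features$gene[duplicated(features$gene)]),
                collapse = ", "))
  }
  if (!all(features$strand %in% c("H", "L"))) {
    stopf("strand must be 'H' or 'L'")
  }
  if (!all(features$feature_class %in% FEATURE_CLASSES)) {
    stopf("unknown feature_class: %s",
          paste(setdiff(features$feature_class, FEATURE_CLASSES),
                collapse = ", "))
  }
  bad <- features$start < 1 | features$start > genome_length |
    features$end < 1 | features$end > genome_length
  if (any(bad)) {
    stopf("feature(s) outside [1, %d]: %s", genome_length,
          paste(features$gene[bad], collapse = ", "))
  }
  features
}

set_features <- function(reference, features) {
  reference$features <- validate_features(features, reference$length)
  reference
}

#' Load a reference genome and its gene map
#'
#' @param fasta_source path to a single-record FASTA file.
#' @param annotation_source path to a gene-map TSV
#'   (columns `gene`, `start`, `end`, `strand`, `feature_class`; a feature
#'   whose `end` is smaller than its `start` wraps the origin, e.g. the
#'   control region `16024..576`).
#' @return an `mt_reference` with features attached.
#' @export
load_reference <- function(fasta_source, annotation_source) {
  seqs <- Biostrings::readDNAStringSet(fasta_source)
  if (length(seqs) != 1L) {
    stopf("reference FASTA must contain exactly one record, found %d",
          length(seqs))
  }
  s <- as.character(seqs[[1L]])
  if (!is_dna(s, allow_n = FALSE)) {
    stopf("reference contains non-A/C/G/T characters")
  }
  features <- read_gene_map(annotation_source)
  mt_reference(s, name = sub("\\s.*$", "", names(seqs)[1L]),
               features = features)
}

#' Read a gene coordinate map
#'
#' @param path TSV with columns `gene`, `start`, `end`, `strand`,
#'   `feature_class`. Lines starting with `#` are comments.
#' @return a data.frame of gene features.
#' @export
read_gene_map <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Path to the bundled human mtDNA gene map
#'
#' Standard public annotation of the human mitochondrial genome (rCRS
#' coordinate frame, 16,569 bp), with gene symbols as printed in clinical
#' mtDNA variant tables (`MT-COX1`, `MT-CYTB`, ...). `MT-TC` (tRNA-Cys) and
#' the other light-strand genes are flagged `L`.
#'
#' @return file path.
#' @export
human_gene_map_path <- function() {
  system.file("extdata", "human_mtdna_genes.tsv", package = "mitoscreen",
              mustWork = TRUE)
}

# positions covered by a (possibly origin-wrapping) feature
feature_covers <- function(feature, position, genome_length) {
  if (feature$start <= feature$end) {
    position >= feature$start & position <= feature$end
  } else {
    position >= feature$start | position <= feature$end
  }
}

#' Feature at a reference position
#'
#' Every position maps to exactly one feature. Overlaps are resolved
#' deterministically: tRNA > rRNA > protein-coding > control region; ties
#' go to the feature with the smaller start. Unannotated positions fall
#' back to a synthetic `intergenic` feature.
#'
#' @param reference an `mt_reference` with features.
#' @param position 1-based position in `[1, length]`.
#' @return one-row data.frame (a `GeneFeature`).
#' @export
feature_at <- function(reference, position) {
  stopifnot(inherits(reference, "mt_reference"))
  if (is.null(reference$features)) stopf("reference has no features")
  position <- as.integer(position)
  if (length(position) != 1L || is.na(position) ||
      position < 1L || position > reference$length) {
    stopf("position must be a single integer in [1, %d]", reference$length)
  }
  f <- reference$features
  hit <- vapply(seq_len(nrow(f)),
                function(i) feature_covers(f[i, ], position, reference$length),
                logical(1))
  if (!any(hit)) {
    return(data.frame(gene = "intergenic", start = position, end = position,
                      strand = "H", feature_class = "intergenic",
                      stringsAsFactors = FALSE))
  }
  cand <- f[hit, , drop = FALSE]
  ord <- order(CLASS_PRIORITY[cand$feature_class], cand$start)
  cand[ord[1L], , drop = FALSE]
}

#' Complement and reverse-complement of DNA
#'
#' Needed for light-strand gene notation: a heavy-strand `T>C` reads `A>G`
#' on a light-strand-encoded gene such as MT-TC.
#'
#' @param base single DNA base (or string of bases to complement in place).
#' @return complemented base(s).
#' @export
mt_complement <- function(base) {
  base <- toupper(base)
  if (!all(vapply(base, is_dna, logical(1), allow_n = TRUE))) {
    stopf("non-DNA character in input")
  }
  chartr("ACGTN", "TGCAN", base)
}

#' @rdname mt_complement
#' @param seq DNA string.
#' @export
mt_reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (!is_dna(seq, allow_n = TRUE)) stopf("non-DNA character in input")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# base at a (wrapping) position
base_at <- function(reference, position) {
  p <- ((as.integer(position) - 1L) %% reference$length) + 1L
  substring(reference$sequence, p, p)
}
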