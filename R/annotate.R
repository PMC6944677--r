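#' Gene-strand variant notation
#'
#' `m.<pos><ref>><alt>` with alleles complemented when the gene is encoded
#' on the light strand (e.g. heavy-strand `5802 T-C` in MT-TC reads
#' `m.5802A>G`). Insertions/deletions keep heavy-strand alleles and use
#' `ref>alt` verbatim.
#' @noRd
gene_strand_notation <- function(position, ref, alt, strand) {
  if (nchar(ref) == 1L && nchar(alt) == 1L && strand == "L") {
    ref <- mt_complement(ref); alt <- mt_complement(alt)
  }
  sprintf("m.%d%s>%s", position, ref, alt)
}

#' Classify the coding effect of a substitution in a protein-coding gene
#'
#' Translates the affected codon under the vertebrate mitochondrial genetic
#' code, on the gene's own strand (light-strand genes are read as the
#' reverse complement of the heavy strand). Codon index is 1-based within
#' the protein, matching `Thr112Ala`-style naming.
#'
#' @param var one-row variant data.frame (substitution).
#' @param feature one-row protein-coding feature.
#' @param reference an `mt_reference`.
#' @return list with `coding_effect` (`silent`, `missense` or `other`) and
#'   `aa_change` (`RefPosAlt` in three-letter code, missense only).
#' @export
classify_coding_effect <- function(var, feature, reference) {
  if (feature$feature_class != "protein_coding") {
    stopf("feature %s is not protein-coding", feature$gene)
  }
  if (var$kind != "substitution") {
    return(list(coding_effect = "other", aa_change = NA_character_))
  }
  glen <- feature$end - feature$start + 1L
  offset <- if (feature$strand == "H") var$position - feature$start
            else feature$end - var$position
  codon_idx <- offset %/% 3L          # 0-based codon
  cpos <- offset %% 3L + 1L           # 1..3 within codon
  if (3L * codon_idx + 3L > glen) {   # incomplete terminal codon
    return(list(coding_effect = "other", aa_change = NA_character_))
  }
  if (feature$strand == "H") {
    gpos <- feature$start + 3L * codon_idx + 0:2
    ref_codon <- vapply(gpos, function(p) base_at(reference, p), "")
    alt_base <- var$alt
  } else {
    gpos <- feature$end - 3L * codon_idx - (0:2)
    ref_codon <- mt_complement(vapply(gpos, function(p) base_at(reference, p), ""))
    alt_base <- mt_complement(var$alt)
  }
  ref_at <- if (feature$strand == "H") var$ref else mt_complement(var$ref)
  if (ref_codon[cpos] != ref_at) {
    stopf("variant ref allele disagrees with reference at %d", var$position)
  }
  alt_codon <- ref_codon
  alt_codon[cpos] <- alt_base
  code <- mito_code()
  ref_aa <- translate_codon(collapse(ref_codon), code)
  alt_aa <- translate_codon(collapse(alt_codon), code)
  if (ref_aa == "*" || alt_aa == "*") {
    return(list(coding_effect = "other", aa_change = NA_character_))
  }
  if (ref_aa == alt_aa) {
    return(list(coding_effect = "silent", aa_change = NA_character_))
  }
  list(coding_effect = "missense",
       aa_change = paste0(aa3(ref_aa), codon_idx + 1L, aa3(alt_aa)))
}

#' Annotate a variant with gene, feature class and coding effect
#'
#' @param var one-row variant data.frame.
#' @param reference an `mt_reference` with features.
#' @return one-row annotated data.frame adding `gene`, `feature_class`,
#'   `strand`, `gene_strand_notation`, `coding_effect`, `aa_change`.
#' @export
annotate_variant <- function(var, reference) {
  feat <- feature_at(reference, var$position)
  notation <- gene_strand_notation(var$position, var$ref, var$alt,
                                   feat$strand)
  if (feat$feature_class == "protein_coding") {
    eff <- classify_coding_effect(var, feat, reference)
  } else {
    eff <- list(coding_effect = "non_coding", aa_change = NA_character_)
  }
  cbind(var,
        data.frame(gene = feat$gene, feature_class = feat$feature_class,
                   strand = feat$strand, gene_strand_notation = notation,
                   coding_effect = eff$coding_effect,
                   aa_change = eff$aa_change, stringsAsFactors = FALSE))
}

#' Annotate a whole variant set
#'
#' @param variants variant data.frame.
#' @param reference an `mt_reference` with features.
#' @return annotated data.frame, one row per variant, sorted by position.
#' @export
annotate_variants <- function(variants, reference) {
  if (nrow(variants) == 0L) {
    return(cbind(variants,
                 data.frame(gene = character(), feature_class = character(),
                            strand = character(),
                            gene_strand_notation = character(),
                            coding_effect = character(),
                            aa_change = character())))
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    annotate_variant(variants[i, , drop = FALSE], reference)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$position), ]
}

#' Partition annotated variants into report categories
#'
#' The disjoint, exhaustive categories of a clinical mtDNA variant summary:
#' control region (D-loop), the two rRNA genes, tRNA genes, then silent /
#' missense / other for protein-coding positions.
#'
#' @param annotated output of [annotate_variants()].
#' @return named integer vector with entries `D-loop`, `MT-RNR1`,
#'   `MT-RNR2`, `tRNA`, `silent`, `missense`, `other`; sums to the number
#'   of variants.
#' @export
partition_variants <- function(annotated) {
  cat_of <- function(i) {
    fc <- annotated$feature_class[i]
    if (fc == "control_region") return("D-loop")
    if (fc == "rRNA") return(annotated$gene[i])
    if (fc == "tRNA") return("tRNA")
    if (fc == "protein_coding") return(annotated$coding_effect[i])
    "other"
  }
  cats <- c("D-loop", "MT-RNR1", "MT-RNR2", "tRNA", "silent", "missense",
            "other")
  got <- vapply(seq_len(nrow(annotated)), cat_of, "")
  got[!got %in% cats] <- "other"
  counts <- table(factor(got, levels = cats))
  setNames(as.integer(counts), cats)
}

#' Write an annotated variant table
#'
#' TSV in the replacement dialect plus effect columns.
#' @param annotated annotated variant data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(annotated, path) {
  if (nrow(annotated) == 0L) {
    writeLines(paste(c("gene", "position", "replacement", "notation",
                       "feature_class", "coding_effect", "aa_change"),
                     collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(
    gene = annotated$gene,
    position = annotated$position,
    replacement = paste0(annotated$ref, "-", annotated$alt),
    notation = annotated$gene_strand_notation,
    feature_class = annotated$feature_class,
    coding_effect = annotated$coding_effect,
    aa_change = ifelse(is.na(annotated$aa_change), "", annotated$aa_change),
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minimal VCF v4.2 writer for mtDNA variants
#'
#' @param annotated annotated variant data.frame.
#' @param path output path.
#' @param contig contig name (default `chrM`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(annotated, path, contig = "chrM") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", contig),
               "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene\">",
               "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(annotated) > 0L) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tGENE=%s;EFFECT=%s",
                       contig, annotated$position, annotated$ref,
                       annotated$alt, annotated$gene,
                       annotated$coding_effect), con)
  }
  invisible(path)
}
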