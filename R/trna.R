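#' Canonical tRNA cloverleaf structure
#'
#' Block segmentation of the cloverleaf in canonical tRNA numbering
#' (anticodon at 34-36, discriminator at 73), matching the block layout of
#' published block-structured tRNA alignments: fixed-width stem blocks
#' anchored at canonical positions (1, 8, 10, 22, 26, 27, 32, 39, 44, 49,
#' 61, 66, 73) and variable-width loop blocks that are left-aligned within
#' their canonical slot range.
#'
#' @return a `trna_structure`: list with `blocks` (name, anchor, slots,
#'   fixed) and `pairs` (stem base pairs, both directions).
#' @export
canonical_trna_structure <- function() {
  blocks <- data.frame(
    name = c("acceptor_stem_5p", "connector", "d_stem_5p", "d_loop",
             "d_stem_3p", "position_26", "anticodon_stem_5p",
             "anticodon_loop", "anticodon_stem_3p", "variable_region",
             "t_stem_5p", "t_loop", "t_stem_3p", "acceptor_stem_3p",
             "discriminator"),
    anchor = c(1L, 8L, 10L, 14L, 22L, 26L, 27L, 32L, 39L, 44L, 49L, 54L,
               61L, 66L, 73L),
    slots = c(7L, 2L, 4L, 8L, 4L, 1L, 5L, 7L, 5L, 5L, 5L, 7L, 5L, 7L, 1L),
    fixed = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
              FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  stem_of <- function(five, three) {
    # pair k-th base of the 5' strand with the (w-k+1)-th of the 3' strand
    w <- blocks$slots[blocks$name == five]
    a5 <- blocks$anchor[blocks$name == five]
    a3 <- blocks$anchor[blocks$name == three]
    cbind(a5 + 0:(w - 1L), a3 + (w - 1L):0)
  }
  pairs <- rbind(stem_of("acceptor_stem_5p", "acceptor_stem_3p"),
                 stem_of("d_stem_5p", "d_stem_3p"),
                 stem_of("anticodon_stem_5p", "anticodon_stem_3p"),
                 stem_of("t_stem_5p", "t_stem_3p"))
  structure(list(blocks = blocks, pairs = pairs), class = "trna_structure")
}

#' @export
print.trna_structure <- function(x, ...) {
  cat(sprintf("<trna_structure> %d blocks, %d stem base pairs\n",
              nrow(x$blocks), nrow(x$pairs)))
  invisible(x)
}

block_of_position <- function(structure, position) {
  b <- structure$blocks
  hit <- which(position >= b$anchor & position <= b$anchor + b$slots - 1L)
  if (length(hit) != 1L) {
    stopf("position %d outside canonical numbering (1..73)", position)
  }
  hit
}

#' Cloverleaf domain of a canonical tRNA position
#'
#' @param structure a `trna_structure`.
#' @param position canonical tRNA position (1..73).
#' @return block name, e.g. position 30 -> `"anticodon_stem_5p"`.
#' @export
map_position_to_domain <- function(structure, position) {
  structure$blocks$name[block_of_position(structure, position)]
}

#' Watson-Crick partner of a stem position
#'
#' A fixed involution independent of sequence content; loop and
#' variable-region positions have no partner.
#'
#' @param structure a `trna_structure`.
#' @param position canonical tRNA position.
#' @return partner position, or `NA` for unpaired positions.
#' @export
pair_partner <- function(structure, position) {
  block_of_position(structure, position)  # validates range
  hit <- which(structure$pairs[, 1L] == position)
  fwd <- if (length(hit)) structure$pairs[hit[1L], 2L] else NA_integer_
  rev <- which(structure$pairs[, 2L] == position)
  if (is.na(fwd) && length(rev)) fwd <- structure$pairs[rev[1L], 1L]
  as.integer(fwd)
}

#' Parse a block-structured multi-species tRNA alignment
#'
#' TSV dialect mirroring published block alignments: a `species` column
#' plus one column per cloverleaf block (named as in
#' [canonical_trna_structure()]). Stem blocks must have identical width
#' across species; loop/variable blocks may differ in length and are
#' treated as left-aligned.
#'
#' @param table_source TSV path.
#' @param structure a `trna_structure`.
#' @param human human row label (default `"Homo sapiens"`).
#' @return a `trna_alignment`: list with `species`, `blocks` (data.frame of
#'   per-species block sequences), `human_row`, `structure`.
#' @export
parse_trna_alignment <- function(table_source,
                                 structure = canonical_trna_structure(),
                                 human = "Homo sapiens") {
  # colClasses: a column of bare "T" bases must not become logical
  tab <- read.delim(table_source, comment.char = "#",
                    stringsAsFactors = FALSE, colClasses = "character")
  if (!"species" %in% names(tab)) stopf("alignment needs a 'species' column")
  missing_blocks <- setdiff(structure$blocks$name, names(tab))
  if (length(missing_blocks)) {
    stopf("alignment missing block(s): %s",
          paste(missing_blocks, collapse = ", "))
  }
  for (bn in structure$blocks$name) {
    tab[[bn]] <- toupper(gsub("\\s", "", tab[[bn]]))
    empty <- !nzchar(tab[[bn]])
    if (any(empty)) {
      stopf("species %s lack(s) block %s",
            paste(tab$species[empty], collapse = ", "), bn)
    }
  }
  b <- structure$blocks
  for (k in which(b$fixed)) {
    w <- nchar(tab[[b$name[k]]])
    if (length(unique(w)) != 1L) {
      stopf("stem block %s has unequal widths across species", b$name[k])
    }
    if (unique(w) != b$slots[k]) {
      stopf("stem block %s is %d wide, expected %d", b$name[k],
            unique(w), b$slots[k])
    }
  }
  hr <- which(tab$species == human)
  if (length(hr) != 1L) stopf("human row '%s' not found exactly once", human)
  # non-human loop rows may overflow the canonical slot range (their extra
  # columns carry no human anchor), but the human row must fit it, since
  # it defines the position-to-column mapping
  too_long <- vapply(which(!b$fixed), function(k) {
    nchar(tab[[b$name[k]]][hr]) > b$slots[k]
  }, logical(1))
  if (any(too_long)) {
    stopf("human loop block longer than its canonical slots")
  }
  structure(list(species = tab$species,
                 blocks = tab[structure$blocks$name],
                 human_row = hr, structure = structure),
            class = "trna_alignment")
}

#' @export
print.trna_alignment <- function(x, ...) {
  cat(sprintf("<trna_alignment> %d species x %d blocks (human row: %s)\n",
              length(x$species), ncol(x$blocks), x$species[x$human_row]))
  invisible(x)
}

#' Path to the bundled tRNA-Cys alignment
#'
#' The 17-species block alignment of the mitochondrial tRNA-Cys (MT-TC)
#' gene (in-paper data transcribed as a fixture). Position 30 — the fourth
#' column of the 5' anticodon-stem block — is the site of the m.5802A>G
#' mutation in gene orientation.
#'
#' @return file path.
#' @export
trna_cys_alignment_path <- function() {
  system.file("extdata", "trna_cys_alignment.tsv", package = "mitoscreen",
              mustWork = TRUE)
}

# per-species character at a canonical position; "" where the row's block
# is too short to reach the column (a gap)
column_at <- function(alignment, position) {
  st <- alignment$structure
  k <- block_of_position(st, position)
  col <- position - st$blocks$anchor[k] + 1L
  substring(alignment$blocks[[st$blocks$name[k]]], col, col)
}

#' Conservation index at a canonical tRNA position
#'
#' Percentage of non-human species whose base at the position equals the
#' human wild-type base. Gaps in non-human rows count as mismatches; a gap
#' in the human row makes the CI undefined (`NA`) — the index is anchored
#' on the human wild-type nucleotide.
#'
#' @param alignment a `trna_alignment`.
#' @param position canonical tRNA position.
#' @param denominator `"non_human"` (default) or `"all"` rows.
#' @return CI percentage in `[0, 100]`, or `NA` where undefined.
#' @export
conservation_index <- function(alignment, position,
                               denominator = c("non_human", "all")) {
  denominator <- match.arg(denominator)
  col <- column_at(alignment, position)
  human_base <- col[alignment$human_row]
  if (!nzchar(human_base)) return(NA_real_)
  others <- if (denominator == "non_human") col[-alignment$human_row] else col
  if (length(others) == 0L) return(100)  # no comparison species: vacuously conserved
  100 * sum(others == human_base) / length(others)
}

#' Conservation profile over the whole cloverleaf
#'
#' @param alignment a `trna_alignment`.
#' @param denominator see [conservation_index()].
#' @return data.frame with `position`, `human_base`, `ci`, `domain`,
#'   `pair_partner`; `ci` is `NA` where the human row has no base.
#' @export
conservation_profile <- function(alignment,
                                 denominator = c("non_human", "all")) {
  denominator <- match.arg(denominator)
  st <- alignment$structure
  positions <- unlist(lapply(seq_len(nrow(st$blocks)), function(k) {
    st$blocks$anchor[k] + 0:(st$blocks$slots[k] - 1L)
  }))
  positions <- sort(unique(positions))
  rows <- lapply(positions, function(p) {
    col <- column_at(alignment, p)
    hb <- col[alignment$human_row]
    data.frame(position = p,
               human_base = ifelse(nzchar(hb), hb, NA_character_),
               ci = conservation_index(alignment, p, denominator),
               domain = map_position_to_domain(st, p),
               pair_partner = pair_partner(st, p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map a genome position to a canonical tRNA position
#'
#' Walks the human row of the alignment: the variant's offset within the
#' tRNA gene (in gene orientation; light-strand genes are counted from the
#' gene's heavy-strand end) is matched to the canonical position of the
#' corresponding human base, fixed blocks column-by-column and variable
#' blocks left-aligned.
#'
#' @param position heavy-strand genome position.
#' @param feature the tRNA gene feature covering it.
#' @param alignment a `trna_alignment` for that tRNA.
#' @return canonical tRNA position (e.g. genome 5802 in MT-TC -> 30).
#' @export
genome_to_trna_position <- function(position, feature, alignment) {
  if (feature$feature_class != "tRNA") stopf("feature is not a tRNA gene")
  idx <- if (feature$strand == "H") position - feature$start + 1L
         else feature$end - position + 1L
  if (idx < 1L) stopf("position %d not inside %s", position, feature$gene)
  st <- alignment$structure
  seen <- 0L
  for (k in seq_len(nrow(st$blocks))) {
    blen <- nchar(alignment$blocks[[st$blocks$name[k]]][alignment$human_row])
    if (idx <= seen + blen) {
      return(st$blocks$anchor[k] + (idx - seen - 1L))
    }
    seen <- seen + blen
  }
  stopf("position %d beyond the human tRNA sequence (%d bases)",
        position, seen)
}

#' Write a conservation profile as TSV
#'
#' @param profile output of [conservation_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conservation_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
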