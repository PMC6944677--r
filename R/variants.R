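#' Construct a point variant
#'
#' Alleles are stated on the heavy strand (reference orientation), 1-based.
#' The table dialect writes a replacement as `ref-alt`, insertions as an
#' extended alt (`310 C-CC` = ref `C`, alt `CC`).
#'
#' @param position 1-based reference position.
#' @param ref reference allele (>= 1 base).
#' @param alt alternate allele (>= 1 base).
#' @param homoplasmy logical; carried flag, not inferred (default TRUE).
#' @return one-row data.frame with columns `position`, `ref`, `alt`,
#'   `kind`, `homoplasmy`.
#' @export
variant <- function(position, ref, alt, homoplasmy = TRUE) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!is_dna(ref) || !is_dna(alt)) stopf("alleles must be A/C/G/T")
  kind <- variant_kind(ref, alt)
  data.frame(position = as.integer(position), ref = ref, alt = alt,
             kind = kind, homoplasmy = homoplasmy, stringsAsFactors = FALSE)
}

variant_kind <- function(ref, alt) {
  if (nchar(ref) == 1L && nchar(alt) == 1L && ref != alt) return("substitution")
  if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) return("insertion")
  if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) return("deletion")
  stopf("cannot classify replacement %s-%s", ref, alt)
}

variant_key <- function(variants) {
  paste0(variants$position, ":", variants$ref, ">", variants$alt)
}

#' Read a variant table in the replacement dialect
#'
#' The dialect of published mtDNA variant tables: columns `gene`,
#' `position`, `replacement` (`ref-alt`), `previously_reported` (Yes/No).
#' The `gene` column may be blank on continuation rows (carried forward).
#'
#' @param path TSV path.
#' @return data.frame with the table columns plus parsed `ref`, `alt`,
#'   `kind`.
#' @export
read_variant_table <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("gene", "position", "replacement")
  if (!all(need %in% names(tab))) {
    stopf("variant table needs columns: %s", paste(need, collapse = ", "))
  }
  # carry gene symbol forward over blank continuation rows
  g <- tab$gene
  for (i in seq_along(g)) if (!nzchar(g[i])) g[i] <- g[i - 1L]
  tab$gene <- g
  rep_clean <- gsub("\\s", "", tab$replacement)
  # strip an amino-acid annotation like "A-G(Thr112Ala)"
  aa <- sub("^.*\\(([A-Za-z]{3}[0-9]+[A-Za-z]{3})\\)$", "\\1", rep_clean)
  aa[!grepl("\\(", rep_clean)] <- NA_character_
  core <- sub("\\(.*$", "", rep_clean)
  parts <- strsplit(core, "-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stopf("malformed replacement(s): %s",
          paste(tab$replacement[lengths(parts) != 2L], collapse = ", "))
  }
  tab$ref <- toupper(vapply(parts, `[`, "", 1L))
  tab$alt <- toupper(vapply(parts, `[`, "", 2L))
  tab$kind <- mapply(variant_kind, tab$ref, tab$alt, USE.NAMES = FALSE)
  tab$aa_annotation <- aa
  tab$position <- as.integer(tab$position)
  tab[order(tab$position), ]
}

#' Path to the bundled family variant table
#'
#' The 47 point variants detected in the proband mitochondrial genome
#' relative to the Cambridge reference, in the replacement dialect
#' (in-paper data transcribed as a machine-readable fixture).
#'
#' @return file path.
#' @export
family_variant_table_path <- function() {
  system.file("extdata", "family_variants.tsv", package = "mitoscreen",
              mustWork = TRUE)
}

#' Apply variants to a reference sequence
#'
#' @param reference an `mt_reference` (or plain DNA string).
#' @param variants variant data.frame (`position`, `ref`, `alt`).
#' @return the sample sequence as a character string.
#' @export
apply_variants <- function(reference, variants) {
  seq <- if (inherits(reference, "mt_reference")) reference$sequence
         else toupper(reference)
  if (is.null(variants) || nrow(variants) == 0L) return(seq)
  variants <- variants[order(variants$position), ]
  if (anyDuplicated(variants$position)) {
    stopf("overlapping variants at position(s) %s",
          paste(unique(variants$position[duplicated(variants$position)]),
                collapse = ", "))
  }
  v <- chars(seq)
  # apply in descending position order so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(variants)))) {
    p <- variants$position[i]
    ref <- variants$ref[i]; alt <- variants$alt[i]
    have <- collapse(v[p:(p + nchar(ref) - 1L)])
    if (have != ref) {
      stopf("ref allele mismatch at %d: expected %s, reference has %s",
            p, ref, have)
    }
    v <- c(v[seq_len(p - 1L)], chars(alt), v[-seq_len(p + nchar(ref) - 1L)])
  }
  collapse(v)
}

#' Extract point variants between a sample genome and the reference
#'
#' Anchored two-pointer scan, not a full pairwise alignment: built for
#' complete circular genomes that differ by isolated substitutions
#' (possibly clustered) and short indels (<= `max_indel` bases) flanked by
#' at least `anchor` matching bases. Indel calls are left-aligned by
#' construction (the scan stops at the first divergent base). A run of
#' in-register mismatches longer than 15 bases is reported as an ambiguous
#' region instead of being guessed at.
#'
#' @param sample_seq sample genome (string; N allowed, counts as mismatch
#'   but is never reported as a variant allele).
#' @param reference an `mt_reference` or DNA string.
#' @param anchor matching bases required to re-anchor after an indel.
#' @param max_indel longest indel considered.
#' @return variant data.frame sorted by position; applying it to the
#'   reference reproduces the sample (round-trip identity).
#' @export
extract_variants <- function(sample_seq, reference, anchor = 10L,
                             max_indel = 5L) {
  ref_seq <- if (inherits(reference, "mt_reference")) reference$sequence
             else toupper(reference)
  smp_seq <- toupper(sample_seq)
  if (!is_dna(smp_seq, allow_n = TRUE)) stopf("sample has non-DNA characters")
  r <- chars(ref_seq); s <- chars(smp_seq)
  nr <- length(r); ns <- length(s)
  out <- vector("list", 64L); nout <- 0L
  push <- function(pos, ref, alt) {
    nout <<- nout + 1L
    if (nout > length(out)) length(out) <<- 2L * nout
    out[[nout]] <<- list(position = pos, ref = ref, alt = alt)
  }
  window_matches <- function(ri, si, n) {
    # truncated at either end; the truncated part counts as matching
    n <- min(n, nr - ri + 1L, ns - si + 1L)
    if (n <= 0L) return(TRUE)
    all(r[ri:(ri + n - 1L)] == s[si:(si + n - 1L)])
  }
  i <- 1L; j <- 1L
  mismatch_run <- 0L
  while (i <= nr && j <= ns) {
    len <- min(nr - i, ns - j) + 1L
    block_r <- r[i:(i + len - 1L)]
    block_s <- s[j:(j + len - 1L)]
    mis <- which(block_r != block_s)
    if (length(mis) == 0L) { i <- i + len; j <- j + len; break }
    d <- mis[1L] - 1L
    if (d > 0L) mismatch_run <- 0L
    i <- i + d; j <- j + d
    # mismatch at (i, j)
    if (window_matches(i + 1L, j + 1L, anchor)) {
      push(i, r[i], s[j])                     # isolated substitution
      mismatch_run <- 0L
      i <- i + 1L; j <- j + 1L
      next
    }
    ins <- del <- NA_integer_
    for (k in seq_len(max_indel)) {
      if (is.na(ins) && window_matches(i, j + k, anchor)) ins <- k
      if (is.na(del) && window_matches(i + k, j, anchor)) del <- k
    }
    if (!is.na(ins) && i > 1L) {
      push(i - 1L, r[i - 1L], collapse(c(r[i - 1L], s[j:(j + ins - 1L)])))
      mismatch_run <- 0L
      j <- j + ins
    } else if (!is.na(del) && i > 1L) {
      push(i - 1L, collapse(c(r[i - 1L], r[i:(i + del - 1L)])), r[i - 1L])
      mismatch_run <- 0L
      i <- i + del
    } else {
      # member of a substitution cluster
      mismatch_run <- mismatch_run + 1L
      if (mismatch_run > 15L) {
        stopf(paste0("ambiguous region near reference position %d: ",
                     "mismatch run exceeds 15 bases (inputs violate the ",
                     "isolated-variant precondition)"), i)
      }
      push(i, r[i], s[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  if (i <= nr || j <= ns) {
    stopf("trailing unaligned sequence (ref %d..%d vs sample %d..%d)",
          i, nr, j, ns)
  }
  if (nout == 0L) {
    return(data.frame(position = integer(), ref = character(),
                      alt = character(), kind = character(),
                      homoplasmy = logical(), stringsAsFactors = FALSE))
  }
  out <- out[seq_len(nout)]
  res <- data.frame(
    position = vapply(out, function(x) x$position, integer(1)),
    ref = vapply(out, function(x) x$ref, character(1)),
    alt = vapply(out, function(x) x$alt, character(1)),
    stringsAsFactors = FALSE
  )
  res <- res[res$alt != "N" & res$ref != "N", , drop = FALSE]
  res$kind <- mapply(variant_kind, res$ref, res$alt, USE.NAMES = FALSE)
  res$homoplasmy <- TRUE
  res <- res[order(res$position), ]
  rownames(res) <- NULL
  res
}
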