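#' Simulation configuration
#'
#' Defaults emulate the study's data regime: a 16,569 bp circular genome,
#' a 106-subject control cohort in which the candidate variant is absent
#' (carrier frequency 0), a haplogroup backbone carried by roughly half of
#' the same-region controls, and a 17-species tRNA alignment.
#'
#' @param seed master seed; each sub-generator derives its own stream so
#'   adding one generator never perturbs another's output.
#' @param genome_length genome length in bases.
#' @param n_controls control cohort size.
#' @param control_carrier_freq probability a control carries the candidate
#'   variant(s).
#' @param backbone_freq probability a control carries the haplogroup
#'   backbone.
#' @param alignment_species species count for generated alignments.
#' @param per_column_match_prob probability a non-human base matches the
#'   human base, per column (scalar or named per-domain vector).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 16569L,
                       n_controls = 106L, control_carrier_freq = 0,
                       backbone_freq = 0.5, alignment_species = 17L,
                       per_column_match_prob = 0.75) {
  stopifnot(genome_length >= 600, n_controls >= 1,
            control_carrier_freq >= 0, control_carrier_freq <= 1,
            backbone_freq >= 0, backbone_freq <= 1,
            all(per_column_match_prob >= 0), all(per_column_match_prob <= 1))
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 n_controls = as.integer(n_controls),
                 control_carrier_freq = control_carrier_freq,
                 backbone_freq = backbone_freq,
                 alignment_species = as.integer(alignment_species),
                 per_column_match_prob = per_column_match_prob),
            class = "sim_config")
}

# feature layout for an arbitrary-length synthetic genome: a wrapping
# control region, one rRNA, H- and L-strand tRNAs and two CDS genes,
# all scaled to the genome length
synthetic_gene_map <- function(genome_length) {
  L <- genome_length
  at <- function(f) max(1L, as.integer(round(f * L)))
  trna_len <- min(66L, as.integer(L * 0.04))
  cds_len <- 3L * (as.integer(L * 0.12) %/% 3L)
  data.frame(
    gene = c("D-loop", "RNR-sim", "TRNA-H-sim", "TRNA-L-sim",
             "CDS-H-sim", "CDS-L-sim"),
    start = c(at(0.96), at(0.05), at(0.20), at(0.26),
              at(0.35), at(0.60)),
    end = c(at(0.03), at(0.15), at(0.20) + trna_len - 1L,
            at(0.26) + trna_len - 1L, at(0.35) + cds_len - 1L,
            at(0.60) + cds_len - 1L),
    strand = c("H", "H", "H", "L", "H", "L"),
    feature_class = c("control_region", "rRNA", "tRNA", "tRNA",
                      "protein_coding", "protein_coding"),
    stringsAsFactors = FALSE
  )
}

#' Generate a random circular reference genome
#'
#' Deterministic for a fixed seed. For the standard 16,569 bp length the
#' bundled human gene map is attached; other lengths get a synthetic map
#' that still exercises every feature class, including a light-strand tRNA.
#'
#' @param config a `sim_config`.
#' @return an `mt_reference` with features.
#' @export
generate_reference <- function(config) {
  set.seed(derive_seed(config$seed, "reference"))
  seq <- random_dna(config$genome_length)
  features <- if (config$genome_length == 16569L) {
    read_gene_map(human_gene_map_path())
  } else {
    synthetic_gene_map(config$genome_length)
  }
  mt_reference(seq, name = sprintf("sim_ref_seed%d", config$seed),
               features = features)
}

# -- codon-constrained surrogate ------------------------------------------

# parse "Thr112Ala" -> list(ref_aa, idx, alt_aa) in one-letter code
parse_aa_annotation <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3})$", s))[[1]]
  if (length(m) != 4L) stopf("bad amino-acid annotation: %s", s)
  one <- setNames(names(AA_THREE), AA_THREE)
  list(ref_aa = unname(one[m[2]]), idx = as.integer(m[3]),
       alt_aa = unname(one[m[4]]))
}

# choose a codon satisfying all constraints accumulated for one codon slot;
# constraints: list of (cpos, ref_base, alt_base, type, ref_aa, alt_aa)
solve_codon <- function(constraints, code = mito_code()) {
  all_codons <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                                DNA_BASES, paste0))
  ok <- vapply(all_codons, function(cd) {
    cv <- chars(cd)
    ref_aa <- code[[cd]]
    if (ref_aa == "*") return(FALSE)
    for (cs in constraints) {
      if (cv[cs$cpos] != cs$ref_base) return(FALSE)
      av <- cv; av[cs$cpos] <- cs$alt_base
      alt_aa <- code[[collapse(av)]]
      if (cs$type == "silent") {
        if (alt_aa != ref_aa) return(FALSE)
      } else {
        if (!is.null(cs$ref_aa) && ref_aa != cs$ref_aa) return(FALSE)
        if (alt_aa != cs$alt_aa || alt_aa == ref_aa) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  if (!any(ok)) {
    stopf("no codon satisfies constraints: %s",
          paste(vapply(constraints, function(cs)
            sprintf("%d%s>%s(%s)", cs$cpos, cs$ref_base, cs$alt_base,
                    cs$type), ""), collapse = "; "))
  }
  all_codons[which(ok)[1L]]  # deterministic first-in-order choice
}

#' Generate a SYNTHETIC surrogate reference consistent with a variant table
#'
#' Builds a random genome of the standard length that is, at every position
#' the supplied variant table touches, consistent with that table: printed
#' reference alleles are pinned, and for coding substitutions the whole
#' codon is chosen (on the gene's strand) so that the printed silent /
#' missense amino-acid annotations follow from translation under the
#' vertebrate mitochondrial code. The base following an insertion anchor is
#' pinned to differ from the inserted base so left-aligned extraction
#' reports the printed anchor position.
#'
#' This is a stand-in for the true Cambridge reference, which is not
#' shipped: everything the surrogate pins is printed table content, and all
#' classification is still computed from sequence. Supplying the genuine
#' NC_012920 FASTA to [load_reference()] gives the same analysis on the
#' real genome.
#'
#' @param variant_table data.frame from [read_variant_table()].
#' @param seed integer seed for the unconstrained positions.
#' @param gene_map gene feature table (default the bundled human map).
#' @param genome_length genome length (default 16,569).
#' @return an `mt_reference` with features.
#' @export
generate_surrogate_reference <- function(variant_table, seed = 1L,
                                         gene_map = read_gene_map(human_gene_map_path()),
                                         genome_length = 16569L) {
  set.seed(derive_seed(seed, "surrogate"))
  g <- chars(random_dna(genome_length))
  ref <- mt_reference(collapse(g), name = "surrogate_rCRS_synthetic",
                      features = gene_map)
  code <- mito_code()
  # accumulate per-codon constraints for coding substitutions
  codon_constraints <- list()
  for (i in seq_len(nrow(variant_table))) {
    v <- variant_table[i, ]
    feat <- feature_at(ref, v$position)
    if (feat$feature_class == "protein_coding" &&
        v$kind == "substitution") {
      offset <- if (feat$strand == "H") v$position - feat$start
                else feat$end - v$position
      codon_idx <- offset %/% 3L
      cpos <- offset %% 3L + 1L
      key <- paste0(feat$gene, ":", codon_idx)
      cs <- list(cpos = cpos,
                 ref_base = if (feat$strand == "H") v$ref
                            else mt_complement(v$ref),
                 alt_base = if (feat$strand == "H") v$alt
                            else mt_complement(v$alt),
                 type = if (is.na(v$aa_annotation)) "silent" else "missense")
      if (cs$type == "missense") {
        aa <- parse_aa_annotation(v$aa_annotation)
        if (aa$idx != codon_idx + 1L) {
          stopf("annotation %s disagrees with codon index %d at %d",
                v$aa_annotation, codon_idx + 1L, v$position)
        }
        cs$ref_aa <- aa$ref_aa
        cs$alt_aa <- aa$alt_aa
      }
      cs$feat <- feat; cs$codon_idx <- codon_idx
      codon_constraints[[key]] <- c(codon_constraints[[key]], list(cs))
    } else {
      # non-coding (or indel): pin the printed reference allele
      rb <- chars(v$ref)
      g[v$position + seq_along(rb) - 1L] <- rb
      if (v$kind == "insertion") {
        ins_first <- substring(v$alt, nchar(v$ref) + 1L, nchar(v$ref) + 1L)
        nxt <- v$position + nchar(v$ref)
        if (g[nxt] == ins_first) {
          g[nxt] <- setdiff(DNA_BASES, ins_first)[1L]
        }
      }
    }
  }
  for (key in names(codon_constraints)) {
    csl <- codon_constraints[[key]]
    codon <- chars(solve_codon(csl, code))
    feat <- csl[[1L]]$feat
    codon_idx <- csl[[1L]]$codon_idx
    if (feat$strand == "H") {
      gpos <- feat$start + 3L * codon_idx + 0:2
      g[gpos] <- codon
    } else {
      gpos <- feat$end - 3L * codon_idx - (0:2)
      g[gpos] <- mt_complement(codon)
    }
  }
  mt_reference(collapse(g), name = "surrogate_rCRS_synthetic",
               features = gene_map)
}

#' Generate pedigree genomes under strict maternal transmission
#'
#' Founders receive the reference plus the haplogroup backbone; carrier
#' founders additionally receive the candidate variants. Every child
#' inherits its mother's genome verbatim (homoplasmy), so all matrilineal
#' descendants of a carrier founder are carriers and nobody else ever is.
#'
#' @param reference an `mt_reference`.
#' @param ped a `pedigree`.
#' @param backbone variant data.frame (haplogroup backbone).
#' @param candidate variant data.frame (candidate variants).
#' @param carrier_founders ids of founders carrying the candidate.
#' @return named list of genome strings, plus attribute `carriers` with
#'   the ground-truth carrier ids.
#' @export
generate_pedigree_genomes <- function(reference, ped, backbone, candidate,
                                      carrier_founders) {
  founders <- setdiff(ped$members, names(ped$mother_of))
  bad <- setdiff(carrier_founders, founders)
  if (length(bad)) stopf("not founders: %s", paste(bad, collapse = ", "))
  genomes <- list()
  is_carrier <- setNames(logical(length(ped$members)), ped$members)
  assign_genome <- function(id) {
    if (!is.null(genomes[[id]])) return(genomes[[id]])
    mom <- unname(ped$mother_of[id])
    gnm <- if (is.na(mom) || is.null(mom)) {
      is_carrier[id] <<- id %in% carrier_founders
      vs <- if (id %in% carrier_founders) rbind(backbone, candidate)
            else backbone
      apply_variants(reference, vs)
    } else {
      g <- assign_genome(mom)
      is_carrier[id] <<- is_carrier[mom]   # homoplasmic inheritance
      g
    }
    genomes[[id]] <<- gnm
    gnm
  }
  for (m in ped$members) assign_genome(m)
  attr(genomes, "carriers") <- names(is_carrier)[is_carrier]
  genomes
}

#' Generate a control cohort of genomes
#'
#' Each control independently carries the haplogroup backbone with
#' probability `backbone_freq` and the candidate variant(s) with
#' probability `control_carrier_freq` (at frequency 0, exactly zero
#' carriers). Deterministic for a fixed config seed.
#'
#' @param config a `sim_config`.
#' @param reference an `mt_reference`.
#' @param backbone,candidate variant data.frames.
#' @return list of genome strings with attribute `carrier` (logical
#'   ground-truth vector for the candidate).
#' @export
generate_controls <- function(config, reference, backbone, candidate) {
  set.seed(derive_seed(config$seed, "controls"))
  n <- config$n_controls
  has_backbone <- runif(n) < config$backbone_freq
  has_candidate <- runif(n) < config$control_carrier_freq
  genomes <- lapply(seq_len(n), function(i) {
    vs <- NULL
    if (has_backbone[i]) vs <- backbone
    if (has_candidate[i]) vs <- rbind(vs, candidate)
    if (is.null(vs) || nrow(vs) == 0L) reference$sequence
    else apply_variants(reference, vs)
  })
  names(genomes) <- sprintf("control_%03d", seq_len(n))
  attr(genomes, "carrier") <- has_candidate
  genomes
}

#' Generate a multi-species tRNA alignment with controlled conservation
#'
#' The human row is a random sequence with the canonical block layout;
#' each non-human base independently equals the human base with the
#' domain's match probability, otherwise it is a uniformly random other
#' base. Stem blocks are fixed-width across species.
#'
#' @param config a `sim_config` (`alignment_species`,
#'   `per_column_match_prob`, seed).
#' @param structure a `trna_structure`.
#' @return a `trna_alignment`.
#' @export
generate_alignment <- function(config,
                               structure = canonical_trna_structure()) {
  set.seed(derive_seed(config$seed, "alignment"))
  n_sp <- config$alignment_species
  if (n_sp < 1L) stopf("need at least one species")
  b <- structure$blocks
  p_of <- function(name) {
    p <- config$per_column_match_prob
    if (length(p) == 1L && is.null(names(p))) return(unname(p))
    if (name %in% names(p)) return(unname(p[name]))
    stopf("no match probability for block %s", name)
  }
  human_lengths <- ifelse(b$fixed, b$slots,
                          pmax(1L, b$slots - sample(0:2, nrow(b), TRUE)))
  species <- c("Homo sapiens",
               sprintf("Simulated species %02d", seq_len(n_sp - 1L)))
  blocks <- list()
  for (k in seq_len(nrow(b))) {
    w <- human_lengths[k]
    human <- chars(random_dna(w))
    col <- character(n_sp)
    for (s in seq_len(n_sp)) {
      if (species[s] == "Homo sapiens") { col[s] <- collapse(human); next }
      match <- runif(w) < p_of(b$name[k])
      row <- ifelse(match, human,
                    vapply(human, function(hb)
                      sample(setdiff(DNA_BASES, hb), 1L), ""))
      col[s] <- collapse(row)
    }
    blocks[[b$name[k]]] <- col
  }
  structure(list(species = species,
                 blocks = as.data.frame(blocks, stringsAsFactors = FALSE,
                                        optional = TRUE),
                 human_row = 1L, structure = structure),
            class = "trna_alignment")
}

#' Generate a random pedigree topology
#'
#' Random maternal trees for property testing: `n_founder_women` founding
#' matriarchs, each member thereafter a child of a random already-present
#' woman (children are women with probability `p_female`).
#'
#' @param seed integer seed.
#' @param n_members total members to generate beyond the founders.
#' @param n_founder_women founding matriarchs.
#' @param p_female probability a child is female (can have children).
#' @return a `pedigree` (no affected set).
#' @export
generate_pedigree <- function(seed = 1L, n_members = 8L,
                              n_founder_women = 2L, p_female = 0.5) {
  set.seed(derive_seed(seed, "pedigree"))
  women <- sprintf("F%02d", seq_len(n_founder_women))
  mother_of <- character()
  all_ids <- women
  for (i in seq_len(n_members)) {
    mom <- sample(women, 1L)
    id <- sprintf("M%02d", i)
    female <- runif(1) < p_female
    if (female) women <- c(women, id)
    mother_of[id] <- mom
    all_ids <- c(all_ids, id)
  }
  pedigree(mother_of)
}
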