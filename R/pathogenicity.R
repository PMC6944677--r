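#' Control-cohort carrier frequency
#'
#' @param carriers number of control subjects carrying the variant.
#' @param n_controls control cohort size (> 0).
#' @return percentage `100 * carriers / n_controls`.
#' @export
control_frequency <- function(carriers, n_controls) {
  if (n_controls <= 0) stopf("n_controls must be positive")
  if (carriers < 0 || carriers > n_controls) {
    stopf("carriers must lie in [0, n_controls]")
  }
  100 * carriers / n_controls
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration: the two-sided p-value is the sum of
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (the usual convention for
#' comparing carrier frequencies between cases and controls).
#'
#' @param a,b,c,d non-negative integer cell counts (rows = groups,
#'   columns = carrier/non-carrier).
#' @return two-sided p-value in `(0, 1]`.
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stopf("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stopf("all-zero table")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(x, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  # tolerance guards against ties lost to floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Structural criterion for a tRNA variant
#'
#' TRUE when the variant's canonical tRNA position lies in a paired stem or
#' in the anticodon loop — the secondary-structure elements whose
#' disruption (e.g. a broken 30-40 anticodon-stem pair) is taken as a
#' potential structural alteration. `NA` (absent) for variants outside
#' tRNA genes: the criterion is only defined for tRNA screening.
#'
#' @param annotated_var one-row annotated variant.
#' @param structure a `trna_structure`.
#' @param alignment a `trna_alignment` (to map the genome position onto
#'   canonical numbering), or `NULL` with `trna_position` given directly.
#' @param feature the tRNA feature (needed with `alignment`).
#' @param trna_position canonical position override.
#' @return logical or `NA`.
#' @export
structural_flag <- function(annotated_var, structure,
                            alignment = NULL, feature = NULL,
                            trna_position = NULL) {
  if (annotated_var$feature_class != "tRNA") return(NA)
  if (is.null(trna_position)) {
    if (is.null(alignment) || is.null(feature)) {
      stopf("need an alignment and feature (or trna_position) for a tRNA variant")
    }
    trna_position <- genome_to_trna_position(annotated_var$position,
                                             feature, alignment)
  }
  paired <- !is.na(pair_partner(structure, trna_position))
  in_ac_loop <- map_position_to_domain(structure, trna_position) ==
    "anticodon_loop"
  paired || in_ac_loop
}

#' Three-criterion pathogenicity classification
#'
#' A variant is a `candidate` only if all three criteria hold (strict
#' inequalities, as in the screening definition): control frequency below
#' `freq_threshold` percent, conservation index above `ci_threshold`
#' percent, and a potential structural alteration. If any criterion's
#' input is absent and no present criterion already fails, the verdict is
#' `indeterminate`.
#'
#' @param annotated_var one-row annotated variant.
#' @param control_carriers,control_n control cohort counts.
#' @param ci_value conservation index percentage, or `NA` if not assessed.
#' @param structural logical structural criterion, or `NA` if not assessed.
#' @param freq_threshold control-frequency threshold in percent (default 1).
#' @param ci_threshold conservation threshold in percent (default 75).
#' @param fisher_p optional case/control Fisher p-value to carry through.
#' @return one-row `PathogenicityReport` data.frame.
#' @export
classify_pathogenicity <- function(annotated_var, control_carriers,
                                   control_n, ci_value, structural,
                                   freq_threshold = 1, ci_threshold = 75,
                                   fisher_p = NA_real_) {
  freq <- control_frequency(control_carriers, control_n)
  crit_freq <- freq < freq_threshold
  crit_ci <- if (is.na(ci_value)) NA else ci_value > ci_threshold
  crit_struct <- if (is.na(structural)) NA else isTRUE(structural)
  crits <- c(crit_freq, crit_ci, crit_struct)
  verdict <- if (any(!crits, na.rm = TRUE)) "not_candidate"
             else if (anyNA(crits)) "indeterminate"
             else "candidate"
  data.frame(
    position = annotated_var$position,
    gene = annotated_var$gene,
    notation = annotated_var$gene_strand_notation,
    control_carriers = control_carriers, control_n = control_n,
    control_freq = freq, freq_criterion = crit_freq,
    ci_value = ci_value, conservation_criterion = crit_ci,
    structural_criterion = crit_struct,
    verdict = verdict, fisher_p = fisher_p,
    stringsAsFactors = FALSE
  )
}

#' Screen an annotated variant set against controls and an alignment
#'
#' Applies the three-criterion filter to every variant: control carrier
#' counts from the cohort's variant sets, conservation index and structural
#' location for tRNA variants via the supplied alignment.
#'
#' @param annotated annotated variants of the index case.
#' @param control_sets list of variant data.frames, one per control
#'   subject (e.g. from [extract_variants()] on each control genome).
#' @param reference an `mt_reference` with features.
#' @param alignment `trna_alignment` for the screened tRNA gene, or `NULL`.
#' @param structure a `trna_structure`.
#' @param freq_threshold,ci_threshold criterion thresholds (percent).
#' @param case_carriers,case_n optional case-cohort counts for a per-variant
#'   Fisher's exact test against the controls.
#' @return `PathogenicityReport` data.frame, one row per variant.
#' @export
screen_variants <- function(annotated, control_sets, reference,
                            alignment = NULL,
                            structure = canonical_trna_structure(),
                            freq_threshold = 1, ci_threshold = 75,
                            case_carriers = NA, case_n = NA) {
  n_controls <- length(control_sets)
  control_keys <- lapply(control_sets, variant_key)
  rows <- lapply(seq_len(nrow(annotated)), function(i) {
    v <- annotated[i, , drop = FALSE]
    key <- variant_key(v)
    carriers <- sum(vapply(control_keys, function(k) key %in% k, logical(1)))
    ci_value <- NA_real_
    struct <- NA
    if (v$feature_class == "tRNA" && !is.null(alignment)) {
      feat <- feature_at(reference, v$position)
      tpos <- genome_to_trna_position(v$position, feat, alignment)
      ci_value <- conservation_index(alignment, tpos)
      struct <- structural_flag(v, structure, trna_position = tpos)
    }
    fp <- NA_real_
    if (!is.na(case_carriers) && !is.na(case_n)) {
      fp <- fisher_exact(case_carriers, case_n - case_carriers,
                         carriers, n_controls - carriers)
    }
    classify_pathogenicity(v, carriers, n_controls, ci_value, struct,
                           freq_threshold, ci_threshold, fisher_p = fp)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
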