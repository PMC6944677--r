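#' Body mass index
#'
#' Weight (kg) divided by squared height (m), reported to one decimal with
#' half-away-from-zero rounding (the precision of clinical summary tables).
#'
#' @param weight_kg weight in kilograms (> 0).
#' @param height_cm height in centimetres (> 0).
#' @return BMI in kg/m^2, rounded to one decimal.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0)) {
    stopf("weight and height must be positive")
  }
  round_half_up(weight_kg / (height_cm / 100)^2, 1)
}

#' Classify obesity from BMI and age/sex percentile cutoffs
#'
#' Children are classed against an age/sex percentile table (obesity above
#' the 95th percentile, severe obesity above the 99th; both strictly
#' "more than"). Adults (age >= `adult_age`) use fixed cutoffs, defaulting
#' to the Chinese adult convention (overweight > 24, obese > 28 kg/m^2).
#'
#' @param bmi_value BMI in kg/m^2.
#' @param age age in years.
#' @param sex `"M"` or `"F"`.
#' @param percentile_table data.frame with columns `sex`, `age_min`,
#'   `age_max`, `p85`, `p95`, `p99` (half-open age bands
#'   `[age_min, age_max)`).
#' @param adult_age adult threshold in years (default 18).
#' @param adult_cutoffs named vector `c(overweight=, obese=, severe=)`.
#' @return one of `"normal"`, `"overweight"`, `"obese"`, `"severe_obese"`.
#'   A child whose (age, sex) has no row in the table is an error, never a
#'   silent default.
#' @export
classify_obesity <- function(bmi_value, age, sex, percentile_table,
                             adult_age = 18,
                             adult_cutoffs = c(overweight = 24, obese = 28,
                                               severe = 32)) {
  if (age >= adult_age) {
    cut <- adult_cutoffs
    return(if (bmi_value > cut[["severe"]]) "severe_obese"
           else if (bmi_value > cut[["obese"]]) "obese"
           else if (bmi_value > cut[["overweight"]]) "overweight"
           else "normal")
  }
  row <- percentile_table[percentile_table$sex == sex &
                            age >= percentile_table$age_min &
                            age < percentile_table$age_max, , drop = FALSE]
  if (nrow(row) != 1L) {
    stopf("no percentile cutoffs for age %.1f sex %s", age, sex)
  }
  if (bmi_value > row$p99) "severe_obese"
  else if (bmi_value > row$p95) "obese"
  else if (bmi_value > row$p85) "overweight"
  else "normal"
}

#' Read a subject anthropometrics table
#'
#' Clinical-summary dialect: columns `id`, `age`, `sex`, `height_cm`,
#' `weight_kg`, `bmi`, `obese_duration`. Each printed BMI is checked
#' against recomputation from height/weight at one-decimal precision.
#'
#' @param path TSV path.
#' @return data.frame of subject records.
#' @export
read_subjects <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "height_cm", "weight_kg", "bmi")
  if (!all(need %in% names(tab))) {
    stopf("subject table needs columns: %s", paste(need, collapse = ", "))
  }
  recomputed <- bmi(tab$weight_kg, tab$height_cm)
  bad <- abs(recomputed - tab$bmi) > 0.05
  if (any(bad)) {
    stopf("BMI inconsistent with height/weight for subject(s): %s",
          paste(tab$id[bad], collapse = ", "))
  }
  tab
}

#' Path to the bundled subject table
#'
#' Anthropometrics of the affected matrilineal relatives (in-paper data
#' transcribed as a fixture).
#' @return file path.
#' @export
subject_table_path <- function() {
  system.file("extdata", "subjects.tsv", package = "mitoscreen",
              mustWork = TRUE)
}

#' Read a pedigree
#'
#' @param links_path two-column TSV `child`, `mother` (maternal links only).
#' @param affected character vector of affected member ids, or a path to a
#'   one-column file.
#' @param carriers optional character vector of variant-carrier ids.
#' @return a `pedigree` object (members, mother_of map, affected set).
#' @export
read_pedigree <- function(links_path, affected = character(),
                          carriers = NULL) {
  tab <- read.delim(links_path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("child", "mother") %in% names(tab))) {
    stopf("pedigree needs columns child, mother")
  }
  if (length(affected) == 1L && file.exists(affected)) {
    affected <- readLines(affected)
    affected <- affected[nzchar(affected) & !startsWith(affected, "#")]
  }
  pedigree(setNames(tab$mother, tab$child), affected, carriers)
}

#' Construct a pedigree
#'
#' @param mother_of named character vector: names are children, values
#'   their mothers.
#' @param affected character vector of affected ids.
#' @param carriers optional character vector of carrier ids; if given,
#'   strict maternal transmission is asserted (every carrier's in-pedigree
#'   mother is a carrier).
#' @return a `pedigree` object.
#' @export
pedigree <- function(mother_of, affected = character(), carriers = NULL) {
  members <- unique(c(names(mother_of), unname(mother_of), affected,
                      carriers))
  ped <- structure(list(members = members, mother_of = mother_of,
                        affected = unique(affected),
                        carriers = carriers),
                   class = "pedigree")
  for (m in members) matriline(ped, m)  # errors on cycles
  if (!is.null(carriers)) {
    for (cid in carriers) {
      mom <- unname(mother_of[cid])
      if (!is.na(mom) && !mom %in% carriers) {
        stopf("carrier %s has non-carrier mother %s (homoplasmic variants
               transmit strictly maternally)", cid, mom)
      }
    }
  }
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d members, %d affected\n",
              length(x$members), length(x$affected)))
  invisible(x)
}

# maternal ancestor chain (self first); errors on cycles
matriline <- function(ped, id) {
  chain <- id
  cur <- id
  repeat {
    mom <- unname(ped$mother_of[cur])
    if (is.na(mom) || is.null(mom)) break
    if (mom %in% chain) stopf("cyclic maternal links at %s", mom)
    chain <- c(chain, mom)
    cur <- mom
  }
  chain
}

#' Matrilineal relatives of a proband
#'
#' Members whose maternal ancestor chain reaches the proband's founding
#' matriarch — the transmission path of mtDNA (males in the matriline are
#' included; they carry but do not transmit).
#'
#' @param ped a `pedigree`.
#' @param proband member id.
#' @return character vector of matrilineal member ids.
#' @export
matrilineal_members <- function(ped, proband) {
  if (!proband %in% ped$members) stopf("proband %s not in pedigree", proband)
  matriarch <- utils::tail(matriline(ped, proband), 1L)
  keep <- vapply(ped$members, function(m) {
    utils::tail(matriline(ped, m), 1L) == matriarch
  }, logical(1))
  ped$members[keep]
}

#' Matrilineal affection summary
#'
#' @param ped a `pedigree`.
#' @param proband member id anchoring the matriline.
#' @return list with `matrilineal` ids, `n_matrilineal`, `n_affected`
#'   (among them) and `penetrance` (their ratio).
#' @export
matrilineal_summary <- function(ped, proband) {
  mat <- matrilineal_members(ped, proband)
  aff <- intersect(ped$affected, mat)
  list(matrilineal = mat, n_matrilineal = length(mat),
       n_affected = length(aff),
       penetrance = length(aff) / length(mat))
}

#' Path to the bundled demo pedigree files
#'
#' Synthetic demo pedigree (maternal links and affected list) emulating a
#' three-generation family with 7 matrilineal members, 3 affected; the
#' published pedigree figure is not machine-readable, so this fixture is
#' illustrative only.
#'
#' @return named character vector with elements `links` and `affected`.
#' @export
demo_pedigree_paths <- function() {
  c(links = system.file("extdata", "pedigree_demo.tsv",
                        package = "mitoscreen", mustWork = TRUE),
    affected = system.file("extdata", "pedigree_demo_affected.txt",
                           package = "mitoscreen", mustWork = TRUE))
}

#' Path to the bundled demo BMI percentile cutoffs
#'
#' Demo age/sex cutoff values for testing the classifier; the national
#' reference tables the thresholds come from are not reprinted here.
#' @return file path.
#' @export
demo_bmi_cutoffs_path <- function() {
  system.file("extdata", "bmi_cutoffs_demo.tsv", package = "mitoscreen",
              mustWork = TRUE)
}
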