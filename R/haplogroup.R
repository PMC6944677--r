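#' Read a haplogroup marker database
#'
#' Accepts either a TSV (`haplogroup`, `position`, `ref`, `alt`) or a JSON
#' object mapping haplogroup names to arrays of `{position, ref, alt}`.
#'
#' @param path file path (`.tsv`/`.txt` or `.json`).
#' @return named list of marker data.frames, one per haplogroup.
#' @export
read_marker_db <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    db <- lapply(raw, function(x) {
      data.frame(position = as.integer(x$position),
                 ref = toupper(x$ref), alt = toupper(x$alt),
                 stringsAsFactors = FALSE)
    })
  } else {
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("haplogroup", "position", "ref", "alt")
    if (!all(need %in% names(tab))) {
      stopf("marker DB needs columns: %s", paste(need, collapse = ", "))
    }
    db <- lapply(split(tab, tab$haplogroup), function(x) {
      data.frame(position = as.integer(x$position),
                 ref = toupper(x$ref), alt = toupper(x$alt),
                 stringsAsFactors = FALSE)
    })
  }
  empty <- vapply(db, nrow, integer(1)) == 0L
  if (any(empty) || length(db) == 0L) {
    stopf("marker DB has empty haplogroup entries")
  }
  db
}

#' Path to the bundled demo marker database
#'
#' Illustrative marker sets only (clearly demo, not a phylogenetic
#' reference): a D4 entry built from well-known D4/D/M-lineage positions,
#' plus two partial-overlap entries for ranking tests.
#'
#' @return file path.
#' @export
demo_marker_db_path <- function() {
  system.file("extdata", "haplogroup_markers_demo.tsv",
              package = "mitoscreen", mustWork = TRUE)
}

#' Match a variant set against haplogroup marker sets
#'
#' Flat set concordance, not tree-walking: each haplogroup is scored by
#' the fraction of its defining markers present in the variant set.
#'
#' @param variants variant data.frame (`position`, `ref`, `alt`).
#' @param marker_db output of [read_marker_db()].
#' @return data.frame `haplogroup`, `score`, `markers_present`,
#'   `markers_defined`, ranked by descending score, ties broken
#'   lexicographically by haplogroup name.
#' @export
match_haplogroup <- function(variants, marker_db) {
  if (length(marker_db) == 0L) stopf("empty marker DB")
  keys <- if (nrow(variants)) variant_key(variants) else character()
  rows <- lapply(names(marker_db), function(h) {
    m <- marker_db[[h]]
    mk <- paste0(m$position, ":", m$ref, ">", m$alt)
    present <- sum(mk %in% keys)
    data.frame(haplogroup = h, score = present / nrow(m),
               markers_present = present, markers_defined = nrow(m),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$haplogroup), ]
  rownames(res) <- NULL
  res
}
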