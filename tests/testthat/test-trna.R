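test_that("the bundled 17-species tRNA-Cys alignment parses", {
  aln <- cys_alignment()
  expect_equal(length(aln$species), 17L)
  expect_equal(aln$species[aln$human_row], "Homo sapiens")
  # stem blocks equal width across species (what makes column CI defined)
  st <- aln$structure
  for (k in which(st$blocks$fixed)) {
    expect_equal(length(unique(nchar(aln$blocks[[st$blocks$name[k]]]))), 1L)
  }
})

test_that("malformed alignments are rejected", {
  tab <- read.delim(trna_cys_alignment_path(), comment.char = "#",
                    colClasses = "character")
  tab$t_stem_5p[3] <- ""
  p <- tempfile(fileext = ".tsv")
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_trna_alignment(p), "lack")
  tab2 <- read.delim(trna_cys_alignment_path(), comment.char = "#",
                     colClasses = "character")
  tab2$t_stem_5p <- NULL
  write.table(tab2, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(parse_trna_alignment(p), "missing block")
})

test_that("domain mapping follows canonical cloverleaf numbering", {
  st <- canonical_trna_structure()
  expect_equal(map_position_to_domain(st, 30), "anticodon_stem_5p")
  expect_equal(map_position_to_domain(st, 35), "anticodon_loop")
  expect_equal(map_position_to_domain(st, 73), "discriminator")
  expect_equal(map_position_to_domain(st, 1), "acceptor_stem_5p")
  expect_error(map_position_to_domain(st, 74), "outside")
})

test_that("pair_partner is a content-free involution with canonical pairs", {
  st <- canonical_trna_structure()
  expect_equal(pair_partner(st, 30), 40L)   # the anticodon-stem 30-40 pair
  expect_equal(pair_partner(st, 1), 72L)
  expect_true(is.na(pair_partner(st, 35)))  # loop position
  # anticodon stem pairs (27,43)..(31,39)
  expect_equal(vapply(27:31, function(p) pair_partner(st, p), integer(1)),
               43:39)
  for (p in 1:73) {
    q <- pair_partner(st, p)
    if (!is.na(q)) expect_equal(pair_partner(st, q), p)
  }
})

test_that("genome coordinates map through the gene strand to tRNA positions", {
  aln <- cys_alignment()
  gm <- read_gene_map(human_gene_map_path())
  tc <- gm[gm$gene == "MT-TC", ]
  expect_equal(genome_to_trna_position(5802, tc, aln), 30L)
  expect_equal(genome_to_trna_position(tc$end, tc, aln), 1L)   # L strand
  expect_equal(genome_to_trna_position(tc$start, tc, aln), 73L)
  expect_error(genome_to_trna_position(5900, tc, aln), "not inside")
})

test_that("conservation index matches a brute-force column count", {
  aln <- cys_alignment()
  # oracle: count matches over rows explicitly
  human <- substring(aln$blocks$anticodon_stem_5p[aln$human_row], 4, 4)
  others <- substring(aln$blocks$anticodon_stem_5p[-aln$human_row], 4, 4)
  expect_equal(conservation_index(aln, 30),
               100 * sum(others == human) / length(others))
  expect_equal(conservation_index(aln, 30), 100 * 15 / 16)  # Lemur mismatch
  # a fully conserved column
  expect_equal(conservation_index(aln, 73), 100)
  # denominator option includes the human row
  expect_equal(conservation_index(aln, 30, denominator = "all"),
               100 * 16 / 17)
})

test_that("CI is bounded, permutation-invariant and duplication-invariant", {
  aln <- cys_alignment()
  prof <- conservation_profile(aln)
  expect_true(all(prof$ci[!is.na(prof$ci)] >= 0 &
                    prof$ci[!is.na(prof$ci)] <= 100))
  # CI defined for every stem position
  st <- aln$structure
  stem_pos <- unlist(lapply(which(st$blocks$fixed), function(k) {
    st$blocks$anchor[k] + 0:(st$blocks$slots[k] - 1L)
  }))
  expect_true(all(!is.na(prof$ci[prof$position %in% stem_pos])))

  tab <- read.delim(trna_cys_alignment_path(), comment.char = "#",
                    colClasses = "character")
  p <- tempfile(fileext = ".tsv")
  set.seed(3)
  write.table(tab[sample(nrow(tab)), ], p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(conservation_profile(parse_trna_alignment(p))$ci, prof$ci)
  # duplicating every non-human row leaves the profile unchanged
  dup <- rbind(tab, tab[tab$species != "Homo sapiens", ])
  dup$species <- make.unique(dup$species)
  write.table(dup, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(conservation_profile(parse_trna_alignment(p))$ci, prof$ci)
})

test_that("adding a perfectly matching species never lowers CI", {
  tab <- read.delim(trna_cys_alignment_path(), comment.char = "#",
                    colClasses = "character")
  before <- conservation_profile(cys_alignment())$ci
  clone <- tab[tab$species == "Homo sapiens", ]
  clone$species <- "Homo sapiens clone"
  p <- tempfile(fileext = ".tsv")
  write.table(rbind(tab, clone), p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  after <- conservation_profile(parse_trna_alignment(p))$ci
  ok <- !is.na(before) & !is.na(after)
  expect_true(all(after[ok] >= before[ok]))
})

test_that("a single-species alignment is valid with CI trivially 100", {
  tab <- read.delim(trna_cys_alignment_path(), comment.char = "#",
                    colClasses = "character")
  p <- tempfile(fileext = ".tsv")
  write.table(tab[tab$species == "Homo sapiens", ], p, sep = "\t",
              quote = FALSE, row.names = FALSE)
  solo <- parse_trna_alignment(p)
  prof <- conservation_profile(solo)
  expect_true(all(prof$ci[!is.na(prof$ci)] == 100))
})

test_that("conservation profiles write and re-read as TSV", {
  prof <- conservation_profile(cys_alignment())
  p <- tempfile(fileext = ".tsv")
  write_conservation_profile(prof, p)
  back <- read.delim(p)
  expect_equal(nrow(back), nrow(prof))
  expect_equal(back$ci[back$position == 30], 93.75)
})
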