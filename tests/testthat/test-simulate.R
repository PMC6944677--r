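test_that("generators are bit-identical for a fixed seed", {
  cfg <- sim_config(seed = 21, genome_length = 2000L)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1$sequence, r2$sequence)
  a1 <- generate_alignment(sim_config(seed = 21, alignment_species = 6L))
  a2 <- generate_alignment(sim_config(seed = 21, alignment_species = 6L))
  expect_identical(a1$blocks, a2$blocks)
  expect_false(identical(
    generate_reference(sim_config(seed = 22, genome_length = 2000L))$sequence,
    r1$sequence))
})

test_that("generated references validate and include an L-strand tRNA", {
  ref <- generate_reference(sim_config(seed = 4, genome_length = 16569L))
  expect_equal(ref$length, 16569L)
  expect_s3_class(ref, "mt_reference")
  small <- small_ref(seed = 4)
  f <- small$features
  expect_true(any(f$feature_class == "tRNA" & f$strand == "L"))
  expect_true(all(f$feature_class %in%
                    c("control_region", "rRNA", "tRNA", "protein_coding")))
  # control region wraps the origin: position 1 maps into it
  expect_equal(feature_at(small, 1L)$feature_class, "control_region")
})

test_that("the surrogate reference embeds the printed table constraints", {
  tab <- family_table()
  ref <- surrogate_ref()
  # printed CRS alleles pinned at every position
  for (i in seq_len(nrow(tab))) {
    p <- tab$position[i]
    expect_equal(substring(ref$sequence, p, p + nchar(tab$ref[i]) - 1L),
                 tab$ref[i])
  }
  # insertion context pinned so extraction anchors at the printed position
  expect_false(substring(ref$sequence, 311, 311) == "C")
  # different seeds agree on pinned positions, differ elsewhere
  ref2 <- generate_surrogate_reference(tab, seed = 202L)
  expect_equal(substring(ref2$sequence, 5802, 5802), "T")
  expect_false(identical(ref$sequence, ref2$sequence))
})

test_that("pedigree genomes transmit strictly maternally", {
  cfg <- sim_config(seed = 8, genome_length = 2000L)
  ref <- generate_reference(cfg)
  backbone <- rbind(variant(300, substring(ref$sequence, 300, 300),
                            setdiff(c("A","C","G","T"),
                                    substring(ref$sequence, 300, 300))[1]),
                    variant(800, substring(ref$sequence, 800, 800),
                            setdiff(c("A","C","G","T"),
                                    substring(ref$sequence, 800, 800))[1]))
  candidate <- variant(1200, substring(ref$sequence, 1200, 1200),
                       setdiff(c("A","C","G","T"),
                               substring(ref$sequence, 1200, 1200))[1])
  ped <- pedigree(c("II-1" = "I-2", "II-2" = "I-2", "III-1" = "II-1",
                    "III-2" = "II-1", "III-3" = "II-9"))
  genomes <- generate_pedigree_genomes(ref, ped, backbone, candidate,
                                       carrier_founders = "I-2")
  carriers <- attr(genomes, "carriers")
  expect_setequal(carriers, c("I-2", "II-1", "II-2", "III-1", "III-2"))
  key <- paste0(candidate$position, ":", candidate$ref, ">", candidate$alt)
  for (m in ped$members) {
    ks <- with(extract_variants(genomes[[m]], ref),
               paste0(position, ":", ref, ">", alt))
    expect_equal(key %in% ks, m %in% carriers)
  }
  # siblings of one mother share identical mtDNA (homoplasmic model)
  expect_identical(genomes[["III-1"]], genomes[["III-2"]])
  # the other matriline never carries the candidate
  expect_false("III-3" %in% carriers)
})

test_that("carrier status propagates down maternal links in random pedigrees", {
  cfg <- sim_config(seed = 1, genome_length = 600L)
  ref <- generate_reference(cfg)
  backbone <- variant(100, substring(ref$sequence, 100, 100),
                      setdiff(c("A","C","G","T"),
                              substring(ref$sequence, 100, 100))[1])
  candidate <- variant(400, substring(ref$sequence, 400, 400),
                       setdiff(c("A","C","G","T"),
                               substring(ref$sequence, 400, 400))[1])
  for (seed in 1:100) {
    ped <- generate_pedigree(seed = seed, n_members = 6L)
    founders <- setdiff(ped$members, names(ped$mother_of))
    genomes <- generate_pedigree_genomes(ref, ped, backbone, candidate,
                                         carrier_founders = founders[1])
    carriers <- attr(genomes, "carriers")
    for (kid in names(ped$mother_of)) {
      mom <- ped$mother_of[[kid]]
      if (kid %in% carriers) expect_true(mom %in% carriers)
      if (!mom %in% carriers) expect_false(kid %in% carriers)
    }
  }
})

test_that("control cohorts honour the configured carrier frequency", {
  ref <- generate_reference(sim_config(seed = 2, genome_length = 600L))
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  backbone <- variant(100, substring(ref$sequence, 100, 100),
                      other(substring(ref$sequence, 100, 100)))
  candidate <- variant(400, substring(ref$sequence, 400, 400),
                       other(substring(ref$sequence, 400, 400)))
  # frequency 0: exactly zero carriers
  ctl0 <- generate_controls(sim_config(seed = 2, n_controls = 106L,
                                       control_carrier_freq = 0,
                                       genome_length = 600L),
                            ref, backbone, candidate)
  expect_length(ctl0, 106L)
  expect_equal(sum(attr(ctl0, "carrier")), 0L)
  expect_equal(control_frequency(sum(attr(ctl0, "carrier")), 106), 0)
  # n=1, freq=1: the single control carries it
  ctl1 <- generate_controls(sim_config(seed = 2, n_controls = 1L,
                                       control_carrier_freq = 1,
                                       genome_length = 600L),
                            ref, backbone, candidate)
  expect_equal(sum(attr(ctl1, "carrier")), 1L)
  # binomial regime: carrier fraction within 3 SE of the target
  cfg <- sim_config(seed = 6, n_controls = 1000L,
                    control_carrier_freq = 0.05, genome_length = 600L)
  ctl <- generate_controls(cfg, ref, backbone, candidate)
  frac <- mean(attr(ctl, "carrier"))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(frac - 0.05), 3 * se)
  # the flagged genomes really contain the candidate allele
  hit <- which(attr(ctl, "carrier"))[1]
  expect_equal(substring(ctl[[hit]], 400, 400), candidate$alt)
})

test_that("generated alignments recover their match probability", {
  # match_prob 1 -> every defined CI is 100
  a1 <- generate_alignment(sim_config(seed = 5, alignment_species = 17L,
                                      per_column_match_prob = 1))
  expect_length(a1$species, 17L)
  p1 <- conservation_profile(a1)$ci
  expect_true(all(p1[!is.na(p1)] == 100))
  # mean CI within 3 binomial SE of 100p, averaged over defined columns
  for (p in c(0.5, 0.75, 0.9)) {
    aln <- generate_alignment(sim_config(seed = 40 + round(100 * p),
                                         alignment_species = 17L,
                                         per_column_match_prob = p))
    ci <- conservation_profile(aln)$ci
    ci <- ci[!is.na(ci)]
    se <- 100 * sqrt(p * (1 - p) / (16 * length(ci)))
    expect_lt(abs(mean(ci) - 100 * p), 3 * se)
  }
})

test_that("generated alignments pass the parser round-trip", {
  aln <- generate_alignment(sim_config(seed = 13, alignment_species = 8L))
  p <- tempfile(fileext = ".tsv")
  tab <- cbind(species = aln$species, aln$blocks)
  write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- parse_trna_alignment(p)
  expect_equal(back$blocks, aln$blocks, ignore_attr = TRUE)
})
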