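test_that("control frequency is an exact percentage with strict thresholds", {
  expect_equal(control_frequency(0, 106), 0)
  expect_equal(control_frequency(106, 106), 100)
  expect_equal(control_frequency(3, 300), 1)   # 1.0% fails a strict <1% test
  expect_false(control_frequency(3, 300) < 1)
  expect_error(control_frequency(0, 0), "positive")
  expect_error(control_frequency(5, 3), "carriers")
})

test_that("fisher_exact matches exhaustive enumeration on small tables", {
  expect_equal(fisher_exact(0, 106, 0, 106), 1)
  # oracle: direct enumeration over all tables with the observed margins
  enum_p <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    xs <- max(0, c1 - r2):min(r1, c1)
    pr <- vapply(xs, function(x) {
      choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
    }, numeric(1))
    sum(pr[pr <= pr[xs == a] * (1 + 1e-7)])
  }
  expect_equal(fisher_exact(1, 9, 9, 1), enum_p(1, 9, 9, 1))
  expect_equal(fisher_exact(0, 10, 10, 0), enum_p(0, 10, 10, 0))
  # the (0,10;10,0) table attains the smallest p for those margins
  ps <- vapply(0:10, function(a) fisher_exact(a, 10 - a, 10 - a, a),
               numeric(1))
  expect_equal(which.min(ps), 1L)
  expect_error(fisher_exact(0, 0, 0, 0), "all-zero")
  expect_error(fisher_exact(-1, 2, 3, 4), "non-negative")
})

test_that("fisher_exact agrees with the reference implementation for margins <= 12", {
  worst <- 0
  for (r1 in 0:12) for (r2 in 0:12) {
    if (r1 + r2 == 0) next
    for (a in 0:r1) for (c in 0:r2) {
      b <- r1 - a; d <- r2 - c
      mine <- fisher_exact(a, b, c, d)
      ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value
      worst <- max(worst, abs(mine - ft))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("the structural criterion flags stems and the anticodon loop", {
  st <- canonical_trna_structure()
  aln <- cys_alignment()
  ref <- surrogate_ref()
  v5802 <- annotate_variant(variant(5802, "T", "C"), ref)
  expect_true(structural_flag(v5802, st, trna_position = 30))   # paired 30-40
  expect_true(structural_flag(v5802, st, trna_position = 35))   # anticodon loop
  expect_false(structural_flag(v5802, st, trna_position = 45))  # variable region
  feat <- feature_at(ref, 5802)
  expect_true(structural_flag(v5802, st, alignment = aln, feature = feat))
  vdloop <- annotate_variant(variant(73, "A", "G"), ref)
  expect_true(is.na(structural_flag(vdloop, st)))               # absent
})

test_that("the three-criterion verdict behaves and is monotone", {
  ref <- surrogate_ref()
  v <- annotate_variant(variant(5802, "T", "C"), ref)
  ok <- classify_pathogenicity(v, 0, 106, ci_value = 93.75, structural = TRUE)
  expect_equal(ok$verdict, "candidate")
  expect_equal(classify_pathogenicity(v, 0, 106, 50, TRUE)$verdict,
               "not_candidate")                     # conservation fails
  expect_equal(classify_pathogenicity(v, 3, 150, 93.75, TRUE)$verdict,
               "not_candidate")                     # 2% control frequency
  expect_equal(classify_pathogenicity(v, 0, 106, NA, NA)$verdict,
               "indeterminate")                     # inputs absent
  expect_equal(classify_pathogenicity(v, 3, 150, NA, NA)$verdict,
               "not_candidate")  # a failing present criterion dominates
  # monotone: worsening one criterion never rescues a verdict
  grid <- expand.grid(carriers = c(0, 5), ci = c(93.75, 50),
                      str = c(TRUE, FALSE))
  verdicts <- apply(grid, 1, function(r) {
    classify_pathogenicity(v, r[["carriers"]], 106, r[["ci"]],
                           as.logical(r[["str"]]))$verdict
  })
  expect_equal(sum(verdicts == "candidate"), 1L)
  expect_equal(verdicts[1], "candidate")
  # thresholds are strict inequalities
  expect_equal(classify_pathogenicity(v, 0, 106, 75, TRUE)$verdict,
               "not_candidate")
  expect_equal(classify_pathogenicity(v, 1, 100, 93.75, TRUE)$verdict,
               "not_candidate")
})

test_that("screening the family variants yields exactly one candidate", {
  ref <- surrogate_ref()
  tab <- family_table()
  ann <- annotate_variants(tab, ref)
  backbone <- tab[tab$previously_reported == "Yes", ]
  controls <- generate_controls(sim_config(seed = 3), ref, backbone,
                                tab[tab$previously_reported == "No", ])
  sets <- lapply(controls, extract_variants, reference = ref)
  rep <- screen_variants(ann, sets, ref, cys_alignment())
  expect_equal(nrow(rep), 47L)
  expect_equal(rep$notation[rep$verdict == "candidate"], "m.5802A>G")
  expect_equal(rep$control_freq[rep$position == 5802], 0)
  expect_equal(rep$ci_value[rep$position == 5802], 93.75)
})
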