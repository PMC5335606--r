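test_that("pair TMRCA matches the haploid coalescent expectation", {
  d <- one_deme_design(n = 2)
  sch <- build_schedule("continuity", neutral_params(N = 1000), d)
  set.seed(101)
  tm <- replicate(10000, tmrca(simulate_genealogy(sch, d)))
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1000), 3 * se)
  # TMRCA of a pair is exponential(1/N); two-sided KS against closed form
  ks <- suppressWarnings(stats::ks.test(tm[1:2000], stats::pexp,
                                        rate = 1 / 1000))
  expect_gt(ks$p.value, 0.01)
})

test_that("serial sampling bounds the TMRCA from below", {
  d <- study_design(populations = data.frame(
    label = c("A", "B"), n = c(1, 1), age_yBP = c(0, 9990),
    deme = "sardinia"), locus_length = 100)
  sch <- build_schedule("continuity", neutral_params(), d)
  set.seed(202)
  tm <- replicate(1000, tmrca(simulate_genealogy(sch, d)))
  expect_true(all(tm >= 333))  # 9990 / 30 = 333 generations
})

test_that("replacement forbids recent Sardinian MS/MSS coalescences", {
  d <- study_design()
  pr <- default_priors()
  set.seed(303)
  bad <- 0
  for (r in 1:1000) {
    th <- draw_parameters(pr, "discontinuity")
    tree <- simulate_genealogy(build_schedule("discontinuity", th, d), d)
    rec <- coalescence_records(tree)
    bad <- bad + sum(rec$has_MS & rec$has_MSS & rec$time < 200)
  }
  expect_identical(bad, 0)
})

test_that("segregating sites match Watterson's expectation", {
  d <- one_deme_design(n = 10, L = 16569)
  th <- neutral_params(N = 1000, mut = 2e-8)
  sch <- build_schedule("continuity", th, d)
  set.seed(404)
  S <- replicate(5000, {
    aln <- drop_mutations(simulate_genealogy(sch, d), th$mut, d)
    segregating_sites(aln, "A")
  })
  expected <- 2 * 1000 * th$mut * 30 * 16569 * sum(1 / 1:9)
  se <- sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expected), 3 * se)
})

test_that("pairwise differences match 2 N mu g L for a pair", {
  d <- one_deme_design(n = 2, L = 16569)
  th <- neutral_params(N = 1000, mut = 2e-8)
  sch <- build_schedule("continuity", th, d)
  set.seed(505)
  pi2 <- replicate(5000, {
    aln <- drop_mutations(simulate_genealogy(sch, d), th$mut, d)
    nucleotide_diversity(aln, "A")
  })
  expected <- 2 * 1000 * (2e-8 * 30) * 16569  # ~19.9
  se <- sd(pi2) / sqrt(length(pi2))
  expect_lt(abs(mean(pi2) - expected), 3 * se)
})

test_that("mutation edge cases behave", {
  d <- one_deme_design(n = 5, L = 50)
  sch <- build_schedule("continuity", neutral_params(), d)
  tree <- simulate_genealogy(sch, d, seed = 606)
  aln0 <- drop_mutations(tree, 0, d, seed = 607)
  expect_identical(ncol(aln0$seq), 0L)
  expect_identical(segregating_sites(aln0, "A"), 0L)
  aln <- drop_mutations(tree, 1e-4, d, seed = 608)  # high rate, tiny locus
  expect_true(all(aln$sites >= 1 & aln$sites <= 50))
  expect_true(all(aln$seq %in% c(0L, 1L)))
})

test_that("reference tables are deterministic and respect the priors", {
  pr <- default_priors()
  d <- study_design()
  f1 <- tempfile(); f2 <- tempfile()
  t1 <- build_reference_table("continuity", pr, d, n_sims = 10, seed = 9,
                              path = f1)
  t2 <- build_reference_table("continuity", pr, d, n_sims = 10, seed = 9,
                              path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(all(t1$P == 0))
  b <- prior_bounds(pr, "continuity")
  for (pn in rownames(b))
    expect_true(all(t1[[pn]] >= b[pn, 1] & t1[[pn]] <= b[pn, 2]))
  expect_false(anyNA(t1))
  # first rows of a longer table replicate the shorter one (per-row seeding)
  t3 <- build_reference_table("continuity", pr, d, n_sims = 12, seed = 9)
  expect_equal(t3[1:10, ], t1, ignore_attr = TRUE)
  unlink(c(f1, f2))
})
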