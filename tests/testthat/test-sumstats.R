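fx <- make_worked_fixture()

test_that("worked fixtures reproduce the hand-computed statistics", {
  a1 <- fx$alignments$aln1
  expect_identical(segregating_sites(a1, "A"), 2L)
  hs <- haplotype_stats(a1, "A")
  expect_identical(hs$H, 3L)
  expect_equal(hs$hapdiv, 1)          # 1.5 * (1 - 3/9)
  expect_equal(nucleotide_diversity(a1, "A"), 4 / 3)  # (1+2+1)/3

  a2 <- fx$alignments$aln2            # patterns {A,A,B,B}
  hs2 <- haplotype_stats(a2, "A")
  expect_identical(hs2$H, 2L)
  expect_equal(hs2$hapdiv, 2 / 3)     # (4/3)(1 - 0.5)

  a3 <- fx$alignments$aln3            # two fixed populations, 10 sites
  expect_equal(pairwise_divergence(a3, "A", "B"), 10)
  expect_equal(hudson_fst(a3, "A", "B"), 1)
})

test_that("degenerate inputs follow the stated conventions", {
  a1 <- fx$alignments$aln1
  single <- haplotype_alignment(matrix(0L, 1, 2), sites = 1:2, L = 10,
                                meta = data.frame(sample_id = "x",
                                                  population = "A",
                                                  age_yBP = 0))
  expect_identical(segregating_sites(single, "A"), 0L)
  expect_error(haplotype_stats(single, "A"), "n = 1")
  expect_error(tajimas_d(a1, "A"), "n >= 4")
  expect_error(segregating_sites(a1, "Z"), "unknown population")
  # populations carrying one identical haplotype: d_xy = 0, FST = 0
  meta4 <- data.frame(sample_id = paste0("s", 1:4),
                      population = rep(c("A", "B"), 2), age_yBP = 0)
  same <- haplotype_alignment(matrix(1L, 4, 2), sites = 1:2, L = 10,
                              meta = meta4)
  expect_identical(hudson_fst(same, "A", "B"), 0)
  # d_xy = 0 is not an error even with no variable site at all
  mono <- haplotype_alignment(matrix(0L, 4, 0), sites = integer(0), L = 10,
                              meta = meta4)
  expect_identical(hudson_fst(mono, "A", "B"), 0)
})

test_that("Tajima's D matches a hand evaluation and the sign convention", {
  # 4 sequences, S = 3 segregating sites
  m <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  a <- haplotype_alignment(m, sites = 1:3, L = 100,
                           meta = data.frame(sample_id = paste0("s", 1:4),
                                             population = "A", age_yBP = 0))
  pi_hand <- (1 + 2 + 3 + 1 + 2 + 1) / 6
  expect_equal(tajimas_d(a, "A"), tajima_oracle(4, 3, pi_hand))
  a0 <- haplotype_alignment(matrix(0L, 4, 0), sites = integer(0), L = 100,
                            meta = a$meta)
  expect_identical(tajimas_d(a0, "A"), 0)
})

test_that("simulated Tajima's D agrees with the independent oracle", {
  d <- one_deme_design(n = 10, L = 16569)
  th <- neutral_params(N = 1000, mut = 2e-8)
  sch <- build_schedule("continuity", th, d)
  set.seed(77)
  for (r in 1:200) {
    aln <- drop_mutations(simulate_genealogy(sch, d), th$mut, d)
    S <- segregating_sites(aln, "A")
    pi <- if (ncol(aln$seq)) nucleotide_diversity(aln, "A") else 0
    expect_equal(tajimas_d(aln, "A"), tajima_oracle(10, S, pi))
  }
})

test_that("the panel is complete, ordered, and invariant", {
  d <- study_design()
  pr <- default_priors()
  set.seed(88)
  th <- draw_parameters(pr, "admixture")
  aln <- drop_mutations(simulate_genealogy(
    build_schedule("admixture", th, d), d), th$mut, d)
  pan <- compute_panel(aln, d)
  expect_identical(length(pan), 31L)
  expect_identical(names(pan), panel_names(d))
  expect_true(all(is.finite(pan)))
  # sample reordering changes nothing
  perm <- sample(nrow(aln$seq))
  aln2 <- haplotype_alignment(aln$seq[perm, ], sites = aln$sites,
                              L = aln$L, meta = aln$meta[perm, ])
  expect_equal(compute_panel(aln2, d), pan)
  # allele relabeling (0/1 toggle at random sites) changes nothing
  aln3 <- aln
  flip <- sample(ncol(aln3$seq), ncol(aln3$seq) %/% 2)
  aln3$seq[, flip] <- 1L - aln3$seq[, flip]
  expect_equal(compute_panel(aln3, d), pan)
  # range invariants
  pops <- c("MS", "MSS", "EN", "MN")
  expect_true(all(pan[paste0("pi_", pops)] <= aln$L))
  expect_true(all(pan[paste0("hapdiv_", pops)] >= 0 &
                    pan[paste0("hapdiv_", pops)] <= 1))
  expect_true(all(pan[paste0("H_", pops)] <=
                    d$populations$n[match(pops, d$populations$label)]))
  # a zero-rate simulation zeroes the panel
  aln0 <- drop_mutations(simulate_genealogy(
    build_schedule("admixture", th, d), d, seed = 1), 0, d, seed = 2)
  pan0 <- compute_panel(aln0, d)
  expect_true(all(pan0[grep("^(S|pi|D|fst|dxy|hapdiv)", names(pan0))] == 0))
  expect_true(all(pan0[paste0("H_", pops)] == 1))
  # size mismatch is named
  expect_error(compute_panel(aln, study_design(populations = data.frame(
    label = c("MS", "MSS", "EN", "MN"), n = c(63, 2, 28, 17),
    age_yBP = c(0, 10000, 8700, 7700),
    deme = c("sardinia", "sardinia", "continent", "continent")))), "MN")
})

test_that("the panel survives a FASTA round-trip exactly", {
  d <- study_design()
  pr <- default_priors()
  set.seed(99)
  th <- draw_parameters(pr, "discontinuity")
  aln <- drop_mutations(simulate_genealogy(
    build_schedule("discontinuity", th, d), d), th$mut, d)
  pan <- compute_panel(aln, d)
  fa <- tempfile(fileext = ".fasta"); tsv <- tempfile(fileext = ".tsv")
  write_study_alignment(aln, fa, tsv, seed = 4)
  aln2 <- read_study_alignment(fa, tsv)
  expect_identical(compute_panel(aln2, d), pan)
  unlink(c(fa, tsv))
})

test_that("PLS recovers a planted signal and reproduces its scores", {
  set.seed(123)
  n <- 300
  param <- runif(n)
  stats <- cbind(sig = 3 * param,
                 matrix(rnorm(n * 9), n, 9,
                        dimnames = list(NULL, paste0("noise", 1:9))))
  tr <- fit_pls(stats, cbind(param), k = 1)
  sc <- apply_pls(tr, stats)
  expect_gte(abs(cor(sc[, 1], stats[, "sig"])), 0.95)
  expect_identical(apply_pls(tr, stats), sc)
  expect_lt(max(abs(colMeans(tr$scores))), 1e-8)
  expect_equal(unname(sc), unname(tr$scores), tolerance = 1e-8)
  expect_error(fit_pls(stats[1:20, ], cbind(param[1:20]), k = 3),
               "10 x k")
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(321)
  n <- 200
  Y <- matrix(runif(n * 2), n, 2)
  X <- cbind(Y %*% matrix(c(1, 2, -1, 0.5, 3, -2), 2, 3),
             matrix(rnorm(n * 4), n, 4))
  colnames(X) <- paste0("x", 1:7)
  ours <- fit_pls(X, Y, k = 2)
  ref <- mixOmics::pls(X, Y, ncomp = 2, scale = TRUE, mode = "regression")
  for (h in 1:2)
    expect_gt(abs(cor(ours$scores[, h], ref$variates$X[, h])), 0.999)
})
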