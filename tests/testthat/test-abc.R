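test_that("standardized distances match hand arithmetic and brute force", {
  tab <- toy_table("admixture_tot", 5, mu = c(0, 0, 0), seed = 10)
  tab[, c("s1", "s2", "s3")] <- rbind(c(1, 2, 3), c(2, 2, 3), c(3, 4, 1),
                                      c(1, 0, 3), c(5, 2, 2))
  obs <- c(s1 = 1, s2 = 2, s3 = 3)
  rk <- standardize_and_rank(tab, obs)
  sds <- apply(tab[, c("s1", "s2", "s3")], 2, sd)
  hand <- sqrt(colSums(((t(tab[, c("s1", "s2", "s3")]) - obs) / sds)^2))
  expect_equal(unname(rk$distances), unname(hand))
  expect_identical(rk$order[1], 1L)       # obs equals row 1 -> rank 1
  expect_equal(rk$distances[1], 0)
  # rescaling a statistic (and obs) is absorbed by the standardization
  tab2 <- tab; tab2$s2 <- tab2$s2 * 10
  rk2 <- standardize_and_rank(tab2, c(s1 = 1, s2 = 20, s3 = 3))
  expect_identical(rk2$order, rk$order)
  expect_equal(rk2$distances, rk$distances)
})

test_that("rejection retains exactly the brute-force nearest neighbours", {
  set.seed(20)
  tab <- toy_table("admixture_tot", 100, mu = c(1, -1, 0), seed = 21)
  obs <- c(s1 = 0.5, s2 = -0.2, s3 = 0.1)
  rk <- standardize_and_rank(tab, obs)
  S <- as.matrix(tab[, c("s1", "s2", "s3")])
  Z <- sweep(S, 2, apply(S, 2, sd), "/")
  zo <- obs / apply(S, 2, sd)
  brute <- order(sqrt(rowSums(sweep(Z, 2, zo)^2)))
  n_keep <- 20
  expect_setequal(rk$order[1:n_keep], brute[1:n_keep])
})

test_that("logtan is a monotone bijection onto the reals", {
  expect_equal(logtan(0.5, 0, 1), 0)            # tan(pi/4) = 1
  expect_equal(logtan(150, 100, 200), 0)
  x <- seq(0.0005, 0.9995, length.out = 1000)
  expect_lt(max(abs(inv_logtan(logtan(x, 0, 1), 0, 1) - x)), 1e-10)
  expect_true(all(diff(logtan(x, 0, 1)) > 0))
  expect_error(logtan(1.5, 0, 1), "outside")
  # bound clamping keeps the transform finite
  expect_true(is.finite(logtan(0, 0, 1)))
  expect_true(all(inv_logtan(c(-30, 30), 2, 3) > 2 &
                    inv_logtan(c(-30, 30), 2, 3) < 3))
})

test_that("model choice separates separable models and not symmetric ones", {
  tabA <- toy_table("continuity", 400, mu = c(0, 0, 0), seed = 31)
  tabB <- toy_table("discontinuity", 400, mu = c(10, 10, 10), seed = 32)
  obs <- c(s1 = 0.1, s2 = -0.1, s3 = 0)
  # the far model vanishes from the retained set (warned, probability 0)
  expect_warning(model_posteriors(list(tabA, tabB), obs, n_retain = 50),
                 "absent")
  mc <- suppressWarnings(
    model_posteriors(list(tabA, tabB), obs, thresholds = c(50, 200)))
  expect_equal(rowSums(mc$probabilities), c(1, 1), tolerance = 1e-9)
  expect_gt(mc$posterior["continuity"], 0.99)
  # two models with identical stat distributions: posterior near 1/2
  ps <- replicate(20, {
    s <- sample.int(1e6, 1)
    t1 <- toy_table("continuity", 300, seed = s)
    t2 <- toy_table("discontinuity", 300, seed = s + 5e6)
    model_posteriors(list(t1, t2), obs, n_retain = 150)$posterior[1]
  })
  expect_lt(abs(mean(ps) - 0.5), 0.05)
})

test_that("model-choice probabilities are invariant to duplicating rows", {
  tabA <- toy_table("continuity", 200, mu = c(0, 0, 0), seed = 41)
  tabB <- toy_table("discontinuity", 200, mu = c(2, 0, -1), seed = 42)
  obs <- c(s1 = 0.5, s2 = 0.5, s3 = 0.5)
  p1 <- model_posteriors(list(tabA, tabB), obs, n_retain = 100)$posterior
  dup <- function(t) { d <- rbind(t, t); class(d) <- class(t); d }
  p2 <- model_posteriors(list(dup(tabA), dup(tabB)), obs,
                         n_retain = 200)$posterior
  expect_equal(p1, p2, tolerance = 0.02)
})

test_that("regression adjustment collapses on a noiseless linear map", {
  set.seed(50)
  n <- 10000
  truth <- 0.63
  tab <- toy_table("admixture_tot", n, seed = 51)
  # stats are exact linear functions of P; other params pure nuisance
  tab$s1 <- 2 * tab$P; tab$s2 <- -tab$P; tab$s3 <- 0.5 * tab$P
  obs <- c(s1 = 2 * truth, s2 = -truth, s3 = 0.5 * truth)
  est <- estimate_parameters(tab, obs, toy_priors(), n_retain = 400,
                             k = 1, pls_train = 2000)
  s <- est$summary[est$summary$parameter == "P", ]
  expect_lt(abs(s$median - truth), 0.01)
  expect_lt(s$hpd_high - s$hpd_low, 0.01)   # < 1% of the prior range
  expect_gt(s$r_squared, 0.999)
  # every adjusted draw stays inside the prior support
  expect_true(all(est$samples >= 0 & est$samples <= 1))
})

test_that("adjustment leaves an uninformative parameter alone", {
  obs <- c(s1 = 0, s2 = 0, s3 = 0)
  diffs <- replicate(20, {
    s <- sample.int(1e6, 1)
    tab <- toy_table("admixture_tot", 600, seed = s)  # stats ~ N, indep of P
    est <- estimate_parameters(tab, obs, toy_priors(), n_retain = 200,
                               k = 2, pls_train = 600)
    rk <- standardize_and_rank(tab, obs)
    sel <- rk$order[1:200]
    w <- 1 - (rk$distances[sel] / max(rk$distances[sel]))^2
    rej_mean <- sum(w * tab$P[sel]) / sum(w)
    adj_mean <- sum(est$weights * est$samples[, "P"]) / sum(est$weights)
    adj_mean - rej_mean
  })
  expect_lt(mean(abs(diffs)), 0.05 * sqrt(1 / 12))  # 0.05 prior SD
})

test_that("posterior summaries are ordered and inside the prior", {
  set.seed(61)
  tab <- toy_table("admixture_tot", 800, seed = 62)
  tab$s1 <- tab$P + rnorm(800, 0, 0.2)
  obs <- c(s1 = 0.7, s2 = 0, s3 = 0)
  est <- estimate_parameters(tab, obs, toy_priors(), n_retain = 300, k = 2,
                             pls_train = 800)
  s <- est$summary
  free <- s$parameter != "P" | TRUE
  expect_true(all(s$hpd_low <= s$median & s$median <= s$hpd_high))
  expect_true(all(s$r_squared >= 0 & s$r_squared <= 1, na.rm = TRUE))
  b <- prior_bounds(toy_priors(), "admixture_tot")
  expect_true(all(s$median >= b[s$parameter, 1] &
                    s$median <= b[s$parameter, 2]))
})

test_that("the posterior-predictive p-value ranks densities correctly", {
  set.seed(70)
  ret <- matrix(rnorm(500 * 4), 500, 4)
  expect_gte(glm_ppp_value(ret, colMeans(ret)), 0.95)
  expect_lte(glm_ppp_value(ret, rep(10, 4)), 0.01)
  p <- replicate(20, glm_ppp_value(ret, rnorm(4, 0, 2)))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("the PCA fit check localizes the observed point", {
  tabA <- toy_table("continuity", 500, mu = c(0, 0, 0), seed = 81)
  tabB <- toy_table("discontinuity", 500, mu = c(0, 0, 0), seed = 81)
  obs <- c(s1 = 0.2, s2 = -0.3, s3 = 0.4)
  rep1 <- pca_fit_check(list(tabA, tabB), obs, n_best = 300)
  # identical tables -> identical percentiles
  expect_equal(rep1$percentile[1], rep1$percentile[2])
  # an observation drawn from the model's own cloud sits inside it
  set.seed(82)
  inside <- replicate(100, {
    o <- c(s1 = rnorm(1), s2 = rnorm(1), s3 = rnorm(1))
    pca_fit_check(list(tabA), o, n_best = 300)$percentile < 0.99
  })
  expect_gte(mean(inside), 0.95)
})
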