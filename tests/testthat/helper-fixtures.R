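# shared fixtures built in code

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-deme design for coalescent-theory checks
one_deme_design <- function(n = 2, age = 0, L = 100) {
  study_design(populations = data.frame(label = "A", n = n, age_yBP = age,
                                        deme = "sardinia"),
               locus_length = L)
}

neutral_params <- function(N = 1000, mut = 2e-8) {
  param_draw(P = 0, rs = 1, Nan = N, Nas = N, Ncn = N, Ncs = N,
             mut = mut, Tcol = 12000)
}

# synthetic gaussian "reference table": stats s1..s3 ~ N(mu, 1), params
# drawn from U(0,1) priors; no coalescent involved
toy_table <- function(model, n, mu = c(0, 0, 0), sd = 1, seed = 1,
                      param_gen = NULL) {
  set.seed(seed)
  pars <- matrix(runif(n * 8), n, 8,
                 dimnames = list(NULL, c("P", "rs", "Nan", "Nas", "Ncn",
                                         "Ncs", "mut", "Tcol")))
  if (!is.null(param_gen)) pars <- param_gen(n)
  stats <- sapply(seq_along(mu), function(j) stats::rnorm(n, mu[j], sd))
  colnames(stats) <- paste0("s", seq_along(mu))
  tab <- data.frame(model = model, pars, stats)
  class(tab) <- c("reference_table", "data.frame")
  tab
}

# uniform(0,1) priors on every parameter, matching toy_table
toy_priors <- function() {
  default_priors(
    rs = list(dist = "uniform", lower = 0, upper = 1),
    Nan = list(dist = "uniform", lower = 0, upper = 1),
    Nas = list(dist = "uniform", lower = 0, upper = 1),
    Ncn = list(dist = "uniform", lower = 0, upper = 1),
    Ncs = list(dist = "uniform", lower = 0, upper = 1),
    mut = list(dist = "uniform", lower = 1e-12, upper = 1),
    Tcol = list(dist = "uniform", lower = 0, upper = 1),
    P = list(admixture_tot = list(dist = "uniform", lower = 0, upper = 1)))
}

# population composition of every coalescence: for each internal node,
# the set of leaf populations below it and its time (slow R oracle)
coalescence_records <- function(tree) {
  nn <- length(tree$parent)
  pops <- vector("list", nn)
  for (i in seq_len(tree$n_leaves)) pops[[i]] <- tree$leaf_meta$population[i]
  ord <- order(tree$time)
  for (i in ord) {
    p <- tree$parent[i]
    if (!is.na(p)) pops[[p]] <- c(pops[[p]], pops[[i]])
  }
  internal <- (tree$n_leaves + 1):nn
  data.frame(time = tree$time[internal],
             has_MS = vapply(pops[internal], function(x) "MS" %in% x,
                             logical(1)),
             has_MSS = vapply(pops[internal], function(x) "MSS" %in% x,
                              logical(1)))
}

# independent textbook implementation of Tajima's D (oracle)
tajima_oracle <- function(n, S, pi) {
  if (S == 0) return(0)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}
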