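#' Generate pseudo-observed datasets (pods)
#'
#' Each pod is a complete simulate-then-summarize run with parameters
#' drawn from the priors; the true parameters are stored alongside the
#' summary statistics so model choice and estimation can be scored against
#' the truth. Pod i uses the derived seed `(seed + i) mod (2^31 - 1)`.
#'
#' @param model generating model label.
#' @param priors a [default_priors()] prior set.
#' @param design a [study_design()].
#' @param n_pods number of pods.
#' @param seed master integer seed.
#' @return List with `params` (n_pods x 8 data.frame of true values) and
#'   `stats` (n_pods x panel matrix).
#' @export
generate_pods <- function(model, priors = default_priors(),
                          design = study_design(), n_pods, seed = 1L) {
  check_model(model)
  stopifnot(n_pods >= 1)
  design <- cache_design(design)
  nms <- panel_names(design)
  stats <- matrix(NA_real_, n_pods, length(nms),
                  dimnames = list(NULL, nms))
  pars <- matrix(NA_real_, n_pods, 8L,
                 dimnames = list(NULL, param_names()))
  for (i in seq_len(n_pods)) {
    set.seed(derive_seed(seed, i))
    th <- draw_parameters(priors, model)
    aln <- drop_mutations(
      simulate_genealogy(build_schedule(model, th, design), design),
      th$mut, design)
    stats[i, ] <- compute_panel(aln, design)
    pars[i, ] <- unlist(th)
  }
  list(model = model, params = as.data.frame(pars), stats = stats)
}

#' Power study of ABC model choice on pseudo-observed data
#'
#' Runs model choice on every pod and scores the selections against the
#' generating models: the confusion matrix, per-model true-positive rate
#' (fraction of a model's own pods for which it gets the highest posterior
#' probability) and false-positive rate (fraction of the pods generated
#' under the *other* models for which it is nevertheless selected).
#' Ties are broken toward the first model in table order (logged).
#'
#' @param pods_by_model list of [generate_pods()] results.
#' @param tables named list of `reference_table`s, one per candidate model.
#' @param n_retain retention threshold for each model-choice run.
#' @param choose_fun optional override returning a named probability
#'   vector for one pod, `function(obs)`; used for harness checks.
#' @return An object of class `validation_report`: `confusion` (generating
#'   x selected counts), `tpr`, `fpr`, `n_pods`, `n_retain`.
#' @export
model_choice_power <- function(pods_by_model, tables, n_retain = 2000,
                               choose_fun = NULL) {
  models <- vapply(tables, function(t) t$model[1], character(1))
  names(tables) <- models
  gen_models <- vapply(pods_by_model, `[[`, character(1), "model")
  if (any(vapply(pods_by_model, function(p) nrow(p$stats) == 0,
                 logical(1))))
    stop("every generating model needs at least one pod")
  if (is.null(choose_fun)) {
    prep <- prep_reference(tables)
    choose_fun <- function(obs)
      model_posteriors(tables, obs, n_retain = n_retain,
                       .prep = prep)$posterior
  }

  confusion <- matrix(0L, length(gen_models), length(models),
                      dimnames = list(generating = gen_models,
                                      selected = models))
  for (g in seq_along(pods_by_model)) {
    pods <- pods_by_model[[g]]
    for (i in seq_len(nrow(pods$stats))) {
      p <- choose_fun(pods$stats[i, ])
      p <- p[models]
      selected <- models[which.max(p)]  # which.max: first (smallest index)
      confusion[g, selected] <- confusion[g, selected] + 1L
    }
  }
  n_pods <- rowSums(confusion)
  tpr <- setNames(rep(NA_real_, length(models)), models)
  fpr <- setNames(rep(NA_real_, length(models)), models)
  for (m in models) {
    if (m %in% gen_models) tpr[m] <- confusion[m, m] / n_pods[m]
    others <- setdiff(gen_models, m)
    if (length(others) > 0)
      fpr[m] <- sum(confusion[others, m]) / sum(n_pods[others])
  }
  stopifnot(all(rowSums(confusion) == n_pods))
  structure(list(confusion = confusion, tpr = tpr, fpr = fpr,
                 n_pods = n_pods, n_retain = n_retain),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Model-choice power study (", sum(x$n_pods), " pods, ",
      x$n_retain, " retained)\n", sep = "")
  print(x$confusion)
  cat("TPR:", paste(names(x$tpr), round(x$tpr, 3), collapse = "  "), "\n")
  cat("FPR:", paste(names(x$fpr), round(x$fpr, 3), collapse = "  "), "\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Estimates the parameters for every pod and scores the posterior medians
#' and 95% HPD intervals against the stored truth.
#'
#' @param pods a [generate_pods()] result (its model must match `table`).
#' @param table `reference_table` under the same model.
#' @param priors the prior set used throughout.
#' @param n_retain retained simulations per estimation.
#' @param pls optional pre-fitted [fit_pls()] transform (fitted once here
#'   when `NULL`, then reused across pods).
#' @param k,pls_train PLS settings when fitting here.
#' @return data.frame per free parameter: mean bias of the posterior
#'   median, RMSE, and empirical coverage of the 95% HPD.
#' @export
parameter_recovery <- function(pods, table, priors = default_priors(),
                               n_retain = 5000, pls = NULL, k = 7,
                               pls_train = 10000) {
  stopifnot(pods$model == unique(table$model))
  bounds <- prior_bounds(priors, pods$model)
  free <- param_names()[bounds[, "upper"] > bounds[, "lower"]]
  if (is.null(pls)) {
    tr <- seq_len(min(pls_train, nrow(table)))
    ytr <- vapply(free, function(pn)
      logtan(table[tr, pn], bounds[pn, 1], bounds[pn, 2]),
      numeric(length(tr)))
    pls <- fit_pls(as.matrix(table[tr, stat_columns(table)]), ytr, k = k)
  }
  n <- nrow(pods$stats)
  med <- hit <- matrix(NA_real_, n, length(free),
                       dimnames = list(NULL, free))
  prep <- prep_reference(table)
  for (i in seq_len(n)) {
    est <- estimate_parameters(table, pods$stats[i, ], priors,
                               n_retain = n_retain, pls = pls,
                               .prep = prep)
    s <- est$summary
    rownames(s) <- s$parameter
    med[i, ] <- s[free, "median"]
    truth <- unlist(pods$params[i, free])
    hit[i, ] <- as.numeric(truth >= s[free, "hpd_low"] &
                             truth <= s[free, "hpd_high"])
  }
  truth <- as.matrix(pods$params[, free, drop = FALSE])
  out <- data.frame(parameter = free,
                    bias = colMeans(med - truth),
                    rmse = sqrt(colMeans((med - truth)^2)),
                    coverage = colMeans(hit),
                    median_of_medians = apply(med, 2, stats::median),
                    row.names = NULL)
  attr(out, "medians") <- med
  out
}
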