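#' The logtan transformation
#'
#' Maps a parameter bounded on (a, b) to the real line:
#' `y = log(tan(pi/2 * (x - a) / (b - a)))`. The inverse maps any real
#' value back into (a, b), which is what keeps regression-adjusted
#' posterior draws inside the prior support. Values at (or numerically
#' outside) the bounds are clamped inwards by `eps` before transforming.
#'
#' @param x,y numeric vectors.
#' @param a,b lower and upper bounds, a < b.
#' @param eps clamping margin as a fraction of (b - a).
#' @return Transformed numeric vector.
#' @export
#' @examples
#' logtan(0.5, 0, 1)              # 0
#' inv_logtan(logtan(0.2, 0, 1), 0, 1)
logtan <- function(x, a, b, eps = 1e-9) {
  if (a >= b) stop("need a < b")
  if (any(x < a - (b - a) * 1e-6, na.rm = TRUE) ||
      any(x > b + (b - a) * 1e-6, na.rm = TRUE))
    stop("x outside (a, b)")
  m <- (b - a) * eps
  x <- pmin(pmax(x, a + m), b - m)
  log(tan(pi / 2 * (x - a) / (b - a)))
}

#' @rdname logtan
#' @export
inv_logtan <- function(y, a, b) {
  if (a >= b) stop("need a < b")
  a + (b - a) * (2 / pi) * atan(exp(y))
}

#' Standardize statistics and rank simulations by distance to the data
#'
#' Every statistic is divided by its pooled standard deviation across all
#' provided reference tables; the distance of each simulation to the
#' observed vector is the Euclidean norm of the standardized differences.
#' Statistics with (pooled) zero variance are dropped with a warning.
#'
#' @param tables a `reference_table` or a list of them (one per model).
#' @param obs named numeric vector of observed statistics (panel order).
#' @return List: `distances` (ascending-order permutation is `order`),
#'   `model` (row model labels), `stats` (standardized pooled stats
#'   matrix), `obs_std`, `sd`, `center`, `kept` (stat names used), `rows`
#'   (row index within the originating table), `table_id`.
#' @export
standardize_and_rank <- function(tables, obs) {
  rank_with_prep(prep_reference(tables), obs)
}

# pooled standardization of one or more reference tables; reusable across
# many observed vectors (the power study calls this once, not per pod)
prep_reference <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  pooled <- do.call(rbind, lapply(tables, as.data.frame))
  snames <- stat_columns(pooled)
  S <- as.matrix(pooled[, snames, drop = FALSE])
  sds <- apply(S, 2, sd)
  keep <- sds > 1e-12
  if (!all(keep))
    warning("dropping constant statistic(s): ",
            paste(snames[!keep], collapse = ", "))
  ctr <- colMeans(S[, keep, drop = FALSE])
  Z <- sweep(sweep(S[, keep, drop = FALSE], 2, ctr), 2, sds[keep], "/")
  list(stats = Z, sq = rowSums(Z^2), model = pooled$model,
       sd = sds[keep], center = ctr, kept = snames[keep],
       rows = unlist(lapply(tables, function(t) seq_len(nrow(t)))),
       table_id = rep(seq_along(tables),
                      vapply(tables, nrow, integer(1))))
}

rank_with_prep <- function(prep, obs) {
  obs <- obs[prep$kept]
  if (any(is.na(obs))) stop("observed vector lacks panel statistics")
  zobs <- (obs - prep$center) / prep$sd
  d2 <- prep$sq - 2 * as.numeric(prep$stats %*% zobs) + sum(zobs^2)
  d <- sqrt(pmax(d2, 0))
  c(prep, list(distances = d, order = order(d), obs_std = zobs))
}

# Epanechnikov weights from distances; the n_retain-th distance is d_max
epanechnikov_weights <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  1 - (d / dmax)^2
}

#' ABC model choice by weighted multinomial logistic regression
#'
#' Pools the reference tables of all candidate models, retains the
#' simulations closest to the observed vector, and fits a multinomial
#' logistic regression of the model label on the standardized statistics
#' with Epanechnikov weights `1 - (d/d_max)^2`; the fitted class
#' probabilities at the observed point are the model posterior
#' probabilities. Repeating this at several retention thresholds gives a
#' stability table.
#'
#' @param tables named list of `reference_table`s, one per model (names
#'   default to each table's model column).
#' @param obs observed summary-statistic vector.
#' @param n_retain single retention threshold; when given, `thresholds`
#'   is ignored.
#' @param thresholds integer vector of retention thresholds (capped at the
#'   pooled table size).
#' @param decay ridge penalty passed to [nnet::multinom()] (numerical
#'   stability under complete separation).
#' @param .prep internal: a pre-computed pooled standardization
#'   ([standardize_and_rank()] constants), reused across the pods of a
#'   power study.
#' @return An object of class `model_choice`: `probabilities` (thresholds
#'   x models matrix, rows summing to 1), `thresholds`, and the headline
#'   `posterior` (probabilities at the largest threshold).
#' @export
model_posteriors <- function(tables, obs, n_retain = NULL,
                             thresholds = c(1000, 5000, 10000, 50000),
                             decay = 1e-6, .prep = NULL) {
  if (inherits(tables, "data.frame")) stop("need one table per model")
  if (length(tables) < 2) stop("need at least 2 candidate models")
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) t$model[1], character(1))
  models <- names(tables)
  if (is.null(.prep)) .prep <- prep_reference(tables)
  rk <- rank_with_prep(.prep, obs)
  npool <- length(rk$distances)
  if (!is.null(n_retain)) thresholds <- n_retain
  thresholds <- sort(unique(pmin(thresholds, npool)))

  probs <- matrix(0, length(thresholds), length(models),
                  dimnames = list(NULL, models))
  for (ti in seq_along(thresholds)) {
    nr <- thresholds[ti]
    sel <- rk$order[seq_len(nr)]
    lab <- factor(rk$model[sel], levels = models)
    present <- levels(droplevels(lab))
    if (length(present) < length(models))
      warning("model(s) absent from the retained set at threshold ", nr,
              ": ", paste(setdiff(models, present), collapse = ", "))
    w <- epanechnikov_weights(rk$distances[sel])
    if (all(w == 0)) w <- rep(1, nr)
    if (length(present) == 1L) {
      probs[ti, present] <- 1
      next
    }
    df <- data.frame(.model = droplevels(lab),
                     rk$stats[sel, , drop = FALSE], check.names = TRUE)
    fit <- nnet::multinom(.model ~ ., data = df, weights = w,
                          decay = decay, trace = FALSE, maxit = 200,
                          MaxNWts = 5000)
    nd <- as.data.frame(matrix(rk$obs_std, 1,
                               dimnames = list(NULL, rk$kept)),
                        check.names = TRUE)
    p <- predict(fit, newdata = nd, type = "probs")
    if (length(present) == 2L) {
      # binary fit returns P(second level)
      p <- c(1 - p, p)
      names(p) <- present
    }
    probs[ti, names(p)] <- pmax(p, 0)
    probs[ti, ] <- probs[ti, ] / sum(probs[ti, ])
  }
  structure(list(probabilities = probs, thresholds = thresholds,
                 posterior = probs[length(thresholds), ]),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat("ABC model choice (posterior probabilities by retention threshold)\n")
  tab <- cbind(retained = x$thresholds, round(x$probabilities, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

# weighted quantile (step interpolation on the cumulative weights)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

# weighted KDE on a grid: mode and smallest 95% density region
weighted_density_summary <- function(x, w, lower, upper, level = 0.95,
                                     n_grid = 512) {
  w <- w / sum(w)
  bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) bw <- max((upper - lower) * 1e-6,
                                           .Machine$double.eps)
  de <- density(x, weights = w, bw = bw, n = n_grid,
                from = max(lower, min(x) - 3 * bw),
                to = min(upper, max(x) + 3 * bw))
  mass <- de$y / sum(de$y)
  ord <- order(de$y, decreasing = TRUE)
  need <- which(cumsum(mass[ord]) >= level)[1]
  sel <- ord[seq_len(need)]
  list(mode = de$x[which.max(de$y)],
       hpd = c(max(lower, min(de$x[sel])), min(upper, max(de$x[sel]))))
}

#' ABC parameter estimation by local-linear regression adjustment
#'
#' Beaumont-style estimation from a single-model reference table: retain
#' the `n_retain` simulations closest to the observed statistics, map each
#' parameter to the real line with [logtan()] (using its prior bounds),
#' regress it on the PLS scores of the retained statistics with
#' Epanechnikov weights, shift every retained draw along the fitted plane
#' to the observed point, and back-transform. Posterior summaries (weighted
#' median, KDE mode, 95% HPD) and the regression R-squared are reported
#' per parameter; fixed parameters (e.g. P under continuity) are passed
#' through as constants with R-squared `NA`.
#'
#' @param table a `reference_table` built under one model.
#' @param obs observed summary-statistic vector.
#' @param priors the `prior_set` the table was generated from (gives the
#'   logtan bounds).
#' @param n_retain number of retained simulations (default 5000).
#' @param pls optional fitted [fit_pls()] transform; when `NULL` one is
#'   fitted on the first `pls_train` rows of the table.
#' @param k number of PLS components when fitting here.
#' @param pls_train size of the training slice for the PLS fit.
#' @param level credible level of the HPD interval.
#' @param .prep internal: pre-computed standardization constants reused
#'   across repeated estimations against the same table.
#' @return An object of class `posterior_result`: `summary` data.frame
#'   (parameter, median, mode, hpd_low, hpd_high, r_squared), `samples`
#'   (adjusted draws), `weights`, `n_retain`, `pls`.
#' @export
estimate_parameters <- function(table, obs, priors = default_priors(),
                                n_retain = 5000, pls = NULL, k = 7,
                                pls_train = 10000, level = 0.95,
                                .prep = NULL) {
  model <- unique(table$model)
  if (length(model) != 1) stop("table must come from a single model")
  check_model(model)
  n_retain <- min(n_retain, nrow(table))
  bounds <- prior_bounds(priors, model)
  free <- bounds[, "upper"] > bounds[, "lower"]
  pmat <- as.matrix(table[, param_names(), drop = FALSE])

  if (is.null(.prep)) .prep <- prep_reference(table)
  rk <- rank_with_prep(.prep, obs)
  sel <- rk$order[seq_len(n_retain)]
  w <- epanechnikov_weights(rk$distances[sel])
  degenerate <- sum(w > 0) < 2 || max(rk$distances[sel]) == 0

  if (is.null(pls)) {
    tr <- seq_len(min(pls_train, nrow(table)))
    ytr <- vapply(param_names()[free], function(pn)
      logtan(pmat[tr, pn], bounds[pn, 1], bounds[pn, 2]), numeric(length(tr)))
    pls <- fit_pls(as.matrix(table[tr, stat_columns(table)]), ytr, k = k)
  }
  Sret <- as.matrix(table[sel, stat_columns(table), drop = FALSE])
  Z <- apply_pls(pls, Sret)
  zobs <- apply_pls(pls, obs[stat_columns(table)])

  if (degenerate) {
    warning("degenerate retained set; falling back to rejection only")
    w <- rep(1, n_retain)
  }
  summ <- vector("list", length(param_names()))
  draws <- matrix(NA_real_, n_retain, length(param_names()),
                  dimnames = list(NULL, param_names()))
  for (pi in seq_along(param_names())) {
    pn <- param_names()[pi]
    a <- bounds[pn, 1]; b <- bounds[pn, 2]
    if (!free[pi]) {
      draws[, pi] <- a
      summ[[pi]] <- data.frame(parameter = pn, median = a, mode = a,
                               hpd_low = a, hpd_high = a,
                               r_squared = NA_real_)
      next
    }
    y <- logtan(pmat[sel, pn], a, b)
    if (degenerate) {
      yadj <- y
      r2 <- NA_real_
    } else {
      Xd <- cbind(1, sweep(Z, 2, as.numeric(zobs)))
      fit <- lm.wfit(Xd, y, w)
      yadj <- fit$coefficients[1] + fit$residuals
      mu <- sum(w * y) / sum(w)
      r2 <- max(0, min(1, 1 - sum(w * fit$residuals^2) /
                            sum(w * (y - mu)^2)))
    }
    x_adj <- inv_logtan(yadj, a, b)
    draws[, pi] <- x_adj
    ds <- weighted_density_summary(x_adj, w, a, b, level = level)
    summ[[pi]] <- data.frame(parameter = pn,
                             median = weighted_quantile(x_adj, w, 0.5),
                             mode = ds$mode, hpd_low = ds$hpd[1],
                             hpd_high = ds$hpd[2], r_squared = r2)
  }
  structure(list(summary = do.call(rbind, summ), samples = draws,
                 weights = w, n_retain = n_retain, model = model,
                 pls = pls),
            class = "posterior_result")
}

#' @export
print.posterior_result <- function(x, ...) {
  cat("ABC posterior (", x$model, ", ", x$n_retain,
      " retained simulations)\n", sep = "")
  s <- x$summary
  s[, -1] <- signif(s[, -1], 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Posterior-predictive p-value under a fitted multivariate-normal model
#'
#' Fits a multivariate normal to the retained standardized statistics and
#' reports the fraction of retained simulations whose density falls below
#' the observed vector's density — small values flag an observed dataset
#' that the retained simulations cannot reproduce.
#'
#' @param retained matrix of retained (standardized) statistics.
#' @param obs observed vector on the same scale.
#' @param ridge diagonal inflation factor for a stable covariance.
#' @return p-value in \[0, 1\].
#' @export
glm_ppp_value <- function(retained, obs, ridge = 1e-8) {
  retained <- as.matrix(retained)
  mu <- colMeans(retained)
  Sg <- cov(retained)
  diag(Sg) <- diag(Sg) + ridge * max(diag(Sg), 1)
  md_obs <- mahalanobis(matrix(obs, 1), mu, Sg)
  md <- mahalanobis(retained, mu, Sg)
  mean(md > md_obs)
}

#' PCA fit check of the retained simulations per model
#'
#' Projects each model's best-fitting simulations onto their first two
#' principal components and reports where the observed vector falls: its
#' coordinates and its Mahalanobis percentile within the retained cloud
#' (values near 1 flag an observed dataset outside the cloud).
#'
#' @param tables named list of `reference_table`s.
#' @param obs observed summary-statistic vector.
#' @param n_best retained simulations per model.
#' @param plot_file optional path: a PDF scatter of the clouds and the
#'   observed point is written there.
#' @return data.frame per model: PC1/PC2 coordinates of the observed data,
#'   Mahalanobis percentile, and the share of variance on the two
#'   components.
#' @export
pca_fit_check <- function(tables, obs, n_best = 5000, plot_file = NULL) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  if (is.null(names(tables)) || any(!nzchar(names(tables))))
    names(tables) <- vapply(tables, function(t) t$model[1], character(1))
  rk <- standardize_and_rank(tables, obs)
  out <- list(); clouds <- list()
  for (m in names(tables)) {
    in_m <- which(rk$model == m)
    sel <- in_m[order(rk$distances[in_m])][seq_len(min(n_best,
                                                       length(in_m)))]
    pc <- prcomp(rk$stats[sel, , drop = FALSE], center = TRUE,
                 scale. = FALSE)
    sc <- pc$x[, 1:2, drop = FALSE]
    so <- predict(pc, matrix(rk$obs_std, 1,
                             dimnames = list(NULL, rk$kept)))[, 1:2]
    mu <- colMeans(sc); Sg <- cov(sc)
    md <- mahalanobis(sc, mu, Sg)
    mdo <- mahalanobis(matrix(so, 1), mu, Sg)
    out[[m]] <- data.frame(model = m, pc1 = so[1], pc2 = so[2],
                           percentile = mean(md <= mdo),
                           var_explained = sum(pc$sdev[1:2]^2) /
                             sum(pc$sdev^2))
    clouds[[m]] <- sc
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  if (!is.null(plot_file)) {
    grDevices::pdf(plot_file, width = 7, height = 6)
    on.exit(grDevices::dev.off())
    cols <- seq_along(clouds) + 1
    xl <- range(c(vapply(clouds, function(s) range(s[, 1]), numeric(2)),
                  report$pc1))
    yl <- range(c(vapply(clouds, function(s) range(s[, 2]), numeric(2)),
                  report$pc2))
    graphics::plot(NA, xlim = xl, ylim = yl, xlab = "PC1", ylab = "PC2",
                   main = "Best-fitting simulations per model")
    for (i in seq_along(clouds))
      graphics::points(clouds[[i]], col = cols[i], pch = 16, cex = 0.3)
    graphics::points(report$pc1, report$pc2, pch = 8, cex = 1.5, lwd = 2)
    graphics::legend("topright", legend = c(names(clouds), "observed"),
                     col = c(cols, 1),
                     pch = c(rep(16, length(clouds)), 8))
  }
  report
}
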