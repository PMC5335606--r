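#' Partial least squares compression of the summary panel
#'
#' Fits standard PLS2 regression components (NIPALS) of the z-scored
#' summary statistics against all (transformed) model parameters jointly,
#' and stores the centering/scaling constants plus the rotation matrix that
#' maps a raw statistic vector into k component scores. The scores of the
#' training rows are reproduced exactly by [apply_pls()].
#'
#' Statistics with zero variance in the training set are dropped (their
#' loadings are zero) with a warning.
#'
#' @param stats numeric matrix (rows = simulations, columns = the panel).
#' @param params numeric matrix of the parameters the components should
#'   predict (already transformed as desired, e.g. by [logtan()]);
#'   constant columns are ignored.
#' @param k number of components (1 <= k <= number of informative stats).
#' @return An object of class `pls_transform` with elements `center`,
#'   `scale`, `rotation` (stats x k), `k`, `scores` (training scores).
#' @export
fit_pls <- function(stats, params, k) {
  stats <- as.matrix(stats); params <- as.matrix(params)
  if (nrow(stats) != nrow(params)) stop("stats/params row mismatch")
  if (nrow(stats) < 10 * k)
    stop("need at least 10 x k training rows (got ", nrow(stats), ")")
  center <- colMeans(stats)
  scl <- apply(stats, 2, sd)
  keep <- scl > 1e-12
  if (!all(keep))
    warning("dropping ", sum(!keep), " constant statistic(s): ",
            paste(colnames(stats)[!keep], collapse = ", "))
  if (k > sum(keep)) stop("k exceeds the number of informative statistics")
  X <- sweep(sweep(stats[, keep, drop = FALSE], 2, center[keep]), 2,
             scl[keep], "/")
  yscl <- apply(params, 2, sd)
  Y <- scale(params[, yscl > 1e-12, drop = FALSE])
  if (ncol(Y) == 0L) stop("all parameter columns are constant")

  np <- ncol(X)
  W <- P <- matrix(0, np, k)
  Tm <- matrix(0, nrow(X), k)
  Xd <- X; Yd <- Y
  for (h in seq_len(k)) {
    u <- Yd[, which.max(apply(Yd, 2, var))]
    w_old <- rep(0, np)
    for (it in 1:500) {
      w <- crossprod(Xd, u)[, 1]
      w <- w / sqrt(sum(w^2))
      tt <- Xd %*% w
      q <- crossprod(Yd, tt)[, 1]
      q <- q / sqrt(sum(q^2))
      u <- Yd %*% q
      if (sum((w - w_old)^2) < 1e-12) break
      w_old <- w
    }
    tt <- as.numeric(Xd %*% w)
    p <- crossprod(Xd, tt)[, 1] / sum(tt^2)
    c_y <- crossprod(Yd, tt)[, 1] / sum(tt^2)
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, c_y)
    W[, h] <- w; P[, h] <- p; Tm[, h] <- tt
  }
  # rotation R = W (P'W)^-1 maps the scaled stats straight to the scores
  Rmat <- W %*% solve(crossprod(P, W))
  rotation <- matrix(0, length(center), k,
                     dimnames = list(colnames(stats), NULL))
  rotation[keep, ] <- Rmat
  structure(list(center = center, scale = ifelse(keep, scl, 1),
                 keep = keep, rotation = rotation, k = k, scores = Tm),
            class = "pls_transform")
}

#' @rdname fit_pls
#' @param transform a fitted `pls_transform`.
#' @param newstats matrix or vector of raw statistics in panel order.
#' @return `apply_pls`: matrix of component scores (rows x k).
#' @export
apply_pls <- function(transform, newstats) {
  if (is.null(dim(newstats))) newstats <- matrix(newstats, 1)
  newstats <- as.matrix(newstats)
  if (ncol(newstats) != length(transform$center))
    stop("newstats must have ", length(transform$center), " columns")
  Z <- sweep(sweep(newstats, 2, transform$center), 2, transform$scale, "/")
  Z %*% transform$rotation
}
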