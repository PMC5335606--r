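#' Prior distributions for the demographic parameters
#'
#' Each free parameter gets a uniform or log-uniform prior on a finite
#' interval. The admixture proportion `P` is model-specific: fixed at 0
#' under continuity, fixed at 1 under discontinuity, uniform on (0, 0.75)
#' under admixture and uniform on (0, 1) under admixture_tot.
#'
#' Defaults: ancient sizes `Nas`, `Nan` log-uniform on (100, 10,000);
#' current sizes `Ncs`, `Ncn` log-uniform on (1,000, 100,000); `mut`
#' uniform on (1e-8, 4e-8) per nucleotide per year; `rs` log-uniform on
#' (1, 100); `Tcol` uniform on (10,500, 21,000) yBP so colonization always
#' predates the oldest (10,000 yBP) sample.
#'
#' @param ... overrides of the form `name = list(dist =, lower =, upper =)`
#'   where `dist` is `"uniform"` or `"loguniform"`, or for `P`,
#'   `P = list(<model> = list(...))`.
#' @return An object of class `prior_set`.
#' @export
#' @examples
#' pr <- default_priors()
#' prior_bounds(pr, "admixture_tot")
default_priors <- function(...) {
  pr <- list(
    rs   = list(dist = "loguniform", lower = 1,     upper = 100),
    Nan  = list(dist = "loguniform", lower = 100,   upper = 10000),
    Nas  = list(dist = "loguniform", lower = 100,   upper = 10000),
    Ncn  = list(dist = "loguniform", lower = 1000,  upper = 100000),
    Ncs  = list(dist = "loguniform", lower = 1000,  upper = 100000),
    mut  = list(dist = "uniform",    lower = 1e-8,  upper = 4e-8),
    Tcol = list(dist = "uniform",    lower = 10500, upper = 21000))
  P_by_model <- list(
    continuity    = list(fixed = 0),
    discontinuity = list(fixed = 1),
    admixture     = list(dist = "uniform", lower = 0, upper = 0.75),
    admixture_tot = list(dist = "uniform", lower = 0, upper = 1))
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "P") {
      for (m in names(dots$P)) P_by_model[[m]] <- dots$P[[m]]
    } else if (nm %in% names(pr)) {
      pr[[nm]] <- utils::modifyList(pr[[nm]], dots[[nm]])
    } else stop("unknown prior name: ", nm)
  }
  obj <- structure(list(params = pr, P_by_model = P_by_model),
                   class = "prior_set")
  validate_priors(obj)
  obj
}

validate_priors <- function(priors) {
  spec1 <- function(s, nm) {
    if (!is.null(s$fixed)) return(invisible())
    if (!s$dist %in% c("uniform", "loguniform"))
      stop("prior for ", nm, ": dist must be uniform or loguniform")
    if (!is.finite(s$lower) || !is.finite(s$upper) || s$lower >= s$upper)
      stop("prior for ", nm, ": need finite lower < upper")
    if (s$dist == "loguniform" && s$lower <= 0)
      stop("prior for ", nm, ": log-uniform requires lower > 0")
  }
  for (nm in names(priors$params)) spec1(priors$params[[nm]], nm)
  for (m in names(priors$P_by_model)) {
    s <- priors$P_by_model[[m]]
    if (!is.null(s$fixed)) {
      if (s$fixed < 0 || s$fixed > 1) stop("fixed P outside [0, 1]")
    } else spec1(s, paste0("P (", m, ")"))
  }
  invisible(priors)
}

# per-model support of every parameter; fixed parameters have lower == upper
#' @rdname default_priors
#' @param priors a `prior_set`.
#' @param model model label.
#' @export
prior_bounds <- function(priors, model) {
  check_model(model)
  ps <- priors$P_by_model[[model]]
  if (!is.null(ps$fixed)) pb <- c(ps$fixed, ps$fixed)
  else pb <- c(ps$lower, ps$upper)
  out <- rbind(P = pb,
               do.call(rbind, lapply(priors$params, function(s)
                 c(s$lower, s$upper))))
  colnames(out) <- c("lower", "upper")
  out[param_names(), , drop = FALSE]
}

draw_one <- function(s) {
  if (!is.null(s$fixed)) return(s$fixed)
  if (s$dist == "uniform") runif(1, s$lower, s$upper)
  else exp(runif(1, log(s$lower), log(s$upper)))
}

#' Draw demographic parameters from their priors
#'
#' Fixed parameters (P = 0 under continuity, P = 1 under discontinuity) are
#' set exactly; the remaining parameters are drawn independently from their
#' priors. With the same `seed` the same draw is returned.
#'
#' @param priors a `prior_set`, see [default_priors()].
#' @param model one of `"continuity"`, `"discontinuity"`, `"admixture"`,
#'   `"admixture_tot"`.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first. When `NULL` the current RNG stream is used.
#' @return A [param_draw()].
#' @export
draw_parameters <- function(priors, model, seed = NULL) {
  check_model(model)
  validate_priors(priors)
  if (!is.null(seed)) set.seed(seed)
  P <- draw_one(priors$P_by_model[[model]])
  v <- vapply(priors$params[setdiff(param_names(), "P")], draw_one,
              numeric(1))
  param_draw(P = P, rs = v[["rs"]], Nan = v[["Nan"]], Nas = v[["Nas"]],
             Ncn = v[["Ncn"]], Ncs = v[["Ncs"]], mut = v[["mut"]],
             Tcol = v[["Tcol"]])
}
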