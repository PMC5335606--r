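#' Sampling design of a serial mitogenome study
#'
#' A study design fixes the population samples (label, size, mean sampling
#' age in years before present, and the branch — deme — each sample sits
#' on), the generation time used to convert years into generations, and the
#' locus length. The default reproduces a four-sample design: 63 modern
#' Sardinian mitogenomes (MS, 0 yBP), 2 Mesolithic Sardinian mitogenomes
#' (MSS, 10,000 yBP), and 28 Early Neolithic (EN, 8,700 yBP) plus 18 Middle
#' Neolithic (MN, 7,700 yBP) mitogenomes on the continental branch, with a
#' 30-year generation time and a 16,569-site locus.
#'
#' @param populations data.frame with columns `label`, `n`, `age_yBP`,
#'   `deme` (`"sardinia"` or `"continent"`).
#' @param generation_time years per generation.
#' @param locus_length number of sites of the non-recombining locus.
#' @return An object of class `study_design`.
#' @export
#' @examples
#' d <- study_design()
#' sum(d$populations$n)  # 111 samples
study_design <- function(populations = NULL, generation_time = 30,
                         locus_length = 16569) {
  if (is.null(populations)) {
    populations <- data.frame(
      label = c("MS", "MSS", "EN", "MN"),
      n = c(63L, 2L, 28L, 18L),
      age_yBP = c(0, 10000, 8700, 7700),
      deme = c("sardinia", "sardinia", "continent", "continent"),
      stringsAsFactors = FALSE)
  }
  req <- c("label", "n", "age_yBP", "deme")
  if (!all(req %in% names(populations)))
    stop("populations must have columns ", paste(req, collapse = ", "))
  if (any(populations$n < 1)) stop("sample sizes must be >= 1")
  if (any(populations$age_yBP < 0)) stop("sampling ages must be >= 0")
  if (any(duplicated(populations$label))) stop("duplicated population label")
  if (!all(populations$deme %in% c("sardinia", "continent")))
    stop("deme must be 'sardinia' or 'continent'")
  if (locus_length < 1) stop("locus_length must be >= 1")
  if (generation_time <= 0) stop("generation_time must be > 0")
  structure(list(populations = populations,
                 generation_time = generation_time,
                 locus_length = as.integer(locus_length),
                 present_reference = "1950 CE"),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", sum(x$populations$n), "samples,",
      nrow(x$populations), "populations; locus", x$locus_length, "sites;",
      x$generation_time, "y/generation\n")
  print(x$populations, row.names = FALSE)
  invisible(x)
}

# sampling times in generations (rounded), in design population order
design_sample_times <- function(design) {
  round(design$populations$age_yBP / design$generation_time)
}

# the per-sample table (ids, population, deme, age, activation time);
# cached on the design object so per-simulation code does not rebuild it
design_samples <- function(design) {
  if (!is.null(attr(design, "samples_cache")))
    return(attr(design, "samples_cache"))
  pops <- design$populations
  data.frame(
    sample_id = unlist(lapply(seq_len(nrow(pops)), function(i)
      sprintf("%s_%03d", pops$label[i], seq_len(pops$n[i])))),
    population = rep(pops$label, pops$n),
    deme = rep(pops$deme, pops$n),
    age_yBP = rep(pops$age_yBP, pops$n),
    time = rep(design_sample_times(design), pops$n),
    stringsAsFactors = FALSE)
}

cache_design <- function(design) {
  attr(design, "samples_cache") <- design_samples(design)
  design
}

#' One point in demographic parameter space
#'
#' Bundles the eight parameters of the two-deme demographic models:
#' `P` (proportion of modern Sardinian lineages of continental Neolithic
#' origin), `rs` (colonization bottleneck reduction factor, >= 1),
#' `Nan`/`Nas` (ancient continental / Sardinian haploid effective sizes),
#' `Ncn`/`Ncs` (current continental / Sardinian sizes), `mut` (mutation
#' rate per nucleotide per year) and `Tcol` (Sardinia colonization time,
#' years BP).
#'
#' @param P,rs,Nan,Nas,Ncn,Ncs,mut,Tcol numeric scalars, see Description.
#' @param design optional `study_design` used to check that `Tcol` predates
#'   the oldest sample.
#' @return An object of class `param_draw` (a named list).
#' @export
param_draw <- function(P, rs, Nan, Nas, Ncn, Ncs, mut, Tcol,
                       design = NULL) {
  x <- list(P = P, rs = rs, Nan = Nan, Nas = Nas, Ncn = Ncn, Ncs = Ncs,
            mut = mut, Tcol = Tcol)
  if (any(!vapply(x, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v), logical(1))))
    stop("all parameters must be finite numeric scalars")
  if (P < 0 || P > 1) stop("P must lie in [0, 1]")
  if (rs < 1) stop("rs must be >= 1")
  if (any(unlist(x[c("Nan", "Nas", "Ncn", "Ncs")]) < 1))
    stop("effective sizes must be >= 1")
  if (mut <= 0) stop("mut must be > 0")
  if (!is.null(design) && Tcol <= max(design$populations$age_yBP))
    stop("colonization postdates sample: Tcol = ", Tcol,
         " must exceed the oldest sampling age ",
         max(design$populations$age_yBP))
  structure(x, class = "param_draw")
}

param_names <- function() c("P", "rs", "Nan", "Nas", "Ncn", "Ncs", "mut",
                            "Tcol")
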