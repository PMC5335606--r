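#' Generate an observed-like study dataset with known ground truth
#'
#' Runs one simulation under a chosen demographic scenario and exports it
#' the way a real study dataset would arrive: a 4-letter multi-FASTA
#' (111 records of 16,569 sites under the default design), a sample
#' metadata TSV, and a truth JSON recording the generating model and
#' parameters. The `"paper-posterior"` preset simulates a Neolithic
#' replacement scenario at the point estimates of the admixture_tot
#' posterior (Nas = 793, Ncs = 21,371, Nan = 2,649, Ncn = 38,574,
#' mut = 2.1e-8, rs = 1.647) with the colonization time at the middle of
#' its prior (15,750 yBP).
#'
#' @param model generating model label.
#' @param params a [param_draw()], or `"paper-posterior"` (default) for
#'   the preset, or `"prior-draw"` to draw from `priors`.
#' @param design a [study_design()].
#' @param priors prior set (used for `"prior-draw"` and recorded bounds).
#' @param seed integer master seed; every output byte is a function of
#'   (preset, seed).
#' @param out_dir output directory (created if needed); when `NULL`
#'   nothing is written and the alignment is returned.
#' @return List with the `haplotype_alignment`, the truth record, and (if
#'   written) the three file paths.
#' @export
make_study_dataset <- function(model = "discontinuity",
                               params = "paper-posterior",
                               design = study_design(),
                               priors = default_priors(), seed = 1L,
                               out_dir = NULL) {
  check_model(model)
  preset <- NULL
  if (identical(params, "paper-posterior")) {
    preset <- "paper-posterior"
    P <- switch(model, continuity = 0, discontinuity = 1,
                admixture = 0.75, admixture_tot = 0.872)
    params <- param_draw(P = P, rs = 1.647, Nan = 2649, Nas = 793,
                         Ncn = 38574, Ncs = 21371, mut = 2.1e-8,
                         Tcol = 15750, design = design)
  } else if (identical(params, "prior-draw")) {
    preset <- "prior-draw"
    params <- draw_parameters(priors, model, seed = derive_seed(seed, 1))
  } else if (!inherits(params, "param_draw")) {
    params <- do.call(param_draw, as.list(params))
  }
  set.seed(derive_seed(seed, 2))
  sch <- build_schedule(model, params, design)
  aln <- drop_mutations(simulate_genealogy(sch, design), params$mut,
                        design)
  panel <- compute_panel(aln, design)
  truth <- list(model = model, preset = preset,
                parameters = unclass(params), seed = seed,
                locus_length = design$locus_length,
                n_samples = nrow(aln$meta))
  out <- list(alignment = aln, truth = truth, panel = panel)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(out_dir, "alignment.fasta")
    tsv <- file.path(out_dir, "samples.tsv")
    js <- file.path(out_dir, "truth.json")
    write_study_alignment(aln, fa, tsv, seed = derive_seed(seed, 3))
    jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    out$paths <- c(fasta = fa, meta = tsv, truth = js)
  }
  out
}

#' Hand-checkable toy alignments with their expected statistics
#'
#' Emits the tiny fixtures used to verify the summary statistics by hand:
#' a 3-sequence alignment with nucleotide diversity 4/3 and haplotype
#' diversity 1, a 4-sequence two-haplotype alignment with haplotype
#' diversity 2/3, and a fully diverged two-population pair with
#' d_xy = 10 and FST = 1. Expected values are stored alongside so a loaded
#' fixture can be re-checked.
#'
#' @param out_dir optional directory; when given, each alignment is
#'   written as FASTA-like plain text plus a JSON sidecar of expected
#'   values.
#' @return List of `haplotype_alignment`s and an `expected` list.
#' @export
make_worked_fixture <- function(out_dir = NULL) {
  L <- 10L
  meta1 <- data.frame(sample_id = c("a", "b", "c"),
                      population = "A", age_yBP = 0)
  aln1 <- haplotype_alignment(
    rbind(c(0L, 0L), c(0L, 1L), c(1L, 1L)), sites = c(9L, 10L), L = L,
    meta = meta1)
  meta2 <- data.frame(sample_id = paste0("s", 1:4),
                      population = "A", age_yBP = 0)
  aln2 <- haplotype_alignment(
    rbind(0L, 0L, 1L, 1L), sites = 5L, L = L, meta = meta2)
  meta3 <- data.frame(sample_id = paste0("t", 1:4),
                      population = rep(c("A", "B"), each = 2), age_yBP = 0)
  aln3 <- haplotype_alignment(
    rbind(rep(0L, 10), rep(0L, 10), rep(1L, 10), rep(1L, 10)),
    sites = 1:10, L = L, meta = meta3)
  expected <- list(
    aln1 = list(S = 2, H = 3, hapdiv = 1, pi = 4 / 3),
    aln2 = list(H = 2, hapdiv = 2 / 3),
    aln3 = list(dxy = 10, fst = 1, pi_within = 0))
  out <- list(alignments = list(aln1 = aln1, aln2 = aln2, aln3 = aln3),
              expected = expected)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out$alignments)) {
      a <- out$alignments[[nm]]
      write_study_alignment(a, file.path(out_dir, paste0(nm, ".fasta")),
                            file.path(out_dir, paste0(nm, ".tsv")),
                            seed = 7L)
    }
    jsonlite::write_json(expected, file.path(out_dir, "expected.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
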