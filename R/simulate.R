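#' Simulate a genealogy under an event schedule
#'
#' Runs the serial-sampling coalescent: within a deme of haploid size N
#' every pair of active lineages coalesces at rate 1/N per generation
#' (continuous-time approximation); lineages enter at their sampling times;
#' move events relocate each lineage of the source deme with probability
#' equal to the event fraction; the process runs until a single common
#' ancestor remains.
#'
#' @param schedule an [build_schedule()] event schedule.
#' @param design the matching [study_design()] (kept for metadata).
#' @param seed optional integer seed.
#' @return An object of class `genealogy`: parent pointers (`NA` at the
#'   root), node times in generations, the deme in which each coalescence
#'   happened, and the leaf metadata. Leaves come first, in schedule sample
#'   order.
#' @export
simulate_genealogy <- function(schedule, design = study_design(),
                               seed = NULL) {
  stopifnot(inherits(schedule, "event_schedule"))
  if (!is.null(seed)) set.seed(seed)
  deme_ids <- c(sardinia = 0L, continent = 1L)
  ev <- schedule$events
  res <- sim_genealogy_cpp(
    samp_time = as.numeric(schedule$samples$time),
    samp_deme = unname(deme_ids[schedule$samples$deme]),
    init_size = as.numeric(schedule$init_sizes),
    ev_time = as.numeric(ev$time),
    ev_type = ifelse(ev$type == "resize", 0L, 1L),
    ev_deme = unname(deme_ids[ev$deme]),
    ev_dest = ifelse(is.na(ev$dest), -1L, deme_ids[ev$dest]),
    ev_size = ifelse(is.na(ev$size), 0, ev$size),
    ev_frac = ifelse(is.na(ev$frac), 0, ev$frac))
  parent <- res$parent
  parent[!is.na(parent)] <- parent[!is.na(parent)] + 1L  # 1-based
  structure(list(parent = parent, time = res$time,
                 deme = names(deme_ids)[res$deme + 1L],
                 n_leaves = nrow(schedule$samples),
                 leaf_meta = schedule$samples),
            class = "genealogy")
}

#' Total time to the most recent common ancestor of a genealogy
#' @param tree a `genealogy`.
#' @return TMRCA in generations (the root node time).
#' @export
tmrca <- function(tree) max(tree$time)

#' Drop finite-sites mutations on a genealogy
#'
#' Mutation counts per branch are Poisson with mean
#' `mut * generation_time * locus_length * branch_length`; each mutation
#' hits a uniformly chosen site and toggles its two-state allele (finite
#' sites: a repeat hit reverts the site). The root carries the all-zeros
#' state.
#'
#' @param tree a [simulate_genealogy()] result.
#' @param mut mutation rate per nucleotide per year (>= 0).
#' @param design a [study_design()] (locus length, generation time).
#' @param seed optional integer seed.
#' @return An object of class `haplotype_alignment`: an n x S 0/1 matrix
#'   over the sites hit at least once (`sites` gives their 1-based
#'   positions in the `locus_length`-site locus), plus sample metadata.
#' @export
drop_mutations <- function(tree, mut, design = study_design(),
                           seed = NULL) {
  stopifnot(inherits(tree, "genealogy"), mut >= 0)
  if (!is.null(seed)) set.seed(seed)
  parent0 <- tree$parent
  parent0[!is.na(parent0)] <- parent0[!is.na(parent0)] - 1L
  res <- drop_mutations_cpp(parent = parent0, node_time = tree$time,
                            n_leaves = tree$n_leaves,
                            rate_site_gen = mut * design$generation_time,
                            L = design$locus_length)
  X <- res$X
  rownames(X) <- tree$leaf_meta$sample_id
  haplotype_alignment(X, sites = res$sites, L = design$locus_length,
                      meta = tree$leaf_meta[, c("sample_id", "population",
                                                "age_yBP")],
                      nstate = 2L)
}

#' Construct a haplotype alignment object
#'
#' The container used throughout: an n x S integer state matrix over the
#' variable (or retained) sites of an L-site locus, with per-sample
#' metadata. Simulated data use two states (0/1); alignments read from
#' FASTA use nucleotide codes 0..3.
#'
#' @param seq integer matrix, samples x sites.
#' @param sites 1-based site positions (length = ncol(seq)).
#' @param L locus length in sites.
#' @param meta data.frame with columns `sample_id`, `population`,
#'   `age_yBP`, one row per sequence row.
#' @param nstate number of possible states per site.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(seq, sites = seq_len(ncol(seq)), L, meta,
                                nstate = 2L) {
  seq <- as.matrix(seq)
  storage.mode(seq) <- "integer"
  if (length(sites) != ncol(seq)) stop("sites must match columns of seq")
  if (nrow(meta) != nrow(seq))
    stop("metadata rows must match sequence rows 1:1")
  req <- c("sample_id", "population", "age_yBP")
  if (!all(req %in% names(meta)))
    stop("meta must have columns ", paste(req, collapse = ", "))
  if (ncol(seq) > L) stop("more sites than locus length")
  structure(list(seq = seq, sites = as.integer(sites), L = as.integer(L),
                 meta = as.data.frame(meta, stringsAsFactors = FALSE),
                 nstate = as.integer(nstate)),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("Haplotype alignment:", nrow(x$seq), "sequences,", x$L,
      "sites (", ncol(x$seq), "variable ),",
      length(unique(x$meta$population)), "populations\n")
  invisible(x)
}

#' Build an ABC reference table
#'
#' Repeats draw-parameters, build-schedule, simulate-genealogy,
#' drop-mutations, compute-panel `n_sims` times under one model and stacks
#' the results. Row i is generated under the derived seed
#' `(seed + i) mod (2^31 - 1)`, so tables are reproducible and can be
#' built in chunks.
#'
#' @param model model label.
#' @param priors a [default_priors()] prior set.
#' @param design a [study_design()].
#' @param n_sims number of simulations (rows).
#' @param seed master integer seed.
#' @param path optional file: the table is also streamed to this TSV.
#' @return A data.frame of class `reference_table`: `model`, the eight
#'   parameter columns, then the summary-statistic panel.
#' @export
build_reference_table <- function(model, priors = default_priors(),
                                  design = study_design(), n_sims,
                                  seed = 1L, path = NULL) {
  check_model(model)
  stopifnot(n_sims >= 1)
  design <- cache_design(design)
  nms <- panel_names(design)
  stats <- matrix(NA_real_, n_sims, length(nms),
                  dimnames = list(NULL, nms))
  pars <- matrix(NA_real_, n_sims, 8L,
                 dimnames = list(NULL, param_names()))
  for (i in seq_len(n_sims)) {
    set.seed(derive_seed(seed, i))
    th <- draw_parameters(priors, model)
    sch <- build_schedule(model, th, design)
    tree <- simulate_genealogy(sch, design)
    aln <- drop_mutations(tree, th$mut, design)
    stats[i, ] <- compute_panel(aln, design)
    pars[i, ] <- unlist(th)
  }
  tab <- data.frame(model = model, pars, stats, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(tab) <- c("reference_table", "data.frame")
  if (!is.null(path)) write_reference_table(tab, path)
  tab
}

# stat column names of a reference table (everything after the parameters)
stat_columns <- function(tab) {
  setdiff(colnames(tab), c("model", param_names()))
}
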