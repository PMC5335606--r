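#' @name sumstats
#' @title Per-population summary statistics
#'
#' @description Single-statistic accessors used by [compute_panel()]:
#' segregating sites, haplotype count and diversity, nucleotide diversity
#' (mean pairwise differences per locus), Tajima's D, between-population
#' mean pairwise differences and Hudson's FST. All statistics depend only
#' on the partition of alleles at each site, so they are invariant to
#' relabeling of allele states and to sample reordering.
#'
#' @param aln a [haplotype_alignment()].
#' @param pop,popA,popB population labels present in `aln$meta$population`.
NULL

pop_rows <- function(aln, pop) {
  idx <- which(aln$meta$population == pop)
  if (length(idx) == 0L) stop("unknown population label: '", pop, "'")
  idx
}

# per-population counts for a set of rows (seg, within, between) via the
# C++ core; only rows named in idx_list take part
pop_counts <- function(aln, idx_list) {
  rows <- unlist(idx_list)
  pop <- rep.int(seq_along(idx_list) - 1L,
                 vapply(idx_list, length, integer(1)))
  sub <- aln$seq[rows, , drop = FALSE]
  nstate <- if (length(sub)) max(aln$nstate, max(sub) + 1L) else aln$nstate
  count_stats_cpp(sub, pop, length(idx_list), nstate)
}

#' @rdname sumstats
#' @return `segregating_sites`: number of sites with two or more states
#'   among the population's sequences.
#' @export
segregating_sites <- function(aln, pop) {
  idx <- pop_rows(aln, pop)
  sub <- aln$seq[idx, , drop = FALSE]
  sum(apply(sub, 2, function(col) length(unique(col))) >= 2)
}

#' @rdname sumstats
#' @return `haplotype_stats`: list with `H` (distinct sequences) and
#'   `hapdiv`, the unbiased haplotype diversity n/(n-1) (1 - sum p_i^2).
#' @export
haplotype_stats <- function(aln, pop) {
  idx <- pop_rows(aln, pop)
  n <- length(idx)
  ids <- hap_ids_cpp(aln$seq[idx, , drop = FALSE])
  H <- length(unique(ids))
  if (n < 2) stop("haplotype diversity needs n >= 2 (population '", pop,
                  "' has n = 1)")
  p <- tabulate(ids) / n
  list(H = H, hapdiv = n / (n - 1) * (1 - sum(p^2)))
}

#' @rdname sumstats
#' @return `nucleotide_diversity`: mean pairwise Hamming distance over all
#'   unordered within-population pairs (per locus, i.e. a count of sites).
#' @export
nucleotide_diversity <- function(aln, pop) {
  idx <- pop_rows(aln, pop)
  n <- length(idx)
  if (n < 2) stop("nucleotide diversity needs n >= 2")
  cs <- pop_counts(aln, list(idx))
  cs$within[1] / (n * (n - 1) / 2)
}

# Tajima's D from (n, S, pi); returns 0 when S == 0 by convention
tajima_from_counts <- function(n, S, pi) {
  if (n < 4) stop("Tajima's D needs n >= 4")
  if (S == 0) return(0)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' @rdname sumstats
#' @return `tajimas_d`: Tajima's D; 0 when there are no segregating sites.
#' @export
tajimas_d <- function(aln, pop) {
  idx <- pop_rows(aln, pop)
  n <- length(idx)
  if (n < 4) stop("Tajima's D needs n >= 4 (population '", pop,
                  "' has n = ", n, ")")
  cs <- pop_counts(aln, list(idx))
  tajima_from_counts(n, cs$seg[1], cs$within[1] / (n * (n - 1) / 2))
}

#' @rdname sumstats
#' @return `pairwise_divergence`: d_xy, the mean Hamming distance over all
#'   between-population pairs.
#' @export
pairwise_divergence <- function(aln, popA, popB) {
  ia <- pop_rows(aln, popA); ib <- pop_rows(aln, popB)
  cs <- pop_counts(aln, list(ia, ib))
  cs$between[1, 2] / (length(ia) * length(ib))
}

#' @rdname sumstats
#' @return `hudson_fst`: 1 - mean(pi_A, pi_B) / d_xy, clamped to
#'   \[-1, 1\]; 0 when d_xy = 0.
#' @export
hudson_fst <- function(aln, popA, popB) {
  ia <- pop_rows(aln, popA); ib <- pop_rows(aln, popB)
  na <- length(ia); nb <- length(ib)
  if (na < 2 || nb < 2) stop("hudson_fst needs n >= 2 in both populations")
  cs <- pop_counts(aln, list(ia, ib))
  dxy <- cs$between[1, 2] / (na * nb)
  if (dxy == 0) return(0)
  piw <- mean(c(cs$within[1] / (na * (na - 1) / 2),
                cs$within[2] / (nb * (nb - 1) / 2)))
  min(1, max(-1, 1 - piw / dxy))
}

#' Names of the summary-statistic panel, in panel order
#'
#' Per population (design order): `S` (segregating sites), `H` (distinct
#' haplotypes), `hapdiv`, `pi`, and `D` (Tajima's D, only for populations
#' with n >= 4); then for every population pair: Hudson `fst` and mean
#' between-population differences `dxy`. With the default four-population
#' design this yields 31 statistics.
#'
#' @param design a [study_design()].
#' @return Character vector of panel entry names.
#' @export
panel_names <- function(design = study_design()) {
  pops <- design$populations
  nms <- unlist(lapply(seq_len(nrow(pops)), function(i) {
    base <- paste0(c("S", "H", "hapdiv", "pi"), "_", pops$label[i])
    if (pops$n[i] >= 4) c(base, paste0("D_", pops$label[i])) else base
  }))
  if (nrow(pops) >= 2) {
    pairs <- utils::combn(pops$label, 2)
    nms <- c(nms, unlist(lapply(seq_len(ncol(pairs)), function(j)
      paste0(c("fst", "dxy"), "_", pairs[1, j], "_", pairs[2, j]))))
  }
  nms
}

#' Compute the full summary-statistic panel
#'
#' Evaluates every panel statistic (see [panel_names()]) on a
#' multi-population alignment. The panel order is fixed and identical for
#' observed data and reference tables.
#'
#' @param aln a [haplotype_alignment()].
#' @param design a [study_design()]; all design populations must be present
#'   with their design sample sizes.
#' @return Named numeric vector in panel order (31 entries for the default
#'   design).
#' @export
compute_panel <- function(aln, design = study_design()) {
  pops <- design$populations
  idx_list <- vector("list", nrow(pops))
  for (i in seq_len(nrow(pops))) {
    idx <- which(aln$meta$population == pops$label[i])
    if (length(idx) == 0L)
      stop("missing population: '", pops$label[i], "'")
    if (length(idx) != pops$n[i])
      stop("population '", pops$label[i], "': expected n = ", pops$n[i],
           ", found ", length(idx))
    idx_list[[i]] <- idx
  }
  cs <- pop_counts(aln, idx_list)
  ids <- hap_ids_cpp(aln$seq)

  out <- numeric(0)
  for (i in seq_len(nrow(pops))) {
    n <- pops$n[i]
    pi_i <- if (n >= 2) cs$within[i] / (n * (n - 1) / 2) else 0
    sub_ids <- ids[idx_list[[i]]]
    H <- length(unique(sub_ids))
    hd <- if (n >= 2) {
      p <- tabulate(match(sub_ids, unique(sub_ids))) / n
      n / (n - 1) * (1 - sum(p^2))
    } else 0
    v <- c(cs$seg[i], H, hd, pi_i)
    if (n >= 4) v <- c(v, tajima_from_counts(n, cs$seg[i], pi_i))
    out <- c(out, v)
  }
  if (nrow(pops) >= 2) {
    pairs <- utils::combn(seq_len(nrow(pops)), 2)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      na <- pops$n[a]; nb <- pops$n[b]
      dxy <- cs$between[a, b] / (na * nb)
      piw <- mean(c(if (na >= 2) cs$within[a] / (na * (na - 1) / 2) else 0,
                    if (nb >= 2) cs$within[b] / (nb * (nb - 1) / 2) else 0))
      fst <- if (dxy == 0) 0 else min(1, max(-1, 1 - piw / dxy))
      out <- c(out, fst, dxy)
    }
  }
  setNames(out, panel_names(design))
}
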