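#' Read and write multi-FASTA haplotype alignments
#'
#' `read_fasta_alignment` reads a standard multi-FASTA file (wrapped or
#' unwrapped, any case) into a named uppercase character matrix, one row
#' per record, keyed by the header token before the first whitespace. All
#' records must have equal length.
#'
#' @param path FASTA file path.
#' @return Character matrix (records x sites) of uppercase bases.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0)
    stop("empty FASTA file: ", path)
  names(recs) <- vapply(strsplit(names(recs), "\\s+"), `[`, character(1), 1)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1)
    stop("records of differing length: ",
         paste(names(recs)[lens != stats::median(lens)], collapse = ", "))
  m <- toupper(as.character(as.matrix(recs)))
  rownames(m) <- names(recs)
  m
}

#' @rdname read_fasta_alignment
#' @param records character matrix (or named list of equal-length character
#'   vectors) of bases.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records)) records <- do.call(rbind, records)
  dna <- ape::as.DNAbin(records)
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated file with header columns `sample_id`, `population`,
#' `age_yBP`; one row per sequence.
#'
#' @param path TSV path.
#' @param fasta_ids optional character vector of FASTA record ids to
#'   cross-check 1:1 against the table.
#' @return data.frame with the three required columns.
#' @export
read_sample_metadata <- function(path, fasta_ids = NULL) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "population", "age_yBP")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("missing metadata column(s): ",
                         paste(miss, collapse = ", "))
  if (any(duplicated(meta$sample_id)))
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
               collapse = ", "))
  if (any(is.na(meta$age_yBP)) || !is.numeric(meta$age_yBP) ||
      any(meta$age_yBP < 0))
    stop("age_yBP must be a non-negative number")
  if (!is.null(fasta_ids)) {
    if (length(fasta_ids) != nrow(meta) ||
        !setequal(fasta_ids, meta$sample_id))
      stop("sample ids do not match the FASTA records 1:1")
  }
  meta
}

# nucleotide encoding used for alignments read from FASTA
.base_codes <- c(A = 0L, C = 1L, G = 2L, T = 3L)

#' Load an observed study dataset (FASTA + metadata)
#'
#' Reads a haplotype alignment and its metadata, checks them against each
#' other, encodes the bases, and keeps the polymorphic columns (columns
#' identical across all samples carry no information for any panel
#' statistic).
#'
#' @param fasta_path multi-FASTA alignment.
#' @param meta_path metadata TSV (see [read_sample_metadata()]).
#' @return A [haplotype_alignment()] with 4-state encoding.
#' @export
read_study_alignment <- function(fasta_path, meta_path) {
  m <- read_fasta_alignment(fasta_path)
  meta <- read_sample_metadata(meta_path, fasta_ids = rownames(m))
  meta <- meta[match(rownames(m), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad <- !m %in% names(.base_codes)
  if (any(bad))
    stop("non-ACGT characters in records: ",
         paste(unique(rownames(m)[which(bad, arr.ind = TRUE)[, 1]]),
               collapse = ", "))
  X <- matrix(.base_codes[m], nrow(m), ncol(m),
              dimnames = list(rownames(m), NULL))
  poly <- which(apply(X, 2, function(col) length(unique(col)) > 1))
  haplotype_alignment(X[, poly, drop = FALSE], sites = poly, L = ncol(m),
                      meta = meta, nstate = 4L)
}

#' Export a simulated alignment as nucleotide FASTA plus metadata
#'
#' Binary simulated states are mapped onto a random reference background:
#' state 0 is the reference base and state 1 its transition partner
#' (A<->G, C<->T). This is cosmetic — every panel statistic depends only on
#' the allele partition per site — but produces realistic-looking files.
#'
#' @param aln a two-state [haplotype_alignment()].
#' @param fasta_path,meta_path output file paths.
#' @param seed integer seed for the reference background.
#' @return Invisibly, the two paths.
#' @export
write_study_alignment <- function(aln, fasta_path, meta_path, seed = 1L) {
  stopifnot(inherits(aln, "haplotype_alignment"), aln$nstate == 2L)
  set.seed(derive_seed(seed, 0))
  bases <- c("A", "C", "G", "T")
  partner <- c(A = "G", C = "T", G = "A", T = "C")
  ref <- sample(bases, aln$L, replace = TRUE)
  out <- matrix(rep(ref, each = nrow(aln$seq)), nrow(aln$seq), aln$L,
                dimnames = list(aln$meta$sample_id, NULL))
  if (ncol(aln$seq) > 0) {
    alt <- partner[ref[aln$sites]]
    for (j in seq_along(aln$sites)) {
      hit <- aln$seq[, j] == 1L
      out[hit, aln$sites[j]] <- alt[j]
    }
  }
  write_fasta(out, fasta_path)
  write.table(aln$meta[, c("sample_id", "population", "age_yBP")],
              meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, meta = meta_path))
}

#' Reference table I/O
#'
#' Tab-separated text with a single header row: `model`, the eight
#' parameter columns, then the statistic panel in panel order.
#'
#' @param tab a `reference_table`.
#' @param path TSV path.
#' @export
write_reference_table <- function(tab, path) {
  tmp <- paste0(path, ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  write.table(as.data.frame(tab), tmp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  file.rename(tmp, path)
  ok <- TRUE
  invisible(path)
}

#' @rdname write_reference_table
#' @return `read_reference_table`: the table, classed `reference_table`.
#' @export
read_reference_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("model", param_names())
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stop("not a reference table, missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(tab)) stop("reference table contains missing values")
  class(tab) <- c("reference_table", "data.frame")
  tab
}

#' Read a plain-text key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; values that look
#' numeric are converted. The same file drives the command-line interface
#' and scripted use.
#'
#' @param path config file path.
#' @param defaults named list the file entries are merged into.
#' @return Named list.
#' @export
read_config <- function(path, defaults = list()) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: '", ln, "'")
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
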