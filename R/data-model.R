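#' Read and write genes-by-lanes count tables
#'
#' Count tables are tab-delimited with a `gene_id` first column and one
#' column of non-negative integer read counts per lane. `read_counts()`
#' returns a tibble in that layout; `write_counts()` writes one.
#'
#' @param path Path to a tab-delimited count table.
#' @return A tibble with a character `gene_id` column followed by one
#'   numeric column per lane.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), L1 = c(3, 0), L2 = c(1, 9))
#' write_counts(counts, tf)
#' read_counts(tf)
read_counts <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_counts(out)
  out
}

#' @rdname read_counts
#' @param counts A counts tibble (`gene_id` plus one numeric column per lane).
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts, integer_counts = FALSE)
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read a gene-feature table
#'
#' Tab-delimited with columns `gene_id`, `gc` (fraction of G and C
#' nucleotides, in \[0, 1\]), `length_bp`, and optionally `mappability`.
#'
#' @param path Path to the table.
#' @return A tibble of per-gene features.
#' @export
read_gene_features <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    .default = readr::col_double()
  ))
  validate_features(out)
  out
}

#' Read a lane-metadata table
#'
#' Tab-delimited with columns `lane_id`, `condition`, and optionally
#' `library`, `flowcell`, `protocol`.
#'
#' @param path Path to the table.
#' @return A tibble of per-lane metadata.
#' @export
read_lane_metadata <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("lane_id", "condition") %in% names(out))) {
    stop("lane metadata must have columns 'lane_id' and 'condition'", call. = FALSE)
  }
  if (anyDuplicated(out$lane_id)) stop("duplicate lane_id in metadata", call. = FALSE)
  out
}

#' GC-content of nucleotide sequences
#'
#' The GC fraction is (#G + #C) / (#A + #C + #G + #T), case-insensitive.
#' `N` bases are excluded from the denominator; any other character is an
#' error. A sequence with no counted bases (empty, or all `N`) has
#' undefined GC and raises an error.
#'
#' @param sequence Character vector of nucleotide sequences
#'   (A/C/G/T/N, either case).
#' @return Numeric vector of GC fractions in \[0, 1\].
#' @export
#' @examples
#' compute_gc(c("GGCC", "ATAT", "ATGCN"))
compute_gc <- function(sequence) {
  if (!is.character(sequence) || length(sequence) == 0) {
    stop("'sequence' must be a non-empty character vector", call. = FALSE)
  }
  vapply(toupper(sequence), function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
    if (length(bad) > 0) {
      stop("sequence contains unsupported characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    counted <- chars[chars != "N"]
    if (length(counted) == 0) {
      stop("GC-content undefined: sequence empty or all-N", call. = FALSE)
    }
    sum(counted %in% c("G", "C")) / length(counted)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Gene features from a FASTA file
#'
#' Reads one record per gene and computes per-gene GC fraction and
#' length in bp.
#'
#' @param path Path to a FASTA file of gene sequences.
#' @return A tibble with columns `gene_id`, `gc`, `length_bp`.
#' @export
features_from_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  tibble::tibble(
    gene_id = names(seqs),
    gc = compute_gc(as.character(seqs)),
    length_bp = Biostrings::width(seqs)
  )
}

#' Filter genes with low counts in every condition
#'
#' A gene is retained if its average read count reaches `threshold` in at
#' least one biological condition, i.e. gene j is dropped when
#' \eqn{\max_k \bar y_{jk} < } `threshold` over conditions k. Lanes are
#' never dropped and gene order is preserved.
#'
#' @param counts Counts tibble (`gene_id` plus one column per lane).
#' @param meta Lane metadata with `lane_id` and `condition`; every lane
#'   in `counts` must appear exactly once.
#' @param threshold Positive mean-count cutoff (default 10).
#' @return The filtered counts tibble.
#' @export
filter_low_counts <- function(counts, meta, threshold = 10) {
  validate_counts(counts)
  stopifnot(threshold > 0)
  mat <- counts_matrix(counts)
  cond <- lane_conditions(meta, colnames(mat))
  cond_means <- vapply(
    split(seq_len(ncol(mat)), cond),
    function(idx) rowMeans(mat[, idx, drop = FALSE]),
    numeric(nrow(mat))
  )
  keep <- apply(cond_means, 1, max) >= threshold
  counts[keep, , drop = FALSE]
}

# ---- internal helpers -------------------------------------------------

validate_counts <- function(counts, integer_counts = TRUE) {
  if (!is.data.frame(counts) || ncol(counts) < 2) {
    stop("counts must be a data frame with 'gene_id' plus at least one lane column",
         call. = FALSE)
  }
  if (names(counts)[1] != "gene_id") {
    stop("first column of a counts table must be 'gene_id'", call. = FALSE)
  }
  if (anyDuplicated(counts$gene_id)) stop("duplicate gene_id", call. = FALSE)
  if (anyDuplicated(names(counts))) stop("duplicate lane ids", call. = FALSE)
  vals <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("lane columns must be numeric", call. = FALSE)
  if (anyNA(vals) || any(vals < 0)) {
    stop("counts must be non-negative and non-missing", call. = FALSE)
  }
  if (integer_counts && any(vals != round(vals))) {
    stop("counts must be integral", call. = FALSE)
  }
  invisible(counts)
}

validate_features <- function(features) {
  need <- c("gene_id", "gc", "length_bp")
  if (!all(need %in% names(features))) {
    stop("gene features must have columns gene_id, gc, length_bp", call. = FALSE)
  }
  if (anyDuplicated(features$gene_id)) stop("duplicate gene_id in features", call. = FALSE)
  if (any(features$gc < 0 | features$gc > 1)) stop("gc must be in [0, 1]", call. = FALSE)
  if (any(features$length_bp < 1)) stop("length_bp must be >= 1", call. = FALSE)
  invisible(features)
}

counts_matrix <- function(counts) {
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}

matrix_to_counts <- function(mat) {
  tibble::as_tibble(mat, rownames = "gene_id")
}

# Condition of each lane, in the column order of the count matrix.
lane_conditions <- function(meta, lane_ids) {
  if (!all(lane_ids %in% meta$lane_id)) {
    stop("metadata missing lanes: ",
         paste(setdiff(lane_ids, meta$lane_id), collapse = ", "), call. = FALSE)
  }
  cond <- meta$condition[match(lane_ids, meta$lane_id)]
  if (anyNA(cond)) stop("every lane needs a condition", call. = FALSE)
  factor(cond, levels = unique(cond))
}

# Features aligned to the gene order of a counts tibble.
align_features <- function(features, counts) {
  validate_features(features)
  missing <- setdiff(counts$gene_id, features$gene_id)
  if (length(missing) > 0) {
    stop("features missing genes: ", paste(head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  features[match(counts$gene_id, features$gene_id), , drop = FALSE]
}
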