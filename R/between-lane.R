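#' Between-lane normalization for sequencing depth
#'
#' Adjusts distributional differences between lanes, applied after
#' within-lane GC normalization and before differential expression
#' testing.
#'
#' `between_lane_scaling()` multiplies each lane by a single factor
#' \eqn{\bar s / s_i}, where \eqn{s_i} is the lane statistic (total
#' count, or the upper quartile / median of the counts of genes with a
#' nonzero count in at least one lane) and \eqn{\bar s} the geometric
#' mean of the lane statistics, then rounds.
#'
#' `between_lane_fq()` is full-quantile normalization across lanes: the
#' reference at each rank is the median across lanes of that order
#' statistic, and each lane's counts are replaced by the reference
#' values at their within-lane ranks. Tied counts within a lane receive
#' the mean of their candidate reference values, so equal inputs map to
#' equal outputs. Results are rounded to the nearest integer.
#'
#' @param counts Counts tibble with at least two lanes.
#' @param statistic Lane statistic for scaling: `"total"`, `"upper"`,
#'   or `"median"`.
#' @return Normalized counts tibble with the shape and ids of the input.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("g1", "g2"), A = c(10, 30), B = c(20, 60))
#' between_lane_scaling(counts, "total")
between_lane_scaling <- function(counts, statistic = c("total", "upper", "median")) {
  statistic <- match.arg(statistic)
  validate_counts(counts)
  mat <- counts_matrix(counts)
  if (ncol(mat) < 2) stop("need at least two lanes", call. = FALSE)
  if (any(colSums(mat) == 0)) stop("lane with all-zero counts", call. = FALSE)
  expressed <- rowSums(mat) > 0  # quantile statistics ignore never-seen genes
  s <- switch(statistic,
    total  = colSums(mat),
    upper  = apply(mat[expressed, , drop = FALSE], 2, quantile, probs = 0.75),
    median = apply(mat[expressed, , drop = FALSE], 2, median)
  )
  if (any(s == 0)) stop("lane statistic is zero; choose another statistic", call. = FALSE)
  s_bar <- exp(mean(log(s)))
  matrix_to_counts(round(sweep(mat, 2, s_bar / s, `*`)))
}

#' @rdname between_lane_scaling
#' @export
between_lane_fq <- function(counts) {
  validate_counts(counts)
  mat <- counts_matrix(counts)
  if (ncol(mat) < 2) stop("need at least two lanes", call. = FALSE)
  sorted <- apply(mat, 2, sort)
  ref <- apply(sorted, 1, median)
  out <- apply(mat, 2, fq_assign, ref = ref)
  dimnames(out) <- dimnames(mat)
  matrix_to_counts(round(out))
}

# Map one lane onto reference order statistics; tie groups get the mean
# of the reference values at the ranks they jointly occupy.
fq_assign <- function(x, ref) {
  ord <- order(x)
  vals <- numeric(length(x))
  vals[ord] <- ref
  for (idx in split(seq_along(x), x)) {
    if (length(idx) > 1) vals[idx] <- mean(vals[idx])
  }
  vals
}
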