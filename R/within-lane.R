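#' Stratify genes into equally-sized GC-content bins
#'
#' Genes are sorted by GC fraction (ties broken by `gene_id`) and split
#' into `K` consecutive bins whose sizes differ by at most one gene; when
#' `K` does not divide the gene count, the lowest-GC bins take the extra
#' gene. Bin index is therefore non-decreasing in GC.
#'
#' @param features Gene-feature tibble with `gene_id` and `gc`.
#' @param K Number of bins, between 1 and the number of genes.
#' @return A tibble with columns `gene_id`, `gc`, `bin` (integer in 1..K),
#'   in the input gene order.
#' @export
#' @examples
#' feats <- tibble::tibble(gene_id = paste0("g", 1:7),
#'                         gc = seq(0.3, 0.6, length.out = 7),
#'                         length_bp = 1000)
#' dplyr::count(make_gc_bins(feats, K = 3), bin)
make_gc_bins <- function(features, K) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1)
  J <- nrow(features)
  if (K > J) stop("K must not exceed the number of genes", call. = FALSE)
  K <- as.integer(K)
  if (length(unique(features$gc)) == 1 && K > 1) {
    warning("all genes have identical GC; collapsing to a single bin")
    K <- 1L
  }
  sizes <- rep(J %/% K, K)
  if (J %% K > 0) sizes[seq_len(J %% K)] <- sizes[seq_len(J %% K)] + 1L
  ord <- order(features$gc, features$gene_id)
  bin <- integer(J)
  bin[ord] <- rep(seq_len(K), times = sizes)
  tibble::tibble(gene_id = features$gene_id, gc = features$gc, bin = bin)
}

#' Within-lane normalization of one lane of log-counts
#'
#' These are the per-lane building blocks operating on a vector of
#' log-counts \eqn{y_j} for one lane.
#'
#' `loess_normalize()` regresses \eqn{y_j} on GC-content \eqn{x_j} with
#' robust local regression and shifts the residuals back to the count
#' scale: \eqn{y'_j = y_j - \hat y_j + T(y_1, \ldots, y_J)}, with
#' \eqn{T} the median by default.
#'
#' `global_scaling_normalize()` shifts each GC stratum by the difference
#' between the global summary and the stratum summary:
#' \eqn{y'_j = y_j - T(y_{j'} : j' \in k(j)) + T(y_1, \ldots, y_J)}.
#'
#' `full_quantile_normalize_within()` matches the full count
#' distribution across GC strata: within each bin values are sorted, the
#' reference quantile at each rank is the median across bins of that
#' order statistic (interpolated on the \[0, 1\] rank grid when bin sizes
#' differ by one), and every gene receives the reference value at its
#' within-bin rank. Ties keep input order (stable sort).
#'
#' @param y Numeric vector of log-scale counts for one lane.
#' @param gc Numeric vector of GC fractions aligned to `y`.
#' @param span Loess span in (0, 1\]; default 2/3.
#' @param summary_fn Summary statistic `T`; the median by default,
#'   `upper_quartile` is the common alternative.
#' @return Numeric vector of normalized log-scale values, same length
#'   and order as `y`.
#' @export
loess_normalize <- function(y, gc, span = 2/3, summary_fn = stats::median) {
  stopifnot(length(y) == length(gc), span > 0, span <= 1)
  if (length(y) < 10) stop("need at least 10 genes for loess normalization", call. = FALSE)
  if (any(gc < 0 | gc > 1)) stop("gc must be in [0, 1]", call. = FALSE)
  if (length(unique(gc)) == 1) {
    stop("GC-content is constant across genes; loess fit is undefined", call. = FALSE)
  }
  fit <- loess(y ~ gc, span = span, degree = 2, family = "symmetric",
               control = loess.control(surface = "direct", iterations = 4))
  y - fit$fitted + summary_fn(y)
}

#' @rdname loess_normalize
#' @param bin Integer vector of GC-bin indices aligned to `y` (the `bin`
#'   column of [make_gc_bins()]).
#' @export
global_scaling_normalize <- function(y, bin, summary_fn = stats::median) {
  stopifnot(length(y) == length(bin))
  if (anyNA(bin)) stop("every gene needs a bin", call. = FALSE)
  bin_stat <- tapply(y, bin, summary_fn)
  y - as.numeric(bin_stat[as.character(bin)]) + summary_fn(y)
}

#' @rdname loess_normalize
#' @export
full_quantile_normalize_within <- function(y, bin) {
  stopifnot(length(y) == length(bin))
  groups <- split(seq_along(y), bin)
  if (length(groups) == 0) stop("no GC bins", call. = FALSE)
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("empty GC bin", call. = FALSE)
  n_ref <- max(sizes)
  p_ref <- (seq_len(n_ref) - 0.5) / n_ref
  # reference quantiles: median across bins of each order statistic,
  # bins one short are put on the common rank grid by interpolation
  qmat <- vapply(groups, function(idx) {
    s <- sort(y[idx])
    if (length(s) == n_ref) s
    else approx((seq_along(s) - 0.5) / length(s), s, xout = p_ref, rule = 2)$y
  }, numeric(n_ref))
  ref <- apply(as.matrix(qmat), 1, median)
  out <- numeric(length(y))
  for (idx in groups) {
    n <- length(idx)
    ord <- order(y[idx])  # stable: ties keep input order
    vals <- if (n == n_ref) ref
            else approx(p_ref, ref, xout = (seq_len(n) - 0.5) / n, rule = 2)$y
    out[idx[ord]] <- vals
  }
  out
}

#' Within-lane GC-content normalization of a count table
#'
#' Applies one of the three within-lane procedures independently to each
#' lane. Counts are log-transformed as `log(count + delta)`, normalized
#' on the log scale, exponentiated back, floored at zero, and rounded to
#' the nearest integer (half-to-even).
#'
#' @param counts Counts tibble (`gene_id` plus one column per lane).
#' @param features Gene-feature tibble covering every gene in `counts`.
#' @param method `"full"` (full-quantile, default), `"loess"`,
#'   `"median"`, or `"upper"` (global scaling by median or upper
#'   quartile).
#' @param K Number of GC bins for the binned methods. The default 10
#'   suits a moderate GC effect; use around 50 when the effect is strong.
#' @param span Loess span for `method = "loess"`.
#' @param delta Offset added before taking logs (default 1).
#' @return Normalized counts tibble with the shape and ids of the input.
#'   Pair with [counts_to_offsets()] to obtain the matching offsets.
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 300, seed = 7))
#' norm <- normalize_within_lane(sim$counts, sim$features, method = "full", K = 10)
normalize_within_lane <- function(counts, features,
                                  method = c("full", "loess", "median", "upper"),
                                  K = 10, span = 2/3, delta = 1) {
  method <- match.arg(method)
  validate_counts(counts)
  features <- align_features(features, counts)
  mat <- counts_matrix(counts)
  logm <- log(mat + delta)
  if (method %in% c("full", "median", "upper")) {
    bin <- make_gc_bins(features, K)$bin
  }
  norm_log <- apply(logm, 2, function(y) {
    switch(method,
      loess  = loess_normalize(y, features$gc, span = span),
      median = global_scaling_normalize(y, bin, summary_fn = stats::median),
      upper  = global_scaling_normalize(y, bin, summary_fn = upper_quartile),
      full   = full_quantile_normalize_within(y, bin)
    )
  })
  dimnames(norm_log) <- dimnames(mat)
  matrix_to_counts(round(pmax(exp(norm_log) - delta, 0)))
}

#' Normalization offsets from raw and normalized counts
#'
#' Offsets encode a normalization as the per-entry difference between
#' the normalized and raw counts, so that a count model can consume raw
#' counts plus offsets instead of modified counts. On the default log
#' scale, `offset = log(normalized + delta) - log(raw + delta)`;
#' `scale = "count"` gives the literal difference `normalized - raw`.
#'
#' @param raw,normalized Counts tibbles of identical shape and ids.
#' @param delta Log-offset constant (default 1).
#' @param scale `"log"` (default) or `"count"`.
#' @return A tibble with the shape of the inputs holding the offsets.
#' @export
counts_to_offsets <- function(raw, normalized, delta = 1, scale = c("log", "count")) {
  scale <- match.arg(scale)
  validate_counts(raw)
  validate_counts(normalized)
  if (!identical(dim(raw), dim(normalized)) ||
      !identical(names(raw), names(normalized)) ||
      !identical(raw$gene_id, normalized$gene_id)) {
    stop("raw and normalized tables must share shape and ids", call. = FALSE)
  }
  rm_ <- counts_matrix(raw)
  nm_ <- counts_matrix(normalized)
  off <- if (scale == "log") log(nm_ + delta) - log(rm_ + delta) else nm_ - rm_
  matrix_to_counts(off)
}

upper_quartile <- function(x) as.numeric(quantile(x, 0.75))
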